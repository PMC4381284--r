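# Independent oracles used by the test suite.  Each is deliberately coded
# against the definitions, not the package's implementation paths:
# exhaustive recursion for structure enumeration, a recursive loop walk for
# element annotation, direct combinatorics for the exact tests, and grid
# refinement for the logistic likelihood.

ALL_CLASSES <- c("loop5", "loop3", "int_loop", "mb_loop",
                 "h_loop", "b_loop", "one_bb", "stem")

oracle_pair_weight <- function(a, b, w = c(GC = 3, AU = 2, GU = 1)) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = w[["GC"]], "AU" = w[["AU"]], "GU" = w[["GU"]], -1)
}

# every nested structure of seq as a list of pair tables (plain recursion)
oracle_enumerate <- function(seq, min_hairpin = 3) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(bases)
    rec <- function(i, j) {
        if (i >= j) return(list(integer(0)))
        # case: i unpaired
        out <- lapply(rec(i + 1, j), function(ps) ps)
        # case: i paired with k
        ks <- if (i + min_hairpin + 1 <= j) (i + min_hairpin + 1):j
              else integer(0)
        for (k in ks) {
            if (oracle_pair_weight(bases[i], bases[k]) < 0) next
            left <- rec(i + 1, k - 1)
            right <- rec(k + 1, j)
            for (L in left) for (R in right)
                out[[length(out) + 1]] <- rbind(c(i, k),
                                                matrix(L, ncol = 2),
                                                matrix(R, ncol = 2))
        }
        out
    }
    if (n < 2) return(list(rep(0L, n)))
    lapply(rec(1, n), function(ps) {
        p <- rep(0L, n)
        ps <- matrix(ps, ncol = 2)
        if (nrow(ps)) {
            p[ps[, 1]] <- as.integer(ps[, 2])
            p[ps[, 2]] <- as.integer(ps[, 1])
        }
        p
    })
}

oracle_structure_weight <- function(seq, p, w = c(GC = 3, AU = 2, GU = 1)) {
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    idx <- which(p > seq_along(p))
    if (!length(idx)) return(0)
    sum(vapply(idx, function(i)
        oracle_pair_weight(bases[i], bases[p[i]], w), numeric(1)))
}

# recursive loop walk: labels per position, coded independently of
# annotate()'s enclosing-pair bookkeeping
oracle_annotate <- function(p) {
    n <- length(p)
    labels <- character(n)
    labels[p > 0] <- "stem"

    # direct children helices of the open interval (a..b), skipping subtrees
    children_of <- function(a, b) {
        kids <- list()
        i <- a
        while (i <= b) {
            if (p[i] > i) {
                kids[[length(kids) + 1]] <- c(i, p[i])
                i <- p[i] + 1
            } else i <- i + 1
        }
        kids
    }

    walk_pair <- function(i, j) {
        kids <- children_of(i + 1, j - 1)
        members <- setdiff((i + 1):(j - 1),
                           unlist(lapply(kids, function(k) k[1]:k[2])))
        members <- members[p[members] == 0]
        if (j - i > 1 && length(members)) {
            lab <- if (length(kids) == 0) {
                "h_loop"
            } else if (length(kids) == 1) {
                s5 <- kids[[1]][1] - i - 1
                s3 <- j - kids[[1]][2] - 1
                if (s5 > 0 && s3 > 0) "int_loop"
                else if (max(s5, s3) == 1) "one_bb"
                else "b_loop"
            } else "mb_loop"
            labels[members] <<- lab
        }
        for (k in kids) walk_pair(k[1], k[2])
    }

    roots <- children_of(1, n)
    for (k in roots) walk_pair(k[1], k[2])
    # exterior positions
    ext <- which(p == 0 & labels == "")
    if (length(ext)) {
        if (!length(roots)) {
            labels[ext] <- "loop5"
        } else {
            first_p <- roots[[1]][1]
            last_p <- roots[[length(roots)]][2]
            for (i in ext) {
                if (i < first_p) labels[i] <- "loop5"
                else if (i > last_p) labels[i] <- "loop3"
            }
            # segments between exterior helices: 5' half -> loop3,
            # 3' half (incl. odd middle) -> loop5
            if (length(roots) > 1) {
                for (t in seq_len(length(roots) - 1)) {
                    a <- roots[[t]][2] + 1
                    b <- roots[[t + 1]][1] - 1
                    if (a > b) next
                    seg <- a:b
                    m <- length(seg)
                    half3 <- seg[seq_len(m %/% 2)]
                    labels[half3] <- "loop3"
                    labels[setdiff(seg, half3)] <- "loop5"
                }
            }
        }
    }
    labels
}

# random RNA string helper for property tests
rand_rna <- function(len, bases = c("A", "C", "G", "U")) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
}

# two-sided Fisher p by direct enumeration over tables with fixed margins
oracle_fisher <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r1 <- a + b; c1 <- a + c; N <- a + b + c + d
    xs <- max(0, r1 + c1 - N):min(r1, c1)
    probs <- vapply(xs, function(x)
        choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1), numeric(1))
    p_obs <- probs[xs == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U as the count of pairwise wins plus half the ties
oracle_mann_whitney_u <- function(a, b) {
    u <- 0
    for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
    u
}

# logistic log-likelihood maximizer by iterative grid refinement
oracle_logit_grid <- function(y, x, lim = 8, steps = 5) {
    ll <- function(b0, b1) {
        eta <- b0 + b1 * x
        sum(y * eta - log1p(exp(eta)))
    }
    c0 <- 0; c1 <- 0; width <- lim
    for (s in seq_len(steps)) {
        g0 <- seq(c0 - width, c0 + width, length.out = 41)
        g1 <- seq(c1 - width, c1 + width, length.out = 41)
        vals <- outer(g0, g1, Vectorize(ll))
        best <- arrayInd(which.max(vals), dim(vals))
        c0 <- g0[best[1]]; c1 <- g1[best[2]]
        width <- width / 10
    }
    c(b0 = c0, b1 = c1)
}

# write a temporary file with content, returning its path
tmp_file <- function(lines, ext = ".txt") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}
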