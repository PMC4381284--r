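# Desk-scale folding engine: a deterministic maximum-pair-weight
# (Nussinov-style) dynamic program, bounded suboptimal enumeration, and
# ss-count aggregation.  Scoring is a hydrogen-bond-count stand-in
# (GC=3, AU=2, GU=1), not a Turner free-energy model: it keeps the engine
# exhaustively verifiable and matches the hydrogen-bond semantics of the
# H-b accessibility index.  Scores are reported negated (more negative =
# more stable) to match the usual energy convention; external CT/ss-count
# files are the route to folder-faithful numbers.

#' Folding parameters
#'
#' @param pair_weights named numeric: hydrogen-bond weights for GC, AU and
#'   GU pairs (unitless; defaults 3, 2, 1).
#' @param min_hairpin minimum number of unpaired nucleotides a hairpin loop
#'   must span (steric minimum, default 3).
#' @param enum_cap hard length cap for exhaustive enumeration (default 40 nt).
#' @param suboptimal_window score width (in weight units) for suboptimal
#'   enumeration; default 5\% of the optimal score.
#' @param max_structures budget guard on the number of structures the
#'   enumerator may materialize per enumeration step; a truncated
#'   enumeration is flagged \code{complete = FALSE}.
#' @return list of class \code{fold_params}.
#' @export
fold_params <- function(pair_weights = c(GC = 3, AU = 2, GU = 1),
                        min_hairpin = 3L, enum_cap = 40L,
                        suboptimal_window = NULL,
                        max_structures = 5000L) {
    if (any(pair_weights <= 0)) stop("pair weights must be positive")
    if (length(setdiff(c("GC", "AU", "GU"), names(pair_weights))))
        stop("pair_weights must name GC, AU and GU")
    if (min_hairpin < 3L) stop("min_hairpin must be >= 3")
    structure(list(pair_weights = pair_weights,
                   min_hairpin = as.integer(min_hairpin),
                   enum_cap = as.integer(enum_cap),
                   suboptimal_window = suboptimal_window,
                   max_structures = as.integer(max_structures)),
              class = "fold_params")
}

mask_from_interval <- function(n, forbidden) {
    mask <- rep(FALSE, n)
    if (!is.null(forbidden) && length(forbidden)) {
        forbidden <- as.integer(forbidden)
        if (any(forbidden < 1L | forbidden > n))
            stop("forbidden interval outside 1..", n)
        mask[forbidden] <- TRUE
    }
    mask
}

#' Optimal fold under the hydrogen-bond-count score
#'
#' Maximizes total pair weight subject to the minimum hairpin span and pair
#' legality, with a deterministic traceback (pairing preferred over
#' bifurcation, outermost partner first).  The recorded \code{energy} is
#' the negated weight.  An unpairable sequence returns the open chain with
#' score 0.
#'
#' @param seq RNA string.
#' @param params a \code{\link{fold_params}} object.
#' @return a \code{secondary_structure} with \code{energy} set.
#' @export
fold_optimal <- function(seq, params = fold_params()) {
    fold_constrained(seq, params, forbidden = integer(0))
}

#' Optimal fold with positions forced single-stranded
#'
#' Same dynamic program as \code{\link{fold_optimal}} with the given
#' positions masked from pairing (used for the target-opening cost: the
#' binding site is forced completely open).
#'
#' @param seq RNA string.
#' @param params a \code{\link{fold_params}} object.
#' @param forbidden integer vector of 1-based positions kept unpaired.
#' @return a \code{secondary_structure} with \code{energy} set.
#' @export
fold_constrained <- function(seq, params = fold_params(), forbidden = integer(0)) {
    seq <- normalize_rna(seq)
    codes <- seq_to_codes(seq)
    mask <- mask_from_interval(length(codes), forbidden)
    w <- params$pair_weights
    res <- .fold_dp(codes, w[["GC"]], w[["AU"]], w[["GU"]],
                    params$min_hairpin, mask)
    new_secondary_structure(seq, res$pairs, energy = -res$weight)
}

# lexicographic order of pair tables, used for deterministic tie-breaking
order_pair_tables <- function(tables) {
    if (length(tables) <= 1L) return(seq_along(tables))
    keys <- vapply(tables, function(p)
        paste(sprintf("%05d", p), collapse = ""), character(1))
    order(keys)
}

#' Structure ensemble container
#'
#' Structures of one sequence, sorted best score first with lexicographic
#' pair-table tie-break.
#'
#' @param sequence RNA string shared by all structures.
#' @param structures list of \code{secondary_structure}s on it.
#' @param complete logical: FALSE when the enumeration budget truncated the
#'   set.
#' @return object of class \code{structure_ensemble}.
#' @export
structure_ensemble <- function(sequence, structures, complete = TRUE) {
    if (!length(structures)) stop("ensemble must be non-empty")
    seqs <- vapply(structures, function(s) s$sequence, character(1))
    if (any(seqs != sequence))
        stop("all structures must share the ensemble sequence")
    scores <- vapply(structures, function(s) s$energy, numeric(1))
    ord <- order(scores, order_pair_tables(lapply(structures, `[[`, "pairs")))
    structure(list(sequence = sequence, structures = structures[ord],
                   scores = scores[ord], complete = isTRUE(complete)),
              class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
    cat("structure_ensemble:", length(x$structures), "structure(s) of a",
        nchar(x$sequence), "nt sequence; scores",
        format(x$scores[1]), "..", format(x$scores[length(x$scores)]),
        if (!x$complete) "(truncated by budget)" else "", "\n")
    invisible(x)
}

#' Enumerate (sub)optimal structures
#'
#' Three modes: \code{window} finite — every structure whose score lies
#' within \code{window} weight units of the optimum (branch-and-bound,
#' duplicate-free, any length, budget-guarded); \code{window = Inf} —
#' every legal nested structure (only for sequences up to
#' \code{params$enum_cap}); \code{k} — the k best structures, found by
#' deepening the window from 0 until at least k are in hand (ties broken
#' lexicographically by pair table).
#'
#' @param seq RNA string.
#' @param params a \code{\link{fold_params}}.
#' @param window score window (weight units); default
#'   \code{params$suboptimal_window}, itself defaulting to 5\% of the
#'   optimal score.
#' @param k number of best structures wanted (overrides \code{window}).
#' @return a \code{structure_ensemble}.
#' @export
enumerate_structures <- function(seq, params = fold_params(),
                                 window = NULL, k = NULL) {
    seq <- normalize_rna(seq)
    n <- nchar(seq)
    codes <- seq_to_codes(seq)
    w <- params$pair_weights
    mask <- rep(FALSE, n)

    run_enum <- function(deficit, budget = params$max_structures) {
        .enum_dp(codes, w[["GC"]], w[["AU"]], w[["GU"]], params$min_hairpin,
                 mask, deficit, as.numeric(budget))
    }
    to_ensemble <- function(res) {
        structs <- mapply(function(p, wt)
            new_secondary_structure(seq, p, energy = -wt),
            res$pairs, res$weights, SIMPLIFY = FALSE)
        # a truncated enumeration must still contain the optimal fold
        if (!res$complete || !length(structs)) {
            opt <- fold_optimal(seq, params)
            if (!any(vapply(structs, function(s)
                    identical(s$pairs, opt$pairs), logical(1))))
                structs <- c(list(opt), structs)
        }
        structure_ensemble(seq, structs, complete = res$complete)
    }

    if (!is.null(k)) {
        k <- as.integer(k)
        if (k < 1L) stop("k must be positive")
        budget <- min(params$max_structures, max(1000L, 50L * k))
        deficit <- 0
        repeat {
            res <- run_enum(deficit, budget)
            if (length(res$pairs) >= k || !res$complete) break
            # an exhaustive (complete) enumeration smaller than k is final
            if (deficit > max(1, res$optimal_weight)) break
            deficit <- deficit + 1
        }
        ens <- to_ensemble(res)
        if (length(ens$structures) > k) {
            ens$structures <- ens$structures[seq_len(k)]
            ens$scores <- ens$scores[seq_len(k)]
        }
        return(ens)
    }

    if (is.null(window)) window <- params$suboptimal_window
    if (is.null(window)) {
        opt <- .fold_dp(codes, w[["GC"]], w[["AU"]], w[["GU"]],
                        params$min_hairpin, mask)
        window <- 0.05 * opt$weight
    }
    if (!is.finite(window)) {
        if (n > params$enum_cap)
            stop("sequence too long for exhaustive enumeration (",
                 n, " > ", params$enum_cap, "); supply external structures")
        window <- 1e15
    }
    if (window < 0) stop("window must be >= 0")
    to_ensemble(run_enum(window))
}

#' ss-count of a structure ensemble
#'
#' \code{counts[i]} = number of ensemble structures in which position i is
#' unpaired; the ensemble size is the denominator of the single-stranded
#' propensity.
#'
#' @param ensemble a \code{structure_ensemble}.
#' @return an \code{ss_count} object.
#' @export
ss_count <- function(ensemble) {
    if (!inherits(ensemble, "structure_ensemble"))
        stop("ss_count expects a structure_ensemble")
    n <- nchar(ensemble$sequence)
    counts <- integer(n)
    for (s in ensemble$structures) counts <- counts + (s$pairs == 0L)
    ss_count_vector(counts, length(ensemble$structures))
}

#' Serialize an ensemble as CT files plus an ss-count file
#'
#' Writes \code{<prefix>_<k>.ct} for each structure (best first) and
#' \code{<prefix>.ss} in the Mfold ss-count dialect, so the internal engine
#' and external folders are interchangeable downstream.
#'
#' @param ensemble a \code{structure_ensemble}.
#' @param prefix path prefix for the output files.
#' @return character vector of the files written.
#' @export
write_ensemble <- function(ensemble, prefix) {
    files <- character(0)
    for (k in seq_along(ensemble$structures)) {
        f <- sprintf("%s_%d.ct", prefix, k)
        write_ct(ensemble$structures[[k]], f)
        files <- c(files, f)
    }
    f <- paste0(prefix, ".ss")
    write_ss_count(ss_count(ensemble), f, sequence = ensemble$sequence)
    invisible(c(files, f))
}
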