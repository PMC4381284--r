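# Seeded generator of complete synthetic studies with the statistical
# structure the analysis assumes: two efficacy groups of fixed size
# (VH coded 1, L coded 0), one siRNA target site per folded mRNA, and
# efficacy labels drawn from a logit model linking efficacy to a chosen
# structural feature (beta = 0 gives the null).  Desk-scale mRNAs (tens of
# nt) keep the internal folding engine exact.

#' Configuration of a synthetic study
#'
#' @param n_per_group siRNAs per efficacy group (default 150, the study's
#'   VH/L group sizes).
#' @param mrna_length integer range \code{c(min, max)} of mRNA lengths in
#'   nt (default 50-120, a desk-scale stand-in for full transcripts).
#' @param gc_composition expected GC fraction of generated mRNAs.
#' @param guide_length guide length in nt (19-21; default 19).
#' @param effect_feature feature column driving efficacy, or \code{"none"}.
#' @param beta log-odds of efficacy per unit of the effect feature
#'   (0 = null model).
#' @param beta0 logit intercept; \code{NULL} auto-centres the logit at the
#'   pilot mean of the effect feature so the marginal prevalence is near
#'   1/2 (slope inference is unaffected by this centring).
#' @param seed integer seed; every draw is reproducible given it.
#' @param ensemble_k ensemble size used for the H-b index (k best
#'   structures).
#' @param features \code{"all"} or a character vector of feature columns to
#'   compute (a runtime option for large simulation studies; the values of
#'   the computed columns are identical either way).
#' @param params a \code{\link{fold_params}}.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_per_group = 150L,
                             mrna_length = c(50L, 120L),
                             gc_composition = 0.5,
                             guide_length = 19L,
                             effect_feature = "none",
                             beta = 0, beta0 = NULL,
                             seed = 1L,
                             ensemble_k = 20L,
                             features = "all",
                             params = fold_params()) {
    if (n_per_group < 10L) stop("n_per_group must be >= 10")
    if (guide_length < 19L || guide_length > 21L)
        stop("guide_length must lie in 19..21")
    if (mrna_length[1] < guide_length)
        stop("mRNA length range must cover the guide length")
    known <- c(ELEMENT_CLASSES, "n_unpaired", "max_run", "hb_index",
               "dg_duplex", "dg_break_target", "dg_oligo_self",
               "dg_overall", "gc_percent")
    if (!identical(effect_feature, "none") && !(effect_feature %in% known))
        stop("unknown effect_feature '", effect_feature, "'")
    if (!identical(features, "all")) {
        if (length(bad <- setdiff(features, known)))
            stop("unknown feature(s): ", paste(bad, collapse = ", "))
        if (!identical(effect_feature, "none"))
            features <- union(features, effect_feature)
    }
    structure(list(n_per_group = as.integer(n_per_group),
                   mrna_length = as.integer(mrna_length),
                   gc_composition = gc_composition,
                   guide_length = as.integer(guide_length),
                   effect_feature = effect_feature,
                   beta = beta, beta0 = beta0,
                   seed = as.integer(seed),
                   ensemble_k = as.integer(ensemble_k),
                   features = features, params = params),
              class = "synthetic_config")
}

random_rna <- function(len, gc) {
    paste(sample(RNA_BASES, len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

#' Generate random mRNA records
#'
#' i.i.d. sequences with the configured GC composition and uniform lengths
#' in the configured range; fully reproducible given the seed.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param n number of records (default \code{2 * n_per_group}).
#' @return data.frame with \code{id}, \code{sequence}, \code{length}.
#' @export
generate_mrnas <- function(config, n = 2L * config$n_per_group) {
    set.seed(config$seed)
    lens <- sample(seq(config$mrna_length[1], config$mrna_length[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, random_rna, character(1), gc = config$gc_composition)
    data.frame(id = sprintf("mrna_%04d", seq_len(n)), sequence = seqs,
               length = lens, stringsAsFactors = FALSE)
}

# compute the requested feature columns for one site; `what` is "all" or a
# character vector of columns.  Lazy: folds/ensembles only when needed.
site_features_for <- function(seq, start, end, guide, config) {
    what <- config$features
    need <- function(x) identical(what, "all") || any(x %in% what)
    params <- config$params
    out <- list()
    opt <- NULL
    get_opt <- function() {
        if (is.null(opt)) opt <<- fold_optimal(seq, params)
        opt
    }
    if (need(ELEMENT_CLASSES)) {
        counts <- element_counts_in_site(annotate(get_opt()), c(start, end))
        out[ELEMENT_CLASSES] <- as.list(as.numeric(counts))
    }
    if (need(c("n_unpaired", "max_run", "runs"))) {
        us <- unpaired_stats(get_opt(), c(start, end))
        out$n_unpaired <- us$n_unpaired
        out$max_run <- us$max_run
        out$runs <- paste(us$runs, collapse = ",")
    }
    if (need("hb_index")) {
        ens <- enumerate_structures(seq, params, k = config$ensemble_k)
        out$hb_index <- hb_index(ss_count(ens), seq, c(start, end))
    }
    if (need(c("dg_duplex", "dg_overall"))) {
        out$dg_duplex <- dg_duplex(guide, substr(seq, start, end),
                                   default_nn_params())
    }
    if (need(c("dg_break_target", "dg_overall"))) {
        out$dg_break_target <- dg_break_target(seq, get_opt(),
                                               c(start, end), params)
    }
    if (need(c("dg_oligo_self", "dg_overall"))) {
        out$dg_oligo_self <- dg_oligo_self(guide, params)
    }
    if (need("dg_overall")) {
        out$dg_overall <- dg_overall(out$dg_duplex, out$dg_break_target,
                                     out$dg_oligo_self)
    }
    if (need("gc_percent")) out$gc_percent <- gc_percent(guide)
    out
}

one_draw <- function(config) {
    len <- sample(seq(config$mrna_length[1], config$mrna_length[2]), 1L)
    seq <- random_rna(len, config$gc_composition)
    start <- sample(seq_len(len - config$guide_length + 1L), 1L)
    end <- start + config$guide_length - 1L
    guide <- rna_revcomp(substr(seq, start, end))
    feats <- site_features_for(seq, start, end, guide, config)
    list(seq = seq, start = start, end = end, guide = guide, feats = feats)
}

#' Generate a complete synthetic study
#'
#' Repeatedly draws an mRNA, a uniform target window and the matching guide
#' (exact reverse complement), computes the configured features on the
#' folded mRNA, and draws efficacy from
#' \code{Bernoulli(plogis(beta0 + beta * feature))}; draws are kept until
#' both groups reach \code{n_per_group} (rejection sampling to the fixed
#' VH/L design), bounded at 1e6 draws.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{synthetic_study}: \code{mrnas},
#'   \code{sirnas} (with target-site coordinates and efficacy classes) and
#'   \code{features} (one row per siRNA, VH coded 1 and L coded 0).
#' @export
generate_study <- function(config) {
    set.seed(config$seed)
    eff <- config$effect_feature
    beta0 <- config$beta0
    if (is.null(beta0)) {
        beta0 <- 0
        if (!identical(eff, "none") && config$beta != 0) {
            pilot <- vapply(seq_len(100L), function(k)
                as.numeric(one_draw(config)$feats[[eff]]), numeric(1))
            beta0 <- -config$beta * mean(pilot)
        }
    }
    n_total <- 2L * config$n_per_group
    want <- c(VH = config$n_per_group, L = config$n_per_group)
    have <- c(VH = 0L, L = 0L)
    seqs <- character(n_total); guides <- character(n_total)
    starts <- integer(n_total); ends <- integer(n_total)
    ys <- integer(n_total)
    feat_rows <- vector("list", n_total)
    taken <- 0L
    draws <- 0L
    while (any(have < want)) {
        draws <- draws + 1L
        if (draws > 1e6)
            stop("could not reach the requested group sizes within 1e6 ",
                 "draws; check beta0/beta")
        d <- one_draw(config)
        f <- if (identical(eff, "none")) 0 else as.numeric(d$feats[[eff]])
        y <- rbinom(1L, 1L, plogis(beta0 + config$beta * f))
        grp <- if (y == 1L) "VH" else "L"
        if (have[[grp]] >= want[[grp]]) next
        have[[grp]] <- have[[grp]] + 1L
        taken <- taken + 1L
        seqs[taken] <- d$seq; guides[taken] <- d$guide
        starts[taken] <- d$start; ends[taken] <- d$end
        ys[taken] <- y
        feat_rows[[taken]] <- d$feats
    }
    mids <- sprintf("mrna_%04d", seq_len(taken))
    sids <- sprintf("sirna_%04d", seq_len(taken))
    features <- data.frame(sirna_id = sids, mrna_id = mids,
                           site_start = starts, site_end = ends,
                           efficacy_code = ys, stringsAsFactors = FALSE)
    for (cn in names(feat_rows[[1]]))
        features[[cn]] <- unlist(lapply(feat_rows, `[[`, cn),
                                 use.names = FALSE)
    sirnas <- data.frame(id = sids, guide = guides, target_id = mids,
                         site_start = starts, site_end = ends,
                         efficacy_class = ifelse(ys == 1L, "VH", "L"),
                         stringsAsFactors = FALSE)
    structure(list(mrnas = data.frame(id = mids, sequence = seqs,
                                      length = nchar(seqs),
                                      stringsAsFactors = FALSE),
                   sirnas = sirnas, features = features,
                   beta0 = beta0, config = config, n_draws = draws),
              class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
    cat("synthetic_study:", nrow(x$sirnas), "siRNAs (",
        sum(x$sirnas$efficacy_class == "VH"), "VH /",
        sum(x$sirnas$efficacy_class == "L"), "L ) on",
        nrow(x$mrnas), "mRNAs;", x$n_draws, "draws\n")
    invisible(x)
}

#' Write a synthetic study as pipeline input files
#'
#' Emits the same FASTA and siRNA-table formats the pipeline consumes (and
#' optionally per-mRNA CT + ss-count files from the internal engine), so a
#' synthetic study is indistinguishable from real input at the interface.
#'
#' @param study a \code{synthetic_study} or the fixture study.
#' @param dir output directory (created if needed).
#' @param with_structures also emit CT/ss-count files per mRNA.
#' @param ensemble_k ensemble size for the emitted ss-count files.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir, with_structures = FALSE, ensemble_k = 20L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "mrnas.fasta")
    writeLines(paste0(">", study$mrnas$id, "\n", study$mrnas$sequence), fa)
    tab <- data.frame(id = study$sirnas$id, guide = study$sirnas$guide,
                      target_id = study$sirnas$target_id,
                      efficacy = study$sirnas$efficacy_class,
                      stringsAsFactors = FALSE)
    write.table(tab, file.path(dir, "sirnas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (with_structures) {
        sdir <- file.path(dir, "structures")
        dir.create(sdir, showWarnings = FALSE)
        cfg_params <- if (inherits(study, "synthetic_study"))
            study$config$params else fold_params()
        for (k in seq_len(nrow(study$mrnas))) {
            ens <- enumerate_structures(study$mrnas$sequence[k],
                                        cfg_params, k = ensemble_k)
            write_ct(ens$structures[[1]],
                     file.path(sdir, paste0(study$mrnas$id[k], ".ct")))
            write_ss_count(ss_count(ens),
                           file.path(sdir, paste0(study$mrnas$id[k], ".ss")),
                           sequence = study$mrnas$sequence[k])
        }
    }
    invisible(dir)
}

#' The hand-checked fixture study
#'
#' A tiny fixed study of 6 siRNAs on 3 short mRNAs with deterministic
#' folds, exercising every element class.  Its feature table is shipped at
#' \code{inst/extdata/fixture/expected_features.tsv} (verified by hand
#' during development) and asserted byte-exactly in the test suite.
#'
#' @return list with \code{mrnas}, \code{sirnas} (same shapes as a
#'   \code{synthetic_study}).
#' @export
fixture_study <- function() {
    mrnas <- data.frame(
        id = c("fixA", "fixB", "fixC"),
        sequence = c(
            # exterior tails + stem with internal loop, one-base bulge, hairpin
            "AAGGGGAAGGGAGGGAAAACCCCCCAACCCCAA",
            # two hairpin arms in a multibranch-like exterior arrangement
            "AAGGGAAGCGCAAAAGCGCAAGGGAAACCCAAACCCAA",
            # multibranch with a bulged helix
            "GGCGAAGGGAAAACCCAAGCGAAAGCGAAGCC"),
        stringsAsFactors = FALSE)
    mrnas$length <- nchar(mrnas$sequence)
    pick <- rbind(
        c("fixA", 2L), c("fixA", 15L),
        c("fixB", 1L), c("fixB", 18L),
        c("fixC", 5L), c("fixC", 14L))
    sirnas <- do.call(rbind, lapply(seq_len(nrow(pick)), function(k) {
        seq <- mrnas$sequence[mrnas$id == pick[k, 1]]
        s <- as.integer(pick[k, 2])
        data.frame(id = sprintf("fix_sirna_%d", k),
                   guide = rna_revcomp(substr(seq, s, s + 18L)),
                   target_id = pick[k, 1],
                   efficacy_class = rep(c("VH", "L"), 3L)[k],
                   stringsAsFactors = FALSE)
    }))
    list(mrnas = mrnas, sirnas = sirnas)
}
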