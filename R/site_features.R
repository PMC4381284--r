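# Target-site location and the structural predictors computed per siRNA:
# per-element base counts, unpaired counts and consecutive-unpaired runs,
# and the H-b accessibility index over a structure ensemble.

#' Locate an siRNA's target site on an mRNA
#'
#' Exact-match search of the reverse complement of the guide in the mRNA.
#' With several exact hits the 5'-most wins and a warning lists all hit
#' positions; no mismatch tolerance.
#'
#' @param guide RNA string, 19-21 nt (antisense strand).
#' @param mrna_seq mRNA RNA string.
#' @param sirna_id,mrna_id identifiers used in messages.
#' @return list of class \code{target_site}: \code{mrna_id},
#'   \code{sirna_id}, \code{start}, \code{end} (1-based inclusive).
#' @export
locate_site <- function(guide, mrna_seq, sirna_id = "siRNA", mrna_id = "mRNA") {
    guide <- normalize_rna(guide, "guide")
    mrna_seq <- normalize_rna(mrna_seq, "mRNA sequence")
    target <- rna_revcomp(guide)
    hits <- gregexpr(target, mrna_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L)
        stop("target site not found: reverse complement of guide '",
             sirna_id, "' has no exact match in mRNA '", mrna_id, "'")
    if (length(hits) > 1L)
        warning("guide '", sirna_id, "' matches mRNA '", mrna_id,
                "' at positions ", paste(hits, collapse = ", "),
                "; using the 5'-most")
    start <- hits[1]
    structure(list(mrna_id = mrna_id, sirna_id = sirna_id,
                   start = as.integer(start),
                   end = as.integer(start + nchar(guide) - 1L)),
              class = "target_site")
}

#' Unpaired-base statistics within a site
#'
#' Runs are maximal blocks of unpaired positions inside the window; a run
#' continuing outside the site counts only its inside portion.
#'
#' @param structure a \code{secondary_structure}.
#' @param site integer \code{c(start, end)}, 1-based inclusive.
#' @return list with \code{n_unpaired}, \code{runs} (integer vector of run
#'   lengths, 5' to 3') and \code{max_run}.
#' @export
unpaired_stats <- function(structure, site) {
    p <- structure$pairs
    start <- as.integer(site[1]); end <- as.integer(site[2])
    if (start < 1L || end > length(p) || start > end)
        stop("site out of range")
    unp <- p[start:end] == 0L
    r <- rle(unp)
    runs <- r$lengths[r$values]
    list(n_unpaired = sum(unp),
         runs = as.integer(runs),
         max_run = if (length(runs)) max(runs) else 0L)
}

#' H-b index of a target site
#'
#' The average number of hydrogen bonds the site forms across a structure
#' ensemble: \deqn{Hb = \sum_{i \in site} (1 - c_i/N) b_i} with \eqn{c_i}
#' the ss-count (times unpaired), N the ensemble size, and \eqn{b_i = 3}
#' for G/C bases, 2 otherwise.  Per-base bond weights approximate pair
#' bonds without knowing the partner (ss-count files do not record it); a
#' G or C pairing via GU wobble is therefore counted with 3 bonds instead
#' of 2.  Low values mean an accessible (mostly single-stranded) site.
#'
#' @param ss an \code{ss_count} object covering the site.
#' @param sequence the mRNA RNA string.
#' @param site integer \code{c(start, end)}.
#' @return non-negative real, at most 3 x site length.
#' @export
hb_index <- function(ss, sequence, site) {
    start <- as.integer(site[1]); end <- as.integer(site[2])
    if (start < 1L || end > length(ss$counts) || start > end)
        stop("site outside the ss-count vector")
    if (nchar(sequence) != length(ss$counts))
        stop("sequence and ss-count lengths differ")
    bases <- strsplit(sequence, "", fixed = TRUE)[[1]][start:end]
    b <- ifelse(bases %in% c("G", "C"), 3, 2)
    frac_paired <- 1 - ss$counts[start:end] / ss$n_structures
    sum(frac_paired * b)
}

#' Dichotomize an H-b index at the accessibility cut-point
#'
#' Sites with H-b below the cut-point (default 25) are called accessible:
#' low H-b values were proposed as predictive of high silencing efficacy.
#' The inequality is strict: exactly 25 is inaccessible.
#'
#' @param hb non-negative real (scalar or vector).
#' @param cutpoint positive real, default 25.
#' @return character vector over \{"accessible","inaccessible"\}.
#' @export
classify_accessibility <- function(hb, cutpoint = 25) {
    if (any(hb < 0)) stop("H-b index must be >= 0")
    ifelse(hb < cutpoint, "accessible", "inaccessible")
}

#' Assemble the full per-siRNA feature row
#'
#' Locates the target site, annotates the ensemble's optimal (first)
#' structure for element counts and unpaired statistics, computes the H-b
#' index from the ensemble's ss-count, and adds the thermodynamic and GC
#' features.  The optimal structure alone is annotated; the ensemble enters
#' only through the H-b denominator.
#'
#' @param sirna list/row with \code{id}, \code{guide} and (optionally)
#'   \code{efficacy_class}.
#' @param mrna list/row with \code{id}, \code{sequence}.
#' @param ensemble a \code{structure_ensemble} of the mRNA (its first
#'   structure is the optimal fold).
#' @param params a \code{\link{fold_params}} used for the opening-cost and
#'   self-structure folds.
#' @param nn a nearest-neighbour parameter set
#'   (\code{\link{read_nn_params}}); default the packaged table.
#' @param ss optional \code{ss_count} overriding the ensemble's own.
#' @return one-row data.frame with the documented feature columns.
#' @export
build_feature_vector <- function(sirna, mrna, ensemble,
                                 params = fold_params(),
                                 nn = default_nn_params(), ss = NULL) {
    site <- locate_site(sirna$guide, mrna$sequence,
                        sirna_id = sirna$id, mrna_id = mrna$id)
    opt <- ensemble$structures[[1]]
    ann <- annotate(opt)
    iv <- c(site$start, site$end)
    counts <- element_counts_in_site(ann, iv)
    us <- unpaired_stats(opt, iv)
    if (is.null(ss)) ss <- ss_count(ensemble)
    hb <- hb_index(ss, mrna$sequence, iv)

    site_seq <- substr(mrna$sequence, site$start, site$end)
    dgd <- dg_duplex(sirna$guide, site_seq, nn)
    dgb <- dg_break_target(mrna$sequence, ensemble, iv, params)
    dgs <- dg_oligo_self(sirna$guide, params)
    dgo <- dg_overall(dgd, dgb, dgs)

    eff <- if (!is.null(sirna$efficacy_class)) {
        if (sirna$efficacy_class == "VH") 1L
        else if (sirna$efficacy_class == "L") 0L
        else NA_integer_
    } else NA_integer_

    row <- data.frame(sirna_id = sirna$id, mrna_id = mrna$id,
                      site_start = site$start, site_end = site$end,
                      efficacy_code = eff,
                      t(counts),
                      n_unpaired = us$n_unpaired, max_run = us$max_run,
                      runs = paste(us$runs, collapse = ","),
                      hb_index = hb, dg_duplex = dgd, dg_break_target = dgb,
                      dg_oligo_self = dgs, dg_overall = dgo,
                      gc_percent = gc_percent(sirna$guide),
                      stringsAsFactors = FALSE)
    stopifnot(sum(counts) == site$end - site$start + 1L,
              us$n_unpaired == sum(counts) - counts[["stem"]])
    row
}
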