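# Thermodynamic and composition features: nearest-neighbour duplex free
# energy, target-opening cost, guide self-structure, their net sum, and GC
# content with the study's bins.
#
# Sign conventions: more negative dg_duplex = more stable duplex;
# dg_break_target and dg_oligo_self are reported as negative stabilities
# (more negative = less accessible / more self-structured);
# dg_overall = dg_duplex - dg_break_target - dg_oligo_self, so the opening
# costs always weaken net binding (dg_overall >= dg_duplex).

#' Read a nearest-neighbour parameter file
#'
#' Delimited text, one stack per row: a key \code{XY/WZ} (top strand 5'->3',
#' bottom strand 3'->5') and an energy in kcal/mol, plus the named rows
#' \code{init} (duplex initiation) and \code{terminal_au} (per AU/UA
#' terminal pair).  All 16 Watson-Crick ordered stacks must be present and
#' rotationally consistent (\code{XY/WZ} equals its 180-degree rotation
#' \code{ZW/YX}).
#'
#' @param path parameter file; the packaged default is the Xia et al. 1998
#'   Watson-Crick RNA/RNA set at 37 degrees C.
#' @return list of class \code{nn_params}: \code{stack} (named numeric),
#'   \code{init}, \code{terminal_au}, \code{source_tag}.
#' @export
read_nn_params <- function(path) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     comment.char = "#")
    if (!all(c("key", "energy") %in% names(df)))
        stop("nn parameter file needs columns 'key' and 'energy'")
    tag <- if ("source_tag" %in% names(df)) df$source_tag[1] else basename(path)
    init <- df$energy[df$key == "init"]
    term <- df$energy[df$key == "terminal_au"]
    if (!length(init) || !length(term))
        stop("nn parameter file must contain 'init' and 'terminal_au' rows")
    st <- df[!(df$key %in% c("init", "terminal_au")), ]
    stack <- st$energy
    names(stack) <- st$key
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    tops <- as.vector(outer(names(comp), names(comp), paste0))
    need <- paste0(tops, "/", vapply(tops, function(xy) {
        b <- strsplit(xy, "")[[1]]
        paste0(comp[b[1]], comp[b[2]])
    }, character(1)))
    if (length(miss <- setdiff(need, names(stack))))
        stop("missing stack parameter(s): ", paste(miss, collapse = ", "))
    for (key in need) {
        b <- strsplit(sub("/.*", "", key), "")[[1]]
        rot <- paste0(comp[b[2]], comp[b[1]], "/", b[2], b[1])
        if (abs(stack[[key]] - stack[[rot]]) > 1e-9)
            stop("rotationally inconsistent stacks: ", key, " vs ", rot)
    }
    structure(list(stack = stack, init = init[1], terminal_au = term[1],
                   source_tag = tag),
              class = "nn_params")
}

.nn_cache <- new.env(parent = emptyenv())

#' The packaged nearest-neighbour parameter set
#' @return an \code{nn_params} object (Xia et al. 1998 WC set, 37 C).
#' @export
default_nn_params <- function() {
    if (is.null(.nn_cache$default)) {
        path <- system.file("extdata", "nn_params_xia1998.tsv",
                            package = "siRNAtarget", mustWork = TRUE)
        .nn_cache$default <- read_nn_params(path)
    }
    .nn_cache$default
}

#' GC content of a sequence, in percent
#' @param seq non-empty RNA string.
#' @return real in [0,100].
#' @export
gc_percent <- function(seq) {
    seq <- normalize_rna(seq)
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    100 * sum(bases %in% c("G", "C")) / length(bases)
}

#' GC binning scheme
#'
#' Main bins partition [0,100]: below 25\%, the closed interval [25,55],
#' above 55\%.  Subgroups are the half-open decades [25,35), [35,45),
#' [45,55), [55,65); values outside them get no subgroup.
#'
#' @param main_breaks,main_labels,sub_lower,sub_upper,sub_labels bin edges
#'   and labels; defaults are the study's scheme.
#' @return list of class \code{gc_binning}.
#' @export
gc_binning <- function(main_breaks = c(25, 55),
                       main_labels = c("<25%", "25-55%", ">55%"),
                       sub_lower = c(25, 35, 45, 55),
                       sub_upper = c(35, 45, 55, 65),
                       sub_labels = c("25-34%", "35-44%", "45-54%", "55-64%")) {
    stopifnot(length(main_labels) == length(main_breaks) + 1L,
              length(sub_lower) == length(sub_upper),
              length(sub_labels) == length(sub_lower),
              all(sub_lower < sub_upper))
    structure(list(main_breaks = main_breaks, main_labels = main_labels,
                   sub_lower = sub_lower, sub_upper = sub_upper,
                   sub_labels = sub_labels),
              class = "gc_binning")
}

#' Assign a GC percentage to its main bin and subgroup
#'
#' @param gc numeric vector in [0,100].
#' @param binning a \code{\link{gc_binning}}.
#' @return data.frame with columns \code{main} and \code{subgroup}
#'   (\code{NA} when no subgroup covers the value).
#' @export
gc_bin <- function(gc, binning = gc_binning()) {
    if (any(gc < 0 | gc > 100)) stop("GC percent must lie in [0,100]")
    main <- ifelse(gc < binning$main_breaks[1], binning$main_labels[1],
            ifelse(gc <= binning$main_breaks[2], binning$main_labels[2],
                   binning$main_labels[3]))
    sub <- rep(NA_character_, length(gc))
    for (k in seq_along(binning$sub_lower)) {
        hit <- gc >= binning$sub_lower[k] & gc < binning$sub_upper[k]
        sub[hit] <- binning$sub_labels[k]
    }
    data.frame(main = main, subgroup = sub, stringsAsFactors = FALSE)
}

#' Hybridization free energy of the guide:target duplex
#'
#' Nearest-neighbour sum over consecutive base pairs of the duplex, plus
#' the initiation penalty and a terminal-AU penalty for each AU/UA end.
#' The two strands must be exact reverse complements (wobble disallowed).
#'
#' @param guide guide RNA string (antisense).
#' @param target_site_seq the targeted mRNA window, 5'->3'.
#' @param nn an \code{nn_params} set.
#' @return free energy in kcal/mol (more negative = more stable).
#' @export
dg_duplex <- function(guide, target_site_seq, nn = default_nn_params()) {
    guide <- normalize_rna(guide, "guide")
    target <- normalize_rna(target_site_seq, "target site")
    if (nchar(target) < 2L) stop("duplex must be at least 2 bp")
    if (rna_revcomp(guide) != target)
        stop("guide and target site are not exact reverse complements")
    top <- strsplit(target, "", fixed = TRUE)[[1]]
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    n <- length(top)
    e <- nn$init
    for (i in seq_len(n - 1L)) {
        xy <- paste0(top[i], top[i + 1L])
        key <- paste0(xy, "/", comp[top[i]], comp[top[i + 1L]])
        e <- e + nn$stack[[key]]
    }
    if (top[1] %in% c("A", "U")) e <- e + nn$terminal_au
    if (top[n] %in% c("A", "U")) e <- e + nn$terminal_au
    unname(e)
}

#' Cost of opening the target site
#'
#' The difference between the optimal fold score and the optimal fold with
#' the site forced single-stranded:
#' \code{score(optimal) - score(constrained)}, which is always <= 0 (more
#' negative = less accessible site) and 0 when the site is already unpaired
#' in the optimal fold.  When external CT energies are available for both
#' folds, pass them as structures via \code{constrained}.
#'
#' @param seq mRNA RNA string.
#' @param ensemble_or_structure a \code{structure_ensemble} (its first,
#'   optimal structure is used) or a \code{secondary_structure} with
#'   \code{energy} set.
#' @param site integer \code{c(start, end)}.
#' @param params a \code{\link{fold_params}} for the constrained refold.
#' @param constrained optional externally folded constrained structure with
#'   \code{energy} set (overrides the internal engine).
#' @return free energy in kcal/mol-equivalent score units, <= 0.
#' @export
dg_break_target <- function(seq, ensemble_or_structure, site,
                            params = fold_params(), constrained = NULL) {
    opt <- if (inherits(ensemble_or_structure, "structure_ensemble"))
        ensemble_or_structure$structures[[1]] else ensemble_or_structure
    if (!is.null(constrained)) {
        # external energies supplied for both folds: use them as-is
        opt_score <- opt$energy
        con_score <- constrained$energy
        if (is.na(opt_score) || is.na(con_score))
            stop("external opening cost needs energies on both structures")
    } else {
        # internal mode: both terms from the engine, on the same score
        # scale (an external structure's energy is not comparable)
        opt_score <- fold_optimal(seq, params)$energy
        con_score <- fold_constrained(seq, params,
                                      forbidden = site[1]:site[2])$energy
    }
    d <- opt_score - con_score
    if (d > 1e-9) stop("opening cost came out positive; inconsistent scores")
    min(d, 0)
}

#' Self-structure stability of the guide
#'
#' The score of the guide's optimal self-fold: <= 0, and exactly 0 when the
#' open chain is optimal (no self-structure).
#'
#' @param guide guide RNA string.
#' @param params a \code{\link{fold_params}}.
#' @return free energy in score units, <= 0.
#' @export
dg_oligo_self <- function(guide, params = fold_params()) {
    fold_optimal(guide, params)$energy
}

#' Net binding free energy
#'
#' \code{dg_overall = dg_duplex - dg_break_target - dg_oligo_self}: duplex
#' formation pays for opening the target site and melting guide
#' self-structure, so the result is never more favourable than the duplex
#' term alone.
#'
#' @param dg_duplex duplex hybridization energy.
#' @param dg_break_target target-opening cost, must be <= 0.
#' @param dg_oligo_self guide self-structure term, must be <= 0.
#' @return net energy; always >= \code{dg_duplex}.
#' @export
dg_overall <- function(dg_duplex, dg_break_target, dg_oligo_self) {
    if (any(dg_break_target > 1e-9) || any(dg_oligo_self > 1e-9))
        stop("break-target and self terms must be <= 0 (negative stabilities)")
    dg_duplex - dg_break_target - dg_oligo_self
}
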