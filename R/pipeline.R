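# End-to-end orchestration: inputs -> feature table -> the full result
# bundle (element-distribution table, logistic-regression tables,
# histogram tables, group comparisons, GC and accessibility contingency
# analyses, machine-readable run log).  Every number in the bundle is a
# pure function of the feature table, and re-running with the same inputs
# is bit-reproducible.

#' Pipeline run configuration
#'
#' @param fasta path to the mRNA FASTA file.
#' @param sirna_table path to the siRNA table (TSV/CSV).
#' @param structures_dir optional directory of external per-mRNA CT files
#'   (\code{<mrna id>.ct}); takes precedence over the internal engine.
#' @param ss_count_dir optional directory of ss-count files
#'   (\code{<mrna id>.ss}).
#' @param out_dir output directory for the result bundle.
#' @param params a \code{\link{fold_params}} for the internal engine.
#' @param binning a \code{\link{gc_binning}}.
#' @param hb_cutpoint H-b accessibility cut-point (> 0; default 25).
#' @param robust_ci robust (HC1) CIs for the logistic models (default TRUE).
#' @param normality_rule test-selection rule for group comparisons.
#' @param ensemble_k internal-engine ensemble size for the H-b index.
#' @param seed integer seed recorded in the run log.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(fasta, sirna_table, structures_dir = NULL,
                       ss_count_dir = NULL, out_dir,
                       params = fold_params(), binning = gc_binning(),
                       hb_cutpoint = 25, robust_ci = TRUE,
                       normality_rule = "auto", ensemble_k = 20L,
                       seed = 1L) {
    for (p in c(fasta, sirna_table, structures_dir, ss_count_dir))
        if (!is.null(p) && !file.exists(p))
            stop("input path does not exist: ", p)
    if (hb_cutpoint <= 0) stop("H-b cut-point must be > 0")
    structure(list(fasta = fasta, sirna_table = sirna_table,
                   structures_dir = structures_dir,
                   ss_count_dir = ss_count_dir, out_dir = out_dir,
                   params = params, binning = binning,
                   hb_cutpoint = hb_cutpoint, robust_ci = robust_ci,
                   normality_rule = normality_rule,
                   ensemble_k = as.integer(ensemble_k),
                   seed = as.integer(seed)),
              class = "run_config")
}

#' Compute the feature table for a set of siRNAs and mRNAs
#'
#' For each siRNA the target mRNA is folded (or its external CT structure
#' read), the site located and all predictors assembled.  External CT
#' files, when provided, take precedence over the internal engine; when no
#' ss-count file is given the H-b denominator comes from the internal
#' ensemble.
#'
#' @param mrnas data.frame from \code{\link{read_fasta}}.
#' @param sirnas data.frame from \code{\link{read_sirna_table}}.
#' @param params a \code{\link{fold_params}}.
#' @param structures optional named list (by mRNA id) of
#'   \code{secondary_structure} or \code{structure_ensemble} objects.
#' @param ss_counts optional named list (by mRNA id) of \code{ss_count}
#'   objects.
#' @param ensemble_k internal ensemble size.
#' @param nn nearest-neighbour parameters.
#' @param log_fn optional callback receiving one named list per siRNA
#'   (structured logging).
#' @return feature data.frame, one row per siRNA.
#' @export
compute_features <- function(mrnas, sirnas, params = fold_params(),
                             structures = NULL, ss_counts = NULL,
                             ensemble_k = 20L, nn = default_nn_params(),
                             log_fn = NULL) {
    if (!nrow(sirnas)) stop("empty siRNA table")
    ens_cache <- new.env(parent = emptyenv())
    get_ensemble <- function(mid, seq) {
        if (!is.null(structures) && !is.null(structures[[mid]])) {
            s <- structures[[mid]]
            if (inherits(s, "structure_ensemble")) return(s)
            return(structure_ensemble(s$sequence, list(s)))
        }
        if (is.null(ens_cache[[mid]]))
            ens_cache[[mid]] <- enumerate_structures(seq, params,
                                                     k = ensemble_k)
        ens_cache[[mid]]
    }
    rows <- vector("list", nrow(sirnas))
    for (k in seq_len(nrow(sirnas))) {
        sirna <- sirnas[k, ]
        mi <- which(mrnas$id == sirna$target_id)
        if (!length(mi))
            stop("feature stage: siRNA '", sirna$id,
                 "' targets unknown mRNA '", sirna$target_id, "'")
        mrna <- mrnas[mi[1], ]
        ens <- get_ensemble(mrna$id, mrna$sequence)
        ss <- if (!is.null(ss_counts)) ss_counts[[mrna$id]] else NULL
        rows[[k]] <- tryCatch(
            build_feature_vector(sirna, mrna, ens, params = params,
                                 nn = nn, ss = ss),
            error = function(e)
                stop("feature stage failed for siRNA '", sirna$id, "': ",
                     conditionMessage(e), call. = FALSE))
        if (!is.null(log_fn)) {
            r <- rows[[k]]
            log_fn(list(sirna = r$sirna_id, mrna = r$mrna_id,
                        site = c(r$site_start, r$site_end),
                        n_unpaired = r$n_unpaired,
                        hb_index = round(r$hb_index, 4)))
        }
    }
    do.call(rbind, rows)
}

#' Element-distribution table (unpaired bases by structure class and group)
#'
#' Rows are base counts 0..max observed; columns are element class x
#' efficacy group; a cell counts the siRNAs of that group whose target
#' site contains exactly that many bases of that element class.  A single
#' siRNA contributes to every class column, so column totals equal the
#' group size times the number of classes only in aggregate; zero rows up
#' to the observed maximum are retained.
#'
#' @param features feature data.frame with the 8 element-count columns.
#' @param group_labels factor/character of group labels per row (default
#'   from \code{efficacy_code}: 1 = VH, 0 = L).
#' @return data.frame, first column \code{unpaired_bases}.
#' @export
tabulate_unpaired_by_structure <- function(features, group_labels = NULL) {
    if (!nrow(features)) stop("empty feature table")
    if (is.null(group_labels))
        group_labels <- ifelse(features$efficacy_code == 1L, "VH", "L")
    groups <- c("VH", "L")
    maxu <- max(vapply(ELEMENT_CLASSES,
                       function(cl) max(features[[cl]]), numeric(1)))
    out <- data.frame(unpaired_bases = 0:maxu)
    for (cl in ELEMENT_CLASSES) {
        for (g in groups) {
            v <- features[[cl]][group_labels == g]
            out[[paste(cl, g, sep = "_")]] <-
                vapply(0:maxu, function(u) sum(v == u), numeric(1))
        }
    }
    out
}

hist_table <- function(values, group_labels, value_name) {
    maxv <- max(values, 0)
    out <- data.frame(v = 0:maxv)
    names(out) <- value_name
    for (g in c("VH", "L"))
        out[[g]] <- vapply(0:maxv,
                           function(u) sum(values[group_labels == g] == u),
                           numeric(1))
    out
}

parse_runs <- function(runs) {
    lapply(strsplit(as.character(runs), ",", fixed = TRUE),
           function(x) as.integer(x[nzchar(x)]))
}

#' Full statistical analysis of a feature table
#'
#' The battery run on a feature table: univariable logistic regressions of
#' efficacy on each element class, on the number of unpaired bases and on
#' the longest consecutive-unpaired run; the multivariable model with all
#' 8 element classes; group comparisons of H-b and the three free-energy
#' terms; the H-b cut-point and GC-bin contingency analyses.
#'
#' @param features feature data.frame (all columns present).
#' @param binning a \code{\link{gc_binning}}.
#' @param hb_cutpoint accessibility cut-point.
#' @param robust_ci robust CIs for the logistic fits.
#' @param normality_rule rule for \code{\link{two_group_compare}}.
#' @param p0_gc null proportion for the one-sample GC test (default 0.517,
#'   the literature proportion of effective siRNAs with GC 25-55\%).
#' @return list of class \code{sirna_analysis} with the tables described
#'   above.
#' @export
analyze_features <- function(features, binning = gc_binning(),
                             hb_cutpoint = 25, robust_ci = TRUE,
                             normality_rule = "auto", p0_gc = 0.517) {
    y <- features$efficacy_code
    if (any(is.na(y))) stop("efficacy_code contains NA")
    grp <- ifelse(y == 1L, "VH", "L")

    na_row <- function(name)
        data.frame(predictor = name, coef = NA_real_, se = NA_real_,
                   odds_ratio = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
    # a fit that cannot be run on this table (too few rows, constant or
    # separated predictor) is recorded as an NA row, not a hard stop
    safe_uni <- function(x, name)
        tryCatch(logistic_univariable(y, x, robust = robust_ci,
                                      name = name)$table,
                 error = function(e) na_row(name))
    uni <- do.call(rbind, lapply(ELEMENT_CLASSES, function(cl)
        safe_uni(features[[cl]], cl)))
    # with fixed-length sites the 8 counts sum to the site length, so the
    # joint model is fitted without an intercept (see logistic_multivariable)
    X <- features[ELEMENT_CLASSES]
    const_sum <- length(unique(rowSums(X))) == 1L
    multi <- tryCatch(
        logistic_multivariable(y, X, robust = robust_ci,
                               intercept = !const_sum)$table,
        error = function(e) do.call(rbind, lapply(ELEMENT_CLASSES, na_row)))
    uni_unpaired <- safe_uni(features$n_unpaired, "n_unpaired")
    uni_run <- safe_uni(features$max_run, "max_run")

    table1 <- tabulate_unpaired_by_structure(features, grp)
    fig2 <- hist_table(features$n_unpaired, grp, "unpaired_bases")
    all_runs <- parse_runs(features$runs)
    run_len <- unlist(all_runs)
    run_grp <- rep(grp, lengths(all_runs))
    fig3 <- if (length(run_len)) hist_table(run_len, run_grp, "run_length")
            else data.frame(run_length = integer(0), VH = numeric(0),
                            L = numeric(0))

    cmp_vars <- c("hb_index", "dg_overall", "dg_duplex", "dg_break_target",
                  "gc_percent")
    comparisons <- do.call(rbind, lapply(cmp_vars, function(v) {
        gc <- two_group_compare(features[[v]][grp == "VH"],
                                features[[v]][grp == "L"],
                                rule = normality_rule)
        data.frame(variable = v,
                   mean_vh = gc$mean_a, sd_vh = gc$sd_a,
                   mean_l = gc$mean_b, sd_l = gc$sd_b,
                   test = gc$test, statistic = gc$statistic,
                   p_value = gc$p_value, stringsAsFactors = FALSE)
    }))

    # H-b accessibility at the cut-point: 2x2 vs group + logistic OR
    acc <- classify_accessibility(features$hb_index, hb_cutpoint)
    hb_tab <- table(factor(acc, c("accessible", "inaccessible")),
                    factor(grp, c("VH", "L")))
    hb_fisher <- fisher_exact_2x2(hb_tab)
    hb_logit <- tryCatch(
        logistic_univariable(y, as.integer(acc == "accessible"),
                             robust = robust_ci, name = "hb_accessible")$table,
        error = function(e) NULL)

    # GC bins
    bins <- gc_bin(features$gc_percent, binning)
    in_main <- bins$main == binning$main_labels[2]
    gc_main_tab <- table(factor(in_main, c(TRUE, FALSE)),
                         factor(grp, c("VH", "L")))
    dimnames(gc_main_tab)[[1]] <- c("gc_25_55", "outside")
    gc_fisher <- fisher_exact_2x2(gc_main_tab)
    sub_ok <- !is.na(bins$subgroup)
    gc_sub_tab <- table(factor(bins$subgroup[sub_ok], binning$sub_labels),
                        factor(grp[sub_ok], c("VH", "L")))
    keep <- rowSums(gc_sub_tab) > 0
    gc_chisq <- if (sum(keep) >= 2 && all(colSums(gc_sub_tab[keep, , drop = FALSE]) > 0))
        suppressWarnings(chi_square_rxc(gc_sub_tab[keep, , drop = FALSE]))
    else list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    n_vh <- sum(grp == "VH")
    gc_onesample <- one_sample_proportion(sum(in_main & grp == "VH"),
                                          n_vh, p0_gc)

    structure(list(univariable = rbind(uni, uni_unpaired, uni_run),
                   multivariable = multi,
                   table1 = table1, fig2 = fig2, fig3 = fig3,
                   comparisons = comparisons,
                   hb = list(table = hb_tab, fisher_p = hb_fisher,
                             logit = hb_logit, cutpoint = hb_cutpoint),
                   gc = list(main_table = gc_main_tab,
                             fisher_p = gc_fisher,
                             sub_table = gc_sub_tab, chisq = gc_chisq,
                             onesample_p = gc_onesample, p0 = p0_gc),
                   n = length(y)),
              class = "sirna_analysis")
}

#' @export
print.sirna_analysis <- function(x, ...) {
    cat("siRNA efficacy analysis, n =", x$n, "\n\nUnivariable logistic:\n")
    tb <- x$univariable
    print(data.frame(predictor = tb$predictor,
                     OR = sprintf("%.3f (%.3f-%.3f)", tb$odds_ratio,
                                  tb$ci_low, tb$ci_high),
                     p = signif(tb$p_value, 3)), row.names = FALSE)
    cat("\nGroup comparisons (VH vs L):\n")
    cm <- x$comparisons
    print(data.frame(variable = cm$variable,
                     VH = sprintf("%.2f±%.2f", cm$mean_vh, cm$sd_vh),
                     L = sprintf("%.2f±%.2f", cm$mean_l, cm$sd_l),
                     test = cm$test, p = signif(cm$p_value, 3)),
          row.names = FALSE)
    invisible(x)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_logit_tsv <- function(uni, multi, path) {
    block <- function(tb, label)
        data.frame(model = label, predictor = tb$predictor,
                   odds_ratio = fmt_num(tb$odds_ratio),
                   ci_low = fmt_num(tb$ci_low),
                   ci_high = fmt_num(tb$ci_high),
                   p_value = fmt_num(tb$p_value), stringsAsFactors = FALSE)
    write.table(rbind(block(uni, "univariable"),
                      block(multi, "multivariable")),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline on input files
#'
#' Reads the FASTA and siRNA table (plus optional external structures and
#' ss-count files), computes the feature table, runs the statistical
#' battery and writes the result bundle into \code{out_dir}:
#' \code{features.tsv}, \code{table_elements.tsv} (element-distribution
#' table), \code{table_logistic.tsv}, \code{hist_unpaired.tsv} and
#' \code{hist_runs.tsv} (histogram data tables), \code{comparisons.tsv},
#' \code{gc_analysis.tsv}, \code{hb_analysis.tsv} and a structured
#' \code{run_log.jsonl}.  Deterministic: the same config and inputs give a
#' byte-identical bundle.
#'
#' @param config a \code{\link{run_config}}.
#' @return the \code{sirna_analysis} bundle, invisibly.
#' @export
run_pipeline <- function(config) {
    mrnas <- read_fasta(config$fasta)
    sirnas <- read_sirna_table(config$sirna_table)
    if (!nrow(sirnas)) stop("validation: empty siRNA table")
    bad <- setdiff(sirnas$target_id, mrnas$id)
    if (length(bad))
        stop("validation: siRNA table references unknown mRNA id(s): ",
             paste(unique(bad), collapse = ", "))

    structures <- NULL
    if (!is.null(config$structures_dir)) {
        structures <- list()
        for (id in unique(sirnas$target_id)) {
            f <- file.path(config$structures_dir, paste0(id, ".ct"))
            if (file.exists(f)) structures[[id]] <- read_ct(f)
        }
    }
    ss_counts <- NULL
    if (!is.null(config$ss_count_dir)) {
        ss_counts <- list()
        for (id in unique(sirnas$target_id)) {
            f <- file.path(config$ss_count_dir, paste0(id, ".ss"))
            if (file.exists(f)) ss_counts[[id]] <- read_ss_count(f)
        }
    }

    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(config$out_dir, "run_log.jsonl")
    log_con <- file(log_path, open = "wt")
    on.exit(close(log_con), add = TRUE)
    log_line <- function(rec)
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
                   log_con)
    log_line(list(event = "run_start",
                  package = "siRNAtarget",
                  version = as.character(utils::packageVersion("siRNAtarget")),
                  seed = config$seed,
                  params = list(pair_weights = as.list(config$params$pair_weights),
                                min_hairpin = config$params$min_hairpin,
                                ensemble_k = config$ensemble_k,
                                hb_cutpoint = config$hb_cutpoint,
                                robust_ci = config$robust_ci),
                  external_structures = !is.null(structures),
                  external_ss_counts = !is.null(ss_counts)))
    if (is.null(ss_counts) || !length(ss_counts))
        log_line(list(event = "note", message = paste(
            "H-b denominators come from the internal engine ensemble",
            "(k =", config$ensemble_k, "); they differ from any",
            "external-folder ss-count")))

    withCallingHandlers(
        features <- compute_features(mrnas, sirnas, params = config$params,
                                     structures = structures,
                                     ss_counts = ss_counts,
                                     ensemble_k = config$ensemble_k,
                                     log_fn = function(rec)
                                         log_line(c(event = "sirna", rec))),
        warning = function(w) {
            log_line(list(event = "warning",
                          message = conditionMessage(w)))
            invokeRestart("muffleWarning")
        })

    an <- analyze_features(features, binning = config$binning,
                           hb_cutpoint = config$hb_cutpoint,
                           robust_ci = config$robust_ci,
                           normality_rule = config$normality_rule)

    od <- config$out_dir
    write_feature_table(features, file.path(od, "features.tsv"))
    write.table(an$table1, file.path(od, "table_elements.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_logit_tsv(an$univariable, an$multivariable,
                    file.path(od, "table_logistic.tsv"))
    write.table(an$fig2, file.path(od, "hist_unpaired.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(an$fig3, file.path(od, "hist_runs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cm <- an$comparisons
    cm$mean_vh <- fmt_num(cm$mean_vh); cm$sd_vh <- fmt_num(cm$sd_vh)
    cm$mean_l <- fmt_num(cm$mean_l); cm$sd_l <- fmt_num(cm$sd_l)
    cm$statistic <- fmt_num(cm$statistic); cm$p_value <- fmt_num(cm$p_value)
    write.table(cm, file.path(od, "comparisons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gc_lines <- c(
        sprintf("gc_25_55_vh\t%d", an$gc$main_table["gc_25_55", "VH"]),
        sprintf("gc_25_55_l\t%d", an$gc$main_table["gc_25_55", "L"]),
        sprintf("fisher_p\t%s", fmt_num(an$gc$fisher_p)),
        sprintf("subgroup_chisq\t%s", fmt_num(an$gc$chisq$statistic)),
        sprintf("subgroup_p\t%s", fmt_num(an$gc$chisq$p_value)),
        sprintf("onesample_p0\t%s", fmt_num(an$gc$p0)),
        sprintf("onesample_p\t%s", fmt_num(an$gc$onesample_p)))
    writeLines(c("quantity\tvalue", gc_lines), file.path(od, "gc_analysis.tsv"))
    hb_lines <- c(
        sprintf("cutpoint\t%s", fmt_num(an$hb$cutpoint)),
        sprintf("accessible_vh\t%d", an$hb$table["accessible", "VH"]),
        sprintf("accessible_l\t%d", an$hb$table["accessible", "L"]),
        sprintf("fisher_p\t%s", fmt_num(an$hb$fisher_p)),
        if (!is.null(an$hb$logit))
            sprintf("logit_or\t%s\nlogit_ci_low\t%s\nlogit_ci_high\t%s\nlogit_p\t%s",
                    fmt_num(an$hb$logit$odds_ratio),
                    fmt_num(an$hb$logit$ci_low),
                    fmt_num(an$hb$logit$ci_high),
                    fmt_num(an$hb$logit$p_value)))
    writeLines(c("quantity\tvalue", hb_lines), file.path(od, "hb_analysis.tsv"))
    log_line(list(event = "run_end", n_sirnas = nrow(features)))
    invisible(an)
}
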