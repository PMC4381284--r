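# The statistical battery: uni/multivariable logistic regression with
# heteroskedasticity-robust (HC1 sandwich) Wald confidence intervals and
# odds ratios, two-group comparisons with a normality-based test choice,
# Fisher's exact and Pearson chi-square contingency tests, and an exact
# one-sample proportion test.  Standard machinery (glm, sandwich, t.test,
# wilcox.test, fisher.test, chisq.test, binom.test) does the fitting; this
# module fixes the interfaces, conventions and error behaviour.

logit_fit <- function(y, X, robust = TRUE, predictor_names,
                      intercept = TRUE) {
    df <- data.frame(y = y, X)
    form <- if (intercept) y ~ . else y ~ . - 1
    fit <- suppressWarnings(glm(form, data = df, family = binomial(),
                                control = list(maxit = 100, epsilon = 1e-8)))
    beta <- coef(fit)
    slopes <- if (intercept) beta[-1] else beta
    if (!fit$converged || any(abs(slopes) > 15))
        stop("logistic fit did not converge (possible complete separation); ",
             "coefficients: ", paste(sprintf("%.2f", slopes), collapse = ", "))
    fv <- fit$fitted.values
    if (all(fv[y == 1] > 1 - 1e-6) && all(fv[y == 0] < 1e-6))
        stop("complete separation: the predictor splits the classes ",
             "perfectly; the MLE does not exist")
    V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
    se <- sqrt(diag(V))
    z <- qnorm(0.975)
    idx <- if (intercept) seq_along(beta)[-1] else seq_along(beta)
    res <- data.frame(predictor = predictor_names,
                      coef = unname(beta[idx]),
                      se = unname(se[idx]),
                      odds_ratio = exp(unname(beta[idx])),
                      ci_low = exp(unname(beta[idx] - z * se[idx])),
                      ci_high = exp(unname(beta[idx] + z * se[idx])),
                      p_value = 2 * pnorm(-abs(unname(beta[idx] / se[idx]))),
                      stringsAsFactors = FALSE)
    structure(list(table = res, n = length(y), converged = fit$converged,
                   robust = robust, fit = fit),
              class = "sirna_logit")
}

#' @export
print.sirna_logit <- function(x, digits = 3, ...) {
    cat("Logistic regression (n = ", x$n, ", ",
        if (x$robust) "robust HC1" else "model-based", " 95% CI)\n", sep = "")
    tb <- x$table
    out <- data.frame(predictor = tb$predictor,
                      OR = round(tb$odds_ratio, digits),
                      CI = sprintf("(%s-%s)",
                                   format(round(tb$ci_low, digits)),
                                   format(round(tb$ci_high, digits))),
                      p = signif(tb$p_value, digits))
    print(out, row.names = FALSE)
    invisible(x)
}

#' Univariable logistic regression of efficacy on one predictor
#'
#' Maximum-likelihood fit of \code{logit P(y = 1) = b0 + b1 x}; the odds
#' ratio is \code{exp(b1)} with a Wald 95\% CI from HC1 sandwich standard
#' errors by default (the classical model-based CI behind
#' \code{robust = FALSE}).
#'
#' @param y 0/1 vector (1 = very high efficacy, 0 = low).
#' @param x numeric predictor.
#' @param robust use sandwich (HC1) standard errors (default TRUE).
#' @param name predictor name for the output table.
#' @return object of class \code{sirna_logit}.
#' @export
logistic_univariable <- function(y, x, robust = TRUE, name = "x") {
    y <- as.integer(y)
    if (length(y) != length(x)) stop("y and x lengths differ")
    if (length(y) < 10L) stop("need at least 10 observations")
    if (!all(y %in% c(0L, 1L))) stop("y must be 0/1")
    if (length(unique(y)) < 2L) stop("y must contain both classes")
    if (length(unique(x)) < 2L) stop("predictor x is constant")
    logit_fit(y, data.frame(x = x), robust = robust, predictor_names = name)
}

#' Multivariable logistic regression of efficacy on all predictors jointly
#'
#' @param y 0/1 vector.
#' @param X numeric matrix or data.frame of predictors (one column each).
#' @param robust use HC1 sandwich standard errors (default TRUE).
#' @param intercept fit an intercept (default TRUE).  With
#'   \code{intercept = FALSE} the model is \code{logit P = sum_j b_j x_j};
#'   this is the identified parameterization when the predictors sum to a
#'   constant per observation (as the 8 element counts of fixed-length
#'   sites do), where an intercept would be exactly collinear.
#' @return object of class \code{sirna_logit} with one row per predictor.
#' @export
logistic_multivariable <- function(y, X, robust = TRUE, intercept = TRUE) {
    y <- as.integer(y)
    X <- as.data.frame(X)
    if (!nrow(X) || nrow(X) != length(y)) stop("y and X sizes differ")
    if (length(y) <= ncol(X) + 1L)
        stop("need n > number of predictors + 1 (n = ", length(y),
             ", predictors = ", ncol(X), ")")
    if (length(unique(y)) < 2L) stop("y must contain both classes")
    M <- if (intercept) cbind(1, as.matrix(X)) else as.matrix(X)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
        drop <- setdiff(colnames(M), colnames(M)[qrM$pivot[seq_len(qrM$rank)]])
        stop("rank-deficient design; exactly collinear column(s): ",
             paste(setdiff(drop, ""), collapse = ", "))
    }
    logit_fit(y, X, robust = robust, predictor_names = colnames(X),
              intercept = intercept)
}

#' Two-group comparison with normality-based test selection
#'
#' Under the default rule both groups are tested with Shapiro-Wilk at
#' alpha = 0.05; if both pass, Student's unpaired (equal-variance) t test
#' is used, otherwise the Mann-Whitney U test.  The rule can be overridden
#' by naming the test.  Two zero-variance groups with equal means return
#' p = 1 by convention.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param rule \code{"auto"}, \code{"t"} or \code{"mann_whitney"}.
#' @return list of class \code{group_comparison}: per-group mean and S.D.,
#'   \code{test}, \code{statistic}, \code{p_value}.
#' @export
two_group_compare <- function(a, b, rule = c("auto", "t", "mann_whitney")) {
    rule <- match.arg(rule)
    if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
    degenerate <- sd(a) == 0 && sd(b) == 0
    test <- rule
    if (rule == "auto") {
        if (degenerate) {
            test <- "t"
        } else {
            norm_ok <- function(x) {
                if (sd(x) == 0) return(FALSE)
                shapiro.test(x)$p.value >= 0.05
            }
            test <- if (norm_ok(a) && norm_ok(b)) "t" else "mann_whitney"
        }
    }
    if (degenerate) {
        if (mean(a) == mean(b)) {
            message("both groups have zero variance and equal means; p = 1")
            stat <- if (test == "t") 0 else length(a) * length(b) / 2
            p <- 1
        } else {
            stat <- if (test == "t") Inf else
                if (mean(a) > mean(b)) length(a) * length(b) else 0
            p <- 0
        }
    } else if (test == "t") {
        ht <- t.test(a, b, var.equal = TRUE)
        stat <- unname(ht$statistic); p <- ht$p.value
    } else {
        ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
        stat <- unname(ht$statistic); p <- ht$p.value
    }
    structure(list(mean_a = mean(a), sd_a = sd(a),
                   mean_b = mean(b), sd_b = sd(b),
                   n_a = length(a), n_b = length(b),
                   test = test, statistic = stat, p_value = p),
              class = "group_comparison")
}

#' Format a group comparison in "mean +/- S.D." style
#' @param x a \code{group_comparison}.
#' @param ... unused.
#' @export
format.group_comparison <- function(x, ...) {
    sprintf("%.2f±%.2f vs %.2f±%.2f (%s, P=%.3g)",
            x$mean_a, x$sd_a, x$mean_b, x$sd_b,
            if (x$test == "t") "t test" else "Mann-Whitney U", x$p_value)
}

#' @export
print.group_comparison <- function(x, ...) {
    cat(format(x), "\n")
    invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' that of the observed table (via \code{stats::fisher.test}).  A zero
#' margin returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
        warning("zero margin; p = 1")
        return(1)
    }
    fisher.test(table)$p.value
}

#' Pearson's chi-square test for an RxC table
#'
#' Uncorrected Pearson statistic against chi-square with (R-1)(C-1)
#' degrees of freedom; warns when any expected count is below 5.
#'
#' @param table RxC matrix of non-negative counts.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
chi_square_rxc <- function(table) {
    table <- as.matrix(table)
    if (any(table < 0)) stop("counts must be non-negative")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("zero margin in contingency table")
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    if (any(ht$expected < 5))
        warning("expected count below 5 in ",
                sum(ht$expected < 5), " cell(s)")
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, expected = ht$expected)
}

#' Exact one-sample proportion test
#'
#' Exact binomial test of \code{successes/n} against \code{p0}, two-sided
#' by the minimum-likelihood method.
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @param p0 null proportion in (0,1).
#' @return the two-sided p-value.
#' @export
one_sample_proportion <- function(successes, n, p0) {
    if (successes < 0 || successes > n) stop("successes must lie in 0..n")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
    binom.test(successes, n, p = p0)$p.value
}
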