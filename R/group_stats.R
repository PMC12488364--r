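#' @title Supporting group statistics
#' @description
#' The descriptive and inferential statistics that accompany the rule
#' mining: z-based confidence intervals of group means (the same
#' mechanism as the control cut-offs), a two-factor fixed-effects ANOVA
#' for a biomarker with disease progression as the effect of interest and
#' treatment as a covariate, reported as least-squares (LS) means; a
#' likelihood-ratio test for treatment vs progression from a binary
#' logistic fit; and rank-based ROC AUC for single markers.
#' @name group_stats
NULL

#' Summarize a group of values
#'
#' @param values numeric vector, `n >= 2`.
#' @param ci_level coverage (default 0.95); the interval is the z-based
#'   `mean +/- z * SD / sqrt(n)` with the sample SD (n-1 denominator).
#' @param group optional group label.
#' @return object of class `group_summary`: `group`, `n`, `mean`, `sd`,
#'   `ci_low`, `ci_high` (full precision; the print method rounds to 2
#'   decimals for display).
#' @export
summarize_group <- function(values, ci_level = 0.95, group = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 non-missing values")
  m <- mean(values)
  s <- stats::sd(values)
  ci <- ci_of_mean(m, s, length(values), ci_level)
  structure(list(group = group, n = length(values), mean = m, sd = s,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 ci_level = ci_level),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.2f (%.2f) [%.2f-%.2f]\n",
              x$group %||% "group", x$n, x$mean, x$sd, x$ci_low, x$ci_high))
  invisible(x)
}

#' Least-squares-means ANOVA with a treatment covariate
#'
#' Fits the additive fixed-effects linear model
#' `response ~ group + treatment` by least squares. The LS mean of a
#' group is the model prediction averaged with equal weight over the
#' treatment levels; its SE comes from the coefficient covariance. The
#' group effect is tested by the extra-sum-of-squares F comparing against
#' the model without `group` (equivalent to the type-III test in the
#' additive model).
#'
#' @param response numeric vector.
#' @param group factor-like, e.g. SD/PD.
#' @param treatment factor-like treatment category.
#' @return object of class `ls_means_result`: data.frame `ls_means`
#'   (`group`, `lsmean`, `se`, `ci_low`, `ci_high`, t-based 95% CI),
#'   `f_statistic`, `df` (numerator, denominator), `p_value`, `fit`.
#' @export
ls_means_anova <- function(response, group, treatment) {
  group <- factor(group)
  treatment <- factor(treatment)
  stopifnot(length(response) == length(group),
            length(response) == length(treatment))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (nlevels(treatment) < 1) stop("need at least 1 treatment level")
  dat <- data.frame(.y = response, .g = group, .t = treatment)
  single_treatment <- nlevels(treatment) < 2
  fit <- if (single_treatment) stats::lm(.y ~ .g, data = dat) else
    stats::lm(.y ~ .g + .t, data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("rank-deficient design; aliased: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  V <- stats::vcov(fit)
  grid <- expand.grid(.g = levels(group), .t = levels(treatment))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  lsm <- vapply(levels(group), function(g) {
    cvec <- colMeans(X[grid$.g == g, , drop = FALSE])  # equal weight per treatment
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    c(est, se)
  }, numeric(2))
  tq <- stats::qt(0.975, fit$df.residual)
  ls_means <- data.frame(group = levels(group),
                         lsmean = lsm[1, ], se = lsm[2, ],
                         ci_low = lsm[1, ] - tq * lsm[2, ],
                         ci_high = lsm[1, ] + tq * lsm[2, ],
                         row.names = NULL, stringsAsFactors = FALSE)
  reduced <- if (single_treatment) stats::lm(.y ~ 1, data = dat) else
    stats::lm(.y ~ .t, data = dat)
  cmp <- stats::anova(reduced, fit)
  structure(list(ls_means = ls_means,
                 f_statistic = cmp$F[2],
                 df = c(cmp$Df[2], fit$df.residual),
                 p_value = cmp$`Pr(>F)`[2],
                 fit = fit),
            class = "ls_means_result")
}

#' @export
print.ls_means_result <- function(x, ...) {
  cat("LS means (equal weight over treatment levels):\n")
  for (i in seq_len(nrow(x$ls_means))) {
    r <- x$ls_means[i, ]
    cat(sprintf("  %s: %.2f (%.2f) [%.2f-%.2f]\n",
                r$group, r$lsmean, r$se, r$ci_low, r$ci_high))
  }
  cat(sprintf("Group effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Likelihood-ratio test of a categorical predictor on a binary outcome
#'
#' Maximum-likelihood binary logistic fit (IRLS/Newton, convergence
#' tolerance 1e-10) of `outcome ~ predictor`, tested against the
#' intercept-only model by the likelihood ratio.
#'
#' @param outcome vector in `{"SD","PD"}` (PD coded 1) or logical/0-1.
#' @param predictor factor-like with >= 2 levels.
#' @return object of class `logistic_test`: `p_value`, `statistic`
#'   (LR chi-square), `df`, `separation` / `degenerate` flags (each
#'   raises a warning; the LRT p-value is still reported).
#' @export
logistic_group_test <- function(outcome, predictor) {
  y <- if (is.character(outcome) || is.factor(outcome)) {
    as.character(outcome) == "PD"
  } else as.logical(outcome)
  predictor <- factor(predictor)
  stopifnot(length(y) == length(predictor))
  if (nlevels(predictor) < 2) stop("need at least 2 predictor levels")
  degenerate <- length(unique(y)) < 2
  if (degenerate) warning("degenerate outcome: all labels identical")
  fit <- stats::glm(y ~ predictor, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) && !degenerate
  if (separation) warning("possible complete separation; LRT p-value reported")
  stat <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(p_value = p, statistic = stat, df = df,
                 separation = separation, degenerate = degenerate),
            class = "logistic_test")
}

#' @export
print.logistic_test <- function(x, ...) {
  cat(sprintf("Logistic LRT: chi-square(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' ROC area under the curve
#'
#' Rank (Mann-Whitney) statistic with half credit for ties; direction is
#' fixed: higher score = more likely positive (PD), so discordant markers
#' report AUC below 0.5 rather than being flipped.
#'
#' @param scores numeric marker values.
#' @param labels positive-class indicator: logical, 0/1, or `"PD"`/`"SD"`.
#' @return AUC in \[0,1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "PD"
  } else as.logical(labels)
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties get half credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
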