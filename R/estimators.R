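#' @name estimators
#' @title The three analyses of a baseline-outcome trial
#'
#' @description
#' Each fit regresses a response on the binary group indicator by
#' ordinary least squares and reports the group coefficient, its
#' model-based standard error and a two-sided p-value from Student's t
#' with the residual degrees of freedom:
#' \describe{
#'   \item{`fit_anova()`}{outcome ~ group: the unadjusted comparison of
#'     post-treatment means, algebraically the pooled two-sample t-test.}
#'   \item{`fit_csa()`}{change ~ group: change-score analysis, the same
#'     computation applied to outcome - baseline.}
#'   \item{`fit_ancova()`}{outcome ~ group + baseline with a common
#'     slope: analysis of covariance; the group coefficient is the
#'     baseline-adjusted treatment effect.}
#' }
#' The normal equations for these one- and two-regressor designs are
#' solved in closed form (group means, pooled within-group slope) rather
#' than through a general matrix solver: the simulation engine performs
#' hundreds of thousands of fits, and the closed forms are exactly
#' testable against a general OLS routine.
#'
#' Two per-trial identities hold to machine precision and are useful
#' checks: with `imb` the observed baseline mean difference
#' (treatment - control),
#' `beta_CSA = beta_ANOVA - imb` and
#' `beta_ANCOVA = beta_ANOVA - slope * imb`.
#'
#' @param trial A `trial_dataset` from [generate_trial()], or any object
#'   with numeric vectors `group` (0/1), `baseline`, `outcome`, `change`.
#' @return An object of class `method_fit`: list with `method`, `beta`,
#'   `se`, `t_stat`, `df`, `p_value`, `slope` (ANCOVA only, otherwise
#'   `NA`), and `degenerate` (`TRUE` when the residual variance is zero,
#'   in which case `se = 0` and `p_value` is `NA` rather than 0).
NULL

method_fit <- function(method, beta, se, df, slope = NA_real_) {
  degenerate <- !is.finite(se) || se <= 0
  if (degenerate) {
    se <- 0
    t_stat <- NA_real_
    p_value <- NA_real_
  } else {
    t_stat <- beta / se
    p_value <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(method = method, beta = beta, se = se, t_stat = t_stat,
         df = as.integer(df), p_value = p_value, slope = slope,
         degenerate = degenerate),
    class = "method_fit"
  )
}

#' @export
print.method_fit <- function(x, ...) {
  cat(sprintf("%s fit: beta = %.5g, se = %.5g, df = %d, p = %.4g%s\n",
              x$method, x$beta, x$se, x$df,
              if (is.na(x$p_value)) NA else x$p_value,
              if (x$degenerate) " (degenerate: zero residual variance)" else ""))
  invisible(x)
}

check_arms <- function(group) {
  nT <- sum(group == 1)
  nC <- sum(group == 0)
  if (nT < 2 || nC < 2) {
    stop("each arm needs at least 2 observations", call. = FALSE)
  }
  c(nT = nT, nC = nC)
}

# Pooled two-group OLS of a response on the group indicator.
fit_two_group <- function(response, group, method) {
  n <- check_arms(group)
  yT <- response[group == 1]
  yC <- response[group == 0]
  beta <- mean(yT) - mean(yC)
  df <- n[["nT"]] + n[["nC"]] - 2L
  s2 <- (sum((yT - mean(yT))^2) + sum((yC - mean(yC))^2)) / df
  se <- sqrt(s2 * (1 / n[["nT"]] + 1 / n[["nC"]]))
  method_fit(method, beta, se, df)
}

#' @rdname estimators
#' @examples
#' tr <- generate_trial(scenario_spec(0.5, 0.5, 1.96, 64), seed = 7)
#' fit_anova(tr)
#' fit_csa(tr)
#' fit_ancova(tr)
#' @export
fit_anova <- function(trial) {
  fit_two_group(trial$outcome, trial$group, "ANOVA")
}

#' @rdname estimators
#' @export
fit_csa <- function(trial) {
  fit_two_group(trial$change, trial$group, "CSA")
}

#' @rdname estimators
#' @export
fit_ancova <- function(trial) {
  g <- trial$group
  z <- trial$baseline
  y <- trial$outcome
  n <- check_arms(g)
  tr <- g == 1
  zT <- z[tr]; zC <- z[!tr]
  yT <- y[tr]; yC <- y[!tr]
  # pooled within-group sums of squares / cross-products
  dzT <- zT - mean(zT); dzC <- zC - mean(zC)
  dyT <- yT - mean(yT); dyC <- yC - mean(yC)
  sxx <- sum(dzT^2) + sum(dzC^2)
  if (sxx <= 0) {
    stop("baseline has no within-group variance: ANCOVA is not estimable",
         call. = FALSE)
  }
  sxy <- sum(dzT * dyT) + sum(dzC * dyC)
  syy <- sum(dyT^2) + sum(dyC^2)
  slope <- sxy / sxx
  imb <- mean(zT) - mean(zC)
  beta <- (mean(yT) - mean(yC)) - slope * imb
  rss <- max(syy - slope * sxy, 0)
  df <- n[["nT"]] + n[["nC"]] - 3L
  s2 <- rss / df
  se <- sqrt(s2 * (1 / n[["nT"]] + 1 / n[["nC"]] + imb^2 / sxx))
  method_fit("ANCOVA", beta, se, df, slope = slope)
}

#' Two-sided rejection decision
#'
#' @param fit A `method_fit`.
#' @param alpha Two-sided significance level in (0, 1).
#' @return `TRUE` iff `p_value < alpha` (strict). A degenerate fit (zero
#'   residual variance, undefined p-value) is an error.
#' @export
reject <- function(fit, alpha) {
  stopifnot(inherits(fit, "method_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  if (is.na(fit$p_value)) {
    stop("p-value is undefined for a degenerate fit", call. = FALSE)
  }
  fit$p_value < alpha
}
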