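#' Closed-form bias of ANOVA and CSA relative to ANCOVA
#'
#' With the ANCOVA estimate taken as the unbiased reference, the
#' expected biases are linear in the absolute imbalance
#' `dz = deviate * sqrt(2 / n_per_group)`:
#' \deqn{bias_{ANOVA} = E[\beta_{ANCOVA} - \beta_{ANOVA}] = -\rho \, dz}
#' \deqn{bias_{CSA} = E[\beta_{ANCOVA} - \beta_{CSA}] = (1 - \rho) \, dz}
#' ANOVA ignores the imbalance entirely (so ANCOVA's correction, of size
#' rho * dz, is the whole difference), whereas CSA subtracts the full
#' imbalance and thereby over-corrects by (1 - rho) * dz whenever
#' rho < 1 — the regression-to-the-mean effect.
#'
#' @param rho Baseline-outcome correlation in [0, 1).
#' @param deviate Signed standard normal deviate of the imbalance.
#' @param n_per_group Per-group sample size.
#' @return List with `bias_anova` and `bias_csa` (SD units).
#' @examples
#' bias_closed_form(0.5, -1.96, 394) # bias_anova ~ +0.07
#' @export
bias_closed_form <- function(rho, deviate, n_per_group) {
  if (!is.numeric(rho) || any(rho < 0 | rho >= 1)) {
    stop("'rho' must be in [0, 1)", call. = FALSE)
  }
  dz <- absolute_imbalance(deviate, n_per_group)
  list(bias_anova = -rho * dz, bias_csa = (1 - rho) * dz)
}

#' Closed-form design effects (ratios of standard errors)
#'
#' Large-sample ratios of the model-based standard errors of the group
#' coefficient, as functions of the baseline-outcome correlation alone:
#' \deqn{SE_{ANCOVA}/SE_{ANOVA} = \sqrt{1 - \rho^2}}
#' \deqn{SE_{CSA}/SE_{ANOVA} = \sqrt{2(1 - \rho)}}
#' \deqn{SE_{ANCOVA}/SE_{CSA} = \sqrt{(1 + \rho)/2}}
#' The CSA/ANOVA ratio crosses 1 exactly at rho = 0.5: change scores are
#' less precise than raw outcomes below that correlation and more
#' precise above it. ANCOVA is never less precise than either, up to
#' finite-sample terms of order 1/n.
#'
#' @param rho Baseline-outcome correlation in [0, 1]. `rho = 1` is
#'   degenerate (the CSA residual variance vanishes) and is flagged with
#'   a warning.
#' @return List with `de_ancova_anova`, `de_csa_anova`, `de_ancova_csa`.
#' @examples
#' design_effect_closed_form(0.5) # 0.866, 1, 0.866
#' @export
design_effect_closed_form <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop("'rho' must be in [0, 1]", call. = FALSE)
  }
  if (rho == 1) {
    warning("rho = 1: CSA has zero residual variance; ratios to CSA degenerate")
  }
  de_aa <- sqrt(1 - rho^2)
  de_ca <- sqrt(2 * (1 - rho))
  list(de_ancova_anova = de_aa,
       de_csa_anova = de_ca,
       de_ancova_csa = sqrt((1 + rho) / 2))
}

method_moments <- function(method, spec) {
  dz <- absolute_imbalance(spec$deviate, spec$n_per_group)
  se0 <- sqrt(2 / spec$n_per_group)
  switch(method,
    ANOVA = list(mu = spec$effect, sigma = se0,
                 df = 2L * spec$n_per_group - 2L),
    CSA = list(mu = spec$effect - dz,
               sigma = se0 * sqrt(2 * (1 - spec$rho)),
               df = 2L * spec$n_per_group - 2L),
    ANCOVA = {
      # finite-sample SE inflation: the ANCOVA variance carries a
      # (zbar_T - zbar_C)^2 / Sxx term, so E[SE^2] is scaled by about
      # 1 + (n dz^2 / 2 + 1) / (2n - 2); negligible at n = 394, a few
      # per cent at n = 26 with extreme imbalance
      n <- spec$n_per_group
      infl <- sqrt(1 + (n * dz^2 / 2 + 1) / (2 * n - 2))
      list(mu = spec$effect - spec$rho * dz,
           sigma = se0 * sqrt(1 - spec$rho^2) * infl,
           df = 2L * n - 3L)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Analytic approximation to conditional power
#'
#' Treats each method's group-coefficient estimate as Gaussian with mean
#' `mu_m` and standard deviation `sigma_m`, where `mu_m` is the
#' method-specific expected estimate conditional on the imbalance
#' (`effect` for ANOVA, `effect - dz` for CSA, `effect - rho * dz` for
#' ANCOVA, with `dz = deviate * sqrt(2/n)`) and `sigma_m` is
#' `sqrt(2/n)` scaled by the method's residual-SD factor (1,
#' `sqrt(2(1-rho))`, `sqrt(1-rho^2)`). Two-sided normal-approximation
#' power is
#' \deqn{\Phi(|\mu|/\sigma - z_{1-\alpha/2}) + \Phi(-|\mu|/\sigma - z_{1-\alpha/2}).}
#' Two refinements matter in small trials: for `n_per_group <= 64` the
#' normal tail probabilities are replaced by noncentral-t ones with the
#' estimator's residual degrees of freedom, and the ANCOVA sigma carries
#' the finite-sample inflation factor
#' `sqrt(1 + (n dz^2/2 + 1)/(2n - 2))` induced by the realized-imbalance
#' term of its standard error (a few per cent at n = 26 under extreme
#' imbalance, negligible at n = 394).
#'
#' This is a verification oracle for the Monte-Carlo rejection rates,
#' not itself a simulation output.
#'
#' @param method One of `"ANOVA"`, `"CSA"`, `"ANCOVA"`.
#' @param spec A [scenario_spec()]; its `alpha` sets the test level.
#' @return Approximate two-sided power in [0, 1].
#' @examples
#' analytic_power("CSA", scenario_spec(0.2, 0.1, 1.96, 394)) # ~0.1
#' @export
analytic_power <- function(method, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- method_moments(match.arg(method, c("ANOVA", "CSA", "ANCOVA")), spec)
  if (m$sigma <= 0) { # rho -> 1 degenerate CSA: any nonzero mu is detected
    return(as.numeric(abs(m$mu) > 0))
  }
  if (spec$n_per_group <= 64) {
    ncp <- m$mu / m$sigma
    tc <- stats::qt(1 - spec$alpha / 2, df = m$df)
    1 - stats::pt(tc, df = m$df, ncp = ncp) +
      stats::pt(-tc, df = m$df, ncp = ncp)
  } else {
    zc <- stats::qnorm(1 - spec$alpha / 2)
    snr <- abs(m$mu) / m$sigma
    stats::pnorm(snr - zc) + stats::pnorm(-snr - zc)
  }
}

two_sample_t_power <- function(n_per_group, effect, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- effect * sqrt(n_per_group / 2)
  tc <- stats::qt(1 - alpha / 2, df = df)
  1 - stats::pt(tc, df = df, ncp = ncp) + stats::pt(-tc, df = df, ncp = ncp)
}

#' Per-group sample size for the two-sample t-test
#'
#' Smallest per-group n such that the two-sided pooled two-sample t-test
#' at level `alpha` attains at least the requested power for a
#' standardized effect, computed by iterating the exact noncentral-t
#' power (df = 2n - 2, noncentrality `effect * sqrt(n/2)`) upward over
#' n. The exact t computation matters: the normal-approximation formula
#' is off by one per-group subject at effect 0.2.
#'
#' @param effect Standardized effect size (> 0).
#' @param power Target power in (0, 1). Default 0.8.
#' @param alpha Two-sided significance level in (0, 1). Default 0.05.
#' @return Integer per-group sample size.
#' @examples
#' required_sample_size(0.2) # 394
#' required_sample_size(0.5) # 64
#' required_sample_size(0.8) # 26
#' @export
required_sample_size <- function(effect, power = 0.8, alpha = 0.05) {
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect) ||
      effect <= 0) {
    stop("'effect' must be a single number > 0", call. = FALSE)
  }
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  n <- 2L
  while (two_sample_t_power(n, effect, alpha) < power) {
    n <- n + 1L
    if (n > 1e7) stop("sample-size search did not converge", call. = FALSE)
  }
  n
}

#' Assemble all closed-form predictions for one scenario
#'
#' Convenience wrapper bundling [bias_closed_form()],
#' [design_effect_closed_form()] and [analytic_power()] for the three
#' methods, in the same shape as a Monte-Carlo scenario summary.
#'
#' @param spec A [scenario_spec()].
#' @return List of class `theory_prediction` with `bias_anova`,
#'   `bias_csa`, the three design effects, and `power_anova`,
#'   `power_csa`, `power_ancova`.
#' @export
theory_prediction <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  b <- bias_closed_form(spec$rho, spec$deviate, spec$n_per_group)
  d <- design_effect_closed_form(spec$rho)
  structure(
    c(b, d,
      list(power_anova = analytic_power("ANOVA", spec),
           power_csa = analytic_power("CSA", spec),
           power_ancova = analytic_power("ANCOVA", spec))),
    class = "theory_prediction"
  )
}

#' @export
print.theory_prediction <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%s=%.5g\n", nm, x[[nm]]))
  invisible(x)
}
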