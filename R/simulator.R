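#' Define a trial scenario
#'
#' A scenario is one cell of the simulation design: a standardized
#' treatment effect, a baseline-outcome correlation, a signed standard
#' normal deviate governing baseline imbalance, and a per-group sample
#' size. All scores are on the standardized scale (population SD = 1).
#'
#' @param effect Standardized treatment effect (SD units), added to the
#'   treatment arm's outcome. Must be >= 0.
#' @param rho Baseline-outcome (pretest-posttest) correlation, in [0, 1).
#' @param deviate Signed standard normal deviate for baseline imbalance.
#'   The absolute baseline shift applied to the treatment arm is
#'   `deviate * sqrt(2 / n_per_group)`, i.e. the deviate times the
#'   standard error of a between-group mean difference. Positive values
#'   put the imbalance in the same direction as the treatment effect.
#' @param n_per_group Number of subjects per arm (1:1 allocation).
#' @param alpha Two-sided significance level used when rejection rates
#'   are computed. Default 0.05.
#'
#' @return An object of class `scenario_spec`: a list with the five
#'   fields above.
#' @examples
#' scenario_spec(effect = 0.2, rho = 0.5, deviate = -1.96, n_per_group = 394)
#' @export
scenario_spec <- function(effect, rho, deviate, n_per_group, alpha = 0.05) {
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect) ||
      effect < 0) {
    stop("'effect' must be a single finite number >= 0", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1) {
    stop("'rho' must be a single number in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(deviate) || length(deviate) != 1L || !is.finite(deviate)) {
    stop("'deviate' must be a single finite number", call. = FALSE)
  }
  n_per_group <- check_n_per_group(n_per_group, min = 2L)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  }
  structure(
    list(effect = effect, rho = rho, deviate = deviate,
         n_per_group = n_per_group, alpha = alpha),
    class = "scenario_spec"
  )
}

check_n_per_group <- function(n, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < min || n != round(n)) {
    stop(sprintf("'n_per_group' must be a single integer >= %d", min),
         call. = FALSE)
  }
  as.integer(n)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Trial scenario: effect %.2g SD, rho %.2g, imbalance deviate %.3g, n %d/group, alpha %.3g\n",
    x$effect, x$rho, x$deviate, x$n_per_group, x$alpha))
  invisible(x)
}

#' Absolute baseline imbalance implied by a standard normal deviate
#'
#' Imbalance is parameterized on the standardized scale: the deviate
#' times the standard error of a between-group difference in means,
#' `sqrt(2 / n_per_group)` with sigma = 1. This keeps the probability of
#' an imbalance of a given deviate constant across sample sizes.
#'
#' @param deviate Signed standard normal deviate.
#' @param n_per_group Per-group sample size (>= 1).
#' @return The signed mean shift (SD units) applied to the treatment
#'   arm's baseline scores.
#' @examples
#' absolute_imbalance(1.96, 394) # 0.1396
#' absolute_imbalance(1.28, 26)  # 0.3550
#' @export
absolute_imbalance <- function(deviate, n_per_group) {
  if (!is.numeric(deviate) || any(!is.finite(deviate))) {
    stop("'deviate' must be finite", call. = FALSE)
  }
  n_per_group <- check_n_per_group(n_per_group, min = 1L)
  deviate * sqrt(2 / n_per_group)
}

#' Generate one simulated two-arm trial
#'
#' Draws one dataset under the generative model. The operation order is
#' load-bearing and deliberate:
#' \enumerate{
#'   \item draw baseline scores z ~ N(0, 1) for all 2n subjects, then an
#'     independent noise vector k ~ N(0, 1);
#'   \item construct the outcome y = z * rho + k * sqrt(1 - rho^2), so
#'     that cor(z, y) = rho within each arm;
#'   \item shift the treatment arm's baseline by the absolute imbalance
#'     `deviate * sqrt(2/n)`;
#'   \item shift the treatment arm's outcome by `effect`.
#' }
#' Because the baseline shift is applied after the outcome has been
#' generated, the imbalance never propagates into the outcome: the
#' expected between-arm outcome difference equals `effect` at every
#' level of imbalance, while the expected change-score difference is
#' `effect - deviate * sqrt(2/n)`. Allocation is deterministic
#' alternation (odd positions treatment, even control), giving exactly n
#' subjects per arm.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed; identical `(spec, seed)` pairs reproduce the
#'   dataset bit-for-bit.
#' @return An object of class `trial_dataset`: list with vectors `group`
#'   (1 = treatment, 0 = control), `baseline`, `outcome`, `change`
#'   (outcome - baseline), and the generating `spec`.
#' @examples
#' tr <- generate_trial(scenario_spec(0.5, 0.5, 1.28, 64), seed = 1)
#' tapply(tr$baseline, tr$group, mean)
#' @export
generate_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  n2 <- 2L * spec$n_per_group
  set.seed(as.integer(seed))
  group <- as.numeric(seq_len(n2) %% 2L)
  z <- stats::rnorm(n2)
  k <- stats::rnorm(n2)
  y <- z * spec$rho + k * sqrt(1 - spec$rho^2)
  z <- z + group * absolute_imbalance(spec$deviate, spec$n_per_group)
  y <- y + group * spec$effect
  structure(
    list(group = group, baseline = z, outcome = y, change = y - z,
         spec = spec),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("Simulated trial: %d subjects (%d/arm)\n",
              length(x$group), sum(x$group == 1)))
  print(x$spec)
  invisible(x)
}

#' @export
as.data.frame.trial_dataset <- function(x, ...) {
  data.frame(group = x$group, baseline = x$baseline,
             outcome = x$outcome, change = x$change)
}

#' Write one trial as a CSV file
#'
#' Debug/inspection dump: four columns (group, baseline, outcome,
#' change) with a header row.
#'
#' @param trial A `trial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_dataset"))
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}
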