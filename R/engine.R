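#' Derive the seed of one replicate
#'
#' Pure integer hash of (master seed, scenario index, replicate index)
#' so that any single replicate is reconstructible in isolation without
#' replaying the stream that preceded it. Each component is folded in
#' with a multiplicative-congruential step modulo 2^31 - 1 (Lehmer
#' constants), keeping every intermediate product below 2^53 so the
#' arithmetic is exact in doubles and the result is a valid 32-bit seed.
#'
#' @param master_seed Non-negative integer master seed.
#' @param scenario_index 1-based index of the scenario in its grid.
#' @param replicate 1-based replicate index.
#' @return A single integer in [1, 2^31 - 2].
#' @export
replicate_seed <- function(master_seed, scenario_index, replicate) {
  m <- 2147483647 # 2^31 - 1
  a <- 48271
  s <- master_seed %% m
  s <- (s * a + scenario_index) %% m
  s <- (s * a + replicate) %% m
  s <- (s * a) %% m
  as.integer(s + 1)
}

#' Run the Monte-Carlo replicates of one scenario
#'
#' Generates `n_reps` trials (replicate r uses
#' `replicate_seed(master_seed, scenario_index, r)`), fits ANOVA, CSA
#' and ANCOVA to each, and aggregates into one summary row.
#'
#' Aggregation conventions:
#' \itemize{
#'   \item `mean_beta_*` and `mean_se_*` are arithmetic means over
#'     replicates; `sd_beta_*` is the empirical SD of the estimates
#'     (the Monte-Carlo sampling SD, a secondary precision diagnostic);
#'     `mc_se_beta_*` = `sd_beta_* / sqrt(n_reps)`.
#'   \item `power_*` is the fraction of replicates with two-sided
#'     p < alpha; `power_pos_*` additionally requires a positive
#'     estimate (rejections in the direction of the true effect), a
#'     supplementary column because a negatively biased estimator can
#'     reject on the wrong side.
#'   \item `bias_anova` = mean over replicates of
#'     (beta_ANCOVA - beta_ANOVA) and `bias_csa` of
#'     (beta_ANCOVA - beta_CSA), computed pairwise on the same
#'     replicates so their Monte-Carlo standard errors
#'     (`mc_se_bias_*`) are the paired ones, far smaller than those of
#'     the individual means.
#'   \item `de_ancova_anova`, `de_csa_anova`, `de_ancova_csa` are ratios
#'     of mean model-based SEs (mean first, then ratio), so
#'     `de_ancova_csa = de_ancova_anova / de_csa_anova` holds exactly.
#' }
#'
#' @param spec A [scenario_spec()].
#' @param n_reps Number of replicates (>= 1).
#' @param master_seed Integer master seed.
#' @param scenario_index 1-based index used in seed derivation; pass the
#'   position in the grid when running many scenarios.
#' @return A one-row `data.frame` (class `scenario_summary`) with the
#'   scenario parameters and the aggregates above.
#' @examples
#' run_scenario(scenario_spec(0.5, 0.5, 1.28, 64), n_reps = 50,
#'              master_seed = 1)
#' @export
run_scenario <- function(spec, n_reps, master_seed, scenario_index = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps)) {
    stop("'n_reps' must be a single integer >= 1", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  b <- matrix(NA_real_, n_reps, 3L,
              dimnames = list(NULL, c("anova", "csa", "ancova")))
  se <- b
  p <- b
  for (r in seq_len(n_reps)) {
    trial <- generate_trial(
      spec, replicate_seed(master_seed, scenario_index, r))
    fits <- list(fit_anova(trial), fit_csa(trial), fit_ancova(trial))
    b[r, ] <- vapply(fits, `[[`, numeric(1), "beta")
    se[r, ] <- vapply(fits, `[[`, numeric(1), "se")
    p[r, ] <- vapply(fits, `[[`, numeric(1), "p_value")
  }
  mean_se <- colMeans(se)
  diff_aa <- b[, "ancova"] - b[, "anova"]
  diff_ac <- b[, "ancova"] - b[, "csa"]
  rej <- p < spec$alpha
  rej_pos <- rej & b > 0
  out <- data.frame(
    deviate = spec$deviate, rho = spec$rho, effect = spec$effect,
    n_per_group = spec$n_per_group, alpha = spec$alpha, n_reps = n_reps,
    mean_beta_anova = mean(b[, "anova"]),
    mean_beta_csa = mean(b[, "csa"]),
    mean_beta_ancova = mean(b[, "ancova"]),
    sd_beta_anova = stats::sd(b[, "anova"]),
    sd_beta_csa = stats::sd(b[, "csa"]),
    sd_beta_ancova = stats::sd(b[, "ancova"]),
    mc_se_beta_anova = stats::sd(b[, "anova"]) / sqrt(n_reps),
    mc_se_beta_csa = stats::sd(b[, "csa"]) / sqrt(n_reps),
    mc_se_beta_ancova = stats::sd(b[, "ancova"]) / sqrt(n_reps),
    mean_se_anova = mean_se[["anova"]],
    mean_se_csa = mean_se[["csa"]],
    mean_se_ancova = mean_se[["ancova"]],
    power_anova = mean(rej[, "anova"]),
    power_csa = mean(rej[, "csa"]),
    power_ancova = mean(rej[, "ancova"]),
    power_pos_anova = mean(rej_pos[, "anova"]),
    power_pos_csa = mean(rej_pos[, "csa"]),
    power_pos_ancova = mean(rej_pos[, "ancova"]),
    bias_anova = mean(diff_aa),
    bias_csa = mean(diff_ac),
    mc_se_bias_anova = stats::sd(diff_aa) / sqrt(n_reps),
    mc_se_bias_csa = stats::sd(diff_ac) / sqrt(n_reps),
    de_ancova_anova = mean_se[["ancova"]] / mean_se[["anova"]],
    de_csa_anova = mean_se[["csa"]] / mean_se[["anova"]],
    de_ancova_csa = mean_se[["ancova"]] / mean_se[["csa"]],
    row.names = NULL
  )
  class(out) <- c("scenario_summary", "data.frame")
  out
}

#' Configure a factorial scenario grid
#'
#' Levels of the three experimental factors plus run settings. Effects
#' and per-group sample sizes are paired, not crossed: each effect size
#' carries the sample size giving it 80% nominal power, so the grid is
#' deviates x correlations x (effect, n) pairs. The defaults are the
#' 7 x 6 x 3 = 126-scenario design: deviates -1.96 ... 1.96,
#' correlations 0 ... 0.9, effects 0.2/0.5/0.8 with n = 394/64/26.
#'
#' @param deviates Numeric vector of signed imbalance deviates.
#' @param correlations Numeric vector of baseline-outcome correlations.
#' @param effects Numeric vector of standardized treatment effects.
#' @param n_per_group Integer vector of per-group sizes, same length as
#'   `effects`.
#' @param n_reps Default replicate count for [run_grid()].
#' @param alpha Two-sided significance level.
#' @param master_seed Default master seed for [run_grid()].
#' @return List of class `grid_config`.
#' @export
grid_config <- function(deviates = c(-1.96, -1.64, -1.28, 0, 1.28, 1.64, 1.96),
                        correlations = c(0, 0.1, 0.3, 0.5, 0.7, 0.9),
                        effects = c(0.2, 0.5, 0.8),
                        n_per_group = c(394L, 64L, 26L),
                        n_reps = 1000L,
                        alpha = 0.05,
                        master_seed = 1L) {
  if (length(deviates) == 0 || length(correlations) == 0 ||
      length(effects) == 0) {
    stop("factor level lists must be non-empty", call. = FALSE)
  }
  if (length(effects) != length(n_per_group)) {
    stop("'effects' and 'n_per_group' must have equal length (paired levels)",
         call. = FALSE)
  }
  structure(
    list(deviates = as.numeric(deviates),
         correlations = as.numeric(correlations),
         effects = as.numeric(effects),
         n_per_group = as.integer(n_per_group),
         n_reps = as.integer(n_reps),
         alpha = alpha,
         master_seed = as.integer(master_seed)),
    class = "grid_config"
  )
}

#' Read a grid configuration from a YAML file
#'
#' Recognized keys: `deviates`, `correlations`, `effects`,
#' `n_per_group`, `n_reps`, `alpha`, `master_seed`; missing keys fall
#' back to the [grid_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `grid_config`.
#' @export
read_grid_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(grid_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(grid_config, raw)
}

#' Expand a configuration into the ordered list of scenarios
#'
#' Deterministic order: deviate varies slowest (in the order configured),
#' then correlation, then the (effect, n) pair fastest. The default
#' configuration yields the 126 scenarios of the full design.
#'
#' @param config A [grid_config()].
#' @return A `data.frame` with one row per scenario: `scenario`,
#'   `deviate`, `rho`, `effect`, `n_per_group`, `alpha`.
#' @examples
#' nrow(build_grid(grid_config())) # 126
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  pairs <- seq_along(config$effects)
  grid <- expand.grid(pair = pairs,
                      rho = config$correlations,
                      deviate = config$deviates,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    scenario = seq_len(nrow(grid)),
    deviate = grid$deviate,
    rho = grid$rho,
    effect = config$effects[grid$pair],
    n_per_group = config$n_per_group[grid$pair],
    alpha = config$alpha
  )
}

grid_row_spec <- function(row) {
  scenario_spec(effect = row$effect, rho = row$rho, deviate = row$deviate,
                n_per_group = row$n_per_group, alpha = row$alpha)
}

#' Run every scenario of a grid
#'
#' Executes [run_scenario()] for each row of [build_grid()] with the
#' scenario's grid index feeding the seed derivation, so the full run is
#' deterministic given `master_seed` and any scenario can be reproduced
#' on its own.
#'
#' @param config A [grid_config()].
#' @param n_reps Replicates per scenario; defaults to `config$n_reps`.
#' @param master_seed Master seed; defaults to `config$master_seed`.
#' @param verbose Emit a progress message per scenario.
#' @param on_error `"stop"` (default) fails fast on the first scenario
#'   error; `"continue"` records the error as a warning and carries on,
#'   dropping that scenario's row.
#' @return A `data.frame` of class `grid_summaries`: one
#'   [run_scenario()] row per scenario, with a `scenario` index column.
#' @export
run_grid <- function(config, n_reps = config$n_reps,
                     master_seed = config$master_seed,
                     verbose = FALSE, on_error = c("stop", "continue")) {
  stopifnot(inherits(config, "grid_config"))
  on_error <- match.arg(on_error)
  grid <- build_grid(config)
  t0 <- proc.time()[["elapsed"]]
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    res <- tryCatch(
      run_scenario(grid_row_spec(row), n_reps, master_seed,
                   scenario_index = i),
      error = function(e) {
        msg <- sprintf(
          "scenario %d (deviate=%g, rho=%g, effect=%g, n=%d): %s",
          i, row$deviate, row$rho, row$effect, row$n_per_group,
          conditionMessage(e))
        if (on_error == "stop") stop(msg, call. = FALSE)
        warning(msg, call. = FALSE)
        NULL
      })
    if (!is.null(res)) {
      res <- cbind(scenario = i, res)
      rows[[i]] <- res
    }
    if (verbose) {
      message(sprintf(
        "[%3d/%d] deviate=%+.2f rho=%.1f effect=%.1f n=%d (%d reps, %.1fs elapsed)",
        i, nrow(grid), row$deviate, row$rho, row$effect, row$n_per_group,
        n_reps, proc.time()[["elapsed"]] - t0))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL) # every scenario failed under "continue"
  class(out) <- c("grid_summaries", "data.frame")
  rownames(out) <- NULL
  out
}
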