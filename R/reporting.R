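#' Arrange grid summaries as a results table
#'
#' Reshapes a full-factorial set of scenario summaries into one of the
#' three wide result tables, with one row per (comparison-or-method,
#' deviate) and one column per (effect, correlation) combination:
#' \describe{
#'   \item{`"bias"`}{mean paired coefficient differences ANCOVA-ANOVA
#'     and ANCOVA-CSA, SD units, rounded to 2 decimals.}
#'   \item{`"design_effect"`}{ratios of mean model-based standard
#'     errors ANCOVA/ANOVA, CSA/ANOVA and ANCOVA/CSA, 2 decimals.}
#'   \item{`"power_increment"`}{`100 * power - 80` for ANCOVA, CSA and
#'     ANOVA: the increment (positive) or decrement (negative) of
#'     Monte-Carlo power, in percentage points, relative to the 80%
#'     nominal level the sample sizes were chosen for.}
#' }
#' Rows are ordered by deviate ascending (-1.96 ... 1.96); columns are
#' named `effect{e}_rho{r}` with effect slowest and correlation
#' ascending.
#'
#' @param summaries A `data.frame` of [run_scenario()] rows covering a
#'   complete deviates x correlations x effects factorial (e.g. from
#'   [run_grid()], or re-read from its CSV). A missing cell is an error
#'   naming the absent combination.
#' @param kind One of `"bias"`, `"design_effect"`, `"power_increment"`.
#' @param digits Rounding applied to the table values. Default 2.
#' @return A `data.frame` of class `result_table` with columns
#'   `comparison`, `deviate`, then one value column per (effect, rho);
#'   the table kind is kept in `attr(, "kind")`.
#' @examples
#' s <- run_grid(grid_config(deviates = c(-1.28, 1.28),
#'                           correlations = c(0, 0.5),
#'                           effects = 0.5, n_per_group = 64),
#'               n_reps = 20, master_seed = 1)
#' tabulate_results(s, "bias")
#' @export
tabulate_results <- function(summaries,
                             kind = c("bias", "design_effect",
                                      "power_increment"),
                             digits = 2) {
  kind <- match.arg(kind)
  req <- c("deviate", "rho", "effect")
  if (!all(req %in% names(summaries))) {
    stop("summaries must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  deviates <- sort(unique(summaries$deviate))
  rhos <- sort(unique(summaries$rho))
  effects <- sort(unique(summaries$effect))
  key <- function(dv, e, r) paste(dv, e, r, sep = "|")
  have <- key(summaries$deviate, summaries$effect, summaries$rho)
  if (anyDuplicated(have)) {
    stop("duplicate scenario cells in summaries", call. = FALSE)
  }
  idx <- stats::setNames(seq_len(nrow(summaries)), have)

  cols <- switch(kind,
    bias = c("ANCOVA-ANOVA" = "bias_anova", "ANCOVA-CSA" = "bias_csa"),
    design_effect = c("ANCOVA/ANOVA" = "de_ancova_anova",
                      "CSA/ANOVA" = "de_csa_anova",
                      "ANCOVA/CSA" = "de_ancova_csa"),
    power_increment = c("ANCOVA" = "power_ancova", "CSA" = "power_csa",
                        "ANOVA" = "power_anova"))

  out <- expand.grid(deviate = deviates, comparison = names(cols),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$comparison, names(cols)), out$deviate),
             c("comparison", "deviate")]
  rownames(out) <- NULL
  for (e in effects) {
    for (r in rhos) {
      colname <- paste0("effect", e, "_rho", r)
      vals <- numeric(nrow(out))
      for (i in seq_len(nrow(out))) {
        k <- key(out$deviate[i], e, r)
        j <- unname(idx[k])
        if (is.na(j)) {
          stop(sprintf("missing cell: deviate=%g, rho=%g, effect=%g",
                       out$deviate[i], r, e), call. = FALSE)
        }
        v <- summaries[[cols[[out$comparison[i]]]]][j]
        if (kind == "power_increment") v <- 100 * v - 80
        vals[i] <- round(v, digits)
      }
      out[[colname]] <- vals
    }
  }
  attr(out, "kind") <- kind
  class(out) <- c("result_table", "data.frame")
  out
}

#' Write result tables, raw summaries and a run manifest
#'
#' Writes one CSV per table (`<kind>.csv`), the full-precision
#' per-scenario summary (`scenario_summaries.csv`) and a plain-text
#' `manifest.txt` echoing the configuration, master seed, package
#' version and wall-clock time. The CSVs are byte-identical across runs
#' with the same configuration and seed; only the manifest carries
#' timing.
#'
#' @param tables List of `result_table` objects from
#'   [tabulate_results()].
#' @param summaries The `data.frame` of scenario summaries the tables
#'   were computed from.
#' @param out_dir Output directory (created if absent).
#' @param config Optional `grid_config` echoed into the manifest.
#' @param master_seed Optional master seed echoed into the manifest.
#' @param elapsed Optional wall-clock seconds echoed into the manifest.
#' @return Character vector of the paths written, invisibly.
#' @export
write_outputs <- function(tables, summaries, out_dir, config = NULL,
                          master_seed = NULL, elapsed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- character(0)
  for (tab in tables) {
    stopifnot(inherits(tab, "result_table"))
    p <- file.path(out_dir, paste0(attr(tab, "kind"), ".csv"))
    write_csv_checked(as.data.frame(tab), p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "scenario_summaries.csv")
  write_csv_checked(as.data.frame(summaries), p)
  paths <- c(paths, p)

  mp <- file.path(out_dir, "manifest.txt")
  lines <- c(
    sprintf("package: ancovasim %s",
            as.character(utils::packageVersion("ancovasim"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (!is.null(master_seed)) sprintf("master_seed: %d", master_seed),
    if (!is.null(elapsed)) sprintf("elapsed_seconds: %.1f", elapsed),
    sprintf("scenarios: %d", nrow(summaries)),
    if (!is.null(config)) c(
      "config:",
      sprintf("  deviates: %s", paste(config$deviates, collapse = ", ")),
      sprintf("  correlations: %s",
              paste(config$correlations, collapse = ", ")),
      sprintf("  effects: %s", paste(config$effects, collapse = ", ")),
      sprintf("  n_per_group: %s",
              paste(config$n_per_group, collapse = ", ")),
      sprintf("  n_reps: %d", config$n_reps),
      sprintf("  alpha: %g", config$alpha))
  )
  writeLines(lines, mp)
  invisible(c(paths, mp))
}

write_csv_checked <- function(df, path) {
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE),
    error = function(e) {
      stop(sprintf("failed to write %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
}
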