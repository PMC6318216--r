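#' @title Report writers and pipeline entry points
#' @description
#' `run_fit`, `run_compare` and `run_simulate` tie the pipeline together for
#' shell use (a thin `bcef.R` dispatcher ships in `inst/scripts/`); each
#' writes plain CSV/JSON with a fixed header and logs to stderr.  Numeric
#' columns are printed at the table precision used throughout: 4 decimals for
#' BCEF/FI/MEP/MPE, 1 decimal for AIC/SE%/CVr%.
#' @name bcef-report
NULL

fmt_num <- function(x, digits) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = digits))
}

format_bcef_table <- function(tab) {
  out <- tab
  for (col in c("bcef", "fi", "mep", "mpe")) {
    out[[col]] <- fmt_num(out[[col]], 4)
  }
  for (col in c("aic", "se_pct", "cvr_pct")) {
    out[[col]] <- fmt_num(out[[col]], 1)
  }
  out
}

log_msg <- function(verbose, ...) {
  if (verbose) message(...)
}

#' Fit and score BCEFs for a tree table, writing the report files
#'
#' Runs the full per-(species, component) analysis and writes:
#' `bcef_table.csv` (both methods, all six metrics), `intercept_tests.csv`
#' (the alpha = 0 test per cell), `ci_table.csv` (95% t intervals per fit)
#' and `run_log.txt` (seed, options, package version).
#'
#' @param data a [tree_data] table, or a path readable by
#'   [read_tree_table()].
#' @param output_dir directory for the report files (created if absent).
#' @param components components to score.
#' @param ratio_variant,gate_alpha,K,seed,hat_source see [compare_methods()].
#' @param level confidence level for `ci_table.csv`.
#' @param column_map forwarded to [read_tree_table()] when `data` is a path.
#' @param verbose log progress to stderr.
#' @return invisibly, a named list of the written file paths.
#' @export
run_fit <- function(data, output_dir, components = .components,
                    ratio_variant = "mean_of_ratios", gate_alpha = 0.05,
                    K = 10L, seed = 1L, hat_source = "own", level = 0.95,
                    column_map = NULL, verbose = TRUE) {
  if (is.character(data)) {
    data <- read_tree_table(data, column_map = column_map)
  }
  stopifnot(inherits(data, "tree_data"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- compare_methods(data, components = components,
                         ratio_variant = ratio_variant,
                         gate_alpha = gate_alpha, K = K, seed = seed,
                         hat_source = hat_source)
  bcef_path <- file.path(output_dir, "bcef_table.csv")
  utils::write.csv(format_bcef_table(tab), bcef_path, row.names = FALSE,
                   quote = TRUE, na = "")
  # intercept tests and confidence intervals per cell
  it_rows <- list()
  ci_rows <- list()
  for (sp in unique(data$species)) {
    sub <- data[data$species == sp, , drop = FALSE]
    for (comp in intersect(components, .components)) {
      W <- sub[[paste0("w_", comp)]]
      V <- sub$volume_m3
      if (length(W) < 3 || stats::var(V) == 0) next
      it <- tryCatch(intercept_zero_test(W, V), error = function(e) NULL)
      if (!is.null(it)) {
        it_rows[[length(it_rows) + 1L]] <- data.frame(
          species = sp, component = comp,
          alpha = fmt_num(it$alpha_hat, 4), beta = fmt_num(it$beta_hat, 4),
          t = fmt_num(it$t_stat, 4), p_value = fmt_num(it$p_value, 4),
          df = it$df, stringsAsFactors = FALSE
        )
      }
      for (row in which(tab$species == sp & tab$component == comp &
                          !tab$flagged)) {
        m <- tab$method[row]
        fit <- if (m == "ratio") {
          ratio_bcef(W, V, ratio_variant)
        } else if (tab$method_detail[row] == "glm_rto") {
          glm_rto_bcef(W, V)
        } else {
          ls_rto_bcef(W, V)
        }
        ci <- confidence_interval(fit, level = level)
        ci_rows[[length(ci_rows) + 1L]] <- data.frame(
          species = sp, component = comp, method = m,
          bcef = fmt_num(fit$estimate, 4), lower = fmt_num(ci$lower, 4),
          upper = fmt_num(ci$upper, 4), significant = ci$significant,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  it_path <- file.path(output_dir, "intercept_tests.csv")
  ci_path <- file.path(output_dir, "ci_table.csv")
  utils::write.csv(do.call(rbind, it_rows), it_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, ci_rows), ci_path, row.names = FALSE)
  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(c(
    paste0("bcef version: ", as.character(utils::packageVersion("bcef"))),
    paste0("seed: ", seed),
    paste0("ratio_variant: ", ratio_variant),
    paste0("gate_alpha: ", gate_alpha),
    paste0("K: ", K),
    paste0("hat_source: ", hat_source),
    paste0("n_trees: ", nrow(data))
  ), log_path)
  log_msg(verbose, "wrote ", bcef_path, ", ", it_path, ", ", ci_path)
  invisible(list(bcef_table = bcef_path, intercept_tests = it_path,
                 ci_table = ci_path, run_log = log_path))
}

#' Summarize a BCEF comparison table, writing reductions and headlines
#'
#' Writes `reductions.csv` (per-metric, per-pair relative reductions with
#' all-pairs and positive-only min/max) and `headline.json` (maximum AIC,
#' MEP and MPE reductions, minimum positive MPE reduction, and the maximum
#' biomass difference per 100 m^3 with its percentage).
#'
#' @param table a `bcef_comparison`, or a path to a CSV readable by
#'   [read_bcef_table()].
#' @param output_dir directory for the report files.
#' @param verbose log progress to stderr.
#' @return invisibly, a list with the headline values and file paths.
#' @export
run_compare <- function(table, output_dir, verbose = TRUE) {
  if (is.character(table)) table <- read_bcef_table(table)
  if (!nrow(table)) stop("empty comparison table", call. = FALSE)
  table <- table[!(if (is.null(table$flagged)) FALSE else table$flagged), ,
                 drop = FALSE]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  red_rows <- list()
  summaries <- list()
  for (metric in .comparison_metrics) {
    red <- relative_reduction(table, metric)
    rows <- red$rows
    rows$metric <- metric
    red_rows[[metric]] <- rows
    summaries[[metric]] <- red
  }
  reductions <- do.call(rbind, red_rows)
  reductions$reduction_pct <- fmt_num(reductions$reduction_pct, 1)
  red_path <- file.path(output_dir, "reductions.csv")
  utils::write.csv(reductions, red_path, row.names = FALSE, na = "")
  bio <- biomass_difference_per_100m3(table)
  headline <- list(
    max_aic_reduction_pct = summaries$aic$max,
    max_mep_reduction_pct = summaries$mep$max,
    max_mpe_reduction_pct = summaries$mpe$max,
    min_positive_mpe_reduction_pct = summaries$mpe$min_positive,
    max_biomass_diff_mg_per_100m3 = bio$max_diff_mg_ha,
    biomass_diff_pct_at_max = bio$pct_at_max_diff
  )
  head_path <- file.path(output_dir, "headline.json")
  jsonlite::write_json(headline, head_path, auto_unbox = TRUE, digits = NA)
  log_msg(verbose, "wrote ", red_path, " and ", head_path)
  invisible(c(headline, list(reductions = red_path, headline = head_path)))
}

#' Simulate a population and write it as a tree table
#'
#' @param spec a [synthetic_spec()], a list of them, or a YAML path.
#' @param seed base integer seed.
#' @param out output CSV path.
#' @param verbose log progress to stderr.
#' @return invisibly, `out`.
#' @export
run_simulate <- function(spec, seed, out, verbose = TRUE) {
  if (is.character(spec)) spec <- read_synthetic_spec(spec)
  if (inherits(spec, "synthetic_spec")) spec <- list(spec)
  pop <- generate_scenario(spec, seed = seed)
  write_tree_table(pop, out)
  log_msg(verbose, "wrote ", nrow(pop), " trees to ", out)
  invisible(out)
}

#' Quick self-check of the package's core identities
#'
#' Verifies, on small random instances, the invariants the estimators and
#' metrics are built on: the through-origin normal equation, hat diagonals
#' summing to one, MEP equal to PRESS/n under explicit leave-one-out
#' refitting, and weighted-least-squares equivalence of the ratio
#' estimators.  Stops on the first violation.
#'
#' @param n_cases number of random instances.
#' @param seed RNG seed.
#' @return `TRUE` invisibly.
#' @export
run_validate <- function(n_cases = 25L, seed = 1L) {
  set.seed(seed)
  for (case in seq_len(n_cases)) {
    n <- sample(3:12, 1)
    V <- stats::rlnorm(n, 0, 0.8)
    W <- 0.7 * V + stats::rnorm(n, 0, 0.2 * sqrt(V))
    W <- abs(W) + 1e-6
    ls <- ls_rto_bcef(W, V)
    stopifnot(abs(sum(V * ls$residuals)) <= 1e-8 * sum(abs(W * V)))
    for (m in c("ls_rto", "ratio_mean_of_ratios", "ratio_ratio_of_means")) {
      h <- hat_diagonal(V, m)
      stopifnot(abs(sum(h) - 1) < 1e-10)
      fit <- refit_bcef(W, V, m)
      press <- mean(vapply(seq_len(n), function(i) {
        (W[i] - refit_bcef(W[-i], V[-i], m)$estimate * V[i])^2
      }, numeric(1)))
      stopifnot(abs(mep(fit$residuals, h) - press) <= 1e-9 * max(press, 1e-12))
    }
    w_ls <- function(wts) sum(wts * W * V) / sum(wts * V^2)
    stopifnot(abs(w_ls(1 / V) - ratio_bcef(W, V, "ratio_of_means")$estimate)
              <= 1e-10 * abs(w_ls(1 / V)))
    stopifnot(abs(w_ls(1 / V^2) - ratio_bcef(W, V, "mean_of_ratios")$estimate)
              <= 1e-10 * abs(w_ls(1 / V^2)))
  }
  invisible(TRUE)
}
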