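#' Side-by-side scoring of ratio-based vs LS-based BCEFs
#'
#' For every species x component subset of the tree table, fits the
#' configured ratio estimator and the least-squares estimator (with the
#' residual-normality gate and GLM fallback), scores both with the full
#' metric suite, and assembles a paired comparison table.  Subsets with fewer
#' than 3 trees are kept as flagged rows with `NA` metrics rather than
#' dropped.
#'
#' @param data a [tree_data] table.
#' @param components components to score (default all five).
#' @param ratio_variant `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param gate_alpha significance level of the residual-normality gate.
#' @param K,seed cross-validation folds and seed (seed is advanced
#'   deterministically per subset so every cell is reproducible).
#' @param hat_source leverage convention for MEP.  The default `"ls"`
#'   applies the projection-matrix diagonal of the through-origin model
#'   (`V_i^2 / sum V^2`) to both methods, scoring them against the same
#'   leverage structure; `"own"` uses each estimator's own smoother
#'   leverage, under which MEP equals that estimator's PRESS/n.
#' @return a data.frame of class `bcef_comparison` with one row per
#'   species x component x method (`method` is `"ratio"` or `"ls"`;
#'   `method_detail` records the estimator actually used), columns `bcef`,
#'   `se_pct`, `aic`, `cvr_pct`, `fi`, `mep`, `mpe`, `n`, `flagged`.
#' @export
compare_methods <- function(data, components = .components,
                            ratio_variant = c("mean_of_ratios",
                                              "ratio_of_means"),
                            gate_alpha = 0.05, K = 10L, seed = NULL,
                            hat_source = c("ls", "own")) {
  stopifnot(inherits(data, "tree_data"))
  ratio_variant <- match.arg(ratio_variant)
  hat_source <- match.arg(hat_source)
  components <- match.arg(components, .components, several.ok = TRUE)
  species <- unique(data$species)
  rows <- list()
  cell <- 0L
  for (sp in species) {
    sub <- data[data$species == sp, , drop = FALSE]
    for (comp in components) {
      cell <- cell + 1L
      W <- sub[[paste0("w_", comp)]]
      V <- sub$volume_m3
      cell_seed <- if (is.null(seed)) NULL else (seed + cell) %% .Machine$integer.max
      if (length(W) < 3) {
        for (m in c("ratio", "ls")) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, component = comp, method = m, method_detail = NA,
            bcef = NA_real_, aic = NA_real_, se_pct = NA_real_,
            cvr_pct = NA_real_, fi = NA_real_, mep = NA_real_,
            mpe = NA_real_, n = length(W), flagged = TRUE,
            stringsAsFactors = FALSE
          )
        }
        next
      }
      ratio_fit <- ratio_bcef(W, V, ratio_variant, component = comp,
                              species = sp)
      ls_fit <- fit_bcef_auto(W, V, alpha_level = gate_alpha,
                              component = comp, species = sp)
      for (m in c("ratio", "ls")) {
        fit <- if (m == "ratio") ratio_fit else ls_fit
        sc <- score_fit(fit, K = K, seed = cell_seed, hat_source = hat_source)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, component = comp, method = m,
          method_detail = fit$method, bcef = fit$estimate, aic = sc$aic,
          se_pct = sc$se_pct, cvr_pct = sc$cvr_pct, fi = sc$fi,
          mep = sc$mep, mpe = sc$mpe, n = fit$n, flagged = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bcef_comparison", "data.frame")
  out
}

.comparison_metrics <- c("aic", "se_pct", "cvr_pct", "fi", "mep", "mpe")

pair_table <- function(table) {
  stopifnot(is.data.frame(table))
  needed <- c("species", "component", "method")
  if (!all(needed %in% names(table))) {
    stop("comparison table needs columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  ratio <- table[table$method == "ratio", , drop = FALSE]
  ls <- table[table$method == "ls", , drop = FALSE]
  key <- function(d) paste(d$species, d$component, sep = "\r")
  if (!setequal(key(ratio), key(ls)) ||
      anyDuplicated(key(ratio)) || anyDuplicated(key(ls))) {
    stop("unpaired rows: every (species, component) needs exactly one ",
         "'ratio' and one 'ls' row; offending keys: ",
         paste(unique(c(setdiff(key(ratio), key(ls)),
                        setdiff(key(ls), key(ratio)))), collapse = "; "),
         call. = FALSE)
  }
  ls <- ls[match(key(ratio), key(ls)), , drop = FALSE]
  list(ratio = ratio, ls = ls)
}

#' Per-pair relative reduction of a metric (ratio vs LS)
#'
#' For each (species, component) pair computes
#' `100 * (m_ratio - m_ls) / |m_ratio|` -- positive when the least-squares
#' fit scores lower (better) on the metric, sign retained otherwise.  The
#' absolute-value denominator is what makes the percentage meaningful for
#' AIC, which is negative for small-biomass components.  Summaries are
#' reported over all finite pairs and over the positive pairs alone.
#'
#' @param table a paired comparison table ([compare_methods()] output or the
#'   bundled reference table).
#' @param metric one of `aic`, `se_pct`, `cvr_pct`, `fi`, `mep`, `mpe`.
#' @return list with `rows` (species, component, metric values, reduction
#'   pct), `min`, `max` (over finite pairs), `min_positive`, `max_positive`,
#'   and `excluded` (keys where the reduction is undefined).
#' @export
relative_reduction <- function(table, metric) {
  metric <- match.arg(metric, .comparison_metrics)
  p <- pair_table(table)
  m_ratio <- p$ratio[[metric]]
  m_ls <- p$ls[[metric]]
  red <- ifelse(m_ratio == 0 & m_ls == 0, 0,
                100 * (m_ratio - m_ls) / abs(m_ratio))
  undef <- which(m_ratio == 0 & m_ls != 0)
  red[undef] <- NA_real_
  rows <- data.frame(species = p$ratio$species,
                     component = p$ratio$component,
                     ratio = m_ratio, ls = m_ls, reduction_pct = red,
                     stringsAsFactors = FALSE)
  fin <- red[is.finite(red)]
  pos <- fin[fin > 0]
  list(metric = metric, rows = rows,
       min = if (length(fin)) min(fin) else NA_real_,
       max = if (length(fin)) max(fin) else NA_real_,
       min_positive = if (length(pos)) min(pos) else NA_real_,
       max_positive = if (length(pos)) max(pos) else NA_real_,
       excluded = rows[undef, c("species", "component")])
}

#' Biomass difference per 100 m^3 of stem volume
#'
#' The practical consequence of the estimator choice: for every paired cell,
#' `(BCEF_ratio - BCEF_ls) * 100` is the extra biomass (Mg) the ratio-based
#' factor assigns to each 100 m^3 ha^-1 of standing stem volume, and
#' `100 * (BCEF_ratio - BCEF_ls) / BCEF_ls` the same gap in percent.  The
#' summary reports the maximum absolute difference together with the
#' percentage of that same cell (the headline pair), plus the overall
#' maximum percentage.
#'
#' @param table a paired comparison table with a `bcef` column.
#' @return list with `rows`, `max_diff_mg_ha`, `pct_at_max_diff`,
#'   `max_pct`.
#' @export
biomass_difference_per_100m3 <- function(table) {
  p <- pair_table(table)
  diff_mg <- (p$ratio$bcef - p$ls$bcef) * 100
  pct <- 100 * (p$ratio$bcef - p$ls$bcef) / p$ls$bcef
  rows <- data.frame(species = p$ratio$species,
                     component = p$ratio$component,
                     bcef_ratio = p$ratio$bcef, bcef_ls = p$ls$bcef,
                     diff_mg_per_100m3 = diff_mg, diff_pct = pct,
                     stringsAsFactors = FALSE)
  i_max <- which.max(diff_mg)
  list(rows = rows,
       max_diff_mg_ha = diff_mg[i_max],
       pct_at_max_diff = pct[i_max],
       max_pct = max(pct[is.finite(pct)]))
}

#' Bundled reference comparison table
#'
#' The published ratio-based vs LS-based BCEF comparison for four Mozambican
#' timber species (Colophospermum mopane, Afzelia quanzensis, Millettia
#' stuhlmannii, Pterocarpus angolensis): one row per species x component x
#' method with the six metrics, as printed.  Used for summary arithmetic and
#' as a worked example; the underlying 75-tree sample is not distributed.
#'
#' @return a `bcef_comparison` data.frame (40 rows).
#' @export
reference_bcef_table <- function() {
  path <- system.file("extdata", "reference_bcef_table.csv", package = "bcef",
                      mustWork = TRUE)
  read_bcef_table(path)
}

#' Read a BCEF comparison table from CSV
#'
#' @param path CSV with columns `species`, `component`, `method`, `bcef`,
#'   `aic`, `se_pct`, `cvr_pct`, `fi`, `mep`, `mpe`.
#' @return a `bcef_comparison` data.frame.
#' @export
read_bcef_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "component", "method", "bcef", .comparison_metrics)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("BCEF table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("bcef_comparison", "data.frame")
  tab
}
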