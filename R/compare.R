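# Per-layer, per-feature two-group comparison table: group moments, ANOVA
# significance at a fixed threshold, and the full ROC summary -- one row per
# layer per feature.

#' Compare layers between two groups
#'
#' For every layer and every requested feature, computes group means and
#' SDs, the one-way ANOVA F/p with significance at the fixed `alpha`, the
#' AUROC with Hanley-McNeil SE and asymptotic 95% CI under the fixed
#' orientation, and cutoff / sensitivity / specificity / PLR by the chosen
#' rule. Eyes missing a value for a feature are excluded from that row only
#' (count recorded in `n_excluded`).
#'
#' @param study eye-level feature table: data frame with `eye_id`, `group`
#'   and columns `<feature>_<layer>` (see [make_cohort()] or
#'   [run_pipeline()] output).
#' @param features feature prefixes to analyze (default
#'   `c("thickness", "fd", "refl")`; only those present are used).
#' @param healthy,diseased the two group labels in `study$group`.
#' @param alpha fixed significance threshold (default 0.001).
#' @param cutoff_rule,direction passed to [select_cutoff()]. The
#'   orientation is fixed across all rows; AUROCs below 0.5 are reported
#'   as-is, never flipped.
#' @return object of class `layer_comparison`: a data frame, one row per
#'   layer x feature, with columns `layer`, `feature`, `healthy_mean`,
#'   `healthy_sd`, `diseased_mean`, `diseased_sd`, `f`, `p`, `significant`,
#'   `auroc`, `auroc_se`, `ci_low`, `ci_high`, `cutoff`, `sensitivity`,
#'   `specificity`, `plr`, `n_healthy`, `n_diseased`, `n_excluded`.
#' @export
compare_layers <- function(study, features = c("thickness", "fd", "refl"),
                           healthy = "healthy", diseased = "MDR",
                           alpha = 0.001,
                           cutoff_rule = "mean_minus_2sd",
                           direction = "low") {
  stopifnot(is.data.frame(study),
            all(c("eye_id", "group") %in% names(study)))
  if (!all(c(healthy, diseased) %in% study$group)) {
    stop("study table must contain both groups '", healthy, "' and '",
         diseased, "'", call. = FALSE)
  }
  rows <- list()
  for (feat in features) {
    for (lay in retinal_layers()) {
      col <- paste0(feat, "_", lay)
      if (!col %in% names(study)) next
      v <- study[[col]]
      ok <- is.finite(v)
      n_excluded <- sum(!ok)
      hv <- v[ok & study$group == healthy]
      dv <- v[ok & study$group == diseased]
      if (length(hv) < 2 || length(dv) < 2) {
        rows[[col]] <- data.frame(
          layer = lay, feature = feat,
          healthy_mean = if (length(hv)) mean(hv) else NA_real_,
          healthy_sd = NA_real_, diseased_mean = if (length(dv))
            mean(dv) else NA_real_, diseased_sd = NA_real_,
          f = NA_real_, p = NA_real_, significant = NA,
          auroc = NA_real_, auroc_se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, cutoff = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_, plr = NA_real_,
          n_healthy = length(hv), n_diseased = length(dv),
          n_excluded = n_excluded)
        next
      }
      av <- anova_oneway(c(hv, dv),
                         rep(c(healthy, diseased), c(length(hv), length(dv))))
      rr <- select_cutoff(dv, hv, rule = cutoff_rule, direction = direction)
      rows[[col]] <- data.frame(
        layer = lay, feature = feat,
        healthy_mean = mean(hv), healthy_sd = stats::sd(hv),
        diseased_mean = mean(dv), diseased_sd = stats::sd(dv),
        f = av$f, p = av$p, significant = av$p < alpha,
        auroc = rr$auroc, auroc_se = rr$se,
        ci_low = rr$ci_low, ci_high = rr$ci_high,
        cutoff = rr$cutoff, sensitivity = rr$sensitivity,
        specificity = rr$specificity, plr = rr$plr,
        n_healthy = length(hv), n_diseased = length(dv),
        n_excluded = n_excluded)
    }
  }
  if (!length(rows)) stop("no feature columns found in the study table",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "direction") <- direction
  attr(out, "cutoff_rule") <- cutoff_rule
  class(out) <- c("layer_comparison", "data.frame")
  out
}

#' @export
print.layer_comparison <- function(x, ...) {
  cat(sprintf(
    "Layer comparison (alpha = %g, orientation: disease %s, cutoff rule: %s)\n",
    attr(x, "alpha"),
    if (attr(x, "direction") == "low") "low" else "high",
    attr(x, "cutoff_rule")))
  show <- x[, c("layer", "feature", "healthy_mean", "healthy_sd",
                "diseased_mean", "diseased_sd", "p", "significant",
                "auroc", "auroc_se", "cutoff", "plr")]
  print.data.frame(show, digits = 4, row.names = FALSE)
  invisible(x)
}
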