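# ROC / AUROC diagnostics with a fixed orientation.
#
# Orientation is declared per feature, never auto-flipped: `direction =
# "low"` means low values call disease (the convention behind sub-0.5
# AUROCs in fixed-orientation reporting). The AUROC is the concordance
# probability P(case on the disease side of control) with weight 1/2 at
# ties -- identical to the Mann-Whitney U statistic divided by n1*n2.

disease_score <- function(x, direction) {
  direction <- match.arg(direction, c("low", "high"))
  if (direction == "low") -as.numeric(x) else as.numeric(x)
}

#' Empirical AUROC
#'
#' Rank-based (Mann-Whitney) computation of the area under the empirical
#' ROC curve, ties counted with weight 1/2.
#'
#' @param cases,controls numeric feature values of the diseased / healthy
#'   group.
#' @param direction `"low"` if low values call disease (default), `"high"`
#'   otherwise.
#' @return the AUROC in `[0, 1]`.
#' @export
auroc <- function(cases, controls, direction = "low") {
  sc <- disease_score(cases, direction)
  sn <- disease_score(controls, direction)
  n1 <- length(sc); n2 <- length(sn)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(sc, sn))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC curve
#'
#' Curve over all distinct thresholds of the feature, under the declared
#' fixed orientation ("disease called" when the value is at or beyond the
#' threshold on the disease side).
#'
#' @inheritParams auroc
#' @return object of class `roc_curve`: data frame with columns `fpr`
#'   (1 - specificity), `tpr` (sensitivity) and `threshold`, ordered from
#'   (0,0) to (1,1); the AUROC is attached as attribute `auroc`.
#' @export
roc_curve <- function(cases, controls, direction = "low") {
  sc <- disease_score(cases, direction)
  sn <- disease_score(controls, direction)
  if (!length(sc) || !length(sn)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  thr <- sort(unique(c(sc, sn)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(sc >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sn >= t), numeric(1))
  sign_thr <- if (match.arg(direction, c("low", "high")) == "low") -thr else thr
  out <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(NA_real_, sign_thr))
  attr(out, "auroc") <- auroc(cases, controls, direction)
  attr(out, "direction") <- direction
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d points, AUROC = %.4f (direction: %s)\n",
              nrow(x), attr(x, "auroc"), attr(x, "direction")))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUROC = %.3f", attr(x, "auroc")), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Hanley-McNeil standard error of an AUROC
#'
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. The asymptotic 95% confidence
#' interval is `A +/- 1.96 SE`.
#'
#' @param a the AUROC in `[0, 1]`.
#' @param n_cases,n_controls group sizes.
#' @return the standard error.
#' @export
auroc_se <- function(a, n_cases, n_controls) {
  stopifnot(a >= 0, a <= 1, n_cases >= 1, n_controls >= 1)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_cases - 1) * (q1 - a^2) +
          (n_controls - 1) * (q2 - a^2)) / (n_cases * n_controls))
}

#' Cutoff selection and ROC summary for one feature
#'
#' Builds the full `roc_result` for a two-group feature: AUROC with
#' Hanley-McNeil SE and asymptotic 95% CI, a cutoff by the requested rule,
#' and sensitivity / specificity / positive likelihood ratio at that cutoff
#' under the "at-or-beyond the cutoff calls disease" convention of the
#' declared direction.
#'
#' Rules: `"mean_minus_2sd"` places the cutoff two healthy SDs from the
#' healthy mean on the disease side (mean - 2SD when disease lowers the
#' feature, mean + 2SD when it raises it); `"youden"` maximizes
#' sensitivity + specificity - 1 over observed thresholds, breaking ties
#' toward higher specificity.
#'
#' @inheritParams auroc
#' @param rule `"mean_minus_2sd"` (default) or `"youden"`.
#' @return object of class `roc_result`: list with `auroc`, `se`, `ci_low`,
#'   `ci_high`, `cutoff`, `cutoff_rule`, `sensitivity`, `specificity`,
#'   `plr`, `plr_infinite`, `direction`, `n_cases`, `n_controls`,
#'   `degenerate_sd` (TRUE when the healthy SD was zero and the rule
#'   degenerated to the mean).
#' @export
select_cutoff <- function(cases, controls,
                          rule = c("mean_minus_2sd", "youden"),
                          direction = "low") {
  rule <- match.arg(rule)
  direction <- match.arg(direction, c("low", "high"))
  if (!length(cases) || !length(controls)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  a <- auroc(cases, controls, direction)
  se <- auroc_se(a, length(cases), length(controls))
  degenerate_sd <- FALSE
  if (rule == "mean_minus_2sd") {
    m <- mean(controls); s <- stats::sd(controls)
    if (!is.finite(s) || s == 0) {
      s <- 0
      degenerate_sd <- TRUE
    }
    cutoff <- if (direction == "low") m - 2 * s else m + 2 * s
  } else {
    cand <- sort(unique(c(cases, controls)))
    sens <- vapply(cand, function(t) if (direction == "low")
      mean(cases <= t) else mean(cases >= t), numeric(1))
    spec <- vapply(cand, function(t) if (direction == "low")
      mean(controls > t) else mean(controls < t), numeric(1))
    j <- sens + spec - 1
    best <- which(j == max(j))
    # ties broken toward higher specificity
    cutoff <- cand[best[which.max(spec[best])]]
  }
  if (direction == "low") {
    sensitivity <- mean(cases <= cutoff)
    specificity <- mean(controls > cutoff)
  } else {
    sensitivity <- mean(cases >= cutoff)
    specificity <- mean(controls < cutoff)
  }
  plr_infinite <- specificity >= 1
  plr <- if (plr_infinite) Inf else sensitivity / (1 - specificity)
  structure(list(auroc = a, se = se,
                 ci_low = a - 1.96 * se, ci_high = a + 1.96 * se,
                 cutoff = cutoff, cutoff_rule = rule,
                 sensitivity = sensitivity, specificity = specificity,
                 plr = plr, plr_infinite = plr_infinite,
                 direction = direction,
                 n_cases = length(cases), n_controls = length(controls),
                 degenerate_sd = degenerate_sd),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC %.3f +/- %.3f (95%% CI %.3f-%.3f), n = %d cases / %d controls\n",
              x$auroc, x$se, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  cat(sprintf("cutoff %.6g (%s, disease %s): sens %.3f, spec %.3f, PLR %s\n",
              x$cutoff, x$cutoff_rule,
              if (x$direction == "low") "<= cutoff" else ">= cutoff",
              x$sensitivity, x$specificity,
              if (x$plr_infinite) "infinite" else sprintf("%.2f", x$plr)))
  if (x$degenerate_sd) cat("note: zero healthy SD; cutoff degenerated to the mean\n")
  invisible(x)
}
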