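# Group comparison: classical one-way ANOVA and the Newman-Keuls step-down
# studentized-range procedure.

#' One-way ANOVA for a feature across groups
#'
#' Classical between/within mean-square F test via
#' [stats::oneway.test()] with `var.equal = TRUE`. Significance in the
#' reporting functions is declared at a fixed threshold (default
#' `p < 0.001`). With zero within-group variance and unequal means the F
#' statistic is unbounded; the p value is reported as the machine floor and
#' flagged.
#'
#' @param values numeric vector of eye-level feature values.
#' @param group factor/character vector of group labels, same length.
#' @return list with `f`, `p`, `df_between`, `df_within`, `degenerate`
#'   (TRUE when within-group variance is zero with unequal means).
#' @export
anova_oneway <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  ok <- is.finite(values)
  values <- values[ok]; group <- droplevels(group[ok])
  means <- tapply(values, group, mean)
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    if (max(means) - min(means) > 0) {
      return(list(f = Inf, p = .Machine$double.xmin,
                  df_between = nlevels(group) - 1,
                  df_within = length(values) - nlevels(group),
                  degenerate = TRUE))
    }
    return(list(f = 0, p = 1, df_between = nlevels(group) - 1,
                df_within = length(values) - nlevels(group),
                degenerate = FALSE))
  }
  ht <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(f = unname(ht$statistic), p = unname(ht$p.value),
       df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]),
       degenerate = FALSE)
}

#' Newman-Keuls post-hoc pairwise comparisons
#'
#' Step-down studentized-range procedure after one-way ANOVA. Groups are
#' ordered by mean; for each pair the statistic
#' `q = |m_i - m_j| / sqrt(MSwithin / n_h)` (with `n_h` the harmonic mean of
#' the two group sizes) is compared to the studentized-range critical value
#' at span `r` = the number of ordered means the pair encloses. A pair
#' nested inside any non-significant span is declared non-significant
#' without testing (the step-down logic that keeps the procedure coherent).
#'
#' @param values numeric vector of feature values.
#' @param group group labels, same length.
#' @param alpha significance level in (0,1).
#' @return object of class `newman_keuls`: a data frame of pairwise rows
#'   (`group1`, `group2`, `diff`, `span`, `q`, `q_crit`, `p`,
#'   `significant`, `blocked`) with attributes `ms_within`, `df`, `alpha`,
#'   `unequal_n` (TRUE when harmonic means were needed).
#' @export
newman_keuls <- function(values, group, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  ok <- is.finite(values)
  values <- values[ok]; group <- droplevels(group[ok])
  k <- nlevels(group)
  ns <- as.vector(table(group))
  means <- tapply(values, group, mean)
  N <- length(values)
  df <- N - k
  msw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / df
  ord <- order(means)
  m <- means[ord]; n_ord <- ns[ord]; labs <- levels(group)[ord]
  sig <- matrix(NA, k, k) # [i, j] over ordered means, j > i
  rows <- list()
  for (r in k:2) {
    for (i in seq_len(k - r + 1)) {
      j <- i + r - 1
      blocked <- FALSE
      for (i2 in seq_len(i)) {
        for (j2 in j:k) {
          if ((j2 - i2 + 1) > r && isFALSE(sig[i2, j2])) blocked <- TRUE
        }
      }
      nh <- 2 / (1 / n_ord[i] + 1 / n_ord[j])
      q <- (m[j] - m[i]) / sqrt(msw / nh)
      qc <- stats::qtukey(1 - alpha, r, df)
      p <- stats::ptukey(q, r, df, lower.tail = FALSE)
      s <- if (blocked) FALSE else (q > qc)
      sig[i, j] <- s
      rows[[length(rows) + 1]] <- data.frame(
        group1 = labs[i], group2 = labs[j], diff = unname(m[j] - m[i]),
        span = r, q = unname(q), q_crit = qc, p = unname(p),
        significant = s, blocked = blocked)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ms_within") <- msw
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  attr(out, "unequal_n") <- length(unique(ns)) > 1
  class(out) <- c("newman_keuls", "data.frame")
  out
}

#' @export
print.newman_keuls <- function(x, ...) {
  cat(sprintf("Newman-Keuls pairwise comparisons (alpha = %g, df = %d%s)\n",
              attr(x, "alpha"), attr(x, "df"),
              if (attr(x, "unequal_n")) ", harmonic-mean n" else ""))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
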