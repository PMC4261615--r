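# Power-spectrum fractal dimension of per-layer depth reflectivity profiles.
#
# For each A-scan the reflectivity profile inside a layer is treated as a 1-D
# fractal signal: its periodogram decays as P(omega) ~ omega^-beta, the
# spectral exponent beta is the magnitude of the slope of an ordinary
# least-squares line fitted to log P vs log omega, and the fractal dimension
# is FD = (5 - beta)/2 (FD in [1, 2] for beta in [1, 3]). Per-layer values
# are the mean over A-scans, per-eye values the mean over scans.

#' Extract the reflectivity profile of one layer at one A-scan
#'
#' Takes the pixels whose depth interval lies entirely inside the half-open
#' band `[upper, lower)`: continuous boundary positions `u`, `l` select rows
#' `ceiling(u) .. ceiling(l) - 1` (0-based coordinates; see the package help
#' page). A zero-height layer yields an empty, flagged profile.
#'
#' @param image a [bscan()].
#' @param seg a [layer_seg()].
#' @param layer one of [retinal_layers()].
#' @param ascan A-scan index (1-based).
#' @return object of class `reflectivity_profile`: list with `values`,
#'   `n`, `layer`, `ascan`.
#' @export
extract_profile <- function(image, seg, layer, ascan) {
  stopifnot(inherits(image, "bscan"), inherits(seg, "layer_seg"))
  if (ascan < 1 || ascan > n_ascans(image)) {
    stop("A-scan index out of range", call. = FALSE)
  }
  band <- layer_band(seg, layer)
  r0 <- ceiling(band$upper[ascan])
  r1 <- ceiling(band$lower[ascan]) - 1
  vals <- if (r1 >= r0) image$pixels[(r0:r1) + 1, ascan] else numeric(0)
  structure(list(values = vals, n = length(vals),
                 layer = layer, ascan = as.integer(ascan)),
            class = "reflectivity_profile")
}

#' Periodogram of a reflectivity profile
#'
#' Optional linear detrend and optional Hann taper, then the periodogram
#' `|FFT|^2 / n`. Only positive-frequency bins strictly below the Nyquist
#' bin are returned; the DC bin is excluded (so the mean never enters the
#' fit).
#'
#' Both options default to off. On layer-length profiles (tens of pixels)
#' removing a fitted line strips genuine low-frequency fractal power and
#' biases the fitted exponent far more than a realistic un-removed
#' intensity ramp does, so the raw periodogram is the default; the Hann
#' taper is there for long-profile validation work, where it suppresses
#' the spectral leakage that otherwise caps the measurable slope near 2
#' (see the methods vignette for the simulations behind both choices).
#'
#' @param profile a `reflectivity_profile` or plain numeric vector.
#' @param detrend subtract the least-squares line first (default `FALSE`).
#' @param taper apply a Hann window (default `FALSE`).
#' @param min_length shortest admissible profile (default 8); shorter input
#'   is an error the caller records as an exclusion.
#' @return object of class `power_spectrum`: list with `frequency`
#'   (cycles/pixel, `k/n`), `power`, and `n`.
#' @export
power_spectrum <- function(profile, detrend = FALSE, taper = FALSE,
                           min_length = 8) {
  x <- if (inherits(profile, "reflectivity_profile")) profile$values else
    as.numeric(profile)
  n <- length(x)
  if (n < min_length) {
    stop("profile too short: ", n, " < ", min_length, " samples",
         call. = FALSE)
  }
  if (detrend) {
    t <- seq_len(n)
    fit <- ols_line(t, x)
    x <- x - (fit$intercept + fit$slope * t)
  }
  if (taper) {
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  P <- Mod(stats::fft(x))^2 / n
  kmax <- ceiling(n / 2) - 1 # strictly below the Nyquist bin, DC excluded
  k <- seq_len(kmax)
  structure(list(frequency = k / n, power = P[k + 1], n = n),
            class = "power_spectrum")
}

#' Fit the spectral exponent and fractal dimension
#'
#' Ordinary least squares of `log P(omega)` on `log omega` over all
#' positive-power bins (zero-power bins are dropped; fewer than `min_points`
#' usable bins gives an invalid estimate). `beta` is the negative of the
#' fitted slope and `FD = (5 - beta)/2`. Estimates whose FD falls outside
#' `[1, 2] +/- 0.5` are flagged invalid, never clamped: silent clamping
#' would bias group means.
#'
#' @param spectrum a [power_spectrum()].
#' @param min_points minimum usable bins (default 4).
#' @param band optional `c(low, high)` frequency limits (cycles/pixel)
#'   restricting the fitted band.
#' @return object of class `fd_fit`: `beta`, `fd`, `r_squared`,
#'   `n_fit_points`, `valid`, `reason`, plus the fitted `intercept` and the
#'   log-log points for plotting.
#' @export
fit_beta <- function(spectrum, min_points = 4, band = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$power > 0
  if (!is.null(band)) {
    keep <- keep & spectrum$frequency >= band[1] & spectrum$frequency <= band[2]
  }
  invalid <- function(reason) {
    structure(list(beta = NA_real_, fd = NA_real_, r_squared = NA_real_,
                   n_fit_points = sum(keep), valid = FALSE, reason = reason,
                   intercept = NA_real_, log_f = numeric(0),
                   log_p = numeric(0)),
              class = "fd_fit")
  }
  if (sum(keep) < min_points) {
    return(invalid(sprintf("only %d usable spectral bins (need >= %d)",
                           sum(keep), min_points)))
  }
  lx <- log(spectrum$frequency[keep])
  ly <- log(spectrum$power[keep])
  fit <- ols_line(lx, ly)
  beta <- -fit$slope
  fd <- (5 - beta) / 2
  out_of_range <- !is.finite(fd) || fd <= 0.5 || fd >= 2.5
  structure(list(beta = beta, fd = fd, r_squared = fit$r_squared,
                 n_fit_points = sum(keep),
                 valid = !out_of_range,
                 reason = if (out_of_range)
                   "fd outside [1,2] +/- 0.5" else NA_character_,
                 intercept = fit$intercept, log_f = lx, log_p = ly),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  if (is.na(x$beta)) {
    cat("<fd_fit> invalid:", x$reason, "\n")
  } else {
    cat(sprintf("<fd_fit> beta = %.4f, FD = %.4f (R^2 = %.3f, %d bins%s)\n",
                x$beta, x$fd, x$r_squared, x$n_fit_points,
                if (x$valid) "" else "; flagged invalid"))
    if (!x$valid) cat("  reason:", x$reason, "\n")
  }
  invisible(x)
}

#' @export
coef.fd_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = -object$beta)
}

#' @export
summary.fd_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.fd_fit <- function(x, ...) {
  if (!length(x$log_f)) {
    warning("nothing to plot for an invalid fit")
    return(invisible(x))
  }
  graphics::plot(x$log_f, x$log_p, xlab = "log frequency",
                 ylab = "log power",
                 main = sprintf("beta = %.3f, FD = %.3f", x$beta, x$fd), ...)
  graphics::abline(x$intercept, -x$beta, col = "red3")
  invisible(x)
}

#' Per-layer fractal dimension of one B-scan
#'
#' Runs [extract_profile()] -> [power_spectrum()] -> [fit_beta()] over all
#' non-masked A-scans of one layer and averages the valid FD values.
#' Exclusions are counted by cause (`shadow`, `too_short`, `invalid`); the
#' invariant `n_used + sum(exclusions) = n_ascans` always holds.
#'
#' @param image a [bscan()].
#' @param seg a [layer_seg()].
#' @param layer one of [retinal_layers()].
#' @param mask optional [shadow_mask()] of columns to exclude.
#' @param min_profile minimum profile length in pixels (default 8); shorter
#'   profiles are excluded, never zero-padded.
#' @param detrend,taper,band,min_points passed to [power_spectrum()] /
#'   [fit_beta()].
#' @return object of class `layer_fd_summary`: `layer`, `mean_fd`, `sd_fd`,
#'   `n_used`, `n_ascans`, `exclusions` (named counts), `reason` (when no
#'   A-scan was usable) and `ascans` (per-A-scan data frame with `beta`,
#'   `fd`, `r_squared`, `valid`, `reason`).
#' @export
layer_fd <- function(image, seg, layer, mask = NULL,
                     min_profile = 8, detrend = FALSE, taper = FALSE,
                     band = NULL, min_points = 4) {
  stopifnot(inherits(image, "bscan"), inherits(seg, "layer_seg"))
  nc <- n_ascans(image)
  shadow_cols <- masked_columns(mask)
  res <- data.frame(ascan = seq_len(nc), beta = NA_real_, fd = NA_real_,
                    r_squared = NA_real_, valid = FALSE,
                    reason = NA_character_)
  excl <- c(shadow = 0L, too_short = 0L, invalid = 0L)
  for (a in seq_len(nc)) {
    if (a %in% shadow_cols) {
      excl["shadow"] <- excl["shadow"] + 1L
      res$reason[a] <- "shadow"
      next
    }
    prof <- extract_profile(image, seg, layer, a)
    if (prof$n < min_profile) {
      excl["too_short"] <- excl["too_short"] + 1L
      res$reason[a] <- "too_short"
      next
    }
    spec <- power_spectrum(prof, detrend = detrend, taper = taper,
                           min_length = min_profile)
    fit <- fit_beta(spec, min_points = min_points, band = band)
    res$beta[a] <- fit$beta
    res$fd[a] <- fit$fd
    res$r_squared[a] <- fit$r_squared
    res$valid[a] <- fit$valid
    if (!fit$valid) {
      excl["invalid"] <- excl["invalid"] + 1L
      res$reason[a] <- fit$reason
    }
  }
  n_used <- sum(res$valid)
  structure(list(
    layer = layer,
    mean_fd = if (n_used > 0) mean(res$fd[res$valid]) else NA_real_,
    sd_fd = if (n_used > 1) stats::sd(res$fd[res$valid]) else NA_real_,
    n_used = n_used, n_ascans = nc, exclusions = excl,
    reason = if (n_used == 0) "no valid A-scans" else NA_character_,
    ascans = res), class = "layer_fd_summary")
}

#' @export
print.layer_fd_summary <- function(x, ...) {
  if (is.na(x$mean_fd)) {
    cat(sprintf("<layer_fd_summary %s> missing (%s)\n", x$layer, x$reason))
  } else {
    cat(sprintf(
      "<layer_fd_summary %s> mean FD %.4f (sd %.4f) over %d/%d A-scans\n",
      x$layer, x$mean_fd, x$sd_fd, x$n_used, x$n_ascans))
  }
  cat("  excluded:", paste(names(x$exclusions), x$exclusions,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Eye-level fractal dimension
#'
#' Unweighted mean over scans of the per-scan, per-layer means. Input is a
#' list of per-scan named vectors (layer -> mean FD) or of lists of
#' `layer_fd_summary` objects. A layer missing in some scans is averaged
#' over the remaining scans; missing in all scans stays missing.
#'
#' @param scans list with one element per scan.
#' @return named numeric vector, one entry per layer present.
#' @export
eye_fd <- function(scans) {
  stopifnot(length(scans) >= 1)
  as_vec <- function(s) {
    if (is.numeric(s)) return(s)
    vals <- vapply(s, function(z) z$mean_fd, numeric(1))
    names(vals) <- vapply(s, function(z) z$layer, character(1))
    vals
  }
  vecs <- lapply(scans, as_vec)
  layers <- unique(unlist(lapply(vecs, names)))
  out <- vapply(layers, function(l) {
    v <- unlist(lapply(vecs, function(x) x[l]))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  names(out) <- layers
  out
}
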