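# Synthetic retinal phantom: layered B-scans with known boundaries,
# per-layer spectral-exponent depth texture, optional multiplicative speckle
# and planted vertical vessel shadows. Every downstream stage is validated
# against the truth this module plants.

# Table of normative per-layer parameters used for the defaults: healthy-eye
# thickness means (microns) and fractal dimensions reported for time-domain
# macular OCT, FD mapped to the spectral exponent via beta = 5 - 2 FD.
default_layer_thickness <- function() {
  c(RNFL = 42.02, `GCL+IPL` = 78.30, INL = 35.02, OPL = 41.30,
    `ONL+IS` = 86.41, OS = 16.27, RPE = 12.71)
}

default_layer_fd <- function() {
  c(RNFL = 1.74, `GCL+IPL` = 1.68, INL = 1.78, OPL = 1.51,
    `ONL+IS` = 1.78, OS = 1.70, RPE = 1.68)
}

default_layer_reflectivity <- function() {
  c(RNFL = 0.75, `GCL+IPL` = 0.35, INL = 0.30, OPL = 0.45,
    `ONL+IS` = 0.20, OS = 0.55, RPE = 0.90)
}

#' Specify a synthetic retinal phantom
#'
#' Collects the geometry, optical and noise parameters of a synthetic macular
#' B-scan. Defaults emulate a Stratus-like time-domain scan: 512 A-scans over
#' a 6 mm transverse line, ~2 um axial sampling, seven layers with
#' literature-typical thickness, reflectivity and fractal dimension, and a
#' Gaussian foveal pit thinning the inner layers. Within each layer the depth
#' texture is a zero-mean fluctuation whose expected power spectrum decays as
#' `omega^-beta` with `beta = 5 - 2 FD`.
#'
#' `speckle_looks` is the shape of unit-mean multiplicative gamma noise
#' (`Inf` disables it). The default is `Inf`: the measurement stages of the
#' pipeline operate on despeckled images, and a simple noise-floor argument
#' (see the methods vignette) shows fully developed speckle would bury the
#' planted spectral slope on layer-length profiles, so speckle is opt-in for
#' exercising the preprocessing stages.
#'
#' @param n_ascans,n_depth image size (columns, rows).
#' @param axial_pitch,lateral_pitch microns per pixel; `lateral_pitch`
#'   defaults to a 6 mm line divided by `n_ascans`.
#' @param layer_thickness,layer_reflectivity,layer_fd named length-7 vectors
#'   (microns; mean intensity in `[0,1]`; fractal dimension in (1,2)).
#' @param texture_sd relative standard deviation of the within-layer texture
#'   fluctuation (the profile is `reflectivity * (1 + fluctuation)`).
#' @param foveal_pit_depth,foveal_pit_width microns; Gaussian thinning of the
#'   inner four layers centered laterally (FWHM = `foveal_pit_width`).
#' @param speckle_looks positive real or `Inf`; gamma shape of the
#'   multiplicative speckle.
#' @param shadow_columns list of `c(start, width)` lateral intervals
#'   (A-scan units, 1-based start) to darken as vessel shadows.
#' @param shadow_attenuation multiplicative factor in (0,1) applied below the
#'   inner retinal surface in shadowed columns.
#' @param background vitreous/choroid base intensity.
#' @param seed master integer seed; all phantom randomness derives from it.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_bscan()], [make_eye()], [make_cohort()]
#' @export
phantom_spec <- function(n_ascans = 512, n_depth = 1024,
                         axial_pitch = 2, lateral_pitch = 6000 / n_ascans,
                         layer_thickness = default_layer_thickness(),
                         layer_reflectivity = default_layer_reflectivity(),
                         layer_fd = default_layer_fd(),
                         texture_sd = 0.3,
                         foveal_pit_depth = 100, foveal_pit_width = 1000,
                         speckle_looks = Inf,
                         shadow_columns = list(),
                         shadow_attenuation = 0.35,
                         background = 0.03,
                         seed = 1L) {
  stopifnot(is_count(n_ascans), is_count(n_depth),
            axial_pitch > 0, lateral_pitch > 0)
  lay <- retinal_layers()
  layer_thickness <- layer_thickness[lay]
  layer_reflectivity <- layer_reflectivity[lay]
  layer_fd <- layer_fd[lay]
  if (any(is.na(layer_thickness)) || any(is.na(layer_reflectivity)) ||
      any(is.na(layer_fd))) {
    stop("layer parameter vectors must be named with all 7 layers",
         call. = FALSE)
  }
  layer_beta <- 5 - 2 * layer_fd
  if (any(layer_reflectivity < 0 | layer_reflectivity > 1)) {
    stop("reflectivities must lie in [0,1]", call. = FALSE)
  }
  if (any(layer_beta <= 1 | layer_beta >= 3)) {
    stop("layer FD must lie in (1,2), i.e. beta in (1,3)", call. = FALSE)
  }
  if (!(shadow_attenuation > 0 && shadow_attenuation < 1) &&
      length(shadow_columns)) {
    stop("shadow_attenuation must lie in (0,1)", call. = FALSE)
  }
  if (!is.numeric(speckle_looks) || speckle_looks <= 0) {
    stop("speckle_looks must be positive (Inf disables speckle)",
         call. = FALSE)
  }
  if (is.matrix(shadow_columns)) { # e.g. a JSON [[start,width],...] array
    shadow_columns <- lapply(seq_len(nrow(shadow_columns)),
                             function(i) shadow_columns[i, ])
  }
  if (texture_sd < 0) stop("texture_sd must be >= 0", call. = FALSE)
  if (sum(layer_thickness) > n_depth * axial_pitch) {
    stop("geometry overflow: layers (", round(sum(layer_thickness)),
         " um) do not fit in ", n_depth * axial_pitch, " um of depth",
         call. = FALSE)
  }
  for (sc in shadow_columns) {
    if (length(sc) != 2 || sc[1] < 1 || sc[2] < 1 ||
        sc[1] + sc[2] - 1 > n_ascans) {
      stop("shadow interval out of range: (", paste(sc, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  structure(list(
    n_ascans = as.integer(n_ascans), n_depth = as.integer(n_depth),
    axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
    layer_thickness = layer_thickness,
    layer_reflectivity = layer_reflectivity,
    layer_fd = layer_fd, layer_beta = layer_beta,
    texture_sd = texture_sd,
    foveal_pit_depth = foveal_pit_depth,
    foveal_pit_width = foveal_pit_width,
    speckle_looks = speckle_looks,
    shadow_columns = shadow_columns,
    shadow_attenuation = shadow_attenuation,
    background = background,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d A-scans x %d px, pitch %.3g x %.3g um, seed %d\n",
    x$n_ascans, x$n_depth, x$axial_pitch, x$lateral_pitch, x$seed))
  cat(sprintf("  retina %.0f um, pit %.0f/%.0f um, texture sd %.2f, looks %s, %d shadow(s)\n",
              sum(x$layer_thickness), x$foveal_pit_depth, x$foveal_pit_width,
              x$texture_sd,
              if (is.finite(x$speckle_looks)) format(x$speckle_looks) else "none",
              length(x$shadow_columns)))
  invisible(x)
}

#' Synthesize a zero-mean power-law (fBm-style) fluctuation
#'
#' Spectral synthesis of a 1-D signal whose expected periodogram decays as
#' `k^-beta`: independent complex-Gaussian Fourier coefficients with variance
#' proportional to `k^-beta`, Hermitian symmetrized and inverted. The result
#' is scaled to standard deviation `sd`. This is the texture planted in every
#' phantom layer and the calibration signal for the spectral-slope estimator.
#'
#' @param n length in samples (`n < 3` returns zeros).
#' @param beta spectral exponent in (1, 3).
#' @param sd target standard deviation of the output.
#' @return numeric vector of length `n` with mean 0 and sd `sd`.
#' @export
fractal_texture <- function(n, beta, sd = 1) {
  if (n < 3 || sd == 0) return(numeric(n))
  half <- floor((n - 1) / 2)          # bins 1..half are free
  amp <- (seq_len(half))^(-beta / 2)
  co <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * amp
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(half + 1)] <- co
  spec[n:(n - half + 1)] <- Conj(co)
  if (n %% 2 == 0) spec[n / 2 + 1] <- stats::rnorm(1) * (n / 2)^(-beta / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# boundary geometry for one scan: 8 x n_ascans matrix of continuous depth
# coordinates (pixel units). Foveal pit thins the inner four layers
# proportionally to their thickness, capped at 90% so order is preserved.
phantom_boundaries <- function(spec) {
  nc <- spec$n_ascans
  th_px <- spec$layer_thickness / spec$axial_pitch
  total <- sum(th_px)
  top <- (spec$n_depth - total) / 2
  x_um <- (seq_len(nc) - (nc + 1) / 2) * spec$lateral_pitch
  sigma <- spec$foveal_pit_width / (2 * sqrt(2 * log(2)))
  pit_px <- spec$foveal_pit_depth / spec$axial_pitch *
    exp(-x_um^2 / (2 * sigma^2))
  inner <- 1:4 # RNFL .. OPL carry the pit
  w <- th_px[inner] / sum(th_px[inner])
  rows <- matrix(0, 8, nc, dimnames = list(retinal_boundaries(), NULL))
  rows[1, ] <- top
  for (l in 1:7) {
    t_l <- rep(th_px[l], nc)
    if (l %in% inner) {
      shrink <- pmin(pit_px * w[l - min(inner) + 1], 0.9 * th_px[l])
      t_l <- t_l - shrink
    }
    rows[l + 1, ] <- rows[l, ] + t_l
  }
  rows
}

#' Generate one synthetic B-scan with ground truth
#'
#' Renders the phantom described by `spec`: smooth layer boundaries with a
#' foveal pit, per-layer mean reflectivity modulated by a depth texture with
#' the layer's spectral exponent (via [fractal_texture()]), optional
#' unit-mean gamma speckle, and vessel-shadow columns attenuated below the
#' inner retinal surface. Identical spec and seed reproduce the image
#' bit-identically.
#'
#' @param spec a [phantom_spec()].
#' @param scan_id,eye_id identifiers stored in the B-scan.
#' @return a list with elements `image` (a [bscan()]) and `truth`, where
#'   `truth` holds `boundaries` (a [layer_seg()]), `shadow_columns` (integer
#'   vector of shadowed A-scans), `intervals`, `layer_beta` and `layer_fd`
#'   (with `fd = (5 - beta)/2` exactly).
#' @export
generate_bscan <- function(spec, scan_id = "phantom", eye_id = "eye") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(derive_seed(spec$seed, 1))
  rows <- phantom_boundaries(spec)
  nd <- spec$n_depth; nc <- spec$n_ascans
  px <- matrix(spec$background, nd, nc)
  for (a in seq_len(nc)) {
    for (l in 1:7) {
      r0 <- ceiling(rows[l, a]); r1 <- ceiling(rows[l + 1, a]) - 1
      if (r1 < r0) next
      n <- r1 - r0 + 1
      fl <- fractal_texture(n, spec$layer_beta[l], spec$texture_sd)
      px[(r0:r1) + 1, a] <- pmax(spec$layer_reflectivity[l] * (1 + fl), 0)
    }
  }
  if (is.finite(spec$speckle_looks)) {
    L <- spec$speckle_looks
    px <- px * matrix(stats::rgamma(nd * nc, shape = L, rate = L), nd, nc)
  }
  shadow_cols <- integer(0)
  intervals <- list()
  for (sc in spec$shadow_columns) {
    cols <- seq.int(sc[1], length.out = sc[2])
    intervals[[length(intervals) + 1]] <- c(start = sc[1], end = sc[1] + sc[2])
    shadow_cols <- c(shadow_cols, cols)
    for (a in cols) {
      r0 <- ceiling(rows[1, a]) + 1
      if (r0 <= nd) px[r0:nd, a] <- px[r0:nd, a] * spec$shadow_attenuation
    }
  }
  img <- bscan(px, spec$axial_pitch, spec$lateral_pitch,
               scan_id = scan_id, eye_id = eye_id)
  truth <- list(
    boundaries = layer_seg(rows, n_depth = nd),
    shadow_columns = sort(unique(shadow_cols)),
    intervals = intervals,
    layer_beta = spec$layer_beta,
    layer_fd = (5 - spec$layer_beta) / 2)
  list(image = img, truth = truth)
}

#' Generate the scans of one synthetic eye
#'
#' Independent replicate B-scans sharing the same layer parameters,
#' emulating the per-eye radial scan set whose per-scan measurements are
#' averaged into eye-level features. Scan seeds derive deterministically
#' from `spec$seed` and the scan index.
#'
#' @param spec a [phantom_spec()].
#' @param n_scans number of replicate scans (default 6).
#' @param eye_id identifier.
#' @return list of `n_scans` elements as returned by [generate_bscan()];
#'   all truths share `layer_fd`.
#' @export
make_eye <- function(spec, n_scans = 6, eye_id = "eye") {
  stopifnot(is_count(n_scans))
  lapply(seq_len(n_scans), function(i) {
    s_i <- spec
    s_i$seed <- derive_seed(spec$seed, 101, i)
    generate_bscan(s_i, scan_id = sprintf("%s_scan%02d", eye_id, i),
                   eye_id = eye_id)
  })
}

#' Simulate a two-group phantom cohort (eye-level truth)
#'
#' Draws per-eye layer parameters for a healthy and a diseased group by
#' jittering each group's phantom spec with normal between-eye deviates, and
#' returns the eye-level ground-truth feature table the statistics module
#' consumes, plus the per-eye specs needed to render images with
#' [make_eye()]. No images are rendered here.
#'
#' @param healthy_spec,diseased_spec [phantom_spec()]s holding each group's
#'   mean parameters (seeds are re-derived per eye from `healthy_spec$seed`).
#' @param n_healthy,n_diseased eyes per group (>= 2).
#' @param between_eye_sd between-eye standard deviations: either a per-layer
#'   numeric vector applied to FD only, or a list with any of `fd`,
#'   `thickness` (microns), `reflectivity`, each a per-layer vector
#'   (recycled). Separate values per group via `between_eye_sd_diseased`.
#' @param between_eye_sd_diseased like `between_eye_sd`, for the diseased
#'   group; defaults to `between_eye_sd`.
#' @param groups labels for the two groups.
#' @return list with `study` (data frame: `eye_id`, `group`, and per-layer
#'   truth columns `fd_<layer>`, `thickness_<layer>`, `refl_<layer>`),
#'   `specs` (named list of per-eye phantom specs) and `n_resampled`
#'   (count of jitter draws rejected for producing invalid parameters).
#' @export
make_cohort <- function(healthy_spec, diseased_spec,
                        n_healthy = 74, n_diseased = 43,
                        between_eye_sd = 0,
                        between_eye_sd_diseased = between_eye_sd,
                        groups = c("healthy", "MDR")) {
  stopifnot(n_healthy >= 2, n_diseased >= 2)
  norm_sd <- function(sd) {
    if (!is.list(sd)) sd <- list(fd = sd)
    list(fd = rep(sd$fd %||% 0, length.out = 7),
         thickness = rep(sd$thickness %||% 0, length.out = 7),
         reflectivity = rep(sd$reflectivity %||% 0, length.out = 7))
  }
  sds <- list(norm_sd(between_eye_sd), norm_sd(between_eye_sd_diseased))
  base <- list(healthy_spec, diseased_spec)
  n_eyes <- c(n_healthy, n_diseased)
  n_resampled <- 0L
  rows <- list(); specs <- list()
  eye_no <- 0L
  for (g in 1:2) {
    sp <- base[[g]]; sd_g <- sds[[g]]
    for (e in seq_len(n_eyes[g])) {
      eye_no <- eye_no + 1L
      eye_id <- sprintf("%s_%03d", groups[g], e)
      set.seed(derive_seed(healthy_spec$seed, 500 + g, e))
      repeat {
        fd <- sp$layer_fd + stats::rnorm(7, 0, sd_g$fd)
        th <- sp$layer_thickness + stats::rnorm(7, 0, sd_g$thickness)
        rf <- sp$layer_reflectivity + stats::rnorm(7, 0, sd_g$reflectivity)
        ok <- all(th > 0) && all(fd > 1.01 & fd < 1.99) &&
          all(rf > 0 & rf <= 1)
        if (ok) break
        n_resampled <- n_resampled + 1L
      }
      names(fd) <- names(th) <- names(rf) <- retinal_layers()
      sp_eye <- sp
      sp_eye$layer_fd <- fd
      sp_eye$layer_beta <- 5 - 2 * fd
      sp_eye$layer_thickness <- th
      sp_eye$layer_reflectivity <- rf
      sp_eye$seed <- derive_seed(healthy_spec$seed, 900, eye_no)
      specs[[eye_id]] <- sp_eye
      feat <- c(stats::setNames(fd, paste0("fd_", retinal_layers())),
                stats::setNames(th, paste0("thickness_", retinal_layers())),
                stats::setNames(rf / rf[7], paste0("refl_", retinal_layers())))
      rows[[eye_id]] <- data.frame(eye_id = eye_id, group = groups[g],
                                   t(feat), check.names = FALSE)
    }
  }
  study <- do.call(rbind, rows)
  rownames(study) <- NULL
  list(study = study, specs = specs, n_resampled = n_resampled)
}
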