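# Preprocessing ahead of any reflectivity-based measurement: optional median
# despeckling, and detection/exclusion of blood-vessel shadow columns via the
# shadowgram technique (vessels cast dark vertical shadows through the outer
# retina).

#' Construct a shadow mask
#'
#' The set of lateral A-scan columns excluded as blood-vessel shadows,
#' stored both as half-open `[start, end)` intervals and as the equivalent
#' column set.
#'
#' @param intervals list of `c(start, end)` half-open column intervals
#'   (1-based start, `end` exclusive).
#' @param n_ascans total number of A-scans (for range checking).
#' @param method_params named list recording the detection settings.
#' @return an object of class `shadow_mask` with elements `columns`,
#'   `intervals`, `n_ascans`, `method_params`.
#' @export
shadow_mask <- function(intervals = list(), n_ascans,
                        method_params = list()) {
  cols <- integer(0)
  for (iv in intervals) {
    if (length(iv) != 2 || iv[2] <= iv[1]) {
      stop("intervals must be half-open c(start, end) with end > start",
           call. = FALSE)
    }
    if (iv[1] < 1 || iv[2] > n_ascans + 1) {
      stop("interval outside [1, n_ascans]: (", iv[1], ", ", iv[2], ")",
           call. = FALSE)
    }
    cols <- c(cols, seq.int(iv[1], iv[2] - 1))
  }
  structure(list(columns = sort(unique(cols)),
                 intervals = intervals, n_ascans = n_ascans,
                 method_params = method_params),
            class = "shadow_mask")
}

#' @export
print.shadow_mask <- function(x, ...) {
  cat(sprintf("<shadow_mask> %d/%d columns excluded in %d interval(s)\n",
              length(x$columns), x$n_ascans, length(x$intervals)))
  invisible(x)
}

empty_mask <- function(image) {
  shadow_mask(list(), n_ascans = n_ascans(image))
}

masked_columns <- function(mask) if (is.null(mask)) integer(0) else mask$columns

#' Median-filter despeckling
#'
#' Plain 2-D median filter with replicated edges; `window = 1` is the
#' identity. A generic speckle reducer for phantoms and external images --
#' it does not reproduce any vendor denoising chain.
#'
#' @param image a [bscan()].
#' @param window odd window side length.
#' @return the filtered [bscan()].
#' @export
despeckle <- function(image, window = 3) {
  stopifnot(inherits(image, "bscan"))
  if (!is_count(window) || window %% 2 == 0) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  if (window == 1) return(image)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  r <- (window - 1) / 2
  # replicated-edge padding, then stack the w^2 shifted copies
  ridx <- pmin(pmax(seq_len(nr + 2 * r) - r, 1), nr)
  cidx <- pmin(pmax(seq_len(nc + 2 * r) - r, 1), nc)
  pad <- px[ridx, cidx, drop = FALSE]
  k <- window^2
  stack <- matrix(0, nr * nc, k)
  m <- 0
  for (dr in 0:(window - 1)) {
    for (dc in 0:(window - 1)) {
      m <- m + 1
      stack[, m] <- as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
    }
  }
  # row-wise median of k values: middle column(s) of the row-sorted stack
  sorted <- matrix(stack[order(row(stack), stack)], nrow = nr * nc,
                   byrow = TRUE)
  med <- if (k %% 2 == 1) sorted[, (k + 1) / 2] else
    (sorted[, k / 2] + sorted[, k / 2 + 1]) / 2
  out <- image
  out$pixels <- matrix(med, nr, nc)
  out
}

#' Lateral shadowgram profile
#'
#' For each A-scan, the mean intensity over the outer-retina band (from the
#' OPL/ONL+IS boundary down to the OS/RPE boundary), where blood-vessel
#' shadows are darkest. Columns whose band has zero height are `NA`.
#'
#' @param image a [bscan()].
#' @param seg a [layer_seg()] valid for the image.
#' @return numeric vector of length `n_ascans`.
#' @export
shadowgram_profile <- function(image, seg) {
  stopifnot(inherits(image, "bscan"), inherits(seg, "layer_seg"))
  if (seg$n_ascans != n_ascans(image)) {
    stop("segmentation covers ", seg$n_ascans, " A-scans but image has ",
         n_ascans(image), call. = FALSE)
  }
  upper <- seg$rows["OPL/ONL+IS", ]
  lower <- seg$rows["OS/RPE", ]
  vapply(seq_len(n_ascans(image)), function(a) {
    r0 <- ceiling(upper[a]); r1 <- ceiling(lower[a]) - 1
    if (r1 < r0) return(NA_real_)
    mean(image$pixels[(r0:r1) + 1, a])
  }, numeric(1))
}

#' Detect blood-vessel shadow columns
#'
#' Thresholds the shadowgram profile at `robust mean - k_sigma * robust SD`
#' (median and MAD-based, so the decision is invariant to rescaling the whole
#' image), takes maximal runs of sub-threshold columns as shadow candidates
#' delimited by the steep vertical walls of the dip (runs separated by a
#' single bright column are merged), and keeps runs whose width lies in
#' `[min_width, max_width]`.
#'
#' The robust SD is floored at `rel_floor` times the profile median, so a
#' pathologically smooth shadowgram (for example a noise-free phantom,
#' where the only lateral variation is pixel-discretization steps) cannot
#' trigger on sub-percent fluctuations; a vessel shadow darkens the band by
#' tens of percent and clears the floored threshold easily. Both threshold
#' terms scale linearly with the image, so detection is invariant to
#' multiplying the image by any positive constant.
#'
#' @param image a [bscan()].
#' @param seg a [layer_seg()].
#' @param k_sigma threshold depth in robust SDs below the median (default 2).
#' @param min_width,max_width admissible shadow widths in columns.
#' @param rel_floor lower bound on the robust SD, as a fraction of the
#'   profile median (default 0.01).
#' @return a [shadow_mask()] with the parameters recorded in
#'   `method_params`.
#' @export
detect_shadows <- function(image, seg, k_sigma = 2,
                           min_width = 3, max_width = 40, rel_floor = 0.01) {
  stopifnot(k_sigma > 0, min_width >= 1, min_width <= max_width,
            rel_floor >= 0)
  prof <- shadowgram_profile(image, seg)
  ok <- !is.na(prof)
  med <- stats::median(prof[ok])
  rsd <- stats::mad(prof[ok]) # 1.4826 * MAD, consistent for gaussian noise
  rsd <- max(rsd, rel_floor * abs(med))
  thr <- med - k_sigma * rsd
  flag <- ok & prof < thr
  if (mean(flag[ok]) > 0.5) {
    stop("threshold implausible: more than half of all columns flagged as shadow",
         call. = FALSE)
  }
  # merge runs separated by a single non-flagged column (shadows are contiguous)
  f <- flag
  inner <- which(!f & c(FALSE, f[-length(f)]) & c(f[-1], FALSE))
  f[inner] <- TRUE
  runs <- rle(f)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  intervals <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    w <- runs$lengths[i]
    if (w >= min_width && w <= max_width) {
      intervals[[length(intervals) + 1]] <- c(starts[i], ends[i] + 1)
    }
  }
  shadow_mask(intervals, n_ascans = n_ascans(image),
              method_params = list(k_sigma = k_sigma, min_width = min_width,
                                   max_width = max_width,
                                   rel_floor = rel_floor, threshold = thr))
}

#' Write / read a shadow mask as CSV
#'
#' Long CSV with columns `scan_id, ascan, excluded` (0/1 flag per A-scan).
#'
#' @param mask a [shadow_mask()].
#' @param path CSV path.
#' @param scan_id identifier written in every row.
#' @param append append rows to an existing file.
#' @return the path (write) or a [shadow_mask()] (read).
#' @export
write_shadow_mask <- function(mask, path, scan_id = "scan", append = FALSE) {
  stopifnot(inherits(mask, "shadow_mask"))
  tab <- data.frame(scan_id = scan_id, ascan = seq_len(mask$n_ascans),
                    excluded = as.integer(seq_len(mask$n_ascans) %in%
                                            mask$columns))
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append)
  invisible(path)
}

#' @rdname write_shadow_mask
#' @export
read_shadow_mask <- function(path, scan_id = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(scan_id)) tab <- tab[tab$scan_id == scan_id, , drop = FALSE]
  tab <- tab[order(tab$ascan), , drop = FALSE]
  flagged <- tab$ascan[tab$excluded != 0]
  intervals <- list()
  if (length(flagged)) {
    brk <- c(0, which(diff(flagged) > 1), length(flagged))
    for (i in seq_len(length(brk) - 1)) {
      grp <- flagged[(brk[i] + 1):brk[i + 1]]
      intervals[[length(intervals) + 1]] <- c(min(grp), max(grp) + 1)
    }
  }
  shadow_mask(intervals, n_ascans = max(tab$ascan))
}
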