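# Readers/writers and the containers shared by every other module.

#' Construct an OCT B-scan object
#'
#' A B-scan is a 2-D non-negative intensity matrix with rows = depth
#' (row 1 on the vitreous side) and columns = lateral A-scan index, plus the
#' axial and lateral pixel pitches in microns.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param axial_pitch microns per depth pixel.
#' @param lateral_pitch microns per A-scan.
#' @param scan_id,eye_id identifier strings.
#' @return an object of class `bscan`.
#' @export
bscan <- function(pixels, axial_pitch, lateral_pitch,
                  scan_id = "scan", eye_id = "eye") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  dimnames(pixels) <- NULL
  if (length(pixels) == 0) stop("empty B-scan", call. = FALSE)
  if (any(!is.finite(pixels))) stop("non-finite intensities", call. = FALSE)
  if (any(pixels < 0)) stop("negative intensities", call. = FALSE)
  if (!is.numeric(axial_pitch) || axial_pitch <= 0 ||
      !is.numeric(lateral_pitch) || lateral_pitch <= 0) {
    stop("pixel pitches must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels, axial_pitch = axial_pitch,
         lateral_pitch = lateral_pitch,
         scan_id = as.character(scan_id), eye_id = as.character(eye_id)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %s / eye %s>  %d depth px x %d A-scans, pitch %.3g x %.3g um\n",
              x$scan_id, x$eye_id, nrow(x$pixels), ncol(x$pixels),
              x$axial_pitch, x$lateral_pitch))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

n_ascans <- function(image) ncol(image$pixels)

#' Construct a layer segmentation object
#'
#' Per-A-scan depth positions of the 8 boundaries delimiting the 7
#' intraretinal layers. Boundary positions are continuous (sub-pixel) depth
#' coordinates in pixel units from the top edge of the image (see the package
#' help for the coordinate conventions). At every A-scan the boundaries must
#' be non-decreasing in anatomical order.
#'
#' @param boundary_rows 8 x n_ascans numeric matrix, one row per boundary in
#'   the order of [retinal_boundaries()]. A named matrix is reordered by row
#'   name.
#' @param n_depth optional image depth (pixels) used to range-check positions.
#' @return an object of class `layer_seg` with elements `rows` (the matrix)
#'   and `n_ascans`.
#' @export
layer_seg <- function(boundary_rows, n_depth = NULL) {
  boundary_rows <- as.matrix(boundary_rows)
  if (nrow(boundary_rows) != 8) {
    stop("expected 8 boundary rows, got ", nrow(boundary_rows), call. = FALSE)
  }
  if (!is.null(rownames(boundary_rows))) {
    unknown <- setdiff(rownames(boundary_rows), retinal_boundaries())
    if (length(unknown)) {
      stop("unknown boundary name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    boundary_rows <- boundary_rows[retinal_boundaries(), , drop = FALSE]
  } else {
    rownames(boundary_rows) <- retinal_boundaries()
  }
  if (any(!is.finite(boundary_rows))) {
    stop("non-finite boundary positions", call. = FALSE)
  }
  bad <- which(apply(boundary_rows, 2, function(col) any(diff(col) < -1e-9)))
  if (length(bad)) {
    stop("boundary crossing (non-monotone order) at A-scan(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  if (any(boundary_rows < 0)) stop("boundary position above image", call. = FALSE)
  if (!is.null(n_depth) && any(boundary_rows > n_depth)) {
    stop("boundary position below image depth range", call. = FALSE)
  }
  structure(list(rows = boundary_rows, n_ascans = ncol(boundary_rows)),
            class = "layer_seg")
}

#' @export
print.layer_seg <- function(x, ...) {
  cat(sprintf("<layer_seg> 8 boundaries x %d A-scans, depth span %.1f..%.1f px\n",
              x$n_ascans, min(x$rows), max(x$rows)))
  invisible(x)
}

# upper/lower boundary positions of one layer (continuous coordinates)
layer_band <- function(seg, layer) {
  i <- match_layer(layer)
  list(upper = seg$rows[i, ], lower = seg$rows[i + 1, ])
}

#' Read a B-scan from a raster image or numeric text file
#'
#' Accepts 8/16-bit grayscale TIFF or PNG (intensities are returned on the
#' `[0, 1]` scale those readers use) or whitespace-delimited numeric text
#' (one row of the matrix per line). Color images are rejected.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`,
#'   `.png`, anything else is read as text).
#' @param axial_pitch,lateral_pitch pixel pitches in microns.
#' @param scan_id,eye_id identifiers; default from the file name.
#' @return a [bscan()].
#' @export
read_bscan <- function(path, axial_pitch, lateral_pitch,
                       scan_id = NULL, eye_id = "eye") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  scan_id <- scan_id %||% tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, convert = FALSE),
    png = png::readPNG(path),
    {
      m <- tryCatch(as.matrix(utils::read.table(path)),
                    error = function(e) stop("unreadable text matrix in ",
                                             path, ": ", conditionMessage(e),
                                             call. = FALSE))
      m
    })
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) {
      stop("color image not supported (", dim(img)[3], " channels): ", path,
           call. = FALSE)
    }
    img <- img[, , 1]
  }
  if (length(img) == 0) stop("empty image: ", path, call. = FALSE)
  bscan(img, axial_pitch, lateral_pitch, scan_id = scan_id, eye_id = eye_id)
}

#' Write a B-scan as a 16-bit grayscale image
#'
#' Intensities are clipped to `[0, 1]` and quantized to 16 bits. TIFF output
#' round-trips bit-exactly through [read_bscan()] for already-quantized data.
#'
#' @param image a [bscan()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @return the path, invisibly.
#' @export
write_bscan <- function(image, path) {
  stopifnot(inherits(image, "bscan"))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 16),
    png = png::writePNG(px, path),
    stop("unsupported image extension: .", ext, call. = FALSE))
  invisible(path)
}

#' Read a layer segmentation table
#'
#' Long-format CSV with columns `scan_id`, `ascan`, `boundary`, `row`
#' (A-scans indexed from 1; `row` is the continuous depth coordinate).
#' Interior A-scans missing for a boundary are filled by linear interpolation
#' from their neighbors; gaps touching the image edge are rejected.
#'
#' @param path CSV path.
#' @param image the [bscan()] the segmentation belongs to (fixes the number
#'   of A-scans and the depth range), or an integer number of A-scans.
#' @param scan_id optionally restrict the table to one scan id.
#' @return a [layer_seg()]; the number of interpolated entries is attached as
#'   attribute `n_interpolated`.
#' @export
read_segmentation <- function(path, image, scan_id = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("scan_id", "ascan", "boundary", "row")
  if (!all(need %in% names(tab))) {
    stop("segmentation CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(scan_id)) tab <- tab[tab$scan_id == scan_id, , drop = FALSE]
  if (nrow(tab) == 0) stop("no segmentation rows", if (!is.null(scan_id))
    paste0(" for scan '", scan_id, "'"), call. = FALSE)
  unknown <- setdiff(unique(tab$boundary), retinal_boundaries())
  if (length(unknown)) {
    stop("unknown boundary name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  nc <- if (inherits(image, "bscan")) n_ascans(image) else as.integer(image)
  nd <- if (inherits(image, "bscan")) nrow(image$pixels) else NULL
  rows <- matrix(NA_real_, 8, nc, dimnames = list(retinal_boundaries(), NULL))
  idx <- cbind(match(tab$boundary, retinal_boundaries()), tab$ascan)
  if (any(tab$ascan < 1 | tab$ascan > nc)) {
    stop("A-scan index outside 1..", nc, call. = FALSE)
  }
  rows[idx] <- tab$row
  n_interp <- 0L
  for (b in seq_len(8)) {
    miss <- is.na(rows[b, ])
    if (!any(miss)) next
    if (miss[1] || miss[nc]) {
      stop("boundary '", retinal_boundaries()[b],
           "' missing at the image edge; only interior gaps are interpolated",
           call. = FALSE)
    }
    known <- which(!miss)
    rows[b, miss] <- stats::approx(known, rows[b, known], xout = which(miss))$y
    n_interp <- n_interp + sum(miss)
  }
  seg <- layer_seg(rows, n_depth = nd)
  attr(seg, "n_interpolated") <- n_interp
  seg
}

#' Write a layer segmentation table
#'
#' Inverse of [read_segmentation()]: long CSV with columns
#' `scan_id, ascan, boundary, row`.
#'
#' @param seg a [layer_seg()].
#' @param path output CSV path.
#' @param scan_id scan identifier written in every row.
#' @param append append to an existing file (no header) rather than create.
#' @return the path, invisibly.
#' @export
write_segmentation <- function(seg, path, scan_id = "scan", append = FALSE) {
  stopifnot(inherits(seg, "layer_seg"))
  long <- data.frame(
    scan_id = scan_id,
    ascan = rep(seq_len(seg$n_ascans), each = 8),
    boundary = rep(retinal_boundaries(), seg$n_ascans),
    row = as.vector(seg$rows))
  utils::write.table(long, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, qmethod = "double")
  invisible(path)
}

#' Validate and write/read eye-level feature tables
#'
#' A study table has one row per eye with columns `eye_id`, `group` and
#' numeric per-layer feature columns (for example `fd_GCL+IPL`,
#' `thickness_OPL`, `refl_OS`). Values are written with full double
#' precision so sub-0.01 cutoffs survive the round trip.
#'
#' @param table a data frame satisfying the contract above.
#' @param path CSV path.
#' @return `write_feature_table()` the path invisibly;
#'   `read_feature_table()` the data frame.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) > 0 && !all(c("eye_id", "group") %in% names(table))) {
    stop("feature table needs eye_id and group columns", call. = FALSE)
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  # format() with 15 significant digits keeps doubles lossless in CSV
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 15, format = "g")
    s[is.na(v)] <- NA
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in setdiff(names(tab), c("eye_id", "group"))) {
    tab[[nm]] <- as.numeric(tab[[nm]])
  }
  tab
}

#' Read a JSON pipeline/phantom configuration
#'
#' @param path JSON file.
#' @return a named list (arrays simplified to vectors).
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
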