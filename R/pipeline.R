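# End-to-end orchestration: images + boundaries -> shadow removal ->
# FD / thickness / reflectivity features per eye -> group statistics.
# Deterministic given config and inputs; every exclusion is counted in the
# run log; outputs are written atomically (temp file + rename).

default_pipeline_config <- function() {
  list(
    axial_pitch = 2, lateral_pitch = 6000 / 512,
    despeckle_window = 0,          # 0 disables despeckling
    shadows = list(enabled = TRUE, k_sigma = 2, min_width = 3,
                   max_width = 40),
    fractal = list(min_profile = 8, detrend = FALSE, taper = FALSE,
                   band = NULL, min_points = 4),
    stats = list(alpha = 0.001, cutoff_rule = "mean_minus_2sd",
                 direction = "low", healthy = "healthy", diseased = "MDR"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads the scans listed in a metadata table, detects and excludes vessel
#' shadows, measures per-layer fractal dimension, thickness and
#' RPE-normalized reflectivity for every scan, averages scans into
#' eye-level features, and compares the two groups layer by layer.
#'
#' @param config a named list or a path to a JSON file. Required fields:
#'   `images` (directory containing the scan image files), `segmentation`
#'   (long CSV readable by [read_segmentation()], all scans in one file),
#'   `metadata` (CSV with columns `eye_id`, `group`, `scan_id`, `file`),
#'   `output_dir`. Optional fields (with defaults): `axial_pitch`,
#'   `lateral_pitch`, `despeckle_window` (0 = off), `shadows`
#'   (`enabled`, `k_sigma`, `min_width`, `max_width`), `fractal`
#'   (`min_profile`, `detrend`, `taper`, `band`, `min_points`), `stats`
#'   (`alpha`, `cutoff_rule`, `direction`, `healthy`, `diseased`).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `study` (the eye-level feature table),
#'   `comparison` (the [compare_layers()] table), `scan_features`
#'   (per-scan rows), `log` (character vector) and `config` (the fully
#'   resolved configuration). Writes `features.csv`, `scan_features.csv`,
#'   `comparison.csv`, `shadow_masks.csv` and `run_log.txt` into
#'   `output_dir`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  for (req in c("images", "segmentation", "metadata", "output_dir")) {
    if (is.null(cfg[[req]])) stop("config is missing '", req, "'",
                                  call. = FALSE)
  }
  for (p in c(cfg$images, cfg$segmentation, cfg$metadata)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("pipeline run: %d config entries", length(cfg)),
           paste0("config: ", jsonlite::toJSON(cfg[setdiff(names(cfg),
             "output_dir")], auto_unbox = TRUE, null = "null")))
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  meta <- utils::read.csv(cfg$metadata, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "scan_id", "file")
  if (!all(need %in% names(meta))) {
    stop("metadata CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lay <- retinal_layers()
  scan_rows <- list()
  mask_file <- file.path(cfg$output_dir, "shadow_masks.csv")
  first_mask <- TRUE
  for (i in seq_len(nrow(meta))) {
    sid <- meta$scan_id[i]
    stage <- "read_bscan"
    res <- tryCatch({
      img <- read_bscan(file.path(cfg$images, meta$file[i]),
                        cfg$axial_pitch, cfg$lateral_pitch,
                        scan_id = sid, eye_id = meta$eye_id[i])
      stage <- "read_segmentation"
      seg <- read_segmentation(cfg$segmentation, img, scan_id = sid)
      if (attr(seg, "n_interpolated") > 0) {
        say("scan %s: interpolated %d missing boundary entries", sid,
            attr(seg, "n_interpolated"))
      }
      if (cfg$despeckle_window >= 3) {
        stage <- "despeckle"
        img <- despeckle(img, cfg$despeckle_window)
      }
      mask <- NULL
      if (isTRUE(cfg$shadows$enabled)) {
        stage <- "detect_shadows"
        mask <- detect_shadows(img, seg, k_sigma = cfg$shadows$k_sigma,
                               min_width = cfg$shadows$min_width,
                               max_width = cfg$shadows$max_width)
        write_shadow_mask(mask, mask_file, scan_id = sid,
                          append = !first_mask)
        first_mask <- FALSE
        say("scan %s: %d shadow column(s) in %d interval(s)", sid,
            length(mask$columns), length(mask$intervals))
      }
      stage <- "features"
      row <- list(eye_id = meta$eye_id[i], group = meta$group[i],
                  scan_id = sid)
      fr <- cfg$fractal
      for (l in lay) {
        fdres <- layer_fd(img, seg, l, mask = mask,
                          min_profile = fr$min_profile,
                          detrend = isTRUE(fr$detrend),
                          taper = isTRUE(fr$taper),
                          band = fr$band, min_points = fr$min_points)
        if (sum(fdres$exclusions) > 0) {
          say("scan %s layer %s: excluded %s of %d A-scans", sid, l,
              paste(names(fdres$exclusions), fdres$exclusions, sep = "=",
                    collapse = ", "), fdres$n_ascans)
        }
        row[[paste0("fd_", l)]] <- fdres$mean_fd
        row[[paste0("thickness_", l)]] <-
          layer_thickness(seg, l, cfg$axial_pitch)
        row[[paste0("refl_", l)]] <- layer_reflectivity(img, seg, l,
                                                        mask = mask)
      }
      as.data.frame(row, check.names = FALSE)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for scan '", sid, "': ",
           conditionMessage(e), call. = FALSE)
    })
    scan_rows[[sid]] <- res
  }
  scan_feat <- do.call(rbind, scan_rows)
  rownames(scan_feat) <- NULL
  # eye-level aggregation: unweighted mean of per-scan values
  feat_cols <- setdiff(names(scan_feat), c("eye_id", "group", "scan_id"))
  eyes <- unique(scan_feat[, c("eye_id", "group")])
  study <- do.call(rbind, lapply(seq_len(nrow(eyes)), function(j) {
    sub <- scan_feat[scan_feat$eye_id == eyes$eye_id[j], , drop = FALSE]
    vals <- lapply(feat_cols, function(cc) {
      v <- sub[[cc]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    names(vals) <- feat_cols
    cbind(data.frame(eye_id = eyes$eye_id[j], group = eyes$group[j]),
          as.data.frame(vals, check.names = FALSE))
  }))
  rownames(study) <- NULL
  say("aggregated %d scans into %d eyes", nrow(scan_feat), nrow(study))
  st <- cfg$stats
  comparison <- compare_layers(study, healthy = st$healthy,
                               diseased = st$diseased, alpha = st$alpha,
                               cutoff_rule = st$cutoff_rule,
                               direction = st$direction)
  write_atomic(function(p) write_feature_table(scan_feat, p),
               file.path(cfg$output_dir, "scan_features.csv"))
  write_atomic(function(p) write_feature_table(study, p),
               file.path(cfg$output_dir, "features.csv"))
  write_atomic(function(p) utils::write.csv(as.data.frame(comparison), p,
                                            row.names = FALSE),
               file.path(cfg$output_dir, "comparison.csv"))
  write_atomic(function(p) writeLines(log, p),
               file.path(cfg$output_dir, "run_log.txt"))
  invisible(list(study = study, comparison = comparison,
                 scan_features = scan_feat, log = log, config = cfg))
}

#' One-command phantom study demo
#'
#' Generates a two-group phantom cohort whose only planted group difference
#' is the GCL+IPL fractal dimension (healthy versus MDR means and
#' between-eye SDs from [reference_moments()]), renders the scans to disk,
#' and runs the full pipeline on them. Geometry is scaled to desk size
#' (default 256 A-scans x 512 depth pixels, 2 scans per eye, 8 eyes per
#' group) so the demo completes in about a minute.
#'
#' @param out_dir output directory (images, tables and results are written
#'   under it).
#' @param seed master integer seed.
#' @param n_healthy,n_diseased eyes per group.
#' @param n_scans scans per eye.
#' @param n_ascans,n_depth phantom geometry.
#' @param quiet passed to [run_pipeline()].
#' @return invisibly, the [run_pipeline()] result list, plus `truth` (the
#'   cohort ground-truth study table).
#' @export
run_phantom_demo <- function(out_dir = tempfile("octfd_demo"), seed = 7,
                             n_healthy = 8, n_diseased = 8, n_scans = 2,
                             n_ascans = 256, n_depth = 512, quiet = TRUE) {
  ref <- reference_moments("fd")
  g <- ref[ref$layer == "GCL+IPL", ]
  healthy_spec <- phantom_spec(n_ascans = n_ascans, n_depth = n_depth,
                               seed = seed)
  diseased_fd <- healthy_spec$layer_fd
  diseased_fd["GCL+IPL"] <- g$mdr_mean
  diseased_spec <- phantom_spec(n_ascans = n_ascans, n_depth = n_depth,
                                layer_fd = diseased_fd, seed = seed)
  cohort <- make_cohort(healthy_spec, diseased_spec,
                        n_healthy = n_healthy, n_diseased = n_diseased,
                        between_eye_sd = list(fd = g$healthy_sd),
                        between_eye_sd_diseased = list(fd = g$mdr_sd))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  seg_path <- file.path(out_dir, "segmentation.csv")
  meta <- list()
  first <- TRUE
  for (eye_id in names(cohort$specs)) {
    scans <- make_eye(cohort$specs[[eye_id]], n_scans = n_scans,
                      eye_id = eye_id)
    for (sc in scans) {
      fn <- paste0(sc$image$scan_id, ".tif")
      write_bscan(sc$image, file.path(img_dir, fn))
      write_segmentation(sc$truth$boundaries, seg_path,
                         scan_id = sc$image$scan_id, append = !first)
      first <- FALSE
      meta[[sc$image$scan_id]] <- data.frame(
        eye_id = eye_id,
        group = cohort$study$group[cohort$study$eye_id == eye_id],
        scan_id = sc$image$scan_id, file = fn)
    }
  }
  meta <- do.call(rbind, meta)
  meta_path <- file.path(out_dir, "metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  cfg <- list(images = img_dir, segmentation = seg_path,
              metadata = meta_path,
              output_dir = file.path(out_dir, "results"),
              axial_pitch = healthy_spec$axial_pitch,
              lateral_pitch = healthy_spec$lateral_pitch)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- run_pipeline(cfg, quiet = quiet)
  res$truth <- cohort$study
  invisible(res)
}
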