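# Layer thickness and RPE-normalized reflectivity.
#
# Thickness is geometric: the mean boundary-to-boundary distance, using the
# real-valued boundary positions (no pixel rounding) so that the per-layer
# thicknesses add up exactly to the total retinal thickness under the shared
# boundary convention. Shadowed columns keep valid boundaries, so thickness
# never uses the shadow mask; reflectivity does.

#' Mean thickness of one layer
#'
#' Mean over all A-scans of (lower - upper boundary position) times the
#' axial pitch. All A-scans are included: vessel shadows darken the image
#' but leave the boundaries valid.
#'
#' @param seg a [layer_seg()].
#' @param layer one of [retinal_layers()].
#' @param axial_pitch microns per depth pixel.
#' @return thickness in microns.
#' @export
layer_thickness <- function(seg, layer, axial_pitch) {
  stopifnot(inherits(seg, "layer_seg"), axial_pitch > 0)
  band <- layer_band(seg, layer)
  mean(band$lower - band$upper) * axial_pitch
}

#' Total retinal thickness
#'
#' Mean distance from the inner retinal surface (vitreous/RNFL) to the
#' RPE/choroid boundary. Equal, by the shared-boundary convention, to the
#' sum of the seven layer thicknesses.
#'
#' @inheritParams layer_thickness
#' @return thickness in microns.
#' @export
total_retina_thickness <- function(seg, axial_pitch) {
  stopifnot(inherits(seg, "layer_seg"), axial_pitch > 0)
  mean(seg$rows["RPE/choroid", ] - seg$rows["vitreous/RNFL", ]) * axial_pitch
}

#' RPE-normalized mean reflectivity of one layer
#'
#' Mean intensity of the layer's pixels over non-masked A-scans, divided by
#' the mean RPE intensity over the same A-scans. The ratio is dimensionless
#' and invariant to rescaling the whole image; the RPE itself normalizes
#' to 1.
#'
#' @param image a [bscan()].
#' @param seg a [layer_seg()].
#' @param layer one of [retinal_layers()].
#' @param mask optional [shadow_mask()]; shadowed columns are excluded from
#'   both the layer and the RPE means.
#' @return dimensionless ratio.
#' @export
layer_reflectivity <- function(image, seg, layer, mask = NULL) {
  stopifnot(inherits(image, "bscan"), inherits(seg, "layer_seg"))
  cols <- setdiff(seq_len(n_ascans(image)), masked_columns(mask))
  if (!length(cols)) stop("all A-scans masked", call. = FALSE)
  band_mean <- function(lname) {
    band <- layer_band(seg, lname)
    tot <- 0; cnt <- 0
    for (a in cols) {
      r0 <- ceiling(band$upper[a]); r1 <- ceiling(band$lower[a]) - 1
      if (r1 < r0) next
      tot <- tot + sum(image$pixels[(r0:r1) + 1, a])
      cnt <- cnt + (r1 - r0 + 1)
    }
    if (cnt == 0) NA_real_ else tot / cnt
  }
  rpe <- band_mean("RPE")
  if (is.na(rpe) || rpe == 0) {
    stop("degenerate reference: RPE band empty or zero over non-masked columns",
         call. = FALSE)
  }
  band_mean(layer) / rpe
}
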