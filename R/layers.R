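# Canonical layer / boundary naming used throughout the package.

#' Intraretinal layer and boundary names
#'
#' The seven intraretinal layers resolved on time-domain macular OCT, in
#' anatomical order from the vitreous downward, and the eight boundaries
#' delimiting them. Layer `i` is the band between boundary `i` and boundary
#' `i + 1`.
#'
#' @return `retinal_layers()` returns a character vector of 7 layer names
#'   (RNFL, GCL+IPL, INL, OPL, ONL+IS, OS, RPE); `retinal_boundaries()`
#'   returns the 8 boundary names.
#' @examples
#' retinal_layers()
#' retinal_boundaries()
#' @export
retinal_layers <- function() {
  c("RNFL", "GCL+IPL", "INL", "OPL", "ONL+IS", "OS", "RPE")
}

#' @rdname retinal_layers
#' @export
retinal_boundaries <- function() {
  c("vitreous/RNFL", "RNFL/GCL+IPL", "GCL+IPL/INL", "INL/OPL",
    "OPL/ONL+IS", "ONL+IS/OS", "OS/RPE", "RPE/choroid")
}

# index of a layer name, with a helpful error
match_layer <- function(layer) {
  i <- match(layer, retinal_layers())
  if (is.na(i)) {
    stop("unknown layer '", layer, "'; expected one of: ",
         paste(retinal_layers(), collapse = ", "), call. = FALSE)
  }
  i
}
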