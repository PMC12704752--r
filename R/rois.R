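#' Define analysis regions of interest
#'
#' Builds the measurement ROI masks from the follicle and oocyte outlines:
#' the outer mural band (inward band of `mural_band_width` from the
#' follicle boundary, default 40 um), the cumulus band (outward band of
#' `cumulus_band_width` from the oocyte boundary, default 25 um), the
#' oocyte disc minus the nucleus, the nucleus disc, and an extra-follicular
#' background region.  Disjointness is enforced with precedence
#' oocyte > cumulus > mural.
#'
#' @param frame_size Frame side in pixels.
#' @param pixel_size Pixel size (um).
#' @param center Follicle centre, pixel coordinates `c(x, y)`.
#' @param follicle_radius Follicle radius (um).
#' @param oocyte_radius Oocyte radius (um).
#' @param nucleus_radius Nucleus radius (um).
#' @param mural_band_width,cumulus_band_width Band widths (um).
#' @param oocyte_center Oocyte centre if different from the follicle
#'   centre.
#' @return An object of class `roi_set`: a named list of logical masks
#'   `outer_mural`, `cumulus`, `oocyte`, `nucleus`, `background`, with
#'   attribute `provenance = "geometric"`.
#' @export
define_rois <- function(frame_size, pixel_size, center,
                        follicle_radius, oocyte_radius,
                        nucleus_radius = 0,
                        mural_band_width = 40, cumulus_band_width = 25,
                        oocyte_center = center) {
  stopifnot(follicle_radius > 0, oocyte_radius > 0, pixel_size > 0)
  if (oocyte_radius >= follicle_radius)
    stop("oocyte outline must lie inside the follicle outline")
  d_oc <- sqrt(sum((oocyte_center - center)^2)) * pixel_size
  if (d_oc + oocyte_radius + cumulus_band_width >
      follicle_radius - mural_band_width)
    stop("cumulus and mural bands overlap: follicle too small for the configured widths")

  n <- frame_size
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  r_f <- sqrt((x - center[1])^2 + (y - center[2])^2) * pixel_size
  r_o <- sqrt((x - oocyte_center[1])^2 + (y - oocyte_center[2])^2) * pixel_size

  oocyte <- r_o < oocyte_radius & r_o >= nucleus_radius
  nucleus <- r_o < nucleus_radius
  cumulus <- r_o >= oocyte_radius & r_o < oocyte_radius + cumulus_band_width
  outer_mural <- r_f < follicle_radius &
    r_f >= follicle_radius - mural_band_width & !cumulus & !oocyte & !nucleus
  background <- r_f >= follicle_radius + 15  # clear of the theca rim

  rois <- list(outer_mural = outer_mural, cumulus = cumulus,
               oocyte = oocyte, nucleus = nucleus, background = background)
  if (any(vapply(rois[c("outer_mural", "cumulus", "oocyte", "background")],
                 function(m) !any(m), logical(1))))
    stop("one or more ROIs are empty for this frame geometry")
  structure(rois, provenance = "geometric", class = "roi_set")
}

#' ROIs from a scene's ground-truth labels
#'
#' Passes the generator's label masks through as measurement ROIs
#' (provenance `"ground-truth"`); antral patches and the theca rim are
#' excluded.
#'
#' @param labels Label matrix from an `image_stack`'s ground truth.
#' @return An object of class `roi_set`.
#' @export
rois_from_labels <- function(labels) {
  rois <- list(outer_mural = labels == region_labels[["outer_mural"]],
               cumulus = labels == region_labels[["cumulus"]],
               oocyte = labels == region_labels[["oocyte"]],
               nucleus = labels == region_labels[["nucleus"]],
               background = labels == region_labels[["background"]])
  structure(rois, provenance = "ground-truth", class = "roi_set")
}

#' Geometric ROIs matching a scene
#'
#' Convenience wrapper building [define_rois()] masks from a
#' [follicle_scene()], as an automated stand-in for manually drawn ROIs.
#'
#' @param scene A [follicle_scene()] object.
#' @return An object of class `roi_set`.
#' @export
rois_from_scene <- function(scene) {
  g <- scene$geometry
  define_rois(scene$frame_size, scene$pixel_size, scene$center,
              follicle_radius = g$follicle_diameter / 2,
              oocyte_radius = g$oocyte_diameter / 2,
              nucleus_radius = g$nucleus_diameter / 2,
              mural_band_width = g$mural_band_width,
              cumulus_band_width = g$cumulus_band_width)
}
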