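#' Follicle geometry
#'
#' Describes an isolated mouse preovulatory follicle as imaged on an
#' organotypic membrane: a sphere of ~320-360 um diameter flattened to a
#' disc ~200 um high, containing a central oocyte, a cumulus cell layer
#' around it, and the remaining granulosa volume of which the outermost
#' band is treated as the "outer mural" region.  Compartment cytosolic
#' volumes for the well-mixed model are derived from these dimensions.
#'
#' The oocyte and cumulus are modelled as concentric spheres (the oocyte
#' is not flattened); the granulosa compartment is the disc volume minus
#' the antral space and the oocyte/cumulus volumes.  Only the volume
#' ratios matter for the dynamics: the granulosa cytoplasm is a much
#' larger reservoir than the oocyte, so cGMP leaving the oocyte through
#' gap junctions is effectively diluted away.
#'
#' @param follicle_diameter Follicle diameter in um (default 340, the
#'   midpoint of the 320-360 um range used for imaging).
#' @param disc_height Height in um of the flattened follicle (default 200).
#' @param mural_band_width Width in um of the outer mural analysis band
#'   (default 40).
#' @param cumulus_band_width Width in um of the cumulus layer around the
#'   oocyte (default 25).
#' @param oocyte_diameter Oocyte diameter in um (default 75, a typical
#'   fully grown mouse oocyte).
#' @param nucleus_diameter Diameter in um of the prophase-arrested nucleus
#'   (default 30).
#' @param antral_fraction Fraction of the disc volume occupied by antral
#'   fluid (default 0.15); excluded from the cytosolic volume.
#'
#' @return An object of class `follicle_geometry`: a list with the input
#'   dimensions plus derived cytosolic volumes `V_o`, `V_c`, `V_m` (um^3)
#'   for oocyte, cumulus and mural granulosa.
#' @examples
#' geom <- follicle_geometry()
#' geom$V_m / geom$V_o  # the granulosa reservoir is ~60x the oocyte
#' @export
follicle_geometry <- function(follicle_diameter = 340,
                              disc_height = 200,
                              mural_band_width = 40,
                              cumulus_band_width = 25,
                              oocyte_diameter = 75,
                              nucleus_diameter = 30,
                              antral_fraction = 0.15) {
  stopifnot(follicle_diameter > 0, disc_height > 0,
            mural_band_width > 0, cumulus_band_width > 0,
            oocyte_diameter > 0, nucleus_diameter > 0,
            antral_fraction >= 0, antral_fraction < 1)
  if (nucleus_diameter >= oocyte_diameter)
    stop("nucleus_diameter must be smaller than oocyte_diameter")
  if (oocyte_diameter + 2 * cumulus_band_width + 2 * mural_band_width >=
      follicle_diameter)
    stop("follicle too small for the configured oocyte and band widths")

  r_f <- follicle_diameter / 2
  r_o <- oocyte_diameter / 2
  r_c <- r_o + cumulus_band_width

  sphere_vol <- function(r) 4 / 3 * pi * r^3
  V_o <- sphere_vol(r_o)
  V_c <- sphere_vol(r_c) - V_o
  disc_vol <- pi * r_f^2 * disc_height
  V_m <- disc_vol * (1 - antral_fraction) - V_o - V_c
  if (V_m <= V_c || V_c <= V_o)
    stop("geometry must satisfy V_m > V_c > V_o")

  structure(list(
    follicle_diameter = follicle_diameter,
    disc_height = disc_height,
    mural_band_width = mural_band_width,
    cumulus_band_width = cumulus_band_width,
    oocyte_diameter = oocyte_diameter,
    nucleus_diameter = nucleus_diameter,
    antral_fraction = antral_fraction,
    V_o = V_o, V_c = V_c, V_m = V_m
  ), class = "follicle_geometry")
}

#' @export
print.follicle_geometry <- function(x, ...) {
  cat("Follicle geometry\n")
  cat(sprintf("  diameter %g um, disc height %g um, antral fraction %g\n",
              x$follicle_diameter, x$disc_height, x$antral_fraction))
  cat(sprintf("  oocyte %g um, cumulus band %g um, mural band %g um\n",
              x$oocyte_diameter, x$cumulus_band_width, x$mural_band_width))
  cat(sprintf("  volumes (um^3): oocyte %.3g, cumulus %.3g, mural %.3g\n",
              x$V_o, x$V_c, x$V_m))
  invisible(x)
}
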