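#' Synthetic follicle scene
#'
#' Geometric and optical description of a model follicle used by the
#' two-channel time-lapse renderer: a flattened follicle imaged at the
#' oocyte equator, with concentric oocyte / cumulus / granulosa regions, a
#' dark prophase nucleus, dark antral patches in the granulosa, a thin dim
#' theca rim, uniform autofluorescence background, spectral bleed-through
#' of CFP into the YFP channel, and frame-to-frame translational jitter.
#'
#' Sensor brightness is expressed in detector counts.  The mural brightness
#' is set so that the baseline YFP sensor signal is `signal_to_background`
#' times the autofluorescence background, matching the 3-10x range of the
#' real recordings; oocyte expression can be scaled over the observed
#' 5-fold range with `oocyte_expression`.
#'
#' @param geometry A [follicle_geometry()] object.
#' @param frame_size Frame side in pixels (default 512).
#' @param pixel_size Pixel size in um (default 0.8, so a 340-um follicle
#'   fits a 512x512 frame with margin).
#' @param center Follicle centre in pixel coordinates (x, y); default the
#'   frame centre.
#' @param signal_to_background Baseline mural YFP sensor signal over
#'   background, in [3, 10].
#' @param oocyte_expression Oocyte sensor level relative to mural
#'   (0.5-2.5 spans the 5-fold range seen across follicles).
#' @param cumulus_expression Cumulus sensor level relative to mural.
#' @param background_level Autofluorescence counts per channel, named
#'   `cfp`, `yfp`.
#' @param bleedthrough_alpha Fraction of CFP intensity added into the YFP
#'   channel (default 0.23, the spectral-overlap fraction subtracted
#'   during analysis).
#' @param read_noise_frac Gaussian read noise sd as a fraction of the
#'   pixel mean (default 0.02).
#' @param jitter_sd Per-frame translational jitter sd in pixels.
#' @param nebd_time Time (min) of nuclear envelope breakdown, after which
#'   the nuclear region fills with sensor fluorescence; `NA` for none.
#' @param n_antral_patches Number of dark antral patches in the granulosa.
#' @param seed Integer seed making the scene (patch placement) and the
#'   rendered stack reproducible.
#'
#' @return An object of class `follicle_scene`.
#' @export
follicle_scene <- function(geometry = follicle_geometry(),
                           frame_size = 512, pixel_size = 0.8,
                           center = NULL,
                           signal_to_background = 6,
                           oocyte_expression = 1,
                           cumulus_expression = 1,
                           background_level = c(cfp = 300, yfp = 300),
                           bleedthrough_alpha = 0.23,
                           read_noise_frac = 0.02,
                           jitter_sd = 0.5,
                           nebd_time = NA_real_,
                           n_antral_patches = 5,
                           seed = 1L) {
  stopifnot(pixel_size > 0, frame_size >= 32,
            signal_to_background >= 3, signal_to_background <= 10,
            bleedthrough_alpha >= 0, bleedthrough_alpha < 1,
            jitter_sd >= 0, oocyte_expression > 0, cumulus_expression > 0)
  if (is.null(center)) center <- c(frame_size, frame_size) / 2 + 0.5
  r_f <- geometry$follicle_diameter / 2 / pixel_size
  if (r_f >= frame_size / 2)
    warning("follicle does not fit the frame; margins will be clipped")

  # antral patches: dark discs in the granulosa annulus, between the
  # cumulus layer and the outer mural band
  rng <- local({set.seed(seed); list(
    ang = stats::runif(n_antral_patches, 0, 2 * pi),
    rad = stats::runif(n_antral_patches, 0.25, 0.9),
    size = stats::runif(n_antral_patches, 12, 28))})
  r_o <- geometry$oocyte_diameter / 2
  r_c <- r_o + geometry$cumulus_band_width
  r_m_in <- geometry$follicle_diameter / 2 - geometry$mural_band_width
  gap <- r_m_in - r_c
  patches <- if (n_antral_patches > 0 && gap > 10) data.frame(
    r_um = r_c + 5 + rng$rad * pmax(gap - 10, 1),
    ang = rng$ang,
    radius_um = pmin(rng$size, gap / 2)
  ) else data.frame(r_um = numeric(), ang = numeric(), radius_um = numeric())

  structure(list(
    geometry = geometry, frame_size = as.integer(frame_size),
    pixel_size = pixel_size, center = center,
    signal_to_background = signal_to_background,
    oocyte_expression = oocyte_expression,
    cumulus_expression = cumulus_expression,
    background_level = background_level,
    bleedthrough_alpha = bleedthrough_alpha,
    read_noise_frac = read_noise_frac,
    jitter_sd = jitter_sd, nebd_time = nebd_time,
    antral_patches = patches, seed = as.integer(seed)
  ), class = "follicle_scene")
}

# region label image for a scene, optionally with the follicle displaced by
# `shift` (pixels, c(dx, dy), subpixel allowed).  Labels:
# 0 background, 1 outer mural band, 2 inner granulosa, 3 cumulus,
# 4 oocyte cytoplasm, 5 nucleus, 6 antral patch, 7 theca rim
region_labels <- c(background = 0, outer_mural = 1, inner_granulosa = 2,
                   cumulus = 3, oocyte = 4, nucleus = 5, antral = 6,
                   theca = 7)

scene_label_image <- function(scene, shift = c(0, 0)) {
  n <- scene$frame_size
  px <- scene$pixel_size
  cx <- scene$center[1] + shift[1]
  cy <- scene$center[2] + shift[2]
  x <- matrix(rep(seq_len(n), each = n), n, n)   # column index = x
  y <- matrix(rep(seq_len(n), times = n), n, n)  # row index = y
  r <- sqrt((x - cx)^2 + (y - cy)^2) * px        # um from centre

  g <- scene$geometry
  r_o <- g$oocyte_diameter / 2
  r_n <- g$nucleus_diameter / 2
  r_c <- r_o + g$cumulus_band_width
  r_f <- g$follicle_diameter / 2
  r_m <- r_f - g$mural_band_width
  theca_w <- 8

  lab <- matrix(region_labels[["background"]], n, n)
  lab[r < r_f + theca_w] <- region_labels[["theca"]]
  lab[r < r_f] <- region_labels[["outer_mural"]]
  lab[r < r_m] <- region_labels[["inner_granulosa"]]
  lab[r < r_c] <- region_labels[["cumulus"]]
  lab[r < r_o] <- region_labels[["oocyte"]]
  lab[r < r_n] <- region_labels[["nucleus"]]

  if (nrow(scene$antral_patches) > 0) {
    for (i in seq_len(nrow(scene$antral_patches))) {
      p <- scene$antral_patches[i, ]
      pxc <- cx + p$r_um * cos(p$ang) / px
      pyc <- cy + p$r_um * sin(p$ang) / px
      d <- sqrt((x - pxc)^2 + (y - pyc)^2) * px
      hit <- d < p$radius_um &
        (lab == region_labels[["inner_granulosa"]] |
         lab == region_labels[["outer_mural"]])
      lab[hit] <- region_labels[["antral"]]
    }
  }
  lab
}
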