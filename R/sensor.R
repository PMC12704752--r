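#' FRET sensor calibration
#'
#' Hill-type mapping between cyclic-nucleotide concentration and the
#' CFP/YFP emission ratio of a FRET-loss biosensor.  Ligand binding
#' decreases FRET, so CFP emission rises relative to YFP and the CFP/YFP
#' ratio increases monotonically with concentration.  With a Hill
#' coefficient of 1 the ratio is approximately proportional to
#' log10(concentration) over roughly EC50/3 to 3*EC50, which is the
#' quasi-linear range used to convert measured ratios to concentrations.
#'
#' The shipped constants place the basal (~700 nM), minimum (~170 nM) and
#' peak (~3,400 nM) cAMP landmarks inside the quasi-linear range of the
#' cAMPFIRE-M curve; they are representative, config-overridable values,
#' not published photophysical constants.
#'
#' @param sensor_id `"cAMPFIRE-M"` (cAMP) or `"cGi500"` (cGMP), or any
#'   label for a custom sensor.
#' @param R_min CFP/YFP ratio at zero ligand.
#' @param R_max Saturating ratio (> R_min).
#' @param EC50 Half-effect concentration (nM).
#' @param hill_n Hill coefficient.
#' @return An object of class `sensor_calibration`.
#' @examples
#' cal <- sensor_calibration("cAMPFIRE-M")
#' ratio_from_concentration(700, cal)
#' @export
sensor_calibration <- function(sensor_id = c("cAMPFIRE-M", "cGi500"),
                               R_min = 1.0, R_max = 3.0,
                               EC50 = NULL, hill_n = 1.0) {
  sensor_id <- if (is.character(sensor_id)) sensor_id[1L] else
    stop("sensor_id must be a character label")
  if (is.null(EC50))
    EC50 <- switch(sensor_id, "cAMPFIRE-M" = 1000, "cGi500" = 500,
                   stop("EC50 must be given for a custom sensor"))
  stopifnot(R_min > 0, R_max > R_min, EC50 > 0, hill_n > 0)
  structure(list(sensor_id = sensor_id, R_min = R_min, R_max = R_max,
                 EC50 = EC50, hill_n = hill_n),
            class = "sensor_calibration")
}

#' Concentration to CFP/YFP emission ratio
#'
#' @param c Concentration (nM), vectorised, >= 0.
#' @param calib A [sensor_calibration()] object.
#' @return CFP/YFP emission ratio(s) in `[R_min, R_max)`.
#' @export
ratio_from_concentration <- function(c, calib) {
  if (any(c < 0)) stop("concentration must be non-negative")
  cn <- c^calib$hill_n
  calib$R_min + (calib$R_max - calib$R_min) * cn / (calib$EC50^calib$hill_n + cn)
}

#' CFP/YFP emission ratio to concentration
#'
#' Exact algebraic inverse of [ratio_from_concentration()]; defined only
#' strictly between `R_min` and `R_max` (at either end the Hill curve is
#' saturated and has no finite inverse).
#'
#' @param r Ratio(s), each in the open interval (R_min, R_max).
#' @param calib A [sensor_calibration()] object.
#' @return Concentration(s) in nM.
#' @export
concentration_from_ratio <- function(r, calib) {
  if (any(r <= calib$R_min))
    stop(sprintf("ratio at or below R_min = %g: sensor at the zero-ligand end",
                 calib$R_min))
  if (any(r >= calib$R_max))
    stop(sprintf("ratio at or above R_max = %g: sensor saturated", calib$R_max))
  f <- (r - calib$R_min) / (calib$R_max - r)
  calib$EC50 * f^(1 / calib$hill_n)
}

#' Read a sensor calibration from YAML
#'
#' A calibration file holds the four Hill constants (and optionally the
#' sensor label): `sensor_id`, `R_min`, `R_max`, `EC50`, `hill_n`.
#' Missing fields fall back to the shipped defaults for that sensor;
#' unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [sensor_calibration()] object.
#' @export
sensor_calibration_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), names(formals(sensor_calibration)))
  if (length(bad))
    stop("unknown calibration key(s): ", paste(bad, collapse = ", "))
  do.call(sensor_calibration, cfg)
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("FRET sensor calibration [%s]: R_min %g, R_max %g, EC50 %g nM, n %g\n",
              x$sensor_id, x$R_min, x$R_max, x$EC50, x$hill_n))
  invisible(x)
}
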