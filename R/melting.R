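#' Construct a CD melt curve
#'
#' A melt curve is a series of CD ellipticity readings (mdeg) at a fixed
#' wavelength over a temperature ramp. Heating curves have strictly
#' increasing temperatures, annealing curves strictly decreasing. Celsius
#' input is detected (all temperatures below 200) and converted to kelvin
#' unless disabled.
#'
#' @param temperature temperatures along the ramp (K, or degrees C with
#'   `celsius = "auto"`/`"yes"`).
#' @param ellipticity CD signal in mdeg, same length.
#' @param direction `"heating"` or `"annealing"`.
#' @param wavelength recording wavelength in nm (default 285, the i-motif
#'   positive band).
#' @param celsius `"auto"` (convert when all temperatures < 200), `"yes"`
#'   (always add 273.15) or `"no"`.
#' @return A `melt_curve` data frame with columns `temperature` (K) and
#'   `ellipticity`, and attributes `direction`, `wavelength`, `data_pitch`.
#' @export
melt_curve <- function(temperature, ellipticity,
                       direction = c("heating", "annealing"),
                       wavelength = 285, celsius = c("auto", "yes", "no")) {
  direction <- match.arg(direction)
  celsius <- match.arg(celsius)
  stopifnot(length(temperature) == length(ellipticity),
            all(is.finite(temperature)), all(is.finite(ellipticity)))
  if (length(temperature) < 10L) {
    stop("a melt curve needs at least 10 points, got ", length(temperature))
  }
  if (celsius == "yes" || (celsius == "auto" && max(temperature) < 200)) {
    temperature <- temperature + 273.15
  }
  dT <- diff(temperature)
  ok <- switch(direction,
    heating = all(dT > 0),
    annealing = all(dT < 0)
  )
  if (!ok) {
    stop("temperatures must be strictly ", switch(direction,
         heating = "increasing", annealing = "decreasing"),
         " for a ", direction, " curve")
  }
  structure(
    data.frame(temperature = temperature, ellipticity = ellipticity),
    direction = direction, wavelength = wavelength,
    data_pitch = stats::median(abs(dT)),
    class = c("melt_curve", "data.frame")
  )
}

#' Read a melt curve from CSV
#'
#' Expects a header row with columns `temperature` and `ellipticity`
#' (additional columns are ignored; an optional `replicate` column can be
#' used to split the file with [split_replicates()]).
#'
#' @param path CSV file path.
#' @inheritParams melt_curve
#' @return A `melt_curve`, or (when a `replicate` column is present) a list
#'   of `melt_curve` objects, one per replicate.
#' @export
read_melt_curve <- function(path, direction = c("heating", "annealing"),
                            wavelength = 285, celsius = c("auto", "yes", "no")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "ellipticity")
  if (!all(need %in% names(df))) {
    stop("CSV must have header columns 'temperature' and 'ellipticity': ", path)
  }
  build <- function(d) {
    melt_curve(d$temperature, d$ellipticity, direction = direction,
               wavelength = wavelength, celsius = celsius)
  }
  if ("replicate" %in% names(df)) {
    lapply(split(df, df$replicate), build)
  } else {
    build(df)
  }
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("melt curve (%s, %g nm): %d points, %.1f-%.1f K, pitch %.2g K\n",
              attr(x, "direction"), attr(x, "wavelength"), nrow(x),
              min(x$temperature), max(x$temperature), attr(x, "data_pitch")))
  invisible(x)
}

#' @export
plot.melt_curve <- function(x, ...) {
  graphics::plot(x$temperature, x$ellipticity, type = "l",
                 xlab = "T (K)", ylab = "ellipticity (mdeg)", ...)
  invisible(x)
}

#' Melting temperature from the first derivative of a melt curve
#'
#' Tm is the temperature at which the first derivative of ellipticity with
#' respect to temperature has its largest magnitude, i.e. the steepest point
#' of the unfolding transition. The derivative is estimated with a
#' Savitzky-Golay (moving polynomial) first-derivative filter, and the peak
#' position is refined by fitting a parabola to the derivative over its
#' half-maximum region and taking the vertex — for a symmetric two-state
#' transition this recovers the midpoint exactly, on or off the temperature
#' grid. Using the magnitude of the derivative makes the estimate
#' direction-agnostic (i-motif unfolding lowers the 285 nm band on heating,
#' so the raw heating-curve extremum is a minimum). Applied to an
#' annealing-direction curve the same extremum is the annealing temperature
#' Ta.
#'
#' A curve whose derivative has no interior extremum standing clear of its
#' typical level (flat or purely linear baseline) raises a "no transition
#' detected" error.
#'
#' @param curve a `melt_curve` with (near-)uniform temperature pitch.
#' @param smoothing_window Savitzky-Golay window length in points; odd,
#'   shorter than the curve. Default 11 (about 2.2 K at 0.2 K pitch).
#' @param polyorder polynomial order of the filter (default 2).
#' @return Tm (or Ta) in K, with attribute `direction`.
#' @examples
#' cu <- synth_melt_curve(tm = 332, seed = 1)
#' tm_from_first_derivative(cu)
#' @export
tm_from_first_derivative <- function(curve, smoothing_window = 11L,
                                     polyorder = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- nrow(curve)
  if (smoothing_window %% 2L != 1L || smoothing_window >= n) {
    stop("smoothing window must be odd and shorter than the curve (",
         n, " points)")
  }
  ord <- order(curve$temperature)
  temp <- curve$temperature[ord]
  theta <- curve$ellipticity[ord]
  pitch <- stats::median(diff(temp))
  deriv <- signal::sgolayfilt(theta, p = polyorder, n = smoothing_window,
                              m = 1L) / pitch
  margin <- max((smoothing_window - 1L) %/% 2L, 1L)
  interior <- (margin + 1L):(n - margin)
  mag <- abs(deriv[interior])
  peak <- which.max(mag)
  # a genuine transition must stand out from the derivative's typical level
  # and sit strictly inside the analysed window
  if (!is.finite(mag[peak]) || mag[peak] <= 0 ||
      peak == 1L || peak == length(mag) ||
      mag[peak] < 2 * stats::median(mag)) {
    stop("no transition detected: derivative has no interior extremum")
  }
  idx <- interior[peak]
  d_signed <- sign(deriv[idx]) * deriv
  tm <- refine_peak_vertex(temp, d_signed, idx)
  attr(tm, "direction") <- attr(curve, "direction")
  tm
}

# Quadratic-vertex refinement of a derivative peak: fit a parabola to the
# contiguous half-maximum region around idx and return the vertex; falls back
# to the grid maximum for too-narrow or ill-conditioned peaks.
refine_peak_vertex <- function(temp, d, idx) {
  half <- d[idx] / 2
  lo <- idx
  while (lo > 1L && d[lo - 1L] >= half) lo <- lo - 1L
  hi <- idx
  while (hi < length(d) && d[hi + 1L] >= half) hi <- hi + 1L
  if (hi - lo + 1L < 5L) return(temp[idx])
  xs <- temp[lo:hi] - temp[idx]
  co <- stats::coef(stats::lm(d[lo:hi] ~ xs + I(xs^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(temp[idx])
  v <- -co[2] / (2 * co[3])
  if (abs(v) > (temp[hi] - temp[lo])) return(temp[idx])
  unname(temp[idx] + v)
}

#' Average replicate melting temperatures
#'
#' Individual melting experiments are averaged arithmetically; three
#' replicates is the usual protocol. A spread above 5 K across replicates is
#' flagged as a quality-control warning on the result.
#'
#' @param replicates numeric vector of per-replicate Tm values (K).
#' @return An object of class `tm_result`: `replicates`, `mean` (full
#'   precision), `mean_rounded` (nearest K), `n`, `spread_flag`.
#' @examples
#' average_tm(c(332.1, 331.8, 332.4))
#' @export
average_tm <- function(replicates) {
  replicates <- as.numeric(replicates)
  if (length(replicates) == 0L) stop("no replicate Tm values supplied")
  stopifnot(all(is.finite(replicates)))
  m <- mean(replicates)
  structure(
    list(
      replicates = replicates,
      mean = m,
      mean_rounded = round(m),
      n = length(replicates),
      spread_flag = diff(range(replicates)) > 5
    ),
    class = "tm_result"
  )
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Tm = %d K (%.2f K, mean of %d replicate%s)%s\n",
              x$mean_rounded, x$mean, x$n, if (x$n == 1L) "" else "s",
              if (x$spread_flag) "  [warning: replicate spread > 5 K]" else ""))
  invisible(x)
}

#' Check a CD spectrum for the i-motif signature
#'
#' A folded i-motif at acidic pH shows a positive CD band near 285 nm and a
#' negative band near 265 nm, with the 285 nm peak about twice the magnitude
#' of the 265 nm trough. The check locates the maximum in 275-295 nm and the
#' minimum in 255-275 nm and passes when the maximum is positive, the
#' minimum negative, and their magnitude ratio is at least 2.
#'
#' @param wavelength wavelengths in nm (strictly increasing, must cover
#'   250-320 nm), or a data frame with columns `wavelength`, `ellipticity`.
#' @param ellipticity CD signal in mdeg.
#' @return A list of class `cd_signature`: `pass`, `peak_nm`, `peak`,
#'   `trough_nm`, `trough`, `ratio`.
#' @export
imotif_spectrum_check <- function(wavelength, ellipticity = NULL) {
  if (is.data.frame(wavelength)) {
    ellipticity <- wavelength$ellipticity
    wavelength <- wavelength$wavelength
  }
  stopifnot(length(wavelength) == length(ellipticity),
            !is.unsorted(wavelength, strictly = TRUE))
  if (min(wavelength) > 250 || max(wavelength) < 320) {
    stop("spectrum must cover 250-320 nm (got ",
         min(wavelength), "-", max(wavelength), " nm)")
  }
  in_peak <- wavelength >= 275 & wavelength <= 295
  in_trough <- wavelength >= 255 & wavelength <= 275
  ip <- which(in_peak)[which.max(ellipticity[in_peak])]
  it <- which(in_trough)[which.min(ellipticity[in_trough])]
  peak <- ellipticity[ip]; trough <- ellipticity[it]
  ratio <- if (trough < 0) abs(peak) / abs(trough) else NA_real_
  structure(
    list(
      pass = peak > 0 && trough < 0 && !is.na(ratio) && ratio >= 2,
      peak_nm = wavelength[ip], peak = peak,
      trough_nm = wavelength[it], trough = trough,
      ratio = ratio
    ),
    class = "cd_signature"
  )
}

#' @export
print.cd_signature <- function(x, ...) {
  cat(sprintf(
    "i-motif CD signature: %s\n  +%.2f mdeg at %g nm, %.2f mdeg at %g nm, |ratio| = %s\n",
    if (x$pass) "PASS" else "FAIL", x$peak, x$peak_nm, x$trough, x$trough_nm,
    if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  invisible(x)
}
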