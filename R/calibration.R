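#' Temperature-averaged RMSD summary statistic
#'
#' The flexibility summary used for thermal-stability prediction: the
#' arithmetic mean of time-averaged RMSD values obtained from simulations at
#' a set of temperatures (conventionally 280, 300, 320, 340 and 360 K).
#' Averaging across temperatures damps the run-to-run irregularity seen in
#' single-temperature simulations of long-loop i-motifs.
#'
#' @param values per-temperature time-averaged RMSDs in A (all `>= 0`).
#' @return The mean in full precision; tables conventionally report it to
#'   1 decimal.
#' @examples
#' mean_rmsd_over_temperatures(c(3.8, 3.3, 3.0, 3.1, 4.0))  # 3.44 -> 3.4
#' @export
mean_rmsd_over_temperatures <- function(values) {
  if (length(values) == 0L) stop("no RMSD values supplied")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("RMSD values must be finite and non-negative")
  }
  mean(values)
}

#' Fit a TR plot (Tm versus temperature-averaged RMSD)
#'
#' Ordinary least-squares fit of experimental melting temperatures against
#' the temperature-averaged RMSD flexibility statistic
#' ([mean_rmsd_over_temperatures()]). The fitted line, `Tm = slope * RMSD +
#' intercept`, is the calibration at the heart of MD-TSPC4: more flexible
#' i-motifs (larger average RMSD) melt at lower temperatures, so the slope is
#' negative.
#'
#' @param rmsd temperature-averaged RMSD values in A, or a data frame with
#'   columns `rmsd`, `tm` and optionally `label`.
#' @param tm experimental melting temperatures in K (ignored when `rmsd` is a
#'   data frame).
#' @param labels optional point labels.
#' @return An object of class `tr_calibration` with components `slope`
#'   (K/A), `intercept` (K), `r_squared`, `points` (data frame), and the
#'   underlying `lm` fit. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `fitted()`, `residuals()` and `plot()`.
#' @examples
#' cal <- fit_tr_plot(c(2.0, 3.4, 5.0), c(332, 321, 311),
#'                    labels = c("CCCT3", "CCCT5", "CCCT7"))
#' coef(cal)           # intercept 345.54, slope -6.98
#' predict(cal, 2.1)   # ~330.9 K
#' @export
fit_tr_plot <- function(rmsd, tm = NULL, labels = NULL) {
  if (is.data.frame(rmsd)) {
    df <- rmsd
    stopifnot(all(c("rmsd", "tm") %in% names(df)))
    if (is.null(df$label)) df$label <- paste0("point", seq_len(nrow(df)))
  } else {
    stopifnot(length(rmsd) == length(tm))
    if (is.null(labels)) labels <- paste0("point", seq_along(rmsd))
    df <- data.frame(rmsd = rmsd, tm = tm, label = labels,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) < 2L) stop("at least two calibration points are required")
  if (any(df$rmsd < 0)) stop("RMSD values must be non-negative")
  if (stats::sd(df$rmsd) == 0) {
    stop("calibration points have zero RMSD variance; cannot fit a line")
  }
  fit <- stats::lm(tm ~ rmsd, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$tm - mean(df$tm))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(
      slope = unname(stats::coef(fit)["rmsd"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      r_squared = r2,
      points = df,
      model = fit
    ),
    class = "tr_calibration"
  )
}

#' Reference TR calibration for thymine-loop model i-motifs
#'
#' The published MD-TSPC4 calibration, refit at run time from its three
#' training points: the CCCT3, CCCT5 and CCCT7 model i-motifs with
#' temperature-averaged whole-molecule RMSDs of 2.0, 3.4 and 5.0 A and
#' CD-derived melting temperatures of 332, 321 and 311 K. The resulting line
#' is `Tm = -6.98 * RMSD + 345.54` with R^2 = 0.99 (values to printed
#' precision).
#'
#' @return A `tr_calibration` object.
#' @examples
#' round(coef(published_calibration()), 2)
#' @export
published_calibration <- function() {
  pts <- reference_tm_values()
  pts <- pts[pts$role == "training", ]
  fit_tr_plot(pts$rmsd, pts$tm, labels = pts$model)
}

#' @export
print.tr_calibration <- function(x, digits = 2, ...) {
  cat("TR-plot calibration (", nrow(x$points), " points)\n", sep = "")
  cat(sprintf("  Tm = %.*f x RMSD(T) + %.*f   [K; RMSD in A]\n",
              digits, x$slope, digits, x$intercept))
  cat(sprintf("  R^2 = %.*f\n", max(digits, 3), x$r_squared))
  invisible(x)
}

#' @export
summary.tr_calibration <- function(object, ...) {
  print(object, digits = 4)
  cat("\nCalibration points:\n")
  pts <- object$points
  pts$fitted <- stats::fitted(object$model)
  pts$residual <- stats::residuals(object$model)
  print(pts, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.tr_calibration <- function(object, ...) {
  c("(Intercept)" = object$intercept, rmsd = object$slope)
}

#' @export
fitted.tr_calibration <- function(object, ...) stats::fitted(object$model)

#' @export
residuals.tr_calibration <- function(object, ...) stats::residuals(object$model)

#' Predict Tm from a calibration
#'
#' @param object a `tr_calibration`.
#' @param newdata numeric vector of temperature-averaged RMSD values (A); if
#'   missing, fitted values are returned.
#' @param ... unused.
#' @return Predicted Tm in K (full precision).
#' @export
predict.tr_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  stopifnot(is.numeric(newdata))
  object$intercept + object$slope * newdata
}

#' @export
plot.tr_calibration <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$rmsd, pts$tm, pch = 19,
                 xlab = expression(bar(RMSD)(T) ~ "(Å)"),
                 ylab = expression(T[m] ~ "(K)"), ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  graphics::text(pts$rmsd, pts$tm, pts$label, pos = 4, cex = 0.8)
  invisible(x)
}

#' Predict an i-motif melting temperature from its flexibility
#'
#' Applies a TR-plot calibration line to a temperature-averaged RMSD value.
#' Predictions outside the calibration's RMSD range are still returned but
#' flagged as extrapolations.
#'
#' @param rmsd_mean temperature-averaged RMSD in A (`>= 0`).
#' @param calibration a `tr_calibration`; defaults to
#'   [published_calibration()].
#' @return An object of class `tm_prediction`: `tm` (K, full precision),
#'   `tm_rounded` (nearest K), `rmsd_mean`, `extrapolated`, `calibration`.
#' @examples
#' predict_tm(2.1)  # ~331 K
#' @export
predict_tm <- function(rmsd_mean, calibration = published_calibration()) {
  stopifnot(is.numeric(rmsd_mean), length(rmsd_mean) == 1L, rmsd_mean >= 0)
  tm <- predict(calibration, rmsd_mean)
  rng <- range(calibration$points$rmsd)
  structure(
    list(
      tm = tm,
      tm_rounded = round(tm),
      rmsd_mean = rmsd_mean,
      extrapolated = rmsd_mean < rng[1] || rmsd_mean > rng[2],
      calibration = calibration
    ),
    class = "tm_prediction"
  )
}

#' @export
print.tm_prediction <- function(x, ...) {
  cat(sprintf("Predicted Tm: %d K (%.2f K) at RMSD(T) = %.2f A%s\n",
              x$tm_rounded, x$tm, x$rmsd_mean,
              if (x$extrapolated) "  [extrapolated beyond calibration range]"
              else ""))
  invisible(x)
}

#' Run the MD-TSPC4 thermal-stability prediction pipeline
#'
#' The full workflow: for each temperature's trajectory, compute the
#' whole-molecule best-fit RMSD series against the first frame, time-average
#' it, average those values across temperatures, and convert the resulting
#' flexibility statistic to a predicted melting temperature with a TR-plot
#' calibration. Per-region (core and loop) averages are tabulated alongside.
#'
#' @param trajectories named list of `md_trajectory` objects; names are the
#'   simulation temperatures in K (at least two required).
#' @param seq the `imotif_sequence` the trajectories represent.
#' @param calibration a `tr_calibration`; defaults to
#'   [published_calibration()].
#' @param burn_in ps discarded from the start of each series (default 0).
#' @param heavy_only restrict all statistics to heavy atoms (default `TRUE`).
#' @return An object of class `md_tspc4`: `rmsd_table` (one row per
#'   temperature with whole/core/loop time-averaged RMSDs), `rmsd_mean`
#'   (the across-temperature average for the whole molecule), `prediction`
#'   (a `tm_prediction`), plus the calibration and sequence.
#' @examples
#' seq <- parse_imotif("d[(CCCTAA)3CCC]", name = "CCCTA2")
#' ref <- toy_imotif_structure(seq)
#' trajs <- temperature_trajectory_set(ref, seq,
#'   target_rmsd = c(1.9, 1.9, 2.1, 2.5, 2.2), n_frames = 100, seed = 1)
#' run_md_tspc4(trajs, seq)
#' @export
run_md_tspc4 <- function(trajectories, seq,
                         calibration = published_calibration(),
                         burn_in = 0, heavy_only = TRUE) {
  stopifnot(is.list(trajectories), inherits(seq, "imotif_sequence"))
  temps <- suppressWarnings(as.numeric(names(trajectories)))
  if (length(trajectories) < 2L || length(temps) != length(trajectories) ||
      anyNA(temps)) {
    stop("trajectories must be a named list with >= 2 numeric temperatures (K)")
  }
  nat <- vapply(trajectories, n_atoms, integer(1))
  if (length(unique(nat)) != 1L) {
    stop("trajectories have inconsistent topologies (atom counts ",
         paste(unique(nat), collapse = ", "), ")")
  }
  regions <- assign_regions(seq)
  sel <- list(
    whole = select_atoms(trajectories[[1]], regions, region = "whole",
                         heavy_only = heavy_only),
    core = select_atoms(trajectories[[1]], regions, region = "core",
                        heavy_only = heavy_only),
    loop = select_atoms(trajectories[[1]], regions, region = "loop",
                        heavy_only = heavy_only)
  )
  rows <- lapply(seq_along(trajectories), function(i) {
    traj <- trajectories[[i]]
    avg <- vapply(sel, function(s) {
      time_average_rmsd(rmsd_series(traj, selection = s), burn_in = burn_in)
    }, numeric(1))
    data.frame(temperature = temps[i], whole = avg[["whole"]],
               core = avg[["core"]], loop = avg[["loop"]])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$temperature), ]
  rownames(tab) <- NULL
  rmsd_mean <- mean_rmsd_over_temperatures(tab$whole)
  structure(
    list(
      rmsd_table = tab,
      rmsd_mean = rmsd_mean,
      region_means = c(whole = rmsd_mean,
                       core = mean(tab$core), loop = mean(tab$loop)),
      prediction = predict_tm(rmsd_mean, calibration),
      calibration = calibration,
      sequence = seq
    ),
    class = "md_tspc4"
  )
}

#' @export
print.md_tspc4 <- function(x, ...) {
  cat("MD-TSPC4 thermal-stability prediction:", x$sequence$name, "\n\n")
  tab <- x$rmsd_table
  tab[-1] <- lapply(tab[-1], function(v) sprintf("%.1f", v))
  names(tab) <- c("T (K)", "whole (A)", "core (A)", "loop (A)")
  print(tab, row.names = FALSE)
  cat(sprintf("\n  RMSD(T) = %.1f A (whole i-motif, %d temperatures)\n",
              x$rmsd_mean, nrow(x$rmsd_table)))
  print(x$prediction)
  invisible(x)
}

#' Reference per-temperature RMSD table for the model i-motifs
#'
#' Time-averaged RMSD (A) of the whole i-motif, core and loop regions from
#' 200 ns simulations of the five model i-motifs (CCCT3/5/6/7 and CCCTA2) at
#' 280-360 K, as published for the MD-TSPC4 calibration study. Shipped as
#' plain CSV in `extdata` and used by the examples and the acceptance
#' analysis.
#'
#' @return Data frame with columns `model`, `region` (`whole`/`core`/`loop`),
#'   `temperature` (K) and `rmsd` (A).
#' @export
reference_rmsd_table <- function() {
  path <- system.file("extdata", "reference_rmsd.csv", package = "tspc4",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference melting data for the model i-motifs
#'
#' CD-derived melting temperatures and published temperature-averaged RMSDs
#' for the five model i-motifs. `role` distinguishes the three TR-plot
#' training sequences (CCCT3/5/7) from the two validation sequences
#' (CCCT6, CCCTA2); `tm` is the experimental CD value in K.
#'
#' @return Data frame with columns `model`, `rmsd` (A), `tm` (K), `role`.
#' @export
reference_tm_values <- function() {
  path <- system.file("extdata", "reference_tm.csv", package = "tspc4",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
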