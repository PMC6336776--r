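#' Electric-field estimation from laminar probe voltages
#'
#' During transcranial stimulation the probe contacts sit in a spatial
#' potential gradient: the per-contact Fourier amplitude at the stimulation
#' frequency increases linearly with depth, and the slope of that increase
#' along each contact column is the electric-field strength along the probe
#' axis. The per-column slopes are averaged into one field value per
#' recording site.
#'
#' @name field_estimation
NULL

#' Per-channel Fourier amplitudes at the stimulation frequency
#'
#' Fourier transforms the unfiltered voltage on each of the 32 contacts and
#' extracts the amplitude of the component at the stimulation frequency
#' (same amplitude convention as [fourier_amplitude_at()]).
#'
#' @param rec A `probe_recording`.
#' @param f Stimulation frequency in Hz; defaults to the recording's.
#' @return Numeric vector of 32 amplitudes (microvolt).
#' @export
channel_amplitudes <- function(rec, f = NULL) {
  stopifnot(inherits(rec, "probe_recording"))
  if (is.null(f)) f <- rec$stim_frequency
  apply(rec$voltages, 2, fourier_amplitude_at, fs = rec$fs, f = f)
}

#' Estimate electric-field strength from contact amplitudes
#'
#' For each contact column the least-squares slope of oscillation amplitude
#' (microvolt) against contact depth (micrometre) is the field strength in
#' V/m (uV/um = V/m); least squares equals finite differencing for
#' two-contact columns and is more noise-robust for longer ones. Column
#' magnitudes are averaged into one unsigned field value. Columns with a
#' single usable contact are skipped with a warning.
#'
#' @param amplitudes 32 per-channel amplitudes (microvolt), as from
#'   [channel_amplitudes()].
#' @param contacts Contact geometry data frame (`channel`, `column`,
#'   `depth_um`), as from [probe_geometry()].
#' @return A `field_estimate`: `per_column` (V/m, one per column), `mean`
#'   (V/m), `amplitudes`.
#' @export
estimate_field <- function(amplitudes, contacts = probe_geometry()) {
  stopifnot(length(amplitudes) == nrow(contacts))
  cols <- split(seq_len(nrow(contacts)), contacts$column)
  per_col <- vapply(cols, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, contacts$depth_um[idx]),
                         amplitudes[idx])
    abs(fit$coefficients[2])
  }, numeric(1))
  if (anyNA(per_col)) {
    warning("column with fewer than 2 contacts skipped", call. = FALSE)
    per_col <- per_col[!is.na(per_col)]
  }
  if (!length(per_col))
    stop("no column has at least 2 contacts", call. = FALSE)
  structure(list(per_column = unname(per_col), mean = mean(per_col),
                 amplitudes = amplitudes), class = "field_estimate")
}

#' Scale a measured field to another stimulation amplitude
#'
#' Field strength scales linearly with injected current, so a field
#' measured at one amplitude predicts the field at another by simple
#' proportion (e.g. 0.9 V/m at 0.1 mA implies 1.8 V/m at 0.2 mA).
#'
#' @param field Field strength (V/m) measured at `at_amplitude`.
#' @param at_amplitude Current amplitude (mA) of the measurement.
#' @param to_amplitude Current amplitude (mA) to predict for.
#' @return Predicted field strength in V/m.
#' @export
scale_field <- function(field, at_amplitude, to_amplitude) {
  check_positive(at_amplitude, "at_amplitude")
  field * to_amplitude / at_amplitude
}

#' Fixed-volume top-field voxel summary
#'
#' Mean field over the hot spot of a tissue: voxels are ranked from high to
#' low and the smallest set whose cumulative volume reaches
#' `target_volume` is averaged (the final voxel is included whole). This is
#' more robust than the single hottest voxel and, unlike a percentage-of-
#' tissue summary, comparable across tissues of different size.
#'
#' @param field A `voxel_field`, or a numeric vector of voxel values with
#'   `voxel_volume` supplied.
#' @param target_volume Target volume in mm^3 (default 10).
#' @param voxel_volume Volume per voxel in mm^3 (taken from `field` if it
#'   is a `voxel_field`).
#' @return Mean field (V/m) over the selected voxels.
#' @examples
#' top_volume_mean(10:1, target_volume = 2, voxel_volume = 1)  # 9.5
#' @export
top_volume_mean <- function(field, target_volume = 10, voxel_volume = NULL) {
  if (inherits(field, "voxel_field")) {
    values <- field$values
    voxel_volume <- field$voxel_volume
  } else values <- as.numeric(field)
  stopifnot(!is.null(voxel_volume))
  check_positive(target_volume, "target_volume")
  if (length(values) * voxel_volume < target_volume)
    stop("total voxel volume is smaller than target_volume", call. = FALSE)
  v <- sort(values, decreasing = TRUE)
  k <- ceiling(target_volume / voxel_volume)
  mean(v[seq_len(k)])
}

#' @export
print.field_estimate <- function(x, ...) {
  cat(sprintf("<field_estimate> mean %.4g V/m (columns: %s)\n", x$mean,
              paste(sprintf("%.4g", x$per_column), collapse = ", ")))
  invisible(x)
}
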