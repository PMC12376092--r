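#' Two-dimensional IR spectrum on a pump x probe grid
#'
#' Container for a 2D IR measurement: a matrix of Delta-OD values indexed by
#' pump frequency (rows) and probe frequency (columns).  The stored sign
#' convention is that fundamental (ground-state bleach / stimulated emission)
#' diagonal peaks are negative and the anharmonically red-shifted overtone
#' lobe is positive; magnitude operations downstream take absolute values
#' explicitly.
#'
#' @param pump_axis Strictly monotonic pump wavenumbers (cm^-1).
#' @param probe_axis Strictly monotonic probe wavenumbers (cm^-1).
#' @param delta_od Numeric matrix, `length(pump_axis)` x `length(probe_axis)`.
#' @param meta Named list of annotations.
#'
#' @return An object of class `grid2d_spectrum` with axes stored ascending
#'   (the matrix is reordered consistently).
#' @export
#' @examples
#' w <- seq(1620, 1660, 10)
#' m <- -outer(dnorm(w, 1640, 8), dnorm(w, 1640, 8))
#' grid2d_spectrum(w, w, m)
grid2d_spectrum <- function(pump_axis, probe_axis, delta_od, meta = list()) {
  pump_axis <- as.numeric(pump_axis)
  probe_axis <- as.numeric(probe_axis)
  if (!is.matrix(delta_od)) delta_od <- as.matrix(delta_od)
  storage.mode(delta_od) <- "double"
  check_axis <- function(a, what) {
    if (length(a) < 2L) stop(what, " axis needs at least 2 points")
    if (anyNA(a) || !all(is.finite(a))) stop(what, " axis must be finite")
    d <- diff(a)
    if (!all(d > 0) && !all(d < 0))
      stop(what, " axis must be strictly monotonic")
  }
  check_axis(pump_axis, "pump")
  check_axis(probe_axis, "probe")
  if (nrow(delta_od) != length(pump_axis) ||
      ncol(delta_od) != length(probe_axis))
    stop("delta_od must be length(pump_axis) x length(probe_axis); got ",
         nrow(delta_od), "x", ncol(delta_od))
  if (diff(pump_axis)[1] < 0) {
    pump_axis <- rev(pump_axis); delta_od <- delta_od[rev(seq_len(nrow(delta_od))), , drop = FALSE]
  }
  if (diff(probe_axis)[1] < 0) {
    probe_axis <- rev(probe_axis); delta_od <- delta_od[, rev(seq_len(ncol(delta_od))), drop = FALSE]
  }
  ov <- pump_axis[pump_axis >= min(probe_axis) - 1 &
                  pump_axis <= max(probe_axis) + 1]
  if (length(ov) == 0L)
    stop("pump and probe axes share no diagonal: no pump frequency lies ",
         "within 1 cm-1 of the probe range")
  structure(list(pump_axis = pump_axis, probe_axis = probe_axis,
                 delta_od = delta_od, meta = meta),
            class = "grid2d_spectrum")
}

#' @export
print.grid2d_spectrum <- function(x, ...) {
  cat(sprintf("<grid2d_spectrum %d pump x %d probe, pump %.5g..%.5g cm-1, probe %.5g..%.5g cm-1>\n",
              length(x$pump_axis), length(x$probe_axis),
              min(x$pump_axis), max(x$pump_axis),
              min(x$probe_axis), max(x$probe_axis)))
  invisible(x)
}

#' @export
dim.grid2d_spectrum <- function(x) dim(x$delta_od)
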