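#' Describe a whole-slide scanner
#'
#' A `scanner_profile` bundles the scan-time model, the slide-loading time,
#' the batch capacity, the acquisition geometry, and whether the scanner runs
#' its own (vendor) quality check during scanning.
#'
#' Two scan-time models are supported:
#' \describe{
#'   \item{`"poisson"`}{Scan duration is a Poisson draw (integer seconds)
#'     with mean `mean_scan_s`; the model used for batch-time simulations.}
#'   \item{`"area_rate"`}{Deterministic duration
#'     `rate_s_per_mm2 * effective area + overhead_s`, tying scan time to the
#'     area the scanner actually sweeps (which depends on `geometry`).}
#' }
#'
#' Geometry determines the effective scanned area from a slide's tissue
#' bounding boxes: a *line* scanner sweeps the (padded) boxes themselves; a
#' *tile* scanner captures every fixed-size tile whose footprint intersects a
#' padded box, so blank space inside partially covered tiles is scanned too.
#'
#' @param name Scanner name.
#' @param time_model `"poisson"` or `"area_rate"`.
#' @param mean_scan_s Mean scan duration in seconds (poisson model); > 0.
#' @param rate_s_per_mm2 Seconds per mm^2 of effective area (area_rate
#'   model); >= 0.
#' @param overhead_s Fixed per-scan overhead in seconds (area_rate model).
#' @param load_s Slide-loading time in seconds, charged per scan; >= 0.
#' @param capacity Slides the scanner holds per loaded batch; >= 1.
#' @param geometry `"line"` or `"tile"`.
#' @param tile_mm Tile side length in mm (tile geometry); > 0.
#' @param padding_mm Padding added around each tissue box on every side, mm.
#' @param internal_qc Logical: does the scanner run a vendor quality check
#'   that can trigger an automatic in-scanner rescan? When `FALSE` the
#'   workflow's first QC stage is skipped (external-QC-only deployment).
#'
#' @return An object of class `"scanner_profile"`.
#' @examples
#' scanner_profile("bench", mean_scan_s = 60, load_s = 10, capacity = 360)
#' @export
scanner_profile <- function(name = "scanner",
                            time_model = c("poisson", "area_rate"),
                            mean_scan_s = 60, rate_s_per_mm2 = 0.25,
                            overhead_s = 0, load_s = 10, capacity = 100,
                            geometry = c("line", "tile"), tile_mm = 1,
                            padding_mm = 0, internal_qc = TRUE) {
  time_model <- match.arg(time_model)
  geometry <- match.arg(geometry)
  if (time_model == "poisson" && (!is.finite(mean_scan_s) || mean_scan_s <= 0))
    stop("poisson time model requires mean_scan_s > 0")
  if (time_model == "area_rate" &&
      (!is.finite(rate_s_per_mm2) || rate_s_per_mm2 < 0))
    stop("area_rate time model requires rate_s_per_mm2 >= 0")
  if (overhead_s < 0) stop("overhead_s must be >= 0")
  if (load_s < 0) stop("load_s must be >= 0")
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L) stop("capacity must be >= 1")
  if (tile_mm <= 0) stop("tile_mm must be > 0")
  if (padding_mm < 0) stop("padding_mm must be >= 0")
  structure(
    list(name = as.character(name), time_model = time_model,
         mean_scan_s = as.numeric(mean_scan_s),
         rate_s_per_mm2 = as.numeric(rate_s_per_mm2),
         overhead_s = as.numeric(overhead_s), load_s = as.numeric(load_s),
         capacity = capacity, geometry = geometry,
         tile_mm = as.numeric(tile_mm), padding_mm = as.numeric(padding_mm),
         internal_qc = isTRUE(internal_qc)),
    class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  tm <- if (x$time_model == "poisson")
    sprintf("Poisson(mean %.0f s)", x$mean_scan_s)
  else
    sprintf("%.3g s/mm^2 + %.3g s", x$rate_s_per_mm2, x$overhead_s)
  cat(sprintf("<scanner_profile> %s: %s, load %.0f s, capacity %d, %s geometry, internal QC %s\n",
              x$name, tm, x$load_s, x$capacity, x$geometry,
              if (x$internal_qc) "on" else "off"))
  invisible(x)
}
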