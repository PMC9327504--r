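#' Normalized scan time (seconds per 15 x 15 mm of tissue)
#'
#' Rescales a measured scan duration to the time it would have taken to scan
#' the standard 15 x 15 mm (225 mm^2) reference area:
#' `scan_time_s / tissue_area_mm2 * 225`. This removes tissue size from
#' scanner comparisons, since manufacturers quote the "15 x 15 scan speed"
#' while real slides carry anywhere from tens to hundreds of mm^2 of tissue.
#' Scale-invariant: doubling both inputs leaves the result unchanged.
#' Vectorised.
#'
#' @param scan_time_s Measured scan duration(s), seconds; > 0.
#' @param tissue_area_mm2 Tissue (or scanned) area(s), mm^2; > 0.
#' @return Normalized time(s) in seconds per 225 mm^2.
#' @examples
#' normalized_scan_time(66, 479.4)  # ~31 s: a fast line scanner on a resection
#' @export
normalized_scan_time <- function(scan_time_s, tissue_area_mm2) {
  scan_time_s <- as.numeric(scan_time_s)
  tissue_area_mm2 <- as.numeric(tissue_area_mm2)
  if (any(!is.finite(scan_time_s)) || any(scan_time_s <= 0))
    stop("scan_time_s must be positive")
  if (any(!is.finite(tissue_area_mm2)) || any(tissue_area_mm2 <= 0))
    stop("tissue_area_mm2 must be positive")
  scan_time_s / tissue_area_mm2 * 225
}

#' Effective scanned area under a scanner's acquisition geometry
#'
#' Computes the area a scanner actually sweeps for a slide, from the slide's
#' tissue bounding boxes and the profile's geometry:
#' \describe{
#'   \item{line}{The scanner sweeps the bounding boxes themselves; effective
#'     area is the sum of box areas after expanding each box by `padding_mm`
#'     on every side.}
#'   \item{tile}{The scanner captures fixed tiles of side `tile_mm` on a grid
#'     anchored at the slide origin (tiles are half-open
#'     `[i*s, (i+1)*s)`); every tile whose footprint overlaps a padded box
#'     (with positive area) is scanned. Effective area is the tile count
#'     times `tile_mm^2`, so blank space inside partially covered tiles is
#'     charged, while blank space *between* distant boxes is not.}
#' }
#'
#' @param slide A [slide_spec()] with `tissue_boxes` present.
#' @param profile A [scanner_profile()].
#' @return Effective area in mm^2 (> 0).
#' @examples
#' s <- slide_spec("S1", "biopsy", 80,
#'                 tissue_boxes = data.frame(x = 2, y = 5, w = 10, h = 10))
#' effective_scan_area(s, scanner_profile(geometry = "line"))
#' @export
effective_scan_area <- function(slide, profile) {
  boxes <- slide$tissue_boxes
  if (is.null(boxes))
    stop("slide '", slide$slide_id,
         "' has no tissue_boxes; effective_scan_area requires bounding boxes")
  p <- profile$padding_mm
  if (profile$geometry == "line")
    return(sum((boxes$w + 2 * p) * (boxes$h + 2 * p)))
  s <- profile$tile_mm
  tiles <- lapply(seq_len(nrow(boxes)), function(i) {
    x1 <- boxes$x[i] - p; x2 <- boxes$x[i] + boxes$w[i] + p
    y1 <- boxes$y[i] - p; y2 <- boxes$y[i] + boxes$h[i] + p
    ix <- seq.int(floor(x1 / s), ceiling(x2 / s) - 1)
    iy <- seq.int(floor(y1 / s), ceiling(y2 / s) - 1)
    # keep only tiles overlapping the padded box with positive measure
    ix <- ix[ix * s < x2 & (ix + 1) * s > x1]
    iy <- iy[iy * s < y2 & (iy + 1) * s > y1]
    expand.grid(ix = ix, iy = iy)
  })
  tiles <- unique(do.call(rbind, tiles))
  nrow(tiles) * s^2
}

# internal constructor for a single scan event
scan_event <- function(attempt, duration_s, load_s, stringent) {
  data.frame(attempt = as.integer(attempt), duration_s = as.numeric(duration_s),
             load_s = as.numeric(load_s), stringent = as.logical(stringent))
}

# internal: vector of first-scan durations under a profile's time model.
# areas: effective areas (area_rate model only).
draw_durations <- function(profile, n, areas = NULL) {
  if (profile$time_model == "poisson") {
    # clamp at 1 s so durations stay positive (Poisson mass at 0 is
    # negligible at operational means but nonzero)
    pmax(stats::rpois(n, profile$mean_scan_s), 1)
  } else {
    if (is.null(areas)) stop("area_rate model needs per-slide areas")
    rep_len(profile$rate_s_per_mm2 * areas + profile$overhead_s, n)
  }
}

# internal: the area the time model charges for a slide (effective geometry
# area when boxes are present, otherwise the recorded tissue area)
charged_area <- function(slide, profile) {
  if (!is.null(slide$tissue_boxes)) effective_scan_area(slide, profile)
  else slide$tissue_area_mm2
}

#' Draw one scan event for a slide
#'
#' Generates the first-attempt scan event for a slide under a profile's
#' scan-time model. Under the `"poisson"` model the duration is an
#' integer-second Poisson draw with mean `mean_scan_s` (floored at 1 s).
#' Under the `"area_rate"` model the duration is deterministic,
#' `rate_s_per_mm2 * area + overhead_s`, where the area is the geometry's
#' [effective_scan_area()] when the slide carries tissue boxes and the
#' recorded tissue area otherwise. Draws come from R's global random number
#' stream, so `set.seed()` makes them reproducible.
#'
#' @param profile A [scanner_profile()].
#' @param slide A [slide_spec()].
#' @return A one-row scan-event `data.frame` with columns `attempt`,
#'   `duration_s`, `load_s`, `stringent`.
#' @export
draw_scan_time <- function(profile, slide) {
  areas <- if (profile$time_model == "area_rate") charged_area(slide, profile)
  scan_event(1L, draw_durations(profile, 1L, areas), profile$load_s, FALSE)
}
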