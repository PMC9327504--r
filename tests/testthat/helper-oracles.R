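# Independent oracles for the closed forms and geometry, written against the
# defining integrals/rasters rather than the package's implementations.

# adaptive quadrature of the defining integral of the missed-slide fraction:
# P(q < cutoff and q + e >= threshold), q ~ U(0,1), e ~ N(0, sigma^2)
quad_missed <- function(sigma, threshold, cutoff) {
  if (cutoff == 0) return(0)
  stats::integrate(function(q) stats::pnorm((q - threshold) / sigma),
                   0, cutoff, rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# quadrature of the flagged fraction P(q + e < threshold)
quad_flagged <- function(sigma, threshold) {
  stats::integrate(function(q) stats::pnorm((threshold - q) / sigma),
                   0, 1, rel.tol = 1e-13, abs.tol = 1e-13)$value
}

# brute-force rasterization of the area covered by a union of boxes, on a
# grid of `res` mm cells; exact when box coordinates are multiples of res
raster_union_area <- function(boxes, res = 0.1) {
  x2 <- boxes$x + boxes$w
  y2 <- boxes$y + boxes$h
  xs <- seq(min(boxes$x) + res / 2, max(x2), by = res)
  ys <- seq(min(boxes$y) + res / 2, max(y2), by = res)
  covered <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_len(nrow(boxes))) {
    covered[xs > boxes$x[i] & xs < x2[i], ys > boxes$y[i] & ys < y2[i]] <- TRUE
  }
  sum(covered) * res^2
}

# area of the single bounding box enclosing all boxes
union_bbox_area <- function(boxes) {
  (max(boxes$x + boxes$w) - min(boxes$x)) *
    (max(boxes$y + boxes$h) - min(boxes$y))
}

# random box set on a 0.1 mm coordinate grid
random_boxes <- function(n_boxes, dim_range = c(2, 15), coord_max = 40) {
  rnd <- function(lo, hi, k) round(stats::runif(k, lo, hi), 1)
  data.frame(x = rnd(0, coord_max, n_boxes), y = rnd(0, coord_max, n_boxes),
             w = rnd(dim_range[1], dim_range[2], n_boxes),
             h = rnd(dim_range[1], dim_range[2], n_boxes))
}

box_slide <- function(boxes, area = NULL) {
  slide_spec("geom", "resection",
             area %||% max(0.5, 0.5 * sum(boxes$w * boxes$h)),
             tissue_boxes = boxes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random-but-valid QC policy for property sweeps
random_policy <- function() {
  qc_policy(
    auto_rescan_rate = stats::runif(1),
    rescan_multiplier = stats::runif(1, 1, 4),
    rescan_includes_load = stats::runif(1) < 0.5,
    rescan_time_mode = sample(c("scaled_original", "fresh_draw_scaled"), 1),
    quality = quality_model(sigma = stats::runif(1, 0, 0.3),
                            threshold = stats::runif(1, -0.2, 1.2),
                            bad_cutoff = stats::runif(1, 0, 0.3)),
    visual_accept_prob = stats::runif(1),
    control_rate = stats::runif(1, 0, 0.3),
    max_rescans = sample(0:3, 1))
}
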