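#' Specification for the synthetic-manifest generator
#'
#' Defines the population a synthetic slide manifest is drawn from. Slide
#' classes are sampled from `class_mix`; tissue areas are log-uniform within
#' per-class bounds whose defaults span the per-class area ranges of the
#' bundled scanner benchmark ([scanner_timings()]): resections 439.6-777
#' mm^2, biopsies 67.2-425.2 mm^2, IHC 34.6-897.7 mm^2. Latent true
#' qualities are uniform on `[0, 1]` (set `quality = "none"` to leave them
#' to be drawn at simulation time). Each slide receives 1-3 tissue bounding
#' boxes consistent with its area (boxes bound tissue loosely, total box
#' area exceeds tissue area).
#'
#' @param n_slides Number of slides to generate (0 gives an empty manifest).
#' @param class_mix Named proportions over `resection`, `biopsy`, `ihc`;
#'   must sum to 1.
#' @param area_bounds Named list of `c(lo, hi)` log-uniform bounds (mm^2)
#'   per class; bounds must be positive and ordered.
#' @param quality `"uniform"` (draw now) or `"none"` (leave unset).
#' @param seed Optional integer seed.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_slides,
                           class_mix = c(resection = 1/3, biopsy = 1/3,
                                         ihc = 1/3),
                           area_bounds = list(
                             resection = c(439.6, 777),
                             biopsy = c(67.2, 425.2),
                             ihc = c(34.6, 897.7)),
                           quality = c("uniform", "none"), seed = NULL) {
  quality <- match.arg(quality)
  n_slides <- as.integer(n_slides)
  if (is.na(n_slides) || n_slides < 0L) stop("n_slides must be >= 0")
  if (!setequal(names(class_mix), SLIDE_CLASSES))
    stop("class_mix must be named over ", paste(SLIDE_CLASSES, collapse = ", "))
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must be nonnegative and sum to 1")
  for (cl in SLIDE_CLASSES) {
    b <- area_bounds[[cl]]
    if (is.null(b) || length(b) != 2L || any(b <= 0) || b[1] > b[2])
      stop("area_bounds$", cl, " must be positive ordered bounds c(lo, hi)")
  }
  structure(list(n_slides = n_slides, class_mix = class_mix[SLIDE_CLASSES],
                 area_bounds = area_bounds, quality = quality, seed = seed),
            class = "generator_spec")
}

#' Generate a synthetic slide manifest
#'
#' Draws a manifest of synthetic slides from a [generator_spec()]:
#' deterministic for a fixed seed, with per-class log-uniform tissue areas,
#' 1-3 tissue bounding boxes per slide, and (by default) uniform latent
#' qualities.
#'
#' @param spec A [generator_spec()].
#' @return A manifest `data.frame` (class `"wsi_manifest"`) with columns
#'   `slide_id`, `slide_class`, `tissue_area_mm2`, `boxes`, `true_quality`.
#' @examples
#' generate_manifest(generator_spec(n_slides = 3, seed = 7))
#' @export
generate_manifest <- function(spec) {
  if (!inherits(spec, "generator_spec")) stop("spec must be a generator_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_slides
  empty <- data.frame(slide_id = character(), slide_class = character(),
                      tissue_area_mm2 = numeric(), boxes = character(),
                      true_quality = numeric())
  class(empty) <- c("wsi_manifest", "data.frame")
  if (n == 0L) return(empty)
  cls <- sample(SLIDE_CLASSES, n, replace = TRUE, prob = spec$class_mix)
  lo <- vapply(spec$area_bounds[cls], `[`, numeric(1), 1L)
  hi <- vapply(spec$area_bounds[cls], `[`, numeric(1), 2L)
  area <- exp(stats::runif(n, log(lo), log(hi)))
  boxes <- vapply(area, function(a) format_boxes(draw_boxes(a)), character(1))
  q <- if (spec$quality == "uniform") stats::runif(n) else rep(NA_real_, n)
  d <- data.frame(slide_id = sprintf("S%04d", seq_len(n)), slide_class = cls,
                  tissue_area_mm2 = area, boxes = boxes, true_quality = q)
  class(d) <- c("wsi_manifest", "data.frame")
  d
}

# 1-3 non-overlapping boxes bounding `area` mm^2 of tissue, stacked down a
# 25 x 55 mm scan region; boxes are looser than the tissue (fill ~70%)
draw_boxes <- function(area) {
  k <- sample.int(3L, 1L)
  shares <- stats::runif(k, 0.5, 1.5)
  shares <- shares / sum(shares)
  box_area <- pmin(area * shares / 0.7, 25 * 50 / k)
  aspect <- stats::runif(k, 0.5, 2)
  w <- pmin(sqrt(box_area * aspect), 24)
  h <- box_area / w
  x <- stats::runif(k, 0.5, pmax(0.51, 25 - w - 0.5))
  gap <- stats::runif(k, 0.5, 2)
  y <- cumsum(c(2, (h + gap)[-k]))
  data.frame(x = x, y = y, w = w, h = h)
}
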