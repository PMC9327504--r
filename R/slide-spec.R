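#' Slide classes recognised by the simulator
#'
#' @format Character vector of the three histology slide classes used
#'   throughout: H&E-stained resections, H&E-stained biopsies, and
#'   immunohistochemistry (IHC) slides.
#' @export
SLIDE_CLASSES <- c("resection", "biopsy", "ihc")

#' Describe a physical slide
#'
#' A `slide_spec` captures the slide-level metadata the simulator operates on:
#' an identifier, the slide class, the tissue area, optionally the axis-aligned
#' bounding boxes enclosing the tissue (used by the scan-area geometry), and
#' optionally a latent true image quality in `[0, 1]`. When `true_quality` is
#' absent it is drawn uniformly on `[0, 1]` at simulation time, the prior used
#' for the quality-threshold analyses.
#'
#' @param slide_id Opaque identifier (coerced to character).
#' @param slide_class One of `"resection"`, `"biopsy"`, `"ihc"`.
#' @param tissue_area_mm2 Tissue area in mm^2; must be positive.
#' @param tissue_boxes Optional `data.frame` with columns `x`, `y`, `w`, `h`
#'   (mm): axis-aligned rectangles bounding the tissue. Boxes bound tissue, so
#'   their total area may exceed the tissue area; every box must have positive
#'   width and height.
#' @param true_quality Optional latent quality in `[0, 1]`; `NA` means
#'   "draw at simulation time".
#'
#' @return An object of class `"slide_spec"`.
#' @examples
#' slide_spec("S1", "biopsy", 150,
#'            tissue_boxes = data.frame(x = 5, y = 10, w = 10, h = 20))
#' @export
slide_spec <- function(slide_id, slide_class, tissue_area_mm2,
                       tissue_boxes = NULL, true_quality = NA_real_) {
  slide_class <- match.arg(slide_class, SLIDE_CLASSES)
  tissue_area_mm2 <- as.numeric(tissue_area_mm2)
  if (!is.finite(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be a positive number, got ", tissue_area_mm2)
  if (!is.null(tissue_boxes)) {
    tissue_boxes <- as.data.frame(tissue_boxes)
    req <- c("x", "y", "w", "h")
    if (!all(req %in% names(tissue_boxes)))
      stop("tissue_boxes must have columns x, y, w, h")
    tissue_boxes <- tissue_boxes[req]
    if (nrow(tissue_boxes) == 0L) tissue_boxes <- NULL
    else if (any(tissue_boxes$w <= 0 | tissue_boxes$h <= 0))
      stop("every tissue box must have positive width and height")
  }
  true_quality <- as.numeric(true_quality)
  if (!is.na(true_quality) && (true_quality < 0 || true_quality > 1))
    stop("true_quality must lie in [0, 1], got ", true_quality)
  structure(
    list(slide_id = as.character(slide_id), slide_class = slide_class,
         tissue_area_mm2 = tissue_area_mm2, tissue_boxes = tissue_boxes,
         true_quality = true_quality),
    class = "slide_spec")
}

#' @export
print.slide_spec <- function(x, ...) {
  cat(sprintf("<slide_spec> %s [%s], %.1f mm^2 tissue", x$slide_id,
              x$slide_class, x$tissue_area_mm2))
  if (!is.null(x$tissue_boxes))
    cat(sprintf(", %d box(es)", nrow(x$tissue_boxes)))
  if (!is.na(x$true_quality))
    cat(sprintf(", true quality %.3f", x$true_quality))
  cat("\n")
  invisible(x)
}

# internal: coerce a list of slide_spec (or a manifest data.frame) to a list
# of slide_spec objects
as_slide_list <- function(slides) {
  if (inherits(slides, "slide_spec")) return(list(slides))
  if (is.data.frame(slides)) return(manifest_to_slides(slides))
  if (!is.list(slides) || !all(vapply(slides, inherits, TRUE, "slide_spec")))
    stop("slides must be a slide_spec, a list of slide_spec, or a manifest data.frame")
  slides
}
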