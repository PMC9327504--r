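#' Read a slide manifest
#'
#' Reads a comma-separated slide manifest with a header row and columns
#' `slide_id`, `slide_class`, `tissue_area_mm2`, and optionally `boxes`
#' (semicolon-separated `x:y:w:h` quadruples, mm) and `true_quality`.
#' Malformed rows are rejected with an error naming the offending file line
#' (header = line 1).
#'
#' @param path Path to the manifest file.
#' @return A manifest `data.frame` (class `"wsi_manifest"`); convert to slide
#'   objects with [manifest_to_slides()] or pass directly to the simulation
#'   functions.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  req <- c("slide_id", "slide_class", "tissue_area_mm2")
  if (!all(req %in% names(d)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  for (i in seq_len(nrow(d))) {
    line <- i + 1L
    if (!d$slide_class[i] %in% SLIDE_CLASSES)
      stop(sprintf("line %d: unknown slide_class '%s' (expected %s)", line,
                   d$slide_class[i], paste(SLIDE_CLASSES, collapse = "/")))
    a <- suppressWarnings(as.numeric(d$tissue_area_mm2[i]))
    if (!is.finite(a) || a <= 0)
      stop(sprintf("line %d: tissue_area_mm2 must be a positive number, got '%s'",
                   line, d$tissue_area_mm2[i]))
    if ("true_quality" %in% names(d) && nzchar(d$true_quality[i]) &&
        !is.na(d$true_quality[i])) {
      q <- suppressWarnings(as.numeric(d$true_quality[i]))
      if (!is.finite(q) || q < 0 || q > 1)
        stop(sprintf("line %d: true_quality must lie in [0, 1], got '%s'",
                     line, d$true_quality[i]))
    }
    if ("boxes" %in% names(d) && nzchar(d$boxes[i]) && !is.na(d$boxes[i])) {
      b <- tryCatch(parse_boxes(d$boxes[i]), error = function(e)
        stop(sprintf("line %d: %s", line, conditionMessage(e)), call. = FALSE))
    }
  }
  d$tissue_area_mm2 <- as.numeric(d$tissue_area_mm2)
  if (!"boxes" %in% names(d)) d$boxes <- NA_character_
  d$boxes[!nzchar(d$boxes) | is.na(d$boxes)] <- NA_character_
  if (!"true_quality" %in% names(d)) d$true_quality <- NA_character_
  d$true_quality[!nzchar(d$true_quality)] <- NA_character_
  d$true_quality <- as.numeric(d$true_quality)
  d <- d[c("slide_id", "slide_class", "tissue_area_mm2", "boxes",
           "true_quality")]
  class(d) <- c("wsi_manifest", "data.frame")
  d
}

# "x:y:w:h;x:y:w:h" -> data.frame(x, y, w, h)
parse_boxes <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("malformed boxes field '", s, "' (expected x:y:w:h quadruples)")
  m <- suppressWarnings(vapply(parts, as.numeric, numeric(4)))
  if (any(!is.finite(m))) stop("non-numeric value in boxes field '", s, "'")
  b <- as.data.frame(t(m))
  names(b) <- c("x", "y", "w", "h")
  if (any(b$w <= 0 | b$h <= 0))
    stop("boxes must have positive width and height in '", s, "'")
  b
}

format_boxes <- function(b) {
  if (is.null(b)) return(NA_character_)
  paste(sprintf("%g:%g:%g:%g", b$x, b$y, b$w, b$h), collapse = ";")
}

#' Convert between manifests and slide objects
#'
#' @param manifest A manifest `data.frame` as returned by [read_manifest()]
#'   or [generate_manifest()].
#' @return `manifest_to_slides()`: a list of [slide_spec()];
#'   `slides_to_manifest()`: a manifest `data.frame`.
#' @export
manifest_to_slides <- function(manifest) {
  if (!"boxes" %in% names(manifest)) manifest$boxes <- NA_character_
  if (!"true_quality" %in% names(manifest))
    manifest$true_quality <- NA_real_
  lapply(seq_len(nrow(manifest)), function(i) {
    b <- manifest$boxes[i]
    slide_spec(manifest$slide_id[i], manifest$slide_class[i],
               manifest$tissue_area_mm2[i],
               tissue_boxes = if (!is.na(b)) parse_boxes(b),
               true_quality = manifest$true_quality[i])
  })
}

#' @rdname manifest_to_slides
#' @param slides A list of [slide_spec()].
#' @export
slides_to_manifest <- function(slides) {
  slides <- as_slide_list(slides)
  d <- data.frame(
    slide_id = vapply(slides, function(s) s$slide_id, character(1)),
    slide_class = vapply(slides, function(s) s$slide_class, character(1)),
    tissue_area_mm2 = vapply(slides, function(s) s$tissue_area_mm2,
                             numeric(1)),
    boxes = vapply(slides, function(s) format_boxes(s$tissue_boxes),
                   character(1)),
    true_quality = vapply(slides, function(s) s$true_quality, numeric(1)))
  class(d) <- c("wsi_manifest", "data.frame")
  d
}

#' Write a slide manifest
#'
#' Writes a manifest in the same comma-separated format [read_manifest()]
#' reads; writing and re-reading reproduces the manifest field for field.
#'
#' @param manifest A manifest `data.frame` or list of [slide_spec()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (!is.data.frame(manifest)) manifest <- slides_to_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write simulation results as comma-separated tables
#'
#' Writes the per-slide table of a [simulate_batch()] result (one row per
#' slide), the per-cell summary and per-replicate tables of a sweep, the
#' per-scanner table of a fleet report, or any plain `data.frame`. All
#' outputs are headered CSV readable with [utils::read.csv()].
#'
#' @param x A `batch_result`, `sweep_result`, `fleet_report`, or
#'   `data.frame`.
#' @param path Destination path for the primary table.
#' @param summary_path Optional second path: the one-row batch summary
#'   (batch results) or the per-replicate table (sweeps).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, summary_path = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.batch_result <- function(x, path, summary_path = NULL) {
  if (is.null(x$slides))
    stop("batch_result has no per-slide table (keep_slides = FALSE)")
  utils::write.csv(x$slides, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- as.data.frame(x[c("n_slides", "total_time_s", "relative_time",
                           "n_rescans", "n_visual_reviews",
                           "n_control_reviews", "n_accepted", "n_rejected",
                           "missed_fraction_observed")])
    utils::write.csv(s, summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_results.sweep_result <- function(x, path, summary_path = NULL) {
  utils::write.csv(x$summary, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(x$replicates, summary_path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.fleet_report <- function(x, path, summary_path = NULL) {
  d <- x$scanners
  d$makespan_s <- x$makespan_s
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.data.frame <- function(x, path, summary_path = NULL) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' Reads a YAML configuration with optional sections `scanner`, `quality`,
#' `policy`, and `fleet`, and assembles the corresponding objects. Keys
#' within each section are the constructor arguments of
#' [scanner_profile()], [quality_model()] and [qc_policy()]; the `quality`
#' section is attached to the policy. The `fleet` section may define
#' `daily_load` and a list `scanners` of additional profile sections.
#'
#' @param path Path to the YAML file.
#' @return List with `profile`, `policy`, `fleet` (list with `daily_load`
#'   and `profiles`), and `raw` (the parsed YAML).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  profile <- do.call(scanner_profile, as.list(cfg$scanner %||% list()))
  quality <- do.call(quality_model, as.list(cfg$quality %||% list()))
  pol_args <- as.list(cfg$policy %||% list())
  pol_args$quality <- quality
  policy <- do.call(qc_policy, pol_args)
  fleet <- NULL
  if (!is.null(cfg$fleet)) {
    profs <- lapply(cfg$fleet$scanners %||% list(),
                    function(s) do.call(scanner_profile, as.list(s)))
    if (length(profs) == 0L) profs <- list(profile)
    fleet <- list(daily_load = cfg$fleet$daily_load, profiles = profs)
  }
  list(profile = profile, policy = policy, fleet = fleet, raw = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
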