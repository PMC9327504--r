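#' Bundled scanner benchmark: nine slides on four commercial scanners
#'
#' Measured scan times and scanned areas for a benchmark set of nine slides
#' — three H&E-stained resections, three H&E-stained biopsies, and three
#' immunohistochemistry (IHC) slides chosen to span a range of tissue
#' geometries — each scanned on four commercial whole-slide scanners
#' (anonymised A-D). The `printed_norm_time` column carries the normalized
#' scan time (seconds per 15 x 15 mm, see [normalized_scan_time()]) as
#' published with the benchmark, rounded to one decimal; recomputing it from
#' the scan time and area reproduces every value to within +/- 0.5 (the
#' areas themselves were rounded before publication).
#'
#' @return `data.frame` with columns `scanner`, `slide`, `slide_class`,
#'   `scan_time_s`, `size_mm2`, `printed_norm_time` (36 rows), and an
#'   attribute `capacities` giving each scanner's batch capacity in slides.
#' @examples
#' tt <- scanner_timings()
#' max(abs(normalized_scan_time(tt$scan_time_s, tt$size_mm2) -
#'         tt$printed_norm_time))
#' @export
scanner_timings <- function() {
  path <- system.file("extdata", "scanner_timings.csv", package = "wsisim",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(d, "capacities") <- c(A = 360L, B = 6L, C = 210L, D = 100L)
  d
}
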