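#' Quality-control policy for the scanning workflow
#'
#' Parameters of the multi-stage QC workflow: an in-scanner vendor quality
#' check that triggers an automatic stringent rescan; an external automated QC
#' algorithm (the noisy threshold classifier in `quality`) that diverts
#' flagged slides to visual review; and random control sampling of passed
#' slides. A stringent rescan takes `rescan_multiplier` times as long as an
#' ordinary scan, and at most `max_rescans` rescans are attempted per slide —
#' a flagged slide whose rescans are exhausted and whose visual review
#' declines it is rejected outright.
#'
#' @param auto_rescan_rate Probability that the in-scanner quality check
#'   rejects a first scan and triggers an automatic stringent rescan. Treated
#'   as a free Bernoulli rate, independent of the slide's true quality.
#' @param rescan_multiplier Stringent-profile slowdown factor; >= 1.
#' @param rescan_includes_load Is the slide-loading time charged again on a
#'   rescan? Default `TRUE` (loading is charged per scan); set `FALSE` for
#'   rescans performed while the slide is still on the stage.
#' @param rescan_time_mode `"scaled_original"` (rescan duration =
#'   multiplier x this slide's original duration) or `"fresh_draw_scaled"`
#'   (multiplier x a fresh draw from the scan-time model).
#' @param quality A [quality_model()]: the external automated QC stage.
#' @param visual_accept_prob Probability that visual review accepts a flagged
#'   slide; otherwise the slide is rescanned if attempts remain, else
#'   rejected.
#' @param control_rate Fraction of QC-passed slides sampled for visual review
#'   as a control on the automated algorithm.
#' @param max_rescans Maximum rescans per slide (default 1: one rescan, then
#'   no further rescanning).
#'
#' @return An object of class `"qc_policy"`.
#' @export
qc_policy <- function(auto_rescan_rate = 0.05, rescan_multiplier = 2,
                      rescan_includes_load = TRUE,
                      rescan_time_mode = c("scaled_original",
                                           "fresh_draw_scaled"),
                      quality = quality_model(),
                      visual_accept_prob = 0.5, control_rate = 0.05,
                      max_rescans = 1L) {
  rescan_time_mode <- match.arg(rescan_time_mode)
  for (p in c(auto_rescan_rate = auto_rescan_rate,
              visual_accept_prob = visual_accept_prob,
              control_rate = control_rate)) {
    if (!is.finite(p) || p < 0 || p > 1)
      stop("probabilities in qc_policy must lie in [0, 1]")
  }
  if (!is.finite(rescan_multiplier) || rescan_multiplier < 1)
    stop("rescan_multiplier must be >= 1")
  max_rescans <- as.integer(max_rescans)
  if (is.na(max_rescans) || max_rescans < 0L)
    stop("max_rescans must be >= 0")
  if (!inherits(quality, "quality_model"))
    stop("quality must be a quality_model")
  structure(
    list(auto_rescan_rate = as.numeric(auto_rescan_rate),
         rescan_multiplier = as.numeric(rescan_multiplier),
         rescan_includes_load = isTRUE(rescan_includes_load),
         rescan_time_mode = rescan_time_mode, quality = quality,
         visual_accept_prob = as.numeric(visual_accept_prob),
         control_rate = as.numeric(control_rate), max_rescans = max_rescans),
    class = "qc_policy")
}

#' @export
print.qc_policy <- function(x, ...) {
  cat(sprintf("<qc_policy> auto-rescan %.3f, multiplier %.2g (%s%s), max rescans %d\n",
              x$auto_rescan_rate, x$rescan_multiplier, x$rescan_time_mode,
              if (x$rescan_includes_load) ", load charged" else "",
              x$max_rescans))
  cat(sprintf("  external QC: sigma %g, threshold %g; visual accept %.2f, control rate %.2f\n",
              x$quality$sigma, x$quality$threshold, x$visual_accept_prob,
              x$control_rate))
  invisible(x)
}

# a policy with every stochastic QC branch switched off: slides pass straight
# through with a single scan
passthrough_policy <- function() {
  qc_policy(auto_rescan_rate = 0, rescan_multiplier = 1,
            quality = quality_model(sigma = 0, threshold = -Inf),
            visual_accept_prob = 1, control_rate = 0)
}
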