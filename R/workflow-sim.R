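#' @name workflow
#' @title Monte-Carlo engine for the AI-enabled QC scanning workflow
#'
#' @description
#' The workflow a slide traverses is:
#' \enumerate{
#'   \item First scan (duration from the profile's scan-time model, plus
#'     slide-loading time).
#'   \item In-scanner vendor QC: with probability `auto_rescan_rate` the scan
#'     fails and the slide is immediately rescanned under a more stringent
#'     profile, taking `rescan_multiplier` times as long (loading charged
#'     again only if `rescan_includes_load`). Skipped when the profile has
#'     `internal_qc = FALSE` or no rescan attempts remain.
#'   \item External automated QC: a noisy score of the slide's true quality
#'     is thresholded ([observe_quality()], [decide_rescan()]). Flagged
#'     slides go to visual review, which accepts with probability
#'     `visual_accept_prob`; a declined slide is rescanned once more if
#'     attempts remain and otherwise rejected without further rescanning.
#'   \item Unflagged slides are accepted; a fraction `control_rate` of them
#'     is additionally reviewed visually as a control, and a control review
#'     that lands on a truly bad slide catches it (the slide is rejected and
#'     not counted as missed).
#' }
#' A slide is *missed* when it is truly bad (`true_quality < bad_cutoff`) yet
#' reaches the repository without any human ever seeing it.
#'
#' All draws come from R's global random stream in a fixed documented order
#' (first-scan durations, auto-rescan coins, stringent durations, missing
#' true qualities, observation noise, visual-review coins, visual-rescan
#' durations, control coins), so a `seed` makes every run bit-reproducible.
NULL

# vectorised workflow kernel: simulates n slides and returns one row each.
# q_true may contain NA (drawn uniform at simulation time). areas are the
# charged areas for the area_rate time model (ignored under poisson).
qc_kernel <- function(n, profile, policy, q_true = NULL, areas = NULL) {
  qm <- policy$quality
  mult <- policy$rescan_multiplier

  # (1) first scans
  dur1 <- draw_durations(profile, n, areas)
  load1 <- rep(profile$load_s, n)
  rescans <- integer(n)

  # (2) in-scanner vendor QC -> automatic stringent rescan
  auto <- if (profile$internal_qc && policy$max_rescans >= 1L)
    stats::runif(n) < policy$auto_rescan_rate else rep(FALSE, n)
  dur2 <- numeric(n)
  if (any(auto)) {
    base <- if (policy$rescan_time_mode == "scaled_original") dur1[auto]
            else draw_durations(profile, sum(auto),
                                if (!is.null(areas)) areas[auto])
    dur2[auto] <- mult * base
  }
  load2 <- ifelse(auto & policy$rescan_includes_load, profile$load_s, 0)
  rescans <- rescans + as.integer(auto)

  # (3) external automated QC + visual review
  if (is.null(q_true)) q_true <- rep(NA_real_, n)
  miss_q <- is.na(q_true)
  if (any(miss_q)) q_true[miss_q] <- stats::runif(sum(miss_q))
  score <- observe_quality(q_true, qm)
  flagged <- decide_rescan(score, qm)
  vis_accept <- rep(FALSE, n)
  if (any(flagged))
    vis_accept[flagged] <- stats::runif(sum(flagged)) < policy$visual_accept_prob
  rescan_vis <- flagged & !vis_accept & rescans < policy$max_rescans
  rejected <- flagged & !vis_accept & !rescan_vis
  dur3 <- numeric(n)
  if (any(rescan_vis)) {
    base <- if (policy$rescan_time_mode == "scaled_original") dur1[rescan_vis]
            else draw_durations(profile, sum(rescan_vis),
                                if (!is.null(areas)) areas[rescan_vis])
    dur3[rescan_vis] <- mult * base
  }
  load3 <- ifelse(rescan_vis & policy$rescan_includes_load, profile$load_s, 0)
  rescans <- rescans + as.integer(rescan_vis)

  # (4) control sampling of passed slides
  passed <- !flagged
  control <- rep(FALSE, n)
  if (any(passed) && policy$control_rate > 0)
    control[passed] <- stats::runif(sum(passed)) < policy$control_rate
  bad <- q_true < qm$bad_cutoff
  control_catch <- control & bad
  rejected <- rejected | control_catch

  data.frame(
    q_true = q_true, score = score,
    dur1 = dur1, load1 = load1, auto = auto, dur2 = dur2, load2 = load2,
    flagged = flagged, visually_reviewed = flagged | control,
    control_sampled = control, rescan_visual = rescan_vis,
    dur3 = dur3, load3 = load3, n_rescans = rescans,
    disposition = ifelse(rejected, "rejected", "accepted"),
    missed_bad = bad & !rejected & !flagged & !control,
    total_time = dur1 + load1 + dur2 + load2 + dur3 + load3)
}

# analytic zero-rescan baseline time for a batch (denominator of the
# relative batch time): expected single-scan time plus loading, per slide
baseline_time <- function(profile, n, areas = NULL) {
  if (profile$time_model == "poisson")
    n * (profile$mean_scan_s + profile$load_s)
  else
    sum(profile$rate_s_per_mm2 * rep_len(areas, n) + profile$overhead_s +
          profile$load_s)
}

#' Run one slide through the QC workflow
#'
#' Simulates a single slide (see the workflow description in
#' [workflow]) and returns its full event log and disposition.
#'
#' @param slide A [slide_spec()].
#' @param profile A [scanner_profile()].
#' @param policy A [qc_policy()].
#' @param seed Optional integer seed.
#' @return A `"slide_record"`: list with `slide_id`, `events` (data.frame of
#'   scan events: `attempt`, `duration_s`, `load_s`, `stringent`),
#'   `true_quality`, `score`, `flagged_external`, `visually_reviewed`,
#'   `control_sampled`, `disposition` (`"accepted"` or `"rejected"`), and
#'   `missed_bad`.
#' @export
run_slide <- function(slide, profile, policy = qc_policy(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  areas <- if (profile$time_model == "area_rate") charged_area(slide, profile)
  k <- qc_kernel(1L, profile, policy, q_true = slide$true_quality,
                 areas = areas)
  ev <- scan_event(1L, k$dur1, k$load1, FALSE)
  if (k$auto) ev <- rbind(ev, scan_event(2L, k$dur2, k$load2, TRUE))
  if (k$rescan_visual)
    ev <- rbind(ev, scan_event(nrow(ev) + 1L, k$dur3, k$load3, TRUE))
  structure(
    list(slide_id = slide$slide_id, events = ev, true_quality = k$q_true,
         score = k$score, flagged_external = k$flagged,
         visually_reviewed = k$visually_reviewed,
         control_sampled = k$control_sampled, disposition = k$disposition,
         missed_bad = k$missed_bad),
    class = "slide_record")
}

#' @export
print.slide_record <- function(x, ...) {
  cat(sprintf("<slide_record> %s: %d scan(s), %.0f s total, %s%s\n",
              x$slide_id, nrow(x$events),
              sum(x$events$duration_s + x$events$load_s), x$disposition,
              if (x$missed_bad) " [missed bad slide]" else ""))
  invisible(x)
}

#' Simulate a batch of slides through the QC workflow
#'
#' Runs every slide through the workflow (see [workflow]) and aggregates
#' timings, rescans, review workload and dispositions. The relative batch
#' time divides the total elapsed time by the analytic zero-rescan baseline
#' — `n * (mean_scan_s + load_s)` under the Poisson model — so a batch with
#' no rescans averages 1.
#'
#' @param slides A list of [slide_spec()] (or a manifest `data.frame` as read
#'   by [read_manifest()]).
#' @param profile A [scanner_profile()].
#' @param policy A [qc_policy()].
#' @param seed Optional integer seed.
#' @param keep_slides Keep the per-slide table (default `TRUE`; sweeps switch
#'   it off).
#' @return A `"batch_result"`: list with `n_slides`, `total_time_s`,
#'   `relative_time`, `n_rescans`, `n_visual_reviews`, `n_control_reviews`,
#'   `n_accepted`, `n_rejected`, `missed_fraction_observed`, and (unless
#'   `keep_slides = FALSE`) `slides`, a per-slide data.frame.
#' @examples
#' m <- generate_manifest(generator_spec(n_slides = 50, seed = 1))
#' simulate_batch(m, scanner_profile(), qc_policy(), seed = 1)
#' @export
simulate_batch <- function(slides, profile, policy = qc_policy(),
                           seed = NULL, keep_slides = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  slides <- as_slide_list(slides)
  n <- length(slides)
  if (n == 0L) stop("cannot simulate an empty batch")
  q_true <- vapply(slides, function(s) s$true_quality, numeric(1))
  areas <- if (profile$time_model == "area_rate")
    vapply(slides, charged_area, numeric(1), profile = profile)
  k <- qc_kernel(n, profile, policy, q_true = q_true, areas = areas)
  out <- list(
    n_slides = n,
    total_time_s = sum(k$total_time),
    relative_time = sum(k$total_time) / baseline_time(profile, n, areas),
    n_rescans = sum(k$n_rescans),
    n_visual_reviews = sum(k$flagged),
    n_control_reviews = sum(k$control_sampled),
    n_accepted = sum(k$disposition == "accepted"),
    n_rejected = sum(k$disposition == "rejected"),
    missed_fraction_observed = mean(k$missed_bad))
  if (keep_slides) {
    k$slide_id <- vapply(slides, function(s) s$slide_id, character(1))
    out$slides <- k[c("slide_id", "q_true", "score", "flagged",
                      "visually_reviewed", "control_sampled", "n_rescans",
                      "disposition", "missed_bad", "total_time")]
  }
  structure(out, class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d slides in %.0f s (relative time %.4f)\n",
              x$n_slides, x$total_time_s, x$relative_time))
  cat(sprintf("  %d rescans, %d visual reviews + %d control reviews; %d accepted / %d rejected; missed fraction %.4f\n",
              x$n_rescans, x$n_visual_reviews, x$n_control_reviews,
              x$n_accepted, x$n_rejected, x$missed_fraction_observed))
  invisible(x)
}

#' Expected relative batch time under automatic rescans
#'
#' Closed form for the mean relative batch time when a fraction `r` of slides
#' undergoes an automatic stringent rescan taking `m` times the original
#' duration:
#' `1 + r * (m * mu + L * [load charged]) / (mu + L)`,
#' linear in the rescan rate with a slope that grows with the multiplier.
#'
#' @param auto_rescan_rate Rescan rate `r` in `[0, 1]`.
#' @param multiplier Stringent-profile slowdown `m`; >= 1.
#' @param mean_scan_s Mean scan duration `mu`, seconds.
#' @param load_s Slide-loading time `L`, seconds.
#' @param rescan_includes_load Is loading charged again on the rescan?
#' @return Expected relative batch time (>= 1).
#' @examples
#' expected_relative_time(0.05, 2, 60, 10)  # 1 + 0.05 * 130/70
#' @export
expected_relative_time <- function(auto_rescan_rate, multiplier,
                                   mean_scan_s = 60, load_s = 10,
                                   rescan_includes_load = TRUE) {
  stopifnot(auto_rescan_rate >= 0, auto_rescan_rate <= 1, multiplier >= 1,
            mean_scan_s > 0, load_s >= 0)
  extra <- multiplier * mean_scan_s +
    if (rescan_includes_load) load_s else 0
  1 + auto_rescan_rate * extra / (mean_scan_s + load_s)
}

#' Schedule slides on a fleet of scanners running in parallel
#'
#' Deals slides round-robin across the fleet; each scanner works through its
#' share in loaded batches of at most `capacity` slides, reloading whenever a
#' batch completes with slides still waiting. Scanners run in parallel, so
#' the day's makespan is the slowest scanner's finish time. Useful for
#' capacity planning: one 1,000-slide scanner fed 400 slides a day never
#' reloads but idles 600 positions, while a 100-slide scanner must be
#' reloaded three times for the same volume.
#'
#' Per-slide times are first-scan durations plus loading (QC rescans are a
#' batch-level concern; see [simulate_batch()]).
#'
#' @param slides List of [slide_spec()] or a manifest `data.frame`.
#' @param profiles A [scanner_profile()] or list of them.
#' @param daily_load Optional cap on how many slides are loaded from the
#'   manifest (slides beyond it are left unscheduled); default all.
#' @param seed Optional integer seed.
#' @return A `"fleet_report"`: list with `makespan_s`, `n_scheduled`, and
#'   `scanners`, a per-scanner data.frame (`scanner`, `n_slides`, `capacity`,
#'   `n_reloads`, `max_simultaneous_load`, `unused_capacity`, `busy_s`).
#' @examples
#' m <- generate_manifest(generator_spec(n_slides = 400, seed = 1))
#' simulate_fleet(m, scanner_profile("big", capacity = 1000), seed = 1)
#' @export
simulate_fleet <- function(slides, profiles, daily_load = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slides <- as_slide_list(slides)
  if (inherits(profiles, "scanner_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("need at least one scanner profile")
  n <- length(slides)
  if (!is.null(daily_load)) n <- min(n, as.integer(daily_load))
  k <- length(profiles)
  assign_to <- if (n > 0) rep_len(seq_len(k), n) else integer(0)
  per <- lapply(seq_len(k), function(j) {
    p <- profiles[[j]]
    mine <- slides[seq_len(n)[assign_to == j]]
    nj <- length(mine)
    areas <- if (p$time_model == "area_rate" && nj > 0)
      vapply(mine, charged_area, numeric(1), profile = p)
    busy <- if (nj > 0)
      sum(draw_durations(p, nj, areas)) + nj * p$load_s else 0
    data.frame(scanner = p$name, n_slides = nj, capacity = p$capacity,
               n_reloads = max(0L, as.integer(ceiling(nj / p$capacity)) - 1L),
               max_simultaneous_load = min(nj, p$capacity),
               unused_capacity = p$capacity - min(nj, p$capacity),
               busy_s = busy)
  })
  per <- do.call(rbind, per)
  structure(list(makespan_s = if (nrow(per)) max(per$busy_s) else 0,
                 n_scheduled = n, scanners = per),
            class = "fleet_report")
}

#' @export
print.fleet_report <- function(x, ...) {
  cat(sprintf("<fleet_report> %d slides on %d scanner(s), makespan %.0f s\n",
              x$n_scheduled, nrow(x$scanners), x$makespan_s))
  print(x$scanners, row.names = FALSE)
  invisible(x)
}
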