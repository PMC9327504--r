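#' Sweep the auto-rescan rate against the rescan multiplier
#'
#' Reproduces the batch-time experiment: for every combination of rescan rate
#' and stringent-profile multiplier, simulate `n_batches` batches of
#' `batch_size` slides in which the external QC stage is switched off (only
#' the in-scanner auto-rescan operates), and record the relative batch time
#' of each replicate. The mean relative time grows linearly in the rescan
#' rate with slope `(m * mu + L)/(mu + L)` (see
#' [expected_relative_time()]), so curves for larger multipliers dominate.
#'
#' Per-replicate values are retained so standard errors can be recomputed or
#' the replicates re-aggregated.
#'
#' @param rates Auto-rescan rates to sweep.
#' @param multipliers Stringent-profile slowdown factors.
#' @param n_batches Replicate batches per grid cell.
#' @param batch_size Slides per batch.
#' @param profile A [scanner_profile()] (Poisson time model).
#' @param rescan_includes_load Charge loading again on rescans?
#' @param seed Optional integer seed.
#' @return A `"sweep_result"` with `$summary` (one row per grid cell:
#'   `rate`, `multiplier`, `mean_relative_time`, `se`, `expected`,
#'   `n_batches`) and `$replicates` (one row per replicate batch).
#' @examples
#' sw <- sweep_rescan_rate(rates = c(0, 0.1), multipliers = 2,
#'                         n_batches = 50, batch_size = 20, seed = 1)
#' sw$summary
#' @export
sweep_rescan_rate <- function(rates = seq(0, 0.2, by = 0.02),
                              multipliers = c(1.5, 2, 3, 4),
                              n_batches = 1000, batch_size = 100,
                              profile = scanner_profile(),
                              rescan_includes_load = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_batches >= 1, batch_size >= 1)
  if (profile$time_model != "poisson")
    stop("sweep_rescan_rate requires a poisson-time scanner profile")
  ntot <- n_batches * batch_size
  batch_id <- rep(seq_len(n_batches), each = batch_size)
  base <- batch_size * (profile$mean_scan_s + profile$load_s)
  grid <- expand.grid(rate = rates, multiplier = multipliers,
                      KEEP.OUT.ATTRS = FALSE)
  reps <- vector("list", nrow(grid))
  summ <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- grid$rate[i]; m <- grid$multiplier[i]
    pol <- qc_policy(auto_rescan_rate = r, rescan_multiplier = m,
                     rescan_includes_load = rescan_includes_load,
                     quality = quality_model(sigma = 0, threshold = -Inf),
                     visual_accept_prob = 1, control_rate = 0)
    k <- qc_kernel(ntot, profile, pol)
    rel <- as.numeric(rowsum(k$total_time, batch_id)) / base
    reps[[i]] <- data.frame(rate = r, multiplier = m,
                            replicate = seq_len(n_batches),
                            relative_time = rel)
    summ[[i]] <- data.frame(
      rate = r, multiplier = m, mean_relative_time = mean(rel),
      se = stats::sd(rel) / sqrt(n_batches),
      expected = expected_relative_time(r, m, profile$mean_scan_s,
                                        profile$load_s,
                                        rescan_includes_load),
      n_batches = n_batches)
  }
  structure(list(summary = do.call(rbind, summ),
                 replicates = do.call(rbind, reps),
                 type = "rescan_rate", profile = profile),
            class = "sweep_result")
}

#' Sweep the QC detection threshold against algorithm noise
#'
#' Reproduces the threshold/accuracy trade-off experiment: for every
#' combination of observation-noise `sigma` and detection `threshold`,
#' simulate `n_batches` batches of `batch_size` slides through the full
#' workflow and record each replicate's relative batch time and missed-slide
#' fraction, together with the closed-form missed and flagged fractions
#' ([missed_fraction()], [flagged_fraction()]). Raising the threshold
#' catches more truly bad slides (fewer missed) at the cost of more rescans
#' and review work (longer batches); noisier algorithms miss more at any
#' threshold above the bad-quality cutoff.
#'
#' The default policy uses a rescan multiplier of 2 and an auto-rescan rate
#' of 0.05; every flagged slide proceeds to a stringent rescan (visual review
#' never rescues it) and control sampling is off, so the scan-time cost of a
#' sensitive threshold is fully visible while the simulated missed fraction
#' still estimates the closed form exactly (a missed slide is an *unflagged*
#' bad slide, whatever happens to the flagged ones).
#'
#' @param sigmas Observation-noise standard deviations.
#' @param thresholds Detection thresholds.
#' @param policy Base [qc_policy()]; its `quality` sigma/threshold are
#'   overridden cell by cell.
#' @param n_batches Replicate batches per grid cell.
#' @param batch_size Slides per batch.
#' @param profile A [scanner_profile()].
#' @param seed Optional integer seed.
#' @return A `"sweep_result"` with `$summary` (per cell: `sigma`,
#'   `threshold`, `mean_relative_time`, `se_relative_time`,
#'   `mean_missed_fraction`, `se_missed_fraction`, `missed_closed_form`,
#'   `missed_given_bad`, `flagged_closed_form`, `n_batches`) and
#'   `$replicates`.
#' @export
sweep_threshold <- function(sigmas = c(0.1, 0.15, 0.2, 0.25),
                            thresholds = seq(0, 1, by = 0.05),
                            policy = NULL, n_batches = 1000,
                            batch_size = 100,
                            profile = scanner_profile(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_batches >= 1, batch_size >= 1)
  if (is.null(policy))
    policy <- qc_policy(auto_rescan_rate = 0.05, rescan_multiplier = 2,
                        visual_accept_prob = 0, control_rate = 0)
  ntot <- n_batches * batch_size
  batch_id <- rep(seq_len(n_batches), each = batch_size)
  grid <- expand.grid(sigma = sigmas, threshold = thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  reps <- vector("list", nrow(grid))
  summ <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    qm <- quality_model(sigma = grid$sigma[i], threshold = grid$threshold[i],
                        bad_cutoff = policy$quality$bad_cutoff)
    pol <- policy
    pol$quality <- qm
    k <- qc_kernel(ntot, profile, pol)
    areas <- NULL
    rel <- as.numeric(rowsum(k$total_time, batch_id)) /
      baseline_time(profile, batch_size, areas)
    missed <- as.numeric(rowsum(as.numeric(k$missed_bad), batch_id)) /
      batch_size
    reps[[i]] <- data.frame(sigma = qm$sigma, threshold = qm$threshold,
                            replicate = seq_len(n_batches),
                            relative_time = rel, missed_fraction = missed)
    summ[[i]] <- data.frame(
      sigma = qm$sigma, threshold = qm$threshold,
      mean_relative_time = mean(rel),
      se_relative_time = stats::sd(rel) / sqrt(n_batches),
      mean_missed_fraction = mean(missed),
      se_missed_fraction = stats::sd(missed) / sqrt(n_batches),
      missed_closed_form = missed_fraction(qm),
      missed_given_bad = if (qm$bad_cutoff > 0)
        missed_fraction(qm) / qm$bad_cutoff else NaN,
      flagged_closed_form = flagged_fraction(qm),
      n_batches = n_batches)
  }
  structure(list(summary = do.call(rbind, summ),
                 replicates = do.call(rbind, reps),
                 type = "threshold", policy = policy, profile = profile),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s sweep: %d grid cells x %d replicate batches\n",
              x$type, nrow(x$summary), x$summary$n_batches[1]))
  print(utils::head(x$summary, 10), row.names = FALSE)
  if (nrow(x$summary) > 10) cat("  ...\n")
  invisible(x)
}

#' Plot a sweep result
#'
#' Line plot of the sweep's primary response (mean relative batch time for a
#' rescan-rate sweep; mean missed fraction for a threshold sweep), one curve
#' per multiplier or noise level.
#'
#' @param x A `"sweep_result"`.
#' @param y Ignored.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, y, ...) {
  s <- x$summary
  if (x$type == "rescan_rate") {
    wide <- stats::reshape(s[c("rate", "multiplier", "mean_relative_time")],
                           idvar = "rate", timevar = "multiplier",
                           direction = "wide")
    graphics::matplot(wide$rate, wide[-1], type = "b", pch = 16, lty = 1,
                      xlab = "auto-rescan rate",
                      ylab = "mean relative batch time", ...)
    graphics::legend("topleft", legend = paste("multiplier",
                                               unique(s$multiplier)),
                     col = seq_along(unique(s$multiplier)), lty = 1, pch = 16)
  } else {
    wide <- stats::reshape(s[c("threshold", "sigma", "mean_missed_fraction")],
                           idvar = "threshold", timevar = "sigma",
                           direction = "wide")
    graphics::matplot(wide$threshold, wide[-1], type = "b", pch = 16, lty = 1,
                      xlab = "detection threshold",
                      ylab = "mean missed-slide fraction", ...)
    graphics::legend("topright", legend = paste("sigma", unique(s$sigma)),
                     col = seq_along(unique(s$sigma)), lty = 1, pch = 16)
  }
  invisible(x)
}

#' Compare scanners on a shared slide set
#'
#' Computes per-slide normalized scan times ([normalized_scan_time()]),
#' per-scanner means, and each scanner's slowdown relative to the fastest
#' scanner (lowest mean normalized time) under three labelled averaging
#' conventions:
#' \describe{
#'   \item{`ratio_of_mean_raw`}{mean raw scan time / fastest's mean raw time.}
#'   \item{`mean_per_slide_ratio`}{mean over shared slides of the per-slide
#'     raw-time ratio.}
#'   \item{`ratio_of_mean_norm`}{mean normalized time / fastest's mean
#'     normalized time.}
#' }
#' The conventions can differ substantially (slide-size weighting differs),
#' which is why each ratio is reported with its convention rather than as a
#' single "x times slower" figure.
#'
#' @param measurements `data.frame` with columns `scanner`, `slide`,
#'   `scan_time_s`, `size_mm2` (e.g. [scanner_timings()]). Rows with a
#'   missing area are skipped with a warning.
#' @return A `"scanner_report"`: list with `measurements` (input plus
#'   `norm_time`), `per_scanner` (mean raw/normalized time per scanner),
#'   `fastest` (scanner name), and `ratios` (long table: `scanner`,
#'   `convention`, `ratio`).
#' @examples
#' rep <- scanner_comparison(scanner_timings())
#' rep$per_scanner
#' @export
scanner_comparison <- function(measurements) {
  req <- c("scanner", "slide", "scan_time_s", "size_mm2")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  bad <- !is.finite(measurements$size_mm2) | measurements$size_mm2 <= 0
  if (any(bad)) {
    warning(sum(bad), " measurement(s) skipped: missing or nonpositive area")
    measurements <- measurements[!bad, , drop = FALSE]
  }
  if (nrow(measurements) == 0L) stop("no usable measurements")
  measurements$norm_time <- normalized_scan_time(measurements$scan_time_s,
                                                 measurements$size_mm2)
  per <- do.call(rbind, lapply(split(measurements, measurements$scanner),
    function(d) data.frame(scanner = d$scanner[1], n_slides = nrow(d),
                           mean_raw_s = mean(d$scan_time_s),
                           mean_norm_time = mean(d$norm_time))))
  rownames(per) <- NULL
  fastest <- per$scanner[which.min(per$mean_norm_time)]
  fast <- measurements[measurements$scanner == fastest, ]
  ratios <- do.call(rbind, lapply(per$scanner, function(sc) {
    d <- measurements[measurements$scanner == sc, ]
    shared <- intersect(d$slide, fast$slide)
    per_slide <- d$scan_time_s[match(shared, d$slide)] /
      fast$scan_time_s[match(shared, fast$slide)]
    data.frame(
      scanner = sc,
      convention = c("ratio_of_mean_raw", "mean_per_slide_ratio",
                     "ratio_of_mean_norm"),
      ratio = c(mean(d$scan_time_s) / mean(fast$scan_time_s),
                mean(per_slide),
                mean(d$norm_time) / mean(fast$norm_time)))
  }))
  structure(list(measurements = measurements, per_scanner = per,
                 fastest = fastest, ratios = ratios),
            class = "scanner_report")
}

#' @export
print.scanner_report <- function(x, ...) {
  cat(sprintf("<scanner_report> %d scanners, fastest: %s\n",
              nrow(x$per_scanner), x$fastest))
  print(x$per_scanner, row.names = FALSE)
  cat(sprintf("Slowdown vs %s (by convention):\n", x$fastest))
  print(x$ratios[x$ratios$scanner != x$fastest, ], row.names = FALSE)
  invisible(x)
}
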