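good_slide <- function(q = 0.9) slide_spec("w1", "biopsy", 120, true_quality = q)

test_that("a clean slide passes straight through with one scan", {
  pol <- qc_policy(auto_rescan_rate = 0, rescan_multiplier = 2,
                   quality = quality_model(sigma = 0, threshold = 0.5),
                   visual_accept_prob = 1, control_rate = 0)
  rec <- run_slide(good_slide(0.9), scanner_profile(), pol, seed = 1)
  expect_equal(nrow(rec$events), 1L)
  expect_identical(rec$disposition, "accepted")
  expect_false(rec$flagged_external)
  expect_false(rec$visually_reviewed)
  expect_false(rec$missed_bad)
})

test_that("an auto-rescan under the stringent profile scales the original duration", {
  pol <- qc_policy(auto_rescan_rate = 1, rescan_multiplier = 2,
                   rescan_time_mode = "scaled_original",
                   quality = quality_model(sigma = 0, threshold = -Inf),
                   visual_accept_prob = 1, control_rate = 0)
  rec <- run_slide(good_slide(), scanner_profile(), pol, seed = 2)
  expect_equal(nrow(rec$events), 2L)
  expect_equal(rec$events$duration_s[2], 2 * rec$events$duration_s[1])
  expect_true(rec$events$stringent[2])
  expect_false(rec$events$stringent[1])
  # loading charged again by default on the rescan
  expect_equal(rec$events$load_s, c(10, 10))
  pol$rescan_includes_load <- FALSE
  rec2 <- run_slide(good_slide(), scanner_profile(), pol, seed = 2)
  expect_equal(rec2$events$load_s, c(10, 0))
})

test_that("a flagged slide whose rescan was already spent is rejected, not rescanned", {
  # force: auto-rescan once, then external flag, then visual review declines
  pol <- qc_policy(auto_rescan_rate = 1, rescan_multiplier = 2,
                   quality = quality_model(sigma = 0, threshold = 2),
                   visual_accept_prob = 0, control_rate = 0, max_rescans = 1)
  rec <- run_slide(good_slide(0.5), scanner_profile(), pol, seed = 3)
  expect_equal(nrow(rec$events), 2L)  # no third scan
  expect_identical(rec$disposition, "rejected")
  expect_true(rec$flagged_external)
  expect_true(rec$visually_reviewed)
})

test_that("a flagged slide with attempts remaining is rescanned after a declined review", {
  pol <- qc_policy(auto_rescan_rate = 0, rescan_multiplier = 3,
                   quality = quality_model(sigma = 0, threshold = 2),
                   visual_accept_prob = 0, control_rate = 0, max_rescans = 1)
  rec <- run_slide(good_slide(0.5), scanner_profile(), pol, seed = 4)
  expect_equal(nrow(rec$events), 2L)
  expect_true(rec$events$stringent[2])
  expect_equal(rec$events$duration_s[2], 3 * rec$events$duration_s[1])
  expect_identical(rec$disposition, "accepted")
})

test_that("a zero-rescan policy still terminates with a disposition", {
  pol <- qc_policy(auto_rescan_rate = 1, rescan_multiplier = 4,
                   quality = quality_model(sigma = 0, threshold = 2),
                   visual_accept_prob = 0, max_rescans = 0)
  rec <- run_slide(good_slide(0.5), scanner_profile(), pol, seed = 5)
  expect_equal(nrow(rec$events), 1L)  # no rescan budget at all
  expect_identical(rec$disposition, "rejected")
})

test_that("batch relative time is 1 without rescans and 2 when every slide rescans at cost 1", {
  prof <- scanner_profile(mean_scan_s = 60, load_s = 10)
  slides <- manifest_to_slides(generate_manifest(
    generator_spec(100, quality = "none", seed = 61)))
  base_pol <- qc_policy(auto_rescan_rate = 0, rescan_multiplier = 1,
                        quality = quality_model(sigma = 0, threshold = -Inf),
                        visual_accept_prob = 1, control_rate = 0)
  set.seed(62)
  rel <- replicate(400, simulate_batch(slides, prof, base_pol,
                                       keep_slides = FALSE)$relative_time)
  se <- sd(rel) / sqrt(length(rel))
  expect_lt(abs(mean(rel) - 1), 3 * se)
  all_pol <- base_pol
  all_pol$auto_rescan_rate <- 1
  set.seed(63)
  rel2 <- replicate(400, simulate_batch(slides, prof, all_pol,
                                        keep_slides = FALSE)$relative_time)
  expect_lt(abs(mean(rel2) - 2), 3 * sd(rel2) / sqrt(length(rel2)))
  expect_error(simulate_batch(list(), prof, base_pol), "empty")
})

test_that("every simulated slide ends accepted or rejected within the rescan budget", {
  set.seed(71)
  slides <- manifest_to_slides(generate_manifest(
    generator_spec(40, quality = "none", seed = 72)))
  for (i in 1:30) {
    pol <- random_policy()
    b <- simulate_batch(slides, scanner_profile(), pol)
    expect_equal(b$n_accepted + b$n_rejected, b$n_slides)
    expect_true(all(b$slides$disposition %in% c("accepted", "rejected")))
    expect_true(all(b$slides$n_rescans <= pol$max_rescans))
    rec <- run_slide(slides[[1]], scanner_profile(), pol)
    expect_lte(nrow(rec$events), 1L + pol$max_rescans)
    expect_true(rec$disposition %in% c("accepted", "rejected"))
  }
})

test_that("observed missed fraction converges to the closed form when review always accepts", {
  qm <- quality_model(sigma = 0.2, threshold = 0.1, bad_cutoff = 0.05)
  pol <- qc_policy(auto_rescan_rate = 0.05, rescan_multiplier = 2,
                   quality = qm, visual_accept_prob = 1, control_rate = 0)
  n <- 2e5
  slides <- rep(list(slide_spec("q", "ihc", 100)), n)  # quality drawn in-sim
  b <- simulate_batch(slides, scanner_profile(), pol, seed = 81,
                      keep_slides = FALSE)
  p <- missed_fraction(qm)
  expect_lt(abs(b$missed_fraction_observed - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("control sampling catches bad unflagged slides and rejects them", {
  qm <- quality_model(sigma = 0, threshold = -1, bad_cutoff = 1)  # all bad, none flagged
  pol <- qc_policy(auto_rescan_rate = 0, rescan_multiplier = 1, quality = qm,
                   visual_accept_prob = 1, control_rate = 1)
  b <- simulate_batch(rep(list(slide_spec("c", "ihc", 50)), 50),
                      scanner_profile(), pol, seed = 85)
  expect_equal(b$n_control_reviews, 50)
  expect_equal(b$n_rejected, 50)
  expect_equal(b$missed_fraction_observed, 0)
})

test_that("expected relative time follows the linear rescan law", {
  expect_equal(expected_relative_time(0, 3), 1)
  expect_equal(expected_relative_time(1, 1, 60, 10, TRUE), 2)
  expect_equal(expected_relative_time(0.05, 2, 60, 10, TRUE),
               1 + 0.05 * 130 / 70)
  # slope grows with the multiplier
  s <- function(m) expected_relative_time(1, m) - expected_relative_time(0, m)
  expect_true(all(diff(vapply(c(1.5, 2, 3, 4), s, numeric(1))) > 0))
})

test_that("fleet scheduling reproduces capacity arithmetic and parallel speed-up", {
  man <- generate_manifest(generator_spec(400, seed = 91))
  big <- simulate_fleet(man, scanner_profile("big", capacity = 1000),
                        seed = 92)
  expect_equal(big$scanners$n_reloads, 0L)
  expect_equal(big$scanners$unused_capacity, 600L)
  small <- simulate_fleet(man, scanner_profile("small", capacity = 100),
                          seed = 92)
  expect_equal(small$scanners$n_reloads, 3L)  # ceil(400/100) - 1
  # identical per-slide times: k parallel scanners cut the makespan k-fold
  det <- function(nm) scanner_profile(nm, time_model = "area_rate",
                                      rate_s_per_mm2 = 0, overhead_s = 60,
                                      load_s = 10, capacity = 100)
  one <- simulate_fleet(man, det("solo"))
  four <- simulate_fleet(man, lapply(paste0("s", 1:4), det))
  expect_equal(four$makespan_s / one$makespan_s, 1 / 4)
  # daily_load caps the schedule
  capped <- simulate_fleet(man, det("solo"), daily_load = 50)
  expect_equal(capped$n_scheduled, 50)
})
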