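---
title: "Modelling throughput and quality control in whole-slide scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling throughput and quality control in whole-slide scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsisim)
```

## The problem

Digitizing glass histology slides at scale is an operations problem as much
as an imaging one. A scanning facility cares about three coupled quantities:
how long a slide takes to scan (which depends on the scanner and on how much
of the slide it decides to sweep), how often a scan has to be repeated
because its quality is insufficient, and how much human review the quality
assurance process consumes. `wsisim` models all three so that policies —
rescan thresholds, stringent-profile settings, fleet composition — can be
compared quantitatively before committing a laboratory to them.

## Scan-time models and the normalized-time metric

Raw scan times are not comparable across slides because tissue area varies
by more than an order of magnitude between a biopsy core and a large
resection. The package therefore works with the *normalized scan time*

$$T_{225} = \frac{T}{A} \times 225\ \mathrm{mm^2},$$

the time the scanner would have needed for the conventional
15 × 15 mm reference area, given measured duration $T$ (s) and tissue area
$A$ (mm²). `scanner_timings()` ships a real benchmark — nine slides (three
H&E resections, three H&E biopsies, three IHC slides) scanned on four
commercial scanners — and `normalized_scan_time()` reproduces its published
normalized column to within ±0.5 s (the published areas were rounded, which
bounds the attainable agreement). `scanner_comparison()` summarises such a
table into per-scanner means and slowdown ratios; because "scanner C is
$k\times$ slower than scanner A" depends on whether one averages raw times,
per-slide ratios, or normalized times, the report keeps all three
conventions explicit rather than collapsing them. On the bundled benchmark
they genuinely disagree (≈7.55, ≈7.59 and ≈5.96 for scanner C), which is
exactly why the labelling matters.

Two per-slide time models are provided:

* **Poisson** — integer-second durations, $T \sim \mathrm{Pois}(\mu)$ with
  mean `mean_scan_s` (default 60 s), plus a constant loading time `load_s`
  (default 10 s) per scan. This is the model used for all batch-level
  experiments. Durations are floored at 1 s so that every scan event has
  positive duration; at operational means the floor is unreachable in
  practice.
* **Area-rate** — deterministic $T = c \cdot A_\mathrm{eff} + T_0$, tying
  duration to the *effective* scanned area. The two models are kept
  orthogonal: area-rate is noise-free by design, so geometry effects can be
  studied without Monte-Carlo error.

Effective area depends on acquisition geometry (`effective_scan_area()`).
A *line* scanner sweeps the tissue bounding boxes themselves (each expanded
by `padding_mm` per side); a *tile* scanner captures every fixed tile of
side `tile_mm` whose footprint overlaps a padded box. The tile grid is
anchored at the slide origin with half-open tiles $[is, (i+1)s)$, and a tile
counts only when the overlap has positive area — a box edge exactly on a
tile boundary does not drag in the neighbouring tile. This makes the
computation deterministic and gives the expected qualitative contrast:
tiles charge for blank space inside partially covered tiles but skip the
blank space *between* distant tissue fragments that a single enclosing
stripe would sweep. Note that tile quantization can exceed a box's own
bounding-box area when boxes are small or misaligned relative to the tile
grid (a 5 × 5 mm box straddling 1 mm tile boundaries occupies a 6 × 6 tile
footprint); the saving relative to a line scanner is a property of
fragmented, well-separated tissue, not a universal inequality.

## The QC workflow

A slide moves through four stages (`run_slide()`, `simulate_batch()`):

1. **First scan** — duration from the time model, plus loading.
2. **In-scanner vendor QC** — with probability `auto_rescan_rate` the scan
   fails and is immediately redone under a more stringent profile taking
   `rescan_multiplier` × as long. The failure coin is independent of the
   slide's true quality: this stage models a *rate* knob on the scanner,
   which is how vendors expose it. Profiles with `internal_qc = FALSE` skip
   the stage (external-QC-only deployments).
3. **External automated QC** — a scanner-agnostic algorithm scores the
   image. The score is the latent true quality plus Gaussian noise of
   standard deviation `sigma`, *not* clipped to [0, 1], and the slide is
   flagged when the score falls strictly below `threshold`. Flagged slides
   go to visual review: with probability `visual_accept_prob` the reviewer
   accepts; otherwise the slide is rescanned if rescan attempts remain and
   rejected outright if not ("no further rescanning once a rescan has been
   spent" is the default `max_rescans = 1`).
4. **Control sampling** — a fraction `control_rate` of passed slides is
   reviewed visually anyway, to monitor the algorithm; a control review
   landing on a truly bad slide catches it (the slide is rejected).

A slide is **missed** when its true quality is below `bad_cutoff` yet it
reaches the repository without any human seeing it — not flagged, not
control-sampled. This joint-probability convention (fraction of *all*
slides) is the primary one; the conditional rate among bad slides is
`missed_fraction(model) / bad_cutoff` and is also reported by the sweep.

Three modelling decisions here were genuinely open and deserve their
rationale:

* **`bad_cutoff` (default 0.05)** defines ground-truth badness, a quantity
  the QC literature leaves to the use case. With qualities uniform on
  [0, 1] the default makes 5% of slides truly bad, matching the default
  first-stage rescan rate so the two QC stages face comparable base rates.
  It is fully configurable.
* **Visual review** is a Bernoulli accept with `visual_accept_prob`
  (default 0.5): with no error model for human reviewers available, a
  maximum-entropy coin is the least-committal choice, and the parameter is
  exposed so sensitivity to it can be swept.
* **A rescan triggered by visual review ends in acceptance.** Under the
  default one-rescan budget there is nothing left to do afterwards anyway;
  allowing re-entry into external QC would require a loop the workflow's
  "no further rescanning" rule forbids. Larger `max_rescans` values are
  exploratory.
* **Loading on rescans** is charged by default (`rescan_includes_load =
  TRUE`), since loading is a per-scan cost in the batch-time model; the
  flag exists because in-scanner rescans plausibly skip reloading, and both
  readings are defensible.

## Closed-form oracles for the classifier

For $q \sim U(0,1)$, $\varepsilon \sim N(0, \sigma^2)$, threshold $t$ and
cutoff $c$, the two operating-characteristic quantities have closed forms
via $G(z) = z\Phi(z) + \varphi(z)$, the antiderivative of the normal CDF:

$$\Pr(q < c,\; q + \varepsilon \ge t)
  = \int_0^{c}\Phi\!\left(\frac{q-t}{\sigma}\right)dq
  = \sigma\left[G\!\left(\tfrac{c-t}{\sigma}\right)
               - G\!\left(\tfrac{-t}{\sigma}\right)\right]$$

(`missed_fraction()`), and

$$\Pr(q + \varepsilon < t)
  = \sigma\left[G\!\left(\tfrac{t}{\sigma}\right)
               - G\!\left(\tfrac{t-1}{\sigma}\right)\right]$$

(`flagged_fraction()`), with the $\sigma = 0$ cases handled as indicator
limits. The test suite checks both against an independent adaptive
quadrature of the defining integrals (to $10^{-9}$) and against
million-slide Monte-Carlo runs (to 3 binomial standard errors), over the
noise grid $\sigma \in \{0.1, 0.15, 0.2, 0.25\}$ and a 0–1 threshold grid.
Tie-break: a score exactly at the threshold is *not* flagged; the event has
probability zero for $\sigma > 0$ but must be defined for the noiseless
case.

Similarly, the expected relative batch time under automatic rescans is
linear in the rescan rate $r$,

$$\mathbb{E}[\text{relative time}] = 1 + r\,\frac{m\mu + L}{\mu + L},$$

with multiplier $m$, mean scan $\mu$ and loading $L$
(`expected_relative_time()`). The simulation's relative time uses this
analytic baseline $n(\mu + L)$ as its denominator rather than a paired
simulated baseline — that removes baseline sampling noise and makes the
linear law hold exactly in expectation.

## Sweeps and their defaults

`sweep_rescan_rate()` runs the rate × multiplier grid (defaults: rates 0 to
0.2, multipliers 1.5/2/3/4, 1,000 batches of 100 slides, $\mu = 60$ s,
$L = 10$ s). `sweep_threshold()` runs the noise × threshold grid with a
rescan multiplier of 2 and an auto-rescan rate of 0.05. Its default policy
sends every externally flagged slide to a stringent rescan
(`visual_accept_prob = 0`) and disables control sampling, so the sweep
exhibits the full scan-time cost of a sensitive threshold while the
simulated missed fraction remains an unbiased estimate of the closed form
(whether a bad slide is missed depends only on it escaping the flag).
Because slides are independent, each grid cell simulates its
`n_batches × batch_size` slides in one vectorised pass and aggregates by
batch index; this is statistically identical to looping over batches and is
what keeps thousand-replicate grids in seconds. Sweeps retain per-replicate
values in `$replicates` so standard errors are recomputable.

## The synthetic-manifest generator

`generate_manifest()` emulates the *metadata* of a realistic scanning
workload, not images: class mix uniform over resection/biopsy/IHC; tissue
areas log-uniform within per-class bounds taken once from the bundled
benchmark's per-class ranges (resections 439.6–777 mm², biopsies 67.2–425.2
mm², IHC 34.6–897.7 mm²) — log-uniform because tissue areas span an order of
magnitude and the benchmark gives ranges, not a shape; latent qualities
uniform on [0, 1]; and 1–3 bounding boxes per slide sized so the boxes
bound the tissue loosely (≈70% fill). What it does **not** emulate:
correlation between slide class and quality, day-to-day drift, focus
failures clustered by batch, or any image content. Passing tests on this
population therefore validates the *engine and its arithmetic*, not the
operational performance of any real QC algorithm on real slides.

## Fleet scheduling

`simulate_fleet()` deals slides round-robin across scanners; each scanner
works sequentially through loaded batches of at most `capacity` slides,
reloading between batches, and scanners run in parallel. Reported per
scanner: reload count ($\lceil n_i/\text{cap}\rceil - 1$), maximum
simultaneous load, unused capacity, busy time; the fleet's makespan is the
slowest scanner's finish time. This is deliberately a capacity-arithmetic
model — no staffing constraints, no within-day arrival process, no
failure/downtime model — sufficient for questions like "one 1,000-slide
scanner versus four 100-slide scanners for a 400-slide day".

## Reproducibility and numerical choices

Every stochastic entry point takes a `seed`; all draws come from R's global
stream in a fixed, documented order (first-scan durations, auto-rescan
coins, stringent durations, missing qualities, observation noise, review
coins, control coins), so runs are bit-reproducible. The CLI writes a run
log capturing command, package version, seed and parameters. Degenerate
inputs are defined, not accidental: `max_rescans = 0` still terminates with
a disposition, `sigma = 0` classifiers use the indicator limits, empty
manifests are valid generator output but invalid batches.

Test problem sizes are chosen to keep Monte-Carlo error well inside the
asserted tolerances: thousand-replicate batches of 100 slides for the
batch-time law, $10^6$ slides per grid cell for classifier agreement,
$10^5$ draws for distributional moments, 200 random policies for the
termination/conservation properties.

## Known limitations

* The first-stage auto-rescan is quality-independent by construction; a
  quality-coupled vendor QC would change the interaction between the two
  QC stages and is out of scope.
* Scan-time and quality are independent; in reality difficult slides are
  both slower and worse.
* The area-rate model is deterministic, and the Poisson model's
  variance-to-mean ratio is fixed at 1; scanners with heavy-tailed scan
  times (focus retries) will be underdispersed here.
* Normalized time inherits whatever the benchmark's "size" column measures
  (scanned area as reported by each vendor), so cross-scanner differences
  partly reflect scan-area strategy, not optics alone — which is precisely
  why the comparison report also carries raw-time conventions.
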