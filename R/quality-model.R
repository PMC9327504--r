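#' Noisy-observation threshold model of automated image-quality QC
#'
#' The automated QC algorithm is modelled as a noisy observer of a latent
#' slide quality `q` (uniform on `[0, 1]` a priori): it reports
#' `score = q + e` with `e ~ Normal(0, sigma^2)` and flags the slide for
#' rescan/review when the score falls strictly below `threshold`. The score is
#' deliberately *not* clipped to `[0, 1]`; the threshold is applied to the
#' noisy value itself. `sigma` encodes the accuracy of the QC algorithm,
#' `threshold` its sensitivity, and `bad_cutoff` defines ground truth: a slide
#' with `q < bad_cutoff` is one that should have been rejected.
#'
#' @param sigma Standard deviation of the Gaussian observation noise; >= 0.
#' @param threshold Flagging threshold applied to the noisy score (strict:
#'   flag iff `score < threshold`). Any real value is allowed.
#' @param bad_cutoff True quality below which a slide should be rejected;
#'   in `[0, 1]`. Defaults to 0.05.
#'
#' @return An object of class `"quality_model"`.
#' @seealso [missed_fraction()], [flagged_fraction()], [observe_quality()]
#' @examples
#' m <- quality_model(sigma = 0.15, threshold = 0.1)
#' missed_fraction(m)
#' flagged_fraction(m)
#' @export
quality_model <- function(sigma = 0.15, threshold = 0.05, bad_cutoff = 0.05) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.finite(bad_cutoff) || bad_cutoff < 0 || bad_cutoff > 1)
    stop("bad_cutoff must lie in [0, 1]")
  if (is.na(threshold)) stop("threshold must be a number")
  structure(list(sigma = as.numeric(sigma), threshold = as.numeric(threshold),
                 bad_cutoff = as.numeric(bad_cutoff)),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model> sigma = %g, threshold = %g, bad cutoff = %g\n",
              x$sigma, x$threshold, x$bad_cutoff))
  cat(sprintf("  closed-form flag rate %.4f, missed-slide rate %.4f\n",
              flagged_fraction(x), missed_fraction(x)))
  invisible(x)
}

#' Observe a noisy quality score
#'
#' Returns `q_true + e`, `e ~ Normal(0, sigma^2)`, the score the automated QC
#' algorithm would report. Vectorised over `q_true`; not clipped to `[0, 1]`.
#'
#' @param q_true True quality value(s) in `[0, 1]`.
#' @param model A [quality_model()].
#' @return Numeric score(s), unbounded.
#' @export
observe_quality <- function(q_true, model) {
  q_true <- as.numeric(q_true)
  if (any(q_true < 0 | q_true > 1, na.rm = TRUE))
    stop("q_true must lie in [0, 1]")
  if (model$sigma == 0) return(q_true)
  q_true + stats::rnorm(length(q_true), 0, model$sigma)
}

#' Apply the rescan threshold to a quality score
#'
#' Flags a slide for rescan/visual review when its observed score is strictly
#' below the model threshold. A score exactly at the threshold is accepted
#' (deterministic tie-break; a zero-measure event whenever `sigma > 0`).
#'
#' @param score Observed quality score(s).
#' @param model A [quality_model()].
#' @return Logical: `TRUE` means "rescan/review".
#' @export
decide_rescan <- function(score, model) {
  as.numeric(score) < model$threshold
}

# antiderivative of Phi(z): int Phi = z*Phi(z) + phi(z)
phi_int <- function(z) z * stats::pnorm(z) + stats::dnorm(z)

#' Closed-form missed-slide fraction
#'
#' Probability that a slide both is truly bad (`q < bad_cutoff`) and escapes
#' the threshold (`q + e >= threshold`), for `q ~ Uniform(0, 1)` and Gaussian
#' noise `e`: the fraction of *all* slides that should have been rejected but
#' were missed. Evaluated in closed form,
#' `int_0^c Phi((q - t)/sigma) dq = sigma * (G(z1) - G(z0))` with
#' `G(z) = z Phi(z) + phi(z)`, `z0 = -t/sigma`, `z1 = (c - t)/sigma`.
#' The noiseless case `sigma = 0` is the indicator limit.
#'
#' To express the rate as a fraction of bad slides instead, divide by
#' `bad_cutoff` (see also the `missed_given_bad` column of [sweep_threshold()]).
#'
#' @param model A [quality_model()].
#' @return Probability in `[0, bad_cutoff]`.
#' @export
missed_fraction <- function(model) {
  c0 <- model$bad_cutoff
  t0 <- model$threshold
  s <- model$sigma
  if (c0 == 0) return(0)
  if (s == 0) {
    # missed iff q >= t (accepted) and q < c: length of [max(0, t), c)
    return(max(0, c0 - min(max(t0, 0), c0)))
  }
  s * (phi_int((c0 - t0) / s) - phi_int((0 - t0) / s))
}

#' Closed-form flagged fraction
#'
#' Probability that a slide's noisy score falls below the threshold,
#' `P(q + e < t)` for `q ~ Uniform(0, 1)`: the fraction of slides diverted to
#' rescan/visual review. Closed form
#' `int_0^1 Phi((t - q)/sigma) dq = sigma * (G(t/sigma) - G((t-1)/sigma))`;
#' `sigma = 0` gives `clamp(t, 0, 1)`.
#'
#' @param model A [quality_model()].
#' @return Probability in `[0, 1]`.
#' @export
flagged_fraction <- function(model) {
  t0 <- model$threshold
  s <- model$sigma
  if (s == 0) return(min(max(t0, 0), 1))
  s * (phi_int(t0 / s) - phi_int((t0 - 1) / s))
}

#' Monte-Carlo draw of classifier outcomes
#'
#' Simulates `n` slides through the noisy threshold classifier alone (no
#' timing): draws true qualities, observes noisy scores, applies the
#' threshold, and tallies flagged and missed slides. The empirical
#' counterpart of [missed_fraction()] and [flagged_fraction()].
#'
#' @param n Number of slides to simulate.
#' @param model A [quality_model()].
#' @param seed Optional integer seed.
#' @return List with `n`, `flagged_fraction`, `missed_fraction` (fraction of
#'   all slides), and `missed_given_bad` (fraction of truly bad slides;
#'   `NaN` when no bad slide was drawn).
#' @export
simulate_quality_outcomes <- function(n, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  q <- stats::runif(n)
  score <- observe_quality(q, model)
  flagged <- decide_rescan(score, model)
  bad <- q < model$bad_cutoff
  missed <- bad & !flagged
  list(n = n,
       flagged_fraction = mean(flagged),
       missed_fraction = mean(missed),
       missed_given_bad = if (any(bad)) mean(missed[bad]) else NaN)
}
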