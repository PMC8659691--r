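#' Configuration of the importance-sampling observer
#'
#' The sampling observer approximates the per-frame log likelihood odds by
#' importance sampling of the latent feature \eqn{x}, drawing samples from
#' a pseudo-posterior that feeds the current categorical belief back as a
#' prior. With few samples the importance weights only partially undo that
#' feedback, biasing the LLO estimate towards the current belief — the
#' confirmation bias this package studies.
#'
#' @param n_samples number of importance samples \eqn{S} per belief update.
#' @param n_updates number of belief sub-updates \eqn{n_U} per stimulus
#'   frame; each sub-update uses \eqn{LLO/n_U}.
#' @param leak integration leak \eqn{\gamma \in [0, 1)}, applied so that the
#'   \eqn{n_U} sub-updates of one frame compound to approximately
#'   \eqn{(1-\gamma)}.
#' @param normalize_weights use self-normalized importance weights. Has no
#'   effect on the LLO estimate (normalization cancels in the ratio) and is
#'   retained for explicitness.
#' @return An object of class \code{sampling_config}.
#' @export
sampling_config <- function(n_samples = 5, n_updates = 5, leak = 0,
                            normalize_weights = TRUE) {
  if (n_samples < 1 || n_updates < 1)
    stop_domain("n_samples and n_updates must be >= 1")
  if (leak < 0 || leak >= 1) stop_domain("leak must be in [0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_updates = as.integer(n_updates),
                 leak = leak, normalize_weights = isTRUE(normalize_weights)),
            class = "sampling_config")
}

# Mixture prior over the feature mode implied by belief prior_c in C = +1:
# weight on the +1 mode is m_plus = q * prior_c + (1 - q) * (1 - prior_c).
mode_weight_plus <- function(prior_c, q) q * prior_c + (1 - q) * (1 - prior_c)

# Vectorized core: for evidence e (length n) and prior_c (length n), draw
# S posterior samples of x per trial and their raw importance weights.
# The pseudo-posterior Q(x) ~ p(e|x) * [m+ N(x;+1,sx^2) + m- N(x;-1,sx^2)]
# is an exact two-Gaussian mixture by conjugacy; no MCMC is needed.
.sample_posterior_x <- function(e, prior_c, params, S) {
  q <- params$category_info
  sx2 <- params$sigma_x^2; se2 <- params$sigma_e^2
  s2 <- sx2 + se2
  n <- length(e)
  mp <- mode_weight_plus(prior_c, q)      # mixture weight, mode +1
  # component responsibilities ~ m_pm * N(e; +/-1, s2)
  la <- log(mp) + stats::dnorm(e, 1, sqrt(s2), log = TRUE)
  lb <- log1p(-mp) + stats::dnorm(e, -1, sqrt(s2), log = TRUE)
  r_plus <- 1 / (1 + exp(lb - la))
  # conjugate component posteriors
  mu_plus <- (se2 * 1 + sx2 * e) / s2
  mu_minus <- (se2 * -1 + sx2 * e) / s2
  sd_post <- sqrt(sx2 * se2 / s2)
  pick <- matrix(stats::runif(n * S), n, S) < r_plus
  mu <- ifelse(pick, mu_plus, mu_minus)
  x <- mu + sd_post * matrix(stats::rnorm(n * S), n, S)
  # raw weights w = 1 / (prior-weighted feature density)
  d_plus <- stats::dnorm(x, 1, params$sigma_x)   # N(x; +1, sx^2)
  d_minus <- stats::dnorm(x, -1, params$sigma_x)
  prior_x <- mp * d_plus + (1 - mp) * d_minus
  list(x = x, w = 1 / prior_x, d_plus = d_plus, d_minus = d_minus, mp = mp)
}

#' Draw importance samples of the latent feature for one frame
#'
#' Samples from the pseudo-posterior
#' \eqn{Q(x) \propto p(e|x) \sum_c p(x|C=c)\,\pi(c)} — analytically a
#' two-Gaussian mixture — together with the unnormalized importance
#' weights \eqn{w^{(s)} = [\sum_c p(x^{(s)}|C=c)\pi(c)]^{-1}} that
#' (asymptotically) undo the prior feedback.
#'
#' @param e scalar evidence value.
#' @param prior_c current belief P(C = +1), strictly inside (0, 1).
#' @param params a [task_params()] object.
#' @param config a [sampling_config()] object (supplies \code{n_samples}).
#' @return List with \code{samples} and \code{raw_weights}
#'   (length \code{n_samples} each).
#' @export
sample_posterior_x <- function(e, prior_c, params, config = sampling_config()) {
  check_prob(prior_c, "prior_c")
  out <- .sample_posterior_x(e, prior_c, params, config$n_samples)
  list(samples = drop(out$x), raw_weights = drop(out$w))
}

#' Importance-sampling estimate of the frame log likelihood odds
#'
#' \eqn{\widehat{LLO} = \log \frac{\sum_s p(x^{(s)}|C=+1) w^{(s)}}
#' {\sum_s p(x^{(s)}|C=-1) w^{(s)}}}. Self-normalizing the weights divides
#' numerator and denominator by the same constant, so the estimate is
#' algebraically identical with normalized or raw weights.
#'
#' @param samples feature samples from [sample_posterior_x()].
#' @param raw_weights their raw importance weights.
#' @param params a [task_params()] object.
#' @param config a [sampling_config()] object.
#' @return Scalar LLO estimate.
#' @export
importance_llo_estimate <- function(samples, raw_weights, params,
                                    config = sampling_config()) {
  if (any(!is.finite(raw_weights)) || all(raw_weights == 0))
    stop("importance weights are degenerate (all zero or non-finite)")
  w <- raw_weights
  if (config$normalize_weights) w <- w / sum(w)
  q <- params$category_info
  d_plus <- stats::dnorm(samples, 1, params$sigma_x)
  d_minus <- stats::dnorm(samples, -1, params$sigma_x)
  p_plus <- q * d_plus + (1 - q) * d_minus   # p(x | C = +1)
  p_minus <- q * d_minus + (1 - q) * d_plus  # p(x | C = -1)
  log(sum(p_plus * w)) - log(sum(p_minus * w))
}

# One belief sub-update for all trials at once; returns the new LPO vector.
.sampling_subupdate <- function(lpo, e, params, config) {
  q <- params$category_info
  S <- config$n_samples
  prior_c <- stats::plogis(lpo)
  sm <- .sample_posterior_x(e, prior_c, params, S)
  p_plus <- q * sm$d_plus + (1 - q) * sm$d_minus
  p_minus <- q * sm$d_minus + (1 - q) * sm$d_plus
  # normalization of w cancels in the ratio; use raw weights directly
  llo_hat <- log(rowSums(p_plus * sm$w)) - log(rowSums(p_minus * sm$w))
  gam_sub <- config$leak / config$n_updates
  (1 - gam_sub) * lpo + llo_hat / config$n_updates
}

#' Run the importance-sampling observer on one trial
#'
#' Per frame, performs \code{n_updates} belief sub-updates. Each sub-update
#' redraws \code{n_samples} feature samples given the current posterior-as-
#' prior, forms the importance-sampling LLO estimate, and applies the leaky
#' accumulation \eqn{LPO \gets (1-\gamma/n_U) LPO + \widehat{LLO}/n_U}.
#'
#' @param trial a list with an \code{evidence} vector.
#' @param params a [task_params()] object.
#' @param config a [sampling_config()] object.
#' @return An inference trace: \code{lpo} (per-frame, length
#'   \code{n_frames + 1}), \code{llo_estimates} (net per-frame increment
#'   before leak), \code{choice}.
#' @export
run_trial_sampling <- function(trial, params, config = sampling_config()) {
  e <- trial$evidence
  stopifnot(length(e) == params$n_frames)
  lpo <- numeric(params$n_frames + 1)
  lpo[1] <- logodds(params$category_prior)
  llo_est <- numeric(params$n_frames)
  cur <- lpo[1]
  for (f in seq_len(params$n_frames)) {
    prev <- cur
    for (u in seq_len(config$n_updates))
      cur <- .sampling_subupdate(cur, e[f], params, config)
    lpo[f + 1] <- cur
    llo_est[f] <- cur - (1 - config$leak) * prev
  }
  list(lpo = lpo, llo_estimates = llo_est,
       choice = choice_from_lpo(lpo[length(lpo)]))
}

#' Simulate many trials of the importance-sampling observer
#'
#' Vectorized across trials (all trials advance frame by frame together).
#'
#' @param n number of trials.
#' @param params a [task_params()] object.
#' @param config a [sampling_config()] object.
#' @return A [choice_dataset()] with the evidence as signals.
#' @export
sampling_observer <- function(n, params, config = sampling_config()) {
  tr <- sample_trials(n, params)
  lpo <- rep(logodds(params$category_prior), n)
  for (f in seq_len(params$n_frames)) {
    e <- tr$evidence[, f]
    for (u in seq_len(config$n_updates))
      lpo <- .sampling_subupdate(lpo, e, params, config)
  }
  choice_dataset(signals = tr$evidence, choices = choice_from_lpo(lpo),
                 categories = tr$categories, model = "sampling",
                 params = params)
}
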