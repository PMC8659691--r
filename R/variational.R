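#' Configuration of the mean-field variational observer
#'
#' The variational observer factorizes the joint posterior over the
#' category \eqn{C}, the per-frame feature \eqn{x_f} and its mode
#' indicator \eqn{z_f} into independent marginals and updates them by
#' coordinate ascent. Because the mean-field factorization discards the
#' posterior correlation between \eqn{x} and \eqn{C}, the feedback of the
#' categorical belief into the feature estimate cannot be divided out
#' exactly — an independent algorithmic route to the same confirmation
#' bias as the sampling observer.
#'
#' @param n_updates coordinate-ascent sweeps per stimulus frame.
#' @param leak integration leak \eqn{\gamma \in [0, 1)} applied to the
#'   categorical log odds (compounding to \eqn{\approx(1-\gamma)} per frame).
#' @param step_size feed-forward scaling \eqn{\eta \in (0, 1]} of the LLO
#'   increment; small values temper the attractor dynamics built into
#'   coordinate ascent (default 0.05).
#' @return An object of class \code{vb_config}.
#' @export
vb_config <- function(n_updates = 5, leak = 0, step_size = 0.05) {
  if (n_updates < 1) stop_domain("n_updates must be >= 1")
  if (leak < 0 || leak >= 1) stop_domain("leak must be in [0, 1)")
  if (step_size <= 0 || step_size > 1) stop_domain("step_size must be in (0, 1]")
  structure(list(n_updates = as.integer(n_updates), leak = leak,
                 step_size = step_size), class = "vb_config")
}

#' One coordinate-ascent sweep of the variational observer
#'
#' Updates, in order: the feature mean
#' \eqn{\mu_x \gets (\sigma_e^2 \mu_C \mu_z + \sigma_x^2 e) /
#' (\sigma_e^2 + \sigma_x^2)}; the mode-indicator log odds
#' \eqn{LPO_z \gets \log\frac{q}{1-q} + 2\mu_x\mu_C/(\sigma_e^2+\sigma_x^2)};
#' and the categorical log odds with the LLO estimate
#' \eqn{\widehat{LLO} = 2\mu_x\mu_z/\sigma_x^2} scaled by the step size and
#' combined with the per-sweep leak.
#'
#' @param e scalar evidence value for the current frame.
#' @param state list with \code{mu_x}, \code{lpo_z}, \code{lpo_c}
#'   (each may be a vector across trials).
#' @param params a [task_params()] object.
#' @param config a [vb_config()] object.
#' @return Updated state (same shape), with the LLO estimate attached as
#'   \code{llo_hat}.
#' @export
vb_frame_update <- function(e, state, params, config = vb_config()) {
  q <- params$category_info
  sx2 <- params$sigma_x^2; se2 <- params$sigma_e^2
  mu_c <- tanh(state$lpo_c / 2)
  mu_z <- tanh(state$lpo_z / 2)
  mu_x <- (se2 * mu_c * mu_z + sx2 * e) / (se2 + sx2)
  lpo_z <- logodds(q) + 2 * mu_x * mu_c / (se2 + sx2)
  mu_z <- tanh(lpo_z / 2)
  llo_hat <- 2 * mu_x * mu_z / sx2
  gam_sub <- config$leak / config$n_updates
  lpo_c <- (1 - gam_sub) * state$lpo_c + config$step_size * llo_hat
  list(mu_x = mu_x, lpo_z = lpo_z, lpo_c = lpo_c, llo_hat = llo_hat)
}

# Fresh per-frame state: feature mean seeded at the likelihood mean e,
# mode-indicator odds at their prior; categorical odds carried across frames.
.vb_frame_init <- function(e, lpo_c, params) {
  list(mu_x = e, lpo_z = rep(logodds(params$category_info), length(e)),
       lpo_c = lpo_c)
}

#' Run the variational observer on one trial
#'
#' Sequential (streaming) inference: frames are processed in order, each
#' with \code{n_updates} coordinate-ascent sweeps; the categorical log
#' odds carry across frames as the prior. Choice is the sign of the final
#' categorical log odds.
#'
#' @param trial a list with an \code{evidence} vector.
#' @param params a [task_params()] object.
#' @param config a [vb_config()] object.
#' @return An inference trace: \code{lpo}, \code{llo_estimates},
#'   \code{choice}.
#' @export
run_trial_vb <- function(trial, params, config = vb_config()) {
  e <- trial$evidence
  stopifnot(length(e) == params$n_frames)
  lpo <- numeric(params$n_frames + 1)
  lpo[1] <- logodds(params$category_prior)
  llo_est <- numeric(params$n_frames)
  for (f in seq_len(params$n_frames)) {
    st <- .vb_frame_init(e[f], lpo[f], params)
    for (u in seq_len(config$n_updates))
      st <- vb_frame_update(e[f], st, params, config)
    lpo[f + 1] <- st$lpo_c
    llo_est[f] <- st$lpo_c - (1 - config$leak) * lpo[f]
  }
  list(lpo = lpo, llo_estimates = llo_est,
       choice = choice_from_lpo(lpo[length(lpo)]))
}

#' Simulate many trials of the variational observer
#'
#' @param n number of trials.
#' @param params a [task_params()] object.
#' @param config a [vb_config()] object.
#' @return A [choice_dataset()] with the evidence as signals.
#' @export
variational_observer <- function(n, params, config = vb_config()) {
  tr <- sample_trials(n, params)
  lpo_c <- rep(logodds(params$category_prior), n)
  for (f in seq_len(params$n_frames)) {
    e <- tr$evidence[, f]
    st <- .vb_frame_init(e, lpo_c, params)
    for (u in seq_len(config$n_updates))
      st <- vb_frame_update(e, st, params, config)
    lpo_c <- st$lpo_c
  }
  choice_dataset(signals = tr$evidence, choices = choice_from_lpo(lpo_c),
                 categories = tr$categories, model = "variational",
                 params = params)
}
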