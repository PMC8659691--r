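#' Parameters of the Extended integration-to-bound observer
#'
#' A leaky/accelerating noisy accumulator of per-frame log likelihood odds
#' with a sticky absorbing bound and a lapse-and-temperature choice rule:
#' \deqn{LPO_f = (1-\alpha) LPO_{f-1} + LLO_f + \epsilon_f,\quad
#'   \epsilon_f \sim N(0, \sigma_\epsilon^2)}
#' with \eqn{LPO_0 = \log\frac{p_C}{1-p_C}}. On the first frame where
#' \eqn{|LPO| \ge B} the accumulator sticks at \eqn{\pm B} for the rest of
#' the trial. The final choice is +1 with probability
#' \eqn{\lambda + (1-2\lambda)\,\sigma(LPO_F / T)}.
#'
#' @param category_prior prior probability of category +1 (\eqn{p_C}).
#' @param lapse symmetric lapse rate \eqn{\lambda \in [0, 0.5]}.
#' @param temperature decision temperature \eqn{T > 0}.
#' @param noise per-frame integration noise std \eqn{\sigma_\epsilon \ge 0}.
#' @param bound absorbing symmetric bound \eqn{B > 0}; \code{Inf} allowed.
#' @param leak leak \eqn{\alpha \in [-1, 1]}; negative values self-reinforce
#'   (confirmation-bias dynamics), positive values forget.
#' @param signal_scale evidence scale \eqn{s > 0} used when mapping raw
#'   signals to log odds (see [signal_to_llo()]); 1 when the mapping is
#'   exactly known.
#' @return An object of class \code{itb_params}.
#' @export
itb_params <- function(category_prior = 0.5, lapse = 0, temperature = 1,
                       noise = 0, bound = Inf, leak = 0, signal_scale = 1) {
  check_prob(category_prior, "category_prior")
  if (lapse < 0 || lapse > 0.5) stop_domain("lapse must be in [0, 0.5]")
  if (temperature <= 0) stop_domain("temperature must be > 0")
  if (noise < 0) stop_domain("noise must be >= 0")
  if (bound <= 0) stop_domain("bound must be > 0")
  if (leak < -1 || leak > 1) stop_domain("leak must be in [-1, 1]")
  if (signal_scale <= 0) stop_domain("signal_scale must be > 0")
  structure(list(category_prior = category_prior, lapse = lapse,
                 temperature = temperature, noise = noise, bound = bound,
                 leak = leak, signal_scale = signal_scale),
            class = "itb_params")
}

#' @export
print.itb_params <- function(x, ...) {
  cat("Extended ITB parameters\n")
  cat(sprintf("  p_C = %.3f  lapse = %.3f  T = %.3f  noise = %.3f\n",
              x$category_prior, x$lapse, x$temperature, x$noise))
  cat(sprintf("  bound = %s  leak = %+.3f  signal scale = %.3f\n",
              format(x$bound), x$leak, x$signal_scale))
  invisible(x)
}

#' Map scalar signals to log likelihood odds
#'
#' \eqn{LLO = g(S/s)} where \eqn{a = S/s} is interpreted as the log odds
#' of the frame's feature sign and
#' \deqn{g(a) = \log\frac{q e^{a/2} + (1-q) e^{-a/2}}{(1-q) e^{a/2} + q e^{-a/2}}}
#' is the sigmoidal correction for category information \eqn{q < 1}.
#' For \eqn{q = 1}, \eqn{g} is the identity; for \eqn{q = 0.5} it is
#' identically 0. For model-generated evidence the exact feature-sign log
#' odds are \eqn{a = 2e/(\sigma_x^2+\sigma_e^2)}, making \eqn{g(a)} equal
#' to [frame_llo()].
#'
#' @param signals numeric vector or matrix of signals.
#' @param scale evidence scale \eqn{s > 0}.
#' @param category_info match probability \eqn{q}.
#' @return Log likelihood odds, same shape as \code{signals}.
#' @export
signal_to_llo <- function(signals, scale = 1, category_info = 0.9) {
  if (scale <= 0) stop_domain("scale must be > 0")
  q <- category_info
  a <- signals / (2 * scale)   # half log odds of the feature sign
  out <- logaddexp(log(q) + a, log1p(-q) - a) -
    logaddexp(log1p(-q) + a, log(q) - a)
  if (is.matrix(signals)) dim(out) <- dim(signals)
  out
}

#' Simulate Extended ITB choices for a set of LLO sequences
#'
#' Monte-Carlo simulation of the accumulator (one stochastic path per
#' trial): noisy leaky integration, sticky bound, then the
#' lapse/temperature choice rule. Noise is added before the bound check
#' within each frame, as in the update equation.
#'
#' @param llo matrix (\code{n x F}) of per-frame log likelihood odds, or a
#'   single-trial vector.
#' @param params an [itb_params()] object.
#' @return List with \code{lpo_final} and \code{choice} (each length
#'   \code{n}).
#' @export
simulate_itb <- function(llo, params) {
  if (!is.matrix(llo)) llo <- matrix(llo, nrow = 1)
  n <- nrow(llo); F <- ncol(llo)
  B <- params$bound
  lpo <- rep(logodds(params$category_prior), n)
  stuck <- abs(lpo) >= B
  lpo[stuck] <- sign(lpo[stuck]) * B
  for (f in seq_len(F)) {
    act <- !stuck
    if (any(act)) {
      upd <- (1 - params$leak) * lpo[act] + llo[act, f]
      if (params$noise > 0)
        upd <- upd + params$noise * stats::rnorm(sum(act))
      hit <- abs(upd) >= B
      upd[hit] <- sign(upd[hit]) * B
      lpo[act] <- upd
      stuck[act] <- hit
    }
  }
  p_plus <- params$lapse + (1 - 2 * params$lapse) *
    stats::plogis(lpo / params$temperature)
  choice <- ifelse(stats::runif(n) < p_plus, 1, -1)
  list(lpo_final = lpo, choice = choice)
}

#' Simulate one Extended ITB trial
#'
#' @param llo_seq per-frame LLO vector for one trial.
#' @param params an [itb_params()] object.
#' @return List with scalar \code{lpo_final} and \code{choice}.
#' @export
simulate_itb_choice <- function(llo_seq, params) {
  out <- simulate_itb(matrix(llo_seq, nrow = 1), params)
  list(lpo_final = out$lpo_final[1], choice = out$choice[1])
}

#' Exact Extended ITB choice probability by discretized propagation
#'
#' Deterministic (non-stochastic) choice probability, marginalizing the
#' integration noise by propagating a probability mass vector over LPO
#' discretized into bins of width at most 0.01 between \eqn{-B} and
#' \eqn{+B}, with two absorbing masses at the bounds. The grid is clipped
#' at \code{clip} (conventionally 3 times the largest log posterior odds
#' reached by the ideal observer on the dataset at hand, see
#' [lpo_clip()]). The noise transition uses the Gaussian kernel integrated
#' over destination bins (CDF differences); zero noise is a deterministic
#' shift deposited by linear interpolation between bins.
#'
#' @param llo matrix (\code{n x F}) of per-frame LLOs, or a single-trial
#'   vector.
#' @param params an [itb_params()] object.
#' @param clip grid clipping value (finite, > 0); caps the effective bound.
#' @param bin_width requested bin width; must be <= 0.01.
#' @param engine \code{"cpp"} (fast path: analytic Gaussian recursion for
#'   trials that provably stay away from the bound, shared transition
#'   operator with an interpolated per-trial LLO shift) or
#'   \code{"reference"} (pure-R full propagation with per-source exact
#'   kernels; slow, used for validation).
#' @return Vector of P(choice = +1), one per trial.
#' @export
itb_choice_probability <- function(llo, params, clip = 20,
                                   bin_width = 0.01,
                                   engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  if (bin_width > 0.01) stop_domain("bin_width must be <= 0.01")
  if (!is.finite(clip) || clip <= 0) stop_domain("clip must be finite and > 0")
  if (!is.matrix(llo)) llo <- matrix(llo, nrow = 1)
  if (any(!is.finite(llo))) stop_domain("llo must be finite")
  if (engine == "cpp") {
    p <- itb_choice_prob_cpp(llo, logodds(params$category_prior),
                             params$lapse, params$temperature, params$noise,
                             params$bound, params$leak, clip, bin_width)
  } else {
    p <- .itb_prob_reference(llo, params, clip, bin_width)
  }
  if (any(!is.finite(p))) stop("non-finite propagated mass")
  p
}

#' Grid clipping value for a dataset of LLO sequences
#'
#' The largest log posterior odds the ideal observer reaches on the
#' dataset, \eqn{\max_i |\sum_f LLO_{if}| + |LPO_0|}, times 3 — the
#' conventional clip for the discretized propagation grid.
#'
#' @param llo matrix of per-frame LLOs.
#' @param category_prior prior probability of category +1.
#' @return Scalar clip value.
#' @export
lpo_clip <- function(llo, category_prior = 0.5) {
  if (!is.matrix(llo)) llo <- matrix(llo, nrow = 1)
  peak <- if (nrow(llo) > 0) max(abs(rowSums(llo))) else 0
  max(1, 3 * (peak + abs(logodds(category_prior))))
}

# Pure-R reference propagation: full per-source CDF-difference kernel,
# no analytic shortcut, no LLO rounding. O(F * n_bins^2) per trial.
.itb_prob_reference <- function(llo, params, clip, bin_width) {
  B <- min(params$bound, clip)
  nb <- max(8L, as.integer(ceiling(2 * B / bin_width)))
  h <- 2 * B / nb
  centers <- -B + (seq_len(nb) - 0.5) * h
  edges <- -B + (0:nb) * h
  lam <- params$lapse; Tt <- params$temperature
  crule <- function(u) lam + (1 - 2 * lam) * stats::plogis(u / Tt)
  n <- nrow(llo); F <- ncol(llo)
  lpo0 <- logodds(params$category_prior)
  out <- numeric(n)
  for (t in seq_len(n)) {
    a_plus <- 0; a_minus <- 0
    g <- numeric(nb)
    if (lpo0 >= B) a_plus <- 1 else if (lpo0 <= -B) a_minus <- 1 else {
      fi <- (lpo0 + B) / h - 0.5
      i0 <- floor(fi); w <- fi - i0
      # deposit a point mass by linear interpolation
      ii <- pmin(pmax(c(i0, i0 + 1), 0), nb - 1) + 1
      g[ii[1]] <- g[ii[1]] + (1 - w); g[ii[2]] <- g[ii[2]] + w
    }
    for (f in seq_len(F)) {
      if (a_plus + a_minus > 1 - 1e-14) break
      mu <- (1 - params$leak) * centers + llo[t, f]
      gn <- numeric(nb)
      if (params$noise == 0) {
        for (j in seq_len(nb)) {
          if (g[j] == 0) next
          if (mu[j] >= B) a_plus <- a_plus + g[j]
          else if (mu[j] <= -B) a_minus <- a_minus + g[j]
          else {
            fi <- (mu[j] + B) / h - 0.5
            i0 <- floor(fi); w <- fi - i0
            lo <- i0 + 1; hi <- i0 + 2
            if (lo >= 1) gn[lo] <- gn[lo] + g[j] * (1 - w) else a_minus <- a_minus + g[j] * (1 - w)
            if (hi <= nb) gn[hi] <- gn[hi] + g[j] * w else a_plus <- a_plus + g[j] * w
          }
        }
      } else {
        for (j in seq_len(nb)) {
          if (g[j] == 0) next
          pcdf <- stats::pnorm(edges, mu[j], params$noise)
          gn <- gn + g[j] * diff(pcdf)
          a_minus <- a_minus + g[j] * pcdf[1]
          a_plus <- a_plus + g[j] * (1 - pcdf[nb + 1])
        }
      }
      g <- gn
    }
    out[t] <- sum(g * crule(centers)) + a_plus * crule(B) + a_minus * crule(-B)
  }
  out
}

#' Simulate an Extended ITB observer on freshly sampled task trials
#'
#' Samples trials from the generative task model, computes the exact
#' per-frame LLOs, and runs the Extended ITB accumulator on them.
#'
#' @param n number of trials.
#' @param params a [task_params()] object.
#' @param itb an [itb_params()] object.
#' @return A [choice_dataset()] with the evidence as signals.
#' @export
itb_observer <- function(n, params, itb) {
  tr <- sample_trials(n, params)
  llo <- frame_llo(tr$evidence, params)
  sim <- simulate_itb(llo, itb)
  choice_dataset(signals = tr$evidence, choices = sim$choice,
                 categories = tr$categories, model = "itb", params = params)
}
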