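## Posterior inference over Extended ITB parameters by Metropolis-Hastings
## with the exact discretized likelihood.

# Parameter vector layout used throughout the sampler.
.itb_par_names <- c("category_prior", "lapse", "temperature", "noise",
                    "bound", "leak", "signal_scale")

#' Priors over Extended ITB parameters
#'
#' The standard priors: \eqn{p_C \sim} Beta(2,2), \eqn{\lambda \sim}
#' Beta(1,10), \eqn{T \sim} Exponential(mean 4), \eqn{\sigma_\epsilon \sim}
#' Exponential(mean 0.25), \eqn{B \sim} Gamma(shape 2, scale 3),
#' \eqn{\alpha \sim} Uniform\eqn{[-1,1]}, \eqn{s \sim} Exponential(mean 20).
#'
#' @return List with \code{log_density(theta)}, \code{quantile(u)} (maps a
#'   point in the unit hypercube to parameter space), and \code{qmarginal}
#'   (per-parameter quantile functions).
#' @export
itb_priors <- function() {
  qfuns <- list(
    category_prior = function(u) stats::qbeta(u, 2, 2),
    lapse = function(u) stats::qbeta(u, 1, 10),
    temperature = function(u) stats::qexp(u, rate = 1 / 4),
    noise = function(u) stats::qexp(u, rate = 1 / 0.25),
    bound = function(u) stats::qgamma(u, shape = 2, scale = 3),
    leak = function(u) 2 * u - 1,
    signal_scale = function(u) stats::qexp(u, rate = 1 / 20))
  log_density <- function(theta) {
    th <- as.numeric(theta)
    if (th[1] <= 0 || th[1] >= 1 || th[2] < 0 || th[2] > 1 ||
        th[3] <= 0 || th[4] < 0 || th[5] <= 0 ||
        th[6] < -1 || th[6] > 1 || th[7] <= 0) return(-Inf)
    if (th[2] > 0.5) return(-Inf)  # lapse constrained to [0, 0.5]
    stats::dbeta(th[1], 2, 2, log = TRUE) +
      stats::dbeta(th[2], 1, 10, log = TRUE) +
      stats::dexp(th[3], rate = 1 / 4, log = TRUE) +
      stats::dexp(th[4], rate = 1 / 0.25, log = TRUE) +
      stats::dgamma(th[5], shape = 2, scale = 3, log = TRUE) +
      stats::dunif(th[6], -1, 1, log = TRUE) +
      stats::dexp(th[7], rate = 1 / 20, log = TRUE)
  }
  quantile <- function(u) {
    stats::setNames(vapply(seq_along(qfuns),
                           function(j) qfuns[[j]](u[j]), 0), .itb_par_names)
  }
  list(log_density = log_density, quantile = quantile, qmarginal = qfuns)
}

#' Extended ITB log-likelihood of observed choices
#'
#' Sum over trials of the log Bernoulli likelihood of each observed choice
#' under the exact discretized choice probability
#' ([itb_choice_probability()]), with signals mapped to log odds by
#' [signal_to_llo()].
#'
#' @param theta named parameter vector (see [itb_params()] fields).
#' @param data a [choice_dataset()].
#' @param category_info match probability \eqn{q} of the task.
#' @param logodds_signals optional matrix of signals already on the
#'   feature-sign log-odds scale (exactly known for model-generated data:
#'   \eqn{2e/(\sigma_x^2+\sigma_e^2)}); defaults to raw \code{data$signals}.
#' @param clip grid clipping value; defaults to [lpo_clip()] of the
#'   dataset's log-odds signals at unit scale.
#' @return Log-likelihood (\code{-Inf} with a warning attribute if the
#'   propagation degenerates).
#' @export
itb_log_likelihood <- function(theta, data, category_info,
                               logodds_signals = NULL, clip = NULL) {
  a <- logodds_signals %||% data$signals
  if (is.null(clip)) clip <- lpo_clip(signal_to_llo(a, 1, category_info))
  llo <- signal_to_llo(a, theta[["signal_scale"]], category_info)
  p <- tryCatch(
    itb_choice_prob_cpp(llo, logodds(theta[["category_prior"]]),
                        theta[["lapse"]], theta[["temperature"]],
                        theta[["noise"]], theta[["bound"]], theta[["leak"]],
                        clip, 0.01),
    error = function(e) NULL)
  if (is.null(p) || any(!is.finite(p))) return(-Inf)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- data$choices > 0
  sum(log(p[y])) + sum(log1p(-p[!y]))
}

#' Run Metropolis-Hastings chains for the Extended ITB model
#'
#' Component-wise Gaussian random-walk MH on the natural parameter scale.
#' Each chain is initialized at the best of a block of quasi-random
#' (Halton) draws from the prior, proposal scales are adapted during a
#' pilot phase targeting 20-40% acceptance and then frozen, and one
#' recorded step is one sweep over the free parameters.
#'
#' @param data a [choice_dataset()].
#' @param category_info task match probability \eqn{q}.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_steps recorded sweeps per chain (after the pilot phase).
#' @param n_adapt pilot sweeps used for proposal adaptation (discarded).
#' @param n_scan quasi-random prior draws scanned for initialization,
#'   split across chains.
#' @param fix_scale fix the evidence scale \eqn{s} (to
#'   \code{scale_value}) instead of sampling it — the convention when the
#'   signal-to-log-odds mapping is exactly known.
#' @param scale_value value of \eqn{s} when fixed.
#' @param logodds_signals,clip passed to [itb_log_likelihood()].
#' @param scan_trials max trials used in the (heuristic) initialization
#'   scan likelihood (the scan only picks starting points).
#' @return List with \code{samples} (list of \code{n_steps x 7} matrices),
#'   \code{log_posteriors}, \code{acceptance} rates, and the frozen
#'   proposal \code{scales}.
#' @export
run_mh_chains <- function(data, category_info, n_chains = 4, n_steps = 2000,
                          n_adapt = max(100, n_steps %/% 4), n_scan = 500,
                          fix_scale = TRUE, scale_value = 1,
                          logodds_signals = NULL, clip = NULL,
                          scan_trials = 300) {
  pri <- itb_priors()
  a_full <- logodds_signals %||% data$signals
  if (is.null(clip)) clip <- lpo_clip(signal_to_llo(a_full, 1, category_info))
  loglik <- function(theta, dat, a) itb_log_likelihood(theta, dat, category_info,
                                                       logodds_signals = a,
                                                       clip = clip)
  free <- if (fix_scale) 1:6 else 1:7
  # initial proposal scales (refined by pilot adaptation); deliberately
  # tighter than the prior sd for the dynamics parameters, whose distant
  # proposals are also the most expensive to evaluate
  init_scale <- c(0.08, 0.03, 0.4, 0.08, 0.8, 0.08, 4)

  n <- nrow(data$signals)
  sub <- if (n > scan_trials) sort(sample.int(n, scan_trials)) else seq_len(n)
  dsub <- choice_dataset(data$signals[sub, , drop = FALSE],
                         data$choices[sub], data$categories[sub])
  asub <- a_full[sub, , drop = FALSE]

  chains <- vector("list", n_chains)
  lps <- vector("list", n_chains)
  acc_rates <- matrix(NA_real_, n_chains, 7,
                      dimnames = list(NULL, .itb_par_names))
  scales_out <- matrix(NA_real_, n_chains, 7)

  block <- max(20L, n_scan %/% n_chains)
  for (ch in seq_len(n_chains)) {
    # initialization: best of this chain's quasi-random prior block
    H <- halton(block, length(free), skip = (ch - 1) * block + 10)
    best <- NULL; best_lp <- -Inf
    for (i in seq_len(block)) {
      u <- stats::runif(7) # placeholder, overwritten for free params
      theta <- pri$quantile(replace(u, free, H[i, ]))
      if (fix_scale) theta["signal_scale"] <- scale_value
      lp <- pri$log_density(theta) + loglik(theta, dsub, asub)
      if (lp > best_lp) { best_lp <- lp; best <- theta }
    }
    if (is.null(best)) best <- pri$quantile(rep(0.5, 7))  # all-rejected scan
    if (fix_scale) best["signal_scale"] <- scale_value
    theta <- best
    lp_cur <- pri$log_density(theta) + loglik(theta, data, a_full)

    sd_prop <- init_scale
    acc_win <- matrix(0, 2, 7)  # accepted / proposed since last adaptation
    samples <- matrix(NA_real_, n_steps, 7,
                      dimnames = list(NULL, .itb_par_names))
    lp_trace <- numeric(n_steps)
    rejected_run <- 0
    total <- n_adapt + n_steps
    for (step in seq_len(total)) {
      for (j in free) {
        prop <- theta
        prop[j] <- prop[j] + sd_prop[j] * stats::rnorm(1)
        lpri <- pri$log_density(prop)
        accept <- FALSE
        if (is.finite(lpri)) {
          lp_prop <- lpri + loglik(prop, data, a_full)
          if (is.finite(lp_prop) &&
              log(stats::runif(1)) < lp_prop - lp_cur) {
            accept <- TRUE
            lp_cur <- lp_prop
          }
        }
        acc_win[2, j] <- acc_win[2, j] + 1
        if (accept) {
          theta <- prop
          acc_win[1, j] <- acc_win[1, j] + 1
          rejected_run <- 0
        } else rejected_run <- rejected_run + 1
      }
      if (step <= n_adapt && step %% 5 == 0) {
        rate <- acc_win[1, free] / pmax(acc_win[2, free], 1)
        sd_prop[free] <- sd_prop[free] * exp(1.5 * (rate - 0.3))
        acc_win[] <- 0
      }
      if (step > n_adapt) {
        samples[step - n_adapt, ] <- theta
        lp_trace[step - n_adapt] <- lp_cur
      }
      if (rejected_run > 60 * length(free))
        warning("MH chain rejecting all proposals; proposal scales may need adaptation")
    }
    chains[[ch]] <- samples
    lps[[ch]] <- lp_trace
    acc_rates[ch, ] <- acc_win[1, ] / pmax(acc_win[2, ], 1)
    scales_out[ch, ] <- sd_prop
  }
  list(samples = chains, log_posteriors = lps, acceptance = acc_rates,
       scales = scales_out, clip = clip, fixed_scale = fix_scale)
}

#' Convergence diagnostics for MH chains
#'
#' Per-chain burn-in is the index of the first sample whose log posterior
#' exceeds that chain's median log posterior, capped at 20% of the chain
#' length. The Gelman-Rubin statistic is the split-\eqn{\hat R}: each
#' post-burn-in chain is split in half and between/within-half variances
#' compared. \eqn{\hat R < 1.1} is the conventional convergence criterion.
#'
#' @param chains list of sample matrices (one per chain).
#' @param log_posteriors list of log-posterior traces.
#' @return List with \code{rhat} (per parameter) and \code{burn_in}
#'   (per chain).
#' @export
convergence_diagnostics <- function(chains, log_posteriors) {
  if (length(chains) < 2) stop_domain("R-hat requires at least 2 chains")
  burn <- vapply(seq_along(chains), function(ch) {
    lp <- log_posteriors[[ch]]
    cap <- max(1L, as.integer(floor(0.2 * length(lp))))
    idx <- which(lp > stats::median(lp))[1]
    if (is.na(idx)) cap else min(idx, cap)
  }, 0L)
  keep <- lapply(seq_along(chains), function(ch)
    chains[[ch]][-seq_len(burn[ch]), , drop = FALSE])
  L <- min(vapply(keep, nrow, 0L))
  L <- L - (L %% 2)
  halves <- list()
  for (k in keep) {
    k <- k[seq_len(L), , drop = FALSE]
    halves <- c(halves, list(k[1:(L / 2), , drop = FALSE],
                             k[(L / 2 + 1):L, , drop = FALSE]))
  }
  P <- ncol(chains[[1]])
  rhat <- vapply(seq_len(P), function(p) {
    m <- length(halves)
    nn <- L / 2
    means <- vapply(halves, function(hh) mean(hh[, p]), 0)
    vars <- vapply(halves, function(hh) stats::var(hh[, p]), 0)
    W <- mean(vars)
    Bv <- nn * stats::var(means)
    if (!is.finite(W) || W <= 0) return(NaN)  # degenerate constant chains
    sqrt(((nn - 1) / nn * W + Bv / nn) / W)
  }, 0)
  names(rhat) <- colnames(chains[[1]])
  list(rhat = rhat, burn_in = burn)
}

#' Fit the Extended ITB model to choice data
#'
#' The package's main fitting function: posterior inference over the seven
#' Extended ITB parameters (category prior, lapse, temperature,
#' integration noise, bound, leak, evidence scale) from per-trial signals
#' and choices, by Metropolis-Hastings with the exact discretized
#' likelihood. Returns a classed fit with \code{print}, \code{summary},
#' \code{coef}, \code{plot} and \code{simulate} methods.
#'
#' @inheritParams run_mh_chains
#' @param ... passed to [run_mh_chains()].
#' @return An object of class \code{itb_fit}.
#' @export
fit_itb <- function(data, category_info, n_chains = 4, n_steps = 2000,
                    fix_scale = TRUE, scale_value = 1,
                    logodds_signals = NULL, ...) {
  a <- logodds_signals %||% data$signals
  mh <- run_mh_chains(data, category_info, n_chains = n_chains,
                      n_steps = n_steps, fix_scale = fix_scale,
                      scale_value = scale_value, logodds_signals = a, ...)
  if (n_chains >= 2) {
    diag <- convergence_diagnostics(mh$samples, mh$log_posteriors)
  } else {
    # single-chain fits carry no R-hat; burn-in still follows the
    # median-log-posterior rule
    diag <- list(rhat = stats::setNames(rep(NA_real_, 7), .itb_par_names),
                 burn_in = vapply(seq_along(mh$samples), function(ch) {
                   lp <- mh$log_posteriors[[ch]]
                   cap <- max(1L, as.integer(floor(0.2 * length(lp))))
                   idx <- which(lp > stats::median(lp))[1]
                   if (is.na(idx)) cap else min(idx, cap)
                 }, 0L))
  }
  structure(list(chains = mh$samples, log_posteriors = mh$log_posteriors,
                 acceptance = mh$acceptance, rhat = diag$rhat,
                 burn_in = diag$burn_in, category_info = category_info,
                 clip = mh$clip, fixed_scale = fix_scale,
                 logodds_signals = a, data = data,
                 n_chains = n_chains, n_steps = n_steps),
            class = "itb_fit")
}

#' Post-burn-in posterior samples, optionally thinned
#'
#' @param fit an [fit_itb()] result.
#' @param thin_to samples retained per chain (\code{Inf} keeps all).
#' @return Matrix of posterior samples (rows) by parameter (columns).
#' @export
posterior_samples <- function(fit, thin_to = Inf) {
  out <- lapply(seq_along(fit$chains), function(ch) {
    s <- fit$chains[[ch]][-seq_len(fit$burn_in[ch]), , drop = FALSE]
    if (is.finite(thin_to) && nrow(s) > thin_to)
      s <- s[round(seq(1, nrow(s), length.out = thin_to)), , drop = FALSE]
    s
  })
  do.call(rbind, out)
}

#' @export
print.itb_fit <- function(x, ...) {
  cat(sprintf("Extended ITB fit: %d chains x %d steps (%d trials)\n",
              x$n_chains, x$n_steps, nrow(x$data$signals)))
  med <- apply(posterior_samples(x), 2, stats::median)
  cat("  posterior medians:\n")
  for (p in names(med))
    cat(sprintf("    %-15s %8.3f   (Rhat %.3f)\n", p, med[p], x$rhat[p]))
  invisible(x)
}

#' @export
summary.itb_fit <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                            ...) {
  s <- posterior_samples(object)
  qs <- t(apply(s, 2, stats::quantile, probs = probs))
  structure(list(quantiles = qs, rhat = object$rhat,
                 burn_in = object$burn_in, acceptance = object$acceptance),
            class = "summary.itb_fit")
}

#' @export
print.summary.itb_fit <- function(x, ...) {
  cat("Posterior quantiles:\n")
  print(round(x$quantiles, 4))
  cat("\nR-hat:\n")
  print(round(x$rhat, 4))
  invisible(x)
}

#' @export
coef.itb_fit <- function(object, ...) {
  apply(posterior_samples(object), 2, stats::median)
}

#' @export
plot.itb_fit <- function(x, pars = c("leak", "bound", "noise"), ...) {
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    traces <- lapply(x$chains, function(s) s[, p])
    graphics::plot(traces[[1]], type = "l", ylab = p, xlab = "",
                   ylim = range(unlist(traces)), ...)
    for (ch in seq_along(traces)[-1])
      graphics::lines(traces[[ch]], col = ch)
  }
  invisible(x)
}

#' Posterior-predictive choice simulation from a fit
#'
#' Per retained posterior sample, simulates one choice per trial from the
#' Extended ITB model on the fitted dataset's signals.
#'
#' @param object an [fit_itb()] result.
#' @param nsim number of posterior draws used (thinned per chain).
#' @param seed optional seed.
#' @param ablation \code{"none"}, \code{"leak_zero"} (sets \eqn{\alpha=0})
#'   or \code{"bound_infinite"} (sets \eqn{B=\infty,\ \sigma_\epsilon=0}).
#' @param ... unused.
#' @return Matrix (draws x trials) of simulated choices in \eqn{\pm 1}.
#' @export
simulate.itb_fit <- function(object, nsim = 100, seed = NULL,
                             ablation = c("none", "leak_zero",
                                          "bound_infinite"), ...) {
  ablation <- match.arg(ablation)
  if (!is.null(seed)) set.seed(seed)
  draws <- posterior_samples(object, thin_to = ceiling(nsim / object$n_chains))
  if (nrow(draws) > nsim) draws <- draws[seq_len(nsim), , drop = FALSE]
  out <- matrix(NA_real_, nrow(draws), nrow(object$data$signals))
  for (i in seq_len(nrow(draws))) {
    th <- draws[i, ]
    th <- .apply_ablation(th, ablation)
    llo <- signal_to_llo(object$logodds_signals, th[["signal_scale"]],
                         object$category_info)
    pars <- itb_params(category_prior = th[["category_prior"]],
                       lapse = th[["lapse"]], temperature = th[["temperature"]],
                       noise = th[["noise"]], bound = th[["bound"]],
                       leak = th[["leak"]], signal_scale = th[["signal_scale"]])
    out[i, ] <- simulate_itb(llo, pars)$choice
  }
  out
}

.apply_ablation <- function(theta, ablation) {
  if (ablation == "leak_zero") theta[["leak"]] <- 0
  if (ablation == "bound_infinite") {
    theta[["bound"]] <- Inf
    theta[["noise"]] <- 0
  }
  theta
}
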