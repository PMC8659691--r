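#' Parameters of the generative task model
#'
#' The task is a three-variable hierarchical generative model
#' \eqn{C \to x_f \to e_f}: a binary trial category \eqn{C \in \{-1,+1\}},
#' a latent sensory feature \eqn{x_f} per frame drawn from a two-Gaussian
#' mixture whose mode matches \eqn{C} with probability equal to the
#' category information, and an observed evidence scalar \eqn{e_f} drawn
#' from a Gaussian around \eqn{x_f}.
#'
#' @param category_prior probability that the trial category is +1.
#' @param category_info probability that a frame's feature mode matches the
#'   category (per-frame match probability / AUC between \eqn{x_f} and
#'   \eqn{C}); in \code{[0.5, 1]}.
#' @param sigma_x standard deviation of the feature around its mode. The
#'   modes sit at \eqn{\pm 1}; the scale is otherwise free and defaults to 1.
#' @param sigma_e standard deviation of the evidence around the feature.
#'   Determines the sensory information via [sensory_information()].
#' @param n_frames number of evidence frames per trial (10 in the task this
#'   model emulates).
#'
#' @return An object of class \code{task_params}.
#' @seealso [sample_trials()], [sensory_information()], [frame_llo()]
#' @export
task_params <- function(category_prior = 0.5, category_info = 0.9,
                        sigma_x = 1, sigma_e = 1, n_frames = 10) {
  check_prob(category_prior, "category_prior")
  if (!is.numeric(category_info) || category_info < 0.5 || category_info > 1)
    stop_domain("category_info must be in [0.5, 1]")
  if (!is.numeric(sigma_x) || sigma_x <= 0) stop_domain("sigma_x must be > 0")
  if (!is.numeric(sigma_e) || sigma_e <= 0) stop_domain("sigma_e must be > 0")
  if (n_frames < 1 || n_frames != round(n_frames))
    stop_domain("n_frames must be a positive integer")
  structure(list(category_prior = category_prior,
                 category_info = category_info,
                 sigma_x = sigma_x, sigma_e = sigma_e,
                 n_frames = as.integer(n_frames)),
            class = "task_params")
}

#' @export
print.task_params <- function(x, ...) {
  cat("Generative task model (C -> x_f -> e_f)\n")
  cat(sprintf("  P(C = +1)            : %.3f\n", x$category_prior))
  cat(sprintf("  category information : %.3f\n", x$category_info))
  cat(sprintf("  sensory information  : %.3f  (sigma_e = %.3f)\n",
              sensory_information(x$sigma_e), x$sigma_e))
  cat(sprintf("  sigma_x              : %.3f\n", x$sigma_x))
  cat(sprintf("  frames per trial     : %d\n", x$n_frames))
  invisible(x)
}

#' Sensory information of one evidence frame
#'
#' Discriminability of the latent feature's sign from a single evidence
#' frame, quantified as the area under the ROC curve for the two
#' evidence distributions: \eqn{\Phi(2/\sigma_e)} where \eqn{\Phi} is the
#' standard normal CDF. Approaches 0.5 (chance) as \eqn{\sigma_e \to \infty}
#' and 1 as \eqn{\sigma_e \to 0}.
#'
#' @param sigma_e evidence noise standard deviation(s), > 0.
#' @return Probability in (0.5, 1).
#' @export
sensory_information <- function(sigma_e) {
  if (any(!is.finite(sigma_e)) || any(sigma_e <= 0))
    stop_domain("sigma_e must be > 0")
  stats::pnorm(2 / sigma_e)
}

#' Evidence noise level for a desired sensory information
#'
#' Inverse of [sensory_information()]: \eqn{\sigma_e = 2/\Phi^{-1}(si)}.
#'
#' @param si sensory information in (0.5, 1).
#' @return Evidence noise standard deviation.
#' @export
sigma_for_sensory_info <- function(si) {
  if (any(si <= 0.5) || any(si >= 1))
    stop_domain("sensory information must be in (0.5, 1)")
  2 / stats::qnorm(si)
}

#' Category information from a frame-count ratio
#'
#' For a stimulus with a discrete ratio of frames matching each category,
#' the per-frame match probability is the fraction of matching frames:
#' a 5:5 ratio gives 0.5 (a frame's sign does not predict the category),
#' a 10:0 ratio gives 1.
#'
#' @param n_match number of frames matching the trial category.
#' @param n_total total number of frames.
#' @return Match probability \code{n_match / n_total}.
#' @export
category_information_from_ratio <- function(n_match, n_total) {
  if (n_total <= 0) stop_domain("n_total must be positive")
  if (n_match < 0 || n_match > n_total)
    stop_domain("n_match must be between 0 and n_total")
  n_match / n_total
}

#' Sample trials from the generative task model
#'
#' Draws \code{n} independent trials: category \eqn{C} from the category
#' prior, per-frame features \eqn{x_f \sim N(\pm C, \sigma_x^2)} with the
#' matching mode chosen with probability equal to the category information,
#' and evidence \eqn{e_f \sim N(x_f, \sigma_e^2)}.
#'
#' @param n number of trials.
#' @param params a [task_params()] object.
#' @return A list with \code{categories} (length-\code{n} vector of
#'   \eqn{\pm 1}), \code{features} and \code{evidence}
#'   (\code{n x n_frames} matrices).
#' @export
sample_trials <- function(n, params) {
  stopifnot(inherits(params, "task_params"))
  F <- params$n_frames
  categories <- ifelse(stats::runif(n) < params$category_prior, 1, -1)
  match <- matrix(stats::runif(n * F) < params$category_info, n, F)
  modes <- categories * ifelse(match, 1, -1)
  features <- modes + params$sigma_x * matrix(stats::rnorm(n * F), n, F)
  evidence <- features + params$sigma_e * matrix(stats::rnorm(n * F), n, F)
  list(categories = categories, features = features, evidence = evidence)
}

#' Single-trial convenience wrapper around [sample_trials()]
#'
#' @param params a [task_params()] object.
#' @return A list with scalar \code{category} and length-\code{n_frames}
#'   vectors \code{features}, \code{evidence}.
#' @export
sample_trial <- function(params) {
  tr <- sample_trials(1L, params)
  list(category = tr$categories[1],
       features = drop(tr$features),
       evidence = drop(tr$evidence))
}

#' Exact per-frame log likelihood odds
#'
#' Marginalizing the latent feature and its mode indicator, the evidence
#' likelihood under category \eqn{c} is a two-Gaussian mixture
#' \eqn{p(e|C=c) = q\,N(e; c, \sigma^2) + (1-q)\,N(e; -c, \sigma^2)} with
#' \eqn{q} the category information and \eqn{\sigma^2 = \sigma_x^2 +
#' \sigma_e^2}. Returns \eqn{\log p(e|C=+1) - \log p(e|C=-1)}, the exact
#' log likelihood odds (LLO) an ideal observer adds per frame. Odd in
#' \code{e}; identically 0 when \eqn{q = 0.5}.
#'
#' @param e evidence value(s); vector or matrix.
#' @param params a [task_params()] object.
#' @return LLO with the same shape as \code{e}.
#' @export
frame_llo <- function(e, params) {
  stopifnot(inherits(params, "task_params"))
  q <- params$category_info
  s <- sqrt(params$sigma_x^2 + params$sigma_e^2)
  lp <- stats::dnorm(e, 1, s, log = TRUE)   # feature mode +1
  lm <- stats::dnorm(e, -1, s, log = TRUE)  # feature mode -1
  out <- logaddexp(log(q) + lp, log1p(-q) + lm) -
    logaddexp(log(q) + lm, log1p(-q) + lp)
  if (is.matrix(e)) dim(out) <- dim(e)
  out
}

# Resolve the sign of final log posterior odds into a +/-1 choice.
# Exact ties (measure zero for continuous evidence, but reachable with
# degenerate inputs) are broken by a fair coin from the current RNG stream.
choice_from_lpo <- function(lpo) {
  ch <- sign(lpo)
  tie <- ch == 0
  if (any(tie)) ch[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, 1, -1)
  ch
}

#' Run the ideal observer on one trial
#'
#' Exact Bayesian inference of the category: the log posterior odds start
#' at the log prior odds and accumulate the exact per-frame LLO,
#' \eqn{LPO_f = LPO_{f-1} + LLO_f}. The choice is the sign of the final
#' LPO (ties broken by a fair coin).
#'
#' @param trial a list with an \code{evidence} vector (see [sample_trial()]).
#' @param params a [task_params()] object.
#' @return An inference trace: list with \code{lpo} (length
#'   \code{n_frames + 1}), \code{llo_estimates} (the exact LLOs), and
#'   \code{choice}.
#' @export
run_ideal_observer <- function(trial, params) {
  e <- trial$evidence
  stopifnot(length(e) == params$n_frames)
  llo <- frame_llo(e, params)
  lpo <- cumsum(c(logodds(params$category_prior), llo))
  list(lpo = lpo, llo_estimates = llo, choice = choice_from_lpo(lpo[length(lpo)]))
}

#' Simulate many ideal-observer trials
#'
#' Vectorized companion of [run_ideal_observer()]: samples \code{n} trials
#' and returns the ideal observer's choices alongside the generative record.
#'
#' @param n number of trials.
#' @param params a [task_params()] object.
#' @return A [choice_dataset()] with the evidence as signals.
#' @export
ideal_observer <- function(n, params) {
  tr <- sample_trials(n, params)
  llo <- frame_llo(tr$evidence, params)
  lpo_final <- logodds(params$category_prior) + rowSums(llo)
  choice_dataset(signals = tr$evidence,
                 choices = choice_from_lpo(lpo_final),
                 categories = tr$categories,
                 model = "ideal", params = params)
}
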