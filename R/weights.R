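#' Fit temporal weights (psychophysical kernel) to choice data
#'
#' Estimates how strongly each stimulus frame influences the final choice,
#' by logistic regression of choices on the per-frame signals. Signals are
#' z-scored per frame before fitting; fitted weights are normalized to
#' have mean 1 (the bias term is fitted but excluded from normalization).
#' Three shapes are available:
#' \describe{
#'   \item{\code{free}}{one weight per frame, penalized by a ridge (AR0)
#'     term \code{ridge * ||w||^2} and a curvature (AR2) term
#'     \code{ar2 * ||second difference of w||^2}. No first-order (AR1)
#'     penalty is used, to avoid biasing the slope.}
#'   \item{\code{exponential}}{\eqn{w_f = a\,e^{\beta f}} with frame index
#'     \eqn{f = 1..F}; \eqn{\beta > 0} is recency, \eqn{\beta < 0} primacy.}
#'   \item{\code{linear}}{\eqn{w_f = a + \mathrm{slope}\cdot f}.}
#' }
#' The constrained shapes maximize the same Bernoulli likelihood as the
#' free regression. The exponential fit profiles \eqn{\beta}: for fixed
#' \eqn{\beta} the model is a 2-parameter logistic GLM, and \eqn{\beta} is
#' optimized by golden-section search on the profile likelihood (with a
#' bracket scan to avoid local optima).
#'
#' @param data a [choice_dataset()].
#' @param shape \code{"free"}, \code{"exponential"} or \code{"linear"}.
#' @param ridge nonnegative ridge penalty (free shape only).
#' @param ar2 nonnegative curvature penalty (free shape only).
#' @param standardize keep \code{TRUE} (the fitting contract); stored
#'   centers/scales let new data be transformed consistently.
#' @return An object of class \code{weight_fit}: normalized \code{weights},
#'   \code{bias}, \code{slope_beta} (\eqn{\beta}, slope, or \code{NA} for
#'   free), \code{amplitude}, the achieved \code{loglik}, and the z-scoring
#'   transform.
#' @export
fit_weights <- function(data, shape = c("exponential", "linear", "free"),
                        ridge = 0, ar2 = 0, standardize = TRUE) {
  shape <- match.arg(shape)
  S <- data$signals
  n <- nrow(S); F <- ncol(S)
  if (n <= F) stop_domain("need more trials than frames")
  y <- as01(data$choices)
  ctr <- if (standardize) colMeans(S) else rep(0, F)
  scl <- if (standardize) apply(S, 2, stats::sd) else rep(1, F)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(S, 2, ctr), 2, scl, "/")
  fit <- switch(shape,
    free = .fit_free(Z, y, ridge, ar2),
    exponential = .fit_exponential(Z, y),
    linear = .fit_linear(Z, y))
  w <- fit$w
  mw <- mean(w)
  if (abs(mw) < 1e-12) mw <- 1  # degenerate all-zero weights: leave as is
  structure(list(weights = w / mw, bias = fit$bias, shape = shape,
                 slope_beta = fit$slope_beta, amplitude = mw,
                 loglik = fit$loglik, ridge = ridge, ar2 = ar2,
                 center = ctr, scale = scl, n_trials = n, n_frames = F),
            class = "weight_fit")
}

# Bernoulli log-likelihood for linear predictor eta, y in {0,1}
.ll <- function(eta, y) {
  # stable: y*eta - log(1+exp(eta))
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

# Penalized IRLS for the free shape; design [Z, 1], penalty on w only.
.fit_free <- function(Z, y, ridge, ar2) {
  F <- ncol(Z)
  X <- cbind(Z, 1)
  D <- diff(diag(F), differences = 2)           # (F-2) x F second difference
  P <- diag(c(rep(ridge, F), 0))
  P[seq_len(F), seq_len(F)] <- P[seq_len(F), seq_len(F)] + ar2 * crossprod(D)
  beta <- numeric(F + 1)
  floor_pen <- 0
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    wts <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * wts, X) + 2 * (P + diag(floor_pen, F + 1))
    gr <- crossprod(X, y - p) - 2 * (P + diag(floor_pen, F + 1)) %*% beta
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) {
      floor_pen <- max(floor_pen * 10, 1e-6)
      warning("singular design; applying regularization floor")
      next
    }
    beta_new <- beta + step
    if (max(abs(beta_new - beta)) > 25) {
      # likely separation: damp and add a small floor
      beta_new <- beta + step / max(abs(step)) * 25
      floor_pen <- max(floor_pen, 1e-6)
    }
    conv <- max(abs(beta_new - beta)) < 1e-9
    beta <- beta_new
    if (conv) break
  }
  eta <- drop(X %*% beta)
  list(w = beta[seq_len(F)], bias = beta[F + 1], slope_beta = NA_real_,
       loglik = .ll(eta, y))
}

# GLM on 2 derived covariates: eta = a * (Z %*% u) + slope_term + bias
.glm2 <- function(x1, x2, y) {
  fit <- suppressWarnings(stats::glm.fit(cbind(x1, x2, 1), y,
                                         family = stats::binomial()))
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  list(cf = cf, loglik = .ll(drop(cbind(x1, x2, 1) %*% cf), y))
}

.fit_linear <- function(Z, y) {
  F <- ncol(Z)
  f <- seq_len(F)
  x1 <- drop(Z %*% rep(1, F))
  x2 <- drop(Z %*% f)
  g <- .glm2(x1, x2, y)
  a <- g$cf[1]; slope <- g$cf[2]
  list(w = a + slope * f, bias = g$cf[3], slope_beta = slope,
       loglik = g$loglik)
}

# Two-parameter logistic fit (slope on x1 plus intercept) by Newton's
# method with a closed-form 2x2 solve; equivalent to the GLM fit but
# without per-call framework overhead, since it sits inside the profile
# search, bootstrap and cross-validation loops.
.logit2 <- function(x1, y) {
  b1 <- 0; b0 <- 0
  for (it in 1:30) {
    eta <- b1 * x1 + b0
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    g1 <- sum((y - p) * x1); g0 <- sum(y - p)
    h11 <- sum(w * x1 * x1); h10 <- sum(w * x1); h00 <- sum(w)
    det <- h11 * h00 - h10 * h10
    if (!is.finite(det) || det < 1e-12) break
    d1 <- (g1 * h00 - g0 * h10) / det
    d0 <- (g0 * h11 - g1 * h10) / det
    # damp huge steps (near-separation)
    sc <- max(abs(d1), abs(d0))
    if (sc > 5) { d1 <- d1 * 5 / sc; d0 <- d0 * 5 / sc }
    b1 <- b1 + d1; b0 <- b0 + d0
    if (abs(b1) > 50 || abs(b0) > 50) break    # separation cap
    if (max(abs(d1), abs(d0)) < 1e-8) break
  }
  c(b1, b0)
}

# Profile likelihood over beta for w_f = a * exp(beta * f).
.exp_profile <- function(Z, y, beta) {
  f <- seq_len(ncol(Z))
  u <- exp(beta * f)
  x1 <- drop(Z %*% u)
  cf <- .logit2(x1, y)
  list(loglik = .ll(cf[1] * x1 + cf[2], y), a = cf[1], bias = cf[2])
}

.fit_exponential <- function(Z, y, lower = -1.5, upper = 1.5) {
  F <- ncol(Z)
  f <- seq_len(F)
  # bracket scan, then golden-section refine via optimize()
  grid <- seq(lower, upper, length.out = 11)
  lls <- vapply(grid, function(b) .exp_profile(Z, y, b)$loglik, 0)
  b0 <- grid[which.max(lls)]
  lo <- max(lower, b0 - 0.31); hi <- min(upper, b0 + 0.31)
  opt <- stats::optimize(function(b) .exp_profile(Z, y, b)$loglik,
                         c(lo, hi), maximum = TRUE, tol = 1e-5)
  beta <- opt$maximum
  pr <- .exp_profile(Z, y, beta)
  list(w = pr$a * exp(beta * f), bias = pr$bias, slope_beta = beta,
       loglik = pr$loglik)
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf("Temporal weights (%s fit, %d trials x %d frames)\n",
              x$shape, x$n_trials, x$n_frames))
  cat("  normalized weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  if (!is.na(x$slope_beta))
    cat(sprintf("  slope %s = %+.4f (%s)\n",
                if (x$shape == "exponential") "beta" else "slope", x$slope_beta,
                if (x$slope_beta < 0) "primacy" else "recency"))
  cat(sprintf("  log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

#' @export
coef.weight_fit <- function(object, ...) {
  c(object$weights * object$amplitude, bias = object$bias)
}

#' @export
plot.weight_fit <- function(x, ...) {
  graphics::plot(seq_len(x$n_frames), x$weights, type = "b",
                 xlab = "frame", ylab = "normalized weight",
                 main = sprintf("Temporal weights (%s)", x$shape), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Predicted choice probabilities from a weight fit
#' @param object a [fit_weights()] result.
#' @param newdata a [choice_dataset()] (or matrix of signals).
#' @param ... unused.
#' @return P(choice = +1) per trial, using the stored z-scoring transform.
#' @export
predict.weight_fit <- function(object, newdata, ...) {
  S <- if (inherits(newdata, "choice_dataset")) newdata$signals else as.matrix(newdata)
  Z <- sweep(sweep(S, 2, object$center), 2, object$scale, "/")
  eta <- drop(Z %*% (object$weights * object$amplitude)) + object$bias
  stats::plogis(eta)
}

#' Bootstrap distribution of the temporal-weight slope
#'
#' Resamples trials with replacement, refits the shape-constrained
#' weights, and summarizes the slope parameter.
#'
#' @param data a [choice_dataset()].
#' @param shape \code{"exponential"} or \code{"linear"}.
#' @param n_boot number of bootstrap resamples (the convention is 500).
#' @param level central interval coverage (default 0.95).
#' @return List with \code{median_beta}, \code{ci} (percentile interval),
#'   \code{sd} and the vector of bootstrap \code{betas}.
#' @export
bootstrap_slope <- function(data, shape = c("exponential", "linear"),
                            n_boot = 500, level = 0.95) {
  shape <- match.arg(shape)
  if (n_boot < 2) stop_domain("n_boot must be >= 2")
  n <- nrow(data$signals)
  betas <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- choice_dataset(data$signals[idx, , drop = FALSE],
                        data$choices[idx], data$categories[idx],
                        model = data$model)
    fit_weights(d, shape = shape)$slope_beta
  }, 0)
  alpha <- (1 - level) / 2
  list(median_beta = stats::median(betas),
       ci = unname(stats::quantile(betas, c(alpha, 1 - alpha))),
       sd = stats::sd(betas), betas = betas)
}

#' Cross-validated comparison of weight-regression variants
#'
#' K-fold cross-validation: per fold, each candidate is fit on the
#' training split and scored by held-out Bernoulli log-likelihood,
#' reported relative to unregularized free logistic regression on the
#' same folds.
#'
#' @param data a [choice_dataset()].
#' @param candidates named list of candidate specs; each a list with
#'   \code{shape} and optional \code{ridge}, \code{ar2}.
#' @param k number of folds.
#' @return Matrix (fold x candidate) of held-out log-likelihood
#'   differences from the unregularized baseline.
#' @export
crossval_select <- function(data, candidates, k = 10) {
  if (k < 2) stop_domain("k must be >= 2")
  n <- nrow(data$signals)
  folds <- rep(seq_len(k), length.out = n)[sample.int(n)]
  scores <- matrix(NA_real_, k, length(candidates),
                   dimnames = list(NULL, names(candidates)))
  base <- numeric(k)
  for (i in seq_len(k)) {
    tr <- folds != i; te <- !tr
    dtr <- choice_dataset(data$signals[tr, , drop = FALSE],
                          data$choices[tr], data$categories[tr])
    hold_ll <- function(fit) {
      p <- predict(fit, data$signals[te, , drop = FALSE])
      y <- as01(data$choices[te])
      sum(log(ifelse(y == 1, p, 1 - p)))
    }
    base[i] <- hold_ll(fit_weights(dtr, shape = "free", ridge = 0, ar2 = 0))
    for (j in seq_along(candidates)) {
      cand <- candidates[[j]]
      fit <- fit_weights(dtr, shape = cand$shape,
                         ridge = cand$ridge %||% 0, ar2 = cand$ar2 %||% 0)
      scores[i, j] <- hold_ll(fit) - base[i]
    }
  }
  scores
}

#' Select ridge/AR2 hyperparameters by cross-validation
#'
#' Logarithmic grid (7 points per hyperparameter), scored by mean held-out
#' log-likelihood with [crossval_select()].
#'
#' @param data a [choice_dataset()].
#' @param k folds.
#' @param grid_ridge,grid_ar2 candidate penalty values.
#' @return List with chosen \code{ridge}, \code{ar2} and the score table.
#' @export
select_hyperparameters <- function(data, k = 10,
                                   grid_ridge = 10^seq(-2, 4, length.out = 7),
                                   grid_ar2 = 10^seq(-2, 4, length.out = 7)) {
  cands <- list()
  for (r in grid_ridge) for (a in grid_ar2)
    cands[[sprintf("r%.3g_a%.3g", r, a)]] <- list(shape = "free", ridge = r, ar2 = a)
  sc <- crossval_select(data, cands, k = k)
  best <- which.max(colMeans(sc))
  ij <- arrayInd(best, c(length(grid_ar2), length(grid_ridge)))
  list(ridge = grid_ridge[ij[2]], ar2 = grid_ar2[ij[1]],
       scores = colMeans(sc))
}
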