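#' Container for per-trial signals, categories and choices
#'
#' The common currency of the package: an \code{n_trials x n_frames} matrix
#' of per-frame scalar signal strengths \strong{S} (for model-generated data
#' these are the evidence values \eqn{e_f}), the true categories, and the
#' observer's binary choices, plus provenance metadata.
#'
#' @param signals numeric \code{n x F} matrix of per-frame signals.
#' @param choices length-\code{n} vector of choices in \eqn{\{-1,+1\}}.
#' @param categories length-\code{n} vector of true categories in
#'   \eqn{\{-1,+1\}}.
#' @param model character label of the generating observer
#'   (\code{"ideal"}, \code{"sampling"}, \code{"variational"},
#'   \code{"itb"}, ...).
#' @param params optional generating [task_params()] (stored as metadata).
#' @param condition optional condition label (e.g. \code{"LSHC"}).
#' @param seed optional seed recorded for provenance.
#' @return An object of class \code{choice_dataset}.
#' @export
choice_dataset <- function(signals, choices, categories,
                           model = "unknown", params = NULL,
                           condition = NULL, seed = NULL) {
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (length(choices) != n || length(categories) != n)
    stop_domain("signals, choices and categories must agree in length")
  if (n > 0 && (any(abs(choices) != 1) || any(abs(categories) != 1)))
    stop_domain("choices and categories must be +1 or -1")
  if (n > 0 && any(!is.finite(signals)))
    stop_domain("signals must be finite (no missing values)")
  structure(list(signals = signals,
                 choices = as.numeric(choices),
                 categories = as.numeric(categories),
                 model = model,
                 params = params,
                 condition = condition,
                 seed = seed),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("Choice dataset: %d trials x %d frames (model = %s%s)\n",
              nrow(x$signals), ncol(x$signals), x$model,
              if (!is.null(x$condition)) paste0(", ", x$condition) else ""))
  if (nrow(x$signals) > 0)
    cat(sprintf("  accuracy: %.3f\n", accuracy(x)))
  invisible(x)
}

#' Fraction of choices matching the true category
#' @param data a [choice_dataset()].
#' @return Proportion correct.
#' @export
accuracy <- function(data) mean(data$choices == data$categories)

#' Write a choice dataset to CSV
#'
#' One row per trial: \code{trial_id, category, choice, model, condition,
#' seed, s1..sF}. Deterministic output: the same dataset always produces
#' byte-identical files.
#'
#' @param data a [choice_dataset()].
#' @param path file path.
#' @export
write_choice_dataset <- function(data, path) {
  F <- ncol(data$signals)
  sig <- as.data.frame(data$signals)
  names(sig) <- paste0("s", seq_len(F))
  n <- nrow(data$signals)
  df <- data.frame(trial_id = seq_len(n),
                   category = data$categories,
                   choice = data$choices,
                   model = rep(data$model, n),
                   condition = rep(data$condition %||% NA_character_, n),
                   seed = rep(data$seed %||% NA_integer_, n))
  df <- cbind(df, sig)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a choice dataset written by [write_choice_dataset()]
#' @param path file path.
#' @return A [choice_dataset()].
#' @export
read_choice_dataset <- function(path) {
  df <- utils::read.csv(path)
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  seed <- if (all(is.na(df$seed))) NULL else df$seed[1]
  cond <- if (all(is.na(df$condition))) NULL else as.character(df$condition[1])
  choice_dataset(signals = as.matrix(df[, scols, drop = FALSE]),
                 choices = df$choice, categories = df$category,
                 model = as.character(df$model[1] %||% "unknown"),
                 condition = cond, seed = seed)
}

#' Write per-frame trial records to CSV
#'
#' Long format, one row per frame: \code{trial_id, category, frame_index,
#' x, e} — the generative record of [sample_trials()].
#'
#' @param trials result of [sample_trials()].
#' @param path file path.
#' @export
write_trials <- function(trials, path) {
  n <- length(trials$categories)
  F <- ncol(trials$features)
  df <- data.frame(trial_id = rep(seq_len(n), each = F),
                   category = rep(trials$categories, each = F),
                   frame_index = rep(seq_len(F), n),
                   x = as.vector(t(trials$features)),
                   e = as.vector(t(trials$evidence)))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
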