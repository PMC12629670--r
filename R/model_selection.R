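# Five partition hypotheses over the three prey types, in the fixed order
# used by all reports. Each block shares one success probability.
MODEL_ORDER <- c("all_different", "all_equal", "heliconius_different",
                 "spicauda_different", "euptychiina_different")

#' The five partition hypotheses over the three prey types
#'
#' A partition model groups the three prey types into equal-probability
#' blocks: all different (k = 3 parameters), all equal (k = 1), or one type
#' different from the other two (k = 2, three variants).
#'
#' @param name model name; one of \code{"all_different"}, \code{"all_equal"},
#'   \code{"heliconius_different"}, \code{"spicauda_different"},
#'   \code{"euptychiina_different"}.
#' @return object of class \code{partition_model}: list with \code{name},
#'   \code{blocks} (list of prey-type character vectors) and \code{k}.
#' @export
partition_model <- function(name) {
  name <- match.arg(name, MODEL_ORDER)
  blocks <- switch(name,
    all_different = list("euptychiina", "heliconius", "spicauda"),
    all_equal = list(PREY_TYPES),
    heliconius_different = list(c("euptychiina", "spicauda"), "heliconius"),
    spicauda_different = list(c("euptychiina", "heliconius"), "spicauda"),
    euptychiina_different = list("euptychiina", c("heliconius", "spicauda")))
  structure(list(name = name, blocks = blocks, k = length(blocks)),
            class = "partition_model")
}

#' @rdname partition_model
#' @export
partition_models <- function() {
  stats::setNames(lapply(MODEL_ORDER, partition_model), MODEL_ORDER)
}

log_fun <- function(log_base) {
  log_base <- match.arg(log_base, c("log10", "natural"))
  if (log_base == "log10") log10 else log
}

#' Binomial log10-likelihood of per-type success probabilities
#'
#' Evaluates \deqn{\log_{10} L = \sum_i a_i \log_{10} P_i +
#' (N_i - a_i)\log_{10}(1 - P_i)} over the three prey types, with the
#' convention \eqn{0 \cdot \log_{10} 0 = 0}. The additive constant that
#' cancels in model comparison is omitted. A boundary probability that
#' contradicts the data (\eqn{P_i = 0} with \eqn{a_i > 0}, or \eqn{P_i = 1}
#' with \eqn{a_i < N_i}) yields \code{-Inf} with attribute
#' \code{"flagged" = TRUE}.
#'
#' @param counts \code{\link{stage_counts}} object.
#' @param probs named per-type probabilities in [0, 1].
#' @param log_base \code{"log10"} (default, the convention of the analysis)
#'   or \code{"natural"}.
#' @return the log-likelihood (numeric scalar).
#' @export
log10_likelihood <- function(counts, probs, log_base = "log10") {
  lg <- log_fun(log_base)
  probs <- probs[PREY_TYPES]
  if (anyNA(probs)) stop("probs must be named by prey type", call. = FALSE)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ll <- 0
  flagged <- FALSE
  for (ty in PREY_TYPES) {
    a <- counts$a[ty]; N <- counts$N[ty]; p <- probs[ty]
    t1 <- if (a > 0) a * lg(p) else 0
    t2 <- if (N - a > 0) (N - a) * lg(1 - p) else 0
    if (!is.finite(t1) || !is.finite(t2)) flagged <- TRUE
    ll <- ll + t1 + t2
  }
  ll <- unname(ll)
  if (flagged) ll <- structure(-Inf, flagged = TRUE)
  ll
}

#' Fit one partition model to stage counts by maximum likelihood
#'
#' The MLE of each block's shared probability is the pooled ratio
#' (block successes)/(block trials). The information criterion is
#' \deqn{AICc = 2k - 2\log_{10}L + \frac{2k(k+1)}{n - k - 1}} with
#' \eqn{n = \sum_i N_i}, keeping the base-10 likelihood of the analysis
#' convention (set \code{log_base = "natural"} for the textbook variant).
#' Prey types with zero trials contribute neither likelihood nor trials.
#'
#' @param counts \code{\link{stage_counts}} object.
#' @param partition a \code{\link{partition_model}} or its name.
#' @param log_base \code{"log10"} (default) or \code{"natural"}.
#' @return object of class \code{model_fit}: list with \code{partition},
#'   \code{p_hat} (per-type MLE), \code{log10L}, \code{aicc}, \code{k},
#'   \code{n}.
#' @export
fit_partition_model <- function(counts, partition, log_base = "log10") {
  if (is.character(partition)) partition <- partition_model(partition)
  p_hat <- stats::setNames(numeric(3), PREY_TYPES)
  for (b in partition$blocks) {
    trials <- sum(counts$N[b])
    p_hat[b] <- if (trials > 0) sum(counts$a[b]) / trials else 0
  }
  ll <- log10_likelihood(counts, p_hat, log_base)
  k <- partition$k
  n <- sum(counts$N)
  if (n - k - 1 <= 0) {
    stop("too few trials (n = ", n, ") for AICc with k = ", k, call. = FALSE)
  }
  aicc <- 2 * k - 2 * as.numeric(ll) + 2 * k * (k + 1) / (n - k - 1)
  structure(list(partition = partition, p_hat = p_hat,
                 log10L = as.numeric(ll), aicc = aicc, k = k, n = n),
            class = "model_fit")
}

#' Compare the five partition models on one stage table
#'
#' Fits every partition hypothesis, ranks by AICc, and computes
#' \eqn{\Delta AICc}, Akaike weights
#' \eqn{w_m = \exp(-\Delta_m/2)/\sum_j \exp(-\Delta_j/2)}, the best model
#' (AICc ties broken by fewer parameters, then fixed model order) and the
#' non-rejected competing set (\eqn{\Delta AICc} below the threshold,
#' default 2).
#'
#' @param counts \code{\link{stage_counts}} object.
#' @param log_base \code{"log10"} (default) or \code{"natural"}.
#' @param aicc_threshold ΔAICc below which a model is not rejected.
#' @return data frame of class \code{model_comparison} with one row per
#'   model: \code{model}, \code{k}, \code{log10L}, \code{aicc},
#'   \code{delta_aicc}, \code{akaike_weight}, \code{is_best},
#'   \code{is_competing} and the per-type fitted probabilities
#'   \code{p_euptychiina}, \code{p_heliconius}, \code{p_spicauda}.
#' @export
compare_models <- function(counts, log_base = "log10", aicc_threshold = 2) {
  fits <- lapply(partition_models(), fit_partition_model, counts = counts,
                 log_base = log_base)
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "k")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  # best: lowest AICc; ties by fewer parameters, then fixed model order
  best_idx <- order(aicc, k, seq_along(aicc))[1]
  tab <- data.frame(
    model = MODEL_ORDER,
    k = k,
    log10L = vapply(fits, `[[`, numeric(1), "log10L"),
    aicc = aicc,
    delta_aicc = delta,
    akaike_weight = w,
    is_best = seq_along(fits) == best_idx,
    is_competing = delta < aicc_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  ph <- t(vapply(fits, function(f) f$p_hat, numeric(3)))
  colnames(ph) <- paste0("p_", PREY_TYPES)
  tab <- cbind(tab, ph)
  class(tab) <- c("model_comparison", "data.frame")
  attr(tab, "stage_label") <- counts$stage_label
  attr(tab, "subset") <- counts$subset
  attr(tab, "n") <- fits[[1]]$n
  tab
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Partition-model comparison [", attr(x, "stage_label"),
      "; subset ", attr(x, "subset"), "; n = ", attr(x, "n"), "]\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
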