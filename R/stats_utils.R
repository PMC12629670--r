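#' Paired Wilcoxon signed-rank test
#'
#' Self-contained signed-rank test on paired differences. Zero differences
#' are dropped; ties among absolute differences receive midranks. The null
#' distribution is enumerated exactly (dynamic programming over all sign
#' assignments, valid under midranks) when the number of nonzero differences
#' is at most \code{exact_max}; above that a normal approximation with
#' tie-corrected variance and continuity correction is used. The statistic is
#' V, the sum of the ranks of the positive differences; the two-sided p-value
#' is \code{min(1, 2 * min(P(V <= v), P(V >= v)))}.
#'
#' @param x numeric vector of differences, or the first member of each pair
#'   when \code{y} is supplied.
#' @param y optional second member of each pair (\code{x - y} is tested).
#' @param exact_max largest n for which the exact null is enumerated.
#' @return list with \code{statistic} (V), \code{p_value}, \code{n_pairs}
#'   (nonzero differences used), \code{method} and \code{all_zero} flag.
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n_pairs = 0L,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # DP over doubled ranks (midranks are multiples of 1/2, so 2r is integer)
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    total <- 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(v2 + 1L)]) / total
    p_ge <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = v, p_value = p, n_pairs = n, method = method,
       all_zero = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons (default \code{length(p)}).
#' @return adjusted p-values \code{min(1, m * p)}.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' All pairwise signed-rank comparisons between columns of a paired matrix
#'
#' @param mat numeric matrix, one row per subject, one column per group;
#'   rows with a missing value in a pair are dropped for that pair.
#' @param exact_max passed to \code{\link{signed_rank_test}}.
#' @return data frame with one row per group pair: \code{group_a},
#'   \code{group_b}, \code{statistic}, \code{p_raw}, \code{p_adjusted}
#'   (Bonferroni over all pairs), \code{n_pairs}.
#' @export
pairwise_signed_rank <- function(mat, exact_max = 25) {
  groups <- colnames(mat)
  if (is.null(groups)) groups <- paste0("g", seq_len(ncol(mat)))
  combs <- utils::combn(seq_len(ncol(mat)), 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    ok <- stats::complete.cases(mat[, c(i1, i2)])
    if (sum(ok) < 2L) {
      stop("fewer than 2 complete pairs for ", groups[i1], " vs ",
           groups[i2], call. = FALSE)
    }
    res <- signed_rank_test(mat[ok, i1], mat[ok, i2], exact_max = exact_max)
    data.frame(group_a = groups[i1], group_b = groups[i2],
               statistic = res$statistic, p_raw = res$p_value,
               n_pairs = res$n_pairs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, nrow(out))
  out[, c("group_a", "group_b", "statistic", "p_raw", "p_adjusted",
          "n_pairs")]
}

#' Compact letter display from a pairwise significance matrix
#'
#' Assigns letters so that two groups share at least one letter exactly when
#' they are not significantly different. Uses the insert-and-absorb
#' construction: start from one letter covering all groups, split it on each
#' significant pair, absorb redundant letters; deterministic in the group
#' order.
#'
#' @param sig logical symmetric matrix; \code{TRUE} marks a significantly
#'   different pair.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(sig) {
  groups <- rownames(sig)
  if (is.null(groups)) groups <- paste0("g", seq_len(nrow(sig)))
  cols <- list(groups)
  combs <- utils::combn(seq_along(groups), 2)
  for (j in seq_len(ncol(combs))) {
    gi <- groups[combs[1, j]]; gj <- groups[combs[2, j]]
    if (!isTRUE(sig[combs[1, j], combs[2, j]])) next
    new_cols <- list()
    for (col in cols) {
      if (gi %in% col && gj %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, gj)), list(setdiff(col, gi)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop empty columns, proper subsets, and later duplicates
    keep <- lengths(new_cols) > 0L
    for (a in seq_along(new_cols)) {
      if (!keep[a]) next
      for (b in seq_along(new_cols)) {
        if (a == b || !keep[b]) next
        subset_ab <- all(new_cols[[a]] %in% new_cols[[b]])
        proper <- subset_ab && length(new_cols[[a]]) < length(new_cols[[b]])
        duplicate <- subset_ab &&
          length(new_cols[[a]]) == length(new_cols[[b]]) && a > b
        if (proper || duplicate) { keep[a] <- FALSE; break }
      }
    }
    cols <- new_cols[keep]
  }
  # deterministic letter order: by index of each column's first group
  first_idx <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_idx)]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(groups, function(g) {
    paste0(letters_used[vapply(cols, function(col) g %in% col, logical(1))],
           collapse = "")
  }, character(1))
  out
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around \code{stats::shapiro.test} used for reporting only:
#' the pipeline always uses the signed-rank test regardless of the screen's
#' outcome. Returns \code{NA} outside the supported sample-size range
#' (3 to 5000).
#'
#' @param x numeric vector.
#' @return list with \code{W}, \code{p_value}, \code{n}.
#' @export
shapiro_screen <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L || n > 5000L || stats::sd(x) == 0) {
    return(list(W = NA_real_, p_value = NA_real_, n = n))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}
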