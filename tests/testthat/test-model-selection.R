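sc <- function(a, N, stage = "attacked") {
  stage_counts(stage, setNames(a, prey_types()), setNames(N, prey_types()))
}

test_that("the binomial log10-likelihood matches closed forms and oracle", {
  # single informative type, symmetric p: log10(0.5^4)
  cnt <- sc(c(2, 0, 0), c(4, 0, 0))
  p <- setNames(c(0.5, 0, 0), prey_types())
  expect_equal(log10_likelihood(cnt, p), log10(0.5^4), tolerance = 1e-12)

  # a_i = 0 with P_i = 0 contributes exactly 0 by convention
  cnt0 <- sc(c(0, 3, 0), c(5, 6, 0))
  p0 <- setNames(c(0, 0.5, 0), prey_types())
  expect_equal(log10_likelihood(cnt0, p0),
               5 * log10(1) + log10(0.5^6), tolerance = 1e-12)

  # boundary contradiction is -Inf and flagged
  bad <- log10_likelihood(sc(c(1, 0, 0), c(2, 0, 0)),
                          setNames(c(0, 0, 0), prey_types()))
  expect_identical(as.numeric(bad), -Inf)
  expect_true(attr(bad, "flagged"))

  # exact-rational oracle on small instances
  set.seed(5)
  for (rep in 1:50) {
    N <- sample(1:12, 3, replace = TRUE)
    a <- vapply(N, function(n) sample(0:n, 1), numeric(1))
    den <- sample(2:12, 3, replace = TRUE)
    num <- vapply(den, function(d) sample(0:d, 1), numeric(1))
    p <- setNames(num / den, prey_types())
    got <- log10_likelihood(sc(a, N), p)
    expect_equal(as.numeric(got), oracle_log10_lik(a, N, num, den),
                 tolerance = 1e-9)
  }
})

test_that("published targeting-stage likelihood matches a high-precision product", {
  cnt <- stage3a_counts("all")
  p <- setNames(cnt$a / cnt$N, prey_types())
  # oracle: sum of per-trial Bernoulli log-terms accumulated pairwise
  terms <- unlist(lapply(prey_types(), function(ty) {
    c(rep(log10(p[[ty]]), cnt$a[[ty]]),
      rep(log10(1 - p[[ty]]), cnt$N[[ty]] - cnt$a[[ty]]))
  }))
  expect_equal(as.numeric(log10_likelihood(cnt, p)), sum(terms),
               tolerance = 1e-9)
  expect_equal(as.numeric(log10_likelihood(cnt, p)), -94.17, tolerance = 1e-2)
})

test_that("partition fits pool block counts and compute AICc", {
  cnt <- stage3a_counts("all")
  fit <- fit_partition_model(cnt, "spicauda_different")
  expect_equal(unname(fit$p_hat[c("euptychiina", "heliconius")]),
               rep(51 / 262, 2))
  expect_equal(unname(fit$p_hat[["spicauda"]]), 52 / 131)

  fit_eq <- fit_partition_model(cnt, "all_equal")
  expect_equal(unname(fit_eq$p_hat), rep(103 / 393, 3))
  expect_equal(fit_eq$log10L, -98.179, tolerance = 1e-3)
  expect_equal(fit_eq$aicc, 2 * 1 - 2 * fit_eq$log10L + 4 / (393 - 2),
               tolerance = 1e-12)

  # saturated fit with a = N: that type contributes zero log-likelihood
  cnt1 <- sc(c(4, 2, 1), c(4, 8, 9))
  fit1 <- fit_partition_model(cnt1, "all_different")
  expect_equal(unname(fit1$p_hat[["euptychiina"]]), 1)
  contrib <- as.numeric(log10_likelihood(sc(c(4, 0, 0), c(4, 0, 0)),
                                         setNames(c(1, 0, 0), prey_types())))
  expect_equal(contrib, 0)

  expect_error(fit_partition_model(sc(c(1, 1, 1), c(1, 1, 1)),
                                   "all_different"), "too few trials")
})

test_that("model comparison ranks, weights and flags the five partitions", {
  cmp <- compare_models(stage3a_counts("all"))
  expect_s3_class(cmp, "model_comparison")
  byname <- function(col) setNames(cmp[[col]], cmp$model)

  expect_equal(cmp$model[cmp$is_best], "spicauda_different")
  expect_equal(sum(cmp$is_best), 1L)
  expect_equal(sum(cmp$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(cmp$delta_aicc[cmp$is_best], 0)
  expect_identical(cmp$is_competing, cmp$delta_aicc < 2)

  # descriptive rates equal the saturated model's per-type MLE
  sat <- cmp[cmp$model == "all_different", ]
  expect_equal(c(sat$p_euptychiina, sat$p_heliconius, sat$p_spicauda),
               c(28, 23, 52) / 131)

  # identical per-type counts: all models share the likelihood and the
  # one-parameter model wins
  cmp_eq <- compare_models(sc(c(10, 10, 10), c(40, 40, 40)))
  expect_equal(diff(range(cmp_eq$log10L)), 0, tolerance = 1e-12)
  expect_equal(cmp_eq$model[cmp_eq$is_best], "all_equal")
})

test_that("saturated likelihood dominates every partition (random tables)", {
  set.seed(99)
  for (rep in 1:1000) {
    N <- sample(3:60, 3, replace = TRUE)
    a <- vapply(N, function(n) sample(0:n, 1), numeric(1))
    cnt <- sc(a, N)
    ll <- vapply(partition_models(), function(m) {
      fit_partition_model(cnt, m)$log10L
    }, numeric(1))
    expect_true(all(ll["all_different"] >= ll - 1e-9))
  }
})

test_that("Akaike weights are invariant to a constant AICc shift", {
  cmp <- compare_models(stage3a_counts("adult"))
  d <- cmp$aicc - min(cmp$aicc)
  w_shift <- exp(-((cmp$aicc + 123.4) - min(cmp$aicc + 123.4)) / 2)
  w_shift <- w_shift / sum(w_shift)
  expect_equal(cmp$akaike_weight, w_shift, tolerance = 1e-12)
  expect_equal(cmp$akaike_weight, exp(-d / 2) / sum(exp(-d / 2)),
               tolerance = 1e-12)
})

test_that("the natural-log convention is available but non-default", {
  cnt <- stage3a_counts("all")
  cmp10 <- compare_models(cnt)
  cmpe <- compare_models(cnt, log_base = "natural")
  expect_equal(cmpe$log10L, cmp10$log10L * log(10), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(cmpe$delta_aicc, cmp10$delta_aicc)))
})
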