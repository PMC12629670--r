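test_that("the study-count fixture reproduces the published targeting rows", {
  fx <- study_count_fixture()
  oc <- apply_exclusion(fx$outcomes)$outcomes
  rep <- suppressWarnings(run_stage_analyses(
    oc, fx$meta,
    subsets = list(all = NULL, immature = list(age = "immature"),
                   adult = list(age = "adult"))))

  total <- rep$tables[["attacked|all"]]
  expect_equal(round(setNames(total$delta_aicc, total$model)[
    c("spicauda_different", "all_different", "heliconius_different",
      "all_equal", "euptychiina_different")], 2),
    c(spicauda_different = 0, all_different = 1.77,
      heliconius_different = 4.29, all_equal = 5.73,
      euptychiina_different = 6.70))

  imm <- rep$tables[["attacked|immature"]]
  expect_equal(imm$model[imm$is_best], "all_equal")
  adult <- rep$tables[["attacked|adult"]]
  expect_equal(adult$model[adult$is_best], "spicauda_different")
  expect_equal(round(adult$akaike_weight[adult$is_best], 2), 0.47)

  # descriptive rates equal the saturated model's fitted probabilities
  for (key in names(rep$tables)) {
    tab <- rep$tables[[key]]
    sat <- tab[tab$model == "all_different", ]
    d <- rep$descriptives
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rates <- d$rate[d$stage_label == parts[1] & d$subset == parts[2]]
    fitted <- as.numeric(sat[, paste0("p_", prey_types())])
    ok <- !is.na(rates)
    expect_equal(fitted[ok], rates[ok], tolerance = 1e-12)
  }

  # whole-percentage attack rates match the published summary
  d <- rep$descriptives
  att <- d[d$stage_label == "attacked" & d$subset == "all", ]
  expect_equal(round(100 * setNames(att$rate, att$prey_type)),
               c(euptychiina = 21, heliconius = 18, spicauda = 40))
})

test_that("a single-bird dataset is analysed without error", {
  oc <- bird_outcomes("solo", list(euptychiina = "NONE",
                                   heliconius = "DETECTED",
                                   spicauda = "ATTACKED"))
  rep <- suppressWarnings(run_stage_analyses(oc, meta_df("solo")))
  expect_s3_class(rep, "stage_analysis_report")
  cnt <- rep$counts[["attacked|all"]]
  expect_equal(unname(cnt$N), rep_len(1, 3))
  expect_equal(unname(cnt$a), c(0, 0, 1))
})

test_that("zero-bird subsets are skipped with a warning", {
  fx <- study_count_fixture()
  oc <- apply_exclusion(fx$outcomes)$outcomes
  meta <- fx$meta
  meta$season <- "wet"
  expect_warning(
    rep <- run_stage_analyses(oc, meta,
                              subsets = list(dry = list(season = "dry"))),
    "zero birds")
  expect_length(rep$tables, 0)
})

test_that("season/habitat subsets carry the confounding note", {
  fx <- study_count_fixture()
  oc <- apply_exclusion(fx$outcomes)$outcomes
  rep <- suppressWarnings(run_stage_analyses(
    oc, fx$meta, subsets = list(`habitat=urban` = list(habitat = "urban"))))
  expect_match(rep$notes, "confounded", all = FALSE)
})

test_that("empirical stage rates track simulated truth within 3 SE", {
  cfg <- sim_config(n_birds = 300, seed = 5)
  sim <- simulate_dataset(cfg)
  oc <- code_outcomes(sim$events, sim$birds$bird_id)
  st <- oc$stage
  w <- c(immature = cfg$p_immature, adult = 1 - cfg$p_immature)
  for (ty in prey_types()) {
    s <- st[oc$prey_type == ty]
    p_det <- sum(w * cfg$stage_probs$detect[names(w), ty])
    est <- mean(s >= "DETECTED")
    se <- sqrt(p_det * (1 - p_det) / length(s))
    expect_lt(abs(est - p_det), 3 * se + 1e-9)
  }
})

test_that("first-attack summaries use the 60-minute no-attack convention", {
  oc <- rbind(
    bird_outcomes("b1", list(euptychiina = "NONE", heliconius = "DETECTED",
                             spicauda = "ATTACKED")),
    bird_outcomes("b2", list(euptychiina = "ATTACKED",
                             heliconius = "ATTACKED",
                             spicauda = "ATTACKED")),
    bird_outcomes("b3", list(euptychiina = "DETECTED",
                             heliconius = "NONE", spicauda = "NONE")))
  fa <- first_attack_summary(oc)
  expect_equal(fa$n_birds, 2)  # b3 never attacked: excluded
  summ <- setNames(fa$summary$mean, fa$summary$prey_type)
  expect_equal(unname(summ["euptychiina"]), (60 + 10) / 2)
  expect_equal(unname(summ["spicauda"]), 10)

  # everyone attacks everything at t = 0: degenerate, all adjusted p = 1
  oc0 <- rbind(bird_outcomes("b1", list(euptychiina = "ATTACKED",
                                        heliconius = "ATTACKED",
                                        spicauda = "ATTACKED")),
               bird_outcomes("b2", list(euptychiina = "ATTACKED",
                                        heliconius = "ATTACKED",
                                        spicauda = "ATTACKED")))
  oc0$first_attack_time <- 0
  fa0 <- first_attack_summary(oc0)
  expect_equal(fa0$summary$mean, rep(0, 3))
  expect_true(all(fa0$pairwise$p_adjusted == 1))
})

test_that("first-attack pairwise p matches the enumeration oracle", {
  set.seed(23)
  ids <- sprintf("b%d", 1:8)
  oc <- do.call(rbind, lapply(ids, function(b) {
    bird_outcomes(b, list(euptychiina = "ATTACKED", heliconius = "ATTACKED",
                          spicauda = "ATTACKED"))
  }))
  oc$first_attack_time <- round(runif(nrow(oc), 0, 60), 1)
  fa <- first_attack_summary(oc)
  wide <- reshape(oc[, c("bird_id", "prey_type", "first_attack_time")],
                  direction = "wide", idvar = "bird_id",
                  timevar = "prey_type")
  d <- wide$first_attack_time.euptychiina - wide$first_attack_time.heliconius
  row <- fa$pairwise[fa$pairwise$group_a == "euptychiina" &
                       fa$pairwise$group_b == "heliconius", ]
  expect_equal(row$p_raw, oracle_signed_rank_p(d), tolerance = 1e-9)
})

test_that("failed-attack ratios divide failures by attacking birds", {
  oc <- rbind(
    bird_outcomes("b1", list(euptychiina = "NONE", heliconius = "NONE",
                             spicauda = "ATTACKED")),
    bird_outcomes("b2", list(euptychiina = "NONE", heliconius = "NONE",
                             spicauda = "CAPTURED")))
  oc$n_failed_attack_events[oc$bird_id == "b1" &
                              oc$prey_type == "spicauda"] <- 2L
  oc$n_failed_attack_events[oc$bird_id == "b2" &
                              oc$prey_type == "spicauda"] <- 1L
  r <- failed_attack_ratio(oc)
  expect_equal(unname(r["spicauda"]), 1.5)
  expect_true(is.na(r["euptychiina"]) && is.na(r["heliconius"]))

  # immediate success everywhere: ratio 0
  oc$n_failed_attack_events <- 0L
  expect_equal(unname(failed_attack_ratio(oc)["spicauda"]), 0)
})

test_that("simulated failed-attack ratio approximates (1-q)/q", {
  # all attackers capture: failures per attacker are geometric with mean
  # (1-q)/q
  probs <- default_stage_probs()
  probs$capture <- probs$capture * 0 + 1
  probs$attack <- probs$attack * 0 + 1
  probs$detect <- probs$detect * 0 + 1
  q <- 0.4
  cfg <- sim_config(n_birds = 250, seed = 9, stage_probs = probs,
                    capture_per_attack = setNames(rep(q, 3), prey_types()))
  sim <- simulate_dataset(cfg)
  oc <- code_outcomes(sim$events, sim$birds$bird_id)
  r <- failed_attack_ratio(oc)
  expected <- (1 - q) / q
  se <- sqrt((1 - q) / q^2 / 250)
  for (ty in prey_types()) {
    expect_lt(abs(r[[ty]] - expected), 4 * se)
  }
})
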