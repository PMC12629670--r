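test_that("a pair's events reduce to the highest stage reached", {
  cases <- list(
    list(ev = ev_df("approach", 120), stage = "DETECTED", fat = 60,
         failed = 0L),
    list(ev = ev_df()[0, ], stage = "NONE", fat = 60, failed = 0L),
    list(ev = ev_df("attack_start", 300, "capture", 302, "consume", 320),
         stage = "CONSUMED", fat = 5, failed = 0L),
    list(ev = ev_df("attack_start", 100, "attack_start", 200,
                    "capture", 205),
         stage = "CAPTURED", fat = 100 / 60, failed = 1L),
    # capture then release with no consume stays CAPTURED
    list(ev = ev_df("approach", 50, "attack_start", 90, "capture", 95,
                    "release", 120),
         stage = "CAPTURED", fat = 1.5, failed = 0L),
    # every strike missing: all attacks count as failed
    list(ev = ev_df("attack_start", 10, "attack_start", 20,
                    "attack_start", 30),
         stage = "ATTACKED", fat = 10 / 60, failed = 3L))
  for (cs in cases) {
    out <- code_predation_outcome(cs$ev)
    expect_equal(as.character(out$stage), cs$stage)
    expect_equal(out$first_attack_time, cs$fat)
    expect_equal(out$n_failed_attack_events, cs$failed)
  }
})

test_that("malformed sequences and unknown tokens are rejected", {
  expect_error(code_predation_outcome(ev_df("consume", 100)),
               "malformed")
  expect_error(code_predation_outcome(ev_df("capture", 100)),
               "malformed")
  expect_error(code_predation_outcome(ev_df("pounce", 100)),
               "unknown event")
  expect_error(code_predation_outcome(ev_df("approach", 5000)),
               "trial window")
})

test_that("code_outcomes yields one row per bird and prey type, NONE implicit", {
  events <- rbind(
    pair_events("b1", "spicauda", ev_df("attack_start", 60, "capture", 65)),
    pair_events("b1", "heliconius", ev_df("approach", 30)),
    pair_events("b2", "euptychiina", ev_df("approach", 10)))
  oc <- code_outcomes(events, c("b1", "b2", "b3"))
  expect_equal(nrow(oc), 9L)
  expect_equal(sum(oc$stage == "NONE"), 6L)
  expect_equal(as.character(oc$stage[oc$bird_id == "b1" &
                                       oc$prey_type == "spicauda"]),
               "CAPTURED")
  expect_error(code_outcomes(events, c("b1")), "unknown bird_id")
})

test_that("exclusion removes only birds with three NONE outcomes", {
  oc <- rbind(
    bird_outcomes("b1", list(euptychiina = "NONE", heliconius = "NONE",
                             spicauda = "NONE")),
    bird_outcomes("b2", list(euptychiina = "NONE", heliconius = "DETECTED",
                             spicauda = "NONE")))
  flt <- apply_exclusion(oc)
  expect_equal(flt$excluded, "b1")
  expect_equal(unique(flt$outcomes$bird_id), "b2")

  empty <- apply_exclusion(oc[0, ])
  expect_equal(nrow(empty$outcomes), 0L)
  expect_length(empty$excluded, 0L)

  expect_error(apply_exclusion(oc[-1, ]), "exactly 3")
})

test_that("stage counts partition interacting birds and stay monotone", {
  fx <- study_count_fixture()
  oc <- apply_exclusion(fx$outcomes)$outcomes
  att <- aggregate_stage_counts(oc, "attacked")
  expect_equal(unname(att$a),
               c(28, 23, 52))  # euptychiina, heliconius, spicauda
  expect_equal(unname(att$N), rep(131, 3))

  und <- aggregate_stage_counts(oc, "undetected")
  sr <- aggregate_stage_counts(oc, "sight_rejected")
  expect_equal(unname(und$a + sr$a + att$a), rep(131, 3))

  cap <- aggregate_stage_counts(oc, "capture_avoided")
  srv <- aggregate_stage_counts(oc, "survived")
  expect_equal(unname(cap$N), unname(att$a))
  expect_equal(unname(srv$N), unname(att$a))
  expect_true(all(cap$a <= cap$N) && all(srv$a <= srv$N))

  adult <- aggregate_stage_counts(oc, "attacked", list(age = "adult"),
                                  fx$meta)
  expect_equal(unname(adult$a), c(9, 3, 22))
  expect_equal(unname(adult$N), rep(41, 3))

  expect_error(aggregate_stage_counts(oc, "attacked",
                                      list(family = "Corvidae"), fx$meta),
               "zero birds")
})

test_that("degenerate stage tables code correctly", {
  oc <- rbind(
    bird_outcomes("b1", list(euptychiina = "DETECTED", heliconius = "NONE",
                             spicauda = "NONE")),
    do.call(rbind, lapply(sprintf("c%02d", 1:10), function(b) {
      bird_outcomes(b, list(euptychiina = "CONSUMED",
                            heliconius = "CONSUMED",
                            spicauda = "CONSUMED"))
    })))
  att_only_det <- aggregate_stage_counts(
    oc[oc$bird_id == "b1", , drop = FALSE], "attacked")
  expect_equal(unname(att_only_det$a), c(0, 0, 0))

  chains <- oc[oc$bird_id != "b1", , drop = FALSE]
  srv <- aggregate_stage_counts(chains, "survived")
  expect_equal(unname(srv$a), c(0, 0, 0))
  expect_equal(unname(srv$N), c(10, 10, 10))
})

test_that("exported GLMM tables have the per-pair binary structure", {
  fx <- study_count_fixture()
  oc <- apply_exclusion(fx$outcomes)$outcomes
  g <- export_glmm_tables(oc, fx$meta)
  expect_equal(nrow(g$attack), 3 * 131)
  expect_equal(nrow(g$sight_reject), 208)
  expect_equal(sum(g$attack$response), 28 + 23 + 52)
  # sight-rejection responses: detected-but-never-attacked pairs
  expect_equal(sum(g$sight_reject$response), 208 - 103)

  oc1 <- bird_outcomes("b9", list(euptychiina = "NONE",
                                  heliconius = "DETECTED",
                                  spicauda = "ATTACKED"))
  g1 <- export_glmm_tables(oc1, meta_df("b9"))
  att <- g1$attack[order(match(g1$attack$prey_type, prey_types())), ]
  expect_equal(att$response, c(0, 0, 1))
  expect_equal(nrow(g1$sight_reject), 2L)
  expect_equal(
    g1$sight_reject$response[order(g1$sight_reject$prey_type)],
    c(1, 0))  # heliconius sight-rejected, spicauda attacked
})

test_that("recoding simulator events recovers the generator's truth", {
  sim <- simulate_dataset(sim_config(n_birds = 40, seed = 42))
  oc <- code_outcomes(sim$events, sim$birds$bird_id)
  key <- function(d) order(d$bird_id, d$prey_type)
  expect_equal(as.character(oc$stage[key(oc)]),
               sim$truth$stage[key(sim$truth)])
  expect_equal(oc$n_failed_attack_events[key(oc)],
               sim$truth$n_failed_attack_events[key(sim$truth)])

  # monotone counts along the sequence per prey type
  flt <- apply_exclusion(oc)
  st <- flt$outcomes$stage
  for (ty in prey_types()) {
    s <- st[flt$outcomes$prey_type == ty]
    n <- length(s)
    expect_true(n >= sum(s >= "DETECTED"))
    expect_true(sum(s >= "DETECTED") >= sum(s >= "ATTACKED"))
    expect_true(sum(s >= "ATTACKED") >= sum(s >= "CAPTURED"))
    expect_true(sum(s >= "CAPTURED") >= sum(s >= "CONSUMED"))
  }
})
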