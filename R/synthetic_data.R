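#' Configuration of the aviary-trial simulator
#'
#' Defines the stochastic structure of a synthetic aviary experiment: each
#' trial presents one wild-caught bird with the three butterfly prey types
#' for 60 minutes in a two-stratum aviary. Per bird and prey type the
#' simulator walks the Bernoulli chain detect -> attack -> capture -> kill;
#' detection can optionally be scaled by the realized vertical co-occurrence
#' index of the pair. Defaults emulate the study design: 131 birds, an
#' immature/adult mix of 90/41, butterflies concentrated in the upper
#' stratum except the cryptic ground-dwelling type, and stage-transition
#' probabilities calibrated to the observed marginal stage rates.
#'
#' @param n_birds number of trials/birds.
#' @param trial_seconds trial length in seconds.
#' @param seed root seed; each bird uses an independent substream derived
#'   from it, so earlier birds are unchanged when \code{n_birds} grows.
#' @param p_immature proportion of immature birds.
#' @param stage_probs list with per-age matrices \code{detect},
#'   \code{attack}, \code{capture}, \code{kill}; each a 2 x 3 matrix
#'   (rows \code{immature}, \code{adult}; columns the prey types) of
#'   conditional stage-transition probabilities.
#' @param occupancy list with \code{butterfly_mean_high} (named per prey
#'   type), \code{bird_mean_high} (default and per-family overrides) and
#'   \code{kappa} concentration parameters of the Beta draws for the
#'   proportion of time spent in the upper stratum.
#' @param capture_per_attack named per-type probability that any single
#'   strike captures the prey, used to generate repeated failed strikes.
#' @param giveup_prob probability after each failed strike that a bird whose
#'   chain says the prey is never captured stops attacking.
#' @param encounter_coupling logical; when \code{TRUE}, detection
#'   probability is multiplied by the realized Co index of the pair.
#' @param families named vector of bird-family sampling weights.
#' @param p_insectivorous probability a bird is fully insectivorous.
#' @param site_probs named probabilities of the habitat x season cells
#'   (\code{forest_wet}, \code{forest_dry}, \code{urban_wet}); the urban/dry
#'   cell is absent, as in the study design.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_birds = 131,
                       trial_seconds = 3600,
                       seed = 1,
                       p_immature = 90 / 131,
                       stage_probs = default_stage_probs(),
                       occupancy = default_occupancy(),
                       capture_per_attack = c(euptychiina = 0.52,
                                              heliconius = 0.38,
                                              spicauda = 0.33),
                       giveup_prob = 0.5,
                       encounter_coupling = FALSE,
                       families = c(Tyrannidae = 0.25, Thamnophilidae = 0.18,
                                    Thraupidae = 0.13, Furnariidae = 0.12,
                                    Turdidae = 0.12, Pipromorphidae = 0.08,
                                    Vireonidae = 0.07, Cardinalidae = 0.05),
                       p_insectivorous = 0.55,
                       site_probs = c(forest_wet = 70 / 216,
                                      forest_dry = 81 / 216,
                                      urban_wet = 65 / 216)) {
  cfg <- list(n_birds = n_birds, trial_seconds = trial_seconds, seed = seed,
              p_immature = p_immature, stage_probs = stage_probs,
              occupancy = occupancy,
              capture_per_attack = capture_per_attack,
              giveup_prob = giveup_prob,
              encounter_coupling = encounter_coupling,
              families = families / sum(families),
              p_insectivorous = p_insectivorous,
              site_probs = site_probs / sum(site_probs))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_stage_probs <- function() {
  mk <- function(imm, ad) {
    m <- rbind(immature = imm, adult = ad)
    colnames(m) <- PREY_TYPES
    m
  }
  # Calibrated to the observed marginal stage rates: detection marginals
  # ~0.30/0.66/0.82, attack marginals by age (immature ~0.21/0.22/0.33,
  # adult ~0.22/0.07/0.54), capture and kill marginals ~0.12/0.06/0.16 and
  # ~0.07/0.04/0.09 of interacting birds.
  list(detect  = mk(c(0.30, 0.66, 0.82), c(0.30, 0.66, 0.82)),
       attack  = mk(c(0.70, 0.34, 0.41), c(0.73, 0.11, 0.65)),
       capture = mk(c(0.57, 0.33, 0.40), c(0.57, 0.33, 0.40)),
       kill    = mk(c(0.58, 0.67, 0.56), c(0.58, 0.67, 0.56)))
}

#' @rdname sim_config
#' @export
default_occupancy <- function() {
  list(butterfly_mean_high = c(euptychiina = 0.45, heliconius = 0.83,
                               spicauda = 0.78),
       bird_mean_high = c(default = 0.70, Vireonidae = 0.86,
                          Thamnophilidae = 0.34),
       kappa = 5)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_birds >= 1, cfg$trial_seconds > 0)
  for (nm in c("detect", "attack", "capture", "kill")) {
    m <- cfg$stage_probs[[nm]]
    if (any(m < 0 | m > 1)) {
      stop("stage_probs$", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(all(cfg$capture_per_attack >= 0 & cfg$capture_per_attack <= 1),
            cfg$giveup_prob > 0, cfg$giveup_prob <= 1)
  invisible(cfg)
}

bird_seed <- function(root, b) {
  # independent substream per bird, stable under changes of n_birds
  (as.numeric(root) * 48271 + b * 99991) %% 2147483647
}

rbeta_mean <- function(n, mean, kappa) {
  mean <- min(max(mean, 1e-6), 1 - 1e-6)
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

# Emit alternating stratum intervals totalling p_high*T in the high stratum.
occupancy_intervals <- function(exp_id, subject_id, kind, p_high,
                                trial_seconds) {
  t_high <- p_high * trial_seconds
  t_low <- trial_seconds - t_high
  segs <- list()
  if (t_high > 0) segs <- c(segs, list(c("high", 0, t_high)))
  if (t_low > 0) segs <- c(segs, list(c("low", t_high, trial_seconds)))
  do.call(rbind, lapply(segs, function(s) {
    data.frame(experiment_id = exp_id, subject_id = subject_id,
               subject_kind = kind, stratum = s[1],
               t_start = as.numeric(s[2]), t_end = as.numeric(s[3]),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a complete aviary experiment
#'
#' Generates the three tables the pipeline reads (bird metadata, behavioral
#' events, stratum-occupancy intervals) plus a truth record holding every
#' realized stage label, Co index and failed-attack count, so that event
#' coding can be verified exactly against the generator. Output is fully
#' reproducible from the configuration seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with data frames \code{birds}, \code{events},
#'   \code{occupancy}, \code{truth} and the \code{config}.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  tlen <- config$trial_seconds
  birds <- events <- occ <- truth <- list()
  for (b in seq_len(config$n_birds)) {
    set.seed(bird_seed(config$seed, b))
    bird_id <- sprintf("bird%04d", b)
    exp_id <- sprintf("exp%04d", b)
    age <- if (stats::runif(1) < config$p_immature) "immature" else "adult"
    family <- sample(names(config$families), 1, prob = config$families)
    diet <- if (stats::runif(1) < config$p_insectivorous) {
      "insectivorous"
    } else {
      "mixed"
    }
    site <- sample(names(config$site_probs), 1, prob = config$site_probs)
    habitat <- sub("_.*$", "", site)
    season <- sub("^.*_", "", site)
    birds[[b]] <- data.frame(
      bird_id = bird_id, species = paste0(family, "_sp"), family = family,
      age = age, diet = diet, habitat = habitat, season = season,
      stringsAsFactors = FALSE)

    bm <- config$occupancy$bird_mean_high
    mean_high <- if (family %in% names(bm)) bm[[family]] else bm[["default"]]
    bird_high <- rbeta_mean(1, mean_high, config$occupancy$kappa)
    occ[[length(occ) + 1L]] <- occupancy_intervals(
      exp_id, bird_id, "bird", bird_high, tlen)

    for (ty in PREY_TYPES) {
      prey_id <- paste(exp_id, ty, sep = "_")
      fly_high <- rbeta_mean(1, config$occupancy$butterfly_mean_high[[ty]],
                             config$occupancy$kappa)
      occ[[length(occ) + 1L]] <- occupancy_intervals(
        exp_id, prey_id, "butterfly", fly_high, tlen)
      co <- bird_high * fly_high + (1 - bird_high) * (1 - fly_high)

      sp <- config$stage_probs
      p_det <- sp$detect[age, ty] * if (config$encounter_coupling) co else 1
      stage <- "NONE"
      n_failed <- 0L
      ev <- list()
      if (stats::runif(1) < p_det) {
        stage <- "DETECTED"
        t_approach <- stats::runif(1, 0, tlen - 60)
        ev <- c(ev, list(c("approach", t_approach)))
        if (stats::runif(1) < sp$attack[age, ty]) {
          stage <- "ATTACKED"
          captured <- stats::runif(1) < sp$capture[age, ty]
          q <- config$capture_per_attack[[ty]]
          if (captured) {
            n_failed <- stats::rgeom(1, max(q, 1e-6))
          } else {
            n_failed <- 1L + stats::rgeom(1, config$giveup_prob)
          }
          n_attacks <- n_failed + as.integer(captured)
          slots <- sort(stats::runif(n_attacks, t_approach + 1, tlen - 30))
          for (tt in slots) ev <- c(ev, list(c("attack_start", tt)))
          if (captured) {
            stage <- "CAPTURED"
            t_cap <- slots[n_attacks] + stats::runif(1, 0.5, 5)
            ev <- c(ev, list(c("capture", t_cap)))
            if (stats::runif(1) < sp$kill[age, ty]) {
              stage <- "CONSUMED"
              ev <- c(ev, list(c("consume", t_cap + stats::runif(1, 1, 20))))
            } else {
              ev <- c(ev, list(c("release", t_cap + stats::runif(1, 1, 20))))
            }
          }
        }
      }
      if (length(ev) > 0L) {
        events[[length(events) + 1L]] <- data.frame(
          experiment_id = exp_id, bird_id = bird_id, prey_id = prey_id,
          prey_type = ty, event = vapply(ev, `[`, character(1), 1),
          t = as.numeric(vapply(ev, `[`, character(1), 2)),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        bird_id = bird_id, prey_type = ty, stage = stage,
        n_failed_attack_events = n_failed, co = co, age = age,
        stringsAsFactors = FALSE)
    }
  }
  empty_events <- data.frame(
    experiment_id = character(0), bird_id = character(0),
    prey_id = character(0), prey_type = character(0),
    event = character(0), t = numeric(0), stringsAsFactors = FALSE)
  list(birds = do.call(rbind, birds),
       events = if (length(events)) do.call(rbind, events) else empty_events,
       occupancy = do.call(rbind, occ),
       truth = do.call(rbind, truth),
       config = config)
}

#' Parameter-recovery study for the simulation-analysis round trip
#'
#' Repeatedly simulates an experiment, codes its events with the events
#' module, and compares (i) the empirical conditional stage-transition rates
#' against the configured truth (bias and coverage of a 3-standard-error
#' binomial interval) and (ii) best-model selection frequencies on the
#' attacked-stage table.
#'
#' @param config a \code{\link{sim_config}}; its seed anchors replicate
#'   substreams.
#' @param n_replicates number of simulated experiments.
#' @return list with \code{rates} (per prey type and transition: truth,
#'   mean estimate, bias, 3-SE coverage) and \code{selection} (table of
#'   best-model frequencies for the attacked stage).
#' @export
parameter_recovery <- function(config, n_replicates) {
  stopifnot(n_replicates >= 1)
  trans <- c("detect", "attack", "capture", "kill")
  est <- array(NA_real_, dim = c(n_replicates, length(trans), 3),
               dimnames = list(NULL, trans, PREY_TYPES))
  denoms <- est
  best <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- bird_seed(config$seed, r * 1000L)
    sim <- simulate_dataset(cfg)
    outcomes <- code_outcomes(sim$events, sim$birds$bird_id,
                              cfg$trial_seconds)
    st <- as_stage(outcomes$stage)
    for (ty in PREY_TYPES) {
      s <- st[outcomes$prey_type == ty]
      n_tot <- length(s)
      n_det <- sum(s >= "DETECTED"); n_att <- sum(s >= "ATTACKED")
      n_cap <- sum(s >= "CAPTURED"); n_kill <- sum(s == "CONSUMED")
      est[r, "detect", ty] <- n_det / n_tot
      denoms[r, "detect", ty] <- n_tot
      if (n_det > 0) { est[r, "attack", ty] <- n_att / n_det
                       denoms[r, "attack", ty] <- n_det }
      if (n_att > 0) { est[r, "capture", ty] <- n_cap / n_att
                       denoms[r, "capture", ty] <- n_att }
      if (n_cap > 0) { est[r, "kill", ty] <- n_kill / n_cap
                       denoms[r, "kill", ty] <- n_cap }
    }
    flt <- apply_exclusion(outcomes)
    cnt <- aggregate_stage_counts(flt$outcomes, "attacked")
    cmp <- compare_models(cnt)
    best[r] <- cmp$model[cmp$is_best]
  }
  # truth: age-mixture of the conditional transition probabilities
  w <- c(immature = config$p_immature, adult = 1 - config$p_immature)
  rows <- list()
  for (tr in trans) {
    for (ty in PREY_TYPES) {
      truth_p <- sum(w * config$stage_probs[[tr]][names(w), ty])
      e <- est[, tr, ty]; d <- denoms[, tr, ty]
      ok <- !is.na(e)
      se <- sqrt(pmax(truth_p * (1 - truth_p), 1e-12) / d[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        transition = tr, prey_type = ty, truth = truth_p,
        mean_estimate = mean(e[ok]), bias = mean(e[ok]) - truth_p,
        coverage_3se = mean(abs(e[ok] - truth_p) <= 3 * se),
        n_replicates_used = sum(ok), stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  list(rates = rates,
       selection = table(factor(best, levels = MODEL_ORDER)))
}

#' Model-selection consistency under a known attack-rate truth
#'
#' Draws per-type attacked counts directly from the binomial law the
#' simulator induces at the attacked stage (per-bird Bernoulli trials are
#' the sufficient statistic there), runs \code{\link{compare_models}} on
#' each replicate, and reports how often each sample size selects the
#' partition model matching the configured truth. Within a replicate the
#' sample sizes are nested (the larger experiment extends the smaller one
#' with additional birds), so the comparison across sizes asks the
#' scientific question directly -- does adding birds to the same experiment
#' improve selection -- and shares random numbers across sizes for variance
#' reduction.
#'
#' @param p_attack named per-type attack probabilities.
#' @param true_model name of the generating partition model.
#' @param n_birds_vec sample sizes to evaluate (nested per replicate).
#' @param n_replicates number of replicates.
#' @param seed RNG seed.
#' @return data frame with \code{n_birds} and \code{freq_true} (fraction of
#'   replicates whose best model is \code{true_model}).
#' @export
selection_consistency <- function(p_attack, true_model,
                                  n_birds_vec = c(50, 200, 800),
                                  n_replicates = 200, seed = 1) {
  p_attack <- p_attack[PREY_TYPES]
  stopifnot(!anyNA(p_attack), true_model %in% MODEL_ORDER)
  n_max <- max(n_birds_vec)
  hits <- matrix(FALSE, n_replicates, length(n_birds_vec))
  for (r in seq_len(n_replicates)) {
    set.seed(bird_seed(seed, r))
    trials <- vapply(p_attack, function(p) {
      stats::runif(n_max) < p
    }, logical(n_max))
    for (i in seq_along(n_birds_vec)) {
      n <- n_birds_vec[i]
      a <- colSums(trials[seq_len(n), , drop = FALSE])
      cnt <- stage_counts("attacked", a,
                          stats::setNames(rep(n, 3), PREY_TYPES))
      cmp <- compare_models(cnt)
      hits[r, i] <- cmp$model[cmp$is_best] == true_model
    }
  }
  data.frame(n_birds = n_birds_vec, freq_true = colMeans(hits))
}
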