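# Builders for tiny in-code fixtures used across the test files.

ev_df <- function(...) {
  # ev_df("approach", 120, "attack_start", 300, ...)
  args <- list(...)
  stopifnot(length(args) %% 2 == 0)
  if (length(args) == 0) {
    return(data.frame(event = character(0), t = numeric(0)))
  }
  idx <- seq(1, length(args), by = 2)
  data.frame(event = unlist(args[idx]),
             t = as.numeric(unlist(args[idx + 1])),
             stringsAsFactors = FALSE)
}

pair_events <- function(bird_id, prey_type, events) {
  if (nrow(events) == 0) {
    return(data.frame(experiment_id = character(0), bird_id = character(0),
                      prey_id = character(0), prey_type = character(0),
                      event = character(0), t = numeric(0)))
  }
  cbind(data.frame(experiment_id = paste0("exp_", bird_id),
                   bird_id = bird_id,
                   prey_id = paste0(bird_id, "_", prey_type),
                   prey_type = prey_type, stringsAsFactors = FALSE),
        events)
}

outcome_row <- function(bird_id, prey_type, stage,
                        first_attack_time = 60, n_failed = 0L) {
  data.frame(bird_id = bird_id, prey_type = prey_type,
             stage = factor(stage, levels = stage_levels(), ordered = TRUE),
             first_attack_time = first_attack_time,
             n_failed_attack_events = n_failed, stringsAsFactors = FALSE)
}

# full 3-row outcome block for one bird from a named stage vector
bird_outcomes <- function(bird_id, stages) {
  do.call(rbind, lapply(prey_types(), function(ty) {
    st <- stages[[ty]]
    outcome_row(bird_id, ty, st,
                first_attack_time = if (st %in% c("ATTACKED", "CAPTURED",
                                                  "CONSUMED")) 10 else 60)
  }))
}

meta_df <- function(bird_ids, age = "adult", diet = "insectivorous",
                    habitat = "forest", season = "wet") {
  data.frame(bird_id = bird_ids, species = "sp1", family = "Tyrannidae",
             age = rep_len(age, length(bird_ids)),
             diet = rep_len(diet, length(bird_ids)),
             habitat = rep_len(habitat, length(bird_ids)),
             season = rep_len(season, length(bird_ids)),
             stringsAsFactors = FALSE)
}

# exact-rational binomial log10-likelihood oracle: per prey type the
# numerator and denominator of the probability product are tracked as
# exactly representable integers (valid for N <= 12 and rational p = s/t
# with small s, t), then log10 is taken per type and summed.
oracle_log10_lik <- function(a, N, p_num, p_den) {
  total <- 0
  for (i in seq_along(a)) {
    num <- p_num[i]^a[i] * (p_den[i] - p_num[i])^(N[i] - a[i])
    den <- p_den[i]^N[i]
    if (num == 0) return(-Inf)
    total <- total + log10(num) - log10(den)
  }
  total
}

# brute-force signed-rank two-sided p by enumerating all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

sim_to_files <- function(sim, dir) {
  paths <- c(birds = file.path(dir, "birds.csv"),
             events = file.path(dir, "events.csv"),
             occupancy = file.path(dir, "occupancy.csv"))
  write.csv(sim$birds, paths["birds"], row.names = FALSE)
  write.csv(sim$events, paths["events"], row.names = FALSE)
  write.csv(sim$occupancy, paths["occupancy"], row.names = FALSE)
  paths
}
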