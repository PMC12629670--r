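#' Code the events of one bird-butterfly pair into a predation outcome
#'
#' Reduces the timestamped behavioral events of a single bird x prey-type
#' pair to the highest predation stage reached, the time of the first attack,
#' and the number of failed attack events. Each pair is assigned the maximum
#' stage implied by any of its events: an \code{approach} implies at least
#' \code{DETECTED}, an \code{attack_start} at least \code{ATTACKED}, a
#' \code{capture} at least \code{CAPTURED} and a \code{consume} implies
#' \code{CONSUMED}. A capture followed by a \code{release} with no later
#' consumption stays \code{CAPTURED}.
#'
#' An \code{attack_start} counts as failed when no \code{capture} occurs
#' after it and before the next \code{attack_start} (or the end of the
#' trial). A \code{capture} or \code{consume} with no preceding
#' \code{attack_start} is rejected as a malformed sequence, as is any
#' unrecognised event token.
#'
#' @param events data frame with columns \code{event} and \code{t} (seconds
#'   from trial start) for one bird x prey-type pair; zero rows means the
#'   pair never interacted.
#' @param trial_seconds trial length in seconds (default 3600).
#' @return A one-row data frame with columns \code{stage} (ordered factor),
#'   \code{first_attack_time} (minutes; 60 when no attack occurred) and
#'   \code{n_failed_attack_events}.
#' @export
code_predation_outcome <- function(events, trial_seconds = 3600) {
  if (nrow(events) == 0L) {
    return(data.frame(stage = as_stage("NONE"), first_attack_time = 60,
                      n_failed_attack_events = 0L))
  }
  bad <- setdiff(unique(as.character(events$event)), EVENT_TOKENS)
  if (length(bad) > 0L) {
    stop("unknown event token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$t < 0 | events$t > trial_seconds)) {
    stop("event time outside the trial window [0, ", trial_seconds, "]",
         call. = FALSE)
  }
  ev <- events[order(events$t), , drop = FALSE]
  tok <- as.character(ev$event)
  has_attack <- any(tok == "attack_start")
  if (any(tok %in% c("capture", "consume")) && !has_attack) {
    stop("malformed sequence: capture/consume without any attack_start",
         call. = FALSE)
  }

  stage <- "NONE"
  if (any(tok == "approach")) stage <- "DETECTED"
  if (has_attack) stage <- "ATTACKED"
  if (any(tok == "capture")) stage <- "CAPTURED"
  if (any(tok == "consume")) stage <- "CONSUMED"

  first_attack <- if (has_attack) min(ev$t[tok == "attack_start"]) / 60 else 60

  # An attack fails when no capture lands before the next attack begins.
  n_failed <- 0L
  if (has_attack) {
    att_t <- ev$t[tok == "attack_start"]
    cap_t <- ev$t[tok == "capture"]
    bounds <- c(att_t[-1], Inf)
    for (j in seq_along(att_t)) {
      if (!any(cap_t > att_t[j] & cap_t <= bounds[j])) {
        n_failed <- n_failed + 1L
      }
    }
  }
  data.frame(stage = as_stage(stage), first_attack_time = first_attack,
             n_failed_attack_events = n_failed)
}

#' Code all bird x prey-type outcomes of an experiment log
#'
#' Produces exactly one outcome row per bird and prey type (three per bird):
#' pairs with no logged events are coded \code{NONE}, since every trial
#' presents all three prey types.
#'
#' @param events event table with columns \code{bird_id}, \code{prey_type},
#'   \code{event}, \code{t}.
#' @param bird_ids character vector of all tested birds (typically
#'   \code{birds$bird_id}); birds absent from the event log still get three
#'   \code{NONE} rows.
#' @param trial_seconds trial length in seconds.
#' @return data frame with one row per bird x prey type: \code{bird_id},
#'   \code{prey_type}, \code{stage}, \code{first_attack_time},
#'   \code{n_failed_attack_events}.
#' @export
code_outcomes <- function(events, bird_ids, trial_seconds = 3600) {
  bird_ids <- unique(as.character(bird_ids))
  bad_type <- setdiff(unique(as.character(events$prey_type)), PREY_TYPES)
  if (length(bad_type) > 0L) {
    stop("unknown prey_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  stray <- setdiff(unique(as.character(events$bird_id)), bird_ids)
  if (length(stray) > 0L) {
    stop("events reference unknown bird_id(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  grid <- expand.grid(bird_id = bird_ids, prey_type = PREY_TYPES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- events$bird_id == grid$bird_id[i] &
      events$prey_type == grid$prey_type[i]
    out <- code_predation_outcome(events[sel, , drop = FALSE], trial_seconds)
    cbind(grid[i, , drop = FALSE], out, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$bird_id, match(out$prey_type, PREY_TYPES)), , drop = FALSE]
}

#' Exclude birds that never entered the predation sequence
#'
#' Birds whose three outcomes are all \code{NONE} (no pursuit, sight
#' rejection or attack toward any butterfly) are removed; the remaining
#' number of birds defines the trial count N used by all stage tables.
#'
#' @param outcomes outcome table from \code{\link{code_outcomes}}; every bird
#'   must have exactly three rows (one per prey type).
#' @return list with \code{outcomes} (filtered table) and \code{excluded}
#'   (character vector of removed bird ids).
#' @export
apply_exclusion <- function(outcomes) {
  if (nrow(outcomes) == 0L) {
    return(list(outcomes = outcomes, excluded = character(0)))
  }
  tab <- table(outcomes$bird_id)
  if (any(tab != 3L)) {
    stop("every bird must have exactly 3 outcomes; offending bird(s): ",
         paste(names(tab)[tab != 3L], collapse = ", "), call. = FALSE)
  }
  interacted <- tapply(outcomes$stage != "NONE", outcomes$bird_id, any)
  excluded <- names(interacted)[!interacted]
  keep <- !(outcomes$bird_id %in% excluded)
  list(outcomes = outcomes[keep, , drop = FALSE], excluded = excluded)
}

subset_birds <- function(meta, subset = NULL) {
  if (is.null(subset) || length(subset) == 0L) return(meta$bird_id)
  keep <- rep(TRUE, nrow(meta))
  for (field in names(subset)) {
    if (!field %in% names(meta)) {
      stop("unknown metadata field in subset: ", field, call. = FALSE)
    }
    keep <- keep & meta[[field]] == subset[[field]]
  }
  meta$bird_id[keep]
}

subset_label <- function(subset = NULL) {
  if (is.null(subset) || length(subset) == 0L) return("all")
  paste(paste0(names(subset), "=", unlist(subset)), collapse = ",")
}

#' Aggregate per-stage success/trial counts by prey type
#'
#' Builds the binomial counts for one predation stage. For the
#' \code{undetected}, \code{sight_rejected} and \code{attacked} stages the
#' number of trials per prey type is the common number of interacting birds
#' N; for \code{capture_avoided} and \code{survived} the trials are that prey
#' type's attacked count, so trials differ between types.
#'
#' @param outcomes exclusion-filtered outcome table.
#' @param stage_label one of \code{stage_labels()}.
#' @param subset optional named list of bird-metadata filters, e.g.
#'   \code{list(age = "adult")}; requires \code{meta}.
#' @param meta bird metadata table (needed when \code{subset} is given).
#' @return An object of class \code{stage_counts}: list with
#'   \code{stage_label}, \code{subset}, and named vectors \code{a}
#'   (successes) and \code{N} (trials) over the three prey types.
#' @export
aggregate_stage_counts <- function(outcomes, stage_label, subset = NULL,
                                   meta = NULL) {
  stage_label <- match.arg(stage_label, STAGE_LABELS)
  if (!is.null(subset)) {
    if (is.null(meta)) stop("subset filtering requires `meta`", call. = FALSE)
    ids <- subset_birds(meta, subset)
    outcomes <- outcomes[outcomes$bird_id %in% ids, , drop = FALSE]
  }
  n_birds <- length(unique(outcomes$bird_id))
  if (n_birds == 0L) {
    stop("subset `", subset_label(subset), "` selects zero birds",
         call. = FALSE)
  }
  st <- as_stage(outcomes$stage)
  a <- N <- stats::setNames(numeric(3), PREY_TYPES)
  for (ty in PREY_TYPES) {
    s <- st[outcomes$prey_type == ty]
    n_att <- sum(s >= "ATTACKED")
    switch(stage_label,
      undetected      = { a[ty] <- sum(s == "NONE");     N[ty] <- n_birds },
      sight_rejected  = { a[ty] <- sum(s == "DETECTED"); N[ty] <- n_birds },
      attacked        = { a[ty] <- n_att;                N[ty] <- n_birds },
      capture_avoided = { a[ty] <- sum(s == "ATTACKED"); N[ty] <- n_att },
      survived        = { a[ty] <- sum(s >= "ATTACKED" & s < "CONSUMED")
                          N[ty] <- n_att })
  }
  stage_counts(stage_label, a, N, subset_label(subset))
}

#' Construct a stage-counts object directly from counts
#'
#' @param stage_label one of \code{stage_labels()}.
#' @param a named vector of successes per prey type.
#' @param N named vector of trials per prey type.
#' @param subset descriptor of the bird subset (default \code{"all"}).
#' @return object of class \code{stage_counts}.
#' @export
stage_counts <- function(stage_label, a, N, subset = "all") {
  a <- a[PREY_TYPES]; N <- N[PREY_TYPES]
  if (anyNA(a) || anyNA(N)) {
    stop("counts must be named by the three prey types", call. = FALSE)
  }
  if (any(a < 0) || any(a > N)) {
    stop("need 0 <= a_i <= N_i for every prey type", call. = FALSE)
  }
  structure(list(stage_label = stage_label, subset = subset,
                 a = a, N = N), class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat("Stage counts [", x$stage_label, "; subset ", x$subset, "]\n", sep = "")
  print(rbind(successes = x$a, trials = x$N))
  invisible(x)
}

#' Export binary response tables for logistic mixed-model fitting
#'
#' Produces the two per-pair binary tables used by downstream GLMM analyses
#' (fit outside this package). The attack table has one row per bird x prey
#' type (3N rows), response 1 when the pair reached at least
#' \code{ATTACKED}. The sight-rejection table is restricted to detected
#' pairs (stage at least \code{DETECTED}), response 1 when the bird
#' approached but never attacked, 0 when it attacked.
#'
#' @param outcomes exclusion-filtered outcome table.
#' @param meta bird metadata table (provides \code{age} and \code{diet}).
#' @return list with data frames \code{attack} and \code{sight_reject}, each
#'   carrying \code{bird_id}, \code{prey_type}, \code{age}, \code{diet},
#'   \code{response}.
#' @export
export_glmm_tables <- function(outcomes, meta) {
  m <- meta[match(outcomes$bird_id, meta$bird_id), c("age", "diet")]
  st <- as_stage(outcomes$stage)
  base <- data.frame(bird_id = outcomes$bird_id,
                     prey_type = outcomes$prey_type,
                     age = m$age, diet = m$diet,
                     stringsAsFactors = FALSE)
  attack <- cbind(base, response = as.integer(st >= "ATTACKED"))
  det <- st >= "DETECTED"
  sight <- cbind(base[det, , drop = FALSE],
                 response = as.integer(st[det] == "DETECTED"))
  rownames(attack) <- rownames(sight) <- NULL
  list(attack = attack, sight_reject = sight)
}
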