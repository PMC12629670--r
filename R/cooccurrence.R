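#' Vertical occupancy profile of one subject
#'
#' Converts the stratum-occupancy intervals of one subject (bird or
#' butterfly) into the proportions of observed time spent in the low
#' (0-200 cm) and high (200-400 cm) stratum. Time during which the subject
#' was not observed in either stratum is excluded from the denominator, so
#' proportions are conditional on observed time.
#'
#' @param intervals data frame with columns \code{stratum} (\code{"low"} or
#'   \code{"high"}), \code{t_start}, \code{t_end} (seconds); intervals of one
#'   subject must not overlap.
#' @param trial_seconds trial length in seconds.
#' @return object of class \code{occupancy_profile}: list with \code{p_low}
#'   and \code{p_high} summing to 1.
#' @export
occupancy_profile <- function(intervals, trial_seconds = 3600) {
  if (nrow(intervals) > 0L) {
    if (any(intervals$t_start >= intervals$t_end)) {
      stop("intervals need t_start < t_end", call. = FALSE)
    }
    if (any(intervals$t_start < 0 | intervals$t_end > trial_seconds)) {
      stop("interval outside the trial window", call. = FALSE)
    }
    o <- intervals[order(intervals$t_start), , drop = FALSE]
    if (nrow(o) > 1L && any(o$t_start[-1] < o$t_end[-nrow(o)])) {
      stop("overlapping occupancy intervals for one subject", call. = FALSE)
    }
  }
  dur <- intervals$t_end - intervals$t_start
  t_low <- sum(dur[intervals$stratum == "low"])
  t_high <- sum(dur[intervals$stratum == "high"])
  if (t_low + t_high <= 0) {
    stop("zero observed occupancy time", call. = FALSE)
  }
  structure(list(p_low = t_low / (t_low + t_high),
                 p_high = t_high / (t_low + t_high)),
            class = "occupancy_profile")
}

#' Two-stratum co-occurrence index
#'
#' Encounter-chance proxy for a bird-butterfly pair:
#' \deqn{Co = Bird_{low} \times Butterfly_{low} +
#'            Bird_{high} \times Butterfly_{high}.}
#' Co ranges from 0 (no vertical overlap, no chance of encounter) to 1
#' (complete overlap). It is symmetric in its two arguments.
#'
#' @param bird,prey occupancy profiles (\code{\link{occupancy_profile}}), or
#'   bare lists with elements \code{p_low} and \code{p_high}.
#' @return numeric Co index in [0, 1].
#' @export
co_index <- function(bird, prey) {
  co <- bird$p_low * prey$p_low + bird$p_high * prey$p_high
  stopifnot(co >= -1e-12, co <= 1 + 1e-12)
  min(max(co, 0), 1)
}

#' Co index for every bird-butterfly pair of an experiment set
#'
#' Joins, within each experiment, the bird's occupancy profile with the
#' profile of each of the three butterflies and evaluates
#' \code{\link{co_index}}.
#'
#' @param occupancy interval table with columns \code{experiment_id},
#'   \code{subject_id}, \code{subject_kind} (\code{"bird"}/\code{"butterfly"}),
#'   \code{stratum}, \code{t_start}, \code{t_end}.
#' @param prey_map data frame mapping butterfly \code{subject_id} to
#'   \code{prey_type}. When \code{NULL}, the prey type is inferred from the
#'   subject id, which must contain the prey-type name as a substring.
#' @param trial_seconds trial length in seconds.
#' @return data frame with \code{experiment_id}, \code{bird_id},
#'   \code{prey_type}, \code{co}.
#' @export
co_index_table <- function(occupancy, prey_map = NULL, trial_seconds = 3600) {
  res <- list()
  for (exp_id in unique(occupancy$experiment_id)) {
    oc <- occupancy[occupancy$experiment_id == exp_id, , drop = FALSE]
    bird_ids <- unique(oc$subject_id[oc$subject_kind == "bird"])
    if (length(bird_ids) != 1L) {
      stop("experiment ", exp_id, " must have exactly one bird subject",
           call. = FALSE)
    }
    bird_prof <- occupancy_profile(
      oc[oc$subject_id == bird_ids, , drop = FALSE], trial_seconds)
    fly_ids <- unique(oc$subject_id[oc$subject_kind == "butterfly"])
    for (fid in fly_ids) {
      ty <- if (!is.null(prey_map)) {
        prey_map$prey_type[match(fid, prey_map$subject_id)]
      } else {
        hit <- PREY_TYPES[vapply(PREY_TYPES, grepl, logical(1), x = fid)]
        if (length(hit) != 1L) NA_character_ else hit
      }
      if (is.na(ty)) {
        stop("cannot resolve prey type of butterfly subject ", fid,
             call. = FALSE)
      }
      prof <- occupancy_profile(oc[oc$subject_id == fid, , drop = FALSE],
                                trial_seconds)
      res[[length(res) + 1L]] <- data.frame(
        experiment_id = exp_id, bird_id = bird_ids, prey_type = ty,
        co = co_index(bird_prof, prof), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare Co indices between prey types (paired design)
#'
#' Each bird contributes one Co value per prey type; the three prey-type
#' pairs are compared with the paired Wilcoxon signed-rank test and
#' Bonferroni adjustment (factor 3, capped at 1). A Shapiro-Wilk normality
#' screen on the pooled Co values is reported alongside but never alters
#' which test is run.
#'
#' @param co_table data frame with \code{bird_id}, \code{prey_type},
#'   \code{co} (one row per bird x prey type).
#' @return list with \code{summary} (per-type mean, sd, n), \code{pairwise}
#'   (pairwise-result table, see \code{\link{pairwise_signed_rank}}) and
#'   \code{shapiro} (normality screen of pooled Co values).
#' @export
compare_co_by_prey <- function(co_table) {
  wide <- stats::reshape(
    co_table[, c("bird_id", "prey_type", "co")],
    direction = "wide", idvar = "bird_id", timevar = "prey_type")
  names(wide) <- sub("^co\\.", "", names(wide))
  missing_ty <- setdiff(PREY_TYPES, names(wide))
  if (length(missing_ty) > 0L) {
    stop("no Co values for prey type(s): ",
         paste(missing_ty, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(wide[, PREY_TYPES])
  if (sum(stats::complete.cases(mat)) < 2L) {
    stop("need at least 2 birds with complete Co values", call. = FALSE)
  }
  summ <- data.frame(
    prey_type = PREY_TYPES,
    mean = colMeans(mat, na.rm = TRUE),
    sd = apply(mat, 2, stats::sd, na.rm = TRUE),
    n = colSums(!is.na(mat)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summ,
       pairwise = pairwise_signed_rank(mat),
       shapiro = shapiro_screen(as.numeric(mat)))
}
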