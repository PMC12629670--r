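#' Run the five-stage partition-model analysis over bird subsets
#'
#' For every requested bird subset, builds the five stage tables (remaining
#' undetected, sight-rejected upon identification, attacked, capture
#' avoided, survived attack) and compares the five partition hypotheses on
#' each with AICc and Akaike weights. Subsets selecting zero birds, and
#' degenerate stage tables with too few trials for AICc, are skipped with a
#' warning. Season and habitat subsets carry a confounding note because the
#' urban site has no dry-season trials.
#'
#' @param outcomes exclusion-filtered outcome table.
#' @param meta bird metadata table.
#' @param subsets named list of subset filters; each element is \code{NULL}
#'   (all birds) or a named list such as \code{list(age = "adult")}.
#' @param log_base \code{"log10"} (default) or \code{"natural"}.
#' @param aicc_threshold ΔAICc non-rejection threshold (default 2).
#' @return object of class \code{stage_analysis_report}: list with
#'   \code{tables} (model-comparison tables keyed \code{"stage|subset"}),
#'   \code{counts} (matching \code{stage_counts}), \code{descriptives}
#'   (per stage/subset/prey-type rates), \code{first_attack},
#'   \code{failed_ratio} and \code{notes}.
#' @export
run_stage_analyses <- function(outcomes, meta,
                               subsets = list(all = NULL),
                               log_base = "log10", aicc_threshold = 2) {
  tables <- list()
  counts <- list()
  desc <- list()
  notes <- character(0)
  for (sname in names(subsets)) {
    subset <- subsets[[sname]]
    ids <- subset_birds(meta, subset)
    ids <- intersect(ids, unique(outcomes$bird_id))
    if (length(ids) == 0L) {
      warning("subset `", sname, "` selects zero birds; skipped",
              call. = FALSE)
      next
    }
    if (!is.null(subset) &&
        any(names(subset) %in% c("season", "habitat"))) {
      notes <- c(notes, paste0(
        "subset `", sname, "`: season and habitat are confounded ",
        "(no dry-season trials in the urban habitat)"))
    }
    for (stg in STAGE_LABELS) {
      cnt <- aggregate_stage_counts(outcomes, stg, subset, meta)
      key <- paste(stg, sname, sep = "|")
      counts[[key]] <- cnt
      tab <- tryCatch(
        compare_models(cnt, log_base = log_base,
                       aicc_threshold = aicc_threshold),
        error = function(e) {
          warning("stage `", stg, "`, subset `", sname, "`: ",
                  conditionMessage(e), "; comparison skipped",
                  call. = FALSE)
          NULL
        })
      if (!is.null(tab)) tables[[key]] <- tab
      desc[[key]] <- data.frame(
        stage_label = stg, subset = sname, prey_type = PREY_TYPES,
        successes = unname(cnt$a), trials = unname(cnt$N),
        rate = unname(ifelse(cnt$N > 0, cnt$a / cnt$N, NA_real_)),
        stringsAsFactors = FALSE)
    }
  }
  descriptives <- do.call(rbind, desc)
  rownames(descriptives) <- NULL
  structure(list(tables = tables, counts = counts,
                 descriptives = descriptives,
                 first_attack = first_attack_summary(outcomes),
                 failed_ratio = failed_attack_ratio(outcomes),
                 notes = notes),
            class = "stage_analysis_report")
}

#' @export
print.stage_analysis_report <- function(x, ...) {
  cat("Stage analysis report:", length(x$tables), "model comparisons\n")
  cat("Failed-attack ratios:\n")
  print(x$failed_ratio)
  if (length(x$notes)) cat("Notes:\n", paste("-", x$notes, collapse = "\n"),
                           "\n")
  invisible(x)
}

#' Summarise times to first attack per prey type
#'
#' Mean and SD (minutes) of the time to the first attack event per prey
#' type, with 60 min recorded for pairs that were never attacked, restricted
#' to birds that attacked at least one butterfly; pairwise signed-rank
#' comparisons with Bonferroni adjustment on the same birds (paired design).
#'
#' @param outcomes outcome table (exclusion-filtered).
#' @param meta optional metadata table, needed when \code{subset} is given.
#' @param subset optional named list of metadata filters.
#' @return list with \code{summary} (per-type mean, sd, n), \code{pairwise}
#'   and \code{n_birds} (birds attacking at least one butterfly).
#' @export
first_attack_summary <- function(outcomes, meta = NULL, subset = NULL) {
  if (!is.null(subset)) {
    if (is.null(meta)) stop("subset filtering requires `meta`", call. = FALSE)
    outcomes <- outcomes[outcomes$bird_id %in% subset_birds(meta, subset), ,
                         drop = FALSE]
  }
  att <- tapply(as_stage(outcomes$stage) >= "ATTACKED", outcomes$bird_id, any)
  attackers <- names(att)[att]
  if (length(attackers) == 0L) {
    stop("no birds attacked any butterfly in this selection", call. = FALSE)
  }
  oc <- outcomes[outcomes$bird_id %in% attackers, , drop = FALSE]
  wide <- stats::reshape(
    oc[, c("bird_id", "prey_type", "first_attack_time")],
    direction = "wide", idvar = "bird_id", timevar = "prey_type")
  names(wide) <- sub("^first_attack_time\\.", "", names(wide))
  mat <- as.matrix(wide[, PREY_TYPES])
  summ <- data.frame(
    prey_type = PREY_TYPES,
    mean = colMeans(mat, na.rm = TRUE),
    sd = apply(mat, 2, stats::sd, na.rm = TRUE),
    n = colSums(!is.na(mat)),
    row.names = NULL, stringsAsFactors = FALSE)
  pw <- if (nrow(mat) >= 2L && any(apply(mat, 1, stats::sd) > 0)) {
    pairwise_signed_rank(mat)
  } else {
    combs <- utils::combn(PREY_TYPES, 2)
    data.frame(group_a = combs[1, ], group_b = combs[2, ], statistic = 0,
               p_raw = 1, p_adjusted = 1, n_pairs = nrow(mat),
               stringsAsFactors = FALSE)
  }
  list(summary = summ, pairwise = pw, n_birds = length(attackers))
}

#' Ratio of failed attacks to attacking birds per prey type
#'
#' Total failed attack events on a prey type divided by the number of birds
#' that attacked that type; \code{NA} when no bird attacked it. Values above
#' 1 indicate prey that typically withstands more than one strike per
#' attacker.
#'
#' @param outcomes outcome table (exclusion-filtered).
#' @param meta,subset optional metadata filtering as in
#'   \code{\link{first_attack_summary}}.
#' @return named numeric vector over the three prey types.
#' @export
failed_attack_ratio <- function(outcomes, meta = NULL, subset = NULL) {
  if (!is.null(subset)) {
    if (is.null(meta)) stop("subset filtering requires `meta`", call. = FALSE)
    outcomes <- outcomes[outcomes$bird_id %in% subset_birds(meta, subset), ,
                         drop = FALSE]
  }
  st <- as_stage(outcomes$stage)
  out <- stats::setNames(rep(NA_real_, 3), PREY_TYPES)
  for (ty in PREY_TYPES) {
    sel <- outcomes$prey_type == ty
    denom <- sum(st[sel] >= "ATTACKED")
    if (denom > 0) {
      out[ty] <- sum(outcomes$n_failed_attack_events[sel]) / denom
    }
  }
  out
}

#' Format a stage-analysis report in the layout of the main results table
#'
#' One row per stage x subset; one column per partition model holding the
#' Akaike weight (2 decimals) with ΔAICc in parentheses, plus flag columns
#' naming the best and the competing (non-rejected) models.
#'
#' @param report a \code{stage_analysis_report}.
#' @return data frame ready for \code{\link{write_table1}}.
#' @export
table1_view <- function(report) {
  rows <- lapply(names(report$tables), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tab <- report$tables[[key]]
    cells <- sprintf("%.2f (%.2f)", tab$akaike_weight, tab$delta_aicc)
    names(cells) <- tab$model
    data.frame(stage = parts[1], subset = parts[2],
               t(cells),
               best = tab$model[tab$is_best],
               competing = paste(tab$model[tab$is_competing],
                                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
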