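REQUIRED_COLS <- list(
  birds = c("bird_id", "species", "family", "age", "diet", "habitat",
            "season"),
  events = c("experiment_id", "bird_id", "prey_id", "prey_type", "event",
             "t"),
  occupancy = c("experiment_id", "subject_id", "subject_kind", "stratum",
                "t_start", "t_end"))

ENUM_COLS <- list(
  birds = list(age = c("adult", "immature"),
               diet = c("insectivorous", "mixed"),
               habitat = c("forest", "urban"),
               season = c("wet", "dry")),
  events = list(prey_type = PREY_TYPES, event = EVENT_TOKENS),
  occupancy = list(subject_kind = c("bird", "butterfly"),
                   stratum = c("low", "high")))

read_validated <- function(path, what) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_COLS[[what]], names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(path, ": no data rows", call. = FALSE)
  }
  for (col in names(ENUM_COLS[[what]])) {
    bad <- which(!df[[col]] %in% ENUM_COLS[[what]][[col]])
    if (length(bad) > 0L) {
      stop(path, ": invalid ", col, " value(s) in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (e.g. '", df[[col]][bad[1]], "')", call. = FALSE)
    }
  }
  df
}

#' Read the pipeline input tables
#'
#' CSV readers with schema validation: required columns, restricted
#' vocabularies and time ranges are checked, and violations are reported
#' with the file name and row numbers.
#'
#' @param path file path.
#' @param trial_seconds trial length used for time-range checks.
#' @return validated data frame.
#' @export
read_birds <- function(path) {
  df <- read_validated(path, "birds")
  dup <- unique(df$bird_id[duplicated(df$bird_id)])
  if (length(dup) > 0L) {
    stop(path, ": duplicated bird_id(s) ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_birds
#' @export
read_events <- function(path, trial_seconds = 3600) {
  df <- read_validated(path, "events")
  bad <- which(!is.finite(df$t) | df$t < 0 | df$t > trial_seconds)
  if (length(bad) > 0L) {
    stop(path, ": event time outside [0, ", trial_seconds,
         "] in row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_birds
#' @export
read_occupancy <- function(path, trial_seconds = 3600) {
  df <- read_validated(path, "occupancy")
  bad <- which(!is.finite(df$t_start) | !is.finite(df$t_end) |
                 df$t_start < 0 | df$t_end > trial_seconds |
                 df$t_start >= df$t_end)
  if (length(bad) > 0L) {
    stop(path, ": invalid interval in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df
}

write_table <- function(df, path, sep = ",") {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 6, format = "fg",
                                 flag = "#"))
  })
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
}

#' Write a stage-analysis report in the main-results-table layout
#'
#' @param report a \code{stage_analysis_report}.
#' @param path output TSV path.
#' @return the formatted data frame, invisibly.
#' @export
write_table1 <- function(report, path) {
  view <- table1_view(report)
  utils::write.table(view, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(view)
}

#' Run the full analysis pipeline on input files
#'
#' Reads the three input tables, codes outcomes, applies the
#' no-interaction exclusion, computes Co indices and their pairwise
#' comparison, runs the five-stage partition-model analysis over the
#' standard subsets (all birds, by age, by season, by habitat), and writes
#' all result tables plus a plain-text log and a JSON echo of the
#' configuration.
#'
#' @param birds,events,occupancy input CSV paths.
#' @param out_dir output directory (created if absent).
#' @param subsets named list of subset filters; default: all, both ages,
#'   both seasons, both habitats.
#' @param trial_seconds trial length in seconds.
#' @param aicc_threshold ΔAICc non-rejection threshold.
#' @param log_base \code{"log10"} or \code{"natural"}.
#' @return invisibly, a list with \code{outcomes}, \code{excluded},
#'   \code{co}, \code{co_comparison}, \code{report}, \code{glmm} and the
#'   output \code{files}.
#' @export
run_pipeline <- function(birds, events, occupancy, out_dir,
                         subsets = default_subsets(),
                         trial_seconds = 3600, aicc_threshold = 2,
                         log_base = "log10") {
  meta <- read_birds(birds)
  ev <- read_events(events, trial_seconds)
  oc <- read_occupancy(occupancy, trial_seconds)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("birds: %d rows (%s)", nrow(meta), birds),
    sprintf("events: %d rows (%s)", nrow(ev), events),
    sprintf("occupancy: %d rows (%s)", nrow(oc), occupancy))

  outcomes <- code_outcomes(ev, meta$bird_id, trial_seconds)
  flt <- apply_exclusion(outcomes)
  log_lines <- c(log_lines, sprintf(
    "excluded %d of %d birds with no interaction: %s",
    length(flt$excluded), nrow(meta),
    if (length(flt$excluded)) paste(flt$excluded, collapse = ", ")
    else "(none)"))
  meta_kept <- meta[meta$bird_id %in% unique(flt$outcomes$bird_id), ,
                    drop = FALSE]

  prey_map <- unique(ev[, c("prey_id", "prey_type")])
  names(prey_map)[1] <- "subject_id"
  co <- co_index_table(oc, prey_map = NULL, trial_seconds)
  co <- co[co$bird_id %in% meta_kept$bird_id, , drop = FALSE]
  co_cmp <- compare_co_by_prey(co)

  report <- run_stage_analyses(flt$outcomes, meta_kept, subsets,
                               log_base = log_base,
                               aicc_threshold = aicc_threshold)
  glmm <- export_glmm_tables(flt$outcomes, meta_kept)

  files <- c(
    outcomes = file.path(out_dir, "outcomes.csv"),
    glmm_attack = file.path(out_dir, "glmm_attack.csv"),
    glmm_sightreject = file.path(out_dir, "glmm_sightreject.csv"),
    co_index = file.path(out_dir, "co_index.csv"),
    co_pairwise = file.path(out_dir, "co_pairwise.csv"),
    model_comparison = file.path(out_dir, "model_comparison.csv"),
    table1 = file.path(out_dir, "table1_report.tsv"),
    descriptives = file.path(out_dir, "descriptives.csv"),
    log = file.path(out_dir, "pipeline_log.txt"),
    config = file.path(out_dir, "config_echo.json"))

  oc_out <- flt$outcomes
  oc_out$stage <- as.character(oc_out$stage)
  write_table(oc_out, files[["outcomes"]])
  write_table(glmm$attack, files[["glmm_attack"]])
  write_table(glmm$sight_reject, files[["glmm_sightreject"]])
  write_table(co[, c("bird_id", "prey_type", "co")], files[["co_index"]])
  pw <- co_cmp$pairwise
  pw$pair <- paste(pw$group_a, pw$group_b, sep = "-")
  write_table(pw[, c("pair", "statistic", "p_raw", "p_adjusted",
                     "n_pairs")], files[["co_pairwise"]])
  mc <- do.call(rbind, lapply(names(report$tables), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    cbind(stage = parts[1], subset = parts[2],
          as.data.frame(report$tables[[key]]))
  }))
  write_table(mc, files[["model_comparison"]])
  write_table1(report, files[["table1"]])
  write_table(report$descriptives, files[["descriptives"]])
  writeLines(log_lines, files[["log"]])
  jsonlite::write_json(
    list(inputs = list(birds = birds, events = events,
                       occupancy = occupancy),
         subsets = subsets, trial_seconds = trial_seconds,
         aicc_threshold = aicc_threshold, log_base = log_base),
    files[["config"]], auto_unbox = TRUE, null = "null")

  invisible(list(outcomes = flt$outcomes, excluded = flt$excluded,
                 co = co, co_comparison = co_cmp, report = report,
                 glmm = glmm, files = files))
}

#' @rdname run_pipeline
#' @export
default_subsets <- function() {
  list(all = NULL,
       `age=immature` = list(age = "immature"),
       `age=adult` = list(age = "adult"),
       `season=wet` = list(season = "wet"),
       `season=dry` = list(season = "dry"),
       `habitat=forest` = list(habitat = "forest"),
       `habitat=urban` = list(habitat = "urban"))
}
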