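# Fixed prey-type order used everywhere: cryptic, aposematic, evasive.
PREY_TYPES <- c("euptychiina", "heliconius", "spicauda")

# Ordered predation stages (highest stage reached by a bird-prey pair).
STAGE_LEVELS <- c("NONE", "DETECTED", "ATTACKED", "CAPTURED", "CONSUMED")

# Recognised behavioral event tokens.
EVENT_TOKENS <- c("approach", "attack_start", "capture", "release", "consume")

# The five stage tables built from coded outcomes.
STAGE_LABELS <- c("undetected", "sight_rejected", "attacked",
                  "capture_avoided", "survived")

#' Prey types, stage levels and event tokens used by the pipeline
#'
#' @return Character vectors giving the fixed vocabulary of the pipeline.
#' @export
prey_types <- function() PREY_TYPES

#' @rdname prey_types
#' @export
stage_levels <- function() STAGE_LEVELS

#' @rdname prey_types
#' @export
stage_labels <- function() STAGE_LABELS

as_stage <- function(x) {
  factor(as.character(x), levels = STAGE_LEVELS, ordered = TRUE)
}
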