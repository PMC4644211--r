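#' Default developmental stage map
#'
#' Seven developmental stages spanning early prenatal development (8 PCW) to
#' adulthood, as half-open age intervals `[lo, hi)` in signed days relative to
#' birth (birth = 40 PCW = day 0). The exact boundaries are an editable
#' convention, not ground truth: override them via [read_stage_map()] or by
#' passing your own data.frame of the same shape.
#'
#' @return data.frame with columns `stage` (1..7), `label`, `lo`, `hi` (days).
#' @export
default_stage_map <- function() {
  data.frame(
    stage = 1:7,
    label = c("early_fetal", "late_fetal", "infancy", "early_childhood",
              "late_childhood", "adolescence", "adulthood"),
    lo = c((8 - 40) * 7, (20 - 40) * 7, 0, 365, 6 * 365, 12 * 365, 20 * 365),
    hi = c((20 - 40) * 7, 0, 365, 6 * 365, 12 * 365, 20 * 365, 45 * 365),
    stringsAsFactors = FALSE
  )
}

#' Read a stage map from a YAML config
#'
#' Expected structure: a top-level `stages:` list whose entries have `label`,
#' `lo`, `hi` (days, half-open `[lo, hi)`).
#'
#' @param path YAML file.
#' @return a stage-map data.frame as in [default_stage_map()].
#' @export
read_stage_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  stages <- cfg$stages
  if (is.null(stages)) stop("stage-map YAML lacks a 'stages' block")
  out <- data.frame(
    stage = seq_along(stages),
    label = vapply(stages, function(s) as.character(s$label), character(1)),
    lo = vapply(stages, function(s) as.numeric(s$lo), numeric(1)),
    hi = vapply(stages, function(s) as.numeric(s$hi), numeric(1)),
    stringsAsFactors = FALSE
  )
  validate_stage_map(out)
  out
}

validate_stage_map <- function(stage_map) {
  stopifnot(all(c("stage", "label", "lo", "hi") %in% names(stage_map)))
  o <- order(stage_map$lo)
  sm <- stage_map[o, ]
  if (any(sm$hi <= sm$lo)) stop("stage intervals must satisfy lo < hi")
  if (nrow(sm) > 1 && any(sm$lo[-1] < sm$hi[-nrow(sm)])) {
    stop("stage intervals overlap")
  }
  invisible(stage_map)
}

#' Map ages to stages under the half-open interval convention
#'
#' An age `a` belongs to stage `i` iff `lo_i <= a < hi_i`; an age equal to a
#' boundary `lo` falls in the interval that starts there.
#'
#' @param age numeric vector of ages in days.
#' @param stage_map stage-map data.frame.
#' @return integer vector of stage ids (`NA` where uncovered).
#' @export
stage_of_age <- function(age, stage_map = default_stage_map()) {
  validate_stage_map(stage_map)
  out <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(stage_map))) {
    hit <- age >= stage_map$lo[i] & age < stage_map$hi[i]
    out[hit] <- stage_map$stage[i]
  }
  out
}

#' The 16 brain-region acronyms used by default
#'
#' Five subcortical/cerebellar structures (AMY amygdala, HIP hippocampus, STR
#' striatum, MD mediodorsal thalamus, CBC cerebellar cortex) and eleven
#' neocortical areas.
#'
#' @return character vector of 16 acronyms.
#' @export
default_regions <- function() {
  c("AMY", "HIP", "STR", "MD", "CBC",
    "OFC", "DFC", "VFC", "MFC", "M1C", "S1C", "IPC", "A1C", "STC", "ITC",
    "V1C")
}
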