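# Rule-based classification of 5hmC/5mC dynamics across stages. All
# functions are vectorised and partition their input domain: every
# defined input receives exactly one label.

#' Classify the 5hmC trajectory between two stages
#'
#' Relative change is `(early - late) / early`. A locus is `decreased`
#' when the relative change exceeds 15%, `increased` when it is below
#' -15%, and `maintained` when its absolute value is at most 15%
#' (boundaries inclusive for `maintained`). Loci with an early level of 0
#' have an undefined trajectory and get NA.
#'
#' @param levelEarly,levelLate 5hmC levels in \[0, 1\] (e.g. four-cell and
#'   eight-cell).
#' @param threshold relative-change threshold (default 0.15).
#' @return factor with levels `decreased`, `increased`, `maintained`; the
#'   relative change is attached as attribute `relChange`.
#' @examples
#' classifyTrajectory(0.10, 0.08)  # decreased (rel. change 0.20)
#' @export
classifyTrajectory <- function(levelEarly, levelLate, threshold = 0.15) {
  rel <- ifelse(levelEarly > 0, (levelEarly - levelLate) / levelEarly,
                NA_real_)
  lab <- ifelse(is.na(rel), NA_character_,
         ifelse(rel > threshold, "decreased",
         ifelse(rel < -threshold, "increased", "maintained")))
  out <- factor(lab, levels = c("decreased", "increased", "maintained"))
  attr(out, "relChange") <- rel
  out
}

#' Band a 5hmC level into high / medium / low
#'
#' `high`: level >= 5%; `medium`: >= 2% and < 5%; `low`: >= 1% and < 2%;
#' `below_low` otherwise. Lower bounds are inclusive.
#'
#' @param level 5hmC level(s) in \[0, 1\].
#' @return factor with levels `high`, `medium`, `low`, `below_low`.
#' @examples
#' classifyBand(c(0.05, 0.02, 0.009))  # high, medium, below_low
#' @export
classifyBand <- function(level) {
  stopifnot(all(level >= 0 & level <= 1, na.rm = TRUE))
  lab <- ifelse(is.na(level), NA_character_,
         ifelse(level >= 0.05, "high",
         ifelse(level >= 0.02, "medium",
         ifelse(level >= 0.01, "low", "below_low"))))
  factor(lab, levels = c("high", "medium", "low", "below_low"))
}

#' Classify the methylation fate of a region across a transition
#'
#' `de_novo_methylation` when the level gain exceeds `delta`,
#' `demethylation` when the loss exceeds `delta`, `maintenance`
#' otherwise. The default `delta` reuses the 0.25 effect cutoff of the
#' 5mC DMR caller, keeping the fate partition consistent with the DMR
#' definitions; it is fully configurable. Swapping the two levels swaps
#' de novo and demethylation.
#'
#' @param levelA,levelB 5mC levels before and after the transition.
#' @param delta absolute-change threshold (default 0.25).
#' @return factor with levels `de_novo_methylation`, `demethylation`,
#'   `maintenance`.
#' @export
classifyFate <- function(levelA, levelB, delta = 0.25) {
  lab <- ifelse(is.na(levelA) | is.na(levelB), NA_character_,
         ifelse(levelB - levelA > delta, "de_novo_methylation",
         ifelse(levelA - levelB > delta, "demethylation", "maintenance")))
  factor(lab, levels = c("de_novo_methylation", "demethylation",
                         "maintenance"))
}

#' Flag loci lowly methylated in the initial growing-oocyte stage
#'
#' TRUE when the DNA methylation level at the earliest growing-oocyte
#' stage is strictly below the cutoff (default 0.15) - the loci whose
#' later hydroxymethylation demonstrates de novo generation rather than
#' inheritance.
#'
#' @param level 5mC level(s) at the initial stage.
#' @param cutoff strict upper bound (default 0.15).
#' @return logical vector.
#' @export
flagLowInitialMeth <- function(level, cutoff = 0.15) {
  level < cutoff
}
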