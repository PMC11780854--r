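#' Per-base mutation and stop rates
#'
#' The mutation rate of a base is the number of reads carrying a mutation
#' at that position divided by the number of reads covering it. The stop
#' rate is the number of reverse-transcription stops recorded at the
#' position divided by the number of reads informative there (reads whose
#' cDNA covers or terminates at the position). Positions with zero depth
#' are flagged invalid and carry the `NaN` sentinel.
#'
#' @param profile A `count_profile` with the matching `mode`
#'   (`"mutation"` for [mutation_rate()], `"stop"` for [stop_rate()]).
#' @return A `reactivity_profile` with `reactivity = events / depth` in
#'   `[0, 1]` at positions with positive depth.
#' @export
#' @examples
#' cp <- count_profile(1:2, c("A", "C"), c(100L, 1000L), c(5L, 0L),
#'                     rna_id = "toy", channel = "plus", mode = "mutation")
#' mutation_rate(cp)$reactivity
mutation_rate <- function(profile) {
  event_rate(profile, "mutation")
}

#' @rdname mutation_rate
#' @export
stop_rate <- function(profile) {
  event_rate(profile, "stop")
}

event_rate <- function(profile, mode) {
  stopifnot(inherits(profile, "count_profile"))
  if (!identical(profile_mode(profile), mode)) {
    abort(sprintf("profile mode is '%s', expected '%s'.",
                  profile_mode(profile), mode),
          class = "probeval_validation_error")
  }
  valid <- profile$depth > 0L
  r <- ifelse(valid, profile$events / profile$depth, NaN)
  reactivity_profile(profile$position, profile$base, r, valid,
                     rna_id = rna_id(profile), mode = mode,
                     background = "none")
}

#' Background-adjusted reactivity
#'
#' Subtracts the probe-free (minus channel) rate from the probe-treated
#' (plus channel) rate position by position. A position is valid in the
#' result only when both inputs are valid there. By default negative
#' differences are kept, so the rank order of the subtraction is
#' preserved for ROC analysis; `clamp = TRUE` floors them at 0.
#'
#' @param plus,minus `reactivity_profile`s of the same RNA, mode and length.
#' @param clamp Floor negative adjusted values at 0 (default `FALSE`).
#' @return A `reactivity_profile` with `background = "subtracted"`.
#' @export
background_adjust <- function(plus, minus, clamp = FALSE) {
  stopifnot(inherits(plus, "reactivity_profile"),
            inherits(minus, "reactivity_profile"))
  if (!identical(rna_id(plus), rna_id(minus)) ||
      !identical(profile_mode(plus), profile_mode(minus)) ||
      nrow(plus) != nrow(minus)) {
    abort(sprintf(
      "cannot pair profiles: rna (%s vs %s), mode (%s vs %s), length (%d vs %d).",
      rna_id(plus), rna_id(minus), profile_mode(plus), profile_mode(minus),
      nrow(plus), nrow(minus)),
      class = "probeval_pairing_error")
  }
  valid <- plus$valid & minus$valid
  r <- ifelse(valid, plus$reactivity - minus$reactivity, NaN)
  if (clamp) r <- pmax(r, 0)
  out <- reactivity_profile(plus$position, plus$base, r, valid,
                            rna_id = rna_id(plus), mode = profile_mode(plus),
                            probe = attr(plus, "probe"),
                            background = "subtracted")
  out
}

#' Coverage filter
#'
#' Invalidates positions whose read depth does not exceed `min_depth`.
#' The comparison is strict: depth 501 is retained under the default
#' threshold of 500, depth 500 is dropped.
#'
#' @param profile A `reactivity_profile`.
#' @param counts The `count_profile` the profile was derived from (same
#'   length); its `depth` column drives the filter.
#' @param min_depth Depth that must be strictly exceeded (default 500).
#' @return The filtered `reactivity_profile`.
#' @export
apply_coverage_filter <- function(profile, counts, min_depth = 500L) {
  stopifnot(inherits(profile, "reactivity_profile"),
            inherits(counts, "count_profile"))
  if (nrow(profile) != nrow(counts)) {
    abort("profile and counts lengths differ.",
          class = "probeval_pairing_error")
  }
  drop <- counts$depth <= min_depth
  profile$valid[drop] <- FALSE
  profile$reactivity[!profile$valid] <- NaN
  profile
}

#' Probe-specific base filter
#'
#' DMS methylates only adenine and cytosine, so for DMS profiles every
#' other base is invalidated. SHAPE acylates the 2'-hydroxyl of all four
#' bases, so SHAPE profiles are unchanged. The probe identity is recorded
#' in the profile's `probe` attribute.
#'
#' @param profile A `reactivity_profile`.
#' @param probe `"DMS"` or `"SHAPE"`.
#' @return The filtered `reactivity_profile`.
#' @export
apply_base_filter <- function(profile, probe = c("DMS", "SHAPE")) {
  probe <- match.arg(probe)
  stopifnot(inherits(profile, "reactivity_profile"))
  if (probe == "DMS") {
    profile$valid[!profile$base %in% c("A", "C")] <- FALSE
    profile$reactivity[!profile$valid] <- NaN
  }
  attr(profile, "probe") <- probe
  profile
}

#' mRNA inclusion rule
#'
#' An mRNA enters the analysis only if it has at least `min_positions`
#' bases with coverage strictly above `min_depth`.
#'
#' @param counts A `count_profile`.
#' @param min_positions Minimum number of qualifying positions (default 50).
#' @param min_depth Depth that must be strictly exceeded (default 500).
#' @return `TRUE` or `FALSE`.
#' @export
mrna_inclusion_rule <- function(counts, min_positions = 50L, min_depth = 500L) {
  stopifnot(inherits(counts, "count_profile"))
  sum(counts$depth > min_depth) >= min_positions
}
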