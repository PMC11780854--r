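#' Correlation between reactivity and solvent accessibility
#'
#' Pearson correlation between per-base reactivity and relative solvent
#' accessibility, over a chosen subset of bases: all mapped bases, the
#' top 10% most reactive, the bottom 90%, or the bases that are
#' paired/unpaired in a reference secondary structure. Residues absent
#' from the coordinate model (unresolved) simply have no accessibility
#' row and are excluded. The `offset` parameter absorbs numbering shifts
#' between the coordinate model and the reference sequence: profile
#' position = residue index + offset.
#'
#' @param reactivity A `reactivity_profile`.
#' @param access Residue accessibility tibble from
#'   [residue_accessibility()].
#' @param subset One of `"all"`, `"top10"`, `"bottom90"`, `"paired"`,
#'   `"unpaired"`.
#' @param structure A `secondary_structure`; required for the
#'   `"paired"`/`"unpaired"` subsets.
#' @param offset Integer added to residue indices to obtain profile
#'   positions (default 0).
#' @return A tibble with columns `subset`, `r` (Pearson correlation) and
#'   `n` (points used).
#' @export
reactivity_accessibility_correlation <- function(reactivity, access,
                                                 subset = c("all", "top10",
                                                            "bottom90",
                                                            "paired",
                                                            "unpaired"),
                                                 structure = NULL,
                                                 offset = 0L) {
  subset <- match.arg(subset)
  stopifnot(inherits(reactivity, "reactivity_profile"))
  mapped <- access |>
    mutate(position = .data$residue_index + as.integer(offset)) |>
    filter(.data$position >= 1L, .data$position <= nrow(reactivity))
  mapped$reactivity <- reactivity$reactivity[mapped$position]
  mapped$valid <- reactivity$valid[mapped$position] &
    is.finite(mapped$reactivity)
  mapped <- filter(mapped, .data$valid)
  if (subset %in% c("paired", "unpaired")) {
    if (is.null(structure)) {
      abort(sprintf("subset '%s' requires a secondary structure.", subset),
            class = "probeval_validation_error")
    }
    paired <- structure$paired[mapped$position]
    mapped <- mapped[if (subset == "paired") paired else !paired, , drop = FALSE]
  } else if (subset %in% c("top10", "bottom90")) {
    # rank within the mapped, valid set (the evaluable population)
    prof <- reactivity
    prof$valid <- prof$position %in% mapped$position
    prof$reactivity[!prof$valid] <- NaN
    top <- top_rank_positions(prof, 10)
    keep <- mapped$position %in% top
    mapped <- mapped[if (subset == "top10") keep else !keep, , drop = FALSE]
  }
  if (nrow(mapped) < 3L) {
    abort(sprintf("subset '%s' has %d points; need at least 3.",
                  subset, nrow(mapped)),
          class = "probeval_degenerate_data_error")
  }
  if (stats::sd(mapped$reactivity) == 0 || stats::sd(mapped$relative_sasa) == 0) {
    abort(sprintf("zero variance in subset '%s'.", subset),
          class = "probeval_degenerate_data_error")
  }
  tibble(subset = subset,
         r = cor(mapped$reactivity, mapped$relative_sasa),
         n = nrow(mapped))
}
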