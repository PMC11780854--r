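# Shared ranking rule: indices (into the profile) of the ceiling(x% of
# n_valid) highest-reactivity valid positions, ties broken by ascending
# position so results are reproducible.
top_rank_positions <- function(profile, x_percent) {
  if (!is.numeric(x_percent) || length(x_percent) != 1L ||
      x_percent <= 0 || x_percent > 100) {
    abort("x_percent must lie in (0, 100].", class = "probeval_validation_error")
  }
  idx <- valid_positions(profile)
  if (length(idx) == 0L) {
    abort("no valid positions.", class = "probeval_degenerate_data_error")
  }
  k <- ceiling(x_percent / 100 * length(idx))
  ord <- idx[order(-profile$reactivity[idx], profile$position[idx])]
  ord[seq_len(k)]
}

#' Fraction of top-x% reactive bases that are unpaired
#'
#' Selects the `ceiling(x/100 * n_valid)` valid positions with the highest
#' reactivity (ties broken by ascending position) and returns the fraction
#' of them that are unpaired in the reference structure. At `x = 100` this
#' is exactly the unpaired fraction of the valid set.
#'
#' @param reactivity A `reactivity_profile`.
#' @param structure A `secondary_structure` of the same length.
#' @param x_percent Percentage in `(0, 100]`.
#' @return The unpaired fraction of the selected bases, a single number.
#' @export
top_fraction_unpaired <- function(reactivity, structure, x_percent) {
  stopifnot(inherits(reactivity, "reactivity_profile"),
            inherits(structure, "secondary_structure"))
  if (nrow(reactivity) != nrow(structure)) {
    abort("profile and structure lengths differ.",
          class = "probeval_pairing_error")
  }
  top <- top_rank_positions(reactivity, x_percent)
  mean(!structure$paired[top])
}

#' Histogram of reactivity values
#'
#' Bins valid reactivities into half-open bins `[k*w, (k+1)*w)` over
#' `[0, range_max]`; values `>= range_max` are pooled into an overflow bin
#' and negative values (possible after background subtraction) into an
#' underflow bin. A value falling exactly on a bin edge belongs to the bin
#' starting there.
#'
#' @param reactivity A `reactivity_profile`.
#' @param bin_width Bin width (> 0), default 0.01.
#' @param range_max Upper end of the binned range, default 1.
#' @return A tibble with columns `bin_start`, `bin_end`, `count`. The
#'   underflow row has `bin_start = -Inf`, the overflow row
#'   `bin_end = Inf`.
#' @export
rate_histogram <- function(reactivity, bin_width = 0.01, range_max = 1) {
  stopifnot(inherits(reactivity, "reactivity_profile"))
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("bin_width must be positive.", class = "probeval_validation_error")
  }
  r <- reactivity$reactivity[valid_positions(reactivity)]
  n_bins <- ceiling(range_max / bin_width - 1e-9)
  starts <- (seq_len(n_bins) - 1L) * bin_width
  bin_of <- floor(r / bin_width + 1e-12)
  counts <- vapply(seq_len(n_bins) - 1L,
                   function(k) sum(r >= 0 & r < range_max & bin_of == k),
                   integer(1))
  out <- tibble(bin_start = starts,
                bin_end = pmin(starts + bin_width, range_max),
                count = counts)
  bind_rows(
    tibble(bin_start = -Inf, bin_end = 0, count = sum(r < 0)),
    out,
    tibble(bin_start = range_max, bin_end = Inf, count = sum(r >= range_max))
  )
}

#' Fraction of valid bases with reactivity at or above a threshold
#'
#' @param reactivity A `reactivity_profile` with at least one valid
#'   position.
#' @param threshold Reactivity threshold (inclusive).
#' @return A single number in `[0, 1]`.
#' @export
fraction_at_least <- function(reactivity, threshold) {
  stopifnot(inherits(reactivity, "reactivity_profile"))
  r <- reactivity$reactivity[valid_positions(reactivity)]
  if (length(r) == 0L) {
    abort("no valid positions.", class = "probeval_degenerate_data_error")
  }
  mean(r >= threshold)
}

#' Class-conditional reactivity summary and histogram overlap
#'
#' Summarises the reactivity distribution separately for unpaired and
#' paired bases and quantifies their overlap as the histogram overlap
#' coefficient `sum_b min(density_unpaired(b), density_paired(b)) * w`,
#' which is 1 for identical distributions and 0 for disjoint supports.
#'
#' @param reactivity A `reactivity_profile`.
#' @param structure A `secondary_structure` of the same length.
#' @param bin_width Bin width used for the overlap coefficient (default
#'   0.01).
#' @return A list with `by_class` (tibble of n, mean, median, q25, q75 per
#'   class) and `overlap` (the overlap coefficient).
#' @export
class_conditional_summary <- function(reactivity, structure, bin_width = 0.01) {
  stopifnot(inherits(reactivity, "reactivity_profile"),
            inherits(structure, "secondary_structure"))
  if (nrow(reactivity) != nrow(structure)) {
    abort("profile and structure lengths differ.",
          class = "probeval_pairing_error")
  }
  idx <- valid_positions(reactivity)
  r <- reactivity$reactivity[idx]
  unpaired <- !structure$paired[idx]
  if (sum(unpaired) == 0L || sum(!unpaired) == 0L) {
    abort("degenerate class: need valid bases in both classes.",
          class = "probeval_degenerate_labels_error")
  }
  by_class <- tibble(
    class = c("unpaired", "paired"),
    n = c(sum(unpaired), sum(!unpaired)),
    mean = c(mean(r[unpaired]), mean(r[!unpaired])),
    median = c(median(r[unpaired]), median(r[!unpaired])),
    q25 = c(quantile(r[unpaired], 0.25, names = FALSE),
            quantile(r[!unpaired], 0.25, names = FALSE)),
    q75 = c(quantile(r[unpaired], 0.75, names = FALSE),
            quantile(r[!unpaired], 0.75, names = FALSE))
  )
  lo <- floor(min(r) / bin_width)
  hi <- floor(max(r) / bin_width)
  bins <- lo:hi
  p_u <- tabulate(floor(r[unpaired] / bin_width) - lo + 1L,
                  nbins = length(bins)) / sum(unpaired)
  p_p <- tabulate(floor(r[!unpaired] / bin_width) - lo + 1L,
                  nbins = length(bins)) / sum(!unpaired)
  list(by_class = by_class, overlap = sum(pmin(p_u, p_p)))
}
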