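default_allowed_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")

check_enum_input <- function(sequence, min_loop) {
  sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
  if (nchar(sequence) > 30L) {
    abort(sprintf("sequence length %d exceeds the enumeration guard (30).",
                  nchar(sequence)),
          class = "probeval_validation_error")
  }
  if (min_loop < 0L) {
    abort("min_loop must be non-negative.", class = "probeval_validation_error")
  }
  sequence
}

#' Exhaustively enumerate nested secondary structures
#'
#' Generates every pseudoknot-free secondary structure of a short RNA
#' exactly once, including the empty structure. A pair `(i, j)` is allowed
#' when the bases form one of `allowed_pairs` and the span satisfies
#' `j - i - 1 >= min_loop`. This toy ensemble is the internal oracle used
#' to validate pairing-probability marginalisation; it deliberately does
#' not emulate a thermodynamic energy model.
#'
#' @param sequence RNA sequence (length at most 30, guarding against
#'   combinatorial blowup).
#' @param min_loop Minimum number of unpaired bases enclosed by a hairpin
#'   pair (default 3).
#' @param allowed_pairs Character vector of allowed base pairs; default
#'   canonical Watson-Crick plus wobble.
#' @return A list of integer partner vectors (1-based, `NA` = unpaired),
#'   one per structure.
#' @export
#' @examples
#' length(enumerate_structures("GAAAC"))  # empty structure + the (1,5) pair
enumerate_structures <- function(sequence, min_loop = 3L,
                                 allowed_pairs = default_allowed_pairs) {
  sequence <- check_enum_input(sequence, min_loop)
  enumerate_structures_cpp(sequence, as.integer(min_loop), allowed_pairs)
}

#' Count nested secondary structures by the Nussinov-style recurrence
#'
#' Independent of [enumerate_structures()]: counts via the dynamic
#' programme `N(i,j) = N(i+1,j) + sum_k N(i+1,k-1) * N(k+1,j)` over
#' pairable `(i,k)`, implemented in plain R with memoisation. Used as a
#' cross-check oracle for the enumerator.
#'
#' @inheritParams enumerate_structures
#' @return The number of structures (a double; exact for the short
#'   sequences the length guard admits).
#' @export
count_structures <- function(sequence, min_loop = 3L,
                             allowed_pairs = default_allowed_pairs) {
  sequence <- check_enum_input(sequence, min_loop)
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L == 0L) return(1)
  pairable <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    js <- seq_len(L)
    ok <- js > i + min_loop & paste0(s[i], s[js]) %in% allowed_pairs
    pairable[i, ok] <- TRUE
  }
  N <- matrix(NA_real_, L + 1L, L + 1L)
  cnt <- function(i, j) {
    if (i > j) return(1)
    if (!is.na(N[i, j])) return(N[i, j])
    total <- cnt(i + 1L, j)
    if (i < j) {
      for (k in (i + 1L):j) {
        if (pairable[i, k]) {
          total <- total + cnt(i + 1L, k - 1L) * (if (k < j) cnt(k + 1L, j) else 1)
        }
      }
    }
    N[i, j] <<- total
    total
  }
  cnt(1L, L)
}

#' Exhaustive agreement check between enumeration and counting recurrence
#'
#' Runs both structure-counting algorithms over every 4-letter sequence of
#' length `1..max_len` (canonical + wobble pairs) and reports the number
#' of sequences checked and of count mismatches.
#'
#' @param max_len Maximum sequence length (exhaustive over `4^L` sequences
#'   per length, so keep this small).
#' @param min_loop Minimum hairpin span (default 3).
#' @return A tibble with columns `n_sequences` and `n_mismatches`.
#' @export
check_enumeration_vs_recurrence <- function(max_len = 10L, min_loop = 3L) {
  res <- check_enumeration_vs_recurrence_cpp(as.integer(max_len),
                                             as.integer(min_loop))
  tibble(n_sequences = res$n_sequences, n_mismatches = res$n_mismatches)
}

#' Toy Boltzmann-like ensemble pairing probabilities
#'
#' Weights every enumerated structure by `pair_weight^(number of pairs)`
#' and returns the pair probability matrix
#' `p[i,j] = sum over structures containing (i,j) of w^pairs / Z`.
#' With `pair_weight = 1` all structures are equally likely; as the weight
#' grows the maximally paired structures dominate.
#'
#' @inheritParams enumerate_structures
#' @param pair_weight Multiplicative weight per base pair (>= 1).
#' @param rna_id Identifier attached to the resulting matrix.
#' @return A [bpp_matrix()] satisfying symmetry, zero diagonal and
#'   marginals in `[0, 1]` exactly.
#' @export
ensemble_bpp <- function(sequence, pair_weight = 1, min_loop = 3L,
                         allowed_pairs = default_allowed_pairs,
                         rna_id = "rna") {
  if (pair_weight < 1) {
    abort("pair_weight must be >= 1.", class = "probeval_validation_error")
  }
  structures <- enumerate_structures(sequence, min_loop, allowed_pairs)
  L <- nchar(check_enum_input(sequence, min_loop))
  num <- matrix(0, L, L)
  Z <- 0
  for (partner in structures) {
    npairs <- sum(!is.na(partner)) / 2
    w <- pair_weight^npairs
    Z <- Z + w
    paired_i <- which(!is.na(partner) & seq_len(L) < partner)
    for (i in paired_i) num[i, partner[i]] <- num[i, partner[i]] + w
  }
  p <- (num + t(num)) / Z
  bpp_matrix(p, rna_id = rna_id)
}
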