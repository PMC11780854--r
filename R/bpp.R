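#' Base-pair probability matrix
#'
#' A symmetric `L x L` matrix of pairing probabilities with zero diagonal.
#' Row sums (the marginal probability that a base pairs with anything)
#' must not exceed 1 beyond a small import tolerance.
#'
#' @param p A symmetric numeric matrix with entries in `[0, 1]` and zero
#'   diagonal.
#' @param rna_id RNA identifier.
#' @param tol Tolerance for symmetry and marginal checks on imported
#'   matrices (default `1e-6`).
#' @return A `bpp_matrix` object.
#' @export
bpp_matrix <- function(p, rna_id = "rna", tol = 1e-6) {
  p <- as.matrix(p)
  if (nrow(p) != ncol(p)) {
    abort("pair probability matrix must be square.",
          class = "probeval_validation_error")
  }
  if (any(abs(p - t(p)) > tol)) {
    abort("pair probability matrix must be symmetric.",
          class = "probeval_validation_error")
  }
  if (any(abs(diag(p)) > tol)) {
    abort("pair probability matrix must have a zero diagonal.",
          class = "probeval_validation_error")
  }
  if (any(p < -tol) || any(p > 1 + tol)) {
    abort("pair probabilities must lie in [0, 1].",
          class = "probeval_validation_error")
  }
  m <- rowSums(p)
  if (any(m > 1 + tol)) {
    i <- which.max(m)
    abort(sprintf("inconsistent matrix: marginal %.6f > 1 at position %d.",
                  m[i], i),
          class = "probeval_inconsistent_matrix_error")
  }
  dimnames(p) <- NULL
  structure(p, class = c("bpp_matrix", "matrix"),
            rna_id = as.character(rna_id))
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat(sprintf("<bpp_matrix> rna=%s L=%d nonzero=%d\n",
              attr(x, "rna_id"), nrow(x), sum(x != 0) / 2))
  invisible(x)
}

#' Marginal pairing probability per position
#'
#' The probability that base `i` pairs with any other base, computed as
#' the row sum `m[i] = sum_j p[i, j]` of the base-pair probability matrix.
#' Marginals exceeding 1 by more than the tolerance raise an
#' inconsistent-matrix error; values inside the tolerance band are clipped
#' to `[0, 1]`.
#'
#' @param matrix A [bpp_matrix()].
#' @param tol Tolerance for the `<= 1` check (default `1e-6`).
#' @return A tibble with columns `position` and `pairing_probability`.
#' @export
marginal_pairing_probability <- function(matrix, tol = 1e-6) {
  stopifnot(inherits(matrix, "bpp_matrix"))
  m <- rowSums(unclass(matrix))
  if (any(m > 1 + tol)) {
    i <- which.max(m)
    abort(sprintf("inconsistent matrix: marginal %.6f > 1 at position %d.",
                  m[i], i),
          class = "probeval_inconsistent_matrix_error")
  }
  tibble(position = seq_along(m),
         pairing_probability = pmin(pmax(m, 0), 1))
}

#' Flag bases discordant between ensemble pairing and reactivity
#'
#' A base is discordant when the ensemble says it is almost certainly
#' paired (marginal pairing probability at or above `bpp_min`, inclusive)
#' while the probing data place it in the top `top_percent` of reactivity
#' among valid positions -- high reactivity normally indicating an
#' unpaired base.
#'
#' @param marginals Tibble from [marginal_pairing_probability()] (or any
#'   tibble with `position` and `pairing_probability`).
#' @param reactivity A `reactivity_profile` of the same RNA.
#' @param bpp_min Marginal pairing probability threshold, inclusive
#'   (default 0.995).
#' @param top_percent Reactivity rank threshold in percent (default 10).
#' @return A tibble of flagged positions with columns `position`, `base`,
#'   `pairing_probability`, `reactivity`; empty when nothing is flagged.
#' @export
flag_discordant <- function(marginals, reactivity, bpp_min = 0.995,
                            top_percent = 10) {
  stopifnot(inherits(reactivity, "reactivity_profile"))
  if (max(marginals$position) > nrow(reactivity)) {
    abort("marginals refer to positions beyond the profile length.",
          class = "probeval_pairing_error")
  }
  top <- top_rank_positions(reactivity, top_percent)
  marginals |>
    filter(.data$pairing_probability >= bpp_min,
           .data$position %in% top) |>
    mutate(base = reactivity$base[.data$position],
           reactivity = reactivity$reactivity[.data$position]) |>
    select("position", "base", "pairing_probability", "reactivity")
}

#' Read and write base-pair probability matrices as sparse TSV
#'
#' The format is three tab-separated columns `i`, `j`, `probability` with
#' 1-based positions (`i < j`), preceded by metadata lines `#rna=` and
#' `#length=`.
#'
#' @param path Path to the TSV file.
#' @return [read_bpp_tsv()] returns a [bpp_matrix()];
#'   [write_bpp_tsv()] returns `path` invisibly.
#' @export
read_bpp_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  meta <- read_meta_lines(path)
  require_meta(meta, c("rna", "length"), path)
  L <- as.integer(meta$length)
  body <- read_body_tsv(path, readr::cols(
    i = readr::col_integer(), j = readr::col_integer(),
    probability = readr::col_double()
  ))
  if (nrow(body) > 0 && (max(body$i, body$j) > L || min(body$i, body$j) < 1)) {
    abort(sprintf("%s: pair position outside 1..%d.", path, L),
          class = "probeval_format_error")
  }
  p <- matrix(0, L, L)
  p[cbind(body$i, body$j)] <- body$probability
  p[cbind(body$j, body$i)] <- body$probability
  bpp_matrix(p, rna_id = meta$rna)
}

#' @rdname read_bpp_tsv
#' @param matrix A [bpp_matrix()] to serialize.
#' @export
write_bpp_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "bpp_matrix"))
  p <- unclass(matrix)
  idx <- which(upper.tri(p) & p != 0, arr.ind = TRUE)
  writeLines(c(paste0("#rna=", attr(matrix, "rna_id")),
               paste0("#length=", nrow(p))), path)
  readr::write_tsv(tibble(i = idx[, 1], j = idx[, 2],
                          probability = p[idx]), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}
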