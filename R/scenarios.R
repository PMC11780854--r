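# Deterministic benchmark structure: repeated stem-loop blocks
# "((((....))))..." (8 paired / 7 unpaired per 15-mer) plus a 5-dot
# 3' tail, giving 96/200 = 48% unpaired -- inside the 38-50% range
# typical of rRNA reference structures. Stems are G-C, loops and
# linkers alternate A/U.
benchmark_structure <- function(n_blocks = 13L, rna_id = "benchmark") {
  db <- paste0(strrep("((((....))))...", n_blocks), ".....")
  sym <- strsplit(db, "", fixed = TRUE)[[1]]
  L <- length(sym)
  base <- rep(c("A", "U"), length.out = L)
  tmp <- parse_dotbracket(paste0(base, collapse = ""), db, rna_id = rna_id)
  base[tmp$paired & tmp$position < tmp$partner] <- "G"
  base[tmp$paired & tmp$position > tmp$partner] <- "C"
  parse_dotbracket(paste0(base, collapse = ""), db, rna_id = rna_id)
}

# Low-skew grid of per-position modification probabilities: most mass
# near the low end, quadratic ramp to `hi`.
quadratic_grid <- function(n, lo, hi) {
  if (n == 1L) return(lo)
  lo + (hi - lo) * ((seq_len(n) - 1) / (n - 1))^2
}

#' Named benchmark scenarios for the probing simulator
#'
#' Returns a ready-made [probing_config()] and its ground-truth structure
#' emulating the qualitative shape of real transcriptome-scale probing
#' data: a large majority of near-zero rates and partially overlapping
#' paired/unpaired rate distributions.
#'
#' * `"overlap"`: MaP readout; per-position modification probabilities
#'   follow quadratic grids (unpaired 0.005-0.10, paired 0.001-0.05) so
#'   the two class distributions overlap substantially, only about 1% of
#'   bases exceed a rate of 0.1, and most rates sit near zero.
#' * `"separable"`: MaP readout with disjoint class rates (unpaired 0.20,
#'   paired 0.002, no noise), giving AUC 1 in expectation.
#' * `"background-heavy"`: SEQ readout under single-hit kinetics (one
#'   expected modification per molecule over L = 200) with a spontaneous
#'   stop rate of 0.005 per position, for plus-only versus
#'   background-subtracted comparisons.
#'
#' @param name One of `"overlap"`, `"separable"`, `"background-heavy"`.
#' @param seed Integer seed stored in the configuration.
#' @param n_molecules Number of molecules (default 1e5).
#' @return A list with elements `config` ([probing_config()]) and
#'   `structure` (`secondary_structure`).
#' @export
make_benchmark_scenario <- function(name, seed = 1L, n_molecules = 100000L) {
  st <- benchmark_structure()
  L <- nrow(st)
  config <- switch(
    name,
    "overlap" = {
      m <- numeric(L)
      m[!st$paired] <- quadratic_grid(sum(!st$paired), 0.005, 0.10)
      m[st$paired] <- quadratic_grid(sum(st$paired), 0.001, 0.05)
      probing_config(st, mode = "mutation", p_mod_by_position = m,
                     n_molecules = n_molecules, mutation_detect_prob = 1,
                     seq_error_rate = 0.001, rng_seed = seed)
    },
    "separable" = probing_config(
      st, mode = "mutation", p_mod_unpaired = 0.20, p_mod_paired = 0.002,
      n_molecules = n_molecules, mutation_detect_prob = 1, rng_seed = seed),
    "background-heavy" = {
      m <- numeric(L)
      m[!st$paired] <- quadratic_grid(sum(!st$paired), 0.004, 0.012)
      m[st$paired] <- quadratic_grid(sum(st$paired), 0.001, 0.004)
      probing_config(st, mode = "stop", p_mod_by_position = m,
                     target_mods_per_molecule = L / 200,
                     natural_stop_rate = 0.005,
                     n_molecules = n_molecules, rng_seed = seed)
    },
    abort(sprintf("unknown scenario '%s'.", name),
          class = "probeval_validation_error")
  )
  list(config = config, structure = st)
}
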