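#' Configuration of a simulated chemical-probing experiment
#'
#' Describes the generative model used by [simulate_experiment()]: a known
#' secondary structure assigns each base a per-molecule modification
#' probability (`p_mod_unpaired` for dots, `p_mod_paired` for brackets, or
#' an explicit per-position vector), optionally rescaled so that the
#' expected number of modifications per molecule matches
#' `target_mods_per_molecule` (single-hit kinetics is roughly one
#' modification per ~200 nucleotides, i.e. a target of `L / 200`).
#' Detection follows the chosen readout: in `"stop"` (SEQ) mode reverse
#' transcription initiates at the 3' end and terminates at the 3'-most
#' modification, so only that modification is detectable -- the origin of
#' the 5' positional bias of stop profiles -- with additional spontaneous
#' stops at `natural_stop_rate` per position; in `"mutation"` (MaP) mode
#' every modification is read through and recorded with probability
#' `mutation_detect_prob`, and sequencing errors add spurious mutations at
#' `seq_error_rate`. The probe-free minus channel runs the same process
#' with all modification probabilities set to zero.
#'
#' @param structure A `secondary_structure` providing length and
#'   pairedness.
#' @param mode `"stop"` or `"mutation"`.
#' @param p_mod_unpaired,p_mod_paired Per-base, per-molecule modification
#'   probabilities for unpaired and paired bases. A warning (not an
#'   error) is raised when paired exceeds unpaired.
#' @param p_mod_by_position Optional numeric vector of length `L`
#'   overriding the two class probabilities position by position.
#' @param target_mods_per_molecule Optional expected modifications per
#'   molecule; when set, modification probabilities are rescaled
#'   proportionally so their sum matches it.
#' @param n_molecules Number of simulated molecules (>= 1).
#' @param mutation_detect_prob MaP only: probability a modification is
#'   recorded as a mutation (default 1).
#' @param natural_stop_rate SEQ only: per-position probability of a
#'   spontaneous reverse-transcription stop (default 0).
#' @param seq_error_rate MaP only: per-read, per-position probability of a
#'   spurious mutation (default 0).
#' @param stop_offset 0 (stop recorded at the modified base, default) or 1
#'   (recorded one position 3' of it, as in protocols where the
#'   polymerase halts after the adduct). Modification stops whose
#'   recorded position falls outside the molecule are not counted as
#'   events, though the molecule still contributes to depth.
#' @param rng_seed Integer seed; all randomness flows from it.
#' @return A `probing_config` list.
#' @export
probing_config <- function(structure, mode = c("stop", "mutation"),
                           p_mod_unpaired = 0.05, p_mod_paired = 0.01,
                           p_mod_by_position = NULL,
                           target_mods_per_molecule = NULL,
                           n_molecules = 10000L,
                           mutation_detect_prob = 1,
                           natural_stop_rate = 0,
                           seq_error_rate = 0,
                           stop_offset = 0L,
                           rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "secondary_structure"))
  L <- nrow(structure)
  probs <- c(p_mod_unpaired, p_mod_paired, mutation_detect_prob,
             natural_stop_rate, seq_error_rate, p_mod_by_position)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1].",
          class = "probeval_validation_error")
  }
  if (!stop_offset %in% c(0L, 1L)) {
    abort("stop_offset must be 0 or +1.", class = "probeval_validation_error")
  }
  if (n_molecules < 1L) {
    abort("n_molecules must be >= 1.", class = "probeval_validation_error")
  }
  if (is.null(p_mod_by_position) && p_mod_paired > p_mod_unpaired) {
    warn("p_mod_paired exceeds p_mod_unpaired; paired bases will look more reactive.")
  }
  m <- if (!is.null(p_mod_by_position)) {
    if (length(p_mod_by_position) != L) {
      abort("p_mod_by_position must have one entry per base.",
            class = "probeval_validation_error")
    }
    as.numeric(p_mod_by_position)
  } else {
    ifelse(structure$paired, p_mod_paired, p_mod_unpaired)
  }
  if (!is.null(target_mods_per_molecule)) {
    total <- sum(m)
    if (total > 0) m <- m * target_mods_per_molecule / total
    if (any(m > 1)) {
      abort("single-hit rescaling pushed a modification probability above 1.",
            class = "probeval_validation_error")
    }
  }
  config <- list(structure = structure, mode = mode, m = m,
                 n_molecules = as.integer(n_molecules),
                 mutation_detect_prob = mutation_detect_prob,
                 natural_stop_rate = natural_stop_rate,
                 seq_error_rate = seq_error_rate,
                 stop_offset = as.integer(stop_offset),
                 rng_seed = as.integer(rng_seed))
  class(config) <- "probing_config"
  config
}

#' Simulate a chemical-probing experiment
#'
#' Draws probe-treated (plus) and probe-free (minus) count profiles from
#' the generative model described in [probing_config()], together with
#' the ground-truth per-position modification counts of the plus channel.
#' Each molecule is modified independently at each position; in SEQ mode
#' reverse transcription runs 3' to 5' and halts at the first modified
#' position or spontaneous stop encountered, so per molecule at most one
#' modification-derived stop is recorded and depth decays towards the 5'
#' end. Results are deterministic given `rng_seed`.
#'
#' @param config A [probing_config()].
#' @return A list with elements `plus` and `minus` (both
#'   [count_profile()]s) and `truth`, a tibble with columns `position`
#'   and `modifications` (molecules carrying a modification at that
#'   position in the plus channel, detected or not).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "probing_config"))
  st <- config$structure
  L <- nrow(st)
  n <- config$n_molecules
  set.seed(config$rng_seed)
  if (config$mode == "mutation") {
    sim_ch <- function(m) {
      mods <- rbinom(L, n, m)
      detected <- rbinom(L, mods, config$mutation_detect_prob)
      spurious <- rbinom(L, n - detected, config$seq_error_rate)
      list(depth = rep(n, L), events = detected + spurious, mods = mods)
    }
    plus <- sim_ch(config$m)
    minus <- sim_ch(rep(0, L))
    truth <- plus$mods
  } else {
    sim_ch <- function(m) {
      nu <- config$natural_stop_rate
      q <- 1 - (1 - m) * (1 - nu)
      # S[i] = P(no stop strictly 3' of i) = prod_{j > i} (1 - q_j)
      S <- rev(cumprod(rev(1 - q)))
      S <- c(S[-1], 1)
      p_mod_stop <- m * S
      p_nat_stop <- (1 - m) * nu * S
      p_full <- prod(1 - q)
      draw <- rmultinom(1, n, c(p_mod_stop, p_nat_stop, p_full))[, 1]
      mod_stop <- draw[seq_len(L)]
      nat_stop <- draw[L + seq_len(L)]
      stops <- mod_stop + nat_stop
      depth <- cumsum(stops) + draw[2L * L + 1L]
      events <- nat_stop
      rec <- seq_len(L) + config$stop_offset
      keep <- rec <= L
      events[rec[keep]] <- events[rec[keep]] + mod_stop[keep]
      # positions 5' of a molecule's stop were never reverse transcribed;
      # modifications there are real but unobservable
      mods <- mod_stop + rbinom(L, n - depth, m)
      list(depth = depth, events = events, mods = mods)
    }
    plus <- sim_ch(config$m)
    minus <- sim_ch(rep(0, L))
    truth <- plus$mods
  }
  make_cp <- function(ch, channel) {
    count_profile(seq_len(L), st$base, ch$depth, ch$events,
                  rna_id = rna_id(st), channel = channel, mode = config$mode)
  }
  list(plus = make_cp(plus, "plus"),
       minus = make_cp(minus, "minus"),
       truth = tibble(position = seq_len(L), modifications = truth))
}

#' Closed-form expected event rates for a simulated experiment
#'
#' The deterministic counterpart of [simulate_experiment()]: for MaP the
#' expected mutation rate is
#' `m * d + (1 - m * d) * e` (modification detected, or a sequencing
#' error on a read not already mutated); for SEQ it is the probability
#' that a stop is recorded at the position divided by the probability the
#' position is informative, both derived by direct products over the
#' positions 3' of it. With `stop_offset = 0` this reduces to the
#' combined per-position stop probability
#' `1 - (1 - m)(1 - natural_stop_rate)`.
#'
#' @param config A [probing_config()].
#' @param channel `"plus"` (default) or `"minus"`.
#' @return A tibble with columns `position` and `expected_rate`.
#' @export
expected_rate_profile <- function(config, channel = c("plus", "minus")) {
  stopifnot(inherits(config, "probing_config"))
  channel <- match.arg(channel)
  L <- nrow(config$structure)
  m <- if (channel == "plus") config$m else rep(0, L)
  if (config$mode == "mutation") {
    md <- m * config$mutation_detect_prob
    rate <- md + (1 - md) * config$seq_error_rate
  } else {
    nu <- config$natural_stop_rate
    q <- 1 - (1 - m) * (1 - nu)
    S <- rev(cumprod(rev(1 - q)))
    S <- c(S[-1], 1)
    e_events <- (1 - m) * nu * S
    idx <- seq_len(L) - config$stop_offset
    ok <- idx >= 1L
    e_events[ok] <- e_events[ok] + (m * S)[idx[ok]]
    # P(informative at i) = P(no stop strictly 3' of i) = S_i
    rate <- ifelse(S > 0, e_events / S, NaN)
  }
  tibble(position = seq_len(L), expected_rate = rate)
}
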