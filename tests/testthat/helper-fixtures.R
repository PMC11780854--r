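# Brute-force pairwise AUC oracle: P(score_pos > score_neg) with half
# credit for exact ties, summed over all (pos, neg) pairs. Independent of
# the trapezoidal ROC construction it is used to validate.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  d <- outer(pos, neg, `-`)
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

# Quick reactivity profile over an implicit 1..L grid.
make_profile <- function(reactivity, base = NULL, valid = NULL,
                         rna_id = "toy", mode = "mutation",
                         background = "none") {
  L <- length(reactivity)
  if (is.null(base)) base <- rep(c("A", "C", "G", "U"), length.out = L)
  if (is.null(valid)) valid <- rep(TRUE, L)
  reactivity_profile(seq_len(L), base, reactivity, valid,
                     rna_id = rna_id, mode = mode, background = background)
}

# Secondary structure from a dot-bracket string; bases are filled in so
# that every bracket pair is G-C and loops alternate A/U.
make_structure <- function(dotbracket, rna_id = "toy") {
  L <- nchar(dotbracket)
  base <- rep(c("A", "U"), length.out = L)
  st <- parse_dotbracket(paste0(base, collapse = ""), dotbracket, rna_id)
  base[st$paired & st$position < st$partner] <- "G"
  base[st$paired & st$position > st$partner] <- "C"
  parse_dotbracket(paste0(base, collapse = ""), dotbracket, rna_id)
}

make_counts <- function(depth, events, base = NULL, rna_id = "toy",
                        channel = "plus", mode = "mutation") {
  L <- length(depth)
  if (is.null(base)) base <- rep(c("A", "C", "G", "U"), length.out = L)
  count_profile(seq_len(L), base, depth, events,
                rna_id = rna_id, channel = channel, mode = mode)
}

# Fixed-column PDB writer for toy structures. `atoms` needs columns
# chain, resno, resname, name, element, x, y, z.
write_toy_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$name, " ", a$resname, a$chain, a$resno,
            a$x, a$y, a$z, 1.0, 0.0, a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

random_rna <- function(L) {
  paste0(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}
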