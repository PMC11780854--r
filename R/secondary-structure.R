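#' Secondary structure from dot-bracket notation
#'
#' Parses a dot-bracket string into a per-position pairing table. The
#' structure alphabet is `.` (unpaired) plus the independently balanced
#' bracket layers `()`, `[]`, `{}` and `<>`; layers beyond `()` encode
#' pseudoknots. Any non-dot symbol counts as paired for evaluation
#' purposes. The partner table is an involution: `partner[partner[i]] == i`
#' wherever defined.
#'
#' @param sequence RNA sequence (same length as `structure`).
#' @param structure Dot-bracket string.
#' @param rna_id RNA identifier.
#' @return A `secondary_structure` tibble with columns `position`, `base`,
#'   `symbol`, `paired` (logical) and `partner` (integer, `NA` when
#'   unpaired), and attributes `rna_id` and `dotbracket`.
#' @export
#' @examples
#' parse_dotbracket("GGGAAACCC", "(((...)))", rna_id = "hairpin")
parse_dotbracket <- function(sequence, structure, rna_id = "rna") {
  sequence <- toupper(gsub("T", "U", sequence, fixed = TRUE))
  if (nchar(sequence) != nchar(structure)) {
    abort(sprintf("sequence length (%d) and structure length (%d) differ.",
                  nchar(sequence), nchar(structure)),
          class = "probeval_format_error")
  }
  sym <- strsplit(structure, "", fixed = TRUE)[[1]]
  layers <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  known <- c(".", unlist(layers))
  if (!all(sym %in% known)) {
    i <- which(!sym %in% known)[1]
    abort(sprintf("unknown structure symbol '%s' at position %d.", sym[i], i),
          class = "probeval_format_error")
  }
  L <- length(sym)
  partner <- rep(NA_integer_, L)
  for (layer in layers) {
    stack <- integer(0)
    for (i in seq_len(L)) {
      if (sym[i] == layer[1]) {
        stack <- c(stack, i)
      } else if (sym[i] == layer[2]) {
        if (length(stack) == 0L) {
          abort(sprintf("unbalanced '%s' at position %d.", layer[2], i),
                class = "probeval_format_error")
        }
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j
        partner[j] <- i
      }
    }
    if (length(stack) > 0L) {
      abort(sprintf("unbalanced '%s' at position %d.", layer[1],
                    stack[length(stack)]),
            class = "probeval_format_error")
    }
  }
  x <- tibble(
    position = seq_len(L),
    base = strsplit(sequence, "", fixed = TRUE)[[1]],
    symbol = sym,
    paired = sym != ".",
    partner = partner
  )
  attr(x, "rna_id") <- as.character(rna_id)
  attr(x, "dotbracket") <- structure
  class(x) <- c("secondary_structure", class(x))
  x
}

#' Read a three-line dot-bracket file
#'
#' The dialect is: a FASTA-style header line, the sequence, and the
#' dot-bracket structure of the same length.
#'
#' @param path Path to the file.
#' @return A `secondary_structure` tibble (see [parse_dotbracket()]).
#' @export
read_dotbracket <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L || !startsWith(lines[1], ">")) {
    abort(sprintf("%s: expected header, sequence and structure lines.", path),
          class = "probeval_format_error")
  }
  id <- sub("\\s.*$", "", sub("^>\\s*", "", lines[1]))
  parse_dotbracket(lines[2], lines[3], rna_id = id)
}

#' Write a secondary structure as a three-line dot-bracket file
#'
#' @param structure A `secondary_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structure, path) {
  writeLines(c(paste0(">", rna_id(structure)),
               paste0(structure$base, collapse = ""),
               paste0(structure$symbol, collapse = "")), path)
  invisible(path)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> rna=%s L=%d paired=%d unpaired=%d\n",
              rna_id(x), nrow(x), sum(x$paired), sum(!x$paired)))
  NextMethod()
}
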