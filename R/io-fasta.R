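#' Read RNA sequences from a FASTA file
#'
#' Sequences are case-folded to upper case and DNA-style `T` is silently
#' converted to `U`. After conversion the alphabet is restricted to
#' `A`,`C`,`G`,`U`,`N`; any other character is a format error that names
#' the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("empty FASTA file: %s", path), class = "probeval_format_error")
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) {
    abort(sprintf("%s: line 1 is not a FASTA header.", path),
          class = "probeval_format_error")
  }
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  # line-number bookkeeping so validation errors can point at the file
  all_lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(all_lines)))
  seqs <- vapply(split(seq_along(lines), rec), function(ix) {
    paste0(lines[ix][!hdr[ix]], collapse = "")
  }, character(1))
  seqs <- toupper(seqs)
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGUN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    body_lines <- keep[which(rec == i & !hdr)]
    offending <- body_lines[1]
    for (ln in body_lines) {
      s <- gsub("T", "U", toupper(all_lines[ln]), fixed = TRUE)
      if (grepl("[^ACGUN]", s)) { offending <- ln; break }
    }
    abort(sprintf("%s: invalid sequence character in record '%s' at line %d.",
                  path, ids[i], offending),
          class = "probeval_format_error")
  }
  if (any(nchar(seqs) == 0L)) {
    i <- which(nchar(seqs) == 0L)[1]
    abort(sprintf("%s: record '%s' has an empty sequence.", path, ids[i]),
          class = "probeval_format_error")
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}
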