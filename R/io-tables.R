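# TSV dialect shared by count and reactivity tables: '#key=value' metadata
# lines, then a header row and tab-separated columns.

read_meta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#", "", meta_lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(trimws(vals)), trimws(keys))
}

require_meta <- function(meta, keys, path) {
  missing <- setdiff(keys, names(meta))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing metadata line '#%s='.", path, missing[1]),
          class = "probeval_format_error")
  }
}

read_body_tsv <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE)
}

#' Read and write per-position count tables
#'
#' Count tables are TSV files with metadata lines `#rna=`, `#channel=` and
#' `#mode=` followed by columns `position`, `base`, `depth`, `events`.
#' All [count_profile()] invariants (contiguous 1-based positions,
#' `events <= depth`) are enforced on read; violations raise a validation
#' error naming the position.
#'
#' @param path Path to the TSV file.
#' @return [read_counts_tsv()] returns a `count_profile`;
#'   [write_counts_tsv()] returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  meta <- read_meta_lines(path)
  require_meta(meta, c("rna", "channel", "mode"), path)
  body <- read_body_tsv(path, readr::cols(
    position = readr::col_integer(), base = readr::col_character(),
    depth = readr::col_double(), events = readr::col_double()
  ))
  need <- c("position", "base", "depth", "events")
  if (!all(need %in% names(body))) {
    abort(sprintf("%s: missing column '%s'.", path,
                  setdiff(need, names(body))[1]),
          class = "probeval_format_error")
  }
  count_profile(body$position, body$base, body$depth, body$events,
                rna_id = meta$rna, channel = meta$channel, mode = meta$mode)
}

#' @rdname read_counts_tsv
#' @param profile A `count_profile` to serialize.
#' @export
write_counts_tsv <- function(profile, path) {
  writeLines(c(paste0("#rna=", rna_id(profile)),
               paste0("#channel=", attr(profile, "channel")),
               paste0("#mode=", attr(profile, "mode"))), path)
  readr::write_tsv(as_tibble(profile), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write reactivity tables
#'
#' Reactivity tables are TSV files with metadata lines `#rna=`, `#mode=`,
#' `#probe=` and `#background=subtracted|none`, followed by columns
#' `position`, `base`, `reactivity`, `valid`. Invalid positions carry the
#' `NaN` sentinel in `reactivity`.
#'
#' @param path Path to the TSV file.
#' @return [read_reactivity_tsv()] returns a `reactivity_profile`;
#'   [write_reactivity_tsv()] returns `path` invisibly.
#' @export
read_reactivity_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  meta <- read_meta_lines(path)
  require_meta(meta, c("rna", "mode", "probe", "background"), path)
  body <- read_body_tsv(path, readr::cols(
    position = readr::col_integer(), base = readr::col_character(),
    reactivity = readr::col_double(), valid = readr::col_logical()
  ))
  reactivity_profile(body$position, body$base, body$reactivity, body$valid,
                     rna_id = meta$rna, mode = meta$mode,
                     probe = if (meta$probe %in% c("NA", "")) NA_character_ else meta$probe,
                     background = meta$background)
}

#' @rdname read_reactivity_tsv
#' @param profile A `reactivity_profile` to serialize.
#' @export
write_reactivity_tsv <- function(profile, path) {
  writeLines(c(paste0("#rna=", rna_id(profile)),
               paste0("#mode=", attr(profile, "mode")),
               paste0("#probe=", attr(profile, "probe")),
               paste0("#background=", attr(profile, "background"))), path)
  readr::write_tsv(as_tibble(profile), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
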