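#' Per-position event-count profile
#'
#' A `count_profile` holds, for one RNA and one channel of a probing
#' experiment, the per-position read depth and event count (reverse
#' transcription stops or mutations). It is a tibble with columns
#' `position`, `base`, `depth`, `events` and attributes `rna_id`,
#' `channel` (`"plus"` = probe-treated, `"minus"` = probe-free background)
#' and `mode` (`"stop"` or `"mutation"`). Positions are 1-based and must
#' form a contiguous `1..L` range; missing data are encoded as depth 0.
#'
#' @param position Integer vector of 1-based positions, contiguous `1..L`.
#' @param base Character vector of nucleotides (`A`,`C`,`G`,`U`,`N`).
#' @param depth Non-negative integer vector: reads informative at each
#'   position. For stop profiles this counts reads whose cDNA covers or
#'   terminates at the position.
#' @param events Non-negative integer vector: stops or mutations observed;
#'   `events[i] <= depth[i]` is enforced.
#' @param rna_id Identifier of the RNA.
#' @param channel `"plus"` or `"minus"`.
#' @param mode `"stop"` or `"mutation"`.
#'
#' @return A `count_profile` tibble.
#' @export
#' @examples
#' count_profile(1:3, c("A", "C", "G"), c(600L, 700L, 800L), c(6L, 0L, 80L),
#'               rna_id = "toy", channel = "plus", mode = "mutation")
count_profile <- function(position, base, depth, events,
                          rna_id, channel = c("plus", "minus"),
                          mode = c("stop", "mutation")) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  x <- tibble(
    position = as.integer(position),
    base = toupper(as.character(base)),
    depth = as.integer(depth),
    events = as.integer(events)
  )
  attr(x, "rna_id") <- as.character(rna_id)
  attr(x, "channel") <- channel
  attr(x, "mode") <- mode
  class(x) <- c("count_profile", class(x))
  validate_count_profile(x)
}

validate_count_profile <- function(x) {
  if (nrow(x) < 1L) {
    abort("count_profile must contain at least one position.",
          class = "probeval_validation_error")
  }
  if (!identical(x$position, seq_len(nrow(x)))) {
    abort("positions must form a contiguous 1..L range.",
          class = "probeval_validation_error")
  }
  if (anyNA(x$depth) || anyNA(x$events) || any(x$depth < 0L) || any(x$events < 0L)) {
    abort("depth and events must be non-negative integers.",
          class = "probeval_validation_error")
  }
  bad <- which(x$events > x$depth)
  if (length(bad) > 0L) {
    abort(
      sprintf("events exceed depth at position %d (events=%d, depth=%d).",
              bad[1], x$events[bad[1]], x$depth[bad[1]]),
      class = "probeval_validation_error"
    )
  }
  ok <- x$base %in% c("A", "C", "G", "U", "N")
  if (!all(ok)) {
    abort(sprintf("invalid base %s at position %d.",
                  x$base[which(!ok)[1]], x$position[which(!ok)[1]]),
          class = "probeval_validation_error")
  }
  x
}

#' @export
print.count_profile <- function(x, ...) {
  cat(sprintf("<count_profile> rna=%s channel=%s mode=%s L=%d\n",
              rna_id(x), attr(x, "channel"), attr(x, "mode"), nrow(x)))
  NextMethod()
}

#' Accessors for profile metadata
#'
#' @param x A `count_profile`, `reactivity_profile` or `secondary_structure`.
#' @return `rna_id()` the RNA identifier; `profile_mode()` the detection
#'   mode (`"stop"` or `"mutation"`).
#' @export
rna_id <- function(x) attr(x, "rna_id")

#' @rdname rna_id
#' @export
profile_mode <- function(x) attr(x, "mode")
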