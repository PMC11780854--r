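#' Per-position reactivity profile
#'
#' A `reactivity_profile` is a tibble with columns `position`, `base`,
#' `reactivity` and `valid`, plus attributes `rna_id`, `mode` (`"stop"` or
#' `"mutation"`), `probe` (`"DMS"`, `"SHAPE"` or `NA`) and `background`
#' (`"none"` or `"subtracted"`). Reactivity at invalid positions is the
#' `NaN` sentinel; positions flagged invalid never enter downstream ROC or
#' top-x% computations. Without background subtraction every reactivity
#' lies in `[0, 1]`; background-adjusted values may be negative unless
#' clamped.
#'
#' @param position,base,reactivity,valid Column vectors (see above).
#' @param rna_id RNA identifier.
#' @param mode `"stop"` or `"mutation"`.
#' @param probe `"DMS"`, `"SHAPE"` or `NA` if not yet assigned.
#' @param background `"none"` or `"subtracted"`.
#'
#' @return A `reactivity_profile` tibble.
#' @export
reactivity_profile <- function(position, base, reactivity, valid,
                               rna_id, mode = c("stop", "mutation"),
                               probe = NA_character_,
                               background = c("none", "subtracted")) {
  mode <- match.arg(mode)
  background <- match.arg(background)
  x <- tibble(
    position = as.integer(position),
    base = toupper(as.character(base)),
    reactivity = as.numeric(reactivity),
    valid = as.logical(valid)
  )
  x$reactivity[!x$valid] <- NaN
  attr(x, "rna_id") <- as.character(rna_id)
  attr(x, "mode") <- mode
  attr(x, "probe") <- probe
  attr(x, "background") <- background
  class(x) <- c("reactivity_profile", class(x))
  validate_reactivity_profile(x)
}

validate_reactivity_profile <- function(x) {
  if (!identical(x$position, seq_len(nrow(x)))) {
    abort("positions must form a contiguous 1..L range.",
          class = "probeval_validation_error")
  }
  r <- x$reactivity[x$valid]
  if (any(!is.finite(r))) {
    abort("valid positions must carry finite reactivity.",
          class = "probeval_validation_error")
  }
  if (identical(attr(x, "background"), "none") &&
      any(r < 0 | r > 1)) {
    abort("reactivity outside [0,1] without background subtraction.",
          class = "probeval_validation_error")
  }
  x
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> rna=%s mode=%s probe=%s background=%s valid=%d/%d\n",
              rna_id(x), attr(x, "mode"), attr(x, "probe"),
              attr(x, "background"), sum(x$valid), nrow(x)))
  NextMethod()
}

# Positions usable for evaluation: valid flag and finite reactivity.
valid_positions <- function(profile) {
  which(profile$valid & is.finite(profile$reactivity))
}
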