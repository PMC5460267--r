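`%||%` <- function(x, y) if (is.null(x)) y else x

#' Abort with a classed condition
#'
#' All user-facing errors in the package carry a class so callers can
#' distinguish configuration mistakes from data validation failures.
#'
#' @param msg message lines (character vector; collapsed with newlines).
#' @param class condition subclass, e.g. `"prscan_config_error"`.
#' @noRd
prscan_abort <- function(msg, class = "prscan_error") {
  stop(structure(
    class = c(class, "prscan_error", "error", "condition"),
    list(message = paste(msg, collapse = "\n"), call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

#' Format numeric columns to a fixed precision for diffable output
#' @noRd
format_fixed <- function(x, digits = 10L) {
  if (is.double(x)) {
    out <- sprintf(paste0("%.", digits, "g"), x)
    out[is.na(x)] <- NA_character_
    out
  } else {
    x
  }
}

#' Seeded evaluation that restores the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream-specific 31-bit seed from a master seed
#' @noRd
derive_seed <- function(seed, stream) {
  # deterministic, cheap, keeps results independent across pipeline stages
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}
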