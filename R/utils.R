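#' @keywords internal
"_PACKAGE"

# Internal validation / misc helpers shared across modules.

.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) .stop_fmt(...)
  invisible(TRUE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

#' Derive a reproducible integer seed from a base seed and string labels
#'
#' Sessions of a simulated campaign need independent but reproducible random
#' streams without manual seed bookkeeping. The per-session seed is a
#' deterministic hash of the campaign seed and the session labels (room,
#' date), folded into the positive 32-bit integer range accepted by
#' [set.seed()].
#'
#' @param seed Integer base seed.
#' @param ... Character scalars (e.g. room identifier, ISO date) mixed into
#'   the hash.
#' @return A single integer in `[1, 2^31 - 8]`.
#' @export
#' @examples
#' derive_seed(42, "G1", "2026-05-20")
derive_seed <- function(seed, ...) {
  .assert(.is_count(seed), "seed must be a single integer")
  labels <- paste(c(seed, ...), collapse = "\x1f")
  # 31-based rolling hash in double arithmetic; modulus keeps products < 2^53
  m <- 2147483629 # largest prime < 2^31 - 16
  h <- 17
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

# Format a calendar date as ISO-8601, accepting Date or "YYYY-MM-DD" strings.
.as_iso_date <- function(x) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) .stop_fmt("invalid calendar date: %s", paste(x, collapse = ", "))
  d
}
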