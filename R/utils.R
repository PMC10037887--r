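#' Derive a reproducible substream seed from a master seed and a key
#'
#' Experiments derive one RNG substream per trial from the master seed and a
#' human-readable key (e.g. `"grid|p=0.130000|depth=30|rep=7"`), so any grid
#' cell can be recomputed in isolation and results do not depend on the order
#' in which cells are visited.
#'
#' The derivation is a 31-bit multiplicative fold of the key's UTF-8 bytes
#' seeded by the master seed: `s <- (s * 31 + byte) mod (2^31 - 1)`. It is a
#' fixed, documented convention, not a cryptographic hash.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric key components; numerics are formatted with
#'   `format()` so `0.1` and `0.10` derive the same stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' derive_seed(42, "grid", p = 0.08, depth = 30, rep = 1)
#' @export
derive_seed <- function(master_seed, ...) {
  parts <- list(...)
  nms <- names(parts) %||% rep("", length(parts))
  fmt <- function(x) {
    if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE) else as.character(x)
  }
  key <- paste(
    vapply(seq_along(parts), function(i) {
      v <- fmt(parts[[i]])
      if (nzchar(nms[i])) paste0(nms[i], "=", v) else v
    }, character(1)),
    collapse = "|"
  )
  m <- 2147483647 # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  s <- as.double(master_seed) %% m
  for (b in utf8ToInt(key)) s <- (s * 31 + b) %% m
  as.integer(s)
}

#' @noRd
assert_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (length(x) != 1L || !is.character(x) || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!allow_empty && !nzchar(x)) stop(what, " must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", x)) {
    stop(what, " may contain only A, C, G, T", call. = FALSE)
  }
  invisible(x)
}

# round-half-up, used for contaminant counts (base round() is round-half-even)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
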