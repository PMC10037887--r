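#' Recovery metrics
#'
#' Three complementary views of how well a consensus matches its reference:
#'
#' * [recovery_accuracy()] -- `1 - Levenshtein / nchar(reference)`, clamped
#'   to `[0, 1]`. Indel-aware: a single residual indel costs 1/L, not a
#'   cascade of positional mismatches.
#' * [normalized_hamming()] -- positional mismatches over the overlap plus
#'   the length difference, divided by the reference length. A residual
#'   indel desynchronises every downstream position, so this metric punishes
#'   synchronisation errors heavily; it is the natural metric for decoded
#'   payloads, where a frame shift garbles the rest of the record.
#' * [errors_corrected_fraction()] -- `1 - Levenshtein / (p * L)`, clamped:
#'   residual consensus errors relative to the expected number of injected
#'   errors per read. This is the scale on which depth-threshold curves are
#'   expressed ("the aligner corrects 95% of the errors").
#'
#' Complete recovery means zero edit distance; a mean accuracy of 1 is
#' reported only when every trial is exact.
#'
#' @name metrics
NULL

#' @noRd
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Indel-aware recovery accuracy
#'
#' @param consensus Consensus DNA string (may be empty).
#' @param reference Non-empty reference DNA string. Accuracy is normalised
#'   by the reference length, so the arguments are not interchangeable.
#' @return `max(0, 1 - Levenshtein(consensus, reference) / nchar(reference))`.
#' @examples
#' recovery_accuracy("ACG", "ACGT") # 0.75
#' @export
recovery_accuracy <- function(consensus, reference) {
  if (!nzchar(reference)) stop("reference must be non-empty", call. = FALSE)
  max(0, min(1, 1 - edit_distance(consensus, reference) / nchar(reference)))
}

#' Normalized Hamming distance
#'
#' Positional mismatches over the common prefix length plus the length
#' difference, divided by the reference length; equal to classical
#' Hamming/length when the strings have equal length.
#'
#' @inheritParams recovery_accuracy
#' @return A non-negative real; 0 iff the strings are identical.
#' @export
normalized_hamming <- function(consensus, reference) {
  if (!nzchar(reference)) stop("reference must be non-empty", call. = FALSE)
  n <- min(nchar(consensus), nchar(reference))
  mism <- if (n == 0L) 0L else {
    sum(chars(substr(consensus, 1L, n)) != chars(substr(reference, 1L, n)))
  }
  (mism + abs(nchar(consensus) - nchar(reference))) / nchar(reference)
}

#' Fraction of injected errors corrected by the consensus
#'
#' @inheritParams recovery_accuracy
#' @param p Channel error rate used to generate the reads; must be > 0.
#' @return `1 - Levenshtein / (p * nchar(reference))`, clamped to `[0, 1]`.
#' @export
errors_corrected_fraction <- function(consensus, reference, p) {
  if (!nzchar(reference)) stop("reference must be non-empty", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0) {
    stop("errors_corrected_fraction is undefined for p <= 0", call. = FALSE)
  }
  max(0, min(1, 1 - edit_distance(consensus, reference) / (p * nchar(reference))))
}

#' Score one decoded consensus against its reference
#'
#' @param consensus Consensus DNA string.
#' @param reference Reference DNA string.
#' @param p Channel error rate (0 allowed; the errors-corrected fraction is
#'   then `NA`).
#' @return A one-row tibble with `edit_distance`, `accuracy` (Levenshtein),
#'   `normalized_hamming`, `hamming_accuracy`, `errors_corrected` and
#'   `complete`.
#' @export
score_consensus <- function(consensus, reference, p = NA_real_) {
  d <- edit_distance(consensus, reference)
  L <- nchar(reference)
  nh <- normalized_hamming(consensus, reference)
  tibble::tibble(
    edit_distance = d,
    accuracy = max(0, min(1, 1 - d / L)),
    normalized_hamming = nh,
    hamming_accuracy = max(0, 1 - nh),
    errors_corrected = if (!is.na(p) && p > 0) max(0, min(1, 1 - d / (p * L))) else NA_real_,
    complete = d == 0L
  )
}
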