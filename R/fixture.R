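#' The packaged storage payload
#'
#' A ~4 KB original story shipped with the package as a synthetic stand-in
#' for a stored text file. Its first 3,920 bytes encode to exactly 140
#' oligos of 120 nt under the default 8-nt-index layout (140 oligos x 28
#' payload bytes), matching the scale the simulation studies are defined on.
#'
#' @param n_bytes Number of bytes to return (default 3920; `Inf` for all).
#' @return A raw vector.
#' @export
fixture_bytes <- function(n_bytes = 3920L) {
  path <- system.file("extdata", "grandmother_synthetic.txt", package = "oligovote")
  bytes <- readBin(path, "raw", file.size(path))
  if (is.finite(n_bytes)) {
    stopifnot(n_bytes <= length(bytes))
    bytes <- bytes[seq_len(n_bytes)]
  }
  bytes
}

#' Reference oligos for the packaged payload
#'
#' Encodes the fixture text and returns the first `n` oligo sequences,
#' the standard reference set for the experiment drivers.
#'
#' @param n Number of oligos (default 20; at most 140).
#' @param L,index_len Oligo layout, see [make_oligos()].
#' @return A tibble with columns `index_id` and `sequence`.
#' @examples
#' demo_oligos(2)
#' @export
demo_oligos <- function(n = 20L, L = 120L, index_len = 8L) {
  enc <- make_oligos(fixture_bytes(), L = L, index_len = index_len)
  stopifnot(n >= 1L, n <= nrow(enc$oligos))
  enc$oligos[seq_len(n), ]
}
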