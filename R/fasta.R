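#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a tibble
#' and normalises sequences to upper case (so soft-masked input aligns and
#' votes like everything else). Gap characters are preserved, which lets the
#' same reader load alignments.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (full header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  tibble::tibble(
    id = sub("\\s.*$", "", full),
    description = full,
    sequence = toupper(as.character(set, use.names = FALSE))
  )
}

#' Write sequences to FASTA
#'
#' @param records A tibble/data frame with columns `id` and `sequence`
#'   (optionally `description`, appended after the id), or a character vector
#'   of sequences (auto-named `seq_1`, ...).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.character(records)) {
    records <- tibble::tibble(
      id = paste0("seq_", seq_along(records)), sequence = records
    )
  }
  headers <- records$id
  if ("description" %in% names(records) && any(nzchar(records$description))) {
    headers <- ifelse(nzchar(records$description),
                      paste(records$id, records$description), records$id)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}
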