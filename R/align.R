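#' Multiple sequence alignment of a read cluster
#'
#' Two engines produce the gap-padded alignment that consensus voting
#' consumes. The primary engine shells out to MAFFT in its default FFT-NS-2
#' strategy (fast progressive alignment, two rounds, no iterative
#' refinement), which is what all quantitative results are defined on. A
#' dependency-free fallback implements classic center-star progressive
#' alignment over pairwise Needleman-Wunsch (match +1, mismatch -1, gap -2,
#' linear): it picks the read with maximal summed pairwise score (ties to the
#' lowest input index), aligns every other read to it, and merges the
#' pairwise alignments under the once-a-gap-always-a-gap rule.
#'
#' Both engines guarantee: row order equals input order, removing gaps from
#' row k restores read k exactly, and no column is all gaps.
#'
#' @name msa_engine
NULL

new_alignment <- function(rows, ids, engine) {
  structure(
    list(rows = rows, source_read_ids = ids, width = nchar(rows[1]),
         engine_tag = engine),
    class = "msa_alignment"
  )
}

#' @export
print.msa_alignment <- function(x, n = 10L, ...) {
  cat(sprintf("<msa_alignment> %d rows x %d columns (%s)\n",
              length(x$rows), x$width, x$engine_tag))
  show <- utils::head(seq_along(x$rows), n)
  for (i in show) cat(sprintf("  %s %s\n", x$source_read_ids[i], x$rows[i]))
  if (length(x$rows) > n) cat("  ...\n")
  invisible(x)
}

validate_alignment <- function(aln, reads) {
  if (length(unique(nchar(aln$rows))) != 1L) {
    stop("alignment rows have unequal widths", call. = FALSE)
  }
  degapped <- gsub("-", "", aln$rows, fixed = TRUE)
  if (!identical(toupper(degapped), toupper(reads))) {
    stop("alignment rows do not degap to the input reads", call. = FALSE)
  }
  aln
}

#' Is a MAFFT executable available?
#'
#' @param mafft_path Name or path of the MAFFT executable.
#' @return `TRUE` if the executable can be found.
#' @export
mafft_available <- function(mafft_path = "mafft") {
  nzchar(Sys.which(mafft_path))
}

#' Align reads with MAFFT (FFT-NS-2)
#'
#' Writes the reads to a temporary FASTA, runs MAFFT in its default strategy
#' (FFT-NS-2) and parses the aligned FASTA back in input order. Sequences are
#' upper-cased on return.
#'
#' @param reads Character vector of DNA reads (length >= 1).
#' @param mafft_path MAFFT executable (default `"mafft"` on the PATH).
#' @param extra_args Additional command-line arguments, e.g. `"--localpair"`
#'   for L-INS-i. Quantitative results in this package are defined on the
#'   default strategy.
#' @return An `msa_alignment`.
#' @export
align_mafft <- function(reads, mafft_path = "mafft", extra_args = character()) {
  stopifnot(is.character(reads), length(reads) >= 1L)
  ids <- sprintf("read_%d", seq_along(reads))
  if (length(reads) == 1L) {
    return(new_alignment(toupper(reads), ids, "mafft-fftns2"))
  }
  if (!mafft_available(mafft_path)) {
    stop("MAFFT executable not found (looked for '", mafft_path,
         "'); use engine = \"fallback\" for the built-in aligner", call. = FALSE)
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  ferr <- tempfile(fileext = ".log")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  write_fasta(tibble::tibble(id = ids, sequence = reads), fin)
  status <- suppressWarnings(system2(
    mafft_path, c("--quiet", "--nuc", extra_args, shQuote(fin)),
    stdout = fout, stderr = ferr
  ))
  if (!identical(status, 0L)) {
    stop("MAFFT exited with status ", status, ": ",
         paste(readLines(ferr, warn = FALSE), collapse = " "), call. = FALSE)
  }
  out <- read_fasta(fout)
  if (nrow(out) != length(reads) || !identical(out$id, ids)) {
    stop("MAFFT output does not match input records", call. = FALSE)
  }
  validate_alignment(new_alignment(out$sequence, ids, "mafft-fftns2"),
                     toupper(reads))
}

#' Align reads with the built-in center-star aligner
#'
#' @param reads Character vector of DNA reads (length >= 1).
#' @param match,mismatch,gap Alignment scoring (defaults +1/-1/-2).
#' @return An `msa_alignment`.
#' @export
align_fallback <- function(reads, match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(is.character(reads), length(reads) >= 1L)
  reads <- toupper(reads)
  ids <- sprintf("read_%d", seq_along(reads))
  n <- length(reads)
  if (n == 1L) return(new_alignment(reads, ids, "fallback-centerstar"))
  center <- which.max(.nw_score_sums(reads, match, mismatch, gap)) # ties -> lowest index
  others <- setdiff(seq_len(n), center)
  pw <- lapply(others, function(k) {
    .nw_align(reads[center], reads[k], match, mismatch, gap)
  })
  # gaps_before[j]: gaps the merged alignment needs before center base j
  # (j = m + 1 means after the last base); max over the pairwise alignments
  m <- nchar(reads[center])
  gaps_before <- integer(m + 1L)
  pw_gap_runs <- lapply(pw, function(al) {
    cc <- chars(al$a)
    runs <- integer(m + 1L)
    pos <- 1L; run <- 0L
    for (ch in cc) {
      if (ch == "-") run <- run + 1L else { runs[pos] <- run; run <- 0L; pos <- pos + 1L }
    }
    runs[m + 1L] <- run
    runs
  })
  for (runs in pw_gap_runs) gaps_before <- pmax(gaps_before, runs)
  pad_row <- function(aligned_center, aligned_other, runs) {
    # re-walk the pairwise alignment, topping up each inter-base gap run to
    # the merged profile
    cc <- chars(aligned_center); oo <- chars(aligned_other)
    out <- character(0)
    pos <- 1L; run <- 0L; buf <- character(0)
    flush <- function(pos, buf, run) c(buf, rep("-", gaps_before[pos] - run))
    for (k in seq_along(cc)) {
      if (cc[k] == "-") { buf <- c(buf, oo[k]); run <- run + 1L }
      else {
        out <- c(out, flush(pos, buf, run), oo[k])
        buf <- character(0); run <- 0L; pos <- pos + 1L
      }
    }
    out <- c(out, flush(m + 1L, buf, run))
    paste(out, collapse = "")
  }
  center_row <- {
    cb <- chars(reads[center])
    paste0(paste0(
      vapply(seq_len(m), function(j) {
        paste0(strrep("-", gaps_before[j]), cb[j])
      }, character(1)), collapse = ""
    ), strrep("-", gaps_before[m + 1L]))
  }
  rows <- character(n)
  rows[center] <- center_row
  for (i in seq_along(others)) {
    rows[others[i]] <- pad_row(pw[[i]]$a, pw[[i]]$b, pw_gap_runs[[i]])
  }
  validate_alignment(new_alignment(rows, ids, "fallback-centerstar"), reads)
}

#' Align a set of reads with the chosen engine
#'
#' @param reads Character vector of DNA reads, or a `read_cluster`.
#' @param engine `"mafft"`, `"fallback"`, or `"auto"` (MAFFT if available).
#' @param ... Passed to [align_mafft()] or [align_fallback()].
#' @return An `msa_alignment`.
#' @export
align_reads <- function(reads, engine = c("auto", "mafft", "fallback"), ...) {
  if (inherits(reads, "read_cluster")) reads <- reads$reads
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (mafft_available()) "mafft" else "fallback"
  switch(engine,
    mafft = align_mafft(reads, ...),
    fallback = align_fallback(reads, ...)
  )
}
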