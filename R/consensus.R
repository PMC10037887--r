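#' Column-wise majority-vote consensus
#'
#' Each alignment column is tallied over `{A, C, G, T, -}`. If the gap symbol
#' has a strict plurality the column is dropped (a majority-supported
#' deletion); otherwise the plurality base is emitted. Ties are resolved by
#' the deterministic default rule -- a base beats the gap, then fixed order
#' A < C < G < T -- so voting is seed-independent; `tie_rule = "random"`
#' draws uniformly among tied symbols for sensitivity analysis. Contaminant
#' reads are never excluded before voting: robustness to imperfect
#' clustering is measured with them included.
#'
#' @param alignment An `msa_alignment` from [align_reads()].
#' @param tie_rule `"deterministic"` (default) or `"random"`.
#' @return An object of class `consensus_call`: list with `sequence` (the
#'   consensus DNA string), `votes` (5 x width count matrix with rows
#'   A, C, G, T, `-`) and `dropped_columns` (indices where the gap won).
#' @examples
#' aln <- align_fallback(c("ACGT", "ACGT", "AGGT"))
#' vote(aln)$sequence
#' @export
vote <- function(alignment, tie_rule = c("deterministic", "random")) {
  stopifnot(inherits(alignment, "msa_alignment"))
  tie_rule <- match.arg(tie_rule)
  if (length(alignment$rows) == 0L) stop("empty alignment", call. = FALSE)
  symbols <- c(DNA_BASES, "-")
  mat <- matrix(
    match(unlist(strsplit(alignment$rows, "", fixed = TRUE)), symbols),
    nrow = alignment$width
  ) # columns of the matrix = alignment rows
  counts <- apply(mat, 1L, tabulate, nbins = 5L) # 5 x width
  rownames(counts) <- symbols
  base_counts <- counts[1:4, , drop = FALSE]
  if (tie_rule == "deterministic") {
    best_base <- apply(base_counts, 2L, which.max) # ties -> A < C < G < T
  } else {
    best_base <- apply(base_counts, 2L, function(v) {
      w <- which(v == max(v))
      if (length(w) == 1L) w else w[sample.int(length(w), 1L)]
    })
  }
  best_count <- base_counts[cbind(best_base, seq_len(ncol(counts)))]
  gap_wins <- counts[5L, ] > best_count # strict plurality only
  if (tie_rule == "random") {
    tied <- counts[5L, ] == best_count
    if (any(tied)) {
      gap_wins[tied] <- stats::runif(sum(tied)) < 0.5
    }
  }
  structure(
    list(
      sequence = paste(DNA_BASES[best_base[!gap_wins]], collapse = ""),
      votes = counts,
      dropped_columns = which(gap_wins)
    ),
    class = "consensus_call"
  )
}

#' @export
print.consensus_call <- function(x, ...) {
  cat(sprintf("<consensus_call> %d nt (%d gap-majority columns dropped)\n",
              nchar(x$sequence), length(x$dropped_columns)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

#' Align a cluster and call its consensus
#'
#' The decode step used throughout the experiments: `vote(align(reads))`.
#'
#' @param reads Character vector of reads or a `read_cluster`.
#' @param engine Alignment engine, see [align_reads()].
#' @param tie_rule Passed to [vote()].
#' @param ... Passed to the aligner.
#' @return The consensus DNA string.
#' @export
decode_cluster <- function(reads, engine = c("auto", "mafft", "fallback"),
                           tie_rule = "deterministic", ...) {
  vote(align_reads(reads, engine = engine, ...), tie_rule = tie_rule)$sequence
}

#' Write a per-column vote table
#'
#' @param call A `consensus_call`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_vote_table <- function(call, path) {
  stopifnot(inherits(call, "consensus_call"))
  tab <- tibble::as_tibble(t(call$votes), .name_repair = "minimal")
  names(tab) <- c("A", "C", "G", "T", "gap")
  tab <- dplyr::mutate(tab,
    column = dplyr::row_number(),
    dropped = .data$column %in% call$dropped_columns,
    .before = 1L
  )
  readr::write_tsv(tab, path)
  invisible(path)
}
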