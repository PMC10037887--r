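#' The uniform IDS error channel
#'
#' Reads are corrupted by insertion-deletion-substitution (IDS) errors placed
#' uniformly at random: scanning the reference left to right, each base
#' independently suffers an error with probability `p`; the error type is
#' drawn from the normalised I:D:S weights. An insertion places one uniformly
#' random base immediately before the current base (which is still emitted);
#' a deletion skips the base; a substitution replaces it with one of the
#' three other bases, uniformly. Inserted bases are never themselves subject
#' to further errors, so the expected number of error events per read is
#' exactly `p * nchar(reference)` and the expected read length is
#' `L * (1 - p * w_D + p * w_I)`.
#'
#' There is no position-dependent error profile, no reverse-complement
#' sampling, no coverage bias and no read dropout: the channel is the
#' idealised uniform model.
#'
#' @name ids_channel
NULL

#' Construct an IDS channel specification
#'
#' @param p Per-base error probability in `[0, 1]`.
#' @param ids Non-negative insertion:deletion:substitution weights; they are
#'   normalised to sum to 1 (so `c(1, 1, 2)` is the 1:1:2 ratio).
#' @return An object of class `channel_spec`.
#' @examples
#' channel_spec(0.08)               # 8% errors, I:D:S = 1:1:1
#' channel_spec(0.1, c(1, 1, 2))    # substitutions twice as likely
#' @export
channel_spec <- function(p, ids = c(1, 1, 1)) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(ids) || length(ids) != 3L || anyNA(ids) || any(ids < 0)) {
    stop("ids must be three non-negative weights (insertion, deletion, substitution)",
         call. = FALSE)
  }
  if (p > 0 && sum(ids) == 0) {
    stop("at least one IDS weight must be positive when p > 0", call. = FALSE)
  }
  w <- if (sum(ids) > 0) ids / sum(ids) else ids
  structure(
    list(p = as.numeric(p), ids_weights = stats::setNames(w, c("I", "D", "S"))),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> p = %g, I:D:S = %s\n", x$p,
              paste(signif(x$ids_weights, 3), collapse = ":")))
  invisible(x)
}

#' Pass one read through the IDS channel
#'
#' Consumes the current RNG stream; experiment drivers seed it per trial via
#' [derive_seed()] so every cluster is reproducible in isolation.
#'
#' @param reference Reference DNA string over `{A,C,G,T}`.
#' @param spec A [channel_spec()].
#' @return The corrupted read (a DNA string; possibly empty at extreme `p`).
#' @examples
#' set.seed(1)
#' corrupt_read("ACGTACGTACGT", channel_spec(0.25))
#' @export
corrupt_read <- function(reference, spec) {
  assert_dna(reference, "reference")
  stopifnot(inherits(spec, "channel_spec"))
  if (spec$p == 0) return(reference)
  out <- chars(reference)
  hit <- which(stats::runif(length(out)) < spec$p)
  if (length(hit) == 0L) return(reference)
  type <- sample.int(3L, length(hit), replace = TRUE, prob = spec$ids_weights)
  sub <- hit[type == 3L]
  if (length(sub)) {
    out[sub] <- SUB_ALT[cbind(sample.int(3L, length(sub), replace = TRUE),
                              match(out[sub], DNA_BASES))]
  }
  ins <- hit[type == 1L]
  if (length(ins)) {
    out[ins] <- paste0(DNA_BASES[sample.int(4L, length(ins), replace = TRUE)], out[ins])
  }
  out[hit[type == 2L]] <- ""
  paste(out, collapse = "")
}

#' Simulate a cluster of independent reads of one oligo
#'
#' @param reference Reference DNA string (one oligo).
#' @param depth Number of independent reads (sequencing depth), >= 1.
#' @param spec A [channel_spec()].
#' @param index_id Optional index id of the reference, kept for bookkeeping.
#' @return An object of class `read_cluster`: list with `reference`,
#'   `true_index_id`, `reads` (character vector of length `depth`),
#'   `is_contaminant` (logical vector), `depth` and `spec`.
#' @export
sample_cluster <- function(reference, depth, spec, index_id = NA_integer_) {
  assert_dna(reference, "reference")
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1) {
    stop("depth must be >= 1", call. = FALSE)
  }
  depth <- as.integer(depth)
  reads <- vapply(seq_len(depth), function(i) corrupt_read(reference, spec), character(1))
  structure(
    list(
      reference = reference, true_index_id = index_id, reads = reads,
      is_contaminant = rep(FALSE, depth), depth = depth, spec = spec
    ),
    class = "read_cluster"
  )
}

#' @export
print.read_cluster <- function(x, ...) {
  cat(sprintf(
    "<read_cluster> depth %d, clustering accuracy %.2f, p = %g (index %s)\n",
    x$depth, clustering_accuracy(x), x$spec$p, as.character(x$true_index_id)
  ))
  invisible(x)
}

#' Fraction of a cluster's reads that come from its own reference
#'
#' @param cluster A `read_cluster`.
#' @return `1 - mean(is_contaminant)`, in `[0, 1]`.
#' @export
clustering_accuracy <- function(cluster) {
  stopifnot(inherits(cluster, "read_cluster"))
  1 - mean(cluster$is_contaminant)
}

#' Replace a fraction of a cluster's reads with reads of other oligos
#'
#' Models imperfect clustering: exactly `round(noise_fraction * depth)` reads
#' (round half up) are replaced by same-channel reads of uniformly chosen
#' donor references, and flagged as contaminants. Cluster depth is unchanged.
#'
#' @param cluster A `read_cluster` from [sample_cluster()].
#' @param noise_fraction Fraction of reads to replace, in `[0, 1)`.
#' @param donors Character vector of donor reference sequences; must not
#'   contain the cluster's own reference.
#' @param spec Channel used to corrupt donor reads (default: the cluster's).
#' @return The contaminated `read_cluster`.
#' @export
contaminate <- function(cluster, noise_fraction, donors, spec = cluster$spec) {
  stopifnot(inherits(cluster, "read_cluster"))
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction >= 1) {
    stop("noise_fraction must be in [0, 1)", call. = FALSE)
  }
  n_rep <- as.integer(round_half_up(noise_fraction * cluster$depth))
  if (n_rep == 0L) return(cluster)
  if (length(donors) == 0L) {
    stop("donor references required when noise_fraction > 0", call. = FALSE)
  }
  if (any(donors == cluster$reference)) {
    stop("donors must exclude the cluster's own reference", call. = FALSE)
  }
  at <- sample.int(cluster$depth, n_rep)
  from <- sample.int(length(donors), n_rep, replace = TRUE)
  cluster$reads[at] <- vapply(seq_len(n_rep), function(k) {
    corrupt_read(donors[from[k]], spec)
  }, character(1))
  cluster$is_contaminant[at] <- TRUE
  cluster
}

#' Write a cluster's reads to FASTA
#'
#' Headers are `cluster_<id>_read_<j>`, with `contaminant` in the description
#' field for reads flagged as contaminants, so clusters round-trip through
#' [decode_clusters()].
#'
#' @param cluster A `read_cluster`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_cluster <- function(cluster, path) {
  stopifnot(inherits(cluster, "read_cluster"))
  cid <- if (is.na(cluster$true_index_id)) "0" else as.character(cluster$true_index_id)
  write_fasta(tibble::tibble(
    id = sprintf("cluster_%s_read_%d", cid, seq_len(cluster$depth)),
    description = ifelse(cluster$is_contaminant, "contaminant", ""),
    sequence = cluster$reads
  ), path)
  invisible(path)
}
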