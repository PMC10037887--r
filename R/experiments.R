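#' Simulation experiment drivers
#'
#' The drivers reproduce the three simulation studies at configurable scale:
#' the recovery-accuracy grid over (error rate, depth), the minimum-depth
#' curves at fixed error rate, the phase-transition scan, and the
#' clustering-robustness study with contaminated clusters. Every trial's RNG
#' substream is derived from the master seed and the trial's coordinates via
#' [derive_seed()], so the whole suite is a pure function of (config, seed,
#' aligner version), cells can be recomputed in isolation, and trials at the
#' same (p, depth, replicate) coincide across drivers.
#'
#' Replicates cycle deterministically through the supplied reference oligos
#' (replicate r uses oligo `(r - 1) %% n_refs + 1`), so a cell with `reps`
#' replicates averages over both replication and reference sequences.
#'
#' @name experiments
NULL

#' @noRd
as_references <- function(references) {
  if (is.data.frame(references)) {
    seqs <- references$sequence
    ids <- references$index_id %||% (seq_along(seqs) - 1L)
  } else {
    seqs <- as.character(references)
    ids <- seq_along(seqs) - 1L
  }
  stopifnot(length(seqs) >= 1L)
  tibble::tibble(index_id = as.integer(ids), sequence = seqs)
}

#' Run one simulate-align-vote trial
#'
#' @param reference Reference DNA string.
#' @param p Channel error rate.
#' @param depth Sequencing depth.
#' @param ids I:D:S weights.
#' @param seed Integer seed for this trial's RNG substream.
#' @param engine Alignment engine, see [align_reads()].
#' @param index_id Bookkeeping id of the reference.
#' @param noise_fraction Fraction of contaminant reads (default 0).
#' @param donors Donor references for contamination.
#' @param tie_rule Consensus tie rule, see [vote()].
#' @return A one-row tibble: trial coordinates plus [score_consensus()]
#'   columns and the consensus itself.
#' @export
run_trial <- function(reference, p, depth, ids = c(1, 1, 1), seed = 1L,
                      engine = "auto", index_id = NA_integer_,
                      noise_fraction = 0, donors = NULL,
                      tie_rule = "deterministic") {
  spec <- channel_spec(p, ids)
  if (engine == "auto") engine <- if (mafft_available()) "mafft" else "fallback"
  cl <- withr::with_seed(seed, {
    x <- sample_cluster(reference, depth, spec, index_id = index_id)
    if (noise_fraction > 0) x <- contaminate(x, noise_fraction, donors, spec) else x
  })
  consensus <- decode_cluster(cl, engine = engine, tie_rule = tie_rule)
  dplyr::bind_cols(
    tibble::tibble(
      index_id = index_id, p = p, depth = as.integer(depth),
      noise_fraction = noise_fraction, seed = as.integer(seed),
      engine = engine
    ),
    score_consensus(consensus, reference, p = p),
    tibble::tibble(consensus = consensus)
  )
}

# one grid cell: reps trials cycling through the references; seed keys do not
# mention the experiment, ids or noise, so matching cells coincide across
# drivers (common random numbers)
#' @noRd
run_cell <- function(refs, p, depth, ids, reps, seed, engine,
                     noise_fraction = 0, tie_rule = "deterministic") {
  purrr::map_dfr(seq_len(reps), function(r) {
    i <- (r - 1L) %% nrow(refs) + 1L
    donors <- if (noise_fraction > 0) refs$sequence[-i] else NULL
    run_trial(
      refs$sequence[i], p, depth, ids,
      seed = derive_seed(seed, "trial", p = p, depth = depth, rep = r),
      engine = engine, index_id = refs$index_id[i],
      noise_fraction = noise_fraction, donors = donors, tie_rule = tie_rule
    ) |>
      dplyr::mutate(replicate = r, .before = 1L)
  })
}

#' @noRd
summarise_cells <- function(trials) {
  trials |>
    dplyr::group_by(.data$p, .data$depth, .data$noise_fraction) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      complete_fraction = mean(.data$complete),
      mean_edit_distance = mean(.data$edit_distance),
      mean_hamming_accuracy = mean(.data$hamming_accuracy),
      mean_errors_corrected = mean(.data$errors_corrected),
      .groups = "drop"
    )
}

# cell column holding the metric a threshold criterion is applied to
#' @noRd
metric_column <- function(metric, p) {
  if (metric == "auto") metric <- if (p > 0) "errors_corrected" else "levenshtein"
  switch(metric,
    errors_corrected = "mean_errors_corrected",
    levenshtein = "mean_accuracy",
    hamming = "mean_hamming_accuracy",
    complete = "complete_fraction",
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Recovery-accuracy grid over error rate and sequencing depth
#'
#' For every (p, depth) cell, simulates `reps` clusters (cycling through the
#' references), aligns, votes and scores. Cells are independent given the
#' master seed; running them in any order or subset yields identical trials.
#'
#' @param references Reference oligos: a character vector of sequences or a
#'   tibble with `index_id` and `sequence` (e.g. [demo_oligos()]).
#' @param p_values Error rates to scan.
#' @param depth_values Sequencing depths to scan.
#' @param ids I:D:S weights (default 1:1:1).
#' @param reps Trials per cell (default 30).
#' @param seed Master seed.
#' @param engine Alignment engine.
#' @param progress Emit a progress message per cell.
#' @return An object of class `recovery_grid` with `trials` (one row per
#'   trial) and `cells` (one row per (p, depth) with means); see
#'   [tidy.recovery_grid()].
#' @export
run_grid <- function(references, p_values, depth_values, ids = c(1, 1, 1),
                     reps = 30L, seed = 1L, engine = "auto", progress = FALSE) {
  refs <- as_references(references)
  stopifnot(length(p_values) >= 1L, length(depth_values) >= 1L, reps >= 1L)
  grid <- tidyr::expand_grid(p = p_values, depth = as.integer(depth_values))
  trials <- purrr::pmap_dfr(grid, function(p, depth) {
    if (progress) message(sprintf("cell p=%g depth=%d", p, depth))
    run_cell(refs, p, depth, ids, reps, seed, engine)
  })
  structure(
    list(
      trials = trials, cells = summarise_cells(trials),
      ids_weights = ids / sum(ids), reps = as.integer(reps),
      seed = as.integer(seed), engine = engine
    ),
    class = "recovery_grid"
  )
}

#' @export
print.recovery_grid <- function(x, ...) {
  cat(sprintf("<recovery_grid> %d cells x %d trials each (I:D:S %s, seed %d)\n",
              nrow(x$cells), x$reps,
              paste(signif(x$ids_weights, 3), collapse = ":"), x$seed))
  print(x$cells, ...)
  invisible(x)
}

#' @rdname run_grid
#' @param x A `recovery_grid`.
#' @param ... Unused.
#' @method tidy recovery_grid
#' @export
tidy.recovery_grid <- function(x, ...) x$cells

#' @rdname run_grid
#' @method glance recovery_grid
#' @export
glance.recovery_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells), n_trials = nrow(x$trials),
    mean_accuracy = mean(x$trials$accuracy),
    complete_fraction = mean(x$trials$complete),
    engine = paste(unique(x$trials$engine), collapse = ","), seed = x$seed
  )
}

#' Minimum sequencing depth to reach recovery thresholds
#'
#' Scans an increasing depth grid at fixed error rate and reports, per
#' threshold, the smallest grid depth meeting the criterion:
#' `complete_fraction == 1` for threshold 1.0 (every replicate exact),
#' otherwise mean `metric` >= threshold. The true depth-accuracy curve is
#' monotone below the phase transition, so by default the cell means are
#' projected onto a non-decreasing curve by isotonic regression
#' ([stats::isoreg()]) before thresholding; raw means on a nearly flat
#' stretch of the curve would otherwise place the crossing erratically
#' under desk-scale replication. `smooth = "none"` thresholds the raw cell
#' means. The exactness criterion for threshold 1.0 is always applied to
#' the raw complete-recovery fractions.
#'
#' With `stop_early = TRUE` the scan stops once all thresholds are
#' resolved; derived seeds make the answer identical either way. Isotonic
#' smoothing needs the whole grid, so `stop_early` is honoured only when
#' every threshold is 1.0 or `smooth = "none"`.
#'
#' @inheritParams run_grid
#' @param p Error rate (single value).
#' @param thresholds Recovery thresholds in `(0, 1]`.
#' @param depth_grid Increasing vector of depths to try.
#' @param metric Cell statistic thresholds apply to: `"auto"` (the
#'   errors-corrected fraction when `p > 0`, else Levenshtein accuracy),
#'   `"errors_corrected"`, `"levenshtein"`, `"hamming"` or `"complete"`.
#' @param stop_early Stop scanning once all thresholds are found (see
#'   Details for the interaction with `smooth`).
#' @param smooth `"isotonic"` (default) to threshold the monotone fit of
#'   the cell means, `"none"` for the raw means.
#' @return An object of class `depth_curve` with `cells` and `thresholds`
#'   (columns `threshold`, `min_depth`; `min_depth` is `NA` when no grid
#'   depth qualifies).
#' @export
min_depth <- function(references, p, thresholds = c(0.90, 0.95, 0.99, 1.00),
                      depth_grid = seq(5L, 100L, by = 5L), ids = c(1, 1, 1),
                      reps = 30L, seed = 1L, engine = "auto", metric = "auto",
                      stop_early = TRUE, smooth = c("isotonic", "none"),
                      progress = FALSE) {
  refs <- as_references(references)
  smooth <- match.arg(smooth)
  stopifnot(length(p) == 1L, all(thresholds > 0), all(thresholds <= 1),
            all(diff(depth_grid) > 0))
  col <- metric_column(metric, p)
  if (smooth == "isotonic" && any(thresholds < 1)) stop_early <- FALSE
  found <- stats::setNames(rep(NA_integer_, length(thresholds)),
                           format(thresholds))
  trials <- list()
  for (depth in as.integer(depth_grid)) {
    if (progress) message("depth ", depth)
    tr <- run_cell(refs, p, depth, ids, reps, seed, engine)
    trials[[as.character(depth)]] <- tr
    cell <- summarise_cells(tr)
    for (k in seq_along(thresholds)) {
      th <- thresholds[k]
      ok <- if (th >= 1) cell$complete_fraction == 1 else cell[[col]] >= th
      if (is.na(found[k]) && isTRUE(ok)) found[k] <- depth
    }
    if (stop_early && !anyNA(found)) break
  }
  trials <- dplyr::bind_rows(trials)
  cells <- summarise_cells(trials)
  if (smooth == "isotonic" && any(thresholds < 1)) {
    fit <- stats::isoreg(cells$depth, cells[[col]])$yf
    for (k in which(thresholds < 1)) {
      hit <- which(fit >= thresholds[k])
      found[k] <- if (length(hit)) cells$depth[min(hit)] else NA_integer_
    }
  }
  structure(
    list(
      cells = cells,
      thresholds = tibble::tibble(threshold = thresholds,
                                  min_depth = unname(found)),
      trials = trials, p = p, metric = metric, metric_column = col,
      smooth = smooth, depth_grid = as.integer(depth_grid),
      reps = as.integer(reps), seed = as.integer(seed),
      ids_weights = ids / sum(ids), engine = engine
    ),
    class = "depth_curve"
  )
}

#' @export
print.depth_curve <- function(x, ...) {
  cat(sprintf("<depth_curve> p = %g, metric = %s, %d trials/cell\n",
              x$p, x$metric_column, x$reps))
  print(x$thresholds, ...)
  invisible(x)
}

#' @rdname min_depth
#' @param x A `depth_curve`.
#' @param ... Unused.
#' @method tidy depth_curve
#' @export
tidy.depth_curve <- function(x, ...) x$thresholds

#' @rdname min_depth
#' @method glance depth_curve
#' @export
glance.depth_curve <- function(x, ...) {
  tibble::tibble(
    p = x$p, metric = x$metric_column, reps = x$reps,
    depths_run = nrow(x$cells), seed = x$seed
  )
}

#' Phase-transition scan: does depth still help?
#'
#' Runs the accuracy grid and, for each error rate, compares the chosen
#' metric at the largest depth with the smallest depth. Depth "helps" at p
#' when the improvement exceeds `margin`; the estimated critical error rate
#' is the largest p at which depth still helps. Below the transition more
#' reads drive recovery toward completeness; above it performance plateaus
#' at a poor level no matter the depth.
#'
#' @inheritParams run_grid
#' @param margin Improvement (top depth minus bottom depth) required to call
#'   "depth helps" (default 0.05).
#' @param metric Cell statistic compared across depths (default
#'   `"errors_corrected"`).
#' @return An object of class `phase_scan` with the underlying
#'   `recovery_grid`, the per-p `indicator` tibble and `critical_p`.
#' @export
phase_scan <- function(references, p_values, depth_values, ids = c(1, 1, 1),
                       reps = 30L, seed = 1L, engine = "auto", margin = 0.05,
                       metric = "errors_corrected", progress = FALSE) {
  stopifnot(length(depth_values) >= 2L)
  grid <- run_grid(references, p_values, depth_values, ids = ids, reps = reps,
                   seed = seed, engine = engine, progress = progress)
  col <- metric_column(metric, p = max(p_values))
  lo <- min(depth_values); hi <- max(depth_values)
  indicator <- grid$cells |>
    dplyr::filter(.data$depth %in% c(lo, hi)) |>
    dplyr::select(dplyr::all_of(c("p", "depth", col))) |>
    tidyr::pivot_wider(names_from = "depth", values_from = dplyr::all_of(col),
                       names_prefix = "metric_at_") |>
    dplyr::mutate(
      improvement = .data[[paste0("metric_at_", hi)]] -
        .data[[paste0("metric_at_", lo)]],
      depth_helps = .data$improvement > margin
    )
  helped <- indicator$p[indicator$depth_helps]
  structure(
    list(
      grid = grid, indicator = indicator,
      critical_p = if (length(helped)) max(helped) else NA_real_,
      margin = margin, metric = metric
    ),
    class = "phase_scan"
  )
}

#' @export
print.phase_scan <- function(x, ...) {
  cat(sprintf("<phase_scan> critical p = %s (margin %g on %s)\n",
              format(x$critical_p), x$margin, x$metric))
  print(x$indicator, ...)
  invisible(x)
}

#' @rdname phase_scan
#' @param x A `phase_scan`.
#' @param ... Unused.
#' @method tidy phase_scan
#' @export
tidy.phase_scan <- function(x, ...) x$indicator

#' @rdname phase_scan
#' @method glance phase_scan
#' @export
glance.phase_scan <- function(x, ...) {
  tibble::tibble(critical_p = x$critical_p, margin = x$margin,
                 metric = x$metric, n_p = nrow(x$indicator))
}

#' Recovery accuracy under imperfect clustering
#'
#' For each (error rate, contaminant fraction), simulates clusters of
#' `cluster_size` reads, replaces the given fraction with same-channel reads
#' of other references, decodes with contaminants included, and scores
#' against the true reference. At `noise_fraction = 0` the trials coincide
#' exactly with [run_grid()] cells at `depth = cluster_size`.
#'
#' @inheritParams run_grid
#' @param cluster_size Reads per cluster (default 100).
#' @param noise_fractions Contaminant fractions in `[0, 1)`
#'   (default 0, 0.2, 0.4, i.e. clustering accuracies 1, 0.8, 0.6).
#' @return A tibble with one row per (p, noise_fraction):
#'   `clustering_accuracy`, `n`, mean metrics, and a `trials` attribute.
#' @export
clustering_robustness <- function(references, p_values, cluster_size = 100L,
                                  noise_fractions = c(0, 0.2, 0.4),
                                  ids = c(1, 1, 1), reps = 30L, seed = 1L,
                                  engine = "auto", progress = FALSE) {
  refs <- as_references(references)
  if (nrow(refs) < 2L && any(noise_fractions > 0)) {
    stop("contamination needs at least two references", call. = FALSE)
  }
  stopifnot(all(noise_fractions >= 0), all(noise_fractions < 1))
  grid <- tidyr::expand_grid(p = p_values, noise_fraction = noise_fractions)
  trials <- purrr::pmap_dfr(grid, function(p, noise_fraction) {
    if (progress) message(sprintf("p=%g noise=%g", p, noise_fraction))
    run_cell(refs, p, cluster_size, ids, reps, seed, engine,
             noise_fraction = noise_fraction)
  })
  out <- summarise_cells(trials) |>
    dplyr::mutate(clustering_accuracy = 1 - .data$noise_fraction,
                  .after = "noise_fraction") |>
    dplyr::select(-"depth")
  attr(out, "trials") <- trials
  out
}

#' Decode clusters of reads from FASTA files
#'
#' The generic decode path for externally clustered reads: either a
#' directory of per-cluster FASTA files (cluster id = file name without
#' extension) or a single combined FASTA whose record ids follow
#' `cluster_<id>_read_<j>`. Each cluster is subsampled to its first
#' `depth_cap` reads (input order), aligned and voted.
#'
#' @param path Directory of FASTA files, or one combined FASTA file.
#' @param references Optional reference sequences, a named character vector
#'   or tibble with `id`/`sequence` (names matching cluster ids); when
#'   given, consensus sequences are scored.
#' @param depth_cap Maximum reads used per cluster (default all).
#' @param engine Alignment engine.
#' @param tie_rule Consensus tie rule.
#' @return A tibble with one row per cluster: `cluster`, `depth_used`,
#'   `consensus`, and -- when references are given -- `edit_distance`,
#'   `accuracy`, `normalized_hamming`, `hamming_accuracy` and `complete`.
#' @export
decode_clusters <- function(path, references = NULL, depth_cap = Inf,
                            engine = "auto", tie_rule = "deterministic") {
  clusters <- load_clusters(path)
  if (!is.null(references)) {
    if (is.data.frame(references)) {
      references <- stats::setNames(references$sequence,
                                    references$id %||% references$index_id)
    }
    references <- stats::setNames(as.character(references), names(references))
  }
  purrr::imap_dfr(clusters, function(reads, cid) {
    use <- utils::head(reads, depth_cap)
    consensus <- decode_cluster(use, engine = engine, tie_rule = tie_rule)
    row <- tibble::tibble(cluster = cid, depth_used = length(use),
                          consensus = consensus)
    if (!is.null(references)) {
      ref <- if (cid %in% names(references)) references[[cid]] else NULL
      if (is.null(ref)) {
        stop("no reference for cluster '", cid, "'", call. = FALSE)
      }
      row <- dplyr::bind_cols(
        row, dplyr::select(score_consensus(consensus, ref), -"errors_corrected")
      )
    }
    row
  })
}

#' @noRd
load_clusters <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files in ", path, call. = FALSE)
    recs <- lapply(files, function(f) {
      r <- tryCatch(read_fasta(f), error = function(e) {
        stop("failed to parse cluster file '", f, "': ", conditionMessage(e),
             call. = FALSE)
      })
      r$sequence
    })
    names(recs) <- tools::file_path_sans_ext(basename(files))
    return(recs)
  }
  recs <- read_fasta(path)
  m <- regmatches(recs$id, regexec("^cluster_(.+)_read_[0-9]+$", recs$id))
  cid <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                character(1))
  if (anyNA(cid)) {
    stop("combined FASTA ids must look like cluster_<id>_read_<j>; offending: ",
         recs$id[which(is.na(cid))[1]], call. = FALSE)
  }
  split(recs$sequence, factor(cid, levels = unique(cid)))
}

#' Write per-trial records as TSV
#'
#' Fixed, documented column order so identical runs produce byte-identical
#' files: `replicate`, `index_id`, `p`, `depth`, `noise_fraction`, `seed`,
#' `engine`, `edit_distance`, `accuracy`, `normalized_hamming`,
#' `hamming_accuracy`, `errors_corrected`, `complete`, `consensus`.
#'
#' @param x A `recovery_grid`, `depth_curve`, or a trials tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trials_tsv <- function(x, path) {
  trials <- if (is.data.frame(x)) x else x$trials
  cols <- c("replicate", "index_id", "p", "depth", "noise_fraction", "seed",
            "engine", "edit_distance", "accuracy", "normalized_hamming",
            "hamming_accuracy", "errors_corrected", "complete", "consensus")
  readr::write_tsv(dplyr::select(trials, dplyr::all_of(cols)), path)
  invisible(path)
}
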