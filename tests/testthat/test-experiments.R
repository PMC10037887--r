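# experiment-driver tests run on the fallback engine at toy scale; the
# MAFFT-based quantitative checks live in test-acceptance.R

refs4 <- demo_oligos(4)

test_that("derived seeds are deterministic, distinct and 32-bit safe", {
  a <- derive_seed(42, "trial", p = 0.1, depth = 30, rep = 1)
  expect_identical(a, derive_seed(42, "trial", p = 0.1, depth = 30, rep = 1))
  others <- c(
    derive_seed(42, "trial", p = 0.1, depth = 30, rep = 2),
    derive_seed(42, "trial", p = 0.1, depth = 35, rep = 1),
    derive_seed(42, "trial", p = 0.2, depth = 30, rep = 1),
    derive_seed(43, "trial", p = 0.1, depth = 30, rep = 1)
  )
  expect_false(a %in% others)
  expect_length(unique(others), 4L)
  expect_true(all(c(a, others) >= 0 & c(a, others) < 2^31))
  # numeric formatting does not split streams
  expect_identical(derive_seed(1, p = 0.1), derive_seed(1, p = 0.10))
})

test_that("a noiseless grid recovers everything at every depth", {
  grid <- run_grid(refs4, p_values = 0, depth_values = c(1, 3, 5),
                   reps = 4, seed = 11, engine = "fallback")
  expect_true(all(grid$cells$mean_accuracy == 1))
  expect_true(all(grid$cells$complete_fraction == 1))
  expect_true(all(grid$cells$mean_edit_distance == 0))
  expect_true(all(is.na(grid$cells$mean_errors_corrected)))
  expect_equal(nrow(grid$trials), 3 * 4)
  expect_true(all(grid$cells$n == 4))
})

test_that("grids are reproducible and serialise byte-identically", {
  g1 <- run_grid(refs4, c(0.05, 0.1), c(3, 6), reps = 5, seed = 7,
                 engine = "fallback")
  g2 <- run_grid(refs4, c(0.05, 0.1), c(3, 6), reps = 5, seed = 7,
                 engine = "fallback")
  expect_identical(g1$trials, g2$trials)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_trials_tsv(g1, t1); write_trials_tsv(g2, t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
  g3 <- run_grid(refs4, c(0.05, 0.1), c(3, 6), reps = 5, seed = 8,
                 engine = "fallback")
  expect_false(identical(g1$trials$consensus, g3$trials$consensus))
})

test_that("tidy/glance/autoplot methods expose grid results", {
  grid <- run_grid(refs4, 0.05, c(2, 4), reps = 3, seed = 3, engine = "fallback")
  expect_identical(tidy(grid), grid$cells)
  gl <- glance(grid)
  expect_equal(gl$n_trials, 6L)
  expect_identical(gl$engine, "fallback")
  expect_s3_class(autoplot(grid), "ggplot")
})

test_that("min_depth finds the smallest qualifying depth", {
  # p = 0: every depth qualifies, so the answer is the smallest grid depth
  dc <- min_depth(refs4, p = 0, thresholds = c(0.9, 1), depth_grid = c(2, 4, 8),
                  reps = 3, seed = 5, engine = "fallback")
  expect_equal(dc$thresholds$min_depth, c(2L, 2L))
  expect_s3_class(autoplot(dc), "ggplot")
  expect_identical(tidy(dc), dc$thresholds)
})

test_that("early stopping does not change min_depth answers", {
  args <- list(refs4, p = 0.08, thresholds = c(0.5, 0.9),
               depth_grid = c(2, 5, 9, 14), reps = 6, seed = 9,
               engine = "fallback", smooth = "none")
  lazy <- do.call(min_depth, c(args, stop_early = TRUE))
  full <- do.call(min_depth, c(args, stop_early = FALSE))
  expect_identical(lazy$thresholds, full$thresholds)
  # full scan evaluated every grid depth, the lazy one at most as many
  expect_lte(nrow(lazy$cells), nrow(full$cells))
  # thresholds are consistent: higher thresholds never need less depth
  found <- full$thresholds$min_depth
  expect_true(all(diff(found) >= 0 | is.na(diff(found))))
})

test_that("isotonic thresholding keeps min_depth monotone in the threshold", {
  dc <- min_depth(refs4, p = 0.1, thresholds = c(0.3, 0.6, 0.9),
                  depth_grid = c(2, 4, 6, 10), reps = 5, seed = 21,
                  engine = "fallback")
  found <- dc$thresholds$min_depth
  expect_true(all(diff(found) >= 0, na.rm = TRUE))
  # the smoothed curve is non-decreasing by construction
  fit <- stats::isoreg(dc$cells$depth, dc$cells[[dc$metric_column]])$yf
  expect_true(all(diff(fit) >= 0))
  # and smoothing ran the full grid
  expect_equal(nrow(dc$cells), 4L)
})

test_that("fallback pipeline recovers reliably in the easy regime", {
  cell <- oligovote:::run_cell(demo_oligos(10), p = 0.05, depth = 10,
                               ids = c(1, 1, 1), reps = 20, seed = 31,
                               engine = "fallback")
  expect_gte(mean(cell$complete), 0.9)
})

test_that("contaminated cells at zero noise coincide with clean grid cells", {
  rob <- clustering_robustness(refs4, p_values = 0.1, cluster_size = 8,
                               noise_fractions = c(0, 0.25), reps = 6,
                               seed = 13, engine = "fallback")
  grid <- run_grid(refs4, 0.1, 8, reps = 6, seed = 13, engine = "fallback")
  clean <- dplyr::filter(rob, noise_fraction == 0)
  expect_equal(clean$mean_accuracy, grid$cells$mean_accuracy)
  expect_equal(clean$complete_fraction, grid$cells$complete_fraction)
  expect_equal(clean$clustering_accuracy, 1)
  dirty_trials <- attr(rob, "trials")
  expect_equal(unique(dirty_trials$depth), 8L)
})

test_that("phase scan flags depth-sensitive error rates", {
  ps <- phase_scan(refs4, p_values = c(0.05, 0.1), depth_values = c(2, 12),
                   reps = 8, seed = 17, engine = "fallback")
  expect_s3_class(ps, "phase_scan")
  expect_equal(nrow(ps$indicator), 2L)
  expect_true(all(c("improvement", "depth_helps") %in% names(ps$indicator)))
  expect_identical(tidy(ps), ps$indicator)
  expect_s3_class(autoplot(ps), "ggplot")
  gl <- glance(ps)
  expect_true(is.na(gl$critical_p) || gl$critical_p %in% c(0.05, 0.1))
})

test_that("decode_clusters handles directories, combined files and caps", {
  refs <- demo_oligos(3)
  dir <- withr::local_tempdir()
  clusters <- lapply(1:3, function(i) {
    withr::with_seed(40 + i, {
      sample_cluster(refs$sequence[i], 6, channel_spec(0.05),
                     index_id = refs$index_id[i])
    })
  })
  for (i in 1:3) {
    write_cluster(clusters[[i]], file.path(dir, sprintf("c%02d.fasta", i)))
  }
  named_refs <- stats::setNames(refs$sequence, sprintf("c%02d", 1:3))
  out <- decode_clusters(dir, references = named_refs, engine = "fallback")
  expect_equal(nrow(out), 3L)
  expect_equal(out$depth_used, rep(6L, 3))
  # scores match the metrics module applied by hand
  for (i in 1:3) {
    expect_equal(out$accuracy[i],
                 recovery_accuracy(out$consensus[i], refs$sequence[i]))
  }

  # combined single-file form, capped at depth 1: consensus = first read
  comb <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(tibble::tibble(
    id = unlist(lapply(1:3, function(i) sprintf("cluster_%d_read_%d", i, 1:6))),
    sequence = unlist(lapply(clusters, `[[`, "reads"))
  ), comb)
  capped <- decode_clusters(comb, depth_cap = 1, engine = "fallback")
  expect_equal(capped$consensus,
               vapply(clusters, function(cl) cl$reads[1], character(1)))

  # ragged read lengths still decode
  ragged <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(tibble::tibble(
    id = sprintf("cluster_x_read_%d", 1:4),
    sequence = c("ACGTACGTACGT", "ACG", "ACGTACGTACGTACGTACGT", "A")
  ), ragged)
  expect_no_error(decode_clusters(ragged, engine = "fallback"))

  # missing reference is an error naming the cluster
  expect_error(decode_clusters(dir, references = named_refs[1:2],
                               engine = "fallback"), "c03")
})
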