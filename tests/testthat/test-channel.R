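test_that("channel_spec validates and normalises", {
  spec <- channel_spec(0.1, c(1, 1, 2))
  expect_equal(sum(spec$ids_weights), 1)
  expect_equal(unname(spec$ids_weights), c(0.25, 0.25, 0.5))
  expect_error(channel_spec(-0.1), "in \\[0, 1\\]")
  expect_error(channel_spec(1.5), "in \\[0, 1\\]")
  expect_error(channel_spec(0.1, c(0, 0, 0)), "positive")
  expect_error(channel_spec(0.1, c(1, -1, 1)), "non-negative")
})

test_that("the noiseless channel is the identity for any seed", {
  spec <- channel_spec(0)
  for (seed in c(1, 99, 2024)) {
    set.seed(seed)
    ref <- random_dna(sample(10:200, 1))
    expect_identical(corrupt_read(ref, spec), ref)
  }
})

test_that("single-type channels realise rate p in the observable statistic", {
  set.seed(42)
  ref <- random_dna(120)
  n <- 8000
  # deletion-only: E[length] = L(1 - p)
  del <- vapply(seq_len(n), function(i) {
    nchar(corrupt_read(ref, channel_spec(0.1, c(0, 1, 0))))
  }, numeric(1))
  expect_equal(mean(del), 108, tolerance = 0.15 / 108)
  # insertion-only: E[length] = L(1 + p)
  ins <- vapply(seq_len(n), function(i) {
    nchar(corrupt_read(ref, channel_spec(0.1, c(1, 0, 0))))
  }, numeric(1))
  expect_equal(mean(ins), 132, tolerance = 0.15 / 132)
  # substitution-only preserves length and mismatches at rate p exactly
  refc <- strsplit(ref, "")[[1]]
  sub <- vapply(seq_len(n), function(i) {
    out <- corrupt_read(ref, channel_spec(0.1, c(0, 0, 1)))
    expect_equal(nchar(out), 120)
    sum(strsplit(out, "")[[1]] != refc)
  }, numeric(1))
  expect_equal(mean(sub), 12, tolerance = 0.15 / 12)
})

test_that("mean read length follows L(1 - p*wD + p*wI) across a weight grid", {
  set.seed(9)
  ref <- random_dna(120)
  cases <- list(
    list(p = 0.05, w = c(1, 1, 1)), list(p = 0.2, w = c(1, 1, 2)),
    list(p = 0.3, w = c(2, 1, 1)), list(p = 0.15, w = c(0, 2, 1))
  )
  for (cs in cases) {
    w <- cs$w / sum(cs$w)
    expected <- 120 * (1 - cs$p * w[2] + cs$p * w[1])
    lens <- vapply(seq_len(4000), function(i) {
      nchar(corrupt_read(ref, channel_spec(cs$p, cs$w)))
    }, numeric(1))
    expect_equal(mean(lens), expected, tolerance = 0.012)
  }
})

test_that("balanced 1:1:1 errors keep length and land near p*L edit distance", {
  set.seed(5)
  ref <- random_dna(120)
  reads <- vapply(seq_len(3000), function(i) {
    corrupt_read(ref, channel_spec(0.1))
  }, character(1))
  expect_equal(mean(nchar(reads)), 120, tolerance = 0.002)
  dists <- as.integer(utils::adist(ref, reads))
  # realised Levenshtein can merge adjacent events, so sits just below p*L
  expect_gt(mean(dists), 11)
  expect_lte(mean(dists), 12.2)
})

test_that("sample_cluster draws independent reads and is seed-reproducible", {
  ref <- random_dna(120)
  spec <- channel_spec(0.12)
  a <- withr::with_seed(33, sample_cluster(ref, 50, spec, index_id = 3L))
  b <- withr::with_seed(33, sample_cluster(ref, 50, spec, index_id = 3L))
  expect_identical(a$reads, b$reads)
  expect_equal(a$depth, 50L)
  expect_false(any(a$is_contaminant))
  expect_equal(clustering_accuracy(a), 1)
  # mean per-read distance ~ p * L
  d <- as.integer(utils::adist(ref, a$reads))
  expect_gt(mean(d), 10)
  expect_lt(mean(d), 18)
  noiseless <- withr::with_seed(1, sample_cluster(ref, 5, channel_spec(0)))
  expect_identical(noiseless$reads, rep(ref, 5))
  expect_error(sample_cluster(ref, 0, spec), "depth")
})

test_that("contaminate replaces the documented number of reads", {
  refs <- withr::with_seed(8, replicate(5, random_dna(120)))
  spec <- channel_spec(0.1)
  cl <- withr::with_seed(2, sample_cluster(refs[1], 100, spec))
  for (frac in c(0.2, 0.4)) {
    dirty <- withr::with_seed(3, contaminate(cl, frac, refs[-1]))
    expect_equal(sum(dirty$is_contaminant), as.integer(100 * frac))
    expect_equal(clustering_accuracy(dirty), 1 - frac)
    expect_equal(dirty$depth, 100L)
    expect_length(dirty$reads, 100L)
    # untouched reads keep their identity
    expect_identical(dirty$reads[!dirty$is_contaminant],
                     cl$reads[!dirty$is_contaminant])
  }
  expect_identical(contaminate(cl, 0, refs[-1]), cl)
  expect_error(contaminate(cl, 1, refs[-1]), "noise_fraction")
  expect_error(contaminate(cl, 0.2, character(0)), "donor")
  expect_error(contaminate(cl, 0.2, refs), "own reference")
  # half-up rounding of the contaminant count
  small <- withr::with_seed(4, sample_cluster(refs[1], 5, spec))
  expect_equal(sum(withr::with_seed(5, contaminate(small, 0.3, refs[-1]))$is_contaminant),
               2L) # 1.5 rounds up
})

test_that("clusters round-trip through FASTA with contaminant flags", {
  refs <- withr::with_seed(21, replicate(3, random_dna(60)))
  cl <- withr::with_seed(22, {
    contaminate(sample_cluster(refs[1], 10, channel_spec(0.05), index_id = 7L),
                0.2, refs[-1])
  })
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_cluster(cl, fa)
  back <- read_fasta(fa)
  expect_equal(nrow(back), 10L)
  expect_identical(back$sequence, cl$reads)
  expect_identical(grepl("contaminant", back$description), cl$is_contaminant)
})
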