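test_that("frameshift calls follow net length change mod 3", {
  expect_false(is_frameshift(list(kind = "deletion", length = 3L)))
  expect_true(is_frameshift(list(kind = "insertion", length = 1L)))
  expect_true(is_frameshift(list(kind = "deletion", length = 7L)))
  expect_false(is_frameshift(list(kind = "wildtype", length = 0L)))

  # brute-force mod table over random distributions
  for (seed in 1:10) {
    d <- rand_mutant_dist(seed, n_del = 8L, n_ins = 2L)
    expected <- vapply(seq_len(nrow(d)), function(i) {
      net <- if (d$kind[i] == "deletion") -d$length[i] else d$length[i]
      r <- net
      while (r < 0) r <- r + 3L
      (r %% 3L) != 0L
    }, logical(1))
    expect_identical(is_frameshift(d), expected)
  }
})

test_that("cumulative frameshift frequency sums the frameshifting mass", {
  d <- outcome_dist(c("insertion", "deletion"), c(1L, 3L), c(0.5, 0.5),
                    del_start = c(NA, -1L), ins_bases = c("A", NA))
  expect_equal(cumulative_frameshift(d), 0.5)
  d1 <- outcome_dist("insertion", 1L, 1.0, ins_bases = "G")
  expect_equal(cumulative_frameshift(d1), 1.0)

  # loop oracle on random 10-entry distributions; also equals 1 - in-frame
  for (seed in 11:20) {
    d <- rand_mutant_dist(seed)
    oracle <- 0
    for (i in seq_len(nrow(d))) {
      net <- if (d$kind[i] == "deletion") -d$length[i] else d$length[i]
      if (net %% 3L != 0L) oracle <- oracle + d$frequency[i]
    }
    expect_equal(cumulative_frameshift(d), oracle)
    inframe <- sum(d$frequency[!is_frameshift(d)])
    expect_equal(cumulative_frameshift(d), 1 - inframe)
  }
})

test_that("cumulative frameshift rejects unnormalized or wildtype input", {
  bad <- outcome_dist(c("insertion", "deletion"), c(1L, 2L), c(0.5, 0.3),
                      del_start = c(NA, 0L), ins_bases = c("A", NA))
  expect_error(cumulative_frameshift(bad), "not normalized")
  wt <- outcome_dist(c("wildtype", "insertion"), c(0L, 1L), c(0.5, 0.5),
                     ins_bases = c(NA, "A"))
  expect_error(cumulative_frameshift(wt), "wildtype")
})

test_that("knockout score is the squared frameshift frequency", {
  expect_equal(ko_score(0.80), 0.64)
  expect_equal(ko_score(0), 0)
  expect_equal(ko_score(1), 1)
  expect_equal(ko_score(0.5), 0.25)
  expect_error(ko_score(1.2), "\\[0, 1\\]")
  expect_error(ko_score(-0.1), "\\[0, 1\\]")
  # monotone and bounded by its argument
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(ko_score(f)) >= 0))
  expect_true(all(ko_score(f) <= f))
})

test_that("observed-table normalization drops wildtype and long insertions", {
  raw <- outcome_dist(c("wildtype", "insertion", "deletion"),
                      c(0L, 1L, 2L), c(0.8, 0.1, 0.1),
                      del_start = c(NA, NA, 0L),
                      ins_bases = c(NA, "A", NA), source = "observed")
  n <- normalize_observed(raw)
  expect_equal(sort(n$frequency), c(0.5, 0.5))
  expect_equal(sum(n$frequency), 1, tolerance = 1e-12)

  already <- outcome_dist("insertion", 1L, 1.0, ins_bases = "A")
  expect_equal(normalize_observed(already)$frequency, 1.0)

  long_ins <- outcome_dist(c("insertion", "insertion", "deletion"),
                           c(1L, 4L, 3L), c(0.2, 0.3, 0.5),
                           del_start = c(NA, NA, -1L),
                           ins_bases = c("A", "ACGT", NA))
  n2 <- normalize_observed(long_ins)
  expect_false(any(n2$kind == "insertion" & n2$length > 1L))
  expect_equal(sum(n2$frequency), 1, tolerance = 1e-12)

  only_wt <- outcome_dist("wildtype", 0L, 1.0)
  expect_error(normalize_observed(only_wt), "no editable signal")
})

test_that("99%-cumulative curation determines the maximal deletion length", {
  # reference: +1 insertions plus deletions of length <= 9 carry 0.992;
  # a 12-bp deletion in the distribution must be dropped at L* = 9
  ref <- outcome_dist(
    kind = c("insertion", rep("deletion", 10L)),
    length = c(1L, 1:9, 12L),
    frequency = c(0.30, rep(0.692 / 9, 9), 0.008),
    del_start = c(NA, rep(0L, 10L)), ins_bases = c("A", rep(NA, 10L)))
  expect_identical(curation_max_deletion(ref), 9L)

  dist <- outcome_dist(
    kind = c("insertion", "deletion", "deletion"),
    length = c(1L, 4L, 12L), frequency = c(0.5, 0.3, 0.2),
    del_start = c(NA, 0L, 0L), ins_bases = c("A", NA, NA))
  cur <- curate_to_reference_classes(dist, ref)
  expect_false(any(cur$length == 12L))
  expect_equal(sum(cur$frequency), 1, tolerance = 1e-12)

  # self-curation renormalizes over retained classes
  self <- curate_to_reference_classes(ref, ref)
  expect_true(all(self$length <= 9L | self$kind == "insertion"))
  expect_equal(sum(self$frequency), 1, tolerance = 1e-12)

  # +1-insertion-only distribution passes through unchanged
  ins_only <- outcome_dist(c("insertion", "insertion"), c(1L, 1L),
                           c(0.6, 0.4), ins_bases = c("A", "G"))
  expect_equal(curate_to_reference_classes(ins_only, ref)$frequency,
               c(0.6, 0.4))

  thin <- outcome_dist("deletion", 1L, 0.5, del_start = 0L)
  expect_error(curation_max_deletion(thin), "mass")
})

test_that("curation L* matches a brute-force cumulative scan", {
  for (seed in 1:100) {
    ref <- rand_mutant_dist(seed, n_del = 10L, n_ins = 2L)
    expect_identical(curation_max_deletion(ref), oracle_lstar(ref),
                     info = paste("seed", seed))
  }
})

test_that("curation never increases the number of distinct outcomes", {
  for (seed in 30:40) {
    d <- rand_mutant_dist(seed)
    cur <- curate_to_reference_classes(d, d)
    expect_lte(nrow(cur), nrow(d))
    expect_equal(sum(cur$frequency), 1, tolerance = 1e-9)
  }
})

test_that("outcome matching zero-fills over the key union", {
  a <- outcome_dist(c("insertion", "deletion"), c(1L, 2L), c(0.7, 0.3),
                    del_start = c(NA, 0L), ins_bases = c("A", NA),
                    guide_id = "g1")
  m <- match_outcomes(a, a)
  expect_identical(m$pred, m$obs)

  b <- outcome_dist(c("deletion", "deletion", "deletion"),
                    c(3L, 5L, 7L), c(0.2, 0.3, 0.5),
                    del_start = c(0L, -1L, -2L), guide_id = "g1")
  m2 <- match_outcomes(a, b)
  expect_length(m2$keys, 5L)
  expect_equal(sum(m2$pred > 0), 2L)
  expect_equal(sum(m2$obs > 0), 3L)

  # dictionary-merge oracle on random pairs
  for (seed in 1:10) {
    p <- rand_mutant_dist(seed, guide_id = "g")
    o <- rand_mutant_dist(seed + 100L, guide_id = "g")
    m3 <- match_outcomes(p, o)
    dict <- new.env()
    for (i in seq_len(nrow(p)))
      assign(p$genotype_key[i], c(p$frequency[i], 0), dict)
    for (i in seq_len(nrow(o))) {
      cur <- if (exists(o$genotype_key[i], dict))
        get(o$genotype_key[i], dict) else c(0, 0)
      assign(o$genotype_key[i], c(cur[1], o$frequency[i]), dict)
    }
    keys <- sort(ls(dict))
    expect_identical(m3$keys, keys)
    vals <- vapply(keys, get, numeric(2), envir = dict)
    expect_equal(m3$pred, unname(vals[1, ]))
    expect_equal(m3$obs, unname(vals[2, ]))
  }

  c_other <- outcome_dist("insertion", 1L, 1, ins_bases = "A",
                          guide_id = "g2")
  expect_error(match_outcomes(a, c_other), "guide_id mismatch")
})

test_that("microhomology-shifted deletion representations collapse to one key", {
  # context ...ACGTACGT|ACGTAA...: deleting ACGT starting at -4 or at 0
  # yields the same edited sequence
  ctx <- paste0(strrep("T", 16), "ACGTACGT", "ACGTAA", strrep("T", 10))
  cut <- 24L
  d <- outcome_dist(kind = c("deletion", "deletion"),
                    length = c(4L, 4L), frequency = c(0.4, 0.6),
                    del_start = c(-4L, 0L),
                    context = ctx, cut = cut)
  expect_identical(nrow(d), 1L)
  expect_equal(d$frequency, 1.0)
  # and the canonical form is the left-aligned one
  expect_identical(d$del_start, left_align_deletion(ctx, cut, 0L, 4L))
})

test_that("outcome tables round-trip through CSV bit-exactly", {
  d1 <- rand_mutant_dist(7, guide_id = "gA")
  d2 <- rand_mutant_dist(8, guide_id = "gB")
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcome_table(list(d1, d2), path)
  back <- read_outcome_table(path)
  expect_identical(names(back), c("gA", "gB"))
  expect_identical(back$gA$frequency, d1$frequency)
  expect_identical(back$gA$genotype_key, d1$genotype_key)
  expect_identical(back$gB$frequency, d2$frequency)
})
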