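test_that("target scanning matches exhaustive sliding-window enumeration", {
  # no GG or CC dinucleotide anywhere: no PAM on either strand
  no_pam <- setNames(paste(rep("AT", 60), collapse = ""), "flat")
  expect_identical(nrow(scan_targets(no_pam, t7_filter = FALSE)), 0L)

  for (seed in 1:30) {
    seq <- rand_seq(sample(80:220, 1), seed = 700 + seed)
    tg <- scan_targets(setNames(seq, "g"), t7_filter = FALSE)
    oracle <- oracle_scan(seq)
    expect_identical(nrow(tg), length(oracle), info = paste("seed", seed))
    if (length(oracle)) {
      key_impl <- sort(paste(tg$protospacer, tg$strand, tg$cut_pos))
      key_or <- sort(vapply(oracle, function(h)
        paste(h$proto, h$strand, h$cut_fwd), character(1)))
      expect_identical(key_impl, key_or)
    }
  }
})

test_that("scanned context windows have the documented geometry", {
  seq <- rand_seq(200, seed = 90)
  tg <- scan_targets(setNames(seq, "g"), t7_filter = FALSE)
  expect_gt(nrow(tg), 0)
  expect_true(all(nchar(tg$context80) == 80L))
  expect_true(all(nchar(tg$context65) == 65L))
  expect_true(all(nchar(tg$context35) == 35L))
  for (i in seq_len(nrow(tg))) {
    # protospacer+PAM sit at positions 7..29 of the 35-nt window
    expect_identical(substr(tg$context35[i], 7L, 26L), tg$protospacer[i])
    expect_identical(substr(tg$context35[i], 27L, 29L), tg$pam[i])
    expect_true(grepl("^[ACGT]GG$", tg$pam[i]))
    # the 80-nt window is centred on the cut: its first 40 nt end at the
    # cut, which sits 3 bp 5' of the PAM (between protospacer 17 and 18)
    expect_identical(substr(tg$context80[i], 24L, 40L),
                     substr(tg$protospacer[i], 1L, 17L))
    expect_identical(substr(tg$context80[i], 41L, 43L),
                     substr(tg$protospacer[i], 18L, 20L))
    # 65-nt window: 30 nt upstream of the cut, 35 downstream
    expect_identical(substr(tg$context65[i], 1L, 30L),
                     substr(tg$context80[i], 11L, 40L))
    expect_identical(substr(tg$context65[i], 31L, 65L),
                     substr(tg$context80[i], 41L, 75L))
  }
})

test_that("T7 filtering retains a subset of GG-start protospacers", {
  seq <- rand_seq(400, seed = 13)
  all_tg <- scan_targets(setNames(seq, "g"), t7_filter = FALSE)
  t7 <- scan_targets(setNames(seq, "g"), t7_filter = TRUE)
  expect_true(all(t7$guide_id %in% all_tg$guide_id))
  expect_true(all(substr(t7$protospacer, 1, 2) == "GG"))
  ga <- scan_targets(setNames(seq, "g"), t7_filter = TRUE,
                     t7_allow_ga = TRUE)
  expect_true(all(substr(ga$protospacer, 1, 2) %in% c("GG", "GA")))
  expect_true(all(t7$guide_id %in% ga$guide_id))
})

test_that("records with ambiguous bases are skipped with a warning", {
  seqs <- c(good = rand_seq(150, 2), bad = paste0(rand_seq(100, 3), "N"))
  expect_warning(tg <- scan_targets(seqs, t7_filter = FALSE), "non-ACGT")
  expect_true(all(tg$gene_id == "good"))
})

test_that("guide scoring wires predictor output into the score panel", {
  seq <- rand_seq(200, seed = 21)
  tg <- scan_targets(setNames(seq, "g"), t7_filter = FALSE)[1:3, ]
  model <- rand_activity_model(5)

  ins_only <- function(ctx, id)
    outcome_dist(c("insertion", "insertion"), c(1L, 1L), c(0.5, 0.5),
                 ins_bases = c("A", "G"), mh = 0, guide_id = id)
  sc <- score_guides(tg, model, predictor = ins_only)
  expect_equal(sc$frameshift_freq, rep(1, 3))
  expect_equal(sc$ko_score, rep(100, 3))
  expect_equal(sc$mmej, rep(0, 3))

  inframe_only <- function(ctx, id)
    outcome_dist(c("deletion", "deletion"), c(3L, 6L), c(0.5, 0.5),
                 del_start = c(0L, 0L), mh = c(3, 3), guide_id = id)
  sc2 <- score_guides(tg, model, predictor = inframe_only)
  expect_equal(sc2$frameshift_freq, rep(0, 3))
  expect_equal(sc2$ko_score, rep(0, 3))

  fixed_fs <- function(ctx, id)
    outcome_dist(c("insertion", "deletion"), c(1L, 3L), c(0.8, 0.2),
                 del_start = c(NA, 0L), ins_bases = c("A", NA), mh = 0,
                 guide_id = id)
  sc3 <- score_guides(tg[1, ], model, predictor = fixed_fs)
  expect_equal(sc3$ko_score, 64)

  failing <- function(ctx, id) stop("boom")
  expect_error(score_guides(tg, model, predictor = failing),
               "predictor failed for guide")

  # the knockout score never exceeds 100 * frameshift frequency
  sc4 <- score_guides(scan_targets(setNames(seq, "g"),
                                   t7_filter = FALSE)[1:8, ], model)
  expect_true(all(sc4$ko_score <= 100 * sc4$frameshift_freq + 1e-9))
})

test_that("per-gene classification flags one highest and one lowest guide", {
  base <- data.frame(gene_id = "g1", guide_id = paste0("u", 1:3),
                     cut_pos = c(50L, 60L, 70L), strand = "+",
                     activity = c(40, 50, 60),
                     ko_score = c(90, 50, 10), stringsAsFactors = FALSE)
  cl <- classify_per_gene(base)
  expect_identical(cl$guide_id[cl$highest_in_class], "u1")
  expect_identical(cl$guide_id[cl$lowest_in_class], "u3")

  # all-equal knockout scores: tie broken by activity, deterministically
  tie <- base
  tie$ko_score <- 50
  cl2 <- classify_per_gene(tie)
  expect_identical(cl2$guide_id[cl2$highest_in_class], "u3")
  expect_identical(cl2$guide_id[cl2$lowest_in_class], "u3")

  # single-guide gene carries both flags
  single <- base[1, ]
  cl3 <- classify_per_gene(single)
  expect_true(cl3$highest_in_class && cl3$lowest_in_class)

  # argmax/argmin oracle on a random 20-guide gene, stable to permutation
  set.seed(8)
  g <- data.frame(gene_id = "gX", guide_id = paste0("v", 1:20),
                  cut_pos = sample(1000L, 20L), strand = "+",
                  activity = runif(20, 0, 100),
                  ko_score = round(runif(20, 0, 100), 3),
                  stringsAsFactors = FALSE)
  cl4 <- classify_per_gene(g)
  expect_identical(cl4$guide_id[cl4$highest_in_class],
                   g$guide_id[which.max(g$ko_score)])
  expect_identical(cl4$guide_id[cl4$lowest_in_class],
                   g$guide_id[which.min(g$ko_score)])
  perm <- g[sample.int(20L), ]
  cl5 <- classify_per_gene(perm)
  expect_identical(sort(cl5$guide_id[cl5$highest_in_class]),
                   sort(cl4$guide_id[cl4$highest_in_class]))
  expect_identical(sort(cl5$guide_id[cl5$lowest_in_class]),
                   sort(cl4$guide_id[cl4$lowest_in_class]))
})

test_that("quadrant report counts threshold crossings exactly", {
  mk <- function(gene, ko, act, mmej, hi, lo)
    data.frame(gene_id = gene, guide_id = paste0(gene, "_", seq_along(ko)),
               cut_pos = seq_along(ko), strand = "+", activity = act,
               ko_score = ko, mmej = mmej, highest_in_class = hi,
               lowest_in_class = lo, stringsAsFactors = FALSE)
  # hand-built 5-gene table: highest-in-class passing KO>75 & activity>50
  # for genes 1 and 4 (2/5); MMEJ > 0.9 for gene 2's highest only (1/5)
  tab <- rbind(
    mk("g1", c(80, 20), c(60, 70), c(0.2, 0.1), c(TRUE, FALSE), c(FALSE, TRUE)),
    mk("g2", c(76, 10), c(40, 80), c(0.95, 0.5), c(TRUE, FALSE), c(FALSE, TRUE)),
    mk("g3", c(60, 50), c(90, 10), c(0.3, 0.2), c(TRUE, FALSE), c(FALSE, TRUE)),
    mk("g4", c(99, 98), c(51, 20), c(0.4, 0.8), c(TRUE, FALSE), c(FALSE, TRUE)),
    mk("g5", c(70, 30), c(90, 90), c(0.1, 0.1), c(TRUE, FALSE), c(FALSE, TRUE)))
  rep <- quadrant_report(tab)
  expect_equal(rep$frac_genes_highest_pass, 2 / 5)
  expect_equal(rep$n_genes_highest_pass, 2L)
  expect_equal(rep$frac_highest_mmej, 1 / 5)
  expect_identical(rep$n_genes, 5L)
  expect_identical(rep$n_guides, 10L)

  # invariant to row order
  rep2 <- quadrant_report(tab[sample.int(nrow(tab)), ])
  expect_equal(rep2$frac_genes_highest_pass, rep$frac_genes_highest_pass)
  expect_equal(rep2$frac_highest_mmej, rep$frac_highest_mmej)

  # all guides below all thresholds
  low <- mk("g1", c(10, 20), c(10, 20), c(0.1, 0.2), c(TRUE, FALSE),
            c(FALSE, TRUE))
  rep3 <- quadrant_report(low)
  expect_equal(rep3$frac_genes_highest_pass, 0)
  expect_equal(rep3$frac_highest_mmej, 0)

  expect_error(quadrant_report(tab, ko_threshold = 120), "\\[0, 100\\]")
})

test_that("the design driver runs FASTA to classified table end to end", {
  fa <- withr::local_tempfile(fileext = ".fa")
  genes <- gen_cds(3L, c(200L, 400L), seed = 77, path = fa)
  model <- rand_activity_model(2)
  res <- design_guides(fa, model, t7_filter = FALSE)
  # row count equals the brute-force enumeration over all records
  n_oracle <- sum(vapply(as.character(genes), function(s)
    length(oracle_scan(s)), integer(1)))
  expect_identical(nrow(res$guides), n_oracle)
  expect_identical(sum(res$guides$highest_in_class),
                   length(unique(res$guides$gene_id)))
  expect_true(all(c("activity", "frameshift_freq", "mmej", "ko_score")
                  %in% names(res$guides)))

  # deterministic rerun, identical CSV output
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  design_guides(fa, model, t7_filter = FALSE, out_csv = out1)
  design_guides(fa, model, t7_filter = FALSE, out_csv = out2)
  expect_identical(readLines(out1), readLines(out2))

  # input without a single PAM site yields an empty result with a warning
  empty <- setNames(paste(rep("AT", 60), collapse = ""), "flat")
  expect_warning(res2 <- design_guides(empty, model), "no guides")
  expect_null(res2$guides)
})
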