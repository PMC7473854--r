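# Synthetic-data generators: every input the pipeline consumes, produced
# with controlled ground truth so recovery can be asserted. All generators
# are deterministic for a fixed seed.

#' Generate random coding-sequence FASTA records
#'
#' @param n_genes number of sequences.
#' @param length_range integer range from which each gene length is drawn
#'   uniformly.
#' @param gc target GC content (per-base probability).
#' @param seed RNG seed.
#' @param path optional FASTA path to write (via Biostrings).
#' @return A `Biostrings::DNAStringSet` named `gene_1` ... `gene_n`.
#' @export
gen_cds <- function(n_genes = 10L, length_range = c(300L, 900L), gc = 0.4,
                    seed = 1L, path = NULL) {
  stopifnot(gc >= 0, gc <= 1, n_genes >= 0)
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_genes), function(i) {
    len <- sample(seq.int(length_range[1], length_range[2]), 1L)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- if (n_genes) paste0("gene_", seq_len(n_genes)) else character(0)
  if (!is.null(path)) Biostrings::writeXStringSet(dss, path, width = 80L)
  dss
}

#' Generate a ground-truth outcome distribution for a context
#'
#' Builds a mutant-only outcome distribution over the classes the pipeline
#' cares about -- +1 insertions, microhomology-flanked deletions and other
#' deletions -- by running the built-in microhomology predictor on the
#' context with per-guide randomized parameters. The realized cumulative
#' frameshift frequency and MMEJ fraction are recorded as attributes
#' `true_frameshift` and `true_mmej`, the controlled ground truth for
#' recovery tests.
#'
#' Per-guide parameters are drawn to emulate the guide-to-guide diversity
#' of a real multi-guide panel: the deletion length decay varies mildly
#' (`0.2 * exp(U(-0.25, 0.25))`, repair physics being roughly shared across
#' sites), while the microhomology reward (`U(1, 6)`, the "precision"
#' axis: high values give spectra dominated by one strong microhomology
#' deletion) and the +1 insertion weight (`0.3 * exp(U(-2, 2.5))`, the
#' insertion-fraction axis) vary strongly. Under these defaults, cumulative
#' frameshift frequencies span roughly 0.4-1.0 across guides with top-class
#' frequencies up to ~0.5, and deep-read recovery through the harness stays
#' above r = 0.999 per guide.
#'
#' @param context80 80-nt context around the cut.
#' @param seed RNG seed (controls the parameter draw).
#' @param guide_id label.
#' @param params optional fixed [mh_params()], bypassing the random draw.
#' @return A mutant-only `outcome_dist` with ground-truth attributes.
#' @export
gen_truth <- function(context80, seed = 1L, guide_id = "guide",
                      params = NULL) {
  set.seed(seed)
  par <- if (!is.null(params)) params else mh_params(
    decay = 0.2 * exp(stats::runif(1, -0.25, 0.25)),
    mh_gamma = stats::runif(1, 1, 6),
    ins_weight = 0.3 * exp(stats::runif(1, -2, 2.5)))
  d <- predict_outcomes_mh(context80, params = par, guide_id = guide_id)
  attr(d, "true_frameshift") <- cumulative_frameshift(d)
  attr(d, "true_mmej") <- mmej_fraction(d)
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Simulate an amplicon-sequencing indel table
#'
#' Models targeted deep sequencing of a mosaic embryo pool as one
#' multinomial draw of `n_reads` reads: wildtype with probability `1 - e`,
#' and each mutant class with probability `e` times its ground-truth
#' frequency. Returned frequencies are read counts over `n_reads`.
#'
#' @param truth mutant-only `outcome_dist` (the ground-truth spectrum).
#' @param e editing efficiency (fraction of non-wildtype reads) in \[0, 1\].
#' @param n_reads total reads.
#' @param seed RNG seed.
#' @return An `outcome_dist` (source `"observed"`, method `"amplicon_sim"`)
#'   including a wildtype entry, with attributes `e`, `seed`, `n_reads` and
#'   a `counts` column.
#' @export
gen_amplicon_table <- function(truth, e, n_reads = 1e5, seed = 1L) {
  stopifnot(e >= 0, e <= 1, n_reads >= 1)
  set.seed(seed)
  p <- c(1 - e, e * truth$frequency / sum(truth$frequency))
  counts <- as.integer(stats::rmultinom(1L, size = n_reads, prob = p))
  kind <- c("wildtype", truth$kind)
  len <- c(0L, truth$length)
  keep <- counts > 0L
  d <- outcome_dist(kind = kind[keep], length = len[keep],
                    frequency = counts[keep] / n_reads,
                    del_start = c(NA_integer_, truth$del_start)[keep],
                    ins_bases = c(NA_character_, truth$ins_bases)[keep],
                    mh = c(NA_real_, truth$mh)[keep],
                    guide_id = attr(truth, "guide_id"), source = "observed",
                    method = "amplicon_sim")
  d$counts <- counts[keep]
  attr(d, "e") <- e
  attr(d, "seed") <- as.integer(seed)
  attr(d, "n_reads") <- n_reads
  d
}

#' Distort a ground-truth spectrum into a mock prediction
#'
#' Applies seeded multiplicative log-normal noise to the ground-truth
#' frequencies and renormalizes, so the output stays on the simplex and
#' `distortion = 0` returns an exact copy. The single `distortion` knob is
#' the log-scale SD of the noise.
#'
#' @param truth mutant-only `outcome_dist`.
#' @param distortion log-normal sigma (>= 0).
#' @param seed RNG seed.
#' @return An `outcome_dist` (source `"predicted"`, method `"mock"`).
#' @export
gen_prediction_table <- function(truth, distortion = 0, seed = 1L) {
  stopifnot(distortion >= 0)
  f <- truth$frequency
  if (distortion > 0) {
    set.seed(seed)
    f <- f * exp(stats::rnorm(base::length(f), 0, distortion))
  }
  d <- .rewrap(as.data.frame(truth), truth, frequency = f / sum(f))
  attr(d, "source") <- "predicted"
  attr(d, "method") <- "mock"
  attr(d, "distortion") <- distortion
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Simulate per-embryo Sanger-deconvolution outcome tables
#'
#' Emulates the few-embryo Sanger/trace-deconvolution setting, including its
#' underpowering mechanism: each embryo's spectrum is built from a small
#' number of discrete repair events (`cells_per_embryo` cells, two alleles
#' each), not from deep reads, so embryos with few cells at the time of
#' editing show high between-embryo variance. Alleles are edited with
#' probability `e` and edited alleles draw their outcome from `truth`;
#' deletions longer than 20 bp are dropped (the deconvolution ingestion
#' limit) and the wildtype fraction is reported alongside mutant classes.
#'
#' @param truth mutant-only `outcome_dist`.
#' @param e per-allele editing probability.
#' @param n_embryos number of embryos.
#' @param cells_per_embryo discrete repair-event pairs per embryo.
#' @param seed RNG seed.
#' @return List of `outcome_dist` (source `"observed"`, method
#'   `"ice_sim"`), one per embryo.
#' @export
gen_ice_tables <- function(truth, e = 0.8, n_embryos = 3L,
                           cells_per_embryo = 16L, seed = 1L) {
  stopifnot(n_embryos >= 1, cells_per_embryo >= 1, e >= 0, e <= 1)
  keep <- !(truth$kind == "deletion" & truth$length > 20L)
  tr <- truth[keep, , drop = FALSE]
  pr <- tr$frequency / sum(tr$frequency)
  set.seed(seed)
  lapply(seq_len(n_embryos), function(emb) {
    n_alleles <- 2L * cells_per_embryo
    edited <- stats::runif(n_alleles) < e
    idx <- sample.int(nrow(tr), sum(edited), replace = TRUE, prob = pr)
    tab <- tabulate(idx, nbins = nrow(tr))
    counts <- c(sum(!edited), tab)
    kind <- c("wildtype", tr$kind)
    len <- c(0L, tr$length)
    nz <- counts > 0L
    outcome_dist(kind = kind[nz], length = len[nz],
                 frequency = counts[nz] / n_alleles,
                 del_start = c(NA_integer_, tr$del_start)[nz],
                 ins_bases = c(NA_character_, tr$ins_bases)[nz],
                 mh = c(NA_real_, tr$mh)[nz],
                 guide_id = attr(truth, "guide_id"), source = "observed",
                 method = "ice_sim")
  })
}

#' Generate a full synthetic concordance panel
#'
#' Convenience wrapper producing, for `n_guides` guides: a random context,
#' its ground-truth spectrum, a mock prediction at the requested distortion,
#' and an amplicon-sequencing observation at the requested efficiency and
#' depth. This is the input shape the concordance harness evaluates.
#'
#' @param n_guides number of guides.
#' @param e editing efficiency of the simulated experiment.
#' @param n_reads reads per amplicon.
#' @param distortion mock-prediction distortion level.
#' @param seed master seed; per-guide seeds are derived from it.
#' @return List of per-guide lists with `truth`, `pred`, `obs_raw`
#'   (wildtype included) and `context`.
#' @export
gen_panel <- function(n_guides = 28L, e = 0.7, n_reads = 1e5,
                      distortion = 0, seed = 1L) {
  set.seed(seed)
  sub <- sample.int(1e6, 3L * n_guides)
  lapply(seq_len(n_guides), function(i) {
    gid <- sprintf("g%02d", i)
    set.seed(sub[3L * i - 2L])
    ctx <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
    truth <- gen_truth(ctx, seed = sub[3L * i - 1L], guide_id = gid)
    list(context = ctx,
         truth = truth,
         pred = gen_prediction_table(truth, distortion, seed = sub[3L * i]),
         obs_raw = gen_amplicon_table(truth, e = e, n_reads = n_reads,
                                      seed = sub[3L * i]))
  })
}
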