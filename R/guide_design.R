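# SpCas9 guide scanning and scoring over coding sequences: protospacer/PAM
# enumeration on both strands, context-window extraction, activity and
# knockout scoring, per-gene highest/lowest-in-class calls.

# scan one forward-oriented sequence; returns 1-based PAM start positions
.pam_starts <- function(seq) {
  n <- nchar(seq)
  if (n < 23L) return(integer(0))
  chars <- strsplit(seq, "")[[1]]
  gg <- which(chars[-n] == "G" & chars[-1] == "G")  # positions of first G of "GG"
  p <- gg - 1L                                      # PAM start (N of NGG)
  p[p >= 21L & p + 2L <= n]
}

#' Scan sequences for SpCas9 targets
#'
#' Enumerates every 20-nt protospacer adjacent to an NGG PAM on both strands
#' of each input record, keeping only sites whose three context windows (80
#' nt centred on the cut, 65 nt with 30 nt upstream / 35 nt downstream, and
#' the 35-nt activity-scoring window) lie fully inside the record. The
#' Cas9 cut site is placed 3 bp 5' of the PAM, between protospacer positions
#' 17 and 18; `cut_pos` reports it as a 0-based between-nucleotide
#' coordinate on the forward strand of the record for both strands.
#'
#' With `t7_filter = TRUE`, only protospacers beginning with GG (the
#' canonical requirement for efficient T7 in vitro transcription) are
#' retained; `t7_allow_ga` additionally accepts GA starts.
#'
#' @param genes a named character vector of ACGT sequences or a
#'   `Biostrings::DNAStringSet`. Records containing non-ACGT symbols are
#'   skipped with a warning.
#' @param t7_filter keep only T7-compatible protospacers (default TRUE).
#' @param t7_allow_ga also accept protospacers starting GA.
#' @return Data frame with columns `gene_id`, `guide_id`, `protospacer`,
#'   `pam`, `strand`, `cut_pos`, `context35`, `context65`, `context80`,
#'   ordered by gene, cut position, strand.
#' @export
scan_targets <- function(genes, t7_filter = TRUE, t7_allow_ga = FALSE) {
  if (inherits(genes, "DNAStringSet")) {
    nm <- names(genes)
    genes <- as.character(genes)
    names(genes) <- nm
  }
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("every input sequence must be named with a gene id")
  out <- list()
  for (gid in names(genes)) {
    fwd <- toupper(genes[[gid]])
    if (grepl("[^ACGT]", fwd)) {
      warning(sprintf("record '%s' contains non-ACGT symbols; skipped", gid))
      next
    }
    n <- nchar(fwd)
    if (n < 80L) next  # cannot host any full context window
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    for (str in c("+", "-")) {
      s <- if (str == "+") fwd else rev
      for (p in .pam_starts(s)) {
        cut <- p - 4L  # between-base coordinate on this orientation
        if (cut < 40L || n - cut < 40L) next
        proto <- substr(s, p - 20L, p - 1L)
        hit <- data.frame(
          gene_id = gid,
          protospacer = proto,
          pam = substr(s, p, p + 2L),
          strand = str,
          cut_pos = if (str == "+") cut else n - cut,
          context35 = substr(s, p - 26L, p + 8L),
          context65 = substr(s, cut - 29L, cut + 35L),
          context80 = substr(s, cut - 39L, cut + 40L),
          stringsAsFactors = FALSE)
        out[[base::length(out) + 1L]] <- hit
      }
    }
  }
  if (!base::length(out)) {
    df <- data.frame(gene_id = character(0), guide_id = character(0),
                     protospacer = character(0), pam = character(0),
                     strand = character(0), cut_pos = integer(0),
                     context35 = character(0), context65 = character(0),
                     context80 = character(0), stringsAsFactors = FALSE)
    return(df)
  }
  df <- do.call(rbind, out)
  if (t7_filter) {
    starts <- substr(df$protospacer, 1L, 2L)
    ok <- starts == "GG" | (t7_allow_ga & starts == "GA")
    df <- df[ok, , drop = FALSE]
  }
  df <- df[order(df$gene_id, df$cut_pos, df$strand), , drop = FALSE]
  df$guide_id <- sprintf("%s:%d:%s", df$gene_id, df$cut_pos, df$strand)
  rownames(df) <- NULL
  df[, c("gene_id", "guide_id", "protospacer", "pam", "strand", "cut_pos",
         "context35", "context65", "context80")]
}

#' Score scanned guides
#'
#' For each target: on-target activity from the 35-nt window via
#' [activity_score()]; an editing-outcome distribution from the 80-nt
#' context via the supplied predictor; cumulative frameshift frequency;
#' MMEJ fraction; and the knockout score (squared frameshift frequency) on
#' the 0-100 scale.
#'
#' @param targets data frame from [scan_targets()].
#' @param activity_model an `activity_model`.
#' @param predictor function `(context80, guide_id) -> outcome_dist`;
#'   defaults to the built-in microhomology heuristic.
#' @param mu_min MMEJ microhomology threshold (bp).
#' @return `targets` with added columns `activity`, `frameshift_freq`,
#'   `mmej`, `ko_score` (0-100).
#' @export
score_guides <- function(targets, activity_model,
                         predictor = function(ctx, id)
                           predict_outcomes_mh(ctx, guide_id = id),
                         mu_min = 2L) {
  n <- nrow(targets)
  act <- numeric(n); fs <- numeric(n); mm <- numeric(n)
  for (i in seq_len(n)) {
    act[i] <- activity_score(targets$context35[i], activity_model)
    dist <- tryCatch(predictor(targets$context80[i], targets$guide_id[i]),
                     error = function(e)
                       stop(sprintf("predictor failed for guide '%s': %s",
                                    targets$guide_id[i], conditionMessage(e))))
    fs[i] <- cumulative_frameshift(dist)
    mm[i] <- mmej_fraction(dist, mu_min = mu_min,
                           context = targets$context80[i])
  }
  targets$activity <- act
  targets$frameshift_freq <- fs
  targets$mmej <- mm
  targets$ko_score <- 100 * ko_score(fs)
  targets
}

#' Flag highest- and lowest-in-class guides per gene
#'
#' Per gene, exactly one guide receives the `highest_in_class` flag (maximal
#' knockout score) and exactly one the `lowest_in_class` flag (minimal
#' knockout score). Ties are broken by higher activity score, then by the
#' 5'-most cut position, then by strand (`+` first), so the calls are
#' deterministic and invariant to row order. A single-guide gene carries
#' both flags.
#'
#' @param scored data frame from [score_guides()].
#' @return `scored` with logical columns `highest_in_class`,
#'   `lowest_in_class`.
#' @export
classify_per_gene <- function(scored) {
  if (!nrow(scored)) stop("no scored guides to classify")
  scored$highest_in_class <- FALSE
  scored$lowest_in_class <- FALSE
  pick <- function(idx, decreasing) {
    o <- order(if (decreasing) -scored$ko_score[idx] else scored$ko_score[idx],
               -scored$activity[idx], scored$cut_pos[idx],
               scored$strand[idx])
    idx[o[1L]]
  }
  for (g in unique(scored$gene_id)) {
    idx <- which(scored$gene_id == g)
    scored$highest_in_class[pick(idx, TRUE)] <- TRUE
    scored$lowest_in_class[pick(idx, FALSE)] <- TRUE
  }
  scored
}

#' Threshold report over a classified guide table
#'
#' Summarizes how the designed guides populate the score quadrants defined
#' by a knockout-score cutoff, an activity cutoff and an MMEJ cutoff
#' (defaults 75, 50 and 90, the conventional demarcations): the fraction of
#' genes whose highest-in-class guide clears both the knockout and activity
#' cutoffs, the fraction of highest-in-class guides exceeding the MMEJ
#' cutoff, and guide-level quadrant counts.
#'
#' @param classified data frame from [classify_per_gene()].
#' @param ko_threshold knockout-score cutoff on the 0-100 scale.
#' @param activity_threshold activity cutoff on the 0-100 scale.
#' @param mmej_threshold MMEJ cutoff in percent.
#' @return List with `n_genes`, `n_guides`, `frac_genes_highest_pass`,
#'   `n_genes_highest_pass`, `frac_highest_mmej`, `n_highest_mmej`, and the
#'   guide-level `quadrant_counts` table.
#' @export
quadrant_report <- function(classified, ko_threshold = 75,
                            activity_threshold = 50, mmej_threshold = 90) {
  if (ko_threshold < 0 || ko_threshold > 100 ||
      activity_threshold < 0 || activity_threshold > 100 ||
      mmej_threshold < 0 || mmej_threshold > 100)
    stop("thresholds must lie in [0, 100]")
  hi <- classified[classified$highest_in_class, , drop = FALSE]
  pass <- hi$ko_score > ko_threshold & hi$activity > activity_threshold
  mmej_pass <- 100 * hi$mmej > mmej_threshold
  quad <- table(ko_high = classified$ko_score > ko_threshold,
                activity_high = classified$activity > activity_threshold)
  list(n_genes = nrow(hi),
       n_guides = nrow(classified),
       frac_genes_highest_pass = mean(pass),
       n_genes_highest_pass = sum(pass),
       frac_highest_mmej = mean(mmej_pass),
       n_highest_mmej = sum(mmej_pass),
       quadrant_counts = quad,
       thresholds = c(ko = ko_threshold, activity = activity_threshold,
                      mmej = mmej_threshold))
}

#' Design and score guides across a set of coding sequences
#'
#' End-to-end driver: read (or accept) CDS records, scan for SpCas9 targets,
#' score, classify per gene and summarize. Records are processed one at a
#' time and results optionally appended to a CSV, so memory stays flat in
#' the number of genes.
#'
#' @param genes FASTA path, named character vector, or `DNAStringSet`.
#' @param activity_model an `activity_model`.
#' @param predictor outcome predictor, as in [score_guides()].
#' @param t7_filter,t7_allow_ga passed to [scan_targets()].
#' @param out_csv optional path; scored rows are appended gene by gene.
#' @param ... thresholds passed to [quadrant_report()].
#' @return List with `guides` (classified table) and `report`.
#' @export
design_guides <- function(genes, activity_model,
                          predictor = function(ctx, id)
                            predict_outcomes_mh(ctx, guide_id = id),
                          t7_filter = TRUE, t7_allow_ga = FALSE,
                          out_csv = NULL, ...) {
  if (is.character(genes) && base::length(genes) == 1L && file.exists(genes))
    genes <- Biostrings::readDNAStringSet(genes)
  if (inherits(genes, "DNAStringSet")) {
    nm <- names(genes)
    genes <- as.character(genes)
    names(genes) <- sub("\\s.*$", "", nm)
  }
  chunks <- list()
  first <- TRUE
  for (gid in names(genes)) {
    tg <- scan_targets(genes[gid], t7_filter = t7_filter,
                       t7_allow_ga = t7_allow_ga)
    if (!nrow(tg)) next
    sc <- score_guides(tg, activity_model, predictor = predictor)
    if (!is.null(out_csv)) {
      utils::write.table(sc, out_csv, sep = ",", row.names = FALSE,
                         col.names = first, append = !first, quote = FALSE)
      first <- FALSE
    }
    chunks[[base::length(chunks) + 1L]] <- sc
  }
  if (!base::length(chunks)) {
    warning("no guides found in input")
    return(list(guides = NULL, report = NULL))
  }
  classified <- classify_per_gene(do.call(rbind, chunks))
  list(guides = classified, report = quadrant_report(classified, ...))
}
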