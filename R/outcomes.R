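#' @keywords internal
"_PACKAGE"

# Canonical outcome categories.
.OUTCOME_KINDS <- c("deletion", "insertion", "wildtype")

#' Editing-outcome distributions
#'
#' An `outcome_dist` holds the repair-product spectrum of one guide RNA: a
#' set of editing outcomes (deletions, 1-bp or longer insertions, and
#' optionally the unedited wildtype class) together with their frequencies.
#' It is the common currency passed between the outcome predictors, the
#' synthetic-data generators and the concordance harness.
#'
#' Each entry is identified by a canonical `genotype_key` so that the same
#' repair product reported by different tools (for example a
#' microhomology-ambiguous deletion emitted in shifted coordinates) collapses
#' to a single class. Deletions are keyed by their left-aligned start offset
#' relative to the cut site; the cut site sits 3 bp 5' of the PAM, between
#' protospacer positions 17 and 18.
#'
#' @param kind character vector, each `"deletion"`, `"insertion"` or
#'   `"wildtype"`.
#' @param length integer vector of net indel sizes in bp; 0 for wildtype,
#'   > 0 otherwise.
#' @param frequency numeric vector of non-negative frequencies. They need
#'   not sum to 1 on construction (raw read fractions are allowed); the
#'   `normalize_*` operations enforce the simplex.
#' @param del_start integer deletion start offsets, 0-based relative to the
#'   cut site (the first deleted base of a deletion starting at the cut has
#'   offset 0; deletions extending 5' have negative offsets). `NA` for
#'   non-deletions.
#' @param ins_bases inserted nucleotides for insertions, `NA` otherwise.
#' @param mh optional microhomology length (bp) per deletion; `NA` when
#'   unknown.
#' @param guide_id single string naming the guide.
#' @param source `"predicted"` or `"observed"`.
#' @param method free-text label of the predictor or assay.
#' @param context optional ACGT sequence around the cut used to left-align
#'   deletion coordinates before keying (recommended whenever available).
#' @param cut 0-based position of the cut within `context` (number of bases
#'   5' of the cut); defaults to `nchar(context) / 2`.
#'
#' @return An object of class `outcome_dist`: a data frame with columns
#'   `kind`, `length`, `del_start`, `ins_bases`, `mh`, `genotype_key`,
#'   `frequency`, plus attributes `guide_id`, `source`, `method`.
#' @export
outcome_dist <- function(kind, length, frequency,
                         del_start = NA_integer_, ins_bases = NA_character_,
                         mh = NA_real_,
                         guide_id = "guide", source = "predicted",
                         method = "unspecified",
                         context = NULL, cut = NULL) {
  n <- base::length(kind)
  stopifnot(is.character(kind), all(kind %in% .OUTCOME_KINDS))
  length <- as.integer(length)
  del_start <- rep_len(as.integer(del_start), n)
  ins_bases <- rep_len(as.character(ins_bases), n)
  mh <- rep_len(as.numeric(mh), n)
  frequency <- as.numeric(frequency)
  if (base::length(length) != n || base::length(frequency) != n)
    stop("kind, length and frequency must have equal lengths")
  if (any(frequency < 0)) stop("frequencies must be non-negative")
  bad_len <- (kind == "wildtype" & length != 0L) |
    (kind != "wildtype" & length <= 0L)
  if (any(bad_len))
    stop("length must be 0 for wildtype and > 0 otherwise")
  if (any(kind == "deletion" & is.na(del_start)))
    stop("deletions require del_start")
  ins <- which(kind == "insertion")
  if (base::length(ins) &&
      any(is.na(ins_bases[ins]) | nchar(ins_bases[ins]) != length[ins]))
    stop("insertions require ins_bases of matching length")

  if (!is.null(context)) {
    context <- toupper(context)
    if (is.null(cut)) cut <- nchar(context) %/% 2L
    del <- which(kind == "deletion")
    for (i in del) {
      del_start[i] <- left_align_deletion(context, cut, del_start[i], length[i])
      if (is.na(mh[i]))
        mh[i] <- mh_length(context, cut, del_start[i], length[i])
    }
  }

  key <- .genotype_key(kind, length, del_start, ins_bases)
  df <- data.frame(kind = kind, length = length, del_start = del_start,
                   ins_bases = ins_bases, mh = mh, genotype_key = key,
                   frequency = frequency, stringsAsFactors = FALSE)
  # collapse entries whose canonical keys coincide (shifted deletion reps)
  if (anyDuplicated(df$genotype_key)) {
    agg <- tapply(df$frequency, df$genotype_key, sum)
    keep <- df[!duplicated(df$genotype_key), , drop = FALSE]
    keep$frequency <- as.numeric(agg[keep$genotype_key])
    df <- keep
  }
  rownames(df) <- NULL
  structure(df,
            guide_id = as.character(guide_id),
            source = match.arg(source, c("predicted", "observed")),
            method = as.character(method),
            class = c("outcome_dist", "data.frame"))
}

#' @export
print.outcome_dist <- function(x, ...) {
  cat(sprintf("outcome_dist: guide '%s' (%s, %s), %d classes, total %.4f\n",
              attr(x, "guide_id"), attr(x, "source"), attr(x, "method"),
              nrow(x), sum(x$frequency)))
  print.data.frame(x, ...)
  invisible(x)
}

# rebuild an outcome_dist from a subset data frame, carrying metadata over
.rewrap <- function(df, template, frequency = df$frequency) {
  df$frequency <- frequency
  rownames(df) <- NULL
  structure(df,
            guide_id = attr(template, "guide_id"),
            source = attr(template, "source"),
            method = attr(template, "method"),
            n_reads = attr(template, "n_reads"),  # depth travels with filters
            class = c("outcome_dist", "data.frame"))
}

.genotype_key <- function(kind, length, del_start, ins_bases) {
  ifelse(kind == "wildtype", "wt",
  ifelse(kind == "insertion", sprintf("ins:%d:%s", length, ins_bases),
         sprintf("del:%d:%+d", length, del_start)))
}

#' Left-align a deletion within its sequence context
#'
#' A deletion flanked by microhomology has several equivalent coordinate
#' representations; predictors and aligners may emit any of them. Shifting
#' the deletion 5' while the base preceding it equals its last base leaves
#' the edited sequence unchanged, so the leftmost representation is used as
#' the canonical one.
#'
#' @param context uppercase ACGT string.
#' @param cut 0-based cut position within `context`.
#' @param del_start 0-based start offset of the deletion relative to the cut.
#' @param length deletion length in bp.
#' @return The canonical (leftmost) `del_start`.
#' @export
left_align_deletion <- function(context, cut, del_start, length) {
  s <- vapply(strsplit(context, "")[[1]], identity, character(1))
  p <- cut + del_start + 1L  # 1-based first deleted position
  if (p < 1L || p + length - 1L > base::length(s))
    stop("deletion outside context window")
  while (p > 1L && s[p - 1L] == s[p + length - 1L]) p <- p - 1L
  as.integer(p - 1L - cut)
}

#' Microhomology length of a deletion
#'
#' Length of the exact repeat shared by the deleted segment's 5' end and the
#' sequence immediately 3' of it (for a left-aligned deletion), i.e. the
#' number of bases for which `context[p..]` and `context[p+length..]` agree.
#'
#' @inheritParams left_align_deletion
#' @return Integer microhomology length (0 = no flanking repeat).
#' @export
mh_length <- function(context, cut, del_start, length) {
  s <- strsplit(context, "")[[1]]
  p <- cut + del_start + 1L
  k <- 0L
  while (p + k <= base::length(s) && p + length + k <= base::length(s) &&
         s[p + k] == s[p + length + k]) k <- k + 1L
  k
}

#' Is an editing outcome frameshifting?
#'
#' An indel shifts the reading frame when its signed net length change is
#' not a multiple of 3. Wildtype is never frameshifting.
#'
#' @param outcome an `outcome_dist` (vectorized over rows) or a list with
#'   elements `kind` and `length`.
#' @return Logical (vector).
#' @export
is_frameshift <- function(outcome) {
  kind <- outcome$kind
  len <- outcome$length
  stopifnot(all(kind %in% .OUTCOME_KINDS))
  net <- ifelse(kind == "deletion", -len, ifelse(kind == "insertion", len, 0L))
  kind != "wildtype" & (net %% 3L) != 0L
}

#' Cumulative frameshift frequency of a mutant-outcome distribution
#'
#' Sums the frequencies of all frameshifting outcomes. The input must be a
#' distribution over mutant outcomes only (wildtype removed, e.g. by
#' [normalize_observed()]) and normalized to 1.
#'
#' @param dist an `outcome_dist` without wildtype entries, summing to 1.
#' @param tol tolerance on the normalization check.
#' @return Fraction in \[0, 1\].
#' @export
cumulative_frameshift <- function(dist, tol = 1e-6) {
  if (any(dist$kind == "wildtype"))
    stop("cumulative_frameshift requires a mutant-only distribution (wildtype present)")
  s <- sum(dist$frequency)
  if (abs(s - 1) > tol)
    stop(sprintf("distribution not normalized: sum = %.8f (deviation %.3g)",
                 s, abs(s - 1)))
  sum(dist$frequency[is_frameshift(dist)])
}

#' Knockout score
#'
#' The predicted fraction of biallelic out-of-frame cells within the pool of
#' all mutant cells of a mosaic embryo: the square of the guide's frameshift
#' frequency (two independent alleles must both acquire a frameshift). A
#' frameshift frequency of 0.80 gives a knockout score of 0.64.
#'
#' @param frameshift_freq fraction in \[0, 1\].
#' @return `frameshift_freq^2`, a fraction in \[0, 1\]. Multiply by 100 for
#'   the conventional 0-100 reporting scale.
#' @export
ko_score <- function(frameshift_freq) {
  if (any(frameshift_freq < 0 | frameshift_freq > 1))
    stop("frameshift_freq must lie in [0, 1]")
  frameshift_freq^2
}

#' Filter and renormalize an observed outcome table
#'
#' Applies the curation used before comparing sequencing observations to
#' predictor output: wildtype reads and insertions longer than 1 bp are
#' removed, and the residual mutant frequencies are rescaled to sum to 1.
#'
#' @param raw an `outcome_dist`, possibly containing wildtype and long
#'   insertions.
#' @return A mutant-only `outcome_dist` summing to 1.
#' @export
normalize_observed <- function(raw) {
  keep <- !(raw$kind == "wildtype" |
              (raw$kind == "insertion" & raw$length > 1L))
  df <- raw[keep, , drop = FALSE]
  tot <- sum(df$frequency)
  if (nrow(df) == 0L || tot <= 0)
    stop(sprintf("no editable signal for guide '%s': no mutant reads survive the filter",
                 attr(raw, "guide_id")))
  .rewrap(as.data.frame(df), raw, frequency = df$frequency / tot)
}

#' Curate a distribution to a reference predictor's outcome classes
#'
#' Comparisons between predicted and observed spectra are restricted to a
#' common class universe derived from a reference prediction: all +1 bp
#' insertions, plus deletions up to the length L* at which the reference's
#' cumulative probability -- accumulated over +1 insertions and deletions in
#' order of increasing deletion length -- first exceeds 99%. This avoids
#' disproportionate weighting of rare large deletions. Retained classes are
#' renormalized to 1.
#'
#' @param dist the `outcome_dist` to curate (predicted or observed,
#'   mutant-only).
#' @param reference the reference predicted `outcome_dist` defining the
#'   class universe.
#' @param cumulative threshold defining L* (default 0.99).
#' @return Curated, renormalized `outcome_dist`.
#' @export
curate_to_reference_classes <- function(dist, reference, cumulative = 0.99) {
  lstar <- curation_max_deletion(reference, cumulative)
  keep <- (dist$kind == "insertion" & dist$length == 1L) |
    (dist$kind == "deletion" & dist$length <= lstar)
  df <- dist[keep, , drop = FALSE]
  tot <- sum(df$frequency)
  if (nrow(df) == 0L || tot <= 0)
    stop(sprintf("curation removed all outcomes for guide '%s'",
                 attr(dist, "guide_id")))
  .rewrap(as.data.frame(df), dist, frequency = df$frequency / tot)
}

#' Maximal deletion length retained by the 99%-cumulative curation rule
#'
#' @inheritParams curate_to_reference_classes
#' @return Integer L*: the smallest deletion length at which the reference's
#'   cumulative mass over +1 insertions plus deletions of length <= L first
#'   exceeds `cumulative`.
#' @export
curation_max_deletion <- function(reference, cumulative = 0.99) {
  if (sum(reference$frequency) < cumulative)
    stop(sprintf("reference distribution carries mass %.4f < %.2f; cannot curate",
                 sum(reference$frequency), cumulative))
  acc <- sum(reference$frequency[reference$kind == "insertion" &
                                   reference$length == 1L])
  del <- reference[reference$kind == "deletion", , drop = FALSE]
  lens <- sort(unique(del$length))
  for (L in lens) {
    acc <- acc + sum(del$frequency[del$length == L])
    if (acc > cumulative) return(as.integer(L))
  }
  stop(sprintf("cumulative mass over +1 insertions and deletions reaches only %.4f <= %.2f",
               acc, cumulative))
}

#' Pair two distributions over the union of their outcome classes
#'
#' Builds zero-filled frequency vectors over the sorted union of genotype
#' keys, the form every correlation in the concordance harness consumes.
#'
#' @param pred,obs `outcome_dist` objects for the same guide.
#' @param check_guide error if the two `guide_id`s differ (default TRUE).
#' @return A list with `keys`, `pred` and `obs` numeric vectors of equal
#'   length, ordered by key.
#' @export
match_outcomes <- function(pred, obs, check_guide = TRUE) {
  if (check_guide && !identical(attr(pred, "guide_id"), attr(obs, "guide_id")))
    stop(sprintf("guide_id mismatch: '%s' vs '%s'",
                 attr(pred, "guide_id"), attr(obs, "guide_id")))
  keys <- sort(union(pred$genotype_key, obs$genotype_key))
  p <- setNames(numeric(base::length(keys)), keys)
  o <- p
  p[pred$genotype_key] <- pred$frequency
  o[obs$genotype_key] <- obs$frequency
  list(keys = keys, pred = unname(p), obs = unname(o))
}

# ---- outcome-table I/O -----------------------------------------------------

#' Read and write outcome tables
#'
#' The native outcome-table format is a CSV with columns `guide_id`,
#' `category` (`del`/`ins`/`wt`), `length`, `del_start`, `ins_bases`,
#' `frequency` and optionally `mh`. One file may hold several guides; the
#' reader returns a named list of `outcome_dist` objects. The writer prints
#' frequencies with full precision so a write/read cycle reproduces them
#' bit-exactly.
#'
#' @param path file path.
#' @param source,method metadata attached to every distribution read.
#' @rdname outcome_table
#' @return `read_outcome_table`: named list of `outcome_dist`.
#' @export
read_outcome_table <- function(path, source = "predicted",
                               method = "native") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "category", "length", "frequency")
  if (!all(need %in% names(df)))
    stop("outcome table must contain columns: ", paste(need, collapse = ", "))
  if (is.null(df$del_start)) df$del_start <- NA_integer_
  if (is.null(df$ins_bases)) df$ins_bases <- NA_character_
  if (is.null(df$mh)) df$mh <- NA_real_
  kind_map <- c(del = "deletion", ins = "insertion", wt = "wildtype")
  if (!all(df$category %in% names(kind_map)))
    stop("category must be one of del/ins/wt")
  out <- lapply(split(df, df$guide_id), function(g) {
    outcome_dist(kind = unname(kind_map[g$category]), length = g$length,
                 frequency = g$frequency, del_start = g$del_start,
                 ins_bases = g$ins_bases, mh = g$mh,
                 guide_id = g$guide_id[1], source = source, method = method)
  })
  out[order(names(out))]
}

#' @param dists an `outcome_dist` or list of them.
#' @rdname outcome_table
#' @export
write_outcome_table <- function(dists, path) {
  if (inherits(dists, "outcome_dist")) dists <- list(dists)
  rows <- lapply(dists, function(d) {
    cat_map <- c(deletion = "del", insertion = "ins", wildtype = "wt")
    data.frame(guide_id = attr(d, "guide_id"),
               category = unname(cat_map[d$kind]),
               length = d$length, del_start = d$del_start,
               ins_bases = d$ins_bases, mh = d$mh,
               frequency = sprintf("%.17g", d$frequency),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
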