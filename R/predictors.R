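# On-target activity scoring and editing-outcome prediction.

#' Load a position-specific activity regression model
#'
#' On-target activity is scored with a linear regression over
#' position-specific mononucleotide and dinucleotide indicator features in a
#' 35-nt window around the protospacer (6 nt of 5' flank, the 20-nt
#' protospacer, the NGG PAM and 6 nt of 3' flank), the feature set used by
#' in-vivo activity models for T7-transcribed guides. Coefficients are
#' supplied as a CSV with columns `feature` (a 1- or 2-mer, or the literal
#' `intercept`), `position` (1-based start within the 35-nt window, empty
#' for the intercept) and `weight`.
#'
#' The linear predictor is mapped to the conventional 0-100 score by a fixed
#' affine rescaling `100 * (lp - scale_lo) / (scale_hi - scale_lo)`, clipped
#' to \[0, 100\]. The rescaling constants are part of the model definition,
#' not fitted to data, so scores are reproducible across runs.
#'
#' @param path coefficient CSV.
#' @param scale_lo,scale_hi affine rescaling constants for the linear
#'   predictor.
#' @return An `activity_model`: list with `intercept`, `weights` (named
#'   `"<position>:<kmer>"`), `scale_lo`, `scale_hi`.
#' @export
load_activity_model <- function(path, scale_lo = 0, scale_hi = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(feature = "character"))
  need <- c("feature", "position", "weight")
  if (!all(need %in% names(df)))
    stop("coefficient table must contain columns: ",
         paste(need, collapse = ", "))
  int <- df$feature == "intercept"
  if (sum(int) != 1L) stop("coefficient table needs exactly one intercept row")
  feats <- df[!int, , drop = FALSE]
  k <- nchar(feats$feature)
  ok <- grepl("^[ACGT]{1,2}$", feats$feature) &
    !is.na(feats$position) & feats$position >= 1 &
    feats$position + k - 1 <= 35
  if (!all(ok))
    stop("unparseable feature rows: ",
         paste(utils::head(which(!ok)), collapse = ", "),
         " (features must be 1- or 2-mers inside the 35-nt window)")
  w <- setNames(feats$weight, paste0(feats$position, ":", feats$feature))
  if (anyDuplicated(names(w))) stop("duplicated (position, k-mer) features")
  structure(list(intercept = df$weight[int], weights = w,
                 scale_lo = scale_lo, scale_hi = scale_hi),
            class = "activity_model")
}

#' Score a 35-nt context with an activity model
#'
#' @param context35 35-nt uppercase ACGT sequence (6 nt 5' flank +
#'   protospacer + PAM + 6 nt 3' flank).
#' @param model an `activity_model` from [load_activity_model()].
#' @return Score in \[0, 100\].
#' @export
activity_score <- function(context35, model) {
  context35 <- toupper(context35)
  if (nchar(context35) != 35L) stop("context35 must be exactly 35 nt")
  if (grepl("[^ACGT]", context35))
    stop("context35 contains ambiguous bases (only ACGT allowed)")
  present <- c(paste0(1:35, ":", substring(context35, 1:35, 1:35)),
               paste0(1:34, ":", substring(context35, 1:34, 2:35)))
  lp <- model$intercept +
    sum(model$weights[intersect(names(model$weights), present)])
  sc <- 100 * (lp - model$scale_lo) / (model$scale_hi - model$scale_lo)
  min(max(sc, 0), 100)
}

#' Parameters for the built-in microhomology outcome predictor
#'
#' @param max_deletion largest deletion length enumerated (bp).
#' @param decay exponential penalty per deleted bp: a length-L candidate is
#'   down-weighted by `exp(-decay * L)`.
#' @param mh_gamma microhomology reward exponent: a candidate with
#'   microhomology length `mu` is up-weighted by `(1 + mu)^mh_gamma`.
#' @param ins_weight unnormalized weight of each of the four +1 insertion
#'   channels.
#' @param ins_match_bonus multiplier applied to the +1 insertion that
#'   duplicates the base immediately 5' of the cut (templated insertion).
#' @return Parameter list.
#' @export
mh_params <- function(max_deletion = 30L, decay = 0.2, mh_gamma = 1.5,
                      ins_weight = 0.06, ins_match_bonus = 3) {
  stopifnot(max_deletion >= 1, decay > 0, mh_gamma >= 0,
            ins_weight > 0, ins_match_bonus >= 1)
  list(max_deletion = as.integer(max_deletion), decay = decay,
       mh_gamma = mh_gamma, ins_weight = ins_weight,
       ins_match_bonus = ins_match_bonus)
}

#' Microhomology-heuristic editing-outcome predictor
#'
#' A deterministic, sequence-context-only stand-in predictor implementing
#' the two dominant template-free repair channels: deletions spanning the
#' cut, favoured when flanked by microhomology, and templated +1 insertions.
#' It enumerates every deletion of length 1..`max_deletion` whose span
#' includes the cut site, collapses microhomology-equivalent candidates to
#' their left-aligned canonical form, weights each by
#' `exp(-decay * length) * (1 + mu)^mh_gamma`, adds four +1 insertion
#' channels (the base matching the nucleotide 5' of the cut gets
#' `ins_match_bonus` times the weight of the others), and normalizes.
#'
#' This predictor defines the plug-in contract (an 80-nt context in, an
#' `outcome_dist` out); exported tables from trained outcome predictors can
#' be ingested with [load_predictions()] and used interchangeably. It makes
#' no claim of reproducing any trained model's numeric output.
#'
#' @param context80 sequence context around the cut; the cut sits at the
#'   midpoint (40 bp upstream and 40 bp downstream for the canonical 80-nt
#'   window).
#' @param params from [mh_params()].
#' @param guide_id label for the returned distribution.
#' @return An `outcome_dist` (source `"predicted"`, method
#'   `"mh_heuristic"`), each deletion annotated with its microhomology
#'   length `mh`; insertions carry `mh = 0`.
#' @export
predict_outcomes_mh <- function(context80, params = mh_params(),
                                guide_id = "guide") {
  context80 <- toupper(context80)
  n <- nchar(context80)
  if (grepl("[^ACGT]", context80)) stop("context must be ACGT only")
  if (n < 2L * params$max_deletion)
    stop(sprintf("context of %d nt too short for max deletion %d (need >= %d)",
                 n, params$max_deletion, 2L * params$max_deletion))
  cut <- n %/% 2L

  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (L in seq_len(params$max_deletion)) {
    for (s in seq.int(-L, 0L)) {
      p <- cut + s + 1L
      if (p < 1L || p + L - 1L > n) next
      s_can <- left_align_deletion(context80, cut, s, L)
      key <- sprintf("del:%d:%+d", L, s_can)
      if (!is.null(seen[[key]])) next
      mu <- mh_length(context80, cut, s_can, L)
      w <- exp(-params$decay * L) * (1 + mu)^params$mh_gamma
      seen[[key]] <- TRUE
      rows[[base::length(rows) + 1L]] <-
        list(kind = "deletion", length = L, del_start = s_can,
             ins_bases = NA_character_, mh = mu, w = w)
    }
  }
  base5 <- substr(context80, cut, cut)
  for (b in c("A", "C", "G", "T")) {
    w <- params$ins_weight * if (b == base5) params$ins_match_bonus else 1
    rows[[base::length(rows) + 1L]] <-
      list(kind = "insertion", length = 1L, del_start = NA_integer_,
           ins_bases = b, mh = 0, w = w)
  }
  kind <- vapply(rows, `[[`, character(1), "kind")
  len <- vapply(rows, `[[`, numeric(1), "length")
  ds <- vapply(rows, function(r) as.numeric(r$del_start), numeric(1))
  ib <- vapply(rows, `[[`, character(1), "ins_bases")
  mh <- vapply(rows, `[[`, numeric(1), "mh")
  w <- vapply(rows, `[[`, numeric(1), "w")
  outcome_dist(kind = kind, length = len, frequency = w / sum(w),
               del_start = ds, ins_bases = ib, mh = mh,
               guide_id = guide_id, source = "predicted",
               method = "mh_heuristic")
}

#' Fraction of repair by microhomology-mediated end joining
#'
#' The fraction of total mutant mass carried by deletions whose
#' microhomology length is at least `mu_min`. The accounting threshold for
#' calling a deletion "MMEJ" is not standardized; 2 nt is the default and
#' it is exposed as a parameter.
#'
#' @param dist an `outcome_dist` whose deletions carry `mh` annotations, or
#'   a `context`/`cut` pair to compute them.
#' @param mu_min minimal microhomology length (bp) qualifying as MMEJ.
#' @param context,cut optional sequence context to compute missing `mh`.
#' @return Fraction in \[0, 1\].
#' @export
mmej_fraction <- function(dist, mu_min = 2L, context = NULL, cut = NULL) {
  del <- dist$kind == "deletion"
  miss <- del & is.na(dist$mh)
  if (any(miss)) {
    if (is.null(context))
      stop("deletions lack microhomology annotations and no context was supplied")
    if (is.null(cut)) cut <- nchar(context) %/% 2L
    for (i in which(miss))
      dist$mh[i] <- mh_length(toupper(context), cut, dist$del_start[i],
                              dist$length[i])
  }
  tot <- sum(dist$frequency)
  if (tot <= 0) stop("empty distribution")
  sum(dist$frequency[del & dist$mh >= mu_min]) / tot
}

#' Ingest predictor-exported outcome tables
#'
#' Reads editing-outcome tables exported by external outcome predictors into
#' `outcome_dist` objects. The dialect is always stated explicitly, never
#' sniffed:
#' \describe{
#'   \item{`native`}{this package's outcome-table CSV (see
#'     [read_outcome_table()]); frequencies are fractions.}
#'   \item{`indelphi`}{columns `Category` (`del`/`ins`), `Genotype position`
#'     (deletion start offset relative to the cut), `Inserted Bases`,
#'     `Length`, `Predicted frequency` (percent).}
#'   \item{`lindel`, `forecast`}{columns `genotype` and `frequency`
#'     (percent), genotype strings `WT`, `I<len>:<bases>` or
#'     `D<len>:<start>`.}
#' }
#' Percent frequency columns are expected to sum to 100 +/- 0.1 per guide;
#' outside that tolerance a warning is emitted and the table renormalized.
#' An optional `guide_id` column splits multi-guide files; otherwise the
#' `guide_id` argument labels the whole file.
#'
#' @param path table path.
#' @param dialect one of `"native"`, `"indelphi"`, `"lindel"`, `"forecast"`.
#' @param guide_id label used when the file has no `guide_id` column.
#' @return Named list of `outcome_dist` (source `"predicted"`).
#' @export
load_predictions <- function(path,
                             dialect = c("native", "indelphi", "lindel",
                                         "forecast"),
                             guide_id = "guide") {
  dialect <- match.arg(dialect)
  if (dialect == "native")
    return(read_outcome_table(path, source = "predicted", method = "native"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = TRUE,
                        stringsAsFactors = FALSE)
  if (is.null(df$guide_id)) df$guide_id <- guide_id
  parse_group <- function(g) {
    if (dialect == "indelphi") {
      need <- c("Category", "Length", "Predicted.frequency")
      if (!all(need %in% names(g)))
        stop("indelphi dialect requires columns Category, Genotype position, ",
             "Inserted Bases, Length, Predicted frequency")
      kind <- ifelse(g$Category == "del", "deletion",
              ifelse(g$Category == "ins", "insertion", "wildtype"))
      len <- g$Length
      ds <- if (!is.null(g$Genotype.position)) g$Genotype.position else NA
      ib <- if (!is.null(g$Inserted.Bases)) g$Inserted.Bases else NA
      freq <- g$Predicted.frequency
    } else {
      if (!all(c("genotype", "frequency") %in% names(g)))
        stop(dialect, " dialect requires columns genotype, frequency")
      m <- regmatches(g$genotype,
                      regexec("^(WT|([ID])([0-9]+):([-+]?[ACGT0-9]+))$",
                              g$genotype))
      bad <- vapply(m, base::length, integer(1)) == 0L
      if (any(bad)) stop("unparseable genotype strings: ",
                         paste(utils::head(g$genotype[bad]), collapse = ", "))
      op <- vapply(m, function(x) x[3], character(1))
      kind <- ifelse(g$genotype == "WT", "wildtype",
              ifelse(op == "I", "insertion", "deletion"))
      len <- ifelse(kind == "wildtype", 0L,
                    as.integer(vapply(m, function(x) x[4], character(1))))
      arg <- vapply(m, function(x) x[5], character(1))
      ds <- ifelse(kind == "deletion", suppressWarnings(as.integer(arg)), NA)
      ib <- ifelse(kind == "insertion", arg, NA)
      freq <- g$frequency
    }
    tot <- sum(freq)
    if (abs(tot - 100) > 0.1)
      warning(sprintf("guide '%s': frequencies sum to %.3f%%, renormalizing",
                      g$guide_id[1], tot))
    outcome_dist(kind = kind, length = len, frequency = freq / tot,
                 del_start = ds, ins_bases = ib,
                 guide_id = g$guide_id[1], source = "predicted",
                 method = dialect)
  }
  out <- lapply(split(df, df$guide_id), parse_group)
  out[order(names(out))]
}
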