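# Prediction-vs-observation concordance harness: per-guide, pooled and
# frameshift-frequency Pearson correlations, residual analyses, and
# Sanger-deconvolution (ICE-style) averaging.

.pearson <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Per-guide concordance between predicted and observed spectra
#'
#' Pearson correlation over the zero-filled matched frequency vectors of one
#' guide's predicted and observed outcome distributions (both already
#' curated to a common class universe; see
#' [curate_to_reference_classes()] and [normalize_observed()]). Guides with
#' fewer than `min_classes` matched classes are flagged underpowered and no
#' correlation is reported for them.
#'
#' @param pred,obs curated `outcome_dist` objects for the same guide.
#' @param min_classes minimal number of matched outcome classes (default 3).
#' @param min_reads observations built from fewer reads than this (as
#'   recorded in the table's `n_reads` attribute, when present) are flagged
#'   underpowered; shallow few-embryo assays cannot resolve a heterogeneous
#'   spectrum.
#' @return A one-row data frame: `guide_id`, `r`, `p`, `n_classes`,
#'   `underpowered`.
#' @export
guide_concordance <- function(pred, obs, min_classes = 3L,
                              min_reads = 500L) {
  m <- match_outcomes(pred, obs)
  n <- base::length(m$keys)
  n_reads <- attr(obs, "n_reads")
  shallow <- !is.null(n_reads) && n_reads < min_reads
  if (n < min_classes || shallow ||
      stats::sd(m$pred) == 0 || stats::sd(m$obs) == 0) {
    return(data.frame(guide_id = attr(pred, "guide_id"), r = NA_real_,
                      p = NA_real_, n_classes = n, underpowered = TRUE,
                      stringsAsFactors = FALSE))
  }
  pr <- .pearson(m$pred, m$obs)
  data.frame(guide_id = attr(pred, "guide_id"), r = pr$r, p = pr$p,
             n_classes = n, underpowered = FALSE, stringsAsFactors = FALSE)
}

#' Pooled concordance across guides
#'
#' A single Pearson correlation over the concatenation of every guide's
#' matched frequency-vector pairs (all guides simultaneously, not an
#' average of per-guide correlations).
#'
#' @param pairs list of `list(pred =, obs =)` curated distribution pairs.
#' @return List with `r`, `p`, `n_points`.
#' @export
pooled_concordance <- function(pairs) {
  if (base::length(pairs) == 0L) stop("no prediction/observation pairs")
  ms <- lapply(pairs, function(pr) match_outcomes(pr$pred, pr$obs))
  x <- unlist(lapply(ms, `[[`, "pred"))
  y <- unlist(lapply(ms, `[[`, "obs"))
  pr <- .pearson(x, y)
  list(r = pr$r, p = pr$p, n_points = base::length(x))
}

#' Concordance of cumulative frameshift frequencies
#'
#' Pearson correlation between predicted and observed per-guide cumulative
#' frameshift frequencies, one point per guide.
#'
#' @inheritParams pooled_concordance
#' @return List with `r`, `p`, `n_guides`, and the per-guide frequency
#'   table `frameshift`.
#' @export
frameshift_concordance <- function(pairs) {
  if (base::length(pairs) < 3L)
    stop("frameshift concordance requires at least 3 guides")
  tab <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(guide_id = attr(pr$pred, "guide_id"),
               predicted = cumulative_frameshift(pr$pred),
               observed = cumulative_frameshift(pr$obs),
               stringsAsFactors = FALSE)
  }))
  prs <- .pearson(tab$predicted, tab$observed)
  list(r = prs$r, p = prs$p, n_guides = nrow(tab), frameshift = tab)
}

#' Summarize per-guide concordance over a panel
#'
#' Runs [guide_concordance()] on every pair and reports the mean and SD of r
#' over non-underpowered guides, surfacing how many guides were excluded as
#' underpowered.
#'
#' @inheritParams pooled_concordance
#' @param min_classes,min_reads passed to [guide_concordance()].
#' @return List with `per_guide` (data frame), `mean_r`, `sd_r`,
#'   `n_underpowered`.
#' @export
panel_concordance <- function(pairs, min_classes = 3L, min_reads = 500L) {
  per <- do.call(rbind, lapply(pairs, function(pr)
    guide_concordance(pr$pred, pr$obs, min_classes = min_classes,
                      min_reads = min_reads)))
  ok <- !per$underpowered
  list(per_guide = per,
       mean_r = mean(per$r[ok]),
       sd_r = stats::sd(per$r[ok]),
       n_underpowered = sum(!ok))
}

#' Residuals between predicted and observed class frequencies
#'
#' For each guide, the residual is predicted minus observed frequency of a
#' selected outcome class. Selecting the +1 insertion class recovers the
#' classic signature of predictors that systematically overestimate
#' templated +1 insertions; selecting deletions stratifies residuals by
#' deletion length. Per class, the mean, SD and SEM (= SD / sqrt(n)) over
#' guides are reported.
#'
#' @inheritParams pooled_concordance
#' @param class_selector `"plus1_insertion"` or `"deletion_by_length"`.
#' @return List with `residuals` (guide x class long data frame) and
#'   `summary` (per-class mean/sd/sem/n).
#' @export
residual_analysis <- function(pairs,
                              class_selector = c("plus1_insertion",
                                                 "deletion_by_length")) {
  class_selector <- match.arg(class_selector)
  rows <- list()
  for (pr in pairs) {
    m <- match_outcomes(pr$pred, pr$obs)
    meta <- rbind(pr$pred[, c("genotype_key", "kind", "length")],
                  pr$obs[, c("genotype_key", "kind", "length")])
    meta <- meta[!duplicated(meta$genotype_key), , drop = FALSE]
    meta <- meta[match(m$keys, meta$genotype_key), , drop = FALSE]
    if (class_selector == "plus1_insertion") {
      sel <- meta$kind == "insertion" & meta$length == 1L
      if (!any(sel)) next
      rows[[base::length(rows) + 1L]] <- data.frame(
        guide_id = attr(pr$pred, "guide_id"), class = "plus1_insertion",
        residual = sum(m$pred[sel]) - sum(m$obs[sel]),
        stringsAsFactors = FALSE)
    } else {
      sel <- which(meta$kind == "deletion")
      if (!base::length(sel)) next
      agg_p <- tapply(m$pred[sel], meta$length[sel], sum)
      agg_o <- tapply(m$obs[sel], meta$length[sel], sum)
      rows[[base::length(rows) + 1L]] <- data.frame(
        guide_id = attr(pr$pred, "guide_id"),
        class = paste0("del_", names(agg_p)),
        residual = as.numeric(agg_p) - as.numeric(agg_o),
        stringsAsFactors = FALSE)
    }
  }
  if (!base::length(rows))
    stop("class selector matched no outcome class in any guide")
  res <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(res$residual, res$class), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v),
               sem = stats::sd(v) / sqrt(base::length(v)),
               n = base::length(v))
  }))
  summ$class <- rownames(summ)
  rownames(summ) <- NULL
  list(residuals = res, summary = summ[, c("class", "mean", "sd", "sem", "n")])
}

#' Average Sanger-deconvolution outcome tables across embryos
#'
#' Per-embryo indel spectra inferred by Sanger trace deconvolution are
#' averaged arithmetically per outcome class across at least `min_embryos`
#' injected embryos, restricted to 1-bp insertions and deletions of at most
#' `max_deletion` bp, then renormalized to 1.
#'
#' @param embryo_tables list of `outcome_dist` objects for one guide, one
#'   per embryo.
#' @param min_embryos minimal number of embryos (default 3).
#' @param max_deletion largest deletion length retained (default 20 bp).
#' @return Averaged, filtered, renormalized `outcome_dist` (source
#'   `"observed"`, method `"ice_average"`).
#' @export
ice_average <- function(embryo_tables, min_embryos = 3L, max_deletion = 20L) {
  gid <- attr(embryo_tables[[1]], "guide_id")
  if (base::length(embryo_tables) < min_embryos)
    stop(sprintf("guide '%s': %d embryo tables supplied, need at least %d",
                 gid, base::length(embryo_tables), min_embryos))
  ids <- vapply(embryo_tables, attr, character(1), "guide_id")
  if (base::length(unique(ids)) != 1L)
    stop("embryo tables belong to different guides: ",
         paste(unique(ids), collapse = ", "))
  all_rows <- do.call(rbind, lapply(embryo_tables, function(d)
    as.data.frame(d)[, c("kind", "length", "del_start", "ins_bases", "mh",
                         "genotype_key", "frequency")]))
  n_emb <- base::length(embryo_tables)
  # mean frequency per class: absent classes count as 0 in that embryo
  mean_f <- tapply(all_rows$frequency, all_rows$genotype_key, sum) / n_emb
  meta <- all_rows[!duplicated(all_rows$genotype_key), , drop = FALSE]
  meta$frequency <- as.numeric(mean_f[meta$genotype_key])
  keep <- (meta$kind == "insertion" & meta$length == 1L) |
    (meta$kind == "deletion" & meta$length <= max_deletion)
  meta <- meta[keep, , drop = FALSE]
  if (!nrow(meta) || sum(meta$frequency) <= 0)
    stop(sprintf("guide '%s': no outcomes survive the ICE class filter", gid))
  outcome_dist(kind = meta$kind, length = meta$length,
               frequency = meta$frequency / sum(meta$frequency),
               del_start = meta$del_start, ins_bases = meta$ins_bases,
               mh = meta$mh, guide_id = gid, source = "observed",
               method = "ice_average")
}
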