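# Workflow drivers tying the modules into the three end-to-end analyses:
# guide design over CDS FASTA, prediction-vs-observation evaluation, and
# mosaic simulation with the prior transform. Each run writes CSV outputs
# with fixed column order plus a JSON provenance record (config echo,
# package version, seeds), so any run is reproducible from its record.

.write_provenance <- function(out_dir, workflow, config) {
  rec <- list(workflow = workflow,
              package = "mosaicKO",
              version = as.character(utils::packageVersion("mosaicKO")),
              config = config)
  jsonlite::write_json(rec, file.path(out_dir, paste0(workflow, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

#' Run the guide-design workflow
#'
#' FASTA in, classified guide table and threshold report out.
#'
#' @param cds_fasta FASTA path (or named sequences / `DNAStringSet`).
#' @param coeffs activity-model coefficient CSV path, or an
#'   `activity_model`.
#' @param out_dir output directory (created if needed).
#' @param predictor outcome predictor, as in [score_guides()].
#' @param t7_filter,t7_allow_ga passed to [scan_targets()].
#' @param ko_threshold,activity_threshold,mmej_threshold passed to
#'   [quadrant_report()].
#' @return Invisibly, the [design_guides()] result.
#' @export
run_design <- function(cds_fasta, coeffs, out_dir,
                       predictor = function(ctx, id)
                         predict_outcomes_mh(ctx, guide_id = id),
                       t7_filter = TRUE, t7_allow_ga = FALSE,
                       ko_threshold = 75, activity_threshold = 50,
                       mmej_threshold = 90) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- if (inherits(coeffs, "activity_model")) coeffs
           else load_activity_model(coeffs)
  res <- design_guides(cds_fasta, model, predictor = predictor,
                       t7_filter = t7_filter, t7_allow_ga = t7_allow_ga,
                       ko_threshold = ko_threshold,
                       activity_threshold = activity_threshold,
                       mmej_threshold = mmej_threshold)
  if (!is.null(res$guides)) {
    cols <- c("gene_id", "guide_id", "protospacer", "pam", "strand",
              "cut_pos", "activity", "frameshift_freq", "mmej", "ko_score",
              "highest_in_class", "lowest_in_class")
    utils::write.csv(res$guides[, cols], file.path(out_dir, "guides.csv"),
                     row.names = FALSE, quote = FALSE)
    rep <- res$report
    utils::write.csv(
      data.frame(metric = c("n_genes", "n_guides", "frac_genes_highest_pass",
                            "frac_highest_mmej"),
                 value = c(rep$n_genes, rep$n_guides,
                           rep$frac_genes_highest_pass,
                           rep$frac_highest_mmej)),
      file.path(out_dir, "design_report.csv"), row.names = FALSE,
      quote = FALSE)
  }
  .write_provenance(out_dir, "design",
                    list(cds_fasta = if (is.character(cds_fasta) &&
                                         base::length(cds_fasta) == 1L)
                           cds_fasta else "<in-memory>",
                         t7_filter = t7_filter, t7_allow_ga = t7_allow_ga,
                         thresholds = c(ko = ko_threshold,
                                        activity = activity_threshold,
                                        mmej = mmej_threshold)))
  invisible(res)
}

#' Run the prediction-vs-observation evaluation workflow
#'
#' Ingests predicted and observed outcome tables, applies the observed-side
#' filter and the 99%-cumulative curation against each guide's prediction,
#' and reports per-guide, pooled and frameshift-frequency concordance plus
#' +1-insertion residuals.
#'
#' @param pred named list of predicted `outcome_dist` (or a table path plus
#'   `pred_dialect`).
#' @param obs named list of observed `outcome_dist` (or a table path;
#'   native dialect), wildtype included.
#' @param out_dir output directory.
#' @param pred_dialect dialect for a `pred` path (see [load_predictions()]).
#' @param min_classes underpowered threshold for per-guide correlations.
#' @return Invisibly, a list with `per_guide`, `pooled`, `frameshift`,
#'   `residuals`, `n_underpowered`.
#' @export
run_evaluate <- function(pred, obs, out_dir, pred_dialect = "native",
                         min_classes = 3L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(pred)) pred <- load_predictions(pred, pred_dialect)
  if (is.character(obs)) obs <- read_outcome_table(obs, source = "observed",
                                                   method = "native")
  missing_obs <- setdiff(names(pred), names(obs))
  missing_pred <- setdiff(names(obs), names(pred))
  if (base::length(missing_obs) || base::length(missing_pred))
    stop("guide-id mismatch between sides; missing observations: [",
         paste(missing_obs, collapse = ", "), "], missing predictions: [",
         paste(missing_pred, collapse = ", "), "]")
  pairs <- lapply(names(pred), function(g) {
    o <- normalize_observed(obs[[g]])
    list(pred = curate_to_reference_classes(pred[[g]], pred[[g]]),
         obs = curate_to_reference_classes(o, pred[[g]]))
  })
  names(pairs) <- names(pred)
  panel <- panel_concordance(pairs, min_classes = min_classes)
  pooled <- pooled_concordance(pairs)
  fs <- frameshift_concordance(pairs)
  resid <- residual_analysis(pairs, "plus1_insertion")
  utils::write.csv(panel$per_guide, file.path(out_dir, "per_guide.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fs$frameshift, file.path(out_dir, "frameshift.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(resid$summary, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(metric = c("pooled_r", "pooled_p", "frameshift_r",
                          "frameshift_p", "mean_per_guide_r",
                          "sd_per_guide_r", "n_underpowered"),
               value = c(pooled$r, pooled$p, fs$r, fs$p, panel$mean_r,
                         panel$sd_r, panel$n_underpowered)),
    file.path(out_dir, "summary.csv"), row.names = FALSE, quote = FALSE)
  .write_provenance(out_dir, "evaluate",
                    list(n_guides = base::length(pairs),
                         pred_dialect = pred_dialect,
                         min_classes = min_classes))
  invisible(list(per_guide = panel$per_guide, pooled = pooled,
                 frameshift = fs, residuals = resid,
                 n_underpowered = panel$n_underpowered))
}

#' Run the mosaic-simulation workflow
#'
#' Simulates a mosaic embryo for the given efficiency and frameshift
#' frequency, compares it with the analytic expectation, and (optionally)
#' pushes a frameshift prior through the biallelic transform and reports
#' the tail probability above a threshold.
#'
#' @param e per-allele efficiency.
#' @param f frameshift frequency (scalar or mutant-only `outcome_dist`).
#' @param n_cells cells in the simulated mosaic.
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @param prior optional [frameshift_prior()].
#' @param threshold tail threshold for the transformed prior (default 0.8).
#' @param prior_n_cells cells used in the finite-cell transform mode
#'   (default `Inf`, the analytic pushforward).
#' @return Invisibly, a list with `expected`, `simulated` and optionally
#'   `tail_probability`.
#' @export
run_simulate <- function(e, f, n_cells = 100000L, seed = 1L, out_dir,
                         prior = NULL, threshold = 0.8,
                         prior_n_cells = Inf) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_scalar <- if (inherits(f, "outcome_dist")) cumulative_frameshift(f) else f
  exp_m <- expected_mosaic(e, f_scalar, n_cells)
  sim <- simulate_mosaic(mosaic_config(n_cells = n_cells, e = e, f = f,
                                       seed = seed))
  tab <- data.frame(class = names(exp_m$fractions),
                    expected = as.numeric(exp_m$fractions),
                    simulated = as.numeric(sim$fractions))
  utils::write.csv(tab, file.path(out_dir, "mosaic.csv"), row.names = FALSE,
                   quote = FALSE)
  out <- list(expected = exp_m, simulated = sim)
  if (!is.null(prior)) {
    td <- transform_prior(prior, e = e, n_cells = prior_n_cells)
    out$tail_probability <- tail_probability(td, threshold)
    utils::write.csv(
      data.frame(metric = c("threshold", "tail_probability"),
                 value = c(threshold, out$tail_probability)),
      file.path(out_dir, "tail.csv"), row.names = FALSE, quote = FALSE)
  }
  .write_provenance(out_dir, "simulate",
                    list(e = e, f = f_scalar, n_cells = n_cells, seed = seed,
                         threshold = threshold,
                         prior_n_cells = if (is.infinite(prior_n_cells))
                           "Inf" else prior_n_cells))
  invisible(out)
}
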