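# Analytic and Monte-Carlo models of the mosaic F0 embryo.
#
# Every cell of the embryo carries two alleles. Each allele is edited
# independently with probability e (per-allele on-target efficiency); each
# edited allele acquires a frameshift outcome with probability f (the
# guide's frameshift frequency), or by sampling a full outcome
# distribution. A cell is a complete protein knockout only when both
# alleles carry frameshift mutations.

.check_ef <- function(e, f = NULL) {
  if (any(e < 0 | e > 1)) stop("efficiency e must lie in [0, 1]")
  if (!is.null(f) && any(f < 0 | f > 1))
    stop("frameshift frequency f must lie in [0, 1]")
  invisible(TRUE)
}

#' Probability that a cell is a biallelic frameshift mutant
#'
#' With per-allele editing probability `e` and per-edited-allele frameshift
#' probability `f`, both alleles of a cell independently end up frameshifted
#' with probability `(e * f)^2`. At full efficiency (`e = 1`) this reduces
#' to `f^2`: the quadratic relationship that makes biallelic knockout much
#' rarer than the frameshift frequency itself (f = 0.80 gives 0.64).
#'
#' @param e per-allele on-target efficiency in \[0, 1\].
#' @param f frameshift frequency in \[0, 1\].
#' @return Probability in \[0, 1\]; vectorized.
#' @export
biallelic_frameshift_prob <- function(e, f) {
  .check_ef(e, f)
  (e * f)^2
}

#' Expected cell-class composition of a mosaic embryo
#'
#' Closed-form per-cell class probabilities under the two-allele model:
#' biallelic frameshift `(e f)^2`; biallelic edited but retaining at least
#' one in-frame allele `e^2 (1 - f^2)` (so the two biallelic classes total
#' `e^2`); monoallelic edited `2 e (1 - e)`; unedited `(1 - e)^2`.
#'
#' @inheritParams biallelic_frameshift_prob
#' @param n_cells number of cells used for expected counts.
#' @return A `mosaic_summary`: list with `fractions` and `counts` (expected,
#'   possibly non-integer) over the four classes, plus `e`, `f`, `n_cells`.
#' @export
expected_mosaic <- function(e, f, n_cells = 100L) {
  .check_ef(e, f)
  stopifnot(n_cells >= 1)
  fr <- c(biallelic_frameshift = (e * f)^2,
          biallelic_with_inframe = e^2 * (1 - f^2),
          monoallelic_edited = 2 * e * (1 - e),
          unedited = (1 - e)^2)
  structure(list(fractions = fr, counts = fr * n_cells,
                 e = e, f = f, n_cells = n_cells, simulated = FALSE),
            class = "mosaic_summary")
}

#' @export
print.mosaic_summary <- function(x, ...) {
  cat(sprintf("mosaic_summary (%s): e = %.3f, f = %.3f, n_cells = %d\n",
              if (x$simulated) "simulated" else "expected", x$e, x$f,
              as.integer(x$n_cells)))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Configuration for a stochastic mosaic simulation
#'
#' @param n_cells number of cells in the mosaic (each an independent pair of
#'   alleles; no clonal structure is modelled).
#' @param e per-allele editing probability.
#' @param f scalar frameshift frequency, or a mutant-only `outcome_dist`
#'   from which each edited allele's repair product is sampled (its
#'   [cumulative_frameshift()] then plays the role of `f`).
#' @param seed integer RNG seed recorded with the run.
#' @return A `mosaic_config` list.
#' @export
mosaic_config <- function(n_cells = 100L, e = 1, f = 0.8, seed = 1L) {
  .check_ef(e, if (is.numeric(f)) f else NULL)
  stopifnot(n_cells >= 1)
  structure(list(n_cells = as.integer(n_cells), e = e, f = f,
                 seed = as.integer(seed)),
            class = "mosaic_config")
}

#' Simulate a mosaic embryo cell by cell
#'
#' Draws, for every cell, two independent allele states: edited with
#' probability `e`, and if edited, frameshifted with probability `f` (or an
#' outcome sampled from a full distribution when `config$f` is an
#' `outcome_dist`). Reproducible for a fixed seed.
#'
#' @param config a [mosaic_config()].
#' @return A `mosaic_summary` with realized `fractions` and integer
#'   `counts`, plus a `cells` data frame of per-cell allele records
#'   (`a1_edited`, `a1_frameshift`, `a2_edited`, `a2_frameshift`, `class`).
#' @export
simulate_mosaic <- function(config) {
  stopifnot(inherits(config, "mosaic_config"))
  n <- config$n_cells
  e <- config$e
  set.seed(config$seed)
  a1e <- stats::runif(n) < e
  a2e <- stats::runif(n) < e
  if (inherits(config$f, "outcome_dist")) {
    dist <- config$f
    if (any(dist$kind == "wildtype"))
      stop("outcome distribution supplied as f must be mutant-only")
    fs_flag <- is_frameshift(dist)
    pr <- dist$frequency / sum(dist$frequency)
    draw_fs <- function(k) {
      if (k == 0L) return(logical(0))
      fs_flag[sample.int(nrow(dist), k, replace = TRUE, prob = pr)]
    }
    f_scalar <- sum(pr[fs_flag])
  } else {
    draw_fs <- function(k) stats::runif(k) < config$f
    f_scalar <- config$f
  }
  a1f <- logical(n); a1f[a1e] <- draw_fs(sum(a1e))
  a2f <- logical(n); a2f[a2e] <- draw_fs(sum(a2e))
  n_edited <- a1e + a2e
  class <- ifelse(n_edited == 0L, "unedited",
           ifelse(n_edited == 1L, "monoallelic_edited",
           ifelse(a1f & a2f, "biallelic_frameshift",
                  "biallelic_with_inframe")))
  lev <- c("biallelic_frameshift", "biallelic_with_inframe",
           "monoallelic_edited", "unedited")
  counts <- table(factor(class, levels = lev))
  fr <- as.numeric(counts) / n
  names(fr) <- lev
  structure(list(fractions = fr, counts = setNames(as.integer(counts), lev),
                 e = e, f = f_scalar, n_cells = n, seed = config$seed,
                 simulated = TRUE,
                 cells = data.frame(a1_edited = a1e, a1_frameshift = a1f,
                                    a2_edited = a2e, a2_frameshift = a2f,
                                    class = class)),
            class = "mosaic_summary")
}

# ---- frameshift-frequency priors and their pushforward ---------------------

#' Priors over the frameshift frequency of a randomly designed guide
#'
#' A `frameshift_prior` is a discrete distribution over the frameshift
#' frequency f in \[0, 1\]: atoms `f` with masses `mass` summing to 1. It
#' stands for the population distribution of f across candidate target
#' sites (empirical histograms of genome-scale predictions, or simple
#' parametric stand-ins for testing).
#'
#' @param f atom locations in \[0, 1\].
#' @param mass non-negative masses; normalized to sum to 1.
#' @return A `frameshift_prior`.
#' @export
frameshift_prior <- function(f, mass = rep(1, base::length(f))) {
  if (base::length(f) == 0L) stop("empty prior")
  if (any(f < 0 | f > 1)) stop("prior support must lie in [0, 1]")
  if (any(mass < 0) || sum(mass) <= 0) stop("invalid prior masses")
  structure(list(f = as.numeric(f), mass = mass / sum(mass)),
            class = "frameshift_prior")
}

#' @rdname frameshift_prior
#' @param n_atoms number of equal-mass atoms placed at bin midpoints of a
#'   uniform grid on \[0, 1\].
#' @export
prior_uniform <- function(n_atoms = 10000L) {
  frameshift_prior(f = (seq_len(n_atoms) - 0.5) / n_atoms)
}

#' @rdname frameshift_prior
#' @param at location of a single point mass.
#' @export
prior_point <- function(at) frameshift_prior(f = at)

#' Pushforward of a frameshift prior to biallelic-frameshift cell fractions
#'
#' For a guide with frameshift frequency f and per-allele efficiency e, each
#' cell of the mosaic is a biallelic frameshift mutant with probability
#' `p = (e f)^2`. Given a prior over f (the population of candidate
#' guides), this transform yields the induced distribution of the
#' biallelic-frameshift cell fraction of the embryo:
#' \itemize{
#'   \item infinite-cells mode (`n_cells = Inf`): the deterministic
#'     pushforward of the prior under `f -> (e f)^2`;
#'   \item finite-cells mode: the mixture over the prior of
#'     `Binomial(n_cells, p) / n_cells`, capturing the extra spread of a
#'     small mosaic (the default schematic mosaic has 100 cells).
#' }
#'
#' @param prior a [frameshift_prior()].
#' @param e per-allele efficiency in \[0, 1\].
#' @param n_cells number of cells, or `Inf` for the analytic pushforward.
#' @return A `fraction_dist`: list with `support` (cell fractions) and
#'   `mass`, sorted by support, masses summing to 1.
#' @export
transform_prior <- function(prior, e = 1, n_cells = Inf) {
  stopifnot(inherits(prior, "frameshift_prior"))
  .check_ef(e)
  p <- (e * prior$f)^2
  if (is.infinite(n_cells)) {
    support <- p
    mass <- prior$mass
  } else {
    n <- as.integer(n_cells)
    stopifnot(n >= 1)
    k <- 0:n
    mass_k <- rowSums(vapply(seq_along(p),
                             function(i) prior$mass[i] * stats::dbinom(k, n, p[i]),
                             numeric(n + 1L)))
    support <- k / n
    mass <- mass_k
  }
  agg <- tapply(mass, support, sum)
  support <- as.numeric(names(agg))
  o <- order(support)
  structure(list(support = support[o], mass = as.numeric(agg)[o],
                 e = e, n_cells = n_cells),
            class = "fraction_dist")
}

#' Tail probability of a transformed fraction distribution
#'
#' Mass at or above a threshold (inclusive boundary): the probability that a
#' randomly designed guide yields at least the given fraction of biallelic
#' frameshift mutant cells in the mosaic.
#'
#' @param dist a `fraction_dist` from [transform_prior()].
#' @param threshold fraction in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @export
tail_probability <- function(dist, threshold) {
  stopifnot(inherits(dist, "fraction_dist"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  sum(dist$mass[dist$support >= threshold])
}
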