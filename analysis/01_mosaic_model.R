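#!/usr/bin/env Rscript
# Mosaic knockout model: how per-allele efficiency (e) and frameshift
# frequency (f) shape the cellular composition of an F0 embryo.
#
# Finding: the biallelic-frameshift fraction is (e*f)^2, so penetrance
# falls off quadratically: a guide with f = 0.80 at full efficiency yields
# only 64% complete-knockout cells, and at e = 0.5 a mere 16%. Monte-Carlo
# mosaics agree with the closed form to within sampling error.

library(mosaicKO)
dir.create("results", showWarnings = FALSE)

# closed-form composition over an (e, f) grid
grid <- expand.grid(e = seq(0.25, 1, by = 0.25), f = seq(0, 1, by = 0.1))
comp <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  m <- expected_mosaic(grid$e[i], grid$f[i], n_cells = 100L)
  data.frame(e = grid$e[i], f = grid$f[i], t(m$fractions))
}))
write.csv(comp, "results/mosaic_grid.csv", row.names = FALSE, quote = FALSE)

# the worked example: e = 1, f = 0.80
cat(sprintf("biallelic-frameshift probability at e=1, f=0.80: %.4f\n",
            biallelic_frameshift_prob(1, 0.80)))

# schematic 100-cell mosaics (one per f), plus a deep Monte-Carlo check
set.seed(1)
schematic <- do.call(rbind, lapply(c(0.2, 0.5, 0.8, 1.0), function(f) {
  s <- simulate_mosaic(mosaic_config(n_cells = 100L, e = 1, f = f, seed = 10))
  data.frame(f = f, t(s$counts))
}))
write.csv(schematic, "results/mosaic_schematic_100cells.csv",
          row.names = FALSE, quote = FALSE)

mc <- run_simulate(e = 1, f = 0.80, n_cells = 100000L, seed = 2026,
                   out_dir = "results/mosaic_mc")
cat(sprintf("Monte-Carlo (n=1e5): biallelic-frameshift fraction %.4f (expect 0.6400)\n",
            mc$simulated$fractions[["biallelic_frameshift"]]))
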