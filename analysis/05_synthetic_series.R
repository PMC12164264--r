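#!/usr/bin/env Rscript
# End-to-end validation on a synthetic congeneric series with known ground
# truth: 50 ligands with barrier-controlled off-rates and near-constant
# on-rates; each ligand's landscape is pulled for 120 Brownian-dynamics
# cycles, reduced to dG_QB with bootstrap errors, paired by fingerprint
# similarity, and classified as cliff/noncliff from ddG_QB. Ground-truth
# labels come from the generated K_D values.

library(quasibound)

res <- run_pipeline(spec = series_spec(n_ligands = 50), seed = 1,
                    out_dir = "results/synthetic_series")

cat("Series of", res$summary$n_ligands, "ligands ->", res$summary$n_pairs,
    "pairs,", res$summary$n_cliffs, "true cliffs.\n")
print(res$confusion)
cat(sprintf("MCC vs ground truth: %.2f (threshold %.2f kcal/mol on ddG_QB)\n",
            res$mcc, res$summary$threshold))
cat(sprintf("dG_QB vs ground-truth pK_D: r = %.2f, rho = %.2f;",
            res$correlations$pkd$pearson_r, res$correlations$pkd$spearman_rho),
    sprintf("vs pk_off: r = %.2f.\n", res$correlations$pkoff$pearson_r))
cat(sprintf("dG_QB tracks the generating barriers with r = %.3f.\n",
            cor(res$estimates$dg_qb, res$series$barriers)))
cat("Tables written under results/synthetic_series/.\n")
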