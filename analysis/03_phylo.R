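#!/usr/bin/env Rscript
# Stage 3: phylogenetic comparative analysis of CTmax.
#
# OTU-mean CTmax on the community tree: ancestral state reconstruction,
# phylogenetic correlogram, Pagel's lambda and Blomberg's K (10,000
# randomizations), phylogenetic regression on elevation under BM and OU
# covariance with AIC comparison, the OU evolutionary optimum theta, and
# likelihood-based variance partitioning.

library(thermotree)

phy <- ape::read.tree("results/synthetic/tree.nwk")
assays <- read_assays("results/synthetic/assays.csv")
ctl <- assays[assays$shocked == "no", ]
trait <- tapply(ctl$ct_value, ctl$otu_id, mean)[phy$tip.label]
elev <- tapply(ctl$elevation, ctl$otu_id, mean)[phy$tip.label]

anc <- ancestral_states(phy, trait)
write_output_csv(anc, "results/ancestral_states.csv")
cat(sprintf("Root-state CTmax estimate: %.2f degC\n",
            anc$estimate[anc$node == length(phy$tip.label) + 1]))

cg <- phylo_correlogram(phy, trait, n_classes = 4, n_perm = 999, seed = 1)
write_output_csv(cg, "results/correlogram.csv")
cat("\nCorrelogram (Moran's I by patristic distance class):\n")
print(cg, row.names = FALSE)

sig <- pagel_lambda(phy, trait)
K <- blomberg_k(phy, trait, n_perm = 10000L, seed = 1)
cat(sprintf("\nPagel's lambda = %.3f (LRT p = %.2g); Blomberg's K = %.3f (p = %.4f, %d randomizations)\n",
            sig$lambda, sig$p, K$K, K$p, K$n_perm))

fits <- list(pgls_fit(phy, trait, data.frame(elevation = elev), "BM"),
             pgls_fit(phy, trait, data.frame(elevation = elev), "OU"),
             pgls_fit(phy, trait, data.frame(elevation = elev), "star"))
cmp <- compare_models(fits)
write_output_csv(cmp, "results/model_comparison.csv")
cat("\nModel comparison:\n"); print(cmp, row.names = FALSE)

opt <- suppressWarnings(fit_ou_optimum(phy, trait))
cat(sprintf("\nOU evolutionary optimum theta = %.2f degC (alpha = %.2f, sigma2 = %.2f)%s\n",
            opt$theta, opt$alpha, opt$sigma2,
            if (opt$boundary)
              " [alpha at search boundary: without the elevation predictor the residual is dominated by plot-level scatter, so the intercept-only optimum degenerates towards the sample mean]"
            else ""))

vp <- variance_partition(phy, trait, data.frame(elevation = elev), "OU")
write_output_csv(data.frame(component = names(vp), partial_r2 = as.numeric(vp)),
                 "results/variance_partition.csv")
cat(sprintf("Partial r2: phylogeny %.3f, elevation %.3f\n",
            vp[["phylogeny"]], vp[["elevation"]]))
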