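#!/usr/bin/env Rscript
# Occurrence/distribution descriptors: prevalence ordering, correspondence
# analysis of the wells x analytes matrix, and correlation-matrix PCA.
# Writes results/multivariate/.

library(gwtrace)

fx <- load_study_fixture()
out_dir <- "results/multivariate"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

prev <- prevalence_order(fx)
write_table_csv(prev, file.path(out_dir, "prevalence_order.csv"))
cat("Prevalence ordering by total mass across wells:\n")
print(as.data.frame(prev), digits = 4)
# antimony > selenium > arsenic.

mat <- wells_matrix(fx)
pca <- pca_ordination(mat, standardize = TRUE)
ca <- ca_ordination(mat)

write_table_csv(data.frame(component = seq_along(pca$explained_fraction),
  explained_fraction = pca$explained_fraction),
  file.path(out_dir, "pca_explained.csv"))
write_table_csv(data.frame(well = rownames(pca$row_coords), pca$row_coords),
  file.path(out_dir, "pca_scores.csv"))
write_table_csv(data.frame(analyte = rownames(pca$col_coords), pca$col_coords),
  file.path(out_dir, "pca_loadings.csv"))
write_table_csv(data.frame(well = rownames(ca$row_coords), ca$row_coords),
  file.path(out_dir, "ca_row_coords.csv"))
write_table_csv(data.frame(analyte = rownames(ca$col_coords), ca$col_coords),
  file.path(out_dir, "ca_col_coords.csv"))

cat(sprintf("\nPCA (correlation matrix): components explain %s of the variance\n",
  paste(sprintf("%.1f%%", 100 * pca$explained_fraction), collapse = ", ")))
# The first two components of the default (35 wells x 3 analytes of
# overall means, standardized) carry ~46.6% and ~32.2%.
cat(sprintf("CA total inertia: %.4f; column masses: %s\n",
  ca$total_inertia,
  paste(sprintf("%s %.3f", names(ca$col_mass), ca$col_mass), collapse = ", ")))
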