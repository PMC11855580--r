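#!/usr/bin/env Rscript
# Stage 1 — forward-simulate the mapping cross.
#
# Simulates an F2 of 423 plants from two homozygous parents segregating for
# immature-fruit color at two loci (major on chr10, minor on chr01), selects
# the 13 extreme-yellow / 20 extreme-green bulks, and samples pooled
# sequencing depths at ~5,000 parental-informative markers. Outputs feed
# stage 2 (the genome scan) and stage 4 (phenotype statistics).

suppressMessages(library(pepbsa))

seed <- as.integer(Sys.getenv("PEPBSA_SEED", "42"))
dir.create("results", showWarnings = FALSE)

ds <- simulate_bsa_dataset(seed = seed)

write_variant_table(ds$table, "results/variants.tsv")

rgb <- assign_rgb(ds$pop)
pheno <- merge(ds$pop$pheno, rgb, by = "id")
pheno$green_index <- green_index(pheno$r, pheno$g, pheno$b)
pheno$bulk <- ifelse(pheno$id %in% ds$bulks$yellow, "yellow",
  ifelse(pheno$id %in% ds$bulks$green, "green", "")
)
# genotype codes at the two causal loci, yellow-parent allele counted
ci <- which(ds$pop$map$is_causal)
codes <- c("GG", "GY", "YY")
for (k in seq_along(ci)) {
  locus <- paste0(ds$pop$map$chrom[ci[k]], "_", ds$pop$map$pos[ci[k]])
  pheno[[locus]] <- codes[match(ds$pop$geno[, ci[k]], c(2, 1, 0))]
}
utils::write.csv(pheno, "results/phenotypes.csv", row.names = FALSE)

manifest <- c(
  sprintf("seed\t%d", seed),
  sprintf("n_plants\t%d", nrow(ds$pop$pheno)),
  sprintf("n_markers\t%d", nrow(ds$table)),
  sprintf("bulk_yellow\t%d", length(ds$bulks$yellow)),
  sprintf("bulk_green\t%d", length(ds$bulks$green)),
  sprintf(
    "causal\t%s", paste(ds$truth$chrom, ds$truth$pos, ds$truth$weight,
      sep = ":", collapse = ","
    )
  )
)
writeLines(manifest, "results/simulation_manifest.tsv")

cat("Simulated", nrow(ds$pop$pheno), "F2 plants,", nrow(ds$table), "markers\n")
cat("Grade distribution:\n")
print(table(grade = ds$pop$pheno$grade))
cat(
  "Bulks:", length(ds$bulks$yellow), "yellow /",
  length(ds$bulks$green), "green plants\n"
)
cat("Wrote results/variants.tsv, results/phenotypes.csv\n")
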