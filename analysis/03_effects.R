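#!/usr/bin/env Rscript
# Stage 3 — CDS consequence annotation of the candidate-gene variants.
#
# The three chlorophyll-pathway candidates inside the mapped intervals carry
# one parental variant each. Real reference sequences are not redistributed
# here; synthetic CDS fixtures are engineered to present the same codons at
# the same positions, which is all the annotator consumes.
#
#   CaAPRR2-like : G>A at CDS position 1428, TGG -> TGA premature stop
#   CaLOL1-like  : T>A at CDS position 479, TTC -> TAC missense (Phe -> Tyr),
#                  outside the functional domain
#   CaGLK2-like  : reported as C>A at 247 bp with TCG -> TAG truncating the
#                  protein to 81 aa of 313 — the printed position, codon
#                  change and length are mutually inconsistent (see note
#                  below); annotated here as the TCG -> TAG change at the
#                  codon containing base 247.

suppressMessages(library(pepbsa))
dir.create("results", showWarnings = FALSE)

aprr2 <- synthetic_cds(586,
  codons = c("476" = "TGG"), id = "CaAPRR2_like_synthetic", seed = 101
)
lol1 <- synthetic_cds(350,
  codons = c("160" = "TTC"), id = "CaLOL1_like_synthetic", seed = 102,
  domains = data.frame(name = "zf-LSD1", aa_start = 200, aa_end = 260)
)
# codon 83 spans bases 247-249; TCG there makes base 248 the C that a C>A
# change turns into a TAG stop
glk2 <- synthetic_cds(313,
  codons = c("83" = "TCG"), id = "CaGLK2_like_synthetic", seed = 103,
  domains = data.frame(name = "GARP", aa_start = 110, aa_end = 170)
)

calls <- annotate_variants(
  list(
    CaAPRR2_like_synthetic = aprr2,
    CaLOL1_like_synthetic = lol1,
    CaGLK2_like_synthetic = glk2
  ),
  data.frame(
    cds_id = c(
      "CaAPRR2_like_synthetic", "CaLOL1_like_synthetic",
      "CaGLK2_like_synthetic"
    ),
    pos = c(1428, 479, 248),
    ref = c("G", "T", "C"),
    alt = c("A", "A", "A")
  )
)
summary <- truncation_summary(calls)

utils::write.table(calls, "results/effect_calls.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
utils::write.table(summary, "results/truncation_summary.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

print(as.data.frame(summary))
cat(sprintf(
  "\nCaAPRR2-like: stop at codon %d -> %d of %d aa retained (%.1f%%)\n",
  calls$codon_index[1], calls$truncated_protein_length[1],
  calls$full_protein_length[1], 100 * summary$truncation_fraction[1]
))
cat(sprintf(
  "CaLOL1-like: %s %s->%s at residue %d, in functional domain: %s\n",
  calls$consequence[2], calls$ref_aa[2], calls$alt_aa[2],
  calls$codon_index[2], calls$in_domain[2]
))
cat(sprintf(
  "CaGLK2-like: stop at codon %d -> truncation to %d aa.\n",
  calls$codon_index[3], calls$truncated_protein_length[3]
))
cat(
  "Note: the reported GLK2 triplet (position 247 bp, TCG->TAG, 81 aa\n",
  "retained) cannot all hold under the position convention that fits the\n",
  "APRR2 call (1428 bp = codon 476): base 247 starts codon 83, a TCG->TAG\n",
  "stop there needs a change at base 248 and retains 82 aa, while an 81-aa\n",
  "truncation would put the stop at codon 82 (bases 244-246). The call\n",
  "above uses the codon containing the printed position.\n"
)
cat("Wrote results/effect_calls.tsv, results/truncation_summary.tsv\n")
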