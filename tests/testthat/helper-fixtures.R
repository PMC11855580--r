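# Shared fixtures and independent brute-force oracles.

# A deliberately mixed 5-site table: 2 clean parental-informative sites,
# 1 heterozygous parent, 1 same-allele parents, 1 low-depth parent.
toy_variant_table <- function() {
  variant_table(
    tibble::tibble(
      chrom = c("chr01", "chr01", "chr01", "chr02", "chr02"),
      pos = c(100L, 200L, 300L, 150L, 250L),
      ref = c("A", "C", "A", "T", "G"),
      alt = c("G", "T", "G", "C", "A"),
      vtype = "SNP",
      P1_ref = c(30L, 15L, 28L, 25L, 4L),
      P1_alt = c(0L, 15L, 0L, 0L, 0L),
      P2_ref = c(0L, 0L, 27L, 1L, 0L),
      P2_alt = c(28L, 30L, 1L, 24L, 30L),
      D1_ref = c(5L, 10L, 12L, 8L, 9L),
      D1_alt = c(25L, 20L, 18L, 22L, 21L),
      D2_ref = c(20L, 15L, 15L, 18L, 14L),
      D2_alt = c(10L, 15L, 15L, 12L, 16L)
    ),
    chrom_lengths = c(chr01 = 1000, chr02 = 1000)
  )
}

# Random biallelic tables for property tests.
random_variant_table <- function(seed, n = 40) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  rd <- function() as.integer(rpois(n, 15))
  tab <- tibble::tibble(
    chrom = sort(sample(c("chrA", "chrB"), n, replace = TRUE)),
    pos = 0L, ref = ref, alt = unname(alt), vtype = "SNP",
    P1_ref = rd(), P1_alt = as.integer(rbinom(n, 6, 0.3)),
    P2_ref = as.integer(rbinom(n, 6, 0.3)), P2_alt = rd(),
    D1_ref = rd(), D1_alt = rd(), D2_ref = rd(), D2_alt = rd()
  )
  tab <- tab[order(tab$chrom), ]
  tab$pos <- stats::ave(seq_len(n), tab$chrom, FUN = function(i) {
    sort(sample(1e5, length(i)))
  })
  variant_table(tab, chrom_lengths = c(chrA = 1e5, chrB = 1e5))
}

# Row-by-row restatement of the parental-informativeness rule.
filter_oracle <- function(x, min_parent_depth = 10, max_minor_fraction = 0.05) {
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    call1 <- parent_call_oracle(
      x$P1_ref[i], x$P1_alt[i],
      min_parent_depth, max_minor_fraction
    )
    call2 <- parent_call_oracle(
      x$P2_ref[i], x$P2_alt[i],
      min_parent_depth, max_minor_fraction
    )
    keep[i] <- !is.na(call1) && !is.na(call2) && call1 != call2
  }
  keep
}

parent_call_oracle <- function(nref, nalt, min_depth, max_minor) {
  tot <- nref + nalt
  if (tot < min_depth) return(NA_character_)
  if (min(nref, nalt) / tot > max_minor) return(NA_character_)
  if (nref == nalt) return(NA_character_)
  if (nref > nalt) "ref" else "alt"
}

# Brute-force sliding-window means: loop over windows and member sites.
window_oracle <- function(sites, chrom_lengths, window_bp, step_bp) {
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    s <- sites[sites$chrom == chr & !sites$masked & !is.na(sites$value), ]
    for (start in seq(1, len, by = step_bp)) {
      end <- min(start + window_bp, len + 1)
      inside <- s$value[s$pos >= start & s$pos < end]
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = start, end = end,
        n_markers = length(inside),
        value = if (length(inside) > 0) mean(inside) else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

# Brute-force threshold-and-merge interval calling on a window track.
intervals_oracle <- function(windows, quantile) {
  value <- if ("smoothed" %in% names(windows)) windows$smoothed else windows$value
  elig <- windows$eligible & !is.na(value)
  thr <- stats::quantile(value[elig], quantile, names = FALSE)
  w <- windows[elig & value >= thr, ]
  w$v <- value[elig & value >= thr]
  w <- w[order(w$chrom, w$start), ]
  if (nrow(w) == 0) return(data.frame())
  merged <- list()
  cur <- w[1, ]
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && w$start[i] <= cur$end) {
      cur$end <- max(cur$end, w$end[i])
      cur$v <- max(cur$v, w$v[i])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- w[i, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  do.call(rbind, merged)[, c("chrom", "start", "end", "v")]
}

# Minimal 4-sample VCF text fixture.
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2\tD1\tD2",
    "chr01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/0:30,0\t1/1:0,28\t0/1:12,18\t0/1:20,10",
    "chr01\t200\t.\tC\tT,G\t50\tPASS\t.\tGT:AD\t0/0:30,0,0\t1/1:0,28,0\t0/1:12,18,0\t0/1:20,10,0",
    "chr01\t300\t.\tCT\tC\t50\tPASS\t.\tGT:AD\t0/0:25,0\t1/1:0,26\t0/1:10,15\t0/1:18,9"
  ), path)
  path
}

# A tiny f2_population built by hand (bypasses the simulator) so pooled
# depth sampling can be checked at known dosages.
manual_population <- function(geno, chrom = "chrT", positions = NULL) {
  n <- nrow(geno)
  m <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(m) * 1000
  structure(
    list(
      map = tibble::tibble(chrom = chrom, pos = positions, is_causal = FALSE),
      geno = geno,
      pheno = tibble::tibble(
        id = seq_len(n), green_score = rowMeans(geno) / 2,
        grade = 1L
      ),
      genome = genome_model(
        chromosomes = data.frame(chrom = chrom, length = max(positions) + 1000) |>
          stats::setNames(c("name", "length"))
      ),
      model = NULL, seed = NA
    ),
    class = "f2_population"
  )
}

# Deterministic "random fixed locus" probe for null-calibration checks.
local_probe_locus <- function(r) {
  set.seed(90000 + r)
  list(
    chrom = sample(c("chr01", "chr10"), 1),
    pos = runif(1, 1, 50e6)
  )
}

# Small single-chromosome genome for fast population-scale simulations.
tiny_genome <- function(len = 50e6, density = 0.2, name = "chr10") {
  genome_model(
    chromosomes = data.frame(name = name, length = len),
    marker_density = density
  )
}
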