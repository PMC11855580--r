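make_site_table <- function(d1_ref, d1_alt, d2_ref, d2_alt, yellow_is_ref = FALSE) {
  n <- length(d1_ref)
  tab <- variant_table(tibble::tibble(
    chrom = "c", pos = seq_len(n) * 100L, ref = "G", alt = "A", vtype = "SNP",
    P1_ref = 30L, P1_alt = 0L, P2_ref = 0L, P2_alt = 30L,
    D1_ref = d1_ref, D1_alt = d1_alt, D2_ref = d2_ref, D2_alt = d2_alt
  ))
  filter_parental_informative(tab)
}

test_that("SNP-index is the bulk's yellow-allele read fraction, masked at low depth", {
  # yellow allele is alt: D1 pure yellow, D2 10 yellow / 20 green, and a
  # low-depth site
  tab <- make_site_table(
    d1_ref = c(0L, 0L, 3L), d1_alt = c(30L, 30L, 2L),
    d2_ref = c(20L, 20L, 20L), d2_alt = c(10L, 10L, 10L)
  )
  idx <- site_indices(tab, min_depth = 10)
  expect_equal(idx$index_D1[1], 1.0)
  expect_equal(round(idx$index_D2[2], 4), 0.3333)
  expect_true(idx$masked[3])
  expect_true(is.na(idx$index_D1[3]))
  expect_false(is.na(idx$index_D2[3]))
  # delta at the dominant-locus configuration, and the trivial anchors
  expect_equal(round(idx$delta[1], 4), 0.6667)
  expect_equal(delta_index(0.5, 0.5), 0)
  expect_equal(delta_index(0, 1), 1)
  expect_true(is.na(delta_index(NA_real_, 0.3)))
})

test_that("index orientation flips to the complement and delta is invariant", {
  for (seed in 1:3) {
    tab <- filter_parental_informative(random_variant_table(seed))
    y <- site_indices(tab, min_depth = 5, orientation = "yellow")
    g <- site_indices(tab, min_depth = 5, orientation = "green")
    expect_equal(g$index_D1, 1 - y$index_D1)
    expect_equal(g$index_D2, 1 - y$index_D2)
    expect_equal(g$delta, y$delta)
    ok <- !y$masked
    expect_true(all(y$index_D1[ok] >= 0 & y$index_D1[ok] <= 1))
    expect_true(all(y$delta[ok] >= 0 & y$delta[ok] <= 1))
  }
})

test_that("Euclidean distance over nucleotide frequency vectors", {
  tab <- make_site_table(
    d1_ref = c(15L, 0L, 30L), d1_alt = c(15L, 30L, 0L),
    d2_ref = c(10L, 20L, 0L), d2_alt = c(10L, 10L, 28L)
  )
  ed <- site_ed(tab)
  # identical frequency vectors
  expect_equal(ed$ed[1], 0)
  # D1 fixed for the yellow allele, D2 at one third yellow
  expect_equal(round(ed$ed[2], 4), 0.9428)
  expect_equal(round(ed$ed2[2], 4), 0.8889)
  # opposite fixed alleles: the maximum sqrt(2)
  expect_equal(ed$ed[3], sqrt(2))
  expect_equal(ed$ed2[3], 2)
  expect_true(all(ed$ed >= 0 & ed$ed <= sqrt(2) + 1e-12))
})

test_that("sliding windows anchor at 1, are half-open, and mean member sites", {
  sites <- tibble::tibble(
    chrom = "c", pos = c(10L, 500L, 900L), value = c(0.2, 0.4, 0.6),
    masked = FALSE
  )
  w <- sliding_windows(sites, c(c = 1200), window_bp = 1000, step_bp = 1000, min_markers = 1)
  expect_equal(w$value[1], 0.4)
  expect_equal(w$n_markers[1], 3L)
  # a site at exactly start + window_bp belongs to the next window only
  sites2 <- tibble::tibble(chrom = "c", pos = 1001L, value = 1, masked = FALSE)
  w2 <- sliding_windows(sites2, c(c = 2000), window_bp = 1000, step_bp = 1000, min_markers = 1)
  expect_equal(w2$n_markers, c(0L, 1L))
})

test_that("window means equal a brute-force recomputation on random tracks", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200
    sites <- tibble::tibble(
      chrom = sample(c("w1", "w2"), n, replace = TRUE),
      pos = sample(1e6, n), value = runif(n),
      masked = runif(n) < 0.1
    )
    sites <- sites[order(sites$chrom, sites$pos), ]
    cl <- c(w1 = 1e6, w2 = 8e5)
    w <- sliding_windows(sites, cl, window_bp = 2e5, step_bp = 7e4, min_markers = 1)
    o <- window_oracle(sites, cl, window_bp = 2e5, step_bp = 7e4)
    expect_equal(w$n_markers, o$n_markers)
    expect_equal(w$value, o$value)
    expect_equal(w$start, o$start)
    expect_equal(w$end, o$end)
  }
})

test_that("LOESS smoothing reproduces constants and lines, reduces noise", {
  const <- tibble::tibble(chrom = "c", mid = seq(1, 100) * 10, value = 5)
  s <- loess_smooth(const, span = 0.3)
  expect_equal(s$smoothed, rep(5, 100), tolerance = 1e-8)
  ramp <- tibble::tibble(chrom = "c", mid = seq(1, 100) * 10, value = seq(1, 100) / 10)
  s2 <- loess_smooth(ramp, span = 0.3, degree = 1)
  expect_equal(s2$smoothed[10:90], ramp$value[10:90], tolerance = 1e-6)
  # variance reduction on a noisy step
  set.seed(4)
  step_true <- rep(c(0, 1), each = 100)
  noisy <- tibble::tibble(
    chrom = "c", mid = seq_len(200) * 10,
    value = step_true + rnorm(200, 0, 0.3)
  )
  sm <- loess_smooth(noisy, span = 0.2)
  expect_lt(
    max(abs(sm$smoothed[-(95:105)] - step_true[-(95:105)])),
    max(abs(noisy$value - step_true))
  )
  few <- tibble::tibble(chrom = "c", mid = 1:3, value = c(1, 2, 3))
  expect_warning(sf <- loess_smooth(few), "too few points")
  expect_equal(sf$smoothed, sf$value)
})

test_that("interval calling thresholds at the quantile and merges maximally", {
  w <- tibble::tibble(
    chrom = "c", start = seq(0, 99) * 100 + 1, end = seq(0, 99) * 100 + 301,
    n_markers = 20L, value = c(rep(0, 50), 10, rep(0, 49)), eligible = TRUE
  )
  iv <- call_intervals(w, quantile = 0.99)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, w$start[51])
  expect_equal(iv$peak_value, 10)
  # overlapping significant windows merge into one interval
  w2 <- w
  w2$value[52] <- 9
  iv2 <- call_intervals(w2, quantile = 0.98)
  expect_equal(nrow(iv2), 1)
  expect_equal(iv2$end, w2$end[52])
  expect_equal(iv2$n_windows, 2L)
  # ties at the threshold are significant
  w3 <- w
  w3$value[80] <- 10
  iv3 <- call_intervals(w3, quantile = 0.99)
  expect_equal(nrow(iv3), 2)
})

test_that("interval calls match a brute-force oracle and are quantile-monotone", {
  for (seed in 1:3) {
    set.seed(seed)
    w <- tibble::tibble(
      chrom = rep(c("k1", "k2"), each = 100),
      start = rep(seq(0, 99) * 300 + 1, 2),
      end = rep(seq(0, 99) * 300 + 1001, 2),
      n_markers = 15L,
      value = rexp(200), eligible = runif(200) > 0.05
    )
    iv <- call_intervals(w, quantile = 0.9)
    o <- intervals_oracle(w, quantile = 0.9)
    expect_equal(nrow(iv), nrow(o))
    expect_equal(iv$start, o$start)
    expect_equal(iv$end, o$end)
    expect_equal(iv$peak_value, o$v)
    # increasing the quantile never increases interval count or total length
    iv_hi <- call_intervals(w, quantile = 0.97)
    expect_lte(nrow(iv_hi), nrow(iv))
    expect_lte(sum(iv_hi$end - iv_hi$start), sum(iv$end - iv$start))
  }
})

test_that("a simulated two-locus cross is mapped to both causal chromosomes", {
  ds <- simulate_bsa_dataset(seed = 42)
  scan <- run_scan(ds$table, per_chromosome = TRUE, quantile = 0.9)
  iv <- scan$intervals[scan$intervals$statistic == "delta_index", ]
  expect_equal(nrow(iv), 2)
  expect_setequal(iv$chrom, c("chr01", "chr10"))
  for (i in seq_len(nrow(ds$truth))) {
    hit <- iv$chrom == ds$truth$chrom[i] &
      iv$start <= ds$truth$pos[i] & iv$end > ds$truth$pos[i]
    expect_true(any(hit))
  }
  # the ED^2 scan corroborates the delta-index scan
  expect_gt(scan$jaccard, 0.5)
})

test_that("scan output BED round-trips as 0-based half-open intervals", {
  iv <- tibble::tibble(
    chrom = "chr10", start = 10150001, end = 22850001,
    peak_value = 0.91, n_windows = 40L, statistic = "delta_index"
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals_bed(iv, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 10150000)
  expect_equal(bed$V3, 22850000)
  expect_equal(bed$V3 - bed$V2, unname(iv$end - iv$start))
})
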