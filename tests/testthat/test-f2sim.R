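test_that("Haldane map function matches its closed form and limits", {
  expect_equal(haldane_recombination_fraction(0), 0)
  expect_equal(round(haldane_recombination_fraction(50), 4), 0.3161)
  expect_equal(haldane_recombination_fraction(1e6), 0.5, tolerance = 1e-12)
  expect_error(haldane_recombination_fraction(-1), "non-negative")
  # monotone increasing, bounded below 0.5
  d <- seq(0, 400, by = 10)
  r <- haldane_recombination_fraction(d)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 0.5))
})

test_that("noise-free genotype extremes hit the score boundaries and grades", {
  genome <- tiny_genome(density = 0.2)
  model <- color_model(
    loci = list(
      causal_locus("chr10", 20e6, weight = 0.7, dominance = 1),
      causal_locus("chr10", 40e6, weight = 0.3, dominance = 1)
    ),
    noise_sd = 0
  )
  pop <- simulate_f2(genome, model, n = 400, seed = 3)
  ci <- which(pop$map$is_causal)
  top <- pop$geno[, ci[1]] == 2L & pop$geno[, ci[2]] == 2L
  bottom <- pop$geno[, ci[1]] == 0L & pop$geno[, ci[2]] == 0L
  expect_true(any(top) && any(bottom))
  expect_true(all(pop$pheno$green_score[top] == 1))
  expect_true(all(pop$pheno$grade[top] == 6L))
  expect_true(all(pop$pheno$green_score[bottom] == 0))
  expect_true(all(pop$pheno$grade[bottom] == 1L))
  # grades always consistent with the cuts
  expect_equal(
    pop$pheno$grade,
    findInterval(pop$pheno$green_score, model$grade_cuts) + 1L
  )
  # reproducible under the seed
  pop2 <- simulate_f2(genome, model, n = 400, seed = 3)
  expect_identical(pop$geno, pop2$geno)
  expect_equal(pop$pheno, pop2$pheno)
})

test_that("unlinked markers segregate 1:2:1 and linkage decays with distance", {
  genome <- genome_model(
    chromosomes = data.frame(name = "chrL", length = 110e6),
    marker_density = 0.1, cm_per_mb = 2
  )
  model <- color_model(
    loci = list(causal_locus("chrL", 55e6, weight = 1, dominance = 1)),
    noise_sd = 0
  )
  pop <- simulate_f2(genome, model, n = 10000, seed = 11)
  counts <- table(factor(pop$geno[, 1], levels = 0:2))
  gof <- suppressWarnings(chisq.test(counts, p = c(0.25, 0.5, 0.25)))
  expect_gt(gof$p.value, 0.001)
  # allele frequency in the full F2 is 1/2
  expect_equal(mean(pop$geno) / 2, 0.5, tolerance = 0.02)
  # dosage correlation: identical at 0 cM, ~gone by >= 200 cM
  pos <- pop$map$pos
  near <- which.min(abs(pos - (pos[1] + 1e4)))
  far <- which.min(abs(pos - (pos[1] + 101e6))) # 202 cM at 2 cM/Mb
  mid <- which.min(abs(pos - (pos[1] + 10e6))) # 20 cM
  r_near <- cor(pop$geno[, 1], pop$geno[, near])
  r_mid <- cor(pop$geno[, 1], pop$geno[, mid])
  r_far <- cor(pop$geno[, 1], pop$geno[, far])
  expect_gt(r_near, r_mid)
  expect_gt(r_mid, abs(r_far))
  expect_lt(abs(r_far), 0.05)
})

test_that("RGB assignment is an affine, monotone encoding of the green score", {
  expect_equal(unlist(assign_rgb(0, base = c(120, 80, 90), gain = 100)),
               c(r = 120L, g = 80L, b = 90L))
  expect_equal(green_index(120, 80, 90), -50)
  one <- assign_rgb(1, base = c(120, 80, 90), gain = 100)
  expect_equal(unlist(one), c(r = 120L, g = 180L, b = 90L))
  expect_equal(green_index(one$r, one$g, one$b), 150)
  scores <- sort(runif(50, -0.2, 1.2))
  rgb <- assign_rgb(scores)
  idx <- green_index(rgb$r, rgb$g, rgb$b)
  expect_true(all(diff(idx) >= 0))
})

test_that("bulk selection takes the score extremes, disjoint, ties by id", {
  pop <- manual_population(matrix(0L, 5, 1))
  pop$pheno$green_score <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  b <- select_bulks(pop, bulk_design(n_yellow = 2, n_green = 2))
  expect_setequal(b$yellow, c(1, 2))
  expect_setequal(b$green, c(5, 4))
  # tie rule: equal scores everywhere -> lowest ids in both bulks, by rank
  pop$pheno$green_score <- rep(0.5, 5)
  b2 <- select_bulks(pop, bulk_design(n_yellow = 2, n_green = 2))
  expect_equal(b2$yellow, c(1, 2))
  expect_equal(b2$green, c(1, 2))
  expect_error(
    select_bulks(pop, bulk_design(n_yellow = 3, n_green = 3)),
    "too small"
  )
})

test_that("the default 13/20 bulk design selects 33 disjoint plants from 423", {
  pop <- simulate_f2(tiny_genome(density = 0.1), n = 423, seed = 5)
  b <- select_bulks(pop, bulk_design())
  expect_length(b$yellow, 13)
  expect_length(b$green, 20)
  expect_length(intersect(b$yellow, b$green), 0)
})

test_that("pooled depth sampling reproduces bulk allele frequencies", {
  # all individuals homozygous yellow (green dosage 0) -> f_yellow = 1
  pop <- manual_population(matrix(0L, 4, 3))
  b <- list(yellow = 1:2, green = 3:4)
  tab <- sample_bulk_depths(pop, b, bulk_design(n_yellow = 2, n_green = 2), seed = 1)
  expect_true(all(tab$D1_ref == 0))
  expect_true(all(tab$D2_ref == 0))
  # dosages (0,1,2) of the green allele -> yellow-allele f = 0.5
  pop2 <- manual_population(matrix(c(0L, 1L, 2L), 3, 1))
  b2 <- list(yellow = 1:3, green = 1:3)
  f <- (2 - mean(c(0, 1, 2))) / 2
  expect_equal(f, 0.5)
  # binomial sampling property: 1000 sites at f = 0.5, depth 40
  pop3 <- manual_population(matrix(rep(c(0L, 1L, 2L), each = 1000), 3, 1000, byrow = TRUE))
  tab3 <- sample_bulk_depths(pop3, list(yellow = 1:3, green = 1:3),
    bulk_design(n_yellow = 2, n_green = 1, mean_depth = 40),
    seed = 7
  )
  obs <- sum(tab3$D1_alt) / sum(tab3$D1_alt + tab3$D1_ref)
  expect_equal(obs, 0.5, tolerance = 0.02)
  # parents are emitted pure: the table passes the informativeness filter whole
  expect_equal(nrow(filter_parental_informative(tab3)), nrow(tab3))
})

test_that("absorbance simulation inverts the chlorophyll equations exactly", {
  d <- simulate_absorbance(0.26, volume_l = 0.05, dilution = 1, weight_g = 0.1)
  chl <- chlorophyll(d["D649"], d["D665"])
  recovered <- pigment_content(chl$Ct, volume_l = 0.05, dilution = 1, weight_g = 0.1)
  expect_lt(abs(recovered - 0.26), 1e-9)
  expect_equal(unname(simulate_absorbance(0)), c(0, 0))
  # the a:b split that the printed equations imply for D649=0.1, D665=0.2
  d2 <- simulate_absorbance(3.142 * 0.05 / 0.1,
    volume_l = 0.05, weight_g = 0.1,
    ratio_ab = 2.11 / 1.032
  )
  expect_equal(round(unname(d2), 4), c(0.1, 0.2))
})

test_that("seed splitting is deterministic, stage-distinct and 32-bit safe", {
  expect_identical(split_seed(42, "population"), split_seed(42, "population"))
  expect_false(split_seed(42, "population") == split_seed(42, "depths"))
  expect_false(split_seed(42, "replicate", 1) == split_seed(42, "replicate", 2))
  big <- split_seed(2147483646, "depths", 1e6)
  expect_true(is.integer(big) && big >= 0 && big < 2^31)
  expect_error(split_seed(1, "nope"), "unknown stage")
})
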