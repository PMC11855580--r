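#' Genome and trait models for the F2 forward simulator
#'
#' `genome_model()` describes the simulated genome: chromosome names and bp
#' lengths, a uniform marker density (parental-informative markers per Mb) and
#' a uniform genetic-map scaling (cM/Mb). `causal_locus()` places a trait
#' locus with a weight (its share of the green score) and a dominance degree
#' `h` (heterozygote effect as a fraction of the homozygous-green effect).
#' `color_model()` combines the loci with Gaussian environmental noise and
#' five ascending grade cuts that bin the green score into six color grades
#' (1 = yellow ... 6 = green).
#'
#' The defaults emulate the mapped cross: two chromosomes of 50 Mb at 50
#' markers/Mb and 2 cM/Mb; a major locus (CaGLK2-like, weight 0.7) on chr10
#' and a minor locus (CaAPRR2-like, weight 0.3) on chr01, both with h = 0.6;
#' noise_sd 0.08; grade cuts placed at the quantiles of the resulting score
#' mixture that match the observed F2 grade proportions.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp).
#' @param marker_density Markers per Mb (> 0).
#' @param cm_per_mb Genetic map scaling in cM/Mb.
#' @return `genome_model()`: a list with class `"genome_model"`.
#' @export
genome_model <- function(chromosomes = tibble(
                           name = c("chr01", "chr10"),
                           length = c(50e6, 50e6)
                         ),
                         marker_density = 50, cm_per_mb = 2) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(chromosomes$length > 0), marker_density > 0, cm_per_mb >= 0)
  structure(
    list(
      chromosomes = chromosomes, marker_density = marker_density,
      cm_per_mb = cm_per_mb
    ),
    class = "genome_model"
  )
}

#' @rdname genome_model
#' @param chrom Chromosome name.
#' @param pos Position in bp.
#' @param weight Contribution to the green score, in [0, 1].
#' @param dominance Heterozygote effect `h` in [0, 1] (1 = full dominance of
#'   green).
#' @export
causal_locus <- function(chrom, pos, weight, dominance) {
  stopifnot(weight >= 0, weight <= 1, dominance >= 0, dominance <= 1, pos >= 1)
  list(chrom = chrom, pos = pos, weight = weight, dominance = dominance)
}

#' @rdname genome_model
#' @param loci List of [causal_locus()] objects; weights must sum to 1.
#' @param noise_sd Standard deviation of the Gaussian environmental noise on
#'   the green score.
#' @param grade_cuts Five strictly ascending score thresholds defining the six
#'   grades.
#' @export
color_model <- function(loci = list(
                          causal_locus("chr10", 25e6, weight = 0.7, dominance = 0.6),
                          causal_locus("chr01", 25e6, weight = 0.3, dominance = 0.6)
                        ),
                        noise_sd = 0.08,
                        grade_cuts = c(0.02, 0.08, 0.265, 0.62, 0.94)) {
  w <- vapply(loci, `[[`, 0, "weight")
  # an empty locus list is allowed: a noise-only (null) phenotype
  if (length(loci) > 0 && abs(sum(w) - 1) > 1e-8) {
    stop("causal-locus weights must sum to 1", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, length(grade_cuts) == 5, !is.unsorted(grade_cuts, strictly = TRUE))
  structure(
    list(loci = loci, noise_sd = noise_sd, grade_cuts = grade_cuts),
    class = "color_model"
  )
}

#' @rdname genome_model
#' @param n_yellow,n_green Bulk sizes (defaults 13 extreme-yellow and 20
#'   extreme-green individuals).
#' @param mean_depth Expected reads per site per bulk (Poisson mean).
#' @export
bulk_design <- function(n_yellow = 13, n_green = 20, mean_depth = 40) {
  stopifnot(n_yellow >= 1, n_green >= 1, mean_depth > 0)
  structure(
    list(
      n_yellow = as.integer(n_yellow), n_green = as.integer(n_green),
      mean_depth = mean_depth
    ),
    class = "bulk_design"
  )
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under no crossover interference: r = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d Genetic distance in cM (>= 0); vectorised.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_recombination_fraction <- function(d) {
  if (any(d < 0)) stop("genetic distance must be non-negative", call. = FALSE)
  (1 - exp(-2 * d / 100)) / 2
}

marker_map <- function(genome, model = NULL) {
  spacing <- 1e6 / genome$marker_density
  maps <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    name <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    pos <- seq(spacing, len, by = spacing)
    tibble(chrom = name, pos = round(pos), is_causal = FALSE)
  })
  map <- dplyr::bind_rows(maps)
  if (!is.null(model)) {
    for (locus in model$loci) {
      hit <- map$chrom == locus$chrom & map$pos == locus$pos
      if (any(hit)) {
        map$is_causal[hit] <- TRUE
      } else {
        map <- dplyr::bind_rows(
          map,
          tibble(chrom = locus$chrom, pos = locus$pos, is_causal = TRUE)
        )
      }
    }
  }
  map <- dplyr::arrange(map, .data$chrom, .data$pos)
  map
}

# One F1 gamete for one chromosome: green-parent allele indicator per marker.
# Crossovers: Poisson(length_cM / 100) count, uniform placement, no
# interference; the starting strand is a fair coin.
sim_gamete <- function(marker_cm, length_cm) {
  k <- rpois(1, length_cm / 100)
  phase <- runif(1) < 0.5
  if (k == 0) {
    return(rep(as.integer(phase), length(marker_cm)))
  }
  breaks <- sort(runif(k, 0, length_cm))
  crossings <- findInterval(marker_cm, breaks)
  as.integer(xor(phase, crossings %% 2 == 1))
}

#' Simulate an F2 population segregating for fruit color
#'
#' Each F2 individual is the union of two gametes drawn from a uniformly
#' heterozygous F1 (crossovers: Poisson count with rate length_cM/100 per
#' chromosome, uniform placement, Haldane model with no interference). The
#' green score is the weighted sum over causal loci of the dosage effect
#' (effect 0 for 0 green alleles, `h` for 1, 1 for 2) plus Gaussian noise;
#' the color grade is the score binned by the model's grade cuts.
#'
#' @param genome A [genome_model()].
#' @param model A [color_model()].
#' @param n Population size (the mapped cross used 423 plants).
#' @param seed Integer seed; the draw is reproducible under a fixed seed.
#' @return An object of class `f2_population`: a list with `map` (tibble
#'   `chrom`, `pos`, `is_causal`), `geno` (n x markers integer matrix of
#'   green-parent allele dosage in 0/1/2), `pheno` (tibble `id`,
#'   `green_score`, `grade`), and the generating models.
#' @export
simulate_f2 <- function(genome = genome_model(), model = color_model(),
                        n = 423, seed = 1) {
  stopifnot(n > 0)
  map <- marker_map(genome, model)
  local_seed(seed, {
    geno <- matrix(0L, nrow = n, ncol = nrow(map))
    for (i in seq_len(nrow(genome$chromosomes))) {
      name <- genome$chromosomes$name[i]
      len_cm <- genome$chromosomes$length[i] / 1e6 * genome$cm_per_mb
      idx <- which(map$chrom == name)
      marker_cm <- map$pos[idx] / 1e6 * genome$cm_per_mb
      for (ind in seq_len(n)) {
        geno[ind, idx] <- sim_gamete(marker_cm, len_cm) +
          sim_gamete(marker_cm, len_cm)
      }
    }
    causal_idx <- vapply(model$loci, function(locus) {
      which(map$chrom == locus$chrom & map$pos == locus$pos)[1]
    }, 0L)
    w <- vapply(model$loci, `[[`, 0, "weight")
    h <- vapply(model$loci, `[[`, 0, "dominance")
    score <- rep(0, n)
    for (j in seq_along(causal_idx)) {
      d <- geno[, causal_idx[j]]
      eff <- ifelse(d == 2L, 1, ifelse(d == 1L, h[j], 0))
      score <- score + w[j] * eff
    }
    if (model$noise_sd > 0) score <- score + rnorm(n, 0, model$noise_sd)
    grade <- findInterval(score, model$grade_cuts) + 1L
    structure(
      list(
        map = map, geno = geno,
        pheno = tibble(id = seq_len(n), green_score = score, grade = grade),
        genome = genome, model = model, seed = seed
      ),
      class = "f2_population"
    )
  })
}

#' @export
print.f2_population <- function(x, ...) {
  cat(
    "<f2_population> ", nrow(x$geno), " individuals, ", ncol(x$geno),
    " markers on ", nrow(x$genome$chromosomes), " chromosome(s)\n",
    sep = ""
  )
  print(table(grade = x$pheno$grade))
  invisible(x)
}

#' Map green scores to RGB fruit color readings
#'
#' Emulates the image-derived RGB phenotyping: the green channel is an affine
#' function of the green score (G = base_G + gain * score, R and B fixed at
#' their base values), so the greenness index 2G - R - B is strictly
#' increasing in the score before channel clipping to [0, 255].
#'
#' @param pop An `f2_population`, or a numeric vector of green scores.
#' @param base Integer RGB triplet at score 0.
#' @param gain Green-channel units per unit score.
#' @return A tibble with columns `r`, `g`, `b` (and the population's `id` when
#'   given a population).
#' @export
assign_rgb <- function(pop, base = c(120, 80, 90), gain = 100) {
  score <- if (inherits(pop, "f2_population")) pop$pheno$green_score else pop
  clip <- function(v) pmin(255L, pmax(0L, as.integer(round(v))))
  out <- tibble(
    r = clip(rep(base[1], length(score))),
    g = clip(base[2] + gain * score),
    b = clip(rep(base[3], length(score)))
  )
  if (inherits(pop, "f2_population")) {
    out <- dplyr::bind_cols(tibble(id = pop$pheno$id), out)
  }
  out
}

#' Select the extreme phenotype bulks
#'
#' The yellow bulk is the `n_yellow` individuals with the lowest green scores;
#' the green bulk is the `n_green` with the highest. Ties are broken by plant
#' id, so selection is deterministic.
#'
#' @param pop An `f2_population`.
#' @param design A [bulk_design()].
#' @return A list with integer id vectors `yellow` and `green` (disjoint).
#' @export
select_bulks <- function(pop, design = bulk_design()) {
  n <- nrow(pop$pheno)
  if (design$n_yellow + design$n_green > n) {
    stop("population too small for the requested bulk sizes", call. = FALSE)
  }
  asc <- order(pop$pheno$green_score, pop$pheno$id)
  desc <- order(-pop$pheno$green_score, pop$pheno$id)
  list(
    yellow = pop$pheno$id[asc[seq_len(design$n_yellow)]],
    green = pop$pheno$id[desc[seq_len(design$n_green)]]
  )
}

#' Sample pooled sequencing depths for the bulks
#'
#' Models pooled DNA sequencing of the bulks: at each marker, the bulk's
#' yellow-parent allele frequency is the mean yellow-allele dosage over bulk
#' members divided by 2 (equal DNA contribution per individual); total depth
#' is Poisson(`mean_depth`) and the yellow-allele read count is
#' Binomial(depth, frequency). Parents are emitted as pure homozygotes at
#' `mean_depth` (P1 all green-parent allele, P2 all yellow-parent allele), so
#' the output passes [filter_parental_informative()] unchanged. The reference
#' allele is the green-parent allele; per-site ref/alt bases are drawn as
#' distinct nucleotides.
#'
#' @param pop An `f2_population`.
#' @param bulks Bulk membership from [select_bulks()].
#' @param design A [bulk_design()].
#' @param seed Integer seed for the depth sampling.
#' @return A [variant_table()] over all markers.
#' @export
sample_bulk_depths <- function(pop, bulks, design = bulk_design(), seed = 1) {
  m <- nrow(pop$map)
  yellow_dose <- 2L - pop$geno # dosage of the yellow-parent allele
  f_d1 <- colMeans(yellow_dose[bulks$yellow, , drop = FALSE]) / 2
  f_d2 <- colMeans(yellow_dose[bulks$green, , drop = FALSE]) / 2
  local_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    depth_d1 <- rpois(m, design$mean_depth)
    depth_d2 <- rpois(m, design$mean_depth)
    y1 <- rbinom(m, depth_d1, f_d1)
    y2 <- rbinom(m, depth_d2, f_d2)
    pd <- as.integer(round(design$mean_depth))
    variant_table(
      tibble(
        chrom = pop$map$chrom, pos = pop$map$pos,
        ref = ref, alt = unname(alt), vtype = "SNP",
        # ref = green-parent allele: P1 pure ref, P2 pure alt (yellow)
        P1_ref = pd, P1_alt = 0L,
        P2_ref = 0L, P2_alt = pd,
        D1_ref = depth_d1 - y1, D1_alt = y1,
        D2_ref = depth_d2 - y2, D2_alt = y2
      ),
      chrom_lengths = stats::setNames(
        pop$genome$chromosomes$length,
        pop$genome$chromosomes$name
      )
    )
  })
}

#' Simulate a full BSA-seq dataset
#'
#' Convenience wrapper running the forward simulation end to end: F2
#' population, extreme-bulk selection, and pooled depth sampling. Stage seeds
#' are derived from the single `seed` via [split_seed()].
#'
#' @inheritParams simulate_f2
#' @param design A [bulk_design()].
#' @return A list with `pop`, `bulks`, `table` (the [variant_table()]) and
#'   `truth` (tibble of causal `chrom`, `pos`).
#' @export
simulate_bsa_dataset <- function(genome = genome_model(), model = color_model(),
                                 n = 423, design = bulk_design(), seed = 1) {
  pop <- simulate_f2(genome, model, n = n, seed = split_seed(seed, "population"))
  bulks <- select_bulks(pop, design)
  table <- sample_bulk_depths(pop, bulks, design, seed = split_seed(seed, "depths"))
  truth <- tibble(
    chrom = vapply(model$loci, `[[`, "", "chrom"),
    pos = vapply(model$loci, `[[`, 0, "pos"),
    weight = vapply(model$loci, `[[`, 0, "weight")
  )
  list(pop = pop, bulks = bulks, table = table, truth = truth, seed = seed)
}

#' Simulate a chlorophyll absorbance reading
#'
#' Inverts the chlorophyll quantification equations: given a true pigment
#' content (mg per g fresh weight) and extraction parameters, finds the
#' cuvette concentration Ct = content * W / (V * D), splits it into
#' chlorophyll a and b at `ratio_ab`, solves the 2x2 linear system of the
#' quantification equations for the two absorbances, and adds optional
#' Gaussian reading noise. With zero noise, [chlorophyll()] and
#' [pigment_content()] recover the true content exactly.
#'
#' @param true_chl_per_g True pigment content in mg per g fresh weight.
#' @param volume_l Extract volume V in litres.
#' @param dilution Dilution factor D.
#' @param weight_g Sample fresh weight W in grams.
#' @param ratio_ab Chlorophyll a : b ratio used to split the total.
#' @param noise_sd Gaussian noise on each absorbance reading.
#' @return Named numeric vector `c(D649 = ..., D665 = ...)`.
#' @export
simulate_absorbance <- function(true_chl_per_g, volume_l = 0.05, dilution = 1,
                                weight_g = 0.1, ratio_ab = 3, noise_sd = 0) {
  stopifnot(true_chl_per_g >= 0, volume_l > 0, dilution > 0, weight_g > 0, ratio_ab > 0)
  ct <- true_chl_per_g * weight_g / (volume_l * dilution)
  ca <- ct * ratio_ab / (1 + ratio_ab)
  cb <- ct / (1 + ratio_ab)
  # Ca = 13.95 D665 - 6.8 D649 ; Cb = 24.96 D649 - 7.32 D665
  m <- rbind(c(-6.8, 13.95), c(24.96, -7.32))
  d <- solve(m, c(ca, cb))
  if (noise_sd > 0) d <- d + rnorm(2, 0, noise_sd)
  c(D649 = d[1], D665 = d[2])
}
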