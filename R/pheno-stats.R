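#' Greenness index from RGB channels
#'
#' The image-derived greenness of a fruit is 2G - R - B: higher values mean
#' greener pericarp. Channels must lie in 0..255; the index may be negative
#' (pure red gives -255).
#'
#' @param r,g,b Channel values in 0..255; vectorised.
#' @return Integer greenness index.
#' @export
green_index <- function(r, g, b) {
  ch <- c(r, g, b)
  if (any(ch < 0 | ch > 255)) {
    stop("RGB channels must be in [0, 255]", call. = FALSE)
  }
  2 * g - r - b
}

#' Chlorophyll quantification from 649/665 nm absorbance
#'
#' Applies the quantification equations for 95% ethanol extracts:
#' Ca = 13.95 D665 - 6.8 D649, Cb = 24.96 D649 - 7.32 D665 (mg/L), and the
#' total Ct both as Ca + Cb and by the direct combined form
#' 18.16 D649 + 6.63 D665 — the two agree identically because the combined
#' coefficients are exactly the sums of the separate ones. Negative
#' concentrations (absorbance pairs outside the model's range) are flagged.
#'
#' @param d649,d665 Absorbance readings at 649 and 665 nm (non-negative);
#'   vectorised.
#' @return Tibble with `Ca`, `Cb`, `Ct` (= Ca + Cb), `Ct_direct` and
#'   `flagged`.
#' @export
chlorophyll <- function(d649, d665) {
  if (any(d649 < 0) || any(d665 < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  ca <- 13.95 * d665 - 6.8 * d649
  cb <- 24.96 * d649 - 7.32 * d665
  tibble(
    Ca = ca, Cb = cb, Ct = ca + cb,
    Ct_direct = 18.16 * d649 + 6.63 * d665,
    flagged = ca < 0 | cb < 0
  )
}

#' Pigment content per gram fresh weight
#'
#' Content (mg/g) = C * V * D / W, with C the cuvette concentration in mg/L,
#' V the extract volume in litres, D the dilution factor and W the sample
#' fresh weight in grams.
#'
#' @param ct Pigment concentration C in mg/L.
#' @param volume_l Extract volume V (L).
#' @param dilution Dilution factor D.
#' @param weight_g Fresh weight W (g); must be positive.
#' @return Pigment content in mg per g fresh weight.
#' @export
pigment_content <- function(ct, volume_l, dilution = 1, weight_g = 0.1) {
  if (any(weight_g <= 0)) stop("fresh weight must be positive", call. = FALSE)
  ct * volume_l * dilution / weight_g
}

#' Normality report for a sample
#'
#' Summary used for the grade-distribution normality table: mean, sample SD
#' (n - 1), adjusted Fisher-Pearson skewness
#' G1 = g1 * sqrt(n(n-1)) / (n-2), adjusted excess kurtosis
#' G2 = ((n+1) g2 + 6)(n-1) / ((n-2)(n-3)) (g1, g2 from 1/n central
#' moments), and the Shapiro-Wilk W and p (Royston's small-sample
#' algorithm, as implemented in [stats::shapiro.test()]). Constant input has
#' no defined W; it is reported as `NA`.
#'
#' @param values Numeric sample, n >= 3.
#' @return A one-row tibble: `n`, `mean`, `sd`, `skewness`, `kurtosis`, `W`,
#'   `p_value`.
#' @export
normality_report <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    return(tibble(
      n = n, mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_,
      W = NA_real_, p_value = NA_real_
    ))
  }
  g1 <- mean((values - m)^3) / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- mean((values - m)^4) / m2^2 - 3
  kurt <- if (n > 3) ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) else NA_real_
  sw <- shapiro.test(values)
  tibble(
    n = n, mean = m, sd = s, skewness = skew, kurtosis = kurt,
    W = unname(sw$statistic), p_value = sw$p.value
  )
}

#' Genotype-by-grade contingency table
#'
#' Cross-tabulates per-plant genotype codes at a marker locus (YY = homozygous
#' yellow-parent, GY = heterozygous, GG = homozygous green-parent) against
#' color grades, with row and column totals appended.
#'
#' @param genotypes Character vector of codes in {YY, GY, GG}.
#' @param grades Integer grades 1..`n_grades`, same length.
#' @param n_grades Number of grade columns (default 6).
#' @return Integer matrix (rows GG, GY, YY + Total; columns grades + Total).
#' @export
grade_table <- function(genotypes, grades, n_grades = 6) {
  stopifnot(length(genotypes) == length(grades))
  levels_g <- c("GG", "GY", "YY")
  bad <- setdiff(unique(genotypes), levels_g)
  if (length(bad) > 0) {
    stop("unknown genotype code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(
    genotype = factor(genotypes, levels = levels_g),
    grade = factor(grades, levels = seq_len(n_grades))
  )
  m <- as.matrix(unclass(tab))
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Chi-square goodness-of-fit test against a segregation ratio
#'
#' Pearson GOF of observed genotype counts against an expected Mendelian
#' ratio (default 1:2:1 for an F2), df = classes - 1.
#'
#' @param counts Observed counts, e.g. `c(GG = 100, GY = 210, YY = 113)`.
#' @param ratio Expected ratio, same length (default `c(1, 2, 1)`).
#' @return A list with `chisq`, `df` and `p_value`.
#' @export
segregation_test <- function(counts, ratio = c(1, 2, 1)) {
  stopifnot(length(counts) == length(ratio), sum(counts) > 0)
  ct <- suppressWarnings(chisq.test(counts, p = ratio / sum(ratio)))
  list(
    chisq = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Mutation-by-phenotype association in an accession panel
#'
#' For a 2x2 table of mutation presence (rows) by fruit color (columns),
#' returns the odds ratio (a d) / (b c) — with the Haldane-Anscombe +0.5
#' correction applied to every cell if and only if any cell is zero — and
#' the two-sided Fisher exact p-value by hypergeometric enumeration.
#'
#' @param tbl 2x2 matrix of non-negative integer counts, conventionally
#'   `rbind(mutated = c(yellow, green), wildtype = c(yellow, green))`.
#' @return A list with `odds_ratio`, `corrected` (whether +0.5 was applied)
#'   and `p_value`.
#' @export
accession_association <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(identical(dim(tbl), c(2L, 2L)), all(tbl >= 0))
  if (sum(tbl) == 0) stop("all-zero table", call. = FALSE)
  corrected <- any(tbl == 0)
  t2 <- if (corrected) tbl + 0.5 else tbl
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- fisher.test(tbl)$p.value
  list(odds_ratio = unname(or), corrected = corrected, p_value = p)
}
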