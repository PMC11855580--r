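#' Variant/allele-depth tables
#'
#' The scan's substrate is a table of biallelic variant sites with per-sample
#' allele read depths for four samples: the two parents (P1, green; P2,
#' yellow) and the two F2 extreme bulks (D1, yellow bulk; D2, green bulk).
#' A `variant_table` is a tibble with columns `chrom`, `pos` (1-based bp),
#' `ref`, `alt`, `vtype` ("SNP" or "InDel") and eight integer depth columns
#' `<sample>_ref` / `<sample>_alt`, sorted by `(chrom, pos)`, carrying a named
#' `chrom_lengths` attribute (bp per chromosome).
#'
#' @param x A data frame with the columns above.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp. If
#'   omitted, the maximum observed position per chromosome is used.
#' @return A `variant_table` tibble.
#' @export
variant_table <- function(x, chrom_lengths = NULL) {
  x <- as_tibble(x)
  needed <- c(
    "chrom", "pos", "ref", "alt", "vtype",
    paste0(rep(c("P1", "P2", "D1", "D2"), each = 2), c("_ref", "_alt"))
  )
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("variant table is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_pos <- which(x$pos < 1)
  if (length(bad_pos) > 0) {
    stop("invalid position (pos < 1) in row(s): ", paste(bad_pos, collapse = ", "),
      call. = FALSE
    )
  }
  bad_allele <- which(x$ref == x$alt)
  if (length(bad_allele) > 0) {
    stop("ref equals alt in row(s): ", paste(bad_allele, collapse = ", "),
      call. = FALSE
    )
  }
  x$vtype <- ifelse(nchar(x$ref) == nchar(x$alt), "SNP", "InDel")
  depth_cols <- needed[6:13]
  for (col in depth_cols) {
    if (any(x[[col]] < 0)) stop("negative depth in column ", col, call. = FALSE)
    x[[col]] <- as.integer(x[[col]])
  }
  ord <- order(x$chrom, x$pos)
  if (is.unsorted(ord) || any(ord != seq_len(nrow(x)))) {
    if (!identical(ord, seq_len(nrow(x)))) {
      warning("input sites were not sorted by (chrom, pos); sorting", call. = FALSE)
      x <- x[ord, ]
    }
  }
  dup <- duplicated(x[, c("chrom", "pos", "alt")])
  if (any(dup)) {
    stop("duplicate (chrom, pos, alt) records in row(s): ",
      paste(which(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(x$pos, x$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  attr(x, "chrom_lengths") <- chrom_lengths
  class(x) <- unique(c("variant_table", class(x)))
  x
}

#' @rdname variant_table
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

parse_depth_cell <- function(cell) {
  parts <- strsplit(cell, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  alleles <- vapply(kv, `[[`, "", 1L)
  counts <- suppressWarnings(as.integer(vapply(kv, `[[`, "", 2L)))
  if (anyNA(counts)) return(NULL)
  stats::setNames(counts, alleles)
}

#' Read a variant/allele-depth table
#'
#' Two dialects are supported. The native TSV has a header line
#' `#chrom  pos  ref  alt  vtype  P1  P2  D1  D2` with sample cells written as
#' semicolon-joined `allele:count` pairs (e.g. `"A:30;G:0"`); optional
#' `##contig=<name>:<length>` comment lines above the header carry chromosome
#' lengths. VCF 4.x input must contain exactly four samples with per-sample
#' allele depths in the `AD` FORMAT field; samples named P1/P2/D1/D2 are
#' mapped by name, otherwise the first four columns are taken in that order.
#' Multi-allelic records (a third allele with nonzero depth, or VCF ALT with a
#' comma) are skipped with a warning. Malformed rows are reported with their
#' line number.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` (native dialect) or `"vcf"`.
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") read_variant_vcf(path) else read_variant_tsv(path)
}

read_variant_tsv <- function(path) {
  lines <- readLines(path)
  contig_lines <- grep("^##contig=", lines, value = TRUE)
  chrom_lengths <- NULL
  if (length(contig_lines) > 0) {
    kv <- sub("^##contig=", "", contig_lines)
    parts <- strsplit(kv, ":", fixed = TRUE)
    chrom_lengths <- stats::setNames(
      as.numeric(vapply(parts, `[[`, "", 2L)),
      vapply(parts, `[[`, "", 1L)
    )
  }
  header_idx <- grep("^#chrom\t", lines)
  if (length(header_idx) != 1) {
    stop("native TSV must have a single '#chrom' header line", call. = FALSE)
  }
  header <- strsplit(sub("^#", "", lines[header_idx]), "\t")[[1]]
  samples <- c("P1", "P2", "D1", "D2")
  if (!all(samples %in% header)) {
    stop(
      "missing sample columns: ",
      paste(setdiff(samples, header), collapse = ", "),
      call. = FALSE
    )
  }
  body_idx <- setdiff(seq_along(lines), c(grep("^##", lines), header_idx))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  rows <- vector("list", length(body_idx))
  skipped <- integer(0)
  for (i in seq_along(body_idx)) {
    lineno <- body_idx[i]
    f <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop("line ", lineno, ": expected ", length(header), " fields, got ",
        length(f),
        call. = FALSE
      )
    }
    rec <- stats::setNames(as.list(f), header)
    pos <- suppressWarnings(as.integer(rec$pos))
    if (is.na(pos) || pos < 1) {
      stop("line ", lineno, ": invalid position '", rec$pos, "'", call. = FALSE)
    }
    depths <- lapply(rec[samples], parse_depth_cell)
    if (any(vapply(depths, is.null, TRUE))) {
      stop("line ", lineno, ": malformed allele:count cell", call. = FALSE)
    }
    alleles <- unique(unlist(lapply(depths, names)))
    extra <- setdiff(alleles, c(rec$ref, rec$alt))
    extra_depth <- sum(vapply(depths, function(d) sum(d[names(d) %in% extra]), 0))
    if (extra_depth > 0) {
      skipped <- c(skipped, lineno)
      next
    }
    dd <- lapply(depths, function(d) {
      d[is.na(d)] <- 0L
      v <- c(
        if (rec$ref %in% names(d)) d[[rec$ref]] else 0L,
        if (rec$alt %in% names(d)) d[[rec$alt]] else 0L
      )
      v
    })
    rows[[i]] <- tibble(
      chrom = rec$chrom, pos = pos, ref = rec$ref, alt = rec$alt,
      vtype = rec$vtype,
      P1_ref = dd$P1[1], P1_alt = dd$P1[2],
      P2_ref = dd$P2[1], P2_alt = dd$P2[2],
      D1_ref = dd$D1[1], D1_alt = dd$D1[2],
      D2_ref = dd$D2[1], D2_alt = dd$D2[2]
    )
  }
  if (length(skipped) > 0) {
    warning(
      "skipped ", length(skipped), " multi-allelic row(s) at line(s): ",
      paste(skipped, collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no usable variant rows in ", path, call. = FALSE)
  variant_table(out, chrom_lengths = chrom_lengths)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || ncol(ad) != 4) {
    stop("VCF must carry AD depths for exactly 4 samples (P1, P2, D1, D2)",
      call. = FALSE
    )
  }
  samples <- c("P1", "P2", "D1", "D2")
  if (all(samples %in% colnames(ad))) {
    ad <- ad[, samples, drop = FALSE]
  } else {
    warning("VCF samples are not named P1/P2/D1/D2; using column order",
      call. = FALSE
    )
    colnames(ad) <- samples
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning("skipped ", sum(multi), " multi-allelic VCF record(s)", call. = FALSE)
  }
  keep <- !multi
  split_ad <- function(col) {
    m <- do.call(rbind, lapply(strsplit(col, ",", fixed = TRUE), function(x) {
      as.integer(x[1:2])
    }))
    m[is.na(m)] <- 0L
    m
  }
  ads <- lapply(samples, function(s) split_ad(ad[keep, s]))
  names(ads) <- samples
  meta <- vcf@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  chrom_len <- NULL
  if (length(contig) > 0) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
    if (!anyNA(lens)) chrom_len <- stats::setNames(lens, ids)
  }
  out <- tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"],
    vtype = ifelse(nchar(fix[keep, "REF"]) == nchar(fix[keep, "ALT"]), "SNP", "InDel"),
    P1_ref = ads$P1[, 1], P1_alt = ads$P1[, 2],
    P2_ref = ads$P2[, 1], P2_alt = ads$P2[, 2],
    D1_ref = ads$D1[, 1], D1_alt = ads$D1[, 2],
    D2_ref = ads$D2[, 1], D2_alt = ads$D2[, 2]
  )
  variant_table(out, chrom_lengths = chrom_len)
}

#' Write a variant table in the native TSV dialect
#'
#' Emits `##contig=` length lines, the `#chrom ...` header and one row per
#' site with `allele:count` sample cells; UTF-8, LF line endings. The output
#' round-trips through [read_variant_table()] field-by-field.
#'
#' @param x A [variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  cl <- chrom_lengths(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n", useBytes = TRUE)
  if (!is.null(cl)) {
    wl(sprintf("##contig=%s:%d", names(cl), as.integer(cl)))
  }
  wl("#chrom\tpos\tref\talt\tvtype\tP1\tP2\tD1\tD2")
  cell <- function(ref_allele, alt_allele, nref, nalt) {
    sprintf("%s:%d;%s:%d", ref_allele, nref, alt_allele, nalt)
  }
  wl(sprintf(
    "%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
    x$chrom, x$pos, x$ref, x$alt, x$vtype,
    cell(x$ref, x$alt, x$P1_ref, x$P1_alt),
    cell(x$ref, x$alt, x$P2_ref, x$P2_alt),
    cell(x$ref, x$alt, x$D1_ref, x$D1_alt),
    cell(x$ref, x$alt, x$D2_ref, x$D2_alt)
  ))
  invisible(path)
}

#' Keep only parental-informative sites
#'
#' Retains exactly the sites at which both parents are called homozygous (the
#' minor-allele read fraction is at most `max_minor_fraction` and total depth
#' is at least `min_parent_depth`) and the two parents' called alleles differ.
#' Each retained site is annotated with which allele the yellow parent (P2)
#' carries: `yellow_allele` (the allele string) and `yellow_is_ref`.
#'
#' @param x A [variant_table()].
#' @param min_parent_depth Minimum total read depth per parent for a call.
#' @param max_minor_fraction Maximum minor-allele read fraction for a
#'   homozygous call.
#' @return A filtered [variant_table()] with the annotation columns; may be
#'   empty.
#' @export
filter_parental_informative <- function(x, min_parent_depth = 10,
                                        max_minor_fraction = 0.05) {
  stopifnot(inherits(x, "variant_table"))
  call_parent <- function(nref, nalt) {
    tot <- nref + nalt
    frac_minor <- ifelse(tot > 0, pmin(nref, nalt) / tot, NA_real_)
    ok <- tot >= min_parent_depth & !is.na(frac_minor) &
      frac_minor <= max_minor_fraction & nref != nalt
    ifelse(ok, ifelse(nref > nalt, "ref", "alt"), NA_character_)
  }
  p1 <- call_parent(x$P1_ref, x$P1_alt)
  p2 <- call_parent(x$P2_ref, x$P2_alt)
  keep <- !is.na(p1) & !is.na(p2) & p1 != p2
  out <- x[keep, ]
  out$yellow_is_ref <- p2[keep] == "ref"
  out$yellow_allele <- ifelse(out$yellow_is_ref, out$ref, out$alt)
  cl <- chrom_lengths(x)
  attr(out, "chrom_lengths") <- cl
  class(out) <- unique(c("variant_table", class(out)))
  out
}
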