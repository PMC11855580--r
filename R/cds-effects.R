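#' Coding sequences and their domain maps
#'
#' A coding sequence (CDS) is the spliced ORF from the A of the start codon
#' through the stop codon: length divisible by 3, beginning with ATG, ending
#' with TAA/TAG/TGA, and free of internal in-frame stops. Variant positions
#' are 1-based offsets from the A of ATG, the convention under which a
#' substitution at base 1428 falls on the third base of codon 476.
#'
#' @param bases CDS nucleotide string (A/C/G/T).
#' @param id Sequence identifier.
#' @param domains Optional tibble of functional domains with columns `name`,
#'   `aa_start`, `aa_end` (1-based amino-acid coordinates).
#' @return A `coding_sequence` list.
#' @export
coding_sequence <- function(bases, id = "cds", domains = NULL) {
  bases <- toupper(bases)
  if (nchar(bases) %% 3 != 0) {
    stop("CDS length must be divisible by 3 (", id, ")", call. = FALSE)
  }
  codons <- codon_split(bases)
  if (codons[1] != "ATG") stop("CDS must begin with ATG (", id, ")", call. = FALSE)
  stops <- c("TAA", "TAG", "TGA")
  if (!codons[length(codons)] %in% stops) {
    stop("CDS must end with a stop codon (", id, ")", call. = FALSE)
  }
  if (any(codons[-length(codons)] %in% stops)) {
    stop("CDS has an internal in-frame stop (", id, ")", call. = FALSE)
  }
  if (!is.null(domains)) domains <- as_tibble(domains)
  structure(list(id = id, bases = bases, domains = domains),
    class = "coding_sequence"
  )
}

codon_split <- function(bases) {
  substring(bases, seq(1, nchar(bases), 3), seq(3, nchar(bases), 3))
}

translate_codon <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codon])
  ifelse(is.na(aa), "X", aa)
}

#' Read CDS FASTA (with optional domain side-car TSV)
#'
#' @param fasta Path to a FASTA file of CDS sequences.
#' @param domains_tsv Optional TSV with columns `cds_id`, `name`, `aa_start`,
#'   `aa_end`.
#' @return Named list of [coding_sequence()] objects.
#' @export
read_cds_fasta <- function(fasta, domains_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  dom <- NULL
  if (!is.null(domains_tsv)) {
    dom <- utils::read.delim(domains_tsv, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(seqs), function(i) {
    id <- sub("\\s.*", "", names(seqs)[i])
    d <- if (!is.null(dom)) dom[dom$cds_id == id, c("name", "aa_start", "aa_end")] else NULL
    if (!is.null(d) && nrow(d) == 0) d <- NULL
    coding_sequence(as.character(seqs[[i]]), id = id, domains = d)
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

#' Annotate the consequence of a CDS substitution
#'
#' Classifies a single-base substitution (or reports an indel as a
#' frameshift) against a [coding_sequence()]. The affected codon is
#' `ceiling(pos / 3)` and the position within the codon is
#' `((pos - 1) %% 3) + 1`. Consequences: `synonymous`, `missense`,
#' `stop_gained`, `stop_lost`, `start_lost`, `frameshift`. For a stop-gained
#' call the truncated protein length is `codon_index - 1` amino acids; the
#' full-length protein is `CDS length / 3 - 1` (the terminal stop is not a
#' residue).
#'
#' @param cds A [coding_sequence()].
#' @param pos 1-based position from the A of the start codon.
#' @param ref,alt Reference and alternate bases (single bases for
#'   substitutions; unequal lengths are treated as an indel/frameshift).
#' @return A one-row tibble: `cds_id`, `pos`, `ref`, `alt`, `consequence`,
#'   `codon_index`, `codon_pos`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `truncated_protein_length`, `full_protein_length`,
#'   `in_domain`.
#' @export
annotate_cds_variant <- function(cds, pos, ref, alt) {
  stopifnot(inherits(cds, "coding_sequence"))
  len <- nchar(cds$bases)
  if (pos < 1 || pos > len) {
    stop("position ", pos, " outside CDS ", cds$id, " (length ", len, ")",
      call. = FALSE
    )
  }
  full_len <- len / 3 - 1
  codon_index <- ceiling(pos / 3)
  codon_pos <- ((pos - 1) %% 3) + 1
  in_domain <- FALSE
  if (!is.null(cds$domains) && nrow(cds$domains) > 0) {
    in_domain <- any(codon_index >= cds$domains$aa_start &
      codon_index <= cds$domains$aa_end)
  }
  if (nchar(ref) != nchar(alt)) {
    return(tibble(
      cds_id = cds$id, pos = pos, ref = ref, alt = alt,
      consequence = "frameshift", codon_index = codon_index,
      codon_pos = codon_pos, ref_codon = NA_character_,
      alt_codon = NA_character_, ref_aa = NA_character_,
      alt_aa = NA_character_, truncated_protein_length = NA_integer_,
      full_protein_length = as.integer(full_len), in_domain = in_domain
    ))
  }
  observed <- substr(cds$bases, pos, pos)
  if (observed != toupper(ref)) {
    stop(
      "reference mismatch at position ", pos, " of ", cds$id,
      ": expected ", ref, ", CDS has ", observed,
      call. = FALSE
    )
  }
  codon_start <- (codon_index - 1) * 3 + 1
  ref_codon <- substr(cds$bases, codon_start, codon_start + 2)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- toupper(alt)
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  consequence <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*" && ref_aa != "*") {
    "stop_gained"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "stop_lost"
  } else if (codon_index == 1) {
    "start_lost"
  } else {
    "missense"
  }
  tibble(
    cds_id = cds$id, pos = pos, ref = toupper(ref), alt = toupper(alt),
    consequence = consequence, codon_index = as.integer(codon_index),
    codon_pos = as.integer(codon_pos), ref_codon = ref_codon,
    alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
    truncated_protein_length = if (consequence == "stop_gained") {
      as.integer(codon_index - 1)
    } else {
      NA_integer_
    },
    full_protein_length = as.integer(full_len),
    in_domain = in_domain
  )
}

#' Annotate a table of CDS variants
#'
#' @param cds_set Named list of [coding_sequence()] objects (see
#'   [read_cds_fasta()]).
#' @param variants Tibble/data frame with columns `cds_id`, `pos`, `ref`,
#'   `alt`.
#' @return A tibble of effect calls, one row per variant.
#' @export
annotate_variants <- function(cds_set, variants) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!v$cds_id %in% names(cds_set)) {
      stop("unknown cds_id: ", v$cds_id, call. = FALSE)
    }
    annotate_cds_variant(cds_set[[v$cds_id]], v$pos, v$ref, v$alt)
  })
  dplyr::bind_rows(rows)
}

#' Summarise truncation calls
#'
#' One row per effect call with, for stop-gained calls, the truncation
#' fraction (truncated / full protein length) — the quantity that lets a
#' premature stop at codon 476 of a 586-residue protein be read as retaining
#' 81% of the protein.
#'
#' @param calls Effect-call tibble from [annotate_variants()].
#' @return The calls with an added `truncation_fraction` column, restricted
#'   to the summary columns.
#' @export
truncation_summary <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(
      cds_id = character(), consequence = character(),
      codon_index = integer(), truncated_protein_length = integer(),
      full_protein_length = integer(), truncation_fraction = numeric(),
      in_domain = logical()
    ))
  }
  out <- calls[, c(
    "cds_id", "consequence", "codon_index",
    "truncated_protein_length", "full_protein_length", "in_domain"
  )]
  out$truncation_fraction <- ifelse(
    calls$consequence == "stop_gained",
    calls$truncated_protein_length / calls$full_protein_length,
    NA_real_
  )
  out
}

#' Build a synthetic CDS fixture
#'
#' Generates a valid CDS of `n_codons` sense codons plus a terminal stop:
#' starts with ATG, random internal sense codons, specified codons pinned at
#' specified indices (e.g. TGG at codon 476 so a third-base G-to-A creates a
#' premature TGA stop). Synthetic stand-ins for real gene models; no real
#' genome sequence is used.
#'
#' @param n_codons Number of amino-acid codons (protein length; the terminal
#'   stop is added on top).
#' @param codons Named list/vector mapping codon index to the codon to place
#'   there (e.g. `c("476" = "TGG")`).
#' @param id Sequence id.
#' @param domains Optional domain tibble (see [coding_sequence()]).
#' @param seed Seed for the random filler codons.
#' @return A [coding_sequence()].
#' @export
synthetic_cds <- function(n_codons, codons = NULL, id = "synthetic_cds",
                          domains = NULL, seed = 1) {
  stopifnot(n_codons >= 1)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sense <- setdiff(sense, "ATG") # keep internal ATGs out for clarity
  local_seed(seed, {
    body <- sample(sense, n_codons, replace = TRUE)
  })
  body[1] <- "ATG"
  if (!is.null(codons)) {
    at <- as.integer(names(codons))
    stopifnot(all(at >= 1), all(at <= n_codons))
    body[at] <- toupper(unlist(codons))
  }
  coding_sequence(paste0(paste(body, collapse = ""), "TAA"),
    id = id, domains = domains
  )
}
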