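#' SNP locus panel for haplotype conversion
#'
#' The panel is the union of SNP loci (single-base ref and alt) across the
#' cohort, sorted by position. Haplotype strings cover these sites only.
#'
#' @param x Either a species-profile tibble ([species_profiles()]) or a
#'   cohort variant tibble; only rows whose alleles are single bases are
#'   used.
#' @return A tibble with columns `pos` and `ref`, positions strictly
#'   increasing.
#' @export
snp_panel <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("pos", "ref", "alt") %in% names(x)))
  panel <- x %>%
    dplyr::filter(variant_kind(.data$ref, .data$alt) == "SNP") %>%
    dplyr::distinct(.data$pos, .data$ref) %>%
    dplyr::arrange(.data$pos)
  if (anyDuplicated(panel$pos)) {
    stop("conflicting reference bases at one panel position", call. = FALSE)
  }
  panel
}

#' Convert per-accession SNP genotypes into IUPAC haplotype strings
#'
#' Per panel locus: no call means the reference base, a homogeneous call
#' the alternative base, and a heterogeneous call the two-base IUPAC
#' ambiguity code. InDel calls are ignored (the panel is SNP-only); a SNP
#' call at a position missing from the panel is an error.
#'
#' @param cohort Variant tibble with columns `accession_id`, `pos`, `ref`,
#'   `alt`, `gt`.
#' @param metadata Tibble with `accession_id` (and optionally `species`)
#'   listing every accession, including those without any call.
#' @param panel Panel from [snp_panel()]; defaults to the cohort's own.
#' @return A tibble with `accession_id`, `species` (when available) and
#'   `haplotype`.
#' @export
haplotype_sequences <- function(cohort, metadata, panel = snp_panel(cohort)) {
  cohort <- as_tibble(cohort)
  snps <- cohort %>%
    dplyr::filter(variant_kind(.data$ref, .data$alt) == "SNP") %>%
    dplyr::mutate(zygosity = classify_zygosity(.data$gt)) %>%
    dplyr::filter(.data$zygosity != "absent")
  col <- match(snps$pos, panel$pos)
  if (anyNA(col)) {
    stop("SNP at position ", snps$pos[which(is.na(col))[1L]],
         " is missing from the panel", call. = FALSE)
  }
  snps$panel_col <- col
  snps$char <- ifelse(
    snps$zygosity == "homogeneous", snps$alt,
    mapply(function(r, a) iupac_code(c(r, a)), snps$ref, snps$alt)
  )
  ref_chars <- panel$ref
  by_acc <- split(snps[, c("panel_col", "char")], snps$accession_id)
  haplo <- vapply(metadata$accession_id, function(acc) {
    chars <- ref_chars
    rows <- by_acc[[acc]]
    if (!is.null(rows)) chars[rows$panel_col] <- rows$char
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out <- tibble(accession_id = metadata$accession_id, haplotype = haplo)
  if ("species" %in% names(metadata)) {
    out <- dplyr::mutate(out, species = metadata$species, .after = "accession_id")
  }
  out
}

#' Collapse haplotype strings into unique groups
#'
#' Groups partition the accessions by exact string equality, ordered by
#' size descending with ties broken by first occurrence.
#'
#' @param seqs A tibble with columns `accession_id` and `haplotype`
#'   (optionally `species`), or a named character vector.
#' @return A tibble with `haplotype_id`, `sequence`, `size`, `species`
#'   (comma-joined when a group spans several) and a `members` list-column.
#' @export
collapse_haplotypes <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- tibble(accession_id = names(seqs), haplotype = unname(seqs))
  }
  seqs <- as_tibble(seqs)
  stopifnot(all(c("accession_id", "haplotype") %in% names(seqs)))
  if (length(unique(nchar(seqs$haplotype))) > 1L) {
    stop("haplotype strings must all have the same length", call. = FALSE)
  }
  seqs$first_idx <- seq_len(nrow(seqs))
  grouped <- seqs %>%
    dplyr::group_by(sequence = .data$haplotype) %>%
    dplyr::summarise(
      size = dplyr::n(),
      first = min(.data$first_idx),
      species = if ("species" %in% names(seqs))
        paste(sort(unique(.data$species)), collapse = ",") else NA_character_,
      members = list(.data$accession_id),
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$size), .data$first) %>%
    dplyr::mutate(haplotype_id = sprintf("H%02d", dplyr::row_number())) %>%
    dplyr::select("haplotype_id", "sequence", "size", "species", "members")
  grouped
}

#' Write haplotypes or group representatives to FASTA
#'
#' Group representatives get headers of the form `H01|size=457`.
#'
#' @param groups A [collapse_haplotypes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(groups, path) {
  seqs <- setNames(groups$sequence,
                   sprintf("%s|size=%d", groups$haplotype_id, groups$size))
  # ambiguity codes are valid FASTA characters; Biostrings accepts them
  write_fasta(seqs, path)
}

#' Write haplotype sequences in relaxed PHYLIP format
#'
#' @param seqs Named character vector (or tibble with `accession_id` and
#'   `haplotype`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$haplotype, seqs$accession_id)
  lines <- c(paste(length(seqs), nchar(seqs[[1L]])),
             paste(names(seqs), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
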