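#' Write a simulated cohort as a multi-sample VCF 4.2 file
#'
#' One row per distinct (pos, ref, alt) site, one genotype column per
#' accession; sites carry the hard-filter annotations in INFO. Accessions
#' without a call at a site are written as 0/0.
#'
#' @param variants Cohort variant tibble from [simulate_cohort()].
#' @param metadata Cohort metadata (defines sample order).
#' @param path Output path.
#' @param contig Contig name, default "nrDNA".
#' @param contig_length Contig length for the VCF header.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, metadata, path, contig = "nrDNA",
                             contig_length = map_length(region_map())) {
  variants <- as_tibble(variants)
  ann_cols <- intersect(names(default_annotations()), names(variants))
  sites <- variants %>%
    dplyr::group_by(.data$pos, .data$ref, .data$alt) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(ann_cols), dplyr::first),
                     .groups = "drop") %>%
    dplyr::arrange(.data$pos, .data$ref, .data$alt)

  gt <- matrix("0/0", nrow = nrow(sites), ncol = nrow(metadata),
               dimnames = list(NULL, metadata$accession_id))
  site_key <- paste(sites$pos, sites$ref, sites$alt)
  row_idx <- match(paste(variants$pos, variants$ref, variants$alt), site_key)
  col_idx <- match(variants$accession_id, metadata$accession_id)
  gt[cbind(row_idx, col_idx)] <- variants$gt

  info_cols <- setdiff(ann_cols, "QUAL")
  info <- vapply(seq_len(nrow(sites)), function(i) {
    paste(sprintf("%s=%g", info_cols,
                  as.numeric(sites[i, info_cols])), collapse = ";")
  }, character(1))
  qual <- if ("QUAL" %in% ann_cols) sprintf("%g", sites$QUAL) else "."

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_cols, info_cols),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", metadata$accession_id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(contig, sites$pos[i], ".", sites$ref[i], sites$alt[i], qual[i],
            "PASS", info[i], "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF back into a long variant tibble
#'
#' Uses the vcfR reader; 0/0 genotypes are dropped by default so the
#' result matches the simulated cohort layout. Species labels are joined
#' from `metadata` when given.
#'
#' @param path VCF path.
#' @param metadata Optional metadata tibble with `accession_id`, `species`.
#' @param drop_absent Drop 0/0 genotypes (default TRUE).
#' @return A tibble with `accession_id`, `pos`, `ref`, `alt`, `gt`,
#'   annotation columns and optionally `species`.
#' @export
read_cohort_vcf <- function(path, metadata = NULL, drop_absent = TRUE) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_cohort_vcf() needs the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sites <- tibble(
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    QUAL = as.numeric(fix$QUAL)
  )
  for (a in c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")) {
    sites[[a]] <- as.numeric(vcfR::extract.info(vcf, element = a))
  }
  long <- tidyr::expand_grid(site = seq_len(nrow(sites)),
                             accession_id = colnames(gt)) %>%
    dplyr::mutate(gt = gt[cbind(.data$site, match(.data$accession_id,
                                                  colnames(gt)))]) %>%
    dplyr::bind_cols(sites[.$site, ]) %>%
    dplyr::select(-"site")
  if (drop_absent) {
    long <- dplyr::filter(long, classify_zygosity(.data$gt) != "absent")
  }
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, as_tibble(metadata)[, c("accession_id",
                                                           "species")],
                             by = "accession_id")
  }
  dplyr::relocate(long, "accession_id", dplyr::any_of("species"), "pos",
                  "ref", "alt", "gt")
}

#' Write / read accession metadata as tab-delimited text
#'
#' @param metadata Tibble with at least `accession_id` and `species`.
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(as_tibble(metadata), path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
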