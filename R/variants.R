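#' Hard-filter thresholds for SNP and InDel calls
#'
#' GATK-style site-level hard filters. A record fails when any listed
#' inequality holds; annotations that are missing (NA) cannot trigger their
#' criterion, mirroring how variant-filtration engines skip unevaluable
#' expressions.
#'
#' SNPs fail on QD < 2, MQ < 40, FS > 60, SOR > 3, QUAL < 30,
#' MQRankSum < -12.5 or ReadPosRankSum < -8; InDels use FS > 200 and
#' SOR > 10 with the remaining thresholds unchanged.
#'
#' @param kind "SNP" or "InDel".
#' @return A tibble with columns `annotation`, `op` (`"lt"`/`"gt"`) and
#'   `threshold`.
#' @export
hard_filter_thresholds <- function(kind = c("SNP", "InDel")) {
  kind <- match.arg(kind)
  tibble(
    annotation = c("QD", "MQ", "FS", "SOR", "QUAL", "MQRankSum",
                   "ReadPosRankSum"),
    op = c("lt", "lt", "gt", "gt", "lt", "lt", "lt"),
    threshold = c(2, 40, if (kind == "SNP") 60 else 200,
                  if (kind == "SNP") 3 else 10, 30, -12.5, -8)
  )
}

#' Classify variant kind from its alleles
#'
#' A record is a SNP iff both the reference and the alternative allele are
#' single bases; anything else is an InDel.
#'
#' @param ref,alt Character vectors of reference and alternative alleles.
#' @return Character vector, "SNP" or "InDel".
#' @export
variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel")
}

#' Apply hard filters to a variant table
#'
#' Takes a data frame of variant records with (any of) the annotation
#' columns `QD`, `MQ`, `FS`, `SOR`, `QUAL`, `MQRankSum`, `ReadPosRankSum`
#' and adds a logical `pass` column plus a `failed` list-column naming every
#' violated criterion. The variant kind is derived from `ref`/`alt` unless a
#' `kind` column is already present.
#'
#' @param variants A data frame with columns `ref`, `alt` (or `kind`) and
#'   annotation columns; absent columns are treated as missing annotations.
#' @return The input as a tibble with `pass` and `failed` columns appended.
#' @examples
#' apply_hard_filters(tibble::tibble(ref = "A", alt = "G", QD = 1.5))
#' @export
apply_hard_filters <- function(variants) {
  variants <- as_tibble(variants)
  kind <- if ("kind" %in% names(variants)) variants$kind
          else variant_kind(variants$ref, variants$alt)
  stopifnot(all(kind %in% c("SNP", "InDel")))
  ann_names <- hard_filter_thresholds("SNP")$annotation
  n <- nrow(variants)
  failed <- vector("list", n)
  for (i in seq_len(n)) failed[[i]] <- character(0)
  for (k in c("SNP", "InDel")) {
    rows <- which(kind == k)
    if (!length(rows)) next
    thr <- hard_filter_thresholds(k)
    for (j in seq_len(nrow(thr))) {
      a <- thr$annotation[j]
      if (!a %in% names(variants)) next
      val <- variants[[a]][rows]
      bad <- if (thr$op[j] == "lt") val < thr$threshold[j] else val > thr$threshold[j]
      bad <- which(!is.na(bad) & bad)
      for (r in bad) failed[[rows[r]]] <- c(failed[[rows[r]]], a)
    }
  }
  variants$pass <- lengths(failed) == 0L
  variants$failed <- failed
  variants
}

#' Classify genotype observations as homogeneous, heterogeneous or absent
#'
#' Within an accession's rDNA copies a variant is *homogeneous* when only
#' the alternative allele is observed, *heterogeneous* when reference and
#' alternative alleles co-occur, and *absent* when only the reference is
#' seen. Genotype strings follow VCF conventions ("1/1", "0/1", "0|1",
#' "0/0", ...): any non-zero allele index counts as the alternative.
#'
#' @param gt Character vector of VCF-style genotype strings.
#' @return Character vector over
#'   `c("homogeneous", "heterogeneous", "absent")`.
#' @examples
#' classify_zygosity(c("1/1", "0/1", "0/0"))
#' @export
classify_zygosity <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || !nzchar(g)) stop("empty genotype observation", call. = FALSE)
    alleles <- strsplit(g, "[/|]")[[1L]]
    alleles <- alleles[alleles != "."]
    if (!length(alleles)) stop("no observed alleles in genotype '", g, "'",
                               call. = FALSE)
    has_ref <- any(alleles == "0")
    has_alt <- any(alleles != "0")
    if (has_alt && has_ref) "heterogeneous"
    else if (has_alt) "homogeneous"
    else "absent"
  }, character(1), USE.NAMES = FALSE)
}

#' Tally variants per species, per region and by zygosity
#'
#' Reproduces the two study-table shapes from a cohort of per-accession
#' variant calls. Per species, distinct variant loci observed in at least
#' one accession are counted by kind (SNP / InDel) and by region, with the
#' three spacer regions pooled into one ITS column; zygosity is aggregated
#' so that a locus heterogeneous in any member accession counts as
#' heterogeneous for the species, otherwise homogeneous.
#'
#' @param cohort A data frame with one row per accession x variant call and
#'   columns `accession_id`, `species`, `pos`, `ref`, `alt`, `gt` (absent
#'   calls may be present; they are dropped).
#' @param map A region map tibble; every `pos` must fall inside it.
#' @return An object of class `nr_tally`: a list with tibbles `region`
#'   (species, n_accessions, then SNP/InDel counts per region) and
#'   `zygosity` (species, homogeneous/heterogeneous counts per kind).
#' @export
tally_variants <- function(cohort, map = region_map()) {
  cohort <- as_tibble(cohort)
  need <- c("accession_id", "species", "pos", "ref", "alt", "gt")
  stopifnot(all(need %in% names(cohort)))
  region_order <- c("18S", "ITS", "26S")

  if (nrow(cohort) == 0L) {
    empty_region <- tibble(species = character(0), n_accessions = integer(0),
                           snp_18S = integer(0), snp_ITS = integer(0),
                           snp_26S = integer(0), indel_18S = integer(0),
                           indel_ITS = integer(0), indel_26S = integer(0))
    empty_zyg <- tibble(species = character(0),
                        snp_homogeneous = integer(0),
                        snp_heterogeneous = integer(0),
                        indel_homogeneous = integer(0),
                        indel_heterogeneous = integer(0))
    return(structure(list(region = empty_region, zygosity = empty_zyg),
                     class = "nr_tally"))
  }

  obs <- cohort %>%
    dplyr::mutate(
      zygosity = classify_zygosity(.data$gt),
      kind = variant_kind(.data$ref, .data$alt),
      region = pool_its(assign_region(.data$pos, map))
    ) %>%
    dplyr::filter(.data$zygosity != "absent")

  n_acc <- obs %>%
    dplyr::distinct(.data$species, .data$accession_id) %>%
    dplyr::count(.data$species, name = "n_accessions")

  # one row per species-level locus, zygosity aggregated across accessions
  loci <- obs %>%
    dplyr::group_by(.data$species, .data$pos, .data$ref, .data$alt,
                    .data$kind, .data$region) %>%
    dplyr::summarise(
      zygosity = if (any(.data$zygosity == "heterogeneous"))
        "heterogeneous" else "homogeneous",
      .groups = "drop"
    )

  region_tbl <- loci %>%
    dplyr::count(.data$species, .data$kind, .data$region) %>%
    dplyr::mutate(
      col = paste0(ifelse(.data$kind == "SNP", "snp_", "indel_"), .data$region)
    ) %>%
    dplyr::select("species", "col", "n") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "n",
                       values_fill = 0L)
  for (col in c(paste0("snp_", region_order), paste0("indel_", region_order))) {
    if (!col %in% names(region_tbl)) region_tbl[[col]] <- 0L
  }
  region_tbl <- region_tbl %>%
    dplyr::left_join(n_acc, by = "species") %>%
    dplyr::select("species", "n_accessions", "snp_18S", "snp_ITS", "snp_26S",
                  "indel_18S", "indel_ITS", "indel_26S") %>%
    dplyr::arrange(.data$species)

  zyg_tbl <- loci %>%
    dplyr::count(.data$species, .data$kind, .data$zygosity) %>%
    dplyr::mutate(
      col = paste0(ifelse(.data$kind == "SNP", "snp_", "indel_"),
                   .data$zygosity)
    ) %>%
    dplyr::select("species", "col", "n") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "n",
                       values_fill = 0L)
  for (col in c("snp_homogeneous", "snp_heterogeneous",
                "indel_homogeneous", "indel_heterogeneous")) {
    if (!col %in% names(zyg_tbl)) zyg_tbl[[col]] <- 0L
  }
  zyg_tbl <- zyg_tbl %>%
    dplyr::select("species", "snp_homogeneous", "snp_heterogeneous",
                  "indel_homogeneous", "indel_heterogeneous") %>%
    dplyr::arrange(.data$species)

  structure(list(region = region_tbl, zygosity = zyg_tbl),
            class = "nr_tally")
}

#' @export
print.nr_tally <- function(x, ...) {
  cat("Variant tally (distinct species-level loci)\n\n")
  cat("Per region:\n")
  print(x$region)
  cat("\nBy zygosity:\n")
  print(x$zygosity)
  invisible(x)
}

#' @rdname tally_variants
#' @param x An `nr_tally` object.
#' @param ... Unused.
#' @return `tidy()` returns one long tibble with columns `species`, `table`
#'   ("region" or "zygosity"), `measure` and `n`.
#' @method tidy nr_tally
#' @export
tidy.nr_tally <- function(x, ...) {
  dplyr::bind_rows(
    x$region %>%
      tidyr::pivot_longer(-c("species", "n_accessions"),
                          names_to = "measure", values_to = "n") %>%
      dplyr::mutate(table = "region") %>%
      dplyr::select("species", "table", "measure", "n"),
    x$zygosity %>%
      tidyr::pivot_longer(-"species", names_to = "measure", values_to = "n") %>%
      dplyr::mutate(table = "zygosity") %>%
      dplyr::select("species", "table", "measure", "n")
  )
}

#' Write a tally as tab-delimited tables
#'
#' @param x An `nr_tally` object.
#' @param region_path,zygosity_path Output paths for the two tables.
#' @return Invisibly, the two paths.
#' @export
write_tally <- function(x, region_path, zygosity_path) {
  stopifnot(inherits(x, "nr_tally"))
  readr::write_tsv(x$region, region_path)
  readr::write_tsv(x$zygosity, zygosity_path)
  invisible(c(region_path, zygosity_path))
}
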