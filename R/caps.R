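#' ITS primer pair and restriction enzymes for the CAPS assay
#'
#' The mulberry-specific ITS primers amplify the complete spacer region plus
#' 41 bp of 18S and 37 bp of 26S. The two diagnostic enzymes are BstEII
#' (G^GTNACC) and MstI (TGC^GCA, blunt). Both recognition motifs are their
#' own reverse complements under IUPAC complementation, so plus-strand
#' scanning accounts for all double-strand cuts.
#'
#' @return `its_primers()` returns a list with `forward` and `reverse`
#'   primer strings (both written 5'->3' on their own strand);
#'   `caps_enzymes()` returns a tibble with columns `name`, `motif`,
#'   `cut_offset` (bases of the motif left of the cut).
#' @export
its_primers <- function() {
  list(forward = "GTAACAAGGTTTCCGTAGGTG",
       reverse = "TAAACTCAGCGGGTAGCC")
}

#' @rdname its_primers
#' @export
caps_enzymes <- function() {
  tibble(name = c("BstEII", "MstI"),
         motif = c("GGTNACC", "TGCGCA"),
         cut_offset = c(1L, 3L))
}

#' Find restriction cut positions on the plus strand
#'
#' Scans a sequence for an IUPAC-degenerate recognition motif (N matches any
#' base) and returns the sorted cut positions: a cut position `p` means the
#' enzyme cuts between bases `p` and `p + 1`.
#'
#' @param seq A single DNA string over A/C/G/T.
#' @param enzyme One row of [caps_enzymes()], or an enzyme name.
#' @return Sorted integer vector of cut positions (empty when no site).
#' @examples
#' find_sites("AAGGTAACCTT", "BstEII")  # cut after position 3
#' @export
find_sites <- function(seq, enzyme) {
  enzyme <- resolve_enzyme(enzyme)
  stopifnot(length(seq) == 1L, is.character(seq))
  hits <- Biostrings::matchPattern(enzyme$motif,
                                   Biostrings::DNAString(seq),
                                   fixed = FALSE)
  starts <- Biostrings::start(hits)
  sort(as.integer(starts) + enzyme$cut_offset - 1L)
}

resolve_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    enz <- caps_enzymes()
    row <- enz[enz$name == enzyme, ]
    if (nrow(row) != 1L) stop("unknown enzyme: ", enzyme, call. = FALSE)
    return(as.list(row))
  }
  stopifnot(is.list(enzyme), all(c("motif", "cut_offset") %in% names(enzyme)))
  as.list(enzyme)
}

#' Digest a sequence and return fragment lengths
#'
#' Fragments are the consecutive differences of `{0, cuts..., length}` and
#' always sum to the sequence length.
#'
#' @inheritParams find_sites
#' @return Sorted integer vector of fragment lengths.
#' @examples
#' digest_fragments("AAGGTAACCTT", "BstEII")  # 3 and 8
#' @export
digest_fragments <- function(seq, enzyme) {
  cuts <- find_sites(seq, enzyme)
  sort(as.integer(diff(c(0L, cuts, nchar(seq)))))
}

#' In-silico PCR: extract the amplicon delimited by a primer pair
#'
#' Searches the plus strand for the forward primer and, downstream of it,
#' for the reverse complement of the reverse primer; the amplicon is the
#' inclusive span from the forward-primer start to the end of the reverse
#' site. Binding must be unique: no site is an error, more than one
#' candidate product is an ambiguity error.
#'
#' @param template A single DNA string.
#' @param primers A list with `forward` and `reverse` primers
#'   (default [its_primers()]).
#' @param max_mismatch Maximum number of mismatches tolerated per primer
#'   (default 0, exact matching).
#' @return The amplicon as a character string.
#' @export
insilico_pcr <- function(template, primers = its_primers(), max_mismatch = 0L) {
  stopifnot(length(template) == 1L, nchar(template) > 0L, max_mismatch >= 0L)
  subj <- Biostrings::DNAString(template)
  fwd <- Biostrings::matchPattern(primers$forward, subj,
                                  max.mismatch = max_mismatch)
  rev_site <- Biostrings::matchPattern(revcomp(primers$reverse), subj,
                                       max.mismatch = max_mismatch)
  if (length(fwd) == 0L || length(rev_site) == 0L) {
    stop("no amplicon: primer site not found", call. = FALSE)
  }
  pairs <- tidyr::expand_grid(
    f = as.integer(Biostrings::start(fwd)),
    fe = as.integer(Biostrings::end(fwd)),
    r = as.integer(Biostrings::start(rev_site)),
    re = as.integer(Biostrings::end(rev_site))
  ) %>% dplyr::filter(.data$r > .data$fe)
  if (nrow(pairs) == 0L) {
    stop("no amplicon: reverse site not downstream of forward primer",
         call. = FALSE)
  }
  if (nrow(pairs) > 1L) {
    stop("ambiguous PCR: ", nrow(pairs), " candidate products", call. = FALSE)
  }
  substr(template, pairs$f, pairs$re)
}

#' Classify an ITS-CAPS banding pattern
#'
#' Applies the species-diagnostic key: an amplicon left undigested by both
#' enzymes is M. notabilis; a ~449 bp BstEII band without a ~602-604 bp MstI
#' band is M. alba; the ~602-604 bp MstI band without the 449 bp band marks
#' the nigra group (M. nigra / M. serrata / M. celtidifolia / M. rubra);
#' both bands together are the mixed pattern of a heterogeneous 13 bp
#' insertion. Small fragments (91/100 bp), often too faint on a gel, are
#' never used as evidence.
#'
#' @param bste2 Integer vector of BstEII fragment lengths (for accessions
#'   with a heterozygous insertion, the union over both allele templates).
#' @param mst1 Integer vector of MstI fragment lengths.
#' @param tol Band-matching tolerance in bp (default 5).
#' @return A list with `label` (one of "M. alba", "M. notabilis",
#'   "nigra_group", "heterogeneous_indel", "unresolved") and `evidence`, the
#'   matched diagnostic bands.
#' @export
classify_banding <- function(bste2, mst1, tol = 5) {
  if (length(bste2) == 0L || length(mst1) == 0L) {
    stop("empty fragment multiset", call. = FALSE)
  }
  stopifnot(tol >= 0)
  if (length(bste2) == 1L && length(mst1) == 1L &&
      abs(bste2 - mst1) <= tol) {
    return(list(label = "M. notabilis",
                evidence = c(undigested = unname(bste2[1L]))))
  }
  b449 <- bste2[abs(bste2 - 449) <= tol]
  m60x <- mst1[mst1 >= 602 - tol & mst1 <= 604 + tol]
  evidence <- c(
    if (length(b449)) setNames(b449, rep("BstEII_449", length(b449))),
    if (length(m60x)) setNames(m60x, rep("MstI_603", length(m60x)))
  )
  label <-
    if (length(b449) && length(m60x)) "heterogeneous_indel"
    else if (length(b449)) "M. alba"
    else if (length(m60x)) "nigra_group"
    else "unresolved"
  list(label = label, evidence = evidence)
}

#' Run the full ITS-CAPS assay over a set of templates
#'
#' For each template: in-silico PCR with the ITS primers, digestion with
#' BstEII and MstI, and the banding-pattern call. The result mirrors the
#' study's fragment-length table.
#'
#' @param templates Named character vector of template sequences (names are
#'   template / species labels).
#' @param primers Primer pair, default [its_primers()].
#' @param tol Band tolerance passed to [classify_banding()].
#' @param max_mismatch Primer mismatch tolerance.
#' @return A tibble of class `nr_caps` with columns `template`,
#'   `amplicon_length`, `bste2` and `mst1` (list-columns of fragment
#'   lengths), `bste2_label`, `mst1_label` (fragments as "a/b" strings) and
#'   `call`.
#' @export
caps_table <- function(templates, primers = its_primers(), tol = 5,
                       max_mismatch = 0L) {
  stopifnot(is.character(templates), !is.null(names(templates)))
  rows <- purrr::imap(templates, function(seq, label) {
    amp <- insilico_pcr(seq, primers, max_mismatch)
    b <- digest_fragments(amp, "BstEII")
    m <- digest_fragments(amp, "MstI")
    tibble(
      template = label,
      amplicon_length = nchar(amp),
      bste2 = list(b),
      mst1 = list(m),
      bste2_label = paste(sort(b, decreasing = TRUE), collapse = "/"),
      mst1_label = paste(sort(m, decreasing = TRUE), collapse = "/"),
      call = classify_banding(b, m, tol)$label
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nr_caps", class(out))
  out
}

#' Write a CAPS digest report as tab-delimited text
#'
#' @param x A `caps_table()` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caps_report <- function(x, path) {
  readr::write_tsv(
    dplyr::select(as_tibble(x), "template", "amplicon_length",
                  "bste2_label", "mst1_label", "call"),
    path
  )
  invisible(path)
}
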