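#' Regular-expression patterns for the 13/16 bp ITS1 insertion
#'
#' Reads supporting the insertion contain the upstream flank TCGAAACC, any
#' intervening bases, then the insertion tail AATGCG immediately followed
#' by the downstream flank CCCCAACCCC; the reverse-orientation alternative
#' is the reverse complement. Reference-supporting reads match the flank
#' pair without the AATGCG tail. Every insertion-matching read also
#' matches the reference pattern, so classification checks the insertion
#' patterns first.
#'
#' @return A list with character vectors `ins` and `ref`, each holding the
#'   forward and reverse-orientation regular expressions.
#' @export
insertion_patterns <- function() {
  list(
    ins = c(forward = "TCGAAACC.+AATGCGCCCCAACCCC",
            reverse = "GGGGTTGGGGCGCATT.+GGTTTCGA"),
    ref = c(forward = "TCGAAACC.+CCCCAACCCC",
            reverse = "GGGGTTGGGG.+GGTTTCGA")
  )
}

#' Classify reads as insertion-supporting, reference-supporting or neither
#'
#' @param reads Character vector of read sequences over A/C/G/T/N.
#' @param patterns Pattern set from [insertion_patterns()].
#' @return Character vector over `c("ins", "ref", "neither")`.
#' @examples
#' classify_reads("TCGAAACCGTGCGCAATGCGCCCCAACCCC")
#' @export
classify_reads <- function(reads, patterns = insertion_patterns()) {
  is_ins <- grepl(patterns$ins[["forward"]], reads) |
    grepl(patterns$ins[["reverse"]], reads)
  is_ref <- grepl(patterns$ref[["forward"]], reads) |
    grepl(patterns$ref[["reverse"]], reads)
  ifelse(is_ins, "ins", ifelse(is_ref, "ref", "neither"))
}

#' Tally reads over the insertion locus and call the allele status
#'
#' Status is `mixed` when both allele classes reach the evidence threshold,
#' `ins_only` / `ref_only` when only one side does, and `nocall` otherwise
#' (including an empty read set).
#'
#' @param reads Character vector of reads.
#' @param patterns Pattern set from [insertion_patterns()].
#' @param min_reads Minimum supporting reads per allele (default 1).
#' @return A one-row tibble with `n_ins`, `n_ref`, `n_total`, `status`.
#' @export
tally_reads <- function(reads, patterns = insertion_patterns(),
                        min_reads = 1L) {
  stopifnot(min_reads >= 1L)
  cls <- if (length(reads)) classify_reads(reads, patterns) else character(0)
  n_ins <- sum(cls == "ins")
  n_ref <- sum(cls == "ref")
  status <-
    if (n_ins >= min_reads && n_ref >= min_reads) "mixed"
    else if (n_ins >= min_reads) "ins_only"
    else if (n_ref >= min_reads) "ref_only"
    else "nocall"
  tibble(n_ins = n_ins, n_ref = n_ref, n_total = length(reads),
         status = status)
}

#' Tally insertion reads per accession
#'
#' @param reads A tibble with columns `accession_id` and `read`.
#' @inheritParams tally_reads
#' @return A tibble with one row per accession: `accession_id`, `n_ins`,
#'   `n_ref`, `n_total`, `status`.
#' @export
tally_insertion_cohort <- function(reads, patterns = insertion_patterns(),
                                   min_reads = 1L) {
  reads <- as_tibble(reads)
  stopifnot(all(c("accession_id", "read") %in% names(reads)))
  reads %>%
    dplyr::group_by(.data$accession_id) %>%
    dplyr::reframe(tally_reads(.data$read, patterns, min_reads))
}

#' Simulate reads over the insertion locus for one accession
#'
#' Draws error-free reads (both orientations, uniform start positions)
#' from the reference-local context around position 1862 and/or from the
#' insertion-carrying allele, so the regex counter recovers the requested
#' allele status.
#'
#' @param reference Reference string from [build_reference()].
#' @param status One of "mixed", "ins_only", "ref_only".
#' @param depth Number of reads (>= 2 for mixed).
#' @param read_length Read length in bp; must cover the full flank span.
#' @param seed Integer seed.
#' @param insert `"13bp"` or `"16bp"` insertion allele.
#' @return Character vector of `depth` reads.
#' @export
simulate_insertion_reads <- function(reference,
                                     status = c("mixed", "ins_only",
                                                "ref_only"),
                                     depth = 50L, read_length = 150L,
                                     seed = 1L, insert = c("13bp", "16bp")) {
  status <- match.arg(status)
  insert <- match.arg(insert)
  stopifnot(depth >= 1L, !(status == "mixed" && depth < 2L))
  set.seed(seed)
  n_ins <- switch(status, mixed = ceiling(depth / 2), ins_only = depth,
                  ref_only = 0L)
  draw_insertion_reads(reference, n_ins = n_ins, n_ref = depth - n_ins,
                       read_length = read_length, insert = insert)
}

# shared read-drawing core (assumes RNG already seeded)
draw_insertion_reads <- function(reference, n_ins, n_ref, read_length,
                                 insert) {
  L <- nr_layout()
  win <- max(1L, L$ins_pos - read_length - 50L)
  ref_local <- substr(reference, win, L$ins_pos + read_length + 50L)
  cut <- L$ins_pos - win + 1L
  ins_seq <- if (insert == "13bp") L$ins13 else L$ins16
  ins_local <- paste0(substr(ref_local, 1L, cut), ins_seq,
                      substr(ref_local, cut + 1L, nchar(ref_local)))
  pats <- insertion_patterns()
  draw <- function(template, pattern, n) {
    if (n == 0L) return(character(0))
    m <- regexpr(pattern, template)
    if (m == -1L) stop("flank pattern not found in template", call. = FALSE)
    span_start <- as.integer(m)
    span_end <- span_start + attr(m, "match.length") - 1L
    if (span_end - span_start + 1L > read_length) {
      stop("read_length too short to span the insertion flanks",
           call. = FALSE)
    }
    starts <- sample(seq(span_end - read_length + 1L, span_start), n,
                     replace = TRUE)
    reads <- substring(template, starts, starts + read_length - 1L)
    flip <- stats::runif(n) < 0.5
    reads[flip] <- revcomp(reads[flip])
    reads
  }
  c(draw(ins_local, pats$ins[["forward"]], n_ins),
    draw(ref_local, pats$ref[["forward"]], n_ref))
}

#' Default per-accession insertion allele statuses for the cohort
#'
#' 539 of the 542 accessions carry both the insertion and the reference
#' allele in their raw reads (`mixed`); the three M. notabilis singleton
#' accessions are pure-insertion. M. notabilis accessions carry the 16 bp
#' allele, all others the 13 bp allele.
#'
#' @param metadata Cohort metadata from [simulate_cohort()].
#' @return A tibble with `accession_id`, `species`, `status`, `insert`.
#' @export
default_insertion_status <- function(metadata) {
  metadata <- as_tibble(metadata)
  pure <- metadata$haplotype_id %in% c("notab_s1", "notab_s2", "notab_s3")
  tibble(
    accession_id = metadata$accession_id,
    species = metadata$species,
    status = ifelse(pure, "ins_only", "mixed"),
    insert = ifelse(metadata$species == "M. notabilis", "16bp", "13bp")
  )
}

#' Simulate insertion-locus reads for a whole cohort
#'
#' @param reference Reference string.
#' @param statuses Status tibble from [default_insertion_status()].
#' @param depth Reads per accession.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return A tibble with columns `accession_id`, `read`.
#' @export
simulate_cohort_reads <- function(reference, statuses, depth = 50L,
                                  read_length = 150L, seed = 1L) {
  statuses <- as_tibble(statuses)
  set.seed(seed)
  rows <- purrr::pmap(
    statuses[, c("accession_id", "status", "insert")],
    function(accession_id, status, insert) {
      n_ins <- switch(status, mixed = ceiling(depth / 2), ins_only = depth,
                      ref_only = 0L)
      tibble(accession_id = accession_id,
             read = draw_insertion_reads(reference, n_ins = n_ins,
                                         n_ref = depth - n_ins,
                                         read_length = read_length,
                                         insert = insert))
    })
  dplyr::bind_rows(rows)
}

#' Write / read FASTQ
#'
#' Minimal FASTQ interchange: constant quality "I" (Q40); `.gz` paths are
#' compressed transparently.
#'
#' @param reads Tibble with `accession_id` and `read` (read names become
#'   `accession_id/n`), or a named character vector.
#' @param path Output path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a
#'   tibble with `name`, `read` and, when names contain `/`,
#'   `accession_id`.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    idx <- stats::ave(seq_len(nrow(reads)), reads$accession_id,
                      FUN = seq_along)
    reads <- setNames(reads$read, paste0(reads$accession_id, "/", idx))
  }
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+",
                           strrep("I", nchar(reads))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- tibble(name = names(set), read = unname(as.character(set)))
  if (all(grepl("/", out$name))) {
    out$accession_id <- sub("/[^/]*$", "", out$name)
  }
  out
}
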