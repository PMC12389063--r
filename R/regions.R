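#' The nrDNA subregion coordinate map
#'
#' The mulberry nrDNA repeat unit is 5814 bp and carries, in order, the 18S
#' rRNA gene (1808 bp), ITS1 (215 bp), 5.8S (163 bp), ITS2 (233 bp) and the
#' 26S rRNA gene (3395 bp). Coordinates are 1-based and inclusive
#' throughout the package; the BED writer converts to 0-based half-open.
#'
#' @param lengths Named integer vector of region lengths, in order. The
#'   default is the packaged mulberry map.
#' @return A tibble with columns `region`, `start`, `end`, `length`, one row
#'   per subregion, contiguous from 1 to the total length.
#' @examples
#' region_map()
#' sum(region_map()$length)  # 5814
#' @export
region_map <- function(lengths = c("18S" = 1808L, "ITS1" = 215L,
                                   "5.8S" = 163L, "ITS2" = 233L,
                                   "26S" = 3395L)) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1), !is.null(names(lengths)))
  ends <- cumsum(as.integer(lengths))
  map <- tibble(
    region = names(lengths),
    start  = c(1L, head(ends, -1L) + 1L),
    end    = ends,
    length = as.integer(lengths)
  )
  validate_region_map(map)
  map
}

validate_region_map <- function(map) {
  stopifnot(
    is.data.frame(map),
    all(c("region", "start", "end") %in% names(map)),
    map$start[1] == 1L,
    all(map$end >= map$start),
    all(map$start[-1] == head(map$end, -1L) + 1L)
  )
  invisible(map)
}

#' Total length of a region map
#' @param map A region map tibble from [region_map()].
#' @return Integer, the last coordinate covered.
#' @export
map_length <- function(map = region_map()) {
  validate_region_map(map)
  max(map$end)
}

#' Map nrDNA positions to their subregion
#'
#' InDels are assigned by their anchor (leftmost reference) position,
#' matching VCF anchoring.
#'
#' @param pos Integer vector of 1-based positions.
#' @param map A region map tibble from [region_map()].
#' @return Character vector of region names, same length as `pos`.
#' @examples
#' assign_region(1862)  # "ITS1"
#' @export
assign_region <- function(pos, map = region_map()) {
  validate_region_map(map)
  pos <- as.integer(pos)
  if (anyNA(pos) || any(pos < 1L) || any(pos > max(map$end))) {
    stop("position out of range 1..", max(map$end), call. = FALSE)
  }
  idx <- findInterval(pos, map$start)
  map$region[idx]
}

#' Pool ITS subregions for table reporting
#'
#' Variant tallies report ITS1, 5.8S and ITS2 as a single pooled "ITS"
#' column; coding regions keep their names.
#'
#' @param region Character vector of region names.
#' @return Character vector with the three spacer-region names replaced by
#'   "ITS".
#' @export
pool_its <- function(region) {
  ifelse(region %in% c("ITS1", "5.8S", "ITS2"), "ITS", region)
}

#' Write / read a region map as BED
#'
#' BED uses 0-based half-open intervals; columns are chrom, start, end, name.
#'
#' @param map A region map tibble.
#' @param path File path.
#' @param chrom Chromosome / contig label used in the BED lines.
#' @return `write_region_bed()` returns `path` invisibly; `read_region_bed()`
#'   returns a region map tibble.
#' @export
write_region_bed <- function(map, path, chrom = "nrDNA") {
  validate_region_map(map)
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, map$start - 1L, map$end, map$region)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_region_bed
#' @export
read_region_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "region"),
                         col_types = "ciic", progress = FALSE)
  map <- tibble(
    region = bed$region,
    start  = as.integer(bed$start0) + 1L,
    end    = as.integer(bed$end),
    length = as.integer(bed$end - bed$start0)
  )
  validate_region_map(map)
  map
}

#' Read a reference sequence from FASTA
#'
#' Reads the first record of a FASTA file as a plain upper-case character
#' string and, when a region map is supplied, checks that the sequence
#' length matches the map.
#'
#' @param path FASTA file path.
#' @param map Optional region map to validate the length against.
#' @return A single character string.
#' @export
read_reference <- function(path, map = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("no sequence in ", path, call. = FALSE)
  seq <- toupper(as.character(set[[1L]]))
  if (!is.null(map)) {
    validate_region_map(map)
    if (nchar(seq) != max(map$end)) {
      stop("reference length ", nchar(seq), " does not match region map (",
           max(map$end), ")", call. = FALSE)
    }
  }
  seq
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(set)), names(set))
}
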