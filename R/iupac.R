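#' IUPAC ambiguity codes for one- and two-base sets
#'
#' Only the codes needed for biallelic SNP haplotypes are supported:
#' A, C, G, T and the six two-base ambiguity codes
#' (R = A/G, Y = C/T, K = G/T, M = A/C, S = G/C, W = A/T).
#'
#' @param bases Character vector of bases forming one set, or a list of such
#'   vectors for vectorised use.
#' @return A single ambiguity character per input set.
#' @examples
#' iupac_code(c("A", "G"))  # "R"
#' iupac_code("C")          # "C"
#' @export
iupac_code <- function(bases) {
  if (is.list(bases)) return(vapply(bases, iupac_code, character(1)))
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be in {A,C,G,T}", call. = FALSE)
  }
  if (length(bases) < 1L || length(bases) > 2L) {
    stop("only one- or two-base sets are supported", call. = FALSE)
  }
  key <- paste(bases, collapse = "")
  code <- c(A = "A", C = "C", G = "G", T = "T",
            AG = "R", CT = "Y", GT = "K", AC = "M", CG = "S", AT = "W")[key]
  unname(code)
}

#' @rdname iupac_code
#' @param code A vector of IUPAC characters (the ten supported codes).
#' @return `iupac_bases()` returns a list of base sets.
#' @export
iupac_bases <- function(code) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
               M = c("A", "C"), S = c("C", "G"), W = c("A", "T"))
  code <- toupper(code)
  if (!all(code %in% names(sets))) {
    stop("unsupported ambiguity code: ",
         paste(setdiff(code, names(sets)), collapse = ", "), call. = FALSE)
  }
  sets[code]
}

#' Reverse complement of a DNA string
#'
#' Plain-base reverse complement used by the read simulator and the in-silico
#' PCR primer search.
#'
#' @param seq Character vector of DNA strings over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
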