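# Layout of the synthetic nrDNA reference: fixed motif islands (primer
# sites, insertion-locus flanks, the two BstEII sites) plus inert filler
# zones that host the InDel anchors. Filler is G-free and CC-free, so no
# enzyme-recognition or primer motif can arise from any edit inside it.
nr_layout <- function() {
  primers <- its_primers()
  list(
    ins_pos   = 1862L,
    ins13     = "CGTGCGCAATGCG",
    ins16     = "CGACGTACACAATGCG",
    primer_f  = list(start = 1768L, seq = primers$forward),
    # TCGAAACC spacer + G^GTAACC (BstEII site 1, spanning position 1862) +
    # the CCCCAACCCC flank that closes the insertion-detection regexes
    locus_zone = list(start = 1846L, seq = "TCGAAACCTCTTGGTAACCCCAACCCC"),
    site1_start = 1858L,
    site2     = list(start = 2307L, seq = "GGTCACC"),
    primer_r  = list(start = 2439L, seq = revcomp(primers$reverse)),
    inert     = list(up = c(1809L, 1845L), alba = c(1895L, 1915L),
                     mid = c(2195L, 2245L), post = c(2325L, 2350L),
                     s26 = c(2995L, 3015L))
  )
}

inert_filler <- function(len) substr(strrep("CTA", ceiling(len / 3)), 1L, len)

# all start positions of `pattern` (a regex) in `s`, overlapping included
locate_all <- function(s, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# patterns that must occur only at their intended positions in the reference
forbidden_patterns <- function(layout = nr_layout()) {
  primers <- its_primers()
  list(
    list(pattern = "GGT[ACGT]ACC", len = 7L,
         allowed = c(layout$site1_start, layout$site2$start)),
    list(pattern = "TGCGCA", len = 6L, allowed = integer(0)),
    list(pattern = primers$forward, len = nchar(primers$forward),
         allowed = layout$primer_f$start),
    list(pattern = revcomp(primers$forward), len = nchar(primers$forward),
         allowed = integer(0)),
    list(pattern = primers$reverse, len = nchar(primers$reverse),
         allowed = integer(0)),
    list(pattern = layout$primer_r$seq, len = nchar(layout$primer_r$seq),
         allowed = layout$primer_r$start),
    list(pattern = "TCGAAACC", len = 8L, allowed = 1846L),
    list(pattern = "GGTTTCGA", len = 8L, allowed = integer(0)),
    list(pattern = "CCCCAACCCC", len = 10L, allowed = 1863L),
    list(pattern = "GGGGTTGGGG", len = 10L, allowed = integer(0))
  )
}

#' Build the synthetic nrDNA reference sequence
#'
#' Generates a 5814 bp reference with uniform-random background and fixed
#' functional islands: the ITS primer sites (placed so the amplicon carries
#' 41 bp of 18S and 37 bp of 26S), the insertion-locus flanks around
#' position 1862 that the read-counting regexes anchor on, the two BstEII
#' sites (ITS1 and ITS2), and G-free inert zones that host the species
#' InDel anchors. Background windows that match any primer or enzyme motif
#' are rejection-resampled, so the assembled sequence passes a motif audit
#' for every seed; generation fails with an error if resampling cannot
#' converge.
#'
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param map Region map (only the total length is used; must be the
#'   packaged 5814 bp map for the default layout to fit).
#' @return A single character string of length 5814.
#' @export
build_reference <- function(seed = 1L, map = region_map()) {
  layout <- nr_layout()
  total <- map_length(map)
  stopifnot(total >= layout$primer_r$start + nchar(layout$primer_r$seq) - 1L)
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)

  place <- function(chars, start, seq) {
    idx <- start:(start + nchar(seq) - 1L)
    chars[idx] <- strsplit(seq, "", fixed = TRUE)[[1L]]
    chars
  }
  fixed_idx <- integer(0)
  for (z in layout$inert) {
    chars <- place(chars, z[1L], inert_filler(z[2L] - z[1L] + 1L))
    fixed_idx <- c(fixed_idx, z[1L]:z[2L])
  }
  for (island in list(layout$primer_f, layout$locus_zone, layout$site2,
                      layout$primer_r)) {
    chars <- place(chars, island$start, island$seq)
    fixed_idx <- c(fixed_idx, island$start:(island$start + nchar(island$seq) - 1L))
  }
  fixed <- logical(total)
  fixed[fixed_idx] <- TRUE

  pats <- forbidden_patterns(layout)
  for (iter in seq_len(200L)) {
    s <- paste(chars, collapse = "")
    dirty <- FALSE
    for (p in pats) {
      hits <- setdiff(locate_all(s, p$pattern), p$allowed)
      for (h in hits) {
        span <- h:(h + p$len - 1L)
        bg <- span[!fixed[span]]
        if (!length(bg)) {
          stop("reference generation error: forbidden motif fixed at ", h,
               call. = FALSE)
        }
        chars[bg] <- sample(c("A", "C", "G", "T"), length(bg), replace = TRUE)
        dirty <- TRUE
      }
    }
    if (!dirty) return(paste(chars, collapse = ""))
  }
  stop("reference generation error: motif resampling did not converge",
       call. = FALSE)
}

#' Audit a sequence for unintended primer / enzyme motif occurrences
#'
#' @param seq The sequence to scan.
#' @param offset Shift applied to the intended positions (0 for the
#'   full-length reference).
#' @return A tibble of violations (zero rows when clean).
#' @export
motif_audit <- function(seq, offset = 0L) {
  out <- purrr::map_dfr(forbidden_patterns(), function(p) {
    hits <- setdiff(locate_all(seq, p$pattern), p$allowed + offset)
    if (!length(hits)) return(NULL)
    tibble(pattern = p$pattern, pos = hits)
  })
  if (nrow(out) == 0L) {
    out <- tibble(pattern = character(0), pos = integer(0))
  }
  out
}

# ---- species variant profiles -------------------------------------------

species_names <- function() {
  c("M. nigra", "M. serrata", "M. rubra", "M. celtidifolia",
    "M. notabilis", "M. alba")
}

# SNP positions per species and region. Pools avoid every fixed island and
# inert zone (with padding), so a substitution can never touch a placed
# motif; counts per region reproduce the study tallies.
snp_position_table <- function() {
  species <- species_names()
  counts <- list(
    `18S`  = c(6L, 8L, 8L, 6L, 11L, 6L),
    ITS1   = c(8L, 9L, 7L, 10L, 17L, 4L),
    `5.8S` = c(0L, 1L, 3L, 0L, 1L, 1L),
    ITS2   = c(9L, 9L, 6L, 9L, 15L, 2L),  # notabilis gains 2313 below
    `26S`  = c(20L, 17L, 23L, 17L, 32L, 10L)
  )
  pools <- list(
    `18S`  = seq(20L, 920L, by = 20L),
    ITS1   = c(seq(1881L, 1891L, by = 2L), seq(1918L, 2022L, by = 2L)),
    `5.8S` = seq(2024L, 2186L, by = 2L),
    ITS2   = c(seq(2187L, 2191L, by = 2L), seq(2248L, 2298L, by = 2L),
               2322L, seq(2353L, 2419L, by = 2L)),
    `26S`  = setdiff(seq(2470L, 5810L, by = 20L), seq(2990L, 3020L))
  )
  tab <- purrr::map_dfr(names(counts), function(rg) {
    n <- counts[[rg]]
    stopifnot(sum(n) <= length(pools[[rg]]))
    tibble(species = rep(species, n),
           pos = pools[[rg]][seq_len(sum(n))],
           region = rg)
  })
  # the site-destroying substitution inside BstEII site 2 (ITS2) that makes
  # the M. notabilis amplicon refractory to digestion
  dplyr::bind_rows(tab, tibble(species = "M. notabilis", pos = 2313L,
                               region = "ITS2")) %>%
    dplyr::arrange(.data$species, .data$pos)
}

# InDel anchors per species. Every anchor sits inside an inert zone (or is
# the 13/16 bp insertion at 1862); the homogeneous sets realise the
# fragment geometry of the digestion table, the heterozygous ones are
# net-zero decorations carried by single accessions.
indel_spec_table <- function() {
  L <- nr_layout()
  tribble_rows <- list(
    # species, pos, op ("ins"/"del"), payload (ins seq or del length), zygosity
    list("M. nigra", 1812L, "del", 1L, "homogeneous"),
    list("M. nigra", L$ins_pos, "ins", L$ins13, "homogeneous"),
    list("M. nigra", 2210L, "ins", "T", "homogeneous"),
    list("M. nigra", 2213L, "ins", "T", "homogeneous"),
    list("M. nigra", 2216L, "ins", "T", "heterogeneous"),
    list("M. nigra", 2219L, "del", 1L, "heterogeneous"),
    list("M. nigra", 2330L, "del", 1L, "homogeneous"),
    list("M. nigra", 3000L, "del", 1L, "homogeneous"),

    list("M. serrata", 1815L, "ins", "T", "homogeneous"),
    list("M. serrata", 1818L, "del", 1L, "homogeneous"),
    list("M. serrata", L$ins_pos, "ins", L$ins13, "homogeneous"),
    list("M. serrata", 2222L, "ins", "T", "homogeneous"),
    list("M. serrata", 2225L, "ins", "T", "homogeneous"),
    list("M. serrata", 2333L, "del", 1L, "homogeneous"),

    list("M. rubra", 1821L, "ins", "T", "homogeneous"),
    list("M. rubra", 1824L, "del", 1L, "homogeneous"),
    list("M. rubra", L$ins_pos, "ins", L$ins13, "homogeneous"),
    list("M. rubra", 2228L, "ins", "T", "homogeneous"),
    list("M. rubra", 2231L, "ins", "T", "homogeneous"),
    list("M. rubra", 2336L, "del", 1L, "homogeneous"),

    list("M. celtidifolia", 1827L, "ins", "T", "homogeneous"),
    list("M. celtidifolia", 1830L, "del", 1L, "homogeneous"),
    list("M. celtidifolia", L$ins_pos, "ins", L$ins13, "homogeneous"),
    list("M. celtidifolia", 2234L, "ins", "AT", "homogeneous"),
    list("M. celtidifolia", 2339L, "ins", "T", "homogeneous"),
    list("M. celtidifolia", 2342L, "del", 1L, "homogeneous"),

    list("M. notabilis", 1833L, "ins", "AT", "homogeneous"),
    list("M. notabilis", 1836L, "ins", "TA", "homogeneous"),
    list("M. notabilis", 1839L, "ins", "T", "homogeneous"),
    list("M. notabilis", 1842L, "del", 1L, "homogeneous"),
    list("M. notabilis", L$ins_pos, "ins", L$ins16, "homogeneous"),
    list("M. notabilis", 2200L, "ins", "T", "homogeneous"),
    list("M. notabilis", 2203L, "del", 1L, "homogeneous"),
    list("M. notabilis", 3010L, "ins", "T", "heterogeneous"),

    list("M. alba", L$ins_pos, "ins", L$ins13, "heterogeneous"),
    list("M. alba", 1900L, "ins", "T", "heterogeneous"),
    list("M. alba", 1910L, "del", 1L, "heterogeneous")
  )
  purrr::map_dfr(tribble_rows, function(r) {
    tibble(species = r[[1]], pos = r[[2]], op = r[[3]],
           payload = list(r[[4]]), zygosity = r[[5]])
  })
}

transition_of <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}

# choose an alternative allele that does not create an enzyme motif in the
# local template context; transition preferred
pick_safe_alt <- function(tmpl, tpos, refbase) {
  cands <- unique(c(unname(transition_of(refbase)),
                    setdiff(c("A", "C", "G", "T"), refbase)))
  for (alt in cands) {
    cand <- tmpl
    substr(cand, tpos, tpos) <- alt
    win <- substr(cand, max(1L, tpos - 9L), min(nchar(cand), tpos + 9L))
    if (!grepl("GGT[ACGT]ACC|TGCGCA", win)) return(alt)
  }
  stop("generation error: no motif-safe alternative allele at template pos ",
       tpos, call. = FALSE)
}

#' Packaged per-species variant profiles
#'
#' Builds the six species variant profiles whose per-region SNP/InDel
#' counts and homogeneous/heterogeneous splits reproduce the study tallies
#' exactly: 43/44/47/42/77/23 SNPs for M. nigra / M. serrata / M. rubra /
#' M. celtidifolia / M. notabilis / M. alba, with 37+6 / 41+3 / 30+17 /
#' 36+6 / 72+5 / 0+23 homogeneous+heterogeneous, and 8/6/6/6/8/3 InDels.
#' M. notabilis carries the 16 bp ITS1 insertion homogeneously, the wild
#' nigra-group species carry the 13 bp insertion homogeneously, and
#' M. alba carries it heterogeneously. Alternative alleles are transitions
#' unless a transition would create an enzyme recognition motif in the
#' species template.
#'
#' @param reference The reference string from [build_reference()].
#' @return A tibble with columns `species`, `pos`, `region`, `kind`,
#'   `ref`, `alt`, `zygosity`.
#' @export
species_profiles <- function(reference) {
  map <- region_map()
  stopifnot(nchar(reference) == map_length(map))
  snps <- snp_position_table()
  indels <- indel_spec_table()

  indel_rows <- indels %>%
    dplyr::mutate(
      ref = purrr::map2_chr(.data$pos, seq_len(nrow(indels)), function(p, i) {
        if (indels$op[i] == "del") {
          substr(reference, p, p + indels$payload[[i]])
        } else substr(reference, p, p)
      }),
      alt = purrr::map_chr(seq_len(nrow(indels)), function(i) {
        p <- indels$pos[i]
        if (indels$op[i] == "del") substr(reference, p, p)
        else paste0(substr(reference, p, p), indels$payload[[i]])
      }),
      region = assign_region(.data$pos, map),
      kind = "InDel"
    ) %>%
    dplyr::select("species", "pos", "region", "kind", "ref", "alt", "zygosity")

  het_counts <- c("M. nigra" = 6L, "M. serrata" = 3L, "M. rubra" = 17L,
                  "M. celtidifolia" = 6L, "M. notabilis" = 5L,
                  "M. alba" = 23L)

  snp_rows <- purrr::map_dfr(species_names(), function(sp) {
    sp_snps <- snps %>% dplyr::filter(.data$species == sp) %>%
      dplyr::arrange(.data$pos)
    n <- nrow(sp_snps)
    k_het <- het_counts[[sp]]
    zyg <- c(rep("homogeneous", n - k_het), rep("heterogeneous", k_het))
    sp_indels <- indel_rows %>%
      dplyr::filter(.data$species == sp, .data$zygosity == "homogeneous")
    # template context with homogeneous InDels applied (descending order
    # keeps upstream coordinates stable)
    tmpl <- apply_edits(reference, sp_indels)
    net <- nchar(sp_indels$alt) - nchar(sp_indels$ref)
    refbase <- substring(reference, sp_snps$pos, sp_snps$pos)
    alt <- character(n)
    for (i in seq_len(n)) {
      p <- sp_snps$pos[i]
      in_its <- sp_snps$region[i] %in% c("ITS1", "5.8S", "ITS2")
      if (!in_its) {
        alt[i] <- unname(transition_of(refbase[i]))
        next
      }
      tpos <- p + sum(net[sp_indels$pos < p])
      alt[i] <- pick_safe_alt(tmpl, tpos, refbase[i])
      if (zyg[i] == "homogeneous") substr(tmpl, tpos, tpos) <- alt[i]
    }
    tibble(species = sp, pos = sp_snps$pos, region = sp_snps$region,
           kind = "SNP", ref = refbase, alt = alt, zygosity = zyg)
  })

  dplyr::bind_rows(snp_rows, indel_rows) %>%
    dplyr::arrange(.data$species, .data$pos) %>%
    as_tibble()
}

#' Apply anchored edits to a sequence
#'
#' Edits are VCF-style (pos, ref, alt) with 1-based anchors; they must not
#' overlap. Application proceeds in descending position order so upstream
#' coordinates stay valid; each edit's `ref` is verified against the
#' sequence before substitution.
#'
#' @param seq A single DNA string.
#' @param edits A data frame with columns `pos`, `ref`, `alt`.
#' @return The edited string.
#' @export
apply_edits <- function(seq, edits) {
  edits <- dplyr::arrange(as_tibble(edits), dplyr::desc(.data$pos))
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    refseq <- edits$ref[i]
    found <- substr(seq, p, p + nchar(refseq) - 1L)
    if (found != refseq) {
      stop("edit at ", p, " expects '", refseq, "' but sequence has '",
           found, "'", call. = FALSE)
    }
    seq <- paste0(substr(seq, 1L, p - 1L), edits$alt[i],
                  substr(seq, p + nchar(refseq), nchar(seq)))
  }
  seq
}

# expected digestion table used by the template audit
caps_expected <- function() {
  list(
    "M. alba"            = list(amp = 689L, bste2 = c(91L, 149L, 449L), mst1 = 689L),
    "M. alba (insertion)" = list(amp = 702L, bste2 = c(149L, 553L), mst1 = c(100L, 602L)),
    "M. celtidifolia"    = list(amp = 704L, bste2 = c(149L, 555L), mst1 = c(100L, 604L)),
    "M. rubra"           = list(amp = 703L, bste2 = c(148L, 555L), mst1 = c(100L, 603L)),
    "M. notabilis"       = list(amp = 709L, bste2 = 709L, mst1 = 709L),
    "M. serrata"         = list(amp = 703L, bste2 = c(148L, 555L), mst1 = c(100L, 603L)),
    "M. nigra"           = list(amp = 702L, bste2 = c(148L, 554L), mst1 = c(99L, 603L))
  )
}

#' Build per-species ITS templates and audit them against the digestion table
#'
#' Applies each species' homogeneous variants to the reference to obtain
#' the consensus template, plus the insertion-allele template of M. alba
#' (whose 13 bp insertion is heterozygous). Every template is audited: the
#' in-silico PCR amplicon length and the BstEII/MstI fragment multisets
#' must equal the packaged digestion table, otherwise generation fails.
#'
#' @param reference Reference string from [build_reference()].
#' @param profiles Profiles from [species_profiles()]; rebuilt when `NULL`.
#' @return A tibble with columns `label`, `species`, `allele`
#'   ("consensus" / "insertion"), `template` and `its_length` (bp between
#'   the 18S and 26S boundaries).
#' @export
build_its_templates <- function(reference, profiles = NULL) {
  if (is.null(profiles)) profiles <- species_profiles(reference)
  its_regions <- c("ITS1", "5.8S", "ITS2")
  rows <- purrr::map_dfr(species_names(), function(sp) {
    hom <- profiles %>%
      dplyr::filter(.data$species == sp, .data$zygosity == "homogeneous")
    net_its <- sum((nchar(hom$alt) - nchar(hom$ref))[hom$region %in% its_regions])
    tibble(label = sp, species = sp, allele = "consensus",
           template = apply_edits(reference, hom),
           its_length = 611L + net_its)
  })
  alba_ins <- profiles %>%
    dplyr::filter(.data$species == "M. alba", .data$kind == "InDel",
                  .data$pos == nr_layout()$ins_pos)
  stopifnot(nrow(alba_ins) == 1L)
  rows <- dplyr::bind_rows(
    rows,
    tibble(label = "M. alba (insertion)", species = "M. alba",
           allele = "insertion",
           template = apply_edits(reference, alba_ins),
           its_length = 611L + nchar(alba_ins$alt) - nchar(alba_ins$ref))
  )
  rows$allele[rows$label == "M. alba"] <- "reference"

  expected <- caps_expected()
  for (i in seq_len(nrow(rows))) {
    lab <- rows$label[i]
    exp <- expected[[lab]]
    amp <- insilico_pcr(rows$template[i])
    b <- digest_fragments(amp, "BstEII")
    m <- digest_fragments(amp, "MstI")
    ok <- nchar(amp) == exp$amp && identical(b, sort(as.integer(exp$bste2))) &&
      identical(m, sort(as.integer(exp$mst1)))
    if (!ok) {
      stop("template audit failed for ", lab, ": amplicon ", nchar(amp),
           ", BstEII ", paste(b, collapse = "/"),
           ", MstI ", paste(m, collapse = "/"), call. = FALSE)
    }
  }
  rows
}

# ---- cohort composition and simulation ----------------------------------

#' The packaged 542-accession cohort composition
#'
#' Thirty-one haplotypes: nine repeated groups of sizes
#' 457, 21, 13, 13, 6, 4, 2, 2, 2 plus 22 singletons. Species membership:
#' 514 M. alba-clade accessions (457 identical to the reference), 16
#' M. notabilis (13 sharing one haplotype), 5 M. celtidifolia, 3 M. nigra,
#' 3 M. rubra and 1 M. serrata. `het_snps` / `het_indels` give, for each
#' haplotype, the indices (position order) of the species' heterogeneous
#' loci it carries; wild-species haplotypes additionally carry all of the
#' species' homogeneous loci.
#'
#' @return A tibble with columns `haplotype_id`, `species`, `size`,
#'   `het_snps`, `het_indels`.
#' @export
cohort_composition <- function() {
  row <- function(id, sp, size, hs = integer(0), hi = integer(0)) {
    tibble(haplotype_id = id, species = sp, size = as.integer(size),
           het_snps = list(as.integer(hs)), het_indels = list(as.integer(hi)))
  }
  # M. alba heterogeneous-SNP ordinals (position order over its 23 loci):
  # 1-6 = 18S, 7-10 = ITS1, 11 = 5.8S, 12-13 = ITS2, 14-23 = 26S
  dplyr::bind_rows(
    row("alba_ref",  "M. alba", 457L),
    row("alba_g21",  "M. alba", 21L, hs = 7L),          # one het SNP in ITS1
    row("alba_g13",  "M. alba", 13L, hs = 1:4),
    row("notab_g13", "M. notabilis", 13L, hs = 5L),
    row("alba_g6",   "M. alba", 6L, hs = c(5L, 6L, 8L, 9L)),
    row("alba_g4",   "M. alba", 4L, hs = 14:17),
    row("alba_g2a",  "M. alba", 2L, hs = 1:12),
    row("alba_g2b",  "M. alba", 2L, hs = 10:13),
    row("alba_g2c",  "M. alba", 2L, hs = 18:21),
    row("alba_s1",   "M. alba", 1L, hs = 22L, hi = 1L),  # het 13 bp insertion
    row("alba_s2",   "M. alba", 1L, hs = 23L, hi = 2L),
    row("alba_s3",   "M. alba", 1L, hs = c(22L, 23L), hi = 3L),
    row("alba_s4",   "M. alba", 1L, hs = c(7L, 22L)),
    row("alba_s5",   "M. alba", 1L, hs = c(7L, 23L)),
    row("alba_s6",   "M. alba", 1L, hs = c(1L, 22L)),
    row("alba_s7",   "M. alba", 1L, hs = c(1L, 23L)),
    row("notab_s1",  "M. notabilis", 1L),
    row("notab_s2",  "M. notabilis", 1L, hs = 1:4, hi = 1L),
    row("notab_s3",  "M. notabilis", 1L, hs = 1:5, hi = 1L),
    row("celt_s1",   "M. celtidifolia", 1L, hs = 1:2),
    row("celt_s2",   "M. celtidifolia", 1L, hs = 1:3),
    row("celt_s3",   "M. celtidifolia", 1L, hs = 1:4),
    row("celt_s4",   "M. celtidifolia", 1L, hs = 1:5),
    row("celt_s5",   "M. celtidifolia", 1L, hs = 1:6),
    row("nigra_s1",  "M. nigra", 1L, hs = 1:4, hi = 1:2),
    row("nigra_s2",  "M. nigra", 1L, hs = 1:5),
    row("nigra_s3",  "M. nigra", 1L, hs = 1:6),
    row("rubra_s1",  "M. rubra", 1L, hs = 1:15),
    row("rubra_s2",  "M. rubra", 1L, hs = 1:16),
    row("rubra_s3",  "M. rubra", 1L, hs = 1:17),
    row("serr_s1",   "M. serrata", 1L, hs = 1:3)
  )
}

# passing GATK-style site annotations attached to every simulated record
default_annotations <- function() {
  tibble(QD = 28.3, MQ = 60, FS = 1.2, SOR = 0.8, QUAL = 2200,
         MQRankSum = 0.4, ReadPosRankSum = -0.6)
}

#' Simulate the accession cohort from species profiles
#'
#' Realises the packaged composition as per-accession variant records:
#' each wild-species accession carries all homogeneous loci of its species
#' as 1/1 calls, plus its haplotype's subset of heterogeneous loci as 0/1
#' calls; M. alba-clade accessions carry only heterozygous subsets. All
#' records get passing filter annotations. The output is deterministic.
#'
#' @param profiles Profiles from [species_profiles()].
#' @param composition Composition tibble, default [cohort_composition()].
#' @return A list with `variants` (one row per accession x call:
#'   accession_id, species, pos, region, kind, ref, alt, gt + annotation
#'   columns) and `metadata` (accession_id, species, haplotype_id).
#' @export
simulate_cohort <- function(profiles, composition = cohort_composition()) {
  stopifnot(all(composition$species %in% profiles$species))
  ids <- sprintf("MUL%04d", seq_len(sum(composition$size)))
  metadata <- tibble(
    accession_id = ids,
    species = rep(composition$species, composition$size),
    haplotype_id = rep(composition$haplotype_id, composition$size)
  )

  per_hap <- purrr::pmap(composition, function(haplotype_id, species, size,
                                               het_snps, het_indels) {
    prof <- profiles[profiles$species == species, ]
    hom <- prof[prof$zygosity == "homogeneous", ]
    het_snp_loci <- prof[prof$zygosity == "heterogeneous" &
                           prof$kind == "SNP", ]
    het_indel_loci <- prof[prof$zygosity == "heterogeneous" &
                             prof$kind == "InDel", ]
    stopifnot(all(het_snps <= nrow(het_snp_loci)),
              all(het_indels <= nrow(het_indel_loci)))
    calls <- dplyr::bind_rows(
      dplyr::mutate(hom, gt = "1/1"),
      dplyr::mutate(het_snp_loci[het_snps, ], gt = "0/1"),
      dplyr::mutate(het_indel_loci[het_indels, ], gt = "0/1")
    )
    dplyr::select(calls, "pos", "region", "kind", "ref", "alt", "gt")
  })
  names(per_hap) <- composition$haplotype_id

  variants <- metadata %>%
    dplyr::mutate(calls = per_hap[.data$haplotype_id]) %>%
    tidyr::unnest("calls") %>%
    dplyr::select(-"haplotype_id")
  ann <- default_annotations()
  for (a in names(ann)) variants[[a]] <- ann[[a]]

  list(variants = variants, metadata = metadata)
}

#' Summarise species profiles into the two study-table shapes
#'
#' Derives the per-region and per-zygosity locus counts directly from the
#' profiles (the counts a faithful cohort simulation must tally back to).
#'
#' @param profiles Profiles from [species_profiles()].
#' @return A list with `region` and `zygosity` tibbles matching the
#'   column layout of [tally_variants()].
#' @export
profile_summary <- function(profiles) {
  loci <- profiles %>%
    dplyr::mutate(region = pool_its(.data$region))
  region <- loci %>%
    dplyr::count(.data$species, .data$kind, .data$region) %>%
    dplyr::mutate(col = paste0(ifelse(.data$kind == "SNP", "snp_", "indel_"),
                               .data$region)) %>%
    dplyr::select("species", "col", "n") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::arrange(.data$species)
  for (col in c("snp_18S", "snp_ITS", "snp_26S",
                "indel_18S", "indel_ITS", "indel_26S")) {
    if (!col %in% names(region)) region[[col]] <- 0L
  }
  region <- dplyr::select(region, "species", "snp_18S", "snp_ITS", "snp_26S",
                          "indel_18S", "indel_ITS", "indel_26S")
  zygosity <- loci %>%
    dplyr::count(.data$species, .data$kind, .data$zygosity) %>%
    dplyr::mutate(col = paste0(ifelse(.data$kind == "SNP", "snp_", "indel_"),
                               .data$zygosity)) %>%
    dplyr::select("species", "col", "n") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::arrange(.data$species)
  for (col in c("snp_homogeneous", "snp_heterogeneous",
                "indel_homogeneous", "indel_heterogeneous")) {
    if (!col %in% names(zygosity)) zygosity[[col]] <- 0L
  }
  zygosity <- dplyr::select(zygosity, "species", "snp_homogeneous",
                            "snp_heterogeneous", "indel_homogeneous",
                            "indel_heterogeneous")
  list(region = region, zygosity = zygosity)
}
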