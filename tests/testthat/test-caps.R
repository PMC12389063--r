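test_that("find_sites locates degenerate motifs with the right cut offsets", {
  # BstEII G^GTNACC: motif at 3, cut after position 3, for every N base
  for (n_base in c("A", "C", "G", "T")) {
    seq <- paste0("AAG", "GT", n_base, "ACCTT")
    expect_equal(find_sites(seq, "BstEII"), 3L, info = n_base)
  }
  # MstI TGC^GCA (blunt): motif at 2, cut after position 4
  expect_equal(find_sites("TTGCGCATT", "MstI"), 4L)
  expect_equal(find_sites("AAAA", "BstEII"), integer(0))
  expect_error(find_sites("AAAA", "NoSuchEnzyme"), "unknown enzyme")
})

test_that("digestion fragments always sum to the sequence length", {
  expect_equal(digest_fragments("AAGGTAACCTT", "BstEII"), c(3L, 8L))
  set.seed(13)
  for (rep in 1:20) {
    s <- random_dna(sample(200:2000, 1))
    for (enz in c("BstEII", "MstI")) {
      fr <- digest_fragments(s, enz)
      expect_equal(sum(fr), nchar(s))
      expect_equal(length(fr), length(find_sites(s, enz)) + 1L)
    }
  }
})

test_that("site finding matches a brute-force windowed-motif oracle", {
  set.seed(19)
  enz <- caps_enzymes()
  for (rep in 1:60) {
    s <- random_dna(2000)
    for (i in 1:2) {
      starts <- brute_motif_starts(s, enz$motif[i])
      expect_equal(find_sites(s, enz[i, ]),
                   sort(starts + enz$cut_offset[i] - 1L))
    }
  }
  # seeded positives: plant motifs explicitly
  planted <- paste0(random_dna(50), "GGTGACC", random_dna(30), "TGCGCA",
                    random_dna(20))
  expect_equal(find_sites(planted, "BstEII"), 51L)
  expect_equal(find_sites(planted, "MstI"), 88L + 2L)
})

test_that("in-silico PCR requires unique, ordered primer sites", {
  ref <- fixture_reference()
  amp <- insilico_pcr(ref)
  expect_equal(nchar(amp), 689L)
  expect_true(startsWith(amp, its_primers()$forward))
  expect_true(endsWith(amp, revcomp(its_primers()$reverse)))
  expect_error(insilico_pcr(random_dna(500)), "primer site not found")
  # duplicated forward site makes the product ambiguous
  dup <- paste0(substr(ref, 1, 100), its_primers()$forward,
                substr(ref, 101, nchar(ref)))
  expect_error(insilico_pcr(dup), "ambiguous")
})

test_that("the insertion alleles carry the documented MstI content", {
  # 13 bp insertion: exactly one MstI motif; 16 bp insertion: none
  ins13 <- "CGTGCGCAATGCG"
  ins16 <- "CGACGTACACAATGCG"
  expect_equal(brute_motif_starts(ins13, "TGCGCA"), 3L)
  expect_equal(brute_motif_starts(ins16, "TGCGCA"), integer(0))
})

test_that("the packaged templates reproduce the fragment-length table", {
  tpl <- fixture_templates()
  ct <- caps_table(setNames(tpl$template, tpl$label))
  row <- function(lab) ct[ct$template == lab, ]
  expect_equal(row("M. alba")$amplicon_length, 689L)
  expect_equal(row("M. alba")$bste2[[1]], c(91L, 149L, 449L))
  expect_equal(row("M. alba")$mst1[[1]], 689L)
  expect_equal(row("M. alba (insertion)")$amplicon_length, 702L)
  expect_equal(row("M. alba (insertion)")$bste2[[1]], c(149L, 553L))
  expect_equal(row("M. alba (insertion)")$mst1[[1]], c(100L, 602L))
  expect_equal(row("M. celtidifolia")$amplicon_length, 704L)
  expect_equal(row("M. celtidifolia")$bste2[[1]], c(149L, 555L))
  expect_equal(row("M. celtidifolia")$mst1[[1]], c(100L, 604L))
  expect_equal(row("M. rubra")$amplicon_length, 703L)
  expect_equal(row("M. rubra")$bste2[[1]], c(148L, 555L))
  expect_equal(row("M. rubra")$mst1[[1]], c(100L, 603L))
  expect_equal(row("M. serrata")$amplicon_length, 703L)
  expect_equal(row("M. serrata")$bste2[[1]], c(148L, 555L))
  expect_equal(row("M. serrata")$mst1[[1]], c(100L, 603L))
  expect_equal(row("M. nigra")$amplicon_length, 702L)
  expect_equal(row("M. nigra")$bste2[[1]], c(148L, 554L))
  expect_equal(row("M. nigra")$mst1[[1]], c(99L, 603L))
  expect_equal(row("M. notabilis")$amplicon_length, 709L)
  expect_equal(row("M. notabilis")$bste2[[1]], 709L)
  expect_equal(row("M. notabilis")$mst1[[1]], 709L)
})

test_that("banding classification implements the diagnostic key", {
  expect_equal(classify_banding(c(91, 149, 449), 689)$label, "M. alba")
  expect_equal(classify_banding(709, 709)$label, "M. notabilis")
  expect_equal(classify_banding(c(148, 554), c(99, 603))$label, "nigra_group")
  het <- classify_banding(c(91, 149, 449, 149, 553), c(689, 100, 602))
  expect_equal(het$label, "heterogeneous_indel")
  # small bands are never evidence: 91/100 alone resolve nothing
  expect_equal(classify_banding(c(91, 598), c(100, 589))$label, "unresolved")
  # tolerance window
  expect_equal(classify_banding(c(150, 553), c(100, 607))$label,
               "nigra_group")
  expect_equal(classify_banding(c(150, 553), c(100, 612), tol = 0)$label,
               "unresolved")
  expect_error(classify_banding(numeric(0), 689), "empty")
})

test_that("caps_table flags a mixed-allele accession via the band union", {
  tpl <- fixture_templates()
  both <- caps_table(setNames(tpl$template, tpl$label))
  union_b <- c(both$bste2[[which(both$template == "M. alba")]],
               both$bste2[[which(both$template == "M. alba (insertion)")]])
  union_m <- c(both$mst1[[which(both$template == "M. alba")]],
               both$mst1[[which(both$template == "M. alba (insertion)")]])
  expect_equal(classify_banding(union_b, union_m)$label,
               "heterogeneous_indel")
})
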