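test_that("reference build is deterministic and passes the motif audit", {
  ref <- fixture_reference()
  expect_equal(nchar(ref), 5814L)
  expect_identical(ref, build_reference(1L))
  expect_equal(nrow(motif_audit(ref)), 0L)
  # placed islands: primers, insertion-locus flanks, both BstEII sites
  expect_equal(substr(ref, 1768, 1788), its_primers()$forward)
  expect_equal(substr(ref, 2439, 2456), revcomp(its_primers()$reverse))
  expect_equal(substr(ref, 1846, 1853), "TCGAAACC")
  expect_equal(substr(ref, 1863, 1872), "CCCCAACCCC")
  expect_equal(find_sites(ref, "BstEII"), c(1858L, 2307L))
  expect_equal(find_sites(ref, "MstI"), integer(0))
  # different seeds give different backgrounds but identical geometry
  ref2 <- fixture_reference(2L)
  expect_false(identical(ref, ref2))
  expect_equal(find_sites(ref2, "BstEII"), c(1858L, 2307L))
})

test_that("species profiles reproduce the published per-species counts", {
  prof <- fixture_profiles()
  s <- profile_summary(prof)
  expected_region <- tibble::tribble(
    ~species, ~snp_18S, ~snp_ITS, ~snp_26S, ~indel_18S, ~indel_ITS, ~indel_26S,
    "M. alba",          6L,  7L, 10L, 0L, 3L, 0L,
    "M. celtidifolia",  6L, 19L, 17L, 0L, 6L, 0L,
    "M. nigra",         6L, 17L, 20L, 0L, 7L, 1L,
    "M. notabilis",    11L, 34L, 32L, 0L, 7L, 1L,
    "M. rubra",         8L, 16L, 23L, 0L, 6L, 0L,
    "M. serrata",       8L, 19L, 17L, 0L, 6L, 0L
  )
  expect_equal(as.data.frame(s$region), as.data.frame(expected_region))
  expected_zyg <- tibble::tribble(
    ~species, ~snp_homogeneous, ~snp_heterogeneous, ~indel_homogeneous,
    ~indel_heterogeneous,
    "M. alba",          0L, 23L, 0L, 3L,
    "M. celtidifolia", 36L,  6L, 6L, 0L,
    "M. nigra",        37L,  6L, 6L, 2L,
    "M. notabilis",    72L,  5L, 7L, 1L,
    "M. rubra",        30L, 17L, 6L, 0L,
    "M. serrata",      41L,  3L, 6L, 0L
  )
  expect_equal(as.data.frame(s$zygosity), as.data.frame(expected_zyg))
})

test_that("profile loci sit inside their assigned regions and pass filters", {
  prof <- fixture_profiles()
  expect_equal(assign_region(prof$pos), prof$region)
  expect_true(all(prof$ref != prof$alt))
  # the insertion alleles at 1862 are the published 13/16 bp sequences
  ins <- prof[prof$pos == 1862L & prof$kind == "InDel", ]
  expect_equal(nchar(ins$alt) - nchar(ins$ref),
               ifelse(ins$species == "M. notabilis", 16L, 13L))
  expect_equal(assign_region(1862L), "ITS1")
  # every simulated record passes the hard filters
  filtered <- apply_hard_filters(fixture_cohort()$variants)
  expect_true(all(filtered$pass))
})

test_that("templates apply edits faithfully and audit against digestion", {
  ref <- fixture_reference()
  expect_equal(apply_edits("ACGTACGT",
                           tibble::tibble(pos = c(2L, 5L),
                                          ref = c("C", "AC"),
                                          alt = c("T", "A"))),
               "ATGTAGT")
  expect_error(apply_edits("ACGT", tibble::tibble(pos = 1L, ref = "G",
                                                  alt = "A")),
               "expects")
  tpl <- fixture_templates()
  expect_equal(nrow(tpl), 7L)
  expect_equal(tpl$its_length[tpl$label == "M. notabilis"], 631L)
  expect_equal(tpl$its_length[tpl$label == "M. alba"], 611L)
  # ITS span equals template length minus the (unchanged) 18S length and
  # the 26S span actually present in each template
  nota <- tpl$template[tpl$label == "M. notabilis"]
  expect_equal(nchar(insilico_pcr(nota)), 41L + 631L + 37L)
})

test_that("cohort simulation is deterministic and matches its composition", {
  comp <- cohort_composition()
  expect_equal(sum(comp$size), 542L)
  expect_equal(nrow(comp), 31L)
  cohort <- fixture_cohort()
  expect_identical(cohort$variants, simulate_cohort(fixture_profiles())$variants)
  expect_equal(nrow(cohort$metadata), 542L)
  counts <- dplyr::count(cohort$metadata, .data$species)
  expect_equal(setNames(counts$n, counts$species),
               c("M. alba" = 514L, "M. celtidifolia" = 5L, "M. nigra" = 3L,
                 "M. notabilis" = 16L, "M. rubra" = 3L, "M. serrata" = 1L))
})

test_that("simulated outputs are byte-identical across runs with one seed", {
  ref_a <- build_reference(7L)
  ref_b <- build_reference(7L)
  expect_identical(ref_a, ref_b)
  sa <- default_insertion_status(fixture_cohort()$metadata)[1:5, ]
  ra <- simulate_cohort_reads(ref_a, sa, depth = 10, seed = 99)
  rb <- simulate_cohort_reads(ref_b, sa, depth = 10, seed = 99)
  expect_identical(ra, rb)
})

test_that("the cohort-wide insertion read counter flags 539 mixed accessions", {
  ref <- fixture_reference()
  statuses <- default_insertion_status(fixture_cohort()$metadata)
  expect_equal(sum(statuses$status == "mixed"), 539L)
  expect_equal(sum(statuses$status == "ins_only"), 3L)
  reads <- simulate_cohort_reads(ref, statuses, depth = 50,
                                 read_length = 150, seed = 5)
  tal <- tally_insertion_cohort(reads)
  expect_equal(sum(tal$status == "mixed"), 539L)
  expect_equal(sum(tal$status == "ins_only"), 3L)
  joined <- dplyr::left_join(statuses, tal, by = "accession_id")
  expect_equal(joined$status.x, joined$status.y)
})
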