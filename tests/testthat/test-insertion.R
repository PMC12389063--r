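# independent oracle: literal substring search instead of regexes
brute_classify <- function(read) {
  find_all <- function(s, p) {
    hits <- integer(0)
    k <- nchar(p)
    for (i in seq_len(max(0, nchar(s) - k + 1))) {
      if (substr(s, i, i + k - 1) == p) hits <- c(hits, i)
    }
    hits
  }
  pair_match <- function(s, left, right) {
    ls <- find_all(s, left)
    rs <- find_all(s, right)
    # ".+" between the flanks requires at least one intervening base
    any(vapply(ls, function(l) any(rs > l + nchar(left)), logical(1)))
  }
  ins <- pair_match(read, "TCGAAACC", "AATGCGCCCCAACCCC") ||
    pair_match(read, "GGGGTTGGGGCGCATT", "GGTTTCGA")
  ref <- pair_match(read, "TCGAAACC", "CCCCAACCCC") ||
    pair_match(read, "GGGGTTGGGG", "GGTTTCGA")
  if (ins) "ins" else if (ref) "ref" else "neither"
}

test_that("read classification follows the printed patterns", {
  expect_equal(classify_reads(paste0("TCGAAACC", "CGTGCGC",
                                     "AATGCGCCCCAACCCC")), "ins")
  # flank pair with no insertion tail is a reference read
  expect_equal(classify_reads("TCGAAACCXCCCCAACCCC"), "ref")
  # reverse-orientation insertion read
  expect_equal(classify_reads("GGGGTTGGGGCGCATTXGGTTTCGA"), "ins")
  expect_equal(classify_reads("ACGTACGT"), "neither")
  # the wildcard needs at least one intervening base
  expect_equal(classify_reads("TCGAAACCCCCCAACCCC"), "neither")
})

test_that("classification matches the brute-force oracle on random reads", {
  set.seed(23)
  parts <- c("TCGAAACC", "AATGCGCCCCAACCCC", "CCCCAACCCC", "GGTTTCGA",
             "GGGGTTGGGGCGCATT", "GGGGTTGGGG")
  reads <- character(0)
  for (rep in 1:120) {
    # random backbone with 0-2 pattern parts spliced in
    read <- random_dna(sample(30:80, 1))
    for (k in seq_len(sample(0:2, 1))) {
      at <- sample(nchar(read), 1)
      read <- paste0(substr(read, 1, at), sample(parts, 1),
                     substr(read, at + 1, nchar(read)))
    }
    reads <- c(reads, read)
  }
  expect_equal(classify_reads(reads),
               vapply(reads, brute_classify, character(1), USE.NAMES = FALSE))
})

test_that("every insertion-matching read also matches the reference pattern", {
  ref <- fixture_reference()
  set.seed(41)
  for (insert in c("13bp", "16bp")) {
    reads <- simulate_insertion_reads(ref, "ins_only", depth = 40,
                                      read_length = 120, seed = 9,
                                      insert = insert)
    pats <- insertion_patterns()
    is_ref <- grepl(pats$ref[["forward"]], reads) |
      grepl(pats$ref[["reverse"]], reads)
    expect_true(all(is_ref))
    expect_true(all(classify_reads(reads) == "ins"))  # precedence wins
  }
})

test_that("tally_reads applies the evidence threshold to the status", {
  ins_read <- "TCGAAACCACGTGCGCAATGCGCCCCAACCCC"
  ref_read <- "TCGAAACCACCCCAACCCC"
  expect_equal(tally_reads(c(rep(ins_read, 50), rep(ref_read, 50)))$status,
               "mixed")
  expect_equal(tally_reads(character(0))$status, "nocall")
  expect_equal(tally_reads(character(0))$n_total, 0L)
  expect_equal(tally_reads(rep(ins_read, 10))$status, "ins_only")
  expect_equal(tally_reads(rep(ref_read, 3))$status, "ref_only")
  t <- tally_reads(c(ins_read, ref_read, "AAAA"), min_reads = 2)
  expect_equal(t$status, "nocall")
  expect_equal(t$n_total, 3L)
  expect_true(t$n_ins + t$n_ref <= t$n_total)
})

test_that("tallies are order-invariant and additive over concatenation", {
  ref <- fixture_reference()
  a <- simulate_insertion_reads(ref, "mixed", depth = 30, seed = 2)
  b <- simulate_insertion_reads(ref, "ref_only", depth = 10, seed = 3)
  t_ab <- tally_reads(c(a, b))
  t_perm <- tally_reads(sample(c(a, b)))
  expect_equal(t_ab[, c("n_ins", "n_ref", "n_total")],
               t_perm[, c("n_ins", "n_ref", "n_total")])
  expect_equal(t_ab$n_ins, tally_reads(a)$n_ins + tally_reads(b)$n_ins)
  expect_equal(t_ab$n_ref, tally_reads(a)$n_ref + tally_reads(b)$n_ref)
})

test_that("the read simulator realises the requested status", {
  ref <- fixture_reference()
  t <- tally_reads(simulate_insertion_reads(ref, "mixed", depth = 100,
                                            read_length = 150, seed = 7))
  expect_equal(t$status, "mixed")
  expect_equal(t$n_ins + t$n_ref, 100L)
  t <- tally_reads(simulate_insertion_reads(ref, "ref_only", depth = 20,
                                            seed = 8))
  expect_equal(t$n_ins, 0L)
  expect_error(simulate_insertion_reads(ref, "mixed", depth = 10,
                                        read_length = 30, seed = 1),
               "read_length too short")
})

test_that("FASTQ round-trips through gzip with accession-coded names", {
  reads <- tibble::tibble(accession_id = rep(c("x1", "x2"), each = 3),
                          read = replicate(6, random_dna(40)))
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$accession_id, reads$accession_id)
  expect_equal(back$read, reads$read)
})
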