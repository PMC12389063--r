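test_that("ambiguity distance counts disjoint base-set columns", {
  expect_equal(ambiguity_distance("ACGT", "ACGT"), 0)
  expect_equal(ambiguity_distance("R", "A"), 0)   # {A,G} and {A} overlap
  expect_equal(ambiguity_distance("R", "C"), 1)
  expect_equal(ambiguity_distance("AC", "GT"), 1) # both columns disjoint
  expect_equal(ambiguity_distance("ARGT", "AAGA"), 0.25)
  expect_error(ambiguity_distance("AC", "A"), "equal")
  # symmetry and identity over random ambiguity strings
  set.seed(5)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "K", "M", "S", "W")
  for (rep in 1:10) {
    a <- paste(sample(alphabet, 20, TRUE), collapse = "")
    b <- paste(sample(alphabet, 20, TRUE), collapse = "")
    expect_equal(ambiguity_distance(a, b), ambiguity_distance(b, a))
    expect_equal(ambiguity_distance(a, a), 0)
  }
})

test_that("three taxa resolve to the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))
  len <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("NJ recovers a known 4-taxon additive tree exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- ape::cophenetic.phylo(true)
  tree <- nj_tree(d[LETTERS[1:4], LETTERS[1:4]])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), tree)), 0)
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]],
               d[LETTERS[1:4], LETTERS[1:4]])
})

test_that("NJ recovers random additive 5-8 taxon trees", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) stats::runif(k, 0.5, 3))
    d <- ape::cophenetic.phylo(true)
    mine <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(true, mine)), 0)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    # cross-check against the independent NJ in ape
    expect_equal(as.numeric(ape::dist.topo(ape::nj(d), mine)), 0)
  }
})

test_that("NJ rejects degenerate input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "symmetric")
})

test_that("species clusters handle degenerate labelings", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  one <- species_clusters(tree, c(a = "s", b = "s", c = "s", d = "s"))
  expect_equal(one$n_clusters, 1L)
  expect_error(species_clusters(tree, c(a = "s")), "species label")

  # perfectly interleaved two-species caterpillar: every leaf its own
  # cluster (brute-force expectation: no internal node is pure)
  cat_tree <- ape::read.tree(
    text = "(((((a1:1,b1:1):1,a2:1):1,b2:1):1,a3:1):1,b3:1);")
  sp <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  inter <- species_clusters(cat_tree, sp)
  expect_equal(inter$n_clusters, 6L)
})

test_that("the synthetic haplotype tree separates the six species", {
  cohort <- fixture_cohort()
  groups <- collapse_haplotypes(
    haplotype_sequences(cohort$variants, cohort$metadata,
                        snp_panel(fixture_profiles())))
  d <- hap_distance_matrix(groups)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  tree <- nj_tree(d)
  cl <- species_clusters(tree, setNames(groups$species, groups$haplotype_id))
  expect_equal(cl$n_clusters, 6L)
  # the partition covers every leaf exactly once and is species-pure
  expect_equal(sort(cl$partition$leaf), sort(groups$haplotype_id))
  purity <- dplyr::count(cl$partition, .data$cluster, .data$species)
  expect_equal(nrow(purity), 6L)
  expect_s3_class(tidy(cl), "tbl_df")
  expect_equal(glance(cl)$n_species, 6L)
})

test_that("newick and PHYLIP-distance writers round-trip", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  back <- read_newick(nwk)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))

  phy <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(d, phy)
  expect_equal(readLines(phy)[1], "3")
})
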