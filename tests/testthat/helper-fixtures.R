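# Shared fixtures: the synthetic study is deterministic per seed, so one
# build serves the whole suite.
fixture_env <- new.env(parent = emptyenv())

fixture_reference <- function(seed = 1L) {
  key <- paste0("ref", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- build_reference(seed)
  }
  fixture_env[[key]]
}

fixture_profiles <- function(seed = 1L) {
  key <- paste0("prof", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- species_profiles(fixture_reference(seed))
  }
  fixture_env[[key]]
}

fixture_cohort <- function(seed = 1L) {
  key <- paste0("cohort", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_cohort(fixture_profiles(seed))
  }
  fixture_env[[key]]
}

fixture_templates <- function(seed = 1L) {
  key <- paste0("tpl", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- build_its_templates(fixture_reference(seed),
                                              fixture_profiles(seed))
  }
  fixture_env[[key]]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force oracle: every start position where a window matches the
# IUPAC motif (N = any base), by direct per-window comparison
brute_motif_starts <- function(seq, motif) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mot <- strsplit(motif, "", fixed = TRUE)[[1L]]
  k <- length(mot)
  n <- length(chars)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (s in seq_len(n - k + 1L)) {
    win <- chars[s:(s + k - 1L)]
    if (all(win == mot | mot == "N")) hits <- c(hits, s)
  }
  hits
}
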