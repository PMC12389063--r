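#' Ambiguity-aware p-distance between haplotype strings
#'
#' The distance is the fraction of columns whose IUPAC base sets are
#' disjoint: a heterozygous R against an A contributes 0 (the sets share
#' A), R against C contributes 1. Symmetric with zero diagonal; the
#' triangle inequality is not guaranteed for ambiguity sets.
#'
#' @param a,b Haplotype strings of equal length over A/C/G/T/R/Y/K/M/S/W.
#' @return A number in `[0, 1]`.
#' @export
ambiguity_distance <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    stop("haplotype strings must have equal positive length", call. = FALSE)
  }
  mean(bitwAnd(iupac_bits(a), iupac_bits(b)) == 0L)
}

# encode an ambiguity string as a vector of 4-bit base masks
iupac_bits <- function(s) {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L,
            R = 5L, Y = 10L, K = 12L, M = 3L, S = 6L, W = 9L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  v <- bits[chars]
  if (anyNA(v)) {
    stop("unsupported character in haplotype string", call. = FALSE)
  }
  unname(v)
}

#' Pairwise ambiguity-aware distance matrix
#'
#' @param seqs Named character vector of haplotype strings (names become
#'   matrix labels), or a [collapse_haplotypes()] result (labels are the
#'   haplotype ids).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
hap_distance_matrix <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$haplotype_id)
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  masks <- lapply(seqs, iupac_bits)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- mean(bitwAnd(masks[[i]], masks[[j]]) == 0L)
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard neighbor joining with deterministic tie-breaking: the pair
#' minimising the Q criterion is joined; among ties the pair with the
#' smallest distance wins (so identical haplotypes coalesce first), then
#' the first pair in row-major order. Negative branch lengths are clamped
#' to zero with the length transferred to the sibling branch. Additive
#' matrices are recovered exactly.
#'
#' @param d A symmetric distance matrix with at least 3 labelled taxa.
#' @return An object of class `phylo` (unrooted, basal trifurcation).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must be labelled", call. = FALSE)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(d)
  frags <- labels  # newick fragments per active node
  active <- d

  join_lengths <- function(dij, ri, rj, n) {
    li <- dij / 2 + (ri - rj) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- dij; li <- 0 }
    if (lj < 0) { li <- dij; lj <- 0 }
    c(li, lj)
  }

  while (nrow(active) > 3L) {
    n <- nrow(active)
    r <- rowSums(active)
    q <- (n - 2) * active - outer(r, r, `+`)
    diag(q) <- Inf
    # deterministic pair choice: min Q, then min distance, then row-major
    best <- NULL
    best_key <- c(Inf, Inf)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- c(q[i, j], active[i, j])
        if (key[1] < best_key[1] - 1e-12 ||
            (abs(key[1] - best_key[1]) <= 1e-12 &&
             key[2] < best_key[2] - 1e-12)) {
          best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    len <- join_lengths(active[i, j], r[i], r[j], n)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], len[1L],
                        frags[j], len[2L])
    keep <- setdiff(seq_len(n), c(i, j))
    new_d <- (active[i, keep] + active[j, keep] - active[i, j]) / 2
    new_d[new_d < 0] <- 0
    m <- active[keep, keep, drop = FALSE]
    active <- rbind(cbind(m, new_d), c(new_d, 0))
    frags <- c(frags[keep], new_frag)
    k <- nrow(active)
    rownames(active) <- colnames(active) <- c(rownames(m), sprintf("n%d", k))
    # move the merged node to the front so zero-distance cascades stay
    # attached to it under the row-major tie-break
    ord <- c(k, seq_len(k - 1L))
    active <- active[ord, ord, drop = FALSE]
    frags <- frags[ord]
  }

  # closed-form resolution of the final three nodes
  l1 <- max(0, (active[1, 2] + active[1, 3] - active[2, 3]) / 2)
  l2 <- max(0, (active[1, 2] + active[2, 3] - active[1, 3]) / 2)
  l3 <- max(0, (active[1, 3] + active[2, 3] - active[1, 2]) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frags[1L], l1, frags[2L], l2, frags[3L], l3)
  ape::read.tree(text = newick)
}

#' Count species-pure clusters on a tree
#'
#' Roots the tree at its midpoint, then assigns every leaf to its highest
#' ancestor whose descendant leaves all share one species. The clusters
#' partition the leaves; their count equals the number of species only
#' when each species is monophyletic.
#'
#' @param tree A `phylo` object.
#' @param species Named character vector mapping every leaf label to a
#'   species.
#' @return An object of class `nr_clusters`: a list with `n_clusters`,
#'   `partition` (tibble leaf / species / cluster) and the rooted tree.
#' @export
species_clusters <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(species))) {
    stop("every leaf needs a species label", call. = FALSE)
  }
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  nnode <- rooted$Nnode
  parent <- integer(ntip + nnode)
  parent[rooted$edge[, 2L]] <- rooted$edge[, 1L]

  # species sets per node via tip descendants
  desc <- phangorn::Descendants(rooted, seq_len(ntip + nnode), type = "tips")
  node_species <- lapply(desc, function(tips) {
    unique(unname(species[rooted$tip.label[tips]]))
  })
  pure <- lengths(node_species) == 1L

  cluster_of <- vapply(seq_len(ntip), function(leaf) {
    nd <- leaf
    while (parent[nd] != 0L && pure[parent[nd]]) nd <- parent[nd]
    nd
  }, integer(1))

  partition <- tibble(
    leaf = rooted$tip.label,
    species = unname(species[rooted$tip.label]),
    cluster = match(cluster_of, sort(unique(cluster_of)))
  )
  structure(list(n_clusters = length(unique(cluster_of)),
                 partition = partition, tree = rooted),
            class = "nr_clusters")
}

#' @export
print.nr_clusters <- function(x, ...) {
  cat("Species-pure clusters:", x$n_clusters, "over",
      nrow(x$partition), "leaves\n")
  print(dplyr::count(x$partition, .data$cluster, .data$species))
  invisible(x)
}

#' @rdname species_clusters
#' @param x An `nr_clusters` object.
#' @param ... Unused.
#' @method tidy nr_clusters
#' @export
tidy.nr_clusters <- function(x, ...) x$partition

#' @rdname species_clusters
#' @method glance nr_clusters
#' @export
glance.nr_clusters <- function(x, ...) {
  tibble(n_clusters = x$n_clusters,
         n_leaves = nrow(x$partition),
         n_species = length(unique(x$partition$species)))
}

#' Write / read trees in Newick format
#'
#' Thin wrappers around the ape readers/writers, kept so the pipeline's
#' file interfaces live in one namespace.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix in PHYLIP format
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(as.character(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
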