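#' Simple-matching dissimilarity among haploid genotypes
#'
#' For each pair of units, d = 1 - (number of matching allele calls) / L,
#' where L counts the loci at which both units have a call (pairwise
#' deletion of missing data; ploidy 1, so a locus matches or it does not).
#'
#' @param gm a haploid `genotype_matrix` with at least 2 units.
#' @param allow_na return `NA` for pairs with no jointly scored locus
#'   instead of raising an error.
#' @return a `dissimilarity` list: `d` (symmetric unit x unit matrix in
#'   `[0, 1]`, zero diagonal) and `loci_used` (pairwise counts of jointly
#'   non-missing loci).
#' @export
simple_matching <- function(gm, allow_na = FALSE) {
  stopifnot(ploidy(gm) == 1, nrow(gm) >= 2)
  calls <- unclass(gm)
  n <- nrow(calls)
  scored <- !is.na(calls)
  shared <- scored %*% t(scored)                 # L per pair
  match_ct <- matrix(0, n, n)
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j]
    eq <- outer(v, v, "==")
    eq[is.na(eq)] <- FALSE
    match_ct <- match_ct + eq
  }
  if (any(shared[upper.tri(shared)] == 0) && !allow_na)
    stop("some unit pairs share no scored locus; ",
         "set allow_na = TRUE to return NA distances")
  d <- 1 - match_ct / shared
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- dimnames(shared) <- list(rownames(calls), rownames(calls))
  structure(list(d = d, loci_used = shared), class = "dissimilarity")
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classic Saitou-Nei neighbor joining (via \pkg{ape}). The `"weighted"`
#' variant requested by distance-variance-weighted joining is not
#' implemented and falls back to classic agglomeration with a warning;
#' for the short, noisy distances of gamete panels the two give very
#' similar topologies. Negative branch lengths are clamped to zero with
#' the deficit transferred to the adjacent branch so leaf-to-leaf path
#' lengths are preserved as far as possible.
#'
#' @param dm a `dissimilarity` (or a plain symmetric matrix / `dist`).
#' @param variant `"classic"` (default) or `"weighted"`.
#' @return an unrooted `phylo` tree (ape) over the unit ids.
#' @export
nj_tree <- function(dm, variant = c("classic", "weighted")) {
  variant <- match.arg(variant)
  if (variant == "weighted") {
    warning("weighted neighbor joining not implemented; ",
            "using classic Saitou-Nei agglomeration")
  }
  d <- if (inherits(dm, "dissimilarity")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 units")
  if (anyNA(d)) stop("dissimilarity matrix contains NA distances")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

# Zero out negative branch lengths, transferring the (negative) amount to
# the branches below the same node so paths through the node keep their
# total length; residual negatives on terminal branches are clamped.
clamp_negative_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_along(tree$edge.length)) {
    len <- tree$edge.length[e]
    if (len >= 0) next
    tree$edge.length[e] <- 0
    down <- which(tree$edge[, 1] == tree$edge[e, 2])
    if (length(down))
      tree$edge.length[down] <- tree$edge.length[down] + len
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Joint neighbor-joining tree over two gamete populations
#'
#' Combines two haploid populations genotyped on the same marker panel,
#' computes simple-matching dissimilarities over the pooled units, builds
#' the NJ tree, and summarises population exclusivity: the maximal clades
#' (on an arbitrary rooting of the unrooted tree) whose tips all come from
#' one population. Population-exclusive clusters are the signature of
#' gamete classes present in the pollen pool but never recovered among
#' progeny-transmitted gametes.
#'
#' @param gm_a,gm_b haploid `genotype_matrix` objects on the same loci.
#' @param labels length-2 character: population labels.
#' @param min_clade minimum tip count for a clade to enter the exclusivity
#'   summary (default 3).
#' @param variant NJ variant, see [nj_tree()].
#' @return list: `tree` (`phylo`), `leaf_populations` (data.frame `unit`,
#'   `population`), `exclusive_clades` (data.frame `population`, `size`),
#'   `n_exclusive`.
#' @export
population_tree_report <- function(gm_a, gm_b, labels = c("A", "B"),
                                   min_clade = 3,
                                   variant = c("classic", "weighted")) {
  if (!identical(colnames(gm_a), colnames(gm_b)))
    stop("the two populations are genotyped on different marker panels")
  ids_a <- paste0(labels[1], ".", rownames(gm_a))
  ids_b <- paste0(labels[2], ".", rownames(gm_b))
  pooled <- rbind(unclass(gm_a), unclass(gm_b))
  rownames(pooled) <- c(ids_a, ids_b)
  gm <- genotype_matrix(pooled, ploidy = 1)
  tree <- nj_tree(simple_matching(gm), variant = variant)
  pop <- stats::setNames(rep(labels, c(nrow(gm_a), nrow(gm_b))),
                         c(ids_a, ids_b))
  excl <- exclusive_clades(tree, pop, min_clade)
  list(tree = tree,
       leaf_populations = data.frame(unit = names(pop), population = pop,
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
       exclusive_clades = excl,
       n_exclusive = nrow(excl))
}

# Maximal single-population clades of size >= min_clade, on the tree's
# internal rooting.
exclusive_clades <- function(tree, pop, min_clade) {
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tip_pop <- pop[tree$tip.label]
  node_info <- lapply(nodes, function(nd) {
    tips <- tips_under(tree, nd)
    pops <- unique(tip_pop[tips])
    list(node = nd, n = length(tips),
         pure = length(pops) == 1L, pop = pops[1])
  })
  pure_nodes <- vapply(node_info, function(x) x$pure, TRUE)
  names(pure_nodes) <- nodes
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- list()
  for (x in node_info) {
    if (!x$pure || x$n < min_clade) next
    p <- parent[x$node]
    parent_pure <- p != 0 && as.character(p) %in% names(pure_nodes) &&
      pure_nodes[[as.character(p)]]
    if (!parent_pure)
      out[[length(out) + 1L]] <- data.frame(population = x$pop, size = x$n,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(population = character(0), size = integer(0))
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Write a tree in Newick format
#' @param tree a `phylo` tree.
#' @param path output path.
#' @param digits branch-length precision (default 6).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  tree$edge.length <- round(tree$edge.length, digits)
  ape::write.tree(tree, file = path)
  invisible(path)
}
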