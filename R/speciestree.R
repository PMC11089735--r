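## Exhaustive coalescent species-tree estimation for small focal sets: score
## every candidate rooted topology by the number of rooted triplets it shares
## with the input gene trees and return the argmax.  Triplet agreement is the
## coalescent-consistent criterion for rooted data: under the multispecies
## coalescent without gene flow the most frequent rooted triplet matches the
## species tree, so the estimator is statistically consistent.

## rooted triplet resolution of {a, b, c} in a rooted tree: the pair with the
## most recent (deepest) MRCA; returns the pair as "x|y" with x < y, or
## "*" if unresolved (all three MRCAs coincide)
.triplet_resolution <- function(depth, mrca_mat, a, b, c) {
  dab <- depth[mrca_mat[a, b]]
  dac <- depth[mrca_mat[a, c]]
  dbc <- depth[mrca_mat[b, c]]
  mx <- max(dab, dac, dbc)
  n_at <- sum(c(dab, dac, dbc) == mx)
  if (n_at != 1L) return("*")
  if (dab == mx) return("ab")
  if (dac == mx) return("ac")
  "bc"
}

## per-tree triplet resolutions for all ingroup triples; trees must contain
## the full focal set and be rooted by the outgroup
.tree_triplets <- function(tree, taxa) {
  og <- outgroup_of(taxa)
  ing <- setdiff(as.character(taxa), og)
  tr <- prune_taxa(tree, as.character(taxa))
  tr <- reroot(tr, og)
  if (!ape::is.rooted(tr)) stop("gene tree could not be rooted on outgroup")
  ## topology-only candidates: unit branch lengths give topological depth
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  depth <- ape::node.depth.edgelength(tr)
  mm <- ape::mrca(tr)
  tipidx <- match(ing, tr$tip.label)
  names(tipidx) <- ing
  combs <- utils::combn(sort(ing), 3L)
  res <- character(ncol(combs))
  for (k in seq_len(ncol(combs))) {
    abc <- combs[, k]
    res[k] <- .triplet_resolution(depth, mm, tipidx[abc[1L]],
                                  tipidx[abc[2L]], tipidx[abc[3L]])
  }
  names(res) <- apply(combs, 2L, paste, collapse = "|")
  res
}

#' Triplet agreement score of a candidate topology
#'
#' For every ingroup leaf triple and every gene tree, the score gains 1 when
#' the gene tree's rooted triplet resolution matches the candidate's.
#'
#' @param candidate A candidate topology: canonical string, newick string or
#'   `phylo`.
#' @param gene_trees List of `phylo` gene trees containing the focal taxa.
#' @param taxa A [taxon_set()].
#' @return A list (`TripletScore`): `matched` (total matches), `possible`
#'   (trees x triples), `normalised`.
#' @export
triplet_score <- function(candidate, gene_trees, taxa) {
  cand_res <- .candidate_triplets(candidate, taxa)
  gt_tab <- .triplet_table(gene_trees, taxa)
  matched <- .score_from_table(cand_res, gt_tab)
  possible <- length(gene_trees) * length(cand_res)
  list(matched = matched, possible = possible,
       normalised = matched / possible)
}

.candidate_triplets <- function(candidate, taxa) {
  tr <- if (inherits(candidate, "phylo")) candidate
    else parse_newick(if (endsWith(trimws(candidate), ";")) candidate
                      else paste0(candidate, ";"))
  .tree_triplets(tr, taxa)
}

## tabulate gene-tree triplet resolutions once: matrix [triple, resolution]
.triplet_table <- function(gene_trees, taxa) {
  all_res <- lapply(gene_trees, .tree_triplets, taxa = taxa)
  triples <- names(all_res[[1L]])
  keys <- c("ab", "ac", "bc", "*")
  tab <- matrix(0L, length(triples), length(keys),
                dimnames = list(triples, keys))
  for (res in all_res)
    for (t in triples) tab[t, res[[t]]] <- tab[t, res[[t]]] + 1L
  tab
}

.score_from_table <- function(cand_res, gt_tab) {
  s <- 0L
  for (t in rownames(gt_tab))
    if (cand_res[[t]] != "*") s <- s + gt_tab[t, cand_res[[t]]]
  s
}

#' Exhaustive triplet-score species tree
#'
#' Enumerates every rooted topology on the focal taxon set (honouring
#' constraint clades), scores each by total rooted-triplet agreement with the
#' gene trees, and returns the argmax; ties are broken by lexicographic
#' canonical string and reported.
#'
#' @param gene_trees Non-empty list of `phylo` gene trees.
#' @param taxa A [taxon_set()] with <= 8 ingroup taxa (enumeration must stay
#'   tractable).
#' @param constraints Constraint clades passed to
#'   [enumerate_rooted_topologies()].
#' @return A list: `best` (canonical string of the winning topology),
#'   `scores` (data.frame: canonical_string, matched, normalised, sorted by
#'   decreasing score), `tie` (logical).
#' @export
exhaustive_species_tree <- function(gene_trees, taxa, constraints = list()) {
  if (!length(gene_trees)) stop("empty gene tree list")
  enum <- enumerate_rooted_topologies(taxa, constraints)
  gt_tab <- .triplet_table(gene_trees, taxa)
  n_triples <- nrow(gt_tab)
  matched <- vapply(enum$canonical_string, function(cs)
    .score_from_table(.candidate_triplets(cs, taxa), gt_tab), integer(1))
  scores <- data.frame(canonical_string = enum$canonical_string,
                       matched = as.integer(matched),
                       normalised = matched / (length(gene_trees) * n_triples),
                       stringsAsFactors = FALSE)
  scores <- scores[order(-scores$matched, scores$canonical_string), ]
  rownames(scores) <- NULL
  tie <- sum(scores$matched == scores$matched[1L]) > 1L
  if (tie)
    message("triplet-score tie broken lexicographically among ",
            sum(scores$matched == scores$matched[1L]), " topologies")
  list(best = scores$canonical_string[1L], scores = scores, tie = tie)
}
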