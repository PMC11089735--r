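#' Parse a newick string into a phylo tree
#'
#' Thin validating front end over [ape::read.tree()]. The input must be a
#' single well-formed newick statement terminated by `";"`; parse failures
#' report the offending character position rather than silently returning a
#' malformed tree.
#'
#' @param text A single newick string ending in `";"`.
#' @return An object of class `phylo` (see \pkg{ape}). Branch lengths are kept
#'   if present; internal node labels are preserved but ignored by all
#'   downstream computations.
#' @examples
#' tr <- parse_newick("(A:1,(B:2,C:3):4);")
#' patristic_distance(tr, "B", "C")  # 5
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("empty input: expected a single newick string")
  s <- trimws(text)
  if (!endsWith(s, ";"))
    stop("newick statement must end in ';' (character position ", nchar(s), ")")
  ## balance check with position reporting
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses at character position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth,
         " unclosed '(' at character position ", nchar(s))
  tr <- tryCatch(ape::read.tree(text = s),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error: unreadable statement")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Serialise a tree to newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Construct a taxon set with a designated outgroup
#'
#' @param labels Character vector of leaf labels (no duplicates).
#' @param outgroup One element of `labels` used to root trees.
#' @return A `taxon_set` object: the label vector with an `outgroup` attribute.
#' @export
taxon_set <- function(labels, outgroup) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in taxon set")
  if (length(outgroup) != 1L || !outgroup %in% labels)
    stop("outgroup must be one of the taxon labels")
  structure(labels, outgroup = outgroup, class = "taxon_set")
}

#' @export
print.taxon_set <- function(x, ...) {
  cat("taxon_set of", length(x), "taxa; outgroup:", attr(x, "outgroup"), "\n")
  cat(" ", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

outgroup_of <- function(taxa) attr(taxa, "outgroup")

#' Prune a tree down to a set of kept taxa
#'
#' Equivalent of `nw_prune` restricted to a keep-list: removes all other
#' leaves and suppresses the resulting degree-2 internal nodes, summing their
#' branch lengths, so pairwise patristic distances among kept leaves are
#' conserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector (or `taxon_set`) of leaf labels to retain.
#' @return A `phylo` object with exactly the kept leaves. The input tree is
#'   not modified.
#' @export
prune_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- as.character(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not present in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Reroot a tree on an outgroup leaf
#'
#' Places the root on the edge subtending the outgroup so the root bipartition
#' is outgroup | everything-else. The unrooted topology and all pairwise
#' patristic distances are unchanged; rerooting twice on the same leaf is
#' idempotent.
#'
#' @param tree A `phylo` object.
#' @param outgroup A leaf label of `tree`.
#' @return A rooted `phylo` object.
#' @export
reroot <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (length(outgroup) != 1L || !outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ## already rooted with the outgroup alone on one side of the root?
  if (ape::is.rooted(tree)) {
    og <- which(tree$tip.label == outgroup)
    root_node <- ape::Ntip(tree) + 1L
    kids <- tree$edge[tree$edge[, 1L] == root_node, 2L]
    if (og %in% kids && length(kids) == 2L) return(tree)
  }
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ## ape can leave the two root child edges with the full outgroup stem on one
  ## side; topology and distances are what downstream consumers rely on.
  out
}

## internal: node numbers for a label or node id
.node_id <- function(tree, x) {
  if (is.character(x)) {
    i <- match(x, tree$tip.label)
    if (is.na(i)) stop("leaf '", x, "' not found in tree")
    return(i)
  }
  x <- as.integer(x)
  if (x < 1L || x > ape::Ntip(tree) + tree$Nnode)
    stop("node id ", x, " out of range")
  x
}

## internal: ancestors of a node up to the root (inclusive), plus edge lengths
.path_to_root <- function(tree, node) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- rep(NA_real_, length(parent))
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2L]] <- tree$edge.length
  nodes <- node
  lens <- numeric(0)
  cur <- node
  while (parent[cur] != 0L) {
    lens <- c(lens, elen[cur])
    cur <- parent[cur]
    nodes <- c(nodes, cur)
  }
  list(nodes = nodes, lens = lens)
}

#' Patristic distance between two nodes
#'
#' Sum of branch lengths on the unique path between two leaves (or internal
#' nodes, given by their `phylo` node numbers). Symmetric, and rooting
#' invariant.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param a,b Leaf labels or node numbers.
#' @return Non-negative numeric path length.
#' @export
patristic_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  na <- .node_id(tree, a); nb <- .node_id(tree, b)
  if (na == nb) return(0)
  pa <- .path_to_root(tree, na)
  pb <- .path_to_root(tree, nb)
  ## most recent common ancestor = first shared node on the two root paths
  shared <- intersect(pa$nodes, pb$nodes)
  if (!length(shared)) stop("nodes share no common ancestor (disconnected?)")
  m <- shared[1L]
  ia <- match(m, pa$nodes); ib <- match(m, pb$nodes)
  lens <- c(if (ia > 1L) pa$lens[seq_len(ia - 1L)],
            if (ib > 1L) pb$lens[seq_len(ib - 1L)])
  if (anyNA(lens)) {
    bad_a <- if (ia > 1L && anyNA(pa$lens[seq_len(ia - 1L)]))
      pa$nodes[which(is.na(pa$lens[seq_len(ia - 1L)]))[1L]] else NULL
    bad <- if (!is.null(bad_a)) bad_a else
      pb$nodes[which(is.na(pb$lens[seq_len(ib - 1L)]))[1L]]
    stop("missing branch length on path: edge above node ", bad)
  }
  sum(lens)
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree A rooted `phylo` object.
#' @param labels Character vector of leaf labels (a single label returns the
#'   leaf itself).
#' @return Node number of the MRCA.
#' @export
mrca_node <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  labels <- as.character(labels)
  if (!length(labels)) stop("empty leaf set")
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stop("taxa not present in tree: ", paste(missing, collapse = ", "))
  if (length(labels) == 1L) return(match(labels, tree$tip.label))
  ape::getMRCA(tree, labels)
}

#' Path length between nested MRCA nodes
#'
#' Distance between `MRCA(setA)` and `MRCA(setA U setB)` — e.g. the depth of a
#' focal clade's ancestor below the node where it joins a second clade. Zero
#' when the two MRCAs coincide.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param setA,setB Non-empty character vectors of leaf labels.
#' @return Non-negative numeric path length.
#' @export
mrca_path_length <- function(tree, setA, setB) {
  if (!length(setA) || !length(setB)) stop("empty leaf set")
  m1 <- mrca_node(tree, setA)
  m2 <- mrca_node(tree, unique(c(as.character(setA), as.character(setB))))
  if (m1 == m2) return(0)
  patristic_distance(tree, m1, m2)
}

#' Read a list of window trees with an optional coordinate index
#'
#' Trees are stored one newick statement per line; the side-car index is a
#' tab-separated file with columns chrom, start, end (BED convention, 0-based
#' half-open), one row per tree line.
#'
#' @param tree_file Path to a newick file (one tree per line).
#' @param index_file Optional path to the BED-like index.
#' @return A list with `trees` (a `multiPhylo` list) and `index` (a data.frame
#'   or `NULL`).
#' @export
read_window_trees <- function(tree_file, index_file = NULL) {
  lines <- readLines(tree_file)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  class(trees) <- "multiPhylo"
  index <- NULL
  if (!is.null(index_file)) {
    index <- utils::read.table(index_file, sep = "\t", header = FALSE,
                               col.names = c("chrom", "start", "end"),
                               stringsAsFactors = FALSE)
    if (nrow(index) != length(trees))
      stop("index has ", nrow(index), " rows but tree file has ",
           length(trees), " trees")
  }
  list(trees = trees, index = index)
}

#' Write a list of window trees with an optional coordinate index
#'
#' @param trees A list of `phylo` objects (or `multiPhylo`).
#' @param tree_file Output newick path (one tree per line).
#' @param index Optional data.frame with chrom, start, end.
#' @param index_file Output path for the index (required if `index` given).
#' @return Invisibly, `tree_file`.
#' @export
write_window_trees <- function(trees, tree_file, index = NULL,
                               index_file = NULL) {
  txt <- vapply(trees, write_newick, character(1))
  writeLines(txt, tree_file)
  if (!is.null(index)) {
    if (is.null(index_file)) stop("index_file required when index is given")
    utils::write.table(index[, c("chrom", "start", "end")], index_file,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(tree_file)
}
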