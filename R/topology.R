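## Canonical rooted-topology identifiers and the constrained topology catalogue.
##
## A topology class is the rooted leaf-labelled shape of a window tree after
## pruning to the focal taxon set and rooting on the outgroup, with branch
## lengths stripped.  The canonical string sorts the children of every node by
## the lexicographically smallest leaf label in their subtree, so it is
## invariant to input leaf order and to branch lengths.

## recursive canonical string for a rooted phylo; returns NA if any node
## (other than handled cases) is multifurcating and resolve_only is TRUE
.canon_recurse <- function(children, labels, node, ntip) {
  if (node <= ntip) return(list(str = labels[node], min = labels[node]))
  kids <- children[[node]]
  parts <- lapply(kids, .canon_recurse, children = children, labels = labels,
                  ntip = ntip)
  mins <- vapply(parts, `[[`, character(1), "min")
  o <- order(mins, method = "radix")
  list(str = paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                               collapse = ","), ")"),
       min = mins[o[1L]])
}

.children_list <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  children <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]],
                                      tree$edge[i, 2L])
  children
}

#' Canonical string of a rooted tree's topology
#'
#' @param tree A rooted `phylo` object.
#' @return A character string; two rooted trees have equal strings iff they
#'   share the same rooted leaf-labelled topology.
#' @export
canonical_string <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  .canon_recurse(.children_list(tree), tree$tip.label, ntip + 1L, ntip)$str
}

#' Classify a window tree into a topology class
#'
#' Prunes the tree to the focal taxon set, reroots on the outgroup, strips
#' branch lengths and returns the canonical rooted-topology string. Trees that
#' are not fully resolved (multifurcating) on the focal set after pruning are
#' assigned the flag class `"unresolved"` rather than raising an error.
#'
#' @param tree A `phylo` object containing (at least) the focal taxa.
#' @param taxa A [taxon_set()] with designated outgroup.
#' @return A single character string: the canonical topology, or
#'   `"unresolved"`.
#' @examples
#' taxa <- taxon_set(c("O","A","B","C"), outgroup = "O")
#' canonical_id(parse_newick("((A:1,B:1):1,(C:1,O:3):1);"), taxa)
#' @export
canonical_id <- function(tree, taxa) {
  stopifnot(inherits(taxa, "taxon_set"))
  tr <- prune_taxa(tree, taxa)
  tr <- reroot(tr, outgroup_of(taxa))
  ## binary check on the rerooted focal tree (root with 2 children required)
  if (!ape::is.binary(tr)) return("unresolved")
  canonical_string(tr)
}

## ---------------------------------------------------------------------------
## enumeration of rooted binary topologies with clade constraints

## all rooted binary shapes over a set of opaque units, each unit a
## list(str, min); recursion on the (unique) root bipartition: every rooted
## binary tree on S splits S into an unordered pair {A, B}, so enumerating
## unordered bipartitions x shapes(A) x shapes(B) yields each shape once.
.enum_shapes <- function(units) {
  n <- length(units)
  if (n == 1L) return(units)
  out <- list()
  ## unordered bipartitions: fix unit 1 on the A side
  for (mask in 0:(2^(n - 1L) - 1L)) {
    sideA <- c(1L, which(bitwAnd(mask, 2L^(seq_len(n - 1L) - 1L)) > 0L) + 1L)
    sideB <- setdiff(seq_len(n), sideA)
    if (!length(sideB)) next
    for (a in .enum_shapes(units[sideA])) for (b in .enum_shapes(units[sideB]))
      out[[length(out) + 1L]] <- .join_shapes(a, b)
  }
  out
}

.join_shapes <- function(a, b) {
  if (a$min <= b$min)
    list(str = paste0("(", a$str, ",", b$str, ")"), min = a$min)
  else
    list(str = paste0("(", b$str, ",", a$str, ")"), min = b$min)
}

## enumerate all canonical subtree strings over a member set honouring nested
## constraints; returns list of (str, min)
.enum_group <- function(members, constraints) {
  ## constraints fully inside members, maximal ones become collapsed units
  inside <- Filter(function(cl) all(cl %in% members) &&
                     length(cl) < length(members), constraints)
  ## maximal = not contained in another inside-constraint
  is_max <- vapply(inside, function(cl) {
    !any(vapply(inside, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1)))
  }, logical(1))
  maximal <- inside[is_max]
  in_clade <- unique(unlist(maximal))
  free <- setdiff(members, in_clade)
  ## each maximal clade expands to its own enumeration (recursively)
  unit_opts <- c(lapply(free, function(x) list(list(str = x, min = x))),
                 lapply(maximal, function(cl) .enum_group(cl, constraints)))
  k <- length(unit_opts)
  if (k == 1L) return(unit_opts[[1L]])
  ## enumerate shapes over unit placeholders, then expand every combination of
  ## the constrained clades' internal resolutions
  out <- list()
  combos <- expand.grid(lapply(unit_opts, seq_along))
  for (r in seq_len(nrow(combos))) {
    picks <- lapply(seq_len(k), function(j)
      unit_opts[[j]][[combos[r, j]]])
    out <- c(out, .enum_shapes(picks))
  }
  out
}

#' Enumerate rooted binary topologies on a taxon set
#'
#' Generates every distinct rooted binary topology on the focal taxa in which
#' the outgroup is the root's immediate sister to all ingroup taxa and every
#' constraint clade appears as a clade. For n unconstrained ingroup lineages
#' the count is (2n-3)!!.
#'
#' @param taxa A [taxon_set()]; the outgroup is fixed at the root.
#' @param constraints A list of character vectors, each a required clade
#'   (subset of the ingroup). Constraints must be compatible (pairwise nested
#'   or disjoint).
#' @return A data.frame with columns `class_index` and `canonical_string`, one
#'   row per topology, sorted lexicographically.
#' @examples
#' taxa <- taxon_set(c("O","A","B","C","D"), outgroup = "O")
#' nrow(enumerate_rooted_topologies(taxa))  # 15
#' @export
enumerate_rooted_topologies <- function(taxa, constraints = list()) {
  stopifnot(inherits(taxa, "taxon_set"))
  og <- outgroup_of(taxa)
  ingroup <- setdiff(as.character(taxa), og)
  if (length(ingroup) < 2L) stop("need at least 2 ingroup taxa")
  constraints <- lapply(constraints, as.character)
  for (cl in constraints) {
    if (!all(cl %in% ingroup))
      stop("constraint clade contains non-ingroup taxa: ",
           paste(setdiff(cl, ingroup), collapse = ", "))
    if (length(cl) < 2L) stop("constraint clades need >= 2 taxa")
  }
  ## compatibility: pairwise nested or disjoint
  if (length(constraints) > 1L) {
    for (i in seq_along(constraints)) for (j in seq_along(constraints)) {
      if (i >= j) next
      a <- constraints[[i]]; b <- constraints[[j]]
      ov <- intersect(a, b)
      if (length(ov) && !(all(a %in% b) || all(b %in% a)))
        stop("incompatible constraints: {", paste(a, collapse = ","),
             "} and {", paste(b, collapse = ","), "}")
    }
  }
  subs <- .enum_group(sort(ingroup), constraints)
  strs <- vapply(subs, function(s) {
    if (s$min <= og) paste0("(", s$str, ",", og, ")")
    else paste0("(", og, ",", s$str, ")")
  }, character(1))
  strs <- sort(unique(strs), method = "radix")
  data.frame(class_index = seq_along(strs), canonical_string = strs,
             stringsAsFactors = FALSE)
}

#' Tabulate topology class frequencies
#'
#' @param classes Character vector of canonical strings (from
#'   [canonical_id()]), possibly including `"unresolved"`.
#' @param enumeration Optional enumeration data.frame from
#'   [enumerate_rooted_topologies()]; classes absent from it are pooled into
#'   `"other"` rows retained individually with `in_catalogue = FALSE`.
#' @param aliases Optional named character vector mapping alias -> canonical
#'   string (see [duck_aliases()]).
#' @param label Optional window-size (or other stratum) label stored on the
#'   result.
#' @return A data.frame with columns `canonical_string`, `alias`, `count`,
#'   `frequency`, `in_catalogue`, sorted by decreasing count; frequencies sum
#'   to 1 over observed classes.
#' @export
tabulate_topologies <- function(classes, enumeration = NULL, aliases = NULL,
                                label = NULL) {
  if (!length(classes)) stop("empty class list")
  tab <- sort(table(classes), decreasing = TRUE)
  out <- data.frame(canonical_string = names(tab),
                    alias = NA_character_,
                    count = as.integer(tab),
                    frequency = as.numeric(tab) / length(classes),
                    stringsAsFactors = FALSE)
  out$in_catalogue <- if (is.null(enumeration)) TRUE else
    out$canonical_string %in% enumeration$canonical_string
  if (!is.null(aliases)) {
    m <- match(out$canonical_string, aliases)
    out$alias[!is.na(m)] <- names(aliases)[m[!is.na(m)]]
  }
  attr(out, "total") <- length(classes)
  attr(out, "label") <- label
  out
}

#' Default six-taxon duck-system topology aliases
#'
#' Binds the aliases of the three primary topology classes observed at the
#' focal node of the six-taxon system (outgroup Muscovy; constrained steamer
#' duck pair; Baikal teal; Northern shoveler; Pekin) to canonical strings:
#' `t1`/`tree-1` groups (Baikal, Shoveler) with Pekin (the species topology);
#' `t2`/`tree-2` groups the steamer pair with Pekin (the introgression
#' topology); `t3`/`tree-3` groups the steamer pair with (Baikal, Shoveler).
#' The strings are computed from explicit newick templates at call time, never
#' hard-coded.
#'
#' @param taxa Optional [taxon_set()] with the six default labels (override to
#'   rename lineages, same order: outgroup, steamer1, steamer2, baikal,
#'   shoveler, pekin).
#' @return Named character vector alias -> canonical string, with names
#'   `t1`, `t2`, `t3`, `tree-1`, `tree-2`, `tree-3`.
#' @export
duck_aliases <- function(taxa = duck_taxa()) {
  lb <- as.character(taxa)
  og <- outgroup_of(taxa)
  ing <- setdiff(lb, og)
  s1 <- ing[1L]; s2 <- ing[2L]; ba <- ing[3L]; sh <- ing[4L]; pe <- ing[5L]
  tpl <- c(
    t1 = sprintf("(%s,((%s,%s),((%s,%s),%s)));", og, s1, s2, ba, sh, pe),
    t2 = sprintf("(%s,((%s,%s),((%s,%s),%s)));", og, ba, sh, s1, s2, pe),
    t3 = sprintf("(%s,(((%s,%s),(%s,%s)),%s));", og, s1, s2, ba, sh, pe))
  canon <- vapply(tpl, function(x)
    canonical_id(parse_newick(x), taxa), character(1))
  c(canon, setNames(canon, c("tree-1", "tree-2", "tree-3")))
}

#' Default six-taxon duck-system taxon set
#'
#' Outgroup plus a two-taxon donor (steamer) clade, two single lineages and
#' the recipient lineage — the pruned system the window-tree discordance
#' analysis operates on.
#'
#' @return A [taxon_set()].
#' @export
duck_taxa <- function() {
  taxon_set(c("Muscovy", "Steamer1", "Steamer2", "Baikal", "Shoveler",
              "Pekin"), outgroup = "Muscovy")
}

#' Read or write an alias binding file
#'
#' Tab-separated, two columns: alias, canonical_string.
#'
#' @param file Path.
#' @return Named character vector alias -> canonical string.
#' @export
read_aliases <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  setNames(df$canonical_string, df$alias)
}

#' @rdname read_aliases
#' @param aliases Named character vector to write.
#' @export
write_aliases <- function(aliases, file) {
  utils::write.table(data.frame(alias = names(aliases),
                                canonical_string = unname(aliases)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
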