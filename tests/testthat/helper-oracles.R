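## Independent brute-force oracles and fixture builders used across tests.
## Every oracle deliberately takes a different route from the implementation
## it checks.

## patristic distance by shortest path over the undirected node graph
oracle_graph_distance <- function(tree, a, b) {
  n <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]; w <- tree$edge.length[i]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  src <- if (is.character(a)) match(a, tree$tip.label) else a
  dst <- if (is.character(b)) match(b, tree$tip.label) else b
  dist <- rep(Inf, n); dist[src] <- 0
  todo <- rep(TRUE, n)
  while (any(todo)) {
    u <- which(todo)[which.min(dist[todo])]
    todo[u] <- FALSE
    if (is.infinite(dist[u])) break
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]
      if (dist[u] + adj[[u]][k, 2] < dist[v])
        dist[v] <- dist[u] + adj[[u]][k, 2]
    }
  }
  dist[dst]
}

## runs by explicit linear scan (no rle)
oracle_runs <- function(classes) {
  if (!length(classes)) return(data.frame(class = character(), length = integer()))
  out <- list()
  cur <- classes[1]; len <- 1L
  for (i in seq_along(classes)[-1]) {
    if (classes[i] == cur) len <- len + 1L
    else {
      out[[length(out) + 1L]] <- data.frame(class = cur, length = len,
                                            stringsAsFactors = FALSE)
      cur <- classes[i]; len <- 1L
    }
  }
  out[[length(out) + 1L]] <- data.frame(class = cur, length = len,
                                        stringsAsFactors = FALSE)
  do.call(rbind, out)
}

## quadratic all-pairs half-open interval overlap
oracle_overlaps <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        min(a$end[i], b$end[j]) > max(a$start[i], b$start[j]))
      hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits)) return(matrix(integer(), 0, 2))
  do.call(rbind, hits)
}

## 4D-site mask via the standard genetic code: a codon prefix is fourfold
## degenerate iff all four third bases translate to one amino acid
oracle_4d_mask <- function(m, frame = 0L) {
  code <- Biostrings::GENETIC_CODE
  if (frame > 0) m <- m[, -seq_len(frame), drop = FALSE]
  ncod <- ncol(m) %/% 3L
  if (ncod == 0) return(logical(0))
  keep <- logical(ncod)
  for (k in seq_len(ncod)) {
    c1 <- m[, 3 * k - 2]; c2 <- m[, 3 * k - 1]
    if (any(!(c1 %in% c("A", "C", "G", "T"))) ||
        any(!(c2 %in% c("A", "C", "G", "T")))) next
    if (length(unique(c1)) != 1 || length(unique(c2)) != 1) next
    aas <- code[paste0(c1[1], c2[1], c("A", "C", "G", "T"))]
    keep[k] <- length(unique(aas)) == 1
  }
  keep
}

## per-column explicit ABBA/BABA classifier
oracle_patterns <- function(aln, quartet) {
  abba <- baba <- 0L
  for (j in seq_len(ncol(aln))) {
    col <- aln[quartet, j]
    if (any(!(col %in% c("A", "C", "G", "T")))) next
    if (length(unique(col)) != 2) next
    anc <- col[4]
    der <- setdiff(unique(col), anc)
    if (col[1] == anc && col[2] == der && col[3] == der) abba <- abba + 1L
    if (col[1] == der && col[2] == anc && col[3] == der) baba <- baba + 1L
  }
  c(abba = abba, baba = baba)
}

## rooted triplet of {a,b,c} by pruning to the triple plus outgroup and
## reading the canonical string
oracle_triplet <- function(tree, taxa, triple) {
  og <- attr(taxa, "outgroup")
  sub <- canonical_id(tree, taxon_set(c(triple, og), outgroup = og))
  pair_of <- function(x, y) paste0("(", min(x, y), ",", max(x, y), ")")
  s <- sort(triple)
  if (grepl(pair_of(s[1], s[2]), sub, fixed = TRUE)) return("ab")
  if (grepl(pair_of(s[1], s[3]), sub, fixed = TRUE)) return("ac")
  if (grepl(pair_of(s[2], s[3]), sub, fixed = TRUE)) return("bc")
  "*"
}

## build a window table realising an explicit run-length spec: each run is
## followed by a single filler window of an alternating off-class so runs
## stay maximal
build_class_sequence <- function(runs_df, fillers = c("fillA", "fillB")) {
  classes <- character(0)
  f <- 1L
  for (i in seq_len(nrow(runs_df))) {
    classes <- c(classes, rep(runs_df$class[i], runs_df$length[i]),
                 fillers[f])
    f <- 3L - f
  }
  n <- length(classes)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 10000L,
             end = seq_len(n) * 10000L, class = classes,
             stringsAsFactors = FALSE)
}

## random alignment matrix over given alphabet
random_aln <- function(ntaxa, ncol, alphabet = c("A", "C", "G", "T"),
                       taxa = paste0("t", seq_len(ntaxa))) {
  m <- matrix(sample(alphabet, ntaxa * ncol, replace = TRUE), ntaxa, ncol)
  rownames(m) <- taxa
  m
}

## serialise a tree to newick with uniformly shuffled child order
shuffle_newick <- function(tree) {
  nt <- ape::Ntip(tree)
  kids <- vector("list", nt + tree$Nnode)
  elen <- numeric(nt + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  rec <- function(node) {
    if (node <= nt) return(paste0(tree$tip.label[node], ":", elen[node]))
    ch <- sample(kids[[node]])
    inner <- paste(vapply(ch, rec, character(1)), collapse = ",")
    if (identical(node, nt + 1L)) paste0("(", inner, ");")
    else paste0("(", inner, "):", elen[node])
  }
  rec(nt + 1L)
}

## default pulse list used throughout
pulse0 <- function(gamma, time = 2)
  list(donor = c("Steamer1", "Steamer2"), recipient = "Pekin",
       time = time, gamma = gamma)
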