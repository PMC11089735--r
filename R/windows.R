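## Alignment windows: splitting, quality filters, 4D-site extraction and the
## internal neighbor-joining tree that closes the pipeline without external
## maximum-likelihood software.
##
## Alignments are plain character matrices (rows = taxa, columns = positions,
## entries in A/C/G/T/N/-); a window wraps one with BED half-open reference
## coordinates.

#' Construct an alignment window
#'
#' @param seqs Character matrix (rows = taxa, names required) or named
#'   character vector of equal-length strings over A/C/G/T/N/-.
#' @param chrom,start,end Reference coordinates (BED, 0-based half-open).
#' @return An `aln_window`: list with `chrom`, `start`, `end`, `seqs`
#'   (character matrix) and `informative` (count of columns with >= 2
#'   non-gap, non-N characters).
#' @export
aln_window <- function(seqs, chrom = "chr1", start = 0L,
                       end = start + ncol(m)) {
  m <- .as_aln_matrix(seqs)
  if (end - start <= 0) stop("end - start must be positive")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), seqs = m,
                 informative = .informative_count(m)),
            class = "aln_window")
}

#' @export
print.aln_window <- function(x, ...) {
  cat(sprintf("aln_window %s:%d-%d  %d taxa x %d columns  (%d informative)\n",
              x$chrom, x$start, x$end, nrow(x$seqs), ncol(x$seqs),
              x$informative))
  invisible(x)
}

.as_aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    if (length(unique(nchar(seqs))) != 1L)
      stop("sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment matrix must have taxon rownames")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("invalid alignment characters: ", paste(bad, collapse = " "))
  m
}

## informative column = >= 2 non-gap, non-N characters
.informative_count <- function(m) {
  sum(colSums(m != "-" & m != "N") >= 2L)
}

#' Split a reference-anchored alignment into fixed-size windows
#'
#' Tiles the reference interval with consecutive non-overlapping windows of
#' `size` bp; every window is returned, with those holding fewer than
#' `min_informative` informative columns flagged `retained = FALSE` (an
#' informative column has at least two non-gap, non-N characters). The
#' retained and dropped windows together tile the input exactly.
#'
#' @param seqs Alignment (matrix or named strings) on reference coordinates.
#' @param size Window size in bp.
#' @param min_informative Minimum informative columns to retain (default 30).
#' @param chrom Reference chromosome name.
#' @param offset Reference coordinate of the alignment's first column.
#' @return A list of `aln_window` objects, each with a `retained` element.
#' @export
split_windows <- function(seqs, size, min_informative = 30, chrom = "chr1",
                          offset = 0L) {
  stopifnot(size > 0)
  m <- .as_aln_matrix(seqs)
  L <- ncol(m)
  if (L == 0L) return(list())
  starts <- seq.int(0L, L - 1L, by = size)
  lapply(starts, function(s) {
    e <- min(L, s + size)
    w <- aln_window(m[, (s + 1L):e, drop = FALSE], chrom = chrom,
                    start = offset + s, end = offset + e)
    w$retained <- w$informative >= min_informative
    w
  })
}

#' Gap-ratio filter
#'
#' Fails a window iff its gap ratio — gap characters `-` over all characters
#' (taxa x columns) — strictly exceeds the threshold; a ratio exactly at the
#' threshold passes.
#'
#' @param w An `aln_window`.
#' @param threshold Maximum tolerated gap ratio (default 0.10).
#' @return A list (`FilterReport` entry): `pass`, `gap_ratio`, `threshold`.
#' @export
gap_filter <- function(w, threshold = 0.10) {
  stopifnot(inherits(w, "aln_window"))
  ratio <- sum(w$seqs == "-") / length(w$seqs)
  list(pass = !(ratio > threshold), gap_ratio = ratio, threshold = threshold)
}

#' Per-sequence base-composition chi-square test
#'
#' For each taxon, compares its A/C/G/T counts (over ungapped, non-N
#' positions) against expectations from the pooled base frequencies of the
#' whole alignment: `X2 = sum (o_b - e_b)^2 / e_b` with `e_b = n_taxon *
#' f_pooled(b)`, tested at 3 degrees of freedom. Expected counts are floored
#' at `1e-6 * n_taxon` to keep the statistic finite when a base is absent
#' from the pool. A window is conventionally discarded when any sequence
#' fails.
#'
#' @param w An `aln_window` with >= 2 taxa having >= 1 ungapped character.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame per taxon: `taxon`, `statistic`, `p`, `pass`; the
#'   window-level verdict (`all(pass)`) is attached as attribute
#'   `"window_pass"`.
#' @export
composition_test <- function(w, alpha = 0.05) {
  stopifnot(inherits(w, "aln_window"))
  m <- w$seqs
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(m, 1L, function(row)
    vapply(bases, function(b) sum(row == b), numeric(1))))
  ns <- rowSums(counts)
  if (sum(ns > 0) < 2L)
    stop("composition test needs >= 2 taxa with ungapped characters")
  pooled <- colSums(counts) / sum(counts)
  stat <- vapply(seq_len(nrow(counts)), function(i) {
    if (ns[i] == 0) return(0)
    e <- pmax(ns[i] * pooled, 1e-6 * ns[i])
    sum((counts[i, ] - e)^2 / e)
  }, numeric(1))
  p <- pchisq(stat, df = 3, lower.tail = FALSE)
  out <- data.frame(taxon = rownames(m), statistic = stat, p = p,
                    pass = p >= alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "window_pass") <- all(out$pass)
  out
}

## two-base prefixes of the eight fourfold-degenerate codon families
.fourfold_prefixes <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

#' Extract fourfold-degenerate third-codon-position columns
#'
#' Reads the alignment in codons (after trimming `frame` leading columns and
#' any incomplete trailing codon) and emits the third-position column of
#' every codon whose first two positions are ungapped, identical across all
#' taxa, and form one of the eight fourfold-degenerate prefixes (TC, CT, CC,
#' CG, AC, GT, GC, GG). Output columns are a concatenation; their coordinates
#' are no longer genomic.
#'
#' @param w An `aln_window` holding an in-frame CDS alignment.
#' @param frame Number of leading columns to skip (0, 1 or 2); `NULL` is an
#'   error — the caller must know the reading frame.
#' @return A character matrix of the emitted third positions (0 columns if
#'   none qualify), with attribute `"codon_index"` giving each emitted
#'   codon's 1-based index in the trimmed alignment.
#' @export
extract_4d_sites <- function(w, frame = 0L) {
  stopifnot(inherits(w, "aln_window"))
  if (is.null(frame)) stop("frame annotation is required")
  stopifnot(frame %in% 0:2)
  m <- w$seqs
  if (frame > 0) m <- m[, -seq_len(frame), drop = FALSE]
  ncod <- ncol(m) %/% 3L
  if (ncod == 0L) return(structure(m[, 0, drop = FALSE], codon_index = integer()))
  m <- m[, seq_len(3L * ncod), drop = FALSE]
  i1 <- seq.int(1L, by = 3L, length.out = ncod)
  keep <- logical(ncod)
  for (k in seq_len(ncod)) {
    c1 <- m[, i1[k]]; c2 <- m[, i1[k] + 1L]
    if (any(!(c1 %in% c("A", "C", "G", "T"))) ||
        any(!(c2 %in% c("A", "C", "G", "T")))) next
    if (length(unique(c1)) != 1L || length(unique(c2)) != 1L) next
    keep[k] <- paste0(c1[1L], c2[1L]) %in% .fourfold_prefixes
  }
  out <- m[, i1[keep] + 2L, drop = FALSE]
  attr(out, "codon_index") <- which(keep)
  out
}

#' Strip columns containing gaps or missing data
#'
#' Drops every column with at least one `-` or `N`; the result is a
#' concatenation whose coordinates are no longer genomic.
#'
#' @param w An `aln_window`.
#' @return An `aln_window` with `start = 0`, `end = ncol`, and attribute
#'   `"genomic"` set to `FALSE`.
#' @export
strip_gap_columns <- function(w) {
  stopifnot(inherits(w, "aln_window"))
  keep <- colSums(w$seqs == "-" | w$seqs == "N") == 0L
  m <- w$seqs[, keep, drop = FALSE]
  out <- structure(list(chrom = w$chrom, start = 0L,
                        end = max(1L, ncol(m)), seqs = m,
                        informative = .informative_count(m)),
                   class = "aln_window")
  attr(out, "genomic") <- FALSE
  out
}

#' Neighbor-joining tree from a window alignment
#'
#' Pairwise Jukes-Cantor distances `d = -(3/4) log(1 - (4/3) p)` are computed
#' on pairwise-complete columns (both sequences in A/C/G/T); saturated pairs
#' (`p >= 3/4`) get the configured distance cap and flag the window. The
#' distance matrix is agglomerated with neighbor joining and negative branch
#' lengths are clamped to zero.
#'
#' @param w An `aln_window` with >= 4 taxa.
#' @param cap Distance assigned to saturated pairs (default 10).
#' @return An unrooted `phylo`; attribute `"saturated"` is `TRUE` if any pair
#'   hit the cap.
#' @export
nj_tree <- function(w, cap = 10) {
  stopifnot(inherits(w, "aln_window"))
  m <- w$seqs
  n <- nrow(m)
  if (n < 4L) stop("neighbor joining needs >= 4 taxa")
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- ok[i, ] & ok[j, ]
    ns <- sum(shared)
    if (ns == 0L)
      stop("taxa ", rownames(m)[i], " and ", rownames(m)[j],
           " share no ungapped columns")
    p <- sum(m[i, shared] != m[j, shared]) / ns
    if (p >= 0.75) {
      warning("saturated pair ", rownames(m)[i], "-", rownames(m)[j],
              ": p = ", signif(p, 3), ", distance capped at ", cap)
      dd <- cap
      saturated <- TRUE
    } else {
      dd <- -0.75 * log(1 - 4 * p / 3)
    }
    d[i, j] <- d[j, i] <- dd
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "saturated") <- saturated
  tr
}

#' Apply the window quality filters and build a filter report
#'
#' Runs the gap-ratio filter and (optionally) the per-sequence composition
#' chi-square test over a list of windows, reporting one row per window.
#' A window is retained when it passes the informative-column threshold
#' applied at split time, the gap filter, and — when enabled — the
#' composition test for every taxon.
#'
#' @param windows A list of `aln_window` objects (from [split_windows()]).
#' @param max_gap Gap-ratio threshold (default 0.10, strict `>` fails).
#' @param alpha Composition-test significance level (default 0.05).
#' @param apply_composition Apply the composition test (default `TRUE`;
#'   conventionally only small windows are subjected to it).
#' @return A data.frame (`FilterReport`): `chrom`, `start`, `end`,
#'   `informative`, `gap_ratio`, `gap_pass`, `composition_pass`, `retained`.
#' @export
filter_windows <- function(windows, max_gap = 0.10, alpha = 0.05,
                           apply_composition = TRUE) {
  rows <- lapply(windows, function(w) {
    gf <- gap_filter(w, threshold = max_gap)
    cp <- if (apply_composition)
      attr(composition_test(w, alpha = alpha), "window_pass") else NA
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               informative = w$informative,
               gap_ratio = gf$gap_ratio, gap_pass = gf$pass,
               composition_pass = cp,
               retained = isTRUE(w$retained) && gf$pass &&
                 (!apply_composition || isTRUE(cp)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a per-window multi-FASTA with filename-encoded coordinates
#'
#' The window's reference coordinates are parsed from a filename of the form
#' `chrom:start-end.fa` (BED half-open).
#'
#' @param path Path to a multi-FASTA file, one record per taxon.
#' @return An `aln_window`.
#' @export
read_window_fasta <- function(path) {
  base <- sub("\\.(fa|fasta)$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^(.+):([0-9]+)-([0-9]+)$", base))[[1]]
  if (length(m) != 4)
    stop("filename must encode coordinates as chrom:start-end, got '",
         base, "'")
  dna <- ape::read.FASTA(path)
  mat <- toupper(as.character(as.matrix(dna)))
  aln_window(mat, chrom = m[2], start = as.integer(m[3]),
             end = as.integer(m[4]))
}

#' Flag trees with abnormally long branches
#'
#' Simplified long-branch screen: for every taxon, its root-to-tip path
#' length is computed in each rooted tree; a tree is flagged when any taxon's
#' root-to-tip length exceeds `factor` times that taxon's median across all
#' trees. With fewer than `min_trees` trees the baseline is unstable and all
#' trees pass with a warning.
#'
#' @param trees List of rooted `phylo` objects sharing a taxon set.
#' @param factor Flagging multiplier (default 5).
#' @param min_trees Minimum tree count for a stable baseline (default 20).
#' @return Logical vector: `TRUE` = flagged (abnormally long branch).
#' @export
long_branch_filter <- function(trees, factor = 5.0, min_trees = 20L) {
  if (length(trees) < min_trees) {
    warning("fewer than ", min_trees, " trees: no long-branch baseline, ",
            "all trees pass")
    return(rep(FALSE, length(trees)))
  }
  labs <- trees[[1L]]$tip.label
  depths <- vapply(trees, function(tr) {
    d <- ape::node.depth.edgelength(tr)
    d[match(labs, tr$tip.label)]
  }, numeric(length(labs)))
  med <- apply(depths, 1L, median)
  colSums(depths > factor * med) > 0L
}
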