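## ABBA-BABA D-statistic with weighted block jackknife, the block-permutation
## distance test, and the percentile + run-length region caller.

#' Count ABBA and BABA site patterns in a quartet alignment
#'
#' Columns where all four taxa carry A/C/G/T are screened; with the outgroup
#' allele taken as ancestral, ABBA columns are those where P2 and P3 share a
#' derived allele and P1 matches the outgroup, BABA those where P1 and P3
#' share it and P2 matches the outgroup. Tri-allelic columns match neither.
#'
#' @param aln Character matrix (rows = taxa) containing the quartet taxa.
#' @param quartet Ordered character vector (P1, P2, P3, Outgroup).
#' @return Named integer vector `c(abba = , baba = )`.
#' @export
count_site_patterns <- function(aln, quartet) {
  stopifnot(is.matrix(aln), length(quartet) == 4L)
  miss <- setdiff(quartet, rownames(aln))
  if (length(miss))
    stop("quartet taxa missing from alignment: ",
         paste(miss, collapse = ", "))
  p1 <- aln[quartet[1L], ]; p2 <- aln[quartet[2L], ]
  p3 <- aln[quartet[3L], ]; og <- aln[quartet[4L], ]
  ok <- p1 %in% c("A", "C", "G", "T") & p2 %in% c("A", "C", "G", "T") &
    p3 %in% c("A", "C", "G", "T") & og %in% c("A", "C", "G", "T")
  abba <- sum(ok & p1 == og & p3 != og & p2 == p3)
  baba <- sum(ok & p2 == og & p3 != og & p1 == p3)
  c(abba = as.integer(abba), baba = as.integer(baba))
}

#' ABBA-BABA D-statistic with weighted block jackknife
#'
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)` over all blocks; the
#' standard error comes from a delete-one-block jackknife (Busing et al.
#' 1999 weighted form), and `Z = D / SE`.
#'
#' Blocks are equal genomic size by construction, so the default gives every
#' block equal jackknife weight (the formula then reduces to the classic
#' delete-one estimator). Weighting by per-block informative-site totals
#' (`weights = "patterns"`) mirrors the common SNP-count weighting but is
#' anticonservative when block totals are dominated by tree-level variance,
#' as they are for few loci per block.
#'
#' @param counts A data.frame with columns `abba` and `baba`, one row per
#'   genomic block (e.g. from [emit_site_patterns()]).
#' @param weights `"equal"` (default) or `"patterns"`.
#' @return An object of class `dstat`: list with `D`, `SE`, `Z`, `n_blocks`,
#'   `abba`, `baba`.
#' @examples
#' d_statistic(data.frame(abba = c(30, 30), baba = c(20, 20)))  # D = 0.2
#' @export
d_statistic <- function(counts, weights = c("equal", "patterns")) {
  weights <- match.arg(weights)
  stopifnot(all(c("abba", "baba") %in% names(counts)))
  a <- as.numeric(counts$abba); b <- as.numeric(counts$baba)
  if (any(a < 0) || any(b < 0)) stop("negative pattern counts")
  tot <- a + b
  if (sum(tot) == 0) stop("all-zero pattern counts: D undefined")
  D <- (sum(a) - sum(b)) / sum(a + b)
  use <- tot > 0
  g <- sum(use)
  if (g < 2) {
    SE <- NA_real_
  } else {
    aj <- a[use]; bj <- b[use]
    mj <- if (weights == "patterns") tot[use] else rep(1, g)
    n <- sum(mj)
    d_del <- vapply(seq_len(g), function(j)
      (sum(aj[-j]) - sum(bj[-j])) / (sum(aj[-j]) + sum(bj[-j])), numeric(1))
    hj <- n / mj
    theta_J <- g * D - sum((1 - mj / n) * d_del)
    tau <- hj * D - (hj - 1) * d_del
    SE <- sqrt(sum((tau - theta_J)^2 / (hj - 1)) / g)
  }
  structure(list(D = D, SE = SE, Z = D / SE, n_blocks = g,
                 abba = sum(a), baba = sum(b)),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("D = %.4f  SE = %.4f  Z = %.2f  (ABBA %d, BABA %d, %d blocks)\n",
              x$D, x$SE, x$Z, x$abba, x$baba, x$n_blocks))
  invisible(x)
}

#' Block-permutation test for a distance shift
#'
#' Compares the mean of an observed window statistic against a null built by
#' repeatedly sampling contiguous blocks of `block` windows from an ordered
#' background track (e.g. per-tree MRCA path lengths of the windows consistent
#' with the species tree). The empirical p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, so p is never exactly 0:
#' with 10,000 permutations the smallest attainable value is < 1e-4.
#'
#' @param observed Numeric vector of the observed windows' statistic values
#'   (or a single precomputed mean).
#' @param background Numeric vector of background statistic values in genomic
#'   order.
#' @param block Number of consecutive background windows per null draw
#'   (default 295).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed for reproducible draws.
#' @param alternative `"greater"` (distance increased; default), `"less"`, or
#'   `"two.sided"`.
#' @return List with `p`, `observed` (the mean), `null` (numeric vector of
#'   null means), `block`, `n_perm`, `alternative`.
#' @export
permutation_test <- function(observed, background, block = 295,
                             n_perm = 10000, seed = NULL,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(observed), is.numeric(background))
  if (block > length(background))
    stop("block (", block, ") exceeds background size (",
         length(background), ")")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(observed)
  ## contiguous-block means via cumulative sums
  cs <- c(0, cumsum(background))
  nstart <- length(background) - block + 1L
  starts <- sample.int(nstart, n_perm, replace = TRUE)
  null <- (cs[starts + block] - cs[starts]) / block
  p <- switch(alternative,
    greater = (1 + sum(null >= obs)) / (1 + n_perm),
    less = (1 + sum(null <= obs)) / (1 + n_perm),
    two.sided = {
      ctr <- mean(null)
      (1 + sum(abs(null - ctr) >= abs(obs - ctr))) / (1 + n_perm)
    })
  list(p = p, observed = obs, null = null, block = block, n_perm = n_perm,
       alternative = alternative)
}

#' Call introgressed and introgression-resistant regions
#'
#' An introgressed region is a run of the introgression topology class longer
#' than `intro_minrun` windows (strict `>`) whose windows' mean distance lies
#' strictly below the genome-wide `intro_pct` quantile of all per-window
#' distances. A resistant region is the mirror image: a run of the species
#' topology class longer than `resist_minrun` with mean distance strictly
#' above the upper `resist_pct` quantile.
#'
#' @param track A data.frame with one row per retained window: `chrom`,
#'   `start`, `end`, `class`, `distance` (ordered by chrom, start).
#' @param runs Output of [detect_runs()] on the same windows (computed from
#'   `track` if `NULL`).
#' @param intro_class,resist_class Canonical strings (or whatever `class`
#'   holds) of the introgression and species topologies.
#' @param intro_pct Lower distance quantile for introgressed calls
#'   (default 0.01).
#' @param intro_minrun Introgressed run-length threshold, strict (default 10).
#' @param resist_pct Upper tail size for resistant calls (default 0.01).
#' @param resist_minrun Resistant run-length threshold, strict (default 5).
#' @return A data.frame of calls: `chrom`, `start`, `end`, `type`
#'   (`introgressed`/`resistant`), `run_length`, `mean_distance`,
#'   `threshold`.
#' @export
call_regions <- function(track, runs = NULL, intro_class, resist_class,
                         intro_pct = 0.01, intro_minrun = 10,
                         resist_pct = 0.01, resist_minrun = 5) {
  req <- c("chrom", "start", "end", "class", "distance")
  if (!all(req %in% names(track)))
    stop("track needs columns: ", paste(req, collapse = ", "))
  if (!nrow(track)) stop("empty distance track: quantile undefined")
  if (is.null(runs)) runs <- detect_runs(track)
  lo <- quantile(track$distance, intro_pct, names = FALSE)
  hi <- quantile(track$distance, 1 - resist_pct, names = FALSE)
  run_mean <- function(r) {
    idx <- which(track$chrom == r$chrom & track$start >= r$start &
                   track$end <= r$end)
    mean(track$distance[idx])
  }
  calls <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (r$class == intro_class && r$length > intro_minrun) {
      m <- run_mean(r)
      if (m < lo)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = r$chrom, start = r$start, end = r$end,
          type = "introgressed", run_length = r$length, mean_distance = m,
          threshold = lo, stringsAsFactors = FALSE)
    }
    if (r$class == resist_class && r$length > resist_minrun) {
      m <- run_mean(r)
      if (m > hi)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = r$chrom, start = r$start, end = r$end,
          type = "resistant", run_length = r$length, mean_distance = m,
          threshold = hi, stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      run_length = integer(), mean_distance = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Overlap region calls with gene annotations
#'
#' bedtools-intersect semantics: a gene is reported for every region it
#' overlaps by at least 1 bp. Coordinates are BED half-open.
#'
#' @param regions A data.frame with `chrom`, `start`, `end` (e.g. from
#'   [call_regions()]).
#' @param genes A data.frame with `chrom`, `start`, `end`, `name`.
#' @return A data.frame with one row per (region, gene) overlap: region
#'   columns prefixed `region_`, plus `gene` and the gene coordinates. The
#'   deduplicated gene list is attached as attribute `"genes"`.
#' @export
overlap_genes <- function(regions, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (!nrow(regions) || !nrow(genes)) {
    out <- data.frame(region_chrom = character(), region_start = integer(),
                      region_end = integer(), gene = character(),
                      gene_start = integer(), gene_end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "genes") <- character()
    return(out)
  }
  unshared <- union(setdiff(regions$chrom, genes$chrom),
                    setdiff(genes$chrom, regions$chrom))
  if (length(unshared))
    warning("chromosomes present in only one input: ",
            paste(unshared, collapse = ", "))
  ## BED half-open -> 1-based closed for IRanges
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(region_chrom = regions$chrom[qi],
                    region_start = regions$start[qi],
                    region_end = regions$end[qi],
                    gene = genes$name[si],
                    gene_start = genes$start[si],
                    gene_end = genes$end[si],
                    stringsAsFactors = FALSE)
  if ("type" %in% names(regions)) out$region_type <- regions$type[qi]
  attr(out, "genes") <- unique(out$gene)
  out
}

#' Read gene annotations from BED or GFF3
#'
#' @param file Path to a BED (>= 4 columns: chrom, start, end, name) or GFF3
#'   file; for GFF3 only `gene` features are kept and coordinates are
#'   converted to BED half-open.
#' @param format `"bed"` or `"gff3"` (guessed from the extension by default).
#' @return A data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_genes <- function(file, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3"
      else "bed"
  if (format == "bed") {
    df <- utils::read.table(file, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) df$V4 <- paste0("feature_", seq_len(nrow(df)))
    return(data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
                      name = df[[4L]], stringsAsFactors = FALSE))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(file, format = "gff3")
  gr <- gr[gr$type == "gene"]
  nm <- if (!is.null(gr$Name)) gr$Name else gr$ID
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = as.character(nm), stringsAsFactors = FALSE)
}
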