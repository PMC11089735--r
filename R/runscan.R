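## Runs of identical window topologies along chromosomes.  "Consecutive"
## operates on the ordinal sequence of retained windows — genomic gaps left
## by filtered-out windows are ignored — but runs never span chromosomes.

#' Detect maximal runs of identical topology classes
#'
#' Windows must be ordered by (chrom, start); the run scan works on the
#' ordinal sequence of retained windows per chromosome, ignoring genomic
#' gaps between them.
#'
#' @param windows A data.frame with columns `chrom`, `start`, `end`, `class`
#'   (canonical strings or aliases), ordered by chrom then start.
#' @return A data.frame of runs: `chrom`, `start`, `end` (genomic span of the
#'   run, BED half-open), `class`, `start_ordinal` (1-based window ordinal
#'   within the chromosome), `length` (number of windows).
#' @export
detect_runs <- function(windows) {
  req <- c("chrom", "start", "end", "class")
  if (!all(req %in% names(windows)))
    stop("windows needs columns: ", paste(req, collapse = ", "))
  if (!nrow(windows)) stop("empty window table")
  ## windows of one chromosome must be contiguous rows in increasing order
  for (ch in unique(windows$chrom)) {
    idx <- which(windows$chrom == ch)
    if (any(diff(idx) != 1L)) stop("windows of ", ch, " are not contiguous")
    if (is.unsorted(windows$start[idx], strictly = TRUE))
      stop("windows of ", ch, " are not ordered by start")
  }
  out <- lapply(unique(windows$chrom), function(ch) {
    sub <- windows[windows$chrom == ch, , drop = FALSE]
    r <- rle(sub$class)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = ch,
               start = sub$start[starts], end = sub$end[ends],
               class = r$values, start_ordinal = starts,
               length = r$lengths, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise consecutive-window statistics per topology class
#'
#' For each class, the number and fraction of its windows that sit in runs of
#' length >= 2 ("scattered in consecutive windows") and in highly consecutive
#' runs of length >= `k_high`.
#'
#' @param runs Output of [detect_runs()].
#' @param k_high Highly-consecutive threshold (default 10 windows).
#' @return A data.frame per class: `class`, `total`, `in_runs2`, `frac_runs2`,
#'   `in_runs_high`, `frac_runs_high`; the run-length histogram per class is
#'   attached as attribute `"histogram"` (a named list of tables).
#' @export
summarize_runs <- function(runs, k_high = 10) {
  stopifnot(k_high >= 2)
  cls <- sort(unique(runs$class))
  res <- lapply(cls, function(cc) {
    len <- runs$length[runs$class == cc]
    data.frame(class = cc,
               total = sum(len),
               in_runs2 = sum(len[len >= 2]),
               frac_runs2 = sum(len[len >= 2]) / sum(len),
               in_runs_high = sum(len[len >= k_high]),
               frac_runs_high = sum(len[len >= k_high]) / sum(len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "histogram") <- lapply(setNames(cls, cls), function(cc)
    table(runs$length[runs$class == cc]))
  attr(out, "k_high") <- k_high
  out
}

#' Count topology classes in fixed genomic bins
#'
#' bedtools-intersect semantics: a window is counted in every bin it overlaps
#' by at least 1 bp (BED half-open coordinates).
#'
#' @param windows A data.frame with `chrom`, `start`, `end`, `class`.
#' @param bin Bin size in bp (default 500 kb).
#' @return A long data.frame: `chrom`, `bin_start`, `bin_end`, `class`,
#'   `count`.
#' @export
bin_counts <- function(windows, bin = 5e5) {
  stopifnot(bin > 0, nrow(windows) > 0)
  ## bins overlapped by window [s, e): floor(s/bin) .. floor((e-1)/bin)
  b0 <- windows$start %/% bin
  b1 <- (windows$end - 1L) %/% bin
  reps <- b1 - b0 + 1L
  long <- data.frame(
    chrom = rep(windows$chrom, reps),
    bin_idx = unlist(lapply(seq_len(nrow(windows)),
                            function(i) b0[i]:b1[i])),
    class = rep(windows$class, reps),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cnt ~ chrom + bin_idx + class,
                          data = transform(long, cnt = 1L), FUN = sum)
  out <- data.frame(chrom = agg$chrom,
                    bin_start = agg$bin_idx * bin,
                    bin_end = (agg$bin_idx + 1) * bin,
                    class = agg$class, count = agg$cnt,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$bin_start, out$class), ]
}
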