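test_that("D-statistic arithmetic and antisymmetry", {
  expect_equal(d_statistic(data.frame(abba = 30, baba = 30))$D, 0)
  expect_equal(d_statistic(data.frame(abba = 60, baba = 40))$D, 0.2)
  expect_error(d_statistic(data.frame(abba = 0, baba = 0)), "all-zero")
  expect_error(d_statistic(data.frame(abba = -1, baba = 2)), "negative")
  ## swapping P1 and P2 swaps ABBA/BABA: D -> -D with identical SE
  set.seed(111)
  cnt <- data.frame(abba = rpois(40, 20), baba = rpois(40, 15))
  d1 <- d_statistic(cnt)
  d2 <- d_statistic(data.frame(abba = cnt$baba, baba = cnt$abba))
  expect_equal(d2$D, -d1$D)
  expect_equal(d2$SE, d1$SE)
})

test_that("equal-weight jackknife reduces to the classic delete-one form", {
  set.seed(112)
  cnt <- data.frame(abba = rpois(30, 25), baba = rpois(30, 20))
  d <- d_statistic(cnt)
  g <- nrow(cnt)
  dj <- vapply(seq_len(g), function(j)
    (sum(cnt$abba[-j]) - sum(cnt$baba[-j])) /
      (sum(cnt$abba[-j]) + sum(cnt$baba[-j])), numeric(1))
  se_classic <- sqrt((g - 1) / g * sum((dj - mean(dj))^2))
  expect_equal(d$SE, se_classic, tolerance = 1e-9)
  ## replicating every block x10 shrinks the SE
  cnt10 <- cnt[rep(seq_len(g), 10), ]
  expect_lt(d_statistic(cnt10)$SE, d$SE / 2)
  ## pattern-count weighting is the Busing weighted alternative
  dw <- d_statistic(cnt, weights = "patterns")
  expect_equal(dw$D, d$D)
  expect_true(is.finite(dw$SE))
})

test_that("site patterns are counted per column with outgroup as ancestral", {
  aln <- rbind(
    P1 = c("A", "A", "A", "A", "C"),
    P2 = c("G", "G", "G", "C", "A"),
    P3 = c("G", "G", "G", "C", "C"),
    O  = c("A", "A", "A", "A", "A"))
  ## three ABBA columns, one ABBA again (col 4), one BABA (col 5)
  cnt <- count_site_patterns(aln, c("P1", "P2", "P3", "O"))
  expect_equal(cnt[["abba"]], 4L)
  expect_equal(cnt[["baba"]], 1L)
  expect_error(count_site_patterns(aln, c("P1", "P2", "Pz", "O")), "missing")
  ## random alignments match the per-column oracle
  set.seed(113)
  for (i in 1:100) {
    m <- random_aln(4, 80, alphabet = c("A", "C", "G", "T", "N", "-"),
                    taxa = c("P1", "P2", "P3", "O"))
    expect_equal(count_site_patterns(m, c("P1", "P2", "P3", "O")),
                 oracle_patterns(m, c("P1", "P2", "P3", "O")))
  }
})

test_that("permutation test orientation, bounds and reproducibility", {
  bg <- 1:1000 / 10
  ## observed below every null draw: upper-tail p near 1
  p_lo <- permutation_test(rep(0, 10), bg, block = 50, n_perm = 200,
                           seed = 1)
  expect_gt(p_lo$p, 0.99)
  ## observed above every null draw: p = 1/(n_perm + 1)
  p_hi <- permutation_test(rep(1e6, 10), bg, block = 50, n_perm = 10000,
                           seed = 1)
  expect_equal(p_hi$p, 1 / 10001)
  expect_lt(p_hi$p, 1e-4)
  ## seed reproducibility and block bound
  a <- permutation_test(5, bg, block = 295, n_perm = 100, seed = 7)
  b <- permutation_test(5, bg, block = 295, n_perm = 100, seed = 7)
  expect_identical(a$null, b$null)
  expect_error(permutation_test(5, bg[1:100], block = 295), "exceeds")
  ## two-sided option
  p2 <- permutation_test(mean(bg), bg, block = 100, n_perm = 200, seed = 2,
                         alternative = "two.sided")
  expect_gt(p2$p, 0.5)
})

test_that("region calling enforces both criteria with strict boundaries", {
  ## fixture: 200 windows, a planted 16-window t2 run at sharply reduced
  ## distance, one 10-window t2 run (boundary: not called), background t1
  n <- 200
  cls <- rep("t1", n)
  cls[50:65] <- "t2"    # 16 windows, qualifies (> 10)
  cls[100:109] <- "t2"  # exactly 10 windows: strict > excludes it
  dist <- rep(10, n) + seq_len(n) * 1e-4  # near-constant background
  dist[50:65] <- 1
  dist[100:109] <- 1
  track <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1e4,
                      end = seq_len(n) * 1e4, class = cls, distance = dist,
                      stringsAsFactors = FALSE)
  calls <- call_regions(track, intro_class = "t2", resist_class = "t1",
                        intro_pct = 0.15, intro_minrun = 10,
                        resist_pct = 0.01, resist_minrun = 5)
  intro <- calls[calls$type == "introgressed", ]
  expect_equal(nrow(intro), 1)
  expect_equal(intro$start, 49 * 1e4)
  expect_equal(intro$end, 65 * 1e4)
  expect_equal(intro$run_length, 16)
  ## every call satisfies both criteria when re-checked independently
  lo <- quantile(track$distance, 0.15, names = FALSE)
  for (r in seq_len(nrow(intro))) {
    idx <- track$start >= intro$start[r] & track$end <= intro$end[r]
    expect_true(all(track$class[idx] == "t2"))
    expect_gt(sum(idx), 10)
    expect_lt(mean(track$distance[idx]), lo)
  }
  ## constant distances: no region can sit strictly inside either tail
  track2 <- track; track2$distance <- 5
  expect_equal(nrow(call_regions(track2, intro_class = "t2",
                                 resist_class = "t1")), 0)
  expect_error(call_regions(track[0, ], intro_class = "t2",
                            resist_class = "t1"), "empty")
})

test_that("gene overlap follows half-open bedtools semantics", {
  regions <- data.frame(chrom = "chr1", start = 150, end = 300,
                        type = "introgressed", stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = c(100, 300),
                      end = c(200, 400), name = c("gA", "gB"),
                      stringsAsFactors = FALSE)
  ov <- overlap_genes(regions, genes)
  expect_equal(attr(ov, "genes"), "gA")  # gB abuts at 300: no overlap
  ## chromosome mismatch warns
  genes2 <- rbind(genes, data.frame(chrom = "chrZ", start = 1, end = 10,
                                    name = "gZ"))
  expect_warning(overlap_genes(regions, genes2), "chrZ")
  ## random fixtures match the quadratic oracle
  set.seed(114)
  for (i in 1:100) {
    nr <- sample(3:12, 1); ng <- sample(3:20, 1)
    rs <- sample.int(1e5, nr); gs <- sample.int(1e5, ng)
    regions3 <- data.frame(chrom = sample(c("c1", "c2"), nr, TRUE),
                           start = rs, end = rs + sample.int(5000, nr),
                           stringsAsFactors = FALSE)
    genes3 <- data.frame(chrom = sample(c("c1", "c2"), ng, TRUE),
                         start = gs, end = gs + sample.int(5000, ng),
                         name = paste0("g", seq_len(ng)),
                         stringsAsFactors = FALSE)
    ov3 <- suppressWarnings(overlap_genes(regions3, genes3))
    hits <- oracle_overlaps(regions3, genes3)
    expect_equal(nrow(ov3), nrow(hits))
    if (nrow(hits))
      expect_setequal(paste(ov3$region_start, ov3$gene),
                      paste(regions3$start[hits[, 1]],
                            genes3$name[hits[, 2]]))
  }
})
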