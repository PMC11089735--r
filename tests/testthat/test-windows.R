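test_that("split_windows tiles the reference and drops uninformative", {
  set.seed(90)
  m <- random_aln(6, 10000)
  ws <- split_windows(m, size = 1000)
  expect_length(ws, 10)
  expect_equal(vapply(ws, function(w) w$start, numeric(1)), 0:9 * 1000)
  expect_equal(vapply(ws, function(w) w$end, numeric(1)), 1:10 * 1000)
  expect_true(all(vapply(ws, function(w) w$retained, logical(1))))
  ## an all-gap stretch yields an uninformative window that is dropped
  m2 <- m
  m2[, 2001:3000] <- "-"
  ws2 <- split_windows(m2, size = 1000, min_informative = 30)
  expect_false(ws2[[3]]$retained)
  expect_equal(ws2[[3]]$informative, 0)
  ## retained + dropped together tile the interval
  expect_equal(sum(vapply(ws2, function(w) w$end - w$start, numeric(1))),
               10000)
  ## informative counts match a brute-force column scan on a gappy fixture
  m3 <- random_aln(5, 3000, alphabet = c("A", "C", "G", "T", "N", "-"))
  ws3 <- split_windows(m3, size = 500)
  for (k in seq_along(ws3)) {
    cols <- m3[, (ws3[[k]]$start + 1):ws3[[k]]$end, drop = FALSE]
    brute <- sum(apply(cols, 2, function(cc) sum(!cc %in% c("N", "-")) >= 2))
    expect_equal(ws3[[k]]$informative, brute)
  }
  expect_length(split_windows(m[, 0, drop = FALSE], 1000), 0)
})

test_that("gap filter uses a strict > threshold on the full-window ratio", {
  m <- random_aln(6, 1000)
  m[1, 1:660] <- "-"   # 660 / 6000 = 0.11
  expect_false(gap_filter(aln_window(m))$pass)
  expect_equal(gap_filter(aln_window(m))$gap_ratio, 0.11)
  m2 <- random_aln(6, 1000)
  expect_true(gap_filter(aln_window(m2))$pass)
  ## exactly at the threshold passes
  m3 <- random_aln(6, 1000)
  m3[1, 1:600] <- "-"
  expect_true(gap_filter(aln_window(m3))$pass)
})

test_that("composition test flags deviant sequences", {
  ## identical composition in every taxon: zero statistic
  m <- do.call(rbind, rep(list(rep(c("A", "C", "G", "T"), 100)), 4))
  rownames(m) <- paste0("t", 1:4)
  ct <- composition_test(aln_window(m))
  expect_true(all(ct$statistic == 0))
  expect_true(attr(ct, "window_pass"))
  ## one all-G taxon among uniform taxa at 400 bp: its statistic is the
  ## hand-formula value, far over the 7.815 critical value
  m2 <- rbind(matrix(rep(c("A", "C", "G", "T"), 100), 3, 400, byrow = TRUE),
              rep("G", 400))
  rownames(m2) <- paste0("t", 1:4)
  ct2 <- composition_test(aln_window(m2))
  pooled <- c(A = 300, C = 300, G = 700, T = 300) / 1600
  expected_stat <- sum((c(0, 0, 400, 0) - 400 * pooled)^2 / (400 * pooled))
  expect_equal(ct2$statistic[4], expected_stat, tolerance = 1e-9)
  expect_gt(ct2$statistic[4], 7.815)
  expect_false(ct2$pass[4])
  expect_false(attr(ct2, "window_pass"))
  ## two taxa both equal to the pooled mean pass
  m3 <- rbind(rep(c("A", "C"), 50), rep(c("A", "C"), 50))
  rownames(m3) <- c("x", "y")
  expect_true(attr(composition_test(aln_window(m3)), "window_pass"))
})

test_that("4D-site extraction honours the fourfold codon families", {
  ## all-Ala column (GC*): third positions emitted
  m <- rbind(c("G", "C", "A"), c("G", "C", "C"), c("G", "C", "G"),
             c("G", "C", "T"))
  rownames(m) <- paste0("t", 1:4)
  out <- extract_4d_sites(aln_window(m), frame = 0)
  expect_equal(ncol(out), 1)
  expect_equal(out[, 1], c(t1 = "A", t2 = "C", t3 = "G", t4 = "T"))
  ## ATG (Met) never qualifies
  m2 <- m; m2[1, ] <- c("A", "T", "G")
  expect_equal(ncol(extract_4d_sites(aln_window(m2), frame = 0)), 0)
  ## prefix not conserved (GGA vs GAA)
  m3 <- rbind(c("G", "G", "A"), c("G", "A", "A"), c("G", "G", "A"),
              c("G", "G", "A"))
  rownames(m3) <- paste0("t", 1:4)
  expect_equal(ncol(extract_4d_sites(aln_window(m3), frame = 0)), 0)
  expect_error(extract_4d_sites(aln_window(m), frame = NULL), "frame")
  ## emitted codons agree with a genetic-code oracle on random fixtures
  set.seed(91)
  for (i in 1:100) {
    mm <- random_aln(4, 60, alphabet = c("A", "C", "G", "T", "-"))
    ## boost prefix conservation so qualifying codons actually occur
    conserved <- sample(20, 8)
    for (k in conserved) {
      mm[, 3 * k - 2] <- sample(c("G", "C", "A", "T"), 1)
      mm[, 3 * k - 1] <- sample(c("C", "G", "T"), 1)
    }
    got <- attr(extract_4d_sites(aln_window(mm), frame = 0), "codon_index")
    expect_equal(got, which(oracle_4d_mask(mm)))
  }
  ## output bounded by one third of the alignment
  expect_lte(ncol(extract_4d_sites(aln_window(m), frame = 0)), 1)
})

test_that("strip_gap_columns equals the brute-force column mask", {
  m <- random_aln(4, 100)
  expect_equal(ncol(strip_gap_columns(aln_window(m))$seqs), 100)
  m[2, 37] <- "-"
  expect_equal(ncol(strip_gap_columns(aln_window(m))$seqs), 99)
  set.seed(92)
  for (i in 1:20) {
    mm <- random_aln(5, 200, alphabet = c("A", "C", "G", "T", "N", "-"))
    keep <- apply(mm, 2, function(cc) all(!cc %in% c("N", "-")))
    expect_equal(strip_gap_columns(aln_window(mm))$seqs,
                 mm[, keep, drop = FALSE])
  }
})

test_that("nj_tree recovers additive and simulated topologies", {
  ## additive matrix with split AB|CD injected through sequences is checked
  ## via the four-point condition instead: construct sequences on a known
  ## tree and verify the split
  taxa <- duck_taxa()
  cfg <- sim_config(pulse = pulse0(0), seed = 93)
  ## identical sequences: star tree, zero lengths after clamping
  m0 <- matrix("A", 4, 100, dimnames = list(paste0("t", 1:4), NULL))
  tr0 <- nj_tree(aln_window(m0))
  expect_true(all(tr0$edge.length == 0))
  ## saturation cap fires with a warning
  m1 <- rbind(t1 = rep("A", 200), t2 = rep("C", 200),
              t3 = rep(c("A", "C", "G", "T"), 50),
              t4 = rep(c("T", "G", "C", "A"), 50))
  expect_warning(tr1 <- nj_tree(aln_window(m1)), "saturated")
  expect_true(attr(tr1, "saturated"))
  ## gappy realistic sequences: the NJ tree from our JC distances equals the
  ## tree from ape::dist.dna (JC69, pairwise deletion) as an oracle
  set.seed(94)
  gt94 <- simulate_gene_trees(1, sim_config(pulse = pulse0(0), seed = 94))
  mm <- evolve_sequences(gt94$trees[[1]], 2000, theta = 0.002)
  mm[sample(length(mm), 600)] <- "-"
  w <- aln_window(mm)
  tr <- nj_tree(w)
  dn <- ape::dist.dna(ape::as.DNAbin(tolower(mm)), model = "JC69",
                      pairwise.deletion = TRUE)
  tr_oracle <- ape::nj(dn)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(tr_oracle))), 0)
  ## simulated 50-kb windows at low rate: >= 95% topology recovery
  gt <- simulate_gene_trees(60, cfg)
  ok <- 0
  for (i in seq_len(60)) {
    aln <- evolve_sequences(gt$trees[[i]], 50000, theta = 0.002)
    est <- nj_tree(aln_window(aln))
    ok <- ok + (canonical_id(est, taxa) ==
                  topowindow:::.lt_canonical(gt$trees[[i]], "Muscovy"))
  }
  expect_gte(ok / 60, 0.95)
})

test_that("filter report combines the quality screens per window", {
  set.seed(96)
  m <- random_aln(6, 4000)
  m[, 1001:1460] <- "-"          # window 2 gap-heavy: 460*6/6000 gaps
  m[6, 2001:3000] <- "G"         # window 3: one deviant-composition taxon
  ws <- split_windows(m, size = 1000)
  rep <- filter_windows(ws)
  expect_equal(nrow(rep), 4)
  expect_false(rep$gap_pass[2])
  expect_false(rep$composition_pass[3])
  expect_equal(rep$retained, c(TRUE, FALSE, FALSE, TRUE))
  ## composition screen can be disabled (large-window convention)
  rep2 <- filter_windows(ws, apply_composition = FALSE)
  expect_true(rep2$retained[3])
})

test_that("per-window FASTA round-trips with coordinate filenames", {
  set.seed(97)
  m <- random_aln(4, 120)
  dir <- tempdir()
  path <- file.path(dir, "chr2:30000-30120.fa")
  writeLines(c(rbind(paste0(">", rownames(m)),
                     apply(m, 1, paste, collapse = ""))), path)
  w <- read_window_fasta(path)
  expect_equal(w$chrom, "chr2")
  expect_equal(w$start, 30000L)
  expect_equal(w$end, 30120L)
  expect_equal(unname(w$seqs), unname(m))
  expect_error(read_window_fasta(file.path(dir, "nocoords.fa")), "chrom")
})

test_that("long-branch filter flags planted outliers only", {
  set.seed(95)
  cfg <- sim_config(pulse = pulse0(0), seed = 95)
  trees <- lapply(seq_len(100), function(i)
    reroot(gene_tree_phylo(simulate_gene_trees(1, sim_config(
      pulse = pulse0(0), seed = 95 + i)), 1), "Muscovy"))
  expect_equal(sum(long_branch_filter(trees, factor = 5)), 0)
  ## plant one tree with one leaf stretched 50x
  planted <- trees
  k <- which(planted[[42]]$edge[, 2] ==
               match("Pekin", planted[[42]]$tip.label))
  planted[[42]]$edge.length[k] <- planted[[42]]$edge.length[k] * 50
  flags <- long_branch_filter(planted, factor = 5)
  expect_equal(which(flags), 42)
  ## infinite factor flags nothing
  expect_equal(sum(long_branch_filter(planted, factor = Inf)), 0)
  ## too few trees: all pass with a warning
  expect_warning(f <- long_branch_filter(planted[1:5]), "baseline")
  expect_equal(sum(f), 0)
})
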