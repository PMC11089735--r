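taxa6 <- duck_taxa()
aliases <- duck_aliases()

## species tree with long outer branches so the focal-node closed form is
## clean: only the internal branch T controls discordance
sp_clean <- function(T) duck_species_tree(T = T, t_inner = 9, t_root = 18)

test_that("config validation enforces the pulse invariants", {
  expect_error(sim_config(pulse = pulse0(1.5)), "gamma")
  expect_error(sim_config(pulse = pulse0(0.2, time = 0.5)),
               "donor population")
  expect_error(sim_config(pulse = pulse0(0.2, time = 3.5)),
               "younger than the recipient")
  expect_error(sim_config(species_tree = "(A:1,(B:1,C:2):1);",
                          pulse = list(gamma = 0)), "ultrametric")
  cfg <- sim_config(pulse = pulse0(0.3))
  expect_equal(cfg$pulse$planted_time, 1.5)
})

test_that("gene-tree frequencies match MSC closed forms at T = 0.5 and 2", {
  ## discordant rooted resolutions at the focal node each have probability
  ## (1/3) exp(-T); 3e4 draws per T (acceptance covers T = 1 at 1e5)
  for (T in c(0.5, 2)) {
    cfg <- sim_config(species_tree = sp_clean(T), pulse = pulse0(0),
                      seed = round(1000 * T))
    gt <- simulate_gene_trees(30000, cfg)
    cl <- classify_gene_trees(gt, taxa6)
    exp_disc <- exp(-T) / 3
    se <- sqrt(exp_disc * (1 - exp_disc) / 30000)
    expect_lt(abs(mean(cl == aliases[["t2"]]) - exp_disc), 3 * se)
    expect_lt(abs(mean(cl == aliases[["t3"]]) - exp_disc), 3 * se)
    expect_lt(abs(mean(cl == aliases[["t1"]]) - (1 - 2 * exp_disc)),
              3 * sqrt((1 - 2 * exp_disc) * 2 * exp_disc / 30000))
  }
})

test_that("no-ILS and full-replacement limits behave", {
  ## T large, gamma 0: always the species topology
  cfg <- sim_config(species_tree = sp_clean(6), pulse = pulse0(0), seed = 1)
  cl <- classify_gene_trees(simulate_gene_trees(2000, cfg), taxa6)
  expect_gt(mean(cl == aliases[["t1"]]), 0.99)
  ## gamma 1: recipient always reroutes; pulse topology dominates as the
  ## donor branch is long enough for coalescence before the focal node
  cfg1 <- sim_config(species_tree = sp_clean(6), pulse = pulse0(1, time = 5),
                     seed = 2)
  gt1 <- simulate_gene_trees(2000, cfg1)
  expect_true(all(gt1$provenance == "pulse"))
  cl1 <- classify_gene_trees(gt1, taxa6)
  expect_gt(mean(cl1 == aliases[["t2"]]), 0.95)
})

test_that("pulse-topology excess over ILS expectation is monotone in gamma", {
  f2 <- vapply(c(0.1, 0.2, 0.4), function(g) {
    cfg <- sim_config(pulse = pulse0(g), seed = round(3000 + 100 * g))
    mean(classify_gene_trees(simulate_gene_trees(15000, cfg), taxa6) ==
           aliases[["t2"]])
  }, numeric(1))
  ils_only <- {
    cfg <- sim_config(pulse = pulse0(0), seed = 3001)
    mean(classify_gene_trees(simulate_gene_trees(15000, cfg), taxa6) ==
           aliases[["t2"]])
  }
  expect_true(all(f2 > ils_only))
  expect_true(all(diff(f2) > 0))
})

test_that("genome layout produces geometric runs and a faithful truth set", {
  ## L = 1: independent windows; mean class-run length follows the renewal
  ## formula 1 / (1 - sum f_c^2)
  cfg <- sim_config(pulse = pulse0(0.3),
                    layout = list(n_chrom = 1, windows_per_chrom = 20000,
                                  mean_run = 1), seed = 31)
  ds <- layout_genome(cfg)
  cl <- classify_gene_trees(ds, taxa6)[ds$windows$tree_id]
  runs <- detect_runs(data.frame(chrom = ds$windows$chrom,
                                 start = ds$windows$start,
                                 end = ds$windows$end, class = cl,
                                 stringsAsFactors = FALSE))
  f <- table(cl) / length(cl)
  expected_mean <- 1 / (1 - sum(f^2))
  expect_lt(abs(mean(runs$length) - expected_mean), 0.05)
  ## planted 300-window run is recovered exactly as one run
  planted <- data.frame(chrom = "chr1", start_window = 101, length = 300)
  cfgp <- sim_config(pulse = pulse0(0.3),
                     layout = list(n_chrom = 1, windows_per_chrom = 1000,
                                   mean_run = 2, planted = planted),
                     seed = 32)
  dsp <- layout_genome(cfgp)
  expect_equal(sum(dsp$windows$planted), 300)
  expect_equal(dsp$truth$length, 300)
  clp <- classify_gene_trees(dsp, taxa6)[dsp$windows$tree_id]
  runsp <- detect_runs(data.frame(chrom = dsp$windows$chrom,
                                  start = dsp$windows$start,
                                  end = dsp$windows$end, class = clp,
                                  stringsAsFactors = FALSE))
  expect_true(any(runsp$length >= 300 &
                    runsp$class == aliases[["t2"]]))
  ## same seed, byte-identical dataset
  ds2 <- layout_genome(cfgp)
  expect_identical(dsp$windows, ds2$windows)
  expect_identical(dsp$trees, ds2$trees)
  expect_identical(dsp$genes, ds2$genes)
})

test_that("sequence evolution is JC-consistent", {
  cfg <- sim_config(pulse = pulse0(0), seed = 41)
  gt <- simulate_gene_trees(1, cfg)
  ## zero-length branches: identical sequences
  lt0 <- gt$trees[[1]]
  lt0$time[] <- 0
  aln0 <- evolve_sequences(lt0, 500)
  expect_true(all(aln0 == aln0[rep(1, nrow(aln0)), ]))
  ## saturation limit: two taxa at enormous distance approach p = 3/4
  sat <- parse_newick("(A:1000,B:1000);")
  set.seed(42)
  alns <- evolve_sequences(sat, 20000, theta = 0.01)
  p <- mean(alns["A", ] != alns["B", ])
  expect_lt(abs(p - 0.75), 0.02)
  ## JC-corrected distances recover the generating patristic distances
  set.seed(43)
  ph <- gene_tree_phylo(gt, 1)
  aln <- evolve_sequences(ph, 1e5, theta = 0.002)
  for (pair in list(c("Pekin", "Baikal"), c("Muscovy", "Pekin"))) {
    p_obs <- mean(aln[pair[1], ] != aln[pair[2], ])
    d_hat <- -0.75 * log(1 - 4 * p_obs / 3) / 0.002
    d_true <- patristic_distance(ph, pair[1], pair[2])
    ## binomial SE propagated through the JC transform
    se_p <- sqrt(p_obs * (1 - p_obs) / 1e5)
    se_d <- se_p / ((1 - 4 * p_obs / 3) * 0.002)
    expect_lt(abs(d_hat - d_true), 3 * se_d)
  }
})

test_that("emitted site patterns are symmetric without gene flow", {
  cfg <- sim_config(pulse = pulse0(0),
                    layout = list(n_chrom = 1, windows_per_chrom = 300,
                                  mean_run = 1), seed = 51)
  ds <- layout_genome(cfg)
  pat <- emit_site_patterns(ds, c("Shoveler", "Pekin", "Steamer1",
                                  "Muscovy"), block_bp = 1e5)
  d <- d_statistic(pat)
  expect_lt(abs(d$D), 0.15)
  expect_error(emit_site_patterns(ds, c("Shoveler", "Pekin", "Nope",
                                        "Muscovy")), "missing")
  ## fast integer counting equals the public column-scan on real alignments
  set.seed(52)
  ph <- ape::keep.tip(gene_tree_phylo(ds, 1),
                      c("Shoveler", "Pekin", "Steamer1", "Muscovy"))
  aln <- evolve_sequences(ph, 5000, theta = 0.002)
  expect_equal(count_site_patterns(aln, c("Shoveler", "Pekin", "Steamer1",
                                          "Muscovy")),
               oracle_patterns(aln, c("Shoveler", "Pekin", "Steamer1",
                                      "Muscovy")))
})

test_that("fast light-tree paths agree with the phylo-based operations", {
  cfg <- sim_config(pulse = pulse0(0.3), seed = 61)
  gt <- simulate_gene_trees(200, cfg)
  for (i in seq_len(200)) {
    ph <- gene_tree_phylo(gt, i)
    expect_identical(topowindow:::.lt_canonical(gt$trees[[i]], "Muscovy"),
                     canonical_id(ph, taxa6))
  }
  d_fast <- tip_distance_track(gt, "Pekin", c("Steamer1", "Steamer2"))
  for (i in seq_len(25)) {
    ph <- gene_tree_phylo(gt, i)
    d_ref <- mean(c(patristic_distance(ph, "Pekin", "Steamer1"),
                    patristic_distance(ph, "Pekin", "Steamer2")))
    expect_equal(d_fast[i], d_ref, tolerance = 1e-9)
  }
})
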