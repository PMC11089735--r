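## End-to-end orchestration: simulate (or load) -> classify -> run scan ->
## distance track -> region calls -> D-statistic -> species tree, with a
## provenance manifest and deterministic re-runs from one seed.

#' Assemble the per-window distance track
#'
#' One row per retained window: coordinates, topology class and the mean
#' patristic distance (coalescent units) from the recipient taxon to the
#' donor taxa — the quantity whose lowest percentile marks candidate
#' introgressed regions.
#'
#' @param dataset A `synthetic_dataset` from [layout_genome()].
#' @param taxa A [taxon_set()] (default [duck_taxa()]).
#' @param from Recipient leaf label (default `"Pekin"`).
#' @param to Donor leaf labels (default the steamer pair).
#' @return A data.frame: `chrom`, `start`, `end`, `class`, `distance`,
#'   `tree_id`, `provenance`, `planted`.
#' @export
distance_track <- function(dataset, taxa = duck_taxa(), from = "Pekin",
                           to = c("Steamer1", "Steamer2")) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  classes <- classify_gene_trees(dataset, taxa)
  dist_tree <- tip_distance_track(dataset, from, to)
  w <- dataset$windows
  data.frame(chrom = w$chrom, start = w$start, end = w$end,
             class = classes[w$tree_id], distance = dist_tree[w$tree_id],
             tree_id = w$tree_id, provenance = w$provenance,
             planted = w$planted, stringsAsFactors = FALSE)
}

#' Per-window MRCA path-length track
#'
#' For each window's gene tree (rooted on the outgroup), the path length from
#' `MRCA(setA)` to `MRCA(setA U setB)` — e.g. from the recipient-side clade's
#' ancestor to the node where it joins (Baikal, Shoveler). Introgressed
#' windows show this distance increased: the recipient coalesces with the
#' donor clade first, pushing the joint MRCA deeper.
#'
#' @param dataset A `synthetic_dataset`.
#' @param setA,setB Leaf label vectors (defaults: recipient; the two single
#'   lineages).
#' @param taxa A [taxon_set()] supplying the outgroup.
#' @return Numeric vector, one value per window (rows of
#'   `dataset$windows`).
#' @export
mrca_track <- function(dataset, setA = "Pekin",
                       setB = c("Baikal", "Shoveler"), taxa = duck_taxa()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  og <- outgroup_of(taxa)
  per_tree <- vapply(seq_along(dataset$trees), function(i) {
    ph <- reroot(.light_to_phylo(dataset$trees[[i]]), og)
    mrca_path_length(ph, setA, setB)
  }, numeric(1))
  per_tree[dataset$windows$tree_id]
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic genome from the configuration and pushes it through
#' every analysis stage: topology classification and frequency table, run
#' detection and consecutive-window summary, 500-kb bin counts, the distance
#' track, region calling, gene overlap, the ABBA-BABA D-statistic and the
#' exhaustive triplet-score species tree. Re-running with the same
#' configuration (same seed) reproduces identical outputs.
#'
#' @param cfg A [sim_config()] (its `seed` governs all randomness).
#' @param taxa A [taxon_set()] matching the simulated taxa.
#' @param quartet Ordered quartet (P1, P2, P3, Outgroup) for the D-statistic,
#'   or `NULL` to skip sequence simulation.
#' @param k_high Highly-consecutive run threshold (default 10).
#' @param bin Bin size for topology counts (default 5e5).
#' @param block_bp Jackknife block size in bp for the D-statistic
#'   (default 5e5).
#' @param intro_pct,intro_minrun,resist_pct,resist_minrun Region-calling
#'   parameters, see [call_regions()].
#' @param n_species_trees Number of gene trees subsampled (deterministically,
#'   evenly spaced) for the species-tree stage (default 500).
#' @param outdir Optional directory; when given, tab-separated outputs and
#'   the manifest are written there.
#' @return A list with elements `dataset`, `track`, `freq`, `runs`,
#'   `run_summary`, `bins`, `calls`, `gene_overlaps`, `dstat`,
#'   `species_tree`, `manifest`.
#' @export
run_pipeline <- function(cfg, taxa = duck_taxa(),
                         quartet = c("Shoveler", "Pekin", "Steamer1",
                                     "Muscovy"),
                         k_high = 10, bin = 5e5, block_bp = 5e5,
                         intro_pct = 0.01, intro_minrun = 10,
                         resist_pct = 0.01, resist_minrun = 5,
                         n_species_trees = 500, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  aliases <- duck_aliases(taxa)
  dataset <- layout_genome(cfg)
  track <- distance_track(dataset, taxa)
  enum <- enumerate_rooted_topologies(
    taxa, constraints = .steamer_constraint(taxa))
  freq <- tabulate_topologies(track$class, enumeration = enum,
                              aliases = aliases)
  runs <- detect_runs(track)
  run_summary <- summarize_runs(runs, k_high = k_high)
  bins <- bin_counts(track, bin = bin)
  calls <- call_regions(track, runs,
                        intro_class = aliases[["t2"]],
                        resist_class = aliases[["t1"]],
                        intro_pct = intro_pct, intro_minrun = intro_minrun,
                        resist_pct = resist_pct, resist_minrun = resist_minrun)
  gene_overlaps <- overlap_genes(calls, dataset$genes)
  dstat <- NULL
  if (!is.null(quartet)) {
    pat <- emit_site_patterns(dataset, quartet, block_bp = block_bp)
    dstat <- d_statistic(pat)
  }
  ## species tree from an even subsample of the window trees
  n_tr <- length(dataset$trees)
  sel <- unique(round(seq(1L, n_tr, length.out = min(n_species_trees, n_tr))))
  st <- exhaustive_species_tree(
    lapply(sel, function(i) gene_tree_phylo(dataset, i)), taxa,
    constraints = .steamer_constraint(taxa))
  manifest <- list(
    seed = cfg$seed,
    n_windows = nrow(dataset$windows),
    n_trees = n_tr,
    n_pulse_windows = sum(dataset$windows$provenance == "pulse"),
    n_planted_windows = sum(dataset$windows$planted),
    n_runs = nrow(runs),
    n_calls = nrow(calls),
    n_overlap_genes = length(attr(gene_overlaps, "genes")),
    species_tree = st$best,
    species_tree_alias = names(aliases)[match(st$best, aliases)][1L],
    counts_conserved = nrow(track) == nrow(dataset$windows) &&
      sum(runs$length) == nrow(track))
  if (!isTRUE(manifest$counts_conserved))
    stop("record-count conservation violated between stages")
  res <- list(dataset = dataset, track = track, freq = freq, runs = runs,
              run_summary = run_summary, bins = bins, calls = calls,
              gene_overlaps = gene_overlaps, dstat = dstat,
              species_tree = st, manifest = manifest)
  if (!is.null(outdir)) .write_pipeline_outputs(res, outdir)
  res
}

## the donor pair is constrained as a clade, mirroring the pruned system
.steamer_constraint <- function(taxa) {
  ing <- setdiff(as.character(taxa), outgroup_of(taxa))
  list(ing[1:2])
}

.write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(res$track, "track.tsv")
  wtsv(res$freq, "topology_frequencies.tsv")
  wtsv(res$runs, "runs.tsv")
  wtsv(res$run_summary, "run_summary.tsv")
  wtsv(res$bins, "bin_counts.tsv")
  wtsv(res$calls, "region_calls.tsv")
  wtsv(res$gene_overlaps, "gene_overlaps.tsv")
  wtsv(res$species_tree$scores, "species_tree_scores.tsv")
  manifest <- res$manifest
  writeLines(paste(names(manifest), vapply(manifest, paste, character(1)),
                   sep = "\t"),
             file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}
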