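## Multispecies-coalescent simulator with one timed unidirectional
## introgression pulse, plus genome layout, sequence evolution and site
## pattern emission.  This module generates every fixture the pipeline is
## validated on: the statistical structure it emulates is incomplete lineage
## sorting (standard exponential coalescence within species-tree branches)
## overlaid with a hybridization pulse that, with probability gamma, reroutes
## the recipient lineage into the donor population at the pulse time.
##
## Gene trees are kept in a light internal representation (parent pointers +
## node times in coalescent units) for speed; `gene_tree_phylo()` converts to
## ape's phylo, and the fast classification/distance paths are cross-checked
## against the phylo-based operations in the test suite.

#' Default six-taxon species tree in coalescent units
#'
#' Ultrametric topology `(Outgroup,((Steamer1,Steamer2),((Baikal,Shoveler),
#' Pekin)))` with leaf-to-node times: steamer split and (Baikal,Shoveler)
#' split at 1, the ((Baikal,Shoveler),Pekin) node at `t_inner`, its parent
#' (the focal node where the steamer clade attaches) `T` units deeper, and
#' the root at `t_root`. `T` is the internal branch whose length controls
#' incomplete lineage sorting at the focal node: each discordant rooted
#' resolution has probability `(1/3)exp(-T)` in the absence of gene flow.
#'
#' @param T Focal internal branch length in coalescent units (default 1).
#' @param t_inner Time of the ((Baikal,Shoveler),Pekin) node (default 3).
#' @param t_root Root (outgroup divergence) time (default 8).
#' @return A newick string.
#' @export
duck_species_tree <- function(T = 1, t_inner = 3, t_root = 8) {
  t_n2 <- t_inner + T
  stopifnot(t_inner > 1, t_root > t_n2)
  sprintf(paste0("(Muscovy:%g,((Steamer1:1,Steamer2:1):%g,",
                 "((Baikal:1,Shoveler:1):%g,Pekin:%g):%g):%g);"),
          t_root, t_n2 - 1, t_inner - 1, t_inner, T, t_root - t_n2)
}

#' Simulation configuration
#'
#' Bundles the species tree (coalescent units), the introgression pulse, the
#' genome layout, the mutation scale and the seed. Defaults state a realistic
#' heavy-ILS system: focal internal branch T = 1 (12.3% of gene trees for each
#' discordant resolution without gene flow), a pulse from the steamer-duck
#' clade into Pekin at time 2 with proportion gamma = 0.3, 10-kb windows, and
#' a mutation scale theta = 0.002 substitutions/site per coalescent unit
#' (a few percent divergence at the root, typical of congeneric waterfowl).
#'
#' @param species_tree Newick string with ultrametric branch lengths in
#'   coalescent units.
#' @param pulse List: `donor` (character vector; its MRCA's population
#'   receives the rerouted lineage), `recipient` (leaf label), `time`
#'   (coalescent units), `gamma` (proportion in \[0,1\]), and optionally
#'   `planted_span` (forced-coalescence span for planted runs, default 0.2).
#' @param layout List: `n_chrom`, `windows_per_chrom`, `window_size` (bp),
#'   `mean_run` (geometric mean number of consecutive windows sharing one
#'   gene tree), `n_genes`, `gene_size`, and optionally `planted`, a
#'   data.frame with columns chrom, start_window (1-based ordinal within the
#'   chromosome), length — deliberately planted forced-pulse runs with
#'   reduced recipient-donor coalescence times.
#' @param theta Substitutions/site per coalescent unit for sequence evolution.
#' @param seed Integer seed, or `NULL` to use the caller's RNG state.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(species_tree = duck_species_tree(),
                       pulse = list(donor = c("Steamer1", "Steamer2"),
                                    recipient = "Pekin",
                                    time = 2, gamma = 0.3),
                       layout = list(n_chrom = 2, windows_per_chrom = 500,
                                     window_size = 10000, mean_run = 2,
                                     n_genes = 100, gene_size = 20000,
                                     planted = NULL),
                       theta = 0.002, seed = NULL) {
  tr <- parse_newick(species_tree)
  model <- .compile_model(tr)
  defaults <- list(n_chrom = 2, windows_per_chrom = 500, window_size = 10000,
                   mean_run = 2, n_genes = 100, gene_size = 20000,
                   planted = NULL)
  layout <- utils::modifyList(defaults, layout)
  if (is.null(pulse$planted_span)) pulse$planted_span <- 0.2
  if (is.null(pulse$gamma)) pulse$gamma <- 0
  stopifnot(pulse$gamma >= 0, pulse$gamma <= 1, layout$mean_run >= 1)
  ## resolve donor population and validate pulse timing
  if (pulse$gamma > 0 || !is.null(layout$planted)) {
    donor_node <- mrca_node(tr, pulse$donor)
    recip_tip <- match(pulse$recipient, tr$tip.label)
    if (is.na(recip_tip)) stop("pulse recipient not in species tree")
    t_donor <- model$time[donor_node]
    t_donor_end <- model$pop_end[donor_node]
    t_recip_join <- model$time[model$parent[recip_tip]]
    if (!(pulse$time > t_donor && pulse$time < t_donor_end))
      stop("pulse time must fall inside the donor population's branch (",
           t_donor, ", ", t_donor_end, ")")
    if (pulse$time >= t_recip_join)
      stop("pulse time must be younger than the recipient's first species",
           " join at ", t_recip_join)
    ## planted runs reroute earlier (reduced recipient-donor distance):
    ## default halfway between the donor clade's MRCA and the pulse time
    if (is.null(pulse$planted_time))
      pulse$planted_time <- (t_donor + pulse$time) / 2
    if (!(pulse$planted_time > t_donor && pulse$planted_time < t_recip_join))
      stop("planted_time must lie between the donor MRCA (", t_donor,
           ") and the recipient's first species join (", t_recip_join, ")")
    for (tt in c(pulse$time, pulse$planted_time)) {
      nxt <- min(model$time[model$time > tt &
                              seq_along(model$time) > model$ntip])
      if (tt + pulse$planted_span > nxt)
        stop("planted_span from time ", tt,
             " crosses the next species event at ", nxt)
    }
    pulse$donor_node <- donor_node
    pulse$recipient_tip <- recip_tip
  }
  structure(list(species_tree = species_tree, tree = tr, model = model,
                 pulse = pulse, layout = layout, theta = theta, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$model$ntip, "taxa;",
      "gamma =", x$pulse$gamma, "at t =", x$pulse$time, "\n")
  cat("  layout:", x$layout$n_chrom, "chrom x", x$layout$windows_per_chrom,
      "windows of", x$layout$window_size, "bp; mean run",
      x$layout$mean_run, "\n")
  invisible(x)
}

## species-tree model: node times, parent links, populations.  Population i
## is the species-tree branch above node i; the root population extends to
## infinity.
.compile_model <- function(tree) {
  nt <- ape::Ntip(tree)
  N <- nt + tree$Nnode
  parent <- integer(N)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  depth <- ape::node.depth.edgelength(tree)
  tim <- max(depth[seq_len(nt)]) - depth
  if (any(abs(tim[seq_len(nt)]) > 1e-8))
    stop("species tree must be ultrametric (branch lengths in coalescent",
         " units, all leaves at time 0)")
  pop_end <- ifelse(parent == 0L, Inf, tim[parent])
  kids <- vector("list", N)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  internal <- (nt + 1L):N
  ev <- internal[order(tim[internal])]
  list(ntip = nt, N = N, parent = parent, time = tim, pop_end = pop_end,
       children = kids, events = ev, labels = tree$tip.label)
}

## one gene tree under the MSC + pulse.  Returns a light tree: parent/time
## over 2n-1 nodes (tips 1..n at time 0, internals in merge order) plus a
## provenance flag.
.sim_gene_tree <- function(model, pulse, force_pulse = NA,
                           pulse_coal_span = NULL) {
  nt <- model$ntip
  n_nodes <- 2L * nt - 1L
  gpar <- integer(n_nodes)
  gtime <- numeric(n_nodes)
  lin_pop <- integer(n_nodes)
  lin_pop[seq_len(nt)] <- seq_len(nt)
  active <- seq_len(nt)
  nxt <- nt + 1L
  has_pulse <- !is.null(pulse$donor_node)
  do_pulse <- if (!has_pulse) FALSE
    else if (!is.na(force_pulse)) force_pulse
    else (pulse$gamma > 0 && runif(1) < pulse$gamma)
  recip <- if (has_pulse) pulse$recipient_tip else 0L
  ## event schedule: species joins plus (optionally) the pulse
  ev_t <- model$time[model$events]
  ev_node <- model$events
  if (do_pulse) {
    ins <- findInterval(pulse$time, ev_t)
    ev_t <- append(ev_t, pulse$time, after = ins)
    ev_node <- append(ev_node, 0L, after = ins)  # 0 marks the pulse
  }
  cur <- 0
  merge2 <- function(i, j, at) {
    gpar[i] <<- nxt; gpar[j] <<- nxt
    gtime[nxt] <<- at
    lin_pop[nxt] <<- lin_pop[i]
    active <<- c(active[active != i & active != j], nxt)
    if (recip == i || recip == j) recip <<- nxt
    nxt <<- nxt + 1L
  }
  n_ev <- length(ev_t)
  N_sp <- length(model$parent)
  for (e in seq_len(n_ev + 1L)) {
    t_next <- if (e <= n_ev) ev_t[e] else Inf
    ## within-interval coalescence
    repeat {
      if (length(active) <= 1L) break
      pops <- lin_pop[active]
      cnt <- tabulate(pops, nbins = N_sp)
      which2 <- which(cnt >= 2L)
      if (!length(which2)) break
      k <- cnt[which2]
      rates <- k * (k - 1) / 2
      total <- sum(rates)
      w <- rexp(1L, total)
      if (cur + w >= t_next) break
      cur <- cur + w
      pop_sel <- if (length(which2) == 1L) which2 else
        which2[sample.int(length(which2), 1L, prob = rates)]
      cand <- active[pops == pop_sel]
      pair <- cand[sample.int(length(cand), 2L)]
      merge2(pair[1L], pair[2L], cur)
    }
    if (length(active) == 1L) break
    if (t_next == Inf) break
    cur <- t_next
    v <- ev_node[e]
    if (v == 0L) {
      ## introgression pulse: reroute the recipient-bearing lineage
      lin_pop[recip] <- pulse$donor_node
      if (!is.null(pulse_coal_span)) {
        ## planted device: donor-internal lineages coalesce first (keeping
        ## the donor clade monophyletic), then the recipient joins their
        ## ancestor, all within the compression span
        others <- setdiff(active[lin_pop[active] == pulse$donor_node], recip)
        if (length(others)) {
          us <- sort(runif(length(others), 0, pulse_coal_span))
          anc <- others[1L]
          if (length(others) > 1L) for (k in 2L:length(others)) {
            merge2(anc, others[k], cur + us[k - 1L])
            anc <- nxt - 1L
          }
          at <- cur + us[length(us)]
          merge2(recip, anc, at)
          cur <- at
        }
      }
    } else {
      ch <- model$children[[v]]
      sel <- lin_pop[active] %in% ch
      if (any(sel)) lin_pop[active[sel]] <- v
    }
  }
  list(parent = gpar, time = gtime, labels = model$labels,
       provenance = if (do_pulse) "pulse" else "species")
}

#' Simulate one gene tree under the MSC with introgression pulse
#'
#' With probability `gamma` the recipient lineage is rerouted into the donor
#' population at the pulse time; otherwise the gene genealogy follows the
#' species tree. Coalescence within every population is the standard
#' exponential with rate `choose(k, 2)`. Branch lengths are in coalescent
#' units.
#'
#' @param cfg A [sim_config()].
#' @return A rooted `phylo` with attribute `provenance` (`"pulse"` or
#'   `"species"`).
#' @export
simulate_gene_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lt <- .sim_gene_tree(cfg$model, cfg$pulse)
  ph <- .light_to_phylo(lt)
  attr(ph, "provenance") <- lt$provenance
  ph
}

#' Simulate a set of gene trees
#'
#' Bulk interface retaining the fast internal representation; use
#' [gene_tree_phylo()] to extract individual `phylo` objects and
#' [classify_gene_trees()] to classify all trees.
#'
#' @param n Number of gene trees.
#' @param cfg A [sim_config()].
#' @param force_pulse `NA` (use `gamma`), or `TRUE`/`FALSE` to condition on
#'   the pulse happening / not happening.
#' @param pulse_coal_span If non-`NULL`, forces the rerouted recipient
#'   lineage to coalesce with a donor lineage within this many coalescent
#'   units of the pulse time (the planted reduced-distance device).
#' @return A `gene_tree_set`: list with elements `trees` (list of light
#'   trees) and `provenance` (character vector).
#' @export
simulate_gene_trees <- function(n, cfg, force_pulse = NA,
                                pulse_coal_span = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  trees <- vector("list", n)
  for (i in seq_len(n))
    trees[[i]] <- .sim_gene_tree(cfg$model, cfg$pulse, force_pulse,
                                 pulse_coal_span)
  structure(list(trees = trees,
                 provenance = vapply(trees, `[[`, character(1), "provenance")),
            class = "gene_tree_set")
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("gene_tree_set:", length(x$trees), "trees;",
      sum(x$provenance == "pulse"), "pulse-derived\n")
  invisible(x)
}

## light tree -> phylo, edges emitted in preorder (cladewise)
.light_to_phylo <- function(lt) {
  nt <- (length(lt$parent) + 1L) %/% 2L
  N <- 2L * nt - 1L
  kids <- vector("list", N)
  root <- 0L
  for (i in seq_len(N)) {
    p <- lt$parent[i]
    if (p == 0L) root <- i else kids[[p]] <- c(kids[[p]], i)
  }
  ## preorder numbering: tips keep 1..nt, internals renumbered from nt+1
  newid <- integer(N)
  n_int <- 0L
  edges <- matrix(0L, N - 1L, 2L)
  elen <- numeric(N - 1L)
  k <- 0L
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node > nt) {
      n_int <- n_int + 1L
      newid[node] <- nt + n_int
    } else newid[node] <- node
    if (lt$parent[node] != 0L) {
      k <- k + 1L
      edges[k, ] <- c(newid[lt$parent[node]], newid[node])
      elen[k] <- lt$time[lt$parent[node]] - lt$time[node]
    }
    if (node > nt) stack <- c(stack, rev(kids[[node]]))
  }
  structure(list(edge = edges, edge.length = elen, Nnode = nt - 1L,
                 tip.label = lt$labels),
            class = "phylo", order = "cladewise")
}

#' Extract one gene tree as a phylo object
#'
#' @param set A `gene_tree_set` (or `synthetic_dataset`).
#' @param i Tree index.
#' @return A rooted `phylo` with `provenance` attribute.
#' @export
gene_tree_phylo <- function(set, i) {
  lt <- set$trees[[i]]
  ph <- .light_to_phylo(lt)
  attr(ph, "provenance") <- lt$provenance
  ph
}

## ---------------------------------------------------------------------------
## fast rooted-at-outgroup canonicalisation and distances on light trees

## canonical string of a light tree rerooted on the outgroup tip (all taxa
## focal); mirrors canonical_id(prune-free case) and is cross-checked against
## it in the tests
.lt_canonical <- function(lt, outgroup) {
  nt <- (length(lt$parent) + 1L) %/% 2L
  og <- match(outgroup, lt$labels)
  adj <- .lt_adjacency(lt, nt)
  rec <- function(node, from) {
    nb <- setdiff(adj[[node]], from)
    if (node <= nt) return(list(str = lt$labels[node], min = lt$labels[node]))
    if (length(nb) == 1L) return(rec(nb, node))  # suppressed degree-2 node
    parts <- lapply(nb, rec, from = node)
    mins <- vapply(parts, `[[`, character(1), "min")
    o <- order(mins, method = "radix")
    list(str = paste0("(", paste(vapply(parts[o], `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = mins[o[1L]])
  }
  inner <- rec(adj[[og]][1L], og)
  oglab <- lt$labels[og]
  if (inner$min <= oglab) paste0("(", inner$str, ",", oglab, ")")
  else paste0("(", oglab, ",", inner$str, ")")
}

.lt_adjacency <- function(lt, nt) {
  N <- 2L * nt - 1L
  adj <- vector("list", N)
  for (i in seq_len(N)) {
    p <- lt$parent[i]
    if (p != 0L) {
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  adj
}

## patristic distance between two tips of a light tree: 2 * MRCA time
.lt_tip_distance <- function(lt, a, b) {
  ia <- match(a, lt$labels); ib <- match(b, lt$labels)
  anc <- logical(length(lt$parent))
  cur <- ia
  while (cur != 0L) { anc[cur] <- TRUE; cur <- lt$parent[cur] }
  cur <- ib
  while (!anc[cur]) cur <- lt$parent[cur]
  2 * lt$time[cur]
}

#' Classify all trees of a gene tree set
#'
#' Fast canonical classification (all taxa focal, rooted on the outgroup);
#' equivalent to applying [canonical_id()] tree by tree.
#'
#' @param set A `gene_tree_set` or `synthetic_dataset`.
#' @param taxa A [taxon_set()] covering all simulated taxa.
#' @return Character vector of canonical strings.
#' @export
classify_gene_trees <- function(set, taxa) {
  stopifnot(inherits(taxa, "taxon_set"))
  og <- outgroup_of(taxa)
  if (!setequal(as.character(taxa), set$trees[[1L]]$labels))
    stop("taxon set must match the simulated taxa; prune via canonical_id",
         " on gene_tree_phylo() for partial focal sets")
  vapply(set$trees, .lt_canonical, character(1), outgroup = og)
}

#' Mean patristic distance from a focal taxon to a set of taxa
#'
#' Per-tree average of the tip-to-tip patristic distances (coalescent units)
#' between `from` and each member of `to` — e.g. Pekin to the two steamer
#' ducks.
#'
#' @param set A `gene_tree_set` or `synthetic_dataset`.
#' @param from A leaf label.
#' @param to Character vector of leaf labels.
#' @return Numeric vector, one value per tree.
#' @export
tip_distance_track <- function(set, from, to) {
  vapply(set$trees, function(lt)
    mean(vapply(to, function(b) .lt_tip_distance(lt, from, b), numeric(1))),
    numeric(1))
}

## ---------------------------------------------------------------------------
## genome layout

#' Lay out a synthetic genome of linked window trees
#'
#' Tiles each chromosome with fixed-size windows and assigns gene trees in
#' runs: a run length is drawn from a geometric distribution with the
#' configured mean, one gene tree is simulated, and all windows of the run
#' share it — the memoryless stand-in for linkage. Planted runs (from
#' `cfg$layout$planted`) are filled with forced-pulse gene trees whose
#' recipient-donor coalescence is compressed to `pulse$planted_span`,
#' producing deliberately long, deliberately low-distance introgressed blocks
#' recorded in the truth set.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_dataset`: list with `windows` (data.frame: chrom,
#'   start, end, window_id, tree_id, provenance, planted), `trees` (list of
#'   light gene trees), `genes` (data.frame BED), `truth` (data.frame of
#'   planted runs with genomic spans), and `config`.
#' @export
layout_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lay <- cfg$layout
  wpc <- rep_len(lay$windows_per_chrom, lay$n_chrom)
  chroms <- paste0("chr", seq_len(lay$n_chrom))
  trees <- list()
  rows <- vector("list", lay$n_chrom)
  truth <- list()
  for (ci in seq_len(lay$n_chrom)) {
    W <- wpc[ci]
    tree_id <- integer(W)
    planted_flag <- logical(W)
    plant <- lay$planted
    plant_here <- if (is.null(plant)) NULL else
      plant[plant$chrom == chroms[ci], , drop = FALSE]
    plant_start <- if (is.null(plant_here) || !nrow(plant_here)) integer(0)
      else plant_here$start_window
    pos <- 1L
    while (pos <= W) {
      pi <- match(pos, plant_start)
      if (!is.na(pi)) {
        len <- plant_here$length[pi]
        shared <- if ("shared" %in% names(plant_here))
          isTRUE(plant_here$shared[pi]) else TRUE
        compress <- if ("compress" %in% names(plant_here))
          isTRUE(plant_here$compress[pi]) else shared
        idx <- pos:(min(W, pos + len - 1L))
        ## compressed planting reroutes at the earlier planted_time with the
        ## forced-coalescence span (low recipient-donor distance); the shift
        ## type keeps ordinary pulse timing and free coalescence
        pp <- cfg$pulse
        span <- NULL
        if (compress) {
          pp$time <- pp$planted_time
          span <- pp$planted_span
        }
        if (shared) {
          ## one forced-pulse tree shared by the whole run: a genuine
          ## topology run
          lt <- .sim_gene_tree(cfg$model, pp, force_pulse = TRUE,
                               pulse_coal_span = span)
          trees[[length(trees) + 1L]] <- lt
          tree_id[idx] <- length(trees)
        } else {
          ## independent forced-pulse trees per window: a contiguous
          ## introgressed stretch (the permutation-test target)
          for (k in idx) {
            lt <- .sim_gene_tree(cfg$model, pp, force_pulse = TRUE,
                                 pulse_coal_span = span)
            trees[[length(trees) + 1L]] <- lt
            tree_id[k] <- length(trees)
          }
        }
        planted_flag[idx] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chroms[ci],
          start = (pos - 1L) * lay$window_size,
          end = min(W, pos + len - 1L) * lay$window_size,
          start_window = pos, length = length(idx),
          type = if (compress) "region" else "shift",
          stringsAsFactors = FALSE)
        pos <- pos + length(idx)
      } else {
        len <- rgeom(1, 1 / lay$mean_run) + 1L
        ## truncate at chromosome end and at the next planted run
        nxt_plant <- plant_start[plant_start > pos]
        lim <- min(W, if (length(nxt_plant)) min(nxt_plant) - 1L else W)
        len <- min(len, lim - pos + 1L)
        lt <- .sim_gene_tree(cfg$model, cfg$pulse)
        trees[[length(trees) + 1L]] <- lt
        tree_id[pos:(pos + len - 1L)] <- length(trees)
        pos <- pos + len
      }
    }
    rows[[ci]] <- data.frame(
      chrom = chroms[ci],
      start = (seq_len(W) - 1L) * lay$window_size,
      end = seq_len(W) * lay$window_size,
      tree_id = tree_id, planted = planted_flag,
      stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, rows)
  windows$window_id <- seq_len(nrow(windows))
  windows$provenance <- vapply(trees, `[[`, character(1),
                               "provenance")[windows$tree_id]
  ## random gene annotation
  genes <- do.call(rbind, lapply(seq_len(lay$n_chrom), function(ci) {
    L <- wpc[ci] * lay$window_size
    ng <- max(1L, round(lay$n_genes * wpc[ci] / sum(wpc)))
    st <- sort(sample.int(max(1L, L - lay$gene_size), ng))
    data.frame(chrom = chroms[ci], start = st,
               end = pmin(L, st + lay$gene_size),
               name = sprintf("%s_g%03d", chroms[ci], seq_len(ng)),
               stringsAsFactors = FALSE)
  }))
  structure(list(windows = windows, trees = trees, genes = genes,
                 truth = if (length(truth)) do.call(rbind, truth) else NULL,
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$windows), "windows on",
      length(unique(x$windows$chrom)), "chromosomes;",
      length(x$trees), "gene trees;",
      sum(x$windows$provenance == "pulse"), "pulse windows",
      if (!is.null(x$truth)) paste0("(", sum(x$windows$planted), " planted)"),
      "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## sequence evolution and site patterns

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' A uniform-random root sequence evolves down the tree; each branch receives
#' `Poisson(length * branch_length * theta)` substitutions at uniform
#' positions, each to one of the three alternative bases. Repeated hits at
#' one site within a single branch collapse to one change.
#'
#' @param tree A rooted `phylo` with branch lengths (coalescent units), or a
#'   light tree from the simulator.
#' @param length Sequence length in bp.
#' @param theta Substitutions/site per unit branch length.
#' @return Character matrix (rows = taxa, cols = positions) over A/C/G/T.
#' @export
evolve_sequences <- function(tree, length, theta = 0.002) {
  if (!inherits(tree, "phylo")) tree <- .light_to_phylo(tree)
  seqs <- .evolve_int(tree, length, theta)
  nt <- nrow(seqs)
  out <- matrix("", nt, length, dimnames = dimnames(seqs))
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nt)) out[i, ] <- bases[seqs[i, ]]
  out
}

## integer core: tips x length matrix with bases coded 1..4 (A,C,G,T)
.evolve_int <- function(tree, length, theta) {
  stopifnot(length > 0)
  if (is.null(attr(tree, "order")) || attr(tree, "order") != "cladewise")
    tree <- ape::reorder.phylo(tree, "cladewise")
  nt <- ape::Ntip(tree)
  N <- nt + tree$Nnode
  seqs <- vector("list", N)
  root <- nt + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; child <- tree$edge[i, 2L]
    s <- seqs[[par]]
    nm <- rpois(1, length * tree$edge.length[i] * theta)
    if (nm > 0) {
      pos <- sample.int(length, min(nm, length), replace = TRUE)
      s[pos] <- ((s[pos] - 1L + sample.int(3L, length(pos),
                                           replace = TRUE)) %% 4L) + 1L
    }
    seqs[[child]] <- s
  }
  out <- matrix(0L, nt, length, dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(nt)) out[i, ] <- seqs[[i]]
  out
}

#' Emit ABBA/BABA site-pattern counts from a synthetic dataset
#'
#' For every retained window, evolves sequences on the window's gene tree
#' pruned to the ordered quartet (P1, P2, P3, Outgroup), counts biallelic
#' ABBA and BABA columns with the outgroup allele taken as ancestral, and
#' aggregates counts into genomic blocks.
#'
#' @param dataset A `synthetic_dataset`.
#' @param quartet Ordered character vector (P1, P2, P3, Outgroup).
#' @param block_bp Block size in bp for the jackknife blocks (default 5e5).
#' @param seq_length Per-window sequence length (default: the window size).
#' @return A data.frame with columns `block`, `chrom`, `block_start`, `abba`,
#'   `baba` suitable for [d_statistic()].
#' @export
emit_site_patterns <- function(dataset, quartet, block_bp = 5e5,
                               seq_length = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"), length(quartet) == 4L)
  labs <- dataset$trees[[1L]]$labels
  miss <- setdiff(quartet, labs)
  if (length(miss))
    stop("quartet taxa missing from dataset: ", paste(miss, collapse = ", "))
  w <- dataset$windows
  if (is.null(seq_length)) seq_length <- dataset$config$layout$window_size
  theta <- dataset$config$theta
  abba <- baba <- numeric(nrow(w))
  ## windows in a run share their gene tree: cache the pruned quartet tree
  pruned <- vector("list", length(dataset$trees))
  for (i in seq_len(nrow(w))) {
    ti <- w$tree_id[i]
    if (is.null(pruned[[ti]])) {
      ph <- .light_to_phylo(dataset$trees[[ti]])
      pruned[[ti]] <- ape::keep.tip(ph, quartet)
    }
    sq <- .evolve_int(pruned[[ti]], seq_length, theta)
    p1 <- sq[quartet[1L], ]; p2 <- sq[quartet[2L], ]
    p3 <- sq[quartet[3L], ]; og <- sq[quartet[4L], ]
    abba[i] <- sum(p1 == og & p3 != og & p2 == p3)
    baba[i] <- sum(p2 == og & p3 != og & p1 == p3)
  }
  blk <- paste0(w$chrom, ":", (w$start %/% block_bp))
  agg <- stats::aggregate(cbind(abba, baba) ~ blk, FUN = sum)
  first <- !duplicated(blk)
  ord <- match(agg$blk, blk[first])
  data.frame(block = agg$blk,
             chrom = w$chrom[first][ord],
             block_start = (w$start[first] %/% block_bp * block_bp)[ord],
             abba = agg$abba, baba = agg$baba,
             stringsAsFactors = FALSE)
}
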