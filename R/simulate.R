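# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed, so fixed seeds give byte-identical outputs.

#' Parameters for the trio beta-matrix simulator
#'
#' The defaults describe the reference simulation used throughout the
#' package: 13 trios (39 samples), 20,000 probes over 2,000 genes, a
#' background beta-value mixture of Beta(0.5, 10) and Beta(10, 0.5) with
#' equal weight (emulating the bimodal marginal of methylation arrays —
#' most CpGs sit near fully unmethylated or fully methylated), and 0.2% of
#' probes planted as trio-differential with the affected pair drawn from
#' `[0.85, 1]` and the unaffected parent from `[0, 0.15]` (or mirrored).
#' The mixture component is drawn once per probe and shared by all samples
#' of that probe: a CpG has a characteristic methylation state, so family
#' members agree at background probes and the trio rule fires there only
#' with vanishing probability.
#'
#' @param n_trios Number of trios (3 samples each).
#' @param n_probes Number of CpG probes.
#' @param n_genes Number of genes in the simulated manifest.
#' @param planted_fraction Fraction of probes planted as trio-differential
#'   (the same probes in every trio, so the family pool is exercised).
#' @param mixture List with `shape_low`, `shape_high` (Beta shape pairs)
#'   and `weight` (probability of the low component).
#' @param band_high,band_low Planted hyper- and hypo-methylated bands; must
#'   respect the 0.8/0.2 state cutoffs.
#' @param seed RNG seed.
#' @return Validated parameter list of class `trio_sim_params`.
#' @export
trio_sim_params <- function(n_trios = 13, n_probes = 20000, n_genes = 2000,
                            planted_fraction = 0.002,
                            mixture = list(shape_low = c(0.5, 10),
                                           shape_high = c(10, 0.5),
                                           weight = 0.5),
                            band_high = c(0.85, 1), band_low = c(0, 0.15),
                            seed = 1L) {
  stopifnot(n_trios >= 1, n_probes >= 1, n_genes >= 1)
  if (planted_fraction < 0 || planted_fraction >= 1)
    stop2("planted_fraction must be in [0, 1)")
  if (mixture$weight <= 0 || mixture$weight >= 1)
    stop2("mixture weight must be in (0, 1)")
  if (band_high[1] < 0.8 || band_high[2] > 1 || band_high[1] >= band_high[2])
    stop2("band_high must lie inside the hyper band [0.8, 1]")
  if (band_low[1] < 0 || band_low[2] > 0.2 || band_low[1] >= band_low[2])
    stop2("band_low must lie inside the hypo band [0, 0.2]")
  structure(list(n_trios = n_trios, n_probes = n_probes, n_genes = n_genes,
                 planted_fraction = planted_fraction, mixture = mixture,
                 band_high = band_high, band_low = band_low,
                 seed = as.integer(seed)),
            class = "trio_sim_params")
}

#' Parameters for the PPI-network and pathway simulator
#'
#' @param n_genes Universe size (should match the manifest's gene count).
#' @param edge_probability Erdos-Renyi background edge probability
#'   (default 0.003, mean degree about 6 at 2,000 genes).
#' @param planted_module_size Number of planted genes wired into a clique.
#' @param n_decoy_pathways Number of random decoy pathways (default 20).
#' @param seed RNG seed.
#' @return Validated parameter list of class `network_sim_params`.
#' @export
network_sim_params <- function(n_genes = 2000, edge_probability = 0.003,
                               planted_module_size = 40,
                               n_decoy_pathways = 20, seed = 1L) {
  if (edge_probability < 0 || edge_probability >= 1)
    stop2("edge_probability must be in [0, 1)")
  if (planted_module_size > n_genes)
    stop2("planted_module_size cannot exceed n_genes")
  structure(list(n_genes = n_genes, edge_probability = edge_probability,
                 planted_module_size = planted_module_size,
                 n_decoy_pathways = n_decoy_pathways, seed = as.integer(seed)),
            class = "network_sim_params")
}

#' Simulate a 450K-style probe manifest
#'
#' Probes are assigned to genes round-robin; region groups are drawn so
#' that about `promoter_fraction` of probe-gene links fall in the
#' TSS200/TSS1500 promoter blocks and about `island_fraction` of probes lie
#' in CpG islands. A handful of `rs`-named control probes and X/Y probes
#' are included so the standard probe filters have something to remove;
#' these carry no gene annotation.
#'
#' @param n_probes,n_genes Counts.
#' @param promoter_fraction Expected fraction of promoter-region links.
#' @param island_fraction Expected fraction of Island probes.
#' @param n_rs_probes,n_sex_probes Filter-fodder probe counts (defaults 5
#'   and 10).
#' @param seed RNG seed.
#' @return Probe annotation `data.frame` (see [probe_annotation()]).
#' @export
simulate_manifest <- function(n_probes, n_genes, promoter_fraction = 0.3,
                              island_fraction = 0.3, n_rs_probes = 5,
                              n_sex_probes = 10, seed = 1L) {
  if (n_genes == 0 && n_probes > 0) stop2("n_genes must be positive")
  stopifnot(promoter_fraction >= 0, promoter_fraction <= 1,
            island_fraction >= 0, island_fraction <= 1)
  set.seed(seed)
  n_cg <- n_probes - n_rs_probes - n_sex_probes
  if (n_cg < 0) stop2("n_probes too small for the requested rs/sex probes")

  probe_id <- c(sprintf("cg%08d", seq_len(n_cg)),
                sprintf("cg%08d", n_cg + seq_len(n_sex_probes)),
                sprintf("rs%07d", seq_len(n_rs_probes)))
  genes <- sprintf("GENE%05d", seq_len(n_genes))

  chrom <- c(as.character(rep_len(1:22, n_cg)),
             rep_len(c("X", "Y"), n_sex_probes),
             as.character(rep_len(1:22, n_rs_probes)))

  gene_of <- c(genes[(seq_len(n_cg) - 1L) %% n_genes + 1L],
               rep("", n_sex_probes + n_rs_probes))
  promoter <- stats::runif(n_probes) < promoter_fraction
  grp <- ifelse(promoter,
                sample(PROMOTER_GROUPS, n_probes, replace = TRUE),
                sample(setdiff(REGION_GROUPS, PROMOTER_GROUPS), n_probes,
                       replace = TRUE))
  grp[gene_of == ""] <- ""

  isl <- ifelse(stats::runif(n_probes) < island_fraction, "Island",
                sample(setdiff(ISLAND_RELATIONS, "Island"), n_probes,
                       replace = TRUE))
  probe_annotation(probe_id, chrom, gene_of, grp, isl)
}

#' @noRd
trio_sample_sheet <- function(n_trios) {
  trio_id <- sprintf("trio%02d", seq_len(n_trios))
  data.frame(trio_id = trio_id,
             child = paste0(trio_id, "_C"),
             affected_parent = paste0(trio_id, "_PA"),
             unaffected_parent = paste0(trio_id, "_PU"),
             stringsAsFactors = FALSE)
}

#' Simulate trio beta matrices with planted differential events
#'
#' Background betas: each probe draws a mixture component (low/high) once,
#' and every sample's value at that probe is drawn i.i.d. from the
#' component's Beta distribution — within-probe consistency, as on real
#' arrays. Planted events: `planted_fraction` of the autosomal, annotated
#' probes (one probe per planted gene, preferring promoter-region links so
#' the promoter-scope pipeline is exercised) are overwritten in every trio
#' with the child and affected parent uniform in one band and the
#' unaffected parent uniform in the opposite band; the direction alternates
#' across planted probes. The truth ledger records the planted events, the
#' planted gene set, and — via a post-hoc scan of the background probes with
#' the trio rule — any chance qualifiers.
#'
#' @param params [trio_sim_params()] object.
#' @param manifest Probe annotation, e.g. from [simulate_manifest()]; must
#'   contain at least `n_probes` rows matching the params.
#'
#' @return List with `beta` (matrix), `trios` (sample sheet), and `truth`:
#'   `dm_events` (`data.frame` probe_id/trio_id/direction/gene),
#'   `planted_genes`, `background_qualifiers` (same columns as
#'   `dm_events`, gene-free).
#' @export
simulate_trio_betas <- function(params, manifest) {
  stopifnot(inherits(params, "trio_sim_params"))
  if (nrow(manifest) != params$n_probes)
    stop2("manifest row count does not match params$n_probes")
  set.seed(params$seed)
  n_probes <- params$n_probes
  trios <- trio_sample_sheet(params$n_trios)
  samples <- as.vector(rbind(trios$child, trios$affected_parent,
                             trios$unaffected_parent))
  n_samp <- length(samples)

  comp_low <- stats::runif(n_probes) < params$mixture$weight
  bm <- matrix(NA_real_, n_probes, n_samp,
               dimnames = list(manifest$probe_id, samples))
  n_low <- sum(comp_low)
  sl <- params$mixture$shape_low; sh <- params$mixture$shape_high
  if (n_low)
    bm[comp_low, ] <- stats::rbeta(n_low * n_samp, sl[1], sl[2])
  if (n_low < n_probes)
    bm[!comp_low, ] <- stats::rbeta((n_probes - n_low) * n_samp, sh[1], sh[2])

  # choose planted probes: one per planted gene, autosomal + annotated,
  # preferring promoter-region links
  n_plant <- round(params$planted_fraction * n_probes)
  planted_probes <- character(0); planted_genes <- character(0)
  if (n_plant > 0) {
    links <- annotation_links(manifest, "genome_wide")
    chr <- manifest$chromosome[match(links$probe_id, manifest$probe_id)]
    links <- links[!chr %in% c("X", "Y") & !startsWith(links$probe_id, "rs"), ,
                   drop = FALSE]
    links$promoter <- links$region_group %in% PROMOTER_GROUPS
    links <- links[order(links$gene, -links$promoter, links$probe_id), ,
                   drop = FALSE]
    links <- links[!duplicated(links$gene), , drop = FALSE]
    if (nrow(links) < n_plant)
      stop2("not enough annotated autosomal genes to plant ", n_plant, " events")
    pick <- links[sample.int(nrow(links), n_plant), , drop = FALSE]
    pick <- pick[order(pick$gene), , drop = FALSE]
    planted_probes <- pick$probe_id
    planted_genes <- pick$gene
  }

  direction <- rep_len(c("affected_hyper", "affected_hypo"), length(planted_probes))
  bh <- params$band_high; bl <- params$band_low
  for (t in seq_len(params$n_trios)) {
    cols <- c(trios$child[t], trios$affected_parent[t], trios$unaffected_parent[t])
    hyp <- direction == "affected_hyper"
    n_h <- sum(hyp); n_l <- sum(!hyp)
    if (n_h) {
      bm[planted_probes[hyp], cols[1:2]] <- stats::runif(2 * n_h, bh[1], bh[2])
      bm[planted_probes[hyp], cols[3]] <- stats::runif(n_h, bl[1], bl[2])
    }
    if (n_l) {
      bm[planted_probes[!hyp], cols[1:2]] <- stats::runif(2 * n_l, bl[1], bl[2])
      bm[planted_probes[!hyp], cols[3]] <- stats::runif(n_l, bh[1], bh[2])
    }
  }

  dm_events <- if (length(planted_probes)) {
    do.call(rbind, lapply(seq_len(params$n_trios), function(t)
      data.frame(probe_id = planted_probes, trio_id = trios$trio_id[t],
                 direction = direction, gene = planted_genes,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(probe_id = character(0), trio_id = character(0),
               direction = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  }

  # post-hoc scan for chance qualifiers among background probes
  bg <- setdiff(manifest$probe_id, planted_probes)
  bgq <- do.call(rbind, lapply(seq_len(params$n_trios), function(t) {
    q <- select_trio_dm_cpgs(bm[bg, , drop = FALSE], trios[t, ])
    q[c("probe_id", "trio_id", "direction")]
  }))

  list(beta = beta_matrix(bm), trios = trios,
       truth = list(dm_events = dm_events,
                    planted_genes = sort(unique(planted_genes)),
                    background_qualifiers = bgq))
}

#' Simulate a PPI network and pathway collection with a planted pathway
#'
#' Background edges follow an Erdos-Renyi graph over the gene universe;
#' the planted genes are additionally wired into a complete clique, giving
#' the subnetwork search a dense module to find. The pathway collection
#' holds one planted pathway (exactly the planted gene set) plus decoy
#' pathways of genes sampled without replacement; a decoy identical to the
#' planted set is redrawn.
#'
#' @param params [network_sim_params()] object.
#' @param universe Character vector of all gene symbols.
#' @param planted_genes Genes to wire into the planted module/pathway;
#'   must be a subset of `universe` with length
#'   `params$planted_module_size`.
#'
#' @return List with `net` (igraph), `pathways` (named list),
#'   `universe`, and `planted_pathway` (its name).
#' @export
simulate_network_pathways <- function(params, universe, planted_genes) {
  stopifnot(inherits(params, "network_sim_params"))
  if (!all(planted_genes %in% universe))
    stop2("planted_genes must be a subset of the universe")
  if (length(planted_genes) != params$planted_module_size)
    stop2("length(planted_genes) must equal params$planted_module_size")
  set.seed(params$seed)

  n <- length(universe)
  g <- igraph::sample_gnp(n, params$edge_probability, directed = FALSE)
  igraph::V(g)$name <- universe
  if (length(planted_genes) >= 2) {
    clique_edges <- t(utils::combn(sort(planted_genes), 2))
    g <- igraph::add_edges(g, t(clique_edges))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  planted_name <- "planted_pathway"
  pw_size <- length(planted_genes)
  pathways <- list()
  pathways[[planted_name]] <- sort(planted_genes)
  for (i in seq_len(params$n_decoy_pathways)) {
    repeat {
      decoy <- sort(sample(universe, pw_size))
      if (!identical(decoy, pathways[[planted_name]])) break
    }
    pathways[[sprintf("decoy_pathway_%02d", i)]] <- decoy
  }
  list(net = g, pathways = pathways, universe = sort(universe),
       planted_pathway = planted_name)
}

#' Simulate a detection p-value matrix
#'
#' Clean measurements draw detection p-values from Uniform(0, 0.01); rows
#' and columns named in `bad_probe_ids` / `bad_sample_ids` draw from
#' Uniform(0.5, 1), so the greedy reliability filter removes exactly them.
#'
#' @param probe_ids,sample_ids Axis identifiers.
#' @param bad_probe_ids,bad_sample_ids Identifiers to contaminate (subsets
#'   of the axes).
#' @param seed RNG seed.
#' @return Numeric matrix of detection p-values.
#' @export
simulate_detection_p <- function(probe_ids, sample_ids,
                                 bad_probe_ids = character(0),
                                 bad_sample_ids = character(0), seed = 1L) {
  if (!all(bad_probe_ids %in% probe_ids) || !all(bad_sample_ids %in% sample_ids))
    stop2("bad ids must be subsets of the matrix axes")
  set.seed(seed)
  dp <- matrix(stats::runif(length(probe_ids) * length(sample_ids), 0, 0.01),
               length(probe_ids), length(sample_ids),
               dimnames = list(probe_ids, sample_ids))
  if (length(bad_probe_ids))
    dp[bad_probe_ids, ] <- stats::runif(length(bad_probe_ids) * ncol(dp), 0.5, 1)
  if (length(bad_sample_ids))
    dp[, bad_sample_ids] <- stats::runif(nrow(dp) * length(bad_sample_ids), 0.5, 1)
  dp
}

#' Write every simulated input to disk in the pipeline's file formats
#'
#' Emits beta TSV, manifest CSV, trio sheet CSV, optional detection-p TSV,
#' edge-list TSV, GMT, universe list, and a truth-ledger TSV.
#'
#' @param sim Output of [simulate_trio_betas()].
#' @param netsim Output of [simulate_network_pathways()].
#' @param manifest Probe annotation used for the simulation.
#' @param dir Output directory (created if needed).
#' @param dp Optional detection p-value matrix.
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated_inputs <- function(sim, netsim, manifest, dir, dp = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             manifest = file.path(dir, "manifest.csv"),
             trios = file.path(dir, "trios.csv"),
             network = file.path(dir, "network.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             universe = file.path(dir, "universe.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_beta_matrix(sim$beta, paths[["beta"]])
  write_manifest(manifest, paths[["manifest"]])
  write_trio_sheet(sim$trios, paths[["trios"]])
  write_edge_list(netsim$net, paths[["network"]])
  write_gmt(netsim$pathways, paths[["gmt"]])
  writeLines(netsim$universe, paths[["universe"]])
  write_tsv_plain(sim$truth$dm_events, paths[["truth"]])
  if (!is.null(dp)) {
    paths <- c(paths, detection_p = file.path(dir, "detection_p.tsv"))
    write_beta_matrix(dp, paths[["detection_p"]])
  }
  invisible(paths)
}
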