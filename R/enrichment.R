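#' Gene z-score from a p-value
#'
#' Upper-tail standard-normal quantile, `z = qnorm(1 - p)`: small p-values
#' map to large positive z.
#'
#' @param p P-value(s) in `(0, 1)`.
#' @return Numeric z-score vector.
#' @examples
#' gene_z(0.05)  # 1.6449
#' @export
gene_z <- function(p) {
  if (any(p <= 0 | p >= 1)) stop2("p must lie strictly inside (0, 1)")
  stats::qnorm(1 - p)
}

#' Aggregate z-score of a gene set
#'
#' `z_A = sum(z) / sqrt(k)` for a set of k gene z-scores: under
#' independence the aggregate of standard normals is again standard normal,
#' so sets of different sizes are comparable.
#'
#' @param zs Numeric vector of gene z-scores, length >= 1.
#' @return The aggregate score (scalar).
#' @export
aggregate_z <- function(zs) {
  k <- length(zs)
  if (k == 0L) stop2("aggregate_z needs at least one z-score")
  sum(zs) / sqrt(k)
}

#' Overlap fraction between two node sets
#'
#' Fraction of the smaller set shared with the other:
#' `|a intersect b| / min(|a|, |b|)`.
#'
#' @param a,b Non-empty character vectors (treated as sets).
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop2("overlap_fraction needs non-empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' @noRd
node_z_scores <- function(net, scores, unscored_p = 1 - 1e-9) {
  nodes <- igraph::V(net)$name
  p <- rep(unscored_p, length(nodes))
  names(p) <- nodes
  hit <- intersect(nodes, names(scores))
  p[hit] <- pmin(pmax(scores[hit], 1e-300), unscored_p)
  gene_z(p)
}

#' Greedy search for active subnetworks
#'
#' Finds connected subgraphs of a protein-interaction network that
#' concentrate low gene p-values. From each of the `n_seeds` top-scoring
#' genes (descending z, ties by gene symbol), the subnetwork grows by
#' repeatedly adding the neighbouring node that maximises the aggregate
#' score `z_A` (ties by gene symbol), stopping when no addition keeps `z_A`
#' from decreasing or the size cap is reached. Grown candidates are then
#' accepted in descending `z_A` order, skipping any candidate whose overlap
#' with an already accepted subnetwork exceeds `max_overlap`, until
#' `n_subnetworks` are accepted. Genes present in the network but absent
#' from `scores` receive p = 1 (clamped just below 1), so they join a
#' subnetwork only when the topology demands it. The procedure is fully
#' deterministic.
#'
#' @param net `igraph` undirected graph with gene symbols as vertex names.
#' @param scores Named numeric vector: gene -> p-value in `(0, 1]`.
#' @param n_subnetworks Maximum number of accepted subnetworks (default 5).
#' @param max_size Maximum subnetwork size (default 50).
#' @param n_seeds Number of top-scoring seed genes to grow from (default 20).
#' @param max_overlap Maximum pairwise overlap fraction between accepted
#'   subnetworks (default 0.5).
#'
#' @return List of subnetworks, each a list with `members` (character),
#'   `z_a` (numeric), and `seed_gene`. Empty list for an empty network.
#' @export
find_active_subnetworks <- function(net, scores, n_subnetworks = 5,
                                    max_size = 50, n_seeds = 20,
                                    max_overlap = 0.5) {
  if (igraph::vcount(net) == 0L) return(list())
  z <- node_z_scores(net, scores)
  nodes <- names(z)
  seeds <- nodes[order(-z, nodes)][seq_len(min(n_seeds, length(nodes)))]

  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- nodes

  grow <- function(seed) {
    members <- seed
    zsum <- z[[seed]]
    za <- zsum
    frontier <- setdiff(adj[[seed]], members)
    while (length(members) < max_size && length(frontier)) {
      cand_za <- (zsum + z[frontier]) / sqrt(length(members) + 1)
      best_i <- order(-cand_za, frontier)[1L]
      if (cand_za[best_i] < za) break
      best <- frontier[best_i]
      za <- cand_za[best_i]
      zsum <- zsum + z[[best]]
      members <- c(members, best)
      frontier <- setdiff(union(frontier, adj[[best]]), members)
    }
    members <- sort(members)
    # recompute from scratch so the reported z_A is exactly consistent
    # with the member z-scores (no accumulated rounding)
    list(members = members, z_a = aggregate_z(z[members]), seed_gene = seed)
  }

  cands <- lapply(seeds, grow)
  ord <- order(-vapply(cands, `[[`, numeric(1), "z_a"),
               vapply(cands, `[[`, character(1), "seed_gene"))
  cands <- cands[ord]

  accepted <- list()
  for (cand in cands) {
    if (length(accepted) >= n_subnetworks) break
    ok <- all(vapply(accepted, function(a)
      overlap_fraction(a$members, cand$members) <= max_overlap, logical(1)))
    if (ok) accepted[[length(accepted) + 1L]] <- cand
  }
  accepted
}

#' Two-sided hypergeometric enrichment/depletion test
#'
#' Tests whether the overlap between a subnetwork of `subnet_size` genes and
#' a pathway of `pathway_size` genes, drawn from a background universe of
#' `background_size` genes, departs from hypergeometric expectation in
#' either direction. The default two-sided p-value is the minimum-likelihood
#' method: the sum of all hypergeometric point probabilities not exceeding
#' that of the observed overlap. `method = "doubling"` instead doubles the
#' smaller tail (capped at 1).
#'
#' @param overlap Observed number of subnetwork genes in the pathway.
#' @param subnet_size,pathway_size,background_size Set sizes; must satisfy
#'   `overlap <= min(subnet_size, pathway_size)` and
#'   `pathway_size <= background_size`.
#' @param method `"minlik"` (default) or `"doubling"`.
#'
#' @return List with `p` and `direction` (`"enriched"` when the overlap is
#'   at or above expectation `subnet_size * pathway_size / background_size`,
#'   else `"depleted"`).
#' @export
hypergeom_two_sided <- function(overlap, subnet_size, pathway_size,
                                background_size, method = c("minlik", "doubling")) {
  method <- match.arg(method)
  if (overlap < 0 || subnet_size < 0 || pathway_size < 0 || background_size < 1 ||
      overlap > min(subnet_size, pathway_size) ||
      pathway_size > background_size || subnet_size > background_size ||
      overlap < subnet_size + pathway_size - background_size)
    stop2("inconsistent counts for the hypergeometric test")

  support <- max(0L, subnet_size + pathway_size - background_size):min(subnet_size, pathway_size)
  dens <- stats::dhyper(support, pathway_size, background_size - pathway_size,
                        subnet_size)
  d_obs <- dens[support == overlap]
  expectation <- subnet_size * pathway_size / background_size
  direction <- if (overlap >= expectation) "enriched" else "depleted"

  if (method == "minlik") {
    # relative tolerance guards against ties broken by floating-point noise
    p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  } else {
    upper <- sum(dens[support >= overlap])
    lower <- sum(dens[support <= overlap])
    p <- min(1, 2 * min(upper, lower))
  }
  list(p = min(p, 1), direction = direction)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` defaulting to the number of p-values supplied.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values, order-preserving.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Test all pathways against one subnetwork
#'
#' @param members Subnetwork gene set.
#' @param pathways Named list of pathway gene sets.
#' @param universe Background gene universe (character).
#' @param subnetwork_id Identifier recorded in the result rows.
#' @param method Passed to [hypergeom_two_sided()].
#'
#' @return `data.frame` with one row per pathway: `pathway`,
#'   `subnetwork_id`, `overlap`, `subnet_size`, `pathway_size`, `raw_p`,
#'   `bonferroni_p` (m = number of pathways tested for this subnetwork),
#'   `direction`.
#' @export
test_subnetwork_pathways <- function(members, pathways, universe,
                                     subnetwork_id = 1L, method = "minlik") {
  members <- intersect(unique(members), universe)
  n_bg <- length(unique(universe))
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    ov <- length(intersect(members, pw))
    ht <- hypergeom_two_sided(ov, length(members), length(pw), n_bg,
                              method = method)
    data.frame(pathway = nm, subnetwork_id = subnetwork_id, overlap = ov,
               subnet_size = length(members), pathway_size = length(pw),
               raw_p = ht$p, direction = ht$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- bonferroni_adjust(out$raw_p, m = nrow(out))
  out[c("pathway", "subnetwork_id", "overlap", "subnet_size", "pathway_size",
        "raw_p", "bonferroni_p", "direction")]
}

#' Collect significant pathways across subnetworks
#'
#' Keeps pathways whose Bonferroni-adjusted p-value reaches `alpha` in at
#' least one subnetwork; a pathway appearing in several subnetworks is
#' reported once, at its most significant occurrence (ties broken by the
#' lower subnetwork id). Sorted by ascending adjusted p, then pathway name.
#'
#' @param results `data.frame` of pathway test rows (rbind of
#'   [test_subnetwork_pathways()] outputs).
#' @param alpha Significance cutoff on `bonferroni_p` (default 0.05).
#' @return Filtered, de-duplicated, sorted `data.frame`.
#' @export
collect_significant_pathways <- function(results, alpha = 0.05) {
  sig <- results[results$bonferroni_p <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  sig <- sig[order(sig$pathway, sig$bonferroni_p, sig$subnetwork_id), , drop = FALSE]
  sig <- sig[!duplicated(sig$pathway), , drop = FALSE]
  sig <- sig[order(sig$bonferroni_p, sig$pathway), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Run the full enrichment for one gene score list
#'
#' Convenience wrapper: z-scores, greedy subnetwork search, per-subnetwork
#' two-sided hypergeometric pathway tests with Bonferroni correction, and
#' the significant-pathway collection.
#'
#' @param scores Named numeric vector, gene -> p-value.
#' @param net `igraph` protein-interaction network.
#' @param pathways Named list of pathway gene sets.
#' @param universe Background universe; defaults to the union of all
#'   pathway genes.
#' @param alpha Cutoff for [collect_significant_pathways()].
#' @param ... Passed to [find_active_subnetworks()].
#'
#' @return List with `subnetworks`, `all_results` (every pathway x
#'   subnetwork row), and `significant` (collected final list).
#' @export
run_enrichment <- function(scores, net, pathways, universe = NULL,
                           alpha = 0.05, ...) {
  if (is.null(universe)) universe <- sort(unique(unlist(pathways)))
  subs <- find_active_subnetworks(net, scores, ...)
  if (!length(subs))
    return(list(subnetworks = subs,
                all_results = test_subnetwork_pathways(character(0), pathways,
                                                       universe)[0, ],
                significant = NULL))
  res <- do.call(rbind, lapply(seq_along(subs), function(i)
    test_subnetwork_pathways(subs[[i]]$members, pathways, universe,
                             subnetwork_id = i)))
  list(subnetworks = subs, all_results = res,
       significant = collect_significant_pathways(res, alpha = alpha))
}

#' Summarize significant pathways across trios
#'
#' Counts, for every pathway, the number of trios in which it reached
#' significance, and reports the family pool's top pathways by ascending
#' Bonferroni p.
#'
#' @param per_trio Named list: trio id -> significant-pathway `data.frame`
#'   (as from [collect_significant_pathways()]).
#' @param pool Family-pool significant-pathway `data.frame` (optional).
#' @param top_n Size of the pool top list (default 10; shorter lists are
#'   not padded).
#'
#' @return List with `trio_counts` (`data.frame`: `pathway`, `n_trios`,
#'   `min_p`, sorted by descending count then ascending p) and `pool_top`.
#' @export
summarize_across_trios <- function(per_trio, pool = NULL, top_n = 10) {
  rows <- do.call(rbind, lapply(names(per_trio), function(id) {
    df <- per_trio[[id]]
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(trio_id = id, pathway = df$pathway, p = df$bonferroni_p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    counts <- data.frame(pathway = character(0), n_trios = integer(0),
                         min_p = numeric(0), stringsAsFactors = FALSE)
  } else {
    counts <- do.call(rbind, lapply(split(rows, rows$pathway), function(g)
      data.frame(pathway = g$pathway[1], n_trios = length(unique(g$trio_id)),
                 min_p = min(g$p), stringsAsFactors = FALSE)))
    counts <- counts[order(-counts$n_trios, counts$min_p, counts$pathway), , drop = FALSE]
    rownames(counts) <- NULL
  }
  pool_top <- NULL
  if (!is.null(pool) && nrow(pool))
    pool_top <- utils::head(pool[order(pool$bonferroni_p, pool$pathway), ,
                                 drop = FALSE], top_n)
  list(trio_counts = counts, pool_top = pool_top)
}

#' Read an undirected PPI network from a two-column edge list
#'
#' Tab-separated, two gene symbols per line, optional header. Self-loops
#' and duplicate edges are dropped.
#'
#' @param path Edge-list path.
#' @param header Does the file start with a header line (default `FALSE`)?
#' @return Undirected `igraph` graph with named vertices.
#' @export
read_edge_list <- function(path, header = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("edge list needs two columns")
  el <- as.matrix(df[, 1:2])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an edge list TSV
#' @param net `igraph` graph.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  write_tsv_plain(data.frame(gene_a = el[, 1], gene_b = el[, 2],
                             stringsAsFactors = FALSE), path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes.
#'
#' @param path GMT path.
#' @return Named list of character gene sets.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop2("GMT line with fewer than 3 fields: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop2("duplicate pathway names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of gene sets.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
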