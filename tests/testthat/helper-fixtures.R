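# Fixture builders and independent oracles used across the suite.

make_beta <- function(values, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- sprintf("cg%05d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  values
}

tiny_annotation <- function() {
  probe_annotation(
    probe_id = c("cg00001", "cg00002", "cg00003", "cg00004", "rs1234567",
                 "cg00005"),
    chromosome = c("1", "2", "chrX", "7", "3", "11"),
    genes = c("GENE1;GENE2", "GENE2", "GENE3", "", "GENE1", "GENE1"),
    region_groups = c("TSS200;Body", "TSS1500", "Body", "", "Body", "Body"),
    island_relation = c("Island", "N_Shore", "Island", "OpenSea", "OpenSea",
                        "Island"))
}

one_trio <- function(id = "trioA") {
  data.frame(trio_id = id, child = "C1", affected_parent = "PA1",
             unaffected_parent = "PU1", stringsAsFactors = FALSE)
}

# Independent state-based scan of the trio rule: classify each member via
# call_state and combine the three state strings. select_trio_dm_cpgs works
# on raw numeric comparisons and never builds these strings.
oracle_trio_scan <- function(bm, trio, hypo_max = 0.2, hyper_min = 0.8) {
  sC <- call_state(bm[, trio$child], hypo_max, hyper_min)
  sPA <- call_state(bm[, trio$affected_parent], hypo_max, hyper_min)
  sPU <- call_state(bm[, trio$unaffected_parent], hypo_max, hyper_min)
  hyper <- !is.na(sC) & !is.na(sPA) & !is.na(sPU) &
    sC == "hyper" & sPA == "hyper" & sPU == "hypo"
  hypo <- !is.na(sC) & !is.na(sPA) & !is.na(sPU) &
    sC == "hypo" & sPA == "hypo" & sPU == "hyper"
  data.frame(probe_id = rownames(bm)[hyper | hypo],
             direction = ifelse(hyper, "affected_hyper", "affected_hypo")[hyper | hypo],
             stringsAsFactors = FALSE)
}

# Exhaustive two-sided hypergeometric by minimum likelihood, written with
# binomial coefficients only (no dhyper), as the enumeration oracle.
oracle_hypergeom <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  dens <- vapply(support, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1))
  d_obs <- dens[support == k]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

# Exhaustive best connected subset by aggregate z (small graphs only).
oracle_best_connected_za <- function(net, z) {
  nodes <- igraph::V(net)$name
  best <- -Inf
  for (sz in seq_along(nodes)) {
    combs <- utils::combn(nodes, sz, simplify = FALSE)
    for (s in combs) {
      sub <- igraph::induced_subgraph(net, s)
      if (igraph::is_connected(sub)) best <- max(best, sum(z[s]) / sqrt(sz))
    }
  }
  best
}
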