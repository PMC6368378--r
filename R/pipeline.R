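#' Read a pipeline configuration from YAML
#'
#' The configuration lists input paths (`beta`, `manifest`, `trio_sheet`,
#' optionally `detection_p`, `network`, `gmt`, `universe`), thresholds
#' (`hypo_max`, `hyper_min`, `alpha`, `fdr`), the `scope` selection,
#' enrichment parameters (`n_subnetworks`, `max_size`, `n_seeds`,
#' `max_overlap`), `out_dir`, and `seed`. Missing thresholds take the
#' package defaults. Command-style overrides can be supplied as `...`.
#'
#' @param path YAML file path.
#' @param ... Named overrides applied on top of the file's keys.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
}

#' @noRd
validate_pipeline_config <- function(cfg) {
  defaults <- list(hypo_max = 0.2, hyper_min = 0.8, alpha = 0.05, fdr = 0.05,
                   scope = "both", seed = 1L, n_subnetworks = 5, max_size = 50,
                   n_seeds = 20, max_overlap = 0.5, heatmap_k = 1000,
                   dual_tol = 0.05)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (cfg$hypo_max < 0 || cfg$hyper_min > 1 || cfg$hypo_max >= cfg$hyper_min)
    stop2("thresholds must satisfy 0 <= hypo_max < hyper_min <= 1")
  if (!cfg$scope %in% c("genome_wide", "promoter", "both"))
    stop2("scope must be genome_wide, promoter, or both")
  for (k in c("beta", "manifest", "trio_sheet", "network", "gmt",
              "universe", "detection_p")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop2("config input does not exist: ", k, " = ", cfg[[k]])
  }
  cfg
}

#' @noRd
scopes_from_config <- function(cfg) {
  if (cfg$scope == "both") c("genome_wide", "promoter") else cfg$scope
}

#' @noRd
log_line <- function(con, ...) {
  if (!is.null(con)) cat(..., "\n", sep = "", file = con, append = TRUE)
}

#' Run the trio-based differential methylation pipeline
#'
#' Executes, for each requested scope: probe filtering, per-trio CpG
#' selection and TbSSch scoring, gene aggregation, family-pool
#' construction, active-subnetwork pathway enrichment per DMG list, and a
#' cross-trio pathway summary. Writes per-owner DMG lists
#' (`dmg_<owner>_<scope>.tsv`), significant pathway tables
#' (`pathways_<owner>_<scope>.tsv`), a cross-trio summary per scope
#' (`summary_<scope>.tsv`), and a `run_log.txt` recording parameters, seed
#' and stage record counts.
#'
#' @param cfg Config list (see [read_pipeline_config()]); input files are
#'   required except `detection_p` and `universe`.
#' @param enrich Run the enrichment stage (default `TRUE`; set `FALSE` for
#'   a scores-only run when no network/GMT is supplied).
#' @return Invisible list of written file paths plus the in-memory results.
#' @export
run_trio_pipeline <- function(cfg, enrich = TRUE) {
  cfg <- validate_pipeline_config(cfg)
  if (is.null(cfg$out_dir)) stop2("config needs out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  unlink(log_path)
  log_line(log_path, "methtrio trio pipeline | seed=", cfg$seed,
           " hypo_max=", cfg$hypo_max, " hyper_min=", cfg$hyper_min,
           " alpha=", cfg$alpha, " scope=", cfg$scope)

  bm <- read_beta_matrix(cfg$beta)
  ann <- read_manifest(cfg$manifest)
  trios <- read_trio_sheet(cfg$trio_sheet)
  if (nrow(trios) == 0L) stop2("trio sheet has no trios")
  validate_trio_design(trios, colnames(bm))
  dp <- if (!is.null(cfg$detection_p)) read_detection_p(cfg$detection_p)
  log_line(log_path, "inputs: ", nrow(bm), " probes x ", ncol(bm),
           " samples, ", nrow(trios), " trios")

  flt <- filter_probes(bm, ann, dp = dp)
  bm <- flt$beta
  log_line(log_path, "filter: removed ",
           nrow(flt$report$removed_probes), " probes (",
           paste(names(flt$report$counts[1:4]),
                 unlist(flt$report$counts[1:4]), sep = "=", collapse = ", "),
           "), ", length(flt$report$removed_samples), " samples; retained ",
           nrow(bm), " probes")

  net <- pathways <- universe <- NULL
  if (enrich) {
    if (is.null(cfg$network) || is.null(cfg$gmt))
      stop2("enrichment stage needs network and gmt inputs")
    net <- read_edge_list(cfg$network)
    pathways <- read_gmt(cfg$gmt)
    universe <- if (!is.null(cfg$universe)) readLines(cfg$universe)
                else sort(unique(unlist(pathways)))
  }

  paths <- character(0)
  results <- list()
  for (scope in scopes_from_config(cfg)) {
    per_trio_dmg <- lapply(seq_len(nrow(trios)), function(i) {
      cpgs <- select_trio_dm_cpgs(bm, trios[i, ], hypo_max = cfg$hypo_max,
                                  hyper_min = cfg$hyper_min)
      aggregate_to_genes(cpgs, ann, scope = scope, owner = trios$trio_id[i])
    })
    names(per_trio_dmg) <- trios$trio_id
    pool <- build_family_pool(per_trio_dmg)
    all_dmg <- c(per_trio_dmg, list(family_pool = pool))

    for (owner in names(all_dmg)) {
      f <- file.path(cfg$out_dir, sprintf("dmg_%s_%s.tsv", owner, scope))
      write_dmg_list(all_dmg[[owner]], f)
      paths <- c(paths, f)
      log_line(log_path, scope, "/", owner, ": ", nrow(all_dmg[[owner]]), " DMGs")
    }

    sig_lists <- NULL
    if (enrich) {
      enr <- lapply(all_dmg, function(dmg) {
        if (nrow(dmg) == 0L) return(NULL)
        run_enrichment(scores_to_pvalues(dmg), net, pathways,
                       universe = universe, alpha = cfg$alpha,
                       n_subnetworks = cfg$n_subnetworks,
                       max_size = cfg$max_size, n_seeds = cfg$n_seeds,
                       max_overlap = cfg$max_overlap)
      })
      sig_lists <- lapply(enr, function(e) if (is.null(e)) NULL else e$significant)
      for (owner in names(sig_lists)) {
        f <- file.path(cfg$out_dir, sprintf("pathways_%s_%s.tsv", owner, scope))
        sig <- sig_lists[[owner]]
        if (is.null(sig))
          sig <- test_subnetwork_pathways(character(0), pathways, universe)[0, ]
        out <- sig
        for (col in c("raw_p", "bonferroni_p")) out[[col]] <- format_num(out[[col]])
        write_tsv_plain(out, f)
        paths <- c(paths, f)
      }
      summ <- summarize_across_trios(sig_lists[trios$trio_id],
                                     pool = sig_lists$family_pool)
      f <- file.path(cfg$out_dir, sprintf("summary_%s.tsv", scope))
      sc <- summ$trio_counts
      sc$min_p <- format_num(sc$min_p)
      write_tsv_plain(sc, f)
      paths <- c(paths, f)
      results[[scope]] <- list(dmg = all_dmg, significant = sig_lists,
                               summary = summ)
    } else {
      results[[scope]] <- list(dmg = all_dmg)
    }
  }
  log_line(log_path, "done: ", length(paths), " output files")
  invisible(list(files = paths, results = results, filter_report = flt$report))
}

#' Run the pooled-group (dual) differential methylation pipeline
#'
#' Derives the affected/unaffected pools from the trio sheet, then writes:
#' the variance-ranked clustering orderings (`clustering.tsv`), the
#' sitewise Welch t-test table with BH adjustment (`site_tests.tsv`), the
#' island-probe gene-level group means (`gene_means.tsv`), and one
#' dual-color table per requested pathway
#' (`dual_color_<pathway>.tsv`). Pathway names absent from the GMT are
#' skipped with a warning.
#'
#' @param cfg Config list; `pathways_for_tables` names the GMT pathways to
#'   export (default: all pathways in the GMT).
#' @return Invisible list of written file paths plus in-memory results.
#' @export
run_dual_pipeline <- function(cfg) {
  cfg <- validate_pipeline_config(cfg)
  if (is.null(cfg$out_dir)) stop2("config needs out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  bm <- read_beta_matrix(cfg$beta)
  ann <- read_manifest(cfg$manifest)
  trios <- read_trio_sheet(cfg$trio_sheet)
  validate_trio_design(trios, colnames(bm))
  design <- group_design_from_trios(trios)
  flt <- filter_probes(bm, ann)
  bm <- flt$beta

  paths <- character(0)

  cl <- top_variance_clustering(bm, k = cfg$heatmap_k)
  f <- file.path(cfg$out_dir, "clustering.tsv")
  ord <- data.frame(
    axis = c(rep("probe", length(cl$probe_order)),
             rep("sample", length(cl$sample_order))),
    position = c(seq_along(cl$probe_order), seq_along(cl$sample_order)),
    id = c(cl$probe_order, cl$sample_order), stringsAsFactors = FALSE)
  write_tsv_plain(ord, f); paths <- c(paths, f)

  tt <- sitewise_ttest(bm, design)
  f <- file.path(cfg$out_dir, "site_tests.tsv")
  out <- tt$results
  for (col in c("t", "df", "raw_p", "fdr_p")) out[[col]] <- format_num(out[[col]])
  write_tsv_plain(out, f); paths <- c(paths, f)

  means <- gene_group_means(bm, ann, design)
  f <- file.path(cfg$out_dir, "gene_means.tsv")
  outm <- means
  for (col in c("mean_affected", "mean_unaffected")) outm[[col]] <- format_num(outm[[col]])
  write_tsv_plain(outm, f); paths <- c(paths, f)

  tables <- list()
  if (!is.null(cfg$gmt)) {
    pathways <- read_gmt(cfg$gmt)
    wanted <- cfg$pathways_for_tables %||% names(pathways)
    for (pw in wanted) {
      if (!pw %in% names(pathways)) {
        warning("pathway not in GMT, skipped: ", pw, call. = FALSE)
        next
      }
      tab <- dual_color_table(means, pathways[[pw]], tol = cfg$dual_tol)
      f <- file.path(cfg$out_dir, sprintf("dual_color_%s.tsv", pw))
      outt <- tab
      for (col in c("mean_affected", "mean_unaffected", "scaled_affected",
                    "scaled_unaffected"))
        outt[[col]] <- format_num(outt[[col]])
      write_tsv_plain(outt, f); paths <- c(paths, f)
      tables[[pw]] <- tab
    }
  }
  invisible(list(files = paths,
                 results = list(clustering = cl, site_tests = tt,
                                gene_means = means, dual_tables = tables)))
}

#' Run the end-to-end simulation and recovery study
#'
#' Generates a full synthetic data set (manifest, trio betas with planted
#' events, PPI network and pathways with a planted module), runs the trio
#' pipeline on it, and scores recovery against the planted truth:
#' sensitivity (fraction of planted events re-identified as qualifying
#' CpGs), the chance-qualifier rate among background probes with its
#' analytic expectation, and the planted pathway's rank by Bonferroni p in
#' the family-pool enrichment.
#'
#' @param sim_params [trio_sim_params()] object.
#' @param net_params [network_sim_params()] object; its
#'   `planted_module_size` is reconciled with the number of planted genes.
#' @param scope DMG scope for the recovery run (default `"genome_wide"`).
#' @param out_dir If non-`NULL`, the report is written there as
#'   `recovery_report.yaml` together with the simulated inputs.
#' @param enrich Run the enrichment/pathway-recovery stage (default
#'   `TRUE`).
#' @return Report list: `n_planted_events`, `n_recovered`, `sensitivity`,
#'   `chance_qualifier_rate`, `analytic_chance_rate`,
#'   `planted_pathway_rank`, `planted_pathway_p`, `n_pathways_tested`.
#' @export
run_simulation_study <- function(sim_params = trio_sim_params(),
                                 net_params = network_sim_params(),
                                 scope = "genome_wide", out_dir = NULL,
                                 enrich = TRUE) {
  manifest <- simulate_manifest(sim_params$n_probes, sim_params$n_genes,
                                seed = sim_params$seed)
  sim <- simulate_trio_betas(sim_params, manifest)
  truth <- sim$truth

  # qualifying CpGs per trio via the pipeline's own selection
  qual <- do.call(rbind, lapply(seq_len(nrow(sim$trios)), function(i)
    select_trio_dm_cpgs(sim$beta, sim$trios[i, ])))
  key <- function(df) paste(df$probe_id, df$trio_id, df$direction)
  recovered <- key(truth$dm_events) %in% key(qual)

  n_bg_cells <- (sim_params$n_probes - length(unique(truth$dm_events$probe_id))) *
    sim_params$n_trios
  chance_rate <- if (n_bg_cells > 0) nrow(truth$background_qualifiers) / n_bg_cells else NA_real_

  report <- list(
    seed = sim_params$seed,
    n_probes = sim_params$n_probes, n_trios = sim_params$n_trios,
    n_planted_events = nrow(truth$dm_events),
    n_recovered = sum(recovered),
    sensitivity = if (nrow(truth$dm_events)) mean(recovered) else NA_real_,
    n_background_qualifiers = nrow(truth$background_qualifiers),
    chance_qualifier_rate = chance_rate,
    analytic_chance_rate = analytic_chance_rate(sim_params))

  netsim <- NULL
  if (enrich) {
    np <- net_params
    if (np$planted_module_size != length(truth$planted_genes))
      np <- network_sim_params(n_genes = np$n_genes,
                               edge_probability = np$edge_probability,
                               planted_module_size = length(truth$planted_genes),
                               n_decoy_pathways = np$n_decoy_pathways,
                               seed = np$seed)
    genes <- sort(unique(annotation_links(manifest, "genome_wide")$gene))
    netsim <- simulate_network_pathways(np, genes, truth$planted_genes)

    per_trio <- lapply(seq_len(nrow(sim$trios)), function(i) {
      cpgs <- select_trio_dm_cpgs(sim$beta, sim$trios[i, ])
      aggregate_to_genes(cpgs, manifest, scope = scope,
                         owner = sim$trios$trio_id[i])
    })
    pool <- build_family_pool(per_trio)
    enr <- run_enrichment(scores_to_pvalues(pool), netsim$net, netsim$pathways,
                          universe = netsim$universe)
    res <- enr$all_results
    if (nrow(res)) {
      best <- vapply(split(res$bonferroni_p, res$pathway), min, numeric(1))
      ranks <- rank(best, ties.method = "min")
      report$planted_pathway_rank <- unname(ranks[netsim$planted_pathway])
      report$planted_pathway_p <- unname(best[netsim$planted_pathway])
      report$n_pathways_tested <- length(best)
    } else {
      report$planted_pathway_rank <- NA_integer_
      report$planted_pathway_p <- NA_real_
      report$n_pathways_tested <- 0L
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(netsim))
      write_simulated_inputs(sim, netsim, manifest, out_dir)
    yaml::write_yaml(report, file.path(out_dir, "recovery_report.yaml"))
  }
  report
}

#' Analytic per-probe chance-qualifier rate for a trio simulation
#'
#' Probability that a background probe satisfies the trio rule by chance,
#' under the probe-level mixture: for each component, the child and
#' affected parent must fall in one state band and the unaffected parent
#' in the opposite band, in either direction; components are weighted by
#' the mixture weight.
#'
#' @param params [trio_sim_params()] object.
#' @param hypo_max,hyper_min State cutoffs.
#' @return Probability (scalar).
#' @export
analytic_chance_rate <- function(params, hypo_max = 0.2, hyper_min = 0.8) {
  rate_for <- function(shape) {
    p_hypo <- stats::pbeta(hypo_max, shape[1], shape[2])
    p_hyper <- 1 - stats::pbeta(hyper_min, shape[1], shape[2])
    p_hyper^2 * p_hypo + p_hypo^2 * p_hyper
  }
  w <- params$mixture$weight
  w * rate_for(params$mixture$shape_low) +
    (1 - w) * rate_for(params$mixture$shape_high)
}
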