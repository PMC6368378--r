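#' Rescale beta values from [0, 1] to [-1, 1]
#'
#' Applies the linear rescaling `y = C + (x - A)(D - C)/(B - A)` piecewise:
#' betas in `[0, 0.5]` map onto `[-1, 0]` and betas in `[0.5, 1]` onto
#' `[0, 1]`. Both pieces reduce algebraically to the single affine map
#' `y = 2x - 1`, continuous at 0.5; the wider negative half makes
#' hypo-methylation visually prominent in dual-color pathway tables.
#'
#' @param x Beta value(s) in `[0, 1]`.
#' @return Scaled value(s) in `[-1, 1]`.
#' @examples
#' rescale_beta(c(0, 0.5, 0.75, 1))  # -1 0 0.5 1
#' @export
rescale_beta <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 1))) stop2("beta values out of [0, 1]")
  lin <- function(x, A, B, C, D) C + (x - A) * (D - C) / (B - A)
  ifelse(x <= 0.5, lin(x, 0, 0.5, -1, 0), lin(x, 0.5, 1, 0, 1))
}

#' Derive the pooled affected/unaffected group design from a trio sheet
#'
#' Children and affected parents form the affected pool; unaffected parents
#' the unaffected pool.
#'
#' @param trios Trio design `data.frame`.
#' @return Named character vector: sample id -> `"affected_pool"` /
#'   `"unaffected_pool"`.
#' @export
group_design_from_trios <- function(trios) {
  g <- c(stats::setNames(rep("affected_pool", 2 * nrow(trios)),
                         c(trios$child, trios$affected_parent)),
         stats::setNames(rep("unaffected_pool", nrow(trios)),
                         trios$unaffected_parent))
  validate_group_design(g)
}

#' @noRd
validate_group_design <- function(design) {
  if (!all(design %in% c("affected_pool", "unaffected_pool")))
    stop2("group design values must be affected_pool/unaffected_pool")
  if (length(unique(design)) < 2L)
    stop2("group design must contain both groups")
  design
}

#' Island-probe gene-level group means
#'
#' For every gene with at least one CpG-island probe, the mean beta over
#' (island probes x group samples) is computed separately for the affected
#' and unaffected pools. Probes outside islands (shores, shelves, open sea)
#' are excluded; a probe annotated to several genes contributes to each.
#'
#' @param bm Beta matrix.
#' @param ann Probe annotation.
#' @param design Group design as from [group_design_from_trios()].
#'
#' @return `data.frame` with columns `gene`, `mean_affected`,
#'   `mean_unaffected`, `n_probes` (island probes supporting the gene),
#'   sorted by gene.
#' @export
gene_group_means <- function(bm, ann, design) {
  design <- validate_group_design(design)
  miss <- setdiff(names(design), colnames(bm))
  if (length(miss)) stop2("design sample(s) not in beta matrix: ",
                          paste(miss, collapse = ", "))
  island <- ann$probe_id[ann$island_relation == "Island"]
  links <- annotation_links(ann, "genome_wide")
  links <- links[links$probe_id %in% island & links$probe_id %in% rownames(bm), ,
                 drop = FALSE]
  if (nrow(links) == 0L)
    return(data.frame(gene = character(0), mean_affected = numeric(0),
                      mean_unaffected = numeric(0), n_probes = integer(0)))
  aff <- names(design)[design == "affected_pool"]
  una <- names(design)[design == "unaffected_pool"]
  by_gene <- split(links$probe_id, links$gene)
  rows <- lapply(sort(names(by_gene)), function(g) {
    p <- unique(by_gene[[g]])
    data.frame(gene = g,
               mean_affected = mean(bm[p, aff, drop = FALSE], na.rm = TRUE),
               mean_unaffected = mean(bm[p, una, drop = FALSE], na.rm = TRUE),
               n_probes = length(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dual-color table for a pathway's genes
#'
#' Rescales the affected and unaffected group means of each pathway gene to
#' the `[-1, 1]` axis and flags genes whose two scaled values differ beyond
#' `tol` as dual-colored — i.e. differentially methylated between the
#' pooled groups at the rendering resolution. Genes without island-probe
#' means are omitted.
#'
#' @param means Output of [gene_group_means()].
#' @param pathway_genes Character vector of genes to annotate.
#' @param tol Scaled-difference tolerance for the dual flag (default 0.05).
#'
#' @return `data.frame` with `gene`, `mean_affected`, `mean_unaffected`,
#'   `scaled_affected`, `scaled_unaffected`, `dual`.
#' @export
dual_color_table <- function(means, pathway_genes, tol = 0.05) {
  if (tol < 0) stop2("tol must be >= 0")
  sub <- means[means$gene %in% pathway_genes, , drop = FALSE]
  sub$scaled_affected <- rescale_beta(sub$mean_affected)
  sub$scaled_unaffected <- rescale_beta(sub$mean_unaffected)
  sub$dual <- abs(sub$scaled_affected - sub$scaled_unaffected) > tol
  rownames(sub) <- NULL
  sub[c("gene", "mean_affected", "mean_unaffected", "scaled_affected",
        "scaled_unaffected", "dual")]
}

#' Sitewise two-sample t-tests between pooled groups
#'
#' Per-probe Welch (unequal-variance) two-sample t-test of the affected
#' pool against the unaffected pool, with Benjamini-Hochberg step-up
#' adjustment across all tested probes. Probes with fewer than two
#' non-missing values in either group, or zero variance in both groups,
#' are skipped and listed with a reason.
#'
#' @param bm Beta matrix.
#' @param design Group design.
#' @param var_equal Use the pooled-variance (Student) statistic instead of
#'   Welch (default `FALSE`).
#'
#' @return List with `results` (`data.frame`: `probe_id`, `t`, `df`,
#'   `raw_p`, `fdr_p`) and `skipped` (`data.frame`: `probe_id`, `reason`).
#' @export
sitewise_ttest <- function(bm, design, var_equal = FALSE) {
  design <- validate_group_design(design)
  a <- bm[, names(design)[design == "affected_pool"], drop = FALSE]
  b <- bm[, names(design)[design == "unaffected_pool"], drop = FALSE]

  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1, stats::var, na.rm = TRUE)
  vb <- apply(b, 1, stats::var, na.rm = TRUE)

  too_few <- na_ < 2 | nb < 2
  no_var <- !too_few & (va + vb) == 0
  skip <- too_few | no_var
  reason <- ifelse(too_few, "fewer_than_2_per_group", "zero_variance")[skip]

  keep <- !skip
  if (var_equal) {
    sp2 <- ((na_ - 1) * va + (nb - 1) * vb) / (na_ + nb - 2)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb))
    df <- na_ + nb - 2
  } else {
    se <- sqrt(va / na_ + vb / nb)
    df <- (va / na_ + vb / nb)^2 /
      ((va / na_)^2 / (na_ - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / se
  raw_p <- 2 * stats::pt(-abs(tstat), df)

  res <- data.frame(probe_id = rownames(bm)[keep], t = tstat[keep],
                    df = df[keep], raw_p = raw_p[keep],
                    stringsAsFactors = FALSE)
  res$fdr_p <- stats::p.adjust(res$raw_p, method = "BH")
  rownames(res) <- NULL
  list(results = res,
       skipped = data.frame(probe_id = rownames(bm)[skip], reason = reason,
                            stringsAsFactors = FALSE))
}

#' Hierarchical clustering of the highest-variance probes
#'
#' Selects the `k` probes with the largest cross-sample variance (ties
#' broken by probe id) and clusters both probes and samples by average
#' linkage on Euclidean distances, as for an exploratory heatmap.
#'
#' @param bm Beta matrix.
#' @param k Number of probes to keep (default 1000, capped at the probe
#'   count).
#'
#' @return List with `probes` (selected ids, variance order), `probe_order`
#'   and `sample_order` (dendrogram leaf orders, as ids), and the two
#'   `hclust` objects.
#' @export
top_variance_clustering <- function(bm, k = 1000) {
  k <- min(k, nrow(bm))
  v <- apply(bm, 1, stats::var, na.rm = TRUE)
  sel <- rownames(bm)[order(-v, rownames(bm))][seq_len(k)]
  sub <- bm[sel, , drop = FALSE]

  hc_probe <- if (length(sel) > 1)
    stats::hclust(stats::dist(sub), method = "average") else NULL
  hc_sample <- if (ncol(sub) > 1)
    stats::hclust(stats::dist(t(sub)), method = "average") else NULL

  list(probes = sel,
       probe_order = if (is.null(hc_probe)) sel else sel[hc_probe$order],
       sample_order = if (is.null(hc_sample)) colnames(sub)
                      else colnames(sub)[hc_sample$order],
       hclust_probes = hc_probe, hclust_samples = hc_sample)
}
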