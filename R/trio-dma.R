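#' Call the methylation state of beta values
#'
#' Classifies each beta value into hypo-methylated (`beta <= hypo_max`,
#' default 0.2), hyper-methylated (`beta >= hyper_min`, default 0.8), or
#' intermediate. The bands are closed at the cutoffs so that the boundary
#' triples attaining the minimum trio score are representable.
#'
#' @param beta Numeric vector of methylation fractions in `[0, 1]`; `NA`
#'   propagates.
#' @param hypo_max Upper bound of the hypo-methylated band (default 0.2).
#' @param hyper_min Lower bound of the hyper-methylated band (default 0.8).
#'
#' @return Character vector over `{"hypo", "intermediate", "hyper"}`.
#' @examples
#' call_state(c(0.1, 0.5, 0.9))
#' @export
call_state <- function(beta, hypo_max = 0.2, hyper_min = 0.8) {
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  if (!all(ok)) stop2("beta values out of [0, 1]")
  out <- rep(NA_character_, length(beta))
  out[!is.na(beta)] <- "intermediate"
  out[!is.na(beta) & beta <= hypo_max] <- "hypo"
  out[!is.na(beta) & beta >= hyper_min] <- "hyper"
  out
}

#' Trio-based score (TbSSch) for a qualifying CpG triple
#'
#' Quantifies how cleanly a CpG separates the affected child-parent pair
#' from the unaffected parent. For a triple where child and affected parent
#' are hyper-methylated and the unaffected parent hypo-methylated:
#' \deqn{[(C - 0.5) + (PA - 0.5) + (0.5 - PU)] / 1.5}
#' and for the mirrored (affected pair hypo) configuration:
#' \deqn{[(0.5 - C) + (0.5 - PA) + (PU - 0.5)] / 1.5}
#' With the default state cutoffs of 0.2 and 0.8 every qualifying triple
#' scores in `[0.6, 1]`: 0.6 at the band boundaries (0.8, 0.8, 0.2) and
#' (0.2, 0.2, 0.8), and 1 at complete separation (1, 1, 0) or (0, 0, 1).
#'
#' @param C Child beta value(s).
#' @param PA Affected-parent beta value(s).
#' @param PU Unaffected-parent beta value(s).
#' @param direction `"affected_hyper"` or `"affected_hypo"` (recycled).
#' @param check Verify that the states are consistent with `direction`
#'   under the default cutoffs (default `TRUE`).
#'
#' @return Numeric score vector.
#' @examples
#' tbssch(0.8, 0.8, 0.2, "affected_hyper")  # 0.6
#' tbssch(0, 0, 1, "affected_hypo")         # 1
#' @export
tbssch <- function(C, PA, PU, direction, check = TRUE) {
  direction <- rep_len(direction, length(C))
  bad_dir <- !direction %in% c("affected_hyper", "affected_hypo")
  if (any(bad_dir)) stop2("unknown direction: ", direction[bad_dir][1])
  if (check) {
    hyp <- direction == "affected_hyper"
    consistent <- ifelse(hyp,
                         C >= 0.8 & PA >= 0.8 & PU <= 0.2,
                         C <= 0.2 & PA <= 0.2 & PU >= 0.8)
    if (!all(consistent, na.rm = TRUE))
      stop2("direction inconsistent with methylation states of the triple")
  }
  ifelse(direction == "affected_hyper",
         ((C - 0.5) + (PA - 0.5) + (0.5 - PU)) / 1.5,
         ((0.5 - C) + (0.5 - PA) + (PU - 0.5)) / 1.5)
}

#' Select trio-differential CpGs
#'
#' A CpG qualifies for a trio when the affected child-parent pair and the
#' unaffected parent sit in opposite methylation bands: both affected
#' members hyper-methylated with the unaffected parent hypo-methylated
#' (direction `affected_hyper`), or the mirror image (`affected_hypo`).
#' Probes with a missing beta in any of the three members are skipped.
#'
#' @param bm Beta matrix containing the trio's three samples.
#' @param trio One-row trio design (`trio_id`, `child`, `affected_parent`,
#'   `unaffected_parent`), e.g. one row of [read_trio_sheet()] output.
#' @param hypo_max,hyper_min State cutoffs, as in [call_state()].
#'
#' @return `data.frame` of qualifying CpGs with columns `probe_id`,
#'   `trio_id`, `direction`, `tbssch`, ordered as in `bm`.
#' @export
select_trio_dm_cpgs <- function(bm, trio, hypo_max = 0.2, hyper_min = 0.8) {
  ids <- c(trio$child, trio$affected_parent, trio$unaffected_parent)
  miss <- setdiff(ids, colnames(bm))
  if (length(miss)) stop2("trio sample(s) not in beta matrix: ", paste(miss, collapse = ", "))
  C <- bm[, trio$child]; PA <- bm[, trio$affected_parent]; PU <- bm[, trio$unaffected_parent]
  complete <- !(is.na(C) | is.na(PA) | is.na(PU))

  hyper_dir <- complete & C >= hyper_min & PA >= hyper_min & PU <= hypo_max
  hypo_dir  <- complete & C <= hypo_max & PA <= hypo_max & PU >= hyper_min
  qual <- hyper_dir | hypo_dir
  direction <- ifelse(hyper_dir, "affected_hyper", "affected_hypo")[qual]

  out <- data.frame(probe_id = rownames(bm)[qual],
                    trio_id = rep(trio$trio_id, sum(qual)),
                    direction = direction,
                    stringsAsFactors = FALSE)
  out$tbssch <- tbssch(C[qual], PA[qual], PU[qual], direction, check = FALSE)
  out
}

#' Aggregate scored CpGs to a differentially methylated gene list
#'
#' Maps each qualifying CpG to its annotated gene(s) — a probe annotated to
#' several genes supports each of them — and keeps, per gene, the maximum
#' TbSSch over its supporting CpGs. Under `scope = "promoter"` only
#' probe-gene links in the TSS200/TSS1500 promoter blocks are used. CpGs
#' with no (in-scope) gene link are dropped.
#'
#' @param cpgs Scored CpGs from [select_trio_dm_cpgs()].
#' @param ann Probe annotation.
#' @param scope `"genome_wide"` or `"promoter"`.
#' @param owner Label for the list (defaults to the CpGs' trio id).
#'
#' @return A DMG list: `data.frame` with columns `owner`, `scope`, `gene`,
#'   `tbssch`, `n_support`, `directions`, `probes`, sorted by descending
#'   score then gene symbol.
#' @export
aggregate_to_genes <- function(cpgs, ann, scope = c("genome_wide", "promoter"),
                               owner = NULL) {
  scope <- match.arg(scope)
  if (is.null(owner))
    owner <- if (nrow(cpgs)) cpgs$trio_id[1] else NA_character_
  links <- annotation_links(ann, scope)
  m <- merge(cpgs, links, by = "probe_id")
  if (nrow(m) == 0L) return(empty_dmg_list(owner, scope))

  m <- m[order(m$gene, -m$tbssch, m$probe_id), , drop = FALSE]
  by_gene <- split(m, m$gene)
  entries <- lapply(by_gene, function(g) {
    data.frame(gene = g$gene[1], tbssch = max(g$tbssch), n_support = nrow(g),
               directions = paste(sort(unique(g$direction)), collapse = ";"),
               probes = paste(g$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, entries)
  out <- cbind(owner = owner, scope = scope, out, stringsAsFactors = FALSE)
  sort_dmg(out)
}

#' @noRd
empty_dmg_list <- function(owner, scope) {
  data.frame(owner = character(0), scope = character(0), gene = character(0),
             tbssch = numeric(0), n_support = integer(0),
             directions = character(0), probes = character(0),
             stringsAsFactors = FALSE)
}

#' @noRd
sort_dmg <- function(dmg) {
  dmg <- dmg[order(-dmg$tbssch, dmg$gene), , drop = FALSE]
  rownames(dmg) <- NULL
  dmg
}

#' Build the family-pool DMG list
#'
#' Pools per-trio DMG lists: a gene enters the family pool when it appears
#' in more than one trio list; its pooled score is the maximum TbSSch over
#' all its occurrences. All input lists must share the same scope.
#'
#' @param lists List of per-trio DMG `data.frame`s from
#'   [aggregate_to_genes()].
#'
#' @return DMG list with `owner = "family_pool"`, sorted by descending
#'   score then gene.
#' @export
build_family_pool <- function(lists) {
  if (length(lists) < 2L) stop2("family pool needs at least two trio DMG lists")
  scopes <- unique(unlist(lapply(lists, function(l) unique(l$scope))))
  scopes <- scopes[!is.na(scopes)]
  if (length(scopes) > 1L) stop2("mixed scopes in family pool input")
  scope <- if (length(scopes)) scopes else "genome_wide"

  all <- do.call(rbind, lists)
  if (is.null(all) || nrow(all) == 0L) return(empty_dmg_list("family_pool", scope))
  n_lists <- tapply(all$owner, all$gene, function(x) length(unique(x)))
  keep <- names(n_lists)[n_lists >= 2L]
  if (!length(keep)) return(empty_dmg_list("family_pool", scope))

  sub <- all[all$gene %in% keep, , drop = FALSE]
  by_gene <- split(sub, sub$gene)
  entries <- lapply(by_gene, function(g) {
    data.frame(owner = "family_pool", scope = scope, gene = g$gene[1],
               tbssch = max(g$tbssch), n_support = sum(g$n_support),
               directions = paste(sort(unique(unlist(strsplit(g$directions, ";")))),
                                  collapse = ";"),
               probes = paste(unique(unlist(strsplit(g$probes, ";"))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  sort_dmg(do.call(rbind, entries))
}

#' Convert TbSSch scores to nominal gene p-values
#'
#' The downstream subnetwork search consumes per-gene p-values. TbSSch is a
#' separation score, not a test statistic; this mapping is the documented
#' package convention `p = max(1 - score, eps)`, strictly decreasing in the
#' score, with a floor to keep p positive. Treat the resulting values as a
#' ranking device, not calibrated significance.
#'
#' @param dmg DMG list `data.frame` with `gene` and `tbssch` columns.
#' @param eps Floor for the p-value (default `1e-6`).
#'
#' @return Named numeric vector: gene -> p-value in `(0, 1]`.
#' @export
scores_to_pvalues <- function(dmg, eps = 1e-6) {
  p <- pmin(pmax(1 - dmg$tbssch, eps), 1)
  stats::setNames(p, dmg$gene)
}

#' Write a DMG list to TSV
#' @param dmg DMG list `data.frame`.
#' @param path Output path.
#' @export
write_dmg_list <- function(dmg, path) {
  out <- dmg
  out$tbssch <- format_num(out$tbssch)
  write_tsv_plain(out, path)
}
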