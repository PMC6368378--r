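REGION_GROUPS <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")
PROMOTER_GROUPS <- c("TSS200", "TSS1500")

#' Construct a probe annotation table
#'
#' Per-probe annotation in the Illumina 450K manifest dialect: chromosome,
#' semicolon-joined gene symbols with an aligned list of gene-region groups
#' (TSS200, TSS1500, 5'UTR, 1stExon, Body, 3'UTR), and the CpG-island
#' relation. A probe may be annotated to zero or more genes; the gene and
#' region lists must have equal length for every probe.
#'
#' @param probe_id Character vector of unique probe ids.
#' @param chromosome Chromosome labels; `"chrX"` style prefixes are stripped.
#' @param genes Semicolon-joined gene symbols per probe (`""` for none).
#' @param region_groups Semicolon-joined region groups, aligned to `genes`.
#' @param island_relation One of Island, N_Shore, S_Shore, N_Shelf, S_Shelf,
#'   OpenSea per probe.
#'
#' @return A `data.frame` with those five columns, validated.
#' @export
probe_annotation <- function(probe_id, chromosome, genes, region_groups,
                             island_relation) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop2("duplicate probe ids in annotation")
  chromosome <- normalize_chromosome(chromosome)
  genes <- as.character(genes); genes[is.na(genes)] <- ""
  region_groups <- as.character(region_groups); region_groups[is.na(region_groups)] <- ""
  island_relation <- as.character(island_relation)

  n_genes <- lengths(strsplit(genes, ";", fixed = TRUE))
  n_groups <- lengths(strsplit(region_groups, ";", fixed = TRUE))
  bad <- which(n_genes != n_groups)
  if (length(bad))
    stop2("gene/region-group lists misaligned for probe(s): ",
          paste(utils::head(probe_id[bad], 5), collapse = ", "))
  grp_vals <- unlist(strsplit(region_groups[region_groups != ""], ";", fixed = TRUE))
  unknown <- setdiff(unique(grp_vals), REGION_GROUPS)
  if (length(unknown))
    stop2("unknown gene-region group(s): ", paste(unknown, collapse = ", "))
  unknown_isl <- setdiff(unique(island_relation), ISLAND_RELATIONS)
  if (length(unknown_isl))
    stop2("unknown island relation(s): ", paste(unknown_isl, collapse = ", "))

  data.frame(probe_id = probe_id, chromosome = chromosome, genes = genes,
             region_groups = region_groups, island_relation = island_relation,
             stringsAsFactors = FALSE)
}

#' Read a 450K-style probe manifest
#'
#' Parses a CSV with the manifest columns `IlmnID`, `CHR`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`, and
#' `Relation_to_UCSC_CpG_Island`; multi-gene probes carry semicolon-separated
#' values in the two RefGene columns, which must stay aligned.
#'
#' @param path CSV path.
#' @return Probe annotation `data.frame` as from [probe_annotation()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("IlmnID", "CHR", "UCSC_RefGene_Name", "UCSC_RefGene_Group",
            "Relation_to_UCSC_CpG_Island")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop2("manifest missing column(s): ", paste(miss, collapse = ", "))
  probe_annotation(df$IlmnID, df$CHR, df$UCSC_RefGene_Name,
                   df$UCSC_RefGene_Group, df$Relation_to_UCSC_CpG_Island)
}

#' Write a probe annotation table as a 450K-style manifest CSV
#'
#' @param ann Probe annotation `data.frame`.
#' @param path Output path.
#' @export
write_manifest <- function(ann, path) {
  out <- data.frame(IlmnID = ann$probe_id, CHR = ann$chromosome,
                    UCSC_RefGene_Name = ann$genes,
                    UCSC_RefGene_Group = ann$region_groups,
                    Relation_to_UCSC_CpG_Island = ann$island_relation,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand probe annotation to one row per probe-gene link
#'
#' @param ann Probe annotation `data.frame`.
#' @param scope `"genome_wide"` keeps every probe-gene link; `"promoter"`
#'   keeps only links whose region group is TSS200 or TSS1500.
#'
#' @return `data.frame` with columns `probe_id`, `gene`, `region_group`.
#'   Probes with no gene annotation contribute no rows.
#' @export
annotation_links <- function(ann, scope = c("genome_wide", "promoter")) {
  scope <- match.arg(scope)
  gl <- strsplit(ann$genes, ";", fixed = TRUE)
  rl <- strsplit(ann$region_groups, ";", fixed = TRUE)
  n <- lengths(gl)
  links <- data.frame(
    probe_id = rep(ann$probe_id, n),
    gene = unlist(gl, use.names = FALSE) %||% character(0),
    region_group = unlist(rl, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  links <- links[links$gene != "", , drop = FALSE]
  # The same gene may annotate one probe under several region groups; for
  # promoter scope filter first, then de-duplicate probe-gene pairs.
  if (scope == "promoter")
    links <- links[links$region_group %in% PROMOTER_GROUPS, , drop = FALSE]
  links <- links[!duplicated(links[c("probe_id", "gene")]), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Read a trio sample sheet
#'
#' CSV with columns `trio_id`, `child`, `affected_parent`,
#' `unaffected_parent`. The three sample ids of a trio must be pairwise
#' distinct.
#'
#' @param path CSV path.
#' @return `data.frame` with the four columns, one row per trio.
#' @export
read_trio_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trio_id", "child", "affected_parent", "unaffected_parent")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop2("trio sheet missing column(s): ", paste(miss, collapse = ", "))
  df$trio_id <- as.character(df$trio_id)
  validate_trio_design(df)
}

#' @noRd
validate_trio_design <- function(trios, sample_ids = NULL) {
  for (i in seq_len(nrow(trios))) {
    ids <- c(trios$child[i], trios$affected_parent[i], trios$unaffected_parent[i])
    if (anyDuplicated(ids))
      stop2("trio ", trios$trio_id[i], ": child/parent sample ids must be distinct")
    if (!is.null(sample_ids) && !all(ids %in% sample_ids))
      stop2("trio ", trios$trio_id[i], ": sample id(s) absent from beta matrix: ",
            paste(setdiff(ids, sample_ids), collapse = ", "))
  }
  if (anyDuplicated(trios$trio_id)) stop2("duplicate trio ids in trio sheet")
  trios
}

#' Write a trio sample sheet CSV
#' @param trios Trio design `data.frame`.
#' @param path Output path.
#' @export
write_trio_sheet <- function(trios, path) {
  utils::write.csv(trios[c("trio_id", "child", "affected_parent", "unaffected_parent")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
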