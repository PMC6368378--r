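test_that("state calls use closed bands at 0.2 and 0.8", {
  expect_equal(call_state(c(0.1, 0.9, 0.5)), c("hypo", "hyper", "intermediate"))
  expect_equal(call_state(c(0.2, 0.8, 0, 1)),
               c("hypo", "hyper", "hypo", "hyper"))
  expect_true(is.na(call_state(NA_real_)))
  expect_error(call_state(1.2), "out of")
})

test_that("TbSSch matches the scoring formulas and their range", {
  expect_equal(tbssch(1, 1, 0, "affected_hyper"), 1)
  expect_equal(tbssch(0, 0, 1, "affected_hypo"), 1)
  expect_equal(tbssch(0.8, 0.8, 0.2, "affected_hyper"), 0.6)
  expect_equal(tbssch(0.2, 0.2, 0.8, "affected_hypo"), 0.6)
  expect_equal(tbssch(0.1, 0.15, 0.9, "affected_hypo"), (0.4 + 0.35 + 0.4) / 1.5)
  expect_error(tbssch(0.5, 0.9, 0.1, "affected_hyper"), "inconsistent")
  expect_error(tbssch(0.9, 0.9, 0.1, "sideways"), "direction")
})

test_that("TbSSch reflection symmetry: mirrored triples score identically", {
  set.seed(11)
  C <- runif(500, 0.8, 1); PA <- runif(500, 0.8, 1); PU <- runif(500, 0, 0.2)
  expect_equal(tbssch(1 - C, 1 - PA, 1 - PU, "affected_hypo"),
               tbssch(C, PA, PU, "affected_hyper"))
})

test_that("trio rule selects exactly the opposite-band triples", {
  bm <- make_beta(rbind(c(0.85, 0.90, 0.10),   # qualifies, affected_hyper
                        c(0.85, 0.50, 0.10),   # PA intermediate
                        c(0.85, 0.90, 0.85),   # no state flip
                        c(0.10, 0.15, 0.90),   # qualifies, affected_hypo
                        c(0.10, 0.15, NA)),    # missing member skipped
                  samples = c("C1", "PA1", "PU1"))
  got <- select_trio_dm_cpgs(bm, one_trio())
  expect_equal(got$probe_id, c("cg00001", "cg00004"))
  expect_equal(got$direction, c("affected_hyper", "affected_hypo"))
  expect_equal(got$tbssch[1], tbssch(0.85, 0.90, 0.10, "affected_hyper"))
})

test_that("trio rule equals the independent state-scan oracle on random matrices", {
  set.seed(202)
  for (rep in 1:5) {
    bm <- make_beta(matrix(runif(300 * 3), 300, 3),
                    samples = c("C1", "PA1", "PU1"))
    got <- select_trio_dm_cpgs(bm, one_trio())
    want <- oracle_trio_scan(bm, one_trio())
    expect_identical(got$probe_id, want$probe_id)
    expect_identical(got$direction, want$direction)
  }
})

test_that("gene aggregation keeps the max score and honors scope", {
  ann <- tiny_annotation()
  cpgs <- data.frame(probe_id = c("cg00001", "cg00002", "cg00005"),
                     trio_id = "trioA",
                     direction = c("affected_hyper", "affected_hyper",
                                   "affected_hypo"),
                     tbssch = c(0.7, 0.9, 0.66), stringsAsFactors = FALSE)
  dmg <- aggregate_to_genes(cpgs, ann, "genome_wide")
  # cg00001 hits GENE1+GENE2; GENE2 takes max(0.7, 0.9)
  expect_equal(dmg$tbssch[dmg$gene == "GENE2"], 0.9)
  expect_equal(dmg$tbssch[dmg$gene == "GENE1"], 0.7)
  expect_equal(dmg$n_support[dmg$gene == "GENE1"], 2L)
  # descending sort, ties broken by gene symbol
  expect_equal(dmg$gene, dmg$gene[order(-dmg$tbssch, dmg$gene)])

  # promoter scope: cg00001 links only via GENE1 (TSS200), not GENE2 (Body)
  prom <- aggregate_to_genes(cpgs, ann, "promoter")
  expect_setequal(prom$gene, c("GENE1", "GENE2"))  # GENE2 via cg00002 TSS1500
  expect_equal(prom$tbssch[prom$gene == "GENE1"], 0.7)
  expect_equal(prom$n_support[prom$gene == "GENE1"], 1L)
})

test_that("gene aggregation equals a brute-force multiset computation", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 40
    genes <- sample(c("", paste0("G", 1:8)), n, replace = TRUE)
    groups <- ifelse(genes == "", "", sample(c("TSS200", "Body"), n, replace = TRUE))
    ann <- probe_annotation(sprintf("cg%03d", 1:n), rep("1", n), genes,
                            groups, rep("Island", n))
    sel <- sort(sample(n, 15))
    cpgs <- data.frame(probe_id = ann$probe_id[sel], trio_id = "t",
                       direction = "affected_hyper",
                       tbssch = round(runif(15, 0.6, 1), 6),
                       stringsAsFactors = FALSE)
    dmg <- aggregate_to_genes(cpgs, ann, "genome_wide")
    # brute force: for each gene, collect scores of its probes
    want <- sapply(unique(ann$genes[sel][ann$genes[sel] != ""]), function(g) {
      max(cpgs$tbssch[cpgs$probe_id %in% ann$probe_id[ann$genes == g]])
    })
    expect_equal(sort(names(want)), sort(dmg$gene))
    expect_equal(unname(want[dmg$gene]), dmg$tbssch)
  }
})

test_that("family pool keeps genes present in more than one trio list at their max", {
  mk <- function(owner, genes, scores)
    data.frame(owner = owner, scope = "genome_wide", gene = genes,
               tbssch = scores, n_support = 1L, directions = "affected_hyper",
               probes = "cgX", stringsAsFactors = FALSE)
  l1 <- mk("t1", c("A", "B"), c(0.7, 0.65))
  l2 <- mk("t2", c("A", "C"), c(0.8, 0.65))
  l3 <- mk("t3", c("D", "C"), c(0.9, 0.65))
  pool <- build_family_pool(list(l1, l2, l3))
  expect_setequal(pool$gene, c("A", "C"))
  expect_equal(pool$tbssch[pool$gene == "A"], 0.8)
  expect_equal(pool$tbssch[pool$gene == "C"], 0.65)
  expect_true(all(pool$owner == "family_pool"))
  # singletons excluded; equal scores keep the shared value
  expect_false("B" %in% pool$gene)
  expect_false("D" %in% pool$gene)

  l4 <- mk("t4", "E", 0.99); l4$scope <- "promoter"
  expect_error(build_family_pool(list(l1, l4)), "mixed scopes")
  expect_error(build_family_pool(list(l1)), "at least two")
})

test_that("score-to-p mapping is the documented 1 - score convention with a floor", {
  dmg <- data.frame(gene = c("A", "B", "C"), tbssch = c(0.6, 1.0, 0.9))
  p <- scores_to_pvalues(dmg)
  expect_equal(unname(p["A"]), 0.4)
  expect_equal(unname(p["B"]), 1e-6)
  expect_true(p["A"] > p["C"] && p["C"] > p["B"])
})

test_that("DMG list files are byte-identical across repeated runs", {
  ann <- tiny_annotation()
  set.seed(5)
  bm <- make_beta(matrix(runif(18), 6, 3), probes = ann$probe_id,
                  samples = c("C1", "PA1", "PU1"))
  bm[1, ] <- c(0.9, 0.95, 0.05)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  dmg <- aggregate_to_genes(select_trio_dm_cpgs(bm, one_trio()), ann)
  write_dmg_list(dmg, f1); write_dmg_list(dmg, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
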