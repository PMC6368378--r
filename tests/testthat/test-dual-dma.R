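test_that("rescaling maps [0,1] onto [-1,1] with both pieces meeting at 0.5", {
  expect_equal(rescale_beta(0), -1)
  expect_equal(rescale_beta(0.5), 0)
  expect_equal(rescale_beta(0.75), 0.5)
  expect_equal(rescale_beta(1), 1)
  # both printed pieces evaluated just either side of the junction agree
  expect_equal(rescale_beta(0.5 - 1e-12), rescale_beta(0.5 + 1e-12),
               tolerance = 1e-10)
  x <- seq(0, 1, by = 0.01)
  expect_equal(rescale_beta(x), 2 * x - 1, tolerance = 1e-14)
  expect_true(all(diff(rescale_beta(x)) > 0))
  expect_error(rescale_beta(1.5), "out of")
})

test_that("group design derives affected/unaffected pools from the trio sheet", {
  trios <- data.frame(trio_id = c("t1", "t2"),
                      child = c("C1", "C2"),
                      affected_parent = c("PA1", "PA2"),
                      unaffected_parent = c("PU1", "PU2"),
                      stringsAsFactors = FALSE)
  d <- group_design_from_trios(trios)
  expect_equal(sum(d == "affected_pool"), 4L)
  expect_equal(unname(d[c("PU1", "PU2")]), rep("unaffected_pool", 2))
})

test_that("gene group means use island probes only and ignore ordering", {
  ann <- tiny_annotation()
  bm <- make_beta(matrix(0.5, 6, 4), probes = ann$probe_id,
                  samples = c("A1", "A2", "U1", "U2"))
  bm["cg00001", ] <- c(0.2, 0.4, 0.6, 0.8)  # Island; GENE1+GENE2
  bm["cg00002", ] <- c(0.9, 0.9, 0.1, 0.1)  # N_Shore -> excluded
  bm["cg00005", ] <- c(0.6, 0.8, 0.2, 0.4)  # Island; GENE1
  design <- c(A1 = "affected_pool", A2 = "affected_pool",
              U1 = "unaffected_pool", U2 = "unaffected_pool")
  m <- gene_group_means(bm, ann, design)
  # GENE2's only island probe is cg00001 -> mean(0.2, 0.4)
  expect_equal(m$mean_affected[m$gene == "GENE2"], 0.3)
  expect_equal(m$mean_unaffected[m$gene == "GENE2"], 0.7)
  # GENE1 pools cg00001 and cg00005 over group samples
  expect_equal(m$mean_affected[m$gene == "GENE1"], mean(c(0.2, 0.4, 0.6, 0.8)))
  expect_equal(m$n_probes[m$gene == "GENE1"], 2L)
  # shore-only probe never contributes
  expect_false(any(grepl("cg00002", m$gene)))

  # order invariance
  m2 <- gene_group_means(bm[rev(rownames(bm)), rev(colnames(bm))], ann, design)
  expect_equal(m2, m)

  # identical groups give identical means
  bm2 <- bm; bm2[, c("U1", "U2")] <- bm[, c("A1", "A2")]
  m3 <- gene_group_means(bm2, ann, design)
  expect_equal(m3$mean_affected, m3$mean_unaffected)
})

test_that("dual-color table rescales means and flags differences beyond tolerance", {
  means <- data.frame(gene = c("G1", "G2"),
                      mean_affected = c(0.9, 0.5),
                      mean_unaffected = c(0.1, 0.5),
                      n_probes = 1L, stringsAsFactors = FALSE)
  tab <- dual_color_table(means, c("G1", "G2", "G3"))
  expect_equal(tab$scaled_affected, c(0.8, 0))
  expect_equal(tab$scaled_unaffected, c(-0.8, 0))
  expect_equal(tab$dual, c(TRUE, FALSE))
  expect_false("G3" %in% tab$gene)  # absent from means -> no record
})

test_that("sitewise Welch t matches stats::t.test per probe", {
  set.seed(7)
  bm <- make_beta(matrix(rbeta(50 * 10, 2, 2), 50, 10))
  design <- setNames(rep(c("affected_pool", "unaffected_pool"), each = 5),
                     colnames(bm))
  got <- sitewise_ttest(bm, design)$results
  for (i in c(1, 17, 50)) {
    want <- t.test(bm[i, 1:5], bm[i, 6:10])
    expect_equal(got$t[i], unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$raw_p[i], want$p.value, tolerance = 1e-12)
  }
  expect_equal(got$fdr_p, p.adjust(got$raw_p, "BH"))
})

test_that("sitewise t handles identical groups and crafted separations", {
  bm <- make_beta(matrix(rep(c(0.3, 0.6), each = 6), 2, 6, byrow = TRUE))
  bm <- rbind(bm, crafted = c(0.1, 0.1, 0.101, 0.9, 0.9, 0.901))
  rownames(bm)[3] <- "crafted"
  design <- setNames(rep(c("affected_pool", "unaffected_pool"), each = 3),
                     colnames(bm))
  # a probe with identical groups but nonzero variance
  bm2 <- make_beta(rbind(c(0.3, 0.4, 0.5, 0.3, 0.4, 0.5),
                         c(0.1, 0.1, 0.101, 0.9, 0.9, 0.901)),
                   probes = c("jit", "crafted"), samples = names(design))
  tt <- sitewise_ttest(bm2, design)
  expect_equal(tt$results$t[tt$results$probe_id == "jit"], 0)
  expect_equal(tt$results$raw_p[tt$results$probe_id == "jit"], 1)
  expect_equal(which.min(tt$results$raw_p),
               which(tt$results$probe_id == "crafted"))

  # zero-variance and too-few-sample probes are skipped with reasons
  tt2 <- sitewise_ttest(bm, design)
  expect_true(all(c("cg00001", "cg00002") %in% tt2$skipped$probe_id))
  expect_true(all(tt2$skipped$reason == "zero_variance"))
})

test_that("BH adjustment matches a hand-computed step-up fixture", {
  # step-up on p = (.01,.02,.03,.04,.25): p*(m/i) = .05,.05,.05,.05,.25
  p <- c(0.01, 0.02, 0.03, 0.04, 0.25)
  expect_equal(p.adjust(p, "BH"), c(0.05, 0.05, 0.05, 0.05, 0.25))
  expect_equal(p.adjust(0.03, "BH"), 0.03)  # m = 1 identity
})

test_that("variance-ranked clustering selects and orders as documented", {
  set.seed(3)
  bm <- make_beta(matrix(0.5, 10, 6))
  bm["cg00004", ] <- c(0.1, 0.9, 0.1, 0.9, 0.1, 0.9)
  cl <- top_variance_clustering(bm, k = 1)
  expect_equal(cl$probes, "cg00004")

  # duplicated samples merge first -> adjacent dendrogram leaves
  bm2 <- make_beta(matrix(runif(60), 10, 6))
  bm2[, "S02"] <- bm2[, "S05"]
  cl2 <- top_variance_clustering(bm2, k = 10)
  pos <- match(c("S02", "S05"), cl2$sample_order)
  expect_equal(abs(diff(pos)), 1L)

  # k = all probes keeps the identity set; constant ties break by id
  cl3 <- top_variance_clustering(bm, k = 10)
  expect_setequal(cl3$probes, rownames(bm))
  expect_equal(top_variance_clustering(make_beta(matrix(0.2, 4, 3)), k = 2)$probes,
               c("cg00001", "cg00002"))
})
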