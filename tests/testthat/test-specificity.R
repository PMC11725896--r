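test_that("dispersion estimation recovers known parameters", {
  set.seed(41)
  n <- 400
  mu <- exp(rnorm(n, log(50), 1))
  ## Poisson data: estimates shrink toward the floor
  pois <- matrix(rpois(n * 6, rep(mu, 6)), n, 6)
  rownames(pois) <- paste0("g", seq_len(n))
  dPois <- estimateDispersion(pois, rep(c("A", "B"), each = 3))
  expect_lte(median(dPois), 0.05)
  ## NB dispersion 0.4: median estimate in [0.2, 0.6]
  nb <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 1 / 0.4), n, 6)
  rownames(nb) <- paste0("g", seq_len(n))
  dNB <- estimateDispersion(nb, rep(c("A", "B"), each = 3))
  expect_gte(median(dNB), 0.2)
  expect_lte(median(dNB), 0.6)
  ## replicate-constant counts: everything sits at the floor
  const <- matrix(rep(c(5L, 80L, 300L, 2L, 40L), each = 6), 5, 6,
                  byrow = TRUE, dimnames = list(paste0("g", 1:5), NULL))
  dC <- estimateDispersion(const, rep(c("A", "B"), each = 3))
  expect_equal(unname(dC), rep(1e-4, 5))
  ## single-replicate-only design is rejected
  expect_error(estimateDispersion(pois[, 1:2], c("A", "B")), "dispersion")
})

test_that("the NB exact test matches brute-force tail summation", {
  ## strongly separated gene: p below 1e-6 and equal to the oracle
  cnt <- rbind(de = c(100L, 100L, 1L, 1L),
               null = c(20L, 22L, 18L, 21L),
               pad = c(1000L, 998L, 1099L, 1097L))
  cnt["pad", ] <- max(colSums(cnt)) - colSums(cnt) + cnt["pad", ]  # equal libs
  se <- makeTinySE(cnt, c("A", "B"), c("embryo", "endosperm"), reps = 2)
  de <- pairwiseDE(se, "A.cot", "B.cot", dispersion = 0.01)
  expect_lt(de$p_value[1], 1e-6)
  for (i in 1:3) {
    ya <- sum(cnt[i, 1:2]); yb <- sum(cnt[i, 3:4])
    expect_equal(de$p_value[i], nbExactOracle(ya, yb, 2, 2, 0.01),
                 tolerance = 1e-10)
  }
})

test_that("the exact test agrees with an independent NB DE implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  m <- matrix(rnbinom(80 * 6, mu = 30, size = 5), 80, 6)
  m[1:5, 1:3] <- m[1:5, 1:3] * 4L
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  m <- rbind(m, pad = max(colSums(m)) - colSums(m) + 500L)
  se <- makeTinySE(m, c("A", "B"), c("embryo", "endosperm"), reps = 3)
  ours <- pairwiseDE(se, "A.cot", "B.cot", dispersion = 0.2)
  ref <- edgeR::exactTest(
    edgeR::DGEList(counts = m, group = rep(c("A", "B"), each = 3)),
    dispersion = 0.2, rejection.region = "smallp")
  expect_equal(ours$p_value, ref$table$PValue, tolerance = 1e-4)
})

test_that("relabeling identical groups gives a perfect null", {
  set.seed(43)
  half <- matrix(rnbinom(100 * 3, mu = 40, size = 10), 100, 3)
  cnt <- cbind(half, half)
  rownames(cnt) <- paste0("g", 1:100)
  se <- makeTinySE(cnt, c("A", "B"), c("embryo", "embryo"), reps = 3)
  de <- pairwiseDE(se, "A.cot", "B.cot", dispersion = 0.1)
  expect_equal(max(abs(de$log2_fold_change)), 0)
  expect_true(all(de$p_value > 0.99))
  expect_error(pairwiseDE(se, "A.cot", "A.cot", dispersion = 0.1),
               "overlapping")
})

test_that("specificity calls respect planted structure and scope nesting", {
  ## gene 10x in both subregions of one region: regional-specific in each,
  ## never subregion-specific
  set.seed(44)
  n <- 60
  mu <- matrix(30, n, 4)
  mu[1, 1:2] <- 300      # high in A1 and A2 (same region)
  mu[2, ] <- 30          # uniform
  muRep <- mu[, rep(1:4, each = 3)]
  cnt <- matrix(rnbinom(n * 12, mu = as.vector(muRep), size = 20),
                n, 12, dimnames = list(paste0("g", seq_len(n)), NULL))
  se <- makeTinySE(cnt, c("A1", "A2", "B1", "B2"),
                   c("embryo", "embryo", "endosperm", "endosperm"), reps = 3)
  sub <- callSpecific(se, "cot", "subregion")
  reg <- callSpecific(se, "cot", "regional")
  expect_false("g1" %in% sub$gene_id)
  expect_setequal(reg$focal_subregion[reg$gene_id == "g1"], c("A1", "A2"))
  expect_false("g2" %in% c(sub$gene_id, reg$gene_id))
  ## nesting: every subregion-scope call also appears at regional scope
  keySub <- paste(sub$gene_id, sub$stage, sub$focal_subregion)
  keyReg <- paste(reg$gene_id, reg$stage, reg$focal_subregion)
  expect_true(all(keySub %in% keyReg))
  ## emitted calls honor the thresholds
  expect_true(all(sub$min_fold_change >= 5))
  expect_true(all(sub$max_fdr < 0.001))
})

test_that("calls are invariant to replicate relabeling within groups", {
  se <- fixtureBulk()$se
  cd <- SummarizedExperiment::colData(se)
  perm <- order(cd$subregion, cd$stage, rev(cd$replicate))
  calls1 <- callSpecific(se, "cot", "subregion")
  calls2 <- callSpecific(se[, perm], "cot", "subregion")
  o1 <- calls1[order(calls1$gene_id, calls1$focal_subregion), ]
  o2 <- calls2[order(calls2$gene_id, calls2$focal_subregion), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("planted specific genes are recovered and non-planted stay quiet", {
  rec <- specificityRecovery(fixtureCalls("subregion"), fixtureBulk()$truth)
  expect_gte(rec$sensitivity, 0.9)
  expect_lte(rec$false_call_rate, 0.01)
})

test_that("called specific mRNAs are more prevalent than the detected bulk", {
  calls <- fixtureCalls("subregion")
  prof <- fixtureProfile()
  det <- fixtureDetected()
  cpmSpec <- vapply(seq_len(nrow(calls)), function(i)
    prof[calls$gene_id[i],
         paste(calls$focal_subregion[i], calls$stage[i], sep = ".")],
    numeric(1))
  expect_gt(median(cpmSpec), median(prof[rowSums(det) >= 1, ]))
})

test_that("conserved regional TF ranking honors orthology and k", {
  bulk <- fixtureBulk()
  ann <- fixtureAnnotation()
  callsReg <- fixtureCalls("regional")
  regionOf <- bulk$truth$region_of
  res <- conservedRegionalTFs(callsReg, ann$calls_b, ann$orthologs,
                              ann$tf_genes, ann$tf_b, ann$region_pairing,
                              regionOf, ann$region_of_b,
                              fixtureProfile(), k = 5)
  truthPairs <- ann$truth$conserved_pairs
  got <- paste(res$gene_a, res$gene_b)
  want <- paste(truthPairs$gene_a, truthPairs$gene_b)
  expect_gt(length(intersect(got, want)), 0)
  expect_true(all(got %in% want))          # only planted pairs can match
  expect_true(all(table(res$region_a) <= 5))
  ## k larger than available: everything returned, no padding
  resAll <- conservedRegionalTFs(callsReg, ann$calls_b, ann$orthologs,
                                 ann$tf_genes, ann$tf_b, ann$region_pairing,
                                 regionOf, ann$region_of_b,
                                 fixtureProfile(), k = 1e6)
  expect_true(all(!duplicated(paste(resAll$gene_a, resAll$gene_b))))
  expect_true(all(paste(resAll$gene_a, resAll$gene_b) %in% want))
  ## disjoint ortholog map: empty result
  om <- OrthologMap("nopeA", "nopeB")
  resNone <- conservedRegionalTFs(callsReg, ann$calls_b, om,
                                  ann$tf_genes, ann$tf_b, ann$region_pairing,
                                  regionOf, ann$region_of_b,
                                  fixtureProfile(), k = 5)
  expect_equal(nrow(resNone), 0)
})
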