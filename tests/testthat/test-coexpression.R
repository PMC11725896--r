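# direct Gaussian factor-model expression: n_mod modules with within-module
# correlation rho across n_samp samples, plus optional unstructured genes
makeFactorExpr <- function(sizes, rho, n_samp = 16, n_noise = 0, seed = 1) {
  set.seed(seed)
  mats <- lapply(seq_along(sizes), function(m) {
    f <- rnorm(n_samp)
    t(sapply(seq_len(sizes[m]), function(i)
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samp)))
  })
  expr <- do.call(rbind, mats)
  if (n_noise > 0)
    expr <- rbind(expr, matrix(rnorm(n_noise * n_samp), n_noise, n_samp))
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", seq_len(n_samp))
  attr(expr, "truth") <- rep(c(seq_along(sizes),
                               rep(0, n_noise > 0)[0]), c(sizes, integer(0)))
  expr
}

test_that("soft-threshold selection follows the scale-free criterion", {
  set.seed(51)
  ## all genes copies of one profile: trivially satisfied at the lowest power
  x <- rnorm(16)
  expr <- t(sapply(1:50, function(i) x + rnorm(16, 0, 1e-4)))
  rownames(expr) <- paste0("g", 1:50); colnames(expr) <- paste0("s", 1:16)
  sft <- pickSoftThreshold(expr)
  expect_equal(sft$power, 1)
  expect_true(sft$reached_target)
  expect_equal(nrow(sft$fit_table), 20)

  ## independent noise over a moderate power grid: target unreachable,
  ## argmax fallback flagged (very high powers can satisfy the criterion
  ## spuriously on unstructured data, which is why the flag matters)
  noise <- matrix(rnorm(400 * 16), 400, 16,
                  dimnames = list(paste0("g", 1:400), paste0("s", 1:16)))
  sftN <- pickSoftThreshold(noise, powers = 1:6)
  expect_false(sftN$reached_target)
  expect_true(all(sftN$fit_table$r_squared < 0.8))
  expect_equal(sftN$power, sftN$fit_table$power[which.max(sftN$fit_table$r_squared)])

  expect_error(pickSoftThreshold(noise[, 1:5]), ">= 8 samples")
})

test_that("adjacency follows the power and sign rules", {
  s <- seq(-1, 1, length.out = 9)
  x <- rnorm(12)
  expr <- rbind(a = x, b = x, c = -x + rnorm(12, 0, 1e-8))
  A <- adjacencyMatrix(expr, power = 6)
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], 1, tolerance = 1e-5)  # unsigned: |-1|^6
  Ah <- adjacencyMatrix(expr, power = 6, network_type = "signed_hybrid")
  expect_equal(Ah["a", "c"], 0)

  ## hand arithmetic: cor 0.5 at power 6
  y <- c(1, 2, 3, 4); z <- c(2, 1, 4, 3)     # cor(y, z) = 0.8: build 0.5 pair
  expect_equal(0.5^6, 0.015625)
  e2 <- rbind(u = c(1, 0, 1, 0, 1, 0, 1, 2),
              v = c(0, 1, 1, 0, 0, 1, 1, 2))
  r <- cor(e2["u", ], e2["v", ])
  expect_equal(adjacencyMatrix(e2, 6)["u", "v"], abs(r)^6)

  expr0 <- rbind(a = x, flat = rep(1, 12))
  expect_error(adjacencyMatrix(expr0, 6), "zero-variance")
})

test_that("topological overlap matches direct formula evaluation", {
  ## 3 nodes, all off-diagonal 0.5: TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  A <- matrix(0.5, 3, 3); diag(A) <- 1
  expect_equal(tomSimilarity(A)[1, 2], 0.5)
  ## isolated perfect pair: TOM = 1
  B <- diag(4); B[1, 2] <- B[2, 1] <- 1
  expect_equal(tomSimilarity(B)[1, 2], 1)
  ## random valid matrices against the triple-loop oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:8, 1)
    M <- matrix(runif(n * n), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    tom <- tomSimilarity(M)
    expect_lt(max(abs(tom - tomBrute(M))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(unname(tom)))
  }
  expect_error(tomSimilarity(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(tomSimilarity(bad), "0, 1")
})

test_that("module cutting recovers planted blocks and ignores noise", {
  ## two clean blocks of 40
  expr <- makeFactorExpr(c(40, 40), rho = 0.9, seed = 52)
  A <- adjacencyMatrix(expr, 6)
  diss <- 1 - tomSimilarity(A); diag(diss) <- 0
  lab <- cutModules(diss, min_module_size = 30, expr = expr)
  expect_equal(ari(rep(1:2, each = 40), lab), 1)

  ## pure noise: nothing of module size
  noise <- matrix(rnorm(300 * 16), 300, 16,
                  dimnames = list(paste0("g", 1:300), paste0("s", 1:16)))
  An <- adjacencyMatrix(noise, 6)
  dn <- 1 - tomSimilarity(An); diag(dn) <- 0
  labN <- cutModules(dn, min_module_size = 30, expr = noise)
  expect_true(all(labN == "unassigned"))

  ## one block of 10 below the size threshold
  small <- makeFactorExpr(10, rho = 0.9, seed = 53)
  ds <- 1 - tomSimilarity(adjacencyMatrix(small, 6)); diag(ds) <- 0
  expect_warning(labS <- cutModules(ds, min_module_size = 30, expr = small),
                 "min_module_size")
  expect_true(all(labS == "unassigned"))

  expect_warning(labT <- cutModules(ds, min_module_size = 100),
                 "min_module_size")
  expect_true(all(labT == "unassigned"))
})

test_that("eigengenes equal the SVD oracle and dominate single members", {
  set.seed(54)
  x <- rnorm(12)
  exprSame <- t(sapply(1:5, function(i) 3 * x + 10))
  rownames(exprSame) <- paste0("g", 1:5)
  colnames(exprSame) <- paste0("s", 1:12)
  eg <- moduleEigengene(exprSame, rownames(exprSame))
  expect_equal(unname(eg), unname(as.numeric(scale(x))), tolerance = 1e-8)

  ## antiphase pair: sign rule keeps mean member correlation non-negative
  expr2 <- rbind(a = x, b = -x)
  colnames(expr2) <- paste0("s", 1:12)
  eg2 <- moduleEigengene(expr2, c("a", "b"))
  expect_equal(abs(cor(eg2, x)), 1, tolerance = 1e-8)
  expect_gte(mean(cor(eg2, t(expr2))), 0)

  ## random module vs full SVD oracle, up to sign
  expr3 <- matrix(rnorm(5 * 12), 5, 12,
                  dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  eg3 <- moduleEigengene(expr3, rownames(expr3))
  sv <- svd(t(scale(t(expr3))))
  oracle <- sv$v[, 1] / sd(sv$v[, 1])
  expect_equal(abs(cor(eg3, oracle)), 1, tolerance = 1e-10)
  expect_equal(sd(eg3), 1)

  ## first-PC optimality: explains at least as much member variance as any
  ## single member profile used as a summary
  expr4 <- makeFactorExpr(8, rho = 0.6, n_samp = 12, seed = 55)
  eg4 <- moduleEigengene(expr4, rownames(expr4))
  r2 <- function(v) mean(cor(v, t(expr4))^2)
  expect_gte(r2(eg4) + 1e-12, max(apply(expr4, 1, r2)))

  expect_error(moduleEigengene(exprSame, "g1"), "members")
})

test_that("module merging is correlation-driven and order-independent", {
  set.seed(56)
  f <- rnorm(16)
  mkMod <- function(f, n) t(sapply(1:n, function(i) f + rnorm(16, 0, 0.1)))
  ## modules a,b nearly identical (eigengene cor ~0.99), c independent
  expr <- rbind(mkMod(f, 30), mkMod(f, 30), mkMod(rnorm(16), 30))
  rownames(expr) <- paste0("g", 1:90)
  colnames(expr) <- paste0("s", 1:16)
  lab <- setNames(rep(c("M1", "M2", "M3"), each = 30), rownames(expr))
  merged <- mergeModules(expr, lab, merge_cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged), "unassigned")), 2)
  expect_equal(length(unique(merged[1:60])), 1)

  ## eigengene correlation 0.5 does not merge at cut height 0.25
  f2 <- rnorm(16)
  g2 <- sqrt(0.25) * f2 + sqrt(0.75) * rnorm(16)  # cor ~0.5
  expr2 <- rbind(mkMod(f2, 30), mkMod(g2, 30))
  rownames(expr2) <- paste0("g", 1:60); colnames(expr2) <- paste0("s", 1:16)
  lab2 <- setNames(rep(c("M1", "M2"), each = 30), rownames(expr2))
  merged2 <- mergeModules(expr2, lab2, merge_cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged2), "unassigned")), 2)

  ## processing order does not matter: permute module ids and gene order
  perm <- sample(rownames(expr))
  lab3 <- setNames(c(M1 = "M3", M2 = "M1", M3 = "M2")[lab[perm]], perm)
  merged3 <- mergeModules(expr[perm, ], lab3, merge_cut_height = 0.25)
  part <- function(l) {
    grp <- lapply(split(names(l), l), sort)
    unname(grp[order(vapply(grp, `[[`, character(1), 1))])
  }
  expect_identical(part(merged), part(merged3))
})

test_that("planted modules with correlation 0.8 are recovered after merging", {
  sizes <- c(40, 50, 60, 70, 80)
  expr <- makeFactorExpr(sizes, rho = 0.8, n_samp = 16, n_noise = 300,
                         seed = 57)
  mods <- buildCoexpressionModules(expr)
  truth <- rep(seq_along(sizes), sizes)
  planted <- rownames(expr)[seq_len(sum(sizes))]
  expect_gte(ari(truth, moduleLabels(mods)[planted]), 0.9)
  ## deterministic: a rerun is identical
  mods2 <- buildCoexpressionModules(expr)
  expect_identical(moduleLabels(mods), moduleLabels(mods2))
  expect_equal(moduleEigengenes(mods), moduleEigengenes(mods2))
})

test_that("spatial classification separates specific, regional, shared", {
  members <- paste0("g", 1:10)
  eg <- setNames(c(3, 2.5, rep(-0.5, 6)),
                 paste(rep(c("SC-EPD", "EP", "SUS", "OI"), each = 2),
                       rep(c("glob", "cot"), 4), sep = "."))
  callsSub <- data.frame(gene_id = paste0("g", 1:8), stage = "cot",
                         focal_subregion = "SC-EPD", scope = "subregion",
                         min_fold_change = 6, max_fdr = 1e-4)
  callsReg <- callsSub
  cl <- classifyModuleSpatial(members, eg, callsSub, callsReg)
  expect_equal(cl$spatial_class, "subregion_specific")
  expect_equal(cl$focal_subregion, "SC-EPD")
  expect_equal(cl$fraction_members_specific, 0.8)

  ## members split across three regions: shared
  callsSplit <- data.frame(gene_id = paste0("g", 1:9), stage = "cot",
                           focal_subregion = rep(c("SC-EPD", "EP", "OI"), 3),
                           scope = "subregion",
                           min_fold_change = 6, max_fdr = 1e-4)
  cl2 <- classifyModuleSpatial(members, eg, callsSplit, callsSplit)
  expect_equal(cl2$spatial_class, "shared")
  expect_true(is.na(cl2$focal_subregion))
})

test_that("the synthetic seed's planted modules are recovered and localized", {
  mods <- fixtureModules()
  truth <- fixtureBulk()$truth
  planted <- unlist(truth$module_members)
  tl <- rep(names(truth$module_members), lengths(truth$module_members))
  expect_gte(ari(tl, moduleLabels(mods)[planted]), 0.9)
  ## every planted module maps to a detected module classified to its
  ## focal subregion
  cls <- moduleClassification(mods)
  mem <- moduleMembers(mods)
  for (m in names(truth$module_members)) {
    ov <- vapply(mem, function(g)
      length(intersect(g, truth$module_members[[m]])), integer(1))
    hit <- names(ov)[which.max(ov)]
    expect_equal(cls$focal_subregion[cls$module_id == hit],
                 unname(truth$module_subregion[m]))
    expect_equal(cls$spatial_class[cls$module_id == hit],
                 "subregion_specific")
  }
})
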