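test_that("shannonEntropy handles the canonical profiles", {
  expect_equal(shannonEntropy(rep(1/5, 5)), log2(5))
  expect_equal(shannonEntropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannonEntropy(c(0.5, 0.5, 0, 0, 0)), 1)
  expect_error(shannonEntropy(c(0.5, 0.2)), class = "crossGEx_validation_error")
  expect_error(shannonEntropy(c(-0.5, 1.5)), class = "crossGEx_validation_error")
})

test_that("entropy agrees with a brute-force loop and an external implementation", {
  set.seed(101)
  for (i in 1:200) {
    p <- fuzzProfile(sample(2:12, 1))
    brute <- 0
    for (pi in p) if (pi > 0) brute <- brute - pi * log2(pi)
    expect_equal(shannonEntropy(p), brute, tolerance = 1e-12)
  }
  if (requireNamespace("vegan", quietly = TRUE)) {
    p <- fuzzProfile(8)
    expect_equal(shannonEntropy(p),
                 vegan::diversity(p, index = "shannon") / log(2),
                 tolerance = 1e-10)
  }
})

test_that("entropy is permutation invariant and specificity Schur-convex", {
  set.seed(102)
  for (i in 1:50) {
    p <- fuzzProfile(6)
    expect_equal(shannonEntropy(p), shannonEntropy(sample(p)))
    # move mass from a smaller to a larger atom: specificity cannot drop
    o <- order(p)
    eps <- p[o[1]] * runif(1)
    q <- p
    q[o[1]] <- q[o[1]] - eps
    q[o[6]] <- q[o[6]] + eps
    s1 <- geneDiversitySpecificity(p)[["specificity"]]
    s2 <- geneDiversitySpecificity(q)[["specificity"]]
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("gene diversity/specificity hits the extremes and the derived case", {
  u <- geneDiversitySpecificity(rep(1/7, 7))
  expect_equal(u[["diversity"]], 1)
  expect_equal(u[["specificity"]], 0)

  oh <- geneDiversitySpecificity(c(0, 0, 1, 0))
  expect_equal(oh[["diversity"]], 0)
  expect_equal(oh[["specificity"]], 1)

  # two equal atoms over 5 categories: D = 1/log2(5)
  ds <- geneDiversitySpecificity(c(0.5, 0.5, 0, 0, 0))
  expect_equal(ds[["diversity"]], 1 / log2(5), tolerance = 1e-12)
  expect_equal(ds[["specificity"]], 1 - 1 / log2(5), tolerance = 1e-12)

  expect_error(geneDiversitySpecificity(1), class = "crossGEx_usage_error")
})

test_that("tissue metrics match a hand-rolled double loop on a 3x3 instance", {
  w <- rbind(g1 = c(8, 1, 1), g2 = c(1, 8, 1), g3 = c(1, 1, 8))
  colnames(w) <- paste0("t", 1:3)

  # independent oracle: explicit loops over the defining sums
  oracle <- function(w, t) {
    G <- nrow(w); Tn <- ncol(w)
    q <- w[, t] / sum(w[, t])
    H <- 0
    for (g in 1:G) if (q[g] > 0) H <- H - q[g] * log2(q[g])
    spec <- 0
    for (g in 1:G) {
      p <- w[g, ] / sum(w[g, ])
      Hg <- 0
      for (x in p) if (x > 0) Hg <- Hg - x * log2(x)
      spec <- spec + q[g] * (log2(Tn) - Hg)
    }
    c(diversity = unname(H) / log2(G), specificity = unname(spec) / log2(Tn))
  }

  vals <- sapply(colnames(w), function(t) tissueDiversitySpecificity(w, t))
  for (t in colnames(w))
    expect_equal(tissueDiversitySpecificity(w, t), oracle(w, t),
                 tolerance = 1e-12)
  # symmetric design: specificity equal across the three tissues
  expect_equal(diff(range(vals["specificity", ])), 0, tolerance = 1e-12)

  # all genes one-hot on t1, equal-valued: tissue1 specificity = 1
  oneHot <- rbind(g1 = c(1, 0, 0), g2 = c(1, 0, 0), g3 = c(1, 0, 0))
  colnames(oneHot) <- paste0("t", 1:3)
  expect_equal(tissueDiversitySpecificity(oneHot, "t1")[["specificity"]], 1)
  expect_equal(tissueDiversitySpecificity(oneHot, "t1")[["diversity"]], 1)

  # all genes uniform: every tissue's specificity is 0
  unif <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("t", 1:3)))
  for (t in colnames(unif))
    expect_equal(tissueDiversitySpecificity(unif, t)[["specificity"]], 0)

  # all-zero column: missing with a reason
  zero <- rbind(g1 = c(0, 1, 1), g2 = c(0, 1, 2))
  colnames(zero) <- paste0("t", 1:3)
  out <- tissueDiversitySpecificity(zero, "t1")
  expect_true(all(is.na(out)))
  expect_equal(attr(out, "reason"), "all_zero_column")
})

test_that("computeCV follows the sd-over-median contract", {
  expect_equal(computeCV(c(4, 4, 4)), 0)
  expect_equal(computeCV(c(2, 4, 6)), 0.5)  # sd (n-1) = 2, median = 4

  set.seed(103)
  for (i in 1:30) {
    x <- rnorm(8, mean = 10)
    c1 <- computeCV(x)
    expect_equal(computeCV(x * runif(1, 0.1, 50)), c1, tolerance = 1e-12)
    expect_true((c1 == 0) == (length(unique(x)) == 1L))
  }

  short <- computeCV(3)
  expect_true(is.na(short))
  expect_equal(attr(short, "reason"), "insufficient_values")
  zm <- computeCV(c(-1, 0, 1))
  expect_true(is.na(zm))
  expect_equal(attr(zm, "reason"), "zero_median")
})

test_that("cvAnalysis computes per-gene CV across tissue or species medians", {
  # identical medians across tissues -> cv 0
  rec <- expand.grid(gene_id = "g1", species = c("human", "mouse"),
                     tissue = paste0("t", 1:5), sample_id = paste0("s", 1:3),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$value <- 5
  rec2 <- rec; rec2$gene_id <- "g2"
  rec2$value <- 5 + as.integer(factor(rec2$tissue))
  tab <- ExpressionTable(rbind(rec, rec2), "vst")

  cv <- cvAnalysis(tab, mode = "cv_tissue")
  expect_equal(nrow(cv), 4L)  # 2 genes x 2 species
  expect_equal(cv$cv[cv$gene_id == "g1"], c(0, 0))
  expect_true(all(cv$cv[cv$gene_id == "g2"] > 0))
  expect_true(all(cv$n_values == 5L))

  # cv_species over equal medians -> 0; reference species carried
  cvs <- cvAnalysis(tab, mode = "cv_species")
  g1rows <- cvs[cvs$gene_id == "g1", ]
  expect_equal(g1rows$cv, rep(0, 5))
  expect_setequal(unique(cvs$species), "human")
  expect_setequal(cvs$group_label, paste0("t", 1:5))

  expect_error(cvAnalysis(makeExampleExpression(1), mode = "cv_tissue"),
               class = "crossGEx_usage_error")  # not vst scale
})

test_that("cv_species reports genes missing in a species instead of dropping them", {
  rec <- expand.grid(gene_id = c("g1", "g2"), species = c("human", "mouse"),
                     tissue = "t1", sample_id = paste0("s", 1:2),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$value <- rnorm(nrow(rec), 10)
  rec <- rec[!(rec$gene_id == "g2" & rec$species == "mouse"), ]
  tab <- ExpressionTable(rec, "vst")
  cvs <- cvAnalysis(tab, mode = "cv_species")
  g2 <- cvs[cvs$gene_id == "g2", ]
  expect_true(is.na(g2$cv))
  expect_equal(g2$reason, "insufficient_values")
})

test_that("dsAnalysis modes slice consistently and honor degeneracy rules", {
  vst <- exampleVst(seed = 2)

  full <- dsAnalysis(vst, mode = "ds_gene_all")
  expect_equal(nrow(full), 10L)  # 5 genes x 2 species
  expect_true(all(full$diversity >= 0 & full$diversity <= 1))
  expect_true(all(full$specificity >= 0 & full$specificity <= 1))

  # ds_gene with the full tissue set equals ds_gene_all
  allTissues <- sort(unique(exprData(vst)$tissue))
  sel <- dsAnalysis(vst, SelectionSpec(tissues = allTissues), mode = "ds_gene")
  expect_equal(sel$diversity, full$diversity)
  expect_equal(sel$specificity, full$specificity)

  # constant nonzero gene row: uniform by convention, flagged
  m <- rbind(flatg = c(4, 4, 4), other = c(1, 2, 3))
  colnames(m) <- paste0("t", 1:3)
  mm <- new("MedianMatrix", values = m, axis = "tissue", context = "human")
  res <- dsAnalysis(mm, mode = "ds_gene")
  flat <- res[res$unit_id == "flatg", ]
  expect_equal(flat$diversity, 1)
  expect_equal(flat$specificity, 0)
  expect_equal(flat$flags, "degenerate_uniform")

  # gene with nonzero scaled value in exactly one tissue: specificity 1
  oneT <- res[res$unit_id == "other", ]  # scaled (0, .5, 1) -> not one-hot
  m2 <- rbind(g1 = c(0, 0, 9), g2 = c(5, 2, 1))
  colnames(m2) <- paste0("t", 1:3)
  mm2 <- new("MedianMatrix", values = m2, axis = "tissue", context = "human")
  res2 <- dsAnalysis(mm2, mode = "ds_gene")
  expect_equal(res2$specificity[res2$unit_id == "g1"], 1)

  # all-zero row: missing with flag
  m3 <- rbind(g0 = c(0, 0, 0), g2 = c(5, 2, 1))
  colnames(m3) <- paste0("t", 1:3)
  res3 <- dsAnalysis(new("MedianMatrix", values = m3, axis = "tissue",
                         context = "human"), mode = "ds_gene")
  g0 <- res3[res3$unit_id == "g0", ]
  expect_true(is.na(g0$diversity))
  expect_equal(g0$flags, "all_zero")

  # tissue mode returns one row per tissue per species
  tis <- dsAnalysis(vst, mode = "ds_tissue_all")
  expect_equal(nrow(tis), 10L)  # 5 tissues x 2 species
  expect_true(all(tis$unit == "tissue"))
})
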