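# Devog acceleration statistics, FDR control, rank-sum comparisons,
# size trends, GO enrichment and dissimilarity clustering.

test_that("log-omega policy excludes zero and undefined ratios", {
  expect_equal(safe_log_omega(1), 0)
  expect_equal(safe_log_omega(exp(1)), 1)
  expect_true(is.na(safe_log_omega(0)))
  expect_true(is.na(safe_log_omega(NA)))
  expect_error(safe_log_omega(-0.1), "non-negative")
})

test_that("one-gene Devog t test matches hand computation and t.test", {
  # mammal mean equals the avian value: zero numerator
  r0 <- devog_gene_test(-2, c(-1, -2, -3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # frozen hand-computed case: mean -2, sd sqrt(0.8), se 0.3651, df 5
  r <- devog_gene_test(-1, c(-1, -2, -3, -1, -2, -3))
  expect_equal(r$t, -2.7386, tolerance = 1e-4)
  expect_equal(r$p, 0.0409, tolerance = 1e-3)
  expect_equal(r$df, 5)

  # independent implementation: one-sample t.test with mu = avian value
  set.seed(10)
  for (i in 1:20) {
    m <- rnorm(sample(3:8, 1))
    av <- rnorm(1)
    mine <- devog_gene_test(av, m)
    ref <- t.test(m, mu = av)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # zero-variance mammalian sample is flagged degenerate
  dg <- devog_gene_test(-1, c(-2, -2, -2))
  expect_true(dg$degenerate)
  expect_equal(dg$p, 0)
  expect_error(devog_gene_test(NA, c(1, 2)), "defined")
})

test_that("paired lineage test: hand case, antisymmetry, t.test oracle", {
  same <- lineage_paired_test(c(h = 1, m = 2), c(h = 1, m = 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")

  # frozen: differences 0.2, 0.1, 0.3, 0.2 -> t = 4.899, p ~ 0.016, df 3
  tk <- c(h = 1.2, m = 1.1, d = 1.3, o = 1.2)
  ck <- c(h = 1.0, m = 1.0, d = 1.0, o = 1.0)
  r <- lineage_paired_test(tk, ck)
  expect_equal(r$t, 4.899, tolerance = 1e-3)
  expect_equal(r$p, 0.01628, tolerance = 1e-3)
  expect_equal(r$direction, "turkey")

  swapped <- lineage_paired_test(ck, tk)
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
  expect_equal(swapped$direction, "chicken")

  set.seed(11)
  a <- rnorm(5); b <- rnorm(5)
  names(a) <- names(b) <- letters[1:5]
  mine <- lineage_paired_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  expect_error(lineage_paired_test(c(x = 1, y = 2), c(x = 1, z = 2)),
               "mammal species")
})

test_that("Benjamini-Hochberg step-up: frozen vector, ties, permutation
           invariance, never below raw p", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(12)
  p <- runif(50)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  perm <- sample(50)
  expect_equal(adjust_bh(p[perm]), adj[perm])
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_devogs flags planted acceleration and assigns lineages", {
  om <- gen_omega_table(400, accel_fraction = 0.15, effect = 8, seed = 31)
  res <- call_devogs(om$omega, q = 0.05)
  truth <- om$truth
  tp <- sum(res$accelerated &
              truth$accelerated[match(res$gene_id, truth$gene_id)])
  expect_gte(tp / sum(truth$accelerated), 0.9)
  # lineage recovery among detected accelerated genes with a strong effect
  acc <- res[res$accelerated &
               truth$accelerated[match(res$gene_id, truth$gene_id)], ]
  want <- truth$lineage[match(acc$gene_id, truth$gene_id)]
  expect_gt(mean(acc$lineage == want), 0.8)

  # q = 1 flags every testable gene
  all_in <- call_devogs(om$omega, q = 1)
  expect_true(all(all_in$accelerated[!all_in$excluded]))
  expect_error(call_devogs(om$omega, q = 0), "q must")
})

test_that("genes with omega = 0 in a needed pair are excluded, not broken", {
  om <- gen_omega_table(20, seed = 2)$omega
  om$omega[om$gene_id == "g00001" & om$role == "avian"] <- 0
  res <- call_devogs(om)
  expect_true(res$excluded[res$gene_id == "g00001"])
  expect_true(is.na(res$p[res$gene_id == "g00001"]))
  expect_equal(sum(res$excluded), 1)
})

test_that("wilcoxon: exact enumeration example, symmetry, oracle", {
  r <- wilcoxon_group_compare(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$p, 1 / 3)

  same <- wilcoxon_group_compare(c(5, 6, 7), c(5, 6, 7), mode = "exact")
  expect_equal(same$p, 1)

  a <- c(0.1, 0.9, 0.4); b <- c(0.5, 0.2)
  expect_equal(wilcoxon_group_compare(a, b, mode = "exact")$p,
               wilcoxon_group_compare(b, a, mode = "exact")$p)

  # tie-free exact p equals the reference implementation for all small sizes
  set.seed(13)
  for (i in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(seq(0.01, 1, by = 0.01), na + nb)  # no ties
    a <- x[1:na]; b <- x[-(1:na)]
    mine <- wilcoxon_group_compare(a, b, mode = "exact")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  expect_error(wilcoxon_group_compare(numeric(0), 1), "non-empty")
})

test_that("approximate wilcoxon agrees with the reference on larger groups", {
  set.seed(14)
  a <- rexp(30); b <- rexp(40) * 1.4
  mine <- wilcoxon_group_compare(a, b, mode = "approximate")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
})

test_that("size trends: monotone case, constant case, formula oracle", {
  df <- data.frame(chromosome = rep(c("c1", "c2", "c3", "c4"), each = 5),
                   length = rep(c(2e8, 1e8, 5e7, 1e7), each = 5),
                   value = rep(c(0.1, 0.2, 0.3, 0.4), each = 5))
  tr <- size_trend(df, "dS")
  expect_equal(tr$spearman, -1)
  expect_lt(tr$slope, 0)

  flat <- df; flat$value <- 0.25
  expect_equal(size_trend(flat)$slope, 0)

  set.seed(15)
  rnd <- data.frame(chromosome = rep(paste0("c", 1:6), each = 7),
                    length = rep(10^runif(6, 6.5, 8.3), each = 7),
                    value = rexp(42, 5))
  tr2 <- size_trend(rnd)
  med <- tapply(rnd$value, rnd$chromosome, median)
  l2 <- log2(rnd$length[!duplicated(rnd$chromosome)])
  names(l2) <- rnd$chromosome[!duplicated(rnd$chromosome)]
  l2 <- l2[names(med)]
  expect_equal(tr2$pearson, cor(l2, med), tolerance = 1e-12)
  expect_equal(tr2$spearman, cor(l2, med, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(tr2$slope, unname(coef(lm(med ~ l2))[2]), tolerance = 1e-10)

  expect_error(size_trend(df[df$chromosome %in% c("c1", "c2"), ]), ">= 3")
})

test_that("GO over-representation: hypergeometric tail with BH across terms", {
  bg <- paste0("g", 1:10)
  terms <- list(T1 = bg[1:5], ALL = bg)
  res <- go_overrepresentation(bg[1:5], bg, terms)
  expect_equal(res$p[res$term == "T1"], 1 / choose(10, 5))
  expect_equal(res$p[res$term == "ALL"], 1)

  none <- go_overrepresentation(character(0), bg, terms)
  expect_true(all(none$p == 1))
  expect_error(go_overrepresentation("zz", bg, terms), "outside background")
})

test_that("GO dissimilarity: bounds, symmetry, containment zero", {
  expect_equal(go_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(go_dissimilarity(c("a", "b"), c("c", "d")), 1)
  expect_equal(go_dissimilarity(c("a", "b"), c("a", "c", "d", "e")), 0.5)
  # zero iff the smaller set is contained in the larger
  expect_equal(go_dissimilarity(c("a", "b"), c("a", "b", "c")), 0)
  expect_gt(go_dissimilarity(c("a", "x"), c("a", "b", "c")), 0)
  set.seed(16)
  for (i in 1:20) {
    x <- sample(letters, sample(2:8, 1))
    y <- sample(letters, sample(2:8, 1))
    d <- go_dissimilarity(x, y)
    expect_equal(d, go_dissimilarity(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(go_dissimilarity(character(0), "a"), "empty")
})

test_that("average-linkage clustering: small cases and hclust equivalence", {
  one <- average_linkage_cluster(matrix(0, 1, 1))
  expect_equal(nrow(one$merge), 0)

  two <- average_linkage_cluster(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_equal(two$height, 0.3)
  expect_equal(sort(two$merge[1, ]), c(-2L, -1L))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(average_linkage_cluster(asym), "symmetric")

  # random tie-free matrices up to 7 items: merge heights equal the
  # reference average-linkage implementation
  set.seed(17)
  for (i in 1:25) {
    n <- sample(3:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample(seq(0.01, 1, by = 0.0001), n * (n - 1) / 2)
    d <- d + t(d)
    mine <- average_linkage_cluster(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    # same partitions at every merge level (up to label renaming)
    for (k in 2:n) {
      tab <- table(cutree(mine$as_hclust, k), cutree(ref, k))
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    }
  }
})
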