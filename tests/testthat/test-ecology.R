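test_that("relative abundance normalizes columns and supports rank collapse", {
  counts <- matrix(c(10, 30), 2, 1,
                   dimnames = list(c("a1", "a2"), "s1"))
  rel <- relative_abundance(counts)
  expect_equal(unname(rel[, 1]), c(0.25, 0.75))
  tax <- c("Bacteria;P1;C1", "Bacteria;P1;C1")
  col <- relative_abundance(counts, tax, collapse_rank = 3)
  expect_equal(nrow(col), 1)
  expect_equal(unname(col[1, 1]), 1)
  counts0 <- cbind(counts, s2 = c(0, 0))
  expect_error(relative_abundance(counts0), "s2")
})

test_that("chloroplast-classified rows are discarded case-insensitively", {
  counts <- matrix(1, 3, 1,
                   dimnames = list(c("a", "b", "c"), "s"))
  tax <- c("Bacteria;Cyanobacteria;Chloroplast", "Bacteria;P;C",
           "Eukaryota;x;CHLOROPLAST;y")
  expect_equal(rownames(drop_chloroplast_asvs(counts, tax)), "b")
})

test_that("Shannon index matches closed forms and bounds", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4))
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_index(c(0.5, 0.5), base = 2), 1)
  expect_error(shannon_index(c(0.7, 0.2)), "sum")
  expect_error(shannon_index(c(1.2, -0.2)), "non-negative")
})

test_that("Bray-Curtis hand cases and metric properties", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 1), c(1, 3)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(13)
  for (i in 1:200) {
    x <- rpois(6, 5); y <- rpois(6, 5)
    if (sum(x) + sum(y) == 0) next
    bc <- bray_curtis(x, y)
    expect_gte(bc, 0); expect_lte(bc, 1)
    expect_equal(bc, bray_curtis(y, x))
  }
})

test_that("Shannon and Bray-Curtis agree with vegan on random tables", {
  skip_if_not_installed("vegan")
  set.seed(41)
  counts <- matrix(rpois(80, 20), 10, 8,
                   dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  rel <- relative_abundance(counts)
  expect_equal(unname(apply(rel, 2, shannon_index)),
               unname(vegan::diversity(t(counts), "shannon")),
               tolerance = 1e-12)
  bc <- bray_curtis_matrix(counts)
  expect_equal(as.numeric(as.dist(bc)),
               as.numeric(vegan::vegdist(t(counts), "bray")),
               tolerance = 1e-12)
})

test_that("average linkage agrees with an independent implementation on random matrices", {
  set.seed(53)
  for (i in 1:100) {
    n <- 5
    x <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    tree <- average_linkage(d)
    ref <- hclust(as.dist(d), method = "average")
    expect_equal(sort(tree$height), sort(ref$height), tolerance = 1e-9)
    expect_equal(as.numeric(cophenetic(tree)),
                 as.numeric(cophenetic(ref)), tolerance = 1e-9)
  }
})

test_that("UPGMA handles trivial and tied inputs deterministically", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- average_linkage(d2)
  expect_equal(t2$height, 0.4)
  # identical samples merge first at height zero
  d3 <- matrix(c(0, 0, 0.8,
                 0, 0, 0.8,
                 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- average_linkage(d3)
  expect_equal(t3$height[1], 0)
  # fully tied distances: lexicographically smallest labels merge first
  d4 <- matrix(0.5, 4, 4,
               dimnames = list(c("d", "b", "c", "a"),
                               c("d", "b", "c", "a")))
  diag(d4) <- 0
  t4 <- average_linkage(d4)
  first <- sort(t4$labels[-t4$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_error(average_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
})

test_that("Newick export encodes ultrametric half-height branch lengths", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.8,
                0.6, 0.8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- average_linkage(d)
  nwk <- as_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
  expect_match(nwk, "c:0.35")   # root height 0.7, leaf depth h/2
  expect_match(nwk, "a:0.1")
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("a", "b", "c"))
  depths <- ape::node.depth.edgelength(ph)[1:3]
  expect_equal(depths, rep(0.35, 3), tolerance = 1e-9)
})

test_that("rank tests behave at boundaries and separate clear shifts", {
  res <- grouped_rank_test(rep(3, 8), rep(c("a", "b"), each = 4),
                           "kruskal_wallis")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- grouped_rank_test(c(1:10, 101:110),
                            rep(c("a", "b"), each = 10),
                            "wilcoxon_rank_sum")
  expect_lt(res2$p_value, 0.001)
  expect_error(grouped_rank_test(1:6, rep(c("a", "b", "c"), 2),
                                 "wilcoxon_rank_sum"), "exactly 2")
  expect_error(grouped_rank_test(1:3, c("a", "a", "a")), "two groups")
})

test_that("asymptotic rank-sum p-values track the exact null at small n", {
  # exact enumeration oracle via stats::wilcox.test exact mode
  set.seed(3)
  x <- c(1.2, 3.4, 2.2, 5.0); y <- c(2.0, 4.1, 6.3, 7.7)
  asym <- grouped_rank_test(c(x, y), rep(c("a", "b"), each = 4),
                            "wilcoxon_rank_sum")
  exact <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(asym$p_value, exact, tolerance = 0.35)
  expect_equal(asym$p_value > 0.05, exact > 0.05)
})

test_that("Kruskal-Wallis type-I error is calibrated at the nominal level", {
  set.seed(71)
  rej <- mean(replicate(1000, {
    v <- rnorm(15)
    grouped_rank_test(v, rep(c("a", "b", "c"), each = 5),
                      "kruskal_wallis")$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("indicator values match hand cases and the loop oracle", {
  groups <- c("A", "A", "B", "B")
  # present in every sample of A only -> perfect indicator
  counts <- rbind(t1 = c(5, 7, 0, 0),
                  t2 = c(4, 4, 4, 4),   # equal mean + full presence: 0.5
                  t3 = c(0, 9, 1, 1))
  res <- indval(counts, groups, n_permutations = 99, seed = 2)
  expect_equal(res$stat[1], 1.0)
  expect_equal(res$group[1], "A")
  expect_equal(res$stat[2], 0.5)
  oracle <- indval_oracle(counts, groups)
  expect_equal(res$stat, unname(oracle[, "stat"]))
  expect_error(indval(counts, groups, n_permutations = 50), "99")
  expect_error(indval(counts, c("A", "A", "A", "A")), "two groups")
})

test_that("permutation p-values approach the exhaustive enumeration", {
  set.seed(5)
  counts <- rbind(t1 = c(8, 6, 1, 0), t2 = c(2, 3, 2, 4),
                  t3 = c(0, 0, 5, 7))
  groups <- c("A", "A", "B", "B")
  res <- indval(counts, groups, n_permutations = 999, seed = 11)
  exh <- indval_exhaustive_p(counts, groups)
  for (i in seq_len(nrow(counts))) {
    se <- sqrt(exh[i] * (1 - exh[i]) / 999)
    expect_lt(abs(res$p_value[i] - exh[i]), 3 * se + 2 / 999)
  }
})

test_that("indval is bit-reproducible under a fixed seed", {
  set.seed(99)
  counts <- matrix(rpois(60, 4), 6, 10)
  groups <- rep(c("g1", "g2"), 5)
  r1 <- indval(counts, groups, 199, seed = 31)
  r2 <- indval(counts, groups, 199, seed = 31)
  expect_identical(r1, r2)
  r3 <- indval(counts, groups, 199, seed = 32)
  expect_false(identical(r1$p_value, r3$p_value))
})

test_that("indval null p-values are super-uniform", {
  set.seed(23)
  counts <- matrix(rpois(200 * 12, 5), 200, 12)
  groups <- rep(c("a", "b"), 6)
  res <- indval(counts, groups, n_permutations = 999, seed = 7)
  # one-sided KS: the empirical CDF must not lie significantly above
  # the uniform CDF (anti-conservative p-values)
  ks <- suppressWarnings(ks.test(res$p_value, "punif",
                                 alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(res$p_value <= 0.05),
             0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("depth layers split at 200 and 1000 m with boundaries shallow", {
  expect_equal(assign_depth_layer(2), "epipelagic")
  expect_equal(assign_depth_layer(200), "epipelagic")
  expect_equal(assign_depth_layer(700), "mesopelagic")
  expect_equal(assign_depth_layer(1000), "mesopelagic")
  expect_equal(assign_depth_layer(2500), "bathypelagic")
  expect_error(assign_depth_layer(-5), "non-negative")
})

test_that("prototroph share sums mapped prototroph proportions only", {
  rel <- matrix(c(0.20, 0.15, 0.40, 0.25), 4, 1,
                dimnames = list(c("p1", "p2", "x", "u"), "s1"))
  map <- c(p1 = "PROTOTROPH", p2 = "PROTOTROPH", x = "AUX_HMP")
  expect_equal(unname(prototroph_share(rel, map)), 0.35)
  expect_equal(unname(prototroph_share(rel, c(x = "AUX_HMP"))), 0)
})

test_that("planted community structure is recovered from simulated amplicons", {
  sim <- simulate_community_profile(seed = 29)
  rel <- relative_abundance(sim$asv$counts)
  omz <- sim$asv$samples$omz & sim$asv$samples$layer == "mesopelagic"
  aoa <- rel["AOA_prototroph", omz]
  expect_equal(unname(aoa), rep(0.24, sum(omz)), tolerance = 0.03)
  map <- setNames(b1_archetypes()$expected_category, b1_archetypes()$name)
  share <- prototroph_share(rel, map)
  expect_equal(unname(share[omz]),
               rep(unname(sim$truth$prototroph_share[omz][1]), sum(omz)),
               tolerance = 0.03)
  expect_gt(min(share[omz]), 0.30)
})
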