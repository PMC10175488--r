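test_that("Pearson distance matches the correlation formula", {
  m <- matrix(c(1, 2, 3,
                3, 2, 1,
                1, 2, 3), ncol = 3,
              dimnames = list(c("A sp", "B sp", "C sp"),
                              c("s1", "s2", "s3")))
  d <- as.matrix(pearson_distance(abund_tbl(m)))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 2)

  tbl <- random_abund(7, 9, seed = 12)
  m2 <- as.matrix(tbl[, -1])
  d2 <- as.matrix(pearson_distance(tbl))
  for (pair in list(c(1, 2), c(3, 7), c(4, 9))) {
    expect_equal(d2[pair[1], pair[2]],
                 1 - cor(m2[, pair[1]], m2[, pair[2]]),
                 tolerance = 1e-12)
  }

  const <- m
  const[, 2] <- 5
  expect_error(pearson_distance(abund_tbl(const)), "s2")
})

test_that("complete linkage merges in the expected order", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hcl_complete(d)
  expect_equal(hc$height, c(0.1, 0.9))
  first_pair <- sort(-hc$merge[1, ])
  expect_equal(first_pair, c(1, 2))

  expect_error(hcl_complete(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  # two samples: one merge at their distance
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("x", "y"), c("x", "y"))))
  hc2 <- hcl_complete(d2)
  expect_equal(hc2$height, 0.4)
})

test_that("cophenetic distances dominate input distances (complete linkage)", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(40), ncol = 4)
    d <- dist(x)
    hc <- hcl_complete(d)
    expect_true(all(stats::cophenetic(hc) >= d - 1e-12))
  }
})

test_that("degenerate dendrograms collapse to a single cluster", {
  # all samples (essentially) identical -> one cluster with everyone
  m <- matrix(rep(c(50, 30, 20), 6), nrow = 3,
              dimnames = list(c("A sp", "B sp", "C sp"), paste0("s", 1:6)))
  m_j <- abs(m + matrix(rnorm(18, sd = 1e-8), nrow = 3))  # break exact ties
  d <- pearson_distance(abund_tbl(m_j))
  hc <- hcl_complete(d)
  part <- extract_icsts(hc, d, min_support = 6)
  expect_equal(unique(part$cluster), "1")

  expect_warning(part2 <- extract_icsts(hc, d, min_support = 7),
                 "min_support")
  expect_equal(unique(part2$cluster), "1")
})

test_that("synthetic multi-state communities are recovered with high agreement", {
  sim <- gen_community(community_spec(
    800, default_icst_defs(), background_taxa = 9,
    dirichlet_concentration = 150, seed = 31
  ))
  fit <- fit_icsts(sim$abundance, sim$metadata, min_support = 0.046)
  expect_equal(nrow(fit$clusters), 8)
  joined <- dplyr::inner_join(fit$assignments, sim$metadata, by = "sample")
  assigned <- joined$cluster != "unassigned"
  agreement <- mclust::adjustedRandIndex(joined$cluster[assigned],
                                         joined$icst_true[assigned])
  expect_gt(agreement, 0.9)

  # each fitted cluster's top taxon matches the generator's dominant taxon
  top_taxon <- vapply(strsplit(fit$clusters$dominant_taxa, "; "),
                      `[`, character(1), 1)
  truth_by_name <- vapply(default_icst_defs(), function(d) {
    names(d$dominant)[1]
  }, character(1))
  names(truth_by_name) <- vapply(default_icst_defs(), `[[`, character(1),
                                 "name")
  # map fitted clusters to majority true state
  for (i in seq_len(nrow(fit$clusters))) {
    members <- fit$assignments$sample[fit$assignments$cluster ==
                                        fit$clusters$cluster[i]]
    true_state <- names(which.max(table(
      sim$metadata$icst_true[sim$metadata$sample %in% members]
    )))
    expect_equal(top_taxon[i], truth_by_name[[true_state]])
  }
})

test_that("partition is invariant to sample order", {
  sim <- gen_community(community_spec(60, default_icst_defs()[1:3],
                                      dirichlet_concentration = 150,
                                      seed = 13))
  fit1 <- fit_icsts(sim$abundance, min_support = 5)
  perm <- sample(2:ncol(sim$abundance))
  shuffled <- sim$abundance[, c(1, perm)]
  fit2 <- fit_icsts(shuffled, min_support = 5)
  p1 <- fit1$assignments
  p2 <- fit2$assignments[match(p1$sample, fit2$assignments$sample), ]
  expect_equal(mclust::adjustedRandIndex(p1$cluster, p2$cluster), 1)
})

test_that("naming uses dominant genera with collision disambiguation", {
  m <- matrix(c(45, 5, 12, 2), ncol = 2, nrow = 2, byrow = FALSE,
              dimnames = list(c("Bifidobacterium longum",
                                "Enterobacter hormaechei"),
                              c("s1", "s2")))
  # mean of B. longum = 28.5 > 10; E. hormaechei mean 3.5 < 10
  nm <- name_icst(c("s1", "s2"), abund_tbl(m))
  expect_equal(as.character(nm), "ICST-BI")

  m2 <- matrix(c(30, 20), ncol = 1,
               dimnames = list(c("Bifidobacterium breve",
                                 "Enterobacter hormaechei"), "s1"))
  nm2 <- name_icst("s1", abund_tbl(m2))
  expect_equal(as.character(nm2), "ICST-BI/EN")

  # two Prevotella species collapse to one code
  m3 <- matrix(c(30, 20), ncol = 1,
               dimnames = list(c("Prevotella copri", "Prevotella spp."),
                               "s1"))
  expect_equal(as.character(name_icst("s1", abund_tbl(m3))), "ICST-PR")

  # distinct genera sharing a code get a species-initial suffix
  m4 <- matrix(c(30, 20), ncol = 1,
               dimnames = list(c("Enterococcus faecalis",
                                 "Enterobacter hormaechei"), "s1"))
  nm4 <- name_icst("s1", abund_tbl(m4), collision_codes = "EN")
  expect_equal(as.character(nm4), "ICST-ENF/ENH")

  # nothing dominant
  m5 <- matrix(rep(5, 20), ncol = 1,
               dimnames = list(paste("Taxon", letters[1:20]), "s1"))
  expect_warning(nm5 <- name_icst("s1", abund_tbl(m5)), "ICST-NA")
  expect_equal(as.character(nm5), "ICST-NA")
})

test_that("health labels follow the PI fraction thresholds", {
  expect_equal(as.character(label_health(c(rep("PI", 85), rep("HI", 15)))),
               "Unhealthy")
  expect_equal(as.character(label_health(c(rep("PI", 19), rep("HI", 67),
                                           rep("RI", 14)))),
               "Healthy")
  expect_equal(as.character(label_health(c(rep("PI", 49), rep("HI", 50),
                                           rep("RI", 1)))),
               "Mixed")
  expect_equal(as.character(label_health(c(NA, NA))), "Unknown")
})

test_that("Bray-Curtis agrees with its formula and basic identities", {
  m <- matrix(c(10, 20, 0,
                10, 20, 0,
                0, 0, 30), ncol = 3,
              dimnames = list(c("A sp", "B sp", "C sp"),
                              c("s1", "s2", "s3")))
  d <- as.matrix(bray_curtis(abund_tbl(m)))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)  # disjoint supports

  tbl <- random_abund(6, 8, seed = 14)
  m2 <- as.matrix(tbl[, -1])
  d2 <- as.matrix(bray_curtis(tbl))
  for (pair in list(c(1, 2), c(2, 5), c(3, 8))) {
    expect_equal(d2[pair[1], pair[2]],
                 bc_formula(m2[, pair[1]], m2[, pair[2]]),
                 tolerance = 1e-12)
  }

  z <- cbind(m, z1 = 0, z2 = 0)
  expect_warning(dz <- bray_curtis(abund_tbl(z)), "all-zero")
  expect_equal(as.matrix(dz)["z1", "z2"], 0)
})

test_that("Bray-Curtis satisfies the triangle inequality on spot checks", {
  tbl <- random_abund(5, 9, seed = 15)
  d <- as.matrix(bray_curtis(tbl))
  combos <- utils::combn(9, 3)
  for (i in seq_len(ncol(combos))) {
    tri <- combos[, i]
    expect_lte(d[tri[1], tri[3]],
               d[tri[1], tri[2]] + d[tri[2], tri[3]] + 1e-12)
  }
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(16)
  pts <- matrix(rnorm(20), ncol = 2,
                dimnames = list(paste0("s", 1:10), NULL))
  d <- dist(pts)
  ord <- pcoa_ordination(d, k = 2)
  coords <- as.matrix(ord$coordinates[, -1])
  expect_equal(as.numeric(dist(coords)), as.numeric(d), tolerance = 1e-9)

  # collinear points: axis 1 carries all positive eigenvalue mass
  line <- matrix(c(0, 1, 2.5), ncol = 1,
                 dimnames = list(c("a", "b", "c"), NULL))
  ord2 <- pcoa_ordination(dist(line), k = 2)
  expect_equal(ord2$explained[1], 1)

  # duplicate samples map to identical coordinates
  dup <- rbind(pts, s11 = pts[1, ])
  ord3 <- pcoa_ordination(dist(dup), k = 2)
  c3 <- as.matrix(ord3$coordinates[, -1])
  rownames(c3) <- ord3$coordinates$sample
  expect_equal(c3["s11", ], c3["s1", ], tolerance = 1e-9)

  expect_error(pcoa_ordination(d, k = 10), "at most")
})

test_that("PERMANOVA p-values behave under null and separation", {
  # two widely separated clusters reach the minimum attainable p
  set.seed(17)
  x <- rbind(matrix(rnorm(20, 0), ncol = 2),
             matrix(rnorm(20, 10), ncol = 2))
  rownames(x) <- paste0("s", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  res <- permanova(dist(x), labels, n_perm = 1000, seed = 18)
  expect_equal(res$p_value, 1 / 1001)
  expect_gt(res$pseudo_F, 100)

  expect_error(permanova(dist(x), rep("a", 20)), "2 groups")

  # p >= 1/(n_perm+1) by construction, even with strong structure
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("PERMANOVA type-I error is close to nominal on unstructured data", {
  n_rep <- 200
  n <- 24
  rejections <- 0
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    x <- matrix(rnorm(n * 2), ncol = 2)
    labels <- rep(c("a", "b"), each = n / 2)
    p <- permanova(dist(x), labels, n_perm = 99, seed = r)$p_value
    if (p <= 0.05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.03)
})

test_that("richness ANOVA with Tukey HSD flags the deviant group", {
  set.seed(19)
  vals <- c(rnorm(10, 10, 1), rnorm(10, 10, 1), rnorm(10, 20, 1))
  labels <- rep(c("g1", "g2", "g3"), each = 10)
  res <- richness_anova(vals, labels)
  expect_lt(res$anova$p_value, 0.001)
  tk <- res$tukey
  expect_lt(tk$p_adjusted[tk$comparison == "g3-g1"], 0.001)
  expect_lt(tk$p_adjusted[tk$comparison == "g3-g2"], 0.001)
  expect_gt(tk$p_adjusted[tk$comparison == "g2-g1"], 0.05)

  # identical group means: tiny F, nothing significant
  same <- c(rnorm(10, 10, 1), rnorm(10, 10, 1))
  res2 <- richness_anova(same, rep(c("a", "b"), each = 10))
  expect_gt(res2$anova$p_value, 0.01)

  expect_error(richness_anova(rep(1, 10), rep(c("a", "b"), each = 5)),
               "variance")
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise t-tests", {
  set.seed(20)
  vals <- rnorm(30)
  labels <- rep(c("a", "b", "c"), each = 10)
  tk <- richness_anova(vals, labels)$tukey
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    t_p <- t.test(vals[labels == pair[1]],
                  vals[labels == pair[2]], var.equal = TRUE)$p.value
    comp <- paste0(pair[2], "-", pair[1])
    expect_gte(tk$p_adjusted[tk$comparison == comp] + 1e-10, t_p)
  }
})
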