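test_that("two samples merge at their Euclidean distance", {
  values <- matrix(
    2^c(10, 12, 11, 13), 2,
    dimnames = list(c("PG(16:0/18:1)", "PE(16:0/16:0)"), c("s1", "s2"))
  )
  m <- intensity_matrix(values)
  cl <- ward_cluster(m)
  expect_equal(cl$height,
               sqrt(sum((values[, 1] - values[, 2])^2)))
  expect_identical(cl$linkage, "ward.D2")
})

test_that("merge heights match a brute-force Ward.D2 agglomeration", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(rnorm(6 * 8), nrow = 6)
    values <- t(x)
    dimnames(values) <- list(
      default_lipid_catalog(14, seed = rep)[1:8], paste0("s", 1:6)
    )
    m <- intensity_matrix(2^values) # construct via raw then log2 to any state
    m$values <- values
    m$state <- "log2_median"
    cl <- ward_cluster(m)
    expect_equal(sort(cl$height), sort(oracle_ward_heights(x)),
                 tolerance = 1e-10)
    # Ward heights are monotone non-decreasing along the merge sequence
    expect_true(all(diff(cl$height) >= -1e-12))
  }
})

test_that("well-separated groups are recovered exactly at k = 3", {
  catalog <- default_lipid_catalog(40, seed = 13)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:9),
    salinity = rep(c(7, 13, 20), each = 3),
    hrt = 24, growth_mode = "planktonic", replicate = rep(1:3, 3)
  )
  sim <- simulate_lipidome(
    catalog = catalog, design = design, sigma = 0.5, seed = 13,
    effects = list(
      list(lipids = catalog[1:10], selector = list(salinity = 13), delta = 5),
      list(lipids = catalog[11:20], selector = list(salinity = 20), delta = 5)
    )
  )
  cl <- ward_cluster(log2_median_normalize(sim$matrix))
  groups <- cut_clusters(cl, 3)
  ari <- mclust::adjustedRandIndex(groups, design$salinity)
  expect_equal(ari, 1)
  # newick export covers every sample label
  nwk <- cluster_newick(cl)
  expect_true(all(vapply(design$sample_id, grepl, logical(1), x = nwk,
                         fixed = TRUE)))
})

test_that("roc_auc matches exhaustive pair counting and is antisymmetric", {
  expect_equal(roc_auc(1:4, c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(2, 6), rep(c(FALSE, TRUE), 3)), 0.5)
  set.seed(14)
  for (rep in 1:20) {
    scores <- sample(seq(0, 1, 0.1), 10, replace = TRUE) # ties likely
    pos <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    if (!any(pos) || all(pos)) next
    auc <- roc_auc(scores, pos)
    expect_equal(auc, oracle_auc(scores, pos))
    expect_equal(roc_auc(-scores, pos), 1 - auc)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("PLS-DA separates planted classes and respects its invariants", {
  catalog <- default_lipid_catalog(194, seed = 15)
  sim <- simulate_lipidome(
    catalog = catalog, seed = 15, sigma = 0.5,
    effects = list(list(lipids = catalog[1:30],
                        selector = list(growth_mode = "biofilm"), delta = 2))
  )
  n <- log2_median_normalize(sim$matrix)
  rep <- plsda(n, "growth_mode")
  expect_gte(rep$accuracy, 0.95)
  expect_gte(rep$Q2, 0.8)
  expect_lte(rep$Q2, rep$R2)
  expect_equal(rep$n_components, 2)
  expect_equal(dim(rep$scores), c(36L, 2L))
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_error(plsda(n, rep("one", 36)), "two classes")
})

test_that("PLS-DA Q2 collapses under label permutation", {
  catalog <- default_lipid_catalog(60, seed = 16)
  design <- study_design(salinities = 13, hrts = c(19.2, 48),
                         biofilm = FALSE, n_rep = 5)
  sim <- simulate_lipidome(
    catalog = catalog, design = design, sigma = 0.5, seed = 16,
    effects = list(list(lipids = catalog[1:10],
                        selector = list(hrt = 48), delta = 3))
  )
  n <- log2_median_normalize(sim$matrix)
  labels <- n$sample_meta$hrt
  set.seed(17)
  q2_null <- replicate(100, plsda(n, sample(labels))$Q2)
  expect_gte(mean(q2_null <= 0.2), 0.95)
})

test_that("duplicated samples get identical PLS-DA scores", {
  sim <- make_two_group_sim(n_lipids = 30, n_signal = 5, delta = 2, seed = 18)
  X <- t(log2_median_normalize(sim$matrix)$values)
  X2 <- rbind(X, X)
  labels <- rep(sim$matrix$sample_meta$salinity, 2)
  rep2 <- plsda(X2, labels)
  n <- nrow(X)
  expect_equal(rep2$scores[seq_len(n), ], rep2$scores[n + seq_len(n), ],
               ignore_attr = TRUE)
})

test_that("MCCV biomarker ranking recovers planted discriminative lipids", {
  catalog <- default_lipid_catalog(194, seed = 19)
  # 18 vs 18: two growth modes, 18 samples each
  design <- tibble::tibble(
    sample_id = paste0("s", 1:36),
    salinity = 13, hrt = 48,
    growth_mode = rep(c("planktonic", "biofilm"), each = 18),
    replicate = rep(1:18, 2)
  )
  sim <- simulate_lipidome(
    catalog = catalog, design = design, sigma = 0.5, seed = 19,
    effects = list(list(lipids = catalog[1:15],
                        selector = list(growth_mode = "biofilm"), delta = 3))
  )
  n <- log2_median_normalize(sim$matrix)
  report <- rf_biomarker_mccv(n, "growth_mode", panel_sizes = 15,
                              n_rounds = 30, seed = 20)
  expect_gte(sum(catalog[1:15] %in% report$selected_panel), 12)
  expect_gte(report$panel_auc$mean_auc[report$panel_auc$panel_size == 15],
             0.95)
  expect_true(report$accuracy >= 0 && report$accuracy <= 1)
  expect_true(all(report$selected_panel %in% report$ranking$lipid_id))
})

test_that("the biomarker procedure is reproducible from its seed", {
  sim <- make_two_group_sim(n_lipids = 40, n_signal = 5, delta = 3,
                            n_rep = 5, seed = 21)
  n <- log2_median_normalize(sim$matrix)
  r1 <- rf_biomarker_mccv(n, "salinity", panel_sizes = c(5, 10),
                          panel_size = 5, n_rounds = 10, seed = 99)
  r2 <- rf_biomarker_mccv(n, "salinity", panel_sizes = c(5, 10),
                          panel_size = 5, n_rounds = 10, seed = 99)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$panel_auc, r2$panel_auc)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_warning(
    rf_biomarker_mccv(n, "salinity", panel_sizes = 5, panel_size = 5,
                      n_rounds = 5, seed = 1),
    "rounds"
  )
})

test_that("feature rankings are stable across seeds on planted-signal data", {
  catalog <- default_lipid_catalog(80, seed = 22)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:24), salinity = 13, hrt = 48,
    growth_mode = rep(c("planktonic", "biofilm"), each = 12),
    replicate = rep(1:12, 2)
  )
  sim <- simulate_lipidome(
    catalog = catalog, design = design, sigma = 0.5, seed = 22,
    effects = list(list(lipids = catalog[1:10],
                        selector = list(growth_mode = "biofilm"), delta = 3))
  )
  n <- log2_median_normalize(sim$matrix)
  r1 <- rf_biomarker_mccv(n, "growth_mode", panel_sizes = 10, panel_size = 10,
                          n_rounds = 20, seed = 1)
  r2 <- rf_biomarker_mccv(n, "growth_mode", panel_sizes = 10, panel_size = 10,
                          n_rounds = 20, seed = 2)
  top30 <- r1$ranking$lipid_id[1:30]
  rank1 <- match(top30, r1$ranking$lipid_id)
  rank2 <- match(top30, r2$ranking$lipid_id)
  expect_gte(stats::cor(rank1, rank2, method = "spearman"), 0.8)
})
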