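test_that("lipid shorthand parsing handles standard and edge-case names", {
  p <- parse_lipid_name(c("PC(36:4)", "TG(52:3)", "Cholesterol",
                          "PE(O-38:5)", "MGDG(34:2)_2", "Cer(d42:1)"))
  expect_identical(p$subclass, c("PC", "TG", NA, "PE", "MGDG", "Cer"))
  expect_identical(p$carbons, c(36L, 52L, NA, 38L, 34L, 42L))
  expect_identical(p$double_bonds, c(4L, 3L, NA, 5L, 2L, 1L))
  expect_identical(p$parse_ok, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("total content reproduces the printed study totals ratio", {
  ## two printed group totals, split over 4 replicates each
  mat <- rbind(c(rep(4097111596 / 4, 4), rep(2779723611 / 4, 4)))
  ds <- lipid_ds_from_matrix(mat)
  tot <- total_content(ds)
  expect_equal(tot$total_wt, 4097111596)
  expect_equal(tot$total_mutant, 2779723611)
  expect_identical(tot$ratio_pct, 67.8)
})

test_that("total content handles identity and zero edge cases", {
  mat <- rbind(c(1, 2, 3, 4, 1, 2, 3, 4), c(5, 5, 5, 5, 5, 5, 5, 5))
  expect_identical(total_content(lipid_ds_from_matrix(mat))$ratio_pct, 100)
  zero <- rbind(c(1, 2, 3, 4, 0, 0, 0, 0))
  expect_identical(total_content(lipid_ds_from_matrix(zero))$ratio_pct, 0)
  allzero <- rbind(rep(0, 8))
  expect_error(total_content(lipid_ds_from_matrix(allzero)), "zero")
})

test_that("the total ratio is invariant to species permutation", {
  ds <- simulate_lipidome(lipidome_spec(seed = 8))
  shuffled <- ds[withr::with_seed(1, sample.int(nrow(ds))), ]
  expect_equal(total_content(shuffled)$ratio, total_content(ds)$ratio)
  ## sum of per-replicate sums equals the direct group total
  per_rep <- dplyr::summarise(dplyr::group_by(ds, group, sample),
                              s = sum(intensity), .groups = "drop")
  expect_equal(sum(per_rep$s[per_rep$group == "mutant"]),
               total_content(ds)$total_mutant)
})

test_that("identical groups give p = 1 and tier ns; constant groups use the degenerate rule", {
  same <- lipid_ds_from_matrix(rbind(c(1, 2, 3, 4, 1, 2, 3, 4),
                                     c(9, 9, 9, 9, 9, 9, 9, 9)),
                               species = c("PC(36:4)", "PC(34:1)"))
  st <- subclass_tests(same)
  expect_true(all(st$p_value == 1 | st$p_value > 0.99))
  expect_true(all(st$tier == "ns"))
  ## {1,1,1,1} vs {2,2,2,2}: zero variance in both groups, different means
  deg <- lipid_ds_from_matrix(rbind(rep(c(1, 2), each = 4)),
                              species = "PE(36:2)")
  std <- subclass_tests(deg)
  expect_identical(std$direction, "up")
  expect_true(std$degenerate)
  expect_identical(std$p_value, 0)
})

test_that("a halved subclass is flagged down-regulated with high power", {
  ## sigma = 0.1, n = 4, log2FC = -1: detected at p < 0.05 in >= 95% of seeds
  sc <- tibble::tibble(subclass = c("PE", "TG"), n_species = c(8L, 8L),
                       log2fc = c(-1, 0), base_scale = 1e6)
  hits <- vapply(1:200, function(s) {
    ds <- simulate_lipidome(lipidome_spec(sc, noise_sigma = 0.1,
                                          seed = 7000 + s))
    st <- subclass_tests(ds)
    st$p_value[st$subclass == "PE"] < 0.05 &&
      st$direction[st$subclass == "PE"] == "down"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("VIP satisfies the sum-of-squares identity on every fit", {
  set.seed(31)
  for (i in 1:8) {
    n_sp <- sample(5:40, 1)
    mat <- matrix(2^rnorm(n_sp * 8, 10, 1), nrow = n_sp)
    ds <- lipid_ds_from_matrix(mat)
    fit <- plsda_fit(ds, n_components = sample(1:3, 1))
    expect_equal(sum(fit$vip^2), length(fit$vip), tolerance = 1e-10)
  }
})

test_that("a single informative species gets the maximum VIP, above 1", {
  set.seed(17)
  ok <- vapply(1:50, function(s) {
    J <- 30
    mat <- matrix(rnorm(J * 8, 10, 0.1), nrow = J)
    mat[5, ] <- 10 + c(rep(0, 4), rep(0.4, 4))  # 4-sigma group shift
    fit <- plsda_fit(lipid_ds_from_matrix(2^mat))
    which.max(fit$vip) == 5 && fit$vip[5] > 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("the PLS-DA fit agrees with the explicit-deflation oracle", {
  set.seed(23)
  for (i in 1:5) {
    mat <- matrix(2^rnorm(10 * 8, 8, 1), nrow = 10)  # 10 species x 8 samples
    ds <- lipid_ds_from_matrix(mat)
    fit <- plsda_fit(ds, n_components = 2)
    oracle <- pls_vip_oracle(t(mat), rep(c(-1, 1), each = 4), 2)
    expect_lt(max(abs(unname(fit$vip) - oracle$vip)), 1e-8)
    expect_lt(max(abs(abs(fit$scores) - abs(oracle$scores))), 1e-8)
    expect_lt(max(abs(fit$ssy - oracle$ssy)), 1e-8)
  }
})

test_that("PLS-DA latent space matches an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(29)
  mat <- matrix(2^rnorm(20 * 8, 8, 1), nrow = 20)
  ds <- lipid_ds_from_matrix(mat)
  fit <- plsda_fit(ds, n_components = 2)
  X <- t(mat)
  y <- rep(c(-1, 1), each = 4)
  mo <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  ## scores agree up to per-component sign
  for (a in 1:2) {
    r <- cor(fit$scores[, a], mo$variates$X[, a])
    expect_gt(abs(r), 1 - 1e-8)
  }
})

test_that("zero-variance species are dropped with VIP 0 and rank is enforced", {
  mat <- rbind(matrix(2^rnorm(6 * 8, 8, 1), nrow = 6), rep(3, 8))
  ds <- lipid_ds_from_matrix(mat)
  expect_warning(fit <- plsda_fit(ds), "zero-variance")
  expect_identical(unname(fit$vip[7]), 0)
  expect_warning(plsda_fit(lipid_ds_from_matrix(mat[1:6, ]),
                           n_components = 10), "truncated")
})

test_that("the differential screen is the exact VIP/p intersection", {
  ds <- simulate_lipidome(lipidome_spec(seed = 14))
  diff <- differential_species(ds)
  vips <- plsda_vip(ds)
  joined <- dplyr::left_join(tibble::as_tibble(diff), vips, by = "species")
  expect_identical(joined$is_differential,
                   joined$vip.y > 1 & joined$p_value < 0.05)
  ## up + down partition the differential set
  cts <- attr(diff, "counts")
  expect_identical(cts$n_up + cts$n_down, cts$n_differential)
  expect_identical(glance(diff)$n_differential, sum(diff$is_differential))
  ## identical groups -> nothing differential
  same <- lipid_ds_from_matrix(rbind(c(1, 2, 3, 4, 1, 2, 3, 4),
                                     c(2, 4, 6, 8, 2, 4, 6, 8)))
  expect_identical(glance(differential_species(same))$n_differential, 0L)
})

test_that("BH correction can only shrink the differential set", {
  ds <- simulate_lipidome(lipidome_spec(seed = 15))
  raw <- differential_species(ds)
  adj <- differential_species(ds, fdr = TRUE)
  expect_lte(glance(adj)$n_differential, glance(raw)$n_differential)
  expect_true(all(adj$is_differential <= raw$is_differential))
})

test_that("chain profiles bin by carbons and double bonds", {
  one <- lipid_ds_from_matrix(rbind(c(10, 11, 12, 13, 5, 6, 7, 8)),
                              species = "PC(36:4)")
  prof <- chain_profiles(one)
  expect_identical(nrow(prof), 2L)
  chain <- prof[prof$dimension == "chain_length", ]
  expect_identical(chain$bin, 36L)
  expect_equal(chain$mean_wt, 11.5)
  expect_equal(chain$mean_mutant, 6.5)
  sat <- prof[prof$dimension == "saturation", ]
  expect_identical(sat$bin, 4L)
  ## unparsable species contribute to no bin
  with_bad <- lipid_ds_from_matrix(
    rbind(c(10, 11, 12, 13, 5, 6, 7, 8), c(1, 1, 1, 1, 1, 1, 1, 1)),
    species = c("PC(36:4)", "Cholesterol"))
  expect_identical(nrow(chain_profiles(with_bad)), 2L)
})

test_that("a shift confined to long chains flags only those bins", {
  set.seed(61)
  carbons <- rep(c(34, 36, 38, 40), each = 3)
  mats <- lapply(seq_along(carbons), function(i) {
    base <- rnorm(8, 0, 0.02)
    shift <- if (carbons[i] >= 38) -1 else 0
    2^(10 + base + c(rep(0, 4), rep(shift, 4)))
  })
  mat <- do.call(rbind, mats)
  species <- sprintf("PE(%d:%d)", carbons, rep(1:3, 4))
  prof <- chain_profiles(lipid_ds_from_matrix(mat, species = species))
  chain <- prof[prof$dimension == "chain_length", ]
  expect_true(all(chain$tier[chain$bin >= 38] != "ns"))
  expect_true(all(chain$log2fc[chain$bin >= 38] < -0.9))
  expect_true(all(abs(chain$log2fc[chain$bin < 38]) < 0.1))
})

test_that("heatmap rows are z-scored and identical rows merge first", {
  base <- c(1, 2, 3, 4, 2, 3, 4, 5)
  mat <- rbind(base, base, c(9, 1, 8, 2, 9, 1, 8, 2), runif(8))
  species <- c("PC(36:1)", "PC(36:2)", "TG(52:3)", "PE(34:1)")
  cl <- cluster_heatmap_order(lipid_ds_from_matrix(mat, species = species))
  z <- as.matrix(cl$z[, -1])
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  ## the two identical (hence identical-z) rows merge first at height 0
  first <- cl$hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))
  expect_equal(cl$hclust$height[1], 0)
  ## leaf order keeps them adjacent
  idx <- match(c("PC(36:1)", "PC(36:2)"), cl$order)
  expect_equal(abs(diff(idx)), 1)
})

test_that("well-separated blocks stay contiguous in leaf order", {
  set.seed(71)
  blockA <- matrix(rep(c(0, 0, 0, 0, 5, 5, 5, 5), 4), nrow = 4, byrow = TRUE) +
    matrix(rnorm(32, 0, 0.05), nrow = 4)
  blockB <- matrix(rep(c(5, 5, 5, 5, 0, 0, 0, 0), 4), nrow = 4, byrow = TRUE) +
    matrix(rnorm(32, 0, 0.05), nrow = 4)
  species <- sprintf("PC(%d:1)", 30:37)
  cl <- cluster_heatmap_order(
    lipid_ds_from_matrix(rbind(blockA, blockB) + 10, species = species))
  pos_a <- sort(match(species[1:4], cl$order))
  expect_identical(pos_a, seq(pos_a[1], pos_a[1] + 3L))
})

test_that("zero-variance rows are flagged and zeroed", {
  mat <- rbind(c(1, 2, 3, 4, 5, 6, 7, 8), rep(2, 8))
  species <- c("PC(36:1)", "TG(50:2)")
  expect_warning(cl <- cluster_heatmap_order(
    lipid_ds_from_matrix(mat, species = species)), "zero-variance")
  expect_identical(cl$flagged, "TG(50:2)")
  expect_true(all(as.matrix(cl$z[2, -1]) == 0))
})
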