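test_that("kernel width conversions follow the Gaussian FWHM relation", {
  expect_equal(kernel_sd(2 * sqrt(2 * log(2))), 1)
  expect_equal(kernel_sd(10), 4.246609, tolerance = 1e-6)
  expect_error(kernel_sd(0), "positive")
  expect_error(kernel_sd(-1), "positive")
  # subject-count convention: ~10 mm FWHM at n = 10, shrinking with n
  expect_equal(fwhm_from_sample_size(10), 10.0, tolerance = 0.01)
  expect_true(fwhm_from_sample_size(50) < fwhm_from_sample_size(10))
  expect_error(fwhm_from_sample_size(0), "positive")
})

test_that("modelled-activation maps match the per-voxel brute-force oracle", {
  g <- tiny_grid(spacing = 2, half = 10)  # 11^3 voxels
  sd <- kernel_sd(10)

  # single focus: kernel mass sums to one over the grid
  one <- modeled_activation(matrix(c(0, 0, 0), 1, 3), g, sd, truncate = Inf)
  expect_equal(sum(one$values), 1, tolerance = 1e-9)
  expect_true(all(one$values >= 0))

  # coincident foci collapse to the single-focus map under the max rule
  two <- modeled_activation(matrix(0, 2, 3), g, sd, truncate = Inf)
  expect_equal(two$values, one$values)

  # random 5-focus study equals the brute-force oracle everywhere
  set.seed(31)
  foci <- matrix(sample(seq(-8, 8, 2), 15, replace = TRUE), 5, 3)
  ma <- modeled_activation(foci, g, sd, truncate = Inf)
  expect_lt(max(abs(ma$values - oracle_ma(foci, g, sd))), 1e-12)

  expect_error(modeled_activation(matrix(c(50, 0, 0), 1, 3), g, sd),
               "outside grid")
  expect_error(modeled_activation(matrix(0, 0, 3), g, sd), "no foci")
})

test_that("the ALE union is the complement product and keeps its bounds", {
  g <- tiny_grid(spacing = 2, half = 8)
  sd <- kernel_sd(12)
  set.seed(77)
  maps <- lapply(1:10, function(i) {
    foci <- matrix(sample(seq(-6, 6, 2), 9, replace = TRUE), 3, 3)
    modeled_activation(foci, g, sd, truncate = Inf, study_id = paste0("s", i))
  })

  # one study: union is the MA map itself
  expect_equal(ale_union(maps[1]), maps[[1]]$values)

  # value identity at an arbitrary pair of levels
  expect_equal(1 - (1 - 0.5) * (1 - 0.5), 0.75)

  # log-domain oracle over ten studies
  log_comp <- Reduce(`+`, lapply(maps, function(m) log1p(-m$values)))
  expect_lt(max(abs(ale_union(maps) - (1 - exp(log_comp)))), 1e-12)

  u <- ale_union(maps)
  expect_true(all(u >= 0 & u < 1))

  # study order never matters
  expect_equal(ale_union(maps[c(4, 1, 9, 2, 3, 10, 6, 5, 8, 7)]), u)

  # adding a study never decreases ALE anywhere
  expect_true(all(ale_union(maps) >= ale_union(maps[-1]) - 1e-15))

  g2 <- tiny_grid(spacing = 2, half = 6)
  m2 <- modeled_activation(matrix(0, 1, 3), g2, sd)
  expect_error(ale_union(list(maps[[1]], m2)), "different grids")
})

test_that("the permutation null is reproducible and validates its inputs", {
  g <- brain_grid(spacing = 10)
  sd <- kernel_sd(10)
  a <- permutation_null(c(5, 8), g, sd, n_perm = 12, seed = 9)
  b <- permutation_null(c(5, 8), g, sd, n_perm = 12, seed = 9)
  expect_identical(a$max_ale, b$max_ale)
  expect_identical(a$max_cluster_vox, b$max_cluster_vox)
  expect_false(identical(
    a$max_ale, permutation_null(c(5, 8), g, sd, n_perm = 12, seed = 10)$max_ale))
  expect_error(permutation_null(c(5, 8), g, sd, n_perm = 0), "n_perm")
  expect_error(permutation_null(integer(0), g, sd, n_perm = 5), "counts")
  expect_error(brain_grid(spacing = 2, mask = array(FALSE, c(2, 2, 2)),
                          lower = c(0, 0, 0), upper = c(2, 2, 2)),
               "empty mask")
})

test_that("cluster thresholding recovers a planted blob and handles nulls", {
  grid <- brain_grid(spacing = 8)
  sim <- simulate_foci(default_benchmark(), seed = 21)
  fit <- ale(filter_group(sim$data, "branded"), grid, fwhm = 10,
             n_perm = 30, seed = 4)
  expect_gte(nrow(fit$clusters), 1L)
  d <- sqrt((fit$clusters$peak_x - 6)^2 + (fit$clusters$peak_y + 88)^2 +
              (fit$clusters$peak_z - 4)^2)
  expect_lte(min(d), 10)  # within one kernel FWHM of the planted centre
  expect_true(all(diff(fit$clusters$size_vox) <= 0))  # sorted by size
  expect_equal(fit$clusters$size_mm3, fit$clusters$size_vox * 8^3)
  p_in <- fit$p_map[grid$mask]
  expect_true(all(p_in > 0 & p_in <= 1))

  # a flat map yields an empty cluster table, not an error
  thr <- threshold_clusters(array(0, grid$dim), fit$null)
  expect_identical(nrow(thr$clusters), 0L)
  expect_error(threshold_clusters(fit$ale, fit$null, forming_p = 0.01),
               "rebuild the null")
})

test_that("26-connected labelling separates diagonal from disjoint voxels", {
  arr <- array(FALSE, c(5, 5, 5))
  arr[1, 1, 1] <- TRUE
  arr[2, 2, 2] <- TRUE  # diagonal neighbour: same cluster under 26-connectivity
  arr[5, 5, 5] <- TRUE  # far corner: its own cluster
  lab <- fociMCPA:::label_clusters(arr)
  expect_identical(sort(lab$sizes), c(1L, 2L))
  expect_identical(lab$labels[1, 1, 1], lab$labels[2, 2, 2])
  expect_false(lab$labels[5, 5, 5] == lab$labels[1, 1, 1])
})

test_that("NIfTI export writes maps that read back on the same grid", {
  grid <- brain_grid(spacing = 10)
  sim <- simulate_foci(default_benchmark(), seed = 5)
  fit <- ale(filter_group(sim$data, "branded"), grid, n_perm = 5, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_ale(fit, dir)
  img <- RNifti::readNifti(file.path(dir, "ale.nii.gz"))
  expect_identical(dim(img), grid$dim)
  expect_equal(max(img), max(fit$ale), tolerance = 1e-6)
  tab <- utils::read.csv(file.path(dir, "clusters.csv"))
  expect_identical(nrow(tab), nrow(fit$clusters))
})
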