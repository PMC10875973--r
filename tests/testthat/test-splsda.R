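# A linearly separable two-block toy used by several tests.
separable_blocks <- function(n = 40, p = 6, shift = 3, seed = 11) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  mk <- function() {
    m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    m[y == "a", 1:2] <- m[y == "a", 1:2] + shift
    m
  }
  list(X = list(b1 = mk(), b2 = mk()), y = y)
}

test_that("the non-sparse single-block solution is the leading SVD direction", {
  set.seed(5)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "a", 1:3] <- X[y == "a", 1:3] + 1.2
  fit <- block_splsda(list(b1 = X), y, ncomp = 1)
  sv <- svd(crossprod(scale(X), scale(stats::model.matrix(~ y - 1))))$u[, 1]
  sv <- sv / sqrt(sum(sv^2))
  if (sv[which.max(abs(sv))] < 0) sv <- -sv
  expect_equal(unname(fit$loadings$b1[, 1]), sv, tolerance = 1e-10)
})

test_that("keep = P reproduces the non-sparse fit; constraints always hold", {
  d <- separable_blocks()
  full <- block_splsda(d$X, d$y, ncomp = 2)
  capped <- block_splsda(d$X, d$y, ncomp = 2, keep = ncol(d$X$b1))
  expect_equal(full$loadings, capped$loadings)

  sparse <- block_splsda(d$X, d$y, ncomp = 2, keep = 3)
  for (q in names(sparse$loadings)) {
    norms <- colSums(sparse$loadings[[q]]^2)
    expect_equal(unname(norms), rep(1, 2))
    expect_true(all(colSums(sparse$loadings[[q]] != 0) <= 3))
    # deflation on own scores makes successive scores orthogonal
    cc <- stats::cor(sparse$scores[[q]])
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  }
})

test_that("sparse loadings agree with mixOmics on a single block", {
  set.seed(5)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "a", 1:3] <- X[y == "a", 1:3] + 1.2
  ours <- block_splsda(list(b1 = X), y, ncomp = 2, keep = 5)$loadings$b1
  theirs <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(5, 5))$loadings$X
  for (h in 1:2) {
    a <- theirs[, h]
    if (sum(a * ours[, h]) < 0) a <- -a
    expect_equal(unname(a), unname(ours[, h]), tolerance = 1e-8)
  }
})

test_that("fitting validates outcome, sparsity, and variance preconditions", {
  d <- separable_blocks()
  expect_error(block_splsda(d$X, factor(rep("a", 40))), "single class")
  expect_error(block_splsda(d$X, d$y, keep = 99), "must lie in")
  Xz <- d$X
  Xz$b1[] <- 1
  expect_error(block_splsda(Xz, d$y), "zero variance")
  Xz2 <- d$X
  Xz2$b1[, 3] <- 0
  expect_warning(block_splsda(Xz2, d$y), "zero-variance column")
  expect_error(block_splsda(d$X, d$y, ncomp = 0), "ncomp")
})

test_that("prediction is a nearest-centroid majority vote over blocks", {
  d <- separable_blocks()
  fit <- block_splsda(d$X, d$y, ncomp = 2, keep = 4)
  pred <- predict(fit, d$X)
  expect_equal(balanced_error_rate(d$y, pred$class), 0)

  # vote oracle: exhaustive count over per-block assignments
  counts <- t(apply(as.matrix(pred$block_class), 1, function(r)
    vapply(fit$levels, function(g) sum(r == g), integer(1))))
  clear <- counts[, 1] != counts[, 2]
  expect_identical(as.character(pred$class[clear]),
                   fit$levels[max.col(counts)[clear]])

  # all-zero rows (unseen test values) classify without error
  zero <- lapply(d$X, function(m) m[1:2, , drop = FALSE] * 0)
  pz <- predict(fit, zero)
  expect_identical(length(pz$class), 2L)
  expect_false(anyNA(pz$class))

  misaligned <- lapply(d$X, function(m) {
    colnames(m) <- paste0("w", seq_len(ncol(m)))
    m
  })
  expect_error(predict(fit, misaligned), "column-aligned")
})

test_that("the balanced error rate averages per-class error", {
  expect_equal(balanced_error_rate(c("a", "a", "b"), c("a", "a", "b")), 0)
  expect_equal(balanced_error_rate(rep(c("a", "b"), c(30, 10)),
                                   rep("a", 40)), 0.5)
  expect_equal(balanced_error_rate(c("a", "a", "b", "b"),
                                   c("a", "b", "b", "b")), 0.25)
  expect_error(balanced_error_rate(c("a", "b"), c("a")), "lengths differ")
})

test_that("keep tuning scans the grid and takes the smallest argmin", {
  set.seed(2)
  sim <- simulate_foci(two_cluster_spec(), seed = 2)
  sp <- stratified_split(sim$data, 120, seed = 1)
  train <- encode_pattern3(sp$train)
  test <- suppressWarnings(align_columns(train, sp$test))
  grid <- c(4L, 8L, 12L)
  tuning <- suppressWarnings(tune_keep(train, test, grid = grid, ncomp = 2))
  expect_identical(nrow(tuning$trajectory), 3L)
  # brute-force argmin over the same grid
  bers <- vapply(grid, function(k) {
    fit <- suppressWarnings(block_splsda(train$blocks, train$outcome,
                                         ncomp = 2, keep = k))
    balanced_error_rate(test$outcome, predict(fit, test$blocks)$class)
  }, numeric(1))
  expect_equal(tuning$trajectory$ber, bers)
  expect_identical(tuning$best_keep, grid[which.min(bers)])

  single <- suppressWarnings(tune_keep(train, test, grid = 5))
  expect_identical(single$best_keep, 5L)
  expect_error(tune_keep(train, test, grid = integer(0)), "empty")
  expect_error(tune_keep(train, test, grid = 10000), "narrowest block")
})

test_that("explained variance matches a direct projection computation", {
  set.seed(14)
  n <- 50
  # rank-one block: component 1 explains essentially everything
  u <- rnorm(n)
  X1 <- outer(u, c(1, 2, -1, 0.5))
  colnames(X1) <- paste0("r", 1:4)
  y <- factor(ifelse(u > 0, "a", "b"))
  fit1 <- block_splsda(list(b = X1), y, ncomp = 2, scale = FALSE)
  expect_equal(explained_variance(fit1, "b", 1), 1, tolerance = 1e-8)

  X2 <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("q", 1:6)))
  fit2 <- block_splsda(list(b = X2), y, ncomp = 2)
  ev <- explained_variance(fit2, "b")
  expect_true(all(ev >= 0 & ev <= 1))
  expect_lte(sum(ev), 1)
  # independent computation: variance of the rank-one reconstruction
  Xc <- scale(X2)
  t1 <- fit2$scores$b[, 1]
  p1 <- drop(crossprod(Xc, t1)) / sum(t1^2)
  expect_equal(ev[1], sum(t1^2) * sum(p1^2) / sum(Xc^2), tolerance = 1e-10)
  expect_error(explained_variance(fit2, "nosuch"), "unknown block")
})

test_that("one block reduces the model to single-block sparse PLS-DA", {
  set.seed(6)
  X <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("c", 1:10)))
  y <- factor(rep(c("a", "b"), 40))
  X[y == "a", 1] <- X[y == "a", 1] + 2
  multi <- block_splsda(list(only = X), y, ncomp = 2, keep = 4)
  theirs <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(4, 4))$loadings$X
  for (h in 1:2) {
    a <- theirs[, h]
    if (sum(a * multi$loadings$only[, h]) < 0) a <- -a
    expect_equal(unname(a), unname(multi$loadings$only[, h]), tolerance = 1e-8)
  }
})

test_that("label permutation drives the test BER to chance", {
  bers <- vapply(1:50, function(s) {
    sim <- simulate_foci(default_benchmark(), seed = 100 + s)
    df <- as.data.frame(sim$data)
    set.seed(500 + s)
    df$group <- sample(df$group)
    ds <- foci_dataset(df, allow_duplicates = TRUE)
    sp <- stratified_split(ds, 200, seed = s)
    train <- encode_pattern3(sp$train)
    test <- suppressWarnings(align_columns(train, sp$test))
    fit <- suppressWarnings(mcpa(train, ncomp = 2, keep = 70))
    balanced_error_rate(test$outcome, predict(fit, test)$class)
  }, numeric(1))
  expect_gte(mean(bers), 0.45)
  expect_lte(mean(bers), 0.55)
})

test_that("planted coordinate values surface in the top-10 loadings", {
  centers <- list(grpA = c(x = 20, y = 30, z = 40),
                  grpB = c(x = -20, y = -30, z = -40))
  hits <- vapply(1:50, function(s) {
    sim <- simulate_foci(two_cluster_spec(), seed = s)
    fit <- suppressWarnings(mcpa(encode_pattern3(sim$data), ncomp = 2,
                                 keep = 10))
    all(vapply(c("x", "y", "z"), function(ax) {
      L <- fit$fit$loadings[[ax]][, 1]
      top10 <- names(sort(-abs(L)))[1:10]
      coord_name(ax, centers$grpA[[ax]]) %in% top10 &&
        coord_name(ax, centers$grpB[[ax]]) %in% top10
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
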