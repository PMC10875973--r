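test_that("identical variables in different blocks score near one", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  y <- factor(ifelse(z + rnorm(n, 0, 0.8) > 0, "a", "b"))
  X1 <- cbind(A1 = z, A2 = rnorm(n))
  X2 <- cbind(B1 = z, B2 = rnorm(n))
  fit <- block_splsda(list(p = X1, q = X2), y, ncomp = 2)
  am <- association_matrix(fit, d = 2)
  expect_equal(am$pairs[["p:q"]]["A1", "B1"], 1, tolerance = 0.05)
  expect_true(all(vapply(am$pairs, function(m) max(abs(m)), numeric(1)) <=
                    1 + 1e-6))
  expect_error(association_matrix(fit, d = 3), "d must lie")
})

test_that("at full depth the score approximates the direct correlation", {
  set.seed(8)
  n <- 200
  z <- rnorm(n)
  y <- factor(ifelse(z + rnorm(n, 0, 0.8) > 0, "a", "b"))
  p1 <- 4; p2 <- 3
  X1 <- outer(z, runif(p1, 0.5, 1.5)) + 0.5 * matrix(rnorm(n * p1), n, p1)
  X2 <- outer(z, runif(p2, 0.5, 1.5)) + 0.5 * matrix(rnorm(n * p2), n, p2)
  colnames(X1) <- paste0("a", 1:p1)
  colnames(X2) <- paste0("b", 1:p2)
  fit <- block_splsda(list(u = X1, v = X2), y, ncomp = 2)
  am <- association_matrix(fit, d = 2)
  expect_lt(max(abs(am$pairs[["u:v"]] - stats::cor(X1, X2))), 0.1)
})

test_that("independent noise variables stay below the reporting cutoffs", {
  set.seed(21)
  mx <- replicate(5, {
    Xa <- matrix(rnorm(500 * 20), 500, 20,
                 dimnames = list(NULL, paste0("n", 1:20)))
    Xb <- matrix(rnorm(500 * 20), 500, 20,
                 dimnames = list(NULL, paste0("m", 1:20)))
    y <- factor(rep(c("a", "b"), 250))
    fit <- block_splsda(list(r = Xa, s = Xb), y, ncomp = 2)
    max(abs(association_matrix(fit)$pairs[["r:s"]]))
  })
  expect_true(all(mx < 0.2))
})

test_that("the score matrix does not depend on block ordering", {
  set.seed(33)
  sim <- simulate_foci(planted_cluster_spec(), seed = 3)
  bl <- encode_pattern3(sim$data)
  fwd <- suppressWarnings(block_splsda(bl$blocks, bl$outcome, ncomp = 2,
                                       keep = 10))
  rev <- suppressWarnings(block_splsda(bl$blocks[c("z", "y", "x")],
                                       bl$outcome, ncomp = 2, keep = 10))
  m1 <- association_matrix(fwd)$pairs[["x:z"]]
  m2 <- t(association_matrix(rev)$pairs[["z:x"]])
  expect_equal(m1[rownames(m2), colnames(m2)], m2, tolerance = 1e-8)
})

test_that("networks threshold by magnitude and shrink monotonically", {
  pairs <- list(
    "x:y" = matrix(c(0.9, -0.5, 0.12, 0.02), 2, 2,
                   dimnames = list(c("X_9", "X_1"), c("Y_m88", "Y_2"))),
    "x:z" = matrix(c(0.4, 0.1), 2, 1,
                   dimnames = list(c("X_9", "X_1"), "Z_m5")),
    "y:z" = matrix(c(0.3, -0.2), 2, 1,
                   dimnames = list(c("Y_m88", "Y_2"), "Z_m5")))
  M <- structure(list(pairs = pairs, d = 1), class = "association_matrix")
  g11 <- build_network(M, 0.11)
  g13 <- build_network(M, 0.13)
  # negative scores count by magnitude
  expect_true("X_1" %in% c(g11$edges$node_a, g11$edges$node_b))
  # raising the cutoff never adds edges
  key <- function(g) paste(g$edges$node_a, g$edges$node_b)
  expect_true(all(key(g13) %in% key(g11)))
  expect_identical(nrow(build_network(M, 0.95)$edges), 0L)
  expect_error(build_network(M, 0), "cutoff")
  expect_error(build_network(M, 1), "cutoff")
})

test_that("triangle reconstruction equals exhaustive enumeration", {
  # the documented worked example: a positive cross-block triangle decodes
  # to the focus its node names spell out
  pairs <- list(
    "x:y" = matrix(0.15, 1, 1, dimnames = list("X_9", "Y_m88")),
    "x:z" = matrix(0.14, 1, 1, dimnames = list("X_9", "Z_m5")),
    "y:z" = matrix(0.13, 1, 1, dimnames = list("Y_m88", "Z_m5")))
  M <- structure(list(pairs = pairs, d = 1), class = "association_matrix")
  rf <- reconstruct_foci(build_network(M, 0.11))
  expect_identical(rf[1, c("x", "y", "z")],
                   data.frame(x = 9L, y = -88L, z = -5L))
  expect_equal(rf$score[1], 0.13)

  # no cross-block triangle: empty result
  pairs$`y:z`[] <- -0.2
  M2 <- structure(list(pairs = pairs, d = 1), class = "association_matrix")
  expect_identical(nrow(reconstruct_foci(build_network(M2, 0.11))), 0L)

  # random graphs up to 30 nodes against the brute-force oracle
  set.seed(71)
  for (i in 1:20) {
    nx <- sample(3:10, 1); ny <- sample(3:10, 1); nz <- sample(3:10, 1)
    vals <- function(n, m) matrix(runif(n * m, -0.4, 0.4), n, m)
    pr <- list(
      "x:y" = matrix(vals(nx, ny), nx, ny,
                     dimnames = list(coord_name("x", seq_len(nx)),
                                     coord_name("y", seq_len(ny)))),
      "x:z" = matrix(vals(nx, nz), nx, nz,
                     dimnames = list(coord_name("x", seq_len(nx)),
                                     coord_name("z", seq_len(nz)))),
      "y:z" = matrix(vals(ny, nz), ny, nz,
                     dimnames = list(coord_name("y", seq_len(ny)),
                                     coord_name("z", seq_len(nz)))))
    Mr <- structure(list(pairs = pr, d = 1), class = "association_matrix")
    g <- build_network(Mr, 0.1)
    got <- reconstruct_foci(g)
    want <- oracle_triangles(g)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("a compact planted cluster is recovered as the top candidate", {
  hits <- vapply(1:15, function(s) {
    sim <- simulate_foci(planted_cluster_spec(), seed = s)
    fit <- suppressWarnings(mcpa(encode_pattern3(sim$data), ncomp = 2,
                                 keep = 10))
    rf <- reconstruct_foci(build_network(association_matrix(fit), 0.11))
    nrow(rf) > 0 && abs(rf$x[1] - 20) <= 4 && abs(rf$y[1] + 60) <= 4 &&
      abs(rf$z[1] - 30) <= 4
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("network export writes an edge list and GraphML", {
  sim <- simulate_foci(planted_cluster_spec(), seed = 2)
  fit <- suppressWarnings(mcpa(encode_pattern3(sim$data), ncomp = 2, keep = 10))
  g <- build_network(association_matrix(fit), 0.11)
  dir <- withr::local_tempdir()
  write_network(g, dir)
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  expect_identical(nrow(edges), nrow(g$edges))
  ig <- igraph::read_graph(file.path(dir, "network.graphml"),
                           format = "graphml")
  expect_equal(igraph::gsize(ig), nrow(g$edges))
})
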