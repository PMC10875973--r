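# Shared fixtures and independent oracles, all built in code.

# small deterministic foci dataset (two groups, two studies each)
tiny_foci <- function() {
  foci_dataset(data.frame(
    study_id = rep(c("S1", "S2", "S3", "S4"), each = 3),
    group = rep(c("branded", "unbranded"), each = 6),
    x = c(9, 6, -4, 10, 8, -2, -6, -5, 0, 12, -8, 3),
    y = c(-88, -88, 40, -85, -74, 42, 42, 38, 40, -60, 20, 5),
    z = c(-5, 4, -8, 0, -2, -10, -16, -12, -8, 30, 15, 0)))
}

# random valid foci dataset for property tests
random_foci <- function(n_studies = 4, foci_range = c(2, 8),
                        groups = c("a", "b")) {
  rows <- do.call(rbind, lapply(seq_len(n_studies), function(s) {
    n <- sample(foci_range[1]:foci_range[2], 1)
    data.frame(study_id = paste0("st", s),
               group = sample(groups, 1),
               x = sample(-70:70, n, replace = TRUE),
               y = sample(-100:65, n, replace = TRUE),
               z = sample(-50:80, n, replace = TRUE))
  }))
  foci_dataset(rows, allow_duplicates = TRUE)
}

# small unmasked cubic grid centred on the origin
tiny_grid <- function(spacing = 2, half = 10) {
  brain_grid(spacing = spacing, mask = "none",
             lower = rep(-half, 3), upper = rep(half, 3))
}

# Brute-force MA map: per-voxel max over per-focus normalised Gaussians,
# written independently of the package internals (full-grid kernels).
oracle_ma <- function(foci, grid, sd) {
  vox <- do.call(expand.grid, lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dim[k]) - 1) * grid$spacing))
  vox <- as.matrix(vox)
  per_focus <- vapply(seq_len(nrow(foci)), function(k) {
    kern <- exp(-rowSums(sweep(vox, 2, foci[k, ])^2) / (2 * sd^2))
    kern / sum(kern)
  }, numeric(nrow(vox)))
  array(apply(per_focus, 1, max), grid$dim)
}

oracle_ale <- function(foci_list, grid, sd) {
  comp <- array(1, grid$dim)
  for (f in foci_list) comp <- comp * (1 - oracle_ma(f, grid, sd))
  1 - comp
}

# Exhaustive triangle enumeration over a relevance graph, independent of
# reconstruct_foci(): tries every (x-node, y-node, z-node) triple.
oracle_triangles <- function(graph) {
  e <- graph$edges
  score_of <- function(a, b) {
    i <- which((e$node_a == a & e$node_b == b) |
               (e$node_a == b & e$node_b == a))
    if (length(i)) e$score[i[1]] else NA_real_
  }
  nodes_in <- function(bl) graph$nodes[substr(graph$nodes, 1, 1) ==
                                         toupper(bl)]
  out <- list()
  for (nx in nodes_in("x")) for (ny in nodes_in("y")) for (nz in nodes_in("z")) {
    s <- c(score_of(nx, ny), score_of(nx, nz), score_of(ny, nz))
    if (any(is.na(s)) || any(s <= 0)) next
    out[[length(out) + 1]] <- data.frame(x = coord_value(nx),
                                         y = coord_value(ny),
                                         z = coord_value(nz),
                                         score = min(s))
  }
  if (!length(out))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, out)
  out[order(-out$score, out$x, out$y, out$z), , drop = FALSE]
}

# compact planted-cluster simulation: one spatial cluster drives one class
planted_cluster_spec <- function(center = c(20, -60, 30), sd = 4,
                                 weight = 0.7, studies = 10L, foci = 40L) {
  simulation_spec(list(
    grpA = list(studies = studies, foci_per_study = foci,
                clusters = list(list(center = center, sd = sd,
                                     weight = weight, name = "planted"))),
    grpB = list(studies = studies, foci_per_study = foci, clusters = list())))
}

# two compact group-specific clusters for loading-recovery checks
two_cluster_spec <- function() {
  simulation_spec(list(
    grpA = list(studies = 10L, foci_per_study = 30L,
                clusters = list(list(center = c(20, 30, 40), sd = 2,
                                     weight = 0.6, name = "A"))),
    grpB = list(studies = 10L, foci_per_study = 30L,
                clusters = list(list(center = c(-20, -30, -40), sd = 2,
                                     weight = 0.6, name = "B")))))
}

expect_same_dataset <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(foci_space(a), foci_space(b))
}
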