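# Activation likelihood estimation (ALE).
#
# Each study's foci are smoothed with an isotropic 3-D Gaussian kernel whose
# mass sums to one over the voxel lattice; a study's modelled-activation (MA)
# map takes, at every voxel, the maximum over its per-focus kernels. The ALE
# map is the probabilistic union across studies,
#   ALE(v) = 1 - prod_i (1 - MA_i(v)),
# i.e. the probability that at least one study's true activation lies at v.
# Inference uses a permutation null: foci are redrawn uniformly over in-mask
# voxels, giving (a) a pooled distribution of null ALE values for voxel-wise
# empirical p-values, and (b) a max-cluster-size distribution for
# cluster-level family-wise error control.

#' Gaussian kernel width conversions
#'
#' `kernel_sd()` converts a full width at half maximum to a standard
#' deviation, `sd = fwhm / (2 sqrt(2 ln 2))`. `fwhm_from_sample_size()`
#' returns a per-study FWHM from the study's subject count using the
#' empirical spatial-uncertainty convention of Eickhoff et al. (2009):
#' between-subject Euclidean uncertainty 11.6 mm (shrinking with
#' `sqrt(n)`) combined with between-template uncertainty 5.7 mm. For
#' n = 10 subjects this gives roughly a 10 mm FWHM.
#'
#' @param fwhm_mm full width at half maximum in mm (> 0).
#' @return standard deviation in mm.
#' @export
kernel_sd <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || any(fwhm_mm <= 0))
    stop("fwhm must be positive", call. = FALSE)
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

#' @rdname kernel_sd
#' @param n subject count(s) (> 0).
#' @export
fwhm_from_sample_size <- function(n) {
  if (!is.numeric(n) || any(n <= 0)) stop("n must be positive", call. = FALSE)
  # mean Euclidean displacement of a 3-D Gaussian is 2*sqrt(2/pi)*sd
  sd_subject <- 11.6 / (2 * sqrt(2 / pi))
  sd_template <- 5.7 / (2 * sqrt(2 / pi))
  sqrt(sd_subject^2 / n + sd_template^2) * 2 * sqrt(2 * log(2))
}

# Per-voxel max over per-focus Gaussian kernels, each kernel normalised to
# sum to one over its in-grid support. `truncate` limits each kernel to a
# cube of half-width truncate*sd around its focus (Inf = full grid).
#' @keywords internal
ma_values <- function(foci_mm, grid, sd, truncate = 5) {
  if (is.null(dim(foci_mm))) foci_mm <- matrix(foci_mm, ncol = 3L)
  if (nrow(foci_mm) < 1L) stop("study has no foci", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("kernel sd must be a single positive number", call. = FALSE)
  mm_to_voxel(grid, foci_mm)  # errors if any focus is outside the grid
  dims <- grid$dim; sp <- grid$spacing; org <- grid$origin
  r <- truncate * sd
  ax <- lapply(1:3, function(k) org[k] + (seq_len(dims[k]) - 1L) * sp)
  out <- array(0, dims)
  for (f in seq_len(nrow(foci_mm))) {
    ctr <- foci_mm[f, ]
    rng <- lapply(1:3, function(k) {
      if (!is.finite(r)) return(seq_len(dims[k]))
      lo <- max(1L, as.integer(ceiling((ctr[k] - r - org[k]) / sp)) + 1L)
      hi <- min(dims[k], as.integer(floor((ctr[k] + r - org[k]) / sp)) + 1L)
      if (lo > hi) {  # degenerate truncation: keep the focus's own voxel
        own <- min(max(1L, as.integer(round((ctr[k] - org[k]) / sp)) + 1L),
                   dims[k])
        lo <- hi <- own
      }
      lo:hi
    })
    d2 <- lapply(1:3, function(k) (ax[[k]][rng[[k]]] - ctr[k])^2)
    dist2 <- outer(outer(d2[[1L]], d2[[2L]], "+"), d2[[3L]], "+")
    kern <- exp(-dist2 / (2 * sd^2))
    kern <- kern / sum(kern)
    cur <- out[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
    out[rng[[1L]], rng[[2L]], rng[[3L]]] <- pmax(cur, kern)
  }
  out
}

#' Modelled-activation map for one study
#'
#' Applies an isotropic Gaussian kernel to each focus, normalised so the
#' kernel sums to one over the voxel lattice, and takes the voxel-wise
#' maximum over the study's foci.
#'
#' @param study_foci integer mm coordinates: an `n x 3` matrix, or a
#'   [foci_dataset()] holding a single study.
#' @param grid a [brain_grid()].
#' @param sd_mm kernel standard deviation in mm (see [kernel_sd()]).
#' @param truncate kernel support half-width in units of `sd_mm`
#'   (`Inf` = untruncated). The default keeps > 99.9999 % of kernel mass.
#' @param study_id optional label.
#' @return an object of class `ma_map`: list with `values` (array over the
#'   grid), `study_id`, `sd`, `grid`.
#' @export
modeled_activation <- function(study_foci, grid, sd_mm, truncate = 5,
                               study_id = NULL) {
  if (inherits(study_foci, "foci_dataset")) {
    if (length(unique(study_foci$study_id)) != 1L)
      stop("modeled_activation() takes a single study", call. = FALSE)
    study_id <- study_id %||% study_foci$study_id[1L]
    study_foci <- as.matrix(as.data.frame(study_foci)[c("x", "y", "z")])
  }
  structure(list(values = ma_values(study_foci, grid, sd_mm, truncate),
                 study_id = study_id %||% "study", sd = sd_mm, grid = grid),
            class = "ma_map")
}

same_grid <- function(g1, g2) {
  identical(g1$dim, g2$dim) && isTRUE(all.equal(g1$spacing, g2$spacing)) &&
    isTRUE(all.equal(g1$origin, g2$origin))
}

#' ALE union of modelled-activation maps
#'
#' Per-voxel complement-product union: `ALE(v) = 1 - prod_i (1 - MA_i(v))`.
#'
#' @param ma_maps list of [modeled_activation()] results sharing one grid.
#' @return numeric array of ALE values over the grid.
#' @export
ale_union <- function(ma_maps) {
  if (inherits(ma_maps, "ma_map")) ma_maps <- list(ma_maps)
  if (!length(ma_maps)) stop("no MA maps supplied", call. = FALSE)
  g <- ma_maps[[1L]]$grid
  comp <- 1
  for (m in ma_maps) {
    if (!same_grid(m$grid, g)) stop("MA maps are on different grids", call. = FALSE)
    comp <- comp * (1 - m$values)
  }
  1 - comp
}

# ALE map straight from a list of per-study foci matrices (mm).
#' @keywords internal
ale_from_foci <- function(foci_list, grid, sds, truncate = 5) {
  comp <- array(1, grid$dim)
  for (i in seq_along(foci_list))
    comp <- comp * (1 - ma_values(foci_list[[i]], grid, sds[[i]], truncate))
  1 - comp
}

# Empirical p with the add-one rule against a sorted pool of null values:
# p = (#{null >= v} + 1) / (n_pool + 1), so p is never zero.
#' @keywords internal
pvals_from_pool <- function(v, sorted_pool) {
  r <- length(sorted_pool) - findInterval(v, sorted_pool, left.open = TRUE)
  (r + 1) / (length(sorted_pool) + 1)
}

#' Permutation null for ALE inference
#'
#' For each permutation every study's foci are redrawn independently and
#' uniformly over in-mask voxel centres and the null ALE map is recomputed.
#' Records, per permutation, the maximum null ALE value and — at the
#' cluster-forming threshold `forming_p`, applied to pooled-null voxel-wise
#' p-values — the maximum 26-connected suprathreshold cluster size. The
#' pooled in-mask null ALE values (capped at `pool_cap`, strided
#' subsampling) provide the voxel-wise empirical null.
#'
#' @param study_sizes integer vector: foci count of each study (matching the
#'   observed per-study structure).
#' @param grid a [brain_grid()].
#' @param sd_mm kernel sd in mm, scalar or one per study.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (null is reproducible given the seed).
#' @param forming_p cluster-forming threshold on voxel-wise p.
#' @param truncate kernel truncation, as in [modeled_activation()].
#' @param pool_cap maximum number of pooled null values retained.
#' @return object of class `ale_null`: `max_ale`, `max_cluster_vox` (per
#'   permutation), `pool` (sorted null ALE values), plus the settings.
#' @export
permutation_null <- function(study_sizes, grid, sd_mm, n_perm, seed = 1L,
                             forming_p = 0.001, truncate = 5,
                             pool_cap = 5e6) {
  study_sizes <- as.integer(study_sizes)
  if (!length(study_sizes) || any(study_sizes < 1L))
    stop("study_sizes must be positive counts", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  sds <- if (length(sd_mm) == 1L) rep(sd_mm, length(study_sizes)) else sd_mm
  if (length(sds) != length(study_sizes))
    stop("sd_mm must be scalar or one per study", call. = FALSE)
  mask_idx <- which(grid$mask)
  if (!length(mask_idx)) stop("empty mask", call. = FALSE)
  mask_mm <- voxel_coordinates(grid)[mask_idx, , drop = FALSE]
  n_mask <- length(mask_idx)

  draws <- with_seed(seed, lapply(seq_len(n_perm), function(p)
    lapply(study_sizes, function(n)
      mask_mm[sample.int(n_mask, n, replace = TRUE), , drop = FALSE])))

  stride <- max(1L, ceiling(as.numeric(n_mask) * n_perm / pool_cap))
  keep <- seq(1L, n_mask, by = stride)
  cache_vals <- as.numeric(n_mask) * n_perm <= 2e7
  cached <- if (cache_vals) vector("list", n_perm)

  max_ale <- numeric(n_perm)
  pool <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    v <- ale_from_foci(draws[[p]], grid, sds, truncate)[mask_idx]
    max_ale[p] <- max(v)
    pool[[p]] <- v[keep]
    if (cache_vals) cached[[p]] <- v
  }
  pool <- sort(unlist(pool))

  max_cluster <- integer(n_perm)
  supra_arr <- array(FALSE, grid$dim)
  for (p in seq_len(n_perm)) {
    v <- if (cache_vals) cached[[p]]
         else ale_from_foci(draws[[p]], grid, sds, truncate)[mask_idx]
    supra <- pvals_from_pool(v, pool) < forming_p
    if (!any(supra)) { max_cluster[p] <- 0L; next }
    supra_arr[] <- FALSE
    supra_arr[mask_idx[supra]] <- TRUE
    max_cluster[p] <- max(label_clusters(supra_arr)$sizes)
  }
  structure(list(max_ale = max_ale, max_cluster_vox = max_cluster,
                 pool = pool, n_perm = n_perm, study_sizes = study_sizes,
                 sd_mm = sds, forming_p = forming_p, seed = seed,
                 grid = grid, truncate = truncate),
            class = "ale_null")
}

# 26-connected components of a logical 3-D array. Returns integer label
# array and per-label voxel counts. Plain BFS; suprathreshold sets are small.
#' @keywords internal
label_clusters <- function(mask_arr) {
  dims <- dim(mask_arr)
  lab <- array(0L, dims)
  idx <- which(mask_arr)
  if (!length(idx)) return(list(labels = lab, sizes = integer(0L)))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  sizes <- integer(0L)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue <- start
    head <- 1L
    count <- 1L
    while (head <= length(queue)) {
      co <- arrayInd(queue[head], dims)
      head <- head + 1L
      nb <- sweep(offs, 2L, as.integer(co), "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1L] + dims[1L] * (nb[, 2L] - 1L) +
        dims[1L] * dims[2L] * (nb[, 3L] - 1L)
      lin <- lin[mask_arr[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
        count <- count + length(lin)
      }
    }
    sizes[cur] <- count
  }
  list(labels = lab, sizes = sizes)
}

#' Voxel-wise p-values and cluster-level FWE thresholding
#'
#' Converts an ALE map to empirical p-values against the pooled permutation
#' null, forms 26-connected clusters of voxels with `p < forming_p`, and
#' keeps clusters whose size strictly exceeds the `(1 - fwe_p)` quantile of
#' the null maximum-cluster-size distribution. An empty cluster table (no
#' suprathreshold voxel or no surviving cluster) is a valid result, not an
#' error.
#'
#' @param ale_map numeric array over the null's grid (see [ale_union()]).
#' @param null an `ale_null` from [permutation_null()].
#' @param forming_p cluster-forming threshold; must equal the value the null
#'   was built with.
#' @param fwe_p cluster-level family-wise error rate.
#' @return list with `p_map` (array; in-mask voxels only, `NA` elsewhere),
#'   `thresholded` (array of ALE values inside surviving clusters, 0
#'   elsewhere), and `clusters` (data frame: `cluster`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_ale`, `size_vox`, `size_mm3`, `cluster_p`, sorted by
#'   size descending).
#' @export
threshold_clusters <- function(ale_map, null, forming_p = null$forming_p,
                               fwe_p = 0.05) {
  stopifnot(inherits(null, "ale_null"))
  if (!length(null$pool)) stop("null is empty", call. = FALSE)
  if (forming_p <= 0 || forming_p >= 1 || fwe_p <= 0 || fwe_p >= 1)
    stop("forming_p and fwe_p must lie in (0, 1)", call. = FALSE)
  if (!isTRUE(all.equal(forming_p, null$forming_p)))
    stop("forming_p differs from the value the null was built with; ",
         "rebuild the null", call. = FALSE)
  grid <- null$grid
  if (!identical(dim(ale_map), grid$dim))
    stop("ale_map does not match the null's grid", call. = FALSE)
  mask_idx <- which(grid$mask)
  p_map <- array(NA_real_, grid$dim)
  p_map[mask_idx] <- pvals_from_pool(ale_map[mask_idx], null$pool)

  supra <- array(FALSE, grid$dim)
  supra[mask_idx] <- p_map[mask_idx] < forming_p
  lab <- label_clusters(supra)
  empty <- data.frame(cluster = integer(0L), peak_x = numeric(0L),
                      peak_y = numeric(0L), peak_z = numeric(0L),
                      peak_ale = numeric(0L), size_vox = integer(0L),
                      size_mm3 = numeric(0L), cluster_p = numeric(0L))
  thresholded <- array(0, grid$dim)
  if (!length(lab$sizes))
    return(list(p_map = p_map, thresholded = thresholded, clusters = empty))

  # surviving clusters must STRICTLY exceed the null size quantile
  cutoff <- stats::quantile(null$max_cluster_vox, 1 - fwe_p, type = 1,
                            names = FALSE)
  surv <- which(lab$sizes > cutoff)
  if (!length(surv))
    return(list(p_map = p_map, thresholded = thresholded, clusters = empty))
  rows <- lapply(surv, function(cl) {
    vox <- which(lab$labels == cl)
    peak <- vox[which.max(ale_map[vox])]
    mm <- voxel_to_mm(grid, arrayInd(peak, grid$dim))
    size <- lab$sizes[cl]
    data.frame(cluster = cl, peak_x = mm[1L], peak_y = mm[2L], peak_z = mm[3L],
               peak_ale = ale_map[peak], size_vox = size,
               size_mm3 = size * voxel_volume(grid),
               cluster_p = (sum(null$max_cluster_vox >= size) + 1) /
                 (null$n_perm + 1))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$size_vox, tab$cluster), , drop = FALSE]
  for (i in seq_len(nrow(tab)))
    thresholded[lab$labels == tab$cluster[i]] <- ale_map[lab$labels == tab$cluster[i]]
  tab$cluster <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(p_map = p_map, thresholded = thresholded, clusters = tab)
}

#' Run a full ALE meta-analysis
#'
#' Computes per-study modelled-activation maps, the ALE union, a permutation
#' null, voxel-wise empirical p-values, and the cluster-level FWE-thresholded
#' result, for all studies in the dataset (subset to one group first for a
#' per-group analysis, see [filter_group()]).
#'
#' @param ds a [foci_dataset()].
#' @param grid a [brain_grid()]; all foci must fall inside it.
#' @param fwhm kernel FWHM in mm: scalar, or a named per-study vector.
#' @param sample_sizes optional named per-study subject counts; when given,
#'   per-study FWHMs come from [fwhm_from_sample_size()] and `fwhm` is
#'   ignored.
#' @param n_perm permutations for the null (the conventional choice is 1000).
#' @param forming_p cluster-forming threshold on voxel-wise p (default 0.001).
#' @param fwe_p cluster-level family-wise error rate (default 0.05).
#' @param seed RNG seed for the permutation null.
#' @param truncate kernel truncation, see [modeled_activation()].
#' @return object of class `ale_result`: `ale` (array), `p_map`,
#'   `thresholded`, `clusters` (table as in [threshold_clusters()]), `null`,
#'   `grid`, and the parameters.
#' @export
ale <- function(ds, grid = brain_grid(), fwhm = 10, sample_sizes = NULL,
                n_perm = 1000, forming_p = 0.001, fwe_p = 0.05, seed = 1L,
                truncate = 5) {
  stopifnot(inherits(ds, "foci_dataset"))
  studies <- unique(ds$study_id)
  foci_list <- lapply(studies, function(s)
    as.matrix(as.data.frame(ds)[ds$study_id == s, c("x", "y", "z")]))
  if (!is.null(sample_sizes)) {
    if (is.null(names(sample_sizes)) || !all(studies %in% names(sample_sizes)))
      stop("sample_sizes must be named by study_id", call. = FALSE)
    fwhms <- fwhm_from_sample_size(sample_sizes[studies])
  } else if (length(fwhm) == 1L) {
    fwhms <- rep(fwhm, length(studies))
  } else {
    if (is.null(names(fwhm)) || !all(studies %in% names(fwhm)))
      stop("per-study fwhm must be named by study_id", call. = FALSE)
    fwhms <- fwhm[studies]
  }
  sds <- kernel_sd(fwhms)
  ma_maps <- lapply(seq_along(studies), function(i)
    modeled_activation(foci_list[[i]], grid, sds[i], truncate = truncate,
                       study_id = studies[i]))
  ale_map <- ale_union(ma_maps)
  null <- permutation_null(vapply(foci_list, nrow, integer(1L)), grid, sds,
                           n_perm = n_perm, seed = seed,
                           forming_p = forming_p, truncate = truncate)
  thr <- threshold_clusters(ale_map, null, forming_p = forming_p,
                            fwe_p = fwe_p)
  structure(c(list(ale = ale_map, ma_maps = ma_maps, grid = grid,
                   studies = studies, fwhm = fwhms, n_perm = n_perm,
                   forming_p = forming_p, fwe_p = fwe_p, seed = seed,
                   null = null), thr),
            class = "ale_result")
}

#' Subset a foci dataset to one group
#' @param ds a [foci_dataset()].
#' @param group group label to keep.
#' @return a [foci_dataset()].
#' @export
filter_group <- function(ds, group) {
  stopifnot(inherits(ds, "foci_dataset"))
  if (!group %in% ds$group) stop("no such group: ", group, call. = FALSE)
  foci_dataset(as.data.frame(ds)[ds$group == group, , drop = FALSE],
               space = foci_space(ds), allow_duplicates = TRUE)
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf("ALE meta-analysis: %d studies, %d permutations\n",
              length(x$studies), x$n_perm))
  cat(sprintf("  forming p < %g, cluster-level FWE p < %g\n",
              x$forming_p, x$fwe_p))
  if (nrow(x$clusters) == 0L) cat("  no surviving clusters\n")
  else {
    cat(sprintf("  %d surviving cluster(s):\n", nrow(x$clusters)))
    print(x$clusters, digits = 4)
  }
  invisible(x)
}

#' @export
summary.ale_result <- function(object, ...) {
  cat(sprintf("Max ALE value: %.4f; in-mask voxels: %d\n",
              max(object$ale[object$grid$mask]), sum(object$grid$mask)))
  print(object)
}

#' Write ALE maps as NIfTI-1 and the cluster table as CSV
#'
#' @param fit an `ale_result` from [ale()].
#' @param dir output directory (created if needed). Writes
#'   `ale.nii.gz` (unthresholded, float32), `ale_thresholded.nii.gz`,
#'   and `clusters.csv`.
#' @return character vector of paths written, invisibly.
#' @export
write_ale <- function(fit, dir) {
  stopifnot(inherits(fit, "ale_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- grid_affine(fit$grid)
  out <- character(0L)
  for (nm in c("ale", "thresholded")) {
    img <- RNifti::asNifti(array(as.numeric(fit[[nm]]), dim = fit$grid$dim),
                           datatype = "float")
    RNifti::sform(img) <- structure(aff, code = 2L)
    path <- file.path(dir, if (nm == "ale") "ale.nii.gz"
                           else "ale_thresholded.nii.gz")
    RNifti::writeNifti(img, path)
    out <- c(out, path)
  }
  csv <- file.path(dir, "clusters.csv")
  utils::write.csv(fit$clusters, csv, row.names = FALSE)
  invisible(c(out, csv))
}

#' @export
plot.ale_result <- function(x, ...) {
  # maximum-intensity projection of the thresholded map onto the sagittal,
  # coronal and axial planes; falls back to the raw ALE map if nothing survives
  src <- if (any(x$thresholded > 0)) x$thresholded else x$ale
  old <- graphics::par(mfrow = c(1, 3), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  planes <- list(c(2, 3), c(1, 3), c(1, 2))
  titles <- c("sagittal MIP", "coronal MIP", "axial MIP")
  for (i in 1:3) {
    proj <- apply(src, planes[[i]], max)
    graphics::image(proj, main = titles[i], axes = FALSE,
                    col = grDevices::hcl.colors(64, "inferno"))
  }
  invisible(x)
}
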