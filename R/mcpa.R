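# Multi-coordinate pattern analysis: the user-facing model.
#
# mcpa() encodes foci into the three per-axis one-hot blocks (unless given a
# ready-made encoding) and fits the multi-block sparse PLS-DA, returning a
# single classed object that owns the column vocabulary, so new foci
# datasets can be predicted directly.

#' Fit a multi-coordinate pattern analysis model
#'
#' One-hot encodes integer foci coordinates into three binary blocks (one
#' per axis) and fits a multi-block sparse PLS discriminant model of the
#' group label. See [block_splsda()] for the model and its constraints.
#'
#' @param x a [foci_dataset()] (encoded internally with
#'   [encode_pattern3()]) or an `onehot_blocks` object.
#' @param ncomp number of latent components (default 2).
#' @param keep retained variables per block per component; `NULL` = all
#'   (non-sparse). See [block_splsda()].
#' @param design block connection weights; default fully connected.
#' @param scale unit-variance scale the binary columns (default `TRUE`).
#' @param ... passed to [block_splsda()].
#' @return object of class `mcpa`: `fit` (the `block_splsda`), `vocabulary`
#'   (the training `onehot_blocks`, data matrices dropped), plus the
#'   encoding levels needed to align new data.
#' @export
mcpa <- function(x, ...) UseMethod("mcpa")

#' @rdname mcpa
#' @export
mcpa.foci_dataset <- function(x, ncomp = 2, keep = NULL, design = NULL,
                              scale = TRUE, ...) {
  mcpa(encode_pattern3(x), ncomp = ncomp, keep = keep, design = design,
       scale = scale, ...)
}

#' @rdname mcpa
#' @export
mcpa.onehot_blocks <- function(x, ncomp = 2, keep = NULL, design = NULL,
                               scale = TRUE, ...) {
  fit <- block_splsda(x$blocks, x$outcome, ncomp = ncomp, keep = keep,
                      design = design, scale = scale, ...)
  structure(list(fit = fit, levels = x$levels, outcome_levels = levels(x$outcome),
                 space = x$space),
            class = "mcpa")
}

#' @export
print.mcpa <- function(x, ...) {
  cat("Multi-coordinate pattern analysis (one-hot blocks + multi-block sPLS-DA)\n")
  print(x$fit)
  invisible(x)
}

#' @export
summary.mcpa <- function(object, ...) {
  print(object)
  fit <- object$fit
  cls <- classify_scores(fit, fit$scores)
  cat(sprintf("  training (resubstitution) BER: %.4f\n",
              balanced_error_rate(fit$y, cls)))
  cat("  confusion matrix (rows = truth):\n")
  print(table(truth = fit$y, predicted = cls))
  invisible(object)
}

# Nearest-centroid vote on precomputed latent scores (shared by predict and
# resubstitution summaries).
#' @keywords internal
classify_scores <- function(fit, scores) {
  bn <- names(scores)
  n <- nrow(scores[[1L]])
  G <- length(fit$levels)
  dist_sum <- matrix(0, n, G)
  block_class <- matrix(NA_integer_, n, length(bn))
  for (k in seq_along(bn)) {
    d <- matrix(0, n, G)
    for (g in seq_len(G))
      d[, g] <- sqrt(rowSums(sweep(scores[[bn[k]]], 2L,
                                   fit$centroids[[bn[k]]][g, ])^2))
    dist_sum <- dist_sum + d
    block_class[, k] <- max.col(-d, ties.method = "first")
  }
  votes <- t(apply(block_class, 1L, tabulate, nbins = G))
  cls <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[order(dist_sum[i, top], top)][1L]
    cls[i] <- top
  }
  factor(fit$levels[cls], levels = fit$levels)
}

#' @export
coef.mcpa <- function(object, ...) {
  load_long(object$fit)
}

# Long-format loadings (block, component, column, value), nonzero rows only.
#' @keywords internal
load_long <- function(fit) {
  rows <- list()
  for (q in names(fit$loadings)) {
    L <- fit$loadings[[q]]
    for (h in seq_len(ncol(L))) {
      nz <- which(L[, h] != 0)
      if (!length(nz)) next
      rows[[length(rows) + 1L]] <-
        data.frame(block = q, component = h, column = rownames(L)[nz],
                   value = L[nz, h], row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' @export
predict.mcpa <- function(object, newdata, ...) {
  if (inherits(newdata, "foci_dataset")) {
    vocab <- structure(list(levels = object$levels,
                            outcome = factor(character(0L),
                                             levels = object$outcome_levels)),
                       class = "onehot_blocks")
    newdata <- align_columns(vocab, newdata)
  }
  predict(object$fit, newdata, ...)
}

#' @export
plot.mcpa <- function(x, block = "x", comps = c(1, 2), ...) {
  s <- x$fit$scores[[block]]
  if (x$fit$ncomp == 1L) {
    graphics::stripchart(s[, 1L] ~ x$fit$y, method = "jitter", pch = 16,
                         xlab = "component 1 score", ...)
  } else {
    plot(s[, comps[1L]], s[, comps[2L]],
         col = as.integer(x$fit$y), pch = 16,
         xlab = sprintf("component %d", comps[1L]),
         ylab = sprintf("component %d", comps[2L]),
         main = sprintf("latent scores, block %s", block), ...)
    graphics::legend("topright", legend = levels(x$fit$y),
                     col = seq_len(nlevels(x$fit$y)), pch = 16, bty = "n")
  }
  invisible(x)
}

#' Serialise / restore a fitted MCPA model as plain JSON
#'
#' Stores loadings, deflation vectors, centroids, centring/scaling
#' parameters, vocabulary and configuration — everything [predict.mcpa()]
#' and [association_matrix()] need except the raw training matrices (the
#' association matrix is precomputed into the archive).
#'
#' @param object an [mcpa()] fit.
#' @param path file to write / read.
#' @return `write_mcpa()` returns `path` invisibly; `read_mcpa()` returns an
#'   `mcpa` object (without training data; refitting is needed for new
#'   association matrices at other depths).
#' @export
write_mcpa <- function(object, path) {
  stopifnot(inherits(object, "mcpa"))
  fit <- object$fit
  payload <- list(
    levels = object$levels, outcome_levels = object$outcome_levels,
    space = object$space, ncomp = fit$ncomp, keep = fit$keep,
    design = fit$design, scaled = fit$scaled,
    loadings = lapply(fit$loadings, function(m)
      list(rows = rownames(m), values = as.numeric(m), ncol = ncol(m))),
    b = list(rows = rownames(fit$b), values = as.numeric(fit$b)),
    p = lapply(fit$p, function(m) as.numeric(m)),
    centroids = lapply(fit$centroids, function(m)
      list(rows = rownames(m), values = as.numeric(m))),
    # named vectors must be stored as JSON objects, not arrays, to keep names
    centers = lapply(fit$centers, as.list),
    scales = lapply(fit$scales, as.list),
    explained = as.numeric(fit$explained),
    association = {
      am <- association_matrix(object)
      lapply(am$pairs, function(m)
        list(rows = rownames(m), cols = colnames(m), values = as.numeric(m)))
    })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mcpa
#' @export
read_mcpa <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(spec, ncol) {
    m <- matrix(spec$values, ncol = ncol)
    rownames(m) <- spec$rows
    m
  }
  ncomp <- pl$ncomp
  loadings <- lapply(pl$loadings, rebuild, ncol = ncomp)
  fit <- structure(list(
    loadings = loadings,
    b = rebuild(pl$b, ncomp),
    p = mapply(function(v, L) matrix(v, ncol = ncomp),
               pl$p, loadings, SIMPLIFY = FALSE),
    centroids = lapply(pl$centroids, rebuild, ncol = ncomp),
    keep = matrix(pl$keep, nrow = ncomp,
                  dimnames = list(NULL, names(loadings))),
    design = pl$design, ncomp = ncomp,
    levels = pl$outcome_levels,
    centers = lapply(pl$centers, unlist),
    scales = lapply(pl$scales, unlist), scaled = pl$scaled,
    explained = matrix(pl$explained, nrow = length(loadings),
                       dimnames = list(names(loadings), NULL))),
    class = "block_splsda")
  assoc <- lapply(pl$association, function(spec) {
    m <- matrix(spec$values, nrow = length(spec$rows),
                dimnames = list(spec$rows, spec$cols))
    m
  })
  structure(list(fit = fit, levels = lapply(pl$levels, as.integer),
                 outcome_levels = pl$outcome_levels, space = pl$space,
                 association = structure(list(pairs = assoc, d = ncomp),
                                         class = "association_matrix")),
            class = "mcpa")
}
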