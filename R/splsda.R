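# Multi-block sparse partial least squares discriminant analysis.
#
# Given Q feature blocks X^(1..Q) over the same N samples and a categorical
# outcome Y (as a centred/scaled dummy matrix), each component h maximises
# the design-weighted sum of covariances
#   sum_{q != j} c_{q,j} cov(X_h^(q) a_h^(q), X_h^(j) a_h^(j))
#     + sum_q c_{q,Y} cov(X_h^(q) a_h^(q), Y_h b_h)
# subject to ||a_h^(q)||_2 = ||b_h||_2 = 1 and a per-block cardinality bound
# (at most `keep` nonzero loading entries — the variable-count reading of an
# L1 constraint). Solved by alternating power-style updates with
# soft-thresholding; blocks and outcome are deflated by regression on their
# own latent scores between components, which makes successive scores within
# a block exactly orthogonal.

# Soft-threshold w so at most `keep` entries stay nonzero: shrink by the
# (keep+1)-th largest |w|. Returns the unit-norm loading.
#' @keywords internal
sparsify_loading <- function(w, keep) {
  w <- as.numeric(w)
  p <- length(w)
  if (keep < p) {
    w_orig <- w
    thr <- sort(abs(w), decreasing = TRUE)[keep + 1L]
    w <- sign(w) * pmax(abs(w) - thr, 0)
    if (all(w == 0)) {
      # fully tied weights: fall back to hard selection, smallest index first
      pick <- order(-abs(w_orig), seq_along(w_orig))[seq_len(keep)]
      w[pick] <- w_orig[pick]
      if (all(w == 0)) w[pick] <- 1
    }
  }
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate loading (all-zero weights)", call. = FALSE)
  w / nrm
}

center_scale <- function(m, scale) {
  ctr <- colMeans(m)
  m <- sweep(m, 2L, ctr)
  scl <- rep(1, ncol(m))
  if (scale) {
    scl <- apply(m, 2L, stats::sd)
    scl[scl == 0] <- 1
    m <- sweep(m, 2L, scl, "/")
  }
  list(m = m, center = ctr, scale = scl)
}

normalize_keep <- function(keep, blocks, ncomp) {
  p <- vapply(blocks, ncol, integer(1L))
  out <- matrix(rep(p, each = ncomp), nrow = ncomp,
                dimnames = list(NULL, names(blocks)))
  if (is.null(keep)) return(out)
  if (is.list(keep)) {
    if (!all(names(keep) %in% names(blocks)))
      stop("keep list must be named by block", call. = FALSE)
    for (b in names(keep)) out[, b] <- rep_len(keep[[b]], ncomp)
  } else if (length(keep) %in% c(1L, ncomp)) {
    out <- matrix(rep_len(keep, ncomp), nrow = ncomp, ncol = length(blocks),
                  dimnames = list(NULL, names(blocks)))
  } else {
    stop("keep must be a scalar, a length-ncomp vector, or a per-block list",
         call. = FALSE)
  }
  storage.mode(out) <- "integer"
  for (b in names(blocks))
    if (any(out[, b] > p[[b]]) || any(out[, b] < 1L))
      stop("keep for block '", b, "' must lie in [1, ", p[[b]], "]",
           call. = FALSE)
  out
}

# Discriminant ("null") design: every block connected to the outcome with
# weight 1, no block-block connections. One-hot coordinate blocks contain
# duplicated columns wherever a focus carries a coordinate value seen
# nowhere else (its x/y/z indicator columns are then identical vectors, so
# their cross-block correlation is exactly 1); any positive block-block
# weight lets a component latch onto such duplicates instead of the class
# signal once the leading discriminative direction is deflated out.
default_design <- function(block_names) {
  n <- length(block_names) + 1L
  d <- matrix(0, n, n, dimnames = list(c(block_names, "Y"),
                                       c(block_names, "Y")))
  d[n, ] <- d[, n] <- 1
  diag(d) <- 0
  d
}

#' Fit a multi-block sparse PLS discriminant model
#'
#' The computational engine behind [mcpa()]. Blocks are column-centred and
#' (by default) unit-variance scaled; zero-variance columns are dropped with
#' a warning. Fitting is deterministic: each component is initialised from
#' the leading singular direction of the block-outcome cross-product, and
#' the loading entry of largest magnitude is made positive.
#'
#' @param X named list of numeric matrices (same rows, named columns).
#' @param y factor outcome (>= 2 classes present).
#' @param ncomp number of latent components H (default 2).
#' @param keep per-block, per-component count of retained variables: `NULL`
#'   (all, non-sparse), a scalar, a length-`ncomp` vector, or a named list
#'   of per-block vectors.
#' @param design symmetric `(Q+1) x (Q+1)` matrix of connection weights in
#'   `[0, 1]` between blocks (and the outcome, last row/column). The default
#'   is the discriminant design — each block linked to the outcome with
#'   weight 1 and no block-block links — which keeps components aimed at
#'   class separation; see the methods vignette for why this matters for
#'   one-hot coordinate blocks.
#' @param scale unit-variance scale columns (default `TRUE`; centring always).
#' @param tol,max_iter convergence control for the alternating updates.
#' @return object of class `block_splsda`; see [mcpa()] for the fields.
#' @export
block_splsda <- function(X, y, ncomp = 2, keep = NULL, design = NULL,
                         scale = TRUE, tol = 1e-9, max_iter = 500L) {
  if (!is.list(X) || is.null(names(X)) || !length(X))
    stop("X must be a named list of matrices", call. = FALSE)
  y <- droplevels(factor(y))
  n <- nrow(X[[1L]])
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (nlevels(y) < 2L) stop("outcome has a single class", call. = FALSE)
  if (any(vapply(X, nrow, integer(1L)) != n))
    stop("blocks have differing row counts", call. = FALSE)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)

  # drop zero-variance columns, keep the map for prediction-time alignment
  kept_cols <- lapply(X, function(m) {
    v <- apply(m, 2L, stats::sd)
    which(v > 0)
  })
  for (b in names(X)) {
    if (!length(kept_cols[[b]]))
      stop("block '", b, "' has zero variance", call. = FALSE)
    if (length(kept_cols[[b]]) < ncol(X[[b]]))
      warning(ncol(X[[b]]) - length(kept_cols[[b]]),
              " zero-variance column(s) dropped from block '", b, "'",
              call. = FALSE)
    X[[b]] <- X[[b]][, kept_cols[[b]], drop = FALSE]
  }
  keep <- normalize_keep(keep, X, ncomp)
  if (is.null(design)) design <- default_design(names(X))
  qn <- c(names(X), "Y")
  if (!identical(dim(design), c(length(qn), length(qn))) ||
      !isTRUE(all.equal(design, t(design))) ||
      any(design < 0) || any(design > 1))
    stop("design must be a symmetric (Q+1)x(Q+1) matrix with entries in [0,1]",
         call. = FALSE)
  dimnames(design) <- list(qn, qn)

  Xs <- lapply(X, center_scale, scale = scale)
  Xc <- lapply(Xs, `[[`, "m")
  Ydum <- stats::model.matrix(~ y - 1)
  colnames(Ydum) <- levels(y)
  Ys <- center_scale(Ydum, scale = scale)
  Yc <- Ys$m

  bn <- names(X)
  Q <- length(bn)
  totvar <- vapply(Xc, function(m) sum(m^2), numeric(1L))

  loadings <- lapply(X, function(m)
    matrix(0, ncol(m), ncomp, dimnames = list(colnames(m), NULL)))
  b_load <- matrix(0, nlevels(y), ncomp, dimnames = list(levels(y), NULL))
  scores <- lapply(X, function(m) matrix(0, n, ncomp))
  u_scores <- matrix(0, n, ncomp)
  ploads <- lapply(X, function(m) matrix(0, ncol(m), ncomp))
  ev <- matrix(0, Q, ncomp, dimnames = list(bn, NULL))
  iters <- integer(ncomp)

  Xh <- Xc
  Yh <- Yc
  for (h in seq_len(ncomp)) {
    a <- lapply(bn, function(b) {
      m <- crossprod(Xh[[b]], Yh)
      v <- svd(m, nu = 1L, nv = 0L)$u[, 1L]
      if (all(v == 0) || sum(m^2) == 0) v <- c(1, rep(0, ncol(Xh[[b]]) - 1L))
      v / sqrt(sum(v^2))
    })
    names(a) <- bn
    tt <- lapply(bn, function(b) drop(Xh[[b]] %*% a[[b]]))
    names(tt) <- bn
    bvec <- drop(crossprod(Yh, Reduce(`+`, tt)))
    if (all(bvec == 0)) bvec <- c(1, rep(0, ncol(Yh) - 1L))
    bvec <- bvec / sqrt(sum(bvec^2))
    u <- drop(Yh %*% bvec)

    for (it in seq_len(max_iter)) {
      a_old <- a
      for (q in bn) {
        s <- design[q, "Y"] * u
        for (j in bn) if (j != q) s <- s + design[q, j] * tt[[j]]
        w <- crossprod(Xh[[q]], s)
        a[[q]] <- sparsify_loading(w, keep[h, q])
        tt[[q]] <- drop(Xh[[q]] %*% a[[q]])
      }
      sy <- 0
      for (j in bn) sy <- sy + design["Y", j] * tt[[j]]
      bvec <- drop(crossprod(Yh, sy))
      bvec <- bvec / sqrt(sum(bvec^2))
      u <- drop(Yh %*% bvec)
      delta <- max(vapply(bn, function(q) max(abs(a[[q]] - a_old[[q]])),
                          numeric(1L)))
      if (delta < tol) break
    }
    iters[h] <- it

    # deterministic sign: largest-|entry| of each loading is positive
    for (q in bn) {
      if (a[[q]][which.max(abs(a[[q]]))] < 0) {
        a[[q]] <- -a[[q]]
        tt[[q]] <- -tt[[q]]
      }
    }
    if (bvec[which.max(abs(bvec))] < 0) {
      bvec <- -bvec
      u <- -u
    }

    for (q in bn) {
      loadings[[q]][, h] <- a[[q]]
      scores[[q]][, h] <- tt[[q]]
      tsq <- sum(tt[[q]]^2)
      p <- if (tsq > 0) drop(crossprod(Xh[[q]], tt[[q]])) / tsq
           else rep(0, ncol(Xh[[q]]))
      ploads[[q]][, h] <- p
      ev[q, h] <- tsq * sum(p^2) / totvar[[q]]
      Xh[[q]] <- Xh[[q]] - tcrossprod(tt[[q]], p)
    }
    b_load[, h] <- bvec
    u_scores[, h] <- u
    usq <- sum(u^2)
    cy <- if (usq > 0) drop(crossprod(Yh, u)) / usq else rep(0, ncol(Yh))
    Yh <- Yh - tcrossprod(u, cy)
  }

  centroids <- lapply(bn, function(q) {
    cm <- matrix(0, nlevels(y), ncomp, dimnames = list(levels(y), NULL))
    for (g in levels(y)) cm[g, ] <- colMeans(scores[[q]][y == g, , drop = FALSE])
    cm
  })
  names(centroids) <- bn

  structure(list(loadings = loadings, b = b_load, scores = scores,
                 u = u_scores, p = ploads, centroids = centroids,
                 keep = keep, design = design, ncomp = ncomp,
                 levels = levels(y), y = y,
                 centers = lapply(Xs, `[[`, "center"),
                 scales = lapply(Xs, `[[`, "scale"),
                 kept_cols = kept_cols, scaled = scale,
                 Xtrain = Xc, explained = ev, totvar = totvar,
                 iterations = iters),
            class = "block_splsda")
}

# Centre/scale new blocks with training parameters, column-aligned by name.
scale_new_blocks <- function(object, blocks) {
  bn <- names(object$loadings)
  out <- vector("list", length(bn))
  names(out) <- bn
  for (q in bn) {
    m <- blocks[[q]]
    if (is.null(m)) stop("missing block '", q, "'", call. = FALSE)
    want <- rownames(object$loadings[[q]])
    if (!all(want %in% colnames(m)))
      stop("block '", q, "' is not column-aligned to the model vocabulary",
           call. = FALSE)
    m <- m[, want, drop = FALSE]
    m <- sweep(m, 2L, object$centers[[q]][want])
    m <- sweep(m, 2L, object$scales[[q]][want], "/")
    out[[q]] <- m
  }
  out
}

# Latent scores of new data under the fitted deflation sequence.
project_blocks <- function(object, Xn) {
  bn <- names(Xn)
  scores <- lapply(Xn, function(m) matrix(0, nrow(m), object$ncomp))
  for (h in seq_len(object$ncomp)) {
    for (q in bn) {
      t_h <- drop(Xn[[q]] %*% object$loadings[[q]][, h])
      scores[[q]][, h] <- t_h
      Xn[[q]] <- Xn[[q]] - tcrossprod(t_h, object$p[[q]][, h])
    }
  }
  scores
}

#' Predict classes from a multi-block sparse PLS-DA model
#'
#' Each block's test rows are projected onto the fitted components and
#' assigned to the nearest training class centroid (Euclidean distance in
#' latent space); blocks are then combined by majority vote, with ties
#' broken by the smallest mean centroid distance across blocks, then by the
#' first class level. All-zero rows (unseen coordinate values) project to
#' the origin and are still classified.
#'
#' @param object a `block_splsda` fit.
#' @param newdata named list of matrices, or an `onehot_blocks` object,
#'   column-aligned to the model vocabulary (see [align_columns()]).
#' @param ... unused.
#' @return list with `class` (factor), `block_class` (per-block factor
#'   matrix), and `scores` (per-block latent score matrices).
#' @export
predict.block_splsda <- function(object, newdata, ...) {
  blocks <- if (inherits(newdata, "onehot_blocks")) newdata$blocks else newdata
  Xn <- scale_new_blocks(object, blocks)
  scores <- project_blocks(object, Xn)
  bn <- names(scores)
  block_class <- vapply(bn, function(q) {
    d <- vapply(seq_along(object$levels), function(g)
      sqrt(rowSums(sweep(scores[[q]], 2L, object$centroids[[q]][g, ])^2)),
      numeric(nrow(scores[[q]])))
    d <- matrix(d, ncol = length(object$levels))
    object$levels[max.col(-d, ties.method = "first")]
  }, character(nrow(scores[[1L]])))
  block_class <- matrix(block_class, ncol = length(bn),
                        dimnames = list(NULL, bn))
  list(class = classify_scores(object, scores),
       block_class = as.data.frame(block_class, stringsAsFactors = FALSE),
       scores = scores)
}

#' Balanced error rate
#'
#' Mean over classes of the per-class misclassification rate, so that
#' imbalanced groups weigh equally. A perfect prediction gives 0; a constant
#' predictor over two present classes gives 0.5.
#'
#' @param truth true labels (every class must have at least one member).
#' @param predicted predicted labels, same length.
#' @return BER in `[0, 1]`.
#' @export
balanced_error_rate <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ", call. = FALSE)
  classes <- sort(unique(truth))
  per_class <- vapply(classes, function(g) {
    in_g <- truth == g
    if (!any(in_g)) stop("class '", g, "' has no members", call. = FALSE)
    mean(predicted[in_g] != g)
  }, numeric(1L))
  mean(per_class)
}

#' Tune the per-block variable count by held-out balanced error rate
#'
#' Fits one model per grid value (the same `keep` for every block and
#' component), evaluates the balanced error rate on the held-out encoding,
#' and selects the argmin (smallest keep on ties).
#'
#' @param train_blocks training `onehot_blocks` (vocabulary owner).
#' @param eval_blocks held-out `onehot_blocks`, column-aligned to
#'   `train_blocks` (see [align_columns()]).
#' @param grid candidate variable counts (default `seq(5, 110, by = 5)`);
#'   values must not exceed the narrowest block.
#' @param ncomp,design,scale passed to [block_splsda()].
#' @return object of class `mcpa_tuning`: `trajectory` (data frame `keep`,
#'   `ber`), `best_keep`, `best_ber`.
#' @export
tune_keep <- function(train_blocks, eval_blocks, grid = seq(5, 110, by = 5),
                      ncomp = 2, design = NULL, scale = TRUE) {
  stopifnot(inherits(train_blocks, "onehot_blocks"))
  if (!length(grid)) stop("empty tuning grid", call. = FALSE)
  grid <- sort(unique(as.integer(grid)))
  pmin_block <- min(vapply(train_blocks$blocks, ncol, integer(1L)))
  if (any(grid > pmin_block))
    stop("grid values exceed the narrowest block (", pmin_block, " columns)",
         call. = FALSE)
  ebl <- if (inherits(eval_blocks, "onehot_blocks")) eval_blocks$blocks
         else eval_blocks
  etruth <- if (inherits(eval_blocks, "onehot_blocks")) eval_blocks$outcome
            else attr(eval_blocks, "outcome")
  ber <- vapply(grid, function(k) {
    fit <- suppressWarnings(block_splsda(train_blocks$blocks,
                                         train_blocks$outcome, ncomp = ncomp,
                                         keep = k, design = design,
                                         scale = scale))
    pred <- predict(fit, ebl)
    balanced_error_rate(etruth, pred$class)
  }, numeric(1L))
  best <- grid[which.min(ber)]  # which.min takes the first (smallest) argmin
  structure(list(trajectory = data.frame(keep = grid, ber = ber),
                 best_keep = best, best_ber = min(ber)),
            class = "mcpa_tuning")
}

#' @export
print.mcpa_tuning <- function(x, ...) {
  cat(sprintf("Sparsity tuning over %d grid values: best keep = %d (BER %.4f)\n",
              nrow(x$trajectory), x$best_keep, x$best_ber))
  invisible(x)
}

#' @export
plot.mcpa_tuning <- function(x, ...) {
  plot(x$trajectory$keep, x$trajectory$ber, type = "b", pch = 16,
       xlab = "retained variables per block", ylab = "balanced error rate",
       main = "BER trajectory", ...)
  graphics::abline(v = x$best_keep, lty = 2, col = "grey40")
  invisible(x)
}

#' Fraction of a block's variance explained by one component
#'
#' The variance of the rank-one reconstruction `t_h p_h'` of the (centred,
#' scaled) block as a fraction of its total variance; fractions across all
#' fitted components of a block sum to at most 1.
#'
#' @param model a `block_splsda` (or [mcpa()]) fit.
#' @param block block name (`"x"`, `"y"` or `"z"` for MCPA).
#' @param component component index `1..ncomp`; omit for all components.
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
explained_variance <- function(model, block, component = NULL) {
  if (inherits(model, "mcpa")) model <- model$fit
  stopifnot(inherits(model, "block_splsda"))
  if (!block %in% rownames(model$explained))
    stop("unknown block: ", block, call. = FALSE)
  if (is.null(component)) return(unname(model$explained[block, ]))
  if (component < 1L || component > model$ncomp)
    stop("component must lie in 1..", model$ncomp, call. = FALSE)
  unname(model$explained[block, component])
}

#' @export
print.block_splsda <- function(x, ...) {
  cat(sprintf("Multi-block sparse PLS-DA: %d blocks, %d components, %d samples\n",
              length(x$loadings), x$ncomp, length(x$y)))
  cat("  keep per component:\n")
  print(x$keep)
  cat("  explained variance per block x component:\n")
  print(round(x$explained, 5))
  invisible(x)
}
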