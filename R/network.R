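# Relevance networks from the latent decomposition.
#
# Both blocks of a pair are decomposed over a SHARED latent variable per
# component (estimated as the sign-aligned bisector of the two blocks'
# scores, U_l ~ t_l^(q) + t_l^(r)); the association score between variables
# in different blocks is then
#   M_kj = sum_{l<=d} cor(X_j, U_l) * cor(X_k, U_l),
# which for standardised variables equals sum_l u_l^2 * phi_jl * phi_kl
# (u_l the training standard deviation of U_l, phi the regression
# coefficients of the variables on it) and approximates the direct
# correlation of the pair whenever the d retained dimensions span their
# cross-block covariance. Scores above a cutoff in magnitude become graph
# edges; cross-block triangles of positive edges decode back to candidate
# (x, y, z) foci.

#' Association scores between variables of different blocks
#'
#' Computes `M_kj` for every cross-block pair of retained variables (columns
#' with a nonzero loading on at least one fitted component), using the first
#' `d` components.
#'
#' @param model an [mcpa()] or [block_splsda()] fit holding its training
#'   data.
#' @param d number of latent dimensions summed (`1 <= d <= ncomp`). The
#'   association score approximates a correlation only when `d` stays below
#'   the full decomposition depth, and a `G`-class outcome spans only
#'   `G - 1` genuinely discriminative latent dimensions — later components
#'   track sampling noise and inflate the scores. Default
#'   `max(1, ncomp - 1)` (one dimension for the usual two-class fit).
#' @return object of class `association_matrix`: `pairs` (named list of
#'   matrices, one per unordered block pair, e.g. `"x:y"` with x-variables
#'   in rows), `d`.
#' @export
association_matrix <- function(model, d = NULL) {
  if (inherits(model, "mcpa")) {
    if (!is.null(model$association) && is.null(d)) return(model$association)
    model <- model$fit
  }
  stopifnot(inherits(model, "block_splsda"))
  d <- d %||% max(1L, model$ncomp - 1L)
  if (d < 1L || d > model$ncomp)
    stop("d must lie in 1..", model$ncomp, call. = FALSE)
  if (is.null(model$Xtrain))
    stop("model carries no training data (restored from archive?); ",
         "refit to compute association matrices", call. = FALSE)
  bn <- names(model$loadings)
  selected <- lapply(bn, function(q)
    which(rowSums(abs(model$loadings[[q]])) > 0))
  names(selected) <- bn
  pairs <- list()
  for (i in seq_along(bn)) for (j in seq_along(bn)) {
    if (i >= j) next
    q <- bn[i]; r <- bn[j]
    if (!length(selected[[q]]) || !length(selected[[r]])) next
    M <- 0
    for (l in seq_len(d)) {
      tq <- model$scores[[q]][, l]
      tr <- model$scores[[r]][, l]
      # shared latent: sign-aligned bisector of the two blocks' scores
      s <- stats::cor(tq, tr)
      u <- tq + if (is.finite(s) && s < 0) -tr else tr
      ca <- suppressWarnings(
        stats::cor(model$Xtrain[[q]][, selected[[q]], drop = FALSE], u))
      cb <- suppressWarnings(
        stats::cor(model$Xtrain[[r]][, selected[[r]], drop = FALSE], u))
      ca[is.na(ca)] <- 0
      cb[is.na(cb)] <- 0
      M <- M + tcrossprod(ca, cb)
    }
    # M approximates a correlation; numerical overshoot beyond +-1 is clamped
    pairs[[paste(q, r, sep = ":")]] <- pmin(pmax(M, -1), 1)
  }
  structure(list(pairs = pairs, d = d), class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Association matrix over %d block pair(s), d = %d\n",
              length(x$pairs), x$d))
  for (nm in names(x$pairs))
    cat(sprintf("  %s: %d x %d, max |M| = %.3f\n", nm, nrow(x$pairs[[nm]]),
                ncol(x$pairs[[nm]]), max(abs(x$pairs[[nm]]))))
  invisible(x)
}

#' Threshold an association matrix into a relevance network
#'
#' Keeps cross-block pairs with `|M| >= cutoff` as signed edges; nodes
#' without edges are dropped. Raising the cutoff never adds edges.
#'
#' @param M an [association_matrix()].
#' @param cutoff magnitude threshold in `(0, 1)`.
#' @return object of class `relevance_graph`: `edges` (data frame `node_a`,
#'   `node_b`, `block_a`, `block_b`, `score`), `nodes`, `cutoff`.
#' @export
build_network <- function(M, cutoff) {
  stopifnot(inherits(M, "association_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)", call. = FALSE)
  rows <- list()
  for (nm in names(M$pairs)) {
    blocks <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    m <- M$pairs[[nm]]
    hit <- which(abs(m) >= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    rows[[nm]] <- data.frame(node_a = rownames(m)[hit[, 1L]],
                             node_b = colnames(m)[hit[, 2L]],
                             block_a = blocks[1L], block_b = blocks[2L],
                             score = m[hit], row.names = NULL)
  }
  edges <- if (length(rows)) do.call(rbind, rows)
           else data.frame(node_a = character(0L), node_b = character(0L),
                           block_a = character(0L), block_b = character(0L),
                           score = numeric(0L))
  edges <- edges[order(-abs(edges$score), edges$node_a, edges$node_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$node_a, edges$node_b))),
                 cutoff = cutoff),
            class = "relevance_graph")
}

#' @export
print.relevance_graph <- function(x, ...) {
  cat(sprintf("Relevance network: %d nodes, %d edges (|M| >= %g)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Convert a relevance network to an igraph object
#' @param graph a [build_network()] result.
#' @return an [igraph::graph_from_data_frame()] undirected graph with a
#'   `score` edge attribute and a `block` vertex attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "relevance_graph"))
  verts <- data.frame(name = graph$nodes,
                      block = tolower(substr(graph$nodes, 1L, 1L)))
  igraph::graph_from_data_frame(
    graph$edges[c("node_a", "node_b", "score")],
    directed = FALSE, vertices = verts)
}

#' Export a relevance network
#'
#' Writes `edges.csv` (`node_a`, `node_b`, `score`) and `network.graphml`.
#'
#' @param graph a [build_network()] result.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_network <- function(graph, dir) {
  stopifnot(inherits(graph, "relevance_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "edges.csv")
  utils::write.csv(graph$edges[c("node_a", "node_b", "score")], csv,
                   row.names = FALSE)
  gml <- file.path(dir, "network.graphml")
  if (nrow(graph$edges)) igraph::write_graph(as_igraph(graph), gml,
                                             format = "graphml")
  else writeLines("<graphml/>", gml)
  invisible(c(csv, gml))
}

#' Reconstruct candidate foci from cross-block triangles
#'
#' Enumerates node triples with exactly one node per coordinate block whose
#' three pairwise edges all exist with positive scores, decodes each triple
#' to an `(x, y, z)` mm coordinate, and scores it by its weakest edge.
#'
#' @param graph a [build_network()] result over the `x`, `y`, `z` blocks.
#' @return data frame (`x`, `y`, `z`, `score`) sorted by score descending
#'   (ties: ascending coordinate); possibly empty.
#' @export
reconstruct_foci <- function(graph) {
  stopifnot(inherits(graph, "relevance_graph"))
  empty <- data.frame(x = integer(0L), y = integer(0L), z = integer(0L),
                      score = numeric(0L))
  e <- graph$edges[graph$edges$score > 0, , drop = FALSE]
  if (!nrow(e)) return(empty)
  pair_scores <- function(ba, bb) {
    sel <- (e$block_a == ba & e$block_b == bb)
    swapped <- (e$block_a == bb & e$block_b == ba)
    rbind(data.frame(a = e$node_a[sel], b = e$node_b[sel],
                     score = e$score[sel]),
          data.frame(a = e$node_b[swapped], b = e$node_a[swapped],
                     score = e$score[swapped]))
  }
  xy <- pair_scores("x", "y")
  xz <- pair_scores("x", "z")
  yz <- pair_scores("y", "z")
  if (!nrow(xy) || !nrow(xz) || !nrow(yz)) return(empty)
  key <- function(a, b) paste(a, b, sep = "\r")
  xz_map <- stats::setNames(xz$score, key(xz$a, xz$b))
  yz_map <- stats::setNames(yz$score, key(yz$a, yz$b))
  zs <- sort(unique(c(xz$b, yz$b)))
  rows <- list()
  for (i in seq_len(nrow(xy))) {
    for (zn in zs) {
      s_xz <- xz_map[key(xy$a[i], zn)]
      s_yz <- yz_map[key(xy$b[i], zn)]
      if (is.na(s_xz) || is.na(s_yz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        x = coord_value(xy$a[i]), y = coord_value(xy$b[i]),
        z = coord_value(zn), score = min(xy$score[i], s_xz, s_yz))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}
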