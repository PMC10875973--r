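# One-hot coordinate encoding for multi-coordinate pattern analysis (MCPA).
#
# Each focus becomes one row across three binary blocks, one per axis: the
# block for axis q has one column per distinct observed coordinate value on
# that axis, and the row carries a single 1 in the column matching the
# focus's value (so three 1s per focus in total). Column names encode the
# millimetre value with an ASCII "m" prefix for negatives, e.g. "X_9",
# "Y_m88", "Z_0".

AXES <- c(x = "X", y = "Y", z = "Z")

#' Coordinate value <-> column name
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param value integer mm value(s).
#' @return character column name(s), e.g. `coord_name("y", -88)` is `"Y_m88"`.
#' @export
coord_name <- function(axis, value) {
  paste0(AXES[[axis]], "_", ifelse(value < 0, paste0("m", -value), value))
}

#' @rdname coord_name
#' @param name column name(s) in the `"X_9"` / `"Y_m88"` convention.
#' @export
coord_value <- function(name) {
  body <- sub("^[XYZ]_", "", name)
  ifelse(grepl("^m", body), -as.integer(sub("^m", "", body)),
         suppressWarnings(as.integer(body)))
}

onehot_block <- function(values, levels, axis) {
  m <- matrix(0, nrow = length(values), ncol = length(levels),
              dimnames = list(NULL, coord_name(axis, levels)))
  hit <- match(values, levels)
  seen <- !is.na(hit)
  m[cbind(which(seen), hit[seen])] <- 1
  m
}

#' One-hot encode foci into three per-axis binary blocks
#'
#' The per-axis column vocabulary is the ascending set of distinct observed
#' values; each row of each block has exactly one 1.
#'
#' @param ds a [foci_dataset()].
#' @return object of class `onehot_blocks`: `blocks` (named list of binary
#'   matrices `x`, `y`, `z`), `levels` (per-axis sorted value vectors),
#'   `outcome` (factor of group labels), `space`.
#' @export
encode_pattern3 <- function(ds) {
  stopifnot(inherits(ds, "foci_dataset"))
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  levels <- lapply(c(x = "x", y = "y", z = "z"),
                   function(ax) sort(unique(ds[[ax]])))
  blocks <- lapply(names(levels), function(ax)
    onehot_block(ds[[ax]], levels[[ax]], ax))
  names(blocks) <- names(levels)
  structure(list(blocks = blocks, levels = levels,
                 outcome = factor(ds$group), space = foci_space(ds)),
            class = "onehot_blocks")
}

#' @export
print.onehot_blocks <- function(x, ...) {
  p <- vapply(x$blocks, ncol, integer(1L))
  cat(sprintf("One-hot blocks: %d foci; columns x: %d, y: %d, z: %d (%d total)\n",
              nrow(x$blocks$x), p[["x"]], p[["y"]], p[["z"]], sum(p)))
  cat("  outcome: ", paste(sprintf("%s (%d)", levels(x$outcome),
                                   table(x$outcome)), collapse = ", "), "\n")
  invisible(x)
}

#' Raw coordinate matrix (comparison encoding)
#'
#' Passes the integer coordinates through unchanged as an `N x 3` matrix —
#' the minimal encoding in which only whole axes, not specific locations,
#' can be assessed. Provided for comparison experiments.
#'
#' @param ds a [foci_dataset()].
#' @return list with `coords` (`N x 3` integer matrix, columns `x`, `y`,
#'   `z`) and `outcome` (factor).
#' @export
encode_pattern2 <- function(ds) {
  stopifnot(inherits(ds, "foci_dataset"))
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  list(coords = as.matrix(as.data.frame(ds)[c("x", "y", "z")]),
       outcome = factor(ds$group))
}

#' Decode one-hot blocks back to coordinates
#' @param blocks an [encode_pattern3()] result (training encoding: every row
#'   has one 1 per block).
#' @return data frame with columns `x`, `y`, `z`, `group`.
#' @export
decode_pattern3 <- function(blocks) {
  stopifnot(inherits(blocks, "onehot_blocks"))
  out <- lapply(c("x", "y", "z"), function(ax) {
    hit <- max.col(blocks$blocks[[ax]], ties.method = "first")
    none <- rowSums(blocks$blocks[[ax]]) == 0
    v <- blocks$levels[[ax]][hit]
    v[none] <- NA_integer_
    v
  })
  data.frame(x = out[[1L]], y = out[[2L]], z = out[[3L]],
             group = as.character(blocks$outcome))
}

#' Encode test foci against a training vocabulary
#'
#' Test foci are one-hot encoded with the column vocabulary fitted on the
#' training data. A test coordinate value unseen in training yields an
#' all-zero row in that block; the per-axis counts of such values are
#' returned and reported as a warning.
#'
#' @param train_blocks an [encode_pattern3()] result (the vocabulary).
#' @param test_ds a [foci_dataset()] to encode.
#' @return an `onehot_blocks` object with an extra field `unseen` (named
#'   integer vector: foci per axis whose value was unseen in training).
#' @export
align_columns <- function(train_blocks, test_ds) {
  stopifnot(inherits(train_blocks, "onehot_blocks"),
            inherits(test_ds, "foci_dataset"))
  blocks <- lapply(c(x = "x", y = "y", z = "z"), function(ax)
    onehot_block(test_ds[[ax]], train_blocks$levels[[ax]], ax))
  unseen <- vapply(c(x = "x", y = "y", z = "z"), function(ax)
    sum(!test_ds[[ax]] %in% train_blocks$levels[[ax]]), integer(1L))
  if (any(unseen > 0L))
    warning(sum(unseen), " test coordinate value(s) unseen in training (",
            paste(sprintf("%s: %d", names(unseen), unseen), collapse = ", "),
            "); affected block rows are all-zero", call. = FALSE)
  structure(list(blocks = blocks, levels = train_blocks$levels,
                 outcome = factor(test_ds$group,
                                  levels = levels(train_blocks$outcome)),
                 space = foci_space(test_ds), unseen = unseen),
            class = "onehot_blocks")
}

#' Size of the coordinate universe
#'
#' Bookkeeping for the full-grid ("pattern 1") encoding that MCPA avoids:
#' given the number of distinct coordinate positions per axis, returns the
#' number of grid points a full one-hot grid encoding would need (the
#' product) and the number of columns the per-axis block encoding uses
#' instead (the sum). At whole-brain 1 mm resolution (151 x 188 x 154
#' positions) the grid encoding needs 4,371,752 columns.
#'
#' @param n_x,n_y,n_z number of distinct coordinate positions per axis.
#' @return list with `per_axis`, `grid_points` (pattern-1 column count) and
#'   `pattern3_columns` (per-axis block column count).
#' @export
coordinate_universe <- function(n_x = 151, n_y = 188, n_z = 154) {
  stopifnot(n_x >= 1, n_y >= 1, n_z >= 1)
  list(per_axis = c(x = n_x, y = n_y, z = n_z),
       grid_points = n_x * n_y * n_z,
       pattern3_columns = n_x + n_y + n_z)
}

#' Export one-hot blocks as sparse MatrixMarket files
#'
#' Writes `block_<axis>.mtx` plus `block_<axis>_columns.txt` sidecars (one
#' column name per line) and `outcome.txt`.
#'
#' @param blocks an `onehot_blocks` object.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_blocks <- function(blocks, dir) {
  stopifnot(inherits(blocks, "onehot_blocks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  for (ax in names(blocks$blocks)) {
    m <- Matrix::Matrix(blocks$blocks[[ax]], sparse = TRUE)
    mtx <- file.path(dir, paste0("block_", ax, ".mtx"))
    Matrix::writeMM(m, mtx)
    side <- file.path(dir, paste0("block_", ax, "_columns.txt"))
    writeLines(colnames(blocks$blocks[[ax]]), side)
    paths <- c(paths, mtx, side)
  }
  oc <- file.path(dir, "outcome.txt")
  writeLines(as.character(blocks$outcome), oc)
  invisible(c(paths, oc))
}
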