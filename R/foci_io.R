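# Foci datasets: reading, validation, writing, stratified splitting.
#
# A foci dataset is the basic data carrier for coordinate-based meta-analysis:
# one row per reported peak-activation coordinate (focus), with the study it
# came from and a group label (the outcome used downstream by MCPA).

#' Construct a foci dataset
#'
#' Builds and validates a `foci_dataset`: a data frame of integer millimetre
#' peak coordinates with study and group structure, tagged with a single
#' stereotactic space. Coordinates follow the right-handed MNI-style axis
#' convention (x: left - / right +, y: posterior - / anterior +,
#' z: inferior - / superior +).
#'
#' @param df data frame with columns `study_id`, `group`, `x`, `y`, `z`.
#' @param space stereotactic space tag, `"MNI"` or `"Talairach"`. Talairach
#'   data are accepted but never converted; mixing spaces in one analysis is
#'   an error.
#' @param allow_duplicates if `FALSE` (default), duplicated
#'   `(study_id, group, x, y, z)` rows are an error.
#' @return an object of class `foci_dataset` (a data frame with a `space`
#'   attribute).
#' @export
foci_dataset <- function(df, space = c("MNI", "Talairach"),
                         allow_duplicates = FALSE) {
  space <- match.arg(space)
  required <- c("study_id", "group", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0L) stop("foci dataset is empty", call. = FALSE)
  for (ax in c("x", "y", "z")) {
    v <- df[[ax]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != trunc(v)))
      stop("coordinate column '", ax, "' must hold integer millimetres",
           call. = FALSE)
    df[[ax]] <- as.integer(v)
  }
  if (any(abs(df$x) > 100L) || any(abs(df$y) > 120L) || any(abs(df$z) > 100L))
    stop("coordinates outside the plausible brain envelope ",
         "(|x| <= 100, |y| <= 120, |z| <= 100)", call. = FALSE)
  df$study_id <- as.character(df$study_id)
  df$group <- as.character(df$group)
  if (any(!nzchar(df$study_id)) || any(is.na(df$study_id)))
    stop("study_id must be non-empty", call. = FALSE)
  if (any(!nzchar(df$group)) || any(is.na(df$group)))
    stop("group must be non-empty", call. = FALSE)
  if (!allow_duplicates && anyDuplicated(df))
    stop("duplicate (study_id, group, x, y, z) rows; ",
         "use allow_duplicates = TRUE to permit them", call. = FALSE)
  rownames(df) <- NULL
  structure(df, space = space, class = c("foci_dataset", "data.frame"))
}

#' @export
print.foci_dataset <- function(x, ...) {
  cat(sprintf("Foci dataset: %d foci, %d studies, space %s\n",
              nrow(x), length(unique(x$study_id)), foci_space(x)))
  tab <- table(group = x$group)
  for (g in names(tab)) {
    n_st <- length(unique(x$study_id[x$group == g]))
    cat(sprintf("  %s: %d studies (%d foci)\n", g, n_st, tab[[g]]))
  }
  invisible(x)
}

#' Stereotactic space of a foci dataset
#' @param ds a `foci_dataset`.
#' @return `"MNI"` or `"Talairach"`.
#' @export
foci_space <- function(ds) attr(ds, "space", exact = TRUE)

#' Read a foci table
#'
#' Reads foci from CSV (header `study_id,group,x,y,z`, optional `space`
#' column) or from GingerALE-style text (`// Reference=<space>` header,
#' `// <study_id>` comment lines, then whitespace-separated `x y z` lines;
#' such files carry one group, given by the `group` argument). Coordinates
#' must be integers; malformed lines raise an error naming the line number.
#'
#' @param path file path.
#' @param format `"csv"` or `"gingerale"`.
#' @param space space tag to assume when the file does not declare one.
#' @param group group label for `gingerale` files (one group per file).
#' @param allow_duplicates passed to [foci_dataset()].
#' @return a [foci_dataset()].
#' @export
read_foci <- function(path, format = c("csv", "gingerale"), space = "MNI",
                      group = "group1", allow_duplicates = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") read_foci_csv(path, space, allow_duplicates)
  else read_foci_gingerale(path, space, group, allow_duplicates)
}

parse_int_or_stop <- function(v, what, lines, path) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) | out != trunc(out))
  if (length(bad))
    stop(sprintf("%s: line %d: %s '%s' is not an integer",
                 path, lines[bad[1L]], what, v[bad[1L]]), call. = FALSE)
  as.integer(out)
}

check_space_tag <- function(tag, path) {
  if (!tag %in% c("MNI", "Talairach"))
    stop(path, ": unknown space tag '", tag, "'", call. = FALSE)
  tag
}

read_foci_csv <- function(path, space, allow_duplicates) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop(path, ": empty file", call. = FALSE)
  required <- c("study_id", "group", "x", "y", "z")
  if (!all(required %in% names(raw)))
    stop(path, ": CSV header must contain ", paste(required, collapse = ","),
         call. = FALSE)
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  for (ax in c("x", "y", "z"))
    raw[[ax]] <- parse_int_or_stop(raw[[ax]], paste0(ax, "-coordinate"),
                                   lines, path)
  if ("space" %in% names(raw)) {
    tags <- unique(raw$space)
    if (length(tags) > 1L)
      stop(path, ": mixed-space file (", paste(tags, collapse = ", "), ")",
           call. = FALSE)
    space <- check_space_tag(tags, path)
  } else {
    space <- check_space_tag(space, path)
  }
  foci_dataset(raw[required], space = space, allow_duplicates = allow_duplicates)
}

read_foci_gingerale <- function(path, space, group, allow_duplicates) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || all(!nzchar(trimws(txt))))
    stop(path, ": empty file", call. = FALSE)
  study <- NA_character_
  rows <- vector("list", length(txt))
  for (i in seq_along(txt)) {
    line <- trimws(txt[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "//")) {
      body <- trimws(sub("^//", "", line))
      if (grepl("^Reference\\s*=", body, ignore.case = TRUE)) {
        space <- check_space_tag(trimws(sub("^Reference\\s*=", "", body,
                                            ignore.case = TRUE)), path)
      } else if (nzchar(body)) {
        study <- body
      }
      next
    }
    if (is.na(study))
      stop(path, ": line ", i, ": coordinates before any '// study' header",
           call. = FALSE)
    parts <- strsplit(line, "\\s+")[[1L]]
    if (length(parts) != 3L)
      stop(path, ": line ", i, ": expected 'x y z', got '", line, "'",
           call. = FALSE)
    xyz <- parse_int_or_stop(parts, "coordinate", rep(i, 3L), path)
    rows[[i]] <- data.frame(study_id = study, group = group,
                            x = xyz[1L], y = xyz[2L], z = xyz[3L])
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop(path, ": no coordinate lines found", call. = FALSE)
  foci_dataset(do.call(rbind, rows), space = check_space_tag(space, path),
               allow_duplicates = allow_duplicates)
}

#' Write a foci table
#'
#' Writes a dataset in either supported format. GingerALE-style text carries
#' one group per file, so a multi-group dataset must be subset first.
#' `write_foci()` then `read_foci()` round-trips to an identical dataset.
#'
#' @param ds a [foci_dataset()].
#' @param path output path.
#' @param format `"csv"` or `"gingerale"`.
#' @return `path`, invisibly.
#' @export
write_foci <- function(ds, path, format = c("csv", "gingerale")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "foci_dataset"))
  if (format == "csv") {
    out <- as.data.frame(ds)
    out$space <- foci_space(ds)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (length(unique(ds$group)) > 1L)
      stop("GingerALE text holds one group per file; subset the dataset first",
           call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("// Reference=", foci_space(ds)), con)
    for (s in unique(ds$study_id)) {
      writeLines(paste0("// ", s), con)
      sub <- ds[ds$study_id == s, , drop = FALSE]
      writeLines(paste(sub$x, sub$y, sub$z), con)
    }
  }
  invisible(path)
}

#' Split foci into train and test sets, stratified by group
#'
#' Splits at the focus level so that test-group proportions match the input
#' (largest-remainder rounding, per-group counts within 1 of exact
#' proportionality). `test_size` may instead be a named integer vector giving
#' the exact number of test foci per group, for reproducing a published
#' non-proportional split.
#'
#' @param ds a [foci_dataset()].
#' @param test_size total number of test foci, or a named per-group vector.
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with elements `train` and `test`, both `foci_dataset`s
#'   (together they partition `ds`).
#' @export
stratified_split <- function(ds, test_size, seed = 1L) {
  stopifnot(inherits(ds, "foci_dataset"))
  n <- nrow(ds)
  groups <- sort(unique(ds$group))
  n_g <- vapply(groups, function(g) sum(ds$group == g), integer(1L))
  if (length(test_size) == 1L && is.null(names(test_size))) {
    test_size <- as.integer(test_size)
    if (test_size < 0L || test_size > n)
      stop("test_size must be between 0 and ", n, call. = FALSE)
    # largest-remainder apportionment of test_size across groups
    exact <- n_g * test_size / n
    take <- floor(exact)
    rem <- test_size - sum(take)
    if (rem > 0L) {
      ord <- order(exact - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
    }
  } else {
    if (is.null(names(test_size)) || !all(names(test_size) %in% groups))
      stop("named test_size must use the dataset's group labels", call. = FALSE)
    take <- stats::setNames(integer(length(groups)), groups)
    take[names(test_size)] <- as.integer(test_size)
    if (any(take > n_g) || any(take < 0L))
      stop("per-group test sizes exceed group sizes", call. = FALSE)
  }
  take <- stats::setNames(as.integer(take), groups)
  test_idx <- with_seed(seed, {
    unlist(lapply(groups, function(g) {
      idx <- which(ds$group == g)
      if (take[[g]] == 0L) integer(0L) else sort(sample(idx, take[[g]]))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  split_subset <- function(idx) {
    df <- as.data.frame(ds)[idx, , drop = FALSE]
    rownames(df) <- NULL
    if (!length(idx))  # empty side of a degenerate split stays a valid object
      return(structure(df, space = foci_space(ds),
                       class = c("foci_dataset", "data.frame")))
    foci_dataset(df, space = foci_space(ds), allow_duplicates = TRUE)
  }
  list(train = split_subset(setdiff(seq_len(n), test_idx)),
       test = split_subset(test_idx))
}
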