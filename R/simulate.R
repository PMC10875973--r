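# Synthetic foci with planted spatial and group structure.
#
# Each group's foci are drawn from a mixture of spatially compact isotropic
# Gaussian clusters plus a uniform background over the brain envelope; some
# clusters are group-specific (the planted discriminative signal) and some
# shared between groups (planted overlap). Samples are truncated to the
# envelope by rejection and rounded half-away-from-zero to integer mm, like
# reported foci.

#' Specify a synthetic foci simulation
#'
#' @param groups named list; each entry describes one group with fields:
#'   `studies` (number of studies), `foci_per_study` (a single count, a
#'   `c(min, max)` range sampled uniformly, or an explicit per-study vector),
#'   and `clusters` (list of cluster specs: `center` (mm, length 3), `sd`
#'   (isotropic mm, >= 0), `weight` (mixture weight), optional `shared` flag
#'   and `name`). Remaining weight (weights must sum to <= 1; the remainder)
#'   goes to the uniform background over the brain envelope.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 1L)
    stop("groups must be a named list", call. = FALSE)
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (is.null(gr$studies) || gr$studies < 1L)
      stop("group '", g, "': studies must be >= 1", call. = FALSE)
    if (is.null(gr$foci_per_study) || any(gr$foci_per_study < 1L))
      stop("group '", g, "': foci_per_study must be positive", call. = FALSE)
    w <- vapply(gr$clusters, function(cl) cl$weight, numeric(1L))
    if (any(w < 0) || sum(w) > 1 + 1e-9)
      stop("group '", g, "': cluster weights must be non-negative and sum ",
           "to at most 1 (the remainder is uniform background)", call. = FALSE)
    for (cl in gr$clusters) {
      if (length(cl$center) != 3L || is.null(cl$sd) || cl$sd < 0)
        stop("group '", g, "': each cluster needs a length-3 center and sd >= 0",
             call. = FALSE)
      if (!inside_envelope(cl$center))
        stop("group '", g, "': cluster center outside the brain envelope",
             call. = FALSE)
    }
  }
  structure(list(groups = groups), class = "simulation_spec")
}

# uniform samples inside the envelope ellipsoid (rejection from bounding box)
runif_envelope <- function(n) {
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    cand <- cbind(stats::runif(m, -1, 1), stats::runif(m, -1, 1),
                  stats::runif(m, -1, 1))
    cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
    out <- rbind(out, cand)
  }
  sweep(sweep(out[seq_len(n), , drop = FALSE], 2L, ENVELOPE_SEMIAXES, "*"),
        2L, ENVELOPE_CENTER, "+")
}

# Gaussian cluster samples truncated to the envelope by rejection.
rnorm_cluster <- function(n, center, sd) {
  if (sd == 0) return(matrix(rep(center, each = n), n, 3L))
  out <- matrix(NA_real_, 0L, 3L)
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    cand <- matrix(stats::rnorm(3L * m, mean = rep(center, each = m), sd = sd),
                   m, 3L)
    cand <- cand[inside_envelope(cand), , drop = FALSE]
    out <- rbind(out, cand)
    tries <- tries + 1L
    if (tries > 1000L) stop("cluster rejection sampling failed", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a foci dataset with planted structure
#'
#' For each focus a mixture component (cluster or background) is drawn, a 3-D
#' point is sampled (Gaussian truncated to the brain envelope, or uniform
#' over the envelope) and rounded half-away-from-zero to integer mm.
#'
#' @param spec a [simulation_spec()].
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return list with `data` (a [foci_dataset()]) and `truth` (data frame:
#'   `study_id`, `group`, `component` — cluster name or `"background"` —
#'   and the sampled row's coordinates).
#' @export
simulate_foci <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(seed, {
    rows <- list()
    for (g in names(spec$groups)) {
      gr <- spec$groups[[g]]
      counts <- if (length(gr$foci_per_study) == gr$studies) {
        as.integer(gr$foci_per_study)
      } else if (length(gr$foci_per_study) == 1L) {
        rep(as.integer(gr$foci_per_study), gr$studies)
      } else if (length(gr$foci_per_study) == 2L) {
        sample(gr$foci_per_study[1L]:gr$foci_per_study[2L], gr$studies,
               replace = TRUE)
      } else stop("foci_per_study must be a count, a range, or one per study",
                  call. = FALSE)
      w <- vapply(gr$clusters, function(cl) cl$weight, numeric(1L))
      comp_names <- vapply(seq_along(gr$clusters), function(i)
        gr$clusters[[i]]$name %||% paste0(g, "_cluster", i), character(1L))
      probs <- c(w, 1 - sum(w))
      labels <- c(comp_names, "background")
      for (s in seq_len(gr$studies)) {
        n <- counts[s]
        comp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
        xyz <- matrix(NA_real_, n, 3L)
        for (ci in unique(comp)) {
          sel <- comp == ci
          xyz[sel, ] <- if (ci > length(gr$clusters))
            runif_envelope(sum(sel))
          else rnorm_cluster(sum(sel), gr$clusters[[ci]]$center,
                             gr$clusters[[ci]]$sd)
        }
        xyz <- round_half_away(xyz)
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sprintf("%s_s%02d", g, s), group = g,
          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
          component = labels[comp])
      }
    }
    df <- do.call(rbind, rows)
    list(data = foci_dataset(df[c("study_id", "group", "x", "y", "z")],
                             allow_duplicates = TRUE),
         truth = df[c("study_id", "group", "component", "x", "y", "z")])
  })
}

#' The package's canonical benchmark simulation
#'
#' Emulates the shape of a two-group foci corpus: 12 "branded" studies (562
#' foci in total) and 20 "unbranded" studies (469 foci), with one spatial
#' cluster shared between the groups at (-4, 40, -8) (a ventromedial
#' prefrontal overlap motif), one branded-only cluster at (6, -88, 4) (a
#' lingual/occipital discriminative motif), isotropic cluster sd 6 mm, and
#' 15 % uniform background over the brain envelope. Branded mixture: 0.50
#' branded-only + 0.35 shared + 0.15 background; unbranded: 0.85 shared +
#' 0.15 background. Used by all recovery benchmarks.
#'
#' @return a [simulation_spec()].
#' @export
default_benchmark <- function() {
  shared <- list(center = c(-4, 40, -8), sd = 6, weight = NA, shared = TRUE,
                 name = "shared_vmpfc")
  branded_only <- list(center = c(6, -88, 4), sd = 6, weight = 0.50,
                       shared = FALSE, name = "branded_lingual")
  shared_b <- shared; shared_b$weight <- 0.35
  shared_u <- shared; shared_u$weight <- 0.85
  # per-study foci counts distributed as evenly as possible over the totals
  n_branded <- c(rep(47L, 10L), rep(46L, 2L))         # sums to 562
  n_unbranded <- c(rep(24L, 9L), rep(23L, 11L))       # sums to 469
  simulation_spec(list(
    branded = list(studies = 12L, foci_per_study = n_branded,
                   clusters = list(branded_only, shared_b)),
    unbranded = list(studies = 20L, foci_per_study = n_unbranded,
                     clusters = list(shared_u))))
}
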