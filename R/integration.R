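#' Bundle per-experiment protein profiles for integration
#'
#' Each experiment contributes, per protein, a real-valued profile vector
#' (its replicate or time-point values in that assay). Proteins need not
#' appear in every experiment; integration handles partial overlap.
#'
#' @param experiments named list of numeric matrices, one per experiment,
#'   rows labeled by protein (rownames); all rows within an experiment
#'   share that experiment's profile length.
#' @return named list of class `profile_set`.
#' @export
profile_set <- function(experiments) {
  if (!length(experiments) || is.null(names(experiments)) ||
      any(!nzchar(names(experiments)))) {
    stopf("experiments must be a non-empty named list")
  }
  experiments <- lapply(experiments, function(m) {
    m <- as.matrix(m)
    if (is.null(rownames(m))) stopf("every experiment needs protein rownames")
    storage.mode(m) <- "double"
    m
  })
  structure(experiments, class = "profile_set")
}

# per-column z-score within one experiment; constant columns map to 0
standardize_experiment <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

#' Per-pair Euclidean and cosine distances over shared experiments
#'
#' For every protein pair, the experiments in which both are present are
#' concatenated into one vector per protein and the Euclidean and cosine
#' distances of the concatenations are computed. Pairs sharing no
#' experiment are marked missing. Experiments are z-scored per column by
#' default so heterogeneous assay scales contribute commensurately.
#'
#' @param profiles a [profile_set()].
#' @param standardize z-score each experiment's columns first (default
#'   `TRUE`).
#' @return list of class `pair_components` with matrices `euclidean`,
#'   `cosine`, `shared` (shared-experiment counts) and logical `missing`,
#'   all proteins x proteins.
#' @export
pair_component_distances <- function(profiles, standardize = TRUE) {
  stopifnot(inherits(profiles, "profile_set"))
  mats <- if (standardize) {
    lapply(unclass(profiles), standardize_experiment)
  } else {
    unclass(profiles)
  }
  proteins <- unique(unlist(lapply(mats, rownames), use.names = FALSE))
  n <- length(proteins)
  eu <- co <- matrix(NA_real_, n, n, dimnames = list(proteins, proteins))
  sh <- matrix(0L, n, n, dimnames = list(proteins, proteins))
  diag(eu) <- diag(co) <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- c()
      b <- c()
      cnt <- 0L
      for (m in mats) {
        if (proteins[i] %in% rownames(m) && proteins[j] %in% rownames(m)) {
          a <- c(a, m[proteins[i], ])
          b <- c(b, m[proteins[j], ])
          cnt <- cnt + 1L
        }
      }
      sh[i, j] <- sh[j, i] <- cnt
      if (cnt > 0L) {
        eu[i, j] <- eu[j, i] <- sqrt(sum((a - b)^2))
        # degenerate all-zero concatenations carry no direction: maximal
        # uninformative cosine distance 1
        co[i, j] <- co[j, i] <- if (sum(a^2) == 0 || sum(b^2) == 0) {
          1
        } else {
          cosine_distance(a, b)
        }
      }
    }
  }
  structure(list(euclidean = eu, cosine = co, shared = sh,
                 missing = sh == 0L & row(sh) != col(sh)),
            class = "pair_components")
}

#' Rescale observed Euclidean distances into (0, 0.9]
#'
#' Linear min-max map of the non-missing off-diagonal Euclidean distances
#' onto \[delta, 0.9\]: the smallest observed distance maps to delta (a
#' small positive floor keeping the subsequent log finite) and the largest
#' to 0.9. Missing pairs are untouched here.
#'
#' @param components a [pair_component_distances()] result, or a numeric
#'   vector of Euclidean distances.
#' @param delta lower endpoint (default 1e-3).
#' @return same shape as the input with the Euclidean values rescaled.
#' @export
rescale_euclidean <- function(components, delta = 1e-3) {
  rescale <- function(v) {
    ok <- !is.na(v)
    lo <- min(v[ok])
    hi <- max(v[ok])
    if (hi == lo) {
      warnf("all Euclidean distances equal; mapping them to 0.9")
      v[ok] <- 0.9
      return(v)
    }
    v[ok] <- delta + (v[ok] - lo) / (hi - lo) * (0.9 - delta)
    v
  }
  if (inherits(components, "pair_components")) {
    eu <- components$euclidean
    off <- row(eu) != col(eu)
    vals <- eu[off]
    eu[off] <- rescale(vals)
    components$euclidean <- eu
    components$rescaled <- TRUE
    components$delta <- delta
    components
  } else {
    rescale(components)
  }
}

#' Assign maximal component distances to pairs sharing no experiment
#'
#' Pairs never co-detected carry no evidence of similarity: their Euclidean
#' component is set to exactly 1 (beyond the 0.9 ceiling of observed
#' pairs) after rescaling, and the cosine component to 1 so the combined
#' distance is defined.
#'
#' @param components a rescaled [pair_component_distances()] result.
#' @return the components with missing pairs filled in.
#' @export
assign_missing <- function(components) {
  stopifnot(inherits(components, "pair_components"))
  if (!isTRUE(components$rescaled)) {
    stopf("rescale_euclidean() must run before assign_missing()")
  }
  miss <- components$missing
  components$euclidean[miss] <- 1
  components$cosine[miss] <- 1
  components
}

#' Combine component distances into the final integrated distance
#'
#' The raw combined distance is log(E' * max(C, delta)) where E' is the
#' rescaled Euclidean component and C the cosine component (floored at
#' delta so the log stays finite); the raw values are then min-max
#' rescaled onto \[0, 1\] over all pairs. The map is monotone in the
#' product E' * C, so pair rankings are preserved.
#'
#' @param components a rescaled, missing-assigned [pair_component_distances()]
#'   result.
#' @param delta cosine floor (default 1e-3).
#' @return symmetric matrix of final distances in \[0, 1\], zero diagonal.
#' @export
combine_and_rescale <- function(components, delta = 1e-3) {
  stopifnot(inherits(components, "pair_components"))
  eu <- components$euclidean
  co <- components$cosine
  if (anyNA(eu) || anyNA(co)) {
    stopf("components incomplete; run assign_missing() first")
  }
  off <- row(eu) != col(eu)
  raw <- log(eu[off] * pmax(co[off], delta))
  lo <- min(raw)
  hi <- max(raw)
  d <- eu  # shape template
  d[off] <- if (hi == lo) 0.5 else (raw - lo) / (hi - lo)
  diag(d) <- 0
  d
}

#' Integrate all experiments and cluster the proteins
#'
#' Runs the full integration chain — component distances over shared
#' experiments, Euclidean rescaling to (0, 0.9], missing-pair assignment,
#' log-product combination rescaled to \[0, 1\] — then average-linkage
#' hierarchical clustering cut into `k` groups.
#'
#' @param profiles a [profile_set()].
#' @param k number of groups (default 5).
#' @param linkage linkage method (default "average").
#' @param standardize z-score experiments first (default `TRUE`).
#' @param delta rescaling floor (default 1e-3).
#' @return list with `groups` (named integer vector), `tree`
#'   ([stats::hclust]), `distance` (final matrix) and `components`.
#' @export
integrate_and_cluster <- function(profiles, k = 5L, linkage = "average",
                                  standardize = TRUE, delta = 1e-3) {
  comp <- pair_component_distances(profiles, standardize = standardize)
  comp <- rescale_euclidean(comp, delta = delta)
  comp <- assign_missing(comp)
  d <- combine_and_rescale(comp, delta = delta)
  if (k > nrow(d)) stopf("k = %d exceeds the %d proteins", k, nrow(d))
  hc <- hierarchical_cluster(d, linkage)
  groups <- stats::cutree(hc, k = k)
  list(groups = groups, tree = hc, distance = d, components = comp)
}
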