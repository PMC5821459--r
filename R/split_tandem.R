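#' Anchor-preserving affine normalization of partition coordinates
#'
#' Rescales each axis of a split-tandem co-partitioning plot so the anchor
#' protein's elution fraction maps to exactly 1 while the population median
#' is left unchanged: per axis the affine map f(x) = a x + b solves
#' f(v_anchor) = 1 and f(median) = median. Being affine, the map preserves
#' the median for any sign of a, and preserves ratios of coordinate
#' differences, so relative tightness of clusters is unchanged.
#'
#' @param values a [merge_swap_pair()] result (both axes normalized
#'   independently) or a named numeric vector (one axis).
#' @param anchor protein label whose value is mapped to 1 (must differ from
#'   the axis median, otherwise the two constraints are contradictory).
#' @return object of class `partition_table`: list with `proteins`, `raw`,
#'   `normalized` (data.frames or named vectors mirroring the input),
#'   `anchor` and `affine` (per-axis `c(a, b)`).
#' @examples
#' v <- c(ORF1 = 0.75, A = 0.5, B = 0.25)  # median 0.5
#' normalize_to_anchor(v, "ORF1")$affine   # a = 2, b = -0.5
#' @export
normalize_to_anchor <- function(values, anchor) {
  solve_axis <- function(v) {
    if (!anchor %in% names(v)) stopf("anchor '%s' not present", anchor)
    m <- stats::median(v)
    va <- v[[anchor]]
    if (abs(va - m) < 1e-12) {
      stopf("anchor value equals the median: affine map is ill-defined")
    }
    a <- (1 - m) / (va - m)
    b <- m - a * m
    list(coef = c(a = a, b = b), mapped = a * v + b)
  }
  if (is.data.frame(values)) {
    x <- stats::setNames(values$x, values$protein)
    y <- stats::setNames(values$y, values$protein)
    sx <- solve_axis(x)
    sy <- solve_axis(y)
    normalized <- data.frame(protein = values$protein,
                             x = unname(sx$mapped), y = unname(sy$mapped),
                             stringsAsFactors = FALSE)
    structure(list(proteins = values$protein,
                   raw = values[c("protein", "x", "y")],
                   normalized = normalized, anchor = anchor,
                   affine = list(x = sx$coef, y = sy$coef)),
              class = "partition_table")
  } else {
    s <- solve_axis(values)
    structure(list(proteins = names(values), raw = values,
                   normalized = s$mapped, anchor = anchor,
                   affine = list(x = s$coef)),
              class = "partition_table")
  }
}

#' @export
print.partition_table <- function(x, ...) {
  cat(sprintf("partition_table: %d proteins, anchor '%s' -> 1\n",
              length(x$proteins), x$anchor))
  invisible(x)
}

# coerce accepted point containers to a labeled n x 2 matrix
as_point_matrix <- function(points) {
  if (inherits(points, "partition_table")) points <- points$normalized
  if (is.data.frame(points)) {
    m <- as.matrix(points[, c("x", "y")])
    rownames(m) <- points$protein
    return(m)
  }
  m <- as.matrix(points)
  if (is.null(rownames(m))) stopf("points must carry labels (rownames)")
  m
}

# minimal enclosing circle radius; exact for k <= 3 via the classic
# obtuse-triangle / circumradius case split, naive check for larger k
enclosing_radius <- function(pts) {
  k <- nrow(pts)
  if (k == 1L) return(0)
  dm <- as.matrix(stats::dist(pts))
  if (k == 2L) return(max(dm) / 2)
  # candidate circles: each pair's diameter circle, each triple's circumcircle
  best <- Inf
  covers <- function(center, r) all(sqrt(colSums((t(pts) - center)^2)) <=
                                      r + 1e-9)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      center <- (pts[i, ] + pts[j, ]) / 2
      r <- dm[i, j] / 2
      if (r < best && covers(center, r)) best <- r
    }
  }
  if (k >= 3L) {
    combs <- utils::combn(k, 3L)
    for (c_i in seq_len(ncol(combs))) {
      tri <- pts[combs[, c_i], , drop = FALSE]
      ax <- tri[1, 1]; ay <- tri[1, 2]
      bx <- tri[2, 1]; by <- tri[2, 2]
      cx <- tri[3, 1]; cy <- tri[3, 2]
      den <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(den) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / den
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / den
      r <- sqrt((ax - ux)^2 + (ay - uy)^2)
      if (r < best && covers(c(ux, uy), r)) best <- r
    }
  }
  best
}

proximity_of <- function(pts, metric) {
  if (nrow(pts) < 2L) return(0)
  switch(metric,
         diameter = max(stats::dist(pts)),
         mean_pairwise = mean(stats::dist(pts)),
         enclosing_radius = enclosing_radius(pts))
}

#' Proximity of a designated protein cluster
#'
#' Measures how tightly a set of proteins co-locate in the partition plane.
#' The default metric is the cluster diameter (maximum pairwise Euclidean
#' distance), the most conservative tightness measure; mean pairwise
#' distance and minimal-enclosing-circle radius are selectable.
#'
#' @param points labeled 2-D points: a `partition_table`, a
#'   [merge_swap_pair()] result, or a matrix with rownames.
#' @param members cluster member labels (k >= 2).
#' @param metric "diameter" (default), "mean_pairwise" or
#'   "enclosing_radius".
#' @return the proximity value (>= 0).
#' @export
cluster_proximity <- function(points, members,
                              metric = c("diameter", "mean_pairwise",
                                         "enclosing_radius")) {
  metric <- match.arg(metric)
  m <- as_point_matrix(points)
  absent <- setdiff(members, rownames(m))
  if (length(absent)) {
    stopf("cluster member(s) absent: %s", paste(absent, collapse = ", "))
  }
  proximity_of(m[members, , drop = FALSE], metric)
}

#' Empirical probability of a cluster's proximity among all k-subsets
#'
#' Compares the observed proximity of a designated k-protein cluster with
#' the proximities of k-subsets of the plotted protein universe. In exact
#' mode every one of the choose(n, k) subsets is enumerated and
#' p = #\{subsets with proximity <= observed\} / choose(n, k); ties count
#' (inclusive), and the observed subset counts itself, so p >=
#' 1 / choose(n, k). Monte-Carlo mode draws subsets uniformly and applies
#' the add-one correction (1 + hits) / (1 + n_samples).
#'
#' @param points labeled 2-D points (the candidate universe).
#' @param members cluster member labels, k = length(members) >= 2.
#' @param metric proximity metric, see [cluster_proximity()].
#' @param mode "exact" (default) or "monte_carlo".
#' @param n_samples Monte-Carlo sample count (default 1e5).
#' @param seed Monte-Carlo seed (required in monte_carlo mode).
#' @param cap largest choose(n, k) enumerated exactly (default 1e8).
#' @return object of class `cluster_proximity_result`: list with `members`,
#'   `k`, `proximity`, `metric`, `n_universe`, `p_empirical`, `method`, and
#'   for Monte-Carlo runs `n_samples` and `seed`.
#' @export
cluster_proximity_pvalue <- function(points, members,
                                     metric = c("diameter", "mean_pairwise",
                                                "enclosing_radius"),
                                     mode = c("exact", "monte_carlo"),
                                     n_samples = 1e5, seed = NULL,
                                     cap = 1e8) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  m <- as_point_matrix(points)
  k <- length(members)
  n <- nrow(m)
  if (k < 2L) stopf("a cluster needs at least 2 members")
  if (n < k) stopf("universe smaller than the cluster")
  obs <- cluster_proximity(m, members, metric)
  # pairwise distances once; diameter / mean of a subset read off the matrix
  dm <- as.matrix(stats::dist(m))
  subset_prox <- function(idx) {
    if (metric == "enclosing_radius") {
      return(enclosing_radius(m[idx, , drop = FALSE]))
    }
    sub <- dm[idx, idx]
    vals <- sub[upper.tri(sub)]
    if (metric == "diameter") max(vals) else mean(vals)
  }
  tol <- 1e-12  # inclusive ties up to floating-point noise

  if (mode == "exact") {
    total <- choose(n, k)
    if (total > cap) {
      stopf(paste0("choose(%d, %d) = %.3g exceeds the exact-enumeration cap;",
                   " use mode = 'monte_carlo'"), n, k, total)
    }
    hits <- sum(utils::combn(n, k,
                             FUN = function(idx) subset_prox(idx) <= obs +
                               tol))
    p <- hits / total
    res <- list(members = members, k = k, proximity = obs, metric = metric,
                n_universe = n, p_empirical = p, method = "exact")
  } else {
    if (is.null(seed)) stopf("monte_carlo mode requires a seed")
    hits <- with_seed(seed, {
      idx <- replicate(n_samples, sample.int(n, k))
      if (metric == "enclosing_radius") {
        sum(apply(idx, 2L, function(i) {
          enclosing_radius(m[i, , drop = FALSE]) <= obs + tol
        }))
      } else {
        # vectorized over samples: proximity from the precomputed pairwise
        # distance matrix, one row per member pair
        pairs <- utils::combn(k, 2L)
        pd <- matrix(dm[cbind(as.vector(idx[pairs[1L, ], , drop = FALSE]),
                              as.vector(idx[pairs[2L, ], , drop = FALSE]))],
                     nrow = ncol(pairs))
        prox <- if (metric == "diameter") {
          apply(pd, 2L, max)
        } else {
          colMeans(pd)
        }
        sum(prox <= obs + tol)
      }
    })
    p <- (1 + hits) / (1 + n_samples)
    res <- list(members = members, k = k, proximity = obs, metric = metric,
                n_universe = n, p_empirical = p, method = "monte_carlo",
                n_samples = n_samples, seed = seed)
  }
  structure(res, class = "cluster_proximity_result")
}

#' @export
print.cluster_proximity_result <- function(x, ...) {
  cat(sprintf(paste0("cluster {%s}: proximity (%s) = %.5g, ",
                     "p = %.4g (%s, universe n = %d)\n"),
              paste(x$members, collapse = ", "), x$metric, x$proximity,
              x$p_empirical, x$method, x$n_universe))
  invisible(x)
}
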