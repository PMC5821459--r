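#' Upper-tail standard-normal quantile
#'
#' Returns z such that P(Z > z) = alpha for a standard normal Z.
#'
#' @param alpha tail probability in (0, 1).
#' @return the quantile z.
#' @examples
#' normal_upper_quantile(0.001)  # 3.090232
#' @export
normal_upper_quantile <- function(alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stopf("alpha must lie strictly within (0, 1)")
  }
  stats::qnorm(alpha, lower.tail = FALSE)
}

test_result <- function(statistic, df, p_value, two_sided = TRUE,
                        degenerate = FALSE, method = "t") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), two_sided = two_sided,
                 degenerate = degenerate, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s test: degenerate (zero variance), p undefined\n",
                x$method))
  } else {
    cat(sprintf("%s test: t = %.4f, df = %.3f, p = %.4g (%s)\n",
                x$method, x$statistic, x$df, x$p_value,
                if (x$two_sided) "two-sided" else "one-sided"))
  }
  invisible(x)
}

#' One-sample t-test
#'
#' Tests whether the mean of `values` differs from `mu0`. Zero-variance
#' input is flagged degenerate (p undefined) rather than an error, so
#' callers can exclude such cases from a multiple-testing family.
#'
#' @param values numeric vector, length >= 2.
#' @param mu0 null mean.
#' @param two_sided two-sided p (default) or upper-tail one-sided.
#' @return a `test_result` with elements `statistic`, `df`, `p_value`,
#'   `two_sided`, `degenerate`.
#' @export
one_sample_t <- function(values, mu0, two_sided = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stopf("need at least 2 values")
  if (stats::sd(values) == 0) {
    return(test_result(NA_real_, length(values) - 1, NA_real_,
                       two_sided, degenerate = TRUE, method = "one-sample t"))
  }
  ht <- stats::t.test(values, mu = mu0,
                      alternative = if (two_sided) "two.sided" else "greater")
  test_result(ht$statistic, ht$parameter, ht$p.value, two_sided,
              method = "one-sample t")
}

#' Two-sample t-test (Welch by default)
#'
#' Welch's unequal-variance t-test of the difference in means; the pooled
#' equal-variance variant is available by flag.
#'
#' @param a,b numeric vectors, each length >= 2.
#' @param pooled assume equal variances (default `FALSE`, i.e. Welch).
#' @param two_sided two-sided p (default).
#' @return a `test_result`.
#' @export
welch_t <- function(a, b, pooled = FALSE, two_sided = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stopf("each sample needs at least 2 values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(0, length(a) + length(b) - 2, 1, two_sided,
                         degenerate = TRUE,
                         method = if (pooled) "pooled t" else "Welch t"))
    }
    return(test_result(NA_real_, NA_real_, NA_real_, two_sided,
                       degenerate = TRUE,
                       method = if (pooled) "pooled t" else "Welch t"))
  }
  ht <- stats::t.test(a, b, var.equal = pooled,
                      alternative = if (two_sided) "two.sided" else "greater")
  test_result(ht$statistic, ht$parameter, ht$p.value, two_sided,
              method = if (pooled) "pooled t" else "Welch t")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone and never below the
#' raw p-values.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed; NA in,
#'   NA out).
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Cosine distance between two vectors
#'
#' d(u, v) = 1 - u.v / (|u| |v|); zero for positively proportional vectors,
#' at most 1 when both vectors are non-negative, at most 2 in general.
#'
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return cosine distance in \[0, 2\].
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v) || !length(u)) {
    stopf("vectors must have equal, positive length")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("cosine distance undefined for a zero vector")
  d <- 1 - sum(u * v) / (nu * nv)
  # clamp floating-point excursions just outside [0, 2]
  min(max(d, 0), 2)
}

#' Pairwise cosine distance matrix
#'
#' @param mat numeric matrix, one row per item (rownames used as labels).
#' @return symmetric matrix of cosine distances with zero diagonal.
#' @export
cosine_distance_matrix <- function(mat) {
  mat <- as.matrix(mat)
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    stopf("cosine distance undefined for all-zero rows: %s",
          paste(rownames(mat)[norms == 0], collapse = ", "))
  }
  sim <- (mat %*% t(mat)) / tcrossprod(norms)
  d <- 1 - sim
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (anyNA(d)) {
    stopf("distance matrix has missing entries; impute or assign them first")
  }
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stopf("distance matrix must have a zero diagonal")
  if (any(d < 0)) stopf("distances must be non-negative")
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin validating wrapper around [stats::hclust()]; complete (no missing
#' entries) symmetric input is required.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @param linkage linkage method (default "average", i.e. UPGMA).
#' @return an [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  if (!inherits(d, "dist")) d <- stats::as.dist(check_distance_matrix(d))
  if (anyNA(d)) stopf("distance matrix has missing entries")
  stats::hclust(d, method = linkage)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are merge-height differences, so leaf-to-root path
#' lengths equal merge heights.
#'
#' @param hc an [stats::hclust] tree.
#' @return single Newick string.
#' @export
as_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}
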