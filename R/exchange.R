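#' Construct a time-course matrix of heavy fractions
#'
#' Rows are proteins, columns the sampling times of the in vitro exchange
#' assay (seconds; the default design is 0 s = untreated capture, then
#' 30 s, 5 min and 30 min of competition with light extract).
#'
#' @param values numeric matrix (proteins x times) of heavy fractions; NA
#'   marks unquantified cells.
#' @param times strictly increasing numeric vector of times in seconds,
#'   one per column.
#' @return matrix of class `timecourse_matrix` with a `times` attribute.
#' @export
timecourse_matrix <- function(values, times = c(0, 30, 300, 1800)) {
  values <- as.matrix(values)
  if (ncol(values) != length(times)) {
    stopf("need one time per column: %d columns vs %d times",
          ncol(values), length(times))
  }
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (is.null(rownames(values))) stopf("proteins must be labeled (rownames)")
  colnames(values) <- paste0("t", times)
  structure(values, times = times,
            class = c("timecourse_matrix", "matrix", "array"))
}

#' Drop proteins not quantified at every time point
#'
#' Only complete trajectories are comparable by cosine distance; rows with
#' any missing cell are removed and recorded in the `"dropped"` attribute.
#'
#' @param matrix a [timecourse_matrix()] (or plain matrix), possibly with
#'   NA cells.
#' @return a complete `timecourse_matrix`.
#' @export
require_complete <- function(matrix) {
  times <- attr(matrix, "times")
  if (is.null(times)) times <- seq_len(ncol(matrix)) - 1
  keep <- stats::complete.cases(matrix)
  if (!any(keep)) stopf("no protein was quantified at every time point")
  out <- timecourse_matrix(unclass(matrix)[keep, , drop = FALSE], times)
  attr(out, "dropped") <- rownames(matrix)[!keep]
  out
}

#' Pairwise cosine distances between exchange trajectories
#'
#' @param matrix a complete [timecourse_matrix()].
#' @param na_action proteins with all-zero trajectories cannot enter the
#'   cosine geometry; they are excluded and listed in the `"excluded"`
#'   attribute.
#' @return symmetric cosine distance matrix with zero diagonal.
#' @export
pairwise_exchange_distance <- function(matrix, na_action = "exclude") {
  m <- unclass(matrix)
  if (anyNA(m)) stopf("trajectories must be complete; see require_complete()")
  zero <- rowSums(m^2) == 0
  excluded <- rownames(m)[zero]
  m <- m[!zero, , drop = FALSE]
  d <- cosine_distance_matrix(m)
  attr(d, "excluded") <- excluded
  d
}

#' Cluster proteins by exchange-trajectory shape
#'
#' Hierarchical (average-linkage by default) clustering of the cosine
#' distance matrix, cut into `k` groups. Because cosine distance ignores
#' uniform rescaling, the groups reflect decay shape, not amplitude.
#' Groups are numbered by decreasing mean terminal heavy fraction, so
#' group 1 is the most stable (slowest-exchanging) cluster.
#'
#' @param matrix a complete [timecourse_matrix()].
#' @param k number of clusters (default 3).
#' @param linkage linkage method (default "average").
#' @return list with `clusters` (named integer vector), `tree`
#'   ([stats::hclust]), and `distance` (the cosine matrix).
#' @export
cluster_exchange <- function(matrix, k = 3L, linkage = "average") {
  d <- pairwise_exchange_distance(matrix)
  if (k > nrow(d)) stopf("k = %d exceeds the %d proteins", k, nrow(d))
  hc <- hierarchical_cluster(d, linkage)
  raw <- stats::cutree(hc, k = k)
  terminal <- unclass(matrix)[names(raw), ncol(matrix)]
  stability <- tapply(terminal, raw, mean)
  relabel <- stats::setNames(rank(-stability, ties.method = "first"),
                             names(stability))
  clusters <- stats::setNames(as.integer(relabel[as.character(raw)]),
                              names(raw))
  list(clusters = clusters, tree = hc, distance = d)
}

#' Cumulative-prefix cosine distance between two trajectories
#'
#' For each prefix t_1..t_j (j >= 2) of the time grid, the cosine distance
#' between the two proteins' prefix vectors: how divergence accrues over
#' the course of the experiment. Not guaranteed monotone.
#'
#' @param matrix a complete [timecourse_matrix()].
#' @param pair character vector of two protein labels.
#' @return data.frame with columns `time` (the prefix endpoint) and
#'   `distance`; attribute `"construction" = "cumulative_prefix"` records
#'   the variant computed.
#' @export
distance_trajectory <- function(matrix, pair) {
  stopifnot(length(pair) == 2L)
  m <- unclass(matrix)
  absent <- setdiff(pair, rownames(m))
  if (length(absent)) stopf("protein(s) absent: %s",
                            paste(absent, collapse = ", "))
  times <- attr(matrix, "times")
  a <- m[pair[[1L]], ]
  b <- m[pair[[2L]], ]
  js <- 2:length(times)
  out <- data.frame(
    time = times[js],
    distance = vapply(js, function(j) cosine_distance(a[1:j], b[1:j]),
                      numeric(1)))
  attr(out, "construction") <- "cumulative_prefix"
  out
}
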