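#' Assemble per-field nuclei centroids
#'
#' One row per nucleus: the microscope field it belongs to, its centroid in
#' microns, and whether it stained positive for the marker of interest.
#'
#' @param df data.frame with columns `field_id`, `x_um`, `y_um`,
#'   `positive` (logical or 0/1).
#' @return data.frame of class `nuclei_fields`.
#' @export
nuclei_fields <- function(df) {
  needed <- c("field_id", "x_um", "y_um", "positive")
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stopf("nuclei table lacks column(s): %s", paste(absent, collapse = ", "))
  }
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    stopf("coordinates must be finite")
  }
  df$field_id <- as.character(df$field_id)
  df$positive <- as.logical(df$positive)
  if (anyNA(df$positive)) stopf("positive flags must be 0/1 or logical")
  structure(as.data.frame(df), class = c("nuclei_fields", "data.frame"))
}

# distances contributed by one set of points under a pairing rule
pair_rule_distances <- function(pts, pairing) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  dm <- as.matrix(stats::dist(pts))
  if (pairing == "all_pairs") return(dm[upper.tri(dm)])
  if (pairing == "mutual_nn") {
    diag(dm) <- Inf
    nn <- apply(dm, 1L, which.min)
    out <- numeric(0)
    for (i in seq_len(n)) {
      j <- nn[i]
      if (j > i && nn[j] == i) out <- c(out, dm[i, j])
    }
    return(out)
  }
  # sequential greedy: repeatedly remove the closest remaining pair
  diag(dm) <- Inf
  alive <- rep(TRUE, n)
  out <- numeric(0)
  while (sum(alive) >= 2L) {
    sub <- dm[alive, alive, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    idx <- which(alive)
    out <- c(out, sub[k])
    alive[idx[k]] <- FALSE
  }
  out
}

#' Observed pair distances between marker-positive nuclei
#'
#' Within each field, positive nuclei are paired (mutual nearest neighbors
#' by default, so a proximal doublet contributes exactly one distance) and
#' the within-pair distances are pooled across fields. Fields with fewer
#' than two positive nuclei contribute nothing and are logged.
#'
#' @param fields a [nuclei_fields()] table.
#' @param pairing "mutual_nn" (default), "all_pairs" or "greedy".
#' @return numeric vector of distances in microns; attribute
#'   `"skipped_fields"` lists fields with < 2 positives.
#' @export
observed_pair_distances <- function(fields,
                                    pairing = c("mutual_nn", "all_pairs",
                                                "greedy")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(fields, "nuclei_fields"))
  out <- numeric(0)
  skipped <- character(0)
  for (f in unique(fields$field_id)) {
    sub <- fields[fields$field_id == f & fields$positive, , drop = FALSE]
    if (nrow(sub) < 2L) {
      skipped <- c(skipped, f)
      next
    }
    out <- c(out, pair_rule_distances(as.matrix(sub[, c("x_um", "y_um")]),
                                      pairing))
  }
  if (!length(out)) stopf("no field has two or more positive nuclei")
  attr(out, "skipped_fields") <- skipped
  out
}

#' Null pair distances by per-field positive-count-matched resampling
#'
#' For each field with x >= 2 positive nuclei, x nuclei are drawn uniformly
#' without replacement from all nuclei of that field, the same pairing rule
#' is applied, and the distances are pooled over `n_resamples` rounds and
#' all fields: the randomization null for the observed distances.
#'
#' @param fields a [nuclei_fields()] table.
#' @param n_resamples resampling rounds per field (default 1000).
#' @param seed RNG seed (required; recorded in the `"seed"` attribute).
#' @param pairing pairing rule, as in [observed_pair_distances()].
#' @return numeric vector of pooled null distances in microns.
#' @export
null_pair_distances <- function(fields, n_resamples = 1000L, seed,
                                pairing = c("mutual_nn", "all_pairs",
                                            "greedy")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(fields, "nuclei_fields"))
  per_field <- list()
  for (f in unique(fields$field_id)) {
    sub <- fields[fields$field_id == f, , drop = FALSE]
    x <- sum(sub$positive)
    if (x < 2L) next
    stopifnot(x <= nrow(sub))
    per_field[[f]] <- list(coords = as.matrix(sub[, c("x_um", "y_um")]),
                           x = x)
  }
  if (!length(per_field)) stopf("no field has two or more positive nuclei")
  out <- with_seed(seed, {
    acc <- vector("list", length(per_field) * n_resamples)
    k <- 0L
    for (fld in per_field) {
      n <- nrow(fld$coords)
      for (r in seq_len(n_resamples)) {
        k <- k + 1L
        pick <- if (fld$x == n) seq_len(n) else sample.int(n, fld$x)
        acc[[k]] <- pair_rule_distances(fld$coords[pick, , drop = FALSE],
                                        pairing)
      }
    }
    unlist(acc, use.names = FALSE)
  })
  attr(out, "seed") <- seed
  attr(out, "n_resamples") <- n_resamples
  out
}

#' Bonferroni-corrected empirical p-values per observed pair
#'
#' The raw empirical p of an observed distance d is the add-one-corrected
#' fraction of null distances <= d; each is multiplied by the Bonferroni
#' factor m (the number of observed pairs by default) and capped at 1.
#'
#' @param observed observed pair distances (microns).
#' @param null pooled null distances from [null_pair_distances()].
#' @param m Bonferroni factor (default `length(observed)`).
#' @return numeric vector of corrected p-values, one per observed pair.
#' @export
per_pair_pvalues <- function(observed, null, m = length(observed)) {
  if (!length(null)) stopf("null distance pool is empty")
  sorted_null <- sort(null)
  p_raw <- (1 + findInterval(observed, sorted_null)) / (1 + length(null))
  pmin(1, m * p_raw)
}

#' Compare observed and null distance distributions
#'
#' Welch's t-test of the pooled observed positive-pair distances against
#' the pooled resampled null distances.
#'
#' @param observed,null numeric distance vectors, each with >= 2 values.
#' @return a `test_result`, see [welch_t()].
#' @export
compare_distributions <- function(observed, null) {
  welch_t(as.numeric(observed), as.numeric(null))
}

#' Spatial proximity test for marker-positive nuclei
#'
#' End-to-end wrapper: observed within-field positive-pair distances,
#' positive-count-matched per-field resampling null, per-pair Bonferroni
#' empirical p-values, and a Welch comparison of the two distance
#' distributions.
#'
#' @param fields a [nuclei_fields()] table.
#' @param n_resamples resampling rounds (default 1000).
#' @param seed RNG seed for the resampling.
#' @param pairing pairing rule (default mutual nearest neighbors).
#' @return object of class `spatial_test_result`: list with
#'   `observed_distances`, `null_distances`, `per_pair_p`, `welch`,
#'   `n_resamples`, `seed`, `pairing`.
#' @export
nuclei_proximity_test <- function(fields, n_resamples = 1000L, seed,
                                  pairing = c("mutual_nn", "all_pairs",
                                              "greedy")) {
  pairing <- match.arg(pairing)
  observed <- observed_pair_distances(fields, pairing)
  null <- null_pair_distances(fields, n_resamples, seed, pairing)
  structure(list(observed_distances = as.numeric(observed),
                 null_distances = as.numeric(null),
                 per_pair_p = per_pair_pvalues(observed, null),
                 welch = compare_distributions(observed, null),
                 n_resamples = n_resamples, seed = seed, pairing = pairing,
                 skipped_fields = attr(observed, "skipped_fields")),
            class = "spatial_test_result")
}

#' @export
print.spatial_test_result <- function(x, ...) {
  cat(sprintf(paste0("spatial_test_result: %d observed pairs (median ",
                     "%.2f um) vs %d null distances (median %.2f um); ",
                     "Welch p = %.4g [pairing: %s, %d resamples]\n"),
              length(x$observed_distances), stats::median(x$observed_distances),
              length(x$null_distances), stats::median(x$null_distances),
              x$welch$p_value, x$pairing, x$n_resamples))
  invisible(x)
}
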