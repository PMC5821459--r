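#' Shift heavy fractions so the bait sits at 0.5
#'
#' Per replicate, the difference between the bait's heavy fraction and 0.5
#' is subtracted from every protein's heavy fraction, removing replicate-
#' level mixing imbalance: the bait maps exactly to 0.5 and all pairwise
#' differences are preserved. Shifted values can leave \[0, 1\]; by default
#' they are used unclipped (clipping a translation would bias downstream
#' means) and the affected proteins are recorded in the `"clipped"`
#' attribute.
#'
#' @param h named numeric vector of heavy fractions for one replicate.
#' @param bait bait protein label (must be present in `h`).
#' @param clip clamp shifted values into \[0, 1\] (default `FALSE`).
#' @return named numeric vector of shifted fractions; attribute `"clipped"`
#'   lists proteins outside \[0, 1\] after the shift.
#' @export
shift_normalize <- function(h, bait, clip = FALSE) {
  if (!bait %in% names(h)) stopf("bait '%s' not quantified in replicate", bait)
  if (is.na(h[[bait]])) stopf("bait '%s' has a missing fraction", bait)
  shifted <- h - (h[[bait]] - 0.5)
  out_of_range <- names(shifted)[!is.na(shifted) &
                                   (shifted < 0 | shifted > 1)]
  if (clip) shifted <- pmin(pmax(shifted, 0), 1)
  attr(shifted, "clipped") <- out_of_range
  shifted
}

#' Relative recovery of each protein in the mutant channel
#'
#' With the wild type heavy-labeled and the mutant light-labeled, the
#' mutant/WT fold of protein i relative to the bait is
#' (L/H)_i / (L/H)_bait = r_bait / r_i on the heavy/light ratio scale; the
#' bait maps to 1, and the value is invariant to rescaling all ratios in a
#' replicate by a constant.
#'
#' @param r named numeric vector of heavy/light ratios for one replicate.
#' @param bait bait protein label.
#' @return named numeric vector of fold recoveries (bait = 1).
#' @export
relative_recovery <- function(r, bait) {
  if (!bait %in% names(r)) stopf("bait '%s' not quantified in replicate", bait)
  if (is.na(r[[bait]]) || r[[bait]] <= 0) stopf("bait ratio unusable")
  r[[bait]] / r
}

#' Proteins quantified in at least `min_n` replicates
#'
#' @param values_list list of named numeric vectors, one per replicate
#'   (NA entries do not count as quantified).
#' @param min_n minimum replicate count (default 2).
#' @return character vector of protein labels, in first-seen order.
#' @export
require_replicates <- function(values_list, min_n = 2L) {
  seen <- unlist(lapply(values_list,
                        function(v) names(v)[!is.na(v)]),
                 use.names = FALSE)
  counts <- table(factor(seen, levels = unique(seen)))
  names(counts)[counts >= min_n]
}

# proteins x replicates matrix (NA where unquantified)
replicate_matrix <- function(values_list, proteins) {
  out <- matrix(NA_real_, nrow = length(proteins),
                ncol = length(values_list),
                dimnames = list(proteins,
                                paste0("rep", seq_along(values_list))))
  for (j in seq_along(values_list)) {
    v <- values_list[[j]]
    shared <- intersect(proteins, names(v))
    out[shared, j] <- v[shared]
  }
  out
}

#' Bundle replicate capture tables into a mutant-vs-WT experiment
#'
#' @param tables list of filtered [protein_group_table()]s, one per
#'   replicate, each with the wild type heavy-labeled and the mutant
#'   light-labeled.
#' @param mutant_label "EN" or "RT" (free text accepted).
#' @param bait bait protein label, present in every replicate.
#' @return object of class `mutant_experiment` with per-replicate shifted
#'   heavy fractions (`$shifted`) and relative recoveries (`$recovery`).
#' @export
mutant_experiment <- function(tables, mutant_label, bait) {
  stopifnot(length(tables) >= 1L)
  shifted <- list()
  recovery <- list()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "protein_group_table"))
    r <- stats::setNames(tab$records$ratio_hl, tab$records$gene_symbol)
    r <- r[!is.na(r)]
    if (!bait %in% names(r)) {
      stopf("bait '%s' not quantified in replicate %d", bait, i)
    }
    shifted[[i]] <- shift_normalize(heavy_fraction(r), bait)
    recovery[[i]] <- relative_recovery(r, bait)
  }
  structure(list(mutant_label = mutant_label, bait = bait,
                 shifted = shifted, recovery = recovery,
                 n_replicates = length(tables)),
            class = "mutant_experiment")
}

#' Test shifted heavy fractions against the no-change value 0.5
#'
#' One-sample t-test per protein on its shifted heavy fractions across
#' replicates, Benjamini-Hochberg corrected over all testable proteins.
#' Proteins quantified in fewer than `min_n` replicates are dropped;
#' zero-variance proteins are flagged degenerate and excluded from the BH
#' family but reported.
#'
#' @param experiment a [mutant_experiment()] (or a list of named shifted
#'   vectors).
#' @param min_n minimum replicate count (default 2).
#' @return data.frame of class `mutant_test_table` with columns `protein`,
#'   `n`, `mean_shifted`, `sd_shifted`, `mean_recovery`, `statistic`, `df`,
#'   `p`, `q`, `degenerate`.
#' @export
test_vs_wt <- function(experiment, min_n = 2L) {
  shifted <- if (inherits(experiment, "mutant_experiment")) {
    experiment$shifted
  } else {
    experiment
  }
  recovery <- if (inherits(experiment, "mutant_experiment")) {
    experiment$recovery
  } else {
    NULL
  }
  proteins <- require_replicates(shifted, min_n)
  mat <- replicate_matrix(shifted, proteins)
  res <- lapply(proteins, function(p) {
    v <- mat[p, ]
    v <- v[!is.na(v)]
    t <- one_sample_t(v, 0.5)
    data.frame(protein = p, n = length(v), mean_shifted = mean(v),
               sd_shifted = stats::sd(v), statistic = t$statistic,
               df = t$df, p = t$p_value, degenerate = t$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  fam <- !out$degenerate
  out$q[fam] <- bh_adjust(out$p[fam])
  if (!is.null(recovery)) {
    rmat <- replicate_matrix(recovery, proteins)
    out$mean_recovery <- rowMeans(rmat, na.rm = TRUE)
  }
  class(out) <- c("mutant_test_table", "data.frame")
  out
}

#' Compare the two mutants protein-by-protein
#'
#' Two-sample test (Welch by default) of each protein's shifted heavy
#' fractions between the EN- and RT-mutant experiments, BH-corrected over
#' proteins testable in both.
#'
#' @param experiment_a,experiment_b [mutant_experiment()]s.
#' @param min_n minimum replicates per experiment (default 2).
#' @param pooled use the pooled equal-variance t-test (default `FALSE`).
#' @return data.frame with columns `protein`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `statistic`, `df`, `p`, `q`, `degenerate`; proteins
#'   untestable in either experiment are listed in the `"excluded"`
#'   attribute.
#' @export
test_en_vs_rt <- function(experiment_a, experiment_b, min_n = 2L,
                          pooled = FALSE) {
  sa <- if (inherits(experiment_a, "mutant_experiment")) {
    experiment_a$shifted
  } else {
    experiment_a
  }
  sb <- if (inherits(experiment_b, "mutant_experiment")) {
    experiment_b$shifted
  } else {
    experiment_b
  }
  pa <- require_replicates(sa, min_n)
  pb <- require_replicates(sb, min_n)
  proteins <- intersect(pa, pb)
  ma <- replicate_matrix(sa, proteins)
  mb <- replicate_matrix(sb, proteins)
  res <- lapply(proteins, function(p) {
    va <- ma[p, ]
    va <- va[!is.na(va)]
    vb <- mb[p, ]
    vb <- vb[!is.na(vb)]
    t <- welch_t(va, vb, pooled = pooled)
    data.frame(protein = p, n_a = length(va), n_b = length(vb),
               mean_a = mean(va), mean_b = mean(vb),
               statistic = t$statistic, df = t$df, p = t$p_value,
               degenerate = t$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  fam <- !out$degenerate & !is.na(out$p)
  out$q[fam] <- bh_adjust(out$p[fam])
  attr(out, "excluded") <- setdiff(union(pa, pb), proteins)
  out
}

#' Aligned double histogram of mutant recoveries
#'
#' Bins the per-protein mean relative recoveries of the two mutant
#' experiments on a common set of bin edges anchored at 0, and counts
#' proteins whose EN and RT positions fall on opposite sides of the bait
#' position ("crisscross" behavior).
#'
#' @param en_recovery,rt_recovery named numeric vectors of per-protein mean
#'   recoveries (bait-normalized, so the bait sits at 1).
#' @param bin_width histogram bin width (default 2).
#' @param bait_position recovery value of the bait (default 1).
#' @return list with `breaks`, `en_counts`, `rt_counts`, `positions`
#'   (data.frame protein, en, rt, crossing) and `n_crisscross`.
#' @export
double_histogram <- function(en_recovery, rt_recovery, bin_width = 2,
                             bait_position = 1) {
  shared <- intersect(names(en_recovery), names(rt_recovery))
  en <- en_recovery[shared]
  rt <- rt_recovery[shared]
  top <- max(en, rt, bait_position)
  breaks <- seq(0, bin_width * ceiling(top / bin_width) + bin_width,
                by = bin_width)
  bin_counts <- function(v) {
    tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                          left.open = TRUE) + (v == 0),
             nbins = length(breaks) - 1L)
  }
  crossing <- (en - bait_position) * (rt - bait_position) < 0
  list(breaks = breaks,
       en_counts = bin_counts(en),
       rt_counts = bin_counts(rt),
       positions = data.frame(protein = shared, en = unname(en),
                              rt = unname(rt), crossing = unname(crossing),
                              stringsAsFactors = FALSE),
       n_crisscross = sum(crossing))
}

#' Significance stars for adjusted p-values
#'
#' "*" for 0.01 < q <= 0.05, "**" for q <= 0.01, "" otherwise.
#'
#' @param q numeric vector of adjusted p-values.
#' @return character vector of stars.
#' @export
significance_stars <- function(q) {
  out <- character(length(q))
  out[!is.na(q) & q <= 0.05] <- "*"
  out[!is.na(q) & q <= 0.01] <- "**"
  out
}
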