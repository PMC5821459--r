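# Independent oracles used to freeze expected values. None of these share
# code with the implementation under test.

# upper-tail standard normal quantile by bisection on the complementary
# error function: P(Z > z) = erfc(z / sqrt(2)) / 2
oracle_upper_quantile <- function(alpha, tol = 1e-9) {
  f <- function(z) pracma::erfc(z / sqrt(2)) / 2 - alpha
  lo <- -40
  hi <- 40
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# upper tail of Student's t by numerical integration of the density
oracle_t_tail <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = abs(t), upper = Inf,
                   rel.tol = 1e-10)$value
}

oracle_two_sided_p <- function(t, df) 2 * oracle_t_tail(t, df)

# one-sample and Welch statistics recomputed from first principles
oracle_one_sample <- function(x, mu0) {
  t <- (mean(x) - mu0) / (sd(x) / sqrt(length(x)))
  list(t = t, df = length(x) - 1, p = oracle_two_sided_p(t, length(x) - 1))
}

oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = oracle_two_sided_p(t, df))
}

# quadratic-time step-up definition of Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(seq(rank_i, m), function(j) {
      min(1, m * p[ord[j]] / j)
    }, numeric(1))
    q[i] <- min(cands)
  }
  q
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
oracle_average_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  avg <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- avg(clusters[[i]], clusters[[j]])
        if (h < best) {
          best <- h
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# quick builders for protein-group fixtures
make_records <- function(symbols, ratios, peptides = 3L,
                         contaminant = FALSE, reverse = FALSE) {
  data.frame(gene_symbol = symbols, ratio_hl = ratios,
             razor_unique_peptides = rep_len(peptides, length(symbols)),
             is_contaminant = rep_len(contaminant, length(symbols)),
             is_reverse = rep_len(reverse, length(symbols)),
             stringsAsFactors = FALSE)
}

make_table <- function(symbols, ratios, design = label_design("A", "B"),
                       sample_id = "t", ...) {
  protein_group_table(make_records(symbols, ratios, ...), sample_id, design)
}

# adjusted Rand index of two labelings (via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
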