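#' Design of a synthetic interactome study
#'
#' Fixes the ground truth every generator draws from: the protein universe,
#' the planted modules and their per-assay effects, the replicate noise
#' level, and decoy counts. Defaults mirror the structure of a bait-anchored
#' affinity-capture study: a 7-member cytoplasmic RNP module (bait, its
#' partner ORF protein and five RNA-linked cofactors), a 16-member nuclear
#' module containing a tightly co-partitioning triple, and an unstructured
#' background.
#'
#' @param n_proteins total real proteins including modules (default 150).
#' @param noise_sd per-mixture logit-scale noise SD for swap assays
#'   (default 0.15, about 0.037 on the fraction scale at h = 0.5).
#' @param n_decoys named counts of planted QC-failure rows per table:
#'   `contaminant`, `reverse`, `one_peptide` (default 5 each).
#' @param rnase list: `displacement_sd`, displacement of the sensitive
#'   module along both axes in units of the fraction-scale noise SD
#'   (default 5).
#' @param split list of true elution fractions: `anchor` (ORF1, default
#'   0.95), `bait` (ORF2, default 0.26), `cytoplasmic` (default 0.8),
#'   `nuclear_max` (default 0.36), `triple` (the tight triple's common
#'   value, default 0.13).
#' @param mutant list: `delta_h` class effect on the heavy-fraction scale
#'   (default 0.15), `sigma` replicate noise SD on the fraction scale
#'   (default 0.05), `bait_offset_sd` SD of the per-replicate bait
#'   mixing offset (default 0.03).
#' @param exchange list: `rates` decay rates in 1/s (default
#'   `c(1e-4, 1e-3, 1e-2)`), `n_per_class` (default 10), `baseline`
#'   plateau b (default 0), `noise_sd` (default 0.02), `times` seconds
#'   (default `c(0, 30, 300, 1800)`).
#' @param seed mandatory integer seed; every generator is a pure function
#'   of (design, seed).
#' @return list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_proteins = 150L,
                             noise_sd = 0.15,
                             n_decoys = c(contaminant = 5L, reverse = 5L,
                                          one_peptide = 5L),
                             rnase = list(displacement_sd = 5),
                             split = list(anchor = 0.95, bait = 0.26,
                                          cytoplasmic = 0.8,
                                          nuclear_max = 0.36, triple = 0.13),
                             mutant = list(delta_h = 0.15, sigma = 0.05,
                                           bait_offset_sd = 0.03),
                             exchange = list(rates = c(1e-4, 1e-3, 1e-2),
                                             n_per_class = 10L, baseline = 0,
                                             noise_sd = 0.02,
                                             times = c(0, 30, 300, 1800)),
                             seed) {
  if (missing(seed)) stopf("a seed is mandatory in a synthetic design")
  cytoplasmic <- c("ORF2", "ORF1", "MOV10", "UPF1", "ZCCHC3",
                   "PABPC1", "PABPC4")
  nuclear <- c("PURA", "PURB", "PCNA", "TOP1", "PARP1", "IPO7",
               "NAP1L1", "NAP1L4", "FKBP4", "HSP90AA1", "HSP90AB1",
               "HSPA8", "HSPA1A", "TUBB", "TUBB4B", "HMCES")
  n_bg <- n_proteins - length(cytoplasmic) - length(nuclear)
  if (n_bg < 10L) stopf("n_proteins too small for the planted modules")
  modules <- list(cytoplasmic = cytoplasmic,
                  nuclear = nuclear,
                  triple = c("PURA", "PURB", "PCNA"),
                  background = sprintf("BG%04d", seq_len(n_bg)))
  structure(list(n_proteins = n_proteins, modules = modules,
                 bait = "ORF2", anchor = "ORF1",
                 noise_sd = noise_sd, n_decoys = n_decoys,
                 rnase = rnase, split = split, mutant = mutant,
                 exchange = exchange, seed = as.integer(seed)),
            class = "synthetic_design")
}

logit_noise <- function(h, sd) stats::plogis(stats::qlogis(h) +
                                               stats::rnorm(length(h), 0, sd))

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# one synthetic mixture table: ratios on the H/L scale consistent with the
# mixture's label design, plus decoy rows exercising the filters
synth_mixture <- function(cond_fraction, design, condition, sample_id,
                          n_decoys) {
  # cond_fraction: named per-protein fraction of `condition`; convert to
  # heavy fraction under this mixture's orientation
  h <- if (identical(condition, unname(design[["heavy"]]))) {
    cond_fraction
  } else {
    1 - cond_fraction
  }
  r <- h / (1 - h)
  real <- data.frame(gene_symbol = names(cond_fraction),
                     ratio_hl = unname(r),
                     razor_unique_peptides = 2L + stats::rpois(length(r), 3),
                     is_contaminant = FALSE, is_reverse = FALSE,
                     stringsAsFactors = FALSE)
  mk_decoys <- function(n, prefix, contaminant = FALSE, reverse = FALSE,
                        peptides = NULL) {
    if (n < 1L) return(NULL)
    data.frame(gene_symbol = sprintf("%s%02d", prefix, seq_len(n)),
               ratio_hl = exp(stats::rnorm(n, 0, 0.5)),
               razor_unique_peptides = if (is.null(peptides)) {
                 2L + stats::rpois(n, 3)
               } else {
                 rep(peptides, n)
               },
               is_contaminant = contaminant, is_reverse = reverse,
               stringsAsFactors = FALSE)
  }
  rec <- rbind(real,
               mk_decoys(n_decoys[["contaminant"]], "CON_", contaminant = TRUE),
               mk_decoys(n_decoys[["reverse"]], "REV_", reverse = TRUE),
               mk_decoys(n_decoys[["one_peptide"]], "ONEPEP_", peptides = 1L))
  protein_group_table(rec, sample_id, design)
}

#' Simulate a label-swapped duplicate of a two-condition capture assay
#'
#' Generates the two cross-mixed mixtures of an RNase-sensitivity or
#' split-tandem experiment: per-protein true condition fractions perturbed
#' by independent logit-normal noise in each mixture, emitted as
#' heavy/light ratios consistent with each mixture's (opposite) label
#' orientation, with decoy rows injected.
#'
#' For `assay = "rnase"` the condition is the control ("BSA") fraction:
#' unchanged proteins sit at 0.5 and the cytoplasmic module (except the
#' immobilized bait) is displaced toward BSA enrichment by
#' `rnase$displacement_sd` noise SDs per axis. For `assay = "split"` the
#' condition is the elution fraction: the anchor partitions almost fully
#' into the elution, the nuclear module stays low with the planted triple
#' at a common value, and the background spreads uniformly.
#'
#' @param design a [synthetic_design()].
#' @param assay "rnase" or "split".
#' @return list with `mix1`, `mix2` ([protein_group_table()]s with opposite
#'   designs), `condition`, and `truth` (per-protein module label and true
#'   condition fraction).
#' @export
simulate_swap_experiment <- function(design, assay = c("rnase", "split")) {
  assay <- match.arg(assay)
  stopifnot(inherits(design, "synthetic_design"))
  mods <- design$modules
  proteins <- c(mods$cytoplasmic, mods$nuclear, mods$background)

  with_seed(design$seed + ifelse(assay == "rnase", 11L, 13L), {
    if (assay == "rnase") {
      condition <- "BSA"
      designs <- list(label_design(heavy = "BSA", light = "RNase"),
                      label_design(heavy = "RNase", light = "BSA"))
      frac_sigma <- design$noise_sd / 4  # dplogis(0) = 1/4
      truth_frac <- stats::setNames(rep(0.5, length(proteins)), proteins)
      sensitive <- setdiff(mods$cytoplasmic, design$bait)
      truth_frac[sensitive] <- clamp01(
        0.5 + design$rnase$displacement_sd * frac_sigma)
      label <- ifelse(proteins %in% sensitive, "sensitive", "unchanged")
    } else {
      condition <- "Elution"
      designs <- list(label_design(heavy = "Elution", light = "Supernatant"),
                      label_design(heavy = "Supernatant", light = "Elution"))
      sp <- design$split
      truth_frac <- stats::setNames(
        stats::runif(length(proteins), 0.05, 0.95), proteins)
      truth_frac[mods$cytoplasmic] <- clamp01(
        stats::rnorm(length(mods$cytoplasmic), sp$cytoplasmic, 0.03))
      truth_frac[mods$nuclear] <- stats::runif(length(mods$nuclear),
                                               0.05, sp$nuclear_max)
      truth_frac[mods$triple] <- sp$triple
      truth_frac[design$anchor] <- sp$anchor
      truth_frac[design$bait] <- sp$bait
      label <- rep("background", length(proteins))
      names(label) <- proteins
      label[mods$cytoplasmic] <- "cytoplasmic"
      label[mods$nuclear] <- "nuclear"
      label[mods$triple] <- "triple"
      label <- unname(label)
    }
    obs1 <- clamp01(logit_noise(truth_frac, design$noise_sd))
    obs2 <- clamp01(logit_noise(truth_frac, design$noise_sd))
    names(obs1) <- names(obs2) <- proteins
    mix1 <- synth_mixture(obs1, designs[[1L]], condition,
                          paste0(assay, "_mix1"), design$n_decoys)
    mix2 <- synth_mixture(obs2, designs[[2L]], condition,
                          paste0(assay, "_mix2"), design$n_decoys)
    list(mix1 = mix1, mix2 = mix2, condition = condition,
         truth = data.frame(protein = proteins, module = label,
                            true_fraction = unname(truth_frac),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate replicate captures of a catalytic mutant against wild type
#'
#' The wild type is heavy-labeled, the mutant light-labeled, so the heavy
#' fraction h = WT / (WT + mutant) sits at 0.5 for unaffected proteins.
#' Proteins whose capture the mutation reduces have h > 0.5; proteins it
#' elevates have h < 0.5. The endonuclease mutant reduces the cytoplasmic
#' module and elevates the nuclear one; the reverse-transcriptase mutant
#' does the opposite. Each replicate additionally carries a bait-level
#' mixing offset (the bait itself is emitted noiselessly at 0.5 + offset)
#' that shift normalization must remove.
#'
#' @param design a [synthetic_design()].
#' @param mutant "EN" or "RT".
#' @param n_replicates replicate count (default 3).
#' @return list with `tables` (list of [protein_group_table()]s), `mutant`,
#'   and `truth` (per-protein class and true shifted heavy fraction).
#' @export
simulate_mutant_experiment <- function(design, mutant = c("EN", "RT"),
                                       n_replicates = 3L) {
  mutant <- match.arg(mutant)
  stopifnot(inherits(design, "synthetic_design"))
  mods <- design$modules
  proteins <- c(mods$cytoplasmic, mods$nuclear, mods$background)
  dh <- design$mutant$delta_h
  sign_cyto <- if (mutant == "EN") +1 else -1  # reduced in mutant => h > 0.5
  truth_h <- stats::setNames(rep(0.5, length(proteins)), proteins)
  cyto <- setdiff(mods$cytoplasmic, design$bait)
  truth_h[cyto] <- 0.5 + sign_cyto * dh
  truth_h[mods$nuclear] <- 0.5 - sign_cyto * dh
  truth_h[design$bait] <- 0.5
  class <- rep("neutral", length(proteins))
  names(class) <- proteins
  class[cyto] <- "cytoplasmic"
  class[mods$nuclear] <- "nuclear"

  ld <- label_design(heavy = "WT", light = mutant)
  tables <- with_seed(design$seed + ifelse(mutant == "EN", 17L, 19L), {
    lapply(seq_len(n_replicates), function(rep_i) {
      offset <- stats::rnorm(1, 0, design$mutant$bait_offset_sd)
      h <- clamp01(truth_h + offset +
                     stats::rnorm(length(proteins), 0, design$mutant$sigma))
      h[design$bait] <- clamp01(0.5 + offset)
      rec <- data.frame(gene_symbol = proteins,
                        ratio_hl = unname(h / (1 - h)),
                        razor_unique_peptides = 2L +
                          stats::rpois(length(proteins), 3),
                        is_contaminant = FALSE, is_reverse = FALSE,
                        stringsAsFactors = FALSE)
      protein_group_table(rec, sprintf("%s_rep%d", mutant, rep_i), ld)
    })
  })
  list(tables = tables, mutant = mutant,
       truth = data.frame(protein = proteins, class = unname(class),
                          true_shifted_h = unname(truth_h),
                          stringsAsFactors = FALSE))
}

#' Simulate exchange-kinetics trajectories
#'
#' Heavy-fraction decay h(t) = (1 - b) exp(-k t) + b for planted rate
#' classes, sampled on the design's time grid. The zero time point is the
#' untreated capture and is emitted noiselessly at 1; later points carry
#' truncated-normal noise (clamped to \[0, 1\]).
#'
#' @param design a [synthetic_design()].
#' @return list with `matrix` (a [timecourse_matrix()]) and `truth`
#'   (per-protein rate class and rate).
#' @export
simulate_timecourse <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  ex <- design$exchange
  if (any(ex$rates < 0)) stopf("decay rates must be non-negative")
  if (ex$baseline < 0 || ex$baseline > 1) stopf("baseline must lie in [0, 1]")
  n_class <- length(ex$rates)
  proteins <- sprintf("P%d_%02d", rep(seq_len(n_class), each = ex$n_per_class),
                      rep(seq_len(ex$n_per_class), n_class))
  rates <- rep(ex$rates, each = ex$n_per_class)
  times <- ex$times
  mean_traj <- outer(rates, times, function(k, t) {
    (1 - ex$baseline) * exp(-k * t) + ex$baseline
  })
  values <- with_seed(design$seed + 23L, {
    noisy <- pmin(pmax(mean_traj +
                         matrix(stats::rnorm(length(mean_traj), 0,
                                             ex$noise_sd),
                                nrow = nrow(mean_traj)), 0), 1)
    noisy[, times == 0] <- 1  # untreated capture: fully heavy by convention
    noisy
  })
  rownames(values) <- proteins
  list(matrix = timecourse_matrix(values, times),
       truth = data.frame(protein = proteins,
                          class = rep(seq_len(n_class), each = ex$n_per_class),
                          rate = rates, stringsAsFactors = FALSE))
}

#' Simulate a multi-experiment profile set with planted modules
#'
#' Each of `n_modules` modules carries its own signature vector per
#' experiment; member proteins observe the signature plus Gaussian noise.
#' The planted partition is the ground truth for integration clustering.
#'
#' @param n_modules module count (default 5).
#' @param proteins_per_module members per module (default 8).
#' @param n_experiments experiments in the set (default 5).
#' @param profile_length values per experiment (default 4).
#' @param sigma within-module noise SD (default 0.05; signatures are
#'   standard normal, so this is a 20:1 signal-to-noise scale).
#' @param drop_fraction fraction of (protein, experiment) entries removed
#'   to exercise missing-pair handling (default 0).
#' @param seed RNG seed.
#' @return list with `profiles` (a [profile_set()]) and `truth`
#'   (per-protein module id).
#' @export
simulate_profile_set <- function(n_modules = 5L, proteins_per_module = 8L,
                                 n_experiments = 5L, profile_length = 4L,
                                 sigma = 0.05, drop_fraction = 0, seed) {
  proteins <- sprintf("M%d_%02d", rep(seq_len(n_modules),
                                      each = proteins_per_module),
                      rep(seq_len(proteins_per_module), n_modules))
  truth <- rep(seq_len(n_modules), each = proteins_per_module)
  experiments <- with_seed(seed, {
    out <- lapply(seq_len(n_experiments), function(e) {
      signatures <- matrix(stats::rnorm(n_modules * profile_length),
                           nrow = n_modules)
      m <- signatures[truth, , drop = FALSE] +
        matrix(stats::rnorm(length(proteins) * profile_length, 0, sigma),
               nrow = length(proteins))
      rownames(m) <- proteins
      m
    })
    names(out) <- sprintf("exp%d", seq_len(n_experiments))
    if (drop_fraction > 0) {
      for (e in seq_along(out)) {
        drop <- stats::runif(length(proteins)) < drop_fraction
        out[[e]] <- out[[e]][!drop, , drop = FALSE]
      }
    }
    out
  })
  list(profiles = profile_set(experiments),
       truth = stats::setNames(truth, proteins))
}

#' Simulate per-field nuclei point patterns
#'
#' Nuclei counts are Poisson in each field and positions uniform (a spatial
#' Poisson process on the observed window). In "random" mode each nucleus
#' is independently marker-positive; in "daughter_pairs" mode positive
#' nuclei are planted as proximal pairs at a fixed displacement (plus
#' isotropic jitter), emulating recently divided cells.
#'
#' @param n_fields number of fields (default 20).
#' @param field_size field width and height in microns (default
#'   `c(400, 400)`).
#' @param density nuclei per square micron (default 1e-4, i.e. mean
#'   nearest-neighbor spacing 50 um).
#' @param positive_fraction expected fraction of positive nuclei
#'   (default 0.18).
#' @param pair_mode "random" or "daughter_pairs".
#' @param displacement within-pair distance in microns (default 10).
#' @param jitter_sd per-coordinate jitter SD around the planted
#'   displacement (default 1).
#' @param seed RNG seed.
#' @return list with `fields` (a [nuclei_fields()] table) and `truth`
#'   (data.frame of planted pairs; empty in random mode).
#' @export
simulate_nuclei_fields <- function(n_fields = 20L, field_size = c(400, 400),
                                   density = 1e-4, positive_fraction = 0.18,
                                   pair_mode = c("random", "daughter_pairs"),
                                   displacement = 10, jitter_sd = 1, seed) {
  pair_mode <- match.arg(pair_mode)
  area <- prod(field_size)
  if (density * area < 2) stopf("expected nuclei per field must be >= 2")
  if (positive_fraction < 0 || positive_fraction > 1) {
    stopf("positive_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    rows <- list()
    pairs <- list()
    for (f in seq_len(n_fields)) {
      fid <- sprintf("field%02d", f)
      n <- stats::rpois(1, density * area)
      if (pair_mode == "random") {
        if (n == 0) next
        rows[[fid]] <- data.frame(
          field_id = fid,
          x_um = stats::runif(n, 0, field_size[[1L]]),
          y_um = stats::runif(n, 0, field_size[[2L]]),
          positive = stats::runif(n) < positive_fraction,
          stringsAsFactors = FALSE)
      } else {
        n_pairs <- max(1L, round(positive_fraction * n / 2))
        n_bg <- max(0L, n - 2L * n_pairs)
        bg <- data.frame(field_id = fid,
                         x_um = stats::runif(n_bg, 0, field_size[[1L]]),
                         y_um = stats::runif(n_bg, 0, field_size[[2L]]),
                         positive = FALSE, stringsAsFactors = FALSE)
        margin <- displacement + 4 * jitter_sd
        cx <- stats::runif(n_pairs, margin, field_size[[1L]] - margin)
        cy <- stats::runif(n_pairs, margin, field_size[[2L]] - margin)
        theta <- stats::runif(n_pairs, 0, 2 * pi)
        dx <- displacement / 2 * cos(theta)
        dy <- displacement / 2 * sin(theta)
        jit <- function(k) stats::rnorm(k, 0, jitter_sd)
        pos <- data.frame(
          field_id = fid,
          x_um = c(cx + dx + jit(n_pairs), cx - dx + jit(n_pairs)),
          y_um = c(cy + dy + jit(n_pairs), cy - dy + jit(n_pairs)),
          positive = TRUE, stringsAsFactors = FALSE)
        rows[[fid]] <- rbind(bg, pos)
        pairs[[fid]] <- data.frame(field_id = fid,
                                   pair = seq_len(n_pairs),
                                   cx = cx, cy = cy,
                                   stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(pairs)) {
      do.call(rbind, c(pairs, list(make.row.names = FALSE)))
    } else {
      data.frame(field_id = character(0), pair = integer(0),
                 cx = numeric(0), cy = numeric(0))
    }
    list(fields = nuclei_fields(do.call(rbind,
                                        c(rows,
                                          list(make.row.names = FALSE)))),
         truth = truth)
  })
}
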