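#' Column-name dialect for quantified protein-group tables
#'
#' Search engines emit tab-delimited protein-group tables whose column names
#' vary between versions. A dialect maps the five fields this package needs
#' onto the column names present in a given file. The defaults match the
#' widely used "proteinGroups.txt" layout.
#'
#' @param gene column holding gene symbols (groups separated by ";").
#' @param ratio column holding the unnormalized heavy/light ratio.
#' @param peptides column holding the razor + unique peptide count.
#' @param contaminant column flagging potential contaminants with "+".
#' @param reverse column flagging reversed-decoy hits with "+".
#' @param intensity optional summed-intensity column used to break ties when
#'   duplicate gene symbols must be collapsed; set to `NULL` if absent.
#' @return a named list of class `pg_dialect`.
#' @export
pg_dialect <- function(gene = "Gene names",
                       ratio = "Ratio H/L",
                       peptides = "Razor + unique peptides",
                       contaminant = "Potential contaminant",
                       reverse = "Reverse",
                       intensity = "Intensity") {
  structure(list(gene = gene, ratio = ratio, peptides = peptides,
                 contaminant = contaminant, reverse = reverse,
                 intensity = intensity),
            class = "pg_dialect")
}

#' Declare which isotope label carries which condition
#'
#' In a label-swap design each mixture assigns the two experimental
#' conditions to the heavy and light SILAC channels; the swapped replicate
#' reverses the assignment. A `label_design` records one mixture's
#' orientation.
#'
#' @param heavy condition label carried by the heavy channel.
#' @param light condition label carried by the light channel.
#' @return named character vector of class `label_design`.
#' @examples
#' label_design(heavy = "BSA", light = "RNase")
#' @export
label_design <- function(heavy, light) {
  if (!is.character(heavy) || !is.character(light) ||
      length(heavy) != 1L || length(light) != 1L) {
    stopf("`heavy` and `light` must be single condition labels")
  }
  if (identical(heavy, light)) stopf("heavy and light conditions must differ")
  structure(c(heavy = heavy, light = light), class = "label_design")
}

#' Construct a protein-group table
#'
#' The in-memory form of one quantified mixture: one record per protein
#' group, with the heavy/light ratio, peptide-count and decoy/contaminant
#' flags needed for filtering. Ambiguous groups (several gene symbols
#' sharing the identifying peptides) are collapsed to their first symbol,
#' with the full membership retained in `group_members`; duplicate symbols
#' are collapsed to the record with the most razor+unique peptides (ties
#' broken by summed intensity when available, else first occurrence).
#'
#' @param records data.frame with columns `gene_symbol`, `ratio_hl`,
#'   `razor_unique_peptides`, `is_contaminant`, `is_reverse` and optionally
#'   `group_members` and `intensity`.
#' @param sample_id identifier for the mixture.
#' @param design a [label_design()].
#' @param collapse collapse duplicate gene symbols (default `TRUE`).
#' @return object of class `protein_group_table`: list with elements
#'   `records`, `sample_id`, `label_design` and `log` (per-reason removal /
#'   collapse bookkeeping).
#' @export
protein_group_table <- function(records, sample_id, design, collapse = TRUE) {
  needed <- c("gene_symbol", "ratio_hl", "razor_unique_peptides",
              "is_contaminant", "is_reverse")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!inherits(design, "label_design")) {
    stopf("`design` must be created with label_design()")
  }
  records$gene_symbol <- as.character(records$gene_symbol)
  records$ratio_hl <- as.numeric(records$ratio_hl)
  records$razor_unique_peptides <- as.integer(records$razor_unique_peptides)
  if (any(records$razor_unique_peptides < 0, na.rm = TRUE)) {
    stopf("razor_unique_peptides must be non-negative")
  }
  if (is.null(records$group_members)) records$group_members <- records$gene_symbol
  log <- list()

  # zero or negative ratios are one-channel-only detections: unusable for
  # fraction coordinates, kept as missing but logged
  bad <- !is.na(records$ratio_hl) & records$ratio_hl <= 0
  if (any(bad)) {
    log$nonpositive_ratio <- records$gene_symbol[bad]
    records$ratio_hl[bad] <- NA_real_
  }

  if (collapse && anyDuplicated(records$gene_symbol)) {
    log$collapsed_duplicates <- unique(
      records$gene_symbol[duplicated(records$gene_symbol)])
    ord <- order(-records$razor_unique_peptides,
                 if (!is.null(records$intensity)) -records$intensity
                 else seq_len(nrow(records)),
                 seq_len(nrow(records)))
    records <- records[ord, , drop = FALSE]
    records <- records[!duplicated(records$gene_symbol), , drop = FALSE]
    records <- records[order(match(records$gene_symbol,
                                   unique(records$gene_symbol))), ,
                       drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 sample_id = as.character(sample_id),
                 label_design = design,
                 log = log),
            class = "protein_group_table")
}

#' @export
print.protein_group_table <- function(x, ...) {
  cat(sprintf("protein_group_table '%s': %d records (heavy=%s, light=%s)\n",
              x$sample_id, nrow(x$records),
              x$label_design[["heavy"]], x$label_design[["light"]]))
  invisible(x)
}

#' Read a quantified protein-group table
#'
#' Parses a tab-delimited protein-group file into a
#' [protein_group_table()]. Blank and zero ratios are preserved as missing;
#' the "+" convention marks contaminant and reversed-decoy rows.
#'
#' @param path file path to a tab-delimited table with a header row.
#' @param sample_id identifier for this mixture.
#' @param design a [label_design()] giving the mixture's label orientation.
#' @param dialect a [pg_dialect()] column-name map.
#' @return a [protein_group_table()].
#' @export
read_protein_groups <- function(path, sample_id, design,
                                dialect = pg_dialect()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  required <- c(dialect$gene, dialect$ratio, dialect$peptides,
                dialect$contaminant, dialect$reverse)
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    stopf("input lacks mapped column(s): %s", paste(absent, collapse = ", "))
  }

  parse_num <- function(x, column) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    blank <- x == "" | toupper(x) %in% c("NA", "NAN")
    out[blank] <- NA_real_
    bad <- is.na(out) & !blank
    if (any(bad)) {
      stopf("unparsable numeric in column '%s' at row %d: '%s'",
            column, which(bad)[1L], x[which(bad)[1L]])
    }
    out
  }

  gene_full <- raw[[dialect$gene]]
  records <- data.frame(
    gene_symbol = vapply(strsplit(gene_full, ";", fixed = TRUE),
                         function(g) if (length(g)) trimws(g[[1L]]) else "",
                         character(1)),
    ratio_hl = parse_num(raw[[dialect$ratio]], dialect$ratio),
    razor_unique_peptides = as.integer(
      parse_num(raw[[dialect$peptides]], dialect$peptides)),
    is_contaminant = trimws(raw[[dialect$contaminant]]) == "+",
    is_reverse = trimws(raw[[dialect$reverse]]) == "+",
    group_members = gene_full,
    stringsAsFactors = FALSE
  )
  if (!is.null(dialect$intensity) && dialect$intensity %in% names(raw)) {
    records$intensity <- suppressWarnings(
      as.numeric(raw[[dialect$intensity]]))
  }
  protein_group_table(records, sample_id, design)
}

#' Filter a protein-group table by the standard quality rules
#'
#' Removes contaminants, reversed-decoy hits, groups with fewer than
#' `min_peptides` razor+unique peptides, and groups with missing ratios.
#' Each removed record is logged under exactly one reason (checked in that
#' order), so the reasons partition the removed set.
#'
#' @param table a [protein_group_table()].
#' @param min_peptides minimum razor+unique peptide count (default 2).
#' @return a filtered [protein_group_table()]; `$log$removed` holds the
#'   removal log, a named list of gene symbols per reason.
#' @export
filter_groups <- function(table, min_peptides = 2L) {
  stopifnot(inherits(table, "protein_group_table"))
  rec <- table$records
  reason <- rep(NA_character_, nrow(rec))
  reason[is.na(reason) & rec$is_contaminant] <- "contaminant"
  reason[is.na(reason) & rec$is_reverse] <- "reverse"
  reason[is.na(reason) & rec$razor_unique_peptides < min_peptides] <-
    "low_peptides"
  reason[is.na(reason) & is.na(rec$ratio_hl)] <- "missing_ratio"
  keep <- is.na(reason)
  out <- table
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$log$removed <- split(rec$gene_symbol[!keep], reason[!keep])
  if (!nrow(out$records)) warnf("no records retained after filtering")
  out
}

#' Heavy fraction of a heavy/light ratio
#'
#' Converts a heavy/light ratio r into the fraction of signal from the
#' heavy channel, h = r / (1 + r). A bijection (0, Inf) -> (0, 1) with
#' inverse r = h / (1 - h); missing ratios stay missing.
#'
#' @param r numeric vector of ratios (> 0 or NA).
#' @return numeric vector of heavy fractions in (0, 1).
#' @examples
#' heavy_fraction(c(1, 3, 0.25))  # 0.5, 0.75, 0.2
#' @export
heavy_fraction <- function(r) {
  if (any(!is.na(r) & r <= 0)) stopf("ratios must be strictly positive")
  r / (1 + r)
}

#' Fraction of a protein attributable to one experimental condition
#'
#' Resolves the label-swap orientation: returns the heavy fraction when the
#' requested condition was heavy-labeled in this mixture, and its
#' complement when it was light-labeled. The fractions of the two
#' conditions always sum to 1.
#'
#' @param r heavy/light ratio(s) (> 0 or NA).
#' @param design a [label_design()].
#' @param condition condition label named in `design`.
#' @return numeric vector of condition fractions in (0, 1).
#' @export
condition_fraction <- function(r, design, condition) {
  stopifnot(inherits(design, "label_design"))
  h <- heavy_fraction(r)
  if (identical(condition, unname(design[["heavy"]]))) {
    h
  } else if (identical(condition, unname(design[["light"]]))) {
    1 - h
  } else {
    stopf("condition '%s' not named in the label design", condition)
  }
}

#' Condition fractions for every record of a table
#'
#' @param table a [protein_group_table()].
#' @param condition condition label named in the table's design.
#' @return named numeric vector (gene symbol -> condition fraction).
#' @export
table_condition_fraction <- function(table, condition) {
  stopifnot(inherits(table, "protein_group_table"))
  stats::setNames(
    condition_fraction(table$records$ratio_hl, table$label_design, condition),
    table$records$gene_symbol)
}

#' Merge a label-swapped pair of mixtures into 2-D coordinates
#'
#' Intersects the gene symbols of two mixtures with opposite label
#' orientations and returns, per protein, the chosen condition's fraction
#' in each mixture: the substrate of the radial and split-tandem analyses.
#' Proteins quantified in only one mixture are excluded and logged.
#'
#' @param table1,table2 filtered [protein_group_table()]s with opposite
#'   label designs for `condition`.
#' @param condition the condition whose fraction becomes the coordinates.
#' @return object of class `swap_pair`: data.frame with columns `protein`,
#'   `x` (fraction in `table1`), `y` (fraction in `table2`); attributes
#'   `condition` and `drop_log`.
#' @export
merge_swap_pair <- function(table1, table2, condition) {
  stopifnot(inherits(table1, "protein_group_table"),
            inherits(table2, "protein_group_table"))
  d1 <- table1$label_design
  d2 <- table2$label_design
  conds <- function(d) unname(c(d[["heavy"]], d[["light"]]))
  if (!condition %in% conds(d1) || !condition %in% conds(d2)) {
    stopf("condition '%s' not present in both label designs", condition)
  }
  if (identical(unname(d1[["heavy"]]), unname(d2[["heavy"]]))) {
    stopf("mixtures have identical label designs; a swapped pair is required")
  }
  f1 <- table_condition_fraction(table1, condition)
  f2 <- table_condition_fraction(table2, condition)
  f1 <- f1[!is.na(f1)]
  f2 <- f2[!is.na(f2)]
  shared <- intersect(names(f1), names(f2))
  out <- data.frame(protein = shared,
                    x = unname(f1[shared]),
                    y = unname(f2[shared]),
                    stringsAsFactors = FALSE)
  structure(out,
            condition = condition,
            drop_log = list(only_mix1 = setdiff(names(f1), shared),
                            only_mix2 = setdiff(names(f2), shared)),
            class = c("swap_pair", "data.frame"))
}

#' Write a protein-group table back to the tab-delimited dialect it came from
#'
#' @param table a [protein_group_table()].
#' @param path output path.
#' @param dialect a [pg_dialect()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path, dialect = pg_dialect()) {
  stopifnot(inherits(table, "protein_group_table"))
  rec <- table$records
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = rec$group_members,
    b = ifelse(is.na(rec$ratio_hl), "", format(rec$ratio_hl, digits = 15)),
    c = rec$razor_unique_peptides,
    d = ifelse(rec$is_contaminant, "+", ""),
    e = ifelse(rec$is_reverse, "+", ""))
  names(out) <- c(dialect$gene, dialect$ratio, dialect$peptides,
                  dialect$contaminant, dialect$reverse)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
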