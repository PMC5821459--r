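test_that("tab-delimited protein-group files parse with flags and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("Gene names", "Ratio H/L", "Razor + unique peptides",
          "Potential contaminant", "Reverse", sep = "\t"),
    "UPF1\t1.0\t5\t\t",
    "MOV10;MOV10L1\t2.0\t4\t\t",
    "KRT1\t\t3\t+\t"), path)
  tab <- read_protein_groups(path, "mix1", label_design("BSA", "RNase"))
  expect_s3_class(tab, "protein_group_table")
  expect_equal(nrow(tab$records), 3L)
  expect_equal(tab$records$ratio_hl, c(1, 2, NA))
  # ambiguous group collapsed to one consistently applied symbol
  expect_equal(tab$records$gene_symbol[2], "MOV10")
  expect_equal(tab$records$group_members[2], "MOV10;MOV10L1")
  expect_true(tab$records$is_contaminant[3])
})

test_that("a missing mapped column is a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Gene names\tRazor + unique peptides", "UPF1\t5"), path)
  expect_error(read_protein_groups(path, "m", label_design("A", "B")),
               "Ratio H/L")
})

test_that("an unparsable ratio is a row-level error with the row index", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("Gene names", "Ratio H/L", "Razor + unique peptides",
          "Potential contaminant", "Reverse", sep = "\t"),
    "UPF1\t1.0\t5\t\t",
    "MOV10\tbogus\t4\t\t"), path)
  expect_error(read_protein_groups(path, "m", label_design("A", "B")),
               "row 2")
})

test_that("duplicate symbols collapse to the best-supported record", {
  rec <- make_records(c("UPF1", "UPF1", "MOV10"), c(1, 2, 3),
                      peptides = c(2L, 6L, 3L))
  tab <- protein_group_table(rec, "m", label_design("A", "B"))
  expect_equal(nrow(tab$records), 2L)
  expect_equal(tab$records$ratio_hl[tab$records$gene_symbol == "UPF1"], 2)
  expect_equal(tab$log$collapsed_duplicates, "UPF1")
})

test_that("filtering applies the contaminant/decoy/peptide/ratio rules", {
  rec <- rbind(
    make_records("CON", 1, contaminant = TRUE),
    make_records("REV", 1, reverse = TRUE),
    make_records("ONEPEP", 1, peptides = 1L),
    make_records(c("A", "B", "C"), c(1, 2, 3)))
  tab <- protein_group_table(rec, "m", label_design("A", "B"))
  kept <- filter_groups(tab)
  expect_equal(kept$records$gene_symbol, c("A", "B", "C"))
  # reasons partition the removed set
  expect_equal(sort(unlist(kept$log$removed, use.names = FALSE)),
               sort(c("CON", "REV", "ONEPEP")))
  expect_equal(kept$log$removed$low_peptides, "ONEPEP")
  # relaxing the peptide floor recovers the one-peptide record
  expect_equal(nrow(filter_groups(tab, min_peptides = 1L)$records), 4L)
  # identity on an already-clean table
  clean <- filter_groups(kept)
  expect_equal(clean$records, kept$records)
})

test_that("missing ratios are removed and logged at filter time", {
  tab <- make_table(c("A", "B"), c(1, NA))
  kept <- filter_groups(tab)
  expect_equal(kept$records$gene_symbol, "A")
  expect_equal(kept$log$removed$missing_ratio, "B")
  expect_warning(filter_groups(make_table("A", NA)), "no records")
})

test_that("heavy_fraction is r/(1+r), preserves NA, rejects r <= 0", {
  expect_equal(heavy_fraction(c(1, 3, 0.25)), c(0.5, 0.75, 0.2))
  expect_true(is.na(heavy_fraction(NA)))
  expect_error(heavy_fraction(0), "positive")
  expect_error(heavy_fraction(-1), "positive")
})

test_that("heavy_fraction is a bijection with inverse h/(1-h)", {
  r <- exp(seq(-8, 8, length.out = 200))
  h <- heavy_fraction(r)
  expect_true(all(diff(h) > 0))
  expect_lt(max(abs(h / (1 - h) - r) / r), 1e-12)
})

test_that("condition fractions resolve the swap and sum to one", {
  d <- label_design(heavy = "BSA", light = "RNase")
  expect_equal(condition_fraction(3, d, "BSA"), 0.75)
  expect_equal(condition_fraction(3, d, "RNase"), 0.25)
  expect_equal(condition_fraction(1, d, "BSA"), 0.5)
  r <- exp(runif(50, -3, 3))
  expect_equal(condition_fraction(r, d, "BSA") +
                 condition_fraction(r, d, "RNase"), rep(1, 50))
  # swapped orientation gives the complement
  dsw <- label_design(heavy = "RNase", light = "BSA")
  expect_equal(condition_fraction(3, d, "BSA") +
                 condition_fraction(3, dsw, "BSA"), 1)
  expect_error(condition_fraction(1, d, "LDS"), "not named")
})

test_that("merging a swapped pair intersects symbols and logs drops", {
  t1 <- make_table(LETTERS[1:10], rep(1, 10),
                   design = label_design("BSA", "RNase"))
  t2 <- make_table(LETTERS[4:13], rep(1, 10),
                   design = label_design("RNase", "BSA"))
  sp <- merge_swap_pair(t1, t2, "BSA")
  expect_equal(nrow(sp), 7L)
  expect_equal(sp$protein, LETTERS[4:10])
  expect_equal(sp$x, rep(0.5, 7))
  expect_equal(sp$y, rep(0.5, 7))
  expect_equal(attr(sp, "drop_log")$only_mix1, LETTERS[1:3])
  expect_equal(attr(sp, "drop_log")$only_mix2, LETTERS[11:13])
  # same orientation is a design error
  expect_error(merge_swap_pair(t1, t1, "BSA"), "identical label designs")
})

test_that("synthetic tables round-trip through write and read", {
  des <- synthetic_design(n_proteins = 40, seed = 3)
  sim <- simulate_swap_experiment(des, "rnase")
  path <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(sim$mix1, path)
  back <- read_protein_groups(path, sim$mix1$sample_id,
                              sim$mix1$label_design)
  expect_equal(back$records$gene_symbol, sim$mix1$records$gene_symbol)
  expect_equal(back$records$ratio_hl, sim$mix1$records$ratio_hl,
               tolerance = 1e-12)
  expect_equal(back$records$is_contaminant, sim$mix1$records$is_contaminant)
})
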