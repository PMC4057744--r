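# synthetic panel generator

test_that("panels are reproducible and structurally sound", {
  p1 <- generate_panel(seed = 42)
  p2 <- generate_panel(seed = 42)
  expect_identical(p1$alignment$seqs, p2$alignment$seqs)
  expect_identical(p1$variants, p2$variants)
  expect_identical(p1$alignment$depth, 20L)
  expect_identical(p1$alignment$length, 60L)
  expect_identical(nrow(p1$variants), 12L)
  expect_true(all(p1$variants$wt != p1$variants$variant))
})

test_that("planted variants live on the intended column types", {
  p <- generate_panel(seed = 42)
  truth <- p$truth
  del <- p$variants[truth$planted$true_label == "D", ]
  neu <- p$variants[truth$planted$true_label == "N", ]
  expect_true(all(del$position %in% truth$conserved_columns))
  expect_true(all(neu$position %in% truth$variable_columns))
  # substitution severity straddles the pairwise median by construction
  expect_true(all(grantham_score(del$wt, del$variant) > truth$gs_median))
  expect_true(all(grantham_score(neu$wt, neu$variant) < truth$gs_median))
  # the stated wild-types match the reference sequence
  expect_silent(gmetric:::validate_wildtypes(p$variants, p$alignment,
                                             strict = TRUE))
})

test_that("fully conserved noiseless panels hit the repeated-string ratio", {
  p <- generate_panel(synth_config(fraction_conserved = 1, noise = 0,
                                   n_neutral = 0, n_deleterious = 3),
                      seed = 8)
  single_ratio <- compression_ratio(strrep("A", 20))
  for (j in seq_len(p$alignment$length)) {
    col <- gmetric:::column_residues(p$alignment, j - 1L)
    expect_identical(length(unique(col)), 1L)
    expect_equal(compression_ratio(column_string(col)), single_ratio)
  }
})

test_that("a 20-distinct-residue column sorts to the full alphabet string", {
  aln <- gm_alignment(setNames(rownames(aa_properties),
                               paste0("s", 1:20)))
  expect_identical(column_string(gmetric:::column_residues(aln, 0L)),
                   "ACDEFGHIKLMNPQRSTVWY")
})

test_that("conserved columns compress better than variable ones", {
  p <- generate_panel(synth_config(noise = 0.05), seed = 15)
  ratio_of <- function(cols) vapply(cols, function(j)
    compression_ratio(column_string(
      gmetric:::column_residues(p$alignment, j - 1L))), numeric(1))
  expect_lt(mean(ratio_of(p$truth$conserved_columns)),
            mean(ratio_of(p$truth$variable_columns)))
})

test_that("infeasible variant counts are rejected", {
  cfg <- synth_config(length = 10, fraction_conserved = 0.2,
                      n_deleterious = 6)
  expect_error(generate_panel(cfg, seed = 1), "infeasible")
  expect_error(synth_config(noise = 2), "noise")
})

test_that("label noise degrades cross-validated accuracy monotonically", {
  mean_mcc <- function(mislabel, seeds) {
    mean(vapply(seeds, function(s) {
      p <- generate_panel(synth_config(mislabel = mislabel), seed = s)
      evaluation_report(loo_cv(list(G = p), control = test_control(),
                               seed = 50 + s))$mcc
    }, numeric(1)))
  }
  seeds <- 1:3
  expect_gte(mean_mcc(0, seeds), mean_mcc(0.25, seeds))
})

test_that("the calibration strings are the five canonical references", {
  s <- calibration_strings()
  expect_identical(length(s), 5L)
  expect_identical(s[1], "ACDEFGHIKLMNPQRSTVWY")
  expect_identical(s[3], "HHHQQQQQQQRRRRRRRRRR")
  expect_identical(s[5], strrep("A", 20))
  # every string is already in canonical sorted form
  for (x in s)
    expect_identical(column_string(strsplit(x, "")[[1]]), x)
})
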