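# Grantham property space: score, variance, deviation

# independent copy of the 1974 property values and coefficients, used to
# recompute expected distances without going through the package's code
ref_prop <- matrix(c(
  # c, p, v
  1.42, 9.2, 32,    # S
  0.65, 10.5, 124,  # R
  0.00, 4.9, 111,   # L
  0.39, 8.0, 32.5,  # P
  0.71, 8.6, 61,    # T
  0.00, 8.1, 31,    # A
  0.00, 5.9, 84,    # V
  0.74, 9.0, 3,     # G
  0.00, 5.2, 111,   # I
  0.00, 5.2, 132,   # F
  0.20, 6.2, 136,   # Y
  2.75, 5.5, 55,    # C
  0.58, 10.4, 96,   # H
  0.89, 10.5, 85,   # Q
  1.33, 11.6, 56,   # N
  0.33, 11.3, 119,  # K
  1.38, 13.0, 54,   # D
  0.92, 12.3, 83,   # E
  0.00, 5.7, 105,   # M
  0.13, 5.4, 170    # W
), ncol = 3, byrow = TRUE,
dimnames = list(c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F", "Y",
                  "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
                c("c", "p", "v")))

ref_gs <- function(w, v) {
  d <- ref_prop[w, ] - ref_prop[v, ]
  sqrt(1.833 * d["c"]^2 + 0.1018 * d["p"]^2 + 0.000399 * d["v"]^2)
}

# widely reproduced integer distances from the published 1974 matrix
published_anchors <- c(
  "L/I" = 5, "L/M" = 15, "I/F" = 21, "F/Y" = 22, "N/D" = 23, "H/Q" = 24,
  "R/K" = 26, "P/A" = 27, "Q/E" = 29, "V/I" = 29, "H/K" = 32, "Y/W" = 37,
  "P/T" = 38, "S/N" = 46, "D/E" = 45, "A/V" = 64, "M/W" = 67, "R/L" = 102,
  "S/R" = 110, "G/W" = 184, "C/F" = 205, "C/W" = 215
)

test_that("scaled scores reproduce the published Grantham distances", {
  for (pair in names(published_anchors)) {
    wv <- strsplit(pair, "/")[[1]]
    expect_lte(abs(grantham_scale * grantham_score(wv[1], wv[2]) -
                     published_anchors[[pair]]), 1,
               label = paste("anchor", pair))
  }
  # full 190-pair sweep against the independent recomputation
  pairs <- combn(rownames(ref_prop), 2)
  for (i in seq_len(ncol(pairs))) {
    w <- pairs[1, i]; v <- pairs[2, i]
    expect_lte(abs(grantham_scale * grantham_score(w, v) -
                     round(grantham_scale * ref_gs(w, v))), 1,
               label = paste(w, v))
  }
  # the 50.723 scaling makes the mean pairwise distance ~100
  all_gs <- grantham_score(pairs[1, ], pairs[2, ])
  expect_equal(mean(grantham_scale * all_gs), 100, tolerance = 0.01)
})

test_that("the score is symmetric and zero only for identical residues", {
  pairs <- combn(rownames(ref_prop), 2)
  expect_equal(grantham_score(pairs[1, ], pairs[2, ]),
               grantham_score(pairs[2, ], pairs[1, ]))
  expect_true(all(grantham_score(pairs[1, ], pairs[2, ]) > 0))
  expect_identical(grantham_score("L", "L"), 0)
})

test_that("unknown and ambiguity codes are rejected by name", {
  expect_error(grantham_score("B", "A"), "B")
  expect_error(grantham_score("A", "X"), "X")
  expect_error(grantham_variance(c("A", "Z")), "Z")
  expect_error(grantham_variance(character(0)), "empty")
  expect_error(grantham_deviation("U", c("A", "C")), "U")
})

test_that("variance of a two-residue set equals the pair score", {
  pairs <- combn(rownames(ref_prop), 2)
  for (i in seq_len(ncol(pairs))) {
    expect_equal(grantham_variance(pairs[, i]),
                 grantham_score(pairs[1, i], pairs[2, i]),
                 tolerance = 1e-12, label = paste(pairs[, i], collapse = ""))
  }
})

test_that("variance matches brute-force per-dimension maxima", {
  brute_gv <- function(res) {
    best <- c(c = 0, p = 0, v = 0)
    for (x in res) for (y in res) for (d in c("c", "p", "v"))
      best[d] <- max(best[d], (ref_prop[x, d] - ref_prop[y, d])^2)
    sqrt(1.833 * best["c"] + 0.1018 * best["p"] + 0.000399 * best["v"])
  }
  expect_equal(grantham_variance(c("L", "I", "V", "M")),
               unname(brute_gv(c("L", "I", "V", "M"))), tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:10) {
    res <- random_residues(sample(2:8, 1))
    expect_equal(grantham_variance(res), unname(brute_gv(res)),
                 tolerance = 1e-12)
  }
})

test_that("variance is duplication-invariant, order-invariant and monotone", {
  set.seed(23)
  for (rep in 1:20) {
    res <- random_residues(sample(1:6, 1))
    gv <- grantham_variance(res)
    expect_equal(grantham_variance(rep(res, 3)), gv)
    expect_equal(grantham_variance(sample(res)), gv)
    extra <- random_residues(1)
    expect_gte(grantham_variance(c(res, extra)), gv)
  }
  expect_identical(grantham_variance(rep("A", 7)), 0)
})

test_that("deviation is zero inside the prism and matches the clamped oracle", {
  brute_gd <- function(v, res) {
    dev <- vapply(c("c", "p", "v"), function(d) {
      x <- ref_prop[v, d]
      max(0, min(ref_prop[res, d]) - x, x - max(ref_prop[res, d]))
    }, numeric(1))
    sqrt(1.833 * dev["c"]^2 + 0.1018 * dev["p"]^2 + 0.000399 * dev["v"]^2)
  }
  expect_identical(grantham_deviation("L", c("L", "I")), 0)
  expect_identical(grantham_deviation("T", c("S", "R", "T")), 0)
  gd <- grantham_deviation("W", c("L", "I"))
  expect_gt(gd, 0)
  expect_equal(gd, unname(brute_gd("W", c("L", "I"))), tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:15) {
    res <- random_residues(sample(2:6, 1))
    v <- random_residues(1)
    expect_equal(grantham_deviation(v, res), unname(brute_gd(v, res)),
                 tolerance = 1e-12)
  }
})

test_that("deviation shrinks to zero as the residue set grows", {
  # progressive loss of sensitivity with alignment depth: once the prism
  # covers the candidate, the deviation stays at zero
  nested <- c("A", "G", "S", "C", "D", "W", "R")
  v <- "K"
  gds <- vapply(2:length(nested), function(n)
    grantham_deviation(v, nested[1:n]), numeric(1))
  expect_true(all(diff(gds) <= 1e-12))
  expect_identical(grantham_deviation(v, rownames(ref_prop)), 0)
})

test_that("gene multipliers rescale the coefficients directly", {
  w <- grantham_weights(c_mult = 2, p_mult = 0.5, v_mult = 0)
  expect_equal(w$alpha, 2 * 1.833)
  expect_equal(w$beta, 0.5 * 0.1018)
  expect_identical(w$gamma, 0)
  expect_error(grantham_weights(c_mult = -1), "non-negative")
  # zero volume weight removes the volume axis from the score
  expect_equal(grantham_score("A", "G", w),
               sqrt(2 * 1.833 * 0.74^2 + 0.5 * 0.1018 * 0.9^2))
})
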