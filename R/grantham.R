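# Amino-acid property space and the three Grantham geometric measures.
#
# Property values are Grantham's (Science 185:862-864, 1974, Table 1):
# composition c (atomic weight ratio of hetero elements in side chain),
# polarity p, and molecular volume v. The 1974 normalisation coefficients
# alpha, beta, gamma rescale each squared-difference axis so that the mean
# pairwise distance per axis is comparable; Grantham's further x50.723
# scaling (making the mean pairwise distance 100) is deliberately not
# applied here -- it is linear and irrelevant to clustering -- but is
# exposed as `grantham_scale` for comparison against the published
# integer distance table.

#' Amino-acid property table (Grantham 1974)
#'
#' Composition (`c`), polarity (`p`) and molecular volume (`v`) for the 20
#' canonical amino acids, keyed by 1-letter code. These are the axes of the
#' property space in which all Grantham measures are Euclidean distances.
#'
#' @format A data frame with 20 rows and columns `c`, `p`, `v`; row names are
#'   1-letter amino-acid codes.
#' @export
aa_properties <- local({
  tab <- data.frame(
    c = c(S = 1.42, R = 0.65, L = 0.00, P = 0.39, T = 0.71,
          A = 0.00, V = 0.00, G = 0.74, I = 0.00, F = 0.00,
          Y = 0.20, C = 2.75, H = 0.58, Q = 0.89, N = 1.33,
          K = 0.33, D = 1.38, E = 0.92, M = 0.00, W = 0.13),
    p = c(S = 9.2, R = 10.5, L = 4.9, P = 8.0, T = 8.6,
          A = 8.1, V = 5.9, G = 9.0, I = 5.2, F = 5.2,
          Y = 6.2, C = 5.5, H = 10.4, Q = 10.5, N = 11.6,
          K = 11.3, D = 13.0, E = 12.3, M = 5.7, W = 5.4),
    v = c(S = 32, R = 124, L = 111, P = 32.5, T = 61,
          A = 31, V = 84, G = 3, I = 111, F = 132,
          Y = 136, C = 55, H = 96, Q = 85, N = 56,
          K = 119, D = 54, E = 83, M = 105, W = 170)
  )
  stopifnot(nrow(tab) == 20L, all(is.finite(as.matrix(tab))))
  tab
})

# base normalisation coefficients (fixed; gene multipliers act on top)
GRANTHAM_ALPHA <- 1.833
GRANTHAM_BETA  <- 0.1018
GRANTHAM_GAMMA <- 0.000399

#' Grantham's published scaling constant
#'
#' Multiplying an unweighted Grantham score by this constant and rounding
#' reproduces the integer distances of the 1974 paper (mean pairwise
#' distance 100). The package works on the unscaled values.
#' @export
grantham_scale <- 50.723

AA_ALPHABET <- rownames(aa_properties)

#' Gene-specific Grantham weights
#'
#' The base coefficients alpha = 1.833, beta = 0.1018, gamma = 0.000399
#' normalise the composition, polarity and volume axes. Per-gene
#' multipliers `c_mult`, `p_mult`, `v_mult` (all >= 0, default 1) rescale
#' an individual gene's sensitivity to each property; the effective
#' coefficients are `alpha' = c_mult * alpha` etc.
#'
#' @param c_mult,p_mult,v_mult Non-negative gene multipliers.
#' @return An object of class `grantham_weights`: a list with elements
#'   `alpha`, `beta`, `gamma` (effective coefficients) and the multipliers.
#' @examples
#' grantham_weights()               # Grantham's original scales
#' grantham_weights(c_mult = 2)     # doubled composition sensitivity
#' @export
grantham_weights <- function(c_mult = 1, p_mult = 1, v_mult = 1) {
  m <- c(c_mult, p_mult, v_mult)
  if (!is.numeric(m) || length(m) != 3L || anyNA(m) || any(m < 0))
    stop("gene multipliers c_mult, p_mult, v_mult must be non-negative numbers",
         call. = FALSE)
  structure(
    list(alpha = c_mult * GRANTHAM_ALPHA,
         beta  = p_mult * GRANTHAM_BETA,
         gamma = v_mult * GRANTHAM_GAMMA,
         c_mult = c_mult, p_mult = p_mult, v_mult = v_mult),
    class = "grantham_weights"
  )
}

#' @export
print.grantham_weights <- function(x, ...) {
  cat("Grantham weights: alpha' =", format(x$alpha),
      " beta' =", format(x$beta),
      " gamma' =", format(x$gamma), "\n")
  invisible(x)
}

# validate residue codes against the 20-AA alphabet; names the offender
check_residues <- function(x, what = "residue") {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), AA_ALPHABET)
  if (length(x) == 0L)
    stop("empty ", what, " set", call. = FALSE)
  if (length(bad))
    stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "),
         " (only the 20 canonical 1-letter amino-acid codes are accepted)",
         call. = FALSE)
  x
}

# per-dimension squared differences between two residues (c, p, v order)
sq_diffs <- function(w, v) {
  pw <- aa_properties[w, ]
  pv <- aa_properties[v, ]
  c(c = (pw$c - pv$c)^2, p = (pw$p - pv$p)^2, v = (pw$v - pv$v)^2)
}

# per-dimension max squared difference over all residue pairs in a set:
# the squared side lengths of the bounding prism
prism_sides <- function(residues) {
  p <- aa_properties[residues, , drop = FALSE]
  c(c = diff(range(p$c))^2, p = diff(range(p$p))^2, v = diff(range(p$v))^2)
}

#' Grantham score (GS)
#'
#' Weighted Euclidean distance between two amino acids in
#' composition/polarity/volume space:
#' \deqn{GS = \sqrt{\alpha'(W_c-V_c)^2 + \beta'(W_p-V_p)^2 + \gamma'(W_v-V_v)^2}}
#' Larger scores mean a biochemically more radical substitution. Vectorised
#' over pairs (`w` and `v` are recycled to a common length).
#'
#' @param w,v 1-letter codes of the wild-type and variant amino acids.
#' @param weights A [grantham_weights()] object.
#' @return Non-negative numeric vector; symmetric in `w` and `v`.
#' @examples
#' grantham_score("L", "I")                      # conservative swap
#' round(grantham_scale * grantham_score("S", "R"))  # published scaled distance
#' @export
grantham_score <- function(w, v, weights = grantham_weights()) {
  w <- check_residues(w, "wild-type")
  v <- check_residues(v, "variant")
  n <- max(length(w), length(v))
  w <- rep_len(w, n); v <- rep_len(v, n)
  dc <- (aa_properties[w, "c"] - aa_properties[v, "c"])^2
  dp <- (aa_properties[w, "p"] - aa_properties[v, "p"])^2
  dv <- (aa_properties[w, "v"] - aa_properties[v, "v"])^2
  sqrt(weights$alpha * dc + weights$beta * dp + weights$gamma * dv)
}

#' Grantham variance (GV)
#'
#' Diversity of a set of amino acids (typically one alignment column): the
#' length of the longest diagonal of the smallest axis-aligned rectangular
#' prism in property space enclosing all residues,
#' \deqn{GV = \sqrt{\alpha'|c| + \beta'|p| + \gamma'|v|}}
#' with \eqn{|d| = \max_{X,Y \in A}(X_d - Y_d)^2} per dimension. Zero for a
#' single residue or identical copies; equal to [grantham_score()] when the
#' set holds exactly two distinct residues. Non-decreasing as residues are
#' added (duplicates have no effect).
#'
#' @param residues Character vector of 1-letter codes drawn from one
#'   alignment column (duplicates allowed and ignored geometrically).
#' @inheritParams grantham_score
#' @return Non-negative scalar.
#' @examples
#' grantham_variance(c("L", "I"))                # == grantham_score("L","I")
#' grantham_variance(c("L", "I", "V", "M"))
#' @export
grantham_variance <- function(residues, weights = grantham_weights()) {
  residues <- check_residues(residues, "column residue")
  s <- prism_sides(residues)
  sqrt(weights$alpha * s[["c"]] + weights$beta * s[["p"]] + weights$gamma * s[["v"]])
}

#' Grantham deviation (GD)
#'
#' Shortest weighted Euclidean distance from a candidate amino acid to the
#' bounding prism of a residue set; zero when the candidate lies inside or
#' on the prism. This is the depth-sensitive quantity whose collapse to
#' zero in deep alignments motivates the compression adjustment: once the
#' prism covers the whole property space every candidate scores 0.
#'
#' @param v 1-letter code of the candidate amino acid.
#' @param residues Character vector of 1-letter codes (the set A).
#' @inheritParams grantham_score
#' @return Non-negative scalar; 0 iff `v` is within the prism of `residues`.
#' @export
grantham_deviation <- function(v, residues, weights = grantham_weights()) {
  v <- check_residues(v, "candidate")
  if (length(v) != 1L) stop("`v` must be a single residue", call. = FALSE)
  residues <- check_residues(residues, "column residue")
  p <- aa_properties[residues, , drop = FALSE]
  pv <- aa_properties[v, ]
  dev1 <- function(x, lo, hi) max(0, lo - x, x - hi)
  dc <- dev1(pv$c, min(p$c), max(p$c))
  dp <- dev1(pv$p, min(p$p), max(p$p))
  dv <- dev1(pv$v, min(p$v), max(p$v))
  sqrt(weights$alpha * dc^2 + weights$beta * dp^2 + weights$gamma * dv^2)
}
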