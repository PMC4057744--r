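# Per-variant feature extraction.
#
# Training and scoring both consume, per variant, the components from which
# GS, GV and GV' are rebuilt under any candidate parameter vector: the
# squared property differences between wild-type and variant (GS axes), the
# squared side lengths of the column's bounding prism (GV axes), and the
# column's compression ratio. Extracting them once makes the swarm
# objective a cheap closed-form recomputation.

#' Extract scoring features for variants against an alignment
#'
#' For each variant: maps its protein position to the alignment column,
#' builds the column's sorted residue string (gaps and non-canonical codes
#' dropped), and records the per-dimension squared differences (wild-type
#' vs variant), the per-dimension squared prism sides of the column residue
#' set, and the column's DEFLATE compression ratio.
#'
#' @param alignment A [gm_alignment()] object.
#' @param variants Data frame as from [read_variants()].
#' @return Data frame: the variant columns plus `dc2`, `dp2`, `dv2` (GS
#'   axes), `rc`, `rp`, `rv` (GV axes), `ratio`, `depth` (filtered column
#'   depth).
#' @export
variant_features <- function(alignment, variants) {
  n <- nrow(variants)
  feat <- data.frame(
    dc2 = numeric(n), dp2 = numeric(n), dv2 = numeric(n),
    rc = numeric(n), rp = numeric(n), rv = numeric(n),
    ratio = numeric(n), depth = integer(n)
  )
  for (i in seq_len(n)) {
    col <- map_position(alignment, variants$position[i])
    res <- column_residues(alignment, col)
    s <- column_string(res, column = col)
    res <- strsplit(s, "")[[1L]]
    d <- sq_diffs(variants$wt[i], variants$variant[i])
    p <- prism_sides(res)
    feat$dc2[i] <- d[["c"]]; feat$dp2[i] <- d[["p"]]; feat$dv2[i] <- d[["v"]]
    feat$rc[i] <- p[["c"]]; feat$rp[i] <- p[["p"]]; feat$rv[i] <- p[["v"]]
    feat$ratio[i] <- compression_ratio(s)
    feat$depth[i] <- nchar(s)
  }
  cbind(variants, feat)
}

# rebuild GS, GV, GV', GM from features under a parameter list
# params: list(k, r, c_mult, p_mult, v_mult)
compute_metrics <- function(features, params) {
  a <- params$c_mult * GRANTHAM_ALPHA
  b <- params$p_mult * GRANTHAM_BETA
  g <- params$v_mult * GRANTHAM_GAMMA
  gs <- sqrt(a * features$dc2 + b * features$dp2 + g * features$dv2)
  gv <- sqrt(a * features$rc + b * features$rp + g * features$rv)
  gv_adj <- adjusted_variance(gv, features$ratio, params$r)
  gm <- grantham_metric(gs, gv_adj, params$k)
  data.frame(gs = gs, gv = gv, ratio = features$ratio,
             gv_adj = gv_adj, gm = gm)
}

#' Cluster-separation objective for a parameter vector
#'
#' Recomputes GV' and GM for every training variant under the candidate
#' parameters and returns the cluster-separation index between the
#' deleterious and neutral metric sets. Deterministic for fixed inputs;
#' this is the function the swarm maximises.
#'
#' @param params List with elements `k`, `r`, `c_mult`, `p_mult`, `v_mult`.
#' @param features Feature data frame from [variant_features()] with a
#'   `label` column containing at least 2 `"D"` and 2 `"N"` rows.
#' @return The cluster index (possibly `Inf` for perfect separation).
#' @export
objective_index <- function(params, features) {
  m <- compute_metrics(features, params)
  cluster_index(m$gm[features$label == "D"], m$gm[features$label == "N"])
}
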