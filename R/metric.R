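# The Grantham Metric and its clustering machinery.
#
# GM = GS * k^(-GV') fuses substitution severity (GS) with evolutionary
# constraint (GV', the compression-adjusted column diversity) through a
# gene-specific attenuation constant k >= 1. A fully constrained position
# (GV' = 0) leaves GS untouched; unconstrained positions drive GM to zero.
# Known deleterious and neutral variants of a gene form two clusters of GM
# values; their separation (a Davies-Bouldin-style index) is the training
# objective, and half the distance between the cluster means is the binary
# cut-off.

#' Grantham Metric (GM)
#'
#' Pathogenicity metric \eqn{GM = GS \cdot k^{-GV'}}. Monotone increasing in
#' GS, monotone decreasing in GV'; equals GS when GV' = 0; tends to 0 as
#' GV' grows (for k > 1). Vectorised over `gs` and `gv_adj`.
#'
#' @param gs Non-negative Grantham score(s).
#' @param gv_adj Non-negative compression-adjusted Grantham variance(s).
#' @param k Gene-specific attenuation constant, `k >= 1`.
#' @return Non-negative numeric vector.
#' @examples
#' grantham_metric(1.7, 0, k = 3)   # constrained position: GS unchanged
#' grantham_metric(2, 1, k = 4)     # 0.5
#' @export
grantham_metric <- function(gs, gv_adj, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop("`k` must be a single number >= 1", call. = FALSE)
  if (any(gv_adj < 0)) stop("GV' must be non-negative", call. = FALSE)
  gs * k^(-gv_adj)
}

#' Cluster-separation index
#'
#' One-dimensional two-cluster distinction index
#' \deqn{R = \frac{|\bar{x}_D - \bar{x}_N|}{s_D + s_N}}
#' (sample means and sample standard deviations). R grows when the cluster
#' means separate at fixed dispersion and shrinks when either dispersion
#' grows at fixed means — the training objective for the gene model.
#'
#' @param x_d,x_n Numeric vectors of metrics for the deleterious and
#'   neutral sets; each needs at least 2 values for a meaningful standard
#'   deviation.
#' @return Non-negative scalar. If both standard deviations are zero with
#'   distinct means, `Inf` is returned (perfect separation sentinel); with
#'   equal means and zero dispersion the index is 0.
#' @examples
#' cluster_index(c(1, 2, 3), c(10, 11, 12))  # 4.5
#' @export
cluster_index <- function(x_d, x_n) {
  if (length(x_d) < 2L || length(x_n) < 2L)
    stop("need at least 2 metric values per class to compute dispersions",
         call. = FALSE)
  sep <- abs(mean(x_d) - mean(x_n))
  disp <- stats::sd(x_d) + stats::sd(x_n)
  if (disp == 0) {
    if (sep == 0) return(0)
    return(Inf)
  }
  sep / disp
}

#' Binary classification cut-off
#'
#' Half the distance between the class mean metrics,
#' \eqn{C = |\bar{x}_D - \bar{x}_N| / 2}. Variants with GM above C are
#' called deleterious. A zero cut-off (equal means) degenerates the model
#' and disables normalised scoring.
#'
#' @param mean_d,mean_n Class mean metrics.
#' @return Non-negative scalar.
#' @export
cutoff <- function(mean_d, mean_n) {
  abs(mean_d - mean_n) / 2
}

#' Binary classification against a cut-off
#'
#' `GM > C` calls deleterious, `GM < C` neutral. The boundary `GM = C` is
#' called deleterious: in triage a false positive is preferable to a missed
#' pathogenic variant.
#'
#' @param gm Positive metric value(s).
#' @param cutoff Positive cut-off C.
#' @return Character vector of `"D"`/`"N"`.
#' @export
classify_binary <- function(gm, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0)
    stop("degenerate model: cut-off must be a single positive number",
         call. = FALSE)
  ifelse(gm >= cutoff, "D", "N")
}

#' Classification by cluster-index maximisation
#'
#' Assigns a candidate metric to the class (deleterious or neutral) whose
#' tentative adoption of the candidate yields the larger recomputed
#' cluster-separation index. This is the first-principles rule from which
#' the cut-off C derives; it is exposed so agreement between the two can be
#' measured. Ties go to deleterious, consistent with [classify_binary()].
#'
#' @param gm Candidate metric value (scalar).
#' @param x_d,x_n Training metrics of the two classes (>= 2 each).
#' @return `"D"` or `"N"`.
#' @export
classify_by_index <- function(gm, x_d, x_n) {
  if (!is.numeric(gm) || length(gm) != 1L || is.na(gm))
    stop("`gm` must be a single metric value", call. = FALSE)
  r_d <- cluster_index(c(x_d, gm), x_n)
  r_n <- cluster_index(x_d, c(x_n, gm))
  if (r_d >= r_n) "D" else "N"
}

#' Gene-normalised score
#'
#' \eqn{\ln(GM / C)}: positive exactly when the binary rule calls
#' deleterious, zero at the cut-off, and comparable across genes (raw GM
#' values are not, because C is gene-specific). Undefined for `GM = 0`
#' (possible only through rounding, since non-synonymous substitutions have
#' GS > 0); such values must be excluded.
#'
#' @param gm Positive metric value(s).
#' @param cutoff Positive cut-off C.
#' @return Numeric vector of normalised scores.
#' @export
normalised_score <- function(gm, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0)
    stop("normalised scoring requires a positive cut-off", call. = FALSE)
  if (any(!is.finite(gm)) || any(gm <= 0))
    stop("GM = 0 (or negative) values are excluded from normalised scoring",
         call. = FALSE)
  log(gm / cutoff)
}
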