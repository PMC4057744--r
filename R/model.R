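# The trained gene model: an S3 class with the usual modelling verbs.

#' Construct a gene model
#'
#' Low-level constructor; [gm_train()] is the user-facing fitting function.
#' Derived quantities are recomputed from the class means and standard
#' deviations: cluster index `R = |mean_D - mean_N| / (sd_D + sd_N)`,
#' cut-off `C = |mean_D - mean_N| / 2`, and the orientation flag
#' `mean_D > mean_N` (classification only expresses pathogenicity when the
#' deleterious cluster sits above the neutral one).
#'
#' @param params List with `k`, `r`, `c_mult`, `p_mult`, `v_mult`.
#' @param mean_d,mean_n,sd_d,sd_n Class metric means and sample SDs.
#' @param gene Gene identifier.
#' @param n_deleterious,n_neutral Training set sizes.
#' @return An object of class `gm_model`.
#' @export
new_gm_model <- function(params, mean_d, mean_n, sd_d, sd_n,
                         gene = NA_character_,
                         n_deleterious = NA_integer_,
                         n_neutral = NA_integer_) {
  stopifnot(sd_d >= 0, sd_n >= 0, params$k >= 1,
            params$c_mult >= 0, params$p_mult >= 0, params$v_mult >= 0)
  disp <- sd_d + sd_n
  structure(list(
    gene = gene,
    params = params[c("k", "r", "c_mult", "p_mult", "v_mult")],
    mean_d = mean_d, mean_n = mean_n, sd_d = sd_d, sd_n = sd_n,
    r_index = if (disp > 0) abs(mean_d - mean_n) / disp
              else if (mean_d == mean_n) 0 else Inf,
    cutoff = cutoff(mean_d, mean_n),
    valid_orientation = mean_d > mean_n,
    n_deleterious = n_deleterious, n_neutral = n_neutral
  ), class = "gm_model")
}

#' @export
print.gm_model <- function(x, digits = 4, ...) {
  cat("Grantham-metric gene model",
      if (!is.na(x$gene)) paste0("for ", x$gene), "\n")
  cat("  parameters: k =", format(x$params$k, digits = digits),
      " r =", format(x$params$r, digits = digits),
      " multipliers (c,p,v) =",
      paste(format(unlist(x$params[c("c_mult", "p_mult", "v_mult")]),
                   digits = digits), collapse = ", "), "\n")
  cat("  clusters: mean_D =", format(x$mean_d, digits = digits),
      "(sd", paste0(format(x$sd_d, digits = digits), ");"),
      "mean_N =", format(x$mean_n, digits = digits),
      "(sd", paste0(format(x$sd_n, digits = digits), ")"), "\n")
  cat("  cluster index R =", format(x$r_index, digits = digits),
      " cut-off C =", format(x$cutoff, digits = digits), "\n")
  if (!x$valid_orientation)
    cat("  WARNING: invalid orientation (mean_D <= mean_N);",
        "classification disabled\n")
  invisible(x)
}

#' @export
coef.gm_model <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.gm_model <- function(object, ...) {
  out <- object
  if (!is.null(object$training)) {
    out$training_summary <- do.call(rbind, lapply(split(
      object$training$gm, object$training$label),
      function(v) c(n = length(v), min = min(v), median = stats::median(v),
                    max = max(v))))
  }
  class(out) <- c("summary.gm_model", "gm_model")
  out
}

#' @export
print.summary.gm_model <- function(x, ...) {
  NextMethod()
  if (!is.null(x$training_summary)) {
    cat("  training metric spread:\n")
    print(round(x$training_summary, 4))
  }
  if (!is.null(x$objective))
    cat("  swarm: objective =", format(x$objective, digits = 4),
        "after", length(x$trace), "iterations\n")
  invisible(x)
}

#' Score and classify variants with a trained gene model
#'
#' Recomputes GS, GV, the compression ratio, GV' and GM for each variant
#' under the model's parameters, then applies the binary cut-off rule
#' (GM >= C calls deleterious) and the gene-normalised score ln(GM/C).
#' When class densities and a prior are supplied, a posterior probability
#' of deleterious classification is appended.
#'
#' @param object A `gm_model`.
#' @param alignment A [gm_alignment()] for the model's gene.
#' @param variants Data frame of variants to score ([read_variants()]).
#' @param densities Optional [fit_class_densities()] pair.
#' @param prior Prior probability of deleterious class (required with
#'   `densities`).
#' @param ... Unused.
#' @return Data frame: the variant columns plus `gs`, `gv`, `ratio`,
#'   `gv_adj`, `gm`, `score`, `pred` (and `posterior` when densities are
#'   given).
#' @export
predict.gm_model <- function(object, alignment, variants, densities = NULL,
                             prior = NULL, ...) {
  if (!object$valid_orientation)
    stop("model orientation invalid (mean_D <= mean_N): ",
         "refusing to classify", call. = FALSE)
  if (object$cutoff <= 0)
    stop("degenerate model: cut-off is zero", call. = FALSE)
  features <- variant_features(alignment, variants)
  m <- compute_metrics(features, object$params)
  out <- cbind(variants, m)
  out$score <- ifelse(m$gm > 0, log(m$gm / object$cutoff), NA_real_)
  out$pred <- classify_binary(m$gm, object$cutoff)
  if (!is.null(densities)) {
    if (is.null(prior))
      stop("posterior scoring requires an explicit `prior`", call. = FALSE)
    out$posterior <- vapply(out$score, function(x)
      if (is.na(x)) NA_real_ else posterior_deleterious(x, densities, prior),
      numeric(1))
  }
  out
}

#' Plot a trained gene model
#'
#' Strip chart of the training metrics by class on a log axis, with the
#' class means and the cut-off C marked. A well-trained model shows the
#' deleterious cluster above the neutral one with C between them.
#'
#' @param x A `gm_model` fitted by [gm_train()] (needs stored training
#'   metrics).
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.gm_model <- function(x, ...) {
  if (is.null(x$training))
    stop("model carries no training metrics to plot", call. = FALSE)
  gm <- x$training$gm
  lab <- factor(x$training$label, levels = c("N", "D"))
  graphics::stripchart(gm ~ lab, vertical = TRUE, method = "jitter",
                       pch = 19, col = c("steelblue", "firebrick"),
                       ylab = "Grantham metric (GM)",
                       main = paste("Gene model", x$gene), ...)
  graphics::abline(h = x$cutoff, lty = 2)
  graphics::segments(c(0.8, 1.8), c(x$mean_n, x$mean_d),
                     c(1.2, 2.2), c(x$mean_n, x$mean_d), lwd = 2)
  invisible(x)
}
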