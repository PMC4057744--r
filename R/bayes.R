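# Continuous classification: posterior probability of the deleterious
# class from the gene-normalised score.
#
# Given class-conditional densities f_D and f_N over x = ln(GM/C) and a
# prior Pr(D), Bayes' rule gives
#
#   Pr(D | x) = f_D(x) Pr(D) / (f_D(x) Pr(D) + f_N(x) (1 - Pr(D)))
#
# The densities are pluggable: any pair of vectorisable density functions
# can be supplied, so richer asymmetric families can replace the default
# normal fits externally.

#' Posterior probability of deleterious classification
#'
#' @param x Normalised score(s) `ln(GM/C)` at which to evaluate.
#' @param densities A density pair from [fit_class_densities()] or
#'   [class_densities()].
#' @param prior Prior probability that the variant is deleterious, in
#'   `[0, 1]`.
#' @return Posterior probabilities in `[0, 1]`. Where both densities are
#'   zero the posterior is undefined and `NA` is returned.
#' @examples
#' d <- class_densities(function(x) dnorm(x, 1), function(x) dnorm(x, -1))
#' posterior_deleterious(0, d, prior = 0.5)   # 0.5 by symmetry
#' @export
posterior_deleterious <- function(x, densities, prior) {
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) ||
      prior < 0 || prior > 1)
    stop("`prior` must be a single probability in [0, 1]", call. = FALSE)
  fd <- densities$f_d(x)
  fn <- densities$f_n(x)
  if (any(fd < 0) || any(fn < 0))
    stop("class densities must be non-negative", call. = FALSE)
  num <- fd * prior
  den <- num + fn * (1 - prior)
  ifelse(den == 0, NA_real_, num / den)
}

#' Bundle a pair of class-conditional densities
#'
#' @param f_d,f_n Vectorisable density functions for the deleterious and
#'   neutral normalised scores.
#' @param provenance Short tag recording where the densities came from.
#' @return A list of class `gm_densities`.
#' @export
class_densities <- function(f_d, f_n, provenance = "user-supplied") {
  stopifnot(is.function(f_d), is.function(f_n))
  structure(list(f_d = f_d, f_n = f_n, provenance = provenance),
            class = "gm_densities")
}

#' @export
print.gm_densities <- function(x, ...) {
  cat("Class-conditional score densities (", x$provenance, ")\n", sep = "")
  if (!is.null(x$pars)) print(x$pars)
  invisible(x)
}

#' Fit default (normal) class densities to normalised scores
#'
#' Maximum-likelihood location-scale normal fit per class. This is an
#' approximate default: empirical score distributions are typically
#' heavy-tailed and asymmetric, so posteriors from these fits rank
#' variants sensibly but should not be read as calibrated probabilities.
#' Supply richer densities through [class_densities()] when calibration
#' matters.
#'
#' @param scores_d,scores_n Normalised scores of known deleterious and
#'   neutral variants (>= 3 each, non-degenerate).
#' @return A `gm_densities` pair with provenance `"fitted-normal"` and the
#'   fitted parameters in `$pars`.
#' @export
fit_class_densities <- function(scores_d, scores_n) {
  for (s in list(scores_d, scores_n)) {
    if (length(s) < 3L)
      stop("need at least 3 scores per class to fit densities", call. = FALSE)
    if (stats::sd(s) == 0)
      stop("degenerate fit: all scores in one class are identical",
           call. = FALSE)
  }
  # ML normal estimates (divisor n, not n-1)
  mlsd <- function(s) sqrt(mean((s - mean(s))^2))
  p <- list(mean_d = mean(scores_d), sd_d = mlsd(scores_d),
            mean_n = mean(scores_n), sd_n = mlsd(scores_n))
  out <- class_densities(
    function(x) stats::dnorm(x, p$mean_d, p$sd_d),
    function(x) stats::dnorm(x, p$mean_n, p$sd_n),
    provenance = "fitted-normal"
  )
  out$pars <- unlist(p)
  out
}
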