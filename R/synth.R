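# Synthetic gene panels: alignments with controlled conservation structure
# and labelled variants whose Grantham/conservation profile separates the
# two classes.
#
# The generator plants class structure through exactly the quantities the
# metric consumes -- substitution severity (GS) and column conservation --
# not through any fitted score distribution, so end-to-end recovery tests
# exercise the pipeline's mechanics rather than a circular density
# assumption. There is no phylogeny: columns are i.i.d., which real
# alignments are not.

#' Synthetic panel configuration
#'
#' @param depth Number of aligned sequences (>= 2).
#' @param length Number of alignment columns.
#' @param fraction_conserved Fraction of columns carrying a single residue
#'   across all sequences (up to `noise`).
#' @param alphabet_size Residue alphabet size of variable columns (2-20).
#' @param noise Per-cell substitution noise rate in conserved columns.
#' @param n_deleterious,n_neutral Numbers of planted variants. Deleterious
#'   variants sit at conserved columns with substitutions whose GS exceeds
#'   the median pairwise GS; neutral variants sit at variable columns with
#'   below-median GS.
#' @param mislabel Probability of flipping each planted label.
#' @param biochem_clustered Draw variable-column alphabets from residues
#'   within a small Grantham radius of a centre residue instead of
#'   uniformly, stressing the distinction between geometric diversity (GV)
#'   and string diversity (compression ratio).
#' @param gene Gene identifier written into the variant table.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(depth = 20L, length = 60L, fraction_conserved = 0.5,
                         alphabet_size = 4L, noise = 0, n_deleterious = 6L,
                         n_neutral = 6L, mislabel = 0,
                         biochem_clustered = FALSE, gene = "SYNTH1") {
  stopifnot(depth >= 2L, length >= 1L,
            fraction_conserved >= 0, fraction_conserved <= 1,
            alphabet_size >= 2L, alphabet_size <= 20L,
            noise >= 0, noise <= 1, mislabel >= 0, mislabel <= 1,
            n_deleterious >= 0L, n_neutral >= 0L)
  structure(as.list(environment()), class = "synth_config")
}

# median of the 190 pairwise Grantham scores: the severity threshold
# separating planted deleterious from neutral substitutions
median_pairwise_gs <- function() {
  pairs <- utils::combn(AA_ALPHABET, 2L)
  stats::median(grantham_score(pairs[1L, ], pairs[2L, ]))
}

#' Generate a synthetic gene panel
#'
#' Builds an alignment with the configured mixture of conserved and
#' variable columns and plants labelled variants on top (see
#' [synth_config()]). Fully reproducible for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return List with `alignment` ([gm_alignment()]), `variants` (data
#'   frame `gene`, `position`, `wt`, `variant`, `label`) and `truth`
#'   (every planted quantity: column roles, true labels, substitution GS,
#'   the config and seed).
#' @examples
#' panel <- generate_panel(seed = 42)
#' panel$alignment
#' head(panel$variants)
#' @export
generate_panel <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    L <- config$length
    n_cons <- round(config$fraction_conserved * L)
    cons_cols <- sort(sample.int(L, n_cons))
    var_cols <- setdiff(seq_len(L), cons_cols)
    if (config$n_deleterious > length(cons_cols))
      stop("infeasible config: ", config$n_deleterious, " deleterious ",
           "variants need as many conserved columns (have ",
           length(cons_cols), ")", call. = FALSE)
    if (config$n_neutral > length(var_cols))
      stop("infeasible config: ", config$n_neutral, " neutral variants ",
           "need as many variable columns (have ", length(var_cols), ")",
           call. = FALSE)

    mat <- matrix("", nrow = config$depth, ncol = L)
    for (j in cons_cols) {
      w <- sample(AA_ALPHABET, 1L)
      col <- rep(w, config$depth)
      flip <- stats::runif(config$depth) < config$noise
      if (any(flip))
        col[flip] <- vapply(which(flip), function(i)
          sample(setdiff(AA_ALPHABET, w), 1L), character(1))
      mat[, j] <- col
    }
    for (j in var_cols) {
      if (config$biochem_clustered) {
        centre <- sample(AA_ALPHABET, 1L)
        d <- grantham_score(centre, AA_ALPHABET)
        alpha <- AA_ALPHABET[order(d)][seq_len(config$alphabet_size)]
      } else {
        alpha <- sample(AA_ALPHABET, config$alphabet_size)
      }
      mat[, j] <- sample(alpha, config$depth, replace = TRUE)
    }

    med <- median_pairwise_gs()
    plant <- function(cols, n, severe) {
      at <- cols[sample.int(length(cols), n)]
      do.call(rbind, lapply(at, function(j) {
        w <- mat[1L, j]
        gs_all <- grantham_score(w, AA_ALPHABET)
        cand <- if (severe) AA_ALPHABET[gs_all > med]
                else AA_ALPHABET[gs_all < med & AA_ALPHABET != w]
        if (length(cand) == 0L)  # extreme residues: fall back to the tail
          cand <- AA_ALPHABET[AA_ALPHABET != w][
            order(gs_all[AA_ALPHABET != w],
                  decreasing = severe)][1L]
        v <- if (length(cand) == 1L) cand else sample(cand, 1L)
        data.frame(position = j, wt = w, variant = v,
                   gs = grantham_score(w, v))
      }))
    }
    del <- nt <- NULL
    if (config$n_deleterious > 0L)
      del <- cbind(plant(cons_cols, config$n_deleterious, TRUE),
                   true_label = "D")
    if (config$n_neutral > 0L)
      nt <- cbind(plant(var_cols, config$n_neutral, FALSE),
                  true_label = "N")
    planted <- rbind(del, nt)
    label <- planted$true_label
    flip <- stats::runif(nrow(planted)) < config$mislabel
    label[flip] <- ifelse(planted$true_label[flip] == "D", "N", "D")

    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- c("ref_human", paste0("species", seq_len(config$depth - 1L)))
    variants <- data.frame(gene = config$gene, position = planted$position,
                           wt = planted$wt, variant = planted$variant,
                           label = label, stringsAsFactors = FALSE)
    list(
      alignment = gm_alignment(seqs),
      variants = variants,
      truth = list(config = config, seed = seed,
                   conserved_columns = cons_cols,
                   variable_columns = var_cols,
                   planted = cbind(planted, label = label),
                   gs_median = med)
    )
  })
}

#' DEFLATE calibration reference strings
#'
#' The five sorted 20-residue column strings, spanning maximal to minimal
#' diversity, whose known compressed lengths (20, 10, 8, 4, 3 bytes; ratios
#' 1.00, 0.50, 0.40, 0.20, 0.15) pin the package's DEFLATE byte-length
#' convention.
#'
#' @return Character vector of five column strings.
#' @export
calibration_strings <- function() {
  c("ACDEFGHIKLMNPQRSTVWY",
    "CCCCCCCCHHRRRRRSSSSS",
    "HHHQQQQQQQRRRRRRRRRR",
    "AAEEEEEEEEEEEEEEEEEE",
    "AAAAAAAAAAAAAAAAAAAA")
}
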