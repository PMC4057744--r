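# Particle swarm optimisation of the gene-specific constants.
#
# The swarm maximises the cluster-separation index R over the model
# parameters. The update rule is a position-perturbation variant without a
# velocity/inertia term:
#
#   s_i^t = s_i^{t-1} + U_i^t + g * (gbest - s_i^{t-1}) + l * (nbest_i - s_i^{t-1})
#
# with U uniform on [-1, 1] per element, g and l in (0, 1), and gbest /
# nbest_i the historically best positions globally and within particle i's
# fixed ring neighbourhood (which always includes the particle itself).
# Historical optima, not final positions, are returned. Positions are
# clamped to the parameter domains (k >= 1; multipliers >= 0) after every
# update.

#' Swarm training control parameters
#'
#' Defaults follow common swarm practice; every value can be overridden.
#' The ring neighbourhood (size 3: each particle plus its two index
#' neighbours) is fixed over time and unrelated to search-space proximity,
#' so information about good optima still propagates swarm-wide across
#' iterations.
#'
#' @param n_particles Number of particles (>= 2).
#' @param g,l Global and local attraction coefficients, each in (0, 1).
#' @param t_max Iteration budget.
#' @param stall Early stop after this many iterations without global-best
#'   improvement.
#' @param neighbourhood Ring width (odd, >= 1; includes self).
#' @param k_init,cpv_init,r_init Initialisation ranges for the attenuation
#'   constant, the property multipliers and the compression exponent.
#' @return A list of class `gm_control`.
#' @export
gm_control <- function(n_particles = 40L, g = 0.5, l = 0.5, t_max = 500L,
                       stall = 50L, neighbourhood = 3L,
                       k_init = c(1, 64), cpv_init = c(0, 4),
                       r_init = c(0, 8)) {
  if (!(g > 0 && g < 1 && l > 0 && l < 1))
    stop("attraction coefficients g and l must lie strictly in (0, 1)",
         call. = FALSE)
  if (n_particles < 2L) stop("need at least 2 particles", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles), g = g, l = l,
                 t_max = as.integer(t_max), stall = as.integer(stall),
                 neighbourhood = as.integer(neighbourhood),
                 k_init = k_init, cpv_init = cpv_init, r_init = r_init),
            class = "gm_control")
}

# generic swarm maximiser
# fn: function(numeric vector) -> scalar (may be Inf)
# init: d x 2 matrix of initialisation ranges; lower: length-d clamp floor
pso_maximise <- function(fn, init, lower, control) {
  n <- control$n_particles
  d <- nrow(init)
  half <- control$neighbourhood %/% 2L
  pos <- matrix(0, n, d)
  for (j in seq_len(d)) pos[, j] <- stats::runif(n, init[j, 1L], init[j, 2L])
  pos <- clamp_rows(pos, lower)
  val <- apply(pos, 1L, fn)
  pbest_pos <- pos
  pbest_val <- val
  trace <- numeric(0)
  best_i <- which.max(pbest_val)
  gbest_val <- pbest_val[best_i]
  gbest_pos <- pbest_pos[best_i, ]
  stalled <- 0L
  neigh <- lapply(seq_len(n), function(i)
    unique((i + seq(-half, half) - 1L) %% n + 1L))
  for (t in seq_len(control$t_max)) {
    nbest <- do.call(rbind, lapply(seq_len(n), function(i) {
      ni <- neigh[[i]]
      pbest_pos[ni[which.max(pbest_val[ni])], , drop = FALSE]
    }))
    u <- matrix(stats::runif(n * d, -1, 1), n, d)
    pos <- pos + u +
      control$g * (matrix(gbest_pos, n, d, byrow = TRUE) - pos) +
      control$l * (nbest - pos)
    pos <- clamp_rows(pos, lower)
    val <- apply(pos, 1L, fn)
    improved <- val > pbest_val
    pbest_pos[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    best_i <- which.max(pbest_val)
    if (pbest_val[best_i] > gbest_val) {
      gbest_val <- pbest_val[best_i]
      gbest_pos <- pbest_pos[best_i, ]
      stalled <- 0L
    } else stalled <- stalled + 1L
    trace <- c(trace, gbest_val)
    if (stalled >= control$stall) break
  }
  list(par = gbest_pos, value = gbest_val, trace = trace,
       iterations = length(trace))
}

clamp_rows <- function(pos, lower) {
  for (j in seq_along(lower)) pos[, j] <- pmax(pos[, j], lower[j])
  pos
}

param_list <- function(par, mode, r_fixed) {
  if (mode == "k_only")
    list(k = par[1L], r = r_fixed, c_mult = 1, p_mult = 1, v_mult = 1)
  else
    list(k = par[1L], r = par[2L], c_mult = par[3L], p_mult = par[4L],
         v_mult = par[5L])
}

#' Train a gene-specific Grantham-metric model
#'
#' Fits the gene model by maximising the cluster-separation index between
#' the deleterious and neutral training metrics with a particle swarm. In
#' the default `k_only` mode the attenuation constant `k` is the single
#' free parameter, the compression exponent is pinned at `r = 2.47` (its
#' empirically optimal constant value) and the property multipliers at 1;
#' `all_five` frees `k`, `r` and the three multipliers jointly.
#'
#' @param alignment A [gm_alignment()] object (or `NULL` when `features`
#'   are supplied directly).
#' @param variants Data frame of labelled variants ([read_variants()]);
#'   at least 2 `"D"` and 2 `"N"` labels are required.
#' @param mode `"k_only"` (default) or `"all_five"`.
#' @param r Compression exponent used in `k_only` mode.
#' @param control A [gm_control()] list.
#' @param seed Integer seed making the stochastic search reproducible;
#'   `NULL` uses the current RNG stream.
#' @param gene Gene identifier stored in the model (defaults to the
#'   variants' gene column).
#' @param features Precomputed [variant_features()] table; bypasses
#'   `alignment`/`variants`.
#' @return An object of class `gm_model`; see [new_gm_model()] for fields.
#' @examples
#' panel <- generate_panel(seed = 1)
#' fit <- gm_train(panel$alignment, panel$variants, seed = 1)
#' fit
#' @export
gm_train <- function(alignment, variants, mode = c("k_only", "all_five"),
                     r = 2.47, control = gm_control(), seed = NULL,
                     gene = NULL, features = NULL) {
  mode <- match.arg(mode)
  if (is.null(features)) {
    labelled <- variants[variants$label %in% c("D", "N"), , drop = FALSE]
    features <- variant_features(alignment, labelled)
  } else {
    features <- features[features$label %in% c("D", "N"), , drop = FALSE]
  }
  n_d <- sum(features$label == "D")
  n_n <- sum(features$label == "N")
  if (n_d < 2L || n_n < 2L)
    stop("training requires at least 2 deleterious and 2 neutral variants ",
         "(got ", n_d, " and ", n_n, ")", call. = FALSE)
  if (is.null(gene)) gene <- features$gene[1L]

  # fast closures over plain vectors; equivalent to objective_index()
  is_d <- features$label == "D"
  if (mode == "k_only") {
    base <- compute_metrics(features,
                            list(k = 1, r = r, c_mult = 1, p_mult = 1,
                                 v_mult = 1))
    gs0 <- base$gs
    gva0 <- base$gv_adj
    fn <- function(par) {
      gm <- gs0 * par[1L]^(-gva0)
      cluster_index(gm[is_d], gm[!is_d])
    }
  } else {
    fn <- function(par) {
      a <- par[3L] * GRANTHAM_ALPHA
      b <- par[4L] * GRANTHAM_BETA
      g2 <- par[5L] * GRANTHAM_GAMMA
      gs <- sqrt(a * features$dc2 + b * features$dp2 + g2 * features$dv2)
      gv <- sqrt(a * features$rc + b * features$rp + g2 * features$rv)
      gm <- gs * par[1L]^(-(gv * features$ratio^par[2L]))
      cluster_index(gm[is_d], gm[!is_d])
    }
  }
  if (mode == "k_only") {
    init <- matrix(control$k_init, 1L, 2L, byrow = TRUE)
    lower <- 1
  } else {
    init <- rbind(control$k_init, control$r_init,
                  control$cpv_init, control$cpv_init, control$cpv_init)
    lower <- c(1, -Inf, 0, 0, 0)
  }
  opt <- with_seed(seed, pso_maximise(fn, init, lower, control))
  params <- param_list(opt$par, mode, r)
  m <- compute_metrics(features, params)
  if (all(m$gm == m$gm[1L]))
    stop("degenerate model: all training metrics identical", call. = FALSE)
  model <- new_gm_model(
    params = params,
    mean_d = mean(m$gm[features$label == "D"]),
    mean_n = mean(m$gm[features$label == "N"]),
    sd_d = stats::sd(m$gm[features$label == "D"]),
    sd_n = stats::sd(m$gm[features$label == "N"]),
    gene = gene, n_deleterious = n_d, n_neutral = n_n
  )
  model$mode <- mode
  model$objective <- opt$value
  model$trace <- opt$trace
  model$training <- cbind(features, m)
  model$seed <- seed
  model
}
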