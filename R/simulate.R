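# Forward-time simulation of trait evolution along a painted tree using the
# exact Gaussian transition of each painting segment (no Euler
# discretization): OU segments draw from
#   Normal(theta + (x - theta) e^{-alpha dt}, sigma2 (1 - e^{-2 alpha dt}) / (2 alpha)),
# BM-type segments from Normal(x, integrated variance). Values at interior
# painting boundaries are recorded so that traitgram interpolation can bridge
# each regime segment with its own (theta, alpha).

#' Sample a root state
#'
#' Normal draw emulating sampling from a posterior distribution of root
#' states; `sd = 0` returns `mean` exactly without consuming random numbers.
#'
#' @param mean,sd Normal parameters, `sd >= 0`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_root <- function(mean, sd = 0, n = 1) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (sd == 0) return(rep(mean, n))
  rnorm(n, mean, sd)
}

# segment transition applied to a vector of current values (one per
# realization); returns new values
.segment_step <- function(x, dt, alpha, sigma2, vincr, theta) {
  n <- length(x)
  if (alpha > 0) {
    E <- exp(-alpha * dt)
    v <- sigma2 * (-expm1(-2 * alpha * dt)) / (2 * alpha)
    theta + (x - theta) * E + rnorm(n, 0, sqrt(v))
  } else {
    x + rnorm(n, 0, sqrt(vincr))
  }
}

# core: simulate n_real realizations; one rnorm(n_real) call per painting
# segment in preorder, so a fixed seed fixes the whole ensemble and
# `n_real = 1` reproduces a single realization exactly
.simulate_core <- function(ctx, sg, theta_by_seg, root_values) {
  n_real <- length(root_values)
  vals <- matrix(NA_real_, n_real, ctx$n_nodes)
  vals[, ctx$root] <- root_values
  nb <- sum(ctx$edge_nseg > 1L)
  bmeta <- list()
  bvals <- list()
  for (e in seq_len(nrow(ctx$edges))) {
    p <- ctx$edges[e, 1]
    c <- ctx$edges[e, 2]
    x <- vals[, p]
    off <- ctx$edge_off[e]
    ns <- ctx$edge_nseg[e]
    for (s in seq_len(ns)) {
      i <- off + s
      x <- .segment_step(
        x, ctx$seg_dt[i], sg$alpha[i], sg$sigma2[i], sg$vincr[i],
        theta_by_seg[i]
      )
      if (s < ns) {
        bmeta[[length(bmeta) + 1]] <- c(node = c, height = ctx$seg_end[i])
        bvals[[length(bvals) + 1]] <- x
      }
    }
    vals[, c] <- x
  }
  boundaries <- if (length(bmeta) > 0) {
    mt <- do.call(rbind, bmeta)
    tibble(node = as.integer(mt[, "node"]), height = mt[, "height"])
  } else {
    tibble(node = integer(0), height = numeric(0))
  }
  list(
    values = vals,
    boundary_meta = boundaries,
    boundary_values = if (length(bvals) > 0) do.call(cbind, bvals) else matrix(0, n_real, 0)
  )
}

.theta_by_seg <- function(sg) {
  if (identical(sg$par_names, "x0")) return(rep(0, length(sg$alpha)))
  sg$beta[sg$seg_par + 1L]
}

#' Simulate one realization of trait evolution
#'
#' Pre-order traversal drawing the exact Gaussian transition along every
#' painting segment.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_map()].
#' @param spec A [model_spec()].
#' @param root_value Trait value at the root.
#' @return A `trait_realization`: list with `values` (named by node id; tips
#'   also accessible via `tip_values`), `boundaries` (tibble of values at
#'   interior painting boundaries: `node`, `height`, `value`), and the
#'   inputs.
#' @export
simulate_realization <- function(tree, painting, spec, root_value) {
  ctx <- .moments_ctx(tree, painting)
  sg <- .spec_segments(ctx, spec)
  core <- .simulate_core(ctx, sg, .theta_by_seg(sg), root_value)
  .realization_from_core(ctx, spec, core, 1L)
}

.realization_from_core <- function(ctx, spec, core, i) {
  vals <- core$values[i, ]
  names(vals) <- as.character(seq_len(ctx$n_nodes))
  structure(
    list(
      values = vals,
      tip_values = setNames(vals[seq_len(ctx$n_tip)], ctx$tree$tip.label),
      boundaries = dplyr::mutate(core$boundary_meta, value = core$boundary_values[i, ]),
      tree = ctx$tree, spec = spec
    ),
    class = "trait_realization"
  )
}

#' Simulate an ensemble of trait-evolution realizations
#'
#' Draws `n_real` independent realizations from a single seeded random
#' stream: first the root states from `Normal(root_mean, root_sd)`, then one
#' vectorized draw per painting segment.
#'
#' @inheritParams simulate_realization
#' @param root_mean,root_sd Root-state distribution (`root_sd = 0` fixes the
#'   root exactly).
#' @param n_real Number of realizations (the default mirrors common practice
#'   of 100 simulated histories for envelope plots).
#' @param seed Optional integer seed recorded in the result.
#' @return A `sim_ensemble`: list with `values` (`n_real` x nodes matrix),
#'   `boundary_meta` / `boundary_values` for interior painting boundaries,
#'   `roots`, and the inputs; `seed` is stored as an attribute of the run.
#' @export
simulate_ensemble <- function(tree, painting, spec, root_mean, root_sd = 0,
                              n_real = 100, seed = NULL) {
  if (n_real < 1) abort("`n_real` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ctx <- .moments_ctx(tree, painting)
  sg <- .spec_segments(ctx, spec)
  roots <- sample_root(root_mean, root_sd, n_real)
  core <- .simulate_core(ctx, sg, .theta_by_seg(sg), roots)
  structure(
    list(
      values = core$values,
      boundary_meta = core$boundary_meta,
      boundary_values = core$boundary_values,
      roots = roots, n_real = n_real,
      tree = tree, painting = painting, spec = spec,
      root_mean = root_mean, root_sd = root_sd, seed = seed
    ),
    class = "sim_ensemble"
  )
}

#' Extract one realization from an ensemble
#'
#' @param ensemble A `sim_ensemble`.
#' @param i Realization index.
#' @return A `trait_realization`.
#' @export
ensemble_realization <- function(ensemble, i = 1L) {
  if (i < 1 || i > ensemble$n_real) abort("realization index out of range")
  ctx <- .moments_ctx(ensemble$tree, ensemble$painting)
  core <- list(
    values = ensemble$values,
    boundary_meta = ensemble$boundary_meta,
    boundary_values = ensemble$boundary_values
  )
  .realization_from_core(ctx, ensemble$spec, core, as.integer(i))
}

#' Serialize an ensemble as TSV (+ JSON header)
#'
#' Writes one row per (realization, node) pair, and a JSON side-car with the
#' model, seed and root settings.
#'
#' @param ensemble A `sim_ensemble`.
#' @param file TSV path; the header goes to `<file>.json`.
#' @return The input, invisibly.
#' @export
write_ensemble <- function(ensemble, file) {
  n_nodes <- ncol(ensemble$values)
  df <- tibble(
    realization = rep(seq_len(ensemble$n_real), n_nodes),
    node = rep(seq_len(n_nodes), each = ensemble$n_real),
    value = as.numeric(ensemble$values)
  )
  readr::write_tsv(df, file)
  hdr <- list(
    family = ensemble$spec$family,
    parameters = unclass(ensemble$spec),
    n_real = ensemble$n_real,
    root = list(mean = ensemble$root_mean, sd = ensemble$root_sd),
    seed = ensemble$seed
  )
  jsonlite::write_json(hdr, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(ensemble)
}
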