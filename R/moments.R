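# Model-implied moments of tip trait values under a painted model: a single
# root-to-tip pass over painting segments gives, per node, the accumulated
# variance, the accumulated exp(-alpha t) decay, and the linear dependence of
# the node mean on the mean parameters (optima / root state). Tip covariances
# follow as Cov(i,j) = Vacc(mrca) * decay(mrca -> i) * decay(mrca -> j).

# resolve a trait table (tibble with label, value[, se]) or named vector into
# tip-ordered values + observation SDs
.resolve_trait_data <- function(tree, data) {
  if (is.data.frame(data)) {
    if (!all(c("label", "value") %in% names(data))) {
      abort("trait data frame needs columns `label` and `value`")
    }
    x <- setNames(data$value, data$label)
    se <- if ("se" %in% names(data)) setNames(data$se, data$label) else NULL
  } else {
    x <- data
    se <- NULL
  }
  labs <- tree$tip.label
  if (is.null(names(x))) abort("trait values must be named by tip label")
  missing <- setdiff(labs, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing trait values for tips: ", paste(missing, collapse = ", ")))
  }
  x <- x[labs]
  if (!all(is.finite(x))) abort("trait values must be finite")
  if (is.null(se)) {
    se <- rep(0, length(labs))
  } else {
    se <- se[labs]
    se[is.na(se)] <- 0
    if (any(se < 0)) abort("per-tip SE must be >= 0")
  }
  list(x = as.numeric(x), se = as.numeric(se), labels = labs)
}

# precomputed geometry shared by every likelihood evaluation on one
# (tree, painting) pair
.moments_ctx <- function(tree, painting) {
  validate_regime_map(tree, painting)
  edges <- .preorder_edges(tree)
  pm <- dplyr::arrange(as_tibble(painting), .data$node, .data$start)
  seg_by_node <- split(seq_len(nrow(pm)), pm$node)
  idx <- unlist(seg_by_node[as.character(edges[, 2])], use.names = FALSE)
  nseg <- lengths(seg_by_node[as.character(edges[, 2])])
  off <- c(0L, cumsum(nseg))[seq_along(nseg)]
  n_tip <- length(tree$tip.label)
  M <- ape::mrca(tree)
  list(
    tree = tree, painting = pm, edges = edges,
    seg_idx = idx, edge_off = as.integer(off), edge_nseg = as.integer(nseg),
    seg_dt = pm$end[idx] - pm$start[idx],
    seg_start = pm$start[idx], seg_end = pm$end[idx],
    seg_regime = pm$regime[idx],
    regimes = sort(unique(pm$regime)),
    root_regime = .root_regime(tree, pm),
    n_tip = n_tip, n_nodes = .n_nodes(tree), root = .root_node(tree),
    mrca = M
  )
}

# per-segment parameter arrays for a model_spec; returns inputs for
# cpp_paint_pass plus the mean-parameter vector beta
.spec_segments <- function(ctx, spec) {
  fam <- spec$family
  reg <- ctx$seg_regime
  if (fam %in% .ou_families()) {
    sig <- if (length(spec$sigma2) > 1) unname(spec$sigma2[reg]) else rep(spec$sigma2, length(reg))
    alp <- if (length(spec$alpha) > 1) unname(spec$alpha[reg]) else rep(spec$alpha, length(reg))
    if (length(spec$theta) > 1) {
      par_names <- names(spec$theta)
      seg_par <- match(reg, par_names) - 1L
      beta <- unname(spec$theta[par_names])
      root_par <- match(.ctx_root_regime(ctx, par_names), par_names) - 1L
    } else {
      par_names <- "theta"
      seg_par <- rep(0L, length(reg))
      beta <- unname(spec$theta)
      root_par <- 0L
    }
    if (anyNA(sig) || anyNA(alp) || anyNA(seg_par)) {
      abort("painting contains regimes absent from the model parameters")
    }
    vincr <- numeric(length(reg))
  } else {
    alp <- rep(0, length(reg))
    seg_par <- rep(0L, length(reg))
    par_names <- "x0"
    beta <- spec$x0
    root_par <- 0L
    if (fam == "BMS") {
      sig <- unname(spec$sigma2[reg])
      if (anyNA(sig)) abort("painting contains regimes absent from `sigma2`")
      vincr <- sig * ctx$seg_dt
    } else if (fam == "ACDC") {
      sig <- rep(spec$sigma2, length(reg))
      r <- spec$r
      vincr <- if (abs(r) < 1e-12) {
        spec$sigma2 * ctx$seg_dt
      } else {
        spec$sigma2 * (exp(r * ctx$seg_end) - exp(r * ctx$seg_start)) / r
      }
    } else { # BM1
      sig <- rep(spec$sigma2, length(reg))
      vincr <- spec$sigma2 * ctx$seg_dt
    }
  }
  list(
    alpha = alp, sigma2 = sig, vincr = vincr, seg_par = seg_par,
    par_names = par_names, beta = beta, root_par = root_par
  )
}

.ctx_root_regime <- function(ctx, par_names) {
  rr <- ctx$root_regime
  if (!rr %in% par_names) {
    abort(sprintf("root regime '%s' has no optimum parameter", rr))
  }
  rr
}

# run the painted pass: per-node Vacc, logdecay, design matrix M
.paint_pass <- function(ctx, sg) {
  cpp_paint_pass(
    ctx$n_nodes, ctx$root,
    ctx$edges[, 1], ctx$edges[, 2],
    ctx$edge_off, ctx$edge_nseg,
    ctx$seg_dt, sg$alpha, sg$sigma2, sg$vincr, sg$seg_par,
    length(sg$par_names), sg$root_par
  )
}

# tip covariance matrix from the pass outputs (+ observation variances)
.tip_cov <- function(ctx, pass, se = NULL) {
  tips <- seq_len(ctx$n_tip)
  ld <- pass$logdecay
  va <- pass$vacc
  m <- ctx$mrca
  V <- va[m] * exp(outer(ld[tips], ld[tips], "+") - 2 * ld[m])
  dim(V) <- c(ctx$n_tip, ctx$n_tip)
  if (!is.null(se) && any(se > 0)) V <- V + diag(se^2, ctx$n_tip)
  dimnames(V) <- list(ctx$tree$tip.label, ctx$tree$tip.label)
  V
}

#' Model-implied mean and covariance of tip trait values
#'
#' Computes the expectation and covariance matrix of the tip values implied by
#' a painted model by one root-to-tip recursion over painting segments: along
#' a segment of duration `dt` in regime `k`, the mean relaxes towards the
#' optimum as `m -> theta_k + (m - theta_k) exp(-alpha_k dt)` and the variance
#' as `v -> v exp(-2 alpha_k dt) + sigma2_k (1 - exp(-2 alpha_k dt)) /
#' (2 alpha_k)`; Brownian segments are the `alpha -> 0` limit. The covariance
#' of two tips is the variance accumulated at their MRCA times the
#' `exp(-alpha dt)` decay products along both descending paths. Optional
#' per-tip standard errors add to the diagonal as `se^2`.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_map`.
#' @param spec A [model_spec()].
#' @param se Optional per-tip standard errors (named by tip label).
#' @return A list with `mean` (named vector) and `cov` (matrix).
#' @export
trait_moments <- function(tree, painting, spec, se = NULL) {
  ctx <- .moments_ctx(tree, painting)
  sg <- .spec_segments(ctx, spec)
  pass <- .paint_pass(ctx, sg)
  tips <- seq_len(ctx$n_tip)
  mu <- as.numeric(pass$M[tips, , drop = FALSE] %*% sg$beta)
  names(mu) <- tree$tip.label
  if (!is.null(se)) se <- se[tree$tip.label]
  V <- .tip_cov(ctx, pass, se)
  list(mean = mu, cov = V)
}

# Gaussian log-density with Cholesky; explicit error on singular covariance
.mvn_logdens <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    abort("model-implied covariance is singular (zero-length tips or sigma2 -> 0?)")
  }
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Log-likelihood of trait data under a painted model
#'
#' The multivariate-normal log-density of the tip values at the model-implied
#' moments of [trait_moments()].
#'
#' @inheritParams trait_moments
#' @param data Trait data: tibble with `label`, `value` and optional `se`
#'   columns, or a named vector.
#' @return Log-likelihood.
#' @export
loglik <- function(tree, painting, spec, data) {
  td <- .resolve_trait_data(tree, data)
  mo <- trait_moments(tree, painting, spec, se = setNames(td$se, td$labels))
  .mvn_logdens(td$x, mo$mean, mo$cov)
}
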