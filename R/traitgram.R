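# Traitgram machinery: anagenetic interpolation of simulated trait
# trajectories with the Ornstein-Uhlenbeck bridge, trait-range envelopes
# through time, and densely sampled polylines for plotting.

#' Expected trait value along an Ornstein-Uhlenbeck bridge
#'
#' The expected OU trajectory pinned at both endpoints of a time interval:
#' \deqn{x(t) = \theta + (x(t_i)-\theta)\frac{\sinh(\alpha(t_j-t))}{\sinh(\alpha(t_j-t_i))}
#'              + (x(t_j)-\theta)\frac{\sinh(\alpha(t-t_i))}{\sinh(\alpha(t_j-t_i))}.}
#' The second term is anchored at the *right* endpoint value `x(t_j)`; this is
#' the only anchoring for which the curve passes through both endpoints
#' (`variant = "corrected"`, the default). `variant = "printed"` anchors both
#' numerators at `x(t_i)`, a formulation that circulates in the literature but
#' violates the `t = t_j` boundary condition; it is provided for comparison
#' only. The `sinh` ratios are evaluated in exp/expm1 form so that large
#' `alpha (t_j - t_i)` does not overflow, and `alpha (t_j - t_i) < 1e-8` falls
#' back to linear interpolation.
#'
#' @param x_i,x_j Trait values at the segment endpoints.
#' @param t_i,t_j Segment start/end times, `t_i < t_j`.
#' @param theta Optimum active on the segment.
#' @param alpha Selection strength, `>= 0` (`0` gives the straight line).
#' @param t Evaluation time(s) in `[t_i, t_j]`.
#' @param variant `"corrected"` (default) or `"printed"`, see Details.
#' @return Expected trait value(s) at `t`.
#' @export
#' @examples
#' ou_bridge(0, 1, 0, 1, theta = 0, alpha = 1, t = 0.5) # sinh(0.5)/sinh(1)
ou_bridge <- function(x_i, x_j, t_i, t_j, theta, alpha, t,
                      variant = c("corrected", "printed")) {
  variant <- match.arg(variant)
  if (t_i >= t_j) abort("need t_i < t_j")
  if (alpha < 0) abort("`alpha` must be >= 0")
  if (any(t < t_i - 1e-12) || any(t > t_j + 1e-12)) {
    abort("evaluation time outside [t_i, t_j]")
  }
  L <- t_j - t_i
  if (alpha * L < 1e-8) {
    return(linear_bridge(x_i, x_j, t_i, t_j, t))
  }
  w_left <- .sinh_ratio(alpha * (t_j - t), alpha * L)
  w_right <- .sinh_ratio(alpha * (t - t_i), alpha * L)
  second <- if (variant == "corrected") (x_j - theta) else (x_i - theta)
  theta + (x_i - theta) * w_left + second * w_right
}

# sinh(a)/sinh(b) for 0 <= a <= b without overflow:
# = exp(a-b) * (1 - e^{-2a}) / (1 - e^{-2b})
.sinh_ratio <- function(a, b) {
  exp(a - b) * expm1(-2 * a) / expm1(-2 * b)
}

#' Linear interpolation between segment endpoints
#'
#' The anagenetic trajectory of Brownian-type segments and the
#' `alpha -> 0` limit of [ou_bridge()].
#'
#' @inheritParams ou_bridge
#' @return Interpolated value(s) at `t`.
#' @export
linear_bridge <- function(x_i, x_j, t_i, t_j, t) {
  if (t_i >= t_j) abort("need t_i < t_j")
  if (any(t < t_i - 1e-12) || any(t > t_j + 1e-12)) {
    abort("evaluation time outside [t_i, t_j]")
  }
  x_i + (t - t_i) * (x_j - x_i) / (t_j - t_i)
}

# per-edge interpolation table: segment endpoints (heights + per-realization
# values) and segment parameters, shared by interpolate/envelope/lines.
# values_at is a function(node) and boundary_value(bi) returning vectors over
# realizations.
.edge_segments_frame <- function(ctx, sg, theta_by_seg) {
  rows <- list()
  bkey <- character(0)
  for (e in seq_len(nrow(ctx$edges))) {
    p <- ctx$edges[e, 1]
    c <- ctx$edges[e, 2]
    off <- ctx$edge_off[e]
    ns <- ctx$edge_nseg[e]
    for (s in seq_len(ns)) {
      i <- off + s
      rows[[length(rows) + 1]] <- list(
        node = c,
        t0 = ctx$seg_start[i], t1 = ctx$seg_end[i],
        alpha = sg$alpha[i], theta = theta_by_seg[i],
        regime = ctx$seg_regime[i],
        from = if (s == 1) c("node", p) else c("boundary", paste0(c, "@", ctx$seg_start[i])),
        to = if (s == ns) c("node", c) else c("boundary", paste0(c, "@", ctx$seg_end[i]))
      )
    }
  }
  rows
}

# resolve endpoint references against a realization/ensemble value store
.endpoint_values <- function(ref, values, boundary_lookup) {
  if (ref[1] == "node") {
    values[, as.integer(ref[2])]
  } else {
    boundary_lookup[[ref[2]]]
  }
}

.boundary_lookup <- function(boundary_meta, boundary_values) {
  out <- list()
  if (nrow(boundary_meta) > 0) {
    keys <- paste0(boundary_meta$node, "@", boundary_meta$height)
    for (j in seq_along(keys)) out[[keys[j]]] <- boundary_values[, j, drop = TRUE]
  }
  out
}

# coerce a trait_realization into the matrix store used by the ensemble path
.realization_store <- function(tree, realization) {
  vals <- matrix(realization$values, nrow = 1)
  list(
    values = vals,
    boundary_meta = realization$boundaries[, c("node", "height")],
    boundary_values = if (nrow(realization$boundaries) > 0) {
      matrix(realization$boundaries$value, nrow = 1)
    } else {
      matrix(0, 1, 0)
    }
  )
}

#' Interpolate lineage trait values at arbitrary times
#'
#' For every time in `grid`, each branch spanning that time contributes one
#' value, obtained from the regime segment covering it: OU segments via
#' [ou_bridge()] with the segment's optimum and selection strength, Brownian
#' segments via [linear_bridge()]. A branch covers the half-open interval
#' from its parent's height (inclusive) to its child's height (exclusive), so
#' a node's value is counted once, on the child side; tip branches include
#' the final time so the present is covered.
#'
#' @param tree A `phylo` object.
#' @param painting A [regime_map()].
#' @param spec A [model_spec()].
#' @param realization A `trait_realization` from [simulate_realization()] or
#'   [ensemble_realization()].
#' @param grid Increasing times within `[0, tree_height(tree)]`.
#' @return Tibble with `time`, `node` (branch child id), `regime`, `value`.
#' @export
interpolate_lineages <- function(tree, painting, spec, realization, grid) {
  T <- tree_height(tree)
  if (any(grid < -1e-12) || any(grid > T + 1e-12)) {
    abort("grid times must lie in [0, tree height]")
  }
  ctx <- .moments_ctx(tree, painting)
  sg <- .spec_segments(ctx, spec)
  store <- .realization_store(tree, realization)
  segs <- .edge_segments_frame(ctx, sg, .theta_by_seg(sg))
  blk <- .boundary_lookup(store$boundary_meta, store$boundary_values)
  n_tip <- ctx$n_tip
  out <- list()
  for (sr in segs) {
    is_tip_end <- sr$to[1] == "node" && as.integer(sr$to[2]) <= n_tip
    sel <- grid >= sr$t0 - 1e-12 & (grid < sr$t1 - 1e-12 |
      (is_tip_end & abs(grid - sr$t1) <= 1e-12))
    if (!any(sel)) next
    tt <- pmin(pmax(grid[sel], sr$t0), sr$t1)
    v0 <- .endpoint_values(sr$from, store$values, blk)
    v1 <- .endpoint_values(sr$to, store$values, blk)
    val <- if (sr$alpha > 0) {
      ou_bridge(v0, v1, sr$t0, sr$t1, sr$theta, sr$alpha, tt)
    } else {
      linear_bridge(v0, v1, sr$t0, sr$t1, tt)
    }
    out[[length(out) + 1]] <- tibble(
      time = tt, node = sr$node, regime = sr$regime, value = as.numeric(val)
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$time, .data$node)
}

#' Trait-range envelope through time
#'
#' For every realization of the ensemble and every grid time, the minimum and
#' maximum trait value across all lineages alive at that time is computed
#' (branch trajectories interpolated with the regime-appropriate bridge); the
#' envelope is the central `level` band of those per-realization extremes:
#' lower bound the 2.5th percentile of per-realization minima and upper bound
#' the 97.5th percentile of per-realization maxima at `level = 0.95`.
#'
#' @param ensemble A `sim_ensemble`.
#' @param grid Optional time grid; defaults to 512 uniform points on
#'   `[0, T]` plus all node heights (so node times are represented exactly).
#' @param level Coverage level of the range band.
#' @param keep_extrema Retain the per-realization min/max matrices as
#'   attributes.
#' @return A `traitgram_envelope` tibble with `time`, `lower`, `upper`.
#' @export
envelope <- function(ensemble, grid = NULL, level = 0.95,
                     keep_extrema = FALSE) {
  tree <- ensemble$tree
  T <- tree_height(tree)
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(0, T, length.out = 512), node_heights(tree))))
  }
  grid <- sort(unique(grid))
  ctx <- .moments_ctx(tree, ensemble$painting)
  sg <- .spec_segments(ctx, ensemble$spec)
  segs <- .edge_segments_frame(ctx, sg, .theta_by_seg(sg))
  blk <- .boundary_lookup(ensemble$boundary_meta, ensemble$boundary_values)
  n_real <- ensemble$n_real
  n_tip <- ctx$n_tip
  lo <- matrix(Inf, n_real, length(grid))
  hi <- matrix(-Inf, n_real, length(grid))
  for (sr in segs) {
    is_tip_end <- sr$to[1] == "node" && as.integer(sr$to[2]) <= n_tip
    sel <- which(grid >= sr$t0 - 1e-12 & (grid < sr$t1 - 1e-12 |
      (is_tip_end & abs(grid - sr$t1) <= 1e-12)))
    if (length(sel) == 0) next
    tt <- pmin(pmax(grid[sel], sr$t0), sr$t1)
    v0 <- .endpoint_values(sr$from, ensemble$values, blk)
    v1 <- .endpoint_values(sr$to, ensemble$values, blk)
    # outer over realizations x selected times
    if (sr$alpha > 0) {
      L <- sr$t1 - sr$t0
      wl <- .sinh_ratio(sr$alpha * (sr$t1 - tt), sr$alpha * L)
      wr <- .sinh_ratio(sr$alpha * (tt - sr$t0), sr$alpha * L)
      if (sr$alpha * L < 1e-8) {
        wl <- (sr$t1 - tt) / L
        wr <- (tt - sr$t0) / L
      }
      vals <- sr$theta + outer(v0 - sr$theta, wl) + outer(v1 - sr$theta, wr)
    } else {
      w <- (tt - sr$t0) / (sr$t1 - sr$t0)
      vals <- outer(v0, 1 - w) + outer(v1, w)
    }
    lo[, sel] <- pmin(lo[, sel], vals)
    hi[, sel] <- pmax(hi[, sel], vals)
  }
  a <- (1 - level) / 2
  out <- tibble(
    time = grid,
    lower = apply(lo, 2, quantile, probs = a, names = FALSE),
    upper = apply(hi, 2, quantile, probs = 1 - a, names = FALSE)
  )
  attr(out, "level") <- level
  attr(out, "n_real") <- n_real
  if (keep_extrema) {
    attr(out, "minima") <- lo
    attr(out, "maxima") <- hi
  }
  class(out) <- c("traitgram_envelope", class(out))
  out
}

#' Traitgram polylines for a single realization
#'
#' Densely sampled bridge curves for every branch, tagged with the regime
#' active on each segment for coloring. Endpoints coincide with the
#' realization's node (and painting-boundary) values, so parent and child
#' polylines connect.
#'
#' @inheritParams interpolate_lineages
#' @param points_per_edge Sample points per branch (at least 2).
#' @return Tibble with `node` (branch child id), `regime`, `time`, `value`.
#' @export
traitgram_lines <- function(tree, painting, spec, realization,
                            points_per_edge = 20) {
  if (points_per_edge < 2) abort("`points_per_edge` must be >= 2")
  ctx <- .moments_ctx(tree, painting)
  sg <- .spec_segments(ctx, spec)
  store <- .realization_store(tree, realization)
  segs <- .edge_segments_frame(ctx, sg, .theta_by_seg(sg))
  blk <- .boundary_lookup(store$boundary_meta, store$boundary_values)
  stem_len <- .stem_lengths(tree)
  out <- list()
  for (sr in segs) {
    frac <- (sr$t1 - sr$t0) / stem_len[sr$node]
    np <- max(2L, ceiling(points_per_edge * frac))
    tt <- seq(sr$t0, sr$t1, length.out = np)
    v0 <- .endpoint_values(sr$from, store$values, blk)
    v1 <- .endpoint_values(sr$to, store$values, blk)
    val <- if (sr$alpha > 0) {
      ou_bridge(v0, v1, sr$t0, sr$t1, sr$theta, sr$alpha, tt)
    } else {
      linear_bridge(v0, v1, sr$t0, sr$t1, tt)
    }
    out[[length(out) + 1]] <- tibble(
      node = sr$node, regime = sr$regime, time = tt, value = as.numeric(val)
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("traitgram_lines", class(res))
  res
}

#' @export
autoplot.traitgram_envelope <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$time, ymin = .data$lower, ymax = .data$upper)
  ) +
    ggplot2::geom_ribbon(fill = "grey70", alpha = 0.8) +
    ggplot2::labs(x = "time since root", y = "trait value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.traitgram_lines <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(
      x = .data$time, y = .data$value,
      group = interaction(.data$node, .data$regime), colour = .data$regime
    )
  ) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "time since root", y = "trait value") +
    ggplot2::theme_minimal()
}

#' Combined traitgram plot
#'
#' Overlays the trait-range envelope of an ensemble with the bridge-curve
#' traitgram of one of its realizations.
#'
#' @param ensemble A `sim_ensemble`.
#' @param realization_index Which realization to draw as polylines.
#' @param points_per_edge Passed to [traitgram_lines()].
#' @return A ggplot object.
#' @export
plot_traitgram <- function(ensemble, realization_index = 1L,
                           points_per_edge = 20) {
  env <- envelope(ensemble)
  real <- ensemble_realization(ensemble, realization_index)
  lines <- traitgram_lines(
    ensemble$tree, ensemble$painting, ensemble$spec, real, points_per_edge
  )
  autoplot(env) +
    ggplot2::geom_path(
      data = lines,
      ggplot2::aes(
        x = .data$time, y = .data$value,
        group = interaction(.data$node, .data$regime), colour = .data$regime
      ),
      inherit.aes = FALSE
    )
}

#' Write an envelope / polylines as TSV
#'
#' @param x A `traitgram_envelope` or `traitgram_lines` tibble.
#' @param file Path.
#' @return The input, invisibly.
#' @export
write_traitgram_tsv <- function(x, file) {
  readr::write_tsv(as_tibble(x), file)
  invisible(x)
}
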