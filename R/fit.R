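# Maximum-likelihood fitting of the trait-evolution model battery.
#
# BM-type families (BM1, BMS, ACDC) are fitted through the O(n) Brownian
# pruning recursion with per-branch variances; OU-type families through the
# painted moment recursion + multivariate-normal density, with the optima
# (and for BM-type the root state) profiled out by generalized least squares
# at every evaluation. The remaining free parameters are optimized on the log
# scale by bounded quasi-Newton from a deterministic grid of starts.

# per-node variance contributions of each regime (n_nodes x m), so that
# stem_var = D %*% sigma2 for multi-rate BM
.bm_regime_durations <- function(ctx) {
  m <- length(ctx$regimes)
  D <- matrix(0, ctx$n_nodes, m)
  nd <- ctx$painting$node
  dt <- ctx$painting$end - ctx$painting$start
  j <- match(ctx$painting$regime, ctx$regimes)
  for (i in seq_along(nd)) D[nd[i], j[i]] <- D[nd[i], j[i]] + dt[i]
  D
}

# ACDC: per-node integral of exp(r * t) along the stem edge segments
.acdc_integral <- function(ctx, r) {
  nd <- ctx$painting$node
  s <- ctx$painting$start
  e <- ctx$painting$end
  inc <- if (abs(r) < 1e-12) e - s else (exp(r * e) - exp(r * s)) / r
  out <- numeric(ctx$n_nodes)
  for (i in seq_along(nd)) out[nd[i]] <- out[nd[i]] + inc[i]
  out
}

# Brownian-pruning evaluation: REML (flat-root marginal) parts + profiled or
# fixed root state
.bm_eval <- function(ctx_post, stem_var, tip_var, x) {
  out <- cpp_bm_pruning(
    ctx_post$n_nodes, ctx_post$n_tip,
    ctx_post$edge_parent, ctx_post$edge_child,
    stem_var, tip_var, x
  )
  lnl_reml <- out[1]
  xhat <- out[2]
  vhat <- out[3]
  list(
    lnl_reml = lnl_reml,
    lnl_ml = lnl_reml - 0.5 * log(2 * pi * vhat),
    x0 = xhat, v0 = vhat
  )
}

.postorder_ctx <- function(tree) {
  ed <- .postorder_edges(tree)
  list(
    n_nodes = .n_nodes(tree), n_tip = length(tree$tip.label),
    edge_parent = ed[, 1], edge_child = ed[, 2]
  )
}

# OU evaluation with GLS-profiled optima; returns profile lnl and theta-hat
.ou_eval <- function(ctx, sg, x, tip_var) {
  pass <- .paint_pass(ctx, sg)
  tips <- seq_len(ctx$n_tip)
  V <- .tip_cov(ctx, pass)
  if (any(tip_var > 0)) V <- V + diag(tip_var, ctx$n_tip)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(lnl = -Inf, beta = NULL))
  M <- pass$M[tips, , drop = FALSE]
  W <- backsolve(R, cbind(x, M), transpose = TRUE)
  z <- W[, 1]
  Zm <- W[, -1, drop = FALSE]
  sv <- svd(Zm)
  pos <- sv$d > max(sv$d[1], 1e-300) * 1e-10
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% z) / sv$d[pos])
  resid <- z - Zm %*% beta
  lnl <- -0.5 * (ctx$n_tip * log(2 * pi) + 2 * sum(log(diag(R))) + sum(resid^2))
  list(lnl = as.numeric(lnl), beta = as.numeric(beta))
}

# free-parameter layout per family: names on the optimizer scale
.fit_layout <- function(family, regimes, se_mode) {
  m <- length(regimes)
  multi <- .family_multi(family)
  nm <- character(0)
  if (family %in% c("BM1", "ACDC", "OU1") || !multi$sigma2) {
    nm <- c(nm, "log_sigma2")
  } else {
    nm <- c(nm, paste0("log_sigma2.", regimes))
  }
  if (family %in% .ou_families()) {
    nm <- c(nm, if (multi$alpha) paste0("log_alpha.", regimes) else "log_alpha")
  }
  if (family == "ACDC") nm <- c(nm, "r")
  if (se_mode == "estimate") nm <- c(nm, "log_se")
  nm
}

.par_block <- function(par, prefix, regimes) {
  nm <- names(par)
  idx <- which(nm == prefix)
  if (length(idx) == 1) {
    return(unname(exp(par[idx])))
  }
  setNames(exp(par[paste0(prefix, ".", regimes)]), regimes)
}

#' Fit a model of continuous trait evolution by maximum likelihood
#'
#' @param tree A `phylo` object.
#' @param data Trait data: tibble with `label`, `value` and optional `se`
#'   columns, or a named vector.
#' @param family Model family, see [model_spec()].
#' @param painting A [regime_map()]; required for multi-regime families,
#'   defaults to a single regime otherwise.
#' @param se_mode Measurement-error handling: `"none"`, `"fixed"` (use the
#'   `se` column as known observation SDs), or `"estimate"` (one common SE
#'   estimated as an extra free parameter).
#' @param n_starts Number of deterministic optimizer starts.
#' @param r_bounds Optional bounds for the `ACDC` exponent `r`, e.g.
#'   `c(-10, 0)/T` restricts to the decelerating early-burst branch.
#' @return A `trait_fit` object: the ML [model_spec()], `lnl`, parameter
#'   count `k`, `n`, `AICc`, and per-start convergence diagnostics.
#'   Optima (OU) and the root state (BM-type) are profiled analytically.
#' @seealso [compare_models()], [aicc()], [loglik()]
#' @export
fit_trait_model <- function(tree, data, family, painting = NULL,
                            se_mode = c("none", "fixed", "estimate"),
                            n_starts = 5, r_bounds = NULL) {
  se_mode <- match.arg(se_mode)
  family <- match.arg(family, c("BM1", "BMS", "ACDC", "OU1", "OUM", "OUMV",
                                "OUMA", "OUMVA"))
  td <- .resolve_trait_data(tree, data)
  n <- length(td$x)
  if (is.null(painting)) {
    if (family %in% c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")) {
      abort(sprintf("family %s requires a regime `painting`", family))
    }
    painting <- one_regime_map(tree)
  }
  ctx <- .moments_ctx(tree, painting)
  regimes <- ctx$regimes
  m <- length(regimes)
  k <- .family_k(family, m, se_mode)
  if (n <= k + 1) {
    abort(sprintf("AICc undefined: n = %d tips but k = %d parameters", n, k))
  }
  T <- tree_height(tree)
  vx <- var(td$x)
  if (vx <= 0) abort("trait values are constant; nothing to fit")
  tip_var_fixed <- if (se_mode == "fixed") td$se^2 else rep(0, n)
  ctx_post <- .postorder_ctx(tree)
  stem_len <- .stem_lengths(tree)

  # cheap single-rate baseline used to seed every family
  bm1_nll <- function(ls2) {
    -.bm_eval(ctx_post, exp(ls2) * stem_len, tip_var_fixed, td$x)$lnl_ml
  }
  s2_lo <- 1e-8
  s2_hi <- 100 * vx / T
  base <- optimize(bm1_nll, log(c(s2_lo, s2_hi)))
  s2hat <- exp(base$minimum)

  layout <- .fit_layout(family, regimes, se_mode)
  p <- length(layout)
  lower <- upper <- start0 <- setNames(numeric(p), layout)
  is_s2 <- grepl("^log_sigma2", layout)
  is_al <- grepl("^log_alpha", layout)
  lower[is_s2] <- log(s2_lo)
  upper[is_s2] <- log(s2_hi)
  start0[is_s2] <- log(s2hat)
  lower[is_al] <- log(1e-8)
  upper[is_al] <- log(50 / T)
  if (family == "ACDC") {
    rb <- r_bounds %||% (c(-10, 10) / T)
    lower["r"] <- rb[1]
    upper["r"] <- rb[2]
    start0["r"] <- mean(rb)
  }
  if (se_mode == "estimate") {
    lower["log_se"] <- log(1e-9)
    upper["log_se"] <- log(3 * sd(td$x))
    start0["log_se"] <- log(0.1 * sd(td$x))
  }

  D <- if (family == "BMS") .bm_regime_durations(ctx) else NULL
  ou_par_names <- if (family %in% c("OUM", "OUMV", "OUMA", "OUMVA")) regimes else "theta"

  eval_par <- function(par, detail = FALSE) {
    names(par) <- layout
    tip_var <- tip_var_fixed
    if (se_mode == "estimate") tip_var <- tip_var + exp(2 * par["log_se"])
    if (family %in% .ou_families()) {
      sig <- .par_block(par, "log_sigma2", regimes)
      alp <- .par_block(par, "log_alpha", regimes)
      reg <- ctx$seg_regime
      sg <- list(
        alpha = if (length(alp) > 1) unname(alp[reg]) else rep(alp, length(reg)),
        sigma2 = if (length(sig) > 1) unname(sig[reg]) else rep(sig, length(reg)),
        vincr = numeric(length(reg)),
        seg_par = if (length(ou_par_names) > 1) match(reg, ou_par_names) - 1L else rep(0L, length(reg)),
        par_names = ou_par_names,
        root_par = if (length(ou_par_names) > 1) match(ctx$root_regime, ou_par_names) - 1L else 0L
      )
      ev <- .ou_eval(ctx, sg, td$x, tip_var)
      if (!detail) return(-ev$lnl)
      spec <- model_spec(family,
        sigma2 = sig, alpha = alp,
        theta = setNames(ev$beta, if (length(ou_par_names) > 1) ou_par_names else NULL),
        regimes = regimes
      )
      return(list(lnl = ev$lnl, spec = spec, tip_var = tip_var, par = par))
    }
    stem_var <- switch(family,
      BM1 = exp(par[["log_sigma2"]]) * stem_len,
      BMS = as.numeric(D %*% .par_block(par, "log_sigma2", regimes)),
      ACDC = exp(par[["log_sigma2"]]) * .acdc_integral(ctx, par[["r"]])
    )
    ev <- .bm_eval(ctx_post, stem_var, tip_var, td$x)
    if (!detail) return(-ev$lnl_ml)
    spec <- switch(family,
      BM1 = model_spec("BM1", sigma2 = exp(par[["log_sigma2"]]), x0 = ev$x0),
      BMS = model_spec("BMS",
        sigma2 = .par_block(par, "log_sigma2", regimes),
        x0 = ev$x0, regimes = regimes
      ),
      ACDC = model_spec("ACDC",
        sigma2 = exp(par[["log_sigma2"]]),
        r = par[["r"]], x0 = ev$x0
      )
    )
    list(lnl = ev$lnl_ml, spec = spec, tip_var = tip_var, par = par)
  }

  starts <- .fit_starts(family, layout, start0, lower, upper, n_starts, T)
  runs <- vector("list", length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      optim(starts[[i]], eval_par,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    runs[[i]] <- fit
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  converged <- any(vapply(runs, function(f) !is.null(f) && f$convergence == 0, TRUE))
  if (is.null(best)) abort("all optimizer starts failed")
  if (!converged) warn("no optimizer start reported convergence; result flagged")
  det <- eval_par(best$par, detail = TRUE)
  lnl <- det$lnl
  diag_tbl <- tibble(
    start = seq_along(starts),
    value = vapply(runs, function(f) if (is.null(f)) NA_real_ else -f$value, 0),
    convergence = vapply(runs, function(f) if (is.null(f)) NA_integer_ else as.integer(f$convergence), 1L)
  )
  structure(
    list(
      family = family, spec = det$spec, lnl = lnl, k = k, n = n,
      aicc = aicc(lnl, k, n),
      se_mode = se_mode,
      se_hat = if (se_mode == "estimate") exp(best$par[[which(layout == "log_se")]]) else NULL,
      converged = converged, starts = diag_tbl,
      tree = tree, painting = painting,
      data = tibble(label = td$labels, value = td$x, se = td$se)
    ),
    class = "trait_fit"
  )
}

# deterministic start grid: alpha log-spaced, ACDC r evenly spaced,
# sigma2 anchored at the single-rate estimate
.fit_starts <- function(family, layout, start0, lower, upper, n_starts, T) {
  is_al <- grepl("^log_alpha", layout)
  if (family %in% .ou_families()) {
    alphas <- log(exp(seq(log(0.1 / T), log(20 / T), length.out = n_starts)))
    lapply(alphas, function(a) {
      s <- start0
      s[is_al] <- a
      s
    })
  } else if (family == "ACDC") {
    rs <- seq(lower[["r"]], upper[["r"]], length.out = n_starts + 2)[-c(1, n_starts + 2)]
    lapply(rs, function(r) {
      s <- start0
      s["r"] <- r
      s
    })
  } else {
    offs <- seq(-2, 2, length.out = min(n_starts, 5))
    lapply(offs, function(o) {
      s <- start0
      s[grepl("^log_sigma2", layout)] <- pmin(
        upper[grepl("^log_sigma2", layout)],
        pmax(lower[grepl("^log_sigma2", layout)], s[grepl("^log_sigma2", layout)] + o)
      )
      s
    })
  }
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param lnl Log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips).
#' @return AICc value.
#' @export
aicc <- function(lnl, k, n) {
  if (n - k - 1 <= 0) abort("AICc undefined: need n > k + 1")
  -2 * lnl + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted models by AICc
#'
#' Computes Delta-AICc against the best model and Akaike weights
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`. Models within 0.01
#' AICc units of each other are ordered by increasing parameter count.
#'
#' @param ... `trait_fit` objects (optionally named), or a single list of
#'   them.
#' @return A `model_comparison` tibble with columns `model`, `family`,
#'   `logLik`, `k`, `AICc`, `delta_AICc`, `weight`, sorted best-first.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "trait_fit")) fits <- fits[[1]]
  if (length(fits) == 0) abort("no fits supplied")
  nm <- names(fits) %||% vapply(fits, function(f) f$family, "")
  nm[!nzchar(nm)] <- vapply(fits[!nzchar(nm)], function(f) f$family, "")
  tab <- tibble(
    model = unname(nm),
    family = unname(vapply(fits, function(f) f$family, "")),
    logLik = unname(vapply(fits, function(f) f$lnl, 0)),
    k = unname(vapply(fits, function(f) f$k, 0)),
    AICc = unname(vapply(fits, function(f) f$aicc, 0))
  )
  idx <- order(tab$AICc)
  tab <- tab[idx, ]
  # near-ties (Delta < 0.01): fewer parameters first
  grp <- cumsum(c(TRUE, diff(tab$AICc) >= 0.01))
  idx2 <- order(grp, tab$k)
  tab <- tab[idx2, ]
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  attr(tab, "fits") <- fits[idx][idx2]
  class(tab) <- c("model_comparison", class(tab))
  tab
}

#' Fit the full model battery and compare by AICc
#'
#' Convenience wrapper fitting several families to the same data and
#' returning their [compare_models()] table. `"ACDC_DC"` and `"ACDC_AC"`
#' denote the decelerating (early burst) and accelerating halves of the ACDC
#' family, fitted with `r` restricted to the corresponding sign.
#'
#' @inheritParams fit_trait_model
#' @param families Character vector of families; multi-regime entries are
#'   skipped with a warning when no painting is given.
#' @return A `model_comparison` tibble (fits in `attr(, "fits")`).
#' @export
fit_battery <- function(tree, data, painting = NULL,
                        families = c("BM1", "OU1", "OUM", "OUMV", "OUMA",
                                     "OUMVA", "ACDC_DC", "ACDC_AC"),
                        se_mode = c("none", "fixed", "estimate"),
                        n_starts = 5) {
  se_mode <- match.arg(se_mode)
  T <- tree_height(tree)
  fits <- list()
  for (fam in families) {
    f <- switch(fam,
      ACDC_DC = fit_trait_model(tree, data, "ACDC",
        painting = painting,
        se_mode = se_mode, n_starts = n_starts, r_bounds = c(-10 / T, 0)
      ),
      ACDC_AC = fit_trait_model(tree, data, "ACDC",
        painting = painting,
        se_mode = se_mode, n_starts = n_starts, r_bounds = c(0, 10 / T)
      ),
      fit_trait_model(tree, data, fam,
        painting = painting,
        se_mode = se_mode, n_starts = n_starts
      )
    )
    fits <- c(fits, list(f))
  }
  names(fits) <- families
  compare_models(fits)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' The ratio of the observed mean squared deviation from the phylogenetically
#' corrected mean (`MSE0`) over the GLS mean squared error under the Brownian
#' covariance (`MSE`), scaled by its expectation under Brownian motion,
#' `(tr(V) - n / (1' V^-1 1)) / (n - 1)` (Blomberg et al. 2003). K is about 1
#' for Brownian-like data and below 1 when close relatives resemble each other
#' less than Brownian motion predicts.
#'
#' @param tree A `phylo` object.
#' @param data Trait values: named vector or tibble with `label`, `value`.
#' @return The K statistic.
#' @export
blomberg_k <- function(tree, data) {
  td <- .resolve_trait_data(tree, data)
  x <- td$x
  n <- length(x)
  if (n < 4) abort("Blomberg's K needs at least 4 tips")
  if (var(x) == 0) abort("constant trait: K undefined")
  C <- ape::vcv(tree)
  Ci <- solve(C)
  ahat <- sum(Ci %*% x) / sum(Ci)
  d <- x - ahat
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(t(d) %*% Ci %*% d) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  (mse0 / mse) / expected
}

# ---- methods --------------------------------------------------------------

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf(
    "<trait_fit: %s>  n = %d, k = %d\n  lnL = %.4f, AICc = %.4f%s\n",
    x$family, x$n, x$k, x$lnl, x$aicc,
    if (!x$converged) "  [not converged]" else ""
  ))
  print(x$spec)
  invisible(x)
}

#' @export
tidy.trait_fit <- function(x, ...) {
  s <- x$spec
  row <- function(term, value) {
    if (is.null(value)) return(NULL)
    tibble(
      term = term,
      regime = names(value) %||% rep(NA_character_, length(value)),
      estimate = unname(value)
    )
  }
  out <- dplyr::bind_rows(
    row("sigma2", s$sigma2), row("alpha", s$alpha), row("theta", s$theta),
    row("r", s$r), row("x0", s$x0),
    if (!is.null(x$se_hat)) row("se", x$se_hat)
  )
  out$regime[out$regime == ""] <- NA_character_
  out
}

#' @export
glance.trait_fit <- function(x, ...) {
  tibble(
    family = x$family, logLik = x$lnl, k = x$k, n = x$n, AICc = x$aicc,
    converged = x$converged
  )
}

#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- as_tibble(object)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
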