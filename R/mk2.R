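# Two-state continuous-time Markov model (Mk2) on a tree: pruning likelihood,
# ML rates, and marginal ancestral state reconstruction. States are coded
# 0/1 throughout.

# closed-form transition matrix for a 2-state chain with rates q01, q10:
# P(t) = Pi + (I - Pi) e^{-(q01+q10) t}, Pi the stationary matrix
.mk2_pmat <- function(q01, q10, t) {
  s <- q01 + q10
  if (s <= 0) return(diag(2))
  p0 <- q10 / s
  p1 <- q01 / s
  E <- exp(-s * t)
  matrix(c(
    p0 + p1 * E, p1 - p1 * E,
    p0 - p0 * E, p1 + p0 * E
  ), nrow = 2, byrow = TRUE)
}

.mk2_root_prior <- function(root_prior, q01, q10) {
  if (root_prior == "flat") return(c(0.5, 0.5))
  s <- q01 + q10
  if (s <= 0) return(c(0.5, 0.5))
  c(q10 / s, q01 / s)
}

.resolve_tip_states <- function(tree, tip_states) {
  if (is.data.frame(tip_states)) {
    tip_states <- setNames(tip_states[[2]], tip_states[[1]])
  }
  labs <- tree$tip.label
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(labs)) {
      abort("unnamed `tip_states` must have one entry per tip")
    }
    names(tip_states) <- labs
  }
  missing <- setdiff(labs, names(tip_states))
  if (length(missing) > 0) {
    abort(paste0("missing states for tips: ", paste(missing, collapse = ", ")))
  }
  st <- suppressWarnings(as.integer(as.character(tip_states[labs])))
  if (anyNA(st) || any(!st %in% c(0L, 1L))) {
    abort("tip states must be coded 0/1")
  }
  st
}

# conditional (partial) likelihoods by pruning, with per-node rescaling;
# returns list(up = n_nodes x 2 scaled partials, logscale = per-node log
# scale, lnl = total log-likelihood)
.mk2_pruning <- function(tree, st, q01, q10, prior) {
  n_tip <- length(tree$tip.label)
  n <- .n_nodes(tree)
  stem <- .stem_lengths(tree)
  up <- matrix(0, n, 2)
  up[cbind(seq_len(n_tip), st + 1L)] <- 1
  logscale <- numeric(n)
  post <- .postorder_edges(tree)
  # transition matrix for the edge above each node
  pm <- lapply(seq_len(n), function(i) .mk2_pmat(q01, q10, stem[i]))
  # accumulate children into parents edge by edge; postorder guarantees a
  # child's subtree is complete before its own edge is processed
  seen <- logical(n)
  for (e in seq_len(nrow(post))) {
    p <- post[e, 1]
    c <- post[e, 2]
    Lc <- as.numeric(pm[[c]] %*% up[c, ])
    if (!seen[p]) {
      up[p, ] <- Lc
      logscale[p] <- logscale[c]
      seen[p] <- TRUE
    } else {
      up[p, ] <- up[p, ] * Lc
      logscale[p] <- logscale[p] + logscale[c]
    }
    sc <- sum(up[p, ])
    if (sc <= 0) {
      logscale[p] <- -Inf
    } else {
      up[p, ] <- up[p, ] / sc
      logscale[p] <- logscale[p] + log(sc)
    }
  }
  root <- .root_node(tree)
  lnl <- log(sum(prior * up[root, ])) + logscale[root]
  list(up = up, logscale = logscale, lnl = lnl, pm = pm)
}

#' Log-likelihood of a two-state Markov model on a tree
#'
#' Felsenstein pruning over the closed-form 2-state transition probabilities.
#'
#' @param tree A `phylo` object.
#' @param tip_states Named vector (by tip label) or two-column data frame of
#'   0/1 states, one per tip.
#' @param q01,q10 Transition rates (per unit branch length) from state 0 to 1
#'   and 1 to 0.
#' @param root_prior `"flat"` (1/2, 1/2) or `"stationary"`.
#' @return Log-likelihood.
#' @export
mk2_loglik <- function(tree, tip_states, q01, q10,
                       root_prior = c("flat", "stationary")) {
  root_prior <- match.arg(root_prior)
  st <- .resolve_tip_states(tree, tip_states)
  prior <- .mk2_root_prior(root_prior, q01, q10)
  .mk2_pruning(tree, st, q01, q10, prior)$lnl
}

#' Fit a two-state Markov model and reconstruct marginal ancestral states
#'
#' Maximum-likelihood transition rates under the equal-rates (`ER`,
#' `q01 = q10`) or all-rates-different (`ARD`) model, by bounded optimization
#' on the log-rate scale from three log-spaced starts, followed by marginal
#' ancestral state probabilities at every node via the standard
#' re-rooting/marginalization pass.
#'
#' @inheritParams mk2_loglik
#' @param model `"ER"` or `"ARD"`.
#' @return An object of class `mk_fit`: a list with elements `rates`
#'   (`q01`, `q10`), `lnl`, `model`, `root_prior`, `marginals` (tibble with
#'   `node`, `p0`, `p1`), and `tree`.
#' @export
fit_mk2 <- function(tree, tip_states, model = c("ER", "ARD"),
                    root_prior = c("flat", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  st <- .resolve_tip_states(tree, tip_states)
  if (length(unique(st)) == 1) {
    warn("all tips share one state; rates are driven to the lower bound")
  }
  T <- tree_height(tree)
  lb <- log(1e-8)
  ub <- log(100 / T)
  nll <- function(lq) {
    q <- exp(lq)
    q01 <- q[1]
    q10 <- if (model == "ER") q[1] else q[2]
    prior <- .mk2_root_prior(root_prior, q01, q10)
    -.mk2_pruning(tree, st, q01, q10, prior)$lnl
  }
  np <- if (model == "ER") 1L else 2L
  starts <- log(exp(seq(lb, ub, length.out = 5))[c(2, 3, 4)])
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(rep(s, np), nll,
        method = "L-BFGS-B",
        lower = rep(lb, np), upper = rep(ub, np)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("all optimizer starts failed")
  q <- exp(best$par)
  q01 <- q[1]
  q10 <- if (model == "ER") q[1] else q[2]
  prior <- .mk2_root_prior(root_prior, q01, q10)
  marg <- .mk2_marginals(tree, st, q01, q10, prior)
  structure(
    list(
      rates = c(q01 = q01, q10 = q10), lnl = -best$value,
      model = model, root_prior = root_prior,
      prior = prior, marginals = marg, tree = tree, tip_states = st
    ),
    class = "mk_fit"
  )
}

# marginal state probabilities at every node: up-pass partials combined with
# a root-to-tip down-pass
.mk2_marginals <- function(tree, st, q01, q10, prior) {
  pr <- .mk2_pruning(tree, st, q01, q10, prior)
  n <- .n_nodes(tree)
  n_tip <- length(tree$tip.label)
  kids <- .children_list(tree)
  root <- .root_node(tree)
  down <- matrix(0, n, 2)
  down[root, ] <- prior
  pre <- .preorder_edges(tree)
  # factor contributed by child c to its parent: P_c %*% up_c (unscaled shape)
  fac <- matrix(1, n, 2)
  for (i in seq_len(n)) {
    if (i != root) fac[i, ] <- as.numeric(pr$pm[[i]] %*% pr$up[i, ])
  }
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]
    c <- pre[e, 2]
    sib <- setdiff(kids[[p]], c)
    base <- down[p, ]
    for (s in sib) base <- base * fac[s, ]
    dc <- as.numeric(t(pr$pm[[c]]) %*% base)
    s <- sum(dc)
    down[c, ] <- if (s > 0) dc / s else c(0.5, 0.5)
  }
  m <- pr$up * down
  rs <- rowSums(m)
  rs[rs <= 0] <- 1
  m <- m / rs
  tibble(node = seq_len(n), p0 = m[, 1], p1 = m[, 2])
}

#' Discretize marginal ancestral probabilities into node states
#'
#' Takes the arg-max state at every node; ties (within `1e-9`) are broken
#' towards the parent's state, which keeps the implied painting parsimonious.
#'
#' @param fit An `mk_fit` object.
#' @return Character vector of states (`"0"`/`"1"`), one per node, usable with
#'   [states_to_regime_map()].
#' @export
ancestral_states <- function(fit) {
  tree <- fit$tree
  m <- fit$marginals
  n <- .n_nodes(tree)
  states <- rep(NA_character_, n)
  root <- .root_node(tree)
  pick <- function(p0, p1, parent_state) {
    if (abs(p0 - p1) < 1e-9 && !is.na(parent_state)) return(parent_state)
    if (p1 > p0) "1" else "0"
  }
  states[root] <- pick(m$p0[root], m$p1[root], NA_character_)
  pre <- .preorder_edges(tree)
  for (e in seq_len(nrow(pre))) {
    c <- pre[e, 2]
    states[c] <- pick(m$p0[c], m$p1[c], states[pre[e, 1]])
  }
  states
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf(
    "Mk2 fit (%s, %s root prior)\n  q01 = %.6g, q10 = %.6g\n  lnL = %.4f\n",
    x$model, x$root_prior, x$rates[["q01"]], x$rates[["q10"]], x$lnl
  ))
  invisible(x)
}

#' @export
tidy.mk_fit <- function(x, ...) {
  tibble(
    term = c("q01", "q10"),
    estimate = unname(x$rates)
  )
}

#' @export
glance.mk_fit <- function(x, ...) {
  k <- if (x$model == "ER") 1L else 2L
  tibble(
    model = x$model, logLik = x$lnl, k = k,
    AICc = aicc(x$lnl, k, length(x$tree$tip.label))
  )
}
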