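# Reversible-jump MCMC over branch-specific Brownian rate paintings.
#
# The state is (S, r): a set of shift edges S (identified by the child node
# of each edge) inducing era-style rate classes, and one rate per class
# (class 0 = root/background). The target is the posterior
#   p(S, r | x)  propto  p(|S|) p(S | |S|) prod_c p(log r_c) L(x | S, r)
# with L the multi-rate Brownian likelihood marginalized over the root state
# under a flat prior (the contrast/REML likelihood), computed in O(n) by
# pruning. Number of shifts ~ truncated Poisson; shift locations uniform over
# edge subsets; log rates ~ Normal(log sigma2_hat_BM, sd). Birth proposals
# draw the new class rate from its prior, so the acceptance ratio reduces to
# the likelihood ratio times the Poisson ratio.

.rjmcmc_lnl <- function(ctx_post, stem_len, classes_by_child, rates, tip_var, x) {
  stem_var <- rates[classes_by_child + 1L] * stem_len
  out <- cpp_bm_pruning(
    ctx_post$n_nodes, ctx_post$n_tip,
    ctx_post$edge_parent, ctx_post$edge_child,
    stem_var, tip_var, x
  )
  c(reml = out[1], ml = out[1] - 0.5 * log(2 * pi * out[3]))
}

# classes indexed by child node id (class of the edge above each node)
.era_classes_by_child <- function(ctx_pre, shifts) {
  cls <- cpp_era_classes(
    ctx_pre$n_nodes, ctx_pre$root,
    ctx_pre$edge_parent, ctx_pre$edge_child, shifts
  )
  out <- integer(ctx_pre$n_nodes)
  out[ctx_pre$edge_child] <- cls
  out
}

#' Reversible-jump MCMC scan for Brownian rate shifts
#'
#' Samples the posterior over the number and placement of branch rate shifts
#' and the per-class rates of a multi-rate Brownian model. Proposals mix
#' shift birth (new class rate drawn from its prior), shift death, a move of
#' a shift to an adjacent edge, and a multiplicative log-normal rate update;
#' dimension changes use the exact Metropolis-Hastings ratio (the Jacobian is
#' 1 for prior-draw births).
#'
#' @param tree A `phylo` object.
#' @param data Trait data (tibble with `label`, `value`, optional `se`, or a
#'   named vector).
#' @param generations Total MCMC iterations (>= 1000).
#' @param thinning Record every `thinning`-th iteration.
#' @param burnin_frac Fraction of recorded samples discarded as burn-in.
#' @param seed Integer seed; recorded in the result.
#' @param priors List: `shift_rate` (Poisson mean of the number of shifts,
#'   default `log(2)`), `log_rate_mean` (default: log of the single-rate ML
#'   estimate), `log_rate_sd` (default 1.5).
#' @param allowed_edges Optional integer vector of child node ids to which
#'   shifts are restricted (default: every non-root edge).
#' @param proposal_sd Standard deviation of the log-normal rate update.
#' @return A `rate_scan` object: `branches` (tibble `node`, `shift_prob`,
#'   `median_rate`), `chain` (tibble per retained sample: `sample`,
#'   `generation`, `lnl`, `lnl_ml`, `n_classes`, `painting` hash),
#'   `rates_by_edge` (retained samples x edges matrix), `settings`, and
#'   acceptance diagnostics.
#' @export
run_rjmcmc <- function(tree, data, generations = 1e5, thinning = 100,
                       burnin_frac = 0.25, seed = NULL, priors = list(),
                       allowed_edges = NULL, proposal_sd = 0.35) {
  if (generations < 1000) abort("`generations` must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  td <- .resolve_trait_data(tree, data)
  tip_var <- td$se^2
  ctx_post <- .postorder_ctx(tree)
  pre <- .preorder_edges(tree)
  ctx_pre <- list(
    n_nodes = .n_nodes(tree), root = .root_node(tree),
    edge_parent = pre[, 1], edge_child = pre[, 2]
  )
  stem_len <- .stem_lengths(tree)
  edges_all <- pre[, 2]
  allowed <- as.integer(allowed_edges %||% edges_all)
  m_edges <- length(allowed)
  T <- tree_height(tree)

  # weakly informative defaults centred on the single-rate estimate
  bm1 <- optimize(
    function(ls2) {
      -.rjmcmc_lnl(ctx_post, stem_len, integer(ctx_pre$n_nodes), exp(ls2), tip_var, td$x)[["ml"]]
    },
    log(c(1e-8, 100 * var(td$x) / T))
  )
  pri <- list(
    shift_rate = priors$shift_rate %||% log(2),
    log_rate_mean = priors$log_rate_mean %||% bm1$minimum,
    log_rate_sd = priors$log_rate_sd %||% 1.5
  )

  # adjacency among edges (sharing a node), for move proposals
  par_vec <- .parent_vec(tree)
  kids <- .children_list(tree)
  adjacent <- function(child, shifts) {
    p <- par_vec[child]
    cand <- c(
      if (p != ctx_pre$root) p,
      kids[[p]][kids[[p]] != child],
      kids[[child]]
    )
    setdiff(intersect(cand, allowed), shifts)
  }

  lprior_rates <- function(lr) {
    sum(dnorm(lr, pri$log_rate_mean, pri$log_rate_sd, log = TRUE))
  }
  lprior_k <- function(k) k * log(pri$shift_rate) - lfactorial(k)

  # state
  shifts <- integer(0)
  lrates <- pri$log_rate_mean # class 0
  classes <- .era_classes_by_child(ctx_pre, shifts)
  lnl <- .rjmcmc_lnl(ctx_post, stem_len, classes, exp(lrates), tip_var, td$x)

  n_keep <- floor(generations / thinning)
  rec_lnl <- rec_ml <- numeric(n_keep)
  rec_k <- integer(n_keep)
  rec_paint <- character(n_keep)
  rec_rates <- matrix(NA_real_, n_keep, length(edges_all))
  acc <- rej <- c(birth = 0, death = 0, move = 0, rate = 0)
  consecutive_rej <- 0

  for (g in seq_len(generations)) {
    u <- runif(1)
    type <- if (u < 0.25) "birth" else if (u < 0.5) "death" else if (u < 0.7) "move" else "rate"
    accepted <- FALSE
    k <- length(shifts)
    if (type == "birth" && k < m_edges) {
      free <- setdiff(allowed, shifts)
      e_new <- free[sample.int(length(free), 1)]
      lr_new <- rnorm(1, pri$log_rate_mean, pri$log_rate_sd)
      shifts2 <- c(shifts, e_new)
      classes2 <- .era_classes_by_child(ctx_pre, shifts2)
      lrates2 <- c(lrates, lr_new)
      lnl2 <- .rjmcmc_lnl(ctx_post, stem_len, classes2, exp(lrates2), tip_var, td$x)
      lacc <- (lnl2[["reml"]] - lnl[["reml"]]) + log(pri$shift_rate) - log(k + 1)
      if (log(runif(1)) < lacc) {
        shifts <- shifts2
        classes <- classes2
        lrates <- lrates2
        lnl <- lnl2
        accepted <- TRUE
      }
    } else if (type == "death" && k > 0) {
      j <- sample.int(k, 1)
      shifts2 <- shifts[-j]
      classes2 <- .era_classes_by_child(ctx_pre, shifts2)
      lrates2 <- lrates[-(j + 1)]
      lnl2 <- .rjmcmc_lnl(ctx_post, stem_len, classes2, exp(lrates2), tip_var, td$x)
      lacc <- (lnl2[["reml"]] - lnl[["reml"]]) - log(pri$shift_rate) + log(k)
      if (log(runif(1)) < lacc) {
        shifts <- shifts2
        classes <- classes2
        lrates <- lrates2
        lnl <- lnl2
        accepted <- TRUE
      }
    } else if (type == "move" && k > 0) {
      j <- sample.int(k, 1)
      cand <- adjacent(shifts[j], shifts)
      if (length(cand) > 0) {
        e_new <- cand[sample.int(length(cand), 1)]
        shifts2 <- shifts
        shifts2[j] <- e_new
        n_rev <- length(adjacent(e_new, shifts2))
        classes2 <- .era_classes_by_child(ctx_pre, shifts2)
        lnl2 <- .rjmcmc_lnl(ctx_post, stem_len, classes2, exp(lrates), tip_var, td$x)
        lacc <- (lnl2[["reml"]] - lnl[["reml"]]) +
          log(length(cand)) - log(n_rev)
        if (is.finite(lacc) && log(runif(1)) < lacc) {
          shifts <- shifts2
          classes <- classes2
          lnl <- lnl2
          accepted <- TRUE
        }
      }
    } else if (type == "rate") {
      j <- sample.int(k + 1, 1)
      lrates2 <- lrates
      lrates2[j] <- lrates2[j] + rnorm(1, 0, proposal_sd)
      lnl2 <- .rjmcmc_lnl(ctx_post, stem_len, classes, exp(lrates2), tip_var, td$x)
      lacc <- (lnl2[["reml"]] - lnl[["reml"]]) +
        dnorm(lrates2[j], pri$log_rate_mean, pri$log_rate_sd, log = TRUE) -
        dnorm(lrates[j], pri$log_rate_mean, pri$log_rate_sd, log = TRUE)
      if (log(runif(1)) < lacc) {
        lrates <- lrates2
        lnl <- lnl2
        accepted <- TRUE
      }
    }
    if (accepted) {
      acc[type] <- acc[type] + 1
      consecutive_rej <- 0
    } else {
      rej[type] <- rej[type] + 1
      consecutive_rej <- consecutive_rej + 1
      if (consecutive_rej >= 1000) {
        abort(paste0(
          "rjMCMC stalled: 1000 consecutive rejected proposals at generation ",
          g, " (k = ", k, ", lnL = ", signif(lnl[["reml"]], 6), ")"
        ))
      }
    }
    if (g %% thinning == 0) {
      i <- g %/% thinning
      rec_lnl[i] <- lnl[["reml"]]
      rec_ml[i] <- lnl[["ml"]]
      rec_k[i] <- length(shifts) + 1L
      srt <- sort(shifts)
      rec_paint[i] <- paste(srt, collapse = ",")
      rec_rates[i, ] <- exp(lrates)[classes[edges_all] + 1L]
    }
  }

  drop <- seq_len(floor(n_keep * burnin_frac))
  keep <- setdiff(seq_len(n_keep), drop)
  paint_kept <- rec_paint[keep]
  shift_sets <- strsplit(paint_kept, ",", fixed = TRUE)
  shift_tab <- table(factor(
    unlist(lapply(shift_sets, function(s) s[nzchar(s)])),
    levels = as.character(edges_all)
  ))
  branches <- tibble(
    node = edges_all,
    shift_prob = as.numeric(shift_tab) / length(keep),
    median_rate = apply(rec_rates[keep, , drop = FALSE], 2, median)
  )
  chain <- tibble(
    sample = seq_along(keep),
    generation = keep * thinning,
    lnl = rec_lnl[keep], lnl_ml = rec_ml[keep],
    n_classes = rec_k[keep], painting = paint_kept
  )
  structure(
    list(
      branches = branches, chain = chain,
      rates_by_edge = rec_rates[keep, , drop = FALSE],
      edge_nodes = edges_all,
      settings = list(
        generations = generations, thinning = thinning,
        burnin_frac = burnin_frac, seed = seed, priors = pri,
        proposal_sd = proposal_sd
      ),
      acceptance = tibble(
        proposal = names(acc),
        accepted = as.numeric(acc), rejected = as.numeric(rej)
      ),
      n = ctx_post$n_tip, tree = tree
    ),
    class = "rate_scan"
  )
}

#' ML multi-rate Brownian fit for a fixed shift configuration
#'
#' The non-censored maximum-likelihood analogue of the rjMCMC: rate classes
#' are the era-style painting induced by `shift_nodes`, and one rate per
#' class plus the root state are estimated (`k = #classes + 1`).
#'
#' @param tree A `phylo` object.
#' @param data Trait data.
#' @param shift_nodes Child node ids of the shift edges (possibly empty, in
#'   which case the fit equals the single-rate Brownian fit).
#' @param se_mode Passed to [fit_trait_model()].
#' @return A `trait_fit` (family `BMS`, or `BM1` when `shift_nodes` is
#'   empty).
#' @export
map_painting_ml <- function(tree, data, shift_nodes = integer(0),
                            se_mode = c("none", "fixed", "estimate")) {
  se_mode <- match.arg(se_mode)
  if (length(shift_nodes) == 0) {
    return(fit_trait_model(tree, data, "BM1", se_mode = se_mode))
  }
  painting <- shift_branches_to_era_map(tree, shift_nodes)
  if (length(regime_levels(painting)) != length(shift_nodes) + 1L) {
    abort("a rate class contains zero total branch length")
  }
  fit_trait_model(tree, data, "BMS", painting = painting, se_mode = se_mode)
}

#' Best-sample AICc of an rjMCMC chain
#'
#' Evaluates every retained sample's AICc from its profiled-root ML
#' log-likelihood with `k = #classes + 1` parameters and returns the best
#' (smallest) value, the chain-based counterpart of the era-map ML refit.
#'
#' @param result A `rate_scan`.
#' @return AICc of the best retained sample.
#' @export
best_sample_aic <- function(result) {
  ch <- result$chain
  if (nrow(ch) == 0) abort("empty chain")
  min(vapply(
    seq_len(nrow(ch)),
    function(i) aicc(ch$lnl_ml[i], ch$n_classes[i] + 1L, result$n),
    0
  ))
}

#' @export
print.rate_scan <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<rate_scan>  %d generations, thinning %d, burn-in %.0f%% (%d samples kept)\n",
    s$generations, s$thinning, 100 * s$burnin_frac, nrow(x$chain)
  ))
  top <- dplyr::arrange(x$branches, dplyr::desc(.data$shift_prob))
  cat("top shift probabilities:\n")
  print(utils::head(as.data.frame(top), 5))
  invisible(x)
}

#' @export
tidy.rate_scan <- function(x, ...) x$branches

#' @export
glance.rate_scan <- function(x, ...) {
  tibble(
    samples = nrow(x$chain),
    mean_n_classes = mean(x$chain$n_classes),
    max_shift_prob = max(x$branches$shift_prob),
    best_AICc = best_sample_aic(x)
  )
}

#' Write rjMCMC outputs as TSV
#'
#' `write_rate_scan()` writes the per-branch summaries (`<file>`), and the
#' chain log (`<file>.chain.tsv`).
#'
#' @param x A `rate_scan`.
#' @param file Path for the branch summary TSV.
#' @return The input, invisibly.
#' @export
write_rate_scan <- function(x, file) {
  readr::write_tsv(x$branches, file)
  readr::write_tsv(x$chain, paste0(file, ".chain.tsv"))
  invisible(x)
}
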