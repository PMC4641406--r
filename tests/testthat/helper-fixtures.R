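# Shared fixtures and independent oracles. The oracles deliberately avoid the
# package's recursion code paths: covariances are built per tip pair by
# explicit path sums with numerically integrated within-segment variance, and
# the Gaussian density uses determinant()/solve() instead of Cholesky.

tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
star3 <- function() read_newick("(A:1,B:1,C:1);")
tree2 <- function() read_newick("(A:1,B:1);")

rand_yule <- function(n, seed, rescale = TRUE) {
  yule_tree(n, birth_rate = 1, seed = seed, rescale = rescale)
}

# random 2-regime painting: era shift on a random internal edge, optionally
# with the longest edge split mid-way into the other regime (exercises
# multi-segment edges)
random_painting <- function(tree, seed, split_edge = TRUE) {
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  internals <- setdiff(seq_len(n_tip + tree$Nnode), c(seq_len(n_tip), n_tip + 1L))
  shift <- if (length(internals) > 0) sample(internals, 1) else integer(0)
  pm <- shift_branches_to_era_map(tree, shift)
  if (split_edge && runif(1) < 0.5) {
    dur <- pm$end - pm$start
    j <- which.max(dur)
    mid <- (pm$start[j] + pm$end[j]) / 2
    other <- setdiff(c("0", "1"), pm$regime[j])[1]
    extra <- pm[j, ]
    pm$end[j] <- mid
    extra$start <- mid
    extra$regime <- other
    pm <- regime_map(tree, c(pm$node, extra$node), c(pm$start, extra$start),
                     c(pm$end, extra$end), c(pm$regime, extra$regime))
  }
  pm
}

# random parameters for a family over the painting's regimes
random_spec <- function(family, painting, seed) {
  set.seed(seed)
  reg <- regime_levels(painting)
  m <- length(reg)
  rs2 <- function(k) setNames(exp(runif(k, log(0.3), log(3))), if (k > 1) reg else NULL)
  ral <- function(k) setNames(exp(runif(k, log(0.5), log(4))), if (k > 1) reg else NULL)
  rth <- function(k) setNames(runif(k, -2, 2), if (k > 1) reg else NULL)
  switch(family,
    BM1 = model_spec("BM1", sigma2 = rs2(1), x0 = runif(1, -1, 1)),
    BMS = model_spec("BMS", sigma2 = rs2(m), x0 = runif(1, -1, 1), regimes = reg),
    ACDC = model_spec("ACDC", sigma2 = rs2(1), r = runif(1, -2, 2), x0 = runif(1, -1, 1)),
    OU1 = model_spec("OU1", sigma2 = rs2(1), alpha = ral(1), theta = rth(1)),
    OUM = model_spec("OUM", sigma2 = rs2(1), alpha = ral(1), theta = rth(m), regimes = reg),
    OUMV = model_spec("OUMV", sigma2 = rs2(m), alpha = ral(1), theta = rth(m), regimes = reg),
    OUMA = model_spec("OUMA", sigma2 = rs2(1), alpha = ral(m), theta = rth(m), regimes = reg),
    OUMVA = model_spec("OUMVA", sigma2 = rs2(m), alpha = ral(m), theta = rth(m), regimes = reg)
  )
}

# ---- brute-force oracle ----------------------------------------------------

# per-node path from the root: ordered list of painting segments
.oracle_paths <- function(tree, painting) {
  pm <- dplyr::arrange(tibble::as_tibble(painting), node, start)
  par <- integer(length(tree$tip.label) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  root <- length(tree$tip.label) + 1L
  path_of <- function(nd) {
    segs <- list()
    while (nd != root) {
      segs <- c(list(pm[pm$node == nd, , drop = FALSE]), segs)
      nd <- par[nd]
    }
    do.call(rbind, segs)
  }
  path_of
}

# segment parameters under a spec (single source of truth for the oracle:
# read straight off the model_spec definition, not .spec_segments)
.oracle_seg_pars <- function(spec, regime) {
  fam <- spec$family
  pick <- function(p) if (length(p) > 1) p[[regime]] else p[[1]]
  if (fam %in% c("OU1", "OUM", "OUMV", "OUMA", "OUMVA")) {
    list(alpha = pick(spec$alpha), theta = pick(spec$theta),
         sigma2f = local({ s <- pick(spec$sigma2); function(t) s }))
  } else if (fam == "ACDC") {
    list(alpha = 0, theta = NA_real_,
         sigma2f = local({ s <- spec$sigma2; r <- spec$r; function(t) s * exp(r * t) }))
  } else {
    s2 <- if (length(spec$sigma2) > 1) spec$sigma2[[regime]] else spec$sigma2[[1]]
    list(alpha = 0, theta = NA_real_, sigma2f = local({ s <- s2; function(t) s }))
  }
}

# variance injected by one segment, discounted to the segment end:
# integral of sigma2(u) exp(-2 alpha (end - u)) du, by numeric quadrature
.oracle_seg_var <- function(sp, s0, s1) {
  stats::integrate(function(u) sp$sigma2f(u) * exp(-2 * sp$alpha * (s1 - u)),
                   s0, s1, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# brute-force mean vector and covariance matrix of the tips
oracle_moments <- function(tree, painting, spec) {
  n_tip <- length(tree$tip.label)
  path_of <- .oracle_paths(tree, painting)
  paths <- lapply(seq_len(n_tip), path_of)
  root_regime <- {
    pre <- tree$edge[tree$edge[, 1] == n_tip + 1L, 2][1]
    seg1 <- painting[painting$node == pre, ]
    seg1$regime[which.min(seg1$start)]
  }
  x0 <- if (is.null(spec$x0)) {
    th <- spec$theta
    if (length(th) > 1) th[[root_regime]] else th[[1]]
  } else {
    spec$x0
  }
  mean_of <- function(path) {
    m <- x0
    for (i in seq_len(nrow(path))) {
      sp <- .oracle_seg_pars(spec, path$regime[i])
      dt <- path$end[i] - path$start[i]
      if (sp$alpha > 0) m <- sp$theta + (m - sp$theta) * exp(-sp$alpha * dt)
    }
    m
  }
  # decay from the end of segment k (on a path) to the path's tip
  decay_after <- function(path, k) {
    d <- 0
    for (i in seq_len(nrow(path))) {
      if (i <= k) next
      sp <- .oracle_seg_pars(spec, path$regime[i])
      d <- d - sp$alpha * (path$end[i] - path$start[i])
    }
    exp(d)
  }
  seg_key <- function(path, i) paste(path$node[i], path$start[i], sep = "@")
  V <- matrix(0, n_tip, n_tip)
  for (i in seq_len(n_tip)) {
    for (j in seq_len(i)) {
      pi <- paths[[i]]
      pj <- paths[[j]]
      keys_j <- vapply(seq_len(nrow(pj)), function(k) seg_key(pj, k), "")
      cov_ij <- 0
      for (k in seq_len(nrow(pi))) {
        kj <- match(seg_key(pi, k), keys_j)
        if (is.na(kj)) next # segment not shared
        sp <- .oracle_seg_pars(spec, pi$regime[k])
        v <- .oracle_seg_var(sp, pi$start[k], pi$end[k])
        cov_ij <- cov_ij + v * decay_after(pi, k) * decay_after(pj, kj)
      }
      V[i, j] <- V[j, i] <- cov_ij
    }
  }
  mu <- vapply(paths, mean_of, 0)
  names(mu) <- tree$tip.label
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  list(mean = mu, cov = V)
}

# Gaussian log-density via determinant/solve (independent of chol path)
oracle_mvn_lnl <- function(x, mu, V) {
  n <- length(x)
  d <- x - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + as.numeric(t(d) %*% solve(V, d)))
}

# simulate BM tip data on a fixed tree via the (independent) vcv Cholesky
sim_bm_tips <- function(tree, sigma2 = 1, x0 = 0) {
  C <- ape::vcv(tree)
  L <- chol(sigma2 * C)
  setNames(x0 + as.numeric(t(L) %*% rnorm(nrow(C))), tree$tip.label)
}

all_families <- c("BM1", "BMS", "ACDC", "OU1", "OUM", "OUMV", "OUMA", "OUMVA")
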