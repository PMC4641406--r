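test_that("the OU bridge is endpoint-exact and fixes the optimum", {
  for (a in c(1e-6, 0.5, 3, 50, 500)) {
    expect_equal(ou_bridge(0.3, -1.2, 0.2, 1.7, theta = 0.5, alpha = a, t = 0.2), 0.3)
    expect_equal(ou_bridge(0.3, -1.2, 0.2, 1.7, theta = 0.5, alpha = a, t = 1.7), -1.2)
    expect_equal(ou_bridge(0.5, 0.5, 0, 1, theta = 0.5, alpha = a, t = 0.37), 0.5)
  }
  # the as-printed variant misses the right endpoint whenever x_i != x_j
  expect_gt(
    abs(ou_bridge(0, 1, 0, 1, 0, 2, 1, variant = "printed") - 1), 0.1
  )
  expect_error(ou_bridge(0, 1, 0, 1, 0, 1, t = 1.5), "outside")
})

test_that("the worked bridge value and the linear limit hold", {
  expect_equal(
    ou_bridge(0, 1, 0, 1, theta = 0, alpha = 1, t = 0.5),
    sinh(0.5) / sinh(1),
    tolerance = 1e-12
  )
  expect_equal(sinh(0.5) / sinh(1), 0.44341, tolerance = 1e-5)
  grid <- seq(0.05, 0.95, length.out = 1000)
  expect_equal(
    ou_bridge(0.2, 1.4, 0, 1, theta = -3, alpha = 1e-8, t = grid),
    linear_bridge(0.2, 1.4, 0, 1, grid),
    tolerance = 1e-6
  )
  # affine invariance of the linear bridge
  expect_equal(
    linear_bridge(0.2 + 5, 1.4 + 5, 0, 1, grid),
    linear_bridge(0.2, 1.4, 0, 1, grid) + 5
  )
  expect_equal(linear_bridge(0, 1, 0, 1, 0.5), 0.5)
  expect_error(linear_bridge(0, 1, 0, 1, 2), "outside")
})

test_that("interpolation recovers node values and counts lineages correctly", {
  tr <- rand_yule(10, seed = 51)
  pm <- random_painting(tr, seed = 51)
  spec <- random_spec("OUMVA", pm, seed = 51)
  set.seed(51)
  real <- simulate_realization(tr, pm, spec, root_value = 0)
  h <- node_heights(tr)
  il <- interpolate_lineages(tr, pm, spec, real, grid = sort(unique(h)))
  # closed-left convention: a node's value is carried by its child edges at
  # the node's height (tips are covered by their own edge at the tip time)
  for (nd in 1:10) {
    row <- il[abs(il$time - h[nd]) < 1e-12 & il$node == nd, ]
    expect_equal(row$value, unname(real$values[nd]), tolerance = 1e-10)
  }
  for (nd in 12:19) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    for (kid in kids) {
      row <- il[abs(il$time - h[nd]) < 1e-12 & il$node == kid, ]
      expect_equal(row$value, unname(real$values[nd]), tolerance = 1e-10)
    }
  }
  # lineage count at time t equals the number of edges covering t
  # (closed-left convention; tips included at the final time)
  grid <- seq(0, tree_height(tr), length.out = 33)
  il2 <- interpolate_lineages(tr, pm, spec, real, grid)
  par <- integer(19)
  par[tr$edge[, 2]] <- tr$edge[, 1]
  for (t in grid) {
    n_expect <- sum(vapply(seq_len(19), function(nd) {
      nd != 11 && h[par[nd]] <= t + 1e-12 &&
        (t < h[nd] - 1e-12 || (nd <= 10 && abs(t - h[nd]) < 1e-12))
    }, TRUE))
    expect_equal(sum(abs(il2$time - t) < 1e-12), n_expect)
  }
})

test_that("bridged interior values bow towards the optimum", {
  tr <- tree2()
  pm <- one_regime_map(tr)
  spec <- model_spec("OU1", sigma2 = 1, alpha = 4, theta = 5)
  real <- structure(
    list(
      values = setNames(c(1, 1, 1), c("1", "2", "3")),
      tip_values = c(A = 1, B = 1),
      boundaries = tibble::tibble(node = integer(0), height = numeric(0), value = numeric(0)),
      tree = tr, spec = spec
    ),
    class = "trait_realization"
  )
  il <- interpolate_lineages(tr, pm, spec, real, grid = 0.5)
  expect_true(all(il$value > 1)) # pulled towards theta = 5
  # constant realization stays constant when theta equals it
  spec2 <- model_spec("OU1", sigma2 = 1, alpha = 4, theta = 1)
  il2 <- interpolate_lineages(tr, pm, spec2, real, grid = 0.5)
  expect_equal(il2$value, rep(1, 2))
})

test_that("envelopes degenerate correctly and start at the root quantiles", {
  tr <- rand_yule(6, seed = 61)
  pm <- one_regime_map(tr)
  spec <- model_spec("BM1", sigma2 = 1e-300, x0 = 0)
  ens <- simulate_ensemble(tr, pm, spec, root_mean = 3, root_sd = 0, n_real = 20, seed = 1)
  env <- envelope(ens)
  expect_equal(env$lower, rep(3, nrow(env)), tolerance = 1e-7)
  expect_equal(env$upper, rep(3, nrow(env)), tolerance = 1e-7)

  # at t = 0 the envelope equals the quantiles of the sampled root states
  spec2 <- model_spec("BM1", sigma2 = 0.5, x0 = 0)
  ens2 <- simulate_ensemble(tr, pm, spec2, root_mean = 0, root_sd = 2, n_real = 400, seed = 2)
  env2 <- envelope(ens2)
  expect_equal(env2$lower[1], quantile(ens2$roots, 0.025, names = FALSE))
  expect_equal(env2$upper[1], quantile(ens2$roots, 0.975, names = FALSE))

  # invariance to realization order / duplication
  ens3 <- ens2
  ens3$values <- ens3$values[400:1, ]
  ens3$boundary_values <- ens3$boundary_values[400:1, , drop = FALSE]
  ens3$roots <- ens3$roots[400:1]
  expect_equal(envelope(ens3)$lower, env2$lower)
  expect_equal(envelope(ens3)$upper, env2$upper)
})

test_that("Brownian envelope width is nondecreasing through time", {
  tr <- rand_yule(15, seed = 63)
  pm <- one_regime_map(tr)
  ens <- simulate_ensemble(tr, pm, model_spec("BM1", sigma2 = 1, x0 = 0),
    root_mean = 0, n_real = 1000, seed = 3
  )
  env <- envelope(ens)
  width <- env$upper - env$lower
  # allow tiny Monte Carlo wiggles
  expect_true(all(diff(width) > -0.02))
  expect_gt(width[length(width)], width[1])
})

test_that("stationary OU envelopes concentrate at theta +/- 1.96 sd", {
  tr <- read_newick("((A:3,B:3):1,(C:3.5,D:3.5):0.5);")
  pm <- one_regime_map(tr)
  alpha <- 6
  sigma2 <- 2
  theta <- 1
  spec <- model_spec("OU1", sigma2 = sigma2, alpha = alpha, theta = theta)
  ens <- simulate_ensemble(tr, pm, spec, root_mean = theta, n_real = 2000, seed = 5)
  env <- envelope(ens)
  tip <- nrow(env)
  sd_st <- sqrt(sigma2 / (2 * alpha))
  # per-realization max over 4 tips: envelope upper ~ upper quantile of max
  expect_lt(abs(env$upper[tip] - theta), 4 * sd_st)
  expect_gt(env$upper[tip], theta + sd_st)
  expect_lt(env$lower[tip], theta - sd_st)
})

test_that("traitgram polylines are straight for BM, bowed for strong OU", {
  tr <- rand_yule(8, seed = 65)
  pm <- one_regime_map(tr)
  spec_bm <- model_spec("BM1", sigma2 = 1, x0 = 0)
  set.seed(6)
  real <- simulate_realization(tr, pm, spec_bm, 0)
  tl <- traitgram_lines(tr, pm, spec_bm, real, points_per_edge = 9)
  for (nd in unique(tl$node)) {
    seg <- tl[tl$node == nd, ]
    resid <- lm(value ~ time, data = seg)$residuals
    expect_lt(max(abs(resid)), 1e-12)
  }
  # endpoints equal the realization's node values
  h <- node_heights(tr)
  for (nd in unique(tl$node)) {
    seg <- tl[tl$node == nd, ]
    expect_equal(seg$value[which.max(seg$time)], unname(real$values[nd]),
      tolerance = 1e-12
    )
  }
  # strong-alpha OU far from theta: deviation from the chord, towards theta
  spec_ou <- model_spec("OU1", sigma2 = 1e-4, alpha = 8, theta = 10)
  real2 <- simulate_realization(tr, pm, spec_ou, 0)
  # overwrite with a flat trajectory far from the optimum
  real2$values[] <- 0
  real2$boundaries$value <- rep(0, nrow(real2$boundaries))
  tl2 <- traitgram_lines(tr, pm, spec_ou, real2, points_per_edge = 9)
  interior <- tl2[!tl2$time %in% h, ]
  expect_gt(max(interior$value), 0.05) # bows towards theta = 10
  expect_true(all(interior$value >= -1e-9))
})

test_that("envelope output and plots are well-formed", {
  tr <- rand_yule(6, seed = 67)
  pm <- random_painting(tr, seed = 67)
  spec <- random_spec("OUM", pm, seed = 67)
  ens <- simulate_ensemble(tr, pm, spec,
    root_mean = 0, n_real = 30, seed = 7
  )
  env <- envelope(ens)
  expect_true(all(env$lower <= env$upper + 1e-12))
  expect_true(all(diff(env$time) > 0))
  expect_equal(env$time[1], 0)
  expect_equal(env$time[nrow(env)], tree_height(tr))
  p1 <- autoplot(env)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_traitgram(ens)
  expect_s3_class(p2, "ggplot")
})
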