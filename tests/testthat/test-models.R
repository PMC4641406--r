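test_that("trait moments match closed-form cases", {
  tr <- tree3()
  pm <- one_regime_map(tr)
  mo <- trait_moments(tr, pm, model_spec("BM1", sigma2 = 1, x0 = 0))
  expect_equal(unname(diag(mo$cov)), rep(2, 3))
  expect_equal(mo$cov["A", "B"], 1)
  expect_equal(mo$cov["A", "C"], 0)

  st <- star3()
  mo2 <- trait_moments(
    st, one_regime_map(st),
    model_spec("OU1", sigma2 = 2, alpha = 1, theta = 0.3)
  )
  expect_equal(unname(diag(mo2$cov)), rep((1 - exp(-2)), 3), tolerance = 1e-12)
  expect_equal(mo2$cov["A", "B"], 0)
  expect_equal(unname(mo2$mean), rep(0.3, 3)) # root starts at theta

  # 2-tip star, per-edge rates 1 and 4
  two <- tree2()
  pm2 <- states_to_regime_map(two, c("1" = "a", "2" = "b", "3" = "a"))
  mo3 <- trait_moments(
    two, pm2,
    model_spec("BMS", sigma2 = c(a = 1, b = 4), x0 = 0, regimes = c("a", "b"))
  )
  expect_equal(unname(diag(mo3$cov)), c(1, 4))
  expect_equal(mo3$cov["A", "B"], 0)
})

test_that("segment-recursion likelihood equals the brute-force oracle", {
  # subset of the full acceptance sweep: a few random trees/paintings per family
  n_case <- 0
  for (seed in 1:5) {
    tr <- rand_yule(sample(4:8, 1), seed = 600 + seed)
    pm <- random_painting(tr, seed = 600 + seed)
    for (fam in all_families) {
      spec <- random_spec(fam, pm, seed = 700 + seed)
      set.seed(800 + seed)
      x <- setNames(rnorm(length(tr$tip.label)), tr$tip.label)
      orc <- oracle_moments(tr, pm, spec)
      expect_equal(
        loglik(tr, pm, spec, x),
        oracle_mvn_lnl(x, orc$mean, orc$cov),
        tolerance = 1e-8
      )
      n_case <- n_case + 1
    }
  }
  expect_equal(n_case, 40L)
})

test_that("closed-form likelihood values are exact", {
  two <- tree2()
  pm <- one_regime_map(two)
  expect_equal(
    loglik(two, pm, model_spec("BM1", sigma2 = 1, x0 = 0), c(A = 0, B = 0)),
    -log(2 * pi),
    tolerance = 1e-12
  )
  # data at the model mean: lnl = -(n log 2pi + log|V|)/2
  tr <- rand_yule(8, seed = 11)
  pm2 <- one_regime_map(tr)
  spec <- model_spec("OU1", sigma2 = 1.3, alpha = 2, theta = 0.7)
  mo <- trait_moments(tr, pm2, spec)
  expect_equal(
    loglik(tr, pm2, spec, mo$mean),
    -0.5 * (8 * log(2 * pi) + as.numeric(determinant(mo$cov)$modulus)),
    tolerance = 1e-10
  )
})

test_that("nested families collapse onto each other", {
  tr <- rand_yule(12, seed = 13)
  pm <- random_painting(tr, seed = 13, split_edge = FALSE)
  set.seed(13)
  x <- setNames(rnorm(12), tr$tip.label)
  bm <- loglik(tr, pm, model_spec("BM1", sigma2 = 1.4, x0 = 0.2), x)
  # OU1 -> BM1 as alpha -> 0 (root tied to theta = x0)
  ou <- loglik(
    tr, pm, model_spec("OU1", sigma2 = 1.4, alpha = 1e-10, theta = 0.2), x
  )
  expect_equal(ou, bm, tolerance = 1e-6)
  # ACDC with r = 0 is exactly BM1
  expect_equal(
    loglik(tr, pm, model_spec("ACDC", sigma2 = 1.4, r = 0, x0 = 0.2), x),
    bm
  )
  # OUM with equal optima collapses to OU1 exactly
  ou1 <- loglik(tr, pm, model_spec("OU1", sigma2 = 1, alpha = 2, theta = 0.5), x)
  oum <- loglik(
    tr, pm,
    model_spec("OUM",
      sigma2 = 1, alpha = 2, theta = c("0" = 0.5, "1" = 0.5),
      regimes = c("0", "1")
    ), x
  )
  expect_equal(oum, ou1, tolerance = 1e-12)
})

test_that("likelihood is invariant to tip relabeling and explicit SE matches V + s2 I", {
  tr <- rand_yule(10, seed = 17)
  pm <- one_regime_map(tr)
  spec <- model_spec("OU1", sigma2 = 1, alpha = 1.5, theta = 0)
  set.seed(17)
  x <- setNames(rnorm(10), tr$tip.label)
  expect_equal(loglik(tr, pm, spec, x), loglik(tr, pm, spec, x[sample(names(x))]))

  s <- 0.4
  dat <- tibble::tibble(label = names(x), value = unname(x), se = s)
  mo <- trait_moments(tr, pm, spec)
  expect_equal(
    loglik(tr, pm, spec, dat),
    oracle_mvn_lnl(x, mo$mean, mo$cov + diag(s^2, 10)),
    tolerance = 1e-10
  )
})

test_that("AICc and Akaike weights follow their closed forms", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_error(aicc(0, 9, 10), "undefined")

  mk_fit_stub <- function(lnl, k, n = 50, fam = "BM1") {
    structure(
      list(family = fam, lnl = lnl, k = k, n = n, aicc = aicc(lnl, k, n)),
      class = "trait_fit"
    )
  }
  # AICc difference of 2: weights e^{-1}-ratio
  f1 <- mk_fit_stub(-10, 2)
  f2 <- mk_fit_stub(-11, 2)
  cmp <- compare_models(a = f1, b = f2)
  expect_equal(cmp$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(cmp$weight[1], 0.7311, tolerance = 1e-4)
  expect_equal(cmp$delta_AICc[1], 0)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)

  # equal AICc: equal weights, fewer-parameter model listed first
  f3 <- mk_fit_stub(-10, 2)
  lnl4 <- -(aicc(-10, 2, 50) - 2 * 3 - 2 * 3 * 4 / 46) / 2
  f4 <- mk_fit_stub(lnl4, 3) # same AICc at n = 50
  cmp2 <- compare_models(k2 = f3, k3 = f4)
  expect_equal(cmp2$weight, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(cmp2$model[1], "k2")

  # weights monotone decreasing in delta; adding a worse model keeps ranking
  f5 <- mk_fit_stub(-30, 2)
  cmp3 <- compare_models(a = f1, b = f2, c = f5)
  expect_true(all(diff(cmp3$weight) <= 0))
  expect_equal(cmp3$model[1:2], cmp$model[1:2])
})

test_that("ML fits recover generating parameters and respect nesting", {
  ds <- make_recovery_dataset("BM1", list(sigma2 = 1, x0 = 0), 200, "none", seed = 31)
  f <- fit_trait_model(ds$tree, ds$traits, "BM1")
  expect_gt(f$spec$sigma2, 0.7)
  expect_lt(f$spec$sigma2, 1.3)
  expect_equal(f$k, 2)
  expect_equal(f$aicc, aicc(f$lnl, 2, 200))

  # OU1 nests BM1: its ML likelihood can never fall below BM1's, and on
  # Brownian data the gain from the extra mean-reversion is marginal
  fo <- fit_trait_model(ds$tree, ds$traits, "OU1")
  expect_gte(fo$lnl, f$lnl - 1e-6)
  expect_lt(fo$lnl - f$lnl, 2)

  # fitted OU likelihood should beat the generating parameters' likelihood
  ds2 <- make_recovery_dataset("OUM",
    list(sigma2 = 1, alpha = 3, theta = c("0" = -1, "1" = 1)),
    100, "clade", seed = 37
  )
  fm <- fit_trait_model(ds2$tree, ds2$traits, "OUM", painting = ds2$painting)
  lnl_truth <- loglik(
    ds2$tree, ds2$painting, ds2$spec,
    setNames(ds2$traits$value, ds2$traits$label)
  )
  expect_gte(fm$lnl, lnl_truth - 1e-6)
  expect_equal(fm$k, 4)
})

test_that("measurement-error modes behave sensibly", {
  ds <- make_recovery_dataset("BM1", list(sigma2 = 1, x0 = 0), 80, "none", seed = 41)
  noisy <- ds$traits
  set.seed(41)
  noisy$value <- noisy$value + rnorm(80, 0, 0.5)
  noisy$se <- 0.5
  f_fix <- fit_trait_model(ds$tree, noisy, "BM1", se_mode = "fixed")
  f_none <- fit_trait_model(ds$tree, noisy, "BM1", se_mode = "none")
  f_est <- fit_trait_model(ds$tree, noisy, "BM1", se_mode = "estimate")
  # ignoring noise inflates the rate; fixed SE corrects it
  expect_lt(f_fix$spec$sigma2, f_none$spec$sigma2)
  expect_equal(f_est$k, 3)
  expect_gt(f_est$se_hat, 0.2)
  expect_lt(f_est$se_hat, 0.9)
})

test_that("Blomberg's K matches its definition and an independent implementation", {
  tr <- rand_yule(50, seed = 43)
  set.seed(43)
  x <- sim_bm_tips(tr)
  # symmetry: K invariant under tip permutation of the data mapping
  expect_equal(blomberg_k(tr, x), blomberg_k(tr, x[sample(names(x))]))

  skip_if_not_installed("phytools")
  expect_equal(
    blomberg_k(tr, x),
    unname(phytools::phylosig(tr, x, method = "K")[[1]]),
    tolerance = 1e-6
  )
  expect_error(blomberg_k(tr, setNames(rep(1, 50), tr$tip.label)), "constant")

  # white noise on a nested tree has low signal
  set.seed(44)
  ks <- replicate(200, blomberg_k(tr, setNames(rnorm(50), tr$tip.label)))
  expect_lt(mean(ks), 0.5)
})

test_that("multi-rate ML fit matches an independent non-censored implementation", {
  skip_if_not_installed("phytools")
  ds <- make_recovery_dataset("BMS", list(sigma2 = c("0" = 1, "1" = 8), x0 = 0),
    60, "clade", seed = 47
  )
  f <- map_painting_ml(ds$tree, ds$traits, ds$shift_node)
  # brownie.lite on the equivalent era-painted tree
  st <- rep("0", nrow(ds$tree$edge))
  pm <- ds$painting
  key <- match(ds$tree$edge[, 2], pm$node)
  sim_tree <- ds$tree
  sim_tree$maps <- lapply(seq_len(nrow(sim_tree$edge)), function(e) {
    setNames(sim_tree$edge.length[e], pm$regime[key[e]])
  })
  sim_tree$mapped.edge <- matrix(0, nrow(sim_tree$edge), 2,
    dimnames = list(NULL, c("0", "1"))
  )
  for (e in seq_len(nrow(sim_tree$edge))) {
    sim_tree$mapped.edge[e, pm$regime[key[e]]] <- sim_tree$edge.length[e]
  }
  class(sim_tree) <- c("simmap", "phylo")
  bl <- phytools::brownie.lite(
    sim_tree, setNames(ds$traits$value, ds$traits$label)
  )
  expect_equal(f$lnl, bl$logL.multiple, tolerance = 1e-4)
  expect_equal(
    sort(unname(f$spec$sigma2)), sort(unname(bl$sig2.multiple)),
    tolerance = 1e-3
  )
})
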