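# end-to-end commands on small synthetic inputs written to temp files

make_cmd_inputs <- function(seed = 91, n = 25) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ds <- make_recovery_dataset("OUM",
    list(sigma2 = 1, alpha = 3, theta = c("0" = -1, "1" = 1)),
    n, "clade", seed = seed
  )
  tree_file <- file.path(dir, "tree.nwk")
  write_newick(ds$tree, tree_file)
  trait_file <- file.path(dir, "traits.tsv")
  write_trait_table(ds$traits, trait_file)
  # node ids in a painting TSV refer to the tree as read from file, so build
  # the painting against the re-read tree (same clade, located by its tips)
  tr2 <- read_newick(file = tree_file)
  shift_tips <- ds$tree$tip.label[
    which(vapply(seq_len(n), function(tp) {
      ds$painting$regime[ds$painting$node == tp] != "0"
    }, TRUE))
  ]
  node2 <- ape::getMRCA(tr2, shift_tips)
  painting2 <- shift_branches_to_era_map(tr2, node2)
  paint_file <- file.path(dir, "painting.tsv")
  write_regime_map(painting2, paint_file)
  # binary states consistent with the painting's tip regimes
  states_file <- file.path(dir, "states.tsv")
  readr::write_tsv(
    tibble::tibble(
      label = ds$tree$tip.label,
      state = as.integer(ds$tree$tip.label %in% shift_tips)
    ),
    states_file
  )
  list(
    dir = dir, ds = ds, tree2 = tr2, tree = tree_file, traits = trait_file,
    painting = paint_file, states = states_file
  )
}

test_that("cmd_compare writes a complete, well-formed report", {
  io <- make_cmd_inputs()
  out <- file.path(io$dir, "out")
  cmp <- suppressMessages(cmd_compare(
    list(tree = io$tree, traits = io$traits, painting = io$painting),
    models = c("BM1", "OU1", "OUM"), out_dir = out
  ))
  expect_equal(nrow(cmp), 3L)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "compare.tsv")))
  expect_true(file.exists(file.path(out, "fits.json")))
  tab <- readr::read_tsv(file.path(out, "compare.tsv"), show_col_types = FALSE)
  expect_equal(tab$model, cmp$model)

  # a model listed twice yields identical rows with the weight split equally
  cmp2 <- suppressMessages(cmd_compare(
    list(tree = io$tree, traits = io$traits),
    models = c("BM1", "BM1"), out_dir = out
  ))
  expect_equal(cmp2$AICc[1], cmp2$AICc[2])
  expect_equal(cmp2$weight, c(0.5, 0.5))

  # multi-regime request without painting fails loudly
  expect_error(
    cmd_compare(list(tree = io$tree, traits = io$traits),
      models = c("BM1", "OUM"), out_dir = out
    ),
    "painting"
  )
})

test_that("cmd_traitgram is deterministic given a seed and brackets its lines", {
  io <- make_cmd_inputs()
  out1 <- file.path(io$dir, "tg1")
  out2 <- file.path(io$dir, "tg2")
  cfg <- list(
    tree = io$tree, traits = io$traits, painting = io$painting,
    family = "OUM", n_real = 40, seed = 77
  )
  r1 <- cmd_traitgram(cfg, out_dir = out1)
  r2 <- cmd_traitgram(cfg, out_dir = out2)
  expect_identical(
    readLines(file.path(out1, "envelope.tsv")),
    readLines(file.path(out2, "envelope.tsv"))
  )
  expect_identical(
    readLines(file.path(out1, "traitgram_lines.tsv")),
    readLines(file.path(out2, "traitgram_lines.tsv"))
  )
  # envelope bounds bracket the large-ensemble polylines at interior times
  env <- r1$envelope
  ln <- r1$lines
  inside <- mean(
    ln$value >= approx(env$time, env$lower, ln$time)$y - 1e-9 &
      ln$value <= approx(env$time, env$upper, ln$time)$y + 1e-9
  )
  expect_gte(inside, 0.9)
})

test_that("cmd_ancestral and cmd_ratescan produce consistent outputs", {
  io <- make_cmd_inputs()
  out <- file.path(io$dir, "anc")
  res <- cmd_ancestral(list(tree = io$tree, states = io$states), out_dir = out)
  expect_true(file.exists(file.path(out, "painting.tsv")))
  pm <- read_regime_map(file.path(out, "painting.tsv"), io$tree2)
  expect_setequal(unique(pm$regime), c("0", "1"))

  # degenerate all-same-state input: single regime plus a warning
  states1 <- tibble::tibble(label = io$ds$tree$tip.label, state = 0L)
  s1 <- file.path(io$dir, "states1.tsv")
  readr::write_tsv(states1, s1)
  expect_warning(
    res1 <- cmd_ancestral(list(tree = io$tree, states = s1),
      out_dir = file.path(io$dir, "anc1")
    ),
    "lower bound|one state"
  )
  expect_equal(unique(res1$painting$regime), "0")

  out2 <- file.path(io$dir, "rs")
  scan <- cmd_ratescan(
    list(tree = io$tree, traits = io$traits),
    generations = 2000, thinning = 20, seed = 5, out_dir = out2
  )
  expect_equal(nrow(scan$chain), 75L)
  expect_true(file.exists(file.path(out2, "ratescan.tsv")))
})

test_that("the documented chain bookkeeping yields 750 retained samples", {
  # 100,000 generations sampled every 100 with 25% burn-in
  n_keep <- floor(1e5 / 100)
  expect_equal(n_keep - floor(n_keep * 0.25), 750L)
  # verified against the sampler itself at a smaller but proportional setting
  ds <- make_recovery_dataset("BM1", list(sigma2 = 1, x0 = 0), 10, "none", seed = 93)
  scan <- run_rjmcmc(ds$tree, ds$traits, generations = 10000, thinning = 10, seed = 3)
  expect_equal(nrow(scan$chain), 750L)
})

test_that("manifests hash inputs and change only when inputs change", {
  io <- make_cmd_inputs()
  out <- file.path(io$dir, "m1")
  suppressMessages(cmd_compare(
    list(tree = io$tree, traits = io$traits),
    models = "BM1", out_dir = out
  ))
  m1 <- jsonlite::read_json(file.path(out, "compare.manifest.json"))
  suppressMessages(cmd_compare(
    list(tree = io$tree, traits = io$traits),
    models = "BM1", out_dir = out
  ))
  m2 <- jsonlite::read_json(file.path(out, "compare.manifest.json"))
  expect_identical(m1, m2)
  # touch an input -> hash changes
  tt <- read_trait_table(io$traits)
  tt$value[1] <- tt$value[1] + 1
  write_trait_table(tt, io$traits)
  suppressMessages(cmd_compare(
    list(tree = io$tree, traits = io$traits),
    models = "BM1", out_dir = out
  ))
  m3 <- jsonlite::read_json(file.path(out, "compare.manifest.json"))
  expect_false(identical(m1$inputs$traits$md5, m3$inputs$traits$md5))
})

test_that("cmd_pca and cmd_simulate run end to end", {
  io <- make_cmd_inputs()
  set.seed(2)
  tab <- tibble::tibble(
    species = paste0("sp", 1:12),
    a = rnorm(12), b = rnorm(12), c = rnorm(12)
  )
  tf <- file.path(io$dir, "means.tsv")
  readr::write_tsv(tab, tf)
  ord <- cmd_pca(list(table = tf), out_dir = file.path(io$dir, "pca"))
  expect_true(file.exists(file.path(io$dir, "pca", "pca_scores.tsv")))
  expect_equal(sum(ord$var_fraction), 1, tolerance = 1e-12)

  ens <- cmd_simulate(
    list(
      tree = io$tree, family = "BM1",
      params = list(sigma2 = 1, x0 = 0), n_real = 10, seed = 4
    ),
    out_dir = file.path(io$dir, "sim")
  )
  expect_equal(ens$n_real, 10)
  expect_true(file.exists(file.path(io$dir, "sim", "ensemble.tsv")))
  expect_true(file.exists(file.path(io$dir, "sim", "ensemble.tsv.json")))
})
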