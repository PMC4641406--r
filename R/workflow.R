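# Workflow commands tying the modules into the end-to-end analyses: model
# battery -> selection -> simulation -> traitgram; rjMCMC rate scan;
# ancestral-state painting; PCA. Each command takes a flat configuration
# list (from read_run_config() or built in R), writes its outputs under
# `out_dir`, and drops a deterministic JSON run manifest with input hashes,
# so a command re-run with identical config + seed is byte-identical.

#' Read a run configuration file
#'
#' Flat key-value configuration, YAML syntax (a simple `key: value` parser is
#' used if the yaml package is unavailable). Values passed as `...` to the
#' `cmd_*` functions override file values, which override defaults.
#'
#' @param file Path to the config file.
#' @return A named list.
#' @export
read_run_config <- function(file) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    return(yaml::read_yaml(file))
  }
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list()
  for (p in kv) {
    val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(p[1])]] <- if (!is.na(num)) num else val
  }
  out
}

.cfg <- function(config, dots, key, default = NULL) {
  dots[[key]] %||% config[[key]] %||% default
}

.require_file <- function(path, what) {
  if (is.null(path)) abort(sprintf("config is missing `%s`", what))
  if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
  path
}

.write_manifest <- function(out_dir, command, seed, inputs, outputs) {
  manifest <- list(
    package = "traitbridge",
    version = as.character(utils::packageVersion("traitbridge")),
    command = command,
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs
  )
  path <- file.path(out_dir, paste0(command, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# shared input loading: tree + traits (+ painting via states or painting file)
.load_inputs <- function(config, dots, need_traits = TRUE) {
  tree_file <- .require_file(.cfg(config, dots, "tree"), "tree")
  tree <- read_newick(file = tree_file)
  inputs <- list(tree = tree_file)
  traits <- NULL
  if (need_traits) {
    trait_file <- .require_file(.cfg(config, dots, "traits"), "traits")
    traits <- read_trait_table(trait_file)
    inputs$traits <- trait_file
  }
  painting <- NULL
  pf <- .cfg(config, dots, "painting")
  sf <- .cfg(config, dots, "states")
  if (!is.null(pf)) {
    painting <- read_regime_map(.require_file(pf, "painting"), tree)
    inputs$painting <- pf
  } else if (!is.null(sf)) {
    states <- read_tip_states(.require_file(sf, "states"))
    fit <- fit_mk2(tree, states)
    painting <- states_to_regime_map(tree, ancestral_states(fit))
    inputs$states <- sf
  }
  list(tree = tree, traits = traits, painting = painting, inputs = inputs)
}

.out_dir <- function(config, dots) {
  out <- .cfg(config, dots, "out_dir", ".")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  out
}

#' Fit the model battery and write an AICc comparison report
#'
#' Fits the requested families (default: single-rate BM, single-regime OU,
#' the four multi-regime OU variants when a painting is available, and both
#' signs of the exponential rate-change model) and writes the AICc /
#' Delta-AICc / Akaike-weight table plus per-fit parameters.
#'
#' @param config Named list (see [read_run_config()]); keys used here:
#'   `tree`, `traits`, `states` or `painting`, `models`
#'   (comma-separated or character vector), `se_mode`, `out_dir`.
#' @param ... Overrides for config entries.
#' @return The `model_comparison` tibble, invisibly.
#' @export
cmd_compare <- function(config = list(), ...) {
  dots <- list(...)
  io <- .load_inputs(config, dots)
  out_dir <- .out_dir(config, dots)
  models <- .cfg(config, dots, "models")
  if (is.null(models)) {
    models <- c("BM1", "OU1", "ACDC_DC", "ACDC_AC")
    if (!is.null(io$painting)) {
      models <- c(models, "OUM", "OUMV", "OUMA", "OUMVA")
    }
  } else if (length(models) == 1) {
    models <- trimws(strsplit(models, ",")[[1]])
  }
  multi <- c("BMS", "OUM", "OUMV", "OUMA", "OUMVA")
  if (any(models %in% multi) && is.null(io$painting)) {
    abort("multi-regime models requested but no `painting` or `states` given")
  }
  se_mode <- .cfg(config, dots, "se_mode", "none")
  cmp <- fit_battery(io$tree, io$traits,
    painting = io$painting,
    families = models, se_mode = se_mode
  )
  readr::write_tsv(as_tibble(cmp), file.path(out_dir, "compare.tsv"))
  fits <- attr(cmp, "fits")
  fit_json <- lapply(fits, function(f) {
    list(
      family = f$family, parameters = unclass(f$spec), logLik = f$lnl,
      k = f$k, n = f$n, AICc = f$aicc
    )
  })
  names(fit_json) <- cmp$model
  jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
    auto_unbox = TRUE, digits = NA
  )
  .write_manifest(out_dir, "compare", NULL, io$inputs,
                  c("compare.tsv", "fits.json"))
  message("best model: ", cmp$model[1], " (AICc ", signif(cmp$AICc[1], 6), ")")
  invisible(cmp)
}

#' Simulate a fitted model and write traitgram plot data
#'
#' Fits the requested family (or uses explicit parameters from
#' `config$params`), simulates an ensemble of realizations from the root,
#' and writes the trait-range envelope and one realization's bridge
#' polylines as TSV.
#'
#' @param config Keys: `tree`, `traits`, `states`/`painting`, `family`,
#'   `n_real` (default 100), `root_sd` (default 0), `seed`, `out_dir`,
#'   `points_per_edge`.
#' @param ... Overrides.
#' @return List with `envelope` and `lines` tibbles, invisibly.
#' @export
cmd_traitgram <- function(config = list(), ...) {
  dots <- list(...)
  io <- .load_inputs(config, dots)
  out_dir <- .out_dir(config, dots)
  seed <- .cfg(config, dots, "seed")
  family <- .cfg(config, dots, "family", "BM1")
  fit <- fit_trait_model(io$tree, io$traits, family, painting = io$painting)
  spec <- fit$spec
  if (!all(vapply(
    c(spec$sigma2, spec$alpha, spec$theta, spec$r, spec$x0),
    is.finite, TRUE
  ))) {
    abort("fitted parameters are not finite; refusing to simulate")
  }
  painting <- io$painting %||% one_regime_map(io$tree)
  root_mean <- if (family %in% .ou_families()) {
    th <- spec$theta
    if (length(th) > 1) th[[.root_regime(io$tree, painting)]] else th
  } else {
    spec$x0
  }
  ens <- simulate_ensemble(
    io$tree, painting, spec,
    root_mean = root_mean,
    root_sd = .cfg(config, dots, "root_sd", 0),
    n_real = .cfg(config, dots, "n_real", 100),
    seed = seed
  )
  env <- envelope(ens)
  lines <- traitgram_lines(
    io$tree, painting, spec, ensemble_realization(ens, 1L),
    points_per_edge = .cfg(config, dots, "points_per_edge", 20)
  )
  write_traitgram_tsv(env, file.path(out_dir, "envelope.tsv"))
  write_traitgram_tsv(lines, file.path(out_dir, "traitgram_lines.tsv"))
  .write_manifest(out_dir, "traitgram", seed, io$inputs,
                  c("envelope.tsv", "traitgram_lines.tsv"))
  invisible(list(envelope = env, lines = lines, fit = fit, ensemble = ens))
}

#' Run the rjMCMC rate scan and write branch summaries
#'
#' @param config Keys: `tree`, `traits`, `generations` (default 100000),
#'   `thinning` (default 100), `burnin_frac` (default 0.25), `seed`,
#'   `out_dir`.
#' @param ... Overrides.
#' @return The `rate_scan`, invisibly.
#' @export
cmd_ratescan <- function(config = list(), ...) {
  dots <- list(...)
  io <- .load_inputs(config, dots)
  out_dir <- .out_dir(config, dots)
  seed <- .cfg(config, dots, "seed")
  scan <- run_rjmcmc(
    io$tree, io$traits,
    generations = .cfg(config, dots, "generations", 1e5),
    thinning = .cfg(config, dots, "thinning", 100),
    burnin_frac = .cfg(config, dots, "burnin_frac", 0.25),
    seed = seed
  )
  write_rate_scan(scan, file.path(out_dir, "ratescan.tsv"))
  .write_manifest(out_dir, "ratescan", seed, io$inputs,
                  c("ratescan.tsv", "ratescan.tsv.chain.tsv"))
  invisible(scan)
}

#' Reconstruct ancestral binary states and write a regime painting
#'
#' @param config Keys: `tree`, `states`, `mk_model` (`ER`/`ARD`),
#'   `root_prior` (`flat`/`stationary`), `out_dir`.
#' @param ... Overrides.
#' @return List with the `mk_fit` and the `regime_map`, invisibly.
#' @export
cmd_ancestral <- function(config = list(), ...) {
  dots <- list(...)
  tree_file <- .require_file(.cfg(config, dots, "tree"), "tree")
  states_file <- .require_file(.cfg(config, dots, "states"), "states")
  tree <- read_newick(file = tree_file)
  states <- read_tip_states(states_file)
  out_dir <- .out_dir(config, dots)
  fit <- fit_mk2(tree, states,
    model = .cfg(config, dots, "mk_model", "ER"),
    root_prior = .cfg(config, dots, "root_prior", "flat")
  )
  painting <- states_to_regime_map(tree, ancestral_states(fit))
  write_regime_map(painting, file.path(out_dir, "painting.tsv"))
  jsonlite::write_json(
    list(
      model = fit$model, rates = as.list(fit$rates), logLik = fit$lnl,
      root_prior = fit$root_prior
    ),
    file.path(out_dir, "mk_fit.json"),
    auto_unbox = TRUE, digits = NA
  )
  .write_manifest(out_dir, "ancestral", NULL,
                  list(tree = tree_file, states = states_file),
                  c("painting.tsv", "mk_fit.json"))
  invisible(list(fit = fit, painting = painting))
}

#' Simulate an ensemble under explicit parameters and write it as TSV
#'
#' @param config Keys: `tree`, `painting` (optional), `family`, `params`
#'   (list of [model_spec()] arguments), `root_mean`, `root_sd`, `n_real`,
#'   `seed`, `out_dir`.
#' @param ... Overrides.
#' @return The `sim_ensemble`, invisibly.
#' @export
cmd_simulate <- function(config = list(), ...) {
  dots <- list(...)
  io <- .load_inputs(config, dots, need_traits = FALSE)
  out_dir <- .out_dir(config, dots)
  seed <- .cfg(config, dots, "seed")
  params <- .cfg(config, dots, "params")
  if (is.null(params)) abort("cmd_simulate needs `params` (model_spec arguments)")
  spec <- do.call(model_spec, c(list(family = .cfg(config, dots, "family", "BM1")), params))
  painting <- io$painting %||% one_regime_map(io$tree)
  ens <- simulate_ensemble(
    io$tree, painting, spec,
    root_mean = .cfg(config, dots, "root_mean", 0),
    root_sd = .cfg(config, dots, "root_sd", 0),
    n_real = .cfg(config, dots, "n_real", 100),
    seed = seed
  )
  write_ensemble(ens, file.path(out_dir, "ensemble.tsv"))
  .write_manifest(out_dir, "simulate", seed, io$inputs,
                  c("ensemble.tsv", "ensemble.tsv.json"))
  invisible(ens)
}

#' Covariance-matrix PCA of a species-mean table
#'
#' @param config Keys: `table` (TSV/CSV of species by trait means),
#'   `out_dir`.
#' @param ... Overrides.
#' @return The `ordination`, invisibly.
#' @export
cmd_pca <- function(config = list(), ...) {
  dots <- list(...)
  table_file <- .require_file(.cfg(config, dots, "table"), "table")
  out_dir <- .out_dir(config, dots)
  df <- if (grepl("\\.csv$", table_file)) {
    readr::read_csv(table_file, show_col_types = FALSE)
  } else {
    readr::read_tsv(table_file, show_col_types = FALSE)
  }
  ord <- pca_species_means(df)
  readr::write_tsv(ord$scores, file.path(out_dir, "pca_scores.tsv"))
  jsonlite::write_json(
    list(
      loadings = as.data.frame(ord$loadings),
      var_fraction = as.list(ord$var_fraction)
    ),
    file.path(out_dir, "pca_loadings.json"),
    auto_unbox = TRUE, digits = NA
  )
  .write_manifest(out_dir, "pca", NULL, list(table = table_file),
                  c("pca_scores.tsv", "pca_loadings.json"))
  invisible(ord)
}
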