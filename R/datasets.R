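# Synthetic data generation: Yule trees, model-simulated trait datasets with
# known truth, and covariance-matrix PCA of species means.

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation of the pure-birth process: starting from the root split
#' (two lineages), each lineage splits independently at rate `birth_rate`;
#' once `n_tips` lineages are alive the tree is cut at the next (unrealized)
#' event time, giving an ultrametric tree. By default heights are rescaled so
#' the total height is 1, the relative-time convention used throughout.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Optional integer seed.
#' @param rescale Rescale total height to 1 (default); set `FALSE` to keep
#'   the simulated time scale (e.g. to inspect lineage-through-time growth at
#'   the nominal rate).
#' @return An ultrametric `phylo` with tips `t1 ... tn`.
#' @export
yule_tree <- function(n_tips, birth_rate = 1, seed = NULL, rescale = TRUE) {
  if (n_tips < 3) abort("`n_tips` must be >= 3")
  if (birth_rate <= 0) abort("`birth_rate` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  max_lin <- 2 * n_tips - 2
  parent_lin <- integer(max_lin) # 0 = root
  start_t <- numeric(max_lin)
  end_t <- numeric(max_lin)
  is_split <- logical(max_lin)
  parent_lin[1:2] <- 0L
  start_t[1:2] <- 0
  active <- c(1L, 2L)
  n_lin <- 2L
  t <- 0
  while (length(active) < n_tips) {
    t <- t + stats::rexp(1, rate = birth_rate * length(active))
    j <- active[sample.int(length(active), 1)]
    end_t[j] <- t
    is_split[j] <- TRUE
    kids <- c(n_lin + 1L, n_lin + 2L)
    parent_lin[kids] <- j
    start_t[kids] <- t
    n_lin <- n_lin + 2L
    active <- c(setdiff(active, j), kids)
  }
  t_end <- t + stats::rexp(1, rate = birth_rate * length(active))
  end_t[active] <- t_end

  # ape numbering: tips 1..n in lineage order, root n+1, splits by time
  tip_ids <- which(!is_split[seq_len(n_lin)])
  split_ids <- which(is_split[seq_len(n_lin)])
  split_ids <- split_ids[order(end_t[split_ids])]
  node_of <- integer(n_lin)
  node_of[tip_ids] <- seq_len(n_tips)
  node_of[split_ids] <- n_tips + 1L + seq_along(split_ids)
  root <- n_tips + 1L
  edge <- matrix(0L, n_lin, 2)
  elen <- numeric(n_lin)
  for (j in seq_len(n_lin)) {
    p <- parent_lin[j]
    edge[j, ] <- c(if (p == 0L) root else node_of[p], node_of[j])
    elen[j] <- end_t[j] - start_t[j]
  }
  if (rescale) elen <- elen / t_end
  tr <- structure(
    list(
      edge = edge, edge.length = elen,
      tip.label = paste0("t", seq_len(n_tips)),
      Nnode = n_tips - 1L
    ),
    class = "phylo", order = NULL
  )
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_tree(tr)
}

# number of tips below each node
.clade_sizes <- function(tree) {
  n <- .n_nodes(tree)
  sz <- integer(n)
  sz[seq_along(tree$tip.label)] <- 1L
  post <- .postorder_edges(tree)
  for (e in seq_len(nrow(post))) {
    sz[post[e, 1]] <- sz[post[e, 1]] + sz[post[e, 2]]
  }
  sz
}

#' Generate a synthetic recovery dataset with known truth
#'
#' Simulates a Yule tree, optionally paints one rate/regime shift on a clade
#' holding a given fraction of the tips, and simulates tip traits under the
#' requested model; the generating parameters are recorded so estimator
#' recovery can be scored.
#'
#' @param family Model family, see [model_spec()].
#' @param params Named list of [model_spec()] arguments (regime labels `"0"`
#'   background, `"1"` shifted clade when `painting_rule = "clade"`).
#' @param n_tips Tree size.
#' @param painting_rule `"none"` (single regime `"0"`) or `"clade"` (one
#'   shift on the largest clade whose tip count lies within
#'   `clade_fraction`).
#' @param clade_fraction Lower/upper bounds on the shifted clade's tip
#'   fraction.
#' @param seed Integer seed; the dataset is a pure function of
#'   (parameters, seed).
#' @param birth_rate Yule rate for the tree simulation.
#' @return A `synthetic_dataset`: list with `tree`, `painting`, `spec`,
#'   `traits` (tibble `label`, `value`), `shift_node`, `root_value`, `seed`.
#' @export
make_recovery_dataset <- function(family, params, n_tips,
                                  painting_rule = c("none", "clade"),
                                  clade_fraction = c(0.2, 0.4),
                                  seed = NULL, birth_rate = 1) {
  painting_rule <- match.arg(painting_rule)
  if (!is.null(seed)) set.seed(seed)
  tree <- yule_tree(n_tips, birth_rate)
  shift_node <- NA_integer_
  if (painting_rule == "clade") {
    sz <- .clade_sizes(tree)
    lo <- ceiling(clade_fraction[1] * n_tips)
    hi <- floor(clade_fraction[2] * n_tips)
    cand <- which(sz >= lo & sz <= hi & seq_along(sz) > n_tips)
    if (length(cand) == 0) {
      abort(sprintf(
        "no clade with between %d and %d tips; painting rule unsatisfiable", lo, hi
      ))
    }
    shift_node <- cand[order(-sz[cand], cand)][1]
    painting <- shift_branches_to_era_map(tree, shift_node)
  } else {
    painting <- one_regime_map(tree)
  }
  spec <- do.call(model_spec, c(list(family = family), params))
  root_value <- if (family %in% .ou_families()) {
    th <- spec$theta
    if (length(th) > 1) th[[.root_regime(tree, painting)]] else th
  } else {
    spec$x0
  }
  real <- simulate_realization(tree, painting, spec, root_value)
  structure(
    list(
      tree = tree, painting = painting, spec = spec,
      traits = tibble(
        label = names(real$tip_values),
        value = unname(real$tip_values)
      ),
      shift_node = shift_node, root_value = root_value, seed = seed
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset: %s, %d tips%s, seed %s>\n",
    x$spec$family, nrow(x$traits),
    if (!is.na(x$shift_node)) sprintf(", shift at node %d", x$shift_node) else "",
    format(x$seed)
  ))
  invisible(x)
}

#' Covariance-matrix PCA of species trait means
#'
#' Eigen-decomposition of the covariance matrix of untransformed species
#' means: scores are the centered data projected on the eigenvectors and
#' each axis's variance fraction is its eigenvalue over the trace. The sign
#' of each loading vector is fixed by making its largest-magnitude entry
#' positive (axis polarity is otherwise arbitrary).
#'
#' @param table Data frame of species by variables: one character/factor
#'   column of species names (or rownames) plus numeric trait-mean columns.
#' @return An `ordination` object: `scores` tibble, `loadings` matrix,
#'   `var_fraction` per axis, `sdev`.
#' @export
pca_species_means <- function(table) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  species <- if (any(!num)) {
    as.character(df[[which(!num)[1]]])
  } else if (!is.null(rownames(df)) && !identical(rownames(df), as.character(seq_len(nrow(df))))) {
    rownames(df)
  } else {
    paste0("sp", seq_len(nrow(df)))
  }
  x <- as.matrix(df[, num, drop = FALSE])
  if (nrow(x) < 3) abort("need at least 3 species")
  if (ncol(x) < 2) abort("need at least 2 variables")
  if (anyNA(x)) abort("missing cells are not allowed")
  zerovar <- apply(x, 2, var) == 0
  if (any(zerovar)) {
    warn(paste0(
      "zero-variance variable(s): ",
      paste(colnames(x)[zerovar], collapse = ", ")
    ))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  total_var <- sum(apply(x, 2, var))
  scores <- as_tibble(p$x)
  scores <- dplyr::bind_cols(tibble(species = species), scores)
  structure(
    list(
      scores = scores,
      loadings = p$rotation,
      var_fraction = setNames(p$sdev^2 / total_var, colnames(p$rotation)),
      sdev = p$sdev
    ),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  vf <- x$var_fraction
  cat("<ordination>\n  variance fractions:",
      paste(sprintf("%s %.1f%%", names(vf)[1:min(3, length(vf))],
                    100 * vf[1:min(3, length(vf))]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ordination <- function(x, ...) x$scores

#' @export
glance.ordination <- function(x, ...) {
  tibble(
    n_axes = length(x$var_fraction),
    pc1_var = x$var_fraction[[1]],
    pc2_var = if (length(x$var_fraction) > 1) x$var_fraction[[2]] else NA_real_,
    first_two = if (length(x$var_fraction) > 1) {
      x$var_fraction[[1]] + x$var_fraction[[2]]
    } else {
      x$var_fraction[[1]]
    }
  )
}

#' @export
autoplot.ordination <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$PC1, y = .data$PC2, label = .data$species)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[[1]]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_fraction[[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Read / write trait tables and tip states as TSV
#'
#' Trait tables have columns `label`, `value` and optionally `se`; tip-state
#' tables have columns `label`, `state` (0/1).
#'
#' @param file Path.
#' @return A tibble.
#' @export
read_trait_table <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  if (!all(c("label", "value") %in% names(df))) {
    abort("trait TSV needs columns `label` and `value`")
  }
  df
}

#' @rdname read_trait_table
#' @export
read_tip_states <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  if (!all(c("label", "state") %in% names(df))) {
    abort("tip-state TSV needs columns `label` and `state`")
  }
  df
}

#' @rdname read_trait_table
#' @param x Tibble to write.
#' @export
write_trait_table <- function(x, file) {
  readr::write_tsv(x, file)
  invisible(x)
}
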