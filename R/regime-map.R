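#' Piecewise-constant regime paintings
#'
#' A regime map assigns a regime (selective regime, rate class, ...) to every
#' point of every branch of a tree. It is stored as a tibble with one row per
#' painting segment: `node` (the child node identifying the edge), `start` and
#' `end` (segment heights, root = 0) and `regime` (a label). Segments on an
#' edge run from the parent end downwards, jointly cover the edge exactly, have
#' positive durations, and adjacent segments carry distinct regimes.
#'
#' @param tree A `phylo` object the painting refers to.
#' @param node,start,end,regime Segment columns, recycled tibble-style.
#' @return A `regime_map` tibble.
#' @seealso [one_regime_map()], [states_to_regime_map()],
#'   [shift_branches_to_era_map()]
#' @export
regime_map <- function(tree, node, start, end, regime) {
  pm <- tibble(
    node = as.integer(node), start = as.numeric(start),
    end = as.numeric(end), regime = as.character(regime)
  )
  pm <- dplyr::arrange(pm, .data$node, .data$start)
  class(pm) <- c("regime_map", class(pm))
  validate_regime_map(tree, pm)
  pm
}

#' Validate a regime map against its tree
#'
#' Checks edge coverage (tolerance `1e-9` relative to tree height), positive
#' segment durations, and that adjacent segments on an edge differ in regime.
#'
#' @param tree A `phylo` object.
#' @param painting A `regime_map`.
#' @return The painting, invisibly.
#' @export
validate_regime_map <- function(tree, painting) {
  h <- node_heights(tree)
  par <- .parent_vec(tree)
  tol <- 1e-9 * max(h, 1)
  if (any(painting$end - painting$start <= 0)) {
    abort("regime map has a segment with non-positive duration")
  }
  non_root <- setdiff(seq_len(.n_nodes(tree)), .root_node(tree))
  for (nd in non_root) {
    seg <- painting[painting$node == nd, , drop = FALSE]
    if (nrow(seg) == 0) abort(sprintf("edge above node %d is not painted", nd))
    if (abs(seg$start[1] - h[par[nd]]) > tol ||
        abs(seg$end[nrow(seg)] - h[nd]) > tol ||
        (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > tol))) {
      abort(sprintf("segments on the edge above node %d do not cover it exactly", nd))
    }
    if (nrow(seg) > 1 && any(seg$regime[-1] == seg$regime[-nrow(seg)])) {
      abort(sprintf("adjacent segments with identical regime on edge above node %d", nd))
    }
  }
  extra <- setdiff(unique(painting$node), non_root)
  if (length(extra) > 0) {
    abort(paste0("painting refers to non-edge nodes: ", paste(extra, collapse = ", ")))
  }
  invisible(painting)
}

#' Paint the whole tree with a single regime
#'
#' @param tree A `phylo` object.
#' @param regime Label for the single regime.
#' @return A `regime_map`.
#' @export
one_regime_map <- function(tree, regime = "0") {
  h <- node_heights(tree)
  par <- .parent_vec(tree)
  nd <- setdiff(seq_len(.n_nodes(tree)), .root_node(tree))
  regime_map(tree, node = nd, start = h[par[nd]], end = h[nd], regime = regime)
}

#' Convert node states into a regime map
#'
#' Every edge is painted uniformly with the state of its child node, the
#' common convention for multi-regime Ornstein-Uhlenbeck models. A state is
#' required for every node (tips and internals); internal states typically
#' come from [ancestral_states()].
#'
#' @param tree A `phylo` object.
#' @param node_states Character vector of states with one entry per node.
#'   Entries may be named by node id (`"1"`, `"2"`, ...) and/or tip label; an
#'   unnamed vector of length `n_nodes` is taken in node-id order.
#' @return A `regime_map` with one segment per edge.
#' @export
states_to_regime_map <- function(tree, node_states) {
  n <- .n_nodes(tree)
  states <- .resolve_node_states(tree, node_states)
  h <- node_heights(tree)
  par <- .parent_vec(tree)
  nd <- setdiff(seq_len(n), .root_node(tree))
  regime_map(tree,
    node = nd, start = h[par[nd]], end = h[nd],
    regime = states[nd]
  )
}

.resolve_node_states <- function(tree, node_states) {
  n <- .n_nodes(tree)
  if (is.null(names(node_states))) {
    if (length(node_states) != n) {
      abort(sprintf("need one state per node (%d), got %d", n, length(node_states)))
    }
    return(as.character(node_states))
  }
  states <- rep(NA_character_, n)
  nm <- names(node_states)
  for (i in seq_along(node_states)) {
    tip <- match(nm[i], tree$tip.label)
    id <- if (!is.na(tip)) tip else suppressWarnings(as.integer(nm[i]))
    if (is.na(id) || id < 1 || id > n) {
      abort(sprintf("state name '%s' matches no node", nm[i]))
    }
    states[id] <- as.character(node_states[[i]])
  }
  if (anyNA(states)) {
    abort(paste0(
      "missing state for node(s): ",
      paste(which(is.na(states)), collapse = ", ")
    ))
  }
  states
}

#' Era-style rate classes from a set of shift branches
#'
#' The root clade carries class `"0"`; each shift edge (identified by its
#' child node) opens a new class inherited by the entire descendant clade,
#' including the shift edge itself, until overridden by a nested shift.
#'
#' @param tree A `phylo` object.
#' @param shift_nodes Integer vector of child node ids of the shift edges
#'   (may be empty).
#' @return A `regime_map` whose regimes are `"0"`, `"1"`, ... in the order of
#'   `shift_nodes`.
#' @export
shift_branches_to_era_map <- function(tree, shift_nodes = integer(0)) {
  shift_nodes <- as.integer(shift_nodes)
  edges <- .preorder_edges(tree)
  cls <- cpp_era_classes(
    .n_nodes(tree), .root_node(tree),
    edges[, 1], edges[, 2], shift_nodes
  )
  h <- node_heights(tree)
  regime_map(tree,
    node = edges[, 2], start = h[edges[, 1]], end = h[edges[, 2]],
    regime = as.character(cls)
  )
}

#' Regime labels of a painting
#' @param painting A `regime_map`.
#' @return Sorted unique regime labels.
#' @export
regime_levels <- function(painting) sort(unique(painting$regime))

#' Total branch duration painted with each regime
#' @param painting A `regime_map`.
#' @return A tibble with `regime` and `duration`.
#' @export
regime_durations <- function(painting) {
  painting |>
    as_tibble() |>
    dplyr::group_by(.data$regime) |>
    dplyr::summarise(duration = sum(.data$end - .data$start), .groups = "drop")
}

# regime active at the parent end of the first root-child edge; the root
# state of an OU model is tied to this regime's optimum
.root_regime <- function(tree, painting) {
  edges <- .preorder_edges(tree)
  first_child <- edges[edges[, 1] == .root_node(tree), 2][1]
  seg <- painting[painting$node == first_child, , drop = FALSE]
  seg$regime[which.min(seg$start)]
}

#' Write / read a regime map as TSV
#'
#' Columns: `node`, `start`, `end`, `regime`.
#'
#' @param painting A `regime_map`.
#' @param file Path.
#' @return `read_regime_map()` returns a `regime_map` validated against
#'   `tree`; `write_regime_map()` returns the painting invisibly.
#' @export
write_regime_map <- function(painting, file) {
  readr::write_tsv(as_tibble(painting), file)
  invisible(painting)
}

#' @rdname write_regime_map
#' @param tree Tree the painting refers to. Node ids in the TSV follow this
#'   tree's numbering, so the painting must be read against the tree object
#'   (or Newick file) it was created from.
#' @export
read_regime_map <- function(file, tree) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  regime_map(tree, df$node, df$start, df$end, df$regime)
}
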