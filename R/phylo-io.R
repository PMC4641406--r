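#' Read a rooted time tree from Newick text
#'
#' Parses a Newick string (or file) into an [ape::phylo] tree and validates it
#' as a rooted time tree: every non-root edge must carry a non-negative branch
#' length, tip labels must be unique and non-empty, and the tree must contain a
#' single root. Node heights are measured from the root (height 0) towards the
#' tips, the convention every other function in the package follows.
#'
#' Square-bracket comments (including NHX annotations) are not interpreted;
#' they are stripped with a warning. Quoted labels are supported. Zero-length
#' edges are legal but flagged with a warning since they create ties in node
#' heights.
#'
#' @param text Newick string (exactly one of `text`/`file`).
#' @param file Path to a Newick file.
#' @return A validated `phylo` object.
#' @seealso [write_newick()], [node_heights()], [prune_tips()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' node_heights(tr)
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    abort("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- .strip_newick_comments(text)
  .check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort("failed to parse Newick string")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.strip_newick_comments <- function(text) {
  if (grepl("[", text, fixed = TRUE)) {
    warn("square-bracket comments (e.g. NHX) are not supported and were dropped")
    text <- gsub("\\[[^]]*\\]", "", text)
  }
  text
}

# Cheap syntactic pre-check so malformed input fails with a character offset
# instead of an opaque ape error.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unmatched ')' at character %d", i))
      }
    }
  }
  if (quoted) abort("malformed Newick: unterminated quoted label")
  if (depth != 0L) {
    abort(sprintf("malformed Newick: %d unclosed '(' at end of string", depth))
  }
  invisible(TRUE)
}

#' Validate a phylo object as a rooted time tree
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly modified only by `ape` storage order.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) abort("tree must have at least 2 tips")
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; every non-root edge needs one")
  }
  if (anyNA(tree$edge.length)) {
    abort("missing branch length on at least one edge; no silent default is applied")
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  if (any(tree$edge.length == 0)) {
    warn("tree contains zero-length edges; heights will contain ties")
  }
  if (any(!nzchar(tree$tip.label))) abort("empty tip labels are not allowed")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (nrow(tree$edge) != n_tip + tree$Nnode - 1) {
    abort("not a tree: edge count must equal node count minus one")
  }
  if (max(node_heights(tree)) <= 0) abort("total tree height must be positive")
  tree
}

#' Node heights measured from the root
#'
#' The root sits at height 0 and time increases towards the tips, so on an
#' ultrametric tree every tip sits at the total height `T`.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector indexed by node id (tips `1..n`, then internals);
#'   tip entries are also named by tip label.
#' @export
node_heights <- function(tree) {
  h <- ape::node.depth.edgelength(tree)
  names(h) <- c(tree$tip.label, rep("", tree$Nnode))
  h
}

#' Total height of a tree
#' @param tree A `phylo` object.
#' @return Maximum tip height (root is at height 0).
#' @export
tree_height <- function(tree) max(node_heights(tree))

#' Test whether a tree is ultrametric
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance: tip heights must agree within
#'   `tol * tree_height(tree)`.
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  h <- node_heights(tree)[seq_along(tree$tip.label)]
  (max(h) - min(h)) <= tol * max(h)
}

#' Prune a tree down to a set of tips
#'
#' Returns the subtree induced by `keep`: other tips are removed and any
#' resulting degree-2 internal nodes are collapsed with their edge lengths
#' summed, so the heights of the kept tips are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `phylo` object.
#' @export
prune_tips <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("unknown tip labels: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2) abort("`keep` must contain at least 2 tips")
  ape::keep.tip(tree, keep)
}

#' Summarize a tree
#'
#' @param tree A `phylo` object.
#' @param tol Relative ultrametricity tolerance.
#' @return A list with `n_tips`, `height` and `ultrametric`, suitable for
#'   JSON serialization.
#' @export
tree_summary <- function(tree, tol = 1e-8) {
  list(
    n_tips = length(tree$tip.label),
    height = tree_height(tree),
    ultrametric = is_ultrametric(tree, tol)
  )
}

# ---- internal geometry helpers -------------------------------------------

.root_node <- function(tree) length(tree$tip.label) + 1L

.n_nodes <- function(tree) length(tree$tip.label) + tree$Nnode

.preorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  tr$edge
}

.postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tr$edge
}

# length of the edge above each node (0 for the root), indexed by node id
.stem_lengths <- function(tree) {
  out <- numeric(.n_nodes(tree))
  out[tree$edge[, 2]] <- tree$edge.length
  out
}

# children of each node as a list indexed by node id
.children_list <- function(tree) {
  n <- .n_nodes(tree)
  out <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    out[[p]] <- c(out[[p]], tree$edge[e, 2])
  }
  out
}

.parent_vec <- function(tree) {
  out <- integer(.n_nodes(tree))
  out[tree$edge[, 2]] <- tree$edge[, 1]
  out
}
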