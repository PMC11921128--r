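#' Flat array-backed phylogenetic trees
#'
#' A `flat_tree` represents a rooted (possibly multifurcating) phylogeny as
#' four parallel arrays indexed by node identifier:
#'
#' * `parent`: `parent[u]` is the parent of node `u` (the null sentinel for
#'   the root),
#' * `children`: `children[u]` lists `u`'s children in Newick left-to-right
#'   order,
#' * `label`: `label[u]` is `u`'s label (`""` means unlabeled); present only
#'   when the configuration stores labels,
#' * `length`: `length[u]` is the length of the edge from `parent[u]` to `u`
#'   (0 when no length was given); present only when lengths are stored.
#'
#' Node identifiers are 0-based and assigned in depth-first pre-order, so the
#' root is node 0 and every node has a smaller identifier than all of its
#' descendants (`parent[u] < u` for every `u > 0`).  Pre-order and post-order
#' traversals therefore reduce to sweeping the identifier range up or down.
#' Trees produced by [parse_newick()], [simulate_tree()] and
#' [extract_subtree()] are sealed: the public interface never modifies the
#' topology, which is what guarantees the ordering invariant.
#'
#' `create_tree()` returns a minimal unsealed tree holding only the root;
#' it exists as the construction entry point used internally by the parser
#' and simulator.
#'
#' @param config A [tree_config()].
#' @return A `flat_tree`.
#' @examples
#' tr <- parse_newick(text = "((A:1,B:2)X:0.5,C:3)R;")
#' num_nodes(tr)
#' num_leaves(tr)
#' total_branch_length(tr)
#' @export
create_tree <- function(config = tree_config()) {
  stopifnot(inherits(config, "flat_tree_config"))
  tr <- structure(
    list(parent = null_node(config),
         children = list(numeric(0)),
         label = if (config$store_labels) "" else NULL,
         length = if (config$store_lengths) 0 else NULL,
         config = config),
    class = "flat_tree")
  attr(tr, "sealed") <- FALSE
  tr
}

# Construction-internal: appends node N as a new child of `parent_id` and
# returns list(tree, id).  Not exported -- sealed trees cannot be edited, and
# the pre-order invariant parent[u] < u holds because new IDs only grow.
ct_add_child <- function(tree, parent_id, .capacity = node_capacity(tree$config)) {
  if (isTRUE(attr(tree, "sealed")))
    stop("tree is sealed: topology cannot be modified", call. = FALSE)
  n <- length(tree$parent)
  parent_id <- check_node_id(tree, parent_id)
  if (n + 1 > .capacity)
    stop("node count would exceed the capacity of the configured ID width",
         call. = FALSE)
  new_id <- n  # 0-based
  tree$parent[n + 1L] <- parent_id
  tree$children[[parent_id + 1L]] <- c(tree$children[[parent_id + 1L]], new_id)
  tree$children[[n + 1L]] <- numeric(0)
  if (!is.null(tree$label)) tree$label[n + 1L] <- ""
  if (!is.null(tree$length)) tree$length[n + 1L] <- 0
  list(tree = tree, id = new_id)
}

ct_seal <- function(tree) {
  attr(tree, "sealed") <- TRUE
  tree
}

# validate a scalar 0-based node id against a tree; returns it as double
check_node_id <- function(tree, u, what = "node id") {
  if (length(u) != 1L || is.na(u) || u != trunc(u))
    stop(sprintf("'%s' must be a single non-negative integer", what), call. = FALSE)
  u <- as.numeric(u)
  if (u < 0 || u >= length(tree$parent))
    stop(sprintf("%s %s is out of range [0, %d]", what, format(u, scientific = FALSE),
                 length(tree$parent) - 1L), call. = FALSE)
  u
}

#' Basic tree properties
#'
#' A leaf is a node with no children; every other node is internal, so
#' `num_leaves(x) + num_internal(x) == num_nodes(x)`.
#'
#' @param x A `flat_tree` or `level_order_tree`.
#' @return A count.
#' @export
num_nodes <- function(x) UseMethod("num_nodes")

#' @export
num_nodes.flat_tree <- function(x) length(x$parent)

#' @rdname num_nodes
#' @export
num_leaves <- function(x) UseMethod("num_leaves")

#' @export
num_leaves.flat_tree <- function(x) sum(lengths(x$children) == 0L)

#' @rdname num_nodes
#' @export
num_internal <- function(x) UseMethod("num_internal")

#' @export
num_internal.flat_tree <- function(x) sum(lengths(x$children) > 0L)

#' Total and average branch length
#'
#' The total is the sum of the stored edge lengths over all non-root nodes;
#' the average divides by the number of edges (`N - 1`), and is 0 for a
#' single-node tree.  A length token attached to the root in the Newick input
#' is stored at node 0 but excluded by default, since a root edge is
#' conventionally not part of the tree; `include_root = TRUE` adds it.  Trees
#' loaded without lengths report 0.
#'
#' @param tree A `flat_tree`.
#' @param include_root Include the root's stored length in the sum?
#' @return A numeric scalar.
#' @export
total_branch_length <- function(tree, include_root = FALSE) {
  stopifnot(inherits(tree, "flat_tree"))
  if (is.null(tree$length)) return(0)
  tot <- sum(tree$length) - if (include_root) 0 else tree$length[1L]
  tot
}

#' @rdname total_branch_length
#' @export
avg_branch_length <- function(tree, include_root = FALSE) {
  n <- num_nodes(tree)
  if (n <= 1L) return(0)
  total_branch_length(tree, include_root) / (n - 1)
}

#' Node labels and branch lengths
#'
#' Getters and setters addressed by 0-based node identifier.  Setters return
#' the modified tree (copy semantics) and never change the topology.  Getting
#' a label or length from a tree loaded without that attribute yields `""` /
#' `0`; setting one is an error.
#'
#' @param tree A `flat_tree`.
#' @param u 0-based node identifier.
#' @param value Replacement label (character) or length (numeric).
#' @export
get_label <- function(tree, u) {
  u <- check_node_id(tree, u)
  if (is.null(tree$label)) return("")
  tree$label[u + 1L]
}

#' @rdname get_label
#' @export
set_label <- function(tree, u, value) {
  u <- check_node_id(tree, u)
  if (is.null(tree$label))
    stop("tree was loaded without labels (store_labels = FALSE)", call. = FALSE)
  stopifnot(is.character(value), length(value) == 1L, !is.na(value))
  tree$label[u + 1L] <- value
  tree
}

#' @rdname get_label
#' @export
get_length <- function(tree, u) {
  u <- check_node_id(tree, u)
  if (is.null(tree$length)) return(0)
  tree$length[u + 1L]
}

#' @rdname get_label
#' @export
set_length <- function(tree, u, value) {
  u <- check_node_id(tree, u)
  if (is.null(tree$length))
    stop("tree was loaded without lengths (store_lengths = FALSE)", call. = FALSE)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (tree$config$length_precision == "single") value <- cpp_as_single(value)
  tree$length[u + 1L] <- value
  tree
}

#' Check the structural invariants of a flat tree
#'
#' Asserts that all present arrays share one length `N >= 1`, that node 0 is
#' the unique root (`parent[0]` is the null sentinel), that `parent[u] < u`
#' for every non-root node, that the parent array and the children lists
#' describe the same edges with no duplicates, and that `N` fits the
#' configured identifier width.  Errors on the first violation.
#'
#' @param tree A `flat_tree`.
#' @return `TRUE`, invisibly.
#' @export
validate_flat_tree <- function(tree) {
  stopifnot(inherits(tree, "flat_tree"))
  n <- length(tree$parent)
  if (n < 1L) stop("tree has no nodes")
  if (length(tree$children) != n) stop("children array length differs from N")
  if (!is.null(tree$label) && length(tree$label) != n)
    stop("label array length differs from N")
  if (!is.null(tree$length) && length(tree$length) != n)
    stop("length array length differs from N")
  if (n > node_capacity(tree$config))
    stop("node count exceeds configured ID width capacity")
  if (tree$parent[1L] != null_node(tree$config))
    stop("parent of the root must be the null sentinel")
  if (n > 1L) {
    u <- seq_len(n - 1L)  # nodes 1..N-1 (0-based)
    if (any(tree$parent[u + 1L] >= u))
      stop("pre-order invariant violated: parent[u] >= u for some node")
    if (any(tree$parent[u + 1L] < 0))
      stop("negative parent id")
    if (any(tree$parent[-1L] == null_node(tree$config)))
      stop("non-root node with null parent")
  }
  # parent <-> children cross-consistency, including child order (ascending
  # IDs within a parent is what pre-order construction produces)
  kid_counts <- lengths(tree$children)
  if (sum(kid_counts) != n - 1L) stop("children lists do not cover all edges")
  rebuilt <- cpp_children_list(tree$parent)
  for (i in seq_len(n)) {
    if (!identical(as.numeric(tree$children[[i]]), as.numeric(rebuilt[[i]])))
      stop(sprintf("children of node %d disagree with the parent array", i - 1L))
  }
  invisible(TRUE)
}

#' @export
print.flat_tree <- function(x, ...) {
  cat(sprintf("flat_tree: %s nodes (%s leaves, %s internal), %d-bit IDs\n",
              format(num_nodes(x), big.mark = ","),
              format(num_leaves(x), big.mark = ","),
              format(num_internal(x), big.mark = ","),
              x$config$id_width))
  if (!is.null(x$length))
    cat(sprintf("  total branch length: %g\n", total_branch_length(x)))
  if (is.null(x$label)) cat("  labels: omitted\n")
  if (is.null(x$length)) cat("  lengths: omitted\n")
  invisible(x)
}
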