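#' Flat child array with per-node offsets
#'
#' Packs all children lists into one flat identifier array (children of node
#' 0, then node 1, ...), with a per-node `(start, end)` offset pair into it.
#' This removes the per-list container overhead of the nested representation:
#' the `N - 1` child entries are stored contiguously and `children[u]` is the
#' half-open slice `child_ids[start[u]:end[u]]` (offsets are 0-based).
#'
#' @param tree A `flat_tree`.
#' @return An object of class `"flat_children_index"`: list with `child_ids`
#'   (numeric, length `N - 1`) and `offsets` (an `N` x 2 matrix of 0-based
#'   half-open `start`/`end` indices).
#' @examples
#' fc <- build_flat_children(parse_newick(text = "(A,B,C);"))
#' fc$child_ids          # 1 2 3
#' fc$offsets[1, ]       # 0 3
#' @export
build_flat_children <- function(tree) {
  stopifnot(inherits(tree, "flat_tree"))
  raw <- cpp_flat_children(tree$parent)
  structure(list(child_ids = raw$child_ids,
                 offsets = cbind(start = raw$start, end = raw$end)),
            class = "flat_children_index")
}

#' Re-encode a tree in level-order numbering
#'
#' Renumbers the nodes breadth-first (0 is the root, then the children of the
#' root in stored order, then the children of the first child, ...).  Under
#' this numbering the children of every node occupy a contiguous identifier
#' interval, so the whole child structure collapses to two integers per node:
#' `child_range[u] = (min_child, max_child)`, with the null sentinel pair
#' marking leaves.  The ordering invariant `parent[u] < u` still holds, so
#' ascending/descending identifier sweeps remain valid pre-/post-orders of
#' the renumbered tree, and [find_mrca()] works unchanged.
#'
#' The conversion is a post-parse transformation of an in-memory tree; the
#' streaming parser itself stays single-pass.
#'
#' @param tree A `flat_tree`.
#' @return An object of class `"level_order_tree"`: list with `parent`,
#'   `min_child`, `max_child` (numeric, null sentinel for leaves), permuted
#'   `label` and `length`, `perm` (0-based map old id -> new id), and the
#'   source `config`.
#' @examples
#' lo <- to_level_order(parse_newick(text = "((A,B)X,(C,D)Y)R;"))
#' lo$min_child[2:3]  # children of X (new id 1) are 3..4, of Y (new id 2) 5..6
#' @export
to_level_order <- function(tree) {
  stopifnot(inherits(tree, "flat_tree"))
  n <- num_nodes(tree)
  nul <- null_node(tree$config)
  new2old <- bfs_order(tree)            # new id -> old id
  perm <- numeric(n)
  perm[new2old + 1] <- seq_len(n) - 1   # old id -> new id
  parent_new <- c(nul, if (n > 1) perm[tree$parent[new2old[-1] + 1] + 1])
  minc <- rep(nul, n)
  maxc <- rep(nul, n)
  if (n > 1) {
    kids <- seq_len(n - 1)              # new ids 1..N-1
    kp <- parent_new[kids + 1]          # grouped runs: siblings are contiguous
    first <- !duplicated(kp)
    last <- !duplicated(kp, fromLast = TRUE)
    minc[kp[first] + 1] <- kids[first]
    maxc[kp[last] + 1] <- kids[last]
  }
  structure(
    list(parent = parent_new,
         min_child = minc,
         max_child = maxc,
         label = if (!is.null(tree$label)) tree$label[new2old + 1],
         length = if (!is.null(tree$length)) tree$length[new2old + 1],
         perm = perm,
         config = tree$config),
    class = "level_order_tree")
}

#' @export
num_nodes.level_order_tree <- function(x) length(x$parent)

#' @export
num_leaves.level_order_tree <- function(x) sum(x$min_child == null_node(x$config))

#' @export
num_internal.level_order_tree <- function(x) sum(x$min_child != null_node(x$config))

#' @export
children_of.level_order_tree <- function(x, u) {
  u <- check_node_id(x, u)
  if (x$min_child[u + 1] == null_node(x$config)) return(numeric(0))
  seq(x$min_child[u + 1], x$max_child[u + 1])
}

#' @export
ancestors_of.level_order_tree <- function(x, u) ancestors_walk(x, u)

#' @export
print.level_order_tree <- function(x, ...) {
  cat(sprintf("level_order_tree: %s nodes (%s leaves), child ranges stored as 2 IDs/node\n",
              format(num_nodes(x), big.mark = ","),
              format(num_leaves(x), big.mark = ",")))
  invisible(x)
}

#' Count the identifier-typed integers each encoding stores
#'
#' Quantifies the memory argument for the level-order re-encoding, counting
#' only ID-typed slots and ignoring per-list container bookkeeping: the
#' depth-first encoding stores `N` parent entries plus `N - 1` child entries
#' (one per edge; a flat child array would add `2N` offsets on top), while
#' the level-order encoding stores `N` parents plus exactly `2N` child-range
#' entries regardless of topology.  Counts depend only on the topology, not
#' on whether labels or lengths are stored.
#'
#' @param x A `flat_tree` or `level_order_tree`.
#' @return Named numeric vector with the component counts and their `total`.
#' @export
integer_storage_count <- function(x) UseMethod("integer_storage_count")

#' @export
integer_storage_count.flat_tree <- function(x) {
  n <- num_nodes(x)
  c(parents = n, child_entries = n - 1, total = 2 * n - 1)
}

#' @export
integer_storage_count.level_order_tree <- function(x) {
  n <- num_nodes(x)
  c(parents = n, range_entries = 2 * n, total = 3 * n)
}
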