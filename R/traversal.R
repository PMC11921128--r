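#' Tree traversals as identifier sweeps
#'
#' Because identifiers are assigned in depth-first pre-order, the ascending
#' sweep `0, 1, ..., N-1` visits every node before all of its descendants
#' (a pre-order) and the descending sweep `N-1, ..., 0` visits every node
#' after all of its descendants (a valid post-order).  Both are pure index
#' ranges: no stack, no recursion, no pointer chasing.  Note the descending
#' post-order visits a node's children right-to-left relative to the Newick
#' text; it satisfies the post-order property but is not the conventional
#' stack-based order, and no conventional variant is provided.
#'
#' `"levelorder"` is breadth-first from the root with children in stored
#' order.  `"inorder"` (left child, node, right child) is defined only for
#' strictly binary trees and errors on any node with one child or more than
#' two.  `"leaves"` yields the childless nodes in increasing identifier
#' order.
#'
#' @param tree A `flat_tree`.
#' @param order One of `"preorder"`, `"postorder"`, `"levelorder"`,
#'   `"inorder"`, `"leaves"`.
#' @return Numeric vector of 0-based node identifiers.
#' @examples
#' tr <- parse_newick(text = "((A,B)X,(C,D)Y)R;")
#' traverse(tr, "levelorder")  # 0 1 4 2 3 5 6
#' @export
traverse <- function(tree, order = c("preorder", "postorder", "levelorder",
                                     "inorder", "leaves")) {
  stopifnot(inherits(tree, "flat_tree"))
  order <- match.arg(order)
  n <- num_nodes(tree)
  switch(order,
    preorder = seq_len(n) - 1,
    postorder = rev(seq_len(n) - 1),
    levelorder = bfs_order(tree),
    inorder = inorder_walk(tree),
    leaves = as.numeric(which(lengths(tree$children) == 0L) - 1L))
}

# breadth-first order, level by level; children lists preserve stored order
bfs_order <- function(tree) {
  n <- num_nodes(tree)
  out <- numeric(n)
  pos <- 1L
  frontier <- 0
  while (pos <= n) {
    out[pos:(pos + length(frontier) - 1L)] <- frontier
    pos <- pos + length(frontier)
    if (pos > n) break
    frontier <- unlist(tree$children[frontier + 1], use.names = FALSE)
  }
  out
}

inorder_walk <- function(tree) {
  kc <- lengths(tree$children)
  if (any(!kc %in% c(0L, 2L)))
    stop("in-order traversal is only defined for strictly binary trees",
         call. = FALSE)
  n <- num_nodes(tree)
  out <- numeric(n)
  k <- 0L
  stack <- numeric(0)
  cur <- 0
  repeat {
    while (!is.na(cur)) {
      stack <- c(stack, cur)
      kids <- tree$children[[cur + 1]]
      cur <- if (length(kids)) kids[1L] else NA_real_
    }
    if (!length(stack)) break
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- cur
    kids <- tree$children[[cur + 1]]
    cur <- if (length(kids)) kids[2L] else NA_real_
  }
  out
}

#' Children and ancestors of a node
#'
#' `children_of()` returns a node's children in stored (textual) order;
#' `ancestors_of()` walks from the parent up to and including the root.  The
#' ancestor sequence is strictly decreasing in identifier, a direct
#' consequence of the pre-order invariant.
#'
#' @param x A `flat_tree` or `level_order_tree`.
#' @param u 0-based node identifier.
#' @return Numeric vector of 0-based identifiers (empty for a leaf / the root).
#' @export
children_of <- function(x, u) UseMethod("children_of")

#' @export
children_of.flat_tree <- function(x, u) {
  u <- check_node_id(x, u)
  x$children[[u + 1]]
}

#' @rdname children_of
#' @export
ancestors_of <- function(x, u) UseMethod("ancestors_of")

#' @export
ancestors_of.flat_tree <- function(x, u) ancestors_walk(x, u)

ancestors_walk <- function(x, u) {
  u <- check_node_id(x, u)
  nul <- null_node(x$config)
  out <- numeric(0)
  p <- x$parent[u + 1]
  while (p != nul) {
    out <- c(out, p)
    p <- x$parent[p + 1]
  }
  out
}
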