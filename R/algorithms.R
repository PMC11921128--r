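#' Most recent common ancestor of a set of nodes
#'
#' Repeatedly replaces the maximum-identifier member of the working set with
#' its parent until the set collapses to a single node.  This is correct and
#' terminating because `parent[u] < u`: the maximum strictly decreases each
#' step, and any node that is not a common ancestor has a larger identifier
#' than some ancestor on another member's root path.  If the root is among
#' the inputs the root is returned immediately.  A singleton set is its own
#' MRCA.  Works on both the depth-first (`flat_tree`) and level-order
#' (`level_order_tree`) encodings, since both satisfy the ordering invariant.
#'
#' @param x A `flat_tree` or `level_order_tree`.
#' @param nodes Nonempty vector of 0-based node identifiers.
#' @return The 0-based identifier of the MRCA.
#' @examples
#' tr <- parse_newick(text = "((A,B)X,(C,D)Y)R;")
#' find_mrca(tr, c(2, 3))  # 1 (X)
#' find_mrca(tr, c(2, 5))  # 0 (R)
#' @export
find_mrca <- function(x, nodes) {
  if (length(nodes) == 0L)
    stop("'nodes' must be nonempty", call. = FALSE)
  ids <- unique(vapply(nodes, function(u) check_node_id(x, u), numeric(1)))
  if (any(ids == 0)) return(0)
  while (length(ids) > 1L) {
    m <- which.max(ids)
    ids[m] <- x$parent[ids[m] + 1]
    ids <- unique(ids)
  }
  ids
}

#' Patristic distance between two nodes
#'
#' Sum of the edge lengths on the path `u -> mrca(u, v) -> v`.  Symmetric,
#' zero on the diagonal.  Trees loaded without lengths error unless
#' `unit_lengths = TRUE`, which counts edges (hop distance) instead of
#' silently assuming unit branch lengths.
#'
#' @inheritParams find_mrca
#' @param u,v 0-based node identifiers.
#' @param unit_lengths Count each edge as 1 instead of using stored lengths.
#' @return A numeric scalar.
#' @export
patristic_distance <- function(x, u, v, unit_lengths = FALSE) {
  u <- check_node_id(x, u)
  v <- check_node_id(x, v)
  if (!unit_lengths && is.null(x$length))
    stop(paste("tree was loaded without branch lengths;",
               "use unit_lengths = TRUE for hop-count distance"), call. = FALSE)
  m <- find_mrca(x, c(u, v))
  walk_up <- function(a) {
    d <- 0
    while (a != m) {
      d <- d + if (unit_lengths) 1 else x$length[a + 1]
      a <- x$parent[a + 1]
    }
    d
  }
  walk_up(u) + walk_up(v)
}

#' Extract the subtree rooted at a node
#'
#' Copies node `r` and all of its descendants into a new `flat_tree` with a
#' fresh pre-order numbering in which the copy of `r` is node 0.  Labels and
#' lengths are carried over; the new root's stored length is zeroed by
#' default because the edge above `r` is not part of the extracted tree
#' (`keep_root_length = TRUE` preserves it).  The input tree is unchanged.
#'
#' @param tree A `flat_tree`.
#' @param r 0-based identifier of the subtree root.
#' @param keep_root_length Keep `r`'s incoming edge length on the new root?
#' @return A sealed `flat_tree` with the same configuration.
#' @export
extract_subtree <- function(tree, r, keep_root_length = FALSE) {
  stopifnot(inherits(tree, "flat_tree"))
  r <- check_node_id(tree, r)
  n <- num_nodes(tree)
  keep <- logical(n)
  keep[r + 1] <- TRUE
  if (r + 2 <= n) {
    for (i in seq(r + 2, n)) {  # node u = i - 1; parents precede children
      keep[i] <- keep[tree$parent[i] + 1]
    }
  }
  sel <- which(keep) - 1               # old ids, ascending
  m <- length(sel)
  pos <- numeric(n)                    # old id -> compact slot (1-based)
  pos[sel + 1] <- seq_len(m)
  # compact parent array (0-based slots), root slot 0
  sub_parent <- c(null_node(tree$config),
                  if (m > 1) pos[tree$parent[sel[-1] + 1] + 1] - 1)
  ord <- cpp_dfs_order(sub_parent)     # compact slots in DFS pre-order
  new_of_slot <- numeric(m)
  new_of_slot[ord + 1] <- seq_len(m) - 1
  old_of_new <- sel[ord + 1]           # new id -> old id
  parent_new <- c(null_node(tree$config),
                  if (m > 1) new_of_slot[sub_parent[ord[-1] + 1] + 1])
  out <- structure(
    list(parent = parent_new,
         children = cpp_children_list(parent_new),
         label = if (!is.null(tree$label)) tree$label[old_of_new + 1],
         length = if (!is.null(tree$length)) tree$length[old_of_new + 1],
         config = tree$config),
    class = "flat_tree")
  if (!is.null(out$length) && !keep_root_length) out$length[1] <- 0
  ct_seal(out)
}
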