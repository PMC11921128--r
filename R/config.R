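#' Tree storage configuration
#'
#' A `flat_tree` stores node identifiers as unsigned integers of a configured
#' width and branch lengths at a configured floating-point precision, and can
#' omit the label and/or length arrays entirely.  The configuration is fixed
#' at construction time and immutable afterwards.
#'
#' R has no native unsigned integer type, so identifiers are held in doubles,
#' which represent integers exactly up to 2^53.  Under the default 32-bit
#' width this is exact everywhere (the null sentinel is 2^32 - 1); under the
#' 64-bit width the sentinel 2^64 - 1 is stored as its nearest double and the
#' practical node capacity is bounded by the exact-integer range of a double.
#'
#' @param id_width Node identifier width in bits: `32` (default) or `64`.
#' @param length_precision `"single"` (default, ~7 significant digits, branch
#'   lengths are passed through a float cast on parse) or `"double"`.
#' @param store_labels,store_lengths Logical; whether the label / length
#'   arrays are kept at all.  Omitting them reduces memory for applications
#'   that only need the topology.
#' @return An object of class `"flat_tree_config"`.
#' @seealso [null_node()], [node_capacity()], [create_tree()], [parse_newick()]
#' @export
tree_config <- function(id_width = 32L, length_precision = c("single", "double"),
                        store_labels = TRUE, store_lengths = TRUE) {
  id_width <- as.integer(id_width)
  if (!id_width %in% c(32L, 64L))
    stop("'id_width' must be 32 or 64", call. = FALSE)
  length_precision <- match.arg(length_precision)
  stopifnot(is.logical(store_labels), length(store_labels) == 1L,
            is.logical(store_lengths), length(store_lengths) == 1L)
  structure(list(id_width = id_width,
                 length_precision = length_precision,
                 store_labels = store_labels,
                 store_lengths = store_lengths),
            class = "flat_tree_config")
}

#' Null-node sentinel and identifier capacity
#'
#' The maximal value of the configured width is reserved to mean "no node"
#' (the parent of the root, the child range of a leaf).  Valid identifiers
#' occupy `[0, 2^w - 2]`, so `2^w - 1` identifiers are representable.
#'
#' @param id_width 32 or 64, or a `flat_tree_config`.
#' @return `null_node()`: the sentinel value; `node_capacity()`: the number of
#'   representable non-null identifiers, `2^w - 1`.
#' @export
null_node <- function(id_width = 32L) {
  if (inherits(id_width, "flat_tree_config")) id_width <- id_width$id_width
  if (id_width == 32L) 4294967295 else 18446744073709551615
}

#' @rdname null_node
#' @export
node_capacity <- function(id_width = 32L) {
  if (inherits(id_width, "flat_tree_config")) id_width <- id_width$id_width
  if (id_width == 32L) 4294967295 else 18446744073709551615
}

#' @export
print.flat_tree_config <- function(x, ...) {
  cat(sprintf("flat_tree_config: %d-bit IDs, %s-precision lengths, labels=%s, lengths=%s\n",
              x$id_width, x$length_precision,
              if (x$store_labels) "stored" else "omitted",
              if (x$store_lengths) "stored" else "omitted"))
  invisible(x)
}
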