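#' Read a Newick tree in a single streaming pass
#'
#' Parses one Newick tree from a file or a character string into a
#' [flat_tree][create_tree].  The reader makes exactly one pass over the
#' input through a fixed-size buffer: its transient memory is bounded by
#' `buffer_size` plus one in-flight token (the longest label or number),
#' independent of the size of the tree.  Node identifiers are assigned in the
#' left-to-right depth-first pre-order of the text, so the root is node 0,
#' children appear in textual order, and `parent[u] < u` for every node.
#'
#' Dialect notes:
#' * single-quoted labels are accepted, with `''` as the escaped quote;
#'   unquoted labels end at any of `( ) , : ;`, whitespace, or a bracket;
#' * square-bracket comments `[...]` are skipped, not stored;
#' * underscores are kept verbatim;
#' * a missing length token stores `0` (there is no missing marker);
#' * length tokens may use scientific notation and a sign; negative lengths
#'   are kept, with one warning per tree;
#' * a bare `";"` yields the single-root tree;
#' * exactly one tree per input: anything after the terminating `;` other
#'   than whitespace is an error, as are unbalanced parentheses, a missing
#'   `;`, an unparseable length, and empty input.
#'
#' @param file Path to a Newick file.
#' @param text A Newick string (used instead of `file` when non-`NULL`).
#' @param config A [tree_config()]; controls identifier width, length
#'   precision, and whether labels/lengths are stored at all (skipping them
#'   saves memory but never changes the parsed topology).
#' @param buffer_size Read buffer size in bytes (default 16 KiB).
#' @return A sealed `flat_tree`.  Attribute `"parser_stats"` records
#'   `buffer_bytes` and `max_token_bytes`, the two components of the
#'   parser's transient memory.
#' @examples
#' tr <- parse_newick(text = "((A:1,B:2)X,(C:3,D:4)Y)R;")
#' tr$parent     # NULL, 0, 1, 1, 0, 4, 4
#' @export
parse_newick <- function(file = "", text = NULL, config = tree_config(),
                         buffer_size = 16384L) {
  stopifnot(inherits(config, "flat_tree_config"))
  buffer_size <- as.numeric(buffer_size)
  if (length(buffer_size) != 1L || is.na(buffer_size) || buffer_size < 1)
    stop("'buffer_size' must be a positive byte count", call. = FALSE)
  if (is.null(text)) {
    if (!nzchar(file)) stop("either 'file' or 'text' must be given", call. = FALSE)
    raw <- cpp_parse_newick(path.expand(file), TRUE, config$store_labels,
                            config$store_lengths,
                            config$length_precision == "single",
                            null_node(config), node_capacity(config), buffer_size)
  } else {
    stopifnot(is.character(text), length(text) == 1L)
    raw <- cpp_parse_newick(text, FALSE, config$store_labels,
                            config$store_lengths,
                            config$length_precision == "single",
                            null_node(config), node_capacity(config), buffer_size)
  }
  if (raw$n_negative_lengths > 0)
    warning(sprintf("%d negative branch length(s) kept as given",
                    raw$n_negative_lengths), call. = FALSE)
  tr <- structure(
    list(parent = raw$parent,
         children = cpp_children_list(raw$parent),
         label = raw$label,
         length = raw$length,
         config = config),
    class = "flat_tree")
  attr(tr, "parser_stats") <- list(buffer_bytes = raw$buffer_bytes,
                                   max_token_bytes = raw$max_token_bytes)
  ct_seal(tr)
}

#' Write a tree as Newick
#'
#' Serializes a `flat_tree` back to Newick.  Re-parsing the output yields a
#' tree identical in topology, child order and labels, with lengths equal
#' within the configured precision (9 significant digits are written for
#' single precision, 17 for double, both of which round-trip their type).
#' Labels needing it are single-quoted with `''` escaping.  Length tokens are
#' written for every non-root node when the tree stores lengths (0 for edges
#' that had none) and for the root only when its stored length is nonzero;
#' trees loaded without lengths are written without any.
#'
#' @param tree A `flat_tree`.
#' @param file Output path; if `NULL` (default) the Newick string is returned.
#' @return `file = NULL`: the Newick string.  Otherwise the path, invisibly.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "flat_tree"))
  digits <- if (tree$config$length_precision == "single") 9L else 17L
  s <- cpp_write_newick(tree$parent, tree$label, tree$length, digits)
  if (is.null(file)) return(s)
  con <- base::file(file, open = "wb")
  on.exit(close(con))
  writeLines(s, con, sep = "\n")
  invisible(file)
}
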