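# Independent reference implementations used as test oracles.
#
# oracle_parse() is a naive recursive-descent Newick parser over an in-memory
# character vector; it shares no code with the package's streaming parser.
# oracle_flatten() assigns depth-first pre-order ids to its nested-list output
# so results are directly comparable to flat_tree arrays.

oracle_parse <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else NA_character_
  advance <- function() pos <<- pos + 1L
  skip_junk <- function() {
    repeat {
      while (pos <= n && chars[pos] %in% c(" ", "\t", "\n", "\r", "\f", "\v"))
        advance()
      if (pos <= n && chars[pos] == "[") {
        depth <- 1L
        advance()
        while (pos <= n && depth > 0L) {
          if (chars[pos] == "[") depth <- depth + 1L
          if (chars[pos] == "]") depth <- depth - 1L
          advance()
        }
        if (depth > 0L) stop("oracle: unterminated comment")
      } else {
        break
      }
    }
  }
  read_quoted <- function() {
    advance()  # opening '
    out <- character(0)
    repeat {
      if (pos > n) stop("oracle: unterminated quote")
      c0 <- chars[pos]
      if (c0 == "'") {
        if (pos + 1L <= n && chars[pos + 1L] == "'") {
          out <- c(out, "'")
          pos <<- pos + 2L
        } else {
          advance()
          break
        }
      } else {
        out <- c(out, c0)
        advance()
      }
    }
    paste(out, collapse = "")
  }
  read_bare <- function() {
    out <- character(0)
    repeat {
      c0 <- peek()
      if (is.na(c0) || c0 %in% c("(", ")", ",", ":", ";", "[", "]",
                                 " ", "\t", "\n", "\r", "\f", "\v")) break
      out <- c(out, c0)
      advance()
    }
    paste(out, collapse = "")
  }
  read_node <- function() {
    skip_junk()
    kids <- list()
    if (identical(peek(), "(")) {
      advance()
      repeat {
        kids[[length(kids) + 1L]] <- read_node()
        skip_junk()
        if (identical(peek(), ",")) {
          advance()
        } else if (identical(peek(), ")")) {
          advance()
          break
        } else {
          stop("oracle: expected ',' or ')'")
        }
      }
    }
    skip_junk()
    lab <- if (identical(peek(), "'")) read_quoted() else read_bare()
    skip_junk()
    len <- 0
    if (identical(peek(), ":")) {
      advance()
      skip_junk()
      tok <- read_bare()
      len <- suppressWarnings(as.numeric(tok))
      if (is.na(len)) stop("oracle: bad length token")
      skip_junk()
    }
    list(label = lab, length = len, children = kids)
  }

  root <- read_node()
  skip_junk()
  if (!identical(peek(), ";")) stop("oracle: missing ';'")
  advance()
  skip_junk()
  if (pos <= n) stop("oracle: trailing content")
  root
}

# DFS pre-order flattening of an oracle_parse() nested list
oracle_flatten <- function(node) {
  parent <- numeric(0)
  label <- character(0)
  length_ <- numeric(0)
  rec <- function(nd, par) {
    id <- length(parent)
    parent[id + 1L] <<- par
    label[id + 1L] <<- nd$label
    length_[id + 1L] <<- nd$length
    for (kid in nd$children) rec(kid, id)
  }
  rec(node, -1)
  list(parent = parent, label = label, length = length_)
}

# compare a flat_tree against the oracle's flattening of the same text
expect_matches_oracle <- function(tree, text, length_tol = 1e-6) {
  ref <- oracle_flatten(oracle_parse(text))
  got_parent <- tree$parent
  got_parent[1] <- -1
  expect_equal(got_parent, ref$parent, ignore_attr = TRUE)
  if (!is.null(tree$label)) expect_equal(tree$label, ref$label)
  if (!is.null(tree$length))
    expect_equal(tree$length, ref$length, tolerance = length_tol)
  invisible(TRUE)
}

# --- random Newick text generator (adversarial dialect features) -----------

rand_label <- function() {
  kind <- sample(4, 1)
  if (kind == 1L) return("")
  base <- paste(sample(c(letters, LETTERS, 0:9, "_", "."),
                       sample(1:8, 1), replace = TRUE), collapse = "")
  if (kind <= 3L) return(base)
  # quoted label with specials and escaped quotes
  inner <- paste(sample(c(letters, " ", "(", ")", ",", ":", ";", "'"),
                        sample(1:6, 1), replace = TRUE), collapse = "")
  paste0("'", gsub("'", "''", inner), "'")
}

rand_length_token <- function() {
  kind <- sample(4, 1)
  if (kind == 1L) return("")  # missing length
  v <- switch(kind - 1L,
              signif(runif(1, 0, 5), 4),
              signif(runif(1, 0, 1e-4), 3),   # forces scientific notation
              round(runif(1, 0, 20)))
  paste0(":", format(v, scientific = kind == 3L))
}

rand_pad <- function() {
  if (runif(1) < 0.15) " " else if (runif(1) < 0.05) "[a comment]" else ""
}

rand_newick_node <- function(depth, max_depth) {
  if (depth >= max_depth || runif(1) < 0.35) {
    return(paste0(rand_label(), rand_length_token()))
  }
  k <- sample(2:4, 1)  # multifurcations included
  kids <- vapply(seq_len(k), function(i) rand_newick_node(depth + 1L, max_depth),
                 character(1))
  paste0("(", paste(kids, collapse = ","), ")", rand_pad(),
         rand_label(), rand_length_token())
}

rand_newick <- function(max_depth = 5L) {
  paste0(rand_pad(), rand_newick_node(0L, max_depth), rand_pad(), ";")
}

# --- brute-force algorithm oracles ------------------------------------------

# ancestors of u including u, by parent walk
oracle_ancestor_set <- function(tree, u) {
  nul <- phyloflat::null_node(tree$config)
  out <- u
  p <- tree$parent[u + 1]
  while (p != nul) {
    out <- c(out, p)
    p <- tree$parent[p + 1]
  }
  out
}

# MRCA = common member of all ancestor sets with maximum depth
oracle_mrca <- function(tree, nodes) {
  common <- Reduce(intersect, lapply(nodes, function(u) oracle_ancestor_set(tree, u)))
  depth <- oracle_depths(tree)
  common[which.max(depth[common + 1])]
}

oracle_depths <- function(tree) {
  n <- length(tree$parent)
  d <- numeric(n)
  for (u in seq_len(n - 1)) d[u + 1] <- d[tree$parent[u + 1] + 1] + 1
  d
}

# weighted shortest-path oracle over the tree graph (igraph)
oracle_distance_matrix <- function(tree) {
  n <- num_nodes(tree)
  kids <- seq_len(n - 1)  # 0-based ids 1..n-1
  g <- igraph::graph_from_edgelist(
    cbind(tree$parent[kids + 1] + 1, kids + 1), directed = FALSE)
  igraph::distances(g, weights = tree$length[kids + 1])
}

# leaf labels below r, by recursive descent over children lists
oracle_descendant_leaves <- function(tree, r) {
  kids <- tree$children[[r + 1]]
  if (!length(kids)) return(tree$label[r + 1])
  unlist(lapply(kids, function(k) oracle_descendant_leaves(tree, k)))
}

# recursive reference traversals
oracle_preorder <- function(tree, u = 0) {
  c(u, unlist(lapply(tree$children[[u + 1]], function(k) oracle_preorder(tree, k))))
}
oracle_levelorder <- function(tree) {
  out <- numeric(0)
  q <- 0
  while (length(q)) {
    out <- c(out, q[1])
    q <- c(q[-1], tree$children[[q[1] + 1]])
  }
  out
}
oracle_inorder <- function(tree, u = 0) {
  kids <- tree$children[[u + 1]]
  if (!length(kids)) return(u)
  c(oracle_inorder(tree, kids[1]), u, oracle_inorder(tree, kids[2]))
}

# ultrametric check helper: root-to-node path lengths by ascending sweep
root_path_lengths <- function(tree) {
  n <- num_nodes(tree)
  pl <- numeric(n)
  for (u in seq_len(n - 1)) pl[u + 1] <- pl[tree$parent[u + 1] + 1] + tree$length[u + 1]
  pl
}
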