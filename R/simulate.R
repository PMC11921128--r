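#' Simulate a tree under the dual-birth (Yule) branching process
#'
#' Gillespie simulation of a binary branching process in which every live
#' lineage carries one of two splitting rates: at each event the waiting time
#' is exponential with rate equal to the sum of live rates, the splitting
#' lineage is chosen with probability proportional to its rate, and it is
#' replaced by two daughters, one carrying `rate_a` and one `rate_b`.  Equal
#' rates give the Yule pure-birth model.  Simulation stops when `n_leaves`
#' live lineages exist; a lineage's branch length is the time from its
#' creation to its split, and lineages still live at the stop are truncated
#' at the stopping time (the final split).  Under this stopping rule the
#' truncation already equalizes all root-to-leaf path lengths, so the
#' `ultrametric` flag does not change the lengths; it is retained to make
#' the intent explicit in calling code.  For the Yule model with rate
#' `lambda` the expected total branch length is `(n_leaves - 1) / lambda`.
#'
#' The result is a strictly binary rooted `flat_tree` with `2 * n_leaves - 1`
#' nodes, identifiers renumbered into depth-first pre-order, leaves labeled
#' with deterministic zero-padded indices (`"L001"`, ...) and internal nodes
#' unlabeled.  The same seed reproduces the identical tree (R's default
#' Mersenne-Twister RNG).
#'
#' @param n_leaves Target number of leaves (>= 1).
#' @param rate_a,rate_b Positive splitting rates of the two daughter classes;
#'   the root lineage carries `rate_a`.  Defaults give Yule with rate 1.
#' @param seed Optional integer seed (`set.seed`) for reproducible trees; if
#'   `NULL` the current RNG stream is used.
#' @param ultrametric Extend live lineages to the stopping time (see above).
#' @param config A [tree_config()].
#' @param label_leaves Attach deterministic leaf labels?  (Internal nodes are
#'   never labeled.)
#' @return A sealed `flat_tree`.
#' @examples
#' tr <- simulate_tree(100, seed = 1)
#' num_nodes(tr)   # 199
#' @export
simulate_tree <- function(n_leaves, rate_a = 1, rate_b = rate_a, seed = NULL,
                          ultrametric = FALSE, config = tree_config(),
                          label_leaves = TRUE) {
  stopifnot(length(n_leaves) == 1L, n_leaves >= 1, n_leaves == trunc(n_leaves),
            length(rate_a) == 1L, is.finite(rate_a), rate_a > 0,
            length(rate_b) == 1L, is.finite(rate_b), rate_b > 0,
            inherits(config, "flat_tree_config"))
  if (!is.null(seed)) set.seed(seed)
  n_leaves <- as.numeric(n_leaves)
  n_nodes <- 2 * n_leaves - 1
  if (n_nodes > node_capacity(config))
    stop("tree would exceed the capacity of the configured ID width", call. = FALSE)
  nul <- null_node(config)

  parent <- numeric(n_nodes)
  created <- numeric(n_nodes)
  edge_len <- numeric(n_nodes)
  parent[1] <- nul

  # live-lineage pools per rate class, O(1) add/remove (swap with last)
  live_a <- numeric(n_leaves); na <- 1L; live_a[1] <- 0
  live_b <- numeric(n_leaves); nb <- 0L
  n_created <- 1
  t <- 0
  while (na + nb < n_leaves) {
    total_rate <- na * rate_a + nb * rate_b
    t <- t + rexp(1L, total_rate)
    if (runif(1L) < na * rate_a / total_rate) {
      i <- if (na > 1L) sample.int(na, 1L) else 1L
      u <- live_a[i]; live_a[i] <- live_a[na]; na <- na - 1L
    } else {
      i <- if (nb > 1L) sample.int(nb, 1L) else 1L
      u <- live_b[i]; live_b[i] <- live_b[nb]; nb <- nb - 1L
    }
    edge_len[u + 1] <- t - created[u + 1]
    c1 <- n_created; c2 <- n_created + 1   # 0-based ids of the daughters
    parent[c1 + 1] <- u; parent[c2 + 1] <- u
    created[c1 + 1] <- t; created[c2 + 1] <- t
    na <- na + 1L; live_a[na] <- c1
    nb <- nb + 1L; live_b[nb] <- c2
    n_created <- n_created + 2
  }
  if (n_leaves > 1) {
    live <- c(live_a[seq_len(na)], live_b[seq_len(nb)])
    edge_len[live + 1] <- t - created[live + 1]   # truncate at stopping time
  }

  # creation order satisfies parent[u] < u; renumber into DFS pre-order
  new2old <- cpp_dfs_order(parent)
  perm <- numeric(n_nodes)
  perm[new2old + 1] <- seq_len(n_nodes) - 1
  parent_new <- c(nul, if (n_nodes > 1) perm[parent[new2old[-1] + 1] + 1])
  len_new <- edge_len[new2old + 1]
  if (config$length_precision == "single") len_new <- cpp_as_single(len_new)
  children <- cpp_children_list(parent_new)

  label <- NULL
  if (config$store_labels) {
    label <- character(n_nodes)
    if (label_leaves) {
      leaf_ids <- which(lengths(children) == 0L)   # 1-based positions
      width <- max(3L, nchar(as.character(n_leaves)))
      label[leaf_ids] <- sprintf("L%0*d", width, seq_along(leaf_ids))
    }
  }
  tr <- structure(
    list(parent = parent_new,
         children = children,
         label = label,
         length = if (config$store_lengths) len_new,
         config = config),
    class = "flat_tree")
  ct_seal(tr)
}

#' Write a suite of simulated Newick fixture files
#'
#' Simulates one Yule/dual-birth tree per requested size and writes each to a
#' Newick file under `dir`.  The RNG is seeded once and the stream continues
#' across trees, so repeated sizes give distinct trees while a rerun with the
#' same seed reproduces the whole suite byte for byte.
#'
#' @param sizes Vector of leaf counts (possibly empty: no files are written).
#' @param seed Integer seed for the whole suite.
#' @param dir Output directory (created if needed).
#' @param rate_a,rate_b Splitting rates, as in [simulate_tree()].
#' @param config A [tree_config()].
#' @return Character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(sizes, seed = 1L, dir = tempdir(),
                               rate_a = 1, rate_b = rate_a,
                               config = tree_config()) {
  stopifnot(is.numeric(sizes), all(sizes >= 1))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  paths <- character(length(sizes))
  for (i in seq_along(sizes)) {
    tr <- simulate_tree(sizes[i], rate_a = rate_a, rate_b = rate_b,
                        config = config)
    paths[i] <- file.path(dir, sprintf("sim_n%d_%02d.nwk", as.integer(sizes[i]), i))
    write_newick(tr, paths[i])
  }
  invisible(paths)
}
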