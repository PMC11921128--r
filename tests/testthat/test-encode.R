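test_that("flat child array reproduces every children list by slicing", {
  fc <- build_flat_children(parse_newick(text = "(A,B,C);"))
  expect_equal(fc$child_ids, c(1, 2, 3))
  expect_equal(unname(fc$offsets[1, ]), c(0, 3))
  expect_equal(unname(fc$offsets[2, ]), c(3, 3))

  single <- build_flat_children(parse_newick(text = ";"))
  expect_equal(length(single$child_ids), 0)

  set.seed(5)
  for (t in 1:10) {
    tr <- parse_newick(text = rand_newick(max_depth = 4))
    fc <- build_flat_children(tr)
    n <- num_nodes(tr)
    expect_equal(length(fc$child_ids), n - 1)   # one entry per edge
    # offsets tile [0, N-1) in order
    expect_equal(unname(fc$offsets[1, "start"]), 0)
    expect_equal(unname(fc$offsets[n, "end"]), n - 1)
    expect_true(all(fc$offsets[, "end"] >= fc$offsets[, "start"]))
    if (n > 1) expect_equal(fc$offsets[2:n, "start"], fc$offsets[1:(n - 1), "end"],
                            ignore_attr = TRUE)
    for (u in 0:(n - 1)) {
      o <- fc$offsets[u + 1, ]
      slice <- if (o[2] > o[1]) fc$child_ids[(o[1] + 1):o[2]] else numeric(0)
      expect_equal(slice, tr$children[[u + 1]])
    }
  }
})

test_that("level-order renumbering matches the hand BFS of the example", {
  tr <- parse_newick(text = "((A,B)X,(C,D)Y)R;")
  lo <- to_level_order(tr)
  nul <- null_node(32)
  # R=0, X=1, Y=2, A=3, B=4, C=5, D=6
  expect_equal(lo$perm, c(0, 1, 3, 4, 2, 5, 6))
  expect_equal(lo$label, c("R", "X", "Y", "A", "B", "C", "D"))
  expect_equal(c(lo$min_child[2], lo$max_child[2]), c(3, 4))
  expect_equal(c(lo$min_child[3], lo$max_child[3]), c(5, 6))
  expect_equal(lo$min_child[4], nul)

  leaf <- to_level_order(parse_newick(text = ";"))
  expect_equal(leaf$min_child, nul)
  expect_equal(leaf$max_child, nul)
})

test_that("level-order trees are isomorphic to their source and keep the invariant", {
  set.seed(404)
  for (t in 1:40) {
    tr <- if (t %% 2) simulate_tree(sample(2:60, 1))
          else parse_newick(text = rand_newick(max_depth = 4))
    lo <- to_level_order(tr)
    n <- num_nodes(tr)
    nul <- null_node(tr$config)
    expect_equal(sort(lo$perm), 0:(n - 1), ignore_attr = TRUE)  # bijection
    expect_equal(num_leaves(lo), num_leaves(tr))
    if (n > 1) {
      # perm-conjugated parent arrays are equal: perm[parent_dfs[old]] == parent_lo[perm[old]]
      old <- 1:(n - 1)
      expect_equal(lo$parent[lo$perm[old + 1] + 1], lo$perm[tr$parent[old + 1] + 1])
      # pre-order invariant survives renumbering
      new_kids <- 1:(n - 1)
      expect_true(all(lo$parent[new_kids + 1] < new_kids))
      # labels and lengths permuted consistently
      expect_equal(lo$label[lo$perm + 1], tr$label)
      expect_equal(lo$length[lo$perm + 1], tr$length)
    }
    # child_range contiguity: children of u are exactly [min_child, max_child]
    for (u in 0:(n - 1)) {
      kids_new <- sort(lo$perm[tr$children[[u + 1]] + 1])
      if (!length(kids_new)) {
        expect_equal(lo$min_child[lo$perm[u + 1] + 1], nul)
      } else {
        rng <- c(lo$min_child[lo$perm[u + 1] + 1], lo$max_child[lo$perm[u + 1] + 1])
        expect_equal(kids_new, seq(rng[1], rng[2]))
      }
    }
  }
})

test_that("MRCA and distances are invariant under the level-order renumbering", {
  set.seed(505)
  for (t in 1:4) {
    tr <- simulate_tree(80)
    lo <- to_level_order(tr)
    n <- num_nodes(tr)
    for (q in 1:60) {
      nodes <- sample(0:(n - 1), sample(2:4, 1))
      expect_equal(find_mrca(lo, lo$perm[nodes + 1]),
                   lo$perm[find_mrca(tr, nodes) + 1])
    }
    for (q in 1:25) {
      uv <- sample(0:(n - 1), 2)
      expect_equal(patristic_distance(lo, lo$perm[uv[1] + 1], lo$perm[uv[2] + 1]),
                   patristic_distance(tr, uv[1], uv[2]), tolerance = 1e-9)
    }
  }
})

test_that("identifier storage accounting: N-1 child entries vs 2N range entries", {
  tr <- parse_newick(text = "((A,B)X,(C,D)Y)R;")
  dfs <- integer_storage_count(tr)
  expect_equal(unname(dfs["child_entries"]), 6)
  expect_equal(unname(dfs["parents"]), 7)
  lvl <- integer_storage_count(to_level_order(tr))
  expect_equal(unname(lvl["range_entries"]), 14)
  expect_equal(unname(lvl["total"]), 21)
  # topology-only accounting: label/length omission changes nothing
  bare <- parse_newick(text = "((A,B)X,(C,D)Y)R;",
                       config = tree_config(store_labels = FALSE,
                                            store_lengths = FALSE))
  expect_equal(integer_storage_count(bare), dfs)
  expect_equal(integer_storage_count(to_level_order(bare)), lvl)
})
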