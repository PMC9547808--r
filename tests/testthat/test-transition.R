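test_that("row_normalize divides positive rows and keeps zero rows zero", {
  A <- rbind(c(1, 3), c(0, 0))
  N <- as.matrix(row_normalize(A))
  expect_equal(N[1, ], c(0.25, 0.75), ignore_attr = TRUE)
  expect_equal(N[2, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(as.numeric(row_normalize(rbind(c(0, 5, 0)))),
               c(0, 1, 0))
  expect_error(row_normalize(rbind(c(-1, 2))), "nonnegative")
})

test_that("off-diagonal blocks are jump-scaled row normalizations", {
  A <- rbind(c(1, 1, 0), c(0, 0, 0))
  B <- as.matrix(offdiagonal_block(A, 0.3))
  expect_equal(B[1, ], c(0.15, 0.15, 0), ignore_attr = TRUE)
  expect_equal(B[2, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(max(abs(as.matrix(offdiagonal_block(A, 0)))), 0)
  expect_error(offdiagonal_block(A, 1), "\\[0, 1\\)")
  expect_error(offdiagonal_block(A, -0.1), "\\[0, 1\\)")
})

test_that("diagonal blocks damp rows by the per-node stay probability", {
  A <- rbind(c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))
  lambda_i <- c(0, 0.2, 0.2)      # layer 1 of 3
  ind <- rbind(c(0, 1, 1),        # node 1 crosses into both other layers
               c(0, 0, 0),        # node 2 has no cross links
               c(0, 1, 0))        # node 3 is within-layer isolated
  D <- as.matrix(diagonal_block(A, lambda_i, ind))
  expect_equal(D[1, ], c(0, 0.3, 0.3), ignore_attr = TRUE)   # (1-0.4)/2
  expect_equal(D[2, ], c(0.5, 0, 0.5), ignore_attr = TRUE)   # stay = 1
  expect_equal(D[3, ], c(0, 0, 0), ignore_attr = TRUE)       # zero row stays
})

test_that("jump_spec defaults split total mass over coupled layers only", {
  l1 <- as_subnetwork(edges_tbl("disease", "d", "gene", "APP"), name = "a")
  l2 <- as_subnetwork(edges_tbl("pathway", "p", "gene", "APP"), name = "b")
  l3 <- as_subnetwork(edges_tbl("pathway", "q", "gene", "ZZZ"), name = "c")
  net <- build_multinet(list(l1, l2, l3))
  L <- unclass(jump_spec(net, total_jump = 0.5))
  # layers a and b share APP; c is disjoint from both
  expect_equal(L[1, ], c(0, 0.5, 0), ignore_attr = TRUE)
  expect_equal(L[2, ], c(0.5, 0, 0), ignore_attr = TRUE)
  expect_equal(L[3, ], c(0, 0, 0), ignore_attr = TRUE)

  expect_error(jump_spec(net, lambda = diag(0.2, 3)), "zero diagonal")
  bad <- matrix(0.6, 3, 3); diag(bad) <- 0
  expect_error(jump_spec(net, lambda = bad), "at most 1")
})

test_that("a single layer with no isolated nodes reduces to plain row normalization", {
  net <- build_multinet(list(cycle_layer(5)))
  tm <- assemble_transition(net)
  expect_equal(as.matrix(tm$M),
               as.matrix(row_normalize(net$adjacency[[1]])))
  expect_equal(tm$row_sums, rep(1, 5), tolerance = 1e-12)
  expect_equal(nrow(tm$layout), 1)
})

test_that("block layout is K^2 blocks in layer order", {
  toy <- generate_toy_network(toy_network_params(rng_seed = 2))
  tm3 <- assemble_transition(toy$network)
  expect_equal(nrow(tm3$layout), 9)
  expect_equal(nrow(assemble_transition(
    build_multinet(seven_layer_fixture()))$layout), 49)
  # spans tile the matrix
  expect_equal(sum((tm3$layout$row_end - tm3$layout$row_start + 1) *
                     (tm3$layout$col_end - tm3$layout$col_start + 1)),
               nrow(tm3$M)^2)
})

test_that("rows with a within-layer edge sum to exactly 1", {
  for (seed in c(4, 21, 33)) {
    net <- random_multinet(seed)
    tm <- assemble_transition(net, total_jump = 0.6)
    within_deg <- unlist(lapply(net$adjacency, rowSums))
    has_edge <- within_deg > 0
    expect_true(all(abs(tm$row_sums[has_edge] - 1) <= 1e-12))
    # substochastic rows only where the within-layer row is zero
    expect_true(all(has_edge | tm$row_sums <= 1 + 1e-12))
    expect_equal(nrow(row_sum_report(tm)), sum(!has_edge))
  }
})

test_that("zero jumping probabilities give a block-diagonal matrix", {
  net <- random_multinet(8)
  K <- net$K
  tm <- assemble_transition(net, jumps = matrix(0, K, K))
  off <- dplyr::filter(tm$layout, .data$layer_row != .data$layer_col)
  expect_true(all(off$nnz == 0))
  # and each diagonal block is the layer's own row normalization
  d1 <- dplyr::filter(tm$layout, .data$layer_row == 1, .data$layer_col == 1)
  block <- tm$M[d1$row_start:d1$row_end, d1$col_start:d1$col_end]
  expect_equal(as.matrix(block), as.matrix(row_normalize(net$adjacency[[1]])))
})

test_that("blockwise assembly matches an independent dense construction", {
  for (seed in c(6, 14, 27)) {
    net <- random_multinet(seed)
    L <- withr::with_seed(seed, random_lambda(net$K))
    tm <- assemble_transition(net, jumps = L)
    expect_lt(max(abs(as.matrix(tm$M) - dense_transition_oracle(net, L))),
              1e-12)
  }
})
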