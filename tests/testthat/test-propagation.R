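# 2-node single-layer fixture with M = [[0,1],[1,0]]; seeded at node 1 the
# recursion S = alpha * t(M) S + (1-alpha) S0 with alpha = 0.5 has the
# hand-solved fixed point (2/3, 1/3).
two_node <- function() {
  net <- build_multinet(list(as_subnetwork(
    edges_tbl("gene", "A", "gene", "B"), name = "pair"
  )))
  list(net = net, tm = assemble_transition(net))
}

test_that("seed mass splits equally over entities, then over replicas", {
  l1 <- as_subnetwork(edges_tbl("disease", "d", "gene", c("APP", "B")),
                      name = "x")
  l2 <- as_subnetwork(edges_tbl("pathway", "p", "gene", c("APP", "C")),
                      name = "y")
  net <- build_multinet(list(l1, l2))

  s1 <- seed_vector(net, "gene:APP")
  hits <- which(net$index$key == "gene:APP")
  expect_equal(s1$scores[hits], c(0.5, 0.5))
  expect_equal(sum(s1$scores), 1)

  s2 <- seed_vector(net, c("gene:B", "gene:C"))  # each in one layer
  expect_equal(sort(s2$scores[s2$scores > 0]), c(0.5, 0.5))

  expect_error(seed_vector(net, "gene:XYZ"), "gene:XYZ")
})

test_that("a single step is exactly alpha * t(M) s + (1 - alpha) s0", {
  f <- two_node()
  s0 <- c(1, 0)
  expect_equal(propagate_step(f$tm, c(0.4, 0.6), s0, alpha = 0), s0)
  expect_equal(propagate_step(f$tm, s0, s0, alpha = 0.5), c(0.5, 0.5))
  expect_equal(propagate_step(f$tm, c(0, 0), s0, alpha = 0.5), 0.5 * s0)
  expect_error(propagate_step(f$tm, c(1, 0, 0), s0, 0.5), "length")
})

test_that("iteration reaches the hand-solved two-node fixed point", {
  f <- two_node()
  s0 <- seed_vector(f$net, "gene:A")
  s <- propagate(f$tm, s0, alpha = 0.5, tol = 1e-12)
  expect_true(s$converged)
  expect_equal(s$scores, c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(closed_form_scores(f$tm, s0, alpha = 0.5)$scores,
               c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("alpha = 0 returns the seed vector after one step", {
  f <- two_node()
  s0 <- seed_vector(f$net, "gene:A")
  s <- propagate(f$tm, s0, alpha = 0)
  expect_equal(s$scores, s0$scores)
  expect_equal(s$iteration, 1L)
  expect_equal(closed_form_scores(f$tm, s0, alpha = 0)$scores, s0$scores)
})

test_that("the closed form matches a dense base-R linear solve", {
  net <- random_multinet(19)
  L <- withr::with_seed(19, random_lambda(net$K))
  tm <- assemble_transition(net, jumps = L)
  s0 <- seed_vector(net, entity("gene", "G0001"))
  alpha <- 0.7
  ref <- solve(diag(net$N) - alpha * t(as.matrix(tm$M)),
               (1 - alpha) * s0$scores)
  expect_equal(closed_form_scores(tm, s0, alpha)$scores, as.numeric(ref),
               tolerance = 1e-12)
})

test_that("iterative propagation matches the closed form on random networks", {
  for (seed in c(2, 31, 58)) {
    net <- random_multinet(seed)
    L <- withr::with_seed(seed + 1000, random_lambda(net$K))
    alpha <- withr::with_seed(seed + 2000, runif(1, 0.1, 0.9))
    tm <- assemble_transition(net, jumps = L)
    s0 <- seed_vector(net, entity("gene", "G0001"))
    it <- propagate(tm, s0, alpha = alpha, tol = 1e-13, max_iter = 5000)
    cf <- closed_form_scores(tm, s0, alpha = alpha)
    expect_lt(max(abs(it$scores - cf$scores)), 1e-8)
  }
})

test_that("score mass is conserved when every row is stochastic", {
  net <- build_multinet(list(cycle_layer(8, "c1"), cycle_layer(8, "c2")))
  tm <- assemble_transition(net)
  expect_equal(tm$row_sums, rep(1, net$N), tolerance = 1e-12)
  s0 <- seed_vector(net, "gene:G1")
  s <- propagate(tm, s0, alpha = 0.7, keep_trace = TRUE)
  expect_true(all(abs(s$trace$total_mass - 1) <= 1e-12))
  expect_equal(sum(s$scores), 1, tolerance = 1e-12)
})

test_that("the L1 residual contracts at rate at most alpha", {
  net <- random_multinet(42)
  tm <- assemble_transition(net)
  s0 <- seed_vector(net, entity("gene", "G0001"))
  for (alpha in c(0.3, 0.7, 0.9)) {
    s <- propagate(tm, s0, alpha = alpha, tol = 1e-11, keep_trace = TRUE)
    r <- s$trace$residual
    ratios <- r[-1] / r[-length(r)]
    expect_true(all(ratios <= alpha + 1e-9))
  }
})

test_that("non-convergence is reported, never silent", {
  net <- random_multinet(13)
  tm <- assemble_transition(net)
  s0 <- seed_vector(net, entity("gene", "G0001"))
  expect_warning(
    s <- propagate(tm, s0, alpha = 0.9, tol = 1e-12, max_iter = 3),
    "did not converge"
  )
  expect_false(s$converged)
  expect_equal(s$iteration, 3L)
  expect_gt(s$residual, 0)
})

test_that("scores are equal on automorphism orbits of star and cycle", {
  # star: all leaves are exchangeable around the seeded center
  star <- build_multinet(list(star_layer(6)))
  s <- propagate(assemble_transition(star),
                 seed_vector(star, "gene:CENTER"), alpha = 0.7,
                 tol = 1e-12)
  leaves <- tidy(s) |> dplyr::filter(.data$identifier != "CENTER")
  expect_lt(diff(range(leaves$score)), 1e-12)

  # two coupled cycle replicas: nodes at the same distance from the seed
  # (clockwise or counterclockwise, either layer) form an orbit
  cyc <- build_multinet(list(cycle_layer(7, "c1"), cycle_layer(7, "c2")))
  s2 <- propagate(assemble_transition(cyc), seed_vector(cyc, "gene:G1"),
                  alpha = 0.7, tol = 1e-12)
  d <- tidy(s2) |>
    dplyr::mutate(pos = as.integer(sub("G", "", .data$identifier)),
                  dist = pmin((.data$pos - 1) %% 7, (1 - .data$pos) %% 7))
  spread <- d |>
    dplyr::group_by(.data$layer, .data$dist) |>
    dplyr::summarise(spread = diff(range(.data$score)), .groups = "drop")
  expect_true(all(spread$spread <= 1e-12))
})

test_that("zero jumping probabilities confine mass to the seed's layer", {
  toy <- generate_toy_network(toy_network_params(rng_seed = 3))
  net <- toy$network
  tm <- assemble_transition(net, jumps = matrix(0, net$K, net$K))
  seed_l1 <- net$index[net$index$layer == 1 &
                         net$index$entity_type == "gene", ][1, ]
  s0 <- numeric(net$N)
  s0[seed_l1$node_id] <- 1
  s <- propagate(tm, s0, alpha = 0.7)
  expect_true(all(s$scores[net$index$layer != 1] == 0))
  expect_gt(sum(s$scores[net$index$layer == 1]), 0)
})

test_that("the planted partner's score is nondecreasing in the coupling", {
  # 2-layer fixture: seeded cycle in layer 1; the partner meets the seed
  # replica only in layer 2
  l1 <- cycle_layer(5, "c1")
  l2 <- as_subnetwork(
    edges_tbl("gene", c("G1", "PARTNER"), "gene", c("PARTNER", "Q1")),
    name = "meet"
  )
  net <- build_multinet(list(l1, l2))
  s0 <- numeric(net$N)  # all seed mass on the layer-1 replica of G1
  s0[net$index$node_id[net$index$layer == 1 & net$index$key == "gene:G1"]] <- 1
  partner_id <- net$index$node_id[net$index$key == "gene:PARTNER"]
  partner_score <- vapply(seq(0, 0.8, by = 0.1), function(lam) {
    L <- matrix(c(0, lam, 0.1, 0), 2, 2, byrow = TRUE)  # vary only lambda_12
    tm <- assemble_transition(net, jumps = L)
    closed_form_scores(tm, s0, alpha = 0.7)$scores[partner_id]
  }, numeric(1))
  expect_true(all(diff(partner_score) >= -1e-12))
  expect_gt(partner_score[9], partner_score[1])
})

test_that("single-layer propagation agrees with personalized PageRank", {
  net <- build_multinet(list(cycle_layer(9)))
  tm <- assemble_transition(net)
  s0 <- seed_vector(net, "gene:G1")
  alpha <- 0.85
  mine <- propagate(tm, s0, alpha = alpha, tol = 1e-13)$scores

  g <- igraph::graph_from_adjacency_matrix(net$adjacency[[1]],
                                           mode = "undirected")
  pr <- igraph::page_rank(g, damping = alpha,
                          personalized = s0$scores)$vector
  expect_equal(mine, as.numeric(pr), tolerance = 1e-8)
})
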