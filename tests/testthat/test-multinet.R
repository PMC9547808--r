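test_that("shared entities become cross links, one per layer pair and entity", {
  l1 <- as_subnetwork(edges_tbl("disease", "d1", "gene", c("APP", "X1")),
                      name = "dg")
  l2 <- as_subnetwork(edges_tbl("pathway", "p1", "gene", c("APP", "X2")),
                      name = "pg")
  net <- build_multinet(list(l1, l2))
  expect_equal(nrow(net$cross_links), 1)
  expect_equal(net$cross_links$identifier, "APP")
  expect_equal(length(bipartite_block(net, 1, 2)@x), 1)

  # disjoint layers: no cross links, empty blocks
  l3 <- as_subnetwork(edges_tbl("pathway", "p9", "gene", "ZZZ"), name = "pg2")
  net2 <- build_multinet(list(l1, l3))
  expect_equal(nrow(net2$cross_links), 0)
  expect_equal(length(bipartite_block(net2, 1, 2)@x), 0)
})

test_that("three layers sharing two genes give six cross links", {
  mk <- function(nm, extra) {
    as_subnetwork(edges_tbl("disease", extra, "gene", c("G1", "G2")),
                  name = nm)
  }
  net <- build_multinet(list(mk("a", "d1"), mk("b", "d2"), mk("c", "d3")))
  expect_equal(nrow(net$cross_links), 6)
})

test_that("duplicate layer names are a configuration error", {
  l1 <- as_subnetwork(edges_tbl("gene", "A", "gene", "B"), name = "same")
  l2 <- as_subnetwork(edges_tbl("gene", "C", "gene", "D"), name = "same")
  expect_error(build_multinet(list(l1, l2)), "Duplicate layer name")
})

test_that("global index is contiguous with one row per (layer, entity)", {
  net <- random_multinet(11)
  expect_equal(net$index$node_id, seq_len(net$N))
  expect_equal(anyDuplicated(paste(net$index$layer, net$index$key)), 0)
  # within a layer, nodes sorted by entity key
  for (i in seq_len(net$K)) {
    keys <- net$index$key[net$index$layer == i]
    expect_equal(keys, sort(keys))
  }
})

test_that("bipartite blocks are mutually transposed", {
  for (seed in c(3, 17)) {
    net <- random_multinet(seed)
    for (i in seq_len(net$K)) {
      for (j in seq_len(net$K)) {
        if (i == j) next
        expect_equal(
          as.matrix(bipartite_block(net, i, j)),
          t(as.matrix(bipartite_block(net, j, i)))
        )
      }
    }
  }
})

test_that("layer input order permutes the index but not entity-level results", {
  toy <- generate_toy_network(toy_network_params(
    genes_per_layer = 15, other_nodes_per_layer = 6, rng_seed = 5
  ))
  layers <- toy$network$layers
  net_a <- build_multinet(layers)
  net_b <- build_multinet(rev(layers))

  named_links <- function(net) {
    nm <- vapply(net$layers, function(l) l$name, character(1))
    dplyr::mutate(net$cross_links,
                  layer_name_a = nm[.data$layer_a],
                  layer_name_b = nm[.data$layer_b])
  }
  canon <- function(links) {
    dplyr::arrange(
      dplyr::mutate(links,
                    a = pmin(.data$layer_name_a, .data$layer_name_b),
                    b = pmax(.data$layer_name_a, .data$layer_name_b)),
      .data$a, .data$b, .data$identifier
    )[, c("a", "b", "entity_type", "identifier")]
  }
  expect_equal(canon(named_links(net_a)), canon(named_links(net_b)))

  score_tbl <- function(net) {
    res <- prioritize(net, toy$truth$seed_entity, total_jump = 0.4)
    dplyr::arrange(res$entity_scores, .data$entity_type, .data$identifier)
  }
  expect_equal(score_tbl(net_a), score_tbl(net_b), tolerance = 1e-10)
})

test_that("diagnostics report layer counts, pair counts and isolated nodes", {
  net7 <- build_multinet(seven_layer_fixture())
  rep7 <- validate_network(net7)
  expect_equal(nrow(rep7$layers), 7)
  expect_equal(nrow(rep7$layer_pairs), 21)
  expect_true(all(rep7$layer_pairs$n_cross_links >= 1))  # APP everywhere

  empty <- as_subnetwork(
    tibble::tibble(source_id = character(), source_type = character(),
                   target_id = character(), target_type = character()),
    name = "empty"
  )
  rep0 <- validate_network(build_multinet(list(empty)))
  expect_equal(rep0$layers$n_nodes, 0)
  expect_equal(rep0$layers$n_edges, 0)
  expect_equal(nrow(rep0$layer_pairs), 0)
  expect_equal(nrow(rep0$isolated), 0)

  # a node with no within-layer edge and no cross link is isolated;
  # an edgeless replica of a shared entity is not
  l1 <- as_subnetwork(edges_tbl("gene", "A", "gene", "B"), name = "x")
  l2 <- as_subnetwork(edges_tbl("gene", "B", "gene", "C"), name = "y")
  rep2 <- validate_network(build_multinet(list(l1, l2)))
  expect_equal(nrow(rep2$isolated), 0)
  expect_equal(sum(rep2$layer_pairs$n_cross_links), 1)
})

test_that("every generated toy network is structurally clean", {
  for (seed in c(1, 9)) {
    toy <- generate_toy_network(toy_network_params(rng_seed = seed))
    rep <- validate_network(toy$network)
    expect_equal(nrow(rep$isolated), 0)
    expect_equal(nrow(rep$layers), 3)
    # node sets are edge-derived, so no within-layer-edgeless strays
    expect_true(all(rep$layers$n_edges > 0))
  }
})
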