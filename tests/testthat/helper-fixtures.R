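# Shared fixtures and independent oracles, built in code at test time.

# Quick edge tibble from parallel vectors.
edges_tbl <- function(st, si, tt, ti, w = NULL) {
  out <- tibble::tibble(source_type = st, source_id = si,
                        target_type = tt, target_id = ti)
  if (!is.null(w)) out$weight <- w
  out
}

# Single-layer gene cycle g1 - g2 - ... - gn - g1.
cycle_layer <- function(n, name = "cyc", prefix = "g") {
  ids <- paste0(prefix, seq_len(n))
  as_subnetwork(
    edges_tbl("gene", ids, "gene", ids[c(2:n, 1)]),
    name = name, weighted = FALSE, directed = FALSE
  )
}

# Single-layer star: center connected to n_leaves leaves.
star_layer <- function(n_leaves, name = "star") {
  as_subnetwork(
    edges_tbl("gene", rep("CENTER", n_leaves),
              "gene", sprintf("LEAF%02d", seq_len(n_leaves))),
    name = name, weighted = FALSE, directed = FALSE
  )
}

# Seven tiny layers sharing gene APP, one per canonical knowledge source.
seven_layer_fixture <- function() {
  nms <- c("omimDGN", "clinvarDGN", "gwasDGN", "PathGN", "PPIN",
           "PhenGN", "ChemicalGN")
  types <- c("disease", "disease", "disease", "pathway", "gene",
             "phenotype", "chemical")
  lapply(seq_along(nms), function(i) {
    other <- if (types[i] == "gene") {
      edges_tbl("gene", "APP", "gene", sprintf("G_%d", i))
    } else {
      edges_tbl(types[i], sprintf("ctx%d", i), "gene",
                c("APP", sprintf("G_%d", i)))
    }
    as_subnetwork(other, name = nms[i], weighted = FALSE, directed = FALSE)
  })
}

# Independent dense one-pass construction of the block transition matrix:
# plain base-R loops over the normalization and jump-weighting rules,
# sharing no code with assemble_transition().
dense_transition_oracle <- function(net, lambda) {
  sizes <- vapply(net$layers, function(l) nrow(l$nodes), integer(1))
  offsets <- cumsum(c(0, sizes))
  N <- sum(sizes)
  K <- length(sizes)
  M <- matrix(0, N, N)
  for (i in seq_len(K)) {
    rows_i <- offsets[i] + seq_len(sizes[i])
    Ai <- as.matrix(net$adjacency[[i]])
    B <- lapply(seq_len(K), function(j) {
      if (j == i) NULL else as.matrix(bipartite_block(net, i, j))
    })
    for (k in seq_len(sizes[i])) {
      ind <- vapply(seq_len(K), function(j) {
        if (j == i) 0 else as.numeric(any(B[[j]][k, ] > 0))
      }, numeric(1))
      stay <- 1 - sum(ind * lambda[i, ])
      rs <- sum(Ai[k, ])
      if (rs > 0) M[rows_i[k], rows_i] <- stay * Ai[k, ] / rs
      for (j in seq_len(K)) {
        if (j == i) next
        rs_b <- sum(B[[j]][k, ])
        if (rs_b > 0) {
          cols_j <- offsets[j] + seq_len(sizes[j])
          M[rows_i[k], cols_j] <- lambda[i, j] * B[[j]][k, ] / rs_b
        }
      }
    }
  }
  M
}

# Random jump matrix respecting the spec of jump_spec(): zero diagonal,
# entries in [0, 1), rows summing to at most max_total.
random_lambda <- function(K, max_total = 0.9) {
  L <- matrix(runif(K * K), K, K)
  diag(L) <- 0
  rs <- rowSums(L)
  scale <- runif(K, 0.1, max_total)
  for (i in seq_len(K)) if (rs[i] > 0) L[i, ] <- L[i, ] * scale[i] / rs[i]
  L
}

# Random small multi-layer network for oracle-equivalence sweeps.
random_multinet <- function(rng_seed) {
  withr::with_seed(rng_seed, {
    params <- toy_network_params(
      n_layers = sample(2:5, 1),
      genes_per_layer = sample(8:20, 1),
      other_nodes_per_layer = sample(3:8, 1),
      within_edge_prob = runif(1, 0.05, 0.3),
      shared_gene_fraction = runif(1, 0.3, 1),
      planted_partner_degree = 0,
      noise_edges = sample(0:10, 1),
      rng_seed = rng_seed + 1
    )
  })
  generate_toy_network(params)$network
}
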