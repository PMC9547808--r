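#' Assemble a multi-layer heterogeneous network from sub-networks
#'
#' Couples an ordered list of typed knowledge layers (disease-gene,
#' pathway-gene, phenotype-gene, protein-protein, ...) through their shared
#' entities: every entity present in two layers produces one cross-layer
#' link between its two replicas (multiplex representation — a shared entity
#' exists as a distinct node in each layer). Cross links have weight 1.
#'
#' The global node index is assigned layer-by-layer in input order and,
#' within a layer, by sorted entity key, so the layout is deterministic.
#' Entity-level results are invariant to layer input order.
#'
#' @param layers A list of [as_subnetwork()] objects with distinct names.
#' @param respect_direction Passed to [layer_adjacency()]; by default
#'   directed layers are symmetrized for walk purposes.
#' @return An object of class `multinet`: layers, a global node `index`
#'   tibble (`node_id`, `layer`, `layer_name`, `entity_type`, `identifier`),
#'   a `cross_links` tibble, per-layer sparse adjacencies `adjacency`, and
#'   bipartite coupling blocks `cross_blocks` (stored for layer pairs
#'   `i < j`; the reverse block is the transpose).
#' @examples
#' l1 <- as_subnetwork(tibble::tibble(
#'   source_id = "d1", source_type = "disease",
#'   target_id = c("APP", "PSEN1"), target_type = "gene"
#' ), name = "dg")
#' l2 <- as_subnetwork(tibble::tibble(
#'   source_id = "p1", source_type = "pathway",
#'   target_id = c("APP", "MAPT"), target_type = "gene"
#' ), name = "pg")
#' net <- build_multinet(list(l1, l2))
#' net$cross_links
#' @export
build_multinet <- function(layers, respect_direction = FALSE) {
  if (length(layers) < 1) abort("Need at least one layer")
  if (inherits(layers, "subnetwork")) layers <- list(layers)
  ok <- vapply(layers, inherits, logical(1), what = "subnetwork")
  if (!all(ok)) abort("All layers must be subnetwork objects")
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) {
    abort(sprintf("Duplicate layer name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  K <- length(layers)

  index <- purrr::imap_dfr(layers, function(l, i) {
    tibble::tibble(
      layer = i, layer_name = l$name,
      entity_type = l$nodes$entity_type, identifier = l$nodes$identifier
    )
  })
  index$key <- entity_key(index$entity_type, index$identifier)
  index$node_id <- seq_len(nrow(index))

  adjacency <- lapply(layers, layer_adjacency,
                      respect_direction = respect_direction)

  keys_by_layer <- split(index$key, index$layer)
  cross_links <- list()
  cross_blocks <- list()
  if (K >= 2) {
    for (i in seq_len(K - 1)) {
      for (j in seq(i + 1, K)) {
        shared <- intersect(keys_by_layer[[i]], keys_by_layer[[j]])
        ni <- length(keys_by_layer[[i]])
        nj <- length(keys_by_layer[[j]])
        if (length(shared) > 0) {
          ri <- match(shared, keys_by_layer[[i]])
          rj <- match(shared, keys_by_layer[[j]])
          B <- sparseMatrix(i = ri, j = rj, x = rep(1, length(shared)),
                            dims = c(ni, nj))
          ent <- layers[[i]]$nodes[ri, ]
          cross_links[[length(cross_links) + 1]] <- tibble::tibble(
            layer_a = i, layer_b = j,
            entity_type = ent$entity_type, identifier = ent$identifier,
            weight = 1
          )
        } else {
          B <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(ni, nj))
        }
        cross_blocks[[block_key(i, j)]] <- B
      }
    }
  }
  cross_links <- if (length(cross_links) > 0) {
    dplyr::bind_rows(cross_links)
  } else {
    tibble::tibble(layer_a = integer(), layer_b = integer(),
                   entity_type = character(), identifier = character(),
                   weight = numeric())
  }

  structure(
    list(layers = layers, index = index, cross_links = cross_links,
         adjacency = adjacency, cross_blocks = cross_blocks,
         K = K, N = nrow(index),
         respect_direction = respect_direction),
    class = "multinet"
  )
}

block_key <- function(i, j) paste(i, j, sep = ":")

#' Bipartite coupling block between two layers
#'
#' The sparse `n_i x n_j` matrix with a nonzero at `(k, l)` iff a cross link
#' joins node `k` of layer `i` to node `l` of layer `j`. By construction it
#' equals the transpose of the block for the reversed pair.
#'
#' @param net A `multinet`.
#' @param i,j Layer indices, `i != j`.
#' @return A sparse matrix.
#' @export
bipartite_block <- function(net, i, j) {
  stopifnot(inherits(net, "multinet"))
  if (i == j) abort("Bipartite blocks are defined for distinct layers")
  if (i < j) net$cross_blocks[[block_key(i, j)]]
  else Matrix::t(net$cross_blocks[[block_key(j, i)]])
}

layer_sizes <- function(net) {
  vapply(net$layers, function(l) nrow(l$nodes), integer(1))
}

#' Structural diagnostics for a multi-layer network
#'
#' Read-only report: per-layer node counts by entity type and edge counts,
#' cross-link counts for every unordered layer pair, and the nodes that are
#' isolated (no within-layer edge and no cross link).
#'
#' @param net A `multinet`.
#' @return A list of class `multinet_report` with tibbles `layers`,
#'   `node_types`, `layer_pairs`, and `isolated`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "multinet"))
  layers_tbl <- purrr::imap_dfr(net$layers, function(l, i) {
    tibble::tibble(layer = i, layer_name = l$name,
                   n_nodes = nrow(l$nodes), n_edges = nrow(l$edges),
                   weighted = l$weighted, directed = l$directed)
  })
  node_types <- purrr::imap_dfr(net$layers, function(l, i) {
    if (nrow(l$nodes) == 0) {
      return(tibble::tibble(layer = integer(), layer_name = character(),
                            entity_type = character(), n_nodes = integer()))
    }
    l$nodes |>
      dplyr::count(.data$entity_type, name = "n_nodes") |>
      dplyr::mutate(layer = i, layer_name = l$name, .before = 1)
  })
  K <- net$K
  pairs <- if (K >= 2) {
    expand.grid(layer_a = seq_len(K), layer_b = seq_len(K)) |>
      dplyr::filter(.data$layer_a < .data$layer_b) |>
      tibble::as_tibble() |>
      dplyr::arrange(.data$layer_a, .data$layer_b)
  } else {
    tibble::tibble(layer_a = integer(), layer_b = integer())
  }
  if (nrow(pairs) > 0) {
    pairs$n_cross_links <- mapply(function(a, b) {
      length(bipartite_block(net, a, b)@x)
    }, pairs$layer_a, pairs$layer_b)
  } else {
    pairs$n_cross_links <- integer()
  }

  within_deg <- unlist(lapply(net$adjacency, function(A) {
    as.numeric(rowSums(A) + colSums(A))
  }), use.names = FALSE)
  cross_deg <- numeric(net$N)
  if (K >= 2) {
    offsets <- cumsum(c(0, layer_sizes(net)))
    for (i in seq_len(K)) {
      deg_i <- numeric(layer_sizes(net)[i])
      for (j in seq_len(K)) {
        if (j == i) next
        deg_i <- deg_i + as.numeric(rowSums(bipartite_block(net, i, j)))
      }
      cross_deg[offsets[i] + seq_along(deg_i)] <- deg_i
    }
  }
  isolated <- net$index[within_deg == 0 & cross_deg == 0,
                        c("node_id", "layer", "layer_name",
                          "entity_type", "identifier")]

  structure(
    list(layers = layers_tbl, node_types = node_types,
         layer_pairs = pairs, isolated = tibble::as_tibble(isolated)),
    class = "multinet_report"
  )
}

#' @export
print.multinet <- function(x, ...) {
  cat(sprintf("<multinet> %d layers, %d global nodes, %d cross links\n",
              x$K, x$N, nrow(x$cross_links)))
  for (i in seq_len(x$K)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] %s: %d nodes, %d edges\n",
                i, l$name, nrow(l$nodes), nrow(l$edges)))
  }
  invisible(x)
}

#' @export
print.multinet_report <- function(x, ...) {
  cat("<multinet diagnostics>\n")
  cat(sprintf("  layers: %d | cross-link pairs with >0 links: %d | isolated nodes: %d\n",
              nrow(x$layers), sum(x$layer_pairs$n_cross_links > 0),
              nrow(x$isolated)))
  print(x$layers)
  invisible(x)
}

#' @rdname tidy-rwrnet
#' @export
tidy.multinet <- function(x, ...) {
  x$index[, c("node_id", "layer", "layer_name", "entity_type", "identifier")]
}

#' @rdname glance-rwrnet
#' @export
glance.multinet <- function(x, ...) {
  tibble::tibble(
    n_layers = x$K, n_nodes = x$N,
    n_edges = sum(vapply(x$layers, function(l) nrow(l$edges), integer(1))),
    n_cross_links = nrow(x$cross_links),
    n_entities = dplyr::n_distinct(x$index$key)
  )
}
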