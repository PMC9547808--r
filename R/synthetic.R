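#' Parameters for the synthetic multi-layer network generator
#'
#' Defines a toy multi-layer network with known structure: `n_layers` typed
#' layers (layer 1 disease-gene, layer 2 pathway-gene, layer 3
#' phenotype-gene, further layers gene-gene), sparse random within-layer
#' edges, a pool of gene symbols reused across layers (the only source of
#' cross-layer coupling), and a planted "partner" gene directly connected
#' to the seed gene in `planted_partner_degree` distinct layers.
#'
#' Defaults mirror a small, desk-scale screen: 3 layers of 50 genes plus 20
#' typed context nodes each, edge probability 0.05 (mean within-layer
#' degree about 1), all gene symbols shared across layers (so genes are
#' exchangeable under the no-signal null), and 20 noise edges.
#'
#' @param n_layers Number of layers, at least 2.
#' @param genes_per_layer Genes per layer.
#' @param other_nodes_per_layer Typed context nodes (diseases, pathways,
#'   phenotypes) per bipartite layer.
#' @param within_edge_prob Within-layer edge probability in `(0, 1)`.
#' @param shared_gene_fraction Fraction of each layer's gene symbols drawn
#'   from the shared pool, in `(0, 1]`.
#' @param planted_partner_degree Number of layers in which the planted
#'   partner is directly connected to the seed (0 = no signal). Requires a
#'   shared pool of at least 2 genes when above 1.
#' @param noise_edges Extra random within-layer edges.
#' @param rng_seed Integer seed; the generated network is fully determined
#'   by the parameters and this seed.
#' @return A validated list of class `toy_network_params`.
#' @export
toy_network_params <- function(n_layers = 3, genes_per_layer = 50,
                               other_nodes_per_layer = 20,
                               within_edge_prob = 0.05,
                               shared_gene_fraction = 1,
                               planted_partner_degree = n_layers,
                               noise_edges = 20, rng_seed = 1) {
  p <- list(
    n_layers = as.integer(n_layers),
    genes_per_layer = as.integer(genes_per_layer),
    other_nodes_per_layer = as.integer(other_nodes_per_layer),
    within_edge_prob = within_edge_prob,
    shared_gene_fraction = shared_gene_fraction,
    planted_partner_degree = as.integer(planted_partner_degree),
    noise_edges = as.integer(noise_edges),
    rng_seed = as.integer(rng_seed)
  )
  if (p$n_layers < 2) abort("n_layers must be >= 2")
  if (p$genes_per_layer < 2) abort("genes_per_layer must be >= 2")
  if (p$other_nodes_per_layer < 1) abort("other_nodes_per_layer must be >= 1")
  if (!is.numeric(p$within_edge_prob) || p$within_edge_prob <= 0 ||
      p$within_edge_prob >= 1) {
    abort("within_edge_prob must be in (0, 1)")
  }
  if (!is.numeric(p$shared_gene_fraction) || p$shared_gene_fraction <= 0 ||
      p$shared_gene_fraction > 1) {
    abort("shared_gene_fraction must be in (0, 1]")
  }
  if (p$planted_partner_degree < 0 || p$planted_partner_degree > p$n_layers) {
    abort("planted_partner_degree must be between 0 and n_layers")
  }
  if (p$noise_edges < 0) abort("noise_edges must be >= 0")
  n_shared <- n_shared_genes(p)
  if (n_shared < 2 && p$planted_partner_degree > 1) {
    abort(paste0("planted_partner_degree > 1 needs a shared gene pool of ",
                 "at least 2 (raise shared_gene_fraction)"))
  }
  structure(p, class = "toy_network_params")
}

n_shared_genes <- function(p) {
  as.integer(round(p$shared_gene_fraction * p$genes_per_layer))
}

toy_layer_schedule <- function(n_layers) {
  base <- c("disease", "pathway", "phenotype")
  c(base[seq_len(min(3, n_layers))],
    rep("gene", max(0, n_layers - 3)))
}

#' Generate a toy multi-layer network with a planted partner
#'
#' Builds the network described by [toy_network_params()]: Erdős–Rényi
#' within-layer edges (bipartite gene-context for the first three layers,
#' gene-gene beyond), cross-layer coupling only through shared gene
#' symbols, a seed gene and a planted partner gene directly connected in
#' `planted_partner_degree` layers, plus random noise edges. The same
#' parameters and seed always give an identical network.
#'
#' @param params A [toy_network_params()] object.
#' @return A list with `network` (a [build_multinet()] object) and `truth`
#'   (class `synthetic_truth`: `seed_entity`, `planted_partner`, `params`).
#' @examples
#' toy <- generate_toy_network(toy_network_params(rng_seed = 42))
#' toy$truth$seed_entity
#' @export
generate_toy_network <- function(params) {
  if (!inherits(params, "toy_network_params")) {
    params <- do.call(toy_network_params, as.list(params))
  }
  p <- params
  n_shared <- n_shared_genes(p)
  shared_genes <- sprintf("G%04d", seq_len(n_shared))
  schedule <- toy_layer_schedule(p$n_layers)
  other_prefix <- c(disease = "D", pathway = "PW", phenotype = "PH")

  if (n_shared >= 2) {
    seed_gene <- shared_genes[1]
    partner_gene <- shared_genes[2]
  } else {
    seed_gene <- sprintf("G%04d_L1", n_shared + 1)
    partner_gene <- sprintf("G%04d_L1", n_shared + 2)
  }

  layers <- withr::with_seed(p$rng_seed, {
    lapply(seq_len(p$n_layers), function(l) {
      type_l <- schedule[l]
      n_specific <- p$genes_per_layer - n_shared
      genes <- c(shared_genes,
                 if (n_specific > 0)
                   sprintf("G%04d_L%d", n_shared + seq_len(n_specific), l))
      if (type_l == "gene") {
        nodes <- tibble::tibble(id = genes, type = "gene")
        edges <- er_pairs(genes, genes, p$within_edge_prob, square = TRUE) |>
          dplyr::mutate(source_type = "gene", target_type = "gene")
      } else {
        others <- sprintf("%s%03d_L%d", other_prefix[[type_l]],
                          seq_len(p$other_nodes_per_layer), l)
        nodes <- tibble::tibble(id = c(genes, others),
                                type = rep(c("gene", type_l),
                                           c(length(genes), length(others))))
        edges <- er_pairs(genes, others, p$within_edge_prob,
                          square = FALSE) |>
          dplyr::mutate(source_type = "gene", target_type = type_l)
      }
      if (l <= p$planted_partner_degree) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          source_id = seed_gene, target_id = partner_gene,
          source_type = "gene", target_type = "gene"
        ))
      }
      if (p$noise_edges > 0) {
        pick <- replicate(p$noise_edges, sample.int(nrow(nodes), 2))
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          source_id = nodes$id[pick[1, ]], target_id = nodes$id[pick[2, ]],
          source_type = nodes$type[pick[1, ]],
          target_type = nodes$type[pick[2, ]]
        ))
      }
      # drop self-loops and unordered duplicates quietly: the generator
      # promises a clean layer, warnings are for user-supplied data
      ka <- entity_key(edges$source_type, edges$source_id)
      kb <- entity_key(edges$target_type, edges$target_id)
      keep <- ka != kb
      edges <- edges[keep, , drop = FALSE]
      und <- paste(pmin(ka[keep], kb[keep]), pmax(ka[keep], kb[keep]))
      edges <- edges[!duplicated(und), , drop = FALSE]
      # the full gene roster belongs to the layer even when a gene drew no
      # edge; context nodes exist only through their annotations
      as_subnetwork(edges, name = sprintf("L%d_%s", l, type_l),
                    weighted = FALSE, directed = FALSE,
                    nodes = tibble::tibble(entity_type = "gene",
                                           identifier = genes))
    })
  })

  network <- build_multinet(layers)
  truth <- structure(
    list(seed_entity = entity("gene", seed_gene),
         planted_partner = entity("gene", partner_gene),
         params = p),
    class = "synthetic_truth"
  )
  list(network = network, truth = truth)
}

# Bernoulli edge sampling over a node grid; square=TRUE samples unordered
# distinct pairs only.
er_pairs <- function(from, to, prob, square = FALSE) {
  if (square) {
    idx <- which(upper.tri(matrix(0, length(from), length(to))),
                 arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_along(from),
                                 col = seq_along(to)))
  }
  keep <- runif(nrow(idx)) < prob
  tibble::tibble(source_id = from[idx[keep, 1]],
                 target_id = to[idx[keep, 2]])
}

#' Planted-partner recovery experiment
#'
#' Runs the full pipeline (generate network, assemble transition matrix,
#' propagate from the synthetic seed, rank genes) over `n_replicates`
#' independently generated networks (replicate `r` uses
#' `rng_seed = base_rng_seed + r - 1`) and records the planted partner's
#' rank and percentile among genes. The report gives the fraction of
#' replicates where the partner ranked first, and the median rank and
#' percentile. Non-convergent replicates are recorded and kept.
#'
#' @param params A [toy_network_params()] object (its
#'   `planted_partner_degree` sets the signal strength; 0 is the null).
#' @param n_replicates Number of replicates, at least 1.
#' @param base_rng_seed First replicate's seed (default `params$rng_seed`).
#' @param alpha,total_jump,tol,max_iter Pipeline settings as in
#'   [prioritize()].
#' @return A list of class `recovery_report` with `replicates` (tibble)
#'   and `summary` (one-row tibble).
#' @export
planted_recovery <- function(params, n_replicates = 100,
                             base_rng_seed = params$rng_seed,
                             alpha = 0.7, total_jump = 0.5,
                             tol = 1e-9, max_iter = 1000) {
  if (!inherits(params, "toy_network_params")) {
    params <- do.call(toy_network_params, as.list(params))
  }
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    p_r <- params
    p_r$rng_seed <- as.integer(base_rng_seed + r - 1)
    toy <- generate_toy_network(p_r)
    tm <- assemble_transition(toy$network, total_jump = total_jump)
    s0 <- seed_vector(toy$network, toy$truth$seed_entity)
    s <- withCallingHandlers(
      propagate(tm, s0, alpha = alpha, tol = tol, max_iter = max_iter),
      warning = function(w) invokeRestart("muffleWarning")
    )
    genes <- rank_by_type(aggregate_entity_scores(s), "gene",
                          seeds = toy$truth$seed_entity,
                          exclude_seeds = TRUE)
    hit <- which(genes$identifier == toy$truth$planted_partner$identifier)
    rows[[r]] <- tibble::tibble(
      replicate = r, rng_seed = p_r$rng_seed,
      converged = isTRUE(s$converged), iterations = s$iteration,
      partner_rank = if (length(hit) == 1) genes$rank[hit] else NA_integer_,
      partner_percentile = if (length(hit) == 1) genes$percentile[hit]
                           else NA_real_,
      n_candidates = attr(genes, "n_candidates")
    )
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    n_replicates = n_replicates,
    n_converged = sum(replicates$converged),
    fraction_rank1 = mean(replicates$partner_rank == 1, na.rm = TRUE),
    median_rank = median(replicates$partner_rank, na.rm = TRUE),
    median_percentile = median(replicates$partner_percentile, na.rm = TRUE),
    planted_partner_degree = params$planted_partner_degree
  )
  structure(list(replicates = replicates, summary = summary,
                 params = params),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<recovery_report> %d replicates (degree %d): rank-1 fraction ",
           "%.2f, median rank %.1f, median percentile %.1f%%\n"),
    s$n_replicates, s$planted_partner_degree, s$fraction_rank1,
    s$median_rank, s$median_percentile
  ))
  invisible(x)
}

#' @rdname tidy-rwrnet
#' @export
tidy.recovery_report <- function(x, ...) {
  x$replicates
}

#' @rdname glance-rwrnet
#' @export
glance.recovery_report <- function(x, ...) {
  x$summary
}

#' Write a generated toy network to edge-list files plus a truth JSON
#'
#' One TSV per layer ([write_edge_list()]) and a `truth.json` naming the
#' seed, the planted partner, and the generator parameters.
#'
#' @param toy Result of [generate_toy_network()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_toy_network <- function(toy, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(toy$network$layers, function(l) {
    path <- file.path(dir, paste0(l$name, ".tsv"))
    write_edge_list(l, path)
    path
  }, character(1))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(
      seed_entity = as.list(toy$truth$seed_entity),
      planted_partner = as.list(toy$truth$planted_partner),
      params = unclass(toy$truth$params)
    ),
    truth_path, auto_unbox = TRUE
  )
  invisible(c(paths, truth_path))
}
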