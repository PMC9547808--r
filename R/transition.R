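#' Row-normalize a nonnegative sparse matrix
#'
#' Each row with positive sum is divided by its sum; an all-zero row stays
#' all-zero (no dangling-node redistribution). This is the normalization
#' applied to every adjacency and coupling block before the jump weights.
#'
#' @param A A nonnegative matrix (sparse or dense).
#' @return A sparse matrix whose rows each sum to 1 or 0.
#' @examples
#' row_normalize(matrix(c(1, 3, 0, 0), 2, byrow = TRUE))
#' @export
row_normalize <- function(A) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  if (length(A@x) > 0 && min(A@x) < 0) {
    abort("row_normalize() requires a nonnegative matrix")
  }
  rs <- rowSums(A)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  Diagonal(x = inv) %*% A
}

#' Jumping-probability matrix for a multi-layer network
#'
#' The walker's chance of crossing from layer `i` to layer `j` through a
#' shared node is `lambda[i, j]`. The matrix has a zero diagonal, entries in
#' `[0, 1)`, and row sums at most 1 so the stay probability stays
#' nonnegative even when a node has cross links into every other layer.
#'
#' By default a total jump mass (default 0.5) is split equally among the
#' layers that layer `i` actually shares at least one entity with; pairs
#' with no shared entity get 0. An explicit `K x K` matrix overrides the
#' default and may be asymmetric.
#'
#' @param net A `multinet`.
#' @param total_jump Total per-layer jump mass in `[0, 1)` used by the
#'   equal-split default.
#' @param lambda Optional explicit `K x K` numeric matrix.
#' @return A validated `K x K` matrix of class `jump_spec`.
#' @export
jump_spec <- function(net, total_jump = 0.5, lambda = NULL) {
  stopifnot(inherits(net, "multinet"))
  K <- net$K
  if (is.null(lambda)) {
    if (!is.numeric(total_jump) || total_jump < 0 || total_jump >= 1) {
      abort("total_jump must be in [0, 1)")
    }
    lambda <- matrix(0, K, K)
    if (K >= 2) {
      shares <- matrix(FALSE, K, K)
      for (i in seq_len(K - 1)) {
        for (j in seq(i + 1, K)) {
          has <- length(net$cross_blocks[[block_key(i, j)]]@x) > 0
          shares[i, j] <- has
          shares[j, i] <- has
        }
      }
      d <- rowSums(shares)
      for (i in seq_len(K)) {
        if (d[i] > 0) lambda[i, shares[i, ]] <- total_jump / d[i]
      }
    }
  }
  lambda <- as.matrix(lambda)
  validate_jump_spec(lambda, K)
  dimnames(lambda) <- list(layer_names(net), layer_names(net))
  structure(lambda, class = c("jump_spec", "matrix"))
}

layer_names <- function(net) {
  vapply(net$layers, function(l) l$name, character(1))
}

validate_jump_spec <- function(lambda, K) {
  if (!is.numeric(lambda) || nrow(lambda) != K || ncol(lambda) != K) {
    abort(sprintf("Jump matrix must be numeric %d x %d", K, K))
  }
  if (any(diag(lambda) != 0)) abort("Jump matrix must have a zero diagonal")
  if (any(lambda < 0) || any(lambda >= 1)) {
    abort("Jumping probabilities must lie in [0, 1)")
  }
  if (any(rowSums(lambda) > 1 + 1e-12)) {
    abort("Each row of the jump matrix must sum to at most 1")
  }
  invisible(lambda)
}

#' Off-diagonal transition block between two coupled layers
#'
#' The coupling block is row-normalized, then every row is weighed by the
#' layer-pair jumping probability. Rows with no cross link remain all-zero.
#'
#' @param A_ij Bipartite coupling matrix (nonnegative, `n_i x n_j`).
#' @param lambda_ij Jumping probability in `[0, 1)`.
#' @return Sparse matrix: `lambda_ij * row_normalize(A_ij)`.
#' @export
offdiagonal_block <- function(A_ij, lambda_ij) {
  if (!is.numeric(lambda_ij) || length(lambda_ij) != 1 ||
      lambda_ij < 0 || lambda_ij >= 1) {
    abort("lambda_ij must be a single number in [0, 1)")
  }
  drop0(lambda_ij * row_normalize(A_ij))
}

#' Diagonal (within-layer) transition block
#'
#' The within-layer adjacency is row-normalized, then row `k` is weighed by
#' its stay probability `1 - sum_j I[k, j] * lambda_i[j]`, where the
#' indicator `I[k, j]` is 1 iff node `k` has at least one cross link into
#' layer `j`. A node with zero within-layer degree keeps an all-zero row
#' (its outgoing mass, if any, lives entirely in the coupling blocks).
#'
#' @param A_i Within-layer adjacency (nonnegative, square).
#' @param lambda_i Numeric vector: row `i` of the jump matrix.
#' @param indicators Logical/0-1 matrix, nodes x layers: `indicators[k, j]`
#'   is 1 iff node `k` has a cross link into layer `j`.
#' @return Sparse matrix of within-layer transition probabilities.
#' @export
diagonal_block <- function(A_i, lambda_i, indicators) {
  indicators <- as.matrix(indicators) * 1
  if (nrow(indicators) != nrow(A_i) || ncol(indicators) != length(lambda_i)) {
    abort("indicators must be (nodes x layers) matching lambda_i")
  }
  stay <- 1 - as.numeric(indicators %*% lambda_i)
  if (any(stay < -1e-9)) {
    abort("Stay probability is negative; jump matrix rows must sum to <= 1")
  }
  stay[stay < 0] <- 0
  drop0(Diagonal(x = stay) %*% row_normalize(A_i))
}

#' Assemble the global block transition matrix
#'
#' Lays out the `K x K` block matrix of the walk: diagonal blocks are
#' within-layer transitions damped by the stay probability
#' ([diagonal_block()]); off-diagonal blocks are the row-normalized
#' couplings scaled by the jumping probabilities ([offdiagonal_block()]).
#' For a node with at least one within-layer edge, the row sums to exactly
#' 1; rows can be substochastic only through the all-zero-row convention
#' for within-layer-isolated nodes.
#'
#' @param net A `multinet`.
#' @param jumps A [jump_spec()] matrix, or `NULL` to use the default
#'   equal-split with `total_jump`.
#' @param total_jump Passed to [jump_spec()] when `jumps` is `NULL`.
#' @return An object of class `transition_matrix`: sparse `M` (N x N), the
#'   jump matrix `lambda`, a `layout` tibble of block spans, per-row sums
#'   `row_sums`, and the node `index`.
#' @examples
#' l1 <- as_subnetwork(tibble::tibble(
#'   source_id = "d1", source_type = "disease",
#'   target_id = c("A", "B"), target_type = "gene"
#' ), name = "dg")
#' tm <- assemble_transition(build_multinet(list(l1)))
#' Matrix::rowSums(tm$M)
#' @export
assemble_transition <- function(net, jumps = NULL, total_jump = 0.5) {
  stopifnot(inherits(net, "multinet"))
  K <- net$K
  if (is.null(jumps)) {
    jumps <- jump_spec(net, total_jump = total_jump)
  } else {
    validate_jump_spec(unclass(as.matrix(jumps)), K)
  }
  lambda <- unclass(as.matrix(jumps))
  sizes <- layer_sizes(net)
  offsets <- cumsum(c(0, sizes))

  block_rows <- vector("list", K)
  layout <- vector("list", K * K)
  for (i in seq_len(K)) {
    indicators <- matrix(0, nrow = sizes[i], ncol = K)
    if (K >= 2) {
      for (j in seq_len(K)) {
        if (j == i) next
        indicators[, j] <- as.numeric(rowSums(bipartite_block(net, i, j)) > 0)
      }
    }
    row_blocks <- vector("list", K)
    for (j in seq_len(K)) {
      B <- if (i == j) {
        diagonal_block(net$adjacency[[i]], lambda[i, ], indicators)
      } else {
        offdiagonal_block(bipartite_block(net, i, j), lambda[i, j])
      }
      row_blocks[[j]] <- B
      layout[[(i - 1) * K + j]] <- tibble::tibble(
        layer_row = i, layer_col = j,
        row_start = offsets[i] + 1L, row_end = offsets[i + 1],
        col_start = offsets[j] + 1L, col_end = offsets[j + 1],
        nnz = length(as(as(B, "CsparseMatrix"), "generalMatrix")@x)
      )
    }
    block_rows[[i]] <- do.call(cbind, row_blocks)
  }
  M <- as(as(do.call(rbind, block_rows), "CsparseMatrix"), "generalMatrix")

  structure(
    list(M = M, lambda = lambda, layout = dplyr::bind_rows(layout),
         row_sums = as.numeric(rowSums(M)), index = net$index,
         alpha_independent = TRUE),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  K <- nrow(x$lambda)
  cat(sprintf("<transition_matrix> %d x %d, %d blocks (%d layers), %d nonzeros\n",
              nrow(x$M), ncol(x$M), nrow(x$layout), K, length(x$M@x)))
  sub <- sum(x$row_sums < 1 - 1e-9)
  cat(sprintf("  rows summing to 1: %d | substochastic rows: %d\n",
              sum(abs(x$row_sums - 1) <= 1e-9), sub))
  invisible(x)
}

#' Tidy a transition matrix into its block layout
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return The block-layout tibble (one row per layer pair, with spans and
#'   nonzero counts).
#' @rdname tidy-rwrnet
#' @export
tidy.transition_matrix <- function(x, ...) {
  x$layout
}

#' @rdname glance-rwrnet
#' @export
glance.transition_matrix <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$M),
    n_blocks = nrow(x$layout),
    n_layers = nrow(x$lambda),
    nnz = length(x$M@x),
    n_stochastic_rows = sum(abs(x$row_sums - 1) <= 1e-9),
    n_substochastic_rows = sum(x$row_sums < 1 - 1e-9),
    max_row_sum = max(x$row_sums)
  )
}

#' Per-row mass-deficit report
#'
#' One row per global node whose outgoing mass is below 1 — i.e. the mass
#' lost to the all-zero-row convention for within-layer-isolated nodes.
#' Useful for auditing how much walk mass a sparse layer leaks.
#'
#' @param tm A `transition_matrix`.
#' @param file Optional path; when given, the report is written as TSV.
#' @return A tibble with `node_id`, layer/entity columns, `row_sum` and
#'   `deficit`.
#' @export
row_sum_report <- function(tm, file = NULL) {
  stopifnot(inherits(tm, "transition_matrix"))
  out <- tm$index[, c("node_id", "layer", "layer_name",
                      "entity_type", "identifier")]
  out$row_sum <- tm$row_sums
  out$deficit <- pmax(0, 1 - tm$row_sums)
  out <- out[out$deficit > 1e-12, , drop = FALSE]
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tibble::as_tibble(out)
}
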