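#' Initial score vector from seed entities
#'
#' Total mass 1 is split equally among the seed entities, and each entity's
#' share is split equally among its layer replicas. Every other entry is 0.
#'
#' @param net A `multinet`.
#' @param seeds Seed entities as `"type:id"` strings or a data frame with
#'   `entity_type` and `identifier`.
#' @return A `score_vector` (scores, iteration 0) aligned to the global
#'   node index.
#' @examples
#' l1 <- as_subnetwork(tibble::tibble(
#'   source_id = "d1", source_type = "disease",
#'   target_id = c("APP", "PSEN1"), target_type = "gene"
#' ), name = "dg")
#' s0 <- seed_vector(build_multinet(list(l1)), "gene:APP")
#' sum(s0$scores)
#' @export
seed_vector <- function(net, seeds) {
  stopifnot(inherits(net, "multinet"))
  seeds <- as_entity_tbl(seeds)
  seeds <- dplyr::distinct(seeds)
  if (nrow(seeds) == 0) abort("Need at least one seed entity")
  keys <- entity_key(seeds$entity_type, seeds$identifier)
  s <- numeric(net$N)
  for (k in seq_along(keys)) {
    hit <- which(net$index$key == keys[k])
    if (length(hit) == 0) {
      abort(sprintf("Seed entity '%s' is not present in any layer", keys[k]))
    }
    s[hit] <- s[hit] + 1 / (nrow(seeds) * length(hit))
  }
  new_score_vector(s, net$index, iteration = 0L, converged = NA,
                   residual = NA_real_, seeds = seeds)
}

new_score_vector <- function(scores, index, iteration, converged, residual,
                             seeds = NULL, trace = NULL) {
  structure(
    list(scores = as.numeric(scores), index = index,
         iteration = as.integer(iteration), converged = converged,
         residual = residual, seeds = seeds, trace = trace),
    class = "score_vector"
  )
}

score_values <- function(s) {
  if (inherits(s, "score_vector")) s$scores else as.numeric(s)
}

#' One step of the restart recursion
#'
#' Computes `alpha * t(M) %*% s + (1 - alpha) * s0` — a single update of the
#' random walk with restart, with no convergence logic.
#'
#' @param tm A `transition_matrix` (or a plain matrix `M`).
#' @param s Current score vector (numeric or `score_vector`).
#' @param s0 Restart vector (numeric or `score_vector`).
#' @param alpha Walk-continuation weight in `[0, 1)`; `1 - alpha` is the
#'   restart probability.
#' @return Numeric vector of updated scores.
#' @export
propagate_step <- function(tm, s, s0, alpha) {
  M <- if (inherits(tm, "transition_matrix")) tm$M else tm
  s <- score_values(s)
  s0 <- score_values(s0)
  check_alpha(alpha)
  if (length(s) != nrow(M) || length(s0) != nrow(M)) {
    abort("Score vector length does not match the transition matrix")
  }
  as.numeric(alpha * Matrix::crossprod(M, s)) + (1 - alpha) * s0
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    abort("alpha must be a single number in [0, 1)")
  }
}

#' Propagate seed scores to convergence
#'
#' Iterates [propagate_step()] from `s0` until the L1 change between
#' successive score vectors falls below `tol`, or `max_iter` is reached (in
#' which case a warning is raised and `converged` is `FALSE`). The
#' iteration is a contraction with rate at most `alpha`, so convergence is
#' geometric and deterministic.
#'
#' @inheritParams propagate_step
#' @param s0 A `score_vector` from [seed_vector()] (or a numeric vector).
#' @param tol L1 convergence threshold (default `1e-9`).
#' @param max_iter Iteration cap (default 1000).
#' @param keep_trace Record per-iteration residual and total mass.
#' @return A `score_vector` with `iteration`, `converged`, `residual`, and
#'   (optionally) a `trace` tibble.
#' @export
propagate <- function(tm, s0, alpha = 0.7, tol = 1e-9, max_iter = 1000,
                      keep_trace = FALSE) {
  check_alpha(alpha)
  if (!is.numeric(tol) || tol <= 0) abort("tol must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) abort("max_iter must be >= 1")
  M <- if (inherits(tm, "transition_matrix")) tm$M else tm
  index <- if (inherits(tm, "transition_matrix")) tm$index else NULL
  if (inherits(s0, "score_vector") && is.null(index)) index <- s0$index
  seeds <- if (inherits(s0, "score_vector")) s0$seeds else NULL
  v0 <- score_values(s0)
  Mt <- Matrix::t(M)

  s <- v0
  converged <- FALSE
  residual <- NA_real_
  trace <- if (keep_trace) vector("list", max_iter) else NULL
  k <- 0L
  for (k in seq_len(max_iter)) {
    s_next <- as.numeric(alpha * (Mt %*% s)) + (1 - alpha) * v0
    residual <- sum(abs(s_next - s))
    if (keep_trace) {
      trace[[k]] <- tibble::tibble(iteration = k, residual = residual,
                                   total_mass = sum(s_next))
    }
    s <- s_next
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "Propagation did not converge in %d iterations (last L1 change %.3g)",
      max_iter, residual
    ))
  }
  new_score_vector(
    s, index, iteration = k, converged = converged, residual = residual,
    seeds = seeds,
    trace = if (keep_trace) dplyr::bind_rows(trace[seq_len(k)]) else NULL
  )
}

#' Closed-form fixed point of the restart recursion
#'
#' Solves the linear system `(I - alpha * t(M)) s = (1 - alpha) * s0`
#' directly. This is the exact fixed point the iteration converges to; it
#' is intended as a test oracle and is guarded to small systems
#' (`N <= 5000`).
#'
#' @inheritParams propagate
#' @return A `score_vector` with `converged = TRUE`.
#' @export
closed_form_scores <- function(tm, s0, alpha = 0.7) {
  check_alpha(alpha)
  M <- if (inherits(tm, "transition_matrix")) tm$M else tm
  index <- if (inherits(tm, "transition_matrix")) tm$index else NULL
  if (inherits(s0, "score_vector") && is.null(index)) index <- s0$index
  n <- nrow(M)
  if (n > 5000) {
    abort("closed_form_scores() is a small-system oracle (N <= 5000)")
  }
  v0 <- score_values(s0)
  A <- Diagonal(n) - alpha * Matrix::t(M)
  s <- as.numeric(solve(A, (1 - alpha) * v0))
  new_score_vector(
    s, index, iteration = NA_integer_, converged = TRUE, residual = 0,
    seeds = if (inherits(s0, "score_vector")) s0$seeds else NULL
  )
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf(
    "<score_vector> %d nodes, total mass %.6f%s\n",
    length(x$scores), sum(x$scores),
    if (is.na(x$iteration)) " (closed form)"
    else sprintf(", %d iterations (converged: %s, residual %.3g)",
                 x$iteration, x$converged, x$residual)
  ))
  invisible(x)
}

#' Tidy methods for rwrnet result objects
#'
#' `tidy()` returns per-node / per-row observations; `glance()` returns a
#' one-row summary.
#'
#' @param x An rwrnet object.
#' @param ... Unused.
#' @name tidy-rwrnet
NULL

#' Glance methods for rwrnet result objects
#'
#' @param x An rwrnet object.
#' @param ... Unused.
#' @name glance-rwrnet
NULL

#' @rdname tidy-rwrnet
#' @export
tidy.score_vector <- function(x, ...) {
  if (is.null(x$index)) {
    return(tibble::tibble(node_id = seq_along(x$scores), score = x$scores))
  }
  out <- x$index[, c("node_id", "layer", "layer_name",
                     "entity_type", "identifier")]
  out$score <- x$scores
  tibble::as_tibble(out)
}

#' @rdname glance-rwrnet
#' @export
glance.score_vector <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$scores),
    total_mass = sum(x$scores),
    iterations = x$iteration,
    converged = x$converged,
    residual = x$residual
  )
}
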