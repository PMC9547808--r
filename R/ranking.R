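#' Collapse layer-replica scores to entity scores
#'
#' A shared entity exists as one replica per layer; ranking is over
#' entities. The default collapse sums replica scores (preserving total
#' probability mass); `collapse = "max"` is available for sensitivity
#' analysis. Entities appear even when every replica scored 0.
#'
#' @param scores A `score_vector` carrying a node index (from
#'   [propagate()] / [closed_form_scores()]), or a tidied per-node tibble.
#' @param collapse `"sum"` (default) or `"max"`.
#' @return A tibble with `entity_type`, `identifier`, `score`, sorted by
#'   descending score.
#' @export
aggregate_entity_scores <- function(scores, collapse = c("sum", "max")) {
  collapse <- match.arg(collapse)
  tbl <- if (inherits(scores, "score_vector")) tidy(scores) else
    tibble::as_tibble(scores)
  if (!all(c("entity_type", "identifier", "score") %in% names(tbl))) {
    abort("Scores must carry entity_type, identifier and score columns")
  }
  fun <- if (collapse == "sum") sum else max
  tbl |>
    dplyr::group_by(.data$entity_type, .data$identifier) |>
    dplyr::summarise(score = fun(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$identifier)
}

#' Ranked candidate table for one entity type
#'
#' Filters entity scores to one type, optionally removes the seed entities,
#' sorts by descending score, and assigns competition ranks (tied scores
#' share the minimal rank; ties are output in lexicographic identifier
#' order). The percentile rank is `100 * rank / n_candidates`, so the top
#' candidate of a large screen has a percentile close to 0 and the last
#' candidate exactly 100.
#'
#' @param entity_scores Tibble from [aggregate_entity_scores()].
#' @param type One of [entity_types()].
#' @param seeds Optional seed entities (strings or data frame) to flag.
#' @param exclude_seeds Drop seed entities of this type before ranking
#'   (default `TRUE`, the usual prioritization convention).
#' @return A tibble of class `ranked_table` with columns `entity_type`,
#'   `identifier`, `score`, `rank`, `percentile`, `is_seed`; attributes
#'   `entity_type` and `n_candidates`.
#' @export
rank_by_type <- function(entity_scores, type, seeds = NULL,
                         exclude_seeds = TRUE) {
  if (!type %in% entity_types()) {
    abort(sprintf("Unknown entity_type '%s' (valid: %s)", type,
                  paste(entity_types(), collapse = ", ")))
  }
  tbl <- tibble::as_tibble(entity_scores)
  tbl <- tbl[tbl$entity_type == type, , drop = FALSE]
  seed_keys <- character()
  if (!is.null(seeds)) {
    seeds <- as_entity_tbl(seeds)
    seed_keys <- entity_key(seeds$entity_type, seeds$identifier)
  }
  tbl$is_seed <- entity_key(tbl$entity_type, tbl$identifier) %in% seed_keys
  if (exclude_seeds) tbl <- tbl[!tbl$is_seed, , drop = FALSE]
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$score), .data$identifier)
  n <- nrow(tbl)
  if (n > 0) {
    tbl$rank <- as.integer(rank(-tbl$score, ties.method = "min"))
    tbl$percentile <- percentile_rank(tbl$rank, n)
  } else {
    tbl$rank <- integer()
    tbl$percentile <- numeric()
  }
  tbl <- tbl[, c("entity_type", "identifier", "score", "rank",
                 "percentile", "is_seed")]
  structure(tbl, entity_type = type, n_candidates = n,
            class = c("ranked_table", class(tbl)))
}

#' Percentile rank
#'
#' `100 * rank / n`: the fraction of the screen at or above this rank,
#' as a percentage in `(0, 100]`. Display formatting conventionally rounds
#' to 3 decimal places ([format_percentile()]), so the top hit of a screen
#' of 30,049 genes reads 0.003\%.
#'
#' @param rank Positive integer rank(s), competition convention.
#' @param n Number of candidates screened, `n >= rank`.
#' @return Numeric percentile(s).
#' @examples
#' percentile_rank(1, 30049)
#' @export
percentile_rank <- function(rank, n) {
  rank <- as.numeric(rank)
  n <- as.numeric(n)
  if (any(!is.finite(rank)) || any(!is.finite(n)) ||
      any(rank < 1) || any(n < 1) || any(rank != floor(rank))) {
    abort("rank must be a positive integer and n a positive count")
  }
  if (any(rank > n)) abort("rank cannot exceed the number of candidates n")
  100 * rank / n
}

#' Format a percentile for display
#'
#' @param p Numeric percentile(s).
#' @param digits Decimal places (default 3).
#' @return Character like `"0.003%"`.
#' @export
format_percentile <- function(p, digits = 3) {
  sprintf(paste0("%.", digits, "f%%"), p)
}

#' @export
print.ranked_table <- function(x, n = 10, ...) {
  cat(sprintf("<ranked_table: %s> %d candidates\n",
              attr(x, "entity_type"), attr(x, "n_candidates")))
  NextMethod(n = n)
}

#' Run the full prioritization pipeline from a network and seeds
#'
#' Convenience wrapper: builds the transition matrix, initializes the seed
#' vector, propagates to convergence, collapses replica scores to entity
#' scores, and returns one ranked table per requested entity type.
#'
#' @param net A `multinet`.
#' @param seeds Seed entities (strings or data frame).
#' @param alpha Walk-continuation weight (default 0.7; restart 0.3).
#' @param jumps Optional explicit [jump_spec()]; default equal-split with
#'   `total_jump`.
#' @param total_jump Total jump mass for the default jump spec.
#' @param types Entity types to rank (default: every type present).
#' @param exclude_seeds Drop seeds from their own type's table.
#' @param collapse Replica collapse rule, `"sum"` or `"max"`.
#' @param tol,max_iter Convergence controls for [propagate()].
#' @return A list of class `prioritization`: `tables` (named list of
#'   `ranked_table`s), `scores` (`score_vector`), `entity_scores`,
#'   `transition`, `seeds`.
#' @examples
#' l1 <- as_subnetwork(tibble::tibble(
#'   source_id = "d1", source_type = "disease",
#'   target_id = c("APP", "PSEN1"), target_type = "gene"
#' ), name = "dg")
#' res <- prioritize(build_multinet(list(l1)), "gene:APP")
#' res$tables$gene
#' @export
prioritize <- function(net, seeds, alpha = 0.7, jumps = NULL,
                       total_jump = 0.5, types = NULL,
                       exclude_seeds = TRUE, collapse = "sum",
                       tol = 1e-9, max_iter = 1000) {
  stopifnot(inherits(net, "multinet"))
  tm <- assemble_transition(net, jumps = jumps, total_jump = total_jump)
  s0 <- seed_vector(net, seeds)
  s <- propagate(tm, s0, alpha = alpha, tol = tol, max_iter = max_iter)
  entity_scores <- aggregate_entity_scores(s, collapse = collapse)
  if (is.null(types)) types <- unique(net$index$entity_type)
  tables <- purrr::map(
    rlang::set_names(types),
    ~ rank_by_type(entity_scores, .x, seeds = s0$seeds,
                   exclude_seeds = exclude_seeds)
  )
  structure(
    list(tables = tables, scores = s, entity_scores = entity_scores,
         transition = tm, seeds = s0$seeds),
    class = "prioritization"
  )
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf(
    "<prioritization> seeds: %s | %s\n",
    paste(entity_key(x$seeds$entity_type, x$seeds$identifier),
          collapse = ", "),
    if (isTRUE(x$scores$converged))
      sprintf("converged in %d iterations", x$scores$iteration)
    else "did not converge"
  ))
  for (nm in names(x$tables)) {
    t1 <- x$tables[[nm]]
    if (nrow(t1) > 0) {
      cat(sprintf("  top %s: %s (score %.4g, percentile %s)\n",
                  nm, t1$identifier[1], t1$score[1],
                  format_percentile(t1$percentile[1])))
    }
  }
  invisible(x)
}

#' @rdname tidy-rwrnet
#' @export
tidy.prioritization <- function(x, ...) {
  dplyr::bind_rows(lapply(x$tables, tibble::as_tibble))
}

#' @rdname glance-rwrnet
#' @export
glance.prioritization <- function(x, ...) {
  g <- glance(x$scores)
  g$n_types_ranked <- length(x$tables)
  g
}

#' Write ranked tables as TSV, one file per entity type
#'
#' @param result A `prioritization`.
#' @param dir Output directory (created if needed).
#' @param types Subset of tables to write (default all).
#' @return Invisibly, the written paths.
#' @export
write_ranked_tables <- function(result, dir, types = NULL) {
  stopifnot(inherits(result, "prioritization"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(types)) types <- names(result$tables)
  paths <- vapply(types, function(ty) {
    path <- file.path(dir, paste0("ranked_", ty, ".tsv"))
    utils::write.table(tibble::as_tibble(result$tables[[ty]]), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
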