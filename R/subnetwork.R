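#' Build a sub-network (one knowledge layer) from an edge table
#'
#' A sub-network is one layer of the heterogeneous network: a typed node set
#' plus an (optionally weighted, optionally directed) edge list. Ingestion
#' enforces the layer invariants: identifiers are case-normalized, self-loops
#' are dropped with a warning, duplicate `(source, target)` rows are
#' collapsed with a warning (weights summed for weighted input, kept at 1
#' for unweighted input), and all weights must be positive.
#'
#' @param edges A data frame with columns `source_id`, `source_type`,
#'   `target_id`, `target_type` and optionally `weight`.
#' @param name Layer name (unique within a multi-layer network).
#' @param weighted Logical; defaults to `TRUE` iff `edges` has a `weight`
#'   column. Unweighted layers store all weights as 1.
#' @param directed Logical; direction metadata is retained, but adjacency
#'   matrices are symmetrized for walk purposes unless
#'   `respect_direction = TRUE` is requested downstream.
#' @param nodes Optional data frame (`entity_type`, `identifier`) of nodes
#'   that belong to the layer even without an edge — e.g. the full gene
#'   roster of a screen. The node set is the union of these with every edge
#'   endpoint.
#' @return An object of class `subnetwork`: a list with `name`, `nodes`
#'   (tibble, sorted by entity key), `edges` (tibble), `weighted`,
#'   `directed`.
#' @examples
#' edges <- tibble::tibble(
#'   source_id = "OMIM:104300", source_type = "disease",
#'   target_id = c("APP", "PSEN1"), target_type = "gene"
#' )
#' as_subnetwork(edges, name = "omimDGN", directed = TRUE)
#' @export
as_subnetwork <- function(edges, name, weighted = NULL, directed = FALSE,
                          nodes = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  edges <- tibble::as_tibble(edges)
  required <- c("source_id", "source_type", "target_id", "target_type")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(sprintf("Edge table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  has_weight <- "weight" %in% names(edges)
  if (is.null(weighted)) weighted <- has_weight

  if (nrow(edges) > 0) {
    src <- entity(edges$source_type, edges$source_id)
    tgt <- entity(edges$target_type, edges$target_id)
    w <- if (has_weight) as.numeric(edges$weight) else rep(1, nrow(edges))
    if (any(!is.finite(w) | w <= 0)) {
      abort("Edge weights must be positive finite numbers")
    }
    edges <- tibble::tibble(
      source_type = src$entity_type, source_id = src$identifier,
      target_type = tgt$entity_type, target_id = tgt$identifier,
      weight = w
    )
    self <- edges$source_type == edges$target_type &
      edges$source_id == edges$target_id
    if (any(self)) {
      warn(sprintf("[%s] dropped %d self-loop edge(s)", name, sum(self)))
      edges <- edges[!self, , drop = FALSE]
    }
    dup_key <- paste(
      entity_key(edges$source_type, edges$source_id),
      entity_key(edges$target_type, edges$target_id),
      sep = "->"
    )
    if (anyDuplicated(dup_key)) {
      n_dup <- nrow(edges) - length(unique(dup_key))
      warn(sprintf(
        "[%s] collapsed %d duplicate edge row(s)%s", name, n_dup,
        if (weighted) " (weights summed)" else ""
      ))
      edges <- edges |>
        dplyr::group_by(.data$source_type, .data$source_id,
                        .data$target_type, .data$target_id) |>
        dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
      if (!weighted) edges$weight <- 1
    }
  } else {
    edges <- tibble::tibble(
      source_type = character(), source_id = character(),
      target_type = character(), target_id = character(),
      weight = numeric()
    )
  }
  if (!weighted) edges$weight <- rep(1, nrow(edges))

  extra <- if (is.null(nodes)) NULL else entity(nodes$entity_type,
                                                nodes$identifier)
  nodes <- dplyr::bind_rows(
    tibble::tibble(entity_type = edges$source_type, identifier = edges$source_id),
    tibble::tibble(entity_type = edges$target_type, identifier = edges$target_id),
    extra
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(entity_key(.data$entity_type, .data$identifier))

  structure(
    list(name = name, nodes = nodes, edges = edges,
         weighted = weighted, directed = directed),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "<subnetwork '%s'> %d nodes, %d edges (%s, %s)\n",
    x$name, nrow(x$nodes), nrow(x$edges),
    if (x$weighted) "weighted" else "unweighted",
    if (x$directed) "directed" else "undirected"
  ))
  counts <- table(x$nodes$entity_type)
  if (length(counts) > 0) {
    cat("  nodes by type:",
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a sub-network from an edge-list TSV
#'
#' The expected format is tab-separated with a header line
#' `source_id<TAB>source_type<TAB>target_id<TAB>target_type[<TAB>weight]`.
#' Lines starting with `#` are ignored. A row with the wrong number of
#' fields, an unknown entity type, or a non-positive / non-numeric weight is
#' a parse error reported with its line number.
#'
#' @param file Path to a TSV file, or a character vector of lines.
#' @param layer_name Layer name; defaults to the file name without extension.
#' @param directed Logical; stored as metadata on the layer.
#' @return A [as_subnetwork()] object; `weighted` is `TRUE` iff the header
#'   has a `weight` column.
#' @export
read_edge_list <- function(file, layer_name = NULL, directed = FALSE) {
  lines <- read_input_lines(file)
  if (is.null(layer_name)) {
    layer_name <- if (length(file) == 1 && file.exists(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "layer"
  }
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    abort(sprintf("[%s] edge list has no header line", layer_name))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("source_id", "source_type", "target_id", "target_type")
  if (!identical(header[seq_along(required)], required) ||
      !(length(header) == 4 ||
        (length(header) == 5 && header[5] == "weight"))) {
    abort(sprintf(
      "[%s] line %d: header must be %s with optional 'weight'",
      layer_name, line_no[1], paste(required, collapse = "\t")
    ))
  }
  has_weight <- length(header) == 5
  body <- lines[-1]
  body_no <- line_no[-1]
  if (length(body) == 0) {
    return(as_subnetwork(
      tibble::tibble(source_id = character(), source_type = character(),
                     target_id = character(), target_type = character()),
      name = layer_name, weighted = has_weight, directed = directed
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- n_fields != length(header)
  if (any(bad)) {
    abort(sprintf(
      "[%s] line %d: expected %d tab-separated fields, found %d",
      layer_name, body_no[which(bad)[1]], length(header),
      n_fields[which(bad)[1]]
    ))
  }
  mat <- do.call(rbind, fields)
  types <- c(mat[, 2], mat[, 4])
  bad_type <- !types %in% entity_types()
  if (any(bad_type)) {
    idx <- ((which(bad_type)[1] - 1) %% nrow(mat)) + 1
    abort(sprintf(
      "[%s] line %d: unknown entity type '%s'",
      layer_name, body_no[idx], types[which(bad_type)[1]]
    ))
  }
  weight <- NULL
  if (has_weight) {
    weight <- suppressWarnings(as.numeric(mat[, 5]))
    bad_w <- !is.finite(weight) | weight <= 0
    if (any(bad_w)) {
      idx <- which(bad_w)[1]
      abort(sprintf(
        "[%s] line %d: weight '%s' is not a positive number",
        layer_name, body_no[idx], mat[idx, 5]
      ))
    }
  }
  edges <- tibble::tibble(
    source_id = mat[, 1], source_type = mat[, 2],
    target_id = mat[, 3], target_type = mat[, 4]
  )
  if (has_weight) edges$weight <- weight
  as_subnetwork(edges, name = layer_name, weighted = has_weight,
                directed = directed)
}

#' Write a sub-network back to edge-list TSV
#'
#' Inverse of [read_edge_list()]: re-reading the written file yields an
#' edge-identical sub-network (up to row order). The `weight` column is
#' written only for weighted layers.
#'
#' @param subnet A `subnetwork`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_edge_list <- function(subnet, file) {
  stopifnot(inherits(subnet, "subnetwork"))
  e <- subnet$edges
  cols <- c("source_id", "source_type", "target_id", "target_type")
  out <- e[, c("source_id", "source_type", "target_id", "target_type")]
  if (subnet$weighted) {
    out$weight <- format(e$weight, trim = TRUE, digits = 15)
    cols <- c(cols, "weight")
  }
  writeLines(
    c(paste(cols, collapse = "\t"),
      do.call(paste, c(unname(as.list(out)), sep = "\t"))),
    con = file
  )
  invisible(file)
}

#' Read a pathway-gene membership layer from a GMT file
#'
#' Standard GMT: one gene set per line, tab-separated fields `set name`,
#' `description`, then member gene symbols. Produces an unweighted,
#' undirected layer with one pathway node per line, one gene node per
#' distinct symbol, and one pathway-gene edge per membership.
#'
#' @param file Path to a GMT file, or a character vector of lines.
#' @param layer_name Layer name (default `"PathGN"`).
#' @return A `subnetwork` with pathway and gene nodes.
#' @export
read_gene_sets_gmt <- function(file, layer_name = "PathGN") {
  lines <- read_input_lines(file)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_subnetwork(
      tibble::tibble(source_id = character(), source_type = character(),
                     target_id = character(), target_type = character()),
      name = layer_name, weighted = FALSE, directed = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    idx <- which(n_fields < 3)[1]
    abort(sprintf(
      "[%s] line %d: GMT line needs a set name, description and >= 1 member",
      layer_name, line_no[idx]
    ))
  }
  edges <- purrr::map_dfr(fields, function(f) {
    tibble::tibble(
      source_id = f[[1]], source_type = "pathway",
      target_id = unique(f[-(1:2)]), target_type = "gene"
    )
  })
  as_subnetwork(edges, name = layer_name, weighted = FALSE, directed = FALSE)
}

#' Within-layer adjacency matrix
#'
#' Sparse nonnegative adjacency over the layer's sorted node index. Directed
#' layers are symmetrized with an entrywise maximum unless
#' `respect_direction = TRUE` — a gene seed could otherwise never reach
#' disease nodes through disease-to-gene annotation edges.
#'
#' @param subnet A `subnetwork`.
#' @param respect_direction Keep directed edges one-way (default `FALSE`).
#' @return A `dgCMatrix` of dimension `|nodes| x |nodes|`, with dimnames set
#'   to entity keys.
#' @export
layer_adjacency <- function(subnet, respect_direction = FALSE) {
  stopifnot(inherits(subnet, "subnetwork"))
  keys <- entity_key(subnet$nodes$entity_type, subnet$nodes$identifier)
  n <- length(keys)
  e <- subnet$edges
  if (nrow(e) == 0) {
    return(sparseMatrix(i = integer(), j = integer(), x = numeric(),
                        dims = c(n, n), dimnames = list(keys, keys)))
  }
  i <- match(entity_key(e$source_type, e$source_id), keys)
  j <- match(entity_key(e$target_type, e$target_id), keys)
  A <- sparseMatrix(i = i, j = j, x = e$weight, dims = c(n, n),
                    dimnames = list(keys, keys))
  if (!subnet$directed || !respect_direction) {
    A <- pmax_sparse(A, Matrix::t(A))
  }
  A
}

# Entrywise maximum of two same-shaped sparse matrices.
pmax_sparse <- function(A, B) {
  out <- (A + B + abs(A - B)) / 2
  drop0(out)
}

read_input_lines <- function(file) {
  if (length(file) == 1 && !grepl("[\t\n]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE), use.names = FALSE)
  }
}
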