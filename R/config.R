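#' Read a network configuration file
#'
#' A config declares the layers of the multi-layer network (name, file,
#' format, weighted/directed flags), the jump specification (either
#' `total_jump`, a scalar split equally among coupled layers, or an
#' explicit `lambda` table), the walk parameter `alpha`, and optional
#' `seeds`. YAML or JSON, chosen by file extension.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` config.
#' @return A list of class `network_config`.
#' @export
read_network_config <- function(file) {
  if (!file.exists(file)) abort(sprintf("Config file not found: %s", file))
  cfg <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    abort("Config must be a .yaml/.yml or .json file")
  }
  validate_network_config(cfg)
}

validate_network_config <- function(cfg) {
  if (is.null(cfg$layers) || length(cfg$layers) == 0) {
    abort("Config must declare at least one layer")
  }
  if (is.data.frame(cfg$layers)) {
    cfg$layers <- lapply(seq_len(nrow(cfg$layers)),
                         function(i) as.list(cfg$layers[i, ]))
  }
  nms <- vapply(cfg$layers, function(l) l$name %||% "", character(1))
  if (any(!nzchar(nms))) abort("Every layer needs a name")
  if (anyDuplicated(nms)) {
    abort(sprintf("Duplicate layer name(s) in config: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  cfg$layers <- lapply(cfg$layers, function(l) {
    l$format <- l$format %||% "edge_list"
    if (!l$format %in% c("edge_list", "gmt")) {
      abort(sprintf("Layer '%s': unknown format '%s'", l$name, l$format))
    }
    l$directed <- isTRUE(l$directed)
    l
  })
  cfg$alpha <- cfg$alpha %||% 0.7
  cfg$total_jump <- cfg$total_jump %||% 0.5
  structure(cfg, class = "network_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a multi-layer network from a configuration
#'
#' Reads every layer file named in the config ([read_edge_list()] or
#' [read_gene_sets_gmt()] by format) and assembles the multi-layer network.
#'
#' @param config A [read_network_config()] result (or an equivalent list).
#' @param base_dir Directory layer file paths are resolved against
#'   (default: current directory).
#' @return A `multinet`.
#' @export
load_network <- function(config, base_dir = ".") {
  if (!inherits(config, "network_config")) {
    config <- validate_network_config(config)
  }
  layers <- lapply(config$layers, function(l) {
    if (is.null(l$file)) {
      abort(sprintf("Layer '%s' has no file", l$name))
    }
    path <- if (file.exists(l$file)) l$file else file.path(base_dir, l$file)
    if (!file.exists(path)) {
      abort(sprintf("Layer '%s': file not found: %s", l$name, l$file))
    }
    if (l$format == "gmt") {
      read_gene_sets_gmt(path, layer_name = l$name)
    } else {
      read_edge_list(path, layer_name = l$name, directed = l$directed)
    }
  })
  build_multinet(layers)
}

#' Seven-layer configuration template
#'
#' A config skeleton for the canonical seven-layer integration of curated
#' disease-gene annotation (OMIM and ClinVar), GWAS associations, pathway
#' membership, protein-protein interaction, mouse-knockout phenotype
#' annotation, and a chemical-gene layer. File paths are left for the user
#' to fill in; the disease-gene layers are directional in their sources and
#' are marked as such (direction is metadata; walks symmetrize by default).
#'
#' @param file Optional path; when given, the template is written there as
#'   YAML.
#' @return The config list (class `network_config`), invisibly when
#'   written to a file.
#' @export
seven_layer_template <- function(file = NULL) {
  cfg <- list(
    layers = list(
      list(name = "omimDGN", file = "omim_dgn.tsv", format = "edge_list",
           directed = TRUE),
      list(name = "clinvarDGN", file = "clinvar_dgn.tsv",
           format = "edge_list", directed = TRUE),
      list(name = "gwasDGN", file = "gwas_dgn.tsv", format = "edge_list",
           directed = TRUE),
      list(name = "PathGN", file = "pathways.gmt", format = "gmt"),
      list(name = "PPIN", file = "ppi.tsv", format = "edge_list"),
      list(name = "PhenGN", file = "phen_gn.tsv", format = "edge_list"),
      list(name = "ChemicalGN", file = "chemical_gn.tsv",
           format = "edge_list")
    ),
    alpha = 0.7,
    total_jump = 0.5,
    seeds = list("gene:CHCHD6")
  )
  cfg <- validate_network_config(cfg)
  if (!is.null(file)) {
    yaml::write_yaml(unclass(cfg), file)
    return(invisible(cfg))
  }
  cfg
}
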