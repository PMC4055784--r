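# Tabular and network I/O: schema-validated TSV readers/writers, GraphML
# export/import, dataset round-trip, JSON manifests. TSV throughout
# (compound names contain commas).

#' Table schemas for every file the pipeline reads or writes
#'
#' Each schema names its required columns with semantic types
#' (`character`, `numeric`, `integer`, `logical`) and any optional columns.
#' @export
table_schemas <- list(
  plant_catalog = list(
    name = "plant_catalog",
    required = c(plant_id = "character", plant_name = "character",
                 edible = "logical"),
    optional = character()
  ),
  plant_compounds = list(
    name = "plant_compounds",
    required = c(plant_id = "character", compound_id = "character"),
    optional = character()
  ),
  compound_table = list(
    name = "compound_table",
    required = c(compound_id = "character", inchikey = "character",
                 mw = "numeric", tpsa = "numeric", slogp = "numeric",
                 fingerprint = "character"),
    optional = c(smiles = "character", group = "character")
  ),
  bioactivity = list(
    name = "bioactivity",
    required = c(compound_inchikey = "character", protein_id = "character",
                 organism = "character", type = "character", value = "numeric"),
    optional = character()
  ),
  ppi = list(
    name = "ppi",
    required = c(protein_a = "character", protein_b = "character",
                 score = "numeric"),
    optional = c(organism = "character")
  ),
  expression = list(
    name = "expression",
    required = c(protein_id = "character", positive = "logical"),
    optional = character()
  ),
  reactions = list(
    name = "reactions",
    required = c(reaction_id = "character", metabolite_id = "character",
                 role = "character", enzyme_id = "character",
                 pathway = "character"),
    optional = character()
  ),
  metabolites = list(
    name = "metabolites",
    required = c(metabolite_id = "character", inchikey = "character",
                 mw = "numeric", fingerprint = "character"),
    optional = character()
  ),
  interactions = list(
    name = "interactions",
    required = c(plant_id = "character", compound_id = "character",
                 protein_id = "character", route = "character",
                 probability = "numeric"),
    optional = character()
  )
)

coerce_column <- function(x, type, col, name) {
  out <- switch(type,
    character = as.character(x),
    numeric = suppressWarnings(as.numeric(x)),
    integer = suppressWarnings(as.integer(x)),
    logical = {
      v <- toupper(trimws(as.character(x)))
      ifelse(v %in% c("TRUE", "T", "1"), TRUE,
             ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
    },
    stop("unknown schema type: ", type)
  )
  bad <- which(is.na(out) & !is.na(x) & x != "" & x != "NA")
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed %s value in column '%s' at data row %d ('%s')",
                 name, type, col, bad[1], x[bad[1]]))
  }
  out
}

#' Read and validate a TSV table against a schema
#'
#' @param path file path.
#' @param schema one of [table_schemas] (or a list of the same shape).
#' @return typed data.frame containing at least the required columns.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("read_table: no such file: ", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop(schema$name, ": cannot parse ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0 && ncol(df) == 0) stop(schema$name, ": empty file: ", path)
  missing <- setdiff(names(schema$required), names(df))
  if (length(missing) > 0) {
    stop(schema$name, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in names(schema$required)) {
    df[[col]] <- coerce_column(df[[col]], schema$required[[col]], col, schema$name)
  }
  for (col in intersect(names(schema$optional), names(df))) {
    df[[col]] <- coerce_column(df[[col]], schema$optional[[col]], col, schema$name)
  }
  df
}

#' Write a table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

graphml_type <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "int"
  else if (is.numeric(x)) "double"
  else "string"
}

#' Write a graph as GraphML
#'
#' Node and edge attribute columns become typed GraphML keys, so node sizes
#' and edge weights survive a round trip into standard network viewers.
#'
#' @param nodes data.frame whose first column is the unique node id;
#'   remaining columns become node attributes.
#' @param edges data.frame whose first two columns are source and target
#'   ids; remaining columns become edge attributes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(nodes, edges, path) {
  ids <- as.character(nodes[[1]])
  if (anyDuplicated(ids)) stop("write_graphml: duplicate node id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  node_attrs <- names(nodes)[-1]
  edge_attrs <- if (ncol(edges) > 2) names(edges)[-(1:2)] else character()
  for (a in node_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), `for` = "node",
                        attr.name = a, attr.type = graphml_type(nodes[[a]]))
  }
  for (a in edge_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), `for` = "edge",
                        attr.name = a, attr.type = graphml_type(edges[[a]]))
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = ids[i])
    for (a in node_attrs) {
      xml2::xml_add_child(nd, "data", key = paste0("n_", a),
                          format_attr(nodes[[a]][i]))
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = as.character(edges[[1]][i]),
                              target = as.character(edges[[2]][i]))
    for (a in edge_attrs) {
      xml2::xml_add_child(ed, "data", key = paste0("e_", a),
                          format_attr(edges[[a]][i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

format_attr <- function(x) {
  if (is.logical(x)) tolower(as.character(x))
  else if (is.numeric(x)) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  else as.character(x)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file.
#' @return list with `nodes` and `edges` data.frames, attribute types
#'   restored from the declared keys.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_info <- data.frame(
    id = xml2::xml_attr(keys, "id"),
    domain = xml2::xml_attr(keys, "for"),
    name = xml2::xml_attr(keys, "attr.name"),
    type = xml2::xml_attr(keys, "attr.type"),
    stringsAsFactors = FALSE
  )
  parse_attr <- function(values, type) {
    switch(type,
           boolean = values == "true",
           int = as.integer(values),
           double = as.numeric(values),
           values)
  }
  node_els <- xml2::xml_find_all(doc, ".//node")
  nodes <- data.frame(id = xml2::xml_attr(node_els, "id"),
                      stringsAsFactors = FALSE)
  for (i in which(key_info$domain == "node")) {
    vals <- vapply(node_els, function(n) {
      d <- xml2::xml_find_first(n, sprintf("./data[@key='%s']", key_info$id[i]))
      xml2::xml_text(d)
    }, character(1))
    nodes[[key_info$name[i]]] <- parse_attr(vals, key_info$type[i])
  }
  edge_els <- xml2::xml_find_all(doc, ".//edge")
  edges <- data.frame(source = xml2::xml_attr(edge_els, "source"),
                      target = xml2::xml_attr(edge_els, "target"),
                      stringsAsFactors = FALSE)
  for (i in which(key_info$domain == "edge")) {
    vals <- vapply(edge_els, function(n) {
      d <- xml2::xml_find_first(n, sprintf("./data[@key='%s']", key_info$id[i]))
      xml2::xml_text(d)
    }, character(1))
    edges[[key_info$name[i]]] <- parse_attr(vals, key_info$type[i])
  }
  list(nodes = nodes, edges = edges)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits the same dialects the pipeline reads, plus a JSON truth manifest
#' and the generator configuration.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phytonet_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(dataset$plants, file.path(dir, "plants.tsv"))
  write_table(dataset$plant_compounds, file.path(dir, "plant_compounds.tsv"))
  write_table(dataset$compounds, file.path(dir, "compounds.tsv"))
  write_table(dataset$bioactivity, file.path(dir, "bioactivity.tsv"))
  write_table(dataset$ppi, file.path(dir, "ppi.tsv"))
  write_table(dataset$expression, file.path(dir, "expression.tsv"))
  write_table(dataset$reactions, file.path(dir, "reactions.tsv"))
  write_table(dataset$metabolites, file.path(dir, "metabolites.tsv"))
  for (cat_name in names(dataset$seeds)) {
    writeLines(dataset$seeds[[cat_name]],
               file.path(dir, paste0("seeds_", cat_name, ".txt")))
  }
  truth <- dataset$truth
  jsonlite::write_json(
    list(planted_interactions = truth$planted_interactions,
         planted_clusters = truth$planted_clusters,
         planted_plant_groups = truth$planted_plant_groups,
         analog_pairs = truth$analog_pairs,
         config = unclass(dataset$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the TSV files and truth manifest.
#' @return list of class `phytonet_dataset`.
#' @export
read_dataset <- function(dir) {
  seed_files <- list.files(dir, pattern = "^seeds_.*\\.txt$", full.names = TRUE)
  seeds <- lapply(seed_files, readLines)
  names(seeds) <- sub("^seeds_(.*)\\.txt$", "\\1", basename(seed_files))
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  config <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE,
                              simplifyMatrix = FALSE)
    truth <- list(
      planted_interactions = as.data.frame(tj$planted_interactions),
      planted_clusters = lapply(tj$planted_clusters, as.character),
      planted_plant_groups = lapply(tj$planted_plant_groups, as.character),
      analog_pairs = as.data.frame(tj$analog_pairs)
    )
    config <- tj$config
  }
  structure(list(
    plants = read_table(file.path(dir, "plants.tsv"), table_schemas$plant_catalog),
    plant_compounds = read_table(file.path(dir, "plant_compounds.tsv"),
                                 table_schemas$plant_compounds),
    compounds = read_table(file.path(dir, "compounds.tsv"),
                           table_schemas$compound_table),
    bioactivity = read_table(file.path(dir, "bioactivity.tsv"),
                             table_schemas$bioactivity),
    ppi = read_table(file.path(dir, "ppi.tsv"), table_schemas$ppi),
    seeds = seeds,
    expression = read_table(file.path(dir, "expression.tsv"),
                            table_schemas$expression),
    reactions = read_table(file.path(dir, "reactions.tsv"),
                           table_schemas$reactions),
    metabolites = read_table(file.path(dir, "metabolites.tsv"),
                             table_schemas$metabolites),
    truth = truth, config = config
  ), class = "phytonet_dataset")
}
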