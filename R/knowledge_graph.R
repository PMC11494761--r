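# Five-dimension cardiopathy knowledge graph: typed nodes and edges,
# schema validation, and the structural/functional context traversals that
# situate a variant's gene within heart anatomy and cardiac pathways.

KG_DIMENSIONS <- c("location", "entity", "structural", "pathway", "variation")

KG_KINDS <- list(
  location = c("System", "Organ", "Tissue", "Cell", "CellularComponent"),
  entity = c("ComplexEntity", "SimpleEntity", "Protein", "Ion", "Molecule",
             "ProteinFamily"),
  structural = c("Chromosome", "GeneElement"),
  pathway = c("Pathway", "Process"),
  variation = c("Variation", "GeneAnnotation", "ProteinAnnotation"))

LOCATION_KINDS <- KG_KINDS$location
ENTITY_ACTOR_KINDS <- c("ComplexEntity", "SimpleEntity", "Protein", "Ion",
                        "Molecule")

# Endpoint legality: for each edge kind, the node kinds allowed at each end.
KG_EDGE_LEGALITY <- list(
  part_of = list(source = LOCATION_KINDS, target = LOCATION_KINDS),
  component_of = list(source = ENTITY_ACTOR_KINDS, target = "ComplexEntity"),
  located_in = list(source = ENTITY_ACTOR_KINDS,
                    target = c("CellularComponent", "Cell", "Tissue", "Organ")),
  contains = list(source = "Chromosome", target = "GeneElement"),
  codes_for = list(source = "GeneElement", target = "Protein"),
  member_of_family = list(source = "Protein", target = "ProteinFamily"),
  decomposes_into = list(source = "Pathway", target = c("Pathway", "Process")),
  takes_part_in = list(source = ENTITY_ACTOR_KINDS, target = "Process"),
  affects = list(source = "Variation", target = c("GeneElement", "Protein")))

KG_HIERARCHY_KINDS <- c("part_of", "component_of", "located_in",
                        "decomposes_into")

#' Construct a knowledge-graph node
#'
#' @param id Unique identifier.
#' @param dimension One of location, entity, structural, pathway, variation.
#' @param kind Node kind, consistent with the dimension.
#' @param label Display name.
#' @param attributes Named list of extra attributes (e.g. a gene symbol).
#' @return List of class `kg_node`.
#' @export
kg_node <- function(id, dimension, kind, label = id, attributes = list()) {
  dimension <- match.arg(dimension, KG_DIMENSIONS)
  if (!kind %in% KG_KINDS[[dimension]]) {
    stop("node '", id, "': kind '", kind, "' not in dimension '",
         dimension, "'")
  }
  structure(list(id = as.character(id), dimension = dimension, kind = kind,
                 label = as.character(label), attributes = attributes),
            class = "kg_node")
}

#' Construct a knowledge-graph edge
#'
#' `role` (input/output/regulator) is meaningful only for `takes_part_in`
#' edges; [kg_validate()] flags acting entities participating without one.
#'
#' @param source,target Node ids.
#' @param kind Edge kind.
#' @param role Participation role or `NA`.
#' @return List of class `kg_edge`.
#' @export
kg_edge <- function(source, target, kind, role = NA_character_) {
  kind <- match.arg(kind, names(KG_EDGE_LEGALITY))
  if (!is.na(role) && kind != "takes_part_in") {
    stop("edge ", source, "->", target, ": role is only valid on ",
         "takes_part_in edges")
  }
  if (!is.na(role) && !role %in% c("input", "output", "regulator")) {
    stop("invalid role '", role, "'")
  }
  structure(list(source = as.character(source), target = as.character(target),
                 kind = kind, role = role),
            class = "kg_edge")
}

#' Assemble a knowledge graph
#'
#' @param nodes List of `kg_node` objects.
#' @param edges List of `kg_edge` objects.
#' @param disorder_group One of cardiomyopathy, channelopathy, aortic.
#' @param schema_version Dialect version string.
#' @return Object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(nodes, edges,
                            disorder_group = c("cardiomyopathy",
                                               "channelopathy", "aortic"),
                            schema_version = "1.0") {
  disorder_group <- match.arg(disorder_group)
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (e in edges) {
    if (!e$source %in% ids || !e$target %in% ids) {
      stop("edge ", e$source, "->", e$target, " references unknown node")
    }
  }
  structure(list(nodes = stats::setNames(nodes, ids), edges = edges,
                 disorder_group = disorder_group,
                 schema_version = schema_version),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph>", x$disorder_group, "-", length(x$nodes), "nodes,",
      length(x$edges), "edges\n")
  invisible(x)
}

# ---- validation --------------------------------------------------------

#' Validate a knowledge graph against the schema
#'
#' Checks (a) endpoint-kind legality per edge kind, (b) acyclicity of the
#' part_of / component_of / located_in / decomposes_into hierarchies,
#' (c) that every acting entity with takes_part_in edges has at least one
#' with a role, and (d) that every Protein has an incoming codes_for edge
#' from a GeneElement. Violations are returned as data, not raised.
#'
#' @param graph A `knowledge_graph`.
#' @return Character vector of violation messages (empty when valid).
#' @export
kg_validate <- function(graph) {
  v <- character(0)
  kind_of <- function(id) graph$nodes[[id]]$kind
  # (a) endpoint legality
  for (e in graph$edges) {
    legal <- KG_EDGE_LEGALITY[[e$kind]]
    if (!kind_of(e$source) %in% legal$source) {
      v <- c(v, sprintf("edge %s-[%s]->%s: illegal source kind %s",
                        e$source, e$kind, e$target, kind_of(e$source)))
    }
    if (!kind_of(e$target) %in% legal$target) {
      v <- c(v, sprintf("edge %s-[%s]->%s: illegal target kind %s",
                        e$source, e$kind, e$target, kind_of(e$target)))
    }
  }
  # (b) hierarchy acyclicity (per edge kind)
  for (k in KG_HIERARCHY_KINDS) {
    sub <- Filter(function(e) e$kind == k, graph$edges)
    if (has_cycle(sub)) v <- c(v, sprintf("cycle in %s hierarchy", k))
  }
  # (c) participation role
  part <- Filter(function(e) e$kind == "takes_part_in", graph$edges)
  actors <- unique(vapply(part, function(e) e$source, character(1)))
  for (a in actors) {
    roles <- vapply(Filter(function(e) e$source == a, part),
                    function(e) e$role, character(1))
    if (all(is.na(roles))) {
      v <- c(v, sprintf("acting entity %s participates without any role", a))
    }
  }
  # (d) protein coding provenance
  coded <- vapply(Filter(function(e) e$kind == "codes_for", graph$edges),
                  function(e) e$target, character(1))
  for (n in graph$nodes) {
    if (n$kind == "Protein" && !n$id %in% coded) {
      v <- c(v, sprintf("protein %s has no incoming codes_for edge", n$id))
    }
  }
  v
}

# DFS cycle detection on an edge list.
has_cycle <- function(edges) {
  if (!length(edges)) return(FALSE)
  adj <- split(vapply(edges, function(e) e$target, character(1)),
               vapply(edges, function(e) e$source, character(1)))
  state <- new.env(parent = emptyenv())
  visit <- function(u) {
    s <- get0(u, envir = state, ifnotfound = "white")
    if (s == "grey") return(TRUE)
    if (s == "black") return(FALSE)
    assign(u, "grey", envir = state)
    for (w in adj[[u]]) if (visit(w)) return(TRUE)
    assign(u, "black", envir = state)
    FALSE
  }
  any(vapply(names(adj), visit, logical(1)))
}

# ---- traversals --------------------------------------------------------

kg_find_gene <- function(graph, gene_symbol) {
  for (n in graph$nodes) {
    if (n$kind != "GeneElement") next
    sym <- if (!is.null(n$attributes$symbol)) n$attributes$symbol else n$label
    if (identical(sym, gene_symbol) || identical(n$id, gene_symbol)) {
      return(n)
    }
  }
  stop("gene '", gene_symbol, "' not found in the ", graph$disorder_group,
       " knowledge graph")
}

edge_targets <- function(graph, ids, kind) {
  sort(unique(vapply(
    Filter(function(e) e$kind == kind && e$source %in% ids, graph$edges),
    function(e) e$target, character(1))))
}

# Transitive closure along one edge kind, breadth-first; returns nodes in
# BFS level order (most specific first), ids sorted within a level.
closure_bfs <- function(graph, start_ids, kind, include_start = TRUE) {
  seen <- character(0)
  frontier <- sort(unique(start_ids))
  out <- if (include_start) frontier else character(0)
  seen <- frontier
  while (length(frontier)) {
    nxt <- setdiff(edge_targets(graph, frontier, kind), seen)
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

#' Structural context of a gene
#'
#' Walks gene -codes_for-> protein(s) -component_of*-> entities
#' -located_in-> cellular components -part_of*-> cell, tissue, organ,
#' system, returning the deduplicated location nodes ordered
#' most-specific-first (BFS level order, ties by node id).
#'
#' @param graph A `knowledge_graph`.
#' @param gene_symbol Gene symbol or GeneElement node id.
#' @return `data.frame` with columns `id`, `kind`, `label` (zero rows when
#'   the gene's products have no located_in placement).
#' @export
structural_context <- function(graph, gene_symbol) {
  g <- kg_find_gene(graph, gene_symbol)
  proteins <- edge_targets(graph, g$id, "codes_for")
  entities <- closure_bfs(graph, proteins, "component_of")
  anchors <- edge_targets(graph, entities, "located_in")
  locs <- closure_bfs(graph, anchors, "part_of")
  data.frame(
    id = locs,
    kind = vapply(locs, function(i) graph$nodes[[i]]$kind, character(1)),
    label = vapply(locs, function(i) graph$nodes[[i]]$label, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Functional context of a gene
#'
#' For each protein coded by the gene, every process it takes part in
#' (with its role) and each ancestor pathway reached via decomposes_into.
#'
#' @param graph A `knowledge_graph`.
#' @param gene_symbol Gene symbol or GeneElement node id.
#' @return `data.frame` with columns `pathway`, `process`, `role` (pathway
#'   is `NA` for orphan processes); zero rows when no protein participates.
#' @export
functional_context <- function(graph, gene_symbol) {
  g <- kg_find_gene(graph, gene_symbol)
  proteins <- edge_targets(graph, g$id, "codes_for")
  # reverse decomposes_into index: process/pathway -> parent pathways
  parents <- list()
  for (e in graph$edges) {
    if (e$kind == "decomposes_into") {
      parents[[e$target]] <- c(parents[[e$target]], e$source)
    }
  }
  ancestors <- function(id) {
    out <- character(0); frontier <- id
    while (length(frontier)) {
      up <- setdiff(sort(unique(unlist(parents[frontier]))), out)
      out <- c(out, up); frontier <- up
    }
    out
  }
  rows <- list()
  for (e in graph$edges) {
    if (e$kind != "takes_part_in" || !e$source %in% proteins) next
    anc <- ancestors(e$target)
    if (!length(anc)) anc <- NA_character_
    for (p in anc) {
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, process = e$target, role = e$role,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pathway = character(0), process = character(0),
                      role = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway, out$process, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- serialization -----------------------------------------------------

#' Load a knowledge graph from JSON
#'
#' The dialect is `{schema_version, disorder_group, nodes[], edges[]}`.
#' The graph is validated on load; violations raise an error listing them.
#'
#' @param path File path.
#' @return A `knowledge_graph`.
#' @export
load_graph <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("failed to parse knowledge graph '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  if (is.null(j$nodes) || is.null(j$disorder_group)) {
    stop("'", path, "' is not a knowledge-graph file (missing nodes or ",
         "disorder_group)")
  }
  nodes <- lapply(j$nodes, function(n)
    kg_node(n$id, n$dimension, n$kind,
            label = if (is.null(n$label)) n$id else n$label,
            attributes = if (is.null(n$attributes)) list() else n$attributes))
  edges <- lapply(j$edges, function(e)
    kg_edge(e$source, e$target, e$kind,
            role = if (is.null(e$role)) NA_character_ else e$role))
  graph <- knowledge_graph(nodes, edges, j$disorder_group,
                           schema_version = j$schema_version)
  viol <- kg_validate(graph)
  if (length(viol)) {
    stop("knowledge graph '", path, "' violates the schema:\n  ",
         paste(viol, collapse = "\n  "))
  }
  graph
}

#' Save a knowledge graph as JSON or GraphML
#'
#' `load_graph(save_graph(g, path))` is the identity on nodes and edges
#' for the JSON format.
#'
#' @param graph A `knowledge_graph`.
#' @param path Output path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
save_graph <- function(graph, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      schema_version = graph$schema_version,
      disorder_group = graph$disorder_group,
      nodes = unname(lapply(graph$nodes, function(n)
        list(id = n$id, dimension = n$dimension, kind = n$kind,
             label = n$label, attributes = n$attributes))),
      edges = lapply(graph$edges, function(e) {
        out <- list(source = e$source, target = e$target, kind = e$kind)
        if (!is.na(e$role)) out$role <- e$role
        out
      }))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    save_graphml(graph, path)
  }
  invisible(path)
}

save_graphml <- function(graph, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (key in list(c("d_kind", "node", "kind"),
                   c("d_dim", "node", "dimension"),
                   c("d_label", "node", "label"),
                   c("d_ekind", "edge", "kind"),
                   c("d_role", "edge", "role"))) {
    xml2::xml_add_child(doc, "key", id = key[1], `for` = key[2],
                        attr.name = key[3], attr.type = "string")
  }
  gx <- xml2::xml_add_child(doc, "graph", id = graph$disorder_group,
                            edgedefault = "directed")
  for (n in graph$nodes) {
    nx <- xml2::xml_add_child(gx, "node", id = n$id)
    xml2::xml_add_child(nx, "data", key = "d_kind", n$kind)
    xml2::xml_add_child(nx, "data", key = "d_dim", n$dimension)
    xml2::xml_add_child(nx, "data", key = "d_label", n$label)
  }
  for (e in graph$edges) {
    ex <- xml2::xml_add_child(gx, "edge", source = e$source,
                              target = e$target)
    xml2::xml_add_child(ex, "data", key = "d_ekind", e$kind)
    if (!is.na(e$role)) xml2::xml_add_child(ex, "data", key = "d_role", e$role)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load one of the packaged disorder-group knowledge graphs
#'
#' @param name One of `"cardiomyopathy"`, `"channelopathy"`, `"aortic"`.
#' @return A `knowledge_graph`.
#' @export
packaged_graph <- function(name = c("cardiomyopathy", "channelopathy",
                                    "aortic")) {
  name <- match.arg(name)
  load_graph(system.file("extdata", "kg", paste0(name, ".json"),
                         package = "cardiorelevance", mustWork = TRUE))
}
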