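#' Load a hierarchical structure ontology
#'
#' Reads an ontology in the Allen "Atlas Drawings and Ontologies" JSON
#' schema: nested objects with `id`, `acronym`, `name` and a `children`
#' array. Both the bare nested form and the API envelope
#' (`{"msg": [ ... ]}`) are accepted. The tree is validated: unique ids,
#' exactly one root, no cycles (guaranteed by the nesting).
#'
#' @param path path to a JSON file.
#' @return the root node, a nested list of class `ontology_node` with
#'   fields `id`, `acronym`, `name`, `parent_id`, `children`.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(doc$msg)) doc <- doc$msg
  if (is.list(doc) && is.null(doc$id)) {
    if (length(doc) != 1L) stop("validation error: ontology must have exactly one root")
    doc <- doc[[1]]
  }
  root <- build_ontology_node(doc, parent_id = NA_integer_)
  ids <- ontology_ids(root)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("validation error: duplicate ontology ids: ", paste(dup, collapse = ", "))
  }
  root
}

build_ontology_node <- function(x, parent_id) {
  if (is.null(x$id)) stop("validation error: ontology node without an id")
  node <- list(id = as.integer(x$id),
               acronym = as.character(x$acronym %||% ""),
               name = as.character(x$name %||% ""),
               parent_id = parent_id,
               children = list())
  kids <- x$children %||% list()
  node$children <- lapply(kids, build_ontology_node, parent_id = node$id)
  class(node) <- "ontology_node"
  node
}

#' @export
print.ontology_node <- function(x, ...) {
  cat(sprintf("<ontology_node> %s (%s), id %d, %d structures in subtree\n",
              x$name, x$acronym, x$id, length(ontology_ids(x))))
  invisible(x)
}

# all ids in the subtree rooted at node (inclusive), depth-first
ontology_ids <- function(node) {
  out <- node$id
  for (ch in node$children) out <- c(out, ontology_ids(ch))
  out
}

find_node <- function(node, id) {
  if (node$id == id) return(node)
  for (ch in node$children) {
    hit <- find_node(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

find_node_by_acronym <- function(node, acronym) {
  if (identical(node$acronym, acronym)) return(node)
  for (ch in node$children) {
    hit <- find_node_by_acronym(ch, acronym)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Collect a structure and every substructure beneath it
#'
#' Returns the union of each requested root structure and all of its
#' descendants in the ontology — the id set whose voxels constitute a
#' VOI.
#'
#' @param tree root [ontology_node] (from [load_ontology()]).
#' @param root_ids integer vector of structure ids.
#' @return sorted integer vector of unique structure ids.
#' @export
collect_substructures <- function(tree, root_ids) {
  out <- integer(0)
  for (id in root_ids) {
    node <- find_node(tree, id)
    if (is.null(node)) stop("lookup error: ontology id not found: ", id)
    out <- c(out, ontology_ids(node))
  }
  sort(unique(out))
}

#' Resolve ontology acronyms to structure ids
#'
#' @param tree root [ontology_node].
#' @param acronyms character vector of structure acronyms.
#' @return integer vector of ids, in the order given.
#' @export
acronyms_to_ids <- function(tree, acronyms) {
  vapply(acronyms, function(a) {
    node <- find_node_by_acronym(tree, a)
    if (is.null(node)) stop("lookup error: ontology acronym not found: ", a)
    node$id
  }, integer(1), USE.NAMES = FALSE)
}
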