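#' Build the reduced DAG of enriched categories and their ancestors
#'
#' Reduces a category hierarchy to the enriched categories (adjusted
#' p-value below `cutoff`) together with all of their ancestors, so that
#' significant categories can be read in their hierarchical context:
#' enriched nodes are flagged `"enriched"`, the remaining ancestors
#' `"ancestor"`. All original edges with both endpoints retained are kept
#' (no transitive reduction), preserving multiple-parent structure.
#' Enrichment can appear at any level of the hierarchy. An analysis with no
#' enriched categories yields an empty DAG, not an error.
#'
#' @param dag An [ontology_dag()] over the category ids.
#' @param enrichment An `enrichment_report` from [run_ora()].
#' @param cutoff Threshold on adjusted p-values (default: the report's own
#'   significance cutoff).
#' @return An object of class `enriched_dag`: list with `nodes` (data frame
#'   `id`, `label`, `flag`) and `edges` (character matrix `child`,
#'   `parent`).
#' @export
build_enriched_dag <- function(dag, enrichment,
                               cutoff = enrichment$params$significance_cutoff) {
  stopifnot(inherits(dag, "ontology_dag"),
            inherits(enrichment, "enrichment_report"))
  tab <- enrichment$table
  hits <- tab$set_id[tab$p_adj < cutoff]
  labels <- tab$name
  names(labels) <- tab$set_id
  unknown <- setdiff(hits, dag$node_ids)
  if (length(unknown)) {
    stop("enriched categories absent from the DAG: ",
         paste(unknown, collapse = ", "))
  }
  if (length(hits) == 0L) {
    nodes <- data.frame(id = character(), label = character(),
                        flag = character(), stringsAsFactors = FALSE)
    em <- matrix(character(), ncol = 2L,
                 dimnames = list(NULL, c("child", "parent")))
    return(structure(list(nodes = nodes, edges = em), class = "enriched_dag"))
  }
  keep <- ancestor_closure(dag, hits)
  lab <- unname(labels[keep])
  lab <- ifelse(is.na(lab) | !nzchar(lab), keep, lab)
  nodes <- data.frame(id = keep, label = lab,
                      flag = ifelse(keep %in% hits, "enriched", "ancestor"),
                      stringsAsFactors = FALSE, row.names = NULL)
  em <- dag$edges[dag$edges[, "child"] %in% keep &
                  dag$edges[, "parent"] %in% keep, , drop = FALSE]
  structure(list(nodes = nodes, edges = em), class = "enriched_dag")
}

#' @export
print.enriched_dag <- function(x, ...) {
  cat(sprintf("<enriched_dag> %d nodes (%d enriched, %d ancestors), %d edges\n",
              nrow(x$nodes), sum(x$nodes$flag == "enriched"),
              sum(x$nodes$flag == "ancestor"), nrow(x$edges)))
  invisible(x)
}

# quote a DOT identifier
dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Render an enriched DAG as Graphviz DOT
#'
#' Enriched categories are coloured red, their non-enriched ancestors black;
#' edges point from child to parent. Node and edge statements are emitted in
#' sorted order, so identical DAGs always produce identical bytes.
#'
#' @param x An `enriched_dag` from [build_enriched_dag()].
#' @param path Optional output path; when `NULL` the DOT text is returned.
#' @return Character scalar of DOT source (invisibly when written).
#' @export
to_dot <- function(x, path = NULL) {
  stopifnot(inherits(x, "enriched_dag"))
  nodes <- x$nodes[order(x$nodes$id), , drop = FALSE]
  lines <- c("digraph enriched_dag {",
             "  node [shape=box, style=rounded];")
  if (nrow(nodes)) {
    col <- ifelse(nodes$flag == "enriched", "red", "black")
    lines <- c(lines, sprintf("  %s [label=%s, color=%s, fontcolor=%s];",
                              dot_quote(nodes$id), dot_quote(nodes$label),
                              col, col))
  }
  if (nrow(x$edges)) {
    em <- x$edges[order(x$edges[, "child"], x$edges[, "parent"]), ,
                  drop = FALSE]
    lines <- c(lines, sprintf("  %s -> %s;", dot_quote(em[, "child"]),
                              dot_quote(em[, "parent"])))
  }
  lines <- c(lines, "}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(txt)
}

#' Serialize an enriched DAG as a JSON node/edge list
#'
#' @param x An `enriched_dag`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
enriched_dag_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "enriched_dag"))
  edges <- if (nrow(x$edges)) {
    data.frame(child = x$edges[, "child"], parent = x$edges[, "parent"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  }
  js <- jsonlite::toJSON(list(nodes = x$nodes, edges = edges),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(js, con, sep = "\n")
  invisible(js)
}
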