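#' Read an identifier mapping table
#'
#' Platform or database identifiers are mapped to a canonical gene namespace
#' (typically Entrez Gene ids) before any analysis. The table is a
#' headerless two-column TSV, `source<TAB>canonical`, possibly many-to-many;
#' duplicate rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @return An object of class `id_mapping_table` with field `pairs`
#'   (two-column character matrix `source`, `canonical`).
#' @export
read_mapping_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) return(id_mapping_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad)) {
    stop(sprintf("mapping-table parse error at line %d of '%s': expected source<TAB>canonical",
                 which(keep)[bad[1L]], path))
  }
  id_mapping_table(do.call(rbind, parts))
}

#' Construct an identifier mapping table
#'
#' @param pairs Two-column character matrix or data frame of
#'   `(source, canonical)` pairs; duplicates collapsed, empty ids rejected.
#' @return An `id_mapping_table`.
#' @export
id_mapping_table <- function(pairs = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pm <- matrix(character(), ncol = 2L, dimnames = list(NULL, c("source", "canonical")))
  } else {
    pm <- as.matrix(pairs)
    if (ncol(pm) != 2L) stop("pairs must have two columns (source, canonical)")
    storage.mode(pm) <- "character"
    colnames(pm) <- c("source", "canonical")
    if (any(!nzchar(pm))) stop("empty identifier in mapping table")
    pm <- unique(pm)
  }
  structure(list(pairs = pm), class = "id_mapping_table")
}

#' @export
print.id_mapping_table <- function(x, ...) {
  cat(sprintf("<id_mapping_table> %d pairs, %d source ids, %d canonical ids\n",
              nrow(x$pairs), length(unique(x$pairs[, "source"])),
              length(unique(x$pairs[, "canonical"]))))
  invisible(x)
}

#' Map source identifiers to the canonical namespace
#'
#' Every input id found in the table contributes all of its canonical
#' targets (a probe mapping to k genes contributes k genes, then the union
#' is deduplicated); ids with two or more targets are reported in
#' `multi_hit` for auditability. Duplicated input ids are mapped once
#' (`input_count` still reports the raw input length).
#' Matching is exact-string and case-sensitive; the mapped set is
#' independent of input order.
#'
#' @param ids Character vector of source identifiers (non-empty).
#' @param table An [id_mapping_table()].
#' @return An object of class `mapping_report` with fields `mapped` (sorted
#'   canonical ids), `unmapped` (source ids not in the table, input order),
#'   `multi_hit` (data frame `source_id`, `n_targets`), `input_count` and
#'   `mapped_count`.
#' @export
map_ids <- function(ids, table) {
  stopifnot(inherits(table, "id_mapping_table"))
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("input id list is empty")
  uids <- unique(ids)
  src <- table$pairs[, "source"]
  hit <- uids %in% src
  mapped <- sort(unique(table$pairs[src %in% uids, "canonical"]))
  counts <- table(src[src %in% uids[hit]])
  multi <- counts[counts >= 2L]
  multi_hit <- data.frame(source_id = as.character(names(multi)),
                          n_targets = as.integer(multi),
                          stringsAsFactors = FALSE, row.names = NULL)
  multi_hit <- multi_hit[order(multi_hit$source_id), , drop = FALSE]
  rownames(multi_hit) <- NULL
  structure(list(mapped = mapped,
                 unmapped = uids[!hit],
                 multi_hit = multi_hit,
                 input_count = length(ids),
                 mapped_count = length(mapped)),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report> %d input ids -> %d canonical ids (%d unmapped, %d multi-target)\n",
              x$input_count, x$mapped_count, length(x$unmapped), nrow(x$multi_hit)))
  invisible(x)
}

#' Serialize a mapping report to JSON
#'
#' @param report A `mapping_report` from [map_ids()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
mapping_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mapping_report"))
  obj <- list(input_count = report$input_count,
              mapped_count = report$mapped_count,
              mapped = as.list(report$mapped),
              unmapped = as.list(report$unmapped),
              multi_hit = report$multi_hit)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(js, con, sep = "\n")
  invisible(js)
}
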