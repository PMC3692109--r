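#' Construct a gene set
#'
#' A gene set is the unit of enrichment analysis: a named, non-empty set of
#' canonical gene identifiers. Duplicate members are removed (first
#' occurrence kept), so membership has true set semantics. Identifier
#' comparison throughout the package is exact and case-sensitive.
#'
#' @param set_id Non-empty unique identifier of the set.
#' @param name Free-text description.
#' @param genes Character vector of member gene identifiers; must be
#'   non-empty after removing duplicates.
#' @return An object of class `gene_set` with fields `set_id`, `name`,
#'   `genes`.
#' @examples
#' gene_set("S1", "toy set", c("G1", "G2", "G2"))
#' @export
gene_set <- function(set_id, name = "", genes = character()) {
  stopifnot(is.character(set_id), length(set_id) == 1L)
  if (!nzchar(set_id)) stop("gene set id must be non-empty")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("gene set '", set_id, "' has no members")
  structure(list(set_id = set_id, name = as.character(name)[1L], genes = genes),
            class = "gene_set")
}

#' Construct a gene-set collection
#'
#' An ordered list of [gene_set()] objects with pairwise-distinct ids.
#' Iteration order is the input order and is preserved by all operations.
#'
#' @param sets List of `gene_set` objects (or lists coercible to them).
#' @param source_label Label describing the provenance of the collection.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets = list(), source_label = "") {
  sets <- lapply(sets, function(s) {
    if (inherits(s, "gene_set")) s else gene_set(s$set_id, s$name %||% "", s$genes)
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  structure(list(sets = sets, source_label = as.character(source_label)[1L]),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes)%s\n", x$set_id, length(x$genes),
              if (nzchar(x$name)) paste0(": ", x$name) else ""))
  invisible(x)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets%s\n", length(x$sets),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  if (length(x$sets)) {
    sizes <- vapply(x$sets, function(s) length(s$genes), 0L)
    cat(sprintf("  set sizes: min %d / median %g / max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' Set ids of a collection
#' @param collection A `gene_set_collection`.
#' @return Character vector of set ids in collection order.
#' @export
set_ids <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  unname(vapply(collection$sets, `[[`, "", "set_id"))
}

#' Read a GMT gene-set file
#'
#' GMT is the de-facto tab-separated exchange format for gene-set
#' collections: each line is `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' The second field is always a description, never a gene. Trailing empty
#' fields are ignored; duplicate genes within a line are deduplicated; line
#' order becomes collection order. Blank lines are skipped.
#'
#' @param path Path to a GMT file.
#' @param source_label Optional provenance label (defaults to the file name).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    # trailing empty fields (e.g. from spreadsheet export) carry no genes
    while (length(f) > 0L && !nzchar(f[length(f)])) f <- f[-length(f)]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d of '%s': expected >= 3 tab-separated fields, got %d",
                   i, path, length(f)))
    }
    sets[[length(sets) + 1L]] <- gene_set(f[1L], f[2L], f[-(1:2)])
  }
  gene_set_collection(sets, source_label = source_label)
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trip guarantee: `read_gmt(write_gmt(x, p))` reproduces `x` exactly
#' (ids, descriptions, membership and order). Lines end in LF.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$set_id, s$name, s$genes), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(unname(lines), con, sep = "\n")
  invisible(path)
}

#' Read or write a plain gene list (one identifier per line)
#'
#' Blank lines and surrounding whitespace are ignored on read; order is
#' preserved and duplicates are kept (downstream set operations deduplicate).
#'
#' @param path File path.
#' @return `read_gene_list`: character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param ids Character vector of identifiers to write.
#' @return `write_gene_list`: `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(ids)) writeLines(as.character(ids), con, sep = "\n")
  invisible(path)
}

#' Restrict a collection to a reference universe and size range
#'
#' Standard ORA preprocessing: every set is intersected with the reference
#' gene universe, and sets whose intersected size falls outside
#' `[min_size, max_size]` are dropped. Order is preserved. The operation is
#' idempotent and its output membership is always a subset of `reference`.
#'
#' @param collection A [gene_set_collection()].
#' @param reference Character vector: the reference gene universe.
#' @param min_size,max_size Inclusive bounds on the intersected set size.
#'   Defaults 3 and 2000 are conventional ORA bounds.
#' @return A filtered [gene_set_collection()].
#' @export
filter_collection <- function(collection, reference, min_size = 3L, max_size = 2000L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) stop("reference universe is empty")
  if (min_size < 1L) stop("min_size must be >= 1")
  if (max_size < min_size) stop("max_size must be >= min_size")
  kept <- list()
  for (s in collection$sets) {
    g <- s$genes[s$genes %in% reference]
    if (length(g) >= min_size && length(g) <= max_size) {
      kept[[length(kept) + 1L]] <- gene_set(s$set_id, s$name, g)
    }
  }
  gene_set_collection(kept, source_label = collection$source_label)
}
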