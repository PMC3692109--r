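#' Upper-tail hypergeometric p-value
#'
#' Probability of observing an overlap of at least `k` genes between an
#' input list of size `n` and a category of size `m`, when the list is drawn
#' uniformly without replacement from a reference universe of size `N`:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,m)} \frac{\binom{m}{i}\binom{N-m}{n-i}}{\binom{N}{n}}}
#' This equals the one-sided Fisher exact test on the 2x2 table
#' `(k, n-k, m-k, N-n-m+k)`. Computation is log-space via [stats::phyper()],
#' so extreme tails do not underflow to zero for universes up to at least
#' 1e5 genes. All arguments are vectorised and recycled.
#'
#' @param k Overlap count, `0 <= k <= min(n, m)`.
#' @param n Input-list size within the reference.
#' @param m Category size within the reference.
#' @param N Reference-universe size, `N >= max(n, m)`.
#' @return Numeric vector of exact upper-tail probabilities in \[0, 1\].
#' @examples
#' hypergeom_pvalue(3, 4, 5, 10)   # 11/42
#' @export
hypergeom_pvalue <- function(k, n, m, N) {
  v <- cbind(k = k, n = n, m = m, N = N)  # recycle
  k <- v[, "k"]; n <- v[, "n"]; m <- v[, "m"]; N <- v[, "N"]
  if (any(v != floor(v))) stop("k, n, m, N must be integers")
  if (any(k < 0 | n < 0 | m < 0 | N < 0)) stop("counts must be non-negative")
  if (any(n > N | m > N)) stop("n and m must not exceed N")
  if (any(k > pmin(n, m))) stop("k must not exceed min(n, m)")
  p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  unname(pmin(pmax(p, 0), 1))
}

#' Enrichment ratio (observed / expected overlap)
#'
#' The expected overlap under the hypergeometric null is `n * m / N`; the
#' enrichment ratio is `k / (n * m / N) = k * N / (n * m)`. A ratio of 1
#' means the observed overlap equals its expectation.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of ratios (0 when `k = 0`).
#' @export
enrichment_ratio <- function(k, n, m, N) {
  v <- cbind(k = k, n = n, m = m, N = N)
  k <- v[, "k"]; n <- v[, "n"]; m <- v[, "m"]; N <- v[, "N"]
  if (any(n * m == 0)) stop("n and m must be positive")
  unname(k * N / (n * m))
}

# the five supported corrections, in canonical order
ora_adjust_methods <- c("bonferroni", "holm", "hochberg", "bh", "by")

#' Adjust p-values for multiple testing
#'
#' Supports the five standard corrections: Bonferroni, Holm (step-down),
#' Hochberg (step-up), Benjamini-Hochberg FDR and Benjamini-Yekutieli FDR.
#' Values are returned in the input order, clipped to \[0, 1\], with each
#' method's step-up/step-down monotonicity enforced; every method satisfies
#' `p_adj >= p_raw` elementwise.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`, `"bh"`,
#'   `"by"`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(pvals, method = "bh") {
  method <- tolower(as.character(method)[1L])
  if (!method %in% ora_adjust_methods) {
    stop("unknown adjustment method '", method, "'; valid methods: ",
         paste(ora_adjust_methods, collapse = ", "))
  }
  pvals <- as.numeric(pvals)
  if (length(pvals) == 0L) return(numeric())
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = c(bonferroni = "bonferroni", holm = "holm",
                             hochberg = "hochberg", bh = "BH", by = "BY")[[method]])
}

#' Enrichment analysis parameters
#'
#' @param adjust_method Multiple-testing correction, see [adjust_pvalues()].
#' @param significance_cutoff Threshold applied to adjusted p-values,
#'   in (0, 1\].
#' @param min_size,max_size Category size bounds after intersection with the
#'   reference (see [filter_collection()]).
#' @param top_k Number of rows shown by the Top-K summary.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(adjust_method = "bh", significance_cutoff = 0.05,
                              min_size = 3L, max_size = 2000L, top_k = 10L) {
  adjust_method <- tolower(as.character(adjust_method)[1L])
  if (!adjust_method %in% ora_adjust_methods) {
    stop("unknown adjustment method '", adjust_method, "'; valid methods: ",
         paste(ora_adjust_methods, collapse = ", "))
  }
  if (!(significance_cutoff > 0 && significance_cutoff <= 1)) {
    stop("significance_cutoff must be in (0, 1]")
  }
  if (top_k < 1L) stop("top_k must be >= 1")
  structure(list(adjust_method = adjust_method,
                 significance_cutoff = as.numeric(significance_cutoff),
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 top_k = as.integer(top_k)),
            class = "enrichment_params")
}

#' Over-representation analysis of a gene list
#'
#' Tests each category of a collection for over-representation in the input
#' list relative to a reference universe. Input genes outside the reference
#' are dropped with a warning (the input list is expected to be a subset of
#' the universe it was drawn from, e.g. all genes of the assayed network or
#' platform). Categories are first restricted to the reference and
#' size-filtered via [filter_collection()]; the multiple-testing correction
#' is then applied over exactly the categories tested. Rows are sorted by
#' raw p-value, ties broken by set id, so output is deterministic.
#'
#' @param input_genes Character vector: the gene list of interest.
#' @param reference_genes Character vector: the reference universe.
#' @param collection A [gene_set_collection()].
#' @param params An [enrichment_params()] object.
#' @return An object of class `enrichment_report`: a list with `table` (data
#'   frame with columns `set_id`, `name`, `k`, `n`, `m`, `N`, `expected`,
#'   `ratio`, `p_raw`, `p_adj`, `significant`), `params`, `n` and `N`.
#' @examples
#' coll <- gene_set_collection(list(gene_set("S1", "toy", paste0("g", 1:4))))
#' ref <- paste0("g", 1:20)
#' rep <- run_ora(paste0("g", 1:5), ref, coll, enrichment_params())
#' rep$table
#' @export
run_ora <- function(input_genes, reference_genes, collection,
                    params = enrichment_params()) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(params, "enrichment_params"))
  reference <- unique(as.character(reference_genes))
  if (length(reference) < 2L) stop("reference universe must contain at least 2 genes")
  input <- unique(as.character(input_genes))
  outside <- setdiff(input, reference)
  if (length(outside)) {
    warning(length(outside), " input gene(s) not in the reference universe were dropped")
    input <- intersect(input, reference)
  }
  if (length(input) == 0L) stop("no input genes remain after restriction to the reference")

  filtered <- filter_collection(collection, reference,
                                min_size = params$min_size,
                                max_size = params$max_size)
  n <- length(input)
  N <- length(reference)
  if (length(filtered$sets) == 0L) {
    tab <- data.frame(set_id = character(), name = character(), k = integer(),
                      n = integer(), m = integer(), N = integer(),
                      expected = numeric(), ratio = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      significant = integer(), stringsAsFactors = FALSE)
  } else {
    m <- vapply(filtered$sets, function(s) length(s$genes), 0L)
    k <- vapply(filtered$sets, function(s) sum(s$genes %in% input), 0L)
    p_raw <- hypergeom_pvalue(k, n, m, N)
    p_adj <- adjust_pvalues(p_raw, params$adjust_method)
    tab <- data.frame(set_id = set_ids(filtered),
                      name = vapply(filtered$sets, `[[`, "", "name"),
                      k = k, n = n, m = m, N = N,
                      expected = n * m / N,
                      ratio = enrichment_ratio(k, n, m, N),
                      p_raw = p_raw, p_adj = p_adj,
                      significant = as.integer(p_adj < params$significance_cutoff),
                      stringsAsFactors = FALSE, row.names = NULL)
    tab <- tab[order(tab$p_raw, tab$set_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, params = params, n = n, N = N),
            class = "enrichment_report")
}

#' Top-K most enriched categories
#'
#' Returns the first `min(k, nrow)` rows of the (already sorted) report,
#' ignoring the significance cutoff — a quick overview of the most enriched
#' categories that helps choose an appropriate significance level.
#'
#' @param report An `enrichment_report` from [run_ora()].
#' @param k Number of rows to keep (default 10).
#' @return An `enrichment_report` containing at most `k` rows.
#' @export
top_k <- function(report, k = 10L) {
  stopifnot(inherits(report, "enrichment_report"))
  if (k < 1L) stop("k must be >= 1")
  out <- report
  out$table <- head(report$table, k)
  out
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> %d categories tested; input n = %d, universe N = %d\n",
              nrow(x$table), x$n, x$N))
  cat(sprintf("  correction: %s; cutoff: %g; significant: %d\n",
              x$params$adjust_method, x$params$significance_cutoff,
              sum(x$table$significant)))
  if (nrow(x$table)) {
    print(head(x$table[, c("set_id", "k", "m", "ratio", "p_raw", "p_adj")], 10L),
          digits = 4)
  }
  invisible(x)
}

#' @export
summary.enrichment_report <- function(object, ...) {
  cat(sprintf("ORA over %d categories (input %d genes, universe %d genes)\n",
              nrow(object$table), object$n, object$N))
  cat(sprintf("%d significant at %s < %g\n", sum(object$table$significant),
              object$params$adjust_method, object$params$significance_cutoff))
  invisible(object$table)
}

#' Write an enrichment report as TSV or JSON
#'
#' The TSV carries the columns `set_id`, `name`, `k`, `n`, `m`, `N`,
#' `expected`, `ratio`, `p_raw`, `p_adj`, `significant` with a header line;
#' the JSON form mirrors the same rows plus the run parameters.
#'
#' @param report An `enrichment_report`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "enrichment_report"))
  format <- match.arg(format)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    tab <- report$table
    num <- vapply(tab, is.double, TRUE)
    tab[num] <- lapply(tab[num], function(x) sprintf("%.6g", x))
    lines <- c(paste(names(tab), collapse = "\t"),
               if (nrow(tab)) do.call(paste, c(unname(tab), sep = "\t")))
    writeLines(lines, con, sep = "\n")
  } else {
    obj <- list(params = unclass(report$params), n = report$n, N = report$N,
                rows = report$table)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), con, sep = "\n")
  }
  invisible(path)
}
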