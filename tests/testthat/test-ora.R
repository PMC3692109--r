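test_that("hypergeometric tail probabilities match exhaustive enumeration", {
  # frozen small cases, expected values from enumerating all draws
  expect_equal(hypergeom_pvalue(0, 4, 5, 10), 1)
  expect_equal(hypergeom_pvalue(3, 4, 5, 10), 11 / 42, tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)

  # a sweep of small geometries against the enumeration oracle
  for (N in c(6L, 9L)) {
    for (n in 1:(N - 1)) for (m in 1:(N - 1)) for (k in 0:min(n, m)) {
      expect_equal(hypergeom_pvalue(k, n, m, N), hyper_oracle(k, n, m, N),
                   tolerance = 1e-12)
    }
  }

  # stable far into the tail of a large universe: for k = n = m the upper
  # tail is exactly 1 / C(N, n)
  expect_gt(hypergeom_pvalue(50, 50, 50, 1e5), 0)
  expect_equal(log(hypergeom_pvalue(50, 50, 50, 1e5)), -lchoose(1e5, 50),
               tolerance = 1e-10)

  expect_error(hypergeom_pvalue(5, 4, 5, 10), "min")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "exceed")
  expect_error(hypergeom_pvalue(0.5, 4, 5, 10), "integer")
})

test_that("one-sided Fisher on the 2x2 table equals the hypergeometric tail", {
  set.seed(421)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    n <- sample(1:(N - 1), 1)
    m <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, m), 1)
    if (N - n - m + k < 0) next
    tab <- matrix(c(k, n - k, m - k, N - n - m + k), 2)
    expect_equal(hypergeom_pvalue(k, n, m, N),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("enrichment ratio is observed over expected overlap", {
  expect_equal(enrichment_ratio(3, 4, 5, 10), 1.5)
  expect_equal(enrichment_ratio(0, 4, 5, 10), 0)
  expect_equal(enrichment_ratio(2, 4, 5, 10), 1)  # k = n m / N exactly
  expect_error(enrichment_ratio(0, 0, 5, 10), "positive")
})

test_that("the five corrections match their defining formulas", {
  expect_equal(adjust_pvalues(0.2, "holm"), 0.2)  # single test identity
  expect_equal(adjust_pvalues(c(0.01, 0.2, 0.4), "bonferroni"),
               c(0.03, 0.6, 1.0))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03, 0.002), "bh"),
               c(0.02, 0.04, 0.04, 0.008))

  set.seed(422)
  for (i in 1:40) {
    p <- runif(sample(1:30, 1))
    for (method in c("bonferroni", "holm", "hochberg", "bh", "by")) {
      got <- adjust_pvalues(p, method)
      expect_equal(got, padj_oracle(p, method), tolerance = 1e-12)
      expect_true(all(got >= p - 1e-15))          # p_adj >= p_raw
      # permutation equivariance
      perm <- sample(length(p))
      expect_equal(adjust_pvalues(p[perm], method), got[perm],
                   tolerance = 1e-12)
    }
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "holm") - 1e-15))
    expect_true(all(adjust_pvalues(p, "bh") <=
                      adjust_pvalues(p, "by") + 1e-15))
  }

  expect_error(adjust_pvalues(0.5, "fdr"), "valid methods")
  expect_error(adjust_pvalues(1.2, "bh"), "\\[0, 1\\]")
})

test_that("run_ora computes counts inside the reference universe", {
  ref <- paste0("g", 1:20)
  coll <- gene_set_collection(list(gene_set("S1", "four", paste0("g", 1:4))))
  rep <- run_ora(paste0("g", 1:5), ref, coll, enrichment_params())
  row <- rep$table[1L, ]
  expect_equal(row$k, 4L)
  expect_equal(row$n, 5L)
  expect_equal(row$m, 4L)
  expect_equal(row$N, 20L)
  expect_equal(row$ratio, 4)
  expect_equal(row$p_raw, 16 / 15504, tolerance = 1e-12)  # enumeration of C(20,5)

  # category disjoint from the input: upper tail at k = 0 is exactly 1
  coll2 <- gene_set_collection(list(gene_set("D", "", paste0("g", 15:18))))
  rep2 <- run_ora(paste0("g", 1:5), ref, coll2, enrichment_params())
  expect_equal(rep2$table$k, 0L)
  expect_equal(rep2$table$p_raw, 1)

  # two identical categories: same p_raw, bonferroni doubles (capped at 1)
  coll3 <- gene_set_collection(list(gene_set("A", "", paste0("g", 1:4)),
                                    gene_set("B", "", paste0("g", 1:4))))
  rep3 <- run_ora(paste0("g", 1:5), ref, coll3,
                  enrichment_params(adjust_method = "bonferroni"))
  expect_equal(rep3$table$p_raw[1L], rep3$table$p_raw[2L])
  expect_equal(rep3$table$p_adj, pmin(1, 2 * rep3$table$p_raw))
  expect_identical(rep3$table$set_id, c("A", "B"))  # tie broken by set_id

  # genes outside the reference are dropped with a warning
  expect_warning(run_ora(c("g1", "g2", "g3", "zz"), ref, coll,
                         enrichment_params()), "dropped")
  expect_error(suppressWarnings(run_ora("zz", ref, coll, enrichment_params())),
               "no input genes")
  expect_error(run_ora("g1", "g1", coll, enrichment_params()), "at least 2")
})

test_that("top_k returns the smallest raw p-values, cutoff ignored", {
  set.seed(423)
  ref <- sprintf("g%03d", 1:100)
  input <- ref[1:20]
  sets <- lapply(1:15, function(i) {
    gene_set(sprintf("S%02d", i), "", sample(ref, 10))
  })
  rep <- run_ora(input, ref, gene_set_collection(sets),
                 enrichment_params(significance_cutoff = 1e-6))
  top <- top_k(rep, 10)
  expect_equal(nrow(top$table), 10L)
  expect_equal(top$table$p_raw, sort(rep$table$p_raw)[1:10])
  expect_true(!is.unsorted(top$table$p_raw))
  # k larger than the report returns everything
  expect_equal(nrow(top_k(rep, 100)$table), 15L)
  small <- top_k(rep, 3)
  expect_equal(nrow(small$table), 3L)
  expect_error(top_k(rep, 0), ">= 1")
})

test_that("enrichment reports serialize to TSV and JSON", {
  ref <- paste0("g", 1:20)
  coll <- gene_set_collection(list(gene_set("S1", "four", paste0("g", 1:4))))
  rep <- run_ora(paste0("g", 1:5), ref, coll, enrichment_params())
  f <- tempfile(fileext = ".tsv")
  write_enrichment(rep, f, "tsv")
  tab <- utils::read.delim(f)
  expect_identical(names(tab),
                   c("set_id", "name", "k", "n", "m", "N", "expected",
                     "ratio", "p_raw", "p_adj", "significant"))
  expect_equal(tab$k, 4L)
  fj <- tempfile(fileext = ".json")
  write_enrichment(rep, fj, "json")
  js <- jsonlite::fromJSON(fj)
  expect_equal(js$rows$p_raw, rep$table$p_raw, tolerance = 1e-12)
})
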