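# DE set concordance, Venn partitioning, Fisher enrichment, ddCt.

mk_de <- function(gene_id, logFC, FDR, PValue = FDR) {
  tibble::tibble(gene_id = gene_id, logFC = logFC, PValue = PValue,
                 FDR = FDR)
}

test_that("significant_genes filters on FDR and direction", {
  tab <- mk_de(c("a", "b", "c", "d"),
               logFC = c(-1.2, 1.2, -0.5, -2),
               FDR = c(0.01, 0.01, 0.2, 0.049))
  expect_setequal(significant_genes(tab, 0.05, "down"), c("a", "d"))
  expect_setequal(significant_genes(tab, 0.05, "up"), "b")
  expect_setequal(significant_genes(tab, 0.05, "any"), c("a", "b", "d"))
  expect_error(significant_genes(tab, 1.5), "fdr_threshold")

  # matches a row-by-row brute-force filter on random tables
  set.seed(31)
  for (i in 1:5) {
    n <- 200
    tab <- mk_de(sprintf("g%03d", 1:n), rnorm(n), runif(n))
    manual <- tab$gene_id[vapply(seq_len(n), function(j) {
      tab$FDR[j] < 0.05 && tab$logFC[j] < 0
    }, logical(1))]
    expect_setequal(significant_genes(tab, 0.05, "down"), manual)
  }
})

test_that("consistent_genes requires shared significance and concordant sign", {
  t1 <- mk_de(c("a", "b", "c", "d"), c(-2, -1, -1, -1),
              c(0.01, 0.01, 0.20, 0.01))
  t2 <- mk_de(c("a", "b", "c", "d"), c(-1.5, 1, -2, -1),
              c(0.01, 0.01, 0.01, 0.30))
  got <- consistent_genes(list(t1, t2), 0.05, "down", mode = "strict")
  expect_setequal(got, "a")         # b flips sign; c, d miss significance once
  len <- consistent_genes(list(t1, t2), 0.05, "down", mode = "lenient")
  expect_setequal(len, c("a", "c", "d"))  # significant in >= 1, concordant

  # a gene absent from one table is treated as not significant there
  t3 <- mk_de(c("a", "b"), c(-2, -1), c(0.01, 0.01))
  expect_message(got3 <- consistent_genes(list(t1, t3), 0.05, "down"),
                 "absent")
  expect_setequal(got3, c("a", "b"))
  expect_error(consistent_genes(list(t1)), "two")
})

test_that("consistent_genes equals set algebra over significant_genes", {
  set.seed(8)
  for (i in 1:5) {
    genes <- sprintf("g%03d", 1:300)
    tabs <- lapply(1:3, function(j) mk_de(genes, rnorm(300), runif(300, 0, 0.2)))
    got <- consistent_genes(tabs, 0.05, "any", mode = "strict")
    sig <- lapply(tabs, significant_genes, fdr_threshold = 0.05)
    inter <- Reduce(intersect, sig)
    sgn <- sapply(tabs, function(t) sign(t$logFC[match(inter, t$gene_id)]))
    manual <- inter[apply(matrix(sgn, nrow = length(inter)), 1,
                          function(s) all(s == s[1]) && s[1] != 0)]
    expect_setequal(got, manual)
    # subset property: consistent genes are significant in every table
    for (s in sig) expect_true(all(got %in% s))
  }
})

test_that("venn_partition counts every disjoint membership region", {
  vp <- venn_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                            C = "c"))
  get <- function(r) vp$count[vp$region == r]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("C"), 0)
  expect_equal(get("A&B"), 1)
  expect_equal(get("A&B&C"), 1)
  expect_equal(sum(vp$count), 4)  # |union|

  # all sets empty / identical
  expect_true(all(venn_partition(list(A = character(), B = character()))$count == 0))
  same <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$region == "A&B"], 2)
  expect_equal(sum(same$count), 2)
  expect_error(venn_partition(list(c("a"))), "named")
})

test_that("venn regions are disjoint, sum to the union and marginalize to set sizes", {
  set.seed(12)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) {
      unique(sample(sprintf("g%02d", 1:40), sample(5:25, 1)))
    })
    names(sets) <- c("A", "B", "C")
    vp <- venn_partition(sets)
    expect_equal(sum(vp$count), length(unique(unlist(sets))))
    oracle <- oracle_venn(sets)
    for (r in seq_len(nrow(vp))) {
      expected <- if (vp$region[r] %in% names(oracle)) {
        oracle[[vp$region[r]]]
      } else {
        0L
      }
      expect_equal(vp$count[r], expected)
    }
    # marginal: sum over regions containing S equals |S|
    for (s in names(sets)) {
      in_s <- vapply(vp$sets, function(m) s %in% m, logical(1))
      expect_equal(sum(vp$count[in_s]), length(sets[[s]]))
    }
  }
})

test_that("fisher_enrichment equals the hypergeometric tail", {
  # forced case: the study set IS the term -> p = 1/C(20,5)
  univ <- sprintf("u%02d", 1:20)
  e <- fisher_enrichment(univ[1:5], list(T1 = univ[1:5]), universe = univ)
  expect_equal(e$p, 1 / 15504, tolerance = 1e-12)
  expect_equal(e$k, 5L)

  # term = universe: degenerate table, p = 1
  e2 <- fisher_enrichment(univ[1:5], list(T1 = univ), universe = univ)
  expect_equal(e2$p, 1)

  # random instances against the explicit tail-sum oracle
  set.seed(77)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    genes <- sprintf("g%03d", 1:N)
    term <- sample(genes, K)
    study <- sample(genes, n)
    e3 <- fisher_enrichment(study, list(T = term), universe = genes)
    k <- length(intersect(term, study))
    expect_equal(e3$p, oracle_hyper_tail(k, K, n, N), tolerance = 1e-10)
    expect_equal(e3$k, k)
    # cross-check against the standard one-sided Fisher exact test
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                             alternative = "greater")
    expect_equal(e3$p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("enrichment handles universes, empty terms and BH adjustment", {
  genes <- sprintf("g%03d", 1:100)
  ann <- list(T1 = genes[1:20], T2 = genes[21:30], T3 = c("zzz1", "zzz2"))
  expect_message(e <- fisher_enrichment(genes[1:10], ann, universe = genes),
                 "empty")
  expect_setequal(e$term_id, c("T1", "T2"))
  # BH q is monotone non-decreasing in the rank of p
  expect_true(all(diff(e$q[order(e$p)]) >= -1e-15))
  expect_equal(e$q, stats::p.adjust(e$p, "BH"), tolerance = 1e-15)
  # study genes outside the universe are dropped with a message
  expect_message(fisher_enrichment(c(genes[1:5], "outsider"), ann,
                                   universe = genes), "outside")
  # default universe is the DE table when supplied
  tab <- mk_de(genes, rnorm(100), runif(100))
  e4 <- fisher_enrichment(genes[1:10], ann["T1"], de_table = tab)
  expect_equal(e4$N, 100L)
})

test_that("term dot metrics follow the dot-plot definitions", {
  tab <- mk_de(c("g1", "g2", "g3", "g4"),
               logFC = c(-1, -3, 2, 0.5),
               FDR = c(0.01, 0.02, 0.5, 0.9))
  ann <- list(TA = c("g1", "g2"), TB = c("g3", "g4"), TC = c("g2", "g3"))
  m <- term_dot_metrics(tab, ann, fdr_threshold = 0.05)
  # both TA genes significant: mean logFC -2, whole term altered
  expect_equal(m$mean_logfc[m$term_id == "TA"], -2)
  expect_equal(m$prop_altered[m$term_id == "TA"], 1)
  # no significant TB gene: proportion 0, mean omitted
  expect_equal(m$prop_altered[m$term_id == "TB"], 0)
  expect_true(is.na(m$mean_logfc[m$term_id == "TB"]))
  expect_equal(m$prop_altered[m$term_id == "TC"], 0.5)

  set.seed(5)
  tab2 <- mk_de(sprintf("g%03d", 1:200), rnorm(200), runif(200))
  ann2 <- list(T = sample(tab2$gene_id, 50))
  m2 <- term_dot_metrics(tab2, ann2)
  expect_true(m2$prop_altered >= 0 && m2$prop_altered <= 1)
})

test_that("ddCt fold changes satisfy the defining identities", {
  # sample identical to control
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1)
  # ddCt = 2 halves expression twice
  expect_equal(ddct_fold_change(22, 18, 20, 18), 0.25)
  # global Ct shift invariance
  expect_equal(ddct_fold_change(22 + 3, 18 + 3, 20 + 3, 18 + 3),
               ddct_fold_change(22, 18, 20, 18))
  # replicate Ct vectors are averaged
  expect_equal(ddct_fold_change(c(21, 23), 18, 20, 18), 0.25)
  expect_error(ddct_fold_change(NA, 18, 20, 18), "finite")
})

test_that("DE TSV and annotation round trips preserve content", {
  de <- generate_de_tables(n_genes = 300, contrasts = "c1", n_terms = 5,
                           term_size_range = c(5, 20), seed = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de$tables$c1, path)
  back <- read_de_table(path, contrast = "c1")
  expect_equal(back$gene_id, de$tables$c1$gene_id)
  expect_equal(back$logFC, de$tables$c1$logFC, tolerance = 1e-12)
  apath <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(de$annotation, apath)
  aback <- read_annotation(apath)
  expect_equal(aback$term_id, de$annotation$term_id)
})
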