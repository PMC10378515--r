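# Gene classification, N-1 chi-squared, identical/similar matching and
# entome graph export.

test_that("gene-set classification tallies classes over an explicit denominator", {
  genes <- synthetic_classified_gene_set()
  expect_length(genes, 317)
  cls <- classify_gene_set(genes, by = "tissue")
  expect_equal(cls$count[cls$class == "immune_inflammatory"], 28L)
  expect_equal(cls$pct[cls$class == "immune_inflammatory"], "8.8")
  expect_equal(sum(cls$proportion), 1, tolerance = 1e-12)
  expect_equal(sum(cls$count), 317L)
  # empty set: all-zero counts
  empty <- classify_gene_set(list(), by = "tissue", denominator = 0)
  expect_true(all(empty$count == 0L))
  # random catalogs agree with a naive tally
  set.seed(5)
  for (k in 1:5) {
    tc <- qual_enums()$tissue_class
    picks <- sample(tc, 30, replace = TRUE)
    gs <- lapply(seq_along(picks), function(i) {
      gene_record(paste0("G", i), list(), tissue_class = picks[i],
                  association_strength = "weak")
    })
    got <- classify_gene_set(gs, "tissue")
    expect_equal(got$count, as.integer(table(factor(picks, levels = tc))))
    expect_equal(got$proportion, got$count / 30)
  }
  # missing class errors name the gene
  g_bad <- toy_catalog()$REL1
  g_bad$tissue_class <- ""
  expect_error(classify_gene_set(list(g_bad)), "REL1")
})

test_that("N-1 chi-squared equals Pearson scaled by (N-1)/N", {
  res <- n1_chi_squared(5, 50, 5, 50)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
  set.seed(99)
  for (k in 1:1000) {
    n_a <- sample(5:400, 1)
    n_b <- sample(5:400, 1)
    a <- sample(0:n_a, 1)
    b <- sample(0:n_b, 1)
    if ((a + b) == 0 || (n_a - a + n_b - b) == 0) next
    got <- n1_chi_squared(a, n_a, b, n_b)
    tab <- matrix(c(a, n_a - a, b, n_b - b), nrow = 2)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    N <- n_a + n_b
    expect_equal(got$chi2_pearson, unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(got$chi2, unname(ref$statistic) * (N - 1) / N,
                 tolerance = 1e-10)
    # invariant under group swap and success/failure swap
    sw <- n1_chi_squared(b, n_b, a, n_a)
    expect_equal(sw$chi2, got$chi2, tolerance = 1e-12)
    fl <- n1_chi_squared(n_a - a, n_a, n_b - b, n_b)
    expect_equal(fl$chi2, got$chi2, tolerance = 1e-12)
  }
})

test_that("the N-1 correction vanishes in the large-N limit", {
  ratios <- sapply(c(1e2, 1e4, 1e6), function(scale) {
    r <- n1_chi_squared(round(0.3 * scale), scale,
                        round(0.4 * scale), scale)
    r$chi2 / r$chi2_pearson
  })
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[3], 1, tolerance = 1e-5)
})

test_that("zero-margin tables are rejected with an explicit message", {
  expect_error(n1_chi_squared(0, 10, 0, 10), "zero margin")
  expect_error(n1_chi_squared(10, 10, 10, 10), "zero margin")
})

test_that("the published gene lists intersect in exactly six identical genes", {
  m <- match_gene_sets(gene_set_fixture("eds"), gene_set_fixture("covid"))
  expect_equal(m$identical,
               sort(c("F2", "LIFR", "NLRP3", "STAT1", "TICAM1",
                      "TNFRSF13B")))
  got_pairs <- paste(m$similar$symbol_a, m$similar$symbol_b, sep = "/")
  for (pair in c("ADAMTS2/ADAMTS13", "TMPRSS6/TMPRSS2", "FOXP2/FOXP4",
                 "NFKB2/NFKB1", "C1R/C3", "POLG/POLD4", "IKBKAP/IKBKG",
                 "NDUFA11/NDUFAF7", "WNT10A/WNT3", "SLC6A2/SLC6A20",
                 "RBM20/RBM15", "ZNF469/ZNF275", "PIK3R1/PIK3C3")) {
    expect_true(pair %in% got_pairs, info = pair)
  }
  # identical pairs never reappear as similar pairs
  expect_false(any(m$similar$symbol_a %in% m$identical))
})

test_that("gene-set matching is symmetric and idempotent on itself", {
  a <- c("ADAMTS2", "COL5A1", "WNT10A")
  b <- c("ADAMTS13", "COL5A1", "WNT3")
  m_ab <- match_gene_sets(a, b)
  m_ba <- match_gene_sets(b, a)
  expect_equal(m_ab$identical, m_ba$identical)
  expect_equal(
    sort(paste(m_ab$similar$symbol_a, m_ab$similar$symbol_b)),
    sort(paste(m_ba$similar$symbol_b, m_ba$similar$symbol_a))
  )
  self <- match_gene_sets(a, a)
  expect_equal(self$identical, sort(normalize_symbol(a)))
  expect_equal(nrow(self$similar), 0)
  one <- match_gene_sets("ADAMTS2", "ADAMTS13")
  expect_equal(one$similar$family_root, "ADAMTS")
})

test_that("alias normalization recovers published symbol variants", {
  expect_equal(normalize_symbol("T1CAM1"), "TICAM1")
  expect_equal(normalize_symbol(" col3a1 "), "COL3A1")
  expect_equal(normalize_symbol("IF1H1"), "IFIH1")
})

test_that("class-by-class comparison flags the immune/inflammatory excess", {
  eds_set <- synthetic_classified_gene_set()
  covid_set <- synthetic_classified_gene_set(c(
    immune_inflammatory = 26, neural = 26, cardiovascular = 10,
    clotting = 4, skin = 4, joint = 2, renal_vascular = 4,
    autonomic_other = 2, muscle = 3, bone = 1
  ))
  cmp <- compare_gene_sets(eds_set, covid_set, by = "tissue")
  expect_equal(cmp$n_b, 82)
  row <- cmp$table[cmp$table$class == "immune_inflammatory", ]
  expect_true(row$significant)
  ref <- n1_chi_squared(28, 317, 26, 82)
  expect_equal(row$chi2, ref$chi2)
})

test_that("entome graphs are tripartite, flag node genes, and round-trip", {
  catalog <- default_gene_catalog()
  genes <- catalog[c("COL3A1", "FLG", "POLG", "NLRP3")]
  mechanisms <- c("tissue_laxity", "immune_inflammatory", "autonomic")
  symptoms <- data.frame(
    symptom = c("joint pain", "brain fog", "rashes"),
    mechanisms = c("tissue_laxity", "autonomic", "immune_inflammatory"),
    freq = c(80, 83, 42)
  )
  g <- export_entome(unname(genes), mechanisms, symptoms)
  types <- igraph::V(g)$type
  expect_setequal(unique(types), c("gene", "mechanism", "symptom"))
  # every edge runs gene->mechanism or mechanism->symptom
  el <- igraph::as_data_frame(g, "edges")
  from_type <- types[match(el$from, igraph::V(g)$name)]
  to_type <- types[match(el$to, igraph::V(g)$name)]
  expect_true(all((from_type == "gene" & to_type == "mechanism") |
                    (from_type == "mechanism" & to_type == "symptom")))
  # minimal construction: 2 genes in, 3 symptoms out of one mechanism
  g2 <- export_entome(
    unname(catalog[c("COL5A1", "COL3A1")]), "tissue_laxity",
    data.frame(symptom = c("s1", "s2", "s3"),
               mechanisms = "tissue_laxity", freq = NA)
  )
  expect_equal(igraph::ecount(g2), 5)
  # empty symptom list: valid graph with no canopy edges
  g3 <- export_entome(unname(genes), mechanisms)
  expect_true(all(igraph::V(g3)$type != "symptom"))

  withr::with_tempdir({
    write_entome(g, "ent.graphml", "graphml")
    rt <- read_entome("ent.graphml", "graphml")
    expect_setequal(igraph::V(rt)$name, igraph::V(g)$name)
    expect_equal(igraph::as_data_frame(rt, "edges"),
                 igraph::as_data_frame(g, "edges"))
    write_entome(g, "ent.json", "json")
    rt2 <- read_entome("ent.json", "json")
    expect_setequal(igraph::V(rt2)$name, igraph::V(g)$name)
    expect_equal(sort(paste(igraph::as_data_frame(rt2, "edges")$from,
                            igraph::as_data_frame(rt2, "edges")$to)),
                 sort(paste(el$from, el$to)))
  })
})

test_that("multi-tag genes have the highest out-degree in the entome", {
  catalog <- default_gene_catalog()
  g <- export_entome(
    unname(catalog[c("COL3A1", "POLG", "MTHFR")]),
    c("tissue_laxity", "autonomic", "neuro", "mitochondrial")
  )
  expect_true("POLG" %in% entome_node_genes(g))
  # orphan mechanisms warn
  expect_warning(
    export_entome(unname(catalog["COL5A1"]),
                  c("tissue_laxity", "viral_response")),
    "orphan"
  )
})
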