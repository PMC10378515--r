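# Unit and property tests for the qualification engine.

within_consensus <- function(v, cls) {
  v$consensus_class <- cls
  v
}

test_that("molecular impact grading follows the substitution classes", {
  cfg <- qual_config()
  mk <- function(gene, p_change, consequence = "missense", cons = NA,
                 silico = NA) {
    variant_observation("v", gene, protein_change = p_change,
                        consequence = consequence,
                        conservation_score = cons, insilico_score = silico)
  }
  # conservative substitution in collagen V: grade 1
  expect_equal(grade_molecular_impact(mk("COL5A1", "p.(Ile588Leu)"),
                                      cfg)$points, 1L)
  # same-class Met->Val promoted to 2 by conservation/in-silico annotations
  v_plain <- mk("COL5A2", "p.(Met667Val)")
  v_annot <- mk("COL5A2", "p.(Met667Val)", cons = 0.95, silico = 0.85)
  expect_equal(grade_molecular_impact(v_plain, cfg)$points, 1L)
  res <- grade_molecular_impact(v_annot, cfg)
  expect_equal(res$points, 2L)
  expect_setequal(res$steps, c("D", "E", "F"))
  # termination in profilaggrin: grade 2
  expect_equal(grade_molecular_impact(
    variant_observation("v", "FLG", consequence = "nonsense"), cfg
  )$points, 2L)
  # cross-class substitutions: grade 2
  expect_equal(grade_molecular_impact(mk("VWF", "p.(Arg854Gln)"),
                                      cfg)$points, 2L)
  # glycine substitution in a fibrillar collagen: grade 2 even though
  # Gly and Pro share a physicochemical class
  expect_equal(grade_molecular_impact(mk("COL3A1", "p.(Gly588Ser)"),
                                      cfg)$points, 2L)
  expect_equal(grade_molecular_impact(mk("COL1A1", "p.(Pro500Gly)"),
                                      cfg)$points, 2L)
  # synonymous and benign-consensus changes: 0, never promoted
  expect_equal(grade_molecular_impact(
    variant_observation("v", "COL5A1", consequence = "synonymous",
                        conservation_score = 1, insilico_score = 1), cfg
  )$points, 0L)
  expect_equal(grade_molecular_impact(
    mk("VWF", "p.(Arg854Gln)") |> within_consensus("benign"), cfg
  )$points, 0L)
})

test_that("protein-change parsing accepts 1- and 3-letter forms and fails loudly", {
  expect_equal(parse_protein_change("p.(Ile588Leu)"),
               list(ref = "I", alt = "L", pos = 588L))
  expect_equal(parse_protein_change("p.I588L"),
               list(ref = "I", alt = "L", pos = 588L))
  expect_equal(parse_protein_change("p.Arg501Ter")$alt, "*")
  expect_equal(parse_protein_change("p.R501X")$alt, "*")
  expect_equal(parse_protein_change("R501*")$alt, "*")
  expect_error(parse_protein_change("p.splice?", "v9"), "v9")
  expect_error(
    grade_molecular_impact(
      variant_observation("vbad", "COL5A1", protein_change = "p.?",
                          consequence = "missense")
    ),
    "vbad"
  )
})

test_that("gene relevance maps mechanism tags to contexts", {
  catalog <- default_gene_catalog()
  expect_equal(assess_gene_relevance(catalog$POLG, "DD"), "relevant")
  expect_equal(assess_gene_relevance(catalog$POLG, "EDS"), "relevant")
  expect_equal(assess_gene_relevance(catalog$MTHFR, "EDS"),
               "other_disease")
  expect_equal(assess_gene_relevance(catalog$FLG, "EDS"),
               "synergistic_adjunct")
  expect_equal(assess_gene_relevance(catalog$FLG, "DD"), "other_disease")
  toy <- toy_catalog()
  expect_equal(assess_gene_relevance(toy$WEAK1, "EDS"), "none")
  expect_error(assess_gene_relevance(catalog$POLG, "XYZ"), "context")
})

test_that("per-variant utilities follow impact, evidence and the frequency gate", {
  catalog <- default_gene_catalog()
  pts <- generate_worked_examples()
  p1 <- pts[[1]]
  q1 <- qualify_variant(p1$variants[[1]], catalog$MTHFR, p1, "EDS")
  expect_equal(q1$utility, "VUDU")
  expect_equal(q1$suffix, "O")
  expect_equal(q1$other_diagnosis_label, "clotting diathesis")

  p4 <- pts[[4]]
  q_hbb <- suppressMessages(
    qualify_variant(p4$variants[[2]], catalog$HBB, p4, "DD")
  )
  expect_equal(q_hbb$utility, "VEDU")
  expect_equal(q_hbb$suffix, "O")

  p2 <- pts[[2]]
  q2 <- qualify_variant(p2$variants[[1]], catalog$COL5A1, p2, "EDS")
  expect_equal(q2$utility, "VUDU")
  expect_equal(q2$impact_points, 1L)
  expect_equal(q2$suffix, "none")

  # benign consensus at high frequency: no diagnostic utility
  v <- variant_observation("b", "COL5A1", protein_change = "p.(Ile5Leu)",
                           consequence = "missense", population_af = 0.4,
                           consensus_class = "benign")
  qb <- qualify_variant(v, catalog$COL5A1, p2, "EDS")
  expect_equal(qb$utility, "VNoDU")
  expect_equal(qb$impact_points, 0L)

  expect_error(qualify_variant(p2$variants[[1]], NULL, p2, "EDS"),
               "no gene record")
  expect_error(qualify_variant(p2$variants[[1]], catalog$FLG, p2, "EDS"),
               "does not match")
})

test_that("frequency gate dominates all promotions", {
  catalog <- default_gene_catalog()
  patient <- toy_patient(list(), n_hist = 40)
  # an established protein change at polymorphic frequency is still capped
  v <- variant_observation("hb", "HBB", protein_change = "p.(Glu6Val)",
                           consequence = "missense", population_af = 0.02)
  q <- qualify_variant(v, catalog$HBB, patient, "DD")
  expect_equal(q$utility, "VUDU")
  for (af in c(0.01, 0.05, 0.5, 1)) {
    v2 <- variant_observation("g", "COL3A1",
                              protein_change = "p.(Gly588Ser)",
                              consequence = "missense", population_af = af,
                              origin = "maternal",
                              transmitting_relative_symptomatic = TRUE)
    q2 <- qualify_variant(v2, catalog$COL3A1, patient, "EDS")
    expect_lte(match(q2$utility, qual_enums()$utility),
               match("VUDU", qual_enums()$utility))
  }
})

test_that("qualification is pure and utility is monotone in association strength", {
  patient <- toy_patient(list(), n_hist = 40)
  v <- toy_variant("REL1", 2, origin = "maternal",
                   relative_symptomatic = TRUE)
  ranks <- sapply(c("weak", "reported", "established"), function(s) {
    g <- gene_record(
      "REL1",
      if (s == "weak") list() else
        list(disease_association("M1", "toy", "tissue_laxity")),
      association_strength = s
    )
    match(qualify_variant(v, g, patient, "EDS")$utility,
          qual_enums()$utility)
  })
  expect_true(all(diff(ranks) >= 0))
  # repeated calls with identical inputs give identical results
  g <- toy_catalog()$REL1
  expect_identical(qualify_variant(v, g, patient, "EDS"),
                   qualify_variant(v, g, patient, "EDS"))
})

test_that("clinical evidence points require abundance, transmission and synergy", {
  catalog <- default_gene_catalog()
  pts <- generate_worked_examples()
  p5 <- qualify_patient(pts[[5]], catalog)
  primary <- p5$qualified[[1]]
  ev <- score_clinical_evidence(p5, primary, p5$qualified[-1])
  expect_equal(ev, list(h_point = 1L, i_point = 1L, s_point = 1L))

  p2 <- qualify_patient(pts[[2]], catalog)
  ev2 <- score_clinical_evidence(p2, p2$qualified[[1]], list())
  expect_equal(ev2, list(h_point = 0L, i_point = 0L, s_point = 0L))

  # missing checklist counts as zero findings (logged, not an error)
  blank <- patient_record("none", "female", "EDS",
                          variants = list(toy_variant("REL1", 2)))
  expect_message(
    ev3 <- score_clinical_evidence(blank,
                                   list(variant = blank$variants[[1]],
                                        suffix = "none"), list()),
    "no findings checklist"
  )
  expect_equal(ev3, list(h_point = 0L, i_point = 0L, s_point = 0L))
})

test_that("patient-level scores match the printed worked examples", {
  catalog <- default_gene_catalog()
  pts <- suppressMessages(
    lapply(generate_worked_examples(), qualify_patient, catalog = catalog)
  )
  expect_scores(pts[[1]], eds = 0, other = list("clotting diathesis" = 1))
  expect_scores(pts[[2]], eds = 1)
  expect_scores(pts[[3]], eds = 2)
  expect_identical(pts[[4]]$mdna_scores$context$DD, 2L)
  expect_scores(pts[[5]], eds = 4)
  # no variants -> zero in every context
  empty <- qualify_patient(toy_patient(list()), toy_catalog())
  expect_scores(empty, eds = 0)
})

test_that("aggregate_mdna matches a brute-force restatement of the rules", {
  catalog <- toy_catalog()
  genes <- c("REL1", "SYN1", "OTH1")
  impacts <- 0:2
  combos2 <- expand.grid(g1 = genes, i1 = impacts, g2 = genes,
                         i2 = impacts, h = c(0, 40), i_bit = c(FALSE, TRUE),
                         stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos2))) {
    cc <- combos2[r, ]
    v1 <- toy_variant(cc$g1, cc$i1, id = "v1",
                      origin = if (cc$i_bit) "maternal" else "de_novo",
                      relative_symptomatic = cc$i_bit)
    v2 <- toy_variant(cc$g2, cc$i2, id = "v2")
    p <- toy_patient(list(v1, v2), n_hist = cc$h)
    p <- qualify_patient(p, catalog)
    expect_identical(
      p$mdna_scores$context$EDS,
      brute_force_mdna(p, p$qualified),
      info = paste(unlist(cc), collapse = "/")
    )
  }
  # random 3-variant patients
  set.seed(42)
  for (k in 1:60) {
    vs <- lapply(1:3, function(j) {
      toy_variant(sample(genes, 1), sample(impacts, 1),
                  id = paste0("r", j),
                  origin = sample(c("maternal", "unknown"), 1),
                  relative_symptomatic = sample(c(TRUE, FALSE), 1))
    })
    p <- qualify_patient(toy_patient(vs, n_hist = sample(0:40, 1)),
                         catalog)
    expect_identical(p$mdna_scores$context$EDS,
                     brute_force_mdna(p, p$qualified))
  }
})

test_that("scores stay in 0-4 and never decrease when evidence is added", {
  catalog <- toy_catalog()
  set.seed(7)
  for (k in 1:40) {
    n_var <- sample(1:3, 1)
    vs <- lapply(seq_len(n_var), function(j) {
      toy_variant(sample(c("REL1", "SYN1", "OTH1"), 1), sample(0:2, 1),
                  id = paste0("m", j))
    })
    base_hist <- sample(0:19, 1)
    p0 <- qualify_patient(toy_patient(vs, n_hist = base_hist), catalog)
    s0 <- p0$mdna_scores$context$EDS
    expect_gte(s0, 0L)
    expect_lte(s0, 4L)
    # more history findings
    p_h <- qualify_patient(toy_patient(vs, n_hist = 40), catalog)
    expect_gte(p_h$mdna_scores$context$EDS, s0)
    # inherited-from-symptomatic-relative evidence on every variant
    vs_i <- lapply(vs, function(v) {
      v$origin <- "maternal"
      v$transmitting_relative_symptomatic <- TRUE
      v
    })
    p_i <- qualify_patient(toy_patient(vs_i, n_hist = base_hist), catalog)
    expect_gte(p_i$mdna_scores$context$EDS, s0)
    # an extra synergistic adjunct
    p_s <- qualify_patient(
      toy_patient(c(vs, list(toy_variant("SYN1", 2, id = "adj"))),
                  n_hist = base_hist), catalog)
    expect_gte(p_s$mdna_scores$context$EDS, s0)
    # raising any impact grade
    vs_up <- vs
    vs_up[[1]] <- toy_variant(vs[[1]]$gene_symbol, 2, id = "m1")
    p_u <- qualify_patient(toy_patient(vs_up, n_hist = base_hist), catalog)
    expect_gte(p_u$mdna_scores$context$EDS, s0)
  }
})
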