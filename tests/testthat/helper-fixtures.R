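# Shared fixtures: a toy gene catalog spanning the relevance outcomes, a
# variant builder keyed by intended molecular impact, and an independent
# brute-force re-statement of the patient-level scoring rules used as an
# oracle against aggregate_mdna().

toy_catalog <- function() {
  list(
    REL1 = gene_record(
      "REL1",
      list(disease_association("M100001", "toy laxity disease",
                               "tissue_laxity")),
      association_strength = "established"
    ),
    REL2 = gene_record(
      "REL2",
      list(disease_association("M100002", "toy autonomic disease",
                               "autonomic")),
      association_strength = "reported"
    ),
    SYN1 = gene_record(
      "SYN1",
      list(
        disease_association("M100003", "toy unrelated disease", "other"),
        disease_association("M100004", "toy synergy",
                            "immune_inflammatory", primary = FALSE)
      ),
      association_strength = "reported"
    ),
    OTH1 = gene_record(
      "OTH1",
      list(disease_association("M100005", "toy other diagnosis", "other")),
      association_strength = "established"
    ),
    WEAK1 = gene_record("WEAK1", list(), association_strength = "weak")
  )
}

# impact 0 = synonymous, 1 = conservative missense, 2 = nonsense
toy_variant <- function(gene, impact, id = paste0(gene, "-", impact),
                        af = 1e-4, origin = "unknown",
                        relative_symptomatic = FALSE) {
  cons <- switch(as.character(impact),
                 `0` = "synonymous", `1` = "missense", `2` = "nonsense")
  variant_observation(
    id, gene, consequence = cons,
    protein_change = if (cons == "missense") "p.(Ile10Leu)" else NA,
    population_af = af, origin = origin,
    transmitting_relative_symptomatic = relative_symptomatic
  )
}

toy_checklist <- function(n_hist, n_phys = 5, beighton = 5) {
  h <- logical(80)
  if (n_hist > 0) h[seq_len(n_hist)] <- TRUE
  p <- logical(40)
  if (n_phys > 0) p[seq_len(n_phys)] <- TRUE
  findings_checklist(h, p, beighton)
}

toy_patient <- function(variants, n_hist = 0, id = "toy") {
  patient_record(id, sex = "female", diagnosis_group = "EDS",
                 findings = toy_checklist(n_hist), variants = variants)
}

# Independent restatement of the scoring rules, written directly from the
# protocol description rather than through the package's aggregation path.
brute_force_mdna <- function(patient, qualified, h_threshold = 20,
                             cap = 4L) {
  ctx <- Filter(function(q) {
    q$suffix %in% c("none", "S") &&
      q$relevance %in% c("relevant", "synergistic_adjunct")
  }, qualified)
  impacts <- vapply(ctx, `[[`, integer(1), "impact_points")
  if (!length(ctx) || max(impacts) == 0L) return(0L)
  best <- which.max(impacts)
  primary <- ctx[[best]]
  h <- as.integer(sum(patient$findings$history) >= h_threshold)
  i <- as.integer(
    primary$variant$origin %in% c("maternal", "paternal") &&
      primary$variant$transmitting_relative_symptomatic
  )
  others <- qualified[!vapply(qualified, identical, logical(1), primary)]
  s <- as.integer(any(vapply(others, function(q) q$suffix == "S",
                             logical(1))))
  min(cap, max(impacts) + h + i + s)
}

expect_scores <- function(patient, eds = NULL, other = NULL) {
  if (!is.null(eds)) {
    expect_identical(patient$mdna_scores$context$EDS, as.integer(eds))
  }
  if (!is.null(other)) {
    for (lab in names(other)) {
      expect_identical(patient$mdna_scores$other[[lab]],
                       as.integer(other[[lab]]))
    }
  }
}
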