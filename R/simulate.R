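# Seeded synthetic-cohort generation: configurable findings-count moments,
# sex ratio and DNA-testing outcome rates, plus the five packaged
# worked-example patients and a deterministic reference cohort realizing
# the published testing-outcome marginals.

#' Simulation configuration for synthetic cohorts
#'
#' Defaults encode the study conditions of the systematically evaluated
#' cohort: 82% female; history findings (of 80) averaging 36 +/- 10 for
#' affected females and 26 +/- 10 for affected males versus 7.2 +/- 1.3
#' for patients not meeting criteria; physical findings (of 40) 19/17
#' +/- 4.7 versus 7.6 +/- 1.3; Beighton hypermobility means 6.9 (female)
#' and 5.6 (male) versus a 4.5 population-like mean for the unaffected
#' group, sd 1.5 (dispersion not published; chosen once and exposed here).
#' Testing-outcome rates follow the published cohort table: 51% DNA
#' tested, 59% of those with a potentially significant variant, 3.5%
#' of carriers company-qualified as condition-relevant, 32% as relevant to
#' another diagnosis, 99.6% author-qualified, 16% with a mitochondrial
#' DNA variant and 3.4% with a nuclear-encoded mitochondrial variant.
#'
#' @param n_total cohort size.
#' @param female_fraction fraction female.
#' @param eds_fraction fraction meeting diagnostic criteria (the rest form
#'   the comparison group).
#' @param history_moments,physical_moments data.frames with columns
#'   `group`, `sex`, `mean`, `sd` (group `NoEDS` rows apply to both sexes).
#' @param beighton_means named vector (`female`, `male`) for the affected
#'   group; `beighton_sd` common dispersion; `beighton_noeds_mean` for the
#'   unaffected group.
#' @param dna_tested_fraction,significant_variant_fraction,
#'   company_relevant_fraction,company_other_fraction,
#'   author_relevant_fraction,mt_variant_fraction,nuclear_mt_fraction
#'   outcome rates (each conditional on the previous gate).
#' @param variant_templates data.frame of template variants (columns
#'   `gene`, `consequence`, `protein_change`, `af`) sampled for
#'   significant-variant carriers; default built from the packaged gene
#'   catalog.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_total = 1325, female_fraction = 0.82,
                              eds_fraction = 1261 / 1325,
                              history_moments = NULL,
                              physical_moments = NULL,
                              beighton_means = c(female = 6.9, male = 5.6),
                              beighton_sd = 1.5,
                              beighton_noeds_mean = 4.5,
                              dna_tested_fraction = 0.51,
                              significant_variant_fraction = 0.59,
                              company_relevant_fraction = 0.035,
                              company_other_fraction = 0.32,
                              author_relevant_fraction = 0.996,
                              mt_variant_fraction = 0.16,
                              nuclear_mt_fraction = 0.034,
                              variant_templates = NULL,
                              seed = 1L) {
  if (is.null(history_moments)) {
    history_moments <- data.frame(
      group = c("EDS", "EDS", "NoEDS"), sex = c("female", "male", "any"),
      mean = c(36, 26, 7.2), sd = c(10, 10, 1.3)
    )
  }
  if (is.null(physical_moments)) {
    physical_moments <- data.frame(
      group = c("EDS", "EDS", "NoEDS"), sex = c("female", "male", "any"),
      mean = c(19, 17, 7.6), sd = c(4.7, 4.7, 1.3)
    )
  }
  if (any(history_moments$mean > 80) || any(physical_moments$mean > 40)) {
    stop("infeasible moments: mean exceeds checklist scale", call. = FALSE)
  }
  fr <- c(female_fraction, eds_fraction, dna_tested_fraction,
          significant_variant_fraction, company_relevant_fraction,
          company_other_fraction, author_relevant_fraction,
          mt_variant_fraction, nuclear_mt_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), n_total >= 0)
  if (is.null(variant_templates)) {
    variant_templates <- data.frame(
      gene = c("COL5A1", "COL5A2", "COL3A1", "FLG", "POLG", "VWF", "F2",
               "PIK3R1", "SLC6A2", "ADAMTS2"),
      consequence = c("missense", "missense", "missense", "nonsense",
                      "missense", "missense", "missense", "missense",
                      "missense", "frameshift"),
      protein_change = c("p.(Ile588Leu)", "p.(Met667Val)", "p.(Gly588Ser)",
                         "p.(Arg501Ter)", "p.(Ala467Thr)", "p.(Arg854Gln)",
                         "p.(Arg596Leu)", "p.(Asn564Asp)", "p.(Ala457Pro)",
                         NA),
      af = c(1e-4, 2e-4, 1e-5, 2e-3, 5e-4, 1e-3, 5e-3, 1e-4, 2e-4, 1e-5)
    )
  }
  structure(list(
    n_total = as.integer(n_total), female_fraction = female_fraction,
    eds_fraction = eds_fraction, history_moments = history_moments,
    physical_moments = physical_moments, beighton_means = beighton_means,
    beighton_sd = beighton_sd, beighton_noeds_mean = beighton_noeds_mean,
    dna_tested_fraction = dna_tested_fraction,
    significant_variant_fraction = significant_variant_fraction,
    company_relevant_fraction = company_relevant_fraction,
    company_other_fraction = company_other_fraction,
    author_relevant_fraction = author_relevant_fraction,
    mt_variant_fraction = mt_variant_fraction,
    nuclear_mt_fraction = nuclear_mt_fraction,
    variant_templates = variant_templates, seed = as.integer(seed)
  ), class = "simulation_config")
}

.moment_row <- function(tab, group, sex) {
  hit <- tab$group == group & (tab$sex == sex | tab$sex == "any")
  tab[which(hit)[1], ]
}

.sample_count <- function(mean, sd, upper) {
  x <- round(rtruncnorm(1, mean, sd, lower = 0, upper = upper))
  as.integer(min(max(x, 0), upper))
}

#' Generate a synthetic patient cohort
#'
#' Seeded, reproducible generation: per patient, sex and diagnosis group
#' are drawn at the configured rates; target history/physical counts are
#' drawn from truncated normal distributions with the configured per-group
#' moments and realized by weighted sampling (without replacement) of the
#' schema's findings using their prevalences as weights; Beighton scores
#' are truncated-normal on 0-9; DNA-testing outcome flags follow the
#' configured conditional rates; significant-variant carriers draw one or
#' two variants from the template library. Every record passes
#' [validate_patient()].
#'
#' @param config a [simulation_config()].
#' @param schema findings schema (default [default_findings_schema()]).
#' @return list of [patient_record()]s.
#' @export
generate_cohort <- function(config = simulation_config(),
                            schema = default_findings_schema()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_total
  if (n == 0L) return(list())
  hist_ids <- schema$finding_id[schema$domain == "history"]
  phys_ids <- schema$finding_id[schema$domain == "physical"]
  hist_w <- schema$prevalence[schema$domain == "history"]
  phys_w <- schema$prevalence[schema$domain == "physical"]
  tmpl <- config$variant_templates
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (stats::runif(1) < config$female_fraction) "female" else "male"
    grp <- if (stats::runif(1) < config$eds_fraction) "EDS" else "NoEDS"
    hm <- .moment_row(config$history_moments, grp, sex)
    pm <- .moment_row(config$physical_moments, grp, sex)
    n_hist <- .sample_count(hm$mean, hm$sd, 80L)
    n_phys <- .sample_count(pm$mean, pm$sd, 40L)
    hist_v <- stats::setNames(logical(80), hist_ids)
    phys_v <- stats::setNames(logical(40), phys_ids)
    if (n_hist > 0) hist_v[sample(80L, n_hist, prob = hist_w)] <- TRUE
    if (n_phys > 0) phys_v[sample(40L, n_phys, prob = phys_w)] <- TRUE
    b_mean <- if (grp == "EDS") config$beighton_means[[sex]] else
      config$beighton_noeds_mean
    beighton <- .sample_count(b_mean, config$beighton_sd, 9L)
    chk <- findings_checklist(hist_v, phys_v, beighton, schema)

    dna <- stats::runif(1) < config$dna_tested_fraction
    sig <- dna && stats::runif(1) < config$significant_variant_fraction
    company <- "none"
    author <- FALSE
    mt <- FALSE
    nucmt <- FALSE
    variants <- list()
    if (sig) {
      u <- stats::runif(1)
      company <- if (u < config$company_relevant_fraction) "eds"
        else if (u < config$company_relevant_fraction +
                   config$company_other_fraction) "other" else "none"
      author <- stats::runif(1) < config$author_relevant_fraction
      mt <- stats::runif(1) < config$mt_variant_fraction
      nucmt <- !mt && stats::runif(1) < config$nuclear_mt_fraction
      n_var <- 1L + (stats::runif(1) < 0.3)
      rows <- sample(nrow(tmpl), n_var)
      variants <- lapply(seq_along(rows), function(k) {
        r <- tmpl[rows[k], ]
        variant_observation(
          variant_id = sprintf("P%04d.%d", i, k), gene_symbol = r$gene,
          protein_change = r$protein_change, consequence = r$consequence,
          population_af = r$af
        )
      })
    }
    age <- sample(c("0-2.5", "2.5-5", "5-7.5", "7.5-10", "10-20", "20-30",
                    "30-40", "40-50", "50-60", "60-70"), 1,
                  prob = c(rep(0.01, 4), 0.2, 0.2, 0.2, 0.18, 0.12, 0.06))
    p <- patient_record(
      patient_id = sprintf("SIM%04d", i), sex = sex, diagnosis_group = grp,
      findings = chk, variants = variants, age_bin = age,
      systematic = TRUE, dna_tested = dna, significant_variant = sig,
      company_relevant = company, author_eds_relevant = author,
      mt_variant = mt, nuclear_mt_variant = nucmt
    )
    validate_patient(p)
    out[[i]] <- p
  }
  out
}

#' The five packaged worked-example patients
#'
#' Fixture patients reproducing the protocol's printed worked examples:
#' \enumerate{
#'   \item a common MTHFR `677C>T` substitution (30% population frequency)
#'     whose only association is a multifactorial clotting diathesis;
#'   \item a conservative (Ile->Leu) collagen-type-V substitution with no
#'     clinical evidence points;
#'   \item a disruptive collagen-type-V substitution (Met->Val promoted by
#'     its conservation/in-silico annotations);
#'   \item a developmental-disability patient with a POLG variant relevant
#'     to the disability and an established sickle beta-globin carrier
#'     change relevant to another diagnosis;
#'   \item an abundant-history patient with a maternally inherited
#'     disruptive COL3A1 variant (symptomatic mother), a synergistic
#'     truncating profilaggrin adjunct, and a cancer-predisposition
#'     variant relevant to another diagnosis.
#' }
#' Annotations are sufficient for [qualify_patient()] to reproduce the
#' printed qualifications with the default configuration and catalog.
#'
#' @param schema findings schema used to build the checklists.
#' @return list of five validated [patient_record()]s.
#' @export
generate_worked_examples <- function(schema = default_findings_schema()) {
  chk <- function(n_hist, beighton = 5) {
    h <- logical(80)
    if (n_hist > 0) h[seq_len(n_hist)] <- TRUE
    p <- logical(40)
    p[seq_len(12)] <- TRUE
    findings_checklist(h, p, beighton, schema)
  }
  p1 <- patient_record(
    "example-1", sex = "female", diagnosis_group = "EDS",
    findings = chk(30), variants = list(variant_observation(
      "1.0", "MTHFR", dna_change = "c.665C>T",
      protein_change = "p.(Ala222Val)", consequence = "missense",
      population_af = 0.30, consensus_class = "uncertain"
    )),
    company_relevant = "other", author_eds_relevant = FALSE
  )
  p2 <- patient_record(
    "example-2", sex = "female", diagnosis_group = "EDS",
    findings = chk(15), variants = list(variant_observation(
      "2.0", "COL5A1", dna_change = "c.1762A>C",
      protein_change = "p.(Ile588Leu)", consequence = "missense",
      population_af = 1e-5, consensus_class = "uncertain",
      conservation_score = 0.5, insilico_score = 0.4
    )),
    author_eds_relevant = TRUE
  )
  p3 <- patient_record(
    "example-3", sex = "female", diagnosis_group = "EDS",
    findings = chk(16), variants = list(variant_observation(
      "3.0", "COL5A2", dna_change = "c.1999A>G",
      protein_change = "p.(Met667Val)", consequence = "missense",
      population_af = 1e-5, consensus_class = "uncertain",
      conservation_score = 0.95, insilico_score = 0.85
    )),
    author_eds_relevant = TRUE
  )
  p4 <- patient_record(
    "example-4", sex = "male", diagnosis_group = "DD",
    findings = NULL, variants = list(
      variant_observation(
        "4.1", "POLG", dna_change = "c.1399G>A",
        protein_change = "p.(Ala467Thr)", consequence = "missense",
        population_af = 5e-4, consensus_class = "likely_pathogenic"
      ),
      variant_observation(
        "4.2", "HBB", dna_change = "c.20A>T",
        protein_change = "p.(Glu6Val)", consequence = "missense",
        population_af = 4e-3, consensus_class = "pathogenic"
      )
    ),
    systematic = FALSE, company_relevant = "other"
  )
  p5 <- patient_record(
    "example-5", sex = "female", diagnosis_group = "EDS",
    findings = chk(40, beighton = 7), variants = list(
      variant_observation(
        "5.1", "COL3A1", dna_change = "c.1762G>A",
        protein_change = "p.(Gly588Ser)", consequence = "missense",
        population_af = 1e-5, consensus_class = "uncertain",
        conservation_score = 0.95, insilico_score = 0.9,
        origin = "maternal", transmitting_relative_symptomatic = TRUE
      ),
      variant_observation(
        "5.2", "FLG", dna_change = "c.1501C>T",
        protein_change = "p.(Arg501Ter)", consequence = "nonsense",
        population_af = 2e-3, consensus_class = "uncertain"
      ),
      variant_observation(
        "5.3", "BRCA1", dna_change = "c.181T>G",
        protein_change = "p.(Cys61Gly)", consequence = "missense",
        population_af = 1e-5, consensus_class = "pathogenic"
      )
    ),
    author_eds_relevant = TRUE
  )
  out <- list(p1, p2, p3, p4, p5)
  lapply(out, validate_patient)
  out
}

#' Deterministic reference cohort with the published testing marginals
#'
#' Builds (without randomness) a cohort whose group-level counts equal the
#' published patient-and-DNA-testing table: 1899 patients meeting criteria
#' (1553 female, 346 male) and 80 not, with the published numbers of
#' systematic evaluations, DNA tests, significant-variant carriers,
#' company- and author-qualified results and mitochondrial variant
#' carriers nested within each sex stratum. Flags only; checklists and
#' variant lists are left empty, since only marginal counts are realized.
#'
#' @return list of [patient_record()]s.
#' @export
reference_cohort <- function() {
  strata <- list(
    list(group = "EDS", sex = "female", total = 1553, systematic = 1064,
         dna = 816, sig = 480, co_eds = 16, co_other = 154, author = 478,
         mt = 79, nucmt = 18),
    list(group = "EDS", sex = "male", total = 346, systematic = 197,
         dna = 151, sig = 88, co_eds = 4, co_other = 27, author = 88,
         mt = 14, nucmt = 1),
    list(group = "NoEDS", sex = "female", total = 66, systematic = 53,
         dna = 19, sig = 3, co_eds = 0, co_other = 0, author = 3,
         mt = 0, nucmt = 0),
    list(group = "NoEDS", sex = "male", total = 14, systematic = 11,
         dna = 4, sig = 1, co_eds = 0, co_other = 0, author = 1,
         mt = 0, nucmt = 0)
  )
  out <- list()
  for (s in strata) {
    for (i in seq_len(s$total)) {
      sig <- i <= s$sig
      out[[length(out) + 1L]] <- patient_record(
        patient_id = sprintf("REF-%s-%s-%04d", s$group, s$sex, i),
        sex = s$sex, diagnosis_group = s$group,
        systematic = i <= s$systematic, dna_tested = i <= s$dna,
        significant_variant = sig,
        company_relevant = if (sig && i <= s$co_eds) "eds"
          else if (sig && i <= s$co_eds + s$co_other) "other" else "none",
        author_eds_relevant = sig && i <= s$author,
        mt_variant = sig && i <= s$mt,
        nuclear_mt_variant = sig && i > s$mt && i <= s$mt + s$nucmt
      )
    }
  }
  out
}
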