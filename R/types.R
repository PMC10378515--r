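# Domain types: variant observations, gene records, findings checklists,
# patient records. All are validating list-based S3 constructors.

.CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "splice_disrupting",
  "inframe_indel", "synonymous", "noncoding"
)
.CONSENSUS_CLASSES <- c(
  "pathogenic", "likely_pathogenic", "uncertain", "likely_benign", "benign"
)
.ORIGINS <- c("maternal", "paternal", "de_novo", "unknown")
.MECHANISM_TAGS <- c(
  "tissue_laxity", "neuro", "autonomic", "immune_inflammatory", "clotting",
  "viral_response", "developmental", "renal_vascular", "mitochondrial",
  "other"
)
.PRODUCT_CLASSES <- c(
  "enzyme", "structural", "signal", "receptor", "membrane_channel",
  "transcription_factor", "transport", "adhesion", "other"
)
.TISSUE_CLASSES <- c(
  "bone", "joint", "cardiovascular", "clotting", "muscle", "skin",
  "neural", "autonomic_other", "immune_inflammatory", "viral_response",
  "renal_vascular", "developmental"
)
.UTILITY_LEVELS <- c("VNoDU", "VUDU", "VMDU", "VSDU", "VEDU")
.CONTEXTS <- c("EDS", "DD", "other")

#' Enumerations used across the package
#'
#' @return named list of the controlled vocabularies: consequence terms,
#'   consensus classes, inheritance origins, mechanism tags, product and
#'   tissue classes, utility categories (ordered worst to best), contexts.
#' @export
qual_enums <- function() {
  list(
    consequence = .CONSEQUENCES, consensus = .CONSENSUS_CLASSES,
    origin = .ORIGINS, mechanism_tags = .MECHANISM_TAGS,
    product_class = .PRODUCT_CLASSES, tissue_class = .TISSUE_CLASSES,
    utility = .UTILITY_LEVELS, context = .CONTEXTS
  )
}

.match_enum <- function(value, choices, what) {
  value <- as.character(value)
  if (length(value) != 1L || !value %in% choices) {
    stop(sprintf(
      "%s must be one of %s (got %s)", what,
      paste(choices, collapse = ", "), paste(value, collapse = "/")
    ), call. = FALSE)
  }
  value
}

#' Construct a variant observation
#'
#' One observed DNA change in one patient, carrying the molecular
#' annotations the qualification protocol consumes: the consequence class,
#' population allele frequency, laboratory consensus class, pre-computed
#' conservation and in-silico scores (the protocol treats these as input
#' annotations from external tools), and inheritance information.
#'
#' @param variant_id identifier string.
#' @param gene_symbol gene symbol (normalized with [normalize_symbol()]).
#' @param dna_change HGVS-style coding change (e.g. `"c.665C>T"`).
#' @param protein_change HGVS-style protein change or `NA`; required for
#'   missense consequences.
#' @param consequence one of `qual_enums()$consequence`.
#' @param population_af population allele frequency in `[0, 1]` or `NA`.
#' @param consensus_class laboratory consensus class.
#' @param conservation_score,insilico_score fractions in `[0, 1]` or `NA`.
#' @param origin inheritance origin.
#' @param transmitting_relative_symptomatic logical: was the transmitting
#'   relative symptomatic (the "matSx"-type evidence).
#' @return object of class `variant_observation`.
#' @export
variant_observation <- function(variant_id, gene_symbol, dna_change = NA,
                                protein_change = NA,
                                consequence = "missense",
                                population_af = NA,
                                consensus_class = "uncertain",
                                conservation_score = NA,
                                insilico_score = NA,
                                origin = "unknown",
                                transmitting_relative_symptomatic = FALSE) {
  gene_symbol <- normalize_symbol(gene_symbol)
  if (!nzchar(gene_symbol)) stop("gene_symbol must be non-empty", call. = FALSE)
  consequence <- .match_enum(consequence, .CONSEQUENCES, "consequence")
  consensus_class <- .match_enum(consensus_class, .CONSENSUS_CLASSES,
                                 "consensus_class")
  origin <- .match_enum(origin, .ORIGINS, "origin")
  if (!is.na(population_af) &&
      (population_af < 0 || population_af > 1)) {
    stop(sprintf("population_af must lie in [0,1] (variant %s: %s)",
                 variant_id, population_af), call. = FALSE)
  }
  for (nm in c("conservation_score", "insilico_score")) {
    v <- get(nm)
    if (!is.na(v) && (v < 0 || v > 1)) {
      stop(sprintf("%s must lie in [0,1] (variant %s)", nm, variant_id),
           call. = FALSE)
    }
  }
  if (consequence == "missense" &&
      (is.na(protein_change) || !nzchar(protein_change))) {
    stop(sprintf("variant %s: protein_change required for missense",
                 variant_id), call. = FALSE)
  }
  structure(list(
    variant_id = as.character(variant_id), gene_symbol = gene_symbol,
    dna_change = as.character(dna_change),
    protein_change = as.character(protein_change),
    consequence = consequence, population_af = as.numeric(population_af),
    consensus_class = consensus_class,
    conservation_score = as.numeric(conservation_score),
    insilico_score = as.numeric(insilico_score), origin = origin,
    transmitting_relative_symptomatic =
      isTRUE(transmitting_relative_symptomatic)
  ), class = "variant_observation")
}

#' Construct a gene-disease association entry
#'
#' @param m_number OMIM-style "M number" identifier string.
#' @param label human-readable disease label.
#' @param mechanism_tags character vector of mechanism tags.
#' @param primary logical: is the mechanism link a primary disease
#'   association (as opposed to a secondary/synergistic connection)?
#' @return list of class `disease_association`.
#' @export
disease_association <- function(m_number, label, mechanism_tags,
                                primary = TRUE) {
  mechanism_tags <- unique(as.character(mechanism_tags))
  bad <- setdiff(mechanism_tags, .MECHANISM_TAGS)
  if (length(bad)) {
    stop("unknown mechanism tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    m_number = as.character(m_number), label = as.character(label),
    mechanism_tags = mechanism_tags, primary = isTRUE(primary)
  ), class = "disease_association")
}

#' Construct a gene record
#'
#' A gene with its associated diseases (each tagged with the pathogenic
#' mechanisms it acts through and whether the association is primary), a
#' product-function class, a primary tissue element/process class, the
#' running strength of the gene-disease association (the dynamic evidence
#' step of the protocol), and any protein changes with long association
#' histories (e.g. the sickle beta-globin substitution).
#'
#' @param gene_symbol gene symbol.
#' @param associated_diseases list of [disease_association()] objects.
#' @param product_class one of `qual_enums()$product_class`.
#' @param tissue_class one of `qual_enums()$tissue_class`.
#' @param association_strength `"established"`, `"reported"` or `"weak"`.
#' @param established_variants character vector of protein changes with
#'   evidenced association histories.
#' @param multi_system logical: gene flagged as affecting multiple systems
#'   (primary `tissue_class` chosen at curation time).
#' @return object of class `gene_record`; its `mechanism_tags` field is the
#'   union of the associations' tags.
#' @export
gene_record <- function(gene_symbol, associated_diseases = list(),
                        product_class = "other", tissue_class = "neural",
                        association_strength = c("established", "reported",
                                                 "weak"),
                        established_variants = character(),
                        multi_system = FALSE) {
  gene_symbol <- normalize_symbol(gene_symbol)
  association_strength <- match.arg(association_strength)
  product_class <- .match_enum(product_class, .PRODUCT_CLASSES,
                               "product_class")
  tissue_class <- .match_enum(tissue_class, .TISSUE_CLASSES, "tissue_class")
  stopifnot(all(vapply(associated_diseases, inherits, logical(1),
                       "disease_association")))
  if (association_strength != "weak" && !length(associated_diseases)) {
    stop(sprintf(
      "gene %s: at least one associated disease required unless association_strength is 'weak'",
      gene_symbol), call. = FALSE)
  }
  tags <- unique(unlist(lapply(associated_diseases, `[[`, "mechanism_tags")))
  structure(list(
    gene_symbol = gene_symbol, associated_diseases = associated_diseases,
    mechanism_tags = as.character(tags %||% character()),
    product_class = product_class, tissue_class = tissue_class,
    association_strength = association_strength,
    established_variants = as.character(established_variants),
    multi_system = isTRUE(multi_system)
  ), class = "gene_record")
}

#' Default findings-checklist schema
#'
#' The systematic evaluation instrument scores 80 binary history findings
#' and 40 binary physical findings plus a 0-9 hypermobility (Beighton)
#' score. Findings documented with published female frequencies carry those
#' as default prevalences; the remaining slots are filled with systematic
#' placeholder names at a uniform background prevalence, since per-finding
#' frequencies for the full instrument are not published.
#'
#' @return data.frame with columns `finding_id`, `domain`
#'   (`history`/`physical`), `category`, `prevalence` (default per-finding
#'   probability used by the synthetic-cohort generator, scaled there to the
#'   configured count moments).
#' @export
default_findings_schema <- function() {
  named_hist <- data.frame(
    finding_id = c(
      "migraines", "poor_balance", "brain_fog", "chronic_fatigue",
      "bowel_irregularity", "bloating_reflux", "rashes", "asthma_dyspnea",
      "sprains", "ligament_tears", "fractures", "sleep_difficulties",
      "tachycardia", "joint_pain", "muscle_weakness", "myalgia",
      "frequent_headaches", "dizziness", "syncope", "whole_body_pain",
      "difficulty_walking", "anxiety", "allergies", "easy_bruising"
    ),
    category = c(
      "neuromuscular", "neuromuscular", "pots", "pots", "ibs", "ibs",
      "mcas", "mcas", "tissue_laxity", "tissue_laxity", "tissue_laxity",
      "pots", "pots", "tissue_laxity", "neuromuscular", "neuromuscular",
      "neuromuscular", "pots", "pots", "neuromuscular", "neuromuscular",
      "pots", "mcas", "tissue_laxity"
    ),
    prevalence = c(
      0.60, 0.61, 0.83, 0.87, 0.82, 0.79, 0.42, 0.49, 0.56, 0.36, 0.49,
      0.70, 0.65, 0.80, 0.60, 0.55, 0.60, 0.55, 0.30, 0.55, 0.35, 0.50,
      0.45, 0.60
    )
  )
  n_pad_h <- 80 - nrow(named_hist)
  pad_hist <- data.frame(
    finding_id = sprintf("history_finding_%02d", seq_len(n_pad_h)),
    category = "general_history", prevalence = 0.35
  )
  named_phys <- data.frame(
    finding_id = c(
      "stretch_marks", "scars_atrophic", "scoliosis", "flat_feet",
      "skin_laxity", "joint_hypermobility_elbow", "joint_hypermobility_knee",
      "pectus_deformity", "high_palate", "soft_skin"
    ),
    category = c(
      "skin", "skin", "skeletal", "skeletal", "skin", "joint", "joint",
      "skeletal", "craniofacial", "skin"
    ),
    prevalence = c(0.59, 0.43, 0.25, 0.46, 0.50, 0.55, 0.55, 0.20, 0.35,
                   0.60)
  )
  n_pad_p <- 40 - nrow(named_phys)
  pad_phys <- data.frame(
    finding_id = sprintf("physical_finding_%02d", seq_len(n_pad_p)),
    category = "general_physical", prevalence = 0.40
  )
  hist <- rbind(named_hist, pad_hist)
  hist$domain <- "history"
  phys <- rbind(named_phys, pad_phys)
  phys$domain <- "physical"
  out <- rbind(hist, phys)
  out[, c("finding_id", "domain", "category", "prevalence")]
}

#' Construct a findings checklist
#'
#' @param history named logical vector of length 80 (history findings).
#' @param physical named logical vector of length 40 (physical findings).
#' @param beighton integer hypermobility score, 0-9.
#' @param schema findings schema (see [default_findings_schema()]); used to
#'   fill names and order when bare logicals are supplied.
#' @return object of class `findings_checklist`.
#' @export
findings_checklist <- function(history = logical(80), physical = logical(40),
                               beighton = 0,
                               schema = default_findings_schema()) {
  hist_ids <- schema$finding_id[schema$domain == "history"]
  phys_ids <- schema$finding_id[schema$domain == "physical"]
  if (length(history) != 80L) stop("history must have exactly 80 slots",
                                   call. = FALSE)
  if (length(physical) != 40L) stop("physical must have exactly 40 slots",
                                    call. = FALSE)
  history <- as.logical(history)
  physical <- as.logical(physical)
  names(history) <- names(history) %||% hist_ids
  names(physical) <- names(physical) %||% phys_ids
  if (is.null(names(history)) || anyNA(names(history))) names(history) <- hist_ids
  if (is.null(names(physical)) || anyNA(names(physical))) names(physical) <- phys_ids
  beighton <- as.integer(beighton)
  if (is.na(beighton) || beighton < 0L || beighton > 9L) {
    stop("beighton must be an integer in [0,9]", call. = FALSE)
  }
  structure(list(history = history, physical = physical,
                 beighton = beighton),
            class = "findings_checklist")
}

#' Count positive findings on a checklist
#'
#' @param checklist a [findings_checklist()] (or `NULL`, counted as zero).
#' @param domain `"history"` or `"physical"`.
#' @return integer count.
#' @export
count_findings <- function(checklist, domain = c("history", "physical")) {
  domain <- match.arg(domain)
  if (is.null(checklist)) return(0L)
  sum(checklist[[domain]], na.rm = TRUE)
}

#' Construct a patient record
#'
#' Bundles identity, diagnosis group, the findings checklist, observed
#' variants, qualification results and per-context medical-DNA utility
#' scores, plus the DNA-testing outcome flags used by cohort summaries.
#'
#' @param patient_id identifier string.
#' @param sex `"female"` or `"male"`.
#' @param diagnosis_group `"EDS"`, `"NoEDS"` or `"DD"`.
#' @param findings a [findings_checklist()] or `NULL` (no systematic
#'   evaluation).
#' @param variants list of [variant_observation()] objects.
#' @param age_bin age-interval label (2.5-year bins under age 10, 10-year
#'   bins above); recorded but unused by the statistics.
#' @param systematic,dna_tested,significant_variant,author_eds_relevant,
#'   mt_variant,nuclear_mt_variant logical testing/outcome flags.
#' @param company_relevant `"eds"`, `"other"`, or `"none"`: what the
#'   commercial laboratory report related the variants to.
#' @return object of class `patient_record` with empty `qualified` and
#'   `mdna_scores` fields (filled by [qualify_patient()]).
#' @export
patient_record <- function(patient_id, sex = c("female", "male"),
                           diagnosis_group = c("EDS", "NoEDS", "DD"),
                           findings = NULL, variants = list(),
                           age_bin = NA_character_,
                           systematic = !is.null(findings),
                           dna_tested = length(variants) > 0,
                           significant_variant = length(variants) > 0,
                           company_relevant = c("none", "eds", "other"),
                           author_eds_relevant = FALSE,
                           mt_variant = FALSE,
                           nuclear_mt_variant = FALSE) {
  sex <- match.arg(sex)
  diagnosis_group <- match.arg(diagnosis_group)
  company_relevant <- match.arg(company_relevant)
  if (!is.null(findings) && !inherits(findings, "findings_checklist")) {
    stop("findings must be a findings_checklist or NULL", call. = FALSE)
  }
  stopifnot(all(vapply(variants, inherits, logical(1),
                       "variant_observation")))
  structure(list(
    patient_id = as.character(patient_id), sex = sex,
    diagnosis_group = diagnosis_group, findings = findings,
    variants = variants, age_bin = as.character(age_bin),
    systematic = isTRUE(systematic), dna_tested = isTRUE(dna_tested),
    significant_variant = isTRUE(significant_variant),
    company_relevant = company_relevant,
    author_eds_relevant = isTRUE(author_eds_relevant),
    mt_variant = isTRUE(mt_variant),
    nuclear_mt_variant = isTRUE(nuclear_mt_variant),
    qualified = list(), mdna_scores = list()
  ), class = "patient_record")
}

#' Validate a patient record's invariants
#'
#' Checks score bounds (every medical-DNA score in 0-4), checklist shape,
#' and variant classes; called by the generators on everything they emit.
#'
#' @param patient a `patient_record`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_patient <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  if (!is.null(patient$findings)) {
    stopifnot(inherits(patient$findings, "findings_checklist"),
              length(patient$findings$history) == 80L,
              length(patient$findings$physical) == 40L,
              patient$findings$beighton >= 0L,
              patient$findings$beighton <= 9L)
  }
  stopifnot(all(vapply(patient$variants, inherits, logical(1),
                       "variant_observation")))
  ctx <- patient$mdna_scores$context %||% list()
  oth <- patient$mdna_scores$other %||% list()
  all_scores <- c(unlist(ctx), unlist(oth))
  if (length(all_scores)) {
    stopifnot(all(all_scores >= 0), all(all_scores <= 4))
  }
  invisible(TRUE)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s, %s): %d variant(s)",
              x$patient_id, x$sex, x$diagnosis_group,
              length(x$variants)))
  if (length(x$mdna_scores$context)) {
    sc <- unlist(x$mdna_scores$context)
    cat(" | MDna:", paste(sprintf("%s=%d", names(sc), sc), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.variant_observation <- function(x, ...) {
  cat(sprintf("<variant_observation> %s %s %s (%s)\n", x$variant_id,
              x$gene_symbol,
              if (is.na(x$protein_change)) x$dna_change else x$protein_change,
              x$consequence))
  invisible(x)
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s [%s/%s, %s]: %d disease(s), tags: %s\n",
              x$gene_symbol, x$product_class, x$tissue_class,
              x$association_strength, length(x$associated_diseases),
              paste(x$mechanism_tags, collapse = ", ")))
  invisible(x)
}
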