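# The stepwise molecular + clinical qualification engine.
#
# Molecular steps grade product disruption from the substitution class
# (with conservation and in-silico annotations consumed as pre-computed
# scores), the gene-relevance step maps genes to disease contexts through
# mechanism tags, and the clinical steps add points for abundant
# disease-related history (H), inheritance from a symptomatic relative (I)
# and synergistic adjunct variants (J/S). Per-variant utilities and the
# 0-4+ per-patient medical DNA (MDna) utility score follow.

# Physicochemical residue classes. Same-class missense = conservative
# (grade 1); cross-class = disruptive (grade 2).
.RESIDUE_CLASSES <- list(
  aliphatic = c("I", "L", "V", "M", "A"),
  aromatic  = c("F", "W", "Y"),
  positive  = c("K", "R", "H"),
  negative  = c("D", "E"),
  polar     = c("S", "T", "N", "Q", "C"),
  special   = c("G", "P")
)

# Fibrillar collagen genes: glycine/proline substitutions in the
# triple-helical (Gly-X-Y) repeat are structurally disruptive regardless of
# physicochemical class.
.FIBRILLAR_COLLAGENS <- c(
  "COL1A1", "COL1A2", "COL2A1", "COL3A1", "COL5A1", "COL5A2",
  "COL11A1", "COL11A2", "COL24A1", "COL27A1"
)

# Mechanism-tag sets defining contextual gene relevance: connective-tissue
# dysplasia with dysautonomia (EDS) versus developmental disability (DD).
.CONTEXT_TAGS <- list(
  EDS = c("tissue_laxity", "neuro", "autonomic", "immune_inflammatory",
          "clotting", "mitochondrial"),
  DD  = c("neuro", "developmental", "mitochondrial")
)

.AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

#' Qualification-engine configuration
#'
#' Tunable thresholds of the qualification protocol, all with documented
#' defaults.
#'
#' @param common_af_threshold population allele frequency at or above which
#'   a variant is treated as too common to exceed uncertain utility
#'   (default 0.01).
#' @param h_threshold number of positive history findings (of 80) counted
#'   as "abundant disease-related symptoms" (default 20, midway between
#'   typical affected and unaffected cohort means).
#' @param conservation_cutoff,insilico_cutoff annotation scores at or above
#'   which a conservative (grade 1) substitution is promoted to disruptive
#'   (grade 2); defaults 0.9 and 0.8.
#' @param residue_classes named list of physicochemical residue classes
#'   (1-letter codes).
#' @param collagen_genes genes in which glycine/proline substitutions are
#'   always disruptive.
#' @param context_tags named list mapping each diagnostic context to the
#'   mechanism tags that make a gene relevant to it.
#' @param mdna_cap maximum per-patient score (default 4).
#' @return list of class `qual_config`.
#' @export
qual_config <- function(common_af_threshold = 0.01, h_threshold = 20,
                        conservation_cutoff = 0.9, insilico_cutoff = 0.8,
                        residue_classes = .RESIDUE_CLASSES,
                        collagen_genes = .FIBRILLAR_COLLAGENS,
                        context_tags = .CONTEXT_TAGS, mdna_cap = 4L) {
  stopifnot(common_af_threshold > 0, common_af_threshold <= 1,
            h_threshold >= 0, h_threshold <= 80,
            conservation_cutoff >= 0, conservation_cutoff <= 1,
            insilico_cutoff >= 0, insilico_cutoff <= 1)
  structure(list(
    common_af_threshold = common_af_threshold, h_threshold = h_threshold,
    conservation_cutoff = conservation_cutoff,
    insilico_cutoff = insilico_cutoff, residue_classes = residue_classes,
    collagen_genes = normalize_symbol(collagen_genes),
    context_tags = context_tags, mdna_cap = as.integer(mdna_cap)
  ), class = "qual_config")
}

#' Parse an HGVS-style protein change
#'
#' Accepts 3-letter (`p.(Ile588Leu)`, `p.Arg501Ter`) and 1-letter
#' (`p.I588L`, `p.R501X`, `p.R501*`) forms, with or without the `p.` prefix
#' and parentheses.
#'
#' @param protein_change character scalar.
#' @param variant_id used in error messages.
#' @return list with 1-letter `ref`, `alt` (`"*"` for stops) and integer
#'   `pos`.
#' @export
parse_protein_change <- function(protein_change, variant_id = "?") {
  fail <- function() {
    stop(sprintf("variant %s: cannot parse protein change '%s'",
                 variant_id, protein_change), call. = FALSE)
  }
  if (is.na(protein_change) || !nzchar(protein_change)) fail()
  s <- gsub("[()]", "", sub("^p\\.", "", trimws(protein_change)))
  m3 <- regmatches(s, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|\\*)$", s))[[1]]
  if (length(m3) == 4L) {
    ref <- .AA3TO1[m3[2]]
    alt <- if (m3[4] == "*") "*" else .AA3TO1[m3[4]]
    if (is.na(ref) || is.na(alt)) fail()
    return(list(ref = unname(ref), alt = unname(alt),
                pos = as.integer(m3[3])))
  }
  m1 <- regmatches(s, regexec("^([A-Z])(\\d+)([A-Z*])$", s))[[1]]
  if (length(m1) == 4L) {
    alt <- if (m1[4] %in% c("X", "*")) "*" else m1[4]
    if (!m1[2] %in% unlist(.RESIDUE_CLASSES)) fail()
    return(list(ref = m1[2], alt = alt, pos = as.integer(m1[3])))
  }
  fail()
}

.residue_class <- function(aa, classes) {
  hit <- vapply(classes, function(cl) aa %in% cl, logical(1))
  if (!any(hit)) NA_character_ else names(classes)[which(hit)[1]]
}

#' Grade the molecular impact of a variant (0-2)
#'
#' The molecular arm of the protocol: 0 for synonymous/noncoding changes or
#' a benign consensus class; 1 for conservative (same physicochemical
#' class) missense substitutions and small in-frame indels; 2 for
#' disruptive (cross-class) missense, glycine/proline substitutions in
#' fibrillar collagen genes, and truncating (nonsense, frameshift,
#' splice-disrupting) changes. Conservation and in-silico annotation scores
#' at or above their configured cut-offs promote grade 1 to 2; they never
#' promote 0.
#'
#' @param variant a [variant_observation()].
#' @param config a [qual_config()].
#' @return list with integer `points` (0-2) and character `steps` (which
#'   protocol step codes among D, E, F fired).
#' @export
grade_molecular_impact <- function(variant, config = qual_config()) {
  stopifnot(inherits(variant, "variant_observation"))
  if (variant$consequence %in% c("synonymous", "noncoding") ||
      variant$consensus_class %in% c("benign", "likely_benign")) {
    return(list(points = 0L, steps = character()))
  }
  if (variant$consequence %in% c("nonsense", "frameshift",
                                 "splice_disrupting")) {
    return(list(points = 2L, steps = "D"))
  }
  if (variant$consequence == "inframe_indel") {
    base <- 1L
    steps <- "D"
  } else {
    aa <- parse_protein_change(variant$protein_change, variant$variant_id)
    if (aa$alt == "*") return(list(points = 2L, steps = "D"))
    if (variant$gene_symbol %in% config$collagen_genes &&
        (aa$ref %in% c("G", "P") || aa$alt %in% c("G", "P"))) {
      return(list(points = 2L, steps = "D"))
    }
    same <- identical(.residue_class(aa$ref, config$residue_classes),
                      .residue_class(aa$alt, config$residue_classes))
    base <- if (same) 1L else 2L
    steps <- "D"
  }
  if (base == 1L) {
    cons_hit <- !is.na(variant$conservation_score) &&
      variant$conservation_score >= config$conservation_cutoff
    silico_hit <- !is.na(variant$insilico_score) &&
      variant$insilico_score >= config$insilico_cutoff
    if (cons_hit) steps <- c(steps, "E")
    if (silico_hit) steps <- c(steps, "F")
    if (cons_hit || silico_hit) base <- 2L
  }
  list(points = base, steps = steps)
}

#' Assess a gene's relevance to a diagnostic context
#'
#' The gene-disease association step: a gene is `relevant` when the
#' context's mechanism tags intersect the tags of a *primary* disease
#' association; a `synergistic_adjunct` when the only overlap runs through
#' a secondary mechanism (e.g. the skin-inflammation synergy of
#' profilaggrin with connective-tissue dysplasia); `other_disease` when the
#' gene has associations but none intersect the context; and `none` when
#' the association strength is weak or no associations exist.
#'
#' @param gene a [gene_record()].
#' @param context `"EDS"`, `"DD"` or `"other"`.
#' @param config a [qual_config()].
#' @return one of `"relevant"`, `"synergistic_adjunct"`, `"other_disease"`,
#'   `"none"`.
#' @export
assess_gene_relevance <- function(gene, context, config = qual_config()) {
  stopifnot(inherits(gene, "gene_record"))
  if (!context %in% .CONTEXTS) {
    stop(sprintf("unknown context '%s' (expected one of %s)", context,
                 paste(.CONTEXTS, collapse = ", ")), call. = FALSE)
  }
  if (gene$association_strength == "weak" ||
      !length(gene$associated_diseases)) {
    return("none")
  }
  ctx_tags <- config$context_tags[[context]] %||% character()
  primary_hit <- any(vapply(gene$associated_diseases, function(d) {
    d$primary && length(intersect(d$mechanism_tags, ctx_tags)) > 0
  }, logical(1)))
  if (primary_hit) return("relevant")
  secondary_hit <- any(vapply(gene$associated_diseases, function(d) {
    !d$primary && length(intersect(d$mechanism_tags, ctx_tags)) > 0
  }, logical(1)))
  if (secondary_hit) return("synergistic_adjunct")
  "other_disease"
}

.utility_rank <- function(u) match(u, .UTILITY_LEVELS)

#' Score the clinical-evidence points for a patient's primary variant
#'
#' The clinical arm of the protocol: one point for abundant disease-related
#' history findings (H), one for inheritance of the primary variant from a
#' symptomatic relative (I), and one when any adjunct variant acts by a
#' synergistic mechanism (S). Other-mechanism (O-suffixed) adjuncts
#' contribute nothing to the context score. A missing checklist counts as
#' zero findings.
#'
#' @param patient a [patient_record()].
#' @param primary the primary `qualified_variant` for the context.
#' @param adjuncts list of other `qualified_variant`s for the patient.
#' @param config a [qual_config()].
#' @return list with `h_point`, `i_point`, `s_point` (each 0 or 1).
#' @export
score_clinical_evidence <- function(patient, primary, adjuncts = list(),
                                    config = qual_config()) {
  if (is.null(patient$findings)) {
    message(sprintf("patient %s: no findings checklist; history counted as 0",
                    patient$patient_id))
  }
  h <- as.integer(count_findings(patient$findings, "history") >=
                    config$h_threshold)
  v <- primary$variant
  i <- as.integer(v$origin %in% c("maternal", "paternal") &&
                    isTRUE(v$transmitting_relative_symptomatic))
  s <- as.integer(any(vapply(adjuncts, function(a) a$suffix == "S",
                             logical(1))))
  list(h_point = h, i_point = i, s_point = s)
}

#' Qualify one variant against a gene record in a diagnostic context
#'
#' Applies the full per-variant protocol. The population-frequency gate
#' comes first: at or above `common_af_threshold` the utility is capped at
#' uncertain (VUDU) whatever the other evidence. Otherwise utility follows
#' the molecular impact (0 -> VNoDU, 1 -> VUDU, 2 -> VMDU), is raised to
#' VSDU for a disruptive variant in an established gene with clinical H or
#' I evidence, and to VEDU for an exact match to an established protein
#' change. Genes relevant only to another disease yield an `O` suffix (the
#' utility then counts against that diagnosis); secondary-mechanism
#' synergy yields an `S` suffix.
#'
#' @param variant a [variant_observation()].
#' @param gene the matching [gene_record()].
#' @param patient the carrying [patient_record()] (for H/I evidence).
#' @param context `"EDS"`, `"DD"` or `"other"`.
#' @param config a [qual_config()].
#' @return object of class `qualified_variant`: the variant plus `context`,
#'   `impact_points`, `utility`, `suffix` (`"none"`, `"S"`, `"O"`),
#'   `other_diagnosis_label`, `relevance`, and the ordered `rationale` of
#'   protocol step codes that fired.
#' @export
qualify_variant <- function(variant, gene, patient, context = "EDS",
                            config = qual_config()) {
  if (is.null(gene)) {
    stop(sprintf("variant %s: no gene record for symbol %s",
                 variant$variant_id, variant$gene_symbol), call. = FALSE)
  }
  if (!identical(normalize_symbol(variant$gene_symbol), gene$gene_symbol)) {
    stop(sprintf("variant %s gene symbol %s does not match gene record %s",
                 variant$variant_id, variant$gene_symbol,
                 gene$gene_symbol), call. = FALSE)
  }
  impact <- grade_molecular_impact(variant, config)
  relevance <- assess_gene_relevance(gene, context, config)
  steps <- impact$steps
  if (relevance != "none") steps <- c(steps, "G")

  s_condition <- relevance == "synergistic_adjunct"
  o_condition <- relevance == "other_disease"
  if (s_condition && o_condition) {
    stop(sprintf("variant %s: both synergistic and other-mechanism conditions hold; refusing to choose",
                 variant$variant_id), call. = FALSE)
  }
  suffix <- if (s_condition) "S" else if (o_condition) "O" else "none"
  other_label <- NA_character_
  if (suffix == "O") {
    prim <- Filter(function(d) d$primary, gene$associated_diseases)
    lab <- if (length(prim)) prim[[1]]$label else
      gene$associated_diseases[[1]]$label
    other_label <- lab
  }

  pts <- impact$points
  utility <- c("VNoDU", "VUDU", "VMDU")[pts + 1L]
  # H/I clinical evidence speaks to the context disease, so the strong
  # (VSDU) promotion applies only to context-relevant variants
  if (pts == 2L && gene$association_strength == "established" &&
      relevance == "relevant") {
    ev <- score_clinical_evidence(
      patient, list(variant = variant, suffix = suffix), list(), config
    )
    if (ev$h_point == 1L || ev$i_point == 1L) {
      utility <- "VSDU"
      if (ev$h_point == 1L) steps <- c(steps, "H")
      if (ev$i_point == 1L) steps <- c(steps, "I")
    }
  }
  est <- normalize_protein_change(gene$established_variants)
  if (!is.na(variant$protein_change) &&
      normalize_protein_change(variant$protein_change) %in% est) {
    utility <- "VEDU"
  }
  # frequency gate dominates every promotion
  gated <- !is.na(variant$population_af) &&
    variant$population_af >= config$common_af_threshold
  if (gated && .utility_rank(utility) > .utility_rank("VUDU")) {
    utility <- "VUDU"
  }
  if (utility == "VNoDU") pts <- 0L

  structure(list(
    variant = variant, context = context, impact_points = pts,
    utility = utility, suffix = suffix,
    other_diagnosis_label = other_label, relevance = relevance,
    rationale = unique(steps)
  ), class = "qualified_variant")
}

#' Normalize a protein-change string for comparison
#'
#' @param x character vector of HGVS-style protein changes.
#' @return canonical `ref-pos-alt` strings (1-letter codes); `NA` in, `NA`
#'   out; unparseable entries returned as trimmed input.
#' @export
normalize_protein_change <- function(x) {
  vapply(x, function(p) {
    if (is.na(p)) return(NA_character_)
    aa <- tryCatch(parse_protein_change(p), error = function(e) NULL)
    if (is.null(aa)) return(trimws(p))
    sprintf("%s%d%s", aa$ref, aa$pos, aa$alt)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.qualified_variant <- function(x, ...) {
  suf <- switch(x$suffix, none = "", S = "S", O = "O")
  cat(sprintf("<qualified_variant> %s %s: %s%s (%d+) [%s]%s\n",
              x$variant$variant_id, x$variant$gene_symbol, x$utility, suf,
              x$impact_points, paste(x$rationale, collapse = ""),
              if (!is.na(x$other_diagnosis_label))
                paste0(" -> ", x$other_diagnosis_label) else ""))
  invisible(x)
}

#' Aggregate qualified variants into per-patient MDna scores
#'
#' The patient-level step: the context score is the maximum molecular
#' impact over the context-relevant variants (suffix `none` or `S`,
#' relevance `relevant`/`synergistic_adjunct`) plus the H, I and S clinical
#' points, capped at 4. Variants qualified for another diagnosis (`O`)
#' produce separate impact-only scores keyed by that diagnosis label, with
#' the same cap. Patients with no context-relevant variant (or only
#' zero-impact ones) score 0 for the context: clinical points only augment
#' a molecularly scored variant.
#'
#' @param patient a [patient_record()] whose variants are already qualified
#'   for `context` (see [qualify_patient()]).
#' @param context the diagnostic context.
#' @param qualified optional list of `qualified_variant`s; defaults to the
#'   entries of `patient$qualified` matching `context`.
#' @param config a [qual_config()].
#' @return list with integer `score` (0-4) and named integer vector
#'   `other` (per-other-diagnosis scores).
#' @export
aggregate_mdna <- function(patient, context = "EDS", qualified = NULL,
                           config = qual_config()) {
  if (is.null(qualified)) {
    qualified <- Filter(function(q) q$context == context, patient$qualified)
  }
  is_ctx <- vapply(qualified, function(q) {
    q$suffix %in% c("none", "S") &&
      q$relevance %in% c("relevant", "synergistic_adjunct")
  }, logical(1))
  ctx_vars <- qualified[is_ctx]
  impacts <- vapply(ctx_vars, `[[`, integer(1), "impact_points")
  score <- 0L
  if (length(ctx_vars) && max(impacts) > 0L) {
    primary <- ctx_vars[[which.max(impacts)]]
    adjuncts <- qualified[!vapply(qualified, identical, logical(1), primary)]
    ev <- score_clinical_evidence(patient, primary, adjuncts, config)
    score <- min(config$mdna_cap,
                 max(impacts) + ev$h_point + ev$i_point + ev$s_point)
  }
  oth <- qualified[vapply(qualified, function(q) q$suffix == "O",
                          logical(1))]
  other <- integer()
  for (q in oth) {
    lab <- q$other_diagnosis_label
    sc <- min(config$mdna_cap, q$impact_points)
    other[lab] <- max(other[lab] %||% 0L, sc, na.rm = TRUE)
  }
  list(score = as.integer(score), other = other)
}

#' Qualify all of a patient's variants and fill in MDna scores
#'
#' Runs [qualify_variant()] for every variant against a gene catalog in one
#' or more contexts, then [aggregate_mdna()] per context. Variant suffixes
#' and other-diagnosis scores are context-specific; the patient's own
#' diagnosis group chooses the default context.
#'
#' @param patient a [patient_record()].
#' @param catalog named list of [gene_record()]s (names are normalized
#'   symbols), e.g. from [read_gene_catalog()] or [default_gene_catalog()].
#' @param contexts character vector of contexts to score (default: the
#'   patient's diagnosis group, with `"NoEDS"` scored in EDS context).
#' @param config a [qual_config()].
#' @return the patient with `qualified` and `mdna_scores` filled;
#'   `mdna_scores$context` is a named list of per-context scores and
#'   `mdna_scores$other` a named list of other-diagnosis scores.
#' @export
qualify_patient <- function(patient, catalog, contexts = NULL,
                            config = qual_config()) {
  if (is.null(contexts)) {
    contexts <- switch(patient$diagnosis_group, DD = "DD", "EDS")
  }
  qualified <- list()
  for (ctx in contexts) {
    for (v in patient$variants) {
      gene <- catalog[[normalize_symbol(v$gene_symbol)]]
      qualified[[length(qualified) + 1L]] <-
        qualify_variant(v, gene, patient, ctx, config)
    }
  }
  patient$qualified <- qualified
  ctx_scores <- list()
  other_scores <- integer()
  for (ctx in contexts) {
    agg <- aggregate_mdna(patient, ctx,
                          Filter(function(q) q$context == ctx, qualified),
                          config)
    ctx_scores[[ctx]] <- agg$score
    for (lab in names(agg$other)) {
      other_scores[lab] <- max(other_scores[lab] %||% 0L, agg$other[[lab]],
                               na.rm = TRUE)
    }
  }
  patient$mdna_scores <- list(context = ctx_scores,
                              other = as.list(other_scores))
  patient
}
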