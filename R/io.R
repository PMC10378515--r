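# Readers and writers for the interchange formats: variant tables (TSV and
# an annotated-VCF dialect), gene catalogs, findings checklists (long
# format), per-patient JSON reports and flat summaries.

#' Read a variant table
#'
#' TSV dialect: header columns `patient_id`, `gene`, `c_change`,
#' `p_change`, `consequence`, `af`, `consensus`, `origin`,
#' `relative_symptomatic` (optional extras `conservation`, `insilico`,
#' `variant_id`). VCF dialect: a VCF whose `INFO/CSQ` field carries
#' `Allele|SYMBOL|Consequence|HGVSc|HGVSp|AF` annotations (fields beyond
#' these are ignored with a warning); positions are 1-based per the VCF
#' standard. Malformed rows are collected into an error report attached as
#' the `"errors"` attribute, never silently dropped; more than 10%
#' malformed rows aborts with a summary.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return list of [variant_observation()]s with attributes `"errors"`
#'   (character vector) and `"patient_id"` (TSV dialect: per-observation
#'   patient identifiers).
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (dialect == "vcf") return(.read_variants_vcf(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."))
  required <- c("patient_id", "gene", "consequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("variant table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- list()
  pid <- character()
  errors <- character()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    v <- tryCatch(
      variant_observation(
        variant_id = r$variant_id %||% sprintf("%s:%d", r$patient_id, i),
        gene_symbol = r$gene, dna_change = r$c_change %||% NA,
        protein_change = r$p_change %||% NA, consequence = r$consequence,
        population_af = r$af %||% NA,
        consensus_class = r$consensus %||% "uncertain",
        conservation_score = r$conservation %||% NA,
        insilico_score = r$insilico %||% NA,
        origin = r$origin %||% "unknown",
        transmitting_relative_symptomatic =
          isTRUE(as.logical(r$relative_symptomatic %||% FALSE))
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(v)) {
      errors <- c(errors, sprintf("row %d: %s", i, v))
    } else {
      obs[[length(obs) + 1L]] <- v
      pid <- c(pid, as.character(r$patient_id))
    }
  }
  if (nrow(tab) > 0 && length(errors) / nrow(tab) > 0.10) {
    stop(sprintf("more than 10%% of rows malformed (%d of %d):\n%s",
                 length(errors), nrow(tab),
                 paste(utils::head(errors, 5), collapse = "\n")),
         call. = FALSE)
  }
  attr(obs, "errors") <- errors
  attr(obs, "patient_id") <- pid
  obs
}

.VCF_CSQ_FIELDS <- c("Allele", "SYMBOL", "Consequence", "HGVSc", "HGVSp",
                     "AF")

.map_vcf_consequence <- function(x) {
  x <- tolower(x)
  if (grepl("stop_gained|nonsense", x)) "nonsense"
  else if (grepl("frameshift", x)) "frameshift"
  else if (grepl("splice", x)) "splice_disrupting"
  else if (grepl("inframe", x)) "inframe_indel"
  else if (grepl("missense", x)) "missense"
  else if (grepl("synonymous", x)) "synonymous"
  else "noncoding"
}

.read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  csq <- vcfR::extract.info(vcf, element = "CSQ")
  obs <- list()
  errors <- character()
  for (i in seq_len(nrow(fix))) {
    if (is.na(csq[i])) {
      errors <- c(errors, sprintf("record %d: no CSQ annotation", i))
      next
    }
    parts <- strsplit(csq[i], "|", fixed = TRUE)[[1]]
    if (length(parts) > length(.VCF_CSQ_FIELDS)) {
      warning(sprintf(
        "record %d: %d unknown CSQ subfield(s) ignored", i,
        length(parts) - length(.VCF_CSQ_FIELDS)), call. = FALSE)
      parts <- parts[seq_along(.VCF_CSQ_FIELDS)]
    }
    parts <- c(parts, rep("", length(.VCF_CSQ_FIELDS) - length(parts)))
    names(parts) <- .VCF_CSQ_FIELDS
    v <- tryCatch(
      variant_observation(
        variant_id = if (!is.na(fix[i, "ID"]) && nzchar(fix[i, "ID"]))
          fix[i, "ID"] else sprintf("%s:%s", fix[i, "CHROM"],
                                    fix[i, "POS"]),
        gene_symbol = parts[["SYMBOL"]],
        dna_change = if (nzchar(parts[["HGVSc"]])) parts[["HGVSc"]] else NA,
        protein_change = if (nzchar(parts[["HGVSp"]])) parts[["HGVSp"]]
          else NA,
        consequence = .map_vcf_consequence(parts[["Consequence"]]),
        population_af = if (nzchar(parts[["AF"]]))
          as.numeric(parts[["AF"]]) else NA
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(v)) errors <- c(errors, sprintf("record %d: %s", i, v))
    else obs[[length(obs) + 1L]] <- v
  }
  if (nrow(fix) > 0 && length(errors) / nrow(fix) > 0.10 &&
      length(obs) == 0) {
    stop("no parseable VCF records:\n",
         paste(utils::head(errors, 5), collapse = "\n"), call. = FALSE)
  }
  attr(obs, "errors") <- errors
  obs
}

#' Read a gene catalog
#'
#' Tab-delimited with header `symbol`, `diseases`, `product_class`,
#' `tissue_class`, `association_strength`, `established_variants`,
#' `multi_system`. The `diseases` field holds semicolon-separated entries
#' of the form `Mnumber|label|tag1,tag2|primary-or-secondary`;
#' `established_variants` is semicolon-separated.
#'
#' @param path input file; default the packaged curated catalog.
#' @return named list of [gene_record()]s keyed by normalized symbol.
#' @export
read_gene_catalog <- function(path = system.file("extdata",
                                                 "gene_catalog.tsv",
                                                 package = "edsqual")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    diseases <- list()
    if (!is.na(r$diseases) && nzchar(r$diseases)) {
      for (entry in strsplit(r$diseases, ";", fixed = TRUE)[[1]]) {
        f <- strsplit(entry, "|", fixed = TRUE)[[1]]
        if (length(f) != 4L) {
          stop(sprintf("gene %s: malformed disease entry '%s'",
                       r$symbol, entry), call. = FALSE)
        }
        diseases[[length(diseases) + 1L]] <- disease_association(
          f[1], f[2], strsplit(f[3], ",", fixed = TRUE)[[1]],
          primary = identical(f[4], "primary")
        )
      }
    }
    est <- if (is.na(r$established_variants)) character() else
      strsplit(r$established_variants, ";", fixed = TRUE)[[1]]
    g <- gene_record(
      r$symbol, associated_diseases = diseases,
      product_class = r$product_class, tissue_class = r$tissue_class,
      association_strength = r$association_strength,
      established_variants = est,
      multi_system = isTRUE(as.logical(r$multi_system))
    )
    out[[g$gene_symbol]] <- g
  }
  out
}

#' The packaged curated gene catalog
#'
#' @return named list of [gene_record()]s (see [read_gene_catalog()]).
#' @export
default_gene_catalog <- function() read_gene_catalog()

#' Write qualified patients to report files
#'
#' Produces `report.json` (per patient: qualified variants with utility,
#' suffix, rationale step codes, and the per-context and per-other-
#' diagnosis medical-DNA scores) and `summary.tsv` (one row per patient and
#' score). Integer counts and scores round-trip losslessly through
#' [read_report()].
#'
#' @param patients list of qualified [patient_record()]s.
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_report <- function(patients, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  tsv_path <- file.path(dir, "summary.tsv")
  doc <- lapply(patients, function(p) {
    list(
      patient_id = p$patient_id, sex = p$sex,
      diagnosis_group = p$diagnosis_group,
      qualified = lapply(p$qualified, function(q) list(
        variant_id = q$variant$variant_id,
        gene = q$variant$gene_symbol, context = q$context,
        utility = q$utility, suffix = q$suffix,
        impact_points = q$impact_points,
        other_diagnosis = q$other_diagnosis_label,
        rationale = q$rationale
      )),
      mdna = list(context = p$mdna_scores$context %||% list(),
                  other = p$mdna_scores$other %||% list())
    )
  })
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, na = "null",
                       digits = NA)
  rows <- list()
  for (p in patients) {
    for (ctx in names(p$mdna_scores$context %||% list())) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, score_type = "context", label = ctx,
        mdna = p$mdna_scores$context[[ctx]]
      )
    }
    for (lab in names(p$mdna_scores$other %||% list())) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, score_type = "other", label = lab,
        mdna = p$mdna_scores$other[[lab]]
      )
    }
  }
  flat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), score_type = character(),
               label = character(), mdna = integer())
  utils::write.table(flat, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path path to `report.json`.
#' @return list (one element per patient) with `patient_id`, `qualified`
#'   and integer `mdna` scores.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(p) {
    p$mdna$context <- lapply(p$mdna$context, as.integer)
    p$mdna$other <- lapply(p$mdna$other, as.integer)
    p
  })
}

#' Write findings checklists in long format
#'
#' One row per positive finding (`patient_id`, `finding_id`, `present`)
#' plus per-patient `beighton` rows; companion of [read_findings()].
#'
#' @param patients list of [patient_record()]s.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(patients, path) {
  rows <- list()
  for (p in patients) {
    if (is.null(p$findings)) next
    chk <- p$findings
    pos <- c(names(chk$history)[chk$history],
             names(chk$physical)[chk$physical])
    if (length(pos)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, finding_id = pos, value = 1L
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = p$patient_id, finding_id = "beighton",
      value = chk$beighton
    )
  }
  flat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), finding_id = character(),
               value = integer())
  utils::write.table(flat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read findings checklists written by [write_findings()]
#'
#' @param path long-format TSV.
#' @param schema findings schema used to rebuild the 80+40 slots.
#' @return named list of [findings_checklist()]s keyed by patient id.
#' @export
read_findings <- function(path, schema = default_findings_schema()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  hist_ids <- schema$finding_id[schema$domain == "history"]
  phys_ids <- schema$finding_id[schema$domain == "physical"]
  unknown <- setdiff(unique(tab$finding_id),
                     c(hist_ids, phys_ids, "beighton"))
  if (length(unknown)) {
    stop("unknown finding id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in unique(tab$patient_id)) {
    sub <- tab[tab$patient_id == id, ]
    h <- stats::setNames(hist_ids %in% sub$finding_id, hist_ids)
    ph <- stats::setNames(phys_ids %in% sub$finding_id, phys_ids)
    b <- sub$value[sub$finding_id == "beighton"]
    out[[as.character(id)]] <- findings_checklist(
      h, ph, if (length(b)) b[1] else 0L, schema
    )
  }
  out
}
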