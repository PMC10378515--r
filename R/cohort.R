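# Cohort summaries, stratified moments, tests from summary statistics and
# symptom-overlap tabulation.

.SUMMARY_ROWS <- c(
  total = "Total number (No.) T",
  systematic = "Number with systematic evaluations (%T)",
  dna_tested = "with DNA testing (%T)",
  significant_variant = "with potentially significant DNA variant (V)",
  company_eds = "with variant relevant to EDS/DD by company (%V)",
  company_other = "with variant relevant to other Dx by company (%V)",
  author_eds = "with variant relevant to EDS/DD by author (%V)",
  mt_variant = "with primary MT DNA variant (%V)",
  nuclear_mt_variant = "with primary nuclear-to-MT DNA variant (%V)"
)

#' Summarize a cohort's DNA-testing outcomes
#'
#' Tabulates, for the whole EDS group and its female/male strata plus the
#' group not meeting diagnostic criteria, the numbers of patients with
#' systematic checklist evaluations, DNA testing, potentially significant
#' variants, company-report relevance (to the condition or to another
#' diagnosis), author-protocol relevance, and mitochondrial/nuclear-to-
#' mitochondrial variants. Percentages are derived from the integer counts
#' at report time: `%T` rows use the group total as denominator, `%V` rows
#' the number of significant-variant carriers.
#'
#' @param patients list of [patient_record()]s.
#' @return object of class `cohort_summary`: a list with integer matrix
#'   `counts` (rows = categories, columns = All EDS/Female/Male/NoEDS),
#'   character matrix `pct` (formatted percentages, `NA` where the
#'   denominator is undefined or the row is a plain count), and the
#'   denominator type per row.
#' @export
summarize_cohort <- function(patients) {
  stopifnot(all(vapply(patients, inherits, logical(1), "patient_record")))
  eds <- Filter(function(p) p$diagnosis_group == "EDS", patients)
  noeds <- Filter(function(p) p$diagnosis_group == "NoEDS", patients)
  cols <- list(
    `All EDS` = eds,
    Female = Filter(function(p) p$sex == "female", eds),
    Male = Filter(function(p) p$sex == "male", eds),
    NoEDS = noeds
  )
  count_of <- function(group, f) sum(vapply(group, f, logical(1)))
  counts <- vapply(cols, function(g) c(
    total = length(g),
    systematic = count_of(g, function(p) p$systematic),
    dna_tested = count_of(g, function(p) p$dna_tested),
    significant_variant = count_of(g, function(p) p$significant_variant),
    company_eds = count_of(g, function(p) p$company_relevant == "eds"),
    company_other = count_of(g, function(p) p$company_relevant == "other"),
    author_eds = count_of(g, function(p) p$author_eds_relevant),
    mt_variant = count_of(g, function(p) p$mt_variant),
    nuclear_mt_variant = count_of(g, function(p) p$nuclear_mt_variant)
  ), integer(9))
  denom_type <- c(
    total = "none", systematic = "T", dna_tested = "T",
    significant_variant = "none", company_eds = "V", company_other = "V",
    author_eds = "V", mt_variant = "V", nuclear_mt_variant = "V"
  )
  pct <- counts
  pct[] <- NA_character_
  for (r in rownames(counts)) {
    d <- switch(denom_type[[r]], T = counts["total", ],
                V = counts["significant_variant", ], NULL)
    if (!is.null(d)) pct[r, ] <- format_pct(counts[r, ], d)
  }
  structure(list(counts = counts, pct = pct, denom_type = denom_type,
                 row_labels = .SUMMARY_ROWS),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  disp <- x$counts
  disp[] <- as.character(x$counts)
  has_pct <- !is.na(x$pct)
  disp[has_pct] <- sprintf("%d (%s)", x$counts[has_pct], x$pct[has_pct])
  rownames(disp) <- unname(x$row_labels[rownames(x$counts)])
  print(as.data.frame(disp), right = TRUE)
  invisible(x)
}

#' Convert a cohort summary to a data frame
#'
#' @param x a `cohort_summary`.
#' @param ... unused.
#' @return data.frame with one row per category/group combination:
#'   `category`, `group`, `count`, `pct`.
#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  out <- expand.grid(category = rownames(x$counts),
                     group = colnames(x$counts),
                     stringsAsFactors = FALSE)
  out$count <- as.integer(x$counts[cbind(out$category, out$group)])
  out$pct <- x$pct[cbind(out$category, out$group)]
  out
}

#' Per-stratum moments of findings counts
#'
#' Computes n, mean and standard deviation of history-finding and
#' physical-finding counts per stratum (sex or diagnosis group), over
#' patients with a findings checklist. Strata of size zero are omitted;
#' the standard deviation of a single-patient stratum is `NA`.
#'
#' @param patients list of [patient_record()]s.
#' @param stratify_by `"sex"` or `"diagnosis"`.
#' @return data.frame of class `group_moments`: `group`, `n`,
#'   `history_mean`, `history_sd`, `physical_mean`, `physical_sd`.
#' @export
group_moments <- function(patients, stratify_by = c("sex", "diagnosis")) {
  stratify_by <- match.arg(stratify_by)
  with_chk <- Filter(function(p) !is.null(p$findings), patients)
  key <- vapply(with_chk, function(p) {
    if (stratify_by == "sex") p$sex else p$diagnosis_group
  }, character(1))
  hist_n <- vapply(with_chk, function(p) count_findings(p$findings,
                                                        "history"),
                   integer(1))
  phys_n <- vapply(with_chk, function(p) count_findings(p$findings,
                                                        "physical"),
                   integer(1))
  groups <- unique(key)
  rows <- lapply(groups, function(g) {
    sel <- key == g
    data.frame(
      group = g, n = sum(sel),
      history_mean = mean(hist_n[sel]),
      history_sd = if (sum(sel) > 1) stats::sd(hist_n[sel]) else NA_real_,
      physical_mean = mean(phys_n[sel]),
      physical_sd = if (sum(sel) > 1) stats::sd(phys_n[sel]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_moments", class(out))
  out
}

#' Pool stratified moments by n-weighting
#'
#' Recombines per-stratum summary moments into an overall mean (n-weighted)
#' and standard deviation (from the pooled second moment, including the
#' between-stratum component).
#'
#' @param n,mean,sd numeric vectors of per-stratum sizes, means and SDs.
#' @return list with `n`, `mean`, `sd`.
#' @export
pool_moments <- function(n, mean, sd = NULL) {
  stopifnot(length(n) == length(mean), all(n >= 1))
  N <- sum(n)
  m <- sum(n * mean) / N
  s <- NA_real_
  if (!is.null(sd) && !anyNA(sd)) {
    ss <- sum((n - 1) * sd^2 + n * (mean - m)^2)
    s <- sqrt(ss / (N - 1))
  }
  list(n = N, mean = m, sd = s)
}

#' Welch's t test from summary moments
#'
#' Two-sided unequal-variance t test computed from per-group n, mean and
#' SD (no raw data required), with Welch-Satterthwaite degrees of freedom.
#' A pooled-variance (Student) variant is available via `pooled = TRUE`.
#'
#' @param mean_a,sd_a,n_a moments of group A.
#' @param mean_b,sd_b,n_b moments of group B.
#' @param pooled use the pooled-variance Student t instead of Welch.
#' @return list with `t`, `df`, `p_two_tailed`.
#' @export
welch_t_from_moments <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                 pooled = FALSE) {
  if (n_a < 2 || n_b < 2) {
    stop("welch_t_from_moments: both groups need n >= 2", call. = FALSE)
  }
  if (sd_a <= 0 || sd_b <= 0) {
    stop("welch_t_from_moments: both groups need sd > 0", call. = FALSE)
  }
  if (pooled) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_two_tailed = p)
}

#' Tabulate symptom overlap between two condition profiles
#'
#' Compares two symptom-frequency profiles (e.g. a connective-tissue
#' dysplasia cohort versus a post-acute infection cohort) on a shared
#' controlled vocabulary. Labels are lower-cased, trimmed and passed
#' through an optional alias mapping; labels that remain unmatched are
#' counted as unique to their profile (and reported).
#'
#' @param profile_a,profile_b data.frames with columns `symptom` and
#'   `freq_range` (character; a percentage or a "lo-hi" range).
#' @param vocabulary optional named character vector mapping label variants
#'   to canonical symptom labels.
#' @return list with `shared` (data.frame: `symptom`, `freq_a`, `freq_b`),
#'   `only_a`, `only_b` (character vectors), and `counts`
#'   (`shared`/`only_a`/`only_b`).
#' @export
symptom_overlap <- function(profile_a, profile_b, vocabulary = NULL) {
  canon <- function(x) {
    x <- tolower(trimws(as.character(x)))
    if (!is.null(vocabulary)) {
      hit <- x %in% names(vocabulary)
      x[hit] <- unname(vocabulary[x[hit]])
    }
    x
  }
  a <- data.frame(symptom = canon(profile_a$symptom),
                  freq = as.character(profile_a$freq_range))
  b <- data.frame(symptom = canon(profile_b$symptom),
                  freq = as.character(profile_b$freq_range))
  shared_lab <- intersect(a$symptom, b$symptom)
  shared <- data.frame(
    symptom = shared_lab,
    freq_a = a$freq[match(shared_lab, a$symptom)],
    freq_b = b$freq[match(shared_lab, b$symptom)]
  )
  only_a <- setdiff(a$symptom, b$symptom)
  only_b <- setdiff(b$symptom, a$symptom)
  list(shared = shared, only_a = only_a, only_b = only_b,
       counts = c(shared = nrow(shared), only_a = length(only_a),
                  only_b = length(only_b)))
}
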