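# Gene-catalog classification, proportion comparison between gene sets,
# identical/family-similar symbol matching and entome-graph export.

#' Classify a gene set by tissue element/process or product function
#'
#' Tallies genes per class and derives proportions over an explicit
#' denominator. Because published comparisons sometimes use a denominator
#' other than the set size (e.g. after excluding virulence-related genes),
#' the denominator is an argument, defaulting to the number of genes.
#'
#' @param genes list of [gene_record()]s.
#' @param by `"tissue"` or `"product"`.
#' @param denominator proportion denominator (default `length(genes)`).
#' @return data.frame: `class`, `count`, `proportion`, `pct` (formatted
#'   under the report rounding convention).
#' @export
classify_gene_set <- function(genes, by = c("tissue", "product"),
                              denominator = length(genes)) {
  by <- match.arg(by)
  field <- if (by == "tissue") "tissue_class" else "product_class"
  levels <- if (by == "tissue") .TISSUE_CLASSES else .PRODUCT_CLASSES
  for (g in genes) {
    stopifnot(inherits(g, "gene_record"))
    if (is.na(g[[field]]) || !nzchar(g[[field]])) {
      stop(sprintf("gene %s: missing %s", g$gene_symbol, field),
           call. = FALSE)
    }
  }
  cls <- vapply(genes, `[[`, character(1), field)
  counts <- table(factor(cls, levels = levels))
  out <- data.frame(class = levels, count = as.integer(counts))
  out$proportion <- if (denominator > 0) out$count / denominator else 0
  out$pct <- if (denominator > 0) format_pct(out$count, denominator) else
    NA_character_
  out
}

#' N-1 chi-squared test for two independent proportions
#'
#' Pearson's chi-squared on the 2x2 table of successes/failures in two
#' groups, scaled by (N-1)/N where N is the combined sample size; the
#' recommended small-sample form for comparing two independent proportions.
#' p is taken from the chi-squared distribution with 1 degree of freedom
#' (no continuity correction).
#'
#' @param a,n_a successes and total in group A.
#' @param b,n_b successes and total in group B.
#' @param alpha significance level for the flag (default 0.05, raw,
#'   uncorrected).
#' @return list with `chi2` (the N-1 statistic), `chi2_pearson`, `p`,
#'   `significant`.
#' @export
n1_chi_squared <- function(a, n_a, b, n_b, alpha = 0.05) {
  stopifnot(a >= 0, b >= 0, a <= n_a, b <= n_b, n_a + n_b >= 2)
  N <- n_a + n_b
  succ <- a + b
  fail <- (n_a - a) + (n_b - b)
  if (succ == 0 || fail == 0 || n_a == 0 || n_b == 0) {
    stop(sprintf(
      "n1_chi_squared: undefined for a zero margin (successes=%d, failures=%d, n_a=%d, n_b=%d)",
      succ, fail, n_a, n_b), call. = FALSE)
  }
  # Pearson statistic on the 2x2 table, expanded algebraically
  num <- N * (a * (n_b - b) - b * (n_a - a))^2
  chi2_pearson <- num / (succ * fail * as.numeric(n_a) * n_b)
  chi2 <- chi2_pearson * (N - 1) / N
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, chi2_pearson = chi2_pearson, p = p,
       significant = p < alpha)
}

#' Default curated gene-family table
#'
#' Family-similarity between gene symbols is decided curated-table-first,
#' because several published pairs (complement C1R/C3, polymerases
#' POLG/POLD4, IKBKAP/IKBKG, NDUFA11/NDUFAF7, and short-prefix families
#' like WNT or RBM) are not recoverable by any prefix rule. Regular
#' families with a long shared alphabetic prefix fall through to the rule
#' in [match_gene_sets()].
#'
#' @return data.frame with columns `root` and `member`.
#' @export
default_family_table <- function() {
  path <- system.file("extdata", "gene_families.tsv", package = "edsqual")
  fam <- utils::read.delim(path, stringsAsFactors = FALSE)
  fam$member <- normalize_symbol(fam$member)
  fam
}

.prefix_root <- function(x, y, min_len = 4L) {
  ax <- sub("[0-9].*$", "", x)
  ay <- sub("[0-9].*$", "", y)
  if (identical(ax, ay) && nchar(ax) >= min_len &&
      nchar(x) > nchar(ax) && nchar(y) > nchar(ay) && !identical(x, y)) {
    return(ax)
  }
  NA_character_
}

#' Match two gene sets by identity and family similarity
#'
#' `identical` is the exact intersection of normalized symbols. `similar`
#' pairs share a family root, taken first from a curated family table and
#' otherwise from a shared leading alphabetic prefix of at least
#' `min_prefix` characters followed by differing alphanumeric suffixes.
#' Identical symbols are excluded from the similar pairs; symbols matched
#' by neither route are reported as unmatched.
#'
#' @param set_a,set_b character vectors of gene symbols (alias map applied
#'   via [normalize_symbol()]).
#' @param family_table data.frame with `root` and `member` columns
#'   (default [default_family_table()]).
#' @param min_prefix minimum shared alphabetic prefix length (default 4).
#' @return list with `identical` (character), `similar` (data.frame:
#'   `symbol_a`, `symbol_b`, `family_root`), `unmatched_a`, `unmatched_b`.
#' @export
match_gene_sets <- function(set_a, set_b,
                            family_table = default_family_table(),
                            min_prefix = 4L) {
  a <- unique(normalize_symbol(set_a))
  b <- unique(normalize_symbol(set_b))
  ident <- sort(intersect(a, b))
  rest_a <- setdiff(a, ident)
  rest_b <- setdiff(b, ident)
  root_of <- function(sym) {
    i <- match(sym, family_table$member)
    if (is.na(i)) NA_character_ else family_table$root[i]
  }
  pairs <- list()
  for (x in rest_a) {
    rx <- root_of(x)
    for (y in rest_b) {
      ry <- root_of(y)
      root <- if (!is.na(rx) && !is.na(ry) && identical(rx, ry)) rx
              else .prefix_root(x, y, min_prefix)
      if (!is.na(root)) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(symbol_a = x, symbol_b = y, family_root = root)
      }
    }
  }
  similar <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(symbol_a = character(), symbol_b = character(),
               family_root = character())
  matched_a <- c(ident, similar$symbol_a)
  matched_b <- c(ident, similar$symbol_b)
  list(identical = ident, similar = similar,
       unmatched_a = setdiff(a, matched_a),
       unmatched_b = setdiff(b, matched_b))
}

#' Compare two classified gene sets class by class
#'
#' Per-class counts and proportions for both sets with an N-1 chi-squared
#' test per class (skipped, with `NA`, where a margin is zero), plus the
#' identical/similar symbol matching. The denominator for set B is
#' explicit because published comparisons variously use the full set or
#' the set after excluding virulence-related (viral-entry/proliferation)
#' genes.
#'
#' @param genes_a,genes_b lists of [gene_record()]s.
#' @param by `"tissue"` or `"product"`.
#' @param exclude_viral_b drop genes of tissue class `viral_response` from
#'   set B and its denominator before comparing (the host-mechanism-only
#'   convention).
#' @param family_table curated family table for [match_gene_sets()].
#' @param alpha significance level for the per-class flags.
#' @return object of class `gene_set_comparison`: list with `table`
#'   (per-class data.frame), `n_a`, `n_b`, `identical`, `similar`.
#' @export
compare_gene_sets <- function(genes_a, genes_b, by = "tissue",
                              exclude_viral_b = FALSE,
                              family_table = default_family_table(),
                              alpha = 0.05) {
  if (exclude_viral_b) {
    genes_b <- Filter(function(g) g$tissue_class != "viral_response",
                      genes_b)
  }
  ca <- classify_gene_set(genes_a, by)
  cb <- classify_gene_set(genes_b, by)
  n_a <- length(genes_a)
  n_b <- length(genes_b)
  tab <- data.frame(
    class = ca$class, count_a = ca$count, pct_a = ca$pct,
    count_b = cb$count, pct_b = cb$pct,
    chi2 = NA_real_, p = NA_real_, significant = NA
  )
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch(
      n1_chi_squared(tab$count_a[i], n_a, tab$count_b[i], n_b, alpha),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      tab$chi2[i] <- res$chi2
      tab$p[i] <- res$p
      tab$significant[i] <- res$significant
    }
  }
  m <- match_gene_sets(vapply(genes_a, `[[`, character(1), "gene_symbol"),
                       vapply(genes_b, `[[`, character(1), "gene_symbol"),
                       family_table)
  structure(list(table = tab, n_a = n_a, n_b = n_b,
                 identical = m$identical, similar = m$similar),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf("<gene_set_comparison> nA=%d, nB=%d; %d identical, %d similar pair(s)\n",
              x$n_a, x$n_b, length(x$identical), nrow(x$similar)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Build the tripartite gene-mechanism-symptom ("entome") graph
#'
#' Genes converge onto pathogenic mechanisms and symptoms diverge from
#' them: a directed tripartite graph with gene -> mechanism edges for every
#' mechanism tag a gene carries (restricted to `mechanisms`) and
#' mechanism -> symptom edges from the symptom table. Genes with the
#' highest out-degree are the "node" genes of the network. Mechanisms with
#' no incident gene or symptom edge trigger a warning.
#'
#' @param genes list of [gene_record()]s (each should carry at least one
#'   mechanism tag).
#' @param mechanisms character vector of mechanism labels forming the
#'   trunk of the graph.
#' @param symptoms data.frame with columns `symptom`, `mechanisms`
#'   (semicolon-separated mechanism labels) and optional `freq`.
#' @return an [igraph::igraph] directed graph with vertex attributes
#'   `type` (`gene`/`mechanism`/`symptom`) and `freq` (symptoms only).
#' @export
export_entome <- function(genes, mechanisms, symptoms = NULL) {
  edges <- character()
  for (g in genes) {
    for (tag in intersect(g$mechanism_tags, mechanisms)) {
      edges <- c(edges, g$gene_symbol, tag)
    }
  }
  sym_names <- character()
  sym_freq <- numeric()
  if (!is.null(symptoms) && nrow(symptoms)) {
    for (i in seq_len(nrow(symptoms))) {
      mechs <- intersect(strsplit(symptoms$mechanisms[i], ";")[[1]],
                         mechanisms)
      for (mm in mechs) edges <- c(edges, mm, symptoms$symptom[i])
    }
    sym_names <- symptoms$symptom
    sym_freq <- if ("freq" %in% names(symptoms)) symptoms$freq else
      rep(NA_real_, nrow(symptoms))
  }
  gene_names <- vapply(genes, `[[`, character(1), "gene_symbol")
  verts <- data.frame(
    name = c(gene_names, mechanisms, sym_names),
    type = c(rep("gene", length(gene_names)),
             rep("mechanism", length(mechanisms)),
             rep("symptom", length(sym_names)))
  )
  verts$freq <- c(rep(NA_real_, length(gene_names) + length(mechanisms)),
                  as.numeric(sym_freq))
  g <- igraph::graph_from_data_frame(
    if (length(edges)) {
      data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)])
    } else {
      data.frame(from = character(), to = character())
    },
    directed = TRUE, vertices = verts
  )
  deg <- igraph::degree(g, mode = "all")
  orphan <- names(deg)[deg == 0 &
                         igraph::V(g)$type == "mechanism"]
  if (length(orphan)) {
    warning("orphan mechanism(s) with no connected gene or symptom: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  g
}

#' Identify the node genes of an entome graph
#'
#' @param graph an entome graph from [export_entome()].
#' @return character vector of the gene(s) with maximal out-degree.
#' @export
entome_node_genes <- function(graph) {
  is_gene <- igraph::V(graph)$type == "gene"
  if (!any(is_gene)) return(character())
  outd <- igraph::degree(graph, mode = "out")[is_gene]
  names(outd)[outd == max(outd)]
}

#' Write an entome graph to GraphML or JSON node-link format
#'
#' @param graph an igraph graph.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_entome <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    doc <- list(
      nodes = data.frame(id = igraph::V(graph)$name,
                         type = igraph::V(graph)$type,
                         freq = igraph::V(graph)$freq),
      links = igraph::as_data_frame(graph, what = "edges")
    )
    jsonlite::write_json(doc, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an entome graph written by [write_entome()]
#'
#' @param path input file.
#' @param format `"graphml"` or `"json"`.
#' @return an igraph graph.
#' @export
read_entome <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  verts <- doc$nodes
  verts <- data.frame(name = verts$id, type = verts$type,
                      freq = as.numeric(verts$freq))
  igraph::graph_from_data_frame(doc$links, directed = TRUE,
                                vertices = verts)
}

#' Packaged gene-list fixtures
#'
#' Curated symbol lists of genes published as relevant to the
#' connective-tissue dysplasia cohort (`"eds"`) and to COVID-19 infection
#' severity (`"covid"`). These carry the genes named in the source body
#' text, not the full (unpublished) appendix tables.
#'
#' @param which `"eds"` or `"covid"`.
#' @return character vector of normalized symbols.
#' @export
gene_set_fixture <- function(which = c("eds", "covid")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_genes.txt"),
                      package = "edsqual")
  normalize_symbol(readLines(path, warn = FALSE))
}

#' Synthetic classified gene set with stated class marginals
#'
#' Builds minimal [gene_record()]s realizing a named vector of per-class
#' counts. The default reproduces the published tissue-element marginals of
#' the 317-gene EDS-relevant catalog where those are stated (28
#' immune/inflammatory, 101 neural, 42 cardiovascular, 13 clotting, 11
#' skin, 20 joint, 3 renal, 43 other-autonomic) and closes the remainder
#' with bone and muscle allocations; the full per-gene table is not
#' published, so this set is synthetic by construction and suitable only
#' for proportion-level computations.
#'
#' @param counts named integer vector (names = tissue classes).
#' @return list of `gene_record`s, one per counted gene.
#' @export
synthetic_classified_gene_set <- function(counts = c(
  immune_inflammatory = 28, neural = 101, cardiovascular = 42,
  clotting = 13, skin = 11, joint = 20, renal_vascular = 3,
  autonomic_other = 43, bone = 35, muscle = 21
)) {
  stopifnot(all(names(counts) %in% .TISSUE_CLASSES))
  genes <- list()
  i <- 0L
  for (cl in names(counts)) {
    for (k in seq_len(counts[[cl]])) {
      i <- i + 1L
      genes[[i]] <- gene_record(
        sprintf("SYNGENE%03d", i),
        associated_diseases = list(disease_association(
          sprintf("M%06d", 100000 + i), paste("synthetic disease", i),
          mechanism_tags = "other"
        )),
        product_class = "other", tissue_class = cl,
        association_strength = "reported"
      )
    }
  }
  genes
}
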