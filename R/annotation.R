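# Gene -> GO annotation tables. The custom two-column TSV is what makes the
# workflow species-agnostic: any identifier scheme works as long as it is
# consistent between the gene lists and the annotation file.

new_annotation_table <- function(gene_to_terms, source_label = "", species_label = "",
                                 stats = list()) {
  gene_to_terms <- gene_to_terms[lengths(gene_to_terms) > 0]
  gene_to_terms <- gene_to_terms[order(names(gene_to_terms))]
  term_to_genes <- invert_index(gene_to_terms)
  structure(list(
    gene_to_terms = gene_to_terms,
    term_to_genes = term_to_genes,
    source_label = source_label,
    species_label = species_label,
    stats = stats
  ), class = "annotation_table")
}

invert_index <- function(gene_to_terms) {
  if (length(gene_to_terms) == 0) return(list())
  genes <- rep(names(gene_to_terms), lengths(gene_to_terms))
  terms <- unlist(gene_to_terms, use.names = FALSE)
  lapply(split(genes, terms), function(g) sort(unique(g)))
}

#' Genes present in an annotation table
#' @param table An `annotation_table`.
#' @return Sorted character vector of gene identifiers.
#' @export
annotated_genes <- function(table) names(table$gene_to_terms)

#' Read a custom gene-to-GO annotation table
#'
#' Each non-comment line carries at least two tab-separated fields: a gene
#' identifier and a GO term id. Multiple lines per gene merge into one term
#' set. Term ids are resolved to primary ids through the ontology
#' (aliases and obsolete-with-replacement ids are accepted); rows whose term
#' cannot be resolved are dropped and counted. A header row is detected by
#' the absence of "GO:" in the second field of the first data line.
#'
#' @param path Path to a TSV file (optionally gzip-compressed) or connection.
#' @param dag A `go_dag` used to resolve term ids.
#' @param source_label,species_label Free-text provenance labels.
#' @return An `annotation_table`; parsing statistics (rows dropped,
#'   unresolved ids, collapsed duplicates) are in `$stats`.
#' @export
read_annotation_tsv <- function(path, dag, source_label = "custom_tsv", species_label = "") {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2
  n_bad <- sum(!ok)
  fields <- fields[ok]
  if (length(fields) > 0 && !grepl("GO:", fields[[1]][2], fixed = TRUE)) {
    fields <- fields[-1]  # header
  }
  if (length(fields) == 0) format_error("annotation file contains no parseable rows")
  genes <- trimws(vapply(fields, `[`, "", 1))
  terms <- trimws(vapply(fields, `[`, "", 2))
  build_annotation_table(genes, terms, dag, source_label, species_label, n_bad)
}

#' Read a GAF 2.x gene association file
#'
#' Thin dialect of the same reader: column 2 (DB object id) and column 5
#' (GO id) are used; rows whose qualifier (column 4) contains `NOT` are
#' dropped. Header/comment lines start with `!`.
#'
#' @inheritParams read_annotation_tsv
#' @return An `annotation_table`.
#' @export
read_gaf <- function(path, dag, source_label = "gaf", species_label = "") {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 5
  n_bad <- sum(!ok)
  fields <- fields[ok]
  if (length(fields) == 0) format_error("GAF file contains no parseable rows")
  not_row <- vapply(fields, function(f) grepl("NOT", f[4], fixed = TRUE), TRUE)
  fields <- fields[!not_row]
  if (length(fields) == 0) format_error("GAF file contains only NOT-qualified rows")
  genes <- trimws(vapply(fields, `[`, "", 2))
  terms <- trimws(vapply(fields, `[`, "", 5))
  build_annotation_table(genes, terms, dag, source_label, species_label, n_bad)
}

build_annotation_table <- function(genes, terms, dag, source_label, species_label, n_bad) {
  resolved <- resolve_terms_safe(dag, terms)
  n_unresolved <- sum(is.na(resolved))
  if (n_unresolved > 0) {
    catego_log(n_unresolved, " annotation row(s) dropped: unresolvable term id")
  }
  if (n_unresolved > length(resolved) / 2) {
    catego_warn(sprintf("%d of %d annotation rows have unresolvable GO ids — wrong ontology or wrong column order?",
                        n_unresolved, length(resolved)))
  }
  keep <- !is.na(resolved) & nzchar(genes)
  genes <- genes[keep]; resolved <- resolved[keep]
  if (length(genes) == 0) format_error("no annotation rows survived term-id resolution")
  n_rows <- length(genes)
  g2t <- lapply(split(resolved, genes), function(x) sort(unique(x)))
  n_dup <- n_rows - sum(lengths(g2t))
  if (n_dup > 0) catego_log(n_dup, " duplicate (gene, term) row(s) collapsed")
  new_annotation_table(g2t, source_label, species_label,
                       stats = list(rows_unparseable = n_bad,
                                    rows_unresolved = n_unresolved,
                                    rows_duplicate = n_dup,
                                    rows_kept = n_rows))
}

#' Restrict an annotation table to selected GO namespaces
#'
#' Keeps only annotations whose term belongs to one of the selected
#' ontologies (`biological_process`, `molecular_function`,
#' `cellular_component`); genes left without any annotation are removed.
#' The input table is not modified.
#'
#' @param table An `annotation_table`.
#' @param dag The `go_dag` the table was resolved against.
#' @param namespaces Non-empty character subset of the three namespaces.
#' @return A new, filtered `annotation_table`.
#' @export
filter_namespace <- function(table, dag, namespaces) {
  if (length(namespaces) == 0) data_error("namespace selection must be non-empty")
  all_ns <- c("biological_process", "molecular_function", "cellular_component")
  bad <- setdiff(namespaces, all_ns)
  if (length(bad) > 0) data_error(paste0("unknown namespace(s): ", paste(bad, collapse = ", ")))
  g2t <- lapply(table$gene_to_terms, function(ts) ts[dag$namespace[ts] %in% namespaces])
  new_annotation_table(g2t, table$source_label, table$species_label, table$stats)
}

#' Genes annotated to any of a set of terms
#'
#' With `include_descendants = TRUE` (the default), a gene annotated to any
#' descendant of a query term also qualifies — specific annotations are
#' mapped up to the slim-level query terms, as is standard for GO-slim-style
#' category membership.
#'
#' @param table An `annotation_table`.
#' @param dag A `go_dag`.
#' @param terms Character vector of GO term ids.
#' @param include_descendants Propagate membership up from descendant terms?
#' @return Sorted character vector of gene identifiers (possibly empty).
#' @export
genes_with_terms <- function(table, dag, terms, include_descendants = TRUE) {
  terms <- vapply(terms, function(t) resolve_term(dag, t), "", USE.NAMES = FALSE)
  if (include_descendants) {
    terms <- unique(c(terms, unlist(lapply(terms, term_descendants, dag = dag), use.names = FALSE)))
  }
  hit <- terms[terms %in% names(table$term_to_genes)]
  sort(unique(unlist(table$term_to_genes[hit], use.names = FALSE)))
}

#' @export
print.annotation_table <- function(x, ...) {
  n_ann <- sum(lengths(x$gene_to_terms))
  cat(sprintf("<annotation_table> %d genes, %d terms, %d annotations",
              length(x$gene_to_terms), length(x$term_to_genes), n_ann))
  if (nzchar(x$species_label)) cat(" [", x$species_label, "]", sep = "")
  cat("\n")
  invisible(x)
}
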