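# Multi-set operations: Venn partitioning of up to four gene sets,
# iterative background selection, and the result store that collects the
# columns of the cross-analysis heat map.

#' A named collection of up to four gene sets
#' @param sets Named list of character vectors (1-4 sets, unique names).
#' @return An object of class `gene_collection`.
#' @export
gene_collection <- function(sets) {
  if (!is.list(sets) || length(sets) < 1) data_error("need at least one gene set")
  if (length(sets) > 4) data_error("at most four gene sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) || anyDuplicated(names(sets))) {
    data_error("gene sets must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) unique(trimws(s[nzchar(trimws(s))])))
  structure(list(sets = sets), class = "gene_collection")
}

#' Venn partitions of a gene-set collection
#'
#' Splits the union of the sets into disjoint membership classes. Each
#' partition carries a signature string of 0/1 flags, one per set in
#' collection order (e.g. `"110"` = in sets 1 and 2 only). Only non-empty
#' partitions are returned; every gene of the union appears in exactly one.
#'
#' @param coll A `gene_collection` (or a named list of gene sets).
#' @return A list of partitions, each `list(signature, genes)`, ordered by
#'   signature (descending, so single-set regions come after the full
#'   intersection); the collection's set names are attached as
#'   `attr(, "set_names")`.
#' @export
venn_partitions <- function(coll) {
  if (!inherits(coll, "gene_collection")) coll <- gene_collection(coll)
  m <- length(coll$sets)
  genes <- sort(unique(unlist(coll$sets, use.names = FALSE)))
  member <- vapply(coll$sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1)
  sig <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  parts <- split(genes, sig)
  sigs <- names(parts)
  ord <- order(sigs, decreasing = TRUE)
  out <- lapply(ord, function(i) list(signature = sigs[i], genes = unname(parts[[i]])))
  attr(out, "set_names") <- names(coll$sets)
  out
}

check_signature <- function(sig, m) {
  if (!grepl("^[01]+$", sig) || nchar(sig) != m || !grepl("1", sig)) {
    data_error(sprintf("malformed partition signature '%s' (expect %d binary flags, at least one set)", sig, m))
  }
  sig
}

#' Select genes of chosen Venn regions
#'
#' @param partitions Output of [venn_partitions()].
#' @param signatures Character vector of signature strings to select.
#' @return Sorted character vector: union of the genes of the requested
#'   partitions (empty if none of them is non-empty).
#' @export
select_region <- function(partitions, signatures) {
  m <- if (length(partitions) > 0) {
    nchar(partitions[[1]]$signature)
  } else {
    length(attr(partitions, "set_names"))
  }
  signatures <- vapply(signatures, check_signature, "", m = m, USE.NAMES = FALSE)
  hit <- Filter(function(p) p$signature %in% signatures, partitions)
  sort(unique(unlist(lapply(hit, `[[`, "genes"), use.names = FALSE)))
}

#' Derive an enrichment background from a gene selection
#'
#' Wraps a gene set (e.g. another dataset, or a Venn region) as the
#' background universe for a subsequent enrichment run, enabling iterative
#' analysis relative to another dataset rather than to all annotated genes.
#'
#' @param genes Non-empty character vector of gene ids.
#' @param sample Optional sample gene set to pair with the background.
#' @return A `sample_spec` when `sample` is given, otherwise the cleaned
#'   background vector.
#' @export
derive_background <- function(genes, sample = NULL) {
  genes <- unique(trimws(genes[nzchar(trimws(genes))]))
  if (length(genes) == 0) data_error("selected background is empty")
  if (is.null(sample)) return(genes)
  sample_spec(sample, background = genes)
}

#' Create an empty result store
#'
#' The store collects one column per analysis (label, test type, background
#' label, and the per-category results); appending never mutates earlier
#' columns, and duplicate labels are suffix-deduplicated. It is the
#' in-memory session object behind the cross-analysis heat map and is
#' serializable to JSON.
#'
#' @return An object of class `result_store`.
#' @export
result_store <- function() {
  structure(list(columns = list()), class = "result_store")
}

#' Append an analysis to a result store
#'
#' @param store A `result_store`.
#' @param result An `enrichment_result` from [run_sea()] or [run_mwu()].
#' @param label Column label (deduplicated with `_2`, `_3`, ... suffixes).
#' @param background_label Free-text species/background annotation.
#' @return The updated `result_store` (functional update: the input store
#'   is unchanged).
#' @export
store_append <- function(store, result, label, background_label = "") {
  stopifnot(inherits(store, "result_store"), inherits(result, "enrichment_result"))
  existing <- vapply(store$columns, `[[`, "", "label")
  lab <- label
  i <- 1L
  while (lab %in% existing) { i <- i + 1L; lab <- sprintf("%s_%d", label, i) }
  store$columns[[length(store$columns) + 1L]] <- list(
    label = lab, test = attr(result, "test"), background_label = background_label,
    results = as.data.frame(result))
  store
}

#' Heat-map matrix over a result store
#'
#' Rows are category names in first-seen order across columns (cross-species
#' rows match by name); columns are the stored analyses. The cell holds the
#' requested measure; where the measure is undefined for a column's test
#' (delta rank for a Fisher column, normalized term-frequency for an MWU
#' column) or the category was not tested there, the cell is `NA`.
#'
#' @param store A non-empty `result_store`.
#' @param measure One of `"p_adj"`, `"normalized_term_frequency"`,
#'   `"delta_rank"`.
#' @return Numeric matrix, `dimnames = list(categories, analysis labels)`.
#' @export
heatmap_matrix <- function(store, measure = c("p_adj", "normalized_term_frequency", "delta_rank")) {
  if (length(store$columns) == 0) data_error("result store is empty")
  measure <- match.arg(measure)
  cats <- unique(unlist(lapply(store$columns, function(col) col$results$unit), use.names = FALSE))
  labs <- vapply(store$columns, `[[`, "", "label")
  mat <- matrix(NA_real_, nrow = length(cats), ncol = length(labs),
                dimnames = list(cats, labs))
  for (j in seq_along(store$columns)) {
    col <- store$columns[[j]]
    vals <- switch(measure,
      p_adj = col$results$p_adj,
      normalized_term_frequency = if (col$test == "fisher") col$results$effect else rep(NA_real_, nrow(col$results)),
      delta_rank = if (col$test == "mwu") col$results$effect else rep(NA_real_, nrow(col$results)))
    mat[col$results$unit, j] <- vals
  }
  mat
}

#' Export a heat-map matrix as TSV
#'
#' Missing cells (measure undefined for that column's test, or category not
#' tested in that analysis) are written as the `NA` sentinel so mixed
#' Fisher/MWU stores export losslessly.
#'
#' @param mat Matrix from [heatmap_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(mat, path) {
  df <- data.frame(category = rownames(mat),
                   as.data.frame(apply(mat, 2, num_chr, digits = 10, simplify = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Serialize a result store to JSON
#' @param store A `result_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
store_to_json <- function(store, path) {
  payload <- list(columns = lapply(store$columns, function(col) {
    list(label = col$label, test = col$test,
         background_label = col$background_label, results = col$results)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a result store from JSON
#' @param path Path written by [store_to_json()].
#' @return A `result_store`.
#' @export
store_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  store <- result_store()
  cols <- payload$columns
  if (is.data.frame(cols)) {
    cols <- lapply(seq_len(nrow(cols)), function(i) {
      list(label = cols$label[i], test = cols$test[i],
           background_label = cols$background_label[i],
           results = cols$results[[i]])
    })
  }
  for (col in cols) {
    store$columns[[length(store$columns) + 1L]] <- list(
      label = col$label, test = col$test,
      background_label = col$background_label %||% "",
      results = as.data.frame(col$results))
  }
  store
}

#' Export Venn partitions as TSV
#'
#' One row per non-empty partition: signature, size, and the
#' comma-separated gene list.
#'
#' @param partitions Output of [venn_partitions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions_tsv <- function(partitions, path) {
  df <- data.frame(
    signature = vapply(partitions, `[[`, "", "signature"),
    size = vapply(partitions, function(p) length(p$genes), 0L),
    genes = vapply(partitions, function(p) paste(sort(p$genes), collapse = ","), ""),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @export
print.result_store <- function(x, ...) {
  cat(sprintf("<result_store> %d column(s)\n", length(x$columns)))
  for (col in x$columns) {
    cat(sprintf("  %-25s %-7s %d categories  %s\n", col$label, col$test,
                nrow(col$results), col$background_label))
  }
  invisible(x)
}
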