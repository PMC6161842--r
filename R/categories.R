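# High-level cross-species GO categories. A category is a named set of GO
# terms spanning any of the three ontologies; member terms must be mutual
# siblings in the GO graph (no member may be an ancestor or descendant of
# another), so that category counts never double-dip along one lineage.

#' Construct a category
#' @param name Category name (free text, e.g. "Cell cycle").
#' @param terms Non-empty character vector of GO term ids.
#' @return An object of class `category`.
#' @export
category <- function(name, terms) {
  if (!nzchar(name)) data_error("category name must be non-empty")
  terms <- sort(unique(terms))
  if (length(terms) == 0) data_error(sprintf("category '%s' has no terms", name))
  structure(list(name = name, terms = terms), class = "category")
}

#' Construct an ordered set of categories
#' @param categories List of `category` objects.
#' @param label Free-text label for the set.
#' @return An object of class `category_set`.
#' @export
category_set <- function(categories, label = "") {
  nms <- vapply(categories, function(c) c$name, "")
  if (anyDuplicated(nms)) {
    data_error(paste0("duplicate category names: ",
                      paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  structure(list(categories = categories, label = label), class = "category_set")
}

category_names <- function(cats) vapply(cats$categories, function(c) c$name, "")

#' Load a category definition file (TSV or JSON)
#'
#' TSV: one `category_name TAB term_id` row per member term, `#` comments
#' allowed. JSON: an object mapping category names to arrays of term ids.
#' The two encodings load to identical `category_set`s. Term ids are
#' resolved against the ontology; unresolvable ids are dropped with a
#' warning, and the siblings-only rule is validated, violations reported as
#' warnings rather than errors so legacy files still load.
#'
#' @param path Path to the category file (optionally gzip-compressed).
#' @param dag A `go_dag`.
#' @param label Label for the resulting set (defaults to the file name).
#' @return A `category_set`.
#' @export
load_categories <- function(path, dag, label = NULL) {
  label <- label %||% basename(if (is.character(path)) path else "categories")
  lines <- read_text_lines(path)
  body <- trimws(paste(lines, collapse = "\n"))
  if (!nzchar(body)) format_error("category file is empty")
  first <- substr(sub("^\\s+", "", body), 1, 1)
  raw <- if (first %in% c("{", "[")) {
    parsed <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                       error = function(e) format_error(paste0("category JSON parse failure: ", conditionMessage(e))))
    if (!is.list(parsed) || is.null(names(parsed))) {
      format_error("category JSON must be an object mapping names to term arrays")
    }
    lapply(parsed, as.character)
  } else {
    dat <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    fields <- strsplit(dat, "\t", fixed = TRUE)
    if (any(lengths(fields) < 2)) {
      format_error("category TSV rows must have 2 tab-separated fields: name, term id")
    }
    nm <- vapply(fields, `[`, "", 1)
    tm <- vapply(fields, `[`, "", 2)
    if (length(nm) > 0 && !grepl("GO:", tm[1], fixed = TRUE)) { nm <- nm[-1]; tm <- tm[-1] }
    if (length(nm) == 0) format_error("category file has no data rows")
    split(tm, factor(nm, levels = unique(nm)))
  }
  cats <- list()
  n_dropped <- 0L
  for (nm in names(raw)) {
    resolved <- resolve_terms_safe(dag, trimws(raw[[nm]]))
    n_dropped <- n_dropped + sum(is.na(resolved))
    resolved <- resolved[!is.na(resolved)]
    if (length(resolved) == 0) {
      catego_warn(sprintf("category '%s' dropped: no term id resolves in this ontology", nm))
      next
    }
    cats[[length(cats) + 1L]] <- category(nm, resolved)
  }
  if (n_dropped > 0) {
    catego_warn(sprintf("%d category term id(s) did not resolve and were dropped", n_dropped))
  }
  if (length(cats) == 0) format_error("no categories could be loaded")
  cs <- category_set(cats, label)
  for (cat_i in cs$categories) {
    v <- validate_category(dag, cat_i)
    if (nrow(v) > 0) {
      catego_warn(sprintf("category '%s' violates the siblings-only rule: %s",
                          cat_i$name,
                          paste(sprintf("%s is an ancestor of %s", v$ancestor, v$descendant),
                                collapse = "; ")))
    }
  }
  cs
}

#' Write a category set as canonical TSV
#' @param cats A `category_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_categories <- function(cats, path) {
  rows <- do.call(rbind, lapply(cats$categories, function(c) {
    data.frame(category = c$name, term = c$terms, stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
  invisible(path)
}

#' Check the siblings-only rule for one category
#'
#' Category members must form an antichain of the GO DAG: no member term may
#' be an ancestor (equivalently, have another member among its descendants)
#' of another member. Every violating ordered pair is reported.
#'
#' @param dag A `go_dag`.
#' @param cat A `category`.
#' @return A data frame with columns `ancestor` and `descendant`; zero rows
#'   means the category is valid.
#' @export
validate_category <- function(dag, cat) {
  terms <- vapply(cat$terms, function(t) resolve_term(dag, t), "", USE.NAMES = FALSE)
  viol <- list()
  for (t in terms) {
    anc <- term_ancestors(dag, t)
    offenders <- intersect(anc, setdiff(terms, t))
    for (a in offenders) viol[[length(viol) + 1L]] <- c(a, t)
  }
  if (length(viol) == 0) {
    return(data.frame(ancestor = character(), descendant = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, viol)
  out <- data.frame(ancestor = m[, 1], descendant = m[, 2], stringsAsFactors = FALSE)
  out <- out[order(out$ancestor, out$descendant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes belonging to a category
#'
#' Delegates to [genes_with_terms()] over the category's member terms.
#'
#' @param cat A `category`.
#' @param table An `annotation_table`.
#' @param dag A `go_dag`.
#' @param include_descendants Propagate annotations up from descendant terms
#'   (default `TRUE`; slim-level category terms would otherwise be nearly
#'   empty for specifically-annotated genomes).
#' @return Sorted character vector of gene ids.
#' @export
category_genes <- function(cat, table, dag, include_descendants = TRUE) {
  genes_with_terms(table, dag, cat$terms, include_descendants = include_descendants)
}

#' Built-in high-level category set
#'
#' A reconstruction of thirteen broad, cross-species functional categories
#' (cell cycle, differentiation, metabolism, signalling, ...) over generic
#' GO-slim-level term ids, shipped as a replaceable data file. The exact
#' term membership is this package's own curation over the generic GO slim;
#' users analysing real data should review or replace it
#' (see `system.file("extdata", "default_categories.tsv", package = "catego")`).
#'
#' @param dag A `go_dag` to resolve the term ids against.
#' @return A `category_set` (categories whose terms are absent from `dag`
#'   are dropped with a warning).
#' @export
default_categories <- function(dag) {
  path <- system.file("extdata", "default_categories.tsv", package = "catego")
  load_categories(path, dag, label = "default")
}

#' @export
print.category_set <- function(x, ...) {
  cat(sprintf("<category_set> '%s': %d categories\n", x$label, length(x$categories)))
  for (c in utils::head(x$categories, 15)) {
    cat(sprintf("  %-40s %d terms\n", c$name, length(c$terms)))
  }
  if (length(x$categories) > 15) cat("  ...\n")
  invisible(x)
}

#' @export
print.category <- function(x, ...) {
  cat(sprintf("<category> '%s': %s\n", x$name, paste(x$terms, collapse = ", ")))
  invisible(x)
}
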