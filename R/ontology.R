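# Gene Ontology structure: OBO parsing, ancestor/descendant closure and
# undirected shortest-path distances between terms. The hierarchy is a DAG
# over the parent relations the caller selects (is_a, part_of by default).

TERMID_RE <- "^GO:[0-9]{7}$"

is_termid <- function(x) grepl(TERMID_RE, x)

#' Parse a Gene Ontology OBO file into a DAG
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and builds a directed acyclic graph of
#' GO terms. Only the requested relation types contribute hierarchy edges;
#' `is_a` and `relationship: part_of` are the GO-slim-style defaults.
#' Obsolete terms are retained (flagged, with no parents) so that historical
#' identifiers can still be resolved through their `replaced_by` pointers,
#' and `alt_id` aliases are indexed.
#'
#' @param path Path to an OBO file (optionally gzip-compressed), a
#'   connection, or a character vector of OBO lines.
#' @param relations Character subset of `c("is_a", "part_of")`: relation
#'   types treated as hierarchy (parent) edges.
#' @return An object of class `go_dag` with elements `ids`, `name`,
#'   `namespace`, `obsolete`, `parents`, `children`, `alt`, `replaced_by`,
#'   `roots` and `n_edges`.
#' @examples
#' obo <- c("format-version: 1.2", "",
#'          "[Term]", "id: GO:0000001", "name: root",
#'          "namespace: biological_process", "",
#'          "[Term]", "id: GO:0000002", "name: child",
#'          "namespace: biological_process", "is_a: GO:0000001 ! root")
#' dag <- parse_obo(obo)
#' term_ancestors(dag, "GO:0000002")
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  lines <- if (is.character(path) && length(path) > 1) path else read_text_lines(path)

  terms <- list()
  cur <- NULL
  cur_line <- 0L
  in_term <- FALSE

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      format_error(sprintf("OBO [Term] stanza starting at line %d has no id", cur$start))
    }
    if (!is_termid(cur$id)) {
      format_error(sprintf("line %d: malformed term id '%s'", cur$id_line, cur$id))
    }
    terms[[cur$id]] <<- cur
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s*!.*$", "", lines[i])  # strip trailing comments
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "[")) {
      flush_term()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(start = i, parents = character(), rel = character(),
                               alt = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) == 0) {
      format_error(sprintf("line %d: malformed OBO tag line '%s'", i, lines[i]))
    }
    key <- m[2]; val <- trimws(m[3])
    if (key == "id") { cur$id <- val; cur$id_line <- i }
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") {
      if (!is_termid(val)) format_error(sprintf("line %d: malformed is_a target '%s'", i, val))
      cur$parents <- c(cur$parents, val); cur$rel <- c(cur$rel, "is_a")
    } else if (key == "relationship") {
      rm2 <- strsplit(val, "\\s+")[[1]]
      if (length(rm2) < 2) format_error(sprintf("line %d: malformed relationship '%s'", i, val))
      if (rm2[1] %in% c("is_a", "part_of")) {
        if (!is_termid(rm2[2])) format_error(sprintf("line %d: malformed relationship target '%s'", i, rm2[2]))
        cur$parents <- c(cur$parents, rm2[2]); cur$rel <- c(cur$rel, rm2[1])
      }
    } else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "replaced_by") cur$replaced_by <- val
  }
  flush_term()

  if (length(terms) == 0) format_error("no [Term] stanzas found in OBO input")

  ids <- names(terms)
  nm <- vapply(terms, function(t) t$name %||% "", "", USE.NAMES = TRUE)
  ns <- vapply(terms, function(t) t$namespace %||% "", "", USE.NAMES = TRUE)
  obs <- vapply(terms, function(t) isTRUE(t$obsolete), TRUE, USE.NAMES = TRUE)
  parents <- lapply(terms, function(t) {
    if (isTRUE(t$obsolete)) return(character())
    keep <- t$rel %in% relations
    sort(unique(t$parents[keep]))
  })
  names(parents) <- ids

  missing <- setdiff(unique(unlist(parents)), ids)
  if (length(missing) > 0) {
    format_error(paste0("parent term(s) referenced but not defined: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }

  # alt_id index; must map injectively onto primary ids
  alt_pairs <- do.call(rbind, lapply(ids, function(id) {
    a <- terms[[id]]$alt
    if (length(a) == 0) NULL else cbind(a, id)
  }))
  alt <- character()
  if (!is.null(alt_pairs)) {
    dup <- alt_pairs[duplicated(alt_pairs[, 1]) | duplicated(alt_pairs[, 1], fromLast = TRUE), , drop = FALSE]
    if (nrow(dup) > 0) {
      format_error(paste0("alt_id claimed by more than one term: ",
                          paste(unique(dup[, 1]), collapse = ", ")))
    }
    alt <- stats::setNames(alt_pairs[, 2], alt_pairs[, 1])
  }

  repl <- vapply(terms, function(t) t$replaced_by %||% NA_character_, "", USE.NAMES = TRUE)

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) children[[id]] <- character()
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children <- lapply(children, sort)

  dag <- structure(list(
    ids = sort(ids),
    name = nm, namespace = ns, obsolete = obs,
    parents = parents, children = children,
    alt = alt, replaced_by = repl,
    roots = sort(ids[!obs & lengths(parents) == 0]),
    n_edges = sum(lengths(parents)),
    relations = relations,
    cache = new.env(parent = emptyenv())
  ), class = "go_dag")

  assert_acyclic(dag)
  dag
}

# Kahn topological sort; on failure, walk parent pointers among the residue
# to exhibit one concrete cycle in the error message.
assert_acyclic <- function(dag) {
  active <- dag$ids[!dag$obsolete[dag$ids]]
  remaining <- stats::setNames(lengths(dag$parents[active]), active)
  queue <- names(remaining)[remaining == 0]
  children <- dag$children
  n_done <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    n_done <- n_done + 1L
    for (ch in children[[v]]) {
      remaining[[ch]] <- remaining[[ch]] - 1L
      if (remaining[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (n_done < length(active)) {
    residue <- names(remaining)[remaining > 0]
    # follow parents within the residue until a repeat appears
    seen <- character()
    v <- residue[[1]]
    while (!(v %in% seen)) {
      seen <- c(seen, v)
      v <- intersect(dag$parents[[v]], residue)[[1]]
    }
    cyc <- c(seen[which(seen == v):length(seen)], v)
    stop_catego(paste0("cyclic hierarchy detected: ", paste(cyc, collapse = " -> ")),
                "catego_validation_error")
  }
  invisible(dag)
}

#' Resolve a GO identifier to its primary term id
#'
#' Primary ids map to themselves; `alt_id` aliases map to their primary
#' term; obsolete terms follow `replaced_by` (transitively). Unknown ids and
#' obsolete terms without a replacement raise distinguishable conditions
#' (`catego_unknown_term`, `catego_obsolete_term`).
#'
#' @param dag A `go_dag`.
#' @param id A single GO term identifier.
#' @return The primary, non-obsolete term id.
#' @export
resolve_term <- function(dag, id) {
  seen <- character()
  cur <- id
  repeat {
    if (cur %in% seen) {
      stop_catego(sprintf("replaced_by loop while resolving '%s'", id), "catego_validation_error")
    }
    seen <- c(seen, cur)
    if (cur %in% names(dag$alt)) {
      cur <- unname(dag$alt[[cur]])
      next
    }
    if (!(cur %in% names(dag$obsolete))) {
      stop_catego(sprintf("unknown term id '%s'", id), "catego_unknown_term")
    }
    if (!dag$obsolete[[cur]]) return(cur)
    repl <- dag$replaced_by[[cur]]
    if (is.na(repl)) {
      stop_catego(sprintf("term '%s' is obsolete with no replacement", id), "catego_obsolete_term")
    }
    cur <- repl
  }
}

# Vectorised, non-throwing resolve; NA where unresolvable.
resolve_terms_safe <- function(dag, ids) {
  vapply(ids, function(id) {
    tryCatch(resolve_term(dag, id), catego_error = function(e) NA_character_)
  }, "", USE.NAMES = FALSE)
}

dag_has_term <- function(dag, id) id %in% names(dag$obsolete) || id %in% names(dag$alt)

closure_over <- function(dag, id, link_field) {
  cache_key <- paste0(link_field, ":", id)
  hit <- dag$cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  links <- dag[[link_field]]
  out <- character()
  frontier <- links[[id]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(links[frontier], use.names = FALSE))
  }
  out <- sort(out)
  assign(cache_key, out, envir = dag$cache)
  out
}

#' Ancestors of a term (transitive closure over parent edges)
#'
#' @param dag A `go_dag`.
#' @param id A GO term id (primary, alias, or obsolete-with-replacement).
#' @return Sorted character vector of ancestor term ids, excluding `id`.
#' @export
term_ancestors <- function(dag, id) closure_over(dag, resolve_term(dag, id), "parents")

#' Descendants of a term (transitive closure over child edges)
#'
#' @inheritParams term_ancestors
#' @return Sorted character vector of descendant term ids, excluding `id`.
#' @export
term_descendants <- function(dag, id) closure_over(dag, resolve_term(dag, id), "children")

# Undirected adjacency (parents + children), each neighbour list sorted so
# BFS expands frontiers in deterministic TermID order.
dag_neighbors <- function(dag) {
  hit <- dag$cache[["neighbors"]]
  if (!is.null(hit)) return(hit)
  nb <- stats::setNames(
    lapply(names(dag$parents), function(id) sort(union(dag$parents[[id]], dag$children[[id]]))),
    names(dag$parents))
  assign("neighbors", nb, envir = dag$cache)
  nb
}

# BFS distances from one term to all terms (named integer vector; terms not
# reached are absent). Sorted frontier expansion for determinism.
term_distances_from <- function(dag, from) {
  key <- paste0("dist:", from)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  nb <- dag_neighbors(dag)
  dist <- stats::setNames(0L, from)
  frontier <- from
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- sort(unique(unlist(nb[frontier], use.names = FALSE)))
    nxt <- nxt[!(nxt %in% names(dist))]
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  assign(key, dist, envir = dag$cache)
  dist
}

#' Undirected shortest-path distance between two GO terms
#'
#' Edge length is 1 per hierarchy edge, traversed in either direction
#' (breadth-first search). Terms in disconnected parts of the ontology
#' (e.g. different namespaces) are unreachable from one another and yield
#' `NA`; no artificial super-root is added.
#'
#' @param dag A `go_dag`.
#' @param a,b GO term ids (resolved through [resolve_term()]).
#' @return Non-negative integer path length, or `NA_integer_` if no path.
#' @export
term_distance <- function(dag, a, b) {
  a <- resolve_term(dag, a)
  b <- resolve_term(dag, b)
  if (identical(a, b)) return(0L)
  d <- term_distances_from(dag, a)
  if (b %in% names(d)) unname(d[[b]]) else NA_integer_
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- table(x$namespace[!x$obsolete])
  cat(sprintf("<go_dag> %d terms (%d obsolete), %d edges [%s]\n",
              length(x$ids), sum(x$obsolete), x$n_edges,
              paste(x$relations, collapse = "+")))
  if (length(ns)) {
    cat("  namespaces:", paste(sprintf("%s (%d)", names(ns), ns), collapse = ", "), "\n")
  }
  cat("  roots:", paste(utils::head(x$roots, 5), collapse = ", "),
      if (length(x$roots) > 5) "..." else "", "\n")
  invisible(x)
}
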