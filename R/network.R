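# Interaction-network analysis: BioGRID TAB-style parsing, undirected
# simple graphs per interaction kind, subgraph extraction with
# breadth-first connector search, GO-graph semantic edge lengths, and
# receptor-ligand pairing across two datasets.

BIOGRID_DEFAULT_COLUMNS <- list(
  a = "Official Symbol Interactor A",
  b = "Official Symbol Interactor B",
  kind = "Experimental System Type",
  organism_a = "Organism Name Interactor A",
  organism_b = "Organism Name Interactor B"
)

#' Read a BioGRID TAB-style interaction table
#'
#' Expects a header row; by default the BioGRID TAB3 official-symbol and
#' experimental-system-type columns are used, remappable through `columns`
#' for other layouts. Self-loop rows are dropped, and rows failing the
#' organism filter (matched against both interactors' organism columns,
#' when present) are dropped. Duplicate A-B / B-A rows are kept at this
#' stage; [build_graph()] collapses them into edge multiplicities.
#'
#' @param path Path to a TSV file (optionally gzip-compressed).
#' @param organism_filter Optional organism name; `NULL` keeps all rows.
#' @param columns Named list mapping `a`, `b`, `kind` (and optionally
#'   `organism_a`, `organism_b`) to header names.
#' @return Data frame of interaction records: `a`, `b`, `kind`
#'   (`"physical"`/`"genetic"`), `source_row`.
#' @export
read_interactions <- function(path, organism_filter = NULL, columns = BIOGRID_DEFAULT_COLUMNS) {
  con <- open_text(path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- unlist(columns[c("a", "b", "kind")])
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    format_error(paste0("interaction file lacks expected column(s): ",
                        paste(missing, collapse = ", "),
                        " — remap with the 'columns' argument"))
  }
  rec <- data.frame(a = trimws(df[[columns$a]]), b = trimws(df[[columns$b]]),
                    kind = tolower(trimws(df[[columns$kind]])),
                    source_row = seq_len(nrow(df)) + 1L,  # +1: header line
                    stringsAsFactors = FALSE)
  if (!is.null(organism_filter)) {
    org_cols <- intersect(unlist(columns[c("organism_a", "organism_b")]), names(df))
    if (length(org_cols) > 0) {
      keep <- Reduce(`&`, lapply(org_cols, function(cn) df[[cn]] == organism_filter))
      rec <- rec[keep, , drop = FALSE]
    }
  }
  rec <- rec[rec$a != rec$b & nzchar(rec$a) & nzchar(rec$b), , drop = FALSE]
  bad_kind <- !(rec$kind %in% c("physical", "genetic"))
  if (any(bad_kind)) {
    catego_log(sum(bad_kind), " record(s) with unrecognized interaction kind dropped")
    rec <- rec[!bad_kind, , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Build an undirected interaction graph from records
#'
#' Collapses records into a simple undirected graph per interaction kind;
#' repeated observations of the same gene pair (in either orientation) are
#' kept as an edge multiplicity count.
#'
#' @param records Data frame from [read_interactions()].
#' @param kinds Non-empty subset of `c("physical", "genetic")`.
#' @return An object of class `interaction_graph` with `nodes` (sorted) and
#'   `edges` (data frame `a`, `b`, `kind`, `multiplicity`, with `a < b`).
#' @export
build_graph <- function(records, kinds = c("physical", "genetic")) {
  kinds <- match.arg(kinds, c("physical", "genetic"), several.ok = TRUE)
  rec <- records[records$kind %in% kinds, , drop = FALSE]
  if (nrow(rec) == 0) {
    edges <- data.frame(a = character(), b = character(), kind = character(),
                        multiplicity = integer(), stringsAsFactors = FALSE)
  } else {
    lo <- pmin(rec$a, rec$b); hi <- pmax(rec$a, rec$b)
    key <- paste(lo, hi, rec$kind, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2),
                        kind = vapply(parts, `[`, "", 3),
                        multiplicity = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b, edges$kind), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
                 kinds = kinds, cache = new.env(parent = emptyenv())),
            class = "interaction_graph")
}

graph_adjacency <- function(g) {
  hit <- g$cache[["adj"]]
  if (!is.null(hit)) return(hit)
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (nd in g$nodes) adj[[nd]] <- character()
  # one undirected neighbour set per node, kinds merged
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$a[i]; b <- g$edges$b[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  assign("adj", adj, envir = g$cache)
  adj
}

# BFS distances from one node; frontier expanded in sorted-GeneID order.
graph_distances_from <- function(g, from) {
  adj <- graph_adjacency(g)
  dist <- stats::setNames(0L, from)
  frontier <- from
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- sort(unique(unlist(adj[frontier], use.names = FALSE)))
    nxt <- nxt[!(nxt %in% names(dist))]
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

induced_subgraph <- function(g, keep) {
  edges <- g$edges[g$edges$a %in% keep & g$edges$b %in% keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(intersect(g$nodes, keep)), edges = edges,
                 kinds = g$kinds, cache = new.env(parent = emptyenv())),
            class = "interaction_graph")
}

#' Extract a subgraph around selected genes, adding connector nodes
#'
#' Builds the induced subgraph on the selected genes, then adds up to
#' `max_connectors` "connecting nodes": non-selected genes lying on at
#' least one shortest path (in the complete graph, breadth-first search)
#' between a pair of selected genes. Candidates are ranked by the number of
#' selected pairs whose shortest-path distance they realize, ties broken
#' lexicographically by gene id.
#'
#' `selected` may be a single character vector (one group) or a named list
#' of gene sets from different analyses/selections; group labels colour the
#' nodes in exports. Genes in several groups keep the first group's label.
#'
#' @param g An `interaction_graph` (the complete graph).
#' @param selected Character vector, or named list of character vectors.
#' @param max_connectors Non-negative connector budget (default 0).
#' @return An object of class `network_view`: `graph` (induced subgraph),
#'   `groups` (named vector gene -> group label, connectors labelled
#'   `"connector"`), `connectors`, and `connector_candidates` (ranked data
#'   frame of all candidates with pair counts).
#' @export
subgraph_with_connectors <- function(g, selected, max_connectors = 0) {
  if (max_connectors < 0) data_error("max_connectors must be non-negative")
  groups_in <- if (is.list(selected)) selected else list(selected = selected)
  if (is.null(names(groups_in)) || any(!nzchar(names(groups_in)))) {
    data_error("selection groups must be named")
  }
  sel_all <- unique(unlist(groups_in, use.names = FALSE))
  sel <- intersect(sel_all, g$nodes)
  if (length(sel) == 0) data_error("no selected genes in graph")
  sel <- sort(sel)

  # Connector candidates: v (not selected) lies on a shortest s-t path
  # iff dist(s, v) + dist(v, t) == dist(s, t).
  dmaps <- lapply(sel, function(s) graph_distances_from(g, s))
  names(dmaps) <- sel
  counts <- integer(0)
  if (length(sel) >= 2) {
    hits <- list()
    for (i in seq_len(length(sel) - 1)) {
      di <- dmaps[[i]]
      for (j in seq(i + 1, length(sel))) {
        t <- sel[j]
        if (!(t %in% names(di))) next
        dst <- di[[t]]
        dj <- dmaps[[j]]
        common <- intersect(names(di), names(dj))
        on_path <- common[di[common] + dj[common] == dst]
        hits[[length(hits) + 1L]] <- setdiff(on_path, sel)
      }
    }
    all_hits <- unlist(hits, use.names = FALSE)
    if (length(all_hits) > 0) {
      tab <- table(all_hits)
      counts <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  candidates <- if (length(counts) > 0) {
    cd <- data.frame(gene = names(counts), pairs_covered = unname(counts),
                     stringsAsFactors = FALSE)
    cd <- cd[order(-cd$pairs_covered, cd$gene), , drop = FALSE]
    rownames(cd) <- NULL
    cd
  } else {
    data.frame(gene = character(), pairs_covered = integer(), stringsAsFactors = FALSE)
  }
  connectors <- utils::head(candidates$gene, max_connectors)

  keep <- c(sel, connectors)
  sub <- induced_subgraph(g, keep)
  groups <- character(0)
  for (gn in names(groups_in)) {
    new <- setdiff(intersect(groups_in[[gn]], sel), names(groups))
    groups[new] <- gn
  }
  groups[connectors] <- "connector"
  structure(list(graph = sub, groups = groups, connectors = connectors,
                 connector_candidates = candidates, edge_lengths = NULL),
            class = "network_view")
}

#' Semantic edge length between two interacting genes
#'
#' The mean of the undirected shortest-path distances in the GO graph over
#' all pairs (t1, t2) with t1 annotated to gene `a` and t2 to gene `b`.
#' Unreachable term pairs (e.g. across namespaces) are excluded from the
#' mean; if either gene is unannotated or no pair is reachable the length
#' is missing (`NA`). A small positive floor (`epsilon`) is applied so
#' genes with identical annotations still get a drawable positive edge.
#'
#' @param dag A `go_dag`.
#' @param table An `annotation_table`.
#' @param a,b Gene identifiers.
#' @param epsilon Positive floor for zero-mean lengths (default 0.01).
#' @return Positive numeric length, or `NA_real_` when undefined.
#' @export
edge_length <- function(dag, table, a, b, epsilon = 0.01) {
  ta <- table$gene_to_terms[[a]]
  tb <- table$gene_to_terms[[b]]
  if (is.null(ta) || is.null(tb)) return(NA_real_)
  dists <- unlist(lapply(ta, function(t1) {
    d <- term_distances_from(dag, t1)
    d[intersect(names(d), tb)]
  }), use.names = FALSE)
  if (length(dists) == 0) return(NA_real_)
  max(mean(dists), epsilon)
}

#' Attach semantic edge lengths to a network view
#'
#' @param view A `network_view`.
#' @param dag A `go_dag`.
#' @param table An `annotation_table`.
#' @param epsilon Floor passed to [edge_length()].
#' @return The view with `edge_lengths` filled (named by `"a|b"` edge keys).
#' @export
add_edge_lengths <- function(view, dag, table, epsilon = 0.01) {
  e <- view$graph$edges
  if (nrow(e) == 0) { view$edge_lengths <- numeric(0); return(view) }
  pairs <- unique(e[, c("a", "b")])
  lens <- mapply(function(a, b) edge_length(dag, table, a, b, epsilon),
                 pairs$a, pairs$b)
  view$edge_lengths <- stats::setNames(as.numeric(lens), paste(pairs$a, pairs$b, sep = "|"))
  view
}

#' Receptor-ligand pairs between two datasets
#'
#' Scans interaction records for pairs where one interactor belongs to
#' dataset 1 and the other to dataset 2 and BOTH carry a receptor or ligand
#' GO annotation (descendant-expanded by default). Historical role term ids
#' are tolerated through [resolve_term()] (obsolete-with-replacement);
#' override `receptor_term` / `ligand_term` if your ontology names the
#' roles differently. With `strict = TRUE` only complementary pairs (one
#' receptor, one ligand) are reported.
#'
#' @param records Data frame from [read_interactions()].
#' @param set1,set2 Character vectors of gene ids (the two datasets).
#' @param table An `annotation_table`.
#' @param dag A `go_dag`.
#' @param receptor_term,ligand_term GO ids marking the two roles (defaults:
#'   signaling receptor activity `GO:0004872`, receptor ligand activity
#'   `GO:0048018`).
#' @param strict Require one receptor and one ligand per pair?
#' @param include_descendants Expand role terms to their descendants?
#' @return Data frame `gene1` (from set 1), `gene2` (from set 2), `roles1`,
#'   `roles2` (comma-joined role labels), sorted, one row per unique pair.
#' @export
receptor_ligand_pairs <- function(records, set1, set2, table, dag,
                                  receptor_term = "GO:0004872",
                                  ligand_term = "GO:0048018",
                                  strict = FALSE, include_descendants = TRUE) {
  role_genes <- function(term, what) {
    tryCatch(genes_with_terms(table, dag, term, include_descendants),
             catego_error = function(e) {
               data_error(sprintf("%s term '%s' does not resolve in this ontology — supply the role term ids explicitly (%s)",
                                  what, term, conditionMessage(e)))
             })
  }
  receptors <- role_genes(receptor_term, "receptor")
  ligands <- role_genes(ligand_term, "ligand")
  roles_of <- function(gene) {
    r <- c(if (gene %in% receptors) "receptor", if (gene %in% ligands) "ligand")
    if (length(r) == 0) NA_character_ else paste(r, collapse = ",")
  }
  out <- list()
  for (i in seq_len(nrow(records))) {
    a <- records$a[i]; b <- records$b[i]
    for (ori in list(c(a, b), c(b, a))) {
      g1 <- ori[1]; g2 <- ori[2]
      if (!(g1 %in% set1 && g2 %in% set2)) next
      r1 <- roles_of(g1); r2 <- roles_of(g2)
      if (is.na(r1) || is.na(r2)) next
      if (strict) {
        complementary <- (grepl("receptor", r1) && grepl("ligand", r2)) ||
                         (grepl("ligand", r1) && grepl("receptor", r2))
        if (!complementary) next
      }
      out[[length(out) + 1L]] <- data.frame(gene1 = g1, gene2 = g2,
                                            roles1 = r1, roles2 = r2,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      roles1 = character(), roles2 = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, out))
  df <- df[order(df$gene1, df$gene2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a network view as an edge-list TSV
#'
#' Columns: node1, node2, kind, multiplicity, length (NA when lengths were
#' not computed or are undefined), group1, group2.
#'
#' @param view A `network_view`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(view, path) {
  e <- view$graph$edges
  key <- paste(e$a, e$b, sep = "|")
  lens <- if (is.null(view$edge_lengths)) rep(NA_real_, nrow(e)) else unname(view$edge_lengths[key])
  df <- data.frame(node1 = e$a, node2 = e$b, kind = e$kind,
                   multiplicity = e$multiplicity,
                   length = num_chr(lens, digits = 6),
                   group1 = unname(view$groups[e$a]),
                   group2 = unname(view$groups[e$b]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Export a network view as GraphML
#'
#' Node attributes: `group`, `connector`; edge attributes: `kind`,
#' `multiplicity`, `length` (when computed).
#'
#' @param view A `network_view`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(view, path) {
  e <- view$graph$edges
  vertices <- data.frame(name = view$graph$nodes,
                         group = unname(view$groups[view$graph$nodes]),
                         connector = view$graph$nodes %in% view$connectors,
                         stringsAsFactors = FALSE)
  edf <- data.frame(from = e$a, to = e$b, kind = e$kind,
                    multiplicity = e$multiplicity, stringsAsFactors = FALSE)
  if (!is.null(view$edge_lengths)) {
    edf$length <- unname(view$edge_lengths[paste(e$a, e$b, sep = "|")])
  }
  ig <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vertices)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges [%s]\n",
              length(x$nodes), nrow(x$edges), paste(x$kinds, collapse = "+")))
  invisible(x)
}

#' @export
print.network_view <- function(x, ...) {
  cat(sprintf("<network_view> %d nodes (%d connectors), %d edges\n",
              length(x$graph$nodes), length(x$connectors), nrow(x$graph$edges)))
  grp <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}
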