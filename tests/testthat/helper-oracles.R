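# Independent oracles and tiny fixture builders used across the suite.
# Oracles deliberately use different algorithms/code paths than the package
# (matrix closures, Floyd-Warshall, exact combinatorial sums, bitmask
# enumeration) so agreement is evidence, not tautology.

go_id <- function(i) sprintf("GO:%07d", i)

# Assemble OBO text from a parent table. `edges` is a data frame with
# columns child, parent, rel ("is_a"/"part_of").
mk_obo <- function(ids, edges = NULL, namespace = "biological_process",
                   obsolete = character(), alt = list(), replaced_by = list()) {
  ns <- if (length(namespace) == 1) rep(namespace, length(ids)) else namespace
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(ids)) {
    id <- ids[i]
    lines <- c(lines, "[Term]", paste0("id: ", id), paste0("name: term ", id),
               paste0("namespace: ", ns[i]))
    for (a in alt[[id]] %||% character()) lines <- c(lines, paste0("alt_id: ", a))
    if (!is.null(edges)) {
      sel <- edges$child == id
      for (j in which(sel)) {
        lines <- c(lines, if (edges$rel[j] == "is_a") paste0("is_a: ", edges$parent[j])
                          else paste0("relationship: part_of ", edges$parent[j]))
      }
    }
    if (id %in% obsolete) lines <- c(lines, "is_obsolete: true")
    rb <- replaced_by[[id]] %||% NULL
    if (!is.null(rb)) lines <- c(lines, paste0("replaced_by: ", rb))
    lines <- c(lines, "")
  }
  lines
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random rooted DAG as OBO lines plus its own bookkeeping.
random_dag <- function(n, seed, p_second_parent = 0.2, p_part_of = 0.2) {
  withr::with_seed(seed, {
    child <- integer(0); parent <- integer(0)
    for (i in 2:n) {
      p1 <- sample.int(i - 1, 1)
      child <- c(child, i); parent <- c(parent, p1)
      if (i >= 3 && stats::runif(1) < p_second_parent) {
        p2 <- sample(setdiff(seq_len(i - 1), p1), 1)
        child <- c(child, i); parent <- c(parent, p2)
      }
    }
    rel <- ifelse(stats::runif(length(child)) < p_part_of, "part_of", "is_a")
    edges <- data.frame(child = go_id(child), parent = go_id(parent), rel = rel,
                        stringsAsFactors = FALSE)
    list(ids = go_id(seq_len(n)), edges = edges,
         obo = mk_obo(go_id(seq_len(n)), edges),
         n_edges = nrow(edges))
  })
}

# Reachability oracle: transitive closure by repeated boolean matrix product
# over the child->parent adjacency.
ancestors_oracle <- function(dagfix, id) {
  ids <- dagfix$ids
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[cbind(dagfix$edges$child, dagfix$edges$parent)] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  sort(ids[R[id, ]])
}

# Floyd-Warshall all-pairs shortest paths over the undirected term graph.
fw_distances <- function(ids, edge_a, edge_b) {
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  ia <- match(edge_a, ids); ib <- match(edge_b, ids)
  for (e in seq_along(ia)) { D[ia[e], ib[e]] <- 1; D[ib[e], ia[e]] <- 1 }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

fw_for_dag <- function(dagfix) fw_distances(dagfix$ids, dagfix$edges$child, dagfix$edges$parent)

# Exact hypergeometric upper tail. All binomial coefficients involved are
# integers below 2^53 for N <= 30, so double arithmetic is exact.
fisher_oracle <- function(k, n, K, N) {
  i <- seq(k, min(n, K))
  if (length(i) == 0 || k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Definitional BH step-up: adj(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Full permutation null of the Mann-Whitney rank-sum statistic by bitmask
# enumeration over all group labelings (two-sided, symmetric deviation).
mwu_oracle <- function(x_in, x_out) {
  n1 <- length(x_in); n <- n1 + length(x_out)
  r <- rank(c(x_in, x_out))
  e_w <- n1 * (n + 1) / 2
  w_obs <- sum(r[seq_len(n1)])
  masks <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(b) bitwAnd(bitwShiftR(masks, b - 1L), 1L),
                 integer(length(masks)))
  keep <- rowSums(bits) == n1
  W <- as.vector(bits[keep, , drop = FALSE] %*% r)
  mean(abs(W - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# All nodes lying on at least one shortest path between any pair of the
# selected nodes: Floyd-Warshall distances + depth-first enumeration of the
# shortest paths themselves (prune on exact remaining distance to target).
connector_candidates_oracle <- function(nodes, edge_a, edge_b, selected) {
  D <- fw_distances(nodes, edge_a, edge_b)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edge_b[edge_a == v], edge_a[edge_b == v])
  })
  on_path <- character(0)
  sel <- intersect(selected, nodes)
  if (length(sel) < 2) return(character(0))
  for (i in seq_len(length(sel) - 1)) for (j in seq(i + 1, length(sel))) {
    s <- sel[i]; t <- sel[j]
    if (!is.finite(D[s, t])) next
    walk <- function(v, remaining, acc) {
      if (v == t) { on_path <<- union(on_path, acc); return(invisible()) }
      for (w in adj[[v]]) {
        if (is.finite(D[w, t]) && D[w, t] == remaining - 1) {
          walk(w, remaining - 1, c(acc, w))
        }
      }
    }
    walk(s, D[s, t], character(0))
  }
  sort(setdiff(on_path, sel))
}

# Small annotation table straight from gene/term pairs (no file round trip).
mk_table <- function(dag, genes, terms) {
  # read_text_lines() closes the connection it is handed
  con <- textConnection(c("gene\tterm", paste(genes, terms, sep = "\t")))
  read_annotation_tsv(con, dag)
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
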