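# Interaction parsing, graph building, connector search, semantic edge
# lengths and receptor-ligand pairing.

toy_records <- function(lines) {
  header <- paste(c("Official Symbol Interactor A", "Official Symbol Interactor B",
                    "Experimental System Type",
                    "Organism Name Interactor A", "Organism Name Interactor B"),
                  collapse = "\t")
  read_interactions(textConnection(c(header, lines)))
}

test_that("read_interactions drops self-loops and filters organisms", {
  lines <- c("A\tB\tphysical\torg1\torg1",
             "B\tB\tphysical\torg1\torg1",
             "B\tC\tgenetic\torg2\torg2")
  rec <- toy_records(lines)
  expect_equal(nrow(rec), 2)          # self-loop gone
  header <- paste(c("Official Symbol Interactor A", "Official Symbol Interactor B",
                    "Experimental System Type",
                    "Organism Name Interactor A", "Organism Name Interactor B"),
                  collapse = "\t")
  rec1 <- read_interactions(textConnection(c(header, lines)), organism_filter = "org1")
  expect_equal(nrow(rec1), 1)
  expect_equal(rec1$a, "A")
  expect_error(read_interactions(textConnection("foo\tbar\nx\ty")),
               class = "catego_format_error")
})

test_that("duplicate rows stay as records but collapse into multiplicity", {
  rec <- toy_records(c("A\tB\tphysical\to\to",
                       "B\tA\tphysical\to\to",
                       "A\tB\tphysical\to\to",
                       "A\tC\tgenetic\to\to"))
  expect_equal(nrow(rec), 4)          # staging keeps both orientations
  g <- build_graph(rec)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$multiplicity[g$edges$b == "B"], 3)
  g_phys <- build_graph(rec, kinds = "physical")
  expect_equal(nrow(g_phys$edges), 1)
  expect_equal(g_phys$nodes, c("A", "B"))
  expect_equal(nrow(build_graph(rec[rec$kind == "genetic", ], "physical")$edges), 0)
})

test_that("parsed fixture interactomes match the generator ledger", {
  cfg <- fixture_config(seed = 13, n_genes = 300, n_terms = 100,
                        planted_category_size = 30, sample_size = 40)
  onto <- make_ontology(cfg)
  pop <- make_annotated_population(cfg, onto)
  net <- make_interactome(cfg, pop)
  rec_all <- read_interactions(textConnection(net$interactions))
  led <- net$ledger
  expect_equal(nrow(rec_all), led$rows_written - led$n_self_loops)
  rec <- read_interactions(textConnection(net$interactions),
                           organism_filter = "Synthetica testensis")
  expect_equal(nrow(rec), led$n_records_same_organism)
  # recount oracle: every record lands in exactly one edge's multiplicity,
  # and the distinct unordered (pair, kind) combinations give the edge count
  g <- build_graph(rec)
  expect_equal(sum(g$edges$multiplicity), nrow(rec))
  expect_equal(nrow(g$edges),
               nrow(unique(data.frame(a = pmin(rec$a, rec$b), b = pmax(rec$a, rec$b),
                                      k = rec$kind))))
  expect_setequal(g$nodes, unique(c(rec$a, rec$b)))
})

test_that("connector search recovers forced paths and obeys the budget", {
  rec <- toy_records(c("A\tx\tphysical\to\to",
                       "x\tB\tphysical\to\to",
                       "A\tC\tphysical\to\to"))
  g <- build_graph(rec)
  v0 <- subgraph_with_connectors(g, c("A", "B"), max_connectors = 0)
  expect_equal(v0$graph$nodes, c("A", "B"))     # plain induced subgraph
  expect_equal(nrow(v0$graph$edges), 0)
  v1 <- subgraph_with_connectors(g, c("A", "B"), max_connectors = 1)
  expect_equal(v1$connectors, "x")
  expect_setequal(paste(v1$graph$edges$a, v1$graph$edges$b), c("A x", "B x"))
  expect_equal(unname(v1$groups[c("A", "B", "x")]),
               c("selected", "selected", "connector"))
  expect_error(subgraph_with_connectors(g, "nope"), class = "catego_data_error")
})

random_graph <- function(n, seed, p = 2 / 10) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p
    data.frame(a = pairs[1, keep], b = pairs[2, keep], stringsAsFactors = FALSE)
  })
}

test_that("connector candidates equal the exhaustive shortest-path oracle", {
  for (seed in 1:12) {
    ed <- random_graph(sample(8:25, 1), seed * 3)
    if (nrow(ed) < 2) next
    rec <- data.frame(a = ed$a, b = ed$b, kind = "physical",
                      source_row = seq_len(nrow(ed)), stringsAsFactors = FALSE)
    g <- build_graph(rec)
    withr::with_seed(seed, sel <- sample(g$nodes, min(4, length(g$nodes))))
    view <- subgraph_with_connectors(g, sel, max_connectors = length(g$nodes))
    want <- connector_candidates_oracle(g$nodes, g$edges$a, g$edges$b, sel)
    expect_equal(sort(view$connector_candidates$gene), want, info = seed)
    # with unlimited budget, selected pairs keep their original distances
    for (i in seq_along(sel)) for (j in seq_len(i - 1)) {
      if (!all(c(sel[i], sel[j]) %in% g$nodes)) next
      d_full <- catego:::graph_distances_from(g, sel[i])
      d_view <- catego:::graph_distances_from(view$graph, sel[i])
      if (sel[j] %in% names(d_full)) {
        expect_equal(d_view[[sel[j]]], d_full[[sel[j]]], info = paste(seed, i, j))
      }
    }
  }
})

length_fixture <- function() {
  # chain 1 - 2 - 3 - 4 - 5 (distances easy to read off)
  edges <- data.frame(child = go_id(2:5), parent = go_id(1:4), rel = "is_a",
                      stringsAsFactors = FALSE)
  dag <- parse_obo(mk_obo(go_id(1:5), edges))
  tab <- mk_table(dag, c("gS", "gS", "gT", "gU", "gU"),
                  go_id(c(1, 3, 5, 1, 5)))
  list(dag = dag, tab = tab)
}

test_that("edge lengths average term distances with epsilon floor and symmetry", {
  f <- length_fixture()
  # gT has {5}; gS has {1,3}: distances 4 and 2 -> mean 3
  expect_equal(edge_length(f$dag, f$tab, "gS", "gT"), 3)
  expect_equal(edge_length(f$dag, f$tab, "gT", "gS"), 3)
  # identical single-term annotation -> floor epsilon
  tab1 <- mk_table(f$dag, c("gA", "gB"), go_id(c(2, 2)))
  expect_equal(edge_length(f$dag, tab1, "gA", "gB"), 0.01)
  expect_equal(edge_length(f$dag, tab1, "gA", "gB", epsilon = 0.5), 0.5)
  # unannotated partner -> missing
  expect_true(is.na(edge_length(f$dag, f$tab, "gS", "gZ")))
})

test_that("edge lengths match the brute-force Floyd-Warshall double loop", {
  for (seed in c(6, 22)) {
    fix <- random_dag(20, seed)
    dag <- parse_obo(fix$obo)
    D <- fw_for_dag(fix)
    withr::with_seed(seed + 1, {
      genes <- sprintf("e%02d", 1:12)
      gg <- rep(genes, each = 2)
      tt <- sample(fix$ids, length(gg), replace = TRUE)
    })
    tab <- mk_table(dag, gg, tt)
    for (i in 1:11) {
      a <- genes[i]; b <- genes[i + 1]
      got <- edge_length(dag, tab, a, b)
      pairs <- expand.grid(t1 = tab$gene_to_terms[[a]], t2 = tab$gene_to_terms[[b]],
                           stringsAsFactors = FALSE)
      dd <- mapply(function(t1, t2) D[t1, t2], pairs$t1, pairs$t2)
      dd <- dd[is.finite(dd)]
      want <- if (length(dd) == 0) NA_real_ else max(mean(dd), 0.01)
      expect_equal(got, want, info = paste(seed, a, b))
      expect_equal(got, edge_length(dag, tab, b, a))   # symmetry
    }
  }
})

rl_dag <- function() {
  # MF: root 10; receptor 11 (child 12); ligand 13. Obsolete 14 -> 11.
  edges <- data.frame(child = go_id(c(11, 12, 13)), parent = go_id(c(10, 11, 10)),
                      rel = "is_a", stringsAsFactors = FALSE)
  parse_obo(mk_obo(go_id(10:14), edges, namespace = "molecular_function",
                   obsolete = go_id(14),
                   replaced_by = stats::setNames(list(go_id(11)), go_id(14))))
}

test_that("receptor-ligand pairing filters on roles, sets and orientation", {
  dag <- rl_dag()
  tab <- mk_table(dag, c("R1", "R2", "L1", "plain"), go_id(c(11, 12, 13, 10)))
  rec <- toy_records(c("L1\tR1\tphysical\to\to",       # stored reversed
                       "R2\tL1\tphysical\to\to",
                       "plain\tL1\tphysical\to\to",    # one endpoint lacks a role
                       "R1\tR2\tphysical\to\to"))      # both receptors
  pairs <- receptor_ligand_pairs(rec, set1 = c("R1", "R2"), set2 = "L1",
                                 tab, dag, receptor_term = go_id(14),  # via replaced_by
                                 ligand_term = go_id(13))
  expect_equal(pairs$gene1, c("R1", "R2"))
  expect_equal(pairs$gene2, c("L1", "L1"))
  expect_equal(unique(pairs$roles1), "receptor")
  # orientation invariance: swapping stored endpoints changes nothing
  rec_sw <- rec; rec_sw$a <- rec$b; rec_sw$b <- rec$a
  expect_equal(receptor_ligand_pairs(rec_sw, c("R1", "R2"), "L1", tab, dag,
                                     receptor_term = go_id(14), ligand_term = go_id(13)),
               pairs)
  # both-receptor pairs appear unless strict
  pr <- receptor_ligand_pairs(rec, "R1", "R2", tab, dag,
                              receptor_term = go_id(11), ligand_term = go_id(13))
  expect_equal(nrow(pr), 1)
  expect_equal(pr$roles2, "receptor")
  pr_strict <- receptor_ligand_pairs(rec, "R1", "R2", tab, dag,
                                     receptor_term = go_id(11), ligand_term = go_id(13),
                                     strict = TRUE)
  expect_equal(nrow(pr_strict), 0)
  expect_error(receptor_ligand_pairs(rec, "R1", "L1", tab, dag,
                                     receptor_term = go_id(99)),
               class = "catego_data_error")
})

test_that("fixture receptor-ligand pairs equal the planted ledger exactly", {
  for (seed in c(2, 29)) {
    cfg <- fixture_config(seed = seed, n_genes = 300, n_terms = 100,
                          planted_category_size = 30, sample_size = 40)
    onto <- make_ontology(cfg)
    pop <- make_annotated_population(cfg, onto)
    net <- make_interactome(cfg, pop)
    dag <- parse_obo(onto$obo)
    tab <- read_annotation_tsv(textConnection(pop$annotations), dag)
    rec <- read_interactions(textConnection(net$interactions))
    got <- receptor_ligand_pairs(rec, net$set1, net$set2, tab, dag)
    expect_equal(got, net$ledger$rl_pairs, info = seed)
  }
})

test_that("network views export edge lists and GraphML", {
  rec <- toy_records(c("A\tx\tphysical\to\to", "x\tB\tphysical\to\to"))
  g <- build_graph(rec)
  v <- subgraph_with_connectors(g, c("A", "B"), max_connectors = 1)
  f <- length_fixture()
  tabx <- mk_table(f$dag, c("A", "x", "B"), go_id(c(1, 3, 5)))
  v <- add_edge_lengths(v, f$dag, tabx)
  t1 <- tempfile(fileext = ".tsv")
  write_edge_list_tsv(v, t1)
  out <- read.delim(t1)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$length), c(2, 2))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(v, gml)
  expect_match(readLines(gml, n = 2)[2], "graphml", fixed = TRUE)
})
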