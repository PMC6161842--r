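# Deterministic synthetic fixtures: toy ontologies, annotated gene
# populations with a planted enriched category, measured lists with a
# planted rank shift, and toy interactomes with planted connector paths and
# receptor-ligand pairs. Every generator is seeded and byte-reproducible,
# and records a ledger with the ground truth (true memberships, planted
# signals, counts) sufficient to verify downstream analyses independently.

#' Fixture generator configuration
#'
#' @param seed Integer master seed; all generators derive from it.
#' @param n_terms Biological-process terms in the toy ontology.
#' @param branching Children per internal node of the term tree skeleton.
#' @param n_genes Genes in the population.
#' @param annotations_per_gene Integer range (length 2): annotations drawn
#'   per gene.
#' @param n_categories Number of generated categories.
#' @param category_size Terms per category.
#' @param planted_category_size Genes belonging to the planted (first)
#'   category.
#' @param sample_size Candidate-sample size drawn from the population.
#' @param planted_fold Representation fold of planted-category genes in the
#'   sample (1 = null: uniform sampling).
#' @param planted_shift_sd Mean shift (in SD units) added to planted-gene
#'   measures in the measured list (0 = null).
#' @param interactome_density Erdos-Renyi edge probability of the toy
#'   interactome.
#' @param junk_fraction Fraction of junk (unresolvable-term) rows mixed
#'   into the annotation file.
#' @param n_rl_pairs Planted receptor-ligand cross-dataset pairs.
#' @param n_paths Planted A-x-B connector paths.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_terms = 300L, branching = 3L,
                           n_genes = 1000L, annotations_per_gene = c(2L, 6L),
                           n_categories = 8L, category_size = 3L,
                           planted_category_size = 100L, sample_size = 100L,
                           planted_fold = 5, planted_shift_sd = 2,
                           interactome_density = 0.002, junk_fraction = 0.1,
                           n_rl_pairs = 5L, n_paths = 3L) {
  stopifnot(n_terms >= 3, branching >= 2, n_genes > 0,
            length(annotations_per_gene) == 2,
            annotations_per_gene[1] >= 1,
            annotations_per_gene[2] >= annotations_per_gene[1],
            n_categories >= 1, category_size >= 2,
            planted_category_size >= 1, planted_category_size < n_genes,
            sample_size >= 1, sample_size <= n_genes,
            planted_fold >= 1, planted_shift_sd >= 0,
            interactome_density >= 0, interactome_density <= 1,
            junk_fraction >= 0, junk_fraction < 1)
  structure(list(seed = as.integer(seed), n_terms = as.integer(n_terms),
                 branching = as.integer(branching), n_genes = as.integer(n_genes),
                 annotations_per_gene = as.integer(annotations_per_gene),
                 n_categories = as.integer(n_categories),
                 category_size = as.integer(category_size),
                 planted_category_size = as.integer(planted_category_size),
                 sample_size = as.integer(sample_size),
                 planted_fold = planted_fold, planted_shift_sd = planted_shift_sd,
                 interactome_density = interactome_density,
                 junk_fraction = junk_fraction,
                 n_rl_pairs = as.integer(n_rl_pairs), n_paths = as.integer(n_paths)),
            class = "fixture_config")
}

# sub-seeds: one PRNG stream per generator invocation
sub_seed <- function(cfg, offset) (cfg$seed * 101L + offset) %% 2000000000L

bp_id <- function(i) sprintf("GO:%07d", 900000L + i)

# Fixed molecular_function block: a small real-id-bearing sub-ontology with
# the receptor/ligand role terms, an alias, and obsolete terms (one with a
# replacement, mirroring the retired receptor-activity id; one without).
MF_ROOT <- "GO:0950001"
MF_RECEPTOR <- "GO:0950002"
MF_RECEPTOR_CHILD <- "GO:0950003"
MF_REGULATOR <- "GO:0950004"
MF_CATALYTIC <- "GO:0950005"
MF_CATALYTIC_ALT <- "GO:0951111"
LIGAND_TERM <- "GO:0048018"
OBSOLETE_RECEPTOR <- "GO:0004872"
OBSOLETE_DEAD <- "GO:0952222"

#' Generate a toy GO ontology as OBO text
#'
#' Builds a rooted biological_process DAG (tree skeleton with `branching`
#' children per internal node, plus ~10% random second parents) and a small
#' fixed molecular_function block carrying the receptor/ligand role terms,
#' an `alt_id` alias, an obsolete term with `replaced_by` and one without.
#' Edges are `is_a` (85%) or `part_of` (15%).
#'
#' @param cfg A `fixture_config`.
#' @return `list(obo = <character lines>, ledger = <list of true counts>)`.
#' @export
make_ontology <- function(cfg) {
  withr::with_seed(sub_seed(cfg, 0L), {
    n <- cfg$n_terms
    b <- cfg$branching
    ids <- bp_id(seq_len(n))
    parent1 <- c(NA_integer_, ((seq_len(n - 1) - 1L) %/% b) + 1L)
    parent2 <- rep(NA_integer_, n)
    extra <- which(seq_len(n) >= 3 & stats::runif(n) < 0.1)
    for (i in extra) {
      cand <- setdiff(seq_len(i - 1L), parent1[i])
      if (length(cand) > 0) parent2[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    }
    edges <- list()
    rel_of <- function() if (stats::runif(1) < 0.85) "is_a" else "part_of"
    for (i in seq_len(n)) {
      ps <- c(parent1[i], parent2[i])
      ps <- ps[!is.na(ps)]
      for (p in ps) edges[[length(edges) + 1L]] <- c(ids[i], ids[p], rel_of())
    }
    emat <- do.call(rbind, edges)

    stanza <- function(id, name, ns, parents = NULL, rels = NULL, alt = NULL,
                       obsolete = FALSE, replaced_by = NULL) {
      out <- c("[Term]", paste0("id: ", id), paste0("name: ", name),
               paste0("namespace: ", ns))
      if (!is.null(alt)) out <- c(out, paste0("alt_id: ", alt))
      if (!is.null(parents)) {
        for (k in seq_along(parents)) {
          out <- c(out, if (rels[k] == "is_a") paste0("is_a: ", parents[k])
                        else paste0("relationship: part_of ", parents[k]))
        }
      }
      if (obsolete) out <- c(out, "is_obsolete: true")
      if (!is.null(replaced_by)) out <- c(out, paste0("replaced_by: ", replaced_by))
      c(out, "")
    }

    lines <- c("format-version: 1.2",
               sprintf("remark: synthetic fixture ontology, seed %d", cfg$seed), "")
    for (i in seq_len(n)) {
      sel <- emat[, 1] == ids[i]
      lines <- c(lines, stanza(ids[i], sprintf("bp term %03d", i), "biological_process",
                               parents = emat[sel, 2], rels = emat[sel, 3]))
    }
    mf <- c(
      stanza(MF_ROOT, "molecular function root", "molecular_function"),
      stanza(MF_RECEPTOR, "signaling receptor activity", "molecular_function",
             MF_ROOT, "is_a"),
      stanza(MF_RECEPTOR_CHILD, "transmembrane receptor activity", "molecular_function",
             MF_RECEPTOR, "is_a"),
      stanza(MF_REGULATOR, "receptor regulator activity", "molecular_function",
             MF_ROOT, "is_a"),
      stanza(LIGAND_TERM, "receptor ligand activity", "molecular_function",
             MF_REGULATOR, "is_a"),
      stanza(MF_CATALYTIC, "catalytic activity", "molecular_function",
             MF_ROOT, "is_a", alt = MF_CATALYTIC_ALT),
      stanza(OBSOLETE_RECEPTOR, "obsolete receptor activity", "molecular_function",
             obsolete = TRUE, replaced_by = MF_RECEPTOR),
      stanza(OBSOLETE_DEAD, "obsolete dead end", "molecular_function",
             obsolete = TRUE)
    )
    lines <- c(lines, mf)
    n_isa <- sum(emat[, 3] == "is_a") + 5L
    n_partof <- sum(emat[, 3] == "part_of")
    ledger <- list(
      seed = cfg$seed,
      n_terms_bp = n, n_terms_mf = 8L, n_obsolete = 2L,
      n_terms_total = n + 8L,
      n_edges_is_a = n_isa, n_edges_part_of = n_partof,
      n_edges = n_isa + n_partof,
      roots = c(bp_id(1L), MF_ROOT),
      receptor_term = MF_RECEPTOR, receptor_descendants = MF_RECEPTOR_CHILD,
      ligand_term = LIGAND_TERM,
      obsolete_with_replacement = OBSOLETE_RECEPTOR,
      obsolete_without_replacement = OBSOLETE_DEAD,
      alt_alias = c(MF_CATALYTIC_ALT), alt_primary = c(MF_CATALYTIC),
      bp_parent1 = parent1, bp_parent2 = parent2
    )
    list(obo = lines, ledger = ledger)
  })
}

# inline ancestor closure over an index-based parent list (generator-side,
# independent of the go_dag cache machinery)
idx_ancestors <- function(p1, p2, i) {
  out <- integer(0)
  frontier <- c(p1[i], p2[i])
  frontier <- frontier[!is.na(frontier)]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(j) c(p1[j], p2[j])))
    frontier <- frontier[!is.na(frontier)]
  }
  out
}

idx_descendants <- function(p1, p2, i) {
  n <- length(p1)
  out <- integer(0)
  frontier <- which(p1 == i | p2 == i)
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, function(j) which(p1 == j | p2 == j)))
  }
  out
}

#' Generate an annotated gene population with a planted enriched category
#'
#' Genes are annotated uniformly at random over the biological_process
#' terms; categories are built from sibling groups of the term tree
#' (satisfying the siblings-only rule by construction), and the first
#' category is "planted": exactly `planted_category_size` genes carry a
#' term from its descendant closure, and no other gene does. A candidate
#' sample of `sample_size` genes is drawn with planted-category genes
#' represented at `planted_fold` times their background rate (`fold = 1`
#' draws uniformly, the exact hypergeometric null). Receptor and ligand
#' role annotations are planted on dedicated genes. A configurable fraction
#' of junk rows with unresolvable term ids is mixed into the annotation
#' file to exercise reader hygiene.
#'
#' @param cfg A `fixture_config`.
#' @param onto Result of [make_ontology()] (its ledger drives construction).
#' @return List: `annotations` (TSV lines), `categories` (TSV lines),
#'   `sample` (gene ids), `ledger`.
#' @export
make_annotated_population <- function(cfg, onto) {
  led0 <- onto$ledger
  p1 <- led0$bp_parent1; p2 <- led0$bp_parent2
  n <- cfg$n_terms
  withr::with_seed(sub_seed(cfg, 1L), {
    # categories: children of distinct internal nodes, antichain-filtered
    n_children <- vapply(seq_len(n), function(i) sum(p1 == i, na.rm = TRUE), 0L)
    internal <- which(n_children >= min(cfg$category_size, cfg$branching, 2L))
    internal <- setdiff(internal, 1L)
    if (length(internal) < cfg$n_categories) {
      data_error("ontology too small for the requested number of categories")
    }
    # Categories emulate slim-level terms: prefer parents whose children
    # carry substantial subtrees, so no category ends up annotating just a
    # gene or two (real high-level categories never do).
    closure_size <- vapply(internal, function(i) {
      kids <- which(p1 == i)
      length(unique(c(kids, unlist(lapply(kids, idx_descendants, p1 = p1, p2 = p2)))))
    }, 0L)
    qualified <- internal[closure_size >= 8L]
    rest <- internal[closure_size < 8L]
    rest <- rest[order(-closure_size[closure_size < 8L])]
    resample <- function(x) x[sample.int(length(x))]
    # candidate parents in random order, rich subtrees first; more are
    # scanned than needed in case some yield no valid sibling group
    parents_pick <- c(resample(qualified), rest)
    # Assemble categories with pairwise-disjoint descendant closures (as
    # with real slim categories, one specific term never feeds two
    # categories) and antichain members within each category.
    used_closure <- integer(0)
    categories <- list()
    for (ci in seq_along(parents_pick)) {
      p <- parents_pick[ci]
      kids <- which(p1 == p)
      keep <- integer(0)
      closure_snapshot <- used_closure
      for (k in kids) {
        sub_k <- c(k, idx_descendants(p1, p2, k))
        if (any(sub_k %in% used_closure)) next
        anc_k <- idx_ancestors(p1, p2, k)
        if (any(keep %in% anc_k) || any(k %in% unlist(lapply(keep, idx_ancestors, p1 = p1, p2 = p2)))) next
        keep <- c(keep, k)
        used_closure <- c(used_closure, sub_k)
        if (length(keep) == cfg$category_size) break
      }
      if (length(keep) < 2) { used_closure <- closure_snapshot; next }
      categories[[sprintf("CAT%02d", length(categories) + 1L)]] <- bp_id(keep)
      if (length(categories) == cfg$n_categories) break
    }
    if (length(categories) == 0) data_error("could not assemble any sibling category")
    planted_name <- names(categories)[1]
    planted_idx <- match(categories[[1]], bp_id(seq_len(n)))
    planted_closure_idx <- sort(unique(c(planted_idx,
                                         unlist(lapply(planted_idx, idx_descendants, p1 = p1, p2 = p2)))))
    planted_closure <- bp_id(planted_closure_idx)
    allowed <- setdiff(bp_id(seq_len(n)), planted_closure)

    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    K <- cfg$planted_category_size
    planted_genes <- genes[seq_len(K)]

    rows_gene <- character(0); rows_term <- character(0)
    r_each <- sample(seq(cfg$annotations_per_gene[1], cfg$annotations_per_gene[2]),
                     cfg$n_genes, replace = TRUE)
    for (gi in seq_len(cfg$n_genes)) {
      g <- genes[gi]
      if (gi <= K) {
        t_planted <- if (length(planted_closure) == 1) planted_closure else sample(planted_closure, 1)
        t_rest <- sample(allowed, max(0L, r_each[gi] - 1L))
        ts <- c(t_planted, t_rest)
      } else {
        ts <- sample(allowed, r_each[gi])
      }
      rows_gene <- c(rows_gene, rep(g, length(ts)))
      rows_term <- c(rows_term, ts)
    }

    # role genes: planted among non-planted-category genes
    pool <- genes[(K + 1L):cfg$n_genes]
    role <- sample(pool, 20L)
    receptor_genes <- sort(role[1:10])
    ligand_genes <- sort(role[11:20])
    recep_terms <- rep(c(MF_RECEPTOR, MF_RECEPTOR_CHILD), 5)
    rows_gene <- c(rows_gene, receptor_genes, ligand_genes)
    rows_term <- c(rows_term, recep_terms, rep(LIGAND_TERM, 10))

    clean_pairs <- unique(data.frame(gene = rows_gene, term = rows_term,
                                     stringsAsFactors = FALSE))
    n_dup_rows <- length(rows_gene) - nrow(clean_pairs)

    # junk rows with unresolvable term ids
    n_junk <- round(cfg$junk_fraction * length(rows_gene))
    if (n_junk > 0) {
      junk_gene <- sample(genes, n_junk, replace = TRUE)
      junk_term <- sprintf("GO:%07d", 777000L + seq_len(n_junk))  # absent from the DAG
      rows_gene <- c(rows_gene, junk_gene)
      rows_term <- c(rows_term, junk_term)
    }
    ord <- sample(length(rows_gene))
    ann_lines <- c(sprintf("# synthetic annotation fixture, seed %d", cfg$seed),
                   "gene\tterm",
                   paste(rows_gene[ord], rows_term[ord], sep = "\t"))

    cat_lines <- c(sprintf("# synthetic categories, seed %d", cfg$seed),
                   "category\tterm",
                   unlist(lapply(names(categories), function(nm) {
                     paste(nm, categories[[nm]], sep = "\t")
                   })))

    # candidate sample with planted representation fold
    if (cfg$planted_fold == 1) {
      smp <- sample(genes, cfg$sample_size)
    } else {
      p_in <- min(1, cfg$planted_fold * cfg$sample_size / cfg$n_genes)
      take <- planted_genes[stats::runif(K) < p_in]
      n_rest <- max(0L, cfg$sample_size - length(take))
      smp <- c(take, sample(setdiff(genes, planted_genes), n_rest))
    }
    smp <- sort(smp)

    # true category membership: direct scan of the emitted pairs against
    # each category's descendant closure
    closure_of <- function(term_ids) {
      idx <- match(term_ids, bp_id(seq_len(n)))
      bp_id(sort(unique(c(idx, unlist(lapply(idx, idx_descendants, p1 = p1, p2 = p2))))))
    }
    category_members <- lapply(categories, function(ts) {
      sort(unique(clean_pairs$gene[clean_pairs$term %in% closure_of(ts)]))
    })

    ledger <- list(
      genes = genes,
      categories = categories,
      category_members = category_members,
      planted_category = planted_name,
      planted_genes = planted_genes,
      planted_closure = planted_closure,
      receptor_genes = receptor_genes,
      ligand_genes = ligand_genes,
      sample = smp,
      observed_k = length(intersect(smp, planted_genes)),
      expected_k = if (cfg$planted_fold == 1) cfg$sample_size * K / cfg$n_genes
                   else K * min(1, cfg$planted_fold * cfg$sample_size / cfg$n_genes),
      clean_pairs = clean_pairs,
      n_duplicate_rows = n_dup_rows,
      n_junk_rows = n_junk
    )
    list(annotations = ann_lines, categories = cat_lines, sample = smp, ledger = ledger)
  })
}

#' Generate a measured gene list with a planted rank shift
#'
#' Background measures are standard normal; genes of the planted category
#' are shifted upward by `planted_shift_sd` standard deviations
#' (`shift = 0` is the null).
#'
#' @param cfg A `fixture_config`.
#' @param pop Result of [make_annotated_population()].
#' @return List: `measured` (TSV lines), `values` (named numeric vector).
#' @export
make_measured_list <- function(cfg, pop) {
  withr::with_seed(sub_seed(cfg, 2L), {
    genes <- pop$ledger$genes
    x <- stats::rnorm(length(genes))
    x[genes %in% pop$ledger$planted_genes] <- x[genes %in% pop$ledger$planted_genes] + cfg$planted_shift_sd
    lines <- c(sprintf("# synthetic measured list, seed %d", cfg$seed),
               "gene\tmeasure",
               paste(genes, sprintf("%.6f", x), sep = "\t"))
    list(measured = lines, values = stats::setNames(x, genes))
  })
}

#' Generate a toy interactome in BioGRID TAB style
#'
#' Erdos-Renyi background edges at `interactome_density` over the non-role,
#' non-reserved genes, plus planted A-x-B connector paths on otherwise
#' isolated genes, planted receptor-ligand records crossing two emitted
#' datasets (`set1`, `set2`), non-qualifying distractor records, duplicate
#' rows, self-loop rows and a few foreign-organism rows. The ledger records
#' the planted paths, the exact qualifying receptor-ligand pairs, and the
#' expected record counts.
#'
#' @param cfg A `fixture_config`.
#' @param pop Result of [make_annotated_population()].
#' @return List: `interactions` (TSV lines), `set1`, `set2`, `ledger`.
#' @export
make_interactome <- function(cfg, pop) {
  withr::with_seed(sub_seed(cfg, 3L), {
    led <- pop$ledger
    genes <- led$genes
    org <- "Synthetica testensis"

    n_path_genes <- 3L * cfg$n_paths
    role <- c(led$receptor_genes, led$ligand_genes)
    reserved <- sort(sample(setdiff(genes, role), n_path_genes + 60L))
    path_genes <- reserved[seq_len(n_path_genes)]
    setpool <- reserved[(n_path_genes + 1L):length(reserved)]

    receptors1 <- led$receptor_genes[seq_len(cfg$n_rl_pairs)]
    ligands2 <- led$ligand_genes[seq_len(cfg$n_rl_pairs)]
    set1 <- sort(c(setpool[1:30], receptors1))
    set2 <- sort(c(setpool[31:60], ligands2))

    rows <- list()
    add <- function(a, b, kind, organism = org) {
      rows[[length(rows) + 1L]] <<- c(a, b, kind, organism)
    }

    # planted receptor-ligand records (qualifying, cross-set)
    for (i in seq_len(cfg$n_rl_pairs)) add(receptors1[i], ligands2[i], "physical")
    # distractors: role-role within one set; role-nonrole cross; nonrole cross
    add(receptors1[1], led$receptor_genes[cfg$n_rl_pairs + 1L], "physical")
    add(receptors1[2], setpool[31], "physical")        # cross-set but partner lacks a role
    add(setpool[1], setpool[32], "physical")           # cross-set, no roles
    # planted paths A-x-B on otherwise isolated genes
    paths <- list()
    for (pidx in seq_len(cfg$n_paths)) {
      tri <- path_genes[(3L * (pidx - 1L) + 1L):(3L * pidx)]
      add(tri[1], tri[2], "physical")
      add(tri[2], tri[3], "physical")
      paths[[pidx]] <- tri  # A, x, B
    }
    # Erdos-Renyi background among free genes
    free <- setdiff(genes, c(role, path_genes))
    nf <- length(free)
    n_pairs <- nf * (nf - 1) / 2
    m <- stats::rbinom(1, n_pairs, cfg$interactome_density)
    if (m > 0) {
      k <- sort(sample(n_pairs, m))
      cum <- cumsum((nf - 1):1)
      i <- findInterval(k - 1, c(0, cum)) # smallest i with cum[i] >= k
      j <- i + (k - c(0, cum)[i])
      kinds <- ifelse(stats::runif(m) < 0.7, "physical", "genetic")
      for (e in seq_len(m)) add(free[i[e]], free[j[e]], kinds[e])
    }
    n_core <- length(rows)
    # duplicates (same and swapped orientation), self-loops, foreign organism
    dup_idx <- seq_len(min(5L, n_core))
    for (d in dup_idx) { r <- rows[[d]]; add(r[1], r[2], r[3]) }
    for (d in utils::head(dup_idx, 3L)) { r <- rows[[d]]; add(r[2], r[1], r[3]) }
    add(free[1], free[1], "physical")
    add(free[2], free[2], "genetic")
    add(free[3], free[4], "physical", organism = "Alia species")
    add(free[5], free[6], "genetic", organism = "Alia species")

    mat <- do.call(rbind, rows)
    header <- paste(c("BioGRID Interaction ID",
                      "Official Symbol Interactor A", "Official Symbol Interactor B",
                      "Experimental System Type",
                      "Organism Name Interactor A", "Organism Name Interactor B"),
                    collapse = "\t")
    body <- paste(seq_len(nrow(mat)), mat[, 1], mat[, 2], mat[, 3], mat[, 4], mat[, 4],
                  sep = "\t")
    lines <- c(header, body)

    rl_pairs <- data.frame(gene1 = receptors1, gene2 = ligands2,
                           roles1 = "receptor", roles2 = "ligand",
                           stringsAsFactors = FALSE)
    rl_pairs <- rl_pairs[order(rl_pairs$gene1, rl_pairs$gene2), , drop = FALSE]
    rownames(rl_pairs) <- NULL

    ledger <- list(
      rows_written = nrow(mat),
      n_self_loops = 2L,
      n_other_organism = 2L,
      n_records_same_organism = nrow(mat) - 4L,  # minus self-loops & foreign rows
      n_er_edges = m, n_er_possible_pairs = n_pairs,
      er_density = cfg$interactome_density,
      paths = paths,
      rl_pairs = rl_pairs,
      set1 = set1, set2 = set2
    )
    list(interactions = lines, set1 = set1, set2 = set2, ledger = ledger)
  })
}

#' Write a complete fixture directory
#'
#' Runs all generators for one configuration and writes
#' `ontology.obo`, `annotations.tsv`, `categories.tsv`, `sample.txt`,
#' `measured.tsv`, `interactions.tsv`, `set1.txt`, `set2.txt` and
#' `ledger.json` into `dir`. Identical configurations produce byte-identical
#' files.
#'
#' @param cfg A `fixture_config`.
#' @param dir Output directory (created if absent).
#' @param force Overwrite an existing non-empty directory?
#' @return The ledger (merged across generators), invisibly; file paths in
#'   `attr(, "paths")`.
#' @export
make_fixtures <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    data_error(sprintf("output directory '%s' is not empty (use force)", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  onto <- make_ontology(cfg)
  pop <- make_annotated_population(cfg, onto)
  meas <- make_measured_list(cfg, pop)
  net <- make_interactome(cfg, pop)
  paths <- c(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    categories = file.path(dir, "categories.tsv"),
    sample = file.path(dir, "sample.txt"),
    measured = file.path(dir, "measured.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    set1 = file.path(dir, "set1.txt"),
    set2 = file.path(dir, "set2.txt"),
    ledger = file.path(dir, "ledger.json")
  )
  writeLines(onto$obo, paths[["ontology"]])
  writeLines(pop$annotations, paths[["annotations"]])
  writeLines(pop$categories, paths[["categories"]])
  writeLines(pop$sample, paths[["sample"]])
  writeLines(meas$measured, paths[["measured"]])
  writeLines(net$interactions, paths[["interactions"]])
  writeLines(net$set1, paths[["set1"]])
  writeLines(net$set2, paths[["set2"]])
  ledger <- c(list(config = unclass(cfg)), onto$ledger,
              pop$ledger[setdiff(names(pop$ledger), "clean_pairs")],
              net$ledger)
  jsonlite::write_json(ledger, paths[["ledger"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  out <- c(onto = list(onto$ledger), pop = list(pop$ledger), net = list(net$ledger))
  attr(out, "paths") <- paths
  invisible(out)
}
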