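# Fisher and Mann-Whitney engines, BH adjustment, and the category runners.

test_that("fisher_unit reproduces closed-form and enumerated tails", {
  expect_equal(fisher_unit(5, 5, 10, 20), choose(10, 5) / choose(20, 5))
  expect_equal(fisher_unit(3, 5, 10, 20), fisher_oracle(3, 5, 10, 20))
  expect_equal(fisher_unit(4, 4, 4, 4), 1)        # certain event
  expect_equal(fisher_unit(0, 5, 10, 20), 1)      # tail from zero is everything
  # spot grid against the exact combinatorial sum
  for (N in c(8, 13)) for (n in c(3, 6)) for (K in c(2, 7)) {
    for (k in seq(max(0, n + K - N), min(n, K))) {
      expect_equal(fisher_unit(k, n, K, N), fisher_oracle(k, n, K, N),
                   tolerance = 1e-14, info = paste(k, n, K, N))
    }
  }
})

test_that("fisher_unit rejects inconsistent counts by name", {
  expect_error(fisher_unit(6, 5, 10, 20), "k=6", class = "catego_data_error")
  expect_error(fisher_unit(2, 5, 25, 20), "K=25", class = "catego_data_error")
  expect_error(fisher_unit(2, 25, 10, 20), "n=25", class = "catego_data_error")
})

test_that("bh_adjust matches the definitional step-up", {
  expect_equal(bh_adjust(0.03), 0.03)                    # single p unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))      # all equal stay equal
  for (seed in 1:20) {
    withr::with_seed(seed, p <- stats::runif(sample(2:12, 1)))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12, info = seed)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "catego_data_error")
})

test_that("bh_adjust is monotone in sorted order and idempotent", {
  withr::with_seed(1, p <- stats::runif(10))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("normalized_term_frequency is k/K with guarded domain", {
  expect_equal(normalized_term_frequency(3, 12), 0.25)
  expect_equal(normalized_term_frequency(12, 12), 1)
  expect_equal(normalized_term_frequency(0, 12), 0)
  expect_error(normalized_term_frequency(1, 0), class = "catego_data_error")
})

test_that("mwu_unit delta ranks follow direct ranking and symmetry", {
  r <- mwu_unit(c(3, 4), c(1, 2))
  expect_equal(r$delta_rank, 2)                    # 3.5 - 1.5
  expect_equal(r$method, "exact")
  # mirror-paired pooled values: symmetric construction gives delta 0
  r0 <- mwu_unit(c(-2, 2), c(-1, 1))
  expect_equal(r0$delta_rank, 0)
  # label swap flips the sign and keeps p
  a <- c(0.3, 1.7, 2.2); b <- c(-1, 0.5, 0.9, 2.0)
  expect_equal(mwu_unit(a, b)$delta_rank, -mwu_unit(b, a)$delta_rank)
  expect_equal(mwu_unit(a, b)$p, mwu_unit(b, a)$p)
  expect_error(mwu_unit(numeric(0), 1), class = "catego_data_error")
  expect_error(mwu_unit(c(1, Inf), c(1, 2)), class = "catego_data_error")
})

test_that("mwu_unit exact p equals full enumeration, with and without ties", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- if (seed %% 2) stats::rnorm(n1 + n2) else sample(1:4, n1 + n2, TRUE)
    })
    got <- mwu_unit(x[seq_len(n1)], x[n1 + seq_len(n2)])
    expect_equal(got$method, "exact")
    expect_equal(got$p, mwu_oracle(x[seq_len(n1)], x[n1 + seq_len(n2)]),
                 tolerance = 1e-12, info = seed)
  }
})

test_that("mwu_unit large-sample p agrees with the exact null where both apply", {
  # compare the normal approximation against enumeration at the threshold
  withr::with_seed(42, x <- stats::rnorm(16))
  exact <- mwu_unit(x[1:8], x[9:16])$p
  approx <- mwu_unit(x[1:8], x[9:16], exact_limit = 0)$p
  expect_equal(approx, exact, tolerance = 0.05)
  # degenerate total tie under the normal branch
  expect_equal(mwu_unit(rep(1, 10), rep(1, 12), exact_limit = 0)$p, 1)
})

# shared fixture for the runners
runner_fixture <- function(seed = 31, fold = 5, shift = 2, K = 50) {
  cfg <- fixture_config(seed = seed, n_genes = 400, n_terms = 150,
                        planted_category_size = K, sample_size = 60,
                        planted_fold = fold, planted_shift_sd = shift)
  onto <- make_ontology(cfg)
  pop <- make_annotated_population(cfg, onto)
  dag <- parse_obo(onto$obo)
  tab <- read_annotation_tsv(textConnection(pop$annotations), dag)
  cats <- load_categories(textConnection(pop$categories), dag)
  meas <- make_measured_list(cfg, pop)
  list(cfg = cfg, onto = onto, pop = pop, dag = dag, tab = tab, cats = cats,
       meas = meas)
}

test_that("run_sea: sample == background gives p = 1 everywhere", {
  f <- runner_fixture()
  res <- run_sea(sample_spec(f$pop$ledger$genes), f$cats, f$tab, f$dag)
  expect_true(all(res$p_raw == 1))
  expect_true(all(res$p_adj == 1))
  expect_true(all(res$effect == 1))   # every category gene is in the sample
})

test_that("run_sea counts equal independent set scans and find the planted signal", {
  f <- runner_fixture()
  res <- run_sea(f$pop$sample, f$cats, f$tab, f$dag)
  led <- f$pop$ledger
  for (i in seq_len(nrow(res))) {
    members <- led$category_members[[res$unit[i]]]
    expect_equal(res$K[i], length(members))
    expect_equal(res$k[i], length(intersect(members, led$sample)))
    expect_equal(res$effect[i], res$k[i] / res$K[i])
  }
  expect_equal(res$unit[which.min(res$p_adj)], led$planted_category)
  expect_lt(res$p_adj[res$unit == led$planted_category], 0.05)
})

test_that("run_sea harmonizes sample into the background with a warning", {
  f <- runner_fixture()
  bg <- f$pop$ledger$genes[1:200]
  smp <- c(intersect(f$pop$sample, bg), "not_a_gene")
  expect_warning(res <- run_sea(sample_spec(smp, bg), f$cats, f$tab, f$dag),
                 "dropped")
  expect_true(all(res$N == 200))
  expect_true(all(res$n == length(intersect(f$pop$sample, bg))))
  expect_error(suppressWarnings(run_sea(sample_spec("nope"), f$cats, f$tab, f$dag)),
               class = "catego_data_error")
})

test_that("run_mwu finds the planted shift and respects rank invariance", {
  f <- runner_fixture()
  res <- run_mwu(f$meas$values, f$cats, f$tab, f$dag)
  planted <- f$pop$ledger$planted_category
  expect_equal(res$unit[which.max(abs(res$effect))], planted)
  expect_gt(res$effect[res$unit == planted], 0)
  # strictly monotone transform leaves every statistic unchanged
  res2 <- run_mwu(exp(f$meas$values / 3), f$cats, f$tab, f$dag)
  expect_equal(res2$p_raw, res$p_raw)
  expect_equal(res2$effect, res$effect)
})

test_that("run_mwu with identical measures gives zero delta ranks", {
  f <- runner_fixture()
  x <- stats::setNames(rep(1, 400), f$pop$ledger$genes)
  res <- run_mwu(x, f$cats, f$tab, f$dag)
  expect_true(all(res$effect == 0))
  expect_true(all(res$p_raw == 1))
})

test_that("zoom results match singleton engine calls and skip adjustment", {
  f <- runner_fixture()
  planted_cat <- f$cats$categories[[match(f$pop$ledger$planted_category,
                                          category_names(f$cats))]]
  z <- zoom_terms(planted_cat, f$pop$sample, f$tab, f$dag)
  expect_false("p_adj" %in% names(z))
  expect_gte(sum(z$k), run_sea(f$pop$sample, f$cats, f$tab, f$dag)$k[1])
  # singleton consistency: each row equals a direct fisher_unit call
  for (i in seq_len(nrow(z))) {
    expect_equal(z$p_raw[i], fisher_unit(z$k[i], z$n[i], z$K[i], z$N[i]))
    # independent set scan per term
    members <- genes_with_terms(f$tab, f$dag, z$unit[i])
    expect_equal(z$K[i], length(members))
    expect_equal(z$k[i], length(intersect(members,
                                          intersect(f$pop$sample, annotated_genes(f$tab)))))
  }
  zm <- zoom_terms(planted_cat, f$meas$values, f$tab, f$dag)
  expect_false("p_adj" %in% names(zm))
  expect_s3_class(zm, "enrichment_result")
})
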