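# Enrichment engines.
#
# Candidate gene lists: one-sided Fisher's exact test (over-representation)
# per category, Benjamini-Hochberg adjustment across the categories tested
# in one run, and the normalized term-frequency k/K as effect size.
#
# Gene lists with a continuous measure: two-sided Mann-Whitney U test per
# category with the delta rank (mean pooled rank of in-category genes minus
# mean rank of the rest) as a signed effect size; positive delta rank means
# the category concentrates in the higher measures.
#
# Zooming into a category re-runs the same engine per member GO term,
# deliberately without multiple-testing adjustment.

#' One-sided Fisher / hypergeometric over-representation probability
#'
#' Probability of observing `k` or more category genes in a sample of size
#' `n` drawn from a background of `N` genes of which `K` are in the
#' category: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Category genes in the sample.
#' @param n Sample size.
#' @param K Category genes in the background.
#' @param N Background size.
#' @return Raw p-value in `[0, 1]`.
#' @export
fisher_unit <- function(k, n, K, N) {
  for (nmv in c("k", "n", "K", "N")) {
    v <- get(nmv)
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      data_error(sprintf("count '%s' must be a single non-negative integer (got %s)", nmv, format(v)))
    }
  }
  if (n > N) data_error(sprintf("sample size n=%d exceeds background N=%d", n, N))
  if (K > N) data_error(sprintf("category count K=%d exceeds background N=%d", K, N))
  if (k > n) data_error(sprintf("category-in-sample count k=%d exceeds sample size n=%d", k, n))
  if (k > K) data_error(sprintf("category-in-sample count k=%d exceeds category count K=%d", k, K))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values in the input order, with monotonicity enforced and
#' values capped at 1 (wraps `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    data_error("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Normalized term-frequency
#'
#' The Fisher-branch effect size: the fraction of background genes in the
#' category that also appear in the sample, `k / K`.
#'
#' @param k Category genes in the sample.
#' @param K Category genes in the background (must be positive).
#' @return Fraction in `[0, 1]`.
#' @export
normalized_term_frequency <- function(k, K) {
  if (K <= 0) data_error("normalized term-frequency requires K > 0")
  if (k < 0 || k > K) data_error("k must lie in [0, K]")
  k / K
}

#' Mann-Whitney U test with delta rank
#'
#' Two-sided test that the measures of in-category genes and the remaining
#' genes come from the same distribution. The delta rank is the mean pooled
#' rank (ascending, average ranks for ties) of `in_unit` minus the mean
#' pooled rank of `out_unit`. For small problems (`n1 + n2 <= exact_limit`)
#' the p-value is computed by full enumeration of all `choose(n1+n2, n1)`
#' group labelings of the observed pooled values (so ties are handled
#' exactly); larger problems use the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param in_unit,out_unit Non-empty numeric vectors of finite measures.
#' @param exact_limit Total size at or below which the exact permutation
#'   null is enumerated.
#' @return A list with elements `p` (two-sided p-value), `delta_rank`,
#'   `n_in`, `n_out` and `method` ("exact" or "normal").
#' @export
mwu_unit <- function(in_unit, out_unit, exact_limit = 16) {
  if (length(in_unit) == 0 || length(out_unit) == 0) {
    data_error("both measure groups must be non-empty")
  }
  if (any(!is.finite(in_unit)) || any(!is.finite(out_unit))) {
    data_error("measures must be finite")
  }
  n1 <- length(in_unit); n2 <- length(out_unit); n <- n1 + n2
  r <- rank(c(in_unit, out_unit))
  delta <- mean(r[seq_len(n1)]) - mean(r[n1 + seq_len(n2)])
  w_obs <- sum(r[seq_len(n1)])                # rank sum of the in-group
  e_w <- n1 * (n + 1) / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
    method <- "exact"
  } else {
    # tie-corrected normal approximation with continuity correction on U
    u <- w_obs - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      if (u == mu) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(p = p, delta_rank = delta, n_in = n1, n_out = n2, method = method)
}

#' Specify a sample and its background
#'
#' `background = NULL` means the complete annotated gene universe of the
#' table used downstream. Harmonization (performed inside [run_sea()])
#' restricts the background to annotated genes and forces
#' `sample` \eqn{\subseteq} `background`, dropping and counting violators.
#'
#' @param sample Character vector of candidate gene ids.
#' @param background Character vector of background gene ids, or `NULL`.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample, background = NULL) {
  sample <- unique(trimws(sample))
  sample <- sample[nzchar(sample)]
  if (length(sample) == 0) data_error("sample gene set is empty")
  if (!is.null(background)) {
    background <- unique(trimws(background))
    background <- background[nzchar(background)]
    if (length(background) == 0) data_error("background gene set is empty")
  }
  structure(list(sample = sample, background = background), class = "sample_spec")
}

harmonize_spec <- function(spec, table) {
  universe <- annotated_genes(table)
  bg <- if (is.null(spec$background)) universe else intersect(spec$background, universe)
  n_bg_dropped <- if (is.null(spec$background)) 0L else length(spec$background) - length(bg)
  sm <- intersect(spec$sample, bg)
  n_sm_dropped <- length(spec$sample) - length(sm)
  if (n_sm_dropped > 0) {
    catego_warn(sprintf("%d sample gene(s) outside the annotated background were dropped", n_sm_dropped))
  }
  if (n_bg_dropped > 0) {
    catego_log(n_bg_dropped, " background gene(s) without annotation dropped")
  }
  if (length(sm) == 0) data_error("no sample gene is part of the annotated background")
  list(sample = sm, background = bg,
       dropped = c(sample = n_sm_dropped, background = n_bg_dropped))
}

new_enrichment_result <- function(df, test, not_testable = character(), dropped = NULL) {
  structure(df, class = c("enrichment_result", "data.frame"),
            test = test, not_testable = not_testable, dropped = dropped)
}

#' Category enrichment of a candidate gene list (Fisher branch)
#'
#' For each category, the genes carrying GO terms of that category and
#' present in the sample are compared against the category's genes in the
#' background via a one-sided Fisher's exact test; p-values are adjusted
#' across the tested categories with Benjamini-Hochberg, and the normalized
#' term-frequency k/K is reported as effect size. Categories with no
#' background gene (K = 0) are not testable and are listed in
#' `attr(result, "not_testable")`.
#'
#' @param spec A `sample_spec` (or a character vector of sample genes, which
#'   is taken against the full annotated universe).
#' @param cats A `category_set`.
#' @param table An `annotation_table`.
#' @param dag A `go_dag`.
#' @param include_descendants Propagate annotations up the DAG for category
#'   membership (default `TRUE`).
#' @return An `enrichment_result` data frame with one row per testable
#'   category: `unit`, `test`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `effect` (rows in category-set order).
#' @export
run_sea <- function(spec, cats, table, dag, include_descendants = TRUE) {
  if (is.character(spec)) spec <- sample_spec(spec)
  h <- harmonize_spec(spec, table)
  n <- length(h$sample); N <- length(h$background)
  rows <- list(); not_testable <- character()
  for (cat_i in cats$categories) {
    cg <- intersect(category_genes(cat_i, table, dag, include_descendants), h$background)
    K <- length(cg)
    if (K == 0) { not_testable <- c(not_testable, cat_i$name); next }
    k <- length(intersect(cg, h$sample))
    rows[[length(rows) + 1L]] <- data.frame(
      unit = cat_i$name, test = "fisher", k = k, K = K, n = n, N = N,
      p_raw = fisher_unit(k, n, K, N), p_adj = NA_real_,
      effect = normalized_term_frequency(k, K), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) data_error("no category is testable against this background")
  df <- do.call(rbind, rows)
  df$p_adj <- bh_adjust(df$p_raw)
  new_enrichment_result(df, "fisher", not_testable, h$dropped)
}

#' Category enrichment of a measured gene list (Mann-Whitney branch)
#'
#' Each gene carries a continuous measure (expression, fold change, ...).
#' Per category, the measures of in-category genes are compared against all
#' remaining annotated genes with a two-sided Mann-Whitney U test; p-values
#' are BH-adjusted across the tested categories and the delta rank is
#' reported as signed effect (positive = category sits in the higher
#' measures).
#'
#' @param measured Named numeric vector: gene id -> finite measure.
#' @param cats,table,dag,include_descendants As in [run_sea()].
#' @return An `enrichment_result` data frame (`effect` = delta rank).
#' @export
run_mwu <- function(measured, cats, table, dag, include_descendants = TRUE) {
  measured <- check_measured(measured)
  keep <- names(measured) %in% annotated_genes(table)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    catego_warn(sprintf("%d measured gene(s) without annotation were dropped", n_dropped))
  }
  measured <- measured[keep]
  if (length(measured) < 2) data_error("fewer than 2 measured genes have annotations")
  genes <- names(measured)
  rows <- list(); not_testable <- character()
  for (cat_i in cats$categories) {
    cg <- intersect(category_genes(cat_i, table, dag, include_descendants), genes)
    if (length(cg) == 0 || length(cg) == length(genes)) {
      not_testable <- c(not_testable, cat_i$name); next
    }
    inside <- genes %in% cg
    res <- mwu_unit(measured[inside], measured[!inside])
    rows[[length(rows) + 1L]] <- data.frame(
      unit = cat_i$name, test = "mwu", k = res$n_in, K = res$n_in,
      n = length(genes), N = length(genes),
      p_raw = res$p, p_adj = NA_real_, effect = res$delta_rank,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) data_error("no category has measured, annotated genes")
  df <- do.call(rbind, rows)
  df$p_adj <- bh_adjust(df$p_raw)
  new_enrichment_result(df, "mwu", not_testable, c(sample = n_dropped))
}

check_measured <- function(measured) {
  if (is.null(names(measured)) || any(!nzchar(names(measured)))) {
    data_error("measured list must be a named numeric vector (gene -> measure)")
  }
  if (anyDuplicated(names(measured))) data_error("measured list has duplicate gene ids")
  if (any(!is.finite(measured))) data_error("measures must be finite")
  if (length(measured) == 0) data_error("measured list is empty")
  measured
}

#' Per-term zoom into one category
#'
#' Re-runs the parent analysis at the level of the category's individual
#' member GO terms (each term descendant-expanded per
#' `include_descendants`), deliberately without p-value adjustment: the
#' result has no `p_adj` column.
#'
#' @param cat A `category` (e.g. picked from the set used in the parent run).
#' @param x Either a `sample_spec` / character vector of sample genes
#'   (Fisher branch) or a named numeric measured vector (MWU branch).
#' @param table An `annotation_table`.
#' @param dag A `go_dag`.
#' @param include_descendants As in [run_sea()].
#' @return An `enrichment_result` data frame with one row per member term
#'   and no `p_adj` column.
#' @export
zoom_terms <- function(cat, x, table, dag, include_descendants = TRUE) {
  per_term_cats <- category_set(lapply(cat$terms, function(t) {
    structure(list(name = t, terms = t), class = "category")
  }), label = paste0("zoom:", cat$name))
  res <- if (is.numeric(x)) {
    run_mwu(x, per_term_cats, table, dag, include_descendants)
  } else {
    run_sea(x, per_term_cats, table, dag, include_descendants)
  }
  res$p_adj <- NULL
  res
}

#' Export an enrichment result as TSV
#' @param res An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(res, path) {
  df <- as.data.frame(res)
  for (col in intersect(c("p_raw", "p_adj", "effect"), names(df))) {
    df[[col]] <- num_chr(df[[col]], digits = 10)
  }
  write_tsv(df, path)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s test, %d unit(s)", attr(x, "test"), nrow(x)))
  nt <- attr(x, "not_testable")
  if (length(nt) > 0) cat(sprintf(" (+%d not testable)", length(nt)))
  cat("\n")
  df <- as.data.frame(x)
  df <- df[order(df$p_raw), , drop = FALSE]
  print(utils::head(df, 12), row.names = FALSE)
  if (nrow(df) > 12) cat("  ... ", nrow(df) - 12, " more rows\n", sep = "")
  invisible(x)
}
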