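make_ds <- function(counts, group = NULL, species = "human", id = "t") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }
  group <- group %||% rep(c("control", "treated"), each = ncol(counts) / 2)
  count_dataset(counts, group, species = species, id = id)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("normalization factors are exact on proportional libraries", {
  base <- matrix(rpois(80, 50) + 1, ncol = 1)
  counts <- cbind(base, 2 * base, base, 2 * base)
  ds <- make_ds(counts)
  f <- normalize_counts(ds)
  expect_equal(unname(f), c(
    2^-0.5, 2^0.5,
    2^-0.5, 2^0.5
  ), tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # identical samples give unit factors
  ds2 <- make_ds(cbind(base, base, base, base))
  expect_equal(unname(normalize_counts(ds2)), rep(1, 4), tolerance = 1e-12)
})

test_that("normalization is invariant to gene order and flags all-zero samples", {
  set.seed(4)
  counts <- matrix(rnbinom(400, mu = 100, size = 10), ncol = 4)
  ds <- make_ds(counts)
  perm <- sample(nrow(counts))
  ds_perm <- make_ds(counts[perm, , drop = FALSE])
  expect_equal(unname(normalize_counts(ds)), unname(normalize_counts(ds_perm)))
  bad <- counts
  bad[, 2] <- 0
  expect_error(normalize_counts(make_ds(bad)), "s2")
})

test_that("bh_adjust matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("a flat gene shows no signal and groups need two samples", {
  counts <- matrix(50L, nrow = 3, ncol = 8)
  counts[2, ] <- c(10L, 12L, 9L, 11L, 40L, 44L, 39L, 41L)
  counts[3, ] <- rpois(8, 30)
  ds <- make_ds(counts)
  de <- test_differential_expression(ds, factors = setNames(rep(1, 8), ds$samples))
  expect_equal(de$log2_fold_change[1], 0)
  expect_gte(de$p_value[1], 0.99)
  expect_lt(de$p_value[2], 0.05)
  expect_error(
    test_differential_expression(
      make_ds(counts[, 1:3], group = c("control", "treated", "treated"))
    ),
    "at least 2"
  )
})

test_that("all-zero genes get p = 1 and zero fold change", {
  counts <- rbind(matrix(rpois(40, 60), ncol = 4), 0L)
  ds <- make_ds(counts)
  de <- test_differential_expression(ds)
  expect_equal(de$p_value[nrow(counts)], 1)
  expect_equal(de$log2_fold_change[nrow(counts)], 0)
})

test_that("size factors track sequencing depth and edgeR effective sizes", {
  skip_if_not_installed("edgeR")
  # samples at deliberately different depths over a common expression profile
  set.seed(21)
  depth <- c(0.5, 1, 2, 4, 1, 2, 0.5, 4)
  base <- 2^runif(500, 4, 10)
  counts <- vapply(depth, function(d) rnbinom(500, mu = base * d, size = 10), numeric(500))
  rownames(counts) <- sprintf("G%03d", 1:500)
  colnames(counts) <- sprintf("s%d", 1:8)
  ds <- count_dataset(counts, rep(c("control", "treated"), each = 4))
  f <- normalize_counts(ds)
  expect_equal(unname(f), depth / exp(mean(log(depth))), tolerance = 0.05)
  eff <- edgeR::calcNormFactors(ds$counts, method = "TMM") * colSums(ds$counts)
  eff <- eff / exp(mean(log(eff)))
  expect_gt(cor(log(f), log(eff)), 0.99)
})

test_that("null p-values are approximately uniform and planted genes are recovered", {
  null_frac <- ks <- numeric(5)
  recall <- numeric(5)
  for (i in 1:5) {
    null_spec <- transcriptome_sim_spec(
      n_genes = 2000, n_planted_up = 0, n_planted_down = 0,
      log2_effect = 0, study_specific_frac = 0, n_studies = 2, seed = 500 + i
    )
    nsim <- simulate_count_datasets(null_spec)
    nde <- test_differential_expression(nsim$datasets[[2]])
    null_frac[i] <- mean(nde$q_value < 0.01)
    ks[i] <- suppressWarnings(stats::ks.test(nde$p_value, "punif")$statistic)

    alt_spec <- transcriptome_sim_spec(
      n_genes = 2000, n_planted_up = 100, n_planted_down = 50,
      log2_effect = 2, dispersion = 0.1, samples_per_group = 4,
      n_studies = 2, seed = 600 + i
    )
    asim <- simulate_count_datasets(alt_spec)
    ade <- test_differential_expression(asim$datasets[[2]])
    planted <- ade$gene %in% c(asim$truth$planted_up, asim$truth$planted_down)
    recall[i] <- mean(ade$q_value[planted] < 0.01)
  }
  expect_lte(max(null_frac), 0.02)
  expect_lt(max(ks), 0.05)
  expect_gte(min(recall), 0.8)
})

test_that("ortholog mapping drops unmapped symbols and direction conflicts", {
  tbl <- tibble::tibble(
    source_symbol = c("Trp53", "A", "B", "Multi", "Multi"),
    human_symbol = c("TP53", "H1", "H1", "M1", "M2")
  )
  m <- map_orthologs(
    tibble::tibble(symbol = "Trp53", direction = "up"), tbl
  )
  expect_equal(m$calls$symbol, "TP53")
  m2 <- map_orthologs(
    tibble::tibble(symbol = "Gm123", direction = "up"), tbl
  )
  expect_equal(nrow(m2$calls), 0)
  expect_equal(m2$unmapped, "Gm123")
  m3 <- map_orthologs(
    tibble::tibble(symbol = c("A", "B"), direction = c("up", "down")), tbl
  )
  expect_equal(nrow(m3$calls), 0)
  expect_equal(m3$conflicting, "H1")
  m4 <- map_orthologs(
    tibble::tibble(symbol = "Multi", direction = "down"), tbl
  )
  expect_setequal(m4$calls$symbol, c("M1", "M2"))
})

test_that("signature intersection is direction-consistent and order-invariant", {
  calls <- list(
    list(up = c("A", "B", "C"), down = c("X", "Z")),
    list(up = c("B", "C", "D"), down = c("X", "Y")),
    list(up = c("B", "C"), down = c("X", "C2"))
  )
  sig <- intersect_signatures(calls)
  expect_setequal(sig$up, c("B", "C"))
  expect_setequal(sig$down, "X")
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    sig_p <- intersect_signatures(calls[perm])
    expect_identical(sig_p$up, sig$up)
    expect_identical(sig_p$down, sig$down)
  }
  # a gene up in two datasets and down in the third is excluded from both
  mixed <- list(
    list(up = c("G"), down = character()),
    list(up = c("G"), down = character()),
    list(up = character(), down = c("G"))
  )
  sig_m <- intersect_signatures(mixed)
  expect_length(sig_m$up, 0)
  expect_length(sig_m$down, 0)
  expect_error(
    intersect_signatures(list(list(up = "A", down = "A"), list(up = "A", down = "B"))),
    "both"
  )
  expect_error(intersect_signatures(calls[1]), "at least 2")
})

test_that("cross-study signature recovery attains Jaccard >= 0.7", {
  jac <- vapply(1:5, function(i) {
    sim <- simulate_count_datasets(transcriptome_sim_spec(seed = 700 + i))
    sig <- build_signature(sim$datasets, sim$ortholog_table, fdr = 0.01)
    got <- c(sig$up, sig$down)
    want <- c(sim$truth$planted_up, sim$truth$planted_down)
    length(intersect(got, want)) / length(union(got, want))
  }, numeric(1))
  expect_gte(min(jac), 0.7)
})

test_that("hypergeometric enrichment matches the exact tail-sum oracle", {
  universe <- sprintf("U%02d", 1:20)
  res <- enrich_gene_sets(
    universe[1:5],
    list(S = c(universe[3:5], universe[11:12])), universe
  )
  expect_equal(res$p_value, 0.07262, tolerance = 1e-4)
  expect_equal(res$p_value, hyper_tail_oracle(3, 5, 5, 20), tolerance = 1e-12)
  # saturated set: overlap = query size, p = 1
  res2 <- enrich_gene_sets(universe[1:5], list(ALL = universe), universe)
  expect_equal(res2$overlap, 5)
  expect_equal(res2$p_value, 1)
  # empty query
  res3 <- enrich_gene_sets(character(), list(S = universe[1:5]), universe)
  expect_equal(res3$p_value, 1)
  expect_error(enrich_gene_sets(universe[1], list(S = "U01"), character()), "universe")
})
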