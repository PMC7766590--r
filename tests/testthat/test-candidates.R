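map_fixture <- function() {
  tibble::tibble(
    name = c("PALONOSETRON", "PACLITAXEL", "VORINOSTAT"),
    atc_code = c("A04AA05", "L01CD01", "L01XH01")
  )
}

test_that("names and ATC codes align into one identity space", {
  space <- harmonize_names(
    c("palonosetron", "Pert_001"), c("A04AA05", "C03CA01"), map_fixture()
  )
  pal <- space[space$identity == "A04AA05", ]
  expect_true(any(pal$connectivity_name == "palonosetron", na.rm = TRUE))
  expect_true("C03CA01" %in% space$identity)
  expect_true("PERT_001" %in% space$identity) # unmapped name kept as itself
})

test_that("salt suffixes are stripped before mapping", {
  space <- harmonize_names("Palonosetron  Hydrochloride", character(), map_fixture())
  expect_equal(space$identity, "A04AA05")
  expect_equal(space$canonical_name, "PALONOSETRON")
})

test_that("an empty mapping table forces an empty intersection", {
  conn <- tibble::tibble(name = "PALONOSETRON", tau = -90)
  faers <- tibble::tibble(drug = "A04AA05", ror = 0.4, ci_low = 0.3, ci_high = 0.6)
  space <- harmonize_names(
    conn$name, faers$drug,
    tibble::tibble(name = character(), atc_code = character())
  )
  out <- intersect_candidates(conn, faers, space)
  expect_false(any(out$in_both))
})

test_that("two perturbagen names mapping to one code merge into one identity", {
  map <- tibble::tibble(
    name = c("PALONOSETRON", "PALONOSETRON HCL"),
    atc_code = c("A04AA05", "A04AA05")
  )
  conn <- tibble::tibble(
    name = c("palonosetron", "PALONOSETRON HCL"), tau = c(-90, -80)
  )
  space <- harmonize_names(conn$name, character(), map)
  out <- intersect_candidates(
    conn,
    tibble::tibble(drug = character(), ror = numeric(), ci_low = numeric(), ci_high = numeric()),
    space
  )
  expect_equal(sum(out$identity == "A04AA05"), 1)
  expect_equal(out$tau[out$identity == "A04AA05"], -90) # strongest reversal kept
})

test_that("in-both candidates equal the set-intersection oracle", {
  map <- map_fixture()
  conn <- tibble::tibble(
    name = c("PALONOSETRON", "VORINOSTAT", "PERT_199"),
    tau = c(-95, -60, -40)
  )
  faers <- tibble::tibble(
    drug = c("A04AA05", "C03CA01"),
    ror = c(0.4, 0.7), ci_low = c(0.3, 0.5), ci_high = c(0.55, 0.9)
  )
  space <- harmonize_names(conn$name, faers$drug, map)
  out <- intersect_candidates(conn, faers, space)
  # oracle: map names through the table, intersect code sets
  mapped <- map$atc_code[match(conn$name, map$name)]
  want <- intersect(mapped[!is.na(mapped)], faers$drug)
  expect_setequal(out$identity[out$in_both], want)
  expect_setequal(
    unlist(out$sources[out$in_both][1]),
    c("connectivity", "faers")
  )
  # input order does not matter
  out2 <- intersect_candidates(conn[3:1, ], faers[2:1, ], space)
  expect_equal(as.data.frame(out2), as.data.frame(out))
})

test_that("the synthetic pipeline nominates exactly the double-role drug", {
  cfg <- default_pipeline_config(seed = 5)
  cfg$simulate$transcriptome <- list(n_genes = 600, n_planted_up = 40, n_planted_down = 20)
  cfg$simulate$faers <- list(n_cases = 20000)
  out_dir <- withr::local_tempdir()
  res <- run_pipeline(cfg, out_dir = out_dir)
  expect_equal(unlist(res$summary$in_both), "PALONOSETRON")
  # summary counts equal the serialized artifact sizes (no silent drops)
  conn_file <- read.delim(file.path(out_dir, "connectivity.tsv"))
  expect_equal(nrow(conn_file), res$summary$n_perturbagens)
  expect_equal(sum(conn_file$selected), res$summary$n_selected_chemicals)
  screen_file <- read.delim(file.path(out_dir, "faers_screen.tsv"))
  expect_equal(nrow(screen_file), res$summary$n_screened_drugs)
  sig_json <- jsonlite::read_json(file.path(out_dir, "signature.json"))
  expect_length(sig_json$up, res$summary$n_up)
  expect_true(file.exists(file.path(out_dir, "run.log")))
})

test_that("rerunning the pipeline with the same seed reproduces the summary", {
  cfg <- default_pipeline_config(seed = 8)
  cfg$simulate$transcriptome <- list(n_genes = 300, n_planted_up = 20, n_planted_down = 10)
  cfg$simulate$faers <- list(n_cases = 5000)
  a <- run_pipeline(cfg)
  b <- run_pipeline(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(as.data.frame(a$candidates), as.data.frame(b$candidates))
})

test_that("a config without pharmacovigilance inputs degrades to connectivity-only", {
  sim <- simulate_count_datasets(transcriptome_sim_spec(
    n_genes = 300, n_planted_up = 20, n_planted_down = 10, seed = 2
  ))
  dir <- withr::local_tempdir()
  for (ds in sim$datasets) write_count_dataset(ds, file.path(dir, ds$id))
  write_tsv_table(sim$ortholog_table, file.path(dir, "orthologs.tsv"))
  sig <- build_signature(sim$datasets, sim$ortholog_table)
  lib_sim <- simulate_signature_library(
    library_sim_spec(n_genes = 300, n_perturbagens = 50, seed = 3), sig
  )
  write_gct(lib_sim$library, file.path(dir, "lib.gct"))
  cfg <- list(
    seed = 1,
    inputs = list(
      counts = file.path(dir, paste0(c("study1", "study2", "study3"), "_counts.tsv")),
      labels = file.path(dir, paste0(c("study1", "study2", "study3"), "_labels.tsv")),
      species = c("mouse", "mouse", "human"),
      ids = c("study1", "study2", "study3"),
      orthologs = file.path(dir, "orthologs.tsv"),
      library = file.path(dir, "lib.gct")
    )
  )
  res <- run_pipeline(cfg)
  expect_null(res$screen)
  expect_null(res$summary$n_protective_drugs)
  expect_false(any(res$candidates$in_both))
})

test_that("a failing stage reports its name", {
  cfg <- list(seed = 1, inputs = list(counts = "missing.tsv", labels = "missing.tsv",
                                      species = "human", ids = "x"))
  expect_error(run_pipeline(cfg), "stage 'signature'")
})
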