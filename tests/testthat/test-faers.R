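write_fixture_files <- function(demo, drug, reac, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- c(
    demo = file.path(dir, "DEMO.txt"),
    drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt")
  )
  writeLines(demo, paths["demo"])
  writeLines(drug, paths["drug"])
  writeLines(reac, paths["reac"])
  paths
}

test_that("the dialect reader joins drugs and reactions to cases", {
  paths <- write_fixture_files(
    demo = c("primaryid$caseid$caseversion", "11$1$1"),
    drug = c("primaryid$drugname", "11$CISPLATIN", "11$Palonosetron HCl"),
    reac = c("primaryid$pt", "11$ACUTE KIDNEY INJURY")
  )
  reports <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(reports), 1)
  expect_length(reports$drugs[[1]], 2)
  expect_equal(reports$reactions[[1]], "ACUTE KIDNEY INJURY")
})

test_that("cases with no reactions are retained and orphan rows are counted", {
  paths <- write_fixture_files(
    demo = c("primaryid$caseid$caseversion", "11$1$1", "21$2$1"),
    drug = c("primaryid$drugname", "11$CISPLATIN", "99$GHOST"),
    reac = c("primaryid$pt")
  )
  reports <- read_faers_tables(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(reports), 2)
  expect_length(reports$reactions[[1]], 0)
  expect_equal(unname(attr(reports, "orphans")["drug"]), 1)
})

test_that("malformed rows and headers fail with a line number", {
  paths <- write_fixture_files(
    demo = c("primaryid$caseid$caseversion", "11$1$1", "12$2"),
    drug = c("primaryid$drugname"),
    reac = c("primaryid$pt")
  )
  expect_error(
    read_faers_tables(paths["demo"], paths["drug"], paths["reac"]),
    "line 3"
  )
  paths2 <- write_fixture_files(
    demo = c("caseid$caseversion", "1$1"),
    drug = c("primaryid$drugname"),
    reac = c("primaryid$pt")
  )
  expect_error(
    read_faers_tables(paths2["demo"], paths2["drug"], paths2["reac"]),
    "header"
  )
})

test_that("deduplication keeps the most recent version and is idempotent", {
  reports <- faers_reports(
    demo = tibble::tibble(
      primaryid = c(71L, 72L, 81L, 95L, 94L),
      caseid = c(7L, 7L, 8L, 9L, 9L),
      caseversion = c(1L, 2L, 1L, 3L, 3L)
    ),
    drug = tibble::tibble(primaryid = c(71L, 72L), drugname = c("OLD", "NEW")),
    reac = tibble::tibble(primaryid = integer(), pt = character())
  )
  dd <- deduplicate_cases(reports)
  expect_equal(dd$caseid, c(7L, 8L, 9L))
  expect_equal(dd$primaryid[dd$caseid == 7L], 72L)
  expect_equal(dd$drugs[[1]], "NEW")
  # version tie broken by highest primaryid
  expect_equal(dd$primaryid[dd$caseid == 9L], 95L)
  expect_identical(
    as.data.frame(deduplicate_cases(dd)),
    as.data.frame(dd)
  )
})

test_that("dedup and collation recover the generator truth exactly", {
  spec <- faers_sim_spec(n_cases = 1000, duplicate_frac = 0.3, seed = 77)
  sim <- simulate_faers_tables(spec)
  reports <- faers_reports(sim$demo, sim$drug, sim$reac) |>
    deduplicate_cases() |>
    collate_to_atc(spec$synonym_table)
  expect_identical(reports$primaryid, sim$truth$cases$primaryid)
  got <- tibble::tibble(
    caseid = rep(reports$caseid, lengths(reports$drugs)),
    atc_code = unlist(reports$drugs)
  ) |> dplyr::arrange(caseid, atc_code)
  expect_identical(got, sim$truth$case_drugs)
})

test_that("collation normalizes verbatim strings and counts unmapped ones", {
  syn <- tibble::tibble(
    verbatim = c("PALONOSETRON HCL", "PALONOSETRON"),
    atc_code = c("A04AA05", "A04AA05")
  )
  reports <- faers_reports(
    demo = tibble::tibble(primaryid = 1L, caseid = 1L, caseversion = 1L),
    drug = tibble::tibble(
      primaryid = 1L,
      drugname = c(" Palonosetron   HCl ", "PALONOSETRON", "HERBAL BLEND")
    ),
    reac = tibble::tibble(primaryid = integer(), pt = character())
  )
  out <- collate_to_atc(reports, syn)
  expect_equal(out$drugs[[1]], "A04AA05")
  expect_equal(attr(out, "unmapped")$verbatim, "HERBAL BLEND")
  expect_equal(attr(out, "unmapped")$n, 1L)
  bad <- tibble::tibble(verbatim = "X", atc_code = "BAD1")
  expect_error(collate_to_atc(reports, bad), "ATC")
})

test_that("cohort construction filters on the causative drug", {
  reports <- faers_reports(
    demo = tibble::tibble(primaryid = 1:3, caseid = 1:3, caseversion = 1L),
    drug = tibble::tibble(
      primaryid = c(1L, 1L, 2L),
      drugname = c("CISPLATIN", "PALONOSETRON", "PALONOSETRON")
    ),
    reac = tibble::tibble(primaryid = integer(), pt = character())
  ) |> collate_to_atc(default_synonym_table())
  cohort <- build_cohort(reports, "L01XA01")
  expect_equal(cohort$caseid, 1L)
  expect_error(build_cohort(reports, "Z99ZZ99"), "empty")
  all_in <- build_cohort(reports[1, ], "L01XA01")
  expect_equal(nrow(all_in), 1)
})

test_that("contingency tables classify one case per cell", {
  rx <- "ACUTE KIDNEY INJURY"
  cohort <- faers_reports(
    demo = tibble::tibble(primaryid = 1:4, caseid = 1:4, caseversion = 1L),
    drug = tibble::tibble(
      primaryid = c(1L, 2L, 1L, 2L, 3L, 4L),
      drugname = c("ONDANSETRON", "ONDANSETRON", rep("CISPLATIN", 4))
    ),
    reac = tibble::tibble(primaryid = c(1L, 3L), pt = rx)
  ) |>
    collate_to_atc(default_synonym_table()) |>
    build_cohort("L01XA01")
  tab <- contingency_for(cohort, "A04AA01", rx)
  expect_equal(unlist(tab), c(d1r1 = 1, d1r0 = 1, d0r1 = 1, d0r0 = 1))
  expect_error(contingency_for(cohort, "L01XA01", rx), "causative")
  # absent co-drug: empty exposed margin
  tab2 <- contingency_for(cohort, "A04AA05", rx)
  expect_equal(tab2$d1r1 + tab2$d1r0, 0)
  # matches the per-case recount oracle
  expect_equal(unlist(tab), contingency_oracle(cohort, "A04AA01", rx))
})

test_that("compute_ror reproduces the closed-form worked examples", {
  balanced <- compute_ror(c(10, 10, 10, 10))
  expect_equal(balanced$ror, 1)
  expect_lt(balanced$ci_low, 1)
  expect_gt(balanced$ci_high, 1)
  expect_false(balanced$protective)

  r <- compute_ror(contingency_table(10, 90, 200, 700))
  expect_equal(r$ror, 0.3889, tolerance = 1e-4)
  expect_equal(r$ci_low, 0.199, tolerance = 5e-3)
  expect_equal(r$ci_high, 0.762, tolerance = 5e-3)
  expect_true(r$protective)
  expect_false(r$corrected)

  rc <- compute_ror(c(0, 50, 100, 400))
  expect_true(rc$corrected)
  expect_equal(rc$ror, 0.03946, tolerance = 1e-3)

  und <- compute_ror(c(0, 0, 10, 20))
  expect_true(und$undefined)
  expect_false(und$protective)
})

test_that("ror matches the log-space oracle on random tables", {
  set.seed(8)
  for (i in 1:500) {
    cells <- rpois(4, lambda = sample(c(2, 20, 200), 1))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    got <- compute_ror(cells)
    want <- ror_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$ror, unname(want["ror"]), tolerance = 1e-10)
    expect_equal(got$ci_low, unname(want["ci_low"]), tolerance = 1e-10)
    expect_equal(got$ci_high, unname(want["ci_high"]), tolerance = 1e-10)
  }
})

test_that("reversing the reaction inverts the odds ratio and its interval", {
  set.seed(9)
  for (i in 1:50) {
    cells <- rpois(4, 30) + 1
    a <- compute_ror(cells)
    b <- compute_ror(cells[c(2, 1, 4, 3)])
    expect_equal(a$ror, 1 / b$ror, tolerance = 1e-10)
    expect_equal(a$ci_low, 1 / b$ci_high, tolerance = 1e-10)
    expect_equal(a$ci_high, 1 / b$ci_low, tolerance = 1e-10)
  }
})

test_that("the screen flags the planted protective drug and spares nulls", {
  spec <- faers_sim_spec(n_cases = 50000, seed = 19)
  sim <- simulate_faers_tables(spec)
  screen <- faers_reports(sim$demo, sim$drug, sim$reac) |>
    deduplicate_cases() |>
    collate_to_atc(spec$synonym_table) |>
    build_cohort("L01XA01") |>
    screen_comedications("ACUTE KIDNEY INJURY", min_exposed = 3)
  truth <- sim$truth$co_drugs
  prot <- truth$atc_code[truth$role == "protective"]
  risk <- truth$atc_code[truth$role == "risk"]
  expect_true(screen$protective[screen$drug == prot])
  expect_false(screen$protective[screen$drug == risk])
  expect_gt(screen$ci_low[screen$drug == risk], 1)
  # sorted by upper bound
  expect_true(!is.unsorted(screen$ci_high))
})

test_that("the screen is invariant to input row order", {
  spec <- faers_sim_spec(n_cases = 2000, seed = 23)
  sim <- simulate_faers_tables(spec)
  run <- function(demo, drug, reac) {
    faers_reports(demo, drug, reac) |>
      deduplicate_cases() |>
      collate_to_atc(spec$synonym_table) |>
      build_cohort("L01XA01") |>
      screen_comedications("ACUTE KIDNEY INJURY")
  }
  a <- run(sim$demo, sim$drug, sim$reac)
  set.seed(1)
  b <- run(
    sim$demo[sample(nrow(sim$demo)), ],
    sim$drug[sample(nrow(sim$drug)), ],
    sim$reac[sample(nrow(sim$reac)), ]
  )
  expect_equal(as.data.frame(a), as.data.frame(b))
})
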