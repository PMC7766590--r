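# End-to-end orchestration: signature construction -> connectivity query, in
# parallel with the pharmacovigilance screen, intersected into a candidate
# report bundle.

#' Default configuration for a fully synthetic pipeline run
#'
#' The synthetic scenario plants one identity with a double role: the first
#' planted reverser in the signature library is displayed as PALONOSETRON,
#' which is also the planted protective co-medication (ATC A04AA05, odds
#' multiplier 0.3) in the adverse-event simulator — so a correct end-to-end
#' run nominates exactly that identity in both candidate lists.
#'
#' @param seed Integer master seed; sub-seeds for the three generators are
#'   derived from it.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    fdr = 0.01,
    tau_threshold = 0,
    drug_a = "L01XA01",
    reaction = "ACUTE KIDNEY INJURY",
    min_exposed = 3,
    simulate = list(
      transcriptome = list(),
      library = list(n_reversers = 5, n_mimickers = 5),
      faers = list(),
      reverser_display_name = "PALONOSETRON"
    ),
    mapping_table = data.frame(
      name = c("PALONOSETRON", "PACLITAXEL", "ONDANSETRON", "VANCOMYCIN"),
      atc_code = c("A04AA05", "L01CD01", "A04AA01", "J01XA01")
    )
  )
}

log_line <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full drug-repositioning pipeline
#'
#' Executes signature construction, the connectivity query and the
#' pharmacovigilance screen, then intersects the candidate lists. Inputs are
#' either simulated (config `simulate` block) or read from the paths in
#' config `inputs`. When the pharmacovigilance inputs are absent the run
#' degrades to a connectivity-only report with null FAERS fields.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir Optional directory; when given, all intermediate artifacts
#'   (signature GMT/JSON, connectivity TSV, screen TSV, candidate TSV,
#'   summary JSON, run log) are written there.
#' @return List with `signature`, `connectivity`, `screen`, `candidates`,
#'   `summary` (list also serialized as JSON), and `truth` when simulated.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- check_seed(config$seed %||% 1)
  fdr <- config$fdr %||% 0.01
  tau_threshold <- config$tau_threshold %||% 0
  min_exposed <- config$min_exposed %||% 3

  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(out_dir, "run.log"), "w")
    on.exit(close(log_con))
  }
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  log_line(log_con, sprintf("pipeline start (seed=%d, config_hash=%.0f)", seed, cfg_hash))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = "cindr_pipeline_error"
      )
    })
  }

  truth <- list()
  simulate <- config$simulate

  # --- signature stage ------------------------------------------------------
  sig <- stage("signature", {
    if (!is.null(simulate)) {
      t_spec <- do.call(
        transcriptome_sim_spec,
        utils::modifyList(list(seed = derive_seed(seed, 1)), simulate$transcriptome %||% list())
      )
      sim <- simulate_count_datasets(t_spec)
      truth$transcriptome <- sim$truth
      datasets <- sim$datasets
      ortho <- sim$ortholog_table
    } else {
      inp <- config$inputs
      datasets <- purrr::pmap(
        data.frame(
          counts = inp$counts, labels = inp$labels,
          species = inp$species, id = inp$ids
        ),
        function(counts, labels, species, id) {
          read_count_dataset(counts, labels, species = species, id = id)
        }
      )
      ortho <- if (!is.null(inp$orthologs)) read_tsv_table(inp$orthologs) else NULL
    }
    build_signature(datasets, ortholog_table = ortho, fdr = fdr)
  })
  log_line(log_con, sprintf(
    "signature: %d up / %d down genes", length(sig$up), length(sig$down)
  ))

  # --- connectivity stage ---------------------------------------------------
  conn <- stage("connectivity", {
    if (!is.null(simulate)) {
      n_genes <- length(truth$transcriptome$universe)
      l_spec <- do.call(
        library_sim_spec,
        utils::modifyList(
          list(seed = derive_seed(seed, 2), n_genes = n_genes),
          simulate$library %||% list()
        )
      )
      lib_sim <- simulate_signature_library(l_spec, sig)
      lib <- lib_sim$library
      display <- simulate$reverser_display_name
      if (!is.null(display)) {
        rev_ids <- lib_sim$truth$perturbagen[lib_sim$truth$role == "reverser"]
        if (length(rev_ids) > 0) {
          lib$names[match(rev_ids[1], lib$perturbagens)] <- display
          lib_sim$truth$name <- lib$names
        }
      }
      truth$library <- lib_sim$truth
    } else {
      lib <- read_gct(config$inputs$library)
    }
    query_library(sig, lib, tau_threshold = tau_threshold)
  })
  log_line(log_con, sprintf("connectivity: %d of %d perturbagens selected (tau < %s)",
    sum(conn$selected), nrow(conn), format(tau_threshold)
  ))

  # --- pharmacovigilance stage ---------------------------------------------
  have_faers <- !is.null(simulate) || !is.null(config$inputs$demo)
  screen <- NULL
  if (have_faers) {
    screen <- stage("faers_screen", {
      if (!is.null(simulate)) {
        f_spec <- do.call(
          faers_sim_spec,
          utils::modifyList(list(seed = derive_seed(seed, 3)), simulate$faers %||% list())
        )
        tabs <- simulate_faers_tables(f_spec)
        truth$faers <- tabs$truth
        reports <- faers_reports(tabs$demo, tabs$drug, tabs$reac)
        synonyms <- f_spec$synonym_table
      } else {
        inp <- config$inputs
        reports <- read_faers_tables(inp$demo, inp$drug, inp$reac)
        synonyms <- read_tsv_table(inp$synonyms)
      }
      reports |>
        deduplicate_cases() |>
        collate_to_atc(synonyms) |>
        build_cohort(config$drug_a %||% "L01XA01") |>
        screen_comedications(
          reaction = config$reaction %||% "ACUTE KIDNEY INJURY",
          min_exposed = min_exposed
        )
    })
    log_line(log_con, sprintf(
      "faers_screen: cohort %d cases, %d drugs screened, %d protective",
      attr(screen, "n_cohort"), nrow(screen), sum(screen$protective)
    ))
  } else {
    log_line(log_con, "faers_screen: skipped (no inputs)")
  }

  # --- candidate stage ------------------------------------------------------
  candidates <- stage("candidates", {
    mapping <- config$mapping_table %||% data.frame(name = character(), atc_code = character())
    if (is.list(mapping) && !is.data.frame(mapping)) mapping <- as.data.frame(mapping)
    faers_codes <- if (is.null(screen)) character() else screen$drug
    space <- harmonize_names(conn$name, faers_codes, mapping)
    empty_screen <- tibble::tibble(
      drug = character(), ror = numeric(),
      ci_low = numeric(), ci_high = numeric()
    )
    intersect_candidates(conn, screen %||% empty_screen, space)
  })

  in_both <- candidates$canonical_name[candidates$in_both]
  summary <- list(
    seed = seed,
    config_hash = cfg_hash,
    n_up = length(sig$up),
    n_down = length(sig$down),
    n_perturbagens = nrow(conn),
    n_selected_chemicals = sum(conn$selected),
    n_cohort = if (is.null(screen)) NULL else attr(screen, "n_cohort"),
    n_screened_drugs = if (is.null(screen)) NULL else nrow(screen),
    n_protective_drugs = if (is.null(screen)) NULL else sum(screen$protective),
    in_both = as.list(in_both)
  )
  log_line(log_con, sprintf(
    "candidates: %d identities, in both lists: %s",
    nrow(candidates),
    if (length(in_both)) paste(in_both, collapse = ", ") else "(none)"
  ))

  if (!is.null(out_dir)) {
    write_signature_gmt(sig, file.path(out_dir, "signature.gmt"))
    jsonlite::write_json(
      list(up = sig$up, down = sig$down, provenance = sig$provenance),
      file.path(out_dir, "signature.json"),
      auto_unbox = FALSE, pretty = TRUE
    )
    write_tsv_table(as.data.frame(conn), file.path(out_dir, "connectivity.tsv"))
    if (!is.null(screen)) {
      write_tsv_table(as.data.frame(screen), file.path(out_dir, "faers_screen.tsv"))
    }
    cand_flat <- dplyr::mutate(candidates,
      sources = vapply(.data$sources, paste, character(1), collapse = ";")
    )
    write_tsv_table(as.data.frame(cand_flat), file.path(out_dir, "candidates.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  log_line(log_con, "pipeline done")

  list(
    signature = sig, connectivity = conn, screen = screen,
    candidates = candidates, summary = summary,
    truth = if (length(truth)) truth else NULL
  )
}
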