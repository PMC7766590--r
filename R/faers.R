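# Adverse-event report screening: parse the simplified $-delimited
# DEMO/DRUG/REAC dialect, deduplicate versioned cases, collate verbatim drug
# strings to ATC level 5, and screen co-medications within the causative-drug
# cohort by reporting odds ratio.

parse_dollar_file <- function(path, expected_header) {
  check_file_exists(path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) {
    rlang::abort(sprintf("%s: empty file (missing header)", path), class = "cindr_parse_error")
  }
  parts <- strsplit(lines, "$", fixed = TRUE)
  header <- parts[[1]]
  if (!identical(header, expected_header)) {
    rlang::abort(
      sprintf(
        "%s: line 1: expected header '%s', found '%s'",
        path, paste(expected_header, collapse = "$"), paste(header, collapse = "$")
      ),
      class = "cindr_parse_error"
    )
  }
  body <- parts[-1]
  arity <- lengths(body)
  bad <- which(arity != length(expected_header))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf(
        "%s: line %d: expected %d fields, found %d",
        path, bad[1] + 1L, length(expected_header), arity[bad[1]]
      ),
      class = "cindr_parse_error"
    )
  }
  if (length(body) == 0) {
    out <- as.data.frame(matrix(character(0), ncol = length(expected_header)))
  } else {
    out <- as.data.frame(do.call(rbind, body))
  }
  names(out) <- expected_header
  tibble::as_tibble(out)
}

#' Read adverse-event report tables
#'
#' Parses the simplified `$`-delimited report dialect (UTF-8, no quoting,
#' first line a fixed header): DEMO `primaryid$caseid$caseversion`, DRUG
#' `primaryid$drugname`, REAC `primaryid$pt`. Drug and reaction rows are
#' joined to reports by `primaryid`; rows referencing unknown primary ids are
#' skipped and counted. Reports with no reaction rows are retained (they
#' count toward the no-reaction cells of the screen).
#'
#' @param demo_path,drug_path,reac_path File paths.
#' @return A tibble of class `faers_reports` with columns `primaryid`,
#'   `caseid`, `caseversion`, list-columns `drugs` (verbatim strings) and
#'   `reactions`; attribute `orphans` counts skipped rows per table.
#' @export
read_faers_tables <- function(demo_path, drug_path, reac_path) {
  demo <- parse_dollar_file(demo_path, c("primaryid", "caseid", "caseversion"))
  drug <- parse_dollar_file(drug_path, c("primaryid", "drugname"))
  reac <- parse_dollar_file(reac_path, c("primaryid", "pt"))
  demo <- dplyr::mutate(
    demo,
    primaryid = as.integer(.data$primaryid),
    caseid = as.integer(.data$caseid),
    caseversion = as.integer(.data$caseversion)
  )
  drug$primaryid <- as.integer(drug$primaryid)
  reac$primaryid <- as.integer(reac$primaryid)
  faers_reports(demo, drug, reac)
}

#' Assemble case reports from DEMO/DRUG/REAC tables
#'
#' Table-level counterpart of [read_faers_tables()] for inputs already in
#' memory (e.g. straight from [simulate_faers_tables()]).
#'
#' @param demo Tibble `primaryid`, `caseid`, `caseversion`.
#' @param drug Tibble `primaryid`, `drugname`.
#' @param reac Tibble `primaryid`, `pt`.
#' @return A `faers_reports` tibble; see [read_faers_tables()].
#' @export
faers_reports <- function(demo, drug, reac) {
  if (anyDuplicated(demo$primaryid)) {
    abort_field("demo", "primaryid must be unique per report")
  }
  known <- demo$primaryid
  orphans <- c(
    drug = sum(!(drug$primaryid %in% known)),
    reac = sum(!(reac$primaryid %in% known))
  )
  drug <- dplyr::filter(drug, .data$primaryid %in% known)
  reac <- dplyr::filter(reac, .data$primaryid %in% known)

  group_list <- function(tbl, col) {
    # named list of per-report values, empty for absent reports
    sp <- split(tbl[[col]], factor(tbl$primaryid, levels = known))
    lapply(sp, unique)
  }
  out <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    caseversion = demo$caseversion,
    drugs = unname(group_list(drug, "drugname")),
    reactions = unname(group_list(reac, "pt"))
  )
  class(out) <- c("faers_reports", class(out))
  attr(out, "orphans") <- orphans
  out
}

#' Deduplicate versioned case reports
#'
#' Keeps, for every `caseid`, the report with the highest `caseversion` (the
#' most recent report); ties are broken by the highest `primaryid`. Output is
#' ordered by `caseid`.
#'
#' @param reports A `faers_reports` tibble.
#' @return A `faers_reports` tibble with one row per case.
#' @export
deduplicate_cases <- function(reports) {
  ord <- order(reports$caseid, -reports$caseversion, -reports$primaryid)
  out <- reports[ord, ][!duplicated(reports$caseid[ord]), ]
  class(out) <- c("faers_reports", class(tibble::tibble()))
  attr(out, "orphans") <- attr(reports, "orphans")
  out
}

#' Collate verbatim drug strings to ATC level 5
#'
#' Normalizes every verbatim drug string (trim, uppercase, collapse internal
#' whitespace), maps it through the synonym table, and replaces each report's
#' drug list with the deduplicated set of ATC level-5 codes. Unmapped strings
#' are dropped and counted. Reaction terms are normalized the same way.
#'
#' @param reports A `faers_reports` tibble.
#' @param synonym_table Tibble with columns `verbatim`, `atc_code`; codes
#'   must match the ATC level-5 pattern `[A-Z]dd[A-Z][A-Z]dd`.
#' @return The reports with `drugs` as ATC codes; attribute `unmapped` is a
#'   tibble of dropped verbatim strings with occurrence counts.
#' @export
collate_to_atc <- function(reports, synonym_table) {
  stopifnot(all(c("verbatim", "atc_code") %in% names(synonym_table)))
  bad <- !is_atc_level5(synonym_table$atc_code)
  if (any(bad)) {
    rlang::abort(
      paste(
        "synonym_table contains malformed ATC level-5 code(s):",
        paste(unique(synonym_table$atc_code[bad]), collapse = ", ")
      ),
      class = "cindr_validation_error"
    )
  }
  lookup <- synonym_table |>
    dplyr::mutate(key = normalize_drug_string(.data$verbatim)) |>
    dplyr::distinct(.data$key, .data$atc_code)
  if (anyDuplicated(lookup$key)) {
    abort_field("synonym_table", "a verbatim string maps to multiple ATC codes")
  }
  map <- stats::setNames(lookup$atc_code, lookup$key)

  long <- tibble::tibble(
    primaryid = rep(reports$primaryid, lengths(reports$drugs)),
    key = normalize_drug_string(unlist(reports$drugs, use.names = FALSE))
  )
  long$atc <- unname(map[long$key])
  unmapped <- long |>
    dplyr::filter(is.na(.data$atc)) |>
    dplyr::count(.data$key, name = "n") |>
    dplyr::rename(verbatim = "key")
  mapped <- long |>
    dplyr::filter(!is.na(.data$atc)) |>
    dplyr::distinct(.data$primaryid, .data$atc)
  sp <- split(mapped$atc, factor(mapped$primaryid, levels = reports$primaryid))

  reac_long <- tibble::tibble(
    primaryid = rep(reports$primaryid, lengths(reports$reactions)),
    pt = normalize_drug_string(unlist(reports$reactions, use.names = FALSE))
  ) |> dplyr::distinct()

  out <- reports
  out$drugs <- unname(sp)
  out$reactions <- unname(split(
    reac_long$pt, factor(reac_long$primaryid, levels = reports$primaryid)
  ))
  attr(out, "unmapped") <- unmapped
  out
}

#' Restrict reports to the causative-drug cohort
#'
#' @param reports Deduplicated, ATC-collated `faers_reports`.
#' @param drug_a ATC code (or set of codes) of the causative drug.
#' @return The subset of reports whose drug set intersects `drug_a`, with
#'   `drug_a` recorded as an attribute. Errors if the cohort is empty.
#' @export
build_cohort <- function(reports, drug_a) {
  keep <- vapply(reports$drugs, function(d) any(d %in% drug_a), logical(1))
  if (!any(keep)) {
    rlang::abort("no case contains the causative drug; cohort is empty",
      class = "cindr_validation_error"
    )
  }
  out <- reports[keep, ]
  class(out) <- c("faers_reports", class(tibble::tibble()))
  attr(out, "drug_a") <- drug_a
  out
}

#' Construct a 2x2 contingency table
#'
#' @param d1r1,d1r0,d0r1,d0r0 Non-negative counts: cohort cases that received
#'   the co-medication and had the reaction, received it without the
#'   reaction, had the reaction without it, and had neither.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(d1r1, d1r0, d0r1, d0r0) {
  cells <- c(d1r1 = d1r1, d1r0 = d1r0, d0r1 = d0r1, d0r0 = d0r0)
  if (any(cells < 0) || anyNA(cells)) {
    abort_field("cells", "must be non-negative counts")
  }
  structure(as.list(cells), class = "contingency_table")
}

#' Cross-classify the cohort by one co-medication and one reaction
#'
#' @param cohort Output of [build_cohort()].
#' @param co_drug ATC code of the co-medication; must differ from the
#'   causative drug.
#' @param reaction Reaction term (normalized before exact matching).
#' @param drug_a Causative-drug code(s); defaults to the cohort attribute.
#' @return A [contingency_table()].
#' @export
contingency_for <- function(cohort, co_drug, reaction,
                            drug_a = attr(cohort, "drug_a")) {
  if (!is.null(drug_a) && co_drug %in% drug_a) {
    abort_field("co_drug", "must differ from the causative drug")
  }
  reaction <- normalize_drug_string(reaction)
  has_d <- vapply(cohort$drugs, function(d) co_drug %in% d, logical(1))
  has_r <- vapply(cohort$reactions, function(r) reaction %in% r, logical(1))
  contingency_table(
    d1r1 = sum(has_d & has_r), d1r0 = sum(has_d & !has_r),
    d0r1 = sum(!has_d & has_r), d0r0 = sum(!has_d & !has_r)
  )
}

# Vectorized ROR core shared by compute_ror() and screen_comedications().
ror_cells <- function(d1r1, d1r0, d0r1, d0r0, z = 1.959964) {
  corrected <- d1r1 == 0 | d1r0 == 0 | d0r1 == 0 | d0r0 == 0
  undefined <- (d1r1 + d1r0 == 0) | (d0r1 + d0r0 == 0)
  a <- d1r1 + 0.5 * corrected
  b <- d1r0 + 0.5 * corrected
  c_ <- d0r1 + 0.5 * corrected
  d <- d0r0 + 0.5 * corrected
  log_ror <- log(a) - log(b) - log(c_) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble::tibble(
    d1r1 = d1r1, d1r0 = d1r0, d0r1 = d0r1, d0r0 = d0r0,
    ror = exp(log_ror),
    ci_low = exp(log_ror - z * se),
    ci_high = exp(log_ror + z * se),
    corrected = corrected,
    undefined = undefined,
    protective = !undefined & exp(log_ror + z * se) < 1
  )
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (d1r1/d1r0) / (d0r1/d0r0)` with the Woolf log-normal interval
#' `exp(log ROR +/- 1.96 * sqrt(1/d1r1 + 1/d1r0 + 1/d0r1 + 1/d0r0))`. If any
#' cell is zero, 0.5 is added to all four cells first (Haldane-Anscombe) and
#' the result is flagged `corrected`. A table with an empty exposed or
#' unexposed margin is flagged `undefined` and never protective. The
#' co-medication is a protective signal when the interval's upper bound lies
#' below 1.
#'
#' @param table A [contingency_table()] or numeric vector
#'   `c(d1r1, d1r0, d0r1, d0r0)`.
#' @return A one-row tibble of class `ror_result` with the cells, `ror`,
#'   `ci_low`, `ci_high`, `corrected`, `undefined`, `protective`.
#' @export
compute_ror <- function(table) {
  if (inherits(table, "contingency_table")) {
    cells <- unlist(table)
  } else {
    cells <- as.numeric(table)
    if (length(cells) != 4 || any(cells < 0) || anyNA(cells)) {
      abort_field("table", "must supply 4 non-negative counts")
    }
  }
  cells <- unname(cells)
  out <- ror_cells(cells[1], cells[2], cells[3], cells[4])
  class(out) <- c("ror_result", class(out))
  out
}

#' Screen co-medications for protective reporting-odds-ratio signals
#'
#' Every co-medication appearing in at least `min_exposed` cohort cases is
#' cross-classified against the indexed reaction and scored with
#' [compute_ror()]. Results are sorted by the upper confidence bound;
#' protective signals are those with `ci_high < 1`. No multiplicity
#' correction is applied by default, mirroring the interval-only criterion;
#' set `adjust = TRUE` to add a BH-adjusted two-sided q-value column.
#'
#' @param cohort Output of [build_cohort()].
#' @param reaction Indexed reaction term.
#' @param min_exposed Minimum number of exposed cohort cases (default 3).
#' @param drug_a Causative-drug code(s); defaults to the cohort attribute.
#' @param adjust Add BH q-values for the Wald test of log ROR = 0.
#' @return A tibble of class `ror_screen`: one row per co-medication with the
#'   contingency cells and ROR columns, sorted by `ci_high` ascending.
#' @export
screen_comedications <- function(cohort, reaction, min_exposed = 3,
                                 drug_a = attr(cohort, "drug_a"),
                                 adjust = FALSE) {
  if (nrow(cohort) == 0) abort_field("cohort", "must be non-empty")
  min_exposed <- check_count(min_exposed, "min_exposed", min = 1L)
  reaction <- normalize_drug_string(reaction)
  n_total <- nrow(cohort)
  has_r <- vapply(cohort$reactions, function(r) reaction %in% r, logical(1))
  n_event <- sum(has_r)

  long <- tibble::tibble(
    row = rep(seq_len(n_total), lengths(cohort$drugs)),
    drug = unlist(cohort$drugs, use.names = FALSE)
  ) |> dplyr::filter(!(.data$drug %in% drug_a))
  per_drug <- long |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      exposed = dplyr::n(),
      exposed_event = sum(has_r[.data$row]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$exposed >= min_exposed)

  out <- ror_cells(
    d1r1 = per_drug$exposed_event,
    d1r0 = per_drug$exposed - per_drug$exposed_event,
    d0r1 = n_event - per_drug$exposed_event,
    d0r0 = n_total - per_drug$exposed - (n_event - per_drug$exposed_event)
  )
  out <- dplyr::bind_cols(tibble::tibble(drug = per_drug$drug), out) |>
    dplyr::filter(!.data$undefined) |>
    dplyr::arrange(.data$ci_high, .data$drug)
  if (adjust) {
    z <- abs(log(out$ror)) / ((log(out$ci_high) - log(out$ci_low)) / (2 * 1.959964))
    out$q_value <- bh_adjust(2 * stats::pnorm(-z))
  }
  class(out) <- c("ror_screen", class(out))
  attr(out, "reaction") <- reaction
  attr(out, "n_cohort") <- n_total
  attr(out, "min_exposed") <- min_exposed
  out
}
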