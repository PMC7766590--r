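# Versioned adverse-event case simulator with planted protective and risk
# co-medications under an independent multiplicative-odds logistic model.

#' Default co-medication panel for the adverse-event simulator
#'
#' One protective drug (odds multiplier 0.3), one risk drug (3.0) and six null
#' drugs (1.0), each with a realistic prevalence among reports.
#'
#' @return Tibble with columns `name`, `atc_code`, `prevalence`,
#'   `odds_multiplier`.
#' @export
default_co_drugs <- function() {
  tibble::tibble(
    name = c(
      "PALONOSETRON", "VANCOMYCIN", "ONDANSETRON", "METFORMIN",
      "OMEPRAZOLE", "PACLITAXEL", "FUROSEMIDE", "AMLODIPINE"
    ),
    atc_code = c(
      "A04AA05", "J01XA01", "A04AA01", "A10BA02",
      "A02BC01", "L01CD01", "C03CA01", "C08CA01"
    ),
    prevalence = c(0.20, 0.15, 0.15, 0.10, 0.10, 0.10, 0.10, 0.10),
    odds_multiplier = c(0.3, 3.0, 1, 1, 1, 1, 1, 1)
  )
}

#' Default verbatim-string synonym table
#'
#' Maps normalized verbatim drug strings to ATC level-5 codes, with two
#' spelling variants per substance so that collation is exercised.
#'
#' @param co_drugs Co-medication panel (see [default_co_drugs()]).
#' @param drug_a_atc ATC code of the causative drug.
#' @return Tibble with columns `verbatim`, `atc_code`.
#' @export
default_synonym_table <- function(co_drugs = default_co_drugs(),
                                  drug_a_atc = "L01XA01") {
  base <- dplyr::bind_rows(
    tibble::tibble(verbatim = "CISPLATIN", atc_code = drug_a_atc),
    tibble::tibble(verbatim = "CISPLATIN INJECTION", atc_code = drug_a_atc),
    tibble::tibble(verbatim = co_drugs$name, atc_code = co_drugs$atc_code),
    tibble::tibble(
      verbatim = paste(co_drugs$name, "HYDROCHLORIDE"),
      atc_code = co_drugs$atc_code
    )
  )
  dplyr::distinct(base)
}

#' Specify an adverse-event report simulation
#'
#' Cases receive the causative drug (drug A) and each co-medication
#' independently by prevalence. For the indexed reaction, the per-case
#' probability is `plogis(qlogis(p0) + sum(log(odds_multiplier)))` over
#' co-medications present on the case, where `p0` is `baseline_event_prob`
#' for drug-A cases and `background_event_prob` otherwise — so each
#' co-medication acts as an independent multiplicative odds factor
#' (protective below 1, risk above 1). A fraction of cases is emitted twice
#' with incremented versions; only the highest version reflects truth, and
#' earlier versions have their drug list perturbed with probability 0.5 so
#' that deduplication errors are observable.
#'
#' @param n_cases Number of distinct cases.
#' @param p_drug_a Probability a case includes drug A.
#' @param co_drugs Tibble (`name`, `atc_code`, `prevalence`,
#'   `odds_multiplier`); multipliers must be positive.
#' @param baseline_event_prob Indexed-reaction probability for drug-A cases
#'   with no co-medications.
#' @param background_event_prob Same for non-drug-A cases.
#' @param duplicate_frac Fraction of cases emitted with two versions.
#' @param n_distractor_reactions Distractor reactions drawn per case.
#' @param synonym_table Tibble (`verbatim`, `atc_code`) resolving every drug.
#' @param drug_a_name,drug_a_atc Verbatim name and ATC code of drug A.
#' @param indexed_reaction Reaction term whose reporting odds are modelled.
#' @param seed Integer seed.
#' @return An object of class `faers_sim_spec`.
#' @seealso [simulate_faers_tables()]
#' @export
faers_sim_spec <- function(n_cases = 200000,
                           p_drug_a = 0.1,
                           co_drugs = default_co_drugs(),
                           baseline_event_prob = 0.3,
                           background_event_prob = 0.05,
                           duplicate_frac = 0.1,
                           n_distractor_reactions = 3,
                           synonym_table = default_synonym_table(co_drugs),
                           drug_a_name = "CISPLATIN",
                           drug_a_atc = "L01XA01",
                           indexed_reaction = "ACUTE KIDNEY INJURY",
                           seed = 1) {
  spec <- list(
    n_cases = check_count(n_cases, "n_cases", min = 10L),
    p_drug_a = check_prob(p_drug_a, "p_drug_a"),
    co_drugs = co_drugs,
    baseline_event_prob = check_prob(baseline_event_prob, "baseline_event_prob"),
    background_event_prob = check_prob(background_event_prob, "background_event_prob"),
    duplicate_frac = check_fraction(duplicate_frac, "duplicate_frac"),
    n_distractor_reactions = check_count(n_distractor_reactions, "n_distractor_reactions", min = 0L),
    synonym_table = synonym_table,
    drug_a_name = drug_a_name,
    drug_a_atc = drug_a_atc,
    indexed_reaction = normalize_drug_string(indexed_reaction),
    seed = check_seed(seed)
  )
  required <- c("name", "atc_code", "prevalence", "odds_multiplier")
  if (!all(required %in% names(co_drugs))) {
    abort_field("co_drugs", paste("must have columns", paste(required, collapse = ", ")))
  }
  if (any(co_drugs$odds_multiplier <= 0)) {
    abort_field("co_drugs", "odds_multiplier must be > 0")
  }
  if (any(co_drugs$prevalence <= 0 | co_drugs$prevalence >= 1)) {
    abort_field("co_drugs", "prevalence must lie in (0, 1)")
  }
  syn_atc <- synonym_table$atc_code[match(
    normalize_drug_string(co_drugs$name),
    normalize_drug_string(synonym_table$verbatim)
  )]
  if (anyNA(syn_atc)) {
    abort_field(
      "synonym_table",
      paste(
        "cannot resolve co_drug name(s):",
        paste(co_drugs$name[is.na(syn_atc)], collapse = ", ")
      )
    )
  }
  if (!any(normalize_drug_string(synonym_table$verbatim) == normalize_drug_string(drug_a_name))) {
    abort_field("synonym_table", "cannot resolve drug_a_name")
  }
  structure(spec, class = "faers_sim_spec")
}

DISTRACTOR_REACTIONS <- c(
  "NAUSEA", "VOMITING", "HEADACHE", "FATIGUE", "DIARRHOEA", "RASH",
  "PYREXIA", "DIZZINESS", "ANAEMIA", "NEUTROPENIA", "PRURITUS",
  "CONSTIPATION", "INSOMNIA", "COUGH", "DYSPNOEA", "HYPOTENSION",
  "HYPERTENSION", "ALOPECIA", "STOMATITIS", "TINNITUS"
)

# Pick a random verbatim synonym (with random case styling) for each ATC code.
style_verbatim <- function(atc, synonym_table) {
  out <- character(length(atc))
  for (code in unique(atc)) {
    idx <- which(atc == code)
    variants <- synonym_table$verbatim[synonym_table$atc_code == code]
    picked <- variants[sample.int(length(variants), length(idx), replace = TRUE)]
    styled <- sample.int(2L, length(idx), replace = TRUE) == 2L
    picked[styled] <- stringr::str_to_title(picked[styled])
    out[idx] <- picked
  }
  out
}

#' Simulate versioned adverse-event report tables
#'
#' Generates DEMO/DRUG/REAC tables in the simplified `$`-delimited
#' adverse-event report dialect, plus a truth record sufficient to score
#' deduplication, collation and the protective screen without re-deriving
#' parameters.
#'
#' @param spec A [faers_sim_spec()].
#' @return List with `demo`, `drug`, `reac` tibbles (columns as in the file
#'   dialect), and `truth`: a list with `cases` (tibble `caseid`,
#'   `primaryid`, `drug_a`, `event`), `case_drugs` (long tibble `caseid`,
#'   `atc_code` of the true, deduplicated per-case drug sets including drug
#'   A), `co_drugs` (panel with a `role` column), and the drug-A code and
#'   indexed reaction term.
#' @export
simulate_faers_tables <- function(spec) {
  if (!inherits(spec, "faers_sim_spec")) abort_field("spec", "must be a faers_sim_spec")
  withr::with_seed(spec$seed, {
    n <- spec$n_cases
    caseid <- seq_len(n)
    has_a <- stats::runif(n) < spec$p_drug_a

    cd <- spec$co_drugs
    expo <- vapply(
      cd$prevalence,
      function(p) stats::runif(n) < p,
      logical(n)
    ) # n x n_co matrix
    if (is.null(dim(expo))) expo <- matrix(expo, nrow = n)

    shift <- as.vector(expo %*% log(cd$odds_multiplier))
    base_logit <- ifelse(
      has_a, stats::qlogis(spec$baseline_event_prob),
      stats::qlogis(spec$background_event_prob)
    )
    event <- stats::runif(n) < stats::plogis(base_logit + shift)

    # true per-case ATC drug sets, long form
    idx <- which(expo, arr.ind = TRUE)
    case_drugs <- dplyr::bind_rows(
      tibble::tibble(caseid = which(has_a), atc_code = spec$drug_a_atc),
      tibble::tibble(caseid = as.integer(idx[, 1]), atc_code = cd$atc_code[idx[, 2]])
    ) |> dplyr::arrange(.data$caseid, .data$atc_code)

    dup <- logical(n)
    n_dup <- round(spec$duplicate_frac * n)
    if (n_dup > 0) dup[sample.int(n, n_dup)] <- TRUE
    final_version <- ifelse(dup, 2L, 1L)

    demo <- tibble::tibble(
      primaryid = c(caseid * 10L + final_version, caseid[dup] * 10L + 1L),
      caseid = c(caseid, caseid[dup]),
      caseversion = c(final_version, rep(1L, sum(dup)))
    ) |> dplyr::arrange(.data$primaryid)

    # final reports carry the true drug list; earlier versions are perturbed
    # with probability 0.5 (drop one drug or add a spurious one)
    drug_long <- dplyr::left_join(
      demo[c("primaryid", "caseid", "caseversion")], case_drugs,
      by = "caseid", relationship = "many-to-many"
    )
    early_ids <- demo$primaryid[demo$caseversion < final_version[demo$caseid]]
    perturb_ids <- early_ids[stats::runif(length(early_ids)) < 0.5]
    if (length(perturb_ids) > 0) {
      mode_add <- stats::runif(length(perturb_ids)) < 0.5
      add_rows <- tibble::tibble(
        primaryid = perturb_ids[mode_add],
        caseid = perturb_ids[mode_add] %/% 10L,
        caseversion = 1L,
        atc_code = sample(cd$atc_code, sum(mode_add), replace = TRUE)
      )
      drop_ids <- perturb_ids[!mode_add]
      if (length(drop_ids) > 0) {
        in_drop <- drug_long$primaryid %in% drop_ids
        # drop one uniformly chosen drug row per report
        sub <- drug_long[in_drop, ]
        pick <- sub |>
          dplyr::mutate(.row = dplyr::row_number(), u = stats::runif(dplyr::n())) |>
          dplyr::group_by(.data$primaryid) |>
          dplyr::slice_max(.data$u, n = 1, with_ties = FALSE) |>
          dplyr::ungroup()
        drug_long <- drug_long[-which(in_drop)[pick$.row], ]
      }
      drug_long <- dplyr::bind_rows(drug_long, add_rows)
    }
    drug_long <- drug_long |>
      dplyr::filter(!is.na(.data$atc_code)) |>
      dplyr::distinct(.data$primaryid, .data$atc_code) |>
      dplyr::arrange(.data$primaryid, .data$atc_code)
    drug <- tibble::tibble(
      primaryid = drug_long$primaryid,
      drugname = style_verbatim(drug_long$atc_code, spec$synonym_table)
    )

    # reactions: distractors (with replacement, deduplicated per report) plus
    # the indexed reaction when the case's true event fired
    k <- spec$n_distractor_reactions
    reac <- dplyr::bind_rows(
      tibble::tibble(
        primaryid = rep(demo$primaryid, each = k),
        pt = sample(DISTRACTOR_REACTIONS, nrow(demo) * k, replace = TRUE)
      ),
      tibble::tibble(
        primaryid = demo$primaryid[event[demo$caseid]],
        pt = spec$indexed_reaction
      )
    ) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$primaryid, .data$pt)

    role <- dplyr::case_when(
      cd$odds_multiplier < 1 ~ "protective",
      cd$odds_multiplier > 1 ~ "risk",
      TRUE ~ "null"
    )
    truth <- list(
      cases = tibble::tibble(
        caseid = caseid,
        primaryid = caseid * 10L + final_version,
        drug_a = has_a,
        event = event
      ),
      case_drugs = case_drugs,
      co_drugs = dplyr::mutate(cd, role = role),
      drug_a_atc = spec$drug_a_atc,
      indexed_reaction = spec$indexed_reaction
    )
    list(demo = demo, drug = drug, reac = reac, truth = truth)
  })
}
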