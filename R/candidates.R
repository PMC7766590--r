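# Harmonize perturbagen names with ATC-coded pharmacovigilance results and
# intersect the two candidate lists.

DEFAULT_SALT_SUFFIXES <- c(
  "HYDROCHLORIDE", "HCL", "SODIUM", "POTASSIUM", "SULFATE", "SULPHATE",
  "PHOSPHATE", "MESYLATE", "MALEATE", "TARTRATE", "CITRATE", "ACETATE",
  "BESYLATE", "FUMARATE", "SUCCINATE"
)

normalize_candidate_name <- function(x, strip_suffixes = DEFAULT_SALT_SUFFIXES) {
  x <- normalize_drug_string(x)
  pattern <- sprintf("\\s+(%s)$", paste(strip_suffixes, collapse = "|"))
  stringr::str_remove(x, stringr::regex(pattern))
}

#' Align perturbagen names and ATC codes into one identity space
#'
#' Perturbagen names are normalized (uppercase, whitespace collapse, salt
#' suffix stripped) and mapped to ATC codes through the mapping table
#' (many-to-one allowed). Identities carrying an ATC code merge with the
#' pharmacovigilance side; unmappable names remain connectivity-only
#' identities keyed by their normalized name.
#'
#' @param connectivity_names Character vector of perturbagen display names.
#' @param faers_atc_codes Character vector of ATC level-5 codes.
#' @param mapping_table Tibble with columns `name`, `atc_code`.
#' @param strip_suffixes Salt/ester suffixes removed during normalization.
#' @return Tibble with columns `identity`, `canonical_name`, `atc_code`,
#'   `connectivity_name` (NA when the identity only appears on the
#'   pharmacovigilance side).
#' @export
harmonize_names <- function(connectivity_names, faers_atc_codes, mapping_table,
                            strip_suffixes = DEFAULT_SALT_SUFFIXES) {
  stopifnot(all(c("name", "atc_code") %in% names(mapping_table)))
  map <- mapping_table |>
    dplyr::mutate(key = normalize_candidate_name(.data$name, strip_suffixes)) |>
    dplyr::distinct(.data$key, .data$atc_code)

  conn <- tibble::tibble(connectivity_name = unique(connectivity_names)) |>
    dplyr::mutate(key = normalize_candidate_name(.data$connectivity_name, strip_suffixes)) |>
    dplyr::left_join(map, by = "key") |>
    dplyr::mutate(identity = ifelse(is.na(.data$atc_code), .data$key, .data$atc_code))

  faers <- tibble::tibble(atc_code = unique(faers_atc_codes)) |>
    dplyr::mutate(identity = .data$atc_code) |>
    dplyr::left_join(
      dplyr::distinct(conn, .data$identity, .data$key),
      by = "identity"
    )

  dplyr::bind_rows(
    dplyr::transmute(conn, .data$identity,
      canonical_name = .data$key,
      atc_code = .data$atc_code, .data$connectivity_name
    ),
    dplyr::transmute(faers, .data$identity,
      canonical_name = dplyr::coalesce(.data$key, .data$atc_code),
      atc_code = .data$atc_code, connectivity_name = NA_character_
    )
  ) |>
    dplyr::distinct(.data$identity, .data$connectivity_name, .keep_all = TRUE)
}

#' Intersect connectivity and pharmacovigilance candidates
#'
#' Maps both candidate lists into the shared identity space and annotates
#' every identity with its sources; identities present in both lists are
#' sorted first, by tau ascending then upper confidence bound ascending.
#'
#' @param connectivity_selection A `connectivity_result` (rows with
#'   `selected`), or tibble with columns `name` and `tau`.
#' @param faers_protective A `ror_screen` (protective rows are used), or
#'   tibble with columns `drug`, `ror`, `ci_low`, `ci_high`.
#' @param identity_space Output of [harmonize_names()].
#' @return A tibble of class `candidate_set`: `identity`, `canonical_name`,
#'   `atc_code`, `tau`, `ror`, `ci_low`, `ci_high`, `sources` (list-column),
#'   `in_both`.
#' @export
intersect_candidates <- function(connectivity_selection, faers_protective,
                                 identity_space) {
  conn <- connectivity_selection
  if (inherits(conn, "connectivity_result")) {
    conn <- dplyr::filter(conn, .data$selected)
  }
  faers <- faers_protective
  if (inherits(faers, "ror_screen")) {
    faers <- dplyr::filter(faers, .data$protective)
  }

  conn_ids <- identity_space |>
    dplyr::filter(!is.na(.data$connectivity_name)) |>
    dplyr::inner_join(
      dplyr::transmute(conn, connectivity_name = .data$name, tau = .data$tau),
      by = "connectivity_name"
    ) |>
    dplyr::group_by(.data$identity) |>
    dplyr::summarise(
      canonical_name = dplyr::first(.data$canonical_name),
      atc_code = dplyr::first(.data$atc_code),
      tau = min(.data$tau), .groups = "drop"
    )

  faers_ids <- identity_space |>
    dplyr::distinct(.data$identity, .data$canonical_name, .data$atc_code) |>
    dplyr::inner_join(
      dplyr::transmute(faers,
        atc_code = .data$drug, ror = .data$ror,
        ci_low = .data$ci_low, ci_high = .data$ci_high
      ),
      by = "atc_code"
    ) |>
    dplyr::distinct(.data$identity, .keep_all = TRUE)

  out <- dplyr::full_join(
    conn_ids, faers_ids,
    by = "identity", suffix = c("", ".f")
  ) |>
    dplyr::mutate(
      canonical_name = dplyr::coalesce(.data$canonical_name, .data$canonical_name.f),
      atc_code = dplyr::coalesce(.data$atc_code, .data$atc_code.f)
    ) |>
    dplyr::select(-dplyr::ends_with(".f")) |>
    dplyr::mutate(
      in_both = !is.na(.data$tau) & !is.na(.data$ror),
      sources = purrr::map2(
        !is.na(.data$tau), !is.na(.data$ror),
        function(c_, f_) c("connectivity", "faers")[c(c_, f_)]
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$in_both), .data$tau, .data$ci_high, .data$identity)
  class(out) <- c("candidate_set", class(out))
  out
}
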