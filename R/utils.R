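# Shared validation and string helpers.

ATC_LEVEL5_REGEX <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

abort_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "cindr_validation_error")
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_prob <- function(x, field, open = TRUE) {
  lo_ok <- if (open) x > 0 else x >= 0
  hi_ok <- if (open) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort_field(field, if (open) "must lie in (0, 1)" else "must lie in [0, 1]")
  }
  as.numeric(x)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_field(field, "must lie in [0, 1]")
  }
  as.numeric(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_field(field, "must be a single positive number")
  }
  as.numeric(x)
}

check_seed <- function(x, field = "seed") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x)) {
    abort_field(field, "must be a single integer")
  }
  as.integer(x)
}

#' Normalize a verbatim drug string
#'
#' Trims leading/trailing whitespace, uppercases, and collapses internal
#' whitespace runs to a single space. This is the normalization applied to
#' every verbatim drug name before synonym-table lookup.
#'
#' @param x Character vector of verbatim drug strings.
#' @return Character vector of normalized strings.
#' @export
#' @examples
#' normalize_drug_string("  Palonosetron   HCl ")
normalize_drug_string <- function(x) {
  stringr::str_squish(stringr::str_to_upper(x))
}

is_atc_level5 <- function(x) {
  grepl(ATC_LEVEL5_REGEX, x)
}

# Deterministic sub-stream seeds, kept within the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% .Machine$integer.max)
}

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "cindr_parse_error")
  }
  invisible(path)
}
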