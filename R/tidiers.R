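# broom-style tidy()/glance() methods for the result objects.

strip_result_class <- function(x) {
  out <- x
  class(out) <- class(tibble::tibble())
  attributes(out)[setdiff(names(attributes(out)), c("names", "row.names", "class"))] <- NULL
  out
}

#' Tidy a differential expression result
#'
#' @param x A `cindr_de` tibble.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @method tidy cindr_de
#' @export
tidy.cindr_de <- function(x, ...) {
  strip_result_class(x)
}

#' @rdname tidy.cindr_de
#' @method glance cindr_de
#' @export
glance.cindr_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant_01 = sum(x$q_value < 0.01),
    n_up_01 = sum(x$q_value < 0.01 & x$log2_fold_change > 0),
    n_down_01 = sum(x$q_value < 0.01 & x$log2_fold_change < 0),
    median_dispersion = stats::median(x$dispersion)
  )
}

#' Tidy a gene signature
#'
#' @param x A [gene_signature()].
#' @param ... Unused.
#' @return Tibble with columns `symbol`, `direction`.
#' @method tidy gene_signature
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble::tibble(
    symbol = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' @rdname tidy.gene_signature
#' @method glance gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  tibble::tibble(
    n_up = length(x$up), n_down = length(x$down),
    n_total = length(x$up) + length(x$down),
    n_datasets = length(x$provenance)
  )
}

#' Tidy a connectivity result
#'
#' @param x A `connectivity_result` tibble.
#' @param ... Unused.
#' @return Plain tibble of per-perturbagen scores.
#' @method tidy connectivity_result
#' @export
tidy.connectivity_result <- function(x, ...) {
  strip_result_class(x)
}

#' @rdname tidy.connectivity_result
#' @method glance connectivity_result
#' @export
glance.connectivity_result <- function(x, ...) {
  tibble::tibble(
    n_perturbagens = nrow(x),
    n_selected = sum(x$selected),
    n_negative_tau = sum(x$tau < 0),
    min_tau = min(x$tau),
    max_tau = max(x$tau)
  )
}

#' Tidy a pharmacovigilance screen
#'
#' @param x A `ror_screen` tibble.
#' @param ... Unused.
#' @return Plain tibble of per-drug reporting odds ratios.
#' @method tidy ror_screen
#' @export
tidy.ror_screen <- function(x, ...) {
  strip_result_class(x)
}

#' @rdname tidy.ror_screen
#' @method glance ror_screen
#' @export
glance.ror_screen <- function(x, ...) {
  tibble::tibble(
    n_cohort = attr(x, "n_cohort"),
    n_drugs = nrow(x),
    n_protective = sum(x$protective),
    n_corrected = sum(x$corrected),
    reaction = attr(x, "reaction")
  )
}
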