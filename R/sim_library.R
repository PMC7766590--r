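# Reference perturbagen signature-library simulator with planted reversers
# and mimickers relative to a query signature.

#' Specify a reference signature-library simulation
#'
#' Background perturbagens receive i.i.d. Gaussian differential-expression
#' scores. Planted reversers additionally depress the query's up genes and
#' elevate its down genes by `5 * reversal_strength` score units; mimickers do
#' the opposite. The amplitude of 5 is fixed so that `reversal_strength` in
#' (0, 1] spans weak-to-strong signals on a z-score-like scale.
#'
#' @param n_perturbagens Number of perturbagens in the library.
#' @param n_genes Size of the library gene universe.
#' @param n_reversers,n_mimickers Planted counts; their sum must not exceed
#'   `n_perturbagens`.
#' @param reversal_strength Signal scale in (0, 1].
#' @param noise_sd Standard deviation of the background scores.
#' @param seed Integer seed.
#' @return An object of class `library_sim_spec`.
#' @seealso [simulate_signature_library()]
#' @export
library_sim_spec <- function(n_perturbagens = 200,
                             n_genes = 1000,
                             n_reversers = 5,
                             n_mimickers = 5,
                             reversal_strength = 0.8,
                             noise_sd = 1,
                             seed = 1) {
  spec <- list(
    n_perturbagens = check_count(n_perturbagens, "n_perturbagens", min = 2L),
    n_genes = check_count(n_genes, "n_genes", min = 10L),
    n_reversers = check_count(n_reversers, "n_reversers", min = 0L),
    n_mimickers = check_count(n_mimickers, "n_mimickers", min = 0L),
    reversal_strength = {
      x <- check_positive(reversal_strength, "reversal_strength")
      if (x > 1) abort_field("reversal_strength", "must lie in (0, 1]")
      x
    },
    noise_sd = {
      if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0) {
        abort_field("noise_sd", "must be a single number >= 0")
      }
      as.numeric(noise_sd)
    },
    seed = check_seed(seed)
  )
  if (spec$n_reversers + spec$n_mimickers > spec$n_perturbagens) {
    abort_field("n_reversers", "n_reversers + n_mimickers must not exceed n_perturbagens")
  }
  structure(spec, class = "library_sim_spec")
}

SIGNAL_AMPLITUDE <- 5

#' Simulate a reference signature library with planted reversers
#'
#' @param spec A [library_sim_spec()].
#' @param query A [gene_signature()] whose genes must all belong to the
#'   simulated gene universe (`GENE00001 ...`).
#' @return List with `library` (a [signature_library()]) and `truth` (tibble
#'   `perturbagen`, `role` in reverser/mimicker/background).
#' @export
simulate_signature_library <- function(spec, query) {
  if (!inherits(spec, "library_sim_spec")) abort_field("spec", "must be a library_sim_spec")
  stopifnot(inherits(query, "gene_signature"))
  genes <- sim_gene_universe(spec$n_genes)
  missing <- setdiff(c(query$up, query$down), genes)
  if (length(missing) > 0) {
    rlang::abort(
      paste0(
        "query genes outside the library universe: ",
        paste(utils::head(missing, 10), collapse = ", "),
        if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10) else ""
      ),
      class = "cindr_validation_error"
    )
  }
  withr::with_seed(spec$seed, {
    perts <- sprintf("PERT_%03d", seq_len(spec$n_perturbagens))
    role <- rep("background", spec$n_perturbagens)
    planted <- sample.int(spec$n_perturbagens, spec$n_reversers + spec$n_mimickers)
    role[planted[seq_len(spec$n_reversers)]] <- "reverser"
    if (spec$n_mimickers > 0) {
      role[planted[spec$n_reversers + seq_len(spec$n_mimickers)]] <- "mimicker"
    }

    scores <- matrix(
      stats::rnorm(spec$n_perturbagens * spec$n_genes, sd = spec$noise_sd),
      nrow = spec$n_perturbagens, dimnames = list(perts, genes)
    )
    amp <- SIGNAL_AMPLITUDE * spec$reversal_strength
    up_idx <- match(query$up, genes)
    dn_idx <- match(query$down, genes)
    for (i in which(role == "reverser")) {
      scores[i, up_idx] <- scores[i, up_idx] - amp
      scores[i, dn_idx] <- scores[i, dn_idx] + amp
    }
    for (i in which(role == "mimicker")) {
      scores[i, up_idx] <- scores[i, up_idx] + amp
      scores[i, dn_idx] <- scores[i, dn_idx] - amp
    }
    list(
      library = signature_library(scores),
      truth = tibble::tibble(perturbagen = perts, role = role)
    )
  })
}
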