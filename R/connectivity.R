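# Connectivity-map-style reversal scoring: weighted Kolmogorov-Smirnov
# enrichment of the query's up/down sets in each perturbagen's ranked
# differential-expression profile, combined, group-normalized, and expressed
# as a signed tau percentile against a touchstone distribution.

#' Construct a reference signature library
#'
#' @param scores Numeric matrix, perturbagens in rows (unique rownames),
#'   genes in columns (unique colnames); entries are differential-expression
#'   z-like scores.
#' @param names Display names, defaults to rownames.
#' @param group Optional grouping label per perturbagen (e.g. cell context)
#'   used by score normalization; default puts everything in one group.
#' @return An object of class `signature_library`.
#' @export
signature_library <- function(scores, names = rownames(scores), group = NULL) {
  if (is.null(rownames(scores)) || anyDuplicated(rownames(scores))) {
    abort_field("scores", "rownames must be unique perturbagen ids")
  }
  if (is.null(colnames(scores)) || anyDuplicated(colnames(scores))) {
    abort_field("scores", "colnames must be unique gene ids")
  }
  if (any(rowSums(is.finite(scores)) == 0)) {
    abort_field("scores", "every perturbagen needs at least one finite score")
  }
  group <- group %||% rep("all", nrow(scores))
  structure(
    list(
      perturbagens = rownames(scores), names = names,
      genes = colnames(scores), scores = scores, group = group
    ),
    class = "signature_library"
  )
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf(
    "<signature_library: %d perturbagens x %d genes, %d group(s)>\n",
    length(x$perturbagens), length(x$genes), length(unique(x$group))
  ))
  invisible(x)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ranked by score in descending order (ties broken by gene id);
#' a running sum gains `|score| / sum(|score| over the query set)` at each
#' query gene and loses `1 / (N - n_query)` at each non-query gene. The
#' enrichment score is the running-sum extremum of largest magnitude
#' (positive extremum on a tie), so it lies in \[-1, 1\]: positive when the
#' set concentrates at the top of the ranking, negative at the bottom.
#'
#' @param ranked_scores Named numeric vector: per-gene scores.
#' @param query_set Character vector; non-empty proper subset of the genes.
#' @return A single number in \[-1, 1\].
#' @export
weighted_enrichment_score <- function(ranked_scores, query_set) {
  genes <- names(ranked_scores)
  if (is.null(genes)) abort_field("ranked_scores", "must be a named vector")
  query_set <- unique(query_set)
  if (length(query_set) == 0 || length(query_set) >= length(genes)) {
    abort_field("query_set", "must be a non-empty proper subset of the gene universe")
  }
  if (!all(query_set %in% genes)) {
    abort_field("query_set", "contains genes outside the universe")
  }
  ord <- order(-ranked_scores, genes)
  hit <- genes[ord] %in% query_set
  s <- abs(ranked_scores[ord])
  n_miss <- length(genes) - length(query_set)
  denom <- sum(s[hit])
  inc <- numeric(length(genes))
  if (denom > 0) {
    inc[hit] <- s[hit] / denom
  } else {
    inc[hit] <- 1 / sum(hit) # all-zero set scores: fall back to equal weights
  }
  inc[!hit] <- -1 / n_miss
  cs <- cumsum(inc)
  hi <- max(cs)
  lo <- min(cs)
  # positive extremum wins ties (up to running-sum rounding)
  if (hi >= -lo - 1e-12) hi else lo
}

#' Combine up- and down-set enrichment into a connectivity score
#'
#' `(es_up - es_down) / 2` when the two scores disagree in sign or either is
#' zero; 0 when they agree (the query's halves move the same way, so no
#' coherent connection is claimed). Vectorized.
#'
#' @param es_up,es_down Enrichment scores in \[-1, 1\].
#' @return WTCS values in \[-1, 1\].
#' @export
combined_score <- function(es_up, es_down) {
  stopifnot(length(es_up) == length(es_down))
  out <- (es_up - es_down) / 2
  out[sign(es_up) == sign(es_down) & es_up != 0 & es_down != 0] <- 0
  out
}

#' Group- and sign-wise score normalization
#'
#' Within each group, positive scores are divided by the mean absolute value
#' of the positive members and negative scores by the mean absolute value of
#' the negative members; zeros stay zero.
#'
#' @param wtcs Numeric vector of combined connectivity scores.
#' @param grouping Grouping labels (default: one group).
#' @return Normalized connectivity scores (NCS), same length and order.
#' @export
normalize_scores <- function(wtcs, grouping = NULL) {
  grouping <- grouping %||% rep("all", length(wtcs))
  stopifnot(length(grouping) == length(wtcs))
  out <- numeric(length(wtcs))
  for (g in unique(grouping)) {
    i <- which(grouping == g)
    x <- wtcs[i]
    pos <- x > 0
    neg <- x < 0
    y <- numeric(length(x))
    if (any(pos)) y[pos] <- x[pos] / mean(abs(x[pos]))
    if (any(neg)) y[neg] <- x[neg] / mean(abs(x[neg]))
    out[i] <- y
  }
  out
}

#' Signed tau percentile against a touchstone distribution
#'
#' `tau = sign(ncs) * 100 * fraction of touchstone values strictly below
#' |ncs|`, in \[-100, 100\]. Vectorized over `ncs`.
#'
#' @param ncs Normalized connectivity score(s).
#' @param touchstone_abs_ncs Non-empty numeric vector of reference |NCS|
#'   values.
#' @return tau value(s).
#' @export
tau_percentile <- function(ncs, touchstone_abs_ncs) {
  if (length(touchstone_abs_ncs) == 0) {
    abort_field("touchstone_abs_ncs", "must be non-empty")
  }
  vapply(ncs, function(x) {
    sign(x) * 100 * mean(touchstone_abs_ncs < abs(x))
  }, numeric(1))
}

#' Query a signature against a reference library
#'
#' Computes, for every perturbagen, the up- and down-set enrichment scores,
#' the combined connectivity score (WTCS), the group-normalized score (NCS)
#' and the tau percentile against the touchstone (by default all perturbagens
#' in the library). Perturbagens with `tau` below the threshold form the
#' reversal selection.
#'
#' @param sig A [gene_signature()]; genes outside the library universe are
#'   dropped first (both halves must stay non-empty).
#' @param lib A [signature_library()].
#' @param tau_threshold Selection threshold (default 0: negative tau).
#' @param touchstone Optional character vector of perturbagen ids defining
#'   the tau reference distribution.
#' @return A tibble of class `connectivity_result`, sorted by tau ascending,
#'   with columns `perturbagen`, `name`, `es_up`, `es_down`, `wtcs`, `ncs`,
#'   `tau`, `selected`. The filtered signature is attached as attribute
#'   `query`.
#' @export
query_library <- function(sig, lib, tau_threshold = 0, touchstone = NULL) {
  stopifnot(inherits(sig, "gene_signature"), inherits(lib, "signature_library"))
  dropped <- setdiff(c(sig$up, sig$down), lib$genes)
  up <- intersect(sig$up, lib$genes)
  down <- intersect(sig$down, lib$genes)
  if (length(up) == 0 || length(down) == 0) {
    rlang::abort(
      paste0(
        "signature empty after filtering to the library universe; dropped: ",
        paste(utils::head(dropped, 20), collapse = ", ")
      ),
      class = "cindr_validation_error"
    )
  }
  es <- t(vapply(seq_along(lib$perturbagens), function(i) {
    row <- lib$scores[i, ]
    c(
      weighted_enrichment_score(row, up),
      weighted_enrichment_score(row, down)
    )
  }, numeric(2)))
  wtcs <- combined_score(es[, 1], es[, 2])
  ncs <- normalize_scores(wtcs, lib$group)
  ts_ids <- touchstone %||% lib$perturbagens
  ts <- abs(ncs[match(ts_ids, lib$perturbagens)])
  if (anyNA(ts)) abort_field("touchstone", "contains unknown perturbagen ids")
  tau <- tau_percentile(ncs, ts)
  out <- tibble::tibble(
    perturbagen = lib$perturbagens,
    name = lib$names,
    es_up = es[, 1], es_down = es[, 2],
    wtcs = wtcs, ncs = ncs, tau = tau,
    selected = tau < tau_threshold
  ) |>
    dplyr::arrange(.data$tau, .data$perturbagen)
  class(out) <- c("connectivity_result", class(out))
  attr(out, "query") <- gene_signature(up, down, provenance = sig$provenance)
  attr(out, "tau_threshold") <- tau_threshold
  out
}
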