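# Cross-dataset gene expression signature construction: count normalization,
# per-gene negative-binomial testing, ortholog mapping, and the
# direction-consistent multi-study intersection.

#' Trimmed-ratio count normalization factors
#'
#' Computes per-sample scale factors by comparing each sample to a reference
#' pseudo-sample (the per-gene geometric mean over samples, taken on genes
#' expressed in every sample) and averaging the log ratios with a 30% trim
#' from each tail. Factors are rescaled so their geometric mean is exactly 1;
#' normalized counts are `counts[, j] / factors[j]`.
#'
#' @param ds A [count_dataset()].
#' @param trim Trim fraction passed to `mean(trim = )` on the log-ratios.
#' @return Named numeric vector of scale factors (one per sample).
#' @export
normalize_counts <- function(ds, trim = 0.3) {
  stopifnot(inherits(ds, "count_dataset"))
  totals <- colSums(ds$counts)
  if (any(totals == 0)) {
    rlang::abort(
      paste("sample(s) with all-zero counts:", paste(ds$samples[totals == 0], collapse = ", ")),
      class = "cindr_validation_error"
    )
  }
  expressed <- rowSums(ds$counts == 0) == 0
  if (!any(expressed)) {
    # degenerate: fall back to library-size factors
    f <- totals / exp(mean(log(totals)))
    return(stats::setNames(f, ds$samples))
  }
  logref <- rowMeans(log(ds$counts[expressed, , drop = FALSE]))
  logratio <- log(ds$counts[expressed, , drop = FALSE]) - logref
  f <- exp(apply(logratio, 2, mean, trim = trim))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, ds$samples)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort_field("p_values", "must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Method-of-moments NB dispersion per gene from normalized counts, with
# common-then-tagwise shrinkage.
estimate_dispersions <- function(norm, g1, g2, shrink_weight = 0.7) {
  n1 <- sum(g1)
  n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  ss1 <- rowSums((norm[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((norm[, g2, drop = FALSE] - m2)^2)
  var_pool <- (ss1 + ss2) / (n1 + n2 - 2)
  mean_pool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  phi <- (var_pool - mean_pool) / mean_pool^2
  phi[!is.finite(phi) | phi < 0] <- 0
  informative <- mean_pool >= 1
  common <- if (any(informative)) stats::median(phi[informative]) else 0
  pmax(shrink_weight * common + (1 - shrink_weight) * phi, 1e-8)
}

#' Per-gene two-group negative-binomial differential expression test
#'
#' Normalizes counts with the supplied scale factors, estimates a per-gene NB
#' dispersion by method of moments shrunk toward the across-gene common value
#' (weight `shrink_weight` on the common value), and performs a Wald test of
#' equal group means on the log scale: the statistic is the log mean ratio
#' over its delta-method standard error
#' `sqrt((1/mu1 + phi')/n1 + (1/mu2 + phi')/n2)`, referred to the standard
#' normal. Log2 fold changes use a pseudo-count of
#' 0.5 on the normalized group means. Genes with zero counts in every sample
#' get `p = 1`, `log2_fold_change = 0`.
#'
#' @param ds A [count_dataset()].
#' @param factors Per-sample scale factors, by default [normalize_counts()].
#' @param shrink_weight Weight on the common dispersion in \[0, 1\].
#' @return A tibble of class `cindr_de` with columns `gene`, `mean_control`,
#'   `mean_treated` (normalized means), `log2_fold_change`, `dispersion`,
#'   `p_value`, `q_value`.
#' @export
test_differential_expression <- function(ds, factors = normalize_counts(ds),
                                         shrink_weight = 0.7) {
  stopifnot(inherits(ds, "count_dataset"))
  g1 <- ds$group == "control"
  g2 <- ds$group == "treated"
  if (sum(g1) < 2 || sum(g2) < 2) {
    abort_field("ds", "each group needs at least 2 samples")
  }
  norm <- sweep(ds$counts, 2, factors, "/")
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  phi <- estimate_dispersions(norm, g1, g2, shrink_weight)

  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  beta <- log(m2 + 0.5) - log(m1 + 0.5)
  se <- sqrt(
    (1 / (m1 + 0.5) + phi) / sum(g1) +
      (1 / (m2 + 0.5) + phi) / sum(g2)
  )
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  all_zero <- m1 + m2 == 0
  p[all_zero] <- 1
  lfc[all_zero] <- 0

  res <- tibble::tibble(
    gene = ds$genes,
    mean_control = unname(m1),
    mean_treated = unname(m2),
    log2_fold_change = unname(lfc),
    dispersion = unname(phi),
    p_value = unname(p),
    q_value = bh_adjust(unname(p))
  )
  class(res) <- c("cindr_de", class(res))
  attr(res, "dataset_id") <- ds$id
  attr(res, "species") <- ds$species
  res
}

#' Threshold a differential result into directional calls
#'
#' @param de A `cindr_de` tibble from [test_differential_expression()].
#' @param fdr q-value threshold (default 0.01).
#' @return Tibble with columns `symbol`, `direction` (`up`/`down`).
#' @export
de_calls <- function(de, fdr = 0.01) {
  de |>
    dplyr::filter(.data$q_value < fdr, .data$log2_fold_change != 0) |>
    dplyr::transmute(
      symbol = .data$gene,
      direction = ifelse(.data$log2_fold_change > 0, "up", "down")
    )
}

#' Map directional gene calls to human orthologs
#'
#' Unmapped source symbols are dropped and reported; one-to-many sources
#' expand to all their human targets; a human symbol receiving conflicting
#' directions from different sources is dropped and reported as conflicting.
#' Human symbols are uppercased.
#'
#' @param calls Tibble with columns `symbol`, `direction`.
#' @param ortholog_table Tibble with columns `source_symbol`, `human_symbol`
#'   (repeated rows encode one-to-many mappings).
#' @return List with `calls` (tibble `symbol`, `direction` in human symbols),
#'   `unmapped` (character) and `conflicting` (character).
#' @export
map_orthologs <- function(calls, ortholog_table) {
  stopifnot(all(c("symbol", "direction") %in% names(calls)))
  stopifnot(all(c("source_symbol", "human_symbol") %in% names(ortholog_table)))
  joined <- dplyr::left_join(
    calls, ortholog_table,
    by = c(symbol = "source_symbol"), relationship = "many-to-many"
  )
  unmapped <- sort(unique(joined$symbol[is.na(joined$human_symbol)]))
  mapped <- joined |>
    dplyr::filter(!is.na(.data$human_symbol)) |>
    dplyr::transmute(
      symbol = stringr::str_to_upper(.data$human_symbol),
      direction = .data$direction
    ) |>
    dplyr::distinct()
  conflicting <- mapped |>
    dplyr::count(.data$symbol) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$symbol) |>
    sort()
  list(
    calls = dplyr::filter(mapped, !(.data$symbol %in% conflicting)),
    unmapped = unmapped,
    conflicting = conflicting
  )
}

#' Construct a gene expression signature
#'
#' Disjoint sets of up- and down-regulated human gene symbols, with the ids of
#' the datasets that contributed to it.
#'
#' @param up,down Character vectors of human symbols (uppercased, deduplicated).
#' @param provenance Character vector of contributing dataset ids.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up, down, provenance = character()) {
  up <- sort(unique(stringr::str_to_upper(as.character(up))))
  down <- sort(unique(stringr::str_to_upper(as.character(down))))
  if (any(!nzchar(up)) || any(!nzchar(down))) {
    abort_field("up", "symbols must be non-empty strings")
  }
  if (length(intersect(up, down)) > 0) {
    abort_field("up", "up and down sets must be disjoint")
  }
  structure(list(up = up, down = down, provenance = provenance),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf(
    "<gene_signature: %d up / %d down genes; provenance: %s>\n",
    length(x$up), length(x$down),
    if (length(x$provenance)) paste(x$provenance, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Direction-consistent intersection of per-dataset calls
#'
#' The signature keeps a gene as up (down) only if it is up (down) in every
#' dataset; a gene called up in some datasets and down in another is thereby
#' excluded from both sets.
#'
#' @param per_dataset_calls List (length >= 2) of lists with elements `up`
#'   and `down` (character vectors); each pair must be internally disjoint.
#' @param provenance Optional dataset ids.
#' @return A [gene_signature()].
#' @export
intersect_signatures <- function(per_dataset_calls, provenance = NULL) {
  if (length(per_dataset_calls) < 2) {
    abort_field("per_dataset_calls", "need at least 2 datasets")
  }
  for (i in seq_along(per_dataset_calls)) {
    x <- per_dataset_calls[[i]]
    if (length(intersect(x$up, x$down)) > 0) {
      abort_field(
        "per_dataset_calls",
        sprintf("dataset %d has genes in both its up and down sets", i)
      )
    }
  }
  up <- Reduce(intersect, lapply(per_dataset_calls, function(x) x$up))
  down <- Reduce(intersect, lapply(per_dataset_calls, function(x) x$down))
  gene_signature(
    up, down,
    provenance = provenance %||% paste0("dataset", seq_along(per_dataset_calls))
  )
}

#' Build a cross-dataset signature from count datasets
#'
#' Runs normalization and differential expression per dataset, thresholds at
#' the given FDR, maps non-human datasets to human symbols through the
#' ortholog table, and intersects the calls direction-consistently.
#'
#' @param datasets List of [count_dataset()] objects (>= 2).
#' @param ortholog_table Tibble (`source_symbol`, `human_symbol`); required
#'   when any dataset is non-human.
#' @param fdr Per-dataset q-value threshold (default 0.01).
#' @return A [gene_signature()] with attributes `per_dataset` (list of call
#'   tibbles) and `mapping_reports`.
#' @export
build_signature <- function(datasets, ortholog_table = NULL, fdr = 0.01) {
  stopifnot(length(datasets) >= 2)
  reports <- list()
  calls <- lapply(datasets, function(ds) {
    de <- test_differential_expression(ds)
    cl <- de_calls(de, fdr = fdr)
    if (!identical(ds$species, "human")) {
      if (is.null(ortholog_table)) {
        abort_field("ortholog_table", sprintf("required for non-human dataset %s", ds$id))
      }
      m <- map_orthologs(cl, ortholog_table)
      reports[[ds$id]] <<- m[c("unmapped", "conflicting")]
      cl <- m$calls
    } else {
      cl$symbol <- stringr::str_to_upper(cl$symbol)
    }
    list(
      up = cl$symbol[cl$direction == "up"],
      down = cl$symbol[cl$direction == "down"],
      calls = cl
    )
  })
  sig <- intersect_signatures(
    lapply(calls, function(x) x[c("up", "down")]),
    provenance = vapply(datasets, function(d) d$id, character(1))
  )
  attr(sig, "per_dataset") <- lapply(calls, function(x) x$calls)
  attr(sig, "mapping_reports") <- reports
  sig
}

#' Hypergeometric over-representation test of a signature
#'
#' One-sided upper-tail hypergeometric p-value per gene set (probability of
#' at least the observed overlap), BH-adjusted across sets, sorted by
#' p-value. Sets are intersected with the universe first; the query must be a
#' subset of the universe.
#'
#' @param sig A [gene_signature()] or character vector of query genes.
#' @param collection Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the testable gene universe.
#' @return Tibble with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `q_value`.
#' @export
enrich_gene_sets <- function(sig, collection, universe) {
  query <- if (inherits(sig, "gene_signature")) c(sig$up, sig$down) else as.character(sig)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort_field("universe", "must be non-empty")
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort_field("sig", "query genes must all belong to the universe")
  }
  n_u <- length(universe)
  n_q <- length(query)
  sets <- lapply(collection, function(genes) intersect(unique(genes), universe))
  set_size <- lengths(sets)
  overlap <- vapply(sets, function(s) sum(s %in% query), integer(1))
  p <- ifelse(
    n_q == 0 | set_size == 0,
    1,
    stats::phyper(overlap - 1, set_size, n_u - set_size, n_q, lower.tail = FALSE)
  )
  out <- tibble::tibble(
    set_name = names(collection), overlap = unname(overlap),
    set_size = unname(set_size), query_size = n_q, universe_size = n_u,
    p_value = pmin(unname(p), 1)
  )
  out$q_value <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$set_name)
}
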