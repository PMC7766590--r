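# Multi-study negative-binomial count simulator with a planted, shared,
# direction-consistent treatment signature plus study-private DE genes.

#' Specify a multi-study count simulation
#'
#' Describes a set of two-group RNA-seq-like count datasets sharing a planted
#' treatment signature, emulating several independent studies of the same
#' exposure (e.g. cisplatin vs control kidney transcriptomes). Counts are
#' negative binomial with variance \eqn{\mu + \phi \mu^2}; planted genes
#' differ between groups by exactly \eqn{2^{log2\_effect}} in expected value,
#' with the same direction in every study. Each study additionally receives
#' its own private differentially expressed genes, so that only the shared
#' signature survives a cross-study intersection.
#'
#' The last study is labelled `human`; all preceding studies are labelled
#' `mouse` and use a separate source-symbol space that must be mapped back to
#' human symbols through the ortholog table emitted alongside the counts.
#'
#' @param n_genes Number of genes per study.
#' @param n_studies Number of studies (>= 2).
#' @param samples_per_group Samples in each of the two groups (>= 2).
#' @param planted_up,planted_down Optional explicit human-symbol sets for the
#'   shared signature; by default `n_planted_up` / `n_planted_down` genes are
#'   sampled from the universe at simulation time.
#' @param n_planted_up,n_planted_down Sizes of the sampled planted sets when
#'   the explicit sets are not given.
#' @param log2_effect Absolute log2 fold change of every planted and
#'   study-private gene (>= 0).
#' @param study_specific_frac Fraction of the gene universe planted as private
#'   DE genes in each study, drawn independently per study with random sign.
#' @param dispersion Negative-binomial dispersion \eqn{\phi}.
#' @param baseline_mean_log_range Length-2 numeric; per-gene baseline means are
#'   `2^runif(range)` (log2 scale), drawn independently per study.
#' @param frac_unmapped Fraction of genes with no row in the ortholog table.
#' @param frac_one_to_many Fraction of genes whose mouse symbol maps to the
#'   true human symbol plus a spurious paralog.
#' @param seed Integer seed; simulation is a pure function of the spec.
#' @return An object of class `transcriptome_sim_spec`.
#' @seealso [simulate_count_datasets()]
#' @export
transcriptome_sim_spec <- function(n_genes = 2000,
                                   n_studies = 3,
                                   samples_per_group = 4,
                                   planted_up = NULL,
                                   planted_down = NULL,
                                   n_planted_up = 100,
                                   n_planted_down = 50,
                                   log2_effect = 2,
                                   study_specific_frac = 0.05,
                                   dispersion = 0.1,
                                   baseline_mean_log_range = c(3, 10),
                                   frac_unmapped = 0.05,
                                   frac_one_to_many = 0.05,
                                   seed = 1) {
  spec <- list(
    n_genes = check_count(n_genes, "n_genes", min = 10L),
    n_studies = check_count(n_studies, "n_studies", min = 2L),
    samples_per_group = check_count(samples_per_group, "samples_per_group", min = 2L),
    planted_up = planted_up,
    planted_down = planted_down,
    n_planted_up = check_count(n_planted_up, "n_planted_up", min = 0L),
    n_planted_down = check_count(n_planted_down, "n_planted_down", min = 0L),
    log2_effect = {
      if (!is.numeric(log2_effect) || length(log2_effect) != 1L || is.na(log2_effect) || log2_effect < 0) {
        abort_field("log2_effect", "must be a single number >= 0")
      }
      as.numeric(log2_effect)
    },
    study_specific_frac = check_fraction(study_specific_frac, "study_specific_frac"),
    dispersion = check_positive(dispersion, "dispersion"),
    baseline_mean_log_range = baseline_mean_log_range,
    frac_unmapped = check_fraction(frac_unmapped, "frac_unmapped"),
    frac_one_to_many = check_fraction(frac_one_to_many, "frac_one_to_many"),
    seed = check_seed(seed)
  )
  if (!is.numeric(baseline_mean_log_range) || length(baseline_mean_log_range) != 2L ||
      baseline_mean_log_range[1] > baseline_mean_log_range[2]) {
    abort_field("baseline_mean_log_range", "must be an increasing pair of reals")
  }
  if (!is.null(planted_up) && !is.null(planted_down) &&
      length(intersect(planted_up, planted_down)) > 0) {
    abort_field("planted_up", "planted_up and planted_down must be disjoint")
  }
  structure(spec, class = "transcriptome_sim_spec")
}

sim_gene_universe <- function(n_genes) sprintf("GENE%05d", seq_len(n_genes))

mouse_symbol_of <- function(human) {
  paste0(stringr::str_to_title(stringr::str_to_lower(human)), "m")
}

#' Construct a two-group count dataset
#'
#' Container for one study's gene-by-sample integer counts with group labels.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param group Factor or character vector over samples with levels
#'   `control` and `treated`.
#' @param species `"human"` or `"mouse"`; mouse symbols need ortholog mapping.
#' @param id Dataset identifier used in signature provenance.
#' @return An object of class `count_dataset`.
#' @export
count_dataset <- function(counts, group, species = "human", id = "dataset") {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    abort_field("counts", "rownames must be unique gene ids")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_field("counts", "must contain non-negative integers")
  }
  group <- factor(as.character(group), levels = c("control", "treated"))
  if (length(group) != ncol(counts) || anyNA(group)) {
    abort_field("group", "must label every sample as control or treated")
  }
  if (any(table(group) < 2)) {
    abort_field("group", "each group needs at least 2 samples")
  }
  structure(
    list(
      genes = rownames(counts), samples = colnames(counts),
      counts = counts, group = group, species = species, id = id
    ),
    class = "count_dataset"
  )
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf(
    "<count_dataset %s: %d genes x %d samples (%d control / %d treated), %s>\n",
    x$id, nrow(x$counts), ncol(x$counts),
    sum(x$group == "control"), sum(x$group == "treated"), x$species
  ))
  invisible(x)
}

#' Simulate multi-study count datasets with planted truth
#'
#' Draws one [count_dataset()] per study from the negative-binomial model in
#' [transcriptome_sim_spec()], together with an ortholog table for the mouse
#' studies and a truth record listing the planted memberships. Mouse-study
#' genes are emitted under mouse source symbols; the ortholog table omits a
#' configurable fraction of genes (unmapped) and maps another fraction to an
#' extra spurious human paralog (one-to-many).
#'
#' @param spec A [transcriptome_sim_spec()].
#' @return A list with elements `datasets` (list of `count_dataset`),
#'   `ortholog_table` (tibble `source_symbol`, `human_symbol`) and `truth`
#'   (list with `planted_up`, `planted_down`, per-study `private` tibble,
#'   `unmapped` symbols).
#' @export
simulate_count_datasets <- function(spec) {
  if (!inherits(spec, "transcriptome_sim_spec")) {
    abort_field("spec", "must be a transcriptome_sim_spec")
  }
  withr::with_seed(spec$seed, {
    universe <- sim_gene_universe(spec$n_genes)
    planted_up <- spec$planted_up %||% sample(universe, spec$n_planted_up)
    planted_down <- spec$planted_down %||%
      sample(setdiff(universe, planted_up), spec$n_planted_down)
    if (length(intersect(planted_up, planted_down)) > 0) {
      abort_field("planted_up", "planted_up and planted_down must be disjoint")
    }
    if (!all(c(planted_up, planted_down) %in% universe)) {
      abort_field("planted_up", "planted genes must belong to the gene universe")
    }

    species <- c(rep("mouse", spec$n_studies - 1L), "human")
    n_private <- round(spec$study_specific_frac * spec$n_genes)
    free <- setdiff(universe, c(planted_up, planted_down))

    private <- vector("list", spec$n_studies)
    datasets <- vector("list", spec$n_studies)
    for (s in seq_len(spec$n_studies)) {
      priv_genes <- if (n_private > 0) sample(free, min(n_private, length(free))) else character()
      priv_sign <- sample(c(1, -1), length(priv_genes), replace = TRUE)
      private[[s]] <- tibble::tibble(study = s, human_symbol = priv_genes, direction = ifelse(priv_sign > 0, "up", "down"))

      lfc <- stats::setNames(rep(0, spec$n_genes), universe)
      lfc[planted_up] <- spec$log2_effect
      lfc[planted_down] <- -spec$log2_effect
      lfc[priv_genes] <- priv_sign * spec$log2_effect

      base <- 2^stats::runif(
        spec$n_genes,
        spec$baseline_mean_log_range[1], spec$baseline_mean_log_range[2]
      )
      n <- spec$samples_per_group
      mu <- cbind(
        matrix(rep(base, n), ncol = n),
        matrix(rep(base * 2^lfc, n), ncol = n)
      )
      counts <- matrix(
        stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / spec$dispersion),
        nrow = spec$n_genes
      )
      ids <- if (species[s] == "mouse") mouse_symbol_of(universe) else universe
      rownames(counts) <- ids
      colnames(counts) <- sprintf("S%d_%s%d", s, rep(c("ctrl", "trt"), each = n), rep(seq_len(n), 2))
      datasets[[s]] <- count_dataset(
        counts,
        group = rep(c("control", "treated"), each = n),
        species = species[s],
        id = sprintf("study%d", s)
      )
    }

    unmapped <- sample(universe, round(spec$frac_unmapped * spec$n_genes))
    one_to_many <- sample(
      setdiff(universe, unmapped),
      round(spec$frac_one_to_many * spec$n_genes)
    )
    mapped <- setdiff(universe, unmapped)
    ortholog_table <- dplyr::bind_rows(
      tibble::tibble(source_symbol = mouse_symbol_of(mapped), human_symbol = mapped),
      tibble::tibble(
        source_symbol = mouse_symbol_of(one_to_many),
        human_symbol = paste0(one_to_many, "B")
      )
    ) |>
      dplyr::arrange(.data$source_symbol, .data$human_symbol)

    list(
      datasets = datasets,
      ortholog_table = ortholog_table,
      truth = list(
        universe = universe,
        planted_up = sort(planted_up),
        planted_down = sort(planted_down),
        private = dplyr::bind_rows(private),
        unmapped = sort(unmapped),
        one_to_many = sort(one_to_many)
      )
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
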