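# Readers and writers for the pipeline's plain-text interchange formats:
# GCT 1.2 (perturbagen x gene score matrices), GMT (gene sets), gene x sample
# count TSVs with group labels, two-column ortholog TSVs, and the
# $-delimited adverse-event report dialect.

#' Write a signature library as GCT 1.2
#'
#' Layout: `#1.2` header line, `nrow ncol`, then a TAB-separated table with
#' `Name` and `Description` columns followed by one column per sample. Rows
#' are genes and columns are perturbagens (the transpose of the in-memory
#' score matrix), matching the usual orientation of the format.
#'
#' @param lib A [signature_library()].
#' @param path Output path.
#' @export
write_gct <- function(lib, path) {
  stopifnot(inherits(lib, "signature_library"))
  m <- t(lib$scores) # genes x perturbagens
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(m)), collapse = "\t")
  writeLines(header, con)
  body <- paste(
    rownames(m), "na",
    apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15), collapse = "\t")),
    sep = "\t"
  )
  writeLines(body, con)
}

#' Read a GCT 1.2 score matrix as a signature library
#'
#' @param path Path to a GCT 1.2 file (genes in rows, perturbagens in
#'   columns).
#' @return A [signature_library()].
#' @export
read_gct <- function(path) {
  check_file_exists(path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
    rlang::abort(sprintf("%s: not a GCT 1.2 file", path), class = "cindr_parse_error")
  }
  dims <- as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != dims[2] + 2 || !identical(header[1:2], c("Name", "Description"))) {
    rlang::abort(sprintf("%s: malformed GCT header", path), class = "cindr_parse_error")
  }
  body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  if (length(body) != dims[1]) {
    rlang::abort(sprintf("%s: expected %d data rows, found %d", path, dims[1], length(body)),
      class = "cindr_parse_error"
    )
  }
  genes <- vapply(body, `[[`, character(1), 1)
  vals <- vapply(body, function(r) as.numeric(r[-(1:2)]), numeric(dims[2]))
  # vals is perturbagen x gene (vapply stacks per-gene columns)
  scores <- matrix(vals,
    nrow = dims[2], ncol = dims[1],
    dimnames = list(header[-(1:2)], genes)
  )
  signature_library(scores)
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a TAB-separated GMT file
#'   (`name<TAB>description<TAB>gene...`).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  check_file_exists(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s: line %d: GMT rows need name, description and >=1 gene", path, bad[1]),
      class = "cindr_parse_error"
    )
  }
  stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, character(1), 1)
  )
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(
    names(collection),
    function(nm) paste(c(nm, description, collection[[nm]]), collapse = "\t"),
    character(1)
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write and read a gene signature as a two-line GMT
#'
#' The signature is serialized as `<name>_UP` and `<name>_DN` sets.
#'
#' @param sig A [gene_signature()].
#' @param path File path.
#' @param name Signature name used as the set-name stem.
#' @export
write_signature_gmt <- function(sig, path, name = "SIGNATURE") {
  stopifnot(inherits(sig, "gene_signature"))
  collection <- stats::setNames(
    list(sig$up, sig$down),
    paste0(name, c("_UP", "_DN"))
  )
  write_gmt(collection, path)
}

#' @rdname write_signature_gmt
#' @return `read_signature_gmt()` returns the [gene_signature()].
#' @export
read_signature_gmt <- function(path) {
  sets <- read_gmt(path)
  up <- which(endsWith(names(sets), "_UP"))
  dn <- which(endsWith(names(sets), "_DN"))
  if (length(up) != 1 || length(dn) != 1) {
    rlang::abort(sprintf("%s: expected exactly one *_UP and one *_DN set", path),
      class = "cindr_parse_error"
    )
  }
  gene_signature(sets[[up]], sets[[dn]])
}

#' Write a count dataset as TSV pair
#'
#' Counts go to `<stem>_counts.tsv` (first column `gene`, one column per
#' sample) and group labels to `<stem>_labels.tsv` (`sample`, `group`).
#'
#' @param ds A [count_dataset()].
#' @param stem Path stem.
#' @return Invisibly, the two paths written.
#' @export
write_count_dataset <- function(ds, stem) {
  stopifnot(inherits(ds, "count_dataset"))
  counts_path <- paste0(stem, "_counts.tsv")
  labels_path <- paste0(stem, "_labels.tsv")
  df <- data.frame(gene = ds$genes, ds$counts, check.names = FALSE)
  utils::write.table(df, counts_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(sample = ds$samples, group = as.character(ds$group)),
    labels_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(counts_path, labels_path))
}

#' Read a count dataset from a TSV pair
#'
#' @param counts_path Gene x sample TSV (first column gene ids).
#' @param labels_path Two-column TSV `sample`, `group`.
#' @param species,id Dataset metadata.
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(counts_path, labels_path,
                               species = "human", id = "dataset") {
  check_file_exists(counts_path)
  check_file_exists(labels_path)
  df <- utils::read.delim(counts_path, check.names = FALSE)
  labels <- utils::read.delim(labels_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  group <- labels$group[match(colnames(counts), labels$sample)]
  if (anyNA(group)) {
    rlang::abort(sprintf("%s: samples missing from label table", labels_path),
      class = "cindr_parse_error"
    )
  }
  count_dataset(counts, group, species = species, id = id)
}

#' Write adverse-event report tables in the `$`-delimited dialect
#'
#' @param tables List with `demo`, `drug`, `reac` tibbles, e.g. from
#'   [simulate_faers_tables()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three paths written.
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_one <- function(tbl, name) {
    path <- file.path(dir, paste0(name, ".txt"))
    lines <- c(
      paste(names(tbl), collapse = "$"),
      do.call(paste, c(unname(as.list(tbl)), sep = "$"))
    )
    writeLines(lines, path, useBytes = TRUE)
    path
  }
  invisible(c(
    write_one(tables$demo, "DEMO"),
    write_one(tables$drug, "DRUG"),
    write_one(tables$reac, "REAC")
  ))
}

#' Write a two-column TSV table
#'
#' Convenience writer for ortholog tables (`source_symbol`, `human_symbol`)
#' and synonym tables (`verbatim`, `atc_code`).
#'
#' @param table Data frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_tsv_table
#' @return `read_tsv_table()` returns a tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}
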