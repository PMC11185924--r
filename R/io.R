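#' Read a gene expression matrix (TSV or GCT 1.2)
#'
#' Reads a genes x samples table of log-scale expression values. The plain
#' TSV dialect expects a header row of sample ids and gene ids in the first
#' column. The GCT 1.2 dialect skips the two-line preamble (`#1.2` and the
#' dimension line), uses the `Name` column as gene ids and drops the
#' `Description` column.
#'
#' Duplicate gene rows are collapsed by their mean (with a warning); blank or
#' non-numeric cells become `NA`. Sample order in the file is preserved.
#' Gene identifiers are matched exactly and case-sensitively throughout the
#' package: inputs must already share a namespace (no alias mapping is done).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"gct"`.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), f)
#' read_expression(f)
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Expression file not found: %s", path))
  skip <- 0L
  if (format == "gct") {
    preamble <- readLines(path, n = 2L)
    if (length(preamble) < 2L || !startsWith(preamble[[1L]], "#1.")) {
      abort(sprintf("Malformed GCT preamble at line 1 of %s (expected '#1.2').", path))
    }
    skip <- 2L
  }
  df <- readr::read_tsv(path, skip = skip, col_types = readr::cols(),
                        na = c("", "NA", "NaN"), progress = FALSE,
                        # '#' provenance headers are tolerated in the TSV
                        # dialect; GCT needs its '#1.2' preamble intact
                        comment = if (format == "tsv") "#" else "",
                        show_col_types = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    abort(sprintf("Empty expression input: %s has %d gene rows and %d sample columns.",
                  path, nrow(df), max(ncol(df) - 1L, 0L)))
  }
  if (format == "gct") {
    if (!identical(names(df)[1:2], c("Name", "Description"))) {
      abort(sprintf("Malformed GCT header at line 3 of %s: first columns must be 'Name' and 'Description'.", path))
    }
    gene_ids <- as.character(df$Name)
    df <- df[, -(1:2), drop = FALSE]
  } else {
    gene_ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) == 0L) abort(sprintf("Empty expression input: %s has zero sample columns.", path))
  values <- vapply(df, function(col) suppressWarnings(as.numeric(col)), numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df),
                   dimnames = list(gene_ids, names(df)))
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warn(sprintf("Collapsing %d duplicated gene id(s) by mean (e.g. %s).",
                 length(dups), dups[[1L]]))
    values <- rowsum(values, group = gene_ids, reorder = FALSE, na.rm = TRUE) /
      rowsum((!is.na(values)) * 1, group = gene_ids, reorder = FALSE)
    values[!is.finite(values)] <- NA_real_
  }
  assert_expression_matrix(values, "parsed expression")
  values
}

#' Read a drugs x cell-lines AUC table
#'
#' Reads a CSV or TSV drug-response table: header row of cell-line ids, drug
#' ids in the first column, non-negative AUC values (higher AUC = more
#' resistant). Missing entries are allowed and excluded pairwise at training.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) infers from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return A numeric matrix, drugs in rows, cell lines in columns.
#' @export
read_response <- function(path, sep = NULL) {
  if (!file.exists(path)) abort(sprintf("Response file not found: %s", path))
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = sep, col_types = readr::cols(),
                          na = c("", "NA", "NaN"), progress = FALSE,
                          comment = "#", show_col_types = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    abort(sprintf("Empty response input: %s.", path))
  }
  drug_ids <- as.character(df[[1L]])
  if (anyDuplicated(drug_ids)) abort(sprintf("Duplicated drug ids in %s.", path))
  values <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)), numeric(nrow(df)))
  values <- matrix(values, nrow = nrow(df), dimnames = list(drug_ids, names(df)[-1L]))
  assert_response_matrix(values, "parsed response")
  values
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' de-duplicated preserving order. An empty file yields an empty collection
#' with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors with a `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warn(sprintf("GMT file %s is empty; returning an empty collection.", path))
    out <- list()
    attr(out, "descriptions") <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf("Malformed GMT line %d in %s: expected name, description and at least one gene.",
                  bad[[1L]], path))
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) abort(sprintf("Duplicated gene-set names in %s.", path))
  descr <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  sets <- lapply(sets, function(g) g[nzchar(g)])
  if (any(lengths(sets) == 0L)) {
    abort(sprintf("GMT set '%s' in %s is empty after deduplication.",
                  names_[which(lengths(sets) == 0L)[1L]], path))
  }
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(descr, names_)
  sets
}

# On-disk DGCP library layout: a directory holding manifest.json (format
# version, lineage, provenance, gene universe, drug ids) plus one
# <drug>.tsv per drug with columns gene, pcc in DGCP order. readr writes
# doubles with shortest round-trip precision, so write/read is lossless.
DGCP_LIBRARY_FORMAT <- 1L

#' Write / read a DGCP library
#'
#' Serializes a [build_library()] result to a directory (a JSON manifest plus
#' one two-column TSV per drug) and reads it back losslessly: gene order and
#' correlation values survive a round trip to full double precision. Reading
#' a library written by an incompatible format version, or a truncated
#' per-drug table, raises an error rather than silently loading a partial
#' library.
#'
#' @param library A `dgcp_library` object.
#' @param path Directory to create (write) or read from.
#' @return `write_dgcp_library()` returns `path` invisibly;
#'   `read_dgcp_library()` returns a `dgcp_library`.
#' @export
write_dgcp_library <- function(library, path) {
  stopifnot(inherits(library, "dgcp_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  drug_files <- setNames(
    paste0("dgcp_", gsub("[^A-Za-z0-9._-]", "_", names(library$dgcps)), ".tsv"),
    names(library$dgcps))
  if (anyDuplicated(drug_files)) abort("Drug ids collide after filename sanitization.")
  manifest <- list(
    format_version = DGCP_LIBRARY_FORMAT,
    lineage = library$lineage,
    provenance = library$provenance,
    gene_universe = library$gene_universe,
    drugs = lapply(names(library$dgcps), function(d) {
      list(drug_id = d, file = unname(drug_files[[d]]),
           n_cell_lines = attr(library$dgcps[[d]], "n_cell_lines"),
           n_genes = nrow(library$dgcps[[d]]))
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (d in names(library$dgcps)) {
    # 17 significant digits guarantee an exact double round trip
    tab <- tibble::tibble(gene = library$dgcps[[d]]$gene,
                          pcc = sprintf("%.17g", library$dgcps[[d]]$pcc))
    readr::write_tsv(tab, file.path(path, drug_files[[d]]), progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_dgcp_library
#' @export
read_dgcp_library <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No DGCP library manifest at %s.", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (!identical(as.integer(manifest$format_version), DGCP_LIBRARY_FORMAT)) {
    abort(sprintf("DGCP library format version %s is not supported (expected %d).",
                  as.character(manifest$format_version %||% "<missing>"),
                  DGCP_LIBRARY_FORMAT))
  }
  universe <- as.character(manifest$gene_universe)
  dgcps <- list()
  for (entry in manifest$drugs) {
    f <- file.path(path, entry$file)
    if (!file.exists(f)) abort(sprintf("DGCP library is missing per-drug table %s.", f))
    tab <- readr::read_tsv(f, col_types = "cc", progress = FALSE, show_col_types = FALSE)
    # base-R strtod is correctly rounded, so %.17g text round-trips exactly
    tab$pcc <- as.numeric(tab$pcc)
    if (!identical(names(tab), c("gene", "pcc")) ||
        nrow(tab) != entry$n_genes || anyNA(tab$pcc)) {
      abort(sprintf("Corrupted or truncated DGCP table %s (expected %d complete rows).",
                    f, entry$n_genes))
    }
    dgcps[[entry$drug_id]] <- new_dgcp(entry$drug_id, tab$gene, tab$pcc,
                                       n_cell_lines = entry$n_cell_lines)
  }
  new_dgcp_library(lineage = manifest$lineage, dgcps = dgcps,
                   gene_universe = universe, provenance = manifest$provenance)
}
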