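#' Read a genes-by-samples expression table
#'
#' Expression tables are plain text with gene symbols in the first column and
#' one column per sample. Values are assumed to be library-normalized
#' (e.g. FPKM/TPM, possibly logged); the pipeline never rescales them, because
#' every downstream quantity is computed from within-sample comparisons only.
#'
#' Duplicate gene symbols are collapsed to the row with the largest
#' (unscaled) median absolute deviation, the most informative measurement;
#' ties keep the first occurrence. Gene symbols are uppercased.
#'
#' @param path Path to a delimited text file. First column: gene symbols;
#'   header row: sample identifiers; body: numeric.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per sample.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_config(paste0("expression file not found: ", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = "c"),
                na = character(), progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort_format("expression table needs a gene column and at least one sample column")
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    abort_format(paste0("duplicate sample id in expression header: ",
                        sample_ids[duplicated(sample_ids)][1]))
  }
  genes <- toupper(trimws(raw[[1]]))
  if (any(!nzchar(genes))) abort_format("empty gene symbol in expression table")
  body <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  body <- matrix(body, nrow = nrow(raw),
                 dimnames = list(NULL, sample_ids))
  bad <- which(!is.finite(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_parse(sprintf(
      "non-numeric or non-finite expression value at gene '%s', sample '%s'",
      genes[bad[1, 1]], sample_ids[bad[1, 2]]))
  }
  expr <- dplyr::bind_cols(tibble(gene = genes), as_tibble(body))
  collapse_duplicate_genes(expr)
}

collapse_duplicate_genes <- function(expr) {
  if (!anyDuplicated(expr$gene)) return(expr)
  m <- expression_matrix(expr, check_unique = FALSE)
  row_mad <- apply(m, 1, mad_value)
  keep <- vapply(split(seq_along(expr$gene), factor(expr$gene, levels = unique(expr$gene))),
                 function(idx) idx[which.max(row_mad[idx])], integer(1))
  expr[sort(keep), , drop = FALSE]
}

#' Validate a genes-by-samples expression tibble
#'
#' @param expr Data frame whose first column holds gene symbols and whose
#'   remaining columns are numeric per-sample values.
#' @return The validated tibble (first column renamed `gene`).
#' @export
as_expression <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    abort_format("expression must be a data frame: gene column + sample columns")
  }
  expr <- as_tibble(expr)
  names(expr)[1] <- "gene"
  if (!is.character(expr$gene)) expr$gene <- as.character(expr$gene)
  if (anyDuplicated(expr$gene)) abort_format("duplicate gene symbols in expression table")
  if (anyDuplicated(names(expr)[-1])) abort_format("duplicate sample ids in expression table")
  m <- expression_matrix(expr)
  if (any(!is.finite(m))) abort_domain("expression values must all be finite")
  expr
}

# genes x samples numeric matrix view of an expression tibble
expression_matrix <- function(expr, check_unique = TRUE) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (check_unique && anyDuplicated(expr$gene)) {
    abort_format("duplicate gene symbols in expression table")
  }
  rownames(m) <- expr$gene
  m
}

#' Write an expression tibble to TSV
#' @param expr Expression tibble (`gene` column + sample columns).
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(as_expression(expr), path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Requires columns `sample_id`, `os_time` (overall-survival time, > 0) and
#' `os_event` (1 = death, 0 = censored). Optional columns `stage`, `grade`,
#' `gender`, `age` are kept; stage and grade are normalized to ordinals 1-4
#' ("Stage IIIA" becomes 3, "G2" becomes 2); unrecognized tokens become `NA`
#' with a message. Rows with non-positive survival time or missing event
#' status are dropped with a message.
#'
#' Survival-time units are whatever the file uses; they are recorded as the
#' `time_unit` attribute and never converted, so ROC horizons must be given
#' in the same unit.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param time_unit Free-text unit of `os_time` (metadata only).
#' @return A tibble with columns `sample_id`, `os_time`, `os_event` and any
#'   optional covariates present.
#' @export
read_clinical <- function(path, dialect = c("tsv", "csv"), time_unit = "as-supplied") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_config(paste0("clinical file not found: ", path))
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  as_clinical(raw, time_unit = time_unit)
}

#' Validate (and normalize) a clinical data frame
#' @inheritParams read_clinical
#' @param clinical Data frame with at least `sample_id`, `os_time`, `os_event`.
#' @export
as_clinical <- function(clinical, time_unit = "as-supplied") {
  clinical <- as_tibble(clinical)
  needed <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols) > 0) {
    abort_format(paste0("clinical table is missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  clinical$sample_id <- as.character(clinical$sample_id)
  clinical$os_time <- suppressWarnings(as.numeric(clinical$os_time))
  ev <- suppressWarnings(as.numeric(clinical$os_event))
  if (any(!is.na(ev) & !ev %in% c(0, 1))) {
    abort_format("os_event must be 0 (censored) or 1 (death)")
  }
  clinical$os_event <- as.integer(ev)
  drop <- is.na(clinical$os_time) | clinical$os_time <= 0 | is.na(clinical$os_event)
  if (any(drop)) {
    rlang::inform(sprintf("read_clinical: dropped %d record(s) with os_time <= 0 or missing os_event",
                          sum(drop)))
    clinical <- clinical[!drop, , drop = FALSE]
  }
  if (anyDuplicated(clinical$sample_id)) abort_format("duplicate sample_id in clinical table")
  if ("stage" %in% names(clinical)) clinical$stage <- normalize_ordinal(clinical$stage, "stage")
  if ("grade" %in% names(clinical)) clinical$grade <- normalize_ordinal(clinical$grade, "grade")
  if ("age" %in% names(clinical)) clinical$age <- suppressWarnings(as.numeric(clinical$age))
  attr(clinical, "time_unit") <- time_unit
  clinical
}

# "Stage IIIA" -> 3, "G2" -> 2, "IV" -> 4, "3" -> 3; unknown -> NA (logged)
normalize_ordinal <- function(x, what) {
  tok <- toupper(trimws(as.character(x)))
  tok <- sub("^STAGE\\s*", "", tok)
  tok <- sub("^G(?=[1-4])", "", tok, perl = TRUE)
  tok <- sub("^(IV|III|II|I)[A-C]?$", "\\1", tok)
  out <- dplyr::case_when(
    tok %in% c("I", "1") ~ 1L,
    tok %in% c("II", "2") ~ 2L,
    tok %in% c("III", "3") ~ 3L,
    tok %in% c("IV", "4") ~ 4L,
    TRUE ~ NA_integer_
  )
  unknown <- !is.na(x) & nzchar(trimws(as.character(x))) & is.na(out)
  if (any(unknown)) {
    rlang::inform(sprintf("read_clinical: %d unrecognized %s value(s) set to NA (e.g. '%s')",
                          sum(unknown), what, as.character(x)[unknown][1]))
  }
  out
}

#' Write a clinical tibble to TSV
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line, `#` comments allowed)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique, uppercased symbols in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_config(paste0("gene list not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  symbols <- toupper(trimws(lines))
  symbols <- symbols[nzchar(symbols)]
  unique(symbols)
}

#' Write a gene list
#' @param symbols Character vector of gene symbols.
#' @param path Output path.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(toupper(symbols), path)
  invisible(path)
}

#' The packaged 127-gene autophagy candidate list
#'
#' Returns the bundled list of 127 autophagy-associated genes used as the
#' default candidate set for the worked examples.
#'
#' @return Character vector of 127 gene symbols.
#' @export
autophagy_genes <- function() {
  read_gene_list(system.file("extdata", "autophagy_genes_127.txt",
                             package = "pairhazard", mustWork = TRUE))
}

signature_schema_version <- 1L

#' Serialize a gene-pair signature to JSON
#'
#' The file stores the ordered pairs, their Cox coefficients, the calibrated
#' risk-score cutoff, the ROC evaluation horizon, and free-text provenance.
#' `read_signature(write_signature(m))` reproduces the model losslessly
#' (reals at full double precision).
#'
#' @param model A `pair_signature` object.
#' @param path Output path (JSON).
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "pair_signature"))
  validate_pair_signature(model)
  payload <- list(
    schema_version = signature_schema_version,
    pairs = purrr::map2(model$pairs$gene_hi, model$pairs$gene_lo, c),
    coefficients = model$pairs$coefficient,
    cutoff = model$cutoff,
    horizon = model$horizon,
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a gene-pair signature from JSON
#' @param path Path written by [write_signature()].
#' @return A `pair_signature` object.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) abort_config(paste0("signature file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- payload$schema_version
  if (is.null(ver) || !identical(as.integer(ver), signature_schema_version)) {
    abort_format(paste0("unknown signature schema version: ",
                        if (is.null(ver)) "<missing>" else ver))
  }
  pairs <- tibble(
    gene_hi = purrr::map_chr(payload$pairs, 1),
    gene_lo = purrr::map_chr(payload$pairs, 2),
    coefficient = purrr::map_dbl(payload$coefficients, identity)
  )
  pair_signature(
    pairs,
    cutoff = if (is.null(payload$cutoff)) NA_real_ else payload$cutoff,
    horizon = if (is.null(payload$horizon)) NA_real_ else payload$horizon,
    provenance = payload$provenance
  )
}
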