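#' Read a feature-by-sample matrix in the tab-delimited scan dialect
#'
#' Reads the tab-separated matrix format used throughout the package:
#' a header row of sample IDs (an optional leading `"id"` cell is
#' tolerated), then one row per feature consisting of the feature ID
#' followed by one numeric field per sample. `"NA"`, `"NaN"` and the
#' empty string all parse as missing. Missing entries are flagged as
#' `NA`, never silently imputed; imputation is a separate, explicit
#' step (see [impute_row_means()]).
#'
#' Validation depends on `kind`:
#' * `"methylation"`: non-missing values must lie in \[0, 1\] (beta
#'   values). Set `validate_range = FALSE` for M-values.
#' * `"genotype"`: non-missing values must be in \{0, 1, 2\} (additive
#'   minor-allele dosage), or anywhere in \[0, 2\] when `dosage = TRUE`.
#' * `"environment"`, `"covariate"`: no range constraint.
#'
#' @param path Path to a tab-separated matrix file.
#' @param kind One of `"methylation"`, `"genotype"`, `"environment"`,
#'   `"covariate"`. Controls range validation.
#' @param validate_range Enforce the per-kind value range? Default `TRUE`.
#' @param dosage For `kind = "genotype"`: accept fractional dosages in
#'   \[0, 2\] (e.g. imputed genotypes) instead of hard calls \{0, 1, 2\}.
#' @return A numeric matrix (features in rows, samples in columns) with
#'   feature IDs as rownames and sample IDs as colnames, and a `"kind"`
#'   attribute.
#' @seealso [write_feature_matrix()] for the inverse, [align_samples()].
#' @export
read_feature_matrix <- function(path,
                                kind = c("methylation", "genotype",
                                         "environment", "covariate"),
                                validate_range = TRUE,
                                dosage = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    stop("empty matrix file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # trailing empty field from a trailing tab would shift the geometry;
  # keep it, as.numeric("") -> NA is caught by the width check instead
  header <- fields[[1L]]
  body <- fields[-1L]
  if (length(body) == 0L) {
    stop("matrix file has a header but no feature rows: ", path,
         call. = FALSE)
  }
  widths <- lengths(body)
  # a data row has featureID + one field per header sample; the header
  # itself may or may not carry a leading id cell
  allowed <- c(length(header), length(header) + 1L)
  bad <- which(!widths %in% allowed | widths != widths[1L])
  if (length(bad) > 0L) {
    stop("ragged row in ", path, ": line ", bad[1L] + 1L, " has ",
         widths[bad[1L]], " fields, expected ",
         paste(unique(intersect(c(widths[1L], allowed), allowed)),
               collapse = " or "), call. = FALSE)
  }
  n_fields <- widths[1L]
  if (length(header) == n_fields) {
    # leading cell names the feature-ID column; drop it
    sample_ids <- header[-1L]
  } else if (length(header) == n_fields - 1L) {
    sample_ids <- header
  } else {
    stop("header of ", path, " has ", length(header),
         " fields but data rows have ", n_fields,
         " (expected ", n_fields - 1L, " or ", n_fields, ")",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  feature_ids <- vapply(body, `[`, character(1L), 1L)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature ID(s) in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  missing_tok <- cells == "" | cells == "NA" | cells == "NaN"
  values <- suppressWarnings(as.numeric(cells))
  unparsed <- is.na(values) & !missing_tok
  if (any(unparsed)) {
    k <- which(unparsed)[1L]
    row <- (k - 1L) %/% (n_fields - 1L) + 1L
    col <- (k - 1L) %% (n_fields - 1L) + 1L
    stop("non-numeric value ", dQuote(cells[k]), " in ", path,
         " at feature ", feature_ids[row], ", sample ", sample_ids[col],
         call. = FALSE)
  }
  values[missing_tok] <- NA_real_
  m <- matrix(values, nrow = length(body), ncol = n_fields - 1L,
              byrow = TRUE,
              dimnames = list(feature_ids, sample_ids))
  if (validate_range) {
    validate_matrix_range(m, kind, dosage = dosage, context = path)
  }
  attr(m, "kind") <- kind
  m
}

# Range rules per matrix kind; lists offending cells on failure.
validate_matrix_range <- function(m, kind, dosage = FALSE,
                                  context = "matrix") {
  bad <- switch(kind,
    methylation = !is.na(m) & (m < 0 | m > 1),
    genotype = if (dosage) {
      !is.na(m) & (m < 0 | m > 2)
    } else {
      !is.na(m) & !(m %in% c(0, 1, 2))
    },
    array(FALSE, dim = dim(m))
  )
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    idx <- idx[seq_len(min(nrow(idx), 5L)), , drop = FALSE]
    cells <- apply(idx, 1L, function(ij) {
      paste0(rownames(m)[ij[1L]], "/", colnames(m)[ij[2L]], "=",
             m[ij[1L], ij[2L]])
    })
    stop("out-of-range ", kind, " value(s) in ", context, ": ",
         paste(cells, collapse = ", "),
         if (sum(bad) > 5L) paste0(" (and ", sum(bad) - 5L, " more)"),
         call. = FALSE)
  }
  invisible(m)
}

#' Write a feature matrix in the tab-delimited scan dialect
#'
#' Inverse of [read_feature_matrix()]. Values are printed with 17
#' significant digits so that a read/write round trip reproduces the
#' matrix bit-exactly; missing cells are written as `NA`.
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  vals <- sprintf("%.17g", m)
  vals[is.na(m)] <- "NA"
  body <- matrix(vals, nrow = nrow(m))
  out <- c(paste(c("id", colnames(m)), collapse = "\t"),
           paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                 sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Restrict matrices to their shared samples, in a common order
#'
#' All returned matrices have identical sample columns: the
#' intersection of the input sample sets, in the relative order they
#' appear in the first matrix. Samples outside the intersection are
#' dropped and reported via the `"dropped"` attribute (a tibble with
#' columns `matrix`, `sample_id`).
#'
#' Idempotent: applying it to its own output changes nothing.
#'
#' @param matrices A list of two or more feature matrices with sample
#'   colnames.
#' @return The list of matrices, columns aligned; attribute `"dropped"`
#'   reports the discarded samples.
#' @export
align_samples <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  ids <- lapply(matrices, colnames)
  if (any(vapply(ids, is.null, logical(1L)))) {
    stop("all matrices must have sample colnames", call. = FALSE)
  }
  shared <- Reduce(intersect, ids[-1L], ids[[1L]])
  shared <- ids[[1L]][ids[[1L]] %in% shared]  # order of the first input
  if (length(shared) == 0L) {
    stop("no shared samples across the supplied matrices", call. = FALSE)
  }
  nm <- names(matrices)
  if (is.null(nm)) nm <- paste0("matrix", seq_along(matrices))
  dropped <- purrr::map2_dfr(ids, nm, function(s, label) {
    tibble::tibble(matrix = label, sample_id = setdiff(s, shared))
  })
  out <- lapply(matrices, function(m) {
    a <- attributes(m)
    m2 <- m[, shared, drop = FALSE]
    attr(m2, "kind") <- a$kind
    m2
  })
  names(out) <- names(matrices)
  attr(out, "dropped") <- dropped
  out
}

#' Read a BED-like feature annotation file
#'
#' Expects at least four tab-separated columns: chromosome, start, end,
#' feature ID. Coordinates are 0-based, half-open (BED convention).
#' Extra columns are ignored. No header row.
#'
#' @param path Path to a BED4(+) file.
#' @return A tibble with columns `feature_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(ann) < 4L) {
    stop("annotation file needs >= 4 columns (chrom, start, end, id): ",
         path, call. = FALSE)
  }
  ann <- tibble::tibble(feature_id = as.character(ann[[4L]]),
                        chrom = as.character(ann[[1L]]),
                        start = as.integer(ann[[2L]]),
                        end = as.integer(ann[[3L]]))
  validate_annotation(ann, context = path)
}

validate_annotation <- function(ann, context = "annotation") {
  if (anyDuplicated(ann$feature_id)) {
    stop("duplicate feature ID(s) in ", context, ": ",
         paste(unique(ann$feature_id[duplicated(ann$feature_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(ann$start) | is.na(ann$end)) ||
      any(ann$start < 0L) || any(ann$start > ann$end)) {
    bad <- which(is.na(ann$start) | is.na(ann$end) | ann$start < 0L |
                 ann$start > ann$end)[1L]
    stop("invalid interval in ", context, " for feature ",
         ann$feature_id[bad], " (need 0 <= start <= end)", call. = FALSE)
  }
  if (any(!nzchar(ann$chrom) | is.na(ann$chrom))) {
    stop("empty chromosome name in ", context, call. = FALSE)
  }
  ann
}

#' Write an association result table
#'
#' Writes scan records as a TSV with a fixed, deterministic column
#' order: `outcome_id`, `predictor_id`, `env_id` (if present), `beta`,
#' `t_stat`, `p_value`, `fdr`, `pair_class` (if present). Numeric
#' columns are printed with 15 significant digits. Records must arrive
#' sorted by ascending p-value (the order every scan emits); unsorted
#' input is a contract violation. Rows are streamed in chunks so memory
#' stays bounded for very large result sets.
#'
#' @param records A data frame of association records (see
#'   [run_emodel()] and friends).
#' @param path Output path.
#' @param chunk_size Rows per write chunk.
#' @return The number of records written, invisibly.
#' @export
write_results <- function(records, path, chunk_size = 65536L) {
  cols <- c("outcome_id", "predictor_id",
            if ("env_id" %in% names(records)) "env_id",
            "beta", "t_stat", "p_value", "fdr",
            if ("pair_class" %in% names(records)) "pair_class")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(records$p_value)) {
    stop("records must be sorted by ascending p-value before writing",
         call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  n <- nrow(records)
  num_cols <- intersect(cols, c("beta", "t_stat", "p_value", "fdr"))
  for (s in seq_len(ceiling(n / chunk_size))) {
    i <- ((s - 1L) * chunk_size + 1L):min(s * chunk_size, n)
    chunk <- records[i, cols, drop = FALSE]
    for (cc in num_cols) chunk[[cc]] <- sprintf("%.15g", chunk[[cc]])
    writeLines(do.call(paste, c(unname(as.list(chunk)), sep = "\t")), con)
  }
  invisible(n)
}

#' Read back an association result table
#'
#' Companion reader for files produced by [write_results()].
#'
#' @param path Path to a result TSV.
#' @return A tibble of association records.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
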