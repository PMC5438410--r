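#' Reading, validating and writing the pipeline's tables
#'
#' Spectral-count matrices travel as TSV (one row per protein, one column
#' per sample) with a sidecar sample sheet; the clinical cohort travels as
#' CSV. Readers validate on entry so downstream stages never see malformed
#' data: rows are never silently dropped, and "unknown" category levels are
#' legal data rather than missing values.
#'
#' @name tabular_io
NULL

SUBJECT_STATUSES <- c("DFS", "AWD", "DOD", "DUC", "alive_unknown", "lost")

#' Construct a spectral-count matrix
#'
#' @param proteins data.frame with columns `protein_id`, `length_aa`
#'   (positive integer residues) and `unique_peptides` (non-negative
#'   integer).
#' @param counts Integer matrix, proteins x samples, of spectral counts;
#'   rownames are protein ids, colnames sample ids.
#' @param samples data.frame with columns `sample`, `condition`
#'   (`tumor`/`para_tumor`) and `pair_id`.
#' @return An object of class `spectral_count_matrix`.
#' @export
spectral_count_matrix <- function(proteins, counts, samples) {
  stopifnot(is.data.frame(proteins), is.data.frame(samples))
  counts <- as.matrix(counts)
  need <- c("protein_id", "length_aa", "unique_peptides")
  if (!all(need %in% names(proteins))) {
    stop("proteins must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(proteins$protein_id)) {
    dup <- proteins$protein_id[duplicated(proteins$protein_id)]
    stop("duplicate protein_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_len <- proteins$length_aa <= 0 | is.na(proteins$length_aa)
  if (any(bad_len)) {
    stop("non-positive protein length for: ",
         paste(proteins$protein_id[bad_len], collapse = ", "), call. = FALSE)
  }
  if (any(proteins$unique_peptides < 0, na.rm = TRUE)) {
    stop("negative unique-peptide count", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spectral counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(counts) != nrow(proteins)) {
    stop("counts rows must match proteins", call. = FALSE)
  }
  if (!all(c("sample", "condition", "pair_id") %in% names(samples))) {
    stop("samples must have columns: sample, condition, pair_id",
         call. = FALSE)
  }
  if (!setequal(colnames(counts), samples$sample) ||
      ncol(counts) != nrow(samples)) {
    stop("count columns must match the sample sheet", call. = FALSE)
  }
  if (!all(samples$condition %in% c("tumor", "para_tumor"))) {
    stop("condition must be tumor or para_tumor", call. = FALSE)
  }
  counts <- counts[, samples$sample, drop = FALSE]
  rownames(counts) <- proteins$protein_id
  structure(list(proteins = proteins, counts = counts, samples = samples),
            class = "spectral_count_matrix")
}

#' @export
print.spectral_count_matrix <- function(x, ...) {
  cat("spectral_count_matrix:", nrow(x$proteins), "proteins x",
      nrow(x$samples), "samples\n")
  cat("  conditions:", paste(sprintf(
    "%s=%d", names(table(x$samples$condition)),
    as.integer(table(x$samples$condition))), collapse = ", "), "\n")
  invisible(x)
}

#' Check tumor/para-tumor pairing of a spectral-count matrix
#'
#' @param x A `spectral_count_matrix`.
#' @return Invisibly, a data.frame mapping `pair_id` to its tumor and
#'   para-tumor sample; errors if any pair is incomplete or duplicated.
#' @export
check_pairing <- function(x) {
  s <- x$samples
  pairs <- split(s, s$pair_id)
  out <- lapply(pairs, function(p) {
    tum <- p$sample[p$condition == "tumor"]
    par <- p$sample[p$condition == "para_tumor"]
    if (length(tum) != 1 || length(par) != 1) {
      stop("pair ", p$pair_id[1],
           " must have exactly one tumor and one para_tumor sample",
           call. = FALSE)
    }
    data.frame(pair_id = p$pair_id[1], tumor = tum, para_tumor = par)
  })
  invisible(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Read a spectral-count table and its sample sheet
#'
#' @param path TSV with header `protein_id length_aa unique_peptides
#'   <sample1> ... <sampleK>` (column names remappable via `schema`).
#' @param sample_sheet TSV with columns `sample`, `condition`, `pair_id`.
#' @param schema Named list mapping the canonical names `protein_id`,
#'   `length_aa`, `unique_peptides` to the file's column names.
#' @param sep Field delimiter override (default tab).
#' @return A validated `spectral_count_matrix`.
#' @export
read_count_table <- function(path, sample_sheet,
                             schema = list(protein_id = "protein_id",
                                           length_aa = "length_aa",
                                           unique_peptides = "unique_peptides"),
                             sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  for (canon in c("protein_id", "length_aa", "unique_peptides")) {
    col <- schema[[canon]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("schema error: missing column '", col %||% canon, "'",
           call. = FALSE)
    }
  }
  meta_cols <- unlist(schema[c("protein_id", "length_aa", "unique_peptides")])
  sample_cols <- setdiff(names(raw), meta_cols)
  counts <- as.matrix(raw[sample_cols])
  if (!is.numeric(counts) || any(is.na(counts)) ||
      any(counts != round(counts)) || any(counts < 0)) {
    bad <- which(apply(raw[sample_cols], 1, function(r) {
      v <- suppressWarnings(as.numeric(r))
      any(is.na(v)) || any(v < 0) || any(v != round(v))
    }))
    stop("parse error: non-integer or negative count in data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  proteins <- data.frame(
    protein_id = as.character(raw[[schema$protein_id]]),
    length_aa = raw[[schema$length_aa]],
    unique_peptides = raw[[schema$unique_peptides]],
    stringsAsFactors = FALSE
  )
  samples <- utils::read.table(sample_sheet, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  spectral_count_matrix(proteins, counts, samples)
}

#' Write a spectral-count matrix (and its sample sheet) to TSV
#'
#' @param x A `spectral_count_matrix`.
#' @param path Output TSV path for the count table.
#' @param sample_sheet Output TSV path for the sample sheet.
#' @export
write_count_table <- function(x, path, sample_sheet) {
  tab <- cbind(x$proteins, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical cohort table
#'
#' One row per patient. Empty cells become `NA`; the literal category level
#' `"unknown"` is preserved as data. Rows are validated, never silently
#' dropped.
#'
#' @param path CSV with the subject-record columns (`subject_id`, `cohort`,
#'   `age`, `sex`, `subtype`, `functional`, `grade`, `stage`, `size_cm`,
#'   `ki67_class`, `metastasis`, `location`, `uchl1_percent`,
#'   `inx_percent`, `followup_months`, `status`).
#' @param sep Field delimiter override (default comma).
#' @return A data.frame of subject records.
#' @export
read_cohort_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  subjects <- utils::read.table(path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE,
                                na.strings = c("", "NA"))
  validate_subjects(subjects)
  subjects
}

#' Validate a subject-record data.frame
#'
#' @param subjects data.frame of subject records.
#' @return Invisibly, `subjects`; errors on the first violated invariant,
#'   citing the offending row.
#' @export
validate_subjects <- function(subjects) {
  bad <- which(!is.na(subjects$status) &
                 !subjects$status %in% SUBJECT_STATUSES)
  if (length(bad)) {
    stop("invalid status '", subjects$status[bad[1]], "' in row ", bad[1],
         call. = FALSE)
  }
  bad <- which(!is.na(subjects$followup_months) & subjects$followup_months < 0)
  if (length(bad)) {
    stop("negative followup_months in row ", bad[1], call. = FALSE)
  }
  for (col in c("uchl1_percent", "inx_percent")) {
    v <- subjects[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop(col, " outside [0,100] in row ", bad[1], call. = FALSE)
    }
  }
  invisible(subjects)
}

#' Write a cohort table to CSV
#'
#' @param subjects data.frame of subject records.
#' @param path Output CSV path.
#' @export
write_cohort_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a homogeneous result table to TSV
#'
#' Values round-trip at full stored precision (17 significant digits), so
#' reading the file back reproduces the records exactly.
#'
#' @param records A data.frame of results (possibly zero rows).
#' @param path Output TSV path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  rec <- records
  num <- vapply(rec, is.numeric, logical(1)) &
    !vapply(rec, is.integer, logical(1))
  rec[num] <- lapply(rec[num], function(x) sprintf("%.17g", x))
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are returned as character; numeric conversion is the caller's
#' decision.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
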