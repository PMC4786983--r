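#' Validate an expression matrix against a sample design
#'
#' Expression values are log-scale normalized intensities, genes in rows and
#' samples in columns; the column set must equal the design's `sample_id`
#' set, gene ids must be unique and values finite.
#'
#' @param expr Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param design Sample design tibble with at least a `sample_id` column.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr, design) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort("Expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) {
    abort("Duplicated gene ids in expression matrix")
  }
  if (!all(is.finite(expr))) {
    abort("Expression matrix contains non-finite values")
  }
  if (!setequal(colnames(expr), design$sample_id)) {
    abort("Expression columns do not match design sample_id set")
  }
  invisible(expr)
}

#' Validate a sample design table
#'
#' A sample design describes one experimental setting: each row is an array,
#' with the chemical, ordinal dose level (control/low/middle/high), its
#' numeric coding, treatment time in hours, replicate index and setting
#' label. Every (chemical, time) stratum holding a treated sample must also
#' hold a control, and `dose_value` is 0 exactly for controls.
#'
#' @param design A tibble with columns `sample_id`, `chemical`, `dose_level`,
#'   `dose_value`, `time_hr`, `replicate`, `setting`.
#' @return `design`, invisibly.
#' @export
validate_design <- function(design) {
  needed <- c("sample_id", "chemical", "dose_level", "dose_value",
              "time_hr", "replicate", "setting")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0L) {
    abort(paste0("Design lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) {
    abort("Duplicated sample_id in design")
  }
  if (!all(design$dose_level %in% c("control", "low", "middle", "high"))) {
    abort("dose_level must be one of control/low/middle/high")
  }
  if (!all((design$dose_value == 0) == (design$dose_level == "control"))) {
    abort("dose_value must be 0 exactly for control rows")
  }
  strata <- dplyr::summarise(
    dplyr::group_by(design, .data$chemical, .data$time_hr),
    has_treated = any(.data$dose_level != "control"),
    has_control = any(.data$dose_level == "control"),
    .groups = "drop"
  )
  bad <- dplyr::filter(strata, .data$has_treated & !.data$has_control)
  if (nrow(bad) > 0L) {
    abort(paste0(
      "Treated stratum without control: chemical ", bad$chemical[1],
      " at time ", bad$time_hr[1], " hr"
    ))
  }
  invisible(design)
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray platforms interrogate many genes with several probe sets. The
#' probe with the largest (unbiased) sample variance across all arrays is
#' retained verbatim for each gene; ties are broken by the lexicographically
#' smallest probe id, and probes absent from the map are dropped.
#'
#' @param expr Probe-level expression matrix (probes in rows).
#' @param probe_map Tibble with columns `probe_id` and `gene_id`
#'   (many probes to one gene).
#' @return Gene-level expression matrix, rows named by `gene_id`, ordered by
#'   gene id.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  present <- probe_map$probe_id %in% rownames(expr)
  if (!any(present)) {
    abort("No probe in the map is present in the expression matrix")
  }
  map <- dplyr::filter(probe_map, .data$probe_id %in% rownames(expr))
  vars <- apply(expr[map$probe_id, , drop = FALSE], 1L, stats::var)
  picked <- map |>
    dplyr::mutate(variance = vars[.data$probe_id]) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$variance), .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  out <- expr[picked$probe_id, , drop = FALSE]
  rownames(out) <- picked$gene_id
  out
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is a TSV with a `gene_id` first column and one column
#' per sample; values are log-scale expression.
#'
#' @param path File path.
#' @return For `read_expression`, a numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample design table as TSV
#'
#' @param path File path.
#' @return For `read_design`, a validated design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      chemical = readr::col_character(),
      dose_level = readr::col_character(),
      dose_value = readr::col_double(),
      time_hr = readr::col_double(),
      replicate = readr::col_integer(),
      setting = readr::col_character()
    ),
    progress = FALSE
  )
  validate_design(design)
  design
}

#' @rdname read_design
#' @param design A design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}
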