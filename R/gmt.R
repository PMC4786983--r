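#' Read a GMT pathway collection
#'
#' Parses the Broad-style tab-separated gene-set format: one set per line,
#' fields are the set name, a free-text description, then one or more gene
#' identifiers. Duplicate gene tokens within a line are collapsed.
#'
#' @param path Path to a GMT file (UTF-8, tab-separated, no quoting).
#' @return A pathway collection: a tibble with columns `pathway_id`,
#'   `description`, `genes` (list-column of character vectors) and `n_genes`.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines(c("A\tdesc\tg1\tg2", "B\tdesc\tg2\tg3"), tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_pathway_collection(character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad) > 0L) {
    abort(paste0(
      "Malformed GMT line ", bad[1], " in ", path,
      ": expected at least 3 tab-separated fields, found ", n_fields[bad[1]]
    ))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate pathway name(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  new_pathway_collection(ids, desc, genes)
}

new_pathway_collection <- function(ids, desc, genes) {
  tibble::tibble(
    pathway_id = as.character(ids),
    description = as.character(desc),
    genes = genes,
    n_genes = lengths(genes)
  )
}

#' Write a pathway collection to GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(coll, f))` reproduces `coll`
#' up to gene order within sets.
#'
#' @param coll A pathway collection tibble as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- purrr::pmap_chr(
    list(coll$pathway_id, coll$description, coll$genes),
    function(id, d, g) paste(c(id, d, g), collapse = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Retains gene sets whose size lies within `[min_size, max_size]`, bounds
#' inclusive. The defaults (15 and 500) are the conventional GSEA bounds used
#' to drop sets too small to score stably and too broad to interpret.
#'
#' @param coll A pathway collection tibble.
#' @param min_size,max_size Inclusive size bounds.
#' @return The filtered collection (same columns). Idempotent.
#' @export
filter_gene_sets <- function(coll, min_size = 15, max_size = 500) {
  stopifnot(min_size >= 1, max_size >= min_size)
  dplyr::filter(coll, .data$n_genes >= min_size, .data$n_genes <= max_size)
}

#' Restrict two pathway collections to their common pathways
#'
#' Cross-species comparison at the pathway level requires a shared pathway
#' namespace: both collections are restricted to the intersection of their
#' `pathway_id`s while gene memberships stay species-specific.
#'
#' @param a,b Pathway collection tibbles sharing a pathway identifier scheme.
#' @return A list with elements `a` and `b`, each restricted to the common
#'   ids, in the id order of `a`.
#' @export
common_pathways <- function(a, b) {
  ids <- intersect(a$pathway_id, b$pathway_id)
  list(
    a = dplyr::arrange(
      dplyr::filter(a, .data$pathway_id %in% ids),
      match(.data$pathway_id, ids)
    ),
    b = dplyr::arrange(
      dplyr::filter(b, .data$pathway_id %in% ids),
      match(.data$pathway_id, ids)
    )
  )
}

#' Convert a pathway collection to a named list of gene vectors
#'
#' @param coll A pathway collection tibble.
#' @return Named list mapping `pathway_id` to character vectors of genes.
#' @export
as_pathway_list <- function(coll) {
  stats::setNames(coll$genes, coll$pathway_id)
}
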