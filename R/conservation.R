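#' One-sided (upper-tail) hypergeometric overlap p-value
#'
#' Probability of observing at least `k` common elements between a set of
#' size `K_a` and a set of size `K_b` drawn from a universe of size `N`:
#' `P[X >= k]` with `X ~ Hypergeometric(N, K_a, K_b)`. The over-
#' representation test used throughout module matching and class enrichment.
#'
#' @param k Observed overlap.
#' @param K_a,K_b Set sizes.
#' @param N Universe size.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeom_p <- function(k, K_a, K_b, N) {
  if (any(K_a < 0 | K_a > N) || any(K_b < 0 | K_b > N)) {
    abort("Set sizes must lie in [0, N]")
  }
  if (any(k < 0 | k > pmin(K_a, K_b))) {
    abort("Overlap k must lie in [0, min(K_a, K_b)]")
  }
  phyper(k - 1, K_a, N - K_a, K_b, lower.tail = FALSE)
}

module_pathways <- function(m) m$row_ids
module_chemicals <- function(m) m$col_ids
module_ids_of <- function(ms) vapply(ms, `[[`, character(1), "module_id")

# All pairwise pathway-overlap tests between two module sets.
pairwise_overlap <- function(a, b, N) {
  tidyr::expand_grid(ia = seq_along(a), ib = seq_along(b)) |>
    dplyr::mutate(
      module_a = module_ids_of(a)[.data$ia],
      module_b = module_ids_of(b)[.data$ib],
      K_a = vapply(a, function(m) length(module_pathways(m)), integer(1))[.data$ia],
      K_b = vapply(b, function(m) length(module_pathways(m)), integer(1))[.data$ib],
      k = purrr::map2_int(
        .data$ia, .data$ib,
        function(i, j) length(intersect(module_pathways(a[[i]]),
                                        module_pathways(b[[j]])))
      ),
      N = N,
      p = hypergeom_p(.data$k, .data$K_a, .data$K_b, N)
    )
}

# Best hit per module_a: minimal p, ties by larger k, then smaller module_b.
best_hits <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$module_a) |>
    dplyr::arrange(.data$p, dplyr::desc(.data$k), .data$module_b,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Reciprocal best-hit module matching between two datasets
#'
#' Two modules are conserved when their pathway supports overlap
#' significantly (one-sided hypergeometric on the common pathway universe)
#' and each is the other's most significant partner. Ties on p are broken
#' toward larger overlap, then smaller module id. Chemical overlap is
#' reported for context but does not enter the criterion — conserved
#' modules need not share chemicals.
#'
#' @param a,b `module_set`s whose pathway supports are drawn from the same
#'   universe.
#' @param N Size of the common pathway universe.
#' @param alpha Significance threshold on the match p-value.
#' @return Tibble of matches: `module_a`, `module_b`, `k`, `K_a`, `K_b`,
#'   `N`, `p`, `k_chemicals`, `reciprocal` (always TRUE for reported rows).
#' @export
reciprocal_best_hits <- function(a, b, N, alpha = 0.001) {
  empty <- tibble::tibble(
    module_a = character(), module_b = character(),
    k = integer(), K_a = integer(), K_b = integer(), N = integer(),
    p = numeric(), k_chemicals = integer(), reciprocal = logical()
  )
  if (length(a) == 0L || length(b) == 0L) return(empty)
  pairs <- pairwise_overlap(a, b, N)
  fwd <- best_hits(pairs)
  rev <- best_hits(
    dplyr::rename(pairs, module_a = "module_b", module_b = "module_a",
                  K_a = "K_b", K_b = "K_a") |>
      dplyr::mutate(ia = .data$ib)
  )
  mutual <- dplyr::inner_join(
    dplyr::select(fwd, "module_a", "module_b", "k", "K_a", "K_b", "N", "p"),
    dplyr::select(rev, module_b = "module_a", module_a = "module_b"),
    by = c("module_a", "module_b")
  )
  out <- dplyr::filter(mutual, .data$p < alpha)
  if (nrow(out) == 0L) return(empty)
  ia <- match(out$module_a, module_ids_of(a))
  ib <- match(out$module_b, module_ids_of(b))
  out$k_chemicals <- purrr::map2_int(ia, ib, function(i, j) {
    length(intersect(module_chemicals(a[[i]]), module_chemicals(b[[j]])))
  })
  out$reciprocal <- TRUE
  out
}

#' Modules conserved across all three experimental settings
#'
#' Anchored on the in vivo reference: a conserved triple is an RLV module
#' whose reciprocal best hits exist in both PRH and PHH at the given alpha.
#' The shared pathway core is the three-way intersection of supports.
#'
#' @param rlv,prh,phh `module_set`s over the same pathway universe.
#' @param N Common pathway universe size.
#' @param alpha Match significance threshold.
#' @return Tibble with `module_rlv`, `module_prh`, `module_phh`, the two
#'   pairwise p-values, and `core_pathways` (list-column).
#' @export
conserved_across_three <- function(rlv, prh, phh, N, alpha = 0.001) {
  m_prh <- reciprocal_best_hits(rlv, prh, N, alpha)
  m_phh <- reciprocal_best_hits(rlv, phh, N, alpha)
  triples <- dplyr::inner_join(
    dplyr::select(m_prh, module_rlv = "module_a", module_prh = "module_b",
                  p_rlv_prh = "p"),
    dplyr::select(m_phh, module_rlv = "module_a", module_phh = "module_b",
                  p_rlv_phh = "p"),
    by = "module_rlv"
  )
  if (nrow(triples) == 0L) {
    triples$core_pathways <- list()
    return(triples)
  }
  triples$core_pathways <- purrr::pmap(
    list(triples$module_rlv, triples$module_prh, triples$module_phh),
    function(mr, mp, mh) {
      Reduce(intersect, list(
        module_pathways(rlv[[match(mr, module_ids_of(rlv))]]),
        module_pathways(prh[[match(mp, module_ids_of(prh))]]),
        module_pathways(phh[[match(mh, module_ids_of(phh))]])
      ))
    }
  )
  triples
}

#' Chemical-class over-representation in a module
#'
#' Tests whether a labelled class of chemicals (e.g. validated
#' hepatocarcinogens) is over-represented among a module's chemical support,
#' by the upper-tail hypergeometric test on the chemical universe.
#'
#' @param module A `bicluster`.
#' @param class_chemicals Chemicals in the class (subset of the universe).
#' @param universe_chemicals All chemicals of the dataset.
#' @param alpha Significance threshold.
#' @return One-row tibble with `k`, `n_module`, `n_class`, `N`, `p`,
#'   `significant`.
#' @export
chemical_class_enrichment <- function(module, class_chemicals,
                                      universe_chemicals, alpha = 0.05) {
  if (length(universe_chemicals) == 0L) abort("Empty chemical universe")
  mod_chems <- module_chemicals(module)
  if (!all(mod_chems %in% universe_chemicals)) {
    abort("Module chemicals not all in the universe")
  }
  if (!all(class_chemicals %in% universe_chemicals)) {
    abort("Class chemicals not all in the universe")
  }
  k <- length(intersect(mod_chems, class_chemicals))
  p <- hypergeom_p(k, length(class_chemicals), length(mod_chems),
                   length(universe_chemicals))
  tibble::tibble(
    k = k, n_module = length(mod_chems), n_class = length(class_chemicals),
    N = length(universe_chemicals), p = p, significant = p < alpha
  )
}

#' Union of leading-edge genes over a module
#'
#' Collects the genes driving the enrichment of every (pathway, chemical)
#' cell of a module — the union of leading edges across all module pathways
#' under all module chemicals.
#'
#' @param module A `bicluster`.
#' @param results Tibble of enrichment results with columns `pathway_id`,
#'   `chemical_id` and `leading_edge` (list-column), covering every module
#'   cell.
#' @return Character vector of gene ids (sorted, unique).
#' @export
leading_edge_union <- function(module, results) {
  pws <- module_pathways(module)
  chems <- module_chemicals(module)
  if (length(pws) == 0L || length(chems) == 0L) {
    abort("Module has an empty pathway or chemical support")
  }
  cells <- tidyr::expand_grid(pathway_id = pws, chemical_id = chems)
  hit <- dplyr::left_join(
    cells,
    dplyr::select(results, "pathway_id", "chemical_id", "leading_edge"),
    by = c("pathway_id", "chemical_id")
  )
  missing <- purrr::map_lgl(hit$leading_edge, is.null)
  if (any(missing)) {
    abort(paste0(
      "Missing enrichment result for cell(s): ",
      paste(utils::head(
        paste0(hit$pathway_id[missing], "/", hit$chemical_id[missing]), 5
      ), collapse = ", ")
    ))
  }
  sort(unique(unlist(hit$leading_edge)))
}

#' Significance of the overlap between two gene lists
#'
#' Upper-tail hypergeometric test of the overlap of two gene sets within a
#' common universe (e.g. module leading-edge genes against an external
#' stereotypical-response list).
#'
#' @param list_a,list_b Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector of all genes considered.
#' @return One-row tibble with `k` and `p`.
#' @export
gene_list_overlap <- function(list_a, list_b, universe) {
  list_a <- unique(list_a)
  list_b <- unique(list_b)
  universe <- unique(universe)
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    abort("Both gene lists must be subsets of the universe")
  }
  k <- length(intersect(list_a, list_b))
  tibble::tibble(
    k = k,
    p = hypergeom_p(k, length(list_a), length(list_b), length(universe))
  )
}
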