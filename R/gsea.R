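#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: meeting a gene-set member
#' ("hit") adds `|score|^weight / sum_hits |score|^weight`, meeting a
#' non-member subtracts `1 / (N - n_hits)`. The enrichment score (ES) is the
#' running-sum value of maximal absolute deviation (earliest position on
#' ties), signed; the sum always returns to 0 at the end of the list. The
#' leading edge is the set members at or before the peak (at or after the
#' trough for negative ES) — the genes that drive the enrichment.
#'
#' If every hit score is exactly zero the weights degenerate; hits then
#' count equally (unweighted statistic) so the walk remains defined.
#'
#' @param ranked Ranked tibble (`gene_id`, `score`) from [rank_genes()],
#'   best-to-worst.
#' @param gene_set Character vector of member gene ids.
#' @param weight Exponent on `|score|` for hit increments; 1 is the
#'   conventional weighted statistic.
#' @return List with `es`, `running_sum` (length-N numeric), `peak`
#'   (1-based rank of the extremum) and `leading_edge` (character vector).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  k <- sum(hit)
  if (k == 0L) abort("Gene set has no overlap with the ranked universe")
  if (k == N) abort("Gene set covers the entire ranked universe")
  w <- abs(ranked$score)^weight
  w[!hit] <- 0
  total <- sum(w)
  if (total == 0) {
    w[hit] <- 1
    total <- k
  }
  steps <- ifelse(hit, w / total, -1 / (N - k))
  running <- cumsum(steps)
  # earliest position achieving the maximal |deviation|; the 1e-9 slack
  # keeps exact rational ties (which do occur structurally) from being
  # resolved by floating-point accumulation order
  peak <- which(abs(running) >= max(abs(running)) - 1e-9)[1]
  es <- running[peak]
  leading <- if (es > 0) {
    ranked$gene_id[hit & seq_len(N) <= peak]
  } else if (es < 0) {
    ranked$gene_id[hit & seq_len(N) >= peak]
  } else {
    character()
  }
  list(es = es, running_sum = running, peak = peak, leading_edge = leading)
}

# ES for many size-matched random sets at once, from hit positions only.
# For sorted hit ranks r_1 < ... < r_k with normalized weights H_i
# (cumulative hit mass), the running sum attains candidate extrema only at
# hit positions (H_i - (r_i - i) * m) and just before them
# (H_{i-1} - (r_i - i) * m), m = 1/(N - k); interleaving these candidates is
# position-sorted, so max.col(..., "first") reproduces the earliest-peak
# tie rule of the full walk.
es_batch <- function(rank_mat, abs_scores, weight = 1) {
  N <- length(abs_scores)
  k <- ncol(rank_mat)
  n <- nrow(rank_mat)
  m <- 1 / (N - k)
  a <- abs_scores^weight
  wmat <- matrix(a[rank_mat], n, k)
  W <- rowSums(wmat)
  deg <- W == 0
  if (any(deg)) {
    wmat[deg, ] <- 1
    W[deg] <- k
  }
  H <- wmat
  if (k > 1) for (j in 2:k) H[, j] <- H[, j - 1] + H[, j]
  H <- H / W
  drop_mat <- (rank_mat - rep(seq_len(k), each = n)) * m
  up <- H - drop_mat
  dn <- cbind(0, H[, -k, drop = FALSE]) - drop_mat
  dn[rank_mat == 1L] <- 0  # position 0 does not exist
  cand <- matrix(0, n, 2L * k)
  cand[, seq(1L, 2L * k, by = 2L)] <- dn
  cand[, seq(2L, 2L * k, by = 2L)] <- up
  ca <- abs(cand)
  rm_ <- ca[cbind(seq_len(n), max.col(ca, ties.method = "first"))]
  j <- max.col(ca >= rm_ - 1e-9, ties.method = "first")
  cand[cbind(seq_len(n), j)]
}

#' Gene-permutation null distribution of the enrichment score
#'
#' The preranked null: ES values of `n_perm` gene sets of the given size
#' drawn uniformly (without replacement) from the ranked universe. This is
#' the only permutation scheme coherent with an externally ranked list.
#'
#' @param ranked Ranked tibble (`gene_id`, `score`).
#' @param set_size Size of the random sets, in `[1, N)`.
#' @param n_perm Number of permutations.
#' @param rng_seed Integer seed; the sample is reproducible.
#' @param weight Hit-weight exponent, as in [enrichment_score()].
#' @return Numeric vector of `n_perm` null ES values.
#' @export
null_distribution <- function(ranked, set_size, n_perm, rng_seed, weight = 1) {
  N <- nrow(ranked)
  if (set_size < 1L || set_size >= N) {
    abort(paste0("set_size must be in [1, ", N - 1, "], got ", set_size))
  }
  stopifnot(n_perm >= 1)
  abs_scores <- abs(ranked$score)
  rank_mat <- withr::with_seed(rng_seed, {
    t(vapply(seq_len(n_perm),
             function(i) sort(sample.int(N, set_size)),
             integer(set_size)))
  })
  if (set_size == 1L) rank_mat <- matrix(rank_mat, ncol = 1L)
  es_batch(rank_mat, abs_scores, weight)
}

#' Normalized enrichment score and nominal p-value
#'
#' NES rescales the ES by the mean absolute null ES of the same sign, making
#' scores comparable across gene-set sizes; the nominal p is the same-sign
#' null exceedance fraction with add-one smoothing so p is never 0. An ES of
#' exactly 0 maps to NES 0 and p 1. When no same-sign null values exist the
#' result is flagged as masked rather than raising an error.
#'
#' @param es Observed enrichment score.
#' @param null_sample Numeric vector of null ES values.
#' @return List with `nes`, `p_nominal` and `masked`.
#' @export
normalize_and_p <- function(es, null_sample) {
  stopifnot(length(null_sample) > 0)
  if (es == 0) {
    return(list(nes = 0, p_nominal = 1, masked = FALSE))
  }
  same <- null_sample[sign(null_sample) == sign(es)]
  if (length(same) == 0L || mean(abs(same)) == 0) {
    return(list(nes = NA_real_, p_nominal = NA_real_, masked = TRUE))
  }
  nes <- es / mean(abs(same))
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(nes = nes, p_nominal = p, masked = FALSE)
}

#' Preranked GSEA of a pathway collection against one ranked list
#'
#' Scores every pathway with at least `min_overlap` genes in the ranked
#' universe; smaller overlaps are reported masked (NA scores), not dropped,
#' so the pathway space stays aligned across chemicals. Null distributions
#' are shared across pathways of equal overlap size and seeded per size, so
#' results do not depend on pathway order.
#'
#' @param ranked Ranked tibble (`gene_id`, `score`).
#' @param coll Pathway collection tibble (already size-filtered).
#' @param n_perm Permutations per null distribution.
#' @param rng_seed Integer seed.
#' @param weight Hit-weight exponent.
#' @param min_overlap Minimum genes in the universe for a pathway to be
#'   scored.
#' @return Tibble with one row per pathway: `pathway_id`, `n_overlap`, `es`,
#'   `nes`, `p_nominal`, `leading_edge` (list-column), `masked`.
#' @export
run_gsea <- function(ranked, coll, n_perm = 1000, rng_seed = 1L,
                     weight = 1, min_overlap = 15) {
  if (nrow(coll) == 0L) abort("Empty pathway collection")
  universe <- ranked$gene_id
  N <- length(universe)
  overlaps <- lapply(coll$genes, function(g) intersect(g, universe))
  n_overlap <- lengths(overlaps)
  scoreable <- n_overlap >= min_overlap & n_overlap < N
  nulls <- list()
  for (k in sort(unique(n_overlap[scoreable]))) {
    nulls[[as.character(k)]] <- null_distribution(
      ranked, k, n_perm, derive_seed(rng_seed, paste0("null-", k)), weight
    )
  }
  rows <- purrr::map(seq_len(nrow(coll)), function(i) {
    if (!scoreable[i]) {
      return(tibble::tibble(
        pathway_id = coll$pathway_id[i], n_overlap = n_overlap[i],
        es = NA_real_, nes = NA_real_, p_nominal = NA_real_,
        leading_edge = list(character()), masked = TRUE
      ))
    }
    sc <- enrichment_score(ranked, overlaps[[i]], weight)
    np <- normalize_and_p(sc$es, nulls[[as.character(n_overlap[i])]])
    tibble::tibble(
      pathway_id = coll$pathway_id[i], n_overlap = n_overlap[i],
      es = sc$es, nes = np$nes, p_nominal = np$p_nominal,
      leading_edge = list(sc$leading_edge), masked = np$masked
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble a pathway x chemical enrichment matrix
#'
#' Stacks per-chemical GSEA results into the NES matrix consumed by
#' biclustering. Masked cells are imputed as 0 ("no enrichment") so the
#' matrix is complete; the mask is retained alongside.
#'
#' @param results Named list of per-chemical tibbles from [run_gsea()]
#'   (names are chemical ids), all scored against the same collection.
#' @return An `enrichment_matrix`: list with numeric matrix `nes`
#'   (pathways x chemicals, column order = input order) and logical `mask`.
#' @export
build_enrichment_matrix <- function(results) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  ids <- results[[1]]$pathway_id
  for (r in results) {
    if (!identical(r$pathway_id, ids)) {
      abort("Inconsistent pathway universes across chemicals")
    }
  }
  nes <- vapply(results, function(r) {
    v <- r$nes
    v[is.na(v)] <- 0
    v
  }, numeric(length(ids)))
  mask <- vapply(results, function(r) r$masked | is.na(r$nes),
                 logical(length(ids)))
  nes <- matrix(nes, nrow = length(ids),
                dimnames = list(ids, names(results)))
  mask <- matrix(mask, nrow = length(ids),
                 dimnames = list(ids, names(results)))
  structure(list(nes = nes, mask = mask), class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("Enrichment matrix:", nrow(x$nes), "pathways x", ncol(x$nes),
      "chemicals;", sum(x$mask), "masked cells\n")
  invisible(x)
}

#' Tidy an enrichment matrix into long form
#'
#' @param x An `enrichment_matrix`.
#' @param ... Unused.
#' @return Tibble with `pathway_id`, `chemical_id`, `nes`, `masked`.
#' @method tidy enrichment_matrix
#' @export
tidy.enrichment_matrix <- function(x, ...) {
  tibble::as_tibble(x$nes, rownames = "pathway_id") |>
    tidyr::pivot_longer(-"pathway_id", names_to = "chemical_id",
                        values_to = "nes") |>
    dplyr::mutate(masked = as.vector(t(x$mask)))
}

#' Heatmap-style plot of an enrichment matrix
#'
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tile plot of NES, masked cells blank).
#' @method autoplot enrichment_matrix
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  df <- tidy.enrichment_matrix(object)
  df$nes[df$masked] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$chemical_id, y = .data$pathway_id, fill = .data$nes
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "seagreen", mid = "white",
                                  high = "steelblue", na.value = "grey85") +
    ggplot2::labs(x = "chemical", y = "pathway", fill = "NES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write an enrichment matrix (and mask) to TSV
#'
#' @param em An `enrichment_matrix`.
#' @param path Output path for the NES matrix; the mask goes to
#'   `<path>.mask.tsv`.
#' @export
write_enrichment_matrix <- function(em, path) {
  readr::write_tsv(tibble::as_tibble(em$nes, rownames = "pathway_id"),
                   path, progress = FALSE)
  readr::write_tsv(
    tibble::as_tibble(em$mask, rownames = "pathway_id"),
    paste0(path, ".mask.tsv"), progress = FALSE
  )
  invisible(path)
}
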