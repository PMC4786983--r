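#' Row- and column-standardized copies of an enrichment matrix
#'
#' ISA preprocessing: `E_r` has each row scaled to mean 0, sd 1 and `E_c`
#' each column likewise (sample sd). Rows/columns with zero variance are
#' left all-zero and recorded in the `degenerate_rows` / `degenerate_cols`
#' attributes so they can never drive a module.
#'
#' @param E An `enrichment_matrix` or a plain numeric matrix.
#' @return List with matrices `E_r` and `E_c` (same shape as the input).
#' @export
standardize <- function(E) {
  m <- if (inherits(E, "enrichment_matrix")) E$nes else E
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  scale_rows <- function(x) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    out <- (x - mu) / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
    list(mat = out, degenerate = which(s == 0))
  }
  r <- scale_rows(m)
  c_ <- scale_rows(t(m))
  out <- list(E_r = r$mat, E_c = t(c_$mat))
  attr(out, "degenerate_rows") <- r$degenerate
  attr(out, "degenerate_cols") <- c_$degenerate
  out
}

# Signed two-directional threshold: keep entries whose absolute value
# exceeds mean(|x|) + thr * sd(|x|) (computed over the full vector), zero
# the rest, retain sign. Modules may therefore mix up- and down-regulated
# pathways.
threshold_scores <- function(x, thr) {
  a <- abs(x)
  cut <- mean(a) + thr * sd(a)
  x[!(a > cut)] <- 0
  x
}

safe_cor <- function(a, b) {
  if (identical(a, b)) return(1)
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' One ISA run from a seed vector
#'
#' Alternates thresholded projections until a self-consistent signature is
#' reached: row scores are the column-standardized matrix times the column
#' scores, thresholded at `mean + thr_row * sd` of the absolute scores (sign
#' retained); column scores are the transposed row-standardized matrix times
#' the row scores, thresholded with `thr_col`. Convergence requires Pearson
#' correlation of successive score vectors of at least `tol` in both
#' dimensions and exactly stable supports; runs whose support empties or
#' that fail to converge within `max_iter` return `NULL`.
#'
#' @param pair Standardized pair from [standardize()].
#' @param seed_cols Numeric column score vector (nonzero) that starts the
#'   iteration.
#' @param thr_row,thr_col Threshold stringencies in SD units.
#' @param max_iter Iteration cap.
#' @param tol Convergence correlation.
#' @param seed_index Provenance index stored on the result.
#' @return A `bicluster` (list with `row_scores`, `col_scores`, `row_ids`,
#'   `col_ids`, thresholds, `n_iterations`, `robustness`) or `NULL`.
#' @export
isa_iterate <- function(pair, seed_cols, thr_row, thr_col,
                        max_iter = 100, tol = 0.99, seed_index = NA_integer_) {
  E_r <- pair$E_r
  E_c <- pair$E_c
  if (length(seed_cols) != ncol(E_c)) abort("seed_cols length != ncol(E)")
  if (all(seed_cols == 0)) abort("seed_cols must be nonzero")
  col_scores <- seed_cols / max(abs(seed_cols))
  row_scores <- rep(0, nrow(E_r))
  prev_rows <- NULL
  prev_cols <- NULL
  for (iter in seq_len(max_iter)) {
    new_rows <- threshold_scores(drop(E_c %*% col_scores), thr_row)
    if (all(new_rows == 0)) return(NULL)
    new_rows <- new_rows / max(abs(new_rows))
    new_cols <- threshold_scores(drop(crossprod(E_r, new_rows)), thr_col)
    if (all(new_cols == 0)) return(NULL)
    new_cols <- new_cols / max(abs(new_cols))
    if (!is.null(prev_rows)) {
      supports_stable <-
        identical(prev_rows != 0, new_rows != 0) &&
        identical(prev_cols != 0, new_cols != 0)
      if (supports_stable &&
          safe_cor(prev_rows, new_rows) >= tol &&
          safe_cor(prev_cols, new_cols) >= tol) {
        robustness <- sqrt(abs(
          (new_rows / sqrt(sum(new_rows^2))) %*%
            E_c %*% (new_cols / sqrt(sum(new_cols^2)))
        ))
        return(structure(
          list(
            row_scores = new_rows, col_scores = new_cols,
            row_ids = rownames(E_r)[new_rows != 0] %||%
              as.character(which(new_rows != 0)),
            col_ids = colnames(E_r)[new_cols != 0] %||%
              as.character(which(new_cols != 0)),
            thr_row = thr_row, thr_col = thr_col,
            seed_index = seed_index, n_iterations = iter,
            robustness = as.numeric(robustness)
          ),
          class = "bicluster"
        ))
      }
    }
    prev_rows <- new_rows
    prev_cols <- new_cols
    col_scores <- new_cols
  }
  NULL
}

#' @export
print.bicluster <- function(x, ...) {
  cat("Bicluster:", length(x$row_ids), "pathways x", length(x$col_ids),
      "chemicals (thr", x$thr_row, "/", x$thr_col,
      ", robustness", round(x$robustness, 2), ")\n")
  invisible(x)
}

sweep_core <- function(pair, thr_row_grid, thr_col_grid, seeds,
                       max_iter, tol) {
  out <- list()
  for (tr in thr_row_grid) {
    for (tc in thr_col_grid) {
      for (i in seq_along(seeds)) {
        bc <- isa_iterate(pair, seeds[[i]], tr, tc,
                          max_iter = max_iter, tol = tol, seed_index = i)
        if (!is.null(bc)) out[[length(out) + 1L]] <- bc
      }
    }
  }
  out
}

#' Threshold-sweep ISA with permutation robustness filtering
#'
#' Runs [isa_iterate()] for every combination of row threshold, column
#' threshold and random sparse seed (binary column vectors with
#' `seed_nnz` nonzero entries), collecting all converged biclusters with
#' their provenance. By default the same sweep is repeated on a
#' within-column permuted copy of the matrix, which destroys any real
#' pathway-chemical structure while preserving the value distribution;
#' biclusters whose robustness does not exceed `perm_margin` times the best
#' robustness seen on the permuted matrix (at the same threshold pair) are
#' discarded as chance signatures. Deterministic under `rng_seed`.
#'
#' @param E An `enrichment_matrix` or numeric matrix.
#' @param thr_row_grid,thr_col_grid Numeric threshold grids.
#' @param n_seeds Random seeds per threshold combination.
#' @param rng_seed Integer seed.
#' @param seed_nnz Nonzero entries per seed vector.
#' @param max_iter,tol Passed to [isa_iterate()].
#' @param perm_filter Apply the permuted-matrix robustness filter.
#' @param perm_margin Safety factor on the permuted-sweep robustness bar.
#' @return List of `bicluster` objects (possibly empty).
#' @export
isa_sweep <- function(E, thr_row_grid = c(1.5, 2, 2.5, 3),
                      thr_col_grid = c(1.5, 2, 2.5, 3),
                      n_seeds = 100, rng_seed = 1L, seed_nnz = 2L,
                      max_iter = 100, tol = 0.99,
                      perm_filter = TRUE, perm_margin = 1.1) {
  stopifnot(length(thr_row_grid) > 0, length(thr_col_grid) > 0, n_seeds >= 1)
  m <- if (inherits(E, "enrichment_matrix")) E$nes else E
  pair <- standardize(m)
  n_cols <- ncol(pair$E_c)
  seeds <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_seeds), function(i) {
      v <- rep(0, n_cols)
      v[sample.int(n_cols, min(seed_nnz, n_cols))] <- 1
      v
    })
  })
  out <- sweep_core(pair, thr_row_grid, thr_col_grid, seeds, max_iter, tol)
  if (!perm_filter || length(out) == 0L) return(out)

  perm <- withr::with_seed(
    derive_seed(rng_seed, "perm-filter"),
    apply(m, 2, sample)
  )
  dimnames(perm) <- dimnames(m)
  perm_out <- sweep_core(standardize(perm), thr_row_grid, thr_col_grid,
                         seeds, max_iter, tol)
  if (length(perm_out) == 0L) return(out)
  perm_tab <- tibble::tibble(
    thr_row = vapply(perm_out, `[[`, numeric(1), "thr_row"),
    thr_col = vapply(perm_out, `[[`, numeric(1), "thr_col"),
    robustness = vapply(perm_out, `[[`, numeric(1), "robustness")
  )
  global_bar <- max(perm_tab$robustness)
  bar_for <- function(tr, tc) {
    hit <- perm_tab$robustness[perm_tab$thr_row == tr & perm_tab$thr_col == tc]
    if (length(hit) == 0L) global_bar else max(hit)
  }
  keep <- vapply(out, function(bc) {
    bc$robustness > perm_margin * bar_for(bc$thr_row, bc$thr_col)
  }, logical(1))
  out[keep]
}

#' Deduplicate biclusters into a nonredundant module set
#'
#' Greedy filter in decreasing robustness order: a bicluster is kept only if
#' its correlation with every already-kept module stays below `cor_limit`,
#' where the correlation between two biclusters is the larger of the
#' absolute Pearson correlations of their full-length row-score and
#' col-score vectors.
#'
#' @param raw List of `bicluster` objects.
#' @param cor_limit Redundancy correlation limit (0.5 mirrors the published
#'   analysis).
#' @return A `module_set`: list of kept biclusters, each given a
#'   `module_id` (`mod1`, `mod2`, ... in kept order).
#' @export
deduplicate_modules <- function(raw, cor_limit = 0.5) {
  if (length(raw) == 0L) {
    return(structure(list(), class = "module_set", cor_limit = cor_limit))
  }
  ord <- order(vapply(raw, `[[`, numeric(1), "robustness"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    cand <- raw[[i]]
    redundant <- any(vapply(kept, function(k) {
      max(abs(safe_cor(k$row_scores, cand$row_scores)),
          abs(safe_cor(k$col_scores, cand$col_scores))) >= cor_limit
    }, logical(1)))
    if (!redundant) kept[[length(kept) + 1L]] <- cand
  }
  for (i in seq_along(kept)) kept[[i]]$module_id <- paste0("mod", i)
  structure(kept, class = "module_set", cor_limit = cor_limit)
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", length(x), "nonredundant modules\n")
  for (m in x) {
    cat(" ", m$module_id, ":", length(m$row_ids), "pathways x",
        length(m$col_ids), "chemicals\n")
  }
  invisible(x)
}

#' Tidy a module set into long membership form
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Tibble with `module_id`, `dimension` ("pathway"/"chemical"),
#'   `id` and `score`.
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  purrr::map_dfr(x, function(m) {
    dplyr::bind_rows(
      tibble::tibble(
        module_id = m$module_id, dimension = "pathway",
        id = m$row_ids, score = m$row_scores[m$row_scores != 0]
      ),
      tibble::tibble(
        module_id = m$module_id, dimension = "chemical",
        id = m$col_ids, score = m$col_scores[m$col_scores != 0]
      )
    )
  })
}

#' One-row-per-module summary of a module set
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Tibble with sizes, thresholds and robustness per module.
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  purrr::map_dfr(x, function(m) {
    tibble::tibble(
      module_id = m$module_id,
      n_pathways = length(m$row_ids),
      n_chemicals = length(m$col_ids),
      thr_row = m$thr_row, thr_col = m$thr_col,
      n_iterations = m$n_iterations,
      robustness = m$robustness
    )
  })
}

#' Module-size overview plot
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot object: pathway vs chemical support sizes per module.
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  df <- glance.module_set(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_chemicals, y = .data$n_pathways, label = .data$module_id
  )) +
    ggplot2::geom_point(ggplot2::aes(size = .data$robustness),
                        colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(x = "chemicals in module", y = "pathways in module",
                  size = "robustness") +
    ggplot2::theme_minimal()
}

#' Write / read a module set as JSON
#'
#' @param modules A `module_set`.
#' @param path File path.
#' @return For `read_modules`, a `module_set`.
#' @export
write_modules <- function(modules, path) {
  payload <- lapply(unclass(modules), function(m) {
    list(
      module_id = m$module_id,
      pathways = as.list(stats::setNames(
        m$row_scores[m$row_scores != 0], m$row_ids
      )),
      chemicals = as.list(stats::setNames(
        m$col_scores[m$col_scores != 0], m$col_ids
      )),
      thr_row = m$thr_row, thr_col = m$thr_col,
      seed_index = m$seed_index, n_iterations = m$n_iterations,
      robustness = m$robustness
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  kept <- lapply(payload, function(m) {
    structure(
      list(
        module_id = m$module_id,
        row_scores = unlist(m$pathways),
        col_scores = unlist(m$chemicals),
        row_ids = names(unlist(m$pathways)),
        col_ids = names(unlist(m$chemicals)),
        thr_row = m$thr_row, thr_col = m$thr_col,
        seed_index = m$seed_index, n_iterations = m$n_iterations,
        robustness = m$robustness
      ),
      class = "bicluster"
    )
  })
  structure(kept, class = "module_set")
}
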