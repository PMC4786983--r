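#' Fit the dose-time linear model for one gene and one chemical
#'
#' Ordinary least squares for
#' `expr = beta0 + beta1 * dose + beta2 * time + beta3 * dose * time + e`,
#' where dose is the ordinal coding 0 (control) to 3 (high) and time is in
#' hours. The dose coefficient `beta1` carries the gene-chemical
#' association; its two-sided p-value comes from the Student t distribution
#' with `n - 4` degrees of freedom. Control rows enter with dose 0 — without
#' them `beta1` is unidentified from a single dose series.
#'
#' @param data Tibble with columns `dose_value`, `time_hr` and `expr`
#'   (one row per sample of one chemical, controls included).
#' @param gene_id,chemical_id Identifiers copied into the result.
#' @return One-row tibble with `gene_id`, `chemical_id`, `beta0`..`beta3`,
#'   `se_beta1`, `t_beta1`, `p_beta1` and the ranking `score`.
#' @export
fit_dose_time_model <- function(data, gene_id = NA_character_,
                                chemical_id = NA_character_) {
  stopifnot(all(c("dose_value", "time_hr", "expr") %in% names(data)))
  res <- fit_dose_time_matrix(
    matrix(data$expr, nrow = 1,
           dimnames = list(gene_id %||% "gene", NULL)),
    data$dose_value, data$time_hr
  )
  res$gene_id <- as.character(gene_id)
  res$chemical_id <- as.character(chemical_id)
  dplyr::relocate(res, "gene_id", "chemical_id")
}

# Vectorized OLS of many genes against one design: QR of the fixed design
# matrix is computed once, coefficients and residual variances for all genes
# follow from matrix products.
fit_dose_time_matrix <- function(expr, dose, time_hr) {
  n <- ncol(expr)
  if (n <= 4L) {
    abort(paste0("Need more than 4 samples to fit the dose-time model, got ", n))
  }
  X <- cbind(`(Intercept)` = 1, dose = dose, time = time_hr,
             `dose:time` = dose * time_hr)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0(
      "Rank-deficient dose-time design; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  coefs <- t(qr.coef(qr_x, t(expr)))  # genes x 4
  fitted <- coefs %*% t(X)
  rss <- rowSums((expr - fitted)^2)
  df <- n - 4L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se1 <- sqrt(sigma2 * xtx_inv[2, 2])
  beta1 <- coefs[, 2]
  # zero-residual fits up to numerical noise: the t test is undefined there,
  # so an exactly-reproduced effect gets the p floor and a flat profile the
  # null convention (beta1 = 0, p = 1, score 0)
  scale <- 1 + rowMeans(expr^2)
  degenerate <- rss <= 1e-16 * scale * n
  beta1[degenerate & abs(beta1) <= 1e-8 * sqrt(scale)] <- 0
  t1 <- ifelse(se1 > 0 & !degenerate, beta1 / se1,
               ifelse(beta1 == 0, 0, Inf * sign(beta1)))
  p1 <- ifelse(is.finite(t1), 2 * pt(abs(t1), df, lower.tail = FALSE), 0)
  p1[t1 == 0 & degenerate] <- 1
  p1 <- pmax(p1, 1e-300)
  res <- tibble::tibble(
    gene_id = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    beta0 = unname(coefs[, 1]), beta1 = unname(beta1),
    beta2 = unname(coefs[, 3]), beta3 = unname(coefs[, 4]),
    se_beta1 = unname(se1), t_beta1 = unname(t1), p_beta1 = unname(p1)
  )
  res$score <- ranking_score(res$beta1, res$p_beta1)
  res
}

#' Signed significance ranking score
#'
#' `sign(beta1) * -log10(p)`, with the p-value floored at `p_floor` so that
#' numerically-zero p-values yield large finite scores.
#'
#' @param beta1 Dose coefficient estimate(s).
#' @param p Two-sided p-value(s) in (0, 1].
#' @param p_floor Lower bound applied to `p` before the log.
#' @return Numeric score(s); 0 when `p = 1` or `beta1 = 0`.
#' @export
ranking_score <- function(beta1, p, p_floor = 1e-300) {
  sign(beta1) * (-log10(pmax(p, p_floor)))
}

#' Per-chemical gene-association table
#'
#' Fits the dose-time model for every gene of an expression matrix against
#' one chemical's samples (its treated rows plus its vehicle controls).
#'
#' @param design Design tibble for one setting.
#' @param expr Gene x sample expression matrix matching `design`.
#' @param chemical Chemical identifier present in `design`.
#' @return Tibble with one row per gene (columns as in
#'   [fit_dose_time_model()]).
#' @export
associate_genes <- function(design, expr, chemical) {
  rows <- design$chemical == chemical
  if (!any(rows)) abort(paste0("Chemical not in design: ", chemical))
  sub <- design[rows, ]
  res <- fit_dose_time_matrix(
    expr[, sub$sample_id, drop = FALSE],
    sub$dose_value, sub$time_hr
  )
  res$chemical_id <- chemical
  dplyr::relocate(res, "gene_id", "chemical_id")
}

#' Rank genes by signed association significance
#'
#' Produces the chemical-specific ranked gene list consumed by preranked
#' GSEA: sorted by `score` descending, ties broken by `gene_id` ascending so
#' the ranking is deterministic.
#'
#' @param results Association tibble for one chemical (one row per gene).
#' @return Tibble with columns `gene_id` and `score`, ranked.
#' @export
rank_genes <- function(results) {
  if (anyDuplicated(results$gene_id)) {
    abort("Duplicate gene_id in association results")
  }
  results |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene_id) |>
    dplyr::select("gene_id", "score")
}

#' Write a ranked list in .rnk format
#'
#' Two tab-separated columns (gene id, score), no header — the conventional
#' preranked-GSEA input format.
#'
#' @param ranked Ranked tibble from [rank_genes()].
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(ranked, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
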