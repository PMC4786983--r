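planted_matrix <- function(P = 100, C = 50, blocks, amplitude = 5,
                           seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(P * C), P, C,
              dimnames = list(paste0("P", seq_len(P)),
                              paste0("c", seq_len(C))))
  for (b in blocks) E[b$rows, b$cols] <- E[b$rows, b$cols] + amplitude
  E
}

test_that("standardization satisfies its invariants", {
  E <- planted_matrix(blocks = list())
  pair <- standardize(E)
  expect_lt(max(abs(rowMeans(pair$E_r))), 1e-10)
  expect_lt(max(abs(apply(pair$E_r, 1, sd) - 1)), 1e-10)
  expect_lt(max(abs(colMeans(pair$E_c))), 1e-10)
  # idempotence on row-standardized input
  expect_equal(standardize(pair$E_r)$E_r, pair$E_r, tolerance = 1e-12)
  # constant row flagged and zeroed
  E2 <- E
  E2[3, ] <- 7
  p2 <- standardize(E2)
  expect_equal(unname(p2$E_r[3, ]), rep(0, ncol(E2)))
  expect_equal(as.integer(attr(p2, "degenerate_rows")), 3L)
})

test_that("isa_iterate recovers a planted block from an inside seed", {
  blocks <- list(list(rows = 1:20, cols = 1:10))
  E <- planted_matrix(P = 200, C = 80, blocks = blocks, amplitude = 5,
                      seed = 2)
  pair <- standardize(E)
  seed_cols <- rep(0, 80)
  seed_cols[c(2, 7)] <- 1  # inside the planted columns
  bc <- isa_iterate(pair, seed_cols, thr_row = 2, thr_col = 2)
  expect_s3_class(bc, "bicluster")
  expect_equal(jaccard_sets(bc$row_ids, paste0("P", 1:20)), 1)
  expect_equal(jaccard_sets(bc$col_ids, paste0("c", 1:10)), 1)

  # self-consistency: one further iteration reproduces the supports
  again <- isa_iterate(pair, bc$col_scores, bc$thr_row, bc$thr_col)
  expect_equal(again$row_ids, bc$row_ids)
  expect_equal(again$col_ids, bc$col_ids)
})

test_that("isa_iterate returns NULL on empty or non-converging runs", {
  zero <- matrix(0, 10, 8)
  pair <- standardize(zero)
  expect_null(isa_iterate(pair, rep(1, 8), 1.5, 1.5))
  # one iteration cannot satisfy the two-successive-iterate rule
  E <- planted_matrix(P = 30, C = 20, blocks = list(), seed = 3)
  p <- standardize(E)
  expect_null(isa_iterate(p, c(1, 1, rep(0, 18)), 1.5, 1.5, max_iter = 1))
  expect_error(isa_iterate(p, rep(0, 20), 1, 1), "nonzero")
  expect_error(isa_iterate(p, rep(1, 5), 1, 1), "length")
})

test_that("isa_sweep finds disjoint planted modules deterministically", {
  blocks <- list(
    list(rows = 1:20, cols = 1:10),
    list(rows = 101:120, cols = 41:50)
  )
  E <- planted_matrix(P = 300, C = 100, blocks = blocks, amplitude = 3,
                      seed = 5)
  raw <- isa_sweep(E, thr_row_grid = c(2, 2.5), thr_col_grid = c(2, 2.5),
                   n_seeds = 40, rng_seed = 9)
  expect_lte(length(raw), 2 * 2 * 40)
  raw2 <- isa_sweep(E, thr_row_grid = c(2, 2.5), thr_col_grid = c(2, 2.5),
                    n_seeds = 40, rng_seed = 9)
  expect_identical(raw, raw2)
  ms <- deduplicate_modules(raw, 0.5)
  for (b in blocks) {
    j <- vapply(ms, function(m) {
      jaccard_sets(m$row_ids, paste0("P", b$rows))
    }, numeric(1))
    best <- which.max(j)
    expect_gte(j[best], 0.9)
    expect_gte(jaccard_sets(ms[[best]]$col_ids, paste0("c", b$cols)), 0.9)
  }
})

test_that("deduplication keeps one of identical and both of disjoint", {
  blocks <- list(list(rows = 1:20, cols = 1:10))
  E <- planted_matrix(P = 200, C = 80, blocks = blocks, amplitude = 5,
                      seed = 6)
  pair <- standardize(E)
  s <- rep(0, 80); s[c(1, 5)] <- 1
  bc <- isa_iterate(pair, s, 2, 2)
  ms <- deduplicate_modules(list(bc, bc), 0.5)
  expect_length(ms, 1L)

  other <- bc
  other$row_scores <- as.numeric(rownames(E) %in% paste0("P", 120:135))
  other$col_scores <- as.numeric(colnames(E) %in% paste0("c", 60:65))
  other$row_ids <- paste0("P", 120:135)
  other$col_ids <- paste0("c", 60:65)
  ms2 <- deduplicate_modules(list(bc, other), 0.5)
  expect_length(ms2, 2L)

  expect_length(deduplicate_modules(list(), 0.5), 0L)
})

test_that("module sets tidy, glance, plot and round-trip", {
  blocks <- list(list(rows = 1:20, cols = 1:10))
  E <- planted_matrix(P = 200, C = 80, blocks = blocks, amplitude = 5,
                      seed = 8)
  ms <- deduplicate_modules(
    isa_sweep(E, thr_row_grid = 2, thr_col_grid = 2, n_seeds = 20,
              rng_seed = 3),
    0.5
  )
  expect_gte(length(ms), 1L)
  long <- tidy(ms)
  expect_true(all(c("module_id", "dimension", "id", "score") %in% names(long)))
  g <- glance(ms)
  expect_equal(nrow(g), length(ms))
  expect_s3_class(autoplot(ms), "ggplot")

  tf <- withr::local_tempfile(fileext = ".json")
  write_modules(ms, tf)
  back <- read_modules(tf)
  expect_equal(back[[1]]$row_ids, ms[[1]]$row_ids)
  expect_equal(back[[1]]$col_ids, ms[[1]]$col_ids)
  expect_equal(back[[1]]$robustness, ms[[1]]$robustness)
})
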