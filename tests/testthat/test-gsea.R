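test_that("the worked enrichment-score example reproduces exactly", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:10), score = 10:1)
  sc <- enrichment_score(ranked, paste0("g", c(2, 5, 9)))
  expect_lt(abs(sc$es - 54 / 119), 1e-12)   # peak value 15/17 - 3/7
  expect_equal(sc$peak, 5L)
  expect_equal(sc$leading_edge, c("g2", "g5"))
  expect_lt(abs(sc$running_sum[10]), 1e-12)

  # a single top hit forces the running sum to 1
  one <- enrichment_score(ranked, "g1")
  expect_equal(one$es, 1)

  expect_error(enrichment_score(ranked, "absent"), "no overlap")
  expect_error(enrichment_score(ranked, paste0("g", 1:10)), "entire")
})

test_that("enrichment score agrees with the brute-force walk", {
  set.seed(101)
  for (i in 1:100) {
    N <- sample(10:50, 1)
    k <- sample(1:min(10, N - 1), 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    ranked <- tibble::tibble(gene_id = paste0("g", 1:N), score = scores)
    hits <- sort(sample(N, k))
    mine <- enrichment_score(ranked, paste0("g", hits))
    oracle <- brute_es(scores, hits)
    expect_lt(abs(mine$es - oracle$es), 1e-12)
    expect_equal(mine$peak, oracle$peak)
    expect_lte(abs(mine$es), 1)
    expect_lt(abs(mine$running_sum[N]), 1e-12)
  }
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(55)
  for (i in 1:30) {
    N <- sample(20:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- paste0("g", 1:N)
    hits <- sort(sample(N, sample(3:8, 1)))
    ranked <- tibble::tibble(gene_id = names(scores), score = scores)
    mine <- enrichment_score(ranked, paste0("g", hits))$es
    ref <- fgsea::calcGseaStat(scores, hits)
    expect_lt(abs(mine - ref), 1e-10)
  }
})

test_that("reversing and negating the ranked list negates the score", {
  set.seed(9)
  N <- 40
  scores <- sort(rnorm(N), decreasing = TRUE)
  ranked <- tibble::tibble(gene_id = paste0("g", 1:N), score = scores)
  flipped <- tibble::tibble(
    gene_id = rev(ranked$gene_id),
    score = rev(-scores)
  )
  for (i in 1:20) {
    hits <- paste0("g", sample(N, 5))
    expect_lt(
      abs(enrichment_score(ranked, hits)$es +
            enrichment_score(flipped, hits)$es),
      1e-12
    )
  }
})

test_that("batched null ES equals the full walk and is seed-stable", {
  ranked <- make_ranked(80, seed = 2)
  null1 <- null_distribution(ranked, 7, 500, rng_seed = 42)
  null2 <- null_distribution(ranked, 7, 500, rng_seed = 42)
  expect_identical(null1, null2)
  expect_error(null_distribution(ranked, 80, 10, 1), "set_size")

  # each batched value equals the walk on the same sampled set
  rank_mat <- withr::with_seed(42, {
    t(vapply(1:500, function(i) sort(sample.int(80, 7)), integer(7)))
  })
  full <- vapply(1:50, function(i) {
    enrichment_score(ranked, ranked$gene_id[rank_mat[i, ]])$es
  }, numeric(1))
  expect_lt(max(abs(null1[1:50] - full)), 1e-12)

  # symmetric score vector -> null symmetric about 0
  sym <- tibble::tibble(
    gene_id = paste0("g", 1:100),
    score = sort(c(seq(0.1, 5, length.out = 50),
                   -seq(0.1, 5, length.out = 50)), decreasing = TRUE)
  )
  nd <- null_distribution(sym, 10, 5000, rng_seed = 7)
  expect_lt(abs(mean(sign(nd))), 0.05)
})

test_that("NES and nominal p follow the same-sign null convention", {
  null_sample <- c(0.2, 0.4, 0.6, -0.1, -0.5)
  # es equal to mean of positive nulls -> nes 1
  np <- normalize_and_p(0.4, null_sample)
  expect_equal(np$nes, 1)
  # p with add-one smoothing: 2 of 3 positive nulls >= 0.4
  expect_equal(np$p_nominal, (1 + 2) / (1 + 3))
  expect_equal(normalize_and_p(0, null_sample),
               list(nes = 0, p_nominal = 1, masked = FALSE))
  # es exceeding all 999 same-sign nulls -> p = 1/1000
  big_null <- runif(999, 0.01, 0.5)
  expect_equal(normalize_and_p(0.9, big_null)$p_nominal, 1 / 1000)
  # no same-sign nulls -> masked, no exception
  expect_true(normalize_and_p(-0.5, c(0.1, 0.2))$masked)
})

test_that("run_gsea masks small overlaps and is deterministic", {
  ranked <- make_ranked(60, seed = 4)
  coll <- tibble::tibble(
    pathway_id = c("top_block", "tiny"),
    description = "",
    genes = list(ranked$gene_id[1:10], ranked$gene_id[30:32]),
    n_genes = c(10L, 3L)
  )
  res <- run_gsea(ranked, coll, n_perm = 200, rng_seed = 1, min_overlap = 5)
  expect_gt(res$nes[res$pathway_id == "top_block"], 0)
  expect_true(res$masked[res$pathway_id == "tiny"])
  res2 <- run_gsea(ranked, coll, n_perm = 200, rng_seed = 1, min_overlap = 5)
  expect_identical(res, res2)
  expect_error(run_gsea(ranked, coll[0, ], n_perm = 10, rng_seed = 1),
               "Empty")
})

test_that("enrichment matrices assemble with masks and stable order", {
  ranked <- make_ranked(60, seed = 4)
  coll <- tibble::tibble(
    pathway_id = c("A", "B"), description = "",
    genes = list(ranked$gene_id[1:8], ranked$gene_id[c(2, 9, 12)]),
    n_genes = c(8L, 3L)
  )
  per_chem <- list(
    c2 = run_gsea(ranked, coll, n_perm = 100, rng_seed = 1, min_overlap = 5),
    c1 = run_gsea(ranked, coll, n_perm = 100, rng_seed = 2, min_overlap = 5)
  )
  em <- build_enrichment_matrix(per_chem)
  expect_equal(dim(em$nes), c(2L, 2L))
  expect_equal(colnames(em$nes), c("c2", "c1"))  # input order kept
  expect_equal(unname(em$nes["B", ]), c(0, 0))   # masked imputed as 0
  expect_true(all(em$mask["B", ]))

  long <- tidy(em)
  expect_equal(nrow(long), 4L)
  expect_s3_class(autoplot(em), "ggplot")

  bad <- per_chem
  bad$c1$pathway_id <- c("A", "C")
  expect_error(build_enrichment_matrix(bad), "Inconsistent")
})
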