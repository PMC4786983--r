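test_that("hypergeometric upper tail matches brute-force enumeration", {
  expect_equal(hypergeom_p(0, 5, 4, 10), 1)
  expect_lt(abs(hypergeom_p(4, 5, 4, 10) - 1 / 42), 1e-15)
  expect_equal(hypergeom_p(6, 6, 6, 6), 1)
  for (N in c(5, 9, 12)) {
    for (K_a in 0:N) for (K_b in 0:N) for (k in 0:min(K_a, K_b)) {
      expect_lt(abs(hypergeom_p(k, K_a, K_b, N) -
                      brute_hyper(k, K_a, K_b, N)), 1e-12)
    }
  }
  # monotone non-increasing in k
  ps <- vapply(0:4, function(k) hypergeom_p(k, 5, 4, 10), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(hypergeom_p(5, 4, 4, 10), "Overlap")
  expect_error(hypergeom_p(1, 11, 4, 10), "sizes")
})

test_that("reciprocal best hits are mutual, significant and symmetric", {
  rows <- paste0("P", 1:400)
  cols <- paste0("c", 1:50)
  mk <- function(sets) fake_module_set(sets, rows, cols)
  a <- mk(list(
    m1 = list(rows = rows[1:15], cols = cols[1:5]),
    m2 = list(rows = rows[101:115], cols = cols[6:10])
  ))
  # identical sets: every module self-matches
  self <- reciprocal_best_hits(a, a, N = 400, alpha = 0.001)
  expect_equal(nrow(self), 2L)
  expect_equal(self$module_a, self$module_b)
  expect_true(all(self$p < 0.001))

  # zero overlap -> unmatched
  b <- mk(list(mz = list(rows = rows[301:315], cols = cols[1:5])))
  expect_equal(nrow(reciprocal_best_hits(a, b, 400)), 0L)

  # empty set -> empty result, not an error
  expect_equal(nrow(reciprocal_best_hits(a, fake_module_set(
    list(), rows, cols), 400)), 0L)

  # symmetry under swapping the two datasets
  b2 <- mk(list(
    x1 = list(rows = rows[c(1:12, 201:203)], cols = cols[1:5]),
    x2 = list(rows = rows[106:120], cols = cols[6:10])
  ))
  ab <- reciprocal_best_hits(a, b2, 400)
  ba <- reciprocal_best_hits(b2, a, 400)
  expect_setequal(paste(ab$module_a, ab$module_b),
                  paste(ba$module_b, ba$module_a))
})

test_that("non-mutual best hits are not reported", {
  rows <- paste0("P", 1:100)
  cols <- paste0("c", 1:10)
  # a1 overlaps b1 by 12 but a2 overlaps b1 by 13 (b1's best is a2);
  # a1's best is still b1 -> a1-b1 must not be reported, a2-b1 is.
  a <- fake_module_set(list(
    a1 = list(rows = rows[c(1:12, 41:42)], cols = cols[1:2]),
    a2 = list(rows = rows[1:14], cols = cols[3:4])
  ), rows, cols)
  b <- fake_module_set(list(
    b1 = list(rows = rows[c(1:13, 31)], cols = cols[1:2])
  ), rows, cols)
  pair_p <- function(x, y) {
    k <- length(intersect(x, y))
    hypergeom_p(k, 14, 14, 100)
  }
  # confirm the intended asymmetry with direct enumeration
  expect_lt(pair_p(a[[2]]$row_ids, b[[1]]$row_ids),
            pair_p(a[[1]]$row_ids, b[[1]]$row_ids))
  res <- reciprocal_best_hits(a, b, N = 100, alpha = 0.001)
  expect_equal(res$module_a, "a2")
  expect_equal(res$module_b, "b1")
})

test_that("three-way conservation is anchored on the in vivo reference", {
  rows <- paste0("P", 1:400)
  cols <- paste0("c", 1:50)
  shared <- lapply(1:5, function(i) {
    list(rows = rows[((i - 1) * 20 + 1):((i - 1) * 20 + 16)],
         cols = cols[1:5])
  })
  names(shared) <- paste0("s", 1:5)
  private <- function(offset) {
    out <- lapply(1:5, function(i) {
      list(rows = rows[(offset + (i - 1) * 16 + 1):(offset + i * 16)],
           cols = cols[6:10])
    })
    names(out) <- paste0("p", offset, "_", 1:5)
    out
  }
  rlv <- fake_module_set(c(shared, private(120)), rows, cols)
  prh <- fake_module_set(c(shared, private(200)), rows, cols)
  phh <- fake_module_set(c(shared, private(280)), rows, cols)
  trip <- conserved_across_three(rlv, prh, phh, N = 400, alpha = 0.001)
  expect_equal(nrow(trip), 5L)
  # the five shared modules and only those
  shared_ids <- vapply(rlv[1:5], `[[`, character(1), "module_id")
  expect_setequal(trip$module_rlv, shared_ids)
  expect_true(all(lengths(trip$core_pathways) == 16L))

  none <- conserved_across_three(rlv, fake_module_set(list(), rows, cols),
                                 phh, N = 400)
  expect_equal(nrow(none), 0L)

  all3 <- conserved_across_three(rlv, rlv, rlv, N = 400)
  expect_equal(nrow(all3), length(rlv))
})

test_that("chemical-class enrichment uses the exact upper tail", {
  rows <- paste0("P", 1:20)
  univ <- paste0("c", 1:115)
  class25 <- univ[1:25]
  mod <- fake_module_set(
    list(m = list(rows = rows[1:5], cols = univ[1:10])), rows, univ
  )[[1]]
  res <- chemical_class_enrichment(mod, class25, univ)
  expect_equal(res$k, 10L)
  expect_lt(abs(res$p - brute_hyper(10, 25, 10, 115)), 1e-12)
  expect_true(res$significant)

  disj <- fake_module_set(
    list(m = list(rows = rows[1:5], cols = univ[30:39])), rows, univ
  )[[1]]
  r2 <- chemical_class_enrichment(disj, class25, univ)
  expect_equal(r2$k, 0L)
  expect_equal(r2$p, 1)

  r3 <- chemical_class_enrichment(mod, univ, univ)
  expect_equal(r3$p, 1)
  expect_error(chemical_class_enrichment(mod, class25, character()), "Empty")
})

test_that("leading-edge unions collect genes across module cells", {
  results <- tibble::tibble(
    pathway_id = c("P1", "P2", "P1", "P2"),
    chemical_id = c("c1", "c1", "c2", "c2"),
    leading_edge = list(c("g1", "g2"), c("g2", "g3"), "g1", character())
  )
  rows <- c("P1", "P2"); cols <- c("c1", "c2")
  mod <- fake_module_set(
    list(m = list(rows = rows, cols = cols)), rows, cols
  )[[1]]
  expect_equal(leading_edge_union(mod, results), c("g1", "g2", "g3"))

  single <- fake_module_set(
    list(m = list(rows = "P1", cols = "c1")), rows, cols
  )[[1]]
  expect_equal(leading_edge_union(single, results), c("g1", "g2"))

  missing_cell <- fake_module_set(
    list(m = list(rows = c("P1", "P3"), cols = "c1")), c(rows, "P3"), cols
  )[[1]]
  expect_error(leading_edge_union(missing_cell, results), "P3/c1")

  empty <- mod
  empty$row_ids <- character()
  expect_error(leading_edge_union(empty, results), "empty")
})

test_that("gene-list overlap significance is exact", {
  univ <- paste0("g", 1:20)
  a <- univ[1:6]; b <- univ[c(1:4, 10)]
  res <- gene_list_overlap(a, b, univ)
  expect_equal(res$k, 4L)
  expect_lt(abs(res$p - brute_hyper(4, 6, 5, 20)), 1e-12)
  expect_equal(gene_list_overlap(univ[1:3], univ[5:7], univ)$p, 1)
  same <- gene_list_overlap(a, a, univ)
  expect_equal(same$k, 6L)
  expect_error(gene_list_overlap(c(a, "zz"), b, univ), "subsets")
})
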