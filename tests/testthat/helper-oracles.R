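# Independent oracles used across the suite. These deliberately re-derive
# each quantity from first principles, step by step, and never call the
# package's own implementation paths.

# Plain running-sum walk: explicit loop over the list.
brute_es <- function(scores, hit_idx, weight = 1) {
  N <- length(scores)
  hit <- seq_len(N) %in% hit_idx
  w <- abs(scores)^weight
  denom <- sum(w[hit])
  if (denom == 0) {
    w[hit] <- 1
    denom <- sum(hit)
  }
  miss_step <- 1 / (N - sum(hit))
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) w[i] / denom else -miss_step
    running[i] <- acc
  }
  peak <- which(abs(running) >= max(abs(running)) - 1e-9)[1]
  list(es = running[peak], running = running, peak = peak)
}

# Upper-tail hypergeometric by direct pmf summation with choose().
brute_hyper <- function(k, K_a, K_b, N) {
  ks <- k:min(K_a, K_b)
  sum(choose(K_a, ks) * choose(N - K_a, K_b - ks)) / choose(N, K_b)
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

make_ranked <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    score = sort(rnorm(n), decreasing = TRUE)
  )
}

# Minimal hepatocyte-style design for one chemical: 3 doses + control,
# times x replicates as in the human/rat in vitro layout.
toy_design <- function(times = c(2, 8, 24), n_rep = 2) {
  grid <- expand.grid(
    dose_level = c("control", "low", "middle", "high"),
    time_hr = times, replicate = seq_len(n_rep),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(grid))),
    chemical = "chemX",
    dose_level = grid$dose_level,
    dose_value = c(control = 0, low = 1, middle = 2, high = 3)[grid$dose_level],
    time_hr = grid$time_hr,
    replicate = as.integer(grid$replicate),
    setting = "PHH"
  )
}

# A module_set built directly from known supports (bypassing ISA), for
# conservation tests.
fake_module_set <- function(supports, universe_rows, universe_cols) {
  mods <- lapply(seq_along(supports), function(i) {
    s <- supports[[i]]
    row_scores <- as.numeric(universe_rows %in% s$rows)
    col_scores <- as.numeric(universe_cols %in% s$cols)
    structure(
      list(
        module_id = names(supports)[i] %||% paste0("mod", i),
        row_scores = row_scores, col_scores = col_scores,
        row_ids = s$rows, col_ids = s$cols,
        thr_row = NA_real_, thr_col = NA_real_,
        seed_index = NA_integer_, n_iterations = 1L,
        robustness = s$robustness %||% 1
      ),
      class = "bicluster"
    )
  })
  names(mods) <- NULL
  structure(mods, class = "module_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
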