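#' Pipeline configuration
#'
#' Bundles every stage's settings with a single global seed. In synthetic
#' mode (`sim` supplied) all inputs are generated; otherwise per-setting
#' design/expression TSVs and per-species GMTs are read from disk.
#'
#' @param sim A [sim_config()], or `NULL` for file inputs.
#' @param design_paths,expression_paths Named lists (by setting) of TSV
#'   paths, used when `sim` is `NULL`.
#' @param gmt_paths Named list (by species: "human", "rat") of GMT paths,
#'   used when `sim` is `NULL`.
#' @param size_filter Inclusive gene-set size bounds applied to the common
#'   pathway collection.
#' @param gsea_n_perm,gsea_weight,gsea_min_overlap Preranked-GSEA settings.
#' @param isa_thr_row,isa_thr_col,isa_n_seeds,isa_cor_limit ISA sweep and
#'   deduplication settings.
#' @param conservation_alpha Module-match significance threshold.
#' @param class_alpha Chemical-class enrichment threshold.
#' @param outdir Output directory (created if absent).
#' @param rng_seed Global seed; every stage derives its own substream.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL,
                            design_paths = NULL, expression_paths = NULL,
                            gmt_paths = NULL,
                            size_filter = c(15, 500),
                            gsea_n_perm = 1000, gsea_weight = 1,
                            gsea_min_overlap = 15,
                            isa_thr_row = c(1.5, 2, 2.5, 3),
                            isa_thr_col = c(1.5, 2, 2.5, 3),
                            isa_n_seeds = 100, isa_cor_limit = 0.5,
                            conservation_alpha = 0.001, class_alpha = 0.05,
                            outdir = tempfile("toxmod_run_"),
                            rng_seed = 1L) {
  if (is.null(sim)) {
    for (p in c(unlist(design_paths), unlist(expression_paths),
                unlist(gmt_paths))) {
      if (!file.exists(p)) abort(paste0("Input path does not exist: ", p))
    }
    if (is.null(design_paths) || is.null(expression_paths) ||
        is.null(gmt_paths)) {
      abort("Non-synthetic mode needs design, expression and GMT paths")
    }
  }
  structure(
    list(
      sim = sim,
      design_paths = design_paths, expression_paths = expression_paths,
      gmt_paths = gmt_paths,
      size_filter = size_filter,
      gsea_n_perm = gsea_n_perm, gsea_weight = gsea_weight,
      gsea_min_overlap = gsea_min_overlap,
      isa_thr_row = isa_thr_row, isa_thr_col = isa_thr_col,
      isa_n_seeds = isa_n_seeds, isa_cor_limit = isa_cor_limit,
      conservation_alpha = conservation_alpha, class_alpha = class_alpha,
      outdir = outdir, rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Run the full pathway-module pipeline
#'
#' Simulate (or load) -> per-chemical dose-time association and gene
#' ranking -> preranked GSEA into an enrichment matrix -> ISA biclustering
#' into nonredundant modules -> cross-setting reciprocal best-hit
#' conservation, writing TSV/JSON artifacts for every stage under
#' `config$outdir`. All randomness derives from the global seed, and
#' per-chemical GSEA substreams are keyed by chemical id, so repeated runs
#' are byte-identical. In synthetic mode the outputs are also scored
#' against the planted truth.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_manifest`: config snapshot, per-stage counts and timings,
#'   output checksums, plus the in-memory results (`enrichment`, `modules`,
#'   `matches`, `triples`, `recovery`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[toxmodules] ", ...)
  stages <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }

  # --- inputs ---------------------------------------------------------
  data <- timed("inputs", {
    if (!is.null(config$sim)) {
      say("simulating synthetic dataset")
      ds <- sim_dataset(config$sim)
      write_truth(ds$truth, file.path(outdir, "planted_truth.json"))
      for (s in names(ds$designs)) {
        write_design(ds$designs[[s]],
                     file.path(outdir, paste0("design_", s, ".tsv")))
      }
      ds
    } else {
      say("loading inputs from disk")
      designs <- lapply(config$design_paths, read_design)
      expression <- lapply(config$expression_paths, read_expression)
      for (s in names(designs)) {
        validate_expression(expression[[s]], designs[[s]])
      }
      list(
        pathways = lapply(config$gmt_paths, read_gmt),
        designs = designs, expression = expression, truth = NULL
      )
    }
  })
  settings <- names(data$designs)

  # --- common, size-filtered pathway space ----------------------------
  shared <- common_pathways(data$pathways$human, data$pathways$rat)
  shared$a <- filter_gene_sets(shared$a, config$size_filter[1],
                               config$size_filter[2])
  shared$b <- filter_gene_sets(shared$b, config$size_filter[1],
                               config$size_filter[2])
  ids <- intersect(shared$a$pathway_id, shared$b$pathway_id)
  coll <- list(
    human = dplyr::filter(shared$a, .data$pathway_id %in% ids),
    rat = dplyr::filter(shared$b, .data$pathway_id %in% ids)
  )
  N_pathways <- length(ids)
  say(N_pathways, " common size-filtered pathways")
  if (N_pathways == 0L) abort("No common pathways after size filtering")

  # --- association + GSEA per setting ---------------------------------
  enrichment <- list()
  results_store <- list()
  for (s in settings) {
    design <- data$designs[[s]]
    expr <- data$expression[[s]]
    species <- setting_layout(s)$species
    chems <- sort(unique(design$chemical))
    say("associating + GSEA: ", s, " (", length(chems), " chemicals)")
    per_chem <- timed(paste0("gsea_", s), {
      res <- lapply(chems, function(ch) {
        ranked <- rank_genes(associate_genes(design, expr, ch))
        write_rnk(ranked,
                  file.path(outdir, paste0("ranked_", s, "_", ch, ".rnk")))
        run_gsea(
          ranked, coll[[species]],
          n_perm = config$gsea_n_perm,
          rng_seed = derive_seed(config$rng_seed, paste0("gsea-", s, "-", ch)),
          weight = config$gsea_weight,
          min_overlap = config$gsea_min_overlap
        )
      })
      names(res) <- chems
      res
    })
    results_store[[s]] <- dplyr::bind_rows(
      purrr::imap(per_chem, function(r, ch) {
        dplyr::mutate(r, chemical_id = ch)
      })
    )
    enrichment[[s]] <- build_enrichment_matrix(per_chem)
    write_enrichment_matrix(
      enrichment[[s]],
      file.path(outdir, paste0("enrichment_", s, ".tsv"))
    )
  }

  # --- ISA biclustering per setting -----------------------------------
  modules <- list()
  for (s in settings) {
    say("ISA biclustering: ", s)
    modules[[s]] <- timed(paste0("isa_", s), {
      raw <- isa_sweep(
        enrichment[[s]],
        thr_row_grid = config$isa_thr_row,
        thr_col_grid = config$isa_thr_col,
        n_seeds = config$isa_n_seeds,
        rng_seed = derive_seed(config$rng_seed, paste0("isa-", s))
      )
      deduplicate_modules(raw, config$isa_cor_limit)
    })
    say("  ", length(modules[[s]]), " nonredundant modules")
    write_modules(modules[[s]],
                  file.path(outdir, paste0("modules_", s, ".json")))
    readr::write_tsv(tidy.module_set(modules[[s]]),
                     file.path(outdir, paste0("modules_", s, ".tsv")),
                     progress = FALSE)
  }

  # --- conservation ----------------------------------------------------
  conserve <- timed("conservation", {
    matches <- list()
    triples <- NULL
    combos <- utils::combn(settings, 2, simplify = FALSE)
    for (pr in combos) {
      key <- paste(pr, collapse = "_")
      matches[[key]] <- reciprocal_best_hits(
        modules[[pr[1]]], modules[[pr[2]]],
        N = N_pathways, alpha = config$conservation_alpha
      )
      readr::write_tsv(
        dplyr::select(matches[[key]], -dplyr::any_of("reciprocal")),
        file.path(outdir, paste0("matches_", key, ".tsv")),
        progress = FALSE
      )
    }
    if (all(c("RLV", "PRH", "PHH") %in% settings)) {
      triples <- conserved_across_three(
        modules$RLV, modules$PRH, modules$PHH,
        N = N_pathways, alpha = config$conservation_alpha
      )
      jsonlite::write_json(
        purrr::pmap(triples, function(module_rlv, module_prh, module_phh,
                                      p_rlv_prh, p_rlv_phh, core_pathways) {
          list(module_rlv = module_rlv, module_prh = module_prh,
               module_phh = module_phh, p_rlv_prh = p_rlv_prh,
               p_rlv_phh = p_rlv_phh, core_pathways = core_pathways)
        }),
        file.path(outdir, "conserved_triples.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      say(nrow(triples), " conserved triples")
    }
    list(matches = matches, triples = triples)
  })
  matches <- conserve$matches
  triples <- conserve$triples

  # --- truth scoring (synthetic mode) ---------------------------------
  recovery <- NULL
  if (!is.null(data$truth) && length(data$truth) > 0) {
    recovery <- score_against_truth(modules, triples, data$truth)
    jsonlite::write_json(
      list(per_module = recovery$per_module,
           triple_recovery_rate = recovery$triple_recovery_rate),
      file.path(outdir, "recovery.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
  }

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!basename(files) %in% "manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(files)
  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("toxmodules")),
      rng_seed = config$rng_seed,
      settings = settings,
      n_common_pathways = N_pathways,
      n_chemicals = length(unique(data$designs[[1]]$chemical)),
      n_modules = vapply(modules, length, integer(1)),
      n_triples = if (is.null(triples)) NA_integer_ else nrow(triples),
      stage_seconds = stages,
      checksums = as.list(checksums),
      outdir = outdir,
      enrichment = enrichment, modules = modules, matches = matches,
      triples = triples, recovery = recovery,
      results_store = results_store
    ),
    class = "run_manifest"
  )
  jsonlite::write_json(
    list(
      package_version = manifest$package_version,
      rng_seed = manifest$rng_seed,
      settings = settings,
      n_common_pathways = N_pathways,
      n_modules = as.list(manifest$n_modules),
      n_triples = manifest$n_triples,
      stage_seconds = stages,
      checksums = as.list(checksums)
    ),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("toxmodules run (seed ", x$rng_seed, "): ",
      x$n_common_pathways, " pathways, settings ",
      paste(x$settings, collapse = "/"), "\n", sep = "")
  cat("  modules:", paste(names(x$n_modules), x$n_modules, sep = "=",
                          collapse = ", "), "\n")
  if (!is.na(x$n_triples)) cat("  conserved triples:", x$n_triples, "\n")
  invisible(x)
}

#' Score pipeline outputs against planted truth
#'
#' For every planted module and setting, finds the output module with the
#' best pathway-support Jaccard and reports Jaccard on both dimensions. A
#' planted module counts as recovered as a conserved triple when some
#' triple's member modules all reach pathway Jaccard >= 0.5 against it.
#'
#' @param modules Named list (by setting) of `module_set`s.
#' @param triples Conserved-triple tibble (or `NULL`).
#' @param truth List of [planted_module()]s.
#' @return List with `per_module` (tibble: planted module x setting,
#'   Jaccards and best match) and `triple_recovery_rate`.
#' @export
score_against_truth <- function(modules, triples, truth) {
  per_module <- purrr::map_dfr(truth, function(tm) {
    purrr::map_dfr(names(modules), function(s) {
      ms <- modules[[s]]
      if (length(ms) == 0L) {
        return(tibble::tibble(
          planted = tm$module_id, setting = s, best_match = NA_character_,
          jaccard_pathways = 0, jaccard_chemicals = 0
        ))
      }
      jp <- vapply(ms, function(m) jaccard(m$row_ids, tm$pathway_ids),
                   numeric(1))
      best <- which.max(jp)
      tibble::tibble(
        planted = tm$module_id, setting = s,
        best_match = ms[[best]]$module_id,
        jaccard_pathways = jp[best],
        jaccard_chemicals = jaccard(ms[[best]]$col_ids, tm$chemical_ids)
      )
    })
  })
  triple_rate <- if (is.null(triples) || nrow(triples) == 0L) {
    0
  } else {
    hit <- vapply(truth, function(tm) {
      any(vapply(seq_len(nrow(triples)), function(i) {
        ids <- c(
          rlv = triples$module_rlv[i],
          prh = triples$module_prh[i],
          phh = triples$module_phh[i]
        )
        all(vapply(names(modules), function(s) {
          key <- tolower(s)
          if (!key %in% names(ids)) return(TRUE)
          ms <- modules[[s]]
          m <- ms[[match(ids[[key]], module_ids_of(ms))]]
          jaccard(m$row_ids, tm$pathway_ids) >= 0.5
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
    mean(hit)
  }
  list(per_module = per_module, triple_recovery_rate = triple_rate)
}
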