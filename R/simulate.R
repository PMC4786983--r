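#' Simulation configuration for synthetic toxicogenomics experiments
#'
#' Describes a synthetic study that mirrors the single-dose liver
#' toxicogenomics designs: primary human hepatocytes (PHH) and primary rat
#' hepatocytes (PRH) profiled at 3 doses x {2, 8, 24} hr x 2 replicates
#' plus vehicle controls, and rat liver in vivo (RLV) at 3 doses x
#' {3, 6, 9, 24} hr x 3 replicates plus controls. Expression follows the
#' per-gene dose-time linear model
#' `G = beta0 + beta1 * D + beta2 * T + beta3 * D * T + e`,
#' with `e ~ Normal(0, noise_sd^2)`; `beta1` is nonzero only for genes
#' belonging to a pathway of a planted module that contains the chemical.
#'
#' @param n_genes Genes per species universe.
#' @param n_pathways Pathways in the shared namespace.
#' @param pathway_size_range Inclusive integer range of gene-set sizes; must
#'   sit inside the downstream size filter.
#' @param n_chemicals Number of chemicals, shared across settings.
#' @param settings Character vector of settings to simulate, from
#'   `c("RLV", "PRH", "PHH")`.
#' @param missing_low_fraction Fraction of chemicals whose low-dose arm is
#'   absent (applied to PHH only, mirroring the incomplete human arm).
#' @param noise_sd Residual standard deviation sigma.
#' @param beta0_mean,beta0_sd Per-gene intercept distribution
#'   (log-intensity-like scale).
#' @param beta2_sd Per-gene time-slope standard deviation (hours^-1).
#' @param beta3 Dose-time interaction coefficient (0 by default).
#' @param modules List of planted modules from [planted_module()].
#' @param rng_seed Integer seed governing every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_pathways = 100,
                       pathway_size_range = c(15L, 40L),
                       n_chemicals = 30,
                       settings = c("RLV", "PRH", "PHH"),
                       missing_low_fraction = 0.25,
                       noise_sd = 1,
                       beta0_mean = 7, beta0_sd = 1,
                       beta2_sd = 0.1,
                       beta3 = 0,
                       modules = list(),
                       rng_seed = 1L) {
  stopifnot(
    n_genes >= 1, n_pathways >= 1, n_chemicals >= 1,
    length(pathway_size_range) == 2,
    pathway_size_range[1] <= pathway_size_range[2],
    missing_low_fraction >= 0, missing_low_fraction <= 1,
    noise_sd >= 0,
    all(settings %in% c("RLV", "PRH", "PHH"))
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_pathways = as.integer(n_pathways),
      pathway_size_range = as.integer(pathway_size_range),
      n_chemicals = as.integer(n_chemicals),
      settings = settings,
      missing_low_fraction = missing_low_fraction,
      noise_sd = noise_sd,
      beta0_mean = beta0_mean, beta0_sd = beta0_sd,
      beta2_sd = beta2_sd,
      beta3 = beta3,
      modules = modules,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
}

setting_layout <- function(setting) {
  switch(setting,
    PHH = list(times = c(2, 8, 24), n_rep = 2L, species = "human"),
    PRH = list(times = c(2, 8, 24), n_rep = 2L, species = "rat"),
    RLV = list(times = c(3, 6, 9, 24), n_rep = 3L, species = "rat"),
    abort(paste0("Unknown setting: ", setting))
  )
}

sim_chemical_ids <- function(n) sprintf("chem%03d", seq_len(n))
sim_pathway_ids <- function(n) sprintf("PW%04d", seq_len(n))
sim_gene_ids <- function(species, n) {
  sprintf("%s%05d", if (species == "human") "h" else "r", seq_len(n))
}

#' A planted pathway-chemical module (simulation ground truth)
#'
#' @param module_id Identifier.
#' @param pathway_ids Pathways carrying the effect.
#' @param chemical_ids Chemicals inducing it.
#' @param effect_size Magnitude of the dose coefficient `beta1` injected per
#'   member gene, in units of the noise SD when `noise_sd = 1`.
#' @param sign_per_pathway Optional named vector of +1/-1 per pathway; when
#'   `NULL`, signs are drawn once (Rademacher) at simulation time so that
#'   enrichment matrices contain both up- and down-regulated pathways.
#' @return A `planted_module` list.
#' @export
planted_module <- function(module_id, pathway_ids, chemical_ids,
                           effect_size, sign_per_pathway = NULL) {
  stopifnot(length(pathway_ids) > 0, length(chemical_ids) > 0,
            effect_size >= 0)
  if (!is.null(sign_per_pathway)) {
    stopifnot(setequal(names(sign_per_pathway), pathway_ids),
              all(sign_per_pathway %in% c(-1, 1)))
  }
  structure(
    list(
      module_id = as.character(module_id),
      pathway_ids = as.character(pathway_ids),
      chemical_ids = as.character(chemical_ids),
      effect_size = effect_size,
      sign_per_pathway = sign_per_pathway
    ),
    class = "planted_module"
  )
}

#' Generate a sample design for one experimental setting
#'
#' Full factorial of dose levels x times x replicates per chemical, plus
#' vehicle controls at every time x replicate. For PHH, a
#' `missing_low_fraction` of chemicals lack their low-dose rows, as in the
#' incomplete human hepatocyte arm.
#'
#' @param config A [sim_config()].
#' @param setting One of "RLV", "PRH", "PHH".
#' @return A validated design tibble.
#' @export
sim_design <- function(config, setting) {
  layout <- setting_layout(setting)
  chems <- sim_chemical_ids(config$n_chemicals)
  grid <- tidyr::expand_grid(
    chemical = chems,
    dose_level = c("control", "low", "middle", "high"),
    time_hr = layout$times,
    replicate = seq_len(layout$n_rep)
  )
  grid$dose_value <- c(control = 0, low = 1, middle = 2, high = 3)[grid$dose_level]
  if (setting == "PHH" && config$missing_low_fraction > 0) {
    n_missing <- floor(config$missing_low_fraction * config$n_chemicals)
    if (n_missing > 0) {
      rng <- derive_seed(config$rng_seed, "missing-low")
      missing_chems <- withr::with_seed(rng, sample(chems, n_missing))
      grid <- dplyr::filter(
        grid,
        !(.data$chemical %in% missing_chems & .data$dose_level == "low")
      )
    }
  }
  design <- grid |>
    dplyr::mutate(
      setting = setting,
      sample_id = sprintf(
        "%s_%s_%s_t%g_r%d",
        setting, .data$chemical, .data$dose_level, .data$time_hr,
        .data$replicate
      )
    ) |>
    dplyr::select(
      "sample_id", "chemical", "dose_level", "dose_value",
      "time_hr", "replicate", "setting"
    )
  validate_design(design)
  design
}

#' Generate a shared pathway namespace over two species gene universes
#'
#' Both species carry the same ordered pathway id list; gene memberships are
#' drawn independently from disjoint species universes, with one size per
#' pathway drawn uniformly from `pathway_size_range` and used for both
#' species.
#'
#' @param config A [sim_config()].
#' @return List with pathway collection tibbles `human` and `rat`.
#' @export
sim_pathway_space <- function(config) {
  lo <- config$pathway_size_range[1]
  hi <- config$pathway_size_range[2]
  if (hi > config$n_genes) {
    abort("pathway_size_range exceeds the gene universe size")
  }
  ids <- sim_pathway_ids(config$n_pathways)
  withr::with_seed(derive_seed(config$rng_seed, "pathway-space"), {
    sizes <- sample(seq.int(lo, hi), config$n_pathways, replace = TRUE)
    per_species <- function(species) {
      universe <- sim_gene_ids(species, config$n_genes)
      genes <- lapply(sizes, function(k) sample(universe, k))
      new_pathway_collection(ids, paste0("synthetic pathway ", ids), genes)
    }
    list(human = per_species("human"), rat = per_species("rat"))
  })
}

#' Simulate an expression matrix for one setting
#'
#' Applies the generative dose-time model gene by gene: per-gene intercepts
#' `beta0 ~ Normal(beta0_mean, beta0_sd^2)` and time slopes
#' `beta2 ~ Normal(0, beta2_sd^2)` are drawn once per species (so rat
#' settings share baselines), the planted dose effects are added for member
#' genes of module pathways under module chemicals, and i.i.d. Gaussian
#' noise completes the matrix. Genes in several planted pathways accumulate
#' the sum of their signed effects.
#'
#' @param design Design tibble from [sim_design()].
#' @param pathways The species-appropriate pathway collection.
#' @param config A [sim_config()].
#' @return Numeric matrix, genes x samples, with attribute `"planted_signs"`:
#'   a named list per module of the +1/-1 sign used per pathway.
#' @export
sim_expression <- function(design, pathways, config) {
  setting <- design$setting[1]
  layout <- setting_layout(setting)
  genes <- sim_gene_ids(layout$species, config$n_genes)
  n_g <- length(genes)
  n_s <- nrow(design)

  base_seed <- derive_seed(config$rng_seed, paste0("baseline-", layout$species))
  baselines <- withr::with_seed(base_seed, {
    list(
      beta0 = rnorm(n_g, config$beta0_mean, config$beta0_sd),
      beta2 = rnorm(n_g, 0, config$beta2_sd)
    )
  })

  D <- design$dose_value
  Tm <- design$time_hr
  expr <- outer(baselines$beta0, rep(1, n_s)) +
    outer(baselines$beta2, Tm) +
    config$beta3 * outer(rep(1, n_g), D * Tm)

  signs <- list()
  for (mod in config$modules) {
    sgn <- mod$sign_per_pathway
    if (is.null(sgn)) {
      sgn_seed <- derive_seed(config$rng_seed, paste0("signs-", mod$module_id))
      sgn <- withr::with_seed(
        sgn_seed,
        stats::setNames(
          sample(c(-1, 1), length(mod$pathway_ids), replace = TRUE),
          mod$pathway_ids
        )
      )
    }
    signs[[mod$module_id]] <- sgn
    cols <- which(design$chemical %in% mod$chemical_ids)
    if (length(cols) == 0L) next
    gene_sets <- as_pathway_list(pathways)
    for (pw in mod$pathway_ids) {
      members <- match(gene_sets[[pw]], genes)
      members <- members[!is.na(members)]
      if (length(members) == 0L) next
      expr[members, cols] <- expr[members, cols] +
        sgn[[pw]] * mod$effect_size * rep(D[cols], each = length(members))
    }
  }

  if (config$noise_sd > 0) {
    noise_seed <- derive_seed(config$rng_seed, paste0("noise-", setting))
    expr <- expr + withr::with_seed(
      noise_seed,
      matrix(rnorm(n_g * n_s, 0, config$noise_sd), n_g, n_s)
    )
  }
  dimnames(expr) <- list(genes, design$sample_id)
  attr(expr, "planted_signs") <- signs
  expr
}

#' Simulate a full multi-setting dataset
#'
#' @param config A [sim_config()].
#' @return List with `pathways` (per species), `designs` and `expression`
#'   (per setting), and `truth` (the planted modules).
#' @export
sim_dataset <- function(config) {
  pw <- sim_pathway_space(config)
  designs <- lapply(config$settings, function(s) sim_design(config, s))
  names(designs) <- config$settings
  expression <- lapply(config$settings, function(s) {
    species <- setting_layout(s)$species
    sim_expression(designs[[s]], pw[[species]], config)
  })
  names(expression) <- config$settings
  list(
    pathways = pw,
    designs = designs,
    expression = expression,
    truth = config$modules
  )
}

#' Write / read planted-module ground truth as JSON
#'
#' @param modules List of [planted_module()] objects.
#' @param path File path.
#' @return For `read_truth`, the list of planted modules.
#' @export
write_truth <- function(modules, path) {
  payload <- lapply(modules, function(m) {
    list(
      module_id = m$module_id,
      pathway_ids = m$pathway_ids,
      chemical_ids = m$chemical_ids,
      effect_size = m$effect_size,
      sign_per_pathway = as.list(m$sign_per_pathway)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(m) {
    planted_module(
      module_id = m$module_id,
      pathway_ids = unlist(m$pathway_ids),
      chemical_ids = unlist(m$chemical_ids),
      effect_size = m$effect_size,
      sign_per_pathway = if (length(m$sign_per_pathway)) {
        unlist(m$sign_per_pathway)
      } else {
        NULL
      }
    )
  })
}

#' The bundled synthetic demo configuration
#'
#' A small two-species, three-setting study: 6,000 genes per species, 100
#' pathways of 15-25 genes, 60 chemicals, unit noise SD, and three disjoint
#' planted modules (8 pathways x 10 chemicals each, dose effect 2 noise SDs)
#' shared across all settings, so conservation analysis has known truth.
#' The sizes keep the chemically responsive fraction of the genome sparse
#' (a few percent per chemical, as in real exposures) and each module a
#' modest fraction of the pathway and chemical universes.
#'
#' @param rng_seed Integer seed.
#' @return A [sim_config()].
#' @export
demo_config <- function(rng_seed = 1L) {
  pw_ids <- sim_pathway_ids(100)
  chems <- sim_chemical_ids(60)
  modules <- lapply(1:3, function(i) {
    planted_module(
      module_id = paste0("truth", i),
      pathway_ids = pw_ids[((i - 1) * 8 + 1):(i * 8)],
      chemical_ids = chems[((i - 1) * 10 + 1):(i * 10)],
      effect_size = 2
    )
  })
  sim_config(
    n_genes = 6000, n_pathways = 100, pathway_size_range = c(15L, 25L),
    n_chemicals = 60, settings = c("RLV", "PRH", "PHH"),
    missing_low_fraction = 0.25, noise_sd = 1,
    modules = modules, rng_seed = rng_seed
  )
}
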