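#' Pipeline configuration
#'
#' Collects the file paths, seed and stage toggles that drive the end-to-end
#' analysis. When `species_csv`/`tree_file` are `NULL` the pipeline runs on
#' synthetic data generated from `generator` (seeded), so the whole analysis
#' is reproducible without external downloads; real deposits can be supplied
#' as optional inputs through the same two paths.
#'
#' @param species_csv Path to a species measurement CSV, or `NULL` to
#'   simulate.
#' @param tree_file Path to a Newick tree, or `NULL` to simulate.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param seed Root seed; each stochastic stage derives its own seed from it.
#' @param n_adequacy_reps Replicates for the adequacy stage.
#' @param stages Named logical list enabling `fit` (mantle PGLS), `beta`
#'   (wingtip regression), `ols` (aspect ratio), `asr`, `adequacy`.
#' @param generator A [generator_config()] used when simulating.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(species_csv = NULL, tree_file = NULL, out_dir = NULL,
                            seed = 1L, n_adequacy_reps = 500L,
                            stages = list(fit = TRUE, beta = TRUE, ols = TRUE,
                                          asr = TRUE, adequacy = TRUE),
                            generator = generator_config(seed = seed)) {
  defaults <- list(fit = TRUE, beta = TRUE, ols = TRUE, asr = TRUE, adequacy = TRUE)
  stages <- utils::modifyList(defaults, as.list(stages))
  structure(list(species_csv = species_csv, tree_file = tree_file,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_adequacy_reps = as.integer(n_adequacy_reps),
                 stages = stages, generator = generator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gen <- do.call(generator_config, cfg$generator %||% list())
  cfg$generator <- gen
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL   # where outputs land does not affect what they contain
  rlang::hash(x)
}

stamp <- function(df, config) {
  df$package_version <- as.character(packageVersion("larimorph"))
  df$config_hash <- config_hash(config)
  df
}

write_stage <- function(df, config, file) {
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(stamp(df, config), file.path(config$out_dir, file))
  }
  invisible(df)
}

#' Generate the synthetic species table and tree fixtures
#'
#' @param config A `"pipeline_config"`.
#' @return A list with `data` (raw species tibble), `tree`, and the file
#'   paths written (when `out_dir` is set).
#' @export
pipeline_simulate <- function(config) {
  gen <- config$generator
  tree <- simulate_tree(gen$n_species, gen$tree_height, seed = gen$seed)
  data <- simulate_species_table(tree, gen)
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(species_csv = file.path(config$out_dir, "species.csv"),
                  tree_file = file.path(config$out_dir, "tree.nwk"))
    readr::write_csv(stamp(data, config), paths$species_csv)
    write_newick(tree, paths$tree_file)
  }
  list(data = data, tree = tree, paths = paths)
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$species_csv) || is.null(config$tree_file)) {
    sim <- pipeline_simulate(config)
    list(data = sim$data, tree = sim$tree)
  } else {
    data <- read_species_csv(config$species_csv)
    drop <- intersect(c("package_version", "config_hash"), names(data))
    if (length(drop)) data <- data[setdiff(names(data), drop)]
    list(data = data, tree = read_newick(config$tree_file))
  }
}

run_stage <- function(enabled, name, expr) {
  if (!isTRUE(enabled)) {
    return(list(status = "skipped", result = NULL))
  }
  t0 <- Sys.time()
  out <- tryCatch(list(status = "ok", result = force(expr)),
                  error = function(e) list(status = "failed",
                                           result = conditionMessage(e)))
  message(sprintf("[larimorph] stage %-8s %-7s (%.2fs)", name, out$status,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full comparative analysis pipeline
#'
#' Derives morphology, fits the four mantle-darkness models with
#' likelihood-ratio selection and half-life, fits the wingtip phylogenetic
#' beta regression with ratios and baseline predictions (latitude 0, wing
#' loading 0/1/2 SD), runs the aspect-ratio OLS and mantle-wingtip
#' correlation, reconstructs ancestral mantle states, and runs the adequacy
#' check. Stages that fail are marked `"failed"` in the report rather than
#' aborting the run. Internal consistency is asserted on every report: the
#' half-life equals `ln(2)/alpha` of the report's own OU fit and each ratio
#' equals `exp(estimate)`.
#'
#' @param config A `"pipeline_config"`.
#' @return A list of class `"pipeline_report"` with one entry per stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_pipeline_inputs(config)
  raw <- inputs$data
  if ("parent_species" %in% names(raw)) raw <- aggregate_subspecies(raw)
  morph <- derive_morphology(raw)
  tree <- inputs$tree
  mantle_formula <- mantle_kgs ~ wing_loading_std + abs_latitude
  wingtip_formula <- wingtip_black ~ wing_loading_std + abs_latitude
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 package_version = as.character(packageVersion("larimorph")),
                 n_species = nrow(morph))
  write_stage(morph, config, "derived_morphology.csv")

  mantle_data <- prepare_analysis(morph, c("wing_loading", "abs_latitude", "mantle_kgs"))
  cmp <- NULL
  report$mantle <- run_stage(config$stages$fit, "fit", {
    cmp <- pgls_compare(mantle_data, tree, mantle_formula)
    ou <- cmp$fits$OU
    hl <- half_life(ou)
    stopifnot(abs(hl - log(2) / ou$param) < 1e-12)
    coef_tab <- purrr::map_dfr(names(cmp$fits), function(m) {
      dplyr::mutate(tidy(cmp$fits[[m]]), model = m, .before = 1)
    })
    lam_ci <- lambda_profile_ci(cmp$fits$LAMBDA)
    write_stage(dplyr::mutate(cmp$table,
                              dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))),
                config, "mantle_model_comparison.csv")
    write_stage(dplyr::mutate(coef_tab,
                              dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))),
                config, "mantle_coefficients.csv")
    list(comparison = cmp$table, coefficients = coef_tab,
         half_life = hl, alpha = ou$param,
         lambda = cmp$fits$LAMBDA$param, lambda_ci = lam_ci)
  })

  beta_fit <- NULL
  report$wingtip <- run_stage(config$stages$beta, "beta", {
    wing_data <- prepare_analysis(morph, c("wing_loading", "abs_latitude", "wingtip_black"))
    beta_fit <- fit_phylo_beta(wing_data, tree, wingtip_formula)
    tab <- tidy(beta_fit)
    stopifnot(all(abs(tab$ratio - exp(tab$estimate)) < 1e-12))
    preds <- tibble::tibble(
      wl_std = c(0, 1, 2), abs_latitude = 0,
      proportion = predict_proportion(beta_fit, wl_std = c(0, 1, 2), abs_lat = 0))
    write_stage(dplyr::mutate(tab,
                              dplyr::across(c("estimate", "std.error", "ratio", "statistic"),
                                            ~ round(.x, 2)),
                              p.value = round(.data$p.value, 3)),
                config, "wingtip_beta_fit.csv")
    list(coefficients = tab, glance = glance(beta_fit), baseline_predictions = preds)
  })

  report$aspect_ratio <- run_stage(config$stages$ols, "ols", {
    d <- prepare_analysis(morph, c("wing_loading", "aspect_ratio"))
    ols <- ols_fit(d$wing_loading_std, d$aspect_ratio)
    cc <- complete.cases(morph$mantle_kgs, morph$wingtip_black)
    r <- pearson(morph$mantle_kgs[cc], morph$wingtip_black[cc])
    list(ols = ols, mantle_wingtip_correlation = r)
  })

  report$asr <- run_stage(config$stages$asr, "asr", {
    m <- match_species_to_tree(mantle_data, tree)
    asr <- asr_bm(m$tree, setNames(m$data$mantle_kgs, m$data$species))
    write_stage(tidy(asr), config, "asr_node_states.csv")
    if (!is.null(config$out_dir)) {
      write_asr_newick(asr, file.path(config$out_dir, "asr_annotated.nwk"))
    }
    list(root_state = asr$node_states[[1]],
         range = range(c(asr$tip_states, asr$node_states)))
  })

  report$adequacy <- run_stage(config$stages$adequacy && !is.null(cmp), "adequacy", {
    adq <- run_adequacy(cmp$fits$BM, cmp$fits$OU,
                        n_reps = config$n_adequacy_reps,
                        seed = config$seed + 1000L)
    write_stage(tidy(adq), config, "adequacy_delta_aic.csv")
    list(observed_delta_aic = adq$observed_delta_aic,
         quantile_of_observed = as.list(adq$quantile_of_observed),
         n_reps = adq$n_reps)
  })

  if (!is.null(config$out_dir)) {
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("larimorph pipeline report (seed ", x$seed, ", ", x$n_species, " species)\n", sep = "")
  for (s in c("mantle", "wingtip", "aspect_ratio", "asr", "adequacy")) {
    if (!is.null(x[[s]])) cat("  ", format(s, width = 13), x[[s]]$status, "\n", sep = "")
  }
  if (identical(x$mantle$status, "ok")) {
    cat("  OU half-life: ", round(x$mantle$result$half_life, 4), " tree units\n", sep = "")
  }
  if (identical(x$wingtip$status, "ok")) {
    p <- x$wingtip$result$baseline_predictions$proportion
    cat("  wingtip black at WL 0/1/2 SD, equator: ",
        paste(round(p, 2), collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}
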