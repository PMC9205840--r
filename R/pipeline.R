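#' Trait matrices from a BLUE table
#'
#' Reshapes a long table of per-trial adjusted genotype means into one
#' trials x genotypes matrix per trait.
#'
#' @param blues data frame with columns `trial`, `genotype`, and one
#'   column per trait.
#' @param traits trait column names.
#' @return named list of trials x genotypes matrices.
#' @export
trait_matrices <- function(blues, traits) {
  lapply(stats::setNames(traits, traits), function(tr) {
    stop_if(!tr %in% names(blues), "no trait column '", tr, "'")
    tapply(blues[[tr]], list(blues$trial, blues$genotype), mean)
  })
}

#' Read a pipeline configuration file
#'
#' YAML key-value file mirroring the arguments of [run_pipeline()]; the
#' `simulate:` block holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "no such config file: ", path)
  yaml::read_yaml(path)
}

#' Run the full classification and evaluation pipeline
#'
#' Executes the two-step environment classification and its evaluation on
#' a simulated (or supplied) trial network: per-trial BLUEs, additive
#' imputation and per-trial scaling, layer-stack construction (per-trait
#' or per-genotype arrangement, the latter with AMMI-2 genotype weights),
#' multi-layer SOM training, hierarchical clustering of prototypes into
#' environment types, geographic clustering, chi-square/Ward zoning into
#' adaptation zones, variance-component models on the derived zones
#' (two-way G x E decomposition and the zone-nested model), the CR/DR
#' selection-response summary, and optionally leave-one-year-out
#' cross-validation.  All artifacts are written as CSV under `out_dir`
#' together with a manifest recording the configuration and seed.
#'
#' @param config named list (or path handled by
#'   [read_pipeline_config()]): `seed`; `simulate` ([sim_config()]
#'   arguments); `arrangement` (`"trait"` or `"genotype"`); `traits`
#'   (subset of simulated traits; first is the target); `use_incidence`
#'   (add the binary incidence layer); `weights` (per-trait layer
#'   weights); `som` (`nx`, `ny`, `rlen`, `mode`); `k_et`; `k_zones`;
#'   `geo_clusters`; `trial_model` (fit per-trial spatial models to
#'   plot-level data); `cv` (run leave-one-year-out CV).
#' @param out_dir output directory (`NULL` for no files).
#' @return object of class `met_pipeline` with all intermediate results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(
    list(seed = 1L, arrangement = "trait", traits = NULL,
         use_incidence = TRUE, weights = NULL,
         som = list(nx = 5, ny = 5, rlen = 100, mode = "batch"),
         k_et = 6, k_zones = 4, geo_clusters = 10,
         trial_model = FALSE, cv = FALSE, simulate = list()),
    config)
  stop_if(!cfg$arrangement %in% c("trait", "genotype"),
          "arrangement must be 'trait' or 'genotype'")
  set.seed(cfg$seed)
  log_msg <- function(...) message("[metzones] ", ...)

  # ---- input data --------------------------------------------------------
  sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
  met <- simulate_met(do.call(sim_config, sim_args),
                      level = if (cfg$trial_model) "plot" else "trial")
  all_traits <- met$truth$config$traits
  traits <- cfg$traits %||% all_traits
  stop_if(!all(traits %in% all_traits), "unknown trait in config$traits")
  log_msg("simulated network: ", nrow(met$trials), " trials, ",
          met$truth$config$n_genotypes, " genotypes")

  # ---- stage 1: per-trial adjusted means --------------------------------
  if (cfg$trial_model) {
    blues_long <- lapply(traits, function(tr)
      cbind(trait = tr, blues_for_network(met$plots, trait = tr)))
    blues <- NULL
    for (tr in seq_along(traits)) {
      b <- blues_long[[tr]]
      b <- b[b$ok, c("trial", "genotype", "blue", "weight")]
      names(b)[3] <- traits[tr]
      blues <- if (is.null(blues)) b else
        merge(blues, b[c("trial", "genotype", traits[tr])],
              by = c("trial", "genotype"))
    }
    log_msg("stage 1: spatial BLUEs for ", length(unique(blues$trial)),
            " trials")
  } else {
    blues <- met$data
    blues <- blues[c("trial", "genotype", traits, "weight")]
  }
  meta <- met$trials

  # ---- stage 2: impute, scale, layers -----------------------------------
  tm <- trait_matrices(blues, traits)
  tm <- lapply(tm, impute_additive)
  tm_scaled <- lapply(tm, scale_rows)
  incidence <- NULL
  if (isTRUE(cfg$use_incidence))
    incidence <- stats::setNames(meta$incidence, meta$trial)
  if (cfg$arrangement == "trait") {
    stack <- build_trait_layers(tm_scaled, binary_scores = incidence,
                                weights = cfg$weights)
    gweights <- NULL
  } else {
    ammi <- fit_ammi(tm_scaled[[traits[1]]])
    gweights <- genotype_weights_from_ammi(ammi, K = min(2, ammi$K))
    stack <- build_genotype_layers(tm_scaled, genotype_weights = gweights,
                                   binary_scores = incidence)
  }
  log_msg("stage 2: ", length(stack$layers), " layers (",
          cfg$arrangement, " arrangement)")

  # ---- stage 3: SOM, environment types ----------------------------------
  som <- train_som(stack,
                   som_grid(cfg$som$nx %||% 5, cfg$som$ny %||% 5),
                   rlen = cfg$som$rlen %||% 100,
                   mode = cfg$som$mode %||% "batch", seed = cfg$seed)
  ets <- cluster_prototypes(som, stack, k_et = cfg$k_et)
  log_msg("stage 3: SOM quantization error ",
          format(som$qerror, digits = 4), "; ", cfg$k_et, " ETs")

  # ---- stage 4: geography, zones ----------------------------------------
  geo <- geo_cluster(meta$latitude, meta$longitude,
                     n_clusters = cfg$geo_clusters,
                     trial_ids = meta$trial, seed = cfg$seed + 1L)
  freq <- et_frequency(ets$trial_et, geo)
  zones <- cluster_zones(freq, k_zones = cfg$k_zones)
  tz <- trial_zones(zones, geo)
  log_msg("stage 4: ", geo$n_clusters, " geo clusters -> ",
          cfg$k_zones, " adaptation zones")

  # ---- stage 5: mixed-model evaluation ----------------------------------
  mdata <- blues
  mdata$location <- meta$location[match(mdata$trial, meta$trial)]
  mdata$year <- meta$year[match(mdata$trial, meta$trial)]
  if (!"weight" %in% names(mdata)) mdata$weight <- 1
  mdata$zone <- unname(tz[mdata$trial])
  target <- traits[1]
  m2 <- fit_model2(mdata, response = target)
  m6 <- fit_model6(mdata, response = target)
  pg <- percent_gxe(m2)
  gz <- gz_share(m6)
  sel <- selection_from_fit(m6, mdata)
  log_msg("stage 5: %GxE (GY/GL/GLY) = ",
          paste(pg, collapse = "/"), "; GZ share = ", gz,
          "; CR/DR = ", round(sel$cr_dr, 3))

  cv <- NULL
  if (isTRUE(cfg$cv)) {
    cv <- loyo_cv(mdata, response = target)
    log_msg("stage 6: CV accuracy main ", round(cv$mean_main, 3),
            " vs zones ", round(cv$mean_zone, 3))
  }

  res <- structure(list(config = cfg, met = met, blues = blues,
                        trait_matrices = tm_scaled, stack = stack,
                        genotype_weights = gweights, som = som, ets = ets,
                        geo = geo, freq = freq, zones = zones,
                        trial_zone = tz, model2 = m2, model6 = m6,
                        percent_gxe = pg, gz_share = gz, selection = sel,
                        cv = cv),
                   class = "met_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.met_pipeline <- function(x, ...) {
  cat("MET classification pipeline (seed ", x$config$seed, ", ",
      x$config$arrangement, " arrangement)\n", sep = "")
  cat(" trials: ", length(x$trial_zone), ", ETs: ", x$ets$k_et,
      ", zones: ", x$zones$k_zones, "\n", sep = "")
  cat(" %GxE (GY/GL/GLY): ", paste(x$percent_gxe, collapse = " / "),
      "\n", sep = "")
  cat(" GZ share: ", x$gz_share, "; CR/DR: ",
      round(x$selection$cr_dr, 3), "\n", sep = "")
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$blues, "blues.csv")
  asn <- res$ets$assignment
  asn$et <- res$ets$trial_et[asn$object]
  names(asn)[1] <- "trial"
  asn$geo_cluster <- res$geo$cluster[asn$trial]
  asn$zone <- res$trial_zone[asn$trial]
  wcsv(asn, "trial_assignment.csv")
  wcsv(data.frame(geo_cluster = rownames(res$freq$counts),
                  res$freq$counts, check.names = FALSE),
       "et_frequency.csv")
  wcsv(data.frame(geo_cluster = names(res$zones$cluster_zone),
                  zone = res$zones$cluster_zone), "zones.csv")
  vc <- rbind(
    data.frame(model = "model2", component = names(res$model2$components),
               estimate = unname(res$model2$components),
               se = unname(res$model2$se)),
    data.frame(model = "model6", component = names(res$model6$components),
               estimate = unname(res$model6$components),
               se = unname(res$model6$se)))
  wcsv(vc, "variance_components.csv")
  sel <- res$selection
  wcsv(data.frame(rho_g = sel$rho_g, h2_undivided = sel$h2_undivided,
                  h2_divided = sel$h2_divided, cr_dr = sel$cr_dr,
                  nl = sel$inputs$nl, ny = sel$inputs$ny,
                  nz = sel$inputs$nz), "selection_response.csv")
  if (!is.null(res$cv)) wcsv(res$cv$trials, "cv_accuracy.csv")
  manifest <- res$config
  manifest$som <- NULL
  yaml::write_yaml(list(config = res$config,
                        n_trials = length(res$trial_zone)),
                   file.path(out_dir, "manifest.yml"))
  invisible(out_dir)
}

#' Compare the adaptation zones of two pipeline runs
#'
#' Per-zone balanced accuracies of an alternative run's zones against a
#' reference run's zones (labels aligned by maximum overlap), mirroring
#' the comparison of layer arrangements and trait subsets.
#'
#' @param ref,alt `met_pipeline` objects on the same trial set.
#' @return named numeric vector of per-zone balanced accuracies.
#' @export
compare_zones <- function(ref, alt) {
  stopifnot(inherits(ref, "met_pipeline"), inherits(alt, "met_pipeline"))
  balanced_accuracy(ref$trial_zone, alt$trial_zone)
}
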