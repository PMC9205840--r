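# Shared fixture builders (all generated in code, seeded by the caller).

# small zone-structured trial-level network for mixed-model tests
zone_structured_met <- function(seed = 11, n_genotypes = 15, n_zones = 4,
                                locations_per_zone = 2, n_years = 4,
                                var_gz = 400) {
  cfg <- sim_config(n_genotypes = n_genotypes, n_zones = n_zones,
                    locations_per_zone = locations_per_zone,
                    n_years = n_years,
                    var_g = 20, var_gz = var_gz, var_glz = 5, var_gy = 5,
                    var_gzy = 5, var_glzy = 10, mu = 1000, var_trial = 100,
                    var_plot = 20, n_replicates = 2, seed = seed)
  simulate_met(cfg, level = "trial")
}

# two geographic regimes with clearly distinct ET frequency profiles
planted_two_regimes <- function(seed = 5, n_clusters = 8, per_cluster = 20) {
  set.seed(seed)
  trials <- sprintf("t%03d", seq_len(n_clusters * per_cluster))
  geo <- stats::setNames(rep(sprintf("c%d", seq_len(n_clusters)),
                             each = per_cluster), trials)
  regime <- ifelse(as.integer(sub("c", "", geo)) <= n_clusters / 2, 1L, 2L)
  et <- ifelse(regime == 1,
               sample(1:3, length(trials), TRUE, prob = c(.7, .2, .1)),
               sample(4:6, length(trials), TRUE, prob = c(.2, .3, .5)))
  list(trial_et = stats::setNames(et, trials), geo = geo,
       truth = stats::setNames(regime, trials))
}

# random single-layer stack
random_stack <- function(seed, n = 20, p = 3) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("o%02d", seq_len(n)),
                              sprintf("v%d", seq_len(p))))
  layer_stack(list(main = X), "sumsquares", 1)
}
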