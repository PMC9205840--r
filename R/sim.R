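#' Configuration for a synthetic multi-environment trial network
#'
#' Defines the genetic and environmental structure of a simulated trial
#' network: a crossed genotype x location x year design with locations nested
#' in adaptation zones, variance components for the genotype main effect and
#' all its interactions with zone, location and year, a row-column field
#' layout with AR1xAR1 spatial plot noise, optional correlated secondary
#' traits, and a zone-specific probability of binary (parasite-pressure-like)
#' incidence.
#'
#' Trait values decompose as trial intercept + G + GZ + GL(Z) + GY + GZY +
#' GL(Z)Y plus field noise; all effects are independent zero-mean normal
#' draws with the configured variances.  Trial intercepts are drawn from a
#' normal with mean `mu` and variance `var_trial` (in a real analysis they
#' are fixed effects; a simulation needs a distribution for them).
#'
#' The defaults mirror a European sunflower-scale network: 22 genotypes,
#' 4 zones x 5 locations x 7 years, yield-like variance components of a few
#' thousand (trait units squared).
#'
#' @param n_genotypes,n_zones,locations_per_zone,n_years design counts.
#' @param var_g,var_gz,var_glz,var_gy,var_gzy,var_glzy variance components
#'   (trait units squared) for G, GxZ, GxL(Z), GxY, GxZxY, GxL(Z)xY.
#' @param mu,var_trial mean and variance of the trial intercepts.
#' @param rows,cols,n_replicates field layout for plot-level simulation.
#' @param var_row,var_col,rho_row,rho_col,var_plot spatial parameters: row
#'   and column effect variances, AR1 correlations along rows and columns,
#'   and the plot (residual) variance.
#' @param traits character vector of trait names; the first is the target
#'   trait.
#' @param trait_cor correlation matrix (traits x traits) for the genotype
#'   main effects across traits; identity if `NULL`.
#' @param incidence_prob per-zone probability of 'high' binary incidence;
#'   defaults to a decreasing gradient across zones.
#' @param missing_rate probability that a trial x (secondary) trait
#'   combination is masked, missing completely at random.
#' @param seed integer seed; all randomness in [simulate_met()] derives
#'   from it (R's default Mersenne-Twister generator).
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_met()]
#' @export
sim_config <- function(n_genotypes = 22, n_zones = 4, locations_per_zone = 5,
                       n_years = 7,
                       var_g = 9600, var_gz = 9600, var_glz = 6800,
                       var_gy = 1960, var_gzy = 390, var_glzy = 32600,
                       mu = 3000, var_trial = 250000,
                       rows = 6, cols = 8, n_replicates = 2,
                       var_row = 2000, var_col = 2000,
                       rho_row = 0.4, rho_col = 0.4, var_plot = 40000,
                       traits = "yield", trait_cor = NULL,
                       incidence_prob = NULL, missing_rate = 0, seed = 1L) {
  vars <- c(var_g = var_g, var_gz = var_gz, var_glz = var_glz,
            var_gy = var_gy, var_gzy = var_gzy, var_glzy = var_glzy,
            var_trial = var_trial, var_row = var_row, var_col = var_col,
            var_plot = var_plot)
  stop_if(any(!is.finite(vars)) || any(vars < 0),
          "all variance components must be finite and >= 0")
  stop_if(abs(rho_row) >= 1 || abs(rho_col) >= 1,
          "|rho_row| and |rho_col| must be < 1")
  n_traits <- length(traits)
  if (is.null(trait_cor)) trait_cor <- diag(n_traits)
  trait_cor <- as.matrix(trait_cor)
  stop_if(!isTRUE(all.equal(dim(trait_cor), c(n_traits, n_traits))),
          "trait_cor must be ", n_traits, " x ", n_traits)
  stop_if(min(eigen(trait_cor, symmetric = TRUE,
                    only.values = TRUE)$values) < -1e-8,
          "trait_cor must be positive semidefinite")
  if (is.null(incidence_prob))
    incidence_prob <- if (n_zones == 1) 0.5 else
      seq(0.8, 0.1, length.out = n_zones)
  stop_if(length(incidence_prob) != n_zones ||
            any(incidence_prob < 0 | incidence_prob > 1),
          "incidence_prob must be one probability per zone")
  stop_if(missing_rate < 0 || missing_rate > 1, "missing_rate in [0,1]")
  cfg <- list(n_genotypes = as.integer(n_genotypes),
              n_zones = as.integer(n_zones),
              locations_per_zone = as.integer(locations_per_zone),
              n_years = as.integer(n_years),
              var_g = var_g, var_gz = var_gz, var_glz = var_glz,
              var_gy = var_gy, var_gzy = var_gzy, var_glzy = var_glzy,
              mu = mu, var_trial = var_trial,
              rows = as.integer(rows), cols = as.integer(cols),
              n_replicates = as.integer(n_replicates),
              var_row = var_row, var_col = var_col,
              rho_row = rho_row, rho_col = rho_col, var_plot = var_plot,
              traits = traits, trait_cor = trait_cor,
              incidence_prob = incidence_prob,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rnorm_v <- function(n, var) if (var == 0) numeric(n) else
  stats::rnorm(n, 0, sqrt(var))

#' Simulate a multi-environment trial network
#'
#' Draws all genetic effects (G, GxZ, GxL(Z), GxY, GxZxY, GxL(Z)xY) and trial
#' intercepts from the configured normal distributions, lays out a network of
#' location x year trials with geographic coordinates clustered by zone, and
#' returns either trial-level genotype values (true genotype-by-trial means
#' plus an effective trial-level error, with weights) or full plot-level
#' row-column fields with AR1xAR1 spatial noise.
#'
#' At `level = "trial"` the observation error variance is
#' `var_plot / n_replicates` (the variance of a replicate mean) and the
#' returned `weight` column is its reciprocal, mimicking the weights carried
#' forward from per-trial spatial analyses.  At `level = "plot"` each trial
#' is an independent call to [simulate_trial_plots()].
#'
#' @param config a [sim_config()] object.
#' @param level `"trial"` for genotype-by-trial values, `"plot"` for full
#'   field layouts.
#' @return an object of class `sim_met`: a list with `data` (trial-level
#'   table: genotype, location, year, zone, trial, one column per trait,
#'   weight), `plots` (plot-level table or `NULL`), `trials` (trial metadata:
#'   trial, location, year, zone, latitude, longitude, incidence), and
#'   `truth` (all sampled effects plus the config).
#' @export
simulate_met <- function(config, level = c("trial", "plot")) {
  stopifnot(inherits(config, "sim_config"))
  level <- match.arg(level)
  set.seed(config$seed)
  cf <- config
  gen <- sprintf("g%02d", seq_len(cf$n_genotypes))
  zone <- sprintf("z%d", seq_len(cf$n_zones))
  loc <- as.vector(t(outer(zone, seq_len(cf$locations_per_zone),
                           function(z, l) paste0(z, "_l", l))))
  loc_zone <- rep(zone, each = cf$locations_per_zone)
  year <- sprintf("y%d", seq_len(cf$n_years))
  n_loc <- length(loc)
  n_traits <- length(cf$traits)

  # geography: zone centres spread across a Europe-like lat/lon box,
  # locations jittered around their centre
  centre_lat <- seq(37, 48, length.out = cf$n_zones)
  centre_lon <- seq(-4, 28, length.out = cf$n_zones)
  lat <- centre_lat[match(loc_zone, zone)] + stats::runif(n_loc, -0.9, 0.9)
  lon <- centre_lon[match(loc_zone, zone)] + stats::runif(n_loc, -0.9, 0.9)

  # genotype main effects, correlated across traits
  L <- t(chol(cf$trait_cor + diag(1e-10, n_traits)))
  G <- matrix(stats::rnorm(cf$n_genotypes * n_traits), cf$n_genotypes) %*%
    t(L) * sqrt(cf$var_g)
  if (cf$var_g == 0) G[] <- 0
  dimnames(G) <- list(gen, cf$traits)

  draw <- function(dims, var, dn) {
    x <- array(rnorm_v(prod(dims) * n_traits, var), c(dims, n_traits))
    dimnames(x) <- c(dn, list(cf$traits))
    x
  }
  GZ  <- draw(c(cf$n_genotypes, cf$n_zones), cf$var_gz, list(gen, zone))
  GL  <- draw(c(cf$n_genotypes, n_loc), cf$var_glz, list(gen, loc))
  GY  <- draw(c(cf$n_genotypes, cf$n_years), cf$var_gy, list(gen, year))
  GZY <- draw(c(cf$n_genotypes, cf$n_zones, cf$n_years), cf$var_gzy,
              list(gen, zone, year))
  GLY <- draw(c(cf$n_genotypes, n_loc, cf$n_years), cf$var_glzy,
              list(gen, loc, year))

  trials <- expand.grid(location = loc, year = year,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trials$zone <- loc_zone[match(trials$location, loc)]
  trials$trial <- paste(trials$location, trials$year, sep = ".")
  trials$latitude <- lat[match(trials$location, loc)]
  trials$longitude <- lon[match(trials$location, loc)]
  n_trial <- nrow(trials)
  intercepts <- matrix(cf$mu + rnorm_v(n_trial * n_traits, cf$var_trial),
                       n_trial, n_traits,
                       dimnames = list(trials$trial, cf$traits))
  pz <- cf$incidence_prob[match(trials$zone, zone)]
  trials$incidence <- ifelse(stats::rbinom(n_trial, 1, pz) == 1,
                             "high", "low")

  # true genotype-by-trial means per trait
  idx_l <- match(trials$location, loc)
  idx_z <- match(trials$zone, zone)
  idx_y <- match(trials$year, year)
  data <- expand.grid(genotype = gen, trial = trials$trial,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  it <- match(data$trial, trials$trial)
  ig <- match(data$genotype, gen)
  data$location <- trials$location[it]
  data$year <- trials$year[it]
  data$zone <- trials$zone[it]
  true_mean <- matrix(0, nrow(data), n_traits,
                      dimnames = list(NULL, cf$traits))
  for (tr in seq_len(n_traits)) {
    true_mean[, tr] <- intercepts[it, tr] + G[ig, tr] +
      GZ[cbind(ig, idx_z[it], tr)] + GL[cbind(ig, idx_l[it], tr)] +
      GY[cbind(ig, idx_y[it], tr)] + GZY[cbind(ig, idx_z[it], idx_y[it], tr)] +
      GLY[cbind(ig, idx_l[it], idx_y[it], tr)]
  }

  plots <- NULL
  if (level == "plot") {
    plot_list <- vector("list", n_trial)
    for (j in seq_len(n_trial)) {
      rows_j <- which(it == j)
      per_trait <- lapply(seq_len(n_traits), function(tr) {
        gm <- true_mean[rows_j, tr]
        names(gm) <- data$genotype[rows_j]
        simulate_trial_plots(gm, rows = cf$rows, cols = cf$cols,
                             n_replicates = cf$n_replicates,
                             var_row = cf$var_row, var_col = cf$var_col,
                             rho_row = cf$rho_row, rho_col = cf$rho_col,
                             var_plot = cf$var_plot)
      })
      pj <- per_trait[[1]][c("genotype", "replicate", "row", "col")]
      for (tr in seq_len(n_traits)) pj[[cf$traits[tr]]] <- per_trait[[tr]]$value
      pj <- cbind(trial = trials$trial[j], location = trials$location[j],
                  year = trials$year[j], zone = trials$zone[j], pj)
      plot_list[[j]] <- pj
    }
    plots <- do.call(rbind, plot_list)
    rownames(plots) <- NULL
  }

  err_var <- cf$var_plot / cf$n_replicates
  for (tr in seq_len(n_traits))
    data[[cf$traits[tr]]] <- true_mean[, tr] +
      rnorm_v(nrow(data), err_var)
  data$weight <- if (err_var > 0) 1 / err_var else 1
  if (cf$missing_rate > 0 && n_traits > 1) {
    for (tr in cf$traits[-1]) {
      drop <- trials$trial[stats::runif(n_trial) < cf$missing_rate]
      data[[tr]][data$trial %in% drop] <- NA_real_
    }
  }

  structure(list(data = data, plots = plots, trials = trials,
                 truth = list(intercepts = intercepts, G = G, GZ = GZ,
                              GL = GL, GY = GY, GZY = GZY, GLY = GLY,
                              true_mean = true_mean, config = cf)),
            class = "sim_met")
}

#' @export
print.sim_met <- function(x, ...) {
  cf <- x$truth$config
  cat("Simulated MET network:", cf$n_genotypes, "genotypes,",
      nrow(x$trials), "trials (", cf$n_zones, "zones x",
      cf$locations_per_zone, "locations x", cf$n_years, "years)\n")
  cat("Traits:", paste(cf$traits, collapse = ", "),
      if (!is.null(x$plots)) sprintf("| %d plots", nrow(x$plots)), "\n")
  invisible(x)
}

#' Simulate one row-column field trial
#'
#' Places genotype replicates at random on a rows x cols grid and adds
#' independent random row effects, random column effects, and a spatially
#' correlated plot error with separable AR1xAR1 correlation: plots separated
#' by `dr` rows and `dc` columns have error correlation
#' `rho_row^dr * rho_col^dc` and variance `var_plot`.
#'
#' @param genotype_means named numeric vector of true genotype means.
#' @param rows,cols layout dimensions.
#' @param n_replicates replicates per genotype.
#' @param var_row,var_col,rho_row,rho_col,var_plot spatial parameters.
#' @return data frame with columns genotype, replicate, row, col, value.
#' @export
simulate_trial_plots <- function(genotype_means, rows, cols,
                                 n_replicates = 1,
                                 var_row = 0, var_col = 0,
                                 rho_row = 0, rho_col = 0, var_plot = 1) {
  stop_if(is.null(names(genotype_means)), "genotype_means must be named")
  stop_if(abs(rho_row) >= 1 || abs(rho_col) >= 1, "|rho| must be < 1")
  stop_if(any(c(var_row, var_col, var_plot) < 0), "variances must be >= 0")
  n_entry <- length(genotype_means) * n_replicates
  stop_if(n_entry > rows * cols,
          "layout too small: ", n_entry, " plots needed, ",
          rows * cols, " available")
  cells <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  use <- cells[sample.int(nrow(cells), n_entry), ]
  entries <- data.frame(
    genotype = rep(names(genotype_means), each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(genotype_means)),
    stringsAsFactors = FALSE)
  entries$row <- use$row
  entries$col <- use$col

  row_eff <- rnorm_v(rows, var_row)
  col_eff <- rnorm_v(cols, var_col)
  E <- matrix(0, rows, cols)
  if (var_plot > 0) {
    Lr <- t(chol(ar1_cor(seq_len(rows), rho_row)))
    Lc <- chol(ar1_cor(seq_len(cols), rho_col))
    E <- sqrt(var_plot) * (Lr %*% matrix(stats::rnorm(rows * cols),
                                         rows, cols) %*% Lc)
  }
  entries$value <- genotype_means[entries$genotype] +
    row_eff[entries$row] + col_eff[entries$col] +
    E[cbind(entries$row, entries$col)]
  rownames(entries) <- NULL
  entries
}

#' Summarize daily environmental variables over developmental periods
#'
#' Computes, for each genotype x trial x developmental period, the mean of
#' each daily environmental variable over that period.  Stage (period)
#' boundaries are genotype-and-trial specific, as produced by a phenology
#' model; the daily weather table is user-supplied.
#'
#' @param stage_dates data frame with columns genotype, trial, period,
#'   start, end (inclusive day indices or dates comparable to
#'   `weather$day`).
#' @param weather data frame with columns trial, day, plus one numeric
#'   column per variable.
#' @return data frame with one row per genotype x trial and one column
#'   `<period>_<variable>_mean` per period x variable.
#' @export
simulate_covariables <- function(stage_dates, weather) {
  need <- c("genotype", "trial", "period", "start", "end")
  stop_if(!all(need %in% names(stage_dates)),
          "stage_dates needs columns: ", paste(need, collapse = ", "))
  stop_if(!all(c("trial", "day") %in% names(weather)),
          "weather needs columns trial, day")
  vars <- setdiff(names(weather), c("trial", "day"))
  stop_if(length(vars) == 0, "weather has no variable columns")
  stop_if(any(stage_dates$end < stage_dates$start),
          "zero or negative length period in stage_dates")
  rng <- range(weather$day)
  stop_if(any(stage_dates$start < rng[1] | stage_dates$end > rng[2]),
          "stage dates outside weather date range")

  out <- unique(stage_dates[c("genotype", "trial")])
  rownames(out) <- NULL
  for (p in unique(stage_dates$period)) for (v in vars)
    out[[paste0(p, "_", v, "_mean")]] <- NA_real_
  wsplit <- split(weather, weather$trial)
  for (i in seq_len(nrow(stage_dates))) {
    s <- stage_dates[i, ]
    w <- wsplit[[as.character(s$trial)]]
    stop_if(is.null(w), "no weather for trial ", s$trial)
    sel <- w$day >= s$start & w$day <= s$end
    stop_if(!any(sel), "empty period ", s$period, " for trial ", s$trial)
    j <- which(out$genotype == s$genotype & out$trial == s$trial)
    for (v in vars)
      out[j, paste0(s$period, "_", v, "_mean")] <- mean(w[[v]][sel])
  }
  out
}

#' Write a simulated network to delimited text files
#'
#' Writes the trial-level data, trial metadata, plot table (if present) and
#' the sampled true effects as CSV files under `dir`.
#'
#' @param met a [simulate_met()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_met <- function(met, dir) {
  stopifnot(inherits(met, "sim_met"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(data = file.path(dir, "trial_data.csv"),
             trials = file.path(dir, "trial_metadata.csv"))
  utils::write.csv(met$data, files["data"], row.names = FALSE)
  utils::write.csv(met$trials, files["trials"], row.names = FALSE)
  if (!is.null(met$plots)) {
    files["plots"] <- file.path(dir, "plot_data.csv")
    utils::write.csv(met$plots, files["plots"], row.names = FALSE)
  }
  truth <- met$truth
  files["truth_g"] <- file.path(dir, "truth_genotype_effects.csv")
  utils::write.csv(data.frame(genotype = rownames(truth$G), truth$G,
                              check.names = FALSE),
                   files["truth_g"], row.names = FALSE)
  invisible(files)
}
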