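test_that("REML equals closed-form ANOVA estimators on balanced designs", {
  set.seed(4)
  a <- 8; r <- 6
  grp <- rep(sprintf("g%d", 1:a), each = r)
  y <- 5 + stats::rnorm(a, 0, 2)[as.integer(factor(grp))] +
    stats::rnorm(a * r, 0, 1.5)
  d <- data.frame(y = y, group = grp, one = "x")
  fit <- reml_fit(d, "y", fixed = "one", random = list(A = "group"))
  av <- stats::anova(stats::lm(y ~ grp))
  msa <- av$`Mean Sq`[1]; mse <- av$`Mean Sq`[2]
  expect_equal(unname(fit$components["A"]), (msa - mse) / r,
               tolerance = 1e-6)
  expect_equal(unname(fit$components["residual"]), mse, tolerance = 1e-6)

  # two-way crossed, genotype random + residual, fixed environments
  set.seed(5)
  g <- 10; e <- 8
  dd <- expand.grid(genotype = sprintf("g%02d", 1:g),
                    env = sprintf("e%d", 1:e), stringsAsFactors = FALSE)
  dd$y <- stats::rnorm(g, 0, 3)[as.integer(factor(dd$genotype))] +
    stats::rnorm(e, 20, 2)[as.integer(factor(dd$env))] +
    stats::rnorm(g * e, 0, 1)
  f2 <- reml_fit(dd, "y", fixed = "env", random = list(G = "genotype"))
  av2 <- stats::anova(stats::lm(y ~ env + genotype, dd))
  msg <- av2["genotype", "Mean Sq"]; mse2 <- av2["Residuals", "Mean Sq"]
  expect_equal(unname(f2$components["G"]), (msg - mse2) / e,
               tolerance = 1e-6)
})

test_that("zero-variance data drive components to the boundary", {
  set.seed(6)
  dd <- expand.grid(genotype = sprintf("g%02d", 1:8),
                    env = sprintf("e%d", 1:6), stringsAsFactors = FALSE)
  dd$y <- stats::rnorm(6, 0, 2)[as.integer(factor(dd$env))] +
    stats::rnorm(48, 0, 0.1)
  dd$w <- 100
  # no genotype signal at all: G at (or near) zero
  f <- reml_fit(dd, "y", fixed = "env", random = list(G = "genotype"),
                weights = "w")
  expect_lt(unname(f$components["G"]), 0.01)
})

test_that("model 2 recovers simulated components within 3 SE", {
  cfg <- sim_config(n_genotypes = 20, n_zones = 3, locations_per_zone = 5,
                    n_years = 5, var_g = 100, var_gz = 0, var_glz = 50,
                    var_gy = 25, var_gzy = 0, var_glzy = 200, mu = 1000,
                    var_trial = 400, var_plot = 100, n_replicates = 2,
                    seed = 42)
  met <- simulate_met(cfg, level = "trial")
  m2 <- fit_model2(met$data)
  truth <- c(G = 100, GL = 50, GY = 25, GLY = 200)
  z <- abs(m2$components[names(truth)] - truth) / m2$se[names(truth)]
  expect_true(all(z < 3))
  # weights = 1/SE^2 convention: the percent shares are well defined
  expect_equal(sum(percent_gxe(m2)), 100, tolerance = 0.02)
})

test_that("model 6 recovers zone-nested components within 3 SE", {
  cfg <- sim_config(n_genotypes = 20, n_zones = 3, locations_per_zone = 5,
                    n_years = 5, var_g = 100, var_gz = 80, var_glz = 50,
                    var_gy = 25, var_gzy = 10, var_glzy = 200, mu = 1000,
                    var_trial = 400, var_plot = 100, n_replicates = 2,
                    seed = 43)
  met <- simulate_met(cfg, level = "trial")
  m6 <- fit_model6(met$data)
  truth <- c(G = 100, GZ = 80, `GL(Z)` = 50, GY = 25, GZY = 10,
             `GL(Z)Y` = 200)
  z <- abs(m6$components[names(truth)] - truth) / m6$se[names(truth)]
  expect_true(all(z < 3))
})

test_that("model 5's zone covariance is positive semidefinite and nests
           the iid genotype-by-zone special case", {
  met <- zone_structured_met(seed = 11)
  m5 <- fit_model5(met$data)
  ev <- eigen(m5$sigma_z, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # diagonal should carry roughly var_g + var_gz of the simulation
  expect_gt(mean(diag(m5$sigma_z)), 100)
  # the iid-GZ variant (Sigma_z = a I, no zone covariances) is nested in
  # the unstructured fit: its restricted likelihood cannot exceed model 5's
  d <- met$data
  d$trial_f <- interaction(d$location, d$year, drop = TRUE)
  m_iid <- reml_fit(d, "yield", fixed = "trial_f",
                    random = list(GZ = c("genotype", "zone"),
                                  GE = c("genotype", "trial_f")),
                    weights = "weight")
  expect_gte(m5$loglik, m_iid$loglik - 1e-4)
})

test_that("doubling all weights shifts only the fixed-scale residual share", {
  met <- zone_structured_met(seed = 13, n_zones = 2, var_gz = 50)
  d <- met$data
  d2 <- d; d2$weight <- 2 * d2$weight
  m <- fit_model4(d); m2 <- fit_model4(d2)
  # BLUP ranking of genotypes is essentially unchanged
  expect_gt(stats::cor(ranef_vc(m, "G"), ranef_vc(m2, "G")), 0.999)
})

test_that("pure-noise covariables yield boundary slopes; a planted slope
           covariable is ranked first among decoys", {
  set.seed(21)
  ng <- 12; ne <- 24
  d <- expand.grid(genotype = sprintf("g%02d", 1:ng),
                   location = sprintf("l%02d", 1:ne),
                   stringsAsFactors = FALSE)
  d$year <- "y1"
  loc_i <- match(d$location, sprintf("l%02d", 1:ne))
  zstar <- stats::rnorm(ne)[loc_i]
  beta <- stats::rnorm(ng, 0, 2)[as.integer(factor(d$genotype))]
  d$yield <- stats::rnorm(ne, 50, 5)[loc_i] +
    stats::rnorm(ng, 0, 1)[as.integer(factor(d$genotype))] +
    beta * zstar + stats::rnorm(nrow(d), 0, 0.8)
  covs <- data.frame(zstar = zstar)
  for (k in 1:6)
    covs[[paste0("noise", k)]] <- stats::rnorm(ne)[loc_i]
  sc <- factorial_regression_scan(d, covs)
  expect_equal(nrow(sc), 7)              # K covariables -> K records
  expect_equal(sc$covariable[1], "zstar")
  expect_lt(sc$p[1], 1e-10)
  # on purely additive data every slope variance sits at the boundary
  d0 <- d
  d0$yield <- d0$yield - beta * zstar
  sc0 <- factorial_regression_scan(d0, covs[1:3])
  # slope variances collapse towards the boundary (tiny vs the residual)
  expect_true(all(sc0$slope_var < 0.1 * sc0$resid_var))
  # and the once-causal covariable now has an exactly-zero slope, LRT ~ 0
  expect_equal(sc0$slope_var[sc0$covariable == "zstar"], 0)
  expect_lt(sc0$lrt[sc0$covariable == "zstar"], 1e-6)
  sel <- forward_select(d, covs)
  expect_equal(sel[1], "zstar")
  # constant covariable skipped with warning
  covs$flat <- 1
  expect_error(suppressWarnings(factorial_regression_scan(d, covs["flat"])),
               "usable")
})

test_that("leave-one-year-out predictions never see the held-out year and
           the zone model wins under strong zone structure", {
  met <- zone_structured_met(seed = 11)
  cv <- loyo_cv(met$data)
  expect_gt(cv$mean_zone, cv$mean_main)
  # every trial of every year is scored exactly once
  expect_setequal(unique(cv$trials$year), unique(met$data$year))
  expect_equal(nrow(cv$trials),
               length(unique(paste(met$data$location, met$data$year))))
})
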