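test_that("with iid residuals forced, BLUEs are genotype plot means", {
  set.seed(1)
  gm <- stats::setNames(c(10, 12, 8, 11), letters[1:4])
  pl <- simulate_trial_plots(gm, rows = 4, cols = 4, n_replicates = 4,
                             var_plot = 2)
  fit <- fit_trial_model(pl, trait = "value", varcomp = list(var_plot = 2))
  mn <- tapply(pl$value, pl$genotype, mean)
  expect_equal(fit$blues$blue, as.vector(mn[fit$blues$genotype]),
               tolerance = 1e-10)
  expect_equal(fit$blues$weight, 1 / fit$blues$se^2)
})

test_that("fixed variance parameters reproduce the explicit GLS solution", {
  set.seed(2)
  gm <- stats::setNames(c(10, 12, 8, 11), letters[1:4])
  pl <- simulate_trial_plots(gm, rows = 4, cols = 4, n_replicates = 2,
                             var_row = 1, var_col = 1, rho_row = 0.5,
                             rho_col = 0.3, var_plot = 4)
  fit <- fit_trial_model(pl, trait = "value",
                         varcomp = list(var_row = 1, var_col = 1,
                                        var_plot = 4, rho_row = 0.5,
                                        rho_col = 0.3))
  # closed-form GLS oracle by explicit matrix inversion
  n <- nrow(pl)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- 4 * 0.5^abs(pl$row[i] - pl$row[j]) *
      0.3^abs(pl$col[i] - pl$col[j]) +
      (pl$row[i] == pl$row[j]) + (pl$col[i] == pl$col[j])
  X <- stats::model.matrix(~ 0 + factor(pl$genotype))
  beta <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% pl$value)
  expect_equal(fit$blues$blue, drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
  se <- sqrt(diag(solve(t(X) %*% solve(V) %*% X)))
  expect_equal(fit$blues$se, unname(se), tolerance = 1e-10)
})

test_that("REML recovers spatial parameters within sampling error", {
  # moderate layout, average estimates over repeated fields
  set.seed(3)
  gm <- stats::setNames(stats::rnorm(12, 100, 4), sprintf("g%02d", 1:12))
  ests <- t(replicate(8, {
    pl <- simulate_trial_plots(gm, rows = 8, cols = 9, n_replicates = 4,
                               var_row = 2, var_col = 2, rho_row = 0.5,
                               rho_col = 0.4, var_plot = 9)
    fit_trial_model(pl, trait = "value")$varcomp[c("rho_row", "rho_col",
                                                   "var_plot")]
  }))
  expect_lt(abs(mean(ests[, "rho_row"]) - 0.5), 0.15)
  expect_lt(abs(mean(ests[, "rho_col"]) - 0.4), 0.15)
  expect_lt(abs(mean(ests[, "var_plot"]) - 9) / 9, 0.35)
})

test_that("rho = 0 restricted likelihood matches the iid model", {
  set.seed(4)
  gm <- stats::setNames(c(5, 7, 6), c("a", "b", "c"))
  pl <- simulate_trial_plots(gm, rows = 3, cols = 4, n_replicates = 4,
                             var_plot = 1)
  f_sp <- fit_trial_model(pl, trait = "value",
                          varcomp = list(var_plot = 1.3, rho_row = 0,
                                         rho_col = 0))
  f_iid <- fit_trial_model(pl, trait = "value",
                           varcomp = list(var_plot = 1.3))
  expect_equal(f_sp$loglik, f_iid$loglik, tolerance = 1e-10)
})

test_that("AR1xAR1 correlation is positive definite for |rho| < 1", {
  for (rho in c(-0.95, -0.3, 0, 0.6, 0.97)) {
    C <- outer(1:7, 1:7, function(i, j) rho^abs(i - j))
    expect_no_error(chol(C))
  }
})

test_that("network batch driver preserves trials and flags failures", {
  set.seed(5)
  gm <- stats::setNames(c(4, 6, 5, 7), letters[1:4])
  mk <- function(id) cbind(trial = id,
                           simulate_trial_plots(gm, 4, 4, 2, var_plot = 1))
  pl <- rbind(mk("tA"), mk("tB"))
  out <- blues_for_network(pl, trait = "value", varcomp = list(var_plot = 1))
  expect_setequal(unique(out$trial), c("tA", "tB"))
  # order independence
  out2 <- blues_for_network(pl[rev(seq_len(nrow(pl))), ], trait = "value",
                            varcomp = list(var_plot = 1))
  m1 <- out[order(out$trial, out$genotype), c("blue", "se")]
  m2 <- out2[order(out2$trial, out2$genotype), c("blue", "se")]
  expect_equal(m1, m2, ignore_attr = TRUE)
  # one broken trial (single genotype) -> flagged row, not an abort
  bad <- mk("tC")
  bad$genotype <- "a"
  bad <- bad[!duplicated(bad[c("row", "col")]), ]
  out3 <- blues_for_network(rbind(pl, bad), trait = "value",
                            varcomp = list(var_plot = 1))
  expect_true(any(!out3$ok))
  expect_named(attr(out3, "failures"))
})

test_that("BLUEs are unbiased for the simulated true genotype means", {
  cfg <- sim_config(n_genotypes = 8, n_zones = 2, locations_per_zone = 2,
                    n_years = 2, var_g = 25, var_gz = 10, var_glz = 10,
                    var_gy = 5, var_gzy = 2, var_glzy = 20, mu = 100,
                    var_trial = 50, rows = 4, cols = 4, n_replicates = 2,
                    var_row = 2, var_col = 2, rho_row = 0.3, rho_col = 0.3,
                    var_plot = 9, seed = 31)
  met <- simulate_met(cfg, level = "plot")
  out <- blues_for_network(met$plots, trait = "yield")
  key_out <- paste(out$trial, out$genotype)
  key_truth <- paste(met$data$trial, met$data$genotype)
  err <- out$blue - met$truth$true_mean[match(key_out, key_truth), "yield"]
  # mean error ~ N(0, avg SE^2 / n): 3-sigma Monte-Carlo bound
  bound <- 3 * sqrt(mean(out$se^2) / nrow(out))
  expect_lt(abs(mean(err)), bound * 2)
})
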