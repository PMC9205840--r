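test_that("additive imputation matches the normal-equations oracle", {
  m <- matrix(c(10, 30, 20, NA), 2, 2,
              dimnames = list(c("t1", "t2"), c("g1", "g2")))
  out <- impute_additive(m)
  expect_equal(out["t2", "g2"], 40)      # 30 + 20 - 10, saturated fit
  expect_equal(out[!is.na(m)], m[!is.na(m)])   # observed untouched
  expect_equal(impute_additive(out), out)      # idempotent
  # complete matrix unchanged
  expect_identical(impute_additive(out), out)
  # larger case vs direct least squares on observed cells
  set.seed(1)
  M <- outer(stats::rnorm(6), rep(1, 5)) + outer(rep(1, 6), stats::rnorm(5)) +
    matrix(stats::rnorm(30, 0, .2), 6, 5)
  dimnames(M) <- list(paste0("t", 1:6), paste0("g", 1:5))
  Mna <- M; Mna[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  imp <- impute_additive(Mna)
  # independent oracle: explicit indicator design, least squares via qr
  obs <- which(!is.na(Mna), arr.ind = TRUE)
  D <- cbind(1, outer(obs[, 1], 2:6, "==") * 1, outer(obs[, 2], 2:5, "==") * 1)
  cf <- qr.solve(D, Mna[obs])
  fitted_cell <- function(i, j)
    cf[1] + (if (i > 1) cf[i] else 0) + (if (j > 1) cf[5 + j] else 0)
  for (k in 1:3) {
    ij <- cbind(c(1, 3, 5), c(2, 4, 1))[k, ]
    expect_equal(imp[ij[1], ij[2]], fitted_cell(ij[1], ij[2]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(impute_additive(matrix(c(1, NA, 2, NA), 2, 2)),
               "no observed cells")
})

test_that("row scaling gives exact zero mean and unit sd", {
  expect_equal(scale_rows(matrix(c(1, 2, 3), 1, 3))[1, ],
               c(-1, 0, 1))
  set.seed(2)
  X <- matrix(stats::rnorm(60, 5, 3), 6, 10)
  S <- scale_rows(X)
  expect_true(all(abs(rowMeans(S)) < 1e-12))
  expect_true(all(abs(apply(S, 1, stats::sd) - 1) < 1e-12))
  expect_equal(scale_rows(S), S, tolerance = 1e-12)   # already standardized
  Xc <- rbind(X, 7)
  expect_error(scale_rows(Xc), "constant")
  expect_warning(S2 <- scale_rows(Xc, on_constant = "drop"), "constant")
  expect_equal(nrow(S2), 6)
})

test_that("per-trait stacks carry the 3/2/1/1 default weights", {
  set.seed(3)
  mk <- function() matrix(stats::rnorm(20), 5, 4,
                          dimnames = list(paste0("t", 1:5),
                                          paste0("g", 1:4)))
  traits <- list(yield = mk(), oil = mk(), flowering = mk())
  scores <- stats::setNames(rep(c("high", "low"), c(2, 3)),
                            paste0("t", 1:5))
  st <- build_trait_layers(traits, binary_scores = scores)
  expect_equal(st$weights, c(3, 2, 1, 1))
  expect_equal(st$metrics, c(rep("sumsquares", 3), "tanimoto"))
  expect_equal(names(st$layers), c("yield", "oil", "flowering", "binary"))
  expect_equal(unname(st$layers$binary[, "high"]), c(1, 1, 0, 0, 0))
  # single trait -> single layer
  expect_length(build_trait_layers(traits["yield"])$layers, 1)
})

test_that("duplicating a layer doubles combined distances", {
  set.seed(4)
  m <- matrix(stats::rnorm(12), 3, 4,
              dimnames = list(paste0("t", 1:3), paste0("g", 1:4)))
  one <- build_trait_layers(list(a = m), weights = c(a = 1))
  two <- build_trait_layers(list(a = m, b = m), weights = c(a = 1, b = 1))
  x1 <- lapply(one$layers, function(l) l[1, ])
  p1 <- lapply(one$layers, function(l) l[2, ])
  x2 <- lapply(two$layers, function(l) l[1, ])
  p2 <- lapply(two$layers, function(l) l[2, ])
  expect_equal(2 * combined_distance(x1, p1, one$metrics, one$weights),
               combined_distance(x2, p2, two$metrics, two$weights))
})

test_that("genotype-layer stacks follow the mean-weight rule", {
  set.seed(5)
  mk <- function() matrix(stats::rnorm(20), 5, 4,
                          dimnames = list(paste0("t", 1:5),
                                          paste0("g", 1:4)))
  traits <- list(yield = mk(), oil = mk())
  gw <- c(g1 = 4, g2 = 1, g3 = 0, g4 = 7)
  scores <- stats::setNames(rep(c("high", "low"), c(2, 3)),
                            paste0("t", 1:5))
  st <- build_genotype_layers(traits, gw, binary_scores = scores)
  expect_equal(names(st$layers), c(paste0("g", 1:4), "binary"))
  expect_equal(st$weights, c(4, 1, 0, 7, mean(gw)))
  expect_equal(dim(st$layers$g1), c(5L, 2L))
  # zero-weight genotype contributes nothing to combined distance
  x <- lapply(st$layers, function(l) l[1, ])
  p <- lapply(st$layers, function(l) l[3, ])
  p_perturbed <- p
  p_perturbed$g3 <- p$g3 + 100
  expect_equal(combined_distance(x, p, st$metrics, st$weights),
               combined_distance(x, p_perturbed, st$metrics, st$weights))
})

test_that("AMMI genotype weights equal rank-K interaction sums of squares", {
  R <- matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("e", 1:3), paste0("g", 1:3)))
  fit <- fit_ammi(R + 5)                 # additive shift leaves R intact
  w <- genotype_weights_from_ammi(fit, K = 2)
  expect_equal(unname(w), c(2, 2, 0), tolerance = 1e-10)
  # reconstruction oracle: row sums of squares of the rank-K fit
  set.seed(6)
  M <- matrix(stats::rnorm(40), 8, 5,
              dimnames = list(paste0("e", 1:8), paste0("g", 1:5)))
  f2 <- fit_ammi(M)
  K <- 2
  recon <- f2$env_scores[, 1:K] %*% diag(f2$lambda[1:K]) %*%
    t(f2$genotype_scores[, 1:K])
  expect_equal(unname(genotype_weights_from_ammi(f2, K)),
               unname(colSums(recon^2)), tolerance = 1e-10)
  # zero interaction -> all weights zero
  A <- outer(stats::rnorm(4), rep(1, 3)) + outer(rep(1, 4), stats::rnorm(3))
  dimnames(A) <- list(paste0("e", 1:4), paste0("g", 1:3))
  expect_true(all(genotype_weights_from_ammi(fit_ammi(A), 2) < 1e-18))
  expect_error(genotype_weights_from_ammi(f2, K = 10), "exceeds")
})
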