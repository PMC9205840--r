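test_that("layer distances follow their defining formulas", {
  expect_equal(layer_distance(c(1, 2), c(1, 2), "sumsquares"), 0)
  expect_equal(layer_distance(c(1, 2), c(1, 2), "tanimoto"), 0)
  expect_equal(layer_distance(c(1, 2), c(0, 0), "sumsquares"), 5)
  expect_equal(layer_distance(c(1, 0), c(0.5, 0.5), "tanimoto"), 0.5)
  expect_equal(layer_distance(c(0, 0), c(0, 0), "tanimoto"), 0)
  expect_error(layer_distance(1:2, 1:3), "mismatch")
})

test_that("combined distance is a weighted width-normalized sum", {
  x <- list(a = c(1, 2, 3), b = c(1, 0), c = 2)
  p <- list(a = c(0, 0, 0), b = c(0.5, 0.5), c = 5)
  metrics <- c("sumsquares", "tanimoto", "sumsquares")
  w <- c(2, 1, 0.5)
  # hand-summed oracle: 2*14/3 + 1*0.5/2 + 0.5*9/1
  expect_equal(combined_distance(x, p, metrics, w),
               2 * 14 / 3 + 0.5 / 2 + 0.5 * 9)
  # single layer weight 1 equals layer_distance / m
  expect_equal(combined_distance(x[1], p[1], "sumsquares", 1), 14 / 3)
  # common weight rescaling scales distances (winner invariant)
  expect_equal(combined_distance(x, p, metrics, 2 * w),
               2 * combined_distance(x, p, metrics, w))
})

test_that("winner search matches brute-force argmin with low-index ties", {
  st <- random_stack(7, n = 30, p = 4)
  m <- train_som(st, som_grid(3, 3), rlen = 20, mode = "batch", seed = 1)
  # mapping codebooks to themselves is the identity
  cb_stack <- layer_stack(list(main = {
    M <- m$codebooks$main
    rownames(M) <- paste0("u", 1:9); M
  }), "sumsquares", 1)
  self_map <- map_objects(m, cb_stack)
  expect_equal(self_map$assignment$unit, 1:9)
  # brute force on random queries
  set.seed(2)
  for (i in 1:50) {
    x <- list(stats::rnorm(4))
    bf <- which.min(vapply(1:9, function(u)
      sum((x[[1]] - m$codebooks$main[u, ])^2) / 4, 0))
    expect_identical(find_winner(m, x), bf)
  }
  # exact tie between two units resolves to the lower index
  m2 <- m
  m2$codebooks$main[5, ] <- m2$codebooks$main[2, ]
  expect_identical(find_winner(m2, list(m2$codebooks$main[5, ])), 2L)
})

test_that("batch training with radius zero reaches Lloyd fixed points", {
  st <- random_stack(3, n = 20, p = 3)
  X <- st$layers$main
  m <- train_som(st, som_grid(2, 2), rlen = 50, radius = 0,
                 mode = "batch", seed = 7)
  # independent Lloyd oracle from the same initial sample
  set.seed(7)
  C <- X[sample.int(20, 4), , drop = FALSE]
  for (it in 1:200) {
    D2 <- outer(rowSums(X^2), rep(1, 4)) + outer(rep(1, 20), rowSums(C^2)) -
      2 * X %*% t(C)
    wi <- apply(D2, 1, which.min)
    C2 <- C
    for (u in 1:4) if (any(wi == u)) C2[u, ] <- colMeans(X[wi == u, ,
                                                           drop = FALSE])
    if (max(abs(C2 - C)) < 1e-14) break
    C <- C2
  }
  expect_equal(unname(m$codebooks$main), unname(C), tolerance = 1e-12)
  # k-means monotonicity: quantization error non-increasing at radius 0
  expect_true(all(diff(m$qerror_history[m$qerror_history > 0]) < 1e-10))
})

test_that("training is seed-reproducible and a single object is absorbed", {
  st <- random_stack(9, n = 25, p = 3)
  m1 <- train_som(st, som_grid(3, 3), rlen = 30, seed = 5)
  m2 <- train_som(st, som_grid(3, 3), rlen = 30, seed = 5)
  expect_identical(m1$codebooks, m2$codebooks)
  # one object, radius 0, online: winning prototype converges to it
  one <- layer_stack(list(main = st$layers$main[1, , drop = FALSE]),
                     "sumsquares", 1)
  mo <- train_som(one, som_grid(1, 1), rlen = 500, radius = 0,
                  mode = "online", seed = 1)
  expect_lt(sum((mo$codebooks$main[1, ] - st$layers$main[1, ])^2), 1e-6)
})

test_that("objects on a line map smoothly onto the grid", {
  # 1-D manifold: adjacent objects should land on grid-adjacent units
  set.seed(11)
  xs <- seq(0, 10, length.out = 40) + stats::rnorm(40, 0, 0.05)
  st <- layer_stack(list(main = matrix(xs, ncol = 1,
                                       dimnames = list(sprintf("o%02d", 1:40),
                                                       "x"))),
                    "sumsquares", 1)
  m <- train_som(st, som_grid(5, 2), rlen = 60, seed = 3)
  mp <- map_objects(m, st)
  gd <- m$grid$unit_dist[cbind(mp$assignment$unit[-40],
                               mp$assignment$unit[-1])]
  expect_gt(mean(gd <= 1), 0.5)          # far better than chance (~0.3)
})

test_that("quantization error is the mean of recomputed winner distances", {
  st <- random_stack(13, n = 22, p = 3)
  m <- train_som(st, som_grid(2, 3), rlen = 25, seed = 2)
  mp <- map_objects(m, st)
  d <- vapply(seq_len(22), function(i)
    sum((st$layers$main[i, ] - m$codebooks$main[mp$assignment$unit[i], ])^2) /
      3, 0)
  expect_equal(mp$assignment$distance, d, tolerance = 1e-12)
  expect_equal(mp$qerror, mean(d))
  expect_equal(sum(mp$unit_counts), 22)
})
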