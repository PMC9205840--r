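#' Rectangular SOM grid
#'
#' A two-dimensional rectangular grid of `nx * ny` units with unit
#' coordinates in grid space and Euclidean inter-unit distances.  Units are
#' indexed row-major: unit `u` sits at x = (u-1) %% nx + 1,
#' y = (u-1) %/% nx + 1.
#'
#' @param nx,ny grid dimensions.
#' @param topology only `"rectangular"` is implemented (`"hexagonal"` and
#'   `"toroidal"` are reserved keywords).
#' @param neighbourhood `"bubble"` (uniform within the radius) or
#'   `"gaussian"`.
#' @return object of class `som_grid`.
#' @export
som_grid <- function(nx = 5, ny = 5, topology = "rectangular",
                     neighbourhood = c("bubble", "gaussian")) {
  stop_if(!identical(topology, "rectangular"),
          "only rectangular topology is implemented")
  neighbourhood <- match.arg(neighbourhood)
  stop_if(nx < 1 || ny < 1, "grid dimensions must be >= 1")
  coords <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  ud <- as.matrix(stats::dist(coords))
  dimnames(ud) <- NULL
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 topology = topology, neighbourhood = neighbourhood,
                 coords = coords, unit_dist = ud),
            class = "som_grid")
}

#' Per-layer distance between an object and a prototype
#'
#' `"sumsquares"`: \eqn{\sum_j (x_j - p_j)^2}.  `"tanimoto"`: one minus the
#' Tanimoto (extended Jaccard) similarity,
#' \eqn{1 - x'p / (x'x + p'p - x'p)}, defined as 0 when both vectors are
#' all-zero.
#'
#' @param x,p numeric vectors of equal length.
#' @param metric `"sumsquares"` or `"tanimoto"`.
#' @return a nonnegative scalar.
#' @export
layer_distance <- function(x, p, metric = c("sumsquares", "tanimoto")) {
  metric <- match.arg(metric)
  stop_if(length(x) != length(p), "length mismatch: ", length(x),
          " vs ", length(p))
  if (metric == "sumsquares") return(sum((x - p)^2))
  xp <- sum(x * p)
  denom <- sum(x * x) + sum(p * p) - xp
  if (denom == 0) 0 else 1 - xp / denom
}

# objects x units distance matrix for one layer
layer_dist_matrix <- function(X, P, metric) {
  X <- as.matrix(X); P <- as.matrix(P)
  if (metric == "sumsquares") {
    D <- outer(rowSums(X^2), rep(1, nrow(P))) +
      outer(rep(1, nrow(X)), rowSums(P^2)) - 2 * X %*% t(P)
    pmax(D, 0)
  } else {
    XP <- X %*% t(P)
    denom <- outer(rowSums(X^2), rep(1, nrow(P)), "+") +
      outer(rep(1, nrow(X)), rowSums(P^2)) - XP
    D <- 1 - XP / denom
    D[denom == 0] <- 0
    D
  }
}

#' Weighted combined distance across layers
#'
#' \eqn{\sum_l w_l d_l / m_l}, where \eqn{d_l} is the layer's metric
#' distance and \eqn{m_l} its number of variables; dividing by the variable
#' count makes user weights comparable across layers of different widths.
#'
#' @param x,p lists of per-layer numeric vectors (same layer order).
#' @param metrics,weights per-layer metrics and weights.
#' @return a nonnegative scalar.
#' @export
combined_distance <- function(x, p, metrics, weights) {
  stop_if(length(x) != length(p) || length(x) != length(metrics) ||
            length(x) != length(weights), "layer lists must align")
  d <- 0
  for (l in seq_along(x))
    d <- d + weights[l] * layer_distance(x[[l]], p[[l]], metrics[l]) /
      length(x[[l]])
  d
}

combined_dist_matrix <- function(stack_layers, codebooks, metrics, weights) {
  D <- 0
  for (l in seq_along(stack_layers))
    D <- D + weights[l] *
      layer_dist_matrix(stack_layers[[l]], codebooks[[l]], metrics[l]) /
      ncol(as.matrix(stack_layers[[l]]))
  D
}

#' Winning unit for one object
#'
#' The unit whose multi-layer prototype minimizes the weighted combined
#' distance to the object; exact ties are broken towards the lowest unit
#' index.
#'
#' @param model a trained [train_som()] model.
#' @param x list of per-layer numeric vectors (the object), in the model's
#'   layer order.
#' @return the winning unit index.
#' @export
find_winner <- function(model, x) {
  stopifnot(inherits(model, "mlsom"))
  d <- vapply(seq_len(nrow(model$codebooks[[1]])), function(u)
    combined_distance(x, lapply(model$codebooks, function(cb) cb[u, ]),
                      model$metrics, model$weights), 0)
  stop_if(all(is.nan(d)), "all distances are NaN")
  which.min(d)
}

#' Train a multi-layer self-organizing map
#'
#' Prototypes (codebook vectors) on a rectangular grid are initialized from
#' a random sample of the objects and iteratively moved towards presented
#' objects.  In online mode, each presentation moves the winning unit and
#' its grid neighbours within the current radius towards the object by a
#' learning rate that declines linearly from `alpha[1]` to `alpha[2]`; the
#' neighbourhood radius declines linearly to zero so training ends with
#' k-means-like updates of the winner only.  In batch mode (the default;
#' order-independent and therefore reproducible), each epoch assigns all
#' objects to winners and replaces every prototype by the mean of the
#' objects assigned within its neighbourhood radius; with radius 0 an epoch
#' is exactly one Lloyd (k-means) iteration under the combined distance.
#'
#' @param stack a [layer_stack()].
#' @param grid a [som_grid()]; default 5 x 5 bubble.
#' @param rlen number of passes through the data (online) or epochs
#'   (batch).
#' @param alpha learning-rate start/end (online mode).
#' @param radius initial neighbourhood radius; default the 2/3 quantile of
#'   inter-unit grid distances.  May be 0.
#' @param mode `"batch"` or `"online"`.
#' @param seed optional integer seed for initialization (and online
#'   presentation order).
#' @return object of class `mlsom`: `grid`, `codebooks` (units x variables
#'   per layer), `metrics`, `weights`, `qerror` (mean winner distance),
#'   `qerror_history` (batch mode), `config`.
#' @export
train_som <- function(stack, grid = som_grid(), rlen = NULL,
                      alpha = c(0.05, 0.01), radius = NULL,
                      mode = c("batch", "online"), seed = NULL) {
  stopifnot(inherits(stack, "layer_stack"), inherits(grid, "som_grid"))
  mode <- match.arg(mode)
  if (is.null(rlen)) rlen <- if (mode == "batch") 100L else 500L
  stop_if(rlen < 1, "rlen must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_units <- grid$nx * grid$ny
  n_obj <- length(stack$objects)
  stop_if(n_obj < 1, "empty stack")
  stop_if(n_obj < n_units,
          "need at least one object per unit to initialize (",
          n_obj, " objects, ", n_units, " units)")
  if (is.null(radius))
    radius <- if (any(grid$unit_dist > 0))
      stats::quantile(grid$unit_dist[grid$unit_dist > 0], 2 / 3,
                      names = FALSE) else 0
  X <- lapply(stack$layers, as.matrix)
  init_idx <- sample.int(n_obj, n_units)
  cb <- lapply(X, function(m) m[init_idx, , drop = FALSE])
  cb <- lapply(cb, function(m) { rownames(m) <- NULL; m })
  ud <- grid$unit_dist
  gaussian <- grid$neighbourhood == "gaussian"
  qhist <- NULL

  if (mode == "online") {
    total <- rlen * n_obj
    it <- 0L
    for (pass in seq_len(rlen)) {
      ord <- sample.int(n_obj)
      for (i in ord) {
        it <- it + 1L
        a <- alpha[1] - (alpha[1] - alpha[2]) * (it - 1) / max(total - 1, 1)
        r <- radius * (1 - (it - 1) / max(total - 1, 1))
        xi <- lapply(X, function(m) m[i, ])
        win <- find_winner(
          structure(list(codebooks = cb, metrics = stack$metrics,
                         weights = stack$weights), class = "mlsom"), xi)
        h <- if (gaussian) exp(-ud[win, ]^2 / (2 * max(r, 1e-8)^2))
             else as.numeric(ud[win, ] <= r)
        upd <- which(h > 1e-12)
        for (l in seq_along(cb))
          cb[[l]][upd, ] <- cb[[l]][upd, , drop = FALSE] +
            (a * h[upd]) * (rep(1, length(upd)) %o% xi[[l]] -
                              cb[[l]][upd, , drop = FALSE])
      }
    }
  } else {
    radii <- if (rlen == 1) 0 else
      pmax(seq(radius, 0, length.out = rlen), 0)
    qhist <- numeric(rlen)
    for (ep in seq_len(rlen)) {
      D <- combined_dist_matrix(X, cb, stack$metrics, stack$weights)
      win <- apply(D, 1, which.min)
      qhist[ep] <- mean(D[cbind(seq_len(n_obj), win)])
      r <- radii[ep]
      newcb <- cb
      changed <- FALSE
      for (u in seq_len(n_units)) {
        if (gaussian && r > 0) {
          h <- exp(-ud[u, win]^2 / (2 * r^2))
          if (sum(h) < 1e-12) next
          for (l in seq_along(cb))
            newcb[[l]][u, ] <- colSums(X[[l]] * h) / sum(h)
          changed <- TRUE
        } else {
          members <- which(ud[u, win] <= r)
          if (length(members) == 0) next
          for (l in seq_along(cb))
            newcb[[l]][u, ] <- colMeans(X[[l]][members, , drop = FALSE])
          changed <- TRUE
        }
      }
      if (identical(newcb, cb) && r == 0) { cb <- newcb; break }
      cb <- newcb
      if (!changed && r == 0) break
    }
  }

  model <- structure(list(grid = grid, codebooks = cb,
                          metrics = stack$metrics, weights = stack$weights,
                          layer_names = names(stack$layers),
                          config = list(rlen = rlen, alpha = alpha,
                                        radius = radius, mode = mode),
                          init = init_idx, qerror_history = qhist),
                     class = "mlsom")
  mp <- map_objects(model, stack)
  model$qerror <- mp$qerror
  model
}

#' @export
print.mlsom <- function(x, ...) {
  cat("Multi-layer SOM: ", x$grid$nx, " x ", x$grid$ny, " ",
      x$grid$topology, " grid, ", length(x$codebooks), " layers, ",
      x$config$mode, " training (rlen ", x$config$rlen, ")\n", sep = "")
  if (!is.null(x$qerror))
    cat("Mean quantization error:", format(x$qerror, digits = 5), "\n")
  invisible(x)
}

#' Map objects to their winning units
#'
#' Assigns every object in the stack to its nearest prototype under the
#' model's weighted combined distance, recording per-object distances; the
#' quantization error is their mean.  Empty units are permitted and
#' reported.
#'
#' @param model a trained [train_som()] model.
#' @param stack a [layer_stack()] with the model's layer structure.
#' @return list: `assignment` (data frame object, unit, distance),
#'   `unit_counts` (objects per unit, including zeros), `qerror`.
#' @export
map_objects <- function(model, stack) {
  stopifnot(inherits(model, "mlsom"), inherits(stack, "layer_stack"))
  stop_if(length(stack$layers) != length(model$codebooks),
          "stack and model layers do not align")
  D <- combined_dist_matrix(lapply(stack$layers, as.matrix),
                            model$codebooks, model$metrics, model$weights)
  win <- apply(D, 1, which.min)
  d <- D[cbind(seq_along(win), win)]
  n_units <- nrow(model$codebooks[[1]])
  counts <- tabulate(win, nbins = n_units)
  list(assignment = data.frame(object = stack$objects, unit = win,
                               distance = d, stringsAsFactors = FALSE),
       unit_counts = counts, qerror = mean(d))
}
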