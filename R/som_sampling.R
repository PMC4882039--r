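#' Fit a self-organizing map
#'
#' Online Kohonen training on a rectangular grid. Each presented sample's
#' winner is the neuron minimizing the squared Euclidean distance to the
#' sample; the winner and its grid neighborhood move toward the sample by a
#' learning rate that decays over training. Neighborhood kernel is Gaussian
#' in Euclidean grid distance, `exp(-d^2 / (2 sigma(t)^2))`; `sigma` decays
#' linearly from `max(rows, cols)/2` to 1 and the learning rate decays
#' linearly from `eta[1]` to `eta[2]`. Weights are initialized uniformly
#' within each feature's observed range. Training order is a fresh random
#' permutation per epoch; everything is reproducible given `seed`.
#'
#' Callers are expected to z-score feature columns first (see
#' [select_training_set()]) so that large-scale features such as transcript
#' length do not dominate the distance.
#'
#' @param X Numeric matrix (samples x features), non-empty.
#' @param rows,cols Grid dimensions (default 8 x 8 = 64 neurons).
#' @param epochs Passes over the data (total iterations = `epochs * nrow(X)`).
#' @param seed RNG seed for initialization and presentation order.
#' @param eta Initial and final learning rate.
#' @return A `som_grid`: list with `weights` (neurons x features, row-major
#'   grid order), `rows`, `cols`, `coords`, `schedule`, `seed`.
#' @export
som_fit <- function(X, rows = 8L, cols = 8L, epochs = 10L, seed = 1L,
                    eta = c(0.5, 0.01)) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X must be non-empty")
  if (epochs < 1L) stop("epochs must be >= 1")
  stopifnot(rows >= 1L, cols >= 1L, length(eta) == 2L, eta[1] >= eta[2])
  m <- ncol(X)
  K <- rows * cols
  set.seed(seed)

  rng <- apply(X, 2L, range)
  W <- vapply(seq_len(m),
              function(j) stats::runif(K, rng[1L, j], rng[2L, j]),
              numeric(K))
  W <- matrix(W, nrow = K, ncol = m)

  coords <- cbind(row = rep(seq_len(rows), each = cols),
                  col = rep(seq_len(cols), times = rows))
  grid_d2 <- as.matrix(stats::dist(coords))^2

  n <- nrow(X)
  total <- epochs * n
  sigma0 <- max(rows, cols) / 2
  ord <- unlist(lapply(seq_len(epochs), function(e) sample.int(n)))
  frac <- if (total > 1L) (seq_len(total) - 1L) / (total - 1L) else 0
  eta_t <- eta[1L] + (eta[2L] - eta[1L]) * frac
  sigma_t <- sigma0 + (1 - sigma0) * frac

  for (t in seq_len(total)) {
    x <- X[ord[t], ]
    xm <- matrix(x, nrow = K, ncol = m, byrow = TRUE)
    d <- rowSums((xm - W)^2)
    win <- which.min(d)
    h <- exp(-grid_d2[, win] / (2 * sigma_t[t]^2))
    W <- W + eta_t[t] * h * (xm - W)
  }

  structure(list(weights = W, rows = rows, cols = cols, coords = coords,
                 schedule = list(eta = eta, sigma = c(sigma0, 1),
                                 epochs = epochs, iterations = total),
                 seed = seed),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("SOM grid %d x %d, %d features, %d training iterations\n",
              x$rows, x$cols, ncol(x$weights), x$schedule$iterations))
  invisible(x)
}

#' Assign samples to their winning SOM neurons
#'
#' @param grid A trained `som_grid`.
#' @param X Numeric matrix with the same feature dimension as the grid.
#' @return List with `winners` (neuron index per sample; lowest index wins
#'   exact ties) and `counts` (occupancy per neuron, summing to `nrow(X)`).
#' @export
som_assign <- function(grid, X) {
  stopifnot(inherits(grid, "som_grid"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(grid$weights)) {
    stop("feature dimension mismatch: grid has ", ncol(grid$weights),
         ", data has ", ncol(X))
  }
  W <- grid$weights
  # squared distances via the expansion |x - w|^2 = |x|^2 - 2 x.w + |w|^2
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) - 2 * X %*% t(W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
  winners <- max.col(-d2, ties.method = "first")
  list(winners = winners, counts = tabulate(winners, nbins = nrow(W)))
}

#' Ceiling-proportional allocation and within-neuron draw
#'
#' Each non-empty neuron i with occupancy `w_i` out of a pool of N receives a
#' quota `O_i = ceiling(w_i / N * L)` toward a target of L training samples
#' (so the pre-cap total lies in `[L, L + #non-empty neurons]`), capped at
#' `w_i` so that drawing without replacement is well-defined; `O_i` samples
#' are then drawn uniformly without replacement within each neuron.
#'
#' @param winners Neuron index per sample (from [som_assign()]).
#' @param L Target training-set size (>= 1).
#' @param seed RNG seed for the within-neuron draws.
#' @param ids Optional sample identifiers (default: positional indices).
#' @param n_neurons Number of neurons (default `max(winners)`).
#' @return A `sample_allocation`: list with `neuron_counts`, `pool_size`,
#'   `target`, `quota_raw` (uncapped `O_i`), `quota` (capped), and
#'   `selected_ids`.
#' @export
allocate_and_draw <- function(winners, L, seed = 1L, ids = NULL,
                              n_neurons = max(winners)) {
  N <- length(winners)
  if (L < 1L) stop("L must be >= 1")
  if (L > N) stop("target L (", L, ") exceeds pool size (", N, ")")
  if (is.null(ids)) ids <- seq_len(N)
  stopifnot(length(ids) == N)
  counts <- tabulate(winners, nbins = n_neurons)
  quota_raw <- ifelse(counts > 0L, ceiling(counts / N * L), 0L)
  quota <- pmin(quota_raw, counts)
  set.seed(seed)
  selected <- unlist(lapply(which(quota > 0L), function(i) {
    members <- ids[winners == i]
    members[sample.int(length(members), quota[i])]
  }), use.names = FALSE)
  structure(list(neuron_counts = counts, pool_size = N, target = L,
                 quota_raw = quota_raw, quota = quota,
                 selected_ids = selected),
            class = "sample_allocation")
}

#' Select representative training subsets per class via SOM
#'
#' Pools both classes to compute a common z-scoring (pooled mean and SD per
#' feature; constant features are left at zero), then fits one SOM per class
#' and draws an occupancy-proportional training subset of about L samples per
#' class via [allocate_and_draw()]. Because quotas are ceilinged per neuron,
#' each returned set has between L and L + rows*cols members.
#'
#' @param positives,negatives Numeric feature matrices with rownames as
#'   transcript ids (e.g. the lncRNA and mRNA pools).
#' @param L Target per-class training-set size (default 2000).
#' @param rows,cols,epochs SOM parameters, see [som_fit()].
#' @param seed Base RNG seed; the two classes use `seed` and `seed + 1`.
#' @return List with `positive_ids`, `negative_ids`, and `details` (per-class
#'   `som_grid` and `sample_allocation`).
#' @export
select_training_set <- function(positives, negatives, L = 2000L,
                                rows = 8L, cols = 8L, epochs = 10L,
                                seed = 1L) {
  positives <- as.matrix(positives)
  negatives <- as.matrix(negatives)
  stopifnot(ncol(positives) == ncol(negatives))
  for (nm in c("positives", "negatives")) {
    n <- nrow(get(nm))
    if (n < L) stop(nm, " pool (", n, ") is smaller than L = ", L)
  }
  pooled <- rbind(positives, negatives)
  mu <- colMeans(pooled)
  sdev <- apply(pooled, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  zscore <- function(M) sweep(sweep(M, 2L, mu, "-"), 2L, sdev, "/")

  pick <- function(M, s) {
    Z <- zscore(M)
    grid <- som_fit(Z, rows = rows, cols = cols, epochs = epochs, seed = s)
    asg <- som_assign(grid, Z)
    ids <- rownames(M)
    if (is.null(ids)) ids <- seq_len(nrow(M))
    alloc <- allocate_and_draw(asg$winners, L = L, seed = s + 1000L,
                               ids = ids, n_neurons = rows * cols)
    list(grid = grid, allocation = alloc)
  }
  pos <- pick(positives, seed)
  neg <- pick(negatives, seed + 1L)
  list(positive_ids = pos$allocation$selected_ids,
       negative_ids = neg$allocation$selected_ids,
       details = list(positive = pos, negative = neg))
}
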