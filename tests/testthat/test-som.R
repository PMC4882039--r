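test_that("the winner's weights converge to a single repeated sample", {
  X <- matrix(rep(c(0.3, -1.2, 0.8), 50), nrow = 50, byrow = TRUE)
  grid <- som_fit(X, rows = 2, cols = 2, epochs = 20, seed = 3)
  d <- sqrt(rowSums(sweep(grid$weights, 2, X[1, ])^2))
  expect_lt(min(d), 1e-3)
})

test_that("SOM training is reproducible given the seed", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4)
  g1 <- som_fit(X, rows = 3, cols = 3, epochs = 4, seed = 99)
  g2 <- som_fit(X, rows = 3, cols = 3, epochs = 4, seed = 99)
  expect_identical(g1$weights, g2$weights)
  g3 <- som_fit(X, rows = 3, cols = 3, epochs = 4, seed = 100)
  expect_false(identical(g1$weights, g3$weights))
})

test_that("som_fit validates its configuration", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(som_fit(X, epochs = 0), "epochs")
  expect_error(som_fit(X[0, , drop = FALSE]), "non-empty")
})

test_that("assignment picks the zero-distance neuron and partitions samples", {
  set.seed(7)
  X <- matrix(rnorm(80 * 3), 80, 3)
  grid <- som_fit(X, rows = 3, cols = 3, epochs = 5, seed = 1)
  asg <- som_assign(grid, X)
  expect_equal(sum(asg$counts), nrow(X))
  expect_length(asg$counts, 9L)
  # a sample equal to a weight vector wins that neuron
  probe <- grid$weights[5, , drop = FALSE]
  expect_equal(som_assign(grid, probe)$winners, 5L)
  # duplicated samples get identical winners
  dup <- X[c(1, 1, 2, 2), ]
  w <- som_assign(grid, dup)$winners
  expect_equal(w[1], w[2])
  expect_equal(w[3], w[4])
  expect_error(som_assign(grid, X[, 1:2]), "dimension mismatch")
})

test_that("allocation reproduces the ceiling arithmetic of the protocol", {
  # occupancy 385 in a pool of 38229 with target 2000 -> ceil(20.14) = 21
  winners <- rep(1:2, times = c(385, 38229 - 385))
  a <- allocate_and_draw(winners, L = 2000, seed = 1)
  expect_equal(a$quota_raw[1], 21)
  # exact proportionality: {10,10}, L = 10 -> {5,5}
  b <- allocate_and_draw(rep(1:2, each = 10), L = 10, seed = 1)
  expect_equal(b$quota, c(5, 5))
  expect_length(b$selected_ids, 10L)
  # empty neuron gets zero
  c_ <- allocate_and_draw(rep(3, 20), L = 5, seed = 1, n_neurons = 4)
  expect_equal(c_$quota[c(1, 2, 4)], c(0, 0, 0))
  expect_error(allocate_and_draw(rep(1, 5), L = 6), "exceeds")
})

test_that("pre-cap quotas satisfy L <= sum(O_i) <= L + #non-empty neurons", {
  set.seed(43)
  for (i in 1:50) {
    K <- sample(2:64, 1)
    counts <- stats::rpois(K, lambda = sample(1:50, 1))
    counts[sample(K, sample(0:(K - 1), 1))] <- 0
    N <- sum(counts)
    if (N < 2) next
    L <- sample(seq_len(N), 1)
    winners <- rep(seq_len(K), times = counts)
    a <- allocate_and_draw(winners, L = L, seed = i, n_neurons = K)
    total <- sum(a$quota_raw)
    expect_gte(total, L)
    expect_lte(total, L + sum(counts > 0))
    expect_true(all(a$quota <= counts))
    # selection is proportional to occupancy within the ceiling
    expect_equal(tabulate(winners[a$selected_ids], nbins = K), a$quota)
  }
})

test_that("per-class selection returns bounded, reproducible id sets", {
  set.seed(47)
  pos <- matrix(rnorm(300 * 5), 300, 5,
                dimnames = list(paste0("p", 1:300), NULL))
  neg <- matrix(rnorm(280 * 5, mean = 2), 280, 5,
                dimnames = list(paste0("n", 1:280), NULL))
  sel <- select_training_set(pos, neg, L = 100, rows = 4, cols = 4,
                             epochs = 3, seed = 9)
  expect_true(length(sel$positive_ids) >= 100 &&
                length(sel$positive_ids) <= 100 + 16)
  expect_true(length(sel$negative_ids) >= 100 &&
                length(sel$negative_ids) <= 100 + 16)
  expect_true(all(sel$positive_ids %in% rownames(pos)))
  expect_true(all(sel$negative_ids %in% rownames(neg)))

  sel2 <- select_training_set(pos, neg, L = 100, rows = 4, cols = 4,
                              epochs = 3, seed = 9)
  expect_identical(sel$positive_ids, sel2$positive_ids)
  expect_identical(sel$negative_ids, sel2$negative_ids)

  # L equal to the pool size returns the whole pool
  whole <- select_training_set(pos, neg, L = 280, rows = 4,
                               cols = 4, epochs = 2, seed = 9)
  expect_setequal(whole$negative_ids, rownames(neg))
  expect_error(select_training_set(pos, neg, L = 301), "smaller than L")
})

test_that("SOM-selected subsets train forests at least as well as random ones", {
  lab <- make_labelled_features(n_per_class = 250, seed = 53,
                                length_range = c(200, 600))
  sel_feats <- select_top(fsc_scores(lab$X, lab$y), 10)
  X <- lab$X[, unique(c(sel_feats, "MaxORF"))]
  y <- lab$y
  pool <- seq_len(nrow(X))
  acc <- function(train_idx, seed) {
    m <- train_classifier(X[train_idx, ], y[train_idx], n_trees = 60,
                          seed = seed, max_orf_values = X[train_idx, "MaxORF"])
    held <- setdiff(pool, train_idx)
    mean(predict(m, X[held, ])$predicted_class == y[held])
  }
  som_acc <- rand_acc <- numeric(10)
  for (s in 1:10) {
    sel <- select_training_set(X[y == "NONCODING", ], X[y == "CODING", ],
                               L = 100, rows = 4, cols = 4, epochs = 3,
                               seed = s)
    som_idx <- match(c(sel$positive_ids, sel$negative_ids), rownames(X))
    som_acc[s] <- acc(som_idx, seed = s)
    set.seed(s + 500)
    rand_idx <- c(sample(which(y == "NONCODING"), length(sel$positive_ids)),
                  sample(which(y == "CODING"), length(sel$negative_ids)))
    rand_acc[s] <- acc(rand_idx, seed = s)
  }
  expect_gte(mean(som_acc), mean(rand_acc) - 0.01)
})
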