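test_that("a 1x1 instance has a single partition and constant H", {
  d <- make_fixture("single")$train
  s <- run_chain(d, sampler_config(n_chains = 1, sweeps_per_chain = 50,
                                   burn_in_sweeps = 10, seed = 4))
  expect_true(all(s$users == 0))
  expect_true(all(s$items == 0))
  expect_equal(unique(s$H), hamiltonian(c(1, 0)), tolerance = 1e-12)
})

test_that("chains are reproducible from the seed and pooled sizes are exact", {
  set.seed(31)
  d <- random_rating_data(6, 6, 2, 12)
  cfg <- sampler_config(n_chains = 3, sweeps_per_chain = 100,
                        burn_in_sweeps = 20, sample_interval_sweeps = 4,
                        seed = 99)
  s1 <- run_ensemble(d, cfg)
  s2 <- run_ensemble(d, cfg)
  expect_identical(s1$users, s2$users)
  expect_identical(s1$items, s2$items)
  expect_equal(s1$H, s2$H)
  expect_length(s1$H, 3 * floor((100 - 20) / 4))
  # distinct chains differ (different sub-seeds / starting regions)
  expect_false(identical(s1$users[s1$chain == 1, ], s1$users[s1$chain == 2, ]))
})

test_that("stored H values match recomputation on the stored partitions", {
  set.seed(32)
  d <- random_rating_data(5, 5, 3, 15)
  s <- run_ensemble(d, sampler_config(n_chains = 2, sweeps_per_chain = 60,
                                      burn_in_sweeps = 10,
                                      sample_interval_sweeps = 10, seed = 8))
  for (k in seq_along(s$H)) {
    part <- sbm_partition(s$users[k, ], s$items[k, ])
    expect_equal(s$H[k], hamiltonian(count_blocks(d, part)), tolerance = 1e-8)
  }
})

test_that("posterior applies the Laplace rule block-wise over samples", {
  d <- rating_dataset(data.frame(user = c("A", "A", "B", "B"),
                                 item = c("x", "y", "x", "y"),
                                 rating = c(1, 1, 1, 2)), K = 2)
  one_group <- manual_sample(list(rep(0L, 2)), list(rep(0L, 2)))
  p <- posterior(d, one_group, data.frame(user = "A", item = "x"))
  expect_equal(p[1, 1], (3 + 1) / (4 + 2), tolerance = 1e-12, ignore_attr = TRUE)

  # empty data: flat posterior
  empty <- rating_dataset(data.frame(user = character(), item = character(),
                                     rating = integer()),
                          K = 4, user_ids = "A", item_ids = "x")
  pe <- posterior(empty, manual_sample(list(0L), list(0L)),
                  data.frame(user = "A", item = "x"))
  expect_equal(as.numeric(pe), rep(1 / 4, 4))

  expect_error(posterior(d, one_group, data.frame(user = "Z", item = "x")),
               "unknown user id: Z")
})

test_that("averaging over samples mixes block predictives", {
  d <- rating_dataset(data.frame(user = c("A", "B"), item = c("x", "x"),
                                 rating = c(1, 2)), K = 2)
  # two samples: both users together vs. apart
  s <- manual_sample(list(c(0L, 0L), c(0L, 1L)), list(c(0L), c(0L)))
  p <- posterior(d, s, data.frame(user = "A", item = "x"))
  expect_equal(p[1, 1], mean(c((1 + 1) / (2 + 2), (1 + 1) / (1 + 2))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("prediction rules follow MAP/mean/median conventions", {
  p <- structure(rbind(c(0.1, 0.2, 0.7), c(0.3, 0.4, 0.3)),
                 class = c("rating_posterior", "matrix"))
  expect_equal(predict_ratings(p, "map"), c(3, 2))
  expect_equal(predict_ratings(rbind(c(0.5, 0.5)), "map"), 1)  # tie -> lowest
  expect_equal(predict_ratings(rbind(c(0.5, 0, 0, 0, 0.5)), "mean"), 3)
  expect_equal(predict_ratings(rbind(c(0.2, 0.2, 0.2, 0.4)), "median"), 3)
  expect_equal(predict_ratings(rbind(c(0.5, 0.5)), "median"), 1)
  expect_error(predict_ratings(p, "mean", ordinal = FALSE), "ordinal")
})

test_that("exhaustive enumeration covers the partition lattice", {
  expect_equal(bell_number(1), 1)
  expect_equal(bell_number(3), 5)
  expect_equal(bell_number(4), 15)
  expect_equal(nrow(set_partitions(3)), 5)
  expect_equal(nrow(unique(set_partitions(4))), 15)

  d <- make_fixture("single")$train
  p <- exhaustive_posterior(d, data.frame(user = "A", item = "a"))
  expect_equal(p[1, 1], 2 / 3, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(p, "n_pairs"), 1)

  set.seed(33)
  d3 <- random_rating_data(3, 3, 2, 5)
  q <- expand.grid(user = d3$user_ids, item = d3$item_ids,
                   stringsAsFactors = FALSE)
  p3 <- exhaustive_posterior(d3, q)
  expect_equal(attr(p3, "n_pairs"), 25)
  expect_equal(rowSums(p3), rep(1, nrow(q)), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(exhaustive_posterior(random_rating_data(12, 12, 2, 10),
                                    data.frame(user = "U1", item = "I1")),
               "partition pairs")
})

test_that("the Metropolis estimator converges to the exhaustive oracle", {
  set.seed(34)
  d <- random_rating_data(3, 3, 2, 5)
  q <- expand.grid(user = d$user_ids, item = d$item_ids,
                   stringsAsFactors = FALSE)
  ex <- exhaustive_posterior(d, q)
  err <- vapply(c(100, 1000, 10000), function(sweeps) {
    s <- run_ensemble(d, sampler_config(n_chains = 4, sweeps_per_chain = sweeps,
                                        burn_in_sweeps = sweeps %/% 5,
                                        sample_interval_sweeps = max(1, sweeps %/% 500),
                                        seed = 17))
    max(abs(posterior(d, s, q) - ex))
  }, 0)
  expect_lt(err[3], err[1])   # long runs beat short runs
  expect_lt(err[3], 0.01)
})

test_that("permuting user identities permutes the exhaustive posterior", {
  set.seed(35)
  d <- random_rating_data(3, 3, 2, 6)
  q <- data.frame(user = d$user_ids, item = d$item_ids)
  p1 <- exhaustive_posterior(d, q)
  perm <- c(3, 1, 2)
  d2 <- rating_dataset(
    data.frame(user = paste0("W", perm[d$user + 1L]),
               item = d$item_ids[d$item + 1L], rating = d$rating),
    K = 2, user_ids = paste0("W", 1:3), item_ids = d$item_ids)
  q2 <- data.frame(user = paste0("W", perm[match(q$user, d$user_ids)]),
                   item = q$item)
  p2 <- exhaustive_posterior(d2, q2)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("empirical transitions on an empty 3-node instance are balanced", {
  # with no data the target is uniform over unlabeled partitions, so the
  # flow between any two partitions must be symmetric
  d <- rating_dataset(data.frame(user = character(), item = character(),
                                 rating = integer()),
                      K = 2, user_ids = c("A", "B", "C"), item_ids = "x")
  s <- run_chain(d, sampler_config(n_chains = 1, sweeps_per_chain = 60000,
                                   burn_in_sweeps = 1000,
                                   sample_interval_sweeps = 1, seed = 12))
  key <- apply(s$users, 1, function(a) paste(canonical_labels(a), collapse = ""))
  from <- key[-length(key)]; to <- key[-1]
  states <- sort(unique(key))
  expect_length(states, 5)  # Bell(3)
  Tm <- table(factor(from, states), factor(to, states))
  off <- upper.tri(Tm)
  a <- Tm[off]; b <- t(Tm)[off]
  # symmetric within 4 binomial standard errors
  expect_true(all(abs(a - b) <= 4 * sqrt(a + b + 1)))
})

test_that("pooling independent chains does not inflate estimator variance", {
  set.seed(36)
  d <- random_rating_data(3, 3, 2, 5)
  q <- data.frame(user = "U1", item = "I1")
  est <- function(n_chains, sweeps, seed) {
    s <- run_ensemble(d, sampler_config(n_chains = n_chains,
                                        sweeps_per_chain = sweeps,
                                        burn_in_sweeps = sweeps %/% 5,
                                        sample_interval_sweeps = 2,
                                        seed = seed))
    posterior(d, s, q)[1, 1]
  }
  single <- vapply(1:30, function(k) est(1, 500, 1000 + k), 0)
  pooled <- vapply(1:30, function(k) est(5, 100, 2000 + k), 0)
  expect_lt(var(pooled), 2 * var(single))
})
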