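test_that("rating_dataset builds dense indices and round-trips ids", {
  d <- rating_dataset(data.frame(user = c("A", "A", "B"),
                                 item = c("x", "y", "x"),
                                 rating = c(1, 2, 1)), K = 2)
  expect_equal(d$n_users, 2)
  expect_equal(d$n_items, 2)
  expect_length(d$rating, 3)
  expect_setequal(d$user_ids, c("A", "B"))
  # internal indices are dense and 0-based
  expect_true(all(d$user %in% 0:1) && all(d$item %in% 0:1))
  # external ids recoverable per triple
  expect_equal(d$user_ids[d$user + 1L], c("A", "A", "B"))

  empty <- rating_dataset(data.frame(user = character(), item = character(),
                                     rating = integer()), K = 5)
  expect_equal(empty$n_users, 0)
  expect_equal(empty$n_items, 0)
  expect_length(empty$rating, 0)
})

test_that("rating_dataset rejects duplicates and out-of-range classes", {
  expect_error(rating_dataset(data.frame(user = c("A", "A"),
                                         item = c("x", "x"),
                                         rating = c(1, 2)), K = 2),
               "duplicate.*A.*x")
  expect_error(rating_dataset(data.frame(user = "A", item = "x", rating = 3),
                              K = 2), "out of range")
  expect_error(rating_dataset(data.frame(user = "A", item = "x", rating = 0.5),
                              K = 2), "positive integer")
  expect_error(rating_dataset(data.frame(user = "A", item = "x", rating = 1),
                              K = 1), "at least 2")
})

test_that("count_blocks tallies per-block class counts", {
  d <- rating_dataset(data.frame(user = c("A", "A", "B"),
                                 item = c("x", "y", "x"),
                                 rating = c(1, 2, 1)), K = 2)
  one <- count_blocks(d, sbm_partition(c(0, 0), c(0, 0)))
  expect_equal(one$arr[1, 1, ], c(2L, 1L))
  expect_equal(sum(one$arr), 3)

  sing <- count_blocks(d, sbm_partition(c(0, 1), c(0, 1)))
  expect_equal(sing$arr[1, 1, ], c(1L, 0L))  # (A, x): one 1-rating
  expect_equal(sing$arr[1, 2, ], c(0L, 1L))  # (A, y): one 2-rating
  expect_equal(sing$arr[2, 1, ], c(1L, 0L))  # (B, x)
  expect_equal(sum(sing$arr), 3)

  empty <- rating_dataset(data.frame(user = character(), item = character(),
                                     rating = integer()),
                          K = 2, user_ids = c("A", "B"), item_ids = c("x", "y"))
  expect_equal(sum(count_blocks(empty, sbm_partition(c(0, 1), c(0, 0)))$arr), 0)

  expect_error(count_blocks(d, sbm_partition(0, c(0, 0))), "does not match")
})

test_that("hamiltonian matches hand-evaluated simplex integrals", {
  # K = 2, single block, counts (2, 0): integral of q^2 over [0,1] is 1/3
  expect_equal(hamiltonian(c(2, 0)), log(3), tolerance = 1e-12)
  # counts (1, 1): integral of q(1-q) is 1/6
  expect_equal(hamiltonian(c(1, 1)), log(6), tolerance = 1e-12)
  expect_equal(hamiltonian(c(0, 0)), 0)
  expect_error(hamiltonian(c(-1, 2)), "negative")

  # empty data: H = 0 regardless of the block structure
  empty <- rating_dataset(data.frame(user = character(), item = character(),
                                     rating = integer()),
                          K = 3, user_ids = c("A", "B", "C"),
                          item_ids = c("x", "y"))
  expect_equal(hamiltonian(count_blocks(empty, sbm_partition(c(0, 1, 2), c(0, 1)))), 0)
})

test_that("hamiltonian agrees with an lgamma-free factorial reference", {
  set.seed(21)
  for (trial in 1:20) {
    K <- sample(2:5, 1)
    arr <- array(sample(0:20, 2 * 3 * K, replace = TRUE), dim = c(2, 3, K))
    counts <- structure(list(arr = arr, K = K), class = "block_counts")
    expect_equal(hamiltonian(counts), hamiltonian_ref(arr, K),
                 tolerance = 1e-9)
  }
})

test_that("hamiltonian is invariant under relabeling and identity permutation", {
  set.seed(22)
  d <- random_rating_data(6, 5, 3, 14)
  part <- sbm_partition(sample(0:5, 6, TRUE), sample(0:4, 5, TRUE))
  H0 <- hamiltonian(count_blocks(d, part))

  # permute group labels on both sides
  pu <- sample(0:5); pi_ <- sample(0:4)
  relab <- sbm_partition(pu[part$users + 1L], pi_[part$items + 1L])
  expect_equal(hamiltonian(count_blocks(d, relab)), H0, tolerance = 1e-12)

  # permute user identities together with their data and assignments
  perm <- sample(6)
  d2 <- rating_dataset(
    data.frame(user = paste0("V", perm[d$user + 1L]),
               item = d$item_ids[d$item + 1L], rating = d$rating),
    K = 3, user_ids = paste0("V", 1:6), item_ids = d$item_ids)
  part2 <- sbm_partition(part$users[order(perm)], part$items)
  expect_equal(hamiltonian(count_blocks(d2, part2)), H0, tolerance = 1e-12)
})

test_that("labeled sampling correction counts injective label maps", {
  expect_equal(label_correction(3, 1), log(3), tolerance = 1e-12)
  expect_equal(label_correction(3, 3), log(6), tolerance = 1e-12)
  expect_equal(label_correction(1, 1), 0)
  expect_error(label_correction(2, 3), "exceeds")

  part <- sbm_partition(c(0, 0, 1), c(0, 0))
  expect_equal(labeled_sampling_correction(part),
               label_correction(3, 2) + label_correction(2, 1),
               tolerance = 1e-12)
})

test_that("move_delta equals full recomputation and is zero for identity moves", {
  set.seed(23)
  d <- random_rating_data(5, 4, 3, 12)
  part <- sbm_partition(sample(0:4, 5, TRUE), sample(0:3, 4, TRUE))
  expect_equal(move_delta(d, part, "user", 2, part$users[3])$delta, 0)

  for (trial in 1:50) {
    side <- sample(c("user", "item"), 1)
    N <- if (side == "user") 5 else 4
    node <- sample(0:(N - 1), 1); target <- sample(0:(N - 1), 1)
    md <- move_delta(d, part, side, node, target)
    p2 <- apply_move(part, side, node, target)
    expect_equal(md$delta,
                 corrected_hamiltonian(d, p2) - corrected_hamiltonian(d, part),
                 tolerance = 1e-9)
    part <- p2
  }
})

test_that("moving an isolated node changes only the correction term", {
  # user C has no ratings; moving it between occupied groups leaves H alone
  d <- rating_dataset(data.frame(user = c("A", "B"), item = c("x", "x"),
                                 rating = c(1, 2)),
                      K = 2, user_ids = c("A", "B", "C"), item_ids = "x")
  part <- sbm_partition(c(0, 1, 0), c(0))
  md <- move_delta(d, part, "user", 2, 1)
  expect_equal(md$delta_h, 0)
  expect_equal(md$delta_c, 0)  # g stays 2
  md2 <- move_delta(d, part, "user", 2, 2)  # open a third group
  expect_equal(md2$delta_h, 0)
  expect_equal(md2$delta_c, label_correction(3, 3) - label_correction(3, 2),
               tolerance = 1e-12)
})

test_that("move deltas over a closed cycle sum to zero and counts are conserved", {
  set.seed(24)
  d <- random_rating_data(5, 4, 2, 10)
  part0 <- sbm_partition(sample(0:4, 5, TRUE), sample(0:3, 4, TRUE))
  part <- part0
  total <- 0
  moves <- list()
  for (step in 1:20) {
    side <- sample(c("user", "item"), 1)
    N <- if (side == "user") 5 else 4
    node <- sample(0:(N - 1), 1)
    old <- if (side == "user") part$users[node + 1L] else part$items[node + 1L]
    target <- sample(0:(N - 1), 1)
    moves[[step]] <- list(side = side, node = node, old = old)
    total <- total + move_delta(d, part, side, node, target)$delta
    part <- apply_move(part, side, node, target)
    expect_equal(sum(count_blocks(d, part)$arr), length(d$rating))
  }
  for (step in rev(seq_along(moves))) {  # walk back to the start
    m <- moves[[step]]
    total <- total + move_delta(d, part, m$side, m$node, m$old)$delta
    part <- apply_move(part, m$side, m$node, m$old)
  }
  expect_equal(part$users, part0$users)
  expect_equal(total, 0, tolerance = 1e-6)
})
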