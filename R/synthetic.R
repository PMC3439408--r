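#' Configuration of the planted-block rating generator
#'
#' The generator emulates dichotomous like/dislike ratings driven by two
#' competing factors: a per-item intrinsic quality Q_i and a block-level
#' a-priori preference pi of the user's group for the item's group. The
#' probability that user u likes item i (class 1, as opposed to class 2) is
#' \deqn{p(u,i) = (1-\lambda)\,Q_i + \lambda\,\pi_{\sigma_u \tau_i},}
#' so `lambda = 0` makes item quality the only relevant factor and
#' `lambda = 1` makes group preferences the only relevant factor.
#'
#' @param n_users,n_items node counts; defaults 100 x 100 so the standard
#'   budget of 4,000 + 1,000 sampled pairs fits comfortably.
#' @param n_user_groups,n_item_groups planted group counts (default 5 each).
#' @param lambda interpolation parameter in [0, 1].
#' @param n_observed,n_test sizes of the training and test sets of distinct
#'   (user, item) pairs; defaults 4,000 and 1,000.
#' @param seed RNG seed.
#' @param pi_matrix optional `n_user_groups x n_item_groups` matrix of block
#'   preferences in [0, 1]; by default each entry is drawn Uniform(0, 1).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_users = 100, n_items = 100,
                             n_user_groups = 5, n_item_groups = 5,
                             lambda = 0.5, n_observed = 4000, n_test = 1000,
                             seed = 1L, pi_matrix = NULL) {
  stopifnot(lambda >= 0, lambda <= 1,
            n_user_groups <= n_users, n_item_groups <= n_items)
  if (n_observed + n_test > n_users * n_items)
    stop("pair budget ", n_observed + n_test, " exceeds ",
         n_users, " x ", n_items, " = ", n_users * n_items, " pairs")
  if (!is.null(pi_matrix))
    stopifnot(nrow(pi_matrix) == n_user_groups,
              ncol(pi_matrix) == n_item_groups,
              all(pi_matrix >= 0 & pi_matrix <= 1))
  structure(list(n_users = as.integer(n_users), n_items = as.integer(n_items),
                 n_user_groups = as.integer(n_user_groups),
                 n_item_groups = as.integer(n_item_groups),
                 lambda = lambda, n_observed = as.integer(n_observed),
                 n_test = as.integer(n_test), seed = as.integer(seed),
                 pi_matrix = pi_matrix),
            class = "generator_config")
}

#' Generate planted-block model ratings
#'
#' Draws the ground truth (planted partitions, item qualities, block
#' preferences), samples `n_observed + n_test` distinct (user, item) pairs
#' uniformly without replacement, labels each pair class 1 ("like") with
#' probability p(u,i) and class 2 otherwise, and splits the pairs into a
#' training `rating_dataset` (K = 2) and a held-out test set.
#'
#' @param config a `generator_config`.
#' @return list with `train` (a `rating_dataset`), `test` (data.frame
#'   `user`, `item`, `rating`, `p_like`), and `truth` (a `ground_truth`:
#'   planted `user_groups`/`item_groups`, `Q`, `pi`, `lambda`).
#' @export
generate_ratings <- function(config) {
  set.seed(config$seed)
  nu <- config$n_users; ni <- config$n_items
  sigma <- sample.int(config$n_user_groups, nu, replace = TRUE)
  tau <- sample.int(config$n_item_groups, ni, replace = TRUE)
  Q <- runif(ni)
  pi_m <- config$pi_matrix
  if (is.null(pi_m))
    pi_m <- matrix(runif(config$n_user_groups * config$n_item_groups),
                   config$n_user_groups, config$n_item_groups)
  truth <- structure(list(user_groups = sigma, item_groups = tau,
                          Q = Q, pi = pi_m, lambda = config$lambda,
                          user_ids = paste0("u", seq_len(nu)),
                          item_ids = paste0("i", seq_len(ni))),
                     class = "ground_truth")
  n_pairs <- config$n_observed + config$n_test
  idx <- sample.int(nu * ni, n_pairs)  # distinct pairs
  u <- (idx - 1L) %% nu + 1L
  i <- (idx - 1L) %/% nu + 1L
  p <- (1 - config$lambda) * Q[i] + config$lambda * pi_m[cbind(sigma[u], tau[i])]
  r <- ifelse(runif(n_pairs) < p, 1L, 2L)
  tr <- seq_len(config$n_observed)
  te <- setdiff(seq_len(n_pairs), tr)
  train <- rating_dataset(
    data.frame(user = sprintf("u%d", u[tr]), item = sprintf("i%d", i[tr]),
               rating = r[tr]),
    K = 2, user_ids = truth$user_ids, item_ids = truth$item_ids)
  test <- data.frame(user = sprintf("u%d", u[te]), item = sprintf("i%d", i[te]),
                     rating = r[te], p_like = p[te])
  list(train = train, test = test, truth = truth)
}

#' True like-probability of (user, item) pairs
#'
#' @param truth a `ground_truth`.
#' @param users,items external id vectors (`"u1"`, `"i3"`, ...).
#' @return numeric vector of probabilities of class 1.
#' @export
p_like <- function(truth, users, items) {
  u <- match(as.character(users), truth$user_ids)
  i <- match(as.character(items), truth$item_ids)
  if (anyNA(u) || anyNA(i)) stop("unknown node id in p_like query")
  (1 - truth$lambda) * truth$Q[i] +
    truth$lambda * truth$pi[cbind(truth$user_groups[u], truth$item_groups[i])]
}

#' Bayes-optimal prediction accuracy on a test set
#'
#' The best possible classifier knows each pair's true like-probability p
#' and predicts the more likely class, succeeding with probability
#' max(p, 1-p). `expected` is the mean of that quantity over the test
#' pairs; `realized` is the accuracy that the argmax rule actually attains
#' on the sampled labels (a binomial draw around `expected`).
#'
#' @param truth a `ground_truth`.
#' @param test data.frame with `user`, `item` and (for `realized`) `rating`.
#' @return list with `expected` and `realized` accuracies.
#' @export
optimal_accuracy <- function(truth, test) {
  p <- p_like(truth, test$user, test$item)
  expected <- mean(pmax(p, 1 - p))
  realized <- if (!is.null(test$rating)) {
    pred <- ifelse(p >= 0.5, 1L, 2L)
    mean(pred == test$rating)
  } else NA_real_
  list(expected = expected, realized = realized)
}

#' Small deterministic fixture datasets
#'
#' Hard-coded datasets with known structure, for regression tests and
#' worked examples.
#'
#' * `"fig1-like"`: 8 users x 8 items in 2 x 2 homogeneous blocks (each
#'   block constant-rated), with 4 entries withheld; for such data the
#'   high-explanatory-power partition is the planted one and the withheld
#'   entries' MAP predictions equal their block's constant rating.
#' * `"empty"`: 2 users x 2 items, no ratings.
#' * `"single"`: 1 user, 1 item, one rating of class 1 (K = 2).
#'
#' @param name fixture name.
#' @return list with `train` (a `rating_dataset`), `withheld` (data.frame
#'   `user`, `item`, `rating`; possibly empty), and `K`.
#' @export
make_fixture <- function(name = c("fig1-like", "empty", "single")) {
  name <- match.arg(name)
  if (name == "empty") {
    train <- rating_dataset(data.frame(user = character(), item = character(),
                                       rating = integer()),
                            K = 2, user_ids = c("A", "B"), item_ids = c("a", "b"))
    return(list(train = train,
                withheld = data.frame(user = character(), item = character(),
                                      rating = integer()),
                K = 2L))
  }
  if (name == "single") {
    train <- rating_dataset(data.frame(user = "A", item = "a", rating = 1L), K = 2)
    return(list(train = train,
                withheld = data.frame(user = character(), item = character(),
                                      rating = integer()),
                K = 2L))
  }
  users <- LETTERS[1:8]; items <- letters[1:8]
  ug <- rep(1:2, each = 4); ig <- rep(1:2, each = 4)
  block_rating <- matrix(c(2L, 1L, 1L, 2L), 2, 2)  # constant rating per block
  grid <- expand.grid(u = 1:8, i = 1:8)
  grid$rating <- block_rating[cbind(ug[grid$u], ig[grid$i])]
  withhold <- c(1 + 8 * 0, 5 + 8 * 1, 2 + 8 * 6, 8 + 8 * 7)  # (A,a),(E,b),(B,g),(H,h)
  wh <- grid[withhold, ]
  tr <- grid[-withhold, ]
  train <- rating_dataset(
    data.frame(user = users[tr$u], item = items[tr$i], rating = tr$rating),
    K = 2, user_ids = users, item_ids = items)
  list(train = train,
       withheld = data.frame(user = users[wh$u], item = items[wh$i],
                             rating = wh$rating),
       K = 2L)
}
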