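#' Naive item-mean recommender
#'
#' Predicts the rating of user u for item i as the average observed rating
#' of i over all users that rated it. Items with no observed rating fall
#' back to the global training mean.
#'
#' @param train a `rating_dataset`.
#' @param queries data.frame with `user`, `item` external ids (or list of
#'   pairs).
#' @return numeric predictions, one per query.
#' @export
naive_predict <- function(train, queries) {
  queries <- as_query_frame(queries)
  # queries may name users/items never seen in training: the item mean does
  # not depend on the user, and an unknown item gets the global fallback
  item <- match(as.character(queries$item), train$item_ids)
  global <- if (length(train$rating) > 0) mean(train$rating) else NA_real_
  sums <- tapply(train$rating, train$item, sum)
  cnts <- tapply(train$rating, train$item, length)
  means <- rep(global, train$n_items)
  means[as.integer(names(sums)) + 1L] <- sums / cnts
  ifelse(is.na(item), global, means[ifelse(is.na(item), 1L, item)])
}

#' Fit a Funk-SVD model with bias terms
#'
#' Matrix-factorization recommender: each rating is modeled as
#' \deqn{\hat r_{ui} = \mu + b_u + b_i + p_u \cdot q_i,}
#' with global mean mu, user/item biases and length-`f` factor vectors. The
#' regularized squared-error objective over the observed pairs,
#' sum (r - rhat)^2 + reg (||p_u||^2 + ||q_i||^2 + b_u^2 + b_i^2), is
#' minimized by stochastic gradient descent over shuffled observations.
#' Biases start at zero; factors are drawn N(0, 0.01).
#'
#' @param train a non-empty `rating_dataset`.
#' @param f number of latent factors.
#' @param rate SGD learning rate.
#' @param reg regularization weight.
#' @param epochs full passes over the training set.
#' @param seed RNG seed (initialization and shuffles).
#' @return An `svd_model` with `mu`, `b_u`, `b_i`, `P`, `Q`, `objective`
#'   (length `epochs + 1`; entry 1 is the objective at initialization) and
#'   the hyperparameters.
#' @export
svd_fit <- function(train, f = 40, rate = 0.002, reg = 0.02, epochs = 100,
                    seed = 1L) {
  stopifnot(f >= 1, rate > 0, reg >= 0, epochs >= 0)
  if (length(train$rating) == 0) stop("cannot fit SVD on an empty training set")
  set.seed(seed)
  P0 <- matrix(rnorm(train$n_users * f, sd = 0.1), train$n_users, f)
  Q0 <- matrix(rnorm(train$n_items * f, sd = 0.1), train$n_items, f)
  fit <- cpp_svd_fit(train$user, train$item, as.numeric(train$rating),
                     train$n_users, train$n_items, as.integer(f),
                     rate, reg, as.integer(epochs), P0, Q0)
  structure(list(mu = fit$mu, b_u = fit$b_u, b_i = fit$b_i,
                 P = fit$P, Q = fit$Q, objective = fit$objective,
                 f = as.integer(f), rate = rate, reg = reg,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 user_ids = train$user_ids, item_ids = train$item_ids,
                 K = train$K),
            class = "svd_model")
}

#' @export
print.svd_model <- function(x, ...) {
  cat("<svd_model> f = ", x$f, ", ", length(x$b_u), " users x ",
      length(x$b_i), " items; objective ", round(x$objective[1], 2), " -> ",
      round(x$objective[length(x$objective)], 2), "\n", sep = "")
  invisible(x)
}

#' Predict ratings from a fitted Funk-SVD model
#'
#' Raw predictions mu + b_u + b_i + p_u . q_i are real numbers and may fall
#' outside the rating range; with `discretize = TRUE` they are rounded to
#' the nearest class (ties toward the lower class) and clipped to the class
#' range,
#' the path used for classification accuracy. Users or items unseen in
#' training get zero bias and zero factors.
#'
#' @param model an `svd_model`.
#' @param queries data.frame with `user`, `item` external ids.
#' @param discretize round and clip to integer classes.
#' @return numeric predictions, one per query.
#' @export
svd_predict <- function(model, queries, discretize = FALSE) {
  queries <- as_query_frame(queries)
  u <- match(as.character(queries$user), model$user_ids)
  i <- match(as.character(queries$item), model$item_ids)
  pred <- rep(model$mu, nrow(queries))
  known <- !is.na(u) & !is.na(i)
  pred[!is.na(u)] <- pred[!is.na(u)] + model$b_u[u[!is.na(u)]]
  pred[!is.na(i)] <- pred[!is.na(i)] + model$b_i[i[!is.na(i)]]
  if (any(known))
    pred[known] <- pred[known] +
      rowSums(model$P[u[known], , drop = FALSE] *
              model$Q[i[known], , drop = FALSE])
  if (discretize) pred <- discretize_rating(pred, model$K)
  pred
}

#' Round a real-valued prediction to a rating class
#'
#' Nearest class, with half-way ties toward the lower class, clipped to the
#' range 1..K.
#' @param x numeric predictions.
#' @param K number of classes.
#' @return integer classes.
#' @export
discretize_rating <- function(x, K) {
  cls <- ceiling(x - 0.5)  # n + 0.5 maps to n (ties toward lower class)
  as.integer(pmin(pmax(cls, 1L), K))
}

#' Item-item adjusted-cosine similarity model
#'
#' For each item pair, the cosine of the two items' rating vectors over
#' their co-rating users, after subtracting each user's mean rating
#' (removing per-user bias toward higher or lower ratings). Pairs with no
#' co-rating user get similarity 0.
#'
#' @param train a `rating_dataset`.
#' @param k neighborhood size used at prediction time.
#' @return An `item_sim_model` with the dense `sim` matrix (zero diagonal
#'   excluded from neighborhoods) and `k`.
#' @export
item_sim_fit <- function(train, k = 30) {
  ni <- train$n_items
  sim <- matrix(0, ni, ni)
  if (length(train$rating) > 0) {
    umean <- tapply(train$rating, train$user, mean)
    x <- train$rating - umean[as.character(train$user)]
    X <- Matrix::sparseMatrix(i = train$user + 1L, j = train$item + 1L,
                              x = as.numeric(x), dims = c(train$n_users, ni))
    Pat <- Matrix::sparseMatrix(i = train$user + 1L, j = train$item + 1L,
                                x = 1, dims = c(train$n_users, ni))
    num <- as.matrix(Matrix::crossprod(X))
    X2 <- X
    X2@x <- X2@x^2
    # (i, j) entry: sum over users that rated j of x_ui^2
    restr <- as.matrix(Matrix::crossprod(X2, Pat))
    denom <- sqrt(restr * t(restr))
    sim <- ifelse(denom > 0, num / denom, 0)
    diag(sim) <- 1
  }
  structure(list(sim = sim, k = as.integer(k),
                 item_ids = train$item_ids),
            class = "item_sim_model")
}

#' Item-item kNN prediction
#'
#' Among the items the user has rated, takes the `k` most similar to the
#' target item (positive similarity only) and returns the
#' similarity-weighted average of their ratings. With no usable neighbor,
#' falls back to the naive item-mean prediction.
#'
#' @param train the `rating_dataset` the model was fitted on.
#' @param model an `item_sim_model`.
#' @param queries data.frame with `user`, `item` external ids.
#' @param k neighborhood size override; defaults to `model$k`.
#' @return numeric predictions, one per query.
#' @export
itemitem_predict <- function(train, model, queries, k = NULL) {
  queries <- as_query_frame(queries)
  if (is.null(k)) k <- model$k
  u_idx <- match(as.character(queries$user), train$user_ids) - 1L
  i_idx <- match(as.character(queries$item), train$item_ids) - 1L
  fallback <- naive_predict(train, queries)
  rated_by <- split(seq_along(train$rating), train$user)
  pred <- fallback
  for (q in seq_len(nrow(queries))) {
    if (is.na(u_idx[q]) || is.na(i_idx[q])) next  # unseen node: naive fallback
    rows <- rated_by[[as.character(u_idx[q])]]
    if (is.null(rows)) next
    items <- train$item[rows] + 1L
    sims <- model$sim[i_idx[q] + 1L, items]
    keep <- sims > 0 & items != i_idx[q] + 1L
    if (!any(keep)) next
    sims <- sims[keep]; ratings <- train$rating[rows][keep]
    ord <- order(sims, decreasing = TRUE)[seq_len(min(k, sum(keep)))]
    pred[q] <- sum(sims[ord] * ratings[ord]) / sum(sims[ord])
  }
  pred
}
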