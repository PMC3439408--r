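#' Classification accuracy
#'
#' Fraction of ratings predicted exactly.
#' @param predicted,true equal-length vectors of rating classes.
#' @return fraction in [0, 1].
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("length mismatch: ", length(predicted), " vs ", length(true))
  if (length(true) == 0) stop("empty prediction vector")
  mean(predicted == true)
}

#' Mean absolute error
#'
#' Mean absolute deviation of the prediction from the actual rating;
#' meaningful when classes are ordinal (predictions may be real-valued).
#' @inheritParams accuracy
#' @return MAE >= 0.
#' @export
mae <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("length mismatch: ", length(predicted), " vs ", length(true))
  if (length(true) == 0) stop("empty prediction vector")
  mean(abs(predicted - true))
}

fit_and_predict <- function(algorithm, train, queries, K,
                            sampler = NULL, svd = list(), knn_k = 30,
                            discretize = TRUE) {
  switch(algorithm,
    naive = {
      p <- naive_predict(train, queries)
      if (discretize) discretize_rating(p, K) else p
    },
    sbm = {
      sample <- run_ensemble(train, sampler)
      post <- posterior(train, sample, queries)
      predict_ratings(post, "map")
    },
    svd = {
      model <- do.call(svd_fit, c(list(train = train), svd))
      svd_predict(model, queries, discretize = discretize)
    },
    itemitem = {
      model <- item_sim_fit(train, k = knn_k)
      p <- itemitem_predict(train, model, queries)
      if (discretize) discretize_rating(p, K) else p
    },
    stop("unknown algorithm: ", algorithm))
}

#' Benchmark algorithms on planted-block model ratings
#'
#' For each value of the interpolation parameter lambda and each replicate,
#' generates a synthetic like/dislike instance, trains each requested
#' algorithm on the observed ratings, scores classification accuracy on the
#' held-out test pairs, and records the Bayes-optimal accuracy of the
#' replicate alongside. SBM predictions use the MAP rule.
#'
#' @param lambda_grid numeric vector of lambda values in [0, 1].
#' @param template a `generator_config` whose lambda and seed are overridden
#'   per cell.
#' @param algorithms subset of `c("sbm", "naive", "svd", "itemitem")`.
#' @param replicates independent generator draws per lambda.
#' @param seed master seed; each (lambda, replicate) cell gets a derived
#'   seed, recorded in the output.
#' @param sampler `sampler_config` for the SBM (its seed is overridden per
#'   cell).
#' @param svd list of arguments for [svd_fit()].
#' @param knn_k item-item neighborhood size.
#' @return data.frame with one row per (lambda, replicate, algorithm):
#'   `lambda`, `replicate`, `algorithm`, `accuracy`, `optimal_expected`,
#'   `optimal_realized`, `n_train`, `n_test`, `seed`.
#' @export
benchmark_model <- function(lambda_grid, template = generator_config(),
                            algorithms = c("sbm", "naive"),
                            replicates = 5, seed = 1L,
                            sampler = sampler_config(),
                            svd = list(), knn_k = 30) {
  stopifnot(all(algorithms %in% c("sbm", "naive", "svd", "itemitem")))
  set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(lambda_grid) * replicates),
                       length(lambda_grid), replicates)
  rows <- list()
  for (li in seq_along(lambda_grid)) {
    for (rep in seq_len(replicates)) {
      cfg <- template
      cfg$lambda <- lambda_grid[li]
      cfg$seed <- cell_seeds[li, rep]
      sim <- generate_ratings(cfg)
      opt <- optimal_accuracy(sim$truth, sim$test)
      for (alg in algorithms) {
        sam <- sampler
        sam$seed <- cell_seeds[li, rep]
        pred <- fit_and_predict(alg, sim$train, sim$test, K = 2,
                                sampler = sam, svd = svd, knn_k = knn_k)
        rows[[length(rows) + 1]] <- data.frame(
          lambda = lambda_grid[li], replicate = rep, algorithm = alg,
          accuracy = accuracy(pred, sim$test$rating),
          optimal_expected = opt$expected, optimal_realized = opt$realized,
          n_train = cfg$n_observed, n_test = cfg$n_test,
          seed = cell_seeds[li, rep])
      }
    }
  }
  do.call(rbind, rows)
}

#' Benchmark algorithms on real train/test splits
#'
#' Scores each algorithm on each supplied split (e.g. the five 80k/20k
#' MovieLens-100k splits): classification accuracy on discretized
#' predictions, and MAE for both the raw and discretized prediction paths
#' where the algorithm produces real values.
#'
#' @param splits list of `list(train = rating_dataset, test = data.frame)`
#'   pairs; test needs `user`, `item`, `rating`.
#' @param algorithms subset of `c("sbm", "naive", "svd", "itemitem")`.
#' @param sampler,svd,knn_k algorithm settings as in [benchmark_model()].
#' @return data.frame with one row per (split, algorithm): `accuracy`,
#'   `mae_raw`, `mae_discrete`, `n_train`, `n_test`.
#' @export
benchmark_real <- function(splits, algorithms = c("naive", "svd", "itemitem"),
                           sampler = sampler_config(), svd = list(),
                           knn_k = 30) {
  rows <- list()
  for (s in seq_along(splits)) {
    train <- splits[[s]]$train
    test <- splits[[s]]$test
    tr_pairs <- paste(train$user_ids[train$user + 1L],
                      train$item_ids[train$item + 1L])
    if (any(paste(test$user, test$item) %in% tr_pairs))
      stop("split ", s, ": train and test overlap")
    K <- train$K
    for (alg in algorithms) {
      raw <- switch(alg,
        naive = naive_predict(train, test),
        svd = svd_predict(do.call(svd_fit, c(list(train = train), svd)), test),
        itemitem = itemitem_predict(train, item_sim_fit(train, knn_k), test),
        sbm = {
          post <- posterior(train, run_ensemble(train, sampler), test)
          predict_ratings(post, "map")
        })
      disc <- if (alg == "sbm") raw else discretize_rating(raw, K)
      rows[[length(rows) + 1]] <- data.frame(
        split = s, algorithm = alg,
        accuracy = accuracy(disc, test$rating),
        mae_raw = mae(raw, test$rating),
        mae_discrete = mae(disc, test$rating),
        n_train = length(train$rating), n_test = nrow(test))
    }
  }
  do.call(rbind, rows)
}

#' Relative improvement of one algorithm over another
#'
#' (A - B) / (B - baseline): the improvement of A over B expressed as a
#' fraction of B's own improvement over the baseline, the scale on which
#' gains between already-good recommenders are meaningfully compared.
#' @param a,b,baseline scores where larger is better (e.g. accuracies); for
#'   error metrics pass negated values.
#' @return the ratio (can be given as a percentage by multiplying by 100).
#' @export
relative_improvement <- function(a, b, baseline) {
  (a - b) / (b - baseline)
}

#' Co-classification matrix of a partition sample
#'
#' Entry (u, v) is the fraction of sampled partitions in which nodes u and v
#' share a group: an estimate of the posterior probability that the two
#' nodes belong together. Symmetric, unit diagonal.
#'
#' @param sample a `partition_sample`.
#' @param side `"users"` or `"items"`.
#' @return N x N numeric matrix.
#' @export
coclassification <- function(sample, side = c("users", "items")) {
  side <- match.arg(side)
  if (n_samples(sample) == 0) stop("empty partition sample")
  cpp_coclass(sample[[side]])
}

#' Consensus partition from a co-classification matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' 1 - coclassification, cut at `k` groups. A simple consensus summary of
#' the sampled ensemble.
#' @param coclass co-classification matrix.
#' @param k number of consensus groups.
#' @return integer group labels (1..k).
#' @export
consensus_partition <- function(coclass, k) {
  hc <- hclust(as.dist(1 - coclass), method = "average")
  cutree(hc, k = k)
}

#' Node attributes versus co-classification frequency
#'
#' Buckets node pairs by their co-classification frequency into equal-width
#' bins over [0, 1] and summarizes an attribute within each bin: for
#' categorical attributes the fraction of same-valued pairs, for numeric
#' attributes the mean absolute difference. Nodes with a missing attribute
#' are excluded and counted.
#'
#' @param coclass co-classification matrix.
#' @param attributes vector of node attributes aligned with the matrix rows.
#' @param n_bins number of equal-width bins (default 10).
#' @param min_pairs bins with fewer pairs are flagged in `sparse`.
#' @return data.frame per bin: `bin_low`, `bin_high`, `n_pairs`, `value`
#'   (same-fraction or mean |diff|), `sparse`; plus attribute
#'   `n_excluded_nodes`.
#' @export
attribute_vs_coclass <- function(coclass, attributes, n_bins = 10,
                                 min_pairs = 20) {
  stopifnot(n_bins >= 1, length(attributes) == nrow(coclass))
  ok <- !is.na(attributes)
  n_excluded <- sum(!ok)
  M <- coclass[ok, ok, drop = FALSE]
  att <- attributes[ok]
  n <- nrow(M)
  if (n < 2) stop("fewer than two nodes with a defined attribute")
  ut <- upper.tri(M)
  freq <- M[ut]
  ii <- row(M)[ut]; jj <- col(M)[ut]
  numeric_att <- is.numeric(att)
  pairval <- if (numeric_att) abs(att[ii] - att[jj]) else att[ii] == att[jj]
  bin <- pmin(floor(freq * n_bins), n_bins - 1) + 1
  out <- data.frame(bin_low = (seq_len(n_bins) - 1) / n_bins,
                    bin_high = seq_len(n_bins) / n_bins,
                    n_pairs = 0L, value = NA_real_)
  counts <- tabulate(bin, nbins = n_bins)
  means <- tapply(as.numeric(pairval), factor(bin, levels = seq_len(n_bins)), mean)
  out$n_pairs <- counts
  out$value <- as.numeric(means)
  out$sparse <- out$n_pairs < min_pairs
  attr(out, "n_excluded_nodes") <- n_excluded
  attr(out, "kind") <- if (numeric_att) "mean_abs_diff" else "same_fraction"
  out
}

#' Genre overlap (Jaccard index)
#'
#' Ratio between the number of genres shared by two items and the total
#' number of genres with which they are labeled.
#' @param genres_i,genres_j non-empty character vectors (or sets) of genres.
#' @return Jaccard index in [0, 1].
#' @export
genre_overlap <- function(genres_i, genres_j) {
  genres_i <- unique(genres_i); genres_j <- unique(genres_j)
  if (length(genres_i) == 0 || length(genres_j) == 0)
    stop("genre overlap undefined for an empty genre set")
  length(intersect(genres_i, genres_j)) / length(union(genres_i, genres_j))
}
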