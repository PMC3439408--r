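#' Sampler configuration
#'
#' Settings for Metropolis sampling of the partition ensemble. One sweep is
#' one attempted single-node move per node (users + items). Several short
#' independent chains, started in different regions of the partition space,
#' are pooled rather than one long chain; this follows the observation that
#' short parallel runs sample the multimodal partition landscape better.
#'
#' @param n_chains number of independent chains.
#' @param sweeps_per_chain sweeps per chain.
#' @param burn_in_sweeps sweeps discarded before recording; default 20% of
#'   `sweeps_per_chain`.
#' @param sample_interval_sweeps record one sample every this many sweeps;
#'   default targets at least 100 samples per chain.
#' @param seed master seed; per-chain sub-seeds are derived from it
#'   deterministically.
#' @param init_groups chain initialization: `"random-g"` draws g uniformly
#'   in 1..N and assigns nodes uniformly to g groups (a different region per
#'   chain); `"singletons"` puts every node in its own group; `"one-group"`
#'   starts from a single group per side.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 10, sweeps_per_chain = 500,
                           burn_in_sweeps = NULL,
                           sample_interval_sweeps = NULL,
                           seed = 1L,
                           init_groups = c("random-g", "singletons", "one-group")) {
  init_groups <- match.arg(init_groups)
  if (is.null(burn_in_sweeps)) burn_in_sweeps <- floor(0.2 * sweeps_per_chain)
  if (is.null(sample_interval_sweeps))
    sample_interval_sweeps <- max(1L, floor((sweeps_per_chain - burn_in_sweeps) / 100))
  stopifnot(n_chains >= 1, sweeps_per_chain >= 1, sample_interval_sweeps >= 1,
            burn_in_sweeps >= 0, burn_in_sweeps < sweeps_per_chain)
  structure(list(n_chains = as.integer(n_chains),
                 sweeps_per_chain = as.integer(sweeps_per_chain),
                 burn_in_sweeps = as.integer(burn_in_sweeps),
                 sample_interval_sweeps = as.integer(sample_interval_sweeps),
                 seed = as.integer(seed), init_groups = init_groups),
            class = "sampler_config")
}

chain_subseeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_chains)
}

init_assignment <- function(N, strategy) {
  switch(strategy,
         "singletons" = seq_len(N) - 1L,
         "one-group" = rep(0L, N),
         "random-g" = {
           g <- sample.int(N, 1)
           sample.int(g, N, replace = TRUE) - 1L
         })
}

#' Run one Metropolis chain over the partition space
#'
#' Simulates a Markov chain over labeled user/item group assignments with
#' stationary weight proportional to exp(-H'), where H' is the Hamiltonian
#' plus the labeled-group over-counting correction. A move picks a node
#' uniformly among all users and items and proposes a uniformly random group
#' label on that node's side; the proposal is accepted with probability
#' min(1, exp(-delta H')).
#'
#' @param dataset a `rating_dataset` with at least one user and one item.
#' @param config a `sampler_config`.
#' @param chain chain index in `1..n_chains`, selecting the sub-seed.
#' @return A `partition_sample` with one row per recorded sample.
#' @export
run_chain <- function(dataset, config, chain = 1L) {
  stopifnot(dataset$n_users >= 1, dataset$n_items >= 1)
  sub <- chain_subseeds(config)[chain]
  set.seed(sub)
  iu <- init_assignment(dataset$n_users, config$init_groups)
  ii <- init_assignment(dataset$n_items, config$init_groups)
  res <- cpp_run_chain(dataset$n_users, dataset$n_items, dataset$K,
                       dataset$user, dataset$item, dataset$rating,
                       iu, ii,
                       config$sweeps_per_chain, config$burn_in_sweeps,
                       config$sample_interval_sweeps)
  structure(list(users = res$users, items = res$items, H = res$H,
                 sweep = res$sweep,
                 chain = rep(as.integer(chain), length(res$H)),
                 n_users = dataset$n_users, n_items = dataset$n_items,
                 acceptance_rate = res$acceptance_rate),
            class = "partition_sample")
}

#' Pool samples from independent parallel chains
#'
#' Runs `n_chains` chains with distinct sub-seeds and starting partitions
#' and pools their recorded samples into one `partition_sample`. The pooled
#' average over samples is the Metropolis estimator of any ensemble average,
#' since each sample already carries its Boltzmann weight.
#'
#' @inheritParams run_chain
#' @return A `partition_sample`.
#' @export
run_ensemble <- function(dataset, config) {
  chains <- lapply(seq_len(config$n_chains), function(c) run_chain(dataset, config, c))
  structure(list(users = do.call(rbind, lapply(chains, `[[`, "users")),
                 items = do.call(rbind, lapply(chains, `[[`, "items")),
                 H = unlist(lapply(chains, `[[`, "H")),
                 sweep = unlist(lapply(chains, `[[`, "sweep")),
                 chain = unlist(lapply(chains, `[[`, "chain")),
                 n_users = dataset$n_users, n_items = dataset$n_items,
                 acceptance_rate = mean(vapply(chains, `[[`, 0, "acceptance_rate"))),
            class = "partition_sample")
}

#' @export
print.partition_sample <- function(x, ...) {
  cat("<partition_sample> ", length(x$H), " samples from ",
      length(unique(x$chain)), " chain(s); H in [",
      round(min(x$H), 3), ", ", round(max(x$H), 3), "]\n", sep = "")
  invisible(x)
}

n_samples <- function(sample) length(sample$H)

as_query_frame <- function(queries) {
  if (is.data.frame(queries)) return(queries)
  as.data.frame(do.call(rbind, lapply(queries, function(q)
    data.frame(user = q[[1]], item = q[[2]]))))
}

#' Posterior rating probabilities from a partition sample
#'
#' For each queried (user, item) pair, averages the Laplace-rule predictive
#' (n^r + 1) / (n + K) of the pair's block over the sampled partitions,
#' where n^r and n are the block's class and total counts under each sample.
#' Queries for users or items with no observed ratings are legal: their
#' group membership still varies across samples and the estimator applies
#' unchanged (reducing to 1/K when nothing is ever co-observed).
#'
#' @param dataset the `rating_dataset` the sample was drawn for.
#' @param sample a `partition_sample`.
#' @param queries data.frame with columns `user`, `item` (external ids), or
#'   a list of (user, item) pairs.
#' @return A `rating_posterior`: matrix with one row per query and K
#'   columns; rows sum to 1. Query ids are attached as attributes.
#' @export
posterior <- function(dataset, sample, queries) {
  queries <- as_query_frame(queries)
  if (n_samples(sample) == 0) stop("empty partition sample")
  idx <- resolve_ids(dataset, queries$user, queries$item)
  post <- cpp_posterior(sample$users, sample$items,
                        dataset$user, dataset$item, dataset$rating,
                        dataset$K, idx$user, idx$item)
  colnames(post) <- as.character(seq_len(dataset$K))
  structure(post, class = c("rating_posterior", "matrix"),
            user = queries$user, item = queries$item)
}

#' Turn posterior probabilities into point predictions
#'
#' @param posterior a `rating_posterior` (rows are queries, columns classes
#'   1..K) or any matrix of class probabilities.
#' @param rule `"map"` (most probable class, ties to the lowest class),
#'   `"mean"` (expected rating, real-valued) or `"median"` (smallest class
#'   with cumulative probability >= 1/2). Mean and median assume the classes
#'   are ordinal.
#' @param ordinal set to FALSE for class sets with no order; mean/median are
#'   then refused.
#' @return numeric vector, one prediction per query.
#' @export
predict_ratings <- function(posterior, rule = c("map", "mean", "median"),
                            ordinal = TRUE) {
  rule <- match.arg(rule)
  p <- unclass(posterior)
  if (rule != "map" && !ordinal)
    stop("rule '", rule, "' requires ordinal rating classes")
  K <- ncol(p)
  switch(rule,
         map = apply(p, 1, which.max),  # which.max ties -> lowest index
         mean = as.numeric(p %*% seq_len(K)),
         median = apply(p, 1, function(row) which(cumsum(row) >= 0.5)[1]))
}
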