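# Shared fixture builders. Everything is generated in code; seeds are fixed
# by the caller.

random_rating_data <- function(n_users, n_items, K, n_pairs,
                               user_prefix = "U", item_prefix = "I") {
  idx <- sample(n_users * n_items, n_pairs)
  u <- (idx - 1L) %% n_users + 1L
  i <- (idx - 1L) %/% n_users + 1L
  rating_dataset(
    data.frame(user = sprintf("%s%d", user_prefix, u),
               item = sprintf("%s%d", item_prefix, i),
               rating = sample.int(K, n_pairs, replace = TRUE)),
    K = K,
    user_ids = sprintf("%s%d", user_prefix, seq_len(n_users)),
    item_ids = sprintf("%s%d", item_prefix, seq_len(n_items)))
}

# Assemble a partition_sample by hand from lists of assignment vectors.
manual_sample <- function(users, items) {
  users <- do.call(rbind, users)
  items <- do.call(rbind, items)
  structure(list(users = users, items = items,
                 H = rep(NA_real_, nrow(users)),
                 sweep = seq_len(nrow(users)),
                 chain = rep(1L, nrow(users)),
                 n_users = ncol(users), n_items = ncol(items),
                 acceptance_rate = NA_real_),
            class = "partition_sample")
}

# Independent Hamiltonian reference: per-block
# H = log((n+K-1)!) - log((K-1)!) - sum_r log(n_r!), with factorial logs
# accumulated as plain sums of log(1..m) rather than through lgamma.
log_fact_ref <- function(m) sum(log(seq_len(m)))

hamiltonian_ref <- function(arr, K) {
  total <- rowSums(arr, dims = 2)
  H <- 0
  for (a in seq_len(dim(arr)[1]))
    for (b in seq_len(dim(arr)[2])) {
      n <- total[a, b]
      if (n == 0) next
      H <- H + log_fact_ref(n + K - 1) - log_fact_ref(K - 1) -
        sum(vapply(arr[a, b, ], log_fact_ref, 0))
    }
  H
}

apply_move <- function(partition, side, node, target) {
  if (side == "user")
    sbm_partition(replace(partition$users, node + 1L, target), partition$items)
  else
    sbm_partition(partition$users, replace(partition$items, node + 1L, target))
}

# Deterministic well-separated block-preference matrix: each user group
# likes its own item group and the next one, so all rows/columns are
# distinct patterns.
separated_pi <- function(g, lo = 0.05, hi = 0.95) {
  m <- matrix(lo, g, g)
  for (a in seq_len(g)) m[a, c(a, a %% g + 1)] <- hi
  m
}
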