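#' Create a joint user/item partition
#'
#' A partition simultaneously groups the users and the items of a bipartite
#' rating network; it is the state of the Metropolis sampler. Group labels
#' are 0-based integers and the label space of each side has one label per
#' node (the labeled-group scheme the sampler works in), so `users[u]` lies
#' in `[0, n_users)` and `items[i]` in `[0, n_items)`.
#'
#' @param users integer vector of user group labels.
#' @param items integer vector of item group labels.
#' @return Object of class `sbm_partition` with fields `users`, `items` and
#'   derived non-empty group counts `g_users`, `g_items`.
#' @export
sbm_partition <- function(users, items) {
  users <- as.integer(users); items <- as.integer(items)
  if (length(users) > 0 && (min(users) < 0 || max(users) >= length(users)))
    stop("user group labels must lie in [0, n_users)")
  if (length(items) > 0 && (min(items) < 0 || max(items) >= length(items)))
    stop("item group labels must lie in [0, n_items)")
  structure(list(users = users, items = items,
                 g_users = length(unique(users)),
                 g_items = length(unique(items))),
            class = "sbm_partition")
}

#' @export
print.sbm_partition <- function(x, ...) {
  cat("<sbm_partition> ", length(x$users), " users in ", x$g_users,
      " groups; ", length(x$items), " items in ", x$g_items, " groups\n",
      sep = "")
  invisible(x)
}

#' Per-block rating-class counts
#'
#' Tallies, for every pair (user group, item group), how many observed
#' ratings of each class fall in that block. These counts are the sufficient
#' statistics of the partition's marginal likelihood: the Hamiltonian
#' depends on the data only through them.
#'
#' @param dataset a `rating_dataset`.
#' @param partition an `sbm_partition` covering all its users and items.
#' @return Object of class `block_counts`: a list with `arr`, an
#'   `n_users x n_items x K` integer array of class counts indexed by
#'   (user label + 1, item label + 1, class), plus `K` and `n_obs`.
#' @export
count_blocks <- function(dataset, partition) {
  if (length(partition$users) != dataset$n_users ||
      length(partition$items) != dataset$n_items)
    stop("partition size does not match dataset (",
         length(partition$users), " vs ", dataset$n_users, " users; ",
         length(partition$items), " vs ", dataset$n_items, " items)")
  nu <- dataset$n_users; ni <- dataset$n_items; K <- dataset$K
  arr <- array(0L, dim = c(max(nu, 1L), max(ni, 1L), K))
  if (length(dataset$rating) > 0) {
    a <- partition$users[dataset$user + 1L] + 1L
    b <- partition$items[dataset$item + 1L] + 1L
    lin <- a + dim(arr)[1] * (b - 1L + dim(arr)[2] * (dataset$rating - 1L))
    tab <- tabulate(lin, nbins = length(arr))
    arr <- array(as.integer(tab), dim = dim(arr))
  }
  structure(list(arr = arr, K = K, n_obs = length(dataset$rating)),
            class = "block_counts")
}

#' Block totals of a count table
#' @param counts a `block_counts` object.
#' @return matrix of per-block total counts.
#' @export
block_totals <- function(counts) {
  rowSums(counts$arr, dims = 2)
}

#' Partition Hamiltonian (minus log marginal likelihood)
#'
#' For each block the K rating probabilities are integrated against a flat
#' Dirichlet prior on the simplex; the integral factorizes over blocks and
#' yields, in the log domain,
#' \deqn{H = \sum_{\alpha\beta} [\ln\Gamma(n_{\alpha\beta}+K)
#'   - \sum_r \ln\Gamma(n^r_{\alpha\beta}+1) - \ln\Gamma(K)],}
#' so that exp(-H) is the marginal likelihood of the partition pair. Lower H
#' means more explanatory power. Empty blocks contribute exactly zero; the
#' per-block -lnGamma(K) term is kept because the number of occupied blocks
#' varies with the partition.
#'
#' @param counts a `block_counts` object (or plain K-vector of class counts
#'   for a single block).
#' @param K number of rating classes; defaults to `counts$K`.
#' @return H, a non-negative scalar.
#' @export
hamiltonian <- function(counts, K = NULL) {
  if (is.numeric(counts)) {
    counts <- structure(list(arr = array(as.integer(counts),
                                         dim = c(1, 1, length(counts))),
                             K = length(counts)), class = "block_counts")
  }
  if (is.null(K)) K <- counts$K
  arr <- counts$arr
  if (any(arr < 0)) stop("negative block counts")
  n <- rowSums(arr, dims = 2)
  occupied <- n > 0
  sum(lgamma(n[occupied] + K)) - sum(lgamma(arr + 1)) -
    lgamma(K) * sum(occupied)
}

#' Log over-counting factor of labeled-group sampling
#'
#' A sampler that moves nodes between labeled groups (with as many potential
#' labels as nodes) visits every unlabeled partition with `g` non-empty
#' groups `N!/(N-g)!` times. Adding the log of that factor to the
#' Hamiltonian cancels the bias exactly, making the chain uniform over
#' unlabeled partitions when H is constant.
#'
#' @param partition an `sbm_partition`; its `g_users`/`g_items` and sizes
#'   define the correction for both sides.
#' @return C = ln(N_U!/(N_U-g_U)!) + ln(N_I!/(N_I-g_I)!).
#' @seealso [label_correction()] for a single side.
#' @export
labeled_sampling_correction <- function(partition) {
  label_correction(length(partition$users), partition$g_users) +
    label_correction(length(partition$items), partition$g_items)
}

#' @rdname labeled_sampling_correction
#' @param N number of nodes (and of potential group labels) on one side.
#' @param g number of non-empty groups, `1 <= g <= N`.
#' @export
label_correction <- function(N, g) {
  if (g > N) stop("g (", g, ") exceeds N (", N, ")")
  if (g < 0) stop("g must be non-negative")
  lfactorial(N) - lfactorial(N - g)
}

# Per-block Hamiltonian term from a K-vector of class counts.
block_term <- function(cnt, K) {
  n <- sum(cnt)
  if (n == 0) return(0)
  lgamma(n + K) - sum(lgamma(cnt + 1)) - lgamma(K)
}

#' Incremental Hamiltonian change of a single-node move
#'
#' Computes the change in the corrected Hamiltonian H' = H + C when one node
#' is reassigned to a target group label, touching only the blocks incident
#' to the node's old and new groups. This is the quantity the Metropolis
#' rule accepts with probability min(1, exp(-delta)).
#'
#' @param dataset a `rating_dataset`.
#' @param partition current `sbm_partition`.
#' @param side `"user"` or `"item"`.
#' @param node 0-based node index on that side.
#' @param target 0-based target group label.
#' @param counts optional precomputed `count_blocks(dataset, partition)`.
#' @return list with `delta` (change in H'), `delta_h`, `delta_c`.
#' @export
move_delta <- function(dataset, partition, side = c("user", "item"),
                       node, target, counts = NULL) {
  side <- match.arg(side)
  if (is.null(counts)) counts <- count_blocks(dataset, partition)
  K <- dataset$K
  if (side == "user") {
    assign <- partition$users; N <- dataset$n_users
    own <- dataset$user == node
    other_grp <- partition$items[dataset$item + 1L]
    slice <- function(a, b) counts$arr[a + 1L, b + 1L, ]
  } else {
    assign <- partition$items; N <- dataset$n_items
    own <- dataset$item == node
    other_grp <- partition$users[dataset$user + 1L]
    slice <- function(a, b) counts$arr[b + 1L, a + 1L, ]
  }
  if (node < 0 || node >= N) stop("node index out of range")
  if (target < 0 || target >= N) stop("target label out of range")
  old <- assign[node + 1L]
  if (target == old) return(list(delta = 0, delta_h = 0, delta_c = 0))

  delta_h <- 0
  if (any(own)) {
    # class counts of the moved node toward each touched opposite-side group
    betas <- other_grp[own]
    r <- dataset$rating[own]
    for (b in unique(betas)) {
      d <- tabulate(r[betas == b], nbins = K)
      ca <- slice(old, b); cb <- slice(target, b)
      delta_h <- delta_h +
        block_term(ca - d, K) - block_term(ca, K) +
        block_term(cb + d, K) - block_term(cb, K)
    }
  }
  sizes <- tabulate(assign + 1L, nbins = N)
  g <- sum(sizes > 0)
  g_new <- g - (sizes[old + 1L] == 1L) + (sizes[target + 1L] == 0L)
  delta_c <- label_correction(N, g_new) - label_correction(N, g)
  list(delta = delta_h + delta_c, delta_h = delta_h, delta_c = delta_c)
}

#' Corrected Hamiltonian of a partition
#'
#' Convenience wrapper: H'(P) = H(P) + C(P), the quantity whose Boltzmann
#' weight the labeled-group sampler targets.
#' @inheritParams move_delta
#' @return scalar H'.
#' @export
corrected_hamiltonian <- function(dataset, partition) {
  hamiltonian(count_blocks(dataset, partition)) +
    labeled_sampling_correction(partition)
}
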