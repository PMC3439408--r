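#' Bell number
#'
#' Number of set partitions of n elements, via the Bell triangle. Governs
#' the feasibility of exhaustive enumeration.
#' @param n non-negative integer.
#' @return B(n) as a double.
#' @export
bell_number <- function(n) {
  if (n <= 1) return(1)
  row <- 1
  for (k in 2:n) row <- cumsum(c(row[length(row)], row))
  row[length(row)]
}

#' Enumerate all set partitions of n elements
#'
#' Partitions are returned in canonical form (restricted growth strings:
#' labels appear in order of first use, starting at 0).
#' @param n number of elements (>= 1).
#' @return integer matrix, one partition per row, B(n) rows.
#' @export
set_partitions <- function(n) {
  stopifnot(n >= 1)
  out <- vector("list", 0)
  rgs <- integer(n)
  recurse <- function(pos, maxlab) {
    if (pos > n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (lab in 0:(maxlab + 1)) {
      rgs[pos] <<- lab
      recurse(pos + 1, max(maxlab, lab))
    }
  }
  rgs[1] <- 0L
  recurse(2, 0)
  if (n == 1) return(matrix(0L, 1, 1))
  do.call(rbind, out)
}

#' Canonical relabeling of a group assignment
#'
#' Relabels groups by order of first appearance, so that two assignments
#' describe the same unlabeled partition iff their canonical forms are equal.
#' @param assign integer vector of group labels.
#' @return integer vector, a restricted growth string.
#' @export
canonical_labels <- function(assign) {
  match(assign, unique(assign)) - 1L
}

#' Exact posterior by exhaustive enumeration
#'
#' Sums the Laplace-rule predictive over *all* pairs of unlabeled user and
#' item partitions, weighted by exp(-H)/Z. Unfeasible beyond tiny instances
#' (the cost is B(n_users) x B(n_items) Hamiltonian evaluations) but exact:
#' this is the ground-truth oracle against which the Metropolis estimator is
#' validated.
#'
#' @inheritParams posterior
#' @param cap refuse instances with more than this many partition pairs.
#' @return A `rating_posterior`, plus attributes `log_Z` (log partition
#'   function up to the constant -H_min) and `n_pairs`.
#' @export
exhaustive_posterior <- function(dataset, queries, cap = 1e6) {
  queries <- as_query_frame(queries)
  n_pairs <- bell_number(dataset$n_users) * bell_number(dataset$n_items)
  if (n_pairs > cap)
    stop("instance requires ", format(n_pairs, big.mark = ","),
         " partition pairs, above the cap of ", cap)
  idx <- resolve_ids(dataset, queries$user, queries$item)
  pu <- set_partitions(dataset$n_users)
  pi_ <- set_partitions(dataset$n_items)
  K <- dataset$K
  Q <- nrow(queries)

  H <- matrix(0, nrow(pu), nrow(pi_))
  for (a in seq_len(nrow(pu)))
    for (b in seq_len(nrow(pi_))) {
      part <- sbm_partition(pu[a, ], pi_[b, ])
      H[a, b] <- hamiltonian(count_blocks(dataset, part))
    }
  w <- exp(-(H - min(H)))
  Z <- sum(w)

  post <- matrix(0, Q, K)
  for (a in seq_len(nrow(pu)))
    for (b in seq_len(nrow(pi_))) {
      part <- sbm_partition(pu[a, ], pi_[b, ])
      cnts <- count_blocks(dataset, part)
      for (q in seq_len(Q)) {
        al <- part$users[idx$user[q] + 1L] + 1L
        be <- part$items[idx$item[q] + 1L] + 1L
        cr <- cnts$arr[al, be, ]
        post[q, ] <- post[q, ] + w[a, b] * (cr + 1) / (sum(cr) + K)
      }
    }
  post <- post / Z
  colnames(post) <- as.character(seq_len(K))
  structure(post, class = c("rating_posterior", "matrix"),
            user = queries$user, item = queries$item,
            log_Z = log(Z) - min(H), n_pairs = n_pairs)
}
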