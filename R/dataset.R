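#' Build a bipartite rating dataset
#'
#' Assembles rating triples (user, item, rating class) into a
#' `rating_dataset`: a bipartite network whose links are labeled with one of
#' `K` rating classes. External user/item identifiers are mapped to dense
#' 0-based internal indices; the external ids are kept so that every output
#' can be expressed in the caller's vocabulary. Classes are categorical: the
#' block model never assumes that class 2 sits "between" 1 and 3. Ordinality
#' is only exploited downstream, by mean/median prediction rules and MAE.
#'
#' @param triples data.frame with columns `user`, `item`, `rating` (extra
#'   columns ignored), or a list of length-3 vectors. May have zero rows.
#' @param K number of rating classes (>= 2). Defaults to the maximum
#'   observed rating.
#' @param user_ids,item_ids optional vectors of external ids fixing the node
#'   universe, so that nodes without any observed rating still exist.
#' @return An object of class `rating_dataset` with fields `n_users`,
#'   `n_items`, `K`, `user` / `item` (0-based internal indices per observed
#'   triple), `rating` (integer in 1..K), `user_ids`, `item_ids`.
#' @examples
#' d <- rating_dataset(data.frame(user = c("A", "A", "B"),
#'                                item = c("x", "y", "x"),
#'                                rating = c(1, 2, 1)), K = 2)
#' d$n_users  # 2
#' @export
rating_dataset <- function(triples, K = NULL, user_ids = NULL, item_ids = NULL) {
  if (is.list(triples) && !is.data.frame(triples)) {
    triples <- as.data.frame(do.call(rbind, lapply(triples, function(t) {
      data.frame(user = t[[1]], item = t[[2]], rating = as.numeric(t[[3]]))
    })))
  }
  if (nrow(triples) > 0) {
    stopifnot(all(c("user", "item", "rating") %in% names(triples)))
    r <- triples$rating
    if (any(r != round(r)) || any(r < 1)) {
      bad <- which(r != round(r) | r < 1)[1]
      stop("rating class must be a positive integer; offending triple: (",
           triples$user[bad], ", ", triples$item[bad], ", ", r[bad], ")")
    }
  }
  if (is.null(K)) {
    K <- if (nrow(triples) > 0) max(triples$rating) else 2L
  }
  K <- as.integer(K)
  if (K < 2) stop("K must be at least 2")
  if (nrow(triples) > 0 && any(triples$rating > K)) {
    bad <- which(triples$rating > K)[1]
    stop("rating class out of range 1..", K, "; offending triple: (",
         triples$user[bad], ", ", triples$item[bad], ", ",
         triples$rating[bad], ")")
  }
  uids <- unique(c(as.character(user_ids), as.character(triples$user)))
  iids <- unique(c(as.character(item_ids), as.character(triples$item)))
  u <- match(as.character(triples$user), uids) - 1L
  i <- match(as.character(triples$item), iids) - 1L
  if (anyDuplicated(cbind(u, i))) {
    d <- which(duplicated(cbind(u, i)))[1]
    stop("duplicate (user, item) pair: (", triples$user[d], ", ",
         triples$item[d], ")")
  }
  structure(list(
    n_users = length(uids), n_items = length(iids), K = K,
    user = as.integer(u), item = as.integer(i),
    rating = as.integer(triples$rating),
    user_ids = uids, item_ids = iids
  ), class = "rating_dataset")
}

#' @export
print.rating_dataset <- function(x, ...) {
  cat("<rating_dataset> ", x$n_users, " users x ", x$n_items, " items, K = ",
      x$K, ", ", length(x$rating), " observed ratings\n", sep = "")
  invisible(x)
}

#' @export
format.rating_dataset <- function(x, ...) {
  paste0(x$n_users, "x", x$n_items, " dataset, K=", x$K,
         ", n=", length(x$rating))
}

n_observed <- function(dataset) length(dataset$rating)

#' Look up internal indices for external ids
#'
#' @param dataset a `rating_dataset`.
#' @param users,items external id vectors.
#' @return list with 0-based `user` and `item` index vectors.
#' @export
resolve_ids <- function(dataset, users, items) {
  u <- match(as.character(users), dataset$user_ids) - 1L
  i <- match(as.character(items), dataset$item_ids) - 1L
  if (anyNA(u)) stop("unknown user id: ", users[which(is.na(u))[1]])
  if (anyNA(i)) stop("unknown item id: ", items[which(is.na(i))[1]])
  list(user = u, item = i)
}
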