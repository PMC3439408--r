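#' Read ratings in the MovieLens tab-separated dialect
#'
#' Parses lines `user<TAB>item<TAB>rating<TAB>timestamp` (the `u.data` /
#' `u1.base` layout); the timestamp is ignored. K is inferred as the
#' maximum observed rating unless given.
#'
#' @param path file path.
#' @param K number of rating classes; overrides inference and makes
#'   out-of-range ratings an error.
#' @param dialect only `"movielens-tab"` is supported.
#' @param user_ids,item_ids optional fixed node universes (useful to align
#'   a test split with its training set).
#' @return a `rating_dataset`.
#' @export
read_ratings <- function(path, K = NULL, dialect = "movielens-tab",
                         user_ids = NULL, item_ids = NULL) {
  dialect <- match.arg(dialect, "movielens-tab")
  if (!is.null(K) && is.na(K)) K <- NULL
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(rating_dataset(data.frame(user = character(), item = character(),
                                     rating = integer()),
                          K = if (is.null(K)) 2 else K,
                          user_ids = user_ids, item_ids = item_ids))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed line ", which(nf < 3)[1], " in ", path,
         ": expected at least 3 tab-separated fields")
  r <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(r))
    stop("malformed line ", which(is.na(r))[1], " in ", path,
         ": rating is not an integer")
  rating_dataset(data.frame(user = vapply(parts, `[[`, "", 1),
                            item = vapply(parts, `[[`, "", 2),
                            rating = r),
                 K = K, user_ids = user_ids, item_ids = item_ids)
}

#' Write ratings in the MovieLens tab-separated dialect
#'
#' Timestamps are zero-filled; external ids are written verbatim, so
#' `read_ratings(write_ratings(d))` round-trips the dataset.
#' @param dataset a `rating_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(dataset, path) {
  lines <- sprintf("%s\t%s\t%d\t0",
                   dataset$user_ids[dataset$user + 1L],
                   dataset$item_ids[dataset$item + 1L],
                   dataset$rating)
  writeLines(lines, path)
  invisible(path)
}

#' Read MovieLens user metadata (`u.user`)
#'
#' Pipe-separated records `id|age|gender|occupation|zip`.
#' @param path file path.
#' @return data.frame with `id`, `age`, `gender`, `occupation`, `zip`.
#' @export
read_user_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5))
    stop("malformed record at line ", which(nf != 5)[1], " in ", path,
         ": expected 5 pipe-separated fields")
  out <- data.frame(id = vapply(parts, `[[`, "", 1),
                    age = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2))),
                    gender = vapply(parts, `[[`, "", 3),
                    occupation = vapply(parts, `[[`, "", 4),
                    zip = vapply(parts, `[[`, "", 5))
  if (anyNA(out$age))
    stop("malformed record at line ", which(is.na(out$age))[1], " in ", path,
         ": age is not an integer")
  if (anyDuplicated(out$id))
    stop("duplicate user id: ", out$id[duplicated(out$id)][1])
  out
}

movielens_genres <- c("unknown", "Action", "Adventure", "Animation",
                      "Children's", "Comedy", "Crime", "Documentary", "Drama",
                      "Fantasy", "Film-Noir", "Horror", "Musical", "Mystery",
                      "Romance", "Sci-Fi", "Thriller", "War", "Western")

#' Read MovieLens item metadata (`u.item`)
#'
#' Pipe-separated records whose last 19 fields are binary genre flags.
#' Items with all flags zero get an empty genre set and are flagged for
#' exclusion from overlap analyses (the Jaccard index is undefined there).
#' @param path file path.
#' @return data.frame with `id`, `title`, and list-column `genres`;
#'   `no_genre` marks empty genre sets.
#' @export
read_item_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "latin1")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 21))
    stop("malformed record at line ", which(nf < 21)[1], " in ", path,
         ": expected at least 21 pipe-separated fields")
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate item id: ", ids[duplicated(ids)][1])
  genres <- lapply(parts, function(p) {
    flags <- suppressWarnings(as.integer(p[(length(p) - 18):length(p)]))
    movielens_genres[which(flags == 1)]
  })
  out <- data.frame(id = ids, title = vapply(parts, `[[`, "", 2))
  out$genres <- genres
  out$no_genre <- lengths(genres) == 0
  out
}

#' Persist a partition sample as plain text
#'
#' Versioned header; each sample stores its chain, sweep, Hamiltonian, and
#' run-length-encoded user/item assignments.
#' @param sample a `partition_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_sample <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#sbmrec-partition-sample v1",
               paste("#n_users", sample$n_users),
               paste("#n_items", sample$n_items)), con)
  rle_str <- function(v) {
    r <- rle(v)
    paste(paste0(r$values, "x", r$lengths), collapse = " ")
  }
  for (s in seq_along(sample$H)) {
    writeLines(c(sprintf("S %d %d %.15g", sample$chain[s], sample$sweep[s],
                         sample$H[s]),
                 paste("U", rle_str(sample$users[s, ])),
                 paste("I", rle_str(sample$items[s, ]))), con)
  }
  invisible(path)
}

#' Read a persisted partition sample
#' @param path file written by [write_partition_sample()].
#' @return a `partition_sample`.
#' @export
read_partition_sample <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#sbmrec-partition-sample"))
    stop("not a partition-sample file: ", path)
  n_users <- as.integer(strsplit(lines[2], " ")[[1]][2])
  n_items <- as.integer(strsplit(lines[3], " ")[[1]][2])
  body <- lines[-(1:3)]
  stopifnot(length(body) %% 3 == 0)
  S <- length(body) / 3
  un_rle <- function(str) {
    toks <- strsplit(strsplit(str, " ", fixed = TRUE)[[1]], "x", fixed = TRUE)
    unlist(lapply(toks, function(t)
      rep(as.integer(t[1]), as.integer(t[2]))))
  }
  users <- matrix(0L, S, n_users); items <- matrix(0L, S, n_items)
  H <- numeric(S); chain <- integer(S); sweep <- integer(S)
  for (s in seq_len(S)) {
    hdr <- strsplit(body[3 * s - 2], " ", fixed = TRUE)[[1]]
    chain[s] <- as.integer(hdr[2]); sweep[s] <- as.integer(hdr[3])
    H[s] <- as.numeric(hdr[4])
    users[s, ] <- un_rle(sub("^U ", "", body[3 * s - 1]))
    items[s, ] <- un_rle(sub("^I ", "", body[3 * s]))
  }
  structure(list(users = users, items = items, H = H, sweep = sweep,
                 chain = chain, n_users = n_users, n_items = n_items,
                 acceptance_rate = NA_real_),
            class = "partition_sample")
}
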