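# Meta-learning task construction: random partitions, substrate-cluster
# leave-one-cluster-out plans, time-based splits, and episode sampling.

new_task <- function(task_id, indices, split_role) {
  stopifnot(length(indices) >= 1, !anyDuplicated(indices),
            split_role %in% c("train", "valid", "test"))
  structure(list(task_id = task_id, indices = as.integer(indices),
                 split_role = split_role),
            class = "dkmeta_task")
}

#' @export
print.dkmeta_task <- function(x, ...) {
  cat(sprintf("<dkmeta_task> %s (%s, %d rows)\n", x$task_id,
              x$split_role, length(x$indices)))
  invisible(x)
}

# Accept either a dkmeta_task or a bare index vector.
task_indices <- function(task) {
  if (inherits(task, "dkmeta_task")) task$indices else as.integer(task)
}

chunk_indices <- function(idx, task_size) {
  n <- length(idx)
  k <- max(1L, n %/% task_size)
  grp <- rep(seq_len(k), each = task_size, length.out = n)
  split(idx, grp)
}

#' Random partition of a dataset into meta-learning tasks
#'
#' Splits the rows 80:20 (by default) into training and test pools, then
#' divides each pool into disjoint tasks of roughly `task_size` rows
#' (the final task absorbs the remainder so every row is used exactly
#' once).  A fraction of the training tasks is set aside for validation.
#'
#' @param n_records number of dataset rows.
#' @param train_frac fraction of rows in the training pool.
#' @param task_size target number of rows per task.
#' @param seed integer seed.
#' @param valid_frac fraction of training tasks reassigned to validation.
#' @return list with elements `train`, `valid`, `test`: lists of
#'   `dkmeta_task` objects.
#' @export
random_task_partition <- function(n_records, train_frac = 0.8, task_size,
                                  seed = 1, valid_frac = 0.1) {
  stopifnot(train_frac > 0, train_frac < 1, task_size >= 2)
  n_train <- round(train_frac * n_records)
  if (task_size > n_train || task_size > (n_records - n_train)) {
    stop("task_size exceeds the split size", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n_records))
  train_pool <- perm[seq_len(n_train)]
  test_pool <- perm[-seq_len(n_train)]
  train_chunks <- chunk_indices(train_pool, task_size)
  test_chunks <- chunk_indices(test_pool, task_size)
  n_valid <- min(length(train_chunks) - 1L,
                 round(valid_frac * length(train_chunks)))
  n_valid <- max(n_valid, 0L)
  roles <- c(rep("train", length(train_chunks) - n_valid),
             rep("valid", n_valid))
  train_tasks <- Map(function(ix, i, role) {
    new_task(sprintf("%s_%02d", role, i), ix, role)
  }, train_chunks, seq_along(train_chunks), roles)
  out <- list(
    train = unname(train_tasks[roles == "train"]),
    valid = unname(train_tasks[roles == "valid"]),
    test = unname(Map(function(ix, i) {
      new_task(sprintf("test_%02d", i), ix, "test")
    }, test_chunks, seq_along(test_chunks))))
  out
}

#' Sample a support/query episode from a task
#'
#' Draws disjoint support and query index sets without replacement.
#' With `stratified = TRUE` (the default) the support set is guaranteed
#' to contain at least one example of each class, so GP and prototype
#' adaptation always sees both labels.
#'
#' @param task a `dkmeta_task` or integer index vector.
#' @param support_size,query_size episode sizes.
#' @param stratified stratify the support draw by class?
#' @param seed integer seed.
#' @param labels full-dataset label vector (required when `stratified`).
#' @return list with integer vectors `support` and `query`.
#' @export
sample_episode <- function(task, support_size, query_size,
                           stratified = TRUE, seed = 1, labels = NULL) {
  idx <- task_indices(task)
  stopifnot(support_size >= 1, query_size >= 1)
  if (support_size + query_size > length(idx)) {
    stop("task too small for the requested episode", call. = FALSE)
  }
  with_seed(seed, {
    if (stratified) {
      if (is.null(labels)) stop("stratified sampling requires labels")
      y <- labels[idx]
      classes <- sort(unique(y))
      if (length(classes) < 2) {
        stop("stratified sampling requires a task with both classes",
             call. = FALSE)
      }
      if (support_size < length(classes)) {
        stop("support_size smaller than the number of classes",
             call. = FALSE)
      }
      # proportional allocation with at least one per class
      n_c <- pmax(1L, round(support_size * table(y)[as.character(classes)] /
                              length(y)))
      while (sum(n_c) > support_size) n_c[which.max(n_c)] <- n_c[which.max(n_c)] - 1L
      while (sum(n_c) < support_size) n_c[which.max(table(y))] <- n_c[which.max(table(y))] + 1L
      support <- unlist(lapply(seq_along(classes), function(i) {
        pool <- idx[y == classes[i]]
        pool[sample.int(length(pool), min(n_c[i], length(pool)))]
      }))
      # top up if a class pool ran short
      if (length(support) < support_size) {
        rest <- setdiff(idx, support)
        support <- c(support, rest[sample.int(length(rest),
                                              support_size - length(support))])
      }
    } else {
      support <- idx[sample.int(length(idx), support_size)]
    }
    rest <- setdiff(idx, support)
    query <- rest[sample.int(length(rest), query_size)]
    list(support = as.integer(support), query = as.integer(query))
  })
}

#' Cluster substrates by structural fingerprints
#'
#' Embeds the (deduplicated) substrate MACCS keys into two dimensions by
#' nonmetric multidimensional scaling of Jaccard dissimilarities (the
#' 2-D manifold embedding; `"pcoa"` gives the deterministic principal
#' coordinates alternative), then k-means clusters the embedded
#' coordinates.  Duplicated fingerprint rows receive identical labels.
#'
#' @param maccs_matrix binary matrix, one row per substrate, 166 columns.
#' @param n_components embedding dimension (default 2).
#' @param n_clusters number of k-means clusters (default 6).
#' @param seed integer seed (embedding and k-means).
#' @param method `"nmds"` (default) or `"pcoa"`.
#' @return integer cluster labels in `1:n_clusters`, with the embedding
#'   coordinates of every substrate attached as attribute `"embedding"`.
#' @export
substrate_clusters <- function(maccs_matrix, n_components = 2,
                               n_clusters = 6, seed = 1,
                               method = c("nmds", "pcoa")) {
  method <- match.arg(method)
  if (!is.matrix(maccs_matrix)) maccs_matrix <- as.matrix(maccs_matrix)
  n <- nrow(maccs_matrix)
  if (n_clusters >= n) {
    stop("need more substrates than clusters", call. = FALSE)
  }
  key <- apply(maccs_matrix, 1, paste0, collapse = "")
  uniq <- !duplicated(key)
  U <- maccs_matrix[uniq, , drop = FALSE]
  if (nrow(U) <= n_clusters) {
    stop("need more distinct substrates than clusters", call. = FALSE)
  }
  d <- vegan::vegdist(U, method = "jaccard", binary = TRUE)
  d[!is.finite(d)] <- 0  # pairs of all-zero keys
  emb <- with_seed(seed, {
    if (method == "nmds") {
      # near-zero stress on easy configurations is routine, not an error
      fit <- suppressWarnings(
        vegan::metaMDS(d, k = n_components, trace = 0, try = 4,
                       trymax = 8, autotransform = FALSE,
                       wascores = FALSE))
      vegan::scores(fit)
    } else {
      e <- stats::cmdscale(d, k = n_components)
      if (ncol(e) < n_components) {
        e <- cbind(e, matrix(0, nrow(e), n_components - ncol(e)))
      }
      e
    }
  })
  km <- with_seed(seed + 1, stats::kmeans(emb, centers = n_clusters,
                                          nstart = 10, iter.max = 100))
  labels_u <- km$cluster
  labels <- labels_u[match(key, key[uniq])]
  attr(labels, "embedding") <- emb[match(key, key[uniq]), , drop = FALSE]
  labels
}

#' Leave-one-cluster-out evaluation plan
#'
#' One train/test combination per cluster: the held-out cluster forms
#' the test task and the remaining clusters form the training pool, so
#' test substrates never appear in training.
#'
#' @param cluster_labels integer cluster label per substrate (or per
#'   reaction, if reactions have inherited their substrate's label).
#' @return Object of class `loco_plan`: a list with one combination per
#'   cluster, each holding `test_cluster`, `train_clusters`,
#'   `test_indices` and `train_indices`.
#' @export
loco_plan <- function(cluster_labels) {
  labs <- sort(unique(cluster_labels))
  if (length(labs) < 2) {
    stop("leave-one-cluster-out requires at least two clusters",
         call. = FALSE)
  }
  combos <- lapply(labs, function(cl) {
    list(test_cluster = cl,
         train_clusters = setdiff(labs, cl),
         test_indices = which(cluster_labels == cl),
         train_indices = which(cluster_labels != cl))
  })
  structure(combos, class = "loco_plan")
}

#' @export
print.loco_plan <- function(x, ...) {
  cat(sprintf("<loco_plan> %d combinations; test sizes: %s\n", length(x),
              paste(vapply(x, function(c) length(c$test_indices), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Time-based train/test split
#'
#' Rows published up to `train_max_year` form the training pool, rows
#' from `test_min_year` on form the test task; rows in the gap are
#' excluded (and counted).
#'
#' @param records data frame with a `year` column.
#' @param train_max_year last year included in training (default 2020).
#' @param test_min_year first year included in the test task
#'   (default 2023).
#' @return list with integer index vectors `train`, `test`, `excluded`.
#' @export
time_split <- function(records, train_max_year = 2020,
                       test_min_year = 2023) {
  stopifnot(train_max_year < test_min_year, "year" %in% names(records))
  yr <- records$year
  train <- which(yr <= train_max_year)
  test <- which(yr >= test_min_year)
  excluded <- which(yr > train_max_year & yr < test_min_year)
  if (!length(test)) {
    stop(sprintf("no rows at or after %d: empty test task", test_min_year),
         call. = FALSE)
  }
  if (!length(train)) {
    stop(sprintf("no rows at or before %d: empty training pool",
                 train_max_year), call. = FALSE)
  }
  list(train = train, test = test, excluded = excluded)
}
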