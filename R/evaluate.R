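# Scoring and aggregation.
#
# The headline metric is the area under the precision-recall curve in
# its average-precision form: the sum over positives of the precision at
# that positive's rank in descending score order.  Ties are handled by
# the tied-block convention -- every positive inside a block of equal
# scores is assigned the precision at the end of the block -- which
# makes the AUPRC of a constant scorer equal to the positive prevalence.

#' Area under the precision-recall curve
#'
#' @param labels binary vector (0/1 or logical) with at least one
#'   positive.
#' @param scores numeric scores, higher = more likely positive.
#' @return scalar AUPRC in \[0, 1\].
#' @examples
#' auprc(c(1, 0, 1), c(0.9, 0.8, 0.7))  # (1 + 2/3) / 2
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0L, 1L)), all(is.finite(scores)))
  P <- sum(labels)
  if (P == 0) stop("AUPRC undefined without positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  block <- cumsum(!duplicated(s))          # tied-score block ids
  tp_end <- cumsum(y)[!duplicated(block, fromLast = TRUE)]
  n_end <- which(!duplicated(block, fromLast = TRUE))
  pos_in_block <- tapply(y, block, sum)
  sum(pos_in_block * tp_end / n_end) / P
}

#' AUPRC of an uninformative (constant) scorer
#'
#' Under the tied-block convention this equals the positive prevalence,
#' the natural chance baseline for imbalanced classification.
#'
#' @param labels binary label vector.
#' @return scalar baseline AUPRC.
#' @export
prevalence_baseline <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), sum(labels) >= 1)
  mean(labels)
}

#' Aggregate per-repeat scores into a results row
#'
#' @param scores numeric vector of per-repeat AUPRC values.
#' @param dispersion_kind `"sd"` (sample standard deviation) or `"se"`
#'   (standard error of the mean).
#' @return one-row data frame with `mean_auprc`, `dispersion`,
#'   `dispersion_kind`, `n_repeats`.
#' @export
aggregate_scores <- function(scores, dispersion_kind = c("sd", "se")) {
  dispersion_kind <- match.arg(dispersion_kind)
  stopifnot(length(scores) >= 1, all(is.finite(scores)))
  s <- if (length(scores) > 1) stats::sd(scores) else 0
  if (dispersion_kind == "se") s <- s / sqrt(length(scores))
  data.frame(mean_auprc = mean(scores), dispersion = s,
             dispersion_kind = dispersion_kind,
             n_repeats = length(scores))
}

#' Evaluate trained models over a factorial test protocol
#'
#' Runs [meta_test()] for every combination of method and support size
#' on each test task and stacks the per-repeat AUPRC values into a tidy
#' results table.
#'
#' @param fits named list of `dkmeta_model` objects.
#' @param X,y dataset feature matrix and 0/1 labels.
#' @param test_tasks list of test tasks (`dkmeta_task` or index vectors).
#' @param support_sizes integer vector of support sizes.
#' @param query_size query-set size (default 128).
#' @param n_repeats support/query resampling repeats per cell
#'   (10 for random/time protocols, 30 for substrate-based).
#' @param seed integer seed.
#' @param split_mode label recorded in the table (e.g. `"random"`).
#' @param stratified stratify support draws by class?
#' @return data frame with columns `method`, `split_mode`, `combination`,
#'   `support_size`, `repeat_id`, `auprc`.
#' @export
run_experiment <- function(fits, X, y, test_tasks, support_sizes,
                           query_size = 128, n_repeats = 10, seed = 1,
                           split_mode = "random", stratified = TRUE) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$method, "")
  }
  if (!is.list(test_tasks) || inherits(test_tasks, "dkmeta_task")) {
    test_tasks <- list(test_tasks)
  }
  seeds <- derive_seeds(seed, length(fits) * length(test_tasks) *
                          length(support_sizes))
  rows <- list()
  k <- 0L
  for (m in names(fits)) {
    for (ti in seq_along(test_tasks)) {
      for (ss in support_sizes) {
        k <- k + 1L
        scores <- meta_test(fits[[m]], X, y, test_tasks[[ti]],
                            support_size = ss, query_size = query_size,
                            n_repeats = n_repeats, seed = seeds[k],
                            stratified = stratified)
        rows[[k]] <- data.frame(method = m, split_mode = split_mode,
                                combination = ti, support_size = ss,
                                repeat_id = seq_len(n_repeats),
                                auprc = scores$auprc)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a results table over repeats
#'
#' @param results data frame from [run_experiment()].
#' @param dispersion_kind `"sd"` or `"se"` (the random/substrate figures
#'   report sd, the time-based figure reports se).
#' @return data frame with one row per (method, split_mode, combination,
#'   support_size).
#' @export
aggregate_results <- function(results, dispersion_kind = c("sd", "se")) {
  dispersion_kind <- match.arg(dispersion_kind)
  key <- c("method", "split_mode", "combination", "support_size")
  stopifnot(all(c(key, "auprc") %in% names(results)))
  groups <- results[key]
  agg <- do.call(rbind, by(results, groups[rev(key)], function(d) {
    cbind(d[1, key, drop = FALSE],
          aggregate_scores(d$auprc, dispersion_kind))
  }))
  rownames(agg) <- NULL
  agg[order(agg$method, agg$combination, agg$support_size), ]
}
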