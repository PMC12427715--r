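#' Replicate-aware train/test/validation split
#'
#' Partitions samples into train/test/validation subsets (default 70/20/10)
#' without ever separating a replicate group: all scans of one fruit stay in
#' one subset, so evaluation reflects generalization rather than memorized
#' replicates. Targets are computed by largest-remainder apportionment;
#' groups are shuffled with the seed and assigned greedily to the partition
#' with the largest remaining deficit. With singleton groups and counts
#' divisible by the fractions the subset sizes are exact.
#'
#' @param df Data frame with `sample_id` and `replicate_group_id` columns.
#' @param fractions Named numeric vector `(train, test, validation)`;
#'   positive, summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @return A `split_plan`: list with `train_ids`, `test_ids`,
#'   `validation_ids`, an `assignments` tibble (`sample_id`,
#'   `replicate_group_id`, `subset`), `fractions` and `seed`.
#' @examples
#' df <- tibble::tibble(sample_id = as.character(1:10),
#'                      replicate_group_id = as.character(1:10))
#' plan <- split_dataset(df, seed = 1)
#' lengths(plan[c("train_ids", "test_ids", "validation_ids")])
#' @export
split_dataset <- function(df,
                          fractions = c(train = 0.7, test = 0.2, validation = 0.1),
                          seed = 1) {
  check_columns(df, c("sample_id", "replicate_group_id"), "split input")
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be positive and sum to 1")
  }
  if (anyDuplicated(df$sample_id)) abort("sample_id values must be unique")
  subsets <- names(fractions)
  if (is.null(subsets)) {
    subsets <- c("train", "test", "validation")[seq_along(fractions)]
    names(fractions) <- subsets
  }
  n <- nrow(df)

  # largest-remainder apportionment of n over the fractions
  raw <- n * fractions
  targets <- floor(raw)
  leftover <- n - sum(targets)
  if (leftover > 0) {
    order_rem <- order(raw - targets, decreasing = TRUE)
    targets[order_rem[seq_len(leftover)]] <- targets[order_rem[seq_len(leftover)]] + 1
  }

  group_sizes <- table(df$replicate_group_id)
  if (max(group_sizes) > min(targets)) {
    abort(sprintf(
      "infeasible split: replicate group of size %d exceeds the smallest partition target (%d)",
      max(group_sizes), min(targets)))
  }

  groups <- names(group_sizes)
  set.seed(seed)
  groups <- sample(groups)
  assigned <- integer(length(fractions))
  names(assigned) <- subsets
  group_subset <- character(length(groups))
  names(group_subset) <- groups
  for (g in groups) {
    deficit <- targets - assigned
    pick <- subsets[which.max(deficit)]   # ties resolve in declared order
    group_subset[g] <- pick
    assigned[pick] <- assigned[pick] + group_sizes[[g]]
  }

  assignments <- tibble::tibble(
    sample_id = df$sample_id,
    replicate_group_id = df$replicate_group_id,
    subset = unname(group_subset[as.character(df$replicate_group_id)])
  )
  structure(list(
    train_ids = assignments$sample_id[assignments$subset == "train"],
    test_ids = assignments$sample_id[assignments$subset == "test"],
    validation_ids = assignments$sample_id[assignments$subset == "validation"],
    assignments = assignments,
    fractions = fractions,
    seed = seed
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Replicate-aware split (seed %d): train %d / test %d / validation %d\n",
              x$seed, length(x$train_ids), length(x$test_ids),
              length(x$validation_ids)))
  invisible(x)
}
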