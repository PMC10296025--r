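#' Within-subject label-permutation test for unequal trial counts
#'
#' Observed statistic: the mean over subjects of the difference of
#' within-subject trial means, `mean_s( mean(A_s) - mean(B_s) )`. The null
#' distribution is built by re-assigning, within each subject, the pooled
#' trials to pseudo-conditions of the original sizes and recomputing the
#' statistic — so unequal trial counts per condition are handled without
#' subsampling. The two-sided p-value uses the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, which can never be 0.
#'
#' @param trials_a,trials_b Named lists (one element per subject, names
#'   aligned) of numeric trial-feature vectors; every subject needs at least
#'   one trial per condition.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param within_subject Shuffle labels within each subject (default,
#'   respecting the subject-paired design); `FALSE` permutes the pooled trial
#'   values across all subjects and conditions.
#' @return An `eeg_perm_result`: `ground_truth`, `null_distribution`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(trials_a, trials_b, n_perm = 1000, seed = 1,
                             within_subject = TRUE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.null(names(trials_a))) names(trials_a) <- seq_along(trials_a)
  if (is.null(names(trials_b))) names(trials_b) <- seq_along(trials_b)
  subjects <- names(trials_a)
  if (!setequal(subjects, names(trials_b)))
    stop("subjects differ between conditions: ",
         paste(union(setdiff(subjects, names(trials_b)),
                     setdiff(names(trials_b), subjects)), collapse = ", "))
  for (s in subjects) {
    if (length(trials_a[[s]]) < 1 || length(trials_b[[s]]) < 1)
      stop("subject ", s, " has no trials in one condition")
  }
  obs <- mean(vapply(subjects, function(s)
    mean(trials_a[[s]]) - mean(trials_b[[s]]), 0))

  pooled <- lapply(subjects, function(s) c(trials_a[[s]], trials_b[[s]]))
  nA <- vapply(subjects, function(s) length(trials_a[[s]]), 0L)
  nT <- lengths(pooled)
  tot <- vapply(pooled, sum, 0)
  ns <- length(subjects)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  null <- numeric(n_perm)
  if (within_subject) {
    for (p in seq_len(n_perm)) {
      acc <- 0
      for (i in seq_len(ns)) {
        sA <- sum(pooled[[i]][sample.int(nT[i], nA[i])])
        acc <- acc + sA / nA[i] - (tot[i] - sA) / (nT[i] - nA[i])
      }
      null[p] <- acc / ns
    }
  } else {
    allv <- unlist(pooled, use.names = FALSE)
    for (p in seq_len(n_perm)) {
      perm <- sample(allv)
      acc <- 0; ptr <- 0
      for (i in seq_len(ns)) {
        v <- perm[(ptr + 1):(ptr + nT[i])]
        sA <- sum(v[seq_len(nA[i])])
        acc <- acc + sA / nA[i] - (sum(v) - sA) / (nT[i] - nA[i])
        ptr <- ptr + nT[i]
      }
      null[p] <- acc / ns
    }
  }
  p_value <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  structure(list(ground_truth = obs, null_distribution = null,
                 p_value = p_value, n_perm = n_perm, seed = seed),
            class = "eeg_perm_result")
}

#' @export
print.eeg_perm_result <- function(x, ...) {
  cat(sprintf("<permutation test> observed = %.4g, p = %.4g (%d permutations, seed %s)\n",
              x$ground_truth, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Bonferroni correction
#'
#' Exact threshold `alpha / family_size`; a p-value is significant when it is
#' strictly below the threshold.
#'
#' @param p_values Numeric vector of p-values.
#' @param family_size Number of tests in the family (default
#'   `length(p_values)`).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `threshold` and logical `significant` flags.
#' @export
#' @examples
#' bonferroni(c(0.001, 0.01), family_size = 32)$threshold  # 0.0015625
bonferroni <- function(p_values, family_size = length(p_values),
                       alpha = 0.05) {
  stopifnot(family_size >= 1, alpha > 0, alpha < 1)
  threshold <- alpha / family_size
  list(threshold = threshold, significant = p_values < threshold)
}

#' Permutation contrasts for a set of features
#'
#' Runs [permutation_test()] for every named feature and applies a
#' Bonferroni correction across the family.
#'
#' @param features Named list; each element is a list with one entry per
#'   contrasted condition, each of which is a named per-subject list of
#'   trial-feature vectors.
#' @param conditions Character length-2: the two condition labels to
#'   contrast (first minus second).
#' @param n_perm,seed Passed to [permutation_test()] (a distinct seed,
#'   `seed + index`, is used per feature).
#' @param alpha Family-wise level.
#' @param family_size Bonferroni family size (default: number of features).
#' @return Data frame: `feature`, `observed`, `p_value`, `significant`,
#'   `seed`; empty input gives an empty data frame.
#' @export
contrast_report <- function(features, conditions = c("planned", "unplanned"),
                            n_perm = 1000, seed = 1, alpha = 0.05,
                            family_size = NULL) {
  if (length(features) == 0)
    return(data.frame(feature = character(0), observed = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      seed = integer(0)))
  stopifnot(!is.null(names(features)), length(conditions) == 2)
  rows <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    pr <- permutation_test(f[[conditions[1]]], f[[conditions[2]]],
                           n_perm = n_perm, seed = as.integer(seed) + i)
    data.frame(feature = names(features)[i], observed = pr$ground_truth,
               p_value = pr$p_value, seed = as.integer(seed) + i)
  })
  out <- do.call(rbind, rows)
  if (is.null(family_size)) family_size <- nrow(out)
  if (1 / (n_perm + 1) >= alpha / family_size)
    warning(sprintf(paste0(
      "the smallest attainable p-value, 1/%d, is not below the Bonferroni ",
      "threshold %.3g; no contrast can be flagged - increase n_perm"),
      n_perm + 1, alpha / family_size))
  out$significant <- bonferroni(out$p_value, family_size, alpha)$significant
  out[, c("feature", "observed", "p_value", "significant", "seed")]
}
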