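#' Per-epoch feature extraction for one subject and condition
#'
#' Computes the three feature families used for classification from a
#' preprocessed epoch set:
#' \describe{
#'   \item{psd_*}{mean band power (theta, alpha) per scalp region, one value
#'     per epoch;}
#'   \item{coh_*}{theta-band region-pair coherence (frontal-frontal,
#'     frontal-parietal, parietal-parietal) estimated on consecutive
#'     non-overlapping blocks of `coh_block` epochs after the CSD transform —
#'     a single epoch gives too few Welch windows for a stable coherence
#'     estimate, so every epoch of a block carries its block's value;}
#'   \item{spe_*}{normalized spectral entropy per channel over
#'     `entropy_range`.}
#' }
#'
#' @param epochs A preprocessed `eeg_epochs`.
#' @param bands List of [band_spec()]s for the power features.
#' @param region_map Named list of channel vectors.
#' @param coh_band [band_spec()] for the coherence features.
#' @param coh_block Epochs per coherence block (default 5).
#' @param entropy_range Hz range for spectral entropy.
#' @param window Welch window in samples.
#' @param apply_csd Apply the surface Laplacian before coherence (default
#'   TRUE).
#' @return Data frame keyed by `subject`, `condition`, `epoch` with one
#'   column per feature.
#' @export
epoch_features <- function(epochs,
                           bands = list(band_spec("theta", 4, 8),
                                        band_spec("alpha", 8, 13)),
                           region_map = eeg_regions(),
                           coh_band = band_spec("theta", 4, 8),
                           coh_block = 5,
                           entropy_range = c(0.5, 32),
                           window = 256,
                           apply_csd = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_ep <- dim(epochs$data)[1]
  out <- data.frame(subject = rep(epochs$subject, n_ep),
                    condition = rep(epochs$condition, n_ep),
                    epoch = seq_len(n_ep))

  psd <- welch_psd(epochs, window = window)
  for (bd in bands) {
    bp <- band_power(psd, bd)
    for (rg in names(region_map)) {
      chans <- intersect(region_map[[rg]], colnames(bp))
      out[[paste("psd", bd$name, rg, sep = "_")]] <-
        rowMeans(bp[, chans, drop = FALSE])
    }
  }

  em <- entropy_matrix(epochs, window = window, f_range = entropy_range)
  for (ch in colnames(em)) out[[paste0("spe_", ch)]] <- em[, ch]

  ce <- if (apply_csd) current_source_density(epochs) else epochs
  blocks <- split(seq_len(n_ep), ceiling(seq_len(n_ep) / coh_block))
  pairs <- list(c("Frontal", "Frontal"), c("Frontal", "Parietal"),
                c("Parietal", "Parietal"))
  for (pr in pairs)
    out[[paste("coh", pr[1], pr[2], sep = "_")]] <- NA_real_
  for (bl in blocks) {
    sub <- ce
    sub$data <- ce$data[bl, , , drop = FALSE]
    cm <- coherency(sub, band = coh_band, fft_points = window)
    for (pr in pairs)
      out[bl, paste("coh", pr[1], pr[2], sep = "_")] <-
        region_pair_coherence(cm, pr, region_map)
  }
  out
}

#' Assemble a labelled feature matrix
#'
#' Joins the three per-epoch feature families on `(subject, condition,
#' epoch)` and selects the requested feature set. Subjects lacking one of the
#' two conditions are dropped with a warning; misaligned rows across families
#' are an error.
#'
#' @param psd_features,coh_features,spe_features Data frames as produced by
#'   [epoch_features()] (each may carry only its own family's columns; a
#'   single combined table can be passed for all three).
#' @param set One of `"psd"`, `"connectivity"`, `"spe"`, `"all"`.
#' @return An `eeg_features` list: `x` (numeric matrix), `y` (factor of
#'   condition labels), `groups` (subject per row), `feature_set`.
#' @export
build_feature_matrix <- function(psd_features, coh_features = psd_features,
                                 spe_features = psd_features,
                                 set = c("all", "psd", "connectivity",
                                         "spe")) {
  set <- match.arg(set)
  key <- c("subject", "condition", "epoch")
  fam <- list(psd = psd_features, connectivity = coh_features,
              spe = spe_features)
  prefix <- c(psd = "psd_", connectivity = "coh_", spe = "spe_")
  tabs <- list()
  for (f in names(fam)) {
    tb <- fam[[f]]
    cols <- grep(paste0("^", prefix[f]), names(tb), value = TRUE)
    if (length(cols) == 0)
      stop("no ", prefix[f], "* columns found in the ", f, " feature table")
    tabs[[f]] <- tb[, c(key, cols)]
  }
  merged <- tabs[[1]]
  for (f in names(tabs)[-1]) {
    before <- nrow(merged)
    merged <- merge(merged, tabs[[f]], by = key)
    if (nrow(merged) != before || nrow(merged) != nrow(tabs[[f]]))
      stop(sprintf(
        "feature families misaligned on (subject, condition, epoch): %d vs %d rows, %d after join",
        before, nrow(tabs[[f]]), nrow(merged)))
  }
  # completeness: every subject must have both conditions
  conds <- unique(merged$condition)
  keep <- vapply(split(merged$condition, merged$subject),
                 function(cc) all(conds %in% cc), TRUE)
  dropped <- names(keep)[!keep]
  if (length(dropped) > 0) {
    warning("dropping subject(s) missing a condition: ",
            paste(dropped, collapse = ", "))
    merged <- merged[!merged$subject %in% dropped, ]
  }
  sel_cols <- switch(set,
    all = unlist(lapply(prefix, function(p)
      grep(paste0("^", p), names(merged), value = TRUE)), use.names = FALSE),
    psd = grep("^psd_", names(merged), value = TRUE),
    connectivity = grep("^coh_", names(merged), value = TRUE),
    spe = grep("^spe_", names(merged), value = TRUE))
  x <- as.matrix(merged[, sel_cols, drop = FALSE])
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(list(x = x, y = factor(merged$condition),
                 groups = as.character(merged$subject), feature_set = set),
            class = "eeg_features")
}

#' Subject-independent cross-validated SVM evaluation
#'
#' Grouped k-fold cross-validation: subjects (groups) are shuffled with the
#' given seed and split into `folds` folds, so no subject ever contributes
#' epochs to both the training and the test side of a fold — the within-fold
#' train/test subject intersection is asserted empty. Features are
#' standardized using training-fold statistics only; the classifier is an
#' RBF-kernel SVM with probability outputs, and performance is summarised by
#' per-fold ROC AUC plus accuracy, precision, recall and F1 (per class and
#' macro-averaged) pooled over folds.
#'
#' @param features An `eeg_features` from [build_feature_matrix()].
#' @param folds Number of folds (default 5); must not exceed the number of
#'   distinct subjects.
#' @param seed Seed controlling fold assignment and the SVM's internal
#'   probability calibration.
#' @param cost,gamma RBF-SVM hyperparameters (defaults: cost 1, gamma
#'   `1/ncol(x)`).
#' @return An `eeg_clf_report`: `auc` (per fold), `auc_mean`, `auc_sd`,
#'   `accuracy`, `per_class` (precision/recall/F1), `macro`, `folds` (the
#'   subject assignment).
#' @export
evaluate_classifier <- function(features, folds = 5, seed = 1, cost = 1,
                                gamma = NULL) {
  stopifnot(inherits(features, "eeg_features"))
  if (nlevels(features$y) != 2) stop("labels must be binary")
  subjects <- unique(features$groups)
  if (length(subjects) < folds)
    stop(sprintf("%d subjects cannot fill %d subject-independent folds",
                 length(subjects), folds))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  shuffled <- sample(subjects)
  assignment <- rep(seq_len(folds), length.out = length(shuffled))
  fold_of <- stats::setNames(assignment, shuffled)

  if (is.null(gamma)) gamma <- 1 / ncol(features$x)
  pos <- levels(features$y)[2]
  auc_folds <- numeric(folds)
  truth_all <- factor(character(0), levels = levels(features$y))
  pred_all <- factor(character(0), levels = levels(features$y))
  for (k in seq_len(folds)) {
    test_subj <- names(fold_of)[fold_of == k]
    train_subj <- setdiff(subjects, test_subj)
    stopifnot(length(intersect(train_subj, test_subj)) == 0)  # no leakage
    tr <- features$groups %in% train_subj
    te <- features$groups %in% test_subj
    if (nlevels(droplevels(features$y[tr])) < 2)
      stop("a training split lost one of the classes")
    mu <- colMeans(features$x[tr, , drop = FALSE])
    sg <- apply(features$x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(features$x[tr, , drop = FALSE], mu, sg)
    xte <- scale(features$x[te, , drop = FALSE], mu, sg)
    set.seed(as.integer(seed) + k)   # svm's probability model resamples
    fit <- e1071::svm(xtr, droplevels(features$y[tr]), kernel = "radial",
                      cost = cost, gamma = gamma, probability = TRUE)
    pr <- predict(fit, xte, probability = TRUE)
    prob <- attr(pr, "probabilities")[, pos]
    auc_folds[k] <- as.numeric(pROC::auc(pROC::roc(
      response = features$y[te] == pos, predictor = prob, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE))))
    truth_all <- c(truth_all, features$y[te])
    pred_all <- c(pred_all, factor(as.character(pr),
                                   levels = levels(features$y)))
  }
  cm <- table(truth = truth_all, predicted = pred_all)
  per_class <- t(vapply(levels(features$y), function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }, c(precision = 0, recall = 0, f1 = 0)))
  structure(list(
    feature_set = features$feature_set,
    auc = auc_folds, auc_mean = mean(auc_folds), auc_sd = sd(auc_folds),
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_class,
    macro = colMeans(per_class),
    confusion = cm,
    folds = fold_of, seed = seed),
    class = "eeg_clf_report")
}

#' @export
print.eeg_clf_report <- function(x, ...) {
  cat(sprintf("<classifier report> feature set '%s': AUC %.3f +/- %.3f (%d folds), accuracy %.3f\n",
              x$feature_set, x$auc_mean, x$auc_sd, length(x$auc),
              x$accuracy))
  invisible(x)
}
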