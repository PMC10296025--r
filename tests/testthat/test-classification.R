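# synthetic per-epoch feature tables with a controllable class separation
fake_features <- function(n_subj = 10, n_ep = 12, effect = 0, seed = 1,
                          subj_sd = 0.5) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    off <- rnorm(3, 0, subj_sd)
    for (cond in c("planned", "unplanned")) {
      mu <- if (cond == "planned") effect else 0
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, condition = cond, epoch = seq_len(n_ep),
        psd_theta_Frontal = rnorm(n_ep, mu + off[1]),
        psd_alpha_Parietal = rnorm(n_ep, -mu + off[2]),
        coh_Frontal_Parietal = rnorm(n_ep, mu + off[3]),
        spe_Fp1 = rnorm(n_ep, -mu),
        spe_Oz = rnorm(n_ep, mu))
    }
  }
  do.call(rbind, rows)
}

test_that("feature-set selection picks exactly the requested columns", {
  ft <- fake_features()
  fm_spe <- build_feature_matrix(ft, ft, ft, set = "spe")
  expect_identical(colnames(fm_spe$x), c("spe_Fp1", "spe_Oz"))
  fm_all <- build_feature_matrix(ft, ft, ft, set = "all")
  n_psd <- ncol(build_feature_matrix(ft, ft, ft, set = "psd")$x)
  n_coh <- ncol(build_feature_matrix(ft, ft, ft, set = "connectivity")$x)
  expect_equal(ncol(fm_all$x), n_psd + n_coh + ncol(fm_spe$x))
  expect_equal(nrow(fm_all$x), nrow(ft))
  expect_equal(nlevels(fm_all$y), 2)
})

test_that("subjects missing a condition are excluded with a warning", {
  ft <- fake_features(n_subj = 5)
  ft <- ft[!(ft$subject == 3 & ft$condition == "unplanned"), ]
  expect_warning(fm <- build_feature_matrix(ft, ft, ft, set = "all"),
                 "3")
  expect_false("3" %in% fm$groups)
  expect_equal(length(unique(fm$groups)), 4)
})

test_that("misaligned feature families are rejected with row counts", {
  ft <- fake_features(n_subj = 4)
  short <- ft[-c(1, 2), ]
  expect_error(build_feature_matrix(ft, short, ft, set = "all"),
               "misaligned")
})

test_that("grouped cross-validation never mixes subjects across the fold boundary", {
  ft <- fake_features(n_subj = 10, effect = 2)
  fm <- build_feature_matrix(ft, ft, ft, set = "all")
  rep <- evaluate_classifier(fm, folds = 5, seed = 3)
  # the fold map is a partition of the subjects
  expect_setequal(names(rep$folds), unique(fm$groups))
  expect_equal(sort(unique(rep$folds)), 1:5)
  expect_length(rep$auc, 5)
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(rep$per_class >= 0 & rep$per_class <= 1))
  # determinism: identical seeds give identical folds and metrics
  rep2 <- evaluate_classifier(fm, folds = 5, seed = 3)
  expect_identical(rep$folds, rep2$folds)
  expect_equal(rep$auc, rep2$auc)
  expect_error(evaluate_classifier(fm, folds = 11, seed = 1), "folds")
})

test_that("separable features reach ceiling AUC; permuted labels fall to chance", {
  ft <- fake_features(n_subj = 10, effect = 3, subj_sd = 0.2, seed = 5)
  fm <- build_feature_matrix(ft, ft, ft, set = "all")
  rep <- evaluate_classifier(fm, folds = 5, seed = 11)
  expect_gte(rep$auc_mean, 0.95)

  # shuffle condition labels within subject: discriminability must vanish
  set.seed(12)
  fm_null <- fm
  for (s in unique(fm$groups)) {
    idx <- which(fm$groups == s)
    fm_null$y[idx] <- sample(fm$y[idx])
  }
  rep_null <- evaluate_classifier(fm_null, folds = 5, seed = 11)
  expect_lt(abs(rep_null$auc_mean - 0.5), 0.1)
})
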