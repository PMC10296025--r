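#' Pipeline configuration
#'
#' Bundles every stage parameter with the defaults of the emulated study:
#' 0.1-100 Hz band-pass, 50 Hz notch, 5 s epochs, 256-sample Welch windows,
#' theta 4-8 / alpha 8-13 Hz, entropy range 0.5-32 Hz, the five-region scalp
#' map, 1000 permutations, 5 folds. The configuration is validated before
#' any stage runs; it can be loaded from YAML (same field names).
#'
#' @param sim A [sim_config()].
#' @param filter_low,filter_high,notch Filter settings, Hz.
#' @param epoch_length Seconds.
#' @param welch_window Samples.
#' @param bands List of [band_spec()]s.
#' @param entropy_range Hz range, length 2.
#' @param region_map Named list of channel vectors.
#' @param n_perm Permutations for the statistics stage.
#' @param folds Cross-validation folds.
#' @param coh_block Epochs per coherence block.
#' @param seed Master analysis seed (stats + classification streams).
#' @param yaml Optional path to a YAML file whose fields override the
#'   defaults (`sim` entries override [sim_config()] arguments).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            filter_low = 0.1, filter_high = 100, notch = 50,
                            epoch_length = 5, welch_window = 256,
                            bands = list(band_spec("theta", 4, 8),
                                         band_spec("alpha", 8, 13)),
                            entropy_range = c(0.5, 32),
                            region_map = eeg_regions(),
                            n_perm = 1000, folds = 5, coh_block = 5,
                            seed = 1, yaml = NULL) {
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    if (!is.null(y$sim)) sim <- do.call(sim_config, y$sim)
    for (f in c("filter_low", "filter_high", "notch", "epoch_length",
                "welch_window", "entropy_range", "n_perm", "folds",
                "coh_block", "seed"))
      if (!is.null(y[[f]])) assign(f, y[[f]])
    if (!is.null(y$bands))
      bands <- lapply(y$bands, function(b)
        band_spec(b$name, b$f_low, b$f_high))
    if (!is.null(y$region_map)) region_map <- y$region_map
  }
  cfg <- structure(list(sim = sim, filter_low = filter_low,
                        filter_high = filter_high, notch = notch,
                        epoch_length = epoch_length,
                        welch_window = welch_window, bands = bands,
                        entropy_range = entropy_range,
                        region_map = region_map, n_perm = n_perm,
                        folds = folds, coh_block = coh_block,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$sim, "sim_config"))
  nyq <- cfg$sim$sampling_rate / 2
  if (!(cfg$filter_low > 0 && cfg$filter_low < cfg$filter_high &&
        cfg$filter_high < nyq))
    stop("invalid band-pass: need 0 < low < high < sampling_rate/2")
  for (b in cfg$bands)
    if (!(b$f_low < b$f_high))
      stop(sprintf("invalid band %s: f_low must be < f_high", b$name))
  if (!(length(cfg$entropy_range) == 2 &&
        cfg$entropy_range[1] < cfg$entropy_range[2]))
    stop("invalid entropy_range")
  if (cfg$epoch_length <= 0 || cfg$welch_window < 8)
    stop("invalid epoch_length/welch_window")
  if (cfg$n_perm < 100) stop("n_perm must be at least 100")
  if (cfg$folds < 2) stop("folds must be at least 2")
  all_ch <- unlist(cfg$region_map)
  bad <- setdiff(all_ch, eeg_channels())
  if (length(bad) > 0)
    stop("region map references unknown channel(s): ",
         paste(bad, collapse = ", "))
  if (any(duplicated(all_ch))) stop("regions may not overlap")
  invisible(TRUE)
}

# small deterministic content hash (FNV-1a over the serialized object)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648) , b) + (h %/% 2147483648) * 2147483648
    # 32-bit modular multiply by the FNV prime, split to keep exact doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' synth -> preprocess -> features -> stats -> classify, writing every
#' intermediate product under `out_dir`: the generated EDFs and behavioral
#' log, regional band-power tables (raw and rest-normalized), the theta
#' coherence matrices and region-pair summary, the per-channel entropy
#' table, the permutation contrast report, the classification report per
#' feature set, and a manifest (package version, configuration hash, seeds)
#' sufficient to regenerate every number. A stage failure aborts with the
#' stage name and leaves a `FAILED` marker in the run directory.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param write_edf_files Write the raw recordings as EDF (default TRUE).
#' @param feature_sets Feature sets to evaluate (default all four).
#' @return Invisibly, a list with the in-memory results (`power`,
#'   `coherence`, `entropy`, `stats`, `classification`, `manifest`).
#' @export
run_all <- function(config, out_dir,
                    write_edf_files = TRUE,
                    feature_sets = c("psd", "connectivity", "spe", "all")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fail <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) fail(name, e))

  theta <- config$bands[[1]]
  feats <- list(); power_rows <- list(); coh_rows <- list()
  coh_pair_rows <- list(); ent_cond <- list(); reports <- list()
  ent_trials <- list(); pow_trials <- list(); coh_trials <- list()
  pairs <- list(c("Frontal", "Frontal"), c("Frontal", "Parietal"),
                c("Parietal", "Parietal"))

  behav <- stage("synth", behavioral_log(config$sim))
  write.csv(behav, file.path(out_dir, "behavioral.csv"), row.names = FALSE)

  for (s in seq_len(config$sim$n_subjects)) {
    per_cond_power <- list()
    for (cond in sim_conditions()) {
      rec <- stage("synth", generate_recording(config$sim, s, cond))
      if (write_edf_files)
        stage("synth", write_edf(rec, file.path(
          out_dir, sprintf("sub-%02d_%s.edf", s, cond))))
      pp <- stage("preprocess", preprocess_recording(
        rec, low = config$filter_low, high = config$filter_high,
        notch = config$notch, epoch_length = config$epoch_length))
      reports[[sprintf("sub%02d_%s", s, cond)]] <- pp$report
      ep <- pp$epochs

      ft <- stage("features", epoch_features(
        ep, bands = config$bands, region_map = config$region_map,
        coh_band = theta, coh_block = config$coh_block,
        entropy_range = config$entropy_range,
        window = config$welch_window))
      if (cond != "rest") feats[[length(feats) + 1]] <- ft

      # regional band power summaries (epochs first, then channels)
      psd <- stage("features", welch_psd(ep, window = config$welch_window))
      for (bd in config$bands) {
        bp <- band_power(psd, bd)
        per_cond_power[[paste(cond, bd$name, sep = ".")]] <- bp
        cbp <- condition_band_power(stats::setNames(list(bp), cond),
                                    config$region_map)
        cbp$subject <- s; cbp$band <- bd$name
        power_rows[[length(power_rows) + 1]] <- cbp
        if (cond != "rest")
          for (rg in names(config$region_map)) {
            key <- paste(bd$name, rg, sep = "_")
            chans <- config$region_map[[rg]]
            v <- rowMeans(bp[, chans, drop = FALSE])
            pow_trials[[key]][[cond]][[as.character(s)]] <- v
          }
      }
      # entropy
      em <- stage("features", entropy_matrix(
        ep, window = config$welch_window, f_range = config$entropy_range))
      if (cond != "rest") {
        ent_cond[[cond]][[as.character(s)]] <- colMeans(em)
        for (ch in colnames(em))
          ent_trials[[paste0("spe_", ch)]][[cond]][[as.character(s)]] <-
            em[, ch]
      }
      # coherence (CSD, per condition and per block for the stats trials)
      if (cond != "rest") {
        ce <- stage("features", current_source_density(ep))
        cm <- stage("features", coherency(ce, band = theta,
                                          fft_points = config$welch_window))
        lt <- which(lower.tri(cm$matrix), arr.ind = TRUE)
        coh_rows[[length(coh_rows) + 1]] <- data.frame(
          subject = s, condition = cond,
          chanA = rownames(cm$matrix)[lt[, 1]],
          chanB = colnames(cm$matrix)[lt[, 2]],
          value = cm$matrix[lt])
        for (pr in pairs)
          coh_pair_rows[[length(coh_pair_rows) + 1]] <- data.frame(
            subject = s, condition = cond,
            pair = paste(pr[1], pr[2], sep = "-"),
            value = region_pair_coherence(cm, pr, config$region_map))
        n_ep <- dim(ce$data)[1]
        blocks <- split(seq_len(n_ep), ceiling(seq_len(n_ep) / config$coh_block))
        fp <- vapply(blocks, function(bl) {
          sub <- ce; sub$data <- ce$data[bl, , , drop = FALSE]
          region_pair_coherence(
            coherency(sub, band = theta, fft_points = config$welch_window),
            c("Frontal", "Parietal"), config$region_map)
        }, 0)
        coh_trials[["coh_Frontal_Parietal"]][[cond]][[as.character(s)]] <- fp
      }
    }
  }

  power_tab <- do.call(rbind, power_rows)
  write.csv(power_tab, file.path(out_dir, "band_power.csv"),
            row.names = FALSE)
  norm <- stage("features", local({
    wide <- reshape(power_tab, idvar = c("subject", "region", "band"),
                    timevar = "condition", direction = "wide")
    wide$planned_vs_rest <- normalize_by_rest(wide$power.planned,
                                              wide$power.rest)
    wide$unplanned_vs_rest <- normalize_by_rest(wide$power.unplanned,
                                                wide$power.rest)
    wide
  }))
  write.csv(norm, file.path(out_dir, "band_power_rest_normalized.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, coh_rows), file.path(out_dir, "coherence_long.csv"),
            row.names = FALSE)
  coh_pair_tab <- do.call(rbind, coh_pair_rows)
  coh_summary <- stage("features", do.call(rbind, lapply(
    split(coh_pair_tab, list(coh_pair_tab$condition, coh_pair_tab$pair)),
    function(d) data.frame(condition = d$condition[1], pair = d$pair[1],
                           mean = mean(d$value), sd = sd(d$value)))))
  write.csv(coh_summary, file.path(out_dir, "coherence_region_pairs.csv"),
            row.names = FALSE)

  ent_tab <- stage("features", local({
    pl <- do.call(rbind, ent_cond[["planned"]])
    up <- do.call(rbind, ent_cond[["unplanned"]])
    data.frame(channel = colnames(pl), entropy_planned = colMeans(pl),
               entropy_unplanned = colMeans(up),
               difference = colMeans(up) - colMeans(pl))
  }))

  stats_features <- c(pow_trials, coh_trials, ent_trials)
  contrasts <- stage("stats", contrast_report(
    stats_features, conditions = c("planned", "unplanned"),
    n_perm = config$n_perm, seed = config$seed))
  ent_p <- contrasts$p_value[match(paste0("spe_", ent_tab$channel),
                                   contrasts$feature)]
  ent_tab$p_value <- ent_p
  write.csv(ent_tab, file.path(out_dir, "entropy_channels.csv"),
            row.names = FALSE)
  write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
            row.names = FALSE)

  all_feats <- do.call(rbind, feats)
  classification <- stage("classify", lapply(
    stats::setNames(feature_sets, feature_sets), function(fset) {
      fm <- build_feature_matrix(all_feats, all_feats, all_feats,
                                 set = fset)
      rep <- evaluate_classifier(fm, folds = config$folds,
                                 seed = config$seed)
      list(auc = rep$auc, auc_mean = rep$auc_mean, auc_sd = rep$auc_sd,
           accuracy = rep$accuracy, macro = as.list(rep$macro))
    }))
  jsonlite::write_json(classification,
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "eegattn",
    version = as.character(utils::packageVersion("eegattn")),
    config_hash = config_hash(config),
    sim_seed = config$sim$seed, analysis_seed = config$seed,
    n_subjects = config$sim$n_subjects,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(reports, file.path(out_dir, "preprocessing.json"),
                       auto_unbox = TRUE, force = TRUE)

  invisible(list(power = power_tab, power_normalized = norm,
                 coherence = coh_summary, entropy = ent_tab,
                 stats = contrasts, classification = classification,
                 manifest = manifest))
}
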