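# Orchestration and table I/O: word-timing TSV round-tripping, pipeline
# configuration with the analysis defaults, and a single driver that runs
# features -> preprocessing -> TRF -> model comparison -> clusters ->
# peaks -> statistics on a simulated or loaded cohort.

#' Read a word-timing table
#'
#' TSV with header `word onset offset pos surprisal altered` (onset and
#' offset in seconds at 6-decimal precision; blank surprisal left unset
#' for later annotation). Malformed rows, non-monotone onsets, and
#' overlapping intervals are reported with their line numbers.
#'
#' @param path TSV path.
#' @return a [token_table()].
#' @export
read_word_timing <- function(path) {
  df <- utils::read.delim(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  need <- c("word", "onset", "offset")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  line_of <- function(i) i + 1L          # header is line 1
  for (col in c("onset", "offset")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed ", col, " at line(s) ",
           paste(line_of(bad), collapse = ", "), " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(df$offset <= df$onset)
  if (length(bad))
    stop("offset <= onset at line(s) ", paste(line_of(bad), collapse = ", "),
         " of ", path, call. = FALSE)
  if (is.unsorted(df$onset))
    stop("onsets not monotone in ", path, " (first violation at line ",
         line_of(which(diff(df$onset) < 0)[1L] + 1L), ")", call. = FALSE)
  ov <- which(df$offset[-nrow(df)] > df$onset[-1L] + 1e-9)
  if (length(ov))
    stop("overlapping intervals at line(s) ",
         paste(line_of(ov), collapse = ", "), " of ", path, call. = FALSE)
  token_table(df$word, df$onset, df$offset,
              pos = if ("pos" %in% names(df)) df$pos else NA,
              surprisal = if ("surprisal" %in% names(df)) df$surprisal else NA,
              altered = if ("altered" %in% names(df))
                !is.na(df$altered) & df$altered %in% c("TRUE", "1", TRUE, 1)
              else FALSE)
}

#' Write a word-timing table
#'
#' @param tokens a [token_table()].
#' @param path output TSV path.
#' @export
write_word_timing <- function(tokens, path) {
  validate_token_table(tokens)
  out <- data.frame(
    word = tokens$word,
    onset = sprintf("%.6f", tokens$onset),
    offset = sprintf("%.6f", tokens$offset),
    pos = ifelse(is.na(tokens$pos), "", tokens$pos),
    surprisal = ifelse(is.na(tokens$surprisal), "",
                       sprintf("%.6f", tokens$surprisal)),
    altered = tokens$altered)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis configuration with the pipeline defaults
#'
#' Collects every tunable constant of the analysis in one place. Defaults:
#' 0.1-40 Hz broadband and 1-20 Hz analysis band-pass filters, 250 Hz
#' analysis rate, 60-s epochs, -100..1000 ms lags, lambda grid
#' `2^-5..2^15`, cluster alpha 0.05 with 1000 permutations and 4 cm
#' adjacency, -100..-4 ms baseline, and peak windows 50-150 / 150-250 /
#' 200-1000 ms.
#'
#' @param ... overrides of any default field.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    broadband = c(0.1, 40), analysis_band = c(1, 20),
    filter_order = 2, rate = 250, trial_s = 60,
    lag_ms = c(-100, 1000), lambda_grid = default_lambda_grid(),
    baseline_ms = c(-100, -4),
    cluster_alpha = 0.05, n_perm = 1000, adjacency_radius = 0.04,
    n1_window = c(50, 150), p2_window = c(150, 250),
    n400_window = c(200, 1000),
    roi_frontocentral = default_roi("frontocentral"),
    roi_parietal = default_roi("parietal"),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis on a simulated cohort
#'
#' Executes, per the stage order of the analysis: regressor assembly and
#' preprocessing (delegated to the simulator, which emits standardized
#' epoched data), group-level lambda selection, acoustic vs full model
#' comparison (added value of surprisal), per-condition TRFs, the
#' within-group surprisal cluster test, sensory and semantic component
#' extraction, group statistics on components and behavior, and
#' brain-behavior correlations. Writes all outputs plus a provenance log
#' into `out_dir` when given.
#'
#' @param subjects cohort from [simulate_cohort()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of result tables (see Details in the vignette).
#' @export
run_pipeline <- function(subjects, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  rate <- subjects[[1L]]$epochs$rate
  lags <- lag_spec(config$lag_ms[1L], config$lag_ms[2L], rate)
  groups <- vapply(subjects, `[[`, character(1), "group")

  # model comparison (CV per subject, both feature sets)
  av <- added_value(subjects = lapply(subjects, `[[`, "epochs"),
                    lambdas = config$lambda_grid, lags = lags)

  # group-level lambda from the full-model CV curves
  cvs <- lapply(subjects, function(s)
    cross_validate_lambda(s$epochs, config$lambda_grid, lags))
  lambda_star <- choose_group_lambda(cvs)

  # per-condition TRFs and the N400 difference wave per subject
  trfs <- lapply(subjects, function(s) {
    list(control = condition_trf(s$epochs, lambda_star, "Control", lags,
                                 baseline_ms = config$baseline_ms),
         e45 = condition_trf(s$epochs, lambda_star, "E45", lags,
                             baseline_ms = config$baseline_ms))
  })

  labels <- subjects[[1L]]$epochs$labels
  roi_par <- intersect(config$roi_parietal, labels)
  roi_fc <- intersect(config$roi_frontocentral, labels)

  n400 <- lapply(trfs, function(tt)
    extract_n400(tt$e45, tt$control, roi_par, window = config$n400_window))
  peaks <- lapply(trfs, function(tt) {
    avg <- average_trf(list(tt$control, tt$e45))
    extract_sensory_peaks(roi_waveform(avg, "envelope", roi_fc),
                          config$n1_window, config$p2_window)
  })

  # within-group E45 vs Control cluster test on the surprisal kernel
  adj <- build_adjacency(subjects[[1L]]$epochs$positions,
                         config$adjacency_radius)
  surp_arrays <- function(which_cond, idx) {
    arr <- vapply(trfs[idx], function(tt)
      t(tt[[which_cond]]$weights["word_surprisal", , ]),
      matrix(0, length(labels), length(lags$lags)))
    aperm(arr, c(3L, 1L, 2L))
  }
  clusters <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    cluster_perm_test(surp_arrays("e45", idx), surp_arrays("control", idx),
                      design = "paired", adjacency = adj,
                      cluster_alpha = config$cluster_alpha,
                      n_perm = config$n_perm, seed = config$seed,
                      times = lags$lags_ms)
  })
  names(clusters) <- unique(groups)

  # group statistics and brain-behavior correlations
  lat <- vapply(n400, `[[`, numeric(1), "latency")
  amp <- vapply(n400, `[[`, numeric(1), "amplitude")
  judg <- vapply(subjects, function(s) s$behavior$judgment_pct, numeric(1))
  reca <- vapply(subjects, function(s) s$behavior$recall_pct, numeric(1))
  is_nh <- groups == "NH"
  stats_tbl <- list(
    n400_latency = welch_t(lat[is_nh], lat[!is_nh]),
    n400_amplitude = welch_t(amp[is_nh], amp[!is_nh]),
    judgment = welch_t(judg[is_nh], judg[!is_nh]),
    recall = welch_t(reca[is_nh], reca[!is_nh]))
  corr <- if (sum(is_nh) >= 5) spearman_fdr(list(
    judgment_vs_n400_amp_nh = list(x = judg[is_nh], y = amp[is_nh]),
    recall_vs_n400_amp_nh = list(x = reca[is_nh], y = amp[is_nh]),
    judgment_vs_n400_lat_nh = list(x = judg[is_nh], y = lat[is_nh])))
  else data.frame(pair = character(0), n = integer(0),
                  rho = numeric(0), p = numeric(0), q = numeric(0))

  res <- list(
    lambda = lambda_star, added_value = av, trfs = trfs,
    n400 = data.frame(group = groups, latency = lat, amplitude = amp,
                      judgment = judg, recall = reca),
    sensory = data.frame(
      group = groups,
      n1_latency = vapply(peaks, function(p) p$N1$latency, numeric(1)),
      p2_latency = vapply(peaks, function(p) p$P2$latency, numeric(1)),
      n1p2 = vapply(peaks, `[[`, numeric(1), "n1p2")),
    clusters = clusters, stats = stats_tbl, correlations = corr,
    provenance = list(
      config = unclass(config), n_subjects = length(subjects),
      rate = rate, started = format(t0), versions = list(
        speechTRF = as.character(utils::packageVersion("speechTRF")),
        R = R.version.string)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$n400, file.path(out_dir, "n400.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$sensory, file.path(out_dir, "sensory.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$correlations,
                       file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(clusters))
      write_cluster_result(clusters[[g]], labels,
                           json_path = file.path(out_dir,
                                                 paste0("clusters_", g, ".json")),
                           tsv_path = file.path(out_dir,
                                                paste0("clusters_", g, ".tsv")))
    jsonlite::write_json(
      list(lambda = lambda_star,
           delta_r = unname(av$delta_r),
           wilcoxon_p = av$test$p,
           provenance = res$provenance),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Export a TRF model to a portable container
#'
#' Weights as a flat TSV (feature, lag ms, channel, weight) plus a JSON
#' sidecar with the lag axis, lambda, features, and channel labels.
#'
#' @param model a `trf_model`.
#' @param stem output path without extension.
#' @export
write_trf <- function(model, stem) {
  dims <- dim(model$weights)
  df <- data.frame(
    feature = rep(model$features, times = dims[2L] * dims[3L]),
    lag_ms = rep(rep(model$lags_ms, each = dims[1L]), times = dims[3L]),
    channel = rep(model$labels, each = dims[1L] * dims[2L]),
    weight = as.numeric(model$weights))
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(lags_ms = model$lags_ms, lambda = model$lambda,
         features = model$features, labels = model$labels,
         baseline_corrected = model$baseline_corrected),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
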