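## Config-driven orchestration of the full analysis chain.

.defaultPipelineConfig <- function() list(
  seed = 1L,
  out_dir = "fingerctx-run",
  stages = c("simulate", "features", "tuning", "decode_offline",
             "simulate_online", "patterns", "geometry", "report"),
  simulate = list(n_channels = 96L, contexts = c("normal", "spring"),
                  trials_per_block = c(175L, 350L), task = "1dof"),
  features = list(bin_ms = 32L, feature = "sbp"),
  tuning = list(fdr = 0.001),
  decode_offline = list(target = "emg_envelope", folds = 10L,
                        lambda = NULL),
  simulate_online = list(n_trials = 200L, context_gain = 1.9,
                         encoder_noise = 0.3),
  patterns = list(),
  geometry = list(K = 16L, set_size = 50L, reps = 100L)
)

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order — simulate a session, extract
#' features, run the tuning analysis, offline cross-context decoding, a
#' closed-loop simulation, neural-activity-pattern extraction, population
#' geometry, and report generation — writing per-stage CSV outputs and a
#' JSON manifest (parameters, input hashes, package version) into the
#' output directory. Reruns with the same configuration and seed produce
#' identical numeric outputs.
#'
#' @param config a configuration list, or the path of a YAML file
#'   containing one; omitted entries fall back to defaults.
#' @return the manifest (invisibly), a list with per-stage output paths.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("fingerctx")),
                   seed = cfg$seed, stages = list())
  t0 <- Sys.time()
  logf <- function(stage, fmt, ...) message(sprintf(
    "[%s +%.1fs] %s", stage, as.numeric(Sys.time() - t0, units = "secs"),
    sprintf(fmt, ...)))
  outputs <- character(0)
  session <- NULL; tensor <- NULL; run <- NULL

  need <- function(what, obj, stage)
    if (is.null(obj)) .stopf("stage '%s' needs the %s stage first", stage, what)

  for (stage in cfg$stages) {
    logf(stage, "start")
    res <- switch(stage,
      simulate = {
        sc <- cfg$simulate
        gen <- generatorConfig(seed = cfg$seed, nChannels = sc$n_channels,
                               trialsPerBlock = sc$trials_per_block)
        session <- generateSession(gen, sc$contexts, task = sc$task)
        p <- file.path(cfg$out_dir, "session")
        writeSession(session, p)
        p
      },
      features = {
        need("simulate", session, stage)
        fb <- binSBP(streams(session), cfg$features$bin_ms)
        p <- file.path(cfg$out_dir, "features.csv")
        data.table::fwrite(data.table::as.data.table(featureValues(fb)), p)
        p
      },
      tuning = {
        need("simulate", session, stage)
        res <- tuningAnalysis(session, cfg$features$feature,
                              fdrLevel = cfg$tuning$fdr)
        p <- file.path(cfg$out_dir, "tuning.csv")
        data.table::fwrite(res$perChannel, p)
        attr(p, "summary") <- c(nTuned = res$nTuned,
                                pctModulated = res$pctModulatedAmongTuned)
        p
      },
      decode_offline = {
        need("simulate", session, stage)
        cv <- crossvalGeneralization(session, cfg$decode_offline$target,
                                     ridgeLambda = cfg$decode_offline$lambda,
                                     folds = cfg$decode_offline$folds)
        p <- file.path(cfg$out_dir, "decode_offline.csv")
        data.table::fwrite(cv$percentChange, p)
        data.table::fwrite(cv$perFold,
                           file.path(cfg$out_dir, "decode_offline_folds.csv"))
        p
      },
      simulate_online = {
        so <- cfg$simulate_online
        enc <- linearEncoder(cfg$simulate$n_channels, seed = cfg$seed,
                             noiseSd = so$encoder_noise)
        td <- simulateTrainingData(enc, 300L, seed = cfg$seed)
        kd <- fitKalman(td$features, td$kinematics)
        run <- simulateClosedLoop(
          enc, intentionModel(), kd, nTrials = so$n_trials,
          contextSchedule = rep(cfg$simulate$contexts, each = 4),
          contextGains = stats::setNames(
            ifelse(cfg$simulate$contexts == "normal", 1, so$context_gain),
            cfg$simulate$contexts),
          task = cfg$simulate$task, seed = cfg$seed)
        p <- file.path(cfg$out_dir, "online_trials.csv")
        data.table::fwrite(run$results, p)
        p
      },
      patterns = {
        need("simulate_online", run, stage)
        enc <- linearEncoder(cfg$simulate$n_channels, seed = cfg$seed,
                             noiseSd = cfg$simulate_online$encoder_noise)
        td50 <- simulateTrainingData(enc, 300L, seed = cfg$seed,
                                     binWidthMs = 50L)
        ro <- fitPatternReadout(td50$features, td50$kinematics[, 3:4],
                                td50$trialId)
        pats <- extractPatterns(ro, run)
        p <- file.path(cfg$out_dir, "patterns.csv")
        data.table::fwrite(pats, p)
        p
      },
      geometry = {
        need("simulate", session, stage)
        tensor <- buildTrialTensor(session)
        K <- min(cfg$geometry$K, sum(tensor$mask))
        pa <- contextPrincipalAngles(tensor, K = K,
                                     setSize = cfg$geometry$set_size,
                                     reps = cfg$geometry$reps,
                                     seed = cfg$seed)
        long <- do.call(rbind, lapply(names(pa$angles), function(cx)
          data.frame(context = cx, rank = seq_along(pa$angles[[cx]]),
                     angle = pa$angles[[cx]],
                     control_mean = if (!is.null(pa$control))
                       pa$control$mean else NA_real_,
                     control_sd = if (!is.null(pa$control))
                       pa$control$sd else NA_real_)))
        p <- file.path(cfg$out_dir, "principal_angles.csv")
        data.table::fwrite(long, p)
        dp <- dpcaFit(tensor)
        mv <- marginalizationVariance(tensor)
        data.table::fwrite(data.frame(marginalization = names(mv),
                                      variance_fraction = as.numeric(mv)),
                           file.path(cfg$out_dir, "dpca_variance.csv"))
        p
      },
      report = {
        makeReport(cfg$out_dir)
      },
      .stopf("unknown pipeline stage '%s'", stage))
    outputs <- c(outputs, res)
    manifest$stages[[stage]] <- list(
      output = as.character(res),
      md5 = if (file.exists(res) && !dir.exists(res))
        as.character(tools::md5sum(res)) else NA_character_)
    logf(stage, "done -> %s", res)
  }
  manifest$elapsed_s <- as.numeric(Sys.time() - t0, units = "secs")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate summary tables and figures from pipeline outputs
#'
#' Reads whichever stage outputs exist in `outDir` and writes a tuning
#' summary table, offline metric-change table, a principal-angle figure
#' with its control band, and a marginalization-variance bar figure.
#' Regeneration is idempotent. No numeric claims beyond computed values.
#'
#' @param outDir a [runPipeline()] output directory.
#' @return path of the report directory.
#' @export
makeReport <- function(outDir) {
  rep_dir <- file.path(outDir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outDir, name)
  if (file.exists(f("tuning.csv"))) {
    tu <- data.table::fread(f("tuning.csv"))
    smry <- data.frame(
      n_channels = nrow(tu), tuned = sum(tu$tuned),
      context_modulated = sum(tu$tuned & tu$context_modulated),
      pct_modulated_among_tuned =
        if (sum(tu$tuned)) 100 * sum(tu$tuned & tu$context_modulated) /
          sum(tu$tuned) else NaN)
    data.table::fwrite(smry, file.path(rep_dir, "tuning_summary.csv"))
  }
  if (file.exists(f("decode_offline.csv")))
    file.copy(f("decode_offline.csv"),
              file.path(rep_dir, "offline_metric_changes.csv"),
              overwrite = TRUE)
  if (file.exists(f("principal_angles.csv"))) {
    pa <- data.table::fread(f("principal_angles.csv"))
    grDevices::pdf(file.path(rep_dir, "principal_angles.pdf"), 6, 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(NA, xlim = range(pa$rank), ylim = c(0, 90),
         xlab = "component rank", ylab = "principal angle (deg)")
    if (all(is.finite(pa$control_mean))) {
      ctl <- unique(pa[, c("rank", "control_mean", "control_sd")])
      graphics::polygon(c(ctl$rank, rev(ctl$rank)),
                        c(ctl$control_mean - ctl$control_sd,
                          rev(ctl$control_mean + ctl$control_sd)),
                        col = "grey85", border = NA)
      graphics::lines(ctl$rank, ctl$control_mean, col = "grey40")
    }
    for (cx in unique(pa$context))
      graphics::lines(pa$rank[pa$context == cx], pa$angle[pa$context == cx],
                      type = "b", pch = 16,
                      col = match(cx, unique(pa$context)) + 1)
    graphics::legend("topleft", legend = unique(pa$context),
                     col = seq_along(unique(pa$context)) + 1, lty = 1,
                     bty = "n")
  }
  if (file.exists(f("dpca_variance.csv"))) {
    mv <- data.table::fread(f("dpca_variance.csv"))
    grDevices::pdf(file.path(rep_dir, "dpca_variance.pdf"), 5, 4)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::barplot(100 * mv$variance_fraction,
                      names.arg = mv$marginalization, las = 2,
                      ylab = "% neural variance")
  }
  rep_dir
}
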