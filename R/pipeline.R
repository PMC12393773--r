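# Stage-oriented pipeline tying the modules together, with a run manifest.

.PIPELINE_STAGES <- c("simulate", "behavior", "decode", "bias", "stats",
                      "searchlight")

.configAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.stageSeed <- function(seed, stage) {
  # deterministic per-stage sub-seed, kept inside 32-bit integer range
  (as.integer(seed) * 97L + match(stage, .PIPELINE_STAGES) * 131L) %%
    .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing per-stage TSV/JSON
#' outputs and a machine-readable run manifest (configuration, seed,
#' package version, config checksum) under \code{outDir}. Rerunning with
#' the same configuration and seed reproduces all stochastic outputs
#' bit-exactly. Stages depend on their upstream outputs (\code{behavior},
#' \code{decode} need \code{simulate}'s; \code{bias}, \code{stats} need
#' \code{decode}'s); requesting a stage without them is an error.
#'
#' @param config An [analysisConfig()].
#' @param outDir Output directory (created if needed).
#' @param stages Character vector, subset of \code{"simulate"},
#'   \code{"behavior"}, \code{"decode"}, \code{"bias"}, \code{"stats"},
#'   \code{"searchlight"}.
#' @param design Task design for the simulate stage (\code{"meg"} or
#'   \code{"eeg"}).
#' @param nParticipants Number of simulated participants (default 4; the
#'   study-scale designs use 20 for MEG and 30 for EEG).
#' @param behavior,neural [behaviorParams()] / [neuralParams()] for the
#'   simulate stage.
#' @param epochSpan,sfreq Epoch limits (s) and sampling rate (Hz) for the
#'   simulate stage.
#' @param timeIndices Optional decoded sample indices (default: all valid).
#' @param biasWindow Fixed window (s) for the bias stage
#'   (default \code{c(0.5, 1.0)}).
#' @param searchlightK Neighborhood size for the searchlight stage.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(config = analysisConfig(), outDir,
                        stages = c("simulate", "behavior", "decode",
                                   "bias", "stats"),
                        design = "meg", nParticipants = 4L,
                        behavior = behaviorParams(),
                        neural = neuralParams(),
                        epochSpan = c(-0.2, 1.2), sfreq = 100,
                        timeIndices = NULL,
                        biasWindow = c(0.5, 1.0),
                        searchlightK = 8L) {
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@seed
  trialsPath <- file.path(outDir, "trials.tsv")
  epochsPath <- function(pid) file.path(outDir,
                                        paste0("epochs_", pid, ".rds"))
  decodePath <- function(pid) file.path(outDir,
                                        paste0("decode_", pid, ".rds"))

  .needs <- function(path, stage, upstream) {
    if (!file.exists(path))
      stop("stage '", stage, "' requires outputs of stage '", upstream,
           "' (missing: ", path, "); run it first")
  }

  for (stage in stages) {
    message("[", stage, "] running")
    switch(stage,
      simulate = {
        trials <- generateTaskSequence(design, nParticipants,
                                       seed = .stageSeed(seed, "simulate"))
        trials <- generateBehavior(trials, behavior,
                                   seed = .stageSeed(seed, "simulate") + 1L)
        writeTrials(trials, trialsPath)
        pids <- unique(trials$participant_id)
        for (i in seq_along(pids)) {
          tt <- trials[trials$participant_id == pids[i], , drop = FALSE]
          ep <- generateEpochs(tt, neural, epochSpan = epochSpan,
                               sfreq = sfreq,
                               seed = .stageSeed(seed, "simulate") + 1L + i)
          writeEpochs(ep, epochsPath(pids[i]))
        }
        message("[simulate] ", nrow(trials), " trials, ",
                length(pids), " participants")
      },
      behavior = {
        .needs(trialsPath, "behavior", "simulate")
        trials <- readTrials(trialsPath)
        est <- rbind(serialBiasEstimates(trials, "previous_target"),
                     if (any(trials$cued_item == "sample2" &
                             !is.na(trials$sample1_orientation)))
                       serialBiasEstimates(trials, "sample1"))
        utils::write.table(est, file.path(outDir, "behavior_bias.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        mae <- vapply(split(trials, trials$participant_id),
                      function(tt) mean(abs(tt$signed_error), na.rm = TRUE),
                      numeric(1))
        prev <- est[est$inducer == "previous_target", ]
        corr <- biasPerformanceCorrelation(
          prev$index, mae[prev$participant_id])
        tt <- windowTtest(prev$index)
        .writeJson(list(bias_performance_correlation = corr,
                        previous_target_bias_ttest = tt),
                   file.path(outDir, "behavior_tests.json"))
        curves <- do.call(rbind, lapply(
          split(trials, trials$participant_id), function(tt2) {
            d <- relativeOrientation(tt2$previous_target_orientation,
                                     tt2$target_orientation)
            ok <- !is.na(d) & !is.na(tt2$signed_error)
            cv <- smoothBiasCurve(tt2$signed_error[ok], d[ok])
            cv$participant_id <- tt2$participant_id[1]
            cv
          }))
        utils::write.table(curves, file.path(outDir,
                                             "behavior_curves.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      decode = {
        .needs(trialsPath, "decode", "simulate")
        trials <- readTrials(trialsPath)
        pids <- unique(trials$participant_id)
        evrows <- list()
        for (pid in pids) {
          .needs(epochsPath(pid), "decode", "simulate")
          ep <- readEpochs(epochsPath(pid))
          tt <- trials[trials$participant_id == pid, , drop = FALSE]
          res <- decodeTimecourse(ep, tt, "target", config, timeIndices)
          saveRDS(res, decodePath(pid))
          evrows[[pid]] <- data.frame(
            participant_id = pid, time = res@times,
            evidence = colMeans(decodingEvidenceMatrix(res), na.rm = TRUE))
        }
        ev <- do.call(rbind, evrows)
        rownames(ev) <- NULL
        utils::write.table(ev, file.path(outDir, "evidence.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      bias = {
        .needs(trialsPath, "bias", "simulate")
        trials <- readTrials(trialsPath)
        pids <- unique(trials$participant_id)
        rows <- list()
        for (pid in pids) {
          .needs(decodePath(pid), "bias", "decode")
          res <- readRDS(decodePath(pid))
          ep <- readEpochs(epochsPath(pid))
          tt <- trials[trials$participant_id == pid, , drop = FALSE]
          b <- participantNeuralBias(ep, tt, "previous_target",
                                     window = biasWindow, config = config,
                                     result = res)
          rows[[pid]] <- data.frame(participant_id = pid,
                                    inducer = "previous_target",
                                    window_start = biasWindow[1],
                                    window_end = biasWindow[2],
                                    bias = b)
        }
        bias <- do.call(rbind, rows)
        rownames(bias) <- NULL
        utils::write.table(bias, file.path(outDir, "neural_bias.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        .writeJson(windowTtest(bias$bias),
                   file.path(outDir, "neural_bias_test.json"))
      },
      stats = {
        evPath <- file.path(outDir, "evidence.tsv")
        .needs(evPath, "stats", "decode")
        ev <- utils::read.delim(evPath)
        tcs <- do.call(rbind, lapply(split(ev, ev$participant_id),
                                     function(d) d$evidence[order(d$time)]))
        times <- sort(unique(ev$time))
        cr <- clusterPermutationTest(tcs, times,
                                     nPermutations = config@nPermutations,
                                     clusterAlpha = config@clusterAlpha,
                                     seed = .stageSeed(seed, "stats"))
        .writeJson(list(clusters = clusters(cr),
                        n_permutations = cr@nPermutations,
                        cluster_alpha = cr@clusterAlpha),
                   file.path(outDir, "evidence_clusters.json"))
      },
      searchlight = {
        .needs(trialsPath, "searchlight", "simulate")
        trials <- readTrials(trialsPath)
        pids <- unique(trials$participant_id)
        maps <- lapply(pids, function(pid) {
          .needs(epochsPath(pid), "searchlight", "simulate")
          ep <- readEpochs(epochsPath(pid))
          tt <- trials[trials$participant_id == pid, , drop = FALSE]
          searchlightMap(ep, tt, "evidence", k = searchlightK,
                         config = config, timeIndices = timeIndices)
        })
        avg <- maps[[1]]
        avg$value <- rowMeans(sapply(maps, `[[`, "value"))
        utils::write.table(avg, file.path(outDir, "searchlight.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      })
  }

  cfgList <- .configAsList(config)
  cfgPath <- file.path(outDir, "config.json")
  .writeJson(cfgList, cfgPath)
  manifest <- list(
    package = "serialdep",
    version = as.character(utils::packageVersion("serialdep")),
    stages = stages,
    seed = seed,
    design = design,
    n_participants = nParticipants,
    config = cfgList,
    config_md5 = unname(tools::md5sum(cfgPath)))
  .writeJson(manifest, file.path(outDir, "manifest.json"))
  invisible(manifest)
}
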