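.TRIAL_COLUMNS <- c(
  "participant_id", "trial_id", "block_id", "condition", "cued_item",
  "sample1_orientation", "sample2_orientation", "target_orientation",
  "previous_target_orientation", "report_orientation", "signed_error",
  "rt", "rotation_start", "first_in_block"
)

.TRIAL_CONDITIONS <- c("both_shown", "first_only", "second_only", "cued_recall")

.ORIENTATION_COLUMNS <- c(
  "sample1_orientation", "sample2_orientation", "target_orientation",
  "previous_target_orientation", "report_orientation"
)

#' Validate (and normalize) a trial table
#'
#' Checks the per-trial metadata table used throughout the package: required
#' columns, value ranges, the agreement between \code{target_orientation} and
#' the cued sample, and the stored \code{signed_error} against
#' \code{relativeOrientation(report, target)}. Orientations in
#' \code{[180, 360)} are reduced modulo 180 with a warning; orientations
#' outside \code{[0, 360)} are an error.
#'
#' @param trials A data.frame with the columns listed under Details.
#' @param tol Tolerance in degrees for the stored \code{signed_error} check.
#' @return The validated data.frame (orientations reduced to \code{[0, 180)}).
#'
#' @details Required columns: \code{participant_id}, \code{trial_id},
#'   \code{block_id}, \code{condition} (\code{both_shown}, \code{first_only},
#'   \code{second_only} or \code{cued_recall}), \code{cued_item}
#'   (\code{sample1}/\code{sample2}), \code{sample1_orientation},
#'   \code{sample2_orientation}, \code{target_orientation},
#'   \code{previous_target_orientation}, \code{report_orientation},
#'   \code{signed_error}, \code{rt}, \code{rotation_start},
#'   \code{first_in_block}. Missing values are \code{NA}.
#' @export
validateTrialTable <- function(trials, tol = 1e-6) {
  missing_cols <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  trials$trial_id <- as.integer(trials$trial_id)
  trials$block_id <- as.integer(trials$block_id)
  trials$first_in_block <- as.logical(trials$first_in_block)
  if (any(trials$trial_id < 0L, na.rm = TRUE))
    stop("trial_id must be >= 0")
  bad_cond <- setdiff(unique(trials$condition), .TRIAL_CONDITIONS)
  if (length(bad_cond))
    stop("unknown condition value(s): ", paste(bad_cond, collapse = ", "))
  bad_cue <- setdiff(unique(trials$cued_item), c("sample1", "sample2"))
  if (length(bad_cue))
    stop("unknown cued_item value(s): ", paste(bad_cue, collapse = ", "))
  for (col in .ORIENTATION_COLUMNS) {
    v <- trials[[col]]
    bad <- !is.na(v) & (v < 0 | v >= 360)
    if (any(bad))
      stop(sprintf("column '%s' has orientation(s) outside [0, 360)", col))
    over <- !is.na(v) & v >= 180
    if (any(over)) {
      warning(sprintf(
        "column '%s': %d orientation(s) in [180, 360) reduced modulo 180",
        col, sum(over)))
      trials[[col]] <- wrapOrientation(v)
    }
  }
  # target must be the cued item's orientation when that item is present
  cue_col <- ifelse(trials$cued_item == "sample1",
                    trials$sample1_orientation, trials$sample2_orientation)
  chk <- !is.na(cue_col) & !is.na(trials$target_orientation)
  if (any(chk) &&
      any(abs(relativeOrientation(trials$target_orientation[chk],
                                  cue_col[chk])) > tol))
    stop("target_orientation does not match the cued sample's orientation")
  # stored signed error must match the report/target difference
  have <- !is.na(trials$report_orientation) &
    !is.na(trials$target_orientation) & !is.na(trials$signed_error)
  if (any(have)) {
    expect <- relativeOrientation(trials$report_orientation[have],
                                  trials$target_orientation[have])
    if (any(abs(expect - trials$signed_error[have]) > tol))
      stop("stored signed_error is inconsistent with ",
           "relativeOrientation(report_orientation, target_orientation)")
  }
  if (any(trials$first_in_block & !is.na(trials$previous_target_orientation)))
    stop("first_in_block trials must have missing previous_target_orientation")
  if (any(!is.na(trials$rt) & trials$rt <= 0))
    stop("rt must be positive where present")
  trials
}

#' Read / write the tab-separated trial table
#'
#' The on-disk trial table is UTF-8 TSV with a mandatory header naming every
#' column and \code{"NA"} for missing values. On read the table is validated
#' with [validateTrialTable()] (the stored \code{signed_error} is checked
#' against the recomputed value).
#'
#' @param path File path.
#' @return \code{readTrials}: the validated trial data.frame.
#' @seealso [validateTrialTable()]
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) stop("trial table not found: ", path)
  trials <- utils::read.delim(path, header = TRUE, sep = "\t",
                              na.strings = "NA", stringsAsFactors = FALSE,
                              check.names = FALSE)
  validateTrialTable(trials)
}

#' @rdname readTrials
#' @param trials A trial data.frame (validated before writing).
#' @export
writeTrials <- function(trials, path) {
  trials <- validateTrialTable(trials)
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the epochs container
#'
#' Serializes an [OrientationEpochs-class] object to the package's native
#' epochs container (a single serialized file holding the data tensor, time
#' axis, sampling rate, trial identifiers, sensor ids/positions and lock
#' event). The round trip is bit-exact.
#'
#' @param path File path (conventionally \code{*.epochs.rds}).
#' @return \code{readEpochs}: an \code{OrientationEpochs}.
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop("epochs container not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "serialdep-epochs"))
    stop("not an epochs container: ", path)
  need <- c("data", "times", "sfreq", "trial_ids", "sensor_ids",
            "sensor_pos", "lock_event")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("epochs container is missing field(s): ",
         paste(miss, collapse = ", "))
  new("OrientationEpochs",
      data = obj$data, times = obj$times, sfreq = obj$sfreq,
      sensorIds = obj$sensor_ids, sensorPos = obj$sensor_pos,
      lockEvent = obj$lock_event, trialIds = obj$trial_ids)
}

#' @rdname readEpochs
#' @param epochs An \code{OrientationEpochs} object.
#' @export
writeEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "OrientationEpochs"))
  validObject(epochs)
  obj <- list(format = "serialdep-epochs",
              data = epochs@data, times = epochs@times, sfreq = epochs@sfreq,
              trial_ids = epochs@trialIds, sensor_ids = epochs@sensorIds,
              sensor_pos = epochs@sensorPos, lock_event = epochs@lockEvent)
  saveRDS(obj, path)
  invisible(path)
}
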