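# Light single-trial preprocessing applied before decoding.

.unfoldTimeLast <- function(data) {
  # (trials x sensors x times) -> ((trials*sensors) x times)
  d <- dim(data)
  matrix(data, d[1] * d[2], d[3])
}

#' Preprocess epochs for decoding
#'
#' Applies the listed steps in order:
#' \describe{
#'   \item{\code{gaussian_smooth}}{Temporal smoothing with a Gaussian kernel
#'     of standard deviation \code{sd_ms} milliseconds (edge-renormalized).}
#'   \item{\code{remove_cross_trial_mean}}{Subtracts the across-trial mean
#'     from every (sensor, time) cell.}
#'   \item{\code{baseline_regress}}{Per sensor, regresses each time point's
#'     across-trial values on the trial's mean voltage in the baseline
#'     \code{window} (seconds) and keeps the residuals.}
#'   \item{\code{unit_variance}}{Scales every (sensor, time) cell to unit
#'     across-trial variance.}
#' }
#'
#' @param epochs An [OrientationEpochs-class].
#' @param steps A list; each element is either a step name (character) or a
#'   list whose first element is the step name followed by named arguments,
#'   e.g. \code{list(list("gaussian_smooth", sd_ms = 8),
#'   "remove_cross_trial_mean", list("baseline_regress",
#'   window = c(-0.2, -0.05)), "unit_variance")}.
#' @return The preprocessed \code{OrientationEpochs}.
#' @export
preprocessEpochs <- function(epochs, steps) {
  stopifnot(is(epochs, "OrientationEpochs"))
  data <- epochs@data
  d <- dim(data)
  times <- epochs@times
  for (step in steps) {
    if (is.character(step)) step <- list(step)
    name <- step[[1]]
    args <- step[-1]
    data <- switch(name,
      gaussian_smooth = {
        sd_ms <- if (!is.null(args$sd_ms)) args$sd_ms else 8
        sd_samp <- sd_ms / 1000 * epochs@sfreq
        half <- max(1L, ceiling(4 * sd_samp))
        k <- stats::dnorm(seq(-half, half), sd = sd_samp)
        Tn <- d[3]
        W <- matrix(0, Tn, Tn)
        for (t in seq_len(Tn)) {
          lo <- max(1L, t - half); hi <- min(Tn, t + half)
          kk <- k[(lo - t + half + 1L):(hi - t + half + 1L)]
          W[t, lo:hi] <- kk / sum(kk)
        }
        M <- .unfoldTimeLast(data) %*% t(W)
        array(M, dim = d)
      },
      remove_cross_trial_mean = {
        mu <- colMeans(data)               # sensors x times
        data - rep(mu, each = d[1])
      },
      baseline_regress = {
        win <- args$window
        if (is.null(win) || length(win) != 2L)
          stop("baseline_regress needs a length-2 'window' (seconds)")
        sel <- which(times >= win[1] & times <= win[2])
        if (!length(sel))
          stop("baseline window [", win[1], ", ", win[2],
               "] lies outside the epoch")
        out <- data
        for (s in seq_len(d[2])) {
          b <- rowMeans(data[, s, sel, drop = FALSE], dims = 1)
          qrX <- qr(cbind(1, b))
          out[, s, ] <- qr.resid(qrX, data[, s, ])
        }
        out
      },
      unit_variance = {
        sds <- sqrt(apply(data, c(2, 3), stats::var))
        sds[sds == 0] <- 1
        data / rep(sds, each = d[1])
      },
      stop("unknown preprocessing step: ", name)
    )
  }
  initialize(epochs, data = data)
}
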