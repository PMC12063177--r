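#' Fit per-protein Gaussian peaks to an event blockade histogram
#'
#' Histograms the per-event excluded currents of a mixed-protein recording
#' and fits a sum of Gaussians, one per protein peak, by least squares.
#' Each protein's abundance is reported as the area under its fitted curve
#' (AUC) in event counts, `amplitude * sd * sqrt(2 pi) / binwidth`.
#'
#' @param events An [EventTable-class] (at least `minEvents` events).
#' @param nComponents Number of Gaussian components; inferred from
#'   `expectedMeans` when those are given.
#' @param expectedMeans Optional starting means (excluded-current percent),
#'   e.g. the known single-protein blockade depths.
#' @param binPct Histogram bin width in excluded-current percent;
#'   `NULL` (default) picks the Freedman-Diaconis width from the data,
#'   bounded to `[0.5, 5]` percent -- sparse event sets need wider bins for
#'   a stable area estimate.
#' @param minEvents Minimum event count.
#' @return A `data.frame`, one row per component sorted by mean:
#'   `mean_iex_pct`, `sd_pct`, `amplitude`, `auc_events`.
#' @examples
#' set.seed(1)
#' df <- data.frame(start_s = 1:300, dwell_s = 0.01,
#'                  I_EX_pct = c(rnorm(150, 35, 2), rnorm(150, 65, 2)))
#' fitMixturePeaks(EventTable(df), nComponents = 2)
#' @export
fitMixturePeaks <- function(events, nComponents = NULL,
                            expectedMeans = NULL, binPct = NULL,
                            minEvents = 50) {
  iex <- eventData(events)$I_EX_pct
  iex <- iex[is.finite(iex)]
  if (!length(iex)) stop("empty event table")
  if (length(iex) < minEvents)
    stop(sprintf("too few events (%d < %d) for a mixture fit",
                 length(iex), minEvents))
  if (!is.null(expectedMeans)) nComponents <- length(expectedMeans)
  if (is.null(nComponents)) stop("give nComponents or expectedMeans")
  if (length(iex) < 2L * nComponents)
    stop("fewer events than needed for the requested components")
  if (is.null(binPct))
    binPct <- max(0.5, min(5, 2 * stats::IQR(iex) / length(iex)^(1 / 3)))
  breaks <- seq(min(iex) - binPct, max(iex) + binPct, by = binPct)
  h <- graphics::hist(iex, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  if (is.null(expectedMeans)) {
    pk <- .histogramPeaks(x, y, smoothSDbins = 2, promFrac = 0.02,
                          refit = FALSE)
    pk <- pk[order(-pk$height), , drop = FALSE]
    if (nrow(pk) < nComponents)
      expectedMeans <- c(pk$mean,
                         stats::quantile(iex, seq(0.1, 0.9, length.out =
                                                    nComponents)))[
                                                      seq_len(nComponents)]
    else expectedMeans <- sort(pk$mean[seq_len(nComponents)])
  }
  k <- nComponents
  sd0 <- rep(max(stats::sd(iex) / (2 * k), binPct), k)
  A0 <- rep(max(y), k) * 0.8
  par0 <- c(A0, sort(expectedMeans), sd0)
  model <- function(p, x) {
    A <- p[1:k]; mu <- p[(k + 1):(2 * k)]; s <- p[(2 * k + 1):(3 * k)]
    rowSums(vapply(seq_len(k),
                   function(j) A[j] * exp(-(x - mu[j])^2 / (2 * s[j]^2)),
                   numeric(length(x))))
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) y - model(p, x),
    lower = c(rep(0, k), rep(min(x), k), rep(binPct / 4, k)),
    upper = c(rep(2 * max(y) + 1, k), rep(max(x), k),
              rep(max(diff(range(x)) / 2, binPct), k)),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  if (fit$info %in% c(0, 9))
    stop("mixture fit did not converge")
  p <- fit$par
  out <- data.frame(mean_iex_pct = p[(k + 1):(2 * k)],
                    sd_pct = p[(2 * k + 1):(3 * k)],
                    amplitude = p[1:k])
  out$auc_events <- out$amplitude * out$sd_pct * sqrt(2 * pi) / binPct
  out[order(out$mean_iex_pct), , drop = FALSE]
}

#' Fold reduction of protein capture between pore variants
#'
#' Ratio of blockade-histogram AUCs between a reference pore and a gated
#' (linker-functionalized) pore recorded over equal analysis durations --
#' the entropic-gate strength for one protein. A zero gated AUC yields
#' `Inf` (a lower bound) with a warning.
#'
#' @param aucReference AUC (event counts) in the reference pore.
#' @param aucGated AUC in the gated pore, same analysis duration.
#' @return `aucReference / aucGated`.
#' @examples
#' foldReduction(1400, 100)   # 14
#' @export
foldReduction <- function(aucReference, aucGated) {
  if (aucReference < 0 || aucGated < 0) stop("AUCs must be >= 0")
  if (aucGated == 0) {
    warning("gated AUC is zero; fold reduction is a lower bound (> ",
            aucReference, ")")
    return(Inf)
  }
  aucReference / aucGated
}

#' Background false-positive fraction
#'
#' Fraction of apparent target events attributable to background:
#' the target-like event frequency measured without analyte divided by the
#' frequency measured with analyte present.
#'
#' @param fBackground Target-like event frequency without analyte, 1/s.
#' @param fTotal Event frequency with analyte, 1/s (> 0).
#' @return Fraction in `[0, 1]`.
#' @examples
#' backgroundFraction(0.06, 0.27)   # 0.22
#' @export
backgroundFraction <- function(fBackground, fTotal) {
  if (!is.finite(fTotal) || fTotal <= 0) stop("fTotal must be > 0")
  if (fBackground < 0 || fBackground > fTotal)
    stop("need 0 <= fBackground <= fTotal")
  fBackground / fTotal
}

#' Default multilevel-fingerprint criteria
#'
#' Acceptance windows for the caged-target fingerprint, derived from the
#' 70-residue-linker calibration statistics: maximum blockade depth
#' 48 +/- 7 percent, blockade bandwidth 15 +/- 6 Delta-percent, duration of
#' at least 10 s, and at least 3 discrete levels.
#'
#' @return A criteria list for [classifyFingerprints()].
#' @export
defaultFingerprintCriteria <- function() {
  list(iexMaxRange = c(41, 55),
       deltaRange = c(9, 21),
       minDurationS = 10,
       minLevels = 3L)
}

#' Classify events as caged-target fingerprints or background
#'
#' Codifies the multilevel-fingerprint identification of a caged target
#' among background blockades: an event is labelled `"target"` when its
#' maximum blockade depth and blockade bandwidth fall inside the criteria
#' windows, it lasts at least the minimum duration, and shows at least the
#' minimum number of discrete levels; otherwise `"background"`.
#'
#' @param metrics Per-event metrics from [eventLevelMetrics()].
#' @param criteria A criteria list, see [defaultFingerprintCriteria()].
#' @return `metrics` with an added `label` column.
#' @export
classifyFingerprints <- function(metrics, criteria =
                                   defaultFingerprintCriteria()) {
  need <- c("iexMaxRange", "deltaRange", "minDurationS", "minLevels")
  stopifnot(all(need %in% names(criteria)))
  if (diff(criteria$iexMaxRange) <= 0 || diff(criteria$deltaRange) <= 0)
    stop("empty criteria window")
  ok <- metrics$iex_max_pct >= criteria$iexMaxRange[1] &
    metrics$iex_max_pct <= criteria$iexMaxRange[2] &
    metrics$delta_iex_pct >= criteria$deltaRange[1] &
    metrics$delta_iex_pct <= criteria$deltaRange[2] &
    metrics$duration_s >= criteria$minDurationS &
    metrics$n_levels >= criteria$minLevels
  ok[is.na(ok)] <- FALSE
  metrics$label <- ifelse(ok, "target", "background")
  metrics
}
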