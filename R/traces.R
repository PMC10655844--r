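#' Common average reference
#'
#' Subtracts the across-channel mean at every sample, so the channel mean is
#' zero everywhere afterwards.
#'
#' @param trace a `seeg_trace` or a channels x samples matrix (µV).
#' @return same type as the input, re-referenced.
#' @export
common_average_reference <- function(trace) {
  V <- if (inherits(trace, "seeg_trace")) trace$voltages else trace
  if (nrow(V) < 2L) stop("common average reference needs at least 2 channels")
  V <- sweep(V, 2, colMeans(V), "-")
  if (inherits(trace, "seeg_trace")) { trace$voltages <- V; trace } else V
}

#' Noise-based discernibility threshold
#'
#' Four times the standard deviation of the spike-free voltages, pooled
#' across channels. For roughly Gaussian noise this bound contains about
#' 99.99% of the samples, so deflections beyond it are discernible spikes.
#'
#' @param trace a `seeg_trace` (uses its spike-free mask) or a matrix, with
#'   `mask` supplied.
#' @param mask logical per-sample mask of spike-free samples.
#' @param multiplier SD multiplier (default 4).
#' @return threshold in µV.
#' @export
noise_threshold <- function(trace, mask = NULL, multiplier = 4) {
  V <- if (inherits(trace, "seeg_trace")) trace$voltages else trace
  if (is.null(mask) && inherits(trace, "seeg_trace")) mask <- trace$spike_free_mask
  if (is.null(mask)) mask <- rep(TRUE, ncol(V))
  if (!any(mask)) stop("spike-free mask is empty")
  multiplier * sd(as.vector(V[, mask, drop = FALSE]))
}

#' Spike amplitude statistics
#'
#' Per spike window, the maximum voltage magnitude over all channels; the
#' summary reports the mean of the maxima and their 25th percentile (linear
#' interpolation between order statistics). The input is expected to be
#' referenced already (see [common_average_reference()]).
#'
#' @param trace a `seeg_trace` (its recorded spike windows are the default)
#'   or a matrix.
#' @param spike_windows list of `c(start, end)` sample index pairs.
#' @return list with `max_per_spike` (µV), `mean_max`, `p25_max`.
#' @export
spike_amplitude_stats <- function(trace, spike_windows = NULL) {
  V <- if (inherits(trace, "seeg_trace")) trace$voltages else trace
  if (is.null(spike_windows) && inherits(trace, "seeg_trace"))
    spike_windows <- trace$spike_windows
  if (is.null(spike_windows) || length(spike_windows) == 0L)
    stop("at least one spike window is required")
  maxima <- vapply(spike_windows, function(w) {
    if (w[1] < 1 || w[2] > ncol(V) || w[1] > w[2])
      stop("spike window outside the trace")
    max(abs(V[, w[1]:w[2], drop = FALSE]))
  }, numeric(1))
  list(max_per_spike = maxima, mean_max = mean(maxima),
       p25_max = as.numeric(quantile(maxima, 0.25, type = 7)))
}
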