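#' @include AllClasses.R
NULL

#' Friedman-Diaconis bin width
#'
#' Returns 2 * IQR(values) * n^(-1/3), the Friedman-Diaconis rule, which is
#' robust to the heavy-tailed charge distributions seen within environment
#' classes. The IQR uses linear-interpolation quantiles (R type 7). A
#' degenerate spread (IQR = 0, including n = 1) yields width 0.
#'
#' @param values non-empty numeric vector of charges in e.
#' @return numeric(1) bin width in e.
#' @export
fdBinWidth <- function(values) {
  if (length(values) == 0L) stop("fdBinWidth: empty value set")
  2 * stats::IQR(values, type = 7) * length(values)^(-1 / 3)
}

# low median: the ceil(n/2)-th order statistic, always an observed value
.alignMedian <- function(values) sort(values)[ceiling(length(values) / 2)]

#' Build the charge histogram of an environment class
#'
#' Bins 3-decimal charge observations with the Friedman-Diaconis width.
#' When that width rounds below 0.001 e the distribution is treated as
#' discrete (each distinct value its own bin, width 0); otherwise a grid of
#' bins of that width is laid with one bin center at the median charge and
#' extended to cover the minimum and maximum, each value is assigned to the
#' nearest bin center (boundary ties to the lower center), empty bins are
#' dropped, and centers are rounded to 3 decimals (bins whose rounded
#' centers coincide are merged). The alignment median is the low median
#' (the ceil(n/2)-th order statistic): it is an observed 3-decimal charge,
#' equal to the usual median for odd n, and its bin is never empty, so one
#' bin center always equals the alignment median.
#'
#' @param values non-empty numeric vector, each a multiple of 0.001.
#' @return a \linkS4class{ChargeHistogram}
#' @export
buildHistogram <- function(values) {
  if (length(values) == 0L) stop("buildHistogram: empty value set")
  bad <- which(!vapply(values, .isMulti001, logical(1)))
  if (length(bad))
    stop(sprintf("value %g is not a multiple of 0.001", values[bad[1]]))
  values <- round(values, 3)
  w <- fdBinWidth(values)
  if (round(w, 3) < 0.001) {
    tab <- table(values)
    centers <- as.numeric(names(tab))
    o <- order(centers)
    return(new("ChargeHistogram", values = values, binWidth = 0,
               binCenters = centers[o], counts = as.integer(tab)[o],
               nValues = length(values)))
  }
  med <- .alignMedian(values)
  # nearest grid index; exact half-way points go to the lower center
  j <- ceiling((values - med) / w - 0.5 + 1e-12)
  centers <- round(med + j * w, 3)
  agg <- tapply(rep(1L, length(values)), centers, sum)
  cu <- as.numeric(names(agg))
  o <- order(cu)
  new("ChargeHistogram", values = values, binWidth = w,
      binCenters = cu[o], counts = as.integer(agg)[o],
      nValues = length(values))
}

# statistics used by the naive baselines -----------------------------------

# mode = center of the highest-count bin; multimodal ties resolved by the
# mode closest to the median of the raw values, remaining ties to the lower
# charge.
.histogramMode <- function(hist) {
  mx <- max(hist@counts)
  cand <- hist@binCenters[hist@counts == mx]
  if (length(cand) == 1L) return(cand)
  ref <- if (length(hist@values)) stats::median(hist@values)
         else sum(hist@binCenters * hist@counts) / sum(hist@counts)
  d <- abs(cand - ref)
  cand <- cand[d <= min(d) + .MILLI_TOL]
  min(cand)
}
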