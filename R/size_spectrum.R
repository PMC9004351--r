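#' Calibrated electropherogram trace
#'
#' A fragment-size trace from capillary electrophoresis: fragment sizes in bp
#' (already calibrated against the ladder by the instrument software, within
#' the 75-50,000 bp sizing range) and the matching relative fluorescence
#' signal. Traces are assumed baseline-subtracted; see
#' [subtract_baseline()] for an optional rolling-minimum correction.
#'
#' @param size strictly increasing fragment sizes, bp; at least 10 points.
#' @param rfu matching non-negative relative fluorescence values.
#' @return An object of class `electropherogram`: list with `size` and `rfu`.
#' @export
electropherogram <- function(size, rfu) {
  stopifnot(is.numeric(size), is.numeric(rfu), length(size) == length(rfu))
  if (length(size) < 10L) stop("trace needs at least 10 points", call. = FALSE)
  if (is.unsorted(size, strictly = TRUE)) {
    stop("sizes must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(rfu)) || any(rfu < 0)) {
    stop("rfu must be finite and non-negative", call. = FALSE)
  }
  structure(list(size = size, rfu = rfu), class = "electropherogram")
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf("electropherogram: %d points, %g-%g bp, integral %.4g\n",
              length(x$size), min(x$size), max(x$size),
              trapz(x$size, x$rfu)))
  invisible(x)
}

#' Read / write an electropherogram as two-column CSV
#'
#' Columns `size_bp`, `rfu`.
#'
#' @param trace an [electropherogram()].
#' @param path CSV path.
#' @return `read_trace()` returns an `electropherogram`; `write_trace()`
#'   returns the trace invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "electropherogram"))
  utils::write.csv(data.frame(size_bp = trace$size, rfu = trace$rfu),
                   path, row.names = FALSE, quote = FALSE)
  invisible(trace)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("size_bp", "rfu") %in% names(df))) {
    stop("trace CSV must have columns size_bp, rfu", call. = FALSE)
  }
  electropherogram(df$size_bp, df$rfu)
}

#' Optional rolling-minimum baseline subtraction
#'
#' Subtracts a rolling minimum (window of `k` points) from the signal,
#' clipping at zero. Off by default everywhere: input traces are normally
#' assumed baseline-subtracted by the instrument software.
#'
#' @param trace an [electropherogram()].
#' @param k window half-width in points.
#' @return A baseline-corrected `electropherogram`.
#' @export
subtract_baseline <- function(trace, k = 25L) {
  stopifnot(inherits(trace, "electropherogram"), k >= 1L)
  n <- length(trace$rfu)
  base <- vapply(seq_len(n), function(i) {
    min(trace$rfu[max(1L, i - k):min(n, i + k)])
  }, numeric(1))
  electropherogram(trace$size, pmax(0, trace$rfu - base))
}

#' Normalize a trace to unit integral
#'
#' Rescales the signal so its trapezoidal integral over the size axis equals
#' 1, turning RFU into a fragment-size density whose band integrals are mass
#' proportions. Shape is preserved up to scale.
#'
#' @param trace an [electropherogram()].
#' @return A normalised `electropherogram`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "electropherogram"))
  total <- trapz(trace$size, trace$rfu)
  if (total <= 0) stop("trace has zero total signal", call. = FALSE)
  electropherogram(trace$size, trace$rfu / total)
}

#' Proportion of DNA mass within a size band
#'
#' Trapezoidal integral of the (normalised) trace density over `[lo, hi)`,
#' with linear interpolation at the band edges, so that bands partitioning
#' the sizing range have proportions summing to 1. Standard bands: low
#' molecular weight below 1,000 bp, high molecular weight 1,000-40,000 bp,
#' and the sub-350 bp degradation band.
#'
#' @param trace a normalised [electropherogram()] (see [normalize_trace()]).
#' @param lo_bp,hi_bp band limits in bp, `75 <= lo < hi <= 50000`.
#' @return The mass proportion in the band.
#' @export
fraction_in_range <- function(trace, lo_bp, hi_bp) {
  stopifnot(inherits(trace, "electropherogram"))
  if (!(lo_bp < hi_bp)) stop("need lo_bp < hi_bp", call. = FALSE)
  if (lo_bp < 75 || hi_bp > 50000) {
    stop("band must lie within the 75-50,000 bp sizing range", call. = FALSE)
  }
  x <- trace$size
  y <- trace$rfu
  lo <- max(lo_bp, x[1L])
  hi <- min(hi_bp, x[length(x)])
  if (lo >= hi) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, lo)$y, y[inside], stats::approx(x, y, hi)$y)
  trapz(xs, ys)
}

#' Detect peaks and classify their widths
#'
#' Finds peaks of the trace as it appears on the instrument's logarithmic
#' size display: apexes are local maxima of the signal per unit log size
#' (`rfu * size`), which places the apex of a log-Gaussian band exactly at
#' its center rather than at the mode of the per-bp density. Peaks whose
#' topographic prominence (on the display curve, relative to its maximum)
#' falls below `prominence` are discarded. Each peak is described by its
#' apex size (bp), its width at half prominence measured on the size axis,
#' and the mass fraction between its flanking minima (the trace is
#' partitioned at the minima separating adjacent retained peaks, so the
#' mass fractions of all peaks sum to at most 1), and is classified
#' as `"distinct"` (width below `distinct_bp`), `"broad"` (width above
#' `broad_bp`) or `"intermediate"`. A flat trace yields zero peaks.
#'
#' @param trace a normalised [electropherogram()].
#' @param prominence minimum prominence as a fraction of the maximum of the
#'   display curve.
#' @param distinct_bp,broad_bp width classification thresholds, bp; defaults
#'   5,000 and 10,000.
#' @return data.frame with columns `apex_bp`, `width_bp`, `mass_fraction`,
#'   `prominence`, `class`; zero rows if no peak qualifies.
#' @export
detect_peaks <- function(trace, prominence = 0.05,
                         distinct_bp = 5000, broad_bp = 10000) {
  stopifnot(inherits(trace, "electropherogram"),
            prominence >= 0, distinct_bp <= broad_bp)
  x <- trace$size
  y <- trace$rfu * trace$size  # signal per unit log size (display curve)
  n <- length(y)
  empty <- data.frame(apex_bp = numeric(0), width_bp = numeric(0),
                      mass_fraction = numeric(0), prominence = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (max(y) <= 0) return(empty)

  apex <- which(diff(sign(diff(y))) < 0) + 1L  # strict local maxima
  apex <- apex[y[apex] > 0]
  if (!length(apex)) return(empty)

  peak_prom <- vapply(apex, function(i) {
    h <- y[i]
    # walk left/right to the first point higher than the peak (or the edge);
    # the base on each side is the minimum over that stretch
    li <- i
    while (li > 1L && y[li - 1L] <= h) li <- li - 1L
    ri <- i
    while (ri < n && y[ri + 1L] <= h) ri <- ri + 1L
    h - max(min(y[li:i]), min(y[i:ri]))
  }, numeric(1))

  keep <- peak_prom >= prominence * max(y)
  apex <- apex[keep]
  peak_prom <- peak_prom[keep]
  if (!length(apex)) return(empty)

  # partition the trace at the minimum between adjacent retained apexes
  bounds <- c(1L, vapply(seq_len(length(apex) - 1L), function(k) {
    span <- apex[k]:apex[k + 1L]
    span[which.min(y[span])]
  }, integer(1)), n)

  rows <- lapply(seq_along(apex), function(k) {
    i <- apex[k]
    lo <- bounds[k]
    hi <- bounds[k + 1L]
    h <- y[i]
    ref <- h - peak_prom[k] / 2
    # width at half prominence: interpolated crossings of the reference level
    wl <- x[lo]
    for (j in seq(i, lo)) {
      if (y[j] < ref) {
        wl <- stats::approx(y[c(j, j + 1L)], x[c(j, j + 1L)], ref)$y
        break
      }
    }
    wr <- x[hi]
    for (j in seq(i, hi)) {
      if (y[j] < ref) {
        wr <- stats::approx(y[c(j - 1L, j)], x[c(j - 1L, j)], ref)$y
        break
      }
    }
    mass <- trapz(x[lo:hi], trace$rfu[lo:hi])
    data.frame(apex_bp = x[i], width_bp = wr - wl, mass_fraction = mass,
               prominence = peak_prom[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- ifelse(out$width_bp < distinct_bp, "distinct",
                      ifelse(out$width_bp > broad_bp, "broad", "intermediate"))
  rownames(out) <- NULL
  out
}

#' Standard molecular-weight band fractions of a trace
#'
#' Convenience wrapper reporting the proportions in the canonical bands:
#' sub-350 bp, 350-1,000 bp, the 1,000-40,000 bp high-molecular-weight band,
#' and 40,000-50,000 bp, plus the aggregate low-molecular-weight (<1,000 bp)
#' fraction.
#'
#' @param trace an [electropherogram()]; normalised internally.
#' @return Named numeric vector of band proportions.
#' @export
band_fractions <- function(trace) {
  tr <- normalize_trace(trace)
  c(sub350 = fraction_in_range(tr, 75, 350),
    b350_1k = fraction_in_range(tr, 350, 1000),
    hmw_1k_40k = fraction_in_range(tr, 1000, 40000),
    b40k_50k = fraction_in_range(tr, 40000, 50000),
    lmw_under_1k = fraction_in_range(tr, 75, 1000))
}
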