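#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/m) - 1`, where `m` is the standard-curve slope in Cq per
#' log10 copies. A perfect doubling assay has `m = -1/log10(2) = -3.32` and
#' `E = 1`; shallower (more negative) slopes give lower efficiency.
#'
#' @param slope standard-curve slope (must be < 0).
#' @return efficiency as a fraction (0.76 means 76%).
#' @examples
#' qpcr_efficiency(-4.0730)  # ~0.76
#' @export
qpcr_efficiency <- function(slope) {
  if (!is.finite(slope) || slope >= 0) stop("standard-curve slope must be < 0")
  10^(-1 / slope) - 1
}

#' qPCR standard curve
#'
#' @param slope Cq per log10 copies (< 0).
#' @param intercept Cq at 1 copy/uL.
#' @param dynamic_range length-2 numeric, low and high bounds of the linear
#'   range in copies/uL (default 20 to 2e6).
#' @return object of class `ndfo_qpcr_curve` with fields `slope`,
#'   `intercept`, `efficiency`, `dynamic_range`.
#' @examples
#' qpcr_curve(-4.0730, 38)
#' @export
qpcr_curve <- function(slope, intercept, dynamic_range = c(20, 2e6)) {
  if (length(dynamic_range) != 2L || dynamic_range[1] >= dynamic_range[2]) {
    stop("dynamic_range must be (low, high) with low < high")
  }
  structure(
    list(slope = slope, intercept = intercept,
         efficiency = qpcr_efficiency(slope),
         dynamic_range = as.numeric(dynamic_range)),
    class = "ndfo_qpcr_curve"
  )
}

#' @export
print.ndfo_qpcr_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f log10(copies) + %.2f\n  efficiency %.1f%%, linear range %g-%g copies/uL\n",
    x$slope, x$intercept, 100 * x$efficiency,
    x$dynamic_range[1], x$dynamic_range[2]))
  invisible(x)
}

#' Convert Cq values to copy numbers via a standard curve
#'
#' `copies = 10^((cq - intercept) / slope)`, flagged against the curve's
#' linear dynamic range.
#'
#' @param cq numeric vector of quantification cycles.
#' @param curve an [qpcr_curve()].
#' @return data frame with columns `cq`, `copies_per_uL`, `in_range`.
#' @export
copies_from_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "ndfo_qpcr_curve"))
  copies <- 10^((cq - curve$intercept) / curve$slope)
  data.frame(
    cq = cq,
    copies_per_uL = copies,
    in_range = copies >= curve$dynamic_range[1] & copies <= curve$dynamic_range[2]
  )
}

#' Expected Cq for a copy number (inverse of [copies_from_cq()])
#'
#' @param copies copies/uL (> 0).
#' @param curve an [qpcr_curve()].
#' @return numeric Cq values.
#' @export
cq_from_copies <- function(copies, curve) {
  stopifnot(inherits(curve, "ndfo_qpcr_curve"))
  if (any(copies <= 0)) stop("copies must be > 0")
  curve$intercept + curve$slope * log10(copies)
}

#' Growth check from a copy-number time series
#'
#' Formalizes the no-growth conclusion: the fold change of the last over the
#' first quantification is compared with a threshold (default 2-fold over
#' the incubation). If a curve is supplied and any point falls outside its
#' linear dynamic range the verdict is `below_range` since the fold change
#' is then not quantitative.
#'
#' @param copies numeric vector of copies/uL in time order (>= 2 points,
#'   all > 0).
#' @param threshold fold-change threshold for calling growth.
#' @param curve optional [qpcr_curve()] supplying the dynamic range.
#' @return list of class `ndfo_growth_check`: `fold_change`, `threshold`,
#'   `verdict` in `{"growth", "no_growth", "below_range"}`.
#' @examples
#' growth_check(c(5e6, 4.8e6, 5.2e6))
#' @export
growth_check <- function(copies, threshold = 2, curve = NULL) {
  if (length(copies) < 2L) stop("need at least 2 time points for a growth check")
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    stop("copy numbers must be finite and > 0")
  }
  fold <- copies[length(copies)] / copies[1]
  verdict <- if (!is.null(curve)) {
    stopifnot(inherits(curve, "ndfo_qpcr_curve"))
    rng <- curve$dynamic_range
    if (any(copies < rng[1] | copies > rng[2])) "below_range"
    else if (fold >= threshold) "growth" else "no_growth"
  } else {
    if (fold >= threshold) "growth" else "no_growth"
  }
  structure(list(fold_change = fold, threshold = threshold, verdict = verdict),
            class = "ndfo_growth_check")
}

#' @export
print.ndfo_growth_check <- function(x, ...) {
  cat(sprintf("growth check: fold change %.3g (threshold %g) -> %s\n",
              x$fold_change, x$threshold, x$verdict))
  invisible(x)
}
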