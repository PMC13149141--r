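#' Sample entropy
#'
#' Negative log conditional probability that template vectors matching for
#' `m` points (Chebyshev distance within `r`) also match for `m + 1`
#' points; self-matches excluded. Tolerance is `r_fraction * sd(x)` unless
#' an absolute `r` is supplied.
#'
#' @param x numeric series (typically the cleaned beat-by-beat RRI
#'   sequence); length >= 100 recommended for stable estimates.
#' @param m template length (default 2).
#' @param r_fraction tolerance as a fraction of `sd(x)` (default 0.2).
#' @param r absolute tolerance; overrides `r_fraction` when given.
#' @return sample entropy (unitless); `+Inf` with a warning when no
#'   template pairs match at length `m`.
#' @export
sampen <- function(x, m = 2L, r_fraction = 0.2, r = NULL) {
  if (inherits(x, "uniform_series")) x <- x$values
  x <- as.numeric(x)
  if (length(x) <= m + 1L) stop("series too short for sample entropy", call. = FALSE)
  if (is.null(r)) r <- r_fraction * stats::sd(x)
  if (r == 0) {
    # constant series: every template matches at every length
    if (stats::sd(x) == 0) return(0)
  }
  cnt <- .sampen_counts_cpp(x, as.integer(m), r)
  if (cnt[2] == 0 || cnt[1] == 0) {
    warning("no template matches: sample entropy undefined (+Inf)", call. = FALSE)
    return(Inf)
  }
  -log(cnt[1] / cnt[2])
}

#' Refined composite multiscale entropy
#'
#' For each scale `tau`, all `tau` coarse-graining offset series are formed
#' (non-overlapping block means starting at offsets 1..tau); template-match
#' counts at lengths `m` and `m + 1` are accumulated across offsets and the
#' entropy is `-log(sum A / sum B)`. The tolerance `r = r_fraction * sd(x)`
#' is frozen from the original series and reused at every scale, so scale 1
#' equals standard sample entropy with the same `(m, r)`.
#'
#' @param x numeric series (e.g. a windowed phase-synchronization series).
#' @param m template length (default 2).
#' @param r_fraction tolerance fraction of the original series' SD
#'   (default 0.15).
#' @param scales integer vector of coarse-graining scales (default 1:3).
#' @return named numeric vector, one entropy per scale; `+Inf` sentinel
#'   (with warning) where no length-`m` matches exist.
#' @export
rcmse <- function(x, m = 2L, r_fraction = 0.15, scales = 1:3) {
  if (inherits(x, "sync_series")) x <- x$rho
  if (inherits(x, "uniform_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (n < 60 * max(scales))
    stop("series too short: need length >= 60 * max(scales)", call. = FALSE)
  sdx <- stats::sd(x)
  if (sdx == 0) return(stats::setNames(rep(0, length(scales)),
                                       paste0("scale", scales)))
  r <- r_fraction * sdx
  out <- vapply(scales, function(tau) {
    A <- 0; B <- 0
    for (k in seq_len(tau)) {
      nb <- floor((n - k + 1) / tau)
      idx <- k + tau * (seq_len(nb) - 1)
      y <- vapply(seq_len(nb), function(i) {
        mean(x[idx[i]:(idx[i] + tau - 1)])
      }, 0)
      cnt <- .sampen_counts_cpp(y, as.integer(m), r)
      A <- A + cnt[1]; B <- B + cnt[2]
    }
    if (B == 0 || A == 0) {
      warning(sprintf("scale %d: no template matches (+Inf sentinel)", tau),
              call. = FALSE)
      return(Inf)
    }
    -log(A / B)
  }, 0)
  stats::setNames(out, paste0("scale", scales))
}

#' Scalar complexity index from per-scale entropies
#'
#' Mean of the finite per-scale entropy values; scales carrying the `+Inf`
#' sentinel (no template matches) are excluded with a warning.
#'
#' @param entropies numeric vector from [rcmse()].
#' @return scalar complexity (mean entropy over usable scales).
#' @export
complexity_index <- function(entropies) {
  fin <- is.finite(entropies)
  if (!any(fin)) stop("all scales undefined: no complexity index", call. = FALSE)
  if (!all(fin))
    warning(sprintf("%d of %d scales undefined; excluded from complexity index",
                    sum(!fin), length(entropies)), call. = FALSE)
  mean(entropies[fin])
}
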