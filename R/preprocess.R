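#' Log2-transform non-negative expression values
#'
#' @param emat genes x samples numeric matrix of non-negative values
#'   (counts or intensities).
#' @param offset non-negative pseudo-value added before taking logs.
#' @return matrix of `log2(value + offset)`.
#' @export
log2_transform <- function(emat, offset = 1) {
  emat <- as_expression_matrix(emat)
  stopifnot(is.numeric(offset), length(offset) == 1L, offset >= 0)
  if (any(emat < 0, na.rm = TRUE)) {
    stop_ntp("negative values found; data may already be on log scale")
  }
  log2(emat + offset)
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the identical empirical distribution: the
#' per-rank mean of the sorted columns. Tied values within a column receive the
#' mean of the reference values at their tied rank positions, so a fully tied
#' column becomes constant at the mean of the reference distribution. Missing
#' values are excluded from rank computation (the column's non-missing values
#' are mapped onto the reference by linear interpolation) and stay missing.
#'
#' @param emat genes x samples numeric matrix with >= 2 samples.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(emat) {
  emat <- as_expression_matrix(emat)
  if (ncol(emat) < 2L) {
    stop_ntp("quantile normalization needs >= 2 samples; skip normalization for a single sample")
  }
  n <- nrow(emat)
  grid <- if (n > 1L) seq(0, 1, length.out = n) else 0.5
  # reference distribution: per-rank mean of sorted columns, each column
  # stretched to n points when it has missing entries
  sorted <- vapply(seq_len(ncol(emat)), function(j) {
    x <- sort(emat[, j])  # drops NA
    if (length(x) == 0L) return(rep(NA_real_, n))
    if (length(x) == n) x else stats::approx(seq(0, 1, length.out = length(x)),
                                             x, grid, rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(sorted, na.rm = TRUE)
  out <- emat
  for (j in seq_len(ncol(emat))) {
    x <- emat[, j]
    ok <- which(!is.na(x))
    m <- length(ok)
    if (m == 0L) next
    ref_j <- if (m == n) ref else stats::approx(grid, ref,
                                                seq(0, 1, length.out = m),
                                                rule = 2)$y
    o <- order(x[ok])
    v <- ref_j
    # tie groups share the mean of the reference values at their rank positions
    v <- stats::ave(v, match(x[ok][o], unique(x[ok][o])))
    out[ok[o], j] <- v
  }
  out
}

#' Row-wise centering and scaling
#'
#' Centers each gene (row) on its mean and/or scales it to unit standard
#' deviation (denominator `n - 1`). Zero-variance rows cannot be scaled and
#' are set to all-zero with a warning. Missing values are ignored in the row
#' statistics and propagate.
#'
#' @param emat genes x samples numeric matrix.
#' @param center subtract the row mean.
#' @param scale divide by the row standard deviation.
#' @return transformed matrix of the same shape.
#' @export
row_center_scale <- function(emat, center = TRUE, scale = TRUE) {
  emat <- as_expression_matrix(emat)
  out <- emat
  if (center) out <- out - rowMeans(out, na.rm = TRUE)
  if (scale) {
    sds <- apply(emat, 1L, stats::sd, na.rm = TRUE)
    degen <- !is.na(sds) & sds == 0
    if (any(degen)) {
      warning(sum(degen), " zero-variance row(s) set to all-zero",
              call. = FALSE)
      out[degen, ] <- 0
      sds[degen] <- 1
    }
    # scaling without centering still divides by the sd about the mean
    out[!degen, ] <- out[!degen, , drop = FALSE] / sds[!degen]
  }
  out
}
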