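#' Aggregate TAD analysis
#'
#' Takes every TAD with a flank of half its length on each side, extracts
#' the corresponding O/E window, rescales it to `out_dim x out_dim` by
#' area-weighted averaging (the TAD body occupies the central 50%), and
#' averages the rescaled windows. The strength scalar is the mean of the
#' central 50% x 50% block divided by the mean of the four corner
#' 25% x 25% blocks; it is ~1 for structureless matrices and grows with
#' domain strength.
#'
#' @param m a `contact_matrix`.
#' @param tads interval data.frame of TADs (e.g. from [borders_to_tads()] or
#'   the reference stage's calls).
#' @param out_dim output matrix dimension.
#' @param oe optional precomputed [observed_over_expected()] matrix for `m`.
#' @return list with `matrix` (out_dim x out_dim mean O/E), `strength`,
#'   `n_tads` (windows used), class `ata_result`.
#' @export
aggregate_tads <- function(m, tads, out_dim = 100, oe = NULL) {
  stopifnot(inherits(m, "contact_matrix"), nrow(tads) >= 1, out_dim %% 4 == 0)
  asm <- m$assembly
  bs <- asm$bin_size
  if (is.null(oe)) oe <- observed_over_expected(m)
  acc <- matrix(0, out_dim, out_dim)
  wacc <- matrix(0, out_dim, out_dim)
  used <- 0L
  for (k in seq_len(nrow(tads))) {
    L <- tads$end[k] - tads$start[k]
    ws <- tads$start[k] - L / 2
    we <- tads$end[k] + L / 2
    ci <- match(tads$chrom[k], asm$chrom_names)
    if (is.na(ci) || ws < 0 || we > asm$chrom_lengths[ci]) next
    b0 <- floor(ws / bs); b1 <- ceiling(we / bs)  # 0-based bin range [b0, b1)
    idx <- asm$offsets[ci] + (b0 + 1):b1
    win <- oe[idx, idx, drop = FALSE]
    rs <- resize_matrix(win, out_dim)
    ok <- !is.na(rs)
    acc[ok] <- acc[ok] + rs[ok]
    wacc[ok] <- wacc[ok] + 1
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TADs: every window leaves its chromosome")
  avg <- acc / wacc
  avg[wacc == 0] <- NA_real_
  structure(list(matrix = avg, strength = ata_strength(avg, out_dim),
                 n_tads = used),
            class = "ata_result")
}

# area-weighted rescale of an n x n matrix (NA = masked) to k x k
resize_matrix <- function(x, k) {
  n <- nrow(x)
  if (n == k) return(x)
  # A[t, i] = overlap of target cell t with source bin i (in source-bin units)
  A <- matrix(0, k, n)
  w <- n / k
  for (t in seq_len(k)) {
    lo <- (t - 1) * w; hi <- t * w
    i0 <- floor(lo) + 1; i1 <- ceiling(hi)
    for (i in i0:min(i1, n)) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) A[t, i] <- ov
    }
  }
  valid <- !is.na(x)
  x0 <- x; x0[!valid] <- 0
  num <- A %*% x0 %*% t(A)
  den <- A %*% valid %*% t(A)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

ata_strength <- function(avg, out_dim = nrow(avg)) {
  q <- out_dim / 4
  ctr <- avg[(q + 1):(3 * q), (q + 1):(3 * q)]
  lo <- 1:q; hi <- (3 * q + 1):out_dim
  corners <- c(avg[lo, lo], avg[lo, hi], avg[hi, lo], avg[hi, hi])
  mean(ctr, na.rm = TRUE) / mean(corners, na.rm = TRUE)
}

#' @export
print.ata_result <- function(x, ...) {
  cat("ata_result:", x$n_tads, "TAD windows, strength",
      format(x$strength, digits = 4), "\n")
  invisible(x)
}
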