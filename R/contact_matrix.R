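#' Binned Hi-C contact matrix
#'
#' A symmetric, nonnegative genome-wide matrix of contact counts over the
#' bins of a [genome_assembly()]. Bins whose marginal sum (coverage) is zero
#' are "dead" (assembly gaps / unmappable regions) and are masked by all
#' downstream analyses.
#'
#' @param assembly a `genome_assembly`.
#' @param counts square numeric matrix over all genome bins; must be
#'   symmetric with nonnegative entries.
#' @param balanced logical flag recording whether counts were balanced.
#' @return an object of class `contact_matrix` with elements `assembly`,
#'   `counts`, `coverage` (per-bin marginal sum), `balanced`.
#' @export
contact_matrix <- function(assembly, counts, balanced = FALSE) {
  stopifnot(inherits(assembly, "genome_assembly"), is.matrix(counts))
  nb <- n_bins(assembly)
  if (!all(dim(counts) == nb))
    stop("counts must be ", nb, " x ", nb, " for this assembly")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8)))
    stop("counts must be symmetric")
  m <- list(assembly = assembly, counts = counts,
            coverage = rowSums(counts), balanced = isTRUE(balanced))
  class(m) <- "contact_matrix"
  m
}

#' Dead (zero-coverage) bins of a contact matrix
#' @param m a `contact_matrix`.
#' @return logical vector, TRUE for masked bins.
#' @export
dead_bins <- function(m) m$coverage == 0

#' Extract the intra-chromosomal block of a matrix
#'
#' @param m a `contact_matrix` (or plain matrix with matching dimension).
#' @param chrom chromosome name.
#' @return the square cis submatrix for `chrom`.
#' @export
cis_block <- function(m, chrom) {
  idx <- chrom_bins(if (inherits(m, "contact_matrix")) m$assembly else attr(m, "assembly"), chrom)
  x <- if (inherits(m, "contact_matrix")) m$counts else m
  x[idx, idx, drop = FALSE]
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", n_bins(x$assembly), "bins,",
      format(sum(x$counts), big.mark = ","), "total counts,",
      sum(dead_bins(x)), "dead bins\n")
  invisible(x)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts of consecutive fine bins within each chromosome. The new bin
#' size must be an integer multiple of the old one. A coarse bin whose valid
#' (non-dead) fine-bin fraction is below `min_valid_frac` is masked (zeroed),
#' so that partially covered bins do not enter compartment calls.
#'
#' @param m a `contact_matrix`.
#' @param new_bin_size target bin size in bp (multiple of `m$assembly$bin_size`).
#' @param min_valid_frac minimum fraction of live fine bins per coarse bin.
#' @return a `contact_matrix` at the new resolution.
#' @export
rebin <- function(m, new_bin_size, min_valid_frac = 0.5) {
  asm <- m$assembly
  k <- new_bin_size / asm$bin_size
  if (k != round(k) || k < 1) stop("new_bin_size must be a multiple of the current bin size")
  asm2 <- genome_assembly(stats::setNames(asm$chrom_lengths, asm$chrom_names), new_bin_size)
  # aggregation matrix: coarse bins x fine bins
  A <- matrix(0, n_bins(asm2), n_bins(asm))
  for (cn in asm$chrom_names) {
    fb <- chrom_bins(asm, cn); cb <- chrom_bins(asm2, cn)
    grp <- floor((seq_along(fb) - 1) / k) + 1
    A[cbind(cb[grp], fb)] <- 1
  }
  cnt <- A %*% m$counts %*% t(A)
  alive <- as.numeric(!dead_bins(m))
  frac <- as.numeric(A %*% alive) / as.numeric(A %*% rep(1, n_bins(asm)))
  drop <- frac < min_valid_frac
  cnt[drop, ] <- 0; cnt[, drop] <- 0
  contact_matrix(asm2, unname(cnt), balanced = m$balanced)
}

#' Write a contact matrix as dense text with a bins sidecar
#'
#' `file` receives the whitespace-delimited dense count matrix; a sidecar
#' `<file>.bins` holds the `chrom start end` table describing the rows.
#'
#' @param m a `contact_matrix`.
#' @param file output path.
#' @export
write_contact_matrix <- function(m, file) {
  data.table::fwrite(data.table::as.data.table(m$counts), file,
                     sep = " ", col.names = FALSE)
  bt <- bin_table(m$assembly)
  data.table::fwrite(bt[, c("chrom", "start", "end")], paste0(file, ".bins"),
                     sep = "\t", col.names = TRUE)
  invisible(file)
}

#' Read a dense-text contact matrix written by [write_contact_matrix()]
#'
#' @param file path to the dense matrix; `<file>.bins` must exist.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(file) {
  bins <- data.table::fread(paste0(file, ".bins"), header = TRUE)
  cnt <- as.matrix(data.table::fread(file, header = FALSE))
  dimnames(cnt) <- NULL
  lens <- vapply(split(bins$end, bins$chrom), max, numeric(1))
  lens <- lens[unique(bins$chrom)]  # preserve file order
  bs <- max(bins$end - bins$start)
  asm <- genome_assembly(lens, bs)
  contact_matrix(asm, cnt)
}
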