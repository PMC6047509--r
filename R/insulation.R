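#' Insulation score of a contact matrix
#'
#' For every bin i, the raw score is the mean contact count in the w x w
#' square spanning bins `[i-w, i-1] x [i+1, i+w]` (the contacts that cross
#' bin i), computed over pairs of live bins only. The normalized score is
#' `log2(raw / chromosome mean raw)`; minima mark domain boundaries. Bins
#' within `w` of a chromosome end, dead bins, and bins whose window holds no
#' valid pair are masked. At 20-kb resolution the default `w = 25`
#' corresponds to a 500-kb window.
#'
#' @param m a `contact_matrix`.
#' @param w window half-size in bins (>= 2).
#' @return object of class `insulation_profile`: data.frame with `chrom`,
#'   `start`, `end`, `raw`, `normalized`; attributes `assembly`, `w`.
#' @export
insulation_score <- function(m, w = 25) {
  stopifnot(inherits(m, "contact_matrix"), w >= 2)
  asm <- m$assembly
  dead <- dead_bins(m)
  bt <- bin_table(asm)
  raw <- rep(NA_real_, nrow(bt))
  for (cn in asm$chrom_names) {
    idx <- chrom_bins(asm, cn)
    n <- length(idx)
    if (n <= 2 * w) {
      warning("chromosome ", cn, " shorter than 2w+1 bins; masked")
      next
    }
    blk <- m$counts[idx, idx, drop = FALSE]
    alive <- !dead[idx]
    for (i in (w + 1):(n - w)) {
      if (!alive[i]) next
      rows <- (i - w):(i - 1); cols <- (i + 1):(i + w)
      npair <- sum(alive[rows]) * sum(alive[cols])
      if (npair == 0) next
      # dead rows/cols are all-zero, so the plain block sum is the live sum
      raw[idx[i]] <- sum(blk[rows, cols]) / npair
    }
  }
  raw[!is.na(raw) & raw == 0] <- NA_real_  # log-undefined windows are masked
  norm <- rep(NA_real_, length(raw))
  for (cn in asm$chrom_names) {
    idx <- chrom_bins(asm, cn)
    mu <- mean(raw[idx], na.rm = TRUE)
    if (is.finite(mu) && mu > 0) norm[idx] <- log2(raw[idx] / mu)
  }
  structure(data.frame(chrom = bt$chrom, start = bt$start, end = bt$end,
                       raw = raw, normalized = norm),
            assembly = asm, w = w,
            class = c("insulation_profile", "data.frame"))
}

#' Border set constructor
#'
#' @param chrom,pos,strength,side column vectors; `side` is `"5p"` or
#'   `"3p"`, the border's role relative to the TAD it delimits.
#' @return data.frame of class `border_set`, sorted by position.
#' @export
border_set <- function(chrom, pos, strength = NA_real_, side = "5p") {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strength = as.numeric(strength), side = as.character(side),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos, df$side), ]
  rownames(df) <- NULL
  structure(df, class = c("border_set", "data.frame"))
}

#' Borders of a TAD partition
#'
#' Every TAD contributes its 5' border (at its start) and its 3' border
#' (at its end).
#'
#' @param tads interval data.frame of TADs.
#' @return a `border_set` with two rows per TAD.
#' @export
tad_borders <- function(tads) {
  border_set(chrom = rep(tads$chrom, 2),
             pos = c(tads$start, tads$end),
             side = rep(c("5p", "3p"), each = nrow(tads)))
}

#' Call TAD borders from an insulation profile
#'
#' Borders are local minima of the normalized insulation score whose dip
#' depth — the mean normalized score over the w bins on each side minus the
#' score at the minimum — reaches `min_strength`. Among minima closer than
#' w bins, only the deepest is kept (ties to the lower coordinate).
#'
#' @param profile an `insulation_profile`.
#' @param min_strength minimum dip depth in log2 units.
#' @return a `border_set` (positions at the bin midpoint); possibly empty.
#' @export
call_borders <- function(profile, min_strength = 0.1) {
  asm <- attr(profile, "assembly")
  w <- attr(profile, "w")
  out <- list()
  for (cn in asm$chrom_names) {
    sub <- profile[profile$chrom == cn, ]
    s <- sub$normalized
    n <- length(s)
    cand <- which(!is.na(s))
    cand <- cand[cand > 1 & cand < n]
    is_min <- vapply(cand, function(i) {
      l <- s[i - 1]; r <- s[i + 1]
      !is.na(l) && !is.na(r) && s[i] < l && s[i] <= r
    }, logical(1))
    cand <- cand[is_min]
    if (!length(cand)) next
    strength <- vapply(cand, function(i) {
      left <- s[max(1, i - w):(i - 1)]; right <- s[(i + 1):min(n, i + w)]
      ml <- mean(left, na.rm = TRUE); mr <- mean(right, na.rm = TRUE)
      (ml + mr) / 2 - s[i]
    }, numeric(1))
    keep <- !is.na(strength) & strength >= min_strength
    cand <- cand[keep]; strength <- strength[keep]
    if (!length(cand)) next
    # non-maximum suppression within w bins; deepest minimum wins,
    # ties broken toward the lower coordinate
    ord <- order(s[cand], cand)
    sel <- logical(length(cand))
    taken <- integer(0)
    for (k in ord) {
      if (!any(abs(cand[k] - taken) < w)) {
        sel[k] <- TRUE
        taken <- c(taken, cand[k])
      }
    }
    out[[cn]] <- data.frame(chrom = cn,
                            pos = (sub$start[cand[sel]] + sub$end[cand[sel]]) / 2,
                            strength = strength[sel])
  }
  if (!length(out)) return(border_set(character(0), numeric(0), numeric(0), character(0)))
  df <- do.call(rbind, out)
  border_set(df$chrom, df$pos, df$strength, side = "5p")
}

#' Filter borders overlapping uncovered bins
#'
#' Removes borders whose containing Hi-C bin, or either flanking bin, has
#' zero coverage. Uncovered bins (assembly gaps) masquerade as strong
#' borders and must not enter downstream statistics.
#'
#' @param borders a `border_set`.
#' @param m the `contact_matrix` supplying the coverage mask.
#' @return the filtered `border_set`, with attribute `n_removed`.
#' @export
filter_borders <- function(borders, m) {
  asm <- m$assembly
  dead <- dead_bins(m)
  nb <- n_bins(asm)
  if (nrow(borders) == 0) return(structure(borders, n_removed = 0L))
  pos <- pmin(borders$pos, asm$chrom_lengths[match(borders$chrom, asm$chrom_names)] - 1)
  b <- bin_of(asm, borders$chrom, pos)
  # flanking bins clipped at chromosome ends (same-chromosome neighbours only)
  ci <- match(borders$chrom, asm$chrom_names)
  lo <- asm$offsets[ci] + 1L; hi <- asm$offsets[ci] + asm$n_bins_chrom[ci]
  bad <- dead[b] |
    ifelse(b - 1 >= lo, dead[pmax(b - 1, 1)], FALSE) |
    ifelse(b + 1 <= hi, dead[pmin(b + 1, nb)], FALSE)
  if (all(bad)) warning("all borders overlap uncovered bins")
  out <- borders[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_removed = sum(bad), class = class(borders))
}

#' TADs implied by a set of called borders
#'
#' Consecutive borders on a chromosome delimit TADs; segments before the
#' first and after the last border are included. Segments shorter than
#' `min_bins` bins are dropped.
#'
#' @param borders a `border_set`.
#' @param assembly the `genome_assembly`.
#' @param min_bins minimum TAD length in bins.
#' @return interval data.frame of TADs.
#' @export
borders_to_tads <- function(borders, assembly, min_bins = 3) {
  out <- lapply(assembly$chrom_names, function(cn) {
    p <- sort(borders$pos[borders$chrom == cn])
    p <- round(p / assembly$bin_size) * assembly$bin_size
    edges <- unique(c(0, p, assembly$chrom_lengths[[cn]]))
    df <- intervals(chrom = cn, start = edges[-length(edges)], end = edges[-1])
    df[df$end - df$start >= min_bins * assembly$bin_size, ]
  })
  out <- do.call(rbind, out)
  out$name <- paste0("tad", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
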