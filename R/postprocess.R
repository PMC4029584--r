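#' Extract candidate CNV regions from a decoded state path
#'
#' A locus is aberrant when either haplotype carries a gain or a loss state.
#' Gains and losses never share a region: gain regions are maximal runs of
#' loci carrying a gain (and no loss) on some haplotype, and symmetrically
#' for losses. The rare locus carrying a gain on one haplotype and a loss on
#' the other joins neither run.
#'
#' @param path L x 2 character matrix of allelic states (columns = the two
#'   haplotypes), as returned by [viterbi_decode()] in \code{$states}.
#' @return data.frame with columns \code{start_idx, end_idx, direction,
#'   n_snps} (indices are positions within the path), unfiltered.
#' @export
extract_regions <- function(path) {
  cls1 <- state_class(path[, 1]); cls2 <- state_class(path[, 2])
  has_gain <- cls1 == "gain" | cls2 == "gain"
  has_loss <- cls1 == "loss" | cls2 == "loss"
  out <- rbind(.runs_of(has_gain & !has_loss, "gain"),
               .runs_of(has_loss & !has_gain, "loss"))
  out <- out[order(out$start_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.runs_of <- function(flag, direction) {
  if (!any(flag)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      direction = character(0), n_snps = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             direction = direction, n_snps = r$lengths[keep])
}

#' Filter candidate CNV regions
#'
#' Applies, in order: (1) regions of a single SNP are dropped; (2) two
#' regions of the same direction separated by at most two SNPs are merged,
#' absorbing the gap loci; (3) regions in which more than 4/5 of the SNPs
#' are low-confidence (signal inside the shaded region) are dropped;
#' (4) regions of fewer than four SNPs are dropped if any member signal lies
#' in the shaded region.
#'
#' @param regions data.frame from [extract_regions()].
#' @param shaded logical vector over the path's loci: TRUE where the
#'   sample's signal falls in the shaded region ([in_shaded_region()]).
#' @return Filtered (and possibly merged) region data.frame.
#' @export
filter_regions <- function(regions, shaded) {
  empty <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      direction = character(0), n_snps = integer(0))
  regions <- regions[regions$n_snps >= 2L, , drop = FALSE]
  if (nrow(regions) == 0L) return(empty)
  merged <- lapply(split(regions, regions$direction), function(g) {
    g <- g[order(g$start_idx), , drop = FALSE]
    i <- 1L
    while (i < nrow(g)) {
      gap <- g$start_idx[i + 1L] - g$end_idx[i] - 1L
      if (gap <= 2L) {
        g$end_idx[i] <- g$end_idx[i + 1L]
        g <- g[-(i + 1L), , drop = FALSE]
      } else {
        i <- i + 1L
      }
    }
    g
  })
  regions <- do.call(rbind, c(merged, list(make.row.names = FALSE)))
  if (is.null(regions) || nrow(regions) == 0L) return(empty)
  regions$n_snps <- regions$end_idx - regions$start_idx + 1L
  n_low <- mapply(function(s, e) sum(shaded[s:e]),
                  regions$start_idx, regions$end_idx)
  keep <- n_low <= (4 / 5) * regions$n_snps &
    !(regions$n_snps < 4L & n_low > 0L)
  regions <- regions[keep, , drop = FALSE]
  regions <- regions[order(regions$start_idx), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Fractional allele-specific copy numbers at one SNP
#'
#' Copy numbers are read off by linear interpolation/extrapolation on the
#' model grid: the A-signal difference between one A copy and zero (M5 vs
#' M9 centers) or between two copies and one (M1 vs M5) gives the per-copy
#' increment, and the larger of the two is used as the divisor as a
#' conservative choice:
#' \preformatted{
#'   nA = (sA - muA(M9)) / max(muA(M5) - muA(M9), muA(M1) - muA(M5))
#'   nB = (sB - muB(M1)) / max(muB(M5) - muB(M1), muB(M9) - muB(M5))
#' }
#' Negative estimates are clipped to zero.
#'
#' @param signal numeric length-2 vector (sA, sB).
#' @param bank a \code{haplocn_bank}.
#' @param snp SNP row index.
#' @return Named numeric \code{c(n_a, n_b)}; \code{NA} with attribute
#'   \code{flagged = TRUE} when a per-copy increment is non-positive.
#' @export
estimate_allelic_cn <- function(signal, bank, snp) {
  mu <- bank$mu[snp, , ]
  dA <- max(mu["M5", 1] - mu["M9", 1], mu["M1", 1] - mu["M5", 1])
  dB <- max(mu["M5", 2] - mu["M1", 2], mu["M9", 2] - mu["M5", 2])
  if (dA <= 0 || dB <= 0) {
    out <- c(n_a = NA_real_, n_b = NA_real_)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  c(n_a = max(0, (signal[1] - mu["M9", 1]) / dA),
    n_b = max(0, (signal[2] - mu["M1", 2]) / dB))
}

# vectorised allelic CN for a whole cohort; returns matrices and a per-SNP
# flag for non-positive increments
.allelic_cn_all <- function(bank, signals) {
  mu <- bank$mu
  dA <- pmax(mu[, "M5", 1] - mu[, "M9", 1], mu[, "M1", 1] - mu[, "M5", 1])
  dB <- pmax(mu[, "M5", 2] - mu[, "M1", 2], mu[, "M9", 2] - mu[, "M5", 2])
  bad <- dA <= 0 | dB <= 0
  cn_a <- pmax((signals$a - mu[, "M9", 1]) / dA, 0)
  cn_b <- pmax((signals$b - mu[, "M1", 2]) / dB, 0)
  cn_a[bad, ] <- NA_real_
  cn_b[bad, ] <- NA_real_
  list(cn_a = cn_a, cn_b = cn_b, flagged = bad)
}

#' Per-haplotype mean copy number over a region
#'
#' At each SNP the allele carried by a haplotype decides whether the A or
#' the B fractional copy number contributes to that haplotype's series; the
#' summaries are the arithmetic means of the two series across the region.
#'
#' @param region one-row data.frame (or list) with \code{start_idx} and
#'   \code{end_idx}.
#' @param path L x 2 character matrix of phased allelic states.
#' @param cn_a,cn_b numeric vectors of per-SNP fractional allele copy
#'   numbers along the path.
#' @return Numeric \code{c(hap1, hap2)} mean copy numbers (NAs dropped).
#' @export
haplotype_cn_summary <- function(region, path, cn_a, cn_b) {
  idx <- region$start_idx:region$end_idx
  per_hap <- vapply(1:2, function(h) {
    allele <- state_allele(path[idx, h])
    vals <- ifelse(allele == "A", cn_a[idx], cn_b[idx])
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(per_hap, c("hap1", "hap2"))
}

#' Mean total copy number of a region
#'
#' The mean over the region's SNPs of the summed fractional allele copy
#' numbers.
#'
#' @inheritParams haplotype_cn_summary
#' @return Mean total copy number.
#' @export
total_cn <- function(region, cn_a, cn_b) {
  idx <- region$start_idx:region$end_idx
  mean(cn_a[idx] + cn_b[idx], na.rm = TRUE)
}

#' Classify a region's mean total copy number
#'
#' A CNV event is reported when the estimated total copy number exceeds 3
#' (gain) or falls below 1 (loss); anything in between is called normal.
#'
#' @param cn mean total copy number.
#' @return \code{"gain"}, \code{"loss"} or \code{"normal"}.
#' @export
call_event <- function(cn) {
  ifelse(cn > 3, "gain", ifelse(cn < 1, "loss", "normal"))
}
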