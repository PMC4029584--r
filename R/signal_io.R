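#' Read per-SNP, per-sample allele intensity summaries
#'
#' Expects a tab-delimited file with header
#' \code{probe_id chrom pos <sample>.A <sample>.B ...}: one row per SNP, two
#' intensity columns per sample (summarised A-allele and B-allele signal).
#' Rows are sorted by (chrom, pos) on read.
#'
#' @param path path to the signals TSV.
#' @return An object of class \code{haplocn_signals}: list with
#'   \describe{
#'     \item{snps}{data.frame (probe_id, chrom, pos), sorted by (chrom, pos)}
#'     \item{samples}{character vector of sample ids}
#'     \item{a, b}{numeric matrices, SNPs x samples, of A and B intensities}
#'   }
#' @export
read_signals <- function(path) {
  tab <- .read_tsv(path)
  hdr <- names(tab)
  if (length(hdr) < 5L || !identical(hdr[1:3], c("probe_id", "chrom", "pos"))) {
    stop("malformed signals header in '", path,
         "': expected 'probe_id chrom pos <sample>.A <sample>.B ...', got: ",
         paste(utils::head(hdr, 5), collapse = " "))
  }
  sig_cols <- hdr[-(1:3)]
  suffix <- sub("^.*\\.", "", sig_cols)
  base <- sub("\\.[AB]$", "", sig_cols)
  n <- length(sig_cols)
  if (n %% 2L != 0L ||
      !all(suffix[seq(1, n, by = 2)] == "A") ||
      !all(suffix[seq(2, n, by = 2)] == "B") ||
      !all(base[seq(1, n, by = 2)] == base[seq(2, n, by = 2)])) {
    stop("malformed signals header in '", path,
         "': sample columns must come in <sample>.A <sample>.B pairs")
  }
  samples <- base[seq(1, n, by = 2)]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in signals header: ",
         samples[duplicated(samples)][1])
  }
  if (anyDuplicated(tab$probe_id)) {
    dup <- tab$probe_id[duplicated(tab$probe_id)][1]
    stop("duplicate probe '", dup, "' in '", path, "' (line ",
         which(tab$probe_id == dup)[2] + 1L, ")")
  }
  pos <- .parse_numeric_col(tab$pos, "pos", path)
  vals <- lapply(sig_cols, function(cn) .parse_numeric_col(tab[[cn]], cn, path))
  names(vals) <- sig_cols
  ord <- order(tab$chrom, pos)
  snps <- data.frame(probe_id = tab$probe_id[ord], chrom = tab$chrom[ord],
                     pos = as.integer(pos[ord]), stringsAsFactors = FALSE)
  a <- do.call(cbind, vals[seq(1, n, by = 2)])[ord, , drop = FALSE]
  b <- do.call(cbind, vals[seq(2, n, by = 2)])[ord, , drop = FALSE]
  dimnames(a) <- dimnames(b) <- list(snps$probe_id, samples)
  structure(list(snps = snps, samples = samples, a = a, b = b),
            class = "haplocn_signals")
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "",
                           stringsAsFactors = FALSE)
  tab
}

.parse_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | !is.finite(out))
  if (length(bad)) {
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "' of '", path, "' (line ", bad[1] + 1L, ")")
  }
  out
}

#' Read rough initial genotype calls
#'
#' Tab-delimited file with header \code{probe_id <sample> ...} and calls in
#' \{AA, AB, BB, NC\}. Calls are coded 1 = AA, 2 = AB, 3 = BB, 0 = no-call.
#'
#' @param path path to the genotypes TSV.
#' @return Integer matrix (SNPs x samples) of codes in \{0, 1, 2, 3\} with
#'   probe ids as rownames.
#' @export
read_genotypes <- function(path) {
  tab <- .read_tsv(path)
  if (names(tab)[1] != "probe_id") {
    stop("malformed genotypes header in '", path, "': first column must be probe_id")
  }
  samples <- names(tab)[-1]
  code_of <- c(AA = 1L, AB = 2L, BB = 3L, NC = 0L)
  g <- vapply(tab[-1], function(col) {
    codes <- code_of[col]
    if (anyNA(codes)) {
      stop("unknown genotype token '", col[is.na(codes)][1], "' in '", path,
           "' (expected AA, AB, BB or NC)")
    }
    codes
  }, integer(nrow(tab)))
  g <- matrix(g, nrow = nrow(tab), dimnames = list(tab$probe_id, samples))
  g
}

#' Read per-SNP seed cluster parameters
#'
#' One row per SNP, and for each of the AA, AB, BB genotype clusters five
#' numbers: mean A signal, mean B signal, variance of A, covariance of A and
#' B, variance of B (columns \code{<g>.muA <g>.muB <g>.vA <g>.cAB <g>.vB}).
#'
#' @param path path to the seeds TSV.
#' @return Object of class \code{haplocn_seeds}: list with \code{probe_id}
#'   and, for each genotype, \code{mu} (SNPs x 2) and \code{sigma}
#'   (SNPs x 2 x 2) arrays, wrapped as \code{seeds$AA$mu} etc.
#' @export
read_seed_clusters <- function(path) {
  tab <- .read_tsv(path)
  out <- list(probe_id = tab$probe_id)
  for (g in c("AA", "AB", "BB")) {
    cols <- paste0(g, c(".muA", ".muB", ".vA", ".cAB", ".vB"))
    miss <- setdiff(cols, names(tab))
    if (length(miss)) stop("seeds file '", path, "' missing column(s): ",
                           paste(miss, collapse = ", "))
    v <- lapply(cols, function(cn) .parse_numeric_col(tab[[cn]], cn, path))
    n <- nrow(tab)
    sigma <- array(0, dim = c(n, 2, 2))
    sigma[, 1, 1] <- v[[3]]; sigma[, 1, 2] <- v[[4]]
    sigma[, 2, 1] <- v[[4]]; sigma[, 2, 2] <- v[[5]]
    out[[g]] <- list(mu = cbind(A = v[[1]], B = v[[2]]), sigma = sigma)
  }
  structure(out, class = "haplocn_seeds")
}

#' Impute missing genotype calls by Mahalanobis distance
#'
#' Every no-call (code 0) is replaced by the genotype among AA, AB, BB whose
#' seed cluster has the smallest Mahalanobis distance to the observed
#' \code{(sA, sB)} pair. Distance ties resolve to the lowest genotype code so
#' output is deterministic.
#'
#' @param signals \code{haplocn_signals} object.
#' @param genos integer genotype matrix from [read_genotypes()], aligned to
#'   \code{signals$snps} rows.
#' @param seeds \code{haplocn_seeds} object aligned to the same SNPs.
#' @return Genotype matrix with no code-0 entries.
#' @export
impute_missing_genotypes <- function(signals, genos, seeds) {
  stopifnot(nrow(genos) == nrow(signals$snps))
  miss <- which(genos == 0L, arr.ind = TRUE)
  if (nrow(miss) == 0L) return(genos)
  for (k in seq_len(nrow(miss))) {
    i <- miss[k, 1]; j <- miss[k, 2]
    s <- c(signals$a[i, j], signals$b[i, j])
    d <- vapply(c("AA", "AB", "BB"), function(g) {
      mu <- seeds[[g]]$mu[i, ]
      sg <- seeds[[g]]$sigma[i, , ]
      det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2]^2
      if (!is.finite(det_s) || det_s <= 0) {
        stop("singular seed covariance for genotype ", g, " at SNP '",
             signals$snps$probe_id[i], "'")
      }
      dx <- s[1] - mu[1]; dy <- s[2] - mu[2]
      sqrt((dx^2 * sg[2, 2] - 2 * dx * dy * sg[1, 2] + dy^2 * sg[1, 1]) / det_s)
    }, numeric(1))
    genos[i, j] <- which.min(d)  # which.min takes the first (lowest code) on ties
  }
  genos
}

#' Write per-SNP calls and CNV region tables
#'
#' Writes (a) a per-SNP TSV of phased allelic-state pairs and fractional
#' allele copy numbers and (b) a BED-like region TSV with one row per CNV
#' region (1-based inclusive positions of the first and last member SNP).
#'
#' @param calls data.frame with columns \code{sample, probe_id, chrom, pos,
#'   h1, h2, cn_a, cn_b} (as produced by [run_pipeline()]).
#' @param regions data.frame of CNV regions with columns \code{sample, chrom,
#'   start_pos, end_pos, start_idx, end_idx, direction, hap1_cn, hap2_cn,
#'   total_cn, n_snps} (extra columns are carried through).
#' @param calls_path,regions_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_calls <- function(calls, regions, calls_path, regions_path) {
  utils::write.table(calls, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reg_cols <- c("sample", "chrom", "start_pos", "end_pos", "start_idx",
                "end_idx", "direction", "hap1_cn", "hap2_cn", "total_cn",
                "n_snps")
  if (nrow(regions) == 0L) {
    regions <- as.data.frame(setNames(rep(list(logical(0)), length(reg_cols)),
                                      reg_cols))
  } else {
    extra <- setdiff(names(regions), reg_cols)
    regions <- regions[, c(reg_cols, extra), drop = FALSE]
  }
  utils::write.table(regions, regions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(calls_path, regions_path))
}

#' Read back a per-SNP calls table written by [write_calls()]
#'
#' @param path path to the calls TSV.
#' @return data.frame with the same columns written by [write_calls()].
#' @export
read_calls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "",
                    quote = "", stringsAsFactors = FALSE)
}
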