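#' Pipeline configuration
#'
#' @param D_norm,D_var,p_aberrant see [decay_params()].
#' @param shaded_quantile chi-square quantile of the shaded region.
#' @param global_iters number of global iterations (tree + decode passes);
#'   the default 2 is one refinement pass after initialisation.
#' @param restrict restrict Viterbi candidates to the nearest-Mahalanobis
#'   model's member states.
#' @return Config list.
#' @export
pipeline_config <- function(D_norm = 1e8, D_var = 1e5, p_aberrant = 0.01,
                            shaded_quantile = 0.99, global_iters = 2L,
                            restrict = TRUE) {
  list(decay = decay_params(D_norm, D_var, p_aberrant),
       shaded_quantile = shaded_quantile,
       global_iters = as.integer(global_iters), restrict = restrict)
}

# initial conditional tables from imputed genotypes (EM per adjacent pair);
# conditionals are floored so no haplotype transition is strictly
# impossible before any phase has been observed
.tables_from_genotypes <- function(genos, floor = 1e-4) {
  L <- nrow(genos)
  lapply(seq_len(L - 1L), function(j) {
    tab <- conditional_probabilities(
      em_haplotype_proportions(count_genotype_pairs(genos, j)))
    tab$C <- pmax(tab$C, floor)
    tab$C <- tab$C / rowSums(tab$C)
    tab
  })
}

# conditional tables from phased haplotype allele letters (L x 2*n matrix);
# a half-count pseudocount per cell keeps rare haplotype transitions
# possible (a hard zero would force spurious haplotype switches in Viterbi)
.tables_from_haplotypes <- function(alleles, pseudocount = 0.5) {
  L <- nrow(alleles)
  isB_from <- alleles[-L, , drop = FALSE] == "B"
  isB_to <- alleles[-1L, , drop = FALSE] == "B"
  lapply(seq_len(L - 1L), function(j) {
    f <- isB_from[j, ]; t <- isB_to[j, ]
    J <- matrix(c(sum(!f & !t), sum(!f & t), sum(f & !t), sum(f & t)),
                2, 2, byrow = TRUE,
                dimnames = list(from = c("A", "B"), to = c("A", "B"))) +
      pseudocount
    J <- J / sum(J)
    conditional_probabilities(list(alpha = c(
      AA = J[1, 1], AB = J[1, 2], BA = J[2, 1], BB = J[2, 2])))
  })
}

#' Run the full copy-number haplotype inference pipeline
#'
#' Alternates (I) haplotype tree construction, merging and aberrant-state
#' branching with (II) per-sample Viterbi recognition, for
#' \code{config$global_iters} passes. The first pass estimates allele
#' transition probabilities by the two-locus EM on the (imputed) genotype
#' calls; later passes re-estimate them from the phased haplotypes of the
#' previous decode and refit the emission models from the decoded state
#' assignments. After the final pass, candidate regions are extracted and
#' filtered, fractional allele copy numbers are computed, and regions are
#' classified as gain (total copy number > 3), loss (< 1) or normal.
#' Chromosomes are processed independently.
#'
#' @param signals a \code{haplocn_signals}.
#' @param genos genotype matrix from [read_genotypes()] (no-calls allowed).
#' @param seeds a \code{haplocn_seeds} aligned to \code{signals$snps}.
#' @param config list from [pipeline_config()].
#' @return List of class \code{haplocn_result}:
#'   \describe{
#'     \item{calls}{per-SNP, per-sample data.frame: sample, probe_id, chrom,
#'       pos, h1, h2, cn_a, cn_b}
#'     \item{regions}{data.frame of filtered regions with positions, per
#'       haplotype mean CN, total CN and event call}
#'     \item{h1, h2}{L x n_samples matrices of phased allelic states}
#'     \item{cn_a, cn_b}{L x n_samples matrices of fractional copy numbers}
#'     \item{bank}{the final emission model bank}
#'   }
#' @export
run_pipeline <- function(signals, genos, seeds, config = pipeline_config()) {
  genos <- impute_missing_genotypes(signals, genos, seeds)
  bank <- seed_model_bank(seeds)
  snps <- signals$snps
  samples <- signals$samples
  L <- nrow(snps); ns <- length(samples)
  chroms <- unique(snps$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(snps$chrom == ch))
  names(chrom_idx) <- chroms
  smodel <- .state_model_idx()
  gs <- genotype_states()

  h1 <- h2 <- matrix(NA_character_, L, ns)
  tables <- NULL
  for (iter in seq_len(config$global_iters)) {
    emis <- cohort_emissions(bank, signals, config$shaded_quantile)
    path_idx <- matrix(NA_integer_, L, ns)
    for (ch in chroms) {
      idx <- chrom_idx[[ch]]
      tab_ch <- if (iter == 1L) {
        .tables_from_genotypes(genos[idx, , drop = FALSE])
      } else {
        nL <- length(idx)
        .tables_from_haplotypes(cbind(
          matrix(state_allele(h1[idx, , drop = FALSE]), nL),
          matrix(state_allele(h2[idx, , drop = FALSE]), nL)))
      }
      tree <- build_binary_tree(genos[idx, , drop = FALSE], tab_ch)
      hmm <- branch_aberrant(tree, snps$pos[idx], config$decay)
      plt <- .pair_log_trans(hmm)
      for (s in seq_len(ns)) {
        dec <- suppressWarnings(viterbi_decode(
          matrix(emis$logdens[idx, s, ], ncol = 11L), emis$group[idx, s],
          hmm, restrict = config$restrict, pair_ltrans = plt))
        path_idx[idx, s] <- dec$path
      }
    }
    pairs <- genotype_state_pair(gs[path_idx])
    h1 <- matrix(pairs[, 1], L, ns)
    h2 <- matrix(pairs[, 2], L, ns)
    if (iter < config$global_iters) {
      bank <- update_models(bank, matrix(smodel[path_idx], L, ns), signals)
    }
  }

  cn <- .allelic_cn_all(bank, signals)
  regions <- .collect_regions(snps, samples, chrom_idx, h1, h2, cn,
                              emis$shaded)
  calls <- data.frame(
    sample = rep(samples, each = L),
    probe_id = rep(snps$probe_id, ns), chrom = rep(snps$chrom, ns),
    pos = rep(snps$pos, ns),
    h1 = as.vector(h1), h2 = as.vector(h2),
    cn_a = as.vector(cn$cn_a), cn_b = as.vector(cn$cn_b),
    stringsAsFactors = FALSE)
  structure(list(calls = calls, regions = regions, h1 = h1, h2 = h2,
                 cn_a = cn$cn_a, cn_b = cn$cn_b, bank = bank,
                 shaded = emis$shaded, snps = snps, samples = samples),
            class = "haplocn_result")
}

.collect_regions <- function(snps, samples, chrom_idx, h1, h2, cn, shaded) {
  out <- list()
  for (s in seq_along(samples)) {
    for (ch in names(chrom_idx)) {
      idx <- chrom_idx[[ch]]
      path <- cbind(h1[idx, s], h2[idx, s])
      regs <- filter_regions(extract_regions(path), shaded[idx, s])
      if (nrow(regs) == 0L) next
      ca <- cn$cn_a[idx, s]; cb <- cn$cn_b[idx, s]
      for (r in seq_len(nrow(regs))) {
        reg <- regs[r, ]
        hap <- haplotype_cn_summary(reg, path, ca, cb)
        tot <- total_cn(reg, ca, cb)
        g <- idx[reg$start_idx]; e <- idx[reg$end_idx]
        out[[length(out) + 1L]] <- data.frame(
          sample = samples[s], chrom = ch,
          start_pos = snps$pos[g], end_pos = snps$pos[e],
          start_idx = g, end_idx = e,
          direction = reg$direction,
          hap1_cn = unname(hap[1]), hap2_cn = unname(hap[2]),
          total_cn = tot, event = call_event(tot),
          n_snps = reg$n_snps, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      start_idx = integer(0), end_idx = integer(0),
                      direction = character(0), hap1_cn = numeric(0),
                      hap2_cn = numeric(0), total_cn = numeric(0),
                      event = character(0), n_snps = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
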