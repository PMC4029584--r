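#' Simulation configuration
#'
#' Defaults describe the cohort the package is benchmarked on: 90 diploids
#' over 2000 SNPs, built by pairing haploid chromosomes (drawn from a pool
#' with block-structured linkage) that each carry a few implanted gain/loss
#' segments, with intensities emitted from well-separated genotype clusters
#' (grid spacing 0.9 intensity units vs noise SD 0.2, i.e. 4.5 SDs).
#'
#' @param n_haploids size of the haploid chromosome pool.
#' @param n_diploids number of diploid samples (random pairs of distinct
#'   haploids, sampled with replacement).
#' @param n_snps number of SNP loci.
#' @param n_founders founder haplotypes the pool mosaics are copied from.
#' @param block_mean mean LD block length in SNPs (geometric switching).
#' @param events_per_haploid CNV events implanted per haploid chromosome.
#' @param event_len inclusive range of event lengths in SNPs.
#' @param gain_frac fraction of events that are gains (rest losses).
#' @param a_centers,b_centers A-axis intensity centers for 0, 1 and 2 copies
#'   of the allele (BB/AB/AA on the A axis), and the mirror for B.
#' @param noise_sd intensity noise SD (isotropic).
#' @param center_jitter_sd per-SNP jitter SD on the cluster centers.
#' @param nocall_rate fraction of genotype calls reported as no-calls.
#' @param pos_spacing range (bp) of uniform inter-SNP spacing.
#' @param chrom chromosome label.
#' @param seed integer seed fixing all randomness.
#' @return Config list of class \code{haplocn_simconfig}.
#' @export
sim_config <- function(n_haploids = 50L, n_diploids = 90L, n_snps = 2000L,
                       n_founders = 8L, block_mean = 20,
                       events_per_haploid = 3L, event_len = c(10L, 50L),
                       gain_frac = 0.5,
                       a_centers = c(0.2, 1.1, 2.0),
                       b_centers = c(0.2, 1.1, 2.0),
                       noise_sd = 0.2, center_jitter_sd = 0.02,
                       nocall_rate = 0.01,
                       pos_spacing = c(500L, 3500L), chrom = "chr1",
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_haploids >= 2L, n_diploids >= 1L, n_snps >= 2L,
            all(event_len >= 1L), noise_sd > 0)
  structure(cfg, class = "haplocn_simconfig")
}

#' Simulate a diploid cohort with known copy-number haplotypes
#'
#' Haploid chromosomes are mosaics of founder haplotypes (geometric block
#' switching), each implanted with non-overlapping gain and loss segments.
#' Diploids pair two distinct haploids at random, emulating random mating of
#' phase-known chromosomes. Intensities are drawn from the bivariate normal
#' of the true genotype state's emission model on a per-SNP jittered center
#' grid; the rough genotype input is a naive nearest-cluster call of each
#' signal against the AA/AB/BB seeds, with a small no-call rate.
#'
#' @param cfg a [sim_config()].
#' @return List with \code{signals} (\code{haplocn_signals}), \code{genos}
#'   (genotype code matrix), \code{seeds} (\code{haplocn_seeds}) and
#'   \code{truth}: list of \code{h1}, \code{h2} (L x n state matrices),
#'   \code{cn_a}, \code{cn_b} (true integer allele copy numbers),
#'   \code{total_cn}, and \code{regions} (true aberrant segments per
#'   sample).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  L <- cfg$n_snps
  # --- haploid pool: founder mosaics ------------------------------------
  p <- stats::runif(L, 0.1, 0.9)
  founders <- matrix(ifelse(stats::runif(cfg$n_founders * L) <
                              rep(p, each = cfg$n_founders), "B", "A"),
                     nrow = cfg$n_founders, byrow = FALSE)
  founders <- t(founders)                       # L x n_founders
  alleles <- matrix(NA_character_, L, cfg$n_haploids)
  for (h in seq_len(cfg$n_haploids)) {
    f <- sample.int(cfg$n_founders, 1L)
    sw <- stats::runif(L) < 1 / cfg$block_mean
    for (j in seq_len(L)) {
      if (sw[j]) f <- sample.int(cfg$n_founders, 1L)
      alleles[j, h] <- founders[j, f]
    }
  }
  # --- implant CNV events on each haploid -------------------------------
  states <- alleles                             # normal state = allele letter
  for (h in seq_len(cfg$n_haploids)) {
    taken <- rep(FALSE, L)
    ev <- 0L; tries <- 0L
    while (ev < cfg$events_per_haploid && tries < 100L) {
      tries <- tries + 1L
      len <- sample(cfg$event_len[1]:cfg$event_len[2], 1L)
      if (len >= L) next
      st <- sample.int(L - len + 1L, 1L)
      span <- st:(st + len - 1L)
      if (any(taken[span])) next
      taken[span] <- TRUE
      dir <- if (stats::runif(1) < cfg$gain_frac) "+" else "-"
      states[span, h] <- paste0(alleles[span, h], dir)
      ev <- ev + 1L
    }
  }
  # --- diploids: pairs of distinct haploids -----------------------------
  pair1 <- sample.int(cfg$n_haploids, cfg$n_diploids, replace = TRUE)
  pair2 <- vapply(pair1, function(i) {
    repeat {
      j <- sample.int(cfg$n_haploids, 1L)
      if (j != i) return(j)
    }
  }, integer(1))
  h1 <- states[, pair1, drop = FALSE]
  h2 <- states[, pair2, drop = FALSE]
  truth <- .truth_from_states(h1, h2)
  # --- per-SNP cluster grid and signals ---------------------------------
  ax <- matrix(rep(cfg$a_centers, each = L), L) +
    matrix(stats::rnorm(3 * L, 0, cfg$center_jitter_sd), L)
  bx <- matrix(rep(cfg$b_centers, each = L), L) +
    matrix(stats::rnorm(3 * L, 0, cfg$center_jitter_sd), L)
  # columns: allele copies 0, 1, 2; the 3-copy position extrapolates the
  # grid with equal spacing, matching the M0/M10 model extension
  ax <- cbind(ax, 2 * ax[, 3] - ax[, 2])
  bx <- cbind(bx, 2 * bx[, 3] - bx[, 2])
  seeds <- .seeds_from_grid(ax, bx, cfg$noise_sd, L)
  gs <- genotype_states()
  centers <- .grid_center_lookup()
  state_idx <- matrix(match(paste(h1, h2, sep = "|"), gs), L)
  n <- cfg$n_diploids
  mu_a <- matrix(ax[cbind(rep(seq_len(L), n), centers$a[state_idx] + 1L)], L)
  mu_b <- matrix(bx[cbind(rep(seq_len(L), n), centers$b[state_idx] + 1L)], L)
  a <- mu_a + matrix(stats::rnorm(L * n, 0, cfg$noise_sd), L)
  b <- mu_b + matrix(stats::rnorm(L * n, 0, cfg$noise_sd), L)
  samples <- sprintf("S%03d", seq_len(n))
  pos <- cumsum(c(1e6L, sample(cfg$pos_spacing[1]:cfg$pos_spacing[2],
                               L - 1L, replace = TRUE)))
  snps <- data.frame(probe_id = sprintf("rs%06d", seq_len(L)),
                     chrom = cfg$chrom, pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  dimnames(a) <- dimnames(b) <- list(snps$probe_id, samples)
  signals <- structure(list(snps = snps, samples = samples, a = a, b = b),
                       class = "haplocn_signals")
  # --- naive genotype calls ---------------------------------------------
  genos <- .naive_calls(signals, seeds)
  nc <- which(stats::runif(L * n) < cfg$nocall_rate)
  genos[nc] <- 0L
  truth$sample <- samples
  list(signals = signals, genos = genos, seeds = seeds, truth = truth,
       config = cfg)
}

# grid column (allele copies 0..3) of each genotype state's emission model
# center; >2-copy states sit on the extrapolated M0/M10 grid positions
.grid_center_lookup <- function() {
  m <- match(genotype_state_model(genotype_states()), model_ids())
  a_col <- c(3L, 2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  b_col <- c(0L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 3L)
  list(a = a_col[m], b = b_col[m])
}

.seeds_from_grid <- function(ax, bx, noise_sd, L) {
  sig <- array(0, dim = c(L, 2, 2))
  sig[, 1, 1] <- noise_sd^2; sig[, 2, 2] <- noise_sd^2
  out <- list(probe_id = sprintf("rs%06d", seq_len(L)),
              AA = list(mu = cbind(A = ax[, 3], B = bx[, 1]), sigma = sig),
              AB = list(mu = cbind(A = ax[, 2], B = bx[, 2]), sigma = sig),
              BB = list(mu = cbind(A = ax[, 1], B = bx[, 3]), sigma = sig))
  structure(out[c("probe_id", "AA", "AB", "BB")], class = "haplocn_seeds")
}

.naive_calls <- function(signals, seeds) {
  L <- nrow(signals$a); n <- ncol(signals$a)
  d <- array(NA_real_, c(L, n, 3))
  for (k in 1:3) {
    g <- c("AA", "AB", "BB")[k]
    mu <- seeds[[g]]$mu
    d[, , k] <- (signals$a - mu[, 1])^2 + (signals$b - mu[, 2])^2
  }
  calls <- apply(d, c(1, 2), which.min)
  matrix(as.integer(calls), L, n, dimnames = dimnames(signals$a))
}

.truth_from_states <- function(h1, h2) {
  L <- nrow(h1); n <- ncol(h1)
  c1 <- matrix(state_copies(h1), L); c2 <- matrix(state_copies(h2), L)
  a1 <- matrix(state_allele(h1), L); a2 <- matrix(state_allele(h2), L)
  cn_a <- c1 * (a1 == "A") + c2 * (a2 == "A")
  cn_b <- c1 * (a1 == "B") + c2 * (a2 == "B")
  regions <- list()
  for (s in seq_len(n)) {
    regs <- extract_regions(cbind(h1[, s], h2[, s]))
    if (nrow(regs)) {
      regs$sample_idx <- s
      regions[[length(regions) + 1L]] <- regs
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(start_idx = integer(0), end_idx = integer(0),
               direction = character(0), n_snps = integer(0),
               sample_idx = integer(0))
  list(h1 = h1, h2 = h2, cn_a = cn_a, cn_b = cn_b,
       total_cn = cn_a + cn_b, regions = regions)
}

#' Write a simulated cohort to tab-delimited files
#'
#' Writes \code{signals.tsv}, \code{genotypes.tsv} and \code{seeds.tsv} in
#' the formats read by [read_signals()], [read_genotypes()] and
#' [read_seed_clusters()], plus \code{truth_states.tsv} (per SNP and sample:
#' the two true haplotype states and integer allele copy numbers) and
#' \code{truth_regions.tsv}.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- sim$signals
  n <- length(sig$samples)
  sig_tab <- data.frame(sig$snps, check.names = FALSE)
  for (s in seq_len(n)) {
    sig_tab[[paste0(sig$samples[s], ".A")]] <- sig$a[, s]
    sig_tab[[paste0(sig$samples[s], ".B")]] <- sig$b[, s]
  }
  utils::write.table(sig_tab, file.path(dir, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  geno_tab <- data.frame(probe_id = sig$snps$probe_id, check.names = FALSE)
  codes <- c("NC", "AA", "AB", "BB")
  for (s in seq_len(n)) {
    geno_tab[[sig$samples[s]]] <- codes[sim$genos[, s] + 1L]
  }
  utils::write.table(geno_tab, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seed_tab <- data.frame(probe_id = sim$seeds$probe_id)
  for (g in c("AA", "AB", "BB")) {
    seed_tab[[paste0(g, ".muA")]] <- sim$seeds[[g]]$mu[, 1]
    seed_tab[[paste0(g, ".muB")]] <- sim$seeds[[g]]$mu[, 2]
    seed_tab[[paste0(g, ".vA")]] <- sim$seeds[[g]]$sigma[, 1, 1]
    seed_tab[[paste0(g, ".cAB")]] <- sim$seeds[[g]]$sigma[, 1, 2]
    seed_tab[[paste0(g, ".vB")]] <- sim$seeds[[g]]$sigma[, 2, 2]
  }
  utils::write.table(seed_tab, file.path(dir, "seeds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  L <- nrow(sig$snps)
  states_tab <- data.frame(
    sample = rep(sig$samples, each = L),
    probe_id = rep(sig$snps$probe_id, n),
    h1 = as.vector(sim$truth$h1), h2 = as.vector(sim$truth$h2),
    cn_a = as.vector(sim$truth$cn_a), cn_b = as.vector(sim$truth$cn_b))
  utils::write.table(states_tab, file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- sim$truth$regions
  reg$sample <- sig$samples[reg$sample_idx]
  utils::write.table(reg, file.path(dir, "truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Round a fractional copy number to its integer state
#'
#' Nearest integer, with half-points resolved by the reporting convention
#' that anything between 0.5 and 1.5 is one copy: 0.5 -> 1, 1.5 -> 1,
#' 2.5 -> 2. Negative values round to 0.
#'
#' @param x numeric vector of fractional copy numbers.
#' @return Integer vector.
#' @export
round_cn <- function(x) {
  r <- as.integer(pmax(0, ceiling(x - 0.5)))
  r[!is.na(x) & x == 0.5] <- 1L
  r
}

#' Build the four-level accuracy report from counts
#'
#' @param num,den named integer vectors (Rregion, Rtotal, Rspecific, Rhap)
#'   of numerators and denominators.
#' @return data.frame with ratio (in percent), numerator and denominator per
#'   level.
#' @export
eval_report <- function(num, den) {
  lv <- c("Rregion", "Rtotal", "Rspecific", "Rhap")
  data.frame(level = lv,
             ratio = ifelse(den[lv] > 0, 100 * num[lv] / den[lv], NA_real_),
             num = as.integer(num[lv]), den = as.integer(den[lv]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate pipeline calls against simulation truth
#'
#' Four nested accuracy levels:
#' \describe{
#'   \item{Rregion}{fraction of predicted CNV regions (event gain or loss)
#'     overlapping a true aberrant segment of the same sample by at least
#'     one SNP}
#'   \item{Rtotal}{among overlapping regions, fraction whose rounded mean
#'     total copy number matches the rounded true mean over the same SNPs}
#'   \item{Rspecific}{among SNPs inside correct-total regions, fraction with
#'     both rounded allele copy numbers correct}
#'   \item{Rhap}{among correct-allele SNPs, fraction with the correct phase,
#'     haplotype labels matched by the better of the two global assignments
#'     per region}
#' }
#'
#' @param result a \code{haplocn_result} from [run_pipeline()].
#' @param truth the \code{truth} element of [simulate_cohort()].
#' @return data.frame from [eval_report()].
#' @export
evaluate_calls <- function(result, truth) {
  regions <- result$regions[result$regions$event != "normal", , drop = FALSE]
  num <- c(Rregion = 0L, Rtotal = 0L, Rspecific = 0L, Rhap = 0L)
  den <- c(Rregion = nrow(regions), Rtotal = 0L, Rspecific = 0L, Rhap = 0L)
  sample_idx <- match(regions$sample, result$samples)
  for (r in seq_len(nrow(regions))) {
    s <- sample_idx[r]
    span <- regions$start_idx[r]:regions$end_idx[r]
    tr <- truth$regions[truth$regions$sample_idx == s, , drop = FALSE]
    overlaps <- any(tr$start_idx <= max(span) & tr$end_idx >= min(span))
    if (!overlaps) next
    num["Rregion"] <- num["Rregion"] + 1L
    den["Rtotal"] <- den["Rtotal"] + 1L
    pred_tot <- round_cn(regions$total_cn[r])
    true_tot <- round_cn(mean(truth$total_cn[span, s]))
    if (is.na(pred_tot) || pred_tot != true_tot) next
    num["Rtotal"] <- num["Rtotal"] + 1L
    ca <- round_cn(result$cn_a[span, s]); cb <- round_cn(result$cn_b[span, s])
    ok_allele <- !is.na(ca) & !is.na(cb) &
      ca == truth$cn_a[span, s] & cb == truth$cn_b[span, s]
    den["Rspecific"] <- den["Rspecific"] + length(span)
    num["Rspecific"] <- num["Rspecific"] + sum(ok_allele)
    if (!any(ok_allele)) next
    sub <- span[ok_allele]
    ph <- vapply(list(c(1L, 2L), c(2L, 1L)), function(perm) {
      th <- cbind(truth$h1[, s], truth$h2[, s])[, perm, drop = FALSE]
      sum(result$h1[sub, s] == th[sub, 1] & result$h2[sub, s] == th[sub, 2])
    }, integer(1))
    den["Rhap"] <- den["Rhap"] + length(sub)
    num["Rhap"] <- num["Rhap"] + max(ph)
  }
  eval_report(num, den)
}
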