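# Hand-built tree fixture: nodes at given levels with explicit branch
# probabilities, for exercising the merge machinery on known values.
make_tree <- function(levels, edges, total) {
  structure(list(n_loci = length(levels), total = total,
                 levels = levels, edges = edges),
            class = "haplocn_tree")
}

# Two same-label nodes (ids 1, 2) at locus 1 with branch conditionals c1/c2
# to shared A/B children at locus 2; counts M1/M2.
two_node_tree <- function(c1, c2, M1 = 100, M2 = 100) {
  lev1 <- data.frame(id = 1:2, label = c("A", "A"), M = c(M1, M2))
  lev2 <- data.frame(id = 1:2, label = c("A", "B"),
                     M = c(M1 * c1[1] + M2 * c2[1], M1 * c1[2] + M2 * c2[2]))
  e1 <- data.frame(from = 0L, to = 1:2, C = c(0.5, 0.5), J = c(0.5, 0.5))
  e2 <- data.frame(from = c(1L, 1L, 2L, 2L), to = c(1L, 2L, 1L, 2L),
                   C = c(c1, c2),
                   J = c(M1 * c1, M2 * c2) / (M1 + M2))
  make_tree(list(lev1, lev2), list(e1, e2), M1 + M2)
}

# A uniform model bank over n SNPs from an equal-increment grid: BB/AB/AA
# centers at (0,2)/(1,1)/(2,0) scaled by `spacing`, isotropic noise.
toy_bank <- function(n_snps = 1L, spacing = 1, noise_sd = 0.1) {
  L <- n_snps
  sig <- array(0, dim = c(L, 2, 2))
  sig[, 1, 1] <- noise_sd^2; sig[, 2, 2] <- noise_sd^2
  grid <- spacing * c(0, 1, 2)
  seeds <- structure(list(
    probe_id = sprintf("rs%03d", seq_len(L)),
    AA = list(mu = cbind(A = rep(grid[3], L), B = rep(grid[1], L)), sigma = sig),
    AB = list(mu = cbind(A = rep(grid[2], L), B = rep(grid[2], L)), sigma = sig),
    BB = list(mu = cbind(A = rep(grid[1], L), B = rep(grid[3], L)), sigma = sig)),
    class = "haplocn_seeds")
  seed_model_bank(seeds)
}

toy_seeds <- function(n_snps = 1L, spacing = 1, noise_sd = 0.1) {
  L <- n_snps
  sig <- array(0, dim = c(L, 2, 2))
  sig[, 1, 1] <- noise_sd^2; sig[, 2, 2] <- noise_sd^2
  grid <- spacing * c(0, 1, 2)
  structure(list(
    probe_id = sprintf("rs%03d", seq_len(L)),
    AA = list(mu = cbind(A = rep(grid[3], L), B = rep(grid[1], L)), sigma = sig),
    AB = list(mu = cbind(A = rep(grid[2], L), B = rep(grid[2], L)), sigma = sig),
    BB = list(mu = cbind(A = rep(grid[1], L), B = rep(grid[3], L)), sigma = sig)),
    class = "haplocn_seeds")
}

# small signals object built directly (bypasses file IO)
make_signals <- function(a, b, chrom = "chr1", pos = NULL) {
  L <- nrow(a)
  samples <- colnames(a)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(a)))
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  snps <- data.frame(probe_id = sprintf("rs%03d", seq_len(L)),
                     chrom = chrom, pos = as.integer(pos),
                     stringsAsFactors = FALSE)
  dimnames(a) <- dimnames(b) <- list(snps$probe_id, samples)
  structure(list(snps = snps, samples = samples, a = a, b = b),
            class = "haplocn_signals")
}

# uniform six-state HMM over L loci with given binary transition table
make_hmm <- function(L, C_bin = matrix(0.5, 2, 2,
                                       dimnames = list(c("A", "B"),
                                                       c("A", "B"))),
                     d = 2000, params = decay_params()) {
  T6 <- expand_transitions(C_bin, d, params)
  st <- allelic_states()
  pab <- params$p_aberrant
  init <- setNames(rep(c(pab / 2, (1 - pab), pab / 2) * 0.5, 2), st)
  structure(list(states = st, init = init,
                 trans = rep(list(T6), L - 1)), class = "haplocn_hmm")
}

# brute-force best path over all |S|^L state sequences (independent oracle)
exhaustive_best_path <- function(logdens, hmm) {
  linit <- haplocn:::.pair_log_init(hmm)
  ltr <- haplocn:::.pair_log_trans(hmm)
  smodel <- haplocn:::.state_model_idx()
  L <- nrow(logdens)
  paths <- as.matrix(expand.grid(rep(list(1:36), L)))
  score <- linit[paths[, 1]] + logdens[cbind(1L, smodel[paths[, 1]])]
  for (t in 2:L) {
    score <- score + ltr[[t - 1]][cbind(paths[, t - 1], paths[, t])] +
      logdens[cbind(t, smodel[paths[, t]])]
  }
  k <- which.max(score)
  list(path = unname(paths[k, ]), log_score = unname(score[k]))
}
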