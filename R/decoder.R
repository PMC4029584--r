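# Index helpers for the 36 ordered genotype states: state k pairs haplotype
# states i1 = (k-1) %/% 6 + 1 (haplotype 1) and i2 = (k-1) %% 6 + 1.
.pair_index <- function() {
  k <- seq_len(36L)
  list(i1 = (k - 1L) %/% 6L + 1L, i2 = (k - 1L) %% 6L + 1L)
}

# 36 x 36 log transition matrices, one per adjacent locus pair: the two
# haplotypes transit independently on the same tree
.pair_log_trans <- function(hmm) {
  ix <- .pair_index()
  lapply(hmm$trans, function(T6) {
    lT <- log(T6)
    lT[ix$i1, ix$i1] + lT[ix$i2, ix$i2]
  })
}

.pair_log_init <- function(hmm) {
  ix <- .pair_index()
  li <- log(hmm$init)
  li[ix$i1] + li[ix$i2]
}

# emission model index (1..11) of each of the 36 genotype states
.state_model_idx <- function() {
  match(genotype_state_model(genotype_states()), model_ids())
}

#' Viterbi decoding of one sample's two-haplotype state path
#'
#' Finds the maximum-log-probability sequence of ordered genotype states
#' (pairs of allelic states) for one sample. The transition probability of a
#' pair state is the product of the two haplotypes' independent tree
#' transitions; the emission is the bivariate normal of the state's model.
#' With \code{restrict = TRUE} the candidate states at each locus are only
#' the member states of the model closest (Mahalanobis) to the observed
#' signal, which is the recommended fast mode; if the restriction leaves a
#' locus unreachable the candidate set is expanded to all 36 states there.
#'
#' @param logdens L x 11 matrix of per-model emission log-densities for this
#'   sample (rows = loci).
#' @param group integer vector (length L) of selected model indices.
#' @param hmm a \code{haplocn_hmm} from [branch_aberrant()].
#' @param restrict restrict candidate states to the selected group.
#' @param pair_ltrans optional precomputed list from the internal pair-log
#'   transition builder (shared across samples for speed).
#' @return List with \code{path} (integer vector of state indices into
#'   [genotype_states()]), \code{states} (L x 2 character matrix of the two
#'   haplotypes' allelic states), \code{log_score} and \code{expanded}
#'   (loci where the fallback expansion fired).
#' @export
viterbi_decode <- function(logdens, group, hmm, restrict = TRUE,
                           pair_ltrans = NULL) {
  L <- nrow(logdens)
  stopifnot(length(group) == L, length(hmm$trans) == L - 1L)
  if (is.null(pair_ltrans)) pair_ltrans <- .pair_log_trans(hmm)
  linit <- .pair_log_init(hmm)
  smodel <- .state_model_idx()
  members <- lapply(seq_len(11L), function(m) which(smodel == m))
  cand_of <- function(t) if (restrict) members[[group[t]]] else seq_len(36L)

  cands <- vector("list", L)
  psi <- vector("list", L)
  expanded <- integer(0)

  cand <- cand_of(1L)
  delta <- linit[cand] + logdens[1L, smodel[cand]]
  if (all(!is.finite(delta))) {
    cand <- seq_len(36L)
    delta <- linit + logdens[1L, smodel]
    expanded <- c(expanded, 1L)
  }
  cands[[1L]] <- cand
  for (t in seq_len(L - 1L) + 1L) {
    cand_new <- cand_of(t)
    tmp <- delta + pair_ltrans[[t - 1L]][cand, cand_new, drop = FALSE]
    best_prev <- max.col(t(tmp), ties.method = "first")
    val <- tmp[cbind(best_prev, seq_along(cand_new))]
    if (all(!is.finite(val))) {
      expanded <- c(expanded, t)
      cand_new <- seq_len(36L)
      tmp <- delta + pair_ltrans[[t - 1L]][cand, , drop = FALSE]
      best_prev <- max.col(t(tmp), ties.method = "first")
      val <- tmp[cbind(best_prev, seq_len(36L))]
    }
    delta <- val + logdens[t, smodel[cand_new]]
    cands[[t]] <- cand_new
    psi[[t]] <- best_prev
    cand <- cand_new
  }
  if (length(expanded)) {
    warning("candidate restriction left ", length(expanded),
            " locus/loci unreachable; expanded to all 36 states there")
  }
  path <- integer(L)
  k <- which.max(delta)
  score <- delta[k]
  path[L] <- cands[[L]][k]
  if (L > 1L) {
    for (t in L:2L) {
      k <- psi[[t]][k]
      path[t - 1L] <- cands[[t - 1L]][k]
    }
  }
  gs <- genotype_states()
  states <- genotype_state_pair(gs[path])
  list(path = path, states = states, log_score = unname(score),
       expanded = expanded)
}
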