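#' Tabulate genotype pairs at two consecutive loci
#'
#' Counts the nine genotype combinations between locus \code{j} and locus
#' \code{j + 1} over the cohort. Genotypes are coded 1 = AA, 2 = AB, 3 = BB.
#'
#' @param genos integer genotype matrix (SNPs x samples), fully imputed
#'   (no zeros).
#' @param j locus index (pairs locus \code{j} with \code{j + 1}).
#' @return 3 x 3 integer matrix \code{N} with \code{N[g, h]} the number of
#'   samples carrying genotype \code{g} at locus \code{j} and \code{h} at
#'   locus \code{j + 1}.
#' @export
count_genotype_pairs <- function(genos, j) {
  if (j < 1L || j + 1L > nrow(genos)) stop("locus index out of range: ", j)
  g <- genos[j, ]; h <- genos[j + 1L, ]
  if (any(g == 0L | h == 0L)) stop("genotype matrix contains no-calls; impute first")
  N <- matrix(0L, 3, 3, dimnames = list(j = 1:3, j1 = 1:3))
  for (k in seq_along(g)) N[g[k], h[k]] <- N[g[k], h[k]] + 1L
  N
}

#' Estimate two-locus haplotype proportions by EM
#'
#' Of the nine genotype combinations only the double heterozygote
#' (AB at both loci) is phase-ambiguous: it resolves either as haplotypes
#' A-A / B-B or as A-B / B-A. Writing \code{q} for the probability of the
#' first resolution, the expected haplotype counts are
#' \preformatted{
#'   n(A-A) = 2 N[1,1] + N[1,2] + N[2,1] + q     N[2,2]
#'   n(A-B) = 2 N[1,3] + N[1,2] + N[2,3] + (1-q) N[2,2]
#'   n(B-A) = 2 N[3,1] + N[2,1] + N[3,2] + (1-q) N[2,2]
#'   n(B-B) = 2 N[3,3] + N[2,3] + N[3,2] + q     N[2,2]
#' }
#' each divided by 2N to give the proportions alpha, and q is re-estimated
#' as \code{a_AA a_BB / (a_AA a_BB + a_AB a_BA)}. Iteration starts at
#' \code{q = 0.5} and stops when the change in \code{q} drops below
#' \code{tol}.
#'
#' @param counts 3 x 3 count matrix from [count_genotype_pairs()].
#' @param tol convergence tolerance on \code{q} (default \code{1e-5}).
#' @param max_iter maximum EM iterations (default 1000).
#' @return List with \code{alpha} (named numeric: AA, AB, BA, BB summing to
#'   1), \code{q}, and \code{iterations}.
#' @export
em_haplotype_proportions <- function(counts, tol = 1e-5, max_iter = 1000L) {
  N <- sum(counts)
  if (N < 1L) stop("need at least one sample")
  q <- 0.5
  alpha <- .alpha_from_q(counts, q)
  for (it in seq_len(max_iter)) {
    num <- alpha["AA"] * alpha["BB"]
    den <- num + alpha["AB"] * alpha["BA"]
    q_new <- if (den > 0) unname(num / den) else q
    alpha <- .alpha_from_q(counts, q_new)
    if (abs(q_new - q) < tol) {
      return(list(alpha = alpha, q = q_new, iterations = it))
    }
    q <- q_new
  }
  err <- simpleError(paste0("haplotype-proportion EM did not converge in ",
                            max_iter, " iterations"))
  err$alpha <- alpha; err$q <- q
  stop(err)
}

.alpha_from_q <- function(N, q) {
  n <- c(
    AA = 2 * N[1, 1] + N[1, 2] + N[2, 1] + q * N[2, 2],
    AB = 2 * N[1, 3] + N[1, 2] + N[2, 3] + (1 - q) * N[2, 2],
    BA = 2 * N[3, 1] + N[2, 1] + N[3, 2] + (1 - q) * N[2, 2],
    BB = 2 * N[3, 3] + N[2, 3] + N[3, 2] + q * N[2, 2]
  )
  n / (2 * sum(N))
}

#' Observed-data log-likelihood of two-locus genotype counts
#'
#' Multinomial log-likelihood of the nine genotype-pair counts under random
#' union of haplotypes with proportions \code{alpha}. Used to check EM
#' monotonicity and as an independent oracle for the EM estimate.
#'
#' @param counts 3 x 3 count matrix.
#' @param alpha named haplotype proportions (AA, AB, BA, BB).
#' @return Log-likelihood (base e).
#' @export
pair_loglik <- function(counts, alpha) {
  a <- alpha
  P <- matrix(0, 3, 3)
  P[1, 1] <- a["AA"]^2;            P[1, 2] <- 2 * a["AA"] * a["AB"]
  P[1, 3] <- a["AB"]^2;            P[2, 1] <- 2 * a["AA"] * a["BA"]
  P[2, 2] <- 2 * a["AA"] * a["BB"] + 2 * a["AB"] * a["BA"]
  P[2, 3] <- 2 * a["AB"] * a["BB"]; P[3, 1] <- a["BA"]^2
  P[3, 2] <- 2 * a["BA"] * a["BB"]; P[3, 3] <- a["BB"]^2
  keep <- counts > 0
  sum(counts[keep] * log(P[keep]))
}

#' Conditional allele-transition probabilities from haplotype proportions
#'
#' The haplotype proportions are joint probabilities of the alleles at two
#' consecutive loci; conditioning on the first-locus allele gives the
#' transition probabilities used on tree branches:
#' \code{C[x -> y] = alpha_xy / (alpha_xA + alpha_xB)}. A row with zero
#' marginal is set to (0.5, 0.5) and flagged so the chain stays stochastic.
#'
#' @param props result of [em_haplotype_proportions()], or any list with an
#'   \code{alpha} element.
#' @return List with \code{C} (2 x 2 matrix, rows = from allele A/B, cols =
#'   to allele), \code{J} (2 x 2 joint matrix) and \code{flagged} (logical
#'   per row).
#' @export
conditional_probabilities <- function(props) {
  a <- props$alpha
  J <- matrix(a[c("AA", "AB", "BA", "BB")], 2, 2, byrow = TRUE,
              dimnames = list(from = c("A", "B"), to = c("A", "B")))
  marg <- rowSums(J)
  C <- J
  flagged <- marg == 0
  for (r in 1:2) {
    C[r, ] <- if (flagged[r]) c(0.5, 0.5) else J[r, ] / marg[r]
  }
  list(C = C, J = J, flagged = flagged)
}
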