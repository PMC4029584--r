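#' Decay parameters for aberrant-state transitions
#'
#' Persistence of a copy-number state between neighbouring SNPs decays
#' exponentially with their distance in nucleotides. Normal sequence
#' stretches are much longer than aberrant ones, so the normal state decays
#' on a 1e8 bp scale and the variant (gain/loss) states on a 1e5 bp scale.
#'
#' @param D_norm decay constant (bp) for the normal states; default 1e8.
#' @param D_var decay constant (bp) for gain/loss states; default 1e5.
#' @param p_aberrant prior probability that a haplotype starts a chromosome
#'   in an aberrant state (split equally between gain and loss); default
#'   0.01. The first locus has no inter-SNP distance so the exponential rule
#'   does not apply there.
#' @return List of class \code{haplocn_decay}.
#' @export
decay_params <- function(D_norm = 1e8, D_var = 1e5, p_aberrant = 0.01) {
  stopifnot(D_norm > 0, D_var > 0, p_aberrant >= 0, p_aberrant < 1)
  structure(list(D_norm = D_norm, D_var = D_var, p_aberrant = p_aberrant),
            class = "haplocn_decay")
}

#' Exponential distance decay
#'
#' Probability that a copy-number condition persists across two loci
#' separated by \code{d} nucleotides: \code{exp(-d / D)}. The complement
#' \code{1 - decay(d, D)} is the rate of change.
#'
#' @param d distance in base pairs (>= 0).
#' @param D decay constant in base pairs.
#' @return Persistence probability in (0, 1].
#' @export
decay <- function(d, D) {
  stopifnot(all(d >= 0), D > 0)
  exp(-d / D)
}

#' Build the binary (A/B) haplotype tree for one chromosome
#'
#' Level \code{j} of the tree holds nodes for the alleles at locus \code{j};
#' each branch carries the conditional probability \code{C} of moving to the
#' child allele and the joint probability \code{J} of the two-locus
#' haplotype. Node counts \code{M} are expected haplotype counts
#' (\code{2N} times the path probability). Histories with identical futures
#' are represented once (level-wise merged), so a first-order chain has two
#' nodes per level; [merge_level()] is applied at every level as the tree
#' grows.
#'
#' @param genos imputed genotype matrix (SNPs x samples) for one chromosome.
#' @param tables list of length \code{nrow(genos) - 1} of conditional tables
#'   from [conditional_probabilities()].
#' @return Object of class \code{haplocn_tree}: list with \code{n_loci},
#'   \code{total} (2N), \code{levels} (per-locus data.frame: id, label, M)
#'   and \code{edges} (per-locus data.frame: from, to, C, J; level 1 edges
#'   come from the root, id 0).
#' @export
build_binary_tree <- function(genos, tables) {
  L <- nrow(genos); N <- ncol(genos)
  stopifnot(L >= 1L, length(tables) == L - 1L)
  total <- 2 * N
  # allele-A dose per genotype code: AA=2, AB=1, BB=0
  pA1 <- sum(c(2, 1, 0)[genos[1, ]]) / total
  levels <- vector("list", L)
  edges <- vector("list", L)
  levels[[1]] <- data.frame(id = 1:2, label = c("A", "B"),
                            M = total * c(pA1, 1 - pA1))
  edges[[1]] <- data.frame(from = 0L, to = 1:2, C = c(pA1, 1 - pA1),
                           J = c(pA1, 1 - pA1))
  tree <- structure(list(n_loci = L, total = total, levels = levels,
                         edges = edges), class = "haplocn_tree")
  for (j in seq_len(L - 1L)) {
    C <- tables[[j]]$C
    lev <- tree$levels[[j]]
    # children aggregated by allele label (identical-history states share a
    # node); M_child = sum over parents of M_parent * C[parent -> child]
    Mw <- vapply(c("A", "B"), function(y) {
      sum(lev$M * C[lev$label, y])
    }, numeric(1))
    tree$levels[[j + 1L]] <- data.frame(id = 1:2, label = c("A", "B"),
                                        M = unname(Mw))
    e <- expand.grid(from = lev$id, to = 1:2)
    from_lab <- lev$label[match(e$from, lev$id)]
    e$C <- C[cbind(from_lab, c("A", "B")[e$to])]
    e$J <- tables[[j]]$J[cbind(from_lab, c("A", "B")[e$to])]
    tree$edges[[j + 1L]] <- e
    tree <- merge_level(tree, j + 1L)
  }
  tree
}

# outgoing branches of a node, with child labels attached
.node_children <- function(tree, locus, id) {
  if (locus >= tree$n_loci) {
    return(data.frame(to = integer(0), label = character(0), C = numeric(0)))
  }
  e <- tree$edges[[locus + 1L]]
  e <- e[e$from == id, , drop = FALSE]
  lev <- tree$levels[[locus + 1L]]
  e$label <- lev$label[match(e$to, lev$id)]
  e[order(e$label), , drop = FALSE]
}

.node_M <- function(tree, locus, id) {
  lev <- tree$levels[[locus]]
  lev$M[match(id, lev$id)]
}

#' Similarity score between two tree nodes
#'
#' The maximal absolute difference of conditional probabilities between the
#' parallel descendants of the two nodes (descendants matched by allele
#' label). Leaf nodes (final locus) score 0.
#'
#' @param tree a \code{haplocn_tree}.
#' @param locus level of both nodes.
#' @param u,v node ids at that level.
#' @return Non-negative similarity score (smaller = more similar).
#' @export
similarity_score <- function(tree, locus, u, v) {
  cu <- .node_children(tree, locus, u)
  cv <- .node_children(tree, locus, v)
  if (nrow(cu) == 0L && nrow(cv) == 0L) return(0)
  if (!identical(cu$label, cv$label)) {
    stop("mismatched descendant sets between nodes ", u, " and ", v,
         " at locus ", locus)
  }
  max(abs(cu$C - cv$C))
}

#' Merge threshold for a pair of node counts
#'
#' Nodes are mergeable when their similarity score falls below roughly twice
#' the standard deviation of a difference of transition proportions under a
#' purely random (p = 1/2) process: \code{sqrt(1/Mu + 1/Mv)}.
#'
#' @param Mu,Mv haplotype counts of the two nodes.
#' @return The threshold; \code{Inf} (with a warning) if a count is zero.
#' @export
merge_threshold <- function(Mu, Mv) {
  if (Mu <= 0 || Mv <= 0) {
    warning("zero haplotype count; node always mergeable")
    return(Inf)
  }
  sqrt(1 / Mu + 1 / Mv)
}

#' Merge two nodes of the haplotype tree
#'
#' The merged node's count is \code{Mu + Mv} and each descendant conditional
#' probability is the count-weighted average
#' \code{(Mu * C_u + Mv * C_v) / (Mu + Mv)}. Parallel descendants are merged
#' recursively and joint probabilities are recomputed as path probability
#' times \code{C}.
#'
#' @inheritParams similarity_score
#' @return The updated tree (the merged node keeps id \code{u}).
#' @export
merge_nodes <- function(tree, locus, u, v) {
  Mu <- .node_M(tree, locus, u); Mv <- .node_M(tree, locus, v)
  Mnew <- Mu + Mv
  cu <- .node_children(tree, locus, u)
  cv <- .node_children(tree, locus, v)
  if (!identical(cu$label, cv$label)) {
    stop("mismatched descendant sets between nodes ", u, " and ", v)
  }
  if (nrow(cu) > 0L) {
    Cnew <- if (Mnew > 0) (Mu * cu$C + Mv * cv$C) / Mnew else (cu$C + cv$C) / 2
    for (k in seq_len(nrow(cu))) {
      if (cu$to[k] != cv$to[k]) {
        tree <- merge_nodes(tree, locus + 1L, cu$to[k], cv$to[k])
      }
    }
    e <- tree$edges[[locus + 1L]]
    drop_v <- e$from == v
    keep_u <- e$from == u
    # rewrite u's outgoing branches with merged probabilities
    ord <- order(tree$levels[[locus + 1L]]$label[
      match(e$to[keep_u], tree$levels[[locus + 1L]]$id)])
    e$C[which(keep_u)[ord]] <- Cnew
    e$J[which(keep_u)[ord]] <- (Mnew / tree$total) * Cnew
    tree$edges[[locus + 1L]] <- e[!drop_v, , drop = FALSE]
  }
  # redirect incoming branches of v to u
  ein <- tree$edges[[locus]]
  ein$to[ein$to == v] <- u
  # a parent now pointing twice at u has its branches combined
  key <- paste(ein$from, ein$to)
  if (anyDuplicated(key)) {
    ein <- do.call(rbind, lapply(split(ein, key), function(g) {
      data.frame(from = g$from[1], to = g$to[1], C = sum(g$C), J = sum(g$J))
    }))
    rownames(ein) <- NULL
  }
  tree$edges[[locus]] <- ein
  lev <- tree$levels[[locus]]
  lev$M[lev$id == u] <- Mnew
  tree$levels[[locus]] <- lev[lev$id != v, , drop = FALSE]
  tree
}

#' Greedy merging of one tree level
#'
#' Scores every pair of same-label nodes at the level, merges the pair with
#' the smallest similarity score if it is below the pair's count-dependent
#' threshold, re-scores, and repeats until no pair qualifies or one node per
#' label remains.
#'
#' @param tree a \code{haplocn_tree}.
#' @param locus level to merge.
#' @return The updated tree.
#' @export
merge_level <- function(tree, locus) {
  repeat {
    lev <- tree$levels[[locus]]
    if (nrow(lev) <= 1L) return(tree)
    best <- NULL
    for (i in seq_len(nrow(lev) - 1L)) {
      for (k in (i + 1L):nrow(lev)) {
        if (lev$label[i] != lev$label[k]) next
        sc <- similarity_score(tree, locus, lev$id[i], lev$id[k])
        th <- merge_threshold(lev$M[i], lev$M[k])
        if (sc < th && (is.null(best) || sc < best$sc)) {
          best <- list(sc = sc, u = lev$id[i], v = lev$id[k])
        }
      }
    }
    if (is.null(best)) return(tree)
    tree <- merge_nodes(tree, locus, best$u, best$v)
  }
}

#' Collapse a tree level to per-allele transition probabilities
#'
#' Count-weighted aggregation of the branch conditionals of all nodes with
#' the same allele label, giving the 2 x 2 allele transition matrix between
#' locus \code{j} and \code{j + 1}.
#'
#' @param tree a \code{haplocn_tree}.
#' @param j locus index (1 .. n_loci - 1).
#' @return 2 x 2 matrix, rows = from allele, cols = to allele.
#' @export
collapse_transitions <- function(tree, j) {
  lev <- tree$levels[[j]]
  out <- matrix(NA_real_, 2, 2, dimnames = list(from = c("A", "B"),
                                                to = c("A", "B")))
  for (x in c("A", "B")) {
    ids <- lev$id[lev$label == x]
    Ms <- lev$M[lev$label == x]
    if (length(ids) == 0L || sum(Ms) == 0) {
      out[x, ] <- 0.5
      next
    }
    acc <- c(A = 0, B = 0)
    for (k in seq_along(ids)) {
      ch <- .node_children(tree, j, ids[k])
      acc[ch$label] <- acc[ch$label] + Ms[k] * ch$C
    }
    out[x, ] <- acc / sum(Ms)
  }
  out
}

#' Expand a binary allele transition matrix to the six allelic states
#'
#' Each conditional total \code{C[x -> y]} is distributed over the allowed
#' six-state transitions that collapse to \code{x -> y}. From a normal state
#' the persistence probability \code{rho_n = decay(d, D_norm)} keeps the
#' normal target and the complement is split equally between the gain and
#' loss targets. From a gain (loss) state, \code{rho_v = decay(d, D_var)}
#' keeps the gain (loss) target and the complement returns to normal;
#' gain-to-loss and loss-to-gain are forbidden (probability 0).
#'
#' @param C_bin 2 x 2 allele transition matrix (rows A, B).
#' @param d distance in bp between the two loci.
#' @param params a [decay_params()] object.
#' @return 6 x 6 row-stochastic matrix over [allelic_states()].
#' @export
expand_transitions <- function(C_bin, d, params) {
  st <- allelic_states()
  rho_n <- decay(d, params$D_norm)
  rho_v <- decay(d, params$D_var)
  T6 <- matrix(0, 6, 6, dimnames = list(from = st, to = st))
  for (x in c("A", "B")) for (y in c("A", "B")) {
    cxy <- C_bin[x, y]
    yl <- paste0(y, "-"); yn <- y; yg <- paste0(y, "+")
    T6[x, yn] <- T6[x, yn] + rho_n * cxy
    T6[x, yg] <- T6[x, yg] + (1 - rho_n) / 2 * cxy
    T6[x, yl] <- T6[x, yl] + (1 - rho_n) / 2 * cxy
    xg <- paste0(x, "+")
    T6[xg, yg] <- T6[xg, yg] + rho_v * cxy
    T6[xg, yn] <- T6[xg, yn] + (1 - rho_v) * cxy
    xl <- paste0(x, "-")
    T6[xl, yl] <- T6[xl, yl] + rho_v * cxy
    T6[xl, yn] <- T6[xl, yn] + (1 - rho_v) * cxy
  }
  T6
}

#' Branch the merged binary tree into the six-state transition chain
#'
#' Collapses each level of the merged tree to its allele transition matrix
#' and expands it to the six allelic states with the distance-decay rule of
#' [expand_transitions()]. The initial distribution at the first locus puts
#' prior mass \code{p_aberrant} (split between gain and loss) on the
#' aberrant states of each allele.
#'
#' @param tree a merged \code{haplocn_tree} for one chromosome.
#' @param pos integer positions (bp) of the tree's loci, ascending.
#' @param params a [decay_params()] object.
#' @return Object of class \code{haplocn_hmm}: list with \code{states},
#'   \code{init} (6-vector) and \code{trans} (list of 6 x 6 matrices, one
#'   per adjacent locus pair).
#' @export
branch_aberrant <- function(tree, pos, params = decay_params()) {
  L <- tree$n_loci
  stopifnot(length(pos) == L)
  st <- allelic_states()
  root <- tree$edges[[1]]
  lev1 <- tree$levels[[1]]
  pA <- sum(root$C[lev1$label[match(root$to, lev1$id)] == "A"])
  pab <- params$p_aberrant
  init <- stats::setNames(numeric(6), st)
  for (x in c("A", "B")) {
    px <- if (x == "A") pA else 1 - pA
    init[x] <- px * (1 - pab)
    init[paste0(x, "+")] <- px * pab / 2
    init[paste0(x, "-")] <- px * pab / 2
  }
  trans <- vector("list", max(L - 1L, 0L))
  for (j in seq_len(L - 1L)) {
    C_bin <- collapse_transitions(tree, j)
    trans[[j]] <- expand_transitions(C_bin, pos[j + 1L] - pos[j], params)
  }
  structure(list(states = st, init = init, trans = trans),
            class = "haplocn_hmm")
}
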