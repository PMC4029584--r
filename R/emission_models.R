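#' Seed the eleven emission models for one SNP
#'
#' The AA, AB and BB seed clusters anchor a grid in (A-signal, B-signal)
#' space: the three A-axis values \code{a_lo < a_mid < a_hi} come from the
#' BB, AB and AA means and likewise \code{b_lo < b_mid < b_hi} on the B
#' axis. The eleven model centers sit on this grid; M0 and M10 extend it so
#' that the center spacing M1--M0 equals M1--M4 (and M9--M10 equals M9--M8).
#' Each model inherits the covariance of the nearest seed cluster (ties go
#' to AB's covariance).
#'
#' @param seeds a \code{haplocn_seeds} object.
#' @param snp SNP row index into \code{seeds}.
#' @return List of 11 models, each \code{list(id, mu, sigma, members)};
#'   attribute \code{degenerate} is TRUE when the seed means were not
#'   properly ordered along an axis (callers should fall back to a
#'   cohort-median grid).
#' @export
seed_models <- function(seeds, snp) {
  mus <- rbind(AA = seeds$AA$mu[snp, ], AB = seeds$AB$mu[snp, ],
               BB = seeds$BB$mu[snp, ])
  sig <- list(AA = seeds$AA$sigma[snp, , ], AB = seeds$AB$sigma[snp, , ],
              BB = seeds$BB$sigma[snp, , ])
  .grid_models(mus, sig)
}

.grid_models <- function(mus, sig) {
  a_hi <- mus["AA", 1]; a_mid <- mus["AB", 1]; a_lo <- mus["BB", 1]
  b_lo <- mus["AA", 2]; b_mid <- mus["AB", 2]; b_hi <- mus["BB", 2]
  degenerate <- !(a_hi > a_mid && a_mid > a_lo &&
                  b_hi > b_mid && b_mid > b_lo)
  centers <- .grid_centers(a_lo, a_mid, a_hi, b_lo, b_mid, b_hi)
  anchor <- rbind(AA = c(a_hi, b_lo), AB = c(a_mid, b_mid),
                  BB = c(a_lo, b_hi))
  models <- lapply(model_ids(), function(id) {
    mu <- centers[id, ]
    d2 <- rowSums(sweep(anchor, 2, mu)^2)
    # ties resolve to AB's covariance
    nearest <- if (sum(d2 == min(d2)) > 1L && d2["AB"] == min(d2)) "AB"
               else names(d2)[which.min(d2)]
    list(id = id, mu = mu, sigma = sig[[nearest]],
         members = model_member_states(id))
  })
  names(models) <- model_ids()
  attr(models, "degenerate") <- degenerate
  models
}

.grid_centers <- function(a_lo, a_mid, a_hi, b_lo, b_mid, b_hi) {
  a_ext <- a_hi + (a_hi - a_mid)
  b_ext <- b_hi + (b_hi - b_mid)
  m <- rbind(
    M0 = c(a_ext, b_lo), M1 = c(a_hi, b_lo), M2 = c(a_hi, b_mid),
    M3 = c(a_hi, b_hi), M4 = c(a_mid, b_lo), M5 = c(a_mid, b_mid),
    M6 = c(a_mid, b_hi), M7 = c(a_lo, b_lo), M8 = c(a_lo, b_mid),
    M9 = c(a_lo, b_hi), M10 = c(a_lo, b_ext))
  colnames(m) <- c("A", "B")
  m
}

#' Seed the model bank for all SNPs
#'
#' Applies [seed_models()] at every SNP. SNPs with degenerate seed geometry
#' (means not strictly ordered along an axis) are flagged and receive a grid
#' built from the cohort-median seed parameters.
#'
#' @param seeds a \code{haplocn_seeds} object.
#' @return Object of class \code{haplocn_bank}: list with \code{n_snps},
#'   \code{mu} (array SNP x 11 x 2), \code{sigma} (array SNP x 11 x 2 x 2)
#'   and \code{flagged} (logical per SNP).
#' @export
seed_model_bank <- function(seeds) {
  n <- length(seeds$probe_id)
  med_mus <- rbind(AA = apply(seeds$AA$mu, 2, stats::median),
                   AB = apply(seeds$AB$mu, 2, stats::median),
                   BB = apply(seeds$BB$mu, 2, stats::median))
  med_sig <- list(AA = apply(seeds$AA$sigma, c(2, 3), stats::median),
                  AB = apply(seeds$AB$sigma, c(2, 3), stats::median),
                  BB = apply(seeds$BB$sigma, c(2, 3), stats::median))
  fallback <- .grid_models(med_mus, med_sig)
  mu <- array(NA_real_, c(n, 11, 2),
              dimnames = list(NULL, model_ids(), c("A", "B")))
  sigma <- array(NA_real_, c(n, 11, 2, 2))
  flagged <- logical(n)
  for (i in seq_len(n)) {
    mods <- seed_models(seeds, i)
    if (isTRUE(attr(mods, "degenerate"))) {
      flagged[i] <- TRUE
      mods <- fallback
    }
    for (m in seq_along(mods)) {
      mu[i, m, ] <- mods[[m]]$mu
      sigma[i, m, , ] <- mods[[m]]$sigma
    }
  }
  structure(list(n_snps = n, mu = mu, sigma = sigma, flagged = flagged,
                 probe_id = seeds$probe_id),
            class = "haplocn_bank")
}

#' Mahalanobis distance of a signal pair to a model center
#'
#' \code{sqrt((s - mu)' Sigma^-1 (s - mu))}. A singular covariance is
#' ridge-regularised by \code{1e-6 * trace(Sigma) / 2} on the diagonal
#' (with a warning).
#'
#' @param signal numeric length-2 vector (sA, sB).
#' @param mu model mean, length 2.
#' @param sigma 2 x 2 covariance.
#' @return Non-negative distance.
#' @export
mahalanobis_distance <- function(signal, mu, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (!is.finite(det_s) || det_s <= 0) {
    warning("singular model covariance; ridge-regularised")
    sigma <- .ridge(sigma)
    det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  }
  dx <- signal[1] - mu[1]; dy <- signal[2] - mu[2]
  sqrt((dx^2 * sigma[2, 2] - 2 * dx * dy * sigma[1, 2] + dy^2 * sigma[1, 1]) /
         det_s)
}

.ridge <- function(sigma) {
  eps <- max(1e-6 * (sigma[1, 1] + sigma[2, 2]) / 2, 1e-8)
  sigma + diag(eps, 2)
}

#' Select the emission model with the smallest Mahalanobis distance
#'
#' @param signal numeric length-2 vector (sA, sB).
#' @param bank a \code{haplocn_bank}.
#' @param snp SNP row index.
#' @return Model id (e.g. \code{"M5"}); ties resolve to the lower model
#'   index (M0 first).
#' @export
select_group <- function(signal, bank, snp) {
  d <- vapply(seq_len(11L), function(m) {
    mahalanobis_distance(signal, bank$mu[snp, m, ],
                         bank$sigma[snp, m, , ])
  }, numeric(1))
  model_ids()[which.min(d)]
}

# squared Mahalanobis distances of all samples at one SNP to one model
.snp_model_d2 <- function(bank, snp, m, sa, sb) {
  sg <- bank$sigma[snp, m, , ]
  det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2] * sg[2, 1]
  if (!is.finite(det_s) || det_s <= 0) {
    sg <- .ridge(sg)
    det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2] * sg[2, 1]
  }
  dx <- sa - bank$mu[snp, m, 1]; dy <- sb - bank$mu[snp, m, 2]
  list(d2 = (dx^2 * sg[2, 2] - 2 * dx * dy * sg[1, 2] + dy^2 * sg[1, 1]) /
         det_s,
       logdet = log(det_s))
}

#' Model selection and emission log-densities for a whole cohort
#'
#' Computes, for every (SNP, sample) signal pair, the bivariate-normal
#' emission log-density under all eleven models, the index of the selected
#' (nearest-Mahalanobis) model, and the shaded-region flag.
#'
#' @param bank a \code{haplocn_bank}.
#' @param signals a \code{haplocn_signals} with the same SNP rows.
#' @param quantile chi-square quantile defining the shaded region.
#' @return List with \code{logdens} (array SNP x sample x 11),
#'   \code{group} (integer matrix SNP x sample, 1 = M0 .. 11 = M10) and
#'   \code{shaded} (logical matrix SNP x sample).
#' @export
cohort_emissions <- function(bank, signals, quantile = 0.99) {
  n <- bank$n_snps
  ns <- length(signals$samples)
  stopifnot(nrow(signals$a) == n)
  logdens <- array(NA_real_, c(n, ns, 11))
  d2min <- matrix(Inf, n, ns)
  group <- matrix(1L, n, ns)
  shaded <- matrix(FALSE, n, ns)
  chi_cut <- stats::qchisq(quantile, df = 2)
  for (i in seq_len(n)) {
    sa <- signals$a[i, ]; sb <- signals$b[i, ]
    for (m in seq_len(11L)) {
      dm <- .snp_model_d2(bank, i, m, sa, sb)
      logdens[i, , m] <- -log(2 * pi) - 0.5 * dm$logdet - 0.5 * dm$d2
      better <- dm$d2 < d2min[i, ]
      group[i, better] <- m
      d2min[i, better] <- dm$d2[better]
      if (m %in% c(2L, 6L, 10L)) {           # M1, M5, M9
        shaded[i, ] <- shaded[i, ] | dm$d2 <= chi_cut
      }
    }
  }
  list(logdens = logdens, group = group, shaded = shaded)
}

#' Emission log-density of a genotype state
#'
#' The emission distribution of a genotype state is the bivariate normal of
#' the model it belongs to, so states sharing a model (e.g. \code{A|A} and
#' \code{A-|A+}) have identical densities.
#'
#' @param signal numeric length-2 vector (sA, sB).
#' @param state genotype state label, e.g. \code{"A|B"}.
#' @param bank a \code{haplocn_bank}.
#' @param snp SNP row index.
#' @return Log density.
#' @export
emission_logdensity <- function(signal, state, bank, snp) {
  m <- match(genotype_state_model(state), model_ids())
  sg <- bank$sigma[snp, m, , ]
  det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2] * sg[2, 1]
  if (!is.finite(det_s) || det_s <= 0) {
    sg <- .ridge(sg)
    det_s <- sg[1, 1] * sg[2, 2] - sg[1, 2] * sg[2, 1]
  }
  dx <- signal[1] - bank$mu[snp, m, 1]; dy <- signal[2] - bank$mu[snp, m, 2]
  d2 <- (dx^2 * sg[2, 2] - 2 * dx * dy * sg[1, 2] + dy^2 * sg[1, 1]) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * d2
}

#' Shaded-region membership of a signal pair
#'
#' The shaded region is the union of the Mahalanobis ellipses (at the given
#' chi-square quantile, boundary included) of the three normal-genotype
#' models M1, M5 and M9. Signals inside it are consistent with a normal
#' genotype, so aberration calls there are low-confidence.
#'
#' @inheritParams select_group
#' @param quantile chi-square quantile (default 0.99).
#' @return TRUE if the signal falls inside any of the three ellipses.
#' @export
in_shaded_region <- function(signal, bank, snp, quantile = 0.99) {
  cut <- stats::qchisq(quantile, df = 2)
  any(vapply(c("M1", "M5", "M9"), function(id) {
    m <- match(id, model_ids())
    mahalanobis_distance(signal, bank$mu[snp, m, ],
                         bank$sigma[snp, m, , ])^2 <= cut
  }, logical(1)))
}

#' Update emission models from decoded state assignments
#'
#' Per SNP and model, the mean becomes the sample mean of the signals of the
#' samples decoded into that model and the covariance the sample covariance
#' (ridge-regularised when degenerate). Models left with fewer than two
#' members are re-seeded by extending the grid through the updated M1, M5
#' and M9 centers, exactly as at initiation; if an anchor model itself has
#' fewer than two members its previous parameters are kept as the anchor.
#'
#' @param bank a \code{haplocn_bank}.
#' @param assignments integer matrix (SNP x sample) of decoded model
#'   indices (1 = M0 .. 11 = M10).
#' @param signals matching \code{haplocn_signals}.
#' @return The updated bank.
#' @export
update_models <- function(bank, assignments, signals) {
  n <- bank$n_snps
  for (i in seq_len(n)) {
    sa <- signals$a[i, ]; sb <- signals$b[i, ]
    counts <- tabulate(assignments[i, ], nbins = 11L)
    new_mu <- bank$mu[i, , ]
    new_sig <- bank$sigma[i, , , ]
    for (m in which(counts >= 2L)) {
      sel <- assignments[i, ] == m
      x <- sa[sel]; y <- sb[sel]
      new_mu[m, ] <- c(mean(x), mean(y))
      cv <- stats::cov(cbind(x, y))
      if (!is.finite(cv[1, 1] * cv[2, 2] - cv[1, 2]^2) ||
          cv[1, 1] * cv[2, 2] - cv[1, 2]^2 <= 0) {
        cv <- .ridge(cv)
      }
      new_sig[m, , ] <- cv
    }
    if (any(counts < 2L)) {
      # rebuild the grid from the (possibly updated) anchors M1, M5, M9
      mus <- rbind(AA = new_mu[2, ], AB = new_mu[6, ], BB = new_mu[10, ])
      sig <- list(AA = new_sig[2, , ], AB = new_sig[6, , ],
                  BB = new_sig[10, , ])
      ext <- .grid_models(mus, sig)
      if (!isTRUE(attr(ext, "degenerate"))) {
        for (m in which(counts < 2L)) {
          new_mu[m, ] <- ext[[m]]$mu
          new_sig[m, , ] <- ext[[m]]$sigma
        }
      }
    }
    bank$mu[i, , ] <- new_mu
    bank$sigma[i, , , ] <- new_sig
  }
  bank
}

#' Serialise a model bank to a tab-delimited table
#'
#' @param bank a \code{haplocn_bank}.
#' @param path optional path; if NULL the data.frame is returned.
#' @return data.frame (snp, model, muA, muB, vA, cAB, vB), invisibly when
#'   written to file.
#' @export
bank_to_table <- function(bank, path = NULL) {
  rows <- expand.grid(model = model_ids(), snp = seq_len(bank$n_snps),
                      stringsAsFactors = FALSE)[, 2:1]
  m_idx <- match(rows$model, model_ids())
  idx <- cbind(rows$snp, m_idx)
  out <- data.frame(
    snp = if (!is.null(bank$probe_id)) bank$probe_id[rows$snp] else rows$snp,
    model = rows$model,
    muA = bank$mu[cbind(idx, 1L)], muB = bank$mu[cbind(idx, 2L)],
    vA = bank$sigma[cbind(idx, 1L, 1L)], cAB = bank$sigma[cbind(idx, 1L, 2L)],
    vB = bank$sigma[cbind(idx, 2L, 2L)])
  if (is.null(path)) return(out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
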