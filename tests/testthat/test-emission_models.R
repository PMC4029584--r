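test_that("seeded grid satisfies the equal-spacing extension constraints", {
  bank <- toy_bank(1)
  mu <- bank$mu[1, , ]
  # M1->M0 extension distance equals M1->M4 grid spacing (A axis)
  expect_equal(mu["M0", 1] - mu["M1", 1], mu["M1", 1] - mu["M4", 1])
  # M9->M10 equals M9->M8 (B axis)
  expect_equal(mu["M10", 2] - mu["M9", 2], mu["M9", 2] - mu["M8", 2])
  expect_equal(unname(mu["M1", ]), c(2, 0))
  expect_equal(unname(mu["M5", ]), c(1, 1))
  expect_equal(unname(mu["M9", ]), c(0, 2))
  expect_equal(unname(mu["M0", ]), c(3, 0))
  expect_equal(unname(mu["M7", ]), c(0, 0))
})

test_that("mirror-symmetric seeds give mirror-symmetric grids", {
  sig <- array(0, dim = c(1, 2, 2)); sig[, 1, 1] <- sig[, 2, 2] <- 0.01
  seeds <- structure(list(
    probe_id = "rs1",
    AA = list(mu = cbind(A = 2.4, B = 0.3), sigma = sig),
    AB = list(mu = cbind(A = 1.2, B = 1.1), sigma = sig),
    BB = list(mu = cbind(A = 0.1, B = 2.2), sigma = sig)),
    class = "haplocn_seeds")
  swapped <- seeds
  swapped$AA$mu <- seeds$BB$mu[, 2:1, drop = FALSE]
  swapped$BB$mu <- seeds$AA$mu[, 2:1, drop = FALSE]
  swapped$AB$mu <- seeds$AB$mu[, 2:1, drop = FALSE]
  colnames(swapped$AA$mu) <- colnames(swapped$BB$mu) <-
    colnames(swapped$AB$mu) <- c("A", "B")
  m1 <- seed_models(seeds, 1); m2 <- seed_models(swapped, 1)
  # allele swap maps each model to its "symmetric model with flipped
  # alleles": M2<->M6, M4<->M8, M1<->M9, M0<->M10
  mirror <- c(M0 = "M10", M1 = "M9", M2 = "M6", M3 = "M3", M4 = "M8",
              M5 = "M5", M6 = "M2", M7 = "M7", M8 = "M4", M9 = "M1",
              M10 = "M0")
  for (id in model_ids()) {
    expect_equal(unname(m2[[mirror[[id]]]]$mu), unname(rev(m1[[id]]$mu)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate seeds fall back to the cohort-median grid, flagged", {
  seeds <- toy_seeds(3)
  seeds$AA$mu[2, ] <- c(0.5, 0)   # a_hi < a_mid: unusable geometry
  bank <- seed_model_bank(seeds)
  expect_equal(bank$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(bank$mu[2, , ], bank$mu[1, , ])
})

test_that("Mahalanobis distance matches the direct matrix oracle", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(4, 6), c(1, 2), diag(2)), 5)
  set.seed(5)
  for (k in 1:10) {
    A <- matrix(rnorm(4), 2)
    S <- crossprod(A) + diag(0.1, 2)
    s <- rnorm(2); mu <- rnorm(2)
    oracle <- sqrt(drop(t(s - mu) %*% solve(S) %*% (s - mu)))
    expect_equal(mahalanobis_distance(s, mu, S), oracle, tolerance = 1e-10)
  }
})

test_that("group selection is the exhaustive argmin with index tie-break", {
  bank <- toy_bank(1)
  expect_equal(select_group(c(1, 1), bank, 1), "M5")
  # midway between M4 (1,0) and M5 (1,1) with equal covariances: lower id
  expect_equal(select_group(c(1, 0.5), bank, 1), "M4")
  set.seed(9)
  for (k in 1:25) {
    s <- runif(2, -0.5, 3)
    d <- vapply(seq_len(11), function(m) {
      mahalanobis_distance(s, bank$mu[1, m, ], bank$sigma[1, m, , ])
    }, numeric(1))
    expect_equal(select_group(s, bank, 1), model_ids()[which.min(d)])
  }
})

test_that("emission densities are shared within a model and integrate to 1", {
  bank <- toy_bank(1)
  # at the M5 center with Sigma = I the closed form is log(1/2pi)
  bank_i <- bank; bank_i$sigma[1, 6, , ] <- diag(2)
  expect_equal(emission_logdensity(c(1, 1), "A|B", bank_i, 1), -log(2 * pi))
  # states of the same model are indistinguishable
  s <- c(1.8, 0.1)
  expect_equal(emission_logdensity(s, "A|A", bank, 1),
               emission_logdensity(s, "A-|A+", bank, 1))
  # quadrature over +-6 sigma around M1
  sd <- sqrt(bank$sigma[1, 2, 1, 1])
  gx <- seq(bank$mu[1, 2, 1] - 6 * sd, bank$mu[1, 2, 1] + 6 * sd,
            length.out = 201)
  gy <- seq(bank$mu[1, 2, 2] - 6 * sd, bank$mu[1, 2, 2] + 6 * sd,
            length.out = 201)
  h <- diff(gx[1:2]) * diff(gy[1:2])
  dens <- outer(gx, gy, function(x, y) {
    vapply(seq_along(x), function(i) {
      exp(emission_logdensity(c(x[i], y[i]), "A|A", bank, 1))
    }, numeric(1))
  })
  expect_equal(sum(dens) * h, 1, tolerance = 1e-3)
  expect_error(emission_logdensity(s, "Z|Z", bank, 1), "not covered")
})

test_that("shaded region is the closed union of the three normal ellipses", {
  bank <- toy_bank(1, noise_sd = 0.1)
  expect_true(in_shaded_region(c(1, 1), bank, 1))           # M5 center
  expect_false(in_shaded_region(c(3, 0), bank, 1))          # M0 center
  # boundary point at exactly the chi-square radius is inside
  r <- sqrt(qchisq(0.99, 2)) * 0.1
  expect_true(in_shaded_region(c(1 + r, 1), bank, 1))
  expect_false(in_shaded_region(c(1 + r + 1e-6, 1 + r), bank, 1))
})

test_that("model update recovers parameters and re-extends empty models", {
  set.seed(11)
  bank <- toy_bank(1)
  n <- 200L
  mu_true <- c(1, 1); S_true <- matrix(c(0.04, 0.01, 0.01, 0.03), 2)
  ch <- chol(S_true)
  xy <- matrix(rnorm(2 * n), ncol = 2) %*% ch
  sig <- make_signals(matrix(mu_true[1] + xy[, 1], 1),
                      matrix(mu_true[2] + xy[, 2], 1))
  assign <- matrix(6L, 1, n)     # all decoded into M5
  up <- update_models(bank, assign, sig)
  se_mu <- sqrt(diag(S_true) / n)
  expect_true(all(abs(up$mu[1, 6, ] - mu_true) <= 3 * se_mu))
  expect_true(all(abs(up$sigma[1, 6, , ] - S_true) <= 3 * 0.05 / sqrt(n) + 0.01))
  # models with no members were re-extended from the new anchors: the grid
  # equal-distance constraints hold for the updated bank
  mu <- up$mu[1, , ]
  expect_equal(mu["M0", 1] - mu["M1", 1], mu["M1", 1] - mu["M4", 1])
  expect_equal(mu["M10", 2] - mu["M9", 2], mu["M9", 2] - mu["M8", 2])
  # degenerate member sets are ridge-regularised, not singular
  sig2 <- make_signals(matrix(1, 1, 4), matrix(2, 1, 4))
  up2 <- update_models(bank, matrix(6L, 1, 4), sig2)
  S <- up2$sigma[1, 6, , ]
  expect_gt(S[1, 1] * S[2, 2] - S[1, 2]^2, 0)
})
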