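test_that("region extraction finds maximal same-direction runs", {
  path <- cbind(rep("A", 6), rep("B", 6))
  expect_equal(nrow(extract_regions(path)), 0L)

  path2 <- cbind(c("A", "A+", "A", "A"), c("B", "B", "B", "B"))
  r2 <- extract_regions(path2)
  expect_equal(r2$start_idx, 2L)
  expect_equal(r2$end_idx, 2L)
  expect_equal(r2$direction, "gain")

  # joint amplification: haplotype 1 at loci 1-3, haplotype 2 at locus 3
  # only, still a single amplified region covering loci 1-3
  path3 <- cbind(c("A+", "B+", "A+", "A"), c("B", "A", "B+", "B"))
  r3 <- extract_regions(path3)
  expect_equal(nrow(r3), 1L)
  expect_equal(c(r3$start_idx, r3$end_idx), c(1L, 3L))

  # gains and losses split into separate regions
  path4 <- cbind(c("A+", "A+", "A", "A-", "A-"), rep("B", 5))
  r4 <- extract_regions(path4)
  expect_equal(r4$direction[order(r4$start_idx)], c("gain", "loss"))
})

test_that("filtering applies the four rules in order", {
  shaded <- rep(FALSE, 30)
  # (1) singleton removed
  r <- data.frame(start_idx = 5L, end_idx = 5L, direction = "gain",
                  n_snps = 1L)
  expect_equal(nrow(filter_regions(r, shaded)), 0L)
  # (2) two 3-SNP gains separated by 2 SNPs merge into one 8-SNP region
  r2 <- data.frame(start_idx = c(1L, 6L), end_idx = c(3L, 8L),
                   direction = "gain", n_snps = 3L)
  f2 <- filter_regions(r2, shaded)
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$n_snps, 8L)
  # opposite directions never merge
  r2b <- data.frame(start_idx = c(1L, 6L), end_idx = c(3L, 8L),
                    direction = c("gain", "loss"), n_snps = 3L)
  expect_equal(nrow(filter_regions(r2b, shaded)), 2L)
  # (3) low-confidence fraction: 9/10 shaded removed, 8/10 kept
  sh <- rep(FALSE, 30); sh[1:9] <- TRUE
  r3 <- data.frame(start_idx = 1L, end_idx = 10L, direction = "loss",
                   n_snps = 10L)
  expect_equal(nrow(filter_regions(r3, sh)), 0L)
  sh8 <- rep(FALSE, 30); sh8[1:8] <- TRUE
  expect_equal(nrow(filter_regions(r3, sh8)), 1L)
  # (4) short regions tolerate no shaded SNP at all
  sh1 <- rep(FALSE, 30); sh1[2] <- TRUE
  r4 <- data.frame(start_idx = 1L, end_idx = 3L, direction = "gain",
                   n_snps = 3L)
  expect_equal(nrow(filter_regions(r4, sh1)), 0L)
  r5 <- data.frame(start_idx = 1L, end_idx = 4L, direction = "gain",
                   n_snps = 4L)
  expect_equal(nrow(filter_regions(r5, sh1)), 1L)
})

test_that("filtering is idempotent", {
  set.seed(13)
  sh <- runif(60) < 0.3
  regs <- data.frame(start_idx = c(1L, 5L, 11L, 30L, 40L),
                     end_idx = c(2L, 8L, 12L, 36L, 40L),
                     direction = c("gain", "gain", "loss", "loss", "gain"),
                     n_snps = c(2L, 4L, 2L, 7L, 1L))
  once <- filter_regions(regs, sh)
  twice <- filter_regions(once, sh)
  expect_equal(once, twice)
})

test_that("allelic copy numbers interpolate on the model grid", {
  bank <- toy_bank(1)
  expect_equal(unname(estimate_allelic_cn(c(1, 1), bank, 1)), c(1, 1))
  expect_equal(unname(estimate_allelic_cn(c(0, 2), bank, 1)), c(0, 2))
  expect_equal(unname(estimate_allelic_cn(c(1.5, 1), bank, 1))[1], 1.5)
  # negative extrapolation clips at zero
  expect_equal(unname(estimate_allelic_cn(c(-0.4, 1), bank, 1))[1], 0)
  # unequal increments: the larger one divides (conservative)
  bank2 <- bank
  bank2$mu[1, 2, 1] <- 2.4   # M1 A-center moved out: upper increment 1.4
  cn <- estimate_allelic_cn(c(2.4, 0), bank2, 1)
  expect_equal(unname(cn[1]), 2.4 / 1.4)
  # collapsed grid flags the SNP
  bank3 <- bank
  bank3$mu[1, , 1] <- 1
  expect_true(isTRUE(attr(estimate_allelic_cn(c(1, 1), bank3, 1), "flagged")))
})

test_that("haplotype and total copy numbers reproduce the worked examples", {
  # 2-SNP amplified region, phase (B,A) then (A,B)
  path <- cbind(c("B", "A+"), c("A", "B"))
  cn_a <- c(0.96, 2.31); cn_b <- c(1.64, 1.15)
  reg <- data.frame(start_idx = 1L, end_idx = 2L)
  hap <- haplotype_cn_summary(reg, path, cn_a, cn_b)
  expect_equal(unname(hap), c(1.975, 1.055))
  expect_equal(total_cn(reg, cn_a, cn_b), 3.03)
  expect_equal(sum(hap), total_cn(reg, cn_a, cn_b))

  # 3-SNP deleted region, phase (A,B)/(B,A)/(A,B)
  path2 <- cbind(c("A", "B-", "A"), c("B", "A", "B-"))
  cn_a2 <- c(0.92, 0.02, 1.06); cn_b2 <- c(0.001, 0.87, 0.11)
  reg2 <- data.frame(start_idx = 1L, end_idx = 3L)
  hap2 <- haplotype_cn_summary(reg2, path2, cn_a2, cn_b2)
  expect_equal(unname(hap2), c(0.95, 0.043667), tolerance = 1e-5)
  expect_equal(total_cn(reg2, cn_a2, cn_b2), 2.981 / 3)

  # identical haplotype alleles give equal means
  path3 <- cbind(c("A", "A"), c("A", "A"))
  hap3 <- haplotype_cn_summary(reg, path3, c(1, 1.2), c(0, 0))
  expect_equal(hap3[["hap1"]], hap3[["hap2"]])
})

test_that("event calls follow the >3 / <1 rule", {
  expect_equal(call_event(3.2), "gain")
  expect_equal(call_event(2.0), "normal")
  expect_equal(call_event(0.99), "loss")
  expect_equal(call_event(3.0), "normal")
  expect_equal(call_event(1.0), "normal")
})
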