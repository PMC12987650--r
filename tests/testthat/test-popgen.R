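test_that("allele frequencies: MAF and DAF", {
  mat <- rbind(matrix(1, 3, 1), matrix(0, 7, 1))
  p <- haplotype_panel(cbind(mat, mat, 0 * mat), pos = c(10, 20, 30),
                       anc = c("ref", "alt", "ref"))
  af <- allele_freqs(p)
  expect_equal(af$maf, c(0.3, 0.3, 0))
  expect_equal(af$daf, c(0.3, 0.7, 0))
  expect_true(all(af$maf >= 0 & af$maf <= 0.5))
})

test_that("Tajima's D, Fay-Wu's H, Fst and r2 match naive oracles", {
  for (seed in 1:30) {
    n <- 2 * sample(2:10, 1)
    S <- sample(2:30, 1)
    p1 <- random_panel(n, S, seed = seed)
    # second panel on the same positions so Fst sees a common SNP set
    set.seed(10000 + seed)
    m2 <- matrix(rbinom(n * ncol(p1$mat), 1, runif(1, 0.2, 0.6)), n)
    p2 <- haplotype_panel(m2, p1$pos, p1$anc)
    expect_equal(tajima_d(p1)$D, oracle_tajima_d(p1$mat), tolerance = 1e-9)
    expect_equal(faywu_h(p1)$H, oracle_faywu_h(p1$mat), tolerance = 1e-9)
    wf <- weighted_fst(p1, p2)
    expect_equal(wf$weighted_fst, oracle_wc_fst(p1$mat, p2$mat),
                 tolerance = 1e-9)
    if (ncol(p1$mat) >= 2) {
      expect_equal(ld_r2(p1, 1, 2), oracle_r2(p1$mat[, 1], p1$mat[, 2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("Fay-Wu's H sign tracks the derived-allele spectrum", {
  # n = 2, one derived singleton: pi = 1, theta_H = 1, H = 0
  p <- haplotype_panel(rbind(1, 0), pos = 5, anc = "ref")
  h <- faywu_h(p)
  expect_equal(h$pi, 1)
  expect_equal(h$theta_H, 1)
  expect_equal(h$H, 0)
  # only high-frequency derived alleles -> H < 0
  mat <- matrix(1, 10, 5); mat[1, ] <- 0
  expect_lt(faywu_h(haplotype_panel(mat, 1:5, rep("ref", 5)))$H, 0)
  # no derived alleles: H = 0 with S = 0
  mono <- suppressWarnings(faywu_h(haplotype_panel(matrix(0, 10, 2), 1:2,
                                                   rep("ref", 2))))
  expect_equal(mono$H, 0)
  # unknown ancestral states everywhere -> undefined flag
  unk <- faywu_h(haplotype_panel(matrix(rbinom(20, 1, 0.5), 10, 2), 1:2,
                                 rep("unknown", 2)))
  expect_false(unk$defined)
})

test_that("Tajima's D is zero at S = 0 boundary and flags undefined", {
  p <- haplotype_panel(matrix(0, 10, 3), 1:3, rep("ref", 3))
  d <- tajima_d(p)
  expect_false(d$defined)
  expect_equal(d$S, 0L)
})

test_that("weighted Fst hits its boundary values", {
  # fixed difference -> 1
  a <- haplotype_panel(matrix(1, 20, 1), 1, "ref")
  b <- haplotype_panel(matrix(0, 20, 1), 1, "ref")
  expect_equal(weighted_fst(a, b)$weighted_fst, 1)
  # no shared polymorphic SNP -> undefined
  expect_false(weighted_fst(a, a)$defined)
  # equal allele frequencies, equal sizes: near zero over seeds
  set.seed(3)
  vals <- replicate(20, {
    m1 <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10)
    m2 <- matrix(rbinom(40 * 10, 1, 0.4), 40, 10)
    weighted_fst(haplotype_panel(m1, 1:10), haplotype_panel(m2, 1:10))$weighted_fst
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("integrated Fst combines the focal population's pairs", {
  fst <- c("CEU-YRI" = 0.3, "CHB-YRI" = 0.3, "CHB-CEU" = 0.0)
  expect_equal(integrated_fst(fst, "YRI"), 0.3)
  expect_equal(integrated_fst(c("CEU-YRI" = 0.2, "CHB-YRI" = 0.1,
                                "CHB-CEU" = 0.4), "CEU"), 0.3)
  expect_equal(integrated_fst(c("CEU-YRI" = 0, "CHB-YRI" = 0,
                                "CHB-CEU" = 0), "CEU"), 0)
  expect_true(is.na(integrated_fst(c("CEU-YRI" = NA, "CHB-YRI" = 0.1,
                                     "CHB-CEU" = 0.4), "CEU")))
  expect_error(integrated_fst(c("A-B" = 0.1), "Z"), "exactly two")
})

test_that("background thresholds are empirical tail quantiles", {
  set.seed(8)
  u <- runif(10000)
  expect_equal(genome_background(u, 0.10, "upper")$threshold, 0.9,
               tolerance = 0.02)
  expect_equal(genome_background(u, 0.10, "lower")$threshold, 0.1,
               tolerance = 0.02)
  cst <- genome_background(rep(2.5, 200), 0.10, "upper")
  expect_equal(cst$threshold, 2.5)
  expect_equal(cst$n_windows, 200)
  expect_error(genome_background(runif(50), 0.1, "upper"), "too few")
})

test_that("the joint selection rule is conjunctive", {
  thr <- c(CEU = -0.97, CHB = -0.96, YRI = -0.97)
  call1 <- joint_selection_call(c(CEU = -1.2, CHB = 0.5, YRI = 0.3),
                                c(CEU = 0.3, CHB = 0.1, YRI = 0.1),
                                thr, 0.22)
  expect_true(call1$is_positive[call1$population == "CEU"])
  expect_false(any(call1$is_positive[call1$population != "CEU"]))
  # another population's D <= 0 blocks the call
  call2 <- joint_selection_call(c(CEU = -1.2, CHB = -0.1, YRI = 0.3),
                                c(CEU = 0.3, CHB = 0.1, YRI = 0.1),
                                thr, 0.22)
  expect_false(any(call2$is_positive))
  # low integrated Fst blocks the call regardless of D
  call3 <- joint_selection_call(c(CEU = -1.2, CHB = 0.5, YRI = 0.3),
                                c(CEU = 0.1, CHB = 0.1, YRI = 0.1),
                                thr, 0.22)
  expect_false(any(call3$is_positive))
  # undefined D -> no call (NA)
  call4 <- joint_selection_call(c(CEU = NA, CHB = 0.5, YRI = 0.3),
                                c(CEU = 0.3, CHB = 0.1, YRI = 0.1),
                                thr, 0.22)
  expect_true(is.na(call4$is_positive[call4$population == "CEU"]))
})

test_that("LD r2 boundaries and permutation mean", {
  x <- rbinom(40, 1, 0.5)
  p <- haplotype_panel(cbind(x, x, 1 - x), 1:3)
  expect_equal(ld_r2(p, 1, 2), 1)
  expect_equal(ld_r2(p, 1, 3), 1)  # perfect repulsion
  mono <- haplotype_panel(cbind(x, rep(0, 40)), 1:2)
  expect_true(is.na(ld_r2(mono, 1, 2)))
  # independently shuffled columns: E[r2] ~ 1/(n-1)
  set.seed(5)
  n <- 50
  vals <- replicate(3000, {
    a <- sample(c(rep(1, 20), rep(0, 30)))
    b <- sample(c(rep(1, 25), rep(0, 25)))
    oracle_r2(a, b)
  })
  expect_equal(mean(vals), 1 / (n - 1), tolerance = 0.15)
  set.seed(6)
  got <- replicate(500, {
    m <- cbind(sample(c(rep(1, 20), rep(0, 30))),
               sample(c(rep(1, 25), rep(0, 25))))
    ld_r2(haplotype_panel(m, 1:2), 1, 2)
  })
  expect_equal(mean(got), 1 / (n - 1), tolerance = 0.3)
})

test_that("SNP density counts MAF-filtered SNPs per base", {
  mat <- rbind(matrix(1, 2, 4), matrix(0, 18, 4))  # MAF 0.1
  mat[, 2] <- c(1, rep(0, 19))                     # MAF 0.05: excluded
  p <- haplotype_panel(mat, c(10, 20, 30, 500))
  sd <- snp_density(p, c(1, 147), maf_min = 0.1)
  expect_equal(sd$count, 2)
  expect_equal(sd$per_base, 2 / 147)
  expect_equal(snp_density(p, c(1000, 2000))$count, 0)
})

test_that("window tiling keeps half-full terminal windows", {
  w <- tile_windows(1, 3000, 1500)
  expect_equal(nrow(w), 2)
  w2 <- tile_windows(1, 3800, 1500)  # terminal 800 >= 750 kept
  expect_equal(nrow(w2), 3)
  w3 <- tile_windows(1, 3500, 1500)  # terminal 500 < 750 dropped
  expect_equal(nrow(w3), 2)
})
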