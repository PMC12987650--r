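fixture_tpm <- function(n_tr = 6, n_samp = 12, seed = 1) {
  set.seed(seed)
  tpm <- matrix(rexp(n_tr * n_samp, 1), n_tr, n_samp,
                dimnames = list(sprintf("tr%02d", 1:n_tr),
                                sprintf("s%02d", 1:n_samp)))
  tissues <- setNames(rep(c("brain", "liver"), each = n_samp / 2),
                      colnames(tpm))
  list(tpm = tpm, tissues = tissues)
}

test_that("robust expression uses a strict median-TPM cutoff", {
  fx <- fixture_tpm()
  fx$tpm["tr01", fx$tissues == "brain"] <- 0.1
  expect_false(robust_expression(fx$tpm, fx$tissues, "tr01", "brain"))
  fx$tpm["tr01", fx$tissues == "brain"] <- 0.1001
  expect_true(robust_expression(fx$tpm, fx$tissues, "tr01", "brain"))
  fx$tpm["tr02", ] <- 0
  expect_false(robust_expression(fx$tpm, fx$tissues, "tr02", "brain"))
  one <- matrix(5, 1, 1, dimnames = list("tr", "s1"))
  expect_true(robust_expression(one, c(s1 = "skin"), "tr", "skin"))
})

test_that("representative transcript needs the DBD, then highest TPM", {
  tpm <- matrix(c(3, 9, 5), 3, 10,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:10)))
  expect_equal(representative_transcript(c("a", "b"), c(TRUE, FALSE), tpm),
               "a")
  expect_equal(representative_transcript(c("a", "c"), c(TRUE, TRUE), tpm),
               "c")
  expect_equal(representative_transcript("a", TRUE, tpm), "a")
  # TPM tie -> lexicographically smallest
  tpm2 <- matrix(3, 2, 4, dimnames = list(c("z", "y"), sprintf("s%d", 1:4)))
  expect_equal(representative_transcript(c("z", "y"), c(TRUE, TRUE), tpm2),
               "y")
  expect_error(representative_transcript(c("a", "b"), c(FALSE, FALSE), tpm),
               "no DBD")
})

test_that("pair correlations: monotone pairs, planted pairs, null control", {
  set.seed(2)
  n <- 30
  x <- sort(rexp(n))
  tpm <- rbind(lnc = x, hit = x^2 + 1, null = rexp(n))
  colnames(tpm) <- sprintf("s%02d", 1:n)
  tissues <- setNames(rep("brain", n), colnames(tpm))
  pc <- pair_correlations(data.frame(lncrna_id = "lnc",
                                     target_id = c("hit", "null")),
                          tpm, tissues)
  expect_equal(pc$rho[pc$target_id == "hit"], 1)
  expect_true(pc$significant[pc$target_id == "hit"])
  # constant vector pairs are skipped
  tpm2 <- rbind(tpm, flat = rep(1, n))
  pc2 <- pair_correlations(data.frame(lncrna_id = "lnc", target_id = "flat"),
                           tpm2, tissues)
  expect_equal(nrow(pc2), 0)
  # independent vectors: < 5% of 600 simulated pairs significant
  set.seed(3)
  big <- matrix(rnorm(402 * 50), 402, 50,
                dimnames = list(c("L", sprintf("t%03d", 1:401)), NULL))
  colnames(big) <- sprintf("s%02d", 1:50)
  tis <- setNames(rep("brain", 50), colnames(big))
  pcn <- pair_correlations(data.frame(lncrna_id = "L",
                                      target_id = sprintf("t%03d", 1:401)),
                           big, tis)
  expect_lt(mean(pcn$significant), 0.05)
})

test_that("BH adjustment matches an independent step-up reference", {
  set.seed(4)
  for (rep in 1:10) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("random-pair background is near the null rate and reproducible", {
  set.seed(7)
  tpm <- matrix(2^rnorm(120 * 40), 120, 40,
                dimnames = list(c(sprintf("lnc%02d", 1:20),
                                  sprintf("pc%03d", 1:100)), NULL))
  colnames(tpm) <- sprintf("s%02d", 1:40)
  tissues <- setNames(rep(c("brain", "liver"), each = 20), colnames(tpm))
  rb1 <- random_pair_background(rownames(tpm)[1:20], rownames(tpm)[-(1:20)],
                                tpm, tissues, n_pairs = 500, seed = 42)
  rb2 <- random_pair_background(rownames(tpm)[1:20], rownames(tpm)[-(1:20)],
                                tpm, tissues, n_pairs = 500, seed = 42)
  expect_identical(rb1$fraction, rb2$fraction)
  expect_lt(rb1$fraction, 0.05)
  expect_error(random_pair_background("a", "b", tpm, tissues,
                                      n_pairs = 100), "fewer than")
})

test_that("tissue shift test flags planted shifts with epoch labels", {
  set.seed(11)
  n_bg <- 200
  base <- rexp(n_bg, rate = 100)  # background distances ~ 0.01
  tissues <- rep(sprintf("tis%02d", 1:10), each = n_bg / 10)
  mk <- function(shifted_genomes) {
    do.call(rbind, lapply(c("altai", "denisovan", "vindija"), function(g) {
      K <- base + ifelse(tissues == "tis01" & g %in% shifted_genomes,
                         0.02, 0)
      data.frame(tissue = tissues, genome = g, K = K)
    }))
  }
  # identical distributions: nothing significant
  r0 <- tissue_shift_test(mk(character(0)))
  expect_true(all(!r0$tests$significant))
  expect_true(all(r0$epochs$epoch == "none"))
  # shift vs all three archaic genomes: tis01 flagged ADV
  r3 <- tissue_shift_test(mk(c("altai", "denisovan", "vindija")))
  expect_true(all(r3$tests$significant[r3$tests$tissue == "tis01"]))
  expect_equal(r3$epochs$epoch[r3$epochs$tissue == "tis01"], "ADV")
  # shift only since the Denisovan: label D
  rD <- tissue_shift_test(mk("denisovan"))
  expect_equal(rD$epochs$epoch[rD$epochs$tissue == "tis01"], "D")
})

test_that("eQTL filtering applies any-population MAF and any-tissue ES", {
  eq <- data.frame(snp_id = rep(c("s1", "s2", "s3"), each = 2),
                   pos = rep(c(10, 20, 30), each = 2),
                   gene = "g", tissue = rep(c("brain", "liver"), 3),
                   es = c(0.6, 0.1, 0.4, -0.4, 0.7, 0))
  maf <- data.frame(snp_id = c("s1", "s2", "s3"),
                    CEU = c(0.05, 0.3, 0.05), CHB = c(0.05, 0.3, 0.05),
                    YRI = c(0.2, 0.3, 0.05))
  dbs <- data.frame(start = 1, end = 100)
  arch3 <- list(altai = dbs, denisovan = dbs, vindija = dbs)
  out <- filter_eqtls(eq, maf, dbs, arch3)
  # s1 qualifies (MAF 0.2 in YRI, |ES| 0.6); s2 fails ES; s3 fails MAF
  expect_equal(out$snp_id, "s1")
  expect_equal(out$class, "conserved")
  # novel: in no archaic counterpart
  none <- list(altai = dbs[0, ], denisovan = dbs[0, ], vindija = dbs[0, ])
  expect_equal(filter_eqtls(eq, maf, dbs, none)$class, "novel")
  # partial archaic presence -> other
  part <- list(altai = dbs, denisovan = dbs[0, ], vindija = dbs)
  expect_equal(filter_eqtls(eq, maf, dbs, part)$class, "other")
})

test_that("eQTL density comparison detects DBS enrichment", {
  dbs <- data.frame(start = seq(1, 1000, by = 10)[1:100],
                    end = seq(1, 1000, by = 10)[1:100] + 4)
  prom <- data.frame(start = seq(2001, 3000, by = 10)[1:100],
                     end = seq(2001, 3000, by = 10)[1:100] + 4)
  # eQTLs planted only inside DBSs
  r <- eqtl_density_compare(dbs, prom, eqtl_pos = dbs$start + 1)
  expect_lt(r$p, 0.001)
  # identical densities: no enrichment
  r0 <- eqtl_density_compare(dbs, dbs, eqtl_pos = dbs$start + 1)
  expect_gte(r0$p, 0.5)
  # empty eQTL set
  re <- eqtl_density_compare(dbs, prom, eqtl_pos = numeric(0))
  expect_gte(re$p, 0.5)
})
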