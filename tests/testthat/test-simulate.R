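test_that("generation is byte-identical under one seed", {
  cfg <- sim_config(seed = 5, n_genes = 3)
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p1 <- gen_population(cfg, c(1, 5000))
  p2 <- gen_population(cfg, c(1, 5000))
  expect_identical(p1, p2)
  e1 <- gen_expression(list(n_modules = 1, module_size = 5, n_background = 5,
                            tissues = "t", samples_per_tissue = 10), seed = 2)
  e2 <- gen_expression(list(n_modules = 1, module_size = 5, n_background = 5,
                            tissues = "t", samples_per_tissue = 10), seed = 2)
  expect_identical(e1, e2)
})

test_that("annotation yields exactly n promoters of the configured width", {
  cfg <- sim_config(seed = 2, n_genes = 10)
  g <- gen_genome(cfg)
  expect_equal(nrow(g$annotation), 10)
  pw <- promoter_windows(g$genome, g$annotation)
  expect_equal(nrow(pw), 10)
  expect_true(all(nchar(pw$sequence) == 5000))
  # a minus-strand promoter is the reverse complement of its genome slice
  k <- which(g$annotation$strand == "-")[1]
  pk <- pw[pw$transcript_id == g$annotation$transcript_id[k], ]
  raw <- substr(g$genome[[1]], pk$start + 1, pk$end)
  expect_equal(pk$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(raw))))
})

test_that("planted tracts are recovered at the planted identity", {
  cfg <- sim_config(seed = 13, n_genes = 3)
  g <- gen_genome(cfg)
  rna <- gen_dbd_rna(200, seed = 13)
  plan <- data.frame(gene_id = c("G001", "G002", "G003"),
                     length = c(100, 100, 100),
                     identity = c(1.0, 0.6, 0.4))
  pl <- plant_triplex_sites(g$genome, g$annotation, rna, plan, cfg)
  # perfect site: a pair covering the tract at 100% identity
  prom <- promoter_windows(pl$genome, g$annotation)
  pairs <- align_triplex(rna, prom$sequence[1])
  tract <- pl$truth[1, ]
  hit <- pairs[pairs$dna_start <= tract$prom_offset &
                 pairs$dna_end >= tract$prom_offset + tract$length, ]
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$identity_percent == 100))
  # identity 0.6 site: recovered affinity density ~60 per 100 bp (+/- 5)
  pairs2 <- align_triplex(rna, prom$sequence[2])
  t2 <- pl$truth[2, ]
  ov <- pairs2[pmin(pairs2$dna_end, t2$prom_offset + t2$length) -
                 pmax(pairs2$dna_start, t2$prom_offset) >= 50, ]
  expect_gte(nrow(ov), 1)
  expect_equal(max(ov$identity_percent), 60, tolerance = 5 / 60)
  # identity 0.4: no strong DBS overlapping the tract
  sc <- scan_promoters(c(L1 = rna), g$annotation, pl$genome)
  s3 <- sc$dbs[sc$dbs$transcript_id == "T003" & sc$dbs$class == "strong", ]
  t3 <- pl$truth[3, ]
  if (nrow(s3) > 0) {
    expect_true(all(pmin(s3$end, t3$prom_offset + t3$length) -
                      pmax(s3$start, t3$prom_offset) < 50))
  } else {
    succeed()
  }
})

test_that("planted strong sites are recovered as strong DBSs across seeds", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 2)
    g <- gen_genome(cfg)
    rna <- gen_dbd_rna(200, seed = seed)
    plan <- data.frame(gene_id = c("G001", "G002"), length = c(120, 100),
                       identity = c(0.9, 0.7))
    pl <- plant_triplex_sites(g$genome, g$annotation, rna, plan, cfg)
    sc <- scan_promoters(c(L1 = rna), g$annotation, pl$genome)
    for (k in 1:2) {
      tr <- pl$truth[k, ]
      s <- sc$dbs[sc$dbs$transcript_id == tr$transcript_id &
                    sc$dbs$class == "strong", ]
      total <- total + 1L
      if (nrow(s) > 0 &&
          any(pmin(s$end, tr$prom_offset + tr$length) -
                pmax(s$start, tr$prom_offset) >= 0.5 * tr$length)) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("neutral panels are neutral: mean Tajima's D near zero", {
  ds <- c()
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed, n_genes = 1, pop_names = "POP",
                      theta = 0.004, n_haplotypes_per_pop = 50)
    pan <- gen_population(cfg, c(1, 6000))[[1]]
    for (w in 1:4) {
      d <- tajima_d(pan, c((w - 1) * 1500 + 1, w * 1500))$D
      if (!is.na(d)) ds <- c(ds, d)
    }
  }
  expect_gte(length(ds), 80)
  expect_lt(abs(mean(ds)), 0.3)
})

test_that("sweep plantings drive D negative in the focal population", {
  neg <- 0
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed, n_genes = 1, pop_names = c("CEU", "YRI"),
                      theta = 0.004, n_haplotypes_per_pop = 50,
                      sweep_spec = list(window = c(1, 1500), focal = "CEU"))
    pans <- gen_population(cfg, c(1, 3000))
    d <- tajima_d(pans$CEU, c(1, 1500))$D
    if (!is.na(d) && d < 0) neg <- neg + 1
  }
  expect_gte(neg / 25, 0.9)
})

test_that("undifferentiated populations give near-zero weighted Fst", {
  ok <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_genes = 1, pop_names = c("A", "B"),
                      theta = 0.004, n_haplotypes_per_pop = 100,
                      diff_spec = list(fst = 0, window = NULL))
    pans <- gen_population(cfg, c(1, 2000))
    f <- weighted_fst(pans$A, pans$B)$weighted_fst
    if (!is.na(f) && f <= 0.05) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("counterpart divergence matches the binomial mutation model", {
  set.seed(4)
  seqs <- c(a = random_dna(1000), b = random_dna(1000))
  # divergence 0 -> identical
  cp0 <- gen_counterparts(seqs, 0, seed = 1)
  expect_identical(unname(cp0["a"]), unname(seqs["a"]))
  ks <- sapply(1:20, function(s) {
    cp <- gen_counterparts(seqs, 0.01, seed = s)
    k2p_distance(seqs[["a"]], cp[["a"]])$K
  })
  expect_true(all(ks >= 0.003 & ks <= 0.022))
  expect_equal(mean(ks), 0.01, tolerance = 0.25)
  # deleted counterpart -> missing -> sentinel 10.0
  cpd <- gen_counterparts(seqs, 0.01, seed = 1, delete = "b")
  expect_true(is.na(cpd[["b"]]))
  expect_identical(dbs_distance(seqs[["b"]], cpd[["b"]]), 10.0)
})

test_that("VCF round trip conserves allele counts and panel content", {
  cfg <- sim_config(seed = 6, n_genes = 1, pop_names = "P", theta = 0.003,
                    n_haplotypes_per_pop = 20)
  pan <- gen_population(cfg, c(1, 3000))[[1]]
  f <- tempfile(fileext = ".vcf")
  write_simple_vcf(pan, f)
  vcf <- read_simple_vcf(f)
  pan2 <- vcf_to_panel(vcf)
  expect_equal(pan2$mat, pan$mat, ignore_attr = TRUE)
  expect_equal(pan2$pos, pan$pos)
  expect_equal(pan2$anc, pan$anc)
  # allele counts in the VCF equal haplotype-matrix column sums
  acs <- sapply(seq_along(vcf$pos), function(j) {
    gts <- unlist(strsplit(unlist(vcf[j, 10:ncol(vcf)]), "|", fixed = TRUE))
    sum(gts == "1")
  })
  expect_equal(acs, unname(colSums(pan$mat)))
})

test_that("expression generator plants modules and additive eQTL effects", {
  spec <- list(n_modules = 2, module_size = 10, n_background = 20,
               loading = 1, noise_sd = 0.05,
               tissues = c("brain", "liver"), samples_per_tissue = 50,
               eqtl = data.frame(gene = "GENE0025", effect = 0.5, maf = 0.4))
  ex <- gen_expression(spec, seed = 9)
  m1 <- ex$modules[[1]]
  r <- cor(t(ex$tpm[m1, ]))
  expect_gt(min(r[upper.tri(r)]), 0.9)  # noise ~ 0 -> r ~ 1
  # planted eQTL: realised normalized effect near 0.5
  expect_equal(ex$eqtl$es, 0.5, tolerance = 0.15)
  # re-estimate independently by OLS on the TPM scale
  g <- ex$genotypes[, 1]
  beta <- coef(lm(as.numeric(scale(ex$tpm["GENE0025", ])) ~ g))[2]
  expect_equal(unname(beta), 0.5, tolerance = 0.2)
})

test_that("the planted pathway is recovered by the hypergeometric test", {
  set.seed(1)
  universe <- sprintf("G%04d", 1:1000)
  module <- universe[1:60]
  planted <- module[1:20]
  pw <- gen_pathways(universe, planted, n_random = 30, seed = 2)
  enr <- enrich_pathways(module, pw, universe, enrich_fdr = 0.01)
  expect_true("planted_pathway" %in% enr$pathway)
  expect_lt(enr$fdr[enr$pathway == "planted_pathway"], 0.01)
  # p equals the exact hypergeometric tail
  expect_equal(enr$p[enr$pathway == "planted_pathway"],
               oracle_hyper_tail(20, 20, 1000, 60), tolerance = 1e-12)
  # GMT round trip, cross-checked against an independent GMT reader
  f <- tempfile(fileext = ".gmt")
  write_gmt(pw, f)
  expect_equal(read_gmt(f), pw)
  skip_if_not_installed("fgsea")
  expect_equal(fgsea::gmtPathways(f), pw)
})
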