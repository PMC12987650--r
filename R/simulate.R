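#' Configuration for the synthetic-data generator
#'
#' The generator produces every input the pipeline consumes — reference
#' genome and annotation, lncRNA sequences with plantable triplex sites,
#' phased population haplotype panels with controllable site-frequency
#' spectrum skew and differentiation, diverged counterpart genomes,
#' expression matrices with planted regulator-driven modules and eQTL
#' effects, and pathway files — together with a ground-truth record of
#' everything planted. Identical configurations (same seed) produce
#' byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of annotated transcripts/genes.
#' @param promoter_len promoter window width in bp (default 5000:
#'   3500 bp upstream and 1500 bp downstream of the TSS).
#' @param upstream,downstream split of the promoter window around the TSS.
#' @param gene_spacing bp between consecutive promoter slots.
#' @param n_haplotypes_per_pop phased haplotypes per population (must be
#'   even so they pair into diploids).
#' @param pop_names population labels.
#' @param theta expected pairwise diversity per site.
#' @param divergence_chimp,divergence_archaic expected substitutions per
#'   site for counterpart genomes.
#' @param sweep_spec optional list: `window` (c(start, end)), `focal`
#'   (population), `rare_frac` (mass on the rare class, default 0.75).
#'   Skews the focal population's SFS in the window toward rare plus
#'   high-frequency-derived variants (sweep signature) and gives the other
#'   populations an intermediate-frequency excess there (the
#'   locally-adapted-allele scenario the joint selection rule targets).
#' @param diff_spec optional list: `fst` (Balding-Nichols differentiation
#'   level), `window` (or `NULL` for everywhere).
#' @param expr_spec optional list, see [gen_expression()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_genes = 10, promoter_len = 5000,
                       upstream = 3500, downstream = 1500,
                       gene_spacing = 500, n_haplotypes_per_pop = 100,
                       pop_names = c("CEU", "CHB", "YRI"), theta = 0.001,
                       divergence_chimp = 0.01, divergence_archaic = 0.002,
                       sweep_spec = NULL, diff_spec = NULL,
                       expr_spec = NULL) {
  stopifnot(upstream + downstream == promoter_len, n_genes >= 1,
            theta > 0, theta <= 1,
            divergence_chimp >= 0, divergence_chimp <= 1,
            divergence_archaic >= 0, divergence_archaic <= 1,
            n_haplotypes_per_pop >= 2, n_haplotypes_per_pop %% 2 == 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a reference genome and annotation
#'
#' Lays out `n_genes` transcripts on one contig, each with a promoter slot
#' wide enough for the full promoter window, alternating strands.
#'
#' @param cfg a [sim_config()].
#' @return list: `genome` (named character vector, one contig),
#'   `annotation` (data frame `gene_id`, `transcript_id`, `chrom`, `tss`
#'   (1-based), `strand`).
#' @export
gen_genome <- function(cfg) {
  set.seed(cfg$seed)
  slot <- cfg$promoter_len + cfg$gene_spacing
  L <- cfg$n_genes * slot + cfg$gene_spacing
  contig <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  rows <- lapply(seq_len(cfg$n_genes), function(i) {
    s0 <- cfg$gene_spacing + (i - 1) * slot  # 0-based slot start
    strand <- if (i %% 2 == 1) "+" else "-"
    tss0 <- if (strand == "+") s0 + cfg$upstream else
      s0 + cfg$downstream - 1
    data.frame(gene_id = sprintf("G%03d", i),
               transcript_id = sprintf("T%03d", i), chrom = "chr1",
               tss = tss0 + 1L, strand = strand, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  pw <- promoter_windows(c(chr1 = contig), ann, cfg$upstream, cfg$downstream)
  if (any(pw$end[-nrow(pw)] > pw$start[-1])) stop("overlapping promoters")
  list(genome = c(chr1 = contig), annotation = ann)
}

#' Generate a pyrimidine-rich lncRNA DNA-binding domain sequence
#'
#' Triplex-forming oligonucleotides are classically pyrimidine-rich; the
#' generated RNA is drawn from T and C so every position has a canonical
#' parallel-motif pairing rule (T.A-T, C.G-C).
#'
#' @param len length in nt.
#' @param seed RNG seed.
#' @param t_frac fraction of T (vs C).
#' @return character string.
#' @export
gen_dbd_rna <- function(len = 200, seed = 1, t_frac = 0.6) {
  set.seed(seed)
  paste(sample(c("T", "C"), len, replace = TRUE,
               prob = c(t_frac, 1 - t_frac)), collapse = "")
}

#' Plant triplex target tracts into promoters
#'
#' For each plan entry, writes into the gene's promoter a tract that the
#' triplex aligner recovers: the RNA prefix of the requested length is
#' mapped through the canonical parallel rules (T -> A, C -> G) onto the
#' duplex purine strand, then a `1 - identity` fraction of evenly spaced
#' positions is corrupted to non-pairing bases (chosen so no T.T
#' juxtaposition arises). A short unpairable spacer (T on the purine
#' strand) is written on both sides of the tract, so the recovered site is
#' delimited by the plant rather than by chance pairing in the random
#' flanks. Minus-strand promoters receive the reverse-complemented tract
#' at the mirrored genome coordinates.
#'
#' @param genome named contig vector from [gen_genome()].
#' @param annotation annotation table from [gen_genome()].
#' @param dbd_rna the lncRNA sequence whose prefix forms the TFO.
#' @param plan data frame: `gene_id`, `length`, `identity` (fraction in
#'   (0, 1]), optional `prom_offset` (0-based offset in the oriented
#'   promoter; default centres the tract in the upstream region).
#' @param cfg a [sim_config()] (promoter geometry).
#' @return list: `genome` (modified), `truth` (data frame of planted
#'   sites: gene, transcript, promoter offset, genome interval, length,
#'   identity).
#' @export
plant_triplex_sites <- function(genome, annotation, dbd_rna, plan, cfg) {
  contig <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
  truth <- list()
  for (k in seq_len(nrow(plan))) {
    p <- plan[k, ]
    stopifnot(p$identity > 0, p$identity <= 1, p$length >= 50)
    if (p$length > cfg$promoter_len) stop("tract longer than promoter")
    a <- annotation[annotation$gene_id == p$gene_id, ]
    stopifnot(nrow(a) == 1)
    rna <- strsplit(substr(dbd_rna, 1, p$length), "", fixed = TRUE)[[1]]
    if (length(rna) < p$length) stop("dbd_rna shorter than planted length")
    tract <- ifelse(rna == "T", "A", "G")
    n_bad <- floor((1 - p$identity) * p$length)
    if (n_bad > 0) {
      bad <- unique(round(seq(1, p$length, length.out = n_bad + 2)))[-1]
      bad <- bad[seq_len(n_bad)]
      tract[bad] <- ifelse(rna[bad] == "T", "C", "A")
    }
    off <- if (!is.null(plan$prom_offset) && !is.na(p$prom_offset)) {
      p$prom_offset
    } else {
      max(0, (cfg$upstream - p$length) %/% 2)
    }
    tss0 <- a$tss - 1L
    sp <- 20L  # unpairable spacer wider than the TTS-chaining offset, so
               # chance pairing in the flanks cannot extend or chain into
               # the recovered site
    if (a$strand == "+") {
      gs <- tss0 - cfg$upstream + off
      contig[(gs + 1):(gs + p$length)] <- tract
      contig[max(1, gs - sp + 1):gs] <- "T"
      contig[(gs + p$length + 1):(gs + p$length + sp)] <- "T"
    } else {
      e <- tss0 + cfg$upstream + 1L
      gs <- e - off - p$length
      rc <- rev(chartr("ACGT", "TGCA", tract))
      contig[(gs + 1):(gs + p$length)] <- rc
      contig[max(1, gs - sp + 1):gs] <- "A"
      contig[(gs + p$length + 1):(gs + p$length + sp)] <- "A"
    }
    truth[[k]] <- data.frame(gene_id = p$gene_id,
                             transcript_id = a$transcript_id,
                             strand = a$strand, prom_offset = off,
                             length = p$length, identity = p$identity,
                             g_start = gs, g_end = gs + p$length,
                             stringsAsFactors = FALSE)
  }
  genome[[1]] <- paste(contig, collapse = "")
  list(genome = genome, truth = do.call(rbind, truth))
}

.sfs_neutral <- function(n) {
  i <- seq_len(n - 1)
  sample(i, 1, prob = 1 / i)
}

.sfs_sweep <- function(n, rare_frac) {
  if (stats::runif(1) < rare_frac) {
    top <- max(2, n %/% 20)
    i <- seq_len(top)
    sample(i, 1, prob = 1 / i)
  } else {
    sample((n - 2):(n - 1), 1)
  }
}

.sfs_intermediate <- function(n) {
  p <- stats::rbeta(1, 8, 8)
  max(1, min(n - 1, round(n * p)))
}

.count_to_hap <- function(n, count) {
  h <- integer(n)
  h[sample.int(n, count)] <- 1L
  h
}

#' Generate phased haplotype panels for one or more populations
#'
#' SNP positions are shared across populations. Each SNP's derived count
#' is drawn from the neutral site-frequency spectrum (P(i) proportional to
#' 1/i) on the pooled sample of all populations' haplotypes, and carriers
#' are assigned at random across the pool; since a random subsample of a
#' neutral sample is itself neutral, every population's marginal SFS is
#' neutral (mean Tajima's D near 0) while populations stay exchangeable
#' (near-zero Fst). The expected pooled segregating-site count is
#' Watterson's `theta * a1 * L`. Under `diff_spec` each population redraws
#' its counts from Balding-Nichols differentiated frequencies in the
#' target window; under `sweep_spec` the focal population's counts in the
#' target window come from a skewed SFS (rare + high-frequency-derived)
#' and the other populations get an intermediate-frequency excess there.
#' The reference allele is ancestral throughout (derived = alternate).
#'
#' @param cfg a [sim_config()].
#' @param region `c(start, end)` 1-based inclusive positions to populate
#'   with SNPs.
#' @param seed_offset added to `cfg$seed` so several independent panels
#'   can be drawn from one config.
#' @return named list of [haplotype_panel()]s, one per population in
#'   `cfg$pop_names`.
#' @export
gen_population <- function(cfg, region, seed_offset = 0) {
  set.seed((cfg$seed + seed_offset) %% .Machine$integer.max)
  n <- cfg$n_haplotypes_per_pop
  npop <- length(cfg$pop_names)
  N <- n * npop
  L <- region[2] - region[1] + 1
  a1 <- sum(1 / seq_len(N - 1))
  S <- stats::rpois(1, cfg$theta * a1 * L)
  S <- max(S, 1)
  pos <- sort(sample(seq(region[1], region[2]), min(S, L)))
  sw <- cfg$sweep_spec
  in_sweep <- if (is.null(sw)) rep(FALSE, length(pos)) else
    pos >= sw$window[1] & pos <= sw$window[2]
  rare_frac <- if (is.null(sw$rare_frac)) 0.75 else sw$rare_frac
  df <- cfg$diff_spec
  in_diff <- if (is.null(df)) rep(FALSE, length(pos)) else if (is.null(df$window))
    rep(TRUE, length(pos)) else pos >= df$window[1] & pos <= df$window[2]

  mats <- lapply(cfg$pop_names, function(p) matrix(0L, n, length(pos)))
  names(mats) <- cfg$pop_names
  for (j in seq_along(pos)) {
    # pooled neutral draw, partitioned into population blocks
    pooled <- .count_to_hap(N, .sfs_neutral(N))
    p0 <- mean(pooled)
    for (k in seq_len(npop)) {
      pp <- cfg$pop_names[k]
      block <- pooled[((k - 1) * n + 1):(k * n)]
      if (in_sweep[j] && pp == sw$focal) {
        block <- .count_to_hap(n, .sfs_sweep(n, rare_frac))
      } else if (in_sweep[j]) {
        block <- .count_to_hap(n, .sfs_intermediate(n))
      } else if (in_diff[j] && df$fst > 0) {
        F <- df$fst
        pk <- stats::rbeta(1, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
        block <- .count_to_hap(n, stats::rbinom(1, n, pk))
      }
      mats[[pp]][, j] <- block
    }
  }
  seg_any <- Reduce(`|`, lapply(mats, function(m) {
    cs <- colSums(m); cs > 0 & cs < n
  }))
  lapply(mats, function(m)
    haplotype_panel(m[, seg_any, drop = FALSE], pos[seg_any],
                    rep("ref", sum(seg_any))))
}

#' Generate diverged counterpart sequences
#'
#' Mutates each input sequence independently per site at the given
#' divergence rate (substitutions only; transitions with probability
#' `ts_prob` among mutated sites). Sequences named in `delete` get no
#' counterpart (`NA`), emulating deleted regions.
#'
#' @param seqs named character vector (e.g. DBS sequences).
#' @param divergence expected substitutions per site.
#' @param seed RNG seed.
#' @param delete names to drop.
#' @param ts_prob transition fraction among substitutions.
#' @return named character vector with `NA` for deleted entries.
#' @export
gen_counterparts <- function(seqs, divergence, seed = 1,
                             delete = character(0), ts_prob = 2 / 3) {
  set.seed(seed)
  TS <- c(A = "G", G = "A", C = "T", T = "C")
  TV <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  out <- vapply(names(seqs), function(id) {
    if (id %in% delete) return(NA_character_)
    b <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < divergence)
    for (i in hit) {
      b[i] <- if (stats::runif(1) < ts_prob) TS[[b[i]]] else
        sample(TV[[b[i]]], 1)
    }
    paste(b, collapse = "")
  }, character(1))
  out
}

#' Generate an expression matrix with planted modules and eQTL effects
#'
#' Regulators (lncRNAs) and target genes are simulated on a latent-factor
#' model: each module's regulator value per sample is standard normal and
#' every module gene is `loading x regulator + noise`. TPM values are an
#' affine transform (`base + scale x value`, floored at 0 with the floor
#' essentially never binding) so Pearson/Spearman structure is preserved.
#' Planted eQTLs add an additive per-alternate-allele shift to their
#' gene's expression; the realised normalized effect size is re-estimated
#' by OLS of standardised expression on genotype dosage and reported in
#' the eQTL table (GTEx-style semantics).
#'
#' @param spec list: `n_modules`, `module_size`, `n_background` (genes
#'   outside modules), `loading` (default 1), `noise_sd` (default 0.3),
#'   `tissues` (labels), `samples_per_tissue`, `active_tissues` (tissues
#'   in which module structure is present; default all), `eqtl` (optional
#'   data frame `gene`, `effect`, `maf`), `base` (default 10), `scale`
#'   (default 2).
#' @param seed RNG seed.
#' @return list: `tpm` (matrix, rows = regulators then genes), `tissues`
#'   (sample -> tissue), `modules` (list regulator -> gene members),
#'   `genotypes` (sample-level dosage matrix for eQTL SNPs or NULL),
#'   `eqtl` (realised eQTL table or NULL).
#' @export
gen_expression <- function(spec, seed = 1) {
  set.seed(seed)
  loading <- if (is.null(spec$loading)) 1 else spec$loading
  noise_sd <- if (is.null(spec$noise_sd)) 0.3 else spec$noise_sd
  base <- if (is.null(spec$base)) 10 else spec$base
  scl <- if (is.null(spec$scale)) 2 else spec$scale
  tissues <- rep(spec$tissues, each = spec$samples_per_tissue)
  samples <- sprintf("%s_s%02d", tissues,
                     unlist(lapply(spec$tissues, function(t)
                       seq_len(spec$samples_per_tissue))))
  names(tissues) <- samples
  ns <- length(samples)
  active <- if (is.null(spec$active_tissues)) spec$tissues else
    spec$active_tissues
  reg_ids <- sprintf("LNC%02d", seq_len(spec$n_modules))
  gene_ids <- sprintf("GENE%04d",
                      seq_len(spec$n_modules * spec$module_size +
                                spec$n_background))
  val <- matrix(stats::rnorm((length(reg_ids) + length(gene_ids)) * ns,
                             sd = 1),
                nrow = length(reg_ids) + length(gene_ids),
                dimnames = list(c(reg_ids, gene_ids), samples))
  modules <- list()
  act <- tissues %in% active
  for (m in seq_len(spec$n_modules)) {
    genes <- gene_ids[((m - 1) * spec$module_size + 1):(m * spec$module_size)]
    modules[[reg_ids[m]]] <- genes
    f <- stats::rnorm(ns)
    val[reg_ids[m], act] <- f[act]
    for (g in genes) {
      val[g, act] <- loading * f[act] + stats::rnorm(sum(act), sd = noise_sd)
    }
  }
  genotypes <- NULL; eqtl_out <- NULL
  if (!is.null(spec$eqtl) && nrow(spec$eqtl) > 0) {
    genotypes <- vapply(seq_len(nrow(spec$eqtl)), function(k)
      stats::rbinom(ns, 2, spec$eqtl$maf[k]), numeric(ns))
    colnames(genotypes) <- sprintf("snp%02d", seq_len(nrow(spec$eqtl)))
    rownames(genotypes) <- samples
    es <- numeric(nrow(spec$eqtl))
    for (k in seq_len(nrow(spec$eqtl))) {
      g <- spec$eqtl$gene[k]
      val[g, ] <- val[g, ] + spec$eqtl$effect[k] * genotypes[, k]
      es[k] <- unname(stats::coef(stats::lm(as.numeric(scale(val[g, ])) ~
                                              genotypes[, k]))[2])
    }
    eqtl_out <- cbind(spec$eqtl,
                      snp_id = colnames(genotypes), es = es,
                      stringsAsFactors = FALSE)
  }
  tpm <- base + scl * val
  tpm[tpm < 0] <- 0
  list(tpm = tpm, tissues = tissues, modules = modules,
       genotypes = genotypes, eqtl = eqtl_out)
}

#' Generate a pathway collection with one planted enriched pathway
#'
#' Random gene sets drawn from the universe, plus one planted pathway that
#' is a subset of a planted module's genes (so a module built on that
#' regulator is enriched for it).
#'
#' @param universe character vector of all gene ids.
#' @param planted_genes genes forming the planted pathway.
#' @param n_random number of random pathways.
#' @param size_range size range for random pathways.
#' @param seed RNG seed.
#' @return named list of pathways (planted pathway first, named
#'   `"planted_pathway"`).
#' @export
gen_pathways <- function(universe, planted_genes, n_random = 50,
                         size_range = c(15, 60), seed = 1) {
  set.seed(seed)
  pw <- list(planted_pathway = planted_genes)
  for (k in seq_len(n_random)) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    pw[[sprintf("random_pathway_%02d", k)]] <- sample(universe, sz)
  }
  pw
}
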