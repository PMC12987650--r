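#' Robust expression of a transcript in a tissue
#'
#' A transcript is robustly expressed in a tissue when its median TPM over
#' that tissue's samples is strictly greater than `tpm_min` (default 0.1).
#'
#' @param tpm transcript x sample TPM matrix (rownames = transcript ids).
#' @param tissues named character vector: sample -> tissue label.
#' @param transcript transcript id.
#' @param tissue tissue label.
#' @param tpm_min median-TPM threshold.
#' @return logical.
#' @export
robust_expression <- function(tpm, tissues, transcript, tissue,
                              tpm_min = 0.1) {
  samp <- names(tissues)[tissues == tissue]
  stopifnot(length(samp) >= 1)
  stats::median(tpm[transcript, samp]) > tpm_min
}

#' Representative transcript of a lncRNA
#'
#' Among the lncRNA's transcripts that contain the predicted DNA-binding
#' domain, selects the one with the highest overall median TPM; ties break
#' to the lexicographically smallest id. A lncRNA without any
#' DBD-containing transcript is an error (it cannot act through triplex
#' binding and is excluded upstream).
#'
#' @param transcripts character vector of the lncRNA's transcript ids.
#' @param has_dbd logical vector parallel to `transcripts`.
#' @param tpm TPM matrix containing the transcripts.
#' @return transcript id.
#' @export
representative_transcript <- function(transcripts, has_dbd, tpm) {
  cand <- transcripts[has_dbd]
  if (length(cand) == 0) stop("no DBD-containing transcript")
  med <- apply(tpm[cand, , drop = FALSE], 1, stats::median)
  cand <- cand[med == max(med)]
  sort(cand)[1]
}

#' lncRNA-target expression correlations per tissue
#'
#' Spearman correlation between each lncRNA (representative transcript)
#' and each of its target transcripts, within every tissue with at least
#' `min_samples` samples. P-values are Benjamini-Hochberg corrected over
#' the whole family of (pair, tissue) tests; a pair is significant when
#' `|rho| > rho_min` and FDR < `fdr_max`.
#'
#' @param pairs data frame with columns `lncrna_id`, `target_id` (both
#'   must be rownames of `tpm`).
#' @param tpm transcript x sample TPM matrix.
#' @param tissues named character vector: sample -> tissue.
#' @param rho_min,fdr_max significance thresholds (defaults 0.3, 0.05).
#' @param min_samples minimum samples per tissue (default 10).
#' @return data frame: `lncrna_id`, `target_id`, `tissue`, `rho`, `p`,
#'   `fdr`, `significant`. Pairs with a constant expression vector in a
#'   tissue are skipped.
#' @export
pair_correlations <- function(pairs, tpm, tissues, rho_min = 0.3,
                              fdr_max = 0.05, min_samples = 10) {
  tl <- split(names(tissues), tissues)
  tl <- tl[vapply(tl, length, integer(1)) >= min_samples]
  out <- list()
  for (tis in names(tl)) {
    samp <- tl[[tis]]
    for (k in seq_len(nrow(pairs))) {
      x <- tpm[pairs$lncrna_id[k], samp]
      y <- tpm[pairs$target_id[k], samp]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = pairs$lncrna_id[k], target_id = pairs$target_id[k],
        tissue = tis, rho = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(lncrna_id = character(), target_id = character(),
                      tissue = character(), rho = numeric(), p = numeric(),
                      fdr = numeric(), significant = logical()))
  }
  res <- do.call(rbind, out)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- abs(res$rho) > rho_min & res$fdr < fdr_max
  rownames(res) <- NULL
  res
}

#' Random-pair correlation background
#'
#' Samples `n_pairs` random (lncRNA, transcript) pairs, applies the same
#' per-tissue correlation and significance rule as [pair_correlations()],
#' and returns the fraction of pairs significant in at least one tissue
#' with a binomial confidence interval. This estimates how often the
#' pair-correlation rule fires by chance.
#'
#' @param lncrna_ids,target_ids candidate id pools (rownames of `tpm`).
#' @param tpm,tissues,rho_min,fdr_max,min_samples as in
#'   [pair_correlations()].
#' @param n_pairs number of random pairs.
#' @param seed RNG seed (fraction is deterministic given the seed).
#' @return list: `fraction`, `ci` (95% binomial), `n_pairs`, `table`.
#' @export
random_pair_background <- function(lncrna_ids, target_ids, tpm, tissues,
                                   n_pairs = 10000, seed = 1,
                                   rho_min = 0.3, fdr_max = 0.05,
                                   min_samples = 10) {
  ncomb <- length(lncrna_ids) * length(target_ids)
  if (ncomb < n_pairs) stop("fewer than n_pairs constructible pairs")
  set.seed(seed)
  idx <- sample.int(ncomb, n_pairs)
  pairs <- data.frame(
    lncrna_id = lncrna_ids[(idx - 1L) %% length(lncrna_ids) + 1L],
    target_id = target_ids[(idx - 1L) %/% length(lncrna_ids) + 1L],
    stringsAsFactors = FALSE)
  tab <- pair_correlations(pairs, tpm, tissues, rho_min, fdr_max, min_samples)
  sig_pair <- unique(paste(tab$lncrna_id, tab$target_id)[tab$significant])
  frac <- length(sig_pair) / n_pairs
  ci <- stats::binom.test(length(sig_pair), n_pairs)$conf.int
  list(fraction = frac, ci = as.numeric(ci), n_pairs = n_pairs, table = tab)
}

#' Tissue-wise DBS distance shift tests against the all-tissue background
#'
#' For each tissue, compares the distribution of DBS sequence distances
#' (modern human to one archaic genome) attached to that tissue's
#' significantly correlated lncRNA-target pairs with the pooled
#' all-tissue background, using a one-sided two-sample Kolmogorov-Smirnov
#' test (alternative: tissue distances stochastically larger). P-values
#' are BH-corrected across tissues x archaic genomes; per tissue, the
#' epoch label records which archaic genomes show a significant shift:
#' `ADV` (all three), `AD` (Altai + Denisovan), `D` (Denisovan), else
#' `none`.
#'
#' @param dist_tab data frame with columns `tissue`, `genome` (archaic
#'   genome id) and `K` (DBS distance), one row per (significant pair,
#'   tissue, genome).
#' @param fdr_max significance level (default 0.001).
#' @param min_dbs minimum per-tissue sample size; smaller tissues are
#'   skipped.
#' @return list: `tests` (tissue, genome, ks_stat, p, fdr, significant)
#'   and `epochs` (tissue, epoch).
#' @export
tissue_shift_test <- function(dist_tab, fdr_max = 0.001, min_dbs = 5) {
  out <- list()
  for (g in unique(dist_tab$genome)) {
    dg <- dist_tab[dist_tab$genome == g, , drop = FALSE]
    background <- dg$K
    for (tis in unique(dg$tissue)) {
      x <- dg$K[dg$tissue == tis]
      if (length(x) < min_dbs) next
      # H1: tissue distances stochastically larger than background, i.e.
      # the tissue ECDF lies below the background ECDF
      ks <- suppressWarnings(stats::ks.test(x, background,
                                            alternative = "less"))
      out[[length(out) + 1L]] <- data.frame(
        tissue = tis, genome = g, ks_stat = unname(ks$statistic),
        p = ks$p.value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, out)
  tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  tests$significant <- tests$fdr < fdr_max
  epochs <- do.call(rbind, lapply(unique(tests$tissue), function(tis) {
    sg <- tests$genome[tests$tissue == tis & tests$significant]
    ep <- if (all(c("altai", "denisovan", "vindija") %in% sg)) "ADV"
      else if (all(c("altai", "denisovan") %in% sg)) "AD"
      else if ("denisovan" %in% sg) "D"
      else "none"
    data.frame(tissue = tis, epoch = ep, stringsAsFactors = FALSE)
  }))
  list(tests = tests, epochs = epochs)
}

#' Filter eQTLs in DBSs and classify them as conserved or novel
#'
#' A SNP qualifies as a DBS eQTL when its MAF is at least `maf_min` in at
#' least one modern population and its absolute cis-effect size reaches
#' `es_min` in at least one tissue. A qualifying eQTL is `conserved` when
#' it falls inside the DBS counterpart interval in all three archaic
#' genomes, `novel` when it lies in the modern DBS only, otherwise
#' `other`.
#'
#' @param eqtl data frame: `snp_id`, `pos`, `gene`, `tissue`, `es`.
#' @param maf_tab data frame: `snp_id` plus one MAF column per population
#'   (columns other than `snp_id`).
#' @param dbs_intervals data frame: `start`, `end` (inclusive positions of
#'   modern DBSs).
#' @param archaic_intervals named list (genome -> data frame `start`,
#'   `end`) of counterpart intervals; genomes where a DBS has no
#'   counterpart simply lack that interval.
#' @param maf_min,es_min thresholds (defaults 0.1 and 0.5).
#' @return data frame of qualifying records: `snp_id`, `pos`, `gene`,
#'   `max_abs_es`, `max_maf`, `class`.
#' @export
filter_eqtls <- function(eqtl, maf_tab, dbs_intervals, archaic_intervals,
                         maf_min = 0.1, es_min = 0.5) {
  es_by_snp <- tapply(abs(eqtl$es), eqtl$snp_id, max)
  snps <- unique(eqtl[, c("snp_id", "pos", "gene")])
  mafcols <- setdiff(names(maf_tab), "snp_id")
  maf_max <- apply(maf_tab[, mafcols, drop = FALSE], 1, max)
  names(maf_max) <- maf_tab$snp_id
  in_any <- function(pos, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(FALSE)
    any(pos >= iv$start & pos <= iv$end)
  }
  rows <- list()
  for (k in seq_len(nrow(snps))) {
    id <- snps$snp_id[k]
    if (is.na(maf_max[id]) || maf_max[id] < maf_min) next
    if (es_by_snp[[id]] < es_min) next
    if (!in_any(snps$pos[k], dbs_intervals)) next
    in_arch <- vapply(archaic_intervals, function(iv) in_any(snps$pos[k], iv),
                      logical(1))
    cls <- if (length(in_arch) == 3 && all(in_arch)) "conserved"
      else if (!any(in_arch)) "novel" else "other"
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = id, pos = snps$pos[k], gene = snps$gene[k],
      max_abs_es = es_by_snp[[id]], max_maf = unname(maf_max[id]),
      class = cls, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(snp_id = character(), pos = integer(),
                      gene = character(), max_abs_es = numeric(),
                      max_maf = numeric(), class = character()))
  }
  do.call(rbind, rows)
}

#' Compare eQTL density in DBSs versus whole promoters
#'
#' Computes per-interval eQTL density (count / length) for DBS intervals
#' and promoter intervals and tests whether DBS densities are larger with
#' a one-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param dbs_intervals,promoter_intervals data frames with `start`,
#'   `end` (inclusive).
#' @param eqtl_pos integer vector of eQTL positions.
#' @return list: `U`, `p`, `dbs_density`, `promoter_density`.
#' @export
eqtl_density_compare <- function(dbs_intervals, promoter_intervals,
                                 eqtl_pos) {
  dens <- function(iv) {
    vapply(seq_len(nrow(iv)), function(k) {
      sum(eqtl_pos >= iv$start[k] & eqtl_pos <= iv$end[k]) /
        (iv$end[k] - iv$start[k] + 1)
    }, numeric(1))
  }
  dd <- dens(dbs_intervals)
  dp <- dens(promoter_intervals)
  wt <- suppressWarnings(stats::wilcox.test(dd, dp, alternative = "greater"))
  list(U = unname(wt$statistic), p = wt$p.value,
       dbs_density = dd, promoter_density = dp)
}
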