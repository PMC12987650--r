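#' Apply sample variants from a VCF table to a reference sequence
#'
#' Builds the consensus sequence of one sample by substituting its alleles
#' into the reference. Only single-nucleotide variants are applied (indels
#' are skipped with a message). When several records call the same locus,
#' the record with the highest QUAL wins; exact QUAL ties are resolved by
#' first-record order.
#'
#' @param reference character string.
#' @param vcf data frame with columns `pos` (1-based), `ref`, `alt`,
#'   `qual`, and one genotype column per sample (strings such as `"1|1"`);
#'   as produced by [read_simple_vcf()].
#' @param sample genotype column name. A haploid consensus is built from
#'   the first allele of heterozygous genotypes.
#' @return character string of the same length as `reference`.
#' @export
apply_variants <- function(reference, vcf, sample) {
  if (nrow(vcf) == 0) return(reference)
  stopifnot(sample %in% names(vcf))
  snv <- nchar(vcf$ref) == 1 & nchar(vcf$alt) == 1
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) skipped")
  vcf <- vcf[snv, , drop = FALSE]
  if (any(vcf$pos < 1 | vcf$pos > nchar(reference))) {
    stop("variant position outside reference")
  }
  # highest-QUAL record per locus; ties -> first record
  o <- order(vcf$pos, -vcf$qual, seq_len(nrow(vcf)))
  vcf <- vcf[o, , drop = FALSE]
  vcf <- vcf[!duplicated(vcf$pos), , drop = FALSE]
  cons <- strsplit(reference, "", fixed = TRUE)[[1]]
  gt <- sub("[|/].*$", "", vcf[[sample]])
  take_alt <- gt == "1"
  cons[vcf$pos[take_alt]] <- vcf$alt[take_alt]
  paste(cons, collapse = "")
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the transition proportion P, transversion proportion Q and the
#' K2P distance K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) per compared site.
#' Sites where either sequence carries a gap or ambiguity code are excluded
#' pairwise; the denominator is the number of compared sites.
#'
#' @param seq_a,seq_b equal-length aligned character strings.
#' @return list with `P`, `Q`, `K`, `n_sites` (compared sites),
#'   `saturated` (logical; when TRUE the log arguments were non-positive
#'   and `K` is `NA` — the sentinel distance is never produced here, see
#'   [dbs_distance()]).
#' @examples
#' k2p_distance(strrep("A", 100), paste0(strrep("G", 10), strrep("A", 90)))
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be aligned (equal length)")
  a <- .seq_codes(seq_a)
  b <- .seq_codes(seq_b)
  ok <- a >= 0 & b >= 0
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  # transitions: A<->G (0,2), C<->T (1,3) -> same parity
  ts <- diff & ((a %% 2) == (b %% 2))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P saturation: distance undefined")
    return(list(P = P, Q = Q, K = NA_real_, n_sites = n, saturated = TRUE))
  }
  K <- -0.5 * log(w1 * sqrt(w2))
  list(P = P, Q = Q, K = K, n_sites = n, saturated = FALSE)
}

#' Tamura-Nei (TN93) distance
#'
#' Used as an internal cross-check of the K2P distances; on weakly diverged
#' sequences the two models agree closely.
#'
#' @inheritParams k2p_distance
#' @return numeric distance (NA on saturation).
#' @export
tn93_distance <- function(seq_a, seq_b) {
  a <- .seq_codes(seq_a); b <- .seq_codes(seq_b)
  ok <- a >= 0 & b >= 0
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  freq <- (tabulate(a + 1L, 4) + tabulate(b + 1L, 4)) / (2 * n)
  gA <- freq[1]; gC <- freq[2]; gG <- freq[3]; gT <- freq[4]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  ts <- diff & ((a %% 2) == (b %% 2))
  P1 <- sum(ts & (a %% 2 == 0)) / n  # purine transitions A<->G
  P2 <- sum(ts & (a %% 2 == 1)) / n  # pyrimidine transitions C<->T
  Q <- sum(diff & !ts) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (any(c(w1, w2, w3) <= 0)) return(NA_real_)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' DBS distance with the missing-counterpart convention
#'
#' Returns the K2P distance between a DBS and its counterpart in another
#' genome, or exactly 10.0 when the counterpart is missing (e.g. the
#' region is deleted in that genome).
#'
#' @param dbs_seq DBS sequence in the focal genome.
#' @param counterpart_seq counterpart sequence, or `NA`/`NULL` when
#'   missing.
#' @return numeric distance per site.
#' @export
dbs_distance <- function(dbs_seq, counterpart_seq) {
  if (is.null(counterpart_seq) || length(counterpart_seq) == 0 ||
      is.na(counterpart_seq)) {
    return(10.0)
  }
  k2p_distance(dbs_seq, counterpart_seq)$K
}

#' Age classification and epoch labelling of DBSs
#'
#' A DBS is `old` when it diverged from chimpanzee before the archaic
#' split (human-chimp distance > 0.034 and human-Altai distance = 0) and
#' `young` when it diverged recently (human-Altai or human-Denisovan
#' distance > 0.034); everything else is `other`.
#'
#' Epoch flags mark continued evolution: among DBSs in the top fraction of
#' human-chimp distances (default top 20%, distance > `epoch_min`), flag
#' `A`/`D`/`V` is set when the distance to the Altai Neanderthal,
#' Denisovan or Vindija Neanderthal genome exceeds `epoch_min` (default
#' 0.037), and `C` when the chimp distance itself does.
#'
#' @param d_chimp,d_altai,d_denisovan,d_vindija numeric vectors of per-DBS
#'   distances (NA allowed; a DBS with missing archaic distance is labelled
#'   `other`).
#' @param age_min old/young distance threshold (default 0.034).
#' @return character vector of `old`/`young`/`other`.
#' @export
classify_age <- function(d_chimp, d_altai, d_denisovan, age_min = 0.034) {
  n <- length(d_chimp)
  out <- rep("other", n)
  miss <- is.na(d_altai) | is.na(d_denisovan)
  young <- !miss & (d_altai > age_min | d_denisovan > age_min)
  old <- !is.na(d_altai) & !is.na(d_chimp) & d_chimp > age_min & d_altai == 0
  out[old] <- "old"
  out[young] <- "young"   # young takes precedence per its definition
  out
}

#' @param top_frac fraction of DBSs (ranked by human-chimp distance) that
#'   are eligible for epoch flags.
#' @param epoch_min distance threshold for an epoch flag.
#' @rdname classify_age
#' @return [flag_epochs()]: character vector of comma-separated flags out
#'   of `C`,`A`,`D`,`V` (empty string when none).
#' @export
flag_epochs <- function(d_chimp, d_altai, d_denisovan, d_vindija,
                        top_frac = 0.20, epoch_min = 0.037) {
  n <- length(d_chimp)
  thr <- stats::quantile(d_chimp, probs = 1 - top_frac, na.rm = TRUE,
                         names = FALSE, type = 1)
  eligible <- !is.na(d_chimp) & d_chimp >= thr & d_chimp > epoch_min
  flags <- character(n)
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    f <- c(
      if (!is.na(d_chimp[i]) && d_chimp[i] >= epoch_min) "C",
      if (!is.na(d_altai[i]) && d_altai[i] > epoch_min) "A",
      if (!is.na(d_denisovan[i]) && d_denisovan[i] > epoch_min) "D",
      if (!is.na(d_vindija[i]) && d_vindija[i] > epoch_min) "V")
    flags[i] <- paste(f, collapse = ",")
  }
  flags
}

#' Ancestor-anchored DBS distances and concordance
#'
#' Computes distances from a reconstructed ancestral sequence to each
#' genome's counterpart of every DBS, and the concordance fraction: the
#' proportion of DBSs for which the ancestor-to-modern distance exceeds
#' the ancestor-to-archaic distance (as expected when the archaic genome
#' lies between ancestor and modern on the lineage).
#'
#' @param ancestor_seqs named list of per-DBS ancestral sequences.
#' @param genome_seqs named list (genome id -> named list of per-DBS
#'   sequences). Must include `"modern"` and at least one archaic genome.
#' @param archaic id of the archaic genome used for the concordance
#'   comparison (default `"altai"`).
#' @return list with `distances` (data frame: dbs, genome, K) and
#'   `concordance` (fraction).
#' @export
ancestor_mode_distances <- function(ancestor_seqs, genome_seqs,
                                    archaic = "altai") {
  ids <- names(ancestor_seqs)
  rows <- list()
  for (g in names(genome_seqs)) {
    K <- vapply(ids, function(i)
      dbs_distance(ancestor_seqs[[i]], genome_seqs[[g]][[i]]), numeric(1))
    rows[[g]] <- data.frame(dbs = ids, genome = g, K = K,
                            stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  km <- d$K[d$genome == "modern"]
  ka <- d$K[d$genome == archaic]
  list(distances = d, concordance = mean(km > ka))
}
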