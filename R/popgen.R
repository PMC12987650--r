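#' Haplotype panels
#'
#' A haplotype panel holds phased biallelic SNPs for one population: a
#' haplotype x SNP 0/1 matrix (1 = alternate allele), SNP positions, and
#' the ancestral state of each SNP (`"ref"`, `"alt"` or `"unknown"`).
#' It is the substrate for all selection statistics.
#'
#' @param mat integer/numeric 0/1 matrix, haplotypes in rows.
#' @param pos integer vector of 1-based SNP positions (one per column).
#' @param anc character vector of ancestral states per SNP.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(mat, pos, anc = rep("unknown", ncol(mat))) {
  stopifnot(ncol(mat) == length(pos), length(anc) == length(pos),
            all(mat %in% c(0, 1)), all(anc %in% c("ref", "alt", "unknown")))
  o <- order(pos)
  structure(list(mat = as.matrix(mat)[, o, drop = FALSE], pos = pos[o],
                 anc = anc[o], n = nrow(mat)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", x$n, "haplotypes,", length(x$pos), "SNPs\n")
  invisible(x)
}

.panel_window <- function(panel, window) {
  if (is.null(window)) return(seq_along(panel$pos))
  which(panel$pos >= window[1] & panel$pos <= window[2])
}

# derived allele count per SNP column (NA when ancestral state unknown)
.derived_counts <- function(panel, idx = seq_along(panel$pos)) {
  alt <- colSums(panel$mat[, idx, drop = FALSE])
  d <- ifelse(panel$anc[idx] == "ref", alt,
              ifelse(panel$anc[idx] == "alt", panel$n - alt, NA))
  as.numeric(d)
}

#' Allele frequencies: MAF and DAF
#'
#' @param panel a [haplotype_panel()].
#' @return data frame with `pos`, `alt_freq`, `maf` (minor allele
#'   frequency, in `[0, 0.5]`) and `daf` (derived allele frequency,
#'   `NA` where the ancestral state is unknown).
#' @export
allele_freqs <- function(panel) {
  p <- colMeans(panel$mat)
  daf <- ifelse(panel$anc == "ref", p,
                ifelse(panel$anc == "alt", 1 - p, NA))
  data.frame(pos = panel$pos, alt_freq = p, maf = pmin(p, 1 - p),
             daf = as.numeric(daf))
}

.tajima_consts <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# mean pairwise differences over the given SNP columns
.pi_hat <- function(panel, idx) {
  if (length(idx) == 0) return(0)
  c_alt <- colSums(panel$mat[, idx, drop = FALSE])
  n <- panel$n
  sum(2 * c_alt * (n - c_alt)) / (n * (n - 1))
}

#' Tajima's D for a window of a haplotype panel
#'
#' D contrasts mean pairwise diversity (pi) with Watterson's estimator
#' (S/a1), normalised by the standard variance estimate; significantly
#' negative values indicate an excess of rare variants, as after a
#' selective sweep; positive values an excess of intermediate-frequency
#' variants, as under balancing selection.
#'
#' @param panel a [haplotype_panel()].
#' @param window `c(start, end)` in panel position units (inclusive), or
#'   `NULL` for all SNPs.
#' @return list: `S`, `pi`, `theta_w`, `D` (`NA` with `defined = FALSE`
#'   when `S` = 0), `n`.
#' @export
tajima_d <- function(panel, window = NULL) {
  stopifnot(panel$n >= 4)
  idx <- .panel_window(panel, window)
  c_alt <- colSums(panel$mat[, idx, drop = FALSE])
  seg <- c_alt > 0 & c_alt < panel$n
  S <- sum(seg)
  pi <- .pi_hat(panel, idx)
  k <- .tajima_consts(panel$n)
  theta_w <- S / k$a1
  if (S == 0) {
    return(list(S = 0L, pi = pi, theta_w = 0, D = NA_real_, defined = FALSE,
                n = panel$n))
  }
  D <- (pi - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(S = as.integer(S), pi = pi, theta_w = theta_w, D = D, defined = TRUE,
       n = panel$n)
}

#' Fay and Wu's H for a window of a haplotype panel
#'
#' H = pi - theta_H, with theta_H = sum_i 2 S_i i^2 / (n(n-1)) over derived
#' allele counts i. Negative H marks an excess of high-frequency derived
#' alleles, the hitchhiking signature of a completed or ongoing sweep.
#' SNPs with unknown ancestral state are excluded.
#'
#' @inheritParams tajima_d
#' @return list: `S`, `pi`, `theta_H`, `H` (`NA` with `defined = FALSE`
#'   when no SNP has a known ancestral state), `n`.
#' @export
faywu_h <- function(panel, window = NULL) {
  idx <- .panel_window(panel, window)
  known <- idx[panel$anc[idx] != "unknown"]
  if (length(known) == 0) {
    return(list(S = 0L, pi = NA_real_, theta_H = NA_real_, H = NA_real_,
                defined = FALSE, n = panel$n))
  }
  d <- .derived_counts(panel, known)
  seg <- d > 0 & d < panel$n
  d <- d[seg]
  n <- panel$n
  pi <- sum(2 * d * (n - d)) / (n * (n - 1))
  theta_H <- sum(2 * d^2) / (n * (n - 1))
  list(S = length(d), pi = pi, theta_H = theta_H, H = pi - theta_H,
       defined = TRUE, n = n)
}

# Weir-Cockerham (1984) variance components for one SNP across 2+
# populations; haplotypes are paired in matrix order into diploids.
.wc_components <- function(panels, j_list) {
  r <- length(panels)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    m <- panels[[k]]$mat[, j_list[[k]], drop = TRUE]
    nh <- length(m)
    ni <- nh %/% 2
    g1 <- m[seq(1, 2 * ni, by = 2)]
    g2 <- m[seq(2, 2 * ni, by = 2)]
    n_i[k] <- ni
    p_i[k] <- mean(c(g1, g2))
    h_i[k] <- mean(g1 != g2)
  }
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_ <- h_bar / 2
  c(a = a, b = b, c = c_)
}

#' Weighted Weir-Cockerham Fst between two panels over a window
#'
#' Computes per-SNP variance components (a: among populations, b: among
#' individuals within populations, c: within individuals) for the SNPs the
#' two panels share in the window, and the weighted (ratio-of-sums)
#' estimator `sum(a) / sum(a + b + c)`. Phased haplotypes are paired in
#' order into diploid individuals.
#'
#' @param panel_a,panel_b two [haplotype_panel()]s.
#' @param window as in [tajima_d()].
#' @return list: `weighted_fst` (`NA` with `defined = FALSE` when no
#'   shared polymorphic SNP), `n_snps`, `components` (per-SNP matrix).
#' @export
weighted_fst <- function(panel_a, panel_b, window = NULL) {
  ia <- .panel_window(panel_a, window)
  ib <- .panel_window(panel_b, window)
  shared <- intersect(panel_a$pos[ia], panel_b$pos[ib])
  comp <- NULL
  for (p in shared) {
    ja <- which(panel_a$pos == p)[1]
    jb <- which(panel_b$pos == p)[1]
    fa <- mean(panel_a$mat[, ja]); fb <- mean(panel_b$mat[, jb])
    if ((fa == 0 && fb == 0) || (fa == 1 && fb == 1)) next
    comp <- rbind(comp, .wc_components(list(panel_a, panel_b), list(ja, jb)))
  }
  if (is.null(comp) || nrow(comp) == 0) {
    return(list(weighted_fst = NA_real_, defined = FALSE, n_snps = 0L,
                components = NULL))
  }
  wf <- sum(comp[, "a"]) / sum(comp[, "a"] + comp[, "b"] + comp[, "c"])
  list(weighted_fst = wf, defined = TRUE, n_snps = nrow(comp),
       components = comp)
}

#' Integrated Fst for a focal population
#'
#' Combines the three pairwise weighted Fst values of a three-population
#' comparison into one per-focal-population score. The default combiner is
#' the mean of the two pairwise values involving the focal population
#' (`"mean"`); `"max"` and `"pbs"` (population branch statistic on
#' -log(1 - Fst) branch lengths) are selectable.
#'
#' @param fst named numeric vector of the three pairwise weighted Fst
#'   values with names like `"CEU-YRI"`, `"CHB-YRI"`, `"CHB-CEU"`.
#' @param focal focal population id appearing in exactly two pair names.
#' @param combiner `"mean"`, `"max"` or `"pbs"`.
#' @return numeric (`NA` when any component is `NA`).
#' @export
integrated_fst <- function(fst, focal, combiner = c("mean", "max", "pbs")) {
  combiner <- match.arg(combiner)
  pairs <- strsplit(names(fst), "-", fixed = TRUE)
  inv <- vapply(pairs, function(p) focal %in% p, logical(1))
  if (sum(inv) != 2) stop("focal population must appear in exactly two pairs")
  if (anyNA(fst)) return(NA_real_)
  f <- fst[inv]
  switch(combiner,
    mean = mean(f),
    max  = max(f),
    pbs  = {
      t_ <- -log(pmax(1e-12, 1 - pmin(fst, 1 - 1e-12)))
      (sum(t_[inv]) - t_[!inv]) / 2
    })
}

#' Empirical genome-background threshold for a selection statistic
#'
#' @param stats numeric vector of the statistic over background windows
#'   (NA/undefined windows removed).
#' @param percentile tail mass, e.g. 0.10.
#' @param tail `"lower"` (Tajima's D style) or `"upper"` (Fst style).
#' @param min_windows minimum number of defined background windows.
#' @return list: `threshold`, `n_windows`.
#' @export
genome_background <- function(stats, percentile = 0.10,
                              tail = c("lower", "upper"),
                              min_windows = 100) {
  tail <- match.arg(tail)
  stats <- stats[!is.na(stats)]
  if (length(stats) < min_windows) {
    stop("too few background windows: ", length(stats))
  }
  thr <- stats::quantile(stats,
                         probs = if (tail == "lower") percentile else 1 - percentile,
                         names = FALSE)
  list(threshold = thr, n_windows = length(stats))
}

#' Joint positive-selection call from Tajima's D and integrated Fst
#'
#' A locus is called under positive selection in a focal population when
#' (1) its Tajima's D in that population is below the population's
#' genome-background threshold while D is positive (> 0) in the two other
#' populations, and (2) its integrated Fst exceeds the genome-background
#' Fst threshold. Calls in several populations simultaneously are allowed.
#'
#' @param d named numeric vector of Tajima's D per population.
#' @param fst_int named numeric vector of integrated Fst per focal
#'   population.
#' @param d_thresholds named numeric vector of per-population D
#'   thresholds (the study's genome-derived values were -0.97 for CEU,
#'   -0.96 for CHB and -0.97 for YRI).
#' @param fst_threshold integrated-Fst threshold (study value 0.22).
#' @return data frame: `population`, `is_positive`, `D`, `fst_int`.
#' @export
joint_selection_call <- function(d, fst_int, d_thresholds,
                                 fst_threshold = 0.22) {
  pops <- names(d)
  res <- lapply(pops, function(p) {
    others <- setdiff(pops, p)
    if (is.na(d[[p]]) || anyNA(d[others]) || is.na(fst_int[[p]])) {
      return(data.frame(population = p, is_positive = NA, D = d[[p]],
                        fst_int = fst_int[[p]]))
    }
    pos <- d[[p]] < d_thresholds[[p]] && all(d[others] > 0) &&
      fst_int[[p]] > fst_threshold
    data.frame(population = p, is_positive = pos, D = d[[p]],
               fst_int = fst_int[[p]])
  })
  do.call(rbind, res)
}

#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' @param panel a [haplotype_panel()].
#' @param i,j SNP column indices.
#' @return r-squared (`NA` when either SNP is monomorphic).
#' @export
ld_r2 <- function(panel, i, j) {
  x <- panel$mat[, i]; y <- panel$mat[, j]
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(x == 1 & y == 1)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' SNP count and density in a DBS interval
#'
#' @param panel a [haplotype_panel()].
#' @param interval `c(start, end)` inclusive positions of the DBS.
#' @param maf_min minimum minor allele frequency (default 0.1).
#' @return list: `count`, `per_base`.
#' @export
snp_density <- function(panel, interval, maf_min = 0.1) {
  stopifnot(interval[2] >= interval[1])
  af <- allele_freqs(panel)
  in_win <- af$pos >= interval[1] & af$pos <= interval[2]
  cnt <- sum(in_win & af$maf >= maf_min)
  len <- interval[2] - interval[1] + 1
  list(count = cnt, per_base = cnt / len)
}

#' Tile an interval into analysis windows
#'
#' Non-overlapping tiles of `size` bp; a partial terminal tile is kept
#' when it covers at least half the window size.
#'
#' @param start,end inclusive interval bounds.
#' @param size window size in bp (1500 for genes, 147 for DBSs).
#' @return matrix with columns `start`, `end`.
#' @export
tile_windows <- function(start, end, size) {
  starts <- seq(start, end, by = size)
  ends <- pmin(starts + size - 1, end)
  keep <- (ends - starts + 1) >= size / 2
  cbind(start = starts[keep], end = ends[keep])
}
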