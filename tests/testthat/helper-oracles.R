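# Independent reference implementations used as oracles. Deliberately
# written as direct enumerations / textbook formulas, sharing no code with
# the package internals they check.

oracle_codes <- function(seq) {
  match(chartr("U", "T", toupper(strsplit(seq, "")[[1]])),
        c("A", "C", "G", "T")) - 1L
}

# exhaustive enumeration of all equal-length substring pairs under the
# rule table, with the same qualification, per-diagonal containment and
# per-motif dominance definitions as the aligner
oracle_align <- function(rna_seq, dna_seq, ruleset, params) {
  out <- list()
  rna0 <- oracle_codes(rna_seq)
  dna <- oracle_codes(dna_seq)
  rna0[is.na(rna0)] <- -1L; dna[is.na(dna)] <- -1L
  for (motif in unique(ruleset$motif)) {
    rs <- ruleset[ruleset$motif == motif, ]
    lut <- matrix(FALSE, 4, 4)
    for (k in seq_len(nrow(rs))) {
      lut[oracle_codes(rs$rna[k]) + 1L, oracle_codes(rs$dna[k]) + 1L] <- TRUE
    }
    rna <- if (motif == "antiparallel") rev(rna0) else rna0
    n <- length(rna); m <- length(dna)
    wins <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        maxlen <- min(n - i, m - j) + 1L
        if (maxlen < params$min_nt) next
        for (len in params$min_nt:maxlen) {
          a <- rna[i:(i + len - 1)]; b <- dna[j:(j + len - 1)]
          valid <- a >= 0 & b >= 0
          paired <- valid & lut[cbind(a + 1L, b + 1L)]
          # must start/end on a paired position
          if (!paired[1] || !paired[len]) next
          sc <- sum(paired) +
            params$tt_penalty * sum(valid & a == 3 & b == 3 & !paired) +
            params$cc_penalty * sum(valid & a == 1 & b == 1 & !paired)
          if (100 * sc >= params$min_identity_percent * len) {
            wins <- rbind(wins, c(i - 1L, i + len - 1L, j - 1L, j + len - 1L,
                                  sum(paired)))
          }
        }
      }
    }
    if (is.null(wins)) next
    wins <- as.data.frame(wins)
    names(wins) <- c("rna_start", "rna_end", "dna_start", "dna_end", "np")
    # per-diagonal containment: drop windows contained in a longer
    # qualifying window on the same diagonal
    diag <- wins$dna_start - wins$rna_start
    keep <- vapply(seq_len(nrow(wins)), function(k) {
      same <- diag == diag[k]
      !any(same & wins$rna_start <= wins$rna_start[k] &
             wins$rna_end >= wins$rna_end[k] &
             (wins$rna_start < wins$rna_start[k] |
                wins$rna_end > wins$rna_end[k]))
    }, logical(1))
    wins <- wins[keep, , drop = FALSE]
    wins$identity <- 100 * wins$np / (wins$rna_end - wins$rna_start)
    # cross-diagonal dominance within the motif
    keep <- vapply(seq_len(nrow(wins)), function(k) {
      contained <- wins$rna_start <= wins$rna_start[k] &
        wins$rna_end >= wins$rna_end[k] &
        wins$dna_start <= wins$dna_start[k] &
        wins$dna_end >= wins$dna_end[k]
      strict <- wins$rna_start < wins$rna_start[k] |
        wins$rna_end > wins$rna_end[k] |
        wins$dna_start < wins$dna_start[k] | wins$dna_end > wins$dna_end[k]
      !any(contained & strict & wins$identity >= wins$identity[k])
    }, logical(1))
    wins <- wins[keep, , drop = FALSE]
    if (motif == "antiparallel" && nrow(wins) > 0) {
      rs_ <- length(rna0) - wins$rna_end
      re_ <- length(rna0) - wins$rna_start
      wins$rna_start <- rs_; wins$rna_end <- re_
    }
    wins$motif <- motif
    out[[motif]] <- wins
  }
  if (length(out) == 0) {
    return(data.frame(rna_start = integer(), rna_end = integer(),
                      dna_start = integer(), dna_end = integer(),
                      identity = numeric(), motif = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$dna_start, res$dna_end, res$rna_start, res$motif), ]
  rownames(res) <- NULL
  res[, c("rna_start", "rna_end", "dna_start", "dna_end", "identity",
          "motif")]
}

# textbook Tajima (1989) D by direct formula from a 0/1 matrix
oracle_tajima_d <- function(mat) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  seg <- cnt > 0 & cnt < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    pi <- pi + sum(mat[a, ] != mat[b, ])
  }
  pi <- pi / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fay & Wu H from derived counts (ancestral = 0 allele)
oracle_faywu_h <- function(mat) {
  n <- nrow(mat)
  d <- colSums(mat)
  d <- d[d > 0 & d < n]
  pi <- sum(sapply(d, function(i) 2 * i * (n - i))) / (n * (n - 1))
  th <- sum(sapply(d, function(i) 2 * i * i)) / (n * (n - 1))
  pi - th
}

# Weir & Cockerham (1984) weighted Fst for two populations of diploids
# (haplotypes paired in order), scalar arithmetic per SNP
oracle_wc_fst <- function(mat1, mat2) {
  r <- 2
  num <- den <- 0
  for (j in seq_len(ncol(mat1))) {
    f1 <- mean(mat1[, j]); f2 <- mean(mat2[, j])
    if ((f1 == 0 && f2 == 0) || (f1 == 1 && f2 == 1)) next
    stat <- lapply(list(mat1[, j], mat2[, j]), function(h) {
      ni <- length(h) %/% 2
      g <- matrix(h[1:(2 * ni)], ncol = 2, byrow = TRUE)
      list(n = ni, p = mean(g), h = mean(g[, 1] != g[, 2]))
    })
    ni <- sapply(stat, `[[`, "n"); pi_ <- sapply(stat, `[[`, "p")
    hi <- sapply(stat, `[[`, "h")
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_r2 <- function(x, y) {
  n <- length(x)
  p11 <- sum(x == 1 & y == 1) / n
  pa <- sum(x) / n; pb <- sum(y) / n
  D <- p11 - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# step-up Benjamini-Hochberg, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

# exact hypergeometric upper tail by summation of the pmf
oracle_hyper_tail <- function(q, K, N, n) {
  ks <- q:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# random haplotype panel for oracle-equivalence sweeps
random_panel <- function(n = 10, S = 10, seed = 1, L = 1000) {
  set.seed(seed)
  repeat {
    mat <- matrix(rbinom(n * S, 1, runif(1, 0.1, 0.5)), n, S)
    cs <- colSums(mat)
    keep <- cs > 0 & cs < n
    if (sum(keep) >= 2) break
  }
  haplotype_panel(mat[, keep, drop = FALSE],
                  sort(sample.int(L, sum(keep))),
                  rep("ref", sum(keep)))
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
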