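#' Triplex pairing rulesets
#'
#' RNA:DNA triplexes form when a single-stranded RNA (the third strand) lies
#' in the major groove of a DNA duplex and hydrogen-bonds to the purine-rich
#' strand. Which third-strand base can pair with which duplex purine depends
#' on the binding motif: in the *parallel* (Hoogsteen) motif the canonical
#' triplets are U.A-T and C.G-C; in the *antiparallel* (reverse-Hoogsteen)
#' motif they are A.A-T, G.G-C and U.A-T. The `"all"` preset adds a small,
#' documented table of non-canonical pairings (parallel G.G-C, antiparallel
#' A.G-C) and takes the union over both motifs. The tables are plain data
#' frames so alternative rule sets can be supplied.
#'
#' @param name one of `"parallel"`, `"antiparallel"`, `"all"`.
#' @return data frame with columns `rna`, `dna`, `motif`, `canonical`.
#'   `dna` is the base read on the duplex purine strand (`A` or `G`).
#' @examples
#' triplex_ruleset("parallel")
#' @export
triplex_ruleset <- function(name = c("all", "parallel", "antiparallel")) {
  name <- match.arg(name)
  canon <- data.frame(
    rna   = c("T", "C",  "A", "G", "T"),
    dna   = c("A", "G",  "A", "G", "A"),
    motif = c("parallel", "parallel",
              "antiparallel", "antiparallel", "antiparallel"),
    canonical = TRUE,
    stringsAsFactors = FALSE
  )
  ext <- data.frame(
    rna   = c("G", "A"),
    dna   = c("G", "G"),
    motif = c("parallel", "antiparallel"),
    canonical = FALSE,
    stringsAsFactors = FALSE
  )
  rs <- switch(name,
    parallel     = canon[canon$motif == "parallel", ],
    antiparallel = canon[canon$motif == "antiparallel", ],
    all          = rbind(canon, ext))
  rownames(rs) <- NULL
  attr(rs, "name") <- name
  rs
}

#' Triplex alignment parameters
#'
#' @param tt_penalty substitution score for a third-strand T over a duplex
#'   T (a pyrimidine interruption); the default -1000 effectively forbids
#'   any alignment containing one.
#' @param cc_penalty substitution score for a C over a duplex C; default 0
#'   (treated as an ordinary unpaired position).
#' @param offset maximum gap in bp when chaining overlapping/nearby TTSs
#'   into a DBS (and TFOs into a DBD).
#' @param min_identity_percent minimum identity (paired positions /
#'   aligned length x 100) for a reported TFO-TTS pair.
#' @param min_nt minimum aligned length in nt.
#' @return list of class `triplex_params`.
#' @export
triplex_params <- function(tt_penalty = -1000, cc_penalty = 0, offset = 15,
                           min_identity_percent = 60, min_nt = 50) {
  stopifnot(min_nt >= 1, min_identity_percent > 0, min_identity_percent <= 100,
            offset >= 0)
  structure(list(tt_penalty = tt_penalty, cc_penalty = cc_penalty,
                 offset = offset, min_identity_percent = min_identity_percent,
                 min_nt = min_nt), class = "triplex_params")
}

.base_code <- function(x) {
  # 0=A 1=C 2=G 3=T; anything else (ambiguity codes) -> -1, treated unpaired
  x <- chartr("U", "T", toupper(x))
  m <- match(x, c("A", "C", "G", "T"))
  ifelse(is.na(m), -1L, m - 1L)
}

.seq_codes <- function(seq) {
  .base_code(strsplit(seq, "", fixed = TRUE)[[1]])
}

.rule_lut <- function(ruleset, motif) {
  lut <- matrix(FALSE, 4, 4)
  rs <- ruleset[ruleset$motif == motif, , drop = FALSE]
  for (k in seq_len(nrow(rs))) {
    i <- .base_code(rs$rna[k]) + 1L
    j <- .base_code(rs$dna[k]) + 1L
    lut[i, j] <- TRUE
  }
  lut
}

#' Align an RNA against a DNA sequence under triplex pairing rules
#'
#' Performs ungapped local alignment of the RNA (third strand) against the
#' DNA read as the duplex purine strand, one binding motif at a time.
#' A position pairs when a ruleset rule matches; identity is the percentage
#' of paired positions over the aligned length. For the antiparallel motif
#' the RNA is reversed before alignment (reverse-Hoogsteen polarity) and
#' coordinates are mapped back. Reported alignments are the per-diagonal
#' maximal qualifying windows, trimmed so that both termini are paired
#' positions; a window qualifies when its length is at least `min_nt` and
#' its penalised score (paired = +1, T.T = `tt_penalty`, C.C =
#' `cc_penalty`, otherwise 0) is at least `min_identity_percent` per 100
#' positions. Within each motif, pairs whose RNA and DNA intervals are
#' both contained in a strictly larger pair of at least equal identity are
#' suppressed, so a perfect uninterrupted tract yields one pair.
#'
#' @param rna_seq,dna_seq character strings over A/C/G/T/U (ambiguity codes
#'   are treated as unpairable positions).
#' @param ruleset a rule table from [triplex_ruleset()] (or same shape).
#' @param params a [triplex_params()] object.
#' @return data frame of TFO-TTS pairs: `rna_start`, `rna_end`,
#'   `dna_start`, `dna_end` (0-based half-open), `length`,
#'   `identity_percent`, `motif`. Zero rows when nothing qualifies.
#' @export
align_triplex <- function(rna_seq, dna_seq, ruleset = triplex_ruleset("all"),
                          params = triplex_params()) {
  if (!nzchar(rna_seq) || !nzchar(dna_seq)) stop("empty sequence")
  rna <- .seq_codes(rna_seq)
  dna <- .seq_codes(dna_seq)
  out <- list()
  for (motif in unique(ruleset$motif)) {
    lut <- .rule_lut(ruleset, motif)
    rseq <- if (motif == "antiparallel") rev(rna) else rna
    df <- triplex_scan_cpp(rseq, dna, lut,
                           params$tt_penalty, params$cc_penalty,
                           params$min_nt, params$min_identity_percent)
    if (nrow(df) == 0) next
    if (motif == "antiparallel") {
      n <- length(rna)
      rs <- n - df$rna_end
      re <- n - df$rna_start
      df$rna_start <- rs
      df$rna_end <- re
    }
    df$length <- df$dna_end - df$dna_start
    df$identity_percent <- 100 * df$n_paired / df$length
    df <- df[.dominant_pairs(df), , drop = FALSE]
    df$motif <- motif
    out[[motif]] <- df[, c("rna_start", "rna_end", "dna_start", "dna_end",
                           "length", "identity_percent", "motif")]
  }
  if (length(out) == 0) {
    return(data.frame(rna_start = integer(), rna_end = integer(),
                      dna_start = integer(), dna_end = integer(),
                      length = integer(), identity_percent = numeric(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$dna_start, res$dna_end, res$rna_start, res$motif), ]
  rownames(res) <- NULL
  res
}

# drop pairs whose RNA and DNA intervals are both contained in those of a
# strictly larger pair with at least equal identity (within one motif)
.dominant_pairs <- function(df) {
  n <- nrow(df)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    contained <- df$rna_start <= df$rna_start[i] &
      df$rna_end >= df$rna_end[i] &
      df$dna_start <= df$dna_start[i] & df$dna_end >= df$dna_end[i]
    strict <- df$rna_start < df$rna_start[i] | df$rna_end > df$rna_end[i] |
      df$dna_start < df$dna_start[i] | df$dna_end > df$dna_end[i]
    if (any(contained & strict &
              df$identity_percent >= df$identity_percent[i])) {
      keep[i] <- FALSE
    }
  }
  keep
}

# chain intervals (0-based half-open) whose gap is <= offset; returns a
# cluster id per row
.chain_intervals <- function(start, end, offset) {
  o <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L; curmax <- -Inf
  for (k in o) {
    if (start[k] > curmax + offset) cur <- cur + 1L
    cl[k] <- cur
    curmax <- max(curmax, end[k])
  }
  cl
}

#' Cluster TFO-TTS pairs into DBSs (DNA side) or DBDs (RNA side)
#'
#' TTSs are chained into one DNA-binding site (DBS) when their DNA
#' intervals overlap or lie within `offset` bp of each other; the DBS span
#' is the union hull and its identity the unweighted mean of member
#' identities. [cluster_tfo()] applies the same chaining to the RNA
#' intervals to form DNA-binding domains (DBDs).
#'
#' @param pairs data frame from [align_triplex()] (one lncRNA-promoter
#'   scan for [cluster_tts()]; all scans of one lncRNA for [cluster_tfo()]).
#' @param params a [triplex_params()] object (uses `offset`).
#' @return data frame with one row per cluster: `start`, `end`, `length`,
#'   `n_members`, `mean_identity_percent`, plus `members` (list of row
#'   indices into `pairs`).
#' @export
cluster_tts <- function(pairs, params = triplex_params()) {
  .cluster_side(pairs, "dna_start", "dna_end", params$offset)
}

#' @rdname cluster_tts
#' @export
cluster_tfo <- function(pairs, params = triplex_params()) {
  .cluster_side(pairs, "rna_start", "rna_end", params$offset)
}

.cluster_side <- function(pairs, scol, ecol, offset) {
  if (nrow(pairs) == 0) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      n_members = integer(), mean_identity_percent = numeric()))
  }
  cl <- .chain_intervals(pairs[[scol]], pairs[[ecol]], offset)
  res <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), cl), function(idx) {
    data.frame(start = min(pairs[[scol]][idx]),
               end = max(pairs[[ecol]][idx]),
               length = max(pairs[[ecol]][idx]) - min(pairs[[scol]][idx]),
               n_members = length(idx),
               mean_identity_percent = mean(pairs$identity_percent[idx]))
  }))
  res$members <- split(seq_len(nrow(pairs)), cl)
  res <- res[order(res$start), ]
  rownames(res) <- NULL
  res
}

#' Score and classify DBSs by binding affinity
#'
#' Binding affinity is the product of DBS length and the averaged identity
#' score of its member TTSs (identity expressed as a fraction, so a 147 bp
#' DBS at 60% identity has affinity 88.2). DBSs with affinity >= 60 are
#' `strong`, those with 36 < affinity < 60 are `weak`, the rest
#' `subthreshold`.
#'
#' @param dbs data frame with `length` and `mean_identity_percent` columns
#'   (e.g. from [cluster_tts()]).
#' @param strong_min,weak_min class boundaries (defaults 60 and 36).
#' @return `dbs` with `affinity` and `class` columns added.
#' @export
score_and_classify <- function(dbs, strong_min = 60, weak_min = 36) {
  dbs$affinity <- dbs$length * dbs$mean_identity_percent / 100
  dbs$class <- ifelse(dbs$affinity >= strong_min, "strong",
                      ifelse(dbs$affinity > weak_min, "weak", "subthreshold"))
  dbs
}

#' Extract strand-oriented promoter windows
#'
#' The promoter of a transcript is the window from 3500 bp upstream to
#' 1500 bp downstream of the transcription start site (5000 bp total),
#' read 5'->3' on the transcript's strand (minus-strand promoters are
#' reverse-complemented).
#'
#' @param genome named character vector (or `Biostrings::DNAStringSet`) of
#'   contig sequences.
#' @param annotation data frame with `gene_id`, `transcript_id`, `chrom`,
#'   `tss` (1-based position of the TSS), `strand` (`+`/`-`).
#' @param upstream,downstream window extent in bp around the TSS.
#' @return data frame `transcript_id`, `chrom`, `start`, `end` (0-based
#'   half-open, reference orientation), `strand`, `sequence`.
#' @export
promoter_windows <- function(genome, annotation,
                             upstream = 3500, downstream = 1500) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  rows <- lapply(seq_len(nrow(annotation)), function(k) {
    a <- annotation[k, ]
    contig <- genome[[a$chrom]]
    tss0 <- a$tss - 1L  # 0-based
    if (a$strand == "+") {
      s <- tss0 - upstream; e <- tss0 + downstream
    } else {
      s <- tss0 - downstream + 1L; e <- tss0 + upstream + 1L
    }
    if (s < 0 || e > nchar(contig)) {
      warning("promoter window for ", a$transcript_id,
              " falls outside contig; skipped")
      return(NULL)
    }
    seq <- substr(contig, s + 1L, e)
    if (a$strand == "-") seq <- .revcomp(seq)
    data.frame(transcript_id = a$transcript_id, chrom = a$chrom,
               start = s, end = e, strand = a$strand, sequence = seq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan promoters for lncRNA DBSs
#'
#' Runs the triplex aligner for every (lncRNA, transcript promoter) pair,
#' clusters TTSs into DBSs and TFOs into DBDs, scores affinities and
#' classifies DBSs. DBS promoter coordinates are 0-based half-open in the
#' strand-oriented promoter; genome coordinates (`g_start`, `g_end`) are
#' 0-based half-open on the reference strand.
#'
#' @param lncrnas named character vector of lncRNA sequences.
#' @param annotation,genome as for [promoter_windows()].
#' @param ruleset,params aligner configuration.
#' @param upstream,downstream promoter extent.
#' @return list with `dbs` (one row per lncRNA x transcript x DBS; columns
#'   `lncrna_id`, `transcript_id`, `chrom`, `start`, `end`, `g_start`,
#'   `g_end`, `strand`, `length`, `mean_identity_percent`, `affinity`,
#'   `class`, `dbd_id`) and `dbd` (per-lncRNA DBD table with genome-wide
#'   DBS counts and ranks).
#' @export
scan_promoters <- function(lncrnas, annotation, genome,
                           ruleset = triplex_ruleset("all"),
                           params = triplex_params(),
                           upstream = 3500, downstream = 1500) {
  prom <- promoter_windows(genome, annotation, upstream, downstream)
  all_pairs <- list()
  dbs_rows <- list()
  for (ln in names(lncrnas)) {
    for (k in seq_len(nrow(prom))) {
      pr <- prom[k, ]
      pairs <- align_triplex(lncrnas[[ln]], pr$sequence, ruleset, params)
      if (nrow(pairs) == 0) next
      pairs$lncrna_id <- ln
      pairs$transcript_id <- pr$transcript_id
      cl <- cluster_tts(pairs, params)
      cl <- score_and_classify(cl)
      # genome coordinates of the DBS span
      if (pr$strand == "+") {
        gs <- pr$start + cl$start; ge <- pr$start + cl$end
      } else {
        gs <- pr$end - cl$end; ge <- pr$end - cl$start
      }
      dbs_rows[[length(dbs_rows) + 1L]] <- data.frame(
        lncrna_id = ln, transcript_id = pr$transcript_id, chrom = pr$chrom,
        start = cl$start, end = cl$end, g_start = gs, g_end = ge,
        strand = pr$strand, length = cl$length,
        mean_identity_percent = cl$mean_identity_percent,
        affinity = cl$affinity, class = cl$class,
        rna_anchor = vapply(cl$members, function(i) {
          # median member RNA start: links the DBS to its DBD
          as.integer(stats::median(pairs$rna_start[i]))
        }, integer(1)),
        stringsAsFactors = FALSE)
      all_pairs[[length(all_pairs) + 1L]] <- pairs
    }
  }
  if (length(dbs_rows) == 0) {
    return(list(dbs = data.frame(), dbd = data.frame()))
  }
  dbs <- do.call(rbind, dbs_rows)
  pairs_all <- do.call(rbind, all_pairs)
  dbd <- .build_dbds(pairs_all, dbs, params)
  dbs$dbd_id <- dbd$assign[seq_len(nrow(dbs))]
  list(dbs = dbs, dbd = dbd$table)
}

# cluster TFOs per lncRNA across all promoters; assign each DBS to the DBD
# covering its rna_anchor
.build_dbds <- function(pairs_all, dbs, params) {
  assign <- character(nrow(dbs))
  tabs <- list()
  for (ln in unique(dbs$lncrna_id)) {
    p <- pairs_all[pairs_all$lncrna_id == ln, , drop = FALSE]
    cl <- cluster_tfo(p, params)
    cl$lncrna_id <- ln
    cl$dbd_id <- paste0(ln, ":DBD", seq_len(nrow(cl)))
    idx <- which(dbs$lncrna_id == ln)
    for (i in idx) {
      a <- dbs$rna_anchor[i]
      hit <- which(cl$start <= a & a < cl$end)
      if (length(hit) == 0) hit <- which.min(pmin(abs(cl$start - a), abs(cl$end - a)))
      assign[i] <- cl$dbd_id[hit[1]]
    }
    tabs[[ln]] <- cl
  }
  tab <- do.call(rbind, tabs)
  tab$n_dbs <- vapply(tab$dbd_id, function(d) sum(assign == d), integer(1))
  tab$sum_affinity <- vapply(tab$dbd_id, function(d) sum(dbs$affinity[assign == d]),
                             numeric(1))
  tab$members <- NULL
  rownames(tab) <- NULL
  list(table = tab, assign = assign)
}

#' Select the top-ranked DBD (DBD1) of a lncRNA
#'
#' DBD1 is the DBD with the most genome-wide DBSs; ties are broken by the
#' larger summed DBS affinity, then by the 5'-most RNA span.
#'
#' @param dbd_table the `dbd` table from [scan_promoters()] (optionally
#'   filtered to one lncRNA).
#' @return the selected row of `dbd_table`.
#' @export
select_dbd1 <- function(dbd_table) {
  stopifnot(nrow(dbd_table) >= 1)
  o <- order(-dbd_table$n_dbs, -dbd_table$sum_affinity, dbd_table$start)
  dbd_table[o[1], , drop = FALSE]
}
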