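#' Read and write the pipeline's plain-text formats
#'
#' Thin wrappers around the standard formats the pipeline consumes and
#' emits: FASTA (via Biostrings), a minimal VCF 4.2 subset with phased
#' genotypes, tab-separated annotation/expression tables, and GMT pathway
#' files.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @name lncevo-io
NULL

#' @rdname lncevo-io
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname lncevo-io
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @param panel a [haplotype_panel()]; haplotypes are paired in order into
#'   diploid samples with phased genotypes.
#' @param chrom contig name written in the CHROM column.
#' @param ref_base,alt_base single characters (or vectors) for REF/ALT.
#' @param qual QUAL value(s).
#' @rdname lncevo-io
#' @export
write_simple_vcf <- function(panel, path, chrom = "chr1",
                             ref_base = "A", alt_base = "G", qual = 100) {
  n_ind <- panel$n %/% 2
  stopifnot(n_ind >= 1)
  samples <- sprintf("S%03d", seq_len(n_ind))
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  nsnp <- length(panel$pos)
  ref <- rep_len(ref_base, nsnp); alt <- rep_len(alt_base, nsnp)
  qual <- rep_len(qual, nsnp)
  aa <- ifelse(panel$anc == "ref", ref, ifelse(panel$anc == "alt", alt, "."))
  lines <- vapply(seq_len(nsnp), function(j) {
    h <- panel$mat[, j]
    gt <- paste0(h[seq(1, 2 * n_ind, 2)], "|", h[seq(2, 2 * n_ind, 2)])
    paste(c(chrom, panel$pos[j], paste0("snp", j), ref[j], alt[j], qual[j],
            "PASS", paste0("AA=", aa[j]), "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname lncevo-io
#' @export
read_simple_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  stopifnot(length(hdr) == 1)
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  body <- lines[-seq_len(hdr)]
  if (length(body) == 0) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols))
  } else {
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            colClasses = "character")
  }
  names(df)[1:9] <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter",
                      "info", "format")
  df$pos <- as.integer(df$pos)
  df$qual <- suppressWarnings(as.numeric(df$qual))
  if (any(diff(df$pos) < 0)) {
    bad <- which(diff(df$pos) < 0)[1] + 1
    stop("VCF not sorted at record ", bad, " (pos ", df$pos[bad], ")")
  }
  df
}

#' Convert a VCF table back to a haplotype panel
#'
#' @param vcf table from [read_simple_vcf()].
#' @rdname lncevo-io
#' @export
vcf_to_panel <- function(vcf) {
  gt_cols <- setdiff(names(vcf), c("chrom", "pos", "id", "ref", "alt",
                                   "qual", "filter", "info", "format"))
  mat <- do.call(rbind, lapply(gt_cols, function(s) {
    g <- strsplit(vcf[[s]], "|", fixed = TRUE)
    rbind(as.integer(vapply(g, `[`, "", 1)), as.integer(vapply(g, `[`, "", 2)))
  }))
  aa <- sub("^AA=", "", vcf$info)
  anc <- ifelse(aa == vcf$ref, "ref", ifelse(aa == vcf$alt, "alt", "unknown"))
  haplotype_panel(mat, vcf$pos, anc)
}

#' @param pathways named list of character vectors for [write_gmt()].
#' @rdname lncevo-io
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(p) {
    paste(c(p, "na", pathways[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname lncevo-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  out
}
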