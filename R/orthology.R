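#' Ortholog and human-specific lncRNA gene calls from exon-hit tables
#'
#' A lncRNA gene is considered to have an ortholog in a genome when the
#' number of its exons with orthologous hits in that genome strictly
#' exceeds half of the gene's exon count. A gene with no ortholog in any
#' of the queried genomes (classically the 16 non-human mammals) is called
#' human-specific (HS).
#'
#' @param hits data frame with columns `gene_id`, `exon_id`, `genome_id`,
#'   `hit` (logical): one row per (human exon, genome) query.
#' @param exon_counts named integer vector: exons per gene. When `NULL`,
#'   derived as the number of distinct `exon_id` per gene in `hits`.
#' @param gene,genome a single gene and genome id for [call_ortholog()].
#' @return [call_ortholog()]: logical. [call_hs_genes()]: character vector
#'   of HS gene ids.
#' @examples
#' h <- expand.grid(gene_id = "g1", exon_id = paste0("e", 1:4),
#'                  genome_id = "mouse", stringsAsFactors = FALSE)
#' h$hit <- c(TRUE, TRUE, TRUE, FALSE)
#' call_ortholog("g1", "mouse", h)   # 3 of 4 exons hit -> TRUE
#' @export
call_ortholog <- function(gene, genome, hits, exon_counts = NULL) {
  g <- hits[hits$gene_id == gene, , drop = FALSE]
  if (nrow(g) == 0) stop("gene not in hit table: ", gene)
  if (!genome %in% g$genome_id) stop("unknown genome id: ", genome)
  n_exons <- if (is.null(exon_counts)) length(unique(g$exon_id)) else
    exon_counts[[gene]]
  gg <- g[g$genome_id == genome, , drop = FALSE]
  n_hit <- length(unique(gg$exon_id[gg$hit]))
  n_hit > n_exons / 2
}

#' @param genomes character vector of genome ids that every gene must have
#'   been queried against; a gene missing any of them is an error, never
#'   silently treated as "no ortholog".
#' @rdname call_ortholog
#' @export
call_hs_genes <- function(hits, genomes, exon_counts = NULL) {
  genes <- unique(hits$gene_id)
  hs <- character(0)
  for (g in genes) {
    sub <- hits[hits$gene_id == g, , drop = FALSE]
    missing <- setdiff(genomes, unique(sub$genome_id))
    if (length(missing) > 0) {
      stop("gene ", g, " lacks hit rows for genome(s): ",
           paste(missing, collapse = ", "))
    }
    any_orth <- any(vapply(genomes, function(gm)
      call_ortholog(g, gm, hits, exon_counts), logical(1)))
    if (!any_orth) hs <- c(hs, g)
  }
  hs
}
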