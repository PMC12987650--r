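#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis, defaulting to the
#' study's printed values: 5000 bp promoters (-3500/+1500 around the TSS),
#' affinity classes 60/36, age thresholds 0.034 (old/young) and 0.037
#' (epoch flags), MAF cutoffs 0.05/0.1, cis-effect size 0.5, Spearman rho
#' 0.3, FDR levels 0.05 (pairs), 0.001 (tissue shifts), 0.01 (module
#' enrichment), window sizes 1500 bp (genes) and 147 bp (DBSs), and the
#' eGRAM defaults (affinity 60, Pearson 0.5, module size 50, FDR 0.01).
#' The configuration (and its hash) is embedded in every result bundle.
#'
#' @param seed master seed for all stochastic stages.
#' @param stages character vector of stages to run, in dependency order;
#'   subset of `c("simulate", "predict_dbs", "hs_call", "compare",
#'   "popgen", "expression", "egram")`.
#' @param sim a [sim_config()] for the `simulate` stage.
#' @param ... named overrides of the threshold defaults listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("simulate", "predict_dbs", "hs_call",
                                       "compare", "popgen", "expression",
                                       "egram"),
                            sim = NULL, ...) {
  defaults <- list(
    upstream = 3500, downstream = 1500,
    affinity_strong = 60, affinity_weak = 36,
    age_min = 0.034, epoch_min = 0.037, epoch_top_frac = 0.20,
    maf_common = 0.05, maf_eqtl = 0.1, es_min = 0.5,
    rho_min = 0.3, fdr_pairs = 0.05, fdr_shift = 0.001, fdr_enrich = 0.01,
    window_gene = 1500, window_dbs = 147,
    bg_percentile = 0.10, fst_threshold = NA, d_thresholds = NA,
    egram = list(affinity_min = 60, pearson_min = 0.5, module_size = 50,
                 enrich_fdr = 0.01),
    n_random_pairs = 1000, min_identity = 60, min_nt = 50, offset = 15)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (is.null(sim)) {
    sim <- sim_config(seed = seed, n_genes = 8, theta = 0.002,
                      sweep_spec = list(window = NULL, focal = "CEU"),
                      expr_spec = list(
                        n_modules = 2, module_size = 55, n_background = 120,
                        loading = 1, noise_sd = 0.3,
                        tissues = c("brain", "liver", "lung"),
                        samples_per_tissue = 60,
                        eqtl = data.frame(gene = c("GENE0001", "GENE0060"),
                                          effect = c(0.5, 0.5),
                                          maf = c(0.3, 0.3))))
  }
  structure(c(list(seed = seed, stages = stages, sim = sim), defaults),
            class = "pipeline_config")
}

#' Content hash of an R object (stable across runs)
#'
#' MD5 of the version-3 serialisation; identical objects hash identically
#' across sessions of the same R version.
#'
#' @param x any serialisable object.
#' @return 32-character hex string.
#' @export
stable_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3), f)
  unname(tools::md5sum(f))
}

#' Serialise / load a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path file path (JSON).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$sim)) {
    x$sim <- structure(x$sim, class = "sim_config")
  }
  structure(x, class = "pipeline_config")
}

#' Generate a synthetic ortholog exon-hit table
#'
#' Emulates the exon-level ortholog search output over a set of genomes:
#' designated human-specific genes receive at most `exon_count / 2` exon
#' hits in every genome (so the strict majority rule never fires), other
#' genes receive a clear majority of hits in at least one genome.
#'
#' @param gene_ids character vector of gene ids.
#' @param hs_genes subset of `gene_ids` to make human-specific.
#' @param genomes genome ids (classically 16 mammals).
#' @param exon_count exons per gene.
#' @param seed RNG seed.
#' @return data frame usable with [call_hs_genes()].
#' @export
gen_ortholog_hits <- function(gene_ids, hs_genes, genomes, exon_count = 4,
                              seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in gene_ids) {
    for (gm in genomes) {
      n_hit <- if (g %in% hs_genes) {
        sample.int(floor(exon_count / 2) + 1L, 1) - 1L  # 0..floor(half)
      } else {
        sample(seq(floor(exon_count / 2) + 1L, exon_count), 1)
      }
      hit <- c(rep(TRUE, n_hit), rep(FALSE, exon_count - n_hit))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, exon_id = sprintf("%s_e%d", g, seq_len(exon_count)),
        genome_id = gm, hit = hit, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate pipeline input files
#'
#' Checks well-formedness of the standard inputs: FASTA readability, VCF
#' record sorting, annotation TSS positions inside their contig, tissue
#' labels covering every expression sample, GMT line structure.
#'
#' @param paths named list; any of `fasta`, `vcf`, `annotation` (TSV with
#'   `chrom`, `tss`), `tpm` (TSV matrix), `tissue_map` (TSV sample,
#'   tissue), `gmt`.
#' @return character vector of problems (empty when all inputs are clean).
#' @export
validate_inputs <- function(paths) {
  problems <- character(0)
  genome <- NULL
  if (!is.null(paths$fasta)) {
    genome <- tryCatch(read_fasta(paths$fasta), error = function(e) {
      problems <<- c(problems, paste("fasta:", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(paths$vcf)) {
    tryCatch(invisible(read_simple_vcf(paths$vcf)), error = function(e)
      problems <<- c(problems, paste("vcf:", conditionMessage(e))))
  }
  if (!is.null(paths$annotation)) {
    ann <- utils::read.delim(paths$annotation, stringsAsFactors = FALSE)
    if (!all(c("chrom", "tss") %in% names(ann))) {
      problems <- c(problems, "annotation: missing chrom/tss columns")
    } else if (!is.null(genome)) {
      for (k in seq_len(nrow(ann))) {
        if (!ann$chrom[k] %in% names(genome)) {
          problems <- c(problems,
                        sprintf("annotation row %d: unknown contig %s", k,
                                ann$chrom[k]))
        } else if (ann$tss[k] < 1 ||
                   ann$tss[k] > nchar(genome[[ann$chrom[k]]])) {
          problems <- c(problems,
                        sprintf("annotation row %d: TSS %d outside contig",
                                k, ann$tss[k]))
        }
      }
    }
  }
  if (!is.null(paths$tpm) && !is.null(paths$tissue_map)) {
    tpm <- utils::read.delim(paths$tpm, check.names = FALSE)
    tm <- utils::read.delim(paths$tissue_map, stringsAsFactors = FALSE)
    miss <- setdiff(colnames(tpm), tm[[1]])
    if (length(miss)) {
      problems <- c(problems, paste("tissue_map: unlabelled samples:",
                                    paste(miss, collapse = ",")))
    }
  }
  if (!is.null(paths$gmt)) {
    ln <- readLines(paths$gmt)
    nf <- lengths(strsplit(ln, "\t"))
    if (any(nf < 3)) {
      problems <- c(problems, sprintf("gmt: line %d has < 3 fields",
                                      which(nf < 3)[1]))
    }
  }
  problems
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on generator-produced
#' inputs: simulate the genome/populations/expression data, predict DBSs
#' by triplex alignment, call human-specific genes from the synthetic
#' ortholog hit table, build chimp/archaic counterparts and distances with
#' age labels, run the window selection scan with the joint decision rule,
#' run the expression-impact statistics, and discover regulatory modules
#' with pathway enrichment. Rerunning with the same configuration
#' reproduces identical outputs (`result$hash`).
#'
#' @param config a [pipeline_config()].
#' @return list of per-stage results plus `config`, `config_hash` and
#'   `hash` (hash of all stage outputs).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  all_stages <- c("simulate", "predict_dbs", "hs_call", "compare", "popgen",
                  "expression", "egram")
  stages <- config$stages
  deps <- list(predict_dbs = "simulate", hs_call = "simulate",
               compare = "predict_dbs", popgen = "simulate",
               expression = c("compare", "egram_inputs"),
               egram = "simulate")
  for (s in intersect(stages, names(deps))) {
    need <- intersect(deps[[s]], all_stages)
    if (!all(need %in% stages)) {
      stop("stage '", s, "' requires stage(s): ",
           paste(setdiff(need, stages), collapse = ", "))
    }
  }
  res <- list(config = config, config_hash = stable_hash(unclass(config)))
  cfg <- config$sim
  params <- triplex_params(offset = config$offset,
                           min_identity_percent = config$min_identity,
                           min_nt = config$min_nt)

  ## -- simulate ------------------------------------------------------
  g <- gen_genome(cfg)
  dbd_rna <- gen_dbd_rna(len = 200, seed = cfg$seed)
  plan <- data.frame(gene_id = g$annotation$gene_id[1:4],
                     length = c(150, 150, 120, 100),
                     identity = c(1, 0.9, 0.85, 0.8))
  pl <- plant_triplex_sites(g$genome, g$annotation, dbd_rna, plan, cfg)
  genome <- pl$genome
  if (!is.null(cfg$sweep_spec) && is.null(cfg$sweep_spec$window)) {
    # default sweep target: the first planted DBS interval
    cfg$sweep_spec$window <- c(pl$truth$g_start[1] + 1, pl$truth$g_end[1])
  }
  panels <- gen_population(cfg, region = c(1, nchar(genome[[1]])))
  res$simulate <- list(annotation = g$annotation, truth = pl$truth,
                       n_snps = length(panels[[1]]$pos))
  message("simulate: ", cfg$n_genes, " genes, ", length(panels[[1]]$pos),
          " SNPs x ", length(panels), " population(s)")

  ## -- predict_dbs ---------------------------------------------------
  if (!"predict_dbs" %in% stages) {
    res$hash <- stable_hash(res[setdiff(names(res), "config")])
    return(res)
  }
  scan <- scan_promoters(c(LNC01 = dbd_rna), g$annotation, genome,
                         params = params,
                         upstream = config$upstream,
                         downstream = config$downstream)
  dbs <- scan$dbs
  res$predict_dbs <- list(dbs = dbs, dbd = scan$dbd,
                          dbd1 = if (nrow(scan$dbd)) select_dbd1(scan$dbd))
  message("predict_dbs: ", nrow(dbs), " DBSs (",
          sum(dbs$class == "strong"), " strong)")

  ## -- hs_call -------------------------------------------------------
  if ("hs_call" %in% stages) {
    genomes16 <- paste0("genome", sprintf("%02d", 1:16))
    hs_true <- g$annotation$gene_id[1:2]
    hits <- gen_ortholog_hits(g$annotation$gene_id, hs_true, genomes16,
                              seed = cfg$seed)
    res$hs_call <- list(hs_genes = call_hs_genes(hits, genomes16),
                        planted = hs_true)
    message("hs_call: ", length(res$hs_call$hs_genes), " HS gene(s)")
  }

  ## -- compare -------------------------------------------------------
  strong <- dbs[dbs$class == "strong", , drop = FALSE]
  if ("compare" %in% stages && nrow(strong) > 0) {
    ids <- sprintf("DBS%03d", seq_len(nrow(strong)))
    seqs <- setNames(substring(genome[[1]], strong$g_start + 1,
                               strong$g_end), ids)
    del <- ids[length(ids)]
    cps <- list(
      chimp = gen_counterparts(seqs, cfg$divergence_chimp,
                               seed = cfg$seed + 11, delete = del),
      altai = gen_counterparts(seqs, cfg$divergence_archaic,
                               seed = cfg$seed + 12),
      denisovan = gen_counterparts(seqs, cfg$divergence_archaic,
                                   seed = cfg$seed + 13),
      vindija = gen_counterparts(seqs, cfg$divergence_archaic,
                                 seed = cfg$seed + 14))
    K <- sapply(names(cps), function(gm)
      vapply(ids, function(i) dbs_distance(seqs[[i]], cps[[gm]][[i]]),
             numeric(1)))
    dist_tab <- data.frame(dbs = ids, K, row.names = NULL)
    dist_tab$age <- classify_age(dist_tab$chimp, dist_tab$altai,
                                 dist_tab$denisovan,
                                 age_min = config$age_min)
    dist_tab$epoch <- flag_epochs(dist_tab$chimp, dist_tab$altai,
                                  dist_tab$denisovan, dist_tab$vindija,
                                  top_frac = config$epoch_top_frac,
                                  epoch_min = config$epoch_min)
    res$compare <- list(distances = dist_tab, deleted = del,
                        counterparts = cps, dbs_seqs = seqs,
                        strong = strong)
    message("compare: ", nrow(dist_tab), " DBS counterpart records")
  }

  ## -- popgen --------------------------------------------------------
  if ("popgen" %in% stages) {
    res$popgen <- .popgen_stage(panels, strong, cfg, config)
    message("popgen: ", nrow(res$popgen$windows), " windows, ",
            sum(res$popgen$calls$is_positive, na.rm = TRUE),
            " positive call(s)")
  }

  ## -- expression + egram --------------------------------------------
  if (any(c("expression", "egram") %in% stages) && !is.null(cfg$expr_spec)) {
    ex <- gen_expression(cfg$expr_spec, seed = cfg$seed)
    if ("expression" %in% stages) {
      res$expression <- .expression_stage(ex, res$compare, config)
      message("expression: ",
              sum(res$expression$pairs$significant), " / ",
              nrow(res$expression$pairs), " significant pair-tissue tests")
    }
    if ("egram" %in% stages) {
      res$egram <- .egram_stage(ex, config, cfg)
      message("egram: ", length(res$egram$modules), " module(s)")
    }
  }
  res$hash <- stable_hash(res[setdiff(names(res), c("config"))])
  res
}

.popgen_stage <- function(panels, strong, cfg, config) {
  pops <- names(panels)
  region <- c(1, max(panels[[1]]$pos))
  tiles <- tile_windows(region[1], region[2], config$window_dbs)
  wrows <- list()
  for (w in seq_len(nrow(tiles))) {
    win <- tiles[w, ]
    d <- vapply(pops, function(p) tajima_d(panels[[p]], win)$D, numeric(1))
    fst <- c()
    if (length(pops) >= 3) {
      prs <- utils::combn(pops, 2)
      fst <- apply(prs, 2, function(pr)
        weighted_fst(panels[[pr[1]]], panels[[pr[2]]], win)$weighted_fst)
      names(fst) <- apply(prs, 2, paste, collapse = "-")
    }
    fint <- if (length(fst)) vapply(pops, function(p)
      integrated_fst(fst, p), numeric(1)) else setNames(rep(NA, length(pops)),
                                                        pops)
    row <- c(start = unname(win[1]), end = unname(win[2]),
             stats::setNames(d, paste0("D_", pops)),
             stats::setNames(as.numeric(fint), paste0("fint_", pops)))
    wrows[[w]] <- as.data.frame(as.list(row), check.names = FALSE)
  }
  windows <- do.call(rbind, wrows)
  d_thr <- vapply(pops, function(p)
    genome_background(windows[[paste0("D_", p)]], config$bg_percentile,
                      "lower", min_windows = 20)$threshold, numeric(1))
  f_all <- unlist(windows[paste0("fint_", pops)])
  f_thr <- genome_background(f_all, config$bg_percentile, "upper",
                             min_windows = 20)$threshold
  calls <- do.call(rbind, lapply(seq_len(nrow(windows)), function(w) {
    d <- setNames(as.numeric(windows[w, paste0("D_", pops)]), pops)
    fi <- setNames(as.numeric(windows[w, paste0("fint_", pops)]), pops)
    cl <- joint_selection_call(d, fi, d_thr, f_thr)
    cl$start <- windows$start[w]; cl$end <- windows$end[w]
    cl
  }))
  list(windows = windows, d_thresholds = d_thr, fst_threshold = f_thr,
       calls = calls)
}

.expression_stage <- function(ex, compare, config) {
  regs <- names(ex$modules)
  targets <- unlist(ex$modules, use.names = FALSE)
  pairs <- data.frame(lncrna_id = rep(regs, lengths(ex$modules)),
                      target_id = targets, stringsAsFactors = FALSE)
  pc <- pair_correlations(pairs, ex$tpm, ex$tissues,
                          rho_min = config$rho_min,
                          fdr_max = config$fdr_pairs)
  # random-pair background emulates genome-wide lncRNA x coding pairs,
  # the vast majority of which are unregulated: draw targets outside the
  # planted modules
  all_genes <- setdiff(rownames(ex$tpm), c(regs, targets))
  rp <- random_pair_background(regs, all_genes, ex$tpm, ex$tissues,
                               n_pairs = min(config$n_random_pairs,
                                             length(regs) * length(all_genes)),
                               seed = config$seed,
                               rho_min = config$rho_min,
                               fdr_max = config$fdr_pairs)
  shift <- NULL
  if (!is.null(compare)) {
    sig <- pc[pc$significant, , drop = FALSE]
    if (nrow(sig) >= 5) {
      set.seed(config$seed + 7)
      dK <- compare$distances
      base_pool <- c(dK$altai, dK$denisovan, dK$vindija)
      rows <- lapply(c("altai", "denisovan", "vindija"), function(gm) {
        K <- sample(dK[[gm]], nrow(sig), replace = TRUE)
        data.frame(tissue = sig$tissue, genome = gm, K = K)
      })
      shift <- tissue_shift_test(do.call(rbind, rows),
                                 fdr_max = config$fdr_shift)
    }
  }
  eq <- NULL
  if (!is.null(ex$eqtl)) {
    maf_tab <- data.frame(snp_id = ex$eqtl$snp_id,
                          CEU = ex$eqtl$maf, CHB = ex$eqtl$maf,
                          YRI = ex$eqtl$maf)
    eq_in <- data.frame(snp_id = ex$eqtl$snp_id,
                        pos = seq_len(nrow(ex$eqtl)) * 10L,
                        gene = ex$eqtl$gene, tissue = "brain",
                        es = ex$eqtl$es)
    dbs_iv <- data.frame(start = 1L, end = nrow(ex$eqtl) * 10L)
    arch <- list(altai = dbs_iv, denisovan = dbs_iv, vindija = dbs_iv)
    eq <- filter_eqtls(eq_in, maf_tab, dbs_iv, arch,
                       maf_min = config$maf_eqtl, es_min = config$es_min)
  }
  list(pairs = pc, random_background = rp[c("fraction", "ci", "n_pairs")],
       tissue_shift = shift, eqtls = eq)
}

.egram_stage <- function(ex, config, cfg) {
  ep <- do.call(egram_params, config$egram)
  regs <- names(ex$modules)
  binding <- do.call(rbind, lapply(regs, function(r)
    data.frame(regulator = r, gene = ex$modules[[r]], affinity = 80,
               stringsAsFactors = FALSE)))
  sets <- coregulator_sets(ex$tpm[regs, , drop = FALSE], ep)
  mods <- form_modules(sets, binding, ex$tpm, ep)
  universe <- setdiff(rownames(ex$tpm), regs)
  planted_pw <- ex$modules[[1]][seq_len(min(20, length(ex$modules[[1]])))]
  pathways <- gen_pathways(universe, planted_pw, seed = cfg$seed)
  enrich <- lapply(mods, function(m)
    enrich_pathways(m$genes, pathways, universe, ep$enrich_fdr))
  list(modules = mods, enrichment = enrich, pathways = names(pathways),
       coreg_sets = sets)
}
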