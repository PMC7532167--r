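#' Run the full haplotype-discovery pipeline
#'
#' Orchestrates the analysis on a genotype panel and multi-environment
#' phenotypes: window haplotyping, diversity and LD summaries,
#' kinship-corrected association scans per environment and across
#' environments, region definition and focus-haplotype selection, candidate
#' assembly, multi-environment backward elimination, effect-stability
#' classification, variance explained, and the landrace-versus-breeding
#' genotypic comparison (overlap, enrichment of favorable/unfavorable
#' haplotype frequencies against a random draw, common flags).
#'
#' @param panel a \linkS4class{GenotypePanel} (landrace DH lines +
#'   optionally breeding lines).
#' @param pheno phenotype data.frame (line, env, trait, value) including
#'   ACROSS rows; typically only DH lines are phenotyped.
#' @param trait trait to analyse.
#' @param direction trait direction convention: +1 positive favorable,
#'   -1 negative favorable, NA unclassified.
#' @param window_size SNPs per haplotype window (default 10).
#' @param min_count marker carrier-count filter (default 3).
#' @param fdr_q FDR level per scan (default 0.15).
#' @param region_dist,region_r2 same-region rule (1 Mb, 0.8).
#' @param elim_threshold backward-elimination Wald cutoff (default 0.01).
#' @param ci_mult CI multiplier (default 1.96).
#' @param random_n random haplotypes for the enrichment baseline
#'   (default 500; capped at the eligible set with a warning).
#' @param kinship_random use kinship for the random line effect in the
#'   multi-environment model (default TRUE, matching the kinship
#'   correction of the scan stage; FALSE gives iid line effects).
#' @param ld_max_pairs subsample cap on SNP pairs for the LD summary.
#' @param seed seed for the random haplotype draw and LD subsampling.
#' @return list of class \code{landhapResult} with elements \code{haps},
#'   \code{diversity}, \code{ld}, \code{scans}, \code{regions},
#'   \code{candidates}, \code{model}, \code{classification},
#'   \code{var_explained}, \code{overlap}, \code{enrichment},
#'   \code{settings}.
#' @export
runPipeline <- function(panel, pheno, trait,
                        direction = 1, window_size = 10, min_count = 3,
                        fdr_q = 0.15, region_dist = 1e6, region_r2 = 0.8,
                        elim_threshold = 0.01, ci_mult = 1.96,
                        random_n = 500, kinship_random = TRUE,
                        ld_max_pairs = 50000, seed = 1L) {
  if (!trait %in% pheno$trait) stop("unknown trait: ", trait)
  env_levels <- setdiff(unique(pheno$env[pheno$trait == trait]), "ACROSS")

  haps <- callHaplotypes(panel, buildWindows(markerMap(panel), window_size))
  freqs <- haplotypeFrequencies(haps, panel)
  has_breeding <- "breeding" %in% populations(panel)
  if (!"count_landrace" %in% names(freqs)) {
    lrc <- grep("^count_LR", names(freqs), value = TRUE)
    freqs$count_landrace <- rowSums(freqs[, lrc, drop = FALSE])
    freqs$freq_landrace <- freqs$count_landrace /
      sum(populations(panel) != "breeding")
  }
  diversity <- diversitySummary(panel, haps)

  dh_idx <- which(populations(panel) != "breeding")
  set.seed(seed)
  pr <- pairwiseR2(panel[dh_idx, ])
  if (nrow(pr) > ld_max_pairs)
    pr <- pr[sample(nrow(pr), ld_max_pairs), ]
  ld <- tryCatch(fitLdDecay(pr, n = length(dh_idx)),
                 error = function(e) NULL)

  K <- computeKinship(panel)
  ph_lines <- unique(pheno$line[pheno$trait == trait])
  flt <- prefilterMarkers(hapScores(haps)[intersect(lineIds(panel),
                                                    ph_lines), ,
                                          drop = FALSE],
                          hapInfo(haps), min_count = min_count)
  sc_all <- hapScores(haps)[, colnames(flt$scores), drop = FALSE]

  scans <- list(); regions <- list()
  for (e in c(env_levels, "ACROSS")) {
    res <- associationScan(pheno, panel, flt$scores, flt$info, K,
                           trait = trait, scan_env = e, fdr_q = fdr_q)
    scans[[e]] <- res
    regions[[e]] <- defineRegions(res, flt$scores, flt$info,
                                  max_dist = region_dist,
                                  r2_min = region_r2)
  }

  candidates <- assembleCandidates(regions, flt$scores, flt$info,
                                   max_dist = region_dist,
                                   r2_min = region_r2)
  model <- backwardEliminate(candidates, pheno, panel, sc_all, trait,
                             threshold = elim_threshold,
                             K = if (kinship_random) K else NULL,
                             min_count = min_count)
  classification <- classifyStability(model, direction = direction,
                                      ci_mult = ci_mult)
  varexp <- varianceExplained(model, pheno, panel, sc_all,
                              K = if (kinship_random) K else NULL)

  overlap <- NULL; enrichment <- NULL
  if (has_breeding) {
    overlap <- panelOverlap(freqs)
    lab_of <- function(lbl) classification$hap_id[classification$label ==
                                                    lbl]
    n_elig <- sum(freqs$count_landrace >= min_count)
    rn <- min(random_n, n_elig)
    if (rn < random_n)
      warning("random_n reduced to ", rn, " eligible haplotypes")
    rnd <- sampleRandomHaplotypes(freqs, n = rn, min_count = min_count,
                                  seed = seed)
    enrichment <- list(random = rnd)
    for (lbl in c("favorable", "unfavorable")) {
      ids <- lab_of(lbl)
      if (!length(ids)) next
      disc <- candidates[candidates$hap_id %in% ids, ]
      ind <- pruneIndependent(
        data.frame(hap_id = disc$hap_id, chrom = disc$chrom,
                   start_bp = disc$start_bp, p = disc$discovery_p),
        sc_all, max_dist = region_dist, r2_min = region_r2)
      fr <- freqs$freq_breeding[match(ind$hap_id, freqs$hap_id)]
      enrichment[[lbl]] <- list(
        hap_id = ind$hap_id, freq_breeding = fr,
        test = frequencyEnrichmentTest(fr, rnd$freq_breeding),
        common = commonHaplotypeFlag(fr, rnd$freq_breeding),
        absent = sum(fr == 0))
    }
  }

  structure(list(haps = haps, freqs = freqs, diversity = diversity,
                 ld = ld, scans = scans, regions = regions,
                 candidates = candidates, model = model,
                 classification = classification,
                 var_explained = varexp, overlap = overlap,
                 enrichment = enrichment,
                 settings = list(trait = trait, direction = direction,
                                 window_size = window_size,
                                 min_count = min_count, fdr_q = fdr_q,
                                 region_dist = region_dist,
                                 region_r2 = region_r2,
                                 elim_threshold = elim_threshold,
                                 ci_mult = ci_mult, random_n = random_n,
                                 seed = seed)),
            class = "landhapResult")
}

#' @export
print.landhapResult <- function(x, ...) {
  cat("landhap pipeline result —", x$settings$trait, "\n")
  n_sig <- sum(vapply(x$scans, function(s) sum(s$fdr_sig), numeric(1)))
  cat("  scans:", length(x$scans), "| significant associations:",
      n_sig, "\n")
  cat("  candidates:", nrow(x$candidates), "| retained after elimination:",
      length(x$model$retained), "\n")
  if (length(x$model$retained))
    print(table(x$classification$label))
  cat("  genetic variance explained:",
      round(100 * x$var_explained$proportion, 1), "%\n")
  if (!is.null(x$overlap))
    cat("  landrace haplotypes absent from breeding panel:",
        round(100 * x$overlap$prop_landrace_private, 1), "%\n")
  invisible(x)
}

#' Export the main pipeline tables to TSV + manifest
#'
#' @param result a \code{landhapResult}.
#' @param out_dir output directory.
#' @return manifest, invisibly.
#' @export
exportResults <- function(result, out_dir) {
  tables <- list(
    diversity = result$diversity,
    candidates = result$candidates,
    classification = result$classification,
    scan_across = result$scans[["ACROSS"]])
  rg <- do.call(rbind, result$regions)
  if (!is.null(rg) && nrow(rg)) tables$regions <- rg
  writeResults(tables, out_dir, settings = result$settings)
}
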