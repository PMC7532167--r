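#' Haplotype overlap between landrace and breeding panels
#'
#' Set operations on catalog keys: counts and proportions of haplotypes
#' shared between the pooled landrace panel and the breeding panel, private
#' to each, and — among landrace haplotypes — the number of landraces each
#' occurs in.
#'
#' @param freqs frequency table from \code{\link{haplotypeFrequencies}}
#'   with \code{count_landrace} (or per-landrace counts) and
#'   \code{count_breeding} columns.
#' @param landrace_cols names of per-landrace count columns (default: all
#'   \code{count_LR*}).
#' @return list: \code{n_landrace}, \code{n_breeding}, \code{n_shared},
#'   \code{prop_landrace_private}, \code{prop_breeding_captured},
#'   \code{landrace_occurrence} table (haplotypes private to the landrace
#'   panel, by number of landraces carrying them).
#' @export
panelOverlap <- function(freqs, landrace_cols = NULL) {
  if (is.null(landrace_cols))
    landrace_cols <- grep("^count_LR", names(freqs), value = TRUE)
  cl <- if ("count_landrace" %in% names(freqs)) freqs$count_landrace
    else rowSums(freqs[, landrace_cols, drop = FALSE])
  cb <- freqs$count_breeding
  in_lr <- cl > 0; in_bl <- cb > 0
  lr_priv <- in_lr & !in_bl
  occ <- if (length(landrace_cols))
    table(rowSums(freqs[lr_priv, landrace_cols, drop = FALSE] > 0))
    else table(integer())
  list(n_landrace = sum(in_lr), n_breeding = sum(in_bl),
       n_shared = sum(in_lr & in_bl),
       prop_landrace_private = sum(lr_priv) / sum(in_lr),
       prop_breeding_captured = sum(in_lr & in_bl) / sum(in_bl),
       landrace_occurrence = occ)
}

#' Prune haplotypes to an independent subset
#'
#' Greedy by ascending discovery p: a haplotype is kept unless an
#' already-kept haplotype lies within \code{max_dist} AND has r^2 >=
#' \code{r2_min} with it (haplotypes farther apart, or in low LD, are
#' independent — "distance > 1 Mb and/or r^2 < 0.8").
#'
#' @param haps data.frame: hap_id, chrom, start_bp, p.
#' @param scores 0/2 score matrix covering the haplotypes.
#' @param max_dist bp threshold (default 1e6).
#' @param r2_min r^2 threshold (default 0.8).
#' @return the kept subset of \code{haps}, in ascending p order.
#' @export
pruneIndependent <- function(haps, scores, max_dist = 1e6, r2_min = 0.8) {
  haps <- haps[order(haps$p, haps$chrom, haps$start_bp), , drop = FALSE]
  keep <- logical(nrow(haps))
  for (i in seq_len(nrow(haps))) {
    clash <- FALSE
    for (j in which(keep)) {
      if (haps$chrom[i] != haps$chrom[j]) next
      if (abs(haps$start_bp[i] - haps$start_bp[j]) > max_dist) next
      r <- suppressWarnings(
        stats::cor(scores[, haps$hap_id[i]], scores[, haps$hap_id[j]]))
      if (!is.na(r) && r^2 >= r2_min) { clash <- TRUE; break }
    }
    keep[i] <- !clash
  }
  out <- haps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw random haplotypes for the enrichment baseline
#'
#' Uniform sample without replacement from the haplotypes occurring at
#' least \code{min_count} times in the landrace panel.
#'
#' @param freqs frequency table from \code{\link{haplotypeFrequencies}}.
#' @param n sample size (default 500).
#' @param min_count landrace count filter (default 3).
#' @param seed integer seed (deterministic sample).
#' @param count_col landrace count column (default "count_landrace").
#' @return the sampled rows of \code{freqs}.
#' @export
sampleRandomHaplotypes <- function(freqs, n = 500, min_count = 3,
                                   seed = 1L,
                                   count_col = "count_landrace") {
  elig <- which(freqs[[count_col]] >= min_count)
  if (n > length(elig))
    stop("requested ", n, " haplotypes but only ", length(elig),
         " occur at least ", min_count, " times")
  set.seed(seed)
  freqs[sort(sample(elig, n)), , drop = FALSE]
}

#' Mann-Whitney enrichment test of class frequencies against random
#'
#' Two-sided rank-sum test comparing the breeding-panel frequencies of a
#' haplotype class (favorable or unfavorable) with those of randomly drawn
#' haplotypes; exact enumeration at small sample sizes (both groups <= 20,
#' no ties), normal approximation with tie correction otherwise.
#'
#' @param class_freqs frequencies of the class haplotypes.
#' @param random_freqs frequencies of the random haplotypes.
#' @return list: \code{p}, \code{mean_class}, \code{mean_random},
#'   \code{n_class}, \code{n_random}.
#' @export
frequencyEnrichmentTest <- function(class_freqs, random_freqs) {
  exact <- length(class_freqs) <= 20 && length(random_freqs) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(class_freqs, random_freqs, exact = exact,
                       alternative = "two.sided"))
  list(p = wt$p.value, mean_class = mean(class_freqs),
       mean_random = mean(random_freqs),
       n_class = length(class_freqs), n_random = length(random_freqs))
}

#' Flag a haplotype as common in the breeding panel
#'
#' TRUE when its breeding-panel frequency strictly exceeds the upper
#' quartile of the random haplotype frequencies (linear-interpolation
#' quartile, R type 7).
#'
#' @param freq frequency (vectorized).
#' @param random_freqs random-draw frequencies defining the quartile.
#' @param quantile_type quantile convention (default 7).
#' @return logical vector.
#' @export
commonHaplotypeFlag <- function(freq, random_freqs, quantile_type = 7) {
  q3 <- stats::quantile(random_freqs, 0.75, type = quantile_type,
                        names = FALSE)
  freq > q3
}

#' Two-sided permutation test for a difference in group means
#'
#' Statistic |mean(A) - mean(B)| under random reassignment of group
#' labels. When the number of distinct assignments is at most
#' \code{n_perm}, all assignments are enumerated and the p-value is exact;
#' otherwise \code{n_perm} random permutations are drawn and the add-one
#' estimator p = (1 + #\{perm >= observed\}) / (n_perm + 1) is used.
#'
#' @param a,b numeric group values.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return list: \code{p}, \code{observed}, \code{exact} flag,
#'   \code{n_used}.
#' @export
permutationMeanTest <- function(a, b, n_perm = 10000, seed = 1L) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  n_comb <- choose(na + nb, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(na + nb, na)
    stats_all <- apply(idx, 2, function(ii)
      abs(mean(pool[ii]) - mean(pool[-ii])))
    p <- sum(stats_all >= obs - 1e-12) / n_comb
    return(list(p = p, observed = obs, exact = TRUE, n_used = n_comb))
  }
  set.seed(seed)
  cnt <- 0L
  for (r in seq_len(n_perm)) {
    ii <- sample(na + nb, na)
    if (abs(mean(pool[ii]) - mean(pool[-ii])) >= obs - 1e-12)
      cnt <- cnt + 1L
  }
  list(p = (1 + cnt) / (n_perm + 1), observed = obs, exact = FALSE,
       n_used = n_perm)
}

#' Recombination-integrity diagnostics per window
#'
#' For judging whether an ancestral haplotype shared between panels is
#' likely to have been broken up by recombination: per window the genetic
#' length (cM), the Hudson-Kaplan minimum recombination count nR and the
#' haplotype similarity 1 - H_hap, computed in a chosen panel (typically
#' the breeding lines).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param haps a \linkS4class{HaplotypeSet} on \code{panel}.
#' @param lines subset of lines (logical/character/integer; default all).
#' @return list: \code{per_window} data.frame (window_id, cM, nR,
#'   similarity), \code{means}.
#' @export
recombinationIntegrityMetrics <- function(panel, haps, lines = NULL) {
  g <- genoMatrix(panel)
  asg <- hapAssign(haps)
  if (!is.null(lines)) {
    g <- g[lines, , drop = FALSE]
    asg <- asg[lines, , drop = FALSE]
  }
  wt <- windowTable(haps)
  res <- data.frame(window_id = wt$window_id, cM = wt$cM,
                    nR = NA_real_, similarity = NA_real_)
  for (w in seq_len(nrow(wt))) {
    res$nR[w] <- minRecombination(
      g[, wt$start_idx[w]:wt$end_idx[w], drop = FALSE])
    f <- as.numeric(table(asg[, w])) / nrow(asg)
    res$similarity[w] <- 1 - geneDiversity(f)
  }
  list(per_window = res,
       means = c(cM = mean(res$cM), nR = mean(res$nR),
                 similarity = mean(res$similarity)))
}
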