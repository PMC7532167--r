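#' Gene diversity (expected heterozygosity)
#'
#' H = 1 - sum(p_i^2) over allele (or haplotype) frequencies.
#'
#' @param freqs numeric vector of frequencies summing to 1.
#' @return value in [0, 1 - 1/k].
#' @export
geneDiversity <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Polymorphism information content
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 (Botstein's measure).
#'
#' @inheritParams geneDiversity
#' @return value in [0, 1]; always <= \code{geneDiversity(freqs)}.
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
#' @export
pic <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  a <- freqs^2
  1 - sum(a) - (sum(a)^2 - sum(a^2))
}

#' Minimum number of historical recombination events (Hudson-Kaplan)
#'
#' Four-gamete test on every SNP pair within a window of homozygous lines,
#' followed by the Hudson-Kaplan interval-removal step: incompatible pairs
#' define open intervals, and nR is the size of a maximal set of mutually
#' non-overlapping intervals (greedy by right endpoint, which is minimal
#' for this lower bound).
#'
#' @param geno lines x SNPs matrix coded 0/2 (one window).
#' @return integer >= 0; 0 for monomorphic windows.
#' @export
minRecombination <- function(geno) {
  g <- as.matrix(geno) / 2
  m <- ncol(g)
  if (m < 2) return(0L)
  ivl <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    types <- unique(g[, i] * 2 + g[, j])
    if (length(types) == 4) ivl[[length(ivl) + 1]] <- c(i, j)
  }
  if (!length(ivl)) return(0L)
  iv <- do.call(rbind, ivl)
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  n_r <- 0L; last_right <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= last_right) {  # open intervals: disjoint if l2 >= r1
      n_r <- n_r + 1L
      last_right <- iv[r, 2]
    }
  }
  n_r
}

#' Modified Rogers' distance matrix
#'
#' MRD(a,b) = sqrt( (1/2m) sum over markers and alleles of
#' (p_a - p_b)^2 ). For fully homozygous lines this reduces to the square
#' root of the proportion of differing markers.
#'
#' @param panel a \linkS4class{GenotypePanel}, or a lines x markers 0/2
#'   matrix.
#' @return symmetric distance matrix with zero diagonal, values in [0, 1].
#' @export
mrdMatrix <- function(panel) {
  g <- if (is(panel, "GenotypePanel")) genoMatrix(panel) else as.matrix(panel)
  m <- ncol(g)
  # squared Euclidean on 0/1 alleles: #diff = (|a|+|b| - 2 a.b) on g/2
  h <- g / 2
  cross <- tcrossprod(h)
  cnt <- rowSums(h)
  d2 <- outer(cnt, cnt, "+") - 2 * cross      # differing markers where one is 1
  # also count markers where coding differs with both patterns; for 0/1
  # vectors hamming = sum(a) + sum(b) - 2 a.b  — exact
  d <- sqrt(pmax(d2, 0) / m)
  dimnames(d) <- list(rownames(g), rownames(g))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: double centering of squared distances and
#' eigendecomposition. Axes are ordered by eigenvalue; percentage variance
#' per axis uses the sum of positive eigenvalues as denominator (negative
#' eigenvalues are dropped, no Lingoes/Cailliez correction).
#'
#' @param d symmetric distance matrix.
#' @param k number of axes (default 2).
#' @return list: \code{coords} (n x k), \code{var_pct} (length k),
#'   \code{eig} all eigenvalues.
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- min(k, n - 1)
  cmd <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- cmd$eig[cmd$eig > 1e-12]
  co <- cmd$points
  # cmdscale may return fewer columns if trailing eigenvalues are ~0
  if (ncol(co) < k)
    co <- cbind(co, matrix(0, n, k - ncol(co)))
  list(coords = co,
       var_pct = 100 * pmax(cmd$eig[seq_len(k)], 0) / sum(pos),
       eig = cmd$eig)
}

#' Pairwise r-squared within a distance window
#'
#' Squared Pearson correlation between 0/2 genotype columns for every
#' intra-chromosome marker pair closer than \code{max_dist}. For fully
#' homozygous lines this equals the gametic D^2 / (p(1-p)q(1-q)).
#'
#' @param panel a \linkS4class{GenotypePanel} or 0/2 matrix (then
#'   \code{map} required).
#' @param max_dist maximum pair distance in bp (default 1e6).
#' @param map marker map when \code{panel} is a bare matrix.
#' @return data.frame: i, j (map indices), dist_bp, r2. Monomorphic
#'   markers are skipped.
#' @export
pairwiseR2 <- function(panel, max_dist = 1e6, map = NULL) {
  if (is(panel, "GenotypePanel")) {
    g <- genoMatrix(panel); map <- markerMap(panel)
  } else g <- as.matrix(panel)
  sds <- apply(g, 2, stats::sd)
  res <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch & sds > 0)
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx]
    gs <- scale(g[, idx, drop = FALSE])
    cc <- crossprod(gs) / (nrow(g) - 1)
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    dd <- abs(pos[pr[, 1]] - pos[pr[, 2]])
    keep <- dd <= max_dist
    if (!any(keep)) next
    res[[ch]] <- data.frame(i = idx[pr[keep, 1]], j = idx[pr[keep, 2]],
                            dist_bp = dd[keep],
                            r2 = cc[pr[keep, , drop = FALSE]]^2)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(i = integer(), j = integer(), dist_bp = numeric(),
               r2 = numeric())
  rownames(out) <- NULL
  out
}

# Hill-Weir drift-recombination expectation of r^2 with finite-sample term;
# C = rho * distance, n = number of sampled chromosomes
.hillWeirExpectation <- function(C, n) {
  ((10 + C) / (2 + C) / (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit LD decay and estimate the decay distance
#'
#' Least-squares fit of the Hill-Weir expectation of r^2 under
#' drift-recombination equilibrium with finite sample size \code{n},
#' parameterized by a per-bp recombination scale rho (C = rho x distance).
#' The decay distance is the smallest distance at which the fitted curve
#' drops below \code{threshold}, evaluated on a 1-bp grid up to the largest
#' observed distance.
#'
#' @param pairs data.frame from \code{\link{pairwiseR2}} (needs
#'   \code{dist_bp}, \code{r2}).
#' @param n sample size (number of lines; for homozygous lines each line
#'   contributes one gamete).
#' @param threshold r^2 threshold defining "decayed" (default 0.2).
#' @return list of class \code{ldDecayFit}: \code{rho}, \code{decay_bp},
#'   \code{threshold}, \code{n}, \code{n_pairs}, \code{beyond_range} flag
#'   (TRUE when the fitted curve never crosses the threshold within the
#'   data range; \code{decay_bp} is then the max distance).
#' @export
fitLdDecay <- function(pairs, n, threshold = 0.2) {
  if (nrow(pairs) < 10) stop("need at least 10 marker pairs")
  d <- pairs$dist_bp; r2 <- pairs$r2
  sse <- function(log_rho) {
    e <- .hillWeirExpectation(exp(log_rho) * d, n)
    sum((r2 - e)^2)
  }
  opt <- stats::optimize(sse, interval = c(log(1e-12), log(1)))
  rho <- exp(opt$minimum)
  grid <- seq(1, max(d), by = 1)
  fit <- .hillWeirExpectation(rho * grid, n)
  below <- which(fit < threshold)
  beyond <- length(below) == 0
  decay <- if (beyond) max(d) else grid[below[1]]
  structure(list(rho = rho, decay_bp = decay, threshold = threshold,
                 n = n, n_pairs = nrow(pairs), beyond_range = beyond),
            class = "ldDecayFit")
}

#' @export
print.ldDecayFit <- function(x, ...) {
  cat(sprintf("LD decay fit: rho=%.3g /bp, decay distance (r2<%.2g) = %s bp%s\n",
              x$rho, x$threshold, format(x$decay_bp, big.mark = ","),
              if (x$beyond_range) " (beyond data range)" else ""))
  invisible(x)
}

#' Per-population diversity summary
#'
#' Mean PIC and gene diversity over SNPs and over window haplotypes, and
#' mean Hudson-Kaplan nR per window, for each population (and optionally
#' pooled groups).
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param haps a \linkS4class{HaplotypeSet} called on \code{panel}.
#' @param groups named list of population-label groups (default: each
#'   population, plus all non-breeding pooled as \code{landrace}).
#' @return data.frame: group, n_lines, PIC_snp, H_snp, PIC_hap, H_hap,
#'   mean_nR.
#' @export
diversitySummary <- function(panel, haps, groups = NULL) {
  pops <- populations(panel)
  if (is.null(groups)) {
    groups <- as.list(stats::setNames(unique(pops), unique(pops)))
    lr <- setdiff(unique(pops), "breeding")
    if (length(lr) > 1) groups$landrace <- lr
  }
  g <- genoMatrix(panel)
  wt <- windowTable(haps)
  out <- list()
  for (gname in names(groups)) {
    rows <- pops %in% groups[[gname]]
    sub <- g[rows, , drop = FALSE]
    p <- colMeans(sub) / 2
    snp_stats <- vapply(p, function(pp) {
      f <- c(pp, 1 - pp)
      c(pic(f), geneDiversity(f))
    }, numeric(2))
    asg <- hapAssign(haps)[rows, , drop = FALSE]
    hap_stats <- vapply(seq_len(ncol(asg)), function(w) {
      f <- as.numeric(table(asg[, w])) / sum(rows)
      c(pic(f), geneDiversity(f))
    }, numeric(2))
    nr <- vapply(seq_len(nrow(wt)), function(w)
      as.numeric(minRecombination(
        sub[, wt$start_idx[w]:wt$end_idx[w], drop = FALSE])), numeric(1))
    out[[gname]] <- data.frame(
      group = gname, n_lines = sum(rows),
      PIC_snp = mean(snp_stats[1, ]), H_snp = mean(snp_stats[2, ]),
      PIC_hap = mean(hap_stats[1, ]), H_hap = mean(hap_stats[2, ]),
      mean_nR = mean(nr))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
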