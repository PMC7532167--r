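#' Prefilter haplotype (or SNP) markers for association scanning
#'
#' Removes markers carried by fewer than \code{min_count} lines (or with
#' fewer than one non-carrier, which are untestable), then collapses
#' duplicate classes at r^2 = 1 — keeping, per class, the first marker by
#' genomic position — so each scanned marker represents a distinct
#' segregation pattern.
#'
#' @param scores lines x markers matrix coded 0/2 (phenotyped lines only).
#' @param info data.frame per marker: hap_id (or marker id), chrom,
#'   start_bp; rows parallel columns of \code{scores}.
#' @param min_count minimum carrier count (default 3).
#' @param dedup_r2 r^2 at or above which two markers are duplicates
#'   (default 1, i.e. only exact duplicates/complements collapse).
#' @return list: \code{scores}, \code{info} (filtered),
#'   \code{removed_rare} ids, \code{dup_map} data.frame (kept, removed).
#' @export
prefilterMarkers <- function(scores, info, min_count = 3, dedup_r2 = 1) {
  stopifnot(ncol(scores) == nrow(info))
  n <- nrow(scores)
  cnt <- colSums(scores == 2)
  keep <- cnt >= min_count & (n - cnt) >= 1
  removed_rare <- info$hap_id[!keep]
  scores <- scores[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  dup_map <- data.frame(kept = character(), removed = character())
  if (ncol(scores) > 1) {
    cc <- suppressWarnings(stats::cor(scores))
    cc[is.na(cc)] <- 0
    r2 <- cc^2
    ord <- order(info$chrom, info$start_bp, info$hap_id)
    drop <- rep(FALSE, ncol(scores))
    kept_by <- rep(NA_character_, ncol(scores))
    for (a in ord) {
      if (drop[a]) next
      dups <- which(r2[a, ] >= dedup_r2 - 1e-12 & !drop &
                      seq_len(ncol(scores)) != a)
      dups <- dups[!(dups %in% which(!is.na(kept_by)))]
      dups <- setdiff(dups, a)
      if (length(dups)) {
        drop[dups] <- TRUE
        kept_by[dups] <- info$hap_id[a]
      }
    }
    if (any(drop))
      dup_map <- data.frame(kept = kept_by[drop],
                            removed = info$hap_id[drop])
    scores <- scores[, !drop, drop = FALSE]
    info <- info[!drop, , drop = FALSE]
  }
  rownames(info) <- NULL
  list(scores = scores, info = info, removed_rare = removed_rare,
       dup_map = dup_map)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up rule at level \code{q}: the largest k with p_(k) <= k q / m and
#' all smaller ranks are significant.
#'
#' @param p vector of p-values.
#' @param q FDR level (default 0.15).
#' @return logical vector parallel to \code{p}.
#' @export
bhFdr <- function(p, q = 0.15) {
  stats::p.adjust(p, method = "BH") <= q
}

#' Kinship-corrected association scan
#'
#' Single-marker mixed-model scan of 0/2 markers against one phenotype
#' vector: y = W alpha + x beta + u + e with u ~ N(0, K sigma_g2). The
#' covariate design W is intercept + population indicators (all but one
#' landrace). Variance components are estimated once by REML under the
#' null model and reused for every marker (EMMA-style), giving GLS effect
#' estimates, standard errors and a one-degree chi-square likelihood-ratio
#' p per marker; \code{refit_per_marker = TRUE} re-optimizes the variance
#' ratio for every marker instead.
#'
#' @param pheno data.frame (line, env, trait, value).
#' @param panel a \linkS4class{GenotypePanel} providing population labels.
#' @param scores lines x markers 0/2 matrix (row names = line ids).
#' @param info marker info (hap_id, chrom, start_bp), parallel to
#'   \code{scores} columns.
#' @param K kinship for the full panel (subset internally).
#' @param trait,scan_env which phenotype slice to scan; \code{scan_env =
#'   "ACROSS"} uses the across-environment values.
#' @param fdr_q FDR level for the significance flag (default 0.15).
#' @param refit_per_marker exact per-marker variance refit (default FALSE).
#' @return data.frame of class \code{assocResult}: hap_id, chrom,
#'   start_bp, scan, beta, se, p, fdr_sig; skipped monomorphic markers are
#'   absent, their ids in \code{attr(, "skipped")}.
#' @export
associationScan <- function(pheno, panel, scores, info, K,
                            trait, scan_env = "ACROSS", fdr_q = 0.15,
                            refit_per_marker = FALSE) {
  ph <- pheno[pheno$trait == trait & pheno$env == scan_env, ]
  if (!nrow(ph)) stop("no phenotypes for trait ", trait, " env ", scan_env)
  if (anyDuplicated(ph$line)) stop("duplicate phenotype records")
  lines_use <- intersect(rownames(scores), ph$line)
  y <- ph$value[match(lines_use, ph$line)]
  pops <- populations(panel)[match(lines_use, lineIds(panel))]
  W <- if (length(unique(pops)) > 1) {
    W0 <- stats::model.matrix(~factor(pops))
    colnames(W0) <- sub("^factor\\(pops\\)", "", colnames(W0))
    W0
  } else matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  Km <- .asK(K)
  if (is.null(rownames(Km)))
    dimnames(Km) <- list(lineIds(panel), lineIds(panel))
  Ksub <- Km[lines_use, lines_use]
  M <- scores[lines_use, , drop = FALSE]

  null_fit <- remlFit(y, W, Ksub)
  ek <- null_fit$eigenK
  d <- pmax(ek$values, 0)
  w <- 1 / (null_fit$lambda * d + 1)
  se2 <- null_fit$sigma_e2
  ty <- as.vector(crossprod(ek$vectors, y))
  tW <- crossprod(ek$vectors, W)
  tM <- crossprod(ek$vectors, M)

  A0 <- crossprod(tW, w * tW)
  b0 <- solve(A0, crossprod(tW, w * ty))
  rss0 <- sum(w * (ty - tW %*% b0)^2)

  cnt <- colSums(M == 2)
  testable <- cnt > 0 & cnt < nrow(M)
  skipped <- info$hap_id[!testable]
  res <- data.frame(hap_id = info$hap_id, chrom = info$chrom,
                    start_bp = info$start_bp,
                    scan = paste(trait, scan_env, sep = ":"),
                    beta = NA_real_, se = NA_real_, p = NA_real_)
  p_w <- ncol(W)
  for (j in which(testable)) {
    tx <- tM[, j]
    if (refit_per_marker) {
      fitj <- remlFit(y, cbind(W, x = M[, j]), Ksub, eigenK = ek)
      res$beta[j] <- fitj$beta[p_w + 1]
      res$se[j] <- fitj$se[p_w + 1]
      res$p[j] <- lrtPvalue(null_fit$ll_ml, fitj$ll_ml)
    } else {
      A <- cbind(tW, tx)
      AtA <- crossprod(A, w * A)
      bt <- solve(AtA, crossprod(A, w * ty))
      rss1 <- sum(w * (ty - A %*% bt)^2)
      covb <- solve(AtA) * se2
      res$beta[j] <- bt[p_w + 1]
      res$se[j] <- sqrt(covb[p_w + 1, p_w + 1])
      stat <- max(0, (rss0 - rss1) / se2)
      res$p[j] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  }
  res <- res[testable, , drop = FALSE]
  res$fdr_sig <- bhFdr(res$p, q = fdr_q)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "null_fit") <- null_fit[c("sigma_g2", "sigma_e2", "lambda")]
  class(res) <- c("assocResult", class(res))
  res
}

#' Cluster significant haplotypes into trait-associated genomic regions
#'
#' Single-linkage clumping: two significant haplotypes mark the same region
#' when they lie on the same chromosome, less than \code{max_dist} apart,
#' AND their 0/2 score vectors have r^2 >= \code{r2_min}. Region bounds are
#' the first and last member window positions; per region the focus
#' haplotype is selected by \code{\link{selectFocusHaplotype}}.
#'
#' @param result an \code{assocResult} (or compatible data.frame with
#'   hap_id, chrom, start_bp, beta, p and a logical \code{fdr_sig}).
#' @param scores 0/2 score matrix containing the significant haplotypes
#'   (used for r^2).
#' @param info marker info with end_bp per hap_id.
#' @param max_dist bp distance threshold (default 1e6).
#' @param r2_min LD threshold (default 0.8).
#' @return data.frame: region_id, chrom, start_bp, end_bp, n_members,
#'   members (comma-joined), focus_hap, focus_p, focus_beta.
#' @export
defineRegions <- function(result, scores, info, max_dist = 1e6,
                          r2_min = 0.8) {
  sig <- result[result$fdr_sig, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(region_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_members = integer(), members = character(),
                      focus_hap = character(), focus_p = numeric(),
                      focus_beta = numeric()))
  sig <- sig[order(sig$chrom, sig$start_bp, sig$hap_id), , drop = FALSE]
  n <- nrow(sig)
  sc <- scores[, sig$hap_id, drop = FALSE]
  comp <- seq_len(n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (sig$chrom[a] != sig$chrom[b]) next
    if (abs(sig$start_bp[a] - sig$start_bp[b]) >= max_dist) next
    r <- suppressWarnings(stats::cor(sc[, a], sc[, b]))
    if (!is.na(r) && r^2 >= r2_min) {
      old <- comp[b]; new <- comp[a]
      comp[comp == old] <- new
    }
  }
  ends <- info$end_bp[match(sig$hap_id, info$hap_id)]
  out <- lapply(unique(comp), function(cid) {
    m <- which(comp == cid)
    foc <- selectFocusHaplotype(sig[m, , drop = FALSE])
    data.frame(chrom = sig$chrom[m[1]],
               start_bp = min(sig$start_bp[m]),
               end_bp = max(ends[m]),
               n_members = length(m),
               members = paste(sig$hap_id[m], collapse = ","),
               focus_hap = foc$hap_id, focus_p = foc$p,
               focus_beta = foc$beta)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  out <- cbind(region_id = sprintf("R%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Select the focus haplotype of a region
#'
#' Minimum LRT p; exact ties broken by larger |beta|, then smaller bp —
#' deterministic.
#'
#' @param members data.frame with hap_id, p, beta, start_bp.
#' @return the selected row (one-row data.frame).
#' @export
selectFocusHaplotype <- function(members) {
  o <- order(members$p, -abs(members$beta), members$start_bp)
  members[o[1], , drop = FALSE]
}

#' In-silico fine-mapping of a trait-associated region
#'
#' Re-scans a region with sliding ten-SNP windows (step one SNP):
#' haplotypes are re-called for every sliding window and each is tested
#' under the same kinship-corrected model as the discovery scan; the best
#' window is the one containing the overall minimum p.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param chrom,start_bp,end_bp the region.
#' @param pheno,K,trait,scan_env as in \code{\link{associationScan}}.
#' @param window_size sliding window size (default 10).
#' @param min_count carrier-count filter within each sliding window.
#' @return list: \code{profile} data.frame (win_start_idx, start_bp,
#'   end_bp, min_p), \code{best} the best window row, \code{best_snps}
#'   map indices of the best window.
#' @export
fineMapRegion <- function(panel, chrom, start_bp, end_bp, pheno, K,
                          trait, scan_env = "ACROSS", window_size = 10,
                          min_count = 3) {
  map <- markerMap(panel)
  idx <- which(map$chrom == chrom & map$pos_bp >= start_bp &
                 map$pos_bp <= end_bp)
  idx <- sort(idx)
  if (length(idx) < window_size)
    stop("region spans fewer SNPs than window_size")
  prof <- list()
  for (s in seq_len(length(idx) - window_size + 1)) {
    wi <- idx[s:(s + window_size - 1)]
    sub <- genoMatrix(panel)[, wi, drop = FALSE]
    strs <- apply(sub / 2, 1, paste, collapse = "")
    lev <- sort(unique(strs))
    f <- factor(strs, levels = lev)
    sc <- matrix(0, nrow(sub), length(lev),
                 dimnames = list(rownames(sub),
                                 sprintf("fm_s%04d_h%02d", s,
                                         seq_along(lev))))
    sc[cbind(seq_len(nrow(sub)), as.integer(f))] <- 2
    inf <- data.frame(hap_id = colnames(sc), chrom = chrom,
                      start_bp = map$pos_bp[wi[1]],
                      end_bp = map$pos_bp[wi[window_size]])
    flt <- prefilterMarkers(sc, inf, min_count = min_count)
    if (!ncol(flt$scores)) next
    res <- associationScan(pheno, panel, flt$scores, flt$info, K,
                           trait = trait, scan_env = scan_env)
    prof[[length(prof) + 1]] <- data.frame(
      win_start_idx = wi[1], start_bp = map$pos_bp[wi[1]],
      end_bp = map$pos_bp[wi[window_size]],
      min_p = if (nrow(res)) min(res$p) else NA_real_)
  }
  profile <- do.call(rbind, prof)
  best <- profile[which.min(profile$min_p), , drop = FALSE]
  bi <- which(map$chrom == chrom & map$pos_bp >= best$start_bp &
                map$pos_bp <= best$end_bp)
  list(profile = profile, best = best, best_snps = bi)
}
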