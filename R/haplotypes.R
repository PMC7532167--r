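#' Build nonoverlapping SNP windows along the marker map
#'
#' Partitions each chromosome's SNPs, in map order, into consecutive
#' nonoverlapping windows of \code{window_size} SNPs. A trailing remainder
#' of fewer than \code{window_size} SNPs forms a final window flagged
#' \code{partial}.
#'
#' @param map marker map data.frame (\code{marker}, \code{chrom},
#'   \code{pos_bp}, optional \code{pos_cM}), sorted by (chrom, pos_bp).
#' @param window_size SNPs per window (default 10).
#' @return data.frame: window_id, chrom, start_idx, end_idx (indices into
#'   the map), start_bp, end_bp, n_snps, cM (end - start genetic position,
#'   NA without a cM map), partial.
#' @examples
#' map <- data.frame(marker = paste0("s", 1:25), chrom = "chr1",
#'                   pos_bp = seq(1e5, 25e5, 1e5))
#' buildWindows(map)   # 3 windows: 10, 10, 5 (partial)
#' @export
buildWindows <- function(map, window_size = 10) {
  stopifnot(window_size >= 1)
  o <- order(map$chrom, map$pos_bp)
  if (!identical(o, seq_len(nrow(map)))) stop("map must be sorted")
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (!length(idx)) { warning("empty chromosome ", ch); next }
    starts <- seq(1, length(idx), by = window_size)
    for (s in starts) {
      e <- min(s + window_size - 1, length(idx))
      wi <- idx[s:e]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_idx = wi[1], end_idx = wi[length(wi)],
        start_bp = map$pos_bp[wi[1]], end_bp = map$pos_bp[wi[length(wi)]],
        n_snps = length(wi),
        cM = if ("pos_cM" %in% names(map))
          map$pos_cM[wi[length(wi)]] - map$pos_cM[wi[1]] else NA_real_,
        partial = length(wi) < window_size)
    }
  }
  w <- do.call(rbind, out)
  w <- cbind(window_id = sprintf("w%05d", seq_len(nrow(w))), w)
  rownames(w) <- NULL
  w
}

#' Call window haplotypes and code presence/absence scores
#'
#' Within each window, a haplotype is the allele string a line carries over
#' the window's SNPs. Haplotype ids are assigned deterministically by
#' (window, lexicographic allele string), so identical strings in different
#' panels always map to the same id — the basis for cross-panel congruency
#' analysis. Haplotypes are coded as presence/absence markers with genotype
#' scores 0 and 2; per line and window exactly one haplotype scores 2.
#'
#' @param panel a \linkS4class{GenotypePanel} (no missing values).
#' @param windows window table from \code{\link{buildWindows}}.
#' @return A \linkS4class{HaplotypeSet}. The catalog carries per-population
#'   and panel-wide carrier counts and frequencies.
#' @export
callHaplotypes <- function(panel, windows) {
  g <- genoMatrix(panel)
  pops <- populations(panel)
  upops <- unique(pops)
  n <- nrow(g)
  cat_rows <- list(); sc_cols <- list(); info_rows <- list()
  assign_mat <- matrix(0L, n, nrow(windows),
                       dimnames = list(rownames(g), windows$window_id))
  for (w in seq_len(nrow(windows))) {
    idx <- windows$start_idx[w]:windows$end_idx[w]
    strs <- apply(g[, idx, drop = FALSE] / 2, 1, paste, collapse = "")
    lev <- sort(unique(strs))
    f <- factor(strs, levels = lev)
    hap_ids <- sprintf("%s_h%02d", windows$window_id[w], seq_along(lev))
    assign_mat[, w] <- as.integer(f)
    cnt_all <- as.integer(table(f))
    rec <- data.frame(window_id = windows$window_id[w], hap_id = hap_ids,
                      allele_string = lev, count = cnt_all,
                      freq = cnt_all / n, stringsAsFactors = FALSE)
    for (p in upops) {
      cp <- as.integer(table(f[pops == p]))
      rec[[paste0("count_", p)]] <- cp
      rec[[paste0("freq_", p)]] <- cp / sum(pops == p)
    }
    cat_rows[[w]] <- rec
    sc <- matrix(0, n, length(lev), dimnames = list(rownames(g), hap_ids))
    sc[cbind(seq_len(n), as.integer(f))] <- 2
    sc_cols[[w]] <- sc
    info_rows[[w]] <- data.frame(
      hap_id = hap_ids, window_id = windows$window_id[w],
      chrom = windows$chrom[w], start_bp = windows$start_bp[w],
      end_bp = windows$end_bp[w], stringsAsFactors = FALSE)
  }
  new("HaplotypeSet", windows = windows,
      catalog = do.call(rbind, cat_rows),
      assign = assign_mat,
      scores = do.call(cbind, sc_cols),
      hapInfo = do.call(rbind, info_rows))
}

#' Cross-panel / cross-population haplotype frequency table
#'
#' Tabulates each catalog haplotype's frequency in every requested grouping,
#' including zero rows for haplotypes absent from a group, enabling the
#' landrace-vs-breeding congruency comparison.
#'
#' @param haps a \linkS4class{HaplotypeSet} called on the combined panel.
#' @param groups named list mapping group name -> character vector of
#'   population labels pooled into that group; default: each population
#'   separately plus \code{landrace} (all non-breeding) and
#'   \code{breeding}.
#' @param panel the \linkS4class{GenotypePanel} the set was called on.
#' @param drop_partial exclude partial trailing windows (default TRUE):
#'   sub-size windows are not length-comparable across panels.
#' @return data.frame: window_id, hap_id, allele_string, then
#'   count_<group> and freq_<group> per group.
#' @export
haplotypeFrequencies <- function(haps, panel, groups = NULL,
                                 drop_partial = TRUE) {
  pops <- populations(panel)
  if (is.null(groups)) {
    groups <- as.list(stats::setNames(unique(pops), unique(pops)))
    lr <- setdiff(unique(pops), "breeding")
    if (length(lr) > 1) groups$landrace <- lr
  }
  keep <- rep(TRUE, nrow(hapCatalog(haps)))
  if (drop_partial) {
    pw <- windowTable(haps)$window_id[windowTable(haps)$partial]
    keep <- !(hapCatalog(haps)$window_id %in% pw)
  }
  out <- hapCatalog(haps)[keep, c("window_id", "hap_id", "allele_string")]
  sc <- hapScores(haps)[, keep, drop = FALSE]
  for (gname in names(groups)) {
    rows <- pops %in% groups[[gname]]
    cnt <- colSums(sc[rows, , drop = FALSE] == 2)
    out[[paste0("count_", gname)]] <- as.integer(cnt)
    out[[paste0("freq_", gname)]] <- cnt / sum(rows)
  }
  rownames(out) <- NULL
  out
}
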