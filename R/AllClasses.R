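#' @import methods
NULL

#' GenotypePanel: homozygous lines scored at mapped biallelic SNPs
#'
#' Container for a panel of fully homozygous (doubled-haploid or inbred)
#' lines. Genotypes are coded 0/2 on a fixed reference strand, the only two
#' states a DH line can take at a biallelic SNP. Each line carries a
#' population label: the landrace it was derived from, or \code{"breeding"}
#' for elite material.
#'
#' @slot geno numeric matrix, lines x markers, values in \{0, 2\}.
#' @slot map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos_bp} (1-based) and optionally \code{pos_cM}; rows parallel the
#'   columns of \code{geno} and are sorted by (chrom, pos_bp).
#' @slot pop character vector of population labels, one per line.
#'
#' @examples
#' pan <- simulateGenotypes(simConfig(seed = 1))
#' pan
#' table(populations(pan))
#' @export
setClass("GenotypePanel",
  representation(geno = "matrix", map = "data.frame", pop = "character"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  g <- object@geno
  if (!all(g %in% c(0, 2)))
    msg <- c(msg, "genotype values must all be 0 or 2 (homozygous coding)")
  if (ncol(g) != nrow(object@map))
    msg <- c(msg, "map rows must parallel genotype columns")
  if (nrow(g) != length(object@pop))
    msg <- c(msg, "one population label per line required")
  req <- c("marker", "chrom", "pos_bp")
  if (!all(req %in% names(object@map)))
    msg <- c(msg, "map needs columns marker, chrom, pos_bp")
  else {
    o <- order(object@map$chrom, object@map$pos_bp)
    if (!identical(o, seq_len(nrow(object@map))))
      msg <- c(msg, "map must be sorted by (chrom, pos_bp)")
    dup <- duplicated(object@map[, c("chrom", "pos_bp")])
    if (any(dup))
      msg <- c(msg, sprintf("duplicated map position at row %d",
                            which(dup)[1]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param geno lines x markers matrix with values in \{0,2\}; rownames are
#'   line identifiers, colnames marker identifiers.
#' @param map data.frame with \code{marker}, \code{chrom}, \code{pos_bp} and
#'   optional \code{pos_cM}. Unsorted input is sorted (with a warning) and
#'   the genotype columns reordered accordingly.
#' @param pop character vector of population labels per line.
#' @return A \linkS4class{GenotypePanel}.
#' @export
GenotypePanel <- function(geno, map, pop) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  map <- as.data.frame(map)
  o <- order(map$chrom, map$pos_bp)
  if (!identical(o, seq_len(nrow(map)))) {
    warning("marker map not sorted by (chrom, pos_bp); sorting")
    map <- map[o, , drop = FALSE]
    geno <- geno[, o, drop = FALSE]
  }
  rownames(map) <- NULL
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  new("GenotypePanel", geno = geno, map = map, pop = as.character(pop))
}

#' @describeIn GenotypePanel-class number of lines
#' @param x,object a GenotypePanel
#' @export
nLines <- function(x) nrow(x@geno)

#' @describeIn GenotypePanel-class number of markers
#' @export
nMarkers <- function(x) ncol(x@geno)

#' @describeIn GenotypePanel-class the lines x markers 0/2 matrix
#' @export
genoMatrix <- function(x) x@geno

#' @describeIn GenotypePanel-class the marker map data.frame
#' @export
markerMap <- function(x) x@map

#' @describeIn GenotypePanel-class population label per line
#' @export
populations <- function(x) x@pop

#' @describeIn GenotypePanel-class line identifiers
#' @export
lineIds <- function(x) rownames(x@geno)

#' Subset a GenotypePanel by lines and/or markers
#'
#' @param x a GenotypePanel
#' @param i line index (logical, integer or character)
#' @param j marker index
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nLines(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  g <- x@geno[i, j, drop = FALSE]
  map <- x@map[j, , drop = FALSE]
  o <- order(map$chrom, map$pos_bp)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  new("GenotypePanel", geno = g[, o, drop = FALSE], map = map,
      pop = x@pop[i])
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nLines(object), "lines x", nMarkers(object),
      "markers\n")
  cat("  chromosomes:", length(unique(object@map$chrom)),
      "| cM map:", if ("pos_cM" %in% names(object@map)) "yes" else "no", "\n")
  tb <- table(object@pop)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
})

#' HaplotypeSet: window haplotype catalog, scores and window table
#'
#' Result of calling haplotypes in nonoverlapping SNP windows. Holds the
#' window table, the haplotype catalog (one row per distinct allele string
#' per window, with per-population carrier counts and frequencies), the
#' lines x windows assignment of catalog ids, and the lines x haplotype
#' 0/2 presence/absence score matrix used as marker input for association
#' scans.
#'
#' @slot windows data.frame: window_id, chrom, start_idx, end_idx, start_bp,
#'   end_bp, n_snps, cM (NA without a genetic map), partial flag.
#' @slot catalog data.frame: window_id, hap_id, allele_string, plus
#'   count_<pop> and freq_<pop> columns and panel-wide count/freq.
#' @slot assign integer matrix lines x windows of hap_ids.
#' @slot scores numeric matrix lines x haplotype-markers in \{0,2\};
#'   column names are hap_ids.
#' @slot hapInfo data.frame per score column: hap_id, window_id, chrom,
#'   start_bp, end_bp.
#' @export
setClass("HaplotypeSet",
  representation(windows = "data.frame", catalog = "data.frame",
                 assign = "matrix", scores = "matrix",
                 hapInfo = "data.frame"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  if (nrow(object@scores)) {
    for (w in object@windows$window_id) {
      cols <- which(object@hapInfo$window_id == w)
      if (length(cols)) {
        rs <- rowSums(object@scores[, cols, drop = FALSE])
        if (!all(rs == 2)) {
          msg <- c(msg, sprintf(
            "window %s: every line must carry exactly one haplotype", w))
          break
        }
      }
    }
  }
  if (!all(object@scores %in% c(0, 2)))
    msg <- c(msg, "scores must be 0/2")
  if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypeSet-class window table
#' @param x,object a HaplotypeSet
#' @export
windowTable <- function(x) x@windows

#' @describeIn HaplotypeSet-class haplotype catalog
#' @export
hapCatalog <- function(x) x@catalog

#' @describeIn HaplotypeSet-class lines x haplotypes 0/2 score matrix
#' @export
hapScores <- function(x) x@scores

#' @describeIn HaplotypeSet-class per-haplotype position info
#' @export
hapInfo <- function(x) x@hapInfo

#' @describeIn HaplotypeSet-class lines x windows catalog-id assignment
#' @export
hapAssign <- function(x) x@assign

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", nrow(object@windows), "windows,",
      nrow(object@catalog), "haplotypes,", nrow(object@scores), "lines\n")
  cat("  mean haplotypes/window:",
      round(nrow(object@catalog) / max(1, nrow(object@windows)), 2), "\n")
  np <- sum(object@windows$partial)
  if (np) cat("  partial trailing windows:", np, "\n")
})
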