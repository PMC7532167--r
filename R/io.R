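#' Read a genotype panel from VCF or TSV
#'
#' VCF: biallelic records only; homozygous calls map to 0 (reference) and
#' 2 (alternate). Heterozygous or missing calls are an error by default —
#' inputs are expected fully imputed homozygous lines; with
#' \code{het_policy = "mean"} such calls are replaced by the marker mean
#' rounded to the nearer of 0/2. TSV: tab-separated matrix, first column
#' line id, remaining columns markers with values 0/2; population labels
#' and the marker map are supplied separately for both formats.
#'
#' @param path input file.
#' @param format "vcf" or "tsv" (default: by file extension).
#' @param map marker map (required for TSV; for VCF it is built from the
#'   CHROM/POS columns, optionally merged with a supplied cM map).
#' @param pop population label per line (single value recycled, or named
#'   by line id); default "unknown".
#' @param het_policy "error" (default) or "mean".
#' @return A \linkS4class{GenotypePanel}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv"),
                          map = NULL, pop = "unknown",
                          het_policy = c("error", "mean")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- t(as.matrix(fx))   # single-record VCF
    multi <- grepl(",", fx[, "ALT"])
    if (any(multi))
      stop("multi-allelic site(s): ",
           paste(fx[multi, "ID"][seq_len(min(3, sum(multi)))],
                 collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- sub("\\|", "/", gt)
    code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    code[gt %in% c("0/0", "0")] <- 0
    code[gt %in% c("1/1", "1")] <- 2
    bad <- is.na(code)
    if (any(bad)) {
      if (het_policy == "error") {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop("heterozygous or missing call at marker ",
             rownames(gt)[w[1]], ", line ", colnames(gt)[w[2]],
             " (het_policy = 'mean' to impute)")
      }
      for (i in which(rowSums(bad) > 0)) {
        mu <- mean(code[i, ], na.rm = TRUE)
        code[i, is.na(code[i, ])] <- if (is.nan(mu)) 0 else
          2 * round(mu / 2)
      }
    }
    vmap <- data.frame(marker = fx[, "ID"], chrom = fx[, "CHROM"],
                       pos_bp = as.numeric(fx[, "POS"]))
    if (!is.null(map) && "pos_cM" %in% names(map))
      vmap$pos_cM <- map$pos_cM[match(vmap$marker, map$marker)]
    geno <- t(code)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    geno <- as.matrix(tab[, -1, drop = FALSE])
    rownames(geno) <- tab[[1]]
    if (any(is.na(geno) | !(geno %in% c(0, 2)))) {
      if (het_policy == "error")
        stop("TSV genotypes must be 0/2 with no missing values")
      for (j in seq_len(ncol(geno))) {
        bad <- is.na(geno[, j]) | !(geno[, j] %in% c(0, 2))
        if (any(bad))
          geno[bad, j] <- 2 * round(mean(geno[!bad, j]) / 2)
      }
    }
    if (is.null(map)) stop("TSV input requires a marker map")
    vmap <- map[match(colnames(geno), map$marker), , drop = FALSE]
    if (any(is.na(vmap$marker))) stop("markers missing from map")
  }
  if (length(pop) == 1 && is.null(names(pop)))
    pop <- rep(pop, nrow(geno))
  else if (!is.null(names(pop)))
    pop <- unname(pop[rownames(geno)])
  GenotypePanel(geno, vmap, pop)
}

#' Write a genotype panel as VCF (GT 0/0 and 1/1) and/or TSV
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output file; format by extension (.vcf or .tsv).
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(panel, path) {
  g <- genoMatrix(panel); map <- markerMap(panel)
  if (grepl("\\.vcf$", path)) {
    con <- file(path, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=landhap",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(g)),
                       collapse = "\t")), con)
    gt <- ifelse(t(g) == 2, "1/1", "0/0")
    body <- paste(map$chrom, map$pos_bp, map$marker, "A", "T", ".",
                  "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
    close(con)
  } else {
    tab <- data.frame(line = rownames(g), g, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a marker map (TSV: marker, chrom, pos_bp[, pos_cM])
#'
#' Unsorted rows are sorted with a warning; duplicate positions within a
#' chromosome and cM decreasing with bp are errors naming the row.
#'
#' @param path TSV file.
#' @return validated map data.frame.
#' @export
readMarkerMap <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("marker", "chrom", "pos_bp")
  if (!all(req %in% names(map)))
    stop("map needs columns: ", paste(req, collapse = ", "))
  o <- order(map$chrom, map$pos_bp)
  if (!identical(o, seq_len(nrow(map)))) {
    warning("map rows not sorted by (chrom, pos_bp); sorting")
    map <- map[o, , drop = FALSE]
  }
  dup <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup))
    stop("duplicate position within chromosome at row ", which(dup)[1])
  if ("pos_cM" %in% names(map)) {
    for (ch in unique(map$chrom)) {
      cm <- map$pos_cM[map$chrom == ch]
      if (any(diff(cm) < 0))
        stop("cM decreasing with bp on chromosome ", ch)
    }
  }
  rownames(map) <- NULL
  map
}

#' Read a phenotype table (TSV: line, env, trait, value)
#'
#' \code{env} may be an environment label or the token \code{ACROSS} for
#' across-environment BLUEs; '.' is read as NA in \code{value}. Duplicate
#' (line, env, trait) records are an error naming the row.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "."))
  req <- c("line", "env", "trait", "value")
  if (!all(req %in% names(ph)))
    stop("phenotypes need columns: ", paste(req, collapse = ", "))
  dup <- duplicated(ph[, c("line", "env", "trait")])
  if (any(dup))
    stop("duplicate (line, env, trait) record at row ", which(dup)[1])
  ph$value <- as.numeric(ph$value)
  ph
}

#' Write pipeline result tables with a reproducibility manifest
#'
#' Writes each table as TSV with fixed column order and a JSON manifest
#' recording row/column counts per file, the settings list and the seeds,
#' so a rerun with identical inputs reproduces identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param settings list recorded verbatim in the manifest.
#' @return the manifest (invisibly); files \code{<name>.tsv} and
#'   \code{manifest.json} under \code{out_dir}.
#' @export
writeResults <- function(tables, out_dir, settings = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    tb <- as.data.frame(tables[[nm]])
    utils::write.table(tb, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    entries[[nm]] <- list(file = basename(f), n_rows = nrow(tb),
                          n_cols = ncol(tb),
                          md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(package = "landhap",
                   version = as.character(utils::packageVersion("landhap")),
                   settings = settings, files = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
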