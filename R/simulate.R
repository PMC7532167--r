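#' Configuration for the synthetic DH-library study
#'
#' Defines a synthetic study emulating doubled-haploid (DH) libraries
#' derived from a small number of self-contained landraces plus an elite
#' breeding panel sharing part of its ancestry with the landraces. Founder
#' haplotypes per landrace are drawn from a shared ancestral pool with
#' landrace-private mutations; DH lines are recombinant founder mosaics;
#' breeding lines are mosaics of a founder subset that overlaps the landrace
#' pools, so some landrace haplotypes are absent from the breeding panel.
#'
#' Trait architecture is controlled by \code{qtl} (planted window-haplotype
#' effects, per environment, on the 0/2 coding scale of the association
#' model so a carrier differs from a non-carrier by twice the effect), a
#' polygenic background with covariance proportional to kinship, and
#' environment-specific residual noise.
#'
#' @param n_landraces number of landraces (DH libraries).
#' @param founders_per_landrace ancestral founder haplotypes per landrace.
#' @param dh_per_landrace DH lines generated per landrace.
#' @param n_breeding breeding (elite) lines.
#' @param n_chromosomes,snps_per_chromosome genome dimensions.
#' @param chrom_length_bp,chrom_length_cM physical and genetic chromosome
#'   length; crossovers per meiosis are Poisson(cM/100).
#' @param n_environments number of test environments.
#' @param qtl list of QTL specs; each a list with \code{window} (window
#'   index over the genome at \code{window_size = 10}), \code{effects}
#'   (length-\code{n_environments} numeric, trait units per coded allele) and
#'   \code{pattern} in \code{c("stable+", "stable-", "interacting", "null")};
#'   the carried haplotype is chosen at planting time as the window's most
#'   frequent DH haplotype below carrier frequency 0.5 (a realistic
#'   detectable frequency), unless \code{hap_rank} picks another.
#' @param polygenic_variance variance of the polygenic line value (trait
#'   units squared) on the kinship scale (see \code{\link{computeKinship}}).
#' @param residual_variance_per_env length-\code{n_environments} vector of
#'   residual variances.
#' @param env_means,landrace_means fixed environment and landrace means
#'   (recycled to length).
#' @param mu common intercept.
#' @param ancestral_pool_size size of the shared ancestral haplotype pool
#'   from which founders are drawn.
#' @param ancestral_base_haplotypes number of deep ancestral haplotypes;
#'   pool haplotypes are segmental mosaics of these, which bounds the
#'   per-window haplotype diversity at a realistic level (the study
#'   panels average about seven haplotypes per ten-SNP window).
#' @param pool_segment_snps mean mosaic segment length in SNPs for pool
#'   haplotypes; short segments decorrelate distant windows so that
#'   carrying a given window haplotype does not imply genome-wide
#'   relatedness.
#' @param breeding_overlap fraction of breeding-line founders drawn from the
#'   landrace founder pools (the rest are private to the breeding panel).
#' @param private_mutation_rate per-SNP probability of a landrace-private
#'   allele flip on a founder haplotype.
#' @param maf_range ancestral allele-frequency range for SNP simulation.
#' @param seed integer seed; all generator functions are deterministic
#'   given the config seed.
#' @return object of class \code{simConfig} (a validated list).
#' @export
simConfig <- function(n_landraces = 3,
                      founders_per_landrace = 32,
                      dh_per_landrace = 150,
                      n_breeding = 65,
                      n_chromosomes = 2,
                      snps_per_chromosome = 500,
                      chrom_length_bp = 1.5e8,
                      chrom_length_cM = 160,
                      n_environments = 6,
                      qtl = list(),
                      polygenic_variance = 1,
                      residual_variance_per_env = rep(1, n_environments),
                      env_means = NULL,
                      landrace_means = NULL,
                      mu = 100,
                      ancestral_pool_size = 100,
                      ancestral_base_haplotypes = 6,
                      pool_segment_snps = 50,
                      breeding_overlap = 0.6,
                      private_mutation_rate = 0.005,
                      maf_range = c(0.1, 0.5),
                      seed = 1L) {
  cfg <- list(n_landraces = n_landraces,
              founders_per_landrace = founders_per_landrace,
              dh_per_landrace = dh_per_landrace,
              n_breeding = n_breeding,
              n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              chrom_length_bp = chrom_length_bp,
              chrom_length_cM = chrom_length_cM,
              n_environments = n_environments,
              qtl = qtl,
              polygenic_variance = polygenic_variance,
              residual_variance_per_env =
                rep_len(residual_variance_per_env, n_environments),
              env_means = if (is.null(env_means))
                seq(-1, 1, length.out = n_environments) else
                rep_len(env_means, n_environments),
              landrace_means = if (is.null(landrace_means))
                seq(0, 2, length.out = n_landraces) else
                rep_len(landrace_means, n_landraces),
              mu = mu,
              ancestral_pool_size = ancestral_pool_size,
              ancestral_base_haplotypes = ancestral_base_haplotypes,
              pool_segment_snps = pool_segment_snps,
              breeding_overlap = breeding_overlap,
              private_mutation_rate = private_mutation_rate,
              maf_range = maf_range,
              seed = as.integer(seed))
  counts <- c("n_landraces", "founders_per_landrace", "dh_per_landrace",
              "n_chromosomes", "snps_per_chromosome", "n_environments")
  for (f in counts)
    if (cfg[[f]] < 1) stop("config field ", f, " must be >= 1")
  if (cfg$n_breeding < 0) stop("n_breeding must be >= 0")
  if (cfg$polygenic_variance < 0 || any(cfg$residual_variance_per_env < 0))
    stop("variances must be >= 0")
  if (cfg$chrom_length_cM < 0) stop("chrom_length_cM must be >= 0")
  n_win <- cfg$n_chromosomes * ceiling(cfg$snps_per_chromosome / 10)
  for (q in cfg$qtl) {
    if (is.null(q$window) || q$window < 1 || q$window > n_win)
      stop("qtl window index out of genome range")
    if (length(q$effects) != cfg$n_environments)
      stop("qtl effect vector must have length n_environments")
    if (!q$pattern %in% c("stable+", "stable-", "interacting", "null"))
      stop("unknown qtl pattern: ", q$pattern)
    ok <- switch(q$pattern,
      "stable+" = all(q$effects[q$effects != 0] > 0) && any(q$effects > 0),
      "stable-" = all(q$effects[q$effects != 0] < 0) && any(q$effects < 0),
      "interacting" = any(q$effects > 0) && any(q$effects < 0),
      "null" = all(q$effects == 0))
    if (!ok) stop("qtl pattern '", q$pattern,
                  "' inconsistent with the sign structure of its effects")
  }
  structure(cfg, class = "simConfig")
}

#' @export
print.simConfig <- function(x, ...) {
  cat("simConfig:", x$n_landraces, "landraces x", x$dh_per_landrace,
      "DH +", x$n_breeding, "breeding lines;",
      x$n_chromosomes * x$snps_per_chromosome, "SNPs;",
      x$n_environments, "environments;", length(x$qtl), "QTL; seed",
      x$seed, "\n")
  invisible(x)
}

# one meiosis between two founder haplotype matrices (per-chromosome list of
# 0/2 vectors); crossovers ~ Poisson(cM/100), positions uniform in cM
.meiose <- function(h1, h2, map) {
  out <- numeric(length(h1))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$pos_cM[idx]
    len <- max(cm) - min(cm)
    n_xo <- stats::rpois(1, len / 100)
    cur <- sample(1:2, 1)
    if (n_xo == 0 || len == 0) {
      out[idx] <- if (cur == 1) h1[idx] else h2[idx]
    } else {
      xo <- sort(stats::runif(n_xo, min(cm), max(cm)))
      seg <- findInterval(cm, xo)        # 0..n_xo segment index
      par <- (cur + seg - 1) %% 2 + 1
      out[idx] <- ifelse(par == 1, h1[idx], h2[idx])
    }
  }
  out
}

#' Simulate landrace DH libraries and a breeding panel
#'
#' Generates the genotype panel defined by a \code{\link{simConfig}}:
#' an ancestral haplotype pool on a marker map, landrace founder sets drawn
#' from that pool with landrace-private mutations, DH lines as doubled
#' single-meiosis gametes of random founder pairs, and breeding lines as
#' mosaics of a founder subset partially overlapping the landrace pools.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A \linkS4class{GenotypePanel}; population labels are
#'   \code{"LR1"..} for landraces and \code{"breeding"}.
#' @examples
#' pan <- simulateGenotypes(simConfig(dh_per_landrace = 20, seed = 7))
#' stopifnot(all(genoMatrix(pan) %in% c(0, 2)))
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  if (config$founders_per_landrace < 1) stop("zero founders")
  set.seed(config$seed)
  m <- config$n_chromosomes * config$snps_per_chromosome
  map <- data.frame(
    marker = sprintf("snp%05d", seq_len(m)),
    chrom = rep(sprintf("chr%d", seq_len(config$n_chromosomes)),
                each = config$snps_per_chromosome),
    pos_bp = rep(round(seq(1, config$chrom_length_bp,
                           length.out = config$snps_per_chromosome)),
                 config$n_chromosomes),
    pos_cM = rep(seq(0, config$chrom_length_cM,
                     length.out = config$snps_per_chromosome),
                 config$n_chromosomes))

  # deep ancestral haplotypes drawn SNP-wise at ancestral frequencies;
  # the pool consists of recombinant mosaics of these, so per-window
  # haplotype diversity stays bounded by the base count plus mutation
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  nb <- config$ancestral_base_haplotypes
  base <- matrix(0, nb, m)
  for (i in seq_len(nb))
    base[i, ] <- ifelse(stats::runif(m) < p_anc, 2, 0)
  # pool members are Markov mosaics over the base haplotypes: segment
  # switches at rate ~pool_segment_snps, so local windows carry few base
  # variants while distant segments are decorrelated (short-range LD)
  seg <- config$pool_segment_snps
  pool <- matrix(0, config$ancestral_pool_size, m)
  for (i in seq_len(config$ancestral_pool_size)) {
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      sw <- c(TRUE, stats::runif(length(idx) - 1) < 1 / seg)
      src <- sample(nb, sum(sw), replace = TRUE)
      pool[i, idx] <- base[cbind(src[cumsum(sw)], idx)]
    }
  }

  nf <- config$founders_per_landrace
  founders <- vector("list", config$n_landraces)
  used <- integer()
  for (l in seq_len(config$n_landraces)) {
    pick <- sample(config$ancestral_pool_size, nf, replace = nf >
                     config$ancestral_pool_size)
    used <- union(used, pick)
    fl <- pool[pick, , drop = FALSE]
    # landrace-private mutations differentiate the libraries
    flip <- matrix(stats::runif(nf * m) < config$private_mutation_rate,
                   nf, m)
    fl[flip] <- 2 - fl[flip]
    founders[[l]] <- fl
  }

  dh_one <- function(fnd) {
    i <- sample(nrow(fnd), 2, replace = nrow(fnd) == 1)
    .meiose(fnd[i[1], ], fnd[i[2], ], map)
  }

  geno <- NULL; pop <- character(); ids <- character()
  for (l in seq_len(config$n_landraces)) {
    g <- t(vapply(seq_len(config$dh_per_landrace),
                  function(k) dh_one(founders[[l]]), numeric(m)))
    geno <- rbind(geno, g)
    pop <- c(pop, rep(sprintf("LR%d", l), config$dh_per_landrace))
    ids <- c(ids, sprintf("LR%d_DH%03d", l, seq_len(config$dh_per_landrace)))
  }

  if (config$n_breeding > 0) {
    n_overlap <- round(config$breeding_overlap *
                         config$n_landraces * nf)
    shared <- do.call(rbind, founders)
    bf <- shared[sample(nrow(shared), max(1, n_overlap)), , drop = FALSE]
    n_priv <- max(0, config$n_landraces * nf - n_overlap)
    if (n_priv > 0) {
      unused <- setdiff(seq_len(config$ancestral_pool_size), used)
      if (length(unused) == 0) unused <- seq_len(config$ancestral_pool_size)
      pk <- sample(unused, n_priv, replace = n_priv > length(unused))
      fp <- pool[pk, , drop = FALSE]
      flip <- matrix(stats::runif(n_priv * m) < config$private_mutation_rate,
                     n_priv, m)
      fp[flip] <- 2 - fp[flip]
      bf <- rbind(bf, fp)
    }
    g <- t(vapply(seq_len(config$n_breeding),
                  function(k) dh_one(bf), numeric(m)))
    geno <- rbind(geno, g)
    pop <- c(pop, rep("breeding", config$n_breeding))
    ids <- c(ids, sprintf("BL%03d", seq_len(config$n_breeding)))
  }
  rownames(geno) <- ids
  colnames(geno) <- map$marker
  GenotypePanel(geno, map, pop)
}

#' Plant QTL effects on existing window haplotypes
#'
#' Resolves each QTL spec of the config against the haplotypes actually
#' segregating in the panel and returns the machine-readable truth table
#' used by phenotype simulation and recovery tests.
#'
#' @param panel a \linkS4class{GenotypePanel} from
#'   \code{\link{simulateGenotypes}}.
#' @param config the same \code{\link{simConfig}}.
#' @param haps optional precomputed \linkS4class{HaplotypeSet} for
#'   \code{panel} (computed if missing).
#' @return list of class \code{truthTable}: \code{qtl} data.frame (window_id,
#'   hap_id, pattern, carrier count/frequency in the DH panel, one
#'   \code{effect_env<i>} column per environment), plus the config's variance
#'   components.
#' @export
plantQtls <- function(panel, config, haps = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(haps)) haps <- callHaplotypes(panel, buildWindows(markerMap(panel)))
  dh <- populations(panel) != "breeding"
  rows <- list()
  for (q in config$qtl) {
    wid <- windowTable(haps)$window_id[q$window]
    cols <- which(hapInfo(haps)$window_id == wid)
    cnt <- colSums(hapScores(haps)[dh, cols, drop = FALSE] == 2)
    frq <- cnt / sum(dh)
    # default target: most frequent DH haplotype with carrier freq < 0.5
    elig <- which(cnt > 0 & frq < 0.5)
    if (!length(elig)) elig <- which(cnt > 0)
    if (!length(elig))
      stop("window ", wid, ": no haplotype with carriers; undetectable QTL")
    rank <- if (is.null(q$hap_rank)) 1L else q$hap_rank
    pick <- elig[order(-cnt[elig])][min(rank, length(elig))]
    if (cnt[pick] == 0)
      stop("selected haplotype has zero carriers; undetectable QTL")
    hid <- hapInfo(haps)$hap_id[cols[pick]]
    rec <- data.frame(window_id = wid, hap_id = hid, pattern = q$pattern,
                      carrier_count = cnt[pick], carrier_freq = frq[pick],
                      stringsAsFactors = FALSE)
    for (i in seq_len(config$n_environments))
      rec[[sprintf("effect_env%d", i)]] <- q$effects[i]
    rows[[length(rows) + 1]] <- rec
  }
  qtl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(window_id = character(), hap_id = character(),
               pattern = character(), carrier_count = integer(),
               carrier_freq = numeric())
  structure(list(qtl = qtl,
                 polygenic_variance = config$polygenic_variance,
                 residual_variance_per_env = config$residual_variance_per_env,
                 n_environments = config$n_environments),
            class = "truthTable")
}

#' Simulate multi-environment phenotypes
#'
#' Generates per-environment line values under the generative counterpart of
#' the multi-environment association model: intercept + environment mean +
#' landrace mean + sum over planted QTLs of (0/2 score) x (per-environment
#' effect) + polygenic line value (multivariate normal with covariance
#' proportional to the SNP kinship matrix) + environment-specific residual
#' noise. Across-environment means are emitted as across-environment BLUE
#' stand-ins under the environment token \code{"ACROSS"}.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param truth a \code{truthTable} from \code{\link{plantQtls}}.
#' @param config the \code{\link{simConfig}}.
#' @param haps optional precomputed \linkS4class{HaplotypeSet}.
#' @param trait trait name used in the output table.
#' @return list: \code{phenotypes} data.frame (line, env, trait, value;
#'   includes ACROSS rows), \code{polygenic} the true polygenic values.
#'   Only non-breeding lines are phenotyped (the study phenotypes the DH
#'   panel; breeding-line phenotypes can be simulated by relabelling).
#' @export
simulatePhenotypes <- function(panel, truth, config, haps = NULL,
                               trait = "trait1") {
  stopifnot(inherits(config, "simConfig"), inherits(truth, "truthTable"))
  if (is.null(haps)) haps <- callHaplotypes(panel, buildWindows(markerMap(panel)))
  if (!identical(rownames(hapScores(haps)), lineIds(panel)))
    stop("panel and haplotype set refer to different line sets")
  set.seed(config$seed + 1L)
  dh <- which(populations(panel) != "breeding")
  n <- length(dh)
  E <- config$n_environments
  lr <- match(populations(panel)[dh],
              sprintf("LR%d", seq_len(config$n_landraces)))

  g_poly <- rep(0, n)
  if (config$polygenic_variance > 0) {
    K <- computeKinship(panel[dh, ])$K
    ek <- eigen(K, symmetric = TRUE)
    lam <- pmax(ek$values, 0)
    g_poly <- as.vector(ek$vectors %*% (sqrt(lam * config$polygenic_variance) *
                                          stats::rnorm(n)))
  }

  qmat <- matrix(0, n, E)  # summed QTL contribution per line x env
  if (nrow(truth$qtl)) {
    sc <- hapScores(haps)[dh, , drop = FALSE]
    for (r in seq_len(nrow(truth$qtl))) {
      x <- sc[, match(truth$qtl$hap_id[r], colnames(sc))]
      eff <- as.numeric(truth$qtl[r, sprintf("effect_env%d", seq_len(E))])
      qmat <- qmat + outer(x, eff)
    }
  }

  vals <- matrix(0, n, E)
  for (i in seq_len(E)) {
    vals[, i] <- config$mu + config$env_means[i] +
      config$landrace_means[lr] + qmat[, i] + g_poly +
      stats::rnorm(n, 0, sqrt(config$residual_variance_per_env[i]))
  }
  ids <- lineIds(panel)[dh]
  ph <- data.frame(
    line = rep(ids, E),
    env = rep(sprintf("env%d", seq_len(E)), each = n),
    trait = trait,
    value = as.vector(vals))
  ph <- rbind(ph, data.frame(line = ids, env = "ACROSS", trait = trait,
                             value = rowMeans(vals)))
  list(phenotypes = ph, polygenic = stats::setNames(g_poly, ids))
}

#' Simulate a complete study (genotypes, truth, phenotypes)
#'
#' Convenience wrapper running \code{\link{simulateGenotypes}},
#' \code{\link{buildWindows}}/\code{\link{callHaplotypes}},
#' \code{\link{plantQtls}} and \code{\link{simulatePhenotypes}}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param trait trait name.
#' @return list with \code{panel}, \code{haps}, \code{truth},
#'   \code{phenotypes}, \code{polygenic}.
#' @export
simulateStudy <- function(config, trait = "trait1") {
  panel <- simulateGenotypes(config)
  haps <- callHaplotypes(panel, buildWindows(markerMap(panel)))
  truth <- plantQtls(panel, config, haps)
  ph <- simulatePhenotypes(panel, truth, config, haps, trait = trait)
  list(panel = panel, haps = haps, truth = truth,
       phenotypes = ph$phenotypes, polygenic = ph$polygenic)
}
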