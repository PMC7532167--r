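# shared fixtures built in code

# tiny deterministic panel: n lines x m markers, seeded
makeTinyPanel <- function(n = 8, m = 30, seed = 1, pop = NULL,
                          n_chrom = 2) {
  set.seed(seed)
  per <- ceiling(m / n_chrom)
  map <- data.frame(
    marker = sprintf("s%03d", seq_len(m)),
    chrom = rep(sprintf("chr%d", seq_len(n_chrom)), each = per)[seq_len(m)],
    pos_bp = rep(seq(1e5, by = 1e5, length.out = per),
                 n_chrom)[seq_len(m)],
    pos_cM = rep(seq(0, 50, length.out = per), n_chrom)[seq_len(m)])
  geno <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m,
                 dimnames = list(sprintf("L%02d", seq_len(n)), map$marker))
  if (is.null(pop)) pop <- rep("LR1", n)
  GenotypePanel(geno, map, pop)
}

# small simulated study used by several test files
smallStudy <- function(seed = 7, effects = rep(0.8, 4), n_env = 4,
                       pattern = "stable+", dh = 80, snps = 120,
                       extra_qtl = NULL) {
  qtl <- list(list(window = 3, effects = effects, pattern = pattern))
  if (!is.null(extra_qtl)) qtl <- c(qtl, extra_qtl)
  cfg <- simConfig(dh_per_landrace = dh, n_breeding = 25,
                   snps_per_chromosome = snps, n_environments = n_env,
                   qtl = qtl, seed = seed)
  simulateStudy(cfg)
}

# dense multivariate-normal log-density (independent oracle for the
# spectral-path likelihood): profile out beta by explicit GLS solve
denseLmmLoglik <- function(y, X, K, sg2, se2) {
  V <- sg2 * K + se2 * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus[1] +
                       t(r) %*% Vi %*% r))
}

# exhaustive Hudson-Kaplan oracle: DP over incompatible intervals
# (maximum set of pairwise non-overlapping open intervals)
nrOracle <- function(geno) {
  g <- as.matrix(geno) / 2
  m <- ncol(g)
  if (m < 2) return(0L)
  iv <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    if (length(unique(g[, i] * 2 + g[, j])) == 4)
      iv[[length(iv) + 1]] <- c(i, j)
  if (!length(iv)) return(0L)
  iv <- do.call(rbind, iv)
  best <- 0L
  # recursive enumeration: f(pos) = max non-overlapping intervals with
  # left endpoint >= pos
  f <- function(pos) {
    cand <- which(iv[, 1] >= pos)
    if (!length(cand)) return(0L)
    max(vapply(cand, function(k) 1L + f(iv[k, 2]), integer(1)))
  }
  f(1L)
}
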