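# two-trait phenotypes with controlled genetic/residual covariance
makeBivariateData <- function(seed, n = 60, E = 2, beta = c(0, 0),
                              hap_freq = 0.3, rg = 0.5, re = 0.3,
                              panel = NULL) {
  set.seed(seed)
  if (is.null(panel)) panel <- makeTinyPanel(n = n, m = 40, seed = seed)
  ids <- lineIds(panel)
  x <- stats::setNames(sample(c(0, 2), n, TRUE, c(1 - hap_freq, hap_freq)),
                       ids)
  G <- matrix(c(1, rg, rg, 1), 2)
  Emat <- matrix(c(1, re, re, 1), 2)
  u <- matrix(rnorm(2 * n), n) %*% chol(G)      # iid line effects here
  ph <- list()
  for (t in 1:2) for (e in seq_len(E)) {
    err <- matrix(rnorm(2 * n), n) %*% chol(Emat)
    ph[[length(ph) + 1]] <- data.frame(
      line = ids, env = paste0("e", e), trait = paste0("t", t),
      value = 10 * t + 0.2 * e + x * beta[t] + u[, t] +
        (matrix(rnorm(2 * n), n) %*% chol(Emat))[, t])
  }
  # rebuild so the residual trait pair shares one draw per (line, env)
  ph <- list()
  for (e in seq_len(E)) {
    err <- matrix(rnorm(2 * n), n) %*% chol(Emat)
    for (t in 1:2)
      ph[[length(ph) + 1]] <- data.frame(
        line = ids, env = paste0("e", e), trait = paste0("t", t),
        value = 10 * t + 0.2 * e + x * beta[t] + u[, t] + err[, t])
  }
  list(pheno = do.call(rbind, ph), x = x, panel = panel)
}

test_that("duplicated trait gives identical per-trait haplotype effects", {
  d <- makeBivariateData(1, beta = c(0.6, 0.6))
  ph2 <- d$pheno
  v1 <- ph2$value[ph2$trait == "t1"]
  ph2$value[ph2$trait == "t2"] <- v1 + 5     # exact duplicate, shifted
  fit <- bivariateHaplotypeTest(d$x, c("t1", "t2"), ph2, d$panel)
  expect_equal(unname(fit$beta[1]), unname(fit$beta[2]), tolerance = 1e-4)
})

test_that("bivariate fit with diagonal covariances matches univariate fits", {
  d <- makeBivariateData(3, beta = c(0.5, -0.3), re = 0, rg = 0)
  fit2 <- bivariateHaplotypeTest(d$x, c("t1", "t2"), d$pheno, d$panel,
                                 diag_only = TRUE)
  for (t in 1:2) {
    ph_t <- d$pheno[d$pheno$trait == paste0("t", t), ]
    ph_t$trait <- "single"
    prep <- landhap:::.kronPrep(ph_t, d$panel, "single", d$x, NULL)
    fit1 <- landhap:::.fitKron(prep)
    expect_equal(unname(fit2$beta[t]),
                 unname(fit1$beta[paste0("hap:", "single")]),
                 tolerance = 1e-5)
  }
})

test_that("trait-specific effects rarely flag both traits", {
  flags <- vapply(1:10, function(s) {
    d <- makeBivariateData(100 + s, beta = c(0.8, 0))
    bivariateHaplotypeTest(d$x, c("t1", "t2"), d$pheno,
                           d$panel)$sig_both
  }, logical(1))
  expect_lte(mean(flags), 0.2)
})

test_that("pleiotropic effects are detected on both traits", {
  flags <- vapply(1:10, function(s) {
    d <- makeBivariateData(200 + s, n = 80, beta = c(0.8, 0.8))
    bivariateHaplotypeTest(d$x, c("t1", "t2"), d$pheno,
                           d$panel)$sig_both
  }, logical(1))
  expect_gte(mean(flags), 0.8)
})

test_that("kronecker likelihood equals the dense MVN oracle", {
  d <- makeBivariateData(7, n = 15, E = 2, beta = c(0.4, 0.2))
  prep <- landhap:::.kronPrep(d$pheno, d$panel, c("t1", "t2"), d$x, NULL)
  G <- matrix(c(1.2, 0.4, 0.4, 0.8), 2)
  Emat <- matrix(c(0.9, 0.2, 0.2, 1.1), 2)
  f <- landhap:::.kronREML(G, Emat, prep)
  # dense construction in (env, trait, line) observation order
  n <- 15; E <- 2
  ph <- d$pheno
  ord <- expand.grid(env = paste0("e", 1:E), trait = c("t1", "t2"),
                     line = sort(unique(ph$line)),
                     stringsAsFactors = FALSE)
  key <- paste(ph$line, ph$trait, ph$env)
  y <- ph$value[match(paste(ord$line, ord$trait, ord$env), key)]
  X <- matrix(0, nrow(ord), 0)
  for (t in c("t1", "t2")) {
    sel <- as.numeric(ord$trait == t)
    X <- cbind(X, sel, sel * (ord$env == "e2"), sel * d$x[ord$line])
  }
  # cov: per line block over (env, trait): G[t,t'] + E[t,t'] (e == e')
  blk <- matrix(0, 2 * E, 2 * E)
  for (t1 in 1:2) for (t2 in 1:2) for (e1 in 1:E) for (e2 in 1:E) {
    r <- (t1 - 1) * E + e1; cc <- (t2 - 1) * E + e2
    blk[r, cc] <- G[t1, t2] + if (e1 == e2) Emat[t1, t2] else 0
  }
  # reorder block to (env fastest, trait) = same as ord within line
  perm <- as.vector(t(matrix(seq_len(2 * E), nrow = 2, byrow = TRUE)))
  ordBlk <- matrix(0, 2 * E, 2 * E)
  idx <- cbind(rep(1:2, each = E), rep(1:E, 2))   # (trait, env) per ord row
  rowmap <- (idx[, 1] - 1) * E + idx[, 2]
  ordBlk <- blk[rowmap, rowmap]
  V <- diag(n) %x% ordBlk
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  llo <- -0.5 * (determinant(V, TRUE)$modulus[1] +
                   determinant(t(X) %*% Vi %*% X, TRUE)$modulus[1] +
                   t(r) %*% Vi %*% r +
                   (length(y) - ncol(X)) * log(2 * pi))
  expect_equal(f$ll, as.numeric(llo), tolerance = 1e-8)
})

test_that("two-haplotype window contrast equals the biallelic effect", {
  # construct a panel whose first window carries exactly two haplotypes
  set.seed(91)
  n <- 60; E <- 4
  map <- data.frame(marker = sprintf("s%02d", 1:20), chrom = "chr1",
                    pos_bp = 1:20 * 1e4)
  g <- matrix(sample(c(0, 2), n * 20, TRUE), n, 20,
              dimnames = list(sprintf("L%02d", 1:n), map$marker))
  carrier <- sample(c(0, 2), n, TRUE, c(0.6, 0.4))
  g[, 1:10] <- 0
  g[, 1] <- carrier                      # window 1: two allele strings
  pan <- GenotypePanel(g, map, rep("LR1", n))
  haps <- callHaplotypes(pan, buildWindows(markerMap(pan)))
  u <- rnorm(n)
  ph <- do.call(rbind, lapply(1:E, function(e) data.frame(
    line = rownames(g), env = paste0("env", e), trait = "trait1",
    value = 10 + 0.1 * e + 0.4 * carrier + u + rnorm(n))))
  info <- hapInfo(haps)
  cols <- info$hap_id[info$window_id == "w00001"]
  expect_length(cols, 2)
  sc <- hapScores(haps)
  # focus = the carrier haplotype (allele string with the alternate SNP)
  focus <- cols[colSums(sc[, cols] == 2) == sum(carrier == 2)][1]
  alt <- setdiff(cols, focus)
  cf <- windowContrast("w00001", focus, character(), haps, ph, pan,
                       "trait1")
  m <- backwardEliminate(focus, ph, pan, sc, "trait1", threshold = 1.01)
  for (e in m$environments) {
    b_contrast <- cf$effects$beta[cf$effects$hap_id == alt &
                                    cf$effects$env == e]
    expect_equal(b_contrast, -2 * m$effects[focus, e], tolerance = 1e-4)
  }
})

test_that("contrast errors and pooling behave at the boundaries", {
  st <- smallStudy(seed = 82, dh = 40, snps = 50)
  info <- hapInfo(st$haps)
  sc <- hapScores(st$haps)
  ph_lines <- unique(st$phenotypes$line)
  # a monomorphic window (single haplotype) has no contrast
  mono <- NULL
  for (w in windowTable(st$haps)$window_id) {
    cols <- info$hap_id[info$window_id == w]
    if (sum(colSums(sc[ph_lines, cols, drop = FALSE] == 2) > 0) == 1)
      mono <- w
  }
  if (!is.null(mono)) {
    foc <- info$hap_id[info$window_id == mono][
      which(colSums(sc[ph_lines, info$hap_id[info$window_id == mono],
                       drop = FALSE] == 2) > 0)]
    expect_error(windowContrast(mono, foc, character(), st$haps,
                                st$phenotypes, st$panel, "trait1"),
                 "no contrast")
  }
  # rare alternatives are pooled
  w <- windowTable(st$haps)$window_id[3]
  cols <- info$hap_id[info$window_id == w]
  cnts <- colSums(sc[ph_lines, cols, drop = FALSE] == 2)
  focus <- cols[which.max(cnts)]
  if (any(cnts > 0 & cnts < 3 & cols != focus)) {
    cf <- windowContrast(w, focus, character(), st$haps, st$phenotypes,
                         st$panel, "trait1")
    expect_true(length(cf$pooled) >= 1)
    expect_true("rare" %in% cf$effects$hap_id)
  }
})
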