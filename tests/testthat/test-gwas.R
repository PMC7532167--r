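test_that("marker prefilter: rare removal, duplicate collapse, recount", {
  sc <- cbind(h1 = c(2, 2, 0, 0, 0, 0, 0, 0),
              h2 = c(2, 2, 2, 0, 0, 0, 0, 0),
              h3 = c(2, 2, 2, 0, 0, 0, 0, 0),   # duplicate of h2
              h4 = c(0, 0, 0, 2, 2, 2, 2, 2))   # complement of h2: r2 = 1
  rownames(sc) <- paste0("L", 1:8)
  info <- data.frame(hap_id = paste0("h", 1:4), chrom = "chr1",
                     start_bp = c(100, 200, 300, 400))
  flt <- prefilterMarkers(sc, info, min_count = 3)
  expect_equal(flt$removed_rare, "h1")            # 2 carriers
  expect_equal(colnames(flt$scores), "h2")        # first by position kept
  expect_setequal(flt$dup_map$removed, c("h3", "h4"))
  # filtered count equals brute-force recount on a simulated panel
  st <- smallStudy(seed = 3, dh = 20, snps = 40)
  sc2 <- hapScores(st$haps)
  f2 <- prefilterMarkers(sc2, hapInfo(st$haps), min_count = 3)
  cnt <- colSums(sc2 == 2)
  expect_equal(ncol(f2$scores) + length(f2$removed_rare) +
                 nrow(f2$dup_map),
               ncol(sc2))
  expect_true(all(colSums(f2$scores == 2) >= 3))
})

test_that("BH flags equal the brute-force all-thresholds oracle", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.20), q = 0.15),
               c(TRUE, TRUE, FALSE))
  expect_equal(bhFdr(rep(1, 5)), rep(FALSE, 5))
  expect_true(bhFdr(0.10, q = 0.15))
  bhOracle <- function(p, q) {
    m <- length(p); o <- order(p); flags <- logical(m)
    k <- 0
    for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
    if (k > 0) flags[o[seq_len(k)]] <- TRUE
    flags
  }
  set.seed(20)
  for (r in 1:300) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- sample(c(0.05, 0.15, 0.3), 1)
    expect_identical(bhFdr(p, q), bhOracle(p, q))
  }
})

test_that("association scan ranks a planted QTL first and is well calibrated", {
  st <- smallStudy(seed = 41, dh = 100, snps = 100, effects = rep(0.9, 4))
  K <- computeKinship(st$panel)
  ph_lines <- unique(st$phenotypes$line)
  flt <- prefilterMarkers(hapScores(st$haps)[ph_lines, ],
                          hapInfo(st$haps), min_count = 3)
  res <- associationScan(st$phenotypes, st$panel, flt$scores, flt$info, K,
                         trait = "trait1", scan_env = "ACROSS")
  top <- res$hap_id[which.min(res$p)]
  planted <- st$truth$qtl$hap_id[1]
  # top marker is the planted haplotype or a near-duplicate of it
  r_top <- cor(hapScores(st$haps)[ph_lines, top],
               hapScores(st$haps)[ph_lines, planted])
  expect_gt(r_top^2, 0.8)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$se > 0))

  # permuted phenotypes: p-values approximately uniform
  set.seed(1)
  ph_perm <- st$phenotypes
  for (e in unique(ph_perm$env)) {
    i <- which(ph_perm$env == e)
    ph_perm$value[i] <- sample(ph_perm$value[i])
  }
  res0 <- associationScan(ph_perm, st$panel, flt$scores, flt$info, K,
                          trait = "trait1", scan_env = "ACROSS")
  ks <- suppressWarnings(stats::ks.test(res0$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("null marker with K = I stays within 3 SE nearly always", {
  set.seed(33)
  n <- 100
  map <- data.frame(marker = paste0("s", 1:10), chrom = "chr1",
                    pos_bp = 1:10 * 1000)
  hits <- replicate(60, {
    g <- matrix(sample(c(0, 2), n * 10, TRUE), n, 10,
                dimnames = list(sprintf("L%03d", 1:n), map$marker))
    pan <- GenotypePanel(g, map, rep("LR1", n))
    ph <- data.frame(line = rownames(g), env = "ACROSS",
                     trait = "t", value = rnorm(n))
    info <- data.frame(hap_id = "m1", chrom = "chr1", start_bp = 1000)
    res <- associationScan(ph, pan, g[, 1, drop = FALSE], info,
                           diag(n), trait = "t")
    abs(res$beta) < 3 * res$se
  })
  expect_gte(mean(hits), 0.95)
})

test_that("region clumping follows the distance-AND-LD rule", {
  set.seed(2)
  n <- 40
  base <- sample(c(0, 2), n, TRUE)
  flip <- function(x, k) { i <- sample(n, k); x[i] <- 2 - x[i]; x }
  sc <- cbind(h1 = base, h2 = flip(base, 2), h3 = flip(base, 2))
  rownames(sc) <- paste0("L", 1:n)
  res <- data.frame(hap_id = c("h1", "h2", "h3"), chrom = "chr1",
                    start_bp = c(0.2e6, 0.5e6, 2.0e6),
                    scan = "t:ACROSS", beta = c(1, 0.9, 0.8),
                    se = 0.1, p = c(1e-6, 1e-5, 1e-4),
                    fdr_sig = TRUE)
  info <- data.frame(hap_id = c("h1", "h2", "h3"), chrom = "chr1",
                     start_bp = res$start_bp, end_bp = res$start_bp + 9000)
  rg <- defineRegions(res, sc, info)
  expect_equal(nrow(rg), 2)          # {h1,h2} within 1 Mb & high LD; {h3}
  expect_equal(rg$n_members, c(2, 1))
  expect_equal(rg$focus_hap[1], "h1")
  expect_equal(rg$end_bp[1], 0.5e6 + 9000)

  # close but uncorrelated haplotypes stay separate (AND rule)
  sc2 <- cbind(h1 = base, h2 = sample(c(0, 2), n, TRUE))
  rownames(sc2) <- paste0("L", 1:n)
  res2 <- res[1:2, ]; res2$start_bp <- c(1e5, 2e5)
  info2 <- info[1:2, ]; info2$start_bp <- res2$start_bp
  rg2 <- defineRegions(res2, sc2, info2)
  expect_equal(nrow(rg2), 2)

  # single significant haplotype forms its own region
  rg1 <- defineRegions(res[1, ], sc[, 1, drop = FALSE], info[1, ])
  expect_equal(nrow(rg1), 1)
  expect_equal(rg1$n_members, 1)
})

test_that("region clumping is idempotent and order-invariant", {
  set.seed(6)
  n <- 30
  sc <- matrix(sample(c(0, 2), n * 6, TRUE), n, 6,
               dimnames = list(NULL, paste0("h", 1:6)))
  res <- data.frame(hap_id = paste0("h", 1:6),
                    chrom = rep(c("chr1", "chr2"), each = 3),
                    start_bp = rep(c(1e5, 4e5, 3e6), 2),
                    scan = "t", beta = rnorm(6), se = 0.1,
                    p = runif(6, 1e-8, 1e-3), fdr_sig = TRUE)
  info <- data.frame(hap_id = res$hap_id, chrom = res$chrom,
                     start_bp = res$start_bp, end_bp = res$start_bp + 1e4)
  r1 <- defineRegions(res, sc, info)
  perm <- sample(6)
  r2 <- defineRegions(res[perm, ], sc, info)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("focus selection tie-breaking is deterministic", {
  m <- data.frame(hap_id = c("a", "b"), p = c(1e-5, 1e-6),
                  beta = c(1, 0.5), start_bp = c(100, 200))
  expect_equal(selectFocusHaplotype(m)$hap_id, "b")
  m2 <- data.frame(hap_id = c("a", "b"), p = c(1e-6, 1e-6),
                   beta = c(0.5, 1), start_bp = c(100, 200))
  expect_equal(selectFocusHaplotype(m2)$hap_id, "b")  # larger |beta|
  m3 <- data.frame(hap_id = c("a", "b"), p = c(1e-6, 1e-6),
                   beta = c(1, -1), start_bp = c(300, 200))
  expect_equal(selectFocusHaplotype(m3)$hap_id, "b")  # leftmost bp
})

test_that("fine-mapping profile localizes the causal window", {
  st <- smallStudy(seed = 55, dh = 120, snps = 60, effects = rep(1, 4))
  wt <- windowTable(st$haps)
  wrow <- wt[wt$window_id == st$truth$qtl$window_id[1], ]
  K <- computeKinship(st$panel)
  fm <- fineMapRegion(st$panel, wrow$chrom,
                      max(1, wrow$start_bp - 3e6), wrow$end_bp + 3e6,
                      st$phenotypes, K, trait = "trait1")
  expect_true(nrow(fm$profile) > 1)
  # the best sliding window overlaps the causal window
  expect_true(fm$best$start_bp <= wrow$end_bp &&
                fm$best$end_bp >= wrow$start_bp)
  # exactly-10-SNP region gives a single profile row
  idx <- which(markerMap(st$panel)$chrom == wrow$chrom)
  pos <- markerMap(st$panel)$pos_bp[idx]
  ten <- pos[seq_len(10)]
  fm1 <- fineMapRegion(st$panel, wrow$chrom, ten[1], ten[10],
                       st$phenotypes, K, trait = "trait1")
  expect_equal(nrow(fm1$profile), 1)
})

test_that("haplotype and SNP scans agree on the top region for a SNP QTL", {
  # plant an effect on a single SNP and scan both marker types
  set.seed(77)
  cfg <- simConfig(dh_per_landrace = 120, n_breeding = 0,
                   snps_per_chromosome = 100, n_environments = 2,
                   seed = 77)
  panel <- simulateGenotypes(cfg)
  haps <- callHaplotypes(panel, buildWindows(markerMap(panel)))
  K <- computeKinship(panel)
  g <- genoMatrix(panel)
  causal <- which(abs(colMeans(g) / 2 - 0.5) < 0.2)[5]
  # polygenic background from the other chromosome only, so it cannot
  # carry the causal marker's own direction (small m would otherwise make
  # the marker-aligned polygenic component non-negligible)
  other <- markerMap(panel)$chrom != markerMap(panel)$chrom[causal]
  K_bg <- computeKinship(panel, markers = which(other))$K
  u <- {
    ek <- eigen(K_bg, symmetric = TRUE)
    as.vector(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(nLines(panel))))
  }
  y <- 10 + 0.6 * g[, causal] + u + rnorm(nLines(panel))
  ph <- data.frame(line = lineIds(panel), env = "ACROSS",
                   trait = "t", value = y)
  # both scans corrected with the background kinship (at desk-scale m the
  # full-genome kinship would shrink the tested marker's own direction)
  fh <- prefilterMarkers(hapScores(haps), hapInfo(haps))
  rh <- associationScan(ph, panel, fh$scores, fh$info, K_bg, trait = "t")
  map <- markerMap(panel)
  snp_info <- data.frame(hap_id = map$marker, chrom = map$chrom,
                         start_bp = map$pos_bp, end_bp = map$pos_bp)
  fs <- prefilterMarkers(g, snp_info)
  rs <- associationScan(ph, panel, fs$scores, fs$info, K_bg, trait = "t")
  top_h <- rh[which.min(rh$p), ]
  top_s <- rs[which.min(rs$p), ]
  expect_equal(top_h$chrom, top_s$chrom)
  # the top SNP falls inside the top haplotype's window span
  span <- fh$info[fh$info$hap_id == top_h$hap_id, ]
  expect_gte(top_s$start_bp, span$start_bp)
  expect_lte(top_s$start_bp, span$end_bp)
  expect_equal(unname(top_s$hap_id), map$marker[causal])
})
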