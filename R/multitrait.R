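# ---- Kronecker-structured multi-trait REML -------------------------------
#
# Model: y_(t,k,i) = fixed + u_(t,k) + e_(t,k,i), u ~ N(0, G (x) K),
# e ~ N(0, E (x) I) with trait covariance E per (line, environment)
# observation and independence across observations. Balanced data
# (every line x environment x trait cell observed once) is required.
#
# Computation: rotate the line space by the eigenvectors of K, and the
# within-line environment space by an orthonormal basis whose first vector
# is 1/sqrt(E): the 2E x 2E per-line covariance block G d_k (x) J_E +
# E (x) I_E splits into E two-by-two trait blocks, of which only the first
# (the environment mean component) carries the genetic part E_env d_k G.
# Every likelihood evaluation is then vectorized 2x2 algebra.

.kronPrep <- function(pheno, panel, traits, hap_scores = NULL, K = NULL) {
  ph <- pheno[pheno$trait %in% traits & pheno$env != "ACROSS", ]
  envs <- sort(unique(ph$env))
  lines_u <- sort(unique(ph$line))
  E <- length(envs); n <- length(lines_u); Tt <- length(traits)
  full <- expand.grid(env = envs, trait = traits, line = lines_u,
                      stringsAsFactors = FALSE)   # env fastest, trait, line
  key <- paste(ph$line, ph$trait, ph$env)
  m <- match(paste(full$line, full$trait, full$env), key)
  if (any(is.na(m)))
    stop("multi-trait model requires balanced line x environment x trait data")
  y <- ph$value[m]
  lr <- populations(panel)[match(full$line, lineIds(panel))]
  # per-trait fixed effects: intercept, env, landrace (+ haplotype score)
  Xs <- list()
  for (t in traits) {
    sel <- as.numeric(full$trait == t)
    Xt <- cbind(sel)
    colnames(Xt) <- paste0("mu:", t)
    for (e in envs[-1]) {
      Xt <- cbind(Xt, sel * (full$env == e))
      colnames(Xt)[ncol(Xt)] <- paste0("env", e, ":", t)
    }
    for (l in sort(unique(lr))[-1]) {
      Xt <- cbind(Xt, sel * (lr == l))
      colnames(Xt)[ncol(Xt)] <- paste0("lr", l, ":", t)
    }
    if (!is.null(hap_scores)) {
      Xt <- cbind(Xt, sel * hap_scores[full$line])
      colnames(Xt)[ncol(Xt)] <- paste0("hap:", t)
    }
    Xs[[t]] <- Xt
  }
  X <- do.call(cbind, Xs)

  d_line <- rep(1, n); R <- NULL
  if (!is.null(K)) {
    Km <- .asK(K)[lines_u, lines_u]
    ek <- eigen(Km, symmetric = TRUE)
    d_line <- pmax(ek$values, 0)
    R <- ek$vectors
  }
  # within-line block = Tt*E rows ordered (trait outer, env inner)
  Q <- qr.Q(qr(cbind(rep(1 / sqrt(E), E), diag(E)[, -E, drop = FALSE])))
  if (sum(Q[, 1]) < 0) Q[, 1] <- -Q[, 1]
  M <- kronecker(diag(Tt), t(Q))           # applies Q' within each trait
  blockify <- function(v) {
    # v over (env fastest, trait, line) -> matrix (Tt*E) x n
    matrix(v, nrow = Tt * E)
  }
  rot <- function(v) {
    B <- M %*% blockify(v)
    if (!is.null(R)) B <- B %*% R
    B
  }
  Yb <- rot(y)
  p <- ncol(X)
  Xbig <- do.call(cbind, lapply(seq_len(p), function(j) rot(X[, j])))
  Xflat <- matrix(Xbig, nrow = Tt * E * n)       # N x p
  list(Yb = Yb, Xbig = Xbig, Xflat = Xflat, p = p,
       xnames = colnames(X), E = E, n = n, Tt = Tt,
       d_line = d_line, envs = envs, traits = traits, lines = lines_u)
}

# negative REML log-likelihood and GLS pieces given G, Emat (Tt x Tt).
# applyV works on (Tt*E) x (n*k) matrices whose columns repeat the n lines
# k times (dcol = d_line recycled accordingly).
.kronREML <- function(G, Emat, prep) {
  E <- prep$E; n <- prep$n; Tt <- prep$Tt; d <- prep$d_line
  p <- prep$p
  if (Tt == 1) {
    v1 <- Emat[1, 1] + E * d * G[1, 1]
    vr <- Emat[1, 1]
    if (any(v1 <= 0) || vr <= 0) return(NULL)
    logdet <- sum(log(v1)) + n * (E - 1) * log(vr)
    applyV <- function(B, k) {
      B[1, ] <- B[1, ] / rep(v1, k)
      if (E > 1) B[-1, ] <- B[-1, ] / vr
      B
    }
  } else {
    a <- Emat[1, 1] + E * d * G[1, 1]
    b <- Emat[1, 2] + E * d * G[1, 2]
    cc <- Emat[2, 2] + E * d * G[2, 2]
    det1 <- a * cc - b^2
    detr <- Emat[1, 1] * Emat[2, 2] - Emat[1, 2]^2
    if (any(det1 <= 0) || detr <= 0 || any(a <= 0) || Emat[1, 1] <= 0)
      return(NULL)
    logdet <- sum(log(det1)) + n * (E - 1) * log(detr)
    i1 <- 1; i2 <- E + 1                    # m=1 rows for trait 1, 2
    applyV <- function(B, k) {
      o <- B
      ak <- rep(a, k); bk <- rep(b, k); ck <- rep(cc, k)
      dk <- rep(det1, k)
      v1 <- B[i1, ]; v2 <- B[i2, ]
      o[i1, ] <- (ck * v1 - bk * v2) / dk
      o[i2, ] <- (-bk * v1 + ak * v2) / dk
      if (E > 1) {
        r1 <- 1 + seq_len(E - 1); r2 <- E + 1 + seq_len(E - 1)
        w1 <- B[r1, , drop = FALSE]; w2 <- B[r2, , drop = FALSE]
        o[r1, ] <- (Emat[2, 2] * w1 - Emat[1, 2] * w2) / detr
        o[r2, ] <- (-Emat[1, 2] * w1 + Emat[1, 1] * w2) / detr
      }
      o
    }
  }
  N <- Tt * E * n
  VY <- applyV(prep$Yb, 1)
  VXflat <- matrix(applyV(prep$Xbig, p), nrow = N)
  A <- crossprod(prep$Xflat, VXflat)
  A <- (A + t(A)) / 2
  bvec <- as.vector(crossprod(prep$Xflat, as.vector(VY)))
  cov_beta <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(cov_beta)) return(NULL)
  beta <- as.vector(cov_beta %*% bvec)
  ypy <- sum(prep$Yb * VY) - sum(bvec * beta)
  ll <- -0.5 * (logdet + determinant(A, logarithm = TRUE)$modulus[1] +
                  ypy + (N - p) * log(2 * pi))
  list(ll = as.numeric(ll), beta = stats::setNames(beta, prep$xnames),
       cov_beta = cov_beta)
}

.fitKron <- function(prep, diag_only = FALSE) {
  Tt <- prep$Tt
  vy <- stats::var(as.vector(prep$Yb))
  if (Tt == 1) {
    th0 <- log(c(vy / 2, vy / 2))
    nll <- function(th) {
      f <- .kronREML(matrix(exp(th[1])), matrix(exp(th[2])), prep)
      if (is.null(f)) 1e10 else -f$ll
    }
    opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    G <- matrix(exp(opt$par[1])); Emat <- matrix(exp(opt$par[2]))
  } else {
    mk <- function(th) {
      if (diag_only) {
        L_g <- diag(exp(th[1:2])); L_e <- diag(exp(th[3:4]))
      } else {
        L_g <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
        L_e <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
      }
      list(G = tcrossprod(L_g), E = tcrossprod(L_e))
    }
    th0 <- if (diag_only) log(rep(sqrt(vy / 2), 4)) else
      c(log(sqrt(vy / 2)), 0, log(sqrt(vy / 2)),
        log(sqrt(vy / 2)), 0, log(sqrt(vy / 2)))
    nll <- function(th) {
      vc <- mk(th)
      f <- .kronREML(vc$G, vc$E, prep)
      if (is.null(f)) 1e10 else -f$ll
    }
    opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    vc <- mk(opt$par)
    G <- vc$G; Emat <- vc$E
  }
  fit <- .kronREML(G, Emat, prep)
  list(G = G, E = Emat, ll = fit$ll, beta = fit$beta,
       cov_beta = fit$cov_beta, convergence = opt$convergence)
}

#' Bivariate mixed-model test of a haplotype on two traits
#'
#' Fits the two-trait mixed model with genetic covariance G (x) K and
#' residual covariance E (x) I (trait covariance within each line x
#' environment observation), per-trait fixed environment and landrace
#' effects, and a per-trait haplotype effect. Significance on both traits
#' means both 95% confidence intervals exclude zero. The per-trait
#' proportion of genetic variance explained is the relative reduction of
#' that trait's diagonal of G between the models without and with the
#' haplotype effect.
#'
#' @param hap_scores named 0/2 vector (line -> score) for the haplotype.
#' @param traits character(2): the trait pair.
#' @param pheno data.frame (line, env, trait, value) with both traits on
#'   overlapping line sets, balanced over environments.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param K kinship (default NULL: iid line effects).
#' @param ci_mult CI multiplier (default 1.96).
#' @param diag_only force G and E diagonal (no trait covariance).
#' @return list of class \code{bivariateFit}: \code{beta} (per trait),
#'   \code{se}, \code{ci} (2 x 2: lo, hi), \code{sig_both}, \code{G},
#'   \code{E}, \code{var_explained} per trait, \code{ll}.
#' @export
bivariateHaplotypeTest <- function(hap_scores, traits, pheno, panel,
                                   K = NULL, ci_mult = 1.96,
                                   diag_only = FALSE) {
  stopifnot(length(traits) == 2)
  lines_t1 <- unique(pheno$line[pheno$trait == traits[1]])
  lines_t2 <- unique(pheno$line[pheno$trait == traits[2]])
  if (!length(intersect(lines_t1, lines_t2)))
    stop("trait pair observed on non-overlapping line sets")
  keep <- pheno$line %in% intersect(lines_t1, lines_t2)
  prep1 <- .kronPrep(pheno[keep, ], panel, traits, hap_scores, K)
  fit1 <- .fitKron(prep1, diag_only = diag_only)
  prep0 <- .kronPrep(pheno[keep, ], panel, traits, NULL, K)
  fit0 <- .fitKron(prep0, diag_only = diag_only)
  hap_ix <- match(paste0("hap:", traits), names(fit1$beta))
  beta <- fit1$beta[hap_ix]
  se <- sqrt(diag(fit1$cov_beta))[hap_ix]
  lo <- beta - ci_mult * se; hi <- beta + ci_mult * se
  ve <- pmax(0, (diag(fit0$G) - diag(fit1$G)) / diag(fit0$G))
  structure(list(traits = traits,
                 beta = stats::setNames(as.numeric(beta), traits),
                 se = stats::setNames(as.numeric(se), traits),
                 ci = cbind(lo = as.numeric(lo), hi = as.numeric(hi)),
                 sig_both = all(lo > 0 | hi < 0),
                 G = fit1$G, E = fit1$E,
                 var_explained = stats::setNames(as.numeric(ve), traits),
                 ll = fit1$ll, full = fit1, null = fit0),
            class = "bivariateFit")
}

#' @export
print.bivariateFit <- function(x, ...) {
  cat("bivariateFit:", paste(x$traits, collapse = " x "),
      "| significant on both:", x$sig_both, "\n")
  print(round(cbind(beta = x$beta, se = x$se, x$ci,
                    varexp = x$var_explained), 4))
  invisible(x)
}

#' Contrast alternative window haplotypes against the focus haplotype
#'
#' Fits the multi-environment model with the retained background
#' haplotypes Q' (all retained haplotypes except the window's focus) plus
#' a categorical window-haplotype factor with the focus as reference:
#' per environment, each alternative haplotype's coefficient is its effect
#' relative to the focus haplotype. Alternatives carried by fewer than
#' \code{min_count} lines are pooled into a \code{"rare"} level. The
#' proportion of genetic variance explained by the window is the relative
#' reduction in line variance from the model with no haplotype terms to
#' the model with Q' plus the window factor (default null), and from the
#' Q'-only model (\code{window_only} variant), both reported.
#'
#' @param window_id window to contrast.
#' @param focus_hap hap_id of the focus haplotype (must belong to the
#'   window and be carried by at least one phenotyped line).
#' @param background character vector: retained haplotype set Q (the focus
#'   is removed internally).
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param pheno,panel,K,trait as in \code{\link{backwardEliminate}}.
#' @param min_count pooling threshold (default 3).
#' @param ci_mult CI multiplier.
#' @return list of class \code{contrastFit}: \code{effects} long
#'   data.frame (hap_id, env, beta, se, lo, hi, sig), \code{var_explained}
#'   (default null), \code{var_explained_window_only}, \code{fit}.
#' @export
windowContrast <- function(window_id, focus_hap, background, haps, pheno,
                           panel, trait, K = NULL, min_count = 3,
                           ci_mult = 1.96) {
  ph <- pheno[pheno$trait == trait & pheno$env != "ACROSS", ]
  sc <- hapScores(haps)
  ph <- ph[ph$line %in% rownames(sc), ]
  line <- factor(ph$line); env <- factor(ph$env)
  lr <- factor(populations(panel)[match(ph$line, lineIds(panel))])

  info <- hapInfo(haps)
  wcols <- info$hap_id[info$window_id == window_id]
  if (!(focus_hap %in% wcols)) stop("focus haplotype not in window")
  lines_u <- levels(line)
  asg <- wcols[apply(sc[lines_u, wcols, drop = FALSE] == 2, 1, which)]
  names(asg) <- lines_u
  if (all(asg == focus_hap))
    stop("all phenotyped lines carry the focus haplotype; no contrast")
  cnt <- table(asg)
  lev <- names(cnt)
  pooled <- setdiff(lev[cnt < min_count], focus_hap)
  asg[asg %in% pooled] <- "rare"
  lev <- c(focus_hap, setdiff(unique(asg), focus_hap))
  wf <- factor(asg[as.character(ph$line)], levels = lev)

  Qp <- setdiff(background, focus_hap)
  # Q' background terms per environment
  X <- stats::model.matrix(~env)
  if (nlevels(lr) > 1)
    X <- cbind(X, stats::model.matrix(~lr)[, -1, drop = FALSE])
  X0 <- X                                    # no haplotype terms
  for (h in Qp) {
    x <- sc[as.character(ph$line), h]
    for (e in levels(env)) {
      X <- cbind(X, as.numeric(env == e) * x)
      colnames(X)[ncol(X)] <- paste0(h, "@", e)
    }
  }
  XQ <- X                                    # Q' only
  for (hl in lev[-1]) for (e in levels(env)) {
    X <- cbind(X, as.numeric(wf == hl & env == e))
    colnames(X)[ncol(X)] <- paste0("win:", hl, "@", e)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]

  fit <- remlFitHetero(ph$value, X, line, env, K = K)
  fit0 <- remlFitHetero(ph$value, X0, line, env, K = K)
  fitQ <- remlFitHetero(ph$value, XQ, line, env, K = K)

  eff <- list()
  for (hl in lev[-1]) for (e in levels(env)) {
    cn <- paste0("win:", hl, "@", e)
    if (!cn %in% colnames(X)) next
    b <- fit$beta[cn]; s <- fit$se[cn]
    eff[[length(eff) + 1]] <- data.frame(
      hap_id = hl, env = e, beta = b, se = s,
      lo = b - ci_mult * s, hi = b + ci_mult * s,
      sig = (b - ci_mult * s > 0) | (b + ci_mult * s < 0))
  }
  eff <- do.call(rbind, eff)
  rownames(eff) <- NULL
  structure(list(window_id = window_id, focus_hap = focus_hap,
                 levels = lev, pooled = pooled, effects = eff,
                 var_explained =
                   max(0, (fit0$sigma_u2 - fit$sigma_u2) / fit0$sigma_u2),
                 var_explained_window_only =
                   max(0, (fitQ$sigma_u2 - fit$sigma_u2) / fitQ$sigma_u2),
                 fit = fit), class = "contrastFit")
}

#' @export
print.contrastFit <- function(x, ...) {
  cat("contrastFit: window", x$window_id, "focus", x$focus_hap, "|",
      length(x$levels) - 1, "alternative levels | window varexp",
      round(x$var_explained, 3), "\n")
  invisible(x)
}
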