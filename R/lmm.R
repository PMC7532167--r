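#' Genomic relationship (kinship) matrix
#'
#' Astle-Balding genomic relationship matrix from 0/2 SNP scores:
#' K = (1/m) sum_i (x_i - 2 p_i)(x_i - 2 p_i)' / (2 p_i (1 - p_i)) with
#' p_i = mean(x_i)/2. For fully homozygous lines the diagonal is close to 2
#' under this denominator; \code{denom = "4pq"} rescales to a unit-diagonal
#' convention.
#'
#' @param panel a \linkS4class{GenotypePanel} or a lines x markers 0/2
#'   matrix.
#' @param markers optional marker subset (indices or names).
#' @param denom \code{"2pq"} (default) or \code{"4pq"}.
#' @return list of class \code{kinship}: \code{K} (n x n symmetric),
#'   \code{n_markers} used, \code{n_monomorphic} dropped.
#' @export
computeKinship <- function(panel, markers = NULL, denom = c("2pq", "4pq")) {
  denom <- match.arg(denom)
  g <- if (is(panel, "GenotypePanel")) genoMatrix(panel) else as.matrix(panel)
  if (!is.null(markers)) g <- g[, markers, drop = FALSE]
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  n_mono <- sum(!poly)
  g <- g[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(g)) stop("no polymorphic markers")
  den <- if (denom == "2pq") 2 * p * (1 - p) else 4 * p * (1 - p)
  xs <- sweep(g, 2, 2 * p) / rep(sqrt(den), each = nrow(g))
  K <- tcrossprod(xs) / ncol(g)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(g), rownames(g))
  structure(list(K = K, n_markers = ncol(g), n_monomorphic = n_mono,
                 denom = denom), class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat("kinship:", nrow(x$K), "lines,", x$n_markers, "markers (",
      x$n_monomorphic, "monomorphic dropped ), mean diagonal",
      round(mean(diag(x$K)), 3), "\n")
  invisible(x)
}

.asK <- function(K) {
  if (inherits(K, "kinship")) K$K else as.matrix(K)
}

# rotated-space profile quantities at variance ratio lambda = sg2/se2;
# ty = U'y, tX = U'X, d = eigenvalues of K
.profileAt <- function(lambda, ty, tX, d) {
  w <- 1 / (lambda * d + 1)
  A <- crossprod(tX, w * tX)
  b <- crossprod(tX, w * ty)
  cf <- solve(A, b)
  res <- ty - tX %*% cf
  rss <- sum(w * res^2)
  list(w = w, A = A, beta = cf, rss = rss)
}

.remlLL <- function(lambda, ty, tX, d) {
  n <- length(ty); p <- ncol(tX)
  pr <- .profileAt(lambda, ty, tX, d)
  se2 <- pr$rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * se2) + sum(log(lambda * d + 1)) +
            determinant(pr$A, logarithm = TRUE)$modulus[1] + (n - p))
}

.mlLL <- function(lambda, ty, tX, d) {
  n <- length(ty)
  pr <- .profileAt(lambda, ty, tX, d)
  se2 <- pr$rss / n
  -0.5 * (n * log(2 * pi * se2) + sum(log(lambda * d + 1)) + n)
}

#' Mixed-model log-likelihood via the spectral path
#'
#' Log-likelihood of y ~ N(X beta, sigma_g2 K + sigma_e2 I) at the GLS
#' estimate of beta, computed through one eigendecomposition of K (reusable
#' across calls). With \code{reml = TRUE} the REML log-likelihood
#' (residual contrast density, including the -log|X'V^-1 X| and +log|X'X|
#' terms) is returned instead.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param K kinship matrix (or \code{kinship} object).
#' @param sigma_g2,sigma_e2 variance components.
#' @param reml logical.
#' @param eigenK optional precomputed \code{eigen(K, symmetric = TRUE)}.
#' @return scalar log-likelihood.
#' @export
lmmLoglik <- function(y, X, K, sigma_g2, sigma_e2, reml = FALSE,
                      eigenK = NULL) {
  K <- .asK(K)
  if (is.null(eigenK)) eigenK <- eigen(K, symmetric = TRUE)
  d <- pmax(eigenK$values, 0)
  ty <- crossprod(eigenK$vectors, y)
  tX <- crossprod(eigenK$vectors, X)
  n <- length(y); p <- ncol(tX)
  v <- sigma_g2 * d + sigma_e2
  w <- 1 / v
  A <- crossprod(tX, w * tX)
  cf <- solve(A, crossprod(tX, w * ty))
  rss <- sum(w * (ty - tX %*% cf)^2)
  ll <- -0.5 * (n * log(2 * pi) + sum(log(v)) + rss)
  if (reml) {
    ll <- ll + 0.5 * p * log(2 * pi) -
      0.5 * determinant(A, logarithm = TRUE)$modulus[1] +
      0.5 * determinant(crossprod(X), logarithm = TRUE)$modulus[1]
  }
  as.numeric(ll)
}

#' REML/ML fit of the single-kinship linear mixed model
#'
#' Fits y = X beta + u + e with u ~ N(0, K sigma_g2), e ~ N(0, I sigma_e2)
#' by profiling the variance ratio lambda = sigma_g2/sigma_e2 over one
#' eigendecomposition of K: a coarse grid over log(lambda) followed by
#' Brent refinement (tolerance 1e-8 on the log-ratio). Fixed effects are
#' GLS at the optimum. Both the REML optimum (variance reporting) and the
#' ML optimum (likelihood-ratio testing across fixed-effect models) are
#' returned.
#'
#' @param y response (numeric, no NA).
#' @param X design matrix, full column rank.
#' @param K kinship matrix or \code{kinship} object; positive semi-definite.
#' @param eigenK optional precomputed eigendecomposition of K (reused
#'   across markers in a scan).
#' @return list of class \code{lmmFit}: \code{beta}, \code{se},
#'   \code{cov_beta}, \code{sigma_g2}, \code{sigma_e2}, \code{lambda},
#'   \code{ll_reml}, \code{ll_ml} (at the ML-optimal ratio),
#'   \code{lambda_ml}, \code{boundary} flag, \code{eigenK}.
#' @export
remlFit <- function(y, X, K, eigenK = NULL) {
  X <- as.matrix(X)
  K <- .asK(K)
  if (any(is.na(y))) stop("y contains NA")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("X is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(eigenK)) eigenK <- eigen(K, symmetric = TRUE)
  if (min(eigenK$values) < -1e-8 * max(abs(eigenK$values)))
    stop("K is not positive semi-definite")
  d <- pmax(eigenK$values, 0)
  ty <- as.vector(crossprod(eigenK$vectors, y))
  tX <- crossprod(eigenK$vectors, X)
  n <- length(y); p <- ncol(X)

  optimise_profile <- function(fn) {
    grid <- seq(log(1e-6), log(1e6), length.out = 61)
    vals <- vapply(grid, function(lg) fn(exp(lg), ty, tX, d), numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(lg) fn(exp(lg), ty, tX, d),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    # boundary handling: compare with endpoints of the full range
    cand <- c(opt$maximum, log(1e-6), log(1e6))
    cv <- c(opt$objective, vals[1], vals[length(vals)])
    best <- which.max(cv)
    list(log_lambda = cand[best], ll = cv[best],
         boundary = best > 1 || i %in% c(1, length(grid)))
  }

  or <- optimise_profile(.remlLL)
  om <- optimise_profile(.mlLL)
  lambda <- exp(or$log_lambda)
  pr <- .profileAt(lambda, ty, tX, d)
  se2 <- pr$rss / (n - p)
  sg2 <- lambda * se2
  cov_beta <- solve(pr$A) * se2
  beta <- as.vector(pr$beta)
  names(beta) <- colnames(X)
  structure(list(beta = beta, se = sqrt(diag(cov_beta)),
                 cov_beta = cov_beta, sigma_g2 = sg2, sigma_e2 = se2,
                 lambda = lambda, ll_reml = or$ll, ll_ml = om$ll,
                 lambda_ml = exp(om$log_lambda),
                 boundary = or$boundary, n = n, eigenK = eigenK),
            class = "lmmFit")
}

#' @export
print.lmmFit <- function(x, ...) {
  cat(sprintf(
    "lmmFit: n=%d, sigma_g2=%.4g, sigma_e2=%.4g (lambda=%.3g)%s\n",
    x$n, x$sigma_g2, x$sigma_e2, x$lambda,
    if (x$boundary) " [boundary]" else ""))
  print(round(cbind(beta = x$beta, se = x$se), 4))
  invisible(x)
}

#' Generalized least squares fixed effects
#'
#' beta = (X' Vinv X)^-1 X' Vinv y with covariance (X' Vinv X)^-1.
#'
#' @param y response.
#' @param X design matrix.
#' @param Vinv inverse covariance: a matrix, or a vector of per-observation
#'   weights (diagonal Vinv).
#' @return list: \code{beta}, \code{cov_beta}, \code{se}.
#' @export
glsEffects <- function(y, X, Vinv) {
  X <- as.matrix(X)
  if (is.matrix(Vinv)) {
    A <- crossprod(X, Vinv %*% X)
    b <- crossprod(X, Vinv %*% y)
  } else {
    A <- crossprod(X, Vinv * X)
    b <- crossprod(X, Vinv * y)
  }
  cov_beta <- solve(A)
  beta <- as.vector(cov_beta %*% b)
  names(beta) <- colnames(X)
  list(beta = beta, cov_beta = cov_beta, se = sqrt(diag(cov_beta)))
}

#' Likelihood-ratio p-value
#'
#' Upper chi-square tail at 2 (llAlt - llNull); a negative statistic
#' (numerical noise) is clipped to 0 with a warning.
#'
#' @param ll_null,ll_alt log-likelihoods of the nested and the larger model
#'   (ML, not REML, when the models differ in fixed effects).
#' @param df degrees of freedom (default 1).
#' @return p-value in [0, 1].
#' @export
lrtPvalue <- function(ll_null, ll_alt, df = 1) {
  stat <- 2 * (ll_alt - ll_null)
  if (stat < 0) {
    if (stat < -1e-6) warning("negative LRT statistic clipped to 0")
    stat <- 0
  }
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Joint Wald test of a coefficient subvector
#'
#' statistic = beta' cov^-1 beta, chi-square with df = length(beta).
#'
#' @param beta coefficient subvector.
#' @param cov_sub its covariance block.
#' @return list: \code{stat}, \code{df}, \code{p}.
#' @export
waldJointTest <- function(beta, cov_sub) {
  beta <- as.numeric(beta)
  stat <- as.numeric(crossprod(beta, solve(cov_sub, beta)))
  df <- length(beta)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

# ---- heteroscedastic multi-environment REML ------------------------------

# V^-1 v for block-diagonal V: per line k, V_k = diag(d_obs) + s_k 11'
# (Sherman-Morrison), d_obs = residual variance per observation, s_k the
# line's genetic variance multiplier. All vectorized over observations.
.bdApply <- function(v, d_obs, line_idx, s_line) {
  vd <- v / d_obs
  S <- rowsum(vd, line_idx)                 # per-line sums of v/d
  Tm <- rowsum(1 / d_obs, line_idx)[, 1]    # per-line sums of 1/d
  adj <- S * (s_line / (1 + s_line * Tm))
  vd - adj[line_idx, , drop = FALSE] / d_obs
}

.bdLogDet <- function(d_obs, line_idx, s_line) {
  Tm <- rowsum(1 / d_obs, line_idx)[, 1]
  sum(log(d_obs)) + sum(log1p(s_line * Tm))
}

# REML log-likelihood and GLS pieces for given variances
.heteroREML <- function(su2, se2_env, y, X, line_idx, env_idx, d_line) {
  d_obs <- se2_env[env_idx]
  s_line <- su2 * d_line
  Vy <- .bdApply(cbind(y), d_obs, line_idx, s_line)[, 1]
  VX <- .bdApply(X, d_obs, line_idx, s_line)
  A <- crossprod(X, VX)
  b <- crossprod(X, Vy)
  cov_beta <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(cov_beta)) return(NULL)
  beta <- as.vector(cov_beta %*% b)
  ypy <- sum(y * Vy) - sum(b * beta)
  ll <- -0.5 * (.bdLogDet(d_obs, line_idx, s_line) +
                determinant(A, logarithm = TRUE)$modulus[1] + ypy +
                (length(y) - ncol(X)) * log(2 * pi))
  list(ll = as.numeric(ll), beta = beta, cov_beta = cov_beta)
}

#' Heteroscedastic multi-environment REML fit
#'
#' Fits the multi-environment model y_obs = X beta + u_line + e_obs with a
#' random line effect (iid by default, or proportional to a kinship matrix)
#' and environment-specific residual variances, by quasi-Newton (L-BFGS-B)
#' maximization of the REML log-likelihood over log-variances. The
#' covariance is block-diagonal per line (after an eigen-rotation of the
#' line space when a kinship matrix is supplied), so each likelihood
#' evaluation is linear in the number of observations.
#'
#' @param y stacked response over (line, environment) observations.
#' @param X stacked fixed-effect design, full rank.
#' @param line factor/character: line of each observation.
#' @param env factor/character: environment of each observation (>= 2
#'   observations per environment required).
#' @param K optional kinship for the line effect (u ~ N(0, K sigma_u2));
#'   requires balanced data (every line observed in every environment).
#'   Default NULL: u iid.
#' @param max_iter maximum optimizer iterations (default 200).
#' @return list of class \code{heteroFit}: \code{beta}, \code{se},
#'   \code{cov_beta}, \code{sigma_u2}, \code{sigma_e2} (named per
#'   environment), \code{ll_reml}, \code{convergence}, \code{boundary}.
#' @export
remlFitHetero <- function(y, X, line, env, K = NULL, max_iter = 200) {
  X <- as.matrix(X)
  line <- as.factor(line); env <- as.factor(env)
  E <- nlevels(env)
  if (any(table(env) < 2)) stop("every environment needs >= 2 observations")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  n_line <- nlevels(line)

  if (!is.null(K)) {
    K <- .asK(K)
    tab <- table(line, env)
    if (any(tab != 1))
      stop("kinship random effect requires balanced line x environment data")
    # order observations line-major, rotate line space by eigenvectors of K
    o <- order(as.integer(line), as.integer(env))
    y <- y[o]; X <- X[o, , drop = FALSE]
    line <- line[o]; env <- env[o]
    ek <- eigen(K[levels(line), levels(line)], symmetric = TRUE)
    d_line <- pmax(ek$values, 0)
    R <- ek$vectors                       # n_line x n_line
    # y is line-major: reshape to E x n_line, rotate columns
    ym <- matrix(y, nrow = E)
    y <- as.vector(ym %*% R)
    Xr <- apply(X, 2, function(cl) as.vector(matrix(cl, nrow = E) %*% R))
    X <- Xr
    line_idx <- rep(seq_len(n_line), each = E)
    env_idx <- rep(seq_len(E), n_line)
  } else {
    d_line <- rep(1, n_line)
    line_idx <- as.integer(line)
    env_idx <- as.integer(env)
  }

  vy <- stats::var(y)
  lb <- log(1e-6 * vy)
  th0 <- log(rep(vy / 2, E + 1))
  nll <- function(th) {
    f <- .heteroREML(exp(th[1]), exp(th[-1]), y, X, line_idx, env_idx,
                     d_line)
    if (is.null(f) || !is.finite(f$ll)) 1e10 else -f$ll
  }
  opt <- stats::optim(th0, nll, method = "L-BFGS-B",
                      lower = lb, upper = log(1e4 * vy),
                      control = list(maxit = max_iter, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("heteroscedastic REML did not converge: ", opt$message)
  th <- opt$par
  fit <- .heteroREML(exp(th[1]), exp(th[-1]), y, X, line_idx, env_idx,
                     d_line)
  beta <- fit$beta
  names(beta) <- colnames(X)
  structure(list(beta = beta, se = sqrt(diag(fit$cov_beta)),
                 cov_beta = fit$cov_beta,
                 sigma_u2 = exp(th[1]),
                 sigma_e2 = stats::setNames(exp(th[-1]), levels(env)),
                 ll_reml = fit$ll, convergence = opt$convergence,
                 boundary = any(th <= lb + 1e-6),
                 n = length(y)), class = "heteroFit")
}

#' @export
print.heteroFit <- function(x, ...) {
  cat(sprintf("heteroFit: n=%d, sigma_u2=%.4g%s\n", x$n, x$sigma_u2,
              if (x$boundary) " [boundary]" else ""))
  cat("  residual variances:",
      paste(sprintf("%s=%.3g", names(x$sigma_e2), x$sigma_e2),
            collapse = ", "), "\n")
  invisible(x)
}
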