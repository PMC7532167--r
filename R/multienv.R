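`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble candidate focus haplotypes across all scans of a trait
#'
#' Union of the focus haplotypes from every scan (per environment and
#' across environments); foci marking the same region (same chromosome,
#' < \code{max_dist} apart AND r^2 >= \code{r2_min}) are deduplicated
#' keeping the one with the smaller discovery p.
#'
#' @param region_list list of region data.frames from
#'   \code{\link{defineRegions}} (one per scan).
#' @param scores 0/2 score matrix covering the focus haplotypes.
#' @param info marker info (hap_id, chrom, start_bp).
#' @param max_dist,r2_min same-region rule (defaults 1 Mb, 0.8).
#' @return data.frame: hap_id, chrom, start_bp, discovery_p, discovery_scan.
#' @export
assembleCandidates <- function(region_list, scores, info,
                               max_dist = 1e6, r2_min = 0.8) {
  rows <- list()
  for (nm in seq_along(region_list)) {
    rg <- region_list[[nm]]
    if (!nrow(rg)) next
    scan_id <- if (!is.null(names(region_list))) names(region_list)[nm]
      else as.character(nm)
    rows[[length(rows) + 1]] <- data.frame(
      hap_id = rg$focus_hap, discovery_p = rg$focus_p,
      discovery_scan = scan_id)
  }
  if (!length(rows))
    return(data.frame(hap_id = character(), chrom = character(),
                      start_bp = numeric(), discovery_p = numeric(),
                      discovery_scan = character()))
  cand <- do.call(rbind, rows)
  # same haplotype in several scans: keep the most significant record
  cand <- cand[order(cand$discovery_p), , drop = FALSE]
  cand <- cand[!duplicated(cand$hap_id), , drop = FALSE]
  m <- match(cand$hap_id, info$hap_id)
  cand$chrom <- info$chrom[m]
  cand$start_bp <- info$start_bp[m]
  # region-level dedup, greedy by ascending p
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    clash <- FALSE
    for (j in which(keep)) {
      if (cand$chrom[i] != cand$chrom[j]) next
      if (abs(cand$start_bp[i] - cand$start_bp[j]) >= max_dist) next
      r <- suppressWarnings(
        stats::cor(scores[, cand$hap_id[i]], scores[, cand$hap_id[j]]))
      if (!is.na(r) && r^2 >= r2_min) { clash <- TRUE; break }
    }
    keep[i] <- !clash
  }
  out <- cand[keep, c("hap_id", "chrom", "start_bp", "discovery_p",
                      "discovery_scan")]
  rownames(out) <- NULL
  out
}

# build the stacked multi-environment design: intercept + env + landrace +
# per-candidate per-environment score columns named "<hap>@<env>"
.buildMultiEnvDesign <- function(pheno, panel, scores, candidates, trait) {
  ph <- pheno[pheno$trait == trait & pheno$env != "ACROSS", ]
  ph <- ph[ph$line %in% rownames(scores), ]
  line <- factor(ph$line)
  env <- factor(ph$env)
  lr <- factor(populations(panel)[match(ph$line, lineIds(panel))])
  X <- stats::model.matrix(~env)
  if (nlevels(lr) > 1) {
    Xl <- stats::model.matrix(~lr)[, -1, drop = FALSE]
    X <- cbind(X, Xl)
  }
  for (h in candidates) {
    x <- scores[as.character(ph$line), h]
    for (e in levels(env)) {
      X <- cbind(X, as.numeric(env == e) * x)
      colnames(X)[ncol(X)] <- paste0(h, "@", e)
    }
  }
  list(y = ph$value, X = X, line = line, env = env, landrace = lr, ph = ph)
}

.hapCols <- function(X, hap) which(startsWith(colnames(X), paste0(hap, "@")))

# drop rank-deficient columns, removing later-entering collinear candidates
.pruneAliased <- function(X, candidates) {
  qx <- qr(X)
  dropped <- character()
  while (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    hit <- unique(sub("@.*$", "", aliased[grepl("@", aliased)]))
    if (!length(hit)) stop("base design is rank deficient")
    victim <- hit[length(hit)]
    warning("dropping collinear candidate ", victim)
    X <- X[, !startsWith(colnames(X), paste0(victim, "@")), drop = FALSE]
    candidates <- setdiff(candidates, victim)
    dropped <- c(dropped, victim)
    qx <- qr(X)
  }
  list(X = X, candidates = candidates, dropped = dropped)
}

#' Backward elimination in the multi-locus multi-environment model
#'
#' Fits all current candidate haplotypes jointly in the heteroscedastic
#' multi-environment mixed model (environment and landrace fixed effects,
#' per-haplotype-per-environment fixed effects combining main and
#' haplotype-by-environment interaction, random line effect, and
#' environment-specific residual variances). At each step every haplotype
#' is tested with a joint Wald test of its per-environment effects as the
#' last one entering the model (conditional on all others); the least
#' significant haplotype is removed while its P >= \code{threshold}.
#' Variance components are re-estimated by REML after every elimination.
#'
#' @param candidates character vector of haplotype ids (or the data.frame
#'   from \code{\link{assembleCandidates}}).
#' @param pheno data.frame (line, env, trait, value), per-environment rows.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param scores 0/2 score matrix (all phenotyped lines x haplotypes).
#' @param trait trait to model.
#' @param threshold Wald P at or above which a haplotype is dropped
#'   (default 0.01).
#' @param K optional kinship for the random line effect (default iid).
#' @param min_count candidates monomorphic (carriers < min_count or no
#'   non-carrier) within the phenotyped subset are dropped up front.
#' @return list of class \code{multiEnvModel}: \code{retained},
#'   \code{effects} (haplotype x environment beta), \code{se}, \code{wald}
#'   (final per-haplotype joint tests), \code{fit} the final
#'   \code{heteroFit}, \code{trace} data.frame of elimination steps,
#'   \code{dropped_degenerate}, \code{environments}, \code{trait}.
#' @export
backwardEliminate <- function(candidates, pheno, panel, scores, trait,
                              threshold = 0.01, K = NULL, min_count = 3) {
  if (is.data.frame(candidates)) candidates <- candidates$hap_id
  d0 <- .buildMultiEnvDesign(pheno, panel, scores, character(), trait)
  lines_ph <- unique(as.character(d0$ph$line))
  cnt <- colSums(scores[lines_ph, candidates, drop = FALSE] == 2)
  degenerate <- candidates[cnt < min_count |
                             cnt > length(lines_ph) - 1]
  candidates <- setdiff(candidates, degenerate)

  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric())
  step <- 0L
  repeat {
    des <- .buildMultiEnvDesign(pheno, panel, scores, candidates, trait)
    pr <- .pruneAliased(des$X, candidates)
    des$X <- pr$X; candidates <- pr$candidates
    fit <- remlFitHetero(des$y, des$X, des$line, des$env, K = K)
    if (!length(candidates)) break
    wald <- vapply(candidates, function(h) {
      cols <- .hapCols(des$X, h)
      waldJointTest(fit$beta[cols], fit$cov_beta[cols, cols])$p
    }, numeric(1))
    worst <- which.max(wald)
    if (wald[worst] < threshold) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     removed = candidates[worst],
                                     p = wald[worst]))
    candidates <- candidates[-worst]
  }

  E <- nlevels(des$env)
  envs <- levels(des$env)
  eff <- se <- matrix(NA_real_, length(candidates), E,
                      dimnames = list(candidates, envs))
  wald_final <- data.frame(hap_id = character(), stat = numeric(),
                           df = integer(), p = numeric())
  for (h in candidates) {
    cols <- .hapCols(des$X, h)
    eff[h, ] <- fit$beta[cols][match(paste0(h, "@", envs),
                                     colnames(des$X)[cols])]
    se[h, ] <- fit$se[cols][match(paste0(h, "@", envs),
                                  colnames(des$X)[cols])]
    wt <- waldJointTest(fit$beta[cols], fit$cov_beta[cols, cols])
    wald_final <- rbind(wald_final,
                        data.frame(hap_id = h, stat = wt$stat, df = wt$df,
                                   p = wt$p))
  }
  structure(list(retained = candidates, effects = eff, se = se,
                 wald = wald_final, fit = fit, trace = trace,
                 dropped_degenerate = degenerate, environments = envs,
                 trait = trait, threshold = threshold,
                 design = des), class = "multiEnvModel")
}

#' @export
print.multiEnvModel <- function(x, ...) {
  cat("multiEnvModel (", x$trait, "):", length(x$retained),
      "haplotypes retained after", nrow(x$trace), "eliminations;",
      length(x$environments), "environments\n")
  invisible(x)
}

#' Classify haplotype effect stability across environments
#'
#' Per environment a haplotype is significant when its 95% confidence
#' interval (estimate +/- \code{ci_mult} x SE) excludes zero. Haplotypes
#' with constant effect sign across their significant environments are
#' favorable or unfavorable according to the trait's direction convention
#' (+1: positive effects favorable, e.g. early vigor and early height;
#' -1: negative effects favorable, e.g. lodging and tillering); changing
#' sign across significant environments means interacting; no significant
#' environment means none. With \code{direction = NA} (traits without a
#' breeding-goal convention) only \code{sign_pattern} and counts are
#' reported, label \code{"unclassified"}.
#'
#' @param model a \code{multiEnvModel} (or any list with \code{effects}
#'   and \code{se} matrices haplotype x environment).
#' @param direction +1, -1 or NA.
#' @param ci_mult CI multiplier (default 1.96 for 95%).
#' @return data.frame of class \code{effectClassification}: hap_id,
#'   n_sig_env, sign_pattern ("+", "-", "mixed", "none"), label.
#' @export
classifyStability <- function(model, direction = 1, ci_mult = 1.96) {
  eff <- model$effects; se <- model$se
  out <- data.frame(hap_id = rownames(eff) %||% character(),
                    n_sig_env = integer(max(0, nrow(eff))),
                    sign_pattern = rep("none", max(0, nrow(eff))),
                    label = rep("none", max(0, nrow(eff))),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(eff))) {
    lo <- eff[i, ] - ci_mult * se[i, ]
    hi <- eff[i, ] + ci_mult * se[i, ]
    sig <- !is.na(lo) & (lo > 0 | hi < 0)
    out$n_sig_env[i] <- sum(sig)
    if (!any(sig)) next
    sgn <- sign(eff[i, sig])
    out$sign_pattern[i] <- if (all(sgn > 0)) "+"
      else if (all(sgn < 0)) "-" else "mixed"
    if (is.na(direction)) { out$label[i] <- "unclassified"; next }
    out$label[i] <- switch(out$sign_pattern[i],
      "+" = if (direction > 0) "favorable" else "unfavorable",
      "-" = if (direction > 0) "unfavorable" else "favorable",
      "mixed" = "interacting")
  }
  class(out) <- c("effectClassification", class(out))
  out
}

#' Proportion of genetic variance explained by the retained haplotypes
#'
#' Relative reduction in the REML genetic (line) variance between the
#' model without and with the haplotype fixed effects:
#' (sigma_u2_null - sigma_u2_full) / sigma_u2_null, floored at 0.
#'
#' @param model a fitted \code{multiEnvModel}.
#' @param pheno,panel,scores,K as passed to
#'   \code{\link{backwardEliminate}} (used to refit the null model).
#' @return list: \code{proportion}, \code{sigma_u2_full},
#'   \code{sigma_u2_null}.
#' @export
varianceExplained <- function(model, pheno, panel, scores, K = NULL) {
  if (!length(model$retained))
    return(list(proportion = 0,
                sigma_u2_full = model$fit$sigma_u2,
                sigma_u2_null = model$fit$sigma_u2))
  des0 <- .buildMultiEnvDesign(pheno, panel, scores, character(),
                               model$trait)
  fit0 <- remlFitHetero(des0$y, des0$X, des0$line, des0$env, K = K)
  v0 <- fit0$sigma_u2; v1 <- model$fit$sigma_u2
  list(proportion = max(0, (v0 - v1) / v0),
       sigma_u2_full = v1, sigma_u2_null = v0)
}

#' Landrace-specific effect stability of the final haplotype set
#'
#' Refits the multi-environment model with landrace-nested
#' environment-specific haplotype effects (effect of haplotype q in
#' environment i within landrace j), for haplotypes carried by at least
#' \code{min_count} lines in each of >= 2 landraces; haplotypes private to
#' one landrace are excluded with a log. For every haplotype shared
#' between a landrace pair, environment effects are cross-tabulated as
#' significant in both / one / neither landrace, with sign concordance
#' among the doubly significant ones.
#'
#' @param model a \code{multiEnvModel}.
#' @param pheno,panel,scores,K as in \code{\link{backwardEliminate}}.
#' @param min_count minimum carriers per landrace (default 3).
#' @param ci_mult CI multiplier (default 1.96).
#' @return list: \code{effects} long data.frame (hap_id, landrace, env,
#'   beta, se, lo, hi, sig), \code{pairs} per-haplotype-pair summary
#'   (n_env, sig_both, sig_one, sig_neither, sign_concordant_both),
#'   \code{excluded} haplotypes not testable in >= 2 landraces.
#' @export
landraceEffectStability <- function(model, pheno, panel, scores, K = NULL,
                                    min_count = 3, ci_mult = 1.96) {
  ph <- pheno[pheno$trait == model$trait & pheno$env != "ACROSS", ]
  ph <- ph[ph$line %in% rownames(scores), ]
  line <- factor(ph$line); env <- factor(ph$env)
  lr <- factor(populations(panel)[match(ph$line, lineIds(panel))])
  lines_u <- levels(line)
  lr_of_line <- populations(panel)[match(lines_u, lineIds(panel))]

  n_landraces <- length(unique(lr_of_line))
  testable <- list(); excluded <- character()
  for (h in model$retained) {
    cnt <- tapply(scores[lines_u, h] == 2, lr_of_line, sum)
    ok <- names(cnt)[!is.na(cnt) & cnt >= min_count]
    # with a single landrace the nested model reduces to the pooled one
    if (length(ok) >= min(2, n_landraces)) testable[[h]] <- ok else
      excluded <- c(excluded, h)
  }
  if (!length(testable))
    return(list(effects = NULL, pairs = NULL, excluded = excluded))

  X <- stats::model.matrix(~env)
  if (nlevels(lr) > 1)
    X <- cbind(X, stats::model.matrix(~lr)[, -1, drop = FALSE])
  for (h in names(testable)) {
    x <- scores[as.character(ph$line), h]
    for (j in testable[[h]]) for (e in levels(env)) {
      X <- cbind(X, as.numeric(env == e & lr == j) * x)
      colnames(X)[ncol(X)] <- paste0(h, "@", e, "@", j)
    }
  }
  keep <- qr(X)$rank
  if (keep < ncol(X)) {
    qx <- qr(X)
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  fit <- remlFitHetero(ph$value, X, line, env, K = K)

  eff <- list()
  for (h in names(testable)) for (j in testable[[h]]) for (e in levels(env)) {
    cn <- paste0(h, "@", e, "@", j)
    if (!cn %in% colnames(X)) next
    b <- fit$beta[cn]; s <- fit$se[cn]
    eff[[length(eff) + 1]] <- data.frame(
      hap_id = h, landrace = j, env = e, beta = b, se = s,
      lo = b - ci_mult * s, hi = b + ci_mult * s,
      sig = (b - ci_mult * s > 0) | (b + ci_mult * s < 0))
  }
  eff <- do.call(rbind, eff)
  rownames(eff) <- NULL

  pairs <- list()
  for (h in names(testable)) {
    ls <- testable[[h]]
    for (a in seq_along(ls)) for (b in seq_along(ls)) {
      if (a >= b) next
      ea <- eff[eff$hap_id == h & eff$landrace == ls[a], ]
      eb <- eff[eff$hap_id == h & eff$landrace == ls[b], ]
      envs <- intersect(ea$env, eb$env)
      sa <- ea$sig[match(envs, ea$env)]; sb <- eb$sig[match(envs, eb$env)]
      both <- sa & sb
      conc <- sum(both &
                    sign(ea$beta[match(envs, ea$env)]) ==
                    sign(eb$beta[match(envs, eb$env)]))
      pairs[[length(pairs) + 1]] <- data.frame(
        hap_id = h, landrace_a = ls[a], landrace_b = ls[b],
        n_env = length(envs), sig_both = sum(both),
        sig_one = sum(xor(sa, sb)), sig_neither = sum(!sa & !sb),
        sign_concordant_both = conc)
    }
  }
  list(effects = eff, pairs = do.call(rbind, pairs), excluded = excluded)
}
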