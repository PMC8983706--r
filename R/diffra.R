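#' Negative-binomial log-likelihood
#'
#' Parameterization: variance = mu + alpha * mu^2; alpha = 0 is the Poisson
#' limit.
#'
#' @param y Counts.
#' @param mu Means (positive).
#' @param alpha Dispersion: a scalar, or a vector with one value per
#'   observation (>= 0).
#' @return Scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, alpha) {
  if (all(alpha < 1e-12)) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, mu = mu, size = 1 / pmax(alpha, 1e-12), log = TRUE))
}

#' Fit a negative-binomial GLM with log link by IRLS
#'
#' Maximizes the NB log-likelihood with mean mu_w = exp(X_w beta + offset_w)
#' and variance mu + alpha mu^2 at fixed dispersion. Convergence is declared
#' when the score norm (scaled by 1 + total count) falls below `tol`.
#' Separation or a failed solve triggers a small ridge penalty
#' (1e-6 ||beta||^2) and flags the fit.
#'
#' @param y Count vector.
#' @param X Full-rank design matrix (rows = samples).
#' @param offset Log-scale offsets (e.g. log size factors), default 0.
#' @param tol Relative score-norm tolerance (default 1e-8).
#' @param maxit Maximum IRLS iterations (default 100).
#' @return List: `beta` (natural-log coefficients), `loglik`, `mu`,
#'   `converged`, `ridged`, `iterations`.
#' @export
fit_nb_glm <- function(y, X, offset = NULL, alpha = 0, tol = 1e-8,
                       maxit = 100L) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(alpha >= 0),
            length(alpha) == 1L || length(alpha) == n)
  if (is.null(offset)) offset <- numeric(n)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")

  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.solve(X, eta), error = function(e) rep(0, p))
  ridged <- FALSE
  lambda <- 0
  scale <- 1 + sum(y)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    score <- crossprod(X, (y - mu) / (1 + alpha * mu)) - lambda * beta
    if (max(abs(score)) < tol * scale) { converged <- TRUE; break }
    if (it > maxit) break
    XtWX <- crossprod(X, X * w)
    if (lambda > 0) XtWX <- XtWX + diag(lambda, p)
    z <- (eta - offset) + (y - mu) / mu
    step <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || max(abs(step)) > 30) {
      if (!ridged) {       # separation / singular system: add ridge, restart
        ridged <- TRUE
        lambda <- 1e-6
        beta <- rep(0, p)
        it <- 0L
        next
      }
      break
    }
    beta <- drop(step)
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = drop(beta), loglik = nb_loglik(y, mu, alpha), mu = mu,
       converged = converged, ridged = ridged, iterations = it)
}

#' Design for the condition-by-library-type interaction model
#'
#' Builds the full (`~ condition + type + condition:type`) and reduced
#' (`~ condition + type`) design matrices for a two-condition,
#' two-library-type comparison. The interaction coefficient is the
#' differential-RA effect: the change in the log ribo:total ratio between
#' drug and control.
#'
#' @param condition Factor-like vector per sample (control level first).
#' @param type Factor-like vector per sample, values "total"/"ribo".
#' @param control Control condition label.
#' @return List: `X_full`, `X_reduced`, `interaction_col`.
#' @export
design_spec <- function(condition, type, control) {
  condition <- as.character(condition)
  type <- as.character(type)
  stopifnot(length(condition) == length(type))
  if (!control %in% condition) stop("control label absent from design")
  other <- setdiff(unique(condition), control)
  if (length(other) != 1)
    stop("design must contain exactly one non-control condition")
  if (!setequal(unique(type), c("total", "ribo")))
    stop("type must take values 'total' and 'ribo'")
  cond_i <- as.numeric(condition == other)
  type_i <- as.numeric(type == "ribo")
  X_full <- cbind(intercept = 1, condition = cond_i, type = type_i,
                  interaction = cond_i * type_i)
  list(X_full = X_full, X_reduced = X_full[, 1:3, drop = FALSE],
       interaction_col = 4L)
}

#' Likelihood-ratio test for the condition-by-type interaction
#'
#' stat = 2 (loglik_full - loglik_reduced), clipped at zero; p from
#' chi-square with 1 degree of freedom.
#'
#' @param y Count vector (stacked samples).
#' @param design A [design_spec()].
#' @param offset Log-scale offsets.
#' @param alpha Dispersion.
#' @return List: `stat`, `pvalue`, `lfc_ln` (interaction coefficient, natural
#'   log), `converged`, `ridged`.
#' @export
lrt_interaction <- function(y, design, offset = NULL, alpha = 0) {
  full <- fit_nb_glm(y, design$X_full, offset, alpha)
  red <- fit_nb_glm(y, design$X_reduced, offset, alpha)
  if (!full$converged || !red$converged)
    return(list(stat = NA_real_, pvalue = NA_real_, lfc_ln = NA_real_,
                converged = FALSE, ridged = full$ridged || red$ridged))
  stat <- max(0, 2 * (full$loglik - red$loglik))
  list(stat = stat,
       pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       lfc_ln = full$beta[design$interaction_col],
       converged = TRUE, ridged = full$ridged || red$ridged)
}

#' Estimate NB dispersions: global trend plus moderated per-gene deviations
#'
#' Dispersion model alpha(mu) = a0 + a1/mu (variance = mu + alpha mu^2),
#' evaluated at each observation's fitted mean so that shallow (ribo) and
#' deep (total) libraries of the same gene carry their own dispersion.
#' Procedure: (1) a preliminary Poisson GLM per gene yields fitted means;
#' (2) the trend coefficients (a0, a1) maximize the Cox-Reid-adjusted
#' likelihood jointly over genes with those means held fixed; (3) each gene's
#' raw fold-deviation phi_g from the trend maximizes its own Cox-Reid-adjusted
#' likelihood; (4) the final per-gene dispersion is the weighted geometric
#' mean of raw and trend values (weight `trend_weight` toward the trend,
#' i.e. phi shrunk as phi^(1 - trend_weight)), floored at `alpha_floor`.
#'
#' @param counts Gene-by-sample count matrix (both library types stacked).
#' @param X Full design matrix.
#' @param offset Log-scale offsets per sample.
#' @param trend_weight Shrinkage weight toward the trend in [0, 1],
#'   default 0.5.
#' @param alpha_floor Lower bound on dispersions, default 1e-8.
#' @param max_trend_genes Cap on genes entering the joint trend fit (random
#'   subsample above it).
#' @return List of class `dispersion_fit`: per gene `alpha_raw`,
#'   `alpha_trend`, `alpha_final` (all evaluated at the gene's mean
#'   normalized count), `phi` (shrunken fold-deviation), `mean_norm`,
#'   `trend_coef` (a0, a1), and `mu` (gene-by-sample fitted means for
#'   per-observation dispersion). All-zero genes carry NA.
#' @export
estimate_dispersions <- function(counts, X, offset = NULL,
                                 trend_weight = 0.5, alpha_floor = 1e-8,
                                 max_trend_genes = 2000L) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (is.null(offset)) offset <- numeric(n)
  G <- nrow(counts)
  mean_norm <- rowMeans(sweep(counts, 2, exp(offset), `/`))
  nonzero <- which(rowSums(counts) > 0)

  mus <- matrix(NA_real_, G, n)
  for (g in nonzero)
    mus[g, ] <- fit_nb_glm(counts[g, ], X, offset, alpha = 0)$mu

  cr_ll <- function(y, mu, a) {
    w <- mu / (1 + a * mu)
    det_ <- determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
    nb_loglik(y, mu, a) - 0.5 * as.numeric(det_)
  }

  trend_idx <- nonzero
  if (length(trend_idx) > max_trend_genes)   # deterministic thinning
    trend_idx <- nonzero[unique(round(seq(1, length(nonzero),
                                          length.out = max_trend_genes)))]
  neg_trend <- function(par) {
    a0 <- exp(par[1]); a1 <- exp(par[2])
    tot <- 0
    for (g in trend_idx) {
      mu <- mus[g, ]
      tot <- tot + cr_ll(counts[g, ], mu, a0 + a1 / mu)
    }
    -tot
  }
  opt <- stats::optim(log(c(0.05, 1)), neg_trend, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-8))
  a0 <- exp(opt$par[1]); a1 <- exp(opt$par[2])
  # a boundary collapse of both coefficients means essentially Poisson data
  if (!is.finite(a0)) a0 <- alpha_floor
  if (!is.finite(a1)) a1 <- 0

  phi_raw <- rep(NA_real_, G)
  for (g in nonzero) {
    y <- counts[g, ]
    mu <- mus[g, ]
    base <- a0 + a1 / mu
    obj <- function(lp) cr_ll(y, mu, exp(lp) * base)
    phi_raw[g] <- exp(stats::optimize(obj, c(log(1e-6), log(100)),
                                      maximum = TRUE, tol = 1e-4)$maximum)
  }
  w <- min(max(trend_weight, 0), 1)
  phi <- phi_raw^(1 - w)
  alpha_trend <- alpha_raw <- alpha_final <- rep(NA_real_, G)
  mpos <- pmax(mean_norm, 1e-8)
  alpha_trend[nonzero] <- pmax(a0 + a1 / mpos[nonzero], alpha_floor)
  alpha_raw[nonzero] <- pmax(alpha_trend[nonzero] * phi_raw[nonzero],
                             alpha_floor)
  alpha_final[nonzero] <- pmax(alpha_trend[nonzero] * phi[nonzero],
                               alpha_floor)
  structure(list(alpha_raw = alpha_raw, alpha_trend = alpha_trend,
                 alpha_final = alpha_final, phi = phi, mean_norm = mean_norm,
                 trend_coef = c(a0 = unname(a0), a1 = unname(a1)),
                 mu = mus, alpha_floor = alpha_floor),
            class = "dispersion_fit")
}

#' Per-observation dispersions for one gene of a dispersion fit
#'
#' alpha_gw = phi_g x (a0 + a1 / mu_gw), floored: the gene's shrunken
#' fold-deviation applied to the trend at each observation's fitted mean.
#'
#' @param disp A `dispersion_fit`.
#' @param g Gene row index.
#' @return Numeric vector over samples.
#' @export
gene_dispersion <- function(disp, g) {
  mu <- disp$mu[g, ]
  if (anyNA(mu)) return(rep(NA_real_, length(mu)))
  a <- disp$phi[g] * (disp$trend_coef["a0"] + disp$trend_coef["a1"] / mu)
  pmax(unname(a), disp$alpha_floor)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH over the non-missing p-values; NAs are passed through and
#' excluded from the number of tests.
#'
#' @param pvalues Numeric vector in [0, 1], NA allowed.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Differential ribosome association for one drug versus control
#'
#' Subsets the plate to the given condition plus control wells, stacks the
#' total and ribo libraries of those wells into one count matrix, computes
#' median-of-ratios size factors across all stacked libraries as GLM offsets,
#' estimates moderated dispersions, and tests every gene for a
#' condition-by-library-type interaction with a likelihood-ratio test. The
#' interaction coefficient (log2) is the per-gene lfcRA. BH adjustment is
#' applied across the tested genes of this contrast; all-zero and
#' non-converged genes are reported NA and excluded from the BH denominator.
#'
#' @param pc A [paired_counts()].
#' @param meta A [plate_meta()] covering the wells.
#' @param condition Drug condition label.
#' @param control Control label (default "DMSO").
#' @param anno Optional [gene_anno()]; spike-ins and blacklisted genes are
#'   excluded from testing (and from the size-factor reference set).
#' @param trend_weight,alpha_floor Passed to [estimate_dispersions()].
#' @param min_count Optional independent filter: genes with mean normalized
#'   count below this are excluded before testing (default 0 = off).
#' @return Data.frame of class `ra_result`: gene, baseMean, lfcRA (log2),
#'   stat, pvalue, fdr, condition, status.
#' @export
differential_ra <- function(pc, meta, condition, control = "DMSO",
                            anno = NULL, trend_weight = 0.5,
                            alpha_floor = 1e-8, min_count = 0) {
  validate_plate(pc, meta = meta)
  idx <- match(pc$wells, meta$well)
  cond_w <- meta$condition[idx]
  for (lab in c(condition, control)) {
    if (sum(cond_w == lab) < 2)
      stop("need >= 2 wells of condition '", lab, "'")
  }
  wells <- pc$wells[cond_w %in% c(condition, control)]
  wc <- cond_w[cond_w %in% c(condition, control)]

  keep_genes <- rep(TRUE, length(pc$genes))
  if (!is.null(anno)) {
    validate_plate(pc, anno = anno)
    a <- anno[match(pc$genes, anno$gene), ]
    keep_genes <- a$biotype != "spikein" & !a$blacklisted
  }
  sub <- subset_paired_counts(pc, genes = which(keep_genes), wells = wells)
  counts <- cbind(sub$total, sub$ribo)
  colnames(counts) <- c(paste0(wells, ".total"), paste0(wells, ".ribo"))
  samp_cond <- c(wc, wc)
  samp_type <- rep(c("total", "ribo"), each = length(wells))

  sf <- size_factors(counts)
  offset <- log(sf)
  des <- design_spec(samp_cond, samp_type, control)

  mean_norm <- rowMeans(sweep(counts, 2, sf, `/`))
  status <- rep("OK", nrow(counts))
  status[rowSums(counts) == 0] <- "allzero"
  if (min_count > 0) status[status == "OK" & mean_norm < min_count] <- "filtered"
  test_idx <- which(status == "OK")

  disp <- estimate_dispersions(counts[test_idx, , drop = FALSE], des$X_full,
                               offset, trend_weight, alpha_floor)
  lfc <- stat <- pval <- rep(NA_real_, nrow(counts))
  for (k in seq_along(test_idx)) {
    g <- test_idx[k]
    res <- lrt_interaction(counts[g, ], des, offset, gene_dispersion(disp, k))
    if (!res$converged) { status[g] <- "no_converge"; next }
    if (res$ridged) status[g] <- "ridged"
    lfc[g] <- res$lfc_ln / log(2)
    stat[g] <- res$stat
    pval[g] <- res$pvalue
  }
  fdr <- bh_adjust(pval)
  out <- data.frame(gene = sub$genes, baseMean = mean_norm, lfcRA = lfc,
                    stat = stat, pvalue = pval, fdr = fdr,
                    condition = condition, status = status,
                    row.names = NULL)
  class(out) <- c("ra_result", "data.frame")
  out
}
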