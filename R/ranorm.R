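#' Median-of-ratios size factors
#'
#' Per-well scale factors s_w = median over reference genes of
#' count_gw / geomean_g, where geomean_g is the geometric mean of gene g
#' across wells and the reference set is the genes with all-positive counts
#' after masking. Factors are returned unscaled (no re-centering). Spike-ins
#' and blacklisted genes should be masked out: spike-ins present in only half
#' the wells would otherwise distort the factors.
#'
#' @param counts Gene-by-well count matrix (one library type).
#' @param gene_mask Logical vector over rows: genes eligible as references
#'   (default all).
#' @return Named numeric vector of positive per-well size factors.
#' @export
size_factors <- function(counts, gene_mask = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_mask)) gene_mask <- rep(TRUE, nrow(counts))
  stopifnot(length(gene_mask) == nrow(counts))
  m <- counts[gene_mask, , drop = FALSE]
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene has positive counts in every well after masking; ",
         "median-of-ratios size factors are undefined")
  lm_ <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(lm_)
  sf <- apply(exp(lm_ - geo), 2, stats::median)
  if (any(sf <= 0)) stop("nonpositive size factor computed")
  sf
}

#' Log-scale variance-stabilizing transform
#'
#' value = log2(count / s_w + pseudocount); monotone in count and finite
#' everywhere. This is the package's stated log-shift stand-in for a
#' parametric variance-stabilizing transform: it matches log-ratio semantics
#' in the moderate-count regime where ribosome association is interpretable.
#'
#' @param counts Gene-by-well count matrix.
#' @param sf Per-well size factors (positive, length = ncol).
#' @param pseudocount Positive shift, default 1.
#' @return Matrix of log2-scale values, same dimnames.
#' @export
vst <- function(counts, sf, pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(sf) == ncol(counts))
  if (any(sf <= 0)) stop("size factors must be positive")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  log2(sweep(counts, 2, sf, `/`) + pseudocount)
}

#' Ribosome association matrix
#'
#' RA_gw = vst_ribo_gw - vst_total_gw: the log2 ratio of normalized ribo to
#' total signal, the per-gene, per-well ribosome association.
#'
#' @param vst_ribo,vst_total Matched log2-scale matrices from [vst()].
#' @return RA matrix (genes x wells).
#' @export
ribosome_association <- function(vst_ribo, vst_total) {
  if (!identical(dim(vst_ribo), dim(vst_total)))
    stop("ribo and total matrices must have identical shapes")
  if (!is.null(dimnames(vst_ribo)) && !is.null(dimnames(vst_total)) &&
      !identical(dimnames(vst_ribo), dimnames(vst_total)))
    stop("ribo and total matrices must share gene/well orderings")
  vst_ribo - vst_total
}

#' Log fold change in RA relative to the vehicle-control mean
#'
#' lfcRA_gw = RA_gw - mean over control wells of RA_g. Over the control wells
#' themselves the per-gene mean of lfcRA is exactly zero.
#'
#' @param ra RA matrix from [ribosome_association()].
#' @param meta [plate_meta()] covering the wells of `ra`.
#' @param control Control condition label (default "DMSO").
#' @return Matrix of lfcRA values, same shape as `ra`.
#' @export
lfc_ra <- function(ra, meta, control = "DMSO") {
  wells <- colnames(ra)
  idx <- match(wells, meta$well)
  if (anyNA(idx)) stop("wells of RA matrix missing from metadata")
  ctrl <- wells[meta$condition[idx] == control]
  if (length(ctrl) < 2)
    stop("need >= 2 wells of control condition '", control, "'")
  baseline <- rowMeans(ra[, ctrl, drop = FALSE])
  ra - baseline
}

#' Convenience: full RA pipeline from paired counts
#'
#' Computes per-library-type size factors (masking spike-ins and blacklisted
#' genes when annotation is given), the log-shift transform, and the RA
#' matrix.
#'
#' @param pc A [paired_counts()].
#' @param anno Optional [gene_anno()]; spike-ins and blacklisted genes are
#'   excluded from the size-factor reference set.
#' @param pseudocount Passed to [vst()].
#' @return List with `ra`, `vst_ribo`, `vst_total`, `sf_ribo`, `sf_total`.
#' @export
ra_profile <- function(pc, anno = NULL, pseudocount = 1) {
  mask <- rep(TRUE, length(pc$genes))
  if (!is.null(anno)) {
    validate_plate(pc, anno = anno)
    a <- anno[match(pc$genes, anno$gene), ]
    mask <- a$biotype != "spikein" & !a$blacklisted
  }
  sf_r <- size_factors(pc$ribo, mask)
  sf_t <- size_factors(pc$total, mask)
  vr <- vst(pc$ribo, sf_r, pseudocount)
  vt <- vst(pc$total, sf_t, pseudocount)
  list(ra = ribosome_association(vr, vt), vst_ribo = vr, vst_total = vt,
       sf_ribo = sf_r, sf_total = sf_t)
}

#' Paired Wilcoxon signed-rank test with a tie-aware exact null
#'
#' Tests the paired differences x - y. Zero differences are dropped; absolute
#' differences are ranked with average ranks for ties. For n <= 25 pairs the
#' null distribution of the signed-rank sum V is enumerated exactly over all
#' 2^n sign assignments (via dynamic programming on doubled ranks, so tied
#' ranks are handled exactly); above that, the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative "less" (x < y), "greater" or "two.sided".
#' @return List: `statistic` (V), `p_value`, `n` (nonzero pairs), `method`.
#' @export
signed_rank_test <- function(x, y,
                             alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L, method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))          # doubled ranks are integers
    tot <- sum(r2)
    dist <- numeric(tot + 1)                # dist[s+1] = #assignments with 2V = s
    dist[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), dist[seq_len(tot + 1 - rr)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1)])
    p_ge <- sum(dist[(v2 + 1):(tot + 1)])
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    p <- switch(alternative,
                less = stats::pnorm(v - mu + cc, sd = sqrt(sig2)),
                greater = stats::pnorm(-(v - mu - cc), sd = sqrt(sig2)),
                two.sided = min(1, 2 * stats::pnorm(
                  -(abs(v - mu) - cc), sd = sqrt(sig2))))
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Spike-in depletion report
#'
#' For every spike-in-bearing well, computes the log2 ratio of summed
#' normalized ribo over summed normalized total counts separately for
#' spike-ins (`spike_depletion`) and endogenous genes (`gene_depletion`),
#' their per-well difference, and a one-tailed paired Wilcoxon signed-rank
#' test of spike-in < gene components. Spike-ins, not being ribosome-bound,
#' should be strongly depleted by the IP relative to the transcriptome.
#'
#' @param pc A [paired_counts()] containing spike-in rows.
#' @param anno [gene_anno()] identifying spike-ins.
#' @param meta [plate_meta()] flagging spike-in-bearing wells.
#' @param sf_ribo,sf_total Optional size factors; computed from non-spike,
#'   non-blacklisted genes when omitted.
#' @return List of class `depletion_report`: `per_well` data.frame (well,
#'   spike_depletion, gene_depletion, difference), `mean_spike_ra`,
#'   `mean_gene_ra`, `statistic`, `p_value`, `n`, `alternative`.
#' @export
spikein_depletion <- function(pc, anno, meta, sf_ribo = NULL, sf_total = NULL) {
  validate_plate(pc, meta = meta, anno = anno)
  a <- anno[match(pc$genes, anno$gene), ]
  spike <- a$biotype == "spikein"
  if (!any(spike)) stop("no spike-in genes present in the count matrices")
  mask <- !spike & !a$blacklisted
  if (is.null(sf_ribo)) sf_ribo <- size_factors(pc$ribo, mask)
  if (is.null(sf_total)) sf_total <- size_factors(pc$total, mask)
  norm_r <- sweep(pc$ribo, 2, sf_ribo, `/`)
  norm_t <- sweep(pc$total, 2, sf_total, `/`)

  flagged <- meta$well[meta$spikein]
  wells <- intersect(pc$wells, flagged)
  if (!length(wells)) stop("no spike-in-bearing wells in the plate")
  sr <- colSums(norm_r[spike, wells, drop = FALSE])
  st <- colSums(norm_t[spike, wells, drop = FALSE])
  gr <- colSums(norm_r[mask, wells, drop = FALSE])
  gt <- colSums(norm_t[mask, wells, drop = FALSE])
  usable <- (sr > 0 | st > 0) & st > 0 & gt > 0
  if (any(!usable))
    message("excluding ", sum(!usable),
            " well(s) with zero spike-in signal in both libraries")
  wells <- wells[usable]
  spike_dep <- log2(sr[usable] / st[usable])
  gene_dep <- log2(gr[usable] / gt[usable])
  wt <- signed_rank_test(spike_dep, gene_dep, alternative = "less")
  structure(list(
    per_well = data.frame(well = wells, spike_depletion = spike_dep,
                          gene_depletion = gene_dep,
                          difference = spike_dep - gene_dep,
                          row.names = NULL),
    mean_spike_ra = mean(2^spike_dep),
    mean_gene_ra = mean(2^gene_dep),
    statistic = wt$statistic,
    p_value = wt$p_value,
    n = length(wells),
    alternative = "less"
  ), class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat("spike-in depletion over ", x$n, " well(s)\n", sep = "")
  cat("  mean spike-in RA: ", signif(x$mean_spike_ra, 3),
      "; mean gene RA: ", signif(x$mean_gene_ra, 3), "\n", sep = "")
  cat("  mean log2 depletion difference: ",
      signif(mean(x$per_well$difference), 3), "\n", sep = "")
  cat("  one-tailed paired Wilcoxon signed-rank p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' RA versus abundance, stratified by biotype
#'
#' Per-gene mean RA against mean total-library abundance, with biotype labels
#' for plotting, plus a one-tailed two-sample Mann-Whitney U test that ncRNA
#' RA is lower than coding RA. Strata with fewer than 2 genes are skipped.
#'
#' @param ra RA matrix.
#' @param vst_total Matched transformed total matrix (abundance scale).
#' @param anno [gene_anno()] covering the genes.
#' @return List: `per_gene` data.frame (gene, mean_abundance, mean_ra,
#'   biotype), `test` (statistic, p_value, n, alternative) or NULL when a
#'   stratum is too small.
#' @export
ra_vs_abundance <- function(ra, vst_total, anno) {
  stopifnot(identical(dim(ra), dim(vst_total)))
  a <- anno[match(rownames(ra), anno$gene), ]
  per_gene <- data.frame(
    gene = rownames(ra),
    mean_abundance = rowMeans(vst_total),
    mean_ra = rowMeans(ra),
    biotype = a$biotype,
    row.names = NULL
  )
  test <- NULL
  nc <- per_gene$mean_ra[per_gene$biotype == "ncRNA"]
  cod <- per_gene$mean_ra[per_gene$biotype == "coding"]
  if (length(nc) >= 2 && length(cod) >= 2) {
    wt <- stats::wilcox.test(nc, cod, alternative = "less",
                             exact = length(nc) * length(cod) <= 10000)
    test <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = c(ncRNA = length(nc), coding = length(cod)),
                 alternative = "less")
  } else {
    message("a biotype stratum has < 2 genes; Mann-Whitney test skipped")
  }
  list(per_gene = per_gene, test = test)
}
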