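#' Subsample a count vector to an exact target depth
#'
#' Draws `depth` reads without replacement from the multiset of gene-assigned
#' reads (multivariate hypergeometric, realized by sequential hypergeometric
#' draws), so the thinned vector sums exactly to the target depth.
#'
#' @param counts Nonnegative integer vector.
#' @param depth Target depth, <= sum(counts).
#' @param seed Optional integer seed for this draw.
#' @return Thinned count vector of the same length and names.
#' @export
subsample_counts <- function(counts, depth, seed = NULL) {
  total <- sum(counts)
  if (depth > total)
    stop("target depth (", depth, ") exceeds library size (", total, ")")
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(length(counts))
  remaining <- total
  need <- depth
  for (i in seq_along(counts)) {
    if (need == 0) break
    ci <- counts[i]
    if (ci == 0) next
    # reads for gene i among the `need` still to draw from `remaining`
    take <- stats::rhyper(1, ci, remaining - ci, need)
    out[i] <- take
    need <- need - take
    remaining <- remaining - ci
  }
  names(out) <- names(counts)
  out
}

#' Gene-detection saturation curves
#'
#' Number of unique genes detected (count >= 1) per well at each subsampled
#' read depth, averaged over seeds, for both library types. Wells smaller
#' than a depth are omitted at that depth.
#'
#' @param pc A [paired_counts()].
#' @param depths Ascending vector of subsampling depths.
#' @param seeds Integer vector of seeds to average over.
#' @return Long data.frame: well, library_type, depth, genes_detected
#'   (seed-averaged).
#' @export
saturation_curve <- function(pc, depths, seeds = 1L) {
  stopifnot(!is.unsorted(depths))
  rows <- list()
  for (lib in c("ribo", "total")) {
    m <- pc[[lib]]
    sizes <- colSums(m)
    for (w in seq_along(pc$wells)) {
      feasible <- depths[depths <= sizes[w]]
      if (!length(feasible)) next
      # nested thinning: each depth subsamples the previous (larger) one, so
      # curves are non-decreasing in depth for every single seed
      det <- matrix(0, length(feasible), length(seeds))
      for (j in seq_along(seeds)) {
        cur <- m[, w]
        for (i in rev(seq_along(feasible))) {
          cur <- subsample_counts(cur, feasible[i], seed = seeds[j] + i)
          det[i, j] <- sum(cur > 0)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        well = pc$wells[w], library_type = lib, depth = feasible,
        genes_detected = rowMeans(det))
    }
  }
  do.call(rbind, rows)
}

#' Per-well ribo:total complexity ratio
#'
#' rho_w = (complexity proxy of the ribo library / proxy of the total
#' library) x (input_fraction_total / input_fraction_ribo). Two proxies are
#' computed: `genes` (genes detected at a common subsampled depth, the
#' default `proxy`) and `size` (summed counts); both appear in the output.
#' The common depth is the largest depth feasible for at least 90% of
#' libraries. Wells whose libraries are both smaller than the common depth
#' are skipped for the `genes` proxy.
#'
#' @param pc A [paired_counts()].
#' @param meta A [plate_meta()] carrying input fractions.
#' @param proxy `"genes"` or `"size"`: which proxy fills the `rho` column and
#'   the plate mean.
#' @param common_depth Override for the common subsampling depth.
#' @param seed Seed for the subsampling draws.
#' @return List: `per_well` data.frame (well, rho_genes, rho_size, rho),
#'   `mean_rho`, `proxy`, `common_depth`.
#' @export
complexity_ratio <- function(pc, meta, proxy = c("genes", "size"),
                             common_depth = NULL, seed = 1L) {
  proxy <- match.arg(proxy)
  validate_plate(pc, meta = meta)
  sizes_r <- colSums(pc$ribo)
  sizes_t <- colSums(pc$total)
  if (is.null(common_depth))
    common_depth <- floor(stats::quantile(c(sizes_r, sizes_t), 0.10,
                                          type = 1, names = FALSE))
  idx <- match(pc$wells, meta$well)
  corr <- meta$input_fraction_total[idx] / meta$input_fraction_ribo[idx]
  rho_size <- sizes_r / sizes_t * corr
  rho_genes <- rep(NA_real_, length(pc$wells))
  feasible <- sizes_r >= common_depth & sizes_t >= common_depth
  if (any(!feasible))
    message("skipping ", sum(!feasible),
            " well(s) below the common depth for the genes proxy")
  for (w in which(feasible)) {
    gr <- sum(subsample_counts(pc$ribo[, w], common_depth, seed = seed) > 0)
    gt <- sum(subsample_counts(pc$total[, w], common_depth, seed = seed) > 0)
    rho_genes[w] <- gr / gt * corr[w]
  }
  per_well <- data.frame(well = pc$wells, rho_genes = rho_genes,
                         rho_size = rho_size, row.names = NULL)
  per_well$rho <- if (proxy == "genes") per_well$rho_genes else per_well$rho_size
  list(per_well = per_well, mean_rho = mean(per_well$rho, na.rm = TRUE),
       proxy = proxy, common_depth = common_depth)
}

#' Immunoprecipitation efficiency from the complexity ratio
#'
#' eta = rho / f_p: the measured ribo:total complexity ratio divided by the
#' assumed fraction of polyadenylated mRNA that is polysome-associated.
#'
#' @param mean_rho Mean complexity ratio, >= 0.
#' @param f_p Polysomal fraction in (0, 1], default 0.80 (literature value
#'   for polyadenylated RNA sedimenting heavier than monosomes).
#' @return List: `eta` (fraction), `percent` (eta x 100).
#' @export
ip_efficiency <- function(mean_rho, f_p = 0.80) {
  if (!is.numeric(f_p) || f_p <= 0 || f_p > 1)
    stop("polysomal fraction f_p must lie in (0, 1]")
  if (mean_rho < 0) stop("complexity ratio must be nonnegative")
  eta <- mean_rho / f_p
  list(eta = eta, percent = 100 * eta)
}

#' Per-well library QC summary
#'
#' Library sizes and genes detected at full depth for both library types.
#'
#' @param pc A [paired_counts()].
#' @return Data.frame: well, library_type, library_size, genes_detected.
#' @export
qc_summary <- function(pc) {
  do.call(rbind, lapply(c("ribo", "total"), function(lib) {
    m <- pc[[lib]]
    data.frame(well = pc$wells, library_type = lib,
               library_size = colSums(m), genes_detected = colSums(m > 0),
               row.names = NULL)
  }))
}
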