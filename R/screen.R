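#' PCA of RA or lfcRA profiles
#'
#' Column-centered principal component analysis of per-well RA (or lfcRA)
#' profiles, restricted to a gene subset (typically the genes with a
#' significant RA change under any treatment).
#'
#' @param mat Gene-by-well matrix (RA or lfcRA).
#' @param genes Optional character vector restricting the gene domain.
#' @param n_components Number of components to keep.
#' @return List: `scores` (wells x components), `loadings`, `explained`
#'   (variance fractions).
#' @export
pca_ra <- function(mat, genes = NULL, n_components = 2) {
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(mat))
    if (!length(genes)) stop("gene subset is disjoint from the matrix")
    mat <- mat[genes, , drop = FALSE]
  }
  if (ncol(mat) < 2) stop("PCA needs at least 2 samples")
  x <- t(mat)                      # samples x genes
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       loadings = pr$rotation[, seq_len(k), drop = FALSE],
       explained = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)])
}

#' Flag PCA outlier wells by robust distance
#'
#' A well is an outlier when its robust z-score (|x - median| / MAD,
#' per component) exceeds `k` on any of the first two components.
#' Zero-MAD components are skipped.
#'
#' @param scores Sample-by-component score matrix from [pca_ra()].
#' @param k Robust z threshold, default 4.
#' @return List: `outliers` (well IDs), `distance` (max robust z per well).
#' @export
detect_outliers <- function(scores, k = 4) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 4) stop("outlier detection needs >= 4 samples")
  use <- seq_len(min(2L, ncol(scores)))
  z <- matrix(0, nrow(scores), length(use))
  for (j in use) {
    s <- scores[, j]
    md <- stats::mad(s)
    if (md == 0) {
      message("component ", j, " has zero MAD; skipped")
      next
    }
    z[, j] <- abs(s - stats::median(s)) / md
  }
  d <- apply(z, 1, max)
  names(d) <- rownames(scores)
  list(outliers = rownames(scores)[d > k], distance = d)
}

#' Build per-condition up/down target sets from differential RA results
#'
#' Thresholds each condition's results at `fdr < q`, split by direction of
#' lfcRA. With `exclusive = TRUE`, any gene appearing in more than one
#' condition's same-direction set is removed from all of them, so no two
#' conditions share an up- or downregulated gene.
#'
#' @param results Named list of `ra_result` tables (one per condition), or a
#'   single table.
#' @param q FDR threshold, default 0.05.
#' @param exclusive Enforce mutual exclusivity across conditions.
#' @return List of class `target_sets`: per condition, `list(up =, down =)`.
#' @export
build_target_sets <- function(results, q = 0.05, exclusive = FALSE) {
  if (is.data.frame(results)) results <- split(results, results$condition)
  sets <- lapply(results, function(tab) {
    sig <- !is.na(tab$fdr) & tab$fdr < q
    list(up = tab$gene[sig & tab$lfcRA > 0],
         down = tab$gene[sig & tab$lfcRA < 0])
  })
  if (exclusive && length(sets) > 1) {
    for (dir in c("up", "down")) {
      all_g <- unlist(lapply(sets, `[[`, dir), use.names = FALSE)
      shared <- unique(all_g[duplicated(all_g)])
      for (nm in names(sets))
        sets[[nm]][[dir]] <- setdiff(sets[[nm]][[dir]], shared)
    }
  }
  structure(sets, class = "target_sets")
}

#' One-tailed two-sample Mann-Whitney shift test
#'
#' Tests whether the lfc values of set A are shifted relative to group B
#' (another set or the background), with the exact null for small groups and
#' the tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param alternative "less", "greater" or "two.sided".
#' @return List: `statistic` (U), `p_value`, `n`, `alternative`.
#' @export
shift_test <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  use_exact <- length(x) * length(y) <= 10000 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = use_exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(x), length(y)), alternative = alternative)
}

# Classic (unweighted) running-sum enrichment score given hit positions.
# ranks: sorted positions of the set's genes in the ranked list (1 = top).
classic_es <- function(ranks, N) {
  k <- length(ranks)
  if (k == 0 || k >= N) return(if (k == N) 1 else NA_real_)
  ranks <- sort(ranks)
  i <- seq_len(k)
  # integer numerators over the common denominator k(N-k): exact ties between
  # the positive and negative extreme resolve deterministically (positive wins)
  hit <- i * (N - k) - (ranks - i) * k          # just after each hit
  before <- (i - 1) * (N - k) - (ranks - i) * k # just before each hit
  m <- max(hit)
  mn <- min(before, 0)
  (if (m >= -mn) m else mn) / (k * (N - k))
}

#' Preranked gene-set enrichment (classic enrichment score)
#'
#' Classic unweighted running sum: +1/Nh at set hits, -1/(N - Nh) at misses,
#' walked down the ranking sorted by descending score (ties broken by gene
#' ID); ES is the maximum signed deviation (an exact tie between the
#' positive and negative extremes reports the positive one). The null is
#' built from
#' `n_perm` random gene-label permutations; NES = ES / mean(|null ES| of the
#' matching sign), and the nominal p is one-sided by ES sign with a +1
#' pseudocount.
#'
#' @param scores Named numeric vector of per-gene ranking scores (e.g. lfcTE).
#' @param gene_set Character vector.
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed.
#' @return List of class `enrichment_result`: `es`, `nes`, `p_value`,
#'   `n_hits`, `n_perm`, `size_universe`. NA `es` (with a message) when the
#'   set misses the universe entirely.
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 1000, seed = 1L) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  N <- length(ranked)
  hits <- which(ranked %in% gene_set)
  k <- length(hits)
  if (k == 0) {
    message("gene set has no overlap with the ranked universe")
    return(structure(list(es = NA_real_, nes = NA_real_, p_value = NA_real_,
                          n_hits = 0L, n_perm = n_perm, size_universe = N),
                     class = "enrichment_result"))
  }
  if (k == N)
    warning("gene set covers the entire universe; ES is degenerate")
  es <- classic_es(hits, N)
  if (k == N) {
    return(structure(list(es = 1, nes = NA_real_, p_value = NA_real_,
                          n_hits = k, n_perm = n_perm, size_universe = N),
                     class = "enrichment_result"))
  }
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i)
    classic_es(sample.int(N, k), N), numeric(1))
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  b <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
  structure(list(es = es, nes = nes, p_value = (b + 1) / (n_perm + 1),
                 n_hits = k, n_perm = n_perm, size_universe = N),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("classic enrichment: ES = ", signif(x$es, 3), ", NES = ",
      signif(x$nes, 3), ", p = ", format(x$p_value, digits = 3),
      " (", x$n_hits, "/", x$size_universe, " genes, ", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Enrichment of many target sets against a ranked signature
#'
#' Runs [gsea_preranked()] for each set and applies a Bonferroni family-wise
#' adjustment across the reported sets.
#'
#' @param scores Named ranking vector.
#' @param sets Named list of gene sets.
#' @param n_perm,seed Passed through.
#' @return Data.frame: set, es, nes, p_value, fwer (Bonferroni), n_hits.
#' @export
gsea_table <- function(scores, sets, n_perm = 1000, seed = 1L) {
  rows <- lapply(names(sets), function(nm) {
    r <- gsea_preranked(scores, sets[[nm]], n_perm, seed)
    data.frame(set = nm, es = r$es, nes = r$nes, p_value = r$p_value,
               n_hits = r$n_hits)
  })
  out <- do.call(rbind, rows)
  out$fwer <- pmin(out$p_value * nrow(out), 1)
  out
}

#' Attenuation of single-drug effects under a combination treatment
#'
#' For every gene significant (fdr < q) under drug A or drug B, compares the
#' stronger individual effect x (the lfcRA of whichever constituent has the
#' larger |lfcRA|) with the combination effect y. Classes: `attenuated` when
#' sign(y) = sign(x) and |y| < |x| (y = 0 included); `enhanced` when
#' sign(y) = sign(x) and |y| >= |x| (the y = x boundary counts as enhanced);
#' `reversed` when the signs differ.
#'
#' @param res_a,res_b,res_combo `ra_result` tables sharing a gene universe.
#' @param q FDR threshold for calling individual-drug targets.
#' @return List of class `attenuation_table`: `per_gene` data.frame (gene,
#'   x, y, direction, class), `fractions` (per direction of x, fraction of
#'   each class).
#' @export
attenuation_analysis <- function(res_a, res_b, res_combo, q = 0.05) {
  if (is.null(res_combo)) stop("combination results are required")
  sig <- function(tab) tab$gene[!is.na(tab$fdr) & tab$fdr < q]
  genes <- union(sig(res_a), sig(res_b))
  genes <- intersect(genes, res_combo$gene[!is.na(res_combo$lfcRA)])
  la <- res_a$lfcRA[match(genes, res_a$gene)]
  lb <- res_b$lfcRA[match(genes, res_b$gene)]
  la[is.na(la)] <- 0; lb[is.na(lb)] <- 0
  x <- ifelse(abs(la) >= abs(lb), la, lb)
  y <- res_combo$lfcRA[match(genes, res_combo$gene)]
  cls <- ifelse(y == 0 | sign(y) == sign(x),
                ifelse(abs(y) < abs(x), "attenuated", "enhanced"),
                "reversed")
  cls[y == 0 & x != 0] <- "attenuated"
  per_gene <- data.frame(gene = genes, x = x, y = y,
                         direction = ifelse(x > 0, "up", "down"),
                         class = cls, row.names = NULL)
  fractions <- do.call(rbind, lapply(split(per_gene, per_gene$direction),
    function(d) {
      data.frame(direction = d$direction[1], n = nrow(d),
                 attenuated = mean(d$class == "attenuated"),
                 enhanced = mean(d$class == "enhanced"),
                 reversed = mean(d$class == "reversed"), row.names = NULL)
    }))
  structure(list(per_gene = per_gene, fractions = fractions),
            class = "attenuation_table")
}

#' TOP-gene enrichment over the regions of a kinase-target network
#'
#' Partitions the union of the kinase target sets into its nonempty
#' intersection regions (every distinct membership pattern), then tests each
#' (region, TOP set) pair for enrichment with a one-sided Fisher's exact test
#' on the 2x2 table {in region / not} x {in TOP set / not} over the given
#' universe, BH-adjusted across all tests. Also emits a kinase-to-gene edge
#' list for external graph tools.
#'
#' @param kinase_sets Named list (>= 2) of per-kinase target gene sets
#'   (e.g. the `down` sets of [build_target_sets()]).
#' @param top_sets Named list of TOP gene sets (canonical, candidate).
#' @param universe Character vector: all analyzed genes.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return List of class `network_table`: `regions` data.frame (region,
#'   kinases, size, set, overlap, p_value, p_adj), `edges` (kinase, gene),
#'   `membership` (gene, region).
#' @export
enrichment_network <- function(kinase_sets, top_sets, universe,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(kinase_sets) < 2) stop("need at least 2 kinase target sets")
  kinase_sets <- lapply(kinase_sets, intersect, y = universe)
  dropped <- setdiff(unlist(top_sets, use.names = FALSE), universe)
  if (length(dropped))
    warning(length(dropped), " TOP set member(s) absent from the universe ",
            "were dropped")
  top_sets <- lapply(top_sets, intersect, y = universe)

  all_targets <- sort(unique(unlist(kinase_sets, use.names = FALSE)))
  memb <- sapply(kinase_sets, function(s) all_targets %in% s)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(all_targets))
  pattern <- apply(memb, 1, function(r)
    paste(names(kinase_sets)[r], collapse = "&"))
  membership <- data.frame(gene = all_targets, region = pattern,
                           row.names = NULL)

  N <- length(universe)
  rows <- list()
  for (reg in unique(pattern)) {
    region_genes <- all_targets[pattern == reg]
    for (ts in names(top_sets)) {
      a <- length(intersect(region_genes, top_sets[[ts]]))
      b <- length(region_genes) - a
      c_ <- length(top_sets[[ts]]) - a
      d <- N - a - b - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                               alternative = alternative)
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, size = length(region_genes), set = ts, overlap = a,
        p_value = ft$p.value)
    }
  }
  regions <- do.call(rbind, rows)
  regions$p_adj <- bh_adjust(regions$p_value)
  edges <- do.call(rbind, lapply(names(kinase_sets), function(k) {
    if (!length(kinase_sets[[k]])) return(NULL)
    data.frame(source = k, target = kinase_sets[[k]], row.names = NULL)
  }))
  structure(list(regions = regions, edges = edges, membership = membership),
            class = "network_table")
}
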