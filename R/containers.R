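#' Paired ribo/total count container
#'
#' Holds the two gene-by-well integer count matrices of a plate experiment:
#' `ribo` (ribosome-IP libraries) and `total` (total-RNA libraries), sharing
#' identical gene and well orderings.
#'
#' @param ribo,total Nonnegative integer matrices (genes x wells) with
#'   identical dimnames, or objects coercible to such matrices.
#' @return An object of class `paired_counts` with elements `genes`, `wells`,
#'   `ribo`, `total`.
#' @export
paired_counts <- function(ribo, total) {
  ribo <- as.matrix(ribo)
  total <- as.matrix(total)
  if (is.null(rownames(ribo)) || is.null(colnames(ribo)) ||
      is.null(rownames(total)) || is.null(colnames(total)))
    stop("count matrices must carry gene rownames and well colnames")
  if (!identical(dim(ribo), dim(total)))
    stop("ribo and total matrices must have identical dimensions")
  if (!identical(rownames(ribo), rownames(total)))
    stop("ribo and total matrices must share the same gene ordering")
  if (!identical(colnames(ribo), colnames(total)))
    stop("ribo and total matrices must share the same well ordering")
  dup <- unique(rownames(ribo)[duplicated(rownames(ribo))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(utils::head(dup, 10L), collapse = ", "))
  for (m in list(ribo, total)) {
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      stop("counts must be finite nonnegative integers")
  }
  storage.mode(ribo) <- "double"
  storage.mode(total) <- "double"
  structure(
    list(genes = rownames(ribo), wells = colnames(ribo),
         ribo = ribo, total = total),
    class = "paired_counts"
  )
}

#' @export
print.paired_counts <- function(x, ...) {
  cat("paired_counts: ", length(x$genes), " genes x ", length(x$wells),
      " wells\n", sep = "")
  cat("  ribo library sizes:  ",
      paste(format(range(colSums(x$ribo)), big.mark = ","), collapse = " - "),
      "\n", sep = "")
  cat("  total library sizes: ",
      paste(format(range(colSums(x$total)), big.mark = ","), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.paired_counts <- function(x) c(length(x$genes), length(x$wells))

#' Subset a paired_counts object by gene and/or well
#'
#' @param pc A `paired_counts` object.
#' @param genes,wells Character vectors (or logical/integer indices) selecting
#'   genes and wells; `NULL` keeps everything.
#' @return A `paired_counts` with both matrices subset identically.
#' @export
subset_paired_counts <- function(pc, genes = NULL, wells = NULL) {
  stopifnot(inherits(pc, "paired_counts"))
  gi <- if (is.null(genes)) seq_along(pc$genes) else genes
  wi <- if (is.null(wells)) seq_along(pc$wells) else wells
  ribo <- pc$ribo[gi, wi, drop = FALSE]
  total <- pc$total[gi, wi, drop = FALSE]
  structure(
    list(genes = rownames(ribo), wells = colnames(ribo),
         ribo = ribo, total = total),
    class = "paired_counts"
  )
}

#' Per-well plate metadata
#'
#' @param well Well IDs (unique).
#' @param condition Treatment label per well ("DMSO" is the usual vehicle
#'   control).
#' @param spikein Logical: did this well receive ERCC spike-in mix?
#' @param input_fraction_ribo,input_fraction_total Fraction of the lysate
#'   volume routed to each library arm, in (0, 1]; used by the complexity
#'   correction.
#' @return A `data.frame` with class `plate_meta`.
#' @export
plate_meta <- function(well, condition, spikein = FALSE,
                       input_fraction_ribo = 0.5,
                       input_fraction_total = 0.5) {
  well <- as.character(well)
  if (anyDuplicated(well)) stop("duplicate well IDs in plate metadata")
  df <- data.frame(
    well = well,
    condition = as.character(condition),
    spikein = as.logical(spikein),
    input_fraction_ribo = as.numeric(input_fraction_ribo),
    input_fraction_total = as.numeric(input_fraction_total),
    stringsAsFactors = FALSE
  )
  bad <- df$input_fraction_ribo <= 0 | df$input_fraction_ribo > 1 |
    df$input_fraction_total <= 0 | df$input_fraction_total > 1
  if (any(bad)) stop("input fractions must lie in (0, 1]")
  class(df) <- c("plate_meta", "data.frame")
  df
}

#' Per-gene annotation
#'
#' @param gene Gene IDs (unique).
#' @param biotype One of "coding", "ncRNA", "spikein" per gene.
#' @param top_status One of "canonical", "candidate", "none": membership in
#'   the canonical or candidate 5' TOP-motif gene sets.
#' @param blacklisted Logical: gene is on the poly(A)-minus blacklist and
#'   excluded from analysis.
#' @return A `data.frame` with class `gene_anno`.
#' @export
gene_anno <- function(gene, biotype = "coding", top_status = "none",
                      blacklisted = FALSE) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene IDs in annotation")
  biotype <- match_vec(biotype, c("coding", "ncRNA", "spikein"), length(gene))
  top_status <- match_vec(top_status, c("canonical", "candidate", "none"),
                          length(gene))
  if (any(biotype == "spikein" & top_status != "none"))
    stop("spike-ins can never carry TOP status")
  df <- data.frame(
    gene = gene, biotype = biotype, top_status = top_status,
    blacklisted = rep_len(as.logical(blacklisted), length(gene)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_anno", "data.frame")
  df
}

match_vec <- function(x, choices, n) {
  x <- rep_len(as.character(x), n)
  bad <- setdiff(unique(x), choices)
  if (length(bad))
    stop("invalid value(s) ", paste(bad, collapse = ", "),
         "; expected one of ", paste(choices, collapse = "/"))
  x
}

#' Check that metadata and annotation cover a paired_counts object
#'
#' @param pc A `paired_counts`.
#' @param meta A `plate_meta` covering every well (optional).
#' @param anno A `gene_anno` covering every gene (optional).
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_plate <- function(pc, meta = NULL, anno = NULL) {
  stopifnot(inherits(pc, "paired_counts"))
  if (!is.null(meta)) {
    missing_w <- setdiff(pc$wells, meta$well)
    if (length(missing_w))
      stop("wells absent from sample sheet: ",
           paste(utils::head(missing_w, 10L), collapse = ", "))
  }
  if (!is.null(anno)) {
    missing_g <- setdiff(pc$genes, anno$gene)
    if (length(missing_g))
      stop("genes absent from annotation: ",
           paste(utils::head(missing_g, 10L), collapse = ", "))
  }
  invisible(TRUE)
}
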