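#' @importFrom Matrix readMM writeMM sparseMatrix
NULL

write_count_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene")
    stop("count TSV must have a leading 'gene' column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

write_count_mtx <- function(m, path) {
  sm <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(sm, path)
  writeLines(rownames(m), paste0(path, ".genes"))
  writeLines(colnames(m), paste0(path, ".wells"))
  invisible(path)
}

read_count_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(paste0(path, ".genes"))
  wells <- readLines(paste0(path, ".wells"))
  if (length(genes) != nrow(m) || length(wells) != ncol(m))
    stop("MatrixMarket sidecar index length mismatch for: ", path)
  dimnames(m) <- list(genes, wells)
  storage.mode(m) <- "double"
  m
}

read_counts_any <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (!file.exists(path)) stop("count file not found: ", path)
  switch(format, tsv = read_count_tsv(path), mtx = read_count_mtx(path))
}

#' Load paired ribo/total counts and the sample sheet
#'
#' Reads the two count matrices (TSV or MatrixMarket, inferred from the file
#' extension unless `format` is given) and the CSV sample sheet, reconciles
#' gene and well orderings by ID (intersection, with a message reporting any
#' drops) and returns a validated pair.
#'
#' @param ribo_path,total_path Count matrix files (genes x wells).
#' @param sheet_path Sample sheet CSV with columns
#'   `well,condition,...,spikein,input_fraction_ribo,input_fraction_total`
#'   (missing optional columns get defaults).
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @return A list with `pc` ([paired_counts()]) and `meta` ([plate_meta()]).
#' @export
load_paired_counts <- function(ribo_path, total_path, sheet_path,
                               format = "auto") {
  ribo <- read_counts_any(ribo_path, format)
  total <- read_counts_any(total_path, format)
  for (nm in list(rownames(ribo), rownames(total))) {
    dup <- unique(nm[duplicated(nm)])
    if (length(dup))
      stop("duplicate gene IDs in counts: ",
           paste(utils::head(dup, 10L), collapse = ", "))
  }
  genes <- intersect(rownames(ribo), rownames(total))
  wells <- intersect(colnames(ribo), colnames(total))
  dropped_g <- setdiff(union(rownames(ribo), rownames(total)), genes)
  dropped_w <- setdiff(union(colnames(ribo), colnames(total)), wells)
  if (length(dropped_g))
    message("dropping ", length(dropped_g),
            " gene(s) absent from one library: ",
            paste(utils::head(dropped_g, 5L), collapse = ", "))
  if (length(dropped_w))
    message("dropping ", length(dropped_w),
            " well(s) absent from one library: ",
            paste(utils::head(dropped_w, 5L), collapse = ", "))
  if (!length(genes) || !length(wells))
    stop("no shared genes/wells between ribo and total matrices")
  pc <- paired_counts(ribo[genes, wells, drop = FALSE],
                      total[genes, wells, drop = FALSE])

  if (!file.exists(sheet_path)) stop("sample sheet not found: ", sheet_path)
  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  if (!all(c("well", "condition") %in% names(sheet)))
    stop("sample sheet must have 'well' and 'condition' columns")
  missing_w <- setdiff(pc$wells, sheet$well)
  if (length(missing_w))
    stop("well(s) present in counts but absent from sample sheet: ",
         paste(utils::head(missing_w, 10L), collapse = ", "))
  sheet <- sheet[match(pc$wells, sheet$well), , drop = FALSE]
  meta <- plate_meta(
    sheet$well, sheet$condition,
    spikein = if ("spikein" %in% names(sheet)) sheet$spikein else FALSE,
    input_fraction_ribo = if ("input_fraction_ribo" %in% names(sheet))
      sheet$input_fraction_ribo else 0.5,
    input_fraction_total = if ("input_fraction_total" %in% names(sheet))
      sheet$input_fraction_total else 0.5
  )
  list(pc = pc, meta = meta)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene,biotype,top_status,blacklisted`.
#' @return A [gene_anno()] data.frame.
#' @export
load_gene_anno <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "biotype", "top_status", "blacklisted")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  gene_anno(df$gene, df$biotype, df$top_status, as.logical(df$blacklisted))
}

#' Load gene sets from GMT or a plain one-gene-per-line file
#'
#' GMT lines are `set<TAB>description<TAB>gene1<TAB>gene2...`. A plain list
#' file yields one set named after the file stem. Duplicate genes within a set
#' are removed; empty sets raise a warning but are retained. Genes unknown to
#' any analysis universe are kept here and filtered at use time.
#'
#' @param path File path.
#' @param format `"auto"`, `"gmt"` or `"list"`.
#' @return Named list of character vectors.
#' @export
load_gene_sets <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  if (format == "list") {
    genes <- unique(trimws(readLines(path)))
    genes <- genes[nzchar(genes)]
    sets <- stats::setNames(list(genes),
                            sub("\\.[^.]*$", "", basename(path)))
  } else {
    lines <- readLines(path)
    sets <- list()
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2)
        stop("malformed GMT line ", i, " in ", path,
             ": need at least set name and description")
      sets[[parts[1]]] <- unique(parts[-(1:2)])
    }
  }
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty))
    warning("empty gene set(s): ", paste(empty, collapse = ", "))
  sets
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove blacklisted genes from a paired_counts object
#'
#' @param pc A [paired_counts()].
#' @param anno A [gene_anno()] covering every gene of `pc`.
#' @return `pc` with blacklisted genes removed from both matrices.
#' @export
apply_blacklist <- function(pc, anno) {
  validate_plate(pc, anno = anno)
  bl <- anno$gene[anno$blacklisted]
  drop <- intersect(pc$genes, bl)
  if (!length(drop)) return(pc)
  keep <- setdiff(pc$genes, drop)
  message("removing ", length(drop), " blacklisted gene(s)")
  if (!length(keep)) {
    warning("blacklist covers every gene; returning an empty object")
  }
  subset_paired_counts(pc, genes = keep)
}

#' Write tidy result tables to a directory
#'
#' Each table is written as a TSV named `<name>.tsv` with stable column names.
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest data.frame (file, md5).
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create results directory: ", dir)
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  invisible(manifest)
}

#' Load a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @param format `"tsv"` or `"mtx"`: which count rendering to read.
#' @return A list with `pc`, `meta`, `anno`, `sets`.
#' @export
load_fixture <- function(dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  ext <- if (format == "tsv") "tsv" else "mtx"
  loaded <- load_paired_counts(
    file.path(dir, paste0("counts_ribo.", ext)),
    file.path(dir, paste0("counts_total.", ext)),
    file.path(dir, "sample_sheet.csv"),
    format = format
  )
  loaded$anno <- load_gene_anno(file.path(dir, "gene_annotation.tsv"))
  loaded$sets <- load_gene_sets(file.path(dir, "gene_sets.gmt"))
  loaded
}
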