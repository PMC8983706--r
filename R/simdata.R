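#' Configuration for the synthetic plate generator
#'
#' Builds a validated configuration for [simulate_experiment()]. The generator
#' emulates a plate-based translational profiling screen: every well yields a
#' paired ribosome-IP ("ribo") and total-RNA ("total") 3'-end library whose
#' counts are negative-binomial draws sharing per-gene abundance and per-well
#' depth, with a per-gene baseline ribosome-association (RA) capture fraction,
#' a global IP efficiency, per-condition multiplicative RA effects concentrated
#' on designated target sets, and attenuated effects under pairwise drug
#' combinations labelled `"A+B"`.
#'
#' @param n_coding,n_ncrna,n_spikein Numbers of coding genes, non-coding RNAs
#'   and ERCC-like spike-in species.
#' @param n_top_canonical,n_top_candidate Numbers of coding genes annotated as
#'   canonical / candidate 5' TOP-motif genes (defaults mirror the 97 + 182
#'   sets used for mTOR-axis targets).
#' @param n_blacklist Number of coding genes flagged on the poly(A)-minus
#'   blacklist (taken from the tail of the coding genes, never TOP).
#' @param conditions Character vector of condition labels; must contain the
#'   vehicle control `"DMSO"`. Labels containing `"+"` (e.g. `"mTORi+PI3Ki"`)
#'   are combination treatments of the two constituents.
#' @param n_wells_per_condition Wells per condition; each well produces one
#'   ribo and one total library.
#' @param depth_mean,depth_cv Expected total-library reads per well and its
#'   coefficient of variation (log-normal per-well depth).
#' @param ribo_depth_factor Scale of the ribo-arm depth relative to
#'   `depth_mean` before IP losses; the realized ribo library is further
#'   reduced by `ip_efficiency` and the RA capture fractions.
#' @param equal_depth If `TRUE`, ribo means are renormalized per well so the
#'   expected ribo library size equals its drawn depth (removing IP losses
#'   from the depth scale).
#' @param abundance_logmean,abundance_logsd Log-normal parameters of relative
#'   gene abundance (normalized to sum to 1 over genes).
#' @param baseline_ra_coding,baseline_ra_ncrna,baseline_ra_spikein Baseline RA
#'   capture fractions in (0, 1] per biotype. Non-ribosome-bound material
#'   (spike-ins, most ncRNA) carries low capture.
#' @param ip_efficiency Global immunoprecipitation efficiency in (0, 1]
#'   multiplying all ribo means.
#' @param spikein_fraction Expected fraction of a spike-in-bearing well's total
#'   library arising from spike-ins.
#' @param dispersion_a0,dispersion_a1 Dispersion trend alpha(mu) = a0 + a1/mu
#'   (variance = mu + alpha mu^2); both nonnegative.
#' @param effect_map Named list keyed by non-control condition. Each entry is
#'   one effect or a list of effects; an effect is
#'   `list(set = <gene-set label>, lfc = <log2 RA fold change>, fraction =
#'   <fraction of the set affected>)`. Combination conditions must not appear
#'   here; their effects are derived from their constituents.
#' @param extra_sets Named integer vector: additional gene sets of the given
#'   sizes, sampled from non-TOP coding genes, usable as effect targets.
#' @param attenuation_factor Multiplier in [0, 1] scaling each constituent
#'   drug's log2 effect under a combination condition.
#' @param spikein_half_plate If `TRUE`, spike-ins are present only in
#'   alternating well columns (the half-plate spike-in design).
#' @param input_fraction_ribo,input_fraction_total Lysate volume fractions
#'   recorded in the sample sheet (the generator itself does not model
#'   input-driven depth differences).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 2000, n_ncrna = 200, n_spikein = 92,
                       n_top_canonical = 97, n_top_candidate = 182,
                       n_blacklist = 0,
                       conditions = c("DMSO", "mTORi"),
                       n_wells_per_condition = 8,
                       depth_mean = 6.7e5, depth_cv = 0.3,
                       ribo_depth_factor = 1, equal_depth = FALSE,
                       abundance_logmean = 0, abundance_logsd = 1,
                       baseline_ra_coding = 0.80,
                       baseline_ra_ncrna = 0.25,
                       baseline_ra_spikein = 0.20,
                       ip_efficiency = 0.21,
                       spikein_fraction = 0.02,
                       dispersion_a0 = 0.01, dispersion_a1 = 1.5,
                       effect_map = list(),
                       extra_sets = NULL,
                       attenuation_factor = 0.5,
                       spikein_half_plate = TRUE,
                       input_fraction_ribo = 0.5,
                       input_fraction_total = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  frac_fields <- c("baseline_ra_coding", "baseline_ra_ncrna",
                   "baseline_ra_spikein", "ip_efficiency",
                   "input_fraction_ribo", "input_fraction_total")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop("'", f, "' must lie in (0, 1]")
  }
  if (cfg$spikein_fraction < 0 || cfg$spikein_fraction >= 1)
    stop("'spikein_fraction' must lie in [0, 1)")
  if (cfg$dispersion_a0 < 0 || cfg$dispersion_a1 < 0)
    stop("dispersion parameters must be nonnegative")
  if (cfg$depth_mean <= 0 || cfg$ribo_depth_factor <= 0)
    stop("depths must be positive")
  if (cfg$attenuation_factor < 0 || cfg$attenuation_factor > 1)
    stop("'attenuation_factor' must lie in [0, 1]")
  if (!"DMSO" %in% cfg$conditions)
    stop("conditions must include the vehicle control \"DMSO\"")
  if (anyDuplicated(cfg$conditions)) stop("duplicate condition labels")
  if (cfg$n_top_canonical + cfg$n_top_candidate + cfg$n_blacklist >
      cfg$n_coding)
    stop("TOP and blacklist gene counts exceed n_coding")
  cfg$effect_map <- normalize_effect_map(cfg$effect_map, cfg$conditions)
  combos <- grep("\\+", cfg$conditions, value = TRUE)
  for (cb in combos) {
    parts <- strsplit(cb, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% cfg$conditions))
      stop("combination condition '", cb,
           "' must be \"A+B\" with A and B among the conditions")
  }
  set_labels <- c("TOP_canonical", "TOP_candidate", names(cfg$extra_sets))
  for (cond in names(cfg$effect_map)) {
    for (eff in cfg$effect_map[[cond]]) {
      if (!eff$set %in% set_labels)
        stop("effect_map target '", eff$set,
             "' is not a generated gene-set label")
    }
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

normalize_effect_map <- function(effect_map, conditions) {
  if (!length(effect_map)) return(list())
  if (is.null(names(effect_map)) || any(names(effect_map) == ""))
    stop("effect_map must be a named list keyed by condition")
  bad <- setdiff(names(effect_map), conditions)
  if (length(bad))
    stop("effect_map condition(s) not in design: ", paste(bad, collapse = ", "))
  if ("DMSO" %in% names(effect_map))
    stop("the control condition cannot carry effects")
  combos <- grep("\\+", names(effect_map), value = TRUE)
  if (length(combos))
    stop("combination conditions derive effects from constituents; remove: ",
         paste(combos, collapse = ", "))
  lapply(effect_map, function(e) {
    if (!is.null(e$set)) e <- list(e)   # single effect entry
    lapply(e, function(one) {
      stopifnot(is.character(one$set), is.numeric(one$lfc))
      if (is.null(one$fraction)) one$fraction <- 1
      if (one$fraction <= 0 || one$fraction > 1)
        stop("effect fraction must lie in (0, 1]")
      one
    })
  })
}

#' Simulate a paired ribo/total plate experiment
#'
#' Draws a full synthetic plate under a [sim_config()]: per-gene log-normal
#' abundances, biotype-specific baseline RA capture, log-normal per-well
#' depths, per-condition multiplicative RA effects on designated target sets
#' (attenuated under combinations), and negative-binomial counts with
#' dispersion trend alpha(mu) = a0 + a1/mu. The random-draw order is fixed
#' (abundance, extra-set sampling, per-condition target sampling, total
#' depths, ribo depths, total counts, ribo counts) so a seed fully determines
#' the output.
#'
#' @param config A `sim_config`.
#' @return A list of class `ribo_sim` with elements `pc` ([paired_counts()]),
#'   `meta` ([plate_meta()]), `anno` ([gene_anno()]), `sets` (named list of
#'   gene-set character vectors), `truth` (ground truth: `abundance_g`,
#'   `ra_g`, `effect_gc` gene-by-condition log2 matrix, `depth_total_w`,
#'   `depth_ribo_w`, `mu_total`, `mu_ribo`) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes_coding <- sprintf("gene%05d", seq_len(cfg$n_coding))
  genes_ncrna <- if (cfg$n_ncrna > 0) sprintf("ncrna%04d", seq_len(cfg$n_ncrna)) else character()
  genes_spike <- if (cfg$n_spikein > 0) sprintf("ERCC-%05d", seq_len(cfg$n_spikein)) else character()
  genes <- c(genes_coding, genes_ncrna, genes_spike)
  biotype <- c(rep("coding", cfg$n_coding), rep("ncRNA", cfg$n_ncrna),
               rep("spikein", cfg$n_spikein))

  top_status <- rep("none", length(genes))
  if (cfg$n_top_canonical > 0)
    top_status[seq_len(cfg$n_top_canonical)] <- "canonical"
  if (cfg$n_top_candidate > 0)
    top_status[cfg$n_top_canonical + seq_len(cfg$n_top_candidate)] <- "candidate"
  blacklisted <- rep(FALSE, length(genes))
  if (cfg$n_blacklist > 0)
    blacklisted[cfg$n_coding - seq_len(cfg$n_blacklist) + 1L] <- TRUE
  anno <- gene_anno(genes, biotype, top_status, blacklisted)

  sets <- list(
    TOP_canonical = genes[top_status == "canonical"],
    TOP_candidate = genes[top_status == "candidate"]
  )

  # -- RNG draw 1: gene abundances (endogenous genes), normalized to sum 1
  n_endo <- cfg$n_coding + cfg$n_ncrna
  abund <- stats::rlnorm(n_endo, cfg$abundance_logmean, cfg$abundance_logsd)
  abund <- abund / sum(abund)
  # Spike-ins on a fixed half-log concentration ladder, scaled so they make
  # up spikein_fraction of a spike-bearing well's library.
  if (cfg$n_spikein > 0) {
    ladder <- 10^(((seq_len(cfg$n_spikein) - 1) %% 8) / 2)
    spike_ab <- ladder / sum(ladder) * cfg$spikein_fraction
  } else spike_ab <- numeric()
  abundance_g <- stats::setNames(c(abund, spike_ab), genes)

  ra_g <- stats::setNames(numeric(length(genes)), genes)
  ra_g[biotype == "coding"] <- cfg$baseline_ra_coding
  ra_g[biotype == "ncRNA"] <- cfg$baseline_ra_ncrna
  ra_g[biotype == "spikein"] <- cfg$baseline_ra_spikein

  # -- RNG draw 2: extra target sets from non-TOP, non-blacklist coding genes
  pool <- genes[biotype == "coding" & top_status == "none" & !blacklisted]
  if (length(cfg$extra_sets)) {
    for (nm in names(cfg$extra_sets)) {
      k <- cfg$extra_sets[[nm]]
      if (k > length(pool)) stop("extra set '", nm, "' larger than gene pool")
      sets[[nm]] <- sort(sample(pool, k))
      pool <- setdiff(pool, sets[[nm]])
    }
  }

  # -- RNG draw 3: per-condition affected genes, in condition order
  conds <- cfg$conditions
  effect_gc <- matrix(0, length(genes), length(conds),
                      dimnames = list(genes, conds))
  for (cond in setdiff(conds, c("DMSO", grep("\\+", conds, value = TRUE)))) {
    for (eff in cfg$effect_map[[cond]]) {
      members <- sets[[eff$set]]
      k <- round(eff$fraction * length(members))
      hit <- if (k >= length(members)) members else sort(sample(members, k))
      effect_gc[hit, cond] <- effect_gc[hit, cond] + eff$lfc
    }
  }
  for (cb in grep("\\+", conds, value = TRUE)) {
    parts <- strsplit(cb, "+", fixed = TRUE)[[1]]
    effect_gc[, cb] <- cfg$attenuation_factor *
      (effect_gc[, parts[1]] + effect_gc[, parts[2]])
  }

  # Plate layout: wells assigned to conditions in blocks, IDs in column-major
  # plate order (A01, B01, ... H01, A02, ...).
  n_wells <- length(conds) * cfg$n_wells_per_condition
  rows <- LETTERS[1:8]
  ncol_plate <- ceiling(n_wells / 8)
  ids <- as.vector(outer(rows, seq_len(ncol_plate),
                         function(r, c) sprintf("%s%02d", r, c)))[seq_len(n_wells)]
  well_cond <- rep(conds, each = cfg$n_wells_per_condition)
  well_col <- as.integer(substr(ids, 2, 3))
  spike_flag <- if (cfg$n_spikein == 0) rep(FALSE, n_wells)
    else if (cfg$spikein_half_plate) well_col %% 2L == 1L else rep(TRUE, n_wells)

  # -- RNG draws 4 & 5: per-well depths (log-normal with given mean and CV)
  sdlog <- sqrt(log(1 + cfg$depth_cv^2))
  meanlog_t <- log(cfg$depth_mean) - sdlog^2 / 2
  depth_total_w <- stats::setNames(stats::rlnorm(n_wells, meanlog_t, sdlog), ids)
  meanlog_r <- log(cfg$depth_mean * cfg$ribo_depth_factor) - sdlog^2 / 2
  depth_ribo_w <- stats::setNames(stats::rlnorm(n_wells, meanlog_r, sdlog), ids)

  spike_mask <- biotype == "spikein"
  ab_mat <- matrix(abundance_g, length(genes), n_wells)
  if (any(spike_mask)) ab_mat[spike_mask, !spike_flag] <- 0
  mu_total <- sweep(ab_mat, 2, depth_total_w, `*`)

  ra_mult <- 2^effect_gc[, well_cond, drop = FALSE]
  capture <- ab_mat * ra_g * ra_mult * cfg$ip_efficiency
  if (cfg$equal_depth) {
    csum <- colSums(capture)
    capture <- sweep(capture, 2, ifelse(csum > 0, csum, 1), `/`)
  }
  mu_ribo <- sweep(capture, 2, depth_ribo_w, `*`)
  dimnames(mu_total) <- dimnames(mu_ribo) <- list(genes, ids)

  # -- RNG draws 6 & 7: NB counts, total then ribo, column-major
  total <- draw_nb_counts(mu_total, cfg$dispersion_a0, cfg$dispersion_a1)
  ribo <- draw_nb_counts(mu_ribo, cfg$dispersion_a0, cfg$dispersion_a1)

  pc <- paired_counts(ribo, total)
  meta <- plate_meta(ids, well_cond, spike_flag,
                     cfg$input_fraction_ribo, cfg$input_fraction_total)
  truth <- list(abundance_g = abundance_g, ra_g = ra_g, effect_gc = effect_gc,
                depth_total_w = depth_total_w, depth_ribo_w = depth_ribo_w,
                mu_total = mu_total, mu_ribo = mu_ribo)
  structure(list(pc = pc, meta = meta, anno = anno, sets = sets,
                 truth = truth, config = cfg),
            class = "ribo_sim")
}

# NB draws with dispersion trend alpha(mu) = a0 + a1/mu; alpha -> 0 is Poisson.
draw_nb_counts <- function(mu, a0, a1) {
  out <- matrix(0, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  pos <- mu > 0
  m <- mu[pos]
  alpha <- a0 + a1 / m
  if (all(alpha < 1e-12)) {
    out[pos] <- stats::rpois(length(m), m)
  } else {
    out[pos] <- stats::rnbinom(length(m), mu = m, size = 1 / pmax(alpha, 1e-12))
  }
  out
}

#' @export
print.ribo_sim <- function(x, ...) {
  cat("ribo_sim: ", length(x$pc$genes), " genes x ", length(x$pc$wells),
      " wells; conditions: ", paste(x$config$conditions, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to disk as plain-text fixture files
#'
#' Emits both count renderings (TSV and MatrixMarket with gene/well index
#' sidecars), the sample sheet, gene annotation, gene sets (GMT) and the
#' ground-truth table.
#'
#' @param sim A `ribo_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest data.frame (file, md5).
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "ribo_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  files <- character()
  for (lib in c("ribo", "total")) {
    m <- sim$pc[[lib]]
    f_tsv <- file.path(dir, paste0("counts_", lib, ".tsv"))
    write_count_tsv(m, f_tsv)
    f_mtx <- file.path(dir, paste0("counts_", lib, ".mtx"))
    write_count_mtx(m, f_mtx)
    files <- c(files, f_tsv, f_mtx,
               paste0(f_mtx, ".genes"), paste0(f_mtx, ".wells"))
  }
  f_meta <- file.path(dir, "sample_sheet.csv")
  meta <- sim$meta
  out_meta <- data.frame(well = meta$well, condition = meta$condition,
                         library_type = "paired", spikein = meta$spikein,
                         input_fraction_ribo = meta$input_fraction_ribo,
                         input_fraction_total = meta$input_fraction_total)
  utils::write.csv(out_meta, f_meta, row.names = FALSE, quote = FALSE)
  f_anno <- file.path(dir, "gene_annotation.tsv")
  utils::write.table(sim$anno, f_anno, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(sim$sets, f_gmt)
  f_truth <- file.path(dir, "truth.tsv")
  tr <- sim$truth
  truth_df <- data.frame(gene = names(tr$abundance_g),
                         abundance = as.numeric(tr$abundance_g),
                         baseline_ra = as.numeric(tr$ra_g))
  eff <- as.data.frame(tr$effect_gc)
  names(eff) <- paste0("effect_", names(eff))
  truth_df <- cbind(truth_df, eff)
  utils::write.table(truth_df, f_truth, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, f_meta, f_anno, f_gmt, f_truth)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         row.names = NULL)
  invisible(manifest)
}
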