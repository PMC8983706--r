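test_that("median-of-ratios size factors match hand enumeration and DESeq2", {
  m <- matrix(c(2, 8, 4, 16, 6, 24), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("w1", "w2")))
  expect_equal(unname(size_factors(m)), c(0.5, 2.0))

  # identical columns give unit factors
  m2 <- matrix(rep(c(5, 9, 1), 4), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("w", 1:4)))
  expect_equal(unname(size_factors(m2)), rep(1, 4))

  # scaling one well multiplies its factor by 10 relative to the others
  # (without re-centering, the common reference geomean shifts all factors
  # by a constant, so equivariance holds on factor ratios)
  m3 <- m2; m3[, 2] <- m3[, 2] * 10
  s2 <- size_factors(m2); s3 <- size_factors(m3)
  expect_equal(unname(s3 / s3[1]), c(1, 10, 1, 1))
  expect_equal(unname(s3[-2] / s2[-2]), rep(s3[[1]] / s2[[1]], 3))

  # gene-order invariance; odd gene count so the median is a single ratio
  set.seed(1)
  r <- matrix(rpois(310, 50) + 1, 31, 10,
              dimnames = list(paste0("g", 1:31), paste0("w", 1:10)))
  expect_equal(size_factors(r), size_factors(r[sample(31), ]))

  # independent cross-check against the reference implementation
  expect_equal(unname(size_factors(r)),
               unname(DESeq2::estimateSizeFactorsForMatrix(r)),
               tolerance = 1e-10)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("log-shift transform has the stated fixed points and limits", {
  m <- matrix(c(0, 7), 1, 2, dimnames = list("g", c("a", "b")))
  v <- vst(m, c(1, 1), pseudocount = 1)
  expect_equal(unname(v[1, ]), c(0, 3))     # log2(0+1)=0, log2(7+1)=3
  expect_error(vst(m, c(1, 1), pseudocount = 0), "positive")
  expect_error(vst(m, c(1, -1)), "positive")

  # doubling a well's size factor shifts it down by at most one log2 unit,
  # approaching exactly one for large counts
  big <- matrix(seq(1e3, 1e4, length.out = 10), 10, 1,
                dimnames = list(paste0("g", 1:10), "w"))
  shift <- vst(big, 1) - vst(big, 2)
  expect_true(all(shift <= 1))
  expect_equal(unname(shift[10, 1]), 1, tolerance = 1e-3)
})

test_that("RA is the transformed difference and is shift-invariant", {
  s <- tiny_sim(seed = 6)
  prof <- ra_profile(s$pc, s$anno)
  expect_equal(prof$ra, prof$vst_ribo - prof$vst_total)
  expect_equal(ribosome_association(prof$vst_ribo, prof$vst_ribo),
               prof$ra * 0)
  expect_equal(ribosome_association(prof$vst_ribo + 3, prof$vst_total + 3),
               prof$ra)
  expect_equal(unname(ribosome_association(matrix(3), matrix(log2(3)))[1, 1]),
               3 - log2(3))
  expect_error(ribosome_association(prof$vst_ribo[, -1], prof$vst_total),
               "shape")
})

test_that("lfcRA centers control wells at zero per gene", {
  s <- tiny_sim(seed = 7)
  prof <- ra_profile(s$pc, s$anno)
  lfc <- lfc_ra(prof$ra, s$meta)
  ctrl <- s$meta$well[s$meta$condition == "DMSO"]
  expect_equal(unname(rowMeans(lfc[, ctrl])), rep(0, nrow(lfc)))
  drug <- setdiff(colnames(lfc), ctrl)[1]
  expect_equal(lfc[, drug],
               prof$ra[, drug] - rowMeans(prof$ra[, ctrl]))
  expect_error(lfc_ra(prof$ra, s$meta, control = "missing"), "control")
})

test_that("spike-in depletion test matches signed-rank enumeration", {
  # constructed so spike depletion is (1,2,3) and gene depletion (2,3,4):
  # all paired differences are -1, and the exact one-tailed signed-rank
  # p-value over the 2^3 sign assignments is 1/8
  ribo <- rbind(ERCC = c(32, 64, 128), gene1 = c(64, 128, 256))
  total <- rbind(ERCC = c(16, 16, 16), gene1 = c(16, 16, 16))
  colnames(ribo) <- colnames(total) <- c("A01", "A02", "A03")
  pc <- paired_counts(ribo, total)
  anno <- gene_anno(c("ERCC", "gene1"), c("spikein", "coding"))
  meta <- plate_meta(colnames(ribo), "DMSO", spikein = TRUE)
  rep_ <- spikein_depletion(pc, anno, meta, sf_ribo = rep(1, 3),
                            sf_total = rep(1, 3))
  expect_equal(rep_$per_well$spike_depletion, c(1, 2, 3))
  expect_equal(rep_$per_well$gene_depletion, c(2, 3, 4))
  expect_equal(rep_$per_well$difference, rep(-1, 3))
  expect_equal(rep_$p_value, 1 / 8)
})

test_that("depletion detects reduced spike-in capture and not a null", {
  eff <- tiny_sim(seed = 8, n_wells_per_condition = 24, depth_mean = 1e5,
                  conditions = "DMSO", baseline_ra_spikein = 0.2,
                  baseline_ra_coding = 0.9, baseline_ra_ncrna = 0.9)
  d_eff <- spikein_depletion(eff$pc, eff$anno, eff$meta)
  expect_lt(d_eff$p_value, 0.01)
  expect_lt(mean(d_eff$per_well$difference), 0)

  null <- tiny_sim(seed = 9, n_wells_per_condition = 24, depth_mean = 1e5,
                   conditions = "DMSO", baseline_ra_spikein = 0.9,
                   baseline_ra_coding = 0.9, baseline_ra_ncrna = 0.9)
  d_null <- spikein_depletion(null$pc, null$anno, null$meta)
  expect_gte(d_null$p_value, 0.05)
})

test_that("RA-abundance stratification ranks ncRNA below coding", {
  s <- tiny_sim(seed = 10, baseline_ra_ncrna = 0.4, baseline_ra_coding = 0.8,
                depth_mean = 1e5)
  prof <- ra_profile(s$pc, s$anno)
  strat <- ra_vs_abundance(prof$ra, prof$vst_total, s$anno)
  pg <- strat$per_gene
  expect_equal(nrow(pg), length(s$pc$genes))
  expect_lt(mean(pg$mean_ra[pg$biotype == "ncRNA"]),
            mean(pg$mean_ra[pg$biotype == "coding"]))
  expect_lt(strat$test$p_value, 0.05)
  expect_equal(strat$test$alternative, "less")
})
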