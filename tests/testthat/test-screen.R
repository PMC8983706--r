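test_that("PCA scores duplicate samples identically and orders variance", {
  set.seed(14)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("w", 1:10)))
  m <- cbind(m, dup = m[, 3])
  colnames(m)[11] <- "w3dup"
  p <- pca_ra(m, n_components = 5)
  expect_equal(unname(p$scores["w3", ]), unname(p$scores["w3dup", ]))
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
  expect_error(pca_ra(m, genes = c("zz1", "zz2")), "disjoint")
})

test_that("PC1 separates conditions under a strong RA shift", {
  for (seed in 1:5) {
    s <- tiny_sim(seed = seed, n_coding = 150, n_ncrna = 0, n_spikein = 0,
                  n_top_canonical = 40, n_top_candidate = 0,
                  effect_map = list(drugA = list(set = "TOP_canonical",
                                                 lfc = -2)),
                  depth_mean = 1e5, n_wells_per_condition = 6)
    prof <- ra_profile(s$pc, s$anno)
    p <- pca_ra(prof$ra, genes = s$sets$TOP_canonical)
    pc1 <- p$scores[, 1]
    grp <- s$meta$condition[match(rownames(p$scores), s$meta$well)]
    # silhouette on one dimension: within-group spread below between-group gap
    gap <- abs(mean(pc1[grp == "DMSO"]) - mean(pc1[grp == "drugA"]))
    spread <- max(sd(pc1[grp == "DMSO"]), sd(pc1[grp == "drugA"]))
    expect_gt(gap, spread)
  }
})

test_that("robust outlier flagging catches planted outliers only", {
  flagged <- sapply(1:10, function(seed) {
    set.seed(seed)
    sc <- matrix(rnorm(60), 30, 2,
                 dimnames = list(sprintf("w%02d", 1:30), NULL))
    length(detect_outliers(sc, k = 4)$outliers)
  })
  expect_lte(mean(flagged), 1)   # tight cloud: ~0 flags per plate

  set.seed(99)
  sc <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("w%02d", 1:20), NULL))
  sc[7, 1] <- median(sc[, 1]) + 20 * mad(sc[, 1])
  out <- detect_outliers(sc, k = 4)
  expect_true("w07" %in% out$outliers)
  expect_length(detect_outliers(sc, k = Inf)$outliers, 0)
})

test_that("target sets split by direction and honor mutual exclusivity", {
  tab <- function(cond, genes, lfc, fdr)
    data.frame(gene = genes, lfcRA = lfc, fdr = fdr, condition = cond)
  res <- list(
    A = tab("A", c("g1", "g2", "g3", "g4"), c(1, -1, 2, -2),
            c(0.01, 0.01, 0.2, 0.01)),
    B = tab("B", c("g1", "g2", "g3", "g4"), c(2, 1, -1, 0.5),
            c(0.01, 0.2, 0.01, 0.2)))
  plain <- build_target_sets(res, q = 0.05)
  expect_equal(plain$A$up, "g1")
  expect_equal(sort(plain$A$down), c("g2", "g4"))
  expect_equal(plain$B$down, "g3")
  excl <- build_target_sets(res, q = 0.05, exclusive = TRUE)
  expect_false("g1" %in% excl$A$up)   # shared up-gene removed everywhere
  expect_false("g1" %in% excl$B$up)
  expect_equal(sort(excl$A$down), c("g2", "g4"))
  expect_equal(build_target_sets(list(A = tab(character(), character(),
                                              numeric(), numeric())))$A$up,
               character())
})

test_that("Mann-Whitney shift test matches rank enumeration", {
  # groups (1,2) vs (3,4): only 1 of the C(4,2)=6 orderings is as extreme
  st <- shift_test(c(1, 2), c(3, 4), "less")
  expect_equal(st$p_value, 1 / 6)
  expect_equal(st$statistic, 0)
  same <- shift_test(c(5, 6, 7), c(5, 6, 7), "less")
  expect_gte(same$p_value, 0.5)
  expect_error(shift_test(numeric(), 1:3), "nonempty")
})

test_that("classic enrichment score matches the running-sum oracle", {
  ranked4 <- c("a", "b", "c", "d")
  sc4 <- setNames(c(4, 3, 2, 1), ranked4)
  expect_equal(gsea_preranked(sc4, "a", n_perm = 10)$es, 1)   # top-ranked hit
  expect_equal(gsea_preranked(sc4, "d", n_perm = 10)$es, -1)  # bottom-ranked
  expect_warning(res <- gsea_preranked(sc4, ranked4, n_perm = 10), "entire")
  expect_equal(res$es, 1)

  set.seed(15)
  for (i in 1:25) {
    N <- sample(4:10, 1)
    genes <- sprintf("g%02d", 1:N)
    scores <- setNames(sort(rnorm(N), decreasing = TRUE), genes)
    set <- sample(genes, sample(1:(N - 1), 1))
    es <- gsea_preranked(scores, set, n_perm = 5, seed = i)$es
    expect_equal(es, es_oracle(genes, set), tolerance = 1e-12)
  }
})

test_that("enrichment score and permutation p agree with fgsea", {
  set.seed(16)
  genes <- sprintf("g%03d", 1:200)
  scores <- setNames(rnorm(200) + c(rep(1.5, 25), rep(0, 175)), genes)
  set <- genes[1:25]
  mine <- gsea_preranked(scores, set, n_perm = 500, seed = 2)
  ref <- suppressWarnings(fgsea::fgseaSimple(
    pathways = list(s = set), stats = sort(scores, decreasing = TRUE),
    nperm = 500, gseaParam = 0, scoreType = "std"))
  expect_equal(mine$es, ref$ES, tolerance = 1e-10)
  expect_lt(mine$p_value, 0.05)
  expect_true(mine$es >= -1 && mine$es <= 1)
  expect_equal(sign(mine$nes), sign(mine$es))
  expect_gte(mine$p_value, 1 / 501)
})

test_that("attenuation classes follow the definition and partition genes", {
  tab <- function(cond, lfc, fdr) data.frame(
    gene = paste0("g", seq_along(lfc)), lfcRA = lfc, fdr = fdr,
    condition = cond)
  res_a <- tab("A", c(-2, 1, -1, 0.5), c(0.01, 0.01, 0.01, 0.5))
  res_b <- tab("B", c(-0.5, 2, 0.1, 3), c(0.5, 0.01, 0.5, 0.5))
  combo <- tab("A+B", c(-1, 2, 0.5, 4), c(0.5, 0.5, 0.5, 0.5))
  att <- attenuation_analysis(res_a, res_b, combo, q = 0.05)
  pg <- att$per_gene
  expect_equal(nrow(pg), 3)            # g4 significant nowhere
  expect_equal(pg$class[pg$gene == "g1"], "attenuated")  # x=-2, y=-1
  expect_equal(pg$class[pg$gene == "g2"], "enhanced")    # |y| = |x| boundary
  expect_equal(pg$class[pg$gene == "g3"], "reversed")    # sign flip
  expect_true(all(pg$class %in% c("attenuated", "enhanced", "reversed")))
  expect_true(all(att$fractions$attenuated + att$fractions$enhanced +
                    att$fractions$reversed == 1))
  expect_error(attenuation_analysis(res_a, res_b, NULL), "combination")
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # 2x2 table a=3, b=1, c=1, d=3: one-sided p = 17/70
  p_hyper <- sum(dhyper(3:4, 4, 4, 4))
  expect_equal(p_hyper, 17 / 70)
  ft <- fisher.test(matrix(c(3, 1, 1, 3), 2), alternative = "greater")
  expect_equal(ft$p.value, p_hyper)

  # network Fisher tests agree with exhaustive enumeration on small universes
  set.seed(17)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", 1:N)
    k1 <- sample(uni, sample(3:(N - 2), 1))
    k2 <- sample(uni, sample(3:(N - 2), 1))
    top <- list(TOP = sample(uni, sample(2:(N - 2), 1)))
    net <- enrichment_network(list(K1 = k1, K2 = k2), top, uni)
    for (r in seq_len(nrow(net$regions))) {
      reg <- net$regions[r, ]
      kn <- strsplit(reg$region, "&")[[1]]
      members <- Reduce(intersect, list(K1 = k1, K2 = k2)[kn])
      for (other in setdiff(c("K1", "K2"), kn))
        members <- setdiff(members, list(K1 = k1, K2 = k2)[[other]])
      a <- length(intersect(members, top$TOP))
      enum <- sum(dhyper(a:min(length(members), length(top$TOP)),
                         length(top$TOP), N - length(top$TOP),
                         length(members)))
      expect_equal(reg$p_value, enum, tolerance = 1e-12)
    }
  }
})

test_that("network regions partition the union of target sets", {
  s <- tiny_sim(seed = 18)
  uni <- s$pc$genes
  k <- list(K1 = uni[1:30], K2 = uni[20:45], K3 = uni[c(1:5, 40:60)])
  top <- list(TOP = uni[1:25])
  net <- enrichment_network(k, top, uni)
  union_size <- length(unique(unlist(k)))
  expect_equal(sum(unique(net$regions[, c("region", "size")])$size),
               union_size)
  expect_equal(nrow(net$membership), union_size)
  expect_equal(sort(unique(net$edges$source)), c("K1", "K2", "K3"))
  # disjoint TOP set: nothing can be enriched
  net0 <- enrichment_network(k, list(TOP = uni[100:110]), uni)
  expect_true(all(net0$regions$p_value == 1))
})
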