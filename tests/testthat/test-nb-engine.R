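test_that("size factors follow the median-of-ratios definition", {
  m <- tibble::tibble(feature = c("f1", "f2"), s1 = c(10, 40), s2 = c(20, 80))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical columns -> unit factors
  ident <- tibble::tibble(feature = c("a", "b", "c"), s1 = c(5, 9, 2),
                          s2 = c(5, 9, 2))
  expect_equal(unname(estimate_size_factors(ident)), c(1, 1))

  # permuting features changes nothing
  perm <- m[c(2, 1), ]
  expect_equal(estimate_size_factors(perm), sf)

  # no all-positive feature -> informative error
  holes <- tibble::tibble(feature = c("a", "b"), s1 = c(0, 3), s2 = c(4, 0))
  expect_error(estimate_size_factors(holes), "pseudo-reference")
})

test_that("dispersion estimation recovers simulated dispersion levels", {
  group <- factor(rep(c("A", "B"), each = 3))
  sf <- rep(1, 6)
  withr::with_seed(71, {
    # Poisson data: estimates collapse to near zero at high means
    mpois <- matrix(rpois(2000 * 6, 800), 2000, 6,
                    dimnames = list(sprintf("f%d", 1:2000), NULL))
    a0 <- estimate_dispersions(mpois, sf, group)
    expect_lte(median(a0), 0.01)

    # alpha = 0.1 data: median lands in the right decade
    m1 <- matrix(rnbinom(2000 * 6, mu = 800, size = 10), 2000, 6,
                 dimnames = list(sprintf("f%d", 1:2000), NULL))
    a1 <- estimate_dispersions(m1, sf, group)
    expect_gte(median(a1), 0.05)
    expect_lte(median(a1), 0.2)
  })

  # constant counts within groups -> floor
  const <- matrix(rep(c(100, 200), each = 3), 1, 6, byrow = TRUE,
                  dimnames = list("f1", NULL))
  expect_equal(unname(estimate_dispersions(const, sf, group,
                                           trend_weight = 0)), 1e-8)

  expect_error(
    estimate_dispersions(const[, c(1, 4), drop = FALSE], sf[1:2],
                         factor(c("A", "B"))),
    "replicates"
  )
})

test_that("the NB GLM recovers known coefficients", {
  X <- cbind(1, rep(c(0, 1), each = 3))
  colnames(X) <- c("(Intercept)", "stage")
  sf <- rep(1, 6)
  withr::with_seed(5, {
    # null: equal means, near-Poisson -> coefficient near zero
    y0 <- rpois(6, 1000)
    f0 <- fit_nb_glm(y0, X, 1e-8, sf)
    expect_lt(abs(f0$coefficients[2]), 0.05)
    expect_true(f0$converged)

    # means (100, 400): stage log2FC ~ 2, averaged over replicates
    est <- replicate(40, {
      y <- rnbinom(6, mu = rep(c(100, 400), each = 3), size = 100)
      fit_nb_glm(y, X, 0.01, sf)$coefficients[2] / log(2)
    })
    expect_equal(mean(est), 2, tolerance = 0.075)
  })

  # doubling all offsets leaves non-intercept coefficients unchanged
  y <- c(90, 110, 95, 380, 420, 410)
  f1 <- fit_nb_glm(y, X, 0.01, sf)
  f2 <- fit_nb_glm(y, X, 0.01, sf * 2)
  expect_equal(f1$coefficients[2], f2$coefficients[2], tolerance = 1e-6)
  expect_equal(f1$coefficients[1] - log(2), f2$coefficients[1],
               tolerance = 1e-6)

  expect_error(fit_nb_glm(y, cbind(X, X[, 2]), 0.01, sf), "rank")
})

test_that("Wald statistics and p-values follow the normal reference", {
  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  expect_equal(wald_test(-0.7, 0.35)$p, wald_test(0.7, 0.35)$p)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.037), 0.037)
  # the NA is excluded from the family size (m = 2)
  expect_equal(adjust_bh(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))

  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(1:50, 1)
      p <- runif(n)^sample(1:3, 1)
      if (i %% 5 == 0) p[sample(n, min(n, 2))] <- NA
      expect_equal(adjust_bh(p), oracle_bh(p))
    }
  })
})

test_that("two-factor interaction isolates discordant changes", {
  # 100 genes, of which 15 carry the effect of interest; the null majority
  # anchors the median-of-ratios normalization, as in real data
  make_counts <- function(chro_fold, rna_fold, n = 3, size = 100, seed = 1) {
    withr::with_seed(seed, {
      meta <- tibble::tibble(
        sample = c(sprintf("c%d", 1:(2 * n)), sprintf("r%d", 1:(2 * n))),
        assay = rep(c("chro", "rna"), each = 2 * n),
        stage = rep(rep(c("A", "B"), each = n), 2)
      )
      g <- 100
      planted <- 1:15
      base <- rep(400, g)
      fold_of <- function(fold) {
        f <- rep(1, g)
        f[planted] <- fold
        f
      }
      draw <- function(fold) {
        sapply(seq_len(2 * n), function(j) {
          mu <- base * (if (j > n) fold_of(fold) else 1)
          rnbinom(g, mu = mu, size = size)
        })
      }
      chro <- draw(chro_fold)
      rna <- draw(rna_fold)
      rownames(chro) <- rownames(rna) <- sprintf("g%03d", 1:g)
      list(
        chro = stats::setNames(ptseq:::matrix_to_count_table(chro, "gene_id"),
                               c("gene_id", meta$sample[meta$assay == "chro"])),
        rna = stats::setNames(ptseq:::matrix_to_count_table(rna, "gene_id"),
                              c("gene_id", meta$sample[meta$assay == "rna"])),
        meta = meta, planted = sprintf("g%03d", planted)
      )
    })
  }

  # identical fold change in both assays -> interaction ~ 0 for everyone
  d0 <- make_counts(chro_fold = 4, rna_fold = 4, seed = 3)
  i0 <- two_factor_interaction(d0$chro, d0$rna, d0$meta, "A", "B")
  expect_lt(abs(median(i0$log2FC[i0$feature %in% d0$planted])), 0.12)

  # ChRO flat, RNA 4x on the planted genes -> interaction log2FC ~ 2
  d2 <- make_counts(chro_fold = 1, rna_fold = 4, seed = 4)
  i2 <- two_factor_interaction(d2$chro, d2$rna, d2$meta, "A", "B")
  expect_equal(median(i2$log2FC[i2$feature %in% d2$planted]), 2,
               tolerance = 0.075)

  # swapping the assay labels negates the interaction estimate
  meta_sw <- d2$meta
  meta_sw$assay <- ifelse(meta_sw$assay == "chro", "rna", "chro")
  i2_sw <- two_factor_interaction(d2$rna, d2$chro, meta_sw, "A", "B")
  expect_equal(i2_sw$log2FC, -i2$log2FC, tolerance = 1e-6)

  # missing design cell errors
  meta_bad <- d2$meta[d2$meta$assay == "chro" | d2$meta$stage == "A", ]
  chro_bad <- d2$chro
  rna_bad <- d2$rna[, c("gene_id", meta_bad$sample[meta_bad$assay == "rna"])]
  expect_error(
    two_factor_interaction(chro_bad, rna_bad, meta_bad, "A", "B"),
    "cell"
  )
})

test_that("Wald p-values approach a Poisson GLM oracle as dispersion vanishes", {
  withr::with_seed(8, {
    X <- cbind(1, rep(c(0, 1), each = 4))
    colnames(X) <- c("(Intercept)", "stage")
    sf <- exp(runif(8, log(0.8), log(1.25)))
    dp <- replicate(300, {
      y <- rpois(8, 600 * sf)
      f <- fit_nb_glm(y, X, 1e-10, sf)
      p_nb <- wald_test(f$coefficients[2], f$se[2])$p
      g <- glm(y ~ X[, 2] + offset(log(sf)), family = poisson())
      p_pois <- 2 * pnorm(-abs(summary(g)$coefficients[2, 3]))
      abs(p_nb - p_pois)
    })
    expect_gte(mean(dp < 0.01), 0.95)
  })
})

test_that("stage tests agree with DESeq2 on a shared dataset", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(15, {
    g <- 200
    mu <- 10^runif(g, 1.5, 3)
    lfc <- c(rep(2, 20), rep(0, g - 20))
    cnt <- cbind(
      sapply(1:3, function(i) rnbinom(g, mu = mu, size = 20)),
      sapply(1:3, function(i) rnbinom(g, mu = mu * 2^lfc, size = 20))
    )
    rownames(cnt) <- sprintf("g%03d", 1:g)
    colnames(cnt) <- sprintf("s%d", 1:6)
  })
  meta <- tibble::tibble(sample = sprintf("s%d", 1:6),
                         stage = rep(c("A", "B"), each = 3))
  ours <- nb_stage_test(ptseq:::matrix_to_count_table(cnt, "gene_id"),
                        meta, "A", "B")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, data.frame(stage = factor(meta$stage)), ~stage
  )
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds)
  # independent implementations: size factors match closely, fold changes
  # track each other, and the same strong genes are called
  expect_equal(unname(ours$baseMean), res$baseMean, tolerance = 0.02)
  big <- which(lfc > 0)
  expect_equal(ours$log2FC[big], res$log2FoldChange[big], tolerance = 0.1)
  ours_hits <- ours$feature[!is.na(ours$padj) & ours$padj < 0.01 &
                              abs(ours$log2FC) > 1]
  deseq_hits <- rownames(res)[!is.na(res$padj) & res$padj < 0.01 &
                                abs(res$log2FoldChange) > 1]
  expect_gt(length(intersect(ours_hits, deseq_hits)) /
              max(length(union(ours_hits, deseq_hits)), 1), 0.8)
})
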