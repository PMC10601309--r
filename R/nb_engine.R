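#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to features with strictly positive counts in every sample) of the ratio
#' of the count to the feature's geometric mean across samples.
#'
#' @param counts Count table (feature id + sample columns) or numeric
#'   matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_table_to_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste0(
      "no feature has positive counts in every sample; ",
      "median-of-ratios is undefined (consider a pseudo-reference fallback)"
    ))
  }
  mm <- m[pos, , drop = FALSE]
  log_geo <- rowMeans(log(mm))
  sf <- apply(mm, 2, function(col) exp(median(log(col) - log_geo)))
  sf
}

#' Per-feature dispersion estimates with trend shrinkage
#'
#' Method-of-moments dispersion from within-group residuals of
#' size-factor-normalized counts (var = mu * mean(1/sf) + alpha * mu^2 per
#' group), floored at 1e-8, then shrunk on the log scale toward a
#' mean-dispersion trend `alpha(mu) = a0 + a1 / mu` fitted across features
#' by a gamma GLM.  At typical replicate numbers (two to four samples per
#' design cell) the per-feature estimate has a coefficient of variation
#' around 50%, so the default blend weights the trend heavily (0.85);
#' lower it when many replicates are available.
#'
#' @param counts Count table or matrix.
#' @param size_factors Per-sample factors from [estimate_size_factors()].
#' @param design Data frame of per-sample factors defining the groups
#'   (all combinations of its columns are treated as cells), or a factor.
#' @param trend_weight Weight of the trend in the log-scale blend.
#' @return Numeric vector of dispersions, one per feature.
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 trend_weight = 0.85) {
  m <- if (is.matrix(counts)) counts else count_table_to_matrix(counts)
  stopifnot(length(size_factors) == ncol(m))
  groups <- if (is.data.frame(design)) {
    interaction(design, drop = TRUE)
  } else {
    as.factor(design)
  }
  if (all(table(groups) < 2)) {
    abort("dispersion estimation needs >= 2 replicates in at least one group")
  }
  q <- sweep(m, 2, size_factors, "/")
  xim <- tapply(1 / size_factors, groups, mean)
  floor_val <- 1e-8
  disp_raw <- rep(floor_val, nrow(m))
  mu_bar <- rowMeans(q)
  num <- matrix(0, nrow(m), nlevels(groups))
  den <- matrix(0, nrow(m), nlevels(groups))
  wt <- numeric(nlevels(groups))
  for (k in seq_len(nlevels(groups))) {
    j <- which(groups == levels(groups)[k])
    if (length(j) < 2) next
    mk <- rowMeans(q[, j, drop = FALSE])
    vk <- apply(q[, j, drop = FALSE], 1, var)
    num[, k] <- vk - xim[[k]] * mk
    den[, k] <- mk^2
    wt[k] <- length(j) - 1
  }
  keep <- wt > 0
  est <- rowSums(sweep(num[, keep, drop = FALSE], 2, wt[keep], "*")) /
    pmax(rowSums(sweep(den[, keep, drop = FALSE], 2, wt[keep], "*")), 1e-300)
  disp_raw <- pmax(est, floor_val)

  # mean-dispersion trend: alpha = a0 + a1 / mu, gamma GLM on informative genes
  use <- disp_raw > 1e-6 & mu_bar > 1 & is.finite(disp_raw)
  med <- if (any(use)) median(disp_raw[use]) else floor_val
  trend <- rep(max(med, floor_val), nrow(m))
  if (sum(use) >= 20) {
    fit <- tryCatch(
      glm(disp_raw[use] ~ I(1 / mu_bar[use]),
          family = Gamma(link = "identity"),
          start = c(max(median(disp_raw[use]), 1e-4), 1)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      a <- pmax(coef(fit), 0)
      trend <- a[1] + a[2] / pmax(mu_bar, 0.1)
    } else {
      trend <- rep(median(disp_raw[use]), nrow(m))
    }
  }
  trend <- pmax(trend, floor_val)
  exp((1 - trend_weight) * log(disp_raw) + trend_weight * log(trend))
}

#' Fit a negative-binomial GLM for one feature
#'
#' Log-link NB GLM fitted by iteratively reweighted least squares with
#' log size factors as offsets.  Coefficients are returned on the natural
#' log scale together with their covariance matrix.  Convergence is on the
#' relative deviance change (tolerance 1e-8, at most 100 iterations).
#' Fractional counts are accepted (the working response and weights only
#' involve y through its value, matching the continuous extension of the
#' NB likelihood).
#'
#' @param y Numeric response vector (counts, possibly fractional).
#' @param design_matrix Full-rank model matrix.
#' @param dispersion NB dispersion alpha for this feature.
#' @param size_factors Per-sample size factors (offsets are their logs).
#' @param tol Relative deviance-change convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return List: coefficients (natural log), cov, se, converged, deviance.
#' @export
fit_nb_glm <- function(y, design_matrix, dispersion, size_factors,
                       tol = 1e-8, max_iter = 100L) {
  X <- design_matrix
  stopifnot(nrow(X) == length(y), length(size_factors) == length(y))
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")
  off <- log(size_factors)
  alpha <- max(dispersion, 1e-12)
  # deviance of the NB with fixed alpha (continuous in y)
  nb_dev <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * mu) / (1 + alpha * y))
    2 * sum(t1 + t2)
  }
  beta <- rep(0, ncol(X))
  beta[1] <- log(max(mean(y / size_factors), 0.1))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e12)
    mu <- pmax(mu, 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    wls <- tryCatch(
      lm.wfit(X, z, w),
      error = function(e) NULL
    )
    if (is.null(wls) || anyNA(wls$coefficients)) break
    beta <- wls$coefficients
    dev <- nb_dev(pmax(pmin(exp(drop(X %*% beta) + off), 1e12), 1e-10))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  eta <- drop(X %*% beta) + off
  mu <- pmax(pmin(exp(eta), 1e12), 1e-10)
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w)
  cov <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(cov), 0))
  list(coefficients = beta, cov = cov, se = se,
       converged = converged && all(is.finite(se)) && all(se > 0),
       deviance = dev_old)
}

#' Wald test for a single coefficient or contrast
#'
#' @param coef Estimate (any log base; the statistic is scale-free).
#' @param se Standard error on the same scale.
#' @return List with `wald_stat` and two-sided normal `p`.
#' @export
wald_test <- function(coef, se) {
  stat <- coef / se
  list(wald_stat = stat, p = 2 * pnorm(-abs(stat)))
}

#' Benjamini-Hochberg adjustment with NA handling
#'
#' Step-up BH with monotonicity enforcement, applied to the non-missing
#' p-values only (the family size m equals the number of non-missing
#' entries); missing entries stay missing.
#'
#' @param p Numeric vector of p-values, possibly with NAs.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' @keywords internal
base_means <- function(m, size_factors) {
  rowMeans(sweep(m, 2, size_factors, "/"))
}

# Shared worker: fit one design across all features and report one contrast
# coefficient (by design-matrix column name) per feature.
#' @keywords internal
nb_fit_contrast <- function(m, X, coef_name, size_factors, dispersions) {
  ci <- match(coef_name, colnames(X))
  if (is.na(ci)) abort(paste0("no design column named ", coef_name))
  n <- nrow(m)
  log2fc <- se <- stat <- pval <- rep(NA_real_, n)
  conv <- logical(n)
  ln2 <- log(2)
  for (i in seq_len(n)) {
    f <- fit_nb_glm(m[i, ], X, dispersions[i], size_factors)
    if (!f$converged) next
    conv[i] <- TRUE
    log2fc[i] <- f$coefficients[ci] / ln2
    se[i] <- f$se[ci] / ln2
    wt <- wald_test(f$coefficients[ci], f$se[ci])
    stat[i] <- wt$wald_stat
    pval[i] <- wt$p
  }
  if (!all(conv)) {
    warn(paste0(sum(!conv), " feature(s) failed to converge; ",
                "excluded from the adjusted-p family"))
  }
  tibble(
    feature = rownames(m),
    baseMean = base_means(m, size_factors),
    log2FC = log2fc, lfcSE = se, stat = stat, pvalue = pval,
    padj = adjust_bh(pval), converged = conv
  )
}

#' One-factor negative-binomial Wald test between two stages
#'
#' Differential testing of raw counts between `stageA` (reference) and
#' `stageB` using the package's NB engine: median-of-ratios size factors,
#' trend-shrunk dispersions, per-feature IRLS GLM fits and a Wald test on
#' the stage coefficient, BH-adjusted across converged features.
#'
#' @param counts Count table (feature id + sample columns) of raw counts.
#' @param metadata Data frame with columns sample, stage (and optionally
#'   assay) covering the count columns.
#' @param stageA,stageB Stage labels; the reported log2FC is stageB vs
#'   stageA.
#' @return Tibble: feature, baseMean, log2FC, lfcSE, stat, pvalue, padj,
#'   converged.
#' @export
nb_stage_test <- function(counts, metadata, stageA, stageB) {
  m <- count_table_to_matrix(counts)
  metadata <- check_metadata(metadata, colnames(m))
  keep <- metadata$stage %in% c(stageA, stageB)
  m <- m[, keep, drop = FALSE]
  stage <- factor(metadata$stage[keep], levels = c(stageA, stageB))
  if (any(table(stage) < 2)) abort("need >= 2 replicates per stage")
  sf <- estimate_size_factors(m)
  disp <- estimate_dispersions(m, sf, stage)
  X <- model.matrix(~stage)
  colnames(X) <- c("(Intercept)", "stage")
  nb_fit_contrast(m, X, "stage", sf, disp)
}

#' Two-factor interaction test: steady-state vs nascent discordance
#'
#' Fits, gene by gene, the full two-factor NB model
#' `~ stage + assay + stage:assay` on the combined nascent ("chro") and
#' steady-state ("rna") counts and extracts the interaction coefficient,
#' interpretable as `log2[(RNA_B/RNA_A) / (ChRO_B/ChRO_A)]`: positive
#' values mean the steady-state change exceeded the transcriptional change
#' (lost post-transcriptional suppression).  Size factors are estimated
#' jointly across the combined matrix by default.
#'
#' @param chro,rna Count tables sharing a gene universe (the intersection
#'   is tested).
#' @param metadata Data frame with sample, assay ("chro"/"rna"), stage for
#'   every sample column of both tables.
#' @param stageA,stageB The stage transition (A is the reference).
#' @param joint_size_factors Estimate size factors on the combined matrix
#'   (default) or per assay.
#' @return Tibble as in [nb_stage_test()], log2FC being the interaction
#'   term.
#' @export
two_factor_interaction <- function(chro, rna, metadata, stageA, stageB,
                                   joint_size_factors = TRUE) {
  mc <- count_table_to_matrix(chro)
  mr <- count_table_to_matrix(rna)
  genes <- intersect(rownames(mc), rownames(mr))
  if (length(genes) == 0) abort("no shared genes between the two assays")
  m <- cbind(mc[genes, , drop = FALSE], mr[genes, , drop = FALSE])
  metadata <- check_metadata(metadata, colnames(m))
  keep <- metadata$stage %in% c(stageA, stageB)
  m <- m[, keep, drop = FALSE]
  metadata <- metadata[keep, , drop = FALSE]
  stage <- factor(metadata$stage, levels = c(stageA, stageB))
  assay <- factor(metadata$assay, levels = c("chro", "rna"))
  cells <- table(stage, assay)
  if (any(cells < 2)) {
    abort("every (stage, assay) cell needs >= 2 samples")
  }
  if (joint_size_factors) {
    sf <- estimate_size_factors(m)
  } else {
    sf <- numeric(ncol(m))
    for (a in levels(assay)) {
      j <- which(assay == a)
      sf[j] <- estimate_size_factors(m[, j, drop = FALSE])
    }
    names(sf) <- colnames(m)
  }
  design <- data.frame(stage = stage, assay = assay)
  disp <- estimate_dispersions(m, sf, design)
  X <- model.matrix(~ stage * assay)
  colnames(X) <- c("(Intercept)", "stage", "assay", "interaction")
  nb_fit_contrast(m, X, "interaction", sf, disp)
}
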