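## Structure-corrected analogues of the F_ST metrics: genotype PCA, a
## PC-adjusted logistic GWAS of sex (L_ST), and sex-stratified linear GWAS of
## LRS feeding the |t| and unfolded-t statistics. Fixed-effect PC adjustment
## stands in for mixed-model kinship correction (a deliberate, documented
## design choice).

## samples x sites standardised dosage matrix; missing dosages mean-imputed.
standardise_dosages <- function(G, cols = NULL, site_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(G))
  if (is.null(cols)) cols <- seq_len(ncol(G))
  X <- t(G[site_idx, cols, drop = FALSE]) * 1.0
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    mj <- is.na(X[, j])
    if (any(mj)) X[mj, j] <- mu[j]
  }
  X <- sweep(X, 2, colMeans(X), "-")
  sds <- sqrt(colSums(X^2) / (nrow(X) - 1))
  ok <- sds > 0
  X[, ok] <- sweep(X[, ok, drop = FALSE], 2, sds[ok], "/")
  X[, !ok] <- 0
  X
}

#' Principal components of the genotype matrix
#'
#' Top-`k` principal components of the standardised (mean-centred,
#' variance-scaled, mean-imputed) dosage matrix, via an eigendecomposition of
#' the site-side covariance. Component signs are fixed by making the largest
#' absolute loading positive, so results are deterministic.
#'
#' @param x a [cohort()] or sites x samples dosage matrix. Sites should be
#'   LD-pruned first.
#' @param k number of components (default 20).
#' @param site_cap maximum number of sites used (evenly spaced subset,
#'   default 2000); caps the cost of the eigendecomposition.
#' @return list of class `"structure_model"`: `pcs` (samples x k scores),
#'   `explained_variance` (fraction per component), `sites_used`.
#' @export
fit_pcs <- function(x, k = 20, site_cap = 2000) {
  G <- if (inherits(x, "cohort")) x$genotypes else x
  n_samp <- ncol(G)
  if (k >= n_samp) stop("k must be smaller than the number of samples")
  idx <- if (nrow(G) > site_cap)
    unique(round(seq(1, nrow(G), length.out = site_cap))) else seq_len(nrow(G))
  X <- standardise_dosages(G, site_idx = idx)
  C <- crossprod(X) / (n_samp - 1)
  eig <- eigen(C, symmetric = TRUE)
  k_eff <- min(k, sum(eig$values > 1e-12))
  V <- eig$vectors[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  structure(list(pcs = scores,
                 explained_variance = eig$values[seq_len(k_eff)] /
                   sum(pmax(eig$values, 0)),
                 sites_used = idx), class = "structure_model")
}

## Design matrix: intercept + user covariates (factors expanded) + PCs.
build_design <- function(x, structure = NULL, covariates = NULL, rows = NULL) {
  n <- nrow(x$samples)
  if (is.null(rows)) rows <- seq_len(n)
  parts <- list(`(Intercept)` = rep(1, length(rows)))
  if (!is.null(covariates)) {
    cv <- x$samples[rows, covariates, drop = FALSE]
    for (nm in names(cv)) {
      v <- cv[[nm]]
      if (is.numeric(v)) {
        parts[[nm]] <- v
      } else {
        f <- factor(v)
        if (nlevels(f) > 1) {
          mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
          colnames(mm) <- paste0(nm, levels(f)[-1])
          for (j in seq_len(ncol(mm))) parts[[colnames(mm)[j]]] <- mm[, j]
        }
      }
    }
  }
  if (!is.null(structure)) {
    pcs <- structure$pcs[rows, , drop = FALSE]
    for (j in seq_len(ncol(pcs))) parts[[paste0("PC", j)]] <- pcs[, j]
  }
  W <- do.call(cbind, parts)
  colnames(W) <- names(parts)
  W
}

#' Logistic GWAS of sex
#'
#' Per-site logistic regression of sex (coded 1 = female, 0 = male, so a
#' positive log-odds means the ALT allele is commoner in females, matching the
#' sign of `p_f - p_m`) on ALT dosage plus covariates and principal
#' components. Missing dosages are mean-imputed.
#'
#' @param x a [cohort()].
#' @param structure optional [fit_pcs()] result.
#' @param covariates optional character vector of sample columns (e.g.
#'   `c("age", "centre")`).
#' @param block sites per processing block.
#' @return data.frame per site: `beta` (log-odds for one ALT copy), `se`,
#'   `n_used`; non-converged or separated fits give `NA`.
#' @export
gwas_of_sex <- function(x, structure = NULL, covariates = NULL, block = 512L) {
  stopifnot(inherits(x, "cohort"))
  y <- as.numeric(x$samples$sex == "F")
  W <- build_design(x, structure, covariates)
  n <- length(y)
  ## warm start from the covariate-only fit
  null_fit <- stats::glm.fit(W, y, family = stats::binomial())
  start0 <- c(0, null_fit$coefficients)
  n_sites <- nrow(x$genotypes)
  beta <- se <- rep(NA_real_, n_sites)
  n_used <- rep(n, n_sites)
  for (s in seq(1L, n_sites, by = block)) {
    idx <- s:min(s + block - 1L, n_sites)
    for (j in seq_along(idx)) {
      g <- x$genotypes[idx[j], ] * 1.0
      mg <- is.na(g)
      if (any(mg)) g[mg] <- mean(g, na.rm = TRUE)
      if (stats::sd(g) == 0) next
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(g = g, W), y,
                                        family = stats::binomial(),
                                        start = start0,
                                        control = stats::glm.control(
                                          epsilon = 1e-12, maxit = 100))),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      ## covariance of coefficients from the final IRLS weights
      Xd <- cbind(g = g, W)
      wt <- fit$weights
      XtWX <- crossprod(Xd * sqrt(wt))
      v <- tryCatch(solve(XtWX)[1, 1], error = function(e) NA_real_)
      if (!is.na(v) && v > 0 && abs(fit$coefficients[1]) < 20) {
        beta[idx[j]] <- fit$coefficients[1]
        se[idx[j]] <- sqrt(v)
      }
    }
  }
  data.frame(beta = beta, se = se, n_used = n_used)
}

#' Frequency-standardised squared log-odds (L_ST)
#'
#' `(p_bar (1 - p_bar) * L)^2` where `L` is the log-odds ratio from the GWAS
#' of sex: the structure-corrected analogue of adult F_ST. The alternative
#' square-root standardiser `(sqrt(p_bar(1-p_bar)) * L)^2` is available via
#' `sqrt_standardiser = TRUE`.
#'
#' @param beta log-odds ratio(s).
#' @param p_bar sex-averaged allele frequency.
#' @param sqrt_standardiser use `sqrt(p_bar(1-p_bar))` instead of
#'   `p_bar(1-p_bar)` (default FALSE, as printed in the source derivation).
#' @return numeric vector; `NA` where `p_bar` is 0/1 or beta is `NA`.
#' @export
l_st <- function(beta, p_bar, sqrt_standardiser = FALSE) {
  w <- p_bar * (1 - p_bar)
  w[w <= 0] <- NA_real_
  if (sqrt_standardiser) w <- sqrt(w)
  (w * beta)^2
}

#' Sex-stratified linear GWAS of LRS
#'
#' Within each sex, ordinary least squares of LRS on ALT dosage plus
#' covariates and principal components. Implemented by residualising LRS and
#' dosages on the covariate block (Frisch-Waugh), which gives the exact OLS
#' dosage coefficient and standard error in a vectorised pass.
#'
#' @param x a [cohort()].
#' @param structure optional [fit_pcs()] result.
#' @param covariates optional character vector of sample columns.
#' @param block sites per processing block.
#' @return data.frame per site: `beta_f`, `se_f`, `n_f`, `beta_m`, `se_m`,
#'   `n_m`; rank-deficient (constant-dosage) sites give `NA`.
#' @export
gwas_of_lrs_by_sex <- function(x, structure = NULL, covariates = NULL,
                               block = 1024L) {
  stopifnot(inherits(x, "cohort"))
  out <- list()
  for (sx in c("F", "M")) {
    rows <- which(x$samples$sex == sx)
    y <- as.numeric(x$samples$lrs[rows])
    W <- build_design(x, structure, covariates, rows = rows)
    qrW <- qr(W)
    q_rank <- qrW$rank
    y_t <- stats::resid(stats::lm.fit(W, y))
    yy <- sum(y_t^2)
    n <- length(rows)
    df <- n - q_rank - 1L
    n_sites <- nrow(x$genotypes)
    beta <- se <- rep(NA_real_, n_sites)
    for (s in seq(1L, n_sites, by = block)) {
      idx <- s:min(s + block - 1L, n_sites)
      X <- t(x$genotypes[idx, rows, drop = FALSE]) * 1.0
      mu <- colMeans(X, na.rm = TRUE)
      for (j in seq_len(ncol(X))) {
        mj <- is.na(X[, j])
        if (any(mj)) X[mj, j] <- mu[j]
      }
      X_t <- X - qr.fitted(qrW, X)
      v <- colSums(X_t^2)
      cxy <- drop(crossprod(X_t, y_t))
      b <- ifelse(v > 1e-10, cxy / v, NA_real_)
      rss <- yy - b^2 * v
      s2 <- rss / df
      beta[idx] <- b
      se[idx] <- ifelse(!is.na(b) & s2 > 0, sqrt(s2 / v), NA_real_)
    }
    out[[sx]] <- data.frame(beta = beta, se = se, n = n)
  }
  data.frame(beta_f = out$F$beta, se_f = out$F$se, n_f = out$F$n,
             beta_m = out$M$beta, se_m = out$M$se, n_m = out$M$n)
}

#' Between-sex rank correlation of GWAS effects
#'
#' Spearman correlation of female and male effect sizes over (LD-pruned)
#' loci; plugged into the denominator of the |t| statistic.
#'
#' @param beta_f,beta_m effect vectors over the same loci.
#' @param min_loci minimum complete pairs (default 100).
#' @return scalar rho.
#' @export
between_sex_rho <- function(beta_f, beta_m, min_loci = 100) {
  ok <- !is.na(beta_f) & !is.na(beta_m)
  if (sum(ok) < min_loci)
    stop("need at least ", min_loci, " loci with defined effects in both sexes")
  stats::cor(beta_f[ok], beta_m[ok], method = "spearman")
}

#' Sex-difference t statistics from sex-stratified GWAS effects
#'
#' `t_signed = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2 - 2 rho se_f se_m)`,
#' `t_abs = |t_signed|`, and the SA/SC-partitioning analogue
#' `unfolded_t = beta_f * beta_m / (se_f * se_m)`.
#'
#' @param effects data.frame with `beta_f`, `se_f`, `beta_m`, `se_m` (as from
#'   [gwas_of_lrs_by_sex()]).
#' @param rho between-sex rank correlation of effects (scalar, from
#'   [between_sex_rho()]).
#' @return data.frame `t_signed`, `t_abs`, `unfolded_t`, `rho`; a
#'   non-positive variance of the difference gives `NA`.
#' @export
t_statistics <- function(effects, rho = 0) {
  v <- effects$se_f^2 + effects$se_m^2 - 2 * rho * effects$se_f * effects$se_m
  v[!is.na(v) & v <= 0] <- NA_real_
  t_signed <- (effects$beta_f - effects$beta_m) / sqrt(v)
  unfolded <- effects$beta_f * effects$beta_m / (effects$se_f * effects$se_m)
  data.frame(t_signed = t_signed, t_abs = abs(t_signed),
             unfolded_t = unfolded, rho = rho)
}
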