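## Forward simulator of biobank-like cohorts with known sex-specific viability
## and reproductive (LRS) selection, optional two-population structure with
## sex-biased sampling, optional LD blocks, and genotyping-artefact injection.
##
## Life cycle: zygotes are drawn at Hardy-Weinberg equilibrium from ancestral
## (or Balding-Nichols subpopulation) frequencies, identical in the two sexes
## at conception; viability selection thins zygotes to the target adult counts
## with survival weight prod_sites (1 + s_viab,sex * g / 2); LRS is then drawn
## with mean mu_sex * prod_sites (1 + s_repr,sex * g / 2); artefacts are
## injected last.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 20,000 adults per
#' sex, 5,000 sites, uniform(0.05, 0.95) ancestral frequencies, Poisson LRS
#' with mean 1.8 in both sexes, no structure, no linkage, no artefacts.
#' Selection presets place `s = 0.1` effects at 10\% of sites:
#' \describe{
#'   \item{neutral}{no selection.}
#'   \item{sa}{sexually antagonistic LRS selection: `s_repr_f = +s`,
#'     `s_repr_m = -s`.}
#'   \item{sc_equal}{sexually concordant LRS selection of equal strength:
#'     `s_repr_f = s_repr_m = +s`.}
#'   \item{sc_unequal}{concordant but sex-differential: `s_repr_f = +s`,
#'     `s_repr_m = +s/2`.}
#'   \item{viability_sa}{sexually antagonistic viability selection:
#'     `s_viab_f = +s`, `s_viab_m = -s`, no LRS selection.}
#' }
#'
#' @param n_f,n_m target adult sample sizes (default 20000 each).
#' @param n_sites number of diallelic sites (default 5000).
#' @param preset selection preset (see above).
#' @param s preset effect size (default 0.1).
#' @param selected_frac preset fraction of selected sites (default 0.1).
#' @param selection optional explicit per-site selection data.frame with
#'   columns `s_viab_f`, `s_viab_m`, `s_repr_f`, `s_repr_m` (overrides the
#'   preset).
#' @param freq_model `list(kind = "uniform", lo, hi)` or
#'   `list(kind = "beta", a, b)` for ancestral ALT frequencies.
#' @param lrs_model `list(kind = "poisson", mu_f, mu_m)` or
#'   `list(kind = "negbin", mu_f, mu_m, cv2)` where `cv2` is the target
#'   squared coefficient of variation sigma^2/mu^2 (default 1.5, a human-like
#'   overdispersion).
#' @param structure `list(kind = "none")` or `list(kind = "two_pop", F,
#'   frac_f_pop1, frac_m_pop1)`: Balding-Nichols divergence `F` and the
#'   fraction of each sex sampled from subpopulation 1 (sex-biased sampling
#'   when the two fractions differ; defaults F = 0.05, 0.8 vs 0.2).
#' @param linkage `NULL` or `list(block_size, rho)`: sites are grouped into
#'   consecutive blocks whose haplotypes share a Gaussian-copula latent factor
#'   with correlation `rho`.
#' @param artefacts `list(missing_rate, missing_rate_m, het_inflation_frac,
#'   het_inflation_strength)`: genotype masking (optionally sex-biased via a
#'   separate male rate) and, at a fraction of sites, conversion of
#'   minor-allele homozygotes to heterozygotes emulating cross-mapping
#'   collapse.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_f = 20000, n_m = 20000, n_sites = 5000,
                       preset = c("neutral", "sa", "sc_equal", "sc_unequal",
                                  "viability_sa"),
                       s = 0.1, selected_frac = 0.1, selection = NULL,
                       freq_model = list(kind = "uniform", lo = 0.05, hi = 0.95),
                       lrs_model = list(kind = "poisson", mu_f = 1.8, mu_m = 1.8),
                       structure = list(kind = "none"),
                       linkage = NULL,
                       artefacts = list(missing_rate = 0, missing_rate_m = NULL,
                                        het_inflation_frac = 0,
                                        het_inflation_strength = 1),
                       seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(n_f >= 2, n_m >= 2, n_sites >= 1, s > -1, s < 1,
            selected_frac >= 0, selected_frac <= 1)
  structure(list(n_f = n_f, n_m = n_m, n_sites = n_sites, preset = preset,
                 s = s, selected_frac = selected_frac, selection = selection,
                 freq_model = freq_model, lrs_model = lrs_model,
                 structure = structure, linkage = linkage,
                 artefacts = artefacts, seed = seed),
            class = "sim_config")
}

## per-site selection table from a preset
preset_selection <- function(cfg) {
  n <- cfg$n_sites
  sel <- data.frame(s_viab_f = numeric(n), s_viab_m = numeric(n),
                    s_repr_f = numeric(n), s_repr_m = numeric(n))
  if (cfg$preset == "neutral" || cfg$selected_frac == 0) return(sel)
  n_sel <- max(1L, round(cfg$selected_frac * n))
  idx <- sample.int(n, n_sel)
  s <- cfg$s
  if (cfg$preset == "sa") {
    sel$s_repr_f[idx] <- s; sel$s_repr_m[idx] <- -s
  } else if (cfg$preset == "sc_equal") {
    sel$s_repr_f[idx] <- s; sel$s_repr_m[idx] <- s
  } else if (cfg$preset == "sc_unequal") {
    sel$s_repr_f[idx] <- s; sel$s_repr_m[idx] <- s / 2
  } else if (cfg$preset == "viability_sa") {
    sel$s_viab_f[idx] <- s; sel$s_viab_m[idx] <- -s
  }
  sel
}

## genotypes for a block of sites x samples at HWE, given per-site-per-sample
## ALT frequency matrix (or per-site vector); optional copula linkage
draw_genotypes <- function(p, n_samp, linkage = NULL, block_id = NULL) {
  n_sites <- if (is.matrix(p)) nrow(p) else length(p)
  if (is.null(linkage)) {
    ## chunked generation keeps the transient double vector small
    g <- matrix(0L, n_sites, n_samp)
    chunk <- max(1L, min(n_samp, ceiling(4e6 / max(1L, n_sites))))
    for (s in seq(1L, n_samp, by = chunk)) {
      cols <- s:min(s + chunk - 1L, n_samp)
      pv <- if (is.matrix(p)) as.vector(p[, cols]) else
        rep(p, length(cols))
      g[, cols] <- as.integer(stats::rbinom(n_sites * length(cols), 2L, pv))
    }
  } else {
    ## two latent haplotype draws; sites within a block share a common factor
    rho <- linkage$rho
    g <- matrix(0L, n_sites, n_samp)
    for (b in unique(block_id)) {
      rows <- which(block_id == b)
      pb <- if (is.matrix(p)) p[rows, , drop = FALSE]
      else matrix(p[rows], length(rows), n_samp)
      thr <- stats::qnorm(pb)
      hap <- matrix(0L, length(rows), n_samp)
      for (h in 1:2) {
        common <- matrix(stats::rnorm(n_samp), length(rows), n_samp,
                         byrow = TRUE)
        z <- sqrt(rho) * common +
          sqrt(1 - rho) * matrix(stats::rnorm(length(rows) * n_samp),
                                 length(rows), n_samp)
        hap <- hap + (z < thr)
      }
      g[rows, ] <- hap
    }
  }
  storage.mode(g) <- "integer"
  g
}

## multiplicative fitness factor prod_sites (1 + s * g / 2) for a genotype
## submatrix (selected sites only)
fitness_factor <- function(G_sel, s_vec) {
  if (nrow(G_sel) == 0L) return(rep(1, ncol(G_sel)))
  ## s_vec recycles down columns (length == nrow); non-positive factors give
  ## NaN here and are rejected by the caller
  lf <- suppressWarnings(log1p((G_sel / 2) * s_vec))
  exp(colSums(lf))
}

## Efraimidis-Spirakis weighted sampling without replacement: top-n keys
weighted_sample_noreplace <- function(n, weights) {
  keys <- log(stats::runif(length(weights))) / weights
  order(keys, decreasing = TRUE)[seq_len(n)]
}

#' Simulate a cohort with known sex-specific selection
#'
#' Runs the zygote -> adult -> offspring life cycle described in
#' [sim_config()] and returns the adult cohort plus a per-site truth table of
#' realised selection coefficients.
#'
#' @param cfg a [sim_config()].
#' @return a [cohort()] with attribute `"truth"` (data.frame: site metadata,
#'   ancestral frequency, selection coefficients, selection regime label,
#'   linkage block).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_sites <- cfg$n_sites
  n_f <- cfg$n_f; n_m <- cfg$n_m

  p0 <- switch(cfg$freq_model$kind,
               uniform = stats::runif(n_sites, cfg$freq_model$lo,
                                      cfg$freq_model$hi),
               beta = stats::rbeta(n_sites, cfg$freq_model$a,
                                   cfg$freq_model$b),
               stop("unknown freq_model kind"))

  sel <- if (is.null(cfg$selection)) preset_selection(cfg) else cfg$selection
  stopifnot(nrow(sel) == n_sites)

  block_id <- if (!is.null(cfg$linkage))
    rep(seq_len(ceiling(n_sites / cfg$linkage$block_size)),
        each = cfg$linkage$block_size)[seq_len(n_sites)] else NULL

  ## subpopulation assignment (sex-biased sampling under structure)
  two_pop <- identical(cfg$structure$kind, "two_pop")
  if (two_pop) {
    Fst <- cfg$structure$F
    a1 <- p0 * (1 - Fst) / Fst
    a2 <- (1 - p0) * (1 - Fst) / Fst
    p_pop <- cbind(stats::rbeta(n_sites, a1, a2),
                   stats::rbeta(n_sites, a1, a2))
    frac_f <- if (is.null(cfg$structure$frac_f_pop1)) 0.8 else
      cfg$structure$frac_f_pop1
    frac_m <- if (is.null(cfg$structure$frac_m_pop1)) 0.2 else
      cfg$structure$frac_m_pop1
    pop_f <- ifelse(stats::runif(n_f) < frac_f, 1L, 2L)
    pop_m <- ifelse(stats::runif(n_m) < frac_m, 1L, 2L)
  } else {
    pop_f <- rep(1L, n_f); pop_m <- rep(1L, n_m)
  }
  pop <- c(pop_f, pop_m)
  sex <- c(rep("F", n_f), rep("M", n_m))

  ## sites whose zygote genotypes must be generated before viability
  ## selection: the viability-selected sites plus their linkage-block mates
  viab_f_sel <- which(sel$s_viab_f != 0)
  viab_m_sel <- which(sel$s_viab_m != 0)
  viab_any <- union(viab_f_sel, viab_m_sel)
  early <- if (is.null(block_id)) viab_any else
    which(block_id %in% unique(block_id[viab_any]))
  early <- sort(early)
  late <- setdiff(seq_len(n_sites), early)

  gen_for_samples <- function(site_idx, samp_idx) {
    ## per-sample frequencies honour subpopulation membership
    if (length(site_idx) == 0L || length(samp_idx) == 0L)
      return(matrix(integer(0), length(site_idx), length(samp_idx)))
    bid <- if (is.null(block_id)) NULL else
      match(block_id[site_idx], unique(block_id[site_idx]))
    if (two_pop) {
      pm <- p_pop[site_idx, pop[samp_idx], drop = FALSE]
      draw_genotypes(pm, length(samp_idx), cfg$linkage, bid)
    } else {
      draw_genotypes(p0[site_idx], length(samp_idx), cfg$linkage, bid)
    }
  }

  if (length(early) > 0L) {
    G <- matrix(NA_integer_, n_sites, n_f + n_m)
    ## 3x oversampled zygote pool per sex, thinned by weighted sampling
    oversample <- 3L
    for (sx in c("F", "M")) {
      n_target <- if (sx == "F") n_f else n_m
      samp_idx <- which(sex == sx)
      pool_n <- oversample * n_target
      pool_pop <- if (two_pop) {
        frac <- if (sx == "F") frac_f else frac_m
        ifelse(stats::runif(pool_n) < frac, 1L, 2L)
      } else rep(1L, pool_n)
      bid <- if (is.null(block_id)) NULL else
        match(block_id[early], unique(block_id[early]))
      pm <- if (two_pop) p_pop[early, pool_pop, drop = FALSE] else NULL
      Gp <- if (two_pop)
        draw_genotypes(pm, pool_n, cfg$linkage, bid)
      else draw_genotypes(p0[early], pool_n, cfg$linkage, bid)
      s_vec <- if (sx == "F") sel$s_viab_f[early] else sel$s_viab_m[early]
      w <- fitness_factor(Gp[s_vec != 0, , drop = FALSE], s_vec[s_vec != 0])
      if (any(!is.finite(w) | w <= 0))
        stop("non-positive survival weights; reduce |s_viab|")
      surv <- weighted_sample_noreplace(n_target, w)
      G[early, samp_idx] <- Gp[, surv, drop = FALSE]
      if (two_pop) pop[samp_idx] <- pool_pop[surv]
    }
    if (length(late) > 0L)
      G[late, ] <- gen_for_samples(late, seq_len(n_f + n_m))
  } else {
    ## no viability selection: a single allocation, no site split
    G <- gen_for_samples(seq_len(n_sites), seq_len(n_f + n_m))
  }

  ## LRS with reproductive selection
  repr_any <- which(sel$s_repr_f != 0 | sel$s_repr_m != 0)
  lrs <- numeric(n_f + n_m)
  for (sx in c("F", "M")) {
    samp_idx <- which(sex == sx)
    mu0 <- if (sx == "F") cfg$lrs_model$mu_f else cfg$lrs_model$mu_m
    s_vec <- if (sx == "F") sel$s_repr_f else sel$s_repr_m
    active <- repr_any[s_vec[repr_any] != 0]
    mult <- if (length(active) > 0)
      fitness_factor(G[active, samp_idx, drop = FALSE], s_vec[active])
    else rep(1, length(samp_idx))
    ## relative fitness: normalise so the sex's mean LRS stays at mu0
    ## regardless of how many loci are under selection
    mult <- mult / mean(mult)
    mu_i <- mu0 * mult
    if (cfg$lrs_model$kind == "poisson") {
      lrs[samp_idx] <- stats::rpois(length(samp_idx), mu_i)
    } else if (cfg$lrs_model$kind == "negbin") {
      cv2 <- if (is.null(cfg$lrs_model$cv2)) 1.5 else cfg$lrs_model$cv2
      ## size chosen so that sigma^2/mu^2 = cv2 at the baseline mean
      size <- mu0 / (cv2 * mu0 - 1)
      if (size <= 0) stop("negbin cv2 must exceed 1/mu")
      lrs[samp_idx] <- stats::rnbinom(length(samp_idx), size = size,
                                      mu = mu_i)
    } else stop("unknown lrs_model kind")
  }

  samples <- data.frame(
    id = sprintf("S%06d", seq_len(n_f + n_m)),
    sex = sex, lrs = as.integer(lrs),
    age = sample(45:69, n_f + n_m, replace = TRUE),
    centre = sample(paste0("C", 1:3), n_f + n_m, replace = TRUE),
    pop = pop, excluded = FALSE, stringsAsFactors = FALSE)

  sites <- data.frame(chrom = "1", pos = seq_len(n_sites) * 1000L,
                      ref = "A", alt = "G", info_score = 1.0,
                      stringsAsFactors = FALSE)

  x <- cohort(G, samples, sites)
  regime <- rep("neutral", n_sites)
  regime[sel$s_viab_f != 0 | sel$s_viab_m != 0] <- "viability"
  is_repr <- sel$s_repr_f != 0 | sel$s_repr_m != 0
  regime[is_repr & sign(sel$s_repr_f) * sign(sel$s_repr_m) < 0] <- "sa"
  regime[is_repr & sign(sel$s_repr_f) * sign(sel$s_repr_m) >= 0] <- "sc"
  truth <- data.frame(sites[, c("chrom", "pos")], p0 = p0, sel,
                      regime = regime,
                      block = if (is.null(block_id)) NA_integer_ else block_id)
  x <- inject_artefacts(x, cfg)
  attr(x, "truth") <- truth
  x
}

#' Inject genotyping artefacts into a cohort
#'
#' Masks genotypes at random (optionally sex-biased via a separate male
#' missing rate) and, at a random fraction of sites, converts minor-allele
#' homozygotes to heterozygotes (emulating the collapse of cross-mapped
#' sex-chromosome reads onto autosomal sites). A strength of 1 converts every
#' minor homozygote. Sites altered by the heterozygote inflation are recorded
#' in the attribute `"artefact_sites"`.
#'
#' @param x a [cohort()].
#' @param cfg a [sim_config()] (only the `artefacts` entry is used).
#' @return the modified cohort.
#' @export
inject_artefacts <- function(x, cfg) {
  a <- cfg$artefacts
  if (is.null(a)) return(x)
  G <- x$genotypes
  rate_f <- if (is.null(a$missing_rate)) 0 else a$missing_rate
  rate_m <- if (is.null(a$missing_rate_m)) rate_f else a$missing_rate_m
  if (rate_f > 0 || rate_m > 0) {
    for (sx in c("F", "M")) {
      r <- if (sx == "F") rate_f else rate_m
      if (r <= 0) next
      colsx <- which(x$samples$sex == sx)
      mask <- matrix(stats::runif(nrow(G) * length(colsx)) < r,
                     nrow(G), length(colsx))
      Gs <- G[, colsx, drop = FALSE]
      Gs[mask] <- NA_integer_
      G[, colsx] <- Gs
    }
  }
  het_sites <- integer(0)
  frac <- if (is.null(a$het_inflation_frac)) 0 else a$het_inflation_frac
  if (frac > 0) {
    strength <- if (is.null(a$het_inflation_strength)) 1 else
      a$het_inflation_strength
    het_sites <- sort(sample.int(nrow(G), max(1L, round(frac * nrow(G)))))
    for (i in het_sites) {
      g <- G[i, ]
      p_alt <- mean(g, na.rm = TRUE) / 2
      minor_g <- if (is.na(p_alt)) next else if (p_alt <= 0.5) 2L else 0L
      hit <- which(!is.na(g) & g == minor_g)
      hit <- hit[stats::runif(length(hit)) < strength]
      g[hit] <- 1L
      G[i, ] <- g
    }
  }
  x$genotypes <- G
  attr(x, "artefact_sites") <- het_sites
  x
}

#' Write a simulated cohort to VCF + phenotype + truth files
#'
#' Emits a plain-text VCF 4.2 (GT only, INFO carrying the imputation score), a
#' tab-separated phenotype table and the per-site truth table. Re-reading the
#' pair through [read_cohort()] reproduces the cohort exactly.
#'
#' @param x a [cohort()] (typically from [simulate_cohort()]).
#' @param out_prefix path prefix; writes `<prefix>.vcf`, `<prefix>.pheno.tsv`
#'   and (when a truth table is attached) `<prefix>.truth.tsv`.
#' @return named character vector of the paths written.
#' @export
write_simulation <- function(x, out_prefix) {
  stopifnot(inherits(x, "cohort"))
  vcf_path <- paste0(out_prefix, ".vcf")
  ph_path <- paste0(out_prefix, ".pheno.tsv")
  truth_path <- paste0(out_prefix, ".truth.tsv")

  con <- file(vcf_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples$id), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(x$sites))) {
    g <- x$genotypes[i, ]
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    info <- if (!is.null(x$sites$info_score) && !is.na(x$sites$info_score[i]))
      sprintf("INFO=%g", x$sites$info_score[i]) else "."
    writeLines(paste(c(x$sites$chrom[i], x$sites$pos[i], ".",
                       x$sites$ref[i], x$sites$alt[i], ".", "PASS",
                       info, "GT", gs), collapse = "\t"), con)
  }

  ph <- x$samples
  utils::write.table(ph, ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(vcf = vcf_path, pheno = ph_path)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, truth = truth_path)
  }
  paths
}
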