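#' @keywords internal
"_PACKAGE"

## Genotypes are stored as an integer matrix (sites x samples) of ALT-allele
## dosages in {0, 1, 2, NA}. Downstream allele frequencies always refer to the
## VCF ALT allele (the "A1" allele of the metric definitions).

#' Construct a cohort object
#'
#' A cohort bundles a genotype dosage matrix with per-sample phenotypes and
#' per-site metadata. Dosages count copies of the ALT allele; missing genotypes
#' are `NA`.
#'
#' @param genotypes integer matrix, sites x samples, entries in `{0,1,2,NA}`.
#' @param samples data.frame with columns `id`, `sex` (`"F"`/`"M"`), `lrs`
#'   (non-negative integer lifetime reproductive success), and optionally
#'   `age`, `centre`, `excluded` (logical), plus repeat-assessment columns
#'   `lrs_1..lrs_k`.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `info_score` plus annotation columns.
#' @return an object of class `"cohort"`.
#' @export
cohort <- function(genotypes, samples, sites) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(sites))
    stop("genotype rows (", nrow(genotypes), ") != number of sites (",
         nrow(sites), ")")
  if (ncol(genotypes) != nrow(samples))
    stop("genotype columns (", ncol(genotypes), ") != number of samples (",
         nrow(samples), ")")
  samples$sex <- normalise_sex(samples$sex)
  ## min/max (unlike range()) allocate nothing on large matrices
  mn <- suppressWarnings(min(genotypes, na.rm = TRUE))
  mx <- suppressWarnings(max(genotypes, na.rm = TRUE))
  if (is.finite(mn) && (mn < 0L || mx > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (!"excluded" %in% names(samples)) samples$excluded <- FALSE
  if (!is.logical(samples$excluded)) {
    ex <- samples$excluded
    samples$excluded <- if (is.numeric(ex)) ex != 0 else
      toupper(trimws(as.character(ex))) %in% c("TRUE", "T", "1", "YES")
  }
  if (is.null(samples$lrs) || anyNA(samples$lrs) || any(samples$lrs < 0))
    stop("every sample needs a non-missing LRS >= 0")
  rownames(samples) <- NULL
  rownames(sites) <- NULL
  structure(list(genotypes = genotypes, samples = samples, sites = sites),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$sites), "sites x", nrow(x$samples), "samples (",
      sum(x$samples$sex == "F"), "F /", sum(x$samples$sex == "M"), "M )\n")
  cat("  missing genotype rate:",
      signif(mean(is.na(x$genotypes)), 3), "\n")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$genotypes)

## Accepts F/M, female/male, and the PLINK 1/2 numeric coding (1 = male,
## 2 = female). Anything else is a fatal error.
normalise_sex <- function(sex) {
  s <- toupper(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("F", "FEMALE", "2")] <- "F"
  out[s %in% c("M", "MALE", "1")] <- "M"
  if (anyNA(out)) {
    bad <- unique(s[is.na(out)])
    stop("unrecognised sex value(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Subset a cohort by site and/or sample index
#'
#' @param x a [cohort()].
#' @param sites,samples integer or logical index vectors (default: keep all).
#' @return the subset cohort.
#' @export
subset_cohort <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(sites)) sites <- seq_len(nrow(x$sites))
  if (is.null(samples)) samples <- seq_len(nrow(x$samples))
  cohort(x$genotypes[sites, samples, drop = FALSE],
         x$samples[samples, , drop = FALSE],
         x$sites[sites, , drop = FALSE])
}

#' Read a genotyped cohort from VCF + phenotype TSV
#'
#' Reads GT fields from a VCF 4.x file (diallelic SNPs only; multi-allelic and
#' non-SNP records are dropped with a message) and joins them with a phenotype
#' table. Samples present in only one of the two files are dropped with a
#' warning. Half-calls and `./.` genotypes are treated as missing.
#'
#' @param vcf_path path to a VCF file (plain text or bgzipped).
#' @param phenotype_path path to a tab-separated phenotype table with header
#'   columns `id`, `sex`, `lrs`, and optionally `age`, `centre`, `excluded`,
#'   and repeat LRS assessments `lrs_1 ... lrs_k`.
#' @param info_key INFO field key holding the imputation quality score
#'   (default `"INFO"`); stored as `info_score`, `NA` when absent.
#' @return a [cohort()].
#' @export
read_cohort <- function(vcf_path, phenotype_path, info_key = "INFO") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", vcf_path)

  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(n_drop, " non-SNP or multi-allelic record(s) dropped")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", vcf_path)
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no diallelic SNP records left in VCF")

  dos <- gt_to_dosage(gt)

  info_score <- rep(NA_real_, nrow(fix))
  if (!is.null(fix$INFO)) {
    pat <- paste0("(?:^|;)", info_key, "=([^;]+)")
    m <- regmatches(fix$INFO, regexec(pat, fix$INFO))
    val <- vapply(m, function(z) if (length(z) == 2) z[2] else NA_character_,
                  character(1))
    info_score <- suppressWarnings(as.numeric(val))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, info_score = info_score,
                      stringsAsFactors = FALSE)

  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = NA)
  req <- c("id", "sex", "lrs")
  if (!all(req %in% names(ph)))
    stop("phenotype file must have columns ", paste(req, collapse = ", "),
         ": ", phenotype_path)
  ph$id <- as.character(ph$id)
  ph$sex <- normalise_sex(ph$sex)

  vcf_ids <- colnames(dos)
  common <- intersect(vcf_ids, ph$id)
  if (length(common) == 0L)
    stop("no overlapping samples between VCF and phenotype table")
  only_vcf <- setdiff(vcf_ids, ph$id)
  only_ph <- setdiff(ph$id, vcf_ids)
  if (length(only_vcf) > 0)
    warning(length(only_vcf), " VCF sample(s) missing from phenotype table, ",
            "dropped: ", paste(utils::head(only_vcf, 5), collapse = ", "))
  if (length(only_ph) > 0)
    warning(length(only_ph), " phenotyped sample(s) missing from VCF, ",
            "dropped: ", paste(utils::head(only_ph, 5), collapse = ", "))

  ph <- ph[match(common, ph$id), , drop = FALSE]
  dos <- dos[, common, drop = FALSE]
  cohort(dos, ph, sites)
}

## "0/0" style GT strings -> ALT dosage; phased separators accepted;
## any half-call ("./0", "0/.") or full miss -> NA.
gt_to_dosage <- function(gt) {
  ids <- colnames(gt)
  g <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[g %in% c("0/0")] <- 0L
  dos[g %in% c("0/1", "1/0")] <- 1L
  dos[g %in% c("1/1")] <- 2L
  colnames(dos) <- ids
  rownames(dos) <- NULL
  dos
}

#' Phenotype-level sample filtering
#'
#' Applies the cohort's sample retention rules: individuals younger than
#' `min_age`, with `max_lrs` or more reported offspring, reporting fewer
#' offspring at a later repeat assessment than at an earlier one, or carrying a
#' pre-set `excluded` flag (relatedness / ancestry / heterozygosity panel QC
#' performed upstream) are removed. When repeat assessments `lrs_1..lrs_k` are
#' present and pass the monotonicity check, `lrs` is set to their maximum.
#'
#' @param x a [cohort()].
#' @param min_age minimum retained age in years (default 45).
#' @param max_lrs exclusive upper bound on offspring count (default 20:
#'   individuals reporting 20 or more offspring are removed).
#' @param verbose log a tally of exclusion reasons (default TRUE).
#' @return the filtered cohort, with an attribute `"exclusions"` tallying
#'   reasons.
#' @export
filter_samples <- function(x, min_age = 45, max_lrs = 20, verbose = TRUE) {
  stopifnot(inherits(x, "cohort"))
  s <- x$samples
  n <- nrow(s)

  hist_cols <- grep("^lrs_[0-9]+$", names(s), value = TRUE)
  hist_cols <- hist_cols[order(as.integer(sub("^lrs_", "", hist_cols)))]
  decreasing <- rep(FALSE, n)
  if (length(hist_cols) >= 1) {
    hm <- as.matrix(s[, hist_cols, drop = FALSE])
    if (ncol(hm) >= 2) {
      for (j in 2:ncol(hm)) {
        dec <- !is.na(hm[, j]) & !is.na(hm[, j - 1]) & hm[, j] < hm[, j - 1]
        decreasing <- decreasing | dec
      }
    }
    ## definitive LRS = max over reports (order of ops: monotonicity check
    ## first, then the maximum)
    mx <- suppressWarnings(apply(hm, 1, max, na.rm = TRUE))
    has <- is.finite(mx)
    s$lrs[has] <- pmax(s$lrs[has], mx[has])
  }

  young <- if (!is.null(s$age)) !is.na(s$age) & s$age < min_age else rep(FALSE, n)
  big <- s$lrs >= max_lrs
  flagged <- !is.na(s$excluded) & s$excluded

  drop <- young | decreasing | big | flagged
  tally <- c(age_below_min = sum(young),
             decreasing_lrs_report = sum(decreasing),
             lrs_at_or_above_max = sum(big),
             preset_excluded_flag = sum(flagged),
             total_removed = sum(drop))
  if (verbose)
    message("filter_samples: removed ", sum(drop), "/", n, " (age<", min_age,
            ": ", tally[1], ", decreasing reports: ", tally[2],
            ", lrs>=", max_lrs, ": ", tally[3], ", pre-flagged: ", tally[4], ")")
  if (all(drop)) warning("filter_samples removed every sample")
  x$samples <- s  # keep updated lrs for retained rows
  out <- subset_cohort(x, samples = which(!drop))
  attr(out, "exclusions") <- tally
  out
}

#' Write a per-site metric table
#'
#' Serialises a metric table (as produced by [lifecycle_metrics()]) to a
#' tab-separated file with a fixed column order, `NA` for missing values and
#' numeric values printed with 10+ significant digits so a round-trip read is
#' numerically faithful.
#'
#' @param records data.frame of per-site metric records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to write")
  lead <- intersect(c("chrom", "pos", "ref", "alt"), names(records))
  records <- records[, c(lead, setdiff(names(records), lead)), drop = FALSE]
  fmt <- records
  num <- vapply(fmt, is.double, logical(1))
  fmt[num] <- lapply(fmt[num], function(z) {
    out <- sprintf("%.12g", z)
    out[is.na(z)] <- "NA"
    out
  })
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a metric table written by [write_metric_table()]
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_metric_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA",
                    colClasses = NA)
}
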