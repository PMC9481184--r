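# Programmatic fixtures shared across test files.

# A tiny hand-specified cohort: genotype matrix given explicitly.
make_toy_cohort <- function(genotypes, sex, lrs, chrom = "1",
                            info_score = 1.0, ...) {
  n_sites <- nrow(genotypes)
  n_samp <- ncol(genotypes)
  samples <- data.frame(id = sprintf("T%03d", seq_len(n_samp)), sex = sex,
                        lrs = lrs, age = rep(50, n_samp),
                        centre = rep("C1", n_samp),
                        stringsAsFactors = FALSE, ...)
  sites <- data.frame(chrom = rep(chrom, n_sites),
                      pos = seq_len(n_sites) * 100L,
                      ref = rep("A", n_sites), alt = rep("G", n_sites),
                      info_score = rep(info_score, n_sites),
                      stringsAsFactors = FALSE)
  cohort(genotypes, samples, sites)
}

# Random cohort with genotypes at HWE and Poisson LRS, no selection.
make_random_cohort <- function(n_sites = 20, n_f = 30, n_m = 30, mu = 1.8,
                               seed = 42) {
  set.seed(seed)
  p <- runif(n_sites, 0.1, 0.9)
  n <- n_f + n_m
  g <- matrix(rbinom(n_sites * n, 2, rep(p, n)), n_sites, n)
  make_toy_cohort(g, sex = c(rep("F", n_f), rep("M", n_m)),
                  lrs = rpois(n, mu))
}

# Write a 3-sample, 2-site VCF + matching phenotype TSV; returns the paths.
write_mini_vcf_pair <- function(dir, pheno_ids = c("A1", "A2", "A3"),
                                sex = c("F", "M", "F")) {
  vcf <- file.path(dir, "mini.vcf")
  ph <- file.path(dir, "mini.tsv")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA1\tA2\tA3",
    "1\t100\t.\tA\tG\t.\tPASS\tINFO=0.95\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\tINFO=0.99\tGT\t1|1\t0/0\t./."), vcf)
  writeLines(c("id\tsex\tlrs\tage\tcentre",
               paste(pheno_ids, sex, c(2L, 0L, 3L), c(55L, 60L, 47L),
                     c("C1", "C2", "C1"), sep = "\t")), ph)
  list(vcf = vcf, pheno = ph)
}
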