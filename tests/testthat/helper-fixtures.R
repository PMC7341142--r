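# Small programmatic fixtures shared across test files.

# genotype matrix from a dosage matrix (samples x sites), sites 1 kb apart
make_gm <- function(dosage, chrom = "1", phased = FALSE,
                    hap1 = NULL, hap2 = NULL, ref = "A", alt = "T") {
  dosage <- as.matrix(dosage)
  ns <- ncol(dosage)
  sites <- data.frame(chrom = chrom, pos = seq_len(ns) * 1000L,
                      ref = ref, alt = alt,
                      id = sprintf("s%03d", seq_len(ns)),
                      stringsAsFactors = FALSE)
  genotype_matrix(sprintf("ind%02d", seq_len(nrow(dosage))), sites, dosage,
                  hap1, hap2, phased = phased)
}

# random dosage matrix with missingness
random_dosage <- function(n_ind, n_sites, miss = 0.1, seed = 1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_ind * n_sites, replace = TRUE), n_ind, n_sites)
  d[matrix(runif(n_ind * n_sites) < miss, n_ind, n_sites)] <- NA
  d
}

# independent exact-HWE mid-p oracle: enumerate all genotype configurations
# with the observed allele counts directly (no shared code with the package)
hwe_midp_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  prob <- sapply(hets, function(h) {
    hAA <- (nA - h) / 2
    haa <- n - hAA - h
    exp(lfactorial(n) - lfactorial(hAA) - lfactorial(h) - lfactorial(haa) +
          h * log(2) - (lchoose(2 * n, nA)))
  })
  prob <- prob / sum(prob)
  obs <- prob[hets == nAa]
  sum(prob[prob < obs - 1e-12 * obs]) +
    0.5 * sum(prob[abs(prob - obs) <= 1e-12 * obs])
}

# write a small VCF text file and return its path
write_test_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("fix", tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}
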