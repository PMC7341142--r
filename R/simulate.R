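#' Configuration for the three-stage accession simulator
#'
#' The generator emulates how a landrace (LR) sample and a doubled-haploid
#' (DH) library arise from the same ancestral accession: (i) an independent
#' LR sample is genotyped (Hardy-Weinberg diploids at the ancestral
#' frequency); (ii) a pool of `n_H` DH lines survives haploid induction,
#' with optional recessive viability selection of strength `s` against
#' homozygous carriers of the alternative allele; (iii) `n_dh_lines` of the
#' surviving pool are genotyped. Defaults mirror a realistic accession pair:
#' 23 genotyped LR individuals (46 chromosomes), 58 genotyped DH lines and a
#' surviving pool of 100.
#'
#' @param n_sites Number of SNPs.
#' @param sfs_model Ancestral-frequency model: `"uniform"`, `"beta"` or
#'   `"neutral"` (density proportional to 1/x, the standard neutral SFS shape).
#' @param sfs_par Two parameters: range (uniform, neutral) or shape pair (beta).
#' @param n_H Surviving DH pool size.
#' @param n_lr_individuals Genotyped LR individuals (diploid).
#' @param n_dh_lines Genotyped DH lines (drawn from the pool without
#'   replacement; must not exceed `n_H`).
#' @param s Selection coefficient in `[0, 1]` against DH carriers of the
#'   alternative allele, applied to the sites flagged by `selected_fraction`.
#' @param selected_fraction Fraction of sites under selection (the first
#'   `round(selected_fraction * n_sites)` sites).
#' @param n_windows,snps_per_window,n_founders,dirichlet_conc Window
#'   structure for [simulate_window_haplotypes()]: number of 50 kb windows,
#'   SNPs per window, founder haplotypes per window and the Dirichlet
#'   concentration of founder frequencies.
#' @param map_cm_per_mbp Constant genetic map rate used by
#'   [write_fixture_set()] (cM per Mbp).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 1000, sfs_model = c("uniform", "beta", "neutral"),
                       sfs_par = c(0.05, 0.95), n_H = 100,
                       n_lr_individuals = 23, n_dh_lines = 58,
                       s = 0, selected_fraction = 0,
                       n_windows = 20, snps_per_window = 8, n_founders = 4,
                       dirichlet_conc = 1, map_cm_per_mbp = 1, seed = 1) {
  sfs_model <- match.arg(sfs_model)
  stopifnot(n_sites >= 1, n_H >= 1, n_lr_individuals >= 1, n_dh_lines >= 1,
            n_dh_lines <= n_H, s >= 0, s <= 1,
            selected_fraction >= 0, selected_fraction <= 1,
            n_founders >= 1, length(sfs_par) == 2)
  structure(list(n_sites = as.integer(n_sites), sfs_model = sfs_model,
                 sfs_par = sfs_par, n_H = as.integer(n_H),
                 n_lr_individuals = as.integer(n_lr_individuals),
                 n_dh_lines = as.integer(n_dh_lines), s = s,
                 selected_fraction = selected_fraction,
                 n_windows = as.integer(n_windows),
                 snps_per_window = as.integer(snps_per_window),
                 n_founders = as.integer(n_founders),
                 dirichlet_conc = dirichlet_conc,
                 map_cm_per_mbp = map_cm_per_mbp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw ancestral site frequencies
#'
#' @param config A [sim_config()].
#' @return Numeric vector of `n_sites` frequencies in (0, 1), reproducible
#'   under the config seed.
#' @export
sample_ancestral_frequencies <- function(config) {
  set.seed(config$seed)
  a <- config$sfs_par[1]; b <- config$sfs_par[2]
  switch(config$sfs_model,
         uniform = stats::runif(config$n_sites, a, b),
         beta = {
           p <- stats::rbeta(config$n_sites, a, b)
           pmin(pmax(p, 1e-9), 1 - 1e-9)
         },
         neutral = {
           ## density proportional to 1/x on (a, b): inverse-CDF draw
           stopifnot(a > 0, b > a)
           u <- stats::runif(config$n_sites)
           a * (b / a)^u
         })
}

## Conditional carrier probability among surviving DH lines. A line carrying
## the alternative allele (homozygous by construction) survives with
## probability 1 - s, so conditioning on survival gives p(1-s)/(1-ps);
## drawing each surviving line from this Bernoulli is distributionally
## identical to rejection-resampling dead lines until n_H survivors.
surviving_pool_frequency <- function(p, s) p * (1 - s) / (1 - p * s)

#' Simulate one landrace/DH accession pair with known ground truth
#'
#' Per site independently: the LR panel draws `2 * n_lr_individuals` alleles
#' at the ancestral frequency (HWE diploids, phased); the surviving DH pool
#' of `n_H` lines draws each line's allele at the selection-adjusted carrier
#' frequency p(1-s)/(1-ps); the genotyped DH panel samples `n_dh_lines`
#' lines from the pool without replacement (dosage 2 x line allele).
#'
#' @param config A [sim_config()].
#' @return List of class `simulated_accession` with elements `lr` and `dh`
#'   ([genotype_matrix()]), and `truth`: data frame `site_id p_anc s
#'   pool_count` (surviving-pool alternative-allele line count).
#' @export
simulate_accession <- function(config) {
  p_anc <- sample_ancestral_frequencies(config)
  n <- config$n_sites
  s_vec <- numeric(n)
  n_sel <- round(config$selected_fraction * n)
  if (n_sel > 0) s_vec[seq_len(n_sel)] <- config$s
  if (any(s_vec >= 1 & p_anc >= 1))
    stop("s = 1 with ancestral frequency 1: no surviving DH line is possible")

  sites <- data.frame(chrom = "1", pos = seq_len(n) * 1000L,
                      ref = "A", alt = "T",
                      id = sprintf("snp%05d", seq_len(n)),
                      stringsAsFactors = FALSE)

  n_lr <- config$n_lr_individuals
  h1 <- matrix(stats::rbinom(n_lr * n, 1L, rep(p_anc, each = n_lr)), n_lr, n)
  h2 <- matrix(stats::rbinom(n_lr * n, 1L, rep(p_anc, each = n_lr)), n_lr, n)
  lr <- genotype_matrix(sprintf("LR%03d", seq_len(n_lr)), sites, h1 + h2,
                        h1, h2, phased = TRUE)

  p_pool <- surviving_pool_frequency(p_anc, s_vec)
  pool_count <- stats::rbinom(n, config$n_H, p_pool)
  ## genotyped DH draw: n_dh_lines lines without replacement from the pool
  d_lines <- stats::rhyper(n, pool_count, config$n_H - pool_count,
                           config$n_dh_lines)
  n_dh <- config$n_dh_lines
  ## assign the d_lines carrier lines uniformly among the genotyped sample
  dh_dos <- matrix(0L, n_dh, n)
  for (j in seq_len(n)) {
    if (d_lines[j] > 0)
      dh_dos[sample.int(n_dh, d_lines[j]), j] <- 2L
  }
  dh <- genotype_matrix(sprintf("DH%03d", seq_len(n_dh)), sites, dh_dos)

  structure(list(lr = lr, dh = dh,
                 truth = data.frame(site_id = sites$id, p_anc = p_anc,
                                    s = s_vec, pool_count = pool_count,
                                    row.names = NULL)),
            class = "simulated_accession")
}

#' Simulate phased multi-SNP windows from founder haplotypes
#'
#' Each window carries `n_founders` random binary founder haplotypes with
#' Dirichlet-distributed frequencies; every LR individual draws two founders
#' independently, every DH line draws one. Windows span less than 50 kb with
#' inter-window gaps above 50 kb, so the physical 50 kb tiling recovers them.
#'
#' @param config A [sim_config()].
#' @return List of class `simulated_accession` with `lr`, `dh`, and
#'   `founders`: list per window of the founder haplotype matrix and
#'   frequencies.
#' @export
simulate_window_haplotypes <- function(config) {
  set.seed(config$seed)
  W <- config$n_windows; L <- config$snps_per_window; K <- config$n_founders
  n_lr <- config$n_lr_individuals; n_dh <- config$n_dh_lines
  ## window w occupies [w*100kb, w*100kb + 49kb): < 50 kb span, > 50 kb gaps
  pos <- as.integer(outer(seq(0, 49000, length.out = L), (seq_len(W)) * 100000L, `+`))
  sites <- data.frame(chrom = "1", pos = pos, ref = "A", alt = "T",
                      id = sprintf("w%03d_s%02d", rep(seq_len(W), each = L),
                                   rep(seq_len(L), W)),
                      stringsAsFactors = FALSE)
  h1 <- matrix(NA_integer_, n_lr, W * L)
  h2 <- matrix(NA_integer_, n_lr, W * L)
  dh_hap <- matrix(NA_integer_, n_dh, W * L)
  founders <- vector("list", W)
  for (w in seq_len(W)) {
    fh <- matrix(stats::rbinom(K * L, 1L, 0.5), K, L)
    g <- stats::rgamma(K, shape = config$dirichlet_conc)
    freq <- g / sum(g)
    cols <- (w - 1L) * L + seq_len(L)
    h1[, cols] <- fh[sample.int(K, n_lr, replace = TRUE, prob = freq), , drop = FALSE]
    h2[, cols] <- fh[sample.int(K, n_lr, replace = TRUE, prob = freq), , drop = FALSE]
    dh_hap[, cols] <- fh[sample.int(K, n_dh, replace = TRUE, prob = freq), , drop = FALSE]
    founders[[w]] <- list(haplotypes = fh, frequencies = freq)
  }
  lr <- genotype_matrix(sprintf("LR%03d", seq_len(n_lr)), sites, h1 + h2,
                        h1, h2, phased = TRUE)
  dh <- genotype_matrix(sprintf("DH%03d", seq_len(n_dh)), sites, 2L * dh_hap,
                        dh_hap, dh_hap, phased = TRUE)
  structure(list(lr = lr, dh = dh, founders = founders),
            class = "simulated_accession")
}

#' Write a simulated accession as a plain-text fixture set
#'
#' Emits LR and DH VCFs, a sample sheet, a linear genetic map, a GERP-like
#' conservation track (point mass at a negative score mixed with an
#' exponential positive tail) and, when available, the ground-truth table.
#'
#' @param sim A `simulated_accession` from [simulate_accession()] or
#'   [simulate_window_haplotypes()].
#' @param dir Output directory (created if absent).
#' @param accession Accession label used in the sample sheet.
#' @param config The [sim_config()] used (provides the map rate and seed).
#' @param gerp_positive_fraction Fraction of sites given a positive
#'   (exponential, mean 1) conservation score; the rest get -1.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_fixture_set <- function(sim, dir, accession = "ACC1", config = sim_config(),
                              gerp_positive_fraction = 0.5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(lr_vcf = file.path(dir, "lr.vcf"),
             dh_vcf = file.path(dir, "dh.vcf"),
             samples = file.path(dir, "samples.tsv"),
             map = file.path(dir, "map.tsv"),
             gerp = file.path(dir, "gerp.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genotype_vcf(sim$lr, paths[["lr_vcf"]])
  write_genotype_vcf(sim$dh, paths[["dh_vcf"]])
  sheet <- data.frame(sample = c(sim$lr$samples, sim$dh$samples),
                      accession = accession,
                      population = rep(c("LR", "DH"),
                                       c(length(sim$lr$samples),
                                         length(sim$dh$samples))))
  utils::write.table(sheet, paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sites <- sim$lr$sites
  map <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    cM = sites$pos / 1e6 * config$map_cm_per_mbp)
  utils::write.table(map, paths[["map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  set.seed(config$seed + 1L)
  n <- nrow(sites)
  pos_score <- stats::runif(n) < gerp_positive_fraction
  score <- ifelse(pos_score, stats::rexp(n, rate = 1), -1)
  gerp <- data.frame(chrom = sites$chrom, pos = sites$pos,
                     score = round(score, 6))
  utils::write.table(gerp, paths[["gerp"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sim$truth)) {
    utils::write.table(sim$truth[c("site_id", "p_anc", "s")], paths[["truth"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
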