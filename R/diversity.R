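#' Per-site nucleotide diversity
#'
#' Unbiased pairwise-difference estimator pi = 2 c (n - c) / (n (n - 1)):
#' the probability that two chromosomes drawn without replacement differ at
#' the site (the per-site convention of standard VCF diversity tools).
#'
#' @param c Alternative-allele count (vectorized).
#' @param n Genotyped chromosome count (vectorized, n >= 2).
#' @return Numeric vector of per-site pi in `[0, 1]`.
#' @export
site_pi <- function(c, n) {
  if (any(n < 2)) stop("site_pi requires at least two genotyped chromosomes")
  if (any(c < 0 | c > n)) stop("allele count outside [0, n]")
  2 * c * (n - c) / (n * (n - 1))
}

#' Compare per-site diversity between a landrace and its DH library
#'
#' Sites monomorphic across the pooled LR-DH pair are removed; per-site pi
#' is computed in each panel over the remaining sites and the two vectors
#' are compared with an unpaired two-sided Mann-Whitney-Wilcoxon test.
#'
#' @param lr,dh [genotype_matrix()] objects on a shared site space.
#' @return List with `pi` (data frame `site_id pi_lr pi_dh`), `mean_lr`,
#'   `mean_dh` and `p_value`.
#' @export
compare_pair_diversity <- function(lr, dh) {
  cnt <- site_counts(lr, dh)
  tot <- cnt$l + cnt$d
  n_tot <- cnt$n_L + cnt$n_D
  poly <- n_tot > 0 & tot > 0 & tot < n_tot & cnt$n_L >= 2 & cnt$n_D >= 2
  if (sum(poly) < 2)
    stop("fewer than two sites polymorphic within the pair")
  cnt <- cnt[poly, ]
  pi_lr <- site_pi(cnt$l, cnt$n_L)
  pi_dh <- site_pi(cnt$d, cnt$n_D)
  wt <- suppressWarnings(stats::wilcox.test(pi_lr, pi_dh,
                                            alternative = "two.sided",
                                            paired = FALSE))
  list(pi = data.frame(site_id = cnt$site_id, pi_lr = pi_lr, pi_dh = pi_dh,
                       row.names = NULL),
       mean_lr = mean(pi_lr), mean_dh = mean(pi_dh),
       p_value = wt$p.value)
}

#' Joint site frequency spectrum of an LR-DH pair
#'
#' Bins each site by its (LR, DH) alternative-allele frequency pair. Bins
#' are half-open `[a, b)` except the last, which is closed.
#'
#' @param counts Data frame from [site_counts()].
#' @param n_bins Frequency bins per axis (default 25).
#' @return List of class `joint_sfs` with `table` (n_bins x n_bins count
#'   matrix, LR rows x DH columns), `breaks`, and `n_skipped` (sites with no
#'   genotyped chromosome in one panel).
#' @export
joint_sfs <- function(counts, n_bins = 25) {
  ok <- counts$n_L > 0 & counts$n_D > 0
  n_skipped <- sum(!ok)
  f_lr <- counts$l[ok] / counts$n_L[ok]
  f_dh <- counts$d[ok] / counts$n_D[ok]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(f) pmin(findInterval(f, breaks, rightmost.closed = TRUE),
                          n_bins)
  tab <- matrix(0L, n_bins, n_bins,
                dimnames = list(lr = sprintf("[%.3f,%.3f)", breaks[-(n_bins + 1)],
                                             breaks[-1]),
                                dh = sprintf("[%.3f,%.3f)", breaks[-(n_bins + 1)],
                                             breaks[-1])))
  for (k in seq_along(f_lr)) {
    i <- bin(f_lr[k]); j <- bin(f_dh[k])
    tab[i, j] <- tab[i, j] + 1L
  }
  structure(list(table = tab, breaks = breaks, n_skipped = n_skipped),
            class = "joint_sfs")
}

#' Per-site genotype frequencies in a diploid panel
#'
#' @param gm A diploid [genotype_matrix()].
#' @return Data frame `site_id n f_hom_ref f_het f_hom_alt` over non-missing
#'   genotypes; frequencies are `NA` (undefined) for all-missing sites.
#' @export
genotype_frequencies <- function(gm) {
  dos <- gm$dosage
  n <- colSums(!is.na(dos))
  f0 <- colSums(dos == 0L, na.rm = TRUE) / n
  f1 <- colSums(dos == 1L, na.rm = TRUE) / n
  f2 <- colSums(dos == 2L, na.rm = TRUE) / n
  f0[n == 0] <- f1[n == 0] <- f2[n == 0] <- NA_real_
  data.frame(site_id = gm$sites$id, n = n,
             f_hom_ref = f0, f_het = f1, f_hom_alt = f2, row.names = NULL)
}
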