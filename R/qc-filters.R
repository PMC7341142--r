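#' Harmonize allele coding to the pooled minor allele
#'
#' Across a list of panels sharing a site space, the minor allele of the
#' pooled sample is defined as the alternative allele; sites where the pooled
#' ALT frequency exceeds 0.5 have their coding flipped (ref/alt swapped,
#' dosages recoded x -> 2 - x, haplotypes complemented). A pooled frequency
#' of exactly 0.5 keeps the input coding.
#'
#' @param panels List of [genotype_matrix()] objects with identical site ids
#'   and ref/alt pairs.
#' @return List of panels with harmonized coding (same order as input), with
#'   an attribute `flipped`: logical vector over sites.
#' @export
define_alternative_allele <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 1)
  ids <- panels[[1]]$sites$id
  for (p in panels[-1]) {
    if (!identical(p$sites$id, ids)) stop("panels must share site ids")
    same <- p$sites$ref == panels[[1]]$sites$ref &
      p$sites$alt == panels[[1]]$sites$alt
    if (!all(same))
      stop("mismatched ref/alt pair at site(s): ",
           paste(utils::head(ids[!same], 5), collapse = ", "))
  }
  alt <- Reduce(`+`, lapply(panels, function(p) colSums(p$dosage, na.rm = TRUE)))
  n <- Reduce(`+`, lapply(panels, function(p) 2L * colSums(!is.na(p$dosage))))
  freq <- alt / n
  flip <- !is.na(freq) & freq > 0.5
  out <- lapply(panels, function(p) {
    if (!any(flip)) return(p)
    s <- p$sites
    tmp <- s$ref[flip]; s$ref[flip] <- s$alt[flip]; s$alt[flip] <- tmp
    dos <- p$dosage
    dos[, flip] <- 2L - dos[, flip]
    h1 <- p$hap1; h2 <- p$hap2
    if (!is.null(h1)) {
      h1[, flip] <- 1L - h1[, flip]
      h2[, flip] <- 1L - h2[, flip]
    }
    genotype_matrix(p$samples, s, dos, h1, h2, phased = p$phased)
  })
  attr(out, "flipped") <- flip
  out
}

#' Mask residual heterozygous calls in a DH panel
#'
#' Doubled-haploid lines are fully homozygous; residual heterozygous calls
#' are genotyping artifacts and are set to missing.
#'
#' @param gm A DH [genotype_matrix()].
#' @return List with `gm` (masked matrix) and `n_masked` (cells changed).
#' @export
mask_dh_heterozygotes <- function(gm) {
  het <- !is.na(gm$dosage) & gm$dosage == 1L
  n <- sum(het)
  if (n > 0) {
    dos <- gm$dosage
    dos[het] <- NA
    h1 <- gm$hap1; h2 <- gm$hap2
    if (!is.null(h1)) { h1[het] <- NA; h2[het] <- NA }
    gm <- genotype_matrix(gm$samples, gm$sites, dos, h1, h2, phased = gm$phased)
  }
  list(gm = gm, n_masked = n)
}

#' Remove sites monomorphic across all panels
#'
#' A site is removed iff exactly one allele is observed across all
#' non-missing genotypes of all panels pooled together; all-missing sites
#' are also removed.
#'
#' @param panels List of [genotype_matrix()] with harmonized site ids.
#' @return List of panels restricted to polymorphic sites, with attribute
#'   `removed`: character vector of removed site ids.
#' @export
filter_monomorphic <- function(panels) {
  alt <- Reduce(`+`, lapply(panels, function(p) colSums(p$dosage, na.rm = TRUE)))
  n <- Reduce(`+`, lapply(panels, function(p) 2L * colSums(!is.na(p$dosage))))
  poly <- n > 0 & alt > 0 & alt < n
  out <- lapply(panels, subset_sites, keep = poly)
  attr(out, "removed") <- panels[[1]]$sites$id[!poly]
  out
}

#' Exact Hardy-Weinberg test with mid-p correction
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count and ranks configurations by their conditional
#' probability (two-sided). The mid-p value is the probability of
#' configurations strictly more extreme (less probable) than the observed
#' one, plus half the probability of configurations exactly as probable.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (hom-ref, het, hom-alt).
#' @return Mid-p value in (0, 1].
#' @export
hwe_exact_midp <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual is required")
  nA <- 2L * n_AA + n_Aa
  ## feasible het counts share the parity of the minor-allele count
  n_min <- min(nA, 2L * n - nA)
  hets <- seq.int(n_min %% 2L, n_min, by = 2L)
  ## P(h | n, nA) = n! 2^h / (hAA! h! haa!) / C(2n, nA) (conditional exact HWE)
  logp <- lgamma(n + 1) + hets * log(2) -
    lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - nA - hets) / 2 + 1) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  if (is.na(obs)) stop("observed heterozygote count incompatible with allele counts")
  tol <- 1e-12 * obs
  sum(p[p < obs - tol]) + 0.5 * sum(p[abs(p - obs) <= tol])
}

#' Remove sites violating Hardy-Weinberg equilibrium in every LR accession
#'
#' A site is removed iff the exact mid-p value falls below `alpha` in every
#' landrace accession where the site has at least one genotyped individual.
#'
#' @param lr_panels Named list of landrace [genotype_matrix()] objects, one
#'   per accession, sharing site ids.
#' @param alpha Violation threshold (default 0.05).
#' @return List with `remove` (site ids to drop) and `midp` (sites x
#'   accessions matrix of mid-p values, `NA` where no data).
#' @export
filter_hwe <- function(lr_panels, alpha = 0.05) {
  ids <- lr_panels[[1]]$sites$id
  midp <- sapply(lr_panels, function(p) {
    if (!identical(p$sites$id, ids)) stop("panels must share site ids")
    dos <- p$dosage
    nAA <- colSums(dos == 0L, na.rm = TRUE)
    nAa <- colSums(dos == 1L, na.rm = TRUE)
    naa <- colSums(dos == 2L, na.rm = TRUE)
    vapply(seq_along(ids), function(j) {
      if (nAA[j] + nAa[j] + naa[j] == 0L) return(NA_real_)
      hwe_exact_midp(nAA[j], nAa[j], naa[j])
    }, numeric(1))
  })
  midp <- matrix(midp, nrow = length(ids),
                 dimnames = list(ids, names(lr_panels)))
  violated <- !is.na(midp) & midp < alpha
  informative <- !is.na(midp)
  drop <- rowSums(informative) > 0 & rowSums(violated) == rowSums(informative)
  list(remove = ids[drop], midp = midp)
}

#' Remove sites with excessive missingness
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Sites with a missing-genotype fraction strictly above
#'   this threshold are removed (default 0.99, i.e. only all-missing or
#'   near-all-missing sites go).
#' @return Filtered `genotype_matrix`.
#' @export
filter_missingness <- function(gm, max_missing = 0.99) {
  frac <- colMeans(is.na(gm$dosage))
  subset_sites(gm, frac <= max_missing)
}

#' Remove sites on an exclusion list
#'
#' Chip-specific quality exclusions (off-target variants, low call rate,
#' insertion-type probes) are supplied as a generic site list.
#'
#' @param gm A [genotype_matrix()].
#' @param exclude Character vector of site ids, or a data frame with a
#'   `site_id` column.
#' @return Filtered `genotype_matrix`.
#' @export
filter_excluded <- function(gm, exclude) {
  if (is.data.frame(exclude)) exclude <- exclude$site_id
  subset_sites(gm, !(gm$sites$id %in% exclude))
}

#' Intersect two panels on physical position
#'
#' Sites are matched on (chromosome, position). A ref/alt pair swapped
#' between panels is accepted and panel `b` is recoded (dosage x -> 2 - x);
#' incompatible allele pairs at a shared position are dropped with a warning.
#'
#' @param a,b [genotype_matrix()] objects sorted by (chrom, pos).
#' @return List with `a` and `b` restricted and harmonized to the common
#'   sites (ordered as in `a`), and `dropped`: data frame of incompatible
#'   positions.
#' @export
intersect_panels <- function(a, b) {
  key_a <- paste(a$sites$chrom, a$sites$pos, sep = ":")
  key_b <- paste(b$sites$chrom, b$sites$pos, sep = ":")
  ia <- which(key_a %in% key_b)
  ib <- match(key_a[ia], key_b)
  ra <- a$sites$ref[ia]; aa <- a$sites$alt[ia]
  rb <- b$sites$ref[ib]; ab <- b$sites$alt[ib]
  same <- ra == rb & aa == ab
  swap <- ra == ab & aa == rb & !same
  ok <- same | swap
  dropped <- data.frame(chrom = a$sites$chrom[ia[!ok]],
                        pos = a$sites$pos[ia[!ok]],
                        stringsAsFactors = FALSE)
  if (nrow(dropped))
    warning(nrow(dropped), " shared position(s) with incompatible alleles dropped")
  ia <- ia[ok]; ib <- ib[ok]; swap <- swap[ok]
  a2 <- subset_sites(a, ia)
  b2 <- subset_sites(b, ib)
  ## force b onto a's site ids so downstream code can align panels
  b2$sites$id <- a2$sites$id
  colnames(b2$dosage) <- a2$sites$id
  if (any(swap)) {
    s <- b2$sites
    tmp <- s$ref[swap]; s$ref[swap] <- s$alt[swap]; s$alt[swap] <- tmp
    dos <- b2$dosage
    dos[, swap] <- 2L - dos[, swap]
    h1 <- b2$hap1; h2 <- b2$hap2
    if (!is.null(h1)) {
      h1[, swap] <- 1L - h1[, swap]
      h2[, swap] <- 1L - h2[, swap]
    }
    b2 <- genotype_matrix(b2$samples, s, dos, h1, h2, phased = b2$phased)
  }
  list(a = a2, b = b2, dropped = dropped)
}

#' Imputation error rate at masked sites
#'
#' For each masked site, E = 1 - z / (k - m) with z the number of imputed
#' genotypes matching the truth, k the number of individuals and m the
#' number of genotypes missing in the imputed panel. Sites where every
#' genotype is missing (k = m) are excluded from the mean.
#'
#' @param truth,imputed [genotype_matrix()] objects on identical sample and
#'   site spaces.
#' @param masked_sites Character vector of site ids whose truth was hidden
#'   before imputation.
#' @return List with `per_site` (data frame `site_id z k m E`) and `mean_E`.
#' @export
imputation_error_rate <- function(truth, imputed, masked_sites) {
  if (!identical(truth$sites$id, imputed$sites$id) ||
      !identical(truth$samples, imputed$samples))
    stop("truth and imputed matrices must share samples and sites")
  j <- match(masked_sites, truth$sites$id)
  if (anyNA(j))
    stop("masked site(s) absent from the panels: ",
         paste(masked_sites[is.na(j)], collapse = ", "))
  k <- length(truth$samples)
  tv <- truth$dosage[, j, drop = FALSE]
  iv <- imputed$dosage[, j, drop = FALSE]
  m <- colSums(is.na(iv))
  z <- colSums(!is.na(iv) & !is.na(tv) & iv == tv)
  E <- ifelse(k > m, 1 - z / (k - m), NA_real_)
  per_site <- data.frame(site_id = masked_sites, z = z, k = k, m = m, E = E,
                         row.names = NULL)
  list(per_site = per_site, mean_E = mean(E, na.rm = TRUE))
}
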