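#' Read a genetic map
#'
#' @param path TSV with header `chrom pos cM`; cM must be non-decreasing in
#'   position within each chromosome, with at least two anchors per
#'   chromosome.
#' @return Data frame of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "cM") %in% names(map)))
    stop("genetic map must have columns: chrom pos cM")
  map$chrom <- as.character(map$chrom)
  map <- map[order(map$chrom, map$pos), c("chrom", "pos", "cM")]
  bad <- unlist(tapply(map$cM, map$chrom, function(x) any(diff(x) < 0)))
  if (any(bad)) stop("cM must be non-decreasing within each chromosome")
  few <- names(which(table(map$chrom) < 2))
  if (length(few)) stop("need >= 2 map anchors on chromosome(s): ",
                        paste(few, collapse = ", "))
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Interpolate genetic positions
#'
#' Linear interpolation between map anchors; constant extrapolation outside
#' the anchored range.
#'
#' @param map A [read_genetic_map()] data frame.
#' @param chrom,pos Vectors of physical coordinates.
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    anchors <- map[map$chrom == ch, ]
    if (nrow(anchors) == 0) stop("chromosome absent from genetic map: ", ch)
    out[idx] <- stats::approx(anchors$pos, anchors$cM, xout = pos[idx],
                              rule = 2, ties = "ordered")$y
  }
  out
}

#' Tile sites into non-overlapping physical windows
#'
#' Half-open tiles `[k w, (k+1) w)` anchored at coordinate 0 on each
#' chromosome; empty tiles are omitted, and every SNP falls in exactly one
#' window.
#'
#' @param sites Site data frame (columns `chrom`, `pos`, `id`), sorted.
#' @param window_size Window width in bp (default 50000).
#' @return Data frame `chrom window start end n_snps` plus a list column
#'   `site_idx` of integer indices into `sites`.
#' @export
make_physical_windows <- function(sites, window_size = 50000) {
  idx <- floor(sites$pos / window_size)
  key <- paste(sites$chrom, idx, sep = "@")
  groups <- split(seq_len(nrow(sites)), factor(key, levels = unique(key)))
  first <- vapply(groups, `[`, integer(1), 1)
  data.frame(chrom = sites$chrom[first],
             window = idx[first],
             start = idx[first] * window_size,
             end = (idx[first] + 1) * window_size,
             n_snps = lengths(groups),
             site_idx = I(unname(groups)),
             row.names = NULL)
}

#' Tile sites into non-overlapping genetic-distance windows
#'
#' Each SNP's cM position is obtained by linear interpolation on the map;
#' tiles `[k w, (k+1) w)` cM anchored at 0 per chromosome.
#'
#' @param sites Site data frame.
#' @param map A [read_genetic_map()] data frame covering the sites.
#' @param window_cm Window width in cM (default 0.2).
#' @return As [make_physical_windows()], with `start`/`end` in cM.
#' @export
make_genetic_windows <- function(sites, map, window_cm = 0.2) {
  cm <- interpolate_cm(map, sites$chrom, sites$pos)
  idx <- floor(cm / window_cm)
  key <- paste(sites$chrom, idx, sep = "@")
  groups <- split(seq_len(nrow(sites)), factor(key, levels = unique(key)))
  first <- vapply(groups, `[`, integer(1), 1)
  data.frame(chrom = sites$chrom[first],
             window = idx[first],
             start = idx[first] * window_cm,
             end = (idx[first] + 1) * window_cm,
             n_snps = lengths(groups),
             site_idx = I(unname(groups)),
             row.names = NULL)
}

#' Drop windows with too few SNPs
#'
#' Used for dense-array windows (windows with <= `min_snps - 1` SNPs are
#' removed); disable for sparse panels where short haplotypes are kept.
#'
#' @param windows Window data frame from a `make_*_windows()` call.
#' @param min_snps Minimum SNP count to keep a window (default 6, i.e.
#'   windows with 5 or fewer SNPs go).
#' @param enabled Set `FALSE` to make the filter a no-op.
#' @return Filtered window data frame.
#' @export
filter_sparse_windows <- function(windows, min_snps = 6, enabled = TRUE) {
  if (!enabled) return(windows)
  windows[windows$n_snps >= min_snps, , drop = FALSE]
}

## haplotype strings for a site index set: LR individuals contribute two
## strings, DH lines one (their chromosomes are identical); strings with any
## missing allele are dropped
hap_strings <- function(gm, site_idx, per_line_one = FALSE) {
  if (per_line_one) {
    al <- gm$dosage[, site_idx, drop = FALSE] / 2L
    strs <- apply(al, 1, paste, collapse = "")
    keep <- !apply(is.na(al), 1, any) & apply(al == floor(al), 1, all)
    strs[keep]
  } else {
    if (is.null(gm$hap1)) stop("phased haplotypes required")
    h1 <- gm$hap1[, site_idx, drop = FALSE]
    h2 <- gm$hap2[, site_idx, drop = FALSE]
    s1 <- apply(h1, 1, paste, collapse = "")
    s2 <- apply(h2, 1, paste, collapse = "")
    k1 <- !apply(is.na(h1), 1, any)
    k2 <- !apply(is.na(h2), 1, any)
    c(s1[k1], s2[k2])
  }
}

#' Enumerate window haplotypes in an LR-DH pair
#'
#' Each LR individual contributes two haplotype strings (phase required),
#' each DH line one (its two chromosomes are identical). Strings containing
#' any missing allele are excluded.
#'
#' @param lr Phased LR [genotype_matrix()].
#' @param dh Homozygous DH [genotype_matrix()].
#' @param site_idx Integer indices of the window's sites.
#' @return List with `table` (data frame `haplotype n_lr n_dh`), `N_lr`,
#'   `N_dh` (retained string counts) and `empty` flag.
#' @export
enumerate_haplotypes <- function(lr, dh, site_idx) {
  s_lr <- hap_strings(lr, site_idx, per_line_one = FALSE)
  s_dh <- hap_strings(dh, site_idx, per_line_one = TRUE)
  haps <- sort(unique(c(s_lr, s_dh)))
  tab <- data.frame(haplotype = haps,
                    n_lr = as.integer(table(factor(s_lr, levels = haps))),
                    n_dh = as.integer(table(factor(s_dh, levels = haps))),
                    row.names = NULL)
  list(table = tab, N_lr = length(s_lr), N_dh = length(s_dh),
       empty = length(s_lr) + length(s_dh) == 0)
}

#' Nei's haplotype diversity
#'
#' H = N/(N-1) (1 - sum x_i^2) with x_i the haplotype frequencies and N the
#' number of sampled haplotypes.
#'
#' @param counts Integer haplotype counts.
#' @param N Sample size (defaults to `sum(counts)`).
#' @return H in `[0, 1]`.
#' @export
haplotype_diversity <- function(counts, N = sum(counts)) {
  if (N < 2) stop("haplotype diversity requires N >= 2")
  x <- counts / N
  N / (N - 1) * (1 - sum(x^2))
}

#' Fate of the major LR haplotype in the DH population
#'
#' The most abundant LR haplotype (ties broken to the lexicographically
#' smallest string) is classified by its DH frequency: `lost` (absent),
#' `fixed` (frequency 1 among retained DH strings) or `segregating`.
#'
#' @param hap_table Data frame `haplotype n_lr n_dh` from
#'   [enumerate_haplotypes()].
#' @return List with `major` (the haplotype string) and `fate`; fate is `NA`
#'   when the DH table is empty.
#' @export
major_haplotype_fate <- function(hap_table) {
  with_lr <- hap_table[hap_table$n_lr > 0, , drop = FALSE]
  if (nrow(with_lr) == 0) stop("no LR haplotype observed in window")
  best <- with_lr[with_lr$n_lr == max(with_lr$n_lr), , drop = FALSE]
  major <- sort(best$haplotype)[1]
  N_dh <- sum(hap_table$n_dh)
  if (N_dh == 0) return(list(major = major, fate = NA_character_))
  d <- hap_table$n_dh[hap_table$haplotype == major]
  fate <- if (d == 0) "lost" else if (d == N_dh) "fixed" else "segregating"
  list(major = major, fate = fate)
}

#' Haplotype-window analysis of an LR-DH pair
#'
#' Enumerates haplotypes per window, computes Nei's diversity in both
#' populations and classifies the major LR haplotype's fate.
#'
#' @param lr,dh [genotype_matrix()] objects on a shared site space.
#' @param windows Window data frame from [make_physical_windows()] or
#'   [make_genetic_windows()] (optionally filtered).
#' @return Data frame `chrom start end n_snps n_hap_lr n_hap_dh N_lr N_dh
#'   H_lr H_dh major_fate` (H is `NA` where a population has < 2 retained
#'   strings; windows with no retained strings are dropped).
#' @export
haplotype_window_analysis <- function(lr, dh, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(w) {
    hp <- enumerate_haplotypes(lr, dh, windows$site_idx[[w]])
    if (hp$empty) return(NULL)
    tab <- hp$table
    H_lr <- if (hp$N_lr >= 2) haplotype_diversity(tab$n_lr, hp$N_lr) else NA_real_
    H_dh <- if (hp$N_dh >= 2) haplotype_diversity(tab$n_dh, hp$N_dh) else NA_real_
    fate <- if (hp$N_lr > 0) major_haplotype_fate(tab)$fate else NA_character_
    data.frame(chrom = windows$chrom[w], start = windows$start[w],
               end = windows$end[w], n_snps = windows$n_snps[w],
               n_hap_lr = sum(tab$n_lr > 0), n_hap_dh = sum(tab$n_dh > 0),
               N_lr = hp$N_lr, N_dh = hp$N_dh,
               H_lr = H_lr, H_dh = H_dh, major_fate = fate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genome-wide haplotype fate and diversity summary
#'
#' @param window_stats Data frame from [haplotype_window_analysis()].
#' @return List with `fates` (proportions of lost/fixed/segregating major
#'   haplotypes over classified windows; they sum to 1) and `mean_H_lr`,
#'   `mean_H_dh` (means over windows with >= 2 LR haplotypes).
#' @export
summarize_fates <- function(window_stats) {
  cls <- window_stats$major_fate[!is.na(window_stats$major_fate)]
  if (length(cls) == 0) stop("no classified window")
  fates <- c(lost = mean(cls == "lost"), fixed = mean(cls == "fixed"),
             segregating = mean(cls == "segregating"))
  div <- window_stats[window_stats$n_hap_lr >= 2, , drop = FALSE]
  list(fates = fates,
       mean_H_lr = mean(div$H_lr, na.rm = TRUE),
       mean_H_dh = mean(div$H_dh, na.rm = TRUE))
}
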