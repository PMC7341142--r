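#' Run the full landrace/DH analysis for one accession pair
#'
#' Chains the pipeline stages on one LR-DH accession pair: DH heterozygote
#' masking, pooled minor-allele harmonization, monomorphic / Hardy-Weinberg
#' / missingness filters, per-site diversity comparison, joint SFS, both
#' allele-frequency outlier tests with fates, haplotype windows, and (when
#' a map and GERP track are supplied) heterozygosity enrichment and genetic
#' load comparisons. All randomness flows from `seed`; outputs are plain
#' TSVs whose bytes are reproducible for a fixed input and seed.
#'
#' @param lr,dh [genotype_matrix()] objects or VCF paths.
#' @param sheet Optional sample sheet (data frame or path) used to check
#'   VCF samples.
#' @param map Optional genetic map (data frame or path); enables
#'   genetic-distance windows and load analysis.
#' @param gerp Optional GERP track (`chrom pos score` data frame or path).
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @param config A [model_config()].
#' @param window_size Physical haplotype window width in bp.
#' @param hwe_alpha,max_missing QC thresholds.
#' @param n_boot Bootstrap replicates for the heterozygosity comparison.
#' @param seed Integer seed.
#' @return List of result tables (counts, diversity, asfs, jointprob,
#'   fates, haplotypes, enrichment, load), invisibly when writing.
#' @export
run_dh_pipeline <- function(lr, dh, sheet = NULL, map = NULL, gerp = NULL,
                            out_dir = NULL, config = model_config(),
                            window_size = 50000, hwe_alpha = 0.05,
                            max_missing = 0.99, n_boot = 1000, seed = 1) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(lr)) lr <- read_genotypes(lr, sheet)
  if (is.character(dh)) dh <- read_genotypes(dh, sheet)
  if (is.character(map)) map <- read_genetic_map(map)
  if (is.character(gerp)) gerp <- utils::read.delim(gerp)

  dh <- mask_dh_heterozygotes(dh)$gm
  pans <- define_alternative_allele(list(lr, dh))
  pans <- filter_monomorphic(pans)
  lr <- pans[[1]]; dh <- pans[[2]]
  hwe <- filter_hwe(list(acc = lr), alpha = hwe_alpha)
  keep <- !(lr$sites$id %in% hwe$remove)
  lr <- subset_sites(lr, keep); dh <- subset_sites(dh, keep)
  lr <- filter_missingness(lr, max_missing)
  dh <- subset_sites(dh, lr$sites$id)
  dh <- filter_missingness(dh, max_missing)
  lr <- subset_sites(lr, dh$sites$id)

  counts <- site_counts(lr, dh)
  div <- compare_pair_diversity(lr, dh)
  jsfs <- joint_sfs(counts)

  asfs <- asfs_classify(counts, config)
  jp <- joint_probability(counts$l, counts$n_L, counts$d, counts$n_D, config)
  jp$site_id <- counts$site_id
  jp$outlier <- as.logical(flag_joint_outliers(jp$neg_log10_P,
                                               config$outlier_fraction))
  asfs_out <- asfs$class != "inside"
  fates <- data.frame(site_id = counts$site_id,
                      asfs_fate = outlier_fate(counts, asfs_out),
                      joint_fate = outlier_fate(counts, jp$outlier))

  windows <- if (!is.null(map)) {
    make_genetic_windows(lr$sites, map)
  } else {
    make_physical_windows(lr$sites, window_size)
  }
  haps <- haplotype_window_analysis(lr, dh, windows)

  ## heterozygosity enrichment of aSFS outliers vs ancestral-frequency
  ## matched, LD-pruned controls
  enrich <- NULL
  het <- genotype_frequencies(lr)
  out_ids <- counts$site_id[asfs_out]
  pool_ids <- counts$site_id[!asfs_out]
  if (length(out_ids) >= 2 && length(pool_ids) >= 2) {
    pruned <- prune_ld(lr, pool_ids)
    p_hat <- stats::setNames(asfs$p_anc_hat, asfs$site_id)
    fm <- frequency_match_sample(p_hat[out_ids], p_hat[pruned], seed = seed)
    if (length(fm$controls) >= 2) {
      hv <- stats::setNames(het$f_het, het$site_id)
      he <- heterozygosity_enrichment(hv[out_ids], hv[fm$controls],
                                      n_boot = n_boot, seed = seed)
      enrich <- data.frame(group = c("outlier", "control"),
                           n_snps = c(length(out_ids), length(fm$controls)),
                           mean_het = c(he$mean_outliers, he$mean_controls),
                           boot_p = he$p_value)
    }
  }

  ## GERP load around outliers vs stratified controls
  load_tab <- NULL
  if (!is.null(map) && !is.null(gerp) && length(out_ids) >= 2) {
    rr <- recombination_rates(map, lr$sites)
    p_hat <- stats::setNames(asfs$p_anc_hat, asfs$site_id)
    sc <- stratified_control_sample(p_hat[out_ids], p_hat[pool_ids],
                                    rr$snp_quantile, seed = seed)
    if (length(sc$controls) >= 2) {
      rows <- list()
      for (popname in c("LR", "DH")) {
        gmp <- if (popname == "LR") lr else dh
        for (mod in c("additive", "recessive")) {
          lo <- vapply(out_ids, function(id)
            gerp_window_load(id, gmp, gerp, map, mod)$mean_load, numeric(1))
          lc <- vapply(sc$controls, function(id)
            gerp_window_load(id, gmp, gerp, map, mod)$mean_load, numeric(1))
          cmp <- compare_load(lo, lc)
          rows[[length(rows) + 1]] <-
            data.frame(population = popname, model = mod,
                       mean_outliers = cmp$mean_outliers,
                       mean_controls = cmp$mean_controls,
                       t_p = cmp$p_value)
        }
      }
      load_tab <- do.call(rbind, rows)
    }
  }

  res <- list(counts = counts,
              site_pi = div$pi, pi_p_value = div$p_value,
              jsfs = jsfs, asfs = asfs, jointprob = jp,
              fates = fates, haplotypes = haps,
              het_enrichment = enrich, load = load_tab)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    wt(div$pi, "site_pi.tsv")
    jt <- as.data.frame(as.table(jsfs$table), stringsAsFactors = FALSE)
    names(jt) <- c("lr_bin", "dh_bin", "count")
    wt(jt, "jsfs.tsv")
    wt(asfs, "asfs.tsv")
    wt(jp[c("site_id", "P", "neg_log10_P", "outlier")], "jointprob.tsv")
    wt(fates, "fates.tsv")
    wt(haps, "haplotypes.tsv")
    if (!is.null(enrich)) wt(enrich, "het_enrichment.tsv")
    if (!is.null(load_tab)) wt(load_tab, "load.tsv")
    return(invisible(res))
  }
  res
}
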