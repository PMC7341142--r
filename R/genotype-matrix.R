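#' Genotype matrix container
#'
#' The universal carrier between pipeline stages: a samples x sites table of
#' alternative-allele dosages (0, 1, 2 or `NA` for missing), site metadata,
#' and optionally the two phased haplotypes per sample.
#'
#' @param samples Character vector of sample identifiers.
#' @param sites Data frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, `id`; site ids must be unique and positions strictly increasing
#'   within each chromosome.
#' @param dosage Integer matrix (samples x sites) of alternative-allele
#'   counts in `{0, 1, 2, NA}`.
#' @param hap1,hap2 Optional integer matrices (samples x sites) of alleles in
#'   `{0, 1, NA}`; wherever both are present their sum must equal the dosage.
#' @param phased Logical scalar: whether haplotype phase is meaningful for
#'   heterozygous genotypes.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, sites, dosage, hap1 = NULL, hap2 = NULL,
                            phased = !is.null(hap1)) {
  samples <- as.character(samples)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "id") %in% names(sites)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$id <- as.character(sites$id)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(sites))
    stop("dosage must be a ", length(samples), " x ", nrow(sites), " matrix")
  dimnames(dosage) <- list(samples, sites$id)
  if (anyDuplicated(sites$id))
    stop("duplicated site ids: ",
         paste(unique(sites$id[duplicated(sites$id)]), collapse = ", "))
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) diff(p) <= 0))))
    stop("positions must strictly increase within each chromosome")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(hap1)) {
    hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
    storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
    stopifnot(all(dim(hap1) == dim(dosage)), all(dim(hap2) == dim(dosage)))
    dimnames(hap1) <- dimnames(hap2) <- dimnames(dosage)
    both <- !is.na(hap1) & !is.na(hap2)
    if (any(both & (hap1 + hap2 != dosage), na.rm = TRUE))
      stop("hap1 + hap2 must equal dosage wherever both haplotypes are present")
  }
  structure(list(samples = samples, sites = sites, dosage = dosage,
                 hap1 = hap1, hap2 = hap2, phased = isTRUE(phased)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      nrow(x$sites), " sites",
      if (x$phased) " (phased)" else "", "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "),
      "; missing: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Number of sites / samples in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer scalar.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site
#'
#' @param gm A [genotype_matrix()].
#' @param keep Logical or integer index over sites, or a character vector of
#'   site ids.
#' @return A `genotype_matrix` restricted to the kept sites, in input order.
#' @export
subset_sites <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$sites$id)
  if (anyNA(keep)) stop("unknown site id in subset")
  genotype_matrix(gm$samples, gm$sites[keep, , drop = FALSE],
                  gm$dosage[, keep, drop = FALSE],
                  if (!is.null(gm$hap1)) gm$hap1[, keep, drop = FALSE],
                  if (!is.null(gm$hap2)) gm$hap2[, keep, drop = FALSE],
                  phased = gm$phased)
}

#' Subset a genotype matrix by sample
#' @param gm A [genotype_matrix()].
#' @param keep Logical/integer index over samples or sample names.
#' @return A `genotype_matrix` restricted to the kept samples.
#' @export
subset_samples <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$samples)
  if (anyNA(keep)) stop("unknown sample in subset")
  genotype_matrix(gm$samples[keep], gm$sites,
                  gm$dosage[keep, , drop = FALSE],
                  if (!is.null(gm$hap1)) gm$hap1[keep, , drop = FALSE],
                  if (!is.null(gm$hap2)) gm$hap2[keep, , drop = FALSE],
                  phased = gm$phased)
}

#' Per-site alternative-allele frequency
#'
#' Frequencies are computed over non-missing genotypes only.
#'
#' @param gm A [genotype_matrix()].
#' @return Numeric vector, one frequency per site (`NaN` for all-missing
#'   sites), named by site id.
#' @export
alt_frequency <- function(gm) {
  n <- 2L * colSums(!is.na(gm$dosage))
  colSums(gm$dosage, na.rm = TRUE) / n
}

#' Per-site sufficient statistics for a landrace/DH accession pair
#'
#' Counts the alternative allele and the genotyped chromosomes per site in
#' the landrace (LR) and doubled-haploid (DH) panels; these four numbers
#' (l, n_L, d, n_D) are the sufficient statistics consumed by the outlier
#' tests. Missing genotypes are excluded from both numerator and denominator.
#'
#' @param lr,dh [genotype_matrix()] objects on the same site space.
#' @return Data frame with columns `site_id`, `l`, `n_L`, `d`, `n_D`.
#' @export
site_counts <- function(lr, dh) {
  if (!identical(lr$sites$id, dh$sites$id))
    stop("LR and DH panels must share an identical site space")
  data.frame(site_id = lr$sites$id,
             l = colSums(lr$dosage, na.rm = TRUE),
             n_L = 2L * colSums(!is.na(lr$dosage)),
             d = colSums(dh$dosage, na.rm = TRUE),
             n_D = 2L * colSums(!is.na(dh$dosage)),
             row.names = NULL)
}

#' Read a sample sheet
#'
#' @param path TSV file with header `sample accession population`;
#'   `population` must be `LR` or `DH`.
#' @return Data frame with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("sample", "accession", "population")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(sheet$population), c("LR", "DH"))
  if (length(bad)) stop("unknown population label(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(sheet$sample))
    stop("duplicated sample id(s) in sheet: ",
         paste(unique(sheet$sample[duplicated(sheet$sample)]), collapse = ", "))
  sheet[need]
}

#' Read a biallelic-SNP VCF into a genotype matrix
#'
#' Multiallelic records and indels are rejected; every sample in the VCF must
#' appear in the sample sheet. Dosages encode counts of the ALT allele; phase
#' is retained where the VCF encodes it (`|` separator). Sites are sorted by
#' (chromosome, position).
#'
#' @param path VCF file (plain or bgzipped).
#' @param sheet Sample sheet data frame from [read_sample_sheet()], or `NULL`
#'   to skip the sample check.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, sheet = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  bad <- grepl(",", fix$ALT) | is.na(fix$ALT) |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(bad)) {
    w <- which(bad)[1]
    stop("multiallelic or non-SNP record at ", fix$CHROM[w], ":", fix$POS[w])
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no genotype (GT) data")
  samples <- colnames(gt)
  if (!is.null(sheet)) {
    unknown <- setdiff(samples, sheet$sample)
    if (length(unknown))
      stop("sample(s) not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  id <- fix$ID
  blank <- is.na(id) | id == "." | id == ""
  id[blank] <- paste0(fix$CHROM[blank], "_", fix$POS[blank])
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, id = id,
                      stringsAsFactors = FALSE)

  ## decode GT strings through a lookup over the distinct values present
  codes <- unique(as.vector(gt))
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA, NA, NA, 0L))
    phased <- grepl("|", g, fixed = TRUE)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L) stop("non-diploid genotype '", g, "'")
    a <- suppressWarnings(as.integer(al))
    a[al == "."] <- NA
    if (any(!is.na(a) & a > 1L)) stop("allele index >1 in genotype '", g, "'")
    c(a[1], a[2], sum(a), as.integer(phased))
  }
  tab <- vapply(codes, parse1, numeric(4))
  m <- match(as.vector(gt), codes)
  nr <- nrow(gt); nc <- ncol(gt)
  a1 <- matrix(tab[1, m], nr, nc); a2 <- matrix(tab[2, m], nr, nc)
  dos <- matrix(tab[3, m], nr, nc)
  ph <- matrix(tab[4, m], nr, nc)
  any_phased <- any(ph == 1, na.rm = TRUE)
  ## haplotypes are known when phased or homozygous; unknown for unphased hets
  unknown_hap <- !is.na(dos) & dos == 1L & ph == 0
  a1[unknown_hap] <- NA
  a2[unknown_hap] <- NA

  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(samples, sites[ord, , drop = FALSE],
                  t(dos)[, ord, drop = FALSE],
                  t(a1)[, ord, drop = FALSE], t(a2)[, ord, drop = FALSE],
                  phased = any_phased)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT fields. Heterozygotes are written
#' phased (`a|b`) when both haplotypes are known and the matrix is phased,
#' otherwise unphased.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=dhdrift",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples), collapse = "\t"))
  ns <- length(gm$samples)
  dos <- gm$dosage
  gt <- matrix("./.", nrow = ns, ncol = ncol(dos))
  gt[!is.na(dos) & dos == 0L] <- "0/0"
  gt[!is.na(dos) & dos == 1L] <- "0/1"
  gt[!is.na(dos) & dos == 2L] <- "1/1"
  if (gm$phased && !is.null(gm$hap1)) {
    known <- !is.na(gm$hap1) & !is.na(gm$hap2)
    gt[known] <- paste0(gm$hap1[known], "|", gm$hap2[known])
  }
  body <- apply(cbind(gm$sites$chrom, gm$sites$pos, gm$sites$id,
                      gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                      t(gt)), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
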