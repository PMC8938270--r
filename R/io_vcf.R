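#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR) into the package's site/genotype
#' representation. Only biallelic SNVs are kept: multiallelic records and
#' non-SNV records (indels, MNVs) are dropped with a reported count.
#' Phase information (`|` separators) is preserved; `./.` maps to the
#' missing state, never to hom-ref.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param samples optional character vector of sample names to keep; a
#'   requested sample absent from the file is fatal.
#' @return An object of class `vcf_data`: `sites` ([site_table()]),
#'   allele matrices `a1`/`a2` (0/1/NA, sites x samples), `phased` logical
#'   matrix, `dosage` matrix, and `dropped = c(multiallelic, non_snv)`.
#' @export
read_vcf <- function(path, samples = NULL) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  avail <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- avail
  missing <- setdiff(samples, avail)
  if (length(missing)) {
    wgr_stop(paste("sample(s) not in VCF:", paste(missing, collapse = ", ")),
             "missing_sample")
  }
  if (nrow(fix) == 0) {
    empty <- matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples))
    sites0 <- site_table(character(), integer(), character(), character())
    return(structure(list(sites = sites0, a1 = empty, a2 = empty,
                          phased = empty == 1, dosage = empty,
                          dropped = c(multiallelic = 0L, non_snv = 0L)),
                     class = "vcf_data"))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- !multi & fix$REF %in% c("A", "C", "G", "T") &
         fix$ALT %in% c("A", "C", "G", "T")
  dropped <- c(multiallelic = sum(multi), non_snv = sum(!snv & !multi))
  if (any(!snv)) {
    message(sprintf("read_vcf: dropped %d multiallelic and %d non-SNV record(s)",
                    dropped[["multiallelic"]], dropped[["non_snv"]]))
  }
  keep <- which(snv)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, samples, drop = FALSE]
  sites <- site_table(fix$CHROM[keep], as.integer(fix$POS[keep]),
                      fix$REF[keep], fix$ALT[keep],
                      id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                                  paste0(normalize_chrom(fix$CHROM[keep]), ":", fix$POS[keep]),
                                  fix$ID[keep]))
  # site_table() sorts; recover the permutation it applied
  perm <- order(chrom_order(normalize_chrom(fix$CHROM[keep])),
                as.integer(fix$POS[keep]))
  gt <- gt[perm, , drop = FALSE]
  parse_allele <- function(x) { x[x == "."] <- NA; as.integer(x) }
  a1 <- apply(gt, 2, function(col) parse_allele(sub("^([0-9.]+)[/|].*$", "\\1", col)))
  a2 <- apply(gt, 2, function(col) parse_allele(sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", col)))
  a1 <- matrix(a1, nrow(sites), dimnames = list(NULL, samples))
  a2 <- matrix(a2, nrow(sites), dimnames = list(NULL, samples))
  phased <- matrix(grepl("|", gt, fixed = TRUE), nrow(sites),
                   dimnames = list(NULL, samples))
  structure(list(sites = sites, a1 = a1, a2 = a2, phased = phased,
                 dosage = a1 + a2, dropped = dropped),
            class = "vcf_data")
}

# minimal structural validation so malformed records fail with a line number
#' @noRd
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8 || is.na(suppressWarnings(as.integer(f[2])))) {
      wgr_stop(sprintf("malformed VCF record at line %d", i), "vcf_parse")
    }
  }
  invisible(TRUE)
}

#' @export
print.vcf_data <- function(x, ...) {
  cat(sprintf("<vcf_data> %d biallelic SNVs x %d sample(s) (dropped: %d multiallelic, %d non-SNV)\n",
              nrow(x$sites), ncol(x$a1),
              x$dropped[["multiallelic"]], x$dropped[["non_snv"]]))
  invisible(x)
}

#' Extract one sample from VCF data as a phased genome
#'
#' Heterozygous unphased calls get NA haplotype alleles (phase unknown);
#' homozygous calls are trivially phased.
#'
#' @param x a [read_vcf()] result.
#' @param sample sample name.
#' @return a [phased_genome()].
#' @export
as_phased_genome <- function(x, sample) {
  stopifnot(inherits(x, "vcf_data"))
  if (!sample %in% colnames(x$a1)) {
    wgr_stop(sprintf("sample '%s' not in VCF data", sample), "missing_sample")
  }
  a1 <- x$a1[, sample]; a2 <- x$a2[, sample]
  unk <- !x$phased[, sample] & !is.na(a1) & !is.na(a2) & a1 != a2
  a1[unk] <- NA; a2[unk] <- NA
  phased_genome(x$sites, a1, a2)
}

#' @noRd
vcf_header <- function(samples, extra_format = character()) {
  c("##fileformat=VCFv4.2",
    "##source=wgr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    extra_format,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write a phased genome as a VCF file
#'
#' Genotypes use the `|` phase separator; an optional per-site phase
#' confidence is carried in a `PC` FORMAT field.
#'
#' @param genome a [phased_genome()].
#' @param path output path.
#' @param sample sample name.
#' @param phase_confidence optional numeric vector (one value per site).
#' @export
write_phased_vcf <- function(genome, path, sample = "sample",
                             phase_confidence = NULL) {
  s <- genome$sites
  gt <- ifelse(is.na(genome$hap1) | is.na(genome$hap2), "./.",
               paste0(genome$hap1, "|", genome$hap2))
  fmt <- "GT"; extra <- character()
  if (!is.null(phase_confidence)) {
    fmt <- "GT:PC"
    extra <- '##FORMAT=<ID=PC,Number=1,Type=Float,Description="Phase confidence">'
    gt <- paste0(gt, ":", format_num(phase_confidence))
  }
  writeLines(c(vcf_header(sample, extra),
               paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".",
                     fmt, gt, sep = "\t")),
             path)
  invisible(path)
}

#' @noRd
format_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "."
  out
}

#' Write / read a reconstructed embryo genome as VCF
#'
#' Genotypes are phased `maternal|paternal`; FORMAT fields `CF` (per-site
#' reconstruction confidence) and `TH` (transmitted maternal,paternal
#' haplotype indices) make the file round-trip back to the identical
#' [fill_genome()] object. Sites on aneuploid (unpredicted) chromosomes are
#' written `./.`.
#'
#' @param recon a `reconstructed_genome`.
#' @param path file path.
#' @param sample sample name.
#' @export
write_reconstruction <- function(recon, path, sample = "embryo") {
  s <- recon$sites
  gt <- ifelse(recon$predicted, paste0(recon$hap1, "|", recon$hap2), "./.")
  th <- ifelse(recon$predicted, paste0(recon$m_hap, ",", recon$p_hap), ".")
  rec <- paste0(gt, ":", format_num(recon$confidence), ":", th)
  extra <- c('##FORMAT=<ID=CF,Number=1,Type=Float,Description="Reconstruction confidence">',
             '##FORMAT=<ID=TH,Number=2,Type=Integer,Description="Transmitted haplotype index (maternal,paternal)">')
  writeLines(c(vcf_header(sample, extra),
               paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".",
                     "GT:CF:TH", rec, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_reconstruction
#' @export
read_reconstruction <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- site_table(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT,
                      id = fix$ID)
  gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1])
  cf <- unname(suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "CF")[, 1])))
  th <- unname(vcfR::extract.gt(v, element = "TH")[, 1])
  predicted <- gt != "./." & !is.na(gt)
  a1 <- ifelse(predicted, suppressWarnings(as.integer(sub("\\|.*", "", gt))), NA_integer_)
  a2 <- ifelse(predicted, suppressWarnings(as.integer(sub(".*\\|", "", gt))), NA_integer_)
  m_hap <- ifelse(predicted, suppressWarnings(as.integer(sub(",.*", "", th))), NA_integer_)
  p_hap <- ifelse(predicted, suppressWarnings(as.integer(sub(".*,", "", th))), NA_integer_)
  structure(list(sites = sites, hap1 = a1, hap2 = a2,
                 m_hap = m_hap, p_hap = p_hap, confidence = cf,
                 predicted = predicted),
            class = c("reconstructed_genome", "phased_genome"))
}

#' Write arbitrary diploid genotypes as an (optionally phased) VCF
#'
#' @param sites a [site_table()].
#' @param genotypes named list of [phased_genome()]s (phased output) or
#'   dosage vectors (unphased output), one per sample.
#' @param path file path.
#' @export
write_vcf <- function(sites, genotypes, path) {
  cols <- lapply(genotypes, function(g) {
    if (inherits(g, "phased_genome")) {
      ifelse(is.na(g$hap1) | is.na(g$hap2), "./.",
             paste0(g$hap1, "|", g$hap2))
    } else {
      c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(g), 4L, as.integer(g) + 1L)]
    }
  })
  body <- do.call(paste, c(list(sites$chrom, sites$pos, sites$id, sites$ref,
                                sites$alt, ".", "PASS", ".", "GT"),
                           cols, list(sep = "\t")))
  writeLines(c(vcf_header(names(genotypes)), body), path)
  invisible(path)
}
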