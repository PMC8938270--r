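#' Create a table of biallelic variant sites
#'
#' The site table is the coordinate system every other object in the package
#' is aligned to: one row per biallelic SNV, sorted by chromosome then
#' position, 1-based inclusive coordinates (the VCF convention). Chromosome
#' labels are normalized by stripping any leading `"chr"`.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference / alternate alleles.
#' @param id optional site identifiers (e.g. rs numbers); autogenerated
#'   `"chrom:pos"` labels when missing.
#' @return A `data.frame` of class `site_table` with columns
#'   `chrom`, `pos`, `ref`, `alt`, `id`.
#' @examples
#' site_table(c("1", "1"), c(100L, 200L), c("A", "C"), c("G", "T"))
#' @export
site_table <- function(chrom, pos, ref, alt, id = NULL) {
  chrom <- normalize_chrom(as.character(chrom))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  if (is.null(id)) id <- if (n == 0) character(0) else paste0(chrom, ":", pos)
  bad <- ref == alt
  if (any(bad)) {
    wgr_stop(sprintf("%d site(s) with identical ref and alt alleles", sum(bad)),
             "site_table")
  }
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   id = as.character(id), stringsAsFactors = FALSE)
  ord <- order(chrom_order(df$chrom), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(site_key(df))
  if (any(dup)) {
    wgr_stop(sprintf("duplicate site(s): %s",
                     paste(utils::head(site_key(df)[dup], 3), collapse = ", ")),
             "site_table")
  }
  class(df) <- c("site_table", "data.frame")
  df
}

#' @noRd
normalize_chrom <- function(x) sub("^chr", "", x)

# stable ordering: numeric chromosomes first in numeric order, then others
#' @noRd
chrom_order <- function(chrom) {
  suppress <- function(x) suppressWarnings(as.numeric(x))
  num <- suppress(chrom)
  rank <- ifelse(is.na(num), 1e6 + as.integer(factor(chrom)), num)
  rank
}

#' @noRd
site_key <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  paste0(sites$chrom, ":", sites$pos)
}

#' Match one site table against another
#'
#' @return integer index into `table` for each row of `query` (NA if absent).
#' @noRd
match_sites <- function(query, table) {
  match(site_key(query), site_key(table))
}

#' Construct a phased diploid genome over a site table
#'
#' A phased genome stores, for each site, the alternate-allele indicator (0 or
#' 1) carried by each of the two haplotypes. For a parent, haplotypes 1 and 2
#' are the two homologous chromosome copies; for an embryo, haplotype 1 is the
#' maternally inherited copy and haplotype 2 the paternal one.
#'
#' @param sites a [site_table()].
#' @param hap1,hap2 integer vectors of 0/1 alternate-allele indicators, one
#'   per site. `NA` marks an unphased/unknown allele.
#' @return An object of class `phased_genome`.
#' @export
phased_genome <- function(sites, hap1, hap2) {
  stopifnot(inherits(sites, "site_table"),
            length(hap1) == nrow(sites), length(hap2) == nrow(sites))
  hap1 <- as.integer(hap1); hap2 <- as.integer(hap2)
  ok <- function(h) all(is.na(h) | h %in% c(0L, 1L))
  if (!ok(hap1) || !ok(hap2)) {
    wgr_stop("haplotype alleles must be 0, 1 or NA", "phased_genome")
  }
  structure(list(sites = sites, hap1 = hap1, hap2 = hap2),
            class = "phased_genome")
}

#' Alternate-allele dosages of a phased genome
#'
#' @param genome a [phased_genome()].
#' @return integer vector of dosages in 0..2 (NA where either allele unknown).
#' @export
dosages <- function(genome) genome$hap1 + genome$hap2

# normalize a genotype input — either a phased_genome or a plain
# list(sites =, dosage =) (for genotypes whose phase is unknown) — to the
# list form
#' @noRd
as_genotypes <- function(x) {
  if (inherits(x, "phased_genome")) {
    list(sites = x$sites, dosage = dosages(x))
  } else if (is.list(x) && !is.null(x$sites) && !is.null(x$dosage)) {
    list(sites = x$sites, dosage = as.integer(x$dosage))
  } else {
    wgr_stop("expected a phased_genome or a list(sites, dosage)", "genotypes")
  }
}

#' Logical vector: is the genome heterozygous at each site?
#' @param genome a [phased_genome()].
#' @export
is_het <- function(genome) genome$hap1 != genome$hap2

#' @export
print.phased_genome <- function(x, ...) {
  nh <- sum(is_het(x), na.rm = TRUE)
  cat(sprintf("<phased_genome> %d sites on %d chromosome(s), %d heterozygous\n",
              nrow(x$sites), length(unique(x$sites$chrom)), nh))
  invisible(x)
}

#' Sparse, noisy SNP-array observation of one embryo biopsy
#'
#' Calls are unphased alternate-allele dosages: 0 (hom ref), 1 (het),
#' 2 (hom alt) or `NA` for a no-call. Chromosomes listed in `aneuploid` are
#' flagged as aneuploid by an upstream copy-number caller and are excluded
#' from reconstruction.
#'
#' @param sites [site_table()] of the array positions.
#' @param call integer dosage vector (0/1/2/NA), one per array site.
#' @param aneuploid character vector of aneuploid chromosome labels.
#' @return An object of class `embryo_obs`.
#' @export
embryo_obs <- function(sites, call, aneuploid = character()) {
  stopifnot(inherits(sites, "site_table"), length(call) == nrow(sites))
  call <- as.integer(call)
  if (!all(is.na(call) | call %in% 0:2)) {
    wgr_stop("array calls must be dosages 0, 1, 2 or NA (no-call)", "embryo_obs")
  }
  structure(list(sites = sites, call = call,
                 aneuploid = normalize_chrom(as.character(aneuploid))),
            class = "embryo_obs")
}

#' @export
print.embryo_obs <- function(x, ...) {
  cat(sprintf("<embryo_obs> %d array sites, %.1f%% no-call, %d aneuploid chromosome(s)\n",
              nrow(x$sites), 100 * mean(is.na(x$call)),
              length(x$aneuploid)))
  invisible(x)
}
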