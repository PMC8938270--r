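#' Fill in the dense embryo genome from a transmission path
#'
#' Every parental variant site — array and non-array alike — receives the
#' allele carried by the transmitted haplotype of each parent, read off the
#' Viterbi segment covering it. Per-site confidence is the product, over the
#' two parents, of the posterior probability (at the nearest informative
#' array site) that the assigned haplotype is the transmitted one; sites
#' inside a breakpoint uncertainty interval therefore inherit the flanking
#' posterior mixture rather than being dropped. Chromosomes flagged
#' aneuploid carry no predictions.
#'
#' @param path a [decode_transmission()] result.
#' @param mother,father phased parental genomes over the full site list.
#' @param sites site table to predict at; defaults to the mother's sites.
#' @param mother_phase_conf,father_phase_conf optional per-site phase
#'   confidences in \[0.5, 1\] (e.g. from [phase_parent()]). Predictions at
#'   sites where the transmitting parent is heterozygous but its phase
#'   confidence is below 0.6 are emitted with confidence multiplied by that
#'   phase confidence, not dropped.
#' @return An object of class `reconstructed_genome` (also a
#'   [phased_genome()]: hap1 = maternal allele, hap2 = paternal allele) with
#'   per-site `confidence`, transmitted haplotype indices `m_hap`/`p_hap`,
#'   and a logical `predicted` mask (FALSE on aneuploid/undecoded
#'   chromosomes, where alleles are NA).
#' @export
fill_genome <- function(path, mother, father, sites = NULL,
                        mother_phase_conf = NULL, father_phase_conf = NULL) {
  stopifnot(inherits(path, "transmission_path"))
  if (is.null(sites)) sites <- mother$sites
  n <- nrow(sites)
  pidx_m <- match_sites(sites, mother$sites)
  pidx_f <- match_sites(sites, father$sites)
  if (anyNA(pidx_m) || anyNA(pidx_f)) {
    wgr_stop("prediction sites must be present in both parental genomes", "sites")
  }
  hap1 <- rep(NA_integer_, n); hap2 <- rep(NA_integer_, n)
  m_hap <- rep(NA_integer_, n); p_hap <- rep(NA_integer_, n)
  conf <- rep(NA_real_, n)
  decoded <- unique(path$segments$chrom)

  for (ch in decoded) {
    at <- which(sites$chrom == ch)
    if (!length(at)) next
    pos <- sites$pos[at]
    ps <- path$sites[path$sites$chrom == ch, , drop = FALSE]
    for (par in c("mother", "father")) {
      segs <- path$segments[path$segments$chrom == ch &
                            path$segments$parent == par, , drop = FALSE]
      segs <- segs[order(segs$start), , drop = FALSE]
      j <- findInterval(pos, segs$start)
      if (any(j == 0 | pos > segs$end[pmax(j, 1)])) {
        stop("internal error: transmission segments do not tile chromosome ", ch)
      }
      hap <- segs$hap[j]
      # confidence anchors: posterior at the nearest site informative for
      # this parent; prediction at a parent-homozygous site is certain
      # regardless of which haplotype was transmitted
      anchors <- if (par == "mother") ps[ps$m_het, , drop = FALSE]
                 else ps[ps$p_het, , drop = FALSE]
      if (nrow(anchors)) {
        post1 <- if (par == "mother") anchors$m_post_hap1 else anchors$p_post_hap1
        nearest <- nearest_index(pos, anchors$pos)
        pconf <- ifelse(hap == 1L, post1[nearest], 1 - post1[nearest])
      } else {
        pconf <- rep(0.5, length(pos))
      }
      par_het <- if (par == "mother") is_het(mother)[pidx_m[at]] else
        is_het(father)[pidx_f[at]]
      pconf <- ifelse(!is.na(par_het) & !par_het, 1, pconf)
      if (par == "mother") {
        g <- mother; pi <- pidx_m[at]
        allele <- ifelse(hap == 1L, g$hap1[pi], g$hap2[pi])
        phc <- mother_phase_conf
        if (!is.null(phc)) {
          low <- is_het(g)[pi] & !is.na(phc[pi]) & phc[pi] < 0.6
          pconf <- ifelse(low, pconf * phc[pi], pconf)
        }
        hap1[at] <- allele; m_hap[at] <- hap
        conf[at] <- pconf
      } else {
        g <- father; pi <- pidx_f[at]
        allele <- ifelse(hap == 1L, g$hap1[pi], g$hap2[pi])
        phc <- father_phase_conf
        if (!is.null(phc)) {
          low <- is_het(g)[pi] & !is.na(phc[pi]) & phc[pi] < 0.6
          pconf <- ifelse(low, pconf * phc[pi], pconf)
        }
        hap2[at] <- allele; p_hap[at] <- hap
        conf[at] <- conf[at] * pconf
      }
    }
  }
  structure(list(sites = sites, hap1 = hap1, hap2 = hap2,
                 m_hap = m_hap, p_hap = p_hap, confidence = conf,
                 predicted = !is.na(hap1) & !is.na(hap2)),
            class = c("reconstructed_genome", "phased_genome"))
}

#' @noRd
nearest_index <- function(x, anchors) {
  lo <- findInterval(x, anchors)
  lo_c <- pmax(lo, 1L)
  hi_c <- pmin(lo + 1L, length(anchors))
  d_lo <- abs(x - anchors[lo_c])
  d_hi <- abs(anchors[hi_c] - x)
  ifelse(lo == 0L, hi_c, ifelse(lo >= length(anchors) | d_lo <= d_hi, lo_c, hi_c))
}

#' @export
print.reconstructed_genome <- function(x, ...) {
  cat(sprintf("<reconstructed_genome> %d/%d sites predicted, mean confidence %.4f\n",
              sum(x$predicted), nrow(x$sites),
              mean(x$confidence[x$predicted])))
  invisible(x)
}

#' High-confidence site mask for a parent-parent-child trio
#'
#' Sites retained are biallelic (guaranteed by the site table), genotyped in
#' all three trio members, not flagged low quality, and Mendelian-consistent:
#' the child's dosage must be attainable as one allele from each parent.
#' Mendelian-inconsistent sites indicate genotyping artifacts and are
#' excluded from accuracy assessment.
#'
#' @param sites a [site_table()].
#' @param mother,father,child alternate-allele dosage vectors (0/1/2, NA for
#'   missing) or [phased_genome()]s.
#' @param low_quality optional logical vector flagging sites to exclude.
#' @return logical mask over `sites` (TRUE = high confidence).
#' @export
high_confidence_filter <- function(sites, mother, father, child,
                                   low_quality = NULL) {
  as_dos <- function(x) if (inherits(x, "phased_genome")) dosages(x) else as.integer(x)
  m <- as_dos(mother); f <- as_dos(father); c_ <- as_dos(child)
  stopifnot(length(m) == nrow(sites), length(f) == nrow(sites),
            length(c_) == nrow(sites))
  min_a <- function(d) ifelse(d == 2L, 1L, 0L)
  max_a <- function(d) ifelse(d == 0L, 0L, 1L)
  feasible <- c_ >= min_a(m) + min_a(f) & c_ <= max_a(m) + max_a(f)
  mask <- !is.na(m) & !is.na(f) & !is.na(c_) & !is.na(feasible) & feasible
  if (!is.null(low_quality)) mask <- mask & !low_quality
  mask[is.na(mask)] <- FALSE
  mask
}

#' Classify sites as rare or common by population allele frequency
#'
#' A variant is rare when its population allele frequency is strictly below
#' 0.1% or when it is absent from the frequency table altogether.
#'
#' @param af numeric vector of population allele frequencies (NA = absent).
#' @param threshold rarity threshold on the allele frequency (default 0.001).
#' @return character vector, `"rare"` or `"common"`.
#' @examples
#' classify_rare(c(0.0005, 0.001, NA))  # rare, common, rare
#' @export
classify_rare <- function(af, threshold = 0.001) {
  ifelse(is.na(af) | af < threshold, "rare", "common")
}
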