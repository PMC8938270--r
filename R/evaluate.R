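#' Genotype accuracy of a reconstruction against a truth genome
#'
#' Accuracy is the percentage of compared sites whose unordered diploid
#' genotype (alternate-allele dosage, for biallelic sites) matches the
#' truth — phase errors do not count as genotype errors. Half-called or
#' unpredicted sites inside the mask count as discordant, not excluded
#' (conservative). Accuracy is stratified by truth genotype class
#' (heterozygous / homozygous) and, when frequencies are supplied, by
#' rarity; PRS-site accuracy is reported on the model-site subset.
#'
#' @param recon a `reconstructed_genome` (or [phased_genome()]).
#' @param truth the truth [phased_genome()] over the same sites.
#' @param mask logical vector over the sites selecting the comparison set
#'   (e.g. a [high_confidence_filter()] result); default: all sites.
#' @param af optional [af_table()] for rare/common stratification.
#' @param prs_sites optional [site_table()] (the union of loaded PRS model
#'   sites) for the PRS-site accuracy figure.
#' @return list of class `accuracy_report`: `n_sites_compared`,
#'   `n_predicted_sites`, `genome_wide_accuracy`, `by_genotype`,
#'   `by_rarity`, `prs_site_accuracy` (all percentages).
#' @export
genotype_accuracy <- function(recon, truth, mask = NULL, af = NULL,
                              prs_sites = NULL) {
  idx <- match_sites(recon$sites, truth$sites)
  if (anyNA(idx)) wgr_stop("reconstruction sites absent from truth genome", "sites")
  if (is.null(mask)) mask <- rep(TRUE, nrow(recon$sites))
  if (!any(mask)) wgr_stop("empty comparison mask", "empty_mask")
  pred <- dosages(recon)
  tru <- dosages(truth)[idx]
  cmp <- which(mask & !is.na(tru))
  concord <- !is.na(pred[cmp]) & pred[cmp] == tru[cmp]
  pct <- function(x) 100 * mean(x)
  het <- tru[cmp] == 1L
  by_genotype <- c(het = if (any(het)) pct(concord[het]) else NA,
                   hom = if (any(!het)) pct(concord[!het]) else NA)
  by_rarity <- NULL
  if (!is.null(af)) {
    rarity <- classify_rare(af_lookup(af, recon$sites[cmp, , drop = FALSE]))
    by_rarity <- vapply(c(rare = "rare", common = "common"), function(cl) {
      if (any(rarity == cl)) pct(concord[rarity == cl]) else NA_real_
    }, 0)
  }
  prs_acc <- NA_real_
  if (!is.null(prs_sites)) {
    on_prs <- site_key(recon$sites[cmp, , drop = FALSE]) %in% site_key(prs_sites)
    if (any(on_prs)) prs_acc <- pct(concord[on_prs])
  }
  n_pred <- if (!is.null(recon$predicted)) sum(recon$predicted) else
    sum(!is.na(pred))
  structure(list(n_sites_compared = length(cmp),
                 n_predicted_sites = n_pred,
                 genome_wide_accuracy = pct(concord),
                 by_genotype = by_genotype,
                 by_rarity = by_rarity,
                 prs_site_accuracy = prs_acc),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %.2f%% genome-wide over %d sites (het %.2f%% / hom %.2f%%)\n",
              x$genome_wide_accuracy, x$n_sites_compared,
              x$by_genotype[["het"]], x$by_genotype[["hom"]]))
  if (!is.na(x$prs_site_accuracy))
    cat(sprintf("  PRS-site accuracy %.2f%%\n", x$prs_site_accuracy))
  invisible(x)
}

#' Squared correlation between embryo and truth PRS
#'
#' Pearson r-squared across paired (embryo biopsy, born-child truth) scores,
#' pooled over conditions. Centered scores are used, so the statistic is
#' location-invariant; being an r-squared it is also sign-invariant.
#'
#' @param embryo_scores,truth_scores paired numeric vectors (>= 3 pairs).
#' @return squared Pearson correlation.
#' @export
prs_concordance <- function(embryo_scores, truth_scores) {
  stopifnot(length(embryo_scores) == length(truth_scores))
  if (length(embryo_scores) < 3) wgr_stop("need at least 3 paired scores", "concordance")
  if (stats::sd(embryo_scores) == 0 || stats::sd(truth_scores) == 0) {
    wgr_stop("zero variance in scores; r-squared undefined", "zero_variance")
  }
  stats::cor(embryo_scores, truth_scores)^2
}

# classify true crossovers by whether any marker-based decoder could see
# them: detectable = flanked by markers informative for this parent, and the
# odd one out within its inter-marker interval (even-parity multiples
# cancel). Also records the bounding marker interval of each crossover.
#' @noRd
classify_crossovers <- function(path, meiosis, parent) {
  het_col <- if (parent == "mother") "m_het" else "p_het"
  out <- list()
  for (ch in names(meiosis)) {
    xo <- meiosis[[ch]]$xo_pos
    if (!length(xo)) next
    inf_pos <- path$sites$pos[path$sites$chrom == ch & path$sites[[het_col]]]
    detectable <- logical(length(xo))
    left <- rep(-Inf, length(xo)); right <- rep(Inf, length(xo))
    if (length(inf_pos) >= 1) {
      bin <- findInterval(xo, inf_pos)
      left[bin >= 1] <- inf_pos[bin[bin >= 1]]
      right[bin < length(inf_pos)] <- inf_pos[bin[bin < length(inf_pos)] + 1]
      inside <- bin >= 1 & bin < length(inf_pos)
      for (b in unique(bin[inside])) {
        members <- which(bin == b & inside)
        if (length(members) %% 2 == 1) detectable[members[1]] <- TRUE
      }
    }
    out[[ch]] <- data.frame(chrom = ch, pos = xo, detectable = detectable,
                            left_marker = left, right_marker = right)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = numeric(),
                      detectable = logical(), left_marker = numeric(),
                      right_marker = numeric()))
  }
  do.call(rbind, unname(out))
}

#' Truth-aware determinable-site mask (synthetic evaluation only)
#'
#' Extends [determined_sites_mask()] using the known true meioses: regions
#' flipped by crossovers no marker-based method could observe — crossovers
#' outside the span of parent-informative markers, or even-parity multiples
#' inside one inter-marker interval — are additionally excluded. The
#' remaining sites are exactly those whose genotype the observed data
#' determine, so a correct decoder must be perfect there in the noiseless
#' limit.
#'
#' @param path a [decode_transmission()] result.
#' @param sites a [site_table()].
#' @param meiosis_m,meiosis_p the embryo's true maternal / paternal
#'   meioses.
#' @return logical vector over `sites`.
#' @export
truth_determined_mask <- function(path, sites, meiosis_m, meiosis_p) {
  mask <- determined_sites_mask(path, sites)
  for (side in list(list(m = meiosis_m, p = "mother"),
                    list(m = meiosis_p, p = "father"))) {
    cls <- classify_crossovers(path, side$m, side$p)
    und <- cls[!cls$detectable, , drop = FALSE]
    for (k in seq_len(nrow(und))) {
      hit <- sites$chrom == und$chrom[k] &
        sites$pos > und$left_marker[k] & sites$pos < und$right_marker[k]
      mask[hit] <- FALSE
    }
  }
  mask
}

#' Mask of sites whose transmitted haplotypes are determined
#'
#' Sites lying inside a reported breakpoint uncertainty interval (for
#' either parent) cannot be assigned to a haplotype from the data: the
#' crossover sits somewhere between the flanking informative markers and
#' its exact position is unobservable. This mask is TRUE everywhere else,
#' and is the natural comparison set when asking whether reconstruction is
#' exact wherever the data determine the answer.
#'
#' @param path a [decode_transmission()] result.
#' @param sites a [site_table()].
#' @return logical vector over `sites`.
#' @export
determined_sites_mask <- function(path, sites) {
  stopifnot(inherits(path, "transmission_path"))
  mask <- rep(TRUE, nrow(sites))
  bp <- path$breakpoints
  for (k in seq_len(nrow(bp))) {
    inside <- sites$chrom == bp$chrom[k] &
      sites$pos > bp$left_pos[k] & sites$pos < bp$right_pos[k]
    mask[inside] <- FALSE
  }
  mask
}

#' Score breakpoint calls against the true meiosis
#'
#' A true crossover is detected when some reported breakpoint interval for
#' the same parent and chromosome contains it; reported breakpoints
#' containing no true crossover are false positives. Crossovers that leave
#' no observable trace are classified undetectable and excluded from the
#' detection denominator: those outside the span of sites heterozygous in
#' this parent (no flanking marker on one side) and, within each
#' inter-marker interval, the even-parity remainder of multiple crossovers
#' (which cancel). This is the resolution limit of any marker-based caller,
#' not a property of the decoder.
#'
#' @param path a [decode_transmission()] result.
#' @param meiosis a `true_meiosis` (from [draw_meiosis()]).
#' @param parent `"mother"` or `"father"` — which parent's meiosis this is.
#' @return list of class `breakpoint_report`: per-crossover data.frame
#'   (`chrom`, `pos`, `detectable`, `detected`, `interval_width`), plus
#'   counts `n_true`, `n_detectable`, `n_detected`, `n_false_positive`.
#' @export
breakpoint_accuracy <- function(path, meiosis, parent) {
  stopifnot(inherits(path, "transmission_path"), parent %in% c("mother", "father"))
  bp <- path$breakpoints[path$breakpoints$parent == parent, , drop = FALSE]
  cls <- classify_crossovers(path, meiosis, parent)
  rows <- list()
  used <- rep(FALSE, nrow(bp))
  for (i in seq_len(nrow(cls))) {
    x <- cls$pos[i]; ch <- cls$chrom[i]
    hit <- which(bp$chrom == ch & bp$left_pos <= x & x <= bp$right_pos & !used)
    det <- cls$detectable[i] && length(hit) > 0
    if (det) used[hit[1]] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch, pos = x, detectable = cls$detectable[i], detected = det,
      interval_width = if (length(hit)) bp$right_pos[hit[1]] - bp$left_pos[hit[1]] else NA_real_)
  }
  per_xo <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = numeric(), detectable = logical(),
               detected = logical(), interval_width = numeric())
  # a reported interval is a false positive when no true crossover lies in it
  fp <- 0L
  for (k in seq_len(nrow(bp))) {
    xs <- unlist(lapply(names(meiosis), function(ch) {
      if (bp$chrom[k] == ch) meiosis[[ch]]$xo_pos else numeric()
    }))
    if (!any(bp$left_pos[k] <= xs & xs <= bp$right_pos[k])) fp <- fp + 1L
  }
  structure(list(crossovers = per_xo,
                 n_true = nrow(per_xo),
                 n_detectable = sum(per_xo$detectable),
                 n_detected = sum(per_xo$detected),
                 n_false_positive = fp),
            class = "breakpoint_report")
}

#' @export
print.breakpoint_report <- function(x, ...) {
  cat(sprintf("<breakpoint_report> %d/%d detectable crossovers detected (%d true, %d below resolution), %d false positive(s)\n",
              x$n_detected, x$n_detectable, x$n_true,
              x$n_true - x$n_detectable, x$n_false_positive))
  invisible(x)
}
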