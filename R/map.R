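#' Construct a genetic map
#'
#' A genetic map anchors cumulative genetic distance (centimorgans) at a set
#' of physical positions per chromosome. Distance at any other position is
#' obtained by linear interpolation between anchors; positions outside the
#' anchored span clamp to the terminal cM values.
#'
#' @param chrom chromosome labels.
#' @param pos 1-based physical positions (sorted within chromosome).
#' @param cM cumulative genetic distance, non-negative and non-decreasing
#'   within each chromosome.
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos, cM) {
  pos <- as.numeric(pos)
  cM <- as.numeric(cM)
  chrom <- rep_len(normalize_chrom(as.character(chrom)), length(pos))
  stopifnot(length(pos) == length(cM))
  if (any(cM < 0)) wgr_stop("negative cM in genetic map", "genetic_map")
  df <- data.frame(chrom = chrom, pos = pos, cM = cM, stringsAsFactors = FALSE)
  df <- df[order(chrom_order(df$chrom), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    d <- diff(df$cM[df$chrom == ch])
    if (any(d < 0)) {
      wgr_stop(sprintf("decreasing cM on chromosome %s", ch), "genetic_map")
    }
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Interpolate genetic-map position
#'
#' @param map a [genetic_map()].
#' @param chrom single chromosome label.
#' @param pos numeric vector of physical positions.
#' @return cumulative cM at each position (linear interpolation, clamped to
#'   the map span at either end).
#' @export
cm_at <- function(map, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) wgr_stop(sprintf("chromosome %s absent from map", chrom), "genetic_map")
  if (nrow(m) == 1) return(rep(m$cM, length(pos)))
  stats::approx(m$pos, m$cM, xout = pos, rule = 2, ties = "ordered")$y
}

#' Invert a genetic map: physical position at a cumulative cM value
#'
#' Used to place crossovers drawn on the cM scale. Flat map segments
#' (zero recombination) invert to their left edge.
#' @inheritParams cm_at
#' @param cm numeric vector of cumulative cM values.
#' @export
pos_at_cm <- function(map, chrom, cm) {
  chrom <- normalize_chrom(chrom)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) wgr_stop(sprintf("chromosome %s absent from map", chrom), "genetic_map")
  if (nrow(m) == 1) return(rep(m$pos, length(cm)))
  stats::approx(m$cM, m$pos, xout = cm, rule = 2, ties = "ordered")$y
}

#' Total genetic length of a chromosome
#' @inheritParams cm_at
#' @export
map_length <- function(map, chrom) {
  chrom <- normalize_chrom(chrom)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) wgr_stop(sprintf("chromosome %s absent from map", chrom), "genetic_map")
  max(m$cM) - min(m$cM)
}

#' Uniform-rate genetic map over a site table
#'
#' Convenience constructor for simulations: a constant recombination rate
#' (default 1 cM/Mb, the genome-wide human average) anchored at the first and
#' last site of each chromosome.
#'
#' @param sites a [site_table()].
#' @param rate_cM_per_Mb recombination rate.
#' @param pad physical padding (bp) added beyond the terminal sites.
#' @return A [genetic_map()].
#' @export
uniform_map <- function(sites, rate_cM_per_Mb = 1, pad = 0) {
  rows <- lapply(unique(sites$chrom), function(ch) {
    p <- sites$pos[sites$chrom == ch]
    span <- c(max(1, min(p) - pad), max(p) + pad)
    data.frame(chrom = ch, pos = span,
               cM = (span - span[1]) * rate_cM_per_Mb / 1e6)
  })
  df <- do.call(rbind, rows)
  genetic_map(df$chrom, df$pos, df$cM)
}

#' Haldane map function: recombination fraction from genetic distance
#'
#' `r(d) = (1 - exp(-2 d / 100)) / 2` for `d` in centimorgans — the
#' interference-free (Poisson) crossover model. Strictly increasing in `d`
#' with supremum 1/2.
#'
#' @param d_cM genetic distance in centimorgans (non-negative).
#' @return recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2
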