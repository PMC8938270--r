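#' Simulate phased parental genomes
#'
#' Draws a synthetic couple: haplotype alleles are sampled independently per
#' haplotype from each site's population allele frequency (Hardy-Weinberg),
#' so expected parental heterozygosity at a site with alternate-allele
#' frequency p is 2p(1-p).
#'
#' @param n_sites total number of biallelic SNV sites.
#' @param n_chromosomes number of chromosomes the sites are spread over.
#' @param af allele-frequency spectrum: a single frequency, a vector of
#'   length `n_sites`, or a function `n -> frequencies`. Default draws from
#'   Uniform(0.05, 0.95), emulating the common-variant content of a
#'   genotyping array.
#' @param chrom_span_bp physical span of each chromosome (positions are
#'   sampled uniformly within it).
#' @param seed optional RNG seed.
#' @return list with elements `mother`, `father` ([phased_genome()]),
#'   `sites` ([site_table()]) and `af_table` (see [af_table()]).
#' @export
simulate_parents <- function(n_sites, n_chromosomes = 1, af = NULL,
                             chrom_span_bp = 1e8, seed = NULL) {
  stopifnot(n_sites >= 1, n_chromosomes >= 1)
  if (!is.null(seed)) set.seed(seed)
  per <- diff(floor(seq(0, n_sites, length.out = n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(per, function(k) sort(sample.int(chrom_span_bp, k))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  sites <- site_table(chrom, pos, ref, alt)

  p <- if (is.null(af)) stats::runif(n_sites, 0.05, 0.95)
       else if (is.function(af)) af(n_sites)
       else rep_len(af, n_sites)
  if (any(p < 0 | p > 1)) wgr_stop("allele frequencies must lie in [0, 1]", "af")
  # sites were generated in sorted order, so p aligns with `sites` rows
  draw_hap <- function() as.integer(stats::runif(n_sites) < p)
  list(
    mother = phased_genome(sites, draw_hap(), draw_hap()),
    father = phased_genome(sites, draw_hap(), draw_hap()),
    sites = sites,
    af_table = af_table(sites$chrom, sites$pos, p)
  )
}

#' Draw one meiosis from a phased parent
#'
#' Crossovers are placed as a Poisson process on the genetic-map scale — an
#' expected one crossover per 100 cM with no interference — and the gamete
#' copies alternately from the two parental haplotypes at crossover
#' boundaries, starting from a uniformly chosen haplotype.
#'
#' @param parent a [phased_genome()].
#' @param map a [genetic_map()] covering the parent's sites.
#' @param seed optional RNG seed.
#' @return list with `meiosis` (class `true_meiosis`: per chromosome, the
#'   starting haplotype index and strictly increasing crossover positions in
#'   bp) and `gamete` (integer allele vector over the parent's sites).
#' @export
draw_meiosis <- function(parent, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- parent$sites
  chroms <- unique(sites$chrom)
  meiosis <- list()
  gamete <- integer(nrow(sites))
  for (ch in chroms) {
    idx <- which(sites$chrom == ch)
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) wgr_stop(sprintf("map does not cover chromosome %s", ch), "genetic_map")
    L <- max(m$cM) - min(m$cM)
    n_xo <- stats::rpois(1, L / 100)
    xo_cm <- sort(stats::runif(n_xo, min(m$cM), max(m$cM)))
    xo_pos <- if (n_xo > 0) pos_at_cm(map, ch, xo_cm) else numeric()
    start_hap <- sample(1:2, 1)
    hap_at <- hap_index_at(sites$pos[idx], start_hap, xo_pos)
    gamete[idx] <- ifelse(hap_at == 1L, parent$hap1[idx], parent$hap2[idx])
    meiosis[[ch]] <- list(start_hap = start_hap, xo_pos = xo_pos)
  }
  class(meiosis) <- "true_meiosis"
  list(meiosis = meiosis, gamete = gamete)
}

# which haplotype is transmitted at each position, given the crossover set
#' @noRd
hap_index_at <- function(pos, start_hap, xo_pos) {
  n_before <- findInterval(pos - 0.5, xo_pos)  # crossovers strictly before pos
  ifelse(n_before %% 2 == 0, start_hap, 3L - start_hap)
}

#' Combine two gametes into a diploid embryo genome
#'
#' @param mat_gamete,pat_gamete integer allele vectors from [draw_meiosis()].
#' @param sites the parental [site_table()].
#' @return a [phased_genome()] with hap1 = maternal, hap2 = paternal.
#' @export
make_embryo <- function(mat_gamete, pat_gamete, sites) {
  phased_genome(sites, mat_gamete, pat_gamete)
}

#' Observe an embryo genome through a noisy SNP array
#'
#' Restricts the true genome to the array site list and pushes each genotype
#' through the noise channel of [emission_matrix()]: allele dropout on
#' heterozygous truth, uniform random miscalls, and no-calls.
#'
#' @param embryo a [phased_genome()] (the true embryo genome).
#' @param array_sites a [site_table()], a subset of the embryo's sites.
#' @param profile a [noise_profile()].
#' @param aneuploid chromosomes to flag as aneuploid on the observation.
#' @param seed optional RNG seed.
#' @return an [embryo_obs()].
#' @export
make_observation <- function(embryo, array_sites, profile = noise_profile("none"),
                             aneuploid = character(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match_sites(array_sites, embryo$sites)
  if (anyNA(idx)) wgr_stop("array sites must be a subset of the genome's sites", "sites")
  truth <- dosages(embryo)[idx]
  E <- emission_matrix(profile)
  calls <- c(0L, 1L, 2L, NA_integer_)
  obs <- integer(length(truth))
  for (g in 0:2) {
    j <- which(truth == g)
    if (length(j)) obs[j] <- calls[sample.int(4, length(j), replace = TRUE, prob = E[g + 1, ])]
  }
  embryo_obs(array_sites, obs, aneuploid = aneuploid)
}

#' Simulate a complete IVF family fixture
#'
#' Generates phased parents, `n_embryos` sibling embryos (each from an
#' independent maternal and paternal meiosis with map-driven crossovers),
#' noisy array observations of every embryo, and designates embryo 1 as the
#' "born child" whose truth genome is known exactly — mirroring a study
#' design in which the born child is whole-genome sequenced and serves as
#' ground truth for reconstruction accuracy.
#'
#' @param n_embryos number of sibling embryos (>= 1).
#' @param n_sites total parental (WGS) variant sites.
#' @param n_array number of array sites (a random subset of `n_sites`).
#' @param n_chromosomes number of chromosomes.
#' @param noise a [noise_profile()] or preset name.
#' @param aneuploid_spec list of `list(embryo =, chrom =)` pairs marking
#'   whole-chromosome aneuploidies on specific embryos' observations.
#' @param rate_cM_per_Mb uniform recombination rate for the family's map.
#' @param af,chrom_span_bp passed to [simulate_parents()].
#' @param seed RNG seed; the whole fixture is reproducible given it.
#' @return An object of class `wgr_family`: parents, `sites`, `af_table`,
#'   `map`, `array_sites`, `embryos` (each with `truth`, `meiosis_m`,
#'   `meiosis_p`, `obs`), and `born_child` (index into `embryos`).
#' @export
simulate_family <- function(n_embryos, n_sites = 4000, n_array = 1500,
                            n_chromosomes = 2, noise = noise_profile("day5"),
                            aneuploid_spec = list(), rate_cM_per_Mb = 1,
                            af = NULL, chrom_span_bp = 1e8, seed = NULL) {
  stopifnot(n_embryos >= 1, n_array <= n_sites)
  if (is.character(noise)) noise <- noise_profile(noise)
  if (!is.null(seed)) set.seed(seed)
  par <- simulate_parents(n_sites, n_chromosomes, af = af,
                          chrom_span_bp = chrom_span_bp)
  map <- uniform_map(par$sites, rate_cM_per_Mb = rate_cM_per_Mb)
  array_idx <- sort(sample.int(n_sites, n_array))
  array_sites <- par$sites[array_idx, , drop = FALSE]
  class(array_sites) <- c("site_table", "data.frame")

  aneu_of <- function(i) {
    ch <- vapply(Filter(function(a) a$embryo == i, aneuploid_spec),
                 function(a) as.character(a$chrom), "")
    normalize_chrom(ch)
  }
  embryos <- lapply(seq_len(n_embryos), function(i) {
    mm <- draw_meiosis(par$mother, map)
    pp <- draw_meiosis(par$father, map)
    truth <- make_embryo(mm$gamete, pp$gamete, par$sites)
    obs <- make_observation(truth, array_sites, noise, aneuploid = aneu_of(i))
    list(truth = truth, meiosis_m = mm$meiosis, meiosis_p = pp$meiosis, obs = obs)
  })
  structure(list(mother = par$mother, father = par$father, sites = par$sites,
                 af_table = par$af_table, map = map, array_sites = array_sites,
                 embryos = embryos, born_child = 1L, noise = noise),
            class = "wgr_family")
}

#' @export
print.wgr_family <- function(x, ...) {
  cat(sprintf("<wgr_family> %d embryos, %d WGS sites (%d on array), %d chromosome(s), noise '%s'\n",
              length(x$embryos), nrow(x$sites), nrow(x$array_sites),
              length(unique(x$sites$chrom)), x$noise$label))
  invisible(x)
}
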