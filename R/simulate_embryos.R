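#' Simulate one virtual embryo with linkage
#'
#' Draws one meiosis per parent on the genetic map (map-driven crossovers,
#' see [draw_meiosis()]) and unites the two virtual gametes into a diploid
#' genome, preserving linkage between neighboring variants.
#'
#' @param mother,father phased parental [phased_genome()]s.
#' @param map a [genetic_map()].
#' @param seed optional RNG seed.
#' @return a [phased_genome()] (hap1 maternal, hap2 paternal).
#' @export
simulate_embryo_linkage <- function(mother, father, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mg <- draw_meiosis(mother, map)
  pg <- draw_meiosis(father, map)
  make_embryo(mg$gamete, pg$gamete, mother$sites)
}

#' Simulate one virtual embryo without linkage
#'
#' Chooses one allele from each parent independently at every site — no
#' assumption that neighboring variants are co-transmitted. Homozygous
#' parental sites transmit deterministically; heterozygous sites transmit
#' either allele with probability 1/2.
#'
#' @param mother,father parental genotypes ([phased_genome()]s; only
#'   dosages are used).
#' @param seed optional RNG seed.
#' @return a [phased_genome()] over the mother's sites.
#' @export
simulate_embryo_unlinked <- function(mother, father, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(parent) {
    d <- dosages(parent)
    stats::rbinom(length(d), 1, d / 2)
  }
  phased_genome(mother$sites, draw(mother), draw(father))
}

#' Simulate the PRS distribution of a couple's potential embryos
#'
#' Repeats virtual-embryo simulation (linkage or unlinked mode) and scores
#' each replicate with the supplied PRS model, optionally standardizing on
#' the same PC model as real embryos so the distribution is on the familiar
#' SD scale. Also calls carrier status for an optional monogenic panel.
#'
#' @param mother,father phased parental genomes.
#' @param model a [prs_model()].
#' @param map a [genetic_map()] (required in linkage mode).
#' @param mode `"linkage"` or `"unlinked"`.
#' @param n_replicates number of simulated embryos (default 500).
#' @param af optional [af_table()] passed to [raw_prs()].
#' @param pc_model optional fitted `pc_model`; when given, scores are
#'   centered and standardized, otherwise raw scores are returned.
#' @param panel optional [monogenic_panel()]; carrier flags per replicate.
#' @param population optional population label for standardization.
#' @param seed RNG seed; the cohort is reproducible given it.
#' @return object of class `simulated_cohort`: data.frame `replicates`
#'   (score, carrier flags) plus `mode`, `n_replicates`, `seed`.
#' @export
simulate_prs_cohort <- function(mother, father, model, map = NULL,
                                mode = c("linkage", "unlinked"),
                                n_replicates = 500, af = NULL,
                                pc_model = NULL, panel = NULL,
                                population = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_replicates >= 1)
  if (mode == "linkage" && is.null(map)) {
    wgr_stop("linkage mode requires a genetic map", "config")
  }
  if (!is.null(seed)) set.seed(seed)
  score_one <- function(g) {
    r <- raw_prs(g, model, af = af)$raw_score
    if (is.null(pc_model)) return(r)
    pcs <- project_pcs(g, pc_model)
    center_and_standardize(r, pcs, pc_model, population = population)
  }
  carrier_one <- function(g) {
    if (is.null(panel)) return(NA)
    any(call_carriers(g, panel)$status == "carrier")
  }
  rows <- lapply(seq_len(n_replicates), function(i) {
    g <- if (mode == "linkage") simulate_embryo_linkage(mother, father, map)
         else simulate_embryo_unlinked(mother, father)
    data.frame(replicate = i, score = score_one(g), carrier = carrier_one(g))
  })
  structure(list(replicates = do.call(rbind, rows), mode = mode,
                 n_replicates = n_replicates, seed = seed),
            class = "simulated_cohort")
}

#' Summarize a simulated embryo cohort against the couple
#'
#' Reports the simulated score distribution (mean, SD, quantiles) alongside
#' the midparent mean — the average of the two parents' scores, which is
#' the Mendelian expectation for offspring — on the same scale.
#'
#' @param cohort a [simulate_prs_cohort()] result.
#' @param parent_scores numeric length-2 vector: the two parents' scores on
#'   the same scale as the cohort.
#' @return list of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort, parent_scores = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  s <- cohort$replicates$score
  if (length(s) < 2) wgr_stop("need at least 2 replicates to summarize", "cohort")
  out <- list(
    mode = cohort$mode,
    n_replicates = cohort$n_replicates,
    mean = mean(s), sd = stats::sd(s),
    quantiles = stats::quantile(s, c(0.025, 0.25, 0.5, 0.75, 0.975)),
    carrier_fraction = if (all(is.na(cohort$replicates$carrier))) NA else
      mean(cohort$replicates$carrier, na.rm = TRUE),
    midparent = if (is.null(parent_scores)) NA else mean(parent_scores)
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s mode, %d replicates: mean %.3f (midparent %s), sd %.3f\n",
              x$mode, x$n_replicates, x$mean,
              if (is.na(x$midparent)) "n/a" else sprintf("%.3f", x$midparent),
              x$sd))
  if (!is.na(x$carrier_fraction))
    cat(sprintf("  carrier fraction %.3f\n", x$carrier_fraction))
  invisible(x)
}
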