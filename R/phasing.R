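#' Phase a parent's heterozygous sites from sibling-embryo co-inheritance
#'
#' Step 1 of parental support. Sibling embryos inherit long stretches of the
#' same parental haplotype, so the pattern of co-inheritance across embryos
#' identifies which alleles at nearby heterozygous sites reside on the same
#' physical chromosome copy. Heterozygous array sites are phased left to
#' right: at each site the two relative phases (coupling/repulsion against
#' the scaffold built so far) are scored by the likelihood of all embryos'
#' observed calls under the transmitted-haplotype model — a Markov chain
#' over each embryo's transmitted haplotype with Haldane switch
#' probabilities, conditioned on everything already observed to the left
#' via a per-embryo forward filter — and the more likely relative phase is
#' chosen and chained along the chromosome. The other parent's contribution
#' is summed over its transmitted haplotype when its phase is known, and
#' marginalized per site otherwise. The global labeling of which set of
#' alleles is "haplotype 1" is arbitrary and fixed by putting the alternate
#' allele of the first heterozygous site on haplotype 1.
#'
#' With a single embryo the relative phase of the parent's sites is
#' unidentifiable (every phase explains the data equally well) and the
#' operation refuses.
#'
#' @param parent parental genotypes: a [phased_genome()] (only its dosages
#'   are used) or a `list(sites =, dosage =)`, covering the array sites.
#' @param other_parent the other parent's genotypes. When its heterozygous
#'   sites carry phase (e.g. a previous-pass scaffold), the pair likelihood
#'   sums over its transmitted haplotype; otherwise its contribution is
#'   marginalized per site.
#' @param embryos list of at least two [embryo_obs()] on a common site list.
#' @param map a [genetic_map()].
#' @param profile a [noise_profile()] describing the biopsy noise.
#' @param other_confidence optional per-site phase confidence for
#'   `other_parent` (a scaffold's `confidence`); the other parent's relative
#'   orientation across each pair is then treated as correct only with the
#'   product of its step confidences inside the pair interval, so its own
#'   phasing errors are marginalized rather than trusted.
#' @return An object of class `phase_scaffold`: `genome` (a
#'   [phased_genome()] over the parent's sites — phased at heterozygous
#'   array sites, trivially phased at homozygous sites, NA elsewhere) and
#'   `confidence` (per-site posterior probability of the chosen relative
#'   phase; in \[0.5, 1\] at phased het sites, NA elsewhere).
#' @export
phase_parent <- function(parent, other_parent, embryos, map,
                         profile = noise_profile("none"),
                         other_confidence = NULL, refine_sweeps = 3) {
  if (length(embryos) < 2) {
    wgr_stop("parental phase is unidentifiable from fewer than 2 sibling embryos",
             "unidentifiable")
  }
  par_gt <- as_genotypes(parent)
  oth_gt <- as_genotypes(other_parent)
  sites <- par_gt$sites
  arr <- embryos[[1]]$sites
  for (e in embryos[-1]) {
    if (!identical(site_key(e$sites), site_key(arr))) {
      wgr_stop("all embryos must be observed on the same array site list", "sites")
    }
  }
  aidx <- match_sites(arr, sites)
  if (anyNA(aidx)) wgr_stop("array sites absent from parental genome", "sites")
  oidx <- match_sites(arr, oth_gt$sites)
  if (anyNA(oidx)) wgr_stop("array sites absent from other parent's genome", "sites")

  par_dos <- par_gt$dosage
  oth_dos <- oth_gt$dosage
  hap1 <- ifelse(par_dos == 0L, 0L, ifelse(par_dos == 2L, 1L, NA_integer_))
  hap2 <- hap1
  conf <- rep(NA_real_, nrow(sites))
  E <- emission_matrix(profile)

  for (ch in unique(arr$chrom)) {
    on_ch <- which(arr$chrom == ch)
    n_obs <- vapply(embryos, function(e) sum(!is.na(e$call[on_ch])), 0L)
    if (sum(n_obs > 0) < 2) {
      wgr_stop(sprintf("fewer than 2 embryos with observations on chromosome %s", ch),
               "unidentifiable")
    }
    het <- on_ch[which(par_dos[aidx[on_ch]] == 1L)]
    if (!length(het)) next
    pos <- arr$pos[het]
    # the other parent's contribution at each pair site: transmitted-allele
    # pair (b for its haplotype 1 / 2) when its phase is known, a fixed
    # allele when homozygous, or an independent uniform draw when its
    # heterozygous phase is unknown ("marg")
    is_phased <- inherits(other_parent, "phased_genome")
    oh1 <- if (is_phased) other_parent$hap1[oidx[het]] else rep(NA_integer_, length(het))
    oh2 <- if (is_phased) other_parent$hap2[oidx[het]] else rep(NA_integer_, length(het))
    oth <- oth_dos[oidx[het]]
    b1 <- ifelse(!is.na(oh1) & !is.na(oh2), oh1,
                 ifelse(!is.na(oth) & oth != 1L, oth / 2L, NA_integer_))
    b2 <- ifelse(!is.na(oh1) & !is.na(oh2), oh2,
                 ifelse(!is.na(oth) & oth != 1L, oth / 2L, NA_integer_))
    # per-embryo emission array: [this-parent allele a + 1, other hap h', site]
    emis <- lapply(embryos, function(e) {
      oc <- ifelse(is.na(e$call[het]), 4L, e$call[het] + 1L)
      em <- array(0, dim = c(2, 2, length(het)))
      for (a in 0:1) for (hp in 1:2) {
        b <- if (hp == 1L) b1 else b2
        marg <- 0.5 * E[cbind(a + 1L, oc)] + 0.5 * E[cbind(a + 2L, oc)]
        fixed <- E[cbind(a + ifelse(is.na(b), 0L, b) + 1L, oc)]
        em[a + 1L, hp, ] <- ifelse(is.na(b), marg, fixed)
      }
      em
    })
    # orientation reliability of the other parent's phase across each
    # inter-site step: product of its step confidences at its phased-het
    # sites inside the interval (1 when no confidence is supplied). An
    # orientation error acts like an extra switch of the other parent's
    # haplotype labels, so it is folded into its transition probability.
    ohet <- which(!is.na(oh1) & !is.na(oh2) & oh1 != oh2)
    orient_q <- rep(0, max(length(het) - 1, 0))
    if (!is.null(other_confidence) && length(ohet) && length(het) > 1) {
      oc <- other_confidence[oidx[het[ohet]]]
      oc[is.na(oc)] <- 1
      opos <- pos[ohet]
      cum <- cumsum(log(pmax(oc, .Machine$double.xmin)))
      for (t in 2:length(het)) {
        k <- findInterval(c(pos[t - 1], pos[t]), opos)
        if (k[2] > k[1]) {
          orient_q[t - 1] <-
            1 - exp(cum[k[2]] - if (k[1] > 0) cum[k[1]] else 0)
        }
      }
    }
    # sequential chaining with a per-embryo forward filter over the joint
    # state (h = this parent's transmitted haplotype, h' = other parent's):
    # the relative-phase decision at site t is pairwise (t against the
    # established scaffold) but conditions on all observations left of t.
    # Refinement sweeps then revisit every decision with full left+right
    # conditioning, which resolves forward-pass ties that later sites
    # disambiguate. State order: s = h + 2*(h' - 1).
    k_het <- length(het)
    e4 <- function(e, j, xj) {
      al <- c(xj, 1L - xj)  # allele by h
      c(e[al + 1L, 1L, j], e[al + 1L, 2L, j])
    }
    Ts <- NULL
    if (k_het > 1) {
      d <- diff(cm_at(map, ch, pos))
      r <- haldane_r(pmax(d, 0))
      Ts <- lapply(seq_len(k_het - 1), function(t) {
        rh <- r[t]
        ro <- rh * (1 - orient_q[t]) + (1 - rh) * orient_q[t]
        Th <- matrix(c(1 - rh, rh, rh, 1 - rh), 2, 2)
        To <- matrix(c(1 - ro, ro, ro, 1 - ro), 2, 2)
        To %x% Th
      })
    }
    x <- integer(k_het)
    x[1] <- 1L  # arbitrary global labeling
    delta_site <- rep(Inf, k_het)  # aggregated decision evidence per site
    fwd <- lapply(emis, function(e) {
      f <- 0.25 * e4(e, 1L, x[1])
      f / max(sum(f), .Machine$double.xmin)
    })
    if (k_het > 1) {
      for (t in 2:k_het) {
        coupling <- x[t - 1]
        pred <- lapply(fwd, function(f) as.vector(crossprod(Ts[[t - 1]], f)))
        lr <- vapply(seq_along(emis), function(k) {
          ls <- sum(pred[[k]] * e4(emis[[k]], t, coupling))
          lf <- sum(pred[[k]] * e4(emis[[k]], t, 1L - coupling))
          log(max(ls, .Machine$double.xmin)) - log(max(lf, .Machine$double.xmin))
        }, 0)
        # order-invariant aggregation: sum the sorted per-embryo
        # log-likelihood ratios so embryo permutation cannot flip a
        # knife-edge decision through rounding
        delta <- sum(sort(lr))
        x[t] <- if (delta >= 0) coupling else 1L - coupling
        delta_site[t] <- abs(delta)
        fwd <- lapply(seq_along(emis), function(k) {
          f <- pred[[k]] * e4(emis[[k]], t, x[t])
          f / max(sum(f), .Machine$double.xmin)
        })
      }
      for (sweep in seq_len(refine_sweeps)) {
        res <- refine_phase_sweep(x, emis, Ts, e4)
        x <- res$x
        delta_site <- res$delta
        if (!res$changed) break
      }
    }
    conf[aidx[het]] <- 1 / (1 + exp(-delta_site))
    conf[aidx[het[1]]] <- 1
    hap1[aidx[het]] <- x
    hap2[aidx[het]] <- 1L - x
  }
  structure(list(genome = phased_genome(sites, hap1, hap2), confidence = conf),
            class = "phase_scaffold")
}

# one refinement sweep: re-evaluate every site's phase with full
# left-and-right conditioning (forward-backward per embryo under the
# current assignment) and flip sites the full-data likelihood disfavors
#' @noRd
refine_phase_sweep <- function(x, emis, Ts, e4) {
  k <- length(x)
  tiny <- .Machine$double.xmin
  lr <- matrix(0, length(emis), k)
  for (ke in seq_along(emis)) {
    e <- emis[[ke]]
    fpred <- matrix(0, 4, k)        # P(state_t | data left of t)
    fpred[, 1] <- 0.25
    f <- fpred[, 1] * e4(e, 1L, x[1])
    f <- f / max(sum(f), tiny)
    for (t in 2:k) {
      fpred[, t] <- as.vector(crossprod(Ts[[t - 1]], f))
      f <- fpred[, t] * e4(e, t, x[t])
      f <- f / max(sum(f), tiny)
    }
    b <- matrix(0, 4, k)            # P(data right of t | state_t), scaled
    b[, k] <- 1
    if (k > 1) {
      for (t in (k - 1):1) {
        v <- Ts[[t]] %*% (e4(e, t + 1L, x[t + 1]) * b[, t + 1])
        b[, t] <- v / max(sum(v), tiny)
      }
    }
    for (t in 1:k) {
      ls <- sum(fpred[, t] * e4(e, t, x[t]) * b[, t])
      lf <- sum(fpred[, t] * e4(e, t, 1L - x[t]) * b[, t])
      lr[ke, t] <- log(max(ls, tiny)) - log(max(lf, tiny))
    }
  }
  delta <- apply(lr, 2, function(v) sum(sort(v)))
  flip <- which(delta < 0)
  x[flip] <- 1L - x[flip]
  if (x[1] == 0L) x <- 1L - x   # labeling stays anchored at the first site
  list(x = x, delta = abs(delta), changed = length(flip) > 0)
}

#' Phase both parents, iterating so each benefits from the other's scaffold
#'
#' First pass phases each parent with the other's heterozygous contribution
#' marginalized per site (its phase is still unknown); subsequent passes
#' re-phase each parent against the other's current scaffold, which lets
#' the pair likelihood sum over the other parent's transmitted haplotype
#' proper and resolves most configurations that are ambiguous under
#' independent marginalization (e.g. both parents heterozygous at both
#' sites of a pair). Two passes are enough in practice; further passes
#' change very little.
#'
#' @inheritParams phase_parent
#' @param mother,father parental genotypes ([phased_genome()]s; input phase
#'   is ignored).
#' @param passes number of phasing passes (>= 1).
#' @return list with `mother` and `father` [phase_parent()] scaffolds.
#' @export
phase_parents <- function(mother, father, embryos, map,
                          profile = noise_profile("none"), passes = 2) {
  strip <- function(g) as_genotypes(g)
  sc_m <- phase_parent(mother, strip(father), embryos, map, profile)
  sc_p <- phase_parent(father, sc_m$genome, embryos, map, profile,
                       other_confidence = sc_m$confidence)
  for (k in seq_len(passes - 1)) {
    sc_m <- phase_parent(mother, sc_p$genome, embryos, map, profile,
                         other_confidence = sc_p$confidence)
    sc_p <- phase_parent(father, sc_m$genome, embryos, map, profile,
                         other_confidence = sc_m$confidence)
  }
  list(mother = sc_m, father = sc_p)
}

#' @export
print.phase_scaffold <- function(x, ...) {
  phased <- sum(!is.na(x$confidence))
  cat(sprintf("<phase_scaffold> %d het site(s) phased, median confidence %.4f\n",
              phased, stats::median(x$confidence, na.rm = TRUE)))
  invisible(x)
}

#' Anchor an externally phased genome to a parental-support scaffold
#'
#' Reference-panel phasing (an upstream external tool) labels haplotypes
#' arbitrarily per block; the embryo-derived scaffold fixes the labeling of
#' the physically transmitted chromosomes. At every site shared between the
#' two (heterozygous, phased in both) the orientation of the external phase
#' relative to the scaffold is recorded; orientation blocks between flips
#' are re-labeled so the result agrees with the scaffold at all scaffold
#' sites, while dense external sites inside each block keep their panel
#' phase relative to the anchoring scaffold sites. Sites present only in
#' the scaffold are appended with their scaffold phase.
#'
#' A warning (suspected sample swap) is raised when more than 40% of shared
#' sites on a chromosome disagree with the chromosome's majority
#' orientation.
#'
#' @param scaffold a [phase_parent()] result.
#' @param external an externally phased [phased_genome()] covering a
#'   superset of the scaffold's phased sites.
#' @return a [phased_genome()] over the union of site lists.
#' @export
merge_with_truth_phase <- function(scaffold, external) {
  stopifnot(inherits(scaffold, "phase_scaffold"))
  sg <- scaffold$genome
  sc_idx <- which(!is.na(sg$hap1) & !is.na(sg$hap2) & sg$hap1 != sg$hap2)
  ext_sites <- external$sites
  hap1 <- external$hap1; hap2 <- external$hap2
  m <- match_sites(sg$sites[sc_idx, , drop = FALSE], ext_sites)
  shared <- which(!is.na(m) & !is.na(hap1[m]) & !is.na(hap2[m]) &
                  hap1[m] != hap2[m])
  for (ch in unique(ext_sites$chrom)) {
    sh <- shared[sg$sites$chrom[sc_idx[shared]] == ch]
    if (!length(sh)) next
    anchor_pos <- sg$sites$pos[sc_idx[sh]]
    o <- hap1[m[sh]] == sg$hap1[sc_idx[sh]]  # TRUE = same orientation
    # a swapped/unrelated sample flips orientation at ~50% of adjacent
    # anchors; genuine block relabeling flips rarely
    if (length(o) > 1 && mean(diff(o) != 0) > 0.4) {
      wgr_warn(sprintf("chromosome %s: orientation flips at %.0f%% of adjacent scaffold sites (suspected sample swap)",
                       ch, 100 * mean(diff(o) != 0)), "sample_swap")
    }
    on_ch <- which(ext_sites$chrom == ch)
    blk <- pmax(findInterval(ext_sites$pos[on_ch], anchor_pos), 1L)
    flip <- on_ch[!o[blk]]
    tmp <- hap1[flip]; hap1[flip] <- hap2[flip]; hap2[flip] <- tmp
  }
  # append scaffold-only sites with their scaffold phase
  only <- sc_idx[is.na(m)]
  if (length(only)) {
    all_sites <- rbind(as.data.frame(ext_sites), as.data.frame(sg$sites[only, ]))
    st <- site_table(all_sites$chrom, all_sites$pos, all_sites$ref,
                     all_sites$alt, all_sites$id)
    h1 <- c(hap1, sg$hap1[only]); h2 <- c(hap2, sg$hap2[only])
    ord <- match(site_key(st), c(site_key(ext_sites), site_key(sg$sites[only, , drop = FALSE])))
    return(phased_genome(st, h1[ord], h2[ord]))
  }
  phased_genome(ext_sites, hap1, hap2)
}

#' Place rare heterozygous variants onto parental haplotypes
#'
#' Rare variants are absent from reference panels and must be phased from
#' direct physical evidence (e.g. linked reads). Each variant supplies
#' either an explicit haplotype index or a linked anchor site: the rare
#' alternate allele is then placed on the haplotype that carries the
#' anchor's alternate allele. Variants whose anchor is missing or unphased
#' are left unphased and flagged.
#'
#' @param genome a phased parental [phased_genome()].
#' @param rare data.frame with columns `chrom`, `pos`, `ref`, `alt`, and
#'   either `hap` (1/2, NA to use the anchor) or `anchor_chrom`/`anchor_pos`.
#' @return list: `genome` (with the rare sites inserted) and `report`
#'   (per variant: assigned `hap` or NA, `flag`).
#' @export
attach_rare_variants <- function(genome, rare) {
  n <- nrow(rare)
  hap_out <- rep(NA_integer_, n)
  flag <- rep("placed", n)
  for (i in seq_len(n)) {
    h <- if ("hap" %in% names(rare)) rare$hap[i] else NA
    if (is.na(h)) {
      if (!all(c("anchor_chrom", "anchor_pos") %in% names(rare))) {
        flag[i] <- "no_evidence"; next
      }
      a <- which(genome$sites$chrom == normalize_chrom(as.character(rare$anchor_chrom[i])) &
                 genome$sites$pos == rare$anchor_pos[i])
      if (!length(a)) { flag[i] <- "anchor_missing"; next }
      if (is.na(genome$hap1[a]) || is.na(genome$hap2[a]) ||
          genome$hap1[a] == genome$hap2[a]) {
        flag[i] <- "anchor_unphased"; next
      }
      h <- if (genome$hap1[a] == 1L) 1L else 2L
    }
    hap_out[i] <- as.integer(h)
  }
  placed <- which(!is.na(hap_out))
  new_sites <- rbind(as.data.frame(genome$sites),
                     data.frame(chrom = normalize_chrom(as.character(rare$chrom)),
                                pos = as.integer(rare$pos),
                                ref = rare$ref, alt = rare$alt,
                                id = paste0(normalize_chrom(as.character(rare$chrom)),
                                            ":", rare$pos)))
  h1 <- c(genome$hap1, ifelse(!is.na(hap_out) & hap_out == 1L, 1L,
                              ifelse(!is.na(hap_out), 0L, NA_integer_)))
  h2 <- c(genome$hap2, ifelse(!is.na(hap_out) & hap_out == 2L, 1L,
                              ifelse(!is.na(hap_out), 0L, NA_integer_)))
  st <- site_table(new_sites$chrom, new_sites$pos, new_sites$ref,
                   new_sites$alt, new_sites$id)
  key_in <- c(site_key(genome$sites),
              paste0(normalize_chrom(as.character(rare$chrom)), ":", rare$pos))
  ord <- match(site_key(st), key_in)
  list(genome = phased_genome(st, h1[ord], h2[ord]),
       report = data.frame(chrom = normalize_chrom(as.character(rare$chrom)),
                           pos = rare$pos, hap = hap_out, flag = flag,
                           stringsAsFactors = FALSE))
}
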