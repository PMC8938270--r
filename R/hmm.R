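#' @noRd
#' state indexing: s = m + 2*(p-1); m,p = transmitted haplotype of mother/father
state_m <- c(1L, 2L, 1L, 2L)
state_p <- c(1L, 1L, 2L, 2L)

# 4x4 joint transition matrix given per-parent switch probabilities
#' @noRd
joint_transition <- function(rm, rp) {
  tm <- matrix(c(1 - rm, rm, rm, 1 - rm), 2, 2)
  tp <- matrix(c(1 - rp, rp, rp, 1 - rp), 2, 2)
  tp %x% tm
}

# emission probabilities for the 4 states at each informative site:
# rows = states, cols = sites
#' @noRd
state_emissions <- function(call, m_hap1, m_hap2, p_hap1, p_hap2, profile) {
  E <- emission_matrix(profile)
  obs_col <- ifelse(is.na(call), 4L, call + 1L)
  mat_allele <- rbind(m_hap1, m_hap2, m_hap1, m_hap2)
  pat_allele <- rbind(p_hap1, p_hap1, p_hap2, p_hap2)
  g <- mat_allele + pat_allele
  em <- matrix(E[cbind(as.vector(g) + 1L, rep(obs_col, each = 4L))], nrow = 4L)
  em
}

#' Decode the transmitted parental haplotypes of one embryo
#'
#' The transmitted-haplotype hidden Markov model: the hidden state at each
#' informative array site (a site heterozygous in at least one parent) is the
#' pair (m, p) of parental haplotype indices the embryo inherited from its
#' mother and father. Transitions between adjacent informative sites
#' factorize per parent — meioses are independent — with per-parent switch
#' probability given by the Haldane map function of the inter-site genetic
#' distance. Emissions are the probability of the observed array call given
#' the genotype implied by the state, under the biopsy noise profile
#' ([emission_matrix()]).
#'
#' Both decodings are returned: the Viterbi (jointly most likely) path, from
#' which haplotype segments and recombination breakpoints are derived, and
#' forward-backward posterior marginals, which supply per-site confidence.
#' A breakpoint is reported as the full interval between the flanking
#' informative sites — the crossover is localized no better than that.
#'
#' @param obs an [embryo_obs()].
#' @param mother,father [phased_genome()]s over the full parental site list.
#' @param map a [genetic_map()].
#' @param profile a [noise_profile()]; the HMM emission model.
#' @param phase_confidence optional numeric vector over mother's/father's
#'   sites — currently used only to mark low-confidence phase sites in the
#'   per-site output (see [fill_genome()]).
#' @return An object of class `transmission_path` with elements
#'   \describe{
#'     \item{segments}{data.frame (chrom, parent, start, end, hap,
#'       mean_posterior): Viterbi haplotype segments tiling each decoded
#'       chromosome, boundaries at midpoints of breakpoint intervals.}
#'     \item{breakpoints}{data.frame (chrom, parent, left_pos, right_pos):
#'       the crossover lies strictly between the flanking informative sites.}
#'     \item{sites}{per informative site: Viterbi haplotype indices and
#'       posterior probability that haplotype 1 is transmitted, per parent.}
#'     \item{loglik}{total observation log-likelihood.}
#'     \item{aneuploid}{chromosomes skipped because the observation flags
#'       them aneuploid.}
#'   }
#' @export
decode_transmission <- function(obs, mother, father, map,
                                profile = noise_profile("none"),
                                phase_confidence = NULL) {
  stopifnot(inherits(obs, "embryo_obs"))
  idx_all <- match_sites(obs$sites, mother$sites)
  if (anyNA(idx_all)) wgr_stop("array sites absent from parental genome", "sites")

  chroms <- setdiff(unique(obs$sites$chrom), obs$aneuploid)
  seg_rows <- list(); bp_rows <- list(); site_rows <- list()
  loglik <- 0; viterbi_loglik <- 0
  for (ch in chroms) {
    on_ch <- which(obs$sites$chrom == ch)
    pidx <- idx_all[on_ch]
    informative <- is_het(mother)[pidx] | is_het(father)[pidx]
    informative[is.na(informative)] <- FALSE
    if (!any(informative)) {
      wgr_stop(sprintf("chromosome %s has no informative sites (both parents homozygous everywhere)", ch),
               "uninformative")
    }
    keep <- on_ch[informative]
    pk <- idx_all[keep]
    pos <- obs$sites$pos[keep]
    em <- state_emissions(obs$call[keep],
                          mother$hap1[pk], mother$hap2[pk],
                          father$hap1[pk], father$hap2[pk], profile)
    d_cm <- diff(cm_at(map, ch, pos))
    r <- haldane_r(pmax(d_cm, 0))
    dec <- hmm_decode(em, r)
    loglik <- loglik + dec$loglik
    viterbi_loglik <- viterbi_loglik + dec$viterbi_loglik

    m_hap <- state_m[dec$viterbi]
    p_hap <- state_p[dec$viterbi]
    post_m1 <- colSums(dec$posterior[state_m == 1L, , drop = FALSE])
    post_p1 <- colSums(dec$posterior[state_p == 1L, , drop = FALSE])
    m_het <- is_het(mother)[pk]
    p_het <- is_het(father)[pk]
    site_rows[[ch]] <- data.frame(
      chrom = ch, pos = pos,
      m_hap = m_hap, p_hap = p_hap,
      m_post_hap1 = post_m1, p_post_hap1 = post_p1,
      m_het = m_het, p_het = p_het
    )
    ext <- range(mother$sites$pos[mother$sites$chrom == ch])
    for (par in c("mother", "father")) {
      # segment structure is read off the sites heterozygous in THIS parent:
      # only they carry signal about this parent's transmitted haplotype, so
      # breakpoint intervals are bounded by them
      inf <- if (par == "mother") m_het else p_het
      hap <- if (par == "mother") m_hap else p_hap
      post1 <- if (par == "mother") post_m1 else post_p1
      sb <- if (any(inf)) {
        segments_from_path(ch, par, pos[inf], hap[inf], post1[inf], ext)
      } else {
        # parent homozygous at every informative site: transmission is
        # observationally irrelevant here; emit one arbitrary segment
        list(segments = data.frame(chrom = ch, parent = par, start = ext[1],
                                   end = ext[2], hap = hap[1],
                                   mean_posterior = 0.5),
             breakpoints = empty_breakpoints())
      }
      seg_rows[[paste(ch, par)]] <- sb$segments
      bp_rows[[paste(ch, par)]] <- sb$breakpoints
    }
  }
  structure(list(
    segments = do.call(rbind, unname(seg_rows)),
    breakpoints = if (length(bp_rows)) do.call(rbind, unname(bp_rows)) else
      empty_breakpoints(),
    sites = do.call(rbind, unname(site_rows)),
    loglik = loglik,
    viterbi_loglik = viterbi_loglik,
    aneuploid = intersect(unique(obs$sites$chrom), obs$aneuploid)
  ), class = "transmission_path")
}

# forward-backward (scaled) + Viterbi over the 4-state chain.
# em: 4 x n emission matrix; r: per-parent switch probabilities (length n-1,
# shared by both parents since distances are sex-averaged here).
#' @noRd
hmm_decode <- function(em, r) {
  n <- ncol(em)
  pi0 <- rep(0.25, 4)
  alpha <- matrix(0, 4, n); beta <- matrix(0, 4, n)
  scale <- numeric(n)
  a <- pi0 * em[, 1]
  scale[1] <- sum(a)
  alpha[, 1] <- a / scale[1]
  Ts <- vector("list", if (n > 1) n - 1 else 0)
  if (n > 1) {
    for (t in 2:n) {
      Ts[[t - 1]] <- joint_transition(r[t - 1], r[t - 1])
      a <- as.vector(crossprod(Ts[[t - 1]], alpha[, t - 1])) * em[, t]
      scale[t] <- sum(a)
      alpha[, t] <- a / scale[t]
    }
  }
  beta[, n] <- 1
  if (n > 1) {
    for (t in (n - 1):1) {
      b <- Ts[[t]] %*% (beta[, t + 1] * em[, t + 1])
      beta[, t] <- b / scale[t + 1]
    }
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")

  # Viterbi in log space; ties broken toward the lowest state index
  lg <- function(x) log(pmax(x, .Machine$double.xmin))
  delta <- matrix(-Inf, 4, n); psi <- matrix(0L, 4, n)
  delta[, 1] <- lg(pi0) + lg(em[, 1])
  if (n > 1) {
    for (t in 2:n) {
      lT <- lg(Ts[[t - 1]])
      cand <- delta[, t - 1] + lT          # rows: from, cols: to
      psi[, t] <- max.col(t(cand), ties.method = "first")
      delta[, t] <- cand[cbind(psi[, t], 1:4)] + lg(em[, t])
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[, n])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[path[t + 1], t + 1]
  list(posterior = post, viterbi = path,
       loglik = sum(log(scale)), viterbi_loglik = max(delta[, n]))
}

# Viterbi path -> tiling segments + breakpoint intervals for one parent
#' @noRd
segments_from_path <- function(chrom, parent, pos, hap, post_hap1, extent) {
  conf <- ifelse(hap == 1L, post_hap1, 1 - post_hap1)
  runs <- rle(hap)
  ends_i <- cumsum(runs$lengths)
  starts_i <- c(1L, utils::head(ends_i, -1) + 1L)
  left <- pos[ends_i[-length(ends_i)]]
  right <- pos[starts_i[-1]]
  cut <- floor((left + right) / 2)
  seg_start <- c(min(extent[1], pos[1]), cut + 1)
  seg_end <- c(cut, max(extent[2], pos[length(pos)]))
  mean_post <- vapply(seq_along(runs$values), function(i) {
    mean(conf[starts_i[i]:ends_i[i]])
  }, 0)
  list(
    segments = data.frame(chrom = chrom, parent = parent,
                          start = seg_start, end = seg_end,
                          hap = runs$values, mean_posterior = mean_post),
    breakpoints = if (length(left))
      data.frame(chrom = chrom, parent = parent,
                 left_pos = left, right_pos = right)
    else empty_breakpoints()
  )
}

#' @noRd
empty_breakpoints <- function() {
  data.frame(chrom = character(), parent = character(),
             left_pos = numeric(), right_pos = numeric())
}

#' @export
print.transmission_path <- function(x, ...) {
  cat(sprintf("<transmission_path> %d segment(s), %d breakpoint(s) across %d chromosome(s); loglik %.3f\n",
              nrow(x$segments), nrow(x$breakpoints),
              length(unique(x$segments$chrom)), x$loglik))
  if (length(x$aneuploid))
    cat("  aneuploid (skipped):", paste(x$aneuploid, collapse = ", "), "\n")
  invisible(x)
}
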