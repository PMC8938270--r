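# small in-code fixture builders shared across test files

toy_sites <- function(n, chrom = "1", start = 1e6, spacing = 1e6) {
  bases <- c("A", "C", "G", "T")
  site_table(rep(chrom, n), start + (seq_len(n) - 1) * spacing,
             rep("A", n), rep("G", n))
}

# phased parent from explicit haplotype allele vectors
toy_parent <- function(sites, hap1, hap2) phased_genome(sites, hap1, hap2)

# a random single-chromosome decode instance for the HMM oracle tests:
# random parental haplotypes (>= 1 informative site), random calls, random
# noise and map distances
random_hmm_instance <- function(n) {
  sites <- toy_sites(n, spacing = sample(c(2e5, 1e6, 5e6), 1))
  repeat {
    m <- toy_parent(sites, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    f <- toy_parent(sites, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    if (all(is_het(m) | is_het(f))) break
  }
  call <- sample(c(0:2, NA), n, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
  prof <- noise_profile(ado = runif(1, 0.01, 0.3), error = runif(1, 0.001, 0.05),
                        missing = runif(1, 0.01, 0.2))
  map <- uniform_map(sites, rate_cM_per_Mb = runif(1, 0.5, 3))
  list(sites = sites, mother = m, father = f,
       obs = embryo_obs(sites, call), profile = prof, map = map)
}

# oracle emissions for a decode instance (states x sites), built from
# first principles
oracle_emissions <- function(inst) {
  n <- nrow(inst$sites)
  em <- matrix(0, 4, n)
  for (t in 1:n) {
    for (s in 1:4) {
      mhap <- ((s - 1) %% 2) + 1
      phap <- ((s - 1) %/% 2) + 1
      g <- (if (mhap == 1) inst$mother$hap1[t] else inst$mother$hap2[t]) +
        (if (phap == 1) inst$father$hap1[t] else inst$father$hap2[t])
      em[s, t] <- oracle_call_prob(inst$obs$call[t], g, inst$profile$ado,
                                   inst$profile$error, inst$profile$missing)
    }
  }
  em
}

# switch-error count/denominator of a phased genome vs the truth phase
count_switch_errors <- function(genome, truth) {
  het <- which(!is.na(genome$hap1) & genome$hap1 != genome$hap2)
  agree <- genome$hap1[het] == truth$hap1[het]
  sw <- 0; tot <- 0
  for (ch in unique(genome$sites$chrom[het])) {
    a <- agree[genome$sites$chrom[het] == ch]
    if (length(a) > 1) {
      sw <- sw + sum(diff(a) != 0)
      tot <- tot + length(a) - 1
    }
  }
  c(errors = sw, pairs = tot)
}

# strip phase from a parent (keep genotypes only)
unphase <- function(g) list(sites = g$sites, dosage = dosages(g))
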