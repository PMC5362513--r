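# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately share no code with the package paths
# they verify.

# Per-lineage branching-process simulator: every molecule is an explicit
# record; each cycle it duplicates with probability p, and a copy of a
# reference molecule mutates with probability e. Tracks one locus.
lineage_sim <- function(n0, cycles, p, e) {
  alleles <- rep("ref", n0)
  for (cyc in seq_len(cycles)) {
    dup <- runif(length(alleles)) < p
    copies <- alleles[dup]
    mut <- copies == "ref" & runif(length(copies)) < e
    copies[mut] <- "alt"
    alleles <- c(alleles, copies)
  }
  c(total = length(alleles), mutant = sum(alleles == "alt"))
}

# Exhaustive enumeration of the expected allele composition of the
# branching process: states are (n_ref, n_alt) with probabilities; each
# cycle every ref molecule independently does nothing (1-p), duplicates
# cleanly (p(1-e)) or duplicates with a mutant copy (pe); alt molecules do
# nothing (1-p) or duplicate (p).
enumerate_branching <- function(n0, cycles, p, e) {
  states <- list(list(ref = n0, alt = 0, prob = 1))
  ref_outcomes <- list(c(0, 0, 1 - p), c(1, 0, p * (1 - e)), c(0, 1, p * e))
  alt_outcomes <- list(c(0, 0, 1 - p), c(0, 1, p))
  expand_one <- function(n, outcomes) {
    # distribution of (added_ref, added_alt) over n iid molecules
    acc <- list(c(0, 0, 1))
    for (i in seq_len(n)) {
      nxt <- list()
      for (a in acc) for (o in outcomes)
        nxt[[length(nxt) + 1]] <- c(a[1] + o[1], a[2] + o[2], a[3] * o[3])
      acc <- nxt
    }
    acc
  }
  for (cyc in seq_len(cycles)) {
    nxt <- list()
    for (s in states) {
      ref_add <- expand_one(s$ref, ref_outcomes)
      alt_add <- expand_one(s$alt, alt_outcomes)
      for (ra in ref_add) for (aa in alt_add)
        nxt[[length(nxt) + 1]] <- list(ref = s$ref + ra[1] + aa[1],
                                       alt = s$alt + ra[2] + aa[2],
                                       prob = s$prob * ra[3] * aa[3])
    }
    states <- nxt
  }
  e_total <- sum(vapply(states, function(s) (s$ref + s$alt) * s$prob, 0))
  e_mut <- sum(vapply(states, function(s) s$alt * s$prob, 0))
  p_tot <- sum(vapply(states, function(s) s$prob, 0))
  list(e_total = e_total, e_mutant = e_mut, prob_mass = p_tot)
}

# Brute-force repeat scanner: examines every substring.
brute_repeats <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  max_homo <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    sub <- chars[i:j]
    if (length(unique(sub)) == 1L) max_homo <- max(max_homo, length(sub))
  }
  max_di <- 0L
  for (i in seq_len(n)) {
    for (units in 1:floor((n - i + 1) / 2)) {
      sub <- chars[i:(i + 2 * units - 1)]
      unit <- sub[1:2]
      if (identical(sub, rep(unit, units))) max_di <- max(max_di, units)
    }
  }
  list(max_homopolymer_len = max_homo, max_dinucleotide_repeat_units = max_di)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (no zeros/ties assumed).
enumerate_signed_rank <- function(d) {
  n <- length(d)
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[unlist(s)]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small synthetic allele-count cohort builder for filter tests.
make_counts <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r$s, locus_id = r$l, allele = r$a,
               fwd_count = r$f, rev_count = r$r,
               mean_base_quality = 35, mean_mapq = 60,
               stringsAsFactors = FALSE)
  }))
}
rowspec <- function(s, l, a, f, r) list(s = s, l = l, a = a, f = f, r = r)
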