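#' Polymerase fidelity profile
#'
#' Vendor-reported error rates are genome-averaged; observed artifact rates
#' at specific loci can exceed them substantially, so a profile carries a
#' base rate plus per-locus multipliers. The effective per-base,
#' per-duplication substitution rate at a locus is
#' \code{base_error_rate * locus_multipliers[locus_id]} (multiplier 1 when a
#' locus is not listed).
#'
#' @param name polymerase label.
#' @param base_error_rate errors per base per template duplication, in
#'   [0, 1e-2].
#' @param locus_multipliers named numeric vector of dimensionless, finite,
#'   non-negative multipliers keyed by locus_id.
#' @param reported_rate vendor-reported numeric error rate, or NA when the
#'   vendor states only a bound.
#' @param reported_bound upper bound on the vendor rate when
#'   \code{reported_rate} is NA (e.g. "more than 100-fold better than Taq"
#'   becomes Taq_rate / 100).
#' @return object of class \code{polymerase_profile}.
#' @export
polymerase_profile <- function(name, base_error_rate, locus_multipliers = numeric(),
                               reported_rate = base_error_rate, reported_bound = NA_real_) {
  check_that(is.numeric(base_error_rate) && base_error_rate >= 0 && base_error_rate <= 1e-2,
             "base_error_rate must be in [0, 1e-2]")
  check_that(all(is.finite(locus_multipliers)) && all(locus_multipliers >= 0),
             "locus multipliers must be finite and >= 0")
  structure(
    list(name = name, base_error_rate = base_error_rate,
         locus_multipliers = locus_multipliers,
         reported_rate = reported_rate, reported_bound = reported_bound),
    class = "polymerase_profile"
  )
}

#' @export
print.polymerase_profile <- function(x, ...) {
  cat(sprintf("<polymerase_profile> %s: base rate %.3g per base per duplication\n",
              x$name, x$base_error_rate))
  if (length(x$locus_multipliers))
    cat("  locus multipliers:",
        paste(sprintf("%s=%.3g", names(x$locus_multipliers), x$locus_multipliers),
              collapse = ", "), "\n")
  invisible(x)
}

effective_error_rate <- function(profile, locus_id) {
  m <- profile$locus_multipliers
  mult <- if (locus_id %in% names(m)) unname(m[locus_id]) else 1
  profile$base_error_rate * mult
}

#' Default polymerase profiles for the AR hotspot assays
#'
#' Three profiles mirroring the enzymes used in the study workflow, with
#' vendor-reported fidelities: a Taq-class enzyme (HotStarTaq-like, reported
#' 2e-5 errors/base/duplication), a proofreading high-fidelity enzyme
#' (Phusion-like, reported 4.4e-7), and an engineered high-fidelity enzyme
#' (SuperFi-like, reported only as a bound: more than 100-fold better than
#' Taq, i.e. below 2e-7).
#'
#' Locus multipliers encode the observed locus-specific artifact propensity
#' and are the generator's default scenario: the Phusion-like F877L
#' multiplier is calibrated so the expected artifact fraction after 22
#' cycles is about 2.1e-4 (the mid-range of observed ddPCR artifact
#' fractions); its T878A multiplier derives from the preamplified wild-type
#' control (2 mutant / 36329 wild-type droplets at 22 cycles); the Taq-class
#' F877L multiplier targets an expected artifact fraction of about 0.2%
#' after a 22-cycle library workflow. W742C shows no artifact under any
#' enzyme and the SuperFi-like profile none anywhere; those multipliers
#' are 0.
#'
#' @return named list of [polymerase_profile()] objects.
#' @export
ar_polymerase_profiles <- function() {
  taq_rate <- 2e-5
  phusion_rate <- 4.4e-7
  # effective rates solved from expected_error_fraction(e, 22, 1) = c*e/2
  phusion_f877l_e <- 2 * 2.1e-4 / 22     # ~1.9e-5
  phusion_t878a_e <- 2 * (2 / 36329) / 22  # ~5.0e-6
  taq_f877l_e <- 2 * 0.002 / 22          # ~1.8e-4
  list(
    hotstartaq = polymerase_profile(
      "HotStarTaq-like", taq_rate,
      locus_multipliers = c(L702H = 0, W742C = 0, H875Y = 0,
                            F877L = taq_f877l_e / taq_rate, T878A = 0.25),
      reported_rate = taq_rate),
    phusion = polymerase_profile(
      "Phusion-like", phusion_rate,
      locus_multipliers = c(L702H = 0, W742C = 0, H875Y = 0,
                            F877L = phusion_f877l_e / phusion_rate,
                            T878A = phusion_t878a_e / phusion_rate),
      reported_rate = phusion_rate),
    superfi = polymerase_profile(
      "SuperFi-like", 2e-7,
      locus_multipliers = c(L702H = 0, W742C = 0, H875Y = 0, F877L = 0, T878A = 0),
      reported_rate = NA_real_, reported_bound = taq_rate / 100)
  )
}

#' Preamplification configuration
#'
#' @param input_genome_equivalents templates at cycle zero (haploid genome
#'   equivalents carrying the amplicon; AR is X-linked, so a male sample has
#'   one AR template per genome equivalent and a female sample two). The
#'   default reflects three pooled 1 ng reactions at ~303 genome
#'   equivalents per ng.
#' @param cycles number of PCR cycles (the assays here use 12 or 22).
#' @param efficiency per-cycle duplication probability in (0, 1].
#' @param rng_seed optional integer seed.
#' @param molecule_cap pool size above which per-molecule binomial sampling
#'   switches to a deterministic-growth approximation (mutant lineages are
#'   still sampled stochastically); results are flagged \code{approximate}.
#' @return object of class \code{amplification_config}.
#' @export
amplification_config <- function(input_genome_equivalents = 3 * 303, cycles = 22,
                                 efficiency = 0.95, rng_seed = NULL,
                                 molecule_cap = 5e6) {
  check_that(is_count(input_genome_equivalents) && input_genome_equivalents >= 1,
             "input_genome_equivalents must be a positive integer")
  check_that(is_count(cycles) && cycles >= 1, "cycles must be >= 1")
  check_that(is.numeric(efficiency) && efficiency > 0 && efficiency <= 1,
             "efficiency must be in (0, 1]")
  structure(
    list(input_genome_equivalents = as.integer(input_genome_equivalents),
         cycles = as.integer(cycles), efficiency = efficiency,
         rng_seed = rng_seed, molecule_cap = molecule_cap),
    class = "amplification_config"
  )
}

#' Construct a template molecule pool
#'
#' Tracks, for each declared hotspot locus, how many template molecules
#' carry each alternate allele; all remaining molecules carry the reference
#' base at that locus. Loci are tracked marginally (no linkage between
#' sites), which is adequate at the allele fractions in play.
#'
#' @param n_templates total template molecules.
#' @param loci named list of [locus_spec()] objects.
#' @param alt_counts optional named list, locus_id -> named vector of
#'   molecule counts per alternate base.
#' @return object of class \code{molecule_pool}.
#' @export
molecule_pool <- function(n_templates, loci, alt_counts = list()) {
  check_that(is.numeric(n_templates) && n_templates >= 0, "n_templates must be >= 0")
  counts <- lapply(loci, function(l) {
    v <- stats::setNames(numeric(length(l$alt_bases)), l$alt_bases)
    got <- alt_counts[[l$locus_id]]
    if (!is.null(got)) {
      check_that(all(names(got) %in% l$alt_bases),
                 "alt_counts for %s names bases not in its alt spectrum", l$locus_id)
      v[names(got)] <- got
    }
    check_that(sum(v) <= n_templates, "alt molecules exceed pool size at %s", l$locus_id)
    v
  })
  names(counts) <- names(loci)
  structure(list(total = as.numeric(n_templates), loci = loci,
                 alt_counts = counts, approximate = FALSE),
            class = "molecule_pool")
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat(sprintf("<molecule_pool> %.6g molecules%s\n", x$total,
              if (x$approximate) " (approximate growth)" else ""))
  for (id in names(x$alt_counts)) {
    v <- x$alt_counts[[id]]
    if (any(v > 0))
      cat(sprintf("  %s: %s\n", id,
                  paste(sprintf("%s=%.6g", names(v), v), collapse = " ")))
  }
  invisible(x)
}

#' Pool allele fractions
#' @param pool a [molecule_pool()].
#' @return named list locus_id -> named fraction vector over ref + alts.
#' @export
allele_fractions <- function(pool) {
  lapply(stats::setNames(names(pool$loci), names(pool$loci)), function(id) {
    l <- pool$loci[[id]]
    alts <- pool$alt_counts[[id]]
    c(stats::setNames(pool$total - sum(alts), l$ref_base), alts) / pool$total
  })
}

#' Simulate PCR preamplification with polymerase error
#'
#' Stochastic branching process: each cycle, every molecule independently
#' produces one copy with probability \code{efficiency}; each newly
#' synthesized copy acquires a substitution at each tracked locus with
#' probability equal to the polymerase's effective error rate there
#' (alternate chosen uniformly from the locus's alt spectrum). Parents
#' persist unchanged; mutant copies propagate in later cycles.
#' Back-mutation is ignored (an e-squared effect, negligible at the rates
#' modelled).
#'
#' When the pool exceeds \code{molecule_cap}, bulk growth switches to its
#' expectation while new mutant lineages remain Poisson-sampled and existing
#' mutant lineages binomial-sampled; the result is flagged
#' \code{approximate}.
#'
#' @param pool starting [molecule_pool()].
#' @param polymerase a [polymerase_profile()].
#' @param config an [amplification_config()].
#' @return the post-amplification \code{molecule_pool}.
#' @export
simulate_preamplification <- function(pool, polymerase, config) {
  for (id in names(pool$loci)) {
    e <- effective_error_rate(polymerase, id)
    check_that(e < 0.01, "effective error rate at %s must be < 0.01", id)
  }
  with_seed(config$rng_seed, {
    p <- config$efficiency
    total <- pool$total
    alt_counts <- pool$alt_counts
    approximate <- pool$approximate
    for (cycle in seq_len(config$cycles)) {
      if (!approximate && total * (1 + p) > config$molecule_cap) approximate <- TRUE
      if (!approximate) {
        dup_total <- stats::rbinom(1, total, p)
        new_total <- total + dup_total
        for (id in names(alt_counts)) {
          e <- effective_error_rate(polymerase, id)
          alts <- alt_counts[[id]]
          n_alt <- sum(alts)
          # duplicated molecules are a simple random subset of the pool
          dup_alt_total <- if (n_alt > 0 && dup_total > 0)
            stats::rhyper(1, n_alt, total - n_alt, dup_total) else 0
          dup_alts <- if (dup_alt_total > 0) {
            as.vector(stats::rmultinom(1, dup_alt_total, alts / n_alt))
          } else rep(0, length(alts))
          dup_ref <- dup_total - dup_alt_total
          new_mut_total <- if (e > 0 && dup_ref > 0) stats::rbinom(1, dup_ref, e) else 0
          new_muts <- if (new_mut_total > 0) {
            as.vector(stats::rmultinom(1, new_mut_total, rep(1, length(alts))))
          } else rep(0, length(alts))
          alt_counts[[id]] <- alts + dup_alts + new_muts
        }
        total <- new_total
      } else {
        dup_total <- total * p   # expectation; bulk is effectively deterministic
        for (id in names(alt_counts)) {
          e <- effective_error_rate(polymerase, id)
          alts <- alt_counts[[id]]
          dup_alts <- vapply(alts, function(a) {
            if (a <= 0) 0
            else if (a < 1e7) stats::rbinom(1, round(a), p)
            else a * p
          }, numeric(1))
          dup_ref <- dup_total - sum(dup_alts)
          new_mut_total <- if (e > 0 && dup_ref > 0) stats::rpois(1, dup_ref * e) else 0
          new_muts <- if (new_mut_total > 0) {
            as.vector(stats::rmultinom(1, new_mut_total, rep(1, length(alts))))
          } else rep(0, length(alts))
          alt_counts[[id]] <- alts + dup_alts + new_muts
        }
        total <- total + dup_total
      }
    }
    out <- pool
    out$total <- total
    out$alt_counts <- alt_counts
    out$approximate <- approximate
    out
  })
}

#' Expected mutant allele fraction after preamplification
#'
#' Analytic companion to [simulate_preamplification()]. Under the
#' molecule-duplication model with efficiency 1, each cycle half of the
#' final molecules trace to new synthesis, giving an expected artifact
#' fraction of exactly cycles * e / 2. For efficiency p < 1 the linear
#' accumulation recurrence M' = M (1 + p) + e p T, T' = T (1 + p) is
#' iterated and M/T returned. (The simulator's exact expectation replaces
#' e p T with e p (T - M) -- new mutants arise only from reference-copy
#' synthesis -- which differs from this first-order law by O(e^2 cycles),
#' negligible at the rates modelled.)
#'
#' @param e effective per-base per-duplication error rate (e * cycles must
#'   be well below 1).
#' @param cycles number of cycles.
#' @param efficiency per-cycle duplication probability.
#' @return expected mutant allele fraction.
#' @examples
#' expected_error_fraction(1e-4, 22, 1)  # 22 * 1e-4 / 2 = 1.1e-3
#' @export
expected_error_fraction <- function(e, cycles, efficiency = 1) {
  check_that(e >= 0 && e * cycles < 1, "e * cycles must be << 1")
  check_that(is_count(cycles) && cycles >= 0, "cycles must be a non-negative integer")
  p <- efficiency
  total <- 1
  mut <- 0
  for (k in seq_len(cycles)) {
    mut <- mut * (1 + p) + e * p * total
    total <- total * (1 + p)
  }
  mut / total
}

#' Sequencing count-sampling configuration
#'
#' @param depth reads sampled per locus (the study's average coverage is
#'   10,000x).
#' @param seq_error_rate per-base miscall probability in [0, 1).
#' @param strand_balance expected forward-strand fraction in (0, 1).
#' @param quality_mean Phred score centre reported for retained reads.
#' @param mapq_mean mapping-quality centre.
#' @return object of class \code{ngs_sim_config}.
#' @export
ngs_sim_config <- function(depth = 10000, seq_error_rate = 5e-4,
                           strand_balance = 0.5, quality_mean = 35,
                           mapq_mean = 60) {
  check_that(is_count(depth) && depth >= 1, "depth must be >= 1")
  check_that(seq_error_rate >= 0 && seq_error_rate < 1, "seq_error_rate must be in [0,1)")
  check_that(strand_balance > 0 && strand_balance < 1, "strand_balance must be in (0,1)")
  structure(list(depth = as.integer(depth), seq_error_rate = seq_error_rate,
                 strand_balance = strand_balance, quality_mean = quality_mean,
                 mapq_mean = mapq_mean),
            class = "ngs_sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate deep-sequencing allele counts from a molecule pool
#'
#' Draws \code{depth} reads per locus multinomially from the pool's allele
#' fractions, applies uniform sequencing miscalls at
#' \code{seq_error_rate} (a miscalled read reports one of the other three
#' bases), assigns strands at \code{strand_balance}, and aggregates to
#' stranded allele-count records.
#'
#' @param pool a [molecule_pool()].
#' @param config an [ngs_sim_config()].
#' @param sample_id label placed on the emitted records.
#' @param rng_seed optional seed.
#' @return data.frame of allele-count records (sample_id, locus_id, allele,
#'   fwd_count, rev_count, mean_base_quality, mean_mapq); the reference
#'   allele row is always present, other bases only when observed.
#' @export
simulate_ngs_counts <- function(pool, config, sample_id = "sim", rng_seed = NULL) {
  check_that(pool$total > 0, "pool is empty")
  with_seed(rng_seed, {
    fracs <- allele_fractions(pool)
    rows <- list()
    for (id in names(fracs)) {
      l <- pool$loci[[id]]
      f <- fracs[[id]]
      true_reads <- as.vector(stats::rmultinom(1, config$depth, f))
      names(true_reads) <- names(f)
      called <- stats::setNames(numeric(4), BASES)
      for (b in names(true_reads)) {
        n <- true_reads[[b]]
        if (n == 0) next
        errs <- if (config$seq_error_rate > 0) stats::rbinom(1, n, config$seq_error_rate) else 0
        called[b] <- called[b] + n - errs
        if (errs > 0) {
          others <- setdiff(BASES, b)
          mis <- as.vector(stats::rmultinom(1, errs, rep(1, 3)))
          called[others] <- called[others] + mis
        }
      }
      for (b in BASES) {
        n <- called[[b]]
        if (n == 0 && b != l$ref_base) next
        fwd <- if (n > 0) stats::rbinom(1, n, config$strand_balance) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, locus_id = id, allele = b,
          fwd_count = fwd, rev_count = n - fwd,
          mean_base_quality = config$quality_mean, mean_mapq = config$mapq_mean,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate droplet digital PCR partitioning
#'
#' Molecules are loaded into droplets under Poisson occupancy: with
#' per-droplet means lambda_mut and lambda_wt, each droplet is
#' mutant-positive with probability 1 - exp(-lambda_mut) and wild-type
#' positive with probability 1 - exp(-lambda_wt), independently; droplet
#' class counts are drawn multinomially. Single-positive, double-positive
#' and negative droplets are reported separately.
#'
#' @param pool a [molecule_pool()].
#' @param locus_id which tracked locus the assay probes.
#' @param n_droplets droplet partitions (the instrument generates ~20,000).
#' @param sampled_molecules number of pool molecules loaded into the
#'   reaction (default: the whole pool).
#' @param sample_id,polymerase,cycles labels carried onto the result.
#' @param rng_seed optional seed.
#' @return a [droplet_data()] with \code{n_total} set.
#' @export
simulate_ddpcr <- function(pool, locus_id, n_droplets = 20000,
                           sampled_molecules = NULL, sample_id = "sim",
                           polymerase = NA_character_, cycles = NA_integer_,
                           rng_seed = NULL) {
  check_that(is_count(n_droplets) && n_droplets >= 1, "n_droplets must be >= 1")
  check_that(locus_id %in% names(pool$loci), "locus %s not tracked in pool", locus_id)
  with_seed(rng_seed, {
    n_alt <- sum(pool$alt_counts[[locus_id]])
    n_ref <- pool$total - n_alt
    if (!is.null(sampled_molecules) && sampled_molecules < pool$total) {
      q <- n_alt / pool$total
      n_alt <- stats::rbinom(1, round(sampled_molecules), q)
      n_ref <- round(sampled_molecules) - n_alt
    }
    lam_mut <- n_alt / n_droplets
    lam_wt <- n_ref / n_droplets
    pm <- 1 - exp(-lam_mut)
    pw <- 1 - exp(-lam_wt)
    probs <- c(mut = pm * (1 - pw), wt = pw * (1 - pm),
               dbl = pm * pw, neg = (1 - pm) * (1 - pw))
    cls <- as.vector(stats::rmultinom(1, n_droplets, probs))
    droplet_data(sample_id = sample_id, locus_id = locus_id,
                 polymerase = polymerase, cycles = cycles,
                 n_mut_pos = cls[1], n_wt_pos = cls[2],
                 n_double_pos = cls[3], n_neg = cls[4],
                 n_total = n_droplets)
  })
}

#' Simulate a full study cohort
#'
#' Generates the paired data structures of the study design: one
#' deep-sequencing allele-count table over the declared hotspot loci for
#' every patient plus healthy male and female control donors, and per
#' high-fidelity polymerase a ddPCR droplet table over the validation loci
#' for every patient plus a preamplified wild-type genomic control and a
#' no-template control. True mutations are injected into template pools
#' before amplification; all other mutant signal arises from polymerase
#' error during preamplification and from sequencing miscalls.
#'
#' AR is X-linked: male samples carry one AR template per genome
#' equivalent, female two; patients are male (prostate cancer cohort).
#'
#' @param n_patients number of patients.
#' @param true_mutations named list, sample_id -> list(locus_id, af) with
#'   allele fraction in [0, 0.5].
#' @param loci named list of [locus_spec()] (default [ar_hotspot_loci()]).
#' @param ngs_polymerase profile used in the sequencing library workflow
#'   (default the Taq-class profile).
#' @param ddpcr_polymerases named list of profiles used for ddPCR
#'   preamplification (default the Phusion-like and SuperFi-like profiles).
#' @param amp_config an [amplification_config()]; its seed field is ignored
#'   (use \code{rng_seed}).
#' @param ngs_config an [ngs_sim_config()].
#' @param ddpcr_loci loci assayed by ddPCR (default F877L, T878A, W742C).
#' @param n_droplets droplets per ddPCR well.
#' @param rng_seed integer seed; output is fully deterministic given it.
#' @return list with \code{ngs_counts} (allele-count data.frame),
#'   \code{ddpcr} (droplet-count data.frame with sample_type column), and
#'   \code{truth}.
#' @export
simulate_cohort <- function(n_patients = 11,
                            true_mutations = list(`Pt 3` = list(locus_id = "W742C", af = 0.0046)),
                            loci = ar_hotspot_loci(),
                            ngs_polymerase = ar_polymerase_profiles()$hotstartaq,
                            ddpcr_polymerases = ar_polymerase_profiles()[c("phusion", "superfi")],
                            amp_config = amplification_config(),
                            ngs_config = ngs_sim_config(),
                            ddpcr_loci = c("F877L", "T878A", "W742C"),
                            n_droplets = 20000,
                            rng_seed = 1L) {
  for (tm in true_mutations)
    check_that(tm$af >= 0 && tm$af <= 0.5, "true-mutation allele fractions must be in [0, 0.5]")
  with_seed(rng_seed, {
    samples <- data.frame(
      sample_id = c(paste("Pt", seq_len(n_patients)), "Male Control", "Female Control"),
      sample_type = c(rep("patient", n_patients), "wt_control", "wt_control"),
      sex = c(rep("male", n_patients), "male", "female"),
      stringsAsFactors = FALSE)
    make_pool <- function(sample_id, sex) {
      n_templates <- amp_config$input_genome_equivalents * if (sex == "female") 2L else 1L
      alt_counts <- list()
      tm <- true_mutations[[sample_id]]
      if (!is.null(tm)) {
        l <- loci[[tm$locus_id]]
        alt_counts[[tm$locus_id]] <-
          stats::setNames(round(tm$af * n_templates), l$alt_bases[1])
      }
      molecule_pool(n_templates, loci, alt_counts)
    }
    cfg_noseed <- amp_config
    cfg_noseed$rng_seed <- NULL

    # sequencing arm: library preamplification then count sampling
    ngs_rows <- lapply(seq_len(nrow(samples)), function(i) {
      pool <- make_pool(samples$sample_id[i], samples$sex[i])
      amp <- simulate_preamplification(pool, ngs_polymerase, cfg_noseed)
      simulate_ngs_counts(amp, ngs_config, sample_id = samples$sample_id[i])
    })
    ngs_counts <- do.call(rbind, ngs_rows)

    # ddPCR arm: per polymerase, patients + preamplified wild-type genomic
    # control + no-template control
    ddpcr_rows <- list()
    for (pname in names(ddpcr_polymerases)) {
      prof <- ddpcr_polymerases[[pname]]
      dd_samples <- rbind(
        samples[samples$sample_type == "patient", ],
        data.frame(sample_id = "WT Genomic DNA", sample_type = "wt_control", sex = "female",
                   stringsAsFactors = FALSE),
        data.frame(sample_id = "No Template Control", sample_type = "ntc", sex = "male",
                   stringsAsFactors = FALSE))
      for (i in seq_len(nrow(dd_samples))) {
        sid <- dd_samples$sample_id[i]
        if (dd_samples$sample_type[i] == "ntc") {
          amp <- molecule_pool(0, loci)
        } else {
          pool <- make_pool(sid, dd_samples$sex[i])
          amp <- simulate_preamplification(pool, prof, cfg_noseed)
        }
        for (lid in ddpcr_loci) {
          d <- if (amp$total == 0) {
            droplet_data(sample_id = sid, locus_id = lid, polymerase = prof$name,
                         cycles = cfg_noseed$cycles, n_mut_pos = 0, n_wt_pos = 0,
                         n_double_pos = 0, n_neg = n_droplets, n_total = n_droplets)
          } else {
            # load an aliquot sized to the observed wild-type-positive droplet
            # regime (tens of thousands of positives per well-sum)
            simulate_ddpcr(amp, lid, n_droplets = n_droplets,
                           sampled_molecules = min(amp$total, 30000),
                           sample_id = sid, polymerase = prof$name,
                           cycles = cfg_noseed$cycles)
          }
          ddpcr_rows[[length(ddpcr_rows) + 1L]] <- data.frame(
            sample_id = sid, sample_type = dd_samples$sample_type[i],
            locus_id = lid, polymerase = prof$name, preamplified = TRUE,
            cycles = cfg_noseed$cycles,
            n_mut_pos = d$n_mut_pos, n_wt_pos = d$n_wt_pos,
            n_double_pos = d$n_double_pos, n_neg = d$n_neg, n_total = d$n_total,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(ngs_counts = ngs_counts, ddpcr = do.call(rbind, ddpcr_rows),
         truth = true_mutations)
  })
}
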