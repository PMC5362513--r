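controls <- c("Male Control", "Female Control")

test_that("error-rate estimation follows the accumulation model transform", {
  # zero artifacts: zero estimate with a zero lower bound
  est0 <- estimate_error_rate(0, 44104, 22)
  expect_equal(est0$e_hat, 0)
  expect_equal(est0$ci_low, 0)
  expect_gt(est0$ci_high, 0)
  # arithmetic from the observed wild-type control artifact
  est <- estimate_error_rate(11, 32975, 22)
  expect_equal(est$e_hat, 2 * (11 / 32975) / 22)
  expect_equal(est$e_hat, 3.03e-5, tolerance = 0.01)
  expect_true(est$ci_low <= est$e_hat && est$e_hat <= est$ci_high)
  # degenerate saturation of the model
  half <- estimate_error_rate(50, 100, 1)
  expect_equal(half$e_hat, 1.0)
  expect_true(half$degenerate)
  expect_error(estimate_error_rate(1, 100, 0), "cycles")
  expect_error(estimate_error_rate(1, 0, 22), "positive")
  # the model factor is configurable for strand-level conventions
  expect_equal(estimate_error_rate(11, 32975, 22, model_factor = 1)$e_hat,
               est$e_hat / 2)
})

test_that("error-rate confidence intervals cover the generating rate", {
  # counts drawn binomially at the model-implied fraction, ddPCR scale
  set.seed(103)
  cycles <- 22
  for (e_true in c(1e-6, 1e-5, 1e-4)) {
    f <- expected_error_fraction(e_true, cycles, 1)
    q <- f / (1 + f)
    hits <- replicate(500, {
      n <- 30000
      mut <- rbinom(1, n, q)
      est <- estimate_error_rate(mut, n - mut, cycles)
      est$ci_low <= e_true && e_true <= est$ci_high
    })
    expect_gte(mean(hits), 0.93)   # Clopper-Pearson is conservative
  }
})

test_that("fold over reported fidelity distinguishes point rates from bounds", {
  profiles <- ar_polymerase_profiles()
  f1 <- fold_over_reported(4.4e-7, profiles$phusion)
  expect_equal(f1$fold, 1.0)
  expect_equal(f1$type, "point")
  f2 <- fold_over_reported(3.03e-5, profiles$phusion)
  expect_equal(f2$fold, 3.03e-5 / 4.4e-7)
  expect_gt(f2$fold, 60)  # "far exceeded" the reported rate
  # scale equivariance
  expect_equal(fold_over_reported(2 * 3.03e-5, profiles$phusion)$fold, 2 * f2$fold)
  # bound-only vendor statement
  f3 <- fold_over_reported(0, profiles$superfi)
  expect_equal(f3$type, "bound")
  expect_true(f3$consistent)
  f4 <- fold_over_reported(1e-5, profiles$superfi)
  expect_false(f4$consistent)
})

test_that("the paired locus comparison reproduces the exact signed-rank result", {
  dd <- cohort_droplet_counts(c("t4", "t5"))
  phus <- dd[dd$polymerase == "Phusion" & dd$sample_type == "patient" &
               as.logical(dd$preamplified), ]
  shared <- intersect(phus$sample_id[phus$locus_id == "F877L"],
                      phus$sample_id[phus$locus_id == "T878A"])
  expect_equal(length(shared), 7)
  af <- function(locus) vapply(shared, function(s) {
    row <- phus[phus$sample_id == s & phus$locus_id == locus, ]
    as.numeric(raw_allelic_fraction(ARfidelity:::as_droplet_data(row)))
  }, numeric(1))
  cmp <- compare_locus_rates(af("F877L"), af("T878A"))
  expect_equal(cmp$n_a_greater, 7)
  expect_true(cmp$wilcoxon_exact)
  expect_equal(cmp$p_wilcoxon, 2 / 128)
  expect_lt(cmp$p_wilcoxon, 0.05)
  expect_lt(cmp$p_ttest, 0.05)
})

test_that("identical paired vectors give a no-signal result", {
  cmp <- compare_locus_rates(rep(0.02, 6), rep(0.02, 6))
  expect_equal(cmp$p_wilcoxon, 1)
  expect_true(cmp$no_signal)
  expect_error(compare_locus_rates(1:3 / 10, 3:1 / 10), "at least 5")
})

test_that("exact signed-rank p-values match brute-force sign enumeration", {
  set.seed(107)
  for (n in c(5, 8, 10, 12)) {
    for (rep in 1:5) {
      a <- round(runif(n, 0, 0.05), 4)
      b <- round(runif(n, 0, 0.05), 4)
      d <- a - b
      if (any(d == 0) || anyDuplicated(abs(d))) next
      cmp <- compare_locus_rates(a, b)
      expect_equal(cmp$p_wilcoxon, enumerate_signed_rank(d),
                   tolerance = 1e-12, info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("simulation-estimated power agrees with the exact test decisions", {
  # on each simulated dataset the implementation and the enumeration oracle
  # must reach the same rejection decision, so their power estimates match
  set.seed(109)
  n <- 10
  rejections <- replicate(100, {
    a <- rnorm(n, 0.02, 0.005)
    b <- a - rnorm(n, 0.008, 0.003)   # known positive shift
    d <- a - b
    if (any(d == 0) || anyDuplicated(abs(d))) return(c(NA, NA))
    c(compare_locus_rates(a, b)$p_wilcoxon < 0.05,
      enumerate_signed_rank(d) < 0.05)
  })
  ok <- !is.na(rejections[1, ])
  expect_equal(rejections[1, ok], rejections[2, ok])
  expect_gt(mean(rejections[1, ok]), 0.5)  # the shift is detectable
})

test_that("cross-platform classification reproduces the study's verdicts", {
  calls <- call_variants(cohort_ngs_counts(), control_samples = controls)
  conc <- classify_concordance(calls, cohort_droplet_counts(),
                               control_samples = controls)
  rec <- conc$records
  expect_equal(nrow(rec), 8)
  f877l <- rec[rec$locus_id == "F877L", ]
  expect_equal(nrow(f877l), 6)
  expect_true(all(f877l$verdict == "FALSE_POSITIVE"))
  expect_equal(rec$verdict[rec$locus_id == "W742C"], "VALIDATED")
  expect_equal(rec$verdict[rec$locus_id == "T878A"], "FALSE_POSITIVE")
  ap <- conc$artifact_prone
  expect_true(ap$artifact_prone[ap$locus_id == "F877L" & ap$polymerase == "Phusion"][1])
  expect_false(any(ap$artifact_prone[ap$polymerase == "SuperFi"]))
})

test_that("classification is total and deterministic over its input domain", {
  # every combination of wild-type-control positivity x patient assay
  # outcome maps to exactly one verdict
  make_dd <- function(ctl_pos, pt_assayed, pt_pos) {
    rows <- list(
      data.frame(sample_id = "WT", sample_type = "wt_control", locus_id = "F877L",
                 polymerase = "P", preamplified = TRUE, cycles = 22,
                 n_mut_pos = if (ctl_pos) 3L else 0L, n_wt_pos = 30000L,
                 n_double_pos = 0L, n_neg = NA, n_total = NA),
      data.frame(sample_id = "NTC", sample_type = "ntc", locus_id = "F877L",
                 polymerase = "P", preamplified = TRUE, cycles = 22,
                 n_mut_pos = 0L, n_wt_pos = 0L, n_double_pos = 0L,
                 n_neg = NA, n_total = NA))
    if (pt_assayed)
      rows[[3]] <- data.frame(sample_id = "s1", sample_type = "patient",
                              locus_id = "F877L", polymerase = "P",
                              preamplified = TRUE, cycles = 22,
                              n_mut_pos = if (pt_pos) 5L else 0L,
                              n_wt_pos = 30000L, n_double_pos = 0L,
                              n_neg = NA, n_total = NA)
    do.call(rbind, rows)
  }
  calls <- call_variants(
    make_counts(rowspec("s1", "F877L", "T", 5000, 5000),
                rowspec("s2", "F877L", "T", 5000, 5000),
                rowspec("s1", "F877L", "C", 15, 15)))
  grid <- expand.grid(ctl_pos = c(TRUE, FALSE), pt_assayed = c(TRUE, FALSE),
                      pt_pos = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    conc <- classify_concordance(calls, make_dd(g$ctl_pos, g$pt_assayed, g$pt_pos),
                                 control_samples = character())
    v <- conc$records$verdict
    expect_equal(length(v), 1)
    want <- if (g$ctl_pos || !g$pt_assayed) "NOT_ASSESSED"
            else if (g$pt_pos) "VALIDATED" else "FALSE_POSITIVE"
    expect_equal(v, want, info = paste(g, collapse = "/"))
    # deterministic: identical on repeat
    conc2 <- classify_concordance(calls, make_dd(g$ctl_pos, g$pt_assayed, g$pt_pos),
                                  control_samples = character())
    expect_identical(conc$records, conc2$records)
  }
})

test_that("classification refuses invalid or control-less runs", {
  calls <- call_variants(
    make_counts(rowspec("s1", "F877L", "T", 5000, 5000),
                rowspec("s2", "F877L", "T", 5000, 5000),
                rowspec("s1", "F877L", "C", 15, 15)))
  no_ctl <- data.frame(sample_id = "s1", sample_type = "patient",
                       locus_id = "F877L", polymerase = "P", preamplified = TRUE,
                       cycles = 22, n_mut_pos = 0L, n_wt_pos = 30000L,
                       n_double_pos = 0L, n_neg = NA, n_total = NA)
  expect_error(classify_concordance(calls, no_ctl), "requires wild-type control")
  bad_ntc <- rbind(no_ctl,
                   data.frame(sample_id = "WT", sample_type = "wt_control",
                              locus_id = "F877L", polymerase = "P",
                              preamplified = TRUE, cycles = 22, n_mut_pos = 0L,
                              n_wt_pos = 30000L, n_double_pos = 0L, n_neg = NA,
                              n_total = NA),
                   data.frame(sample_id = "NTC", sample_type = "ntc",
                              locus_id = "F877L", polymerase = "P",
                              preamplified = TRUE, cycles = 22, n_mut_pos = 2L,
                              n_wt_pos = 0L, n_double_pos = 0L, n_neg = NA,
                              n_total = NA))
  expect_error(classify_concordance(calls, bad_ntc), "run invalid")
})

test_that("a SuperFi-like profile yields no mutant droplets at assay occupancy", {
  set.seed(113)
  loci <- ar_hotspot_loci()
  prof <- ar_polymerase_profiles()$superfi   # multiplier 0 at F877L
  cfg <- amplification_config(909, cycles = 22, efficiency = 0.95)
  zeros <- replicate(200, {
    amp <- simulate_preamplification(molecule_pool(909, loci["F877L"]), prof, cfg)
    d <- simulate_ddpcr(amp, "F877L", n_droplets = 20000,
                        sampled_molecules = min(amp$total, 40000))
    (d$n_mut_pos + d$n_double_pos) == 0
  })
  expect_gte(mean(zeros), 0.99)
})

test_that("the cohort fidelity report summarises the study findings", {
  report <- fidelity_report(
    cohort_ngs_counts(), cohort_droplet_counts(),
    polymerases = list(Phusion = ar_polymerase_profiles()$phusion,
                       SuperFi = ar_polymerase_profiles()$superfi),
    control_samples = controls)
  cs <- report$call_summary
  expect_equal(cs$n_patient_calls[cs$locus_id == "F877L"], 5)
  expect_equal(cs$n_control_calls[cs$locus_id == "F877L"], 1)
  expect_equal(report$n_patients, 11)
  verdicts <- report$concordance$records
  expect_equal(sum(verdicts$verdict == "VALIDATED"), 1)
  expect_equal(sum(verdicts$verdict == "FALSE_POSITIVE"), 7)
  # the Phusion F877L wild-type-control estimate far exceeds the vendor rate
  er <- report$error_rates
  phus_f877l <- er[er$locus_id == "F877L" & er$polymerase == "Phusion" &
                     er$cycles == 22, ]
  expect_gt(phus_f877l$fold_over_reported[1], 10)
  expect_false(phus_f877l$consistent_with_reported[1])
  # deterministic report text
  expect_identical(capture.output(print(report)), capture.output(print(report)))
})

test_that("an empty cohort produces an empty report", {
  empty <- cohort_ngs_counts()[0, ]
  report <- fidelity_report(empty, cohort_droplet_counts())
  expect_true(report$empty)
  expect_match(capture.output(print(report))[1], "empty")
})
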