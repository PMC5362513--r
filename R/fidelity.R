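#' Estimate a locus/polymerase amplification error rate
#'
#' Under the molecule-duplication accumulation model, an artifact fraction
#' f observed after c preamplification cycles implies a per-base
#' per-duplication error rate of about 2 f / c (each cycle, roughly half of
#' the final molecules trace to new synthesis). The observed fraction is
#' the mutant/wild-type ratio; its exact binomial (Clopper-Pearson)
#' confidence interval on mut / (mut + wt) is mapped through the odds
#' transform and the same model factor.
#'
#' @param mut_count,wt_count observed mutant and wild-type counts
#'   (droplets or reads); \code{wt_count} must be positive.
#' @param cycles preamplification cycles (>= 1).
#' @param conf_level confidence level for the exact interval.
#' @param model_factor 2 under the molecule-duplication convention
#'   (default); 1 for strand-level accumulation conventions.
#' @return object of class \code{error_rate_estimate} with \code{f_obs},
#'   \code{e_hat}, \code{ci_low}, \code{ci_high} and a \code{degenerate}
#'   flag when the estimate saturates the model (e_hat >= 1).
#' @examples
#' estimate_error_rate(11, 32975, cycles = 22)  # ~3.0e-5 per base per duplication
#' @export
estimate_error_rate <- function(mut_count, wt_count, cycles, conf_level = 0.95,
                                model_factor = 2) {
  check_that(is_count(cycles) && cycles >= 1, "cycles must be >= 1")
  check_that(wt_count > 0, "wt_count must be positive")
  check_that(mut_count >= 0, "mut_count must be >= 0")
  f_obs <- mut_count / wt_count
  e_hat <- model_factor * f_obs / cycles
  ci_q <- stats::binom.test(mut_count, mut_count + wt_count,
                            conf.level = conf_level)$conf.int
  odds <- ci_q / (1 - ci_q)       # q / (1 - q) = mut / wt
  ci <- model_factor * odds / cycles
  structure(list(mut_count = mut_count, wt_count = wt_count, cycles = cycles,
                 f_obs = f_obs, e_hat = e_hat,
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, model_factor = model_factor,
                 degenerate = e_hat >= 1),
            class = "error_rate_estimate")
}

#' @export
print.error_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<error_rate_estimate> %d/%d over %d cycles: e = %.3g [%.3g, %.3g] per base per duplication%s\n",
    x$mut_count, x$wt_count, x$cycles, x$e_hat, x$ci_low, x$ci_high,
    if (x$degenerate) " (degenerate: estimate saturates the model)" else ""))
  invisible(x)
}

#' Fold-change of an observed error rate over the vendor-reported fidelity
#'
#' For polymerases with a numeric reported rate, returns the point fold
#' e_hat / reported. For polymerases whose fidelity is stated only as a
#' bound (reported rate below some value), returns a bound-type comparison:
#' the fold over the bound, and whether the observation is consistent with
#' the reported fidelity (e_hat at or below the bound).
#'
#' @param e_hat estimated rate, or an [estimate_error_rate()] result.
#' @param polymerase a [polymerase_profile()].
#' @return object of class \code{fidelity_fold}.
#' @export
fold_over_reported <- function(e_hat, polymerase) {
  if (inherits(e_hat, "error_rate_estimate")) e_hat <- e_hat$e_hat
  if (!is.na(polymerase$reported_rate)) {
    check_that(polymerase$reported_rate > 0, "reported rate must be positive")
    out <- list(type = "point", polymerase = polymerase$name, e_hat = e_hat,
                reported = polymerase$reported_rate,
                fold = e_hat / polymerase$reported_rate,
                consistent = e_hat <= polymerase$reported_rate)
  } else {
    check_that(!is.na(polymerase$reported_bound) && polymerase$reported_bound > 0,
               "polymerase '%s' has neither a reported rate nor a bound",
               polymerase$name)
    out <- list(type = "bound", polymerase = polymerase$name, e_hat = e_hat,
                reported = polymerase$reported_bound,
                fold = e_hat / polymerase$reported_bound,
                consistent = e_hat <= polymerase$reported_bound)
  }
  structure(out, class = "fidelity_fold")
}

#' @export
print.fidelity_fold <- function(x, ...) {
  if (x$type == "point")
    cat(sprintf("<fidelity_fold> %s: observed %.3g = %.1fx the reported %.3g\n",
                x$polymerase, x$e_hat, x$fold, x$reported))
  else
    cat(sprintf(
      "<fidelity_fold> %s: observed %.3g vs reported bound <= %.3g (%s)\n",
      x$polymerase, x$e_hat, x$reported,
      if (x$consistent) "consistent with reported fidelity" else
        sprintf("%.1fx above the bound", x$fold)))
  invisible(x)
}

#' Compare artifact rates between two loci on paired samples
#'
#' Paired comparison of per-sample allelic fractions at two loci under one
#' polymerase. The primary test is the exact Wilcoxon signed-rank (exact
#' null enumeration for n <= 25 when differences have no zeros or ties);
#' a paired t-test is reported alongside. All-zero differences yield a
#' no-signal result with p = 1.
#'
#' @param af_a,af_b paired per-sample allelic fractions (same length,
#'   >= 5 pairs).
#' @return object of class \code{locus_rate_comparison} with
#'   \code{p_wilcoxon}, \code{p_ttest}, \code{n_pairs},
#'   \code{n_a_greater}, and \code{wilcoxon_exact}.
#' @export
compare_locus_rates <- function(af_a, af_b) {
  check_that(length(af_a) == length(af_b), "paired vectors must have equal length")
  n <- length(af_a)
  check_that(n >= 5, "need at least 5 paired samples")
  d <- af_a - af_b
  if (all(d == 0)) {
    out <- list(p_wilcoxon = 1, p_ttest = 1, statistic = NA_real_,
                n_pairs = n, n_a_greater = 0L, wilcoxon_exact = TRUE,
                no_signal = TRUE)
    return(structure(out, class = "locus_rate_comparison"))
  }
  dnz <- d[d != 0]
  exact_ok <- length(unique(abs(dnz))) == length(dnz) && length(dnz) == n
  wt <- if (exact_ok) {
    stats::wilcox.test(af_a, af_b, paired = TRUE, exact = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(af_a, af_b, paired = TRUE, exact = FALSE,
                                        correct = TRUE))
  }
  tt <- stats::t.test(af_a, af_b, paired = TRUE)
  structure(list(p_wilcoxon = wt$p.value, p_ttest = tt$p.value,
                 statistic = unname(wt$statistic), n_pairs = n,
                 n_a_greater = sum(d > 0), wilcoxon_exact = exact_ok,
                 no_signal = FALSE),
            class = "locus_rate_comparison")
}

#' @export
print.locus_rate_comparison <- function(x, ...) {
  cat(sprintf(
    "<locus_rate_comparison> %d pairs, A > B in %d; Wilcoxon signed-rank p = %.4g (%s), paired t p = %.4g\n",
    x$n_pairs, x$n_a_greater, x$p_wilcoxon,
    if (x$wilcoxon_exact) "exact" else "normal approximation", x$p_ttest))
  invisible(x)
}

#' Classify sequencing candidates by cross-platform ddPCR concordance
#'
#' Decision rules, evaluated per CALLED sequencing candidate:
#' \enumerate{
#'   \item a positive no-template control anywhere invalidates the run
#'     (error);
#'   \item a locus where preamplified wild-type control DNA is
#'     ddPCR-positive under a polymerase is flagged artifact-prone for that
#'     polymerase, and that polymerase cannot adjudicate calls there;
#'   \item a call ddPCR-positive under at least one clean polymerase (one
#'     whose wild-type control is negative at the locus) is VALIDATED;
#'   \item a call assayed under at least one clean polymerase and negative
#'     under all of them is FALSE_POSITIVE;
#'   \item a call in a sample that is itself a wild-type/healthy control is
#'     FALSE_POSITIVE (a somatic hotspot call in control DNA is an error by
#'     design);
#'   \item anything else is NOT_ASSESSED.
#' }
#'
#' @param ngs_calls a \code{variant_calls} data.frame ([call_variants()]).
#' @param ddpcr droplet-count data.frame ([read_droplet_table()] schema
#'   with a \code{sample_type} column: patient / wt_control / ntc /
#'   mutant_control / positive_cfdna).
#' @param control_samples sample_ids in \code{ngs_calls} that are healthy
#'   controls.
#' @return object of class \code{concordance} with \code{records} (one row
#'   per CALLED candidate: verdict and supporting evidence) and
#'   \code{artifact_prone} (locus x polymerase flags).
#' @export
classify_concordance <- function(ngs_calls, ddpcr, control_samples = character()) {
  check_that(!is.null(ddpcr$sample_type), "ddpcr table needs a sample_type column")
  pre <- ddpcr[as.logical(ddpcr$preamplified), , drop = FALSE]
  check_that(any(pre$sample_type == "wt_control") && any(ddpcr$sample_type == "ntc"),
             "classification requires wild-type control and no-template control rows")
  ntc <- ddpcr[ddpcr$sample_type == "ntc", , drop = FALSE]
  if (any(ntc$n_mut_pos > 0 | ntc$n_wt_pos > 0))
    stop("run invalid: a no-template control is positive", call. = FALSE)

  wt_ctl <- pre[pre$sample_type == "wt_control", , drop = FALSE]
  combos <- unique(wt_ctl[, c("locus_id", "polymerase")])
  combos$artifact_prone <- vapply(seq_len(nrow(combos)), function(i) {
    rows <- wt_ctl[wt_ctl$locus_id == combos$locus_id[i] &
                   wt_ctl$polymerase == combos$polymerase[i], , drop = FALSE]
    any(rows$n_mut_pos > 0)
  }, logical(1))

  is_clean <- function(locus, poly) {
    hit <- combos$locus_id == locus & combos$polymerase == poly
    any(hit) && !any(combos$artifact_prone[hit])
  }

  called <- ngs_calls[ngs_calls$status == "CALLED", , drop = FALSE]
  records <- lapply(seq_len(nrow(called)), function(i) {
    sid <- called$sample_id[i]
    lid <- called$locus_id[i]
    rows <- pre[pre$sample_id == sid & pre$locus_id == lid, , drop = FALSE]
    clean <- vapply(rows$polymerase, is_clean, logical(1), locus = lid)
    clean_rows <- rows[clean, , drop = FALSE]
    verdict <- if (nrow(clean_rows) && any(clean_rows$n_mut_pos > 0)) {
      "VALIDATED"
    } else if (nrow(clean_rows)) {
      "FALSE_POSITIVE"
    } else if (sid %in% control_samples) {
      "FALSE_POSITIVE"
    } else {
      "NOT_ASSESSED"
    }
    data.frame(sample_id = sid, locus_id = lid, alt = called$alt[i],
               ngs_af_percent = called$af_percent[i],
               n_ddpcr_assays = nrow(rows), n_clean_assays = nrow(clean_rows),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(sample_id = character(), locus_id = character(), alt = character(),
               ngs_af_percent = numeric(), n_ddpcr_assays = integer(),
               n_clean_assays = integer(), verdict = character(),
               stringsAsFactors = FALSE)
  structure(list(records = records, artifact_prone = combos),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Cross-platform concordance\n")
  ap <- x$artifact_prone[x$artifact_prone$artifact_prone, , drop = FALSE]
  if (nrow(ap))
    cat("Artifact-prone loci:",
        paste(sprintf("%s under %s", ap$locus_id, ap$polymerase), collapse = "; "),
        "\n")
  if (nrow(x$records)) print.data.frame(x$records, row.names = FALSE)
  else cat("No sequencing calls to classify.\n")
  invisible(x)
}

#' Build a structured fidelity report for a cohort
#'
#' Runs the downstream analysis end to end on a cohort's sequencing
#' allele-count table and ddPCR droplet table: the filter cascade, raw
#' ddPCR allelic fractions, per-locus per-polymerase error-rate estimates
#' from the preamplified wild-type controls, fold-over-reported fidelity
#' comparisons, and cross-platform concordance verdicts.
#'
#' @param ngs_counts allele-count data.frame ([read_count_table()] schema).
#' @param ddpcr droplet table with \code{sample_type} column.
#' @param loci locus definitions.
#' @param config a [filter_config()].
#' @param polymerases named list of [polymerase_profile()] used to compare
#'   observed rates with reported fidelities, keyed by the polymerase
#'   labels appearing in \code{ddpcr}.
#' @param control_samples healthy-control sample_ids in the sequencing
#'   cohort.
#' @return object of class \code{fidelity_report}.
#' @export
fidelity_report <- function(ngs_counts, ddpcr, loci = ar_hotspot_loci(),
                            config = filter_config(), polymerases = list(),
                            control_samples = character()) {
  if (nrow(ngs_counts) == 0L) {
    return(structure(list(calls = NULL, concordance = NULL,
                          error_rates = NULL, empty = TRUE),
                     class = "fidelity_report"))
  }
  calls <- call_variants(ngs_counts, config, loci, control_samples)
  conc <- classify_concordance(calls, ddpcr, control_samples)

  wt_ctl <- ddpcr[ddpcr$sample_type == "wt_control" & as.logical(ddpcr$preamplified), ,
                  drop = FALSE]
  # the same control assay can be reported in several source tables;
  # estimate each physical assay once
  wt_ctl <- unique(wt_ctl[, c("locus_id", "polymerase", "cycles",
                              "n_mut_pos", "n_wt_pos"), drop = FALSE])
  err <- lapply(seq_len(nrow(wt_ctl)), function(i) {
    row <- wt_ctl[i, ]
    if (row$n_wt_pos == 0) return(NULL)
    est <- estimate_error_rate(row$n_mut_pos, row$n_wt_pos, row$cycles)
    fold <- if (row$polymerase %in% names(polymerases))
      fold_over_reported(est, polymerases[[row$polymerase]]) else NULL
    data.frame(locus_id = row$locus_id, polymerase = row$polymerase,
               cycles = row$cycles, mut = row$n_mut_pos, wt = row$n_wt_pos,
               e_hat = est$e_hat, ci_low = est$ci_low, ci_high = est$ci_high,
               fold_over_reported = if (is.null(fold)) NA_real_ else fold$fold,
               consistent_with_reported = if (is.null(fold)) NA else fold$consistent,
               stringsAsFactors = FALSE)
  })
  err <- do.call(rbind, err)

  patient_ids <- setdiff(unique(ngs_counts$sample_id), control_samples)
  called <- calls[calls$status == "CALLED", , drop = FALSE]
  per_locus <- lapply(split(called, called$locus_id), function(g) {
    data.frame(locus_id = g$locus_id[1],
               n_patient_calls = length(intersect(unique(g$sample_id), patient_ids)),
               n_control_calls = length(intersect(unique(g$sample_id), control_samples)),
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, per_locus)

  structure(list(calls = calls, concordance = conc, error_rates = err,
                 call_summary = per_locus, n_patients = length(patient_ids),
                 empty = FALSE),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Fidelity report: empty cohort\n")
    return(invisible(x))
  }
  cat("== Fidelity report ==\n\nSequencing calls by locus (of",
      x$n_patients, "patients):\n")
  if (!is.null(x$call_summary)) print.data.frame(x$call_summary, row.names = FALSE)
  cat("\nAmplification error rates (preamplified wild-type controls):\n")
  if (!is.null(x$error_rates)) {
    show <- x$error_rates
    for (col in c("e_hat", "ci_low", "ci_high", "fold_over_reported"))
      show[[col]] <- signif(show[[col]], 3)
    print.data.frame(show, row.names = FALSE)
  }
  cat("\n")
  print(x$concordance)
  invisible(x)
}
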