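#' Droplet digital PCR classified droplet counts
#'
#' One sample x assay record of droplet classifications: mutant-only
#' positive, wild-type-only positive, double-positive and negative
#' droplets. The published tables report only mutant and wild-type droplet
#' counts (doubles folded in, totals unprinted), so \code{n_double_pos},
#' \code{n_neg} and \code{n_total} may be zero/NA; Poisson quantities are
#' only computable when \code{n_total} is known.
#'
#' @param sample_id sample label.
#' @param locus_id assayed hotspot codon.
#' @param polymerase preamplification enzyme label (NA for non-amplified
#'   wells).
#' @param cycles preamplification cycles (NA for non-amplified wells).
#' @param n_mut_pos,n_wt_pos,n_double_pos,n_neg droplet counts (>= 0).
#' @param n_total total droplets, if known.
#' @param preamplified logical.
#' @return object of class \code{droplet_data}.
#' @export
droplet_data <- function(sample_id, locus_id, polymerase = NA_character_,
                         cycles = NA_integer_, n_mut_pos = 0, n_wt_pos = 0,
                         n_double_pos = 0, n_neg = NA_integer_,
                         n_total = NULL, preamplified = TRUE) {
  counts <- c(n_mut_pos, n_wt_pos, n_double_pos)
  check_that(all(counts >= 0), "droplet counts must be >= 0")
  if (!is.null(n_total) && !is.na(n_total)) {
    used <- n_mut_pos + n_wt_pos + n_double_pos + if (is.na(n_neg)) 0 else n_neg
    check_that(n_total >= used, "n_total smaller than the classified droplets")
  }
  structure(list(sample_id = sample_id, locus_id = locus_id,
                 polymerase = polymerase, cycles = cycles,
                 n_mut_pos = n_mut_pos, n_wt_pos = n_wt_pos,
                 n_double_pos = n_double_pos, n_neg = n_neg,
                 n_total = if (is.null(n_total)) NA_integer_ else n_total,
                 preamplified = preamplified),
            class = "droplet_data")
}

#' @export
print.droplet_data <- function(x, ...) {
  cat(sprintf("<droplet_data> %s %s [%s, %s cycles]: mut %d / wt %d / double %d%s\n",
              x$sample_id, x$locus_id,
              ifelse(is.na(x$polymerase), "non-amplified", x$polymerase),
              ifelse(is.na(x$cycles), "-", x$cycles),
              x$n_mut_pos, x$n_wt_pos, x$n_double_pos,
              if (!is.na(x$n_total)) sprintf(" (of %d)", x$n_total) else ""))
  invisible(x)
}

#' Read a delimited droplet-count table
#'
#' Columns: \code{sample_id, locus_id, polymerase, preamplified, cycles,
#' n_mut_pos, n_wt_pos} and optionally \code{n_double_pos, n_neg, n_total,
#' sample_type}.
#'
#' @param path tab-delimited file.
#' @return data.frame, missing optional columns filled with 0/NA.
#' @export
read_droplet_table <- function(path) {
  check_that(file.exists(path), "droplet table '%s' not found", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "locus_id", "polymerase", "preamplified", "cycles",
                "n_mut_pos", "n_wt_pos")
  missing <- setdiff(required, names(df))
  check_that(length(missing) == 0, "droplet table missing columns: %s",
             paste(missing, collapse = ", "))
  if (is.null(df$n_double_pos)) df$n_double_pos <- 0L
  if (is.null(df$n_neg)) df$n_neg <- NA_integer_
  if (is.null(df$n_total)) df$n_total <- NA_integer_
  check_that(all(df$n_mut_pos >= 0 & df$n_wt_pos >= 0), "negative droplet counts")
  df
}

as_droplet_data <- function(row) {
  droplet_data(sample_id = row$sample_id, locus_id = row$locus_id,
               polymerase = row$polymerase, cycles = row$cycles,
               n_mut_pos = row$n_mut_pos, n_wt_pos = row$n_wt_pos,
               n_double_pos = row$n_double_pos, n_neg = row$n_neg,
               n_total = row$n_total,
               preamplified = isTRUE(as.logical(row$preamplified)))
}

#' Merge ddPCR replicate wells by summation
#'
#' Reported results are the summation of four or more replicate wells;
#' this merges replicates of one sample x assay elementwise.
#'
#' @param replicates list of [droplet_data()] for the same sample and assay.
#' @return a single merged \code{droplet_data}.
#' @export
merge_replicates <- function(replicates) {
  check_that(length(replicates) >= 1, "no replicates supplied")
  first <- replicates[[1]]
  for (r in replicates) {
    same <- identical(r$sample_id, first$sample_id) &&
      identical(r$locus_id, first$locus_id) &&
      identical(r$polymerase, first$polymerase) &&
      identical(r$cycles, first$cycles) &&
      identical(r$preamplified, first$preamplified)
    check_that(same, "replicates mix samples or assays (%s/%s vs %s/%s)",
               r$sample_id, r$locus_id, first$sample_id, first$locus_id)
  }
  sum_field <- function(f) {
    v <- vapply(replicates, `[[`, numeric(1), f)
    if (anyNA(v)) NA_integer_ else sum(v)
  }
  out <- first
  out$n_mut_pos <- sum_field("n_mut_pos")
  out$n_wt_pos <- sum_field("n_wt_pos")
  out$n_double_pos <- sum_field("n_double_pos")
  out$n_neg <- sum_field("n_neg")
  out$n_total <- sum_field("n_total")
  out
}

#' Raw ddPCR allelic fraction (mutant / wild-type ratio, percent)
#'
#' The statistic the published tables print: 100 * mutant-positive /
#' wild-type-positive droplets. Double-positive droplets are wild-type
#' positive by definition and count toward the mutant channel too by
#' default (configurable). A positive mutant count with zero wild-type
#' droplets (non-amplified mutant-control wells) saturates the ratio:
#' 100 is returned with the \code{"saturated"} attribute set.
#'
#' @param d a [droplet_data()].
#' @param include_double_in_mut count double-positives in the mutant
#'   channel.
#' @return percent, with logical attribute \code{"saturated"}.
#' @export
raw_allelic_fraction <- function(d, include_double_in_mut = TRUE) {
  mut <- d$n_mut_pos + if (include_double_in_mut) d$n_double_pos else 0
  wt <- d$n_wt_pos + d$n_double_pos
  if (wt == 0) {
    if (mut == 0) return(structure(0, saturated = FALSE))
    return(structure(100, saturated = TRUE))
  }
  structure(100 * mut / wt, saturated = FALSE)
}

#' Poisson mean occupancy from digital PCR positives
#'
#' Standard digital PCR statistics: with fraction p of n_total droplets
#' positive, the mean target molecules per droplet is -ln(1 - p).
#'
#' @param n_pos positive droplets (0 <= n_pos < n_total).
#' @param n_total total droplets.
#' @return lambda, mean molecules per droplet.
#' @export
poisson_lambda <- function(n_pos, n_total) {
  check_that(n_total >= 1 && n_pos >= 0, "invalid droplet counts")
  if (n_pos >= n_total)
    stop("all droplets positive: occupancy saturated, lambda not estimable",
         call. = FALSE)
  -log1p(-n_pos / n_total)
}

#' Confidence interval for the Poisson occupancy
#'
#' Exact binomial (Clopper-Pearson) interval on the positive fraction,
#' mapped through -ln(1 - p).
#'
#' @param n_pos,n_total droplet counts.
#' @param conf_level confidence level.
#' @return numeric c(lower, upper) on the lambda scale.
#' @export
poisson_lambda_ci <- function(n_pos, n_total, conf_level = 0.95) {
  ci <- stats::binom.test(n_pos, n_total, conf.level = conf_level)$conf.int
  -log1p(-ci)
}

#' Poisson-corrected fractional abundance, percent
#'
#' 100 * lambda_mut / (lambda_mut + lambda_wt), with each channel's
#' positives = single-positive + double-positive droplets. Requires
#' \code{n_total}; without it the result is NA with a NO_TOTAL flag. At
#' low occupancy this agrees with the raw ratio to first order.
#'
#' @param d a [droplet_data()] with \code{n_total}.
#' @return percent, or NA with attribute \code{flag = "NO_TOTAL"}.
#' @export
poisson_fractional_abundance <- function(d) {
  if (is.na(d$n_total))
    return(structure(NA_real_, flag = "NO_TOTAL"))
  mut_pos <- d$n_mut_pos + d$n_double_pos
  wt_pos <- d$n_wt_pos + d$n_double_pos
  lam_mut <- poisson_lambda(mut_pos, d$n_total)
  lam_wt <- poisson_lambda(wt_pos, d$n_total)
  if (lam_mut + lam_wt == 0) return(structure(0, flag = NULL))
  100 * lam_mut / (lam_mut + lam_wt)
}

#' AR copy-number call from ddPCR concentrations
#'
#' Copy number is the target-to-reference concentration ratio scaled by the
#' reference's expected copies in the sample: an X-linked reference (ZXDB)
#' has 1 expected copy in a male and 2 in a female; an autosomal reference
#' (NSUN3) has 2, with the target read against the male single-X baseline.
#' Estimates at or above 1.9 are called increased.
#'
#' @param target_lambda target (AR) concentration, as lambda or any
#'   proportional concentration; a [droplet_data()] with \code{n_total} is
#'   also accepted.
#' @param reference_lambda reference-gene concentration (same units).
#' @param reference_copies_in_sample expected reference copies (1 for
#'   X-linked reference in a male, 2 for female X or autosomal).
#' @param sample_id label.
#' @param threshold increased-copy-number cut, inclusive.
#' @return object of class \code{copy_number_result} with
#'   \code{cn_estimate} and \code{increased}.
#' @export
copy_number <- function(target_lambda, reference_lambda,
                        reference_copies_in_sample = 1, sample_id = NA_character_,
                        threshold = 1.9) {
  to_lambda <- function(x) {
    if (inherits(x, "droplet_data")) {
      check_that(!is.na(x$n_total), "copy number from droplet_data needs n_total")
      poisson_lambda(x$n_mut_pos + x$n_double_pos + x$n_wt_pos, x$n_total)
    } else x
  }
  tl <- to_lambda(target_lambda)
  rl <- to_lambda(reference_lambda)
  check_that(rl > 0, "reference concentration must be positive")
  cn <- tl / rl * reference_copies_in_sample
  structure(list(sample_id = sample_id, cn_estimate = cn,
                 increased = cn >= threshold, threshold = threshold),
            class = "copy_number_result")
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat(sprintf("<copy_number_result> %s: CN = %.3f (%sincreased, cut %.2f)\n",
              x$sample_id, x$cn_estimate, if (x$increased) "" else "not ",
              x$threshold))
  invisible(x)
}
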