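#' Read a per-sample per-locus allele count table
#'
#' Expected delimited columns: \code{sample_id, locus_id, allele,
#' fwd_count, rev_count, mean_base_quality, mean_mapq}. Each (sample,
#' locus) must carry a row for the locus's reference allele; alternate
#' alleles appear only where observed.
#'
#' @param path tab-delimited file with header.
#' @param loci named list of [locus_spec()]; rows at undeclared loci are
#'   rejected with their row number.
#' @return validated data.frame of allele-count records.
#' @export
read_count_table <- function(path, loci = ar_hotspot_loci()) {
  check_that(file.exists(path), "count table '%s' not found", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("count table '", path, "' is empty")
    return(df)
  }
  required <- c("sample_id", "locus_id", "allele", "fwd_count", "rev_count",
                "mean_base_quality", "mean_mapq")
  missing <- setdiff(required, names(df))
  check_that(length(missing) == 0, "count table missing columns: %s",
             paste(missing, collapse = ", "))
  bad_locus <- which(!df$locus_id %in% names(loci))
  check_that(length(bad_locus) == 0, "unknown locus '%s' at row %d",
             df$locus_id[bad_locus[1]], bad_locus[1])
  neg <- which(df$fwd_count < 0 | df$rev_count < 0)
  check_that(length(neg) == 0, "negative count at row %d", neg[1])
  key <- paste(df$sample_id, df$locus_id, df$allele)
  dup <- which(duplicated(key))
  check_that(length(dup) == 0, "duplicate (sample, locus, allele) at row %d", dup[1])
  df
}

#' Aggregate a per-read table through the read-quality gate
#'
#' Retains reads with base quality >= 25 and mapping quality strictly > 18
#' (the sequencing workflow's inclusion rule), then aggregates to stranded
#' allele counts with mean qualities of the retained reads.
#'
#' @param reads data.frame with columns \code{sample_id, locus_id, allele,
#'   strand} ("+" or "-"), \code{base_quality, mapq}.
#' @param min_base_quality inclusive Phred threshold.
#' @param min_mapq_exclusive exclusive mapping-quality threshold.
#' @return allele-count data.frame in the [read_count_table()] schema.
#' @export
apply_read_quality_gate <- function(reads, min_base_quality = 25,
                                    min_mapq_exclusive = 18) {
  required <- c("sample_id", "locus_id", "allele", "strand", "base_quality", "mapq")
  missing <- setdiff(required, names(reads))
  check_that(length(missing) == 0, "per-read table missing columns: %s",
             paste(missing, collapse = ", "))
  keep <- reads$base_quality >= min_base_quality & reads$mapq > min_mapq_exclusive
  kept <- reads[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(sample_id = character(), locus_id = character(),
                      allele = character(), fwd_count = integer(),
                      rev_count = integer(), mean_base_quality = numeric(),
                      mean_mapq = numeric(), stringsAsFactors = FALSE))
  key <- interaction(kept$sample_id, kept$locus_id, kept$allele, drop = TRUE)
  agg <- lapply(split(kept, key), function(g) {
    data.frame(sample_id = g$sample_id[1], locus_id = g$locus_id[1],
               allele = g$allele[1],
               fwd_count = sum(g$strand == "+"),
               rev_count = sum(g$strand == "-"),
               mean_base_quality = mean(g$base_quality),
               mean_mapq = mean(g$mapq), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Allelic fraction as a percentage
#'
#' The study tables report mutant burden as 100 * mutant / wild-type
#' (mutant-to-reference ratio), not mutant over total depth; both
#' conventions are exposed and the table convention is the default. With a
#' positive mutant count over zero reference reads the fraction saturates:
#' 100 is returned and the \code{"saturated"} attribute flags the affected
#' entries.
#'
#' @param alt_count,ref_count numeric vectors (recycled).
#' @param convention \code{"ref"} (100 * alt / ref, the reported
#'   convention) or \code{"total"} (100 * alt / (alt + ref)).
#' @return numeric percent vector with logical attribute
#'   \code{"saturated"}.
#' @examples
#' allelic_fraction_percent(21, 4519)  # 0.4647... -> prints as 0.46
#' @export
allelic_fraction_percent <- function(alt_count, ref_count,
                                     convention = c("ref", "total")) {
  convention <- match.arg(convention)
  n <- max(length(alt_count), length(ref_count))
  alt <- rep_len(alt_count, n)
  ref <- rep_len(ref_count, n)
  check_that(all(alt >= 0) && all(ref >= 0), "counts must be non-negative")
  undef <- alt == 0 & ref == 0
  if (any(undef))
    stop("allelic fraction undefined: both counts zero", call. = FALSE)
  saturated <- ref == 0 & alt > 0
  out <- numeric(n)
  denom <- if (convention == "ref") ref else alt + ref
  ok <- !saturated
  out[ok] <- 100 * alt[ok] / denom[ok]
  out[saturated] <- 100
  attr(out, "saturated") <- saturated
  out
}

#' Variant filter configuration
#'
#' Thresholds of the deep-sequencing filter cascade, with the boundary
#' semantics of the original workflow: base quality >= 25 inclusive,
#' mapping quality > 18 exclusive, alternate reads >= 15 inclusive,
#' allelic fraction must exceed 0.15\% (a fraction equal to 0.15\% is
#' excluded) and must not exceed 50\%, both sequencing strands must carry
#' the alternate, the alternate count must be at least twice the
#' next-highest non-reference allele at the site, and variants provisionally
#' called in more than half the cohort are excluded.
#'
#' @param min_base_quality inclusive Phred cut (read gate).
#' @param min_mapq_exclusive exclusive mapping-quality cut (read gate).
#' @param min_alt_reads inclusive minimum alternate read count.
#' @param min_af_exclusive percent; candidates at or below it fail.
#' @param max_af percent; candidates above it fail.
#' @param require_both_strands drop single-strand candidates.
#' @param next_allele_ratio required fold over the next-highest
#'   non-reference allele frequency.
#' @param max_cohort_prevalence fraction of samples above which a variant
#'   is excluded (strict inequality).
#' @param prevalence_includes_controls whether control samples count toward
#'   the cohort denominator (the original workflow leaves this unstated;
#'   both behaviours are supported).
#' @param af_convention see [allelic_fraction_percent()].
#' @return object of class \code{filter_config}.
#' @export
filter_config <- function(min_base_quality = 25, min_mapq_exclusive = 18,
                          min_alt_reads = 15, min_af_exclusive = 0.15,
                          max_af = 50, require_both_strands = TRUE,
                          next_allele_ratio = 2, max_cohort_prevalence = 0.5,
                          prevalence_includes_controls = TRUE,
                          af_convention = "ref") {
  check_that(min_af_exclusive < max_af, "min_af_exclusive must be below max_af")
  vals <- list(min_base_quality = min_base_quality,
               min_mapq_exclusive = min_mapq_exclusive,
               min_alt_reads = min_alt_reads,
               min_af_exclusive = min_af_exclusive, max_af = max_af,
               require_both_strands = require_both_strands,
               next_allele_ratio = next_allele_ratio,
               max_cohort_prevalence = max_cohort_prevalence,
               prevalence_includes_controls = prevalence_includes_controls,
               af_convention = af_convention)
  num <- unlist(vals[c("min_base_quality", "min_mapq_exclusive", "min_alt_reads",
                       "min_af_exclusive", "max_af", "next_allele_ratio",
                       "max_cohort_prevalence")])
  check_that(all(num >= 0), "filter thresholds must be >= 0")
  structure(vals, class = "filter_config")
}

#' Apply the variant-filter cascade to an allele-count cohort
#'
#' Each candidate (sample, locus, alternate allele) is evaluated against
#' the conjunctive filters MIN_ALT (alternate reads below threshold),
#' STRAND (alternate absent from one strand), LOW_AF (allelic fraction at
#' or below the floor), HIGH_AF (fraction above the ceiling) and
#' NEXT_ALLELE (alternate less than the required fold over the next-highest
#' non-reference allele at the site; passes when no second non-reference
#' allele exists). The cohort-prevalence filter COHORT is applied last,
#' over provisional calls only: if a (locus, allele) is provisionally
#' called in more than \code{max_cohort_prevalence} of the cohort's
#' samples, all its calls fail. All failure reasons are recorded; the
#' conjunctive filters are order-independent.
#'
#' @param records allele-count data.frame ([read_count_table()] schema);
#'   every (sample, locus) present must include its reference-allele row.
#' @param config a [filter_config()].
#' @param loci named list of [locus_spec()].
#' @param control_samples sample_ids excluded from the prevalence
#'   denominator when \code{prevalence_includes_controls} is FALSE.
#' @return data.frame of class \code{variant_calls}: one row per candidate
#'   with counts, allelic fraction, \code{status} (CALLED / FILTERED) and
#'   comma-separated failure \code{reasons}.
#' @export
call_variants <- function(records, config = filter_config(),
                          loci = ar_hotspot_loci(), control_samples = character()) {
  check_that(inherits(config, "filter_config"), "config must be a filter_config")
  check_that(nrow(records) >= 1, "empty cohort")
  all_samples <- unique(records$sample_id)
  prevalence_samples <- if (config$prevalence_includes_controls) all_samples
                        else setdiff(all_samples, control_samples)

  rows <- list()
  for (sid in all_samples) {
    srec <- records[records$sample_id == sid, , drop = FALSE]
    for (lid in unique(srec$locus_id)) {
      lrec <- srec[srec$locus_id == lid, , drop = FALSE]
      ref_base <- loci[[lid]]$ref_base
      ref_rows <- lrec[lrec$allele == ref_base, , drop = FALSE]
      check_that(nrow(ref_rows) == 1,
                 "sample %s locus %s lacks its reference-allele row", sid, lid)
      ref_count <- ref_rows$fwd_count + ref_rows$rev_count
      alt_rows <- lrec[lrec$allele != ref_base, , drop = FALSE]
      alt_totals <- alt_rows$fwd_count + alt_rows$rev_count
      for (i in seq_len(nrow(alt_rows))) {
        alt_count <- alt_totals[i]
        if (alt_count == 0) next
        af <- as.numeric(allelic_fraction_percent(alt_count, ref_count,
                                                  convention = config$af_convention))
        reasons <- character()
        if (alt_count < config$min_alt_reads) reasons <- c(reasons, "MIN_ALT")
        if (config$require_both_strands &&
            (alt_rows$fwd_count[i] == 0 || alt_rows$rev_count[i] == 0))
          reasons <- c(reasons, "STRAND")
        if (af <= config$min_af_exclusive) reasons <- c(reasons, "LOW_AF")
        if (af > config$max_af) reasons <- c(reasons, "HIGH_AF")
        next_best <- if (nrow(alt_rows) > 1) max(alt_totals[-i]) else 0
        if (next_best > 0 && alt_count < config$next_allele_ratio * next_best)
          reasons <- c(reasons, "NEXT_ALLELE")
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, locus_id = lid, alt = alt_rows$allele[i],
          alt_count = alt_count, ref_count = ref_count,
          fwd_count = alt_rows$fwd_count[i], rev_count = alt_rows$rev_count[i],
          af_percent = af,
          status = if (length(reasons)) "FILTERED" else "CALLED",
          reasons = paste(reasons, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), locus_id = character(), alt = character(),
               alt_count = integer(), ref_count = integer(),
               fwd_count = integer(), rev_count = integer(),
               af_percent = numeric(), status = character(), reasons = character(),
               stringsAsFactors = FALSE)

  # cohort-prevalence filter, applied last over provisional calls
  if (nrow(calls)) {
    prov <- calls$status == "CALLED"
    key <- paste(calls$locus_id, calls$alt)
    for (k in unique(key[prov])) {
      idx <- which(prov & key == k)
      n_called <- length(unique(calls$sample_id[idx]))
      if (n_called / length(prevalence_samples) > config$max_cohort_prevalence) {
        calls$status[idx] <- "FILTERED"
        calls$reasons[idx] <- vapply(calls$reasons[idx], function(r)
          if (nzchar(r)) paste(r, "COHORT", sep = ",") else "COHORT", "")
      }
    }
  }
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' @export
print.variant_calls <- function(x, digits = 2, ...) {
  n_called <- sum(x$status == "CALLED")
  cat(sprintf("Variant calls: %d candidate(s), %d CALLED\n", nrow(x), n_called))
  if (nrow(x)) {
    show <- as.data.frame(x)
    show$af_percent <- round_half_up(show$af_percent, digits)
    print.data.frame(show, row.names = FALSE)
  }
  invisible(x)
}

#' Write variant calls to disk
#'
#' Either a tab-delimited call table (round-trippable via [read_calls()])
#' or a minimal VCF 4.2 with allelic fraction, stranded alternate depths
#' and failure reasons; candidates that failed the cascade are emitted with
#' their reason codes in FILTER.
#'
#' @param calls a \code{variant_calls} data.frame.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @param loci locus definitions (required for VCF coordinates).
#' @return \code{path}, invisibly.
#' @export
write_calls <- function(calls, path, format = c("tsv", "vcf"),
                        loci = ar_hotspot_loci()) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allelic fraction, percent of wild-type reads\">",
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"Hotspot codon label\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Ref,Alt read depths\">",
    "##FORMAT=<ID=SB,Number=2,Type=Integer,Description=\"Alt forward,reverse depths\">",
    paste0("##FILTER=<ID=", c("MIN_ALT", "STRAND", "LOW_AF", "HIGH_AF",
                              "NEXT_ALLELE", "COHORT"),
           ",Description=\"Filter cascade failure\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tcall")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    l <- loci[[calls$locus_id[i]]]
    filt <- if (calls$status[i] == "CALLED") "PASS"
            else gsub(",", ";", calls$reasons[i])
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tAF=%.4f;LOCUS=%s;SAMPLE=%s\tAD:SB\t%d,%d:%d,%d",
            l$chrom, l$position, calls$locus_id[i], l$ref_base, calls$alt[i],
            filt, calls$af_percent[i], calls$locus_id[i],
            gsub("[ \t]", "_", calls$sample_id[i]),
            calls$ref_count[i], calls$alt_count[i],
            calls$fwd_count[i], calls$rev_count[i])
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read back a written call table
#' @param path tab-delimited file produced by [write_calls()].
#' @return \code{variant_calls} data.frame.
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(reasons = "character"))
  df$reasons[is.na(df$reasons)] <- ""
  class(df) <- c("variant_calls", "data.frame")
  df
}
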