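#' Packaged worked-example cohort: deep-sequencing allele counts
#'
#' The 13-sample (11 mCRPC patients + healthy male and female control
#' donors) x 5-locus allele-count table of the study's sequencing run, as
#' published mutant / wild-type read counts. The published table does not
#' break counts down by strand; the packaged fixture splits each count
#' near-evenly across strands (synthetic detail), which leaves the filter
#' cascade's strand test permissive for these records. One wild-type cell is
#' printed with a malformed thousands separator in the source table and is
#' stored here as 21143; it carries no mutant call.
#'
#' @return allele-count data.frame ([read_count_table()] schema).
#' @export
cohort_ngs_counts <- function() {
  read_count_table(system.file("extdata", "ngs_counts_cohort.tsv",
                               package = "ARfidelity"))
}

#' Packaged worked-example cohort: ddPCR droplet counts
#'
#' The study's four ddPCR validation tables in one long table:
#' F877L under Phusion and SuperFi preamplification (table "t4"), T878A
#' under both ("t5"), the 22- vs 12-cycle wild-type genomic DNA comparison
#' ("t6"), and W742C under both ("t7"). Each row carries the published
#' mutant / wild-type droplet counts, the printed percent-mutant value
#' (\code{percent_mutant_printed}, as a string preserving the table's
#' precision), and a \code{sample_type} annotation (patient, wt_control,
#' ntc, mutant_control, positive_cfdna). Total droplet counts were not
#' published, so Poisson quantities are not computable from this fixture.
#'
#' @param tables optional subset of c("t4","t5","t6","t7").
#' @return droplet-count data.frame ([read_droplet_table()] schema plus
#'   \code{table}, \code{sample_type} and \code{percent_mutant_printed}).
#' @export
cohort_droplet_counts <- function(tables = NULL) {
  df <- read_droplet_table(system.file("extdata", "ddpcr_droplets.tsv",
                                       package = "ARfidelity"))
  if (!is.null(tables)) df <- df[df$table %in% tables, , drop = FALSE]
  df
}

#' Published percent-mutant cells of the sequencing run
#'
#' The eight populated percent-mutant cells of the sequencing table (five
#' F877L patient calls, the male-control F877L signal, one W742C and one
#' T878A call) with their printed two-decimal values, for convention
#' checks.
#'
#' @return data.frame with sample_id, locus_id, mut, wt, printed_percent.
#' @export
ngs_reported_fractions <- function() {
  data.frame(
    sample_id = c("JHU Pt 3", "JHU Pt 3", "JHU Pt 4", "JHU Pt 7", "JHU Pt 8",
                  "JHU Pt 10", "JHU Pt 11", "Male Control"),
    locus_id = c("W742C", "F877L", "T878A", "F877L", "F877L", "F877L",
                 "F877L", "F877L"),
    mut = c(21, 26, 33, 36, 25, 51, 15, 30),
    wt = c(4519, 11152, 7924, 13386, 8863, 20322, 7334, 17609),
    printed_percent = c(0.46, 0.23, 0.42, 0.27, 0.28, 0.25, 0.20, 0.17),
    stringsAsFactors = FALSE
  )
}

#' Packaged synthetic hotspot context windows
#'
#' Illustrative 41-base windows centred on each hotspot site. The sequences
#' are synthetic (the source figure's sequence is not machine-readable and
#' no coordinates are given); they carry the correct reference base and
#' codon context at the site and serve to exercise the context-feature
#' operations, not to assert reference-genome content.
#'
#' @return named list of [context_window()] objects.
#' @export
ar_hotspot_windows <- function() {
  read_context_windows(system.file("extdata", "ar_hotspot_windows_synthetic.fa",
                                   package = "ARfidelity"))
}
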