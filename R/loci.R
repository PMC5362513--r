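#' Construct a hotspot locus specification
#'
#' A \code{locus_spec} describes one interrogated codon: the mutated genomic
#' base, the permitted substitutions, and the codon-change notation used on
#' assay report tables (lowercase marks the substituted base within the
#' codon, e.g. \code{"tTC>cTC"} for F877L).
#'
#' Coordinates are 1-based inclusive in all user-facing tables (VCF
#' convention); any 0-based arithmetic is internal and documented at the
#' boundary where it occurs.
#'
#' @param gene gene symbol (e.g. \code{"AR"}).
#' @param locus_id codon label such as \code{"F877L"}.
#' @param chrom chromosome name.
#' @param position 1-based genomic coordinate of the mutated base.
#' @param ref_base single uppercase reference nucleotide.
#' @param alt_bases character vector of single uppercase alternate
#'   nucleotides (some codons admit more than one, e.g. W742C TGg>TGt/c).
#' @param codon_notation codon-change string, validated against
#'   \code{ref_base}/\code{alt_bases} via [parse_codon_notation()].
#' @param orientation \code{"genomic"} or \code{"transcript"}; codon
#'   notation for minus-strand genes is stored as printed (transcript
#'   orientation) with this flag set. AR is on the plus strand of X, so its
#'   loci are \code{"genomic"}.
#' @return an object of class \code{locus_spec}.
#' @seealso [ar_hotspot_loci()] for the packaged AR ligand-binding-domain set.
#' @export
locus_spec <- function(gene, locus_id, chrom, position, ref_base, alt_bases,
                       codon_notation, orientation = c("genomic", "transcript")) {
  orientation <- match.arg(orientation)
  check_that(is_count(position) && position >= 1, "position must be a 1-based coordinate")
  check_that(grepl("^[ACGT]$", ref_base), "ref_base must be one of A/C/G/T, got '%s'", ref_base)
  check_that(length(alt_bases) >= 1 && all(grepl("^[ACGT]$", alt_bases)),
             "alt_bases must be single uppercase nucleotides")
  check_that(!ref_base %in% alt_bases, "ref_base '%s' may not appear among alt_bases", ref_base)
  parsed <- parse_codon_notation(codon_notation)
  check_that(parsed$ref_base == ref_base,
             "codon_notation '%s' implies ref %s, not %s", codon_notation, parsed$ref_base, ref_base)
  check_that(all(parsed$alt_base %in% alt_bases),
             "codon_notation '%s' implies alts not listed in alt_bases", codon_notation)
  structure(
    list(gene = gene, locus_id = locus_id, chrom = chrom,
         position = as.integer(position), ref_base = ref_base,
         alt_bases = alt_bases, codon_notation = codon_notation,
         codon_offset = parsed$codon_offset, orientation = orientation),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s %s (%s) %s:%d %s>%s\n",
              x$gene, x$locus_id, x$codon_notation, x$chrom, x$position,
              x$ref_base, paste(x$alt_bases, collapse = "/")))
  invisible(x)
}

#' Parse codon-change notation
#'
#' Parses strings of the form \code{"tTC>cTC"}: three bases on each side of
#' \code{">"}, exactly one lowercase position on each side (the same
#' position), the two sides differing only there. The lowercase base is the
#' substituted one. Multi-alternate codons are written with \code{"/"}
#' separating the alternate bases (e.g. \code{"TGg>TGt/c"}).
#'
#' @param notation codon-change string.
#' @return a list with \code{ref_base}, \code{alt_base} (vector if the
#'   notation lists several alternates), and \code{codon_offset}, the
#'   0-based position of the substitution within the codon.
#' @examples
#' parse_codon_notation("tTC>cTC")  # F877L: T>C at codon offset 0
#' parse_codon_notation("TGg>TGt/c")  # W742C: G>T or G>C at offset 2
#' @export
parse_codon_notation <- function(notation) {
  bad <- function(why) stop(sprintf("malformed codon notation '%s': %s", notation, why),
                            call. = FALSE)
  if (!is.character(notation) || length(notation) != 1L || !grepl(">", notation, fixed = TRUE))
    bad("expected '<codon>><codon>'")
  sides <- strsplit(notation, ">", fixed = TRUE)[[1]]
  if (length(sides) != 2L) bad("exactly one '>' expected")
  lhs <- sides[1]
  # alternates after the first are single lowercase bases separated by '/'
  rhs_parts <- strsplit(sides[2], "/", fixed = TRUE)[[1]]
  rhs <- rhs_parts[1]
  extra_alts <- rhs_parts[-1]
  if (nchar(lhs) != 3L || nchar(rhs) != 3L) bad("each side must have 3 bases")
  if (!grepl("^[ACGTacgt]+$", lhs) || !grepl("^[ACGTacgt]+$", rhs)) bad("non-nucleotide character")
  if (length(extra_alts) && !all(grepl("^[acgt]$", extra_alts)))
    bad("alternates after '/' must be single lowercase bases")
  lhs_chars <- strsplit(lhs, "")[[1]]
  rhs_chars <- strsplit(rhs, "")[[1]]
  low_l <- which(lhs_chars %in% letters)
  low_r <- which(rhs_chars %in% letters)
  if (length(low_l) != 1L || length(low_r) != 1L) bad("exactly one lowercase base per side")
  if (low_l != low_r) bad("lowercase positions differ between sides")
  up_l <- toupper(lhs_chars)
  up_r <- toupper(rhs_chars)
  if (!identical(up_l[-low_l], up_r[-low_r])) bad("sides differ outside the marked base")
  if (up_l[low_l] == up_r[low_r]) bad("no change at the marked base")
  alts <- unique(c(up_r[low_r], toupper(extra_alts)))
  if (up_l[low_l] %in% alts) bad("an alternate equals the reference base")
  list(ref_base = up_l[low_l], alt_base = alts, codon_offset = low_l - 1L)
}

#' Reconstruct codon-change notation from its parse
#'
#' Inverse of [parse_codon_notation()] given the wild-type codon; used to
#' verify notation round-trips.
#'
#' @param wt_codon uppercase 3-base wild-type codon.
#' @param parsed result of [parse_codon_notation()].
#' @return the notation string.
#' @export
codon_notation_from_parse <- function(wt_codon, parsed) {
  check_that(nchar(wt_codon) == 3L && grepl("^[ACGT]{3}$", wt_codon),
             "wt_codon must be a 3-base uppercase codon")
  i <- parsed$codon_offset + 1L
  chars <- strsplit(wt_codon, "")[[1]]
  check_that(chars[i] == parsed$ref_base,
             "wt_codon base at offset %d is %s, parse says %s", i - 1L, chars[i], parsed$ref_base)
  lhs <- chars; lhs[i] <- tolower(lhs[i])
  rhs <- chars; rhs[i] <- tolower(parsed$alt_base[1])
  out <- paste0(paste(lhs, collapse = ""), ">", paste(rhs, collapse = ""))
  if (length(parsed$alt_base) > 1L)
    out <- paste0(out, "/", paste(tolower(parsed$alt_base[-1]), collapse = "/"))
  out
}

#' The AR ligand-binding-domain hotspot loci
#'
#' Returns the five interrogated AR codons (L702H, W742C, H875Y, F877L,
#' T878A) as a named list of [locus_spec()] objects, read from the packaged
#' configuration file. Genomic coordinates in the shipped configuration are
#' illustrative placeholders: the analysis operates on locus identifiers and
#' never performs genome lookups.
#'
#' @param config_path optional path to an alternative YAML locus
#'   configuration (fields per locus: gene, locus_id, chrom, position, ref,
#'   alts, notation, orientation).
#' @return named list of \code{locus_spec} objects, keyed by locus_id.
#' @export
ar_hotspot_loci <- function(config_path = NULL) {
  if (is.null(config_path))
    config_path <- system.file("extdata", "ar_hotspot_loci.yaml", package = "ARfidelity")
  read_locus_config(config_path)
}

#' Read a locus configuration file
#'
#' @param path YAML file with a top-level \code{loci} list.
#' @return named list of \code{locus_spec} objects.
#' @export
read_locus_config <- function(path) {
  check_that(file.exists(path), "locus config '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  check_that(!is.null(cfg$loci), "locus config must have a top-level 'loci' list")
  out <- lapply(cfg$loci, function(l) {
    locus_spec(gene = l$gene, locus_id = l$locus_id, chrom = l$chrom,
               position = l$position, ref_base = l$ref,
               alt_bases = unlist(l$alts), codon_notation = l$notation,
               orientation = if (is.null(l$orientation)) "genomic" else l$orientation)
  })
  names(out) <- vapply(out, `[[`, "", "locus_id")
  out
}

#' Construct a sequence-context window around a hotspot site
#'
#' @param locus_id locus label.
#' @param sequence uppercase nucleotide string (ACGTN).
#' @param offset_of_site 0-based index of the mutated base within
#'   \code{sequence}.
#' @param window_half_width bases intended on each side; the sequence may be
#'   shorter if truncated at a contig end, but the offset must still index
#'   the site.
#' @return object of class \code{context_window}.
#' @export
context_window <- function(locus_id, sequence, offset_of_site, window_half_width) {
  sequence <- toupper(sequence)
  check_that(grepl("^[ACGTN]+$", sequence), "sequence may contain only A/C/G/T/N")
  n <- nchar(sequence)
  check_that(is_count(offset_of_site) && offset_of_site < n,
             "offset_of_site (0-based) must index into the sequence")
  check_that(n <= 2 * window_half_width + 1,
             "sequence longer than 2*half_width+1")
  structure(
    list(locus_id = locus_id, sequence = sequence,
         offset_of_site = as.integer(offset_of_site),
         window_half_width = as.integer(window_half_width)),
    class = "context_window"
  )
}

#' Read context windows from a FASTA file
#'
#' Each FASTA record header must be
#' \code{"<locus_id> offset=<0-based site index> half_width=<w>"}.
#' The packaged windows
#' (\code{inst/extdata/ar_hotspot_windows_synthetic.fa}) are synthetic
#' illustrative sequences, not assertions about the reference genome.
#'
#' @param path FASTA file.
#' @return named list of \code{context_window} objects keyed by locus_id.
#' @export
read_context_windows <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    fields <- strsplit(header, "\\s+")[[1]]
    locus_id <- fields[1]
    kv <- fields[-1]
    get_kv <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      check_that(length(hit) == 1L, "FASTA header '%s' lacks %s=", header, key)
      as.integer(sub(paste0("^", key, "="), "", hit))
    }
    context_window(locus_id, as.character(seqs[[i]]), get_kv("offset"), get_kv("half_width"))
  })
  names(out) <- vapply(out, `[[`, "", "locus_id")
  out
}

#' GC content of a context window
#'
#' Fraction (G+C)/(A+C+G+T); N bases are excluded from both numerator and
#' denominator, so windows crossing masked sequence remain comparable.
#'
#' @param window a [context_window()] (or a plain nucleotide string).
#' @return fraction in [0, 1].
#' @export
gc_content <- function(window) {
  seq <- if (inherits(window, "context_window")) window$sequence else toupper(window)
  check_that(nzchar(seq), "sequence is empty")
  chars <- strsplit(seq, "")[[1]]
  acgt <- chars[chars != "N"]
  if (length(acgt) == 0L)
    stop("GC content undefined: sequence is all N", call. = FALSE)
  sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Repeat features of a context window
#'
#' Two simple low-complexity descriptors used to compare hotspot contexts:
#' the longest homopolymer run and the longest tandem dinucleotide repeat.
#' A homopolymer of length 2k is itself a degenerate dinucleotide repeat of
#' k units; both counts are reported as-is.
#'
#' @param window a [context_window()] or nucleotide string.
#' @return list with \code{max_homopolymer_len} and
#'   \code{max_dinucleotide_repeat_units} (whole tandem units of a 2-mer).
#' @export
repeat_features <- function(window) {
  seq <- if (inherits(window, "context_window")) window$sequence else toupper(window)
  check_that(nzchar(seq), "sequence is empty")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  runs <- rle(chars)
  max_homo <- max(runs$lengths)
  max_di <- if (n >= 2L) 1L else 0L
  if (n >= 2L) {
    # tandem 2-mer scan from each phase position
    for (start in seq_len(n - 1L)) {
      unit <- chars[start:(start + 1L)]
      units <- 1L
      i <- start + 2L
      while (i + 1L <= n && chars[i] == unit[1] && chars[i + 1L] == unit[2]) {
        units <- units + 1L
        i <- i + 2L
      }
      if (units > max_di) max_di <- units
    }
  }
  list(max_homopolymer_len = as.integer(max_homo),
       max_dinucleotide_repeat_units = as.integer(max_di))
}
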