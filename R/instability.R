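#' Weighted genome integrity index (wGII)
#'
#' For each autosome, the fraction of its covered length whose total copy
#' number (\code{n_major + n_minor}) differs from the rounded sample ploidy
#' (half-up at .5); wGII is the unweighted mean of these per-chromosome
#' fractions, so small chromosomes weigh as much as large ones. Covered
#' length is the denominator: uncovered gaps do not dilute the fraction.
#'
#' @param profile a canonicalized [segment_profile] with ploidy set.
#' @param annotation a [genome_annotation].
#' @param config a [scar_config()] (controls sex-chromosome inclusion).
#' @return wGII in [0, 1].
#' @export
wgii <- function(profile, annotation, config = scar_config()) {
  target <- floor(profile$ploidy + 0.5)
  s <- profile$segments
  chroms <- scored_chroms(profile, config)
  fracs <- numeric(0)
  for (chrom in chroms) {
    ann_row(annotation, chrom)
    cs <- s[s$chrom == chrom, , drop = FALSE]
    len <- cs$end - cs$start
    cov <- sum(len)
    if (cov <= 0) next
    aberrant <- sum(len[cs$n_major + cs$n_minor != target])
    fracs <- c(fracs, aberrant / cov)
  }
  if (!length(fracs))
    stop("sample ", profile$sample_id, ": no covered autosomes for wGII")
  mean(fracs)
}

#' Fraction of the genome in LOH (FLOH)
#'
#' Total covered autosomal length with \code{n_minor == 0} divided by the
#' total covered autosomal length.
#'
#' @inheritParams wgii
#' @return FLOH in [0, 1].
#' @export
floh <- function(profile, annotation, config = scar_config()) {
  s <- profile$segments
  s <- s[s$chrom %in% scored_chroms(profile, config), , drop = FALSE]
  for (chrom in unique(s$chrom)) ann_row(annotation, chrom)
  len <- s$end - s$start
  cov <- sum(len)
  if (cov <= 0)
    stop("sample ", profile$sample_id, ": zero covered length for FLOH")
  sum(len[s$n_minor == 0]) / cov
}

#' Total mutation count (Nmut)
#'
#' The number of called base substitutions, indels, and dinucleotide
#' mutations. Classes are validated on ingest ([read_mutations()]), so
#' Nmut is simply the record count.
#'
#' @param mutations mutation data frame; \code{NULL} yields \code{NA}
#'   (missing mutation data is never silently zero).
#' @param sample_id optional sample to subset to.
#' @return Integer count, or \code{NA_integer_} when no table is given.
#' @export
nmut <- function(mutations, sample_id = NULL) {
  if (is.null(mutations)) return(NA_integer_)
  if (!is.null(sample_id))
    mutations <- mutations[mutations$sample == sample_id, , drop = FALSE]
  nrow(mutations)
}

#' DNA index and ploidy class
#'
#' The DNA index is the tumor ploidy divided by the expected ploidy of 2.
#' Samples with DNA index strictly greater than the threshold (default
#' 1.2) are classified near-tetraploid; all others near-diploid, following
#' the view that whole-genome duplication is the dominant route to
#' aneuploidy.
#'
#' @param ploidy tumor ploidy (> 0).
#' @param threshold DNA-index cutoff (strict \code{>}).
#' @return \code{list(dna_index =, ploidy_class =)} with
#'   \code{ploidy_class} one of \code{"near_diploid"},
#'   \code{"near_tetraploid"}.
#' @examples
#' classify_ploidy(2.0)  # near_diploid
#' classify_ploidy(3.1)  # near_tetraploid
#' @export
classify_ploidy <- function(ploidy, threshold = 1.2) {
  if (!is.finite(ploidy) || ploidy <= 0) stop("ploidy must be > 0")
  di <- ploidy / 2
  list(dna_index = di,
       ploidy_class = if (di > threshold) "near_tetraploid"
                      else "near_diploid")
}

#' Instability metrics for one sample
#'
#' Computes wGII, FLOH, Nmut, DNA index and ploidy class on a canonicalized
#' profile.
#'
#' @inheritParams wgii
#' @param mutations optional mutation table for Nmut.
#' @param dna_index_threshold near-tetraploid cutoff on DNA index.
#' @return One-row data frame with columns \code{sample}, \code{wgii},
#'   \code{floh}, \code{nmut}, \code{dna_index}, \code{ploidy_class}.
#' @export
instability_metrics <- function(profile, annotation, mutations = NULL,
                                config = scar_config(),
                                dna_index_threshold = 1.2) {
  profile <- merge_adjacent_equal(profile)
  pc <- classify_ploidy(profile$ploidy, dna_index_threshold)
  data.frame(sample = profile$sample_id,
             wgii = wgii(profile, annotation, config),
             floh = floh(profile, annotation, config),
             nmut = nmut(mutations, profile$sample_id),
             dna_index = pc$dna_index,
             ploidy_class = pc$ploidy_class,
             stringsAsFactors = FALSE)
}
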