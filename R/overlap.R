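#' Breakpoints measured by each signature
#'
#' Collects, per signature, the set of internal segmentation boundaries
#' that delimit its counted events. Positions are namespaced by sample (the
#' three signatures run on the same segmentation of the same sample, so
#' breakpoint identity is exact coordinate equality within a sample).
#'
#' @param events event data frame from [score_sample()] or
#'   [score_cohort()] (columns \code{sample}, \code{signature},
#'   \code{chrom}, \code{breakpoints} with semicolon-joined positions).
#' @return Named list \code{NTAI}, \code{LST}, \code{HRD_LOH} of character
#'   vectors \code{"sample:chrom:pos"}.
#' @export
signature_breakpoints <- function(events) {
  out <- list(NTAI = character(0), LST = character(0),
              HRD_LOH = character(0))
  if (is.null(events) || !nrow(events)) return(out)
  has_bp <- nzchar(events$breakpoints)
  for (i in which(has_bp)) {
    pos <- strsplit(events$breakpoints[i], ";", fixed = TRUE)[[1L]]
    ids <- paste(events$sample[i], events$chrom[i], pos, sep = ":")
    sig <- events$signature[i]
    out[[sig]] <- union(out[[sig]], ids)
  }
  out
}

#' Venn fractions of signature breakpoints
#'
#' Partitions the union of all breakpoints measured by one or more
#' signatures into the seven exclusive Venn regions and reports each as a
#' percentage of the union.
#'
#' @param bp_sets named list (\code{NTAI}, \code{LST}, \code{HRD_LOH}) of
#'   breakpoint identifier vectors, as produced by
#'   [signature_breakpoints()].
#' @return Named numeric vector of percentages (\code{ntai_only},
#'   \code{lst_only}, \code{hrdloh_only}, \code{ntai_lst},
#'   \code{ntai_hrdloh}, \code{lst_hrdloh}, \code{all_three}); sums to 100.
#' @export
venn_fractions <- function(bp_sets) {
  a <- unique(bp_sets$NTAI); b <- unique(bp_sets$LST)
  c_ <- unique(bp_sets$HRD_LOH)
  u <- unique(c(a, b, c_))
  if (!length(u)) stop("no breakpoints: Venn fractions are undefined")
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c_
  n <- length(u)
  pct <- function(keep) 100 * sum(keep) / n
  c(ntai_only   = pct(in_a & !in_b & !in_c),
    lst_only    = pct(!in_a & in_b & !in_c),
    hrdloh_only = pct(!in_a & !in_b & in_c),
    ntai_lst    = pct(in_a & in_b & !in_c),
    ntai_hrdloh = pct(in_a & !in_b & in_c),
    lst_hrdloh  = pct(!in_a & in_b & in_c),
    all_three   = pct(in_a & in_b & in_c))
}

#' Write Venn fractions to a tab-delimited file
#' @param fractions output of [venn_fractions()].
#' @param path output path.
#' @export
write_venn <- function(fractions, path) {
  utils::write.table(
    data.frame(region = names(fractions), percent = as.numeric(fractions),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
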