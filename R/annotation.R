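#' Construct a genome annotation table
#'
#' A genome annotation holds, per chromosome, the chromosome length and the
#' centromere interval. It defines the chromosome arms used throughout the
#' package: the p arm is \code{[0, cen_start)} and the q arm is
#' \code{[cen_end, length)} (0-based, half-open).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length chromosome lengths in bp.
#' @param cen_start,cen_end centromere interval in bp; must satisfy
#'   \code{0 < cen_start < cen_end < length}.
#' @return A \code{genome_annotation} object (a data frame with columns
#'   \code{chrom}, \code{length}, \code{cen_start}, \code{cen_end}).
#' @examples
#' genome_annotation(c("chr1", "chr2"), c(100e6, 80e6),
#'                   c(45e6, 35e6), c(55e6, 45e6))
#' @export
genome_annotation <- function(chrom, length, cen_start, cen_end) {
  ann <- data.frame(chrom = as.character(chrom),
                    length = as.numeric(length),
                    cen_start = as.numeric(cen_start),
                    cen_end = as.numeric(cen_end),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' @rdname genome_annotation
#' @param ann a data frame with the four annotation columns.
#' @export
validate_annotation <- function(ann) {
  req <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(req, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(ann) < 1L)
    stop("annotation must contain at least one chromosome")
  dup <- ann$chrom[duplicated(ann$chrom)]
  if (length(dup))
    stop("duplicate chromosome name(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  bad <- !(is.finite(ann$length) & ann$length > 0 &
             is.finite(ann$cen_start) & is.finite(ann$cen_end) &
             ann$cen_start > 0 & ann$cen_start < ann$cen_end &
             ann$cen_end < ann$length)
  if (any(bad))
    stop("invalid chromosome geometry (need 0 < cen_start < cen_end < length) for: ",
         paste(ann$chrom[bad], collapse = ", "))
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Read a genome annotation from a tab-delimited file
#'
#' Expects a header with columns \code{chrom}, \code{length},
#' \code{cen_start}, \code{cen_end} (BED-like; bp coordinates).
#'
#' @param path file path.
#' @return A [genome_annotation] object.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Write a genome annotation to a tab-delimited file
#' @param ann a [genome_annotation].
#' @param path output file path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Approximate human autosome annotation
#'
#' Chromosome lengths and centromere intervals approximating the 22 human
#' autosomes (GRCh37 scale, rounded to 0.1 Mb). Used as the default genome
#' for the simulator; positions are deliberately round numbers, not exact
#' assembly coordinates.
#'
#' @return A [genome_annotation] with 22 autosomes named \code{chr1..chr22}.
#' @export
hg_autosomes <- function() {
  Mb <- 1e6
  len <- c(249.3, 243.2, 198.0, 191.2, 180.9, 171.1, 159.1, 146.4, 141.2,
           135.5, 135.0, 133.9, 115.2, 107.3, 102.5, 90.4, 81.2, 78.1,
           59.1, 63.0, 48.1, 51.3)
  cs <- c(121.5, 92.3, 90.5, 49.7, 46.4, 58.8, 58.1, 43.8, 47.4, 39.3,
          51.6, 34.9, 16.0, 16.1, 17.0, 35.3, 22.3, 15.5, 24.4, 26.4,
          11.3, 13.0)
  genome_annotation(paste0("chr", 1:22), len * Mb, cs * Mb, (cs + 3) * Mb)
}

# Arm table: one row per (chrom, arm) with half-open arm interval.
chrom_arms <- function(ann) {
  rbind(
    data.frame(chrom = ann$chrom, arm = "p", start = 0,
               end = ann$cen_start, stringsAsFactors = FALSE),
    data.frame(chrom = ann$chrom, arm = "q", start = ann$cen_end,
               end = ann$length, stringsAsFactors = FALSE)
  )
}

# Single annotation row for a chromosome; errors on unknown names.
ann_row <- function(ann, chrom) {
  i <- match(chrom, ann$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  ann[i, , drop = FALSE]
}

# Sex chromosomes are accepted on input but excluded from scoring by default.
is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}
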