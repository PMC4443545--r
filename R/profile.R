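#' Construct an allele-specific segment profile
#'
#' A segment profile holds one tumor's allele-specific copy-number segments
#' together with its ASCAT-style ploidy (average copies per locus) and
#' aberrant cell fraction (ACF). Coordinates are 0-based, half-open, so a
#' segment's length is simply \code{end - start}. Per chromosome, segments
#' must be sorted and non-overlapping; gaps (uncovered probes) are allowed
#' and are never merged across.
#'
#' @param sample_id sample label.
#' @param segments data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{n_major}, \code{n_minor} (integer copy numbers with
#'   \code{n_major >= n_minor >= 0}).
#' @param ploidy average copy number per locus; must be > 0.
#' @param acf aberrant cell fraction in (0, 1].
#' @param annotation optional [genome_annotation]; when supplied, segments
#'   are checked to lie within their chromosome bounds.
#' @return A \code{segment_profile} object.
#' @export
segment_profile <- function(sample_id, segments, ploidy = 2, acf = 1,
                            annotation = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "n_major", "n_minor")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stop("segments missing column(s): ", paste(miss, collapse = ", "))
  segments <- segments[req]
  segments$chrom <- as.character(segments$chrom)
  for (col in req[-1]) segments[[col]] <- as.numeric(segments[[col]])
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  prof <- structure(list(sample_id = as.character(sample_id),
                         ploidy = as.numeric(ploidy),
                         acf = as.numeric(acf),
                         segments = segments),
                    class = "segment_profile")
  validate_profile(prof, annotation)
}

#' @rdname segment_profile
#' @param profile a \code{segment_profile}.
#' @export
validate_profile <- function(profile, annotation = NULL) {
  if (!inherits(profile, "segment_profile"))
    stop("not a segment_profile")
  s <- profile$segments
  id <- profile$sample_id
  if (!is.finite(profile$ploidy) || profile$ploidy <= 0)
    stop("sample ", id, ": ploidy must be > 0")
  if (!is.finite(profile$acf) || profile$acf <= 0 || profile$acf > 1)
    stop("sample ", id, ": acf must be in (0, 1]")
  if (nrow(s)) {
    bad <- !(is.finite(s$start) & is.finite(s$end) & s$start < s$end)
    if (any(bad))
      stop("sample ", id, ": segment with start >= end on ",
           paste(unique(s$chrom[bad]), collapse = ", "))
    bad <- !(s$n_major >= s$n_minor & s$n_minor >= 0 &
               s$n_major == round(s$n_major) & s$n_minor == round(s$n_minor))
    if (any(bad))
      stop("sample ", id, ": invalid copy state (need integer n_major >= n_minor >= 0) on ",
           paste(unique(s$chrom[bad]), collapse = ", "))
    for (chr in unique(s$chrom)) {
      cs <- s[s$chrom == chr, , drop = FALSE]
      if (nrow(cs) > 1L && any(cs$start[-1] < cs$end[-nrow(cs)]))
        stop("sample ", id, ": overlapping segments on ", chr)
      if (!is.null(annotation)) {
        a <- ann_row(annotation, chr)
        if (any(cs$start < 0) || any(cs$end > a$length))
          stop("sample ", id, ": segment outside chromosome bounds on ", chr)
      }
    }
  }
  profile
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile '%s': %d segments on %d chromosome(s); ploidy %.3g, ACF %.3g\n",
              x$sample_id, nrow(x$segments),
              length(unique(x$segments$chrom)), x$ploidy, x$acf))
  invisible(x)
}

#' Read allele-specific segment profiles from a tab-delimited file
#'
#' Reads an ASCAT-style segment table with header columns \code{sample},
#' \code{chrom}, \code{start}, \code{end}, \code{nMajor}, \code{nMinor}
#' (aliases \code{n_major}/\code{n_minor} accepted). Per-sample ploidy and
#' ACF may be supplied either as constant columns \code{ploidy}/\code{acf}
#' in the segment table or via a sidecar \code{metadata} table with columns
#' \code{sample}, \code{ploidy}, \code{acf}; both dialects are accepted.
#'
#' @param path segment table path.
#' @param annotation optional [genome_annotation] used to validate bounds.
#' @param one_based if \code{TRUE}, input coordinates are interpreted as
#'   1-based inclusive (the common dialect of ASCAT tables) and converted to
#'   the internal 0-based half-open convention on ingest.
#' @param metadata optional path or data frame with per-sample
#'   \code{ploidy} and \code{acf}.
#' @return Named list of [segment_profile] objects, one per distinct sample.
#' @export
read_segments <- function(path, annotation = NULL, one_based = FALSE,
                          metadata = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "nMajor"] <- "n_major"
  names(df)[names(df) == "nMinor"] <- "n_minor"
  req <- c("sample", "chrom", "start", "end", "n_major", "n_minor")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("segment file missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("start", "end", "n_major", "n_minor")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop("malformed value in column '", col, "' at file line ",
           bad[1L] + 1L, " of ", path)
    df[[col]] <- v
  }
  if (one_based) df$start <- df$start - 1
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata))
      utils::read.delim(metadata, stringsAsFactors = FALSE) else metadata
    if (!all(c("sample", "ploidy", "acf") %in% names(meta)))
      stop("metadata must have columns sample, ploidy, acf")
  }
  out <- list()
  for (id in unique(df$sample)) {
    rows <- df[df$sample == id, , drop = FALSE]
    if (!is.null(meta)) {
      j <- match(id, meta$sample)
      if (is.na(j)) stop("no metadata row for sample ", id)
      ploidy <- meta$ploidy[j]; acf <- meta$acf[j]
    } else if (all(c("ploidy", "acf") %in% names(rows))) {
      ploidy <- rows$ploidy[1L]; acf <- rows$acf[1L]
    } else {
      ploidy <- 2; acf <- 1
    }
    out[[id]] <- segment_profile(id, rows[, c("chrom", "start", "end",
                                              "n_major", "n_minor")],
                                 ploidy = ploidy, acf = acf,
                                 annotation = annotation)
  }
  out
}

#' Write segment profiles to a tab-delimited file
#'
#' Inverse of [read_segments()]: writes the ASCAT-style dialect with inline
#' \code{ploidy} and \code{acf} columns so that a write/read round trip
#' reproduces the profiles exactly.
#'
#' @param profiles a [segment_profile] or list of them.
#' @param path output path.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "segment_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    cbind(data.frame(sample = p$sample_id, stringsAsFactors = FALSE),
          p$segments, ploidy = p$ploidy, acf = p$acf)
  })
  df <- do.call(rbind, tabs)
  names(df)[names(df) == "n_major"] <- "nMajor"
  names(df)[names(df) == "n_minor"] <- "nMinor"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal MAF-like mutation table
#'
#' Expects header columns \code{sample}, \code{chrom}, \code{pos},
#' \code{variant_class}, with \code{variant_class} restricted to
#' \code{substitution}, \code{indel}, or \code{dinucleotide} (the three
#' classes entering the Nmut count).
#'
#' @param path file path.
#' @return Data frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "pos", "variant_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mutation file missing column(s): ", paste(miss, collapse = ", "))
  allowed <- c("substitution", "indel", "dinucleotide")
  bad <- !(df$variant_class %in% allowed)
  if (any(bad))
    stop("unknown variant_class at file line ", which(bad)[1L] + 1L, ": '",
         df$variant_class[which(bad)[1L]], "'")
  df
}

#' Merge abutting equal-state segments
#'
#' Canonicalizes a profile so that no two abutting segments on the same
#' chromosome share the same \code{(n_major, n_minor)} state. Segments
#' separated by an uncovered gap are never merged, so total covered length
#' is unchanged. All signature counters apply this canonicalization first;
#' scores are therefore invariant to splitting any segment into abutting
#' equal-state pieces.
#'
#' @param profile a [segment_profile].
#' @return A canonicalized [segment_profile].
#' @export
merge_adjacent_equal <- function(profile) {
  s <- profile$segments
  if (nrow(s) < 2L) return(profile)
  pieces <- lapply(split(s, s$chrom), function(cs) {
    cs <- cs[order(cs$start), , drop = FALSE]
    n <- nrow(cs)
    if (n < 2L) return(cs)
    # run id increments where the state changes or segments do not abut
    new_run <- c(TRUE, !(cs$start[-1] == cs$end[-n] &
                           cs$n_major[-1] == cs$n_major[-n] &
                           cs$n_minor[-1] == cs$n_minor[-n]))
    run <- cumsum(new_run)
    data.frame(chrom = cs$chrom[!duplicated(run)],
               start = tapply(cs$start, run, min),
               end = tapply(cs$end, run, max),
               n_major = cs$n_major[!duplicated(run)],
               n_minor = cs$n_minor[!duplicated(run)],
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, pieces)
  segment_profile(profile$sample_id, merged, profile$ploidy, profile$acf)
}

# Per-chromosome segment matrices (start, end, n_major, n_minor), sorted.
# Internal fast path used by the counters.
chrom_seg_list <- function(profile) {
  s <- profile$segments
  if (!nrow(s)) return(list())
  m <- as.matrix(s[, c("start", "end", "n_major", "n_minor")])
  lapply(split.data.frame(m, s$chrom), function(x) {
    x[order(x[, 1L]), , drop = FALSE]
  })
}
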