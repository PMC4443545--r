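#' Scar-counting configuration
#'
#' Thresholds for the three signature counters. Defaults follow the
#' published definitions: LST flanks of at least 10 Mb after removal of
#' segments shorter than 3 Mb, with counted boundaries separated by less
#' than 3 Mb; HRD-LOH regions strictly longer than 15 Mb. Chromosome 17 is
#' included in HRD-LOH by default (\code{exclude_chroms} empty); the
#' original HRD-LOH exclusion can be reproduced with
#' \code{exclude_chroms = "chr17"}. NtAI imposes no minimum event size by
#' default; \code{min_tai} is provided for sensitivity analysis.
#'
#' @param min_flank minimum flank segment length for an LST, bp.
#' @param max_gap maximum genomic distance between LST flanks, bp
#'   (boundaries with a gap of \code{max_gap} or more are not counted).
#' @param min_keep LST smoothing threshold: segments strictly shorter than
#'   this are removed before counting, bp.
#' @param min_loh HRD-LOH regions must be strictly longer than this, bp.
#' @param min_tai minimum NtAI event size, bp (default 0: none).
#' @param exclude_chroms chromosomes skipped by the HRD-LOH counter.
#' @param include_sex if \code{TRUE}, X/Y are scored like autosomes;
#'   by default sex chromosomes are excluded from all signatures and
#'   metrics.
#' @return A list of class \code{scar_config}.
#' @export
scar_config <- function(min_flank = 10e6, max_gap = 3e6, min_keep = 3e6,
                        min_loh = 15e6, min_tai = 0,
                        exclude_chroms = character(), include_sex = FALSE) {
  stopifnot(min_flank > 0, max_gap > 0, min_keep > 0, min_loh > 0,
            min_tai >= 0)
  structure(list(min_flank = min_flank, max_gap = max_gap,
                 min_keep = min_keep, min_loh = min_loh, min_tai = min_tai,
                 exclude_chroms = as.character(exclude_chroms),
                 include_sex = isTRUE(include_sex)),
            class = "scar_config")
}

# Chromosomes a profile is scored on, honouring sex-chromosome policy.
scored_chroms <- function(profile, config) {
  chroms <- unique(profile$segments$chrom)
  if (!config$include_sex) chroms <- chroms[!is_sex_chrom(chroms)]
  chroms
}

#' Major copy number state of a chromosome
#'
#' The major copy state is the allele-specific state \code{(n_major,
#' n_minor)} covering the greatest total length among segments with total
#' copy number greater than zero. It is the reference against which NtAI
#' events must deviate, which corrects the over-counting of interstitial
#' events on chromosomes with an uneven (e.g. triploid) background state.
#' Ties are broken deterministically: greatest total length, then lower
#' total copy number, then lower \code{n_major}.
#'
#' @param profile a canonicalized [segment_profile].
#' @param chrom chromosome name.
#' @param annotation optional [genome_annotation]; when given, \code{chrom}
#'   must be one of its chromosomes.
#' @return Numeric \code{c(n_major, n_minor)}, or \code{NULL} when the
#'   chromosome carries no segment with total copy number > 0.
#' @export
major_copy_state <- function(profile, chrom, annotation = NULL) {
  if (!is.null(annotation)) ann_row(annotation, chrom)
  s <- profile$segments
  s <- s[s$chrom == chrom, , drop = FALSE]
  if (!nrow(s)) return(NULL)
  m <- as.matrix(s[, c("start", "end", "n_major", "n_minor")])
  major_state_mat(m)
}

# matrix fast path; m has columns start, end, n_major, n_minor
major_state_mat <- function(m) {
  keep <- m[, 3L] + m[, 4L] > 0
  if (!any(keep)) return(NULL)
  m <- m[keep, , drop = FALSE]
  key <- paste(m[, 3L], m[, 4L])
  len <- vapply(split(m[, 2L] - m[, 1L], key), sum, numeric(1))
  st <- do.call(rbind, strsplit(names(len), " ", fixed = TRUE))
  nmaj <- as.numeric(st[, 1L]); nmin <- as.numeric(st[, 2L])
  i <- order(-len, nmaj + nmin, nmaj)[1L]
  c(n_major = nmaj[i], n_minor = nmin[i])
}

empty_events <- function() {
  data.frame(sample = character(), signature = character(),
             chrom = character(), region_start = numeric(),
             region_end = numeric(), breakpoints = character(),
             stringsAsFactors = FALSE)
}

event_row <- function(sample, signature, chrom, start, end, breakpoints) {
  data.frame(sample = sample, signature = signature, chrom = chrom,
             region_start = unname(start), region_end = unname(end),
             breakpoints = paste(unname(breakpoints), collapse = ";"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count telomeric allelic imbalances (NtAI)
#'
#' NtAI counts subtelomeric regions of allelic imbalance that extend to the
#' telomere, do not span the centromere, and deviate from the chromosome's
#' [major_copy_state()]. Operationally, for each autosome and each
#' chromosome end, the terminal covered segment is counted iff it
#' (a) forms the outermost covered coordinate of the chromosome on that
#' side (array coverage rarely reaches the physical telomere, so the
#' terminal covered segment stands in for it), (b) lies fully within one
#' arm (segments overlapping the centromere interval are disqualified, so a
#' whole-chromosome aberration is never counted), (c) is allelically
#' imbalanced (\code{n_major != n_minor}), and (d) differs from the major
#' copy state of the chromosome.
#'
#' @inheritParams major_copy_state
#' @param annotation a [genome_annotation] covering the profile.
#' @param config a [scar_config()].
#' @return \code{list(count =, events =)} where \code{events} is a data
#'   frame of per-event records (one row per counted telomeric region; the
#'   \code{breakpoints} column holds the interior boundary when it is an
#'   internal segmentation boundary).
#' @export
count_ntai <- function(profile, annotation, config = scar_config()) {
  segs <- chrom_seg_list(profile)
  events <- list()
  for (chrom in scored_chroms(profile, config)) {
    a <- ann_row(annotation, chrom)
    m <- segs[[chrom]]
    ms <- major_state_mat(m)
    if (is.null(ms)) next
    n <- nrow(m)
    taken <- integer(0)  # guard against counting a lone segment twice
    for (side in c("p", "q")) {
      i <- if (side == "p") 1L else n
      if (i %in% taken) next
      st <- m[i, 1L]; en <- m[i, 2L]
      nmaj <- m[i, 3L]; nmin <- m[i, 4L]
      in_arm <- if (side == "p") en <= a$cen_start else st >= a$cen_end
      if (!in_arm) next
      if (nmaj == nmin) next
      if (nmaj == ms[1L] && nmin == ms[2L]) next
      if ((en - st) < config$min_tai) next
      inner <- if (side == "p") en else st
      abuts <- if (side == "p") (n > 1L && m[2L, 1L] == en)
               else (n > 1L && m[n - 1L, 2L] == st)
      in_cen <- inner >= a$cen_start && inner <= a$cen_end
      bp <- if (abuts && !in_cen) inner else numeric(0)
      events[[length(events) + 1L]] <-
        event_row(profile$sample_id, "NTAI", chrom, st, en, bp)
      taken <- c(taken, i)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  list(count = nrow(ev), events = ev)
}

#' Arm-level smoothing for LST counting
#'
#' Splits a profile's segments at the centromere into p- and q-arm pieces
#' (the part inside the centromere interval is dropped), then iteratively
#' removes segments strictly shorter than \code{min_keep} (default 3 Mb),
#' joining the flanking segments when they carry an identical
#' allele-specific state and the resulting gap is below \code{min_keep}.
#' Shortest segments are removed first (leftmost on ties) until a fixed
#' point is reached.
#'
#' @inheritParams count_ntai
#' @return Named list (\code{"<chrom>_p"}, \code{"<chrom>_q"}) of segment
#'   matrices with columns \code{start}, \code{end}, \code{n_major},
#'   \code{n_minor}.
#' @export
smooth_for_lst <- function(profile, annotation, config = scar_config()) {
  segs <- chrom_seg_list(profile)
  out <- list()
  for (chrom in scored_chroms(profile, config)) {
    a <- ann_row(annotation, chrom)
    m <- segs[[chrom]]
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 0 else a$cen_end
      hi <- if (arm == "p") a$cen_start else a$length
      am <- m
      am[, 1L] <- pmax(am[, 1L], lo)
      am[, 2L] <- pmin(am[, 2L], hi)
      am <- am[am[, 1L] < am[, 2L], , drop = FALSE]
      out[[paste(chrom, arm, sep = "_")]] <-
        smooth_arm(am, config$min_keep)
    }
  }
  out
}

# iterative small-segment removal on one arm's segment matrix
smooth_arm <- function(m, min_keep) {
  repeat {
    if (nrow(m) == 0L) break
    len <- m[, 2L] - m[, 1L]
    short <- which(len < min_keep)
    if (!length(short)) break
    j <- short[which.min(len[short])]
    m <- m[-j, , drop = FALSE]
    # try joining the new neighbours around the removed segment
    if (j > 1L && j <= nrow(m)) {
      l <- j - 1L; r <- j
      if (m[l, 3L] == m[r, 3L] && m[l, 4L] == m[r, 4L] &&
          (m[r, 1L] - m[l, 2L]) < min_keep) {
        m[l, 2L] <- m[r, 2L]
        m <- m[-r, , drop = FALSE]
      }
    }
  }
  m
}

#' Count large-scale state transitions (LST)
#'
#' An LST is a chromosomal break between adjacent regions of at least
#' \code{min_flank} (default 10 Mb) after arm-level smoothing
#' ([smooth_for_lst()]). Per arm, each boundary between consecutive
#' segments with differing allele-specific states is counted when both
#' flanking segments are at least \code{min_flank} long and the genomic
#' distance between them (nonzero only where a sub-\code{min_keep} stretch
#' was removed or uncovered) is less than \code{max_gap}.
#'
#' @inheritParams count_ntai
#' @return \code{list(count =, events =)}; each event carries exactly one
#'   breakpoint (the counted boundary).
#' @export
count_lst <- function(profile, annotation, config = scar_config()) {
  arms <- smooth_for_lst(profile, annotation, config)
  events <- list()
  for (key in names(arms)) {
    m <- arms[[key]]
    n <- nrow(m)
    if (n < 2L) next
    chrom <- sub("_[pq]$", "", key)
    for (i in seq_len(n - 1L)) {
      same <- m[i, 3L] == m[i + 1L, 3L] && m[i, 4L] == m[i + 1L, 4L]
      if (same) next
      if ((m[i, 2L] - m[i, 1L]) < config$min_flank) next
      if ((m[i + 1L, 2L] - m[i + 1L, 1L]) < config$min_flank) next
      if ((m[i + 1L, 1L] - m[i, 2L]) >= config$max_gap) next
      events[[length(events) + 1L]] <-
        event_row(profile$sample_id, "LST", chrom, m[i, 1L], m[i + 1L, 2L],
                  m[i, 2L])
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  list(count = nrow(ev), events = ev)
}

#' Count HRD-LOH regions
#'
#' HRD-LOH counts regions of loss of heterozygosity longer than
#' \code{min_loh} (strictly; default 15 Mb) but shorter than the whole
#' chromosome. Contiguous runs of abutting segments with \code{n_minor ==
#' 0} and \code{n_major >= 1} are merged into LOH regions regardless of
#' copy-state changes within the run; homozygous deletions \code{(0,0)}
#' neither extend a run nor fuse two runs. A run spanning the entire
#' covered extent of its chromosome is not counted. No chromosome is
#' excluded by default: chromosome 17 is retained because its loss is not
#' ubiquitous across cancer types (pass \code{exclude_chroms} to restore
#' the original exclusion).
#'
#' @inheritParams count_ntai
#' @return \code{list(count =, events =)}.
#' @export
count_hrd_loh <- function(profile, annotation, config = scar_config()) {
  segs <- chrom_seg_list(profile)
  events <- list()
  skip <- config$exclude_chroms
  for (chrom in setdiff(scored_chroms(profile, config), skip)) {
    ann_row(annotation, chrom)
    m <- segs[[chrom]]
    n <- nrow(m)
    is_loh <- m[, 4L] == 0 & m[, 3L] >= 1
    if (!any(is_loh)) next
    # run id increments at non-LOH rows and at non-abutting joins
    brk <- c(TRUE, !(is_loh[-1L] & is_loh[-n] & m[-1L, 1L] == m[-n, 2L]))
    run <- cumsum(brk)
    cov_min <- m[1L, 1L]; cov_max <- m[n, 2L]
    for (r in unique(run[is_loh])) {
      idx <- which(run == r & is_loh)
      if (!length(idx)) next
      st <- m[idx[1L], 1L]; en <- m[idx[length(idx)], 2L]
      if ((en - st) <= config$min_loh) next
      if (st == cov_min && en == cov_max) next  # whole covered chromosome
      bp <- numeric(0)
      i0 <- idx[1L]; i1 <- idx[length(idx)]
      if (i0 > 1L && m[i0 - 1L, 2L] == st) bp <- c(bp, st)
      if (i1 < n && m[i1 + 1L, 1L] == en) bp <- c(bp, en)
      events[[length(events) + 1L]] <-
        event_row(profile$sample_id, "HRD_LOH", chrom, st, en, bp)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  list(count = nrow(ev), events = ev)
}

#' Score one sample with all three scar signatures
#'
#' Canonicalizes the profile ([merge_adjacent_equal()]) and runs the NtAI,
#' LST, and HRD-LOH counters.
#'
#' @inheritParams count_ntai
#' @return \code{list(scores =, events =)}: \code{scores} is a one-row data
#'   frame with columns \code{sample}, \code{ntai}, \code{lst},
#'   \code{hrd_loh}; \code{events} collects every counted aberration with
#'   its breakpoints (semicolon-joined bp positions).
#' @examples
#' ann <- genome_annotation("chr1", 100e6, 45e6, 55e6)
#' p <- segment_profile("s1", data.frame(
#'   chrom = "chr1", start = c(0, 60e6), end = c(60e6, 100e6),
#'   n_major = c(1, 2), n_minor = c(1, 1)))
#' score_sample(p, ann)$scores
#' @export
score_sample <- function(profile, annotation, config = scar_config()) {
  profile <- merge_adjacent_equal(profile)
  validate_profile(profile, annotation)
  tai <- count_ntai(profile, annotation, config)
  lst <- count_lst(profile, annotation, config)
  loh <- count_hrd_loh(profile, annotation, config)
  list(scores = data.frame(sample = profile$sample_id,
                           ntai = tai$count, lst = lst$count,
                           hrd_loh = loh$count, stringsAsFactors = FALSE),
       events = rbind(tai$events, lst$events, loh$events))
}

#' Score a list of profiles
#'
#' @param profiles list of [segment_profile] objects.
#' @inheritParams count_ntai
#' @param mutations optional mutation table (see [read_mutations()]) used
#'   for the per-sample Nmut column.
#' @param metrics if \code{TRUE}, append instability metrics (wGII, FLOH,
#'   Nmut, DNA index, ploidy class) to the score table.
#' @return \code{list(scores =, events =)} with one score row per sample.
#' @export
score_cohort <- function(profiles, annotation, config = scar_config(),
                         mutations = NULL, metrics = TRUE) {
  res <- lapply(profiles, score_sample, annotation = annotation,
                config = config)
  scores <- do.call(rbind, lapply(res, `[[`, "scores"))
  events <- do.call(rbind, lapply(res, `[[`, "events"))
  rownames(scores) <- NULL
  scores$ploidy <- vapply(profiles, `[[`, numeric(1), "ploidy")
  scores$acf <- vapply(profiles, `[[`, numeric(1), "acf")
  if (metrics) {
    met <- do.call(rbind, lapply(profiles, instability_metrics,
                                 annotation = annotation,
                                 mutations = mutations, config = config))
    scores <- cbind(scores, met[, setdiff(names(met), "sample"),
                                drop = FALSE])
    rownames(scores) <- NULL
  }
  list(scores = scores, events = events)
}
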