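# Shared fixtures: toy annotations and random profile generators.

toy_ann <- function() {
  genome_annotation(c("chr1", "chr2"), c(100e6, 80e6),
                    c(45e6, 35e6), c(55e6, 45e6))
}

seg_df <- function(chrom, start, end, n_major, n_minor) {
  data.frame(chrom = chrom, start = start, end = end,
             n_major = n_major, n_minor = n_minor,
             stringsAsFactors = FALSE)
}

# Random small genome + random valid segment profile on it. States span
# 0..3 copies with gaps, so every counting clause gets exercised.
random_case <- function(seed, max_chroms = 5L, max_segs = 20L) {
  set.seed(seed)
  n_chr <- sample.int(max_chroms, 1L)
  len <- round(runif(n_chr, 60e6, 150e6))
  cs <- round(len * runif(n_chr, 0.3, 0.45))
  ce <- cs + round(len * runif(n_chr, 0.05, 0.1))
  ann <- genome_annotation(paste0("chr", seq_len(n_chr)), len, cs, ce)
  segs <- list()
  budget <- max_segs
  for (i in seq_len(n_chr)) {
    k <- sample.int(max(1L, min(6L, budget)), 1L)
    budget <- budget - k
    cuts <- sort(sample(seq(1e6, len[i] - 1e6, by = 1e6), k - 1L))
    bounds <- c(0, cuts, len[i])
    nmaj <- sample(0:3, k, replace = TRUE)
    nmin <- vapply(nmaj, function(m) sample(0:m, 1L), integer(1))
    keep <- runif(k) > 0.15  # random uncovered gaps
    if (!any(keep)) keep[1L] <- TRUE
    segs[[i]] <- seg_df(paste0("chr", i), bounds[-(k + 1L)][keep],
                        bounds[-1L][keep], nmaj[keep], nmin[keep])
    if (budget <= 0) break
  }
  prof <- segment_profile(paste0("rnd", seed), do.call(rbind, segs),
                          ploidy = sample(c(2, 2.7, 3.8), 1L), acf = 0.9,
                          annotation = ann)
  list(profile = prof, annotation = ann)
}

# Random segmentation of a fully balanced diploid genome: (1,1) everywhere,
# random boundaries and random gaps.
random_balanced_profile <- function(seed, ann = hg_autosomes()) {
  set.seed(seed)
  segs <- list()
  for (i in seq_len(nrow(ann))) {
    len <- ann$length[i]
    k <- sample(1:5, 1L)
    cuts <- sort(sample(seq(1e6, len - 1e6, by = 1e6), k - 1L))
    bounds <- c(0, cuts, len)
    keep <- runif(k) > 0.1
    if (!any(keep)) keep[1L] <- TRUE
    segs[[i]] <- seg_df(ann$chrom[i], bounds[-(k + 1L)][keep],
                        bounds[-1L][keep], 1, 1)
  }
  segment_profile(paste0("bal", seed), do.call(rbind, segs),
                  ploidy = 2, acf = 0.95, annotation = ann)
}

# Split random segments into abutting equal-state pieces; scores must be
# invariant to this refinement.
refine_profile <- function(profile, seed) {
  set.seed(seed)
  s <- profile$segments
  out <- list()
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    if (row$end - row$start > 2e6 && runif(1) < 0.5) {
      mid <- round(runif(1, row$start + 1e6, row$end - 1e6))
      a <- row; a$end <- mid
      b <- row; b$start <- mid
      out[[length(out) + 1L]] <- rbind(a, b)
    } else {
      out[[length(out) + 1L]] <- row
    }
  }
  segment_profile(profile$sample_id, do.call(rbind, out),
                  profile$ploidy, profile$acf)
}
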