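# Brute-force reference implementations: each counting rule is tested
# clause by clause with explicit loops, independent of the package's
# optimized matrix code paths. Used for oracle-equivalence checks.

oracle_major_state <- function(segs) {
  tally <- list()
  for (i in seq_len(nrow(segs))) {
    if (segs$n_major[i] + segs$n_minor[i] == 0) next
    key <- paste(segs$n_major[i], segs$n_minor[i], sep = "/")
    tally[[key]] <- (if (is.null(tally[[key]])) 0 else tally[[key]]) +
      (segs$end[i] - segs$start[i])
  }
  if (!length(tally)) return(NULL)
  best <- NULL; best_key <- NULL
  for (key in names(tally)) {
    st <- as.numeric(strsplit(key, "/")[[1]])
    cand <- c(tally[[key]], st[1] + st[2], st[1])
    if (is.null(best) ||
        cand[1] > best[1] ||
        (cand[1] == best[1] && cand[2] < best[2]) ||
        (cand[1] == best[1] && cand[2] == best[2] && cand[3] < best[3])) {
      best <- cand; best_key <- st
    }
  }
  best_key
}

oracle_ntai <- function(profile, ann, min_tai = 0) {
  profile <- merge_adjacent_equal(profile)
  count <- 0
  for (chrom in unique(profile$segments$chrom)) {
    if (sub("^chr", "", chrom) %in% c("X", "Y")) next
    segs <- profile$segments[profile$segments$chrom == chrom, ]
    segs <- segs[order(segs$start), ]
    ai <- ann[ann$chrom == chrom, ]
    ms <- oracle_major_state(segs)
    if (is.null(ms)) next
    counted <- c()
    for (side in c("p", "q")) {
      i <- if (side == "p") 1 else nrow(segs)
      if (i %in% counted) next
      seg <- segs[i, ]
      # clause (b): fully within one arm
      if (side == "p" && !(seg$end <= ai$cen_start)) next
      if (side == "q" && !(seg$start >= ai$cen_end)) next
      # clause (c): allelic imbalance
      if (seg$n_major == seg$n_minor) next
      # clause (d): deviates from major copy state
      if (seg$n_major == ms[1] && seg$n_minor == ms[2]) next
      if (seg$end - seg$start < min_tai) next
      count <- count + 1
      counted <- c(counted, i)
    }
  }
  count
}

oracle_lst <- function(profile, ann, min_flank = 10e6, max_gap = 3e6,
                       min_keep = 3e6) {
  profile <- merge_adjacent_equal(profile)
  count <- 0
  for (chrom in unique(profile$segments$chrom)) {
    if (sub("^chr", "", chrom) %in% c("X", "Y")) next
    segs <- profile$segments[profile$segments$chrom == chrom, ]
    segs <- segs[order(segs$start), ]
    ai <- ann[ann$chrom == chrom, ]
    for (arm in c("p", "q")) {
      lo <- if (arm == "p") 0 else ai$cen_end
      hi <- if (arm == "p") ai$cen_start else ai$length
      rows <- list()
      for (i in seq_len(nrow(segs))) {
        s <- max(segs$start[i], lo); e <- min(segs$end[i], hi)
        if (s < e) rows[[length(rows) + 1]] <-
            c(s, e, segs$n_major[i], segs$n_minor[i])
      }
      if (!length(rows)) next
      m <- do.call(rbind, rows)
      # smoothing: repeatedly drop the shortest sub-threshold segment,
      # joining equal-state flanks separated by less than min_keep
      repeat {
        lens <- m[, 2] - m[, 1]
        if (all(lens >= min_keep)) break
        j <- which(lens == min(lens[lens < min_keep]) & lens < min_keep)[1]
        m <- m[-j, , drop = FALSE]
        if (j > 1 && j <= nrow(m)) {
          if (all(m[j - 1, 3:4] == m[j, 3:4]) &&
              m[j, 1] - m[j - 1, 2] < min_keep) {
            m[j - 1, 2] <- m[j, 2]
            m <- m[-j, , drop = FALSE]
          }
        }
        if (!nrow(m)) break
      }
      if (nrow(m) < 2) next
      for (i in 1:(nrow(m) - 1)) {
        states_differ <- !(m[i, 3] == m[i + 1, 3] && m[i, 4] == m[i + 1, 4])
        left_ok <- (m[i, 2] - m[i, 1]) >= min_flank
        right_ok <- (m[i + 1, 2] - m[i + 1, 1]) >= min_flank
        gap_ok <- (m[i + 1, 1] - m[i, 2]) < max_gap
        if (states_differ && left_ok && right_ok && gap_ok)
          count <- count + 1
      }
    }
  }
  count
}

oracle_hrd_loh <- function(profile, ann, min_loh = 15e6,
                           exclude_chroms = character()) {
  profile <- merge_adjacent_equal(profile)
  count <- 0
  for (chrom in unique(profile$segments$chrom)) {
    if (sub("^chr", "", chrom) %in% c("X", "Y")) next
    if (chrom %in% exclude_chroms) next
    segs <- profile$segments[profile$segments$chrom == chrom, ]
    segs <- segs[order(segs$start), ]
    cov_min <- min(segs$start); cov_max <- max(segs$end)
    # build LOH runs by explicit scan
    runs <- list(); cur <- NULL
    for (i in seq_len(nrow(segs))) {
      loh <- segs$n_minor[i] == 0 && segs$n_major[i] >= 1
      abuts <- !is.null(cur) && segs$start[i] == cur[2]
      if (loh && abuts) {
        cur[2] <- segs$end[i]
      } else if (loh) {
        if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
        cur <- c(segs$start[i], segs$end[i])
      } else {
        if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
        cur <- NULL
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
    for (r in runs) {
      long_enough <- (r[2] - r[1]) > min_loh
      whole_chrom <- r[1] == cov_min && r[2] == cov_max
      if (long_enough && !whole_chrom) count <- count + 1
    }
  }
  count
}

oracle_scores <- function(profile, ann) {
  c(ntai = oracle_ntai(profile, ann),
    lst = oracle_lst(profile, ann),
    hrd_loh = oracle_hrd_loh(profile, ann))
}

# Membership-pattern tally for Venn fractions.
oracle_venn <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  tab <- c(ntai_only = 0, lst_only = 0, hrdloh_only = 0, ntai_lst = 0,
           ntai_hrdloh = 0, lst_hrdloh = 0, all_three = 0)
  for (x in u) {
    pat <- paste0(as.integer(x %in% a), as.integer(x %in% b),
                  as.integer(x %in% c_))
    key <- switch(pat, "100" = "ntai_only", "010" = "lst_only",
                  "001" = "hrdloh_only", "110" = "ntai_lst",
                  "101" = "ntai_hrdloh", "011" = "lst_hrdloh",
                  "111" = "all_three")
    tab[key] <- tab[key] + 1
  }
  100 * tab / length(u)
}
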