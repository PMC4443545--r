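#' Simulation configuration
#'
#' Describes a synthetic allele-specific segment profile with implanted,
#' counted scar events on a diploid \code{(1,1)} baseline. Events are
#' placed one per chromosome arm and sized/separated so that, outside of
#' composite mode, no implanted event satisfies another signature's rule:
#' telomeric AI and interstitial LOH implants carry a 3 Mb uncovered gap on
#' their interior side(s), emulating the probe dropout commonly seen at
#' rearrangement boundaries, which keeps their state changes below the LST
#' gap rule. Implanted counts are therefore recovered exactly by
#' [score_sample()].
#'
#' @param seed integer seed governing all randomness.
#' @param k_ntai,k_lst,k_loh number of telomeric-AI, large-scale
#'   transition, and LOH events to implant.
#' @param k_composite number of composite events: telomeric \code{(2,0)}
#'   regions > 15 Mb with an abutting >= 10 Mb balanced flank, which are
#'   counted by all three signatures at a shared breakpoint.
#' @param annotation a [genome_annotation] (default [hg_autosomes()]).
#' @param ploidy,acf sample metadata for the generated profile.
#' @param tai_size,lst_size,loh_size,comp_size bp size ranges
#'   \code{c(min, max)} for each event class.
#' @param gap uncovered spacing, bp, inserted on the interior side(s) of
#'   telomeric-AI and LOH implants (must be >= the LST \code{max_gap} for
#'   the separation guarantee; default 3 Mb).
#' @param max_tries placement attempts before giving up with an error.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, k_ntai = 0L, k_lst = 0L, k_loh = 0L,
                       k_composite = 0L, annotation = hg_autosomes(),
                       ploidy = 2, acf = 0.8,
                       tai_size = c(5e6, 30e6), lst_size = c(10e6, 30e6),
                       loh_size = c(16e6, 40e6), comp_size = c(16e6, 30e6),
                       gap = 3e6, max_tries = 20L) {
  stopifnot(k_ntai >= 0, k_lst >= 0, k_loh >= 0, k_composite >= 0,
            gap > 0, max_tries >= 1)
  structure(list(seed = as.integer(seed), k_ntai = as.integer(k_ntai),
                 k_lst = as.integer(k_lst), k_loh = as.integer(k_loh),
                 k_composite = as.integer(k_composite),
                 annotation = annotation, ploidy = ploidy, acf = acf,
                 tai_size = tai_size, lst_size = lst_size,
                 loh_size = loh_size, comp_size = comp_size,
                 gap = gap, max_tries = as.integer(max_tries)),
            class = "sim_config")
}

# minimum arm length an event class needs (size_min + spacing margins)
.arm_need <- function(type, config) {
  g <- config$gap
  switch(type,
         tai = config$tai_size[1L] + g + 5e6,
         lst = config$lst_size[1L] + 10e6,
         loh = config$loh_size[1L] + 2 * g + 4e6,
         comp = config$comp_size[1L] + 10e6)
}

# largest event size an arm of length L can host for a class
.arm_cap <- function(type, L, config) {
  g <- config$gap
  switch(type,
         tai = min(config$tai_size[2L], L - g - 5e6),
         lst = min(config$lst_size[2L], L - 10e6),
         loh = min(config$loh_size[2L], L - 2 * g - 4e6),
         comp = min(config$comp_size[2L], L - 10e6))
}

#' Simulate one segment profile with implanted scar events
#'
#' Deterministic for a fixed seed. Each event occupies its own chromosome
#' arm; a per-chromosome budget keeps the diploid baseline the major copy
#' state of every chromosome. Configurations that cannot be placed raise an
#' explicit generation error rather than silently truncating.
#'
#' @param config a [sim_config()].
#' @param sample_id label for the generated profile.
#' @return \code{list(profile =, truth =)}: the [segment_profile] and a
#'   truth table with one row per implanted event plus attributes
#'   \code{expected} (named vector of expected NtAI/LST/HRD-LOH scores).
#' @export
simulate_profile <- function(config, sample_id = "sim") {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  ann <- config$annotation
  auto <- ann[!is_sex_chrom(ann$chrom), , drop = FALSE]
  arms <- chrom_arms(auto)
  arms$len <- arms$end - arms$start
  types <- c(rep("comp", config$k_composite), rep("loh", config$k_loh),
             rep("lst", config$k_lst), rep("tai", config$k_ntai))
  # per-chromosome budget on implanted length (events + their uncovered
  # gaps): keeps the (1,1) baseline the major copy state of every
  # chromosome, since baseline coverage >= 0.6 L > 0.4 L >= any one state
  budget <- structure(0.4 * auto$length, names = auto$chrom)
  used <- numeric(length(auto$chrom)); names(used) <- auto$chrom

  placed <- NULL
  for (attempt in seq_len(config$max_tries)) {
    free <- rep(TRUE, nrow(arms))
    used[] <- 0
    events <- vector("list", length(types))
    ok <- TRUE
    for (e in seq_along(types)) {
      type <- types[e]
      cap <- vapply(seq_len(nrow(arms)), function(i)
        .arm_cap(type, arms$len[i], config), numeric(1))
      cand <- which(free & cap >= switch(type,
                                         tai = config$tai_size[1L],
                                         lst = config$lst_size[1L],
                                         loh = config$loh_size[1L],
                                         comp = config$comp_size[1L]) &
                      pmin(cap, budget[arms$chrom] - used[arms$chrom]) >=
                      switch(type, tai = config$tai_size[1L],
                             lst = config$lst_size[1L],
                             loh = config$loh_size[1L],
                             comp = config$comp_size[1L]))
      if (!length(cand)) { ok <- FALSE; break }
      i <- if (length(cand) == 1L) cand else sample(cand, 1L)
      smax <- min(cap[i], budget[arms$chrom[i]] - used[arms$chrom[i]])
      smin <- switch(type, tai = config$tai_size[1L],
                     lst = config$lst_size[1L],
                     loh = config$loh_size[1L], comp = config$comp_size[1L])
      size <- round(stats::runif(1L, smin, smax))
      events[[e]] <- list(type = type, chrom = arms$chrom[i],
                          arm = arms$arm[i], arm_start = arms$start[i],
                          arm_end = arms$end[i], size = size)
      free[i] <- FALSE
      used[arms$chrom[i]] <- used[arms$chrom[i]] + size + 2 * config$gap
    }
    if (ok) { placed <- events; break }
  }
  if (is.null(placed))
    stop("cannot place ", length(types), " events on this annotation: ",
         "no free chromosome arm satisfies the size/separation constraints")

  chrom_len <- structure(auto$length, names = auto$chrom)
  # painted intervals per chromosome: state rows and uncovered gaps
  paint <- list()
  truth <- list()
  g <- config$gap
  for (ev in placed) {
    L <- chrom_len[ev$chrom]
    at_p <- ev$arm == "p"
    if (ev$type == "tai") {
      reg <- if (at_p) c(0, ev$size) else c(L - ev$size, L)
      state <- c(2, 1)
      gp <- if (at_p) c(reg[2L], reg[2L] + g) else c(reg[1L] - g, reg[1L])
      paint[[length(paint) + 1L]] <- list(chrom = ev$chrom, seg = reg,
                                          state = state, gaps = list(gp))
      sig <- "NTAI"
    } else if (ev$type == "lst") {
      reg <- if (at_p) c(0, ev$size) else c(L - ev$size, L)
      state <- c(2, 2)
      paint[[length(paint) + 1L]] <- list(chrom = ev$chrom, seg = reg,
                                          state = state, gaps = list())
      sig <- "LST"
    } else if (ev$type == "loh") {
      lo <- ev$arm_start + g + 2e6
      hi <- ev$arm_end - ev$size - g - 2e6
      a0 <- round(stats::runif(1L, lo, hi))
      reg <- c(a0, a0 + ev$size)
      state <- c(1, 0)
      paint[[length(paint) + 1L]] <- list(
        chrom = ev$chrom, seg = reg, state = state,
        gaps = list(c(reg[1L] - g, reg[1L]), c(reg[2L], reg[2L] + g)))
      sig <- "HRD_LOH"
    } else {  # composite: counted by all three signatures
      reg <- if (at_p) c(0, ev$size) else c(L - ev$size, L)
      state <- c(2, 0)
      paint[[length(paint) + 1L]] <- list(chrom = ev$chrom, seg = reg,
                                          state = state, gaps = list())
      sig <- "COMPOSITE"
    }
    truth[[length(truth) + 1L]] <-
      data.frame(sample = sample_id, signature = sig, chrom = ev$chrom,
                 start = reg[1L], end = reg[2L], n_major = state[1L],
                 n_minor = state[2L], stringsAsFactors = FALSE)
  }

  # assemble per-chromosome segments: baseline filled around the implants
  segs <- list()
  for (chrom in auto$chrom) {
    L <- chrom_len[chrom]
    mine <- Filter(function(p) p$chrom == chrom, paint)
    blocks <- list()  # covered state blocks + uncovered gaps
    for (p in mine) {
      blocks[[length(blocks) + 1L]] <-
        c(p$seg, p$state[1L], p$state[2L], 1)  # covered
      for (gp in p$gaps)
        blocks[[length(blocks) + 1L]] <- c(gp, NA, NA, 0)
    }
    if (length(blocks)) {
      bm <- do.call(rbind, blocks)
      bm <- bm[order(bm[, 1L]), , drop = FALSE]
    } else bm <- matrix(numeric(0), 0L, 5L)
    rows <- list()
    cursor <- 0
    if (nrow(bm)) for (i in seq_len(nrow(bm))) {
      if (bm[i, 1L] > cursor)
        rows[[length(rows) + 1L]] <- c(cursor, bm[i, 1L], 1, 1)
      if (bm[i, 5L] == 1)
        rows[[length(rows) + 1L]] <- c(bm[i, 1L], bm[i, 2L],
                                       bm[i, 3L], bm[i, 4L])
      cursor <- bm[i, 2L]
    }
    if (cursor < L) rows[[length(rows) + 1L]] <- c(cursor, L, 1, 1)
    sm <- do.call(rbind, rows)
    segs[[chrom]] <- data.frame(chrom = chrom, start = sm[, 1L],
                                end = sm[, 2L], n_major = sm[, 3L],
                                n_minor = sm[, 4L],
                                stringsAsFactors = FALSE)
  }
  profile <- segment_profile(sample_id, do.call(rbind, segs),
                             ploidy = config$ploidy, acf = config$acf,
                             annotation = ann)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), signature = character(),
               chrom = character(), start = numeric(), end = numeric(),
               n_major = numeric(), n_minor = numeric(),
               stringsAsFactors = FALSE)
  attr(truth_df, "expected") <-
    c(ntai = config$k_ntai + config$k_composite,
      lst = config$k_lst + config$k_composite,
      hrd_loh = config$k_loh + config$k_composite)
  list(profile = profile, truth = truth_df)
}

#' Simulate a cohort of profiles with group-specific event rates
#'
#' Per-sample event counts are drawn from Poisson distributions with
#' group-specific rates, emulating high-scar and low-scar subpopulations.
#' Reproducible for a fixed seed.
#'
#' @param groups named list; each element is a list with \code{n} (samples)
#'   and rates \code{ntai_rate}, \code{lst_rate}, \code{loh_rate}
#'   (defaults 0), plus optional \code{ploidy} and \code{acf}.
#' @param seed master seed.
#' @param annotation a [genome_annotation].
#' @return \code{list(profiles =, truth =)}: named list of profiles and a
#'   data frame with per-sample group labels, implanted counts, ploidy and
#'   ACF.
#' @export
simulate_cohort <- function(groups, seed = 1L,
                            annotation = hg_autosomes()) {
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  profiles <- list()
  truth <- list()
  for (gname in names(groups)) {
    gr <- groups[[gname]]
    n <- gr$n
    rate <- function(x) if (is.null(gr[[x]])) 0 else gr[[x]]
    ks <- cbind(stats::rpois(n, rate("ntai_rate")),
                stats::rpois(n, rate("lst_rate")),
                stats::rpois(n, rate("loh_rate")))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", gname, i)
      cfg <- sim_config(seed = seeds[i], k_ntai = ks[i, 1L],
                        k_lst = ks[i, 2L], k_loh = ks[i, 3L],
                        annotation = annotation,
                        ploidy = if (is.null(gr$ploidy)) 2 else gr$ploidy,
                        acf = if (is.null(gr$acf)) 0.8 else gr$acf)
      sim <- simulate_profile(cfg, sample_id = id)
      profiles[[id]] <- sim$profile
      truth[[id]] <- data.frame(sample = id, group = gname,
                                k_ntai = ks[i, 1L], k_lst = ks[i, 2L],
                                k_loh = ks[i, 3L],
                                ploidy = cfg$ploidy, acf = cfg$acf,
                                stringsAsFactors = FALSE)
    }
  }
  list(profiles = profiles, truth = do.call(rbind, c(truth,
                                                     make.row.names = FALSE)))
}
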