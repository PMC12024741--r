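# Synthetic degraded-read generator with per-read ground truth.
#
# The generative model emulates hair-shaft whole-genome resequencing after
# trimming and alignment: short fragments (mean length ~30-90 bp),
# endogenous (mapped) fractions ~0.10-0.93, multi-mapped fractions
# ~0.14-0.74, and terminal cytosine deamination (C->T from the molecule's
# 5' end, G->A from its 3' end) with geometrically decaying per-position
# probability d0 * decay^(i-1). Deamination is applied to the molecule
# before uniform sequencing error (lesion precedes read-out). Exogenous
# (microbial/contaminant) reads are emitted as unmapped records: the
# simulator models the aligner's verdict, not the aligner.

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Bundles and validates the generative parameters of [simulate_reads()].
#' Defaults describe a moderately preserved hair-shaft sample: mean
#' fragment length ~50 bp, terminal deamination 0.03 at position 1
#' decaying by 0.75 per position, 0.1% sequencing error, and 30% of mapped
#' reads multi-mapped.
#'
#' @param seed integer RNG seed.
#' @param ref_length reference length in bp (>= 1000).
#' @param gc reference GC fraction, in (0, 1).
#' @param n_reads total reads to emit.
#' @param endogenous_fraction probability a read is endogenous (mapped).
#' @param fragment_law list: `list(law = "lognormal", meanlog, sdlog)` or
#'   `list(law = "geometric", p)` (shifted to start at `len_min`); rounded
#'   and truncated to `[len_min, len_max]` by resampling.
#' @param len_min,len_max fragment-length truncation bounds in bp
#'   (`len_min >= 20`, `len_max <= ref_length`).
#' @param d0_5p,d0_3p deamination probability at position 1 of the 5' (C->T)
#'   and 3' (G->A) molecule ends.
#' @param decay per-position multiplicative decay of the deamination
#'   probability, in (0, 1].
#' @param seq_error per-base uniform sequencing-error rate.
#' @param multi_fraction probability a mapped read is flagged multi-mapped
#'   (MAPQ 0, XT:A:R).
#' @param map_intercept,map_slope optional linear law for the per-read
#'   mapping probability, `p = map_intercept + map_slope * length`
#'   (clamped to [0, 1]); overrides `endogenous_fraction` when both given.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, ref_length = 100000L, gc = 0.42,
                              n_reads = 10000L, endogenous_fraction = 0.5,
                              fragment_law = list(law = "lognormal",
                                                  meanlog = log(50) - 0.25^2 / 2,
                                                  sdlog = 0.25),
                              len_min = 25L, len_max = 150L,
                              d0_5p = 0.03, d0_3p = 0.03, decay = 0.75,
                              seq_error = 0.001, multi_fraction = 0.3,
                              map_intercept = NULL, map_slope = NULL) {
  cfg <- list(seed = as.integer(seed), ref_length = as.integer(ref_length),
              gc = gc, n_reads = as.integer(n_reads),
              endogenous_fraction = endogenous_fraction,
              fragment_law = fragment_law,
              len_min = as.integer(len_min), len_max = as.integer(len_max),
              d0_5p = d0_5p, d0_3p = d0_3p, decay = decay,
              seq_error = seq_error, multi_fraction = multi_fraction,
              map_intercept = map_intercept, map_slope = map_slope)
  probs <- c(endogenous_fraction, d0_5p, d0_3p, seq_error, multi_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)", call. = FALSE)
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]", call. = FALSE)
  if (cfg$len_min < 20L) stop("len_min must be >= 20", call. = FALSE)
  if (cfg$len_max > cfg$ref_length)
    stop("len_max exceeds ref_length", call. = FALSE)
  if (!fragment_law$law %in% c("lognormal", "geometric"))
    stop("unknown fragment law: ", fragment_law$law, call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a random reference sequence
#'
#' @param ref_length sequence length (>= 1000 bp).
#' @param gc target GC fraction, in (0, 1).
#' @param seed RNG seed.
#' @param name sequence name.
#' @return named character vector of length 1 (compatible with
#'   [read_reference()] output).
#' @export
simulate_reference <- function(ref_length, gc = 0.42, seed = 1L,
                               name = "chr1") {
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)", call. = FALSE)
  stopifnot(ref_length >= 1000L)
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), ref_length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    setNames(paste(bases, collapse = ""), name)
  })
}

# draw fragment lengths, rounded and truncated by resampling
draw_lengths <- function(n, cfg) {
  law <- cfg$fragment_law
  draw <- switch(law$law,
    lognormal = function(k) as.integer(round(rlnorm(k, law$meanlog,
                                                    law$sdlog))),
    geometric = function(k) cfg$len_min + stats::rgeom(k, law$p))
  len <- draw(n)
  bad <- which(len < cfg$len_min | len > cfg$len_max)
  guard <- 0L
  while (length(bad)) {
    len[bad] <- draw(length(bad))
    bad <- bad[len[bad] < cfg$len_min | len[bad] > cfg$len_max]
    guard <- guard + 1L
    if (guard > 1000L)
      stop("fragment law mass inside [len_min, len_max] is negligible",
           call. = FALSE)
  }
  len
}

# paste a big base vector back into per-read strings via one long string
collapse_reads <- function(chars, lens) {
  long <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(long, ends - lens + 1L, ends)
}

# MD strings from per-read mismatch offsets (1-based) and reference bases
build_md <- function(len, offsets, ref_bases) {
  if (!length(offsets)) return(as.character(len))
  o <- order(offsets)
  offsets <- offsets[o]; ref_bases <- ref_bases[o]
  gaps <- diff(c(0L, offsets)) - 1L
  paste0(paste0(gaps, ref_bases, collapse = ""),
         len - offsets[length(offsets)])
}

#' Simulate degraded reads over a reference
#'
#' Endogenous reads take uniform start positions and fragment-law lengths;
#' each molecule's source bases (C from the 5' end, G from the 3' end) at
#' distance i from the end are deaminated with probability
#' `d0 * decay^(i-1)`; uniform sequencing errors are then added. Records
#' are emitted mapped, with an all-M CIGAR and an MD tag reflecting every
#' reference mismatch; strand is uniform. Multi-mapped reads get MAPQ 0
#' and XT:A:R, the rest MAPQ 37 and XT:A:U. Exogenous reads are i.i.d.
#' random sequence emitted as unmapped records. A truth table carries one
#' row per read.
#'
#' @param config a [simulation_config()].
#' @param reference named character vector (e.g. from
#'   [simulate_reference()] or [read_reference()]); the first sequence is
#'   used.
#' @param emit_sam include the formatted SAM text in the return value
#'   (set `FALSE` in tight simulation loops that only need the records;
#'   `format_sam`/[write_alignments()] can regenerate it at any time).
#' @return list with `records` (a `shaftqc_alignments` data.frame),
#'   `sam` (the corresponding SAM text lines, or `NULL` when
#'   `emit_sam = FALSE`), `truth` (data.frame: `read_id`, `origin`,
#'   `true_length`, `events_5p`, `events_3p`, `multi_flag`) and `config`.
#' @export
simulate_reads <- function(config, reference, emit_sam = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  refseq <- reference[[1]]
  ref_name <- names(reference)[1]
  if (config$len_max > nchar(refseq))
    stop("len_max exceeds the reference length", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_reads
    len <- draw_lengths(n, config)
    if (!is.null(config$map_intercept) && !is.null(config$map_slope)) {
      p_map <- pmin(pmax(config$map_intercept + config$map_slope * len, 0), 1)
      endo <- runif(n) < p_map
    } else {
      endo <- runif(n) < config$endogenous_fraction
    }
    ids <- sprintf("read%07d", seq_len(n))

    seqs <- character(n)
    md <- rep(NA_character_, n)
    ev5 <- integer(n); ev3 <- integer(n)
    multi <- rep(FALSE, n)
    is_rev <- rep(FALSE, n)
    start0 <- rep(NA_integer_, n)

    ne <- sum(endo)
    if (ne > 0L) {
      el <- len[endo]
      estart <- as.integer(floor(runif(ne) * (nchar(refseq) - el + 1)))
      frag <- substring(refseq, estart + 1L, estart + el)
      rev_e <- runif(ne) < 0.5
      ref_big <- unlist(strsplit(frag, "", fixed = TRUE), use.names = FALSE)
      nb <- length(ref_big)
      ridx <- rep.int(seq_len(ne), el)
      pos_left <- sequence(el)
      pos_right <- el[ridx] - pos_left + 1L
      rev_b <- rev_e[ridx]
      # deamination in stored (reference-forward) frame: a stored C on the
      # left edge is a molecule-5' C on forward reads but a molecule-3' G
      # (complement) on reverse reads, so the d0 rates swap with strand
      dectab <- config$decay^(seq_len(config$len_max) - 1L)
      symmetric <- config$d0_5p == config$d0_3p
      u <- runif(nb)
      cidx <- which(ref_big == "C")
      gidx <- which(ref_big == "G")
      d_left_c <- if (symmetric) config$d0_5p else
        config$d0_5p + (config$d0_3p - config$d0_5p) * rev_b[cidx]
      d_right_g <- if (symmetric) config$d0_3p else
        config$d0_3p + (config$d0_5p - config$d0_3p) * rev_b[gidx]
      conv_ct <- cidx[u[cidx] < d_left_c * dectab[pos_left[cidx]]]
      conv_ga <- gidx[u[gidx] < d_right_g * dectab[pos_right[gidx]]]
      read_big <- ref_big
      read_big[conv_ct] <- "T"
      read_big[conv_ga] <- "A"
      # molecule-frame event bookkeeping
      rev_ct <- rev_b[conv_ct]; rev_ga <- rev_b[conv_ga]
      ev5[endo] <- tabulate(c(ridx[conv_ct][!rev_ct], ridx[conv_ga][rev_ga]),
                            nbins = ne)
      ev3[endo] <- tabulate(c(ridx[conv_ga][!rev_ga], ridx[conv_ct][rev_ct]),
                            nbins = ne)
      # uniform sequencing error after the lesions
      err <- integer(0)
      if (config$seq_error > 0) {
        err <- which(runif(nb) < config$seq_error)
        if (length(err)) {
          shift <- sample.int(3L, length(err), replace = TRUE)
          bmap <- c(A = 1L, C = 2L, G = 3L, T = 4L)
          read_big[err] <- c("A", "C", "G", "T")[
            ((bmap[read_big[err]] - 1L + shift) %% 4L) + 1L]
        }
      }
      # rebuild only the reads whose bases changed
      eseq <- frag
      chg_reads <- sort(unique(ridx[c(conv_ct, conv_ga, err)]))
      if (length(chg_reads)) {
        flag <- logical(ne)
        flag[chg_reads] <- TRUE
        in_chg <- flag[ridx]
        eseq[chg_reads] <- collapse_reads(read_big[in_chg],
                                          el[chg_reads])
      }
      emd <- as.character(el)
      mm <- which(read_big != ref_big)
      if (length(mm)) {
        by_read <- split(pos_left[mm], ridx[mm])
        ref_by_read <- split(ref_big[mm], ridx[mm])
        for (j in seq_along(by_read)) {
          i <- as.integer(names(by_read)[j])
          emd[i] <- build_md(el[i], by_read[[j]], ref_by_read[[j]])
        }
      }
      seqs[endo] <- eseq
      md[endo] <- emd
      multi[endo] <- runif(ne) < config$multi_fraction
      is_rev[endo] <- rev_e
      start0[endo] <- estart
    }

    nx <- n - ne
    if (nx > 0L) {
      xl <- len[!endo]
      xbig <- sample(c("A", "C", "G", "T"), sum(xl), replace = TRUE,
                     prob = c((1 - config$gc) / 2, config$gc / 2,
                              config$gc / 2, (1 - config$gc) / 2))
      seqs[!endo] <- collapse_reads(xbig, xl)
    }

    records <- data.frame(
      read_id = ids,
      sequence = seqs,
      length = len,
      is_mapped = endo,
      is_reverse = is_rev,
      mapq = ifelse(endo, ifelse(multi, 0L, 37L), 0L),
      cigar = ifelse(endo, paste0(len, "M"), ""),
      md = md,
      is_primary = TRUE,
      is_duplicate = FALSE,
      ref_name = ifelse(endo, ref_name, NA_character_),
      ref_start = start0,
      xt = ifelse(endo, ifelse(multi, "R", "U"), NA_character_),
      stringsAsFactors = FALSE
    )
    ref_lengths <- setNames(nchar(refseq), ref_name)
    records <- structure(records, ref_lengths = ref_lengths,
                         class = c("shaftqc_alignments", "data.frame"))
    truth <- data.frame(
      read_id = ids,
      origin = ifelse(endo, "endogenous", "exogenous"),
      true_length = len,
      events_5p = ev5,
      events_3p = ev3,
      multi_flag = multi,
      stringsAsFactors = FALSE
    )
    list(records = records,
         sam = if (emit_sam) format_sam(records, ref_lengths),
         truth = truth, config = config)
  })
}

# per-scenario generative parameters; group means/SDs follow the observed
# hair regimes (lightly medullated R_m ~0.83 +/- 0.073, highly ~0.44 +/-
# 0.224, tanning levels ~0.57/0.50/0.10, R_dm ~0.036 hair CV 0.29 vs skin
# CV 0.49)
study_scenarios <- function() {
  list(
    hair_type_contrast = list(
      groups = data.frame(
        group = c("light", "high"), n = c(8L, 8L),
        endo_mean = c(0.8313, 0.4405), endo_sd = c(0.0734, 0.2235),
        mean_len = c(50.3, 43.1), sdlog = c(0.25, 0.165),
        d0 = c(0.03, 0.03)),
      variable = "hair_type", paired = FALSE,
      comparisons = c("r_m", "r_m0", "a_l")),
    tanning_gradient = list(
      groups = data.frame(
        group = c("none", "slight", "deep"), n = c(5L, 5L, 5L),
        endo_mean = c(0.5700, 0.4990, 0.0994),
        endo_sd = c(0.2676, 0.0694, 0.0629),
        mean_len = c(55, 48, 40), sdlog = c(0.2, 0.2, 0.2),
        d0 = c(0.03, 0.03, 0.03)),
      variable = "tanning", paired = FALSE,
      comparisons = c("r_m", "a_l")),
    paired_hair_skin = list(
      groups = data.frame(
        group = c("hair", "skin"), n = c(8L, 8L),
        endo_mean = c(0.83, 0.64), endo_sd = c(0.07, 0.23),
        mean_len = c(50, 60), sdlog = c(0.25, 0.25),
        d0 = c(0.036, 0.040), d0_cv = c(0.294, 0.494)),
      variable = "tissue", paired = TRUE,
      comparisons = c("n_db", "r_dm"))
  )
}

#' Generate a complete study fixture
#'
#' Writes a shared synthetic reference, one SAM file per sample, a truth
#' TSV and a study-config JSON for one of three study designs:
#' `hair_type_contrast` (two hair types with distinct endogenous
#' fractions), `tanning_gradient` (three tanning levels with declining
#' endogenous fraction and mean read length) or `paired_hair_skin`
#' (matched pairs differing in damage-rate dispersion). Byte-identical
#' given the same seed.
#'
#' @param scenario one of `"hair_type_contrast"`, `"tanning_gradient"`,
#'   `"paired_hair_skin"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param n_reads reads per sample (default 3000, desk scale).
#' @param ref_length shared reference length in bp.
#' @return list with `config_path`, `config` (the parsed study config),
#'   `truth` (row-bound per-read truth with a `sample_id` column) and
#'   `sample_params` (per-sample generative parameters).
#' @export
make_study_fixture <- function(scenario = c("hair_type_contrast",
                                            "tanning_gradient",
                                            "paired_hair_skin"),
                               seed = 1L, dir = tempfile("fixture"),
                               n_reads = 3000L, ref_length = 60000L) {
  scenario <- match.arg(scenario)
  sc <- study_scenarios()[[scenario]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  reference <- simulate_reference(ref_length, gc = 0.42,
                                  seed = seed %% 100000L + 7L)
  ref_path <- file.path(dir, "reference.fa")
  write_reference(reference, ref_path)

  g <- sc$groups
  n_samples <- sum(g$n)
  with_seed(seed, {
    sample_seeds <- sample.int(2^31 - 2L, n_samples)
    rows <- list(); truths <- list(); k <- 0L
    for (gi in seq_len(nrow(g))) {
      for (si in seq_len(g$n[gi])) {
        k <- k + 1L
        endo <- min(max(rnorm(1, g$endo_mean[gi], g$endo_sd[gi]), 0.02), 0.98)
        d0 <- g$d0[gi]
        if (!is.null(g$d0_cv)) {
          sdl <- sqrt(log(1 + g$d0_cv[gi]^2))
          d0 <- min(rlnorm(1, log(g$d0[gi]) - sdl^2 / 2, sdl), 0.5)
        }
        sample_id <- sprintf("%s_%02d", g$group[gi], si)
        rows[[k]] <- data.frame(
          sample_id = sample_id, group = g$group[gi],
          pair_id = if (sc$paired) sprintf("pair_%02d", si) else NA_character_,
          endogenous_fraction = endo, d0 = d0,
          mean_len = g$mean_len[gi], sdlog = g$sdlog[gi],
          seed = sample_seeds[k], stringsAsFactors = FALSE)
      }
    }
    params <- do.call(rbind, rows)

    samples <- list()
    for (k in seq_len(nrow(params))) {
      p <- params[k, ]
      cfg <- simulation_config(
        seed = p$seed, ref_length = ref_length, n_reads = n_reads,
        endogenous_fraction = p$endogenous_fraction,
        fragment_law = list(law = "lognormal",
                            meanlog = log(p$mean_len) - p$sdlog^2 / 2,
                            sdlog = p$sdlog),
        len_min = 25L, len_max = min(200L, ref_length),
        d0_5p = p$d0, d0_3p = p$d0, decay = 0.75,
        seq_error = 0.001, multi_fraction = 0.3)
      sim <- simulate_reads(cfg, reference)
      sam_path <- file.path(dir, paste0(p$sample_id, ".sam"))
      writeLines(sim$sam, sam_path)
      tr <- sim$truth
      tr$sample_id <- p$sample_id
      truths[[k]] <- tr
      entry <- list(
        sample_id = p$sample_id,
        path = paste0(p$sample_id, ".sam"),
        group = setNames(list(p$group), sc$variable))
      if (sc$paired) entry$pair_id <- p$pair_id
      samples[[k]] <- entry
    }
    truth <- do.call(rbind, truths)
    write_report(truth, file.path(dir, "truth.tsv"))

    comparisons <- lapply(sc$comparisons, function(metric) list(
      label = paste0(sc$variable, "_", metric),
      variable = sc$variable, metric = metric, paired = sc$paired))
    config <- list(
      schema = "shaftqc-study/1",
      options = list(seed = as.integer(seed), damage_window = 25L,
                     multi_def = "mapq0", a_l_scope = "all",
                     bin_step = 10L, min_reads = 100L, alpha = 0.05,
                     count_duplicates = TRUE, min_mapq = 0L),
      reference = "reference.fa",
      samples = samples,
      comparisons = comparisons)
    config_path <- file.path(dir, "study_config.json")
    jsonlite::write_json(config, config_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(config_path = config_path, config = config, truth = truth,
         sample_params = params, dir = dir)
  })
}
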