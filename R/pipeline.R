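# Study orchestration: per-sample metrics, size bins and trend fits,
# damage profiles and summaries at both ends, configured group
# comparisons, and a JSON manifest with per-file checksums. All internal
# math is on fractions; rendering to percent happens only in report text.

STUDY_SCHEMA <- "shaftqc-study/1"

default_study_options <- function() {
  list(seed = 1L, damage_window = 25L, multi_def = "mapq0",
       a_l_scope = "all", bin_step = 10L, min_reads = 100L, alpha = 0.05,
       count_duplicates = TRUE, min_mapq = 0L)
}

#' Read a study configuration
#'
#' The study config is a JSON document (`schema: "shaftqc-study/1"`) with
#' `options` (damage window, multi-mapping definition, A_L scope, bin
#' step, min reads per bin, alpha, seed, ...), an optional `reference`
#' FASTA path, a `samples` array (`sample_id`, `path`, `group` labels,
#' optional `pair_id`) and a `comparisons` array (`label`, grouping
#' `variable`, `metric`, `paired`). Relative paths resolve against the
#' config file's directory.
#'
#' @param path path to the JSON config.
#' @return list of class `study_config` with normalised options, a
#'   `samples` data.frame and a `comparisons` data.frame.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$schema, STUDY_SCHEMA))
    stop("unsupported study config schema: ",
         if (is.null(raw$schema)) "<missing>" else raw$schema, call. = FALSE)
  base_dir <- dirname(normalizePath(path, mustWork = TRUE))

  opts <- utils::modifyList(default_study_options(),
                            if (is.null(raw$options)) list() else raw$options)

  samples <- do.call(rbind, lapply(raw$samples, function(s) {
    grp <- if (is.null(s$group)) list() else s$group
    row <- data.frame(sample_id = s$sample_id, path = s$path,
                      pair_id = if (length(s$pair_id) != 1L) NA_character_
                                else as.character(s$pair_id),
                      stringsAsFactors = FALSE)
    for (v in names(grp)) row[[v]] <- as.character(grp[[v]])
    row
  }))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in study config", call. = FALSE)
  samples$path <- ifelse(grepl("^/", samples$path), samples$path,
                         file.path(base_dir, samples$path))

  comparisons <- if (length(raw$comparisons)) {
    do.call(rbind, lapply(raw$comparisons, function(cp) data.frame(
      label = cp$label, variable = cp$variable,
      metric = if (is.null(cp$metric)) "r_m" else cp$metric,
      paired = isTRUE(cp$paired), stringsAsFactors = FALSE)))
  } else {
    data.frame(label = character(), variable = character(),
               metric = character(), paired = logical())
  }

  reference <- NULL
  if (!is.null(raw$reference)) {
    rp <- if (grepl("^/", raw$reference)) raw$reference
          else file.path(base_dir, raw$reference)
    reference <- rp
  }
  structure(list(options = opts, samples = samples,
                 comparisons = comparisons, reference = reference,
                 path = path),
            class = "study_config")
}

# metric lookup for comparisons: per-sample metrics + 3' damage summaries
comparison_value <- function(metric, metrics_row, damage_row) {
  switch(metric,
    r_m = metrics_row$r_m,
    r_m0 = metrics_row$r_m0,
    a_l = metrics_row$a_l,
    n_db = damage_row$n_db,
    r_dm = damage_row$r_dm,
    window_mean = damage_row$window_mean,
    stop("unknown comparison metric: ", metric, call. = FALSE))
}

#' Run a configured study
#'
#' Computes, for every sample, the per-sample metrics, read-size bins,
#' and damage profiles/summaries at both ends (5' C->T and 3' G->A); fits
#' pooled size trends for `r_m` and `r_m0`; runs every configured group
#' comparison through the normality gate; and writes the whole bundle as
#' TSV files plus a JSON manifest with MD5 checksums. Reruns with
#' identical inputs are byte-identical.
#'
#' Comparisons whose groups have fewer than 3 samples are skipped with a
#' warning, as are trend fits with too few points; undefined `r_m0` or CV
#' values are reported as NA.
#'
#' @param config a `study_config` from [read_study_config()] (or a path to
#'   one).
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return list of class `study_report` with elements `sample_metrics`,
#'   `size_bins`, `trend_fits`, `damage_profiles`, `damage_summaries`,
#'   `dispersion`, `comparisons`, `manifest` and `out_dir`.
#' @export
run_study <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  opts <- config$options
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  missing <- !file.exists(config$samples$path)
  if (any(missing))
    stop("missing alignment file for sample ",
         config$samples$sample_id[which(missing)[1]], ": ",
         config$samples$path[which(missing)[1]], call. = FALSE)
  reference <- if (!is.null(config$reference)) read_reference(config$reference)

  metrics <- list(); bins <- list(); profiles <- list(); summaries <- list()
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[i]
    rec <- read_alignments(config$samples$path[i])
    metrics[[i]] <- compute_sample_metrics(
      rec, sample_id = sid, multi_def = opts$multi_def,
      count_duplicates = opts$count_duplicates, a_l_scope = opts$a_l_scope)
    bn <- bin_by_read_size(rec, step = opts$bin_step,
                           min_reads = opts$min_reads,
                           multi_def = opts$multi_def,
                           count_duplicates = opts$count_duplicates)
    bn <- cbind(sample_id = sid, bn)
    bins[[i]] <- bn
    if (any(rec$is_mapped & rec$is_primary)) {
      for (spec in list(c("five_prime", "C>T"), c("three_prime", "G>A"))) {
        prof <- compute_damage_profile(
          rec, end = spec[1], substitution = spec[2],
          window = opts$damage_window, reference = reference,
          min_mapq = opts$min_mapq)
        sm <- summarize_damage(prof)
        profiles[[length(profiles) + 1L]] <- cbind(
          sample_id = sid, end = spec[1], substitution = spec[2],
          as.data.frame(prof))
        summaries[[length(summaries) + 1L]] <- data.frame(
          sample_id = sid, end = spec[1], substitution = spec[2],
          n_db = sm$n_db, r_dm = sm$r_dm, window_mean = sm$window_mean,
          stringsAsFactors = FALSE)
      }
    } else {
      warning("sample ", sid, ": no mapped primary records, ",
              "damage profile skipped", call. = FALSE)
    }
  }
  sample_metrics <- do.call(rbind, metrics)
  size_bins <- do.call(rbind, bins)
  damage_profiles <- if (length(profiles)) do.call(rbind, profiles)
  damage_summaries <- if (length(summaries)) do.call(rbind, summaries)

  # pooled (sample x bin) trend fits, unweighted
  trend_rows <- list()
  for (resp in c("r_m", "r_m0")) {
    fit <- tryCatch(fit_size_trend(size_bins, response = resp),
                    error = function(e) {
                      warning("size trend for ", resp, " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(fit))
      trend_rows[[resp]] <- data.frame(
        response = resp, slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, p_value = fit$p_value,
        slope_se = fit$slope_se, n_points = fit$n_points,
        stringsAsFactors = FALSE)
  }
  trend_fits <- if (length(trend_rows)) do.call(rbind, trend_rows) else
    data.frame(response = character(), slope = numeric(),
               intercept = numeric(), r_squared = numeric(),
               p_value = numeric(), slope_se = numeric(),
               n_points = integer())
  rownames(trend_fits) <- NULL

  # across-sample dispersion of the 3' damage statistics
  disp_rows <- list()
  if (!is.null(damage_summaries)) {
    d3 <- damage_summaries[damage_summaries$end == "three_prime", ]
    if (nrow(d3) >= 2L) {
      for (stat in c("n_db", "r_dm")) {
        dsp <- dispersion(d3[[stat]])
        disp_rows[[stat]] <- data.frame(
          statistic = stat, mean = dsp$mean, sd = dsp$sd,
          cv = dsp$cv, n = nrow(d3), stringsAsFactors = FALSE)
      }
    }
  }
  dispersion_tab <- if (length(disp_rows)) do.call(rbind, disp_rows) else
    data.frame(statistic = character(), mean = numeric(), sd = numeric(),
               cv = numeric(), n = integer())
  rownames(dispersion_tab) <- NULL

  comparisons <- run_comparisons(config, sample_metrics, damage_summaries,
                                 opts)

  paths <- c(
    sample_metrics = "sample_metrics.tsv", size_bins = "size_bins.tsv",
    trend_fits = "trend_fits.tsv", damage_profiles = "damage_profiles.tsv",
    damage_summaries = "damage_summaries.tsv", dispersion = "dispersion.tsv",
    comparisons = "comparisons.tsv")
  tables <- list(
    sample_metrics = rename_metric_columns(sample_metrics),
    size_bins = size_bins,
    trend_fits = trend_fits,
    damage_profiles = if (is.null(damage_profiles))
      data.frame() else damage_profiles,
    damage_summaries = if (is.null(damage_summaries))
      data.frame() else rename_summary_columns(damage_summaries),
    dispersion = dispersion_tab,
    comparisons = comparisons)
  for (nm in names(paths))
    write_report(tables[[nm]], file.path(out_dir, paths[nm]))

  manifest <- list(
    schema = "shaftqc-report/1",
    config = basename(config$path),
    config_md5 = unname(md5sum(config$path)),
    seed = opts$seed,
    options = opts,
    n_samples = nrow(config$samples),
    files = lapply(unname(paths), function(p) list(
      path = p, md5 = unname(md5sum(file.path(out_dir, p))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(sample_metrics = sample_metrics, size_bins = size_bins,
                 trend_fits = trend_fits,
                 damage_profiles = damage_profiles,
                 damage_summaries = damage_summaries,
                 dispersion = dispersion_tab,
                 comparisons = comparisons, manifest = manifest,
                 out_dir = out_dir),
            class = "study_report")
}

# report-facing column names for the metric tables
rename_metric_columns <- function(m) {
  stats::setNames(m, c("sample_id", "n_total", "n_mapped", "n_multi",
                       "R_m", "R_m0", "A_L"))
}
rename_summary_columns <- function(s) {
  stats::setNames(s, c("sample_id", "end", "substitution", "N_db", "R_dm",
                       "window_mean"))
}

run_comparisons <- function(config, sample_metrics, damage_summaries, opts) {
  empty <- data.frame(
    label = character(), variable = character(), metric = character(),
    test_used = character(), paired = logical(), statistic = numeric(),
    p_value = numeric(), n_a = integer(), n_b = integer(),
    mean_a = numeric(), sd_a = numeric(), mean_b = numeric(),
    sd_b = numeric(), normality_p_a = numeric(), normality_p_b = numeric(),
    group_a = character(), group_b = character())
  if (!nrow(config$comparisons)) return(empty)

  d3 <- if (!is.null(damage_summaries))
    damage_summaries[damage_summaries$end == "three_prime", ]
  value_for <- function(sid, metric) {
    mrow <- sample_metrics[sample_metrics$sample_id == sid, ]
    drow <- if (!is.null(d3)) d3[d3$sample_id == sid, ] else NULL
    if (metric %in% c("n_db", "r_dm", "window_mean") &&
        (is.null(drow) || !nrow(drow))) return(NA_real_)
    as.numeric(comparison_value(metric, mrow, drow))
  }

  rows <- list()
  for (i in seq_len(nrow(config$comparisons))) {
    cp <- config$comparisons[i, ]
    if (!cp$variable %in% names(config$samples)) {
      warning("comparison ", cp$label, " skipped: unknown grouping variable ",
              cp$variable, call. = FALSE)
      next
    }
    lev <- unique(config$samples[[cp$variable]])
    lev <- lev[!is.na(lev)]
    pairs_of_levels <- if (length(lev) < 2L) list() else
      utils::combn(lev, 2L, simplify = FALSE)
    for (pl in pairs_of_levels) {
      sa <- config$samples[config$samples[[cp$variable]] == pl[1], ]
      sb <- config$samples[config$samples[[cp$variable]] == pl[2], ]
      if (cp$paired) {
        shared <- intersect(sa$pair_id, sb$pair_id)
        shared <- shared[!is.na(shared)]
        sa <- sa[match(shared, sa$pair_id), ]
        sb <- sb[match(shared, sb$pair_id), ]
      }
      a <- vapply(sa$sample_id, value_for, 0, metric = cp$metric)
      b <- vapply(sb$sample_id, value_for, 0, metric = cp$metric)
      ok_a <- a[!is.na(a)]; ok_b <- b[!is.na(b)]
      if (cp$paired) {
        keep <- !is.na(a) & !is.na(b)
        ok_a <- a[keep]; ok_b <- b[keep]
      }
      if (length(ok_a) < 3L || length(ok_b) < 3L) {
        warning("comparison ", cp$label, " (", pl[1], " vs ", pl[2],
                ") skipped: fewer than 3 samples per group", call. = FALSE)
        next
      }
      label <- if (length(pairs_of_levels) > 1L)
        sprintf("%s:%s_vs_%s", cp$label, pl[1], pl[2]) else cp$label
      gc_ <- compare_groups(ok_a, ok_b, paired = cp$paired,
                            alpha = opts$alpha, label = label)
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, variable = cp$variable, metric = cp$metric,
        test_used = gc_$test_used, paired = cp$paired,
        statistic = gc_$statistic, p_value = gc_$p_value,
        n_a = gc_$n_a, n_b = gc_$n_b,
        mean_a = gc_$mean_a, sd_a = gc_$sd_a,
        mean_b = gc_$mean_b, sd_b = gc_$sd_b,
        normality_p_a = if (cp$paired) gc_$normality_p_diff
                        else gc_$normality_p_a,
        normality_p_b = if (cp$paired) NA_real_ else gc_$normality_p_b,
        group_a = pl[1], group_b = pl[2], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
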