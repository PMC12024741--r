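# Terminal deamination damage profiling.
#
# Post-mortem cytosine deamination shows up as C->T mismatches at the 5'
# end of the original molecule and G->A at the 3' end (double-stranded
# library convention), decaying inward. Reference bases at each aligned
# column are reconstructed from the MD tag against the CIGAR, or sliced
# from a reference; reverse-strand records are reverse-complemented so all
# positions are counted in the molecule's own 5'->3' frame.
#
# Damage statistics over a terminal window:
#   rate[i]     = damage_count[i] / ref_base_count[i]
#   window_mean = mean of the defined rates over positions 1..window
#   N_db        = length of the run, starting at the terminal base, of
#                 positions with rate strictly above window_mean
#   R_dm        = maximum defined rate in the window

#' Reconstruct the per-column read/reference pairing of one record
#'
#' Expands the MD tag against the CIGAR (or slices a reference sequence) to
#' recover the reference base under every aligned (match/mismatch) column.
#' Inserted read bases contribute no reference base, deleted reference
#' bases no read base; soft-clipped bases are skipped but counted. The
#' output is oriented 5'->3' of the original molecule: both base vectors of
#' a reverse-strand record are reverse-complemented.
#'
#' @param record a single-row `shaftqc_alignments` data.frame (or a list
#'   with the same fields) for a mapped primary record.
#' @param reference optional named character vector from
#'   [read_reference()]; required when the record has no MD tag.
#' @return list of class `pairwise_alignment` with elements `read_id`,
#'   `read` and `ref` (aligned-column base vectors, molecule-oriented),
#'   `n_aligned`, `n_clipped`, `n_inserted`, `n_deleted`.
#' @export
reconstruct_pairwise <- function(record, reference = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  id <- record$read_id
  if (!isTRUE(record$is_mapped))
    stop("cannot reconstruct unmapped record ", id, call. = FALSE)
  toks <- regmatches(record$cigar,
                     gregexpr("\\d+[MIDNSHP=X]", record$cigar))[[1]]
  if (!length(toks))
    stop("empty CIGAR for mapped record ", id, call. = FALSE)
  ops <- substring(toks, nchar(toks), nchar(toks))
  lens <- as.integer(substring(toks, 1L, nchar(toks) - 1L))

  read_chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  read_pos <- 0L
  aln_read_idx <- integer(0)   # read index of each aligned column
  ref_cols <- character(0)     # "M" or "D" for each reference-consuming col
  n_clipped <- 0L; n_inserted <- 0L; n_deleted <- 0L
  for (i in seq_along(ops)) {
    op <- ops[i]; k <- lens[i]
    if (op %in% c("M", "=", "X")) {
      aln_read_idx <- c(aln_read_idx, read_pos + seq_len(k))
      ref_cols <- c(ref_cols, rep("M", k))
      read_pos <- read_pos + k
    } else if (op == "I") {
      n_inserted <- n_inserted + k; read_pos <- read_pos + k
    } else if (op == "S") {
      n_clipped <- n_clipped + k; read_pos <- read_pos + k
    } else if (op == "D") {
      ref_cols <- c(ref_cols, rep("D", k)); n_deleted <- n_deleted + k
    } else if (op == "N") {
      ref_cols <- c(ref_cols, rep("D", k))  # skipped ref, no read base
    } # H, P consume nothing we track
  }
  if (read_pos != record$length)
    stop("CIGAR query length disagrees with sequence for read ", id,
         call. = FALSE)

  aln_read <- read_chars[aln_read_idx]
  m_cols <- which(ref_cols == "M")

  if (!is.na(record$md)) {
    aln_ref <- expand_md(record$md, aln_read, ref_cols, m_cols, id)
  } else if (!is.null(reference)) {
    refseq <- reference[[record$ref_name]]
    if (is.null(refseq))
      stop("reference sequence ", record$ref_name, " not found for read ",
           id, call. = FALSE)
    span <- strsplit(substr(refseq, record$ref_start + 1L,
                            record$ref_start + length(ref_cols)),
                     "", fixed = TRUE)[[1]]
    if (length(span) != length(ref_cols))
      stop("record ", id, " extends past the reference end", call. = FALSE)
    aln_ref <- span[m_cols]
  } else {
    stop("read ", id, " has no MD tag and no reference was given",
         call. = FALSE)
  }

  read_out <- aln_read
  ref_out <- aln_ref
  if (isTRUE(record$is_reverse)) {
    read_out <- rev(complement_bases(read_out))
    ref_out <- rev(complement_bases(ref_out))
  }
  structure(list(read_id = id, read = read_out, ref = ref_out,
                 n_aligned = length(m_cols), n_clipped = n_clipped,
                 n_inserted = n_inserted, n_deleted = n_deleted),
            class = "pairwise_alignment")
}

# Expand an MD tag over the reference-consuming columns. MD covers matched
# runs (numbers), mismatch reference bases (letters) and deleted reference
# bases (^SEQ), in reference order across M and D columns.
expand_md <- function(md, aln_read, ref_cols, m_cols, id) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  aln_ref <- aln_read[match(seq_along(ref_cols), m_cols)]  # matches default
  ptr <- 1L  # next reference column
  n_ref <- length(ref_cols)
  for (tk in toks) {
    c1 <- substr(tk, 1L, 1L)
    if (c1 >= "0" && c1 <= "9") {
      ptr <- ptr + as.integer(tk)
    } else if (c1 == "^") {
      k <- nchar(tk) - 1L
      if (ptr + k - 1L > n_ref || any(ref_cols[ptr:(ptr + k - 1L)] != "D"))
        stop("MD/CIGAR inconsistency (deletion) for read ", id,
             call. = FALSE)
      ptr <- ptr + k
    } else {
      if (ptr > n_ref || ref_cols[ptr] != "M")
        stop("MD/CIGAR inconsistency (mismatch) for read ", id,
             call. = FALSE)
      aln_ref[ptr] <- toupper(tk)
      ptr <- ptr + 1L
    }
  }
  if (ptr != n_ref + 1L)
    stop("MD/CIGAR inconsistency (expanded lengths disagree) for read ", id,
         call. = FALSE)
  aln_ref[match(m_cols, seq_along(ref_cols))]
}

SUBSTITUTIONS <- list(
  "C>T" = c(source = "C", target = "T"),
  "G>A" = c(source = "G", target = "A")
)

#' Terminal damage profile over a stream of records
#'
#' For each position `i = 1..window` from the chosen end of the molecule,
#' counts aligned columns whose reference base is the substitution's source
#' base (`ref_base_count`) and, of those, how many carry the substitution's
#' target base in the read (`damage_count`); `rate = damage_count /
#' ref_base_count`. Positions are counted in the molecule's 5'->3' frame,
#' so reverse-strand records contribute after reverse-complementation.
#' Reads whose aligned length L is below `2*window` are split at the
#' midpoint — the 5' end sees positions `1..ceiling(L/2)`, the 3' end
#' `1..floor(L/2)` — so no column is counted toward both ends. Columns with
#' an N in read or reference are excluded. Only mapped, primary,
#' non-duplicate records with `mapq >= min_mapq` contribute.
#'
#' @param records a `shaftqc_alignments` data.frame.
#' @param end `"three_prime"` (default) or `"five_prime"`.
#' @param substitution `"G>A"` (default, the 3' convention), `"C>T"`, or
#'   `"any"` to count every mismatch against every non-N reference base.
#' @param window positions per end (default 25 bp).
#' @param reference optional reference for records lacking MD tags.
#' @param min_mapq minimum MAPQ (default 0: include all mapped records).
#' @return data.frame of class `damage_profile` with columns `position`,
#'   `ref_base_count`, `damage_count`, `rate` (`NA` where no source base
#'   was seen), plus attributes `end`, `substitution`, `window`, `n_reads`.
#' @export
compute_damage_profile <- function(records,
                                   end = c("three_prime", "five_prime"),
                                   substitution = c("G>A", "C>T", "any"),
                                   window = 25L, reference = NULL,
                                   min_mapq = 0L) {
  end <- match.arg(end)
  substitution <- match.arg(substitution)
  keep <- records$is_mapped & records$is_primary & !records$is_duplicate &
    records$mapq >= min_mapq
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no usable mapped records", call. = FALSE)

  ref_count <- numeric(window)
  dmg_count <- numeric(window)

  simple <- grepl("^[0-9]+M$", rec$cigar) & !is.na(rec$md)
  if (any(simple)) {
    cnt <- profile_counts_vectorized(rec[simple, , drop = FALSE], end,
                                     substitution, window)
    ref_count <- ref_count + cnt$ref
    dmg_count <- dmg_count + cnt$dmg
  }
  for (i in which(!simple)) {
    pw <- reconstruct_pairwise(rec[i, , drop = FALSE], reference)
    cnt <- profile_counts_one(pw$read, pw$ref, end, substitution, window)
    ref_count <- ref_count + cnt$ref
    dmg_count <- dmg_count + cnt$dmg
  }

  out <- data.frame(
    position = seq_len(window),
    ref_base_count = as.integer(ref_count),
    damage_count = as.integer(dmg_count),
    rate = ifelse(ref_count > 0, dmg_count / ref_count, NA_real_)
  )
  structure(out, end = end, substitution = substitution, window = window,
            n_reads = nrow(rec),
            class = c("damage_profile", "data.frame"))
}

# positions from the relevant end with the short-read midpoint split
end_position_limits <- function(L, end, window) {
  if (end == "five_prime") ifelse(L < 2L * window, ceiling(L / 2), window)
  else ifelse(L < 2L * window, floor(L / 2), window)
}

# fully vectorised counting for gapless (all-M, MD-tagged) records
profile_counts_vectorized <- function(rec, end, substitution, window) {
  lens <- rec$length
  read_big <- unlist(strsplit(rec$sequence, "", fixed = TRUE),
                     use.names = FALSE)
  ref_big <- read_big
  # apply MD mismatch letters; only records whose MD contains a letter
  has_mm <- grepl("[A-Za-z]", rec$md)
  if (any(has_mm)) {
    offs0 <- c(0L, cumsum(lens))
    toks_all <- regmatches(rec$md[has_mm],
                           gregexpr("\\d+|[A-Za-z]", rec$md[has_mm]))
    for (j in seq_along(toks_all)) {
      tk <- toks_all[[j]]
      is_num <- grepl("^[0-9]", tk)
      adv <- rep(1L, length(tk))
      adv[is_num] <- as.integer(tk[is_num])
      pos_after <- cumsum(adv)
      mm_pos <- pos_after[!is_num]            # read offsets of mismatches
      i <- which(has_mm)[j]
      ref_big[offs0[i] + mm_pos] <- toupper(tk[!is_num])
    }
  }
  read_idx <- rep.int(seq_along(lens), lens)
  pos_left <- sequence(lens)
  pos_right <- lens[read_idx] - pos_left + 1L
  rev_base <- rec$is_reverse[read_idx]
  # molecule-frame position from each end and molecule-frame bases
  pos5 <- ifelse(rev_base, pos_right, pos_left)
  pos <- if (end == "five_prime") pos5
         else ifelse(rev_base, pos_left, pos_right)
  read_m <- ifelse(rev_base, complement_bases(read_big), read_big)
  ref_m <- ifelse(rev_base, complement_bases(ref_big), ref_big)
  lim <- end_position_limits(lens, end, window)[read_idx]
  in_win <- pos <= window & pos <= lim
  if (substitution == "any") {
    den <- in_win & ref_m != "N" & read_m != "N"
    num <- den & read_m != ref_m
  } else {
    sub <- SUBSTITUTIONS[[substitution]]
    den <- in_win & ref_m == sub[["source"]] & read_m != "N"
    num <- den & read_m == sub[["target"]]
  }
  list(ref = tabulate(pos[den], nbins = window),
       dmg = tabulate(pos[num], nbins = window))
}

# counting for one reconstructed (molecule-oriented) pairing
profile_counts_one <- function(read, ref, end, substitution, window) {
  L <- length(read)
  if (!L) return(list(ref = numeric(window), dmg = numeric(window)))
  pos <- if (end == "five_prime") seq_len(L) else rev(seq_len(L))
  lim <- end_position_limits(L, end, window)
  in_win <- pos <= window & pos <= lim
  if (substitution == "any") {
    den <- in_win & ref != "N" & read != "N"
    num <- den & read != ref
  } else {
    sub <- SUBSTITUTIONS[[substitution]]
    den <- in_win & ref == sub[["source"]] & read != "N"
    num <- den & read == sub[["target"]]
  }
  list(ref = tabulate(pos[den], nbins = window),
       dmg = tabulate(pos[num], nbins = window))
}

#' Damage summary statistics of a terminal profile
#'
#' `window_mean` is the mean of the defined per-position rates over the
#' window; `n_db` is the length of the maximal run, starting at the
#' terminal base, of positions with rate strictly greater than
#' `window_mean` (an undefined rate ends the run); `r_dm` is the maximum
#' defined rate.
#'
#' @param profile a `damage_profile` from [compute_damage_profile()].
#' @return list of class `damage_summary` with `n_db`, `r_dm`,
#'   `window_mean`, `end`, `substitution`.
#' @export
summarize_damage <- function(profile) {
  rate <- profile$rate
  def <- !is.na(rate)
  if (!any(def)) stop("all positions undefined", call. = FALSE)
  wmean <- mean(rate[def])
  above <- def & rate > wmean
  n_db <- if (!above[1]) 0L else which.min(c(above, FALSE)) - 1L
  structure(list(n_db = as.integer(n_db), r_dm = max(rate[def]),
                 window_mean = wmean,
                 end = attr(profile, "end"),
                 substitution = attr(profile, "substitution")),
            class = "damage_summary")
}

#' @export
print.damage_summary <- function(x, ...) {
  cat(sprintf("Damage summary (%s, %s): N_db = %d, R_dm = %.4f, window mean = %.4f\n",
              x$end, x$substitution, x$n_db, x$r_dm, x$window_mean))
  invisible(x)
}

#' Coefficient of variation across samples
#'
#' @param values numeric vector (length >= 2), e.g. one damage statistic
#'   per sample.
#' @return list of class `dispersion_summary` with `mean`, `sd` (sample,
#'   n-1 denominator) and `cv = sd/mean` (`NA`, flagged `undefined`, when
#'   the mean is zero).
#' @export
dispersion <- function(values) {
  if (length(values) < 2L)
    stop("dispersion needs at least 2 values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  undef <- m == 0
  structure(list(mean = m, sd = s,
                 cv = if (undef) NA_real_ else s / m,
                 undefined = undef),
            class = "dispersion_summary")
}
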