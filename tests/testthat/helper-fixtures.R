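# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately use naive, loop-based logic so
# they stay independent of the vectorised implementation paths.

# --- independent single-pass flag-counting oracle for sample metrics ----
oracle_sample_metrics <- function(records, count_duplicates = TRUE) {
  n_total <- 0L; n_mapped <- 0L; n_multi <- 0L; len_sum <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$is_primary) next
    if (!count_duplicates && r$is_duplicate) next
    n_total <- n_total + 1L
    len_sum <- len_sum + r$length
    if (r$is_mapped) {
      n_mapped <- n_mapped + 1L
      if (r$mapq == 0L) n_multi <- n_multi + 1L
    }
  }
  list(n_total = n_total, n_mapped = n_mapped, n_multi = n_multi,
       r_m = n_mapped / n_total,
       r_m0 = if (n_mapped > 0L) n_multi / n_mapped else NA_real_,
       a_l = len_sum / n_total)
}

# --- brute-force N_db scan oracle ---------------------------------------
oracle_ndb <- function(rates) {
  def <- !is.na(rates)
  wmean <- mean(rates[def])
  n <- 0L
  for (i in seq_along(rates)) {
    if (!is.na(rates[i]) && rates[i] > wmean) n <- n + 1L else break
  }
  n
}

# --- random complex alignment generator with its own pairing oracle -----
# Builds a record over `reference` with soft clips, indels, mismatches and
# either strand; the oracle pairing is recorded during construction, so it
# never touches the package's MD/CIGAR expansion.
random_base <- function(n = 1L) sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE)
other_base <- function(b) vapply(b, function(x)
  sample(setdiff(c("A", "C", "G", "T"), x), 1L), "", USE.NAMES = FALSE)

gen_complex_record <- function(reference, id, mismatch_p = 0.15) {
  refseq <- reference[[1]]
  ref_name <- names(reference)[1]
  n_blocks <- sample(1:3, 1)
  ops <- list()
  if (runif(1) < 0.4) ops[[length(ops) + 1L]] <- c("S", sample(1:4, 1))
  for (b in seq_len(n_blocks)) {
    ops[[length(ops) + 1L]] <- c("M", sample(6:15, 1))
    if (b < n_blocks) {
      if (runif(1) < 0.5) ops[[length(ops) + 1L]] <- c("I", sample(1:3, 1))
      else ops[[length(ops) + 1L]] <- c("D", sample(1:3, 1))
    }
  }
  if (runif(1) < 0.4) ops[[length(ops) + 1L]] <- c("S", sample(1:4, 1))

  ref_needed <- sum(vapply(ops, function(o)
    if (o[1] %in% c("M", "D")) as.integer(o[2]) else 0L, 0L))
  ref_start <- sample.int(nchar(refseq) - ref_needed - 1L, 1L)

  read_chars <- character(0)
  md <- character(0)
  run <- 0L
  pair_read <- character(0); pair_ref <- character(0)
  rpos <- ref_start  # 0-based walker
  for (o in ops) {
    k <- as.integer(o[2])
    if (o[1] == "S" || o[1] == "I") {
      read_chars <- c(read_chars, random_base(k))
    } else if (o[1] == "M") {
      for (j in seq_len(k)) {
        rb <- substr(refseq, rpos + 1L, rpos + 1L)
        if (runif(1) < mismatch_p) {
          qb <- other_base(rb)
          md <- c(md, as.character(run), rb); run <- 0L
        } else {
          qb <- rb
          run <- run + 1L
        }
        read_chars <- c(read_chars, qb)
        pair_read <- c(pair_read, qb); pair_ref <- c(pair_ref, rb)
        rpos <- rpos + 1L
      }
    } else if (o[1] == "D") {
      del <- substr(refseq, rpos + 1L, rpos + k)
      md <- c(md, as.character(run), "^", del); run <- 0L
      rpos <- rpos + k
    }
  }
  md <- paste0(paste(md, collapse = ""), run)
  cigar <- paste0(vapply(ops, function(o) paste0(o[2], o[1]), ""),
                  collapse = "")
  is_rev <- runif(1) < 0.5
  if (is_rev) {
    pair_read <- rev(chartr("ACGTN", "TGCAN", pair_read))
    pair_ref <- rev(chartr("ACGTN", "TGCAN", pair_ref))
  }
  rec <- alignment_records(
    id, paste(read_chars, collapse = ""), cigar = cigar, md = md,
    is_reverse = is_rev, ref_name = ref_name, ref_start = ref_start,
    ref_lengths = setNames(nchar(refseq), ref_name))
  list(record = rec, pair_read = pair_read, pair_ref = pair_ref)
}

# flip a gapless record to the opposite strand without changing the
# molecule it represents: reverse-complement the sequence and mirror the MD
flip_strand <- function(records) {
  out <- records
  out$sequence <- vapply(records$sequence, function(s)
    paste(rev(chartr("ACGTN", "TGCAN",
                     strsplit(s, "", fixed = TRUE)[[1]])), collapse = ""),
    "", USE.NAMES = FALSE)
  out$is_reverse <- !records$is_reverse
  out$md <- vapply(records$md, function(m) {
    if (is.na(m)) return(NA_character_)
    toks <- regmatches(m, gregexpr("\\d+|[A-Z]", m))[[1]]
    toks <- rev(toks)
    lett <- grepl("[A-Z]", toks)
    toks[lett] <- chartr("ACGTN", "TGCAN", toks[lett])
    paste(toks, collapse = "")
  }, "", USE.NAMES = FALSE)
  out
}

# small deterministic simulated sample shared across tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- simulate_reference(20000, 0.42, seed = 404)
      cfg <- simulation_config(seed = 99, ref_length = 20000L,
                               n_reads = 1500L,
                               endogenous_fraction = 0.7,
                               len_max = 150L)
      cache <<- list(ref = ref, sim = simulate_reads(cfg, ref))
    }
    cache
  }
})
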