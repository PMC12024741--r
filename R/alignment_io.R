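# Alignment I/O: a format-independent alignment-record model over SAM/BAM,
# FASTA reference handling, and TSV report writing.
#
# Records are held as a plain data.frame (one row per alignment line) with
# class "shaftqc_alignments" and an attribute "ref_lengths" carrying the
# @SQ header. All coordinates are 0-based half-open internally; SAM's
# 1-based POS is converted on read and back on write.

ALIGNMENT_COLUMNS <- c(
  "read_id", "sequence", "length", "is_mapped", "is_reverse", "mapq",
  "cigar", "md", "is_primary", "is_duplicate", "ref_name", "ref_start", "xt"
)

#' Construct an alignment-record table
#'
#' Builds the canonical record data.frame used throughout the package.
#' Normally produced by [read_alignments()] or [simulate_reads()]; exposed
#' so tests and callers can build records directly.
#'
#' @param read_id character read names.
#' @param sequence upper-case nucleotide strings in stored
#'   (reference-forward) orientation.
#' @param is_mapped,is_reverse,is_primary,is_duplicate logical SAM flag
#'   bits 0x4 (negated), 0x10, 0x100/0x800 (negated), 0x400.
#' @param mapq integer mapping quality, 0-255.
#' @param cigar CIGAR strings ("" for unmapped records).
#' @param md MD tag strings or `NA` when absent.
#' @param ref_name reference sequence name or `NA` for unmapped records.
#' @param ref_start 0-based leftmost mapping position (`NA` if unmapped).
#' @param xt optional BWA-style XT:A tag value ("U", "R", ...) or `NA`.
#' @param ref_lengths named integer vector of reference sequence lengths,
#'   used to emit the @SQ header on write.
#' @return a data.frame of class `shaftqc_alignments`.
#' @export
alignment_records <- function(read_id, sequence,
                              is_mapped = TRUE, is_reverse = FALSE,
                              mapq = 60L, cigar = paste0(nchar(sequence), "M"),
                              md = NA_character_, is_primary = TRUE,
                              is_duplicate = FALSE, ref_name = NA_character_,
                              ref_start = NA_integer_, xt = NA_character_,
                              ref_lengths = integer()) {
  n <- length(read_id)
  rec <- data.frame(
    read_id = as.character(read_id),
    sequence = toupper(as.character(sequence)),
    length = nchar(sequence),
    is_mapped = rep_len(as.logical(is_mapped), n),
    is_reverse = rep_len(as.logical(is_reverse), n),
    mapq = rep_len(as.integer(mapq), n),
    cigar = rep_len(as.character(cigar), n),
    md = rep_len(as.character(md), n),
    is_primary = rep_len(as.logical(is_primary), n),
    is_duplicate = rep_len(as.logical(is_duplicate), n),
    ref_name = rep_len(as.character(ref_name), n),
    ref_start = rep_len(as.integer(ref_start), n),
    xt = rep_len(as.character(xt), n),
    stringsAsFactors = FALSE
  )
  rec$cigar[!rec$is_mapped] <- ""
  validate_alignments(rec)
  structure(rec, ref_lengths = ref_lengths,
            class = c("shaftqc_alignments", "data.frame"))
}

# invariant checks shared by the constructor and the SAM parser
validate_alignments <- function(rec, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("record %d (%s)", i, rec$read_id[i])
    else sprintf("line %d", lines[i])
  }
  if (any(bad <- rec$length < 1L | rec$length != nchar(rec$sequence)))
    stop("sequence/length mismatch at ", where(which(bad)[1]), call. = FALSE)
  if (any(bad <- !is.na(rec$md) & !rec$is_mapped))
    stop("MD tag on unmapped record at ", where(which(bad)[1]), call. = FALSE)
  if (any(bad <- grepl("[^ACGTN]", rec$sequence)))
    stop("non-ACGTN base at ", where(which(bad)[1]), call. = FALSE)
  chk <- rec$is_mapped & rec$is_primary
  if (any(chk)) {
    qlen <- cigar_query_length(rec$cigar[chk])
    if (any(bad <- qlen != rec$length[chk]))
      stop("CIGAR query length disagrees with sequence length at ",
           where(which(chk)[which(bad)[1]]), call. = FALSE)
  }
  invisible(rec)
}

# vectorised query-consuming length of CIGAR strings (M/I/S/=/X consume query)
cigar_query_length <- function(cigar) {
  out <- integer(length(cigar))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (!length(tk)) next
    op <- substring(tk, nchar(tk), nchar(tk))
    len <- as.integer(substring(tk, 1L, nchar(tk) - 1L))
    out[i] <- sum(len[op %in% c("M", "I", "S", "=", "X")])
  }
  out
}

#' Read alignments from SAM or BAM
#'
#' Parses every alignment line into the package's record model. SAM text is
#' parsed in-package; BAM is delegated to \pkg{Rsamtools}. Secondary,
#' supplementary and duplicate records are retained but flagged
#' (`is_primary`, `is_duplicate`) so downstream denominators can exclude
#' them.
#'
#' @param path path to the alignment file.
#' @param format `"sam"` or `"bam"`; default guessed from the extension.
#' @return a `shaftqc_alignments` data.frame in file order, with the header
#'   reference lengths in `attr(, "ref_lengths")`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "bam") return(read_bam(path))

  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  if (any(is_hdr) && !all(which(is_hdr) == seq_len(sum(is_hdr))))
    stop("header lines after first alignment record", call. = FALSE)
  hdr <- lines[is_hdr]
  body_idx <- which(!is_hdr & nzchar(lines))
  ref_lengths <- parse_sq_header(hdr)

  if (!length(body_idx))
    return(structure(
      empty_alignments(), ref_lengths = ref_lengths,
      class = c("shaftqc_alignments", "data.frame")))

  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record (fewer than 11 fields) at line ",
         body_idx[which(nf < 11L)[1]], call. = FALSE)
  fm <- matrix("", nrow = length(fields), ncol = 11L)
  for (j in 1:11) fm[, j] <- vapply(fields, `[[`, "", j)

  flag <- suppressWarnings(as.integer(fm[, 2]))
  pos <- suppressWarnings(as.integer(fm[, 4]))
  mapq <- suppressWarnings(as.integer(fm[, 5]))
  bad <- is.na(flag) | is.na(pos) | is.na(mapq) | !nzchar(fm[, 1]) |
    fm[, 10] == "*" | grepl("[^ACGTNacgtn]", fm[, 10])
  if (any(bad))
    stop("malformed SAM record at line ", body_idx[which(bad)[1]],
         call. = FALSE)

  # optional tags beyond the 11 mandatory fields
  md <- rep(NA_character_, length(fields))
  xt <- rep(NA_character_, length(fields))
  has_opt <- which(nf > 11L)
  for (i in has_opt) {
    opt <- fields[[i]][-(1:11)]
    m <- opt[startsWith(opt, "MD:Z:")]
    if (length(m)) md[i] <- substring(m[1], 6L)
    x <- opt[startsWith(opt, "XT:A:")]
    if (length(x)) xt[i] <- substring(x[1], 6L)
  }

  is_mapped <- bitwAnd(flag, 0x4) == 0L
  rec <- data.frame(
    read_id = fm[, 1],
    sequence = toupper(fm[, 10]),
    length = nchar(fm[, 10]),
    is_mapped = is_mapped,
    is_reverse = bitwAnd(flag, 0x10) != 0L,
    mapq = mapq,
    cigar = ifelse(is_mapped & fm[, 6] != "*", fm[, 6], ""),
    md = md,
    is_primary = bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L,
    is_duplicate = bitwAnd(flag, 0x400) != 0L,
    ref_name = ifelse(is_mapped & fm[, 3] != "*", fm[, 3], NA_character_),
    ref_start = ifelse(is_mapped & pos > 0L, pos - 1L, NA_integer_),
    xt = xt,
    stringsAsFactors = FALSE
  )
  rec$md[!rec$is_mapped] <- NA_character_
  validate_alignments(rec, lines = body_idx)
  structure(rec, ref_lengths = ref_lengths,
            class = c("shaftqc_alignments", "data.frame"))
}

empty_alignments <- function() {
  as.data.frame(setNames(
    list(character(), character(), integer(), logical(), logical(),
         integer(), character(), character(), logical(), logical(),
         character(), integer(), character()),
    ALIGNMENT_COLUMNS))
}

parse_sq_header <- function(hdr) {
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq)) return(integer())
  nm <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  setNames(ln, nm)
}

read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package", call. = FALSE)
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  if (!length(hdr$targets) && !length(hdr$text))
    stop("BAM file has no header: ", path, call. = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("MD", "XT"))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  flag <- b$flag
  is_mapped <- bitwAnd(flag, 0x4) == 0L
  seqs <- toupper(as.character(b$seq))
  rec <- data.frame(
    read_id = b$qname,
    sequence = seqs,
    length = nchar(seqs),
    is_mapped = is_mapped,
    is_reverse = bitwAnd(flag, 0x10) != 0L,
    mapq = as.integer(b$mapq),
    cigar = ifelse(is_mapped & !is.na(b$cigar), b$cigar, ""),
    md = if (is.null(b$tag$MD)) NA_character_ else as.character(b$tag$MD),
    is_primary = bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L,
    is_duplicate = bitwAnd(flag, 0x400) != 0L,
    ref_name = ifelse(is_mapped, as.character(b$rname), NA_character_),
    ref_start = ifelse(is_mapped, as.integer(b$pos) - 1L, NA_integer_),
    xt = if (is.null(b$tag$XT)) NA_character_ else as.character(b$tag$XT),
    stringsAsFactors = FALSE
  )
  rec$mapq[is.na(rec$mapq)] <- 0L
  rec$md[!rec$is_mapped] <- NA_character_
  validate_alignments(rec)
  structure(rec, ref_lengths = as.integer(hdr$targets) |>
              setNames(names(hdr$targets)),
            class = c("shaftqc_alignments", "data.frame"))
}

#' Write alignment records as SAM text
#'
#' Emits a SAM file (header plus one line per record) that round-trips
#' through [read_alignments()] with field-identical results. Base qualities
#' are not modelled and are written as a constant placeholder.
#'
#' @param records a `shaftqc_alignments` data.frame.
#' @param path output file path.
#' @param ref_lengths named integer vector for the @SQ header; defaults to
#'   `attr(records, "ref_lengths")`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(records, path,
                             ref_lengths = attr(records, "ref_lengths")) {
  writeLines(format_sam(records, ref_lengths), path)
  invisible(path)
}

format_sam <- function(records, ref_lengths = attr(records, "ref_lengths")) {
  hdr <- "@HD\tVN:1.6\tSO:unsorted"
  if (length(ref_lengths))
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                          as.integer(ref_lengths)))
  if (!nrow(records)) return(hdr)
  flag <- 4L * (!records$is_mapped) + 16L * records$is_reverse +
    256L * (!records$is_primary) + 1024L * records$is_duplicate
  body <- paste(
    records$read_id, flag,
    ifelse(records$is_mapped, records$ref_name, "*"),
    ifelse(records$is_mapped, records$ref_start + 1L, 0L),
    records$mapq,
    ifelse(records$is_mapped & nzchar(records$cigar), records$cigar, "*"),
    "*", 0L, 0L,
    records$sequence,
    strrep("I", records$length),
    sep = "\t")
  has_md <- !is.na(records$md)
  body[has_md] <- paste0(body[has_md], "\tMD:Z:", records$md[has_md])
  has_xt <- !is.na(records$xt)
  body[has_xt] <- paste0(body[has_xt], "\tXT:A:", records$xt[has_xt])
  c(hdr, body)
}

#' Read a FASTA reference
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of upper-case sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate sequence name in FASTA: ", nm[duplicated(nm)][1],
         call. = FALSE)
  setNames(toupper(as.character(set)), nm)
}

#' Write a FASTA reference
#'
#' @param reference named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(reference)) {
    writeLines(paste0(">", nm), con)
    s <- reference[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Tab-delimited, UTF-8, header row, plain decimal notation, deterministic
#' column order (as given). The standard output format of the pipeline.
#'
#' @param rows a data.frame (possibly with zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, TRUE)
  out <- rows
  # plain decimal notation regardless of options(scipen)
  for (j in which(num)) {
    out[[j]] <- vapply(rows[[j]], function(v) {
      if (is.na(v)) "NA" else format(v, scientific = FALSE, digits = 15)
    }, "")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path path to a file written by [write_report()].
#' @return a data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

# reverse-complement of a character vector of sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-base complement of a character vector of single bases
complement_bases <- function(x) chartr("ACGTN", "TGCAN", x)
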