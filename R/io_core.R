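# Sequence records travel through the pipeline as a plain data.frame with
# columns id, desc, seq and a list-column qual of integer Phred vectors
# (NULL when absent). Constructors validate the record invariants once, at
# ingestion; downstream stages rely on them.

#' Construct a set of sequence records
#'
#' @param id character vector of whitespace-free identifiers.
#' @param seq character vector of sequences (uppercased on ingestion).
#' @param qual optional list of integer Phred vectors (0-93), each the same
#'   length as its sequence, or `NULL`.
#' @param desc optional character vector of free-text descriptions.
#' @return data.frame of class `seq_records`.
#' @export
seq_records <- function(id, seq, qual = NULL, desc = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(id)
  stopifnot(length(seq) == n)
  if (any(grepl("\\s", id))) stop("record ids must not contain whitespace")
  if (any(nchar(seq) < 1)) stop("zero-length sequence in records: ",
                                paste(id[nchar(seq) < 1], collapse = ", "))
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seq)
  if (any(bad)) stop("non-IUPAC symbol in sequence of record ", id[which(bad)[1]])
  if (is.null(qual)) qual <- rep(list(NULL), n)
  stopifnot(length(qual) == n)
  for (i in seq_len(n)) {
    q <- qual[[i]]
    if (!is.null(q)) {
      if (length(q) != nchar(seq[i]))
        stop("quality length mismatch for record ", id[i])
      if (any(q < 0 | q > 93)) stop("Phred score out of [0, 93] in record ", id[i])
      qual[[i]] <- as.integer(q)
    }
  }
  if (is.null(desc)) desc <- rep("", n)
  out <- data.frame(id = id, desc = as.character(desc), seq = seq,
                    stringsAsFactors = FALSE)
  out$qual <- qual
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict 4-line records; malformed records (quality shorter or longer than
#' the sequence, missing separator) are a hard error naming the record and
#' the line number. Other Phred encodings are rejected, not guessed.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [seq_records] data.frame with decoded integer qualities.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(seq_records(character(), character()))
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  i <- seq(1, length(lines), by = 4)
  hdr <- lines[i]
  if (any(substr(hdr, 1, 1) != "@"))
    stop("malformed FASTQ header at line ", i[which(substr(hdr, 1, 1) != "@")[1]])
  if (any(substr(lines[i + 2], 1, 1) != "+"))
    stop("missing '+' separator at line ", (i + 2)[which(substr(lines[i + 2], 1, 1) != "+")[1]])
  hdr <- sub("^@", "", hdr)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- toupper(lines[i + 1])
  quals <- lines[i + 3]
  bad <- nchar(quals) != nchar(seq)
  if (any(bad)) {
    k <- which(bad)[1]
    stop("quality/sequence length mismatch for record '", id[k],
         "' at line ", i[k] + 3)
  }
  qual <- lapply(quals, function(q) as.integer(utf8ToInt(q)) - 33L)
  seq_records(id, seq, qual, desc)
}

#' Write records as FASTQ (Phred+33)
#'
#' @param records a [seq_records] data.frame; all records must carry quality.
#' @param path output path.
#' @export
write_fastq <- function(records, path) {
  if (any(vapply(records$qual, is.null, TRUE)))
    stop("cannot write FASTQ: records without quality present")
  hdr <- ifelse(records$desc == "", records$id, paste(records$id, records$desc))
  q <- vapply(records$qual, function(x) intToUtf8(x + 33L), "")
  writeLines(as.vector(rbind(paste0("@", hdr), records$seq, "+", q)), path)
  invisible(path)
}

#' Read a FASTA file into sequence records
#'
#' @param path path to an uncompressed FASTA file.
#' @return a [seq_records] data.frame (no qualities).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq_records(id, as.character(x), NULL, desc)
}

#' Write records as unwrapped FASTA
#'
#' @param records a [seq_records] data.frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- ifelse(records$desc == "", records$id, paste(records$id, records$desc))
  writeLines(as.vector(rbind(paste0(">", hdr), records$seq)), path)
  invisible(path)
}

SHEET_COLS <- c("sample_id", "index_f", "index_r", "marker", "site_id",
                "elevation_m", "field_replicate", "rpa_replicate",
                "is_negative_control")

#' Validate a sample sheet data.frame
#'
#' The sheet maps dual 20-base index pairs to samples with site, elevation
#' and replicate metadata. Index pairs and sample ids must be unique; the
#' two-step indexing design fixes indexes at exactly 20 bases.
#'
#' @param df data.frame with columns `sample_id`, `index_f`, `index_r`,
#'   `marker` ("edna" or "barcode"), `site_id`, `elevation_m`,
#'   `field_replicate`, `rpa_replicate`, `is_negative_control`.
#' @return the validated data.frame, class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  miss <- setdiff(SHEET_COLS, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  df <- df[, SHEET_COLS]
  df$index_f <- toupper(df$index_f); df$index_r <- toupper(df$index_r)
  badlen <- nchar(df$index_f) != 20 | nchar(df$index_r) != 20
  if (any(badlen))
    stop("indexes must be exactly 20 bases; offending row(s): ",
         paste(df$sample_id[badlen], collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  pair <- paste(df$index_f, df$index_r)
  if (anyDuplicated(pair))
    stop("duplicate (index_f, index_r) pair for samples: ",
         paste(df$sample_id[pair %in% pair[duplicated(pair)]], collapse = ", "))
  if (!all(df$marker %in% c("edna", "barcode")))
    stop("marker must be 'edna' or 'barcode'")
  stopifnot(all(df$elevation_m >= 0), all(df$field_replicate >= 1),
            all(df$rpa_replicate >= 1))
  df$is_negative_control <- as.logical(df$is_negative_control)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet TSV
#'
#' Tab-separated, UTF-8, header row naming all fields; lines starting with
#' `#` are comments.
#'
#' @param path path to the TSV file.
#' @return validated `sample_sheet` data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Write a sample sheet TSV
#' @param sheet a `sample_sheet` data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Defaults are the workflow's published operating point: mean Phred
#' strictly greater than 12, read length 172-212 bp for the eDNA marker and
#' 520-580 bp for the barcoding marker (closed intervals), identity
#' thresholds 95 and 99 percent, per-sample taxon noise floor of 5 reads,
#' and edit-distance tolerances of 2 per index and 3 for primers.
#'
#' @param min_mean_phred quality cutoff (kept iff mean Phred > this).
#' @param length_window_edna,length_window_barcode closed length intervals.
#' @param identity_thresholds percent-identity cutoffs in (0, 100].
#' @param noise_floor per-sample taxon counts <= this are zeroed.
#' @param index_edit_tolerance,primer_edit_tolerance demux tolerances.
#' @param rng_seed integer seed echoed into run reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_mean_phred = 12,
                       length_window_edna = c(172L, 212L),
                       length_window_barcode = c(520L, 580L),
                       identity_thresholds = c(95, 99),
                       noise_floor = 5L,
                       index_edit_tolerance = 2L,
                       primer_edit_tolerance = 3L,
                       rng_seed = 1L) {
  stopifnot(index_edit_tolerance >= 0, primer_edit_tolerance >= 0,
            noise_floor >= 0,
            all(identity_thresholds > 0 & identity_thresholds <= 100),
            length(length_window_edna) == 2,
            length(length_window_barcode) == 2,
            diff(length_window_edna) >= 0, diff(length_window_barcode) >= 0)
  structure(list(min_mean_phred = min_mean_phred,
                 length_window_edna = as.integer(length_window_edna),
                 length_window_barcode = as.integer(length_window_barcode),
                 identity_thresholds = sort(identity_thresholds),
                 noise_floor = as.integer(noise_floor),
                 index_edit_tolerance = as.integer(index_edit_tolerance),
                 primer_edit_tolerance = as.integer(primer_edit_tolerance),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}
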