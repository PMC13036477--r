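# MIDORI2-style reference databases: accession + ranked lineage + sequence,
# with provenance tracking (base records vs locally generated consensus
# barcodes) so that base-vs-combined comparisons can trace every hit.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Construct a taxonomy lineage
#'
#' @param ... named rank tokens among kingdom, phylum, class, order,
#'   family, genus, species; missing ranks become `"UNKNOWN"`.
#' @return named character vector over all seven ranks.
#' @export
lineage <- function(...) {
  v <- c(...)
  out <- setNames(rep("UNKNOWN", length(RANKS)), RANKS)
  out[names(v)] <- v
  if (out["species"] != "UNKNOWN" && out["genus"] == "UNKNOWN")
    out["genus"] <- strsplit(out["species"], " ")[[1]][1]
  if (out["species"] != "UNKNOWN" &&
      !startsWith(strsplit(out["species"], " ")[[1]][1], out["genus"]))
    stop("genus '", out["genus"], "' does not match species binomial '",
         out["species"], "'")
  out
}

#' Build a reference database from parsed records
#'
#' @param accession unique accession tokens.
#' @param lineages data.frame (or matrix) with the seven rank columns.
#' @param seq sequences.
#' @param provenance `"base"` or `"local"` per record.
#' @return data.frame of class `reference_db`.
#' @export
reference_db <- function(accession, lineages, seq, provenance = "base") {
  if (anyDuplicated(accession))
    stop("duplicate accession: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  lineages <- as.data.frame(lineages, stringsAsFactors = FALSE)
  stopifnot(all(RANKS %in% names(lineages)))
  db <- data.frame(accession = as.character(accession),
                   lineages[, RANKS, drop = FALSE],
                   seq = toupper(as.character(seq)),
                   provenance = rep(provenance, length.out = length(accession)),
                   stringsAsFactors = FALSE)
  rownames(db) <- NULL
  class(db) <- c("reference_db", "data.frame")
  db
}

# "accession.version" then semicolon-delimited rank_Name_taxid tokens, e.g.
# >AB123456.1 root_1;class_Amphibia_20;...;species_Rhinella horribilis_95055
parse_midori_header <- function(hdr) {
  body <- sub("^\\S+?[;[:space:]]+", "", hdr)  # drop accession token
  parts <- strsplit(body, ";", fixed = TRUE)[[1]]
  out <- setNames(rep("UNKNOWN", length(RANKS)), RANKS)
  warned <- FALSE
  for (p in parts) {
    m <- regmatches(p, regexec("^\\s*([a-z]+)_(.+)_[0-9]+$", p))[[1]]
    if (length(m) == 3) {
      if (m[2] %in% RANKS) out[m[2]] <- m[3]  # other ranks (root etc.) ignored
    } else if (nzchar(trimws(p))) warned <- TRUE
  }
  list(lineage = out, warned = warned)
}

#' Parse a reference FASTA into a database
#'
#' Two header dialects are supported. `"midori2"`: an accession.version
#' token followed by semicolon-delimited `rank_Name_taxid` fields;
#' unparseable fields degrade to `UNKNOWN` with a single warning, never a
#' crash. `"simple"` (the canonical internal format):
#' `accession|kingdom|phylum|class|order|family|genus|species binomial`.
#'
#' @param path FASTA file path.
#' @param dialect `"simple"` or `"midori2"`.
#' @return a `reference_db` data.frame (provenance `"base"`).
#' @export
parse_reference_fasta <- function(path, dialect = c("simple", "midori2")) {
  dialect <- match.arg(dialect)
  recs <- read_fasta(path)
  hdr <- ifelse(recs$desc == "", recs$id, paste(recs$id, recs$desc))
  if (dialect == "simple") {
    fields <- strsplit(hdr, "|", fixed = TRUE)
    acc <- vapply(fields, `[`, "", 1)
    lin <- t(vapply(fields, function(f) {
      v <- setNames(rep("UNKNOWN", length(RANKS)), RANKS)
      got <- f[-1]
      got[!nzchar(got)] <- "UNKNOWN"
      v[seq_along(got)] <- got
      v
    }, setNames(character(length(RANKS)), RANKS)))
  } else {
    acc <- vapply(strsplit(hdr, "[; ]"), `[`, "", 1)
    parsed <- lapply(hdr, parse_midori_header)
    if (any(vapply(parsed, `[[`, TRUE, "warned")))
      warning("some midori2 rank tokens were unparseable; set to UNKNOWN")
    lin <- t(vapply(parsed, `[[`, setNames(character(length(RANKS)), RANKS),
                    "lineage"))
  }
  reference_db(acc, lin, recs$seq, "base")
}

#' Write a reference database as simple-dialect FASTA
#' @param db a `reference_db`.
#' @param path output path.
#' @export
write_reference_fasta <- function(db, path) {
  hdr <- apply(db[, c("accession", RANKS)], 1, paste, collapse = "|")
  writeLines(as.vector(rbind(paste0(">", hdr), db$seq)), path)
  invisible(path)
}

#' Augment a reference database with local consensus barcodes
#'
#' Adds each barcode as a record with provenance `"local"` and accession
#' `LOCAL_<id>`. The species label comes from field identification (sample
#' sheet / checklist), not sequence inference. A barcode whose sequence is
#' identical to an existing record of the same species is skipped with a
#' message, so augmentation is idempotent.
#'
#' @param base a `reference_db`.
#' @param barcodes data.frame with columns `local_id` (unique tokens),
#'   `species` (binomial), `seq`, and optionally rank columns (defaults:
#'   genus from the binomial, class `"Amphibia"`).
#' @return the augmented `reference_db`.
#' @export
augment <- function(base, barcodes) {
  if (nrow(barcodes) == 0) return(base)
  if (anyDuplicated(barcodes$local_id))
    stop("local identifier collision: ",
         paste(unique(barcodes$local_id[duplicated(barcodes$local_id)]),
               collapse = ", "))
  db <- base
  for (i in seq_len(nrow(barcodes))) {
    b <- barcodes[i, ]
    dup <- db$seq == toupper(b$seq) & db$species == b$species
    if (any(dup)) {
      message("augment: skipping ", b$local_id,
              " (identical sequence already present for ", b$species, ")")
      next
    }
    acc <- paste0("LOCAL_", b$local_id)
    if (acc %in% db$accession) stop("local identifier collision: ", b$local_id)
    lin <- lineage(kingdom = b$kingdom %||% "Metazoa",
                   phylum = b$phylum %||% "Chordata",
                   class = b$class %||% "Amphibia",
                   order = b$order %||% "UNKNOWN",
                   family = b$family %||% "UNKNOWN",
                   genus = strsplit(b$species, " ")[[1]][1],
                   species = b$species)
    row <- data.frame(accession = acc, t(lin), seq = toupper(b$seq),
                      provenance = "local", stringsAsFactors = FALSE)
    db <- rbind(db, row)
  }
  class(db) <- c("reference_db", "data.frame")
  rownames(db) <- NULL
  db
}
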