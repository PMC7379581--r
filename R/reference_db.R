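## Taxonomy-annotated reference sequence databases.
##
## A reference_db is a validated data.frame of records, one per sequence,
## carrying the full rank lineage (species, genus, family, order) and a
## circularity flag. Two on-disk dialects are supported:
##   * taxfasta: FASTA with headers ">seq_id|species|genus|family|order|circular={0,1}"
##   * ecopcr_dump: tab-separated with a header row and columns
##     seq_id, species, genus, family, order, sequence, circular

.DB_COLUMNS <- c("seq_id", "species", "genus", "family", "order",
                 "circular", "sequence")

.VALID_SEQ_CHARS <- names(.IUPAC_SETS)

#' Construct a reference database
#'
#' Validates and wraps a data.frame of taxonomy-annotated sequences.
#' Sequences are uppercased; characters outside the IUPAC nucleotide
#' alphabet are an error (no silent masking). Species represented by
#' several sequences are kept as-is: intraspecific variation is what the
#' resolution indices measure.
#'
#' @param records data.frame with columns `seq_id`, `species`, `genus`,
#'   `family`, `order`, `circular` (logical) and `sequence`.
#' @return object of class `reference_db`.
#' @export
reference_db <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.DB_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[, .DB_COLUMNS]
  rownames(records) <- NULL
  if (nrow(records) == 0L) stop("empty database", call. = FALSE)
  for (col in c("seq_id", "species", "genus", "family", "order", "sequence")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$circular <- as.logical(records$circular)
  if (anyNA(records$circular)) {
    stop("circular flag must be logical (or 0/1)", call. = FALSE)
  }
  dup <- records$seq_id[duplicated(records$seq_id)]
  if (length(dup)) {
    stop("duplicated seq_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records$seq_id))) stop("empty seq_id", call. = FALSE)
  if (any(!nzchar(records$species))) {
    stop("records without species label: ",
         paste(records$seq_id[!nzchar(records$species)], collapse = ", "),
         call. = FALSE)
  }
  records$sequence <- toupper(records$sequence)
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for: ",
         paste(records$seq_id[!nzchar(records$sequence)], collapse = ", "),
         call. = FALSE)
  }
  bad <- vapply(
    records$sequence,
    function(s) any(!(.seq_chars(s) %in% .VALID_SEQ_CHARS)),
    logical(1L), USE.NAMES = FALSE
  )
  if (any(bad)) {
    stop("sequence with characters outside the IUPAC alphabet: ",
         paste(records$seq_id[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(records = records), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  s <- db_stats(x)
  cat(sprintf(
    "<reference_db> %d records | %d species | %d genera | %d families | %d orders\n",
    s$records, s$species, s$genera, s$families, s$orders
  ))
  invisible(x)
}

#' Record, species and rank counts of a database
#'
#' @param db a [reference_db()].
#' @return one-row data.frame with columns `records`, `species`, `genera`,
#'   `families`, `orders`.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  r <- db$records
  data.frame(
    records = nrow(r),
    species = length(unique(r$species)),
    genera = length(unique(r$genus)),
    families = length(unique(r$family)),
    orders = length(unique(r$order))
  )
}

#' Species index of a database
#'
#' @param db a [reference_db()].
#' @return named list mapping each species label to its `seq_id`s.
#' @export
species_index <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  split(db$records$seq_id, db$records$species)
}

.parse_taxfasta_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  if (length(fields) != 6L || !grepl("^circular=[01]$", fields[6L])) {
    return(NULL)
  }
  list(
    seq_id = fields[1L], species = fields[2L], genus = fields[3L],
    family = fields[4L], order = fields[5L],
    circular = fields[6L] == "circular=1"
  )
}

#' Load a reference database from disk
#'
#' Reads either of the two supported dialects and validates the result.
#' Records without a species label are dropped with a message reporting the
#' count; all other validation failures are errors. Counts of records,
#' species, genera, families and orders are reported via `message()`.
#'
#' @param path path to the database file.
#' @param dialect `"taxfasta"` (FASTA, headers
#'   `seq_id|species|genus|family|order|circular={0,1}`) or
#'   `"ecopcr_dump"` (TSV with a header row).
#' @return a [reference_db()].
#' @export
load_reference_db <- function(path, dialect = c("taxfasta", "ecopcr_dump")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  if (dialect == "taxfasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
    parsed <- lapply(names(seqs), .parse_taxfasta_header)
    bad <- which(vapply(parsed, is.null, logical(1L)))
    if (length(bad)) {
      lines <- readLines(path, warn = FALSE)
      lineno <- which(lines == paste0(">", names(seqs)[bad[1L]]))[1L]
      stop("malformed taxfasta header at line ",
           if (is.na(lineno)) "?" else lineno, ": >", names(seqs)[bad[1L]],
           call. = FALSE)
    }
    records <- do.call(rbind, lapply(parsed, as.data.frame))
    records$sequence <- as.character(seqs)
  } else {
    records <- read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
    missing_cols <- setdiff(.DB_COLUMNS, names(records))
    if (length(missing_cols)) {
      stop("ecopcr_dump at ", path, " lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    records$circular <- records$circular %in% c("1", "TRUE", "true")
  }
  no_species <- !nzchar(trimws(records$species))
  if (any(no_species)) {
    message("dropped ", sum(no_species), " record(s) without species label")
    records <- records[!no_species, , drop = FALSE]
    if (nrow(records) == 0L) {
      stop("no records with species labels in ", path, call. = FALSE)
    }
  }
  db <- reference_db(records)
  s <- db_stats(db)
  message(sprintf(
    "loaded %d records: %d species, %d genera, %d families, %d orders",
    s$records, s$species, s$genera, s$families, s$orders
  ))
  db
}

#' Write a reference database to disk
#'
#' Round-trips with [load_reference_db()]: writing and re-loading either
#' dialect reproduces the identical record set.
#'
#' @param db a [reference_db()].
#' @param path output file path.
#' @param dialect see [load_reference_db()].
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path,
                               dialect = c("taxfasta", "ecopcr_dump")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(db, "reference_db"))
  r <- db$records
  if (dialect == "taxfasta") {
    seqs <- Biostrings::DNAStringSet(r$sequence)
    names(seqs) <- sprintf("%s|%s|%s|%s|%s|circular=%d",
                           r$seq_id, r$species, r$genus, r$family, r$order,
                           as.integer(r$circular))
    Biostrings::writeXStringSet(seqs, path)
  } else {
    out <- r[, .DB_COLUMNS]
    out$circular <- as.integer(out$circular)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Subset a database to one taxonomic order
#'
#' Used for within-order marker evaluation (per-order ETR is computed on the
#' subset's own species set).
#'
#' @param db a [reference_db()].
#' @param order order label present in `db`.
#' @return a [reference_db()] containing exactly the matching records.
#' @export
subset_by_order <- function(db, order) {
  stopifnot(inherits(db, "reference_db"))
  available <- sort(unique(db$records$order))
  if (!order %in% available) {
    stop("unknown order '", order, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  reference_db(db$records[db$records$order == order, , drop = FALSE])
}
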