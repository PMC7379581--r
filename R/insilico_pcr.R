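## In silico PCR: emulate amplification of an IUPAC-degenerate primer pair
## over a reference database under a configurable matching policy
## (per-primer mismatch budget, mismatch-free 3' anchor, inosine pairing
## mode, amplicon length window, circular templates).
##
## Conventions:
##   * coordinates are 0-based half-open on the template forward strand;
##     wrap-around products on circular templates report end > length.
##   * the insert excludes the two primer annealing sites, and the length
##     window applies to the insert (expected_len is an insert length).
##   * degenerate positions match set-theoretically: the primer code's base
##     set must contain the template base; template N (or any ambiguity
##     code) never matches.

#' Primer constructor
#'
#' @param name primer name.
#' @param seq primer sequence written 5'->3' over IUPAC codes plus `"I"`
#'   (inosine); at least 10 bases.
#' @return object of class `primer`.
#' @export
primer <- function(name, seq) {
  seq <- toupper(seq)
  chars <- .seq_chars(seq)
  bad <- !(chars %in% c(names(.IUPAC_SETS), "I"))
  if (any(bad)) {
    stop("primer '", name, "' contains non-IUPAC character(s): ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  if (length(chars) < 10L) {
    stop("primer '", name, "' shorter than 10 bases", call. = FALSE)
  }
  structure(list(name = as.character(name), seq = seq), class = "primer")
}

.as_primer <- function(x, name = "primer") {
  if (inherits(x, "primer")) return(x)
  primer(name, x)
}

#' Primer pair constructor
#'
#' @param name marker/pair name.
#' @param fwd,rev forward and reverse primers ([primer()] objects or plain
#'   sequences), both written 5'->3'.
#' @param expected_len expected insert length (bases between, and excluding,
#'   the two annealing sites).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev, expected_len) {
  fwd <- .as_primer(fwd, paste0(name, "_F"))
  rev <- .as_primer(rev, paste0(name, "_R"))
  expected_len <- as.integer(expected_len)
  if (expected_len <= nchar(fwd$seq) + nchar(rev$seq)) {
    stop("expected_len must exceed the summed primer lengths", call. = FALSE)
  }
  structure(list(name = as.character(name), fwd = fwd, rev = rev,
                 expected_len = expected_len),
            class = "primer_pair")
}

#' Matching policy for in silico PCR
#'
#' @param max_mismatches maximum mismatches allowed per primer.
#' @param anchor3_len number of 3'-terminal primer bases where no mismatch
#'   is tolerated (vacuous at `max_mismatches = 0`). Default 2; design-time
#'   screens conventionally use 3.
#' @param inosine_mode `"as_N"` (inosine pairs with all bases) or `"as_H"`
#'   (A/C/T only).
#' @param length_window fractional tolerance around the expected insert
#'   length, e.g. `0.10` for +/-10%. `NULL` disables the filter.
#' @return object of class `match_policy`.
#' @export
match_policy <- function(max_mismatches = 0L, anchor3_len = 2L,
                         inosine_mode = c("as_N", "as_H"),
                         length_window = 0.10) {
  inosine_mode <- match.arg(inosine_mode)
  max_mismatches <- as.integer(max_mismatches)
  anchor3_len <- as.integer(anchor3_len)
  stopifnot(max_mismatches >= 0L, anchor3_len >= 0L)
  if (!is.null(length_window) &&
      (length_window < 0 || length_window >= 1)) {
    stop("length_window must lie in [0, 1)", call. = FALSE)
  }
  structure(list(max_mismatches = max_mismatches, anchor3_len = anchor3_len,
                 inosine_mode = inosine_mode, length_window = length_window),
            class = "match_policy")
}

#' Degeneracy of a primer
#'
#' Number of unique concrete oligonucleotides the primer denotes: the
#' product over positions of the number of bases each code stands for.
#' Inosine contributes 4 under `"as_N"` and 3 under `"as_H"`.
#'
#' @param p a [primer()] or plain sequence.
#' @param inosine_mode inosine pairing mode.
#' @return integer (double for very degenerate primers).
#' @examples
#' primer_degeneracy("ACTWTGTTACGACTTDTY")  # 12
#' @export
primer_degeneracy <- function(p, inosine_mode = c("as_N", "as_H")) {
  inosine_mode <- match.arg(inosine_mode)
  seq <- if (inherits(p, "primer")) p$seq else toupper(p)
  sets <- lapply(.seq_chars(seq), .iupac_bases, inosine_mode = inosine_mode)
  prod(lengths(sets))
}

#' Mismatches between a primer and a template window
#'
#' Counts positions where the template base is outside the base set of the
#' primer code at that position. Template characters other than A/C/G/T
#' never match.
#'
#' @param primer a [primer()] or plain sequence.
#' @param window template window (same length as the primer).
#' @param inosine_mode inosine pairing mode.
#' @return integer mismatch count.
#' @examples
#' iupac_mismatches("ACRT", "ACGT")  # 0
#' @export
iupac_mismatches <- function(primer, window,
                             inosine_mode = c("as_N", "as_H")) {
  inosine_mode <- match.arg(inosine_mode)
  seq <- if (inherits(primer, "primer")) primer$seq else toupper(primer)
  window <- toupper(window)
  if (nchar(seq) != nchar(window)) {
    stop("primer and window lengths differ", call. = FALSE)
  }
  allowed <- .allowed_matrix(seq, inosine_mode)
  code <- .encode_dna(window)
  sum(!allowed[cbind(code, seq_along(code))])
}

## mismatch profile of one primer along a template: returns, for every
## window start (1-based), the total and anchor-region mismatch counts
.scan_sites <- function(code, allowed, anchor_cols, max_mm) {
  L <- ncol(allowed)
  n_off <- length(code) - L + 1L
  if (n_off < 1L) return(list(pos = integer(0), mm = integer(0)))
  mm <- integer(n_off)
  am <- integer(n_off)
  idx <- seq_len(n_off)
  for (j in seq_len(L)) {
    bad <- !allowed[, j][code[idx + (j - 1L)]]
    mm <- mm + bad
    if (j %in% anchor_cols) am <- am + bad
  }
  keep <- mm <= max_mm & am == 0L
  list(pos = idx[keep], mm = mm[keep])
}

## amplify one template strand; `seq` is the strand actually scanned
## (already reverse-complemented for "-" products), coordinates are on
## that strand, 0-based half-open
.amplify_strand <- function(seq, circular, fwd_allowed, rev_allowed,
                            Lf, Lr, anchor, lo, hi, max_mm) {
  n <- nchar(seq)
  scan <- if (circular) paste0(seq, seq) else seq
  code <- .encode_dna(scan)
  f_anchor <- if (anchor > 0L) (Lf - anchor + 1L):Lf else integer(0)
  ## the reverse primer's 3' end maps to the first columns of its
  ## reverse-complemented annealing window
  r_anchor <- if (anchor > 0L) seq_len(anchor) else integer(0)
  F <- .scan_sites(code, fwd_allowed, f_anchor, max_mm)
  keepF <- F$pos <= n
  F$pos <- F$pos[keepF]; F$mm <- F$mm[keepF]
  if (!length(F$pos)) return(NULL)
  R <- .scan_sites(code, rev_allowed, r_anchor, max_mm)
  if (!length(R$pos)) return(NULL)
  out <- vector("list", length(F$pos))
  for (k in seq_along(F$pos)) {
    f <- F$pos[k]
    ins_start <- f + Lf               # 1-based start of insert
    r_ok <- which(R$pos >= ins_start + lo & R$pos <= ins_start + hi)
    if (!length(r_ok)) next
    r <- R$pos[r_ok]
    plen <- Lf + (r - ins_start) + Lr
    if (circular) {
      ok <- plen <= n
      r <- r[ok]; r_ok <- r_ok[ok]; plen <- plen[ok]
    }
    if (!length(r)) next
    out[[k]] <- data.frame(
      start0 = f - 1L,
      plen = plen,
      fwd_mismatches = F$mm[k],
      rev_mismatches = R$mm[r_ok],
      insert_seq = substring(scan, ins_start, r - 1L),
      insert_len = r - ins_start
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

.empty_hits <- function() {
  data.frame(
    seq_id = character(0), species = character(0),
    product_start = integer(0), product_end = integer(0),
    strand = character(0),
    fwd_mismatches = integer(0), rev_mismatches = integer(0),
    insert_seq = character(0), insert_len = integer(0)
  )
}

#' In silico PCR over a reference database
#'
#' Finds every site where the forward primer anneals to one strand and the
#' reverse primer (as its reverse complement) anneals to the opposite
#' strand facing it, subject to the matching policy, producing an insert
#' whose length falls within `expected_len * (1 +/- length_window)`. Both
#' product orientations are searched; circular templates are scanned across
#' the origin; a template may yield several hits.
#'
#' @param db a [reference_db()].
#' @param pair a [primer_pair()].
#' @param policy a [match_policy()].
#' @return data.frame of hits (class `amplicon_hits`) with columns
#'   `seq_id`, `species`, `product_start`, `product_end` (0-based half-open
#'   forward-strand coordinates; `product_end` may exceed the template
#'   length for wrap-around products), `strand`, `fwd_mismatches`,
#'   `rev_mismatches`, `insert_seq` (read 5'->3' on the product strand) and
#'   `insert_len`.
#' @export
amplify <- function(db, pair, policy = match_policy()) {
  stopifnot(inherits(db, "reference_db"), inherits(pair, "primer_pair"),
            inherits(policy, "match_policy"))
  Lf <- nchar(pair$fwd$seq)
  Lr <- nchar(pair$rev$seq)
  if (policy$anchor3_len > min(Lf, Lr)) {
    stop("anchor3_len exceeds a primer length", call. = FALSE)
  }
  if (pair$expected_len <= Lf + Lr) {
    stop("expected_len must exceed the summed primer lengths", call. = FALSE)
  }
  w <- policy$length_window
  if (is.null(w)) {
    lo <- 1L
    hi <- .Machine$integer.max %/% 4L
  } else {
    lo <- max(1L, as.integer(ceiling(pair$expected_len * (1 - w))))
    hi <- as.integer(floor(pair$expected_len * (1 + w)))
  }
  mode <- policy$inosine_mode
  fwd_allowed <- .allowed_matrix(pair$fwd$seq, mode)
  rcrev_allowed <- .allowed_matrix(pair$rev$seq, mode,
                                   complement = TRUE, reverse = TRUE)
  recs <- db$records
  hits <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    tpl <- recs$sequence[i]
    n <- nchar(tpl)
    plus <- .amplify_strand(tpl, recs$circular[i], fwd_allowed,
                            rcrev_allowed, Lf, Lr, policy$anchor3_len,
                            lo, hi, policy$max_mismatches)
    minus <- .amplify_strand(.revcomp_dna(tpl), recs$circular[i],
                             fwd_allowed, rcrev_allowed, Lf, Lr,
                             policy$anchor3_len, lo, hi,
                             policy$max_mismatches)
    rows <- list()
    if (!is.null(plus)) {
      rows$p <- data.frame(
        seq_id = recs$seq_id[i], species = recs$species[i],
        product_start = plus$start0,
        product_end = plus$start0 + plus$plen,
        strand = "+",
        fwd_mismatches = plus$fwd_mismatches,
        rev_mismatches = plus$rev_mismatches,
        insert_seq = plus$insert_seq, insert_len = plus$insert_len
      )
    }
    if (!is.null(minus)) {
      ## map reverse-strand coordinates back to the forward strand:
      ## a product spanning [s, e) on the reverse strand occupies
      ## [n - e, n - s) forward; wrap-around starts are reduced modulo n
      fstart <- (n - (minus$start0 + minus$plen)) %% n
      rows$m <- data.frame(
        seq_id = recs$seq_id[i], species = recs$species[i],
        product_start = fstart,
        product_end = fstart + minus$plen,
        strand = "-",
        fwd_mismatches = minus$fwd_mismatches,
        rev_mismatches = minus$rev_mismatches,
        insert_seq = minus$insert_seq, insert_len = minus$insert_len
      )
    }
    if (length(rows)) hits[[i]] <- do.call(rbind, rows)
  }
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  out <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
  rownames(out) <- NULL
  out <- out[order(match(out$seq_id, recs$seq_id), out$strand,
                   out$product_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- pair$name
  class(out) <- c("amplicon_hits", "data.frame")
  out
}

#' Taxonomic coverage of an amplification result
#'
#' \eqn{B_C = |S_A| / |S|}: the fraction of database species with at least
#' one amplified sequence.
#'
#' @param hits result of [amplify()].
#' @param db the [reference_db()] the hits were produced from.
#' @return fraction in `[0, 1]`.
#' @export
taxonomic_coverage <- function(hits, db) {
  stopifnot(inherits(db, "reference_db"))
  n_species <- length(unique(db$records$species))
  if (n_species == 0L) stop("empty database", call. = FALSE)
  length(unique(hits$species)) / n_species
}

#' Turn an amplification result into clustering input
#'
#' One amplicon per hit; amplicon ids are the template `seq_id`s, suffixed
#' with `make.unique()` when a template yields several products.
#'
#' @param hits result of [amplify()].
#' @return data.frame with columns `id`, `species`, `insert_seq`.
#' @export
hits_to_amplicons <- function(hits) {
  data.frame(
    id = make.unique(as.character(hits$seq_id), sep = "#"),
    species = as.character(hits$species),
    insert_seq = as.character(hits$insert_seq)
  )
}

#' Read a primer list from TSV
#'
#' Expects columns `name`, `fwd_seq`, `rev_seq`, `expected_len`.
#'
#' @param path TSV file path.
#' @return list of [primer_pair()] objects, named by pair name.
#' @export
read_primer_list <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  need <- c("name", "fwd_seq", "rev_seq", "expected_len")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("primer list lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pairs <- lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$name[i], tab$fwd_seq[i], tab$rev_seq[i],
                as.integer(tab$expected_len[i]))
  })
  stats::setNames(pairs, tab$name)
}
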