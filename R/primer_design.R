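## Degenerate primer design from a multiple sequence alignment:
## gap-column trimming, windowed Shannon entropy profiling, greedy
## degeneracy-capped consensus construction, and primer pairing by
## amplicon length. The construction is deterministic; no RNG.

.as_alignment <- function(aln) {
  if (inherits(aln, "DNAStringSet") || inherits(aln, "XStringSet")) {
    aln <- as.character(aln)
  }
  if (is.matrix(aln)) {
    aln <- apply(aln, 1L, paste, collapse = "")
  }
  aln <- toupper(unname(as.character(aln)))
  if (!length(aln)) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  chartr(".", "-", aln)
}

.aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

#' Trim gap-rich columns from an alignment
#'
#' Retains exactly the columns whose gap fraction is at most
#' `1 - min_occupancy` (a column with gaps in strictly more than that
#' fraction of rows is removed; a column at the boundary is kept).
#'
#' @param aln alignment: character vector of equal-length rows, a
#'   character matrix, or a `DNAStringSet`. Gap characters are `-`/`.`.
#' @param min_occupancy minimum fraction of rows that must be ungapped for
#'   a column to survive; the conventional setting is 0.9.
#' @return list with `alignment` (character vector of trimmed rows) and
#'   `column_map` (original column index of each retained column).
#' @export
trim_alignment <- function(aln, min_occupancy = 0.9) {
  aln <- .as_alignment(aln)
  stopifnot(min_occupancy > 0, min_occupancy <= 1)
  m <- .aln_char_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= 1 - min_occupancy + 1e-12)
  trimmed <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  list(alignment = trimmed, column_map = keep)
}

#' Windowed entropy profile of an alignment
#'
#' For each window start position the Shannon entropy
#' \eqn{-\sum_i p_i \log_2 p_i} is computed over the frequencies of the
#' unique full-length window strings; rows whose window contains a gap are
#' dropped from that window's frequency table. Entropy is 0 when all
#' (ungapped) windows are identical and at most log2 of the number of
#' rows.
#'
#' @param aln alignment, see [trim_alignment()].
#' @param window_len primer-site window length (default 18).
#' @return data.frame (class `entropy_profile`) with columns `position`,
#'   `entropy` and `n_seqs` (ungapped rows contributing at the position).
#' @export
entropy_profile <- function(aln, window_len = 18L) {
  aln <- .as_alignment(aln)
  window_len <- as.integer(window_len)
  width <- nchar(aln[1L])
  if (window_len > width) {
    stop("window longer than the alignment", call. = FALSE)
  }
  starts <- seq_len(width - window_len + 1L)
  entropy <- numeric(length(starts))
  n_seqs <- integer(length(starts))
  for (k in seq_along(starts)) {
    w <- substring(aln, starts[k], starts[k] + window_len - 1L)
    w <- w[!grepl("-", w, fixed = TRUE)]
    n_seqs[k] <- length(w)
    if (length(w)) {
      p <- tabulate(match(w, unique(w)))
      p <- p / sum(p)
      entropy[k] <- -sum(p * log2(p))
    }
  }
  out <- data.frame(position = starts, entropy = entropy, n_seqs = n_seqs)
  attr(out, "window_len") <- window_len
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Design a degeneracy-capped degenerate primer for one window
#'
#' Degenerate-consensus construction with a deterministic beam: start from
#' the most frequent base in every column, then repeatedly add single
#' bases while the cap permits, keeping the `beam_width` most promising
#' partial primers (most rows matched exactly, then least residual
#' mismatch mass, then lowest degeneracy). A width of 1 is plain greedy;
#' the small default beam lets the search spend degeneracy on base
#' combinations that only pay off jointly across columns. The result is
#' deterministic; rows with a gap (or non-ACGT character) in the window
#' are excluded from the frequency tables and counted as unmatched.
#'
#' @param window the window rows: character vector of equal-length
#'   strings, or a character matrix.
#' @param max_degeneracy degeneracy cap (>= 1); the conventional presets
#'   are 12 ("d12") and 216 ("d216").
#' @param beam_width number of partial primers carried through the search.
#' @return list with `primer` (IUPAC string), `degeneracy`, `coverage`
#'   (fraction of all rows matched exactly) and `matched` (logical per
#'   row).
#' @export
design_degenerate_primer <- function(window, max_degeneracy = 12L,
                                     beam_width = 4L) {
  window <- .as_alignment(window)
  stopifnot(max_degeneracy >= 1, beam_width >= 1)
  L <- nchar(window[1L])
  if (L == 0L) stop("empty window", call. = FALSE)
  n_rows <- length(window)
  M <- do.call(rbind, lapply(strsplit(window, "", fixed = TRUE),
                             match, table = .DNA_BASES))
  eligible <- !apply(M, 1L, anyNA)
  if (!any(eligible)) stop("no ungapped rows in window", call. = FALSE)
  E <- M[eligible, , drop = FALSE]
  ne <- nrow(E)
  counts <- vapply(seq_len(L), function(j) tabulate(E[, j], 4L),
                   integer(4L))                      # 4 x L
  sets0 <- matrix(FALSE, nrow = 4L, ncol = L)
  sets0[cbind(max.col(t(counts), ties.method = "first"), seq_len(L))] <- TRUE
  mk_state <- function(sets) {
    colmis <- matrix(FALSE, nrow = ne, ncol = L)
    for (j in seq_len(L)) colmis[, j] <- !sets[E[, j], j]
    rowmm <- rowSums(colmis)
    list(sets = sets, colmis = colmis, rowmm = rowmm,
         deg = prod(colSums(sets)),
         matched = sum(rowmm == 0L), mass = sum(rowmm),
         key = paste(which(sets), collapse = ","))
  }
  state_better <- function(a, b) {
    if (a$matched != b$matched) return(a$matched > b$matched)
    a$deg < b$deg || (a$deg == b$deg && a$key < b$key)
  }
  beam <- list(mk_state(sets0))
  best <- beam[[1L]]
  seen <- new.env(parent = emptyenv())
  repeat {
    cand <- list()
    for (st in beam) {
      for (j in seq_len(L)) {
        k <- sum(st$sets[, j])
        newdeg <- st$deg / k * (k + 1)
        if (newdeg > max_degeneracy) next
        for (b in which(!st$sets[, j])) {
          hits <- E[, j] == b & st$colmis[, j]
          sec <- sum(hits)                    # rows losing one mismatch
          if (sec == 0L) next
          sets2 <- st$sets
          sets2[b, j] <- TRUE
          key <- paste(which(sets2), collapse = ",")
          if (!is.null(seen[[key]])) next
          assign(key, TRUE, envir = seen)
          s2 <- st
          s2$sets <- sets2
          s2$colmis[hits, j] <- FALSE
          s2$rowmm[hits] <- s2$rowmm[hits] - 1L
          s2$deg <- newdeg
          s2$matched <- st$matched + sum(hits & st$rowmm == 1L)
          s2$mass <- st$mass - sec
          s2$key <- key
          cand[[length(cand) + 1L]] <- s2
        }
      }
    }
    if (!length(cand)) break
    ord <- order(-vapply(cand, `[[`, numeric(1L), "matched"),
                 vapply(cand, `[[`, numeric(1L), "mass"),
                 vapply(cand, `[[`, numeric(1L), "deg"),
                 vapply(cand, `[[`, "", "key"), method = "radix")
    beam <- cand[ord[seq_len(min(beam_width, length(ord)))]]
    for (st in beam) if (state_better(st, best)) best <- st
  }
  primer <- paste(vapply(seq_len(L), function(j) {
    .code_for_set(.DNA_BASES[best$sets[, j]])
  }, ""), collapse = "")
  matched <- logical(n_rows)
  matched[eligible] <- best$rowmm == 0L
  list(primer = primer, degeneracy = best$deg,
       coverage = sum(matched) / n_rows, matched = matched)
}

#' Propose candidate primers over the low-entropy windows of an alignment
#'
#' Window start positions are pre-filtered to the lowest-entropy quantile
#' (to bound the pairing search), then a degenerate consensus primer is
#' designed for each.
#'
#' @param aln alignment, see [trim_alignment()].
#' @param window_len primer length (default 18).
#' @param max_degeneracy degeneracy cap.
#' @param entropy_quantile fraction of lowest-entropy windows retained.
#' @return data.frame (class `primer_candidates`) with columns `position`,
#'   `primer`, `degeneracy`, `entropy`, `coverage`; the per-row match
#'   matrix is attached as attribute `match_matrix` (candidates x rows).
#' @export
propose_primers <- function(aln, window_len = 18L, max_degeneracy = 12L,
                            entropy_quantile = 0.10) {
  aln <- .as_alignment(aln)
  prof <- entropy_profile(aln, window_len)
  prof <- prof[prof$n_seqs > 0L, , drop = FALSE]
  ## rank-based selection: the floor(q * n) lowest-entropy windows (at
  ## least 2 so pairing stays possible), ties broken by position
  k <- max(2L, min(nrow(prof), ceiling(entropy_quantile * nrow(prof))))
  sel <- prof[order(prof$entropy, prof$position)[seq_len(k)], , drop = FALSE]
  sel <- sel[order(sel$position), , drop = FALSE]
  designs <- lapply(sel$position, function(p) {
    design_degenerate_primer(substring(aln, p, p + window_len - 1L),
                             max_degeneracy)
  })
  out <- data.frame(
    position = sel$position,
    primer = vapply(designs, `[[`, "", "primer"),
    degeneracy = vapply(designs, `[[`, numeric(1L), "degeneracy"),
    entropy = sel$entropy,
    coverage = vapply(designs, `[[`, numeric(1L), "coverage")
  )
  attr(out, "match_matrix") <-
    do.call(rbind, lapply(designs, `[[`, "matched"))
  attr(out, "window_len") <- as.integer(window_len)
  class(out) <- c("primer_candidates", "data.frame")
  out
}

#' Pair candidate primers by amplicon length
#'
#' All forward/reverse pairings of the candidates whose ungapped insert
#' length (median across rows) lies in `insert_range`, ranked by predicted
#' joint coverage (rows matched exactly by both windows), ties broken by
#' lower summed entropy. The reverse primer is emitted as the reverse
#' complement of its window consensus, written 5'->3'.
#'
#' @param candidates a [propose_primers()] result.
#' @param insert_range length-2 numeric: allowed insert lengths, e.g.
#'   `c(100, 500)` for metabarcoding-sized fragments.
#' @param aln the alignment the candidates were designed on.
#' @return data.frame (class `designed_pairs`) with columns
#'   `fwd_position`, `rev_position`, `fwd_primer`, `rev_primer`,
#'   `insert_median`, `joint_coverage`, `entropy_sum`, `fwd_degeneracy`,
#'   `rev_degeneracy`, sorted best-first. Empty (with a warning) when no
#'   pairing is feasible.
#' @export
pair_primers <- function(candidates, insert_range, aln) {
  stopifnot(inherits(candidates, "primer_candidates"),
            length(insert_range) == 2L, insert_range[1L] < insert_range[2L])
  aln <- .as_alignment(aln)
  L <- attr(candidates, "window_len")
  mm <- attr(candidates, "match_matrix")
  empty <- data.frame(
    fwd_position = integer(0), rev_position = integer(0),
    fwd_primer = character(0), rev_primer = character(0),
    insert_median = numeric(0), joint_coverage = numeric(0),
    entropy_sum = numeric(0), fwd_degeneracy = numeric(0),
    rev_degeneracy = numeric(0)
  )
  if (nrow(candidates) < 2L) {
    warning("fewer than two candidate windows; no pairing possible")
    class(empty) <- c("designed_pairs", "data.frame")
    return(empty)
  }
  ## cumulative ungapped length per row for O(1) insert lengths
  m <- .aln_char_matrix(aln)
  cum <- t(apply(m != "-", 1L, cumsum))
  n_rows <- nrow(m)
  joint <- tcrossprod(mm * 1L) / n_rows   # candidates x candidates
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_len(nrow(candidates))) {
      pi <- candidates$position[i]
      pj <- candidates$position[j]
      if (pj < pi + L) next               # windows must not overlap
      ins <- cum[, pj - 1L] - cum[, pi + L - 1L]
      med <- median(ins)
      if (med < insert_range[1L] || med > insert_range[2L]) next
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_position = pi, rev_position = pj,
        fwd_primer = candidates$primer[i],
        rev_primer = revcomp_iupac(candidates$primer[j]),
        insert_median = med,
        joint_coverage = joint[i, j],
        entropy_sum = candidates$entropy[i] + candidates$entropy[j],
        fwd_degeneracy = candidates$degeneracy[i],
        rev_degeneracy = candidates$degeneracy[j]
      )
    }
  }
  if (!length(rows)) {
    warning("no feasible primer pairing in the insert range")
    class(empty) <- c("designed_pairs", "data.frame")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$joint_coverage, out$entropy_sum,
                   out$fwd_position, out$rev_position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("designed_pairs", "data.frame")
  out
}

#' Design ranked primer pairs from an alignment
#'
#' Convenience wrapper: optional gap-column trimming, candidate proposal
#' over low-entropy windows, then pairing by insert length.
#'
#' @inheritParams propose_primers
#' @inheritParams pair_primers
#' @param min_occupancy if non-`NULL`, the alignment is first trimmed with
#'   [trim_alignment()].
#' @return a [pair_primers()] result (positions refer to the possibly
#'   trimmed alignment).
#' @export
design_primer_pairs <- function(aln, window_len = 18L, max_degeneracy = 12L,
                                insert_range = c(100L, 500L),
                                entropy_quantile = 0.10,
                                min_occupancy = NULL) {
  aln <- .as_alignment(aln)
  if (!is.null(min_occupancy)) {
    aln <- trim_alignment(aln, min_occupancy)$alignment
  }
  candidates <- propose_primers(aln, window_len, max_degeneracy,
                                entropy_quantile)
  pair_primers(candidates, insert_range, aln)
}
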