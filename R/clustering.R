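## Greedy centroid clustering of amplified insert sequences at a similarity
## threshold, UCLUST-style: inputs are processed in a fixed order
## (descending insert length, ties by lexicographic id); each sequence
## joins the first existing centroid with identity >= threshold, otherwise
## it founds a new cluster. No RNG, no abundance weighting: every amplicon
## is one point.

#' Pairwise identity of two sequences
#'
#' Fraction of identical positions in the optimal global alignment
#' (match +1, mismatch -1, gap -2, end gaps penalized in the score), with
#' terminal gap columns excluded from the denominator. Character equality
#' defines a match, so `N` matches only `N`. Symmetric and in `[0, 1]`.
#'
#' @param a,b non-empty DNA strings.
#' @param details if `TRUE`, also return the alignment score, match count
#'   and denominator columns.
#' @return identity fraction, or a list when `details = TRUE`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")  # 0.875
#' @export
pairwise_identity <- function(a, b, details = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  res <- pairwise_identity_cpp(toupper(a), toupper(b))
  if (details) res else res$identity
}

#' Pairwise identity matrix
#'
#' @param seqs character vector of non-empty sequences.
#' @return symmetric numeric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(seqs) {
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  identity_matrix_cpp(toupper(seqs))
}

.as_amplicons <- function(amplicons) {
  if (inherits(amplicons, "amplicon_hits")) {
    amplicons <- hits_to_amplicons(amplicons)
  }
  stopifnot(is.data.frame(amplicons),
            all(c("id", "species", "insert_seq") %in% names(amplicons)))
  if (nrow(amplicons) == 0L) stop("no amplicons", call. = FALSE)
  if (anyDuplicated(amplicons$id)) {
    stop("duplicated amplicon ids", call. = FALSE)
  }
  data.frame(id = as.character(amplicons$id),
             species = as.character(amplicons$species),
             insert_seq = toupper(as.character(amplicons$insert_seq)))
}

## deterministic processing order: descending insert length, ties broken by
## lexicographic (C-locale) id
.cluster_order <- function(amplicons) {
  order(-nchar(amplicons$insert_seq), amplicons$id, method = "radix")
}

#' Construct a clustering result
#'
#' Mostly used internally by [greedy_cluster()]; exposed so partitions can
#' also be built directly (e.g. from an external clustering) and fed to
#' [compute_indices()].
#'
#' @param threshold similarity threshold in `(0, 1]`.
#' @param members data.frame with columns `id`, `species`, `cluster`
#'   (integer cluster index in founding order) and `centroid_id`.
#' @return object of class `clustering_result`.
#' @export
clustering_result <- function(threshold, members) {
  stopifnot(is.data.frame(members),
            all(c("id", "species", "cluster", "centroid_id") %in%
                  names(members)))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(members$id)) {
    stop("clusters must partition the amplicons (duplicated id)",
         call. = FALSE)
  }
  members$cluster <- as.integer(members$cluster)
  structure(
    list(threshold = threshold,
         members = members,
         n_clusters = length(unique(members$cluster))),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> threshold %.2f: %d amplicons in %d clusters\n",
              x$threshold, nrow(x$members), x$n_clusters))
  invisible(x)
}

#' Greedy centroid clustering at one similarity threshold
#'
#' @param amplicons data.frame with columns `id`, `species`, `insert_seq`
#'   (or an `amplicon_hits` object from [amplify()]).
#' @param threshold similarity threshold in `(0, 1]`.
#' @param .identity optional precomputed identity matrix over the
#'   amplicons in processing order (used by [threshold_sweep()]).
#' @return a [clustering_result()].
#' @export
greedy_cluster <- function(amplicons, threshold, .identity = NULL) {
  amplicons <- .as_amplicons(amplicons)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  ord <- .cluster_order(amplicons)
  amplicons <- amplicons[ord, , drop = FALSE]
  n <- nrow(amplicons)
  seqs <- amplicons$insert_seq
  assign <- integer(n)
  centroids <- integer(0)           # row indices of founding sequences
  for (i in seq_len(n)) {
    hit <- NA_integer_
    if (length(centroids)) {
      ids <- if (is.null(.identity)) {
        identity_to_refs_cpp(seqs[i], seqs[centroids])
      } else {
        .identity[i, centroids]
      }
      hit <- which(ids >= threshold)[1L]
    }
    if (is.na(hit)) {
      centroids <- c(centroids, i)
      assign[i] <- length(centroids)
    } else {
      assign[i] <- hit
    }
  }
  members <- data.frame(
    id = amplicons$id,
    species = amplicons$species,
    cluster = assign,
    centroid_id = amplicons$id[centroids[assign]]
  )
  clustering_result(threshold, members)
}

#' Cluster across a range of similarity thresholds
#'
#' The identity matrix is computed once and reused, so a sweep costs little
#' more than a single clustering.
#'
#' @param amplicons see [greedy_cluster()].
#' @param thresholds strictly increasing thresholds in `(0, 1]`; the
#'   conventional evaluation range is `seq(0.95, 1, 0.01)`.
#' @return named list of [clustering_result()]s, one per threshold.
#' @export
threshold_sweep <- function(amplicons, thresholds = seq(0.95, 1, 0.01)) {
  if (!length(thresholds)) stop("no thresholds", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be sorted and distinct", call. = FALSE)
  }
  amplicons <- .as_amplicons(amplicons)
  ord <- .cluster_order(amplicons)
  amplicons <- amplicons[ord, , drop = FALSE]
  idmat <- identity_matrix_cpp(amplicons$insert_seq)
  out <- lapply(thresholds, function(t) {
    greedy_cluster(amplicons, t, .identity = idmat)
  })
  stats::setNames(out, sprintf("%g", thresholds))
}
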