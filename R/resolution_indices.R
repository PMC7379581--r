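## Taxonomic coverage/resolution index family computed from a database, an
## amplification result and a clustering of the amplified inserts.
##
## Species sets (S = all species, S_A = amplified, S_R = species all of
## whose clusters are homogeneously labelled, S_U = species in exactly one,
## homogeneously labelled cluster) and cluster sets (C_U = pure clusters
## whose label occurs in no other cluster, C_M = mixed-label clusters,
## C_N = pure clusters whose label is shared with other clusters) give:
##   B_C  = |S_A|/|S|        taxonomic coverage
##   B_S  = |S_R|/|S_A|      taxonomic resolution
##   B_E  = |S_U|/|S_A|      exclusive taxonomic resolution
##   ETR  = |S_U|/|S|        effective taxonomic resolution (= B_C * B_E)
##   B_E' = |C_U|/|C_A|      cluster-relative exclusive resolution
##
## A species is in S_R only when NONE of its clusters contains sequences of
## another species (the all-pure reading); indices are computed over the
## amplified sequences only.

#' Classify clusters into pure-unique, mixed and pure-shared
#'
#' @param result a [clustering_result()].
#' @return list with integer vectors `C_U`, `C_M`, `C_N` of cluster
#'   indices, and a per-cluster summary data.frame `table`.
#' @export
classify_clusters <- function(result) {
  stopifnot(inherits(result, "clustering_result"))
  m <- result$members
  labs <- split(m$species, m$cluster)
  cl_ids <- as.integer(names(labs))
  n_labels <- vapply(labs, function(x) length(unique(x)), integer(1L))
  single_label <- ifelse(n_labels == 1L,
                         vapply(labs, `[[`, "", 1L), NA_character_)
  ## in how many clusters does each species occur?
  sp_nclust <- vapply(split(m$cluster, m$species),
                      function(x) length(unique(x)), integer(1L))
  cls <- character(length(labs))
  cls[n_labels > 1L] <- "M"
  pure <- n_labels == 1L
  shared <- pure & sp_nclust[single_label] > 1L
  cls[pure & !shared] <- "U"
  cls[shared] <- "N"
  list(
    C_U = cl_ids[cls == "U"],
    C_M = cl_ids[cls == "M"],
    C_N = cl_ids[cls == "N"],
    table = data.frame(
      cluster = cl_ids,
      n_members = lengths(labs),
      n_labels = n_labels,
      label = single_label,
      class = cls
    )
  )
}

#' Compute the marker quality indices for one clustering
#'
#' @param db the [reference_db()] the amplification ran against (defines S).
#' @param hits result of [amplify()], or a data.frame of amplicons with
#'   columns `id`, `species`, `insert_seq` (defines S_A).
#' @param result a [clustering_result()] partitioning exactly those
#'   amplicons.
#' @return object of class `index_report`: the five indices plus the
#'   underlying species sets and cluster partition counts.
#' @export
compute_indices <- function(db, hits, result) {
  stopifnot(inherits(db, "reference_db"),
            inherits(result, "clustering_result"))
  amplicons <- .as_amplicons(hits)
  if (!setequal(amplicons$id, result$members$id)) {
    stop("clustering does not partition the amplicons in `hits`",
         call. = FALSE)
  }
  S <- sort(unique(db$records$species))
  S_A <- sort(unique(amplicons$species))
  if (!length(S_A)) {
    stop("no amplified species: resolution indices are undefined",
         call. = FALSE)
  }
  if (!all(S_A %in% S)) {
    stop("hits contain species absent from the database", call. = FALSE)
  }
  parts <- classify_clusters(result)
  m <- result$members
  labs <- split(m$species, m$cluster)
  pure <- vapply(labs, function(x) length(unique(x)) == 1L, logical(1L))
  sp_clusters <- split(m$cluster, m$species)
  all_pure <- vapply(sp_clusters,
                     function(cl) all(pure[as.character(unique(cl))]),
                     logical(1L))
  n_clust <- vapply(sp_clusters, function(cl) length(unique(cl)),
                    integer(1L))
  S_R <- sort(names(sp_clusters)[all_pure])
  S_U <- sort(names(sp_clusters)[all_pure & n_clust == 1L])
  n_CA <- result$n_clusters
  structure(list(
    threshold = result$threshold,
    B_C = length(S_A) / length(S),
    B_S = length(S_R) / length(S_A),
    B_E = length(S_U) / length(S_A),
    B_E_prime = length(parts$C_U) / n_CA,
    ETR = length(S_U) / length(S),
    sets = list(S = S, S_A = S_A, S_R = S_R, S_U = S_U),
    clusters = list(C_U = parts$C_U, C_M = parts$C_M, C_N = parts$C_N),
    n_clusters = n_CA
  ), class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf(
    paste0("<index_report> threshold %.2f\n",
           "  B_C %.2f | B_S %.2f | B_E %.2f | B_E' %.2f | ETR %.2f\n",
           "  |S| %d  |S_A| %d  |S_U| %d  |C_U| %d  |C_M| %d  |C_N| %d\n"),
    x$threshold, x$B_C, x$B_S, x$B_E, x$B_E_prime, x$ETR,
    length(x$sets$S), length(x$sets$S_A), length(x$sets$S_U),
    length(x$clusters$C_U), length(x$clusters$C_M), length(x$clusters$C_N)
  ))
  invisible(x)
}

#' Locate the barcoding gap in a threshold sweep
#'
#' The barcoding gap is taken as the similarity threshold maximizing the
#' cluster-relative exclusive resolution B_E'; ties break toward the
#' lowest threshold.
#'
#' @param sweep list of [compute_indices()] reports (one per threshold).
#' @return the threshold of the maximizing report.
#' @export
find_barcoding_gap <- function(sweep) {
  if (!length(sweep)) stop("empty sweep", call. = FALSE)
  thresholds <- vapply(sweep, `[[`, numeric(1L), "threshold")
  be <- vapply(sweep, `[[`, numeric(1L), "B_E_prime")
  ord <- order(thresholds)
  thresholds <- thresholds[ord]
  be <- be[ord]
  thresholds[which.max(be)]
}

#' Evaluate one marker end to end
#'
#' Amplifies, clusters across a threshold sweep and computes the index
#' family at every threshold; also locates the barcoding gap.
#'
#' @param db a [reference_db()].
#' @param pair a [primer_pair()].
#' @param policy a [match_policy()].
#' @param thresholds similarity thresholds, see [threshold_sweep()].
#' @return list with elements `hits`, `coverage` (B_C), `reports` (one
#'   [compute_indices()] report per threshold), `gap` (barcoding-gap
#'   threshold) and `gap_report`. When nothing amplifies, `coverage` is 0,
#'   `reports` is empty and `gap` is `NA` (with a warning).
#' @export
evaluate_marker <- function(db, pair, policy = match_policy(),
                            thresholds = seq(0.95, 1, 0.01)) {
  hits <- amplify(db, pair, policy)
  if (nrow(hits) == 0L) {
    warning("primer pair '", pair$name, "' amplifies nothing")
    return(list(hits = hits, coverage = 0, reports = list(),
                gap = NA_real_, gap_report = NULL))
  }
  amplicons <- hits_to_amplicons(hits)
  sweep <- threshold_sweep(amplicons, thresholds)
  reports <- lapply(sweep, function(r) compute_indices(db, amplicons, r))
  gap <- find_barcoding_gap(reports)
  gap_report <- reports[[which.min(abs(vapply(reports, `[[`, numeric(1L),
                                              "threshold") - gap))]]
  list(hits = hits, coverage = taxonomic_coverage(hits, db),
       reports = reports, gap = gap, gap_report = gap_report)
}
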