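## Joint performance of two markers. The independent approach is purely
## set-algebraic on the uniquely resolved species sets of two markers
## evaluated over the same database (each at its own optimal threshold;
## reads of two markers are never merged at the sequence level). The
## residual approach designs a new primer pair over the species the first
## marker failed to amplify and scores the combination.

#' Combine two independently evaluated markers
#'
#' \eqn{ETR_T = |S_U(i) \cup S_U(j)| / |S|} (also called ETR_CS), with the
#' unique contributions \eqn{ETR_U(i) = |S_U(i) \setminus S_U(j)| / |S|}
#' (and symmetrically for j) and the redundant part
#' \eqn{ETR_R = |S_U(i) \cap S_U(j)| / |S|}. The decomposition is additive
#' by construction: \eqn{ETR_T = ETR_U(i) + ETR_U(j) + ETR_R}.
#'
#' @param rep_i,rep_j [compute_indices()] reports for the two markers,
#'   computed over the same database (identical total species set S).
#' @param names length-2 character vector naming the markers.
#' @return object of class `combination_report` with fields `ETR_T`,
#'   `ETR_U_i`, `ETR_U_j`, `ETR_R` and the underlying species sets.
#' @export
combine_independent <- function(rep_i, rep_j, names = c("i", "j")) {
  stopifnot(inherits(rep_i, "index_report"), inherits(rep_j, "index_report"))
  if (!identical(rep_i$sets$S, rep_j$sets$S)) {
    stop("reports were computed over different databases (S differs)",
         call. = FALSE)
  }
  S <- rep_i$sets$S
  U_i <- rep_i$sets$S_U
  U_j <- rep_j$sets$S_U
  structure(list(
    marker_i = names[1L], marker_j = names[2L],
    ETR_T = length(union(U_i, U_j)) / length(S),
    ETR_U_i = length(setdiff(U_i, U_j)) / length(S),
    ETR_U_j = length(setdiff(U_j, U_i)) / length(S),
    ETR_R = length(intersect(U_i, U_j)) / length(S),
    sets = list(S = S, S_U_i = U_i, S_U_j = U_j)
  ), class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf(
    "<combination_report> %s + %s: ETR_T %.2f (U_%s %.2f, U_%s %.2f, R %.2f)\n",
    x$marker_i, x$marker_j, x$ETR_T, x$marker_i, x$ETR_U_i,
    x$marker_j, x$ETR_U_j, x$ETR_R
  ))
  invisible(x)
}

#' Pairwise combination matrix for a set of markers
#'
#' @param reports named list of [compute_indices()] reports over one
#'   database.
#' @return data.frame with one row per unordered marker pair (upper
#'   triangle) and the ETR_T / ETR_U / ETR_R breakdown.
#' @export
combination_matrix <- function(reports) {
  stopifnot(length(reports) >= 2L, !is.null(names(reports)))
  nm <- names(reports)
  rows <- list()
  for (i in seq_len(length(reports) - 1L)) {
    for (j in (i + 1L):length(reports)) {
      cmb <- combine_independent(reports[[i]], reports[[j]],
                                 names = c(nm[i], nm[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        marker_i = nm[i], marker_j = nm[j],
        ETR_T = cmb$ETR_T, ETR_U_i = cmb$ETR_U_i,
        ETR_U_j = cmb$ETR_U_j, ETR_R = cmb$ETR_R
      )
    }
  }
  do.call(rbind, rows)
}

#' Residual marker design
#'
#' Designs a complementary primer pair over only the species the first
#' marker failed to amplify ("unable to detect" = not amplified,
#' S \\ S_A), evaluates the new pair on the full database, and reports
#' \eqn{ETR_{CR} = |S_U(first) \cup S_U(new)| / |S|}.
#'
#' The residual sequences must be alignable as-is (equal lengths); the
#' design runs on them ungapped.
#'
#' @param db a [reference_db()].
#' @param first [compute_indices()] report of the first marker over `db`.
#' @param design_params list overriding any of: `window_len` (18),
#'   `max_degeneracy` (12), `insert_range` (`c(100, 500)`),
#'   `entropy_quantile` (0.10), `policy` (`match_policy()`), `threshold`
#'   (the first marker's threshold).
#' @return object of class `residual_report` with the residual species
#'   set, the designed pair (`NULL` when the residual is empty or design
#'   fails), the new pair's index report and `ETR_CR`.
#' @export
residual_design <- function(db, first, design_params = list()) {
  stopifnot(inherits(db, "reference_db"), inherits(first, "index_report"))
  if (!identical(first$sets$S, sort(unique(db$records$species)))) {
    stop("report was not computed over this database", call. = FALSE)
  }
  p <- utils::modifyList(
    list(window_len = 18L, max_degeneracy = 12L,
         insert_range = c(100L, 500L), entropy_quantile = 0.10,
         policy = match_policy(), threshold = first$threshold),
    design_params
  )
  residual_species <- setdiff(first$sets$S, first$sets$S_A)
  base <- list(residual_species = residual_species, new_pair = NULL,
               new_report = NULL, ETR_CR = first$ETR)
  if (!length(residual_species)) {
    return(structure(base, class = "residual_report"))
  }
  res_seqs <- db$records$sequence[db$records$species %in% residual_species]
  if (length(unique(nchar(res_seqs))) != 1L) {
    stop("residual sequences are not aligned (unequal lengths)",
         call. = FALSE)
  }
  pairs <- design_primer_pairs(
    res_seqs, window_len = p$window_len, max_degeneracy = p$max_degeneracy,
    insert_range = p$insert_range, entropy_quantile = p$entropy_quantile
  )
  if (nrow(pairs) == 0L) {
    warning("no feasible primer pair over the residual set")
    return(structure(base, class = "residual_report"))
  }
  new_pair <- primer_pair("residual", pairs$fwd_primer[1L],
                          pairs$rev_primer[1L],
                          round(pairs$insert_median[1L]))
  hits <- amplify(db, new_pair, p$policy)
  if (nrow(hits) == 0L) {
    warning("residual-designed pair amplifies nothing on the full database")
    base$new_pair <- new_pair
    return(structure(base, class = "residual_report"))
  }
  amplicons <- hits_to_amplicons(hits)
  clus <- greedy_cluster(amplicons, p$threshold)
  new_report <- compute_indices(db, amplicons, clus)
  structure(list(
    residual_species = residual_species,
    new_pair = new_pair,
    new_report = new_report,
    ETR_CR = length(union(first$sets$S_U, new_report$sets$S_U)) /
      length(first$sets$S)
  ), class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf(
    "<residual_report> %d residual species; %s; ETR_CR %.2f\n",
    length(x$residual_species),
    if (is.null(x$new_pair)) "no new pair" else
      paste0("new pair ", x$new_pair$fwd$seq, " / ", x$new_pair$rev$seq),
    x$ETR_CR
  ))
  invisible(x)
}
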