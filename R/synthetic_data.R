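## Synthetic reference databases with known ground truth. A root genome is
## mutated down a rank tree (order -> family -> genus -> species ->
## haplotype) at per-rank substitution rates; two conserved primer sites
## are planted into every sequence and degraded independently per copy;
## species labels can be scrambled within genera to emulate annotation
## errors. Substitutions only (no indels), so identity arithmetic in
## downstream tests is closed-form and equal-length sequences double as an
## alignment.

.DEFAULT_FWD_SITE <- "GGATTCGGAAACTGACTA"
.DEFAULT_REV_SITE <- "CTACTACGTGGCAATCAC"

#' Simulation configuration
#'
#' Defaults give the package's standard validation fixture: 300 species
#' (5 orders x 3 families x 4 genera x 5 species) of 2 kb circular
#' genomes, a 130 bp marker flanked by two perfectly conserved planted
#' 18-mers degraded in 1% of copies, ~1% intraspecific and ~5%
#' interspecific (congeneric) pairwise divergence, and no label noise.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   counts per rank.
#' @param haplotype_probs probabilities of a species carrying 1, 2, ...
#'   sequences; the default (0.7/0.2/0.1) emulates databases dominated by
#'   singletons with a minority of multi-sequence species.
#' @param genome_length genome length in bases.
#' @param rate_order,rate_family,rate_genus per-branch substitution rates
#'   down the rank tree.
#' @param intraspecific_divergence expected pairwise divergence between
#'   conspecific haplotypes; each haplotype mutates from its species
#'   sequence at half this rate. Must be smaller than
#'   `interspecific_divergence` (the premise of a barcoding gap).
#' @param interspecific_divergence expected pairwise divergence between
#'   congeneric species.
#' @param planted_sites data.frame with columns `position`, `template`,
#'   `mut_prob`; defaults to two 18-mers flanking a 130 bp insert. Sites
#'   are protected from tree mutations; with probability `mut_prob` a
#'   site copy receives one random substitution.
#' @param site_mutation_prob per-copy degradation probability used for the
#'   default sites.
#' @param mislabel_rate fraction of sequences whose species label is
#'   swapped within the genus (around 10% in public insect mitogenome
#'   annotations).
#' @param circular are the genomes circular?
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_orders = 5L, families_per_order = 3L,
                       genera_per_family = 4L, species_per_genus = 5L,
                       haplotype_probs = c(0.7, 0.2, 0.1),
                       genome_length = 2000L,
                       rate_order = 0.12, rate_family = 0.06,
                       rate_genus = 0.04,
                       intraspecific_divergence = 0.01,
                       interspecific_divergence = 0.05,
                       planted_sites = NULL,
                       site_mutation_prob = 0.01,
                       mislabel_rate = 0,
                       circular = TRUE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  counts <- c(n_orders, families_per_order, genera_per_family,
              species_per_genus)
  if (any(counts < 1L)) stop("rank counts must be >= 1", call. = FALSE)
  rates <- c(rate_order, rate_family, rate_genus,
             intraspecific_divergence, interspecific_divergence,
             site_mutation_prob, mislabel_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("rates and divergences must lie in [0, 1)", call. = FALSE)
  }
  if (intraspecific_divergence >= interspecific_divergence) {
    stop("intraspecific divergence must be below interspecific divergence",
         call. = FALSE)
  }
  if (is.null(planted_sites)) {
    planted_sites <- data.frame(
      position = c(401L, 401L + 18L + 130L),
      template = c(.DEFAULT_FWD_SITE, .DEFAULT_REV_SITE),
      mut_prob = site_mutation_prob
    )
  }
  stopifnot(is.data.frame(planted_sites),
            all(c("position", "template", "mut_prob") %in%
                  names(planted_sites)))
  if (any(planted_sites$position + nchar(planted_sites$template) - 1L >
            genome_length)) {
    stop("planted site extends past the genome end", call. = FALSE)
  }
  structure(list(
    n_orders = as.integer(n_orders),
    families_per_order = as.integer(families_per_order),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    haplotype_probs = haplotype_probs / sum(haplotype_probs),
    genome_length = as.integer(genome_length),
    rate_order = rate_order, rate_family = rate_family,
    rate_genus = rate_genus,
    intraspecific_divergence = intraspecific_divergence,
    interspecific_divergence = interspecific_divergence,
    planted_sites = planted_sites,
    mislabel_rate = mislabel_rate,
    circular = isTRUE(circular),
    seed = as.integer(seed)
  ), class = "sim_config")
}

## substitute each position independently with probability `rate`,
## always to a different base (codes 1..4)
.mutate_codes <- function(codes, rate) {
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + shift) %% 4L) + 1L
  }
  codes
}

#' Simulate a reference database with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `db` (a [reference_db()]) and `truth`: the planted
#'   sites, the planted marker's [primer_pair()] (`expected_len` = the
#'   planted insert length), the expected amplifiable species set (both
#'   site copies intact in at least one haplotype), per-sequence site
#'   intactness, the lineage table and any mislabelled ids. Deterministic
#'   given `cfg$seed`.
#' @export
simulate_reference_db <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  glen <- cfg$genome_length
  sites <- cfg$planted_sites
  site_codes <- lapply(sites$template,
                       function(s) match(.seq_chars(s), .DNA_BASES))
  site_idx <- lapply(seq_len(nrow(sites)), function(k) {
    sites$position[k]:(sites$position[k] + nchar(sites$template[k]) - 1L)
  })
  root <- sample.int(4L, glen, replace = TRUE)
  recs <- list()
  intact <- list()
  for (o in seq_len(cfg$n_orders)) {
    o_seq <- .mutate_codes(root, cfg$rate_order)
    o_name <- sprintf("Order%02d", o)
    for (f in seq_len(cfg$families_per_order)) {
      f_seq <- .mutate_codes(o_seq, cfg$rate_family)
      f_name <- sprintf("%s_Fam%02d", o_name, f)
      for (g in seq_len(cfg$genera_per_family)) {
        g_seq <- .mutate_codes(f_seq, cfg$rate_genus)
        g_name <- sprintf("%s_Gen%02d", f_name, g)
        for (s in seq_len(cfg$species_per_genus)) {
          s_seq <- .mutate_codes(g_seq, cfg$interspecific_divergence / 2)
          s_name <- sprintf("%s_sp%02d", g_name, s)
          n_hap <- sample.int(length(cfg$haplotype_probs), 1L,
                              prob = cfg$haplotype_probs)
          for (h in seq_len(n_hap)) {
            hap <- .mutate_codes(s_seq, cfg$intraspecific_divergence / 2)
            ok <- logical(nrow(sites))
            for (k in seq_len(nrow(sites))) {
              hap[site_idx[[k]]] <- site_codes[[k]]
              if (stats::runif(1L) < sites$mut_prob[k]) {
                pos <- site_idx[[k]][sample.int(length(site_idx[[k]]), 1L)]
                hap[pos] <- ((hap[pos] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
              } else {
                ok[k] <- TRUE
              }
            }
            recs[[length(recs) + 1L]] <- data.frame(
              seq_id = sprintf("%s_h%02d", s_name, h),
              species = s_name, genus = g_name, family = f_name,
              order = o_name, circular = cfg$circular,
              sequence = paste(.DNA_BASES[hap], collapse = "")
            )
            intact[[length(intact) + 1L]] <- all(ok)
          }
        }
      }
    }
  }
  records <- do.call(rbind, recs)
  intact <- unlist(intact)
  mislabelled <- character(0)
  if (cfg$mislabel_rate > 0) {
    swapped <- .inject_core(records, cfg$mislabel_rate)
    records <- swapped$records
    mislabelled <- swapped$altered
  }
  insert_len <- sites$position[2L] -
    (sites$position[1L] + nchar(sites$template[1L]))
  truth <- list(
    sites = sites,
    primer_pair = primer_pair("planted", sites$template[1L],
                              revcomp_iupac(sites$template[2L]),
                              insert_len),
    sites_intact = stats::setNames(intact, records$seq_id),
    expected_species = sort(unique(records$species[intact])),
    lineage = unique(records[, c("species", "genus", "family", "order")]),
    mislabelled = mislabelled
  )
  list(db = reference_db(records), truth = truth)
}

.inject_core <- function(records, rate) {
  n <- nrow(records)
  k <- floor(rate * n)
  sp_per_genus <- tapply(records$species, records$genus,
                         function(x) length(unique(x)))
  eligible <- which(sp_per_genus[records$genus] >= 2L)
  if (k > length(eligible)) {
    stop("not enough sequences in multi-species genera to mislabel ",
         k, " records", call. = FALSE)
  }
  altered <- character(0)
  if (k > 0L) {
    pick <- sort(sample(eligible, k))
    for (i in pick) {
      others <- setdiff(unique(
        records$species[records$genus == records$genus[i]]
      ), records$species[i])
      records$species[i] <- others[sample.int(length(others), 1L)]
    }
    altered <- records$seq_id[pick]
  }
  list(records = records, altered = altered)
}

#' Inject species-label noise into a database
#'
#' Relabels `floor(rate * N)` sequences with the species label of a random
#' congener, emulating the ~10% annotation disagreement observed between
#' public repositories.
#'
#' @param db a [reference_db()].
#' @param rate mislabelling rate in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `db` (relabelled database) and `altered` (ids of the
#'   relabelled sequences).
#' @export
inject_mislabels <- function(db, rate, seed) {
  stopifnot(inherits(db, "reference_db"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  sp_per_genus <- tapply(db$records$species, db$records$genus,
                         function(x) length(unique(x)))
  if (!any(sp_per_genus >= 2L)) {
    stop("no genus with >= 2 species; nothing to mislabel into",
         call. = FALSE)
  }
  set.seed(seed)
  swapped <- .inject_core(db$records, rate)
  list(db = reference_db(swapped$records), altered = swapped$altered)
}
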