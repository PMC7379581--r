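# Shared fixture builders. All fixtures are generated in code; no files.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# overwrite part of a sequence string (1-based)
plant <- function(seq, pos, site) {
  substr(seq, pos, pos + nchar(site) - 1L) <- site
  seq
}

mutate_string <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(BASES, ch[p])[1L]
  paste(ch, collapse = "")
}

# quick single-order database from named sequences
quick_db <- function(seqs, species = names(seqs), genus = "GenA",
                     family = "FamA", order = "OrdA", circular = FALSE) {
  reference_db(data.frame(
    seq_id = names(seqs), species = species, genus = genus,
    family = family, order = order, circular = circular,
    sequence = unname(unlist(seqs))
  ))
}

# small taxonomically structured database for subsetting tests
mixed_order_db <- function() {
  reference_db(data.frame(
    seq_id = paste0("s", 1:5),
    species = c("Aedes aegypti", "Aedes aegypti", "Apis mellifera",
                "Apis mellifera", "Vespa crabro"),
    genus = c("Aedes", "Aedes", "Apis", "Apis", "Vespa"),
    family = c("Culicidae", "Culicidae", "Apidae", "Apidae", "Vespidae"),
    order = c("Diptera", "Diptera", "Hymenoptera", "Hymenoptera",
              "Hymenoptera"),
    circular = FALSE,
    sequence = replicate(5, random_dna(60))
  ))
}

# build a clustering_result directly from a list of clusters, each a named
# character vector of species labels (names = amplicon ids)
partition_result <- function(threshold, clusters) {
  members <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    data.frame(id = names(clusters[[k]]),
               species = unname(clusters[[k]]),
               cluster = k,
               centroid_id = names(clusters[[k]])[1L])
  }))
  clustering_result(threshold, members)
}

# amplicon table matching a partition_result (dummy inserts)
partition_amplicons <- function(clusters) {
  ids <- unlist(lapply(clusters, names))
  sp <- unlist(lapply(clusters, unname))
  data.frame(id = ids, species = sp,
             insert_seq = strrep("ACGT", 5L))
}

# db containing one dummy record per species label
species_only_db <- function(species) {
  species <- unique(species)
  reference_db(data.frame(
    seq_id = paste0("ref_", seq_along(species)),
    species = species, genus = "G", family = "F", order = "O",
    circular = FALSE, sequence = strrep("ACGT", 5L)
  ))
}
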