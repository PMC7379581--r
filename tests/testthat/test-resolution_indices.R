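test_that("clusters are classified into pure-unique, mixed and shared", {
  ## {A,A}, {B}, {B}, {C}: the two B clusters share a label
  res <- partition_result(0.97, list(
    c(a1 = "A", a2 = "A"), c(b1 = "B"), c(b2 = "B"), c(c1 = "C")
  ))
  parts <- classify_clusters(res)
  expect_equal(length(parts$C_U), 2L)
  expect_equal(length(parts$C_M), 0L)
  expect_equal(length(parts$C_N), 2L)

  mixed <- classify_clusters(partition_result(0.97,
                                              list(c(a = "A", b = "B"))))
  expect_equal(lengths(mixed[c("C_U", "C_M", "C_N")]),
               c(C_U = 0L, C_M = 1L, C_N = 0L))

  ## every species in one pure cluster: C_A = C_U
  pure <- classify_clusters(partition_result(0.97, list(
    c(a = "A"), c(b = "B"), c(c = "C")
  )))
  expect_equal(length(pure$C_U), 3L)
  expect_equal(length(pure$C_M) + length(pure$C_N), 0L)

  ## a pure cluster whose label also sits inside a mixed cluster is shared
  tangled <- classify_clusters(partition_result(0.97, list(
    c(a1 = "A"), c(a2 = "A", b = "B")
  )))
  expect_equal(lengths(tangled[c("C_U", "C_M", "C_N")]),
               c(C_U = 0L, C_M = 1L, C_N = 1L))
})

test_that("compute_indices reproduces hand-enumerated toy values", {
  clusters <- list(c(a1 = "A", a2 = "A"), c(b1 = "B"), c(b2 = "B"),
                   c(c1 = "C"))
  amp <- partition_amplicons(clusters)
  db <- species_only_db(c("A", "B", "C", "D", "E"))
  rep <- compute_indices(db, amp, partition_result(0.97, clusters))
  expect_equal(rep$B_C, 3 / 5)
  expect_equal(rep$B_S, 1.0)           # all clusters pure
  expect_equal(rep$B_E, 2 / 3)         # B split across two clusters
  expect_equal(rep$B_E_prime, 2 / 4)
  expect_equal(rep$ETR, 2 / 5)
  expect_lte(rep$B_E, rep$B_S)

  ## identity case: everything amplified, one pure cluster per species
  ident <- list(c(a = "A"), c(b = "B"), c(c = "C"))
  repi <- compute_indices(species_only_db(c("A", "B", "C")),
                          partition_amplicons(ident),
                          partition_result(0.99, ident))
  for (f in c("B_C", "B_S", "B_E", "B_E_prime", "ETR")) {
    expect_equal(repi[[f]], 1.0, label = f)
  }

  ## no amplified species is an error, distinct from B_C = 0 reporting
  expect_error(
    compute_indices(db, amp[0, ], partition_result(0.97, clusters)),
    "amplicons"
  )
})

test_that("index identities hold exactly on random partitions", {
  set.seed(31)
  for (rep in 1:60) {
    species <- paste0("sp", 1:sample(4:10, 1))
    n <- sample(8:25, 1)
    amp_sp <- sample(species, n, replace = TRUE)
    clusters <- split(
      setNames(amp_sp, sprintf("a%02d", 1:n)),
      sample(seq_len(sample(2:8, 1)), n, replace = TRUE)
    )
    clusters <- clusters[lengths(clusters) > 0]
    db <- species_only_db(c(species, "ghost1", "ghost2"))
    res <- partition_result(0.97, clusters)
    r <- compute_indices(db, partition_amplicons(clusters), res)
    S <- r$sets$S; S_A <- r$sets$S_A; S_R <- r$sets$S_R; S_U <- r$sets$S_U
    ## set chain
    expect_true(all(S_U %in% S_R))
    expect_true(all(S_R %in% S_A))
    expect_true(all(S_A %in% S))
    ## |C_U| = |S_U| and the five formulas
    expect_equal(length(r$clusters$C_U), length(S_U))
    expect_equal(r$B_C, length(S_A) / length(S))
    expect_equal(r$B_S, length(S_R) / length(S_A))
    expect_equal(r$B_E, length(S_U) / length(S_A))
    expect_equal(r$ETR, length(S_U) / length(S))
    expect_equal(r$ETR, r$B_C * r$B_E, tolerance = 1e-12)
    expect_equal(r$B_E_prime,
                 length(r$clusters$C_U) / r$n_clusters)
    expect_equal(length(r$clusters$C_U) + length(r$clusters$C_M) +
                   length(r$clusters$C_N), r$n_clusters)
    ## independent brute-force recomputation of S_R / S_U from raw labels
    lab <- lapply(clusters, unname)
    brute_SR <- Filter(function(sp) {
      all(vapply(lab, function(l) !(sp %in% l) || all(l == sp), TRUE))
    }, unique(amp_sp))
    brute_SU <- Filter(function(sp) {
      sum(vapply(lab, function(l) sp %in% l, TRUE)) == 1
    }, brute_SR)
    expect_setequal(S_R, brute_SR)
    expect_setequal(S_U, brute_SU)
  }
})

test_that("one-sequence-per-species databases give B_E = B_S", {
  set.seed(32)
  for (rep in 1:20) {
    species <- paste0("sp", 1:sample(5:12, 1))
    clusters <- split(setNames(species, paste0("a_", species)),
                      sample(seq_len(sample(2:6, 1)), length(species),
                             replace = TRUE))
    clusters <- clusters[lengths(clusters) > 0]
    r <- compute_indices(species_only_db(species),
                         partition_amplicons(clusters),
                         partition_result(0.97, clusters))
    expect_equal(r$B_E, r$B_S)
  }
})

test_that("species-refining clusterings keep B_E' at or below B_E", {
  ## when every cluster is label-pure (splitting only), |C_A| >= |S_A|
  set.seed(33)
  for (rep in 1:20) {
    species <- paste0("sp", 1:sample(4:8, 1))
    clusters <- list()
    for (sp in species) {
      n_seq <- sample(1:4, 1)
      groups <- split(
        setNames(rep(sp, n_seq), paste0(sp, "_", seq_len(n_seq))),
        sample(seq_len(sample(1:n_seq, 1)), n_seq, replace = TRUE)
      )
      clusters <- c(clusters, groups[lengths(groups) > 0])
    }
    r <- compute_indices(species_only_db(species),
                         partition_amplicons(clusters),
                         partition_result(0.99, clusters))
    expect_equal(r$B_S, 1.0)
    expect_lte(r$B_E_prime, r$B_E + 1e-12)
  }
})

test_that("find_barcoding_gap takes the argmax with low-threshold ties", {
  mk <- function(t, bep) {
    structure(list(threshold = t, B_E_prime = bep), class = "index_report")
  }
  sweep <- list(mk(0.96, 0.5), mk(0.97, 0.7), mk(0.98, 0.9), mk(0.99, 0.8))
  expect_equal(find_barcoding_gap(sweep), 0.98)
  flat <- list(mk(0.95, 0.6), mk(0.96, 0.6), mk(0.97, 0.6))
  expect_equal(find_barcoding_gap(flat), 0.95)
  expect_error(find_barcoding_gap(list()), "empty")
})

test_that("the barcoding gap is recovered on simulated divergence", {
  fwd <- "GGATTCGGAAACTGACTA"; rev <- "CTACTACGTGGCAATCAC"
  for (seed in c(101, 102)) {
    cfg <- sim_config(n_orders = 2, families_per_order = 2,
                      genera_per_family = 2, species_per_genus = 3,
                      genome_length = 800,
                      planted_sites = data.frame(
                        position = c(101L, 249L),
                        template = c(fwd, rev), mut_prob = 0.01),
                      seed = seed)
    sim <- simulate_reference_db(cfg)
    ev <- evaluate_marker(sim$db, sim$truth$primer_pair)
    expect_gt(ev$gap, 0.95)
    expect_lte(ev$gap, 0.99)
  }
})
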