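test_that("trimming removes columns with too many gaps, boundary kept", {
  rows <- c("AC-GTA", "ACAGTA", "ACAGT-", rep("ACAGTA", 7))
  ## col 3: 1 gap in 10 rows (10%, kept); col 6: 1 gap (kept)
  tr <- trim_alignment(rows, 0.9)
  expect_equal(tr$column_map, 1:6)
  ## two gaps in one column (20% > 10%) -> removed
  rows2 <- c("AC-GTA", "AC-GTA", rep("ACAGTA", 8))
  tr2 <- trim_alignment(rows2, 0.9)
  expect_equal(tr2$column_map, c(1, 2, 4, 5, 6))
  expect_equal(nchar(tr2$alignment[1]), 5L)
  ## gap-free alignments are unchanged
  rows3 <- rep("ACGTACGT", 4)
  expect_equal(trim_alignment(rows3, 0.9)$alignment, rows3)
  expect_error(trim_alignment(c("ACGT", "ACG"), 0.9), "ragged")
})

test_that("windowed entropy has its closed-form values", {
  expect_equal(entropy_profile(rep("ACGTACGT", 6), 4)$entropy,
               rep(0, 5))
  two <- c("AAAA", "AAAA", "TTTT", "TTTT")
  expect_equal(entropy_profile(two, 4)$entropy, 1.0)
  four <- c("AAAA", "CCCC", "GGGG", "TTTT")
  expect_equal(entropy_profile(four, 4)$entropy, 2.0)
  ## row order invariance and the log2(n) bound
  set.seed(61)
  aln <- vapply(1:8, function(i) random_dna(30), "")
  p1 <- entropy_profile(aln, 10)
  p2 <- entropy_profile(rev(aln), 10)
  expect_equal(p1$entropy, p2$entropy)
  expect_true(all(p1$entropy >= 0 & p1$entropy <= log2(8) + 1e-12))
  ## gapped rows are dropped from the window's table
  gappy <- c("AA-A", "AAAA", "AATA")
  expect_equal(entropy_profile(gappy, 4)$entropy, 1.0)
  expect_equal(entropy_profile(gappy, 4)$n_seqs, 2L)
  expect_error(entropy_profile(c("ACGT"), 5), "window")
})

test_that("degenerate consensus construction honours cap and forced cases", {
  inv <- rep("ACGTACGTACG", 5)
  d <- design_degenerate_primer(inv, 12)
  expect_equal(d$primer, "ACGTACGTACG")
  expect_equal(d$degeneracy, 1)
  expect_equal(d$coverage, 1.0)
  ## a 50/50 A/G column becomes R when the cap allows
  split_col <- c(rep("AACGTACGTA", 3), rep("AGCGTACGTA", 3))
  d2 <- design_degenerate_primer(split_col, 2)
  expect_equal(d2$primer, "ARCGTACGTA")
  expect_equal(d2$coverage, 1.0)
  d1 <- design_degenerate_primer(split_col, 1)
  expect_equal(d1$degeneracy, 1)
  expect_equal(d1$coverage, 0.5)
  expect_error(design_degenerate_primer(character(0), 2), "empty")
})

test_that("greedy construction is near the exhaustive optimum", {
  set.seed(62)
  n_equal <- 0
  n_cases <- 60
  for (i in seq_len(n_cases)) {
    ## 6-column windows, each column drawing from <= 3 distinct bases
    nrows <- sample(8:16, 1)
    cols <- lapply(1:6, function(j) {
      pool <- sample(BASES, sample(1:3, 1))
      sample(pool, nrows, replace = TRUE)
    })
    window <- apply(do.call(cbind, cols), 1, paste, collapse = "")
    cap <- sample(c(2, 4, 8), 1)
    greedy <- design_degenerate_primer(window, cap)
    expect_lte(greedy$degeneracy, cap)
    optimum <- exhaustive_best_coverage(window, cap)
    expect_lte(greedy$coverage, optimum + 1e-12)
    if (abs(greedy$coverage - optimum) < 1e-12) n_equal <- n_equal + 1
  }
  ## the greedy heuristic should hit the optimum in the vast majority
  expect_gte(n_equal / n_cases, 0.9)
})

test_that("coverage never decreases when the cap is raised", {
  set.seed(63)
  for (i in 1:20) {
    window <- vapply(1:10, function(j) random_dna(8), "")
    cov <- vapply(c(1, 2, 4, 12, 216), function(cap) {
      design_degenerate_primer(window, cap)$coverage
    }, numeric(1))
    expect_true(all(diff(cov) >= -1e-12))
  }
})

test_that("pairing respects the insert range and ranks planted sites first", {
  fwd <- "GGATTCGGAAACTGACTA"; rev <- "CTACTACGTGGCAATCAC"
  set.seed(64)
  cfg <- sim_config(n_orders = 2, families_per_order = 2,
                    genera_per_family = 2, species_per_genus = 3,
                    genome_length = 800,
                    planted_sites = data.frame(
                      position = c(101L, 401L),
                      template = c(fwd, rev), mut_prob = 0.005),
                    seed = 65)
  sim <- simulate_reference_db(cfg)
  aln <- sim$db$records$sequence
  pairs <- design_primer_pairs(aln, insert_range = c(100, 500))
  expect_gt(nrow(pairs), 0)
  ## top-ranked pair overlaps both planted sites (insert 282)
  expect_true(pairs$fwd_position[1] >= 84 && pairs$fwd_position[1] <= 118)
  expect_true(pairs$rev_position[1] >= 384 && pairs$rev_position[1] <= 418)
})

test_that("sites too far apart for the insert range yield no pairing", {
  ## only two conserved 18-mers, 582 bp of unique sequence between them:
  ## the insert exceeds the 100-500 bp metabarcoding range
  fwd <- "GGATTCGGAAACTGACTA"; rev <- "CTACTACGTGGCAATCAC"
  set.seed(66)
  aln <- vapply(1:12, function(i) {
    paste0(fwd, random_dna(582), rev)
  }, "")
  expect_warning(
    none <- design_primer_pairs(aln, insert_range = c(100, 500),
                                entropy_quantile = 0.005),
    "no feasible"
  )
  expect_equal(nrow(none), 0L)
})

test_that("all feasible forward/reverse pairings are enumerated", {
  ## 3 conserved windows; pairing is the cartesian product of windows
  ## separated by an in-range insert
  base <- strrep("A", 10)
  row <- paste0("GGATTCGGAA", strrep("C", 30), "TTGACCGAGT",
                strrep("G", 30), "CTACTACGTG")
  aln <- rep(row, 6)
  cands <- propose_primers(aln, window_len = 10, max_degeneracy = 2,
                           entropy_quantile = 1)
  pairs <- pair_primers(cands, insert_range = c(5, 200), aln)
  ## every candidate pair with >= 0 separation and in-range insert appears
  n_cand <- nrow(cands)
  expected <- 0
  for (i in seq_len(n_cand)) {
    for (j in seq_len(n_cand)) {
      pi <- cands$position[i]; pj <- cands$position[j]
      if (pj >= pi + 10 && (pj - pi - 10) >= 5 && (pj - pi - 10) <= 200) {
        expected <- expected + 1
      }
    }
  }
  expect_equal(nrow(pairs), expected)
  ## reverse primers are reverse complements of their window consensus
  k <- which(pairs$fwd_position == 1 & pairs$rev_position == 81)[1]
  expect_equal(pairs$rev_primer[k], revcomp_iupac("CTACTACGTG"))
})
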