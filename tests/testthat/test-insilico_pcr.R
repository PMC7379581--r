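FWD <- "GGATTCGGAAACTGACTA"
REVSITE <- "CTACTACGTGGCAATCAC"   # reverse-primer annealing site (fwd strand)
REV <- revcomp_iupac(REVSITE)

test_that("primer degeneracy is the product of IUPAC multiplicities", {
  expect_equal(primer_degeneracy("ACGTACGTAC"), 1)
  expect_equal(primer_degeneracy("ACTWTGTTACGACTTDTY"), 12)
  expect_equal(primer_degeneracy("HCCHGAYATRGCHTTYCC"), 216)
  ## inosine counts per the active pairing mode
  expect_equal(primer_degeneracy("ACGTIACGTA", "as_N"), 4)
  expect_equal(primer_degeneracy("ACGTIACGTA", "as_H"), 3)
  expect_error(primer_degeneracy("ACGTXACGTA"), "IUPAC")
  ## cross-check against exhaustive expansion enumeration
  for (p in c("ACTWTGTTACGACTTDTY", "HCCHGAYATRGCHTTYCC", "ACGGNRYACT")) {
    expect_equal(primer_degeneracy(p), length(unique(expand_iupac(p))))
  }
})

test_that("iupac_mismatches counts disallowed template bases", {
  expect_equal(iupac_mismatches("ACGT", "ACGT"), 0)
  expect_equal(iupac_mismatches("ACRT", "ACGT"), 0)
  expect_equal(iupac_mismatches("ACRT", "ACCT"), 1)
  expect_equal(iupac_mismatches("ACIT", "ACGT", "as_H"), 1)
  expect_equal(iupac_mismatches("ACIT", "ACGT", "as_N"), 0)
  ## template N never matches, not even N against N
  expect_equal(iupac_mismatches("ACNT", "ACNT"), 1)
  expect_error(iupac_mismatches("ACGT", "ACGTA"), "length")
  ## random windows against the set-lookup oracle
  set.seed(5)
  codes <- c(names(metabarprime:::.IUPAC_SETS), "I")
  for (i in 1:25) {
    p <- paste(sample(codes, 12, replace = TRUE), collapse = "")
    w <- random_dna(12)
    for (mode in c("as_N", "as_H")) {
      expect_equal(iupac_mismatches(p, w, mode),
                   oracle_mismatches(p, w, mode))
    }
  }
})

test_that("amplify finds planted sites with exact coordinates", {
  set.seed(7)
  tpl <- plant(plant(random_dna(500), 101, FWD), 249, REVSITE)
  db <- quick_db(c(t1 = tpl))
  h <- amplify(db, primer_pair("m", FWD, REV, 130))
  expect_equal(nrow(h), 1L)
  expect_equal(h$product_start, 100L)
  expect_equal(h$product_end, 266L)
  expect_equal(h$strand, "+")
  expect_equal(h$fwd_mismatches + h$rev_mismatches, 0L)
  expect_equal(h$insert_seq, substr(tpl, 119, 248))
  expect_equal(h$insert_len, 130L)
})

test_that("origin-straddling products require a circular template", {
  set.seed(8)
  tpl <- random_dna(400)
  tpl <- plant(tpl, 392, substr(FWD, 1, 9))
  tpl <- plant(tpl, 1, substr(FWD, 10, 18))
  tpl <- plant(tpl, 140, REVSITE)
  pp <- primer_pair("m", FWD, REV, 130)
  circ <- quick_db(c(t = tpl), circular = TRUE)
  lin <- quick_db(c(t = tpl), circular = FALSE)
  expect_equal(nrow(amplify(circ, pp)), 1L)
  expect_equal(nrow(amplify(lin, pp)), 0L)
})

test_that("the amplicon length window filters inserts", {
  set.seed(9)
  tpl <- plant(plant(random_dna(600), 101, FWD), 275, REVSITE)  # insert 156
  db <- quick_db(c(t = tpl))
  pp <- primer_pair("m", FWD, REV, 130)                          # 1.2x
  expect_equal(nrow(amplify(db, pp, match_policy(length_window = 0.10))), 0L)
  expect_equal(nrow(amplify(db, pp, match_policy(length_window = 0.25))), 1L)
  expect_error(primer_pair("m", FWD, REV, 30), "expected_len")
})

test_that("hits are monotone in the mismatch budget and inosine mode", {
  set.seed(10)
  for (rep in 1:5) {
    tpl <- random_dna(800)
    tpl <- plant(tpl, 101, mutate_string(FWD, sample(3:15, 1)))
    tpl <- plant(tpl, 249, REVSITE)
    tpl <- plant(tpl, 501, FWD)
    tpl <- plant(tpl, 649, mutate_string(REVSITE, sample(3:15, 2)))
    db <- quick_db(c(t = tpl))
    pp <- primer_pair("m", FWD, REV, 130)
    key <- function(h) paste(h$strand, h$product_start, h$insert_len)
    prev <- character(0)
    for (k in 0:2) {
      h <- amplify(db, pp, match_policy(max_mismatches = k))
      expect_true(all(prev %in% key(h)))
      prev <- key(h)
    }
  }
  ## inosine: as_H accepts a subset of what as_N accepts
  set.seed(11)
  ifwd <- "GGATTCGGAIACTGACTA"
  tpl <- plant(plant(random_dna(500), 101, "GGATTCGGAGACTGACTA"), 249,
               REVSITE)
  db <- quick_db(c(t = tpl))
  pp <- primer_pair("m", ifwd, REV, 130)
  expect_equal(nrow(amplify(db, pp, match_policy(inosine_mode = "as_N"))), 1L)
  expect_equal(nrow(amplify(db, pp, match_policy(inosine_mode = "as_H"))), 0L)
})

test_that("the 3' anchor vetoes sites with terminal mismatches", {
  set.seed(12)
  fwd_mut <- mutate_string(FWD, 18)        # 3'-terminal mismatch
  tpl <- plant(plant(random_dna(500), 101, fwd_mut), 249, REVSITE)
  db <- quick_db(c(t = tpl))
  pp <- primer_pair("m", FWD, REV, 130)
  expect_equal(nrow(amplify(db, pp, match_policy(max_mismatches = 1,
                                                 anchor3_len = 2))), 0L)
  expect_equal(nrow(amplify(db, pp, match_policy(max_mismatches = 1,
                                                 anchor3_len = 0))), 1L)
})

test_that("reverse-complementing every template preserves the hits", {
  set.seed(13)
  seqs <- replicate(4, {
    tpl <- random_dna(700)
    fpos <- sample(50:150, 1)
    tpl <- plant(tpl, fpos, FWD)
    plant(tpl, fpos + 18 + sample(120:140, 1), REVSITE)
  })
  names(seqs) <- paste0("t", 1:4)
  pp <- primer_pair("m", FWD, REV, 130)
  for (circ in c(FALSE, TRUE)) {
    db <- quick_db(seqs, circular = circ)
    rcdb <- db
    rcdb$records$sequence <- vapply(db$records$sequence, oracle_revcomp,
                                    "", USE.NAMES = FALSE)
    h <- amplify(db, pp)
    hrc <- amplify(rcdb, pp)
    expect_equal(nrow(hrc), nrow(h))
    ## the insert read 5'->3' on the product strand does not depend on
    ## the orientation in which the template was stored
    expect_setequal(hrc$insert_seq, h$insert_seq)
    expect_setequal(paste(hrc$strand, hrc$fwd_mismatches,
                          hrc$rev_mismatches),
                    paste(ifelse(h$strand == "+", "-", "+"),
                          h$fwd_mismatches, h$rev_mismatches))
  }
})

test_that("taxonomic coverage counts species, not sequences", {
  set.seed(14)
  tpl_hit <- function() plant(plant(random_dna(500), 101, FWD), 249, REVSITE)
  seqs <- c(a1 = tpl_hit(), a2 = random_dna(500), b1 = tpl_hit(),
            c1 = random_dna(500), d1 = tpl_hit())
  db <- quick_db(seqs, species = c("A", "A", "B", "C", "D"))
  h <- amplify(db, primer_pair("m", FWD, REV, 130))
  expect_equal(taxonomic_coverage(h, db), 3 / 4)
  expect_equal(taxonomic_coverage(h[0, ], db), 0)
})
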