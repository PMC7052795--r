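test_that("digest profiles match independent cut arithmetic and conserve length", {
  withr::with_seed(41, {
    base <- domesticate(rand_dna(5000))$sequence
    # plant two + strand BsaI sites; watson cuts land at s+7
    s1 <- 200; s2 <- 2193
    seqv <- base
    for (s in c(s1, s2))
      seqv <- paste0(substr(seqv, 1, s), "GGTCTC",
                     substr(seqv, s + 7, nchar(seqv)))
    mol <- dna_molecule("p5k", seqv, "circular")
    prof <- digest_profile(mol, bsai())
    cut1 <- s1 + 7; cut2 <- s2 + 7
    expect_equal(prof$lengths,
                 sort(c(cut2 - cut1, nchar(seqv) - (cut2 - cut1)),
                      decreasing = TRUE))
    expect_equal(sum(prof$lengths), seq_length(mol))
    expect_false(prof$uncut)
    # uncut circular molecule: single full-length band, flagged
    clean <- dna_molecule("u", base, "circular")
    pu <- digest_profile(clean, bsai())
    expect_true(pu$uncut)
    expect_equal(pu$lengths, 5000)
  })
})

test_that("simulated products verify against analytic profiles", {
  x <- sim_cached("L2-4_sfGFP")
  root <- x$sim$root
  prof <- digest_profile(root, list(bsai(), sapi()))
  expect_equal(sum(prof$lengths), seq_length(root))
  # expected pattern computed from cut positions, independently
  cuts <- sort(c(scan_sites(root, bsai())$cut_top,
                 scan_sites(root, sapi())$cut_top))
  exp_lens <- sort(diff(c(cuts, cuts[1] + seq_length(root))),
                   decreasing = TRUE)
  expect_true(compare_profile(prof$lengths, exp_lens, 0)$verdict)
  # perturbing one band beyond tolerance flips the verdict
  bad <- exp_lens; bad[1] <- bad[1] + 250
  expect_false(compare_profile(prof$lengths, bad, 100)$verdict)
})

test_that("compare_profile does exact matching within tolerance", {
  expect_true(compare_profile(c(3000, 2000), c(3000, 2000), 0)$verdict)
  expect_true(compare_profile(c(3000, 2000), c(2950, 2050), 100)$verdict)
  expect_false(compare_profile(c(3000, 2000), c(3000), 100)$verdict)
  expect_false(compare_profile(c(3000, 2000), c(2950, 2050), 49)$verdict)
  # a case where greedy pairing fails but exact matching succeeds
  expect_true(compare_profile(c(100, 90), c(95, 86), 10)$verdict)
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- sample(100:5000, sample(2:8, 1))
      b <- a + sample(-60:60, length(a), replace = TRUE)
      tol <- sample(0:100, 1)
      f <- compare_profile(a, b, tol)$verdict
      # symmetry
      expect_identical(f, compare_profile(b, a, tol)$verdict)
      # monotone in tolerance
      if (f) expect_true(compare_profile(a, b, tol + 50)$verdict)
      if (!compare_profile(a, b, tol + 50)$verdict)
        expect_false(f)
    }
  })
})

test_that("in-silico PCR finds the UNS amplicon exactly once", {
  fx <- fx_cached()
  r <- fx$kits$pAN[["pANe-2"]]
  amps <- insilico_pcr(r$molecule, fx$table$uns1,
                       reverse_complement(fx$table$unsx))
  expect_length(amps, 1)
  expect_false(attr(amps, "ambiguous"))
  # coordinate oracle: amplicon spans UNS1 start to UNSX end
  L <- seq_length(r$molecule)
  f <- as.integer(regexpr(fx$table$uns1, r$molecule$sequence, fixed = TRUE)) - 1L
  rjoin <- as.integer(regexpr(fx$table$unsx, r$molecule$sequence, fixed = TRUE)) - 1L
  expect_equal(amps[[1]]$length, rjoin + nchar(fx$table$unsx) - f)
  # the dropout lies inside the amplicon
  expect_true(grepl(loopassembly:::synthetic_lacz(), amps[[1]]$sequence,
                    fixed = TRUE))
  # absent primer
  expect_length(insilico_pcr(r$molecule, strrep("ACGTT", 3),
                             reverse_complement(fx$table$unsx)), 0)
  expect_error(insilico_pcr(r$molecule, "ACGT", "ACGTACGTACGTA"), "12 nt")
  # wrap-aware on a rotated template
  s <- r$molecule$sequence
  rot <- paste0(substr(s, 2001, L), substr(s, 1, 2000))
  amps2 <- insilico_pcr(dna_molecule("rot", rot, "circular"), fx$table$uns1,
                        reverse_complement(fx$table$unsx))
  expect_length(amps2, 1)
  expect_equal(amps2[[1]]$length, amps[[1]]$length)
  expect_identical(amps2[[1]]$sequence, amps[[1]]$sequence)
})

test_that("efficiency and productivity calculators follow the definitions", {
  m <- efficiency_metrics(list(sfgfp = 91, white_nonfluorescent = 9, blue = 5))
  expect_equal(m$efficiency_pct, 91)
  expect_equal(m$productivity, 3000)
  expect_equal(m$excluded_blue, 5)
  m2 <- efficiency_metrics(list(sfgfp = 10, white_nonfluorescent = 0, blue = 0))
  expect_equal(m2$efficiency_pct, 100)
  expect_equal(m2$productivity, 300)
  m3 <- efficiency_metrics(list(sfgfp = 0, white_nonfluorescent = 0, blue = 7))
  expect_true(is.na(m3$efficiency_pct))
  expect_match(m3$note, "undefined")
  m4 <- efficiency_metrics(list(sfgfp = 5, white_nonfluorescent = 5, blue = 0),
                           plated_fraction_factor = 10)
  expect_equal(m4$productivity, 100)
})

test_that("concatemer ladders enumerate contiguous sub-chains", {
  withr::with_seed(43, {
    ovs <- c("ATG", "GCA", "TAC", "CAG", "GGT")
    lens <- sample(50:150, 4)
    pool <- lapply(1:4, function(i)
      sticky_fragment(paste0(ovs[i], rand_dna(lens[i] - 3)), ovs[i],
                      ovs[i + 1], paste0("f", i)))
    lad <- concatemer_ladder(sample(pool))   # order-insensitive
    expect_equal(as.integer(table(lad$table$n)), c(4L, 3L, 2L, 1L))
    cores <- vapply(pool, function(f) nchar(f$core), 0L)
    # integer oracle: full length = sum of cores + trailing overhang
    expect_equal(lad$full_length_bp, sum(cores) + 3L)
    mono <- lad$table$length_bp[lad$table$n == 1]
    expect_setequal(mono, cores + 3L)
    expect_equal(concatemer_ladder(pool[1])$table$n, 1L)
    # a non-chain pool errors
    loopy <- list(sticky_fragment("ATGAAAA", "ATG", "GCA", "a"),
                  sticky_fragment("GCAAAAA", "GCA", "ATG", "b"))
    expect_error(concatemer_ladder(loopy), "linear chain")
  })
})
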