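test_that("scan_sites geometry matches the enzymes' cut arithmetic", {
  # + strand BsaI: GGTCTC at s=3 -> watson cut s+7, crick cut s+11
  m <- dna_molecule("t", paste0("AAA", "GGTCTC", "T", "ACGTACGTACGT"))
  h <- scan_sites(m, bsai())
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$recognition_start, 3)
  expect_equal(h$cut_top, 3 + 6 + 1)
  expect_equal(h$cut_bottom, h$cut_top + 4)
  # - strand: GAGACC at s -> watson cut s-5, crick s-1
  m2 <- dna_molecule("t2", paste0("ACGTACGTACGT", "GAGACC", "AAA"))
  h2 <- scan_sites(m2, bsai())
  expect_equal(h2$strand, "-")
  expect_equal(h2$cut_top, 12 - 1 - 4)
  expect_equal(h2$cut_bottom, 12 - 1)
  # SapI + strand: 7-nt recognition, 3-nt overhang
  m3 <- dna_molecule("t3", paste0("GCTCTTC", "A", "ACGTACGTACGT"))
  h3 <- scan_sites(m3, sapi())
  expect_equal(h3$cut_top, 8)
  expect_equal(h3$cut_bottom, 11)
  expect_equal(nrow(scan_sites(dna_molecule("n", "ACGTACGTACGT"), bsai())), 0)
})

test_that("scan_sites agrees with brute-force substring search, wrap-aware", {
  withr::with_seed(21, {
    for (i in 1:30) {
      L <- sample(60:400, 1)
      s <- rand_dna(L)
      mol <- dna_molecule("r", s, "circular")
      for (enz in list(bsai(), sapi())) {
        hits <- scan_sites(mol, enz)
        # oracle: fixed search in the doubled sequence
        dbl <- paste0(s, s)
        pl <- gregexpr(enz$recognition, dbl, fixed = TRUE)[[1]]
        pl <- unique((as.integer(pl[pl > 0]) - 1L) %% L)
        if (identical(pl, numeric(0)) || (length(pl) == 1 && pl[1] < 0)) pl <- integer()
        mn <- gregexpr(reverse_complement(enz$recognition), dbl,
                       fixed = TRUE)[[1]]
        mn <- unique((as.integer(mn[mn > 0]) - 1L) %% L)
        got_p <- sort(hits$recognition_start[hits$strand == "+"])
        got_m <- sort(hits$recognition_start[hits$strand == "-"])
        expect_identical(got_p, as.integer(sort(pl)))
        expect_identical(got_m, as.integer(sort(mn)))
      }
    }
  })
})

test_that("circular digestion conserves length; fragment ends carry codes", {
  fx <- fx_cached()
  tab <- fx$table
  # two convergent BsaI sites in a fixture receiver -> 2 hits, opposite strands
  r <- fx$kits$pCA[["pCAo-1"]]
  h <- scan_sites(r$molecule, bsai())
  expect_equal(nrow(h), 2)
  expect_setequal(h$strand, c("+", "-"))
  fr <- digest(r$molecule, bsai())
  expect_equal(sum(vapply(fr, function(f) nchar(f$core), 0L)),
               seq_length(r$molecule))
  # fixture L0 plasmid: insert fragment overhangs equal the declared codes
  p <- fx$parts$CE_sfGFP
  pf <- digest(p$molecule, bsai())
  rel <- pf[[which(!vapply(pf, loopassembly:::fragment_has_site, TRUE,
                           enz = bsai()))]]
  expect_identical(rel$left_ov, code_seq(tab, "C"))
  expect_identical(rel$right_ov, code_seq(tab, "E"))
})

test_that("linear digestion leaves blunt termini; uncut paths are distinct", {
  withr::with_seed(22, {
    s <- paste0(rand_dna(40), "GGTCTC", "A", rand_dna(60))
    m <- dna_molecule("lin", domesticate(substr(s, 1, 40))$sequence)  # no sites
    expect_length(digest(m, bsai()), 1)                # uncut linear: whole
    expect_identical(digest(m, bsai())[[1]]$left_ov, "")
    lin <- dna_molecule("lin2", s)
    fr <- digest(lin, bsai())
    expect_length(fr, 2)
    expect_identical(fr[[1]]$left_ov, "")
    expect_identical(fr[[2]]$right_ov, "")
    expect_identical(fr[[1]]$right_ov, fr[[2]]$left_ov)
    expect_equal(sum(nchar(vapply(fr, `[[`, "", "core"))), nchar(s))
    circ <- dna_molecule("c", domesticate(rand_dna(100))$sequence, "circular")
    expect_error(digest(circ, bsai()), class = "loop_uncut_circular")
  })
})

test_that("flip_fragment is an involution that swaps overhangs", {
  f <- sticky_fragment("AATGCCGGTTAGGT", left_ov = "AATG", right_ov = "GCTT",
                       parent_id = "x",
                       features = list(feature("tag", "t", 5, 9, "+")))
  g <- flip_fragment(f)
  expect_identical(g$left_ov, reverse_complement(f$right_ov))
  expect_identical(g$right_ov, reverse_complement(f$left_ov))
  h <- flip_fragment(g)
  expect_identical(h$core, f$core)
  expect_identical(h$left_ov, f$left_ov)
  expect_identical(h$features[[1]]$start, f$features[[1]]$start)
  expect_identical(h$features[[1]]$strand, "+")
})

test_that("enumerate_ligations matches the exhaustive oracle on small pools", {
  withr::with_seed(23, {
    ovset <- c("AATG", "GCTT", "TACA", "CGAT")
    for (rep in 1:12) {
      k <- sample(2:5, 1)
      pool <- lapply(seq_len(k), function(i) {
        core <- paste0(sample(ovset, 1), rand_dna(sample(5:20, 1)))
        sticky_fragment(core, substr(core, 1, 4), sample(ovset, 1),
                        paste0("f", i))
      })
      got <- tryCatch(enumerate_ligations(pool, "include_linear",
                                          max_copies = 1),
                      loop_combinatorial_cap = function(e) NULL)
      if (is.null(got)) next
      want <- oracle_ligations(pool, include_linear = TRUE)
      got_c <- sort(unique(vapply(
        Filter(function(p) p$topology == "circular", got),
        function(p) canonical_rotation(p$molecule), "")))
      got_l <- sort(unique(vapply(
        Filter(function(p) p$topology == "linear", got),
        function(p) min(p$molecule$sequence,
                        reverse_complement(p$molecule$sequence)), "")))
      expect_identical(got_c, want$circular)
      expect_identical(got_l, want$linear)
    }
  })
})

test_that("enumerate_ligations handles the canonical small cases", {
  # two fragments with ends (x,y) and (y,x) -> exactly one circular dimer
  f1 <- sticky_fragment("AATGCCCCC", "AATG", "GCTT", "a")
  f2 <- sticky_fragment("GCTTGGGGG", "GCTT", "AATG", "b")
  prods <- enumerate_ligations(list(f1, f2), "circular_only", max_copies = 1)
  expect_length(prods, 1)
  expect_equal(nrow(prods[[1]]$parts), 2)
  # four chained fragments -> linear 1..4-mers with exactly one full 4-mer
  ovs <- c("ATG", "GCA", "TAC", "CAG", "GGT")
  ch <- lapply(1:4, function(i)
    sticky_fragment(paste0(ovs[i], rand_dna(10)), ovs[i], ovs[i + 1],
                    paste0("c", i)))
  lp <- Filter(function(p) p$topology == "linear",
               enumerate_ligations(ch, "include_linear", max_copies = 1))
  sizes <- table(vapply(lp, function(p) nrow(p$parts), 0L))
  expect_equal(as.integer(sizes[c("1", "2", "3", "4")]), c(4L, 3L, 2L, 1L))
  # duplicated left overhangs yield alternative (misassembly) products
  dup <- c(ch, list(sticky_fragment(paste0("GCA", rand_dna(25)),
                                    "GCA", "GGT", "dup")))
  lp2 <- Filter(function(p) p$topology == "linear",
                enumerate_ligations(dup, "include_linear", max_copies = 1))
  full <- Filter(function(p) 5L %in% p$parts$pool_index && nrow(p$parts) >= 2,
                 lp2)
  expect_gt(length(full), 0)  # chains routing through the duplicate exist
})

test_that("the combinatorial guard reports duplicated overhangs", {
  pool <- lapply(1:6, function(i)
    sticky_fragment(paste0("AATG", rand_dna(6)), "AATG", "AATG", paste0("f", i)))
  err <- tryCatch(enumerate_ligations(pool, "include_linear", max_copies = 6,
                                      cap = 50),
                  loop_combinatorial_cap = function(e) e)
  expect_s3_class(err, "loop_combinatorial_cap")
  expect_match(conditionMessage(err), "AATG")
})

test_that("one_pot_assemble produces a scar-free intended product", {
  fx <- fx_cached()
  r <- fx$kits$pSB[["pSBo-4"]]
  parts <- fx$parts[c("AB_J23101", "BC_B0034m", "CE_sfGFP", "EF_B0015")]
  rep <- one_pot_assemble(r, unname(parts), bsai())
  expect_length(rep$intended, 1)
  prod <- rep$intended[[1]]
  expect_equal(nrow(scan_sites(prod, bsai())), 0)        # scar-free
  expect_error(digest(prod, bsai()), class = "loop_uncut_circular")
  expect_equal(nrow(scan_sites(prod, sapi())), 2)        # release pair intact
  expect_identical(rep$chain,
                   c("AB_J23101", "BC_B0034m", "CE_sfGFP", "EF_B0015"))
  # conservation oracle: intended length from independent cut arithmetic
  cutlen <- function(mol) {
    h <- scan_sites(mol, bsai())
    stopifnot(nrow(h) == 2)
    w <- sort(h$cut_top)
    w[2] - w[1]
  }
  # receiver keeps everything outside its two cuts; each insert contributes
  # its cut-to-cut span
  recv_keep <- seq_length(r$molecule) - cutlen(r$molecule)
  ins_give <- vapply(parts, function(p) {
    h <- scan_sites(p$molecule, bsai())
    w <- sort(h$cut_top)
    w[2] - w[1]
  }, 0)
  expect_equal(seq_length(prod), recv_keep + sum(ins_give))
  # parental re-ligations are reported, not counted as intended
  expect_gt(length(rep$parental), 0)
  expect_length(rep$misassembly, 0)
})

test_that("one_pot_assemble raises chain errors for gaps", {
  fx <- fx_cached()
  r <- fx$kits$pCA[["pCAo-4"]]
  parts <- unname(fx$parts[c("AB_J23101", "CE_sfGFP", "EF_B0015")])  # B->C gap
  err <- tryCatch(one_pot_assemble(r, parts, bsai()),
                  loop_chain_error = function(e) e)
  expect_s3_class(err, "loop_chain_error")
  expect_match(conditionMessage(err), code_seq(fx$table, "B"), fixed = TRUE)
})

test_that("fidelity_check flags duplicates, palindromes and collisions", {
  tab <- default_overhang_table()
  expect_true(fidelity_check(unname(tab$even_codes))$clean)
  expect_true(fidelity_check(unname(tab$odd_codes))$clean)
  expect_equal(fidelity_check(c("AATT", "GGCC"))$palindromes,
               c("AATT", "GGCC"))
  expect_equal(fidelity_check(c("ATG", "ATG"))$duplicates, "ATG")
  fc <- fidelity_check(c("AATG", "CATT"))   # revcomp pair
  expect_equal(nrow(fc$complement_collisions), 1)
  expect_false(fc$clean)
  expect_error(fidelity_check(c("ATG", "AATG")), "same length")
})
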