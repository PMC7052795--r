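test_that("the default overhang tables honour the published even codes", {
  tab <- default_overhang_table()
  expect_identical(unname(tab$even_codes[c("alpha", "beta", "gamma",
                                           "epsilon", "omega")]),
                   c("ATG", "GCA", "TAC", "CAG", "GGT"))
  expect_true(all(nchar(tab$odd_codes) == 4))
  # the D overhang must support the Ala/Gly CDS junction
  expect_identical(substr(tab$odd_codes[["D"]], 2, 3), "GG")
  expect_error(overhang_table(even_codes = c(alpha = "ATG", beta = "ATG",
                                             gamma = "TAC", epsilon = "CAG",
                                             omega = "GGT")),
               "fidelity")
})

test_that("overhang config files round-trip", {
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# custom odd code", "A=GTAA", "alpha=TTG",
               "uns1=ACGTACGTACGTACGTACGT"), cfg)
  tab <- load_overhang_config(cfg)
  expect_identical(unname(tab$odd_codes[["A"]]), "GTAA")
  # palindromic replacement codes are rejected by the fidelity gate
  writeLines("A=GTAC", cfg)
  expect_error(load_overhang_config(cfg), "fidelity")
  writeLines(c("A=GTAA", "alpha=TTG", "uns1=ACGTACGTACGTACGTACGT"), cfg)
  expect_identical(unname(tab$even_codes[["alpha"]]), "TTG")
  expect_identical(tab$uns1, "ACGTACGTACGTACGTACGT")
  expect_identical(unname(tab$odd_codes[["B"]]),
                   unname(default_overhang_table()$odd_codes[["B"]]))
  writeLines("A=GTAC=X", cfg)
  expect_error(load_overhang_config(cfg), "bad config line")
})

test_that("part names compose and parse as inverses", {
  expect_identical(compose_name("C", "E", "oriT"), "CE_oriT")
  expect_identical(parse_name("EF_PtBle"),
                   list(five_code = "E", three_code = "F", label = "PtBle"))
  expect_identical(parse_name("AC_CEN-ARS-HIS")$label, "CEN-ARS-HIS")
  withr::with_seed(31, {
    for (i in 1:25) {
      f <- sample(LETTERS[1:6], 1); t <- sample(LETTERS[1:6], 1)
      lab <- paste(sample(c(letters, LETTERS, 0:9, "-", "."),
                          sample(1:12, 1), replace = TRUE), collapse = "")
      expect_identical(parse_name(compose_name(f, t, lab)),
                       list(five_code = f, three_code = t, label = lab))
    }
  })
  expect_error(parse_name("CEoriT"), "malformed")
  expect_error(parse_name("CX_oriT"), "malformed")
})

test_that("validate_part_chain orders parts and reports gaps/branches", {
  fx <- fx_cached()
  r <- fx$kits$pCA[["pCAo-4"]]
  parts <- unname(fx$parts[c("CE_sfGFP", "AB_J23101", "EF_B0015",
                             "BC_B0034m")])       # shuffled input order
  chain <- validate_part_chain(parts, r)
  expect_identical(vapply(chain, function(p) p$name, ""),
                   c("AB_J23101", "BC_B0034m", "CE_sfGFP", "EF_B0015"))
  err <- tryCatch(
    validate_part_chain(unname(fx$parts[c("AB_J23101", "CE_sfGFP",
                                          "EF_B0015")]), r),
    loop_chain_error = function(e) e)
  expect_match(conditionMessage(err), "no part starts at code B")
  err2 <- tryCatch(
    validate_part_chain(unname(fx$parts[c("AB_J23101", "BC_B0034m",
                                          "CE_sfGFP", "CD_mRuby3",
                                          "EF_B0015")]), r),
    loop_chain_error = function(e) e)
  expect_match(conditionMessage(err2), "branch: code C")
  # four even composites chain alpha..omega into an even receiver
  comp <- lapply(1:4, function(i)
    list(five_code = EVEN <- c("alpha", "beta", "gamma", "epsilon")[i],
         three_code = c("beta", "gamma", "epsilon", "omega")[i],
         name = paste0("c", i)))
  even <- fx$kits$pCA[["pCAe-1"]]
  expect_identical(vapply(validate_part_chain(rev(comp), even),
                          function(x) x$name, ""),
                   c("c1", "c2", "c3", "c4"))
})

test_that("receivers satisfy the kit grammar", {
  fx <- fx_cached()
  tab <- fx$table
  # odd parity: kanamycin, accepts A..F, releases the sigma chain window
  r <- fx$kits$pCA[["pCAo-4"]]
  expect_identical(r$marker, "kanamycin")
  expect_identical(r$accept_codes, c("A", "F"))
  expect_identical(r$release_codes, c("epsilon", "omega"))
  # even parity position 1: accepts alpha..omega, releases (A, chain[2])
  r2 <- fx$kits$pSB[["pSBe-1"]]
  expect_identical(r2$marker, "chloramphenicol")
  expect_identical(r2$accept_codes, c("alpha", "omega"))
  expect_identical(r2$release_codes,
                   c("A", tab$even_release_chain[2]))
  expect_identical(fx$kits$pCO[["pCOe-3"]]$marker, "spectinomycin")
  # every built receiver: exactly 2 BsaI + 2 SapI sites
  for (r in fx$kits$pAN) {
    expect_equal(nrow(scan_sites(r$molecule, bsai())), 2)
    expect_equal(nrow(scan_sites(r$molecule, sapi())), 2)
  }
  # a backbone carrying a site is refused
  bad <- dna_molecule("bad", paste0("GGTCTC", strrep("ACGT", 300)))
  expect_error(build_receiver("pCA", "odd", 1, bad), "domesticate")
})

test_that("domestication removes planted sites and is translation-safe", {
  withr::with_seed(32, {
    # identity on clean input
    clean <- domesticate(rand_dna(400))
    expect_equal(nrow(domesticate(clean$sequence)$edits), 0)
    # planted sites in non-coding sequence: one edit per site, rescan clean
    for (rep in 1:8) {
      base <- domesticate(rand_dna(2000))$sequence
      sites <- c("GGTCTC", "GAGACC", "GCTCTTC", "GAAGAGC")
      nplant <- sample(2:5, 1)
      pos <- sort(sample(seq(10, 1900, by = 60), nplant))
      seqv <- base
      for (p in pos) {
        s <- sample(sites, 1)
        seqv <- paste0(substr(seqv, 1, p), s,
                       substr(seqv, p + nchar(s) + 1, nchar(seqv)))
      }
      seqv <- substr(seqv, 1, 2000)
      before <- loopassembly:::site_occurrences(seqv)
      out <- domesticate(seqv)
      expect_gte(nrow(before), nplant)
      expect_equal(nrow(out$edits), nrow(before))
      # oracle rescan: plain substring search finds nothing
      for (s in sites)
        expect_false(grepl(s, out$sequence, fixed = TRUE))
      expect_equal(nchar(out$sequence), nchar(seqv))
    }
    # synonymous edits inside CDS leave translation unchanged
    for (rep in 1:8) {
      ncod <- 200
      orf <- loopassembly:::random_orf_body(ncod)
      p <- 3 * sample(20:150, 1)  # plant on a codon boundary
      site <- sample(c("GGTCTC", "GCTCTTC"), 1)
      orf2 <- paste0(substr(orf, 1, p), site,
                     substr(orf, p + nchar(site) + 1, nchar(orf)))
      orf2 <- substr(orf2, 1, 3 * ncod)
      out <- domesticate(orf2, cds_intervals = list(c(0, 3 * ncod)))
      expect_identical(translate_cds(out$sequence), translate_cds(orf2))
      expect_equal(nrow(loopassembly:::site_occurrences(out$sequence)), 0)
      if (nrow(out$edits)) expect_true(all(out$edits$type == "synonymous"))
    }
  })
  # the classic case: GGT(Gly) -> GGA destroys a BsaI site synonymously
  cds <- paste0("ATG", "GGT", "CTC", "AAA")  # GGTCTC spans codons 2-3
  out <- domesticate(cds, cds_intervals = list(c(0, 12)))
  expect_identical(translate_cds(out$sequence), translate_cds(cds))
  expect_false(grepl("GGTCTC", out$sequence, fixed = TRUE))
  expect_equal(nrow(out$edits), 1)
})

test_that("the D-overhang CDS rule is enforced", {
  tab <- default_overhang_table()
  good <- paste0(loopassembly:::random_orf_body(10), "GC")
  expect_silent(check_d_rule(good, code_seq(tab, "D")))
  expect_error(check_d_rule(paste0(loopassembly:::random_orf_body(10), "AT"),
                            code_seq(tab, "D")), "end in GC")
  withstop <- paste0(loopassembly:::random_orf_body(4), "TAA",
                     loopassembly:::random_orf_body(4), "GC")
  expect_error(check_d_rule(withstop, code_seq(tab, "D")), "stop codon")
  expect_error(check_d_rule(paste0("A", good), code_seq(tab, "D")),
               "out of frame")
  expect_error(check_d_rule(good, "ATTA"), "central GG")
})

test_that("build_l0_entry builds a SapI-free plasmid releasing on BsaI", {
  fx <- fx_cached()
  withr::with_seed(33, {
    ins <- domesticate(rand_dna(220))$sequence
    p <- build_l0_entry(ins, "C", "E", fx$entry, "oriT", "other", fx$table)
    expect_identical(p$name, "CE_oriT")
    expect_equal(nrow(scan_sites(p$molecule, sapi())), 0)
    expect_equal(nrow(scan_sites(p$molecule, bsai())), 2)
    # refuse a non-domesticated insert, listing the site
    dirty <- paste0(substr(ins, 1, 50), "GGTCTC", substr(ins, 51, 220))
    expect_error(build_l0_entry(dirty, "C", "E", fx$entry, "x", "other",
                                fx$table),
                 "internal sites at.*BsaI", perl = TRUE)
    # unusual syntax position draws a warning
    expect_warning(build_l0_entry(ins, "E", "F", fx$entry, "odd1",
                                  "promoter", fx$table),
                   "syntax")
  })
})

test_that("Loop recursion invariant holds for all positions and parities", {
  fx <- fx_cached()
  tab <- fx$table
  withr::with_seed(34, {
    for (parity in c("odd", "even")) {
      asm <- if (parity == "odd") bsai() else sapi()
      rel <- if (parity == "odd") sapi() else bsai()
      for (pos in 1:4) {
        r <- fx$kits$pCO[[sprintf("pCO%s-%d", substr(parity, 1, 1), pos)]]
        aL <- code_seq(tab, r$accept_codes[1])
        aR <- code_seq(tab, r$accept_codes[2])
        ins <- make_insert_plasmid(paste0("ins", pos), asm, aL, aR,
                                   domesticate(rand_dna(150))$sequence)
        rep <- one_pot_assemble(r, list(ins), asm)
        expect_length(rep$intended, 1)
        prod <- rep$intended[[1]]
        expect_equal(nrow(scan_sites(prod, asm)), 0)
        fr <- digest(prod, rel)
        free <- Filter(function(f)
          !loopassembly:::fragment_has_site(f, rel), fr)
        expect_length(free, 1)
        expect_identical(free[[1]]$left_ov,
                         code_seq(tab, r$release_codes[1]))
        expect_identical(free[[1]]$right_ov,
                         code_seq(tab, r$release_codes[2]))
      }
    }
  })
})
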