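# fixtures: deterministic synthetic-data generator. Produces vector kits,
# an L0 part library and the benchmark assembly trees so the whole system is
# testable offline. Same seed => byte-identical output (RNG use is isolated
# with withr::with_seed).
#
# Sequences are synthetic stand-ins: grammar, sites and feature labels are
# faithful; nucleotide content and exact lengths are not those of the real
# deposited vectors.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random coding body of n_codons codons, no stop codons in frame
random_orf_body <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

scrubbed_backbone <- function(id, len) {
  seq <- domesticate(random_dna(len))$sequence
  dna_molecule(id, seq, "linear", provenance = "synthetic backbone")
}

#' Generate the four synthetic uLoop-style vector kits
#'
#' Builds, for each kit (pCA, pCO, pSB, pAN), four odd and four even
#' receivers (`pXXo-1..4`, `pXXe-1..4`) on random site-free backbones
#' (2-4 kb, rejection/scrub sampled), plus the SapI entry vector
#' (`pL0R-lacZ`). Odd receivers carry the kanamycin marker; even receivers
#' spectinomycin (pCA, pCO) or chloramphenicol (pSB, pAN).
#'
#' @param seed Integer seed; identical seeds give identical kits.
#' @param table Active [overhang_table()].
#' @return List: `kits` (kit -> named list of 8 `loop_receiver`s), `entry`
#'   (the entry vector molecule), `table`.
#' @export
generate_kit <- function(seed = 42L, table = default_overhang_table()) {
  withr::with_seed(as.integer(seed), {
    kits <- list()
    for (kit in KITS) {
      backbone <- scrubbed_backbone(paste0(kit, "_backbone"),
                                    sample(2000:4000, 1L))
      recs <- list()
      for (parity in c("odd", "even")) for (pos in 1:4) {
        r <- build_receiver(kit, parity, pos, backbone, table)
        recs[[r$name]] <- r
      }
      kits[[kit]] <- recs
    }
    entry <- make_entry_vector(scrubbed_backbone("pL0R_backbone",
                                                 sample(1800:2500, 1L)),
                               table)
    list(kits = kits, entry = entry, table = table)
  })
}

# catalog of synthetic L0 parts: the bacterial sfGFP cassette parts and the
# three plant expression cassettes (35S promoter TUs). N7 nuclear tags go
# with the mTurquoise2 and Venus TUs only — the unique assignment consistent
# with the level-4 census arithmetic (32 N7 tags; mRuby3 TUs untagged).
PART_CATALOG <- list(
  list(five = "A", three = "B", label = "J23101", kind = "promoter", len = 36),
  list(five = "B", three = "C", label = "B0034m", kind = "RBS", len = 21),
  list(five = "C", three = "E", label = "sfGFP", kind = "CDS", len = 717),
  list(five = "E", three = "F", label = "B0015", kind = "terminator", len = 129),
  list(five = "A", three = "C", label = "CaMV35S", kind = "promoter", len = 420),
  list(five = "C", three = "D", label = "mRuby3", kind = "CDS", len = 710),
  list(five = "C", three = "D", label = "mTurquoise2", kind = "CDS", len = 713),
  list(five = "C", three = "D", label = "Venus", kind = "CDS", len = 713),
  list(five = "D", three = "E", label = "N7", kind = "tag", len = 255),
  list(five = "D", three = "E", label = "3xSTOP", kind = "other", len = 9),
  list(five = "E", three = "F", label = "nos", kind = "terminator", len = 253))

make_part_insert <- function(spec) {
  if (spec$label == "3xSTOP") return("TAATGATAA")
  if (spec$kind == "CDS") {
    if (spec$three == "D") {
      # body codons + GC: in frame after the C overhang's ATG, ends on the
      # split alanine codon completed by the D overhang
      n_codons <- (spec$len - 2L) %/% 3L
      return(paste0(random_orf_body(n_codons), "GC"))
    }
    # CDS carrying its own stop (C-E syntax)
    n_codons <- spec$len %/% 3L - 1L
    return(paste0(random_orf_body(n_codons), "TAA"))
  }
  random_dna(spec$len)
}

#' Generate the synthetic L0 part library
#'
#' Domesticated-by-construction synthetic inserts for the benchmark parts
#' (`AB_J23101`, `BC_B0034m`, `CE_sfGFP`, `EF_B0015`, the 35S plant-TU
#' parts, `DE_N7`, `DE_3xSTOP`, `EF_nos`), entered into the entry vector via
#' [build_l0_entry()]. CDS inserts are stop-free random ORFs; parts ending
#' on the D overhang end in `GC` per the Ala/Gly junction rule.
#'
#' @param seed Integer seed.
#' @param entry Entry vector (from [generate_kit()]); generated if missing.
#' @param table Active [overhang_table()].
#' @return Named list of `loop_part`s keyed by part name.
#' @export
generate_part_library <- function(seed = 42L, entry = NULL,
                                  table = default_overhang_table()) {
  if (is.null(entry)) entry <- generate_kit(seed, table)$entry
  withr::with_seed(as.integer(seed) + 1L, {
    parts <- list()
    for (spec in PART_CATALOG) {
      part <- NULL
      for (attempt in 1:25) {
        insert <- make_part_insert(spec)
        if (spec$kind == "CDS")
          insert <- domesticate(insert,
                                cds_intervals = list(c(0L, 3L * (nchar(insert) %/% 3L))))$sequence
        else insert <- domesticate(insert)$sequence
        part <- tryCatch(
          suppressWarnings(build_l0_entry(insert, spec$five, spec$three,
                                          entry, spec$label, spec$kind, table)),
          error = function(e) NULL)
        if (!is.null(part)) break
      }
      if (is.null(part))
        stop("could not generate a clean insert for ", spec$label,
             call. = FALSE)
      parts[[part$name]] <- part
    }
    parts
  })
}

#' Generate the complete fixture library
#'
#' Kits, entry vector, part library and the benchmark designs, all from one
#' seed.
#' @param seed Integer seed.
#' @param table Active [overhang_table()].
#' @return List: `kits`, `entry`, `parts`, `table`, `designs`.
#' @export
generate_fixtures <- function(seed = 42L, table = default_overhang_table()) {
  kit <- generate_kit(seed, table)
  parts <- generate_part_library(seed, kit$entry, table)
  c(kit, list(parts = parts, designs = benchmark_designs()))
}

## -------------------------------------------------------- benchmark trees --

tu_design <- function(which, position, kit = "pCA") {
  children <- switch(which,
    sfGFP = list(design_part("AB_J23101"), design_part("BC_B0034m"),
                 design_part("CE_sfGFP"), design_part("EF_B0015")),
    mR3 = list(design_part("AC_CaMV35S"), design_part("CD_mRuby3"),
               design_part("DE_3xSTOP"), design_part("EF_nos")),
    mT2 = list(design_part("AC_CaMV35S"), design_part("CD_mTurquoise2"),
               design_part("DE_N7"), design_part("EF_nos")),
    Ve = list(design_part("AC_CaMV35S"), design_part("CD_Venus"),
              design_part("DE_N7"), design_part("EF_nos")),
    stop("unknown TU ", which))
  design_node(1L, position, children, kit = kit)
}

l2_allx4 <- function(position, kit = "pCA") {
  design_node(2L, position,
              list(tu_design("mR3", 1, kit), tu_design("mT2", 2, kit),
                   tu_design("Ve", 3, kit), tu_design("mR3", 4, kit)),
              kit = kit)
}

#' The benchmark hierarchical test designs
#'
#' Encodes the test-assembly trees used throughout: `L1-4_sfGFP` (the
#' bacterial sfGFP cassette in an odd position-4 receiver); `L2_allx4`
#' (four plant TUs: mRuby3 / mTurquoise2 / Venus / mRuby3); `L2-4_sfGFP`
#' (three plant TUs plus `L1-4_sfGFP`); `L3_allx4` (4 x `L2_allx4`, 16
#' TUs); `L3-4_sfGFP` (3 x `L2_allx4` plus `L2-4_sfGFP`, 16 TUs); and the
#' receiver-free 64-TU level-4 design `L4` from the three all-plant L3
#' composites plus `L3-4_sfGFP`.
#'
#' @param kit Kit used by every node (default pCA).
#' @return Named list of `loop_design`s.
#' @export
benchmark_designs <- function(kit = "pCA") {
  l3_allx4 <- function(pos) design_node(3L, pos, lapply(1:4, l2_allx4,
                                                        kit = kit), kit = kit)
  l2_4_sfgfp <- design_node(2L, 4L,
                            list(tu_design("mR3", 1, kit),
                                 tu_design("mT2", 2, kit),
                                 tu_design("Ve", 3, kit),
                                 tu_design("sfGFP", 4, kit)), kit = kit)
  l3_4_sfgfp <- design_node(3L, 4L,
                            list(l2_allx4(1, kit), l2_allx4(2, kit),
                                 l2_allx4(3, kit), l2_4_sfgfp), kit = kit)
  list(
    `L1-4_sfGFP` = tu_design("sfGFP", 4, kit),
    `L2_allx4` = l2_allx4(4, kit),
    `L2-4_sfGFP` = l2_4_sfgfp,
    `L3_allx4` = l3_allx4(4L),
    `L3-4_sfGFP` = l3_4_sfgfp,
    `L4` = design_node(4L, NA, list(l3_allx4(1L), l3_allx4(2L),
                                    l3_allx4(3L), l3_4_sfgfp),
                       kit = kit, receiver_free = TRUE))
}

## ----------------------------------------------------------- part tables --

#' Write / read an L0 part catalog as CSV
#'
#' Columns: `name`, `five_code`, `three_code`, `kind`, `label`, `sequence`
#' (the insert). Reading rebuilds parts through [build_l0_entry()].
#'
#' @param parts Named list of `loop_part`s.
#' @param path CSV path.
#' @return `write_part_table`: `path`, invisibly. `read_part_table`: named
#'   list of `loop_part`s.
#' @export
write_part_table <- function(parts, path) {
  df <- do.call(rbind, lapply(parts, function(p)
    data.frame(name = p$name, five_code = p$five_code,
               three_code = p$three_code, kind = p$kind, label = p$label,
               sequence = p$insert)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_part_table
#' @param entry Entry vector used to rebuild the part plasmids.
#' @param table Active [overhang_table()].
#' @export
read_part_table <- function(path, entry, table = default_overhang_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "five_code", "three_code", "kind", "label", "sequence")
  if (!all(need %in% names(df)))
    stop("part table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  parts <- list()
  for (i in seq_len(nrow(df))) {
    p <- suppressWarnings(
      build_l0_entry(df$sequence[i], df$five_code[i], df$three_code[i],
                     entry, df$label[i], df$kind[i], table))
    stopifnot(identical(p$name, df$name[i]))
    parts[[p$name]] <- p
  }
  parts
}
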