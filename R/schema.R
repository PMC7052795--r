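# schema: the Loop/uLoop grammar layer — overhang alphabets, part
# nomenclature, receiver construction, L0 entry and domestication.
#
# The scheme alternates two enzymes: odd assembly levels (L1, L3) assemble
# with BsaI over a six-letter 4-nt overhang alphabet A..F; even levels
# (L2, L4) assemble with SapI over the 3-nt alphabet alpha..omega. Receivers
# carry convergent assembly-enzyme sites that excise a lacZ dropout (the
# recognition sites leave with the dropout) and inverted release-enzyme
# sites that cut outward, so the product of level n is a substrate of level
# n+1.

ODD_LETTERS <- c("A", "B", "C", "D", "E", "F")
EVEN_LETTERS <- c("alpha", "beta", "gamma", "epsilon", "omega")

#' Overhang tables and schema configuration
#'
#' The even (SapI) 3-nt codes are fixed to the published Loop set:
#' alpha=ATG, beta=GCA, gamma=TAC, epsilon=CAG, omega=GGT. The odd (BsaI)
#' 4-nt codes follow the community "common syntax" and ship as replaceable
#' defaults (they are configuration, not a contract of this package); the
#' default D code satisfies the Ala/Gly junction constraint (pattern nGGn,
#' see [check_d_rule()]). `even_release_chain` is the 5-term odd-letter chain
#' used by even receivers to chain four even-level composites into an odd
#' receiver (first term A, last F; interior codes reuse B, C, E). `uns1` and
#' `unsx` are synthetic stand-ins for the unique flanking primer sites.
#'
#' @param odd_codes Named character vector over letters A..F (4-nt each).
#' @param even_codes Named character vector over alpha..omega (3-nt each).
#' @param even_release_chain Five odd letters, first "A", last "F".
#' @param uns1,unsx Flanking verification-primer sequences.
#' @param entry Length-2 named vector of 3-nt L0 entry overhangs.
#' @return A list of class `overhang_table`.
#' @export
overhang_table <- function(odd_codes = c(A = "GGAG", B = "TACT", C = "AATG",
                                         D = "AGGT", E = "GCTT", F = "CGCT"),
                           even_codes = c(alpha = "ATG", beta = "GCA",
                                          gamma = "TAC", epsilon = "CAG",
                                          omega = "GGT"),
                           even_release_chain = c("A", "B", "C", "E", "F"),
                           uns1 = "CATTACTCGCATCCATTCTC",
                           unsx = "GTTTGGATCTTCCAGTCCAA",
                           entry = c(left = "ACT", right = "CCA")) {
  stopifnot(identical(sort(names(odd_codes)), sort(ODD_LETTERS)),
            identical(sort(names(even_codes)), sort(EVEN_LETTERS)),
            all(nchar(odd_codes) == 4L), all(nchar(even_codes) == 3L),
            length(even_release_chain) == 5L,
            even_release_chain[1] == "A", even_release_chain[5] == "F",
            all(even_release_chain %in% ODD_LETTERS),
            all(nchar(entry) == 3L))
  for (set in list(odd_codes, even_codes)) {
    fc <- fidelity_check(unname(set))
    if (!fc$clean)
      stop("overhang alphabet fails fidelity check: ",
           paste(c(fc$duplicates, fc$palindromes,
                   if (nrow(fc$complement_collisions))
                     paste(fc$complement_collisions$x,
                           fc$complement_collisions$y, sep = "~")),
                 collapse = ","), call. = FALSE)
  }
  structure(list(odd_codes = toupper(odd_codes),
                 even_codes = toupper(even_codes),
                 even_release_chain = even_release_chain,
                 sigma_chain = EVEN_LETTERS,
                 uns1 = toupper(uns1), unsx = toupper(unsx),
                 entry = toupper(entry)),
            class = "overhang_table")
}

#' @rdname overhang_table
#' @export
default_overhang_table <- function() overhang_table()

#' Look up an overhang code sequence
#' @param table An [overhang_table()].
#' @param code A letter of either alphabet (`"A"`..`"F"` or
#'   `"alpha"`..`"omega"`).
#' @return The overhang sequence.
#' @export
code_seq <- function(table, code) {
  if (code %in% names(table$odd_codes)) return(unname(table$odd_codes[[code]]))
  if (code %in% names(table$even_codes)) return(unname(table$even_codes[[code]]))
  stop("unknown overhang code: ", code, call. = FALSE)
}

#' Read an overhang table from a key=value config file
#'
#' Lines of the form `code=SEQUENCE` (e.g. `A=GGAG`, `alpha=ATG`,
#' `uns1=...`); `#` comments and blank lines ignored. Unspecified keys keep
#' their defaults.
#' @param path Config file path.
#' @return An [overhang_table()].
#' @export
load_overhang_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("bad config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- toupper(trimws(vapply(kv, `[[`, "", 2L)))
  tab <- default_overhang_table()
  args <- list(odd_codes = tab$odd_codes, even_codes = tab$even_codes,
               even_release_chain = tab$even_release_chain,
               uns1 = tab$uns1, unsx = tab$unsx, entry = tab$entry)
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% ODD_LETTERS) args$odd_codes[[k]] <- vals[i]
    else if (tolower(k) %in% EVEN_LETTERS) args$even_codes[[tolower(k)]] <- vals[i]
    else if (tolower(k) == "uns1") args$uns1 <- vals[i]
    else if (tolower(k) == "unsx") args$unsx <- vals[i]
    else if (tolower(k) == "entry_left") args$entry[["left"]] <- vals[i]
    else if (tolower(k) == "entry_right") args$entry[["right"]] <- vals[i]
    else if (tolower(k) == "even_release_chain")
      args$even_release_chain <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    else stop("unknown config key: ", k, call. = FALSE)
  }
  do.call(overhang_table, args)
}

## ----------------------------------------------------------- nomenclature --

#' Compose / parse Loop part names
#'
#' Part names are `<five_code><three_code>_<label>` over the odd alphabet,
#' e.g. `CE_oriT`, `EF_PtBle`; A and F are the terminal overhangs.
#' `parse_name(compose_name(...))` is the identity.
#'
#' @param five_code,three_code Odd-alphabet letters.
#' @param label Part label (must not be empty).
#' @return `compose_name`: the name string. `parse_name`: list with
#'   `five_code`, `three_code`, `label`.
#' @examples
#' compose_name("C", "E", "oriT")   # "CE_oriT"
#' parse_name("EF_PtBle")
#' @export
compose_name <- function(five_code, three_code, label) {
  stopifnot(five_code %in% ODD_LETTERS, three_code %in% ODD_LETTERS,
            nzchar(label))
  paste0(five_code, three_code, "_", label)
}

#' @rdname compose_name
#' @param name A part name to parse.
#' @export
parse_name <- function(name) {
  m <- regmatches(name, regexec("^([A-F])([A-F])_(.+)$", name))[[1]]
  if (length(m) != 4L)
    stop("malformed part name: '", name,
         "' (expected <code><code>_<label> over letters A-F)", call. = FALSE)
  list(five_code = m[2], three_code = m[3], label = m[4])
}

# Common-syntax position rules, enforced as warnings (not errors).
SYNTAX_RULES <- list(
  promoter   = list(c("A", "C"), c("A", "B")),
  tag        = list(c("B", "C"), c("D", "E")),  # N-tag B-C, C-tag D-E
  CDS        = list(c("C", "D"), c("C", "E")),  # C-E: CDS carrying its stop
  RBS        = list(c("B", "C")),
  terminator = list(c("E", "F")))

check_syntax_position <- function(kind, five_code, three_code) {
  rules <- SYNTAX_RULES[[kind]]
  if (is.null(rules)) return(invisible(TRUE))
  ok <- any(vapply(rules, function(r)
    identical(r, c(five_code, three_code)), TRUE))
  if (!ok)
    warning(sprintf("part syntax: %s between %s and %s is unusual (expected %s)",
                    kind, five_code, three_code,
                    paste(vapply(rules, paste, "", collapse = "-"),
                          collapse = " or ")), call. = FALSE)
  invisible(ok)
}

#' Validate the ordering of a part chain against a receiver
#'
#' Given parts (or composites) declaring `(five_code, three_code)` and a
#' receiver exposing accept codes, returns the unique ordering forming a
#' path `accept_left -> ... -> accept_right` using every junction code
#' exactly once. Input order is irrelevant. Raises an error of class
#' `loop_chain_error` naming any gap or code collision.
#'
#' @param parts List of objects with `five_code`/`three_code` fields
#'   (e.g. [loop_part][build_l0_entry()]s or plain lists).
#' @param receiver A `loop_receiver` (see [build_receiver()]).
#' @return The input parts, reordered into the chain.
#' @export
validate_part_chain <- function(parts, receiver) {
  accept <- receiver$accept_codes
  fives <- vapply(parts, function(p) p$five_code, "")
  threes <- vapply(parts, function(p) p$three_code, "")
  labels <- vapply(parts, function(p)
    if (!is.null(p$name)) p$name else paste0(p$five_code, p$three_code), "")
  order_out <- integer()
  cur <- accept[1]
  remaining <- seq_along(parts)
  while (length(remaining)) {
    hit <- remaining[fives[remaining] == cur]
    if (length(hit) == 0L)
      stop(structure(class = c("loop_chain_error", "error", "condition"),
                     list(message = paste0(
                       "chain gap: no part starts at code ", cur,
                       " (unplaced: ", paste(labels[remaining], collapse = ","),
                       ")"), call = NULL)))
    if (length(hit) > 1L)
      stop(structure(class = c("loop_chain_error", "error", "condition"),
                     list(message = paste0("chain branch: code ", cur,
                                           " shared by ",
                                           paste(labels[hit], collapse = " and ")),
                          call = NULL)))
    order_out <- c(order_out, hit)
    cur <- threes[hit]
    remaining <- setdiff(remaining, hit)
  }
  if (cur != accept[2])
    stop(structure(class = c("loop_chain_error", "error", "condition"),
                   list(message = paste0("chain ends at code ", cur,
                                         " but receiver accepts ", accept[2]),
                        call = NULL)))
  parts[order_out]
}

## ----------------------------------------------------------- domestication --

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C", N = "A")

# All recognition-site occurrences of the given enzymes on both strands of a
# (linear, top-strand) sequence: data.frame(enzyme, strand, start, width),
# 0-based starts, sorted.
site_occurrences <- function(seq, enzymes = list(bsai(), sapi())) {
  rows <- list()
  for (enz in enzymes) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") enz$recognition
             else reverse_complement(enz$recognition)
      for (s in find_matches0(seq, pat, circular = FALSE))
        rows[[length(rows) + 1L]] <-
          data.frame(enzyme = enz$name, strand = strand, start = s,
                     width = nchar(pat))
    }
  }
  if (!length(rows))
    return(data.frame(enzyme = character(), strand = character(),
                      start = integer(), width = integer()))
  df <- do.call(rbind, rows)
  df[order(df$start, df$strand), , drop = FALSE]
}

syn_codon_alternatives <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  alts <- names(gc)[gc == aa & names(gc) != codon]
  # one substitution per site: only Hamming-distance-1 alternatives
  h1 <- vapply(alts, function(a)
    sum(strsplit(a, "")[[1]] != strsplit(codon, "")[[1]]) == 1L, TRUE)
  sort(alts[h1])
}

apply_sub <- function(seq, pos0, base) {
  paste0(substr(seq, 1L, pos0), base, substr(seq, pos0 + 2L, nchar(seq)))
}

#' Remove internal Type IIS sites by single-base substitution
#'
#' Destroys every BsaI/SapI recognition site (both strands) with exactly one
#' substitution per site. Inside a declared CDS interval the substitution is
#' synonymous (translation of every interval is unchanged); outside, the
#' most degenerate recognition position — the last base of the recognition
#' sequence on its own strand — is mutated to its transition base. Edits can
#' create new sites, so scanning iterates to a fixpoint (bounded at
#' `max_iter` passes).
#'
#' @param seq DNA string (top strand; treated as linear).
#' @param cds_intervals List of 0-based half-open `c(start, end)` spans that
#'   must keep their translation.
#' @param enzymes Enzymes whose sites are removed.
#' @param max_iter Fixpoint bound.
#' @return List with `sequence` (edited) and `edits` (data.frame: `pos`
#'   0-based, `from`, `to`, `enzyme`, `type` synonymous/transition).
#' @export
domesticate <- function(seq, cds_intervals = list(),
                        enzymes = list(bsai(), sapi()), max_iter = 10L) {
  seq <- toupper(seq)
  enzymes <- lapply(enzymes, as_enzyme)
  enz_by_name <- stats::setNames(enzymes,
                                 vapply(enzymes, function(e) e$name, ""))
  edits <- list()
  for (iter in seq_len(max_iter)) {
    occ <- site_occurrences(seq, enzymes)
    if (!nrow(occ)) break
    for (r in seq_len(nrow(occ))) {
      s <- occ$start[r]; w <- occ$width[r]
      pat <- substr(seq, s + 1L, s + w)
      # site may already have been destroyed by an earlier edit in this pass
      expected <- if (occ$strand[r] == "+")
        enz_by_name[[occ$enzyme[r]]]$recognition
      else reverse_complement(enz_by_name[[occ$enzyme[r]]]$recognition)
      if (pat != expected) next
      cds <- Filter(function(iv) s < iv[2] && (s + w) > iv[1], cds_intervals)
      edited <- FALSE
      if (length(cds)) {
        iv <- cds[[1]]
        # codons of this CDS overlapping the site, left to right
        first_codon <- max(0L, (s - iv[1]) %/% 3L)
        last_codon <- min((iv[2] - iv[1]) %/% 3L - 1L,
                          (s + w - 1L - iv[1]) %/% 3L)
        for (ci in first_codon:last_codon) {
          cstart <- iv[1] + 3L * ci
          codon <- substr(seq, cstart + 1L, cstart + 3L)
          if (grepl("N", codon, fixed = TRUE)) next
          for (alt in syn_codon_alternatives(codon)) {
            pos <- cstart + which(strsplit(alt, "")[[1]] !=
                                    strsplit(codon, "")[[1]]) - 1L
            if (pos < s || pos >= s + w) next  # must hit the site itself
            cand <- apply_sub(seq, pos, substr(alt, pos - cstart + 1L,
                                               pos - cstart + 1L))
            if (substr(cand, s + 1L, s + w) != expected) {
              edits[[length(edits) + 1L]] <-
                data.frame(pos = pos, from = substr(seq, pos + 1L, pos + 1L),
                           to = substr(cand, pos + 1L, pos + 1L),
                           enzyme = occ$enzyme[r], type = "synonymous")
              seq <- cand; edited <- TRUE
              break
            }
          }
          if (edited) break
        }
        if (!edited)
          stop("no synonymous escape for ", occ$enzyme[r], " site at ", s,
               " within CDS codon(s) ",
               paste(first_codon:last_codon, collapse = ","), call. = FALSE)
      } else {
        # last base of the recognition sequence on its own strand:
        # rightmost base for + occurrences, leftmost for - occurrences
        pos <- if (occ$strand[r] == "+") s + w - 1L else s
        from <- substr(seq, pos + 1L, pos + 1L)
        seq <- apply_sub(seq, pos, TRANSITION[[from]])
        edits[[length(edits) + 1L]] <-
          data.frame(pos = pos, from = from, to = TRANSITION[[from]],
                     enzyme = occ$enzyme[r], type = "transition")
      }
    }
  }
  if (nrow(site_occurrences(seq, enzymes)))
    stop("domestication did not reach a site-free fixpoint in ",
         max_iter, " iterations", call. = FALSE)
  list(sequence = seq,
       edits = if (length(edits)) do.call(rbind, edits)
               else data.frame(pos = integer(), from = character(),
                               to = character(), enzyme = character(),
                               type = character()))
}

#' Check the D-overhang junction rule for a CDS insert
#'
#' A CDS part ending on the D overhang must carry no stop codon; its stop is
#' removed and the insert ends in `GC` so that the junction completes an
#' alanine codon and the D overhang's central `GG` begins a glycine codon.
#' Frame convention: the open reading frame is `ATG` (supplied by the C
#' overhang) followed directly by the insert.
#'
#' @param insert CDS insert sequence (without the flanking overhangs).
#' @param d_code The active D overhang sequence (checked for the nGGn motif).
#' @return TRUE invisibly, or an error describing the violation.
#' @export
check_d_rule <- function(insert, d_code) {
  if (substr(d_code, 2, 3) != "GG")
    stop("D overhang '", d_code, "' cannot encode the Ala/Gly junction ",
         "(needs central GG)", call. = FALSE)
  n <- nchar(insert)
  if (n < 2L || substr(insert, n - 1L, n) != "GC")
    stop("CDS insert with three_code D must end in GC ",
         "(completes the alanine codon at the D junction)", call. = FALSE)
  if ((3L + n - 2L) %% 3L != 0L)
    stop("CDS insert with three_code D is out of frame ",
         "(ATG + insert must end exactly at the trailing GC)", call. = FALSE)
  orf <- paste0("ATG", substr(insert, 1L, n - 2L))
  if (grepl("*", translate_cds(orf), fixed = TRUE))
    stop("CDS insert with three_code D contains an internal stop codon",
         call. = FALSE)
  invisible(TRUE)
}

## ----------------------------------------------------------------- parts --

#' Build an L0 part by simulated SapI entry
#'
#' Simulates entry of a domesticated insert into the SapI entry vector:
#' the entry cassette (modelling the domesticated PCR product) carries the
#' complete BsaI release flanks `GGTCTC-N-<five_code> ... <three_code>-N-GAGACC`
#' between the vector's fixed 3-nt entry overhangs, and replaces the lacZ
#' dropout. The resulting plasmid is SapI-free and releases the insert with
#' the declared odd-alphabet overhangs when cut with BsaI.
#'
#' @param insert Domesticated insert sequence (no internal BsaI/SapI sites).
#' @param five_code,three_code Odd-alphabet overhang codes.
#' @param entry_vector The entry vector molecule (see [make_entry_vector()]).
#' @param label Part label used in the derived name.
#' @param kind Feature kind annotated on the insert (enforces the D rule for
#'   CDS parts ending on D, and triggers syntax-position warnings).
#' @param table Active [overhang_table()].
#' @return An object of class `loop_part`: fields `name`, `five_code`,
#'   `three_code`, `label`, `kind`, `insert`, `insert_span`, `molecule`.
#' @export
build_l0_entry <- function(insert, five_code, three_code, entry_vector,
                           label, kind = "other",
                           table = default_overhang_table()) {
  insert <- toupper(insert)
  stopifnot(five_code %in% ODD_LETTERS, three_code %in% ODD_LETTERS)
  occ <- site_occurrences(insert)
  if (nrow(occ))
    stop("insert is not domesticated; internal sites at ",
         paste(sprintf("%s%s@%d", occ$enzyme, occ$strand, occ$start),
               collapse = ", "), call. = FALSE)
  if (three_code == "D" && kind == "CDS")
    check_d_rule(insert, code_seq(table, "D"))
  check_syntax_position(kind, five_code, three_code)

  sp <- "A"
  five_seq <- code_seq(table, five_code)
  three_seq <- code_seq(table, three_code)
  core <- paste0(table$entry[["left"]],
                 bsai()$recognition, sp, five_seq, insert, three_seq, sp,
                 reverse_complement(bsai()$recognition))
  ins_off <- nchar(table$entry[["left"]]) + 6L + 1L + 4L
  cassette <- sticky_fragment(
    core, left_ov = table$entry[["left"]], right_ov = table$entry[["right"]],
    parent_id = compose_name(five_code, three_code, label),
    features = list(feature(kind, label, ins_off, ins_off + nchar(insert),
                            "+", qualifiers = if (kind == "CDS")
                              list(partial = TRUE) else list())))
  efr <- digest(entry_vector, sapi())
  stable <- !vapply(efr, fragment_has_site, TRUE, enz = sapi())
  stopifnot(sum(stable) == 1L)
  backbone <- efr[[which(stable)]]
  name <- compose_name(five_code, three_code, label)
  mol <- ligate_chain(list(backbone, cassette), "circular", id = name)
  stopifnot(nrow(scan_sites(mol, sapi())) == 0L,
            nrow(scan_sites(mol, bsai())) == 2L)
  rel <- digest(mol, bsai())
  relf <- rel[[which(!vapply(rel, fragment_has_site, TRUE, enz = bsai()))]]
  stopifnot(identical(relf$left_ov, five_seq),
            identical(relf$right_ov, three_seq))
  structure(list(name = name, five_code = five_code, three_code = three_code,
                 label = label, kind = kind, insert = insert,
                 insert_span = c(NA_integer_, NA_integer_), molecule = mol),
            class = "loop_part")
}

#' @export
print.loop_part <- function(x, ...) {
  cat(sprintf("<loop_part> %s (%s, %d bp insert) on %d bp plasmid\n",
              x$name, x$kind, nchar(x$insert), seq_length(x$molecule)))
  invisible(x)
}

## -------------------------------------------------------------- receivers --

KITS <- c("pCA", "pCO", "pSB", "pAN")

receiver_marker <- function(kit, parity) {
  if (parity == "odd") return("kanamycin")
  if (kit %in% c("pCA", "pCO")) "spectinomycin" else "chloramphenicol"
}

#' Build a Loop receiver plasmid
#'
#' Inserts the Loop cassette
#' `UNS1 - [release site, inverted] - accept_left - [assembly site] - lacZ
#' dropout - [assembly site] - accept_right - [release site, inverted] - UNSX`
#' into a site-free backbone, with the parity-correct selection marker
#' (odd: kanamycin; even: spectinomycin for pCA/pCO, chloramphenicol for
#' pSB/pAN). Assembly-enzyme sites leave with the dropout; release-enzyme
#' sites cut inward onto the cargo so the assembled product of this level
#' releases as a substrate of the next.
#'
#' @param kit One of `"pCA"`, `"pCO"`, `"pSB"`, `"pAN"`.
#' @param parity `"odd"` (BsaI assembly / SapI release) or `"even"`.
#' @param position Receiver position 1-4 within the next level's chain.
#' @param backbone A [dna_molecule()] free of BsaI/SapI sites.
#' @param table Active [overhang_table()].
#' @param dropout_seq Dropout stuffer sequence (lacZ placeholder).
#' @return An object of class `loop_receiver`: fields `name`, `kit`,
#'   `parity`, `position`, `marker`, `accept_codes`, `release_codes`,
#'   `molecule`.
#' @export
build_receiver <- function(kit, parity = c("odd", "even"), position,
                           backbone, table = default_overhang_table(),
                           dropout_seq = synthetic_lacz()) {
  parity <- match.arg(parity)
  kit <- match.arg(kit, KITS)
  position <- as.integer(position)
  stopifnot(position >= 1L, position <= 4L)
  occ <- site_occurrences(backbone$sequence)
  if (nrow(occ))
    stop("backbone contains BsaI/SapI sites at ",
         paste(occ$start, collapse = ","), "; domesticate it first",
         call. = FALSE)
  sp <- "A"
  bsa <- bsai()$recognition; sap <- sapi()$recognition
  if (parity == "odd") {
    assembly_enz <- bsai(); release_enz <- sapi()
    accept <- c("A", "F")
    release <- table$sigma_chain[c(position, position + 1L)]
    aL <- code_seq(table, accept[1]); aR <- code_seq(table, accept[2])
    rL <- code_seq(table, release[1]); rR <- code_seq(table, release[2])
    cassette <- paste0(table$uns1,
                       sap, sp, rL, aL, sp, reverse_complement(bsa),
                       dropout_seq,
                       bsa, sp, aR, rR, sp, reverse_complement(sap),
                       table$unsx)
    drop_start <- nchar(table$uns1) + 7L + 1L + 3L + 4L + 1L + 6L
  } else {
    assembly_enz <- sapi(); release_enz <- bsai()
    accept <- c("alpha", "omega")
    release <- table$even_release_chain[c(position, position + 1L)]
    aL <- code_seq(table, accept[1]); aR <- code_seq(table, accept[2])
    rL <- code_seq(table, release[1]); rR <- code_seq(table, release[2])
    cassette <- paste0(table$uns1,
                       bsa, sp, rL, aL, sp, reverse_complement(sap),
                       dropout_seq,
                       sap, sp, aR, rR, sp, reverse_complement(bsa),
                       table$unsx)
    drop_start <- nchar(table$uns1) + 6L + 1L + 4L + 3L + 1L + 7L
  }
  name <- sprintf("%s%s-%d", kit, substr(parity, 1, 1), position)
  marker <- receiver_marker(kit, parity)
  clen <- nchar(cassette)
  feats <- list(
    feature("UNS", "UNS1", 0L, nchar(table$uns1)),
    feature("dropout", "lacZ", drop_start, drop_start + nchar(dropout_seq)),
    feature("UNS", "UNSX", clen - nchar(table$unsx), clen),
    feature("marker", marker, clen + 20L,
            clen + 20L + min(600L, seq_length(backbone) - 40L)))
  bb_feats <- lapply(backbone$features, function(f) {
    f$start <- f$start + clen; f$end <- f$end + clen; f
  })
  mol <- dna_molecule(name, paste0(cassette, backbone$sequence), "circular",
                      features = c(feats, bb_feats),
                      provenance = sprintf("built receiver %s on %s", name,
                                           backbone$id))
  stopifnot(nrow(scan_sites(mol, bsai())) == 2L,
            nrow(scan_sites(mol, sapi())) == 2L)
  structure(list(name = name, kit = kit, parity = parity, position = position,
                 marker = marker, accept_codes = accept,
                 release_codes = release,
                 assembly_enzyme = assembly_enz$name,
                 release_enzyme = release_enz$name, molecule = mol),
            class = "loop_receiver")
}

#' @export
print.loop_receiver <- function(x, ...) {
  cat(sprintf(paste0("<loop_receiver> %s (%s, %s lvl, pos %d): %s marker, ",
                     "accepts %s..%s, releases %s..%s\n"),
              x$name, x$kit, x$parity, x$position, x$marker,
              x$accept_codes[1], x$accept_codes[2],
              x$release_codes[1], x$release_codes[2]))
  invisible(x)
}

#' Build the SapI entry vector
#'
#' The lacZ dropout sits between SapI sites whose recognition sequences
#' leave with the dropout, exposing the fixed 3-nt entry overhangs on the
#' backbone. UNS flanks allow verification PCR of every L0 plasmid.
#'
#' @param backbone Site-free [dna_molecule()].
#' @param table Active [overhang_table()].
#' @param dropout_seq Dropout stuffer sequence.
#' @return A circular [dna_molecule()] named `pL0R-lacZ`.
#' @export
make_entry_vector <- function(backbone, table = default_overhang_table(),
                              dropout_seq = synthetic_lacz()) {
  occ <- site_occurrences(backbone$sequence)
  if (nrow(occ)) stop("entry-vector backbone contains BsaI/SapI sites",
                      call. = FALSE)
  sp <- "A"
  sap <- sapi()$recognition
  cassette <- paste0(table$uns1,
                     table$entry[["left"]], sp, reverse_complement(sap),
                     dropout_seq,
                     sap, sp, table$entry[["right"]],
                     table$unsx)
  clen <- nchar(cassette)
  drop_start <- nchar(table$uns1) + 3L + 1L + 7L
  feats <- list(
    feature("UNS", "UNS1", 0L, nchar(table$uns1)),
    feature("dropout", "lacZ", drop_start, drop_start + nchar(dropout_seq)),
    feature("UNS", "UNSX", clen - nchar(table$unsx), clen),
    feature("marker", "ampicillin", clen + 20L,
            clen + 20L + min(600L, seq_length(backbone) - 40L)))
  bb_feats <- lapply(backbone$features, function(f) {
    f$start <- f$start + clen; f$end <- f$end + clen; f
  })
  mol <- dna_molecule("pL0R-lacZ", paste0(cassette, backbone$sequence),
                      "circular", features = c(feats, bb_feats),
                      provenance = "synthetic entry vector")
  stopifnot(nrow(scan_sites(mol, sapi())) == 2L,
            nrow(scan_sites(mol, bsai())) == 0L)
  mol
}

# Deterministic synthetic lacZ-placeholder stuffer (site-free by
# construction); a fixed LCG keeps it independent of R's RNG state.
synthetic_lacz <- function(len = 300L) {
  x <- 48271
  bases <- character(len)
  for (i in seq_len(len)) {
    x <- (x * 69621) %% 2147483647
    bases[i] <- c("A", "C", "G", "T")[(x %% 4) + 1]
  }
  domesticate(paste(bases, collapse = ""))$sequence
}
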