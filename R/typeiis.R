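# typeiis: Type IIS digestion and sticky-end ligation engine.
#
# Cut geometry. For a recognition site found on the + strand at 0-based
# position s (recognition occupies [s, s+reclen)), the enzyme cuts the top
# (Watson) strand at boundary s + reclen + spacer and the bottom (Crick)
# strand overhang_len further, leaving a 5' overhang whose top-strand
# sequence is [cut_top, cut_top + overhang_len). For a site on the - strand
# (reverse complement of the recognition found on the top strand at s) the
# Watson cut lies upstream at s - spacer - overhang_len. In both cases
# cut_bottom = cut_top + overhang_len in top-strand coordinates.
#
# Fragment convention: a fragment's core runs between successive Watson
# cuts and INCLUDES its left overhang bases while EXCLUDING its right
# overhang bases, so that circular parent length == sum of core lengths.

#' Define a Type IIS enzyme
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (top strand, 5'->3').
#' @param spacer Nucleotides between the recognition 3' end and the
#'   top-strand cut.
#' @param overhang_len Length of the 5' overhang left by the cut.
#' @return An object of class `tiis_enzyme`.
#' @examples
#' enzyme("BsaI", "GGTCTC", 1, 4)
#' @export
enzyme <- function(name, recognition, spacer, overhang_len) {
  recognition <- toupper(recognition)
  stopifnot(nchar(recognition) > 0, spacer >= 0, overhang_len >= 0)
  structure(list(name = name, recognition = recognition,
                 spacer = as.integer(spacer),
                 overhang_len = as.integer(overhang_len)),
            class = "tiis_enzyme")
}

#' Shipped enzymes
#'
#' `bsai()`: GGTCTC(N1), 4-nt 5' overhang, used at odd assembly levels.
#' `sapi()`: GCTCTTC(N1), 3-nt 5' overhang, used at even assembly levels.
#' @return A `tiis_enzyme`.
#' @export
bsai <- function() enzyme("BsaI", "GGTCTC", 1L, 4L)

#' @rdname bsai
#' @export
sapi <- function() enzyme("SapI", "GCTCTTC", 1L, 3L)

#' Resolve an enzyme argument
#' @param x A `tiis_enzyme` or the strings `"bsai"`/`"sapi"` (case-insensitive).
#' @return A `tiis_enzyme`.
#' @export
as_enzyme <- function(x) {
  if (inherits(x, "tiis_enzyme")) return(x)
  switch(tolower(as.character(x)), bsai = bsai(), sapi = sapi(),
         stop("unknown enzyme: ", x, call. = FALSE))
}

# All 0-based match starts of fixed pattern `pat` in `seq`; wrap-aware when
# circular (matches may span the origin). Patterns containing N never match
# (fixed matching), the conservative site-calling rule.
find_matches0 <- function(seq, pat, circular) {
  L <- nchar(seq); w <- nchar(pat)
  if (L < w) return(integer())
  hay <- if (circular && w > 1L) paste0(seq, substr(seq, 1L, w - 1L)) else seq
  m <- gregexpr(pat, hay, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  starts <- as.integer(m) - 1L
  starts[starts < L]
}

#' Scan a molecule for Type IIS sites
#'
#' Finds all occurrences of the recognition sequence on both strands,
#' including matches spanning the origin of circular molecules, and computes
#' the Watson (`cut_top`) and Crick (`cut_bottom`) cut coordinates from the
#' enzyme geometry. On linear molecules, sites whose cuts would fall outside
#' the molecule are dropped. Result is sorted by `recognition_start`, then
#' strand.
#'
#' @param mol A [dna_molecule()].
#' @param enz A `tiis_enzyme` (or `"bsai"`/`"sapi"`).
#' @return A data.frame with columns `enzyme`, `strand`, `recognition_start`,
#'   `cut_top`, `cut_bottom` (0-based; cut positions are boundary indices).
#' @export
scan_sites <- function(mol, enz) {
  enz <- as_enzyme(enz)
  L <- seq_length(mol)
  circ <- mol$topology == "circular"
  rec <- enz$recognition; w <- nchar(rec)
  reach <- w + enz$spacer + enz$overhang_len
  rows <- list()
  plus <- find_matches0(mol$sequence, rec, circ)
  for (s in plus) {
    ct <- s + w + enz$spacer
    cb <- ct + enz$overhang_len
    if (!circ && cb > L) next
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = enz$name, strand = "+", recognition_start = s,
      cut_top = if (circ) ct %% L else ct,
      cut_bottom = if (circ) cb %% L else cb)
  }
  rc <- reverse_complement(rec)
  minus <- find_matches0(mol$sequence, rc, circ)
  for (s in minus) {
    ct <- s - enz$spacer - enz$overhang_len
    cb <- s - enz$spacer
    if (!circ && ct < 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      enzyme = enz$name, strand = "-", recognition_start = s,
      cut_top = if (circ) ct %% L else ct,
      cut_bottom = if (circ) cb %% L else cb)
  }
  if (!length(rows))
    return(data.frame(enzyme = character(), strand = character(),
                      recognition_start = integer(), cut_top = integer(),
                      cut_bottom = integer()))
  if (circ && L < reach)
    stop("circular molecule shorter than the enzyme's cut reach", call. = FALSE)
  df <- do.call(rbind, rows)
  df[order(df$recognition_start, df$strand), , drop = FALSE]
}

#' Construct a sticky-ended fragment
#'
#' Overhangs are 5' extensions; both are expressed as the top-strand sequence
#' of the duplex they form on ligation. The left overhang bases are the first
#' `nchar(left_ov)` bases of `core`; the right overhang bases are *not* part
#' of `core` (they open the neighbouring fragment's core).
#'
#' @param core Top-strand sequence between the fragment's two Watson cuts.
#' @param left_ov,right_ov Overhang sequences (possibly `""` for blunt ends).
#' @param parent_id Id of the parent molecule.
#' @param source_start,source_end 0-based half-open span in the parent
#'   (`source_end` may exceed the parent length for origin-wrapping fragments).
#' @param features Features carried along, in fragment-local coordinates.
#' @return An object of class `sticky_fragment`.
#' @export
sticky_fragment <- function(core, left_ov = "", right_ov = "",
                            parent_id = "", source_start = NA_integer_,
                            source_end = NA_integer_, features = list()) {
  stopifnot(nchar(core) >= nchar(left_ov))
  structure(list(core = core, left_ov = left_ov, right_ov = right_ov,
                 parent_id = parent_id, source_start = source_start,
                 source_end = source_end, features = features),
            class = "sticky_fragment")
}

#' @export
print.sticky_fragment <- function(x, ...) {
  cat(sprintf("<sticky_fragment> %d bp core [%s ... %s] from %s\n",
              nchar(x$core),
              if (nzchar(x$left_ov)) x$left_ov else "blunt",
              if (nzchar(x$right_ov)) x$right_ov else "blunt",
              x$parent_id))
  invisible(x)
}

# Does this fragment's duplex still carry a recognition site of `enz`
# (either strand)? Used for the end-product stability rule and for telling
# release fragments from vector-side fragments.
fragment_has_site <- function(frag, enz) {
  enz <- as_enzyme(enz)
  grepl(enz$recognition, frag$core, fixed = TRUE) ||
    grepl(reverse_complement(enz$recognition), frag$core, fixed = TRUE)
}

#' Flip a sticky fragment to its reverse complement
#' @param frag A [sticky_fragment()].
#' @return The fragment in the opposite orientation.
#' @export
flip_fragment <- function(frag) {
  lo <- nchar(frag$left_ov); Lc <- nchar(frag$core); ro <- nchar(frag$right_ov)
  new_core <- reverse_complement(paste0(substr(frag$core, lo + 1L, Lc),
                                        frag$right_ov))
  newLc <- nchar(new_core)
  # new core covers the old local interval [lo, Lc + ro) reverse-complemented;
  # an old span [a,b) maps to [(Lc+ro) - b, (Lc+ro) - a) shifted by -lo.
  # Features extending into a lost overhang region are dropped.
  feats <- lapply(frag$features, function(f) {
    a2 <- (Lc + ro) - f$end - lo
    b2 <- (Lc + ro) - f$start - lo
    if (a2 < 0L || b2 > newLc) return(NULL)
    feature(f$kind, f$label, a2, b2, if (f$strand == "+") "-" else "+",
            f$qualifiers)
  })
  feats <- Filter(Negate(is.null), feats)
  sticky_fragment(new_core,
                  left_ov = reverse_complement(frag$right_ov),
                  right_ov = reverse_complement(frag$left_ov),
                  parent_id = frag$parent_id,
                  source_start = frag$source_start,
                  source_end = frag$source_end,
                  features = feats)
}

#' Digest a molecule with one or more Type IIS enzymes
#'
#' Fragments run between successive Watson cuts. Each fragment's core
#' includes its left overhang bases and excludes its right overhang bases,
#' so for a circular parent the core lengths sum exactly to the parent
#' length. An uncut linear molecule is returned whole (blunt at both ends);
#' an uncut circular molecule is an error of class `loop_uncut_circular`.
#'
#' @param mol A [dna_molecule()].
#' @param enzymes A `tiis_enzyme`, enzyme name, or list of either (combined
#'   simultaneous digestion).
#' @return List of [sticky_fragment()]s, ordered by position in the parent.
#' @export
digest <- function(mol, enzymes) {
  if (inherits(enzymes, "tiis_enzyme") || is.character(enzymes))
    enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, as_enzyme)
  L <- seq_length(mol)
  circ <- mol$topology == "circular"
  cuts <- integer(); ovs <- integer()
  for (enz in enzymes) {
    hits <- scan_sites(mol, enz)
    if (nrow(hits)) {
      cuts <- c(cuts, hits$cut_top)
      ovs <- c(ovs, rep.int(enz$overhang_len, nrow(hits)))
    }
  }
  keep <- !duplicated(cuts)
  cuts <- cuts[keep]; ovs <- ovs[keep]
  o <- order(cuts); cuts <- cuts[o]; ovs <- ovs[o]
  if (!length(cuts)) {
    if (circ)
      stop(structure(class = c("loop_uncut_circular", "error", "condition"),
                     list(message = paste0("uncut circular molecule: ", mol$id),
                          call = NULL)))
    return(list(sticky_fragment(mol$sequence, "", "", mol$id, 0L, L,
                                features = mol$features)))
  }
  frag_at <- function(start, end, lov, rov) {
    core <- subseq0(mol$sequence, start, end)
    feats <- list()
    for (f in mol$features) {
      fs <- f$start; fe <- f$end
      # try both the unwrapped and the +L-shifted placement of the feature
      for (off in c(0L, L)) {
        if (fs + off >= start && fe + off <= end) {
          feats[[length(feats) + 1L]] <-
            feature(f$kind, f$label, fs + off - start, fe + off - start,
                    f$strand, f$qualifiers)
          break
        }
      }
    }
    sticky_fragment(core, lov, rov, mol$id, start, end, feats)
  }
  frags <- list()
  if (circ) {
    k <- length(cuts)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      start <- cuts[i]
      end <- if (j == 1L) cuts[1L] + L else cuts[j]
      if (end <= start) end <- end + L
      frags[[i]] <- frag_at(start, end,
                            subseq0(mol$sequence, cuts[i], cuts[i] + ovs[i]),
                            subseq0(mol$sequence, cuts[j], cuts[j] + ovs[j]))
    }
  } else {
    bounds <- c(0L, cuts, L)
    bovs <- c(0L, ovs, 0L)
    for (i in seq_len(length(bounds) - 1L)) {
      start <- bounds[i]; end <- bounds[i + 1L]
      if (end <= start) next
      lov <- if (bovs[i] > 0L) substr(mol$sequence, start + 1L, start + bovs[i]) else ""
      rov <- if (bovs[i + 1L] > 0L)
        substr(mol$sequence, end + 1L, end + bovs[i + 1L]) else ""
      frags[[length(frags) + 1L]] <- frag_at(start, end, lov, rov)
    }
  }
  frags
}

# Sequence of a ligated chain of oriented fragments. For circular products
# the sequence is the concatenation of cores; for linear products the
# trailing right overhang (bottom-strand 5' extension) is appended so the
# string covers the full duplex extent.
chain_sequence <- function(frags, circular) {
  s <- paste(vapply(frags, function(f) f$core, ""), collapse = "")
  if (!circular) s <- paste0(s, frags[[length(frags)]]$right_ov)
  s
}

chain_features <- function(frags, circular, scars = TRUE) {
  feats <- list(); off <- 0L
  n <- length(frags)
  for (i in seq_len(n)) {
    f <- frags[[i]]
    ov <- nchar(f$left_ov)
    if (scars && ov > 0L && (circular || i > 1L))
      feats[[length(feats) + 1L]] <-
        feature("scar", f$left_ov, off, off + ov, "+",
                list(junction = TRUE))
    for (ft in f$features) {
      ft$start <- ft$start + off; ft$end <- ft$end + off
      feats[[length(feats) + 1L]] <- ft
    }
    off <- off + nchar(f$core)
  }
  feats
}

#' Assemble a molecule from an ordered, oriented fragment chain
#'
#' Junction compatibility (`right_ov(i) == left_ov(i+1)`, non-empty, no `N`)
#' is checked; for circular products the last-to-first junction must close.
#' Scar features are annotated at each junction.
#'
#' @param frags List of [sticky_fragment()]s in ligation order/orientation.
#' @param topology `"circular"` or `"linear"`.
#' @param id Id for the product molecule.
#' @return A [dna_molecule()].
#' @export
ligate_chain <- function(frags, topology = c("circular", "linear"),
                         id = "product") {
  topology <- match.arg(topology)
  circ <- topology == "circular"
  n <- length(frags)
  for (i in seq_len(if (circ) n else n - 1L)) {
    j <- if (i == n) 1L else i + 1L
    if (!overhangs_ligate(frags[[i]]$right_ov, frags[[j]]$left_ov))
      stop("incompatible junction between fragments ", i, " and ", j,
           call. = FALSE)
  }
  dna_molecule(id, chain_sequence(frags, circ), topology,
               features = chain_features(frags, circ))
}

# Both overhangs are stored as the same top-strand text, so sticky ligation
# is plain string equality; blunt-blunt joining is excluded, as is any
# overhang containing N (conservative: N never base-pairs here).
overhangs_ligate <- function(right_ov, left_ov) {
  nzchar(right_ov) && identical(right_ov, left_ov) &&
    !grepl("N", right_ov, fixed = TRUE)
}

canonical_cycle_key <- function(idx_orient) {
  # idx_orient: character vector of "i+"/"i-" tokens; canonical form over
  # rotation and reflection (reflection reverses order and flips tokens)
  n <- length(idx_orient)
  flip <- function(v) {
    rev(vapply(v, function(t) {
      i <- substr(t, 1, nchar(t) - 1L)
      o <- substr(t, nchar(t), nchar(t))
      paste0(i, if (o == "+") "-" else "+")
    }, ""))
  }
  best <- NULL
  for (v in list(idx_orient, flip(idx_orient))) {
    for (r in seq_len(n)) {
      rot <- paste(c(v[r:n], v[seq_len(r - 1L)]), collapse = "|")
      if (is.null(best) || rot < best) best <- rot
    }
  }
  best
}

#' Enumerate ligation products of a fragment pool
#'
#' Every distinct product whose junctions are all complementary sticky-end
#' pairs is returned: circular products are unique up to rotation and
#' reflection, linear products up to reversal. Fragments may appear in either
#' orientation, each at most `max_copies` times. Output is deterministic,
#' sorted by length then canonical sequence. Blunt-blunt ligation is
#' excluded.
#'
#' @param pool List of [sticky_fragment()]s.
#' @param mode `"circular_only"` or `"include_linear"`.
#' @param max_copies Maximum copies of any one pool fragment per product.
#' @param cap Guard on the number of chains explored; exceeding it raises an
#'   error of class `loop_combinatorial_cap` listing duplicated overhangs.
#' @return List of products; each has elements `topology`, `parts`
#'   (data.frame of pool index + orientation), `junctions` (overhang
#'   sequences) and `molecule` (a [dna_molecule()]).
#' @export
enumerate_ligations <- function(pool, mode = c("circular_only", "include_linear"),
                                max_copies = 1L, cap = 20000L) {
  mode <- match.arg(mode)
  stopifnot(length(pool) >= 1L, max_copies >= 1L)
  n <- length(pool)
  oriented <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    oriented[[2L * i - 1L]] <- pool[[i]]
    oriented[[2L * i]] <- flip_fragment(pool[[i]])
  }
  tok <- function(i, o) paste0(i, if (o == 1L) "+" else "-")
  results <- new.env(parent = emptyenv())
  explored <- 0L
  overflow <- FALSE
  emit <- function(chain, circular) {
    idx <- vapply(chain, `[[`, 0L, "idx")
    ori <- vapply(chain, `[[`, 0L, "ori")
    toks <- mapply(tok, idx, ori)
    key <- if (circular) canonical_cycle_key(toks) else {
      fwd <- paste(toks, collapse = "|")
      rtoks <- rev(vapply(toks, function(t) {
        i <- substr(t, 1, nchar(t) - 1L); o <- substr(t, nchar(t), nchar(t))
        paste0(i, if (o == "+") "-" else "+")
      }, ""))
      min(fwd, paste(rtoks, collapse = "|"))
    }
    key <- paste0(if (circular) "c:" else "l:", key)
    if (!is.null(results[[key]])) return()
    frs <- lapply(chain, function(e) oriented[[2L * e$idx - (e$ori == 1L)]])
    results[[key]] <- list(
      topology = if (circular) "circular" else "linear",
      parts = data.frame(pool_index = idx,
                         orientation = ifelse(ori == 1L, "+", "-")),
      junctions = vapply(frs, function(f) f$left_ov, "")[
        if (circular) seq_along(frs) else -1L],
      molecule = dna_molecule(paste0("lig_", length(ls(results))),
                              chain_sequence(frs, circular),
                              if (circular) "circular" else "linear",
                              features = chain_features(frs, circular)))
  }
  counts <- integer(n)
  chain <- list()
  extend <- function() {
    explored <<- explored + 1L
    if (explored > cap) { overflow <<- TRUE; return() }
    last <- chain[[length(chain)]]
    lastf <- oriented[[2L * last$idx - (last$ori == 1L)]]
    first <- chain[[1L]]
    firstf <- oriented[[2L * first$idx - (first$ori == 1L)]]
    if (overhangs_ligate(lastf$right_ov, firstf$left_ov))
      emit(chain, circular = TRUE)
    if (mode == "include_linear") emit(chain, circular = FALSE)
    for (i in seq_len(n)) {
      if (counts[i] >= max_copies) next
      for (o in c(1L, 2L)) {
        cand <- oriented[[2L * i - (o == 1L)]]
        if (!overhangs_ligate(lastf$right_ov, cand$left_ov)) next
        counts[i] <<- counts[i] + 1L
        chain[[length(chain) + 1L]] <<- list(idx = i, ori = o)
        extend()
        chain[[length(chain)]] <<- NULL
        counts[i] <<- counts[i] - 1L
        if (overflow) return()
      }
    }
  }
  for (i in seq_len(n)) {
    for (o in c(1L, 2L)) {   # both seed orientations: linear chains are only
      counts[i] <- 1L        # deduplicated up to whole-chain reversal
      chain <- list(list(idx = i, ori = o))
      extend()
      counts[i] <- 0L
      if (overflow) break
    }
    if (overflow) break
  }
  if (overflow) {
    lovs <- vapply(pool, function(f) f$left_ov, "")
    dup <- unique(lovs[duplicated(lovs) & nzchar(lovs)])
    stop(structure(class = c("loop_combinatorial_cap", "error", "condition"),
                   list(message = paste0(
                     "ligation enumeration exceeded cap (", cap, " chains); ",
                     "duplicated left overhangs: ",
                     if (length(dup)) paste(dup, collapse = ",") else "none"),
                     call = NULL)))
  }
  out <- mget(ls(results), envir = results)
  ord <- order(vapply(out, function(p) nchar(p$molecule$sequence), 0L),
               vapply(out, function(p)
                 if (p$topology == "circular")
                   canonical_rotation(p$molecule) else p$molecule$sequence, ""))
  unname(out[ord])
}

#' Check a set of overhangs for ligation-fidelity hazards
#'
#' Flags duplicates, palindromes (self-complementary overhangs, which can
#' ligate head-to-head) and complement collisions (`x == revcomp(y)` for
#' `x != y`, which cross-ligate).
#'
#' @param overhangs Character vector of equal-length overhang sequences.
#' @return List with elements `duplicates`, `palindromes`,
#'   `complement_collisions` (data.frame of pairs) and logical `clean`.
#' @export
fidelity_check <- function(overhangs) {
  overhangs <- toupper(overhangs)
  if (length(unique(nchar(overhangs))) > 1L)
    stop("all overhangs must have the same length", call. = FALSE)
  dup <- unique(overhangs[duplicated(overhangs)])
  uo <- unique(overhangs)
  rc <- reverse_complement(uo)
  pal <- uo[uo == rc]
  pairs <- data.frame(x = character(), y = character())
  if (length(uo) > 1L) {
    for (i in seq_along(uo)) for (j in seq_along(uo)) {
      if (i < j && rc[i] == uo[j])
        pairs <- rbind(pairs, data.frame(x = uo[i], y = uo[j]))
    }
  }
  list(duplicates = dup, palindromes = pal, complement_collisions = pairs,
       clean = !length(dup) && !length(pal) && !nrow(pairs))
}

## ------------------------------------------------------- one-pot assembly --

#' Simulate a one-pot Golden Gate reaction
#'
#' Digests the receiver and all insert plasmids with the assembly enzyme,
#' identifies each plasmid's stable fragment (the one not carrying a
#' recognition site: the receiver's backbone, each insert's release
#' fragment), validates the overhang chain from the receiver's left accept
#' overhang to its right one, and enumerates circular products. Products are
#' classified by the Golden Gate end-state abstraction: a circular product is
#' *stable* iff it carries no intact recognition site of the reaction enzyme.
#'
#' Classification: `intended` = backbone plus exactly one release fragment
#' per insert, dropout absent; `parental` = re-ligation reconstituting an
#' input plasmid (still carries sites, e.g. lacZ+ receiver); `misassembly` =
#' any other stable circular product.
#'
#' @param receiver A circular [dna_molecule()] (or `loop_receiver`) with a
#'   dropout cassette.
#' @param inserts List of circular [dna_molecule()]s (or `loop_part`s).
#' @param enz Assembly enzyme.
#' @param max_copies Copy bound for product enumeration (1 = intended-product
#'   search; 2 explores concatemeric misassemblies).
#' @param product_id Id given to the intended product.
#' @return An `assembly_report`: list with `intended`, `parental`,
#'   `misassembly` (lists of products), `chain` (ordered insert ids) and
#'   `n_products`.
#' @export
one_pot_assemble <- function(receiver, inserts, enz, max_copies = 1L,
                             product_id = "assembly") {
  enz <- as_enzyme(enz)
  rec_mol <- if (inherits(receiver, "loop_receiver")) receiver$molecule else receiver
  ins_mols <- lapply(inserts, function(x)
    if (inherits(x, "loop_part")) x$molecule else x)
  if (rec_mol$topology != "circular" ||
      any(vapply(ins_mols, function(m) m$topology, "") != "circular"))
    stop("receiver and inserts must be circular plasmids", call. = FALSE)

  rfr <- digest(rec_mol, enz)
  stable <- !vapply(rfr, fragment_has_site, TRUE, enz = enz)
  if (sum(stable) != 1L)
    stop("receiver must yield exactly one site-free backbone fragment (got ",
         sum(stable), ")", call. = FALSE)
  backbone <- rfr[[which(stable)]]
  dropouts <- rfr[!stable]

  releases <- list(); vector_side <- list()
  for (m in ins_mols) {
    fr <- digest(m, enz)
    st <- !vapply(fr, fragment_has_site, TRUE, enz = enz)
    if (sum(st) != 1L)
      stop("insert ", m$id, " must yield exactly one site-free release ",
           "fragment (got ", sum(st), ")", call. = FALSE)
    releases[[length(releases) + 1L]] <- fr[[which(st)]]
    vector_side <- c(vector_side, fr[!st])
  }

  # overhang chain: backbone right overhang -> ... -> backbone left overhang
  chain_order <- integer()
  cur <- backbone$right_ov
  remaining <- seq_along(releases)
  repeat {
    if (cur == backbone$left_ov && !length(remaining)) break
    hit <- remaining[vapply(remaining, function(i)
      identical(releases[[i]]$left_ov, cur), TRUE)]
    if (length(hit) == 0L) {
      stop(structure(class = c("loop_chain_error", "error", "condition"),
                     list(message = paste0(
                       "chain error: no insert starts at overhang ", cur,
                       if (length(remaining)) paste0(
                         " (unplaced: ",
                         paste(vapply(remaining, function(i)
                           releases[[i]]$parent_id, ""), collapse = ","), ")")
                       else " (chain closed early)"),
                       call = NULL)))
    }
    if (length(hit) > 1L)
      stop(structure(class = c("loop_chain_error", "error", "condition"),
                     list(message = paste0(
                       "chain error: overhang ", cur, " duplicated by ",
                       paste(vapply(hit, function(i)
                         releases[[i]]$parent_id, ""), collapse = " and ")),
                       call = NULL)))
    chain_order <- c(chain_order, hit)
    remaining <- setdiff(remaining, hit)
    cur <- releases[[hit]]$right_ov
  }
  if (cur != backbone$left_ov)
    stop(structure(class = c("loop_chain_error", "error", "condition"),
                   list(message = paste0("chain error: chain ends at ", cur,
                                         " but receiver accepts ",
                                         backbone$left_ov), call = NULL)))

  intended_mol <- ligate_chain(c(list(backbone), releases[chain_order]),
                               "circular", id = product_id)
  stopifnot(nrow(scan_sites(intended_mol, enz)) == 0L)

  pool <- c(list(backbone), releases, dropouts, vector_side)
  products <- enumerate_ligations(pool, "circular_only",
                                  max_copies = max_copies)
  canon_int <- canonical_rotation(intended_mol)
  canon_parental <- vapply(c(list(rec_mol), ins_mols), canonical_rotation, "")
  intended <- list(); parental <- list(); misassembly <- list()
  for (p in products) {
    ck <- canonical_rotation(p$molecule)
    if (ck == canon_int) { intended <- c(intended, list(p)); next }
    if (ck %in% canon_parental) { parental <- c(parental, list(p)); next }
    if (nrow(scan_sites(p$molecule, enz)) == 0L)
      misassembly <- c(misassembly, list(p))
    # unstable non-parental intermediates are transient: dropped
  }
  structure(list(intended = list(intended_mol),
                 intended_products = intended,
                 parental = parental, misassembly = misassembly,
                 chain = vapply(releases[chain_order], function(f)
                   f$parent_id, ""),
                 backbone_core_len = nchar(backbone$core),
                 insert_core_lens = vapply(releases[chain_order], function(f)
                   nchar(f$core), 0L),
                 enzyme = enz$name, n_products = length(products)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf(paste0("<assembly_report> %s reaction: %d circular product(s); ",
                     "%d intended, %d parental, %d misassembly\n"),
              x$enzyme, x$n_products, length(x$intended_products),
              length(x$parental), length(x$misassembly)))
  cat("  chain:", paste(x$chain, collapse = " -> "), "\n")
  invisible(x)
}
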