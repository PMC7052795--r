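# verify: in-silico verification readouts and bench metrics as calculators.

#' Predict a restriction digest profile
#'
#' Combined simultaneous digestion with all given enzymes; band lengths are
#' fragment core lengths, sorted descending, so for circular sources they
#' sum exactly to the molecule length. An uncut circular molecule yields a
#' single full-length band flagged `uncut`.
#'
#' @param mol A [dna_molecule()].
#' @param enzymes Enzyme(s) accepted by [digest()].
#' @return A `digest_profile`: list with `molecule_id`, `enzymes`,
#'   `lengths` (descending), `uncut`.
#' @export
digest_profile <- function(mol, enzymes) {
  if (inherits(enzymes, "tiis_enzyme") || is.character(enzymes))
    enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, as_enzyme)
  frags <- tryCatch(digest(mol, enzymes), loop_uncut_circular = function(e) NULL)
  uncut <- is.null(frags)
  lengths <- if (uncut) seq_length(mol)
             else sort(vapply(frags, function(f) nchar(f$core), 0L),
                       decreasing = TRUE)
  structure(list(molecule_id = mol$id,
                 enzymes = vapply(enzymes, function(e) e$name, ""),
                 lengths = lengths, uncut = uncut),
            class = "digest_profile")
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest_profile> %s + %s: %s bp%s\n", x$molecule_id,
              paste(x$enzymes, collapse = "/"),
              paste(x$lengths, collapse = ", "),
              if (x$uncut) " [uncut]" else ""))
  invisible(x)
}

# exact bipartite matching of observed to expected bands within tolerance;
# brute-force recursion (fine for the <= 12 bands of a plasmid digest)
match_bands <- function(obs, exp, tol) {
  n <- length(obs)
  if (n != length(exp)) return(NULL)
  assign_rec <- function(i, free) {
    if (i > n) return(integer())
    for (j in free) {
      if (abs(obs[i] - exp[j]) <= tol) {
        rest <- assign_rec(i + 1L, setdiff(free, j))
        if (!is.null(rest)) return(c(j, rest))
      }
    }
    NULL
  }
  assign_rec(1L, seq_len(n))
}

#' Score an observed digest profile against the expected pattern
#'
#' The verdict is true iff a one-to-one pairing of observed and expected
#' bands exists with every `|obs - exp| <= tolerance_bp` (exact matching,
#' not greedy). Symmetric in its two arguments and monotone in tolerance.
#'
#' @param observed,expected Numeric band lengths (bp) or `digest_profile`s.
#' @param tolerance_bp Per-band tolerance in bp (gel resolution; default 100).
#' @return A `profile_match`: `verdict`, `pairing` (data.frame observed /
#'   expected / delta), `tolerance_bp`.
#' @export
compare_profile <- function(observed, expected, tolerance_bp = 100) {
  stopifnot(tolerance_bp >= 0)
  if (inherits(observed, "digest_profile")) observed <- observed$lengths
  if (inherits(expected, "digest_profile")) expected <- expected$lengths
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  exp <- sort(as.numeric(expected), decreasing = TRUE)
  pairing <- if (length(obs) == length(exp))
    match_bands(obs, exp, tolerance_bp) else NULL
  verdict <- !is.null(pairing)
  structure(list(
    verdict = verdict,
    observed = obs, expected = exp, tolerance_bp = tolerance_bp,
    pairing = if (verdict) data.frame(observed = obs, expected = exp[pairing],
                                      delta = obs - exp[pairing])
              else NULL),
    class = "profile_match")
}

#' @export
print.profile_match <- function(x, ...) {
  cat(sprintf("<profile_match> %s at +/-%g bp (%d vs %d bands)\n",
              if (x$verdict) "MATCH" else "MISMATCH", x$tolerance_bp,
              length(x$observed), length(x$expected)))
  invisible(x)
}

# 0-based starts where `primer` matches `hay` with at most `mm` mismatches
primer_sites <- function(hay, primer, circular, mm = 0L) {
  if (mm == 0L) return(find_matches0(hay, primer, circular))
  L <- nchar(hay); w <- nchar(primer)
  ext <- if (circular) paste0(hay, substr(hay, 1L, w - 1L)) else hay
  pv <- strsplit(primer, "")[[1]]
  starts <- integer()
  for (s in 0:(nchar(ext) - w)) {
    if (s >= L) break
    win <- strsplit(substr(ext, s + 1L, s + w), "")[[1]]
    if (sum(win != pv) <= mm) starts <- c(starts, s)
  }
  starts
}

#' In-silico PCR
#'
#' Finds exact (or up to `max_mismatches`) binding sites of the forward
#' primer on the plus strand and the reverse primer on the minus strand,
#' wrap-aware on circular templates, and reports every amplicon spanning a
#' forward site to a downstream reverse site. More than one binding site for
#' either primer flags the result ambiguous.
#'
#' @param mol A [dna_molecule()].
#' @param fwd,rev Primer sequences, 5'->3', each >= 12 nt.
#' @param max_mismatches Allowed mismatches per primer (default 0).
#' @return List of amplicons (`start`, `end` 0-based half-open in template
#'   coordinates, `length`, `sequence`), with attribute `ambiguous`.
#' @export
insilico_pcr <- function(mol, fwd, rev, max_mismatches = 0L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 12L || nchar(rev) < 12L)
    stop("primers must be at least 12 nt", call. = FALSE)
  circ <- mol$topology == "circular"
  L <- seq_length(mol)
  fsites <- primer_sites(mol$sequence, fwd, circ, max_mismatches)
  rsites <- primer_sites(mol$sequence, reverse_complement(rev), circ,
                         max_mismatches)
  ambiguous <- length(fsites) > 1L || length(rsites) > 1L
  amps <- list()
  for (f in fsites) for (r in rsites) {
    rend <- r + nchar(rev)
    if (circ) {
      end <- if (rend > f) rend else rend + L
      if (end - f > L) next  # primers overlapping themselves
      amps[[length(amps) + 1L]] <-
        list(start = f, end = end, length = end - f,
             sequence = subseq0(mol$sequence, f, end))
    } else if (rend > f) {
      amps[[length(amps) + 1L]] <-
        list(start = f, end = rend, length = rend - f,
             sequence = substr(mol$sequence, f + 1L, rend))
    }
  }
  structure(amps, ambiguous = ambiguous)
}

#' Assembly efficiency and productivity from colony counts
#'
#' Efficiency is the percentage of fluorescent (correct-phenotype) colonies
#' among all colonies not expressing the dropout marker (white colonies);
#' blue (lacZ+, parental) colonies are excluded from both metrics.
#' Productivity scales the white-colony count by the plated-fraction factor
#' (default 30: 10 ul plated of 300 ul recovery).
#'
#' @param counts Named list/vector: `sfgfp`, `white_nonfluorescent`, `blue`.
#' @param plated_fraction_factor Scale-up from plate count to reaction.
#' @return List: `efficiency_pct` (NA with `note` when no white colonies),
#'   `productivity`, `excluded_blue`.
#' @export
efficiency_metrics <- function(counts, plated_fraction_factor = 30) {
  g <- counts[["sfgfp"]]; w <- counts[["white_nonfluorescent"]]
  b <- if (!is.null(counts[["blue"]])) counts[["blue"]] else 0
  stopifnot(g >= 0, w >= 0, b >= 0)
  denom <- g + w
  list(efficiency_pct = if (denom > 0) 100 * g / denom else NA_real_,
       productivity = denom * plated_fraction_factor,
       excluded_blue = b,
       note = if (denom == 0) "efficiency undefined: no white colonies"
              else NULL)
}

#' Concatemer ladder of a chained fragment pool
#'
#' For a pool forming one linear overhang chain (e.g. the four SapI release
#' fragments alpha->omega of a receiver-free level-4 reaction), reports the
#' product length of every contiguous sub-chain of n fragments, n = 1..pool
#' size — the monomer/dimer/trimer/... ladder seen on a pulsed-field gel —
#' with the full-length product singled out.
#'
#' @param pool List of [sticky_fragment()]s forming a chain.
#' @return List: `table` (data.frame `n`, `start`, `length_bp`),
#'   `full_length_bp`, `order` (pool indices in chain order).
#' @export
concatemer_ladder <- function(pool) {
  k <- length(pool)
  lovs <- vapply(pool, function(f) f$left_ov, "")
  rovs <- vapply(pool, function(f) f$right_ov, "")
  start <- which(!lovs %in% rovs)
  if (length(start) != 1L)
    stop("pool does not form a single linear chain (",
         length(start), " candidate start fragments)", call. = FALSE)
  ord <- start
  while (length(ord) < k) {
    nxt <- which(lovs == rovs[ord[length(ord)]])
    nxt <- setdiff(nxt, ord)
    if (length(nxt) != 1L)
      stop("pool does not form a single linear chain (at overhang ",
           rovs[ord[length(ord)]], ")", call. = FALSE)
    ord <- c(ord, nxt)
  }
  rows <- list()
  for (n in seq_len(k)) {
    for (s in seq_len(k - n + 1L)) {
      idx <- ord[s:(s + n - 1L)]
      len <- nchar(chain_sequence(pool[idx], circular = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(n = n, start = s,
                                              length_bp = len)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, full_length_bp = tab$length_bp[tab$n == k],
       order = ord)
}
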