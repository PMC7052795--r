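# seqio: DNA record model with strand/topology semantics and GenBank/FASTA I/O.
# Coordinates are 0-based half-open everywhere inside the package; they are
# converted to 1-based inclusive only when touching the GenBank format.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create an annotated DNA molecule
#'
#' The universal substrate of the package: an uppercase DNA string over
#' `A,C,G,T,N` with linear or circular topology and a list of features.
#' Circular molecules are stored unwrapped; features may wrap the origin
#' (span end larger than the sequence length) on circular topology only.
#'
#' @param id Unique identifier (string).
#' @param sequence DNA string; lower case input is uppercased.
#' @param topology `"linear"` or `"circular"`.
#' @param features List of features built with [feature()].
#' @param provenance Free-text provenance note.
#' @return An object of class `dna_molecule` with fields `id`, `sequence`,
#'   `topology`, `features`, `provenance`.
#' @examples
#' dna_molecule("p1", "ACGTACGT", "circular")
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"),
                         features = list(), provenance = "") {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
  if (length(bad))
    stop("sequence contains residues outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","), call. = FALSE)
  mol <- structure(list(id = as.character(id), sequence = sequence,
                        topology = topology, features = features,
                        provenance = provenance),
                   class = "dna_molecule")
  for (f in features) validate_feature(f, mol)
  mol
}

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp %s, %d feature(s)\n",
              x$id, nchar(x$sequence), x$topology, length(x$features)))
  invisible(x)
}

#' Sequence length of a molecule
#' @param mol A [dna_molecule()].
#' @return Integer number of base pairs.
#' @export
seq_length <- function(mol) nchar(mol$sequence)

FEATURE_KINDS <- c("promoter", "CDS", "terminator", "tag", "RBS", "marker",
                   "dropout", "recognition_site", "UNS", "scar", "other")

#' Create a sequence feature
#'
#' @param kind One of `r paste(FEATURE_KINDS, collapse=", ")`.
#' @param label Display label (e.g. `"CaMV35S"`, `"sfGFP"`).
#' @param start,end 0-based half-open span. `end` may exceed the molecule
#'   length (wrapped span) on circular molecules.
#' @param strand `"+"` or `"-"`.
#' @param qualifiers Named list of additional key/value qualifiers.
#' @return A list of class `dna_feature`.
#' @export
feature <- function(kind, label, start, end, strand = "+", qualifiers = list()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(strand %in% c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("feature span must satisfy end > start (after unwrapping)",
                         call. = FALSE)
  structure(list(kind = kind, label = as.character(label), start = start,
                 end = end, strand = strand, qualifiers = qualifiers),
            class = "dna_feature")
}

validate_feature <- function(f, mol) {
  L <- seq_length(mol)
  if (f$start < 0L || f$start >= L)
    stop("feature '", f$label, "' start out of range", call. = FALSE)
  if (f$end > L && mol$topology != "circular")
    stop("wrapped feature '", f$label, "' on linear molecule", call. = FALSE)
  if (f$end - f$start > L)
    stop("feature '", f$label, "' longer than molecule", call. = FALSE)
  if (f$kind == "CDS" && !isTRUE(f$qualifiers$partial) &&
      (f$end - f$start) %% 3L != 0L)
    stop("CDS feature '", f$label, "' length not divisible by 3 ",
         "(set qualifier partial=TRUE for partial CDS)", call. = FALSE)
  invisible(TRUE)
}

#' Extract a wrap-aware subsequence (0-based half-open)
#'
#' `end` may exceed the sequence length, in which case the extraction wraps
#' through the origin (only meaningful for circular sequences).
#' @param seq DNA string.
#' @param start,end 0-based half-open bounds with `start < end <= start + nchar(seq)`.
#' @return The extracted string.
#' @keywords internal
subseq0 <- function(seq, start, end) {
  L <- nchar(seq)
  start <- start %% L
  end <- start + (end - start)
  if (end <= L) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Vectorised.
#' @param seq Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("GGTCTC")  # "GAGACC"
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  vapply(comp, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Standard genetic code (via Biostrings' `GENETIC_CODE`); stop codons are
#' rendered as `"*"`. Codons containing `N` translate to `"X"`.
#' @param seq DNA string with length divisible by 3.
#' @return Protein string.
#' @examples
#' translate_cds("ATGGCAGGT")  # "MAG"
#' @export
translate_cds <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Booth's least-rotation algorithm; O(n). `k` is the 0-based start of the
# lexicographically least rotation. Verified against brute-force enumeration
# of all rotations in the test suite.
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  v <- utf8ToInt(paste0(s, s))   # doubled string, 1-based
  f <- rep.int(-1L, 2L * n)      # failure function, f[idx0 + 1]
  k <- 0L
  for (jj in 1L:(2L * n - 1L)) { # 0-based index into the doubled string
    sj <- v[jj + 1L]
    i <- f[jj - k]               # f[(jj - k - 1) + 1]
    while (i != -1L && sj != v[k + i + 2L]) {
      if (sj < v[k + i + 2L]) k <- jj - i - 1L
      i <- f[i + 1L]
    }
    if (sj != v[k + i + 2L]) {   # here i == -1, so this compares with v[k+1]
      if (sj < v[k + 1L]) k <- jj
      f[jj - k + 1L] <- -1L
    } else {
      f[jj - k + 1L] <- i + 1L
    }
  }
  substr(paste0(s, s), k + 1L, k + n)
}

#' Canonical rotation of a circular sequence
#'
#' Returns the lexicographically smallest string among all rotations of the
#' sequence and all rotations of its reverse complement. Two circular
#' molecules describe the same plasmid iff their canonical rotations match.
#'
#' @param mol A circular [dna_molecule()] or a plain DNA string.
#' @return The canonical string.
#' @examples
#' canonical_rotation(dna_molecule("x", "CGA", "circular"))  # "ACG"
#' @export
canonical_rotation <- function(mol) {
  if (inherits(mol, "dna_molecule")) {
    if (mol$topology != "circular")
      stop("canonical_rotation requires a circular molecule", call. = FALSE)
    s <- mol$sequence
  } else s <- toupper(as.character(mol))
  min(least_rotation(s), least_rotation(reverse_complement(s)))
}

#' Compare two DNA records for identity
#'
#' Linear molecules are equal iff their sequences match exactly or as reverse
#' complements; circular molecules iff their canonical rotations match.
#' @param a,b [dna_molecule()] objects.
#' @return Logical.
#' @export
records_equal <- function(a, b) {
  if (a$topology != b$topology) return(FALSE)
  if (a$topology == "circular")
    return(canonical_rotation(a) == canonical_rotation(b))
  a$sequence == b$sequence || a$sequence == reverse_complement(b$sequence)
}

## ---------------------------------------------------------------- GenBank --

# Minimal flat-file GenBank support: LOCUS (length + topology), FEATURES with
# complement()/join() locations (join used for origin-wrapping spans), ORIGIN.

gb_kind_map <- c(promoter = "promoter", CDS = "CDS", terminator = "terminator",
                 tag = "misc_feature", RBS = "RBS", marker = "misc_feature",
                 dropout = "misc_feature", recognition_site = "misc_feature",
                 UNS = "misc_feature", scar = "misc_feature", other = "misc_feature")

format_gb_location <- function(f, L) {
  if (f$end <= L) loc <- sprintf("%d..%d", f$start + 1L, f$end)
  else loc <- sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end - L)
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a DNA record to GenBank or FASTA
#'
#' GenBank output records topology in the LOCUS line and writes all features
#' with 1-based inclusive coordinates; origin-wrapping features are emitted as
#' `join()` locations. Wrapped features on linear molecules are an error.
#'
#' @param mol A [dna_molecule()].
#' @param path Output file path.
#' @param format `"genbank"` or `"fasta"`.
#' @return Invisibly, `path`.
#' @export
save_record <- function(mol, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  L <- seq_length(mol)
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(mol$sequence)
    names(x) <- mol$id
    Biostrings::writeXStringSet(x, filepath = path)
    return(invisible(path))
  }
  for (f in mol$features)
    if (f$end > L && mol$topology != "circular")
      stop("wrapped feature on linear molecule: ", f$label, call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(mol$id, 1, 16), L,
                     mol$topology, format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s", mol$id), con)
  if (nzchar(mol$provenance)) writeLines(sprintf("COMMENT     %s", mol$provenance), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in mol$features) {
    writeLines(sprintf("     %-16s%s", gb_kind_map[[f$kind]],
                       format_gb_location(f, L)), con)
    writeLines(sprintf('                     /label="%s"', f$label), con)
    writeLines(sprintf('                     /loop_kind="%s"', f$kind), con)
    for (q in names(f$qualifiers))
      writeLines(sprintf('                     /%s="%s"', q,
                         as.character(f$qualifiers[[q]])), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, 60L)
  for (p in pos) {
    chunk <- substr(mol$sequence, p, min(p + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(blocks), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

parse_gb_location <- function(loc, L, lineno) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    spans <- strsplit(inner, ",", fixed = TRUE)[[1]]
    m <- regmatches(spans, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", spans))
    if (any(vapply(m, length, 1L) != 3L))
      stop("GenBank parse error at line ", lineno, ": bad location ", loc,
           call. = FALSE)
    a <- as.integer(m[[1]][2]); b <- as.integer(m[[1]][3])
    c2 <- as.integer(m[[2]][2]); d <- as.integer(m[[2]][3])
    if (length(spans) == 2L && b == L && c2 == 1L)
      return(list(start = a - 1L, end = L + d, strand = strand))
    stop("GenBank parse error at line ", lineno,
         ": unsupported join() location ", loc, call. = FALSE)
  }
  m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
  if (length(m) == 3L)
    return(list(start = as.integer(m[2]) - 1L, end = as.integer(m[3]),
                strand = strand))
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    return(list(start = p - 1L, end = p, strand = strand))
  }
  stop("GenBank parse error at line ", lineno, ": bad location ", loc,
       call. = FALSE)
}

load_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    while (i <= n && !grepl("^LOCUS", lines[i])) i <- i + 1L
    if (i > n) break
    locus <- lines[i]
    toks <- strsplit(trimws(locus), "\\s+")[[1]]
    id <- toks[2]
    topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
    declared_len <- suppressWarnings(as.integer(toks[which(tolower(toks) == "bp") - 1L]))
    feats_raw <- list(); seq_chunks <- character(); comment <- ""
    i <- i + 1L
    in_feat <- FALSE; in_origin <- FALSE
    cur <- NULL
    while (i <= n && !grepl("^//", lines[i])) {
      ln <- lines[i]
      if (grepl("^COMMENT", ln) && !in_feat && !in_origin)
        comment <- trimws(sub("^COMMENT", "", ln))
      if (grepl("^FEATURES", ln)) { in_feat <- TRUE; in_origin <- FALSE }
      else if (grepl("^ORIGIN", ln)) {
        if (!is.null(cur)) { feats_raw[[length(feats_raw) + 1L]] <- cur; cur <- NULL }
        in_feat <- FALSE; in_origin <- TRUE
      } else if (in_origin) {
        seq_chunks <- c(seq_chunks, gsub("[^A-Za-z]", "", ln))
      } else if (in_feat) {
        if (grepl("^     \\S", ln)) {
          if (!is.null(cur)) feats_raw[[length(feats_raw) + 1L]] <- cur
          parts <- strsplit(trimws(ln), "\\s+")[[1]]
          cur <- list(gbkey = parts[1], loc = paste(parts[-1], collapse = ""),
                      quals = list(), lineno = i)
        } else if (!is.null(cur) && grepl("^\\s{10,}", ln)) {
          txt <- trimws(ln)
          if (grepl("^/", txt)) {
            m <- regmatches(txt, regexec('^/([^=]+)=?"?([^"]*)"?$', txt))[[1]]
            if (length(m) == 3L) cur$quals[[m[2]]] <- m[3]
          } else cur$loc <- paste0(cur$loc, txt)  # continuation of a location
        }
      }
      i <- i + 1L
    }
    if (!is.null(cur)) feats_raw[[length(feats_raw) + 1L]] <- cur
    sequence <- toupper(paste(seq_chunks, collapse = ""))
    if (!nzchar(sequence))
      stop("GenBank parse error: record '", id, "' has no ORIGIN sequence",
           call. = FALSE)
    if (!is.na(declared_len) && length(declared_len) == 1L &&
        declared_len != nchar(sequence))
      stop("GenBank parse error: LOCUS length ", declared_len,
           " != sequence length ", nchar(sequence), " for '", id, "'",
           call. = FALSE)
    feats <- list()
    for (fr in feats_raw) {
      if (fr$gbkey == "source") next
      loc <- parse_gb_location(fr$loc, nchar(sequence), fr$lineno)
      kind <- fr$quals$loop_kind
      if (is.null(kind)) {
        kind <- switch(fr$gbkey, promoter = "promoter", CDS = "CDS",
                       terminator = "terminator", RBS = "RBS", "other")
      }
      quals <- fr$quals
      quals$loop_kind <- NULL
      label <- quals$label
      if (is.null(label)) label <- fr$gbkey
      quals$label <- NULL
      if (identical(quals$partial, "TRUE")) quals$partial <- TRUE
      feats[[length(feats) + 1L]] <-
        feature(kind, label, loc$start, loc$end, loc$strand, quals)
    }
    recs[[length(recs) + 1L]] <-
      dna_molecule(id, sequence, topology, feats, provenance = comment)
    i <- i + 1L
  }
  if (!length(recs)) stop("GenBank parse error: no LOCUS record found in ",
                          path, call. = FALSE)
  recs
}

#' Load DNA records from GenBank or FASTA
#'
#' Sequences are uppercased; topology is taken from the GenBank LOCUS line
#' when present (FASTA records are linear); GenBank features are preserved.
#' Residues outside the IUPAC subset `A,C,G,T,N` are rejected.
#'
#' @param path Input file path.
#' @param format `"genbank"` or `"fasta"`.
#' @return A single [dna_molecule()] if the file holds one record, else a
#'   list of molecules.
#' @export
load_record <- function(path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  recs <- if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path)
    lapply(seq_along(x), function(i)
      dna_molecule(names(x)[i], as.character(x[[i]]), "linear",
                   provenance = path))
  } else load_genbank(path)
  ids <- vapply(recs, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ","), call. = FALSE)
  if (length(recs) == 1L) recs[[1]] else recs
}
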