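# Shared fixtures, generated once per test run (seed fixed) and memoised.

.fx_env <- new.env(parent = emptyenv())

fx_cached <- function(seed = 42L) {
  key <- paste0("fx", seed)
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- generate_fixtures(seed)
  .fx_env[[key]]
}

sim_cached <- function(design_name, seed = 42L) {
  key <- paste0("sim:", design_name, ":", seed)
  if (is.null(.fx_env[[key]])) {
    fx <- fx_cached(seed)
    plan <- plan_design(fx$designs[[design_name]], fx)
    .fx_env[[key]] <- list(plan = plan, sim = simulate_plan(plan, fx))
  }
  .fx_env[[key]]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a circular plasmid that releases [lov][cargo][rov-as-right-overhang] when
# cut with `enz` (sites convergent on the cargo, recognitions stay vector-side)
make_insert_plasmid <- function(id, enz, lov, rov, cargo, backbone_len = 600) {
  enz <- as_enzyme(enz)
  bb <- domesticate(rand_dna(backbone_len))$sequence
  seqn <- paste0(enz$recognition, "A", lov, cargo, rov, "A",
                 reverse_complement(enz$recognition), bb)
  dna_molecule(id, seqn, "circular")
}

## Independent brute-force ligation oracle. Fragments are modelled as
## (top = core + right overhang, l = left overhang length, r = right
## overhang length); orientation flip is top -> revcomp(top), l/r swapped.
## All subsets x permutations x orientation vectors are enumerated and
## products deduplicated by canonical string (brute-force rotations).
oracle_ligations <- function(pool, include_linear = FALSE) {
  tops <- lapply(pool, function(f) list(top = paste0(f$core, f$right_ov),
                                        l = nchar(f$left_ov),
                                        r = nchar(f$right_ov)))
  get <- function(i, o) {
    t <- tops[[i]]
    if (o == 1L) t
    else list(top = reverse_complement(t$top), l = t$r, r = t$l)
  }
  lov <- function(t) substr(t$top, 1, t$l)
  rov <- function(t) substr(t$top, nchar(t$top) - t$r + 1, nchar(t$top))
  ok_junction <- function(a, b)
    a$r > 0 && identical(rov(a), lov(b)) && !grepl("N", rov(a), fixed = TRUE)
  chain_seq <- function(ts, circular) {
    cores <- vapply(ts, function(t)
      substr(t$top, 1, nchar(t$top) - t$r), "")
    s <- paste(cores, collapse = "")
    if (!circular) s <- paste0(s, rov(ts[[length(ts)]]))
    s
  }
  canon_circ <- function(s) {
    n <- nchar(s)
    rots <- vapply(0:(n - 1), function(k)
      paste0(substr(s, k + 1, n), substr(s, 1, k)), "")
    rc <- reverse_complement(s)
    rots2 <- vapply(0:(n - 1), function(k)
      paste0(substr(rc, k + 1, n), substr(rc, 1, k)), "")
    min(c(rots, rots2))
  }
  n <- length(pool)
  circ <- character(); linr <- character()
  subsets <- unlist(lapply(1:n, function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (sub in subsets) {
    for (p in perms(sub)) {
      k <- length(p)
      for (bits in 0:(2^k - 1)) {
        os <- 1L + bitwAnd(bits %/% 2^(seq_len(k) - 1), 1L)
        ts <- lapply(seq_len(k), function(i) get(p[i], os[i]))
        good <- all(vapply(seq_len(k - 1), function(i)
          ok_junction(ts[[i]], ts[[i + 1]]), TRUE))
        if (k == 1) good <- TRUE
        if (!good) next
        if (ok_junction(ts[[k]], ts[[1]]))
          circ <- c(circ, canon_circ(chain_seq(ts, TRUE)))
        if (include_linear) {
          s <- chain_seq(ts, FALSE)
          linr <- c(linr, min(s, reverse_complement(s)))
        }
      }
    }
  }
  list(circular = sort(unique(circ)), linear = sort(unique(linr)))
}
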