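# planner: hierarchical assembly planning and end-to-end simulation.
#
# A design is a tree: leaves are L0 part references, internal nodes carry
# (level, kit, receiver position, ordered children). Level parity decides
# the assembly enzyme (odd: BsaI, even: SapI); a node's children occupy
# receiver positions 1..k in slot order, and nodes of level >= 2 require
# full four-child chains. Level-4 nodes may be receiver-free, yielding a
# linear product plus its partial concatemers.

#' Design-tree constructors
#'
#' `design_part(name)` references an L0 part by name; `design_node()` builds
#' an internal node. Children of level-1 nodes are part references; children
#' of level-n nodes (n >= 2) are level-(n-1) nodes.
#'
#' @param name L0 part name (e.g. `"CE_sfGFP"`).
#' @return A `loop_design` list.
#' @export
design_part <- function(name) {
  structure(list(type = "part", part = name), class = "loop_design")
}

#' @rdname design_part
#' @param level Target level 1..4.
#' @param position Receiver position 1..4 (ignored for receiver-free nodes).
#' @param children List of child designs.
#' @param kit Vector kit for this node's receiver.
#' @param receiver_free Assemble without a receiver (level 4 only): the
#'   product is the full-length linear concatemer.
#' @export
design_node <- function(level, position, children, kit = "pCA",
                        receiver_free = FALSE) {
  stopifnot(level >= 1L, level <= 4L, length(children) >= 1L)
  structure(list(type = "node", level = as.integer(level),
                 position = if (receiver_free) NA_integer_
                            else as.integer(position),
                 children = children, kit = kit,
                 receiver_free = isTRUE(receiver_free)),
            class = "loop_design")
}

level_parity <- function(level) if (level %% 2L == 1L) "odd" else "even"

#' Validate a design against a part/receiver library
#'
#' Checks level alternation (each node's children are one level below),
#' full-chain arity for levels >= 2, marker alternation between parent and
#' child levels, resolves every node's receiver, and validates every chain
#' with [validate_part_chain()] (errors carry the node path). Receiver-borne
#' level-4 nodes trigger a stability warning (high direct-repeat content).
#'
#' @param design A `loop_design` tree.
#' @param library A fixture library as returned by [generate_fixtures()]
#'   (fields `kits`, `parts`, `entry`, `table`).
#' @return A validated plan tree (class `loop_plan`); each node gains `id`
#'   (path such as `"L3-4/L2-1"`), its resolved `receiver` and ordered
#'   children.
#' @export
plan_design <- function(design, library) {
  validate_node <- function(node, path) {
    if (identical(node$type, "part")) {
      part <- library$parts[[node$part]]
      if (is.null(part))
        stop("unresolved part '", node$part, "' at ", path, call. = FALSE)
      return(list(type = "part", id = paste0(path, "/", node$part),
                  part = part, level = 0L,
                  five_code = part$five_code, three_code = part$three_code,
                  marker = "ampicillin"))
    }
    self <- sprintf("L%d-%s", node$level,
                    if (is.na(node$position)) "x" else node$position)
    path <- if (nzchar(path)) paste0(path, "/", self) else self
    kids <- lapply(seq_along(node$children), function(i)
      validate_node(node$children[[i]], path))
    lv <- vapply(kids, function(k) k$level, 0L)
    if (any(lv != node$level - 1L))
      stop("level mismatch at ", path, ": children at level(s) ",
           paste(unique(lv), collapse = ","), " under a level-", node$level,
           " node", call. = FALSE)
    if (node$level >= 2L && length(kids) != 4L)
      stop("node ", path, " needs a full 4-child chain (got ",
           length(kids), ")", call. = FALSE)
    for (i in seq_along(kids)) {
      if (kids[[i]]$type == "node" && kids[[i]]$position != i)
        stop("position collision at ", path, ": child ", i,
             " declares receiver position ", kids[[i]]$position, call. = FALSE)
    }
    parity <- level_parity(node$level)
    if (node$receiver_free) {
      if (node$level != 4L)
        stop("receiver-free assembly is only supported at level 4 (node ",
             path, ")", call. = FALSE)
      receiver <- NULL
      accept <- c("alpha", "omega")
      marker <- NA_character_
    } else {
      if (node$level == 4L)
        warning("receiver-borne level-4 assembly at ", path, ": high ",
                "direct-repeat content makes such plasmids unstable in vivo",
                call. = FALSE)
      rname <- sprintf("%s%s-%d", node$kit, substr(parity, 1, 1),
                       node$position)
      receiver <- library$kits[[node$kit]][[rname]]
      if (is.null(receiver))
        stop("unresolved receiver ", rname, " at ", path, call. = FALSE)
      accept <- receiver$accept_codes
      marker <- receiver$marker
      for (k in kids)
        if (identical(k$marker, marker))
          stop("marker alternation violated at ", path, ": child and ",
               "parent both select on ", marker, call. = FALSE)
    }
    chain_in <- lapply(kids, function(k) {
      if (k$type == "part")
        list(five_code = k$five_code, three_code = k$three_code, name = k$id)
      else list(five_code = k$receiver$release_codes[1],
                three_code = k$receiver$release_codes[2], name = k$id)
    })
    ordered <- tryCatch(
      validate_part_chain(chain_in, list(accept_codes = accept)),
      loop_chain_error = function(e)
        stop("at node ", path, ": ", conditionMessage(e), call. = FALSE))
    ord <- match(vapply(ordered, function(x) x$name, ""),
                 vapply(chain_in, function(x) x$name, ""))
    list(type = "node", id = path, level = node$level, kit = node$kit,
         position = node$position, receiver = receiver,
         receiver_free = node$receiver_free, marker = marker,
         parity = parity, children = kids[ord])
  }
  structure(validate_node(design, ""), class = "loop_plan")
}

#' Simulate a validated plan bottom-up
#'
#' Runs [one_pot_assemble()] at every node (leaf-to-root), propagating
#' features so the root product is fully annotated; each level-1 product is
#' annotated with a transcription-unit (`TU:`) feature over its cargo.
#' Identical subtrees (same design, same receiver) are simulated once.
#' Receiver-free level-4 nodes return the full-length linear product and
#' the partial concatemer set (monomer/dimer/trimer/...).
#'
#' @param plan A `loop_plan` from [plan_design()].
#' @param library The same library used to plan.
#' @return List with `molecules` (named by node id: every node's product),
#'   `root_id`, `root` (the root product molecule) and, for receiver-free
#'   roots, `ladder` (all linear concatemer products).
#' @export
simulate_plan <- function(plan, library) {
  molecules <- list()
  ladder <- NULL
  cache <- new.env(parent = emptyenv())
  node_key <- function(node) {
    if (node$type == "part") return(paste0("p:", node$part$name))
    paste0("n:", node$level, ":", node$kit, ":", node$position, ":",
           node$receiver_free, "(",
           paste(vapply(node$children, node_key, ""), collapse = ","), ")")
  }
  sim <- function(node) {
    key <- node_key(node)
    hit <- cache[[key]]
    if (!is.null(hit)) { molecules[[node$id]] <<- hit; return(hit) }
    if (node$type == "part") {
      mol <- node$part$molecule
      cache[[key]] <- mol
      molecules[[node$id]] <<- mol
      return(mol)
    }
    kid_mols <- lapply(node$children, sim)
    enz <- if (node$parity == "odd") bsai() else sapi()
    if (isTRUE(node$receiver_free)) {
      frs <- lapply(kid_mols, function(m) {
        fr <- digest(m, enz)
        st <- which(!vapply(fr, fragment_has_site, TRUE, enz = enz))
        if (length(st) != 1L)
          stop("receiver-free assembly: child ", m$id, " does not release ",
               "a unique site-free fragment", call. = FALSE)
        fr[[st]]
      })
      prods <- enumerate_ligations(frs, "include_linear", max_copies = 1L)
      linear <- Filter(function(p) p$topology == "linear", prods)
      lens <- vapply(linear, function(p) nchar(p$molecule$sequence), 0L)
      full <- linear[[which.max(lens)]]
      if (nrow(full$parts) != length(frs))
        stop("receiver-free assembly at ", node$id,
             ": no full-length concatemer (chain incomplete)", call. = FALSE)
      mol <- full$molecule
      mol$id <- node$id
      ladder <<- linear
      cache[[key]] <- mol
      molecules[[node$id]] <<- mol
      return(mol)
    }
    rep <- tryCatch(
      one_pot_assemble(node$receiver, kid_mols, enz, product_id = node$id),
      error = function(e)
        stop("simulation failed at node ", node$id, ": ",
             conditionMessage(e), call. = FALSE))
    if (length(rep$intended) != 1L)
      stop("node ", node$id, ": expected exactly one intended product",
           call. = FALSE)
    mol <- rep$intended[[1]]
    if (node$level == 1L) {
      cargo_start <- rep$backbone_core_len
      mol$features <- c(mol$features,
                        list(feature("other", paste0("TU:", basename_id(node$id)),
                                     cargo_start, seq_length(mol), "+",
                                     list(tu = TRUE))))
    }
    cache[[key]] <- mol
    molecules[[node$id]] <<- mol
    mol
  }
  root <- sim(plan)
  out <- list(molecules = molecules, root_id = plan$id, root = root)
  if (isTRUE(plan$receiver_free)) out$ladder <- ladder
  out
}

basename_id <- function(id) {
  parts <- strsplit(id, "/", fixed = TRUE)[[1]]
  parts[length(parts)]
}

## ------------------------------------------------------------ composition --

CENSUS_KINDS <- c("promoter", "CDS", "tag", "terminator")

#' Count part composition of a plan or simulated product
#'
#' For a plan, counts are exact multiset sums over the tree of leaf features
#' (promoters, CDSs, tags, terminators, by label) plus the
#' transcription-unit count (one per level-1 node). For a molecule, the same
#' census is taken over its annotated features (`TU:` features for TUs).
#' Counting on the plan equals counting on the simulated product.
#'
#' @param x A `loop_plan` or a [dna_molecule()].
#' @return List with `tu_count` and `counts` (named integer vector by label).
#' @export
count_composition <- function(x) {
  counts <- integer()
  bump <- function(label, by = 1L) {
    if (is.null(counts[label]) || is.na(counts[label]))
      counts[label] <<- 0L
    counts[label] <<- counts[label] + by
  }
  tu <- 0L
  if (inherits(x, "dna_molecule")) {
    for (f in x$features) {
      if (startsWith(f$label, "TU:")) tu <- tu + 1L
      else if (f$kind %in% CENSUS_KINDS) bump(f$label)
    }
  } else {
    walk <- function(node) {
      if (node$type == "part") {
        part <- node$part
        if (part$kind %in% CENSUS_KINDS) bump(part$label)
        else if (!part$kind %in% FEATURE_KINDS || !nzchar(part$label)) {
          warning("unlabeled leaf ", part$name, "; counted under 'other'",
                  call. = FALSE)
          bump("other")
        }
        # labelled non-census kinds (RBS, markers, ...) are not tallied
        return(invisible())
      }
      if (node$level == 1L) tu <<- tu + 1L
      for (k in node$children) walk(k)
    }
    walk(x)
  }
  list(tu_count = tu, counts = counts[order(names(counts))])
}

## ---------------------------------------------------------------- recipes --

#' Assemble a bench recipe for one reaction
#'
#' DNA mix: 15 fmol of each part/composite plus 7.5 fmol of the receiver,
#' filled to 5 ul with water; volumes use ng = fmol x length(bp) x 650 / 1e6
#' (average 650 g/mol/bp, configurable). Master mix (5 ul) by parity —
#' odd: 3 dH2O / 1 T4 ligase buffer 10x / 0.5 BSA / 0.25 T4 ligase /
#' 0.25 BsaI; even: 3.5 dH2O / 0.5 T4 ligase buffer 10x / 0.5 CutSmart 10x /
#' 0.25 T4 ligase / 0.25 SapI. Total reaction 10 ul. Cycling defaults to 25
#' regular cycles (3 min 37C / 4 min 16C); options: `short_cycle` (1 min /
#' 1.5 min), `double_enzyme` (2x enzyme, water reduced), `cycles` (e.g. 50).
#'
#' @param node A `loop_plan` node (or receiver-free root node).
#' @param concentrations Named numeric vector, ng/ul, keyed by input id:
#'   part names for leaves, child node ids for composites, the receiver name
#'   for the receiver.
#' @param molecules Named molecule list from [simulate_plan()] (supplies
#'   composite lengths); not needed if all children are parts.
#' @param options List: `short_cycle`, `double_enzyme`, `cycles`.
#' @param grams_per_mol_bp Molar mass per base pair (g/mol/bp).
#' @return A `loop_recipe`: `dna_mix`, `master_mix` (data.frames with
#'   volumes in ul), `cycling`, `options`.
#' @export
make_recipe <- function(node, concentrations, molecules = NULL,
                        options = list(), grams_per_mol_bp = 650) {
  stopifnot(all(concentrations > 0))
  opts <- utils::modifyList(list(short_cycle = FALSE, double_enzyme = FALSE,
                                 cycles = 25L), options)
  input_len <- function(id) {
    if (!is.null(molecules) && !is.null(molecules[[id]]))
      return(seq_length(molecules[[id]]))
    stop("no molecule length known for input '", id, "'", call. = FALSE)
  }
  rows <- list()
  add_input <- function(id, mol_len, fmol) {
    conc <- concentrations[[id]]
    if (is.null(conc) || is.na(conc))
      stop("no concentration given for input '", id, "'", call. = FALSE)
    ng <- fmol * mol_len * grams_per_mol_bp / 1e6
    rows[[length(rows) + 1L]] <<-
      data.frame(id = id, fmol = fmol, length_bp = mol_len,
                 ng = ng, volume_ul = ng / conc)
  }
  if (!is.null(node$receiver))
    add_input(node$receiver$name, seq_length(node$receiver$molecule), 7.5)
  for (k in node$children) {
    if (k$type == "part") add_input(k$part$name, seq_length(k$part$molecule), 15)
    else add_input(k$id, input_len(k$id), 15)
  }
  dna <- do.call(rbind, rows)
  used <- sum(dna$volume_ul)
  if (used > 5) {
    worst <- dna$id[which.max(dna$volume_ul)]
    stop("DNA volumes exceed the 5 ul DNA mix at the given concentrations ",
         sprintf("(need %.2f ul); raise concentrations (limiting input: %s, ",
                 used, worst),
         sprintf("minimum ~%.1f ng/ul overall scale-up %.2fx)",
                 concentrations[[worst]] * used / 5, used / 5), call. = FALSE)
  }
  dna <- rbind(dna, data.frame(id = "dH2O", fmol = NA, length_bp = NA,
                               ng = NA, volume_ul = 5 - used))
  parity <- if (!is.null(node$parity)) node$parity else "even"
  enzv <- if (opts$double_enzyme) 0.5 else 0.25
  mm <- if (parity == "odd") data.frame(
    component = c("dH2O", "T4 ligase buffer 10x", "BSA 1 mg/ml",
                  "T4 DNA ligase 400 U/ul", "BsaI 10 U/ul"),
    volume_ul = c(3 - (enzv - 0.25), 1, 0.5, 0.25, enzv))
  else data.frame(
    component = c("dH2O", "T4 ligase buffer 10x", "CutSmart 10x",
                  "T4 DNA ligase 400 U/ul", "SapI 10 U/ul"),
    volume_ul = c(3.5 - (enzv - 0.25), 0.5, 0.5, 0.25, enzv))
  cyc <- list(cycles = as.integer(opts$cycles),
              cut_step = list(temp_c = 37, minutes = if (opts$short_cycle) 1 else 3),
              ligate_step = list(temp_c = 16,
                                 minutes = if (opts$short_cycle) 1.5 else 4))
  stopifnot(abs(sum(dna$volume_ul) - 5) < 1e-9,
            abs(sum(mm$volume_ul) - 5) < 1e-9)
  structure(list(node_id = node$id, dna_mix = dna, master_mix = mm,
                 cycling = cyc, options = opts,
                 total_ul = sum(dna$volume_ul) + sum(mm$volume_ul)),
            class = "loop_recipe")
}

#' @export
print.loop_recipe <- function(x, ...) {
  cat(sprintf("<loop_recipe> %s (%d ul reaction)\nDNA mix (5 ul):\n",
              x$node_id, round(x$total_ul)))
  print(x$dna_mix, row.names = FALSE, digits = 4)
  cat("Master mix (5 ul):\n")
  print(x$master_mix, row.names = FALSE, digits = 4)
  cat(sprintf("Cycling: %d x (%g min %gC / %g min %gC)\n", x$cycling$cycles,
              x$cycling$cut_step$minutes, x$cycling$cut_step$temp_c,
              x$cycling$ligate_step$minutes, x$cycling$ligate_step$temp_c))
  invisible(x)
}

## ------------------------------------------------------------- plan files --

#' Serialise / deserialise designs as JSON
#'
#' @param design A `loop_design`.
#' @param path Output (input) path.
#' @return `design_to_json` invisibly returns `path`; `design_from_json`
#'   returns a `loop_design`.
#' @export
design_to_json <- function(design, path) {
  strip <- function(node) {
    if (identical(node$type, "part")) return(list(part = node$part))
    list(level = node$level, position = node$position, kit = node$kit,
         receiver_free = node$receiver_free,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(design), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  build <- function(x) {
    if (!is.null(x$part)) return(design_part(x$part))
    design_node(x$level, if (is.null(x$position)) NA else x$position,
                lapply(x$children, build), kit = x$kit,
                receiver_free = isTRUE(x$receiver_free))
  }
  build(jsonlite::read_json(path))
}
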