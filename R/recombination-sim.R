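#' Construct a system state
#'
#' A system state is the set of DNA molecules present in a cell model
#' (chromosome, delivery plasmids, excised circles) plus the ordered log of
#' recombination events that produced it. Excised circles are retained: they
#' carry an active lox site and can re-integrate, which is exactly the
#' mechanism of the one-step cut-and-paste.
#'
#' @param molecules List of [molecule()] objects.
#' @param log List of event records already applied.
#' @return An object of class `system_state`.
#' @export
system_state <- function(molecules, log = list()) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  structure(list(molecules = molecules, log = log), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system state> %d molecule(s), %d event(s) applied\n",
              length(x$molecules), length(x$log)))
  for (m in x$molecules) {
    nlox <- sum(vapply(m$features, function(f) f$kind == "lox", logical(1)))
    cat(sprintf("  %s: %d bp %s, %d lox\n", m$id, mol_len(m), m$topology, nlox))
  }
  invisible(x)
}

# Canonical strand/rotation-independent representation of a molecule's
# sequence, used to deduplicate states during closure.
canonical_mol_seq <- function(mol) {
  s <- mol$sequence
  rc <- revcomp(s)
  if (mol$topology == "circular") {
    min(least_rotation(s), least_rotation(rc))
  } else {
    min(s, rc)
  }
}

state_key <- function(state) {
  paste(sort(vapply(state$molecules, canonical_mol_seq, character(1))),
        collapse = "|")
}

get_feat_by_id <- function(mol, id) {
  for (j in seq_along(mol$features)) {
    if (identical(mol$features[[j]]$.id, id)) return(mol$features[[j]])
  }
  NULL
}

shift_feats <- function(feats, d) {
  lapply(feats, function(f) {
    f$start <- f$start + as.integer(d); f$end <- f$end + as.integer(d)
    f
  })
}

# Remap features of a slice of length `len` through an inversion of that slice.
invert_feats <- function(feats, len) {
  lapply(feats, function(f) {
    ns <- len - f$end; ne <- len - f$start
    f$start <- as.integer(ns); f$end <- as.integer(ne)
    f$strand <- if (f$strand == "+") "-" else "+"
    if (f$kind == "lox") f$payload <- flip_orientation(f$payload)
    f
  })
}

lox_feature <- function(site, start, label) {
  feature("lox", start, start + 34L,
          strand = if (site$orientation == "forward") "+" else "-",
          label = label, payload = site)
}

# Normalize an intramolecular lox pair so that site A is forward and, on a
# circular molecule, starts at position 0 (on a linear molecule, A precedes
# B). Identities are tracked through rotation/reverse-complement via .id tags.
norm_intra <- function(mol, ida, idb) {
  for (i in 1:8) {
    fa <- get_feat_by_id(mol, ida); fb <- get_feat_by_id(mol, idb)
    oa <- fa$payload$orientation; ob <- fb$payload$orientation
    if (oa == "reverse" && ob == "reverse") { mol <- revcomp_molecule(mol); next }
    if (oa == "reverse") { tmp <- ida; ida <- idb; idb <- tmp; next }
    if (mol$topology == "circular") {
      if (fa$start != 0L) { mol <- rotate_molecule(mol, fa$start); next }
    } else if (fa$start > fb$start) {
      if (ob == "forward") { tmp <- ida; ida <- idb; idb <- tmp } else {
        mol <- revcomp_molecule(mol)
      }
      next
    }
    return(list(mol = mol, ida = ida, idb = idb))
  }
  loxtron_error("loxtron_internal_error", "pair normalization did not converge")
}

# One intramolecular Cre event between the lox features at indices j1, j2.
# Same orientation -> excision (main product plus excised circle carrying one
# recombinant site); opposite orientation -> inversion of the intervening
# segment. Returns NULL when the molecule cannot support the event.
intra_event <- function(mol, j1, j2, compat = NULL, circle_tag = "circ") {
  mol$features[[j1]]$.id <- "siteA"
  mol$features[[j2]]$.id <- "siteB"
  nm <- norm_intra(mol, "siteA", "siteB")
  mol <- nm$mol
  fa <- get_feat_by_id(mol, nm$ida); fb <- get_feat_by_id(mol, nm$idb)
  A <- fa$payload; B <- fb$payload
  a1 <- fa$start; a2 <- fa$end; b1 <- fb$start; b2 <- fb$end
  L <- mol_len(mol)
  seq <- mol$sequence
  r <- recombine(A, B, compat)
  p1 <- r[[1]]; p2 <- r[[2]]
  lbl <- paste0(fa$label, "*", fb$label)
  strip <- function(fs) lapply(fs, function(f) { f$.id <- NULL; f })
  if (B$orientation == "forward") {
    # excision
    main_seq <- paste0(substr(seq, 1L, a1), lox_sequence(p1),
                       substr(seq, b2 + 1L, L))
    main_feats <- c(slice_features(mol, 0L, a1),
                    list(lox_feature(p1, a1, lbl)),
                    shift_feats(slice_features(mol, b2, L), a1 + 34L))
    circ_seq <- paste0(lox_sequence(p2), substr(seq, a2 + 1L, b1))
    circ_feats <- c(list(lox_feature(p2, 0L, lbl)),
                    shift_feats(slice_features(mol, a2, b1), 34L))
    products <- list(
      molecule(mol$id, main_seq, mol$topology, strip(main_feats)),
      molecule(paste0(mol$id, ".", circle_tag), circ_seq, "circular",
               strip(circ_feats))
    )
    type <- "excision"
  } else {
    # inversion
    p2 <- flip_orientation(p2)
    mid <- slice_features(mol, a2, b1)
    lenM <- b1 - a2
    inv_seq <- paste0(substr(seq, 1L, a1), lox_sequence(p1),
                      revcomp(substr(seq, a2 + 1L, b1)), lox_sequence(p2),
                      substr(seq, b2 + 1L, L))
    feats <- c(slice_features(mol, 0L, a1),
               list(lox_feature(p1, a1, lbl)),
               shift_feats(invert_feats(mid, lenM), a1 + 34L),
               list(lox_feature(p2, a1 + 34L + lenM, lbl)),
               shift_feats(slice_features(mol, b2, L), b2))
    products <- list(molecule(mol$id, inv_seq, mol$topology, strip(feats)))
    type <- "inversion"
  }
  list(event = list(type = type, sites = c(fa$label, fb$label),
                    molecules = mol$id,
                    forms_inactive = !is_active(p1) || !is_active(p2)),
       molecules = products)
}

# Intermolecular Cre event fusing two circular molecules (integration).
fusion_event <- function(m1, j1, m2, j2, compat = NULL) {
  m1$features[[j1]]$.id <- "siteA"
  m2$features[[j2]]$.id <- "siteB"
  if (m1$features[[j1]]$payload$orientation == "reverse") m1 <- revcomp_molecule(m1)
  if (m2$features[[j2]]$payload$orientation == "reverse") m2 <- revcomp_molecule(m2)
  fa <- get_feat_by_id(m1, "siteA")
  m1 <- rotate_molecule(m1, fa$start)
  fb <- get_feat_by_id(m2, "siteB")
  m2 <- rotate_molecule(m2, fb$start)
  fa <- get_feat_by_id(m1, "siteA"); fb <- get_feat_by_id(m2, "siteB")
  A <- fa$payload; B <- fb$payload
  r <- recombine(A, B, compat)
  p1 <- r[[1]]; p2 <- r[[2]]
  L1 <- mol_len(m1); L2 <- mol_len(m2)
  lbl <- paste0(fa$label, "*", fb$label)
  seq <- paste0(lox_sequence(p1), substr(m2$sequence, 35L, L2),
                lox_sequence(p2), substr(m1$sequence, 35L, L1))
  feats <- c(list(lox_feature(p1, 0L, lbl)),
             shift_feats(slice_features(m2, 34L, L2), 34L),
             list(lox_feature(p2, L2, lbl)),
             shift_feats(slice_features(m1, 34L, L1), L2 + 34L))
  feats <- lapply(feats, function(f) { f$.id <- NULL; f })
  list(event = list(type = "fusion", sites = c(fa$label, fb$label),
                    molecules = c(m1$id, m2$id),
                    forms_inactive = !is_active(p1) || !is_active(p2)),
       molecules = list(molecule(m1$id, seq, "circular", feats)))
}

#' Enumerate single Cre recombination events from a state
#'
#' Produces one successor state per unordered pair of active,
#' linker-compatible lox sites: intramolecular same-orientation pairs excise
#' the intervening region as a circle, opposite-orientation pairs invert it,
#' and pairs on two circular molecules fuse them (integration). Product sites
#' follow the arm-exchange rule of [recombine()].
#'
#' @param state A [system_state()].
#' @param compat Optional linker compatibility matrix, see
#'   [linker_compatible()].
#' @return A list of `list(event=, state=)` entries; empty when no pair is
#'   eligible.
#' @export
cre_step <- function(state, compat = NULL) {
  mols <- state$molecules
  locs <- list()
  for (i in seq_along(mols)) {
    for (j in seq_along(mols[[i]]$features)) {
      f <- mols[[i]]$features[[j]]
      if (f$kind == "lox" && is_active(f$payload)) {
        locs <- c(locs, list(c(i, j)))
      }
    }
  }
  succs <- list()
  if (length(locs) < 2L) return(succs)
  ncirc <- 0L
  for (x in seq_len(length(locs) - 1L)) {
    for (y in seq.int(x + 1L, length(locs))) {
      i1 <- locs[[x]][1]; j1 <- locs[[x]][2]
      i2 <- locs[[y]][1]; j2 <- locs[[y]][2]
      sa <- mols[[i1]]$features[[j1]]$payload
      sb <- mols[[i2]]$features[[j2]]$payload
      if (!linker_compatible(sa, sb, compat)) next
      if (i1 == i2) {
        ncirc <- ncirc + 1L
        res <- intra_event(mols[[i1]], j1, j2, compat,
                           circle_tag = sprintf("c%02d", ncirc))
        new_mols <- c(mols[-i1], res$molecules)
      } else {
        if (mols[[i1]]$topology != "circular" ||
            mols[[i2]]$topology != "circular") next
        res <- fusion_event(mols[[i1]], j1, mols[[i2]], j2, compat)
        new_mols <- c(mols[-c(i1, i2)], res$molecules)
      }
      succs <- c(succs, list(list(
        event = res$event,
        state = system_state(new_mols, c(state$log, list(res$event)))
      )))
    }
  }
  succs
}

# Does any molecule of the state carry an adjacent pair of homologous
# intron(-remnant) features in inverted orientation -- the repeat structure a
# recombination junction creates and the host subsequently deletes? Homology
# = same intron type and at least min_homology nt of shared scaffold
# coordinates; adjacency = separated by no more than ir_gap nt (the
# recombinant lox scar). Far-apart inverted intron copies are not counted:
# those exist before recombination whenever introns are inserted in opposite
# orientations.
has_inverted_repeat <- function(state, min_homology = 200L, ir_gap = 100L) {
  for (m in state$molecules) {
    ints <- Filter(function(f) f$kind == "intron", m$features)
    if (length(ints) < 2L) next
    ints <- ints[order(vapply(ints, function(f) f$start, integer(1)))]
    L <- mol_len(m)
    for (x in seq_len(length(ints) - 1L)) {
      for (y in seq.int(x + 1L, length(ints))) {
        gap <- ints[[y]]$start - ints[[x]]$end
        if (m$topology == "circular") {
          gap <- min(gap, L - ints[[y]]$end + ints[[x]]$start)
        }
        if (homologous_introns(ints[[x]], ints[[y]], min_homology) &&
            ints[[x]]$strand != ints[[y]]$strand &&
            gap <= ir_gap) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

homologous_introns <- function(f1, f2, min_homology = 200L) {
  if (f1$payload$intron_type != f2$payload$intron_type) return(FALSE)
  r1 <- f1$payload$scaffold_range; r2 <- f2$payload$scaffold_range
  ov <- min(r1[2], r2[2]) - max(r1[1], r2[1])
  ov >= min_homology
}

#' Explore all Cre-reachable states and report terminal outcomes
#'
#' Breadth-first exploration of the Cre transition graph with canonical
#' deduplication of states (rotation- and strand-independent). Terminal
#' outcomes are the entry states of terminal strongly connected components of
#' the graph: pools of states connected by reversible events from which no
#' further event escapes. Formation of a double arm-mutant (lox72-type) site
#' is what creates such irreversible exits.
#'
#' @param state Initial [system_state()].
#' @param max_states Bound on the number of distinct states explored.
#' @param compat Optional linker compatibility matrix.
#' @param min_homology Minimum shared scaffold run (nt) for two intron
#'   remnants to count as a homologous repeat when scanning products.
#' @return An `outcome_report`: list with `terminal_states`, `reversible`
#'   (initial configuration reachable from a non-initial state),
#'   `inverted_repeat_generated`, `n_states`, and `transitions`.
#' @export
cre_closure <- function(state, max_states = 10000L, compat = NULL,
                        min_homology = 200L) {
  keys <- state_key(state)
  states <- list(state)
  e_from <- integer(0); e_to <- integer(0); e_lock <- logical(0)
  queue <- 1L
  while (length(queue) > 0L) {
    cur <- queue[1]; queue <- queue[-1]
    for (s in cre_step(states[[cur]], compat)) {
      k <- state_key(s$state)
      idx <- match(k, keys)
      if (is.na(idx)) {
        if (length(states) >= max_states) {
          loxtron_error("loxtron_state_bound_error",
                        sprintf("state space exceeds max_states = %d", max_states))
        }
        states <- c(states, list(s$state))
        idx <- length(states)
        keys <- c(keys, k)
        queue <- c(queue, idx)
      }
      e_from <- c(e_from, cur); e_to <- c(e_to, idx)
      e_lock <- c(e_lock, isTRUE(s$event$forms_inactive))
    }
  }
  n <- length(states)
  if (length(e_from) == 0L) {
    terminal_idx <- 1L
  } else {
    g <- igraph::make_graph(rbind(e_from, e_to), n = n, directed = TRUE)
    memb <- igraph::components(g, mode = "strong")$membership
    cross <- memb[e_from] != memb[e_to]
    exiting_sccs <- unique(memb[e_from[cross]])
    terminal_sccs <- setdiff(unique(memb), exiting_sccs)
    terminal_idx <- integer(0)
    for (scc in terminal_sccs) {
      members <- which(memb == scc)
      entries <- unique(e_to[cross & memb[e_to] == scc])
      if (1L %in% members) entries <- unique(c(entries, 1L))
      if (length(entries) == 0L) entries <- members[1]
      terminal_idx <- c(terminal_idx, sort(entries))
    }
  }
  terminal_states <- states[terminal_idx]
  reversible <- any(e_to == 1L)
  structure(list(
    terminal_states = terminal_states,
    reversible = reversible,
    inverted_repeat_generated = any(vapply(terminal_states, has_inverted_repeat,
                                           logical(1), min_homology = min_homology)),
    cre_independent_recombination = NA,
    cre_independent_level = NA_character_,
    scar_description = NULL,
    n_states = n,
    transitions = data.frame(from = e_from, to = e_to, forms_inactive = e_lock)
  ), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome report> %d state(s) explored, %d terminal outcome(s)\n",
              x$n_states, length(x$terminal_states)))
  cat(sprintf("  reversible: %s\n  inverted repeat generated: %s\n",
              x$reversible, x$inverted_repeat_generated))
  if (!is.na(x$cre_independent_level)) {
    cat(sprintf("  Cre-independent recombination: %s\n", x$cre_independent_level))
  }
  if (!is.null(x$scar_description)) {
    cat(sprintf("  scar: %d nt, contains lox: %s\n",
                x$scar_description$length, x$scar_description$contains_lox))
  }
  invisible(x)
}

# Map a scaffold coordinate to the genomic coordinate inside an intron
# (remnant) feature.
genomic_of_scaffold <- function(f, s) {
  sr <- f$payload$scaffold_range
  if (f$strand == "+") f$start + (s - sr[1]) else f$start + (sr[2] - s)
}

#' Enumerate host homologous-recombination events between intron repeats
#'
#' The host's own recombination machinery acts on repeated intron scaffolds:
#' direct repeats collapse (deleting one repeat copy plus the intervening
#' sequence), adjacent inverted repeats are removed outright -- taking the lox
#' sites with them and shrinking the scar from hundreds to tens of base pairs
#' -- and separated inverted repeats invert the intervening segment (a
#' reversible event). Repeats are homologous intron features per
#' [cre_closure()]'s rule: same intron type, shared scaffold run of at least
#' `min_homology` nt.
#'
#' @param mol A [molecule()].
#' @param min_homology Minimum shared scaffold run in nt (default 200).
#' @param adjacent_gap Maximum gap (nt) between inverted repeats for them to
#'   be removed as a unit rather than drive an inversion (default 100).
#' @param scar_remnant Length (nt) of scaffold remnant left behind by
#'   inverted-repeat removal (default 40).
#' @return A list of `list(event=, molecule=)` entries; empty when no
#'   homologous pair exists.
#' @export
host_recombination <- function(mol, min_homology = 200L, adjacent_gap = 100L,
                               scar_remnant = 40L) {
  stopifnot(min_homology >= 1L)
  mol <- rotate_clear(mol)
  ints <- Filter(function(f) f$kind == "intron", mol$features)
  out <- list()
  if (length(ints) < 2L) return(out)
  for (x in seq_len(length(ints) - 1L)) {
    for (y in seq.int(x + 1L, length(ints))) {
      f1 <- ints[[x]]; f2 <- ints[[y]]
      if (f1$start > f2$start) { tmp <- f1; f1 <- f2; f2 <- tmp }
      if (!homologous_introns(f1, f2, min_homology)) next
      r1 <- f1$payload$scaffold_range; r2 <- f2$payload$scaffold_range
      os <- max(r1[1], r2[1]); oe <- min(r1[2], r2[2])
      if (f1$strand == f2$strand) {
        ev <- hr_collapse(mol, f1, f2, os)
      } else {
        gap <- f2$start - f1$end
        if (gap <= adjacent_gap) {
          ev <- hr_ir_removal(mol, f1, f2, scar_remnant)
        } else {
          ev <- hr_inversion(mol, f1, f2, as.integer((os + oe) / 2))
        }
      }
      out <- c(out, list(ev))
    }
  }
  out
}

hr_collapse <- function(mol, f1, f2, os) {
  # both strands identical; for minus-strand repeats work on the other strand
  if (f1$strand == "-") {
    res <- hr_collapse(revcomp_molecule(mol),
                       flip_feat_frame(f2, mol_len(mol)),
                       flip_feat_frame(f1, mol_len(mol)), os)
    res$molecule <- revcomp_molecule(res$molecule)
    return(res)
  }
  x1 <- genomic_of_scaffold(f1, os)
  x2 <- genomic_of_scaffold(f2, os)
  L <- mol_len(mol)
  seq <- paste0(substr(mol$sequence, 1L, x1), substr(mol$sequence, x2 + 1L, L))
  feats <- c(slice_features(mol, 0L, x1),
             shift_feats(slice_features(mol, x2, L), x1))
  list(event = list(type = "hr_collapse", sites = c(f1$label, f2$label),
                    deleted = x2 - x1),
       molecule = molecule(mol$id, seq, mol$topology, feats))
}

flip_feat_frame <- function(f, L) {
  ns <- L - f$end; ne <- L - f$start
  f$start <- as.integer(ns); f$end <- as.integer(ne)
  f$strand <- if (f$strand == "+") "-" else "+"
  f
}

hr_ir_removal <- function(mol, f1, f2, scar_remnant) {
  L <- mol_len(mol)
  remnant <- substr(feature_sequence(mol, f1), 1L,
                    min(scar_remnant, f1$end - f1$start))
  seq <- paste0(substr(mol$sequence, 1L, f1$start), remnant,
                substr(mol$sequence, f2$end + 1L, L))
  # suffix features move from f2$end to f1$start + nchar(remnant)
  feats <- c(slice_features(mol, 0L, f1$start),
             list(feature("scar", f1$start, f1$start + nchar(remnant),
                          strand = "+", label = "ir_scar")),
             shift_feats(slice_features(mol, f2$end, L),
                         f1$start + nchar(remnant)))
  list(event = list(type = "hr_ir_removal", sites = c(f1$label, f2$label),
                    deleted = (f2$end - f1$start) - nchar(remnant)),
       molecule = molecule(mol$id, seq, mol$topology, feats))
}

hr_inversion <- function(mol, f1, f2, sm) {
  x1 <- genomic_of_scaffold(f1, sm)
  x2 <- genomic_of_scaffold(f2, sm)
  if (x1 > x2) { tmp <- x1; x1 <- x2; x2 <- tmp }
  L <- mol_len(mol)
  seq <- paste0(substr(mol$sequence, 1L, x1),
                revcomp(substr(mol$sequence, x1 + 1L, x2)),
                substr(mol$sequence, x2 + 1L, L))
  feats <- c(slice_features(mol, 0L, x1),
             shift_feats(invert_feats(slice_features(mol, x1, x2), x2 - x1), x1),
             shift_feats(slice_features(mol, x2, L), x2))
  list(event = list(type = "hr_inversion", sites = c(f1$label, f2$label),
                    span = c(x1, x2)),
       molecule = molecule(mol$id, seq, mol$topology, feats))
}
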