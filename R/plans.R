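#' Describe one lox-delivery site of an edit plan
#'
#' @param locus Name of the target gene locus.
#' @param lox Catalogue name(s) of the lox site(s) the intron delivers (two
#'   names for a double-site cargo as used in cassette-exchange insertions).
#' @param orientation Desired genomic orientation(s) of the delivered lox
#'   site(s), `"forward"`/`"reverse"`; the cargo orientation inside the
#'   intron is derived from this and the insertion strand.
#' @param intron_type `"Ll.LtrB"` or `"EcI5"`.
#' @param intron_strand `"s"` (sense) or `"a"` (antisense).
#' @return A `plan_site` list.
#' @export
plan_site <- function(locus, lox, orientation = "forward",
                      intron_type = "EcI5", intron_strand = "s") {
  orientation <- rep_len(orientation, length(lox))
  structure(list(locus = locus, lox = lox, orientation = orientation,
                 intron_type = intron_type, intron_strand = intron_strand),
            class = "plan_site")
}

#' Construct an edit plan
#'
#' A declarative description of one genome-editing operation: which loci
#' receive lox-carrying introns, which lox variants and orientations they
#' carry, and (for cassette exchange) what the delivery plasmid looks like.
#'
#' @param operation One of `"deletion"`, `"inversion"`, `"cut_and_paste"`,
#'   `"rmce_insertion"`. Deletions may carry several regions (simultaneous
#'   multi-deletion), which must use mutually incompatible linker classes.
#' @param regions List of regions. Deletion/inversion regions are
#'   `list(locus_up=, locus_down=)` of [plan_site()]s; cut-and-paste adds
#'   `locus_target`; cassette exchange uses `list(locus=)` with a two-site
#'   [plan_site()].
#' @param delivery For `rmce_insertion`: `list(lox = c(name, name),
#'   cargo_length =, backbone_length =)` describing the delivery plasmid.
#' @param name Plan name.
#' @return An object of class `edit_plan`.
#' @export
edit_plan <- function(operation = c("deletion", "inversion", "cut_and_paste",
                                    "rmce_insertion"),
                      regions, delivery = NULL, name = "plan") {
  operation <- match.arg(operation)
  structure(list(operation = operation, regions = regions,
                 delivery = delivery, name = name),
            class = "edit_plan")
}

resolve_lox <- function(name, catalog, orientation = "forward") {
  s <- catalog[[name]]
  if (is.null(s)) {
    loxtron_error("loxtron_unknown_site_error",
                  sprintf("no catalogue site named %s", name))
  }
  s$orientation <- orientation
  attr(s, "lox_name") <- name
  s
}

# Junction product of recombining two same-orientation genomic sites, with
# `up` upstream of `down` on the reference strand.
junction_product <- function(up, down, compat = NULL) {
  if (up$orientation == "forward") recombine(up, down, compat)[[1]]
  else recombine(down, up, compat)[[1]]
}

circle_product <- function(up, down, compat = NULL) {
  if (up$orientation == "forward") recombine(up, down, compat)[[2]]
  else recombine(down, up, compat)[[2]]
}

#' Validate an edit plan's lox pattern
#'
#' Checks that the lox variants, orientations and linker classes satisfy the
#' operation's compatibility pattern before any simulation is attempted:
#' deletions need a same-orientation, same-class pair whose junction product
#' is the inactive double mutant (making the deletion one-way); simultaneous
#' multi-deletions must use pairwise-incompatible linker classes (re-using a
#' class would allow cross-reaction between regions); inversions need an
#' opposite-orientation active pair; cut-and-paste needs a reversible cut
#' pair plus a target site that locks the paste by lox72 formation; cassette
#' exchange needs two incompatible classes with complementary arm mutants
#' between genome and plasmid.
#'
#' @param plan An [edit_plan()].
#' @param catalog A [lox_catalog()].
#' @param compat Optional linker compatibility matrix.
#' @return `TRUE` invisibly; signals a design error otherwise.
#' @export
validate_plan <- function(plan, catalog = lox_catalog(), compat = NULL) {
  op <- plan$operation
  fail <- function(msg) loxtron_error("loxtron_design_error", msg)
  if (op %in% c("deletion", "inversion", "cut_and_paste")) {
    classes <- character(0)
    for (region in plan$regions) {
      up <- resolve_lox(region$locus_up$lox[1], catalog,
                        region$locus_up$orientation[1])
      down <- resolve_lox(region$locus_down$lox[1], catalog,
                          region$locus_down$orientation[1])
      if (!linker_compatible(up, down, compat)) {
        fail(sprintf("sites at %s and %s have incompatible linkers",
                     region$locus_up$locus, region$locus_down$locus))
      }
      if (!is_active(up) || !is_active(down)) fail("inactive lox site in plan")
      if (op == "deletion") {
        if (up$orientation != down$orientation) {
          fail("deletion requires same-orientation lox sites")
        }
        if (is_active(junction_product(up, down, compat))) {
          fail("deletion junction product would remain Cre-active; use complementary arm mutants")
        }
        classes <- c(classes, up$linker_class)
      } else if (op == "inversion") {
        if (up$orientation == down$orientation) {
          fail("inversion requires opposite-orientation lox sites")
        }
      } else {
        if (up$orientation != down$orientation) {
          fail("cut-and-paste flanking sites must share orientation")
        }
        tgt <- resolve_lox(region$locus_target$lox[1], catalog,
                           region$locus_target$orientation[1])
        if (!linker_compatible(up, tgt, compat)) {
          fail("target site linker incompatible with the cut pair")
        }
        if (!is_active(junction_product(up, down, compat))) {
          fail("cut junction would be inactive; the cut step must stay reversible")
        }
        circ <- circle_product(up, down, compat)
        paste_products <- recombine(circ, tgt, compat)
        if (sum(!vapply(paste_products, is_active, logical(1))) != 1L) {
          fail("paste must be locked by forming exactly one inactive (lox72) site")
        }
      }
    }
    if (op == "deletion" && anyDuplicated(classes)) {
      fail(sprintf("simultaneous deletions re-use linker class %s; regions need mutually incompatible classes",
                   classes[duplicated(classes)][1]))
    }
  } else if (op == "rmce_insertion") {
    region <- plan$regions[[1]]
    gsite <- region$locus
    if (length(gsite$lox) != 2L) fail("cassette exchange needs a two-site genomic cargo")
    if (is.null(plan$delivery) || length(plan$delivery$lox) != 2L) {
      fail("cassette exchange needs a two-site delivery plasmid")
    }
    g1 <- resolve_lox(gsite$lox[1], catalog, gsite$orientation[1])
    g2 <- resolve_lox(gsite$lox[2], catalog, gsite$orientation[2])
    if (linker_compatible(g1, g2, compat)) {
      fail("genomic lox pair must use incompatible linker classes")
    }
    for (g in list(g1, g2)) {
      partner <- NULL
      for (dn in plan$delivery$lox) {
        d <- resolve_lox(dn, catalog)
        if (linker_compatible(g, d, compat)) partner <- d
      }
      if (is.null(partner)) fail("no delivery site matches a genomic linker class")
      prods <- recombine(g, partner, compat)
      if (sum(!vapply(prods, is_active, logical(1))) != 1L) {
        fail("each exchange junction must be locked by forming one inactive site")
      }
    }
  }
  invisible(TRUE)
}

# 0-based coordinate at which a locus's intron is inserted (gene midpoint).
locus_insertion_coord <- function(genome, locus) {
  g <- locus_feature(genome, locus)
  g$start + (g$end - g$start) %/% 2L
}

# Compose desired genomic lox orientation with the insertion strand to get
# the cargo-frame orientation.
cargo_orientation <- function(genomic, intron_strand) {
  if (intron_strand == "s") genomic
  else if (genomic == "forward") "reverse" else "forward"
}

#' Apply an edit plan to a genome, producing the uninduced state
#'
#' Inserts the plan's lox-carrying introns at their loci (at the gene
#' midpoint of each named locus) and, for cassette exchange, constructs the
#' delivery plasmid. The result is the "U" strain state, ready for
#' [cre_closure()].
#'
#' @param plan A validated [edit_plan()].
#' @param genome Wild-type genome [molecule()] with the plan's loci as gene
#'   features.
#' @param catalog A [lox_catalog()].
#' @param flexible Build cargo inserts with GAGAG flanks (default `TRUE`).
#' @return A [system_state()] containing the edited chromosome (and the
#'   delivery plasmid for cassette exchange).
#' @export
apply_plan <- function(plan, genome, catalog = lox_catalog(), flexible = TRUE) {
  validate_plan(plan, catalog)
  mol <- genome
  specs <- list()
  for (region in plan$regions) {
    specs <- c(specs, region[intersect(c("locus_up", "locus_down", "locus_target",
                                         "locus"), names(region))])
  }
  for (sp in specs) {
    sites <- lapply(seq_along(sp$lox), function(i) {
      s <- resolve_lox(sp$lox[i], catalog)
      s$orientation <- cargo_orientation(sp$orientation[i], sp$intron_strand)
      attr(s, "lox_name") <- sp$lox[i]
      s
    })
    cargo <- design_insert(sites, flexible = flexible, catalog = catalog)
    coord <- locus_insertion_coord(mol, sp$locus)
    g <- locus_feature(mol, sp$locus)
    design <- intron_design(sp$intron_type, sp$locus,
                            target_position = coord - g$start,
                            target_strand = sp$intron_strand, cargo = cargo)
    mol <- insert_intron(mol, coord, design)
  }
  mols <- list(mol)
  if (plan$operation == "rmce_insertion") {
    mols <- c(mols, list(build_delivery_plasmid(plan, catalog)))
  }
  system_state(mols)
}

# Delivery plasmid for cassette exchange: cargo flanked by the two delivery
# lox sites, on a synthetic backbone.
build_delivery_plasmid <- function(plan, catalog = lox_catalog()) {
  d <- plan$delivery
  cargo_len <- d$cargo_length %||% 1000L
  backbone_len <- d$backbone_length %||% 2500L
  s1 <- resolve_lox(d$lox[1], catalog)
  s2 <- resolve_lox(d$lox[2], catalog)
  body <- with_seed(d$seed %||% 424243L, {
    list(cargo = random_dna(cargo_len), backbone = random_dna(backbone_len))
  })
  seq <- paste0(lox_sequence(s1), body$cargo, lox_sequence(s2), body$backbone)
  feats <- list(
    feature("lox", 0L, 34L, "+", label = paste0("plasmid:", d$lox[1]), payload = s1),
    feature("gene", 34L, 34L + cargo_len, "+", label = "cargo"),
    feature("lox", 34L + cargo_len, 68L + cargo_len, "+",
            label = paste0("plasmid:", d$lox[2]), payload = s2)
  )
  molecule("delivery_plasmid", seq, "circular", feats)
}

#' Deterministic host inverted-repeat removal pass
#'
#' Applies adjacent inverted-repeat removal events (see
#' [host_recombination()]) repeatedly until none remain. The cell deletes
#' such repeats after Cre-mediated recombination, removing the lox sites
#' entirely and shrinking the scar from hundreds to tens of base pairs; the
#' pass is applied after [cre_closure()] because it is a subsequent host
#' event, not part of the Cre transition system.
#'
#' @param mol A [molecule()].
#' @param min_homology,adjacent_gap,scar_remnant See [host_recombination()].
#' @return The molecule after all adjacent inverted repeats are removed.
#' @export
resolve_inverted_repeats <- function(mol, min_homology = 200L,
                                     adjacent_gap = 100L, scar_remnant = 40L) {
  repeat {
    evs <- host_recombination(mol, min_homology, adjacent_gap, scar_remnant)
    hit <- Filter(function(e) e$event$type == "hr_ir_removal", evs)
    if (length(hit) == 0L) return(mol)
    mol <- hit[[1]]$molecule
  }
}

#' Classify the qualitative outcome of an edit design
#'
#' Simulates the design and reports the qualitative outcome columns used to
#' summarize rearrangement strains: whether the Cre products contain an
#' inverted repeat of intron sequences (scanned on the terminal states),
#' whether recombination can occur in the absence of Cre (host homologous
#' recombination between intron scaffolds, possible only when homologous
#' introns are present in an orientation permitting it: `"full"` when the
#' host event reproduces the designed operation, `"partial"` when it only
#' mimics an intermediate -- the inversions seen for cut-and-paste designs --
#' and `"none"` otherwise), and whether the initial configuration is
#' re-reachable (reversibility).
#'
#' @param plan An [edit_plan()].
#' @param genome Wild-type genome [molecule()]; generated from the plan's
#'   loci with [make_genome()] when `NULL`.
#' @param catalog A [lox_catalog()].
#' @param min_homology Minimum homologous run (nt) between intron scaffolds.
#' @param max_states Bound for [cre_closure()].
#' @param compat Optional linker compatibility matrix.
#' @param scar_remnant Scar remnant length for the host removal pass.
#' @return An `outcome_report` with `inverted_repeat_generated`,
#'   `cre_independent_recombination` (logical), `cre_independent_level`
#'   (`"none"`/`"partial"`/`"full"`), `reversible`, `scar_description` and
#'   `terminal_states`.
#' @export
classify_design <- function(plan, genome = NULL, catalog = lox_catalog(),
                            min_homology = 200L, max_states = 10000L,
                            compat = NULL, scar_remnant = 40L) {
  validate_plan(plan, catalog, compat)
  if (is.null(genome)) {
    loci <- unique(unlist(lapply(plan$regions, function(r) {
      vapply(r[intersect(c("locus_up", "locus_down", "locus_target", "locus"),
                         names(r))],
             function(sp) sp$locus, character(1))
    })))
    genome <- make_genome(fixture_spec(seed = 99L, genome_length = 8000L * length(loci),
                                       loci = loci), catalog)$molecule
  }
  ustate <- apply_plan(plan, genome, catalog)
  rep <- cre_closure(ustate, max_states = max_states, compat = compat,
                     min_homology = min_homology)
  rep$cre_independent_level <- cre_independent_level(plan, ustate$molecules[[1]],
                                                     min_homology)
  rep$cre_independent_recombination <- rep$cre_independent_level != "none"
  # scar bookkeeping on the operation-consistent induced chromosome
  term <- pick_induced_terminal(rep, genome$id, plan)
  chrom <- Filter(function(m) m$id == genome$id, term$molecules)
  if (length(chrom) > 0L) {
    chrom <- resolve_inverted_repeats(chrom[[1]], min_homology,
                                      scar_remnant = scar_remnant)
    scars <- Filter(function(f) f$kind == "scar", chrom$features)
    dead_lox <- Filter(function(f) f$kind == "lox" && !is_active(f$payload),
                       chrom$features)
    rep$scar_description <- if (length(scars) > 0L) {
      list(length = scars[[1]]$end - scars[[1]]$start, contains_lox = FALSE)
    } else if (length(dead_lox) > 0L) {
      list(length = 34L, contains_lox = TRUE)
    } else NULL
  }
  rep
}

# Structural rule for Cre-independent (host) recombination: homologous
# introns must be present in an orientation whose homologous-recombination
# product matches the assayed rearrangement. Direct repeats recombine to a
# deletion, inverted repeats to an inversion; for cut-and-paste designs an
# inverted homologous pair yields only the intermediate inversion (partial).
cre_independent_level <- function(plan, chrom, min_homology = 200L) {
  ints <- Filter(function(f) f$kind == "intron", chrom$features)
  if (length(ints) < 2L) return("none")
  find_intron <- function(locus) {
    for (f in ints) {
      if (grepl(paste0("\\.", locus, "\\."), f$label)) return(f)
    }
    NULL
  }
  level <- "none"
  for (region in plan$regions) {
    up <- find_intron(region$locus_up$locus)
    down <- find_intron(region$locus_down$locus)
    if (plan$operation == "deletion") {
      if (!is.null(up) && !is.null(down) &&
          homologous_introns(up, down, min_homology) &&
          up$strand == down$strand) {
        return("full")
      }
    } else if (plan$operation == "inversion") {
      if (!is.null(up) && !is.null(down) &&
          homologous_introns(up, down, min_homology) &&
          up$strand != down$strand) {
        return("full")
      }
    } else if (plan$operation == "cut_and_paste") {
      for (x in seq_len(length(ints) - 1L)) {
        for (y in seq.int(x + 1L, length(ints))) {
          if (homologous_introns(ints[[x]], ints[[y]], min_homology) &&
              ints[[x]]$strand != ints[[y]]$strand) {
            level <- "partial"
          }
        }
      }
    }
  }
  level
}

#' Load the shipped rearrangement design panel
#'
#' A catalogue of twelve representative chromosome-rearrangement designs
#' (deletions, inversions and cut-and-pastes between named loci, with the
#' intron type and insertion strand used at each locus) together with their
#' expected qualitative outcomes, used to exercise [classify_design()].
#'
#' @param path Optional TSV path; defaults to the shipped panel.
#' @return A data.frame.
#' @export
rearrangement_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rearrangement_panel.tsv", package = "loxtron")
  }
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Build the edit plan for one rearrangement-panel row
#'
#' Standard lox assignments per operation: deletions place lox71 upstream
#' and lox66 downstream in the same orientation; inversions the same pair in
#' opposite orientations; cut-and-pastes flank the region with loxP and
#' lox71 and put lox66 at the target.
#'
#' @param row One row of [rearrangement_panel()].
#' @return An [edit_plan()].
#' @export
panel_plan <- function(row) {
  if (row$operation == "deletion") {
    regions <- list(list(
      locus_up = plan_site(row$locus_a, "lox71", "forward",
                           row$type_a, row$strand_a),
      locus_down = plan_site(row$locus_b, "lox66", "forward",
                             row$type_b, row$strand_b)))
  } else if (row$operation == "inversion") {
    regions <- list(list(
      locus_up = plan_site(row$locus_a, "lox71", "forward",
                           row$type_a, row$strand_a),
      locus_down = plan_site(row$locus_b, "lox66", "reverse",
                             row$type_b, row$strand_b)))
  } else {
    regions <- list(list(
      locus_up = plan_site(row$locus_a, "loxP", "forward",
                           row$type_a, row$strand_a),
      locus_down = plan_site(row$locus_b, "lox71", "forward",
                             row$type_b, row$strand_b),
      locus_target = plan_site(row$locus_target, "lox66", "forward",
                               row$type_target, row$strand_target)))
  }
  edit_plan(row$operation, regions, name = row$id)
}

#' Read an edit plan from a YAML document
#'
#' Schema (version 1): top-level `operation`, `regions` (list of mappings
#' with `locus_up`/`locus_down`/`locus_target`/`locus` entries, each with
#' `locus`, `lox`, `orientation`, `intron_type`, `intron_strand`), and
#' optional `delivery`.
#'
#' @param path YAML file path.
#' @return An [edit_plan()].
#' @export
read_edit_plan <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$operation) || is.null(doc$regions)) {
    loxtron_error("loxtron_parse_error",
                  "edit plan must declare 'operation' and 'regions'")
  }
  regions <- lapply(doc$regions, function(r) {
    lapply(r, function(sp) {
      plan_site(sp$locus, unlist(sp$lox),
                unlist(sp$orientation) %||% "forward",
                sp$intron_type %||% "EcI5", sp$intron_strand %||% "s")
    })
  })
  edit_plan(doc$operation, regions, delivery = doc$delivery,
            name = doc$name %||% tools::file_path_sans_ext(basename(path)))
}
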