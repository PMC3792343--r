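#' Construct an annotated DNA molecule
#'
#' Molecules host chromosomes, plasmids and excised circles. Coordinates are
#' 0-based half-open on the reference strand; features never wrap the origin
#' of a circular molecule (operations that would create a wrapping feature
#' rotate or split instead).
#'
#' @param id Molecule identifier.
#' @param sequence DNA string.
#' @param topology `"circular"` or `"linear"`.
#' @param features List of [feature()] objects.
#' @return An object of class `molecule`.
#' @export
molecule <- function(id, sequence, topology = c("circular", "linear"),
                     features = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  stopifnot(is_dna(sequence))
  mol <- structure(list(id = id, sequence = sequence, topology = topology,
                        features = list()), class = "molecule")
  for (f in features) mol <- add_feature(mol, f)
  mol
}

#' Construct a feature annotation
#'
#' @param kind One of `"gene"`, `"intron"`, `"lox"`, `"primer_site"`, `"scar"`.
#' @param start,end 0-based half-open interval on the reference strand.
#' @param strand `"+"` or `"-"`.
#' @param label Free-text label.
#' @param payload For `lox` features a [lox_site()]; for `intron` features a
#'   list with `intron_type`, `scaffold_range` (0-based half-open interval of
#'   the full insert sequence still present) and `scaffold_len`.
#' @return An object of class `feature`.
#' @export
feature <- function(kind, start, end, strand = "+", label = "", payload = NULL) {
  kind <- match.arg(kind, c("gene", "intron", "lox", "primer_site", "scar"))
  stopifnot(strand %in% c("+", "-"), start >= 0, end > start)
  if (kind == "lox") {
    stopifnot(end - start == 34L)
    stopifnot(inherits(payload, "lox_site"))
  }
  if (kind == "intron") {
    stopifnot(!is.null(payload$intron_type))
  }
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 strand = strand, label = label, payload = payload),
            class = "feature")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> %d bp, %s, %d features\n",
              x$id, mol_len(x), x$topology, length(x$features)))
  for (f in x$features) {
    cat(sprintf("  %-12s [%d, %d) %s %s\n", f$kind, f$start, f$end, f$strand, f$label))
  }
  invisible(x)
}

#' Length of a molecule in base pairs
#' @param mol A [molecule()].
#' @return Integer length.
#' @export
mol_len <- function(mol) nchar(mol$sequence)

#' Add a feature to a molecule
#' @param mol A [molecule()].
#' @param feat A [feature()].
#' @return The molecule with the feature appended (sorted by start).
#' @export
add_feature <- function(mol, feat) {
  if (feat$end > mol_len(mol)) {
    loxtron_error("loxtron_bounds_error",
                  sprintf("feature [%d,%d) outside molecule of length %d",
                          feat$start, feat$end, mol_len(mol)))
  }
  mol$features <- c(mol$features, list(feat))
  ord <- order(vapply(mol$features, function(f) f$start, integer(1)))
  mol$features <- mol$features[ord]
  mol
}

#' Extract the sequence under a feature
#' @param mol A [molecule()].
#' @param feat A [feature()] of `mol`.
#' @return Reference-strand sequence of the feature interval.
#' @export
feature_sequence <- function(mol, feat) {
  substr(mol$sequence, feat$start + 1L, feat$end)
}

# Remap the features of mol that survive restriction to the slice [from, to),
# re-origined at 0. Intron features are clipped (scaffold_range updated);
# other partially overlapping features are dropped (they are disrupted).
slice_features <- function(mol, from, to) {
  out <- list()
  for (f in mol$features) {
    if (f$start >= from && f$end <= to) {
      f$start <- f$start - as.integer(from)
      f$end <- f$end - as.integer(from)
      out <- c(out, list(f))
    } else if (f$kind == "intron" && f$start < to && f$end > from) {
      ns <- max(f$start, from)
      ne <- min(f$end, to)
      f <- clip_intron(f, ns, ne)
      f$start <- ns - as.integer(from)
      f$end <- ne - as.integer(from)
      out <- c(out, list(f))
    }
  }
  out
}

# Clip an intron feature to genomic subinterval [ns, ne), updating the
# scaffold_range payload so homology bookkeeping survives truncation.
clip_intron <- function(f, ns, ne) {
  sr <- f$payload$scaffold_range
  if (f$strand == "+") {
    f$payload$scaffold_range <- c(sr[1] + (ns - f$start), sr[1] + (ne - f$start))
  } else {
    f$payload$scaffold_range <- c(sr[2] - (ne - f$start), sr[2] - (ns - f$start))
  }
  f
}

# Rotate a circular molecule so that position `offset` becomes position 0.
# Features crossing the new origin are split (introns) or dropped (others).
rotate_molecule <- function(mol, offset) {
  stopifnot(mol$topology == "circular")
  L <- mol_len(mol)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(mol)
  seq2 <- paste0(substr(mol$sequence, offset + 1L, L), substr(mol$sequence, 1L, offset))
  feats <- list()
  for (f in mol$features) {
    if (f$start >= offset) {
      f$start <- f$start - offset; f$end <- f$end - offset
      feats <- c(feats, list(f))
    } else if (f$end <= offset) {
      f$start <- f$start + (L - offset); f$end <- f$end + (L - offset)
      feats <- c(feats, list(f))
    } else if (f$kind == "intron") {
      head_part <- clip_intron(f, f$start, offset)
      head_part$end <- offset
      head_part$start <- f$start
      head_part$start <- head_part$start + (L - offset)
      head_part$end <- head_part$end + (L - offset)
      tail_part <- clip_intron(f, offset, f$end)
      tail_part$start <- 0L
      tail_part$end <- f$end - offset
      feats <- c(feats, list(head_part), list(tail_part))
    }
  }
  molecule(mol$id, seq2, mol$topology, feats)
}

# Reverse-complement a molecule, remapping features to the other strand.
revcomp_molecule <- function(mol) {
  L <- mol_len(mol)
  feats <- lapply(mol$features, function(f) {
    ns <- L - f$end
    ne <- L - f$start
    f$start <- as.integer(ns); f$end <- as.integer(ne)
    f$strand <- if (f$strand == "+") "-" else "+"
    if (f$kind == "lox") f$payload <- flip_orientation(f$payload)
    f
  })
  molecule(mol$id, revcomp(mol$sequence), mol$topology, feats)
}

# Offset r such that rotating the circular sequence to start at r yields its
# lexicographically least rotation (deterministic canonical frame).
canonical_offset <- function(seq) {
  least_rotation_offset(seq)
}

# Rotate a circular molecule so that the origin falls in the middle of the
# largest feature-free stretch; feature adjacency can then be read without
# wraparound arithmetic.
rotate_clear <- function(mol) {
  if (mol$topology != "circular" || length(mol$features) == 0L) return(mol)
  L <- mol_len(mol)
  starts <- vapply(mol$features, function(f) f$start, integer(1))
  ends <- vapply(mol$features, function(f) f$end, integer(1))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  gaps <- c(starts[-1] - ends[-length(ends)], L - ends[length(ends)] + starts[1])
  i <- which.max(gaps)
  off <- if (i == length(gaps)) (ends[length(ends)] + gaps[i] %/% 2L) %% L
         else ends[i] + gaps[i] %/% 2L
  rotate_molecule(mol, off)
}

#' List all lox sites on a molecule in coordinate order
#'
#' For circular molecules the order is taken in the canonical rotation frame
#' (the lexicographically least rotation of the sequence), so rotated
#' representations of the same molecule list their sites identically.
#'
#' @param mol A [molecule()].
#' @return A list of entries `list(feature=, site=)`, ordered by coordinate.
#' @export
locate_lox <- function(mol) {
  lox <- Filter(function(f) f$kind == "lox", mol$features)
  if (length(lox) == 0L) return(list())
  starts <- vapply(lox, function(f) f$start, integer(1))
  if (mol$topology == "circular") {
    r <- canonical_offset(mol$sequence)
    key <- (starts - r) %% mol_len(mol)
  } else {
    key <- starts
  }
  lox <- lox[order(key)]
  lapply(lox, function(f) list(feature = f, site = f$payload))
}

#' Describe an intron design
#'
#' Couples an intron scaffold with its target (gene, position, strand) and
#' the lox cargo placed at the scaffold's cargo cloning site (the position
#' occupied by the intron-encoded protein ORF in the wild-type intron).
#'
#' @param intron_type `"Ll.LtrB"` or `"EcI5"`.
#' @param target_gene Gene name.
#' @param target_position 1-based position within the gene (field convention:
#'   the intron inserts between this base and the next).
#' @param target_strand `"s"` (sense) or `"a"` (antisense).
#' @param cargo A `cargo_insert` from [design_insert()], or `NULL` for a
#'   cargo-less intron.
#' @param scaffold An [intron_scaffold()]; defaults to the synthetic scaffold
#'   for `intron_type`.
#' @return An object of class `intron_design`.
#' @export
intron_design <- function(intron_type = c("Ll.LtrB", "EcI5"), target_gene,
                          target_position, target_strand = c("s", "a"),
                          cargo = NULL, scaffold = NULL) {
  intron_type <- match.arg(intron_type)
  target_strand <- match.arg(target_strand)
  if (is.null(scaffold)) scaffold <- intron_scaffold(intron_type)
  structure(list(intron_type = intron_type, target_gene = target_gene,
                 target_position = as.integer(target_position),
                 target_strand = target_strand, cargo = cargo,
                 scaffold = scaffold),
            class = "intron_design")
}

# Full insert sequence of a design (scaffold with cargo spliced at the cargo
# site), plus cargo lox offsets within that insert, in the scaffold frame.
design_insert_seq <- function(design) {
  sc <- design$scaffold
  if (is.null(design$cargo)) {
    return(list(seq = sc$sequence, lox = list()))
  }
  cs <- design$cargo$sequence
  seq <- paste0(substr(sc$sequence, 1L, sc$cargo_pos),
                cs,
                substr(sc$sequence, sc$cargo_pos + 1L, nchar(sc$sequence)))
  lox <- lapply(design$cargo$lox, function(l) {
    l$offset <- l$offset + sc$cargo_pos
    l
  })
  list(seq = seq, lox = lox)
}

#' Insert a designed intron into a molecule
#'
#' Splices the scaffold-plus-cargo sequence between the bases at
#' `site_coordinate` and `site_coordinate + 1` (0-based: between positions
#' `site_coordinate - 1` and `site_coordinate` of the reference strand),
#' shifting downstream features. Antisense (`"a"`) designs insert the
#' reverse complement, and cargo lox orientations compose with the insertion
#' strand.
#'
#' @param mol A [molecule()].
#' @param site_coordinate 0-based coordinate at which the insert begins.
#' @param design An [intron_design()].
#' @return The edited molecule.
#' @export
insert_intron <- function(mol, site_coordinate, design) {
  L <- mol_len(mol)
  if (site_coordinate < 0 || site_coordinate > L) {
    loxtron_error("loxtron_bounds_error",
                  sprintf("insertion coordinate %d outside [0, %d]", site_coordinate, L))
  }
  for (f in mol$features) {
    if (f$kind == "intron" && f$start < site_coordinate && f$end > site_coordinate) {
      loxtron_error("loxtron_conflict_error",
                    sprintf("insertion coordinate %d lies inside existing intron %s",
                            site_coordinate, f$label))
    }
  }
  ins <- design_insert_seq(design)
  n <- nchar(ins$seq)
  sense <- design$target_strand == "s"
  ins_seq <- if (sense) ins$seq else revcomp(ins$seq)
  seq2 <- paste0(substr(mol$sequence, 1L, site_coordinate), ins_seq,
                 substr(mol$sequence, site_coordinate + 1L, L))
  feats <- lapply(mol$features, function(f) {
    if (f$start >= site_coordinate) {
      f$start <- f$start + n; f$end <- f$end + n
    }
    f
  })
  name <- format_intron_name(design)
  intron_feat <- feature("intron", site_coordinate, site_coordinate + n,
                         strand = if (sense) "+" else "-", label = name,
                         payload = list(intron_type = design$intron_type,
                                        scaffold_range = c(0L, n),
                                        scaffold_len = n))
  lox_feats <- lapply(ins$lox, function(l) {
    if (sense) {
      s <- site_coordinate + l$offset
      site <- l$site
    } else {
      s <- site_coordinate + (n - l$offset - 34L)
      site <- flip_orientation(l$site)
    }
    feature("lox", s, s + 34L,
            strand = if (site$orientation == "forward") "+" else "-",
            label = paste0(name, ":", l$name), payload = site)
  })
  out <- molecule(mol$id, seq2, mol$topology, feats)
  out <- add_feature(out, intron_feat)
  for (lf in lox_feats) out <- add_feature(out, lf)
  out
}

#' Synthetic intron scaffold
#'
#' Deterministic synthetic stand-ins (~1 kb) for the Ll.LtrB and EcI5 intron
#' scaffolds, sized to match the roughly 1-kb enlargement that intron
#' insertion adds to verification amplicons. The two types share no designed
#' homology. Each scaffold carries annotated recognition-element coordinates
#' (EBS2, EBS1, delta), a cargo cloning position (the MluI-equivalent site),
#' and the restriction ends used for retargeting-fragment cloning.
#'
#' @param intron_type `"Ll.LtrB"` or `"EcI5"`.
#' @param length Scaffold length in nt (default 1000).
#' @return An object of class `intron_scaffold`.
#' @export
intron_scaffold <- function(intron_type = c("Ll.LtrB", "EcI5"), length = 1000L) {
  intron_type <- match.arg(intron_type)
  # fixed internal seeds make the synthetic scaffolds package constants
  seed <- if (intron_type == "Ll.LtrB") 761001L else 761002L
  seq <- with_seed(seed, random_dna(length))
  if (intron_type == "Ll.LtrB") {
    elements <- list(EBS2 = c(41L, 45L), EBS1 = c(60L, 65L), delta = c(70L, 72L))
    ends <- c("HindIII", "BsrGI")
  } else {
    elements <- list(EBS2 = c(36L, 40L), EBS1 = c(55L, 60L), delta = c(65L, 66L))
    ends <- c("AvaII", "XbaI")
  }
  structure(list(intron_type = intron_type, sequence = seq,
                 cargo_pos = as.integer(length / 2L), elements = elements,
                 ends = ends),
            class = "intron_scaffold")
}

#' Read sequences from a FASTA file
#'
#' Headers containing the word `circular` yield circular molecules; all
#' others are linear.
#'
#' @param path FASTA file path.
#' @return A list of [molecule()] objects (without features).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    topo <- if (grepl("circular", nm)) "circular" else "linear"
    molecule(sub("\\s.*$", "", nm), as.character(set[[i]]), topo)
  })
}

#' Write molecules to a FASTA file
#' @param mols A [molecule()] or list of molecules.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  seqs <- Biostrings::DNAStringSet(vapply(mols, function(m) m$sequence, character(1)))
  names(seqs) <- vapply(mols, function(m) paste(m$id, m$topology), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

genbank_location <- function(f) {
  loc <- sprintf("%d..%d", f$start + 1L, f$end)
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

feature_note <- function(f) {
  if (f$kind == "intron") {
    sprintf("kind:intron;type:%s;srange:%d-%d;slen:%d",
            f$payload$intron_type, f$payload$scaffold_range[1],
            f$payload$scaffold_range[2], f$payload$scaffold_len)
  } else {
    paste0("kind:", f$kind)
  }
}

#' Write a molecule to a GenBank flat file
#'
#' Genes map to `gene` features, primer sites to `primer_bind`, and lox,
#' intron and scar annotations to `misc_feature` with structured `/note`
#' qualifiers that [read_genbank()] can reconstruct.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(mol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  L <- mol_len(mol)
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT",
                     substr(mol$id, 1, 16), L, mol$topology), con)
  writeLines(sprintf("DEFINITION  %s.", mol$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (f in mol$features) {
    key <- switch(f$kind, gene = "gene", primer_site = "primer_bind", "misc_feature")
    writeLines(sprintf("     %-15s %s", key, genbank_location(f)), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label), con)
    writeLines(sprintf("                     /note=\"%s\"", feature_note(f)), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(mol$sequence, p, min(p + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tolower(groups), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' A minimal reader for the subset of the format this package writes: LOCUS
#' topology, `gene` / `primer_bind` / `misc_feature` keys with `/label` and
#' structured `/note` qualifiers, and the ORIGIN sequence block. Lox payloads
#' are reconstructed by parsing the annotated 34-mer against the catalogue.
#'
#' @param path GenBank file path.
#' @param catalog A [lox_catalog()] used to reparse lox features.
#' @return A [molecule()].
#' @export
read_genbank <- function(path, catalog = lox_catalog()) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  topo <- if (grepl("circular", locus)) "circular" else "linear"
  ori <- which(grepl("^ORIGIN", lines))[1]
  seq_lines <- lines[(ori + 1L):(length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtACGT]", "", paste(seq_lines, collapse = "")))
  feat_lines <- lines[seq_len(ori - 1L)]
  idx <- which(grepl("^     \\S", feat_lines))
  feats <- list()
  for (i in idx) {
    parts <- strsplit(trimws(feat_lines[i]), "\\s+")[[1]]
    if (parts[1] == "source") next
    loc <- parts[2]
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
    start <- nums[1] - 1L; end <- nums[2]
    quals <- character(0)
    j <- i + 1L
    while (j <= length(feat_lines) && grepl("^\\s{10,}/", feat_lines[j])) {
      quals <- c(quals, trimws(feat_lines[j])); j <- j + 1L
    }
    get_q <- function(name) {
      hit <- quals[grepl(paste0("^/", name, "="), quals)]
      if (length(hit) == 0L) return("")
      gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
    }
    label <- get_q("label")
    note <- get_q("note")
    kind <- sub("^kind:([a-z_]+).*$", "\\1", note)
    if (!kind %in% c("gene", "intron", "lox", "primer_site", "scar")) {
      kind <- switch(parts[1], gene = "gene", primer_bind = "primer_site", "scar")
    }
    payload <- NULL
    if (kind == "lox") {
      payload <- parse_lox(substr(sequence, start + 1L, end), catalog)
    } else if (kind == "intron") {
      m <- regmatches(note, regexec("type:([^;]+);srange:([0-9]+)-([0-9]+);slen:([0-9]+)", note))[[1]]
      payload <- list(intron_type = m[2],
                      scaffold_range = c(as.integer(m[3]), as.integer(m[4])),
                      scaffold_len = as.integer(m[5]))
    }
    feats <- c(feats, list(feature(kind, start, end, strand, label, payload)))
  }
  molecule(id, sequence, topo, feats)
}
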