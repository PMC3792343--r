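# Canonical intron-type labels <-> the tokens used in intron names.
intron_type_token <- function(intron_type) {
  if (intron_type == "Ll.LtrB") "LtrB" else intron_type
}

intron_type_from_token <- function(token) {
  if (token == "LtrB") "Ll.LtrB" else token
}

#' Parse an intron name
#'
#' Intron names follow the grammar `TYPE.GENE.POSITION{s|a}[.CARGO]`, e.g.
#' `EcI5.LacZ.1806s`: the number is the 1-based position within the gene at
#' which the intron inserts, and `s`/`a` says whether it inserts into the
#' sense or antisense strand. An optional trailing token names the lox cargo
#' carried in the intron (as in `T5.rDNA.798s.1WL2R`).
#'
#' @param name Intron name string.
#' @return List with `intron_type` (canonical, `LtrB` token maps to
#'   `Ll.LtrB`), `gene`, `position`, `strand` (`"s"`/`"a"`), and `cargo`
#'   (`NA` if absent).
#' @export
parse_intron_name <- function(name) {
  m <- regmatches(name, regexec(
    "^([A-Za-z][A-Za-z0-9]*)\\.([A-Za-z][A-Za-z0-9_]*)\\.([0-9]+)([sa])(\\.([A-Za-z0-9/]+))?$",
    name))[[1]]
  if (length(m) == 0L) {
    bad <- if (!grepl("\\.", name)) name else {
      toks <- strsplit(name, ".", fixed = TRUE)[[1]]
      toks[max(1L, length(toks))]
    }
    loxtron_error("loxtron_parse_error",
                  sprintf("malformed intron name '%s' (offending token: '%s')",
                          name, bad))
  }
  list(intron_type = intron_type_from_token(m[2]), gene = m[3],
       position = as.integer(m[4]), strand = m[5],
       cargo = if (nchar(m[7]) > 0L) m[7] else NA_character_)
}

#' Format an intron name
#'
#' Inverse of [parse_intron_name()]; also accepts an [intron_design()].
#'
#' @param x An [intron_design()], or a list with fields `intron_type`,
#'   `gene` (or `target_gene`), `position` (or `target_position`), `strand`
#'   (or `target_strand`) and optionally `cargo`.
#' @return The name string.
#' @export
format_intron_name <- function(x) {
  gene <- x$gene %||% x$target_gene
  pos <- x$position %||% x$target_position
  strand <- x$strand %||% x$target_strand
  cargo <- if (inherits(x$cargo, "cargo_insert")) x$cargo$name else x$cargo
  base <- sprintf("%s.%s.%d%s", intron_type_token(x$intron_type), gene, pos, strand)
  if (is.null(cargo) || is.na(cargo)) base else paste0(base, ".", cargo)
}

#' Build a target-site recognition template
#'
#' Describes the base-pairing elements through which the intron RNA reads
#' its DNA target: each element (EBS2 pairing IBS2, EBS1 pairing IBS1, and
#' the delta element) covers a range of positions relative to the insertion
#' point, which sits between the -1 and +1 bases. Default ranges per intron
#' type are editable configuration. Optional `fixed_bases` give hard
#' constraints (named by offset, e.g. `c("1" = "T")`) that
#' [enumerate_sites()] enforces; detailed efficiency scoring is delegated to
#' a pluggable scorer.
#'
#' @param intron_type `"Ll.LtrB"` or `"EcI5"`.
#' @param elements Named list of `c(from, to)` offset ranges (no position 0).
#' @param window `c(from, to)` recognition window offsets.
#' @param fixed_bases Optional named character vector of required bases.
#' @return An object of class `pairing_template`.
#' @export
pairing_template <- function(intron_type = c("Ll.LtrB", "EcI5"),
                             elements = NULL, window = c(-15L, 5L),
                             fixed_bases = NULL) {
  intron_type <- match.arg(intron_type)
  if (is.null(elements)) {
    elements <- if (intron_type == "Ll.LtrB") {
      list(EBS2 = c(-12L, -8L), EBS1 = c(-6L, -1L), delta = c(1L, 3L))
    } else {
      list(EBS2 = c(-11L, -7L), EBS1 = c(-6L, -1L), delta = c(1L, 2L))
    }
  }
  for (e in elements) {
    stopifnot(length(e) == 2L, e[1] <= e[2], e[1] >= window[1], e[2] <= window[2])
  }
  # ranges must be pairwise disjoint
  covered <- unlist(lapply(elements, function(e) seq(e[1], e[2])))
  stopifnot(!anyDuplicated(covered), !0L %in% covered)
  structure(list(intron_type = intron_type, elements = elements,
                 window = as.integer(window), fixed_bases = fixed_bases),
            class = "pairing_template")
}

# Index of offset k (k != 0) within the contiguous window string.
window_index <- function(k, wmin) {
  ifelse(k < 0L, k - wmin + 1L, k - wmin)
}

window_at <- function(window, template) {
  wmin <- template$window[1]
  function(k) substr(window, window_index(k, wmin), window_index(k, wmin))
}

#' Enumerate candidate intron insertion sites in a gene
#'
#' Scans every insertion position on both strands and keeps those whose
#' recognition window satisfies the template's hard base constraints. The
#' window spans the template's offset range around the insertion point
#' (between the -1 and +1 bases). An optional scorer function
#' `function(window) -> numeric` is applied to each surviving site.
#'
#' @param gene_sequence DNA string of the gene (sense strand).
#' @param template A [pairing_template()].
#' @param scorer Optional scoring hook.
#' @return A data.frame with columns `gene_position` (1-based, sense-strand
#'   coordinates; the intron inserts after this base on the given strand),
#'   `strand` (`"s"`/`"a"`), `window`, and `score` if a scorer was given,
#'   ordered by coordinate.
#' @export
enumerate_sites <- function(gene_sequence, template, scorer = NULL) {
  gene_sequence <- toupper(gene_sequence)
  L <- nchar(gene_sequence)
  wmin <- template$window[1]; wmax <- template$window[2]
  span <- wmax - wmin
  out <- list()
  if (L < span) {
    return(data.frame(gene_position = integer(0), strand = character(0),
                      window = character(0), stringsAsFactors = FALSE))
  }
  scan_strand <- function(seq, strand) {
    res <- list()
    for (pos in seq.int(-wmin, L - wmax)) {
      win <- substr(seq, pos + wmin + 1L, pos + wmax)
      ok <- TRUE
      for (nm in names(template$fixed_bases %||% character(0))) {
        k <- as.integer(nm)
        if (substr(win, window_index(k, wmin), window_index(k, wmin)) !=
            template$fixed_bases[[nm]]) { ok <- FALSE; break }
      }
      if (!ok) next
      gp <- if (strand == "s") pos else L - pos
      res <- c(res, list(data.frame(gene_position = gp, strand = strand,
                                    window = win, stringsAsFactors = FALSE)))
    }
    res
  }
  out <- c(scan_strand(gene_sequence, "s"),
           scan_strand(revcomp(gene_sequence), "a"))
  if (length(out) == 0L) {
    return(data.frame(gene_position = integer(0), strand = character(0),
                      window = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$gene_position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(scorer)) df$score <- vapply(df$window, scorer, numeric(1))
  df
}

#' Build a retargeting fragment for a chosen target site
#'
#' Rewrites the scaffold's recognition elements so that each base-pairs
#' (antiparallel Watson-Crick) with its assigned range of the target window,
#' and emits the primer set used to assemble the fragment: the four-primer
#' set (IBS, EBS1, EBS2, EBS2AS) for Ll.LtrB, or the two sequential PCRs
#' (IBS1/2S + EBS2AS, then EBS1S + EBSR) for EcI5. Fragment ends carry the
#' restriction labels used for cloning into the intron vector:
#' HindIII/BsrGI for Ll.LtrB, AvaII/XbaI for EcI5.
#'
#' @param site One row of [enumerate_sites()] output (or a list with
#'   `window`), plus optionally `gene_position`/`strand` for naming.
#' @param template The [pairing_template()] used for enumeration.
#' @param scaffold An [intron_scaffold()] of the matching type.
#' @return A `retargeting_fragment`: list with `intron_type`, `sequence`,
#'   `ends` (named restriction labels), `primers` (data.frame name/sequence)
#'   and `elements` (element sequences placed in the fragment).
#' @export
build_fragment <- function(site, template, scaffold = NULL) {
  if (is.null(scaffold)) scaffold <- intron_scaffold(template$intron_type)
  stopifnot(scaffold$intron_type == template$intron_type)
  window <- toupper(site$window)
  if (!is_dna(window)) {
    loxtron_error("loxtron_sequence_error",
                  "target window contains ambiguity codes")
  }
  wmin <- template$window[1]
  seq <- scaffold$sequence
  placed <- list()
  for (nm in names(template$elements)) {
    rng <- template$elements[[nm]]
    tgt <- substr(window, window_index(rng[1], wmin), window_index(rng[2], wmin))
    el <- revcomp(tgt)
    coords <- scaffold$elements[[nm]]
    stopifnot(coords[2] - coords[1] + 1L == nchar(el))
    substr(seq, coords[1], coords[2]) <- el
    placed[[nm]] <- el
  }
  lo <- min(vapply(scaffold$elements, `[`, integer(1), 1L))
  hi <- max(vapply(scaffold$elements, `[`, integer(1), 2L))
  frag <- substr(seq, max(1L, lo - 20L), min(nchar(seq), hi + 20L))
  n <- nchar(frag)
  primers <- if (template$intron_type == "Ll.LtrB") {
    data.frame(
      name = c("IBS", "EBS1", "EBS2", "EBS2AS"),
      sequence = c(substr(frag, 1L, 30L),
                   substr(frag, n - 39L, n),
                   substr(frag, 15L, 54L),
                   revcomp(substr(frag, 21L, 60L))),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      name = c("IBS1/2S", "EBS2AS", "EBS1S", "EBSR"),
      sequence = c(substr(frag, 1L, 30L),
                   revcomp(substr(frag, 21L, 55L)),
                   substr(frag, 36L, 75L),
                   revcomp(substr(frag, n - 29L, n))),
      stringsAsFactors = FALSE)
  }
  structure(list(intron_type = template$intron_type, sequence = frag,
                 ends = setNames(scaffold$ends, c("left", "right")),
                 primers = primers, elements = placed,
                 site = list(gene_position = site$gene_position %||% NA,
                             strand = site$strand %||% NA)),
            class = "retargeting_fragment")
}

#' Write primers to TSV
#' @param fragment A `retargeting_fragment` (or data.frame name/sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primers_tsv <- function(fragment, path) {
  df <- if (inherits(fragment, "retargeting_fragment")) fragment$primers else fragment
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
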