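#' Construct a lox site
#'
#' A lox site is a 34-nt Cre recombination target: two 13-nt arms flanking an
#' asymmetric 8-nt linker. The linker's asymmetry gives the site a defined
#' orientation, and its sequence class determines which sites it can recombine
#' with. Arm mutations (as in lox66 and lox71) weaken Cre binding on one side;
#' a site with both arms mutant (lox72) is no longer recombined by Cre.
#'
#' Sites are stored internally in the linker-forward frame: `left_arm`,
#' `linker` and `right_arm` always read in the direction in which the linker
#' sequence matches its catalogue class. The `orientation` field records which
#' strand of the hosting molecule that frame lies on.
#'
#' @param left_arm,linker,right_arm DNA strings of length 13, 8 and 13.
#' @param left_state,right_state `"wild_type"` or `"mutant"`.
#' @param linker_class Label of the linker specificity class (e.g. `"P"`,
#'   `"511"`, `"FAS"`, `"m2"`, `"2272"`, `"N"`).
#' @param orientation `"forward"` or `"reverse"` relative to the hosting
#'   molecule's reference strand.
#' @return An object of class `lox_site`.
#' @export
lox_site <- function(left_arm, linker, right_arm,
                     left_state = "wild_type", right_state = "wild_type",
                     linker_class = "P", orientation = "forward") {
  stopifnot(nchar(left_arm) == 13L, nchar(linker) == 8L, nchar(right_arm) == 13L)
  left_state <- match.arg(left_state, c("wild_type", "mutant"))
  right_state <- match.arg(right_state, c("wild_type", "mutant"))
  orientation <- match.arg(orientation, c("forward", "reverse"))
  structure(
    list(left_arm = toupper(left_arm), linker = toupper(linker),
         right_arm = toupper(right_arm), left_state = left_state,
         right_state = right_state, linker_class = linker_class,
         orientation = orientation),
    class = "lox_site"
  )
}

#' @export
print.lox_site <- function(x, ...) {
  cat(sprintf("<lox site> class %s, arms %s/%s, %s\n  %s %s %s\n",
              x$linker_class, x$left_state, x$right_state, x$orientation,
              x$left_arm, x$linker, x$right_arm))
  invisible(x)
}

#' Render a lox site to its 34-nt sequence
#'
#' Returns the sequence as it appears on the reference strand of the hosting
#' molecule: reverse-orientation sites are reverse-complemented.
#'
#' @param site A [lox_site()].
#' @return A 34-character DNA string.
#' @export
lox_sequence <- function(site) {
  s <- paste0(site$left_arm, site$linker, site$right_arm)
  if (site$orientation == "reverse") revcomp(s) else s
}

#' Load the lox-site catalogue
#'
#' The catalogue ships as a plain TSV of named sites (loxP, the lox66/lox71
#' arm mutants and their lox72 product, and the heterospecific linker classes
#' lox511, loxFAS, loxm2, lox2272 and loxN, with arm-mutant combinations).
#' Names ending `/66` carry the mutant right arm, `/71` the mutant left arm.
#'
#' @param path Optional path to a catalogue TSV with columns `name`,
#'   `left_arm`, `linker`, `right_arm`, `linker_class`, `left_state`,
#'   `right_state`. Defaults to the catalogue shipped with the package.
#' @return A named list of [lox_site()] objects with class `lox_catalog`.
#' @export
lox_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lox_catalog.tsv", package = "loxtron")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sites <- lapply(seq_len(nrow(tab)), function(i) {
    lox_site(tab$left_arm[i], tab$linker[i], tab$right_arm[i],
             left_state = tab$left_state[i], right_state = tab$right_state[i],
             linker_class = as.character(tab$linker_class[i]))
  })
  names(sites) <- tab$name
  structure(sites, class = "lox_catalog")
}

# Arm sequences known to the catalogue, per linker class, used to classify
# arm-mutation state when parsing.
catalog_arm_table <- function(catalog) {
  arms <- list(left = list(), right = list())
  for (s in catalog) {
    arms$left[[s$left_state]] <- unique(c(arms$left[[s$left_state]], s$left_arm))
    arms$right[[s$right_state]] <- unique(c(arms$right[[s$right_state]], s$right_arm))
  }
  arms
}

catalog_linkers <- function(catalog) {
  cls <- vapply(catalog, function(s) s$linker_class, character(1))
  lnk <- vapply(catalog, function(s) s$linker, character(1))
  unique(data.frame(linker = lnk, linker_class = cls, stringsAsFactors = FALSE))
}

#' Parse a 34-nt sequence into a lox site
#'
#' Decomposes a 34-mer into arms and linker, infers orientation from the
#' strand on which the linker matches a known class, and classifies each arm
#' as wild type or mutant by comparison with catalogue arm sequences.
#'
#' @param sequence A 34-character DNA string.
#' @param catalog A [lox_catalog()].
#' @return A [lox_site()].
#' @export
parse_lox <- function(sequence, catalog = lox_catalog()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != 34L) {
    loxtron_error("loxtron_length_error",
                  sprintf("lox sites are 34 nt; got %d", nchar(sequence)))
  }
  if (!is_dna(sequence)) {
    loxtron_error("loxtron_unknown_site_error", "sequence contains non-ACGT characters")
  }
  linkers <- catalog_linkers(catalog)
  fwd_link <- substr(sequence, 14L, 21L)
  rev_seq <- revcomp(sequence)
  rev_link <- substr(rev_seq, 14L, 21L)
  fwd_hit <- linkers$linker_class[linkers$linker == fwd_link]
  rev_hit <- linkers$linker_class[linkers$linker == rev_link]
  if (length(fwd_hit) > 0L && length(rev_hit) > 0L) {
    loxtron_error("loxtron_ambiguous_site_error",
                  "linker matches catalogue classes on both strands")
  }
  if (length(fwd_hit) == 0L && length(rev_hit) == 0L) {
    loxtron_error("loxtron_unknown_site_error",
                  sprintf("linker %s matches no catalogue class", fwd_link))
  }
  if (length(fwd_hit) > 1L || length(rev_hit) > 1L) {
    loxtron_error("loxtron_ambiguous_site_error",
                  "linker matches more than one catalogue class")
  }
  orientation <- if (length(fwd_hit) == 1L) "forward" else "reverse"
  frame <- if (orientation == "forward") sequence else rev_seq
  cls <- if (orientation == "forward") fwd_hit else rev_hit
  left <- substr(frame, 1L, 13L)
  right <- substr(frame, 22L, 34L)
  arms <- catalog_arm_table(catalog)
  classify <- function(arm, side) {
    if (arm %in% arms[[side]][["wild_type"]]) return("wild_type")
    if (arm %in% arms[[side]][["mutant"]]) return("mutant")
    loxtron_error("loxtron_unknown_site_error",
                  sprintf("%s arm %s matches no catalogue arm", side, arm))
  }
  lox_site(left, substr(frame, 14L, 21L), right,
           left_state = classify(left, "left"),
           right_state = classify(right, "right"),
           linker_class = cls, orientation = orientation)
}

#' Can two lox sites recombine, judged by their linkers?
#'
#' Sites recombine only when their linkers belong to compatible specificity
#' classes; by default compatibility is exact class identity, which makes
#' distinct classes (P, 511, FAS, m2, 2272, N) mutually orthogonal. A custom
#' logical compatibility matrix (dimnames = class labels) may be supplied.
#'
#' @param a,b [lox_site()] objects.
#' @param compat Optional logical matrix indexed by linker-class labels.
#' @return `TRUE` or `FALSE`.
#' @export
linker_compatible <- function(a, b, compat = NULL) {
  if (is.null(compat)) return(a$linker_class == b$linker_class)
  stopifnot(is.matrix(compat))
  if (!(a$linker_class %in% rownames(compat)) ||
      !(b$linker_class %in% colnames(compat))) {
    return(FALSE)
  }
  isTRUE(compat[a$linker_class, b$linker_class])
}

#' Is a lox site an active Cre substrate?
#'
#' A site with both arms mutant (the lox72 product of a lox66 x lox71
#' recombination) is no longer recognized by Cre; all other sites are active.
#'
#' @param s A [lox_site()].
#' @return `TRUE` or `FALSE`.
#' @export
is_active <- function(s) {
  !(s$left_state == "mutant" && s$right_state == "mutant")
}

#' Recombine two lox sites
#'
#' Models the Cre crossover as an exchange of arms across the linker, in the
#' linker-forward frame: the products are `a$left_arm + linker + b$right_arm`
#' and `b$left_arm + linker + a$right_arm`. Arm-mutation states travel with
#' their arms, so recombining a left-arm mutant (lox71) with a right-arm
#' mutant (lox66) yields an inactive double mutant (lox72) plus a wild-type
#' site -- the unidirectional reaction exploited by the editing designs.
#'
#' @param a,b [lox_site()] objects; must be linker-compatible and active.
#' @param compat Optional compatibility matrix, see [linker_compatible()].
#' @return A list of two [lox_site()] products (both reported in forward
#'   orientation; placement on a molecule is the simulator's concern).
#' @export
recombine <- function(a, b, compat = NULL) {
  if (!linker_compatible(a, b, compat)) {
    loxtron_error("loxtron_no_reaction_error",
                  sprintf("incompatible linker classes %s and %s",
                          a$linker_class, b$linker_class))
  }
  if (!is_active(a) || !is_active(b)) {
    loxtron_error("loxtron_no_reaction_error",
                  "inactive (double arm-mutant) participant")
  }
  p1 <- lox_site(a$left_arm, a$linker, b$right_arm,
                 left_state = a$left_state, right_state = b$right_state,
                 linker_class = a$linker_class)
  p2 <- lox_site(b$left_arm, b$linker, a$right_arm,
                 left_state = b$left_state, right_state = a$right_state,
                 linker_class = a$linker_class)
  list(p1, p2)
}

# TRUE when two site objects are the same site up to orientation metadata.
same_lox <- function(a, b) {
  identical(a$left_arm, b$left_arm) && identical(a$linker, b$linker) &&
    identical(a$right_arm, b$right_arm)
}

# Toggle the strand the linker-forward frame lies on. The stored arms and
# linker are unchanged: only the orientation metadata flips, which keeps the
# arm-exchange rule of recombine() orientation-free.
flip_orientation <- function(s) {
  s$orientation <- if (s$orientation == "forward") "reverse" else "forward"
  s
}
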