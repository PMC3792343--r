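# Cloning contexts used when assembling cargo inserts.
MLUI_SITE <- "ACGCGT"
PMEI_SPACER <- "GTTTAAACAGCT"  # PmeI site plus a short linker
GAGAG_FLANK <- "GAGAG"

#' Design a lox cargo insert
#'
#' Builds the sequence cloned into the intron's cargo site: one or two lox
#' sites between MluI-compatible ends, with two-site payloads joined by a
#' PmeI site plus a short linker. When `flexible = TRUE` the payload is
#' flanked by `GAGAG` on both sides, which relaxes the tight RNA hairpin the
#' palindromic lox arms would otherwise fold into -- the redesign that
#' restores intron insertion efficiency.
#'
#' @param lox_list A list of 1 or 2 [lox_site()] objects, or catalogue names.
#'   The `orientation` field of each site gives its orientation within the
#'   insert.
#' @param flexible Add GAGAG flanks (default `FALSE`).
#' @param name Insert name; autogenerated from the payload if `NULL`.
#' @param catalog Catalogue used to resolve character names.
#' @return A `cargo_insert`: list with `name`, `sequence`, `lox` (each entry
#'   `list(name=, site=, offset=)`, offset 0-based within the insert) and
#'   `flexible`.
#' @export
design_insert <- function(lox_list, flexible = FALSE, name = NULL,
                          catalog = lox_catalog()) {
  if (length(lox_list) == 0L) {
    loxtron_error("loxtron_design_error", "empty lox payload")
  }
  if (length(lox_list) > 2L) {
    loxtron_error("loxtron_design_error",
                  sprintf("inserts carry 1 or 2 lox sites; got %d", length(lox_list)))
  }
  sites <- lapply(lox_list, function(l) {
    if (is.character(l)) {
      s <- catalog[[l]]
      if (is.null(s)) {
        loxtron_error("loxtron_unknown_site_error",
                      sprintf("no catalogue site named %s", l))
      }
      attr(s, "lox_name") <- l
      s
    } else l
  })
  site_names <- vapply(seq_along(sites), function(i) {
    attr(sites[[i]], "lox_name") %||% sites[[i]]$linker_class
  }, character(1))
  seq <- MLUI_SITE
  if (flexible) seq <- paste0(seq, GAGAG_FLANK)
  lox <- list()
  for (i in seq_along(sites)) {
    if (i > 1L) seq <- paste0(seq, PMEI_SPACER)
    lox <- c(lox, list(list(name = site_names[i], site = sites[[i]],
                            offset = nchar(seq))))
    seq <- paste0(seq, lox_sequence(sites[[i]]))
  }
  if (flexible) seq <- paste0(seq, GAGAG_FLANK)
  seq <- paste0(seq, MLUI_SITE)
  structure(list(name = name %||% paste(site_names, collapse = "+"),
                 sequence = seq, lox = lox, flexible = flexible),
            class = "cargo_insert")
}

#' Load the cargo-insert catalogue
#'
#' The shipped catalogue mirrors the naming grammar of the insert series
#' (1L66, 1L71, 1WL1, 1WL2, 2ML1, 2ML4, 2ML5): `1`/`2` for the number of lox
#' sites, and a trailing generation marker distinguishing rigid payloads from
#' GAGAG-flanked flexible redesigns.
#'
#' @param path Optional TSV path (columns `name`, `lox_sites`
#'   comma-separated, `flexible`). Defaults to the shipped catalogue.
#' @param catalog A [lox_catalog()].
#' @return Named list of `cargo_insert` objects.
#' @export
insert_catalog <- function(path = NULL, catalog = lox_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "lox_inserts.tsv", package = "loxtron")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    design_insert(strsplit(tab$lox_sites[i], ",")[[1]],
                  flexible = as.logical(tab$flexible[i]),
                  name = tab$name[i], catalog = catalog)
  })
  names(out) <- tab$name
  out
}

rna_pairable <- function(a, b) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "U") || (a == "U" && b == "G")
}

#' Fold an RNA by base-pair maximization
#'
#' Nussinov-style dynamic programming: maximizes the number of nested
#' Watson-Crick plus GU pairs with a minimum hairpin loop of 3 nt. The
#' traceback is deterministic, preferring the pairing partner at the
#' smallest 5' index. This is a structural approximation used only to judge
#' the presence and size of non-pairing regions; a thermodynamic folder's
#' dot-bracket string can be supplied to downstream scoring instead.
#'
#' @param rna RNA string (AUGC), length at least 10.
#' @return A `fold_result`: list with `pairs` (integer vector, 0 =
#'   unpaired, otherwise 1-based partner), `dotbracket`, `n_pairs`, and
#'   flexibility metrics (`unpaired_fraction`, `longest_unpaired_run`,
#'   `end_unpaired_5p`, `end_unpaired_3p`).
#' @export
fold_rna <- function(rna) {
  rna <- toupper(rna)
  if (grepl("T", rna) && !grepl("U", rna)) rna <- transcribe(rna)
  if (!grepl("^[AUGC]+$", rna)) {
    loxtron_error("loxtron_sequence_error", "sequence contains non-AUGC characters")
  }
  n <- nchar(rna)
  if (n < 10L) {
    loxtron_error("loxtron_bounds_error", "fold needs at least 10 nt")
  }
  b <- strsplit(rna, "")[[1]]
  code <- match(b, c("A", "C", "G", "U"))
  can_pair <- matrix(FALSE, 4, 4)
  can_pair[1, 4] <- can_pair[4, 1] <- TRUE  # A-U
  can_pair[2, 3] <- can_pair[3, 2] <- TRUE  # C-G
  can_pair[3, 4] <- can_pair[4, 3] <- TRUE  # G-U
  M <- matrix(0L, n, n)
  for (span in 4:(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- i:(j - 4L)
      ks <- ks[can_pair[code[ks], code[j]]]
      if (length(ks) > 0L) {
        left <- integer(length(ks))
        inner <- ks > i
        if (any(inner)) left[inner] <- M[i, ks[inner] - 1L]
        vals <- 1L + M[cbind(ks + 1L, j - 1L)] + left
        best <- max(best, vals)
      }
      M[i, j] <- best
    }
  }
  pairs <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (j - i < 4L) next
    target <- M[i, j]
    if (target == 0L) next
    chosen <- FALSE
    for (k in i:(j - 4L)) {
      if (rna_pairable(b[k], b[j])) {
        v <- 1L + M[k + 1L, j - 1L] + if (k > i) M[i, k - 1L] else 0L
        if (v == target) {
          pairs[k] <- j; pairs[j] <- k
          if (k > i) stack <- c(stack, list(c(i, k - 1L)))
          stack <- c(stack, list(c(k + 1L, j - 1L)))
          chosen <- TRUE
          break
        }
      }
    }
    if (!chosen) stack <- c(stack, list(c(i, j - 1L)))
  }
  db <- rep(".", n)
  db[pairs > 0 & seq_len(n) < pairs] <- "("
  db[pairs > 0 & seq_len(n) > pairs] <- ")"
  unp <- pairs == 0L
  runs <- rle(unp)
  structure(list(
    pairs = pairs,
    dotbracket = paste(db, collapse = ""),
    n_pairs = sum(pairs > 0) %/% 2L,
    unpaired_fraction = mean(unp),
    longest_unpaired_run = if (any(runs$values)) max(runs$lengths[runs$values]) else 0L,
    end_unpaired_5p = sum(unp[1:5]),
    end_unpaired_3p = sum(unp[(n - 4L):n])
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold> %d pairs, %.0f%% unpaired, ends %d/%d unpaired of 5\n",
              x$n_pairs, 100 * x$unpaired_fraction,
              x$end_unpaired_5p, x$end_unpaired_3p))
  cat(" ", x$dotbracket, "\n")
  invisible(x)
}

#' Score the structural flexibility of a cargo insert
#'
#' Folds the insert (as RNA) and scores how much of it, particularly the 5
#' positions at each end -- the base of the stem in the folded hairpin --
#' remains unpaired. Inserts with at least `flex_min` unpaired bases within
#' each terminal window are classed flexible; the threshold is configurable
#' because the two-class distinction is qualitative.
#'
#' The MluI cloning context is stripped before folding: it is a perfect
#' reverse-complement palindrome pair that would always seal the stem base,
#' whereas the structural question is whether the payload between the
#' cloning ends leaves the stem base open.
#'
#' @param insert A `cargo_insert`, or a raw DNA/RNA string.
#' @param flex_min Minimum unpaired bases per terminal 5-nt window for the
#'   flexible class (default 2).
#' @param fold Optional externally computed `fold_result` (e.g. parsed from
#'   a thermodynamic folder's dot-bracket output) to score instead of the
#'   built-in fold.
#' @return A list with `score`, `class` (`"flexible"` or `"inflexible"`),
#'   and the `fold_result` used.
#' @export
flexibility_score <- function(insert, flex_min = 2L, fold = NULL) {
  seq <- if (inherits(insert, "cargo_insert")) insert$sequence else insert
  seq <- toupper(seq)
  if (startsWith(seq, MLUI_SITE) && endsWith(seq, MLUI_SITE)) {
    seq <- substr(seq, nchar(MLUI_SITE) + 1L, nchar(seq) - nchar(MLUI_SITE))
  }
  f <- fold %||% fold_rna(transcribe(seq))
  # judge flexibility on helices only: an isolated long-range pair is not a
  # stem and would not constrain the structure
  p <- drop_lonely_pairs(f$pairs)
  n <- length(p)
  unp <- p == 0L
  runs <- rle(unp)
  m <- list(
    unpaired_fraction = mean(unp),
    longest_unpaired_run = if (any(runs$values)) max(runs$lengths[runs$values]) else 0L,
    end_unpaired_5p = sum(unp[1:min(5L, n)]),
    end_unpaired_3p = sum(unp[max(1L, n - 4L):n])
  )
  flexible <- m$end_unpaired_5p >= flex_min && m$end_unpaired_3p >= flex_min
  score <- m$unpaired_fraction + (m$end_unpaired_5p + m$end_unpaired_3p) / 10
  c(list(score = score, class = if (flexible) "flexible" else "inflexible",
         fold = f), m)
}

# Remove pairs with no stacked neighbour (lone pairs): (i, j) survives only
# if (i+1, j-1) or (i-1, j+1) is also paired.
drop_lonely_pairs <- function(pairs) {
  n <- length(pairs)
  keep <- pairs
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j == 0L) next
    inner <- i + 1L <= n && j - 1L >= 1L && pairs[i + 1L] == j - 1L
    outer <- i - 1L >= 1L && j + 1L <= n && pairs[i - 1L] == j + 1L
    if (!inner && !outer) keep[i] <- 0L
  }
  keep
}

#' Parse a dot-bracket string into a fold result
#'
#' Accepts structures computed by an external (e.g. thermodynamic) folder so
#' they can be scored with [flexibility_score()].
#'
#' @param dotbracket Dot-bracket string (characters `.`, `(`, `)`).
#' @return A `fold_result`.
#' @export
parse_dotbracket <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  n <- length(ch)
  pairs <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) {
        loxtron_error("loxtron_sequence_error", "unbalanced dot-bracket string")
      }
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    } else if (ch[i] != ".") {
      loxtron_error("loxtron_sequence_error",
                    sprintf("unexpected character '%s' in dot-bracket", ch[i]))
    }
  }
  if (length(stack) > 0L) {
    loxtron_error("loxtron_sequence_error", "unbalanced dot-bracket string")
  }
  unp <- pairs == 0L
  runs <- rle(unp)
  structure(list(
    pairs = pairs, dotbracket = dotbracket, n_pairs = sum(pairs > 0) %/% 2L,
    unpaired_fraction = mean(unp),
    longest_unpaired_run = if (any(runs$values)) max(runs$lengths[runs$values]) else 0L,
    end_unpaired_5p = sum(unp[1:min(5L, n)]),
    end_unpaired_3p = sum(unp[max(1L, n - 4L):n])
  ), class = "fold_result")
}
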