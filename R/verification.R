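#' Construct a primer pair
#'
#' Primer names follow the diagnostic-gel grammar: the first letter is the
#' genomic locus the primer amplifies and the following `u`/`d` marks it as
#' the "up" (upstream, forward) or "down" (downstream, reverse) primer;
#' assays are named by the two primer names separated by a slash.
#'
#' @param fwd_name,fwd Forward primer name and sequence.
#' @param rev_name,rev Reverse primer name and sequence.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(fwd_name, fwd, rev_name, rev) {
  structure(list(fwd_name = fwd_name, fwd = toupper(fwd),
                 rev_name = rev_name, rev = toupper(rev)),
            class = "primer_pair")
}

count_occurrences <- function(seq, pattern) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

# TRUE when the k-mer occurs exactly once genome-wide on either strand
# (circular molecules are searched across the origin).
unique_in_genome <- function(mol, kmer) {
  seq <- mol$sequence
  if (mol$topology == "circular") {
    seq <- paste0(seq, substr(seq, 1L, nchar(kmer) - 1L))
  }
  n <- count_occurrences(seq, kmer) + count_occurrences(seq, revcomp(kmer))
  n == 1L
}

# Leftmost unique k-mer within [win_start, win_end) (0-based half-open).
leftmost_unique_kmer <- function(mol, win_start, win_end, k = 20L) {
  win_start <- max(0L, win_start)
  win_end <- min(mol_len(mol), win_end)
  if (win_end - win_start < k) return(NULL)
  for (s in seq.int(win_start, win_end - k)) {
    kmer <- substr(mol$sequence, s + 1L, s + k)
    if (unique_in_genome(mol, kmer)) {
      return(list(start = s, sequence = kmer))
    }
  }
  NULL
}

# Design the up (forward) and down (reverse) primers flanking a locus
# insertion point: leftmost unique 20-mer within a search window on each
# side, checked genome-wide by exact match.
locus_primers <- function(mol, locus, coord, search_window = 300L,
                          primer_len = 20L) {
  u <- leftmost_unique_kmer(mol, coord - search_window, coord - primer_len,
                            primer_len)
  d <- leftmost_unique_kmer(mol, coord, coord + search_window, primer_len)
  if (is.null(u) || is.null(d)) {
    loxtron_error("loxtron_design_error",
                  sprintf("no unique primer placement within the search window at locus %s",
                          locus))
  }
  list(u = list(name = paste0(locus_letter(locus), "u"), sequence = u$sequence,
                start = u$start),
       d = list(name = paste0(locus_letter(locus), "d"),
                sequence = revcomp(d$sequence), start = d$start))
}

# lacZ is abbreviated L on the gels; other loci use their first letter.
locus_letter <- function(locus) {
  if (tolower(locus) == "lacz") "L" else substr(locus, 1L, 1L)
}

#' Exact in-silico PCR
#'
#' Finds all products formed by exact-match annealing of the two primers on
#' opposite strands in convergent orientation, up to `max_product` in size.
#' Either primer may act as the left (plus-strand) primer. Circular
#' molecules are searched across the origin.
#'
#' @param mol A [molecule()].
#' @param pair A [primer_pair()], or a character vector of two primer
#'   sequences.
#' @param max_product Maximum product size in bp (default 5000).
#' @return A data.frame with columns `start` (0-based), `end`, `size`;
#'   zero rows means no band.
#' @export
insilico_pcr <- function(mol, pair, max_product = 5000L) {
  if (inherits(pair, "primer_pair")) {
    p1 <- pair$fwd; p2 <- pair$rev
  } else {
    p1 <- toupper(pair[1]); p2 <- toupper(pair[2])
  }
  if (nchar(p1) < 15L || nchar(p2) < 15L) {
    loxtron_error("loxtron_design_error", "primers must be at least 15 nt")
  }
  L <- mol_len(mol)
  seq <- mol$sequence
  circular <- mol$topology == "circular"
  if (circular) {
    ext <- min(L, max_product)
    seq <- paste0(seq, substr(mol$sequence, 1L, ext))
  }
  occ <- function(p) {
    hits <- gregexpr(p, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
  }
  out <- list()
  combos <- list(c(p1, p2), c(p2, p1))
  if (p1 == p2) combos <- combos[1]
  size_cap <- if (circular) min(max_product, L) else max_product
  for (cb in combos) {
    left <- cb[1]; right <- cb[2]
    ls <- occ(left)
    rs <- occ(revcomp(right))
    ls <- ls[ls < L]  # left primer starts within the original sequence
    for (a in ls) {
      for (b in rs) {
        pend <- b + nchar(right)
        size <- pend - a
        if (size >= nchar(left) && size <= size_cap) {
          out <- c(out, list(c(a %% L, pend, size)))
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), size = integer(0)))
  }
  df <- unique(do.call(rbind, out))
  df <- data.frame(start = df[, 1], end = df[, 2], size = df[, 3])
  df[order(df$start, df$size), , drop = FALSE]
}

#' Design the diagnostic PCR plan for an edit
#'
#' Emits the assay set used to verify each operation across the three strain
#' states (W wild type, U uninduced with introns placed, I induced): for a
#' deletion, two assays bridging the two insertion sites plus one bridging
#' the expected deletion junction (3 per region); for an inversion, the two
#' insertion-site bridges plus two assays bridging the new ends of the
#' inversion (4); for a cut-and-paste, three insertion-site bridges, one
#' bridging the cut, and two bridging the paste boundaries (6). Primers are
#' placed in unique flanking sequence outside the introns.
#'
#' @param plan An [edit_plan()].
#' @param genome The wild-type genome [molecule()] carrying the plan's loci
#'   as gene features.
#' @param max_product In-silico PCR size cap used to orient paste-boundary
#'   assays (default 5000).
#' @param search_window,primer_len Primer placement parameters.
#' @return An `assay_plan`: list with `assays` (data.frame: name, role,
#'   primer names/sequences) and `expected` (logical presence per state).
#' @export
design_assays <- function(plan, genome, max_product = 5000L,
                          search_window = 300L, primer_len = 20L) {
  validate_plan(plan)
  region <- plan$regions[[1]]
  op <- plan$operation
  site_specs <- region[intersect(c("locus_up", "locus_down", "locus_target"),
                                 names(region))]
  prim <- list()
  for (sp in site_specs) {
    coord <- locus_insertion_coord(genome, sp$locus)
    prim[[sp$locus]] <- locus_primers(genome, sp$locus, coord,
                                      search_window, primer_len)
  }
  la <- region$locus_up$locus
  lb <- region$locus_down$locus
  mk <- function(role, f, r) {
    data.frame(name = paste0(f$name, "/", r$name), role = role,
               fwd_name = f$name, fwd_seq = f$sequence,
               rev_name = r$name, rev_seq = r$sequence,
               stringsAsFactors = FALSE)
  }
  rows <- list(mk("site_bridge", prim[[la]]$u, prim[[la]]$d),
               mk("site_bridge", prim[[lb]]$u, prim[[lb]]$d))
  if (op == "deletion") {
    rows <- c(rows, list(mk("junction", prim[[la]]$u, prim[[lb]]$d)))
  } else if (op == "inversion") {
    # the inversion flips the templates of Bu and Ad, making Au/Bu and Ad/Bd
    # convergent only in the induced state
    rows <- c(rows,
              list(mk("inversion_end", prim[[la]]$u, prim[[lb]]$u),
                   mk("inversion_end", prim[[la]]$d, prim[[lb]]$d)))
  } else if (op == "cut_and_paste") {
    lt <- region$locus_target$locus
    rows <- c(rows, list(
      mk("site_bridge", prim[[lt]]$u, prim[[lt]]$d),
      mk("cut_bridge", prim[[la]]$u, prim[[lb]]$d)))
    # paste-boundary orientation depends on how the excised circle enters
    # the target site; resolve it against the simulated induced state
    istate <- induced_state(plan, genome)
    chrom <- istate$molecules[[1]]
    fwd_pairs <- list(mk("paste_bridge", prim[[lt]]$u, prim[[la]]$d),
                      mk("paste_bridge", prim[[lb]]$u, prim[[lt]]$d))
    rev_pairs <- list(mk("paste_bridge", prim[[lt]]$u, prim[[lb]]$u),
                      mk("paste_bridge", prim[[la]]$d, prim[[lt]]$d))
    works <- function(pairs) {
      all(vapply(pairs, function(p) {
        nrow(insilico_pcr(chrom, c(p$fwd_seq, p$rev_seq), max_product)) > 0L
      }, logical(1)))
    }
    rows <- c(rows, if (works(fwd_pairs)) fwd_pairs else rev_pairs)
  }
  assays <- do.call(rbind, rows)
  rownames(assays) <- NULL
  expected <- data.frame(
    name = assays$name,
    W = assays$role == "site_bridge",
    U = assays$role == "site_bridge",
    I = assays$role != "site_bridge",
    stringsAsFactors = FALSE
  )
  structure(list(assays = assays, expected = expected, operation = op,
                 loci = names(prim), primers = prim),
            class = "assay_plan")
}

#' @export
print.assay_plan <- function(x, ...) {
  cat(sprintf("<assay plan> %s, %d assays\n", x$operation, nrow(x$assays)))
  print(x$assays[, c("name", "role")])
  invisible(x)
}

# The simulated induced (post-Cre, post host inverted-repeat removal) state.
induced_state <- function(plan, genome, max_states = 10000L,
                          min_homology = 200L) {
  u <- apply_plan(plan, genome)
  rep <- cre_closure(u, max_states = max_states, min_homology = min_homology)
  st <- pick_induced_terminal(rep, genome$id, plan)
  st$molecules <- lapply(st$molecules, function(m) {
    if (m$id == genome$id) resolve_inverted_repeats(m, min_homology) else m
  })
  st
}

# Among terminal outcomes, prefer the one consistent with the planned
# operation: for cut-and-paste the state whose chromosome still contains all
# locus barcodes and carries an inactive (lox72) junction site.
pick_induced_terminal <- function(rep, genome_id, plan) {
  terms <- rep$terminal_states
  if (length(terms) == 1L) return(terms[[1]])
  score <- vapply(terms, function(st) {
    chrom <- Filter(function(m) m$id == genome_id, st$molecules)
    if (length(chrom) == 0L) return(-Inf)
    chrom <- chrom[[1]]
    genes <- sum(vapply(chrom$features, function(f) f$kind == "gene", logical(1)))
    lox72 <- sum(vapply(chrom$features, function(f) {
      f$kind == "lox" && !is_active(f$payload)
    }, logical(1)))
    genes * 10 + lox72
  }, numeric(1))
  terms[[which.max(score)]]
}

#' Predict the diagnostic PCR signature across strain states
#'
#' Runs exact in-silico PCR for every assay of the plan on each provided
#' strain state and tabulates the resulting bands. Insertion-site bridges
#' grow by the intron insert length between W and U and disappear in I;
#' junction assays produce a band only in I.
#'
#' @param assay_plan An `assay_plan` from [design_assays()].
#' @param states Named list of states (`W`, `U`, `I`); each a [molecule()]
#'   or [system_state()].
#' @param max_product PCR size cap (default 5000).
#' @return A data.frame with one row per assay x state: `assay`, `state`,
#'   `n_bands`, `sizes` (comma-separated).
#' @export
predict_signature <- function(assay_plan, states, max_product = 5000L) {
  rows <- list()
  for (st_name in names(states)) {
    st <- states[[st_name]]
    mols <- if (inherits(st, "system_state")) st$molecules else list(st)
    for (i in seq_len(nrow(assay_plan$assays))) {
      a <- assay_plan$assays[i, ]
      sizes <- integer(0)
      for (m in mols) {
        hit <- insilico_pcr(m, c(a$fwd_seq, a$rev_seq), max_product)
        sizes <- c(sizes, hit$size)
      }
      rows <- c(rows, list(data.frame(
        assay = a$name, role = a$role, state = st_name,
        n_bands = length(sizes),
        sizes = paste(sort(sizes), collapse = ","),
        stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an assay plan to TSV
#' @param assay_plan An `assay_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assays_tsv <- function(assay_plan, path) {
  utils::write.table(assay_plan$assays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
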