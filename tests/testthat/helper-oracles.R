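# Independent oracles and fixture builders used across the suite. These are
# deliberately written against raw strings (no package internals) so they
# check the implementation rather than mirror it.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# --- lox site dictionary built from the shipped catalogue TSV --------------

oracle_lox_dictionary <- function() {
  path <- system.file("extdata", "lox_catalog.tsv", package = "loxtron")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  arms_l <- unique(data.frame(arm = tab$left_arm, state = tab$left_state))
  arms_r <- unique(data.frame(arm = tab$right_arm, state = tab$right_state))
  linkers <- unique(data.frame(linker = tab$linker, class = tab$linker_class))
  out <- list()
  for (i in seq_len(nrow(arms_l))) for (j in seq_len(nrow(arms_r))) {
    for (k in seq_len(nrow(linkers))) {
      seq <- paste0(arms_l$arm[i], linkers$linker[k], arms_r$arm[j])
      out[[seq]] <- list(left = arms_l$state[i], right = arms_r$state[j],
                         class = linkers$class[k], seq = seq)
    }
  }
  out
}

# --- brute-force Cre closure on raw strings --------------------------------

# Scan a raw sequence for dictionary 34-mers on both strands.
oracle_scan_lox <- function(seq, dict) {
  hits <- list()
  n <- nchar(seq)
  if (n < 34L) return(hits)
  subs <- substring(seq, 1:(n - 33L), 34:n)
  for (p in seq_along(subs)) {
    s <- subs[p]
    if (!is.null(dict[[s]])) {
      e <- dict[[s]]; e$pos <- p - 1L; e$strand <- "+"
      hits <- c(hits, list(e))
    } else {
      rc <- oracle_revcomp(s)
      if (!is.null(dict[[rc]])) {
        e <- dict[[rc]]; e$pos <- p - 1L; e$strand <- "-"
        hits <- c(hits, list(e))
      }
    }
  }
  hits
}

oracle_active <- function(site) !(site$left == "mutant" && site$right == "mutant")

oracle_site_seq <- function(left_arm_state, cls, right_arm_state, dict) {
  for (e in dict) {
    if (e$left == left_arm_state && e$right == right_arm_state && e$class == cls) {
      return(e$seq)
    }
  }
  stop("no dictionary entry")
}

# Products of the arm exchange, as raw 34-mers in the linker frame.
oracle_products <- function(a, b, dict) {
  list(oracle_site_seq(a$left, a$class, b$right, dict),
       oracle_site_seq(b$left, b$class, a$right, dict))
}

# All single-event successors of a state; each molecule is list(seq, circular).
oracle_cre_step <- function(mols, dict) {
  sites <- list()
  for (m in seq_along(mols)) {
    for (h in oracle_scan_lox(mols[[m]]$seq, dict)) {
      if (oracle_active(h)) { h$mol <- m; sites <- c(sites, list(h)) }
    }
  }
  succ <- list()
  if (length(sites) < 2L) return(succ)
  for (x in seq_len(length(sites) - 1L)) for (y in seq.int(x + 1L, length(sites))) {
    a <- sites[[x]]; b <- sites[[y]]
    if (a$class != b$class) next
    if (a$mol == b$mol) {
      res <- oracle_intra(mols[[a$mol]], a, b, dict)
      if (is.null(res)) next
      succ <- c(succ, list(c(mols[-a$mol], res)))
    } else {
      if (!mols[[a$mol]]$circular || !mols[[b$mol]]$circular) next
      res <- oracle_fuse(mols[[a$mol]], a, mols[[b$mol]], b, dict)
      succ <- c(succ, list(c(mols[-c(a$mol, b$mol)], res)))
    }
  }
  succ
}

oracle_intra <- function(mol, a, b, dict) {
  seq <- mol$seq; n <- nchar(seq)
  # normalize: first site forward at the start of a rotation frame
  if (a$strand == "-" && b$strand == "-") {
    seq <- oracle_revcomp(seq)
    na <- list(left = b$left, right = b$right, class = b$class,
               pos = n - b$pos - 34L, strand = "+", seq = NA)
    nb <- list(left = a$left, right = a$right, class = a$class,
               pos = n - a$pos - 34L, strand = "+", seq = NA)
    # re-derive arm states in the flipped frame: a site read from the other
    # strand keeps its stored linker-frame decomposition
    a <- na; b <- nb
  } else if (a$strand == "-") {
    tmp <- a; a <- b; b <- tmp
  }
  if (mol$circular) {
    seq <- paste0(substr(seq, a$pos + 1L, n), substr(seq, 1L, a$pos))
    b$pos <- (b$pos - a$pos) %% n
    a$pos <- 0L
  } else if (a$pos > b$pos) {
    if (b$strand == "+") { tmp <- a; a <- b; b <- tmp } else {
      seq <- oracle_revcomp(seq)
      na <- list(left = b$left, right = b$right, class = b$class,
                 pos = n - b$pos - 34L, strand = "+")
      nb <- list(left = a$left, right = a$right, class = a$class,
                 pos = n - a$pos - 34L, strand = "-")
      a <- na; b <- nb
    }
  }
  pr <- oracle_products(a, b, dict)
  a1 <- a$pos; a2 <- a$pos + 34L; b1 <- b$pos; b2 <- b$pos + 34L
  if (b$strand == "+") {
    main <- paste0(substr(seq, 1L, a1), pr[[1]], substr(seq, b2 + 1L, n))
    circ <- paste0(pr[[2]], substr(seq, a2 + 1L, b1))
    list(list(seq = main, circular = mol$circular),
         list(seq = circ, circular = TRUE))
  } else {
    out <- paste0(substr(seq, 1L, a1), pr[[1]],
                  oracle_revcomp(substr(seq, a2 + 1L, b1)),
                  oracle_revcomp(pr[[2]]), substr(seq, b2 + 1L, n))
    list(list(seq = out, circular = mol$circular))
  }
}

oracle_fuse <- function(m1, a, m2, b, dict) {
  s1 <- m1$seq; s2 <- m2$seq
  if (a$strand == "-") {
    s1 <- oracle_revcomp(s1); a$pos <- nchar(s1) - a$pos - 34L; a$strand <- "+"
  }
  if (b$strand == "-") {
    s2 <- oracle_revcomp(s2); b$pos <- nchar(s2) - b$pos - 34L; b$strand <- "+"
  }
  s1 <- paste0(substr(s1, a$pos + 1L, nchar(s1)), substr(s1, 1L, a$pos))
  s2 <- paste0(substr(s2, b$pos + 1L, nchar(s2)), substr(s2, 1L, b$pos))
  pr <- oracle_products(a, b, dict)
  list(list(seq = paste0(pr[[1]], substr(s2, 35L, nchar(s2)),
                         pr[[2]], substr(s1, 35L, nchar(s1))),
            circular = TRUE))
}

oracle_canonical <- function(mol) {
  s <- mol$seq
  rc <- oracle_revcomp(s)
  if (!mol$circular) return(min(s, rc))
  rots <- function(x) {
    n <- nchar(x); d <- paste0(x, x)
    min(substring(d, 1:n, n:(2L * n - 1L)))
  }
  min(rots(s), rots(rc))
}

oracle_state_key <- function(mols) {
  paste(sort(vapply(mols, oracle_canonical, character(1))), collapse = "|")
}

# Brute-force closure: BFS + terminal SCCs, on raw strings.
oracle_closure <- function(mols, dict, max_states = 500L) {
  states <- list(mols)
  keys <- oracle_state_key(mols)
  e_from <- integer(0); e_to <- integer(0)
  queue <- 1L
  while (length(queue) > 0L) {
    cur <- queue[1]; queue <- queue[-1]
    for (s in oracle_cre_step(states[[cur]], dict)) {
      k <- oracle_state_key(s)
      idx <- match(k, keys)
      if (is.na(idx)) {
        stopifnot(length(states) < max_states)
        states <- c(states, list(s)); keys <- c(keys, k)
        idx <- length(states); queue <- c(queue, idx)
      }
      e_from <- c(e_from, cur); e_to <- c(e_to, idx)
    }
  }
  n <- length(states)
  if (length(e_from) == 0L) return(list(terminal_keys = keys[1], n = n))
  g <- igraph::make_graph(rbind(e_from, e_to), n = n, directed = TRUE)
  memb <- igraph::components(g, mode = "strong")$membership
  cross <- memb[e_from] != memb[e_to]
  terminal_sccs <- setdiff(unique(memb), unique(memb[e_from[cross]]))
  term <- integer(0)
  for (scc in terminal_sccs) {
    entries <- unique(e_to[cross & memb[e_to] == scc])
    if (1L %in% which(memb == scc)) entries <- unique(c(entries, 1L))
    if (length(entries) == 0L) entries <- which(memb == scc)[1]
    term <- c(term, sort(entries))
  }
  list(terminal_keys = sort(keys[term]), n = n)
}

# --- small fixture builders -------------------------------------------------

# Build matched inputs for implementation and oracle: a circular molecule
# with named catalogue sites planted at given positions/orientations.
plant_sites <- function(len, placements, seed = 1L, circular = TRUE,
                        catalog = lox_catalog()) {
  seq <- local({
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  })
  feats <- list()
  for (p in placements) {
    site <- catalog[[p$lox]]
    site$orientation <- p$orientation
    ls <- lox_sequence(site)
    substr(seq, p$at + 1L, p$at + 34L) <- ls
    feats <- c(feats, list(feature("lox", p$at, p$at + 34L,
                                   strand = if (p$orientation == "forward") "+" else "-",
                                   label = p$lox, payload = site)))
  }
  list(molecule = molecule("fix", seq, if (circular) "circular" else "linear", feats),
       raw = list(seq = seq, circular = circular))
}

# Terminal canonical keys from the package implementation, for comparison
# with oracle_closure.
impl_terminal_keys <- function(state, ...) {
  rep <- cre_closure(state, ...)
  sort(vapply(rep$terminal_states, function(st) {
    paste(sort(vapply(st$molecules,
                      function(m) oracle_canonical(list(seq = m$sequence,
                                                        circular = m$topology == "circular")),
                      character(1))), collapse = "|")
  }, character(1)))
}

# --- misc oracles -----------------------------------------------------------

# Independent Nussinov pair count: classic 4-case top-down recursion.
oracle_nussinov_count <- function(rna) {
  b <- strsplit(chartr("T", "U", toupper(rna)), "")[[1]]
  n <- length(b)
  pairable <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- matrix(NA_integer_, n, n)
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- max(rec(i + 1L, j), rec(i, j - 1L))
    if (pairable(b[i], b[j])) best <- max(best, 1L + rec(i + 1L, j - 1L))
    for (k in (i + 1L):(j - 1L)) {
      best <- max(best, rec(i, k) + rec(k + 1L, j))
    }
    memo[i, j] <<- best
    best
  }
  rec(1L, n)
}

# Naive substring-scan PCR: product sizes on a linear string.
oracle_pcr_sizes_linear <- function(seq, p1, p2, max_product) {
  n <- nchar(seq)
  find <- function(p) {
    k <- nchar(p)
    if (n < k) return(integer(0))
    subs <- substring(seq, 1:(n - k + 1L), k:n)
    which(subs == p)
  }
  sizes <- integer(0)
  for (cb in list(c(p1, p2), c(p2, p1))) {
    ls <- find(cb[1])
    rs <- find(oracle_revcomp(cb[2]))
    for (a in ls) for (b in rs) {
      size <- b + nchar(cb[2]) - a
      if (size >= nchar(cb[1]) && size <= max_product) sizes <- c(sizes, size)
    }
  }
  sort(unique(sizes))
}

# Rotate-and-rescan oracle for circular molecules.
oracle_pcr_sizes <- function(mol, p1, p2, max_product) {
  if (mol$topology == "linear") {
    return(oracle_pcr_sizes_linear(mol$sequence, p1, p2, max_product))
  }
  n <- mol_len(mol)
  half <- paste0(substr(mol$sequence, n %/% 2L + 1L, n),
                 substr(mol$sequence, 1L, n %/% 2L))
  sort(unique(c(oracle_pcr_sizes_linear(mol$sequence, p1, p2, max_product),
                oracle_pcr_sizes_linear(half, p1, p2, max_product))))
}

# Direct per-window regression R^2.
oracle_window_r2 <- function(times, y) {
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in 4:(n - 3L)) {
    idx <- (i - 3L):(i + 3L)
    fit <- lm(y[idx] ~ times[idx])
    tss <- sum((y[idx] - mean(y[idx]))^2)
    out[i] <- if (tss == 0) 0 else 1 - sum(residuals(fit)^2) / tss
  }
  out
}
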