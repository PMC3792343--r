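#' Specification for a synthetic genome fixture
#'
#' Describes a random circular (or linear) genome with named gene loci at
#' regular spacing, each locus carrying a unique 25-nt barcode in its
#' flanking sequence so that diagnostic primers can always be placed
#' uniquely. Optionally plants bare lox sites downstream of named loci.
#'
#' @param seed Integer seed; identical spec + seed gives byte-identical output.
#' @param genome_length Total length in bp (default 50000).
#' @param topology `"circular"` or `"linear"`.
#' @param loci Character vector of locus (gene) names, placed in order.
#' @param gene_length Length of each gene feature (default 600).
#' @param planted_lox Optional list of `list(locus=, lox=, orientation=)`
#'   entries; the named catalogue site is inserted immediately downstream of
#'   the locus gene.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 50000L,
                         topology = c("circular", "linear"),
                         loci = c("A", "B", "C", "D", "E", "lacZ"),
                         gene_length = 600L, planted_lox = NULL) {
  topology <- match.arg(topology)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 topology = topology, loci = loci,
                 gene_length = as.integer(gene_length),
                 planted_lox = planted_lox),
            class = "fixture_spec")
}

#' Generate a synthetic annotated genome
#'
#' A pure function of its spec: the genome is uniform-random ATGC with genes
#' planted at evenly spaced positions, each preceded by a unique 25-nt
#' barcode. The returned manifest records the ground truth of every planted
#' feature, which tests use to verify downstream operations.
#'
#' @param spec A [fixture_spec()].
#' @param catalog A [lox_catalog()] for resolving planted lox names.
#' @return A list with elements `molecule` (a [molecule()]) and `manifest`
#'   (a data.frame of planted features).
#' @export
make_genome <- function(spec, catalog = lox_catalog()) {
  n <- length(spec$loci)
  L <- spec$genome_length
  glen <- spec$gene_length
  spacing <- L %/% n
  if (spacing < glen + 200L) {
    loxtron_error("loxtron_bounds_error",
                  sprintf("%d loci of %d bp do not fit in %d bp", n, glen, L))
  }
  with_seed(spec$seed, {
    seq <- random_dna(L)
    feats <- list()
    manifest <- list()
    for (i in seq_len(n)) {
      start <- (i - 1L) * spacing + spacing %/% 4L
      barcode <- random_dna(25L)
      # barcode sits just upstream of the gene, inside the primer window
      substr(seq, start - 25L + 1L, start) <- barcode
      feats <- c(feats, list(feature("gene", start, start + glen, "+",
                                     label = spec$loci[i])))
      manifest <- c(manifest, list(data.frame(
        kind = "gene", label = spec$loci[i], start = start,
        end = start + glen, strand = "+", stringsAsFactors = FALSE)))
    }
    mol <- molecule("genome", seq, spec$topology, feats)
    for (p in spec$planted_lox %||% list()) {
      site <- catalog[[p$lox]]
      if (is.null(site)) {
        loxtron_error("loxtron_unknown_site_error",
                      sprintf("no catalogue site named %s", p$lox))
      }
      site$orientation <- p$orientation %||% "forward"
      g <- locus_feature(mol, p$locus)
      at <- g$end + 50L
      ls <- lox_sequence(site)
      mol$sequence <- paste0(substr(mol$sequence, 1L, at), ls,
                             substr(mol$sequence, at + 1L, mol_len(mol)))
      mol$features <- lapply(mol$features, function(f) {
        if (f$start >= at) { f$start <- f$start + 34L; f$end <- f$end + 34L }
        f
      })
      mol <- add_feature(mol, feature("lox", at, at + 34L,
                                      strand = if (site$orientation == "forward") "+" else "-",
                                      label = paste0("planted:", p$lox),
                                      payload = site))
      manifest <- c(manifest, list(data.frame(
        kind = "lox", label = p$lox, start = at, end = at + 34L,
        strand = if (site$orientation == "forward") "+" else "-",
        stringsAsFactors = FALSE)))
    }
    list(molecule = mol, manifest = do.call(rbind, manifest))
  })
}

locus_feature <- function(mol, locus) {
  for (f in mol$features) {
    if (f$kind == "gene" && identical(f$label, locus)) return(f)
  }
  loxtron_error("loxtron_bounds_error", sprintf("no locus named %s", locus))
}

#' Specification for synthetic plate-reader growth curves
#'
#' Emulates a plate-reader fitness measurement: cultures diluted to a low
#' starting OD600, readings every `interval_s` seconds, three biological
#' replicates. Curves are three-phase -- lag at the starting OD, exponential
#' growth with the given doubling time, then saturation at the stationary
#' cap -- with multiplicative log-normal measurement noise.
#'
#' @param seed Integer master seed; per-replicate streams are derived from it.
#' @param od0 Starting OD600 (default 0.001).
#' @param lag_min Lag-phase duration in minutes (default 60).
#' @param doubling_time Exponential-phase doubling time in minutes.
#' @param stationary_od OD600 cap (default 1.0).
#' @param interval_s Sampling interval in seconds (default 560).
#' @param total_min Total duration in minutes (default 700).
#' @param noise Multiplicative noise fraction, the log-normal sdlog
#'   (default 0.01, i.e. about 1 percent CV).
#' @param replicates Number of replicates (default 3).
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(seed = 1L, od0 = 0.001, lag_min = 60, doubling_time = 30,
                        stationary_od = 1.0, interval_s = 560, total_min = 700,
                        noise = 0.01, replicates = 3L) {
  stopifnot(od0 > 0, doubling_time > 0, stationary_od > od0, interval_s > 0,
            noise >= 0, replicates >= 1)
  structure(list(seed = as.integer(seed), od0 = od0, lag_min = lag_min,
                 doubling_time = doubling_time, stationary_od = stationary_od,
                 interval_s = interval_s, total_min = total_min, noise = noise,
                 replicates = as.integer(replicates)),
            class = "growth_spec")
}

#' Generate synthetic growth curves
#'
#' @param spec A [growth_spec()].
#' @return A `growth_curve`: list with `times` (minutes) and `od` (matrix,
#'   one column per replicate).
#' @export
make_growth_curves <- function(spec) {
  times <- seq(0, spec$total_min, by = spec$interval_s / 60)
  mean_od <- ifelse(times < spec$lag_min, spec$od0,
                    pmin(spec$stationary_od,
                         spec$od0 * 2^((times - spec$lag_min) / spec$doubling_time)))
  od <- matrix(NA_real_, nrow = length(times), ncol = spec$replicates)
  for (r in seq_len(spec$replicates)) {
    od[, r] <- with_seed(spec$seed + 104729L * r, {
      mean_od * exp(rnorm(length(times), 0, spec$noise))
    })
  }
  colnames(od) <- paste0("rep", seq_len(spec$replicates))
  structure(list(times = times, od = od), class = "growth_curve")
}

#' Write growth curves to CSV (wide format: time_min, rep1, rep2, ...)
#' @param curve A `growth_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(curve, path) {
  df <- data.frame(time_min = curve$times, curve$od, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read growth curves from CSV
#'
#' Accepts wide format (a time column followed by one column per replicate)
#' or long format (columns `time`, `replicate`, `od`; name matching is
#' case-insensitive and `time_min`/`od600` are accepted).
#'
#' @param path CSV path.
#' @return A `growth_curve`.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- tolower(names(df))
  if (all(c("replicate", "od") %in% nms) ||
      all(c("replicate", "od600") %in% nms)) {
    tcol <- which(nms %in% c("time", "time_min"))[1]
    rcol <- which(nms == "replicate")[1]
    ocol <- which(nms %in% c("od", "od600"))[1]
    reps <- sort(unique(df[[rcol]]))
    times <- sort(unique(df[[tcol]]))
    od <- sapply(reps, function(r) {
      sub <- df[df[[rcol]] == r, ]
      sub[[ocol]][order(sub[[tcol]])]
    })
    colnames(od) <- paste0("rep", seq_along(reps))
    structure(list(times = times, od = od), class = "growth_curve")
  } else {
    structure(list(times = df[[1]],
                   od = as.matrix(df[, -1, drop = FALSE])),
              class = "growth_curve")
  }
}
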