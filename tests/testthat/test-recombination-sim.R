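catalog <- lox_catalog()
dict <- oracle_lox_dictionary()

test_that("same-orientation excision leaves a lox72 scar and a wild-type circle", {
  fx <- plant_sites(2000L, list(list(lox = "lox71", at = 200L, orientation = "forward"),
                                list(lox = "lox66", at = 1200L, orientation = "forward")),
                    seed = 1)
  succ <- cre_step(system_state(fx$molecule))
  expect_length(succ, 1L)
  expect_equal(succ[[1]]$event$type, "excision")
  expect_true(succ[[1]]$event$forms_inactive)
  st <- succ[[1]]$state
  expect_length(st$molecules, 2L)
  main <- Filter(function(m) m$id == "fix", st$molecules)[[1]]
  circ <- Filter(function(m) m$id != "fix", st$molecules)[[1]]
  main_lox <- locate_lox(main)
  expect_length(main_lox, 1L)
  expect_false(is_active(main_lox[[1]]$site))
  expect_equal(lox_sequence(main_lox[[1]]$site), lox_sequence(catalog$lox72))
  circ_lox <- locate_lox(circ)
  expect_length(circ_lox, 1L)
  expect_equal(lox_sequence(circ_lox[[1]]$site), lox_sequence(catalog$loxP))
  # sequence content conserved
  count_bases <- function(mols) {
    sort(table(strsplit(paste(vapply(mols, function(m) m$sequence, character(1)),
                              collapse = ""), "")[[1]]))
  }
  expect_equal(count_bases(st$molecules), count_bases(list(fx$molecule)))
})

test_that("a lone lox site or incompatible pair produces no successors", {
  fx1 <- plant_sites(1000L, list(list(lox = "loxP", at = 300L, orientation = "forward")))
  expect_length(cre_step(system_state(fx1$molecule)), 0L)
  fx2 <- plant_sites(1500L, list(list(lox = "loxP", at = 200L, orientation = "forward"),
                                 list(lox = "lox2272", at = 900L, orientation = "forward")))
  rep <- cre_closure(system_state(fx2$molecule))
  expect_equal(rep$n_states, 1L)
  expect_length(rep$terminal_states, 1L)
  expect_false(rep$reversible)
})

test_that("opposite-orientation recombination inverts the intervening segment exactly", {
  fx <- plant_sites(1600L, list(list(lox = "loxP", at = 150L, orientation = "forward"),
                                list(lox = "loxP", at = 1100L, orientation = "reverse")),
                    seed = 3, circular = FALSE)
  m <- fx$molecule
  succ <- cre_step(system_state(m))
  expect_length(succ, 1L)
  expect_equal(succ[[1]]$event$type, "inversion")
  inv <- succ[[1]]$state$molecules[[1]]
  # middle reverse-complemented, flanks untouched
  expect_equal(substr(inv$sequence, 1, 150), substr(m$sequence, 1, 150))
  expect_equal(substr(inv$sequence, 185, 1100),
               oracle_revcomp(substr(m$sequence, 185, 1100)))
  expect_equal(substr(inv$sequence, 1135, 1600), substr(m$sequence, 1135, 1600))
  # involution: applying the reverse event restores the molecule exactly
  succ2 <- cre_step(succ[[1]]$state)
  expect_length(succ2, 1L)
  expect_equal(succ2[[1]]$state$molecules[[1]]$sequence, m$sequence)
})

test_that("every Cre successor conserves the duplex base content", {
  # inversions reverse-complement a segment, so conservation holds at the
  # duplex level: A+T and C+G totals (and overall length) are invariant
  duplex_counts <- function(seqs) {
    b <- table(strsplit(paste(seqs, collapse = ""), "")[[1]])
    g <- function(x) if (x %in% names(b)) as.integer(b[[x]]) else 0L
    c(at = g("A") + g("T"), cg = g("C") + g("G"))
  }
  set.seed(11)
  combos <- list(
    list(list(lox = "lox71", at = 100L, orientation = "forward"),
         list(lox = "lox66", at = 700L, orientation = "forward")),
    list(list(lox = "loxP", at = 150L, orientation = "forward"),
         list(lox = "loxP", at = 800L, orientation = "reverse")),
    list(list(lox = "lox66", at = 100L, orientation = "forward"),
         list(lox = "loxP", at = 600L, orientation = "forward"),
         list(lox = "lox71", at = 1100L, orientation = "forward")))
  for (pl in combos) {
    fx <- plant_sites(1500L, pl, seed = sample(1e6, 1))
    st <- system_state(fx$molecule)
    ref <- duplex_counts(fx$molecule$sequence)
    for (s in cre_step(st)) {
      got <- duplex_counts(vapply(s$state$molecules, function(m) m$sequence,
                                  character(1)))
      expect_equal(got, ref)
      # excisions and fusions additionally conserve single-strand counts
      if (s$event$type != "inversion") {
        expect_equal(
          as.list(table(strsplit(paste(vapply(s$state$molecules,
                                              function(m) m$sequence,
                                              character(1)), collapse = ""),
                                 "")[[1]])),
          as.list(table(strsplit(fx$molecule$sequence, "")[[1]])))
      }
    }
  }
})

test_that("cre_closure matches the brute-force string-splicing enumerator", {
  cases <- list(
    # deletion pair
    list(list(lox = "lox71", at = 200L, orientation = "forward"),
         list(lox = "lox66", at = 1200L, orientation = "forward")),
    # inversion pair, wild type (reversible)
    list(list(lox = "loxP", at = 150L, orientation = "forward"),
         list(lox = "loxP", at = 1000L, orientation = "reverse")),
    # inversion locking pair
    list(list(lox = "lox71", at = 150L, orientation = "forward"),
         list(lox = "lox66", at = 1000L, orientation = "reverse")),
    # incompatible linkers
    list(list(lox = "loxP", at = 300L, orientation = "forward"),
         list(lox = "lox2272", at = 1100L, orientation = "forward")),
    # cut-and-paste triple
    list(list(lox = "loxP", at = 100L, orientation = "forward"),
         list(lox = "lox71", at = 700L, orientation = "forward"),
         list(lox = "lox66", at = 1500L, orientation = "forward")),
    # reverse-orientation pair
    list(list(lox = "lox71", at = 200L, orientation = "reverse"),
         list(lox = "lox66", at = 1100L, orientation = "reverse")),
    # three wild-type sites, mixed orientation
    list(list(lox = "loxP", at = 100L, orientation = "forward"),
         list(lox = "loxP", at = 800L, orientation = "reverse"),
         list(lox = "loxP", at = 1400L, orientation = "forward")))
  for (ci in seq_along(cases)) {
    fx <- plant_sites(2000L, cases[[ci]], seed = 100 + ci)
    impl <- impl_terminal_keys(system_state(fx$molecule), max_states = 500L)
    orac <- oracle_closure(list(fx$raw), dict, max_states = 500L)
    expect_equal(impl, orac$terminal_keys, info = paste("case", ci))
  }
  # two-molecule integration (fusion)
  fx1 <- plant_sites(1200L, list(list(lox = "lox66", at = 300L, orientation = "forward")),
                     seed = 201)
  fx2 <- plant_sites(800L, list(list(lox = "lox71", at = 100L, orientation = "forward")),
                     seed = 202)
  impl <- impl_terminal_keys(system_state(list(fx1$molecule, fx2$molecule)))
  orac <- oracle_closure(list(fx1$raw, fx2$raw), dict)
  expect_equal(impl, orac$terminal_keys)
})

test_that("state-space bound raises an explicit truncation error", {
  fx <- plant_sites(2000L, list(list(lox = "loxP", at = 100L, orientation = "forward"),
                                list(lox = "loxP", at = 700L, orientation = "forward"),
                                list(lox = "loxP", at = 1400L, orientation = "forward")),
                    seed = 7)
  expect_error(cre_closure(system_state(fx$molecule), max_states = 2L),
               class = "loxtron_state_bound_error")
})

test_that("RMCE integrates then resolves, leaving cargo locked by dead sites", {
  fx <- make_genome(fixture_spec(seed = 11, genome_length = 12000, loci = "lacZ"),
                    catalog)
  plan <- edit_plan("rmce_insertion",
    regions = list(list(locus = plan_site("lacZ", c("loxm2/71", "lox66"),
                                          c("forward", "forward"), "EcI5", "s"))),
    delivery = list(lox = c("loxm2/66", "lox71"), cargo_length = 800L,
                    backbone_length = 2000L))
  u <- apply_plan(plan, fx$molecule)
  rep <- cre_closure(u)
  # two sequential events: integration then backbone excision
  expect_true(any(vapply(rep$terminal_states, function(st) length(st$log) == 2L,
                         logical(1))))
  expect_length(rep$terminal_states, 1L)
  chrom <- Filter(function(m) m$id == "genome", rep$terminal_states[[1]]$molecules)[[1]]
  lox <- Filter(function(f) f$kind == "lox", chrom$features)
  expect_length(lox, 2L)
  expect_true(all(!vapply(lox, function(f) is_active(f$payload), logical(1))))
  expect_setequal(vapply(lox, function(f) f$payload$linker_class, character(1)),
                  c("P", "m2"))
  cargo <- Filter(function(f) f$kind == "gene" && f$label == "cargo", chrom$features)
  expect_length(cargo, 1L)
})

test_that("cut-and-paste reaches exactly one translocated terminal locked by lox72", {
  fx <- make_genome(fixture_spec(seed = 21, genome_length = 30000,
                                 loci = c("A", "lacZ", "E")), catalog)
  plan <- edit_plan("cut_and_paste", list(list(
    locus_up = plan_site("A", "loxP", "forward", "Ll.LtrB", "s"),
    locus_down = plan_site("lacZ", "lox71", "forward", "EcI5", "s"),
    locus_target = plan_site("E", "lox66", "forward", "EcI5", "a"))))
  u <- apply_plan(plan, fx$molecule)
  rep <- cre_closure(u)
  expect_true(rep$reversible)  # the cut step is reversible
  translocated <- Filter(function(st) {
    chrom <- Filter(function(m) m$id == "genome", st$molecules)
    if (length(chrom) == 0L) return(FALSE)
    feats <- chrom[[1]]$features
    genes <- sum(vapply(feats, function(f) f$kind == "gene", logical(1)))
    dead <- sum(vapply(feats, function(f) f$kind == "lox" && !is_active(f$payload),
                       logical(1)))
    genes == 3L && dead == 1L
  }, rep$terminal_states)
  expect_length(translocated, 1L)
  # the translocation event itself formed the lox72 lock
  expect_true(any(vapply(translocated[[1]]$log, function(e) e$forms_inactive,
                         logical(1))))
})

test_that("host recombination collapses direct repeats by one repeat plus spacing", {
  # two identical direct-repeat scaffolds 1 kb apart
  sc <- intron_scaffold("EcI5")
  set.seed(9)
  spacer <- paste(sample(c("A","C","G","T"), 1000, TRUE), collapse = "")
  flank1 <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
  flank2 <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
  seq <- paste0(flank1, sc$sequence, spacer, sc$sequence, flank2)
  pay <- function() list(intron_type = "EcI5", scaffold_range = c(0L, 1000L),
                         scaffold_len = 1000L)
  m <- molecule("toy", seq, "linear", list(
    feature("intron", 500L, 1500L, "+", "i1", pay()),
    feature("intron", 2500L, 3500L, "+", "i2", pay())))
  evs <- host_recombination(m)
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$event$type, "hr_collapse")
  prod <- evs[[1]]$molecule
  expect_equal(mol_len(prod), mol_len(m) - 1000L - 1000L)
  # hand-spliced expectation: one scaffold copy plus the spacer removed
  expect_equal(prod$sequence, paste0(flank1, sc$sequence, flank2))
})

test_that("non-homologous introns support no host recombination", {
  ltr <- intron_scaffold("Ll.LtrB")
  eci <- intron_scaffold("EcI5")
  set.seed(10)
  seq <- paste0(strrep("A", 100), ltr$sequence,
                paste(sample(c("A","C","G","T"), 800, TRUE), collapse = ""),
                eci$sequence, strrep("T", 100))
  m <- molecule("toy", seq, "linear", list(
    feature("intron", 100L, 1100L, "+", "i1",
            list(intron_type = "Ll.LtrB", scaffold_range = c(0L, 1000L),
                 scaffold_len = 1000L)),
    feature("intron", 1900L, 2900L, "+", "i2",
            list(intron_type = "EcI5", scaffold_range = c(0L, 1000L),
                 scaffold_len = 1000L))))
  expect_length(host_recombination(m), 0L)
})

test_that("adjacent inverted repeats are removed to a short lox-free scar", {
  panel <- rearrangement_panel()
  row <- panel[panel$id == "R04", ]  # deletion leaving an inverted repeat
  rep <- classify_design(panel_plan(row))
  expect_true(rep$inverted_repeat_generated)
  expect_false(rep$scar_description$contains_lox)
  expect_equal(rep$scar_description$length, 40L)
  expect_lt(rep$scar_description$length, 1000L)  # shorter than one scaffold
})

test_that("separated inverted repeats drive a reversible host inversion", {
  sc <- intron_scaffold("EcI5")
  set.seed(12)
  mid <- paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = "")
  seq <- paste0(strrep("A", 50), sc$sequence, mid, oracle_revcomp(sc$sequence),
                strrep("T", 50))
  pay <- function() list(intron_type = "EcI5", scaffold_range = c(0L, 1000L),
                         scaffold_len = 1000L)
  m <- molecule("toy", seq, "linear", list(
    feature("intron", 50L, 1050L, "+", "i1", pay()),
    feature("intron", 3050L, 4050L, "-", "i2", pay())))
  evs <- host_recombination(m)
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$event$type, "hr_inversion")
  prod <- evs[[1]]$molecule
  expect_equal(mol_len(prod), mol_len(m))
  # applying the inversion again restores the original sequence
  evs2 <- host_recombination(prod)
  expect_equal(evs2[[1]]$event$type, "hr_inversion")
  expect_equal(evs2[[1]]$molecule$sequence, m$sequence)
})
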