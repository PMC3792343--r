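catalog <- lox_catalog()

test_that("in-silico PCR finds exactly the planted convergent product", {
  set.seed(41)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  fwd <- substr(seq, 1001, 1020)
  rev <- oracle_revcomp(substr(seq, 1481, 1500))
  m <- molecule("lin", seq, "linear")
  hits <- insilico_pcr(m, c(fwd, rev))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$size, 500L)
  expect_equal(hits$start, 1000L)
  # absent primer: no band
  expect_equal(nrow(insilico_pcr(m, c(fwd, strrep("ACGT", 5)))), 0L)
  # primers below 15 nt are refused
  expect_error(insilico_pcr(m, c("ACGTACGTACGT", rev)),
               class = "loxtron_design_error")
})

test_that("circular molecules amplify across the origin", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  m <- molecule("circ", seq, "circular")
  # primers convergent across the origin: left primer near the end,
  # right primer annealing near the start
  fwd <- substr(seq, 1901, 1920)
  rev <- oracle_revcomp(substr(seq, 181, 200))
  hits <- insilico_pcr(m, c(fwd, rev))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$size, 300L)
  # linear representation of the same sequence yields no product
  expect_equal(nrow(insilico_pcr(molecule("lin", seq, "linear"), c(fwd, rev))), 0L)
})

test_that("in-silico PCR product sizes match the substring-scan oracle", {
  set.seed(43)
  for (rep in 1:8) {
    n <- sample(2000:10000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    topo <- sample(c("linear", "circular"), 1)
    m <- molecule("m", seq, topo)
    a <- sample(n - 600, 1)
    b <- a + sample(300:550, 1)
    p1 <- substr(seq, a, a + 19)
    p2 <- oracle_revcomp(substr(seq, b, b + 19))
    got <- sort(unique(insilico_pcr(m, c(p1, p2), max_product = 5000L)$size))
    expect_equal(got, oracle_pcr_sizes(m, p1, p2, 5000L), info = paste("rep", rep))
  }
})

test_that("assay plans have 3, 4 and 6 assays for the three operations", {
  fx <- make_genome(fixture_spec(seed = 21, genome_length = 30000,
                                 loci = c("A", "lacZ", "E")), catalog)
  del <- edit_plan("deletion", list(list(
    locus_up = plan_site("A", "lox71"), locus_down = plan_site("lacZ", "lox66"))))
  inv <- edit_plan("inversion", list(list(
    locus_up = plan_site("A", "lox71"),
    locus_down = plan_site("lacZ", "lox66", "reverse"))))
  cap <- edit_plan("cut_and_paste", list(list(
    locus_up = plan_site("A", "loxP", "forward", "Ll.LtrB", "s"),
    locus_down = plan_site("lacZ", "lox71", "forward", "EcI5", "s"),
    locus_target = plan_site("E", "lox66", "forward", "EcI5", "a"))))
  expect_equal(nrow(design_assays(del, fx$molecule)$assays), 3L)
  expect_equal(nrow(design_assays(inv, fx$molecule)$assays), 4L)
  expect_equal(nrow(design_assays(cap, fx$molecule)$assays), 6L)
  # primer naming follows the locus-letter + u/d grammar, lacZ abbreviated L
  ap <- design_assays(del, fx$molecule)
  expect_setequal(ap$assays$name, c("Au/Ad", "Lu/Ld", "Au/Ld"))
})

test_that("assay counts hold for randomly generated valid plans", {
  set.seed(44)
  ops <- c(rep("deletion", 45), rep("inversion", 45), rep("cut_and_paste", 10))
  for (k in seq_along(ops)) {
    op <- ops[k]
    loci <- c("A", "B", "C")
    fx <- make_genome(fixture_spec(seed = sample(1e6, 1),
                                   genome_length = sample(c(18000L, 24000L), 1),
                                   loci = loci), catalog)
    strands <- sample(c("s", "a"), 3, replace = TRUE)
    types <- sample(c("EcI5", "Ll.LtrB"), 3, replace = TRUE)
    plan <- if (op == "deletion") {
      edit_plan(op, list(list(
        locus_up = plan_site("A", "lox71", "forward", types[1], strands[1]),
        locus_down = plan_site("B", "lox66", "forward", types[2], strands[2]))))
    } else if (op == "inversion") {
      edit_plan(op, list(list(
        locus_up = plan_site("A", "lox71", "forward", types[1], strands[1]),
        locus_down = plan_site("B", "lox66", "reverse", types[2], strands[2]))))
    } else {
      edit_plan(op, list(list(
        locus_up = plan_site("A", "loxP", "forward", types[1], strands[1]),
        locus_down = plan_site("B", "lox71", "forward", types[2], strands[2]),
        locus_target = plan_site("C", "lox66", "forward", types[3], strands[3]))))
    }
    ap <- design_assays(plan, fx$molecule)
    expect_equal(nrow(ap$assays),
                 c(deletion = 3L, inversion = 4L, cut_and_paste = 6L)[[op]],
                 info = paste(op, k))
  }
})

test_that("deletion signatures follow the W/U/I diagnostic logic", {
  fx <- make_genome(fixture_spec(seed = 45, genome_length = 24000,
                                 loci = c("A", "lacZ")), catalog)
  plan <- edit_plan("deletion", list(list(
    locus_up = plan_site("A", "lox71"), locus_down = plan_site("lacZ", "lox66"))))
  ap <- design_assays(plan, fx$molecule)
  u <- apply_plan(plan, fx$molecule)
  i <- loxtron:::induced_state(plan, fx$molecule)
  sig <- predict_signature(ap, list(W = fx$molecule, U = u, I = i))
  for (r in seq_len(nrow(sig))) {
    exp_present <- ap$expected[[sig$state[r]]][ap$expected$name == sig$assay[r]]
    expect_equal(sig$n_bands[r] > 0L, exp_present,
                 info = paste(sig$assay[r], sig$state[r]))
  }
  # U-state insertion bands exceed W by the intron insert length
  wsize <- sig$sizes[sig$assay == "Au/Ad" & sig$state == "W"]
  usize <- sig$sizes[sig$assay == "Au/Ad" & sig$state == "U"]
  growth <- as.integer(usize) - as.integer(wsize)
  expect_gt(growth, 900L)   # "about 1 kb larger"
  expect_lt(growth, 1200L)
})

test_that("inverted-repeat collapse shrinks the deletion junction band", {
  fx <- make_genome(fixture_spec(seed = 46, genome_length = 24000,
                                 loci = c("D", "E")), catalog)
  collapse_plan <- edit_plan("deletion", list(list(
    locus_up = plan_site("D", "lox71", "forward", "EcI5", "s"),
    locus_down = plan_site("E", "lox66", "forward", "EcI5", "a"))))
  plain_plan <- edit_plan("deletion", list(list(
    locus_up = plan_site("D", "lox71", "forward", "EcI5", "s"),
    locus_down = plan_site("E", "lox66", "forward", "EcI5", "s"))))
  ap1 <- design_assays(collapse_plan, fx$molecule)
  ap2 <- design_assays(plain_plan, fx$molecule)
  i1 <- loxtron:::induced_state(collapse_plan, fx$molecule)
  i2 <- loxtron:::induced_state(plain_plan, fx$molecule)
  s1 <- predict_signature(ap1, list(I = i1))
  s2 <- predict_signature(ap2, list(I = i2))
  j1 <- as.integer(s1$sizes[s1$role == "junction"])
  j2 <- as.integer(s2$sizes[s2$role == "junction"])
  # collapsed junction is smaller by at least one scaffold length
  expect_gt(j2 - j1, 1000L)
})

test_that("every induced-state band arises from a terminal state of the closure", {
  fx <- make_genome(fixture_spec(seed = 47, genome_length = 30000,
                                 loci = c("A", "lacZ", "E")), catalog)
  plan <- edit_plan("cut_and_paste", list(list(
    locus_up = plan_site("A", "loxP", "forward", "Ll.LtrB", "s"),
    locus_down = plan_site("lacZ", "lox71", "forward", "EcI5", "s"),
    locus_target = plan_site("E", "lox66", "forward", "EcI5", "a"))))
  ap <- design_assays(plan, fx$molecule)
  i <- loxtron:::induced_state(plan, fx$molecule)
  sig <- predict_signature(ap, list(I = i))
  expect_true(all(sig$n_bands[sig$role %in% c("cut_bridge", "paste_bridge")] > 0L))
  expect_true(all(sig$n_bands[sig$role == "site_bridge"] == 0L))
})
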