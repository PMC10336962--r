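test_that("only termini titrate in a glycine pentamer at neutral pH", {
  ca <- assign_charges("GGGGG", pH = 7)
  expect_equal(ca$per_bead_charge, c(1L, 0L, 0L, 0L, -1L))
  expect_equal(ca$net_charge, 0L)
  expect_equal(ca$n_positive, 1L)
  expect_equal(ca$n_negative, 1L)
})

test_that("Henderson-Hasselbalch rounding gives the expected end states", {
  # lysines fully protonated at pH 7; termini cancel as dedicated beads
  expect_equal(
    assign_charges("KKKKK", pH = 7, termini_mode = "extra_beads")$net_charge,
    5L)
  # in merged mode the N-terminal +1 lands on an already positive lysine
  # bead and is clamped to the model's +1 ceiling
  expect_warning(km <- assign_charges("KKKKK", pH = 7), "clamped")
  expect_equal(km$net_charge, 4L)
  # at pH 2 glutamates and the C-terminus are protonated; N-terminus +1
  expect_equal(assign_charges("EEEEE", pH = 2)$net_charge, 1L)
  # histidine neutral at pH 7 by rounding, +1 well below its pKa
  expect_equal(assign_charges("GHG", pH = 7)$per_bead_charge[2], 0L)
  expect_equal(assign_charges("GHG", pH = 4)$per_bead_charge[2], 1L)
})

test_that("termini modes agree on net charge and differ in bead count", {
  m <- assign_charges("GDKG", termini_mode = "merged")
  x <- assign_charges("GDKG", termini_mode = "extra_beads")
  expect_length(m$per_bead_charge, 4L)
  expect_length(x$per_bead_charge, 6L)
  expect_equal(x$per_bead_charge[1], 1L)     # N-terminal bead
  expect_equal(x$per_bead_charge[6], -1L)    # C-terminal bead
  expect_equal(m$net_charge, x$net_charge)
  # merging a terminal charge onto a like-charged residue clamps with warning
  expect_warning(ck <- assign_charges("KGGGG"), "clamped")
  expect_equal(ck$per_bead_charge[1], 1L)
})

test_that("invalid sequences and incomplete pKa tables are rejected", {
  expect_error(assign_charges("ACXDE"), "position 3")
  expect_error(assign_charges(""), "non-empty")
  expect_error(assign_charges("AK", pH = 20), "pH")
  broken <- default_pka()
  broken$residues$K <- NULL
  expect_error(assign_charges("AKA", pka_table = broken), "missing titratable")
})

test_that("bead charge is monotonically non-increasing in pH", {
  for (res in c("D", "E", "H", "C", "Y", "K", "R")) {
    seqs <- paste0("G", res, "G")
    q <- vapply(seq(0, 14, by = 0.25),
                function(p) assign_charges(seqs, pH = p)$per_bead_charge[2],
                integer(1))
    expect_true(all(diff(q) <= 0), info = res)
  }
})

test_that("composition descriptors follow their definitions", {
  d <- sequence_descriptors("KKDAAAAAAG")   # 2 positive, 1 negative, len 10
  expect_equal(d$fcr, 0.3)
  expect_equal(d$ncpr, 0.1)

  dp <- sequence_descriptors("PPPP")
  expect_equal(dp$proline_fraction, 1)
  expect_equal(dp$fcr, 0)
  expect_equal(dp$ncpr, 0)
  expect_equal(dp$kd_hydrophobicity, -1.6)

  expect_error(sequence_descriptors(""), "non-empty")
})

test_that("descriptors are invariant under sequence reversal", {
  set.seed(101)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    s <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    ds <- sequence_descriptors(s); dr <- sequence_descriptors(r)
    expect_equal(ds$fcr, dr$fcr)
    expect_equal(ds$ncpr, dr$ncpr)
    expect_equal(ds$kd_hydrophobicity, dr$kd_hydrophobicity)
    expect_equal(ds$proline_fraction, dr$proline_fraction)
  }
})

test_that("NCPR never exceeds FCR on random sequences", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:1000) {
    s <- paste(sample(aas, sample(5:60, 1), replace = TRUE), collapse = "")
    d <- sequence_descriptors(s)
    expect_lte(d$ncpr, d$fcr + 1e-12)
    expect_gte(d$fcr, 0); expect_lte(d$fcr, 1)
  }
})

test_that("FASTA reading normalizes wrapping and preserves order", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE"), p)
  expect_equal(read_fasta(p), c(a = "ACDE"))

  # wrapped record concatenates, lower case is normalized
  p2 <- tempfile(fileext = ".fasta")
  writeLines(c(">wrapped some description",
               strrep("ACDEFGHIKL", 8), "mnpq"), p2)
  s2 <- read_fasta(p2)
  expect_equal(nchar(s2[["wrapped"]]), 84L)
  expect_equal(substr(s2[["wrapped"]], 81, 84), "MNPQ")

  p3 <- tempfile(fileext = ".fasta")
  writeLines(c(">z", "AAA", ">y", "CCC", ">x", "DDD"), p3)
  expect_equal(names(read_fasta(p3)), c("z", "y", "x"))

  p4 <- tempfile(fileext = ".fasta")
  file.create(p4)
  expect_error(read_fasta(p4), "no records|parse")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("packaged histatin 5 record matches its published composition", {
  s <- hst5_sequence()
  expect_equal(nchar(s), 24L)
  ca <- assign_charges(s)
  expect_equal(ca$net_charge, 5L)
  d <- sequence_descriptors(s)
  # histatin 5 is a basic, histidine-rich peptide
  expect_gt(d$ncpr, 0.15)
  expect_lt(d$kd_hydrophobicity, 0)
})
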