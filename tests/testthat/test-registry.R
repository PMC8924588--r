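test_that("overhang fidelity check flags duplicates, rc-collisions, palindromes", {
  expect_true(check_overhang_set(c("AATG", "AGGT", "GCTT", "CCAG"))$faithful)

  r <- check_overhang_set(c("AATG", "ACGT"))
  expect_false(r$faithful)
  expect_match(r$failures, "self-palindromic overhang ACGT", all = FALSE)

  r <- check_overhang_set(c("GGAC", "GTCC", "AATG"))
  expect_false(r$faithful)
  expect_match(r$failures, "reverse-complement collision", all = FALSE)

  r <- check_overhang_set(c("AATG", "AATG"))
  expect_false(r$faithful)
  expect_match(r$failures, "duplicate", all = FALSE)

  expect_error(check_overhang_set(c("AAT")), "exactly 4 nt")
})

test_that("the shipped fusion-site table is faithful", {
  tab <- default_overhang_table()
  expect_equal(tab$label, 1:11)
  expect_true(all(nchar(tab$sequence) == 4))
  expect_true(check_overhang_set(tab$sequence)$faithful)
})

test_that("slot layouts give 4/7/10 fragments with shared junction labels", {
  l1 <- slot_layout("pGGYL1")
  l2 <- slot_layout("pGGYL2")
  l3 <- slot_layout("pGGYL3")
  expect_equal(nrow(l1), 4L)
  expect_equal(nrow(l2), 7L)
  expect_equal(nrow(l3), 10L)
  expect_equal(sum(l1$role == "promoter"), 1L)  # 1 transcription unit
  expect_equal(sum(l3$role == "promoter"), 3L)  # 3 transcription units
  for (l in list(l1, l2, l3)) {
    expect_identical(l$left_label[-1], l$right_label[-nrow(l)])
  }
  # labels drawn from 1..11 without repetition, plus the closing junction
  expect_equal(c(l3$left_label, l3$right_label[10]), 1:11)
  expect_error(slot_layout("pGGYL9"), "unknown backbone")
})

test_that("validate_part reports internal sites, bad labels, degenerate pairs", {
  clean <- ggyl_part("ok", "promoter", dna_seq(random_seq_fixed(300)), 2, 3)
  v <- validate_part(clean)
  expect_true(v$ok)
  expect_length(v$violations, 0L)

  dirty <- ggyl_part("bad", "promoter",
                     dna_seq(paste0(random_seq_fixed(40), "GGTCTC",
                                    random_seq_fixed(40))), 2, 3)
  v <- validate_part(dirty)
  expect_false(v$ok)
  expect_match(v$violations, "internal BsaI site at position 40", all = FALSE)

  selfcirc <- ggyl_part("loop", "promoter", dna_seq(random_seq_fixed(100)), 2, 2)
  v <- validate_part(selfcirc)
  expect_match(v$violations, "self-circularizing", all = FALSE)

  badlab <- ggyl_part("nolabel", "promoter", dna_seq(random_seq_fixed(100)), 2, 99)
  expect_match(validate_part(badlab)$violations, "unknown overhang label 99",
               all = FALSE)
})

test_that("a self-circularizing part really does close on itself", {
  # confirm the validation verdict by brute force over the released fragment
  tab <- default_overhang_table()
  oh <- tab$sequence[tab$label == 2]
  frag <- sticky_fragment(dna_seq(paste0(oh, random_seq_fixed(80), oh)),
                          oh, oh, "loop")
  circles <- enumerate_products_bruteforce(list(frag))
  expect_length(circles, 1L)
  expect_equal(circles[[1]]$composition, 1L)
})

test_that("donor plasmids release the part as one of exactly two fragments", {
  reg <- demo_registry()
  for (pid in c("PGPD", "ERG10", "HUH", "TXPR2")) {
    bb <- building_block_plasmid(reg$parts[[pid]], reg$overhangs)
    frags <- digest(bb, bsaI())
    expect_length(frags, 2L)
    n_sites <- vapply(frags, function(f) nrow(scan_sites(f$seq, bsaI())),
                      integer(1))
    # the part fragment carries no recognition site; the vector keeps both
    expect_setequal(n_sites, c(0L, 2L))
    part_frag <- frags[[which(n_sites == 0L)]]
    p <- reg$parts[[pid]]
    oh <- function(l) reg$overhangs$sequence[reg$overhangs$label == l]
    expect_identical(part_frag$seq$bases,
                     paste0(oh(p$left_label), p$insert$bases, oh(p$right_label)))
  }
})

test_that("backbones carry two SwaI sites bracketing the slot region only", {
  reg <- demo_registry()
  for (id in names(reg$backbones)) {
    bb <- reg$backbones[[id]]
    expect_equal(nrow(scan_sites(bb, swaI())), 2L)
    expect_equal(nrow(scan_sites(bb, bsaI())), 2L)
    # digest at SwaI: the stuffer-side fragment has no vector-body feature
    halves <- digest(bb, swaI())
    has_stuffer <- vapply(halves, function(f)
      nrow(get_features(f$seq, "lacZ_stuffer")) > 0, logical(1))
    expect_equal(sum(has_stuffer), 1L)
    slotside <- halves[[which(has_stuffer)]]$seq
    expect_equal(nrow(get_features(slotside, "kanR")), 0L)
    expect_equal(nrow(get_features(slotside, "ori")), 0L)
  }
})

test_that("registry load is atomic, counts roles, and round-trips", {
  reg <- demo_registry()
  rc <- role_counts(reg)
  expect_equal(unname(rc["promoter"]), 8L)
  expect_equal(unname(rc["terminator"]), 9L)
  expect_equal(unname(rc["marker"]), 6L)
  expect_equal(unname(rc["mva_cds"]), 8L)

  # empty catalog -> empty registry
  empty <- load_registry(data.frame(), list())
  expect_length(empty$parts, 0L)

  # serialization round trip reproduces every part
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  reg2 <- load_registry(file.path(dir, "catalog.tsv"),
                        file.path(dir, "parts.fasta"))
  expect_setequal(names(reg2$parts), names(reg$parts))
  for (pid in names(reg$parts)) {
    expect_identical(reg2$parts[[pid]]$insert$bases,
                     reg$parts[[pid]]$insert$bases)
    expect_identical(reg2$parts[[pid]]$role, reg$parts[[pid]]$role)
  }
  # and loading the re-serialized output is idempotent
  dir2 <- withr::local_tempdir()
  write_registry(reg2, dir2)
  expect_identical(readLines(file.path(dir, "catalog.tsv")),
                   readLines(file.path(dir2, "catalog.tsv")))

  # a row naming an absent record fails atomically, listing the id
  cat2 <- data.frame(id = c("a", "b"), role = "promoter", left_label = 2,
                     right_label = 3, sequence_ref = c("a", "ghost"),
                     stringsAsFactors = FALSE)
  seqs <- list(a = dna_seq(random_seq_fixed(300)))
  expect_error(load_registry(cat2, seqs), "missing sequence record 'ghost'")

  # duplicate ids are rejected
  cat3 <- data.frame(id = c("a", "a"), role = "promoter", left_label = 2,
                     right_label = 3, sequence_ref = "a",
                     stringsAsFactors = FALSE)
  expect_error(load_registry(cat3, seqs), "duplicate part id")
})

test_that("retargeting re-labels a part and records its origin", {
  reg <- demo_registry()
  p <- reg$parts[["PGPD"]]
  v <- retarget_part(p, 5, 6)
  expect_equal(v$left_label, 5L)
  expect_equal(v$right_label, 6L)
  expect_equal(v$variant_of, "PGPD")
  expect_identical(v$insert$bases, p$insert$bases)
  # retargeting to the part's own slot is a no-op
  expect_identical(retarget_part(p, p$left_label, p$right_label)$id, "PGPD")
})
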