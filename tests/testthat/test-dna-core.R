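test_that("reverse complement: palindrome fixed point, involution, naive oracle", {
  expect_identical(reverse_complement(dna_seq("ATTTAAAT"))$bases, "ATTTAAAT")

  set.seed(101)
  for (i in 1:10) {
    s <- random_seq(sample(50:200, 1))
    x <- dna_seq(s)
    expect_identical(reverse_complement(reverse_complement(x))$bases, s)
  }

  set.seed(102)
  s <- random_seq(1000)
  expect_identical(reverse_complement(dna_seq(s))$bases, naive_rc(s))
  # independent library cross-check
  expect_identical(
    reverse_complement(dna_seq(s))$bases,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
})

test_that("non-ACGT input is rejected with the offending position", {
  expect_error(dna_seq("ACGTNACGT"), "position 5")
  expect_error(dna_seq("acgu"), "position 4")
})

test_that("reverse complement remaps features to the flipped coordinates", {
  x <- dna_seq("AAACCCGGGTTT", annotations = data.frame(
    label = "f", start = 3L, end = 6L, strand = "+"))
  y <- reverse_complement(x)
  f <- get_features(y, "f")
  expect_equal(f$start, 6L)
  expect_equal(f$end, 9L)
  expect_equal(f$strand, "-")
  expect_identical(substr(y$bases, f$start + 1, f$end), naive_rc("CCC"))
})

test_that("translation follows the standard code and rejects broken frames", {
  expect_identical(translate_cds("ATGGGT"), "MG")
  expect_identical(translate_cds("TAA"), "*")
  expect_error(translate_cds("ATGG"), "frame error")

  set.seed(103)
  cds <- random_cds(100)
  expect_identical(
    translate_cds(cds),
    as.character(Biostrings::translate(Biostrings::DNAString(cds))))
})

test_that("scan_sites matches a naive sliding-window oracle on both strands", {
  expect_equal(nrow(scan_sites(dna_seq(""), bsaI())), 0L)

  set.seed(104)
  s <- random_seq(10000)
  found <- scan_sites(dna_seq(s), bsaI())
  exp_f <- naive_find(s, "GGTCTC")
  exp_r <- naive_find(s, naive_rc("GGTCTC"))
  expect_setequal(found$position[found$strand == "+"], exp_f)
  expect_setequal(found$position[found$strand == "-"], exp_r)
  expect_false(is.unsorted(found$position))

  sw <- scan_sites(dna_seq(s), swaI())
  expect_setequal(sw$position, naive_find(s, "ATTTAAAT"))
  expect_true(all(sw$strand == "+"))  # palindromes reported once
})

test_that("scan_sites finds sites spanning the origin of a circular sequence", {
  # GGT at the very end, CTC at the start: one plus-strand site over the origin
  s <- paste0("CTC", "A", random_seq_fixed(40), "GGT")
  x <- dna_seq(s, "circular")
  hits <- scan_sites(x, bsaI())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, nchar(s) - 3L)
  expect_equal(hits$strand, "+")
  # the same sequence treated as linear finds nothing
  expect_equal(nrow(scan_sites(dna_seq(s), bsaI())), 0L)
})

test_that("circular scanning is rotation-invariant up to index shift", {
  set.seed(105)
  for (rep in 1:5) {
    s <- paste0(random_seq(200), "GGTCTC", random_seq(200), "GAGACC",
                random_seq(100))
    n <- nchar(s)
    base_hits <- scan_sites(dna_seq(s, "circular"), bsaI())
    for (k in sample(seq_len(n - 1), 3)) {
      rot <- paste0(substr(s, k + 1, n), substr(s, 1, k))
      hits <- scan_sites(dna_seq(rot, "circular"), bsaI())
      expect_setequal((hits$position + k) %% n, base_hits$position)
    }
  }
})

test_that("digest reproduces the hand-traced BsaI cut geometry", {
  # two inward-facing sites around a 12-bp core; overhangs are the 4 bases
  # immediately 3' of each top-strand cut
  core <- "GATTACAGATTA"
  s <- paste0("TTTTTTTTTT", "GGTCTC", "A", "AATG", core, "AGGT", "A",
              "GAGACC", "TTTTTTTTTT")
  frags <- digest(dna_seq(s, "circular", id = "toy"), bsaI())
  expect_length(frags, 2L)
  ov <- vapply(frags, function(f) f$left_overhang, character(1))
  expect_setequal(ov, c("AATG", "AGGT"))
  insert <- frags[[which(ov == "AATG")]]
  expect_identical(insert$seq$bases, paste0("AATG", core, "AGGT"))
})

test_that("uncut circles, linear digestion counts, and entangled cuts behave", {
  x <- dna_seq(random_seq_fixed(60), "circular")
  frags <- digest(x, bsaI())
  expect_length(frags, 1L)
  expect_true(frags[[1]]$uncut)
  expect_true(frags[[1]]$circular)

  # linear parent with k sites gives k + 1 fragments
  s <- paste0("AAAAAAAA", "ATTTAAAT", "CCCCCCCC", "ATTTAAAT", "GGGGGGGG")
  frags <- digest(dna_seq(s), swaI())
  expect_length(frags, 3L)
  expect_identical(paste(vapply(frags, function(f) f$seq$bases, character(1)),
                         collapse = ""), s)

  # opposing sites whose cut windows overlap cannot be resolved
  s2 <- paste0("GGTCTC", "A", "TTTTTT", "GAGACC", "CCCCC")
  expect_error(digest(dna_seq(s2, topology = "linear"), bsaI()),
               "entangled cut")
})

test_that("digestion conserves content: re-ligation reconstructs the parent", {
  set.seed(106)
  for (rep in 1:20) {
    # plant 2-4 well-separated BsaI sites around a circle
    k <- sample(2:4, 1)
    chunks <- replicate(k, random_seq(sample(60:150, 1)))
    s <- paste(vapply(seq_len(k), function(i) {
      paste0("GGTCTC", "A", chunks[i])
    }, character(1)), collapse = "")
    x <- dna_seq(s, "circular")
    sites <- scan_sites(x, bsaI())
    if (nrow(sites) != k) next  # chance extra site in random filler
    frags <- digest(x, bsaI())
    expect_length(frags, k)
    rejoined <- ligate_fragments(frags, circularize = TRUE)
    expect_equal(seq_length(rejoined), seq_length(x))
    expect_identical(canonical_key(rejoined$bases), canonical_key(x$bases))
    # the two ends created by one cut are mutually compatible
    rights <- vapply(frags, function(f) f$right_overhang, character(1))
    lefts <- vapply(frags, function(f) f$left_overhang, character(1))
    expect_identical(rights, lefts[c(2:k, 1)])
  }
})

test_that("fragment flipping swaps and complements normalized overhangs", {
  f <- sticky_fragment(dna_seq("AATGCCCCAGGT"), "AATG", "AGGT", "demo")
  g <- flip_fragment(f)
  expect_identical(g$left_overhang, naive_rc("AGGT"))
  expect_identical(g$right_overhang, naive_rc("AATG"))
  expect_identical(flip_fragment(g)$seq$bases, f$seq$bases)
})
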