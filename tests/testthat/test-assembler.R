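test_that("a faithful 4-fragment design closes uniquely into a white product", {
  reg <- demo_registry()
  d <- design_with_retargeting("pGGYL1", c("HUH", "PTEF", "ERG10", "TXPR2"), reg)
  prod <- simulate_assembly(d)
  expect_s3_class(prod, "assembly_product")
  expect_length(prod$misjoin_flags, 0L)
  expect_equal(as.character(prod$colony_color), "white")
  expect_true(attr(prod$colony_color, "platable"))
  # scar-free: the converged product has no recognition sites left
  expect_equal(nrow(scan_sites(prod$sequence, bsaI())), 0L)
  expect_equal(nrow(scan_sites(prod$sequence, swaI())), 2L)
  # junctions follow the slot order
  expect_equal(prod$junctions$label, 1:5)
  expect_true(attr(junction_report(prod), "order_matches_design"))
  # and the brute-force oracle agrees the intended circle is what it is
  pool <- yaliclone:::design_fragment_pool(d)
  stable <- Filter(function(f) nrow(scan_sites(f$seq, bsaI())) == 0L, pool)
  bf <- enumerate_products_bruteforce(stable)
  expect_length(bf, 1L)
  expect_identical(bf[[1]]$key, canonical_key(prod$sequence$bases))
})

test_that("product equals direct slot-wise concatenation of vector and parts", {
  reg <- demo_registry()
  d <- design_with_retargeting("pGGYL2",
                               c("LEU2", "PGPD", "ERG13", "TMig1",
                                 "PTEF", "IDI", "TLip2"), reg)
  prod <- simulate_assembly(d, include_transient = FALSE)
  oh <- function(l) reg$overhangs$sequence[reg$overhangs$label == l]
  body <- digest(reg$backbones[["pGGYL2"]], bsaI())
  body <- body[[which(vapply(body, function(f)
    nrow(get_features(f$seq, "kanR")) > 0, logical(1)))]]
  layout <- slot_layout("pGGYL2")
  # direct concatenation: body footprint (left window dropped: it is the
  # closing junction), then insert + right-junction window per slot
  expected <- paste0(
    substr(body$seq$bases, 5L, nchar(body$seq$bases)),
    paste(vapply(seq_len(nrow(layout)), function(i) {
      base <- sub("@.*$", "", d$assignments[i])
      paste0(reg$parts[[base]]$insert$bases, oh(layout$right_label[i]))
    }, character(1)), collapse = ""))
  expect_identical(canonical_key(prod$sequence$bases), canonical_key(expected))
})

test_that("an unfilled slot leaves only the blue religation background", {
  reg <- demo_registry()
  d <- assembly_design("pGGYL1", c("HUH", "PTEF", "ERG10", NA), reg,
                       allow_unfilled = TRUE)
  err <- tryCatch(simulate_assembly(d), yaliclone_assembly_failure = identity)
  expect_s3_class(err, "yaliclone_assembly_failure")
  expect_match(conditionMessage(err), "longest linear extension")
  relig <- Filter(function(s) s$classification == "backbone-religation",
                  err$side_products)
  expect_gt(length(relig), 0L)
  expect_equal(as.character(predict_colony_color(relig[[1]]$sequence)), "blue")
})

test_that("a planted overhang collision produces a detected ambiguity", {
  # doctor the fusion-site table so labels 3 and 5 share a 4-mer: the
  # promoter's right junction can then also close onto the vector body
  tab <- default_overhang_table()
  tab$sequence[tab$label == 5] <- tab$sequence[tab$label == 3]
  cfg <- fixture_config(seed = 4242, overhang_table = tab)
  parts <- list(
    gen_random_part("marker", c(1, 2), cfg, id = "M", recycling = "loxP"),
    gen_random_part("promoter", c(2, 3), cfg, id = "P"),
    gen_random_part("cds", c(3, 4), cfg, id = "C"),
    gen_random_part("terminator", c(4, 5), cfg, id = "T"))
  reg <- ggyl_registry(parts, overhang_table = tab)
  d <- assembly_design("pGGYL1", c("M", "P", "C", "T"), reg)
  prod <- simulate_assembly(d, include_transient = FALSE)
  expect_gt(length(prod$misjoin_flags), 0L)
  # a shorter mis-joined closure exists: marker + promoter circle onto body
  expect_gt(length(prod$side_products), 0L)
  # the false-positive caveat: a misjoin circle without the stuffer is white
  mis <- Filter(function(s) s$classification == "misjoin-circle",
                prod$side_products)
  expect_gt(length(mis), 0L)
  expect_equal(as.character(predict_colony_color(mis[[1]]$sequence)), "white")
})

test_that("brute-force enumeration covers subsets, orders and orientations", {
  # two mutually compatible fragments -> one circle
  a <- sticky_fragment(dna_seq("AATGCCCCCCAGGT"), "AATG", "AGGT", "a")
  b <- sticky_fragment(dna_seq("AGGTGGGGGGAATG"), "AGGT", "AATG", "b")
  circles <- enumerate_products_bruteforce(list(a, b))
  expect_length(circles, 1L)
  expect_equal(seq_length(circles[[1]]$sequence), 14L + 14L - 8L)

  # incompatible ends -> nothing
  c2 <- sticky_fragment(dna_seq("GCTTCCCCTACA"), "GCTT", "TACA", "c")
  expect_length(enumerate_products_bruteforce(list(a, c2)), 0L)

  # a flipped fragment still closes: flip b and let the search reorient it
  circles2 <- enumerate_products_bruteforce(list(a, flip_fragment(b)))
  expect_length(circles2, 1L)
  expect_identical(circles2[[1]]$key, circles[[1]]$key)

  expect_error(enumerate_products_bruteforce(as.list(1:7)), "limited to 6")
})

test_that("graph closure search equals brute force on seeded pools", {
  reg <- demo_registry()
  set.seed(2024)
  designs <- list(
    c("HUH", "PTEF", "ERG10", "TXPR2"),
    c("LEU2", "PGPD", "tHMG1", "TYlCYC1"),
    c("URA3", "PEXP", "MrBBS", "TPOT1"))
  for (ids in designs) {
    d <- design_with_retargeting("pGGYL1", ids, reg)
    pool <- yaliclone:::design_fragment_pool(d)
    # seeded sub-pools of <= 6 fragments, mixing parts, vectors, stuffer
    for (rep in 1:4) {
      sub <- pool[sort(sample(seq_along(pool), sample(3:6, 1)))]
      bf <- enumerate_products_bruteforce(sub)
      gr <- yaliclone:::enumerate_circles(sub, max_pieces = 6)
      expect_identical(circle_keys(sub, gr),
                       sort(vapply(bf, function(x) x$key, character(1))))
    }
  }
})

test_that("10-fragment assembly yields 11 junctions in slot order", {
  reg <- demo_registry()
  ids <- c("HUH", "PTEF", "ERG10", "TXPR2", "PGPD", "ERG13", "TMig1",
           "PGPDin", "IDI", "TLip2")
  d <- design_with_retargeting("pGGYL3", ids, reg)
  prod <- simulate_assembly(d, include_transient = FALSE)
  expect_equal(nrow(prod$junctions), 11L)
  expect_equal(prod$junctions$label, 1:11)
  expect_length(prod$misjoin_flags, 0L)
  expect_equal(nrow(scan_sites(prod$sequence, bsaI())), 0L)
})

test_that("ligation protocol recommendation matches the optimized conditions", {
  p4 <- recommend_protocol(4)
  expect_equal(p4$ligase_units, 600L)
  expect_equal(p4$cycles, 60L)
  p7 <- recommend_protocol(7)
  expect_equal(p7$ligase_units, 1400L)
  expect_equal(p7$cycles, 120L)
  p10 <- recommend_protocol(10)
  expect_equal(p10$ligase_units, 1400L)
  expect_equal(p10$cycles, 120L)
  expect_match(p10$thermal_program$cycle, "37C 3 min / 16C 4 min")
  expect_error(recommend_protocol(1), "2\\.\\.10")
  expect_error(recommend_protocol(11), "2\\.\\.10")
})
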