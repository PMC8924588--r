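test_that("promoter x terminator shuffling enumerates the full product", {
  reg <- demo_registry()
  proms <- names(Filter(function(p) p$role == "promoter" &&
                          is.na(p$variant_of), reg$parts))
  terms <- names(Filter(function(p) p$role == "terminator" &&
                          is.na(p$variant_of), reg$parts))
  spec <- shuffle_spec("pGGYL1",
                       list("HUH", proms, "MrBBS", terms), reg)
  designs <- enumerate_designs(spec)
  expect_equal(nrow(designs), 8L * 9L)  # 72 designs
  expect_equal(anyDuplicated(designs), 0L)
  # deterministic lexicographic order: later slots vary fastest
  expect_equal(designs[1, 2], proms[1])
  expect_equal(designs[2, 4], terms[2])
  expect_equal(designs[10, 2], proms[2])

  # all slots fixed -> a single design
  fixed <- shuffle_spec("pGGYL1", list("HUH", "PGPD", "MrBBS", "TMig1"), reg)
  expect_equal(nrow(enumerate_designs(fixed)), 1L)

  expect_error(shuffle_spec("pGGYL1", list("HUH", "MrBBS", "PGPD", "TMig1"),
                            reg),
               "expects role")
  expect_error(shuffle_spec("pGGYL1", list("HUH", character(), "MrBBS",
                                           "TMig1"), reg),
               "empty candidate list")
})

test_that("three TUs each shuffling two promoters give 2^3 designs", {
  reg <- demo_registry()
  spec <- shuffle_spec("pGGYL3", list(
    "HUH",
    c("PGPD", "PTEF"), "tHMG1", "TMig1",
    c("PGPD", "PTEF"), "ERG12", "TLip1",
    c("PGPD", "PTEF"), "ERG19", "TLip2"), reg)
  designs <- enumerate_designs(spec)
  expect_equal(nrow(designs), 8L)
  expect_equal(anyDuplicated(designs), 0L)
})

test_that("design counts match a naive nested-loop oracle on random specs", {
  reg <- demo_registry()
  proms <- names(Filter(function(p) p$role == "promoter" &&
                          is.na(p$variant_of), reg$parts))
  terms <- names(Filter(function(p) p$role == "terminator" &&
                          is.na(p$variant_of), reg$parts))
  cdss <- names(Filter(function(p) p$role == "cds" &&
                         is.na(p$variant_of), reg$parts))
  set.seed(401)
  for (rep in 1:5) {
    sp <- list("HUH",
               sample(proms, sample(1:4, 1)),
               sample(cdss, sample(1:3, 1)),
               sample(terms, sample(1:4, 1)))
    spec <- shuffle_spec("pGGYL1", sp, reg)
    designs <- enumerate_designs(spec)
    # naive oracle: nested loops
    count <- 0L
    for (a in sp[[2]]) for (b in sp[[3]]) for (d in sp[[4]]) count <- count + 1L
    expect_equal(nrow(designs), count)
  }
})

test_that("round planning maps gene sets to the smallest fitting backbone", {
  reg <- demo_registry()
  sets <- list(c("tHMG1", "ERG12", "ERG19"),
               c("ERG10", "ERG13", "IDI"),
               c("ERG8", "ERG20"))
  plan <- plan_rounds(sets, reg)
  expect_equal(vapply(plan, function(r) r$backbone_id, character(1)),
               c("pGGYL3", "pGGYL3", "pGGYL2"))

  single <- plan_rounds(list("MrBBS"), reg)
  expect_equal(single[[1]]$backbone_id, "pGGYL1")

  expect_error(plan_rounds(list(c("ERG10", "ERG13", "ERG12", "ERG8")), reg),
               "exceeds toolkit capacity")
})

test_that("planned rounds assemble into cassettes with 3, 3 and 2 TUs", {
  reg <- demo_registry()
  sets <- list(c("tHMG1", "ERG12", "ERG19"),
               c("ERG10", "ERG13", "IDI"),
               c("ERG8", "ERG20"))
  plan <- plan_rounds(sets, reg)
  tu_counts <- vapply(plan, function(r) {
    prod <- simulate_assembly(r$design, include_transient = FALSE)
    cassette <- extract_cassette(prod)$cassette
    sum(grepl("^part:cds:", cassette$annotations$label))
  }, integer(1))
  expect_equal(tu_counts, c(3L, 3L, 2L))
})

test_that("titer arithmetic reproduces the published improvement ladder", {
  expect_equal(report_round(fold_change(2.5, 70.6)), 28.2)
  expect_equal(round(fold_change(2.5, 70.6)), 28)             # "28-fold"
  expect_equal(report_round(fold_change(2.5, 242.6)), 97)     # "nearly 97-fold"
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(0, 10), "positive")

  expect_equal(round(percent_increase(70.6, 135.3), 1), 91.6)
  expect_equal(round(percent_increase(135.3, 242.6), 1), 79.3)
  expect_equal(round(percent_increase(242.6, 275.3), 2), 13.48)
  expect_equal(round(percent_increase(275.3, 573.7), 1), 108.4)
  expect_error(percent_increase(0, 1), "positive")

  expect_equal(round(productivity(4400, 168), 1), 26.2)
  expect_equal(productivity(0, 10), 0)
  expect_error(productivity(100, 0), "positive")
})

test_that("metrics are scale invariant", {
  set.seed(402)
  for (rep in 1:10) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 1000); k <- runif(1, 0.1, 50)
    expect_equal(fold_change(k * a, k * b), fold_change(a, b))
    expect_equal(percent_increase(k * a, k * b), percent_increase(a, b))
  }
})

test_that("ladder report tracks best-of-round and cumulative folds", {
  titers <- c(2.5, 70.6, 135.3, 242.6, 275.3, 573.7)
  records <- do.call(rbind, lapply(seq_along(titers), function(r) {
    data.frame(strain = sprintf("LYW%d-%d", r, 1:3), round = r,
               titer = c(titers[r], titers[r] * 0.6, titers[r] * 0.3),
               stringsAsFactors = FALSE)
  }))
  rep <- ladder_report(records)
  expect_equal(rep$titer, titers)
  expect_equal(round(rep$fold_cumulative, 1),
               c(1, 28.2, 54.1, 97.0, 110.1, 229.5))
  expect_equal(round(rep$fold_prev[2], 1), 28.2)

  # order invariance
  shuffled <- records[sample(nrow(records)), ]
  expect_equal(ladder_report(shuffled), rep)

  # ties break by strain id
  tied <- data.frame(strain = c("b", "a"), round = 1, titer = 10)
  expect_equal(ladder_report(tied)$best_strain, "a")

  single <- ladder_report(records[records$round == 1, ])
  expect_equal(single$fold_prev, single$fold_cumulative)

  expect_error(ladder_report(records[0, ]), "empty")
})
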