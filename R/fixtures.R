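#' Configuration for the synthetic demo toolkit
#'
#' The generator emulates the published toolkit's structure with fully
#' synthetic sequences: part lengths are drawn per role (promoters
#' 300-800 nt, CDSs 600-1,800 nt, terminators 100-300 nt, markers
#' 1,000-2,000 nt), GC content within the given bounds, and every part is
#' guaranteed free of BsaI/SwaI sites. The seed fully determines all
#' generated sequences.
#'
#' @param seed Integer master seed.
#' @param promoter_len,cds_len,terminator_len,marker_len Length ranges
#'   (2-vectors, nt).
#' @param gc Two-sided GC-content bounds.
#' @param overhang_table Fusion-site table to build against.
#' @return A `fixture_config`.
#' @export
fixture_config <- function(seed = 1001L,
                           promoter_len = c(300L, 800L),
                           cds_len = c(600L, 1800L),
                           terminator_len = c(100L, 300L),
                           marker_len = c(1000L, 2000L),
                           gc = c(0.35, 0.65),
                           overhang_table = default_overhang_table()) {
  stopifnot(all(promoter_len > 0), all(cds_len > 0), all(terminator_len > 0),
            all(marker_len > 0), gc[1] > 0, gc[2] < 1, gc[1] <= gc[2])
  structure(list(seed = as.integer(seed), promoter_len = promoter_len,
                 cds_len = cds_len, terminator_len = terminator_len,
                 marker_len = marker_len, gc = gc,
                 overhang_table = overhang_table),
            class = "fixture_config")
}

## derived sub-seed, kept inside 32-bit range
sub_seed <- function(config_seed, tag, attempt = 0L) {
  (config_seed %% 100000L) * 21001L + str_hash(tag) %% 1000000L +
    attempt * 7919L
}

random_bases <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## resample until no forbidden motif on either strand
site_free_bases <- function(len, gc) {
  for (i in 1:300) {
    s <- random_bases(len, gc)
    if (!has_forbidden_motif(s)) return(s)
  }
  stop("could not generate a site-free sequence within the retry limit")
}

## random CDS: ATG + sense codons + one stop, site-free, frame-safe
random_cds_bases <- function(len_range) {
  n_codons <- sample(seq(len_range[1] %/% 3L, len_range[2] %/% 3L), 1L)
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(GENETIC_CODE_TABLE), stops)
  for (i in 1:300) {
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    s <- paste(c("ATG", body, "TAA"), collapse = "")
    if (!has_forbidden_motif(s)) return(s)
  }
  stop("could not generate a site-free CDS within the retry limit")
}

#' Generate one random part
#'
#' Deterministic for a given configuration seed, role, and id: the part is
#' sampled within its role's length and GC bounds and rejected until free
#' of BsaI/SwaI sites on both strands. CDSs are built codon-wise (ATG
#' start, sense codons, a single terminal stop), so they translate cleanly
#' and domestication-style reasoning applies. Marker parts get their
#' recycling architecture: loxP-flanked gene, or hisG-URA3-hisG direct
#' repeats, with features annotated.
#'
#' @param role Part role.
#' @param labels Length-2 integer vector `(left, right)` of junction labels.
#' @param config A `fixture_config`.
#' @param id Part id (also seeds the draw).
#' @param recycling For markers: `"loxP"`, `"hisG"` or `NA`.
#' @param attempt Bump to re-draw a fresh sequence for the same id.
#' @return A `ggyl_part`.
#' @export
gen_random_part <- function(role, labels, config = fixture_config(),
                            id = role, recycling = NA_character_,
                            attempt = 0L) {
  role <- match.arg(role, PART_ROLES)
  seed <- sub_seed(config$seed, paste0(role, ":", id), attempt)
  with_seed(seed, {
    gc <- stats::runif(1, config$gc[1], config$gc[2])
    if (role == "cds") {
      insert <- dna_seq(random_cds_bases(config$cds_len), id = id)
    } else if (role == "marker" && identical(recycling, "hisG")) {
      hisg <- site_free_bases(400L, gc)
      ura3 <- random_cds_bases(c(450L, 600L))
      if (has_forbidden_motif(paste0(hisg, ura3, hisg))) {
        return(gen_random_part(role, labels, config, id, recycling,
                               attempt + 1L))
      }
      insert <- dna_seq(paste0(hisg, ura3, hisg), id = id)
      insert <- add_feature(insert, "hisG", 0L, 400L)
      insert <- add_feature(insert, "URA3", 400L, 400L + nchar(ura3))
      insert <- add_feature(insert, "hisG", 400L + nchar(ura3),
                            800L + nchar(ura3))
    } else if (role == "marker") {
      len_range <- config$marker_len
      gene <- random_cds_bases(c(len_range[1] - 68L, len_range[2] - 68L))
      bases <- if (identical(recycling, "loxP")) {
        paste0(LOXP_SEQ, gene, LOXP_SEQ)
      } else gene
      if (has_forbidden_motif(bases)) {
        return(gen_random_part(role, labels, config, id, recycling,
                               attempt + 1L))
      }
      insert <- dna_seq(bases, id = id)
      if (identical(recycling, "loxP")) {
        insert <- add_feature(insert, "loxP", 0L, 34L)
        insert <- add_feature(insert, paste0(id, "_orf"), 34L,
                              34L + nchar(gene))
        insert <- add_feature(insert, "loxP", 34L + nchar(gene),
                              68L + nchar(gene))
      }
    } else {
      len_range <- switch(role, promoter = config$promoter_len,
                          terminator = config$terminator_len,
                          stuffer = c(200L, 400L))
      len <- sample(seq(len_range[1], len_range[2]), 1L)
      insert <- dna_seq(site_free_bases(len, gc), id = id)
    }
    ggyl_part(id, role, insert, labels[1], labels[2], recycling = recycling)
  })
}

## names mirroring the published catalog
DEMO_PROMOTERS <- c("PGPD", "PGPDin", "PEXP", "PTEF", "PTEFin", "PILV5",
                    "PFBAin", "PYAT")
DEMO_TERMINATORS <- c("TMig1", "TLip1", "TLip2", "TScCYC1", "TYlCYC1",
                      "TTEF", "TPOT1", "TAco3", "TXPR2")
DEMO_MARKERS <- c("HUH", "LEU2", "HPH", "NEO", "URA3", "DsdA")

## possible (left, right) junction labels by role across all slot positions
role_label_space <- function() {
  list(marker = list(c(1L, 2L)),
       promoter = list(c(2L, 3L), c(5L, 6L), c(8L, 9L)),
       cds = list(c(3L, 4L), c(6L, 7L), c(9L, 10L)),
       terminator = list(c(4L, 5L), c(7L, 8L), c(10L, 11L)))
}

## scan an 18-nt junction context window for unintended forbidden motifs
junction_window_clean <- function(tail7, oh, head7) {
  !has_forbidden_motif(paste0(tail7, oh, head7))
}

tail_n <- function(part, n) {
  b <- part$insert$bases
  substr(b, max(1L, nchar(b) - n + 1L), nchar(b))
}
head_n <- function(part, n) substr(part$insert$bases, 1L, n)

## donor-plasmid joint contexts for every label a part can carry
bb_joints_clean <- function(part, table) {
  space <- role_label_space()[[part$role]]
  if (is.null(space)) return(TRUE)
  oh <- function(l) table$sequence[table$label == l]
  for (labs in space) {
    left_ctx <- paste0("GGTCTCA", oh(labs[1]), head_n(part, 7L))
    right_ctx <- paste0(tail_n(part, 7L), oh(labs[2]), "AGAGACC")
    if (length(find_fixed(left_ctx, "GGTCTC")) != 1L ||
        length(find_fixed(left_ctx, "GAGACC")) != 0L ||
        length(find_fixed(left_ctx, "ATTTAAAT")) != 0L) return(FALSE)
    if (length(find_fixed(right_ctx, "GAGACC")) != 1L ||
        length(find_fixed(right_ctx, "GGTCTC")) != 0L ||
        length(find_fixed(right_ctx, "ATTTAAAT")) != 0L) return(FALSE)
  }
  TRUE
}

## which parts participate in a dirty product junction, across every
## adjacency the slot grammar allows
junction_offenders <- function(parts_by_role, table, backbones) {
  oh <- function(l) table$sequence[table$label == l]
  offenders <- character()
  pairings <- list(
    list(up = "marker", labels = 2L, down = "promoter"),
    list(up = "promoter", labels = c(3L, 6L, 9L), down = "cds"),
    list(up = "cds", labels = c(4L, 7L, 10L), down = "terminator"),
    list(up = "terminator", labels = c(5L, 8L), down = "promoter")
  )
  for (pr in pairings) {
    for (up in parts_by_role[[pr$up]]) {
      t7 <- tail_n(up, 7L)
      for (lab in pr$labels) {
        for (down in parts_by_role[[pr$down]]) {
          if (!junction_window_clean(t7, oh(lab), head_n(down, 7L))) {
            offenders <- c(offenders, down$id)
          }
        }
      }
    }
  }
  # vector-facing junctions: padC | oh1 | marker and terminator | ohk | padD
  for (bb in backbones) {
    meta <- attr(bb, "backbone_meta")
    layout <- meta$layout
    oh1 <- oh(layout$left_label[1])
    ohk <- oh(layout$right_label[nrow(layout)])
    sites <- scan_sites(bb, bsaI())
    minus <- sites[sites$strand == "-", ]
    plus <- sites[sites$strand == "+", ]
    padC_tail <- subseq_circ(bb$bases, minus$top_cut - 7L, minus$top_cut,
                             circular = TRUE)
    padD_head <- subseq_circ(bb$bases, plus$bottom_cut, plus$bottom_cut + 7L,
                             circular = TRUE)
    for (mk in parts_by_role$marker) {
      if (!junction_window_clean(padC_tail, oh1, head_n(mk, 7L))) {
        offenders <- c(offenders, mk$id)
      }
    }
    for (tm in parts_by_role$terminator) {
      if (!junction_window_clean(tail_n(tm, 7L), ohk, padD_head)) {
        offenders <- c(offenders, tm$id)
      }
    }
  }
  unique(offenders)
}

#' Generate the full synthetic demo toolkit
#'
#' Builds a registry mirroring the published catalog's structure: 8
#' promoters, 9 terminators, the 8 mevalonate-pathway CDSs plus the
#' bisabolol-synthase stand-in `MrBBS`, and 6 selection markers (one
#' hisG-URA3-hisG, five loxP-flanked), together with the three destination
#' vectors and a 5-kb genome stub. Every part validates, every donor
#' plasmid releases its part as exactly two BsaI fragments, and every
#' junction context the slot grammar allows is checked to be free of
#' accidental BsaI/SwaI sites (offending parts are deterministically
#' redrawn), so assembled products are guaranteed scar-free.
#'
#' @param config A `fixture_config`.
#' @return List with `registry` (a `ggyl_registry`) and `genome`
#'   (linear `dna_seq`).
#' @export
gen_demo_toolkit <- function(config = fixture_config()) {
  table <- config$overhang_table
  rep_check <- check_overhang_set(table$sequence)
  if (!rep_check$faithful) {
    stop("overhang table is not faithful: ",
         paste(rep_check$failures, collapse = "; "))
  }
  specs <- list()
  for (nm in DEMO_PROMOTERS) {
    specs[[nm]] <- list(role = "promoter", labels = c(2L, 3L), recycling = NA)
  }
  for (nm in c(mva_genes(), "MrBBS")) {
    specs[[nm]] <- list(role = "cds", labels = c(3L, 4L), recycling = NA)
  }
  for (nm in DEMO_TERMINATORS) {
    specs[[nm]] <- list(role = "terminator", labels = c(4L, 5L), recycling = NA)
  }
  for (nm in DEMO_MARKERS) {
    specs[[nm]] <- list(role = "marker", labels = c(1L, 2L),
                        recycling = if (nm == "HUH") "hisG" else "loxP")
  }

  attempts <- stats::setNames(rep(0L, length(specs)), names(specs))
  gen_one <- function(nm) {
    sp <- specs[[nm]]
    gen_random_part(sp$role, sp$labels, config, id = nm,
                    recycling = sp$recycling, attempt = attempts[[nm]])
  }
  parts <- lapply(stats::setNames(nm = names(specs)), gen_one)

  backbones <- lapply(stats::setNames(nm = c("pGGYL1", "pGGYL2", "pGGYL3")),
                      backbone_plasmid, overhang_table = table)

  # deterministic repair loop: redraw any part implicated in an unclean
  # donor-plasmid joint or product junction
  for (iter in 1:60) {
    bad <- character()
    for (nm in names(parts)) {
      v <- validate_part(parts[[nm]], table)
      if (!v$ok || !bb_joints_clean(parts[[nm]], table)) bad <- c(bad, nm)
    }
    if (!length(bad)) {
      by_role <- split(parts, vapply(parts, function(p) p$role, character(1)))
      bad <- junction_offenders(by_role, table, backbones)
    }
    if (!length(bad)) break
    for (nm in bad) {
      attempts[[nm]] <- attempts[[nm]] + 1L
      parts[[nm]] <- gen_one(nm)
    }
  }
  if (iter == 60L) stop("toolkit generation did not converge")

  genome <- with_seed(sub_seed(config$seed, "genome"), {
    dna_seq(random_bases(5000L, 0.5), id = "genome_stub")
  })
  list(registry = ggyl_registry(parts, overhang_table = table,
                                backbones = backbones),
       genome = genome)
}
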