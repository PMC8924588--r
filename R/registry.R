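## roles a part may take and the genes of the mevalonate pathway set
PART_ROLES <- c("marker", "promoter", "cds", "terminator", "stuffer")

#' Mevalonate-pathway gene identifiers carried by the default catalog
#' @return Character vector of the eight MVA gene names.
#' @export
mva_genes <- function() {
  c("tHMG1", "IDI", "ERG8", "ERG10", "ERG12", "ERG13", "ERG19", "ERG20")
}

# default colony-PCR verification primers; they bind the destination vector
# outside the SwaI sites, so amplicons span the whole assembled region
PRIMER_F_DEFAULT <- "TCTCCCCGCGCGTTGGCCGATT"
PRIMER_R_DEFAULT <- "GTCTCGCGCGTTTCGGTGATG"

# canonical 34-nt loxP site (configurable in the recycling operations)
LOXP_SEQ <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"

## evaluate expr under a fixed RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 17
  for (x in v) h <- (h * 31 + x) %% 2147480009
  as.integer(h)
}

FORBIDDEN_MOTIFS <- c("GGTCTC", "GAGACC", "ATTTAAAT")

has_forbidden_motif <- function(bases) {
  any(vapply(FORBIDDEN_MOTIFS, function(m) grepl(m, bases, fixed = TRUE),
             logical(1)))
}

## deterministic site-free filler sequence (placeholder vector elements)
placeholder_seq <- function(len, seed, gc = 0.5) {
  with_seed(seed, {
    for (try in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                 collapse = "")
      if (!has_forbidden_motif(s)) return(s)
    }
    stop("could not generate a site-free placeholder")
  })
}

#' Construct a typed part
#'
#' A part is a DNA module (selection marker, promoter, CDS, terminator, or
#' stuffer) together with the numeric junction labels it is cloned between.
#' Validity (no internal BsaI/SwaI sites, distinct labels) is checked by
#' [validate_part()].
#'
#' @param id Part identifier.
#' @param role One of `marker`, `promoter`, `cds`, `terminator`, `stuffer`.
#' @param insert Linear `dna_seq`.
#' @param left_label,right_label Overhang labels (integers into the table).
#' @param recycling `NA`, `"loxP"` (Cre-excisable marker) or `"hisG"`
#'   (direct-repeat pop-out marker).
#' @param variant_of For slot-retargeted copies, the base part id.
#' @return A `ggyl_part`.
#' @export
ggyl_part <- function(id, role, insert, left_label, right_label,
                      recycling = NA_character_, variant_of = NA_character_) {
  role <- match.arg(role, PART_ROLES)
  stopifnot(inherits(insert, "dna_seq"), !is_circular(insert))
  structure(list(id = id, role = role, insert = insert,
                 left_label = as.integer(left_label),
                 right_label = as.integer(right_label),
                 recycling = recycling, variant_of = variant_of),
            class = "ggyl_part")
}

#' @export
print.ggyl_part <- function(x, ...) {
  cat(sprintf("<ggyl_part %s> %s, %d bp, junctions %d-%d%s\n", x$id, x$role,
              seq_length(x$insert), x$left_label, x$right_label,
              if (!is.na(x$recycling)) paste0(", recycling ", x$recycling) else ""))
  invisible(x)
}

#' Re-label a part for a different slot position
#'
#' The physical toolkit stores one donor plasmid per slot position: reusing
#' a promoter in transcription unit 2 means re-cloning the same insert
#' between that slot's junctions. This returns such a re-labelled copy
#' (id suffixed, `variant_of` set).
#'
#' @param part A `ggyl_part`.
#' @param left_label,right_label New junction labels.
#' @return A `ggyl_part` variant.
#' @export
retarget_part <- function(part, left_label, right_label) {
  if (part$left_label == left_label && part$right_label == right_label) {
    return(part)
  }
  base_id <- if (is.na(part$variant_of)) part$id else part$variant_of
  ggyl_part(sprintf("%s@%d-%d", base_id, left_label, right_label), part$role,
            part$insert, left_label, right_label, recycling = part$recycling,
            variant_of = base_id)
}

#' Validate a part against the toolkit grammar
#'
#' A usable part must be free of internal BsaI and SwaI recognition sites on
#' either strand (otherwise the one-pot reaction cuts inside it), must use
#' known junction labels, and must not carry the same label on both ends
#' (such a part ligates head-to-tail with itself and self-circularizes).
#'
#' @param part A `ggyl_part`.
#' @param overhang_table Overhang table (defaults to the shipped one).
#' @return List with `ok` and a character vector of `violations`.
#' @export
validate_part <- function(part, overhang_table = default_overhang_table()) {
  stopifnot(inherits(part, "ggyl_part"))
  violations <- character()
  for (enz in list(bsaI(), swaI())) {
    sites <- scan_sites(part$insert, enz)
    if (nrow(sites)) {
      violations <- c(violations, sprintf(
        "internal %s site at position %d (%s strand)", enz$name,
        sites$position, sites$strand))
    }
  }
  for (lab in c(part$left_label, part$right_label)) {
    if (!lab %in% overhang_table$label) {
      violations <- c(violations, sprintf("unknown overhang label %d", lab))
    }
  }
  if (part$left_label == part$right_label) {
    violations <- c(violations,
                    sprintf("self-circularizing part: left label equals right label (%d)",
                            part$left_label))
  }
  list(ok = length(violations) == 0L, violations = violations)
}

#' Slot layout of a destination vector
#'
#' pGGYL1 holds one transcription unit (4 fragments: marker, promoter, CDS,
#' terminator), pGGYL2 two (7 fragments) and pGGYL3 three (10 fragments).
#' Junction labels run left to right around the maximal design; adjacent
#' slots share a label, the marker-side vector junction is label 1, and the
#' terminator-side closing junction is label 5, 8, or 11.
#'
#' @param backbone_id `"pGGYL1"`, `"pGGYL2"` or `"pGGYL3"`.
#' @return Data frame with columns `slot`, `role`, `left_label`,
#'   `right_label`.
#' @export
slot_layout <- function(backbone_id) {
  n_tu <- switch(backbone_id, pGGYL1 = 1L, pGGYL2 = 2L, pGGYL3 = 3L,
                 stop(sprintf("unknown backbone '%s' (expected pGGYL1-3)",
                              backbone_id)))
  roles <- c("marker", rep(c("promoter", "cds", "terminator"), n_tu))
  k <- length(roles)
  data.frame(slot = seq_len(k), role = roles, left_label = seq_len(k),
             right_label = seq_len(k) + 1L, stringsAsFactors = FALSE)
}

#' Construct a building-block (donor) plasmid around a part
#'
#' The insert sits between two inward-pointing BsaI sites arranged so that
#' digestion releases exactly `overhang_left + insert + overhang_right`,
#' with both recognition sites retained on the vector fragment. The vector
#' stub is a deterministic site-free placeholder.
#'
#' @param part A `ggyl_part`.
#' @param overhang_table Overhang table.
#' @return A circular `dna_seq` (id `pBB-<part id>`), with features
#'   `bb_vector` and `part:<id>`.
#' @export
building_block_plasmid <- function(part, overhang_table = default_overhang_table()) {
  oh <- function(lab) {
    s <- overhang_table$sequence[overhang_table$label == lab]
    if (!length(s)) stop(sprintf("label %d not in overhang table", lab))
    s
  }
  ohl <- oh(part$left_label)
  ohr <- oh(part$right_label)
  ins <- part$insert$bases
  id <- sprintf("pBB-%s", part$id)
  for (attempt in 1:50) {
    stub <- placeholder_seq(150L, str_hash(id) + attempt)
    bases <- paste0(stub, "GGTCTC", "A", ohl, ins, ohr, "A", "GAGACC")
    pl <- dna_seq(bases, "circular", id = id)
    if (nrow(scan_sites(pl, bsaI())) == 2L &&
        nrow(scan_sites(pl, swaI())) == 0L) {
      stub_len <- nchar(stub)
      ins_start <- stub_len + 11L  # stub + GGTCTC + A + 4-nt overhang
      pl <- add_feature(pl, "bb_vector", 0L, stub_len)
      pl <- add_feature(pl, sprintf("part:%s:%s", part$role, part$id),
                        ins_start, ins_start + nchar(ins))
      ia <- part$insert$annotations
      if (nrow(ia)) {
        ia$start <- ia$start + ins_start
        ia$end <- ia$end + ins_start
        pl$annotations <- rbind(pl$annotations, ia)
      }
      return(pl)
    }
  }
  stop(sprintf("could not build a two-site donor plasmid for part '%s' %s",
               part$id,
               "(insert/overhang joints recreate a forbidden site)"))
}

#' Construct a destination vector (backbone plasmid)
#'
#' Circular plasmid carrying, in order: an ori placeholder, a kanR
#' placeholder, the forward verification-primer site, a SwaI site, the lacZ
#' stuffer between two BsaI sites pointing away from the vector body (so
#' digestion hands the vector fragment the backbone's two junction
#' overhangs and discards both recognition sites with the stuffer), the
#' second SwaI site, and the reverse-primer site. The two SwaI sites
#' bracket the whole slot region and nothing of the vector body.
#'
#' @param backbone_id `"pGGYL1"`, `"pGGYL2"` or `"pGGYL3"`.
#' @param overhang_table Overhang table.
#' @return A circular annotated `dna_seq`.
#' @export
backbone_plasmid <- function(backbone_id,
                             overhang_table = default_overhang_table()) {
  layout <- slot_layout(backbone_id)
  oh <- function(lab) overhang_table$sequence[overhang_table$label == lab]
  oh1 <- oh(layout$left_label[1])
  ohk <- oh(layout$right_label[nrow(layout)])
  rprimer_site <- rc_string(PRIMER_R_DEFAULT)

  for (attempt in 1:50) {
    h <- str_hash(backbone_id) + attempt
    ori <- placeholder_seq(150L, h + 1L)
    kanr <- placeholder_seq(210L, h + 2L)
    lacz <- placeholder_seq(300L, h + 3L)
    padA <- placeholder_seq(20L, h + 4L)
    padB <- placeholder_seq(10L, h + 5L)
    padC <- placeholder_seq(10L, h + 6L)
    padD <- placeholder_seq(10L, h + 7L)
    padE <- placeholder_seq(10L, h + 8L)

    segs <- list(
      ori = ori, kanR = kanr, padA = padA, primer_F = PRIMER_F_DEFAULT,
      padB = padB, SwaI_up = "ATTTAAAT", padC = padC,
      oh1 = oh1, spacer1 = "A", bsa_rev = "GAGACC",
      lacZ_stuffer = lacz,
      bsa_fwd = "GGTCTC", spacer2 = "A", ohk = ohk,
      padD = padD, SwaI_down = "ATTTAAAT", padE = padE,
      primer_R = rprimer_site
    )
    bases <- paste(unlist(segs), collapse = "")
    pl <- dna_seq(bases, "circular", id = backbone_id)
    if (nrow(scan_sites(pl, bsaI())) != 2L ||
        nrow(scan_sites(pl, swaI())) != 2L) next

    pos <- 0L
    for (nm in names(segs)) {
      len <- nchar(segs[[nm]])
      lab <- switch(nm, SwaI_up = "SwaI", SwaI_down = "SwaI", nm)
      if (nm %in% c("ori", "kanR", "primer_F", "SwaI_up", "lacZ_stuffer",
                    "SwaI_down", "primer_R")) {
        strand <- if (nm == "primer_R") "-" else "+"
        pl <- add_feature(pl, lab, pos, pos + len, strand = strand)
      }
      pos <- pos + len
    }
    attr(pl, "backbone_meta") <- list(id = backbone_id, layout = layout,
                                      overhang_table = overhang_table)
    return(pl)
  }
  stop(sprintf("could not build backbone '%s'", backbone_id))
}

#' Assemble a registry catalog object
#'
#' @param parts Named list of `ggyl_part`.
#' @param overhang_table Overhang table.
#' @param backbones Optional named list of backbone plasmids; built from the
#'   table when omitted.
#' @return A `ggyl_registry`.
#' @export
ggyl_registry <- function(parts, overhang_table = default_overhang_table(),
                          backbones = NULL) {
  if (is.null(backbones)) {
    backbones <- lapply(stats::setNames(nm = c("pGGYL1", "pGGYL2", "pGGYL3")),
                        backbone_plasmid, overhang_table = overhang_table)
  }
  names(parts) <- vapply(parts, function(p) p$id, character(1))
  structure(list(overhangs = overhang_table, parts = parts,
                 backbones = backbones),
            class = "ggyl_registry")
}

#' Count catalog parts by role
#'
#' Slot-retargeted variants (`variant_of` set) are position re-clones of an
#' existing insert and are excluded from the counts.
#'
#' @param registry A `ggyl_registry`.
#' @return Named integer vector over roles, plus `mva_cds` (how many of the
#'   CDS entries belong to the mevalonate pathway set).
#' @export
role_counts <- function(registry) {
  stopifnot(inherits(registry, "ggyl_registry"))
  base <- Filter(function(p) is.na(p$variant_of), registry$parts)
  roles <- vapply(base, function(p) p$role, character(1))
  counts <- vapply(stats::setNames(nm = PART_ROLES),
                   function(r) sum(roles == r), integer(1))
  ids <- vapply(base, function(p) p$id, character(1))
  c(counts, mva_cds = sum(ids %in% mva_genes() & roles == "cds"))
}

#' @export
print.ggyl_registry <- function(x, ...) {
  rc <- role_counts(x)
  cat(sprintf("<ggyl_registry> %d parts (%s), %d backbones, %d overhangs\n",
              length(x$parts),
              paste(sprintf("%s=%d", names(rc), rc), collapse = ", "),
              length(x$backbones), nrow(x$overhangs)))
  invisible(x)
}

#' Load a registry from a catalog table plus sequence records
#'
#' The catalog (data frame, TSV path, or JSON path) has columns `id`,
#' `role`, `left_label`, `right_label`, `recycling`, `sequence_ref`;
#' sequences come as a named list of `dna_seq` or a FASTA path. Loading is
#' atomic: every violation across all rows (missing sequence, unknown role,
#' duplicate id, part-validation failures) is collected and reported in one
#' error.
#'
#' @param catalog Catalog table or path.
#' @param sequences Named `dna_seq` list or FASTA path.
#' @param overhang_table Overhang table.
#' @return A `ggyl_registry`.
#' @export
load_registry <- function(catalog, sequences,
                          overhang_table = default_overhang_table()) {
  if (is.character(catalog)) {
    catalog <- if (grepl("\\.json$", catalog, ignore.case = TRUE)) {
      as.data.frame(jsonlite::fromJSON(catalog), stringsAsFactors = FALSE)
    } else {
      utils::read.delim(catalog, stringsAsFactors = FALSE)
    }
  }
  if (is.character(sequences)) sequences <- read_fasta(sequences)
  if (nrow(catalog) == 0L) {
    return(ggyl_registry(list(), overhang_table = overhang_table))
  }
  required <- c("id", "role", "left_label", "right_label", "sequence_ref")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols)) {
    stop("catalog missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"recycling" %in% names(catalog)) catalog$recycling <- NA_character_
  if (!"variant_of" %in% names(catalog)) catalog$variant_of <- NA_character_

  errors <- character()
  dup <- unique(catalog$id[duplicated(catalog$id)])
  for (d in dup) errors <- c(errors, sprintf("duplicate part id '%s'", d))

  parts <- list()
  for (i in seq_len(nrow(catalog))) {
    row <- catalog[i, ]
    if (!row$role %in% PART_ROLES) {
      errors <- c(errors, sprintf("part '%s': unknown role '%s'", row$id, row$role))
      next
    }
    if (!row$sequence_ref %in% names(sequences)) {
      errors <- c(errors, sprintf("part '%s': missing sequence record '%s'",
                                  row$id, row$sequence_ref))
      next
    }
    rec <- if (is.na(row$recycling) || row$recycling == "") NA_character_ else row$recycling
    vof <- if (is.na(row$variant_of) || row$variant_of == "") NA_character_ else row$variant_of
    p <- ggyl_part(row$id, row$role, sequences[[row$sequence_ref]],
                   row$left_label, row$right_label, recycling = rec,
                   variant_of = vof)
    v <- validate_part(p, overhang_table)
    if (!v$ok) {
      errors <- c(errors, sprintf("part '%s': %s", row$id,
                                  paste(v$violations, collapse = "; ")))
      next
    }
    parts[[row$id]] <- p
  }
  if (length(errors)) {
    stop("registry load failed:\n  ", paste(errors, collapse = "\n  "))
  }
  ggyl_registry(parts, overhang_table = overhang_table)
}

#' Serialize a registry to a directory (catalog TSV + FASTA)
#'
#' [load_registry()] on the written files reproduces the catalog
#' (idempotent round trip).
#'
#' @param registry A `ggyl_registry`.
#' @param dir Output directory (created if absent).
#' @return Invisible list with the written paths.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "ggyl_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- do.call(rbind, lapply(registry$parts, function(p) {
    data.frame(id = p$id, role = p$role, left_label = p$left_label,
               right_label = p$right_label,
               recycling = ifelse(is.na(p$recycling), "", p$recycling),
               variant_of = ifelse(is.na(p$variant_of), "", p$variant_of),
               sequence_ref = p$id, stringsAsFactors = FALSE)
  }))
  catalog_path <- file.path(dir, "catalog.tsv")
  utils::write.table(catalog, catalog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- lapply(registry$parts, function(p) {
    s <- p$insert; s$id <- p$id; s
  })
  fasta_path <- file.path(dir, "parts.fasta")
  write_fasta(seqs, fasta_path)
  invisible(list(catalog = catalog_path, fasta = fasta_path))
}
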