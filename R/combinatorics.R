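#' Specify a combinatorial shuffling library
#'
#' Each slot of the chosen destination vector gets a candidate part list
#' (a single id for a fixed slot, several for a shuffled one). Candidate
#' roles must match the slot roles; no list may be empty.
#'
#' @param backbone_id Destination vector id.
#' @param slot_candidates List (length = slot count) of character vectors of
#'   part ids.
#' @param registry A `ggyl_registry`.
#' @return A `shuffle_spec`.
#' @export
shuffle_spec <- function(backbone_id, slot_candidates, registry) {
  layout <- slot_layout(backbone_id)
  if (length(slot_candidates) != nrow(layout)) {
    stop(sprintf("%s has %d slots; %d candidate lists given", backbone_id,
                 nrow(layout), length(slot_candidates)))
  }
  for (i in seq_along(slot_candidates)) {
    cands <- slot_candidates[[i]]
    if (!length(cands)) stop(sprintf("slot %d has an empty candidate list", i))
    for (pid in cands) {
      part <- registry$parts[[pid]]
      if (is.null(part)) stop(sprintf("part '%s' not in registry", pid))
      if (part$role != layout$role[i]) {
        stop(sprintf("slot %d expects role '%s'; candidate '%s' is a %s", i,
                     layout$role[i], pid, part$role))
      }
    }
  }
  structure(list(backbone_id = backbone_id, slot_candidates = slot_candidates,
                 registry = registry, layout = layout),
            class = "shuffle_spec")
}

#' Enumerate every design of a shuffling library
#'
#' Full Cartesian product over the candidate lists, in deterministic
#' lexicographic order (later slots vary fastest; candidates in list
#' order). The count equals the product of the list sizes.
#'
#' @param spec A `shuffle_spec`.
#' @param build If `TRUE`, return validated `assembly_design` objects
#'   (parts are retargeted to their slot junctions as needed); otherwise a
#'   data frame of id combinations.
#' @return List of designs or a data frame.
#' @export
enumerate_designs <- function(spec, build = FALSE) {
  stopifnot(inherits(spec, "shuffle_spec"))
  sizes <- lengths(spec$slot_candidates)
  total <- prod(sizes)
  k <- length(sizes)
  # odometer with the last slot fastest => lexicographic over slot order
  combos <- vector("list", total)
  idx <- rep(1L, k)
  for (r in seq_len(total)) {
    combos[[r]] <- vapply(seq_len(k), function(i)
      spec$slot_candidates[[i]][idx[i]], character(1))
    j <- k
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j - 1L
    }
  }
  if (!build) {
    df <- as.data.frame(do.call(rbind, combos), stringsAsFactors = FALSE)
    names(df) <- sprintf("slot%d_%s", seq_len(k), spec$layout$role)
    return(df)
  }
  lapply(combos, function(ids) {
    design_with_retargeting(spec$backbone_id, ids, spec$registry)
  })
}

#' Build a design, retargeting parts to their slot junctions as needed
#'
#' Convenience wrapper around [assembly_design()]: any part whose junction
#' labels differ from its assigned slot is re-cloned via [retarget_part()]
#' and the variant is added to a working copy of the registry.
#'
#' @param backbone_id Destination vector id.
#' @param part_ids Part ids in slot order.
#' @param registry A `ggyl_registry`.
#' @return An `assembly_design`.
#' @export
design_with_retargeting <- function(backbone_id, part_ids, registry) {
  layout <- slot_layout(backbone_id)
  stopifnot(length(part_ids) == nrow(layout))
  reg <- registry
  ids <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    part <- reg$parts[[part_ids[i]]]
    if (is.null(part)) stop(sprintf("part '%s' not in registry", part_ids[i]))
    v <- retarget_part(part, layout$left_label[i], layout$right_label[i])
    if (!v$id %in% names(reg$parts)) reg$parts[[v$id]] <- v
    ids[i] <- v$id
  }
  assembly_design(backbone_id, ids, reg)
}

#' Plan a multi-round pathway build
#'
#' Splits a pathway into per-round gene sets and maps each set to the
#' smallest destination vector that fits it: a marker plus k transcription
#' units needs 1 + 3k fragments, so 1, 2 and 3 TU sets go to pGGYL1,
#' pGGYL2 and pGGYL3. Each round's transcription units are assembled
#' slot-positionally from the supplied promoter/terminator assignments (or
#' cycled from the registry catalog when omitted), with gene order
#' following the input order.
#'
#' @param pathway_sets List of character vectors of CDS part ids (1-3 genes
#'   per set), or of data frames with columns `promoter`, `cds`,
#'   `terminator`.
#' @param registry A `ggyl_registry`.
#' @param markers Character vector of marker part ids, one per round
#'   (recycled cyclically when shorter). Defaults to the registry's
#'   recyclable markers.
#' @return A `round_plan`: list of rounds, each with `backbone_id`,
#'   `design` (an `assembly_design`) and `genes`.
#' @export
plan_rounds <- function(pathway_sets, registry, markers = NULL) {
  stopifnot(inherits(registry, "ggyl_registry"))
  base_parts <- Filter(function(p) is.na(p$variant_of), registry$parts)
  by_role <- function(r) names(Filter(function(p) p$role == r, base_parts))
  if (is.null(markers)) {
    rec <- names(Filter(function(p) !is.na(p$recycling), base_parts))
    if (!length(rec)) stop("registry has no recyclable markers")
    markers <- rec
  }
  promoters <- by_role("promoter")
  terminators <- by_role("terminator")

  rounds <- list()
  for (r in seq_along(pathway_sets)) {
    set <- pathway_sets[[r]]
    if (is.data.frame(set)) {
      genes <- set$cds
      proms <- set$promoter
      terms <- set$terminator
    } else {
      genes <- set
      proms <- promoters[((seq_along(genes) - 1L) %% length(promoters)) + 1L]
      terms <- terminators[((seq_along(genes) - 1L) %% length(terminators)) + 1L]
    }
    k <- length(genes)
    if (k < 1L) stop(sprintf("round %d: empty gene set", r))
    if (k > 3L) {
      stop(sprintf("round %d: %d transcription units exceeds toolkit capacity (max 3)",
                   r, k))
    }
    for (g in c(genes, proms, terms)) {
      if (!g %in% names(registry$parts)) {
        stop(sprintf("round %d: part '%s' not in registry", r, g))
      }
    }
    backbone_id <- c("pGGYL1", "pGGYL2", "pGGYL3")[k]
    marker <- markers[((r - 1L) %% length(markers)) + 1L]
    # marker reuse across rounds requires recyclability
    if (r > length(markers)) {
      mk <- registry$parts[[marker]]
      if (is.na(mk$recycling)) {
        stop(sprintf("round %d reuses marker '%s', which is not recyclable",
                     r, marker))
      }
    }
    ids <- c(marker, as.vector(rbind(proms, genes, terms)))
    design <- design_with_retargeting(backbone_id, ids, registry)
    rounds[[r]] <- list(round = r, backbone_id = backbone_id, design = design,
                        genes = genes, marker = marker)
  }
  structure(rounds, class = "round_plan")
}

#' @export
print.round_plan <- function(x, ...) {
  for (r in x) {
    cat(sprintf("round %d: %s  [%s]  marker %s\n", r$round, r$backbone_id,
                paste(r$genes, collapse = ", "), r$marker))
  }
  invisible(x)
}

#' Fold change of a titer over a baseline
#' @param baseline,value Titers (mg/L); baseline must be positive.
#' @return `value / baseline` (dimensionless).
#' @examples fold_change(2.5, 70.6)
#' @export
fold_change <- function(baseline, value) {
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    stop("baseline must be positive")
  }
  value / baseline
}

#' Percent increase of b over a
#' @param a,b Titers (mg/L); `a` must be positive.
#' @return `(b/a - 1) * 100`.
#' @examples percent_increase(70.6, 135.3)
#' @export
percent_increase <- function(a, b) {
  if (!is.numeric(a) || any(a <= 0)) stop("baseline must be positive")
  (b / a - 1) * 100
}

#' Volumetric productivity
#' @param titer Final titer (mg/L).
#' @param time Fermentation time (h); must be positive.
#' @return Productivity in mg per litre per hour.
#' @examples productivity(4400, 168)
#' @export
productivity <- function(titer, time) {
  if (!is.numeric(time) || any(time <= 0)) stop("time must be positive")
  titer / time
}

#' Strain-improvement ladder report
#'
#' From a ledger of (strain, round, titer) records, reports each round's
#' best strain (ties broken by strain id), the fold improvement over the
#' previous round's best, and the cumulative fold over the first round's
#' best. The report is invariant to input row order.
#'
#' @param records Data frame with columns `strain`, `round`, `titer`
#'   (mg/L) and optionally `yield` (mg/g DCW) and `time` (h).
#' @return Data frame `round`, `best_strain`, `titer`, `fold_prev`,
#'   `fold_cumulative`.
#' @export
ladder_report <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("strain", "round", "titer") %in% names(records)))
  if (!nrow(records)) stop("empty ledger")
  if (any(records$titer <= 0)) stop("titers must be positive")
  rounds <- sort(unique(records$round))
  rows <- lapply(rounds, function(r) {
    sub <- records[records$round == r, , drop = FALSE]
    sub <- sub[order(-sub$titer, sub$strain), , drop = FALSE]
    sub[1, c("strain", "round", "titer")]
  })
  best <- do.call(rbind, rows)
  baseline <- best$titer[1]
  prev <- c(NA_real_, best$titer[-nrow(best)])
  data.frame(round = best$round, best_strain = best$strain,
             titer = best$titer,
             fold_prev = ifelse(is.na(prev), 1, best$titer / prev),
             fold_cumulative = best$titer / baseline,
             stringsAsFactors = FALSE)
}

#' Round a fold or percentage the way the reports print it
#'
#' Folds print to one decimal, collapsing to an integer when within 0.05
#' of one; percentages print to one decimal by default.
#'
#' @param x Numeric value.
#' @param digits Decimals for the general case.
#' @return Numeric rounded value.
#' @export
report_round <- function(x, digits = 1) {
  r <- round(x, digits)
  near_int <- abs(x - round(x)) <= 0.05
  ifelse(near_int, round(x), r)
}
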