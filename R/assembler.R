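#' Specify a Golden Gate assembly design
#'
#' Maps each slot of a destination vector to a part id from the registry.
#' Validation is strict: every slot must be filled (unless
#' `allow_unfilled = TRUE`, used to study failure modes), the assigned
#' part's role must equal the slot role, and its junction labels must equal
#' the slot's labels (use [retarget_part()] to re-clone a part into another
#' slot position).
#'
#' @param backbone_id `"pGGYL1"`, `"pGGYL2"` or `"pGGYL3"`.
#' @param assignments Character vector of part ids in slot order (or named
#'   by slot number).
#' @param registry A `ggyl_registry`.
#' @param allow_unfilled Permit `NA` slots.
#' @return An `assembly_design`.
#' @export
assembly_design <- function(backbone_id, assignments, registry,
                            allow_unfilled = FALSE) {
  layout <- slot_layout(backbone_id)
  k <- nrow(layout)
  if (!is.null(names(assignments)) && all(names(assignments) != "")) {
    full <- rep(NA_character_, k)
    full[as.integer(names(assignments))] <- assignments
    assignments <- full
  }
  if (length(assignments) != k) {
    stop(sprintf("%s has %d slots; %d assignments given", backbone_id, k,
                 length(assignments)))
  }
  for (i in seq_len(k)) {
    pid <- assignments[i]
    if (is.na(pid)) {
      if (!allow_unfilled) stop(sprintf("slot %d is unfilled", i))
      next
    }
    part <- registry$parts[[pid]]
    if (is.null(part)) stop(sprintf("part '%s' not in registry", pid))
    if (part$role != layout$role[i]) {
      stop(sprintf("slot %d expects role '%s' but part '%s' is a %s", i,
                   layout$role[i], pid, part$role))
    }
    if (part$left_label != layout$left_label[i] ||
        part$right_label != layout$right_label[i]) {
      stop(sprintf(
        "slot %d expects junctions %d-%d but part '%s' carries %d-%d (use retarget_part)",
        i, layout$left_label[i], layout$right_label[i], pid,
        part$left_label, part$right_label))
    }
  }
  structure(list(backbone_id = backbone_id, assignments = assignments,
                 registry = registry, layout = layout),
            class = "assembly_design")
}

#' @export
print.assembly_design <- function(x, ...) {
  cat(sprintf("<assembly_design %s> %s\n", x$backbone_id,
              paste(ifelse(is.na(x$assignments), "-", x$assignments),
                    collapse = " | ")))
  invisible(x)
}

## digest every input plasmid of a design into the one-pot fragment pool
design_fragment_pool <- function(design) {
  reg <- design$registry
  pool <- digest(reg$backbones[[design$backbone_id]], bsaI())
  for (pid in design$assignments) {
    if (is.na(pid)) next
    bb <- building_block_plasmid(reg$parts[[pid]], reg$overhangs)
    pool <- c(pool, digest(bb, bsaI()))
  }
  pool
}

## orientation helpers over the fragment pool
arc_ends <- function(frag, orient) {
  if (orient > 0) c(frag$left_overhang, frag$right_overhang)
  else c(rc_string(frag$right_overhang), rc_string(frag$left_overhang))
}

## build the circular product of an oriented fragment cycle
circle_product <- function(frags, path, id = NA_character_) {
  oriented <- lapply(seq_len(nrow(path)), function(i) {
    f <- frags[[path$idx[i]]]
    if (path$orient[i] > 0) f else flip_fragment(f)
  })
  ligate_fragments(oriented, circularize = TRUE, id = id)
}

## lexicographically least rotation, by iterative candidate refinement
least_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  d <- paste0(s, s)
  chars <- strsplit(d, "", fixed = TRUE)[[1]]
  cand <- which(chars[1:n] == min(chars[1:n]))
  depth <- 1L
  while (length(cand) > 1L && depth < n) {
    nxt <- chars[cand + depth]
    cand <- cand[nxt == min(nxt)]
    depth <- depth + 1L
  }
  substr(d, cand[1], cand[1] + n - 1L)
}

## canonical representative of a circular sequence, invariant to rotation
## and to which strand is read
canonical_circle_key <- function(bases) {
  min(least_rotation(bases), least_rotation(rc_string(bases)))
}

## cheap canonical key of a fragment cycle: minimal rotation of the
## (idx, orient) token ring, also considering the mirror traversal
canonical_path_key <- function(idx, orient) {
  k <- length(idx)
  reps <- character(0)
  tok_f <- sprintf("%d:%d", idx, orient)
  tok_m <- sprintf("%d:%d", rev(idx), -rev(orient))
  for (tok in list(tok_f, tok_m)) {
    for (r in seq_len(k)) {
      rot <- c(tok[r:k], if (r > 1L) tok[seq_len(r - 1L)])
      reps <- c(reps, paste(rot, collapse = ","))
    }
  }
  min(reps)
}

## enumerate simple fragment cycles (each physical fragment used at most
## once, consecutive normalized overhangs equal). `anchor`: only cycles
## through that fragment index. Returns list of data.frames (idx, orient).
enumerate_circles <- function(frags, max_pieces = 12L, anchor = NULL) {
  n <- length(frags)
  sticky <- vapply(frags, function(f) {
    nchar(f$left_overhang) > 0L && nchar(f$right_overhang) > 0L && !f$circular
  }, logical(1))
  results <- list()
  keys <- character()
  longest <- integer()

  starts <- if (is.null(anchor)) which(sticky) else anchor
  for (start in starts) {
    if (!sticky[start]) next
    for (so in if (is.null(anchor)) c(1L, -1L) else 1L) {
      ends0 <- arc_ends(frags[[start]], so)
      used <- rep(FALSE, n)
      used[start] <- TRUE
      path_idx <- start
      path_or <- so

      recurse <- function(cur_right, depth) {
        if (depth > length(longest)) longest <<- path_idx
        # close the circle?
        if (identical(cur_right, ends0[1])) {
          key <- canonical_path_key(path_idx, path_or)
          if (!key %in% keys) {
            keys <<- c(keys, key)
            results[[length(results) + 1L]] <<-
              data.frame(idx = path_idx, orient = path_or)
          }
        }
        if (depth >= max_pieces) return(invisible())
        for (j in seq_len(n)) {
          if (used[j] || !sticky[j]) next
          if (is.null(anchor) && j < start) next  # min-index start dedup
          for (o in c(1L, -1L)) {
            ej <- arc_ends(frags[[j]], o)
            if (!identical(ej[1], cur_right)) next
            used[j] <<- TRUE
            path_idx <<- c(path_idx, j)
            path_or <<- c(path_or, o)
            recurse(ej[2], depth + 1L)
            used[j] <<- FALSE
            path_idx <<- path_idx[-length(path_idx)]
            path_or <<- path_or[-length(path_or)]
          }
        }
        invisible()
      }
      recurse(ends0[2], 1L)
    }
  }
  attr(results, "longest_path") <- longest
  results
}

#' Simulate a one-pot Golden Gate reaction
#'
#' Digests the destination vector and every assigned donor plasmid with
#' BsaI, then searches the sticky-fragment pool for circular closures in
#' which each physical fragment is used at most once and every junction
#' joins equal normalized 4-nt overhangs. The intended product is the
#' closure consisting of the vector-body fragment plus the assigned parts
#' in slot order; it is returned with its ordered junction report and a
#' colony-colour call. All other closures (up to `max_side_pieces`
#' fragments, deduplicated by canonical rotation/reflection) are reported
#' as side products: the vector-stuffer religation (blue colonies), and
#' mis-join circles (the white false positives the verification PCR is
#' there to catch).
#'
#' @param design An `assembly_design`.
#' @param max_side_pieces Size bound for side-product circles.
#' @param include_transient Also enumerate circles that still carry BsaI
#'   recognition sites (vector-stuffer religation and donor-vector
#'   combinations). These species are re-cut by the cyclic
#'   digestion-ligation and cannot persist as end products, but they do
#'   transform (the blue-colony background) and are reported as side
#'   products. Stable closures - circles built entirely from site-free
#'   fragments - are always searched.
#' @return An `assembly_product`; side products in `$side_products`. When
#'   no stable closure contains the vector body, an error of class
#'   `yaliclone_assembly_failure` is signalled, carrying the longest
#'   linear extension (`$diagnostic`) and the side products
#'   (`$side_products`).
#' @export
simulate_assembly <- function(design, max_side_pieces = 12L,
                              include_transient = TRUE) {
  stopifnot(inherits(design, "assembly_design"))
  pool <- design_fragment_pool(design)
  prov <- vapply(pool, function(f) f$provenance, character(1))
  backbone_idx <- which(prov == design$backbone_id &
                          vapply(pool, function(f) {
                            nrow(get_features(f$seq, "kanR")) > 0
                          }, logical(1)))
  stopifnot(length(backbone_idx) == 1L)

  # stable end products can only be built from fragments free of internal
  # recognition sites; anything else is re-digested by the cycling reaction
  site_free <- vapply(pool, function(f) {
    nrow(scan_sites(f$seq, bsaI())) == 0L
  }, logical(1))
  stable_idx <- which(site_free)
  remap <- function(circles) {
    lapply(circles, function(p) {
      data.frame(idx = stable_idx[p$idx], orient = p$orient)
    })
  }
  stable_raw <- enumerate_circles(pool[stable_idx],
                                  max_pieces = max_side_pieces)
  stable <- remap(stable_raw)

  circles <- stable
  if (include_transient) {
    all_circles <- enumerate_circles(pool, max_pieces = max_side_pieces)
    stable_keys <- vapply(stable, function(p)
      canonical_path_key(p$idx, p$orient), character(1))
    extra <- Filter(function(p) {
      !canonical_path_key(p$idx, p$orient) %in% stable_keys
    }, all_circles)
    circles <- c(stable, extra)
  }

  with_backbone <- Filter(function(p) backbone_idx %in% p$idx, stable)
  if (!length(with_backbone)) {
    anch <- enumerate_circles(pool[stable_idx],
                              anchor = which(stable_idx == backbone_idx),
                              max_pieces = max_side_pieces)
    longest <- stable_idx[attr(anch, "longest_path")]
    sides <- build_side_products(pool, circles, backbone_idx, NULL)
    cond <- structure(
      class = c("yaliclone_assembly_failure", "error", "condition"),
      list(message = sprintf(
        "assembly failure: no stable circular closure contains the vector body; longest linear extension: %s",
        paste(prov[longest], collapse = " -> ")),
        call = sys.call(-1),
        diagnostic = prov[longest], side_products = sides))
    stop(cond)
  }

  part_ids <- design$assignments[!is.na(design$assignments)]
  is_intended <- vapply(with_backbone, function(p) {
    ids <- sub("^part:[^:]+:", "", vapply(p$idx, function(i) {
      feats <- pool[[i]]$seq$annotations
      pf <- feats$label[grepl("^part:", feats$label)]
      if (length(pf)) pf[1] else prov[i]
    }, character(1)))
    setequal(ids, c(design$backbone_id, part_ids)) &&
      length(p$idx) == length(part_ids) + 1L
  }, logical(1))

  chosen <- if (any(is_intended)) which(is_intended)[1] else 1L
  misjoin_flags <- character()
  if (length(with_backbone) > 1L) {
    others <- setdiff(seq_along(with_backbone), chosen)
    misjoin_flags <- vapply(others, function(k) {
      sprintf("alternative closure: %s",
              paste(prov[with_backbone[[k]]$idx], collapse = " + "))
    }, character(1))
  }
  if (!any(is_intended)) {
    misjoin_flags <- c("no closure matches the design slot-wise", misjoin_flags)
  }

  product <- build_assembly_product(pool, with_backbone[[chosen]],
                                    backbone_idx, design, misjoin_flags)
  product$side_products <- build_side_products(
    pool, circles, backbone_idx, with_backbone[[chosen]])
  product
}

build_side_products <- function(pool, circles, backbone_idx, chosen_path) {
  prov <- vapply(pool, function(f) f$provenance, character(1))
  chosen_key <- if (!is.null(chosen_path)) {
    canonical_path_key(chosen_path$idx, chosen_path$orient)
  } else ""
  sides <- list()
  for (p in circles) {
    if (identical(canonical_path_key(p$idx, p$orient), chosen_key)) next
    seqp <- circle_product(pool, p)
    cls <- if (nrow(get_features(seqp, "lacZ_stuffer")) > 0 &&
               backbone_idx %in% p$idx) "backbone-religation"
    else "misjoin-circle"
    sides[[length(sides) + 1L]] <- list(sequence = seqp,
                                        composition = prov[p$idx],
                                        classification = cls)
  }
  sides
}

## orient a backbone-containing cycle to start at the vector body, with the
## vector body in + orientation, then assemble product + junction table
build_assembly_product <- function(pool, path, backbone_idx, design,
                                   misjoin_flags) {
  pos <- which(path$idx == backbone_idx)
  ord <- c(pos:nrow(path), seq_len(pos - 1L))[seq_len(nrow(path))]
  path <- path[ord, , drop = FALSE]
  if (path$orient[1] < 0) {  # mirror the whole circle
    path <- path[c(1L, rev(seq_len(nrow(path))[-1L])), , drop = FALSE]
    path$orient <- -path$orient
  }
  seqp <- circle_product(pool, path,
                         id = paste0(design$backbone_id, "-assembly"))

  # junction table: boundary overhangs in slot order, starting with the
  # vector->marker junction
  tab <- design$registry$overhangs
  k <- nrow(path)
  junctions <- do.call(rbind, lapply(seq_len(k), function(i) {
    nxt <- if (i == k) 1L else i + 1L
    ov <- arc_ends(pool[[path$idx[nxt]]], path$orient[nxt])[1]
    data.frame(label = tab$label[match(ov, tab$sequence)], sequence = ov,
               stringsAsFactors = FALSE)
  }))

  structure(list(sequence = seqp, junctions = junctions,
                 colony_color = predict_colony_color(seqp),
                 misjoin_flags = misjoin_flags,
                 fragment_provenance = vapply(path$idx, function(i)
                   pool[[i]]$provenance, character(1)),
                 design = design, side_products = list()),
            class = "assembly_product")
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product> %d bp circular, %d junctions, colony %s%s\n",
              seq_length(x$sequence), nrow(x$junctions), x$colony_color,
              if (length(x$misjoin_flags))
                sprintf(", %d misjoin flag(s)", length(x$misjoin_flags)) else ""))
  invisible(x)
}

#' Exhaustive circle enumeration over a small fragment pool
#'
#' Independent brute-force oracle: iterates over every non-empty subset,
#' circular permutation, and orientation assignment of at most six
#' fragments, keeps arrangements whose consecutive overhangs all match,
#' and deduplicates by canonical rotation/reflection of the resulting
#' circle sequence.
#'
#' @param fragments List of `sticky_fragment` (at most 6).
#' @param max_pieces Upper bound on circle size (<= 6).
#' @return List of circles, each with `sequence` (circular `dna_seq`),
#'   `composition` (fragment indices) and `key` (canonical string).
#' @export
enumerate_products_bruteforce <- function(fragments, max_pieces = 6L) {
  n <- length(fragments)
  if (n > 6L) stop("brute-force enumeration is limited to 6 fragments")
  if (max_pieces > 6L) max_pieces <- 6L
  sticky <- vapply(fragments, function(f) {
    nchar(f$left_overhang) > 0L && nchar(f$right_overhang) > 0L && !f$circular
  }, logical(1))
  out <- list()
  keys <- character()
  idxs <- which(sticky)
  for (size in seq_len(min(max_pieces, length(idxs)))) {
    subsets <- utils::combn(idxs, size, simplify = FALSE)
    for (S in subsets) {
      first <- S[1]
      rest <- S[-1]
      perms <- if (length(rest)) all_permutations(rest) else list(integer())
      for (perm in perms) {
        ordering <- c(first, perm)
        orient_grid <- orientation_grid(size)
        for (orients in orient_grid) {
          ok <- TRUE
          ends <- lapply(seq_len(size), function(i)
            arc_ends(fragments[[ordering[i]]], orients[i]))
          for (i in seq_len(size)) {
            nxt <- if (i == size) 1L else i + 1L
            if (!identical(ends[[i]][2], ends[[nxt]][1])) { ok <- FALSE; break }
          }
          if (!ok) next
          pd <- data.frame(idx = ordering, orient = orients)
          seqp <- circle_product(fragments, pd)
          key <- canonical_circle_key(seqp$bases)
          if (key %in% keys) next
          keys <- c(keys, key)
          out[[length(out) + 1L]] <- list(sequence = seqp,
                                          composition = ordering, key = key)
        }
      }
    }
  }
  out
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

orientation_grid <- function(k) {
  grid <- expand.grid(rep(list(c(1L, -1L)), k))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

#' Predict colony colour on X-Gal/IPTG plates
#'
#' Circles carrying the intact lacZ stuffer give blue colonies; stuffer
#' replacement (the intended assembly) gives white. Mis-joined circles that
#' lost the stuffer are also white — the false positives that make PCR
#' verification necessary. A circle without the kanamycin-resistance
#' placeholder cannot form a colony on the selection plate at all and is
#' flagged not platable.
#'
#' @param product An `assembly_product` or a circular `dna_seq`.
#' @return `"blue"` or `"white"`, with attribute `platable`.
#' @export
predict_colony_color <- function(product) {
  seqp <- if (inherits(product, "assembly_product")) product$sequence else product
  stopifnot(inherits(seqp, "dna_seq"))
  platable <- nrow(get_features(seqp, "kanR")) > 0
  color <- if (nrow(get_features(seqp, "lacZ_stuffer")) > 0) "blue" else "white"
  structure(color, platable = platable)
}

#' Ordered junction report of an assembled product
#'
#' Lists the junction overhang labels and 4-mers in product order, starting
#' from the vector-marker junction, and diagnoses any mismatch against the
#' design's slot order (a sequencing-level mis-join signal).
#'
#' @param product An `assembly_product`.
#' @return Data frame `label`, `sequence`, with attribute
#'   `order_matches_design`.
#' @export
junction_report <- function(product) {
  stopifnot(inherits(product, "assembly_product"))
  out <- product$junctions
  layout <- product$design$layout
  expected <- c(layout$left_label[1], layout$right_label)
  matches <- nrow(out) == length(expected) &&
    identical(as.integer(out$label), as.integer(expected))
  attr(out, "order_matches_design") <- isTRUE(matches)
  out
}

#' Recommended ligation protocol for a given fragment count
#'
#' Up to four fragments assemble at high efficiency with 600 U of T4 DNA
#' ligase and 60 thermal cycles; five or more fragments need the optimized
#' conditions of 1,400 U and 120 cycles. The thermal program is fixed:
#' (37 degrees C 3 min / 16 degrees C 4 min) per cycle, then 50 degrees C
#' 5 min and 80 degrees C 5 min.
#'
#' @param n_fragments Number of fragments to ligate (2..10).
#' @return List with `ligase_units`, `cycles`, `thermal_program`.
#' @export
recommend_protocol <- function(n_fragments) {
  if (!is.numeric(n_fragments) || length(n_fragments) != 1L ||
      n_fragments < 2 || n_fragments > 10 || n_fragments != round(n_fragments)) {
    stop("n_fragments must be an integer in 2..10")
  }
  if (n_fragments <= 4) {
    units <- 600L; cycles <- 60L
  } else {
    units <- 1400L; cycles <- 120L
  }
  list(ligase_units = units, cycles = cycles,
       thermal_program = list(cycle = "37C 3 min / 16C 4 min",
                              n_cycles = cycles,
                              final = c("50C 5 min", "80C 5 min")))
}
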