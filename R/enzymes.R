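#' Restriction enzyme specification
#'
#' Two kinds are modelled. A type IIS enzyme (BsaI-like) recognises an
#' asymmetric motif and cuts downstream of it: `spacer` nucleotides after the
#' recognition end on the top strand and `spacer + overhang_len` on the
#' bottom, leaving an `overhang_len`-nt 5' overhang. A blunt cutter
#' (SwaI-like) recognises a palindrome and cuts both strands at
#' `cut_offset` from the recognition start.
#'
#' @param name Enzyme name.
#' @param recognition Recognition motif (A/C/G/T only; no ambiguity codes).
#' @param kind `"typeIIS"` or `"blunt"`.
#' @param spacer Type IIS: nucleotides between recognition end and top-strand
#'   cut.
#' @param overhang_len Type IIS: length of the 5' overhang.
#' @param cut_offset Blunt: cut index from recognition start (both strands).
#' @return An `enzyme_spec` object.
#' @seealso [bsaI()], [swaI()]
#' @export
enzyme_spec <- function(name, recognition, kind = c("typeIIS", "blunt"),
                        spacer = NA_integer_, overhang_len = NA_integer_,
                        cut_offset = NA_integer_) {
  kind <- match.arg(kind)
  recognition <- toupper(recognition)
  if (grepl("[^ACGT]", recognition)) stop("recognition motif must be A/C/G/T")
  if (kind == "typeIIS") {
    stopifnot(!is.na(spacer), !is.na(overhang_len), spacer >= 0L,
              overhang_len > 0L)
  } else {
    stopifnot(!is.na(cut_offset), cut_offset >= 0L,
              cut_offset <= nchar(recognition))
    if (rc_string(recognition) != recognition) {
      stop("blunt enzyme with symmetric cut must have palindromic recognition")
    }
  }
  structure(list(name = name, recognition = recognition, kind = kind,
                 spacer = as.integer(spacer),
                 overhang_len = as.integer(overhang_len),
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme_spec")
}

#' BsaI: GGTCTC(N1), 4-nt 5' overhangs
#' @return An `enzyme_spec`.
#' @export
bsaI <- function() {
  enzyme_spec("BsaI", "GGTCTC", "typeIIS", spacer = 1L, overhang_len = 4L)
}

#' SwaI: ATTTAAAT, blunt mid-palindrome cut
#' @return An `enzyme_spec`.
#' @export
swaI <- function() {
  enzyme_spec("SwaI", "ATTTAAAT", "blunt", cut_offset = 4L)
}

## all start positions (0-based) of fixed `pat` in `s`
find_fixed <- function(s, pat) {
  if (!nchar(s) || nchar(pat) > nchar(s)) return(integer())
  m <- gregexpr(pat, s, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m) - 1L
}

#' Scan a sequence for restriction sites
#'
#' Reports every occurrence of the recognition motif on either strand, with
#' the absolute cut indices implied by the enzyme geometry. On circular
#' sequences occurrences spanning the origin are found and positions are
#' reduced modulo length. Cut indices follow the convention "index of the
#' first base to the right of the cut"; for a type IIS site the top-strand
#' window `[top_cut, bottom_cut)` is the overhang the cut creates.
#'
#' For a plus-strand type IIS site whose recognition starts at `p`:
#' `top_cut = p + reclen + spacer`, `bottom_cut = top_cut + overhang_len`.
#' For a minus-strand site (reverse-complemented motif starting at `q`):
#' `top_cut = q - spacer - overhang_len`, `bottom_cut = q - spacer`.
#' Palindromic recognitions are reported once, on the plus strand.
#'
#' @param seq A `dna_seq` (may be empty).
#' @param enzyme An `enzyme_spec`.
#' @return Data frame with columns `enzyme`, `position`, `strand`,
#'   `top_cut`, `bottom_cut`, sorted by position.
#' @export
scan_sites <- function(seq, enzyme) {
  stopifnot(inherits(seq, "dna_seq"), inherits(enzyme, "enzyme_spec"))
  s <- seq$bases
  n <- nchar(s)
  rec <- enzyme$recognition
  reclen <- nchar(rec)
  empty <- data.frame(enzyme = character(), position = integer(),
                      strand = character(), top_cut = integer(),
                      bottom_cut = integer(), stringsAsFactors = FALSE)
  if (n == 0L || reclen > n) return(empty)

  search_space <- if (is_circular(seq)) paste0(s, substr(s, 1L, reclen - 1L)) else s
  pos_f <- find_fixed(search_space, rec)
  rcrec <- rc_string(rec)
  palindromic <- identical(rcrec, rec)
  pos_r <- if (palindromic) integer() else find_fixed(search_space, rcrec)
  if (is_circular(seq)) {
    pos_f <- pos_f[pos_f < n]
    pos_r <- pos_r[pos_r < n]
  }

  cuts <- function(p, strand) {
    if (enzyme$kind == "typeIIS") {
      if (strand == "+") {
        tc <- p + reclen + enzyme$spacer
        bc <- tc + enzyme$overhang_len
      } else {
        tc <- p - enzyme$spacer - enzyme$overhang_len
        bc <- p - enzyme$spacer
      }
    } else {
      tc <- bc <- p + enzyme$cut_offset
    }
    c(tc, bc)
  }

  rows <- lapply(c(pos_f, pos_r), function(p) p)
  strands <- c(rep("+", length(pos_f)), rep("-", length(pos_r)))
  if (!length(rows)) return(empty)
  out <- do.call(rbind, Map(function(p, st) {
    cb <- cuts(p, st)
    data.frame(enzyme = enzyme$name, position = as.integer(p), strand = st,
               top_cut = as.integer(cb[1]), bottom_cut = as.integer(cb[2]),
               stringsAsFactors = FALSE)
  }, rows, strands))
  if (is_circular(seq)) {
    win <- out$bottom_cut - out$top_cut
    out$top_cut <- ((out$top_cut %% n) + n) %% n
    out$bottom_cut <- out$top_cut + win
  } else {
    # a linear molecule has no duplex beyond its ends: a site whose cut
    # window falls outside the molecule cannot be cleaved
    keep <- out$top_cut >= 0L & out$bottom_cut <= n
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sticky-ended linear fragment
#'
#' A double-stranded fragment as produced by digestion. `seq` holds the full
#' top-strand footprint including both overhang windows; `left_overhang` and
#' `right_overhang` are the 4-nt (or empty, for blunt ends) windows
#' normalized to the top-strand 5'->3' reading. Under this normalization two
#' ends are ligation-compatible iff their strings are equal, and flipping a
#' fragment maps `(left, right)` to `(rc(right), rc(left))`.
#'
#' @param seq A linear `dna_seq` (the footprint).
#' @param left_overhang,right_overhang Normalized overhang strings (`""` for
#'   blunt).
#' @param provenance Identifier of the parent molecule/region.
#' @param circular Fragment is an uncut circle (zero-site digestion).
#' @param uncut Flag set when a circular parent had no sites.
#' @return A `sticky_fragment`.
#' @export
sticky_fragment <- function(seq, left_overhang = "", right_overhang = "",
                            provenance = NA_character_, circular = FALSE,
                            uncut = FALSE) {
  stopifnot(inherits(seq, "dna_seq"))
  for (ov in c(left_overhang, right_overhang)) {
    if (nchar(ov) && grepl("[^ACGT]", ov)) stop("overhang must be A/C/G/T")
  }
  structure(list(seq = seq, left_overhang = left_overhang,
                 right_overhang = right_overhang, provenance = provenance,
                 circular = circular, uncut = uncut),
            class = "sticky_fragment")
}

#' @export
print.sticky_fragment <- function(x, ...) {
  cat(sprintf("<sticky_fragment %s> %d bp  5'-%s...%s  %s\n",
              ifelse(is.na(x$provenance), "?", x$provenance),
              seq_length(x$seq),
              ifelse(nchar(x$left_overhang), x$left_overhang, "(blunt)"),
              ifelse(nchar(x$right_overhang), x$right_overhang, "(blunt)"),
              if (x$circular) "(circular)" else ""))
  invisible(x)
}

#' Flip a sticky fragment to its reverse complement orientation
#' @param frag A `sticky_fragment`.
#' @return The flipped fragment.
#' @export
flip_fragment <- function(frag) {
  stopifnot(inherits(frag, "sticky_fragment"))
  sticky_fragment(reverse_complement(frag$seq),
                  left_overhang = rc_string(frag$right_overhang),
                  right_overhang = rc_string(frag$left_overhang),
                  provenance = frag$provenance, circular = frag$circular,
                  uncut = frag$uncut)
}

## remap parent annotations into a fragment window [from, to) (unwrapped
## coordinates; `to` may exceed n on circles)
map_annotations <- function(parent, from, to) {
  ann <- parent$annotations
  if (!nrow(ann)) return(empty_annotations())
  n <- seq_length(parent)
  keep <- list()
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[i]; e <- ann$end[i]
    # try the feature at its stated coords and, on circles, shifted by +n
    shifts <- if (is_circular(parent)) c(0L, n) else 0L
    for (sh in shifts) {
      if (s + sh >= from && e + sh <= to) {
        keep[[length(keep) + 1L]] <- data.frame(
          label = ann$label[i], start = as.integer(s + sh - from),
          end = as.integer(e + sh - from), strand = ann$strand[i],
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(keep)) return(empty_annotations())
  do.call(rbind, keep)
}

#' Digest a sequence with a restriction enzyme
#'
#' Cuts at every scanned site and returns the resulting sticky fragments in
#' positional order. Each fragment's footprint runs from its left cut's
#' `top_cut` to its right cut's `bottom_cut`, so the shared overhang window
#' appears in both flanking fragments but is counted once in the conservation
#' identity: summing `length - overhang_len` over fragments of a circular
#' parent gives the parent length.
#'
#' A circular parent with `k` sites yields `k` fragments; a linear parent
#' yields `k + 1` (terminal fragments get blunt outer ends). A circular
#' parent with zero sites is returned intact, flagged `uncut`. Two sites
#' whose cut windows overlap make the cut geometry ill-defined and raise an
#' "entangled cut" error.
#'
#' @param seq A `dna_seq`.
#' @param enzyme An `enzyme_spec`.
#' @return List of `sticky_fragment` objects.
#' @export
digest <- function(seq, enzyme) {
  stopifnot(inherits(seq, "dna_seq"), inherits(enzyme, "enzyme_spec"))
  n <- seq_length(seq)
  if (n == 0L) stop("cannot digest an empty sequence")
  sites <- scan_sites(seq, enzyme)
  circ <- is_circular(seq)
  prov <- if (is.na(seq$id)) "unnamed" else seq$id

  if (nrow(sites) == 0L) {
    if (circ) {
      return(list(sticky_fragment(seq, provenance = prov, circular = TRUE,
                                  uncut = TRUE)))
    }
    return(list(sticky_fragment(seq, provenance = prov)))
  }

  ord <- order(sites$top_cut)
  sites <- sites[ord, , drop = FALSE]
  tc <- sites$top_cut
  bc <- sites$bottom_cut
  k <- nrow(sites)
  # overlapping cut windows (wrap-aware on circles) are not resolvable
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      if (bc[i] > tc[i + 1L]) stop("entangled cut: overlapping cut windows")
    }
    if (circ && bc[k] > tc[1L] + n) {
      stop("entangled cut: overlapping cut windows")
    }
  } else if (circ && bc[1L] - tc[1L] > n) {
    stop("entangled cut: overlapping cut windows")
  }

  frag_from_window <- function(from, to_bc, left_ov, right_ov) {
    fb <- subseq_circ(seq$bases, from, to_bc, circular = circ)
    ann <- map_annotations(seq, from, to_bc)
    sticky_fragment(dna_seq(fb, "linear", annotations = ann,
                            id = sprintf("%s[%d..%d)", prov, from, to_bc)),
                    left_overhang = left_ov, right_overhang = right_ov,
                    provenance = prov)
  }
  ov_at <- function(i) {
    if (bc[i] == tc[i]) "" else subseq_circ(seq$bases, tc[i], bc[i],
                                            circular = circ)
  }

  frags <- list()
  if (circ) {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      to_bc <- if (i == k) bc[j] + n else bc[j]
      frags[[i]] <- frag_from_window(tc[i], to_bc, ov_at(i), ov_at(j))
    }
  } else {
    frags[[1L]] <- frag_from_window(0L, bc[1L], "", ov_at(1L))
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        frags[[i + 1L]] <- frag_from_window(tc[i], bc[i + 1L], ov_at(i),
                                            ov_at(i + 1L))
      }
    }
    frags[[k + 1L]] <- frag_from_window(tc[k], n, ov_at(k), "")
  }
  frags
}

#' Re-join sticky fragments in order
#'
#' Concatenates fragments whose consecutive ends carry equal normalized
#' overhangs, counting each shared overhang window once. With
#' `circularize = TRUE` the last fragment's right end must match the first
#' fragment's left end and a circular `dna_seq` is returned.
#'
#' @param frags List of `sticky_fragment` (already oriented).
#' @param circularize Close the molecule into a circle.
#' @param id Identifier for the joined molecule.
#' @return A `dna_seq`.
#' @export
ligate_fragments <- function(frags, circularize = FALSE, id = NA_character_) {
  stopifnot(length(frags) >= 1L)
  pieces <- character(length(frags))
  ann_all <- list()
  offset <- 0L
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    if (i > 1L) {
      prev <- frags[[i - 1L]]
      if (!identical(prev$right_overhang, f$left_overhang)) {
        stop(sprintf("incompatible junction between fragments %d and %d", i - 1L, i))
      }
    }
    drop <- nchar(f$left_overhang)
    contrib <- substr(f$seq$bases, drop + 1L, nchar(f$seq$bases))
    pieces[i] <- contrib
    ann <- f$seq$annotations
    if (nrow(ann)) {
      ann$start <- ann$start - drop + offset
      ann$end <- ann$end - drop + offset
      ann <- ann[ann$start >= 0L, , drop = FALSE]
      if (nrow(ann)) ann_all[[length(ann_all) + 1L]] <- ann
    }
    offset <- offset + nchar(contrib)
  }
  if (circularize) {
    first <- frags[[1L]]; last <- frags[[length(frags)]]
    if (!identical(last$right_overhang, first$left_overhang)) {
      stop("cannot circularize: terminal overhangs incompatible")
    }
  } else {
    # a linear join keeps the first fragment's left window
    lead <- frags[[1L]]$left_overhang
    pieces[1L] <- paste0(lead, pieces[1L])
    if (length(ann_all)) {
      ann_all <- lapply(ann_all, function(a) {
        a$start <- a$start + nchar(lead); a$end <- a$end + nchar(lead); a
      })
    }
  }
  ann <- if (length(ann_all)) do.call(rbind, ann_all) else NULL
  dna_seq(paste(pieces, collapse = ""),
          topology = if (circularize) "circular" else "linear",
          annotations = ann, id = id)
}
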