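#' Excise the SwaI integration cassette from an assembled plasmid
#'
#' The two SwaI sites of the destination vector bracket the assembled
#' selection marker and transcription units. Blunt digestion of a correct
#' product yields exactly two linear fragments; the one carrying the marker
#' feature is the cassette handed to yeast transformation, the other is the
#' vector fragment (kanR + ori). Base count is conserved.
#'
#' @param product An `assembly_product` or circular `dna_seq`.
#' @return List with `cassette` and `vector_fragment` (linear `dna_seq`).
#' @export
extract_cassette <- function(product) {
  seqp <- if (inherits(product, "assembly_product")) product$sequence else product
  stopifnot(inherits(seqp, "dna_seq"))
  sites <- scan_sites(seqp, swaI())
  if (nrow(sites) != 2L) {
    stop(sprintf("cassette not excisable: %d SwaI site(s), need exactly 2",
                 nrow(sites)))
  }
  frags <- digest(seqp, swaI())
  stopifnot(length(frags) == 2L)
  has_marker <- vapply(frags, function(f) {
    any(grepl("^part:marker:", f$seq$annotations$label))
  }, logical(1))
  if (sum(has_marker) != 1L) {
    # fall back on the vector-body features: the cassette is the fragment
    # without kanR/ori
    has_vec <- vapply(frags, function(f) {
      nrow(get_features(f$seq, "kanR")) > 0 || nrow(get_features(f$seq, "ori")) > 0
    }, logical(1))
    if (sum(has_vec) != 1L) stop("cannot identify the cassette fragment")
    has_marker <- !has_vec
  }
  cassette <- frags[[which(has_marker)]]$seq
  vector_fragment <- frags[[which(!has_marker)]]$seq
  cassette$id <- paste0(seqp$id, "-cassette")
  vector_fragment$id <- paste0(seqp$id, "-vector")
  list(cassette = cassette, vector_fragment = vector_fragment)
}

#' Verification primer pair
#'
#' Defaults are the toolkit's F/R colony-PCR primers, which bind the
#' destination vector just outside the SwaI sites so that the amplicon
#' spans the entire assembled region.
#'
#' @param forward,reverse Primer sequences, 5' to 3'.
#' @return A `primer_pair`.
#' @export
primer_pair <- function(forward = PRIMER_F_DEFAULT,
                        reverse = PRIMER_R_DEFAULT) {
  forward <- gsub("\\s", "", toupper(forward))
  reverse <- gsub("\\s", "", toupper(reverse))
  stopifnot(nchar(forward) > 0L, nchar(reverse) > 0L)
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' In silico PCR with exact-match primers
#'
#' The forward primer must bind one strand and the reverse primer the
#' other, 3' ends facing each other; binding is exact (the verification
#' primers were designed for exact targets). On circular templates both
#' ways around are measured and the shortest spanning amplicon is
#' returned. No product is a valid outcome (`NULL`).
#'
#' @param template A `dna_seq`.
#' @param primers A `primer_pair`.
#' @return `NULL`, or a list with `start` (0-based, on the top strand,
#'   where the amplicon begins), `length`, and `sequence`.
#' @export
in_silico_pcr <- function(template, primers = primer_pair()) {
  stopifnot(inherits(template, "dna_seq"), inherits(primers, "primer_pair"))
  s <- template$bases
  n <- nchar(s)
  if (!n) return(NULL)
  circ <- is_circular(template)

  amplicons <- list()
  consider <- function(fwd, rev) {
    # fwd binds the top strand pointing right; rev binds the bottom strand,
    # so its reverse complement appears on the top strand, pointing left
    f_pos <- find_fixed(s, fwd)
    r_pos <- find_fixed(s, rc_string(rev))
    if (circ) {
      space <- paste0(s, s)
      f_pos <- find_fixed(space, fwd); f_pos <- f_pos[f_pos < n]
      r_pos <- find_fixed(space, rc_string(rev)); r_pos <- r_pos[r_pos < n]
    }
    for (f in f_pos) {
      for (r in r_pos) {
        r_end <- r + nchar(rev)
        len <- r_end - f
        if (circ) {
          len <- ((len %% n) + n) %% n
          if (len == 0L) len <- n
        } else if (len <= 0L) next
        if (len < nchar(fwd) + nchar(rev)) next  # primers must not overlap
        amplicons[[length(amplicons) + 1L]] <<- list(
          start = f, length = len,
          sequence = subseq_circ(s, f, f + len, circular = circ))
      }
    }
  }
  consider(primers$forward, primers$reverse)
  consider(primers$reverse, primers$forward)
  if (!length(amplicons)) return(NULL)
  lens <- vapply(amplicons, function(a) a$length, numeric(1))
  amplicons[[which.min(lens)]]
}

#' Cre-mediated marker excision between direct loxP sites
#'
#' Finds loxP motifs on the sequence; with at least two in direct (same
#' strand) orientation, the region between the first such pair is removed
#' together with one of the sites, leaving a single loxP scar. Inverted
#' pairs would invert rather than excise and are not modelled.
#'
#' @param seq A `dna_seq`.
#' @param loxp loxP sequence (canonical 34-nt site by default).
#' @return The excised `dna_seq` (length reduced by the inter-loxP distance
#'   plus one loxP length).
#' @export
cre_excise <- function(seq, loxp = LOXP_SEQ) {
  stopifnot(inherits(seq, "dna_seq"))
  fwd <- find_fixed(seq$bases, loxp)
  rev <- find_fixed(seq$bases, rc_string(loxp))
  if (length(fwd) >= 2L || length(rev) >= 2L) {
    pos <- if (length(fwd) >= 2L) fwd else rev
    first_end <- pos[1] + nchar(loxp)
    second_end <- pos[2] + nchar(loxp)
    remove_region(seq, first_end, second_end,
                  id = paste0(seq$id, "-creX"))
  } else if (length(fwd) >= 1L && length(rev) >= 1L) {
    stop("loxP sites are inverted: inversion is not modelled, nothing to excise")
  } else {
    stop("nothing to excise: fewer than 2 direct loxP sites")
  }
}

#' hisG-URA3-hisG pop-out recombination
#'
#' Models 5-FOA counter-selection of the HUH marker: recombination between
#' the two identical direct hisG repeats collapses the locus to a single
#' hisG copy and deletes URA3. Repeats are located through the sequence's
#' `hisG` features and must be identical; a `URA3` feature must lie
#' between them.
#'
#' @param seq A `dna_seq` annotated with two `hisG` features and a `URA3`
#'   feature.
#' @return The popped-out `dna_seq`, shorter by exactly
#'   (hisG + intervening) length.
#' @export
hisG_popout <- function(seq) {
  stopifnot(inherits(seq, "dna_seq"))
  hg <- get_features(seq, "hisG")
  if (nrow(hg) < 2L) stop("hisG repeats not found (need two direct copies)")
  hg <- hg[order(hg$start), , drop = FALSE]
  a <- hg[1, ]; b <- hg[2, ]
  if (a$strand != b$strand) stop("hisG repeats are not in direct orientation")
  rep1 <- subseq_circ(seq$bases, a$start, a$end, circular = is_circular(seq))
  rep2 <- subseq_circ(seq$bases, b$start, b$end, circular = is_circular(seq))
  if (!identical(rep1, rep2)) stop("hisG repeats are not identical")
  ura <- get_features(seq, "URA3")
  if (!nrow(ura) || !(ura$start[1] >= a$end && ura$end[1] <= b$start)) {
    stop("no URA3 feature between the hisG repeats")
  }
  remove_region(seq, a$start, b$start, id = paste0(seq$id, "-popout"))
}

## delete [from, to) from a sequence, shifting/dropping features
remove_region <- function(seq, from, to, id = seq$id) {
  n <- seq_length(seq)
  stopifnot(from >= 0L, to <= n, to >= from)
  bases <- paste0(substr(seq$bases, 1L, from), substr(seq$bases, to + 1L, n))
  w <- to - from
  ann <- seq$annotations
  if (nrow(ann)) {
    keep <- !(ann$start < to & ann$end > from)   # drop anything overlapping
    ann <- ann[keep, , drop = FALSE]
    shift <- ann$start >= to
    ann$start[shift] <- ann$start[shift] - w
    ann$end[ann$end >= to] <- ann$end[ann$end >= to] - w
  }
  dna_seq(bases, topology = seq$topology, annotations = ann, id = id)
}
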