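## motifs forbidden inside parts: BsaI on either strand, SwaI (palindromic)
forbidden_motif_set <- function() FORBIDDEN_MOTIFS

## synonymous alternatives for each codon, standard code
synonymous_codons <- function(codon) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  alts <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
  setdiff(alts, codon)
}

## leftmost forbidden-motif occurrence in a plain string, or NULL
first_motif_hit <- function(bases, motifs) {
  best <- NULL
  for (m in motifs) {
    p <- find_fixed(bases, m)
    if (length(p) && (is.null(best) || p[1] < best$pos)) {
      best <- list(pos = p[1], motif = m)
    }
  }
  best
}

#' Remove forbidden restriction sites from a CDS by synonymous substitution
#'
#' Golden Gate parts must not contain the assembly enzymes' recognition
#' sites internally, or the one-pot reaction cuts inside them. Within a
#' coding sequence the sites can be destroyed without touching the protein:
#' for each motif occurrence (either strand), every codon overlapping the
#' site is tried with every synonymous replacement, and the replacement
#' that (1) destroys the site, (2) creates no new forbidden motif in a
#' rescanned window of +/- 10 nt, and (3) changes the fewest bases is
#' applied. Ties break deterministically: leftmost codon, then
#' lexicographically smallest new codon. The process repeats, with a final
#' full-sequence scan, until the CDS is clean.
#'
#' @param cds A linear `dna_seq` or base string; length divisible by 3.
#' @param forbidden_motifs Motif strings (defaults: BsaI forward/reverse,
#'   SwaI).
#' @return A `domestication_result`: `sequence` (edited `dna_seq`), `edits`
#'   (data frame `codon_index`, `old_codon`, `new_codon`, `motif_removed`,
#'   `position`), and `clean` (logical).
#' @export
domesticate_cds <- function(cds, forbidden_motifs = forbidden_motif_set()) {
  input_id <- NA_character_
  if (inherits(cds, "dna_seq")) {
    input_id <- cds$id
    cds <- cds$bases
  }
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop(sprintf("frame error: CDS length %d is not divisible by 3", n))
  }
  protein <- translate_cds(cds)
  edits <- list()
  guard <- 0L
  repeat {
    hit <- first_motif_hit(cds, forbidden_motifs)
    if (is.null(hit)) break
    guard <- guard + 1L
    if (guard > n) stop("domestication did not converge")
    mstart <- hit$pos             # 0-based
    mend <- mstart + nchar(hit$motif)
    codon_lo <- mstart %/% 3L
    codon_hi <- (mend - 1L) %/% 3L

    best <- NULL
    for (ci in codon_lo:codon_hi) {
      old_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
      for (new_codon in sort(synonymous_codons(old_codon))) {
        cand <- cds
        substr(cand, ci * 3L + 1L, ci * 3L + 3L) <- new_codon
        # the targeted occurrence must be gone
        if (substr(cand, mstart + 1L, mend) == hit$motif) next
        # no new forbidden motif may appear near the edit
        wlo <- max(0L, ci * 3L - 10L)
        whi <- min(n, ci * 3L + 3L + 10L)
        window_before <- substr(cds, wlo + 1L, whi)
        window_after <- substr(cand, wlo + 1L, whi)
        n_before <- sum(vapply(forbidden_motifs, function(m)
          length(find_fixed(window_before, m)), integer(1)))
        n_after <- sum(vapply(forbidden_motifs, function(m)
          length(find_fixed(window_after, m)), integer(1)))
        if (n_after >= n_before) next
        changed <- hamming_str(old_codon, new_codon)
        cand_rec <- list(codon_index = ci, old_codon = old_codon,
                         new_codon = new_codon, changed = changed)
        if (is.null(best) ||
            changed < best$changed ||
            (changed == best$changed && ci < best$codon_index) ||
            (changed == best$changed && ci == best$codon_index &&
               new_codon < best$new_codon)) {
          best <- cand_rec
        }
      }
    }
    if (is.null(best)) {
      stop(sprintf("undomesticatable site: %s at position %d has no synonymous fix",
                   hit$motif, mstart))
    }
    substr(cds, best$codon_index * 3L + 1L, best$codon_index * 3L + 3L) <-
      best$new_codon
    edits[[length(edits) + 1L]] <- data.frame(
      codon_index = best$codon_index, old_codon = best$old_codon,
      new_codon = best$new_codon, motif_removed = hit$motif,
      position = mstart, stringsAsFactors = FALSE)
  }
  stopifnot(identical(translate_cds(cds), protein))
  structure(list(
    sequence = dna_seq(cds, "linear", id = input_id),
    edits = if (length(edits)) do.call(rbind, edits) else
      data.frame(codon_index = integer(), old_codon = character(),
                 new_codon = character(), motif_removed = character(),
                 position = integer(), stringsAsFactors = FALSE),
    clean = TRUE), class = "domestication_result")
}

hamming_str <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' @export
print.domestication_result <- function(x, ...) {
  cat(sprintf("<domestication_result> %d bp, %d edit(s), %s\n",
              seq_length(x$sequence), nrow(x$edits),
              if (x$clean) "clean" else "residual sites"))
  invisible(x)
}

#' Flag forbidden sites in non-coding sequence
#'
#' Non-coding parts (promoters, terminators, vector regions) cannot be
#' edited synonymously; automated edits could change their function, so
#' internal sites are only reported, for manual removal. Positions are
#' 0-based motif starts; on circular sequences, origin-spanning occurrences
#' are found and reported modulo length.
#'
#' @param seq A `dna_seq`.
#' @param forbidden_motifs Motif strings.
#' @return Data frame `motif`, `position`.
#' @export
flag_noncoding_sites <- function(seq, forbidden_motifs = forbidden_motif_set()) {
  stopifnot(inherits(seq, "dna_seq"))
  s <- seq$bases
  n <- nchar(s)
  space <- if (is_circular(seq) && n > 0L) {
    paste0(s, substr(s, 1L, min(n, max(nchar(forbidden_motifs))) - 1L))
  } else s
  rows <- list()
  for (m in forbidden_motifs) {
    p <- find_fixed(space, m)
    if (is_circular(seq)) p <- p[p < n]
    for (pp in p) {
      rows[[length(rows) + 1L]] <- data.frame(motif = m, position = pp,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}
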