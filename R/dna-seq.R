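#' Nucleotide sequence with topology and features
#'
#' Lightweight container for a fully specified DNA sequence: an uppercase
#' string over `{A,C,G,T}`, a topology (`"linear"` or `"circular"`), and an
#' optional feature table. Coordinates are 0-based, half-open, on the top
#' strand; on circular sequences a feature may wrap the origin, in which case
#' `end` exceeds the sequence length and positions are read modulo length.
#'
#' Ambiguity codes are rejected: the toolkit's parts are fully specified
#' sequences, and every downstream operation (site scanning, digestion,
#' ligation) assumes exact base identity.
#'
#' @param bases Character scalar over A/C/G/T (case-insensitive on input,
#'   stored uppercase). May be empty only for scanning-type operations.
#' @param topology `"linear"` (default) or `"circular"`.
#' @param annotations Data frame with columns `label`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), or `NULL`.
#' @param id Optional identifier carried through I/O and reports.
#' @return An object of class `dna_seq`.
#' @examples
#' s <- dna_seq("ATGGGTTAA", id = "demo")
#' seq_length(s)
#' @export
dna_seq <- function(bases, topology = c("linear", "circular"),
                    annotations = NULL, id = NA_character_) {
  topology <- match.arg(topology)
  if (!is.character(bases) || length(bases) != 1L || is.na(bases)) {
    stop("`bases` must be a single character string")
  }
  bases <- toupper(bases)
  bad <- regexpr("[^ACGT]", bases)
  if (bad > 0L) {
    stop(sprintf("non-ACGT character '%s' at position %d (1-based)",
                 substr(bases, bad, bad), as.integer(bad)))
  }
  n <- nchar(bases)
  if (is.null(annotations)) {
    annotations <- empty_annotations()
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start", "end", "strand") %in% names(annotations)))
    annotations <- annotations[, c("label", "start", "end", "strand")]
    if (nrow(annotations)) {
      if (any(annotations$start < 0L | annotations$start >= max(n, 1L))) {
        stop("annotation start out of range [0, length)")
      }
      if (any(annotations$end < annotations$start)) {
        stop("annotation end precedes start")
      }
      if (topology == "linear" && any(annotations$end > n)) {
        stop("annotation exceeds linear sequence end")
      }
      if (!all(annotations$strand %in% c("+", "-"))) {
        stop("annotation strand must be '+' or '-'")
      }
    }
  }
  structure(
    list(bases = bases, topology = topology, annotations = annotations,
         id = id),
    class = "dna_seq"
  )
}

empty_annotations <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$bases)
  head <- if (n > 60L) paste0(substr(x$bases, 1L, 57L), "...") else x$bases
  cat(sprintf("<dna_seq%s> %s, %d bp, %d feature(s)\n  %s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              x$topology, n, nrow(x$annotations), head))
  invisible(x)
}

#' Sequence length in base pairs
#' @param x A `dna_seq`.
#' @return Integer length.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "dna_seq"))
  nchar(x$bases)
}

#' Is a sequence circular?
#' @param x A `dna_seq`.
#' @return Logical scalar.
#' @export
is_circular <- function(x) {
  stopifnot(inherits(x, "dna_seq"))
  identical(x$topology, "circular")
}

#' Add a feature to a sequence
#' @param x A `dna_seq`.
#' @param label Feature label.
#' @param start,end 0-based half-open coordinates (end may wrap on circles).
#' @param strand `"+"` or `"-"`.
#' @return The modified `dna_seq`.
#' @export
add_feature <- function(x, label, start, end, strand = "+") {
  stopifnot(inherits(x, "dna_seq"))
  x$annotations <- rbind(
    x$annotations,
    data.frame(label = label, start = as.integer(start), end = as.integer(end),
               strand = strand, stringsAsFactors = FALSE)
  )
  x
}

#' Look up features by label
#' @param x A `dna_seq`.
#' @param label Label (exact match).
#' @return The matching rows of the feature table.
#' @export
get_features <- function(x, label) {
  stopifnot(inherits(x, "dna_seq"))
  x$annotations[x$annotations$label == label, , drop = FALSE]
}

## fast complement on a plain string; positions preserved
comp_string <- function(s) chartr("ACGT", "TGCA", s)

rc_string <- function(s) {
  if (!nchar(s)) return(s)
  paste(rev(strsplit(comp_string(s), "", fixed = TRUE)[[1]]), collapse = "")
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed. Topology is preserved; features are
#' remapped to the flipped coordinate system with their strands swapped.
#'
#' @param seq A `dna_seq`.
#' @return The reverse-complemented `dna_seq`.
#' @examples
#' reverse_complement(dna_seq("ATTTAAAT"))$bases  # palindrome fixed point
#' @export
reverse_complement <- function(seq) {
  stopifnot(inherits(seq, "dna_seq"))
  n <- nchar(seq$bases)
  ann <- seq$annotations
  if (nrow(ann)) {
    # [s, e) on the top strand maps to [n - e, n - s) on the flipped one
    new_start <- n - ann$end
    new_end <- n - ann$start
    if (seq$topology == "circular") {
      w <- new_end - new_start
      new_start <- ((new_start %% n) + n) %% n
      new_end <- new_start + w
    }
    ann <- data.frame(label = ann$label, start = as.integer(new_start),
                      end = as.integer(new_end),
                      strand = ifelse(ann$strand == "+", "-", "+"),
                      stringsAsFactors = FALSE)
  }
  dna_seq(rc_string(seq$bases), topology = seq$topology, annotations = ann,
          id = seq$id)
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons render as `*`. The frame starts at the
#' first base and the length must be divisible by three.
#'
#' @param cds A `dna_seq` (linear reading assumed) or a plain base string.
#' @return Single-letter amino-acid string.
#' @examples
#' translate_cds("ATGGGT")
#' @export
translate_cds <- function(cds) {
  s <- if (inherits(cds, "dna_seq")) cds$bases else toupper(cds)
  n <- nchar(s)
  if (n == 0L) return("")
  if (n %% 3L != 0L) {
    stop(sprintf("frame error: CDS length %d is not divisible by 3", n))
  }
  codons <- substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) stop("invalid codon encountered")
  paste(aa, collapse = "")
}

# named lookup vector built once from the Biostrings standard-code constant
GENETIC_CODE_TABLE <- local({
  tbl <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(tbl), names(tbl))
})

## substring of a possibly-circular sequence; [from, to) 0-based, to may
## exceed length on circles (wraps); returns plain string
subseq_circ <- function(bases, from, to, circular = FALSE) {
  n <- nchar(bases)
  if (to < from) stop("empty-reversed range")
  if (!circular) {
    if (from < 0L || to > n) stop("range out of bounds on linear sequence")
    return(substr(bases, from + 1L, to))
  }
  from2 <- ((from %% n) + n) %% n
  shift <- from2 - from
  to2 <- to + shift
  if (to2 <= n) return(substr(bases, from2 + 1L, to2))
  if (to2 > 2L * n) stop("range longer than circular sequence")
  paste0(substr(bases, from2 + 1L, n), substr(bases, 1L, to2 - n))
}
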