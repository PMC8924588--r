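#' Default 11-entry fusion-site (overhang) table
#'
#' The toolkit numbers its junction overhangs 1 through 11 across the
#' maximal ten-fragment design: junction 1 sits between the destination
#' vector and the selection marker, 2..10 separate the marker and the three
#' promoter-gene-terminator units, and 11 closes back onto the vector. The
#' shipped 4-mers are a synthetic faithful set (no duplicates, no
#' reverse-complement collisions, no self-palindromes); a user table can be
#' supplied anywhere a registry is built.
#'
#' @return Data frame with columns `label` (1..11) and `sequence` (4-mers).
#' @seealso [check_overhang_set()]
#' @export
default_overhang_table <- function() {
  data.frame(
    label = 1:11,
    sequence = c("AATG", "AGGT", "GCTT", "CCAG", "TGCC", "ACTC",
                 "CAGA", "GACT", "CGAA", "TACA", "GGAG"),
    stringsAsFactors = FALSE
  )
}

#' Check a set of 4-nt overhangs for ligation fidelity
#'
#' In one-pot Golden Gate, any two ends whose overhangs can anneal will be
#' joined by the ligase, so a usable fusion-site set must avoid cross-talk.
#' The check flags, as failures: (a) duplicate sequences, (b) pairs that are
#' reverse complements of each other (their ends anneal to each other's
#' partners), and (c) self-palindromic entries (such an end anneals to a
#' copy of itself, letting a part self-circularize or flip). Pairs at
#' Hamming distance 1 are reported as warnings: a single mismatched base
#' pair can still ligate at reduced fidelity, which is the route to white
#' but mis-joined colonies. A set with no (a)-(c) failures is "faithful".
#'
#' @param overhangs Character vector of 4-mers.
#' @return List with `faithful` (logical), `failures` and `warnings`
#'   (character vectors describing each flagged pair), of class
#'   `overhang_report`.
#' @examples
#' check_overhang_set(c("AATG", "AGGT", "GCTT", "CCAG"))$faithful
#' @export
check_overhang_set <- function(overhangs) {
  overhangs <- toupper(overhangs)
  if (any(nchar(overhangs) != 4L)) {
    stop("every overhang must be exactly 4 nt")
  }
  if (any(grepl("[^ACGT]", overhangs))) stop("overhangs must be A/C/G/T")
  failures <- character()
  warnings <- character()

  dup <- unique(overhangs[duplicated(overhangs)])
  for (d in dup) failures <- c(failures, sprintf("duplicate overhang %s", d))

  for (o in unique(overhangs)) {
    if (rc_string(o) == o) {
      failures <- c(failures, sprintf("self-palindromic overhang %s", o))
    }
  }

  u <- unique(overhangs)
  if (length(u) > 1L) {
    for (i in seq_len(length(u) - 1L)) {
      for (j in (i + 1L):length(u)) {
        if (rc_string(u[i]) == u[j]) {
          failures <- c(failures,
                        sprintf("reverse-complement collision %s / %s", u[i], u[j]))
        }
        if (hamming4(u[i], u[j]) == 1L) {
          warnings <- c(warnings,
                        sprintf("near-collision (Hamming 1) %s / %s", u[i], u[j]))
        }
      }
    }
  }
  structure(list(faithful = length(failures) == 0L, failures = failures,
                 warnings = warnings), class = "overhang_report")
}

hamming4 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' @export
print.overhang_report <- function(x, ...) {
  cat(sprintf("<overhang_report> %s\n",
              if (x$faithful) "faithful" else "NOT faithful"))
  for (f in x$failures) cat("  FAIL:", f, "\n")
  for (w in x$warnings) cat("  warn:", w, "\n")
  invisible(x)
}
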