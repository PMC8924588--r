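#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param topology Topology to assign to every record (FASTA itself does not
#'   record it); a ` [circular]` tag in a record's description overrides.
#' @return Named list of `dna_seq`.
#' @export
read_fasta <- function(path, topology = "linear") {
  set <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    full <- names(set)[i]
    id <- strsplit(full, "\\s+")[[1]][1]
    topo <- if (grepl("\\[circular\\]", full)) "circular" else topology
    out[[id]] <- dna_seq(as.character(set[[i]]), topology = topo, id = id)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Circular sequences get a ` [circular]` description tag so topology
#' round-trips.
#'
#' @param seqs A `dna_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  strings <- vapply(seqs, function(s) s$bases, character(1))
  ids <- vapply(seqs, function(s) {
    base <- if (is.na(s$id)) "unnamed" else s$id
    if (is_circular(s)) paste0(base, " [circular]") else base
  }, character(1))
  set <- Biostrings::DNAStringSet(strings)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# fixed sentinel date so emitted files are byte-reproducible
GENBANK_DATE <- "01-JAN-1980"

#' Write a sequence as a GenBank flat file
#'
#' Minimal but standards-shaped writer: LOCUS line (with topology),
#' `misc_feature` entries with `/label` qualifiers (minus-strand features via
#' `complement(...)`), and the ORIGIN block. The header date is a fixed
#' sentinel so output is byte-reproducible.
#'
#' @param seq A `dna_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path) {
  stopifnot(inherits(seq, "dna_seq"))
  n <- seq_length(seq)
  id <- if (is.na(seq$id)) "UNNAMED" else gsub("\\s", "_", seq$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(id, 1, 16), n,
                     if (is_circular(seq)) "circular" else "linear",
                     GENBANK_DATE), con)
  writeLines(sprintf("DEFINITION  %s.", id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ann <- seq$annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      s1 <- ann$start[i] + 1L
      e1 <- ann$end[i]
      loc <- if (is_circular(seq) && e1 > n) {
        # origin-spanning feature: GenBank join() notation
        sprintf("join(%d..%d,1..%d)", s1, n, e1 - n)
      } else {
        sprintf("%d..%d", s1, e1)
      }
      if (ann$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", ann$label[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  i <- 1L
  while (i <= n) {
    chunk <- substr(seq$bases, i, min(i + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, paste(tolower(blocks), collapse = " ")), con)
    i <- i + 60L
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file written by [write_genbank()]
#'
#' Parses the LOCUS topology, `misc_feature`/`label` annotations (including
#' `complement()` and origin-spanning `join()` locations) and the ORIGIN
#' sequence.
#'
#' @param path GenBank file.
#' @return A `dna_seq`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- lines[grepl("^LOCUS", lines)][1]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line")
  circular <- grepl("circular", locus)
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus)), "\\s+")[[1]][1]

  feat <- list()
  i <- which(grepl("^FEATURES", lines))
  if (length(i)) {
    j <- i + 1L
    while (j <= length(lines) && !grepl("^ORIGIN", lines[j])) {
      ln <- lines[j]
      if (grepl("^\\s{5}misc_feature\\s", ln)) {
        loc <- trimws(sub("^\\s{5}misc_feature\\s+", "", ln))
        lab <- NA_character_
        if (j + 1L <= length(lines) && grepl("/label=", lines[j + 1L])) {
          lab <- sub(".*?/label=\"([^\"]*)\".*", "\\1", lines[j + 1L])
        }
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        if (grepl("^join\\(", loc)) {
          parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
          r1 <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
          r2 <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
          start <- r1[1] - 1L
          end <- NA_integer_  # resolved after sequence length is known
          feat[[length(feat) + 1L]] <- list(label = lab, start = start,
                                            wrap_extra = r2[2], strand = strand)
        } else {
          r <- as.integer(strsplit(loc, "\\.\\.")[[1]])
          feat[[length(feat) + 1L]] <- list(label = lab, start = r[1] - 1L,
                                            end = r[2], strand = strand)
        }
      }
      j <- j + 1L
    }
  }

  oi <- which(grepl("^ORIGIN", lines))
  stopifnot(length(oi) == 1L)
  seq_lines <- lines[(oi + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[^acgtACGT]", "", paste(seq_lines, collapse = "")))
  n <- nchar(bases)

  ann <- empty_annotations()
  for (f in feat) {
    end <- if (!is.null(f$wrap_extra)) n + f$wrap_extra else f$end
    ann <- rbind(ann, data.frame(label = f$label, start = f$start,
                                 end = as.integer(end), strand = f$strand,
                                 stringsAsFactors = FALSE))
  }
  dna_seq(bases, topology = if (circular) "circular" else "linear",
          annotations = ann, id = id)
}
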