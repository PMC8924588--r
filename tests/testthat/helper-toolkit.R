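# shared demo toolkit, generated once per test run
.toolkit_cache <- new.env(parent = emptyenv())

demo_kit <- function(seed = 1001L) {
  key <- as.character(seed)
  if (is.null(.toolkit_cache[[key]])) {
    .toolkit_cache[[key]] <- gen_demo_toolkit(fixture_config(seed = seed))
  }
  .toolkit_cache[[key]]
}

demo_registry <- function(seed = 1001L) demo_kit(seed)$registry

# random sequence as a plain base string
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deterministic motif-free filler
random_seq_fixed <- function(n) {
  substr(strrep("ACGATCAT", ceiling(n / 8)), 1, n)
}

# naive per-base reverse complement, independent of the package internals
naive_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive sliding-window motif scan over the top strand of `s`
naive_find <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  if (m > n) return(integer())
  hits <- integer()
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# a random in-frame CDS (sense codons only) as a plain string
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

canonical_key <- function(bases) yaliclone:::canonical_circle_key(bases)

circle_keys <- function(frags, circles) {
  sort(vapply(circles, function(p) {
    canonical_key(yaliclone:::circle_product(frags, p)$bases)
  }, character(1)))
}
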