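# Internal helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#' @importFrom methods is new validObject slot
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T")

## Coerce to a plain uppercase DNA character string, rejecting anything
## outside the unambiguous DNA alphabet (N allowed only where stated).
.as_dna_chr <- function(x, allow_n = FALSE, what = "sequence") {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (is.character(x) && length(x) == 1L) {
    s <- toupper(x)
  } else {
    stop(what, " must be a DNAString or single character string")
  }
  ok <- .DNA_ALPHABET
  if (allow_n) ok <- c(ok, "N")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), ok)
  if (length(bad)) {
    stop(what, " contains non-DNA characters: ", paste(bad, collapse = ", "))
  }
  s
}

.revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

## Transition partner for each base (A<->G, C<->T).
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## Is the (ref, alt) substitution a transition?
.is_transition <- function(ref, alt) {
  unname(.TRANSITION[ref] == alt)
}

## Longest common prefix / suffix length of two character strings.
.lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- substring(a, seq_len(n), seq_len(n))
  bv <- substring(b, seq_len(n), seq_len(n))
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

.lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  na <- nchar(a); nb <- nchar(b)
  av <- substring(a, na - seq_len(n) + 1L, na - seq_len(n) + 1L)
  bv <- substring(b, nb - seq_len(n) + 1L, nb - seq_len(n) + 1L)
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

## Seeded-RNG evaluation that restores the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## Random DNA of length n at the given GC content.
.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
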