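#' @importFrom methods is
#' @importFrom stats setNames runif
#' @importFrom utils head tail combn
NULL

# IUPAC alphabets (DNA / RNA); ambiguity letters are accepted in backgrounds
# but rejected inside repeats and spacers (see repeat_set(), tigr_unit()).
.DNA_STRICT <- c("A", "C", "G", "T")
.RNA_STRICT <- c("A", "C", "G", "U")
.DNA_IUPAC <- c(.DNA_STRICT, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.RNA_IUPAC <- c(.RNA_STRICT, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.COMP <- c(A = "T", C = "G", G = "C", T = "A",
           R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
           B = "V", D = "H", H = "D", V = "B", N = "N")

#' Nucleotide sequence container
#'
#' Lightweight carrier for a single named DNA or RNA sequence. Input is
#' normalized to uppercase; the alphabet is checked against the declared
#' kind (full IUPAC codes are allowed so genomic backgrounds may contain
#' ambiguity letters). Empty sequences are rejected.
#'
#' @param seq Character scalar, the sequence.
#' @param id Identifier string.
#' @param kind `"dna"` or `"rna"`.
#' @return An object of class `nuc_seq` with fields `id`, `seq`, `kind`.
#' @examples
#' nuc_seq("acgt", "x")
#' @export
nuc_seq <- function(seq, id = "seq", kind = c("dna", "rna")) {
  kind <- match.arg(kind)
  if (is(seq, "nuc_seq")) return(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence rejected")
  alpha <- if (kind == "dna") .DNA_IUPAC else .RNA_IUPAC
  ch <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(ch, alpha)
  if (length(bad)) {
    stop(sprintf("invalid %s letters: %s", toupper(kind),
                 paste(bad, collapse = ", ")))
  }
  structure(list(id = as.character(id), seq = seq, kind = kind),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$seq)
  shown <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(sprintf("<nuc_seq %s> %s  (%d nt, %s)\n", x$kind, x$id, n, shown))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

.seq_chr <- function(x) {
  if (is(x, "nuc_seq")) x$seq else toupper(as.character(x))
}

.chars <- function(x) strsplit(.seq_chr(x), "", fixed = TRUE)[[1L]]

#' Reverse complement
#'
#' Standard reverse complement via Biostrings. IUPAC ambiguity codes pass
#' through the complement table. Plain character input returns character.
#'
#' @param x A `nuc_seq` or character scalar.
#' @return Object of the same type as `x`.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  if (is(x, "nuc_seq")) {
    xs <- if (x$kind == "dna") Biostrings::DNAString(x$seq) else
      Biostrings::RNAString(x$seq)
    nuc_seq(as.character(Biostrings::reverseComplement(xs)),
            id = x$id, kind = x$kind)
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(toupper(x))))
  }
}

# fast internal reverse complement on plain DNA character scalars
.rc <- function(s) {
  paste(rev(.COMP[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Transliterate DNA to RNA (T to U)
#' @param x A `nuc_seq` (dna) or character scalar.
#' @return RNA `nuc_seq` (or character).
#' @examples
#' to_rna("TGGATCGCCA")
#' @export
to_rna <- function(x) {
  if (is(x, "nuc_seq")) {
    if (x$kind == "rna") return(x)
    nuc_seq(chartr("T", "U", x$seq), id = x$id, kind = "rna")
  } else chartr("Tt", "Uu", toupper(x))
}

#' Transliterate RNA to DNA (U to T)
#' @param x A `nuc_seq` (rna) or character scalar.
#' @return DNA `nuc_seq` (or character).
#' @export
to_dna <- function(x) {
  if (is(x, "nuc_seq")) {
    if (x$kind == "dna") return(x)
    nuc_seq(chartr("U", "T", x$seq), id = x$id, kind = "dna")
  } else chartr("Uu", "Tt", toupper(x))
}

#' Random DNA sequence
#'
#' i.i.d. background sequence with an optional GC-bias knob. Uses the
#' current RNG state (seed management is the caller's job; the fixture
#' generators wrap this with an explicit seed).
#'
#' @param n Length in nt.
#' @param gc GC fraction in \[0, 1\] (default 0.5, i.e. uniform).
#' @return Character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Read the first record of a FASTA file as a `nuc_seq`
#' @param file Path to a FASTA file.
#' @param kind `"dna"` or `"rna"`.
#' @return A `nuc_seq`.
#' @export
read_fasta_seq <- function(file, kind = "dna") {
  set <- if (kind == "dna") Biostrings::readDNAStringSet(file) else
    Biostrings::readRNAStringSet(file)
  if (length(set) < 1L) stop("no FASTA records in ", file)
  nuc_seq(as.character(set[[1L]]), id = names(set)[1L], kind = kind)
}

#' Write one or more `nuc_seq` objects to FASTA
#' @param x A `nuc_seq` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(x, file) {
  if (is(x, "nuc_seq")) x <- list(x)
  kinds <- vapply(x, function(s) s$kind, "")
  seqs <- vapply(x, function(s) s$seq, "")
  ids <- vapply(x, function(s) s$id, "")
  set <- if (all(kinds == "rna")) Biostrings::RNAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
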