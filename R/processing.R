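# Maturation of tigRNAs from array models, partial-processing simulation,
# and concordance of observed read boundaries with the processing model.
#
# Processing is modelled as deterministic cuts at `processing_offset` inside
# each full edge repeat (the responsible host RNase is not modelled). Cut
# positions use the "after base i" convention: the integer i means the
# phosphodiester bond between bases i and i+1 of the array body (1-based),
# with 0 = the 5' terminus.

#' Mature tigRNA
#'
#' One 36-nt-class guide: the 3' part of an edge repeat (ending with box C
#' `CCA`), spacer A, the full loop repeat (`UG...CCA`), spacer B, and the
#' 5' part of the next edge repeat (beginning with box D `UG`). Box offsets
#' are 1-based starts of the `CCA` / `UG` motifs within the guide.
#'
#' @param edge_3part,spacer_a,loop,spacer_b,edge_5part RNA segments.
#' @param index Unit ordinal.
#' @return Object of class `tigrna`.
#' @export
tigrna <- function(edge_3part, spacer_a, loop, spacer_b, edge_5part,
                   index = 1L) {
  seg <- c(edge_3part, spacer_a, loop, spacer_b, edge_5part)
  seq <- paste(seg, collapse = "")
  l3 <- nchar(edge_3part); la <- nchar(spacer_a); ll <- nchar(loop)
  lb <- nchar(spacer_b)
  boxC <- c(l3 - 2L, l3 + la + ll - 2L)            # starts of the two CCA
  boxD <- c(l3 + la + 1L, l3 + la + ll + lb + 1L)  # starts of the two UG
  structure(list(index = as.integer(index), edge_3part = edge_3part,
                 spacer_a = spacer_a, loop = loop, spacer_b = spacer_b,
                 edge_5part = edge_5part, seq = seq,
                 boxC_positions = boxC, boxD_positions = boxD),
            class = "tigrna")
}

#' @export
print.tigrna <- function(x, ...) {
  cat(sprintf("<tigrna %d> %s (%d nt; boxC @ %s, boxD @ %s)\n", x$index,
              x$seq, nchar(x$seq), paste(x$boxC_positions, collapse = ","),
              paste(x$boxD_positions, collapse = ",")))
  invisible(x)
}

#' @export
as.character.tigrna <- function(x, ...) x$seq

#' Extract mature tigRNAs from an array model
#'
#' Each of the `n_units` guides is `edge[p+1..] + sA + loop + sB + edge[..p]`
#' transliterated to RNA (length = [unit_period()]), with box C/D anchor
#' positions annotated. Guides are defined by the grammar, so terminal units
#' are completed from the repeat set even if the model's retained edge
#' truncations differ from the processing offset.
#'
#' @param model A [tigr_array_model()].
#' @return List of [tigrna()] objects, one per unit.
#' @export
extract_tigrnas <- function(model) {
  stopifnot(is(model, "tigr_array_model"))
  rs <- model$repeat_set
  p <- rs$processing_offset
  le <- nchar(rs$edge_repeat)
  e3 <- to_rna(substr(rs$edge_repeat, p + 1L, le))
  e5 <- to_rna(substr(rs$edge_repeat, 1L, p))
  loop <- to_rna(rs$loop_repeat)
  lapply(seq_along(model$units), function(i) {
    u <- model$units[[i]]
    tigrna(e3, to_rna(u$spacer_a), loop, to_rna(u$spacer_b), e5, index = i)
  })
}

#' Predicted processing-site set of an array
#'
#' Cut coordinates on the array body: the two termini plus one cut per full
#' edge repeat at the processing offset. With the default truncations
#' (`leading = len(edge) - p`, `trailing = p`) consecutive cuts are exactly
#' one [unit_period()] apart.
#'
#' @param model A [tigr_array_model()].
#' @return Integer vector of cut positions ("after base i", 0 = 5' end),
#'   class `processing_sites`, with attribute `period`.
#' @export
processing_sites <- function(model) {
  rs <- model$repeat_set
  n <- length(model$units)
  P <- unit_period(rs)
  mid <- rs$spacer_len_a + nchar(rs$loop_repeat) + rs$spacer_len_b
  # full edge j (j in 1..n-1) starts after lead + j-th unit interior
  starts <- model$leading_edge_len + mid + (seq_len(max(n - 1L, 0L)) - 1L) * P
  cuts <- c(0L, starts + rs$processing_offset, model_length(model))
  structure(sort(unique(as.integer(cuts))), class = "processing_sites",
            period = P)
}

# internal: simulate fragment intervals (1-based closed) per transcript
.simulate_fragments <- function(model, completeness, n) {
  sites <- unclass(processing_sites(model))
  L <- sites[length(sites)]
  internal <- sites[sites > 0L & sites < L]
  lapply(seq_len(n), function(i) {
    keep <- internal[runif(length(internal)) < completeness]
    b <- c(0L, keep, L)
    data.frame(start = head(b, -1L) + 1L, end = b[-1L])
  })
}

#' Simulate partial processing of array transcripts
#'
#' Each of `n` precursor transcripts is cut independently at every internal
#' processing site with probability `completeness`; termini are always
#' processed. Returns the pooled fragment lengths, which are all multiples
#' of [unit_period()] under default truncations (peaks at 36, 72, 108 nt
#' for the Ta-like set).
#'
#' @param model A [tigr_array_model()].
#' @param completeness Per-site cut probability in \[0, 1\].
#' @param n Number of transcripts.
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return Integer vector of fragment lengths.
#' @export
simulate_partial_processing <- function(model, completeness, n = 1L,
                                        seed = NULL) {
  stopifnot(completeness >= 0, completeness <= 1, n >= 0)
  .with_seed(seed, {
    frags <- .simulate_fragments(model, completeness, n)
    as.integer(unlist(lapply(frags, function(f) f$end - f$start + 1L)))
  })
}

#' Read evidence container
#'
#' Aligned small-RNA read intervals on the array body, 1-based closed.
#' @param start,end Integer vectors of equal length.
#' @return data.frame of class `read_evidence`.
#' @export
read_evidence <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  structure(data.frame(start = as.integer(start), end = as.integer(end)),
            class = c("read_evidence", "data.frame"))
}

#' Read evidence from a BED file of aligned read intervals
#' @param file BED path (0-based half-open; converted to 1-based closed).
#' @return A [read_evidence()].
#' @export
read_evidence_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  read_evidence(GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# reference-space width of a CIGAR string (M/=/X/D/N consume reference);
# kept local so the pinned environment needs no GenomicAlignments
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    w <- 0L
    for (t in toks) {
      op <- substr(t, nchar(t), nchar(t))
      if (op %in% c("M", "=", "X", "D", "N"))
        w <- w + as.integer(substr(t, 1L, nchar(t) - 1L))
    }
    w
  }, 0L, USE.NAMES = FALSE)
}

#' Read evidence from a SAM file (array as reference)
#'
#' The SAM is converted to BAM via Rsamtools and mapped reads are returned
#' as reference intervals (CIGAR-aware for M/=/X/D/N operations).
#'
#' @param file SAM path.
#' @return A [read_evidence()].
#' @export
read_evidence_sam <- function(file) {
  bam <- Rsamtools::asBam(file, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("pos", "cigar")))[[1L]]
  keep <- !is.na(res$pos)
  w <- .cigar_ref_width(res$cigar[keep])
  read_evidence(res$pos[keep], res$pos[keep] + w - 1L)
}

#' Concordance of read boundaries with predicted processing sites
#'
#' Fraction of reads whose start AND end both fall within `tol` nt of a
#' predicted cut. Read interval (start, end) corresponds to cuts at
#' `start - 1` and `end`.
#'
#' @param evidence A [read_evidence()] (or data.frame with start/end).
#' @param sites A [processing_sites()] vector.
#' @param tol Tolerance in nt (>= 0).
#' @return Fraction in \[0, 1\].
#' @export
processing_concordance <- function(evidence, sites, tol = 0L) {
  stopifnot(tol >= 0)
  if (NROW(evidence) == 0L) stop("empty read evidence")
  s <- as.integer(unclass(sites))
  near <- function(x) vapply(x, function(v) min(abs(v - s)) <= tol, NA)
  mean(near(evidence$start - 1L) & near(evidence$end))
}

#' Write tigRNAs to FASTA (RNA alphabet) with box annotations in headers
#' @param tigs List of [tigrna()] objects.
#' @param file Output path.
#' @param prefix Record-name prefix.
#' @return `file`, invisibly.
#' @export
write_tigrna_fasta <- function(tigs, file, prefix = "tigRNA") {
  seqs <- vapply(tigs, `[[`, "", "seq")
  hdr <- vapply(tigs, function(t)
    sprintf("%s%d boxC=%s boxD=%s", prefix, t$index,
            paste(t$boxC_positions, collapse = ","),
            paste(t$boxD_positions, collapse = ",")), "")
  set <- Biostrings::RNAStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}
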