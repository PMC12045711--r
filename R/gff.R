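# GFF3 / BED writers. Coordinates are 1-based closed in GFF3 (standard)
# and converted to 0-based half-open for BED.

#' Convert package objects to GFF3-style GRanges
#'
#' Feature types: `TIGR_array`, `edge_repeat`, `loop_repeat`, `spacer_A`,
#' `spacer_B`, `terminator`, linked through a `Parent` hierarchy.
#'
#' @param x Object ([tigr_array_model()], `tigr_array_call`, or a fixture
#'   locus from [make_locus()]).
#' @param ... Passed on between methods.
#' @return A [GenomicRanges::GRanges] with `type`, `ID`, `Parent` columns.
#' @export
as_gff3 <- function(x, ...) UseMethod("as_gff3")

# local features of an array model along the transcribed strand
.model_features <- function(model, term_len = 0L) {
  rs <- model$repeat_set
  le <- nchar(rs$edge_repeat); ll <- nchar(rs$loop_repeat)
  sla <- rs$spacer_len_a; slb <- rs$spacer_len_b
  mid <- sla + ll + slb
  P <- unit_period(rs)
  n <- length(model$units)
  Lb <- model_length(model)
  rows <- data.frame(start = 1L, end = Lb + term_len, type = "TIGR_array",
                     ID = "array", Parent = NA_character_)
  add <- function(st, en, type, id) {
    rows <<- rbind(rows, data.frame(start = st, end = en, type = type,
                                    ID = id, Parent = "array"))
  }
  if (model$leading_edge_len > 0L)
    add(1L, model$leading_edge_len, "edge_repeat", "edge_lead")
  for (j in seq_len(n)) {
    u0 <- model$leading_edge_len + (j - 1L) * P + 1L
    add(u0, u0 + sla - 1L, "spacer_A", sprintf("spacerA_%d", j))
    add(u0 + sla, u0 + sla + ll - 1L, "loop_repeat",
        sprintf("loop_%d", j))
    add(u0 + sla + ll, u0 + mid - 1L, "spacer_B", sprintf("spacerB_%d", j))
    if (j < n)
      add(u0 + mid, u0 + mid + le - 1L, "edge_repeat",
          sprintf("edge_%d", j))
  }
  if (model$trailing_edge_len > 0L)
    add(Lb - model$trailing_edge_len + 1L, Lb, "edge_repeat", "edge_trail")
  if (term_len > 0L)
    add(Lb + 1L, Lb + term_len, "terminator", "terminator")
  rows
}

.features_to_granges <- function(rows, contig, at, strand, prefix) {
  total <- max(rows$end)
  if (strand == "+") {
    gs <- at + rows$start - 1L
    ge <- at + rows$end - 1L
  } else {
    block_end <- at + total - 1L
    gs <- block_end - rows$end + 1L
    ge <- block_end - rows$start + 1L
  }
  ids <- paste0(prefix, ".", rows$ID)
  parent <- ifelse(is.na(rows$Parent), NA_character_,
                   paste0(prefix, ".", rows$Parent))
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = gs, end = ge),
    strand = strand)
  S4Vectors::mcols(gr)$source <- "tigrkit"
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$Parent <- parent
  gr
}

#' @rdname as_gff3
#' @param contig Sequence name.
#' @param at Genome start (1-based) of the array block.
#' @param strand `"+"` or `"-"`.
#' @param prefix Feature-ID prefix.
#' @export
as_gff3.tigr_array_model <- function(x, contig = "seq", at = 1L,
                                     strand = "+", prefix = "tigr1", ...) {
  term_len <- if (x$has_terminator)
    nchar(terminator_cassette()) else 0L
  .features_to_granges(.model_features(x, term_len), contig, at, strand,
                       prefix)
}

#' @rdname as_gff3
#' @export
as_gff3.tigr_array_call <- function(x, prefix = "tigr1", ...) {
  term_len <- if (!is.null(x$terminator))
    x$terminator$hairpin_end - x$terminator$hairpin_start + 1L else 0L
  m <- x$model
  m$has_terminator <- FALSE  # terminator coordinates come from the call
  gr <- .features_to_granges(.model_features(m, 0L), x$contig,
                             if (x$strand == "+") x$start else x$start,
                             x$strand, prefix)
  gr
}

#' Write GFF3 via rtracklayer
#' @param x A GRanges or an object with an [as_gff3()] method.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gff3 <- function(x, file) {
  gr <- if (is(x, "GRanges")) x else as_gff3(x)
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' Write target sites as BED6 (footprints) plus nick features
#'
#' Footprints go to `file`; if `nick_file` is given, nick positions are
#' written as 1-nt features at the 3' base of the 5' fragment (the base
#' the cut falls after), per strand.
#'
#' @param sites List of `target_site` objects.
#' @param calls Optional parallel list of `cleavage_call` objects.
#' @param file BED output path for footprints.
#' @param nick_file Optional BED output path for nicks.
#' @return `file`, invisibly.
#' @export
write_sites_bed <- function(sites, file, calls = NULL, nick_file = NULL) {
  lines <- vapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    sprintf("%s\t%d\t%d\tsite_%d\t%d\t+", s$contig, s$start - 1L, s$end,
            i, length(s$mismatches_a) + length(s$mismatches_b))
  }, "")
  writeLines(lines, file)
  if (!is.null(nick_file) && !is.null(calls)) {
    nl <- character(0)
    for (i in seq_along(calls)) {
      cl <- calls[[i]]; s <- sites[[i]]
      if (!is.na(cl$nick_a))
        nl <- c(nl, sprintf("%s\t%d\t%d\tnickA_%d\t0\t%s", s$contig,
                            cl$nick_a - 1L, cl$nick_a, i, cl$strand_a))
      if (!is.na(cl$nick_b))
        nl <- c(nl, sprintf("%s\t%d\t%d\tnickB_%d\t0\t%s", s$contig,
                            cl$nick_b - 1L, cl$nick_b, i, cl$strand_b))
    }
    writeLines(nl, nick_file)
  }
  invisible(file)
}
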