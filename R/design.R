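# Design of tigRNAs and minimal expression arrays for user-chosen targets:
# the inverse problem of the tandem dual-strand targeting rule.

#' Enumerate guide candidates against a target region
#'
#' For every footprint window and every gap `0..max_gap`, derives the
#' unique [guide_pair()] whose spacers pair the two strands in the
#' canonical geometry: spacer A is the RNA form of the left top-strand
#' segment (it pairs the bottom strand), spacer B the RNA form of the
#' reverse complement of the right segment (it pairs the top strand).
#' Candidates are flagged (not removed) for homopolymer runs >= 6 nt in a
#' spacer, spacers that themselves look like a box-motif repeat
#' (`TG...CCA`), palindromic spacer pairs (`spacer_a == revcomp(spacer_b)`
#' as DNA, the only case where an expression array can self-target), and a
#' positive [self_target_check()] against the candidate's own construct.
#'
#' @param region DNA sequence (`nuc_seq` or character).
#' @param repeat_set Scaffold [repeat_set()] (default the packaged Ta-like
#'   set); spacer lengths are taken from it.
#' @param max_gap Maximum inter-region gap (default 2).
#' @param n_units Units in the checked expression construct (default 3).
#' @param check_self_target Run [self_target_check()] per candidate
#'   (default TRUE; O(candidates x construct length)).
#' @return List of `design_candidate` objects; see [designs_table()].
#' @export
enumerate_guides <- function(region, repeat_set = ta_like_repeat_set(),
                             max_gap = 2L, n_units = 3L,
                             check_self_target = TRUE) {
  s <- .seq_chr(region)
  L <- nchar(s)
  a <- repeat_set$spacer_len_a; b <- repeat_set$spacer_len_b
  if (L < a + b) stop("region shorter than the minimal footprint")
  out <- list()
  for (g in 0:max_gap) {
    w <- a + g + b
    if (w > L) next
    for (st in seq_len(L - w + 1L)) {
      left <- substr(s, st, st + a - 1L)
      right <- substr(s, st + a + g, st + w - 1L)
      if (grepl("[^ACGT]", left) || grepl("[^ACGT]", right)) next
      spa <- left              # DNA form of spacer A
      spb <- .rc(right)        # DNA form of spacer B
      guide <- guide_pair(to_rna(spa), to_rna(spb))
      construct <- build_expression_array(guide, repeat_set,
                                          n_units = n_units)
      flags <- list(
        homopolymer = grepl("A{6}|C{6}|G{6}|T{6}", spa) ||
          grepl("A{6}|C{6}|G{6}|T{6}", spb),
        box_like = grepl("^TG.*CCA$", spa) || grepl("^TG.*CCA$", spb),
        palindromic = identical(spa, .rc(spb)),
        self_target = if (check_self_target)
          self_target_check(guide, construct$seq) else NA)
      out[[length(out) + 1L]] <- structure(
        list(guide = guide, start = st, end = st + w - 1L, gap = g,
             construct = construct, flags = flags),
        class = "design_candidate")
    }
  }
  out
}

#' Summarize design candidates as a data.frame
#' @param candidates List of `design_candidate` objects.
#' @return data.frame, one row per candidate.
#' @export
designs_table <- function(candidates) {
  if (!length(candidates)) return(data.frame())
  data.frame(
    start = vapply(candidates, `[[`, 0L, "start"),
    end = vapply(candidates, `[[`, 0L, "end"),
    gap = vapply(candidates, `[[`, 0L, "gap"),
    spacer_a = vapply(candidates, function(c) c$guide$spacer_a, ""),
    spacer_b = vapply(candidates, function(c) c$guide$spacer_b, ""),
    homopolymer = vapply(candidates, function(c) c$flags$homopolymer, NA),
    box_like = vapply(candidates, function(c) c$flags$box_like, NA),
    palindromic = vapply(candidates, function(c) c$flags$palindromic, NA),
    self_target = vapply(candidates, function(c)
      as.logical(c$flags$self_target), NA))
}

#' Build a minimal expression array for a guide
#'
#' Assembles a [tigr_array_model()] with `n_units` identical units carrying
#' the guide's spacers (the minimized-array strategy: an array of one to
#' three identical units is processed into identical tigRNAs), optionally
#' followed by the terminator cassette.
#'
#' @param guide A [guide_pair()].
#' @param repeat_set Scaffold [repeat_set()].
#' @param n_units Number of identical units (default 3).
#' @param with_terminator Append the terminator cassette (default TRUE).
#' @return List of class `expression_construct`: `seq` (DNA [nuc_seq()]),
#'   `model`, `body_len`.
#' @export
build_expression_array <- function(guide, repeat_set = ta_like_repeat_set(),
                                   n_units = 3L, with_terminator = TRUE) {
  spa <- chartr("U", "T", guide$spacer_a)
  spb <- chartr("U", "T", guide$spacer_b)
  if (nchar(spa) != repeat_set$spacer_len_a ||
      nchar(spb) != repeat_set$spacer_len_b)
    stop("guide spacer lengths do not match the repeat set")
  model <- tigr_array_model(repeat_set,
                            rep(spa, n_units), rep(spb, n_units),
                            has_terminator = isTRUE(with_terminator))
  seqv <- assemble_array(model, id = "expression_array")
  structure(list(seq = seqv, model = model,
                 body_len = attr(seqv, "body_len")),
            class = "expression_construct")
}

#' @export
print.expression_construct <- function(x, ...) {
  cat(sprintf("<expression_construct> %d units, body %d nt%s\n",
              length(x$model$units), x$body_len,
              if (x$model$has_terminator) " + terminator" else ""))
  invisible(x)
}
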