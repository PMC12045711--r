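# Core TIGR array grammar: repeats, spacers, units, boundaries, and the
# lossless assembly/parsing between array models and nucleotide sequence.
#
# A dual-repeat TIGR array reads, on the transcribed strand:
#   edge[p+1..] sA1 loop sB1 edge sA2 loop sB2 edge ... sAn loop sBn edge[..p]
# i.e. it begins with a 5'-truncated edge repeat and ends with a 3'-truncated
# edge repeat (optionally followed by a rho-independent terminator). The
# mature guide (tigRNA) spans mid-edge to mid-edge: one full repeat period.

.check_repeat <- function(x, what) {
  x <- toupper(x)
  n <- nchar(x)
  if (n < 8L || n > 12L)
    stop(what, " length must be 8-12 nt, got ", n)
  if (grepl("[^ACGT]", x))
    stop(what, " must be unambiguous DNA (A/C/G/T)")
  x
}

#' Repeat set of a dual-repeat TIGR array
#'
#' The full repeat "genotype" of a locus: the edge and loop repeat sequences
#' (DNA, 8-12 nt each, transcribed-strand orientation), the spacer lengths,
#' and the processing offset, i.e. the position inside the edge repeat at
#' which the maturation cut falls. When `enforce_boxes = TRUE` both repeats
#' must begin with box D (`TG` on the coding strand, `UG` in RNA) and end
#' with box C (`CCA`).
#'
#' @param edge_repeat,loop_repeat DNA strings, 8-12 nt.
#' @param spacer_len_a,spacer_len_b Spacer lengths, 8-12 nt (default 9).
#' @param processing_offset Cut position inside the edge repeat,
#'   `1 <= p < nchar(edge_repeat)`; defaults to `floor(len(edge)/2)` so the
#'   mature unit spans exactly one period ("middle of an edge repeat").
#' @param enforce_boxes Require the box C/D grammar on both repeats.
#' @return Object of class `repeat_set`.
#' @examples
#' rs <- ta_like_repeat_set()
#' unit_period(rs)
#' @export
repeat_set <- function(edge_repeat, loop_repeat,
                       spacer_len_a = 9L, spacer_len_b = 9L,
                       processing_offset = NULL, enforce_boxes = TRUE) {
  edge_repeat <- .check_repeat(edge_repeat, "edge_repeat")
  loop_repeat <- .check_repeat(loop_repeat, "loop_repeat")
  spacer_len_a <- as.integer(spacer_len_a)
  spacer_len_b <- as.integer(spacer_len_b)
  if (spacer_len_a < 8L || spacer_len_a > 12L ||
      spacer_len_b < 8L || spacer_len_b > 12L)
    stop("spacer lengths must be 8-12 nt")
  le <- nchar(edge_repeat)
  if (is.null(processing_offset)) processing_offset <- le %/% 2L
  processing_offset <- as.integer(processing_offset)
  if (processing_offset < 1L || processing_offset >= le)
    stop("processing_offset must be strictly inside the edge repeat")
  if (isTRUE(enforce_boxes)) {
    for (r in c(edge = edge_repeat, loop = loop_repeat)) {
      if (!startsWith(r, "TG") || !endsWith(r, "CCA"))
        stop("with enforce_boxes, repeats must start 'TG' (box D) and end ",
             "'CCA' (box C); offending repeat: ", r)
    }
  }
  structure(list(edge_repeat = edge_repeat, loop_repeat = loop_repeat,
                 spacer_len_a = spacer_len_a, spacer_len_b = spacer_len_b,
                 processing_offset = processing_offset,
                 enforce_boxes = isTRUE(enforce_boxes)),
            class = "repeat_set")
}

#' @export
print.repeat_set <- function(x, ...) {
  cat(sprintf(paste0("<repeat_set> edge %s (%d nt)  loop %s (%d nt)\n",
                     "  spacers %d+%d nt, processing offset %d, boxes %s\n"),
              x$edge_repeat, nchar(x$edge_repeat),
              x$loop_repeat, nchar(x$loop_repeat),
              x$spacer_len_a, x$spacer_len_b, x$processing_offset,
              if (x$enforce_boxes) "enforced" else "free"))
  invisible(x)
}

#' Repeat period of an array (= mature guide length)
#'
#' `len(edge) + len(loop) + spacer_len_a + spacer_len_b`. For the packaged
#' Ta-like set (edge 10, loop 8, spacers 9+9) this is 36 nt, the mature
#' tigRNA length.
#'
#' @param repeat_set A [repeat_set()].
#' @return Integer period in nt.
#' @export
unit_period <- function(repeat_set) {
  stopifnot(is(repeat_set, "repeat_set"))
  nchar(repeat_set$edge_repeat) + nchar(repeat_set$loop_repeat) +
    repeat_set$spacer_len_a + repeat_set$spacer_len_b
}

#' One TIGR unit (a spacer pair)
#'
#' @param index 1-based ordinal within the array.
#' @param spacer_a,spacer_b Unambiguous DNA strings.
#' @param repeat_set Optional [repeat_set()] to validate lengths against.
#' @return Object of class `tigr_unit`.
#' @export
tigr_unit <- function(index, spacer_a, spacer_b, repeat_set = NULL) {
  spacer_a <- toupper(spacer_a); spacer_b <- toupper(spacer_b)
  if (grepl("[^ACGT]", spacer_a) || grepl("[^ACGT]", spacer_b))
    stop("spacers must be unambiguous DNA (no ambiguity codes)")
  if (!is.null(repeat_set)) {
    if (nchar(spacer_a) != repeat_set$spacer_len_a ||
        nchar(spacer_b) != repeat_set$spacer_len_b)
      stop("spacer lengths do not match the repeat set")
  }
  structure(list(index = as.integer(index), spacer_a = spacer_a,
                 spacer_b = spacer_b), class = "tigr_unit")
}

#' Full model of a dual-repeat TIGR array
#'
#' @param repeat_set A [repeat_set()].
#' @param spacers_a,spacers_b Character vectors of per-unit spacers (equal
#'   length, >= 1 unit).
#' @param leading_edge_len Edge-repeat nt retained at the array 5' end
#'   (default `len(edge) - processing_offset`).
#' @param trailing_edge_len Edge-repeat nt retained at the 3' end
#'   (default `processing_offset`).
#' @param has_terminator Append a rho-independent terminator cassette when
#'   assembling.
#' @return Object of class `tigr_array_model`.
#' @export
tigr_array_model <- function(repeat_set, spacers_a, spacers_b,
                             leading_edge_len = NULL,
                             trailing_edge_len = NULL,
                             has_terminator = FALSE) {
  stopifnot(is(repeat_set, "repeat_set"))
  spacers_a <- toupper(spacers_a); spacers_b <- toupper(spacers_b)
  n <- length(spacers_a)
  if (n < 1L || length(spacers_b) != n)
    stop("need >= 1 unit and equal numbers of A and B spacers")
  units <- lapply(seq_len(n), function(i)
    tigr_unit(i, spacers_a[i], spacers_b[i], repeat_set))
  le <- nchar(repeat_set$edge_repeat)
  p <- repeat_set$processing_offset
  if (is.null(leading_edge_len)) leading_edge_len <- le - p
  if (is.null(trailing_edge_len)) trailing_edge_len <- p
  leading_edge_len <- as.integer(leading_edge_len)
  trailing_edge_len <- as.integer(trailing_edge_len)
  if (leading_edge_len < 0L || leading_edge_len > le ||
      trailing_edge_len < 0L || trailing_edge_len > le)
    stop("edge truncation lengths must lie within the edge repeat")
  structure(list(repeat_set = repeat_set, units = units,
                 leading_edge_len = leading_edge_len,
                 trailing_edge_len = trailing_edge_len,
                 has_terminator = isTRUE(has_terminator)),
            class = "tigr_array_model")
}

#' @export
print.tigr_array_model <- function(x, ...) {
  cat(sprintf("<tigr_array_model> %d units, body %d nt (lead %d / trail %d)%s\n",
              length(x$units), model_length(x), x$leading_edge_len,
              x$trailing_edge_len,
              if (x$has_terminator) " + terminator" else ""))
  invisible(x)
}

#' Number of units in an array model
#' @param model A [tigr_array_model()].
#' @return Integer.
#' @export
n_units <- function(model) length(model$units)

#' Assembled array body length (terminator excluded)
#'
#' `leading + trailing + sum(unit spacers + loop) + (n-1) * len(edge)`;
#' equals `n_units * unit_period` when `leading + trailing = len(edge)`.
#'
#' @param model A [tigr_array_model()].
#' @return Integer length in nt.
#' @export
model_length <- function(model) {
  rs <- model$repeat_set
  n <- length(model$units)
  model$leading_edge_len + model$trailing_edge_len +
    n * (rs$spacer_len_a + nchar(rs$loop_repeat) + rs$spacer_len_b) +
    (n - 1L) * nchar(rs$edge_repeat)
}

#' Default rho-independent terminator cassette
#'
#' A perfect 8-bp GC stem, 4-nt loop and 7-nt U-tract (T in DNA). The stem's
#' first base can be forced away from a given base so that greedy
#' truncated-edge boundary inference never extends into the terminator.
#'
#' @param avoid_first Optional single base the cassette must not start with.
#' @return DNA character scalar.
#' @export
terminator_cassette <- function(avoid_first = NULL) {
  stem <- "GCGCCGGC"
  if (!is.null(avoid_first) && startsWith(stem, toupper(avoid_first)))
    stem <- "CGCGGCCG"
  paste0(stem, "TTCG", .rc(stem), "TTTTTTT")
}

#' Assemble a model into transcribed-strand DNA
#'
#' Concatenates `edge[p+1..] + (sA + loop + sB + edge) x (n-1) + sA + loop +
#' sB + edge[..p]` (with the configured truncation lengths), then the
#' terminator cassette if `has_terminator`. Deterministic.
#'
#' @param model A [tigr_array_model()].
#' @param id Identifier for the returned sequence.
#' @return A DNA [nuc_seq()] with attribute `body_len` (array body length,
#'   terminator excluded).
#' @export
assemble_array <- function(model, id = "tigr_array") {
  stopifnot(is(model, "tigr_array_model"))
  rs <- model$repeat_set
  edge <- rs$edge_repeat; loop <- rs$loop_repeat
  le <- nchar(edge)
  lead <- if (model$leading_edge_len > 0L)
    substr(edge, le - model$leading_edge_len + 1L, le) else ""
  trail <- if (model$trailing_edge_len > 0L)
    substr(edge, 1L, model$trailing_edge_len) else ""
  n <- length(model$units)
  mids <- vapply(model$units, function(u)
    paste0(u$spacer_a, loop, u$spacer_b), "")
  body <- paste0(lead, paste(mids, collapse = edge), trail)
  # paste(collapse=edge) inserts the full edge repeat between interior units
  stopifnot(nchar(body) == model_length(model))
  seqstr <- body
  if (model$has_terminator) {
    nxt <- if (model$trailing_edge_len < le)
      substr(edge, model$trailing_edge_len + 1L, model$trailing_edge_len + 1L)
      else NULL
    seqstr <- paste0(body, terminator_cassette(avoid_first = nxt))
  }
  out <- nuc_seq(seqstr, id = id, kind = "dna")
  attr(out, "body_len") <- nchar(body)
  out
}

# vectorized mismatch counts of `pattern` against every offset of `chars`
# (plain character vector); returns integer vector over starts 1..L-w+1
.slide_mm <- function(chars, pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  w <- length(pc)
  L <- length(chars)
  if (L < w) return(integer(0))
  ns <- L - w + 1L
  mm <- integer(ns)
  for (k in seq_len(w)) mm <- mm + (chars[k:(k + ns - 1L)] != pc[k])
  mm
}

#' Parse a sequence into a TIGR array model
#'
#' Given a known [repeat_set()], locates the alternating repeat copies
#' (allowing up to `max_mismatch_per_copy` substitutions per copy), infers
#' the spacers between them and the truncated edge boundaries, and records
#' per-copy mismatch counts. The input should be the array region (flanking
#' background is tolerated; truncation inference is exact-match greedy).
#'
#' @param x Sequence (`nuc_seq` or character) containing >= 1 unit.
#' @param repeat_set The locus [repeat_set()].
#' @param max_mismatch_per_copy Substitutions tolerated per repeat copy.
#' @return A [tigr_array_model()] with a `parse` element carrying `start`,
#'   `end` (1-based closed, array body), `loop_mismatches` and
#'   `edge_mismatches` per copy.
#' @export
parse_array <- function(x, repeat_set, max_mismatch_per_copy = 0L) {
  stopifnot(is(repeat_set, "repeat_set"))
  s <- .seq_chr(x)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  rs <- repeat_set
  loop <- rs$loop_repeat; edge <- rs$edge_repeat
  ll <- nchar(loop); le <- nchar(edge)
  sla <- rs$spacer_len_a; slb <- rs$spacer_len_b
  P <- unit_period(rs)
  mm <- .slide_mm(ch, loop)
  cand <- which(mm <= max_mismatch_per_copy)
  if (!length(cand))
    stop("parse failure: no loop repeat copy found (best has ",
         if (length(mm)) min(mm) else NA, " mismatches)")
  # loops occur at an exact arithmetic progression with difference P;
  # take the longest chain (leftmost on ties)
  candset <- logical(length(mm)); candset[cand] <- TRUE
  best <- NULL
  for (p0 in cand) {
    if (p0 - P >= 1L && candset[p0 - P]) next  # not a chain head
    chain <- p0
    nxt <- p0 + P
    while (nxt <= length(candset) && candset[nxt]) {
      chain <- c(chain, nxt)
      nxt <- nxt + P
    }
    if (is.null(best) || length(chain) > length(best)) best <- chain
  }
  loops <- best
  ecount <- function(p) {
    seg <- substr(s, p, p + le - 1L)
    if (nchar(seg) < le) return(le)
    sum(strsplit(seg, "")[[1L]] != strsplit(edge, "")[[1L]])
  }
  edge_mm_of <- function(lp) {
    if (length(lp) > 1L) vapply(lp[-length(lp)] + ll + slb, ecount, 0L)
    else integer(0)
  }
  edge_mm <- edge_mm_of(loops)
  # a chance loop-like match one period beyond a boundary produces a chain
  # element with no consistent edge beside it: trim boundary units, but
  # treat interior inconsistency as a parse failure
  while (length(loops) >= 2L && edge_mm[1L] > max_mismatch_per_copy) {
    loops <- loops[-1L]
    edge_mm <- edge_mm_of(loops)
  }
  while (length(loops) >= 2L &&
         edge_mm[length(edge_mm)] > max_mismatch_per_copy) {
    loops <- loops[-length(loops)]
    edge_mm <- edge_mm_of(loops)
  }
  n <- length(loops)
  if (any(edge_mm > max_mismatch_per_copy))
    stop("parse failure: no consistent alternating repeat placement ",
         "(edge copy mismatches: ", paste(edge_mm, collapse = ","),
         " at tolerance ", max_mismatch_per_copy, ")")
  loop_mm <- mm[loops]
  if (loops[1L] - sla < 1L || loops[n] + ll + slb - 1L > length(ch))
    stop("parse failure: first/last spacer extends beyond the sequence")
  spacers_a <- vapply(loops, function(p) substr(s, p - sla, p - 1L), "")
  spacers_b <- vapply(loops, function(p)
    substr(s, p + ll, p + ll + slb - 1L), "")
  # greedy exact-match truncated-edge boundaries
  lead <- 0L
  while (lead < le) {
    pos <- loops[1L] - sla - lead - 1L
    if (pos < 1L || ch[pos] != substr(edge, le - lead, le - lead)) break
    lead <- lead + 1L
  }
  trail <- 0L
  after <- loops[n] + ll + slb
  while (trail < le) {
    pos <- after + trail
    if (pos > length(ch) || ch[pos] != substr(edge, trail + 1L, trail + 1L))
      break
    trail <- trail + 1L
  }
  start <- loops[1L] - sla - lead
  end <- after + trail - 1L
  term <- NULL
  if (end < length(ch)) {
    term <- predict_terminator(s, window = c(end + 1L,
                                             min(length(ch), end + 60L)))
  }
  model <- tigr_array_model(rs, spacers_a, spacers_b,
                            leading_edge_len = lead,
                            trailing_edge_len = trail,
                            has_terminator = !is.null(term))
  model$parse <- list(start = start, end = end,
                      loop_mismatches = as.integer(loop_mm),
                      edge_mismatches = as.integer(edge_mm),
                      terminator = term)
  model
}

#' Test whether two array models describe the same array
#'
#' Compares repeat set, spacers, truncations and the terminator flag
#' (ignoring parse diagnostics).
#' @param a,b [tigr_array_model()] objects.
#' @return Logical.
#' @export
same_array_model <- function(a, b) {
  isTRUE(all.equal(a$repeat_set, b$repeat_set)) &&
    length(a$units) == length(b$units) &&
    all(vapply(a$units, `[[`, "", "spacer_a") ==
          vapply(b$units, `[[`, "", "spacer_a")) &&
    all(vapply(a$units, `[[`, "", "spacer_b") ==
          vapply(b$units, `[[`, "", "spacer_b")) &&
    a$leading_edge_len == b$leading_edge_len &&
    a$trailing_edge_len == b$trailing_edge_len &&
    a$has_terminator == b$has_terminator
}

#' Write / read a repeat set as a flat key-value config
#' @param rs A [repeat_set()].
#' @param file Path.
#' @return `file` (write) or a [repeat_set()] (read).
#' @export
write_repeat_config <- function(rs, file) {
  stopifnot(is(rs, "repeat_set"))
  lines <- c(
    paste0("edge_repeat=", rs$edge_repeat),
    paste0("loop_repeat=", rs$loop_repeat),
    paste0("spacer_len_a=", rs$spacer_len_a),
    paste0("spacer_len_b=", rs$spacer_len_b),
    paste0("processing_offset=", rs$processing_offset),
    paste0("enforce_boxes=", rs$enforce_boxes))
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_repeat_config
#' @export
read_repeat_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  repeat_set(vals[["edge_repeat"]], vals[["loop_repeat"]],
             as.integer(vals[["spacer_len_a"]]),
             as.integer(vals[["spacer_len_b"]]),
             as.integer(vals[["processing_offset"]]),
             as.logical(vals[["enforce_boxes"]]))
}
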