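# Seed-deterministic synthetic-data generators: ground-truthed TIGR loci,
# target genomes and read evidence, so every module is testable without
# external data. All generators restore the caller's RNG state.
#
# Identifiability guarantees (see the methods vignette): planted truth must
# be recoverable exactly, so make_locus (i) pins the background base 5' of
# the array and the first terminator base so greedy truncated-edge
# inference stops exactly at the planted boundary, and (ii) constrains
# spacer columns so no column is near-unanimous across units and the
# first/last spacer columns never repeat between adjacent units. These are
# properties of the stated world, not tuning knobs.

.BASES <- c("A", "C", "G", "T")

#' The packaged Ta-like repeat set
#'
#' Edge 10 nt, loop 8 nt (A-rich interior), spacers 9+9 nt, processing
#' offset 5: the unit period is 36 nt, the canonical mature tigRNA length.
#' The repeat sequences are synthetic but grammar-conformant (box D `TG`
#' start, box C `CCA` end).
#'
#' @return A [repeat_set()].
#' @export
ta_like_repeat_set <- function() {
  repeat_set("TGCAGTGCCA", "TGAAACCA", 9L, 9L, processing_offset = 5L,
             enforce_boxes = TRUE)
}

#' Generate a random grammar-conformant repeat set
#'
#' Both repeats begin `TG` and end `CCA`; the loop interior is A-rich
#' (fraction >= 0.6), mirroring the tetraloop-like loop repeat.
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param edge_len,loop_len Repeat lengths, 8-12 nt.
#' @param spacer_len_a,spacer_len_b Spacer lengths, 8-12 nt.
#' @return A [repeat_set()].
#' @export
make_repeat_set <- function(seed, edge_len = 10L, loop_len = 8L,
                            spacer_len_a = 9L, spacer_len_b = 9L) {
  .with_seed(seed, {
    repeat {
      e_int <- paste(sample(.BASES, edge_len - 5L, replace = TRUE),
                     collapse = "")
      l_int <- paste(sample(.BASES, loop_len - 5L, replace = TRUE,
                            prob = c(0.7, 0.1, 0.1, 0.1)), collapse = "")
      # enforce the A-rich loop interior
      lch <- strsplit(l_int, "")[[1L]]
      while (mean(lch == "A") < 0.6) {
        idx <- which(lch != "A")
        lch[idx[sample.int(length(idx), 1L)]] <- "A"
      }
      l_int <- paste(lch, collapse = "")
      edge <- paste0("TG", e_int, "CCA")
      loop <- paste0("TG", l_int, "CCA")
      if (edge != loop) break
    }
    repeat_set(edge, loop, spacer_len_a, spacer_len_b,
               processing_offset = edge_len %/% 2L, enforce_boxes = TRUE)
  })
}

# enforce spacer-column identifiability across units (see file header)
.fix_spacer_matrix <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(m)
  cap <- ceiling(n / 2)
  for (iter in 1:25) {
    changed <- FALSE
    for (cc in seq_len(ncol(m))) {
      tb <- table(m[, cc])
      while (max(tb) > cap) {
        maj <- names(tb)[which.max(tb)]
        j <- which(m[, cc] == maj)[1L]
        m[j, cc] <- sample(setdiff(.BASES, maj), 1L)
        tb <- table(m[, cc])
        changed <- TRUE
      }
    }
    for (cc in c(1L, ncol(m))) {
      for (j in seq_len(n - 1L)) {
        if (m[j, cc] == m[j + 1L, cc]) {
          m[j + 1L, cc] <- sample(setdiff(.BASES, m[j, cc]), 1L)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m
}

.sample_spacers <- function(n, len) {
  m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
  m <- .fix_spacer_matrix(m)
  apply(m, 1L, paste, collapse = "")
}

#' Generate a ground-truthed dual-repeat TIGR locus
#'
#' Builds an array with random spacers (identifiability-constrained, see
#' package docs), default edge truncations and a terminator, embeds it at
#' a recorded offset in i.i.d. random background, and optionally injects
#' recorded substitutions into every loop-repeat copy.
#'
#' The documented default parameters (Ta-like repeat set, 8 units, 2 kb
#' background) define the packaged default fixture locus.
#'
#' @param seed Integer seed.
#' @param repeat_set A [repeat_set()] (default [ta_like_repeat_set()]).
#' @param n_units Units (default 8; natural arrays most often have 5-15).
#' @param background_len Total genome length (default 2000).
#' @param per_copy_mutations Substitutions injected into each loop copy
#'   (default 0), positions recorded in the truth.
#' @param gc Background GC fraction (default 0.5).
#' @return List of class `tigr_locus_fixture`: `seq` (genome
#'   [nuc_seq()]), `start`/`end` (array body), `strand`, `model`,
#'   `repeat_set`, `mutations`, `terminator` interval, `gff`, `seed`.
#' @export
make_locus <- function(seed, repeat_set = ta_like_repeat_set(),
                       n_units = 8L, background_len = 2000L,
                       per_copy_mutations = 0L, gc = 0.5) {
  .with_seed(seed, {
    rs <- repeat_set
    sa <- .sample_spacers(n_units, rs$spacer_len_a)
    sb <- .sample_spacers(n_units, rs$spacer_len_b)
    model <- tigr_array_model(rs, sa, sb, has_terminator = TRUE)
    arr <- assemble_array(model)
    body_len <- attr(arr, "body_len")
    total <- nchar(arr$seq)
    if (background_len < total + 120L)
      stop("background too short for the array")
    margin <- 50L
    offset <- sample(margin:(background_len - total - margin), 1L)
    bg <- random_dna(background_len, gc)
    arr_s <- arr$seq
    # inject recorded loop-copy mutations
    mut <- data.frame(copy = integer(), loop_pos = integer(),
                      genome_pos = integer(), from = character(),
                      to = character())
    if (per_copy_mutations > 0L) {
      P <- unit_period(rs)
      ll <- nchar(rs$loop_repeat)
      ach <- strsplit(arr_s, "")[[1L]]
      for (j in seq_len(n_units)) {
        l0 <- model$leading_edge_len + (j - 1L) * P + rs$spacer_len_a
        pos <- sample(seq_len(ll), per_copy_mutations)
        for (pp in pos) {
          ap <- l0 + pp
          from <- ach[ap]
          to <- sample(setdiff(.BASES, from), 1L)
          ach[ap] <- to
          mut <- rbind(mut, data.frame(
            copy = j, loop_pos = pp, genome_pos = offset + ap - 1L,
            from = from, to = to))
        }
      }
      arr_s <- paste(ach, collapse = "")
    }
    pre <- substr(bg, 1L, offset - 1L)
    post <- substr(bg, offset + total, background_len)
    # pin the flanking base so greedy edge-truncation inference is exact
    p <- rs$processing_offset
    guard <- substr(rs$edge_repeat, p, p)
    if (substr(pre, nchar(pre), nchar(pre)) == guard) {
      substr(pre, nchar(pre), nchar(pre)) <-
        sample(setdiff(.BASES, guard), 1L)
    }
    gch <- strsplit(paste0(pre, arr_s, post), "")[[1L]]
    start <- offset
    end <- offset + body_len - 1L
    # guard against chance loop-like matches exactly one period beyond
    # either boundary, which would let a chain-based parser annex a
    # phantom unit (the flanking half of the phantom edge copy matches
    # the truncated edge by construction, so the loop window is the only
    # stochastic part)
    P <- unit_period(rs)
    ll2 <- nchar(rs$loop_repeat)
    loop1 <- start + model$leading_edge_len + rs$spacer_len_a
    lch <- strsplit(rs$loop_repeat, "")[[1L]]
    term_end <- offset + total - 1L
    term_loop <- (end + nchar("GCGCCGGC") + 1L):(end + nchar("GCGCCGGC") +
                                                   4L)
    for (ph in c(loop1 - P, loop1 + n_units * P)) {
      if (ph < 1L || ph + ll2 - 1L > length(gch)) next
      idx <- ph:(ph + ll2 - 1L)
      while (sum(gch[idx] != lch) < 3L) {
        # free positions: background, or the terminator's 4-nt loop
        free <- idx[(idx < start - 1L | idx > term_end | idx %in%
                       term_loop) & gch[idx] == lch]
        if (!length(free)) break
        pp <- free[1L]
        gch[pp] <- sample(setdiff(.BASES, c(gch[pp],
                                            lch[which(idx == pp)])), 1L)
      }
    }
    genome <- nuc_seq(paste(gch, collapse = ""), id = "fixture_locus")
    gff <- as_gff3(model, contig = genome$id, at = start, strand = "+",
                   prefix = "tigr1")
    structure(list(seq = genome, start = start, end = end, strand = "+",
                   model = model, repeat_set = rs, mutations = mut,
                   terminator = c(end + 1L, offset + total - 1L),
                   gff = gff, seed = seed),
              class = "tigr_locus_fixture")
  })
}

#' @export
print.tigr_locus_fixture <- function(x, ...) {
  cat(sprintf(paste0("<tigr_locus_fixture seed %s> array %d-%d (+) in %d nt",
                     " background, %d units, %d mutations\n"),
              x$seed, x$start, x$end, nchar(x$seq$seq),
              length(x$model$units), nrow(x$mutations)))
  invisible(x)
}

#' Generate a ground-truthed stem-loop TIGR locus
#'
#' Each unit is `arm + spacer A + loop + spacer B + revcomp(arm)` with the
#' arm ending in box C (`CCA`, so the right arm begins `TGG`) and the loop
#' a `TG...CCA` repeat; arms vary per unit but are consistently
#' palindromic. Units are joined by short random linkers; sub-arrays are
#' separated by long intergenic linkers (default ~450 nt, mirroring the
#' 13-units-in-3-subarrays organization). Optionally breaks the palindrome
#' of chosen units (recorded) so they drop out of detection.
#'
#' @param seed Integer seed.
#' @param subarray_sizes Units per sub-array (default `c(5, 4, 4)`).
#' @param arm_len Palindromic arm length (default 7).
#' @param spacer_len,loop_len Spacer / loop-repeat lengths.
#' @param unit_linker_range Range of intra-subarray linker lengths.
#' @param subarray_linker Inter-subarray linker length (default 450).
#' @param flank Background flank length on each side (default 200).
#' @param break_palindromy_in Integer vector of unit indices whose right
#'   arm is mutated to break the stem (default none).
#' @return List of class `stem_loop_fixture`: `seq`, `units` (truth
#'   data.frame), `subarray` assignment, `broken`, `seed`.
#' @export
make_stem_loop_locus <- function(seed, subarray_sizes = c(5L, 4L, 4L),
                                 arm_len = 7L, spacer_len = 9L,
                                 loop_len = 8L,
                                 unit_linker_range = c(15L, 30L),
                                 subarray_linker = 450L, flank = 200L,
                                 break_palindromy_in = integer(0)) {
  .with_seed(seed, {
    n <- sum(subarray_sizes)
    loop_int <- paste(sample(.BASES, loop_len - 5L, replace = TRUE,
                             prob = c(0.7, 0.1, 0.1, 0.1)), collapse = "")
    loop <- paste0("TG", loop_int, "CCA")
    mk_unit <- function() {
      arm <- paste0(paste(sample(.BASES, arm_len - 3L, replace = TRUE),
                          collapse = ""), "CCA")
      sa <- paste(sample(.BASES, spacer_len, replace = TRUE), collapse = "")
      sb <- paste(sample(.BASES, spacer_len, replace = TRUE), collapse = "")
      list(arm = arm, sa = sa, sb = sb,
           seq = paste0(arm, sa, loop, sb, .rc(arm)))
    }
    units <- replicate(n, mk_unit(), simplify = FALSE)
    subarray <- rep(seq_along(subarray_sizes), subarray_sizes)
    pieces <- character(0)
    starts <- integer(n)
    pos <- flank + 1L
    pieces <- random_dna(flank)
    for (i in seq_len(n)) {
      starts[i] <- pos
      pieces <- paste0(pieces, units[[i]]$seq)
      pos <- pos + nchar(units[[i]]$seq)
      if (i < n) {
        ln <- if (subarray[i + 1L] != subarray[i]) subarray_linker else
          sample(unit_linker_range[1L]:unit_linker_range[2L], 1L)
        pieces <- paste0(pieces, random_dna(ln))
        pos <- pos + ln
      }
    }
    pieces <- paste0(pieces, random_dna(flank))
    s <- pieces
    ends <- starts + vapply(units, function(u) nchar(u$seq), 0L) - 1L
    # pin the bases flanking each unit so the maximal palindrome stops
    # exactly at the planted arm (truth identifiability)
    ch0 <- strsplit(s, "")[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (i in seq_len(n)) {
      lf <- starts[i] - 1L; rf <- ends[i] + 1L
      if (lf >= 1L && rf <= length(ch0) &&
          comp[[ch0[lf]]] == ch0[rf]) {
        ch0[rf] <- sample(setdiff(.BASES, comp[[ch0[lf]]]), 1L)
      }
    }
    s <- paste(ch0, collapse = "")
    # break chosen palindromes: mutate right-arm bases 4 and 5 (counted
    # from the TGG box outward) to their transversions
    broken <- intersect(break_palindromy_in, seq_len(n))
    if (length(broken)) {
      ch <- strsplit(s, "")[[1L]]
      transv <- c(A = "T", T = "A", G = "C", C = "G")
      for (i in broken) {
        r0 <- starts[i] + arm_len + 2L * spacer_len + loop_len
        for (off in c(3L, 4L)) ch[r0 + off] <- transv[[ch[r0 + off]]]
      }
      s <- paste(ch, collapse = "")
    }
    truth <- data.frame(unit = seq_len(n), start = starts, end = ends,
                        subarray = subarray,
                        arm = vapply(units, `[[`, "", "arm"),
                        spacer_a = vapply(units, `[[`, "", "sa"),
                        spacer_b = vapply(units, `[[`, "", "sb"))
    structure(list(seq = nuc_seq(s, id = "stem_loop_locus"),
                   units = truth, loop = loop, broken = broken,
                   seed = seed),
              class = "stem_loop_fixture")
  })
}

.TRANSV <- c(A = "T", T = "A", G = "C", C = "G")

#' Generate a ground-truthed target genome for a guide
#'
#' Plants canonical-geometry sites (perfect, gapped, or with specified
#' per-position transversion mismatches) at non-overlapping recorded
#' positions in i.i.d. random background. The generator verifies with
#' [brute_force_find_sites()] that the perfect, gap-tolerant planted sites
#' are the only such sites in the genome, resampling the background if a
#' spurious site arises.
#'
#' @param seed Integer seed.
#' @param guide A [guide_pair()].
#' @param n_sites Number of planted sites.
#' @param gaps Integer vector of gaps (recycled over sites).
#' @param mismatch_spec Optional data.frame with columns `site`, `region`
#'   ("A"/"B") and `index` (spacer base, 1 = box-C-proximal): a
#'   transversion is applied to the DNA base pairing that spacer base.
#' @param background_len Genome length (default 10000).
#' @param gc Background GC fraction.
#' @param max_tries Background resampling budget (default 25).
#' @return List of class `target_genome_fixture`: `seq`, `sites` (truth
#'   data.frame with `start`, `end`, `gap`, `n_mismatches`), `guide`,
#'   `seed`.
#' @export
make_target_genome <- function(seed, guide, n_sites = 1L, gaps = 0L,
                               mismatch_spec = NULL,
                               background_len = 10000L, gc = 0.5,
                               max_tries = 25L) {
  stopifnot(is(guide, "guide_pair"))
  .with_seed(seed, {
    a <- nchar(guide$spacer_a); b <- nchar(guide$spacer_b)
    dnaA <- chartr("U", "T", guide$spacer_a)
    dnaB <- chartr("U", "T", guide$spacer_b)
    gaps <- rep_len(as.integer(gaps), n_sites)
    segs <- character(n_sites)
    n_mm <- integer(n_sites)
    for (i in seq_len(n_sites)) {
      g <- gaps[i]
      seg <- paste0(dnaA, random_dna(g), .rc(dnaB))
      if (!is.null(mismatch_spec)) {
        spec <- mismatch_spec[mismatch_spec$site == i, , drop = FALSE]
        n_mm[i] <- nrow(spec)
        if (nrow(spec)) {
          ch <- strsplit(seg, "")[[1L]]
          w <- a + g + b
          for (r in seq_len(nrow(spec))) {
            k <- spec$index[r]
            pos <- if (spec$region[r] == "A") k else w - k + 1L
            ch[pos] <- .TRANSV[[ch[pos]]]
          }
          seg <- paste(ch, collapse = "")
        }
      }
      segs[i] <- seg
    }
    widths <- nchar(segs)
    for (try in seq_len(max_tries)) {
      bg <- random_dna(background_len, gc)
      # spread the sites over the genome with generous margins
      slot <- (background_len - 200L) %/% max(n_sites, 1L)
      if (n_sites > 0L && slot < max(widths) + 50L)
        stop("background too short")
      starts <- integer(n_sites)
      ok <- TRUE
      for (i in seq_len(n_sites)) {
        lo <- 100L + (i - 1L) * slot
        hi <- lo + slot - widths[i] - 10L
        if (hi < lo) { ok <- FALSE; break }
        starts[i] <- if (hi == lo) lo else sample(lo:hi, 1L)
      }
      if (!ok) next
      ch <- strsplit(bg, "")[[1L]]
      for (i in seq_len(n_sites)) {
        ch[starts[i]:(starts[i] + widths[i] - 1L)] <-
          strsplit(segs[i], "")[[1L]]
      }
      genome <- paste(ch, collapse = "")
      found <- brute_force_find_sites(genome, guide, max_gap = 2L,
                                      max_mm = 0L)
      expected <- sort(starts[gaps <= 2L & n_mm == 0L])
      if (identical(sort(vapply(found, `[[`, 0L, "start")), expected)) {
        truth <- data.frame(start = starts, end = starts + widths - 1L,
                            gap = gaps, n_mismatches = n_mm)
        return(structure(list(seq = nuc_seq(genome, id = "target_genome"),
                              sites = truth, guide = guide, seed = seed),
                         class = "target_genome_fixture"))
      }
    }
    stop("could not generate a spurious-site-free background in ",
         max_tries, " tries")
  })
}

#' Simulate aligned small-RNA read intervals from an array
#'
#' Fragments follow [simulate_partial_processing()]; optional uniform
#' boundary jitter emulates imprecise read ends. Truth (unjittered
#' intervals) is retained as an attribute.
#'
#' @param model A [tigr_array_model()].
#' @param completeness Per-site cut probability.
#' @param n Number of transcripts.
#' @param boundary_jitter Maximum uniform jitter per boundary, nt
#'   (default 0).
#' @param seed Integer seed.
#' @return A [read_evidence()] data.frame with attribute `truth`.
#' @export
make_reads <- function(model, completeness, n, boundary_jitter = 0L,
                       seed = NULL) {
  .with_seed(seed, {
    frags <- do.call(rbind, .simulate_fragments(model, completeness, n))
    truth <- frags
    L <- model_length(model)
    if (boundary_jitter > 0L) {
      j <- boundary_jitter
      frags$start <- pmax(1L, pmin(L, frags$start +
                                     sample(-j:j, nrow(frags), TRUE)))
      frags$end <- pmax(frags$start,
                        pmin(L, frags$end + sample(-j:j, nrow(frags), TRUE)))
    }
    ev <- read_evidence(frags$start, frags$end)
    attr(ev, "truth") <- truth
    ev
  })
}

#' Write read evidence as BED (0-based half-open)
#' @param ev A [read_evidence()].
#' @param file Output path.
#' @param contig Reference name (default "array").
#' @return `file`, invisibly.
#' @export
write_reads_bed <- function(ev, file, contig = "array") {
  writeLines(sprintf("%s\t%d\t%d\tread_%d\t0\t+", contig, ev$start - 1L,
                     ev$end, seq_len(nrow(ev))), file)
  invisible(file)
}
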