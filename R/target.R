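# Tandem dual-strand target-site search and cleavage-geometry prediction.
#
# Geometry. A guide's two spacers pair the two strands of a contiguous dsDNA
# footprint: one spacer pairs the bottom strand over the left region, the
# other pairs the top strand over the right region, with 0..max_gap bp
# between the duplex regions. Spacer base 1 (box-C-proximal) pairs the
# region's distal (outer) DNA base. Both assignments (A-left or B-left) are
# physical sites and are scanned; because the RNP is C2-pseudosymmetric each
# physical site is reported once in top-strand coordinates.
#
# Cleavage (C-5 rule). Each matched strand is nicked 5' of the DNA base that
# pairs spacer base 5 (the 5th guide base downstream of box C). For the
# left ("-" strand) region that bond lies after top-strand base
# region_start + 4; for the right ("+" strand) region after base
# region_end - 5. A perfect 9+9 zero-gap site therefore yields a DSB with
# 8-nt 3' overhangs; gapped sites give 8 + gap (model extrapolation).

#' Guide pair
#'
#' The two spacers of a tigRNA, the minimal information needed for
#' targeting. Accepts RNA or DNA letters; stored as RNA.
#'
#' @param spacer_a,spacer_b Spacer sequences (8-12 nt, unambiguous).
#' @param id Optional source tigRNA id.
#' @return Object of class `guide_pair`.
#' @examples
#' guide_pair("ACGUACGUA", "GGAUCCGGA")
#' @export
guide_pair <- function(spacer_a, spacer_b, id = NULL) {
  norm <- function(s, what) {
    s <- chartr("Tt", "Uu", toupper(as.character(s)))
    if (grepl("[^ACGU]", s)) stop(what, " contains ambiguity codes")
    if (nchar(s) < 8L || nchar(s) > 12L)
      stop(what, " length must be 8-12 nt")
    s
  }
  structure(list(spacer_a = norm(spacer_a, "spacer_a"),
                 spacer_b = norm(spacer_b, "spacer_b"),
                 id = id), class = "guide_pair")
}

#' @export
print.guide_pair <- function(x, ...) {
  cat(sprintf("<guide_pair%s> A: %s  B: %s\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$spacer_a, x$spacer_b))
  invisible(x)
}

#' Swap spacer A and B of a guide
#' @param guide A [guide_pair()].
#' @return A [guide_pair()].
#' @export
swap_spacers <- function(guide) {
  guide_pair(guide$spacer_b, guide$spacer_a, id = guide$id)
}

.target_site <- function(contig, start, end, gap, left_len, assignA_left,
                         mm_left, mm_right, seqstr) {
  left <- list(start = start, end = start + left_len - 1L, strand = "-")
  right <- list(start = start + left_len + gap, end = end, strand = "+")
  if (assignA_left) {
    region_a <- left; region_b <- right
    mm_a <- mm_left; mm_b <- mm_right
  } else {
    region_a <- right; region_b <- left
    mm_a <- mm_right; mm_b <- mm_left
  }
  structure(list(contig = contig, start = start, end = end, gap = gap,
                 region_a = region_a, region_b = region_b,
                 mismatches_a = as.integer(mm_a),
                 mismatches_b = as.integer(mm_b),
                 arrangement = if (assignA_left) "A_left" else "B_left",
                 seq = seqstr),
            class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf(
    "<target_site> %s:%d-%d gap %d (%s)  mmA=[%s] mmB=[%s]  %s\n",
    x$contig, x$start, x$end, x$gap, x$arrangement,
    paste(x$mismatches_a, collapse = ","),
    paste(x$mismatches_b, collapse = ","), x$seq))
  invisible(x)
}

#' Summarize a list of target sites as a data.frame
#' @param sites List of `target_site` objects.
#' @return data.frame with one row per site.
#' @export
sites_table <- function(sites) {
  if (!length(sites)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), gap = integer(),
                      arrangement = character(), mm_a = character(),
                      mm_b = character()))
  }
  data.frame(
    contig = vapply(sites, `[[`, "", "contig"),
    start = vapply(sites, `[[`, 0L, "start"),
    end = vapply(sites, `[[`, 0L, "end"),
    gap = vapply(sites, `[[`, 0L, "gap"),
    arrangement = vapply(sites, `[[`, "", "arrangement"),
    mm_a = vapply(sites, function(s)
      paste(s$mismatches_a, collapse = ","), ""),
    mm_b = vapply(sites, function(s)
      paste(s$mismatches_b, collapse = ","), ""))
}

# pairing predicate helpers ---------------------------------------------

# For a spacer pairing the BOTTOM strand over the left region, Watson-Crick
# pairing at spacer base k is equivalent to top-strand base == DNA(spacer_k).
# For the TOP strand (right region), it is top == complement(DNA(spacer_k)).
# Wobble (off by default) additionally allows rG:dT and rU:dG.

.mm_left_indices <- function(top_chars, spacer_rna, wobble) {
  sp <- strsplit(chartr("U", "T", spacer_rna), "", fixed = TRUE)[[1L]]
  ok <- top_chars == sp
  if (wobble) {
    rna <- strsplit(spacer_rna, "", fixed = TRUE)[[1L]]
    # spacer G : bottom T  => top A ; spacer U : bottom G => top C
    ok <- ok | (rna == "G" & top_chars == "A") |
      (rna == "U" & top_chars == "C")
  }
  which(!ok)
}

.mm_right_indices <- function(top_chars, spacer_rna, wobble) {
  # spacer base k pairs the top base k positions in from the right edge
  sp <- strsplit(chartr("U", "T", spacer_rna), "", fixed = TRUE)[[1L]]
  comp <- .COMP[sp]
  topk <- rev(top_chars)  # topk[k] = top base pairing spacer base k
  ok <- topk == comp
  if (wobble) {
    rna <- strsplit(spacer_rna, "", fixed = TRUE)[[1L]]
    ok <- ok | (rna == "G" & topk == "T") | (rna == "U" & topk == "G")
  }
  which(!ok)
}

#' Find tandem dual-strand target sites for a guide on dsDNA
#'
#' Returns all loci where one spacer is Watson-Crick complementary
#' (antiparallel, at most `max_mm_per_region` mismatches) to one strand over
#' a contiguous region and the other spacer to the opposite strand over an
#' adjacent region separated by `0..max_gap` bp, each spacer's base 1
#' pairing the distal end of its region. Each physical site is reported
#' once, in canonical top-strand coordinates, sorted by coordinate.
#'
#' @param genome DNA sequence (`nuc_seq` or character).
#' @param guide A [guide_pair()].
#' @param max_gap Maximum gap between the two duplex regions (default 2,
#'   the experimentally tolerated bound).
#' @param max_mm_per_region Mismatches tolerated per spacer region.
#' @param wobble Allow G:U wobble pairing (default FALSE).
#' @return List of `target_site` objects (empty list when none).
#' @examples
#' g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
#' find_sites(paste0(strrep("T", 10), "ACGTACGTATCCGGATCC"), g)
#' @export
find_sites <- function(genome, guide, max_gap = 2L, max_mm_per_region = 0L,
                       wobble = FALSE) {
  stopifnot(is(guide, "guide_pair") || inherits(guide, "guide_pair"))
  gs <- .seq_chr(genome)
  contig <- if (is(genome, "nuc_seq")) genome$id else "seq"
  ch <- strsplit(gs, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  a <- nchar(guide$spacer_a); b <- nchar(guide$spacer_b)
  if (L < a + b) return(list())
  dnaA <- chartr("U", "T", guide$spacer_a)
  dnaB <- chartr("U", "T", guide$spacer_b)
  sites <- list()
  seen <- character(0)
  for (arr in c("A_left", "B_left")) {
    lsp <- if (arr == "A_left") guide$spacer_a else guide$spacer_b
    rsp <- if (arr == "A_left") guide$spacer_b else guide$spacer_a
    ldna <- chartr("U", "T", lsp)
    # left-region pattern: top == dna(spacer); right-region pattern:
    # top segment == revcomp(dna(spacer))
    rpat <- .rc(chartr("U", "T", rsp))
    wl <- nchar(ldna); wr <- nchar(rpat)
    mmL_all <- if (wobble) NULL else .slide_mm(ch, ldna)
    mmR_all <- if (wobble) NULL else .slide_mm(ch, rpat)
    for (g in 0:max_gap) {
      w <- wl + g + wr
      if (L < w) next
      ns <- L - w + 1L
      if (!wobble) {
        mmL <- mmL_all[seq_len(ns)]
        mmR <- mmR_all[seq_len(ns) + wl + g]
        hits <- which(mmL <= max_mm_per_region & mmR <= max_mm_per_region)
      } else {
        hits <- integer(0)
        for (s in seq_len(ns)) {
          il <- .mm_left_indices(ch[s:(s + wl - 1L)], lsp, TRUE)
          ir <- .mm_right_indices(ch[(s + wl + g):(s + w - 1L)], rsp, TRUE)
          if (length(il) <= max_mm_per_region &&
              length(ir) <= max_mm_per_region) hits <- c(hits, s)
        }
      }
      for (s in hits) {
        key <- paste(s, s + w - 1L, sep = ":")
        if (key %in% seen) next  # palindromic double-assignment: report once
        seen <- c(seen, key)
        il <- .mm_left_indices(ch[s:(s + wl - 1L)], lsp, wobble)
        ir <- .mm_right_indices(ch[(s + wl + g):(s + w - 1L)], rsp, wobble)
        sites[[length(sites) + 1L]] <- .target_site(
          contig, s, s + w - 1L, g, wl, assignA_left = (arr == "A_left"),
          mm_left = il, mm_right = ir,
          seqstr = substr(gs, s, s + w - 1L))
      }
    }
  }
  ord <- order(vapply(sites, `[[`, 0L, "start"),
               vapply(sites, `[[`, 0L, "end"))
  sites[ord]
}

#' Brute-force oracle for [find_sites()]
#'
#' Naive enumeration of every offset, gap and strand assignment, checking
#' antiparallel Watson-Crick pairing base by base with an explicit
#' complement table. Independent of the [find_sites()] code path; must
#' return the identical site set on all inputs.
#'
#' @inheritParams find_sites
#' @param max_mm Mismatches tolerated per spacer region.
#' @return List of `target_site` objects.
#' @export
brute_force_find_sites <- function(genome, guide, max_gap = 2L,
                                   max_mm = 0L) {
  gs <- .seq_chr(genome)
  contig <- if (is(genome, "nuc_seq")) genome$id else "seq"
  L <- nchar(gs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_wc <- function(rna_base, dna_base) {
    dna_of_rna <- c(A = "A", C = "C", G = "G", U = "T")[[rna_base]]
    # antiparallel WC: the matched-strand base must be the complement of
    # the spacer base's DNA transliteration
    identical(dna_base, comp[[dna_of_rna]])
  }
  out <- list()
  seen <- character(0)
  for (s in seq_len(L)) {
    for (g in 0:max_gap) {
      for (arr in c("A_left", "B_left")) {
        lsp <- strsplit(if (arr == "A_left") guide$spacer_a else
          guide$spacer_b, "")[[1L]]
        rsp <- strsplit(if (arr == "A_left") guide$spacer_b else
          guide$spacer_a, "")[[1L]]
        wl <- length(lsp); wr <- length(rsp)
        e <- s + wl + g + wr - 1L
        if (e > L) next
        # left region: spacer pairs the bottom strand; bottom base at top
        # position x is comp(top[x]); spacer base k pairs position s+k-1
        mml <- integer(0)
        for (k in seq_len(wl)) {
          topb <- substr(gs, s + k - 1L, s + k - 1L)
          if (!pairs_wc(lsp[k], comp[[topb]])) mml <- c(mml, k)
        }
        if (length(mml) > max_mm) next
        # right region: spacer pairs the top strand; spacer base k pairs
        # the k-th base in from the right (outer) edge
        mmr <- integer(0)
        for (k in seq_len(wr)) {
          topb <- substr(gs, e - k + 1L, e - k + 1L)
          if (!pairs_wc(rsp[k], topb)) mmr <- c(mmr, k)
        }
        if (length(mmr) > max_mm) next
        key <- paste(s, e, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- .target_site(
          contig, s, e, g, wl, assignA_left = (arr == "A_left"),
          mm_left = mml, mm_right = mmr, seqstr = substr(gs, s, e))
      }
    }
  }
  ord <- order(vapply(out, `[[`, 0L, "start"),
               vapply(out, `[[`, 0L, "end"))
  out[ord]
}

#' Mismatch-tolerance rule table
#'
#' Spacer-base index sets (1 = box-C-proximal) governing cleavage: `seed`
#' positions are the DNA bases immediately 3' of the cut (mismatch there
#' abolishes cleavage of both strands); `nickase` positions immediately 5'
#' of the cut impair only the mismatched strand; simultaneous mismatches at
#' both `edge5` positions of one region abolish cleavage. Positions not
#' listed are tolerated singly.
#'
#' @param seed_positions Default `c(4, 5)`.
#' @param nickase_positions Default `c(6, 7)`.
#' @param edge5_positions Default `c(8, 9)`.
#' @return Object of class `mismatch_model`.
#' @export
mismatch_model <- function(seed_positions = c(4L, 5L),
                           nickase_positions = c(6L, 7L),
                           edge5_positions = c(8L, 9L)) {
  sets <- list(seed = as.integer(seed_positions),
               nickase = as.integer(nickase_positions),
               edge5 = as.integer(edge5_positions))
  all <- unlist(sets)
  if (anyDuplicated(all)) stop("mismatch position sets must be disjoint")
  structure(sets, class = "mismatch_model")
}

#' Predict cleavage outcome and geometry at a target site
#'
#' Applies the C-5 rule (each matched strand nicked 5' of the DNA base
#' pairing spacer base 5) and the mismatch rule table to classify the site
#' as a double-strand break, a single nick, or no cleavage. For a DSB the
#' central 3' single-stranded overhang is reported (length
#' `a + b + gap - 10`, i.e. 8 + gap for 9+9 spacers).
#'
#' @param site A `target_site` from [find_sites()].
#' @param model A [mismatch_model()].
#' @return Object of class `cleavage_call` with fields `outcome` (one of
#'   `"dsb"`, `"nick_A_strand"`, `"nick_B_strand"`, `"none"`),
#'   `nick_a`/`nick_b` ("after base i" top-strand coordinates of the nick
#'   on the strand matched by spacer A / B, NA when uncleaved),
#'   `overhang_len` and `overhang_seq` (top-strand, DSB only).
#' @export
predict_cleavage <- function(site, model = mismatch_model()) {
  stopifnot(is(site, "target_site"), is(model, "mismatch_model"))
  len_a <- site$region_a$end - site$region_a$start + 1L
  len_b <- site$region_b$end - site$region_b$start + 1L
  if (length(site$mismatches_a) && max(site$mismatches_a) > len_a)
    stop("mismatch index exceeds spacer A length")
  if (length(site$mismatches_b) && max(site$mismatches_b) > len_b)
    stop("mismatch index exceeds spacer B length")
  nick_at <- function(region) {
    if (region$strand == "-") region$start + 4L else region$end - 5L
  }
  nick_a <- nick_at(site$region_a)  # nick on the strand matched by spacer A
  nick_b <- nick_at(site$region_b)
  seed_hit <- any(site$mismatches_a %in% model$seed) ||
    any(site$mismatches_b %in% model$seed)
  edge5_dead <- (length(model$edge5) > 0L &&
                   all(model$edge5 %in% site$mismatches_a)) ||
    (length(model$edge5) > 0L && all(model$edge5 %in% site$mismatches_b))
  a_cleaved <- !any(site$mismatches_a %in% model$nickase)
  b_cleaved <- !any(site$mismatches_b %in% model$nickase)
  if (seed_hit || edge5_dead) {
    a_cleaved <- FALSE; b_cleaved <- FALSE
  }
  outcome <- if (a_cleaved && b_cleaved) "dsb"
  else if (a_cleaved) "nick_A_strand"
  else if (b_cleaved) "nick_B_strand"
  else "none"
  overhang_len <- NA_integer_; overhang_seq <- NA_character_
  if (outcome == "dsb") {
    p_left <- min(nick_a, nick_b)   # nick of the "-" (left) region
    p_right <- max(nick_a, nick_b)  # nick of the "+" (right) region
    overhang_len <- p_right - p_left
    overhang_seq <- substr(site$seq, p_left - site$start + 2L,
                           p_right - site$start + 1L)
  }
  structure(list(outcome = outcome,
                 nick_a = if (a_cleaved) nick_a else NA_integer_,
                 nick_b = if (b_cleaved) nick_b else NA_integer_,
                 strand_a = site$region_a$strand,
                 strand_b = site$region_b$strand,
                 overhang_len = overhang_len, overhang_seq = overhang_seq),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat(sprintf("<cleavage_call> %s  nickA after %s (%s)  nickB after %s (%s)",
              x$outcome, x$nick_a, x$strand_a, x$nick_b, x$strand_b))
  if (!is.na(x$overhang_len))
    cat(sprintf("  3' overhang %d nt (%s)", x$overhang_len, x$overhang_seq))
  cat("\n")
  invisible(x)
}

#' Gap-tolerance scan
#'
#' For each requested gap, reports whether a site with that inter-region
#' gap is found by [find_sites()] (which enforces the tolerated `max_gap`)
#' and classified as a DSB. Planted sites with gaps beyond `max_gap` are
#' not sites at all and come back non-cleavable.
#'
#' @param genome DNA sequence containing planted sites.
#' @param guide A [guide_pair()].
#' @param gaps Integer vector of gaps to interrogate (default 0:6).
#' @param max_gap Gap tolerance passed to [find_sites()] (default 2).
#' @param model A [mismatch_model()].
#' @return data.frame with columns `gap`, `cleavable`.
#' @export
gap_scan <- function(genome, guide, gaps = 0:6, max_gap = 2L,
                     model = mismatch_model()) {
  sites <- find_sites(genome, guide, max_gap = max_gap)
  calls <- lapply(sites, predict_cleavage, model = model)
  site_gaps <- vapply(sites, `[[`, 0L, "gap")
  dsb <- vapply(calls, function(cl) cl$outcome == "dsb", NA)
  data.frame(gap = as.integer(gaps),
             cleavable = vapply(as.integer(gaps), function(g)
               any(site_gaps == g & dsb), NA))
}

#' Scan single-stranded DNA for independent per-spacer matches
#'
#' Each spacer is matched independently against the single strand
#' (antiparallel Watson-Crick; a matching segment read 5'->3' equals the
#' reverse complement of the spacer's DNA form). Nicks follow the same C-5
#' placement: 5' of the base pairing spacer base 5, reported as "after
#' base i" in strand coordinates. RNA input yields no matches.
#'
#' @param x Single-stranded sequence (`nuc_seq`; kind `"rna"` gives 0 hits).
#' @param guide A [guide_pair()].
#' @param max_mm Mismatches tolerated (default 0).
#' @return data.frame with columns `spacer` ("A"/"B"), `start`, `end`,
#'   `nick_after`.
#' @export
ssdna_scan <- function(x, guide, max_mm = 0L) {
  empty <- data.frame(spacer = character(), start = integer(),
                      end = integer(), nick_after = integer())
  if (is(x, "nuc_seq") && x$kind == "rna") return(empty)
  s <- .seq_chr(x)
  if (!nzchar(s)) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  res <- empty
  for (nm in c("A", "B")) {
    sp <- if (nm == "A") guide$spacer_a else guide$spacer_b
    pat <- .rc(chartr("U", "T", sp))
    n <- nchar(pat)
    if (length(ch) < n) next
    mm <- .slide_mm(ch, pat)
    hits <- which(mm <= max_mm)
    if (length(hits)) {
      res <- rbind(res, data.frame(
        spacer = nm, start = hits, end = hits + n - 1L,
        # spacer base 5 pairs segment base n-4; nick 5' of it
        nick_after = hits + n - 6L))
    }
  }
  res[order(res$start), , drop = FALSE]
}

#' Relaxed-mismatch off-target scan
#'
#' Composition of [find_sites()] (with relaxed per-region mismatches) and
#' [predict_cleavage()], ranked by predicted outcome severity
#' (dsb > nick > none), then total mismatches, then coordinate.
#'
#' @inheritParams find_sites
#' @param model A [mismatch_model()].
#' @return List with elements `summary` (ranked data.frame), `sites`,
#'   `calls` (parallel lists in ranked order).
#' @export
off_target_scan <- function(genome, guide, max_mm_per_region = 2L,
                            max_gap = 2L, model = mismatch_model()) {
  sites <- find_sites(genome, guide, max_gap = max_gap,
                      max_mm_per_region = max_mm_per_region)
  calls <- lapply(sites, predict_cleavage, model = model)
  if (!length(sites))
    return(list(summary = data.frame(), sites = list(), calls = list()))
  sev <- vapply(calls, function(cl)
    switch(cl$outcome, dsb = 3L, nick_A_strand = 2L, nick_B_strand = 2L,
           none = 1L), 0L)
  tot <- vapply(sites, function(st)
    length(st$mismatches_a) + length(st$mismatches_b), 0L)
  starts <- vapply(sites, `[[`, 0L, "start")
  ord <- order(-sev, tot, starts)
  df <- sites_table(sites)[ord, , drop = FALSE]
  df$outcome <- vapply(calls, `[[`, "", "outcome")[ord]
  df$total_mismatches <- tot[ord]
  rownames(df) <- NULL
  list(summary = df, sites = sites[ord], calls = calls[ord])
}

#' Does a guide target a given construct (e.g. its own expression array)?
#'
#' `TRUE` iff [find_sites()] reports at least one site on the construct.
#' Because the two spacers are encoded in tandem on the same strand of
#' their own array, a guide does not form the dual-strand arrangement
#' against it: TIGR systems avoid self-targeting without needing a TAM/PAM.
#' Palindromic spacers (`spacer_a == revcomp(spacer_b)` as DNA) are the
#' corner case where self-targeting can occur; [enumerate_guides()] flags
#' such designs.
#'
#' @param guide A [guide_pair()].
#' @param construct_seq DNA sequence of the construct.
#' @return Logical.
#' @export
self_target_check <- function(guide, construct_seq) {
  length(find_sites(construct_seq, guide, max_gap = 2L,
                    max_mm_per_region = 0L)) > 0L
}
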