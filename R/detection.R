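# De novo detection of dual-repeat and stem-loop TIGR arrays, terminator
# annotation, consensus building and box-motif covariation analysis.
#
# Dual-repeat detection contract: find maximal regions where k-mers recur at
# a near-constant period within `period_range`; resolve the recurring
# elements into exactly two alternating repeat families; refine repeat
# boundaries against cross-copy identity; extend to the truncated edge
# copies at both array boundaries. Seeding uses exact k-mer periodicity
# (repeats are near-identical within a locus), so a family whose every copy
# is mutated is invisible to the seed; such a family is recovered from the
# cross-copy consensus of the inter-copy segments instead.

#' Detection parameters
#'
#' @param k Seed k-mer length (default 7).
#' @param period_range Allowed repeat period, nt (default c(30, 50)).
#' @param repeat_len_range Allowed repeat lengths (default c(8, 12)).
#' @param spacer_len_range Allowed spacer lengths (default c(8, 12)).
#' @param min_units Minimum units per call (default 3).
#' @param max_mismatch_per_copy Substitutions tolerated per repeat copy
#'   (default 2).
#' @param scan_both_strands Default TRUE.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(k = 7L, period_range = c(30L, 50L),
                             repeat_len_range = c(8L, 12L),
                             spacer_len_range = c(8L, 12L),
                             min_units = 3L, max_mismatch_per_copy = 2L,
                             scan_both_strands = TRUE) {
  if (period_range[1L] < 2L * repeat_len_range[1L] +
      2L * spacer_len_range[1L] - 2L)  # small slack below exact minimum
    stop("period_range inconsistent with repeat/spacer ranges")
  structure(list(k = as.integer(k),
                 period_range = as.integer(period_range),
                 repeat_len_range = as.integer(repeat_len_range),
                 spacer_len_range = as.integer(spacer_len_range),
                 min_units = as.integer(min_units),
                 max_mismatch_per_copy = as.integer(max_mismatch_per_copy),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "detection_params")
}

# ---- internal helpers -------------------------------------------------

.majority_consensus <- function(copies) {
  m <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  }), collapse = "")
}

.count_mm <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

# extend a run of period-P copies outward from a known copy position
.copy_run <- function(s, pos0, width, P, cons, max_mm) {
  L <- nchar(s)
  grab <- function(p) substr(s, p, p + width - 1L)
  ok <- function(p) p >= 1L && p + width - 1L <= L &&
    .count_mm(grab(p), cons) <= max_mm
  if (!ok(pos0)) return(integer(0))
  pos <- pos0
  p <- pos0 - P
  while (ok(p)) { pos <- c(p, pos); p <- p - P }
  p <- pos0 + P
  while (ok(p)) { pos <- c(pos, p); p <- p + P }
  pos
}

# circular runs of TRUE phases; returns list of c(start_phase0, width)
.circular_arcs <- function(keep) {
  P <- length(keep)
  if (all(keep)) return(list(c(0L, P)))
  if (!any(keep)) return(list())
  # rotate so position 1 is FALSE, then take linear runs
  off <- which(!keep)[1L]
  rot <- keep[c(off:P, seq_len(off - 1L))]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  arcs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    ph <- ((starts[i] - 1L) + (off - 1L)) %% P
    arcs[[length(arcs) + 1L]] <- c(ph, r$lengths[i])
  }
  arcs
}

# evaluate one (period, seed-hit cluster) candidate on strand-local chars;
# returns an unpolished call (list) or NULL
.evaluate_candidate <- function(s, ch, P, hits, params) {
  k <- params$k
  L <- length(ch)
  rng_r <- params$repeat_len_range
  rng_s <- params$spacer_len_range
  max_mm <- params$max_mismatch_per_copy
  cov <- sort(unique(c(outer(hits, 0:(k - 1L), "+"),
                       outer(hits + P, 0:(k - 1L), "+"))))
  cov <- cov[cov >= 1L & cov <= L]
  anchor <- cov[1L]
  counts <- tabulate(((cov - anchor) %% P) + 1L, nbins = P)
  thr <- max(2L, ceiling(0.5 * max(counts)))
  keep <- counts >= thr
  arcs <- .circular_arcs(keep)
  if (!length(arcs)) return(NULL)
  widths <- vapply(arcs, `[`, 0L, 2L)
  if (max(widths) > rng_r[2L]) return(NULL)  # low-complexity / not a repeat
  totals <- vapply(arcs, function(a)
    sum(counts[(a[1L] + seq_len(a[2L]) - 1L) %% P + 1L]), 0)
  arcs <- arcs[order(-totals)]
  fam <- list()
  build_family <- function(phi, width) {
    # collect seeded copies congruent to anchor+phi, overlapping coverage
    base <- anchor + ((phi - 0L) %% P)
    jr <- seq(floor((1L - base) / P), ceiling((L - base) / P))
    pos <- base + jr * P
    pos <- pos[pos >= 1L & pos + width - 1L <= L]
    covset <- logical(L); covset[cov] <- TRUE
    seeded <- pos[vapply(pos, function(p)
      any(covset[p:(p + width - 1L)]), NA)]
    if (length(seeded) < 2L) return(NULL)
    cons <- .majority_consensus(vapply(seeded, function(p)
      substr(s, p, p + width - 1L), ""))
    mmv <- vapply(seeded, function(p)
      .count_mm(substr(s, p, p + width - 1L), cons), 0L)
    run <- .copy_run(s, seeded[which.min(mmv)], width, P, cons, max_mm)
    if (length(run) < 2L) return(NULL)
    cons <- .majority_consensus(vapply(run, function(p)
      substr(s, p, p + width - 1L), ""))
    run <- .copy_run(s, run[1L], width, P, cons, max_mm)
    list(phi = phi %% P, width = width, cons = cons, pos = run)
  }
  f1 <- build_family(arcs[[1L]][1L], arcs[[1L]][2L])
  if (is.null(f1) || f1$width < rng_r[1L]) return(NULL)
  f2 <- NULL
  if (length(arcs) >= 2L && arcs[[2L]][2L] >= rng_r[1L]) {
    cand <- build_family(arcs[[2L]][1L], arcs[[2L]][2L])
    if (!is.null(cand)) {
      gap1 <- (cand$phi - (f1$phi + f1$width)) %% P
      gap2 <- (f1$phi - (cand$phi + cand$width)) %% P
      if (gap1 >= rng_s[1L] && gap1 <= rng_s[2L] &&
          gap2 >= rng_s[1L] && gap2 <= rng_s[2L]) f2 <- cand
    }
  }
  if (is.null(f2)) {
    # family 2 is invisible to exact k-mer seeding (e.g. every copy
    # mutated): recover it from the consensus of the inter-copy segments
    if (length(f1$pos) < 3L) return(NULL)
    seglen <- P - f1$width
    segs <- vapply(f1$pos[-length(f1$pos)], function(p)
      substr(s, p + f1$width, p + f1$width + seglen - 1L), "")
    m <- do.call(rbind, strsplit(segs, "", fixed = TRUE))
    colmaj <- apply(m, 2L, function(col) max(table(col)))
    nseg <- length(segs)
    best <- NULL
    for (r2 in rng_r[1L]:rng_r[2L]) {
      for (off in rng_s[1L]:rng_s[2L]) {
        s2 <- seglen - r2 - off
        if (s2 < rng_s[1L] || s2 > rng_s[2L]) next
        sc <- sum(colmaj[off + seq_len(r2)]) - 0.75 * nseg * r2
        if (is.null(best) || sc > best$sc)
          best <- list(sc = sc, off = off, r2 = r2)
      }
    }
    if (is.null(best) || best$sc <= 0) return(NULL)
    copies2 <- vapply(f1$pos[-length(f1$pos)], function(p)
      substr(s, p + f1$width + best$off,
             p + f1$width + best$off + best$r2 - 1L), "")
    f2 <- list(phi = (f1$phi + f1$width + best$off) %% P,
               width = best$r2, cons = .majority_consensus(copies2))
  }
  if (f1$cons == f2$cons) return(NULL)  # single tandem family, not an array
  # place the copies by re-parsing the locus region with the inferred
  # repeat set; both edge/loop assignments are tried and the one that
  # explains more units wins (the wrong assignment loses the two
  # boundary-truncated units)
  span_lo <- max(1L, min(hits) - 2L * P)
  span_hi <- min(L, max(hits) + 3L * P + 80L)
  region <- substr(s, span_lo, span_hi)
  try_assign <- function(fe, fl) {
    sla <- (fl$phi - (fe$phi + fe$width)) %% P
    slb <- (fe$phi - (fl$phi + fl$width)) %% P
    if (sla < rng_s[1L] || sla > rng_s[2L] ||
        slb < rng_s[1L] || slb > rng_s[2L]) return(NULL)
    if (fe$width < rng_r[1L] || fl$width < rng_r[1L]) return(NULL)
    rs <- tryCatch(repeat_set(fe$cons, fl$cons, sla, slb,
                              processing_offset = max(1L, fe$width %/% 2L),
                              enforce_boxes = FALSE),
                   error = function(e) NULL)
    if (is.null(rs)) return(NULL)
    pm <- tryCatch(parse_array(region, rs, max_mm),
                   error = function(e) NULL)
    if (is.null(pm)) return(NULL)
    list(rs = rs, model = pm)
  }
  res <- list(try_assign(f1, f2), try_assign(f2, f1))
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(NULL)
  nu <- vapply(res, function(r) length(r$model$units), 0L)
  mmtot <- vapply(res, function(r)
    sum(r$model$parse$loop_mismatches, r$model$parse$edge_mismatches), 0)
  pick <- res[[order(-nu, mmtot)[1L]]]
  model <- pick$model
  rs <- pick$rs
  n <- length(model$units)
  if (n < params$min_units) return(NULL)
  spacers_a <- vapply(model$units, `[[`, "", "spacer_a")
  spacers_b <- vapply(model$units, `[[`, "", "spacer_b")
  # low-complexity guard: true spacers are variable regions
  sp_units <- paste0(spacers_a, spacers_b)
  if (n >= 2L) {
    pid <- combn(n, 2L)
    ident <- mean(apply(pid, 2L, function(ij)
      1 - .count_mm(sp_units[ij[1L]], sp_units[ij[2L]]) /
        nchar(sp_units[1L])))
    if (ident > 0.9) return(NULL)
  }
  loop_mm <- model$parse$loop_mismatches
  edge_mm <- model$parse$edge_mismatches
  rl <- nchar(rs$loop_repeat); re <- nchar(rs$edge_repeat)
  copy_len <- c(rep(rl, length(loop_mm)), rep(re, length(edge_mm)))
  score <- 1 - sum(c(loop_mm, edge_mm)) / sum(copy_len)
  boxes_ok <- grepl("^TG.*CCA$", rs$edge_repeat) &&
    grepl("^TG.*CCA$", rs$loop_repeat)
  list(start = span_lo - 1L + model$parse$start,
       end = span_lo - 1L + model$parse$end,
       period = P, n_units = n,
       edge = rs$edge_repeat, loop = rs$loop_repeat,
       sla = rs$spacer_len_a, slb = rs$spacer_len_b,
       lead = model$leading_edge_len, trail = model$trailing_edge_len,
       spacers_a = spacers_a, spacers_b = spacers_b,
       loop_mismatches = as.integer(loop_mm),
       edge_mismatches = as.integer(edge_mm),
       score = score, boxes_ok = boxes_ok)
}

.scan_strand <- function(s, params) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  k <- params$k
  raw <- list()
  for (P in params$period_range[1L]:params$period_range[2L]) {
    if (L < 2L * P + k) next
    eq <- ch[seq_len(L - P)] == ch[(1L + P):L]
    cs <- c(0L, cumsum(eq))
    n_i <- L - P - k + 1L
    if (n_i < 1L) next
    hits <- which((cs[(k + 1L):(n_i + k)] - cs[seq_len(n_i)]) == k)
    if (length(hits) < 4L) next
    # cluster hits separated by more than 2 periods into distinct loci
    br <- c(0L, which(diff(hits) > 2L * P), length(hits))
    for (ci in seq_len(length(br) - 1L)) {
      hc <- hits[(br[ci] + 1L):br[ci + 1L]]
      if (length(hc) < 4L) next
      if (diff(range(hc)) < P) next  # needs recurrence over >= 2 periods
      cand <- .evaluate_candidate(s, ch, P, hc, params)
      if (!is.null(cand)) raw[[length(raw) + 1L]] <- cand
    }
  }
  raw
}

.prune_overlaps <- function(calls) {
  if (length(calls) <= 1L) return(calls)
  ord <- order(-vapply(calls, `[[`, 0L, "n_units"),
               -vapply(calls, `[[`, 0, "score"),
               vapply(calls, `[[`, 0L, "start"))
  calls <- calls[ord]
  kept <- list()
  for (cl in calls) {
    clash <- any(vapply(kept, function(kp)
      cl$start <= kp$end && cl$end >= kp$start, NA))
    if (!isTRUE(clash)) kept[[length(kept) + 1L]] <- cl
  }
  kept
}

#' Detect dual-repeat TIGR arrays de novo
#'
#' Scans for two distinct, alternating 8-12-nt repeat families recurring at
#' a near-constant period, with variable spacers between them, truncated
#' edge copies at both boundaries, and at least `min_units` units. Both
#' strands are scanned; a physical array detected on both orientations is
#' reported once, on the strand whose repeats conform to the box C/D
#' grammar (`TG...CCA`), defaulting to `+`. Calls never overlap on the
#' same strand.
#'
#' @param x DNA sequence (`nuc_seq` or character).
#' @param params A [detection_params()].
#' @return List of `tigr_array_call` objects (empty when none), sorted by
#'   coordinate.
#' @export
detect_dual_repeat_arrays <- function(x, params = detection_params()) {
  xs <- nuc_seq(.seq_chr(x), id = if (is(x, "nuc_seq")) x$id else "seq")
  s <- xs$seq
  L <- nchar(s)
  fwd <- .prune_overlaps(.scan_strand(s, params))
  for (i in seq_along(fwd)) fwd[[i]]$strand <- "+"
  rev <- list()
  if (params$scan_both_strands) {
    rc <- .rc(s)
    rev <- .prune_overlaps(.scan_strand(rc, params))
    rev <- lapply(rev, function(cl) {
      new_start <- L - cl$end + 1L
      cl$end <- L - cl$start + 1L
      cl$start <- new_start
      cl$strand <- "-"
      cl
    })
  }
  # cross-strand dedup: the same physical array is periodic on both
  # orientations; keep the orientation carrying the box grammar
  calls <- fwd
  for (rcall in rev) {
    partner <- NULL
    for (i in seq_along(calls)) {
      if (rcall$start <= calls[[i]]$end && rcall$end >= calls[[i]]$start) {
        partner <- i; break
      }
    }
    if (is.null(partner)) {
      calls[[length(calls) + 1L]] <- rcall
    } else if (rcall$boxes_ok && !calls[[partner]]$boxes_ok) {
      calls[[partner]] <- rcall
    }
  }
  calls <- calls[order(vapply(calls, `[[`, 0L, "start"))]
  lapply(calls, function(cl) .finalize_call(cl, xs))
}

.finalize_call <- function(cl, xs) {
  p_off <- min(max(nchar(cl$edge) - cl$lead, 1L), nchar(cl$edge) - 1L)
  rs <- repeat_set(cl$edge, cl$loop, cl$sla, cl$slb,
                   processing_offset = p_off, enforce_boxes = FALSE)
  model <- tigr_array_model(rs, cl$spacers_a, cl$spacers_b,
                            leading_edge_len = cl$lead,
                            trailing_edge_len = cl$trail)
  # look for a terminator just downstream (strand-aware)
  term <- NULL
  L <- nchar(xs$seq)
  if (cl$strand == "+" && cl$end < L) {
    term <- predict_terminator(xs$seq,
                               window = c(cl$end + 1L, min(L, cl$end + 60L)))
  } else if (cl$strand == "-" && cl$start > 1L) {
    rcseq <- .rc(xs$seq)
    rstart <- L - cl$end + 1L; rend <- L - cl$start + 1L
    term <- predict_terminator(rcseq,
                               window = c(rend + 1L, min(L, rend + 60L)))
  }
  model$has_terminator <- !is.null(term)
  structure(list(contig = xs$id, start = cl$start, end = cl$end,
                 strand = cl$strand, repeat_set = rs, model = model,
                 n_units = cl$n_units, period = cl$period,
                 loop_mismatches = cl$loop_mismatches,
                 edge_mismatches = cl$edge_mismatches,
                 score = cl$score, boxes_ok = cl$boxes_ok,
                 terminator = term),
            class = "tigr_array_call")
}

#' @export
print.tigr_array_call <- function(x, ...) {
  cat(sprintf(paste0("<tigr_array_call> %s:%d-%d (%s)  %d units, period %d",
                     "  score %.3f%s\n"),
              x$contig, x$start, x$end, x$strand, x$n_units, x$period,
              x$score, if (x$boxes_ok) ", boxC/D ok" else ""))
  invisible(x)
}

#' Summarize array calls as a data.frame (one row per call)
#' @param calls List of `tigr_array_call` objects.
#' @return data.frame.
#' @export
calls_table <- function(calls) {
  if (!length(calls)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_units = integer(), period = integer(),
                      edge_repeat = character(), loop_repeat = character(),
                      spacer_len_a = integer(), spacer_len_b = integer(),
                      score = numeric(), boxes_ok = logical()))
  }
  data.frame(
    contig = vapply(calls, `[[`, "", "contig"),
    start = vapply(calls, `[[`, 0L, "start"),
    end = vapply(calls, `[[`, 0L, "end"),
    strand = vapply(calls, `[[`, "", "strand"),
    n_units = vapply(calls, `[[`, 0L, "n_units"),
    period = vapply(calls, `[[`, 0L, "period"),
    edge_repeat = vapply(calls, function(c) c$repeat_set$edge_repeat, ""),
    loop_repeat = vapply(calls, function(c) c$repeat_set$loop_repeat, ""),
    spacer_len_a = vapply(calls, function(c) c$repeat_set$spacer_len_a, 0L),
    spacer_len_b = vapply(calls, function(c) c$repeat_set$spacer_len_b, 0L),
    score = vapply(calls, `[[`, 0, "score"),
    boxes_ok = vapply(calls, `[[`, NA, "boxes_ok"))
}

# ---- stem-loop arrays -------------------------------------------------

#' Detect stem-loop TIGR arrays
#'
#' Finds tandem units each consisting of a palindromic stem (arms of at
#' least `min_arm` bp) whose enclosed region holds two spacer-length
#' segments flanked by box C (`CCA`) and box D (`TG`) motifs in the
#' dual-spacer arrangement: `arm...CCA | spacer A | TG...CCA | spacer B |
#' TGG...rc(arm)`. Inter-unit linkers are variable; runs of at least
#' `min_units` units form a call, and sub-arrays separated by more than
#' `max_linker` nt are reported as separate calls.
#'
#' @param x DNA sequence.
#' @param params A [detection_params()] (spacer/repeat ranges, min_units).
#' @param min_arm Minimum palindromic arm length, bp (default 5; the source
#'   biology gives no arm length).
#' @param max_arm Maximum arm length considered (default 15).
#' @param max_linker Maximum inter-unit linker within one call (default
#'   150 nt).
#' @return List of `stem_loop_call` objects.
#' @export
detect_stem_loop_arrays <- function(x, params = detection_params(),
                                    min_arm = 5L, max_arm = 15L,
                                    max_linker = 150L) {
  xs <- nuc_seq(.seq_chr(x), id = if (is(x, "nuc_seq")) x$id else "seq")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") xs$seq else .rc(xs$seq)
    units <- .find_stem_loop_units(s, params, min_arm, max_arm)
    if (!NROW(units)) next
    if (strand == "-") {
      L <- nchar(s)
      tmp <- units
      units$start <- L - tmp$end + 1L
      units$end <- L - tmp$start + 1L
      units <- units[order(units$start), , drop = FALSE]
    }
    units$strand <- strand
    # group into calls split at long linkers
    gaps <- if (nrow(units) > 1L)
      units$start[-1L] - head(units$end, -1L) - 1L else integer(0)
    grp <- cumsum(c(TRUE, gaps > max_linker))
    for (g in unique(grp)) {
      u <- units[grp == g, , drop = FALSE]
      if (nrow(u) < params$min_units) next
      res[[length(res) + 1L]] <- structure(
        list(contig = xs$id, start = min(u$start), end = max(u$end),
             strand = strand, units = u, n_units = nrow(u)),
        class = "stem_loop_call")
    }
  }
  res[order(vapply(res, `[[`, 0L, "start"))]
}

.find_stem_loop_units <- function(s, params, min_arm, max_arm) {
  rng_s <- params$spacer_len_range
  rng_r <- params$repeat_len_range
  L <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      arm_len = integer(), spacer_a = character(),
                      spacer_b = character(), loop = character())
  cca <- gregexpr("CCA", s, fixed = TRUE)[[1L]]
  if (cca[1L] == -1L) return(empty)
  rows <- empty
  for (c0 in as.integer(cca)) {
    c_end <- c0 + 2L  # last base of the left box C
    found <- NULL
    for (sa in rng_s[1L]:rng_s[2L]) {
      for (lp in rng_r[1L]:rng_r[2L]) {
        loop_start <- c_end + sa + 1L
        loop_end <- loop_start + lp - 1L
        if (loop_end > L) next
        loop <- substr(s, loop_start, loop_end)
        if (!grepl("^TG.*CCA$", loop)) next
        for (sb in rng_s[1L]:rng_s[2L]) {
          r0 <- loop_end + sb + 1L
          if (r0 + 2L > L) next
          if (substr(s, r0, r0 + 2L) != "TGG") next
          # maximal palindromic arms around the unit (left arm ends at
          # c_end and right arm starts at r0, so the box C/D pair is part
          # of the stem)
          m <- 0L
          while (m < max_arm) {
            lpos <- c_end - m
            rpos <- r0 + m
            if (lpos < 1L || rpos > L) break
            lb <- substr(s, lpos, lpos)
            rb <- substr(s, rpos, rpos)
            if (.COMP[[lb]] != rb) break
            m <- m + 1L
          }
          if (m < min_arm) next
          cand <- data.frame(
            start = c_end - m + 1L, end = r0 + m - 1L, arm_len = m,
            spacer_a = substr(s, c_end + 1L, c_end + sa),
            spacer_b = substr(s, loop_end + 1L, loop_end + sb),
            loop = loop)
          if (is.null(found) || cand$arm_len > found$arm_len) found <- cand
        }
      }
    }
    if (!is.null(found)) rows <- rbind(rows, found)
  }
  if (!nrow(rows)) return(empty)
  # dedupe overlapping candidates, keeping longer arms then leftmost
  rows <- rows[order(-rows$arm_len, rows$start), , drop = FALSE]
  kept <- rows[0L, ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (!any(r$start <= kept$end & r$end >= kept$start))
      kept <- rbind(kept, r)
  }
  kept[order(kept$start), , drop = FALSE]
}

#' @export
print.stem_loop_call <- function(x, ...) {
  cat(sprintf("<stem_loop_call> %s:%d-%d (%s)  %d units\n",
              x$contig, x$start, x$end, x$strand, x$n_units))
  invisible(x)
}

# ---- terminator -------------------------------------------------------

#' Predict a rho-independent terminator
#'
#' Simple heuristic: a hairpin with stem >= 6 bp (at most 1 mismatch),
#' loop 3-8 nt, and at least 4 T within the 8 nt following the hairpin.
#' The highest-scoring candidate is returned (score = stem length + T
#' count - 2 x stem mismatches; ties resolved leftmost).
#'
#' @param x DNA sequence.
#' @param window Optional `c(start, end)` (1-based closed) search window.
#' @return A `terminator_call` (fields `hairpin_start`, `hairpin_end`,
#'   `stem_len`, `loop_len`, `u_tract_len`, `score`) or `NULL`.
#' @export
predict_terminator <- function(x, window = NULL) {
  s <- .seq_chr(x)
  L <- nchar(s)
  if (is.null(window)) window <- c(1L, L)
  if (window[1L] < 1L || window[2L] > L || window[1L] > window[2L])
    stop("search window outside the sequence")
  sub <- substr(s, window[1L], window[2L])
  ch <- strsplit(sub, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  best <- NULL
  for (stem in 6L:12L) {
    for (loop in 3L:8L) {
      span <- 2L * stem + loop
      if (span > n) next
      for (i in seq_len(n - span + 1L)) {
        left <- ch[i:(i + stem - 1L)]
        right <- ch[(i + stem + loop):(i + span - 1L)]
        mm <- sum(.COMP[left] != rev(right))
        if (mm > 1L) next
        tail_start <- i + span
        tail_end <- min(n, tail_start + 7L)
        if (tail_start > n) next
        tcount <- sum(ch[tail_start:tail_end] == "T")
        if (tcount < 4L) next
        score <- stem + tcount - 2L * mm
        if (is.null(best) || score > best$score ||
            (score == best$score && i < best$i)) {
          best <- list(i = i, stem = stem, loop = loop, mm = mm,
                       tcount = tcount, score = score)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  hs <- window[1L] + best$i - 1L
  he <- hs + 2L * best$stem + best$loop - 1L
  structure(list(hairpin_start = hs, hairpin_end = he,
                 stem_len = best$stem, loop_len = best$loop,
                 stem_mismatches = best$mm, u_tract_len = best$tcount,
                 score = best$score),
            class = "terminator_call")
}

# ---- consensus & covariation -----------------------------------------

.IUPAC_FROM_SET <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  setNames(names(map),
           vapply(strsplit(map, ""), function(x)
             paste(sort(x), collapse = ""), ""))
})

#' Build a per-column IUPAC consensus
#'
#' For each column, the IUPAC code covering all residues observed at
#' frequency >= `threshold`.
#'
#' @param units Character vector of equal-length aligned repeat copies.
#' @param threshold Minimum per-column frequency (default 0.25).
#' @return IUPAC consensus string.
#' @export
build_consensus <- function(units, threshold = 0.25) {
  if (!length(units)) stop("no copies supplied")
  units <- toupper(units)
  if (length(unique(nchar(units))) != 1L)
    stop("copies must have equal length")
  m <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  paste(apply(m, 2L, function(col) {
    fr <- table(col) / length(col)
    keep <- sort(names(fr)[fr >= threshold])
    if (!length(keep)) keep <- names(sort(fr, decreasing = TRUE))[1L]
    .IUPAC_FROM_SET[[paste(keep, collapse = "")]]
  }), collapse = "")
}

#' Box-motif covariation across loci
#'
#' (i) Identity covariation: fraction of loci in which the edge-repeat
#' motif equals the loop-repeat motif at the configured positions (the
#' box C/D motifs may diverge from the canonical `TG`/`CCA`, but almost
#' always covary between the two repeats of one locus, consistent with
#' binding a symmetric protein dimer). (ii) For each configured
#' intra-repeat position pair, the fraction of loci whose bases are
#' Watson-Crick complementary, evaluated in both repeats.
#'
#' @param loci data.frame (or list) with elements/columns `edge` and
#'   `loop` (>= 2 loci).
#' @param motif_positions List with integer vectors `edge` and `loop`
#'   (equal lengths). Default: box D (first two bases) plus box C (last
#'   three bases) of each repeat.
#' @param pair_positions Optional list of `c(i, j)` intra-repeat pairs.
#' @return List of class `covariation_report` with `identity_covariation`,
#'   `pair_complementarity` (per repeat type), and `per_locus`.
#' @export
covariation_check <- function(loci, motif_positions = NULL,
                              pair_positions = NULL) {
  if (is.list(loci) && !is.data.frame(loci)) {
    loci <- data.frame(edge = vapply(loci, `[[`, "", "edge"),
                       loop = vapply(loci, `[[`, "", "loop"))
  }
  if (nrow(loci) < 2L) stop("need >= 2 loci")
  le <- nchar(loci$edge[1L]); ll <- nchar(loci$loop[1L])
  if (is.null(motif_positions)) {
    motif_positions <- list(edge = c(1L, 2L, (le - 2L):le),
                            loop = c(1L, 2L, (ll - 2L):ll))
  }
  if (length(motif_positions$edge) != length(motif_positions$loop))
    stop("edge and loop motif positions must have equal length")
  if (max(motif_positions$edge) > le || max(motif_positions$loop) > ll ||
      min(unlist(motif_positions)) < 1L)
    stop("motif positions out of range")
  pick <- function(seqs, idx) vapply(seqs, function(q)
    paste(strsplit(q, "")[[1L]][idx], collapse = ""), "", USE.NAMES = FALSE)
  e_mot <- pick(loci$edge, motif_positions$edge)
  l_mot <- pick(loci$loop, motif_positions$loop)
  ident <- e_mot == l_mot
  pairs <- list()
  if (!is.null(pair_positions)) {
    for (rep_type in c("edge", "loop")) {
      reps <- loci[[rep_type]]
      rl <- nchar(reps[1L])
      for (pp in pair_positions) {
        if (max(pp) > rl || min(pp) < 1L)
          stop("pair positions out of range for ", rep_type)
        wc <- vapply(reps, function(q) {
          chq <- strsplit(q, "")[[1L]]
          .COMP[[chq[pp[1L]]]] == chq[pp[2L]]
        }, NA, USE.NAMES = FALSE)
        pairs[[sprintf("%s_%d:%d", rep_type, pp[1L], pp[2L])]] <- mean(wc)
      }
    }
  }
  structure(list(identity_covariation = mean(ident),
                 pair_complementarity = unlist(pairs),
                 per_locus = data.frame(edge_motif = e_mot,
                                        loop_motif = l_mot,
                                        identical = ident)),
            class = "covariation_report")
}

#' @export
print.covariation_report <- function(x, ...) {
  cat(sprintf("<covariation_report> identity covariation %.3f over %d loci\n",
              x$identity_covariation, nrow(x$per_locus)))
  if (length(x$pair_complementarity)) {
    cat("  pair complementarity:\n")
    for (nm in names(x$pair_complementarity))
      cat(sprintf("    %s  %.3f\n", nm, x$pair_complementarity[[nm]]))
  }
  invisible(x)
}
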