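# Target engine: tandem dual-strand site search and cleavage geometry.
# The worked example plants the top-strand 18-mer ACGTACGTATCCGGATCC at
# 1-based position 101 for the guide A=ACGUACGUA / B=GGAUCCGGA: spacer A
# pairs the bottom strand over the left 9 bp, spacer B the top strand over
# the right 9 bp.

worked_genome <- function() {
  set.seed(77)
  g <- make_target_genome(77, guide_pair("ACGUACGUA", "GGAUCCGGA"),
                          background_len = 400)
  # use a fixed embedding instead for exact coordinates
  pre <- strrep("T", 100)
  post <- strrep("C", 82)
  nuc_seq(paste0(pre, "ACGTACGTATCCGGATCC", post), "worked")
}

test_that("find_sites reproduces the canonical tandem dual-strand site", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  gen <- worked_genome()
  sites <- find_sites(gen, g)
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_identical(c(s$start, s$end, s$gap), c(101L, 118L, 0L))
  expect_identical(s$region_a$strand, "-")
  expect_identical(s$region_b$strand, "+")
  expect_identical(c(s$region_a$start, s$region_a$end), c(101L, 109L))
  expect_identical(c(s$region_b$start, s$region_b$end), c(110L, 118L))
  expect_length(s$mismatches_a, 0L)
  expect_length(s$mismatches_b, 0L)
  # reverse-complemented spacer B abolishes the site
  g_rc <- guide_pair(g$spacer_a, to_rna(revcomp(chartr("U", "T",
                                                       g$spacer_b))))
  expect_length(find_sites(gen, g_rc), 0L)
  # swapped spacers find the identical physical site
  sw <- find_sites(gen, swap_spacers(g))
  expect_identical(footprint_sig(sw), footprint_sig(sites))
  expect_identical(sw[[1]]$arrangement, "B_left")
  expect_identical(sw[[1]]$region_b$strand, "-")
})

test_that("predict_cleavage applies the C-5 rule with 8-nt 3' overhangs", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  s <- find_sites(worked_genome(), g)[[1]]
  cl <- predict_cleavage(s)
  expect_identical(cl$outcome, "dsb")
  # bottom nick between footprint-local bases 5|6, top between 13|14
  expect_identical(cl$nick_a, 105L)
  expect_identical(cl$nick_b, 113L)
  expect_identical(cl$overhang_len, 8L)
  expect_identical(cl$overhang_seq, "CGTATCCG")
  # exactly 5 matched-region bases lie 3' of each nick on its strand
  expect_identical(cl$nick_a - s$region_a$start + 1L, 5L)
  expect_identical(s$region_b$end - cl$nick_b, 5L)
})

test_that("the mismatch rule table classifies outcomes", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  one_mm <- function(region, index) {
    fx <- make_target_genome(1000 + index * 7 + (region == "B"), g,
                             mismatch_spec = data.frame(
                               site = 1L, region = region, index = index),
                             background_len = 600)
    sites <- find_sites(fx$seq, g, max_mm_per_region = 1L)
    sites[[which(vapply(sites, `[[`, 0L, "start") == fx$sites$start)]]
  }
  # seed mismatches (positions 4, 5) abolish cleavage of both strands
  for (idx in c(4L, 5L)) {
    for (rg in c("A", "B")) {
      st <- one_mm(rg, idx)
      expect_identical(predict_cleavage(st)$outcome, "none")
    }
  }
  # nickase mismatch in region A leaves only the B-strand nick
  stA6 <- one_mm("A", 6L)
  clA6 <- predict_cleavage(stA6)
  expect_identical(clA6$outcome, "nick_B_strand")
  expect_true(is.na(clA6$nick_a) && !is.na(clA6$nick_b))
  stB7 <- one_mm("B", 7L)
  expect_identical(predict_cleavage(stB7)$outcome, "nick_A_strand")
  # single edge-proximal and PAM-distal mismatches are tolerated
  for (idx in c(1L, 2L, 3L, 8L, 9L)) {
    expect_identical(predict_cleavage(one_mm("A", idx))$outcome, "dsb")
  }
  # simultaneous mismatches at both 5' edge positions kill the site
  fx2 <- make_target_genome(555, g,
                            mismatch_spec = data.frame(
                              site = c(1L, 1L), region = "A",
                              index = c(8L, 9L)),
                            background_len = 600)
  sites2 <- find_sites(fx2$seq, g, max_mm_per_region = 2L)
  st2 <- sites2[[which(vapply(sites2, `[[`, 0L, "start") ==
                         fx2$sites$start)]]
  expect_identical(predict_cleavage(st2)$outcome, "none")
  # mismatch indices beyond the spacer length error out
  bad <- find_sites(worked_genome(), g)[[1]]
  bad$mismatches_a <- 10L
  expect_error(predict_cleavage(bad), "exceeds")
})

test_that("gap tolerance has its boundary at 2 bp", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  fx <- make_target_genome(31, g, n_sites = 7L, gaps = 0:6,
                           background_len = 4000)
  tab <- gap_scan(fx$seq, g, gaps = 0:6)
  expect_identical(tab$cleavable, c(TRUE, TRUE, TRUE, rep(FALSE, 4)))
  # gapped DSBs carry 8 + gap overhangs
  sites <- find_sites(fx$seq, g)
  for (s in sites) {
    cl <- predict_cleavage(s)
    expect_identical(cl$overhang_len, 8L + s$gap)
  }
})

test_that("ssDNA is matched per spacer with C-5 nicks; RNA is not", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  target_b <- revcomp(chartr("U", "T", g$spacer_b))  # pairs spacer B
  ss <- nuc_seq(paste0("TTTTT", target_b, "AAAAA"), "ss")
  hits <- ssdna_scan(ss, g)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$spacer, "B")
  expect_identical(hits$start, 6L)
  # nick between the bases pairing spacer bases 6 and 5 (local 4|5)
  expect_identical(hits$nick_after, 6L + 3L)
  rna <- nuc_seq(chartr("T", "U", ss$seq), "ss_rna", kind = "rna")
  expect_identical(nrow(ssdna_scan(rna, g)), 0L)
  expect_identical(nrow(ssdna_scan(nuc_seq("ACG"), g)), 0L)
})

test_that("off-target scan ranks by severity, mismatches, coordinate", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  fx <- make_target_genome(91, g, background_len = 800)
  gs <- fx$seq$seq
  # append a decoy: the perfect segment with a seed transversion
  seg <- paste0("ACGTACGTA", "TCCGGATCC")
  ch <- strsplit(seg, "")[[1]]
  ch[4] <- "A"  # transversion T->A at the base pairing spacer-A base 4
  decoy <- paste(ch, collapse = "")
  gen <- nuc_seq(paste0(gs, strrep("T", 20), decoy, strrep("T", 20)),
                 "ot")
  res <- off_target_scan(gen, g, max_mm_per_region = 1L)
  expect_gte(nrow(res$summary), 2L)
  expect_identical(res$summary$outcome[1], "dsb")
  expect_identical(res$summary$start[1], fx$sites$start)
  decoy_rows <- which(res$summary$start > nchar(gs))
  expect_true(all(res$summary$outcome[decoy_rows] == "none"))
  expect_true(all(decoy_rows > 1L))
  # no relaxed matches gives an empty result
  empty <- off_target_scan(nuc_seq(strrep("A", 60), "a"), g)
  expect_identical(nrow(empty$summary), 0L)
  # identical outcomes order by coordinate
  perfect <- "ACGTACGTATCCGGATCC"
  res2 <- off_target_scan(paste0(strrep("T", 10), perfect, strrep("T", 10),
                                 perfect, strrep("T", 10)), g)
  expect_identical(res2$summary$start, sort(res2$summary$start))
})

test_that("find_sites agrees with the brute-force oracle", {
  for (seed in 1:40) {
    set.seed(seed + 2000)
    gen <- nuc_seq(random_dna(400), sprintf("g%d", seed))
    gd <- random_guide(seed, sample(8:12, 1), sample(8:12, 1))
    mm <- seed %% 3L
    mg <- seed %% 3L
    fast <- find_sites(gen, gd, max_gap = mg, max_mm_per_region = mm)
    slow <- brute_force_find_sites(gen, gd, max_gap = mg, max_mm = mm)
    expect_identical(sites_sig(fast), sites_sig(slow))
  }
})

test_that("site sets are strand-symmetric and flank-independent", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  for (seed in c(5, 6, 7)) {
    fx <- make_target_genome(seed, g, n_sites = 2L, gaps = c(0L, 1L),
                             background_len = 1500)
    L <- nchar(fx$seq$seq)
    fwd <- find_sites(fx$seq, g)
    rev <- find_sites(revcomp(fx$seq), g)
    mirrored <- sort(vapply(rev, function(s)
      paste(L - s$end + 1L, L - s$start + 1L, s$gap, sep = "|"), ""))
    expect_identical(mirrored, footprint_sig(fwd))
    # randomizing everything outside the footprints changes nothing
    set.seed(seed + 9000)
    ch <- strsplit(random_dna(L), "")[[1]]
    for (i in seq_len(nrow(fx$sites))) {
      idx <- fx$sites$start[i]:fx$sites$end[i]
      ch[idx] <- strsplit(substr(fx$seq$seq, fx$sites$start[i],
                                 fx$sites$end[i]), "")[[1]]
    }
    reflank <- nuc_seq(paste(ch, collapse = ""), "reflank")
    again <- find_sites(reflank, g)
    keep <- vapply(again, function(s)
      s$start %in% fx$sites$start, NA)
    expect_identical(footprint_sig(again[keep]), footprint_sig(fwd))
    calls1 <- lapply(fwd, predict_cleavage)
    calls2 <- lapply(again[keep], predict_cleavage)
    expect_identical(vapply(calls1, `[[`, "", "outcome"),
                     vapply(calls2, `[[`, "", "outcome"))
    # spacer swap leaves footprints and geometry unchanged
    sw <- find_sites(fx$seq, swap_spacers(g))
    expect_identical(footprint_sig(sw), footprint_sig(fwd))
    nick_pair <- function(cl) sort(c(cl$nick_a, cl$nick_b))
    expect_identical(lapply(lapply(sw, predict_cleavage), nick_pair),
                     lapply(calls1, nick_pair))
  }
})

test_that("G:U wobble pairing is honoured only when requested", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  # spacer-A base 3 is G; give the top strand an A there so the bottom
  # strand presents T (an rG:dT wobble pair)
  seg <- "ACATACGTATCCGGATCC"
  gen <- paste0(strrep("T", 30), seg, strrep("T", 30))
  expect_length(find_sites(gen, g), 0L)
  wob <- find_sites(gen, g, wobble = TRUE)
  expect_length(wob, 1L)
  expect_identical(wob[[1]]$mismatches_a, integer(0))
})

test_that("guides do not target their own expression arrays", {
  g <- guide_pair("ACGUACGUA", "GGAUCCGGA")
  con <- build_expression_array(g)
  expect_false(self_target_check(g, con$seq))
  # a construct with the true target inserted is targeted
  with_target <- paste0(con$seq$seq, strrep("T", 10),
                        "ACGTACGTATCCGGATCC")
  expect_true(self_target_check(g, with_target))
  # palindromic spacers are the flagged corner case: spacer pairs whose
  # DNA forms are reverse complements can produce self-matches
  pal <- guide_pair("ACGUACGUA", to_rna(revcomp("ACGTACGTA")))
  expect_identical(chartr("U", "T", pal$spacer_b),
                   revcomp(chartr("U", "T", pal$spacer_a)))
})
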