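# De novo array detection, terminator heuristic, consensus, covariation.

test_that("a clean planted array is recovered coordinate-exactly", {
  fx <- make_locus(1)
  calls <- detect_dual_repeat_arrays(fx$seq)
  expect_length(calls, 1L)
  cl <- calls[[1]]
  expect_identical(cl$start, fx$start)
  expect_identical(cl$end, fx$end)
  expect_identical(cl$strand, "+")
  expect_identical(cl$n_units, 8L)
  expect_identical(cl$repeat_set$edge_repeat,
                   fx$repeat_set$edge_repeat)
  expect_identical(cl$repeat_set$loop_repeat,
                   fx$repeat_set$loop_repeat)
  expect_identical(cl$repeat_set$spacer_len_a, 9L)
  expect_identical(cl$score, 1)
  expect_true(cl$boxes_ok)
  expect_true(cl$model$has_terminator)
  # the called model reassembles to the called region
  body <- substr(fx$seq$seq, cl$start, cl$end)
  expect_identical(substr(assemble_array(cl$model)$seq, 1,
                          nchar(body)), body)
})

test_that("random sequence yields no calls", {
  set.seed(2024)
  r <- nuc_seq(random_dna(5000), "rand")
  expect_length(detect_dual_repeat_arrays(r), 0L)
  # independent necessary condition: no 7-mer recurs three times at any
  # constant period in range, so no >= 3-unit periodic repeat exists
  ch <- strsplit(r$seq, "")[[1]]
  L <- length(ch)
  triple <- FALSE
  for (P in 30:50) {
    eq <- ch[seq_len(L - P)] == ch[(1 + P):L]
    cs <- c(0L, cumsum(eq))
    n_i <- L - P - 7L + 1L
    hit <- (cs[8L:(n_i + 7L)] - cs[seq_len(n_i)]) == 7L
    both <- which(hit[seq_len(n_i - P)] & hit[(1L + P):n_i])
    if (length(both)) triple <- TRUE
  }
  expect_false(triple)
})

test_that("mutated loop copies are recovered within tolerance", {
  fx <- make_locus(101, per_copy_mutations = 1L)
  calls <- detect_dual_repeat_arrays(fx$seq)
  expect_length(calls, 1L)
  cl <- calls[[1]]
  expect_identical(cl$start, fx$start)
  expect_identical(cl$end, fx$end)
  expect_identical(cl$n_units, 8L)
  expect_identical(cl$loop_mismatches, rep(1L, 8L))
  expect_identical(cl$edge_mismatches, rep(0L, 7L))
})

test_that("unit recovery is monotone in the mismatch tolerance", {
  fx <- make_locus(103, per_copy_mutations = 1L)
  units_at <- vapply(0:3, function(mm) {
    calls <- detect_dual_repeat_arrays(
      fx$seq, detection_params(max_mismatch_per_copy = mm))
    if (length(calls)) max(vapply(calls, `[[`, 0L, "n_units")) else 0L
  }, 0L)
  expect_true(all(diff(units_at) >= 0L))
  expect_identical(units_at[3], 8L)  # tolerance 2 recovers everything
})

test_that("detection is strand-symmetric", {
  for (seed in c(2, 3)) {
    fx <- make_locus(seed)
    fwd <- detect_dual_repeat_arrays(fx$seq)
    bwd <- detect_dual_repeat_arrays(revcomp(fx$seq))
    expect_length(bwd, length(fwd))
    L <- nchar(fx$seq$seq)
    expect_identical(L - bwd[[1]]$end + 1L, fwd[[1]]$start)
    expect_identical(L - bwd[[1]]$start + 1L, fwd[[1]]$end)
    expect_identical(bwd[[1]]$strand, "-")
    expect_identical(fwd[[1]]$strand, "+")
  }
})

test_that("multiple arrays on one contig give non-overlapping calls", {
  fa <- make_locus(7, n_units = 6L, background_len = 800L)
  fb <- make_locus(8, n_units = 5L, background_len = 800L)
  joint <- nuc_seq(paste0(fa$seq$seq, fb$seq$seq), "joint")
  calls <- detect_dual_repeat_arrays(joint)
  expect_length(calls, 2L)
  expect_identical(calls[[1]]$start, fa$start)
  expect_identical(calls[[2]]$start, 800L + fb$start)
  expect_lt(calls[[1]]$end, calls[[2]]$start)
})

test_that("low-complexity regions are not called", {
  homopoly <- nuc_seq(paste0(random_dna(200), strrep("A", 400),
                             random_dna(200)), "homo")
  expect_length(detect_dual_repeat_arrays(homopoly), 0L)
  set.seed(55)
  micro <- nuc_seq(paste0(random_dna(200), strrep("ACT", 150),
                          random_dna(200)), "micro")
  expect_length(detect_dual_repeat_arrays(micro), 0L)
  # a single 36-mer repeated in tandem is one family, not a TIGR array
  set.seed(56)
  unit36 <- random_dna(36)
  tand <- nuc_seq(paste0(random_dna(200), strrep(unit36, 8),
                         random_dna(200)), "tandem")
  expect_length(detect_dual_repeat_arrays(tand), 0L)
})

test_that("stem-loop arrays are found as sub-array calls", {
  fx <- make_stem_loop_locus(3)
  calls <- detect_stem_loop_arrays(fx$seq)
  expect_length(calls, 3L)
  expect_identical(sum(vapply(calls, `[[`, 0L, "n_units")), 13L)
  expect_identical(vapply(calls, `[[`, 0L, "n_units"), c(5L, 4L, 4L))
  got_units <- do.call(rbind, lapply(calls, `[[`, "units"))
  expect_identical(got_units$start, fx$units$start)
  expect_identical(got_units$end, fx$units$end)
  expect_identical(got_units$spacer_a, fx$units$spacer_a)
  expect_identical(got_units$spacer_b, fx$units$spacer_b)
})

test_that("stem-loops need box motifs and intact palindromes", {
  # a hairpin without the box C/D grammar is not a unit
  arm <- "GATTGATC"
  hp <- nuc_seq(paste0(strrep("T", 50), arm, strrep("T", 21),
                       revcomp(arm), strrep("T", 50)), "hp")
  expect_length(detect_stem_loop_arrays(hp), 0L)
  # breaking one unit's palindrome drops exactly that unit
  fx <- make_stem_loop_locus(3, break_palindromy_in = 7L)
  calls <- detect_stem_loop_arrays(fx$seq)
  expect_identical(sum(vapply(calls, `[[`, 0L, "n_units")), 12L)
  got <- do.call(rbind, lapply(calls, `[[`, "units"))
  expect_false(fx$units$start[7] %in% got$start)
})

test_that("predict_terminator implements the stated heuristic", {
  stem <- "GCGCGCGC"
  hit <- paste0("ACGT", stem, "TTAA", revcomp(stem), "TTTTTTT", "ACGT")
  tc <- predict_terminator(hit)
  expect_identical(tc$stem_len, 8L)
  expect_identical(tc$u_tract_len, 7L)
  expect_identical(tc$hairpin_start, 5L)
  none <- paste0("ACGT", stem, "TTAA", revcomp(stem), "AAAAAAA")
  expect_null(predict_terminator(none))
  set.seed(1234)
  expect_null(predict_terminator(random_dna(200)))
  expect_error(predict_terminator("ACGT", window = c(1L, 10L)), "window")
})

test_that("build_consensus emits per-column IUPAC codes", {
  expect_identical(build_consensus(c("TGGATCGCCA", "TGGATCGCCA")),
                   "TGGATCGCCA")
  expect_identical(build_consensus(c("TGATTT", "TGCTTT")), "TGMTTT")
  # below-threshold residues are dropped from the code
  expect_identical(build_consensus(rep(c("TA", "TC", "TG", "TT"),
                                       c(5, 5, 5, 1)), threshold = 0.25),
                   "TV")
  expect_error(build_consensus(character(0)), "no copies")
  expect_error(build_consensus(c("ACGT", "ACG")), "equal length")
})

test_that("covariation_check counts identity and pairing fractions", {
  # joint box D divergence TG -> TA in 4 of 10 loci covaries perfectly
  edge0 <- "TGCAGTGCCA"; loop0 <- "TGAAACCA"
  flip <- function(x) paste0("TA", substr(x, 3, nchar(x)))
  loci <- data.frame(
    edge = c(rep(edge0, 6), rep(flip(edge0), 4)),
    loop = c(rep(loop0, 6), rep(flip(loop0), 4)))
  rep1 <- covariation_check(loci)
  expect_identical(rep1$identity_covariation, 1)
  # independent motif changes score as directly counted
  loci2 <- loci
  loci2$edge[1] <- flip(edge0)  # edge diverges alone in locus 1
  rep2 <- covariation_check(loci2)
  expect_identical(rep2$identity_covariation, 0.9)
  # a single shared repeat set is trivially covarying
  rep3 <- covariation_check(data.frame(edge = rep(edge0, 3),
                                       loop = rep(loop0, 3)))
  expect_identical(rep3$identity_covariation, 1)
  # intra-repeat Watson-Crick pairs
  rep4 <- covariation_check(loci, pair_positions = list(c(1L, 8L)))
  expect_true("edge_1:8" %in% names(rep4$pair_complementarity))
  expect_error(covariation_check(loci, motif_positions = list(
    edge = 1:99, loop = 1:99)), "out of range")
  expect_error(covariation_check(loci[1, , drop = FALSE]), ">= 2")
})
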