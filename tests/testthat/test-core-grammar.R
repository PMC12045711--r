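test_that("unit_period follows the grammar arithmetic", {
  expect_identical(unit_period(ta_like_repeat_set()), 36L)
  rs34 <- repeat_set("TGCAGTGCCA", "TGAAACCA", 8L, 8L)
  expect_identical(unit_period(rs34), 34L)
  rs48 <- repeat_set("TGCGATCGACCA", "TGAAATAAACCA", 12L, 12L)
  expect_identical(unit_period(rs48), 48L)
})

test_that("repeat_set validates its invariants", {
  expect_error(repeat_set("TGCCA", "TGAAACCA"), "8-12")
  expect_error(repeat_set("TGCAGTGCCA", "TGAAACCA", spacer_len_a = 13L),
               "8-12")
  expect_error(repeat_set("ACGTACGTAC", "TGAAACCA"), "enforce_boxes|TG")
  expect_error(repeat_set("TGCAGTGCCA", "TGAAACCA",
                          processing_offset = 10L), "strictly inside")
  expect_error(repeat_set("TGCANTGCCA", "TGAAACCA", enforce_boxes = FALSE),
               "unambiguous")
  # non-box repeats are fine when the grammar is not enforced
  rs <- repeat_set("ACGTACGTAC", "GGGTTTAA", enforce_boxes = FALSE)
  expect_identical(rs$processing_offset, 5L)
})

test_that("assembly produces the expected lengths and sequences", {
  rs <- ta_like_repeat_set()
  m2 <- tigr_array_model(rs, c("ACGTACGTA", "CCCTTTGGG"),
                         c("GATCGATCG", "TTTCCCAAA"))
  out <- assemble_array(m2)
  expect_identical(nchar(out$seq), 72L)  # lead 5 + 36 + 26 + trail 5
  m1 <- tigr_array_model(rs, "ACGTACGTA", "GATCGATCG")
  u1 <- assemble_array(m1)
  expect_identical(nchar(u1$seq), 36L)
  # single unit equals the mature unit in DNA form
  tig <- extract_tigrnas(m1)[[1]]
  expect_identical(u1$seq, chartr("U", "T", tig$seq))
  # terminator cassette is appended after the body
  mt <- tigr_array_model(rs, "ACGTACGTA", "GATCGATCG",
                         has_terminator = TRUE)
  at <- assemble_array(mt)
  expect_identical(attr(at, "body_len"), 36L)
  expect_gt(nchar(at$seq), 36L)
  expect_error(tigr_array_model(rs, "ACGTACG", "GATCGATCG"),
               "do not match")
})

test_that("assemble/parse round trip is lossless over random models", {
  for (seed in 1:12) {
    p <- sweep_params(seed)
    rs <- make_repeat_set(seed, p$edge_len, p$loop_len,
                          p$spacer_len, p$spacer_len)
    set.seed(seed + 500L)
    n <- p$n_units
    sa <- replicate(n, paste(sample(c("A", "C", "G", "T"), p$spacer_len,
                                    TRUE), collapse = ""))
    sb <- replicate(n, paste(sample(c("A", "C", "G", "T"), p$spacer_len,
                                    TRUE), collapse = ""))
    m <- tigr_array_model(rs, sa, sb,
                          has_terminator = (seed %% 2 == 0))
    out <- assemble_array(m)
    expect_identical(attr(out, "body_len"), model_length(m))
    # body length equals n * period under default truncations
    expect_identical(model_length(m), n * unit_period(rs))
    pm <- parse_array(out, rs, 0L)
    expect_true(same_array_model(m, pm))
    expect_identical(pm$parse$start, 1L)
    expect_identical(pm$parse$end, model_length(m))
    expect_true(all(pm$parse$loop_mismatches == 0L))
  }
})

test_that("parse_array tolerates and reports per-copy mismatches", {
  rs <- ta_like_repeat_set()
  set.seed(42)
  n <- 8L
  sa <- replicate(n, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                           collapse = ""))
  sb <- replicate(n, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                           collapse = ""))
  m <- tigr_array_model(rs, sa, sb)
  s <- assemble_array(m)$seq
  # inject one substitution into each loop copy, recording positions
  ch <- strsplit(s, "")[[1]]
  P <- unit_period(rs)
  for (j in seq_len(n)) {
    l0 <- m$leading_edge_len + (j - 1L) * P + rs$spacer_len_a
    pp <- l0 + ((j - 1L) %% nchar(rs$loop_repeat)) + 1L
    ch[pp] <- setdiff(c("A", "C", "G", "T"), ch[pp])[1]
  }
  mut <- paste(ch, collapse = "")
  pm <- parse_array(mut, rs, 2L)
  expect_identical(length(pm$units), 8L)
  expect_identical(pm$parse$loop_mismatches, rep(1L, 8L))
  expect_identical(pm$parse$edge_mismatches, rep(0L, 7L))
  expect_identical(vapply(pm$units, `[[`, "", "spacer_a"), sa)
  # zero tolerance on the mutated array fails informatively
  expect_error(parse_array(mut, rs, 0L), "parse failure")
})

test_that("12-nt spacers parse per the grammar's stated range", {
  rs <- repeat_set("TGCAGTGCCA", "TGAAACCA", 12L, 12L)
  set.seed(3)
  sa <- replicate(4, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                           collapse = ""))
  sb <- replicate(4, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                           collapse = ""))
  m <- tigr_array_model(rs, sa, sb)
  pm <- parse_array(assemble_array(m), rs, 0L)
  expect_true(same_array_model(m, pm))
  expect_identical(nchar(pm$units[[1]]$spacer_a), 12L)
})

test_that("every parsed spacer is flanked by box C and box D", {
  rs <- ta_like_repeat_set()
  set.seed(9)
  sa <- replicate(5, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                           collapse = ""))
  sb <- replicate(5, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                           collapse = ""))
  m <- tigr_array_model(rs, sa, sb)
  s <- assemble_array(m)$seq
  P <- unit_period(rs)
  for (j in seq_len(5)) {
    a0 <- m$leading_edge_len + (j - 1L) * P  # 0-based start of spacer A
    b0 <- a0 + rs$spacer_len_a + nchar(rs$loop_repeat)
    for (s0 in c(a0, b0)) {
      expect_identical(substr(s, s0 - 2L, s0), "CCA")
      sp_end <- s0 + rs$spacer_len_a
      expect_identical(substr(s, sp_end + 1L, sp_end + 2L), "TG")
    }
  }
})

test_that("revcomp and to_rna behave as standard plumbing", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(to_rna("TGGATCGCCA"), "UGGAUCGCCA")
  for (seed in 1:5) {
    set.seed(seed)
    x <- nuc_seq(random_dna(50), "x")
    expect_identical(revcomp(revcomp(x))$seq, x$seq)
  }
  # ambiguity codes pass through the complement table
  expect_identical(revcomp("ANRT"), "AYNT")
  expect_error(nuc_seq(""), "empty")
  expect_error(nuc_seq("ACGU", kind = "dna"), "invalid")
})

test_that("repeat-set config serializes losslessly", {
  rs <- make_repeat_set(7, 11L, 9L, 10L, 8L)
  f <- tempfile(fileext = ".cfg")
  write_repeat_config(rs, f)
  expect_identical(read_repeat_config(f), rs)
})

test_that("GFF3 export carries the feature hierarchy", {
  fx <- make_locus(5)
  gr <- fx$gff
  tab <- table(S4Vectors::mcols(gr)$type)
  expect_identical(unname(tab[["spacer_A"]]), 8L)
  expect_identical(unname(tab[["spacer_B"]]), 8L)
  expect_identical(unname(tab[["loop_repeat"]]), 8L)
  expect_identical(unname(tab[["edge_repeat"]]), 9L)  # 7 full + 2 partial
  expect_identical(unname(tab[["terminator"]]), 1L)
  parents <- S4Vectors::mcols(gr)$Parent
  expect_true(all(is.na(parents) | parents == "tigr1.array"))
  f <- tempfile(fileext = ".gff3")
  write_gff3(gr, f)
  back <- rtracklayer::import(f, format = "gff3")
  expect_identical(length(back), length(gr))
  # spacer_A features land on the genome where the model says
  spa <- gr[S4Vectors::mcols(gr)$type == "spacer_A"]
  expect_identical(GenomicRanges::start(spa)[1],
                   fx$start + fx$model$leading_edge_len)
})
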