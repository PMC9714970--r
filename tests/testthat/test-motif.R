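test_that("residue classification follows the normalized-symbol table", {
  expect_true(all(c("Omega", "Phi") %in% classify_residue("F")))
  expect_true(all(c("pi", "zeta") %in% classify_residue("S")))
  for (aa in bundlequant:::AA20)
    expect_gte(length(classify_residue(aa)), 1)
  expect_error(classify_residue("B"), "unknown residue")
  expect_identical(classify_residue("B", permissive = TRUE), character(0))
  # table overrides propagate and unclassified residues are rejected
  expect_error(residue_class_table(list(Phi = "F", pi = "A")), "unclassified")
})

test_that("pattern text parses, formats and rejects malformed input", {
  txt <- "[pi]-[ST]-[Omega]-[ST]-[Psi]-[zeta]-[zeta]-[Omega]"
  p <- parse_pattern(txt)
  expect_equal(format_pattern(p), txt)
  expect_equal(vapply(p$positions, `[[`, "", "type")[1], "class")
  g <- parse_pattern("L-x(1,5)-Y")
  expect_equal(g$positions[[2]]$min, 1)
  expect_equal(g$positions[[2]]$max, 5)
  expect_error(parse_pattern("A-[J1]-C"), "position 2")
  expect_error(parse_pattern("x(5,2)"), "gap min > max")
})

test_that("column classification maps sets and classes as specified", {
  aln <- c("SF", "TW", "SY", "TF")  # col1 {S,T}; col2 {F,W,Y}
  pats <- derive_pattern(aln, min_literal_frac = 0.9, max_set_size = 2,
                         min_window_len = 2)
  expect_equal(length(pats), 1)
  expect_equal(format_pattern(pats[[1]]), "[ST]-[Omega]")
  # a dominant residue becomes a literal
  aln2 <- c(rep("AA", 19), "AG")
  p2 <- derive_pattern(aln2, min_window_len = 2)
  expect_equal(format_pattern(p2[[1]]), "A-A")
  expect_error(derive_pattern(character(0)), "empty")
})

test_that("derived patterns are invariant to sequence order", {
  spec <- msa_sim_spec(seed = 13, across_class_rate = 0.05)
  aln <- simulate_alignment(spec)
  p1 <- derive_pattern(aln)
  p2 <- derive_pattern(rev(aln))
  expect_equal(lapply(p1, format_pattern), lapply(p2, format_pattern))
})

test_that("planted patterns round-trip through simulation and derivation", {
  spec <- msa_sim_spec(n_sequences = 40, length = 60,
                       within_class_rate = 0.5, across_class_rate = 0,
                       planted_at = 20, seed = 17)
  aln <- simulate_alignment(spec)
  pats <- derive_pattern(aln, min_literal_frac = 0.9, max_set_size = 2,
                         min_window_len = 3)
  np <- length(spec$pattern$positions)
  hit <- NULL
  for (p in pats) {
    st <- attr(p, "start")
    if (st <= spec$planted_at &&
        st + length(p$positions) - 1 >= spec$planted_at + np - 1) hit <- p
  }
  expect_false(is.null(hit))
  off <- spec$planted_at - attr(hit, "start")
  sub <- bundlequant:::.new_pattern(hit$positions[off + seq_len(np)],
                                    hit$table)
  expect_equal(format_pattern(sub), format_pattern(spec$pattern))
})

test_that("pattern scanning reports overlapping hits with 1-based spans", {
  hits <- scan_pattern("[Omega]-x-[Omega]", c(s1 = "AFAYA"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$match, "FAY")
  # longer than the sequence: no matches
  expect_equal(nrow(scan_pattern("[Omega]-x-x-x-x-x-x", c(s = "AFA"))), 0)
  # overlapping matches are all reported
  hits2 <- scan_pattern("[Omega]-x-[Omega]", c(s = "FYFYF"))
  expect_equal(hits2$start, c(1, 2, 3))
})

test_that("scanning agrees with the direct-membership oracle", {
  set.seed(31)
  seqs <- stats::setNames(vapply(1:50, function(i) random_protein(50), ""),
                          paste0("s", 1:50))
  for (rep_ in 1:5) {
    p <- random_pattern(sample(3:6, 1))
    got <- scan_pattern(p, seqs)[, c("seq_id", "start", "end")]
    want <- scan_oracle(p, seqs)
    rownames(got) <- rownames(want) <- NULL
    want <- want[order(want$seq_id, want$start, want$end), ]
    rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("pattern concatenation matches where both halves match", {
  set.seed(7)
  seqs <- stats::setNames(vapply(1:10, function(i) random_protein(40), ""),
                          paste0("s", 1:10))
  a <- parse_pattern("[Psi]-[zeta]")
  b <- parse_pattern("[Omega]-x")
  ab <- parse_pattern("[Psi]-[zeta]-[Omega]-x")
  ha <- scan_pattern(a, seqs); hb <- scan_pattern(b, seqs)
  hab <- scan_pattern(ab, seqs)
  joint <- merge(ha, hb, by.x = c("seq_id"), by.y = c("seq_id"))
  joint <- joint[joint$start.y == joint$end.x + 1, c("seq_id", "start.x")]
  got <- hab[, c("seq_id", "start")]
  expect_equal(nrow(got), nrow(joint))
  expect_true(all(paste(got$seq_id, got$start) %in%
                    paste(joint$seq_id, joint$start.x)))
})

test_that("CRAC and CARC motifs are found with their definitions", {
  hits <- scan_crac_carc(c(q = "VAAAYAAAK"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$kind, "CRAC")
  expect_equal(hits$start, 1)
  expect_equal(hits$end, 9)
  # no aromatic center, no motif of either kind
  none <- scan_crac_carc(c(q = "VAAAKAAALRRKLV"))
  expect_equal(nrow(none), 0)
  # the bundled synthetic 190-aa sequence carries exactly three motifs
  fa <- system.file("extdata", "minar2_synthetic.fasta",
                    package = "bundlequant")
  hits3 <- scan_crac_carc(read_fasta(fa))
  expect_equal(nrow(hits3), 3)
  expect_setequal(hits3$kind, c("CRAC", "CARC", "CRAC"))
})

test_that("CRAC of a sequence mirrors CARC of its reverse", {
  set.seed(12)
  for (i in 1:10) {
    s <- random_protein(60)
    n <- nchar(s)
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    crac <- scan_pattern(parse_pattern("[LV]-x(1,5)-Y-x(1,5)-[KR]"),
                         c(a = s))
    carc_rev <- scan_pattern(parse_pattern("[KR]-x(1,5)-Y-x(1,5)-[LV]"),
                             c(a = rs))
    mirrored <- data.frame(start = n - carc_rev$end + 1,
                           end = n - carc_rev$start + 1)
    mirrored <- mirrored[order(mirrored$start, mirrored$end), ]
    expect_equal(crac[, c("start", "end")], mirrored, ignore_attr = TRUE)
  }
})
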