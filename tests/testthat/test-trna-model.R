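test_that("normalization folds case, maps T to U and rejects other letters", {
  expect_equal(normalize_rna("acgu"), "ACGU")
  expect_equal(normalize_rna("ACGT"), "ACGU")
  expect_error(normalize_rna("ACGN"), "alphabet")
  expect_error(trna_record("x", strrep("AC", 20)), "length")
})

test_that("parsing a constrained scaffold recovers exactly its elements", {
  ann <- thr_cgu_ann()
  pr <- element_profile(ann)
  expect_equal(pr$n72, "C")
  expect_equal(pr$n73, "U")
  expect_equal(unname(pr$pair_2_71), c("C", "G"))
  expect_equal(unname(pr$pair_3_70), c("C", "G"))
  expect_equal(unname(pr$pair_11_24), c("C", "G"))
  expect_equal(unname(pr$pair_12_23), c("C", "G"))
  expect_true(pr$cca_present)
})

test_that("arm spans are disjoint, ordered and cover the full sequence", {
  for (seed in c(11, 12, 13)) {
    ann <- parse_cloverleaf(generate_scaffold(
      scaffold_constraints(seed = seed, long_variable_arm = seed %% 2 == 0)))
    sp <- ann$arm_spans
    expect_true(all(diff(sp$start) > 0))
    covered <- unlist(Map(seq, sp$start, sp$end))
    expect_equal(sort(covered), seq_len(nchar(ann$record$sequence)))
    expect_equal(anyDuplicated(covered), 0L)
    # position map injective
    expect_equal(anyDuplicated(ann$position_map), 0L)
  }
})

test_that("acceptor stem reports canonical 1-7 against 66-72 with computed kinds", {
  ann <- thr_cgu_ann()
  acc <- ann$pairs[ann$pairs$stem == "acceptor", ]
  expect_equal(acc$pos5, 1:7)
  expect_equal(acc$pos3, 72:66)
  expect_true(all(acc$kind %in% c("watson-crick", "wobble")))
  # kind is computed from the bases
  expect_equal(acc$kind, mapply(function(a, b) {
    if (paste0(a, b) %in% c("AU", "UA", "GC", "CG")) "watson-crick"
    else if (paste0(a, b) %in% c("GU", "UG")) "wobble" else "mismatch"
  }, acc$base5, acc$base3, USE.NAMES = FALSE))
})

test_that("reported stem pairs match brute-force complementarity at the generator's indices", {
  # Oracle: the generator's fixed type-I geometry places stems at known
  # sequence indices; enumerate those pairs directly from the raw sequence.
  stems <- list(acceptor = list(p5 = 1:7, p3 = 72:66),
                D = list(p5 = 10:13, p3 = 26:23),
                anticodon = list(p5 = 28:32, p3 = 44:40),
                T = list(p5 = 49:53, p3 = 65:61))
  for (seed in 1:50) {
    ann <- parse_cloverleaf(generate_scaffold(scaffold_constraints(seed = seed)))
    ch <- strsplit(ann$record$sequence, "")[[1]]
    for (stem in names(stems)) {
      got <- ann$pairs[ann$pairs$stem == stem, ]
      expect_equal(got$base5, ch[stems[[stem]]$p5])
      expect_equal(got$base3, ch[stems[[stem]]$p3])
    }
  }
})

test_that("parser is deterministic", {
  con <- thr_cgu_constraints_fix()
  r <- generate_scaffold(con)
  expect_identical(parse_cloverleaf(r), parse_cloverleaf(r))
})

test_that("CCA-truncated input parses with discriminator at the former 73", {
  ann <- thr_cgu_ann()
  s <- ann$record$sequence
  trunc <- parse_cloverleaf(trna_record("trunc", substr(s, 1, nchar(s) - 3)))
  expect_false(trunc$cca_present)
  expect_equal(residue_at_test(trunc, 73), residue_at_test(ann, 73))
  # all other elements unchanged
  pr0 <- element_profile(ann); pr1 <- element_profile(trunc)
  for (f in c("n72", "n73", "pair_2_71", "pair_3_70", "pair_11_24",
              "pair_12_23")) {
    expect_identical(pr0[[f]], pr1[[f]])
  }
})

test_that("parse failure is signalled for non-folding sequences", {
  expect_error(parse_cloverleaf(trna_record("bad", strrep("A", 76))),
               "parse failure")
})

test_that("point mutations change exactly one residue and re-annotate", {
  ann <- thr_cgu_ann()
  mut <- apply_point_mutation(ann, 73, "G")
  expect_equal(element_profile(mut)$n73, "G")
  d <- mapply(`!=`, strsplit(ann$record$sequence, "")[[1]],
              strsplit(mut$record$sequence, "")[[1]])
  expect_equal(sum(d), 1L)
  # identity mutation leaves the sequence unchanged
  same <- apply_point_mutation(ann, 73, "U")
  expect_identical(same$record$sequence, ann$record$sequence)
  # involution: C72A then A72C restores byte-for-byte
  back <- apply_point_mutation(apply_point_mutation(ann, 72, "A"), 72, "C")
  expect_identical(back$record$sequence, ann$record$sequence)
  expect_error(apply_point_mutation(ann, 47, "A"), "unknown position")
})

test_that("pair swaps replace both strands and reclassify the pair kind", {
  ann <- thr_cgu_ann()
  sw <- apply_pair_swap(ann, 2, 71, "G", "C")
  expect_equal(unname(element_profile(sw)$pair_2_71), c("G", "C"))
  sw2 <- apply_pair_swap(ann, 11, 24, "A", "U")
  expect_equal(unname(element_profile(sw2)$pair_11_24), c("A", "U"))
  expect_equal(sw2$pairs$kind[sw2$pairs$pos5 == 11], "watson-crick")
  sw3 <- apply_pair_swap(ann, 12, 23, "U", "G")
  expect_equal(sw3$pairs$kind[sw3$pairs$pos5 == 12], "wobble")
  expect_error(apply_pair_swap(ann, 2, 70, "A", "U"), "not a pair")
})

test_that("CCA deletion shortens by 3, flips the flag, and is reversible", {
  ann <- thr_cgu_ann()
  del <- delete_cca(ann)
  expect_false(del$cca_present)
  expect_equal(nchar(del$record$sequence), nchar(ann$record$sequence) - 3L)
  expect_error(delete_cca(del), "no CCA")
  restored <- parse_cloverleaf(
    trna_record("r", paste0(del$record$sequence, "CCA")))
  expect_identical(restored$record$sequence, ann$record$sequence)
  # profile differs only in cca_present
  pr0 <- element_profile(ann); pr1 <- element_profile(del)
  expect_false(pr1$cca_present)
  for (f in c("n72", "n73", "pair_2_71", "pair_3_70", "pair_11_24",
              "pair_12_23")) {
    expect_identical(pr0[[f]], pr1[[f]])
  }
})

test_that("extinction coefficient is the additive per-residue sum", {
  expect_equal(extinction_coefficient_260("ACGU"),
               15400 + 7400 + 11500 + 9900)
  s <- generate_scaffold(scaffold_constraints(seed = 3))$sequence
  # independent oracle: explicit per-residue loop
  coefs <- c(A = 15400, C = 7400, G = 11500, U = 9900)
  acc <- 0
  for (b in strsplit(s, "")[[1]]) acc <- acc + coefs[[b]]
  expect_equal(extinction_coefficient_260(s), acc)
  expect_equal(extinction_coefficient_260(paste0(s, s)),
               2 * extinction_coefficient_260(s))
  expect_gt(extinction_coefficient_260(s), 0)
})

test_that("FASTA round-trips through write and read", {
  panel <- generate_panel(published_panels()$HC3, base_seed = 5)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_trna_fasta(panel, path)
  back <- read_trna_fasta(path)
  expect_equal(names(back), names(panel$records))
  for (id in names(back)) {
    expect_equal(back[[id]]$sequence, panel$records[[id]]$sequence)
  }
})

test_that("annotation JSON export carries spans, map and pairs", {
  ann <- thr_cgu_ann()
  js <- jsonlite::fromJSON(annotation_json(ann))
  expect_equal(js$sequence, ann$record$sequence)
  expect_true(js$cca_present)
  expect_equal(nrow(js$arm_spans), nrow(ann$arm_spans))
  expect_equal(js$position_map[["73"]],
               unname(ann$position_map[["73"]]))
  expect_equal(nrow(js$pairs), nrow(ann$pairs))
})
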