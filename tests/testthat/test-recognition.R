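test_that("builtin rule sets encode the archaeal and human requirements", {
  rs <- builtin_rulesets()
  expect_setequal(names(rs), c("PhNSun6", "hNSun6"))
  expect_setequal(rs$PhNSun6$allowed_n73, c("U", "G"))
  expect_equal(rs$hNSun6$allowed_n73, "U")
  expect_equal(rs$PhNSun6$required_pair_2_71, list(c("C", "G")))
  expect_equal(rs$hNSun6$required_pair_2_71, list(c("G", "C")))
  expect_null(rs$PhNSun6$required_d_stem_pairs)
  expect_null(rs$PhNSun6$required_pair_3_70)
  expect_true(rs$PhNSun6$required_cca && rs$hNSun6$required_cca)
  expect_equal(rs$PhNSun6$required_n72, "C")
})

test_that("classifier equals exhaustive constraint enumeration", {
  rs <- builtin_rulesets()
  n_checked <- 0L
  for (n73 in c("A", "C", "G", "U")) {
    for (p in ALL_PAIRS) {
      for (cca in c(TRUE, FALSE)) {
        for (n72 in c("C", "A")) {
          pr <- make_profile(n72 = n72, n73 = n73, pair_2_71 = p,
                             cca_present = cca)
          for (nm in names(rs)) {
            oracle <- if (nm == "PhNSun6") ph_oracle(pr) else h_oracle(pr)
            res <- classify(pr, rs[[nm]])
            expect_identical(res$substrate, oracle)
            expect_identical(res$substrate,
                             nrow(res$violated_elements) == 0L)
          }
          # rule-set exclusivity: never a substrate of both
          expect_false(classify(pr, rs$PhNSun6)$substrate &&
                         classify(pr, rs$hNSun6)$substrate)
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  expect_equal(n_checked, 4L * 16L * 2L * 2L)
})

test_that("archaeal rules accept exactly {U,G}73 x C2:G71 on parsed scaffolds", {
  rules <- builtin_rulesets()$PhNSun6
  accepted <- character(0)
  for (n73 in c("A", "C", "G", "U")) {
    for (p in ALL_PAIRS) {
      con <- scaffold_constraints(n73 = n73, pair_2_71 = p, seed = 77)
      pr <- element_profile(parse_cloverleaf(generate_scaffold(con)))
      if (classify(pr, rules)$substrate) {
        accepted <- c(accepted, paste0(n73, "/", p[1], ":", p[2]))
      }
    }
  }
  expect_setequal(accepted, c("U/C:G", "G/C:G"))
})

test_that("violations name the failing element with observed values", {
  rules <- builtin_rulesets()$PhNSun6
  pr <- make_profile(n73 = "A", cca_present = FALSE)
  res <- classify(pr, rules)
  expect_false(res$substrate)
  expect_setequal(res$violated_elements$element, c("CCA", "n73"))
  obs <- res$violated_elements$observed[res$violated_elements$element == "n73"]
  expect_equal(obs, "A")
  # missing pair counts as a violation, not an error
  pr2 <- make_profile(pair_2_71 = NULL)
  res2 <- classify(pr2, rules)
  expect_false(res2$substrate)
  expect_equal(res2$violated_elements$element, "pair_2_71")
})

test_that("shipped panels have the published composition", {
  panels <- published_panels()
  expect_equal(length(panels$PH12$members), 12L)
  g73 <- vapply(panels$PH12$members,
                function(m) identical(m$constraints$n73, "G"), logical(1))
  expect_equal(sum(g73), 7L)
  expect_equal(length(panels$HC3$members), 3L)
  for (m in panels$HC3$members) {
    expect_equal(m$constraints$n73, "U")
    expect_equal(m$constraints$pair_2_71, c("G", "C"))
  }
  # the ten D-stem swap mutants are all expected substrates
  d_members <- Filter(function(m) grepl("11:24|12:23", m$id),
                      panels$MUTANTS$members)
  expect_equal(length(d_members), 10L)
  expect_true(all(vapply(d_members, function(m) m$expected[["PhNSun6"]],
                         logical(1))))
})

test_that("panel classification reproduces the published truth tables", {
  rules <- builtin_rulesets()
  panels <- published_panels()
  ph12 <- generate_panel(panels$PH12, base_seed = 42)
  tab_ph <- classify_panel(panels$PH12, rules$PhNSun6, ph12)
  expect_equal(attr(tab_ph, "n_substrate"), 11L)
  expect_false(tab_ph$substrate[tab_ph$id == "PhtRNA-Phe-GAA"])
  expect_true(all(tab_ph$match))

  tab_h <- classify_panel(panels$PH12, rules$hNSun6, ph12)
  expect_equal(attr(tab_h, "n_substrate"), 0L)

  hc3 <- generate_panel(panels$HC3, base_seed = 42)
  expect_equal(attr(classify_panel(panels$HC3, rules$PhNSun6, hc3),
                    "n_substrate"), 0L)
  expect_equal(attr(classify_panel(panels$HC3, rules$hNSun6, hc3),
                    "n_substrate"), 3L)
})

test_that("the mutant series reproduces every published verdict", {
  rules <- builtin_rulesets()$PhNSun6
  panels <- published_panels()
  muts <- generate_panel(panels$MUTANTS, base_seed = 42)
  tab <- classify_panel(panels$MUTANTS, rules, muts)
  expect_true(all(tab$match))
  rejected <- tab$id[!tab$substrate]
  expect_setequal(rejected,
                  c("Thr-CGU-dCCA", "Thr-CGU-C72A", "Thr-CGU-C72G",
                    "Thr-CGU-C72U", "Thr-CGU-U73A", "Thr-CGU-U73C",
                    "Thr-CGU-C2G:G71C", "Thr-CGU-C2G:G71U"))
  # U73G, the three 3:70 swaps and all ten D-stem swaps stay substrates
  expect_true(all(tab$substrate[grepl("U73G|C3|11:24|12:23", tab$id)]))
})

test_that("panel errors and edge cases behave", {
  rules <- builtin_rulesets()$PhNSun6
  empty <- panel_spec("EMPTY", list())
  tab <- classify_panel(empty, rules, list())
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "n_substrate"), 0L)
  p <- published_panels()$HC3
  expect_error(classify_panel(p, rules, list()), "hctRNA-Thr-AGU")
})

test_that("rule sets load from declarative JSON and YAML configs", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rulesets:",
               "  - name: archaeal-like",
               "    required_cca: true",
               "    required_n72: [C]",
               "    allowed_n73: [U, G]",
               '    required_pair_2_71: ["C:G"]',
               "  - name: d-stem-reader",
               "    allowed_n73: [U]",
               '    required_pair_2_71: ["G:C"]',
               "    required_d_stem_pairs:",
               '      "11:24": ["C:G", "G:C"]'), yml)
  rs <- load_rulesets(yml)
  expect_setequal(names(rs), c("archaeal-like", "d-stem-reader"))
  expect_equal(rs[["archaeal-like"]]$required_pair_2_71, list(c("C", "G")))
  expect_equal(rs[["d-stem-reader"]]$required_d_stem_pairs[["11:24"]],
               list(c("C", "G"), c("G", "C")))
  # behaves like the builtin on a wild-type profile
  expect_true(classify(element_profile(thr_cgu_ann()),
                       rs[["archaeal-like"]])$substrate)
  # D-stem constraint is enforced when present
  pr <- make_profile(pair_2_71 = c("G", "C"), pair_11_24 = c("A", "U"))
  expect_false(classify(pr, rs[["d-stem-reader"]])$substrate)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(rulesets = list(list(
    name = "json-rules", allowed_n73 = list("U"),
    required_pair_2_71 = list("G:C")))), js, auto_unbox = TRUE)
  rs2 <- load_rulesets(js)
  expect_equal(rs2[["json-rules"]]$allowed_n73, "U")
})

test_that("panel results export to TSV and JSON and round-trip", {
  rules <- builtin_rulesets()$PhNSun6
  panels <- published_panels()
  hc3 <- generate_panel(panels$HC3, base_seed = 9)
  tab <- classify_panel(panels$HC3, rules, hc3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_panel_results(tab, tsv = tsv, json = js)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$id, tab$id)
  expect_equal(back$substrate, tab$substrate)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$counts$substrates, 0L)
})
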