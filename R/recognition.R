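# Rule-based substrate classification for NSun6-family m5C72
# methyltransferases. A rule set names the identity elements an enzyme
# requires; classification is the conjunction of element matches, with every
# failure reported.

#' Construct a recognition rule set
#'
#' A named set of constraints on the identity-element profile of a tRNA:
#' CCA requirement, allowed residues at the target site 72 and the
#' discriminator 73, and allowed ordered base pairs at 2:71, 3:70 and the
#' D-stem positions. \code{NULL} leaves an element unconstrained. Ordered
#' pairs are compared strand-wise: C2:G71 and G2:C71 are distinct.
#'
#' @param name rule-set label.
#' @param required_cca logical.
#' @param required_n72 character vector of allowed residues at 72.
#' @param allowed_n73 character vector of allowed discriminator residues.
#' @param required_pair_2_71,required_pair_3_70 list of allowed ordered
#'   pairs (each \code{c(base5, base3)}) or \code{NULL}.
#' @param required_d_stem_pairs named list (names \code{"11:24"},
#'   \code{"12:23"}) of lists of allowed ordered pairs, or \code{NULL}.
#' @return an object of class \code{"rule_set"}.
#' @export
rule_set <- function(name, required_cca = TRUE, required_n72 = "C",
                     allowed_n73 = c("U", "G"),
                     required_pair_2_71 = NULL, required_pair_3_70 = NULL,
                     required_d_stem_pairs = NULL) {
  chk_set <- function(x, what) {
    if (!is.null(x) && length(x) == 0L) {
      stop("constrained element '", what, "' must allow at least one value",
           call. = FALSE)
    }
    x
  }
  structure(list(name = name, required_cca = isTRUE(required_cca),
                 required_n72 = chk_set(required_n72, "n72"),
                 allowed_n73 = chk_set(allowed_n73, "n73"),
                 required_pair_2_71 = chk_set(required_pair_2_71, "2:71"),
                 required_pair_3_70 = chk_set(required_pair_3_70, "3:70"),
                 required_d_stem_pairs = required_d_stem_pairs),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  fmt_pairs <- function(p) {
    if (is.null(p)) "unconstrained"
    else paste(vapply(p, function(q) paste0(q[1], ":", q[2]), ""),
               collapse = " | ")
  }
  cat(sprintf("Rule set '%s'\n", x$name))
  cat("  CCA terminus:", if (x$required_cca) "required" else "optional", "\n")
  cat("  N72 in {", paste(x$required_n72, collapse = ","), "}\n", sep = "")
  cat("  N73 in {", paste(x$allowed_n73, collapse = ","), "}\n", sep = "")
  cat("  pair 2:71:", fmt_pairs(x$required_pair_2_71), "\n")
  cat("  pair 3:70:", fmt_pairs(x$required_pair_3_70), "\n")
  if (is.null(x$required_d_stem_pairs)) {
    cat("  D-stem: unconstrained\n")
  } else {
    for (nm in names(x$required_d_stem_pairs)) {
      cat("  pair ", nm, ": ", fmt_pairs(x$required_d_stem_pairs[[nm]]),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Built-in NSun6 recognition rule sets
#'
#' Returns the archaeal and eukaryotic rule sets. \code{PhNSun6} (archaeal):
#' CCA terminus required, target site C72, discriminator U73 or G73, and the
#' discriminatory pair C2:G71; pair 3:70 and the D-stem are unconstrained.
#' \code{hNSun6} (human): CCA required, C72, strictly U73, and G2:C71; 3:70
#' and D-stem requirements reported elsewhere are representable but left
#' unconstrained here.
#'
#' @return named list of \code{rule_set} objects.
#' @export
builtin_rulesets <- function() {
  list(
    PhNSun6 = rule_set("PhNSun6", required_cca = TRUE, required_n72 = "C",
                       allowed_n73 = c("U", "G"),
                       required_pair_2_71 = list(c("C", "G"))),
    hNSun6 = rule_set("hNSun6", required_cca = TRUE, required_n72 = "C",
                      allowed_n73 = "U",
                      required_pair_2_71 = list(c("G", "C")))
  )
}

match_pair <- function(observed, allowed) {
  if (is.null(observed)) return(FALSE)
  any(vapply(allowed, function(p) identical(unname(observed), unname(p)),
             logical(1)))
}

violation_row <- function(element, observed, required) {
  data.frame(element = element, observed = observed, required = required,
             stringsAsFactors = FALSE)
}

#' Classify a tRNA profile under a recognition rule set
#'
#' A tRNA is a substrate iff every constrained element of the rule set
#' matches its identity-element profile. Missing elements (unparsed pairs,
#' absent CCA) count as violations of constrained rules, never as errors.
#'
#' @param profile an \code{identity_profile}.
#' @param rules a \code{rule_set}.
#' @return an object of class \code{"classification_result"} with fields
#'   \code{trna_id}, \code{ruleset_name}, \code{substrate} and
#'   \code{violated_elements} (data.frame: element, observed, required).
#' @export
classify <- function(profile, rules) {
  stopifnot(inherits(profile, "identity_profile"), inherits(rules, "rule_set"))
  v <- list()
  fmt_set <- function(x) paste(x, collapse = "|")
  fmt_allowed <- function(p) {
    paste(vapply(p, function(q) paste0(q[1], ":", q[2]), ""), collapse = "|")
  }
  if (rules$required_cca && !isTRUE(profile$cca_present)) {
    v <- c(v, list(violation_row("CCA", "absent", "present")))
  }
  if (!is.null(rules$required_n72) &&
        !(isTRUE(profile$n72 %in% rules$required_n72))) {
    v <- c(v, list(violation_row("n72", as.character(profile$n72),
                                 fmt_set(rules$required_n72))))
  }
  if (!is.null(rules$allowed_n73) &&
        !(isTRUE(profile$n73 %in% rules$allowed_n73))) {
    v <- c(v, list(violation_row("n73", as.character(profile$n73),
                                 fmt_set(rules$allowed_n73))))
  }
  if (!is.null(rules$required_pair_2_71) &&
        !match_pair(profile$pair_2_71, rules$required_pair_2_71)) {
    v <- c(v, list(violation_row("pair_2_71", fmt_pair(profile$pair_2_71),
                                 fmt_allowed(rules$required_pair_2_71))))
  }
  if (!is.null(rules$required_pair_3_70) &&
        !match_pair(profile$pair_3_70, rules$required_pair_3_70)) {
    v <- c(v, list(violation_row("pair_3_70", fmt_pair(profile$pair_3_70),
                                 fmt_allowed(rules$required_pair_3_70))))
  }
  for (nm in names(rules$required_d_stem_pairs)) {
    field <- switch(nm, "11:24" = "pair_11_24", "12:23" = "pair_12_23",
                    stop("unknown D-stem pair position: ", nm, call. = FALSE))
    if (!match_pair(profile[[field]], rules$required_d_stem_pairs[[nm]])) {
      v <- c(v, list(violation_row(field, fmt_pair(profile[[field]]),
                                   fmt_allowed(rules$required_d_stem_pairs[[nm]]))))
    }
  }
  violated <- if (length(v)) do.call(rbind, v)
              else violation_row(character(0), character(0), character(0))
  structure(list(trna_id = profile$trna_id, ruleset_name = rules$name,
                 substrate = nrow(violated) == 0L,
                 violated_elements = violated),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %s\n", x$trna_id, x$ruleset_name,
              if (x$substrate) "substrate" else "non-substrate"))
  if (nrow(x$violated_elements)) {
    ve <- x$violated_elements
    cat(paste(sprintf("  %s: observed %s, required %s",
                      ve$element, ve$observed, ve$required),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Specify a tRNA panel
#'
#' A named list of panel members, each with an id, either de novo scaffold
#' constraints or a base member plus mutation operations, and the expected
#' substrate verdict under one or more rule sets.
#'
#' @param name panel label.
#' @param members list of member descriptors (see \code{\link{published_panels}}
#'   for the shipped examples).
#' @return an object of class \code{"panel_spec"}.
#' @export
panel_spec <- function(name, members) {
  ids <- vapply(members, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("panel member ids must be unique", call. = FALSE)
  }
  structure(list(name = name, members = members), class = "panel_spec")
}

member <- function(id, constraints = NULL, base = NULL, mutations = NULL,
                   expected = NULL) {
  list(id = id, constraints = constraints, base = base,
       mutations = mutations, expected = expected)
}

#' Classify every member of a panel
#'
#' Applies one rule set to the parsed sequences of all panel members and
#' tabulates verdicts, violations and (when the panel declares expected
#' verdicts for that rule set) agreement with expectation. Sequences that
#' fail to parse are reported as non-substrates with a parse-failure
#' violation.
#'
#' @param panel a \code{panel_spec}.
#' @param rules a \code{rule_set}.
#' @param annotations named list of \code{annotated_trna} (or a
#'   \code{generated_panel}) covering every member id.
#' @return an object of class \code{"panel_classification"}: a data.frame
#'   with one row per member (columns id, ruleset, substrate, violations,
#'   expected, match) plus counts in attributes \code{n_substrate} and
#'   \code{n_non_substrate}.
#' @export
classify_panel <- function(panel, rules, annotations) {
  stopifnot(inherits(panel, "panel_spec"), inherits(rules, "rule_set"))
  if (inherits(annotations, "generated_panel")) {
    annotations <- annotations$annotations
  }
  rows <- lapply(panel$members, function(m) {
    ann <- annotations[[m$id]]
    if (is.null(ann)) {
      stop("missing sequence for panel member '", m$id, "'", call. = FALSE)
    }
    res <- tryCatch(classify(element_profile(ann), rules),
                    error = function(e) {
                      structure(list(trna_id = m$id, ruleset_name = rules$name,
                                     substrate = FALSE,
                                     violated_elements = violation_row(
                                       "parse-failure", conditionMessage(e),
                                       "parsable")),
                                class = "classification_result")
                    })
    exp_v <- if (!is.null(m$expected) && rules$name %in% names(m$expected)) {
      as.logical(m$expected[[rules$name]])
    } else NA
    data.frame(id = m$id, ruleset = rules$name, substrate = res$substrate,
               violations = paste(res$violated_elements$element,
                                  collapse = ";"),
               expected = exp_v,
               match = if (is.na(exp_v)) NA else res$substrate == exp_v,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), ruleset = character(0),
               substrate = logical(0), violations = character(0),
               expected = logical(0), match = logical(0))
  attr(tab, "n_substrate") <- sum(tab$substrate)
  attr(tab, "n_non_substrate") <- sum(!tab$substrate)
  class(tab) <- c("panel_classification", "data.frame")
  tab
}

#' @export
print.panel_classification <- function(x, ...) {
  cat(sprintf("Panel classification (%d members): %d substrates, %d non-substrates\n",
              nrow(x), attr(x, "n_substrate"), attr(x, "n_non_substrate")))
  print.data.frame(x)
  invisible(x)
}

thr_cgu_constraints <- function(anticodon = "CGU") {
  list(n72 = "C", n73 = "U", pair_2_71 = c("C", "G"),
       pair_3_70 = c("C", "G"), pair_11_24 = c("C", "G"),
       pair_12_23 = c("C", "G"), cca = TRUE, anticodon = anticodon)
}

#' Panels describing the published substrate series
#'
#' Ships three panels with the expected verdicts of the methylation assays:
#' \describe{
#'   \item{PH12}{the twelve archaeal tRNAs: Thr(CGU)/(GGU)/(UGU) and
#'     Cys(GCA) with U73 + C2:G71; Ser(UGA)/(CGA)/(GGA)/(GCU) (type II, long
#'     variable arm), Asn(GUU), Asp(GUC) and Arg(GCG) with G73 + C2:G71; and
#'     the negative control Phe(GAA) with A73 + G2:C71. Eleven substrates of
#'     the archaeal enzyme, none of the human enzyme. The G73 members are
#'     encoded with C2:G71, the permitted pair implied for them.}
#'   \item{HC3}{three human cytoplasmic tRNAs (Thr(AGU), Thr(UGU),
#'     Cys(GCA)) with U73 + G2:C71: substrates of the human enzyme only.}
#'   \item{MUTANTS}{the Thr(CGU) mutant series: delta-CCA; C72A/G/U;
#'     U73A/C/G; 2:71 swaps C2G:G71C and C2G:G71U; 3:70 swaps C3G:G70C,
#'     C3A:G70U, C3G:G70U; and all ten D-stem replacements of C11:G24 and
#'     C12:G23 by A:U, U:A, G:C, G:U and U:G. Expected verdicts as assayed:
#'     only U73G, the 3:70 swaps and the D-stem swaps remain substrates.}
#' }
#'
#' @return named list of \code{panel_spec} objects.
#' @export
published_panels <- function() {
  ph_expect_sub <- c(PhNSun6 = TRUE, hNSun6 = FALSE)
  ph_expect_non <- c(PhNSun6 = FALSE, hNSun6 = FALSE)
  u73 <- function(id, ac) {
    member(id, constraints = thr_cgu_constraints(ac), expected = ph_expect_sub)
  }
  g73 <- function(id, ac, long = FALSE) {
    con <- thr_cgu_constraints(ac); con$n73 <- "G"
    con$long_variable_arm <- long
    member(id, constraints = con, expected = ph_expect_sub)
  }
  ph12 <- panel_spec("PH12", list(
    u73("PhtRNA-Thr-CGU", "CGU"),
    u73("PhtRNA-Thr-GGU", "GGU"),
    u73("PhtRNA-Thr-UGU", "UGU"),
    u73("PhtRNA-Cys-GCA", "GCA"),
    g73("PhtRNA-Ser-UGA", "UGA", long = TRUE),
    g73("PhtRNA-Ser-CGA", "CGA", long = TRUE),
    g73("PhtRNA-Ser-GGA", "GGA", long = TRUE),
    g73("PhtRNA-Ser-GCU", "GCU", long = TRUE),
    g73("PhtRNA-Asn-GUU", "GUU"),
    g73("PhtRNA-Asp-GUC", "GUC"),
    g73("PhtRNA-Arg-GCG", "GCG"),
    member("PhtRNA-Phe-GAA",
           constraints = local({
             con <- thr_cgu_constraints("GAA")
             con$n73 <- "A"; con$pair_2_71 <- c("G", "C"); con
           }),
           expected = ph_expect_non)))

  hc_con <- function(ac) {
    con <- thr_cgu_constraints(ac)
    con$pair_2_71 <- c("G", "C")
    con$gc_content_target <- 0.6
    con
  }
  hc_expect <- c(PhNSun6 = FALSE, hNSun6 = TRUE)
  hc3 <- panel_spec("HC3", list(
    member("hctRNA-Thr-AGU", constraints = hc_con("AGU"), expected = hc_expect),
    member("hctRNA-Thr-UGU", constraints = hc_con("UGU"), expected = hc_expect),
    member("hctRNA-Cys-GCA", constraints = hc_con("GCA"), expected = hc_expect)))

  wt <- "PhtRNA-Thr-CGU"
  mut_point <- function(id, pos, base, ok) {
    member(id, base = wt,
           mutations = list(list(op = "point", pos = pos, base = base)),
           expected = c(PhNSun6 = ok))
  }
  mut_swap <- function(id, p5, p3, n5, n3, ok) {
    member(id, base = wt,
           mutations = list(list(op = "pair_swap", pos5 = p5, pos3 = p3,
                                 new5 = n5, new3 = n3)),
           expected = c(PhNSun6 = ok))
  }
  d_swaps <- function(p5, p3, tag) {
    combos <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("G", "U"),
                   c("U", "G"))
    lapply(combos, function(co) {
      mut_swap(sprintf("Thr-CGU-%s-%s%s", tag, co[1], co[2]),
               p5, p3, co[1], co[2], TRUE)
    })
  }
  mutants <- panel_spec("MUTANTS", c(list(
    member(wt, constraints = thr_cgu_constraints("CGU"),
           expected = c(PhNSun6 = TRUE)),
    member("Thr-CGU-dCCA", base = wt,
           mutations = list(list(op = "delete_cca")),
           expected = c(PhNSun6 = FALSE)),
    mut_point("Thr-CGU-C72A", 72, "A", FALSE),
    mut_point("Thr-CGU-C72G", 72, "G", FALSE),
    mut_point("Thr-CGU-C72U", 72, "U", FALSE),
    mut_point("Thr-CGU-U73A", 73, "A", FALSE),
    mut_point("Thr-CGU-U73C", 73, "C", FALSE),
    mut_point("Thr-CGU-U73G", 73, "G", TRUE),
    mut_swap("Thr-CGU-C2G:G71C", 2, 71, "G", "C", FALSE),
    mut_swap("Thr-CGU-C2G:G71U", 2, 71, "G", "U", FALSE),
    mut_swap("Thr-CGU-C3G:G70C", 3, 70, "G", "C", TRUE),
    mut_swap("Thr-CGU-C3A:G70U", 3, 70, "A", "U", TRUE),
    mut_swap("Thr-CGU-C3G:G70U", 3, 70, "G", "U", TRUE)),
    d_swaps(11, 24, "11:24"),
    d_swaps(12, 23, "12:23")))

  list(PH12 = ph12, HC3 = hc3, MUTANTS = mutants)
}
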