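# Constraint-satisfying tRNA scaffold generator. Geometry (1-based indices,
# type I, 76 nt): acceptor 5' 1-7 | 8-9 | D-stem 10-13 | D-loop 14-22 (9 nt) |
# D-stem' 23-26 | 27 | AC-stem 28-32 | AC-loop 33-39 | AC-stem' 40-44 |
# variable 45-48 (4 nt; 14 nt for type II) | T-stem 49-53 | T-loop 54-60 |
# T-stem' 61-65 | acceptor 3' 66-72 | discriminator | CCA.

# Evaluate expr with a private RNG stream; global .Random.seed untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_residue <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || !(x %in% RNA_BASES)) {
    stop("infeasible constraint: ", what, " must be one of A/C/G/U",
         call. = FALSE)
  }
  x
}

check_pair <- function(x, what) {
  if (!is.character(x) || length(x) != 2L || !all(x %in% RNA_BASES)) {
    stop("infeasible constraint: ", what,
         " must be an ordered pair of A/C/G/U residues", call. = FALSE)
  }
  x
}

#' Constraints for a synthetic tRNA scaffold
#'
#' Defines the identity elements and geometry of one generated tRNA:
#' the target site N72, the discriminator N73, base pairs 2:71, 3:70, 11:24
#' and 12:23, CCA presence, variable-arm type and stem GC content. Defaults
#' describe the wild-type archaeal Thr(CGU)-like substrate: U73, C72,
#' C2:G71, C3:G70, C11:G24, C12:G23, CCA present, high-GC stems (0.7) as in
#' hyperthermophile tRNAs.
#'
#' @param n72 residue at canonical position 72.
#' @param n73 discriminator residue.
#' @param pair_2_71,pair_3_70,pair_11_24,pair_12_23 ordered residue pairs
#'   (5' strand, 3' strand).
#' @param cca logical; append the 3' CCA terminus.
#' @param long_variable_arm logical; 14-nt type-II variable arm (serine
#'   tRNAs) instead of the 4-nt type-I region.
#' @param gc_content_target target G+C fraction for unconstrained stem
#'   pairs, in [0.4, 0.9].
#' @param anticodon optional 3-residue anticodon triplet.
#' @param seed integer seed; same seed, same scaffold.
#' @return an object of class \code{"scaffold_constraints"}.
#' @export
scaffold_constraints <- function(n72 = "C", n73 = "U",
                                 pair_2_71 = c("C", "G"),
                                 pair_3_70 = c("C", "G"),
                                 pair_11_24 = c("C", "G"),
                                 pair_12_23 = c("C", "G"),
                                 cca = TRUE, long_variable_arm = FALSE,
                                 gc_content_target = 0.7,
                                 anticodon = NULL, seed = 1L) {
  check_residue(n72, "n72"); check_residue(n73, "n73")
  check_pair(pair_2_71, "pair_2_71"); check_pair(pair_3_70, "pair_3_70")
  check_pair(pair_11_24, "pair_11_24"); check_pair(pair_12_23, "pair_12_23")
  if (!is.numeric(gc_content_target) || gc_content_target < 0.4 ||
        gc_content_target > 0.9) {
    stop("infeasible constraint: gc_content_target must be in [0.4, 0.9]",
         call. = FALSE)
  }
  if (!is.null(anticodon)) {
    anticodon <- normalize_rna(anticodon)
    if (nchar(anticodon) != 3L) {
      stop("infeasible constraint: anticodon must be 3 residues",
           call. = FALSE)
    }
  }
  structure(list(n72 = n72, n73 = n73, pair_2_71 = pair_2_71,
                 pair_3_70 = pair_3_70, pair_11_24 = pair_11_24,
                 pair_12_23 = pair_12_23, cca = isTRUE(cca),
                 long_variable_arm = isTRUE(long_variable_arm),
                 gc_content_target = gc_content_target,
                 anticodon = anticodon, seed = as.integer(seed)),
            class = "scaffold_constraints")
}

# Draw the 5' residue of a free Watson-Crick stem pair with P(G or C) = gc.
draw_stem_base <- function(n, gc) {
  pool <- ifelse(stats::runif(n) < gc,
                 sample(c("G", "C"), n, replace = TRUE),
                 sample(c("A", "U"), n, replace = TRUE))
  pool
}

draw_loop_base <- function(n) sample(RNA_BASES, n, replace = TRUE)

#' Generate a tRNA scaffold satisfying identity-element constraints
#'
#' Builds a 76-nt (86-nt for type II) sequence with canonical cloverleaf
#' geometry: 7-bp acceptor stem, 4-bp D-stem with 9-nt D-loop, 5-bp
#' anticodon stem with 7-nt loop (U33/purine-37 convention, anticodon
#' settable), 4-nt or 14-nt variable region, 5-bp T-stem with 7-nt loop
#' carrying the T54-U55-C56 motif, discriminator and optional CCA.
#' Constrained positions are set exactly; free stem pairs are Watson-Crick
#' with G:C probability at the GC target; free loop residues uniform.
#' Deterministic given the seed.
#'
#' @param constraints a \code{scaffold_constraints} object.
#' @param id identifier for the generated record.
#' @return a \code{trna_record}.
#' @export
generate_scaffold <- function(constraints, id = "scaffold") {
  stopifnot(inherits(constraints, "scaffold_constraints"))
  con <- constraints
  # A CCA-less scaffold whose constrained 3' residues (71=C, 72=C, 73=A)
  # spell CCA is indistinguishable from a CCA-terminated tRNA under
  # 3'-anchored parsing; refuse to generate the ambiguity.
  if (!con$cca && con$pair_2_71[2] == "C" && con$n72 == "C" &&
        con$n73 == "A") {
    stop("infeasible constraint: without a CCA terminus the 3' end ",
         "71=C/72=C/73=A spells CCA and cannot be parsed unambiguously",
         call. = FALSE)
  }
  with_seed(con$seed, {
    gc <- con$gc_content_target
    # Stems as 5' strands; 3' strands derived as WC complements, then
    # constrained pairs overwritten on both strands.
    acc5 <- draw_stem_base(7, gc)
    acc5[1] <- WC_PARTNER[[con$n72]]
    acc5[2] <- con$pair_2_71[1]
    acc5[3] <- con$pair_3_70[1]
    acc3 <- rev(unname(WC_PARTNER[acc5]))       # indices 66..72
    acc3[7] <- con$n72
    acc3[6] <- con$pair_2_71[2]
    acc3[5] <- con$pair_3_70[2]

    dst5 <- draw_stem_base(4, gc)               # canonical 10-13
    dst5[2] <- con$pair_11_24[1]
    dst5[3] <- con$pair_12_23[1]
    dst3 <- rev(unname(WC_PARTNER[dst5]))       # canonical 22-25
    dst3[3] <- con$pair_11_24[2]                # canonical 24
    dst3[2] <- con$pair_12_23[2]                # canonical 23

    acst5 <- draw_stem_base(5, gc)
    acst3 <- rev(unname(WC_PARTNER[acst5]))
    acloop <- draw_loop_base(7)                 # canonical 32-38
    acloop[2] <- "U"                            # U33
    acloop[6] <- sample(c("A", "G"), 1)         # purine 37
    if (!is.null(con$anticodon)) {
      acloop[3:5] <- strsplit(con$anticodon, "")[[1]]
    }

    var_len <- if (con$long_variable_arm) 14L else 4L
    var_reg <- draw_loop_base(var_len)

    tst5 <- draw_stem_base(5, gc)
    tst3 <- rev(unname(WC_PARTNER[tst5]))
    tloop <- draw_loop_base(7)
    tloop[1:3] <- c("U", "U", "C")              # T54-psi55-C56 motif

    seq <- c(acc5,
             "U", sample(c("A", "G"), 1),       # positions 8, 9
             dst5, draw_loop_base(9), dst3,
             draw_loop_base(1),                 # position 26
             acst5, acloop, acst3,
             var_reg,
             tst5, tloop, tst3,
             acc3, con$n73,
             if (con$cca) c("C", "C", "A"))
    trna_record(id, paste(seq, collapse = ""),
                source = sprintf("synthetic scaffold (seed %d)", con$seed))
  })
}

# Deterministic 31-bit seed derived from a base seed and a member id.
derive_seed <- function(base_seed, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)) * 131L)
  as.integer((as.numeric(base_seed) * 7919 + h) %% 2147483647)
}

#' Generate all scaffolds of a panel
#'
#' Builds one scaffold per panel member with member-specific seeds derived
#' from \code{base_seed}. Members defined as mutants of another member are
#' produced by applying the named mutation operations to the parsed
#' wild-type scaffold (never by independent resampling), so a mutant differs
#' from its wild type only at the mutated positions.
#'
#' @param panel a \code{panel_spec}, e.g. from \code{\link{published_panels}}.
#' @param base_seed integer seed.
#' @return an object of class \code{"generated_panel"}: list with
#'   \code{panel_name}, \code{records} (named list of \code{trna_record})
#'   and \code{annotations} (named list of \code{annotated_trna}).
#' @export
generate_panel <- function(panel, base_seed = 1L) {
  stopifnot(inherits(panel, "panel_spec"))
  anns <- list()
  for (m in panel$members) {
    if (!is.null(m$base)) {
      base_ann <- anns[[m$base]]
      if (is.null(base_ann)) {
        stop("panel member '", m$id, "' references unknown base '",
             m$base, "'", call. = FALSE)
      }
      ann <- base_ann
      for (mu in m$mutations) {
        ann <- switch(mu$op,
          point = apply_point_mutation(ann, mu$pos, mu$base, id = m$id),
          pair_swap = apply_pair_swap(ann, mu$pos5, mu$pos3, mu$new5,
                                      mu$new3, id = m$id),
          delete_cca = delete_cca(ann, id = m$id),
          stop("unknown mutation op: ", mu$op, call. = FALSE))
      }
      if (length(m$mutations) == 0L) ann$record$id <- m$id
      anns[[m$id]] <- ann
    } else {
      con_args <- m$constraints
      con_args$seed <- derive_seed(base_seed, m$id)
      con <- do.call(scaffold_constraints, con_args)
      anns[[m$id]] <- parse_cloverleaf(generate_scaffold(con, id = m$id))
    }
  }
  structure(list(panel_name = panel$name,
                 records = lapply(anns, `[[`, "record"),
                 annotations = anns),
            class = "generated_panel")
}

#' @export
print.generated_panel <- function(x, ...) {
  cat(sprintf("Generated panel '%s': %d members\n", x$panel_name,
              length(x$records)))
  for (r in x$records) {
    cat(sprintf("  %-22s %d nt\n", r$id, nchar(r$sequence)))
  }
  invisible(x)
}
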