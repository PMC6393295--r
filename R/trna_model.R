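# Cloverleaf model: canonical numbering with acceptor stem 1-7:66-72,
# discriminator 73, CCA 74-76, D-stem 10:25-13:22. Internal indices are
# 1-based inclusive (R convention); all reported coordinates are canonical.

RNA_BASES <- c("A", "C", "G", "U")
WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

#' Normalize an RNA/DNA sequence string
#'
#' Upper-cases and converts T to U. Errors on residues outside A/C/G/U
#' after normalization.
#'
#' @param sequence character scalar.
#' @return normalized RNA string.
#' @export
normalize_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("tT", "uU", sequence)
  s <- toupper(gsub("\\s", "", s))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), RNA_BASES)
  if (length(bad) > 0L) {
    stop("alphabet error: non-ACGU residue(s) after normalization: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

#' Create a tRNA record
#'
#' A minimal container for one tRNA sequence, as produced by in vitro T7
#' transcription: an identifier, a normalized RNA sequence (60-100 nt) and a
#' free-text provenance tag.
#'
#' @param id character label.
#' @param sequence RNA or DNA string; T is converted to U.
#' @param source free-text provenance.
#' @return an object of class \code{"trna_record"}.
#' @export
trna_record <- function(id, sequence, source = "") {
  seq <- normalize_rna(sequence)
  n <- nchar(seq)
  if (n < 60L || n > 100L) {
    stop("sequence length must be in [60, 100], got ", n, call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = seq,
                 source = as.character(source)),
            class = "trna_record")
}

#' @export
print.trna_record <- function(x, ...) {
  cat(sprintf("tRNA record '%s' (%d nt)\n", x$id, nchar(x$sequence)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

# Classify a base pair: Watson-Crick, wobble (G:U/U:G) or mismatch.
pair_kind <- function(b5, b3) {
  ifelse((b5 == "A" & b3 == "U") | (b5 == "U" & b3 == "A") |
           (b5 == "G" & b3 == "C") | (b5 == "C" & b3 == "G"), "watson-crick",
         ifelse((b5 == "G" & b3 == "U") | (b5 == "U" & b3 == "G"),
                "wobble", "mismatch"))
}

is_valid_pair <- function(b5, b3) pair_kind(b5, b3) != "mismatch"

# Score a candidate 5-bp stem + 7-nt loop hairpin starting at index s0.
# Returns c(valid, wc, flank): counts of non-mismatch pairs, Watson-Crick
# pairs, and loop-flank convention hits (U at loop pos 1, purine at loop
# pos 7 - the U33/R37 convention).
score_hairpin <- function(ch, s0) {
  k <- 0:4
  b5 <- ch[s0 + k]
  b3 <- ch[s0 + 16 - k]
  kinds <- pair_kind(b5, b3)
  c(valid = sum(kinds != "mismatch"),
    wc = sum(kinds == "watson-crick"),
    flank = (ch[s0 + 6] == "U") + (ch[s0 + 10] %in% c("A", "G")))
}

#' Parse a tRNA sequence into an annotated cloverleaf
#'
#' Deterministic 3'-anchored template parse. If the sequence ends in CCA the
#' discriminator is the 4th residue from the 3' end (otherwise the last
#' residue, with \code{cca_present = FALSE}); the acceptor 3' strand is the 7
#' residues 5' of the discriminator, paired against residues 1-7 and required
#' to form at least 5 Watson-Crick/wobble pairs. The anticodon arm is the
#' 5-bp stem with 7-nt loop in the central window maximizing valid then
#' Watson-Crick pairs (loop-flank U33/purine-37 convention used as an early
#' tie-break; remaining ties 5'-most). The T arm is the 5-bp stem + 7-nt loop
#' immediately preceding the acceptor 3' strand; the D arm is the best 3-4 bp
#' stem between position 9 and the anticodon arm, preferring 4 bp.
#'
#' @param record a \code{trna_record}, or a bare sequence string.
#' @return an object of class \code{"annotated_trna"} with components
#'   \code{record}, \code{arm_spans} (data.frame of 1-based inclusive
#'   intervals), \code{position_map} (named integer vector, canonical
#'   position to sequence index), \code{pairs} (data.frame with canonical
#'   coordinates, residues, kind and stem) and \code{cca_present}.
#' @export
parse_cloverleaf <- function(record) {
  if (is.character(record)) record <- trna_record("tRNA", record)
  stopifnot(inherits(record, "trna_record"))
  ch <- strsplit(record$sequence, "")[[1]]
  n <- length(ch)

  cca <- n >= 3L && identical(paste(ch[(n - 2):n], collapse = ""), "CCA")
  disc <- if (cca) n - 3L else n

  if (disc < 50L) {
    stop("parse failure: sequence too short to anchor a cloverleaf",
         call. = FALSE)
  }

  # Acceptor stem: canonical i pairs canonical 73-i at index disc-i.
  acc5_idx <- 1:7
  acc3_idx <- disc - (1:7)          # canonical 72, 71, ..., 66
  acc_kinds <- pair_kind(ch[acc5_idx], ch[acc3_idx])
  if (sum(acc_kinds != "mismatch") < 5L) {
    stop("parse failure: no acceptor-stem anchoring with >= 5 valid pairs",
         call. = FALSE)
  }

  # Anticodon arm search window: central region, clear of the 3' arms.
  t_start <- disc - 24L             # T arm occupies disc-24 .. disc-8
  lo <- max(16L, floor(n / 3) - 10L)
  hi <- min(t_start - 18L, ceiling(2 * n / 3))
  if (hi < lo) stop("parse failure: no room for an anticodon arm", call. = FALSE)
  cands <- list()
  for (s0 in lo:hi) {
    sc <- score_hairpin(ch, s0)
    if (sc[["valid"]] < 4L) next
    cands[[length(cands) + 1L]] <-
      list(s0 = s0, key = c(sc[["valid"]], sc[["flank"]], sc[["wc"]]))
  }
  if (length(cands) == 0L) {
    stop("parse failure: no anticodon stem-loop (5 bp stem, 7 nt loop) ",
         "found in the central window", call. = FALSE)
  }
  # Keep the candidates with the best (valid, flank, wc) score; break the
  # remaining ties by overall cloverleaf consistency (the candidate leaving
  # the best D-stem upstream), then 5'-most.
  top <- cands[[1]]$key
  for (cd in cands) if (lexi_gt(cd$key, top)) top <- cd$key
  cands <- Filter(function(cd) !lexi_gt(top, cd$key), cands)
  best <- NULL
  for (cd in cands) {
    dk <- find_d_arm(ch, cd$s0)
    key <- if (is.null(dk)) c(0, 0, 0, -cd$s0) else {
      loop_len <- dk$c - (dk$a + dk$L)
      c(dk$L, as.integer(loop_len >= 7L && loop_len <= 11L), dk$valid,
        -cd$s0)
    }
    if (is.null(best) || lexi_gt(key, best$key)) {
      best <- list(s0 = cd$s0, key = key, d = dk)
    }
  }
  ac_start <- best$s0
  d_best <- best$d

  # Canonical position map.
  pm <- integer(0)
  add <- function(pm, canon, idx) { pm[as.character(canon)] <- idx; pm }
  pm <- add(pm, 1:7, acc5_idx)
  pm <- add(pm, 8:min(9L, if (is.null(d_best)) 9L else d_best$a - 1L),
            8:min(9L, if (is.null(d_best)) 9L else d_best$a - 1L))
  if (!is.null(d_best)) {
    L <- d_best$L
    pm <- add(pm, 10:(9L + L), d_best$a + 0:(L - 1L))
    loop_idx <- (d_best$a + L):(d_best$c - 1L)
    nl <- min(8L, length(loop_idx))
    pm <- add(pm, 14:(13L + nl), loop_idx[seq_len(nl)])
    pm <- add(pm, (26L - L):25L, d_best$c + 0:(L - 1L))
    if (d_best$e + 1L <= ac_start - 1L) pm <- add(pm, 26L, d_best$e + 1L)
  }
  pm <- add(pm, 27:31, ac_start + 0:4)
  pm <- add(pm, 32:38, ac_start + 5:11)
  pm <- add(pm, 39:43, ac_start + 12:16)
  pm <- add(pm, 49:53, t_start + 0:4)
  pm <- add(pm, 54:60, t_start + 5:11)
  pm <- add(pm, 61:65, t_start + 12:16)
  pm <- add(pm, 66:72, disc - (7:1))
  pm <- add(pm, 73L, disc)
  if (cca) pm <- add(pm, 74:76, disc + 1:3)
  storage.mode(pm) <- "integer"

  # Pair table (canonical coordinates).
  mk_pairs <- function(p5, p3, stem) {
    i5 <- pm[as.character(p5)]; i3 <- pm[as.character(p3)]
    data.frame(pos5 = p5, pos3 = p3, base5 = ch[i5], base3 = ch[i3],
               kind = pair_kind(ch[i5], ch[i3]), stem = stem,
               stringsAsFactors = FALSE)
  }
  pairs <- mk_pairs(1:7, 72:66, "acceptor")
  if (!is.null(d_best)) {
    L <- d_best$L
    pairs <- rbind(pairs, mk_pairs(10:(9L + L), 25:(26L - L), "D"))
  }
  pairs <- rbind(pairs,
                 mk_pairs(27:31, 43:39, "anticodon"),
                 mk_pairs(49:53, 65:61, "T"))

  # Arm spans: disjoint, ordered 5'->3', covering the whole sequence.
  d_end <- ac_start - 1L
  spans <- data.frame(
    region = c("acceptor-5p", "D-arm", "anticodon-arm", "variable",
               "T-arm", "acceptor-3p", "discriminator",
               if (cca) "CCA"),
    start = c(1L, 8L, ac_start, ac_start + 17L, t_start, disc - 7L, disc,
              if (cca) disc + 1L),
    end = c(7L, d_end, ac_start + 16L, t_start - 1L, disc - 8L, disc - 1L,
            disc, if (cca) disc + 3L),
    stringsAsFactors = FALSE)
  spans <- spans[spans$start <= spans$end, , drop = FALSE]
  rownames(spans) <- NULL

  structure(list(record = record, arm_spans = spans, position_map = pm,
                 pairs = pairs, cca_present = cca),
            class = "annotated_trna")
}

# Lexicographic greater-than for numeric score vectors.
lexi_gt <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0L && d[i[1]] > 0
}

# Best 3-4 bp D-stem between index 10 (positions 8-9 are the canonical
# linker) and a putative anticodon arm start, preferring 4 bp, then most
# valid pairs, then a stem 3' end at the canonical one-residue spacing
# before the anticodon arm, then 5'-most.
find_d_arm <- function(ch, ac_start) {
  d_best <- NULL
  for (L in c(4L, 3L)) {
    a_hi <- ac_start - 2L * L - 3L
    if (a_hi < 10L) next
    for (a in 10:a_hi) {
      cc_lo <- a + L + 3L
      cc_hi <- ac_start - L
      if (cc_hi < cc_lo) next
      for (cc in cc_lo:cc_hi) {
        e <- cc + L - 1L
        if (e > ac_start - 1L) next
        k <- 0:(L - 1L)
        kinds <- pair_kind(ch[a + k], ch[e - k])
        valid <- sum(kinds != "mismatch")
        if (valid < L - 1L) next
        key <- c(L, -abs(e - (ac_start - 2L)), -a, valid)
        if (is.null(d_best) || lexi_gt(key, d_best$key)) {
          d_best <- list(a = a, L = L, e = e, c = cc, valid = valid,
                         key = key)
        }
      }
    }
    if (!is.null(d_best)) break   # prefer 4 bp outright
  }
  d_best
}

#' @export
print.annotated_trna <- function(x, ...) {
  cat(sprintf("Annotated tRNA '%s' (%d nt, CCA %s)\n", x$record$id,
              nchar(x$record$sequence),
              if (x$cca_present) "present" else "absent"))
  sp <- x$arm_spans
  cat(paste(sprintf("  %-13s %3d-%3d", sp$region, sp$start, sp$end),
            collapse = "\n"), "\n")
  pr <- element_profile(x)
  cat("Identity elements: "); print(pr)
  invisible(x)
}

residue_at <- function(annotated, canonical) {
  idx <- annotated$position_map[as.character(canonical)]
  if (is.na(idx)) return(NA_character_)
  substr(annotated$record$sequence, idx, idx)
}

pair_at <- function(annotated, p5, p3) {
  pr <- annotated$pairs
  row <- pr[pr$pos5 == p5 & pr$pos3 == p3, ]
  if (nrow(row) == 0L) return(NULL)
  c(row$base5[1], row$base3[1])
}

#' Extract the identity-element profile of an annotated tRNA
#'
#' Reads the residues and base pairs at the canonical positions that NSun6
#' enzymes recognize: position 72 (the target cytosine), the discriminator
#' base 73, acceptor-stem pairs 2:71 and 3:70, D-stem pairs 11:24 and 12:23,
#' and the presence of the 3' CCA terminus. Positions missing from the
#' annotation (e.g. a 3-bp D-stem) are reported as NULL, never an error.
#'
#' @param annotated an \code{annotated_trna}.
#' @return an object of class \code{"identity_profile"}.
#' @export
element_profile <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_trna"))
  structure(list(
    trna_id = annotated$record$id,
    n72 = residue_at(annotated, 72L),
    n73 = residue_at(annotated, 73L),
    pair_2_71 = pair_at(annotated, 2L, 71L),
    pair_3_70 = pair_at(annotated, 3L, 70L),
    pair_11_24 = pair_at(annotated, 11L, 24L),
    pair_12_23 = pair_at(annotated, 12L, 23L),
    cca_present = annotated$cca_present), class = "identity_profile")
}

fmt_pair <- function(p) if (is.null(p)) "unpaired" else paste0(p[1], ":", p[2])

#' @export
print.identity_profile <- function(x, ...) {
  cat(sprintf("N72=%s N73=%s 2:71=%s 3:70=%s 11:24=%s 12:23=%s CCA=%s\n",
              x$n72, x$n73, fmt_pair(x$pair_2_71), fmt_pair(x$pair_3_70),
              fmt_pair(x$pair_11_24), fmt_pair(x$pair_12_23),
              if (x$cca_present) "yes" else "no"))
  invisible(x)
}

reparse <- function(annotated, new_seq, id = annotated$record$id) {
  parse_cloverleaf(trna_record(id, new_seq, annotated$record$source))
}

#' Apply a point mutation at a canonical position
#'
#' Replaces the residue at one canonical position (e.g. U73G) and re-parses
#' the mutated sequence. Exactly one residue of the raw sequence changes.
#'
#' @param annotated an \code{annotated_trna}.
#' @param position canonical position present in the position map.
#' @param base replacement residue (A/C/G/U).
#' @param id optional identifier for the mutant record.
#' @return a re-parsed \code{annotated_trna}.
#' @export
apply_point_mutation <- function(annotated, position, base,
                                 id = annotated$record$id) {
  stopifnot(inherits(annotated, "annotated_trna"))
  base <- normalize_rna(base)
  idx <- annotated$position_map[as.character(position)]
  if (is.na(idx) || is.null(idx) || length(idx) == 0L) {
    stop("unknown position: canonical ", position,
         " is not in the position map", call. = FALSE)
  }
  s <- annotated$record$sequence
  substr(s, idx, idx) <- base
  reparse(annotated, s, id)
}

#' Replace both residues of an annotated base pair
#'
#' Implements assay-style pair swaps, e.g. C2G:G71C: both strands of a
#' stem pair are replaced in one operation and the result re-parsed.
#'
#' @param annotated an \code{annotated_trna}.
#' @param pos5,pos3 canonical coordinates of an annotated pair.
#' @param new5,new3 replacement residues for the 5' and 3' strands.
#' @param id optional identifier for the mutant record.
#' @return a re-parsed \code{annotated_trna}.
#' @export
apply_pair_swap <- function(annotated, pos5, pos3, new5, new3,
                            id = annotated$record$id) {
  stopifnot(inherits(annotated, "annotated_trna"))
  pr <- annotated$pairs
  if (!any(pr$pos5 == pos5 & pr$pos3 == pos3)) {
    stop("not a pair: ", pos5, ":", pos3,
         " is not an annotated base pair", call. = FALSE)
  }
  i5 <- annotated$position_map[as.character(pos5)]
  i3 <- annotated$position_map[as.character(pos3)]
  s <- annotated$record$sequence
  substr(s, i5, i5) <- normalize_rna(new5)
  substr(s, i3, i3) <- normalize_rna(new3)
  reparse(annotated, s, id)
}

#' Delete the 3' CCA terminus
#'
#' Removes the last three residues of a CCA-terminated tRNA (the assayed
#' delta-CCA mutant) and re-parses; the discriminator keeps canonical
#' number 73.
#'
#' @param annotated an \code{annotated_trna} with \code{cca_present = TRUE}.
#' @param id optional identifier for the mutant record.
#' @return a re-parsed \code{annotated_trna} with \code{cca_present = FALSE}.
#' @export
delete_cca <- function(annotated, id = annotated$record$id) {
  stopifnot(inherits(annotated, "annotated_trna"))
  if (!annotated$cca_present) {
    stop("no CCA terminus to delete", call. = FALSE)
  }
  s <- annotated$record$sequence
  reparse(annotated, substr(s, 1L, nchar(s) - 3L), id)
}

# Per-monomer molar absorptivities at 260 nm (per molar per cm), additive
# base-composition model without hypochromicity correction.
EXT_COEF_260 <- c(A = 15400, C = 7400, G = 11500, U = 9900)

#' Molar extinction coefficient at 260 nm
#'
#' Additive base-composition estimate used to convert A260 into molar tRNA
#' concentration: the sum of fixed per-monomer coefficients (AMP 15400,
#' CMP 7400, GMP 11500, UMP 9900 per molar per cm).
#'
#' @param record a \code{trna_record} or sequence string.
#' @return extinction coefficient in \eqn{M^{-1} cm^{-1}}.
#' @export
extinction_coefficient_260 <- function(record) {
  seq <- if (inherits(record, "trna_record")) record$sequence
         else normalize_rna(record)
  counts <- table(factor(strsplit(seq, "")[[1]], levels = RNA_BASES))
  sum(as.numeric(counts) * EXT_COEF_260[RNA_BASES])
}
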