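# Shared fixtures: all built in code at test time.

VALID_PAIRS <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                    c("G", "U"), c("U", "G"))

ALL_PAIRS <- unlist(lapply(c("A", "C", "G", "U"), function(b5) {
  lapply(c("A", "C", "G", "U"), function(b3) c(b5, b3))
}), recursive = FALSE)

# Wild-type Thr(CGU)-like scaffold: U73, C72, C2:G71, C3:G70, C11:G24,
# C12:G23, CCA.
thr_cgu_constraints_fix <- function(seed = 11L) {
  scaffold_constraints(n72 = "C", n73 = "U", pair_2_71 = c("C", "G"),
                       pair_3_70 = c("C", "G"), pair_11_24 = c("C", "G"),
                       pair_12_23 = c("C", "G"), cca = TRUE,
                       anticodon = "CGU", seed = seed)
}

thr_cgu_ann <- function(seed = 11L) {
  parse_cloverleaf(generate_scaffold(thr_cgu_constraints_fix(seed),
                                     id = "Thr-CGU"))
}

# Build an identity profile directly (classifier input for enumeration
# oracles).
make_profile <- function(n72 = "C", n73 = "U", pair_2_71 = c("C", "G"),
                         pair_3_70 = c("C", "G"), pair_11_24 = c("C", "G"),
                         pair_12_23 = c("C", "G"), cca_present = TRUE,
                         id = "synthetic-profile") {
  structure(list(trna_id = id, n72 = n72, n73 = n73, pair_2_71 = pair_2_71,
                 pair_3_70 = pair_3_70, pair_11_24 = pair_11_24,
                 pair_12_23 = pair_12_23, cca_present = cca_present),
            class = "identity_profile")
}

residue_at_test <- function(ann, pos) {
  idx <- ann$position_map[[as.character(pos)]]
  substr(ann$record$sequence, idx, idx)
}

# Independent oracle for the archaeal rules: direct constraint conjunction,
# written without reference to classify() internals.
ph_oracle <- function(profile) {
  isTRUE(profile$cca_present) &&
    identical(profile$n72, "C") &&
    profile$n73 %in% c("U", "G") &&
    !is.null(profile$pair_2_71) &&
    identical(unname(profile$pair_2_71), c("C", "G"))
}

h_oracle <- function(profile) {
  isTRUE(profile$cca_present) &&
    identical(profile$n72, "C") &&
    identical(profile$n73, "U") &&
    !is.null(profile$pair_2_71) &&
    identical(unname(profile$pair_2_71), c("G", "C"))
}
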