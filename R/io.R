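# File formats: FASTA in/out (Biostrings), TSV tables, JSON annotation and
# result exports, declarative rule-set / panel configuration (JSON or YAML).

#' Read tRNA records from a FASTA file
#'
#' Accepts RNA or DNA alphabet; sequences are normalized (T to U,
#' upper case) on import.
#'
#' @param path FASTA file (multi-record supported).
#' @return named list of \code{trna_record} objects.
#' @export
read_trna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  recs <- lapply(seq_along(set), function(i) {
    trna_record(names(set)[i], as.character(set[[i]]),
                source = paste0("fasta:", basename(path)))
  })
  stats::setNames(recs, names(set))
}

#' Write tRNA records to a FASTA file
#'
#' @param records list of \code{trna_record} (or a \code{generated_panel}).
#' @param path output file; lines wrapped at 60 columns.
#' @return invisibly, \code{path}.
#' @export
write_trna_fasta <- function(records, path) {
  if (inherits(records, "generated_panel")) records <- records$records
  if (inherits(records, "trna_record")) records <- list(records)
  seqs <- Biostrings::RNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Export a cloverleaf annotation as JSON
#'
#' Serializes arm spans, the canonical position map and the base-pair list.
#'
#' @param annotated an \code{annotated_trna}.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
annotation_json <- function(annotated, path = NULL) {
  stopifnot(inherits(annotated, "annotated_trna"))
  obj <- list(id = annotated$record$id,
              sequence = annotated$record$sequence,
              cca_present = annotated$cca_present,
              arm_spans = annotated$arm_spans,
              position_map = as.list(annotated$position_map),
              pairs = annotated$pairs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write panel classification results
#'
#' @param results a \code{panel_classification}.
#' @param tsv,json optional output paths. The TSV carries columns id,
#'   ruleset, substrate, violations.
#' @return \code{results}, invisibly.
#' @export
write_panel_results <- function(results, tsv = NULL, json = NULL) {
  core <- results[, c("id", "ruleset", "substrate", "violations")]
  if (!is.null(tsv)) {
    utils::write.table(core, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(results = core,
           counts = list(substrates = attr(results, "n_substrate"),
                         non_substrates = attr(results, "n_non_substrate"))),
      json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}

#' Read/write initial-rate datasets as TSV
#'
#' Two columns: \code{s_uM}, \code{v_uM_per_min}; the enzyme concentration
#' travels as a \code{# enzyme_nM=} header comment.
#'
#' @param data a \code{rate_dataset}.
#' @param path file path.
#' @return \code{write_rate_tsv}: the path, invisibly;
#'   \code{read_rate_tsv}: a \code{rate_dataset}.
#' @export
write_rate_tsv <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# enzyme_nM=%g", attr(data, "enzyme_nM")), con)
  utils::write.table(data.frame(s_uM = data$s_uM,
                                v_uM_per_min = data$v_uM_per_min),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_tsv
#' @export
read_rate_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  e <- if (grepl("^# enzyme_nM=", first)) {
    as.numeric(sub("^# enzyme_nM=", "", first))
  } else NA_real_
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(out, "enzyme_nM") <- e
  class(out) <- c("rate_dataset", "data.frame")
  out
}

#' Read/write melting curves as two-column TSV
#'
#' Columns \code{temp_c}, \code{a260}.
#'
#' @param curve a \code{melting_curve}.
#' @param path file path.
#' @return \code{write_melt_tsv}: the path, invisibly;
#'   \code{read_melt_tsv}: a \code{melting_curve}.
#' @export
write_melt_tsv <- function(curve, path) {
  utils::write.table(data.frame(temp_c = curve$temp_c, a260 = curve$a260),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_tsv
#' @export
read_melt_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("melting_curve", "data.frame")
  out
}

parse_pair_string <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(nchar(parts) == 1L)) {
    stop("pair must be written as '<base5>:<base3>', got '", x, "'",
         call. = FALSE)
  }
  toupper(parts)
}

ruleset_from_config <- function(entry) {
  pairs_of <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(as.character(unlist(x)), parse_pair_string)
  }
  d <- entry$required_d_stem_pairs
  if (!is.null(d)) d <- lapply(d, pairs_of)
  rule_set(name = entry$name,
           required_cca = !isFALSE(entry$required_cca),
           required_n72 = if (is.null(entry$required_n72)) "C"
                          else as.character(unlist(entry$required_n72)),
           allowed_n73 = as.character(unlist(entry$allowed_n73)),
           required_pair_2_71 = pairs_of(entry$required_pair_2_71),
           required_pair_3_70 = pairs_of(entry$required_pair_3_70),
           required_d_stem_pairs = d)
}

#' Load rule sets from a declarative configuration file
#'
#' JSON (\code{.json}) or YAML (anything else) with the schema:
#' \preformatted{
#' rulesets:
#'   - name: MyEnzyme
#'     required_cca: true
#'     required_n72: [C]
#'     allowed_n73: [U, G]
#'     required_pair_2_71: ["C:G"]   # ordered "base5:base3" strings
#'     required_pair_3_70: ~          # null/omitted = unconstrained
#'     required_d_stem_pairs:
#'       "11:24": ["C:G", "G:C"]
#' }
#'
#' @param path configuration file.
#' @return named list of \code{rule_set} objects.
#' @export
load_rulesets <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  entries <- cfg$rulesets
  if (is.null(entries)) stop("config has no 'rulesets' key", call. = FALSE)
  out <- lapply(entries, ruleset_from_config)
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}
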