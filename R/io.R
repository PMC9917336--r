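# Standard-format I/O: FASTA via Biostrings, TSV reports, JSON configs.

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write the enumerated barcode library as FASTA
#'
#' Record ids are the underscore-joined 0-based variant indices
#' (e.g. `bc_1_3_0_2`).
#'
#' @param design a `library_design`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(design, path) {
  lib <- enumerate_library(design)
  write_fasta(setNames(lib$sequence, lib$id), path)
}

#' Write a validation report as TSV
#'
#' @param report data.frame from [validate_variable_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize code constraints or a variable-region set to JSON
#'
#' @param x a `code_constraints` or `variable_region_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(x, path) {
  obj <- if (inherits(x, "code_constraints")) {
    list(type = "code_constraints", fields = unclass(x))
  } else if (inherits(x, "variable_region_set")) {
    list(type = "variable_region_set",
         sequences = x$sequences,
         constraints = unclass(x$constraints),
         provenance = x$provenance)
  } else if (inherits(x, "library_design")) {
    list(type = "library_design",
         layout = as.data.frame(x$layout)[, c("name", "role", "length")],
         sequences = x$vset$sequences,
         constraints = unclass(x$vset$constraints),
         provenance = x$vset$provenance,
         overhangs = x$overhangs,
         primers = x$primers,
         traptag_whitelist = x$traptag_whitelist,
         primer_sets = x$primer_sets,
         seed = x$seed)
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Deserialize an object written by [write_design_json()]
#'
#' Library designs are rebuilt through [compile_blocks()], regenerating the
#' seeded constant padding, so a round trip reproduces the design exactly.
#'
#' @param path JSON file.
#' @return the reconstructed object.
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cons_from <- function(f) {
    code_constraints(k = f$k, max_homopolymer_run = f$max_homopolymer_run,
                     min_hamming = f$min_hamming,
                     min_shifted_hamming = f$min_shifted_hamming,
                     forbid_duplicates = f$forbid_duplicates,
                     unique_terminal_nt = f$unique_terminal_nt)
  }
  as_block_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) unname(x[i, ]))
    else lapply(x, unlist)
  }
  if (obj$type == "code_constraints") return(cons_from(obj$fields))
  if (obj$type == "variable_region_set") {
    return(variable_region_set(as_block_list(obj$sequences),
                               cons_from(obj$constraints),
                               obj$provenance))
  }
  if (obj$type == "library_design") {
    vset <- variable_region_set(as_block_list(obj$sequences),
                                cons_from(obj$constraints),
                                obj$provenance)
    layout <- layout_config(obj$layout)
    compile_blocks(layout, vset, obj$overhangs, obj$primers,
                   traptag_whitelist = obj$traptag_whitelist,
                   primer_sets = obj$primer_sets, seed = obj$seed)
  } else stop("unsupported JSON object", call. = FALSE)
}

#' Read a run configuration (JSON or YAML)
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", ext, call. = FALSE)
}
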