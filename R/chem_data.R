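#' Normalize typographic variants in a repeat-unit SMILES
#'
#' Published tables frequently typeset the attachment-point wildcard as the
#' asterisk operator glyph (U+2217) and insert spaces around bond symbols.
#' Neither is chemistry: this helper maps such typography back to plain ASCII
#' SMILES before parsing. It never touches the molecular graph itself.
#'
#' @param smiles character vector of raw SMILES strings.
#' @return character vector of cleaned SMILES.
#' @examples
#' normalize_smiles_typography("∗CC(∗)c1ccccc1")
#' @export
normalize_smiles_typography <- function(smiles) {
  out <- gsub("∗", "*", smiles, fixed = TRUE)
  out <- gsub("[[:space:]]+", "", out)
  out
}

#' Canonicalize a SMILES string (wildcard atoms preserved)
#'
#' Converts each SMILES to OpenBabel's canonical form so that two spellings of
#' the same molecular graph map to the same string. Attachment-point `*` atoms
#' are legal wildcard atoms and survive the round trip. The operation is
#' idempotent.
#'
#' @param smiles character vector of SMILES (typography is normalized first).
#' @return character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles(c("*CC(O)*", "C(C(O)*)*"))
#' @export
canonicalize_smiles <- function(smiles) {
  smiles <- normalize_smiles_typography(smiles)
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) {
      stop("cannot canonicalize empty SMILES", call. = FALSE)
    }
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
    out <- trimws(out)
    if (!nzchar(out)) {
      stop("SMILES failed to parse: '", s, "'", call. = FALSE)
    }
    # canonical output is "smiles\ttitle" or bare smiles
    strsplit(out, "[\t ]")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the string parses as a molecule
#'   (with `*` wildcard support).
#' @export
smiles_parses <- function(smiles) {
  smiles <- normalize_smiles_typography(smiles)
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    ok <- try(canonicalize_smiles(s), silent = TRUE)
    !inherits(ok, "try-error")
  }, logical(1), USE.NAMES = FALSE)
}

#' Construct a degradation dataset
#'
#' A degradation dataset is an ordered collection of polymers (repeat-unit
#' SMILES with `*` attachment points) with one non-negative degradability
#' value per polymer. Values are comparable only *within* a dataset; this is
#' the premise of the whole rank-based integration.
#'
#' @param records data.frame with at least columns `smiles` and `value`;
#'   optional `name` and `abbreviation`. Extra columns are kept.
#' @param id dataset label, e.g. `"literature"`, `"exp1"`.
#' @param units free-text unit label (e.g. `"%/day"` or `"delta"`).
#' @param canonicalize canonicalize SMILES on construction (default `TRUE`);
#'   the raw string is kept in column `smiles_raw`.
#' @return object of class `degradation_dataset`: a list with elements `id`,
#'   `units` and `records` (a data.frame with columns `id`, `name`,
#'   `abbreviation`, `smiles`, `smiles_raw`, `value`).
#' @export
degradation_dataset <- function(records, id, units = "", canonicalize = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (!all(c("smiles", "value") %in% names(records))) {
    stop("records must have columns 'smiles' and 'value'", call. = FALSE)
  }
  value <- as.numeric(records$value)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("degradability values must be finite and >= 0", call. = FALSE)
  }
  raw <- normalize_smiles_typography(as.character(records$smiles))
  smi <- if (canonicalize) canonicalize_smiles(raw) else raw
  if (anyDuplicated(smi)) {
    dup <- unique(smi[duplicated(smi)])
    stop("duplicate SMILES within dataset '", id, "': ",
         paste(dup, collapse = ", "),
         " (within-dataset duplicates make preferences ill-defined)",
         call. = FALSE)
  }
  abbr <- if ("abbreviation" %in% names(records)) {
    as.character(records$abbreviation)
  } else {
    sprintf("%s_%02d", id, seq_len(nrow(records)))
  }
  if (anyDuplicated(abbr)) {
    stop("abbreviations must be unique within dataset '", id, "'",
         call. = FALSE)
  }
  name <- if ("name" %in% names(records)) as.character(records$name) else abbr
  out <- data.frame(
    id = paste(id, abbr, sep = ":"),
    name = name,
    abbreviation = abbr,
    smiles = smi,
    smiles_raw = raw,
    value = value,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(records), c(names(out), "smiles", "value"))
  for (col in extra) out[[col]] <- records[[col]]
  structure(list(id = id, units = units, records = out),
            class = "degradation_dataset")
}

#' @export
print.degradation_dataset <- function(x, ...) {
  cat(sprintf("degradation_dataset '%s': %d polymers (units: %s)\n",
              x$id, nrow(x$records),
              if (nzchar(x$units)) x$units else "unspecified"))
  print(utils::head(x$records[, c("abbreviation", "smiles", "value")], 10))
  if (nrow(x$records) > 10) cat("...\n")
  invisible(x)
}

#' Read a degradability table from disk
#'
#' Accepts CSV or TSV with a header row (the dialect is inferred from the
#' file extension, or forced with `sep`). Rows whose SMILES fail to parse are
#' rejected and reported in the `rejected` attribute, never silently dropped.
#'
#' @param path path to a delimited text file.
#' @param dataset_id label recorded as provenance on every record.
#' @param column_map named list mapping the canonical roles `smiles`, `value`
#'   and optionally `name`, `abbreviation` to column names in the file.
#'   Defaults to identically named columns.
#' @param units unit label stored on the dataset.
#' @param sep field separator; default inferred (`","` for .csv, else tab).
#' @return a [degradation_dataset()]; attribute `rejected` holds a data.frame
#'   of rejected rows (columns `row`, `smiles`, `reason`).
#' @export
read_dataset <- function(path, dataset_id,
                         column_map = list(smiles = "smiles", value = "value"),
                         units = "", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE)
  for (role in c("smiles", "value")) {
    col <- column_map[[role]]
    if (is.null(col)) col <- role
    if (!col %in% names(tab)) {
      stop("mapped column '", col, "' (role '", role, "') not found in ",
           path, call. = FALSE)
    }
  }
  get_col <- function(role) {
    col <- column_map[[role]]
    if (is.null(col)) col <- role
    if (col %in% names(tab)) tab[[col]] else NULL
  }
  smi <- normalize_smiles_typography(as.character(get_col("smiles")))
  val <- suppressWarnings(as.numeric(get_col("value")))
  ok_smi <- smiles_parses(smi)
  ok_val <- is.finite(val) & val >= 0
  keep <- ok_smi & ok_val
  reason <- ifelse(!ok_smi, "unparseable SMILES",
                   ifelse(!ok_val, "missing/negative value", ""))
  rejected <- data.frame(row = which(!keep), smiles = smi[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("no valid rows in ", path, " (", nrow(rejected), " rejected)",
         call. = FALSE)
  }
  rec <- data.frame(smiles = smi[keep], value = val[keep],
                    stringsAsFactors = FALSE)
  nm <- get_col("name"); ab <- get_col("abbreviation")
  if (!is.null(nm)) rec$name <- as.character(nm)[keep]
  if (!is.null(ab)) rec$abbreviation <- as.character(ab)[keep]
  # carry through exposure-measurement columns when present (exp1-style files)
  for (col in intersect(c("W_film", "TOC", "TC", "IC", "V_water", "M_c",
                          "S_film"), names(tab))) {
    rec[[col]] <- suppressWarnings(as.numeric(tab[[col]]))[keep]
  }
  ds <- degradation_dataset(rec, id = dataset_id, units = units)
  attr(ds, "rejected") <- rejected
  ds
}

#' Write a degradation dataset as canonical TSV
#'
#' Emits columns `dataset_id`, `abbreviation`, `name`, `smiles`, `value`,
#' `units`. The output round-trips through [read_dataset()].
#'
#' @param dataset a [degradation_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  r <- dataset$records
  out <- data.frame(dataset_id = dataset$id,
                    abbreviation = r$abbreviation,
                    name = r$name,
                    smiles = r$smiles,
                    value = r$value,
                    units = dataset$units,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
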