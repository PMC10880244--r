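# Clinical table schema: column names in their required file order.
CLINICAL_COLUMNS <- c(
  "patient_id", "arm", "sex", "histology", "smoking", "ecog",
  "tmb", "pdl1", "pfs_time", "pfs_event", "os_time", "os_event", "bor_pd"
)

ARM_LEVELS <- c("ICI", "CHEMO")

icibench_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "icibench_error")))
}

#' Two-arm trial dataset
#'
#' Bundles the clinical table of a randomized two-arm trial (immune
#' checkpoint inhibitor vs chemotherapy) with its genes-by-patients
#' expression matrix and validates the joint invariants: unique patient
#' identifiers, expression columns matching the clinical rows, positive
#' follow-up times, binary event indicators, and PD-L1 percentages in
#' \[0, 100\].
#'
#' @param clinical data.frame with columns `patient_id` (unique strings),
#'   `arm` ("ICI"/"CHEMO"), `sex` ("male"/"female"), `histology`
#'   ("squamous"/"nonsquamous"), `smoking` ("ever"/"never"), `ecog`
#'   (0 or 1), `tmb` (non-negative missense-mutation count, may be `NA`),
#'   `pdl1` (percent tumor cells staining positive, may be `NA`),
#'   `pfs_time`/`os_time` (months, > 0), `pfs_event`/`os_event` (0/1), and
#'   `bor_pd` (1 = best overall response is progressive disease, may be `NA`).
#' @param expression numeric matrix, genes in rows (rownames = gene ids),
#'   patients in columns (colnames = `patient_id`). Assumed already
#'   log-scale and library-normalized; no normalization is applied here.
#'
#' @return An object of class `trial_dataset`: a list with elements
#'   `clinical` and `expression` (columns reordered to the clinical row
#'   order).
#' @export
trial_dataset <- function(clinical, expression) {
  clinical <- as.data.frame(clinical)
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(clinical))
  if (length(missing_cols) > 0) {
    icibench_error("icibench_schema_error", paste0(
      "clinical table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  clinical <- clinical[, CLINICAL_COLUMNS]
  clinical$patient_id <- as.character(clinical$patient_id)
  if (nrow(clinical) == 0) {
    icibench_error("icibench_schema_error", "dataset has no patients")
  }
  if (anyDuplicated(clinical$patient_id)) {
    dup <- unique(clinical$patient_id[duplicated(clinical$patient_id)])
    icibench_error("icibench_duplicate_id_error", paste0(
      "duplicated patient_id value(s): ", paste(dup, collapse = ", ")
    ))
  }

  for (col in c("tmb", "pdl1", "pfs_time", "pfs_event",
                "os_time", "os_event", "bor_pd", "ecog")) {
    v <- clinical[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- !is.na(v) & v != "NA" & is.na(vn)
      if (any(bad)) {
        icibench_error("icibench_value_error", paste0(
          "non-numeric values in column '", col, "'"
        ))
      }
      v <- vn
    }
    clinical[[col]] <- as.numeric(v)
  }

  check_levels <- function(col, levels) {
    v <- clinical[[col]]
    if (!all(v[!is.na(v)] %in% levels)) {
      icibench_error("icibench_value_error", paste0(
        "column '", col, "' must be one of: ", paste(levels, collapse = ", ")
      ))
    }
  }
  check_levels("arm", ARM_LEVELS)
  check_levels("sex", c("male", "female"))
  check_levels("histology", c("squamous", "nonsquamous"))
  check_levels("smoking", c("ever", "never"))
  if (!all(clinical$ecog %in% c(0, 1))) {
    icibench_error("icibench_value_error", "ecog must be 0 or 1")
  }

  for (col in c("pfs_time", "os_time")) {
    if (any(is.na(clinical[[col]]) | clinical[[col]] <= 0)) {
      icibench_error("icibench_value_error",
                     paste0("all ", col, " values must be present and > 0"))
    }
  }
  for (col in c("pfs_event", "os_event")) {
    if (any(is.na(clinical[[col]]) | !clinical[[col]] %in% c(0, 1))) {
      icibench_error("icibench_value_error",
                     paste0(col, " must be 0 or 1 for every patient"))
    }
  }
  bor <- clinical$bor_pd
  if (any(!is.na(bor) & !bor %in% c(0, 1))) {
    icibench_error("icibench_value_error", "bor_pd must be 0, 1 or NA")
  }
  tmb <- clinical$tmb
  if (any(!is.na(tmb) & tmb < 0)) {
    icibench_error("icibench_value_error", "tmb must be non-negative")
  }
  pdl1 <- clinical$pdl1
  if (any(!is.na(pdl1) & (pdl1 < 0 | pdl1 > 100))) {
    icibench_error("icibench_value_error", "pdl1 must lie in [0, 100]")
  }

  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  if (is.null(colnames(expression)) ||
      !setequal(colnames(expression), clinical$patient_id) ||
      ncol(expression) != nrow(clinical)) {
    icibench_error("icibench_sample_mismatch_error", paste0(
      "expression column names do not match clinical patient ids (",
      ncol(expression), " expression columns vs ",
      nrow(clinical), " patients)"
    ))
  }
  expression <- expression[, clinical$patient_id, drop = FALSE]

  rownames(clinical) <- NULL
  structure(list(clinical = clinical, expression = expression),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cl <- x$clinical
  cat("trial_dataset:", nrow(cl), "patients (",
      sum(cl$arm == "ICI"), "ICI /", sum(cl$arm == "CHEMO"), "CHEMO ),",
      nrow(x$expression), "genes\n")
  cat("  missing TMB:", sum(is.na(cl$tmb)),
      " missing PD-L1:", sum(is.na(cl$pdl1)), "\n")
  invisible(x)
}

#' Number of patients in a trial dataset
#' @param dataset a `trial_dataset`.
#' @return integer patient count.
#' @export
n_patients <- function(dataset) nrow(dataset$clinical)

#' Read a two-arm trial from TSV files
#'
#' @param clinical_path path to a tab-separated clinical table with the
#'   column order `patient_id, arm, sex, histology, smoking, ecog, tmb,
#'   pdl1, pfs_time, pfs_event, os_time, os_event, bor_pd`; missing values
#'   are the literal string `NA`.
#' @param expression_path path to a tab-separated expression table with
#'   header `gene_id` followed by the patient ids, one gene per row.
#' @return a validated [trial_dataset].
#' @export
read_trial <- function(clinical_path, expression_path) {
  clinical <- utils::read.delim(clinical_path, sep = "\t",
                                colClasses = "character",
                                na.strings = NULL,
                                check.names = FALSE)
  clinical[clinical == "NA"] <- NA
  expr_tab <- utils::read.delim(expression_path, sep = "\t",
                                check.names = FALSE, na.strings = "NA")
  if (names(expr_tab)[1] != "gene_id") {
    icibench_error("icibench_schema_error",
                   "expression table must start with a 'gene_id' column")
  }
  expr <- as.matrix(expr_tab[, -1, drop = FALSE])
  rownames(expr) <- as.character(expr_tab$gene_id)
  trial_dataset(clinical, expr)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a two-arm trial to TSV files
#'
#' Text encoding is bit-stable: `read_trial(write_trial(d))` reproduces the
#' dataset exactly (numerics are written with 17 significant digits, missing
#' values as the literal `NA`).
#'
#' @param dataset a valid [trial_dataset].
#' @param clinical_path,expression_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_trial <- function(dataset, clinical_path, expression_path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  cl <- dataset$clinical
  if (nrow(cl) == 0) {
    icibench_error("icibench_value_error", "refusing to write empty dataset")
  }
  out <- cl
  for (col in c("ecog", "tmb", "pdl1", "pfs_time", "pfs_event",
                "os_time", "os_event", "bor_pd")) {
    out[[col]] <- fmt_num(cl[[col]])
  }
  utils::write.table(out, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  expr <- dataset$expression
  expr_chr <- matrix(fmt_num(expr), nrow = nrow(expr))
  expr_out <- data.frame(gene_id = rownames(expr), expr_chr,
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(expr_out) <- c("gene_id", colnames(expr))
  utils::write.table(expr_out, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(clinical_path, expression_path))
}

#' Per-patient model prediction
#'
#' @param model_name string label.
#' @param subchallenge one of `"PFS"`, `"OS"`, `"BOR"`.
#' @param scores named numeric vector, names = patient ids.
#' @param direction `"benefit_high"` if larger scores mean better predicted
#'   outcome under immune checkpoint inhibition, `"benefit_low"` otherwise.
#' @return object of class `model_score`.
#' @export
model_score <- function(model_name, subchallenge, scores,
                        direction = c("benefit_high", "benefit_low")) {
  subchallenge <- match.arg(subchallenge, c("PFS", "OS", "BOR"))
  direction <- match.arg(direction)
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    icibench_error("icibench_value_error",
                   "scores must be named by unique patient ids")
  }
  structure(list(model_name = model_name, subchallenge = subchallenge,
                 scores = scores, direction = direction),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat("model_score:", x$model_name, "[", x$subchallenge, ",",
      x$direction, "]", length(x$scores), "patients\n")
  invisible(x)
}

#' Validate a prediction against a dataset (submission checks)
#'
#' Mirrors a challenge-style submission check: predictions must be numeric
#' and finite (type), cover every patient (completeness), and contain no
#' unknown patients (sample matching). Failures are reported, never raised.
#'
#' @param dataset a [trial_dataset].
#' @param score a [model_score].
#' @return data.frame with columns `check`, `patient_id`, `message`;
#'   zero rows if and only if all checks pass.
#' @export
validate_predictions <- function(dataset, score) {
  ids <- dataset$clinical$patient_id
  s <- score$scores
  rows <- list()
  add <- function(check, patient_id, message) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, patient_id = patient_id, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.numeric(s)) {
    add("type", NA_character_, "scores are not numeric")
  } else {
    bad <- names(s)[!is.finite(s)]
    for (p in bad) add("type", p, "non-finite score")
  }
  for (p in setdiff(ids, names(s))) {
    add("completeness", p, "patient has no prediction")
  }
  for (p in setdiff(names(s), ids)) {
    add("sample_matching", p, "prediction for unknown patient")
  }
  if (length(rows) == 0) {
    return(data.frame(check = character(), patient_id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Gene set
#'
#' @param name signature name.
#' @param genes character vector of gene identifiers; duplicates are
#'   dropped with a warning.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) {
    icibench_error("icibench_value_error",
                   paste0("gene set '", name, "' is empty"))
  }
  if (anyDuplicated(genes)) {
    warning("dropping duplicated genes in set '", name, "'")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description
#' (ignored), then gene identifiers. Parsing is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return named list of [gene_set] objects (empty list for an empty file).
#' @export
read_gene_sets <- function(path) {
  if (file.info(path)$size == 0) return(list())
  raw <- fgsea::gmtPathways(path)
  sets <- lapply(names(raw), function(nm) gene_set(nm, raw[[nm]]))
  names(sets) <- names(raw)
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write predictions TSV (patient_id, score)
#' @param score a [model_score].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_predictions <- function(score, path) {
  utils::write.table(
    data.frame(patient_id = names(score$scores),
               score = fmt_num(score$scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read predictions TSV written by [write_predictions()]
#' @param path predictions file.
#' @param model_name,subchallenge,direction metadata for the returned
#'   [model_score] (not stored in the file).
#' @return a [model_score].
#' @export
read_predictions <- function(path, model_name = basename(path),
                             subchallenge = "PFS",
                             direction = "benefit_high") {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  scores <- as.numeric(tab$score)
  names(scores) <- tab$patient_id
  model_score(model_name, subchallenge, scores, direction)
}
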