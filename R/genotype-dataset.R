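#' Genotype dataset container
#'
#' Holds a patients-by-variables table of small categorical integer codes
#' (SNP genotypes, typically 0/1/2 alternate-allele counts) plus, optionally,
#' one non-negative outcome column such as a disease-complexity score.
#' Missing entries are kept as `NA` in `values` and flagged in
#' `missing_mask` until [complete_case_filter()] removes the affected rows.
#'
#' @param values numeric matrix (subjects x variables) with `NA` for missing
#'   entries; genotype columns must hold non-negative integers.
#' @param subject_ids optional identifiers (default `s1..sn`).
#' @param outcome_name name of the outcome column, or `NULL`.
#' @param cardinalities optional named integer vector of per-variable
#'   category counts; inferred as `max + 1` when omitted (`NA` for a
#'   non-integer outcome column).
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(values, subject_ids = NULL, outcome_name = NULL,
                             cardinalities = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  vars <- colnames(values)
  if (is.null(vars)) stop("values must have column names")
  if (anyDuplicated(vars))
    stop("duplicate variable name(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  if (is.null(subject_ids)) subject_ids <- sprintf("s%d", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length must match the number of rows")
  if (!is.null(outcome_name) && !outcome_name %in% vars)
    stop("outcome column '", outcome_name, "' not present")
  geno_cols <- setdiff(vars, outcome_name)
  gv <- values[, geno_cols, drop = FALSE]
  ok <- is.na(gv) | (gv >= 0 & gv == floor(gv))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer or negative genotype value at row %d, column '%s'",
                 bad[1], geno_cols[bad[2]]))
  }
  if (!is.null(outcome_name)) {
    ov <- values[, outcome_name]
    if (any(ov < 0, na.rm = TRUE)) stop("outcome values must be non-negative")
  }
  if (is.null(cardinalities)) {
    cardinalities <- vapply(vars, function(v) {
      x <- values[, v]
      if (all(is.na(x))) return(1L)
      if (any(x != floor(x), na.rm = TRUE)) return(NA_integer_)
      as.integer(max(x, na.rm = TRUE) + 1)
    }, integer(1))
  } else {
    if (is.null(names(cardinalities)) || !all(vars %in% names(cardinalities)))
      stop("cardinalities must be named for every variable")
    cardinalities <- as.integer(cardinalities[vars])
    names(cardinalities) <- vars
    over <- vapply(geno_cols, function(v)
      any(values[, v] >= cardinalities[[v]], na.rm = TRUE), logical(1))
    if (any(over))
      stop("values exceed the stated cardinality for: ",
           paste(geno_cols[over], collapse = ", "))
  }
  structure(list(values = values,
                 subject_ids = as.character(subject_ids),
                 variables = vars,
                 cardinalities = cardinalities,
                 outcome_name = outcome_name,
                 missing_mask = is.na(values)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d subjects x %d variables%s\n",
              nrow(x$values), length(x$variables),
              if (is.null(x$outcome_name)) ""
              else paste0(" (outcome: ", x$outcome_name, ")")))
  nm <- sum(x$missing_mask)
  if (nm) cat(sprintf("  %d missing entr%s in %d row(s)\n", nm,
                      if (nm == 1) "y" else "ies",
                      sum(rowSums(x$missing_mask) > 0)))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param ds a `genotype_dataset`.
#' @export
n_subjects <- function(ds) nrow(ds$values)

#' Row subset of a dataset
#'
#' @param x a `genotype_dataset`.
#' @param i row index vector.
#' @param ... ignored.
#' @return a `genotype_dataset` with the selected subjects.
#' @export
`[.genotype_dataset` <- function(x, i, ...) {
  genotype_dataset(x$values[i, , drop = FALSE],
                   subject_ids = x$subject_ids[i],
                   outcome_name = x$outcome_name,
                   cardinalities = x$cardinalities)
}

#' Read a genotype/outcome table from CSV or TSV
#'
#' The file must carry a header row of unique variable names. Genotype
#' entries must be non-negative integer tokens; a configurable set of tokens
#' is treated as missing. Per-variable category counts are inferred from the
#' observed codes (`max + 1`).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param outcome_column name of the outcome column, or `NULL` if none.
#' @param missing_tokens character vector of tokens read as missing.
#' @return a `genotype_dataset`.
#' @export
read_genotype_table <- function(path, dialect = c("csv", "tsv"),
                                outcome_column = NULL,
                                missing_tokens = c("", "NA", "NaN", ".")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE,
                           sep = if (dialect == "csv") "," else "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  vars <- names(raw)
  if (anyDuplicated(vars))
    stop("duplicate column name(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  if (!is.null(outcome_column) && !outcome_column %in% vars)
    stop("outcome column '", outcome_column, "' not found")
  vals <- matrix(NA_real_, nrow(raw), length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    x <- trimws(raw[[v]])
    miss <- x %in% missing_tokens
    tok <- x[!miss]
    pat <- if (!is.null(outcome_column) && v == outcome_column)
      "^[0-9]+(\\.[0-9]+)?$" else "^[0-9]+$"
    bad <- !grepl(pat, tok)
    if (any(bad)) {
      row <- which(!miss)[which(bad)[1]]
      stop(sprintf("cannot parse value '%s' at row %d, column '%s'",
                   tok[bad][1], row, v))
    }
    vals[!miss, v] <- as.numeric(tok)
  }
  genotype_dataset(vals, outcome_name = outcome_column)
}

#' Write a genotype dataset to CSV or TSV
#'
#' Missing entries are written as `NA`. `read_genotype_table()` on the
#' written file recovers the dataset.
#'
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  utils::write.table(as.data.frame(ds$values), path,
                     sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Import genotypes from a VCF file
#'
#' Biallelic GT-bearing records become variables coded as alternate-allele
#' counts (0/1/2); missing genotypes (`./.`) are masked. Multiallelic sites
#' are skipped with a warning. Requires the vcfR package.
#'
#' @param path VCF file path.
#' @param sample_subset optional character vector of sample names to keep.
#' @return a `genotype_dataset`.
#' @export
import_vcf_genotypes <- function(path, sample_subset = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF import")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))))
    stop("VCF records lack a GT field")
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ids <- vcf@fix[!multi, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(vcf@fix[!multi, "CHROM"][noid], "_",
                      vcf@fix[!multi, "POS"][noid])
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(gt))
    if (length(missing_s))
      stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  code <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  vals <- t(apply(gt, c(1, 2), code))
  colnames(vals) <- ids
  rownames(vals) <- NULL
  genotype_dataset(vals, subject_ids = colnames(gt))
}

#' Remove subjects with any missing value
#'
#' @param ds a `genotype_dataset`.
#' @param quiet suppress the removed/retained message.
#' @return a `genotype_dataset` containing only complete cases.
#' @export
complete_case_filter <- function(ds, quiet = FALSE) {
  incomplete <- rowSums(ds$missing_mask) > 0
  if (all(incomplete))
    stop("all rows contain missing values; nothing learnable remains")
  if (!quiet)
    message(sprintf("complete-case filter: removed %d of %d subjects, retained %d",
                    sum(incomplete), length(incomplete), sum(!incomplete)))
  ds[!incomplete]
}

#' Split a dataset on zero versus positive outcome
#'
#' @param ds a complete-case `genotype_dataset` with an outcome column.
#' @param drop_outcome drop the outcome column from both parts (the default,
#'   appropriate when learning the genotype-only structure); set `FALSE` to
#'   retain it, e.g. for local-structure analysis around the outcome.
#' @return list with elements `zero_part` and `positive_part`.
#' @export
split_by_outcome <- function(ds, drop_outcome = TRUE) {
  if (is.null(ds$outcome_name)) stop("dataset has no outcome column")
  ov <- ds$values[, ds$outcome_name]
  if (anyNA(ov)) stop("outcome column contains missing values; filter first")
  if (any(ov < 0)) stop("outcome values must be non-negative")
  part <- function(keep) {
    d <- ds[keep]
    if (drop_outcome && length(d$variables) > 1L) {
      vals <- d$values[, setdiff(d$variables, d$outcome_name), drop = FALSE]
      genotype_dataset(vals, subject_ids = d$subject_ids,
                       cardinalities = d$cardinalities[colnames(vals)])
    } else d
  }
  list(zero_part = part(ov == 0), positive_part = part(ov > 0))
}

#' Discretize the outcome column
#'
#' The resampling pipeline's local-structure analysis treats the outcome as
#' a categorical variable. `"quantile"` bins the observed scores into
#' (approximately) equal-frequency categories, `"binary"` codes zero versus
#' positive, `"raw"` keeps already-integer scores as categories.
#'
#' @param ds a `genotype_dataset` with an outcome column.
#' @param bins number of quantile bins (method `"quantile"`).
#' @param method `"quantile"`, `"binary"` or `"raw"`.
#' @return a `genotype_dataset` whose outcome column holds codes
#'   `0..levels-1`.
#' @export
discretize_outcome <- function(ds, bins = 3L,
                               method = c("quantile", "binary", "raw")) {
  method <- match.arg(method)
  if (is.null(ds$outcome_name)) stop("dataset has no outcome column")
  x <- ds$values[, ds$outcome_name]
  code <- switch(method,
    quantile = {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   na.rm = TRUE, names = FALSE))
      if (length(br) < 2L) rep(0, length(x))
      else as.integer(cut(x, breaks = br, include.lowest = TRUE)) - 1L
    },
    binary = as.integer(x > 0),
    raw = {
      if (any(x != floor(x), na.rm = TRUE))
        stop("outcome is not integer-coded; use method 'quantile' or 'binary'")
      as.integer(x) - as.integer(min(x, na.rm = TRUE))
    })
  vals <- ds$values
  vals[, ds$outcome_name] <- code
  genotype_dataset(vals, subject_ids = ds$subject_ids,
                   outcome_name = ds$outcome_name)
}
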