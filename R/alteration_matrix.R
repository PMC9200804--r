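#' Patient-by-alteration binary matrix
#'
#' Constructs and validates the central data object of the package: a
#' patients x features matrix of presence/absence (0/1) calls for driver
#' SNVs, copy-number alterations (CNAs), IgH/MYC translocations and
#' summative ploidy flags. This is the `X` that the binary matrix
#' factorization approximates.
#'
#' Patients are rows and features are columns throughout the package and in
#' all files it writes. Every cell must be exactly 0 or 1: missing genetic
#' calls are resolved to 0 upstream (see [binarize_calls()]) because the
#' matrix models presence/absence, not assay dropout. Patients with no
#' alterations at all are legitimate (and retained), so all-zero rows are
#' allowed; they are listed in the `all_zero_patients` attribute.
#'
#' @param values numeric/integer matrix with entries in {0, 1}; rownames are
#'   used as patient ids and colnames as feature ids when the id arguments
#'   are omitted.
#' @param patient_ids,feature_ids character vectors of unique identifiers.
#' @param feature_class optional named character vector mapping feature id to
#'   one of `"SNV"`, `"CNA"`, `"TRANSLOCATION"`, `"PLOIDY"`. Unnamed features
#'   get a class from [infer_feature_class()].
#' @return An object of class `alteration_matrix`: a list with elements
#'   `values` (integer matrix with dimnames), `patient_ids`, `feature_ids`,
#'   `feature_class`.
#' @seealso [read_alteration_matrix()], [binarize_calls()], [bmf_subtype()]
#' @export
alteration_matrix <- function(values, patient_ids = rownames(values),
                              feature_ids = colnames(values),
                              feature_class = NULL) {
  values <- as.matrix(values)
  if (is.null(patient_ids) || is.null(feature_ids)) {
    stop("patient and feature ids are required (as arguments or dimnames)")
  }
  patient_ids <- as.character(patient_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(patient_ids) || ncol(values) != length(feature_ids)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("an alteration matrix needs at least 2 patients and 2 features")
  }
  dup_p <- unique(patient_ids[duplicated(patient_ids)])
  if (length(dup_p)) {
    stop("duplicate patient id(s): ", paste(dup_p, collapse = ", "))
  }
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f)) {
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  }
  bad <- which(is.na(values) | !(values == 0 | values == 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-binary cell at patient '%s', feature '%s' (value: %s)%s",
      patient_ids[i], feature_ids[j], as.character(values[i, j]),
      if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""
    ))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(patient_ids, feature_ids)
  cls <- infer_feature_class(feature_ids)
  if (!is.null(feature_class)) {
    if (is.null(names(feature_class))) {
      stop("feature_class must be named by feature id")
    }
    unknown <- setdiff(names(feature_class), feature_ids)
    if (length(unknown)) {
      stop("feature_class names not in matrix: ", paste(unknown, collapse = ", "))
    }
    bad_cls <- setdiff(feature_class, c("SNV", "CNA", "TRANSLOCATION", "PLOIDY"))
    if (length(bad_cls)) {
      stop("unknown feature class(es): ", paste(bad_cls, collapse = ", "))
    }
    cls[names(feature_class)] <- feature_class
  }
  out <- structure(
    list(values = values, patient_ids = patient_ids,
         feature_ids = feature_ids, feature_class = cls),
    class = "alteration_matrix"
  )
  attr(out, "all_zero_patients") <- patient_ids[rowSums(values) == 0L]
  out
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("alteration_matrix: %d patients x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$feature_class)
  cat("  feature classes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat(sprintf("  overall alteration rate: %.3f\n", mean(x$values)))
  nz <- attr(x, "all_zero_patients")
  if (length(nz)) cat(sprintf("  all-zero patients: %d\n", length(nz)))
  invisible(x)
}

#' @export
dim.alteration_matrix <- function(x) dim(x$values)

#' @export
as.matrix.alteration_matrix <- function(x, ...) x$values

#' Guess the class of an alteration feature from its identifier
#'
#' Ids starting with `t(` are translocations; ids carrying del/gain/amp/loss
#' or +/- arm prefixes are CNAs; hyper/hypodiploidy flags are PLOIDY; plain
#' gene symbols default to SNV. The mapping can always be overridden via the
#' `feature_class` argument of [alteration_matrix()].
#'
#' @param feature_ids character vector of feature identifiers.
#' @return named character vector of classes.
#' @export
infer_feature_class <- function(feature_ids) {
  cls <- rep("SNV", length(feature_ids))
  cls[grepl("^t\\(", feature_ids)] <- "TRANSLOCATION"
  cls[grepl("^(del|gain|amp|loss|\\+|-)", feature_ids, ignore.case = TRUE)] <- "CNA"
  cls[grepl("diploid", feature_ids, ignore.case = TRUE)] <- "PLOIDY"
  names(cls) <- feature_ids
  cls
}

#' Read a patient-by-alteration matrix from TSV/CSV
#'
#' Expects a header row of feature ids and a first column of patient ids;
#' cells must be 0 or 1. The separator is taken from the file extension
#' (`.csv` comma, otherwise tab) unless given.
#'
#' @param path path to the file.
#' @param sep field separator; default by extension.
#' @param feature_class_path optional two-column side-car file
#'   (feature_id, class) overriding the inferred feature classes.
#' @return an [alteration_matrix()].
#' @export
read_alteration_matrix <- function(path, sep = NULL, feature_class_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >= 1 feature column")
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  fc <- NULL
  if (!is.null(feature_class_path)) {
    sc <- utils::read.table(feature_class_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    fc <- stats::setNames(as.character(sc[[2L]]), as.character(sc[[1L]]))
  }
  alteration_matrix(num, patient_ids = ids, feature_ids = colnames(vals),
                    feature_class = fc)
}

#' Write a patient-by-alteration matrix
#'
#' Emits patients as rows, feature ids as the header, patient ids in the
#' first column (`patient_id`). [read_alteration_matrix()] of the result is
#' the identity.
#'
#' @param x an [alteration_matrix()].
#' @param path output path; `.csv` extension switches to comma separation.
#' @return `path`, invisibly.
#' @export
write_alteration_matrix <- function(x, path) {
  stopifnot(inherits(x, "alteration_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(patient_id = x$patient_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize per-patient call lists into an alteration matrix
#'
#' Entry (p, f) is 1 iff patient p carries at least one call for feature f;
#' repeated calls are idempotent and call order is irrelevant. Patients with
#' no calls keep an all-zero row (dropping them would silently change the
#' cohort size).
#'
#' @param snv_calls,cna_calls,tra_calls named lists, one character vector of
#'   feature ids per patient. Any may be `NULL`.
#' @param feature_catalog ordered character vector of feature ids defining
#'   the columns.
#' @param patient_ids optional explicit patient order; default is first
#'   appearance across the three call lists.
#' @param strict if `TRUE` (default) a call to a feature outside the catalog
#'   is an error; if `FALSE` it is skipped with a warning naming the feature.
#' @return an [alteration_matrix()]; feature classes are set from which call
#'   list contributed each feature, falling back to [infer_feature_class()].
#' @export
binarize_calls <- function(snv_calls = NULL, cna_calls = NULL, tra_calls = NULL,
                           feature_catalog, patient_ids = NULL, strict = TRUE) {
  if (missing(feature_catalog) || length(feature_catalog) == 0L) {
    stop("feature_catalog must be a non-empty vector of feature ids")
  }
  feature_catalog <- as.character(feature_catalog)
  lists <- list(SNV = snv_calls, CNA = cna_calls, TRANSLOCATION = tra_calls)
  if (is.null(patient_ids)) {
    patient_ids <- unique(unlist(lapply(lists, names), use.names = FALSE))
  }
  if (length(patient_ids) == 0L) stop("no patients in any call list")
  vals <- matrix(0L, length(patient_ids), length(feature_catalog),
                 dimnames = list(patient_ids, feature_catalog))
  cls <- infer_feature_class(feature_catalog)
  for (k in names(lists)) {
    calls <- lists[[k]]
    if (is.null(calls)) next
    for (p in names(calls)) {
      if (!p %in% patient_ids) next
      feats <- unique(as.character(calls[[p]]))
      unknown <- setdiff(feats, feature_catalog)
      if (length(unknown)) {
        msg <- sprintf("patient '%s': call(s) to uncataloged feature(s) %s",
                       p, paste(unknown, collapse = ", "))
        if (strict) stop(msg) else warning(msg, " -- skipped", call. = FALSE)
        feats <- setdiff(feats, unknown)
      }
      vals[p, feats] <- 1L
      cls[intersect(feats, feature_catalog)] <- k
    }
  }
  alteration_matrix(vals, feature_class = cls)
}

#' Hyperdiploidy / hypodiploidy flags from a chromosome count
#'
#' A tumor is hyperdiploid when it has more than 48 chromosomes and
#' hypodiploid when it has fewer than 45; karyotypes of 45-48 chromosomes
#' are neither. The two flags are mutually exclusive by construction.
#'
#' @param chromosome_count vector of positive integer chromosome counts.
#' @return data.frame with logical columns `hyperdiploid`, `hypodiploid`.
#' @export
derive_ploidy_flags <- function(chromosome_count) {
  cc <- chromosome_count
  if (any(is.na(cc)) || any(cc <= 0) || any(cc != round(cc))) {
    stop("chromosome counts must be positive integers")
  }
  data.frame(hyperdiploid = cc > 48, hypodiploid = cc < 45)
}

#' Read per-patient gene calls from a MAF-dialect file
#'
#' Minimal MAF reader: only the `Hugo_Symbol` and `Tumor_Sample_Barcode`
#' columns are used; each sample's mutated genes become its SNV call list.
#'
#' @param path tab-separated MAF file.
#' @return named list: sample barcode -> character vector of gene symbols.
#' @export
read_maf_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  if (!all(need %in% names(df))) {
    stop("MAF file must contain columns: ", paste(need, collapse = ", "))
  }
  split(df$Hugo_Symbol, df$Tumor_Sample_Barcode)
}

#' Read GISTIC-thresholded copy-number calls
#'
#' Expects a sample x arm table with values in {-2,-1,0,1,2}; a call is made
#' where |value| >= 1 in the configured direction. Losses are prefixed
#' `del`, gains `gain`, so calls line up with the CNA naming used by
#' [infer_feature_class()].
#'
#' @param path TSV with first column = sample id, remaining columns = arms.
#' @param direction one of `"both"`, `"gain"`, `"loss"`.
#' @return named list: sample -> character vector of CNA feature ids.
#' @export
read_gistic_calls <- function(path, direction = c("both", "gain", "loss")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(vals %in% -2:2)) stop("GISTIC calls must be integers in -2..2")
  arms <- colnames(vals)
  out <- lapply(seq_along(ids), function(i) {
    v <- vals[i, ]
    gains <- arms[v >= 1]; losses <- arms[v <= -1]
    calls <- character(0)
    if (direction %in% c("both", "gain") && length(gains)) {
      calls <- c(calls, paste0("gain", gains))
    }
    if (direction %in% c("both", "loss") && length(losses)) {
      calls <- c(calls, paste0("del", losses))
    }
    calls
  })
  stats::setNames(out, ids)
}

#' Read a clinical baseline table
#'
#' Columns: `patient_id`, `m_protein_baseline` (g/dL), `flc_ratio`
#' (involved/uninvolved), `bmpc_percent` (0-100), `hemoglobin_baseline`
#' (g/dL), `ttp_months`, `progressed` (0/1 or TRUE/FALSE), plus any extras
#' (e.g. `subtype`). Staging fields may be missing (NA); `ttp_months` must
#' be positive for every patient entering survival analysis.
#'
#' @param path CSV file.
#' @return data.frame with `progressed` coerced to logical.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("clinical table needs a patient_id column")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids in clinical table")
  if ("progressed" %in% names(df)) df$progressed <- as.logical(df$progressed)
  if ("ttp_months" %in% names(df) && any(!is.na(df$ttp_months) & df$ttp_months <= 0)) {
    stop("ttp_months must be positive")
  }
  df
}

#' Read longitudinal biomarker series
#'
#' Long format, one measurement per row: `patient_id`, `marker` (`"mp"`
#' M-protein g/dL or `"hb"` hemoglobin g/dL), `month` (offset from
#' diagnosis, >= 0), `value`. Month offsets must be strictly increasing
#' within each (patient, marker) series.
#'
#' @param path CSV file.
#' @return data.frame sorted by patient, marker, month.
#' @export
read_biomarker_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "marker", "month", "value")
  if (!all(need %in% names(df))) {
    stop("series table must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(df$month < 0)) stop("month offsets must be >= 0")
  df <- df[order(df$patient_id, df$marker, df$month), , drop = FALSE]
  key <- paste(df$patient_id, df$marker)
  dup <- duplicated(cbind(key, df$month))
  if (any(dup)) stop("duplicate month offset within a series")
  rownames(df) <- NULL
  df
}
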