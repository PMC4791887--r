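#' mirfluid: exploratory miRNA RT-qPCR biomarker analysis in CSF and blood
#'
#' Tools for analysing RT-qPCR panel screens of microRNAs measured in paired
#' cerebrospinal fluid (CSF) and blood samples from a small two-group dementia
#' cohort: detection filtering against negative controls, spike-in QC,
#' global-mean delta-Ct normalization with NormFinder-style stability ranking,
#' Mann-Whitney differential tables, Fisher presence/absence screens,
#' leave-one-out logistic classification, a two-miRNA ratio biomarker, cohort
#' demographics, blood-brain-barrier flagging, and a synthetic cohort
#' generator for end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

# ---- domain containers -------------------------------------------------------

#' Construct a Ct matrix
#'
#' A `ct_matrix` holds raw quantification-cycle (Ct) values for one biofluid:
#' one row per miRNA assay, one column per sample. Missing entries represent
#' no amplification. An optional per-assay negative-control Ct and optional
#' per-cell QC pass/fail flags (melting curve / amplification efficiency,
#' supplied externally) travel with the matrix.
#'
#' @param ct numeric matrix, assays x samples; `NA` = no amplification.
#' @param assay_ids character vector of unique miRNA assay names (rownames).
#' @param sample_ids character vector of unique sample names (colnames).
#' @param fluid `"CSF"` or `"BLOOD"`.
#' @param negctrl_ct optional per-assay negative-control Ct (cycles); `NA`
#'   means the control did not amplify.
#' @param qc_flags optional logical matrix, same shape as `ct`; `FALSE` marks
#'   a measurement that failed upstream QC.
#' @return an object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, assay_ids = rownames(ct), sample_ids = colnames(ct),
                      fluid = c("CSF", "BLOOD"), negctrl_ct = NULL,
                      qc_flags = NULL) {
  fluid <- match.arg(toupper(fluid), c("CSF", "BLOOD"))
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(assay_ids) || is.null(sample_ids)) {
    stop("assay_ids and sample_ids are required")
  }
  assay_ids <- as.character(assay_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(ct) != length(assay_ids) || ncol(ct) != length(sample_ids)) {
    stop("ct dimensions must be |assay_ids| x |sample_ids|")
  }
  if (anyDuplicated(assay_ids)) {
    stop("duplicate assay ids: ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  present <- !is.na(ct)
  if (any(!is.finite(ct[present])) || any(ct[present] <= 0)) {
    stop("all present Ct values must be finite and > 0 (cycles start at 1)")
  }
  dimnames(ct) <- list(assay_ids, sample_ids)
  if (!is.null(negctrl_ct)) {
    if (length(negctrl_ct) != length(assay_ids)) {
      stop("negctrl_ct must have one value per assay")
    }
    negctrl_ct <- as.numeric(negctrl_ct)
    ok <- is.na(negctrl_ct) | (is.finite(negctrl_ct) & negctrl_ct > 0)
    if (!all(ok)) stop("negative-control Ct values must be > 0 or missing")
    names(negctrl_ct) <- assay_ids
  }
  if (!is.null(qc_flags)) {
    qc_flags <- as.matrix(qc_flags)
    if (!identical(dim(qc_flags), dim(ct)) || !is.logical(qc_flags)) {
      stop("qc_flags must be a logical matrix with the same shape as ct")
    }
    qc_flags[is.na(qc_flags)] <- TRUE
    dimnames(qc_flags) <- dimnames(ct)
  }
  structure(list(assay_ids = assay_ids, sample_ids = sample_ids, ct = ct,
                 fluid = fluid, negctrl_ct = negctrl_ct, qc_flags = qc_flags),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples [%s], %d missing, negctrl %s\n",
              length(x$assay_ids), length(x$sample_ids), x$fluid,
              sum(is.na(x$ct)),
              if (is.null(x$negctrl_ct)) "absent" else "present"))
  invisible(x)
}

# group labels accepted on disk, mapped to canonical AD / CONTROL
.group_aliases <- list(
  AD = c("ad", "alzheimer", "alzheimers", "alzheimer's disease",
         "alzheimers disease", "alzheimer disease"),
  CONTROL = c("control", "ctrl", "ctl", "other", "other dementia",
              "other_dementia", "non-ad", "nonad")
)

canonical_group <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% .group_aliases$AD] <- "AD"
  out[key %in% .group_aliases$CONTROL] <- "CONTROL"
  if (anyNA(out)) {
    stop("unknown group label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected AD or CONTROL variants)")
  }
  out
}

# Normalise a `groups` argument (metadata data.frame or named character
# vector of AD/CONTROL per sample) into a named character vector covering
# `sample_ids`, both groups nonempty.
as_group_vector <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      stop("metadata must contain sample_id and group columns")
    }
    g <- stats::setNames(as.character(groups$group), groups$sample_id)
  } else {
    g <- stats::setNames(as.character(groups), names(groups))
  }
  missing <- setdiff(sample_ids, names(g))
  if (length(missing)) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  g <- canonical_group(g[sample_ids])
  names(g) <- sample_ids
  if (!all(c("AD", "CONTROL") %in% g)) {
    stop("both AD and CONTROL groups must be nonempty")
  }
  g
}

# ---- readers / writers -------------------------------------------------------

# tokens treated as "no amplification" on disk
.na_tokens <- c("", "na", "nan", "undetermined", "no amplification", "n/a")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"),
                   function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0L)) stop("could not detect delimiter in ", path)
  c(",", "\t", ";")[which.max(counts)]
}

parse_ct_cell <- function(x, assay, sample) {
  x <- trimws(x)
  if (tolower(x) %in% .na_tokens) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop(sprintf("non-numeric Ct value '%s' at assay '%s', column '%s'",
                 x, assay, sample))
  }
  v
}

#' Read a Ct panel from delimited text
#'
#' The on-disk layout is one row per miRNA assay: the first column holds the
#' assay id, an optional reserved column (default name `negctrl`) holds the
#' per-assay negative-control Ct, and every other column is a sample. Empty
#' cells (or `NA`/`Undetermined`) encode no amplification. The delimiter is
#' auto-detected among comma, tab and semicolon; decimal points only.
#'
#' @param path file path.
#' @param fluid `"CSF"` or `"BLOOD"` label to attach.
#' @param negctrl_col name of the reserved negative-control column.
#' @return a [ct_matrix()].
#' @export
read_ct_table <- function(path, fluid, negctrl_col = "negctrl") {
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("Ct table needs an assay column plus >= 1 sample column")
  assay_ids <- trimws(raw[[1L]])
  if (anyDuplicated(assay_ids)) {
    stop("duplicate assay ids in ", path, ": ",
         paste(unique(assay_ids[duplicated(assay_ids)]), collapse = ", "))
  }
  cols <- names(raw)[-1L]
  if (anyDuplicated(cols)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  negctrl <- NULL
  sample_cols <- cols
  if (negctrl_col %in% cols) {
    negctrl <- vapply(seq_along(assay_ids), function(i) {
      parse_ct_cell(raw[[negctrl_col]][i], assay_ids[i], negctrl_col)
    }, numeric(1))
    sample_cols <- setdiff(cols, negctrl_col)
  }
  if (!length(sample_cols)) stop("no sample columns found in ", path)
  ct <- matrix(NA_real_, length(assay_ids), length(sample_cols),
               dimnames = list(assay_ids, sample_cols))
  for (j in sample_cols) {
    ct[, j] <- vapply(seq_along(assay_ids), function(i) {
      parse_ct_cell(raw[[j]][i], assay_ids[i], j)
    }, numeric(1))
  }
  ct_matrix(ct, assay_ids, sample_cols, fluid, negctrl_ct = negctrl)
}

#' Write a Ct panel to CSV
#'
#' Inverse of [read_ct_table()]; missing values become empty cells.
#'
#' @param x a [ct_matrix()].
#' @param path output file path.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  df <- data.frame(miRNA = x$assay_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in x$sample_ids) df[[j]] <- fmt(x$ct[, j])
  if (!is.null(x$negctrl_ct)) df[["negctrl"]] <- fmt(x$negctrl_ct)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata
#'
#' Requires `sample_id` and `group` columns; group labels are canonicalized
#' case-insensitively to `AD` / `CONTROL` (e.g. `"ad "`, `"Ctrl"` are
#' accepted). Optional columns (`age`, `sex`, `duration`, `mmse`, `ace`,
#' `abeta42`, `total_tau`, `p_tau`, `qalb`) are typed when present; empty
#' cells become `NA`.
#'
#' @param path delimited text file.
#' @return a data.frame of class `cohort_metadata`.
#' @export
read_metadata <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "n/a"))
  required <- c("sample_id", "group")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  df$sample_id <- trimws(as.character(df$sample_id))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  df$group <- canonical_group(df$group)
  if (!all(c("AD", "CONTROL") %in% df$group)) {
    stop("both AD and CONTROL groups must be nonempty")
  }
  numeric_cols <- intersect(
    c("age", "duration", "mmse", "ace", "abeta42", "total_tau", "p_tau", "qalb"),
    names(df))
  for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Write a marker table (differential or categorical) to CSV
#'
#' Column order mirrors the published table shapes. Differential tables
#' (fold-change screen) are written with header
#' `miRNA,N_AD,N_control,M_AD,range_AD,M_control,range_control,FC,p,p_adj`,
#' where each range is serialized as `min..max`. Categorical tables keep
#' `miRNA,N_AD,N_control,OR,sensitivity,specificity,p,significant`. Values
#' are written with 15 significant digits so a round trip is faithful.
#'
#' @param table a data.frame from [differential_table()] or
#'   [categorical_screen()].
#' @param path output file path.
#' @export
write_marker_table <- function(table, path) {
  fmt <- function(v) {
    if (!length(v)) return(character(0))
    ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE))
  }
  pair <- function(lo, hi) if (!length(lo)) character(0) else
    paste0(fmt(lo), "..", fmt(hi))
  if (all(c("M_AD", "FC") %in% names(table))) {
    out <- data.frame(
      miRNA = table$miRNA, N_AD = table$N_AD, N_control = table$N_control,
      M_AD = fmt(table$M_AD),
      range_AD = pair(table$range_AD_min, table$range_AD_max),
      M_control = fmt(table$M_control),
      range_control = pair(table$range_control_min, table$range_control_max),
      FC = fmt(table$FC), p = fmt(table$p), p_adj = fmt(table$p_adj),
      stringsAsFactors = FALSE)
  } else if ("OR" %in% names(table)) {
    out <- data.frame(
      miRNA = table$miRNA, N_AD = table$N_AD, N_control = table$N_control,
      OR = fmt(table$OR), sensitivity = fmt(table$sensitivity),
      specificity = fmt(table$specificity), p = fmt(table$p),
      significant = table$significant, stringsAsFactors = FALSE)
  } else {
    out <- table
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a differential marker table written by [write_marker_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric range columns restored.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  split_range <- function(v) {
    parts <- strsplit(as.character(v), "..", fixed = TRUE)
    list(min = as.numeric(vapply(parts, `[`, "", 1L)),
         max = as.numeric(vapply(parts, `[`, "", 2L)))
  }
  if ("range_AD" %in% names(df)) {
    r1 <- split_range(df$range_AD); r2 <- split_range(df$range_control)
    df$range_AD_min <- r1$min; df$range_AD_max <- r1$max
    df$range_control_min <- r2$min; df$range_control_max <- r2$max
    df$range_AD <- NULL; df$range_control <- NULL
    df <- df[, c("miRNA", "N_AD", "N_control", "M_AD", "range_AD_min",
                 "range_AD_max", "M_control", "range_control_min",
                 "range_control_max", "FC", "p", "p_adj")]
  }
  df
}
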