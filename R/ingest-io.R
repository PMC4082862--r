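#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads a tab-delimited PSM export with one row per peptide-spectrum match.
#' Required columns: \code{sample_id}, \code{accession}, \code{peptide},
#' \code{charge}, \code{xcorr}, \code{b_ions}, \code{y_ions}; an optional
#' \code{modifications} column is carried through untouched. The fragment-ion
#' columns hold the ordinal indices of matched b-/y-ions as comma-separated
#' integers (empty for none). Column order is irrelevant; extra columns are
#' ignored.
#'
#' Rows violating the record invariants (peptide made of the 20 standard
#' amino-acid letters, length >= 1; charge integer >= 1; xcorr >= 0; every
#' fragment index in \code{[1, nchar(peptide) - 1]}) are rejected, never
#' silently dropped: each rejection is reported with its line number in the
#' \code{"rejections"} attribute and summarised in a warning. Accepted rows
#' keep their file order.
#'
#' @param path path to the TSV file.
#' @return A \code{psm_table} (data frame) with list-columns \code{b_ions}
#'   and \code{y_ions}; attribute \code{"rejections"} is a data frame with
#'   columns \code{line} (1-based file line) and \code{reason}.
#' @export
read_psm_table <- function(path) {
  raw <- read_tsv_checked(path)
  required <- c("sample_id", "accession", "peptide", "charge", "xcorr",
                "b_ions", "y_ions")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  rej_line <- integer(0)
  rej_reason <- character(0)
  keep <- logical(n)
  b_list <- vector("list", n)
  y_list <- vector("list", n)

  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    reason <- validate_psm_row(raw[i, ])
    if (is.null(reason$msg)) {
      keep[i] <- TRUE
      b_list[[i]] <- reason$b
      y_list[[i]] <- reason$y
    } else {
      rej_line <- c(rej_line, line)
      rej_reason <- c(rej_reason, reason$msg)
    }
  }

  out <- data.frame(
    sample_id = as.character(raw$sample_id)[keep],
    accession = as.character(raw$accession)[keep],
    peptide   = as.character(raw$peptide)[keep],
    charge    = as.integer(raw$charge)[keep],
    xcorr     = as.numeric(raw$xcorr)[keep],
    stringsAsFactors = FALSE
  )
  out$b_ions <- b_list[keep]
  out$y_ions <- y_list[keep]
  if ("modifications" %in% names(raw))
    out$modifications <- as.character(raw$modifications)[keep]

  rejections <- data.frame(line = rej_line, reason = rej_reason,
                           stringsAsFactors = FALSE)
  if (nrow(rejections) > 0)
    warning(nrow(rejections), " PSM row(s) rejected; see attr(x, 'rejections')",
            call. = FALSE)
  attr(out, "rejections") <- rejections
  class(out) <- c("psm_table", "data.frame")
  out
}

# Validates one raw row; returns list(msg = NULL, b =, y =) on success or
# list(msg = "...") on failure.
validate_psm_row <- function(row) {
  pep <- as.character(row$peptide)
  if (is.na(pep) || nchar(pep) < 1)
    return(list(msg = "empty peptide"))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep))
    return(list(msg = "peptide contains non-standard amino-acid letters"))
  charge <- suppressWarnings(as.numeric(row$charge))
  if (is.na(charge) || charge != round(charge) || charge < 1)
    return(list(msg = "charge must be an integer >= 1"))
  xcorr <- suppressWarnings(as.numeric(row$xcorr))
  if (is.na(xcorr) || xcorr < 0)
    return(list(msg = "xcorr must be a nonnegative number"))
  b <- parse_ion_list(as.character(row$b_ions))
  if (is.null(b)) return(list(msg = "unparsable b_ions fragment list"))
  y <- parse_ion_list(as.character(row$y_ions))
  if (is.null(y)) return(list(msg = "unparsable y_ions fragment list"))
  lim <- nchar(pep) - 1L
  if (length(b) > 0 && (min(b) < 1 || max(b) > lim))
    return(list(msg = "b-ion index outside [1, peptide length - 1]"))
  if (length(y) > 0 && (min(y) < 1 || max(y) > lim))
    return(list(msg = "y-ion index outside [1, peptide length - 1]"))
  list(msg = NULL, b = b, y = y)
}

# "1,2,3" -> sorted unique integer vector; "" / NA -> integer(0); NULL if bad
parse_ion_list <- function(s) {
  if (is.na(s) || trimws(s) == "") return(integer(0))
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  if (length(parts) == 0) return(integer(0))
  if (!all(grepl("^[0-9]+$", parts))) return(NULL)
  sort(unique(as.integer(parts)))
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = character(0))
}

#' Read a protein catalog (identification table)
#'
#' Reads the tab-delimited catalog of identified proteins, one row per
#' protein, with columns \code{accession}, \code{n_aa}, \code{mw_da},
#' \code{description} and \code{coverage_pct}. Decimal commas in numeric
#' fields (as printed in European-style tables, e.g. \code{"2,2"}) are
#' normalized to decimal points at parse time. A transcription of the
#' study's 165-protein identification table ships with the package; see the
#' example.
#'
#' @param path path to the TSV file.
#' @return A \code{protein_catalog} data frame in file order.
#' @examples
#' cat165 <- read_protein_catalog(
#'   system.file("extdata", "table1_proteins.tsv", package = "spcregress"))
#' nrow(cat165)  # 165
#' @export
read_protein_catalog <- function(path) {
  raw <- read_tsv_checked(path)
  required <- c("accession", "n_aa", "mw_da", "description", "coverage_pct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("protein catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- raw$accession[duplicated(raw$accession)]
  if (length(dup) > 0)
    stop("duplicate accession(s) in catalog: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  decomma <- function(x) as.numeric(sub(",", ".", x, fixed = TRUE))
  out <- data.frame(
    accession    = as.character(raw$accession),
    n_aa         = as.integer(decomma(raw$n_aa)),
    mw_da        = decomma(raw$mw_da),
    description  = as.character(raw$description),
    coverage_pct = decomma(raw$coverage_pct),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$coverage_pct) | out$coverage_pct < 0 |
                 out$coverage_pct > 100)
  if (length(bad) > 0)
    stop("coverage_pct outside [0, 100] at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  class(out) <- c("protein_catalog", "data.frame")
  out
}

#' Read a spectral-count matrix with sample labels
#'
#' The counts file is a TSV with an \code{accession} column followed by one
#' column per sample (integer spectral counts). The labels file is a TSV
#' with columns \code{sample_id}, \code{group} (\code{regression} or
#' \code{persistence}) and \code{split} (\code{learning} or
#' \code{validation}). Every sample column must be labelled.
#'
#' @param counts_path path to the counts TSV.
#' @param labels_path path to the labels TSV.
#' @param quiet suppress the group-size message.
#' @return An \code{\link{spc_matrix}}.
#' @seealso [write_spc_matrix()] for the inverse; the pair round-trips
#'   exactly.
#' @export
read_spc_matrix <- function(counts_path, labels_path, quiet = FALSE) {
  raw <- read_tsv_checked(counts_path)
  if (!"accession" %in% names(raw))
    stop("counts file is missing required column: accession", call. = FALSE)
  samples <- setdiff(names(raw), "accession")
  if (length(samples) == 0) stop("counts file has no sample columns",
                                 call. = FALSE)
  counts <- matrix(NA_integer_, nrow(raw), length(samples),
                   dimnames = list(raw$accession, samples))
  for (j in seq_along(samples)) {
    col <- raw[[samples[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | num != round(num) | num < 0)
    if (length(bad) > 0)
      stop(sprintf("non-integer count at protein '%s', sample '%s'",
                   raw$accession[bad[1]], samples[j]), call. = FALSE)
    counts[, j] <- as.integer(num)
  }

  lab <- read_tsv_checked(labels_path)
  for (col in c("sample_id", "group", "split"))
    if (!col %in% names(lab))
      stop("labels file is missing required column: ", col, call. = FALSE)
  unlabelled <- setdiff(samples, lab$sample_id)
  if (length(unlabelled) > 0)
    stop("sample(s) in matrix missing from labels: ",
         paste(unlabelled, collapse = ", "), call. = FALSE)
  idx <- match(samples, lab$sample_id)
  group <- stats::setNames(lab$group[idx], samples)
  split <- stats::setNames(lab$split[idx], samples)
  m <- spc_matrix(counts, group = group, split = split)
  if (!quiet) {
    sizes <- table(factor(group, levels = GROUP_LEVELS))
    message("spectral-count matrix: ", nrow(counts), " proteins x ",
            length(samples), " samples (",
            paste(names(sizes), sizes, sep = " = ", collapse = ", "), ")")
  }
  m
}

#' Write a spectral-count matrix and its sample labels
#'
#' @param m an \code{\link{spc_matrix}}.
#' @param counts_path,labels_path output TSV paths.
#' @return Invisibly, \code{m}.
#' @export
write_spc_matrix <- function(m, counts_path, labels_path) {
  stopifnot(inherits(m, "spc_matrix"))
  df <- data.frame(accession = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample_id = colnames(m$counts),
                    group = as.character(m$group),
                    split = if (is.null(m$split)) NA_character_
                            else as.character(m$split),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(m)
}
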