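#' Construct a spectral-count matrix
#'
#' Container for a proteins x samples matrix of nonnegative integer spectral
#' counts together with a two-level group label per sample and an optional
#' learning/validation split label.
#'
#' @param counts integer matrix, proteins in rows, samples in columns;
#'   dimnames required.
#' @param group per-sample labels, \code{"regression"} or
#'   \code{"persistence"}; a named vector (names = sample ids) or in column
#'   order.
#' @param split optional per-sample labels, \code{"learning"} or
#'   \code{"validation"}.
#' @param offset_applied has the +1 offset already been applied?
#' @return An object of class \code{spc_matrix}: a list with elements
#'   \code{counts}, \code{group} (factor), \code{split} (factor or NULL) and
#'   \code{offset_applied}.
#' @export
spc_matrix <- function(counts, group, split = NULL, offset_applied = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have protein rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate protein accessions in counts", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  samples <- colnames(counts)

  group <- align_labels(group, samples, "group")
  group <- check_group(group)
  if (offset_applied && any(counts < 1))
    stop("offset_applied is TRUE but some counts are below 1", call. = FALSE)
  if (!is.null(split)) {
    split <- align_labels(split, samples, "split")
    if (!all(split %in% SPLIT_LEVELS))
      stop("split labels must be one of: ",
           paste(SPLIT_LEVELS, collapse = ", "), call. = FALSE)
    split <- factor(as.character(split), levels = SPLIT_LEVELS)
    names(split) <- samples
  }
  names(group) <- samples
  structure(list(counts = counts, group = group, split = split,
                 offset_applied = offset_applied),
            class = "spc_matrix")
}

align_labels <- function(x, samples, what) {
  x <- stats::setNames(as.character(x), names(x))
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing) > 0)
      stop(what, " labels missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- x[samples]
  } else if (length(x) != length(samples)) {
    stop(what, " labels must be named or match the number of samples",
         call. = FALSE)
  }
  x
}

#' @export
print.spc_matrix <- function(x, ...) {
  cat("spc_matrix: ", nrow(x$counts), " proteins x ", ncol(x$counts),
      " samples", if (x$offset_applied) " (offset +1 applied)" else "",
      "\n", sep = "")
  print(table(group = x$group,
              split = if (is.null(x$split)) "all" else x$split))
  invisible(x)
}

#' Add the +1 offset to a spectral-count matrix
#'
#' Increments every spectral count by one so that zeros (undetected
#' proteins) become 1 before normalization; on the offset scale "count <= 1"
#' is exactly "not detected". Applying the offset twice is an error.
#'
#' @param m an \code{\link{spc_matrix}}.
#' @return The offset \code{spc_matrix} with \code{offset_applied = TRUE}.
#' @export
add_offset <- function(m) {
  stopifnot(inherits(m, "spc_matrix"))
  if (m$offset_applied)
    stop("offset already applied; refusing to apply it twice", call. = FALSE)
  m$counts <- m$counts + 1L
  m$offset_applied <- TRUE
  m
}

#' Normalize an offset spectral-count matrix
#'
#' Scales each sample's offset counts by the ratio of its total spectral
#' count to the average total of its group. Two modes are provided:
#' \describe{
#'   \item{\code{"as_printed"}}{value = SPC x (sample total / group average
#'     of totals). This is the published formula taken literally; note that
#'     it scales deep samples \emph{up}.}
#'   \item{\code{"depth_corrected"}}{value = SPC x (group average / sample
#'     total), the conventional depth correction that equalizes sequencing
#'     depth across samples.}
#' }
#' Sample totals are computed on the offset counts; the per-group average is
#' the mean of the totals of the samples present in \code{m}, so learning
#' and validation sets normalized separately use their own averages.
#'
#' @param m an \code{\link{spc_matrix}} with the offset applied.
#' @param mode \code{"as_printed"} (default) or \code{"depth_corrected"}.
#' @return An object of class \code{spc_norm}: list with \code{values}
#'   (proteins x samples numeric), \code{mode}, \code{sample_sums},
#'   \code{group_avg}, \code{group}, \code{split}.
#' @export
normalize_spc <- function(m, mode = c("as_printed", "depth_corrected")) {
  stopifnot(inherits(m, "spc_matrix"))
  mode <- match.arg(mode)
  if (!m$offset_applied)
    stop("apply add_offset() before normalizing", call. = FALSE)
  sample_sums <- colSums(m$counts)
  present <- unique(as.character(m$group))
  group_avg <- vapply(present, function(g) {
    idx <- which(m$group == g)
    if (length(idx) == 0) stop("group '", g, "' has zero samples",
                               call. = FALSE)
    mean(sample_sums[idx])
  }, numeric(1))
  avg_of <- group_avg[as.character(m$group)]
  factor_per_sample <- if (mode == "as_printed") sample_sums / avg_of
                       else avg_of / sample_sums
  values <- sweep(m$counts, 2, factor_per_sample, `*`)
  structure(list(values = values, mode = mode, sample_sums = sample_sums,
                 group_avg = group_avg, group = m$group, split = m$split),
            class = "spc_norm")
}

#' @export
print.spc_norm <- function(x, ...) {
  cat("spc_norm (", x$mode, "): ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples\n", sep = "")
  cat("group averages of sample totals:\n")
  print(round(x$group_avg, 2))
  invisible(x)
}

# samples x proteins numeric matrix from the containers used across modules
as_sample_matrix <- function(x) {
  if (inherits(x, "spc_norm")) t(x$values)
  else if (inherits(x, "spc_matrix")) t(x$counts)
  else if (is.matrix(x)) x
  else stop("expected an spc_matrix, spc_norm or a samples x proteins matrix",
            call. = FALSE)
}

group_from <- function(x, y = NULL) {
  if (!is.null(y)) return(check_group(y))
  if (inherits(x, c("spc_norm", "spc_matrix"))) return(check_group(x$group))
  stop("group labels must be supplied for a plain matrix", call. = FALSE)
}
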