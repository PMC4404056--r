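#' Build a two-condition count object
#'
#' Bundles a features x libraries matrix of non-negative integer read counts
#' with a two-condition design and per-library sizes. Library size `N_i` is
#' the total read count of library `i`; per-library proportions used by the
#' beta-binomial model are `X_i / N_i`.
#'
#' @param counts A data frame whose first column holds unique feature
#'   identifiers and whose remaining columns hold one library each, or a
#'   numeric matrix with rownames as feature ids.
#' @param condition Character or factor with one label per library; exactly
#'   two distinct labels, both non-empty.
#' @param library_sizes Optional positive totals per library. Each must be at
#'   least the corresponding column sum. Defaults to column sums.
#' @return An object of class `mbeta_counts`: a list with `counts` (tibble,
#'   `feature` + one column per library) and `design` (tibble with `library`,
#'   `condition`, `size`).
#' @examples
#' cm <- mbeta_counts(
#'   data.frame(feature = c("g1", "g2"), a1 = c(5L, 0L), a2 = c(7L, 1L),
#'              b1 = c(50L, 2L), b2 = c(44L, 0L)),
#'   condition = c("A", "A", "B", "B"))
#' cm
#' @export
mbeta_counts <- function(counts, condition, library_sizes = NULL) {
  if (is.matrix(counts)) {
    ids <- rownames(counts)
    if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(counts)))
    counts <- tibble::as_tibble(counts, .name_repair = "minimal")
    counts <- tibble::add_column(counts, feature = ids, .before = 1)
  }
  counts <- tibble::as_tibble(counts)
  if (ncol(counts) < 3L) {
    stop("need a feature-id column plus at least 2 library columns", call. = FALSE)
  }
  names(counts)[1] <- "feature"
  counts$feature <- as.character(counts$feature)
  if (anyDuplicated(counts$feature)) {
    dup <- unique(counts$feature[duplicated(counts$feature)])
    stop("duplicated feature identifiers: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat)) stop("counts must be numeric and complete", call. = FALSE)
  if (any(mat < 0) || any(mat != round(mat))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  libs <- colnames(mat)
  condition <- as.character(condition)
  if (length(condition) != length(libs)) {
    stop("`condition` must supply one label per library column", call. = FALSE)
  }
  if (length(unique(condition)) != 2L) {
    stop("exactly two condition labels are required, got: ",
         paste(unique(condition), collapse = ", "), call. = FALSE)
  }
  col_sums <- colSums(mat)
  if (is.null(library_sizes)) {
    library_sizes <- col_sums
  } else {
    if (length(library_sizes) != length(libs)) {
      stop("`library_sizes` must supply one value per library", call. = FALSE)
    }
    if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
    bad <- which(library_sizes < col_sums)
    if (length(bad)) {
      stop("library size smaller than column sum for: ",
           paste(libs[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (any(library_sizes <= 0)) {
    stop("all-zero library (size 0): ", paste(libs[library_sizes <= 0], collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      design = tibble::tibble(library = libs,
                              condition = condition,
                              size = as.numeric(library_sizes))
    ),
    class = "mbeta_counts"
  )
}

#' @export
print.mbeta_counts <- function(x, ...) {
  cat(sprintf("<mbeta_counts> %d features x %d libraries\n",
              nrow(x$counts), nrow(x$design)))
  tab <- table(x$design$condition)
  cat("  conditions:", paste(sprintf("%s (m=%d)", names(tab), tab), collapse = ", "), "\n")
  cat("  library sizes:", paste(format(x$design$size, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

count_matrix <- function(cm) {
  mat <- as.matrix(cm$counts[, -1, drop = FALSE])
  rownames(mat) <- cm$counts$feature
  mat
}

replace_counts <- function(cm, mat, sizes = NULL) {
  new <- tibble::as_tibble(mat, .name_repair = "minimal")
  cm$counts <- tibble::add_column(new, feature = rownames(mat), .before = 1)
  cm$design$size <- if (is.null(sizes)) colSums(mat) else as.numeric(sizes)
  cm
}

#' Read a count matrix and design from TSV/CSV
#'
#' The counts file holds feature identifiers in its first column and one
#' library per remaining column; the design file maps `library` to
#' `condition` (and optionally `size`). Delimiters are inferred from the
#' file extension (`.csv` = comma, otherwise tab).
#'
#' @param counts_path Path to the counts table.
#' @param design_path Path to the design table with columns `library`,
#'   `condition` and optionally `size`.
#' @return An [mbeta_counts] object.
#' @export
read_counts <- function(counts_path, design_path) {
  reader <- function(p) {
    if (grepl("\\.csv$", p, ignore.case = TRUE)) {
      readr::read_csv(p, show_col_types = FALSE)
    } else {
      readr::read_tsv(p, show_col_types = FALSE)
    }
  }
  counts <- reader(counts_path)
  design <- reader(design_path)
  if (!all(c("library", "condition") %in% names(design))) {
    stop("design file needs columns `library` and `condition`", call. = FALSE)
  }
  libs <- names(counts)[-1]
  miss <- setdiff(libs, design$library)
  if (length(miss)) {
    stop("libraries missing from design: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  design <- design[match(libs, design$library), ]
  sizes <- if ("size" %in% names(design)) design$size else NULL
  mbeta_counts(counts, design$condition, sizes)
}

#' Write a count object back to TSV
#'
#' @param cm An [mbeta_counts] object.
#' @param counts_path Destination for the counts table (TSV).
#' @param design_path Optional destination for the design table (TSV).
#' @return `cm`, invisibly.
#' @export
write_counts <- function(cm, counts_path, design_path = NULL) {
  readr::write_tsv(cm$counts, counts_path)
  if (!is.null(design_path)) readr::write_tsv(cm$design, design_path)
  invisible(cm)
}

#' Equalise effective library sizes
#'
#' Rescales libraries so that all replicate libraries have the same effective
#' size before proportions are formed. `"scale"` rescales every column to the
#' mean library size; `"median-ratios"` derives per-library size factors as
#' the median ratio to the per-feature geometric-mean reference and divides
#' each column by its factor. Rescaled counts are rounded to the nearest
#' integer (ties to even); library sizes are recomputed from the normalized
#' column sums unless sizes were user-supplied, in which case they are
#' rescaled by the same factors.
#'
#' @param cm An [mbeta_counts] object with at least two libraries.
#' @param method `"scale"` (scale to common size, default) or
#'   `"median-ratios"`.
#' @return A normalized [mbeta_counts] object with a `size_factors` attribute.
#' @export
normalize_libraries <- function(cm, method = c("scale", "median-ratios")) {
  method <- match.arg(method)
  mat <- count_matrix(cm)
  if (ncol(mat) < 2L) stop("normalization needs at least 2 libraries", call. = FALSE)
  zero <- colSums(mat) == 0
  if (any(zero)) {
    stop("all-zero library cannot be normalized: ",
         paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
  }
  sizes <- cm$design$size
  if (method == "scale") {
    target <- mean(sizes)
    sf <- sizes / target
  } else {
    pos <- rowSums(mat > 0) == ncol(mat)
    if (!any(pos)) {
      stop("median-ratios needs at least one feature observed in every library",
           call. = FALSE)
    }
    ref <- exp(rowMeans(log(mat[pos, , drop = FALSE])))
    sf <- apply(mat[pos, , drop = FALSE] / ref, 2, stats::median)
    sf <- sf / exp(mean(log(sf)))
  }
  out <- round(sweep(mat, 2, sf, "/"))
  storage.mode(out) <- "double"
  new_sizes <- colSums(out)
  cm <- replace_counts(cm, out, sizes = new_sizes)
  attr(cm, "size_factors") <- stats::setNames(sf, colnames(mat))
  cm
}

#' Drop features with low average counts
#'
#' Retains exactly the features whose mean count across all libraries is at
#' least `min_mean`; feature order is preserved. In the standard pipeline
#' this filter is applied after library-size normalization.
#'
#' @param cm An [mbeta_counts] object.
#' @param min_mean Minimum mean count across libraries (default 5, i.e.
#'   features with averaged read count < 5 are removed).
#' @return The filtered [mbeta_counts] with attribute `retained` holding the
#'   retained feature identifiers.
#' @export
filter_low_count <- function(cm, min_mean = 5) {
  mat <- count_matrix(cm)
  keep <- rowMeans(mat) >= min_mean
  cm$counts <- cm$counts[keep, , drop = FALSE]
  attr(cm, "retained") <- rownames(mat)[keep]
  cm
}
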