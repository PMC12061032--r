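#' Paired categorical ratings from two raters
#'
#' Bundles two equal-length label sequences (one per rater, one element per
#' case) with the category set. Cases where either rating is missing (`NA` or
#' the empty string) are dropped pairwise, with a message; all agreement
#' statistics assume both ratings are present.
#'
#' @param ratings_a,ratings_b vectors of category labels, one element per case.
#'   Coerced to character.
#' @param categories optional character vector of distinct category labels.
#'   When `NULL`, the sorted union of observed labels is used. Supply it
#'   explicitly whenever a category may be unobserved: the number of
#'   categories `n` enters the multi-category maximum-likelihood formulas.
#' @return An object of class `paired_ratings`: a list with elements
#'   `ratings_a`, `ratings_b` (character vectors of length `N`), `categories`,
#'   and `n_dropped` (count of pairwise-deleted incomplete cases).
#' @examples
#' x <- paired_ratings(c("+", "+", "-", "+"), c("+", "-", "-", "+"))
#' summarize_agreement(x)
#' @seealso [summarize_agreement()], [read_ratings()]
#' @export
paired_ratings <- function(ratings_a, ratings_b, categories = NULL) {
  a <- as.character(ratings_a)
  b <- as.character(ratings_b)
  if (length(a) != length(b)) {
    stop("ratings_a and ratings_b must have the same length (one case per element), got ",
         length(a), " and ", length(b), call. = FALSE)
  }
  missing <- is.na(a) | is.na(b) | a == "" | b == ""
  n_dropped <- sum(missing)
  if (n_dropped > 0L) {
    message("Dropped ", n_dropped, " case(s) with a missing rating.")
    a <- a[!missing]
    b <- b[!missing]
  }
  if (length(a) == 0L) {
    stop("No complete cases: at least one case with both ratings is required.",
         call. = FALSE)
  }
  observed <- sort(unique(c(a, b)))
  if (is.null(categories)) {
    categories <- observed
    if (length(categories) < 2L) {
      stop("Only one category ('", categories, "') was observed; supply ",
           "`categories` explicitly so the number of categories is known.",
           call. = FALSE)
    }
  } else {
    categories <- as.character(categories)
    if (anyDuplicated(categories)) {
      stop("`categories` contains duplicated labels.", call. = FALSE)
    }
    if (length(categories) < 2L) {
      stop("At least two categories are required, got ", length(categories),
           call. = FALSE)
    }
    unknown <- setdiff(observed, categories)
    if (length(unknown) > 0L) {
      stop("Rating label(s) not in `categories`: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(ratings_a = a, ratings_b = b, categories = categories,
         n_dropped = n_dropped),
    class = "paired_ratings"
  )
}

#' @export
print.paired_ratings <- function(x, ...) {
  cat("Paired ratings: ", length(x$ratings_a), " cases, ",
      length(x$categories), " categories (",
      paste(x$categories, collapse = ", "), ")\n", sep = "")
  if (x$n_dropped > 0L) {
    cat("  (", x$n_dropped, " incomplete case(s) dropped)\n", sep = "")
  }
  invisible(x)
}

# integer-coded view used by the estimators and the bootstrap
ratings_codes <- function(x) {
  stopifnot(inherits(x, "paired_ratings"))
  list(
    a = match(x$ratings_a, x$categories),
    b = match(x$ratings_b, x$categories),
    n = length(x$categories),
    N = length(x$ratings_a)
  )
}

#' Summarize observed agreement
#'
#' Counts the cases on which the two raters give identical labels and returns
#' the agreement and disagreement counts and rates.
#'
#' @param ratings a [paired_ratings()] object.
#' @return An object of class `agreement_summary`: a list with `n_cases` (N),
#'   `n_agree` (Na), `n_disagree` (Nd), `p_agree` (Pa = Na/N) and `p_disagree`
#'   (Pd = Nd/N).
#' @examples
#' summarize_agreement(paired_ratings(c("+", "+", "-", "+"),
#'                                    c("+", "-", "-", "+")))
#' @export
summarize_agreement <- function(ratings) {
  stopifnot(inherits(ratings, "paired_ratings"))
  n_cases <- length(ratings$ratings_a)
  n_agree <- sum(ratings$ratings_a == ratings$ratings_b)
  n_disagree <- n_cases - n_agree
  structure(
    list(n_cases = n_cases, n_agree = n_agree, n_disagree = n_disagree,
         p_agree = n_agree / n_cases, p_disagree = n_disagree / n_cases),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement: %d of %d cases (Pa = %.4f, Pd = %.4f)\n",
              x$n_agree, x$n_cases, x$p_agree, x$p_disagree))
  invisible(x)
}

# per-rater marginal proportions over the category set (rows: a, b)
marginal_rates <- function(ratings) {
  cd <- ratings_codes(ratings)
  p_a <- tabulate(cd$a, nbins = cd$n) / cd$N
  p_b <- tabulate(cd$b, nbins = cd$n) / cd$N
  list(p_a = p_a, p_b = p_b)
}

#' Read paired ratings from a delimited file
#'
#' Two input layouts are supported. `"two_column"` expects one row per case
#' with the two raters' labels in the first two columns; a header row is
#' detected automatically (or forced via `header`). `"contingency"` expects a
#' square table of non-negative integer counts with matching row and column
#' labels (rows: rater A, columns: rater B), which is expanded to case-level
#' pairs in row-major label order — case order is irrelevant to every
#' statistic computed by this package.
#'
#' @param path path to a delimited text file.
#' @param format `"two_column"` (default) or `"contingency"`.
#' @param sep field separator; by default `","` for `.csv` files and
#'   whitespace/tab otherwise.
#' @param header for `"two_column"`: `NA` (default) auto-detects a header row
#'   (the first row is treated as a header when neither of its entries recurs
#'   as a label in the remaining rows); `TRUE`/`FALSE` force the choice.
#' @param categories optional explicit category set, passed to
#'   [paired_ratings()].
#' @return A [paired_ratings()] object.
#' @export
read_ratings <- function(path, format = c("two_column", "contingency"),
                         sep = NULL, header = NA, categories = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""

  if (format == "two_column") {
    raw <- tryCatch(
      read.table(path, sep = sep, header = FALSE, colClasses = "character",
                 strip.white = TRUE, blank.lines.skip = TRUE,
                 stringsAsFactors = FALSE),
      error = function(e) stop("Failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (nrow(raw) == 0L) stop("Empty input: ", path, " contains no cases.",
                              call. = FALSE)
    if (ncol(raw) < 2L) {
      stop("Expected two columns of labels in ", path, ", found ", ncol(raw),
           call. = FALSE)
    }
    if (is.na(header)) {
      rest <- unique(c(raw[-1L, 1L], raw[-1L, 2L]))
      header <- nrow(raw) > 1L && !any(unlist(raw[1L, 1:2]) %in% rest)
    }
    if (header) raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L) stop("Empty input: ", path, " has a header but no cases.",
                              call. = FALSE)
    paired_ratings(raw[[1L]], raw[[2L]], categories = categories)
  } else {
    tab <- tryCatch(
      as.matrix(read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE)),
      error = function(e) stop("Failed to parse contingency table ", path,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    expand_contingency(tab, categories = categories)
  }
}

# expand a square count table (rows: rater A, cols: rater B) to case pairs
expand_contingency <- function(tab, categories = NULL) {
  if (nrow(tab) != ncol(tab)) {
    stop("Contingency table must be square, got ", nrow(tab), "x", ncol(tab),
         call. = FALSE)
  }
  if (!setequal(rownames(tab), colnames(tab))) {
    stop("Contingency row labels and column labels must match.", call. = FALSE)
  }
  tab <- tab[, rownames(tab), drop = FALSE]
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("Contingency table entries must be non-negative integers.",
         call. = FALSE)
  }
  if (sum(tab) == 0) stop("Contingency table contains zero cases.", call. = FALSE)
  labels <- rownames(tab)
  idx <- which(tab > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  counts <- tab[idx]
  paired_ratings(rep(labels[idx[, 1L]], counts),
                 rep(labels[idx[, 2L]], counts),
                 categories = if (is.null(categories)) labels else categories)
}

#' Write paired ratings to a two-column CSV
#'
#' @param ratings a [paired_ratings()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "paired_ratings"))
  df <- data.frame(rater_a = ratings$ratings_a, rater_b = ratings$ratings_b,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
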