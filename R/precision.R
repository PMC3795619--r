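#' Multi-reader age matrix
#'
#' Wraps an animals-by-readers matrix of age reads (years, half-year
#' resolution allowed) with optional per-animal readability scores, as
#' produced by the blind multi-reader ageing protocol: each vertebral
#' sample is read independently by two or more readers, and a readability
#' score from 1 (clear bands) to 3 (unreadable) is assigned.
#'
#' @param reads numeric matrix or data frame, one row per animal, one
#'   column per reader; at least two readers, no missing cells, all reads
#'   `>= 0`.
#' @param readability optional integer vector (one per animal) in 1..3.
#' @param animal_ids optional identifiers; default `1:n`.
#' @return an object of class `"reader_matrix"`.
#' @export
reader_matrix <- function(reads, readability = NULL, animal_ids = NULL) {
  reads <- as.matrix(reads)
  storage.mode(reads) <- "double"
  if (ncol(reads) < 2L) stop("need at least 2 readers")
  if (anyNA(reads)) stop("missing cells in reader matrix")
  if (any(reads < 0)) stop("age reads must be >= 0")
  n <- nrow(reads)
  if (is.null(animal_ids)) animal_ids <- seq_len(n)
  if (length(animal_ids) != n) stop("'animal_ids' length mismatch")
  if (!is.null(readability)) {
    if (length(readability) != n) stop("'readability' length mismatch")
    if (!all(readability %in% 1:3)) stop("readability scores must be in {1, 2, 3}")
    readability <- as.integer(readability)
  }
  colnames(reads) <- paste0("reader_", seq_len(ncol(reads)))
  structure(list(reads = reads, readability = readability,
                 animal_ids = animal_ids),
            class = "reader_matrix")
}

#' @export
print.reader_matrix <- function(x, ...) {
  cat(sprintf("Reader matrix: %d animals x %d readers\n",
              nrow(x$reads), ncol(x$reads)))
  if (!is.null(x$readability)) {
    cat("readability counts:",
        paste(names(table(x$readability)), table(x$readability),
              sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Consensus age from multiple reads
#'
#' An animal's final age estimate is the value on which two or more
#' readers agree (the modal read, when its count is at least two).
#' Without such agreement — or when two distinct values tie for the mode
#' with four or more readers — the animal is unresolved and `NA` is
#' returned (it is excluded downstream).
#'
#' @param reads numeric vector of one animal's reads (length >= 2), or a
#'   [reader_matrix] for all animals.
#' @return a single age (or `NA` if unresolved); for a matrix, a data
#'   frame with `animal_id`, `consensus` and `resolved`.
#' @examples
#' consensus_age(c(3, 3, 4))   # 3
#' consensus_age(c(3, 4, 5))   # NA (unresolved)
#' @export
consensus_age <- function(reads) {
  if (inherits(reads, "reader_matrix")) {
    cons <- apply(reads$reads, 1L, consensus_age)
    return(data.frame(animal_id = reads$animal_ids, consensus = cons,
                      resolved = !is.na(cons)))
  }
  stopifnot(is.numeric(reads), length(reads) >= 2L, all(reads >= 0))
  tab <- table(reads)
  top <- max(tab)
  if (top < 2L) return(NA_real_)
  modes <- as.numeric(names(tab)[tab == top])
  if (length(modes) > 1L) return(NA_real_)  # tied modes: unresolved
  modes
}

#' Filter out unreadable samples
#'
#' Removes animals whose vertebrae received a readability score of 3
#' (unreadable) and reports the per-score counts.
#'
#' @param x a [reader_matrix] with readability scores, or a data frame of
#'   size-at-age records with a `readability` column.
#' @return a list with `retained` (same type as `x`), `n_excluded` and
#'   `report` (named counts for scores "1", "2", "3").
#' @export
filter_readability <- function(x) {
  scores <- if (inherits(x, "reader_matrix")) {
    if (is.null(x$readability)) stop("no readability scores present")
    x$readability
  } else if (is.data.frame(x)) {
    if (is.null(x$readability)) stop("no readability column present")
    x$readability
  } else {
    stop("'x' must be a reader_matrix or a data frame")
  }
  if (length(scores) && !all(scores %in% 1:3)) {
    stop("readability scores must be in {1, 2, 3}")
  }
  report <- vapply(1:3, function(s) sum(scores == s), 0L)
  names(report) <- as.character(1:3)
  keep <- scores != 3L
  retained <- if (inherits(x, "reader_matrix")) {
    reader_matrix(x$reads[keep, , drop = FALSE], x$readability[keep],
                  x$animal_ids[keep])
  } else {
    x[keep, , drop = FALSE]
  }
  list(retained = retained, n_excluded = sum(!keep), report = report)
}

per_animal_stats <- function(m) {
  means <- rowMeans(m$reads)
  if (any(means <= 0)) {
    bad <- m$animal_ids[which(means <= 0)[1L]]
    stop(sprintf("animal '%s' has mean age 0; percent error undefined", bad))
  }
  means
}

#' Index of average percent error (IAPE)
#'
#' Ageing-precision index of Beamish & Fournier: for animal j with R
#' reads, `APE_j = (100 / R) * sum_i |x_ij - xbar_j| / xbar_j`; the
#' overall IAPE is the mean of `APE_j` over animals. With `per_reader =
#' TRUE`, reader i's index is the mean over animals of
#' `100 * |x_ij - xbar_j| / xbar_j`.
#'
#' @param m a [reader_matrix].
#' @param per_reader also return per-reader indices.
#' @return overall IAPE (percent); with `per_reader`, a list with
#'   `overall` and `per_reader`.
#' @examples
#' m <- reader_matrix(rbind(c(2, 2, 2), c(4, 5, 6)))
#' iape(m)               # 6.667
#' iape(m, per_reader = TRUE)$per_reader
#' @export
iape <- function(m, per_reader = FALSE) {
  stopifnot(inherits(m, "reader_matrix"))
  means <- per_animal_stats(m)
  rel_dev <- abs(sweep(m$reads, 1L, means)) / means
  ape <- 100 * rowMeans(rel_dev)
  overall <- mean(ape)
  if (!per_reader) return(overall)
  list(overall = overall, per_reader = 100 * colMeans(rel_dev))
}

#' Coefficient of variation of age reads
#'
#' Per-animal percent coefficient of variation of the reader age
#' estimates, `CV_j = 100 * sd_j / xbar_j` with the sample (R - 1)
#' standard deviation, averaged over animals (Chang's convention). With
#' two readers this satisfies `CV = sqrt(2) * APE` per animal. The
#' per-reader variant scales each reader's absolute deviation by
#' `sqrt(R / (R - 1))` so that it averages to the per-animal CV across
#' readers.
#'
#' @inheritParams iape
#' @return overall CV (percent); with `per_reader`, a list with `overall`
#'   and `per_reader`.
#' @export
cv_index <- function(m, per_reader = FALSE) {
  stopifnot(inherits(m, "reader_matrix"))
  means <- per_animal_stats(m)
  dev <- sweep(m$reads, 1L, means)
  R <- ncol(m$reads)
  sd_j <- sqrt(rowSums(dev^2) / (R - 1))
  cv_j <- 100 * sd_j / means
  overall <- mean(cv_j)
  if (!per_reader) return(overall)
  per <- 100 * colMeans(abs(dev) * sqrt(R / (R - 1)) / means)
  list(overall = overall, per_reader = per)
}

#' Ageing precision report
#'
#' Computes the full precision table for a multi-reader matrix: overall
#' and per-reader IAPE and CV, after excluding unreadable samples when
#' readability scores are present.
#'
#' @param m a [reader_matrix].
#' @param exclude_unreadable drop readability-3 animals first (default
#'   when scores are present).
#' @return a list of class `"precision_report"` with `iape`, `cv`,
#'   `per_reader` (data frame), `n_used`, `readability_report`.
#' @export
ageing_precision <- function(m, exclude_unreadable = !is.null(m$readability)) {
  stopifnot(inherits(m, "reader_matrix"))
  readability_report <- NULL
  if (exclude_unreadable) {
    f <- filter_readability(m)
    readability_report <- f$report
    m <- f$retained
  }
  if (nrow(m$reads) == 0L) stop("no animals left after readability filtering")
  i <- iape(m, per_reader = TRUE)
  cv <- cv_index(m, per_reader = TRUE)
  structure(list(
    iape = i$overall, cv = cv$overall,
    per_reader = data.frame(reader = seq_along(i$per_reader),
                            iape = unname(i$per_reader),
                            cv = unname(cv$per_reader)),
    n_used = nrow(m$reads), readability_report = readability_report
  ), class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf("Ageing precision (n = %d animals)\n", x$n_used))
  cat(sprintf("  IAPE = %.3f%%   CV = %.3f%%\n", x$iape, x$cv))
  pr <- x$per_reader
  pr[, c("iape", "cv")] <- round(pr[, c("iape", "cv")], 3)
  print(pr, row.names = FALSE)
  if (!is.null(x$readability_report)) {
    cat("readability counts:",
        paste(names(x$readability_report), x$readability_report,
              sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}
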