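#' Construct a pairwise-comparison (judgment) matrix
#'
#' A judgment matrix holds one expert's pairwise importance ratios for the
#' sibling elements under a node of an evaluation hierarchy, on the Saaty
#' 1--9 scale. Entry \code{[i, j]} answers "how much more important is
#' element i than element j": 1 equal, 3 slightly, 5 significantly, 7
#' strongly, 9 extremely, with 2/4/6/8 intermediate and reciprocals for the
#' reversed comparison.
#'
#' @param x square numeric matrix (or object coercible to one) of positive
#'   ratios with unit diagonal and reciprocal symmetry
#'   (\code{x[j, i] == 1 / x[i, j]}).
#' @param labels optional character vector of element names; defaults to the
#'   dimnames of \code{x} or \code{e1..en}.
#' @param strict if \code{TRUE}, every off-diagonal entry must belong to the
#'   Saaty set \{1/9, ..., 1/2, 1, 2, ..., 9\}. Use for questionnaire input;
#'   leave \code{FALSE} for synthetic perturbed matrices.
#' @return the validated matrix with class \code{"judgment_matrix"}.
#' @examples
#' judgment_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1)),
#'                 labels = c("soil", "crop", "amendment"))
#' @seealso [priority_vector()], [consistency()]
#' @export
judgment_matrix <- function(x, labels = NULL, strict = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop("judgment matrix entries must be numeric", call. = FALSE)
  }
  if (nrow(x) != ncol(x)) {
    stop(sprintf("judgment matrix must be square, got %d x %d",
                 nrow(x), ncol(x)), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- paste0("e", seq_len(nrow(x)))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(labels, labels)
  class(x) <- c("judgment_matrix", "matrix", "array")
  validate_judgment_matrix(x, strict = strict)
}

#' Validate a judgment matrix
#'
#' Checks squareness, strict positivity, a unit diagonal, reciprocity
#' (\code{m[j, i] * m[i, j] == 1} within 1e-9 relative tolerance) and,
#' in strict mode, membership of every off-diagonal entry in the Saaty set.
#' Violations are reported with the offending row/column.
#'
#' @param m matrix to validate.
#' @param strict enforce Saaty-set membership of off-diagonal entries.
#' @return \code{m}, invisibly classed as a \code{judgment_matrix}.
#' @export
validate_judgment_matrix <- function(m, strict = FALSE) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("judgment matrix must be square, got %d x %d",
                 nrow(m), ncol(m)), call. = FALSE)
  }
  n <- nrow(m)
  if (n < 1L) stop("judgment matrix must have order >= 1", call. = FALSE)
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-positive or non-finite entry at (%d,%d)",
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  if (any(abs(diag(m) - 1) > 1e-9)) {
    i <- which(abs(diag(m) - 1) > 1e-9)[1L]
    stop(sprintf("diagonal entry (%d,%d) must equal 1, got %g", i, i, m[i, i]),
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(m[i, j] * m[j, i] - 1) > 1e-9) {
        stop(sprintf(
          "reciprocity violated at (%d,%d): %g * %g != 1", j, i,
          m[i, j], m[j, i]), call. = FALSE)
      }
    }
  }
  if (strict) {
    off <- m[row(m) != col(m)]
    idx <- which(row(m) != col(m), arr.ind = TRUE)
    ok <- vapply(off, function(v) any(abs(v - saaty_scale()) < 1e-6), logical(1))
    if (!all(ok)) {
      b <- idx[which(!ok)[1L], ]
      stop(sprintf("entry (%d,%d) = %g is not a Saaty scale value",
                   b[1L], b[2L], m[b[1L], b[2L]]), call. = FALSE)
    }
  }
  class(m) <- c("judgment_matrix", "matrix", "array")
  invisible(m)
}

#' The Saaty 1--9 ratio scale
#'
#' @return numeric vector of the 17 admissible pairwise ratios
#'   \{1/9, 1/8, ..., 1/2, 1, 2, ..., 9\}.
#' @export
saaty_scale <- function() c(1 / (9:2), 1:9)

#' Column-normalize a judgment matrix
#'
#' Divides each entry by its column sum so that every column of the result
#' sums to 1. This is the first step of the sum-product approximation to the
#' principal eigenvector.
#'
#' @param m a judgment matrix (validated on entry).
#' @return numeric matrix with unit column sums.
#' @export
column_normalize <- function(m) {
  m <- validate_judgment_matrix(m)
  sweep(unclass(m), 2L, colSums(m), "/")
}

#' Priority (weight) vector by the sum-product method
#'
#' Column-normalizes the matrix, sums the rows, and renormalizes the row
#' sums to 1. For a perfectly consistent matrix (\code{b_ik = b_ij * b_jk})
#' this recovers the generating weights exactly; otherwise it is a one-step
#' approximation to the principal eigenvector.
#'
#' @param m a judgment matrix.
#' @return named numeric weight vector summing to 1.
#' @examples
#' m <- judgment_matrix(rbind(c(1, 2), c(1/2, 1)))
#' priority_vector(m)  # 2/3, 1/3
#' @export
priority_vector <- function(m) {
  m <- validate_judgment_matrix(m)
  w <- rowSums(column_normalize(m))
  w <- w / sum(w)
  names(w) <- rownames(m)
  w
}

#' Maximum characteristic root of a judgment matrix
#'
#' Estimates the principal eigenvalue as the mean Rayleigh-type ratio
#' \code{mean((m \%*\% w) / w)} at the priority vector \code{w}. Equals the
#' order \code{n} exactly when the matrix is consistent and exceeds it
#' otherwise.
#'
#' @param m a judgment matrix.
#' @param w its priority vector; computed with [priority_vector()] when
#'   omitted.
#' @return scalar estimate of \eqn{\lambda_{max}}.
#' @export
lambda_max <- function(m, w = priority_vector(m)) {
  m <- validate_judgment_matrix(m)
  if (any(w <= 0)) {
    stop(sprintf("weight component %d is not positive", which(w <= 0)[1L]),
         call. = FALSE)
  }
  aw <- as.vector(unclass(m) %*% w)
  mean(aw / w)
}

# Random consistency index for orders 1..9 (Saaty's simulated values).
.ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Random consistency index RI
#'
#' @param n matrix order, 1 to 9.
#' @return the tabulated RI value.
#' @export
random_index <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1) {
    stop("n must be a single positive integer", call. = FALSE)
  }
  if (n > 9) {
    stop(sprintf("RI is tabulated only for orders 1..9 (got n = %d)", n),
         call. = FALSE)
  }
  .ri_table[[n]]
}

#' Consistency test of a judgment matrix
#'
#' Computes the consistency index \eqn{CI = (\lambda_{max} - n) / (n - 1)}
#' and the consistency ratio \eqn{CR = CI / RI}, with RI the tabulated
#' random index for the matrix order. A matrix passes when \eqn{CR < 0.1}.
#' Orders 1 and 2 are always consistent (RI = 0); CR is defined as 0 there
#' rather than dividing by zero.
#'
#' @param m a judgment matrix of order 1..9.
#' @return object of class \code{"consistency_report"}: a list with
#'   \code{n}, \code{lambda_max}, \code{ci}, \code{ri}, \code{cr},
#'   \code{passed}.
#' @examples
#' consistency(judgment_matrix(rbind(c(1, 3, 5), c(1/3, 1, 5/3), c(1/5, 3/5, 1))))
#' @export
consistency <- function(m) {
  m <- validate_judgment_matrix(m)
  n <- nrow(m)
  lm <- if (n == 1L) 1 else lambda_max(m)
  ci <- if (n <= 2L) 0 else (lm - n) / (n - 1)
  ri <- random_index(n)
  cr <- if (ri == 0) 0 else ci / ri
  structure(
    list(n = n, lambda_max = lm, ci = ci, ri = ri, cr = cr,
         passed = cr < 0.1),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency test (n = %d)\n  lambda_max = %.6f\n  CI = %.6f  RI = %.2f  CR = %.6f\n  %s\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$passed) "PASSED (CR < 0.1)" else "FAILED (CR >= 0.1): readjust the matrix"
  ))
  invisible(x)
}

#' Read a judgment matrix from CSV or JSON
#'
#' CSV files carry a header row and a leading label column; JSON files are
#' either a bare array-of-arrays or an object with \code{entries} and
#' optional \code{labels}.
#'
#' @param path file path ending in \code{.csv} or \code{.json}.
#' @param strict passed to [judgment_matrix()].
#' @return a \code{judgment_matrix}.
#' @export
read_judgment_matrix <- function(path, strict = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.list(obj) && !is.null(obj$entries)) {
      return(judgment_matrix(obj$entries, labels = obj$labels, strict = strict))
    }
    return(judgment_matrix(obj, strict = strict))
  }
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  judgment_matrix(as.matrix(df), labels = colnames(df), strict = strict)
}

#' Read an expert panel of judgment matrices
#'
#' @param path either a directory of per-expert CSV/JSON matrix files, or a
#'   single JSON file holding an array of matrices (each an array-of-arrays
#'   or \code{\{entries, labels\}} object).
#' @param strict passed through to the matrix constructor.
#' @return list of \code{judgment_matrix} objects.
#' @export
read_panel <- function(path, strict = FALSE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(csv|json)$", full.names = TRUE))
    if (length(files) == 0L) stop("no matrix files found in ", path, call. = FALSE)
    return(lapply(files, read_judgment_matrix, strict = strict))
  }
  arr <- jsonlite::fromJSON(path, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  lapply(arr, function(o) {
    if (is.list(o) && !is.null(o$entries)) {
      judgment_matrix(do.call(rbind, lapply(o$entries, unlist)),
                      labels = unlist(o$labels), strict = strict)
    } else {
      judgment_matrix(do.call(rbind, lapply(o, unlist)), strict = strict)
    }
  })
}
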