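#' Aggregate an expert panel into one weight vector
#'
#' Each expert contributes either a judgment matrix or an already-computed
#' weight vector for the same sibling set. Matrices failing the CR < 0.1
#' consistency test are excluded (and reported); the surviving priority
#' vectors are combined by a (weighted) arithmetic mean and renormalized.
#' A geometric-mean aggregation of the matrix entries is available as an
#' alternative; it forms the element-wise geometric mean matrix (which is
#' again reciprocal) and takes its priority vector.
#'
#' @param panel list whose elements are \code{judgment_matrix} objects or
#'   numeric weight vectors summing to 1.
#' @param expert_weights optional nonnegative per-expert weights (defaults
#'   to equal weights); renormalized over the experts that survive
#'   consistency filtering.
#' @param cr_threshold consistency-ratio cutoff for excluding a matrix.
#' @param method \code{"vector"} (default: mean of priority vectors) or
#'   \code{"geometric_matrix"}.
#' @return list with \code{weights} (named, sums to 1), \code{excluded}
#'   (indices of experts dropped by the CR filter) and \code{n_used}.
#' @examples
#' aggregate_experts(list(c(a = 0.6, b = 0.4), c(a = 0.4, b = 0.6)))$weights
#' @export
aggregate_experts <- function(panel, expert_weights = NULL, cr_threshold = 0.1,
                              method = c("vector", "geometric_matrix")) {
  method <- match.arg(method)
  if (length(panel) == 0L) stop("empty expert panel", call. = FALSE)
  is_mat <- vapply(panel, function(p) inherits(p, "judgment_matrix") ||
                     (is.matrix(p) && nrow(p) == ncol(p)), logical(1))
  if (is.null(expert_weights)) expert_weights <- rep(1, length(panel))
  stopifnot(length(expert_weights) == length(panel), all(expert_weights >= 0))

  excluded <- integer(0)
  for (i in seq_along(panel)) {
    if (is_mat[[i]]) {
      rep_i <- consistency(panel[[i]])
      if (rep_i$cr >= cr_threshold) excluded <- c(excluded, i)
    }
  }
  keep <- setdiff(seq_along(panel), excluded)
  if (length(keep) == 0L) {
    stop("no experts remain after consistency filtering", call. = FALSE)
  }

  vecs <- lapply(keep, function(i) {
    if (is_mat[[i]]) priority_vector(panel[[i]]) else {
      v <- panel[[i]]
      if (abs(sum(v) - 1) > 1e-6) stop(
        sprintf("expert %d: weight vector does not sum to 1", i), call. = FALSE)
      v
    }
  })
  ns <- lengths(vecs)
  if (length(unique(ns)) != 1L) {
    stop("experts disagree on the number of elements", call. = FALSE)
  }

  if (method == "geometric_matrix") {
    mats <- panel[keep]
    if (!all(is_mat[keep])) {
      stop("geometric_matrix aggregation requires judgment matrices", call. = FALSE)
    }
    ew <- expert_weights[keep] / sum(expert_weights[keep])
    logm <- Reduce(`+`, Map(function(m, w) w * log(unclass(m)), mats, ew))
    w <- priority_vector(judgment_matrix(exp(logm),
                                         labels = rownames(mats[[1L]])))
  } else {
    ew <- expert_weights[keep] / sum(expert_weights[keep])
    w <- Reduce(`+`, Map(`*`, vecs, ew))
    w <- w / sum(w)
  }
  list(weights = w, excluded = excluded, n_used = length(keep))
}

# ---- evaluation hierarchy ---------------------------------------------------

#' Read an evaluation hierarchy from JSON or YAML
#'
#' The document is a tree of nodes \code{\{name, weight, children\}}; leaves
#' are indicators. Leaves may instead carry a \code{comprehensive} (global)
#' weight, in which case their local weights are derived by renormalizing the
#' comprehensive weights within each parent. Every node's children must have
#' local weights summing to 1 (within 1e-6).
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return the validated tree, class \code{"evaluation_hierarchy"}.
#' @seealso [compose_weights()], [default_hierarchy()]
#' @export
read_hierarchy <- function(path) {
  tree <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  as_hierarchy(tree)
}

#' Coerce and validate a nested list as an evaluation hierarchy
#'
#' @param tree nested list of \code{\{name, weight, children\}} nodes.
#' @return validated tree of class \code{"evaluation_hierarchy"}.
#' @export
as_hierarchy <- function(tree) {
  fill <- function(node) {
    if (is.null(node$name)) stop("hierarchy node without a name", call. = FALSE)
    if (!is.null(node$children)) {
      kw <- vapply(node$children, function(k) {
        if (!is.null(k$weight)) as.numeric(k$weight) else NA_real_
      }, numeric(1))
      if (anyNA(kw)) {
        comp <- vapply(node$children, function(k) {
          if (!is.null(k$comprehensive)) as.numeric(k$comprehensive) else NA_real_
        }, numeric(1))
        if (anyNA(comp)) stop(sprintf(
          "children of '%s' need either local or comprehensive weights",
          node$name), call. = FALSE)
        kw <- comp / sum(comp)
      }
      if (any(kw < 0)) stop(sprintf(
        "negative child weight under '%s'", node$name), call. = FALSE)
      if (abs(sum(kw) - 1) > 1e-6) stop(sprintf(
        "local weights under '%s' sum to %.6f, not 1", node$name, sum(kw)),
        call. = FALSE)
      node$children <- Map(function(k, w) { k$weight <- w; fill(k) },
                           node$children, kw)
    }
    node
  }
  out <- fill(tree)
  class(out) <- "evaluation_hierarchy"
  out
}

#' Compose comprehensive (global) indicator weights
#'
#' The comprehensive weight of each leaf indicator is the product of the
#' local weights along its path from the root; over all leaves these sum
#' to 1.
#'
#' @param h an \code{evaluation_hierarchy}.
#' @return named numeric vector, one comprehensive weight per leaf.
#' @examples
#' h <- as_hierarchy(list(name = "root", children = list(
#'   list(name = "a", weight = 0.6,
#'        children = list(list(name = "x", weight = 1))),
#'   list(name = "b", weight = 0.4,
#'        children = list(list(name = "y", weight = 0.5),
#'                        list(name = "z", weight = 0.5))))))
#' compose_weights(h)  # x 0.6, y 0.2, z 0.2
#' @export
compose_weights <- function(h) {
  stopifnot(inherits(h, "evaluation_hierarchy") || is.list(h))
  walk <- function(node, acc) {
    if (is.null(node$children)) {
      out <- acc
      names(out) <- node$name
      return(out)
    }
    unlist(lapply(node$children, function(k) walk(k, acc * k$weight)))
  }
  w <- walk(h, 1)
  if (abs(sum(w) - 1) > 1e-6) {
    stop(sprintf("composed leaf weights sum to %.6f, not 1", sum(w)),
         call. = FALSE)
  }
  w
}

#' The packaged expert-derived weight hierarchy
#'
#' The evaluation tree obtained from a 20-expert questionnaire panel:
#' soil (0.544: fertility 0.295, heavy metal 0.705), crop (0.316: growth
#' 0.265, pollution accumulation 0.735) and amendment (0.140), with 16 leaf
#' indicators. Leaf local weights are derived from the published
#' comprehensive weights by within-parent renormalization.
#'
#' @return an \code{evaluation_hierarchy}.
#' @export
default_hierarchy <- function() {
  read_hierarchy(system.file("extdata", "hierarchy_weights.json",
                             package = "stabeval", mustWork = TRUE))
}

#' Published comprehensive indicator weights
#'
#' The 16 expert-derived comprehensive weights as published. Because each
#' was rounded to 3 decimals independently, the printed values sum to 1.003;
#' \code{source = "renormalized"} divides them by their sum so they sum to
#' exactly 1.
#'
#' @param source \code{"printed"} (verbatim, default — reproduces the
#'   package's worked example) or \code{"renormalized"}.
#' @return named numeric vector of 16 weights.
#' @export
default_weights <- function(source = c("printed", "renormalized")) {
  source <- match.arg(source)
  h <- default_hierarchy()
  collect <- function(node) {
    if (is.null(node$children)) {
      w <- if (!is.null(node$comprehensive)) as.numeric(node$comprehensive)
           else NA_real_
      stats::setNames(w, node$name)
    } else {
      unlist(lapply(node$children, collect))
    }
  }
  w <- collect(h)
  if (anyNA(w)) stop("packaged hierarchy lacks comprehensive weights",
                     call. = FALSE)
  if (source == "renormalized") w <- w / sum(w)
  w
}
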