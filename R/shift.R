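# Inter-species pI divergence: pairwise differences, the non-parametric
# shift threshold 2 x (Q3 - median), permutation significance, pI
# discretization, and minimum state-change counts on a species tree.

#' Construct an ortholog pI set
#'
#' Per-family, per-species pI values. Accepts either a long data frame with
#' columns `family`, `species`, `pi`, or a numeric matrix with family
#' rownames and species colnames. Missing species within a family are `NA`.
#'
#' @param x long data frame or matrix (see above).
#' @return an object of class `ortholog_pi_set` wrapping the family-by-
#'   species matrix.
#' @export
ortholog_pi_set <- function(x) {
  if (is.matrix(x)) {
    mat <- x
  } else if (is.data.frame(x)) {
    miss <- setdiff(c("family", "species", "pi"), names(x))
    if (length(miss)) {
      stop("pI table is missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    if (anyDuplicated(x[, c("family", "species")])) {
      stop("duplicate (family, species) entries in pI table")
    }
    fams <- unique(x$family); sps <- unique(x$species)
    mat <- matrix(NA_real_, length(fams), length(sps),
                  dimnames = list(fams, sps))
    mat[cbind(match(x$family, fams), match(x$species, sps))] <- x$pi
  } else {
    stop("x must be a data frame or a matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must carry family rownames and species colnames")
  }
  if (any(!is.finite(mat) & !is.na(mat))) stop("pI values must be finite")
  structure(list(pi = mat), class = "ortholog_pi_set")
}

#' @export
print.ortholog_pi_set <- function(x, ...) {
  cat(sprintf("<ortholog_pi_set> %d families x %d species (%s)\n",
              nrow(x$pi), ncol(x$pi),
              paste(colnames(x$pi), collapse = ", ")))
  invisible(x)
}

#' Read / write an ortholog pI table
#'
#' Long TSV with columns `family`, `species`, `pi`.
#'
#' @param path TSV path.
#' @return `read_pi_table`: an [ortholog_pi_set()].
#' @export
read_pi_table <- function(path) {
  ortholog_pi_set(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_pi_table
#' @param piset an `ortholog_pi_set`.
#' @export
write_pi_table <- function(piset, path) {
  mat <- piset$pi
  long <- data.frame(
    family = rep(rownames(mat), ncol(mat)),
    species = rep(colnames(mat), each = nrow(mat)),
    pi = as.vector(mat), stringsAsFactors = FALSE)
  long <- long[!is.na(long$pi), ]
  long <- long[order(long$family, long$species), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Absolute pI differences between two species
#'
#' @param piset an [ortholog_pi_set()].
#' @param species_a,species_b distinct species names.
#' @return named numeric vector of `|pI_A - pI_B|`, one entry per family
#'   that has both species.
#' @export
pairwise_diffs <- function(piset, species_a, species_b) {
  stopifnot(inherits(piset, "ortholog_pi_set"), species_a != species_b)
  mat <- piset$pi
  for (sp in c(species_a, species_b)) {
    if (!sp %in% colnames(mat)) stop("unknown species: ", sp)
  }
  d <- abs(mat[, species_a] - mat[, species_b])
  d[!is.na(d)]
}

#' The non-parametric pI shift threshold
#'
#' `2 * (Q3 - median)` of the absolute ortholog pI differences between a
#' species pair. The difference distribution follows no standard law, hence
#' the quartile-based spread measure. Quantiles use linear interpolation of
#' order statistics at plotting positions `(k - 1) / (n - 1)` (R type 7), so
#' the statistic is deterministic and order-invariant.
#'
#' @param diffs numeric vector of absolute pI differences; at least 4
#'   values.
#' @return the threshold, in pH units (always >= 0).
#' @examples
#' shift_threshold(c(0.0, 0.1, 0.2, 0.3, 1.0)) # 0.2
#' @export
shift_threshold <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 4L) {
    stop("need at least 4 differences to set a threshold, got ",
         length(diffs))
  }
  if (any(!is.finite(diffs))) stop("differences must be finite")
  q <- stats::quantile(diffs, c(0.5, 0.75), type = 7, names = FALSE)
  2 * (q[2] - q[1])
}

#' Flag families whose pI shift exceeds the threshold
#'
#' A family is flagged iff its absolute difference is strictly greater than
#' the threshold.
#'
#' @param diffs named numeric vector from [pairwise_diffs()].
#' @param threshold nonnegative; defaults to [shift_threshold()] of `diffs`.
#' @param species_pair optional character pair, carried into the result.
#' @return an object of class `shift_result`: list with `species_pair`,
#'   `diffs`, `threshold`, `flagged` (family names) and `perm_pvalue`
#'   (filled by [permutation_pvalue()] callers; `NULL` here).
#' @export
flag_shifters <- function(diffs, threshold = shift_threshold(diffs),
                          species_pair = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  structure(
    list(species_pair = species_pair, diffs = diffs, threshold = threshold,
         flagged = names(diffs)[diffs > threshold], perm_pvalue = NULL),
    class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift_result> %d families, threshold %.3f, %d flagged\n",
              length(x$diffs), x$threshold, length(x$flagged)))
  if (length(x$flagged)) {
    cat("  flagged:", paste(utils::head(x$flagged, 10), collapse = ", "),
        if (length(x$flagged) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Permutation p-value for one family's pI shift
#'
#' Breaks the ortholog pairing by shuffling species-B pI values across
#' families (species A fixed) and recomputing the family's statistic each
#' time. In mode `"protein"` the statistic is the family's absolute
#' difference; in mode `"threshold"` it is the difference minus the shift
#' threshold recomputed from the permuted differences, so the significance
#' of exceeding the (re-estimated) threshold is assessed.
#'
#' When `factorial(n_families) <= n_perm` all permutations are enumerated
#' and the exact tail fraction is returned (the identity permutation makes
#' it positive); otherwise `n_perm` random shuffles are drawn and the
#' add-one estimator `(1 + #{perm >= obs}) / (n_perm + 1)` is used, so the
#' p-value always lies in `[1/(n_perm + 1), 1]`.
#'
#' @param piset an [ortholog_pi_set()].
#' @param species_a,species_b the species pair.
#' @param family family whose shift is tested; must have both species.
#' @param n_perm number of permutations (Monte Carlo mode).
#' @param seed RNG seed; the result is bit-identical for a fixed seed.
#' @param mode `"protein"` or `"threshold"` (see above).
#' @return the p-value.
#' @export
permutation_pvalue <- function(piset, species_a, species_b, family,
                               n_perm = 1000L, seed = 42L,
                               mode = c("protein", "threshold")) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1L)
  mat <- piset$pi
  for (sp in c(species_a, species_b)) {
    if (!sp %in% colnames(mat)) stop("unknown species: ", sp)
  }
  ok <- !is.na(mat[, species_a]) & !is.na(mat[, species_b])
  fams <- rownames(mat)[ok]
  if (!family %in% fams) {
    stop("family '", family, "' lacks a pI in both species")
  }
  a <- mat[ok, species_a]; b <- mat[ok, species_b]
  idx <- match(family, fams)
  n <- length(fams)

  stat <- if (mode == "protein") {
    function(bperm) abs(a[idx] - bperm[idx])
  } else {
    function(bperm) {
      d <- abs(a - bperm)
      d[idx] - shift_threshold(d)
    }
  }
  obs <- stat(b)

  exhaustive <- n <= 10 && factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    vals <- apply(perms, 1L, function(p) stat(b[p]))
    return(mean(vals >= obs))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) stat(sample(b)) >= obs, logical(1)))
  })
  (1 + hits) / (n_perm + 1)
}

#' Discretize a pI into acidic / neutral / basic
#'
#' `acidic` if `pI < low`, `basic` if `pI > high`, `neutral` otherwise
#' (bounds inclusive on the neutral side). Defaults bracket neutrality at
#' 6.8--7.2.
#'
#' @param pi numeric vector of pI values.
#' @param bounds length-2 numeric `(low, high)`, `low < high`.
#' @return character vector in `{"acidic", "neutral", "basic"}`.
#' @export
discretize_pi <- function(pi, bounds = c(6.8, 7.2)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  out <- rep("neutral", length(pi))
  out[pi < bounds[1]] <- "acidic"
  out[pi > bounds[2]] <- "basic"
  out
}

#' Minimum number of discrete pI-category changes on a species tree
#'
#' Small-parsimony count of state changes over an unordered alphabet
#' (Fitch's problem), computed by unit-cost dynamic programming over the
#' tree so the count is exact on multifurcating as well as binary trees.
#'
#' @param tree an \pkg{ape} `phylo` object, or a path to / string of Newick.
#' @param states named character vector, leaf label -> state; every leaf of
#'   the tree must be present.
#' @return the minimum number of state changes (integer).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_shift_count(tr, c(A = "acidic", B = "acidic",
#'                         C = "basic", D = "basic")) # 1
#' @export
fitch_shift_count <- function(tree, states) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("tree has duplicate leaf labels")
  missing <- setdiff(tips, names(states))
  if (length(missing)) {
    stop("no state for leaf/leaves: ", paste(missing, collapse = ", "))
  }
  if (any(is.na(states[tips]))) stop("leaf states must not be NA")
  alphabet <- unique(unname(states[tips]))
  k <- length(alphabet)
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  cost <- matrix(Inf, n_node, k)
  cost[cbind(seq_len(n_tip), match(states[tips], alphabet))] <- 0
  tree <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    # postorder guarantees children are finalized before their parent edge
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    if (all(!is.finite(cost[parent, ]))) cost[parent, ] <- 0
    child_min <- apply(
      outer(seq_len(k), seq_len(k),
            function(i, j) cost[child, j] + (i != j)),
      1L, min)
    cost[parent, ] <- cost[parent, ] + child_min
  }
  root <- tree$edge[nrow(tree$edge), 1]
  as.integer(min(cost[root, ]))
}
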