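#' Whole-network structure metrics for weighted bipartite networks
#'
#' Networks are plants (rows) by frugivorous birds (columns) matrices of
#' interaction frequencies. All metrics expect a "trimmed" matrix: every row
#' and every column carries at least one nonzero cell (as produced by
#' [build_network()]).
#'
#' @name structure_metrics
NULL

check_matrix <- function(M, what = "interaction matrix") {
  if (!is.matrix(M) || !is.numeric(M))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(M) < 1L || ncol(M) < 1L) stop(what, " is empty", call. = FALSE)
  if (any(M < 0)) stop(what, " has negative cells", call. = FALSE)
  invisible(M)
}

#' Connectance of a bipartite network
#'
#' Proportion of realised unique pairwise links relative to all possible
#' links, i.e. the count of nonzero cells divided by the product of the
#' numbers of plants and birds.
#'
#' @param M numeric plants x birds frequency matrix, trimmed.
#' @return a single value in (0, 1].
#' @export
connectance <- function(M) {
  check_matrix(M)
  if (sum(M) == 0) stop("matrix has no interactions", call. = FALSE)
  sum(M > 0) / (nrow(M) * ncol(M))
}

#' Barber modularity of a bipartite partition
#'
#' Weighted Barber Q for a given assignment of rows and columns to modules:
#' Q = sum over modules of (w_m / F - K_m * D_m / F^2), where F is the total
#' matrix weight, w_m the weight inside module m, and K_m, D_m the row and
#' column marginal totals of the module. Modules holding only rows or only
#' columns contribute zero.
#'
#' @param M numeric plants x birds frequency matrix.
#' @param row_labels,col_labels module labels, one per row / per column.
#'   Any atomic label type; equality defines module membership.
#' @return Q, a value in \[-1, 1\].
#' @export
barber_modularity <- function(M, row_labels, col_labels) {
  check_matrix(M)
  if (length(row_labels) != nrow(M) || length(col_labels) != ncol(M))
    stop("labels must cover every row and column", call. = FALSE)
  F_tot <- sum(M)
  if (F_tot == 0) stop("matrix has zero total weight", call. = FALSE)
  rmar <- rowSums(M)
  cmar <- colSums(M)
  mods <- union(unique(row_labels), unique(col_labels))
  Q <- 0
  for (m in mods) {
    rin <- row_labels == m
    cin <- col_labels == m
    if (!any(rin) || !any(cin)) next
    w <- sum(M[rin, cin, drop = FALSE])
    Q <- Q + w / F_tot - sum(rmar[rin]) * sum(cmar[cin]) / F_tot^2
  }
  Q
}

# One LPAwb+ run: alternating row/column label updates. Given the row
# labels, Q is additive over columns, so every column can move to its
# Q-maximising label in one vectorised batch (and vice versa); each half
# sweep is exact coordinate ascent, so Q never decreases. Stops when a full
# sweep changes nothing. Ties go to the lowest label; a node whose best
# score is negative takes a fresh singleton label (score 0).
lpa_wb_plus_run <- function(M, row_labels, max_sweeps = 200L) {
  nr <- nrow(M)
  nc <- ncol(M)
  F_tot <- sum(M)
  rmar <- rowSums(M)
  cmar <- colSums(M)
  col_labels <- rep(NA_integer_, nc)
  next_label <- max(row_labels) + 1L

  batch_update <- function(A, own_mar, side_labels, side_mar) {
    # A: matrix with rows = the side holding fixed labels; returns the new
    # label for each column of A
    labs <- sort(unique(side_labels))
    lf <- factor(side_labels, levels = labs)
    W <- rowsum(A, lf)                    # labels x nodes weight
    K <- as.vector(rowsum(side_mar, lf))  # label marginals
    score <- W / F_tot - outer(K, own_mar) / F_tot^2
    pick <- apply(score, 2L, which.max)   # ties: first = lowest label
    best <- score[cbind(pick, seq_along(pick))]
    new <- labs[pick]
    fresh <- best < 0                     # better off alone
    if (any(fresh)) {
      new[fresh] <- seq.int(next_label, length.out = sum(fresh))
      next_label <<- next_label + sum(fresh)
    }
    new
  }

  converged <- FALSE
  q_prev <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    new_cols <- batch_update(M, cmar, row_labels, rmar)
    new_rows <- batch_update(t(M), rmar, new_cols, cmar)
    changed <- !identical(new_cols, col_labels) ||
      !identical(new_rows, row_labels)
    col_labels <- new_cols
    row_labels <- new_rows
    q <- barber_modularity(M, row_labels, col_labels)
    if (!changed || q <= q_prev + 1e-12) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  list(row_labels = row_labels, col_labels = col_labels,
       Q = barber_modularity(M, row_labels, col_labels),
       converged = converged)
}

#' Maximise Barber modularity by DIRTLPAwb+ label propagation
#'
#' Runs the weighted bipartite label-propagation maximiser (LPAwb+) from an
#' identity initialisation (every row its own module) and, following the
#' DIRTLPAwb+ restart strategy, from repeated random initialisations
#' constrained to k initial modules for every k in `module_sweep`. The
#' partition with the highest Q over all runs is returned; it is never worse
#' than the best single run.
#'
#' @param M numeric plants x birds frequency matrix, trimmed.
#' @param n_restarts random restarts per initial module count.
#' @param module_sweep initial module counts to try; default `2:min(dim(M))`.
#' @param seed optional integer seed for reproducible restarts.
#' @param max_sweeps per-run iteration cap; if a run hits the cap the result
#'   carries `converged = FALSE` with a warning and the best partition so far.
#' @return list with `row_labels`, `col_labels`, `Q`, `converged`.
#' @export
dirt_lpa_wb_plus <- function(M, n_restarts = 20L, module_sweep = NULL,
                             seed = NULL, max_sweeps = 200L) {
  check_matrix(M)
  if (sum(M) == 0) stop("matrix has zero total weight", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(module_sweep)) {
    k_max <- min(nrow(M), ncol(M))
    module_sweep <- if (k_max >= 2L) 2:k_max else integer(0)
  }
  best <- lpa_wb_plus_run(M, seq_len(nrow(M)), max_sweeps)
  for (k in module_sweep) {
    for (r in seq_len(n_restarts)) {
      init <- sample.int(k, nrow(M), replace = TRUE)
      run <- lpa_wb_plus_run(M, init, max_sweeps)
      if (run$Q > best$Q) best <- run
    }
  }
  if (!best$converged)
    warning("label propagation hit the iteration cap; reporting best partition found")
  # relabel modules 1..k for a tidy surface
  labs <- sort(unique(c(best$row_labels, best$col_labels)))
  best$row_labels <- match(best$row_labels, labs)
  best$col_labels <- match(best$col_labels, labs)
  best
}

#' Weighted nestedness (wNODF)
#'
#' Nestedness based on overlap and decreasing fill for weighted matrices, on
#' a 0-100 scale. For an (unordered) pair of columns whose totals differ,
#' with i the heavier and j the lighter column, the pair score is 100 times
#' the fraction of the lighter column's nonzero cells that are both present
#' and strictly exceeded by the heavier column's cell in the same row. Pairs
#' with equal totals score 0 (decreasing fill is strict). Row pairs are
#' scored the same way; wNODF is the mean over all row pairs and column
#' pairs.
#'
#' @param M numeric plants x birds frequency matrix, trimmed, with at least
#'   two rows or two columns.
#' @return a value in \[0, 100\].
#' @export
wnodf <- function(M) {
  check_matrix(M)
  if (nrow(M) == 1L && ncol(M) == 1L)
    stop("wNODF is undefined for a single-row, single-column matrix",
         call. = FALSE)
  pair_scores <- function(A) {
    # columns of A are the entities being compared
    tot <- colSums(A)
    n <- ncol(A)
    if (n < 2L) return(numeric(0))
    out <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        hv <- if (tot[i] > tot[j]) i else if (tot[j] > tot[i]) j else NA_integer_
        if (is.na(hv)) {
          out <- c(out, 0)
          next
        }
        lt <- if (hv == i) j else i
        lo_nz <- A[, lt] > 0
        out <- c(out, 100 * sum(lo_nz & A[, hv] > A[, lt]) / sum(lo_nz))
      }
    }
    out
  }
  scores <- c(pair_scores(M), pair_scores(t(M)))
  mean(scores)
}

#' Normalised degree of one species
#'
#' Number of distinct interaction partners divided by the number of possible
#' partners in the network.
#'
#' @param M numeric plants x birds frequency matrix, trimmed.
#' @param species species label, matched against the dimnames of `M`.
#' @param guild `"plant"` (a row of `M`) or `"bird"` (a column).
#' @return a value in (0, 1].
#' @export
normalized_degree <- function(M, species, guild = c("bird", "plant")) {
  check_matrix(M)
  guild <- match.arg(guild)
  if (guild == "bird") {
    if (!species %in% colnames(M))
      stop("bird '", species, "' absent from network", call. = FALSE)
    sum(M[, species] > 0) / nrow(M)
  } else {
    if (!species %in% rownames(M))
      stop("plant '", species, "' absent from network", call. = FALSE)
    sum(M[species, ] > 0) / ncol(M)
  }
}
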