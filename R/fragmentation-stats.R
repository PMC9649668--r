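#' Island-attribute statistics
#'
#' Multiple regressions of diversity/structure metrics on island area and
#' isolation (log10-transformed predictors; richness-type responses also
#' log10-transformed, whereas connectance, nestedness and robustness stay on
#' their own scale), slope comparison of the species-area and
#' interactions-area relationships, Pearson correlations, an
#' incidence-function family of connectivity indices, and a piecewise
#' structural equation model summarised by Fisher's C.
#'
#' @name fragmentation_stats
NULL

std_coefs <- function(fit, data) {
  b <- stats::coef(fit)[-1L]
  y <- all.vars(stats::formula(fit))[1L]
  sds <- vapply(names(b), function(v) stats::sd(data[[v]]), numeric(1))
  b * sds / stats::sd(data[[y]])
}

#' Regress a network metric on island area and isolation
#'
#' Ordinary least squares on transformed variables: predictors are always
#' log10-transformed; the response is log10-transformed unless it is one of
#' the metrics kept on its natural scale (connectance, nestedness,
#' robustness and any z-score).
#'
#' @param table island-level data frame; mainland rows (`is_mainland`) are
#'   excluded from the fit.
#' @param response column name of the response.
#' @param predictors columns used as predictors (log10-transformed);
#'   default island area and isolation.
#' @param log10_response force the response transform; default follows the
#'   naming rule above.
#' @return list with the `lm` fit, `coefficients` (raw), `std_coefficients`,
#'   `p_values`, `r_squared`, `n`.
#' @export
fit_metric_model <- function(table, response,
                             predictors = c("area_ha", "isolation_m"),
                             log10_response = NULL) {
  if (!is.null(table$is_mainland)) table <- table[!table$is_mainland, ]
  if (nrow(table) < length(predictors) + 3L)
    stop("need at least ", length(predictors) + 3L, " islands", call. = FALSE)
  raw_scale <- grepl("connectance|wnodf|nestedness|robustness|(^|_)z($|_)",
                     response)
  if (is.null(log10_response)) log10_response <- !raw_scale
  d <- data.frame(y = table[[response]])
  if (log10_response) {
    if (any(d$y <= 0)) stop("response must be positive for log10", call. = FALSE)
    d$y <- log10(d$y)
  }
  for (p in predictors) d[[paste0("log10_", p)]] <- log10(table[[p]])
  pv <- paste0("log10_", predictors)
  X <- as.matrix(d[pv])
  kappa_x <- kappa(cbind(1, scale(X)))
  if (kappa_x > 30) warning("predictors nearly collinear (condition number ",
                            round(kappa_x, 1), ")")
  fit <- stats::lm(stats::reformulate(pv, "y"), data = d)
  sm <- summary(fit)
  list(fit = fit, coefficients = stats::coef(fit),
       std_coefficients = std_coefs(fit, d),
       p_values = sm$coefficients[, 4L],
       r_squared = sm$r.squared, n = nrow(d))
}

#' Compare species-area and interactions-area slopes
#'
#' Both relationships are fitted as log10(count) ~ log10(area); the slope
#' difference is tested through a pooled model with an outcome-type
#' interaction term.
#'
#' @param table island data frame with `area_ha`, species richness
#'   `n_species` and unique-link richness `n_links`; islands with a zero
#'   count are dropped with a warning.
#' @return list with `sar_slope`, `iar_slope`, `difference`
#'   (iar - sar), `p_difference`.
#' @export
sar_iar_slopes <- function(table) {
  if (!is.null(table$is_mainland)) table <- table[!table$is_mainland, ]
  bad <- table$n_species <= 0 | table$n_links <= 0
  if (any(bad)) {
    warning(sum(bad), " island(s) with zero counts dropped")
    table <- table[!bad, , drop = FALSE]
  }
  if (nrow(table) < 2L) stop("need at least two islands", call. = FALSE)
  long <- data.frame(
    log_count = log10(c(table$n_species, table$n_links)),
    log_area = rep(log10(table$area_ha), 2L),
    type = rep(c("sar", "iar"), each = nrow(table)))
  long$type <- factor(long$type, levels = c("sar", "iar"))
  fit <- stats::lm(log_count ~ log_area * type, data = long)
  co <- summary(fit)$coefficients
  sar <- co["log_area", 1L]
  iar <- sar + co["log_area:typeiar", 1L]
  list(sar_slope = sar, iar_slope = iar, difference = iar - sar,
       p_difference = co["log_area:typeiar", 4L])
}

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Incidence-function connectivity indices
#'
#' For island i: \eqn{S_i = \sum_{j \ne i} sim_{ij}^w e^{-\alpha d_{ij}}
#' A_j^b}, with d the centroid distance, A the neighbour area, b the area
#' exponent and sim the Bray-Curtis similarity of plant composition. Six
#' variants: with/without the similarity weight (w = 1 or 0) crossed with
#' area exponents 0, 0.5 and 1.
#'
#' @param islands island data frame with `island_id`, `x`, `y`, `area_ha`.
#' @param plant_composition data frame `island_id`, `plant_species`,
#'   `abundance` (needed for the similarity-weighted variants).
#' @param alpha distance-decay rate (1/m); default 1/mean inter-island
#'   distance.
#' @return data frame: `island_id` and columns `conn_a<b>` and
#'   `conn_sim_a<b>` for b in 0, 0.5, 1. A single island gets all zeros.
#' @export
connectivity_indices <- function(islands, plant_composition = NULL,
                                 alpha = NULL) {
  n <- nrow(islands)
  exps <- c(0, 0.5, 1)
  nm <- c(paste0("conn_a", exps), paste0("conn_sim_a", exps))
  out <- data.frame(island_id = islands$island_id)
  if (n < 2L) {
    out[nm] <- 0
    return(out)
  }
  d <- as.matrix(stats::dist(islands[, c("x", "y")]))
  if (is.null(alpha)) alpha <- 1 / mean(d[upper.tri(d)])
  sim <- matrix(1, n, n)
  if (!is.null(plant_composition)) {
    comm <- stats::xtabs(abundance ~ island_id + plant_species,
                         data = plant_composition)
    comm <- matrix(comm, nrow(comm), ncol(comm), dimnames = dimnames(comm))
    comm <- comm[match(islands$island_id, rownames(comm)), , drop = FALSE]
    comm[is.na(comm)] <- 0
    sim <- 1 - as.matrix(vegan::vegdist(comm, method = "bray"))
    sim[is.na(sim)] <- 0
  }
  decay <- exp(-alpha * d)
  diag(decay) <- 0
  for (k in seq_along(exps)) {
    Ab <- islands$area_ha^exps[k]
    out[[paste0("conn_a", exps[k])]] <- as.vector(decay %*% Ab)
    out[[paste0("conn_sim_a", exps[k])]] <- as.vector((decay * sim) %*% Ab)
  }
  out
}

#' Product of standardised coefficients along a directed path
#'
#' The indirect effect of the path's origin on its endpoint.
#'
#' @param path_coefficients standardised coefficients along the path, in
#'   order (length >= 1).
#' @return their product.
#' @export
indirect_effect <- function(path_coefficients) {
  if (length(path_coefficients) == 0L) stop("empty path", call. = FALSE)
  prod(path_coefficients)
}

topo_sort <- function(nodes, edges) {
  order <- character(0)
  left <- nodes
  repeat {
    free <- left[!left %in% order &
                   vapply(left, function(v)
                     all(edges$from[edges$to == v] %in% order), logical(1))]
    if (!length(free)) break
    order <- c(order, free)
    left <- setdiff(left, free)
  }
  if (length(left)) stop("path model is cyclic", call. = FALSE)
  order
}

#' Fit a piecewise structural equation model
#'
#' One linear regression per endogenous node on its parents, on scaled and
#' centred data (so coefficients are standardised). Overall fit is tested by
#' d-separation: for every non-adjacent pair with at least one endogenous
#' member, the claim that they are independent given the union of both
#' parent sets is tested by the p-value of the omitted upstream variable in
#' the downstream node's augmented regression. Fisher's
#' \eqn{C = -2 \sum \ln p_i} is compared to a chi-squared distribution with
#' 2k degrees of freedom (k claims); a large p indicates the DAG is
#' consistent with the data.
#'
#' @param edges data frame with columns `from`, `to` (directed edges).
#' @param data data frame holding every node as a numeric column.
#' @return list of class `"piecewise_sem"`: `coefficients` (data frame
#'   `from`, `to`, `estimate`, `p`, `significant`), `r_squared` per
#'   endogenous node, `claims` (data frame `from`, `to`, `conditioning`,
#'   `p`), `fisher_c`, `df`, `p_value`, `n`.
#' @export
piecewise_sem <- function(edges, data) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  nodes <- unique(c(edges$from, edges$to))
  missing <- setdiff(nodes, names(data))
  if (length(missing))
    stop("data lacks node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  order <- topo_sort(nodes, edges)
  d <- as.data.frame(scale(data[nodes]))
  parents <- function(v) edges$from[edges$to == v]
  endo <- nodes[vapply(nodes, function(v) length(parents(v)) > 0, logical(1))]
  max_par <- max(vapply(endo, function(v) length(parents(v)), integer(1)))
  if (nrow(d) <= max_par + 2L)
    stop("too few observations for the largest equation", call. = FALSE)

  coef_rows <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (v in endo) {
    pa <- parents(v)
    fit <- stats::lm(stats::reformulate(pa, v), data = d)
    sm <- summary(fit)
    r2[v] <- sm$r.squared
    coef_rows[[v]] <- data.frame(from = pa, to = v,
                                 estimate = sm$coefficients[pa, 1L],
                                 p = sm$coefficients[pa, 4L],
                                 stringsAsFactors = FALSE)
  }
  coefs <- do.call(rbind, c(coef_rows, list(make.row.names = FALSE)))
  coefs$significant <- coefs$p < 0.05

  # d-separation basis set
  adjacent <- function(a, b) any((edges$from == a & edges$to == b) |
                                   (edges$from == b & edges$to == a))
  claims <- list()
  pos <- stats::setNames(seq_along(order), order)
  for (i in seq_along(order)) {
    for (j in seq_along(order)) {
      if (i >= j) next
      a <- order[i]; b <- order[j]  # b is downstream
      if (adjacent(a, b)) next
      if (!length(parents(b))) next  # both exogenous: covariance free
      cond <- setdiff(union(parents(a), parents(b)), c(a, b))
      fit <- stats::lm(stats::reformulate(c(cond, a), b), data = d)
      p <- summary(fit)$coefficients[a, 4L]
      claims[[length(claims) + 1L]] <-
        data.frame(from = a, to = b,
                   conditioning = paste(cond, collapse = "+"), p = p,
                   stringsAsFactors = FALSE)
    }
  }
  claims <- if (length(claims)) {
    do.call(rbind, c(claims, list(make.row.names = FALSE)))
  } else {
    data.frame(from = character(0), to = character(0),
               conditioning = character(0), p = numeric(0))
  }
  k <- nrow(claims)
  fisher_c <- if (k) -2 * sum(log(claims$p)) else 0
  df <- 2L * k
  p_value <- if (k) stats::pchisq(fisher_c, df, lower.tail = FALSE) else 1
  structure(list(coefficients = coefs, r_squared = r2, claims = claims,
                 fisher_c = fisher_c, df = df, p_value = p_value,
                 n = nrow(d)),
            class = "piecewise_sem")
}

#' @export
print.piecewise_sem <- function(x, ...) {
  cat("Piecewise SEM:", nrow(x$coefficients), "paths,",
      nrow(x$claims), "independence claims\n")
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.3f\n",
              x$fisher_c, x$df, x$p_value))
  print(x$coefficients, digits = 3)
  invisible(x)
}
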