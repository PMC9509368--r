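## Pan-gene occupancy classification, accumulation curves, exponential
## plateau model, and group frequency-differentiation on presence/absence.

#' Classify orthogroups by occupancy
#'
#' With N genomes and occupancy count k: k = N is core; 0.9 N < k < N is
#' softcore; 2 <= k <= 0.9 N is dispensable; k = 1 is private.
#'
#' @param occ An [OccupancyMatrix] (or a logical matrix).
#' @return List with `class` (factor per orthogroup), `counts` (named
#'   integer vector over the four classes), `percent` (counts / total x
#'   100) and `total`.
#' @export
classifyOrthogroups <- function(occ) {
  p <- if (is(occ, "OccupancyMatrix")) presence(occ) else {
    m <- as.matrix(occ); mode(m) <- "logical"; m
  }
  N <- ncol(p)
  k <- rowSums(p)
  if (any(k == 0)) stop("orthogroups absent from every genome are invalid")
  cls <- ifelse(k == N, "core",
                ifelse(k > 0.9 * N, "softcore",
                       ifelse(k >= 2, "dispensable", "private")))
  cls <- factor(cls, levels = c("core", "softcore", "dispensable", "private"))
  counts <- table(cls)
  counts <- setNames(as.integer(counts), names(counts))
  list(class = cls, counts = counts,
       percent = 100 * counts / nrow(p), total = nrow(p))
}

## Pan/core counts along one genome ordering of a logical matrix.
.curveOneOrder <- function(p, ord) {
  m <- p[, ord, drop = FALSE]
  N <- ncol(m)
  first_present <- max.col(m, ties.method = "first")     # rows all have >=1 TRUE
  pan <- cumsum(tabulate(first_present, N))
  all_true <- rowSums(m) == N
  first_absent <- max.col(!m, ties.method = "first")
  first_absent[all_true] <- N + 1L
  lost_at <- tabulate(first_absent, N + 1L)[seq_len(N)]
  core <- nrow(m) - cumsum(lost_at)
  list(pan = pan, core = core)
}

#' Pan- and core-gene accumulation curves
#'
#' pan(x) is the expected number of orthogroups present in at least one
#' of the first x genomes; core(x) the number present in all x. With
#' random orders the mean over `n_orders` seeded permutations is
#' returned; alternatively a fixed genome order (e.g. phylogeny-guided)
#' can be supplied.
#'
#' @param occ [OccupancyMatrix] or logical matrix (rows = features,
#'   columns = genomes).
#' @param n_orders Number of random permutations (default 100).
#' @param seed Seed for the permutations (recorded in the result).
#' @param order Optional fixed genome order (indices or column names);
#'   overrides the permutations.
#' @return List with `x`, `pan`, `core`, `n_orders`, `seed`.
#' @export
accumulationCurves <- function(occ, n_orders = 100, seed = 1, order = NULL) {
  p <- if (is(occ, "OccupancyMatrix")) presence(occ) else {
    m <- as.matrix(occ); mode(m) <- "logical"; m
  }
  N <- ncol(p)
  if (N < 2) stop("need at least two genomes")
  if (!is.null(order)) {
    if (is.character(order)) order <- match(order, colnames(p))
    if (length(order) != N || anyNA(order) || any(sort(order) != seq_len(N)))
      stop("order must be a permutation of the genomes")
    cv <- .curveOneOrder(p, order)
    return(list(x = seq_len(N), pan = cv$pan, core = cv$core,
                n_orders = 1L, seed = NA_integer_))
  }
  if (n_orders < 1) stop("need a fixed order or at least one permutation")
  pan <- core <- numeric(N)
  set.seed(seed)
  for (i in seq_len(n_orders)) {
    cv <- .curveOneOrder(p, sample.int(N))
    pan <- pan + cv$pan
    core <- core + cv$core
  }
  list(x = seq_len(N), pan = pan / n_orders, core = core / n_orders,
       n_orders = as.integer(n_orders), seed = seed)
}

#' Fit the exponential accumulation model y = A + B exp(C x)
#'
#' Nonlinear least squares via Levenberg-Marquardt. Starting values:
#' A0 = max(y) (saturating pan curve) or min(y) (decaying core curve),
#' C0 from a log-linear regression of log|y - A0| on x, B0 from its
#' intercept; the fit is restarted from five jittered starts and the
#' best residual sum of squares kept.
#'
#' @param x,y Numeric vectors (>= 4 points; y non-constant).
#' @return List of class `accumulation_model` with `A`, `B`, `C`, `rss`,
#'   `fitted` and `converged`.
#' @export
fitExponential <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least four points")
  if (var(y) == 0) stop("constant y: model unidentifiable")
  increasing <- stats::cor(x, y) >= 0
  A0 <- if (increasing) max(y) + 0.05 * diff(range(y)) else
    min(y) - 0.05 * diff(range(y))
  resid0 <- abs(y - A0)
  resid0[resid0 <= 0] <- min(resid0[resid0 > 0]) / 10
  lf <- stats::lm(log(resid0) ~ x)
  C0 <- min(unname(coef(lf)[2]), -1e-6)
  B0 <- exp(unname(coef(lf)[1])) * (if (increasing) -1 else 1)
  starts <- list(c(A0, B0, C0))
  set.seed(20411)
  for (i in 1:5)
    starts[[i + 1]] <- c(A0 * runif(1, 0.9, 1.1), B0 * runif(1, 0.7, 1.3),
                         C0 * runif(1, 0.5, 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A + B * exp(C * x),
                        start = list(A = st[1], B = st[2], C = st[3]),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(A = unname(cf["A"]), B = unname(cf["B"]),
                   C = unname(cf["C"]), rss = rss,
                   fitted = stats::fitted(fit), converged = TRUE)
    }
  }
  if (is.null(best))
    stop("exponential fit failed to converge from all starts")
  structure(best, class = "accumulation_model")
}

#' Plateau size of a fitted accumulation model
#'
#' Smallest integer n >= 1 at which the per-genome increment
#' y(n+1) - y(n) = B e^(C n) (e^C - 1) falls below
#' `epsilon_fraction * A`. Requires a saturating curve (C < 0).
#'
#' @param model An `accumulation_model` (or list with A, B, C).
#' @param epsilon_fraction Increment threshold as a fraction of the
#'   asymptote (default 0.001).
#' @return Integer plateau size.
#' @export
plateauSize <- function(model, epsilon_fraction = 0.001) {
  A <- model$A; B <- model$B; C <- model$C
  if (C >= 0) stop("no plateau: rate parameter C is non-negative")
  thr <- epsilon_fraction * A
  inc1 <- B * exp(C) * (exp(C) - 1)          # increment at n = 1
  if (inc1 < thr) return(1L)
  n <- ceiling(log(thr / (B * (exp(C) - 1))) / C)
  ## guard the integer boundary against floating-point edge effects
  while (n > 1 && B * exp(C * (n - 1)) * (exp(C) - 1) < thr) n <- n - 1
  while (B * exp(C * n) * (exp(C) - 1) >= thr) n <- n + 1
  as.integer(n)
}

#' Orthogroup frequency differentiation between two genome groups
#'
#' Per orthogroup, a 2x2 presence/absence table between the groups is
#' tested with Fisher's exact test; p-values are BH-adjusted across all
#' tested orthogroups. An orthogroup is significant when q < `fdr` and
#' the presence-frequency fold change exceeds `fc`.
#'
#' @param occ An [OccupancyMatrix].
#' @param group_a,group_b Group labels (e.g. "wild", "local"); `group_a`
#'   is the ancestral side of the contrast.
#' @param fdr FDR threshold (default 1e-4).
#' @param fc Fold-change threshold (default 2).
#' @return Data frame, one row per orthogroup: freq_a, freq_b, p_value,
#'   q_value, fold_change, significant, direction (relative to group_b).
#' @export
geneFrequencyDifferentiation <- function(occ, group_a, group_b,
                                         fdr = 1e-4, fc = 2) {
  p <- presence(occ)
  grp <- sampleGroups(occ)
  ia <- grp %in% group_a
  ib <- grp %in% group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("each group needs >= 2 genomes")
  res <- .freqDifferentiation(rowSums(p[, ia, drop = FALSE]), sum(ia),
                              rowSums(p[, ib, drop = FALSE]), sum(ib),
                              fdr = fdr, fc = fc)
  rownames(res) <- rownames(p)
  res
}
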