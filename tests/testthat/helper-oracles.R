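## Independent oracles used across the test suite. These deliberately use
## naive, brute-force formulations so they cannot share bugs with the
## package implementations they check.

## Brute-force sliding-window minimum: mean VO2 over every window
## [t_i, t_i + window) fully inside [from, bound], lowest mean wins.
brute_min_window <- function(t, vo2, from, bound, window) {
  best <- Inf
  for (i in seq_along(t)) {
    if (t[i] < from || t[i] + window > bound + 1e-9) next
    sel <- t >= t[i] & t < t[i] + window - 1e-9
    m <- mean(vo2[sel])
    if (m < best) best <- m
  }
  best
}

## Classical balanced one-way ANOVA (expected-mean-squares) variance
## components and intraclass correlation.
anova_icc <- function(y, g) {
  g <- factor(g)
  k <- length(y) / nlevels(g)
  stopifnot(k == round(k))  # balanced designs only
  gm <- tapply(y, g, mean)
  msb <- k * sum((gm - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - nlevels(g))
  s2u <- max((msb - msw) / k, 0)
  list(sigma2_group = s2u, sigma2_resid = msw, icc = s2u / (s2u + msw))
}

## d-separation test by moralized-ancestral-graph reachability.
## A is an adjacency matrix (A[i, j] = 1 for i -> j); x, y, S are indices.
dsep_oracle <- function(A, x, y, S = integer()) {
  n <- nrow(A)
  nodes <- c(x, y, S)
  repeat {
    pa <- which(rowSums(A[, nodes, drop = FALSE]) > 0)
    new <- setdiff(pa, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  keep <- sort(nodes)
  Ak <- A[keep, keep, drop = FALSE]
  M <- (Ak + t(Ak)) > 0
  for (ch in seq_along(keep)) {
    ps <- which(Ak[, ch] > 0)
    if (length(ps) > 1) M[ps, ps] <- TRUE
  }
  diag(M) <- FALSE
  Si <- match(S, keep)
  if (length(Si)) { M[Si, ] <- FALSE; M[, Si] <- FALSE }
  xi <- match(x, keep); yi <- match(y, keep)
  vis <- rep(FALSE, length(keep)); vis[xi] <- TRUE
  front <- xi
  while (length(front)) {
    nb <- which(apply(M[front, , drop = FALSE], 2, any) & !vis)
    vis[nb] <- TRUE
    front <- nb
  }
  !vis[yi]
}

## Enumerate all labelled DAGs on n nodes as adjacency matrices
## (via all topological orders x all edge subsets, deduplicated).
enumerate_dags <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  ords <- perms(seq_len(n))
  npairs <- n * (n - 1) / 2
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  seen <- new.env(hash = TRUE)
  out <- list()
  for (ord in ords) {
    for (mask in 0:(2^npairs - 1)) {
      A <- matrix(0L, n, n)
      bits <- bitwAnd(bitwShiftR(mask, seq_len(npairs) - 1L), 1L)
      sel <- which(bits == 1L)
      if (length(sel))
        A[cbind(ord[ij[sel, 1]], ord[ij[sel, 2]])] <- 1L
      key <- paste(A, collapse = "")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- A
    }
  }
  out
}

## dag_spec from an adjacency matrix with letter node names.
dag_from_matrix <- function(A, families = NULL) {
  nn <- letters[seq_len(nrow(A))]
  if (is.null(families)) families <- stats::setNames(rep("gaussian", nrow(A)), nn)
  e <- which(A == 1L, arr.ind = TRUE)
  dag_spec(families, data.frame(from = nn[e[, 1]], to = nn[e[, 2]]))
}

## Small Gaussian repeated-measures data set with known structure.
make_grouped_data <- function(n_id = 40, k = 3, beta = 0.5, sd_u = 0.8,
                              sd_e = 1, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(n_id), each = k)
  x <- stats::rnorm(n_id * k)
  y <- beta * x + stats::rnorm(n_id, 0, sd_u)[id] + stats::rnorm(n_id * k, 0, sd_e)
  data.frame(y = y, x = x, id = factor(id),
             prior_tests = rep(seq_len(k) - 1L, n_id))
}

## Generator config with every causal path switched off (pure
## variance-component structure), used for null and ICC-fidelity checks.
null_generator_config <- function(...) {
  generator_config(path_coefficients = c("birth->rmr" = 0),
                   missing_behaviour_prob = 0, missing_mr_prob = 0, ...)
}
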