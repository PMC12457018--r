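## Directed acyclic graph specification and the d-separation basis set for
## piecewise structural equation models.

#' Specify a DAG for piecewise structural equation modelling
#'
#' @param nodes Named character vector mapping node (column) names to a
#'   family, `"gaussian"` or `"binomial"`.
#' @param edges Data frame with columns `from`, `to`: the directed edges.
#' @param correlated_errors Optional data frame with columns `a`, `b`:
#'   unordered pairs whose residual association is modelled as a
#'   correlated error rather than a directed path. Such pairs must not
#'   also be connected by a directed edge, and are excluded from the
#'   independence basis set.
#' @return A `dag_spec`.
#' @export
dag_spec <- function(nodes, edges,
                     correlated_errors = data.frame(a = character(),
                                                    b = character())) {
  stopifnot(is.character(nodes), !is.null(names(nodes)),
            all(nodes %in% c("gaussian", "binomial")),
            all(c("from", "to") %in% names(edges)))
  nn <- names(nodes)
  if (anyDuplicated(nn)) stop("duplicate node names")
  bad <- setdiff(c(edges$from, edges$to, correlated_errors$a,
                   correlated_errors$b), nn)
  if (length(bad)) stop("edge endpoints not among nodes: ",
                        paste(unique(bad), collapse = ", "))
  edges <- unique(edges[c("from", "to")])
  cyc <- .find_cycle(nn, edges)
  if (!is.null(cyc))
    stop("specification is cyclic: ", paste(cyc, collapse = " -> "))
  adj <- paste(edges$from, edges$to)
  for (i in seq_len(nrow(correlated_errors))) {
    a <- correlated_errors$a[i]; b <- correlated_errors$b[i]
    if (paste(a, b) %in% adj || paste(b, a) %in% adj)
      stop("correlated-error pair (", a, ", ", b,
           ") is also connected by a directed edge")
  }
  structure(list(nodes = nodes, edges = edges,
                 correlated_errors = correlated_errors),
            class = "dag_spec")
}

## Returns NULL if acyclic, else a vector of node names forming a cycle.
.find_cycle <- function(nodes, edges) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  kids <- split(edges$to, factor(edges$from, levels = nodes))
  path <- character()
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    if (state[[v]] == 1L) {
      i <- match(v, path)
      cyc <<- c(path[i:length(path)], v)
      return()
    }
    if (state[[v]] == 2L) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in kids[[v]]) visit(w)
    path <<- path[-length(path)]
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  cyc
}

.parents <- function(dag, v) dag$edges$from[dag$edges$to == v]
.children <- function(dag, v) dag$edges$to[dag$edges$from == v]

.ancestors <- function(dag, v) {
  out <- character(); front <- v
  while (length(front)) {
    pa <- unique(unlist(lapply(front, .parents, dag = dag)))
    pa <- setdiff(pa, c(out, v))
    out <- c(out, pa); front <- pa
  }
  out
}

.topo_order <- function(dag) {
  nn <- names(dag$nodes)
  indeg <- stats::setNames(tabulate(match(dag$edges$to, nn), length(nn)), nn)
  out <- character()
  avail <- nn[indeg == 0]
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]; out <- c(out, v)
    for (w in .children(dag, v)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  out
}

.endogenous <- function(dag) unique(dag$edges$to)

#' @export
print.dag_spec <- function(x, ...) {
  cat("<dag_spec> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges, ", nrow(x$correlated_errors),
      " correlated-error pair(s)\n", sep = "")
  for (i in seq_len(nrow(x$edges)))
    cat("  ", x$edges$from[i], " -> ", x$edges$to[i], "\n", sep = "")
  for (i in seq_len(nrow(x$correlated_errors)))
    cat("  ", x$correlated_errors$a[i], " <~> ",
        x$correlated_errors$b[i], "\n", sep = "")
  invisible(x)
}

#' Build the study DAG relating birth date, personality and metabolism
#'
#' Constructs the path-model graph for one metabolic response: birth date
#' drives the three behaviours (with correlated errors among them) and,
#' together with the environmental covariates, body mass and the
#' behaviours, the metabolic response. The `"mr_to_behaviour"` variant
#' inverts the purported causal direction between personality and
#' metabolism (metabolic response at the top tier, behaviours as
#' outcomes).
#'
#' @param response Metabolic response node: `"rmr"`, `"stress_max"` or
#'   `"stress_integral"` (column name in the analysis table).
#' @param direction `"behaviour_to_mr"` (default) or `"mr_to_behaviour"`.
#' @param birth Birth-date column name.
#' @param behaviours Behaviour column names; the first is the binary
#'   entry-probability trait (binomial-logit).
#' @param covariates Exogenous covariate columns entering the metabolic
#'   model (year and age-class codes, temperature, food abundance, body
#'   mass).
#' @return A [dag_spec()].
#' @export
build_dag <- function(response = "rmr",
                      direction = c("behaviour_to_mr", "mr_to_behaviour"),
                      birth = "birth_date_numeric",
                      behaviours = c("entry", "distance", "exploration"),
                      covariates = c("year_code", "age_code", "temperature",
                                     "food", "body_mass")) {
  direction <- match.arg(direction)
  nodes <- stats::setNames(rep("gaussian", 2 + length(behaviours) +
                                 length(covariates)),
                           c(birth, behaviours, response, covariates))
  nodes[behaviours[1]] <- "binomial"
  if (direction == "behaviour_to_mr") {
    edges <- rbind(
      data.frame(from = birth, to = behaviours),
      data.frame(from = c(birth, behaviours, covariates), to = response))
  } else {
    edges <- rbind(
      data.frame(from = c(birth, covariates), to = response),
      data.frame(from = birth, to = rep(behaviours, each = 1)),
      data.frame(from = response, to = behaviours))
  }
  ce <- data.frame(a = behaviours[c(1, 1, 2)], b = behaviours[c(2, 3, 3)])
  dag_spec(nodes, edges, ce)
}

#' Directed-separation basis set of a DAG
#'
#' For every unordered pair of non-adjacent nodes (no directed edge in
#' either direction and no declared correlated error) with at least one
#' endogenous member, emits the independence claim
#' `x _||_ y | parents(x) u parents(y)`. The dependent variable of the
#' claim's test regression is the topologically later node (always an
#' endogenous one), matching the convention of piecewise SEM evaluation.
#' Pairs of two exogenous nodes carry no testable claim (no component
#' model) and are omitted.
#'
#' @param dag A [dag_spec()].
#' @return List of claims, each a list with `x` (independent), `y`
#'   (dependent), `cond` (conditioning set), `family` (of `y`).
#' @export
basis_set <- function(dag) {
  nn <- names(dag$nodes)
  topo <- .topo_order(dag)
  endo <- .endogenous(dag)
  adj <- c(paste(dag$edges$from, dag$edges$to),
           paste(dag$edges$to, dag$edges$from),
           paste(dag$correlated_errors$a, dag$correlated_errors$b),
           paste(dag$correlated_errors$b, dag$correlated_errors$a))
  claims <- list()
  if (length(nn) < 2) return(claims)
  for (i in seq_len(length(nn) - 1)) for (j in (i + 1):length(nn)) {
    a <- nn[i]; b <- nn[j]
    if (paste(a, b) %in% adj) next
    if (!(a %in% endo) && !(b %in% endo)) next
    ## dependent = topologically later of the two (endogenous if only one is)
    y <- if (match(a, topo) > match(b, topo)) a else b
    x <- setdiff(c(a, b), y)
    if (!(y %in% endo)) { tmp <- y; y <- x; x <- tmp }
    cond <- setdiff(union(.parents(dag, x), .parents(dag, y)), c(x, y))
    claims[[length(claims) + 1]] <-
      list(x = x, y = y, cond = cond, family = unname(dag$nodes[y]))
  }
  claims
}
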