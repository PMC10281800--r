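# Directed-acyclic-graph plumbing shared by the simulator and the path
# models: a DAG is an edge tibble (from, to, plus optional metadata) over
# named nodes, some exogenous (covariates) and some endogenous (milestones).

MILESTONE_KINDS <- c("depart_breeding", "complete_sahara_south",
                     "arrive_winter", "depart_winter",
                     "depart_west_africa", "arrive_breeding")

EXOGENOUS_NODES <- c("habitat", "route", "breeding_lat", "breeding_lon",
                     "euro_stopover_lat", "wa_stopover_lon")

#' Declare a path-model DAG
#'
#' @param edges Tibble/data frame with character columns `from` and `to`
#'   (and optionally `beta`, a true standardized coefficient used by the
#'   simulator).
#' @param endogenous Character vector of endogenous node names; these are
#'   the nodes with structural equations. Defaults to the six milestones
#'   present among the edge targets.
#' @param exogenous Character vector of exogenous node names (covariates).
#' @return A `dag_spec` list with elements `edges`, `endogenous`,
#'   `exogenous`, `order` (topological order of endogenous nodes).
#' @export
dag_spec <- function(edges,
                     endogenous = intersect(MILESTONE_KINDS, unique(edges$to)),
                     exogenous = setdiff(unique(edges$from), endogenous)) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (any(!edges$to %in% endogenous)) {
    stop("edge target(s) not declared endogenous: ",
         paste(setdiff(edges$to, endogenous), collapse = ", "))
  }
  ord <- topo_sort(endogenous, edges)
  structure(list(edges = edges, endogenous = endogenous,
                 exogenous = exogenous, order = ord),
            class = "dag_spec")
}

# Topological sort of `nodes` under `edges` restricted to those nodes;
# stops with an explicit cycle report if the graph is cyclic.
topo_sort <- function(nodes, edges) {
  e <- edges[edges$from %in% nodes & edges$to %in% nodes, , drop = FALSE]
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (v in e$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- e$to[e$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < length(nodes)) {
    cyc <- setdiff(nodes, out)
    stop("DAG contains a cycle among: ", paste(cyc, collapse = " -> "))
  }
  out
}

parents_of <- function(dag, node) dag$edges$from[dag$edges$to == node]

#' The default breeding-arrival timing DAG
#'
#' Encodes the structure used throughout: breeding habitat and migration
#' route feed every milestone; breeding coordinates feed departure from and
#' arrival to the breeding grounds; the latitude of the last European
#' pre-Sahara stopover feeds the southbound Sahara crossing; the longitude
#' of the last West African stopover feeds departure from West Africa; each
#' milestone feeds the next milestone and breeding-grounds arrival; and a
#' direct edge links the southbound Sahara crossing to departure from West
#' Africa (the directed-separation-guided revision that replaces the
#' wintering-arrival to West-Africa-departure link).
#'
#' @param betas Optional named numeric vector of true standardized
#'   coefficients, names `"from->to"`; unnamed edges default to the values
#'   below (used by the simulator; ignored by fitting).
#' @param revised If `TRUE` (default) the DAG carries the
#'   directed-separation-guided direct edge from the southbound Sahara
#'   crossing to West-Africa departure; if `FALSE` it carries the initial
#'   wintering-arrival to West-Africa-departure link instead.
#' @return A [dag_spec()].
#' @export
default_timing_dag <- function(betas = NULL, revised = TRUE) {
  m <- MILESTONE_KINDS
  ed <- dplyr::bind_rows(
    tidyr::expand_grid(from = c("habitat", "route"), to = m),
    tibble::tibble(from = c("breeding_lat", "breeding_lon"), to = m[1]),
    tibble::tibble(from = c("breeding_lat", "breeding_lon"), to = m[6]),
    tibble::tibble(from = "euro_stopover_lat", to = m[2]),
    tibble::tibble(from = "wa_stopover_lon", to = m[5]),
    tibble::tibble(from = m[1:5], to = m[2:6]),          # chain
    tibble::tibble(from = m[1:4], to = m[6]),            # direct to arrival
    if (revised) tibble::tibble(from = m[2], to = m[5])  # d-sep revision edge
    else tibble::tibble(from = m[3], to = m[5])          # initial extra link
  ) |>
    dplyr::distinct(.data$from, .data$to)
  default_beta <- c(
    "depart_breeding->complete_sahara_south" = 0.397,   # 15.8% of variation
    "complete_sahara_south->arrive_winter"   = 0.35,
    "arrive_winter->depart_winter"           = 0.30,
    "depart_winter->depart_west_africa"      = 0.10,
    "complete_sahara_south->depart_west_africa" = 0.516, # 26.6%
    "depart_west_africa->arrive_breeding"    = 0.883,   # 78.0%
    "depart_winter->arrive_breeding"         = -0.329,  # 10.8%
    "breeding_lon->depart_breeding"          = 0.653,   # 42.6%
    "euro_stopover_lat->complete_sahara_south" = -0.224, # 5.0%
    "wa_stopover_lon->depart_west_africa"    = 0.274,   # 7.5%
    "habitat->complete_sahara_south"         = 0.15,
    "habitat->depart_winter"                 = 0.15,
    "route->depart_winter"                   = 0.15
  )
  key <- paste0(ed$from, "->", ed$to)
  ed$beta <- unname(default_beta[key])
  ed$beta[is.na(ed$beta)] <- 0
  if (!is.null(betas)) {
    idx <- match(names(betas), key)
    if (anyNA(idx)) stop("unknown edge(s): ",
                         paste(names(betas)[is.na(idx)], collapse = ", "))
    ed$beta[idx] <- unname(betas)
  }
  dag_spec(ed, endogenous = m, exogenous = EXOGENOUS_NODES)
}
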