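## Branched 1-D element mesh: source zone -> (optional shared pathway) ->
## junction -> one or two long-distance pathways -> unloading zones.

#' Build the branched element mesh of a scenario
#'
#' Discretizes the plant into a tree of 1-D elements: a loading (source)
#' zone, an explicit zero-length junction node, one long-distance pathway
#' per sink (per-branch element length = `pathway_length` / pathway element
#' count) and one unloading zone per sink. Reference phloem and xylem
#' volumes are \eqn{N_{Ph} \pi a_{Ph}^2 L} and \eqn{N_X \pi a_X^2 L}; the
#' radial exchange area is the lateral sieve-tube surface
#' \eqn{N_{Ph}\, 2 \pi a_{Ph} L}.
#'
#' The junction appears in the element table as a zero-length bookkeeping
#' node carrying no state; flux edges connect its parent element directly to
#' the first element of each branch, which makes the junction a
#' zero-resistance node (axial resistance between neighbours comes only from
#' their own half-lengths). A finite shared pathway can be requested via
#' `mesh_spec(shared_pathway_length = )`.
#'
#' @param config a [scenario_config].
#' @return An object of class `munch_mesh`: list with
#'   \describe{
#'     \item{elements}{data.frame: `id`, `zone` (`source`, `shared`,
#'       `junction`, `pathway_i`, `sink_i`), `branch` (0 for trunk), `length`
#'       (m), `x` (distance of the element midpoint from the plant base, m),
#'       `vref_ph`, `vref_x` (m^3), `arad` (m^2), `is_state`.}
#'     \item{edges}{data.frame of directed parent -> child flux edges between
#'       state elements, positive flow = away from the source.}
#'   }
#' @examples
#' m <- build_mesh(scenario_config())
#' nrow(m$elements)  # 121 for the default two-sink mesh
#' @export
build_mesh <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ms <- config$mesh
  p <- config$parameters
  n_sinks <- length(config$sinks)
  if (!n_sinks %in% c(1L, 2L)) stop("build_mesh: need one or two sinks")

  a_ph <- p$N_Ph * pi * p$a_Ph^2
  a_x <- p$N_X * pi * p$a_X^2

  zone <- character(0); branch <- integer(0); len <- numeric(0)
  add_zone <- function(z, b, lengths) {
    zone <<- c(zone, rep(z, length(lengths)))
    branch <<- c(branch, rep(b, length(lengths)))
    len <<- c(len, lengths)
  }
  add_zone("source", 0L, rep(ms$source_element_length, ms$n_source))
  if (ms$shared_pathway_length > 0)
    add_zone("shared", 0L, rep(ms$shared_pathway_length / ms$n_shared, ms$n_shared))
  junction_at <- length(len) + 1L
  add_zone("junction", 0L, 0)
  for (i in seq_len(n_sinks)) {
    L <- config$sinks[[i]]$pathway_length
    if (L <= 0) stop("build_mesh: pathway_length must be positive")
    add_zone(paste0("pathway_", i), i, rep(L / ms$n_pathway, ms$n_pathway))
    add_zone(paste0("sink_", i), i, rep(ms$sink_element_length, ms$n_sink))
  }

  n <- length(len)
  is_state <- zone != "junction"
  ## midpoint position along the branch chain, measured from the plant base
  trunk_len <- sum(len[branch == 0L])
  x <- numeric(n)
  off <- 0
  for (b in 0L:n_sinks) {
    sel <- which(branch == b)
    start <- if (b == 0L) 0 else trunk_len
    x[sel] <- start + cumsum(len[sel]) - len[sel] / 2
  }

  elements <- data.frame(id = seq_len(n), zone = zone, branch = branch,
                         length = len, x = x,
                         axial_area_ph = ifelse(is_state, a_ph, 0),
                         axial_area_x = ifelse(is_state, a_x, 0),
                         vref_ph = a_ph * len, vref_x = a_x * len,
                         arad = p$N_Ph * 2 * pi * p$a_Ph * len,
                         is_state = is_state)

  ## edges between state elements (junction bypassed)
  chain_edges <- function(ids) if (length(ids) >= 2) cbind(ids[-length(ids)], ids[-1]) else NULL
  trunk_ids <- which(branch == 0L & is_state)
  edges <- chain_edges(trunk_ids)
  for (i in seq_len(n_sinks)) {
    br_ids <- which(branch == i)
    edges <- rbind(edges, cbind(tail(trunk_ids, 1), br_ids[1]), chain_edges(br_ids))
  }
  edges <- data.frame(parent = edges[, 1], child = edges[, 2])
  edges$lbar <- (elements$length[edges$parent] + elements$length[edges$child]) / 2

  for (i in seq_len(n_sinks)) {
    s <- sum(elements$length[elements$zone == paste0("pathway_", i)])
    if (abs(s - config$sinks[[i]]$pathway_length) > 1e-12 * config$sinks[[i]]$pathway_length)
      stop("build_mesh: pathway element lengths do not sum to pathway_length")
  }

  structure(list(elements = elements, edges = edges, n_sinks = n_sinks,
                 junction_id = junction_at),
            class = "munch_mesh")
}

#' @export
print.munch_mesh <- function(x, ...) {
  tab <- table(x$elements$zone)
  cat(sprintf("Branched mesh: %d elements (%d carrying state), %d edges\n",
              nrow(x$elements), sum(x$elements$is_state), nrow(x$edges)))
  for (z in names(tab))
    cat(sprintf("  %-10s %3d elements, %g m\n", z, tab[[z]],
                sum(x$elements$length[x$elements$zone == z])))
  invisible(x)
}
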