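# Binarization of FC matrices and the six graph indicators, static and
# per-window dynamic. Indicator computations run on igraph; conventions:
# unreachable pairs contribute 0 to efficiency, nodes of degree < 2
# contribute 0 to the mean clustering coefficient and local efficiency,
# community structure for modularity comes from greedy agglomerative
# modularity maximization, and assortativity is missing (NA) when undefined.

#' Binarize a connectivity matrix into a network
#'
#' \code{mode = "density"} keeps the top \code{floor(value * N(N-1)/2)}
#' upper-triangle edges by correlation value, ties at the cutoff broken by
#' (smaller i, smaller j) lexicographic edge order so the edge count is
#' exact; by default negative correlations are never made edges, so the
#' realized count can be smaller when positive entries run out
#' (\code{positiveOnly = FALSE} disables the floor). \code{mode =
#' "absolute"} keeps edges with r strictly greater than \code{value}.
#'
#' @param fc N x N symmetric matrix with unit diagonal.
#' @param mode \code{"density"} or \code{"absolute"}.
#' @param value density in (0, 1] or absolute threshold in (-1, 1).
#' @param positiveOnly density mode only: exclude negative correlations from
#'   the ranking (default TRUE).
#' @return list of class \code{BinaryNetwork}: \code{adjacency} (0/1
#'   symmetric, zero diagonal), \code{threshold_rule}, \code{n_edges}.
#' @export
binarizeFC <- function(fc, mode = c("density", "absolute"), value = 0.15,
                       positiveOnly = TRUE) {
  mode <- match.arg(mode)
  n <- nrow(fc)
  adj <- matrix(0L, n, n, dimnames = dimnames(fc))
  ut <- which(upper.tri(fc), arr.ind = TRUE)
  r <- fc[ut]
  if (mode == "density") {
    stopifnot(value > 0)
    m <- length(r)
    want <- floor(value * m)
    if (want > m) {
      warning("density requests more edges than pairs; clamping to complete graph")
      want <- m
    }
    ord <- order(-r, ut[, 1], ut[, 2])  # by r desc, ties lexicographic
    keep <- ord[seq_len(want)]
    if (positiveOnly) keep <- keep[r[keep] > 0]
  } else {
    stopifnot(value > -1, value <= 1)
    keep <- which(r > value)
  }
  if (length(keep)) {
    sel <- ut[keep, , drop = FALSE]
    adj[sel] <- 1L
    adj[sel[, c(2, 1), drop = FALSE]] <- 1L
  }
  structure(list(adjacency = adj,
                 threshold_rule = list(mode = mode, value = value,
                                       positive_only = positiveOnly),
                 n_edges = length(keep)),
            class = "BinaryNetwork")
}

asIgraph <- function(net) {
  adj <- if (inherits(net, "BinaryNetwork")) net$adjacency else net
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' The six graph indicators of a binary network
#'
#' Mean nodal clustering coefficient (triangle definition; isolated and
#' degree-1 nodes contribute 0), maximum k-core number, modularity Q of a
#' greedy agglomerative modularity-maximizing partition (NA for an edgeless
#' graph), degree assortativity (NA when undefined, e.g. all degrees
#' equal), global efficiency (mean inverse shortest-path length over
#' ordered pairs, unreachable pairs contributing 0) and local efficiency
#' (mean over nodes of the global efficiency of the node's open
#' neighborhood subgraph).
#'
#' @param net a \code{BinaryNetwork} from \code{\link{binarizeFC}}, or a 0/1
#'   symmetric adjacency matrix.
#' @return one-row data.frame: \code{k_core}, \code{clustering_coefficient},
#'   \code{modularity}, \code{assortativity}, \code{global_efficiency},
#'   \code{local_efficiency}.
#' @examples
#' k3 <- matrix(1, 3, 3) - diag(3)
#' graphIndicators(k3)
#' @export
graphIndicators <- function(net) {
  g <- asIgraph(net)
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes")
  cc <- mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  kcore <- max(igraph::coreness(g))
  q <- if (igraph::ecount(g) == 0L) NA_real_ else
    igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g)))
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (!is.finite(assort)) assort <- NA_real_
  geff <- if (igraph::ecount(g) == 0L) 0 else igraph::global_efficiency(g)
  # local efficiency of a node = global efficiency of the subgraph induced
  # by its open neighborhood (paths may not leave the neighborhood; nodes of
  # degree < 2 contribute 0)
  leff <- mean(vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0L) 0 else igraph::global_efficiency(sub)
  }, numeric(1)))
  data.frame(k_core = as.integer(kcore), clustering_coefficient = cc,
             modularity = q, assortativity = assort,
             global_efficiency = geff, local_efficiency = leff)
}

#' Per-window dynamic graph indicators of a dFC series
#'
#' Binarizes every window of a dFC series with one threshold rule and
#' computes the six indicators per window, preserving window order; this is
#' the multilayer (one network layer per window) view of the run.
#'
#' @param dfc a \linkS4class{DfcSeries}.
#' @param mode,value,positiveOnly threshold rule, as in
#'   \code{\link{binarizeFC}}.
#' @return data.frame with one row per window: provenance columns
#'   (\code{participant_id}, \code{session}, \code{run_id},
#'   \code{window_index}, \code{start_tr}) followed by the six indicators.
#' @export
dynamicIndicators <- function(dfc, mode = c("density", "absolute"),
                              value = 0.15, positiveOnly = TRUE) {
  mode <- match.arg(mode)
  w <- nWindows(dfc)
  rows <- vector("list", w)
  for (i in seq_len(w)) {
    ind <- tryCatch(
      graphIndicators(binarizeFC(dfc@mats[, , i], mode = mode, value = value,
                                 positiveOnly = positiveOnly)),
      error = function(e) stop("window ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    rows[[i]] <- cbind(data.frame(participant_id = dfc@participantId,
                                  session = dfc@session, run_id = dfc@runId,
                                  window_index = i,
                                  start_tr = dfc@startsTr[i],
                                  stringsAsFactors = FALSE),
                       ind)
  }
  do.call(rbind, rows)
}
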