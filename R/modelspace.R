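# The 15-model space: 3 connectivity families x 5 modulation schemes over
# six nodes (bilateral temporal, frontal, parietal).
#
# Edge-type convention (hierarchical): ascending intrahemispheric edges
# temporal->frontal, temporal->parietal and parietal->frontal are "forward";
# their reciprocals are "backward"; interhemispheric homologous edges are
# "lateral" (symmetric). Mask entry [i, j] = connection from node j to i.

.node_idx <- function(region, hemi) {
  which(.NODES$region == region & .NODES$hemisphere == hemi)
}

# Directed edge lists per family. Ascending = forward.
.family_edges <- function(family) {
  fw <- list(); lat <- list()
  for (h in c("L", "R")) {
    tn <- .node_idx("temporal", h); fn <- .node_idx("frontal", h)
    pn <- .node_idx("parietal", h)
    fw <- c(fw, list(c(tn, fn), c(tn, pn)))          # T->F, T->P
    if (family == "full") fw <- c(fw, list(c(pn, fn)))  # P->F
  }
  if (family %in% c("full", "partial")) {
    for (reg in c("temporal", "frontal", "parietal")) {
      l <- .node_idx(reg, "L"); r <- .node_idx(reg, "R")
      lat <- c(lat, list(c(l, r), c(r, l)))
    }
  }
  list(forward = fw, lateral = lat)
}

.edges_to_mask <- function(edges) {
  m <- matrix(FALSE, .N_NODES, .N_NODES,
              dimnames = list(nodeNames(), nodeNames()))
  for (e in edges) m[e[2], e[1]] <- TRUE   # from e[1] to e[2]
  m
}

.scheme_mask <- function(scheme, fwd, bwd, lat) {
  edges <- fwd | bwd | lat
  reg <- .NODES$region
  pairsel <- function(a, b) {
    m <- matrix(FALSE, .N_NODES, .N_NODES)
    m[reg == a, reg == b] <- TRUE
    m[reg == b, reg == a] <- TRUE
    m
  }
  switch(scheme,
    all = edges,
    anterior = edges & pairsel("temporal", "frontal"),
    posterior = edges & pairsel("temporal", "parietal"),
    forward = fwd,
    backward = bwd,
    stop("unknown scheme ", scheme))
}

.make_model <- function(id, family, scheme) {
  fe <- .family_edges(family)
  fwd <- .edges_to_mask(fe$forward)
  bwd <- t(fwd)                       # each forward edge has its reciprocal
  lat <- .edges_to_mask(fe$lateral)
  mod <- .scheme_mask(scheme, fwd, bwd, lat)
  new("NetworkModel", id = as.integer(id), family = family, scheme = scheme,
      forwardMask = fwd, backwardMask = bwd, lateralMask = lat,
      modulationMask = mod,
      inputNodes = c(.node_idx("temporal", "L"), .node_idx("temporal", "R")),
      intrinsicNodes = c(.node_idx("temporal", "L"), .node_idx("temporal", "R")))
}

#' Build the 15-model connectivity space
#'
#' Three families of extrinsic connectivity over the six nodes:
#' \describe{
#'   \item{full}{intrahemispheric temporal-frontal, temporal-parietal and
#'     frontal-parietal edges plus interhemispheric homologous edges;}
#'   \item{partial}{full minus the intrahemispheric frontal-parietal edges;}
#'   \item{sparse}{intrahemispheric temporal-frontal and temporal-parietal
#'     only, no interhemispheric edges.}
#' }
#' Each family contains five models whose deviant-vs-standard modulation
#' applies to all extrinsic edges, only anterior (frontal-temporal), only
#' posterior (temporal-parietal), only forward, or only backward edges.
#' All models drive left and right auditory (temporal) cortex and modulate
#' the intrinsic gain of the two temporal nodes. Model ids are 1..15,
#' families ordered full, partial, sparse; schemes ordered all, anterior,
#' posterior, forward, backward.
#'
#' @return A \linkS4class{ModelSpace} of 15 models.
#' @examples
#' space <- buildModelSpace()
#' table(familyPartition(space))
#' @export
buildModelSpace <- function() {
  fams <- c("full", "partial", "sparse")
  schemes <- c("all", "anterior", "posterior", "forward", "backward")
  id <- 0L
  ms <- list()
  for (f in fams) for (s in schemes) {
    id <- id + 1L
    ms[[id]] <- .make_model(id, f, s)
  }
  new("ModelSpace", models = ms)
}

#' Find a model by family and modulation scheme
#' @param space a \linkS4class{ModelSpace}.
#' @param family,scheme labels as in \code{\link{buildModelSpace}}.
#' @return The matching \linkS4class{NetworkModel}.
#' @export
findModel <- function(space, family, scheme) {
  for (m in models(space))
    if (m@family == family && m@scheme == scheme) return(m)
  stop("no model with family ", family, " and scheme ", scheme)
}

#' Validate a network model (report-only)
#'
#' Checks the structural invariants a well-formed model must satisfy:
#' modulation restricted to existing edges, hierarchical reciprocity of
#' forward/backward edges, symmetric lateral edges, and the presence of
#' auditory input nodes. Violations are reported, never raised.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @return A character vector of violations (empty when valid).
#' @export
validateModel <- function(model) {
  v <- character(0)
  edges <- model@forwardMask | model@backwardMask | model@lateralMask
  if (any(model@modulationMask & !edges))
    v <- c(v, "modulation on an edge absent from the model")
  if (!identical(model@backwardMask, t(model@forwardMask)))
    v <- c(v, "forward/backward edges are not reciprocal pairs")
  if (!identical(model@lateralMask, t(model@lateralMask)))
    v <- c(v, "lateral edges are not symmetric")
  tn <- .node_idx("temporal", "L")
  if (!all(c(tn, .node_idx("temporal", "R")) %in% model@inputNodes))
    v <- c(v, "driving input must target left and right auditory cortex")
  v
}

#' Export a model space as JSON for audit
#'
#' One record per model: id, family, scheme, directed edge list with types,
#' and the modulated edge list.
#'
#' @param space a \linkS4class{ModelSpace}.
#' @param path output file.
#' @export
exportModelSpace <- function(space, path) {
  nn <- nodeNames()
  edge_df <- function(mask, type) {
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w) == 0) return(NULL)
    data.frame(from = nn[w[, 2]], to = nn[w[, 1]], type = type,
               stringsAsFactors = FALSE)
  }
  recs <- lapply(models(space), function(m) {
    ed <- rbind(edge_df(m@forwardMask, "forward"),
                edge_df(m@backwardMask, "backward"),
                edge_df(m@lateralMask, "lateral"))
    list(id = m@id, family = m@family, scheme = m@scheme,
         edges = ed, modulated = edge_df(m@modulationMask, "modulated"),
         input_nodes = nn[m@inputNodes])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}
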