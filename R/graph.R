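## Grid neighborhood graphs. Sites are the unmasked grid cells, numbered
## 1..nSites in the grid's column-major (R linear-index) raster order; that
## order is also the fixed Gibbs sweep order.

#' Build the neighborhood graph of a pixel grid
#'
#' 4- or 8-connectivity over the unmasked cells, unit edge weights,
#' symmetric, no self-loops. Edges to masked-out cells are dropped.
#'
#' @param dims grid dimensions (rows, cols).
#' @param connectivity 4 or 8.
#' @param mask optional logical matrix; \code{FALSE} cells carry no site.
#' @return a \linkS4class{NeighborhoodGraph}.
#' @export
gridGraph <- function(dims, connectivity = 4L, mask = NULL) {
  dims <- as.integer(dims)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8")
  nr <- dims[1]; nc <- dims[2]
  keep <- if (is.null(mask)) rep(TRUE, nr * nc) else as.vector(mask)
  m <- sum(keep)
  siteIndex <- rep(NA_integer_, nr * nc)
  siteIndex[keep] <- seq_len(m)
  dim(siteIndex) <- c(nr, nc)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  rows <- row(siteIndex); cols <- col(siteIndex)
  from <- integer(); to <- integer()
  for (o in offs) {
    rr <- rows + o[1]; cc <- cols + o[2]
    ok <- !is.na(siteIndex) & rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    idx <- which(ok)
    nb <- siteIndex[cbind(rr[idx], cc[idx])]
    has <- !is.na(nb)
    from <- c(from, siteIndex[idx][has])
    to <- c(to, nb[has])
  }
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]
  offsets <- c(0L, cumsum(tabulate(from, nbins = m)))
  new("NeighborhoodGraph", nSites = as.integer(m),
      offsets = as.integer(offsets), nbr = as.integer(to),
      w = rep(1, length(to)), dims = dims, siteIndex = siteIndex)
}

#' Neighbors of one site
#'
#' @param graph a \linkS4class{NeighborhoodGraph}.
#' @param site 1-based site index.
#' @return list with elements \code{nbr} (site indices) and \code{w}
#'   (edge weights).
#' @export
neighborsOf <- function(graph, site) {
  if (site < 1L || site > graph@nSites)
    stop("site outside the graph")
  sel <- seq.int(graph@offsets[site] + 1L, length.out =
                   graph@offsets[site + 1L] - graph@offsets[site])
  list(nbr = graph@nbr[sel], w = graph@w[sel])
}
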