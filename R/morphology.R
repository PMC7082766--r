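# Binary morphology and component labelling on 2-D matrices and 3-D arrays.
# Connectivity conventions: 26 (3-D) / 8 (2-D) for foreground components,
# 6 / 4 for background when filling holes.

# Shift a logical array so that out[i] = a[i + d], padding with `fill`.
shift_array <- function(a, d, fill = FALSE) {
  dm <- dim(a)
  nd <- length(dm)
  out <- array(fill, dim = dm)
  src <- vector("list", nd); dst <- vector("list", nd)
  for (k in seq_len(nd)) {
    dk <- if (k <= length(d)) d[k] else 0L
    if (dk >= 0) {
      if (dk >= dm[k]) return(out)
      src[[k]] <- (1L + dk):dm[k]; dst[[k]] <- 1L:(dm[k] - dk)
    } else {
      if (-dk >= dm[k]) return(out)
      src[[k]] <- 1L:(dm[k] + dk); dst[[k]] <- (1L - dk):dm[k]
    }
  }
  if (nd == 3) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  } else {
    out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  }
  out
}

# Structuring-element offsets: Chebyshev ball of radius r. in_plane = TRUE
# keeps the element within a slice (2-D disc applied slice-wise in 3-D).
se_offsets <- function(r, nd = 3, in_plane = FALSE) {
  s <- -r:r
  if (nd == 2) {
    g <- expand.grid(dr = s, dc = s)
  } else {
    g <- expand.grid(dr = s, dc = s, ds = if (in_plane) 0L else s)
  }
  as.matrix(g[rowSums(abs(g)) > 0 | TRUE, , drop = FALSE])
}

binary_dilate <- function(a, r = 1, in_plane = FALSE) {
  off <- se_offsets(r, nd = length(dim(a)), in_plane = in_plane)
  out <- a
  for (i in seq_len(nrow(off))) out <- out | shift_array(a, off[i, ])
  out
}

binary_erode <- function(a, r = 1, in_plane = FALSE) {
  off <- se_offsets(r, nd = length(dim(a)), in_plane = in_plane)
  out <- a
  for (i in seq_len(nrow(off))) out <- out & shift_array(a, off[i, ], fill = FALSE)
  out
}

binary_close <- function(a, r = 1, in_plane = FALSE) {
  binary_erode(binary_dilate(a, r, in_plane), r, in_plane)
}

# Neighbour offsets for a connectivity convention.
connectivity_offsets <- function(connectivity) {
  switch(as.character(connectivity),
    "4"  = rbind(c(1, 0), c(0, 1)),
    "8"  = rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)),
    "6"  = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "26" = {
      g <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
      g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
      # keep one of each +/- pair (half-space)
      keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
      g[keep, , drop = FALSE]
    },
    stop("unsupported connectivity: ", connectivity))
}

#' Label connected components of a binary image or volume
#'
#' Components are found over an explicit pixel/voxel adjacency graph
#' (8-connectivity in 2-D, 26-connectivity in 3-D by default; 4/6 available
#' for background topology), using graph connected components.
#'
#' @param mask Logical matrix or 3-D array.
#' @param connectivity One of 4, 8 (2-D) or 6, 26 (3-D).
#' @return Integer array of the same shape: 0 for background, 1..n component
#'   labels (label order is arbitrary but deterministic).
#' @export
label_components <- function(mask,
                             connectivity = if (length(dim(mask)) == 2) 8 else 26) {
  mask <- if (is.logical(mask)) mask else array(as.logical(mask), dim = dim(mask))
  idx <- which(mask)
  lab <- array(0L, dim = dim(mask))
  if (length(idx) == 0) return(lab)
  id <- array(0L, dim = dim(mask))
  id[idx] <- seq_along(idx)
  off <- connectivity_offsets(connectivity)
  edges <- vector("list", nrow(off))
  for (i in seq_len(nrow(off))) {
    nb_mask <- shift_array(mask, off[i, ])
    both <- which(mask & nb_mask)
    if (length(both)) {
      nb_id <- shift_array(id, off[i, ], fill = 0L)
      edges[[i]] <- cbind(id[both], nb_id[both])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Fill fully enclosed holes: background components (face connectivity) that
# do not touch the array border become foreground.
fill_holes <- function(mask) {
  nd <- length(dim(mask))
  bg <- !mask
  lab <- label_components(bg, connectivity = if (nd == 2) 4 else 6)
  dm <- dim(mask)
  border <- array(FALSE, dim = dm)
  if (nd == 2) {
    border[c(1, dm[1]), ] <- TRUE; border[, c(1, dm[2])] <- TRUE
  } else {
    border[c(1, dm[1]), , ] <- TRUE; border[, c(1, dm[2]), ] <- TRUE
    border[, , c(1, dm[3])] <- TRUE
  }
  outside <- unique(lab[border & bg])
  holes <- bg & !(lab %in% outside)
  mask | holes
}

# Zhang-Suen topology-preserving thinning of a 2-D binary image.
# Returns the 1-px-wide skeleton (medial axis approximation).
thin_zhang_suen <- function(m) {
  stopifnot(is.matrix(m))
  m <- matrix(as.logical(m), nrow = nrow(m))
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(offs, function(d) shift_array(m, d))
      B <- Reduce(`+`, P)
      ring <- c(P, P[1])
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!ring[[i]] & ring[[i + 1]])
      if (step == 1) {
        c1 <- !(P[[1]] & P[[3]] & P[[5]])  # P2*P4*P6 == 0
        c2 <- !(P[[3]] & P[[5]] & P[[7]])  # P4*P6*P8 == 0
      } else {
        c1 <- !(P[[1]] & P[[3]] & P[[7]])  # P2*P4*P8 == 0
        c2 <- !(P[[1]] & P[[5]] & P[[7]])  # P2*P6*P8 == 0
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Path length of a skeleton: sum of inter-pixel steps, 1 per axial
# adjacency, sqrt(2) per diagonal adjacency (each adjacent pair once), plus
# one pixel for the two end half-pixels (pixel centers to object extent), so
# a straight n-pixel skeleton measures n pixels. A single-pixel skeleton has
# zero length.
skeleton_length_px <- function(skel) {
  ax <- sum(skel & shift_array(skel, c(0, 1))) +
        sum(skel & shift_array(skel, c(1, 0)))
  dg <- sum(skel & shift_array(skel, c(1, 1))) +
        sum(skel & shift_array(skel, c(1, -1)))
  steps <- ax + sqrt(2) * dg
  if (steps == 0) 0 else steps + 1
}
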