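# Low-level binary-mask utilities shared by segmentation and the phantom
# generator. Masks are logical matrices in the image frame (row-major,
# 0-based externally, 1-based internally).

# 4-connected flood fill over `open` starting from linear indices `seeds`.
# Returns the reached region as a logical matrix. Vectorised frontier BFS:
# each pass expands one ring, so the loop runs O(grid diameter) times.
flood_fill4 <- function(open, seeds) {
  nr <- nrow(open); nc <- ncol(open)
  seeds <- seeds[open[seeds]]
  visited <- matrix(FALSE, nr, nc)
  if (length(seeds) == 0L) return(visited)
  visited[seeds] <- TRUE
  frontier <- unique(seeds)
  while (length(frontier) > 0L) {
    r <- ((frontier - 1L) %% nr) + 1L
    cands <- c(frontier[r > 1L] - 1L,
               frontier[r < nr] + 1L,
               frontier[frontier > nr] - nr,
               frontier[frontier <= (nc - 1L) * nr] + nr)
    cands <- cands[open[cands] & !visited[cands]]
    frontier <- unique(cands)
    visited[frontier] <- TRUE
  }
  visited
}

border_indices <- function(nr, nc) {
  unique(c(seq_len(nr),                       # first column
           (nc - 1L) * nr + seq_len(nr),      # last column
           (seq_len(nc) - 1L) * nr + 1L,      # first row
           (seq_len(nc) - 1L) * nr + nr))     # last row
}

# Connected-component labelling. EBImage::bwlabel is 4-connected; for the
# 8-connected variant labels touching diagonally are merged with union-find.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), find, integer(1))
      relab <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
  }
  lab
}

touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

# Pixels enclosed by `mask`: not in the mask and not 4-reachable from the
# grid border. Empty when the mask does not close a region.
enclosed_interior <- function(mask) {
  open <- !mask
  outside <- flood_fill4(open, border_indices(nrow(mask), ncol(mask)))
  open & !outside
}

mask_centroid <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  c(mean(((idx - 1L) %% nr) + 1L), mean(((idx - 1L) %/% nr) + 1L))
}

dilate3 <- function(mask) {
  k <- EBImage::makeBrush(3, shape = "box")
  EBImage::dilate(mask * 1, k) > 0
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b Logical matrices of equal dimension.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}
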