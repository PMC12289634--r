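# Connected-component labeling on binary matrices.
#
# EBImage::bwlabel is 4-connected; 8-connectivity is obtained by merging
# 4-labels that touch diagonally, via a small union-find over label ids.

label_components <- function(bin, connectivity = 8) {
  stopifnot(is.matrix(bin), connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  nl <- max(lab)
  if (connectivity == 4 || nl <= 1) return(lab)

  H <- nrow(lab); W <- ncol(lab)
  # diagonal neighbor pairs: (r,c)-(r+1,c+1) and (r+1,c)-(r,c+1)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -W]; b2 <- lab[-H, -1]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                        cbind(a2[keep2], b2[keep2])))
  if (nrow(pairs) == 0) return(lab)

  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  compact <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

# id (and area) of the largest component; ties go to the lowest label
component_areas <- function(lab) tabulate(lab[lab > 0L], nbins = max(lab, 1L))

# binary morphological opening-then-closing with a disc brush
open_close <- function(bin, radius) {
  if (radius < 1) return(bin)
  side <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(side, shape = "disc")
  x <- matrix(as.numeric(bin), nrow(bin), ncol(bin))
  y <- EBImage::closing(EBImage::opening(x, brush), brush)
  matrix(as.numeric(y) > 0.5, nrow(bin), ncol(bin))
}
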