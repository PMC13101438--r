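# Instance separation of annular fibers and segmentation evaluation.

#' Label connected components of a binary matrix
#'
#' 8-connectivity by default (diagonal neighbors connect, which keeps thin
#' diagonal lumens intact). Components are numbered 1..k in order of their
#' smallest column-major pixel index, so labeling is deterministic across
#' runs and platforms.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8) {
  if (!is.matrix(binary)) stopf("binary must be a matrix")
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  h <- nrow(binary); w <- ncol(binary)
  fg <- which(binary != 0)
  out <- matrix(0L, h, w)
  if (length(fg) == 0) return(out)
  pos <- integer(h * w)
  pos[fg] <- seq_along(fg)
  r <- (fg - 1L) %% h + 1L
  cc <- (fg - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0)
  for (o in offs) {
    nr <- r + o[1]; nc <- cc + o[2]
    valid <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[valid] - 1L) * h + nr[valid]
    hit <- pos[nidx] > 0L
    from <- c(from, pos[fg[valid]][hit])
    to <- c(to, pos[nidx][hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  first_idx <- tapply(fg, memb, min)
  relabel <- integer(length(first_idx))
  relabel[order(first_idx)] <- seq_along(first_idx)
  out[fg] <- relabel[memb]
  out
}

# Shift a matrix by (dr, dc), filling exposed border with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Classical myelin-first segmentation of a CARS image
#'
#' A deterministic classical surrogate for a trained segmentation model,
#' following the myelin-first convention: bright pixels above a threshold
#' (Otsu by default) are myelin candidates, optionally cleaned by
#' morphological opening and closing with a disc whose radius is given in um
#' (off by default: myelin sheaths are often only 2-4 px thick and do not
#' survive even a 1-px opening, while isolated bright speckle is already
#' removed by the hole rule); the axon class is obtained by filling the
#' interior holes of each myelin component; bright components with no
#' interior hole (solid blobs such as two-photon artifact spots) are
#' suppressed.
#'
#' @param image Integer matrix, 0-255.
#' @param pixel_size Pixel pitch, um per pixel.
#' @param threshold `"otsu"` for automatic histogram thresholding, or a fixed
#'   numeric cutoff on the 0-255 scale.
#' @param morph_radius_um Structuring-element radius for opening/closing, um
#'   (0 disables the morphological cleanup).
#' @return A [semantic_mask()]. A blank image yields an all-background mask.
#' @export
baseline_segment <- function(image, pixel_size, threshold = "otsu",
                             morph_radius_um = 0) {
  if (!is.matrix(image)) stopf("image must be a matrix")
  h <- nrow(image); w <- ncol(image)
  zeros <- function() semantic_mask(matrix(0L, h, w), pixel_size)
  if (diff(range(image)) == 0) return(zeros())
  img01 <- image / 255
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  } else {
    as.numeric(threshold) / 255
  }
  binary <- img01 > thr
  if (morph_radius_um > 0) {
    r_px <- max(1L, round(morph_radius_um / pixel_size))
    kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    binary <- EBImage::closing(EBImage::opening(binary * 1, kern), kern) > 0.5
  }
  bin <- matrix(as.vector(binary), h, w)
  if (!any(bin)) return(zeros())
  filled <- as.matrix(EBImage::fillHull(bin * 1)) > 0.5
  holes <- filled & !bin
  mye_lab <- label_components(bin, 8)
  # a hole's surrounding myelin component: label of any 8-neighbor
  hole_idx <- which(holes)
  keep <- logical(max(mye_lab))
  if (length(hole_idx) > 0) {
    hr <- (hole_idx - 1L) %% h + 1L
    hc <- (hole_idx - 1L) %/% h + 1L
    for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                   c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
      nr <- hr + o[1]; nc <- hc + o[2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      lab <- mye_lab[(nc[ok] - 1L) * h + nr[ok]]
      keep[lab[lab > 0L]] <- TRUE
    }
  }
  out <- matrix(0L, h, w)
  kept_mye <- bin & keep[pmax(mye_lab, 1L)] & mye_lab > 0L
  out[kept_mye] <- CLASS_MYELIN
  if (length(hole_idx) > 0) {
    # keep only holes of surviving components
    kept_filled <- holes & as.matrix(
      EBImage::fillHull(kept_mye * 1)) > 0.5
    out[kept_filled] <- CLASS_AXON
  }
  semantic_mask(out, pixel_size)
}

#' Separate a semantic mask into per-fiber instances
#'
#' Axon instances are the 8-connected components of the axon class. Each
#' myelin pixel is assigned to the instance of the nearest axon component by
#' a watershed-style flood over the distance transform restricted to myelin
#' pixels (multi-source breadth-first growth from the axon components,
#' 8-connected); ties are broken toward the smallest instance label, so the
#' result is deterministic. Myelin components reachable from no axon are
#' discarded and counted in `$discarded_myelin`.
#'
#' @param mask A [semantic_mask()].
#' @return An [instance_map()].
#' @export
separate_instances <- function(mask) {
  stopifnot(inherits(mask, "semantic_mask"))
  h <- nrow(mask); w <- ncol(mask)
  m <- unclass(mask); attributes(m) <- list(dim = c(h, w))
  axon <- m == CLASS_AXON
  myelin <- m == CLASS_MYELIN
  labels <- label_components(axon, 8)
  cur <- labels
  if (any(myelin) && max(labels) > 0) {
    offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
    big <- .Machine$integer.max
    repeat {
      nb <- matrix(big, h, w)
      for (o in offs) {
        s <- shift_matrix(cur, o[1], o[2], 0L)
        s[s == 0L] <- big
        nb <- pmin(nb, s)
      }
      grow <- myelin & cur == 0L & nb < big
      if (!any(grow)) break
      cur[grow] <- nb[grow]
    }
  }
  orphan <- myelin & cur == 0L
  discarded <- if (any(orphan)) max(label_components(orphan, 8)) else 0L
  roles <- matrix(0L, h, w)
  roles[axon] <- CLASS_AXON
  roles[myelin & cur > 0L] <- CLASS_MYELIN
  out_labels <- cur
  out_labels[roles == 0L] <- 0L
  instance_map(out_labels, roles, attr(mask, "pixel_size"),
               discarded_myelin = discarded)
}

class_pixels <- function(mask, class) {
  if (is.character(class)) {
    class <- match(class, c("background", "myelin", "axon")) - 1L
    if (is.na(class)) stopf("unknown class name")
  }
  unclass(mask) == class
}

#' Dice and IoU overlap scores for one class
#'
#' `Dice = 2|A n B| / (|A| + |B|)`, `IoU = |A n B| / |A u B|`. When both
#' masks are empty for the class, both scores are defined as 1.
#'
#' @param predicted,truth [semantic_mask()] objects of identical shape.
#' @param class Class to score: `"background"`, `"myelin"`, `"axon"` (or
#'   integer code 0/1/2).
#' @return A number in `[0, 1]`.
#' @export
dice_score <- function(predicted, truth, class = "axon") {
  if (!all(dim(predicted) == dim(truth)))
    stopf("mask shapes differ")
  a <- class_pixels(predicted, class)
  b <- class_pixels(truth, class)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice_score
#' @export
iou_score <- function(predicted, truth, class = "axon") {
  if (!all(dim(predicted) == dim(truth)))
    stopf("mask shapes differ")
  a <- class_pixels(predicted, class)
  b <- class_pixels(truth, class)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
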